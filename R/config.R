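#' Pipeline configuration
#'
#' Collects every numeric threshold used by the pipeline stages. Defaults follow
#' the published Iso-Seq desk-scale conventions: reads are kept at a minimum
#' predicted accuracy of 0.75, inserts are clustered into unigenes at 99%
#' identity and 90% coverage, exon-skipping detection uses exact 100-base
#' terminal anchors and keeps only internal indels strictly longer than 100
#' bases, and SSR scanning uses MISA-style minimum repeat counts.
#'
#' @param min_read_quality Minimum per-read predicted accuracy in (0,1].
#' @param cluster_identity Minimum pairwise identity for clustering and for the
#'   reciprocal identity check in AS detection, in (0,1]. Identity is matched
#'   columns divided by columns of the aligned core (terminal overhangs
#'   excluded, internal gap columns counted).
#' @param cluster_coverage Minimum fraction of the shorter sequence that must be
#'   covered by the aligned core, in (0,1].
#' @param anchor_len Terminal anchor length in bases used to group isoforms of
#'   one gene without a reference genome.
#' @param min_indel Indels must be strictly longer than this (bases) to count as
#'   an alternative-splicing event.
#' @param adapter5,adapter3 5' and 3' library adapters (uppercase ACGT).
#' @param adapter_max_mismatch Maximum Hamming mismatches allowed when locating
#'   an adapter.
#' @param min_orf_len Minimum ORF length in codons for a candidate coding
#'   region.
#' @param ssr_min_repeats Named numeric vector, names "1".."6": minimum repeat
#'   count per motif length for an SSR call.
#' @param polya_min_run Minimum terminal A-run length (bases) removed when
#'   trimming an insert.
#' @param anchor_mode Where terminal anchors are taken: `"unigene"` (transcript
#'   ends, default) or `"cds"` (ends of the complete ORF's CDS; isoforms
#'   without a complete ORF spanning at least `2 * anchor_len + 1` bases are
#'   then excluded). See the methods vignette for the trade-off.
#' @param kmer_filter Use a shared 12-mer containment prefilter to skip
#'   hopeless alignments during clustering. Output is unchanged; it only skips
#'   pairs that cannot reach the identity threshold in practice.
#'
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$cluster_identity
#' @export
pipeline_config <- function(min_read_quality = 0.75,
                            cluster_identity = 0.99,
                            cluster_coverage = 0.90,
                            anchor_len = 100L,
                            min_indel = 100L,
                            adapter5 = "AAGCAGTGGTATCAACGCAG",
                            adapter3 = "GTACTCTGCGTTGATACCAC",
                            adapter_max_mismatch = 2L,
                            min_orf_len = 100L,
                            ssr_min_repeats = c(`1` = 10, `2` = 6, `3` = 5,
                                                `4` = 5, `5` = 4, `6` = 4),
                            polya_min_run = 10L,
                            anchor_mode = c("unigene", "cds"),
                            kmer_filter = TRUE) {
  anchor_mode <- match.arg(anchor_mode)
  cfg <- list(
    min_read_quality = as.numeric(min_read_quality),
    cluster_identity = as.numeric(cluster_identity),
    cluster_coverage = as.numeric(cluster_coverage),
    anchor_len = as.integer(anchor_len),
    min_indel = as.integer(min_indel),
    adapter5 = toupper(adapter5),
    adapter3 = toupper(adapter3),
    adapter_max_mismatch = as.integer(adapter_max_mismatch),
    min_orf_len = as.integer(min_orf_len),
    ssr_min_repeats = ssr_min_repeats,
    polya_min_run = as.integer(polya_min_run),
    anchor_mode = anchor_mode,
    kmer_filter = isTRUE(kmer_filter)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  frac <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      abort(sprintf("config key '%s' must be a fraction in (0, 1], got %s",
                    key, deparse(cfg[[key]])))
    }
  }
  frac("min_read_quality"); frac("cluster_identity"); frac("cluster_coverage")
  for (key in c("anchor_len", "min_indel", "adapter_max_mismatch",
                "min_orf_len", "polya_min_run")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < if (key == "adapter_max_mismatch") 0 else 1) {
      abort(sprintf("config key '%s' is out of range: %s", key, deparse(v)))
    }
  }
  for (key in c("adapter5", "adapter3")) {
    v <- cfg[[key]]
    if (!is.character(v) || length(v) != 1L || nchar(v) == 0L ||
        grepl("[^ACGT]", v)) {
      abort(sprintf("config key '%s' must be a non-empty ACGT string", key))
    }
  }
  if (identical(cfg$adapter5, cfg$adapter3)) {
    abort("config keys 'adapter5' and 'adapter3' must be distinct")
  }
  smr <- cfg$ssr_min_repeats
  if (is.null(names(smr)) || !setequal(names(smr), as.character(1:6)) ||
      any(!is.finite(smr)) || any(smr < 1)) {
    abort("config key 'ssr_min_repeats' must map motif lengths \"1\"..\"6\" to counts >= 1")
  }
  invisible(cfg)
}

#' Read and write a pipeline configuration as JSON
#'
#' `load_config()` reads a JSON object whose keys are arguments of
#' [pipeline_config()]; missing keys take the documented defaults and unknown
#' keys are rejected. `write_config()` writes a configuration so that
#' `load_config(write_config(cfg))` round-trips.
#'
#' @param path Path to a JSON file.
#' @return `load_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) abort("config file must contain a JSON object")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$ssr_min_repeats)) {
    raw$ssr_min_repeats <- unlist(raw$ssr_min_repeats)
  }
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  out$ssr_min_repeats <- as.list(out$ssr_min_repeats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (key in names(x)) {
    v <- x[[key]]
    cat(sprintf("  %-22s %s\n", key,
                if (length(v) > 1L) paste(names(v), v, sep = ":", collapse = " ")
                else as.character(v)))
  }
  invisible(x)
}
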