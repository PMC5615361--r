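#' Locate an adapter in a read
#'
#' Reports every start position (1-based) at which the adapter matches the
#' sequence with at most `max_mismatch` Hamming mismatches (no indels),
#' sorted ascending. An adapter longer than the sequence yields no matches.
#'
#' @param seq Nucleotide string.
#' @param adapter Adapter string, shorter than `seq` for a match to exist.
#' @param max_mismatch Maximum number of mismatching positions.
#' @return Integer vector of 1-based start positions.
#' @examples
#' find_adapter("GACGTACGTA", "CGTA", max_mismatch = 0)
#' @export
find_adapter <- function(seq, adapter, max_mismatch = 0L) {
  if (nchar(adapter) > nchar(seq)) return(integer(0))
  hits <- Biostrings::matchPattern(
    adapter, Biostrings::DNAString(seq),
    max.mismatch = as.integer(max_mismatch), with.indels = FALSE
  )
  pos <- sort(Biostrings::start(hits))
  # drop partial matches hanging over either end of the sequence
  pos[pos >= 1L & pos <= nchar(seq) - nchar(adapter) + 1L]
}

#' Classify long reads by adapter content
#'
#' Desk-scale re-implementation of full-length read classification: a read
#' below the minimum predicted accuracy is `LOWQ`; a read in which either
#' adapter occurs more than once, or in which the 3' adapter lies 5' of (or
#' overlaps) the 5' adapter, is `CHIMERIC`; a read containing both adapters
#' exactly once and in order is full-length non-chimeric (`FLNC`) and its
#' insert is trimmed out; anything else is `NONFL`. Every read receives
#' exactly one label. Reads without a quality value (FASTA input) are never
#' `LOWQ`.
#'
#' @param reads Tibble with columns `id`, `seq`, and optionally `quality`.
#' @param cfg A [pipeline_config()].
#' @return A tibble with columns `read_id`, `category` (one of FLNC, NONFL,
#'   CHIMERIC, LOWQ), `insert_seq` (non-NA iff FLNC), `adapter5_pos`,
#'   `adapter3_pos` (1-based starts, NA when absent or ambiguous), `quality`.
#' @examples
#' cfg <- pipeline_config()
#' rd <- tibble::tibble(
#'   id = "r1",
#'   seq = paste0(cfg$adapter5, "ATGAAATAG", strrep("A", 12), cfg$adapter3),
#'   quality = 0.99
#' )
#' classify_reads(rd, cfg)
#' @export
classify_reads <- function(reads, cfg) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  quality <- if ("quality" %in% names(reads)) reads$quality else
    rep(NA_real_, nrow(reads))
  rows <- pmap(list(reads$id, reads$seq, quality), function(id, seq, q) {
    classify_one(id, seq, q, cfg)
  })
  bind_rows(rows)
}

classify_one <- function(id, seq, quality, cfg) {
  out <- tibble(read_id = id, category = NA_character_,
                insert_seq = NA_character_,
                adapter5_pos = NA_integer_, adapter3_pos = NA_integer_,
                quality = quality)
  if (!is.na(quality) && quality < cfg$min_read_quality) {
    out$category <- "LOWQ"
    return(out)
  }
  h5 <- find_adapter(seq, cfg$adapter5, cfg$adapter_max_mismatch)
  h3 <- find_adapter(seq, cfg$adapter3, cfg$adapter_max_mismatch)
  if (length(h5) > 1L || length(h3) > 1L) {
    out$category <- "CHIMERIC"
    return(out)
  }
  if (length(h5) == 1L && length(h3) == 1L) {
    a5_end <- h5 + nchar(cfg$adapter5) - 1L
    if (h3 <= a5_end) {
      out$category <- "CHIMERIC"  # disordered or overlapping adapters
      return(out)
    }
    out$category <- "FLNC"
    out$adapter5_pos <- h5
    out$adapter3_pos <- h3
    out$insert_seq <- trim_to_insert(seq, a5_end, h3, cfg$polya_min_run)
    return(out)
  }
  out$category <- "NONFL"
  out
}

#' Trim an FLNC read to its insert
#'
#' Returns the bases strictly between the end of the 5' adapter match and the
#' start of the 3' adapter match, with one maximal terminal poly(A) run of at
#' least `polya_min_run` A's removed from the 3' end. Internal A-runs are
#' retained.
#'
#' @param seq Read sequence.
#' @param adapter5_end 1-based last position of the 5' adapter match.
#' @param adapter3_start 1-based first position of the 3' adapter match.
#' @param polya_min_run Minimum terminal A-run length to strip.
#' @return The insert sequence.
#' @export
trim_to_insert <- function(seq, adapter5_end, adapter3_start, polya_min_run = 10L) {
  if (adapter3_start <= adapter5_end) {
    abort("trim_to_insert(): adapter matches overlap; read should not be FLNC")
  }
  insert <- substr(seq, adapter5_end + 1L, adapter3_start - 1L)
  sub(sprintf("A{%d,}$", as.integer(polya_min_run)), "", insert)
}
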