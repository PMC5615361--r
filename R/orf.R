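#' Enumerate candidate open reading frames
#'
#' Scans the three forward frames of a sequence and reports every maximal ORF:
#' `COMPLETE` (ATG through an in-frame stop, stop codon included in the CDS),
#' `PARTIAL5` (frame open at the 5' end, running to the first stop),
#' `PARTIAL3` (ATG running off the 3' end with no stop), and `INTERNAL` (open
#' at both ends). An open-ended (`PARTIAL5`/`INTERNAL`) candidate whose span
#' is contained inside another candidate's span is redundant and pruned, so a
#' clean `ATG...stop` transcript yields a single candidate. The reverse strand
#' is not searched: inserts are orientation-resolved by adapter classification
#' upstream. Candidates shorter than `min_len` codons are dropped.
#'
#' @param seq Nucleotide string.
#' @param min_len Minimum candidate length in codons (stop codon included for
#'   stop-terminated candidates).
#' @return A tibble with columns `start`, `end` (0-based half-open), `frame`
#'   (0/1/2), `completeness`, `cds_seq`, `protein_len` (residues, excluding
#'   the stop). Empty tibble when nothing qualifies.
#' @examples
#' find_candidate_orfs("ATGAAATAA", min_len = 1)
#' @export
find_candidate_orfs <- function(seq, min_len = 100L) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + 1L + 3L * (0:(n_codons - 1L))
    codons <- substring(seq, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)

    # segment boundaries in codon index space: (prev_stop, next_stop]
    seg_starts <- c(1L, stop_idx + 1L)
    seg_stops <- c(stop_idx, NA_integer_)  # NA = runs off the 3' end
    for (k in seq_along(seg_starts)) {
      s0 <- seg_starts[k]
      s1 <- seg_stops[k]
      open5 <- s0 == 1L           # no stop precedes this segment
      open3 <- is.na(s1)
      last_codon <- if (open3) n_codons else s1
      if (s0 > last_codon) next
      atg_here <- which(is_atg[s0:last_codon])
      first_atg <- if (length(atg_here)) s0 + atg_here[1] - 1L else NA_integer_

      emit <- function(c0, c1, completeness) {
        start0 <- starts[c0] - 1L
        end0 <- starts[c1] + 2L
        ncod <- c1 - c0 + 1L
        if (ncod < min_len) return(NULL)
        tibble(
          start = start0, end = end0, frame = frame,
          completeness = completeness,
          cds_seq = substr(seq, start0 + 1L, end0),
          protein_len = if (completeness %in% c("COMPLETE", "PARTIAL5"))
            ncod - 1L else ncod
        )
      }
      if (!is.na(first_atg) && !open3) {
        out[[length(out) + 1L]] <- emit(first_atg, s1, "COMPLETE")
      }
      if (!is.na(first_atg) && open3 && first_atg <= last_codon) {
        out[[length(out) + 1L]] <- emit(first_atg, last_codon, "PARTIAL3")
      }
      if (open5 && !open3 && (is.na(first_atg) || first_atg > s0)) {
        out[[length(out) + 1L]] <- emit(s0, s1, "PARTIAL5")
      }
      if (open5 && open3 && (is.na(first_atg) || first_atg > s0)) {
        out[[length(out) + 1L]] <- emit(s0, last_codon, "INTERNAL")
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(0), end = integer(0), frame = integer(0),
                  completeness = character(0), cds_seq = character(0),
                  protein_len = integer(0)))
  }
  res <- bind_rows(out)
  open_ended <- res$completeness %in% c("PARTIAL5", "INTERNAL")
  contained <- vapply(seq_len(nrow(res)), function(i) {
    open_ended[i] && any(res$start <= res$start[i] & res$end >= res$end[i] &
                           (res$start != res$start[i] | res$end != res$end[i]))
  }, logical(1))
  res <- res[!contained, , drop = FALSE]
  arrange(res, .data$start, .data$frame)
}

#' Select the best candidate ORF
#'
#' Score is the CDS nucleotide length plus a 30-nt bonus for `COMPLETE`
#' candidates (so a complete ORF outranks an incomplete one up to 30 nt
#' longer); ties are broken by smaller start, then lower frame.
#'
#' @param candidates Tibble from [find_candidate_orfs()] for one unigene.
#' @return A one-row tibble, or `NULL` when `candidates` is empty.
#' @export
select_best_orf <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  score <- (candidates$end - candidates$start) +
    30L * (candidates$completeness == "COMPLETE")
  ord <- order(-score, candidates$start, candidates$frame)
  candidates[ord[1], ]
}

#' Annotate unigenes with their best ORF
#'
#' Runs [find_candidate_orfs()] and [select_best_orf()] over a unigene table.
#' Unigenes without any qualifying candidate are omitted from the result (a
#' sizeable fraction of real transcript sets has none).
#'
#' @param unigenes Tibble with columns `unigene_id` (or `id`) and `seq`.
#' @param cfg A [pipeline_config()]; `min_orf_len` is used.
#' @return A tibble with `unigene_id` plus the [find_candidate_orfs()]
#'   columns of the selected ORF.
#' @export
annotate_orfs <- function(unigenes, cfg) {
  id_col <- if ("unigene_id" %in% names(unigenes)) "unigene_id" else "id"
  rows <- pmap(list(unigenes[[id_col]], unigenes$seq), function(uid, s) {
    best <- select_best_orf(find_candidate_orfs(s, min_len = cfg$min_orf_len))
    if (is.null(best)) return(NULL)
    best$unigene_id <- uid
    best
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0L) {
    return(tibble(unigene_id = character(0), start = integer(0),
                  end = integer(0), frame = integer(0),
                  completeness = character(0), cds_seq = character(0),
                  protein_len = integer(0)))
  }
  res[, c("unigene_id", "start", "end", "frame", "completeness",
          "cds_seq", "protein_len")]
}

#' Summarise ORF completeness
#'
#' @param orfs Tibble from [annotate_orfs()].
#' @param n_unigenes Total number of unigenes scanned (to count the NONE
#'   class).
#' @return A tibble with one row per completeness class (including `NONE`),
#'   columns `completeness`, `n`, `fraction`, `mean_cds_len`.
#' @export
orf_summary <- function(orfs, n_unigenes) {
  classes <- c("COMPLETE", "PARTIAL5", "PARTIAL3", "INTERNAL")
  counts <- vapply(classes, function(cl) sum(orfs$completeness == cl), integer(1))
  mean_len <- vapply(classes, function(cl) {
    sel <- orfs$completeness == cl
    if (any(sel)) mean(orfs$end[sel] - orfs$start[sel]) else NA_real_
  }, numeric(1))
  tibble(
    completeness = c(classes, "NONE"),
    n = unname(c(counts, n_unigenes - nrow(orfs))),
    fraction = unname(c(counts, n_unigenes - nrow(orfs))) / n_unigenes,
    mean_cds_len = unname(c(mean_len, NA_real_))
  )
}

#' Translate annotated coding sequences
#'
#' @param orfs Tibble from [annotate_orfs()].
#' @return `orfs` with an added `protein_seq` column (stop codon dropped for
#'   stop-terminated ORFs; standard genetic code).
#' @export
translate_orfs <- function(orfs) {
  orfs$protein_seq <- vapply(seq_len(nrow(orfs)), function(i) {
    cds <- orfs$cds_seq[i]
    if (orfs$completeness[i] %in% c("COMPLETE", "PARTIAL5")) {
      cds <- substr(cds, 1L, nchar(cds) - 3L)
    }
    cds <- substr(cds, 1L, 3L * (nchar(cds) %/% 3L))
    if (nchar(cds) == 0L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  }, character(1))
  orfs
}

#' Write ORF annotations as GFF3
#'
#' Coordinates are converted to the 1-based closed convention of GFF3.
#'
#' @param orfs Tibble from [annotate_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_gff3 <- function(orfs, path) {
  lines <- c("##gff-version 3")
  if (nrow(orfs) > 0L) {
    lines <- c(lines, sprintf(
      "%s\tisoformscope\tCDS\t%d\t%d\t.\t+\t0\tID=cds-%s;frame=%d;completeness=%s",
      orfs$unigene_id, orfs$start + 1L, orfs$end,
      orfs$unigene_id, orfs$frame, orfs$completeness
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
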