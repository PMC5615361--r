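#' Read sequences from FASTA
#'
#' Parses a FASTA file into a tibble of sequence records. Multi-line sequences
#' are concatenated, sequences are uppercased on ingest, record order is
#' preserved, and the id is the first whitespace-delimited token of the header.
#' Characters outside `A,C,G,T,N` and duplicated ids are rejected rather than
#' silently mapped.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `seq` (character).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC", "gt", ">b", "TTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  check_fasta_structure(path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  records_from_stringset(set, path)
}

# light structural scan so errors can name a line number, which the
# Biostrings parser does not report
check_fasta_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) abort(paste0("empty FASTA file: ", path))
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(sprintf("%s:%d: expected FASTA header starting with '>'",
                  path, nonblank[1]))
  }
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    if (!nzchar(trimws(sub("^>", "", lines[h])))) {
      abort(sprintf("%s:%d: malformed FASTA header (empty id)", path, h))
    }
    if (h == length(lines) || startsWith(lines[h + 1L], ">") ||
        !nzchar(trimws(lines[h + 1L]))) {
      abort(sprintf("%s:%d: record has an empty sequence", path, h))
    }
  }
  invisible(TRUE)
}

records_from_stringset <- function(set, path) {
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("%s: duplicate record id '%s'", path, ids[duplicated(ids)][1]))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("%s: record '%s' contains characters outside {A,C,G,T,N}",
                  path, ids[bad][1]))
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("%s: record '%s' has an empty sequence",
                  path, ids[!nzchar(seqs)][1]))
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param records A tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param wrap Line width for the sequence body (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = as.integer(wrap))
  invisible(path)
}

#' Read reads from FASTQ
#'
#' Parses a 4-line-record Sanger (Phred+33) FASTQ file. The per-read `quality`
#' is the mean per-base accuracy, where a base with Phred score Q has accuracy
#' `1 - 10^(-Q/10)`; a read with all-Phred-40 bases therefore has quality
#' 0.9999. A published minimum "read quality of 75" corresponds to 0.75 on this
#' scale.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `seq`, and `quality` (fraction in
#'   \[0,1\]).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  check_fastq_structure(path)
  set <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
    ),
    error = function(e) {
      abort(sprintf("%s: malformed FASTQ (%s)", path, conditionMessage(e)))
    }
  )
  rec <- records_from_stringset(set, path)
  qints <- as(Biostrings::quality(set), "IntegerList")
  rec$quality <- vapply(qints, function(q) mean(1 - 10^(-q / 10)), numeric(1))
  rec
}

# structural scan: 4-line records with matching sequence/quality lengths
check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("%s: malformed FASTQ (truncated record: %d lines, not a multiple of 4)",
                  path, length(lines)))
  }
  for (r in seq_len(length(lines) %/% 4L)) {
    base <- 4L * (r - 1L)
    if (!startsWith(lines[base + 1L], "@") || !startsWith(lines[base + 3L], "+")) {
      abort(sprintf("%s:%d: malformed FASTQ record header", path, base + 1L))
    }
    if (nchar(lines[base + 2L]) != nchar(lines[base + 4L])) {
      abort(sprintf("%s:%d: sequence and quality lengths differ", path, base + 2L))
    }
  }
  invisible(TRUE)
}

#' Write reads to FASTQ
#'
#' The fractional per-read quality is encoded as a constant per-base Phred+33
#' score `round(-10 * log10(1 - quality))`, capped at 41; `quality = 1` maps to
#' the cap.
#'
#' @param records A tibble with columns `id`, `seq`, and `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq", "quality") %in% names(records)))
  phred <- ifelse(records$quality >= 1, 41L,
                  pmin(41L, pmax(0L, round(-10 * log10(1 - records$quality)))))
  qual_str <- vapply(seq_len(nrow(records)), function(i) {
    strrep(rawToChar(as.raw(phred[i] + 33L)), nchar(records$seq[i]))
  }, character(1))
  set <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(records$seq, records$id)),
    Biostrings::PhredQuality(qual_str)
  )
  Biostrings::writeQualityScaledXStringSet(set, path)
  invisible(path)
}
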