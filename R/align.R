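#' Semi-global pairwise alignment
#'
#' Optimal ends-free (semi-global) alignment of two nucleotide sequences under
#' affine gap penalties: match +2, mismatch -3, gap open -5, gap extension -1
#' per gapped base, terminal gaps free. A shorter sequence therefore nests in a
#' longer one without penalty. The dynamic programming is delegated to
#' [Biostrings::pairwiseAlignment()] with `type = "overlap"`.
#'
#' Identity is matched columns divided by the number of columns of the aligned
#' core, i.e. the columns between the first and last column in which both rows
#' carry a base; internal gap columns count against identity, terminal
#' overhangs do not. Coverage is the fraction of the shorter sequence's bases
#' that lie inside the aligned core.
#'
#' @param a,b Non-empty uppercase nucleotide strings.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters (signs as usual:
#'   `match` positive, the others penalties given as positive magnitudes for
#'   `gap_open`/`gap_ext` and a negative value for `mismatch`).
#' @return A list of class `pair_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings whose ungapped content recovers
#'   the inputs), `score`, `identity`, `coverage`, and `core` (first/last core
#'   column, 1-based).
#' @examples
#' aln <- align_pair("ACGTACGT", "ACGACGT")
#' aln$identity  # 7/8: one internal gap column
#' @export
align_pair <- function(a, b, match = 2, mismatch = -3, gap_open = 5, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("align_pair(): sequences must be non-empty")
  if (a == b) {  # trivial alignment; skips the DP for identical inputs
    return(structure(list(
      a = a, b = b, aligned_a = a, aligned_b = b,
      score = match * nchar(a), identity = 1, coverage = 1,
      core = c(1L, nchar(a))
    ), class = "pair_alignment"))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext
  )
  core_a <- as.character(Biostrings::alignedPattern(pa))
  core_b <- as.character(Biostrings::alignedSubject(pa))
  ps <- Biostrings::start(Biostrings::pattern(pa))
  pe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))

  a_pre <- substr(a, 1L, ps - 1L); a_suf <- substr(a, pe + 1L, nchar(a))
  b_pre <- substr(b, 1L, ss - 1L); b_suf <- substr(b, se + 1L, nchar(b))
  aligned_a <- paste0(a_pre, strrep("-", nchar(b_pre)), core_a,
                      strrep("-", nchar(b_suf)), a_suf)
  aligned_b <- paste0(strrep("-", nchar(a_pre)), b_pre, core_b,
                      b_suf, strrep("-", nchar(a_suf)))

  ca <- strsplit(core_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(core_b, "", fixed = TRUE)[[1]]
  ncore <- length(ca)
  matches <- sum(ca == cb & ca != "-")
  shorter_len <- min(nchar(a), nchar(b))
  span_a <- pe - ps + 1L
  span_b <- se - ss + 1L
  shorter_span <- if (nchar(a) <= nchar(b)) span_a else span_b

  core_start <- nchar(a_pre) + nchar(b_pre) + 1L
  structure(list(
    a = a, b = b,
    aligned_a = aligned_a, aligned_b = aligned_b,
    score = Biostrings::score(pa),
    identity = if (ncore > 0) matches / ncore else 0,
    coverage = shorter_span / shorter_len,
    core = c(core_start, core_start + ncore - 1L)
  ), class = "pair_alignment")
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment> score %.1f, identity %.4f, coverage %.4f, %d columns\n",
              x$score, x$identity, x$coverage, nchar(x$aligned_a)))
  invisible(x)
}

# gap-excluded identity for the reciprocal comparison in AS detection:
# matched columns over the shorter input's length. Gap-run columns thereby
# never enter the denominator (a skipped exon costs nothing), but bases the
# aligner pushes into gap runs still count as unmatched — a decoy that shares
# anchors yet diverges internally cannot hide its divergence inside gaps,
# which a matches / non-gap-columns ratio would allow.
alignment_identity_nongap <- function(aln) {
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  sum(a[both] == b[both]) / min(nchar(aln$a), nchar(aln$b))
}

#' Center-star multiple sequence alignment
#'
#' Deterministic multiple alignment built by aligning every sequence to a
#' center sequence with [align_pair()] and merging under the "once a gap,
#' always a gap" rule: the master alignment reserves, after each center
#' position, the widest insertion any member requires, and member insertions
#' are left-justified within that block.
#'
#' @param seqs Named character vector of sequences (names are ids).
#' @param center_id Id of the center sequence; defaults to the longest
#'   (ties broken by id order).
#' @return A named character vector of equal-length gapped strings, in the
#'   input order.
#' @export
msa_center_star <- function(seqs, center_id = NULL) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (is.null(center_id)) {
    ord <- order(-nchar(seqs), names(seqs))
    center_id <- names(seqs)[ord[1]]
  }
  center <- seqs[[center_id]]
  lc <- nchar(center)
  others <- setdiff(names(seqs), center_id)

  # per-member: member char per center position, and insertion string after
  # each center position (index 0..lc, 0 = before the first base)
  parsed <- lapply(others, function(id) {
    aln <- align_pair(center, seqs[[id]])
    ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
    cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
    pos <- cumsum(ca != "-")          # center position of each column
    at_base <- ca != "-"
    chars <- cb[at_base]              # member char at each center position
    ins <- character(lc + 1L)
    if (any(!at_base)) {
      runs <- rle(at_base)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(!runs$values)) {
        p <- if (starts[k] == 1L) 0L else pos[starts[k] - 1L]
        ins[p + 1L] <- paste(cb[starts[k]:ends[k]], collapse = "")
      }
    }
    list(chars = chars, ins = ins)
  })
  names(parsed) <- others

  ins_width <- integer(lc + 1L)
  for (p in parsed) ins_width <- pmax(ins_width, nchar(p$ins))

  build_row <- function(chars, ins) {
    blocks <- character(2L * lc + 1L)
    for (i in 0:lc) {
      pad <- ins_width[i + 1L] - nchar(ins[i + 1L])
      blocks[2L * i + 1L] <- paste0(ins[i + 1L], strrep("-", pad))
    }
    if (lc > 0L) blocks[2L * (1:lc)] <- chars
    paste(blocks, collapse = "")
  }
  rows <- setNames(vector("character", length(seqs)), names(seqs))
  center_chars <- strsplit(center, "", fixed = TRUE)[[1]]
  rows[[center_id]] <- build_row(center_chars, character(lc + 1L))
  for (id in others) rows[[id]] <- build_row(parsed[[id]]$chars, parsed[[id]]$ins)
  rows[names(seqs)]
}
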