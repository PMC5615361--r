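#' Assembly length statistics
#'
#' Sequence count, total and mean length, N50 (the length at which the
#' cumulative length of sequences sorted in descending order first reaches
#' half the total), and a histogram over 1-kb bins up to >6 kb, matching the
#' library size fractions commonly used for full-length cDNA sequencing.
#'
#' @param seqs Tibble with a `seq` column (ids optional).
#' @return An object of class `length_stats` with fields `n_seqs`,
#'   `total_len`, `mean_len`, `n50`, `histogram` (tibble `bin`, `n`). Use
#'   [glance()] for a one-row summary and [tidy()] for the histogram.
#' @examples
#' glance(length_stats(tibble::tibble(seq = strrep("A", c(2, 3, 4, 7)))))
#' @export
length_stats <- function(seqs) {
  if (is.null(seqs) || nrow(seqs) == 0L) abort("length_stats(): empty input")
  len <- nchar(seqs$seq)
  sorted <- sort(len, decreasing = TRUE)
  total <- sum(len)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  edges <- c(0, 1000, 2000, 3000, 4000, 5000, 6000, Inf)
  labels <- c("0-1kb", "1-2kb", "2-3kb", "3-4kb", "4-5kb", "5-6kb", ">6kb")
  binned <- cut(len, breaks = edges, labels = labels, right = FALSE)
  structure(list(
    n_seqs = length(len),
    total_len = total,
    mean_len = mean(len),
    n50 = n50,
    histogram = tibble(bin = labels,
                       n = as.integer(table(factor(binned, levels = labels))))
  ), class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf("<length_stats> n = %d, total = %d bp, mean = %.1f bp, N50 = %d bp\n",
              x$n_seqs, x$total_len, x$mean_len, x$n50))
  invisible(x)
}

#' @rdname length_stats
#' @param x An object of class `length_stats`.
#' @param ... Unused.
#' @export
glance.length_stats <- function(x, ...) {
  tibble(n_seqs = x$n_seqs, total_len = x$total_len,
         mean_len = x$mean_len, n50 = x$n50)
}

#' @rdname length_stats
#' @export
tidy.length_stats <- function(x, ...) x$histogram

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a treated sample relative to a control
#' sample, each normalised to a reference gene:
#' `2^-((Ct_target,treated - Ct_ref,treated) - (Ct_target,control - Ct_ref,control))`.
#' All arguments are vectorised over biological replicates.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Finite threshold-cycle values.
#' @return Numeric vector of fold changes.
#' @examples
#' fold_change_ddct(19, 15, 20, 15)  # 2.0
#' @export
fold_change_ddct <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  vals <- list(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(vapply(vals, function(v) any(!is.finite(v)), logical(1)))) {
    abort("fold_change_ddct(): all Ct values must be finite")
  }
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Summarise per-replicate fold changes
#'
#' Mean and standard error over biological replicates, the conventional way
#' qRT-PCR fold changes are reported.
#'
#' @param fc Numeric vector of per-replicate fold changes.
#' @return One-row tibble with `mean_fc`, `se_fc`, `n`.
#' @export
fold_change_summary <- function(fc) {
  tibble(mean_fc = mean(fc),
         se_fc = if (length(fc) > 1L) stats::sd(fc) / sqrt(length(fc)) else NA_real_,
         n = length(fc))
}
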