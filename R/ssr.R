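#' Canonical SSR motif class
#'
#' Maps a repeat unit to its canonical class: the lexicographically smallest
#' string among all rotations of the motif and all rotations of its reverse
#' complement, so that GA, CT and TC all report as AG. The motif must be a
#' minimal unit (not itself a repetition of a shorter motif).
#'
#' @param motif Character vector of repeat units, each 1-6 bases over ACGT.
#' @return Character vector of canonical classes.
#' @examples
#' canonical_motif(c("GA", "TC", "AAG", "ATG"))
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n < 1L || n > 6L || grepl("[^ACGT]", m)) {
      abort(sprintf("motif '%s' must be 1-6 bases over ACGT", m))
    }
    if (minimal_period(m) < n) {
      abort(sprintf(
        "motif '%s' is a repetition of a shorter unit; use the minimal unit", m))
    }
    rc <- revcomp(m)
    min(c(rotations(m), rotations(rc)))
  }, character(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  n <- nchar(m)
  vapply(seq_len(n), function(i) {
    paste0(substr(m, i, n), substr(m, 1L, i - 1L))
  }, character(1))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

minimal_period <- function(m) {
  n <- nchar(m)
  for (d in seq_len(n)) {
    if (n %% d == 0L && strrep(substr(m, 1L, d), n %/% d) == m) return(d)
  }
  n
}

#' Scan sequences for simple sequence repeats
#'
#' Finds all maximal perfect tandem repeats of unit length 1-6 meeting the
#' per-unit-length minimum repeat counts in `cfg$ssr_min_repeats` (MISA
#' convention by default: mono 10, di 6, tri 5, tetra 5, penta 4, hexa 4).
#' Each locus is reported once, under its minimal unit and leftmost phase,
#' trimmed to whole units; a region whose unit is a repetition of a shorter
#' motif is reported only at the shorter unit length. Only perfect repeats are
#' detected (no compound or interrupted SSRs).
#'
#' @param seqs Tibble with columns `id` (or `unigene_id`) and `seq`.
#' @param cfg A [pipeline_config()].
#' @return A tibble with columns `seq_id`, `motif` (unit as found),
#'   `canonical` (class from [canonical_motif()]), `repeats`, `start`, `end`
#'   (0-based half-open).
#' @export
scan_ssrs <- function(seqs, cfg = pipeline_config()) {
  id_col <- if ("unigene_id" %in% names(seqs)) "unigene_id" else "id"
  hits <- pmap(list(seqs[[id_col]], seqs$seq), function(sid, s) {
    h <- scan_ssrs_one(s, cfg$ssr_min_repeats)
    if (nrow(h) > 0L) h$seq_id <- sid
    h
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble(seq_id = character(0), motif = character(0),
                  canonical = character(0), repeats = integer(0),
                  start = integer(0), end = integer(0)))
  }
  hits[, c("seq_id", "motif", "canonical", "repeats", "start", "end")]
}

scan_ssrs_one <- function(s, min_repeats) {
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- list()
  for (l in 1:6) {
    minr <- min_repeats[[as.character(l)]]
    if (n < l * minr) next
    eq <- chars[seq_len(n - l)] == chars[seq_len(n - l) + l]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (w in which(r$values)) {
      # region [i, j + l] is periodic with period l
      region_len <- r$lengths[w] + l
      repeats <- region_len %/% l
      if (repeats < minr) next
      i <- starts[w]
      motif <- substr(s, i, i + l - 1L)
      if (minimal_period(motif) < l) next  # found at the shorter unit length
      out[[length(out) + 1L]] <- tibble(
        motif = motif,
        canonical = canonical_motif(motif),
        repeats = as.integer(repeats),
        start = i - 1L,
        end = i - 1L + repeats * l
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(motif = character(0), canonical = character(0),
                  repeats = integer(0), start = integer(0), end = integer(0)))
  }
  arrange(bind_rows(out), .data$start, .data$end)
}

#' Localize SSR hits relative to an ORF
#'
#' A hit lying entirely 5' of the CDS is `UTR5`, entirely 3' of it `UTR3`, and
#' any overlap with the CDS classifies it as `ORF`. Sequences without an ORF
#' annotation yield `NOORF`.
#'
#' @param hits Tibble from [scan_ssrs()].
#' @param orfs Tibble from [annotate_orfs()] (or `NULL`).
#' @return `hits` with an added `region` column.
#' @export
localize_ssrs <- function(hits, orfs = NULL) {
  if (nrow(hits) == 0L) {
    hits$region <- character(0)
    return(hits)
  }
  if (is.null(orfs) || nrow(orfs) == 0L) {
    hits$region <- "NOORF"
    return(hits)
  }
  om <- orfs[match(hits$seq_id, orfs$unigene_id), c("start", "end")]
  hits$region <- dplyr::case_when(
    is.na(om$start) ~ "NOORF",
    hits$end <= om$start ~ "UTR5",
    hits$start >= om$end ~ "UTR3",
    TRUE ~ "ORF"
  )
  hits
}

#' SSR frequency table
#'
#' Counts and within-unit-length fractions per canonical motif class,
#' stratified by region; fractions within each unit length sum to 1.
#'
#' @param hits Tibble from [scan_ssrs()] (with or without a `region` column).
#' @return A tibble with columns `unit_len`, `canonical`, `n`, `fraction`, and
#'   one `n_<region>` column per region present.
#' @export
ssr_summary <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(unit_len = integer(0), canonical = character(0),
                  n = integer(0), fraction = numeric(0)))
  }
  h <- hits
  h$unit_len <- nchar(h$canonical)
  base <- h |>
    group_by(.data$unit_len, .data$canonical) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  if ("region" %in% names(h)) {
    reg <- h |>
      group_by(.data$unit_len, .data$canonical, .data$region) |>
      summarise(n = n(), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "region", values_from = "n",
                         values_fill = 0L, names_prefix = "n_")
    base <- left_join(base, reg, by = c("unit_len", "canonical"))
  }
  arrange(base, .data$unit_len, desc(.data$n), .data$canonical)
}

#' Plot SSR motif frequencies
#'
#' @param summary Tibble from [ssr_summary()].
#' @return A ggplot object: motif-class frequencies faceted by unit length.
#' @importFrom ggplot2 facet_wrap
#' @export
plot_ssr_summary <- function(summary) {
  ggplot(summary, aes(x = stats::reorder(.data$canonical, -.data$n),
                      y = .data$fraction)) +
    geom_col(fill = "darkorange") +
    facet_wrap(~unit_len, scales = "free_x") +
    labs(x = "canonical motif", y = "fraction within unit length",
         title = "SSR motif frequencies")
}
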