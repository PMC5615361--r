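#' Terminal anchors of a coding region
#'
#' Extracts the exact `k`-base blocks at the 5' and 3' ends of a complete
#' coding sequence. These anchors group isoforms of one gene without a
#' reference genome: two transcripts of the same gene that differ by an
#' internal skipped exon still share both anchors exactly.
#'
#' @param cds Coding sequence (or whole unigene in unigene-anchor mode).
#' @param orf One-row ORF tibble ([annotate_orfs()]) or `NULL`. When supplied,
#'   a non-`COMPLETE` ORF is rejected.
#' @param k Anchor length in bases. The sequence must span at least
#'   `2 * k + 1` bases so the anchors do not overlap.
#' @return A list with elements `head` and `tail` (each exactly `k` bases), or
#'   `NULL` with a `reason` attribute when the record is excluded.
#' @export
orf_anchors <- function(cds, orf = NULL, k = 100L) {
  if (!is.null(orf) && orf$completeness != "COMPLETE") {
    return(structure(NULL_with_reason("ORF not COMPLETE")))
  }
  if (nchar(cds) < 2L * k + 1L) {
    return(structure(NULL_with_reason("sequence shorter than 2*k+1: anchors would overlap")))
  }
  list(head = substr(cds, 1L, k),
       tail = substr(cds, nchar(cds) - k + 1L, nchar(cds)))
}

NULL_with_reason <- function(reason) {
  structure(list(), class = "anchor_skip", reason = reason)
}

is_anchor_skip <- function(x) inherits(x, "anchor_skip")

#' Group unigenes by exact terminal anchors
#'
#' Partitions unigenes by exact equality of the (head, tail) anchor pair and
#' returns only groups of two or more members — the candidate
#' alternative-splicing groups. In `"cds"` anchor mode, only unigenes with a
#' `COMPLETE` ORF spanning at least `2 * anchor_len + 1` bases participate and
#' the compared sequence is the CDS; in `"unigene"` mode (default) anchors are
#' taken on the whole transcript and no ORF is required.
#'
#' @param unigenes Tibble with columns `unigene_id` (or `id`) and `seq`.
#' @param orfs Tibble from [annotate_orfs()]; required for `"cds"` mode.
#' @param cfg A [pipeline_config()].
#' @return A tibble with columns `group_id`, `anchor_head`, `anchor_tail`, and
#'   `members` (list-column of tibbles with `unigene_id`, `seq`). An attribute
#'   `skipped` records excluded records and reasons.
#' @export
group_by_anchors <- function(unigenes, orfs = NULL, cfg = pipeline_config()) {
  id_col <- if ("unigene_id" %in% names(unigenes)) "unigene_id" else "id"
  k <- cfg$anchor_len
  skipped <- list()
  rows <- list()
  for (i in seq_len(nrow(unigenes))) {
    uid <- unigenes[[id_col]][i]
    if (cfg$anchor_mode == "cds") {
      if (is.null(orfs)) abort("anchor_mode 'cds' requires an ORF table")
      o <- orfs[orfs$unigene_id == uid, , drop = FALSE]
      if (nrow(o) == 0L) {
        skipped[[length(skipped) + 1L]] <- tibble(unigene_id = uid, reason = "no ORF")
        next
      }
      target <- o$cds_seq[1]
      anc <- orf_anchors(target, o[1, ], k = k)
    } else {
      target <- unigenes$seq[i]
      anc <- orf_anchors(target, NULL, k = k)
    }
    if (is_anchor_skip(anc)) {
      skipped[[length(skipped) + 1L]] <-
        tibble(unigene_id = uid, reason = attr(anc, "reason"))
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      unigene_id = uid, seq = target,
      anchor_head = anc$head, anchor_tail = anc$tail
    )
  }
  if (length(rows) == 0L) {
    res <- tibble(group_id = character(0), anchor_head = character(0),
                  anchor_tail = character(0), members = list())
    attr(res, "skipped") <- bind_rows(skipped)
    return(res)
  }
  tab <- bind_rows(rows)
  keys <- paste(tab$anchor_head, tab$anchor_tail, sep = "|")
  groups <- split(seq_len(nrow(tab)), keys)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  # deterministic order: by first member id
  if (length(groups) > 0L) {
    first_ids <- vapply(groups, function(ix) min(tab$unigene_id[ix]), character(1))
    groups <- groups[order(first_ids)]
  }
  res <- tibble(
    group_id = sprintf("GRP_%04d", seq_along(groups)),
    anchor_head = vapply(groups, function(ix) tab$anchor_head[ix[1]], character(1)),
    anchor_tail = vapply(groups, function(ix) tab$anchor_tail[ix[1]], character(1)),
    members = lapply(groups, function(ix) {
      m <- tab[ix, c("unigene_id", "seq")]
      m[order(m$unigene_id), ]
    })
  )
  attr(res, "skipped") <- bind_rows(skipped)
  res
}

#' Reciprocal identity filter within a candidate group
#'
#' Checks every ordered pair of group members by semi-global alignment,
#' computing identity as matched columns over the shorter sequence's length —
#' gap-run columns never enter the denominator, so a genuine skipped exon does
#' not depress identity, while internally divergent decoys that share anchors
#' by chance do. A member is retained if it reaches
#' `cfg$cluster_identity` against at least one other member in both directions
#' of comparison; groups reduced below two members are discarded by the
#' caller.
#'
#' @param members Tibble with columns `unigene_id`, `seq`.
#' @param cfg A [pipeline_config()].
#' @return The filtered members tibble (possibly with fewer rows).
#' @export
reciprocal_identity <- function(members, cfg) {
  n <- nrow(members)
  if (n < 2L) return(members)
  pass <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ab <- alignment_identity_nongap(align_pair(members$seq[i], members$seq[j]))
      ba <- alignment_identity_nongap(align_pair(members$seq[j], members$seq[i]))
      ok <- ab >= cfg$cluster_identity && ba >= cfg$cluster_identity
      pass[i, j] <- ok
      pass[j, i] <- ok
    }
  }
  keep <- rowSums(pass) > 0L
  members[keep, , drop = FALSE]
}

#' Internal indel events of a pairwise alignment
#'
#' Every maximal run of consecutive gap columns lying strictly between the two
#' anchor regions becomes one event; runs separated by match columns are never
#' merged. Events are reported regardless of length — filtering against the
#' minimum alternative-splicing size happens in [build_as_clusters()].
#'
#' @param aln A [align_pair()] result for two group members; the first
#'   sequence (`a`) is taken as the reference.
#' @param anchor_len Anchor length `k`: the first and last `k` bases of the
#'   reference are anchor territory and events must lie strictly between.
#' @return A tibble with columns `start` (0-based position on the ungapped
#'   reference), `length` (bases), `kind` (`"deletion_in_alt"` for gaps in the
#'   second sequence, `"insertion_in_alt"` for gaps in the reference).
#' @export
detect_indels <- function(aln, anchor_len = 100L) {
  a <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  ref_len <- sum(a != "-")
  ref_pos_before <- cumsum(a != "-")  # ref bases consumed up to each column
  k <- anchor_len

  events <- list()
  gap_runs <- function(row_is_gap, kind) {
    r <- rle(row_is_gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (w in which(r$values)) {
      c0 <- starts[w]; c1 <- ends[w]
      len <- c1 - c0 + 1L
      if (kind == "deletion_in_alt") {
        ref_start <- ref_pos_before[c0] - 1L       # 0-based on ref
        inside <- ref_start >= k && (ref_start + len) <= (ref_len - k)
      } else {
        p <- if (c0 == 1L) 0L else ref_pos_before[c0 - 1L]  # insertion point
        inside <- p >= k && p <= (ref_len - k)
        ref_start <- p
      }
      if (inside) {
        events[[length(events) + 1L]] <<- tibble(
          start = as.integer(ref_start), length = as.integer(len), kind = kind
        )
      }
    }
  }
  gap_runs(b == "-" & a != "-", "deletion_in_alt")
  gap_runs(a == "-" & b != "-", "insertion_in_alt")
  if (length(events) == 0L) {
    return(tibble(start = integer(0), length = integer(0), kind = character(0)))
  }
  arrange(bind_rows(events), .data$start)
}

#' Build alternative-splicing clusters from anchor groups
#'
#' For each candidate group that survived the reciprocal identity filter,
#' events are called for every member against the group's reference (the
#' longest member, ties broken by id). A group becomes an AS cluster iff at
#' least one event is strictly longer than `cfg$min_indel` bases — the strict
#' inequality implements the published "more than 100 bases" rule, under which
#' a 78-base skipped exon is observed but not called as alternative splicing.
#' Groups whose members differ only by short indels or substitutions are
#' thereby excluded as ambiguous near-identical forms.
#'
#' @param groups Tibble from [group_by_anchors()].
#' @param cfg A [pipeline_config()].
#' @param validate Run [validate_msa()] on each reported cluster.
#' @return An object of class `as_result`: a list with `clusters` (tibble:
#'   `cluster_id`, `anchor_head`, `anchor_tail`, `member_ids` list-column,
#'   `n_members`, `n_events`, `n_qualifying`, `validated`), `events` (tibble:
#'   `cluster_id`, `ref_id`, `alt_id`, `start`, `length`, `kind`,
#'   `qualifying`), and `msa` (named list of per-cluster alignments).
#' @export
build_as_clusters <- function(groups, cfg, validate = TRUE) {
  clusters <- list()
  events_out <- list()
  msas <- list()
  for (g in seq_len(nrow(groups))) {
    members <- reciprocal_identity(groups$members[[g]], cfg)
    if (nrow(members) < 2L) next
    ord <- order(-nchar(members$seq), members$unigene_id)
    members <- members[ord, ]
    ref <- members[1, ]
    ev <- list()
    for (i in seq(2L, nrow(members))) {
      aln <- align_pair(ref$seq, members$seq[i])
      e <- detect_indels(aln, anchor_len = cfg$anchor_len)
      if (nrow(e) > 0L) {
        e$ref_id <- ref$unigene_id
        e$alt_id <- members$unigene_id[i]
        ev[[length(ev) + 1L]] <- e
      }
    }
    ev <- if (length(ev)) bind_rows(ev) else
      tibble(start = integer(0), length = integer(0), kind = character(0),
             ref_id = character(0), alt_id = character(0))
    ev$qualifying <- ev$length > cfg$min_indel
    if (!any(ev$qualifying)) next

    cid <- sprintf("AS_%04d", length(clusters) + 1L)
    ev$cluster_id <- cid
    seqs <- setNames(members$seq, members$unigene_id)
    msa <- msa_center_star(seqs, center_id = ref$unigene_id)
    validated <- if (validate) {
      validate_msa_events(msa, ev, ref$unigene_id)
    } else NA
    clusters[[length(clusters) + 1L]] <- tibble(
      cluster_id = cid,
      anchor_head = groups$anchor_head[g],
      anchor_tail = groups$anchor_tail[g],
      member_ids = list(members$unigene_id),
      n_members = nrow(members),
      n_events = nrow(ev),
      n_qualifying = sum(ev$qualifying),
      validated = validated
    )
    events_out[[length(events_out) + 1L]] <- ev
    msas[[cid]] <- msa
  }
  empty_events <- tibble(cluster_id = character(0), ref_id = character(0),
                         alt_id = character(0), start = integer(0),
                         length = integer(0), kind = character(0),
                         qualifying = logical(0))
  res <- list(
    clusters = if (length(clusters)) bind_rows(clusters) else
      tibble(cluster_id = character(0), anchor_head = character(0),
             anchor_tail = character(0), member_ids = list(),
             n_members = integer(0), n_events = integer(0),
             n_qualifying = integer(0), validated = logical(0)),
    events = if (length(events_out)) {
      e <- bind_rows(events_out)
      e[, c("cluster_id", "ref_id", "alt_id", "start", "length", "kind",
            "qualifying")]
    } else empty_events,
    msa = msas
  )
  structure(res, class = "as_result")
}

#' Validate an AS cluster by multiple alignment
#'
#' Rebuilds each qualifying pairwise event from the cluster's center-star
#' multiple alignment and flags the cluster as validated iff every qualifying
#' event reappears as a gap block of exactly the same length. Inconsistent
#' clusters are flagged, not dropped.
#'
#' @param cluster_msa Named character vector of gapped rows
#'   ([msa_center_star()]).
#' @param events Events tibble for this cluster ([build_as_clusters()]).
#' @param ref_id Id of the reference row.
#' @return Logical scalar.
#' @export
validate_msa <- function(cluster_msa, events, ref_id) {
  validate_msa_events(cluster_msa, events, ref_id)
}

validate_msa_events <- function(msa, events, ref_id) {
  qual <- events[events$qualifying, , drop = FALSE]
  if (nrow(qual) == 0L) return(TRUE)
  ref_row <- strsplit(msa[[ref_id]], "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(qual))) {
    alt_row <- strsplit(msa[[qual$alt_id[i]]], "", fixed = TRUE)[[1]]
    keep <- !(ref_row == "-" & alt_row == "-")
    a <- ref_row[keep]; b <- alt_row[keep]
    gap_in <- if (qual$kind[i] == "deletion_in_alt") b == "-" & a != "-" else
      a == "-" & b != "-"
    r <- rle(gap_in)
    lens <- r$lengths[r$values]
    if (!(qual$length[i] %in% lens)) return(FALSE)
  }
  TRUE
}

#' Detect exon-skipping clusters among unigenes
#'
#' End-to-end reference-free alternative-splicing detection: group unigenes by
#' exact terminal anchors ([group_by_anchors()]), filter by reciprocal
#' identity, call internal indels against each group's longest member, keep
#' groups with at least one indel strictly longer than `cfg$min_indel` bases,
#' and validate each reported cluster by center-star multiple alignment.
#'
#' @param unigenes Tibble with columns `unigene_id` (or `id`) and `seq`.
#' @param orfs Optional ORF table ([annotate_orfs()]); required when
#'   `cfg$anchor_mode == "cds"`.
#' @param cfg A [pipeline_config()].
#' @return An `as_result` object; see [build_as_clusters()]. Use [tidy()] for
#'   the event table, [glance()] for a one-row summary, and
#'   [ggplot2::autoplot()] for the indel-size histogram.
#' @export
detect_exon_skipping <- function(unigenes, orfs = NULL, cfg = pipeline_config()) {
  groups <- group_by_anchors(unigenes, orfs, cfg)
  res <- build_as_clusters(groups, cfg)
  attr(res, "skipped") <- attr(groups, "skipped")
  res
}

#' Report table and indel-size histogram for AS clusters
#'
#' Bins qualifying event sizes as in the field's standard presentation:
#' 101-200, 201-300, 301-400, and >400 bases (with the default
#' `min_indel = 100`).
#'
#' @param res An `as_result` object.
#' @param min_indel Lower strict bound used for the first bin edge.
#' @return A list with `table` (one row per cluster: id, member count, event
#'   sizes and 1-based positions) and `histogram` (tibble `bin`, `n`).
#' @export
as_report <- function(res, min_indel = 100L) {
  sizes <- res$events$length[res$events$qualifying]
  breaks <- c(min_indel, min_indel + 100L, min_indel + 200L, min_indel + 300L, Inf)
  labels <- c(sprintf("%d-%d", min_indel + 1L, min_indel + 100L),
              sprintf("%d-%d", min_indel + 101L, min_indel + 200L),
              sprintf("%d-%d", min_indel + 201L, min_indel + 300L),
              sprintf(">%d", min_indel + 300L))
  binned <- cut(sizes, breaks = breaks, labels = labels, right = TRUE)
  hist <- tibble(bin = labels,
                 n = as.integer(table(factor(binned, levels = labels))))
  tab <- res$clusters
  if (nrow(tab) > 0L) {
    ev_by_cluster <- split(res$events, res$events$cluster_id)
    tab$event_sizes <- vapply(tab$cluster_id, function(cid) {
      e <- ev_by_cluster[[cid]]
      paste(e$length[e$qualifying], collapse = ",")
    }, character(1))
    tab$event_positions <- vapply(tab$cluster_id, function(cid) {
      e <- ev_by_cluster[[cid]]
      paste(e$start[e$qualifying] + 1L, collapse = ",")  # 1-based in reports
    }, character(1))
  } else {
    tab$event_sizes <- character(0)
    tab$event_positions <- character(0)
  }
  list(table = tab[, setdiff(names(tab), "member_ids")], histogram = hist)
}

#' @export
print.as_result <- function(x, ...) {
  cat(sprintf("<as_result> %d AS cluster(s), %d qualifying event(s), %d validated\n",
              nrow(x$clusters), sum(x$events$qualifying),
              sum(x$clusters$validated, na.rm = TRUE)))
  invisible(x)
}

#' @rdname detect_exon_skipping
#' @param x,object An `as_result`.
#' @param ... Unused.
#' @export
tidy.as_result <- function(x, ...) x$events

#' @rdname detect_exon_skipping
#' @export
glance.as_result <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    n_events = nrow(x$events),
    n_qualifying = sum(x$events$qualifying),
    n_validated = sum(x$clusters$validated, na.rm = TRUE),
    median_event_size = if (any(x$events$qualifying))
      stats::median(x$events$length[x$events$qualifying]) else NA_real_
  )
}

#' @rdname detect_exon_skipping
#' @importFrom ggplot2 autoplot ggplot aes geom_col labs
#' @export
autoplot.as_result <- function(object, ...) {
  hist <- as_report(object)$histogram
  hist$bin <- factor(hist$bin, levels = hist$bin)
  ggplot(hist, aes(x = .data$bin, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = "indel size (bases)", y = "AS events",
         title = "Size distribution of alternative-splicing indels")
}
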