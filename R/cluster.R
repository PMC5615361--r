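#' Greedy identity clustering of inserts into unigenes
#'
#' CD-HIT-style greedy clustering: sequences are processed in order of
#' decreasing length (ties broken by id), and each sequence joins the first
#' existing cluster whose representative it matches at identity at least
#' `cfg$cluster_identity` and coverage at least `cfg$cluster_coverage`
#' (see [align_pair()] for the definitions); otherwise it founds a new
#' cluster. The representative of a cluster is its founding (longest) member,
#' so results are independent of input order.
#'
#' When `cfg$kmer_filter` is `TRUE`, a pair is aligned only if at least 30% of
#' the shorter sequence's distinct 12-mers occur in the representative; at 99%
#' identity and 90% coverage the expected containment exceeds 75%, so the
#' filter only skips alignments that could not pass.
#'
#' @param seqs Tibble with columns `id` and `seq` (typically FLNC inserts).
#' @param cfg A [pipeline_config()].
#' @return A tibble with columns `cluster_id`, `rep_id`, `member_ids`
#'   (list-column), `n_members`.
#' @export
greedy_cluster <- function(seqs, cfg) {
  stopifnot(nrow(seqs) > 0L, all(c("id", "seq") %in% names(seqs)))
  ord <- order(-nchar(seqs$seq), seqs$id)
  ids <- seqs$id[ord]
  sq <- seqs$seq[ord]

  rep_id <- character(0)
  rep_seq <- character(0)
  rep_kmers <- list()
  members <- list()

  for (i in seq_along(sq)) {
    s <- sq[i]
    placed <- FALSE
    km <- if (cfg$kmer_filter) kmer_set(s) else NULL
    for (j in seq_along(rep_seq)) {
      if (cfg$kmer_filter &&
          !kmer_compatible(km, rep_kmers[[j]], min_containment = 0.3)) next
      aln <- align_pair(s, rep_seq[j])
      if (aln$identity >= cfg$cluster_identity &&
          aln$coverage >= cfg$cluster_coverage) {
        members[[j]] <- c(members[[j]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      k <- length(rep_seq) + 1L
      rep_id[k] <- ids[i]
      rep_seq[k] <- s
      if (cfg$kmer_filter) rep_kmers[[k]] <- km
      members[[k]] <- ids[i]
    }
  }
  tibble(
    cluster_id = sprintf("CL_%04d", seq_along(rep_id)),
    rep_id = rep_id,
    member_ids = members,
    n_members = lengths(members)
  )
}

kmer_set <- function(seq, k = 12L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

kmer_compatible <- function(km_query, km_rep, min_containment = 0.3) {
  mean(km_query %in% km_rep) >= min_containment
}

#' Polish a cluster into a consensus unigene
#'
#' Column-wise majority vote over the center-star alignment of all members to
#' the cluster representative ([msa_center_star()]). Ties are resolved toward
#' the representative's character; a majority gap deletes the column, and an
#' insertion relative to the representative survives only with majority
#' support, so the consensus length can differ from the representative only at
#' majority-supported indel columns. A singleton cluster returns its
#' representative unchanged.
#'
#' @param rep_seq Representative sequence.
#' @param member_seqs Named character vector of all member sequences
#'   (including the representative).
#' @return Consensus sequence string.
#' @export
polish_unigene <- function(rep_seq, member_seqs) {
  if (length(member_seqs) <= 1L) return(rep_seq)
  if (all(member_seqs == rep_seq)) return(rep_seq)  # unanimous cluster
  rep_name <- names(member_seqs)[match(rep_seq, member_seqs)]
  if (is.na(rep_name)) {
    member_seqs <- c(`.rep` = rep_seq, member_seqs)
    rep_name <- ".rep"
  }
  msa <- msa_center_star(member_seqs, center_id = rep_name)
  mat <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  rep_row <- strsplit(msa[[rep_name]], "", fixed = TRUE)[[1]]

  letters5 <- c("A", "C", "G", "T", "-")
  counts <- vapply(letters5, function(ch) colSums(mat == ch),
                   numeric(ncol(mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)  # 1-column MSA
  nmax <- apply(counts, 1L, max)
  win <- letters5[apply(counts, 1L, which.max)]
  # ties toward the representative's character
  rep_idx <- match(rep_row, letters5)
  rep_count <- counts[cbind(seq_along(rep_row), rep_idx)]
  win[!is.na(rep_count) & rep_count == nmax] <-
    rep_row[!is.na(rep_count) & rep_count == nmax]
  paste(win[win != "-"], collapse = "")
}

#' Cluster FLNC inserts and emit polished unigenes
#'
#' Convenience wrapper chaining [greedy_cluster()] and [polish_unigene()],
#' assigning zero-padded unigene ids.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param cfg A [pipeline_config()].
#' @param id_prefix Prefix for unigene ids (default `"KG_SIM"`).
#' @return A tibble with columns `unigene_id`, `seq` (polished consensus),
#'   `rep_id`, `member_ids` (list-column), `n_members`.
#' @export
cluster_unigenes <- function(seqs, cfg, id_prefix = "KG_SIM") {
  cl <- greedy_cluster(seqs, cfg)
  seq_by_id <- setNames(seqs$seq, seqs$id)
  cl$unigene_id <- sprintf("%s_%06d", id_prefix, seq_len(nrow(cl)))
  cl$seq <- map2_chr_safe(cl$rep_id, cl$member_ids, function(rid, mids) {
    polish_unigene(seq_by_id[[rid]], seq_by_id[mids])
  })
  cl[, c("unigene_id", "seq", "rep_id", "member_ids", "n_members")]
}

map2_chr_safe <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))
}
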