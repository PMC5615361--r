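cfg <- pipeline_config()

# a full transcript and a variant lacking an internal block of `skip` bases,
# both long enough that the 100-base terminal anchors lie in shared sequence
make_skip_pair <- function(skip, total = 1200, at = 500, seed = 61) {
  withr::with_seed(seed, {
    full <- random_seq(total)
    list(full = full,
         skipped = paste0(substr(full, 1, at - 1),
                          substr(full, at + skip, total)))
  })
}

test_that("anchors are the exact terminal blocks and short CDSs are excluded", {
  cds <- strrep("ACGTT", 60)  # 300 bases
  anc <- orf_anchors(cds, k = 100)
  expect_equal(anc$head, substr(cds, 1, 100))
  expect_equal(anc$tail, substr(cds, 201, 300))

  expect_s3_class(orf_anchors(strrep("A", 150), k = 100), "anchor_skip")
  orf <- tibble::tibble(completeness = "PARTIAL3")
  expect_s3_class(orf_anchors(cds, orf, k = 100), "anchor_skip")
})

test_that("anchor grouping joins skip variants and is broken by one anchor substitution", {
  pair <- make_skip_pair(183)
  uni <- tibble::tibble(unigene_id = c("u_full", "u_skip"),
                        seq = c(pair$full, pair$skipped))
  grp <- group_by_anchors(uni, cfg = cfg)
  expect_equal(nrow(grp), 1)
  expect_equal(sort(grp$members[[1]]$unigene_id), c("u_full", "u_skip"))

  # mutate one base inside the head anchor of the skipped variant
  mut <- pair$skipped
  flip <- setdiff(c("A", "C", "G", "T"), substr(mut, 50, 50))[1]
  substr(mut, 50, 50) <- flip
  uni2 <- tibble::tibble(unigene_id = c("u_full", "u_skip"),
                         seq = c(pair$full, mut))
  expect_equal(nrow(group_by_anchors(uni2, cfg = cfg)), 0)

  # all singletons: empty result
  withr::local_seed(62)
  uni3 <- tibble::tibble(unigene_id = c("a", "b"),
                         seq = c(random_seq(500), random_seq(500)))
  expect_equal(nrow(group_by_anchors(uni3, cfg = cfg)), 0)
})

test_that("cds anchor mode groups on CDS ends and requires a complete ORF", {
  ccfg <- pipeline_config(anchor_mode = "cds")
  # construct codon-aligned skip pairs so both forms keep a full-span ORF
  withr::local_seed(63)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  mk_pair <- function(tag) {
    body <- sample(sense, 400, replace = TRUE)  # 1206-bp CDS
    full <- paste0("ATG", paste(body, collapse = ""), "TAG")
    skipped <- paste0("ATG", paste(body[-(100:160)], collapse = ""), "TAG")
    tibble::tibble(unigene_id = paste0(tag, c("_full", "_skip")),
                   seq = c(full, skipped))
  }
  uni <- dplyr::bind_rows(mk_pair("g1"), mk_pair("g2"))
  orfs <- annotate_orfs(uni, ccfg)
  expect_true(all(orfs$completeness == "COMPLETE"))
  grp <- group_by_anchors(uni, orfs, ccfg)
  expect_equal(nrow(grp), 2)
  expect_error(group_by_anchors(uni, NULL, ccfg), "requires an ORF table")

  # a frame-disrupting variant loses its full-span ORF: its early-stop CDS no
  # longer shares the tail anchor, so cds mode cannot group it
  pair <- mk_pair("g3")
  frameshift <- paste0(substr(pair$seq[1], 1, 500),
                       substr(pair$seq[1], 751, nchar(pair$seq[1])))  # 250-bp loss
  uni3 <- tibble::tibble(unigene_id = c("g3_full", "g3_fs"),
                         seq = c(pair$seq[1], frameshift))
  orfs3 <- annotate_orfs(uni3, ccfg)
  grp3 <- group_by_anchors(uni3, orfs3, ccfg)
  expect_equal(nrow(grp3), 0)
  # unigene mode recovers the same pair from transcript-end anchors
  expect_equal(nrow(group_by_anchors(uni3, cfg = cfg)), 1)
})

test_that("reciprocal identity keeps skip variants and drops shuffled decoys", {
  pair <- make_skip_pair(183)
  members <- tibble::tibble(unigene_id = c("u_full", "u_skip"),
                            seq = c(pair$full, pair$skipped))
  kept <- reciprocal_identity(members, cfg)
  expect_equal(nrow(kept), 2)

  # decoy: same anchors, internal block shuffled (~ random identity inside)
  withr::local_seed(64)
  inner <- strsplit(substr(pair$full, 101, 1100), "", fixed = TRUE)[[1]]
  decoy <- paste0(substr(pair$full, 1, 100),
                  paste(sample(inner), collapse = ""),
                  substr(pair$full, 1101, 1200))
  members2 <- tibble::tibble(unigene_id = c("u_full", "u_skip", "u_decoy"),
                             seq = c(pair$full, pair$skipped, decoy))
  kept2 <- reciprocal_identity(members2, cfg)
  expect_setequal(kept2$unigene_id, c("u_full", "u_skip"))
})

test_that("indel events report exact gap-run lengths between the anchors", {
  for (skip in c(183, 78)) {
    pair <- make_skip_pair(skip)
    ev <- detect_indels(align_pair(pair$full, pair$skipped), anchor_len = 100)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$length, skip)
    # gap placement may slide within a short repeated boundary context
    expect_lte(abs(ev$start - 499), 10)
    expect_equal(ev$kind, "deletion_in_alt")
  }
  aln <- align_pair("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(nrow(detect_indels(aln, anchor_len = 2)), 0)
})

test_that("the >100-base rule is strict: 78 and 100 excluded, 101 reported", {
  for (skip in c(78, 100, 101)) {
    pair <- make_skip_pair(skip)
    uni <- tibble::tibble(unigene_id = c("u_full", "u_skip"),
                          seq = c(pair$full, pair$skipped))
    res <- detect_exon_skipping(uni, cfg = cfg)
    if (skip > 100) {
      expect_equal(nrow(res$clusters), 1)
      expect_equal(res$events$length[res$events$qualifying], skip)
    } else {
      expect_equal(nrow(res$clusters), 0)
    }
  }
})

test_that("sub-threshold events are listed but only qualifying ones gate the cluster", {
  withr::local_seed(65)
  full <- random_seq(1500)
  # one 60-base and one 250-base deletion in the same variant
  alt <- paste0(substr(full, 1, 399), substr(full, 460, 899),
                substr(full, 1150, 1500))
  uni <- tibble::tibble(unigene_id = c("u_full", "u_alt"),
                        seq = c(full, alt))
  res <- detect_exon_skipping(uni, cfg = cfg)
  expect_equal(nrow(res$clusters), 1)
  ev <- res$events[order(res$events$length), ]
  expect_equal(ev$length, c(60L, 250L))
  expect_equal(ev$qualifying, c(FALSE, TRUE))
})

test_that("a multi-member cluster validates both planted events in the MSA", {
  # 12 homologous unigenes: the full form plus variants lacking 78- and
  # 183-base internal blocks, padded out with exact duplicates of the full form
  withr::local_seed(66)
  full <- random_seq(1600)
  sk78 <- paste0(substr(full, 1, 399), substr(full, 478, 1600))
  sk183 <- paste0(substr(full, 1, 899), substr(full, 1083, 1600))
  uni <- tibble::tibble(
    unigene_id = sprintf("u%02d", 1:12),
    seq = c(full, sk78, sk183, rep(full, 9))
  )
  res <- detect_exon_skipping(uni, cfg = cfg)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_members, 12)
  expect_true(res$clusters$validated)
  expect_setequal(res$events$length[res$events$qualifying], 183)
  expect_setequal(res$events$length, c(78, 183))

  # adversarial MSA: claim an event length that no gap block supports
  ev <- res$events
  ev$length[ev$qualifying][1] <- 999L
  expect_false(validate_msa(res$msa[[res$clusters$cluster_id]], ev,
                            ref_id = ev$ref_id[1]))
})

test_that("event lengths are invariant to member input order", {
  pair <- make_skip_pair(250)
  uni <- tibble::tibble(unigene_id = c("u_full", "u_skip"),
                        seq = c(pair$full, pair$skipped))
  res1 <- detect_exon_skipping(uni, cfg = cfg)
  res2 <- detect_exon_skipping(uni[2:1, ], cfg = cfg)
  expect_equal(res1$events$length, res2$events$length)
  expect_equal(res1$events$ref_id, res2$events$ref_id)
})

test_that("planted simulation skips are recovered exactly and exclusively", {
  scfg <- sim_config(n_genes = 10, skip_fraction = 0.4,
                     skip_len_choices = c(120, 183, 250, 350),
                     reads_per_isoform = 1, error_rate = 0,
                     truncation_fraction = 0, seed = 67)
  sim <- simulate_isoseq(scfg, cfg)
  uni <- tibble::tibble(unigene_id = sim$isoforms$isoform_id,
                        seq = sim$isoforms$seq)
  res <- detect_exon_skipping(uni, annotate_orfs(uni, cfg), cfg)
  planted <- sort(sim$genes$skip_len[sim$genes$skip_len > 0])
  expect_equal(nrow(res$clusters), length(planted))
  expect_equal(sort(res$events$length[res$events$qualifying]), planted)
  expect_true(all(res$clusters$validated))
})

test_that("the indel-size histogram uses the published bins", {
  scfg <- sim_config(n_genes = 12, skip_fraction = 1,
                     skip_len_choices = c(120, 183, 250, 350),
                     reads_per_isoform = 1, error_rate = 0,
                     truncation_fraction = 0, seed = 68)
  sim <- simulate_isoseq(scfg, cfg)
  uni <- tibble::tibble(unigene_id = sim$isoforms$isoform_id,
                        seq = sim$isoforms$seq)
  res <- detect_exon_skipping(uni, cfg = cfg)
  rep <- as_report(res)
  expect_equal(rep$histogram$bin, c("101-200", "201-300", "301-400", ">400"))
  planted <- sim$genes$skip_len
  expect_equal(rep$histogram$n,
               c(sum(planted %in% c(120, 183)), sum(planted == 250),
                 sum(planted == 350), 0L))

  empty <- detect_exon_skipping(
    tibble::tibble(unigene_id = "u1", seq = strrep("ACGTT", 100)), cfg = cfg)
  rep0 <- as_report(empty)
  expect_equal(nrow(rep0$table), 0)
  expect_equal(rep0$histogram$n, rep(0L, 4))
})
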