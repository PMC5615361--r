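cfg <- pipeline_config()

test_that("canonical classes collapse rotations and reverse complements", {
  expect_equal(canonical_motif(c("AG", "GA", "CT", "TC")), rep("AG", 4))
  rots_aag <- c("AAG", "AGA", "GAA", "CTT", "TTC", "TCT")
  expect_equal(canonical_motif(rots_aag), rep("AAG", 6))
  expect_equal(canonical_motif("ATG"), "ATC")  # min over {ATG,TGA,GAT,CAT,ATC,TCA}
  expect_error(canonical_motif("ATAT"), "shorter unit")
  expect_error(canonical_motif("AXG"), "1-6 bases")
})

test_that("canonicalization is idempotent and invariant, exhaustively to length 4", {
  bases <- c("A", "C", "G", "T")
  all_motifs <- unlist(lapply(1:4, function(l) {
    apply(expand.grid(rep(list(bases), l)), 1, paste, collapse = "")
  }))
  minimal <- all_motifs[vapply(all_motifs, function(m) {
    l <- nchar(m)
    !any(vapply(seq_len(l - 1), function(d)
      l %% d == 0 && strrep(substr(m, 1, d), l / d) == m, logical(1)))
  }, logical(1))]
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rot1 <- function(s) paste0(substr(s, 2, nchar(s)), substr(s, 1, 1))
  for (m in minimal) {
    can <- canonical_motif(m)
    expect_equal(canonical_motif(can), can)          # idempotent
    expect_equal(canonical_motif(rot1(m)), can)      # rotation-invariant
    expect_equal(canonical_motif(rc(m)), can)        # RC-invariant
  }
})

test_that("simple repeats are found with minimal units and whole-unit spans", {
  hits <- scan_ssrs(tibble::tibble(id = "s", seq = strrep("A", 12)), cfg)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif, "A")
  expect_equal(hits$repeats, 12)
  expect_equal(c(hits$start, hits$end), c(0, 12))

  hits <- scan_ssrs(tibble::tibble(id = "s", seq = "AGAGAGAGAGAG"), cfg)
  expect_equal(hits$motif, "AG")
  expect_equal(hits$canonical, "AG")
  expect_equal(hits$repeats, 6)

  # below the minimum repeat count: nothing
  hits <- scan_ssrs(tibble::tibble(id = "s", seq = "AGAGAGAGAG"), cfg)
  expect_equal(nrow(hits), 0)

  # end - start always equals motif length times repeats
  withr::local_seed(71)
  seqs <- tibble::tibble(id = sprintf("r%d", 1:10),
                         seq = vapply(rep(800, 10), random_seq, character(1)))
  hits <- scan_ssrs(seqs, cfg)
  expect_equal(hits$end - hits$start, nchar(hits$motif) * hits$repeats)
})

test_that("the scanner agrees with the brute-force oracle", {
  withr::local_seed(72)
  low_thresholds <- pipeline_config(
    ssr_min_repeats = c(`1` = 5, `2` = 3, `3` = 3, `4` = 2, `5` = 2, `6` = 2)
  )
  for (k in 1:30) {
    # AT-rich alphabet so repeats actually occur at small lengths
    s <- random_seq(600, alphabet = c("A", "T", "A", "G", "C"))
    got <- as.data.frame(scan_ssrs(tibble::tibble(id = "s", seq = s),
                                   low_thresholds)[, c("motif", "repeats", "start", "end")])
    want <- oracle_scan_ssrs(s, low_thresholds$ssr_min_repeats)
    rownames(got) <- NULL
    rownames(want) <- NULL
    want$repeats <- as.integer(want$repeats)
    want$start <- as.integer(want$start)
    want$end <- as.integer(want$end)
    expect_equal(got, want, info = s)
  }
})

test_that("hits are localized by CDS overlap", {
  orfs <- tibble::tibble(unigene_id = "u", start = 100L, end = 400L)
  hits <- tibble::tibble(seq_id = rep("u", 4),
                         motif = "AG", canonical = "AG", repeats = 6L,
                         start = c(10L, 395L, 500L, 100L),
                         end = c(22L, 407L, 512L, 112L))
  loc <- localize_ssrs(hits, orfs)
  expect_equal(loc$region, c("UTR5", "ORF", "UTR3", "ORF"))

  loc2 <- localize_ssrs(hits, NULL)
  expect_true(all(loc2$region == "NOORF"))
})

test_that("summary fractions are per unit length and conserve counts", {
  hits <- tibble::tibble(
    seq_id = "u",
    motif = c(rep("AG", 7), rep("AT", 3), rep("AAG", 2)),
    canonical = c(rep("AG", 7), rep("AT", 3), rep("AAG", 2)),
    repeats = 6L, start = 0L, end = 12L,
    region = c(rep("UTR5", 5), rep("ORF", 5), "UTR3", "UTR3")
  )
  s <- ssr_summary(hits)
  expect_equal(s$fraction[s$canonical == "AG"], 0.7)
  expect_equal(s$fraction[s$canonical == "AT"], 0.3)
  expect_equal(s$fraction[s$canonical == "AAG"], 1)
  expect_equal(sum(s$n), nrow(hits))
  region_cols <- grep("^n_", names(s), value = TRUE)
  expect_equal(sum(unlist(s[, region_cols])), nrow(hits))

  expect_equal(nrow(ssr_summary(hits[0, ])), 0)
})

test_that("planted SSR classes are recovered from simulated genes", {
  scfg <- sim_config(n_genes = 30, skip_fraction = 0, ssr_fraction = 1,
                     ssr_motifs = c("AG", "AC"), ssr_repeats_range = c(8, 10),
                     seed = 73)
  genes <- simulate_gene_models(scfg)
  iso <- derive_isoforms(genes)
  hits <- scan_ssrs(tibble::tibble(id = iso$isoform_id, seq = iso$seq), cfg)
  planted <- dplyr::bind_rows(genes$ssr)
  expect_gt(nrow(planted), 0)
  # every planted repeat is recovered with its canonical class
  for (i in seq_len(nrow(genes))) {
    pl <- genes$ssr[[i]]
    if (nrow(pl) == 0) next
    iso_id <- paste0(genes$gene_id[i], "_FL")
    h <- hits[hits$seq_id == iso_id, ]
    expect_true(canonical_motif(pl$motif) %in% h$canonical,
                info = iso_id)
  }
})
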