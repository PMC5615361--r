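pcfg <- pipeline_config()

test_that("gene model simulation is deterministic and respects ranges", {
  scfg <- sim_config(n_genes = 5, seed = 1)
  g1 <- simulate_gene_models(scfg)
  g2 <- simulate_gene_models(scfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 5)
  expect_true(all(g1$n_exons >= 3 & g1$n_exons <= 12))

  expect_equal(nrow(simulate_gene_models(sim_config(n_genes = 0))), 0)
})

test_that("misconfigured simulations are rejected", {
  expect_error(sim_config(n_genes = 5, exon_count_range = c(2, 2),
                          skip_fraction = 0.5), "internal exon")
  expect_error(sim_config(n_genes = 5, skip_len_choices = 700,
                          exon_len_range = c(80, 600)), "exceeds")
  expect_error(sim_config(n_genes = 5, skip_fraction = 1.5), "skip_fraction")
})

test_that("full isoforms are clean coding sequences", {
  scfg <- sim_config(n_genes = 10, skip_fraction = 0.5, seed = 2)
  iso <- derive_isoforms(simulate_gene_models(scfg))
  full <- iso[iso$truth_skip_len == 0, ]
  for (s in full$seq) {
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    starts <- seq(4, nchar(s) - 5, 3)
    expect_false(any(substring(s, starts, starts + 2) %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("skip lengths are planted exactly", {
  scfg <- sim_config(n_genes = 12, skip_fraction = 0.5,
                     skip_len_choices = c(78, 183), seed = 3)
  genes <- simulate_gene_models(scfg)
  iso <- derive_isoforms(genes)
  skipped <- iso[iso$truth_skip_len > 0, ]
  expect_equal(nrow(skipped), 6)  # round(0.5 * 12)
  expect_true(all(skipped$truth_skip_len %in% c(78, 183)))
  # truth_skip_len equals full length minus skipped length, exactly
  full_len <- setNames(nchar(iso$seq[iso$truth_skip_len == 0]),
                       iso$gene_id[iso$truth_skip_len == 0])
  expect_equal(unname(full_len[skipped$gene_id]) - nchar(skipped$seq),
               skipped$truth_skip_len)
  # the skipped exon is always internal
  expect_true(all(genes$skip_exon[!is.na(genes$skip_exon)] > 1))
  expect_true(all(genes$skip_exon[!is.na(genes$skip_exon)] <
                    genes$n_exons[!is.na(genes$skip_exon)]))
})

test_that("read synthesis conserves counts and honours the truth sidecar", {
  scfg <- sim_config(n_genes = 6, skip_fraction = 0.5, reads_per_isoform = 4,
                     error_rate = 0, truncation_fraction = 0.5, seed = 4)
  genes <- simulate_gene_models(scfg)
  iso <- derive_isoforms(genes)
  rt <- synthesize_reads(iso, scfg, pcfg)
  expect_equal(nrow(rt$reads), nrow(iso) * 4)
  expect_equal(nrow(rt$truth), nrow(rt$reads))
  expect_equal(anyDuplicated(rt$truth$read_id), 0)
  expect_equal(sum(rt$truth$category == "nFL"), round(0.5 * nrow(rt$reads)))
  # truncated reads have lost the 5' adapter; intact reads carry it at base 1
  has_a5 <- vapply(rt$reads$seq,
                   function(s) length(find_adapter(s, pcfg$adapter5, 0)) > 0,
                   logical(1))
  expect_equal(unname(has_a5), rt$truth$category == "FL")
})

test_that("full truncation removes every 5' adapter", {
  scfg <- sim_config(n_genes = 3, reads_per_isoform = 3, error_rate = 0,
                     truncation_fraction = 1, seed = 5)
  sim <- simulate_isoseq(scfg, pcfg)
  expect_true(all(sim$truth$category == "nFL"))
  res <- classify_reads(sim$reads, pcfg)
  expect_true(all(res$category == "NONFL"))
})

test_that("a fixed seed reproduces the FASTQ bundle byte for byte", {
  scfg <- sim_config(n_genes = 4, reads_per_isoform = 3, error_rate = 0.01,
                     truncation_fraction = 0.3, seed = 6)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_isoseq(scfg, pcfg), d1)
  write_simulation(simulate_isoseq(scfg, pcfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("zero reads per isoform warns and returns empty output", {
  scfg <- sim_config(n_genes = 2, reads_per_isoform = 0, seed = 7)
  iso <- derive_isoforms(simulate_gene_models(scfg))
  expect_warning(rt <- synthesize_reads(iso, scfg, pcfg), "no reads")
  expect_equal(nrow(rt$reads), 0)
})
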