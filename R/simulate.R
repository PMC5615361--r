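#' Simulation configuration
#'
#' Parameters of the synthetic full-length transcript generator. Defaults
#' describe the conditions the pipeline is validated under: multi-exon genes
#' (3-12 exons of 80-600 bp), 30% of genes carrying one skipped internal exon
#' whose length is drawn from 78/120/183/250/350 bp (spanning the published
#' exemplar events and the 100-400 bp indel range), 10 reads per isoform at a
#' 0.2% per-base substitution rate, 30% of reads 5'-truncated, and a 30-base
#' poly(A) tail.
#'
#' Every full isoform is a clean coding sequence: it begins with ATG, ends
#' with a TAG stop, has length divisible by 3 and no internal in-frame stop.
#' Skipped-exon lengths need not be multiples of 3; a frame-disrupting skip is
#' intentional (detection operates on nucleotide anchors, not on frames).
#'
#' @param n_genes Number of gene models.
#' @param exon_count_range,exon_len_range Integer ranges `[min, max]`.
#' @param skip_fraction Fraction of genes given one skipped isoform.
#' @param skip_len_choices Possible skipped-exon lengths (bases); the chosen
#'   exon is constructed to that exact length.
#' @param reads_per_isoform Reads synthesised per isoform.
#' @param error_rate Per-base substitution probability.
#' @param indel_rate Per-base probability of a 1-3 bp sequencing indel
#'   (default 0 so planted exon skips are the only gap sources).
#' @param truncation_fraction Fraction of reads truncated at a uniform 5'
#'   point past the 5' adapter (these become non-full-length truth).
#' @param polya_len Poly(A) tail length (bases).
#' @param ssr_fraction Fraction of genes given one embedded SSR.
#' @param ssr_motifs Repeat units planted (kept free of T so no stop codon can
#'   arise inside a planted repeat).
#' @param ssr_repeats_range Range of planted repeat counts.
#' @param anchor_margin Minimum exonic flank (bases) guaranteed on both sides
#'   of a skipped exon, so terminal anchors lie in shared sequence.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       exon_count_range = c(3L, 12L),
                       exon_len_range = c(80L, 600L),
                       skip_fraction = 0.3,
                       skip_len_choices = c(78L, 120L, 183L, 250L, 350L),
                       reads_per_isoform = 10L,
                       error_rate = 0.002,
                       indel_rate = 0,
                       truncation_fraction = 0.3,
                       polya_len = 30L,
                       ssr_fraction = 0.5,
                       ssr_motifs = c("AG", "AAG"),
                       ssr_repeats_range = c(6L, 12L),
                       anchor_margin = 120L,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_len_range = as.integer(exon_len_range),
    skip_fraction = as.numeric(skip_fraction),
    skip_len_choices = as.integer(skip_len_choices),
    reads_per_isoform = as.integer(reads_per_isoform),
    error_rate = as.numeric(error_rate),
    indel_rate = as.numeric(indel_rate),
    truncation_fraction = as.numeric(truncation_fraction),
    polya_len = as.integer(polya_len),
    ssr_fraction = as.numeric(ssr_fraction),
    ssr_motifs = toupper(ssr_motifs),
    ssr_repeats_range = as.integer(ssr_repeats_range),
    anchor_margin = as.integer(anchor_margin),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 0L) abort("n_genes must be >= 0")
  if (cfg$exon_count_range[1] > cfg$exon_count_range[2] ||
      cfg$exon_len_range[1] > cfg$exon_len_range[2]) {
    abort("ranges must be ordered [min, max]")
  }
  for (key in c("skip_fraction", "error_rate", "indel_rate",
                "truncation_fraction", "ssr_fraction")) {
    if (cfg[[key]] < 0 || cfg[[key]] > 1) {
      abort(sprintf("'%s' must be in [0, 1]", key))
    }
  }
  if (cfg$skip_fraction > 0 && cfg$exon_count_range[2] < 3L) {
    abort("exon skipping requires genes with at least 3 exons (no internal exon otherwise)")
  }
  if (cfg$skip_fraction > 0 &&
      max(cfg$skip_len_choices) > cfg$exon_len_range[2]) {
    abort("a skip_len_choices value exceeds exon_len_range max")
  }
  if (any(grepl("[^ACG]", cfg$ssr_motifs))) {
    abort("ssr_motifs must avoid T (a planted T could create a stop codon)")
  }
  structure(cfg, class = "sim_config")
}

# codons with no T-containing stop; terminal stop fixed to TAG so the poly(A)
# tail stays separable from the transcript body by terminal-A-run trimming
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA")
)

#' Simulate multi-exon gene models
#'
#' Draws exon counts and lengths, selects `round(skip_fraction * n_genes)`
#' genes for exon skipping (forcing one internal exon to a length from
#' `skip_len_choices` and guaranteeing `anchor_margin` bases of shared flank
#' on both sides), makes the total exonic length a clean CDS, and embeds SSRs
#' in a `ssr_fraction` of genes. Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `gene_id`, `exon_seqs` (list-column),
#'   `n_exons`, `skip_exon` (1-based index or NA), `skip_len`, `ssr`
#'   (list-column of placements: exon index, offset, motif, repeats).
#' @export
simulate_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes == 0L) {
    return(tibble(gene_id = character(0), exon_seqs = list(),
                  n_exons = integer(0), skip_exon = integer(0),
                  skip_len = integer(0), ssr = list()))
  }
  withr::with_seed(cfg$seed, {
    n_skip <- round(cfg$skip_fraction * cfg$n_genes)
    skip_genes <- if (n_skip > 0L) sort(sample.int(cfg$n_genes, n_skip)) else integer(0)
    n_ssr <- round(cfg$ssr_fraction * cfg$n_genes)
    ssr_genes <- if (n_ssr > 0L) sort(sample.int(cfg$n_genes, n_ssr)) else integer(0)
    rows <- lapply(seq_len(cfg$n_genes), function(g) {
      simulate_one_gene(g, g %in% skip_genes, g %in% ssr_genes, cfg)
    })
    bind_rows(rows)
  })
}

# sample() treats a length-1 numeric as 1:x; this never does
sample1 <- function(x) x[sample.int(length(x), 1L)]

simulate_one_gene <- function(g, with_skip, with_ssr, cfg) {
  ecr <- cfg$exon_count_range
  elr <- cfg$exon_len_range
  n_exons <- if (with_skip) {
    sample1(seq(max(3L, ecr[1]), ecr[2]))
  } else {
    sample1(seq(ecr[1], ecr[2]))
  }
  lens <- sample(seq(elr[1], elr[2]), n_exons, replace = TRUE)
  skip_exon <- NA_integer_
  skip_len <- 0L
  if (with_skip) {
    skip_exon <- if (n_exons == 3L) 2L else sample1(seq(2L, n_exons - 1L))
    skip_len <- sample1(cfg$skip_len_choices)
    lens[skip_exon] <- skip_len
    # guarantee shared flanks so terminal anchors avoid the skipped exon
    if (sum(lens[seq_len(skip_exon - 1L)]) < cfg$anchor_margin) {
      lens[1L] <- lens[1L] + cfg$anchor_margin
    }
    if (sum(lens[seq(skip_exon + 1L, n_exons)]) < cfg$anchor_margin) {
      lens[n_exons] <- lens[n_exons] + cfg$anchor_margin
    }
  }
  # clean CDS: length divisible by 3 and comfortably above typical ORF minima,
  # adjusted on a non-skipped terminal exon
  total <- sum(lens)
  pad <- (3L - total %% 3L) %% 3L
  if (total + pad < 330L) pad <- pad + 3L * ceiling((330L - total - pad) / 3)
  lens[n_exons] <- lens[n_exons] + as.integer(pad)
  total <- sum(lens)

  cds <- make_cds(total)
  ssr <- tibble(exon = integer(0), offset = integer(0),
                motif = character(0), repeats = integer(0))
  if (with_ssr) {
    planted <- plant_ssr(cds, lens, cfg)
    cds <- planted$cds
    ssr <- planted$ssr
  }
  bounds <- cumsum(lens)
  starts <- c(1L, bounds[-n_exons] + 1L)
  exon_seqs <- substring(cds, starts, bounds)
  tibble(
    gene_id = sprintf("GENE_%04d", g),
    exon_seqs = list(exon_seqs),
    n_exons = n_exons,
    skip_exon = skip_exon,
    skip_len = skip_len,
    ssr = list(ssr)
  )
}

make_cds <- function(total_len) {
  stopifnot(total_len %% 3L == 0L, total_len >= 9L)
  n_codons <- total_len %/% 3L
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAG")
}

plant_ssr <- function(cds, lens, cfg) {
  motif <- sample1(cfg$ssr_motifs)
  repeats <- sample1(seq(cfg$ssr_repeats_range[1], cfg$ssr_repeats_range[2]))
  run <- strrep(motif, repeats)
  total <- nchar(cds)
  # interior placement: keep the start codon, terminal stop and 3 bp margins
  lo <- 5L
  hi <- total - nchar(run) - 4L
  if (hi <= lo) {
    return(list(cds = cds, ssr = tibble(exon = integer(0), offset = integer(0),
                                        motif = character(0), repeats = integer(0))))
  }
  for (try in 1:25) {
    at <- sample1(seq(lo, hi))
    candidate <- paste0(substr(cds, 1L, at - 1L), run,
                        substr(cds, at + nchar(run), total))
    if (!has_internal_stop(candidate)) {
      bounds <- cumsum(lens)
      exon <- which(bounds >= at)[1]
      offset <- at - c(0L, bounds)[exon] - 1L
      return(list(cds = candidate,
                  ssr = tibble(exon = exon, offset = offset,
                               motif = motif, repeats = repeats)))
    }
  }
  list(cds = cds, ssr = tibble(exon = integer(0), offset = integer(0),
                               motif = character(0), repeats = integer(0)))
}

has_internal_stop <- function(cds) {
  n <- nchar(cds)
  starts <- seq(1L, n - 5L, 3L)  # exclude the terminal codon
  any(substring(cds, starts, starts + 2L) %in% STOP_CODONS)
}

#' Derive isoform templates from gene models
#'
#' Emits the full isoform for every gene (all exons, in order) and, for genes
#' carrying a skipped exon, one skipped isoform omitting that internal exon.
#' `truth_skip_len` is exactly the full-isoform length minus the skipped
#' isoform length. Deterministic: all randomness lives in
#' [simulate_gene_models()].
#'
#' @param genes Tibble from [simulate_gene_models()].
#' @param cfg A [sim_config()] (unused fields tolerated; kept for symmetry).
#' @return A tibble with columns `isoform_id`, `gene_id`, `included_exons`
#'   (list-column), `seq`, `truth_skip_len`.
#' @export
derive_isoforms <- function(genes, cfg = NULL) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    exons <- genes$exon_seqs[[i]]
    gid <- genes$gene_id[i]
    full <- tibble(
      isoform_id = paste0(gid, "_FL"),
      gene_id = gid,
      included_exons = list(seq_along(exons)),
      seq = paste(exons, collapse = ""),
      truth_skip_len = 0L
    )
    if (is.na(genes$skip_exon[i])) return(full)
    keep <- setdiff(seq_along(exons), genes$skip_exon[i])
    skipped <- tibble(
      isoform_id = paste0(gid, "_SK"),
      gene_id = gid,
      included_exons = list(keep),
      seq = paste(exons[keep], collapse = ""),
      truth_skip_len = nchar(exons[genes$skip_exon[i]])
    )
    bind_rows(full, skipped)
  })
  bind_rows(rows)
}

#' Synthesise adapter-flanked long reads with a truth sidecar
#'
#' Each full-length read is `adapter5 + isoform + polyA + adapter3` with
#' independent per-base substitutions at `error_rate` (and, if `indel_rate >
#' 0`, short sequencing indels). A `truncation_fraction` of reads (chosen
#' exactly, at random) lose a uniform-random 5' prefix that removes the 5'
#' adapter and part of the insert — these are non-full-length truth. Per-read
#' quality is `1 - error_rate`. Deterministic for a fixed seed (the generator
#' uses `cfg$seed + 1` so gene models and reads draw from independent
#' streams).
#'
#' @param isoforms Tibble from [derive_isoforms()].
#' @param cfg A [sim_config()].
#' @param pcfg A [pipeline_config()] supplying the adapters.
#' @return A list with `reads` (tibble `id`, `seq`, `quality`) and `truth`
#'   (tibble `read_id`, `isoform_id`, `gene_id`, `category` "FL"/"nFL",
#'   `truncation_len`).
#' @export
synthesize_reads <- function(isoforms, cfg, pcfg = pipeline_config()) {
  if (cfg$reads_per_isoform == 0L) {
    warn("reads_per_isoform is 0: no reads synthesised")
    return(list(
      reads = tibble(id = character(0), seq = character(0), quality = numeric(0)),
      truth = tibble(read_id = character(0), isoform_id = character(0),
                     gene_id = character(0), category = character(0),
                     truncation_len = integer(0))
    ))
  }
  withr::with_seed(cfg$seed + 1L, {
    n_total <- nrow(isoforms) * cfg$reads_per_isoform
    iso_idx <- rep(seq_len(nrow(isoforms)), each = cfg$reads_per_isoform)
    read_ids <- sprintf("READ_%06d", seq_len(n_total))
    n_trunc <- round(cfg$truncation_fraction * n_total)
    trunc_set <- if (n_trunc > 0L) sample.int(n_total, n_trunc) else integer(0)
    a5 <- pcfg$adapter5
    a3 <- pcfg$adapter3
    polya <- strrep("A", cfg$polya_len)

    seqs <- character(n_total)
    trunc_len <- integer(n_total)
    for (r in seq_len(n_total)) {
      ins <- isoforms$seq[iso_idx[r]]
      full <- paste0(a5, ins, polya, a3)
      if (r %in% trunc_set) {
        # lose the 5' adapter plus up to half the insert
        cut <- nchar(a5) + sample.int(max(1L, nchar(ins) %/% 2L), 1L)
        full <- substr(full, cut + 1L, nchar(full))
        trunc_len[r] <- cut
      }
      full <- mutate_sequence(full, cfg$error_rate, cfg$indel_rate)
      seqs[r] <- full
    }
    list(
      reads = tibble(id = read_ids, seq = seqs,
                     quality = 1 - cfg$error_rate),
      truth = tibble(
        read_id = read_ids,
        isoform_id = isoforms$isoform_id[iso_idx],
        gene_id = isoforms$gene_id[iso_idx],
        category = ifelse(trunc_len > 0L, "nFL", "FL"),
        truncation_len = trunc_len
      )
    )
  })
}

mutate_sequence <- function(seq, error_rate, indel_rate = 0) {
  n <- nchar(seq)
  if (error_rate > 0) {
    n_err <- stats::rbinom(1L, n, error_rate)
    if (n_err > 0L) {
      pos <- sample.int(n, n_err)
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      seq <- paste(chars, collapse = "")
    }
  }
  if (indel_rate > 0) {
    n_ind <- stats::rbinom(1L, n, indel_rate)
    for (k in seq_len(n_ind)) {
      p <- sample.int(nchar(seq), 1L)
      len <- sample.int(3L, 1L)
      if (stats::runif(1) < 0.5) {
        seq <- paste0(substr(seq, 1L, p - 1L),
                      substr(seq, p + len, nchar(seq)))
      } else {
        seq <- paste0(substr(seq, 1L, p),
                      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
                      substr(seq, p + 1L, nchar(seq)))
      }
    }
  }
  seq
}

#' Run the full simulation bundle
#'
#' Chains [simulate_gene_models()], [derive_isoforms()] and
#' [synthesize_reads()] into one object.
#'
#' @param cfg A [sim_config()].
#' @param pcfg A [pipeline_config()].
#' @return A list of class `isoseq_sim` with `genes`, `isoforms`, `reads`,
#'   `truth`, and the two configs.
#' @export
simulate_isoseq <- function(cfg, pcfg = pipeline_config()) {
  genes <- simulate_gene_models(cfg)
  isoforms <- derive_isoforms(genes, cfg)
  rt <- synthesize_reads(isoforms, cfg, pcfg)
  structure(list(genes = genes, isoforms = isoforms,
                 reads = rt$reads, truth = rt$truth,
                 sim_config = cfg, pipeline_config = pcfg),
            class = "isoseq_sim")
}

#' @export
print.isoseq_sim <- function(x, ...) {
  cat(sprintf("<isoseq_sim> %d gene(s), %d isoform(s), %d read(s); %d gene(s) with a skipped exon\n",
              nrow(x$genes), nrow(x$isoforms), nrow(x$reads),
              sum(!is.na(x$genes$skip_exon))))
  invisible(x)
}

#' Write a simulation bundle to disk
#'
#' Emits `reads.fastq`, `isoforms.fasta`, `truth.json` (per-read and per-gene
#' truth), and `gene_models.tsv` (one row per exon with 1-based closed
#' isoform coordinates).
#'
#' @param sim An `isoseq_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  write_fasta(tibble(id = sim$isoforms$isoform_id, seq = sim$isoforms$seq),
              file.path(dir, "isoforms.fasta"))
  genes_truth <- lapply(seq_len(nrow(sim$genes)), function(i) {
    list(gene_id = sim$genes$gene_id[i],
         n_exons = sim$genes$n_exons[i],
         skip_exon = if (is.na(sim$genes$skip_exon[i])) NULL else
           sim$genes$skip_exon[i],
         skip_len = sim$genes$skip_len[i],
         ssr = sim$genes$ssr[[i]])
  })
  jsonlite::write_json(
    list(reads = sim$truth, genes = genes_truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  exon_rows <- lapply(seq_len(nrow(sim$genes)), function(i) {
    lens <- nchar(sim$genes$exon_seqs[[i]])
    ends <- cumsum(lens)
    tibble(gene_id = sim$genes$gene_id[i],
           exon_index = seq_along(lens),
           start = ends - lens + 1L, end = ends)
  })
  readr::write_tsv(bind_rows(exon_rows), file.path(dir, "gene_models.tsv"))
  invisible(dir)
}
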