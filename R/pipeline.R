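#' Run the full pipeline
#'
#' Executes the stages in order — classify, cluster, ORF annotation,
#' exon-skipping detection, SSR scan, length statistics — writing every
#' stage's report under `out_dir` together with a run manifest (config hash
#' and per-stage input/output counts). FASTA input is treated as pre-assembled
#' unigenes: the classify and cluster stages are skipped and later stages run
#' directly on the records. Rerunning with identical inputs and configuration
#' reproduces byte-identical outputs; nothing in the pipeline is randomised.
#'
#' @param input Path to a FASTQ file of long reads, or to a FASTA file of
#'   unigenes; alternatively a tibble of reads (columns `id`, `seq`,
#'   optionally `quality`).
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param input_type `"auto"` (by file extension), `"reads"`, or
#'   `"unigenes"`.
#' @return The manifest, invisibly (a list, also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(input, cfg = pipeline_config(), out_dir,
                         input_type = c("auto", "reads", "unigenes")) {
  input_type <- match.arg(input_type)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(unclass(cfg)), stages = list())

  if (is.character(input)) {
    if (input_type == "auto") {
      input_type <- if (grepl("\\.(fastq|fq)(\\.gz)?$", input, ignore.case = TRUE))
        "reads" else "unigenes"
    }
    records <- if (input_type == "reads") {
      tryCatch(read_fastq(input), error = function(e) {
        abort(paste0("stage classify: cannot read input: ", conditionMessage(e)))
      })
    } else {
      read_fasta(input)
    }
  } else {
    records <- input
    if (input_type == "auto") {
      input_type <- if ("quality" %in% names(records)) "reads" else "unigenes"
    }
  }

  if (input_type == "reads") {
    classified <- classify_reads(records, cfg)
    readr::write_tsv(
      classified[, c("read_id", "category", "adapter5_pos", "adapter3_pos")],
      file.path(out_dir, "classify_report.tsv")
    )
    flnc <- classified[classified$category == "FLNC",
                       c("read_id", "insert_seq")]
    names(flnc) <- c("id", "seq")
    write_fasta(flnc, file.path(out_dir, "flnc.fasta"))
    manifest$stages$classify <- list(
      n_in = nrow(records),
      n_out = as.list(table(classified$category))
    )
    if (nrow(flnc) == 0L) {
      abort("stage classify: no FLNC reads; cannot continue")
    }

    unigenes <- cluster_unigenes(flnc, cfg)
    readr::write_tsv(
      tibble(unigene_id = unigenes$unigene_id,
             rep_id = unigenes$rep_id,
             n_members = unigenes$n_members,
             member_ids = vapply(unigenes$member_ids, paste,
                                 character(1), collapse = ",")),
      file.path(out_dir, "clusters.tsv")
    )
    write_fasta(tibble(id = unigenes$unigene_id, seq = unigenes$seq),
                file.path(out_dir, "unigenes.fasta"))
    manifest$stages$cluster <- list(n_in = nrow(flnc), n_out = nrow(unigenes))
  } else {
    unigenes <- records
    names(unigenes)[names(unigenes) == "id"] <- "unigene_id"
    write_fasta(tibble(id = unigenes$unigene_id, seq = unigenes$seq),
                file.path(out_dir, "unigenes.fasta"))
    manifest$stages$classify <- list(skipped = TRUE)
    manifest$stages$cluster <- list(skipped = TRUE, n_out = nrow(unigenes))
  }

  orfs <- annotate_orfs(unigenes, cfg)
  write_orf_gff3(orfs, file.path(out_dir, "orfs.gff3"))
  if (nrow(orfs) > 0L) {
    write_fasta(tibble(id = orfs$unigene_id, seq = orfs$cds_seq),
                file.path(out_dir, "cds.fasta"))
    prot <- translate_orfs(orfs)
    write_fasta(tibble(id = prot$unigene_id, seq = prot$protein_seq),
                file.path(out_dir, "proteins.fasta"))
  }
  readr::write_tsv(orf_summary(orfs, nrow(unigenes)),
                   file.path(out_dir, "orf_summary.tsv"))
  manifest$stages$orf <- list(n_in = nrow(unigenes), n_out = nrow(orfs))

  as_res <- detect_exon_skipping(unigenes, orfs, cfg)
  rep <- as_report(as_res, min_indel = cfg$min_indel)
  readr::write_tsv(rep$table, file.path(out_dir, "as_clusters.tsv"))
  readr::write_tsv(as_res$events, file.path(out_dir, "as_events.tsv"))
  readr::write_tsv(rep$histogram, file.path(out_dir, "as_histogram.tsv"))
  msa_dir <- file.path(out_dir, "as_msa")
  dir.create(msa_dir, showWarnings = FALSE)
  for (cid in names(as_res$msa)) {
    rows <- as_res$msa[[cid]]
    write_fasta(tibble(id = names(rows), seq = unname(rows)),
                file.path(msa_dir, paste0(cid, ".aln.fasta")))
  }
  manifest$stages$asdetect <- list(
    n_in = nrow(unigenes),
    n_clusters = nrow(as_res$clusters),
    n_qualifying_events = sum(as_res$events$qualifying)
  )

  hits <- localize_ssrs(scan_ssrs(unigenes, cfg), orfs)
  ssr_out <- hits
  if (nrow(ssr_out) > 0L) {  # reports are 1-based closed
    ssr_out$start <- ssr_out$start + 1L
  }
  readr::write_tsv(ssr_out, file.path(out_dir, "ssrs.tsv"))
  readr::write_tsv(ssr_summary(hits), file.path(out_dir, "ssr_summary.tsv"))
  manifest$stages$ssr <- list(n_in = nrow(unigenes), n_hits = nrow(hits))

  stats <- length_stats(unigenes)
  readr::write_tsv(glance(stats), file.path(out_dir, "stats.tsv"))
  readr::write_tsv(tidy(stats), file.path(out_dir, "length_histogram.tsv"))
  manifest$stages$stats <- list(n_in = nrow(unigenes))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write aligned FASTA for a gapped alignment
#'
#' @param msa Named character vector of equal-length gapped rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  writeLines(
    as.vector(rbind(paste0(">", names(msa)), unname(msa))),
    path
  )
  invisible(path)
}
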