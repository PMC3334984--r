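#' Simulate probe design scores for candidate SNPs
#'
#' Assay design scores are proprietary vendor output and enter the real
#' pipeline as an input column; the simulator draws them from a
#' right-skewed distribution on `[0, 1]`, penalising candidates with
#' another segregating site inside the probe footprint (hidden flanking
#' polymorphism is the main empirical driver of probe failure).
#'
#' @param candidates Candidate tibble (`chrom`, `pos`).
#' @param config A [sim_config()].
#' @param truth Optional tibble of all true variant positions (`chrom`,
#'   `pos`) used to detect flanking polymorphism.
#' @param flank_bp Probe footprint half-width.
#' @return `candidates` with a `design_score` column.
#' @export
simulate_design_scores <- function(candidates, config, truth = NULL,
                                   flank_bp = 50L) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(candidates)
  with_seed(config$seed + 4L, {
    penalised <- rep(FALSE, n)
    if (!is.null(truth) && n > 0) {
      near <- dplyr::inner_join(
        dplyr::mutate(candidates[, c("chrom", "pos")],
                      .row = dplyr::row_number()),
        dplyr::rename(truth[, c("chrom", "pos")], tpos = "pos"),
        by = "chrom", relationship = "many-to-many"
      )
      near <- near[abs(near$pos - near$tpos) <= flank_bp &
                     near$pos != near$tpos, ]
      penalised <- seq_len(n) %in% near$.row
    }
    score <- 1 - rbeta(n, 1, 12)
    score[penalised] <- 1 - rbeta(sum(penalised), 1.5, 4)
    candidates$design_score <- round(score, 4)
    candidates
  })
}

#' Run the full array-design pipeline on simulated data
#'
#' Chains every stage: genome/panel/call simulation, Stage-1 filtering
#' under both detection regimes (the first deep-coverage pools through
#' regime A with the repeat track, the remaining pools through regime B
#' with k-mer copy number), merge and deduplication, the Infinium probe
#' screens (type II restriction, probe-tail uniqueness, design score),
#' Stage-2 filtering, even-spacing selection into `slots` bead slots,
#' optional manufacturing dropout, a simulated evaluation-panel genotype
#' report, and evaluation (QC, classification, gap statistics).
#'
#' @param config A [sim_config()].
#' @param slots Array size in bead slots.
#' @param min_support Stage-2 accession-support threshold.
#' @param score_threshold Design-score threshold for de-novo candidates.
#' @param dropout_rate Manufacturing dropout rate.
#' @param regimeA_pools Pool numbers routed through regime A (default:
#'   the first 5/12 of pools, the deep-coverage share of the panel).
#' @param outdir Optional directory: when given, all stage outputs are
#'   written there (FASTA/GFF3/BED/TSV/VCF/CSV plus a stage-count log).
#' @return A list with every intermediate object plus `funnel`, a tibble
#'   of per-stage, per-rule counts sufficient to reconstruct the
#'   filtering funnel.
#' @export
run_pipeline <- function(config, slots = 500L, min_support = 5L,
                         score_threshold = 0.9, dropout_rate = 0,
                         regimeA_pools = NULL, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_genome(config)
  panel <- simulate_panel(sim$genome, sim$annotation, config)
  calls <- simulate_callsets(panel, config)

  if (is.null(regimeA_pools)) {
    regimeA_pools <- seq_len(max(1L, floor(config$n_pools * 5 / 12)))
  }
  accA <- panel$accessions$accession[panel$accessions$pool %in% regimeA_pools]
  callsA <- calls[calls$accession %in% accA, , drop = FALSE]
  callsB <- calls[!calls$accession %in% accA, , drop = FALSE]

  candA <- filter_stage1(callsA, stage1_params("A"), genome = sim$genome,
                         repeats = sim$repeats)
  candB <- filter_stage1(callsB, stage1_params("B"), genome = sim$genome)
  merged <- merge_dedup(candA, candB)

  funnel <- dplyr::bind_rows(
    dplyr::mutate(stage_log(candA), stage = "stage1_regimeA"),
    dplyr::mutate(stage_log(candB), stage = "stage1_regimeB"),
    tibble::tibble(stage = "merge", rule = "dedup",
                   removed = nrow(candA) + nrow(candB) - nrow(merged),
                   remaining = nrow(merged))
  )

  # probe candidacy screens
  n0 <- nrow(merged)
  screened <- merged[classify_infinium(merged$ref, merged$alt) == "II", ,
                     drop = FALSE]
  funnel <- dplyr::bind_rows(funnel, tibble::tibble(
    stage = "probe", rule = "infinium_II", removed = n0 - nrow(screened),
    remaining = nrow(screened)))
  if (nrow(screened) > 0) {
    probes <- extract_probe_context(sim$genome, screened$chrom, screened$pos)
    dup <- probe_tail_duplicated(sim$genome, probes)
    n0 <- nrow(screened)
    screened <- screened[!dup, , drop = FALSE]
    funnel <- dplyr::bind_rows(funnel, tibble::tibble(
      stage = "probe", rule = "tail_duplicated",
      removed = n0 - nrow(screened), remaining = nrow(screened)))
  }
  screened <- simulate_design_scores(screened, config, truth = panel$snps)
  n0 <- nrow(screened)
  screened <- apply_score_filter(screened, threshold = score_threshold)
  funnel <- dplyr::bind_rows(funnel, tibble::tibble(
    stage = "probe", rule = "design_score", removed = n0 - nrow(screened),
    remaining = nrow(screened)))

  stage2 <- filter_stage2(screened, annotation = sim$annotation,
                          genome = sim$genome, min_support = min_support)
  funnel <- dplyr::bind_rows(
    funnel, dplyr::mutate(stage_log(stage2), stage = "stage2"))

  plan <- selection_plan(slots, n_candidates = nrow(stage2))
  design <- select_even_spacing(stage2, plan)
  design$snp_id <- paste0(design$chrom, "_", design$pos)
  funnel <- dplyr::bind_rows(funnel, tibble::tibble(
    stage = "selection", rule = "even_spacing",
    removed = nrow(stage2) - nrow(design), remaining = nrow(design)))
  if (dropout_rate > 0) {
    n0 <- nrow(design)
    design <- apply_manufacturing_dropout(design, rate = dropout_rate,
                                          seed = config$seed + 5L)
    funnel <- dplyr::bind_rows(funnel, tibble::tibble(
      stage = "manufacturing", rule = "dropout",
      removed = n0 - nrow(design), remaining = nrow(design)))
  }

  report <- simulate_genotype_report(design, panel, config)
  classification <- classify_snps(report)
  gaps <- gap_statistics(design)

  out <- list(genome = sim$genome, annotation = sim$annotation,
              repeats = sim$repeats, panel = panel, calls = calls,
              candidates = list(A = candA, B = candB, merged = merged),
              screened = screened, stage2 = stage2, plan = plan,
              design = design, report = report,
              classification = classification, gaps = gaps,
              funnel = funnel[, c("stage", "rule", "removed", "remaining")])

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(sim$genome, file.path(outdir, "genome.fasta"))
    write_gff3(sim$annotation, file.path(outdir, "annotation.gff3"))
    write_bed(sim$repeats, file.path(outdir, "repeats.bed"))
    write_call_table(calls, file.path(outdir, "calls.tsv"))
    write_candidate_vcf(merged, file.path(outdir, "candidates.vcf"))
    write_manifest(design, file.path(outdir, "manifest.csv"))
    write_genotype_report(report, file.path(outdir, "genotype_report.tsv"))
    tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
    readr::write_tsv(out$funnel, tmp, progress = FALSE)
    file.rename(tmp, file.path(outdir, "stage_log.tsv"))
    tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
    readr::write_tsv(tibble::as_tibble(unclass(classification)), tmp,
                     progress = FALSE)
    file.rename(tmp, file.path(outdir, "classification.tsv"))
    tmp <- tempfile(tmpdir = outdir, fileext = ".tmp")
    readr::write_tsv(tibble::as_tibble(unclass(gaps)), tmp, progress = FALSE)
    file.rename(tmp, file.path(outdir, "gap_stats.tsv"))
  }
  out
}
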