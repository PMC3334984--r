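#' Genotype-quality QC of array SNPs
#'
#' A SNP passes QC only if its GenTrain score exceeds `gentrain_min`, its
#' 10th-percentile GenCall score exceeds `gencall10_min`, and it clusters
#' (produces a call) for at least half of the samples. The returned table
#' partitions the SNP set exhaustively.
#'
#' @param gm A `genotype_matrix` ([simulate_genotype_report()] or
#'   [read_genotype_report()]).
#' @param gentrain_min,gencall10_min Keep thresholds (strict `>`).
#' @param max_nocall_fraction SNPs with a no-call fraction strictly above
#'   this fail.
#' @return Tibble `snp_id`, `gentrain`, `gencall10`, `nocall_fraction`,
#'   `passed`, `fail_reason` (NA for passing SNPs).
#' @export
qc_genotypes <- function(gm, gentrain_min = 0.4, gencall10_min = 0.2,
                         max_nocall_fraction = 0.5) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sc <- gm$snp_scores
  if (anyNA(sc$gentrain) || anyNA(sc$gencall10)) {
    abort("qc_genotypes: missing cluster-quality score",
          class = "snparray_qc_input_error")
  }
  nc <- colMeans(gm$calls == "NC")
  nc <- unname(nc[match(sc$snp_id, colnames(gm$calls))])
  fail_score <- sc$gentrain <= gentrain_min | sc$gencall10 <= gencall10_min
  fail_nc <- nc > max_nocall_fraction
  tibble::tibble(
    snp_id = sc$snp_id,
    gentrain = sc$gentrain,
    gencall10 = sc$gencall10,
    nocall_fraction = unname(nc),
    passed = !(fail_score | fail_nc),
    fail_reason = dplyr::case_when(
      fail_score ~ "cluster_score",
      fail_nc ~ "no_call",
      TRUE ~ NA_character_
    )
  )
}

#' Minor allele frequency from genotype calls
#'
#' @param calls Character vector of calls in `{AA, AB, BB, NC}` for one
#'   SNP.
#' @return `min(p, 1 - p)` where `p` is the B-allele fraction over called
#'   samples; `NA` when every sample is a no-call.
#' @export
#' @examples
#' compute_maf(c(rep("AA", 6), rep("AB", 3), "NC"))  # 3/18
compute_maf <- function(calls) {
  called <- calls[calls != "NC"]
  if (length(called) == 0) return(NA_real_)
  bad <- setdiff(unique(called), c("AA", "AB", "BB"))
  if (length(bad)) {
    abort(paste0("compute_maf: unknown call(s): ", paste(bad, collapse = ", ")),
          class = "snparray_invalid_config")
  }
  p <- (2 * sum(called == "BB") + sum(called == "AB")) / (2 * length(called))
  min(p, 1 - p)
}

maf_bin3 <- function(maf) {
  cut(maf, breaks = c(-Inf, 0.05, 0.10, Inf),
      labels = c("<5%", "5-10%", ">10%"), right = FALSE)
}

#' Classify array SNPs as failed, monomorphic or polymorphic
#'
#' Applies [qc_genotypes()] and computes the observed MAF of every
#' passing SNP; passing SNPs with MAF 0 are monomorphic, the rest
#' polymorphic. [glance()] on the result returns the class proportions
#' plus the fraction of polymorphic SNPs with MAF > 0.10 and > 0.20.
#'
#' @param gm A `genotype_matrix`.
#' @inheritParams qc_genotypes
#' @return An object of class `snp_classification`: tibble `snp_id`,
#'   `class` (factor failed/monomorphic/polymorphic), `maf`, `maf_bin`
#'   (`<5%`, `5-10%`, `>10%`; polymorphic SNPs only).
#' @export
classify_snps <- function(gm, gentrain_min = 0.4, gencall10_min = 0.2,
                          max_nocall_fraction = 0.5) {
  qc <- qc_genotypes(gm, gentrain_min, gencall10_min, max_nocall_fraction)
  maf <- vapply(qc$snp_id, function(id) compute_maf(gm$calls[, id]),
                numeric(1), USE.NAMES = FALSE)
  maf[!qc$passed] <- NA_real_
  cls <- dplyr::case_when(
    !qc$passed ~ "failed",
    maf == 0 ~ "monomorphic",
    TRUE ~ "polymorphic"
  )
  out <- tibble::tibble(
    snp_id = qc$snp_id,
    class = factor(cls, levels = c("failed", "monomorphic", "polymorphic")),
    maf = maf,
    maf_bin = ifelse(cls == "polymorphic", as.character(maf_bin3(maf)),
                     NA_character_)
  )
  class(out) <- c("snp_classification", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.snp_classification <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.snp_classification <- function(x, ...) {
  n <- nrow(x)
  poly <- x$maf[x$class == "polymorphic"]
  nf <- sum(x$class == "failed")
  nm <- sum(x$class == "monomorphic")
  np <- sum(x$class == "polymorphic")
  tibble::tibble(
    n = n,
    n_failed = nf,
    n_monomorphic = nm,
    n_polymorphic = np,
    prop_failed = nf / n,
    prop_monomorphic = nm / n,
    prop_polymorphic = np / n,
    maf_gt_10 = if (length(poly)) mean(poly > 0.10) else NA_real_,
    maf_gt_20 = if (length(poly)) mean(poly > 0.20) else NA_real_
  )
}

#' Inter-marker gap statistics of an array design
#'
#' Gaps are the distances between successive SNP positions on the same
#' chromosome; the flanks from the chromosome ends to the outermost SNPs
#' are not gaps. Reported per chromosome and pooled genome-wide (the
#' `"total"` row averages over all within-chromosome gaps).
#'
#' @param design Tibble with columns `chrom`, `pos` (unique positions).
#' @param threshold_kb Gap-size threshold for the exceedance count.
#' @return A `gap_stats` tibble: `chrom`, `n_snps`, `n_gaps`,
#'   `avg_gap_kb`, `largest_gap_kb`, `n_gaps_over`; chromosomes with
#'   fewer than two SNPs have zero gaps and `NA` summaries.
#' @export
gap_statistics <- function(design, threshold_kb = 150) {
  stopifnot(all(c("chrom", "pos") %in% names(design)))
  if (anyDuplicated(design[, c("chrom", "pos")])) {
    abort("gap_statistics: duplicate positions",
          class = "snparray_invalid_config")
  }
  per <- design |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      gaps = list(diff(sort(.data$pos)) / 1000),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_gaps = lengths(.data$gaps),
      avg_gap_kb = vapply(.data$gaps, function(g)
        if (length(g)) mean(g) else NA_real_, numeric(1)),
      largest_gap_kb = vapply(.data$gaps, function(g)
        if (length(g)) max(g) else NA_real_, numeric(1)),
      n_gaps_over = vapply(.data$gaps, function(g)
        sum(g > threshold_kb), numeric(1))
    )
  all_gaps <- unlist(per$gaps)
  total <- tibble::tibble(
    chrom = "total",
    n_snps = sum(per$n_snps),
    n_gaps = length(all_gaps),
    avg_gap_kb = if (length(all_gaps)) mean(all_gaps) else NA_real_,
    largest_gap_kb = if (length(all_gaps)) max(all_gaps) else NA_real_,
    n_gaps_over = sum(all_gaps > threshold_kb)
  )
  out <- dplyr::bind_rows(dplyr::select(per, -"gaps"), total)
  class(out) <- c("gap_stats", class(out))
  out
}

#' Compare polymorphic SNP sets of two evaluation panels
#'
#' @param class_a,class_b Two classifications over the same SNP universe:
#'   [classify_snps()] results or any tibbles with `snp_id` and `class`
#'   columns.
#' @return One-row tibble: `shared`, `a_only`, `b_only`, `union`,
#'   `shared_fraction` (shared over union) and `shared_pct`.
#' @export
compare_panels <- function(class_a, class_b) {
  if (!setequal(class_a$snp_id, class_b$snp_id)) {
    abort("compare_panels: classifications cover different SNP sets",
          class = "snparray_consistency_error")
  }
  pa <- class_a$snp_id[class_a$class == "polymorphic"]
  pb <- class_b$snp_id[class_b$class == "polymorphic"]
  shared <- length(intersect(pa, pb))
  un <- length(union(pa, pb))
  tibble::tibble(
    shared = shared,
    a_only = length(setdiff(pa, pb)),
    b_only = length(setdiff(pb, pa)),
    union = un,
    shared_fraction = if (un > 0) shared / un else NA_real_,
    shared_pct = if (un > 0) round_half_up(100 * shared / un, 1) else NA_real_
  )
}

#' Validation outcome cross-tabulation
#'
#' Tabulates, for every level of every labelling column, the proportion of
#' SNPs that failed, were monomorphic, or were polymorphic in a validation
#' assay, and the split of the polymorphic proportion across validation
#' MAF bins (`<5%`, `5-10%`, `>10%`). Proportions are rounded half-up to
#' two decimals, the convention of published validation tables, in the
#' `prop_*` columns; raw fractions stay in `frac_*` columns.
#'
#' @param snps Tibble with one row per SNP: an `outcome` column in
#'   `{failed, monomorphic, polymorphic}`, a `validation_maf` column
#'   (required for polymorphic SNPs), and the labelling columns named in
#'   `by`.
#' @param by Character vector of labelling column names; a `"Total"`
#'   stratum over all SNPs is always appended.
#' @return Tibble with columns `parameter`, `level`, `total`,
#'   `prop_failed`, `prop_monomorphic`, `prop_polymorphic`,
#'   `prop_maf_lt5`, `prop_maf_5_10`, `prop_maf_gt10` (and matching
#'   unrounded `frac_*` columns).
#' @export
crosstab_validation <- function(snps, by = character()) {
  stopifnot("outcome" %in% names(snps))
  bad <- setdiff(unique(snps$outcome),
                 c("failed", "monomorphic", "polymorphic"))
  if (length(bad)) {
    abort(paste0("crosstab_validation: unknown outcome(s): ",
                 paste(bad, collapse = ", ")),
          class = "snparray_labeling_error")
  }
  if (!all(by %in% names(snps))) {
    abort("crosstab_validation: missing labelling column(s)",
          class = "snparray_labeling_error")
  }
  for (b in by) {
    if (anyNA(snps[[b]])) {
      abort(paste0("crosstab_validation: unlabeled SNP in column ", b),
            class = "snparray_labeling_error")
    }
  }
  if (!"validation_maf" %in% names(snps)) snps$validation_maf <- NA_real_
  poly_na <- snps$outcome == "polymorphic" & is.na(snps$validation_maf)
  if (any(poly_na)) {
    abort("crosstab_validation: polymorphic SNP without validation MAF",
          class = "snparray_labeling_error")
  }
  one <- function(sub, parameter, level) {
    n <- nrow(sub)
    poly <- sub$outcome == "polymorphic"
    bins <- table(maf_bin3(sub$validation_maf[poly]))
    fr <- c(failed = mean(sub$outcome == "failed"),
            mono = mean(sub$outcome == "monomorphic"),
            poly = mean(poly),
            lt5 = unname(bins["<5%"]) / n,
            mid = unname(bins["5-10%"]) / n,
            gt10 = unname(bins[">10%"]) / n)
    tibble::tibble(
      parameter = parameter, level = as.character(level), total = n,
      prop_failed = round_half_up(fr[["failed"]], 2),
      prop_monomorphic = round_half_up(fr[["mono"]], 2),
      prop_polymorphic = round_half_up(fr[["poly"]], 2),
      prop_maf_lt5 = round_half_up(fr[["lt5"]], 2),
      prop_maf_5_10 = round_half_up(fr[["mid"]], 2),
      prop_maf_gt10 = round_half_up(fr[["gt10"]], 2),
      frac_failed = fr[["failed"]], frac_monomorphic = fr[["mono"]],
      frac_polymorphic = fr[["poly"]], frac_maf_lt5 = fr[["lt5"]],
      frac_maf_5_10 = fr[["mid"]], frac_maf_gt10 = fr[["gt10"]]
    )
  }
  rows <- list()
  for (b in by) {
    for (lv in unique(snps[[b]])) {
      rows[[length(rows) + 1L]] <- one(snps[snps[[b]] == lv, , drop = FALSE],
                                       b, lv)
    }
  }
  rows[[length(rows) + 1L]] <- one(snps, "Total", "Total")
  dplyr::bind_rows(rows)
}

#' Progeny informativeness of polymorphic SNPs
#'
#' @param flags Logical matrix (or data frame) of polymorphic SNPs x
#'   progenies: `TRUE` where the SNP segregates in that progeny.
#' @return A list: `per_progeny` (tibble `progeny`, `n_segregating`,
#'   `fraction`), `any_progeny_fraction` (share of SNPs segregating in at
#'   least one progeny), `any_progeny_pct` (the same as a half-up
#'   percentage at 0 dp), `by_progeny_count` (tibble `n_progenies`,
#'   `n_snps` over the observed counts).
#' @export
progeny_informativeness <- function(flags) {
  flags <- as.matrix(flags)
  storage.mode(flags) <- "logical"
  n <- nrow(flags)
  per <- tibble::tibble(
    progeny = colnames(flags) %||% paste0("progeny", seq_len(ncol(flags))),
    n_segregating = colSums(flags),
    fraction = if (n > 0) colSums(flags) / n else NA_real_
  )
  counts <- rowSums(flags)
  any_frac <- if (n > 0) mean(counts >= 1) else NA_real_
  list(
    per_progeny = per,
    any_progeny_fraction = any_frac,
    any_progeny_pct = if (!is.na(any_frac)) round_half_up(100 * any_frac)
                      else NA_real_,
    by_progeny_count = dplyr::count(tibble::tibble(n_progenies = counts),
                                    .data$n_progenies, name = "n_snps")
  )
}

#' Sequencing coverage accounting
#'
#' Converts per-run read counts and lengths into genome coverage
#' (`reads x length / genome size`) and keeps any supplied metadata. Use
#' [coverage_summary()] for aggregates.
#'
#' @param records Tibble with columns `read_count_million` and
#'   `read_length` (bp); alternatively a precomputed `coverage` column.
#' @param genome_size Effective genome size in bp.
#' @return `records` with a `coverage` column (x genome).
#' @export
coverage_accounting <- function(records, genome_size = NULL) {
  has_reads <- all(c("read_count_million", "read_length") %in% names(records))
  if (has_reads) {
    if (is.null(genome_size) || genome_size <= 0) {
      abort("coverage_accounting: genome_size must be positive",
            class = "snparray_invalid_config")
    }
    if (any(records$read_count_million < 0 | records$read_length <= 0)) {
      abort("coverage_accounting: read counts/lengths must be positive",
            class = "snparray_invalid_config")
    }
    records$coverage <- records$read_count_million * 1e6 *
      records$read_length / genome_size
  } else if (!"coverage" %in% names(records)) {
    abort(paste0("coverage_accounting: need read_count_million + ",
                 "read_length, or a coverage column"),
          class = "snparray_invalid_config")
  }
  records
}

#' Aggregate coverage records
#'
#' @param records Output of [coverage_accounting()] (must have a
#'   `coverage` column; an optional logical `excluded` column marks
#'   flagged low-yield runs that are left out of the mean but kept in the
#'   total).
#' @param by Optional grouping column names (e.g. `"platform"`,
#'   `"pool"`).
#' @return Tibble with `n`, `total_coverage` and `mean_coverage` per
#'   group.
#' @export
coverage_summary <- function(records, by = NULL) {
  stopifnot("coverage" %in% names(records))
  if (!"excluded" %in% names(records)) records$excluded <- FALSE
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character()))) |>
    dplyr::summarise(
      n = dplyr::n(),
      total_coverage = sum(.data$coverage),
      mean_coverage = mean(.data$coverage[!.data$excluded]),
      .groups = "drop"
    )
}

#' MAF concordance between two sample groups
#'
#' Pearson correlation of per-SNP minor allele frequencies over the SNPs
#' shared (named in both vectors, both non-missing).
#'
#' @param maf_a,maf_b Named numeric vectors of per-SNP MAF.
#' @return The correlation coefficient.
#' @export
maf_concordance <- function(maf_a, maf_b) {
  if (is.null(names(maf_a)) || is.null(names(maf_b))) {
    if (length(maf_a) != length(maf_b)) {
      abort("maf_concordance: unnamed vectors must have equal length",
            class = "snparray_invalid_config")
    }
    shared_a <- maf_a
    shared_b <- maf_b
  } else {
    ids <- intersect(names(maf_a), names(maf_b))
    shared_a <- maf_a[ids]
    shared_b <- maf_b[ids]
  }
  ok <- is.finite(shared_a) & is.finite(shared_b)
  if (sum(ok) < 3) {
    abort("maf_concordance: fewer than 3 shared SNPs",
          class = "snparray_insufficient_data")
  }
  if (sd(shared_a[ok]) == 0 || sd(shared_b[ok]) == 0) {
    warn("maf_concordance: zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(shared_a[ok], shared_b[ok])
}
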