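#' Stage-1 filtering parameters
#'
#' Two detection regimes are supported, mirroring the two variant-calling
#' laboratories' rule sets:
#'
#' * **Regime A** (deep-coverage pools): caller quality inclusive
#'   `>= 25`; total site coverage (reads summed over the pool's
#'   accessions) between `cov_min = 30` and `2.5 x` the mean site
#'   coverage of the input; minor-allele read support `>= 5`; sites inside
#'   a supplied repeat interval track removed.
#' * **Regime B** (shallow pools): quality strictly `> 30`; the larger
#'   per-allele read total must stay below the mean site total plus three
#'   standard deviations (both derived from the input call tables); minor
#'   allele support `>= 5` with total coverage `>= 10`; average k-mer copy
#'   number of the SNP flanking region must be `< 2`.
#'
#' The coverage ceilings are recomputed from the data at run time, not
#' fixed constants: on the study scale they correspond to ceilings of 161
#' and 380 reads respectively.
#'
#' @param regime `"A"` or `"B"`.
#' @param q_min Quality threshold (inclusive for A, strict for B).
#' @param q_strict Whether the quality comparison is strict (`>`); default
#'   follows the regime.
#' @param cov_min Minimum total site coverage, in reads.
#' @param cov_max_rule List describing the ceiling: either
#'   `list(type = "multiple_of_mean", factor = 2.5)` (applied to the site
#'   total) or `list(type = "mean_plus_sd", k = 3)` (applied to the larger
#'   per-allele total).
#' @param minor_allele_min_reads Minimum reads supporting the minor allele.
#' @param copy_number_max Flank copy-number ceiling (regime B; strict `<`).
#' @param flank_bp,kmer_k Flank half-width and k-mer size for copy-number
#'   estimation.
#' @return A list of class `stage1_params`.
#' @export
stage1_params <- function(regime = c("A", "B"),
                          q_min = NULL,
                          q_strict = NULL,
                          cov_min = NULL,
                          cov_max_rule = NULL,
                          minor_allele_min_reads = 5L,
                          copy_number_max = 2,
                          flank_bp = 50L,
                          kmer_k = 31L) {
  regime <- match.arg(regime)
  if (regime == "A") {
    q_min <- q_min %||% 25
    q_strict <- q_strict %||% FALSE
    cov_min <- cov_min %||% 30L
    cov_max_rule <- cov_max_rule %||% list(type = "multiple_of_mean",
                                           factor = 2.5)
  } else {
    q_min <- q_min %||% 30
    q_strict <- q_strict %||% TRUE
    cov_min <- cov_min %||% 10L
    cov_max_rule <- cov_max_rule %||% list(type = "mean_plus_sd", k = 3)
  }
  if (q_min < 0 || minor_allele_min_reads < 1) {
    abort("stage1_params: q_min must be >= 0 and minor_allele_min_reads >= 1",
          class = "snparray_invalid_config")
  }
  if (!cov_max_rule$type %in% c("multiple_of_mean", "mean_plus_sd", "none")) {
    abort("stage1_params: unknown cov_max_rule type",
          class = "snparray_invalid_config")
  }
  if ((cov_max_rule$type == "multiple_of_mean" && cov_max_rule$factor <= 0) ||
      (cov_max_rule$type == "mean_plus_sd" && cov_max_rule$k <= 0)) {
    abort("stage1_params: cov_max_rule factor/k must be positive",
          class = "snparray_invalid_config")
  }
  structure(
    list(regime = regime, q_min = q_min, q_strict = q_strict,
         cov_min = cov_min, cov_max_rule = cov_max_rule,
         minor_allele_min_reads = as.integer(minor_allele_min_reads),
         copy_number_max = copy_number_max, flank_bp = as.integer(flank_bp),
         kmer_k = as.integer(kmer_k)),
    class = "stage1_params"
  )
}

site_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  hit <- dplyr::inner_join(
    tibble::tibble(chrom = chrom, pos = pos, .row = seq_along(pos)),
    intervals[, c("chrom", "start", "end")],
    by = "chrom", relationship = "many-to-many"
  )
  hit <- hit[hit$pos >= hit$start & hit$pos <= hit$end, ]
  seq_along(pos) %in% hit$.row
}

#' Stage-1 variant filtering
#'
#' Filters pooled per-accession call records down to candidate SNPs under
#' one of the two detection regimes (see [stage1_params()]). Records whose
#' quality fails the regime threshold are discarded first; remaining
#' evidence is aggregated per site (chromosome, position, ref, alt), and a
#' site survives only if its total coverage sits inside the regime's
#' coverage band, its minor allele (the less-supported of the two alleles)
#' has sufficient read support, and it passes the repeat screen (interval
#' track for regime A, flank k-mer copy number for regime B).
#'
#' @param calls Tibble of call records with columns `accession`, `chrom`,
#'   `pos`, `ref`, `alt`, `ref_depth`, `alt_depth`, `qual` (e.g. from
#'   [simulate_callsets()] or [read_call_table()]).
#' @param params A [stage1_params()].
#' @param genome Optional [genome_assembly]; required for coordinate
#'   validation and for the regime-B copy-number rule.
#' @param repeats Optional repeat-interval tibble (`chrom`, `start`,
#'   `end`, 1-based inclusive) used by regime A.
#' @return A tibble of candidate SNPs sorted by `(chrom, pos)` with
#'   columns `chrom`, `pos`, `ref`, `alt`, `n_support` (accessions with at
#'   least one minor-allele-supporting read), `maf` (detection minor
#'   allele frequency from allele-presence genotypes across accessions),
#'   `source` (`"regimeA"`/`"regimeB"`). A funnel log of per-rule removal
#'   counts is attached as attribute `"funnel"` (see [stage_log()]).
#' @export
filter_stage1 <- function(calls, params, genome = NULL, repeats = NULL) {
  stopifnot(inherits(params, "stage1_params"))
  req <- c("accession", "chrom", "pos", "ref", "alt",
           "ref_depth", "alt_depth", "qual")
  if (!all(req %in% names(calls))) {
    abort(paste0("filter_stage1: calls must have columns ",
                 paste(req, collapse = ", ")),
          class = "snparray_invalid_config")
  }
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          n_support = integer(), maf = numeric(),
                          source = character())
  if (nrow(calls) == 0) {
    attr(empty, "funnel") <- tibble::tibble(rule = character(),
                                            removed = integer(),
                                            remaining = integer())
    return(empty)
  }
  if (!is.null(genome)) {
    lens <- genome_seq_length(genome, calls$chrom)
    if (any(calls$pos < 1 | calls$pos > lens)) {
      abort("filter_stage1: call position outside chromosome",
            class = "snparray_reference_mismatch")
    }
  }
  if (any(calls$ref_depth < 0 | calls$alt_depth < 0)) {
    abort("filter_stage1: negative read depth",
          class = "snparray_invalid_config")
  }

  log <- list()
  note <- function(rule, removed, remaining) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      rule = rule, removed = as.integer(removed),
      remaining = as.integer(remaining))
  }

  n_sites0 <- dplyr::n_distinct(paste(calls$chrom, calls$pos, calls$alt))
  ok_q <- if (params$q_strict) calls$qual > params$q_min else
    calls$qual >= params$q_min
  calls <- calls[ok_q, , drop = FALSE]

  site <- calls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      site_ref = sum(.data$ref_depth),
      site_alt = sum(.data$alt_depth),
      .groups = "drop"
    )
  site$total <- site$site_ref + site$site_alt
  note("quality", n_sites0 - nrow(site), nrow(site))

  if (nrow(site) > 0) {
    keep <- site$total >= params$cov_min
    site_min <- site[keep, , drop = FALSE]
    note("cov_min", sum(!keep), nrow(site_min))

    rule <- params$cov_max_rule
    if (rule$type == "multiple_of_mean") {
      cov_max <- rule$factor * mean(site$total)
      keep <- site_min$total <= cov_max
    } else if (rule$type == "mean_plus_sd") {
      cov_max <- mean(site$total) +
        rule$k * (if (nrow(site) > 1) sd(site$total) else 0)
      keep <- pmax(site_min$site_ref, site_min$site_alt) < cov_max
    } else {
      cov_max <- Inf
      keep <- rep(TRUE, nrow(site_min))
    }
    site2 <- site_min[keep, , drop = FALSE]
    note("cov_max", sum(!keep), nrow(site2))

    keep <- pmin(site2$site_ref, site2$site_alt) >=
      params$minor_allele_min_reads
    site3 <- site2[keep, , drop = FALSE]
    note("minor_allele", sum(!keep), nrow(site3))

    if (params$regime == "A") {
      inrep <- site_in_intervals(site3$chrom, site3$pos, repeats)
      site4 <- site3[!inrep, , drop = FALSE]
      note("repeat_track", sum(inrep), nrow(site4))
    } else {
      if (!is.null(genome) && nrow(site3) > 0) {
        cn <- estimate_copy_number(genome, site3$chrom, site3$pos,
                                   flank_bp = params$flank_bp,
                                   k = params$kmer_k)
        keep <- !is.na(cn) & cn < params$copy_number_max
      } else {
        keep <- rep(TRUE, nrow(site3))
      }
      site4 <- site3[keep, , drop = FALSE]
      note("copy_number", sum(!keep), nrow(site4))
    }
  } else {
    site4 <- site
  }

  if (nrow(site4) == 0) {
    out <- empty
  } else {
    # per-accession allele-presence genotypes at surviving sites
    ev <- dplyr::semi_join(calls, site4, by = c("chrom", "pos", "ref", "alt"))
    geno <- ev |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt,
                      .data$accession) |>
      dplyr::summarise(has_ref = any(.data$ref_depth > 0),
                       has_alt = any(.data$alt_depth > 0), .groups = "drop") |>
      dplyr::mutate(dosage = dplyr::case_when(
        .data$has_alt & .data$has_ref ~ 1L,
        .data$has_alt ~ 2L,
        TRUE ~ 0L))
    stats <- geno |>
      dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::summarise(p_alt = sum(.data$dosage) / (2 * dplyr::n()),
                       n_alt_acc = sum(.data$has_alt),
                       n_ref_acc = sum(.data$has_ref), .groups = "drop")
    out <- site4 |>
      dplyr::left_join(stats, by = c("chrom", "pos", "ref", "alt")) |>
      dplyr::mutate(
        maf = pmin(.data$p_alt, 1 - .data$p_alt),
        minor_is_alt = .data$site_alt <= .data$site_ref,
        n_support = ifelse(.data$minor_is_alt, .data$n_alt_acc,
                           .data$n_ref_acc),
        source = paste0("regime", params$regime)
      ) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$alt) |>
      dplyr::select("chrom", "pos", "ref", "alt", "n_support", "maf",
                    "source")
  }
  attr(out, "funnel") <- dplyr::bind_rows(log)
  out
}

#' Retrieve the per-rule removal log of a filtering step
#'
#' Filtering operations attach a funnel log (rule, removed, remaining) as
#' an attribute; this accessor returns it as a tibble.
#'
#' @param x A result of [filter_stage1()] or [filter_stage2()].
#' @return A tibble with columns `rule`, `removed`, `remaining`.
#' @export
stage_log <- function(x) {
  f <- attr(x, "funnel")
  if (is.null(f)) {
    abort("no funnel log attached to this object",
          class = "snparray_invalid_config")
  }
  f
}

#' Average k-mer copy number of a SNP flanking region
#'
#' For each site, takes the window of `flank_bp` bases on either side of
#' the position (truncated at chromosome ends), enumerates all its k-mers,
#' and returns the mean over those k-mers of their genome-wide occurrence
#' counts (both strands, canonical counting). Unique sequence gives 1.0; a
#' region duplicated exactly once elsewhere gives 2.0.
#'
#' @param genome A [genome_assembly].
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param flank_bp Flank half-width in bp.
#' @param k K-mer size; must not exceed the window width.
#' @return Numeric vector of average copy numbers; `NA` where the window
#'   contains no ACGT-only k-mer (e.g. all-N sequence), with a warning.
#' @export
estimate_copy_number <- function(genome, chrom, pos, flank_bp = 50L, k = 31L) {
  stopifnot(inherits(genome, "genome_assembly"))
  chrom <- rep(chrom, length.out = length(pos))
  lens <- genome_seq_length(genome, chrom)
  if (any(pos < 1 | pos > lens)) {
    abort("estimate_copy_number: position outside chromosome",
          class = "snparray_coordinate_error")
  }
  start <- pmax(1, pos - flank_bp)
  end <- pmin(lens, pos + flank_bp)
  if (any(end - start + 1 < k)) {
    abort("estimate_copy_number: window narrower than k",
          class = "snparray_invalid_config")
  }
  windows <- vapply(seq_along(pos), function(i) {
    genome_subseq(genome, chrom[i], start[i], end[i])
  }, character(1))
  kmers_per_window <- lapply(windows, function(w) {
    n <- nchar(w) - k + 1L
    substring(w, seq_len(n), seq_len(n) + k - 1L)
  })
  all_kmers <- unlist(kmers_per_window, use.names = FALSE)
  counts <- count_genome_kmers(genome, all_kmers)
  idx <- rep(seq_along(pos), lengths(kmers_per_window))
  out <- vapply(seq_along(pos), function(i) {
    ci <- counts[idx == i]
    ci <- ci[!is.na(ci)]
    if (length(ci) == 0) NA_real_ else mean(ci)
  }, numeric(1))
  if (anyNA(out)) {
    warn("estimate_copy_number: window(s) with no ACGT k-mer; returning NA")
  }
  out
}

#' Compare two call sets of one accession at candidate positions
#'
#' Classifies each candidate position as not comparable (no coverage in at
#' least one call set) or comparable, and among comparable positions
#' compares allele-presence genotypes (the set of alleles with at least
#' one supporting read): identical sets, sharing one allele, or sharing
#' none. Diploid genotype calling is deliberately avoided because the
#' coverage regimes under comparison are too shallow for it.
#'
#' @param calls_a,calls_b Call-record tibbles for the same accession
#'   identity (columns as in [filter_stage1()]).
#' @param candidate_positions Tibble with columns `chrom`, `pos`.
#' @return An object of class `concordance_report` (also a one-row
#'   tibble): `n_candidates`, `n_not_covered_both`, `n_comparable`,
#'   `comparable_fraction`, `same_genotype_fraction`,
#'   `partial_share_fraction`, `no_share_fraction`. With zero comparable
#'   positions the fractions are `NA` and `zero_denominator` is `TRUE`.
#' @export
compare_callsets <- function(calls_a, calls_b, candidate_positions) {
  stopifnot(all(c("chrom", "pos") %in% names(candidate_positions)))
  allele_sets <- function(calls) {
    if (nrow(calls) == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            alleles = list()))
    }
    calls |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(alleles = list(sort(unique(c(
        .data$ref[.data$ref_depth > 0], .data$alt[.data$alt_depth > 0]
      )))), .groups = "drop") |>
      dplyr::filter(lengths(.data$alleles) > 0)
  }
  ga <- allele_sets(calls_a)
  gb <- allele_sets(calls_b)
  cand <- dplyr::distinct(candidate_positions[, c("chrom", "pos")])
  m <- cand |>
    dplyr::left_join(dplyr::rename(ga, a = "alleles"), by = c("chrom", "pos")) |>
    dplyr::left_join(dplyr::rename(gb, b = "alleles"), by = c("chrom", "pos"))
  comparable <- !vapply(m$a, is.null, logical(1)) &
    !vapply(m$b, is.null, logical(1))
  n_comp <- sum(comparable)
  cls <- character(0)
  if (n_comp > 0) {
    cls <- mapply(function(a, b) {
      if (identical(a, b)) "identical"
      else if (length(intersect(a, b)) > 0) "partial"
      else "none"
    }, m$a[comparable], m$b[comparable])
  }
  out <- tibble::tibble(
    n_candidates = nrow(cand),
    n_not_covered_both = nrow(cand) - n_comp,
    n_comparable = n_comp,
    comparable_fraction = if (nrow(cand) > 0) n_comp / nrow(cand) else NA_real_,
    same_genotype_fraction = if (n_comp > 0) mean(cls == "identical") else NA_real_,
    partial_share_fraction = if (n_comp > 0) mean(cls == "partial") else NA_real_,
    no_share_fraction = if (n_comp > 0) mean(cls == "none") else NA_real_,
    zero_denominator = n_comp == 0
  )
  class(out) <- c("concordance_report", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.concordance_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("comparable_fraction", "same_genotype_fraction",
                  "partial_share_fraction", "no_share_fraction"),
    value = c(x$comparable_fraction, x$same_genotype_fraction,
              x$partial_share_fraction, x$no_share_fraction)
  )
}
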