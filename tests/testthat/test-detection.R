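make_calls <- function(...) {
  tibble::tibble(...)
}

# a one-site pool split across accessions, easy to reason about by hand
site_calls <- function(chrom = "chr1", pos = 500L, depths, quals = 35) {
  n <- nrow(depths)
  tibble::tibble(
    accession = sprintf("a%02d", seq_len(n)), chrom = chrom, pos = pos,
    ref = "A", alt = "G",
    ref_depth = depths[, 1], alt_depth = depths[, 2],
    qual = rep(quals, length.out = n)
  )
}

test_that("regime A enforces the 30-read coverage floor at the boundary", {
  # 29 total reads -> excluded; 30 -> kept (cov_max not binding: single site)
  below <- site_calls(depths = cbind(c(12, 12), c(3, 2)))
  at <- site_calls(depths = cbind(c(12, 12), c(3, 3)))
  p <- stage1_params("A")
  expect_equal(nrow(filter_stage1(below, p)), 0)
  expect_equal(nrow(filter_stage1(at, p)), 1)
  # and the funnel names the rule
  expect_equal(stage_log(filter_stage1(below, p))$rule[2], "cov_min")
})

test_that("hand-built records at each rule boundary match the brute-force evaluator", {
  # 12 sites straddling: quality 30 vs 31 (regime B strict), minor reads
  # 4 vs 5, and coverage at the ceiling
  rows <- list(
    site_calls("chr1", 100L, cbind(30, 5), quals = 31),   # all pass
    site_calls("chr1", 200L, cbind(30, 5), quals = 30),   # quality == 30 fails B
    site_calls("chr1", 300L, cbind(30, 4), quals = 35),   # minor reads 4
    site_calls("chr1", 400L, cbind(40, 5), quals = 35),
    site_calls("chr1", 500L, cbind(5, 5), quals = 35),    # total 10 at floor
    site_calls("chr1", 600L, cbind(5, 4), quals = 35),    # total 9 below floor
    site_calls("chr2", 100L, cbind(300, 6), quals = 35),  # large ref total
    site_calls("chr2", 200L, cbind(6, 6), quals = 35),
    site_calls("chr2", 300L, cbind(0, 12), quals = 35),   # no ref reads
    site_calls("chr2", 400L, cbind(12, 0), quals = 35),   # no alt reads
    site_calls("chr2", 500L, cbind(20, 20), quals = 32),
    site_calls("chr2", 600L, cbind(8, 150), quals = 35)
  )
  calls <- do.call(rbind, rows)
  calls$accession <- sprintf("a%02d", seq_len(nrow(calls)))
  for (regime in c("A", "B")) {
    p <- stage1_params(regime)
    got <- filter_stage1(calls, p)
    want <- oracle_stage1(calls, p)
    expect_equal(got$pos, want$pos, info = paste("regime", regime))
    expect_equal(got$chrom, want$chrom, info = paste("regime", regime))
  }
})

test_that("stage-1 filter equals the brute-force evaluator on random panels", {
  set.seed(404)
  genome <- make_test_genome(seed = 8, lengths = c(chr1 = 3000, chr2 = 2000))
  for (rep in 1:6) {
    n_sites <- sample(20:50, 1)
    n_acc <- sample(3:10, 1)
    sites <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n_sites, replace = TRUE),
      pos = sample(100:1900, n_sites),
      ref = sample(c("A", "C"), n_sites, replace = TRUE),
      alt = sample(c("G", "T"), n_sites, replace = TRUE)
    )
    calls <- tidyr::crossing(accession = sprintf("a%02d", seq_len(n_acc)),
                             sites) |>
      dplyr::mutate(
        ref_depth = rpois(dplyr::n(), 8),
        alt_depth = rpois(dplyr::n(), 3),
        qual = sample(c(20, 24, 25, 26, 30, 31, 35), dplyr::n(),
                      replace = TRUE)
      )
    repeats <- tibble::tibble(chrom = "chr1", start = 500L, end = 900L)
    for (regime in c("A", "B")) {
      p <- stage1_params(regime)
      cn <- NULL
      if (regime == "B") {
        key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
        uq <- !duplicated(key)
        cn_vals <- estimate_copy_number(genome, calls$chrom[uq],
                                        calls$pos[uq], flank_bp = 50, k = 31)
        cn <- as.list(setNames(cn_vals, key[uq]))
      }
      got <- filter_stage1(calls, p, genome = genome,
                           repeats = if (regime == "A") repeats)
      want <- oracle_stage1(calls, p,
                            repeats = if (regime == "A") repeats,
                            copy_number = cn)
      expect_equal(paste(got$chrom, got$pos, got$alt),
                   paste(want$chrom, want$pos, want$alt),
                   info = paste("rep", rep, "regime", regime))
    }
  }
})

test_that("stage-1 filtering is order-invariant and monotone in its thresholds", {
  set.seed(77)
  calls <- tidyr::crossing(
    accession = sprintf("a%02d", 1:6),
    tibble::tibble(chrom = "chr1", pos = seq(100L, 4000L, by = 100L),
                   ref = "A", alt = "T")
  ) |>
    dplyr::mutate(ref_depth = rpois(dplyr::n(), 7),
                  alt_depth = rpois(dplyr::n(), 2),
                  qual = runif(dplyr::n(), 20, 40))
  base <- filter_stage1(calls, stage1_params("A"))
  shuffled <- filter_stage1(calls[sample(nrow(calls)), ], stage1_params("A"))
  expect_equal(base, shuffled, ignore_attr = TRUE)
  # output positions are a subset of input positions, sorted
  expect_true(all(base$pos %in% calls$pos))
  expect_false(is.unsorted(base$pos))

  for (tweak in list(list(q_min = 30), list(minor_allele_min_reads = 8),
                     list(cov_min = 45))) {
    p <- do.call(stage1_params, c(list(regime = "A"), tweak))
    tightened <- filter_stage1(calls, p)
    expect_true(all(paste(tightened$chrom, tightened$pos) %in%
                      paste(base$chrom, base$pos)))
  }
  # empty input -> empty output, no error
  expect_equal(nrow(filter_stage1(calls[0, ], stage1_params("A"))), 0)
  # unknown chromosome -> reference mismatch
  genome <- make_test_genome(lengths = c(chr1 = 5000))
  bad <- calls
  bad$chrom[1] <- "chrX"
  expect_error(filter_stage1(bad, stage1_params("A"), genome = genome),
               class = "snparray_reference_mismatch")
})

test_that("flank copy number is 1 in unique sequence and 2 in a duplicated block", {
  genome <- make_test_genome(seed = 12, lengths = c(chr1 = 6000, chr2 = 4000))
  expect_equal(estimate_copy_number(genome, "chr1", 3000L), 1.0)

  dup <- duplicate_block(genome, "chr1", start = 2800L, len = 401L,
                         dst_chrom = "chr2", dst_start = 1000L)
  cn <- estimate_copy_number(dup, "chr1", 3000L, flank_bp = 50, k = 31)
  expect_equal(cn, 2.0)
  # brute-force cross-check of the window k-mer counts
  census <- oracle_kmer_census(dup$seq, 31)
  win <- substr(as.character(dup$seq[["chr1"]]), 2950, 3050)
  kmers <- substring(win, 1:(nchar(win) - 30), 31:nchar(win))
  expect_equal(mean(vapply(kmers, function(k)
    oracle_kmer_count(census, k), integer(1))), cn)

  # the regime-B rule (< 2) excludes the duplicated site
  calls <- site_calls("chr1", 3000L, cbind(c(10, 10), c(5, 5)), quals = 35)
  expect_equal(nrow(filter_stage1(calls, stage1_params("B"), genome = dup)), 0)
  expect_equal(nrow(filter_stage1(calls, stage1_params("B"), genome = genome)), 1)

  # window narrower than k errors
  expect_error(estimate_copy_number(genome, "chr1", 3000L, flank_bp = 5,
                                    k = 31),
               class = "snparray_invalid_config")
})

test_that("call-set concordance classifies shared, partial and disjoint genotypes", {
  mk <- function(pos, ref, alt, rd, ad) {
    tibble::tibble(accession = "acc", chrom = "chr1", pos = pos, ref = ref,
                   alt = alt, ref_depth = rd, alt_depth = ad, qual = 35)
  }
  # 6 candidate positions: 2 identical, 1 half-shared, 1 disjoint, 2 uncovered
  a <- rbind(mk(100L, "A", "G", 5L, 5L),  # {A,G}
             mk(200L, "C", "T", 8L, 0L),  # {C}
             mk(300L, "A", "G", 4L, 4L),  # {A,G}
             mk(400L, "C", "T", 6L, 0L),  # {C}
             mk(500L, "A", "G", 3L, 3L))  # covered in A only
  b <- rbind(mk(100L, "A", "G", 6L, 2L),  # {A,G} identical
             mk(200L, "C", "T", 9L, 0L),  # {C} identical
             mk(300L, "A", "G", 0L, 7L),  # {G} shares one allele
             mk(400L, "C", "T", 0L, 5L))  # {T} disjoint
  cand <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L, 300L, 400L,
                                                 500L, 600L))
  rep <- compare_callsets(a, b, cand)
  expect_equal(rep$n_comparable, 4)
  expect_equal(rep$n_not_covered_both, 2)
  expect_equal(rep$same_genotype_fraction, 0.5)
  expect_equal(rep$partial_share_fraction, 0.25)
  expect_equal(rep$no_share_fraction, 0.25)
  expect_equal(rep$same_genotype_fraction + rep$partial_share_fraction +
                 rep$no_share_fraction, 1)

  # identical call sets covering 10 of 50 candidates
  set.seed(9)
  cand50 <- tibble::tibble(chrom = "chr1", pos = seq(100L, 5000L, by = 100L))
  covered <- mk(cand50$pos[1:10], "A", "G", 5L, 5L)
  rep2 <- compare_callsets(covered, covered, cand50)
  expect_equal(rep2$comparable_fraction, 0.2)
  expect_equal(rep2$same_genotype_fraction, 1.0)

  # empty second call set: nothing comparable, zero denominator flagged
  rep3 <- compare_callsets(covered, covered[0, ], cand50)
  expect_equal(rep3$n_comparable, 0)
  expect_true(rep3$zero_denominator)
  expect_true(is.na(rep3$same_genotype_fraction))
})
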