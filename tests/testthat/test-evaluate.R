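test_that("QC thresholds are strict keep rules and the partition is exhaustive", {
  calls <- matrix("AA", nrow = 10, ncol = 4,
                  dimnames = list(paste0("s", 1:10), paste0("m", 1:4)))
  calls[1:6, 3] <- "NC"   # 60% no-call
  calls[1:5, 4] <- "NC"   # exactly 50% no-call: allowed
  gm <- make_genotype_matrix(calls,
                             gentrain = c(0.39, 0.8, 0.9, 0.9),
                             gencall10 = c(0.5, 0.19, 0.6, 0.6))
  qc <- qc_genotypes(gm)
  expect_equal(qc$passed, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(qc$fail_reason[1:3], c("cluster_score", "cluster_score",
                                      "no_call"))
  gm$snp_scores$gentrain[1] <- NA
  expect_error(qc_genotypes(gm), class = "snparray_qc_input_error")
})

test_that("QC on a large planted report equals the rule-by-rule brute force", {
  set.seed(66)
  n <- 1000
  calls <- matrix(sample(c("AA", "AB", "BB"), 40 * n, replace = TRUE),
                  nrow = 40, dimnames = list(paste0("s", 1:40),
                                             paste0("m", 1:n)))
  nc_frac <- sample(c(0, 0.2, 0.55, 0.8), n, replace = TRUE)
  for (j in seq_len(n)) {
    k <- round(40 * nc_frac[j])
    if (k > 0) calls[sample(40, k), j] <- "NC"
  }
  gentrain <- runif(n)
  gencall10 <- runif(n)
  gm <- make_genotype_matrix(calls, gentrain, gencall10)
  qc <- qc_genotypes(gm)
  want <- logical(n)
  for (j in seq_len(n)) {
    want[j] <- gentrain[j] > 0.4 && gencall10[j] > 0.2 &&
      mean(calls[, j] == "NC") <= 0.5
  }
  expect_equal(qc$passed, want)
  # partition conservation through classification
  cls <- classify_snps(gm)
  expect_equal(sum(table(cls$class)), n)
  expect_true(all(cls$maf[cls$class == "polymorphic"] > 0))
  expect_true(all(is.na(cls$maf[cls$class == "failed"])))
  expect_true(all(cls$maf <= 0.5, na.rm = TRUE))
})

test_that("MAF from genotype calls counts alleles over called samples only", {
  expect_equal(compute_maf(c("AA", "AA", "AA")), 0)
  expect_equal(compute_maf(c("AA", "AB", "BB")), 0.5)
  expect_equal(compute_maf(c(rep("AA", 6), rep("AB", 3), "NC")), 3 / 18)
  expect_true(is.na(compute_maf(c("NC", "NC"))))
})

test_that("gap statistics match hand arithmetic and the brute-force oracle", {
  d <- tibble::tibble(chrom = "chr1", pos = c(1e5, 2e5, 5e5))
  g <- gap_statistics(d)
  row <- g[g$chrom == "chr1", ]
  expect_equal(row$avg_gap_kb, 200)
  expect_equal(row$largest_gap_kb, 300)
  expect_equal(row$n_gaps_over, 1)

  # single SNP on a chromosome: no gap entries
  g1 <- gap_statistics(tibble::tibble(chrom = "chr9", pos = 5L))
  expect_equal(g1$n_gaps[g1$chrom == "chr9"], 0)
  expect_true(is.na(g1$avg_gap_kb[g1$chrom == "chr9"]))

  # 50 random positions across chromosomes vs oracle
  set.seed(12)
  d50 <- tibble::tibble(chrom = sample(paste0("chr", 1:3), 50, replace = TRUE),
                        pos = sample(2e6, 50))
  got <- gap_statistics(d50)
  want <- oracle_gap_stats(d50)
  for (ch in want$per_chrom$chrom) {
    i <- which(got$chrom == ch); j <- which(want$per_chrom$chrom == ch)
    expect_equal(got$avg_gap_kb[i], want$per_chrom$avg_gap_kb[j])
    expect_equal(got$largest_gap_kb[i], want$per_chrom$largest_gap_kb[j])
    expect_equal(got$n_gaps_over[i], want$per_chrom$n_gaps_over[j])
    expect_equal(got$n_gaps[i], got$n_snps[i] - 1)
  }
  tot <- got[got$chrom == "total", ]
  expect_equal(tot$avg_gap_kb, want$total$avg_gap_kb)
  expect_equal(tot$n_gaps_over, want$total$n_gaps_over)
  expect_error(gap_statistics(rbind(d, d[1, ])),
               class = "snparray_invalid_config")
})

test_that("panel comparison reports shared and unique polymorphic SNPs", {
  ids <- paste0("m", 1:10)
  mk <- function(poly) tibble::tibble(
    snp_id = ids, class = ifelse(ids %in% poly, "polymorphic", "monomorphic"))
  cmp <- compare_panels(mk(ids[1:6]), mk(ids[4:9]))
  expect_equal(cmp$shared, 3)
  expect_equal(cmp$a_only, 3)
  expect_equal(cmp$b_only, 3)
  expect_equal(cmp$union, 9)
  expect_equal(cmp$shared_fraction, 1 / 3)

  ident <- compare_panels(mk(ids[1:5]), mk(ids[1:5]))
  expect_equal(ident$shared_fraction, 1)
  disj <- compare_panels(mk(ids[1:3]), mk(ids[7:9]))
  expect_equal(disj$shared, 0)
  expect_error(compare_panels(mk(ids), mk(ids)[1:5, ]),
               class = "snparray_consistency_error")
})

test_that("validation cross-tab reproduces group proportions and flags unlabeled SNPs", {
  # exonic stratum: 30 SNPs of which 23 polymorphic -> 0.77
  snps <- tibble::tibble(
    snp_id = paste0("v", 1:40),
    genic = c(rep("exonic", 30), rep("intergenic", 10)),
    outcome = c(rep("failed", 4), rep("monomorphic", 3),
                rep("polymorphic", 23), rep("failed", 4),
                rep("monomorphic", 3), rep("polymorphic", 3)),
    validation_maf = NA_real_
  )
  snps$validation_maf[snps$outcome == "polymorphic"] <- 0.3
  tab <- crosstab_validation(snps, by = "genic")
  ex <- tab[tab$level == "exonic", ]
  expect_equal(ex$total, 30)
  expect_equal(ex$prop_polymorphic, 0.77)
  expect_equal(ex$prop_failed, 0.13)

  # single SNP, single category: proportions in {0, 1}
  one <- crosstab_validation(snps[1, ], by = "genic")
  expect_true(all(unlist(one[1, c("prop_failed", "prop_monomorphic",
                                  "prop_polymorphic")]) %in% c(0, 1)))

  # random labeled set vs an independent group-by tally
  set.seed(8)
  rnd <- tibble::tibble(
    snp_id = paste0("r", 1:40),
    bin = sample(c("x", "y", "z"), 40, replace = TRUE),
    outcome = sample(c("failed", "monomorphic", "polymorphic"), 40,
                     replace = TRUE),
    validation_maf = NA_real_
  )
  rnd$validation_maf[rnd$outcome == "polymorphic"] <-
    runif(sum(rnd$outcome == "polymorphic"), 0.01, 0.5)
  tab <- crosstab_validation(rnd, by = "bin")
  for (lv in c("x", "y", "z")) {
    sub <- rnd[rnd$bin == lv, ]
    row <- tab[tab$parameter == "bin" & tab$level == lv, ]
    expect_equal(row$total, nrow(sub))
    expect_equal(row$frac_polymorphic, mean(sub$outcome == "polymorphic"))
    expect_equal(row$frac_maf_gt10,
                 sum(sub$outcome == "polymorphic" &
                       sub$validation_maf >= 0.10) / nrow(sub))
  }
  # MAF bins sum to the polymorphic fraction
  expect_equal(tab$frac_maf_lt5 + tab$frac_maf_5_10 + tab$frac_maf_gt10,
               tab$frac_polymorphic)

  rnd$bin[1] <- NA
  expect_error(crosstab_validation(rnd, by = "bin"),
               class = "snparray_labeling_error")
})

test_that("progeny informativeness summarises segregation flags", {
  # planted distribution: 1 SNP in 5 progenies, 10 in 4, 17 in 3, 10 in 2,
  # 14 in 1, 3 in none (55 polymorphic SNPs)
  counts <- c(rep(5, 1), rep(4, 10), rep(3, 17), rep(2, 10), rep(1, 14),
              rep(0, 3))
  set.seed(2)
  flags <- t(vapply(counts, function(k) {
    f <- rep(FALSE, 5); f[sample(5, k)] <- TRUE; f
  }, logical(5)))
  colnames(flags) <- paste0("prog", 1:5)
  res <- progeny_informativeness(flags)
  expect_equal(res$any_progeny_fraction, 52 / 55)
  expect_equal(res$any_progeny_pct, 95)
  expect_equal(sum(res$by_progeny_count$n_snps), 55)
  expect_equal(res$by_progeny_count$n_snps[res$by_progeny_count$n_progenies == 3],
               17)

  none <- progeny_informativeness(matrix(FALSE, 5, 3))
  expect_equal(none$any_progeny_fraction, 0)
  expect_true(all(none$per_progeny$fraction == 0))
  all_on <- progeny_informativeness(matrix(TRUE, 5, 3))
  expect_true(all(all_on$per_progeny$fraction == 1))
})

test_that("coverage accounting converts read counts to genome coverage", {
  rec <- tibble::tibble(read_count_million = c(5.85, 0),
                        read_length = c(94, 80))
  cov <- coverage_accounting(rec, genome_size = 227.4e6)
  expect_equal(cov$coverage[1], 5.85e6 * 94 / 227.4e6)
  expect_equal(round(cov$coverage[1], 2), 2.42)
  expect_equal(cov$coverage[2], 0)
  expect_error(coverage_accounting(rec, genome_size = 0),
               class = "snparray_invalid_config")

  # grouped aggregates honour the exclusion flag in means but not totals
  rec2 <- tibble::tibble(platform = c("a", "a", "b"),
                         coverage = c(2, 4, 1),
                         excluded = c(FALSE, TRUE, FALSE))
  s <- coverage_summary(rec2, by = "platform")
  expect_equal(s$total_coverage[s$platform == "a"], 6)
  expect_equal(s$mean_coverage[s$platform == "a"], 2)
})

test_that("MAF concordance is Pearson correlation over shared SNPs", {
  a <- setNames(c(0.1, 0.2, 0.3, 0.4, 0.25), paste0("m", 1:5))
  expect_equal(maf_concordance(a, a), 1.0)
  expect_warning(r <- maf_concordance(a, setNames(rep(0.2, 5), names(a))))
  expect_true(is.na(r))
  expect_error(maf_concordance(a[1:2], a[1:2]),
               class = "snparray_insufficient_data")

  # hand-written vectors vs the textbook formula
  set.seed(4)
  b <- setNames(runif(10, 0, 0.5), paste0("m", 1:10))
  c2 <- setNames(runif(10, 0, 0.5), paste0("m", 1:10))
  num <- sum((b - mean(b)) * (c2 - mean(c2)))
  den <- sqrt(sum((b - mean(b))^2) * sum((c2 - mean(c2))^2))
  expect_equal(maf_concordance(b, c2), num / den)
})
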