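# Independent brute-force oracles, written as plain loops so they share no
# code path with the vectorised implementations they check.

# Forward-strand census of every k-mer in a genome (list/char vector of
# sequences). Returns a named count table.
oracle_kmer_census <- function(seqs, k) {
  seqs <- as.character(seqs)
  words <- character(0)
  for (s in seqs) {
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    words <- c(words, substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  table(words)
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

# Occurrences of one k-mer in the genome, counting the reverse complement
# when canonical = TRUE.
oracle_kmer_count <- function(census, kmer, canonical = TRUE) {
  cnt <- function(w) {
    i <- match(w, names(census))
    if (is.na(i)) 0L else as.integer(census[[i]])
  }
  n <- cnt(kmer)
  if (canonical) n <- n + cnt(oracle_revcomp(kmer))
  n
}

# Rule-by-rule Stage-1 evaluator: one site at a time, explicit loops.
oracle_stage1 <- function(calls, params, repeats = NULL, copy_number = NULL) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    keep[i] <- if (params$q_strict) calls$qual[i] > params$q_min else
      calls$qual[i] >= params$q_min
  }
  calls <- calls[keep, , drop = FALSE]
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  sites <- unique(key)
  ref_sum <- alt_sum <- numeric(length(sites))
  for (j in seq_along(sites)) {
    rows <- which(key == sites[j])
    ref_sum[j] <- sum(calls$ref_depth[rows])
    alt_sum[j] <- sum(calls$alt_depth[rows])
  }
  totals <- ref_sum + alt_sum
  ok <- logical(length(sites))
  for (j in seq_along(sites)) {
    tot <- totals[j]
    pass <- tot >= params$cov_min
    rule <- params$cov_max_rule
    if (pass && rule$type == "multiple_of_mean") {
      pass <- tot <= rule$factor * mean(totals)
    }
    if (pass && rule$type == "mean_plus_sd") {
      s <- if (length(totals) > 1) sd(totals) else 0
      pass <- max(ref_sum[j], alt_sum[j]) < mean(totals) + rule$k * s
    }
    if (pass) pass <- min(ref_sum[j], alt_sum[j]) >= params$minor_allele_min_reads
    parts <- strsplit(sites[j], " ")[[1]]
    ch <- parts[1]; p <- as.integer(parts[2])
    if (pass && params$regime == "A" && !is.null(repeats)) {
      for (r in seq_len(nrow(repeats))) {
        if (repeats$chrom[r] == ch && p >= repeats$start[r] &&
            p <= repeats$end[r]) {
          pass <- FALSE
          break
        }
      }
    }
    if (pass && params$regime == "B" && !is.null(copy_number)) {
      cn <- copy_number[[sites[j]]]
      if (!is.null(cn)) pass <- !is.na(cn) && cn < params$copy_number_max
    }
    ok[j] <- pass
  }
  out <- do.call(rbind, lapply(sites[ok], function(s) {
    parts <- strsplit(s, " ")[[1]]
    data.frame(chrom = parts[1], pos = as.integer(parts[2]),
               ref = parts[3], alt = parts[4])
  }))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
  }
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}

# Brute-force gap statistics for one threshold.
oracle_gap_stats <- function(design, threshold_kb = 150) {
  chroms <- sort(unique(design$chrom))
  rows <- list()
  all_gaps <- numeric(0)
  for (ch in chroms) {
    p <- sort(design$pos[design$chrom == ch])
    gaps <- numeric(0)
    if (length(p) >= 2) {
      for (i in 2:length(p)) gaps <- c(gaps, (p[i] - p[i - 1]) / 1000)
    }
    all_gaps <- c(all_gaps, gaps)
    rows[[ch]] <- data.frame(
      chrom = ch, n_snps = length(p), n_gaps = length(gaps),
      avg_gap_kb = if (length(gaps)) mean(gaps) else NA_real_,
      largest_gap_kb = if (length(gaps)) max(gaps) else NA_real_,
      n_gaps_over = sum(gaps > threshold_kb)
    )
  }
  list(per_chrom = do.call(rbind, rows),
       total = data.frame(
         n_gaps = length(all_gaps),
         avg_gap_kb = if (length(all_gaps)) mean(all_gaps) else NA_real_,
         largest_gap_kb = if (length(all_gaps)) max(all_gaps) else NA_real_,
         n_gaps_over = sum(all_gaps > threshold_kb)))
}

# Exhaustive even-spacing search: minimal sum over ideal-grid points of the
# distance to the nearest selected candidate; returns the minimal cost and
# all cost-minimising subsets.
oracle_even_spacing <- function(pos, k) {
  grid <- seq(min(pos), max(pos), length.out = k)
  cost <- function(s) sum(vapply(grid, function(g) min(abs(s - g)),
                                 numeric(1)))
  combs <- utils::combn(sort(pos), k)
  costs <- apply(combs, 2, cost)
  list(min_cost = min(costs),
       best = lapply(which(costs == min(costs)),
                     function(j) sort(combs[, j])),
       cost = cost)
}

# Small hand-made genome for probe / copy-number tests.
make_test_genome <- function(seed = 5, lengths = c(chr1 = 6000, chr2 = 4000),
                             unanchored = character()) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  genome_assembly(Biostrings::DNAStringSet(seqs), unanchored = unanchored)
}

# Duplicate the block [start, start+len-1] of `chrom` onto dst_chrom at
# dst_start, returning the modified genome.
duplicate_block <- function(genome, chrom, start, len, dst_chrom, dst_start) {
  seqs <- as.character(genome$seq)
  block <- substr(seqs[[chrom]], start, start + len - 1L)
  substr(seqs[[dst_chrom]], dst_start, dst_start + len - 1L) <- block
  genome_assembly(
    Biostrings::DNAStringSet(seqs),
    unanchored = genome$chromosomes$chrom[genome$chromosomes$unanchored]
  )
}

# Construct a genotype_matrix with planted per-SNP outcomes.
make_genotype_matrix <- function(calls, gentrain, gencall10) {
  structure(
    list(
      calls = calls,
      snp_scores = tibble::tibble(snp_id = colnames(calls),
                                  gentrain = gentrain,
                                  gencall10 = gencall10),
      samples = tibble::tibble(sample_id = rownames(calls),
                               null_flagged = FALSE)
    ),
    class = "genotype_matrix"
  )
}
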