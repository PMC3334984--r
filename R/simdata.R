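#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' list. The defaults emulate the structure of a resequenced stone-fruit
#' breeding panel at toy genome scale: eight 1 Mb chromosomes, a detection
#' panel of 56 accessions split into 12 pools (the last pool on a long-read
#' low-yield platform), heterogeneous per-accession coverage between 0.2x
#' and 8x, and array reports carrying cluster-quality scores and no-calls.
#'
#' @param seed Integer seed; together with the other fields it fully
#'   determines every simulated object.
#' @param n_chrom,chrom_length Number and length (bp) of anchored
#'   chromosomes (pseudomolecules).
#' @param n_unanchored,unanchored_length Number and length (bp) of
#'   unanchored scaffolds appended after the chromosomes.
#' @param gene_density Genes per Mb.
#' @param repeat_fraction Fraction of each chromosome occupied by exactly
#'   duplicated repeat blocks, in `[0, 0.5]`.
#' @param repeat_block Length (bp) of one repeat block.
#' @param n_accessions,n_pools Detection-panel size and number of pools;
#'   the last pool is tagged `"454"`, the others `"illumina"`.
#' @param coverage_range,coverage_range_454 Per-accession expected coverage
#'   (x genome) drawn uniformly from these ranges for short-read and
#'   long-read pools respectively.
#' @param n_snps Number of true segregating sites to plant.
#' @param maf_range Range of the true population minor allele frequency,
#'   inside `(0, 0.5]`.
#' @param error_rate Per-read probability that a read reports the wrong
#'   allele at a site.
#' @param qual_mean,qual_sd,qual_max Caller quality-score model: normal
#'   with this mean/sd, truncated to `[0, qual_max]`. The default mean of
#'   32 places mass on both sides of the two detection thresholds (25, 30).
#' @param n_eval_samples Evaluation-panel size for simulated array reports.
#' @param failure_fraction Fraction of array SNPs forced to fail
#'   (low cluster scores or majority no-calls).
#' @param nocall_rate Baseline per-cell no-call probability.
#' @param null_sample_fraction,null_nocall_rate Fraction of samples that
#'   carry null-allele-like behaviour, and their elevated no-call rate.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_chrom = 2, chrom_length = 5e4, n_snps = 100)
sim_config <- function(seed = 1L,
                       n_chrom = 8L,
                       chrom_length = 1e6,
                       n_unanchored = 2L,
                       unanchored_length = 5e4,
                       gene_density = 100,
                       repeat_fraction = 0.05,
                       repeat_block = 500L,
                       n_accessions = 56L,
                       n_pools = 12L,
                       coverage_range = c(0.2, 8),
                       coverage_range_454 = c(0.15, 0.3),
                       n_snps = 4000L,
                       maf_range = c(0.05, 0.5),
                       error_rate = 0.005,
                       qual_mean = 32,
                       qual_sd = 6,
                       qual_max = 40,
                       n_eval_samples = 100L,
                       failure_fraction = 0.05,
                       nocall_rate = 0.01,
                       null_sample_fraction = 0.02,
                       null_nocall_rate = 0.5) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.numeric(chrom_length),
    n_unanchored = as.integer(n_unanchored),
    unanchored_length = as.numeric(unanchored_length),
    gene_density = gene_density, repeat_fraction = repeat_fraction,
    repeat_block = as.integer(repeat_block),
    n_accessions = as.integer(n_accessions), n_pools = as.integer(n_pools),
    coverage_range = coverage_range, coverage_range_454 = coverage_range_454,
    n_snps = as.integer(n_snps), maf_range = maf_range,
    error_rate = error_rate, qual_mean = qual_mean, qual_sd = qual_sd,
    qual_max = qual_max, n_eval_samples = as.integer(n_eval_samples),
    failure_fraction = failure_fraction, nocall_rate = nocall_rate,
    null_sample_fraction = null_sample_fraction,
    null_nocall_rate = null_nocall_rate
  )
  rates <- c(
    repeat_fraction = cfg$repeat_fraction, error_rate = cfg$error_rate,
    failure_fraction = cfg$failure_fraction, nocall_rate = cfg$nocall_rate,
    null_sample_fraction = cfg$null_sample_fraction,
    null_nocall_rate = cfg$null_nocall_rate
  )
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    abort(paste0("sim_config: rates outside [0, 1]: ",
                 paste(names(rates)[bad], collapse = ", ")),
          class = "snparray_invalid_config")
  }
  if (cfg$n_chrom < 1L || cfg$chrom_length <= 0 ||
      (cfg$n_unanchored > 0L && cfg$unanchored_length <= 0)) {
    abort("sim_config: chromosome counts and lengths must be positive",
          class = "snparray_invalid_config")
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5) {
    abort("sim_config: maf_range must lie in (0, 0.5]",
          class = "snparray_invalid_config")
  }
  if (any(cfg$coverage_range < 0) || any(cfg$coverage_range_454 < 0)) {
    abort("sim_config: coverage ranges must be non-negative",
          class = "snparray_invalid_config")
  }
  if (cfg$n_accessions < 1L) {
    abort("sim_config: need at least one accession",
          class = "snparray_invalid_config")
  }
  structure(cfg, class = "sim_config")
}

# Run `code` under `seed`, restoring the caller's RNG state afterwards so
# generator calls do not perturb user-level randomness.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a genome assembly
#'
#' A genome assembly couples a [Biostrings::DNAStringSet] with a sequence
#' table flagging which sequences are chromosome-scale pseudomolecules and
#' which are unanchored scaffolds.
#'
#' @param seq Named [Biostrings::DNAStringSet].
#' @param unanchored Character vector of sequence names that are unanchored
#'   scaffolds.
#' @return An object of class `genome_assembly`: a list with elements
#'   `seq` (the `DNAStringSet`) and `chromosomes` (a tibble with columns
#'   `chrom`, `length`, `unanchored`).
#' @export
genome_assembly <- function(seq, unanchored = character()) {
  if (is.null(names(seq)) || anyDuplicated(names(seq)) ||
      any(names(seq) == "")) {
    abort("genome_assembly: sequences must carry unique non-empty names",
          class = "snparray_invalid_config")
  }
  if (any(Biostrings::width(seq) == 0)) {
    abort("genome_assembly: zero-length sequence",
          class = "snparray_invalid_config")
  }
  if (!all(unanchored %in% names(seq))) {
    abort("genome_assembly: unknown sequence in `unanchored`",
          class = "snparray_invalid_config")
  }
  structure(
    list(
      seq = seq,
      chromosomes = tibble::tibble(
        chrom = names(seq),
        length = Biostrings::width(seq),
        unanchored = names(seq) %in% unanchored
      )
    ),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  n_ps <- sum(!x$chromosomes$unanchored)
  cat("<genome_assembly> ", n_ps, " pseudomolecule(s), ",
      sum(x$chromosomes$unanchored), " unanchored scaffold(s), ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp total\n",
      sep = "")
  invisible(x)
}

genome_seq_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i)) {
    abort(paste0("unknown chromosome: ",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")),
          class = "snparray_reference_mismatch")
  }
  genome$chromosomes$length[i]
}

#' Simulate a genome, gene annotation and repeat track
#'
#' Generates random chromosome sequences, plants exactly duplicated repeat
#' blocks (so that k-mer copy-number estimation finds them), and lays out a
#' non-overlapping gene annotation with exons, introns and flanking UTR
#' intervals (UTRs extend up to 2 kb beyond the coding span). Every genomic
#' position classifies into exactly one of exonic / intronic / UTR /
#' intergenic via [classify_positions()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` ([genome_assembly]), `annotation`
#'   (tibble of `gene`/`exon`/`UTR` intervals with columns `chrom`, `start`,
#'   `end`, `type`, `gene_id`, `strand`; 1-based inclusive), and `repeats`
#'   (tibble `chrom`, `start`, `end`).
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(seed = 7, n_chrom = 2,
#'                                   chrom_length = 2e4, n_snps = 50))
#' sim$genome
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    lens <- c(rep(config$chrom_length, config$n_chrom),
              rep(config$unanchored_length, config$n_unanchored))
    nms <- c(paste0("chr", seq_len(config$n_chrom)),
             if (config$n_unanchored > 0)
               paste0("scaffold_", seq_len(config$n_unanchored)))
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))

    repeats <- list()
    if (config$repeat_fraction > 0) {
      for (i in seq_along(seqs)) {
        L <- lens[i]
        blk <- min(config$repeat_block, floor(L / 4))
        n_blocks <- floor(config$repeat_fraction * L / blk / 2)
        if (blk < 10 || n_blocks < 1) next
        s <- seqs[[i]]
        for (b in seq_len(n_blocks)) {
          src <- sample.int(floor(L / 2) - blk, 1L)
          dst <- floor(L / 2) + sample.int(floor(L / 2) - blk, 1L)
          substr(s, dst, dst + blk - 1L) <- substr(s, src, src + blk - 1L)
          repeats[[length(repeats) + 1L]] <- tibble::tibble(
            chrom = nms[i],
            start = c(src, dst), end = c(src + blk - 1L, dst + blk - 1L)
          )
        }
        seqs[[i]] <- s
      }
    }
    repeats <- if (length(repeats)) {
      dplyr::arrange(dplyr::bind_rows(repeats), .data$chrom, .data$start)
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer())
    }

    ann <- list()
    gene_no <- 0L
    for (i in seq_along(seqs)) {
      L <- lens[i]
      n_genes <- floor(config$gene_density * L / 1e6)
      if (n_genes < 1L) next
      slice <- floor(L / n_genes)
      gene_len <- min(2000L, max(300L, floor(slice / 3)))
      utr_len <- min(500L, floor(gene_len / 2))
      for (g in seq_len(n_genes)) {
        lo <- (g - 1L) * slice + 1L
        room <- slice - gene_len - 2L * utr_len
        if (room < 2L) next
        start <- lo + utr_len + sample.int(room, 1L)
        end <- start + gene_len - 1L
        gene_no <- gene_no + 1L
        id <- sprintf("gene%05d", gene_no)
        n_ex <- sample(2:4, 1L)
        bounds <- round(seq(start, end + 1L, length.out = 2L * n_ex))
        ex_start <- bounds[seq(1L, 2L * n_ex - 1L, by = 2L)]
        ex_end <- pmax(ex_start, bounds[seq(2L, 2L * n_ex, by = 2L)] - 1L)
        strand <- sample(c("+", "-"), 1L)
        f_start <- c(start, ex_start, start - utr_len, end + 1L)
        f_end <- c(end, ex_end, start - 1L, end + utr_len)
        ann[[length(ann) + 1L]] <- tibble::tibble(
          chrom = nms[i],
          start = f_start,
          end = f_end,
          type = c("gene", rep("exon", n_ex), "UTR", "UTR"),
          gene_id = id, strand = strand
        )
      }
    }
    annotation <- if (length(ann)) {
      dplyr::arrange(dplyr::bind_rows(ann), .data$chrom, .data$start,
                     dplyr::desc(.data$type == "gene"))
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer(),
                     type = character(), gene_id = character(),
                     strand = character())
    }

    genome <- genome_assembly(
      Biostrings::DNAStringSet(setNames(seqs, nms)),
      unanchored = nms[grepl("^scaffold_", nms)]
    )
    list(genome = genome, annotation = annotation, repeats = repeats)
  })
}

#' Classify genomic positions by genic context
#'
#' Assigns each position exactly one class with precedence
#' exon > intron (inside a gene span but not in an exon) > UTR >
#' intergenic.
#'
#' @param annotation Annotation tibble as produced by [simulate_genome()]
#'   or [read_gff3()].
#' @param positions Tibble with columns `chrom` and `pos`.
#' @return The `positions` tibble with an added factor column `genic_class`
#'   with levels `exonic`, `intronic`, `UTR`, `intergenic`.
#' @export
classify_positions <- function(annotation, positions) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  in_type <- function(type) {
    iv <- annotation[annotation$type == type, , drop = FALSE]
    if (nrow(iv) == 0) return(rep(FALSE, nrow(positions)))
    hit <- dplyr::inner_join(
      dplyr::mutate(positions[, c("chrom", "pos")], .row = dplyr::row_number()),
      iv[, c("chrom", "start", "end")],
      by = "chrom", relationship = "many-to-many"
    )
    hit <- hit[hit$pos >= hit$start & hit$pos <= hit$end, ]
    seq_len(nrow(positions)) %in% hit$.row
  }
  ex <- in_type("exon")
  gn <- in_type("gene")
  ut <- in_type("UTR")
  cls <- dplyr::case_when(
    ex ~ "exonic",
    gn ~ "intronic",
    ut ~ "UTR",
    TRUE ~ "intergenic"
  )
  positions$genic_class <- factor(cls, levels = c("exonic", "intronic",
                                                  "UTR", "intergenic"))
  positions
}

#' Simulate a detection panel of accessions and true SNPs
#'
#' Plants `n_snps` biallelic sites at distinct positions, draws a true
#' population minor allele frequency for each from
#' `Uniform(config$maf_range)`, and samples diploid genotypes per accession
#' under Hardy-Weinberg proportions (alt dosage `~ Binomial(2, MAF)`, the
#' alternate allele being the minor one). Accessions are split into pools;
#' the last pool carries the `"454"` platform tag and its own coverage
#' range.
#'
#' @param genome A [genome_assembly].
#' @param annotation Annotation tibble (used to record each SNP's genic
#'   class).
#' @param config A [sim_config()].
#' @return A list of class `true_panel`: `accessions` (tibble `accession`,
#'   `pool`, `platform`, `coverage`), `snps` (tibble `snp_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `maf`, `genic_class`, `on_pseudomolecule`), and
#'   `genotypes` (integer matrix, accessions x SNPs, alt-allele dosage
#'   0/1/2).
#' @export
simulate_panel <- function(genome, annotation, config) {
  stopifnot(inherits(genome, "genome_assembly"), inherits(config, "sim_config"))
  total_len <- sum(genome$chromosomes$length)
  if (config$n_snps > total_len) {
    abort("simulate_panel: more SNPs requested than genome positions",
          class = "snparray_invalid_config")
  }
  with_seed(config$seed + 1L, {
    pool <- rep(seq_len(config$n_pools), length.out = config$n_accessions)
    pool <- sort(pool)
    platform <- ifelse(pool == config$n_pools & config$n_pools > 1L,
                       "454", "illumina")
    cov <- ifelse(
      platform == "454",
      runif(config$n_accessions, config$coverage_range_454[1],
            config$coverage_range_454[2]),
      runif(config$n_accessions, config$coverage_range[1],
            config$coverage_range[2])
    )
    accessions <- tibble::tibble(
      accession = sprintf("acc%03d", seq_len(config$n_accessions)),
      pool = pool, platform = platform, coverage = cov
    )

    if (config$n_snps == 0L) {
      snps <- tibble::tibble(
        snp_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), maf = numeric(),
        genic_class = factor(character(), levels = c("exonic", "intronic",
                                                     "UTR", "intergenic")),
        on_pseudomolecule = logical()
      )
      geno <- matrix(integer(), nrow = config$n_accessions, ncol = 0,
                     dimnames = list(accessions$accession, NULL))
      return(structure(list(accessions = accessions, snps = snps,
                            genotypes = geno), class = "true_panel"))
    }

    # sample genome-wide offsets, convert to (chrom, pos)
    offs <- sort(sample(total_len, config$n_snps))
    cum <- cumsum(genome$chromosomes$length)
    idx <- findInterval(offs - 1, c(0, cum), rightmost.closed = FALSE)
    pos <- as.integer(offs - c(0, cum)[idx])
    chrom <- genome$chromosomes$chrom[idx]
    ref <- vapply(seq_along(pos), function(i) {
      as.character(Biostrings::subseq(genome$seq[[chrom[i]]], pos[i], pos[i]))
    }, character(1))
    keep <- ref %in% c("A", "C", "G", "T")
    chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]
    n <- length(pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    maf <- runif(n, config$maf_range[1], config$maf_range[2])
    snps <- tibble::tibble(
      snp_id = sprintf("%s_%d", chrom, pos),
      chrom = chrom, pos = pos, ref = ref, alt = alt, maf = maf,
      on_pseudomolecule = !chrom %in%
        genome$chromosomes$chrom[genome$chromosomes$unanchored]
    )
    snps <- classify_positions(annotation, snps)
    geno <- matrix(
      rbinom(config$n_accessions * n, 2L, rep(maf, each = config$n_accessions)),
      nrow = config$n_accessions, ncol = n,
      dimnames = list(accessions$accession, snps$snp_id)
    )
    structure(list(accessions = accessions, snps = snps, genotypes = geno),
              class = "true_panel")
  })
}

#' @export
print.true_panel <- function(x, ...) {
  cat("<true_panel> ", nrow(x$accessions), " accession(s) in ",
      length(unique(x$accessions$pool)), " pool(s), ",
      nrow(x$snps), " true SNP(s)\n", sep = "")
  invisible(x)
}

#' Simulate per-accession raw call tables
#'
#' Emits site-level sequencing evidence at every true SNP for every
#' accession: read depth `~ Poisson(coverage)`, allele split binomial given
#' the true diploid genotype with a per-read error rate, and a caller
#' quality score from a truncated normal model. Sites with zero depth in an
#' accession produce no record, which is what creates the low-coverage
#' missingness the concordance analysis studies.
#'
#' @param panel A [simulate_panel()] result.
#' @param config A [sim_config()].
#' @return A tibble with columns `accession`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_depth`, `alt_depth`, `qual`, sorted by accession then position.
#' @export
simulate_callsets <- function(panel, config) {
  stopifnot(inherits(panel, "true_panel"), inherits(config, "sim_config"))
  if (any(panel$accessions$coverage < 0)) {
    abort("simulate_callsets: negative coverage",
          class = "snparray_invalid_config")
  }
  n_snp <- nrow(panel$snps)
  n_acc <- nrow(panel$accessions)
  if (n_snp == 0L || n_acc == 0L) {
    return(tibble::tibble(accession = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), ref_depth = integer(),
                          alt_depth = integer(), qual = numeric()))
  }
  with_seed(config$seed + 2L, {
    acc_i <- rep(seq_len(n_acc), times = n_snp)
    snp_i <- rep(seq_len(n_snp), each = n_acc)
    depth <- rpois(length(acc_i), panel$accessions$coverage[acc_i])
    keep <- depth > 0L
    acc_i <- acc_i[keep]; snp_i <- snp_i[keep]; depth <- depth[keep]
    dosage <- panel$genotypes[cbind(acc_i, snp_i)]
    f <- dosage / 2
    p_alt <- f * (1 - config$error_rate) + (1 - f) * config$error_rate
    alt_depth <- rbinom(length(depth), depth, p_alt)
    qual <- pmin(config$qual_max,
                 pmax(0, rnorm(length(depth), config$qual_mean, config$qual_sd)))
    tibble::tibble(
      accession = panel$accessions$accession[acc_i],
      chrom = panel$snps$chrom[snp_i],
      pos = panel$snps$pos[snp_i],
      ref = panel$snps$ref[snp_i],
      alt = panel$snps$alt[snp_i],
      ref_depth = as.integer(depth - alt_depth),
      alt_depth = as.integer(alt_depth),
      qual = round(qual, 2)
    ) |>
      dplyr::arrange(.data$accession, .data$chrom, .data$pos)
  })
}

#' Simulate an array genotype report
#'
#' Emulates a genotype-calling report for an evaluation panel scanned with
#' a designed array: per-SNP cluster-quality scores (GenTrain and GenCall
#' 10th percentile), per-cell calls in `{AA, AB, BB, NC}`, a configurable
#' fraction of forced-failure SNPs (low scores or majority no-calls), and
#' null-allele-like samples with elevated no-call rates.
#'
#' @param design An [select_even_spacing()] design (or any tibble with
#'   `snp_id` column); its SNPs must exist in `panel$snps` unless flagged
#'   in `decoys`.
#' @param panel A [simulate_panel()] result supplying true MAFs.
#' @param config A [sim_config()].
#' @param decoys Optional character vector of `snp_id`s in `design` that
#'   are monomorphic decoys (absent from the panel truth).
#' @return An object of class `genotype_matrix`: list with `calls`
#'   (character matrix samples x SNPs), `snp_scores` (tibble `snp_id`,
#'   `gentrain`, `gencall10`), `samples` (tibble `sample_id`,
#'   `null_flagged`).
#' @export
simulate_genotype_report <- function(design, panel, config,
                                     decoys = character()) {
  stopifnot(inherits(panel, "true_panel"), inherits(config, "sim_config"))
  ids <- design$snp_id
  known <- ids %in% panel$snps$snp_id
  if (!all(known | ids %in% decoys)) {
    abort(paste0("simulate_genotype_report: design SNPs absent from panel ",
                 "and not flagged as decoys: ",
                 paste(head(ids[!known & !ids %in% decoys], 3), collapse = ", ")),
          class = "snparray_consistency_error")
  }
  with_seed(config$seed + 3L, {
    n_s <- config$n_eval_samples
    n_m <- length(ids)
    maf <- ifelse(known, panel$snps$maf[match(ids, panel$snps$snp_id)], 0)
    dosage <- matrix(
      rbinom(n_s * n_m, 2L, rep(maf, each = n_s)),
      nrow = n_s, ncol = n_m
    )
    calls <- matrix(c("AA", "AB", "BB")[dosage + 1L], nrow = n_s, ncol = n_m)

    null_flagged <- runif(n_s) < config$null_sample_fraction
    nc_rate <- ifelse(null_flagged, config$null_nocall_rate, config$nocall_rate)
    nc <- matrix(runif(n_s * n_m) < nc_rate, nrow = n_s, ncol = n_m)

    failed <- runif(n_m) < config$failure_fraction
    gentrain <- ifelse(failed, runif(n_m, 0, 0.35), runif(n_m, 0.55, 0.95))
    gencall10 <- ifelse(failed, runif(n_m, 0, 0.15), runif(n_m, 0.35, 0.9))
    # a third of forced failures fail by majority no-call instead of score
    nc_fail <- failed & (runif(n_m) < 1 / 3)
    gentrain[nc_fail] <- runif(sum(nc_fail), 0.55, 0.95)
    gencall10[nc_fail] <- runif(sum(nc_fail), 0.35, 0.9)
    if (any(nc_fail)) {
      nc[, nc_fail] <- matrix(runif(n_s * sum(nc_fail)) < 0.75,
                              nrow = n_s)
    }
    calls[nc] <- "NC"

    samples <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n_s)),
      null_flagged = null_flagged
    )
    dimnames(calls) <- list(samples$sample_id, ids)
    structure(
      list(
        calls = calls,
        snp_scores = tibble::tibble(snp_id = ids,
                                    gentrain = round(gentrain, 4),
                                    gencall10 = round(gencall10, 4)),
        samples = samples
      ),
      class = "genotype_matrix"
    )
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " sample(s) x ", ncol(x$calls),
      " SNP(s)\n", sep = "")
  invisible(x)
}
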