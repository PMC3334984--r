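#' Classify a SNP's Infinium assay type
#'
#' Type I SNPs are the A/T and C/G transversions, which need two bead
#' types on the array; every other allele pair is type II (one bead
#' type). The classification is symmetric in allele order.
#'
#' @param ref,alt Vectors of single-base alleles.
#' @return Character vector of `"I"` / `"II"`.
#' @export
#' @examples
#' classify_infinium(c("A", "C", "A"), c("T", "G", "G"))
classify_infinium <- function(ref, alt) {
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok) || any(ref == alt)) {
    abort("classify_infinium: alleles must be two distinct bases in ACGT",
          class = "snparray_invalid_allele")
  }
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  ifelse(pair %in% c("A T", "C G"), "I", "II")
}

#' Extract 50 bp probe context around SNPs
#'
#' Returns the upstream (`[pos - 50, pos - 1]`) and downstream
#' (`[pos + 1, pos + 50]`) flanking sequences used as Infinium probe
#' bodies; flanks truncated by a chromosome end are flagged.
#'
#' @param genome A [genome_assembly].
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @param width Flank width in bp (50 for Infinium probes).
#' @return Tibble `chrom`, `pos`, `upstream`, `downstream`, `truncated`.
#' @export
extract_probe_context <- function(genome, chrom, pos, width = 50L) {
  stopifnot(inherits(genome, "genome_assembly"))
  chrom <- rep(chrom, length.out = length(pos))
  lens <- genome_seq_length(genome, chrom)
  if (any(pos < 1 | pos > lens)) {
    abort("extract_probe_context: position outside chromosome",
          class = "snparray_coordinate_error")
  }
  up_start <- pmax(1, pos - width)
  dn_end <- pmin(lens, pos + width)
  up <- dn <- character(length(pos))
  for (i in seq_along(pos)) {
    up[i] <- if (pos[i] > 1) {
      genome_subseq(genome, chrom[i], up_start[i], pos[i] - 1L)
    } else ""
    dn[i] <- if (pos[i] < lens[i]) {
      genome_subseq(genome, chrom[i], pos[i] + 1L, dn_end[i])
    } else ""
  }
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), upstream = up, downstream = dn,
    truncated = nchar(up) < width | nchar(dn) < width
  )
}

#' Flag probe-tail duplication
#'
#' The assay extends from the probe base adjacent to the SNP, so a probe
#' whose terminal 25-mer (the 25 bases immediately next to the SNP)
#' occurs more than once in the genome risks off-target extension.
#' For each SNP the tails of both possible probe sides are checked; the
#' SNP is flagged if either tail's 25-mer has more than one genomic
#' occurrence. Reverse-complement occurrences count by default
#' (canonical k-mers); `canonical = FALSE` restricts to forward-strand
#' occurrences. Probes truncated below `tail_k` are flagged
#' (undetermined, conservatively treated as duplicated).
#'
#' @param genome A [genome_assembly].
#' @param probes Tibble from [extract_probe_context()] (columns
#'   `upstream`, `downstream`).
#' @param tail_k Tail length in bp.
#' @param canonical Count reverse-complement hits too.
#' @return Logical vector, `TRUE` where the tail is duplicated or
#'   undetermined.
#' @export
probe_tail_duplicated <- function(genome, probes, tail_k = 25L,
                                  canonical = TRUE) {
  stopifnot(inherits(genome, "genome_assembly"),
            all(c("upstream", "downstream") %in% names(probes)))
  n <- nrow(probes)
  if (n == 0) return(logical())
  short <- nchar(probes$upstream) < tail_k | nchar(probes$downstream) < tail_k
  up_tail <- ifelse(short, NA_character_,
                    substr(probes$upstream,
                           nchar(probes$upstream) - tail_k + 1L,
                           nchar(probes$upstream)))
  dn_tail <- ifelse(short, NA_character_, substr(probes$downstream, 1L, tail_k))
  tails <- c(up_tail[!short], dn_tail[!short])
  out <- rep(TRUE, n)  # truncated probes: undetermined -> excluded
  if (any(!short)) {
    cnt <- count_genome_kmers(genome, tails, canonical = canonical)
    m <- sum(!short)
    dup <- (is.na(cnt[seq_len(m)]) | cnt[seq_len(m)] > 1L) |
      (is.na(cnt[m + seq_len(m)]) | cnt[m + seq_len(m)] > 1L)
    out[!short] <- dup
  }
  out
}

#' Filter candidates on assay design score
#'
#' Retains candidates whose design score meets the threshold and which
#' carry no designability failure code. The default threshold 0.9 is the
#' stringent de-novo screen; pre-validated markers use 0.6.
#'
#' @param candidates Candidate tibble with a `design_score` column and
#'   optionally `failure_code` (NA/empty = none).
#' @param threshold Minimum retained score in `[0, 1]` (strictly lower
#'   scores are removed).
#' @return The retained rows.
#' @export
apply_score_filter <- function(candidates, threshold = 0.9) {
  if (!"design_score" %in% names(candidates)) {
    abort("apply_score_filter: candidates need a design_score column",
          class = "snparray_invalid_config")
  }
  sc <- candidates$design_score
  if (any(!is.na(sc) & (sc < 0 | sc > 1))) {
    abort("apply_score_filter: design scores must lie in [0, 1]",
          class = "snparray_invalid_score")
  }
  keep <- !is.na(sc) & sc >= threshold
  if ("failure_code" %in% names(candidates)) {
    fc <- candidates$failure_code
    keep <- keep & (is.na(fc) | fc == "")
  }
  candidates[keep, , drop = FALSE]
}

#' Merge candidate SNP sets and remove duplicates
#'
#' Candidates identical in (chromosome, position, unordered allele pair)
#' collapse to a single record: accession support is summed across
#' sources (union of independent evidence), the maximum detection MAF and
#' the first non-missing value of other fields are kept, and the source
#' tags are concatenated. Records at the same position with conflicting
#' allele pairs are dropped entirely and reported in the
#' `"conflicts"` attribute.
#'
#' @param ... Candidate tibbles (or one list of them), all on the same
#'   genome, with columns `chrom`, `pos`, `ref`, `alt` and optionally
#'   `n_support`, `maf`, `source`.
#' @return Merged candidate tibble sorted by `(chrom, pos)`; positions
#'   with allele conflicts are recorded in `attr(, "conflicts")`.
#' @export
merge_dedup <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !is.data.frame(sets[[1]])) {
    sets <- sets[[1]]
  }
  all <- dplyr::bind_rows(sets)
  if (nrow(all) == 0) {
    attr(all, "conflicts") <- all
    return(all)
  }
  if (!"n_support" %in% names(all)) all$n_support <- 1L
  if (!"source" %in% names(all)) all$source <- NA_character_
  all <- all |>
    dplyr::mutate(a1 = pmin(.data$ref, .data$alt),
                  a2 = pmax(.data$ref, .data$alt)) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$a1, .data$a2, .data$ref)
  # collapse duplicate (chrom, pos, allele-pair) keys; the slow grouped
  # summarise only ever touches the (typically few) truly duplicated keys
  key <- paste(all$chrom, all$pos, all$a1, all$a2, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  singles <- all[!key %in% dup_keys, , drop = FALSE]
  if (length(dup_keys)) {
    collapsed <- all[key %in% dup_keys, , drop = FALSE] |>
      dplyr::group_by(.data$chrom, .data$pos, .data$a1, .data$a2) |>
      dplyr::summarise(
        dplyr::across(dplyr::any_of(c("ref", "alt")), dplyr::first),
        n_support = sum(.data$n_support, na.rm = TRUE),
        dplyr::across(dplyr::any_of("maf"),
                      ~if (all(is.na(.x))) NA_real_ else
                        max(.x, na.rm = TRUE)),
        source = paste(sort(unique(stats::na.omit(.data$source))),
                       collapse = "+"),
        dplyr::across(
          dplyr::any_of(c("genic_class", "design_score", "failure_code",
                          "on_pseudomolecule", "snp_id")),
          ~dplyr::first(stats::na.omit(.x))[1]
        ),
        .groups = "drop"
      )
    merged <- dplyr::bind_rows(singles, collapsed)
  } else {
    merged <- singles
  }
  pos_key <- paste(merged$chrom, merged$pos, sep = "\r")
  conflicted <- pos_key %in% unique(pos_key[duplicated(pos_key)])
  conflicts <- merged[conflicted, , drop = FALSE]
  out <- merged[!conflicted, , drop = FALSE] |>
    dplyr::select(-"a1", -"a2") |>
    dplyr::arrange(.data$chrom, .data$pos)
  attr(out, "conflicts") <- dplyr::select(conflicts, -"a1", -"a2")
  out
}
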