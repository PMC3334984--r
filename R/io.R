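# Readers and writers for the standard flat formats the pipeline touches.
# Internal coordinate convention: 1-based inclusive everywhere (the
# VCF/GFF3 convention); BED is converted at the boundary. All writers are
# atomic: output goes to a temp file in the target directory which is
# renamed into place.

atomic_write <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read / write a genome assembly as FASTA
#'
#' Sequence names carrying the suffix `" unanchored"` in their FASTA
#' description (or listed in `unanchored`) are flagged as unanchored
#' scaffolds.
#'
#' @param path FASTA file path.
#' @param unanchored Character vector of unanchored sequence names
#'   (defaults to names starting `"scaffold"`).
#' @return A [genome_assembly].
#' @export
read_genome_fasta <- function(path, unanchored = NULL) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  if (is.null(unanchored)) {
    unanchored <- names(seq)[grepl("^scaffold", names(seq))]
  }
  genome_assembly(seq, unanchored = unanchored)
}

#' @rdname read_genome_fasta
#' @param genome A [genome_assembly].
#' @export
write_genome_fasta <- function(genome, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  Biostrings::writeXStringSet(genome$seq, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read / write gene annotation as GFF3
#'
#' The annotation dialect uses `gene`, `exon` and `UTR` feature rows with
#' a `Parent`/`ID` attribute carrying the gene id. Malformed lines (not
#' nine tab-separated fields, or non-numeric coordinates) raise a parse
#' error naming the line.
#'
#' @param path GFF3 file path.
#' @return Annotation tibble (`chrom`, `start`, `end`, `type`, `gene_id`,
#'   `strand`).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    bad <- idx[which(nf != 9)[1]]
    abort(paste0("read_gff3: malformed record at line ", bad,
                 " (expected 9 tab-separated fields, got ",
                 nf[which(nf != 9)[1]], ")"),
          class = "snparray_parse_error")
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    abort(paste0("read_gff3: non-numeric coordinate at line ", bad),
          class = "snparray_parse_error")
  }
  gene_id <- sub(".*(?:ID|Parent)=([^;]+).*", "\\1", m[, 9])
  tibble::tibble(
    chrom = m[, 1], start = start, end = end, type = m[, 3],
    gene_id = gene_id, strand = m[, 7]
  )
}

#' @rdname read_gff3
#' @param annotation Annotation tibble.
#' @export
write_gff3 <- function(annotation, path) {
  attr9 <- ifelse(annotation$type == "gene",
                  paste0("ID=", annotation$gene_id),
                  paste0("Parent=", annotation$gene_id))
  lines <- c("##gff-version 3",
             paste(annotation$chrom, "snparray", annotation$type,
                   annotation$start, annotation$end, ".",
                   annotation$strand, ".", attr9, sep = "\t"))
  atomic_write(lines, path)
}

#' Read / write interval tracks as BED
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package-internal 1-based inclusive convention on read and back on
#' write.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    bad <- idx[which(lengths(fields) < 3)[1]]
    abort(paste0("read_bed: malformed record at line ", bad),
          class = "snparray_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- idx[which(is.na(start0) | is.na(end0))[1]]
    abort(paste0("read_bed: non-numeric coordinate at line ", bad),
          class = "snparray_parse_error")
  }
  tibble::tibble(chrom = m[, 1], start = start0 + 1L, end = end0)
}

#' @rdname read_bed
#' @param intervals Tibble `chrom`, `start`, `end` (1-based inclusive).
#' @export
write_bed <- function(intervals, path) {
  atomic_write(
    paste(intervals$chrom, intervals$start - 1L, intervals$end, sep = "\t"),
    path
  )
}

#' Read / write per-accession call tables as TSV
#'
#' Eight columns: accession, chrom, pos, ref, alt, ref_depth, alt_depth,
#' qual.
#'
#' @param path TSV path.
#' @return Call-record tibble.
#' @export
read_call_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          accession = readr::col_character(),
                          chrom = readr::col_character(),
                          pos = readr::col_integer(),
                          ref = readr::col_character(),
                          alt = readr::col_character(),
                          ref_depth = readr::col_integer(),
                          alt_depth = readr::col_integer(),
                          qual = readr::col_double()))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("read_call_table: parse error at line ", prob$row[1] + 1L),
          class = "snparray_parse_error")
  }
  df
}

#' @rdname read_call_table
#' @param calls Call-record tibble.
#' @export
write_call_table <- function(calls, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_tsv(calls, tmp, progress = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read / write candidate SNP sets as VCF
#'
#' Minimal VCFv4.2 with INFO fields `NS` (supporting accessions), `MAF`
#' (detection minor allele frequency) and `SRC` (source tag).
#'
#' @param path VCF path.
#' @return Candidate tibble (`chrom`, `pos`, `ref`, `alt`, `n_support`,
#'   `maf`, `source`).
#' @export
read_candidate_vcf <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(body) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          n_support = integer(), maf = numeric(),
                          source = character()))
  }
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  if (any(lengths(fields) < 8)) {
    bad <- body[which(lengths(fields) < 8)[1]]
    abort(paste0("read_candidate_vcf: malformed record at line ", bad),
          class = "snparray_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:8))
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) {
    bad <- body[which(is.na(pos))[1]]
    abort(paste0("read_candidate_vcf: non-numeric POS at line ", bad),
          class = "snparray_parse_error")
  }
  info_get <- function(info, key) {
    val <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    val
  }
  tibble::tibble(
    chrom = m[, 1], pos = pos, ref = m[, 4], alt = m[, 5],
    n_support = as.integer(info_get(m[, 8], "NS")),
    maf = as.numeric(info_get(m[, 8], "MAF")),
    source = info_get(m[, 8], "SRC")
  )
}

#' @rdname read_candidate_vcf
#' @param candidates Candidate tibble.
#' @export
write_candidate_vcf <- function(candidates, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Supporting accessions\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Detection minor allele frequency\">",
    "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Detection source\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(candidates) > 0) {
    paste(candidates$chrom, candidates$pos, ".", candidates$ref,
          candidates$alt, ".", "PASS",
          paste0("NS=", candidates$n_support,
                 ";MAF=", formatC(candidates$maf, digits = 6, format = "g"),
                 ";SRC=", candidates$source),
          sep = "\t")
  } else {
    character()
  }
  atomic_write(c(header, body), path)
}

#' Read / write genotype reports (GenomeStudio-like TSV)
#'
#' Long format: sample, snp_id, call, gentrain, gencall10 (scores repeated
#' per SNP).
#'
#' @param path TSV path.
#' @return A `genotype_matrix`.
#' @export
read_genotype_report <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          sample = readr::col_character(),
                          snp_id = readr::col_character(),
                          call = readr::col_character(),
                          gentrain = readr::col_double(),
                          gencall10 = readr::col_double()))
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("read_genotype_report: parse error at line ",
                 prob$row[1] + 1L),
          class = "snparray_parse_error")
  }
  samples <- unique(df$sample)
  snps <- unique(df$snp_id)
  calls <- matrix("NC", nrow = length(samples), ncol = length(snps),
                  dimnames = list(samples, snps))
  calls[cbind(match(df$sample, samples), match(df$snp_id, snps))] <- df$call
  scores <- dplyr::distinct(df, .data$snp_id, .data$gentrain,
                            .data$gencall10)
  structure(
    list(calls = calls, snp_scores = scores,
         samples = tibble::tibble(sample_id = samples,
                                  null_flagged = NA)),
    class = "genotype_matrix"
  )
}

#' @rdname read_genotype_report
#' @param gm A `genotype_matrix`.
#' @export
write_genotype_report <- function(gm, path) {
  long <- tibble::tibble(
    sample = rep(rownames(gm$calls), times = ncol(gm$calls)),
    snp_id = rep(colnames(gm$calls) %||% character(), each = nrow(gm$calls)),
    call = as.vector(gm$calls)
  ) |>
    dplyr::left_join(gm$snp_scores, by = "snp_id")
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_tsv(long, tmp, progress = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read / write an array manifest as CSV
#'
#' @param path CSV path.
#' @return Design tibble.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("read_manifest: parse error at line ", prob$row[1] + 1L),
          class = "snparray_parse_error")
  }
  df
}

#' @rdname read_manifest
#' @param design Design tibble.
#' @export
write_manifest <- function(design, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_csv(as.data.frame(design), tmp, progress = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a flat key-value pipeline configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values parse as numbers where possible.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- stringr::str_match(lines, "^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$")
  if (anyNA(kv[, 1])) {
    abort(paste0("read_pipeline_config: malformed line: ",
                 lines[which(is.na(kv[, 1]))[1]]),
          class = "snparray_parse_error")
  }
  vals <- as.list(kv[, 3])
  num <- suppressWarnings(as.numeric(kv[, 3]))
  vals[!is.na(num)] <- num[!is.na(num)]
  setNames(vals, kv[, 2])
}
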