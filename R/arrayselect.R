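#' Build a selection plan for a fixed-size array
#'
#' @param total_slots Total bead slots on the array.
#' @param pinned Tibble of pre-validated SNPs automatically included
#'   (may be empty). Must carry `chrom`, `pos`.
#' @param n_candidates Optional count of available design-stage candidates;
#'   when given, the selection ratio (candidates per available slot) is
#'   recorded.
#' @return A list of class `selection_plan` with `total_slots`, `pinned`,
#'   `available_slots` and `selection_ratio` (NA when `n_candidates` is
#'   not supplied).
#' @export
#' @examples
#' plan <- selection_plan(9000, n_candidates = 40794,
#'                        pinned = tibble::tibble(chrom = character(),
#'                                                pos = integer())[0, ])
selection_plan <- function(total_slots, pinned = NULL, n_candidates = NULL) {
  if (is.null(pinned)) {
    pinned <- tibble::tibble(chrom = character(), pos = integer())
  }
  n_pin <- nrow(pinned)
  if (n_pin > total_slots) {
    abort("selection_plan: more pinned SNPs than slots",
          class = "snparray_invalid_plan")
  }
  available <- total_slots - n_pin
  ratio <- if (!is.null(n_candidates) && available > 0) {
    n_candidates / available
  } else {
    NA_real_
  }
  structure(
    list(total_slots = as.integer(total_slots), pinned = pinned,
         available_slots = as.integer(available), selection_ratio = ratio),
    class = "selection_plan"
  )
}

#' @export
print.selection_plan <- function(x, ...) {
  cat("<selection_plan> ", x$total_slots, " slots, ", nrow(x$pinned),
      " pinned, ", x$available_slots, " available",
      if (!is.na(x$selection_ratio))
        sprintf("; selection ratio %.2f", x$selection_ratio), "\n", sep = "")
  invisible(x)
}

#' Stage-2 (design-level) filtering
#'
#' Applies, in order, the design-stage retention rules: accession support
#' at least `min_support`, genic class exonic (restriction to predicted
#' coding regions), and location on an anchored pseudomolecule. Candidates
#' must already have passed the probe screens (Infinium type, tail
#' duplication, design score). Per-rule removal counts are attached as the
#' `"funnel"` attribute ([stage_log()]).
#'
#' @param candidates Candidate tibble with columns `n_support`,
#'   `genic_class`, `on_pseudomolecule` (the latter two can be supplied
#'   via `annotation`/`genome`).
#' @param annotation Optional annotation tibble used to fill a missing
#'   `genic_class` column via [classify_positions()].
#' @param genome Optional [genome_assembly] used to fill a missing
#'   `on_pseudomolecule` column.
#' @param min_support Minimum number of supporting accessions (default 5,
#'   i.e. removal of candidates supported by fewer than five).
#' @return The retained candidates with funnel log attached.
#' @export
filter_stage2 <- function(candidates, annotation = NULL, genome = NULL,
                          min_support = 5L) {
  if (!"genic_class" %in% names(candidates)) {
    if (is.null(annotation)) {
      abort("filter_stage2: no genic_class column and no annotation supplied",
            class = "snparray_annotation_gap")
    }
    candidates <- classify_positions(annotation, candidates)
  }
  if (anyNA(candidates$genic_class)) {
    abort("filter_stage2: candidates with missing genic class",
          class = "snparray_annotation_gap")
  }
  if (!"on_pseudomolecule" %in% names(candidates)) {
    if (is.null(genome)) {
      abort(paste0("filter_stage2: no on_pseudomolecule column and no ",
                   "genome supplied"),
            class = "snparray_annotation_gap")
    }
    un <- genome$chromosomes$chrom[genome$chromosomes$unanchored]
    candidates$on_pseudomolecule <- !candidates$chrom %in% un
  }
  log <- list()
  step <- function(x, keep, rule) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      rule = rule, removed = sum(!keep), remaining = sum(keep))
    x[keep, , drop = FALSE]
  }
  out <- candidates
  out <- step(out, out$n_support >= min_support, "accession_support")
  out <- step(out, out$genic_class == "exonic", "exonic_restriction")
  out <- step(out, out$on_pseudomolecule, "pseudomolecule_restriction")
  attr(out, "funnel") <- dplyr::bind_rows(log)
  out
}

# Bisection-refinement ordering of grid points over [a, b]: the two
# endpoints first, then interval midpoints level by level (1/2; 1/4, 3/4;
# 1/8, 3/8, ...). The first k points for k = 2^m + 1 are exactly the
# uniform k-point grid, and the point set for k slots is nested inside the
# set for k + 1 — which makes the largest inter-SNP gap of the selection
# non-increasing in the slot count.
grid_sequence <- function(a, b, k) {
  if (k < 1) return(numeric(0))
  if (k == 1) return((a + b) / 2)
  offs <- c(0, 1)
  m <- 1L
  while (length(offs) < k) {
    offs <- c(offs, seq(1, 2^m - 1, by = 2) / 2^m)
    m <- m + 1L
  }
  a + offs[seq_len(k)] * (b - a)
}

# Largest-remainder apportionment of `slots` across groups proportional
# to `weights`; ties on the fractional remainder go to the earlier group.
largest_remainder <- function(weights, slots) {
  if (sum(weights) == 0 || slots == 0) return(rep(0L, length(weights)))
  quota <- slots * weights / sum(weights)
  base <- floor(quota)
  left <- slots - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Select evenly spaced SNPs into a fixed-size array design
#'
#' Pre-validated (pinned) SNPs are always included. Remaining slots are
#' allocated to chromosomes by largest-remainder rounding proportional to
#' their candidate counts, so that design density tracks candidate
#' density. Within a chromosome, ideal target positions spanning the
#' interval from the first to the last candidate (or pinned) position are
#' laid down in bisection-refinement order (endpoints, then interval
#' midpoints level by level); each pinned SNP consumes its nearest target
#' point, and every remaining target point is filled, in refinement
#' order, by the nearest still-unused candidate (ties go to the lower
#' position). Because the target-point sets are nested as slots grow, the
#' largest inter-SNP gap on a chromosome never increases when the slot
#' count increases.
#'
#' @param stage2 Design-stage candidate tibble (`chrom`, `pos`, ...).
#' @param plan A [selection_plan()]. Pinned SNPs on unanchored scaffolds
#'   are included without participating in any grid.
#' @return An `array_design` tibble: the selected SNPs sorted by
#'   `(chrom, pos)` with a `pinned` flag, of size
#'   `min(total_slots, pinned + candidates)`.
#' @export
select_even_spacing <- function(stage2, plan) {
  stopifnot(inherits(plan, "selection_plan"))
  pinned <- plan$pinned
  if (nrow(pinned) > 0) {
    pinned <- dplyr::mutate(pinned, pinned = TRUE)
  }
  cand <- dplyr::anti_join(stage2,
                           pinned[, intersect(c("chrom", "pos"), names(pinned)),
                                  drop = FALSE],
                           by = c("chrom", "pos"))
  cand <- dplyr::distinct(cand, .data$chrom, .data$pos, .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos)
  n_take <- min(plan$available_slots, nrow(cand))

  chroms <- unique(c(cand$chrom, pinned$chrom))
  counts <- vapply(chroms, function(ch) sum(cand$chrom == ch), integer(1))
  alloc <- largest_remainder(counts, n_take)

  picks <- list()
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    pc <- if (nrow(pinned) > 0) pinned[pinned$chrom == ch, , drop = FALSE]
          else pinned
    n_grid <- alloc[i] + nrow(pc)
    if (alloc[i] == 0 || nrow(cc) == 0) next
    span <- range(c(cc$pos, pc$pos))
    grid <- grid_sequence(span[1], span[2], n_grid)
    # pinned SNPs consume their nearest grid points first
    free <- rep(TRUE, length(grid))
    for (p in pc$pos) {
      j <- which(free)[which.min(abs(grid[free] - p))]
      if (length(j)) free[j] <- FALSE
    }
    grid <- grid[free]
    used <- rep(FALSE, nrow(cc))
    sel <- integer(0)
    for (g in grid) {
      if (!any(!used)) break
      open <- which(!used)
      d <- abs(cc$pos[open] - g)
      j <- open[order(d, cc$pos[open])[1]]
      used[j] <- TRUE
      sel <- c(sel, j)
    }
    picks[[ch]] <- cc[sort(sel), , drop = FALSE]
  }
  chosen <- dplyr::bind_rows(picks)
  if (nrow(chosen) > 0) chosen$pinned <- FALSE
  design <- dplyr::bind_rows(pinned, chosen) |>
    dplyr::arrange(.data$chrom, .data$pos)
  class(design) <- c("array_design", class(design))
  design
}

#' Remove SNPs lost during array manufacturing
#'
#' Bead synthesis loses a fraction of designed assays ("technical
#' dropout"). Dropout can be given as an explicit id/position list or as
#' a random rate (deterministic under `seed`).
#'
#' @param design An `array_design` tibble.
#' @param dropout_ids Character vector of `snp_id`s (or `chrom_pos`
#'   strings when no `snp_id` column exists) to remove.
#' @param rate Alternative: fraction of SNPs removed at random.
#' @param seed Seed for rate mode.
#' @return The design minus dropped SNPs.
#' @export
apply_manufacturing_dropout <- function(design, dropout_ids = NULL,
                                        rate = NULL, seed = 1L) {
  ids <- if ("snp_id" %in% names(design)) design$snp_id else
    paste0(design$chrom, "_", design$pos)
  if (!is.null(dropout_ids)) {
    unknown <- setdiff(dropout_ids, ids)
    if (length(unknown)) {
      abort(paste0("apply_manufacturing_dropout: unknown ids: ",
                   paste(head(unknown, 3), collapse = ", ")),
            class = "snparray_consistency_error")
    }
    keep <- !ids %in% dropout_ids
  } else if (!is.null(rate)) {
    if (rate < 0 || rate > 1) {
      abort("apply_manufacturing_dropout: rate must be in [0, 1]",
            class = "snparray_invalid_config")
    }
    keep <- with_seed(seed, runif(length(ids)) >= rate)
  } else {
    keep <- rep(TRUE, length(ids))
  }
  design[keep, , drop = FALSE]
}
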