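#' Coverage rate at fixed depth thresholds
#'
#' Fraction of target bases covered at or above each depth: `rate[n]` is the
#' share of bases with depth >= n ("covered at nX"). Rates are monotone
#' non-increasing in the threshold.
#'
#' @param profile A `coverage_profile`.
#' @param thresholds Depths in X (default `c(15, 30, 50, 100)`).
#' @param effort Optional sequencing-effort label attached as a column.
#' @return A tibble with columns `depth`, `rate` (and `effort` if given).
#' @examples
#' coverage_rate(coverage_profile(c(0, 10, 20, 30, 40)), thresholds = 20)
#' @export
coverage_rate <- function(profile, thresholds = c(15, 30, 50, 100),
                          effort = NULL) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (length(profile$depth) == 0) stop("empty coverage profile")
  out <- tibble::tibble(
    depth = as.numeric(thresholds),
    rate = vapply(thresholds, function(n) mean(profile$depth >= n), numeric(1))
  )
  if (!is.null(effort)) out <- dplyr::mutate(out, effort = effort, .before = 1)
  out
}

#' Fold-80 base penalty
#'
#' The fold increase of (non-zero) coverage needed to bring 80% of target
#' bases up to the observed mean coverage: mean depth divided by the 20th
#' percentile of the per-base depth distribution (ascending rank
#' `ceiling(0.2 * N)` over all target bases, zeros included). A perfectly
#' uniform profile scores exactly 1; larger values mean more re-sequencing
#' would be needed to rescue the worst-covered fifth of the target. When the
#' 20th percentile is zero the statistic is undefined and `NA` is returned
#' with a warning rather than an infinity.
#'
#' @param profile A `coverage_profile`.
#' @return A single ratio >= 1, or `NA` if undefined.
#' @examples
#' fold80(coverage_profile(c(10, 10, 10, 10, 50))) # 18 / 10 = 1.8
#' @export
fold80 <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  d <- profile$depth
  if (length(d) == 0) stop("empty coverage profile")
  p20 <- sort(d)[ceiling(0.2 * length(d))]
  if (p20 == 0) {
    warning("fold80 undefined: 20th-percentile coverage is zero")
    return(NA_real_)
  }
  mean(d) / p20
}

#' Evenness score of a coverage profile
#'
#' Coverage-homogeneity score in percent; 100 iff coverage is perfectly
#' uniform. The default `"truncated"` form is
#' `E = 100 * sum(pmin(depth, C)) / (C * N)` with `C` the mean depth over the
#' `N` target bases: depth above the mean earns no credit, so piling reads
#' onto already-covered bases lowers the score. The `"discrete"` variant
#' averages the fraction of bases covered at each integer depth up to
#' `round(C)`; both forms agree at uniformity.
#'
#' @param profile A `coverage_profile` with positive mean depth.
#' @param method `"truncated"` (default) or `"discrete"`.
#' @return Percentage in `(0, 100]`.
#' @examples
#' evenness(coverage_profile(rep(50, 1000))) # 100
#' evenness(coverage_profile(c(10, 10, 10, 10, 50))) # 64.44
#' @export
evenness <- function(profile, method = c("truncated", "discrete")) {
  stopifnot(inherits(profile, "coverage_profile"))
  method <- match.arg(method)
  d <- profile$depth
  C <- mean(d)
  if (!is.finite(C) || C <= 0) stop("evenness undefined: mean depth is zero")
  if (method == "truncated") {
    100 * sum(pmin(d, C)) / (C * length(d))
  } else {
    k <- max(1L, round(C))
    100 * mean(vapply(seq_len(k), function(i) mean(d >= i), numeric(1)))
  }
}

#' Seeded downsampling of read pairs
#'
#' Selects exactly `n_pairs` whole templates (pairs kept intact, mates never
#' separated) uniformly at random without replacement. The same input and
#' seed always select the same pairs, which is how downsampled
#' sequencing-effort points stay reproducible.
#'
#' @param reads An alignment tibble.
#' @param n_pairs Number of templates to keep.
#' @param seed Integer seed (required).
#' @return The subsampled alignment tibble.
#' @export
downsample_pairs <- function(reads, n_pairs, seed) {
  ids <- unique(reads$qname)
  if (n_pairs > length(ids)) {
    stop(
      "requested ", n_pairs, " pairs but only ",
      length(ids), " are available"
    )
  }
  keep <- withr::with_seed(seed, sample(ids, n_pairs))
  reads[reads$qname %in% keep, , drop = FALSE]
}

#' Coverage-efficiency curves across sequencing efforts
#'
#' For each sequencing effort, downsamples the read pairs, re-marks and
#' removes duplicates (by default), computes the depth profile over the
#' target and tabulates coverage rates at the requested depths. Sampling is
#' *nested* by default (each smaller effort is a subset of the next), so the
#' rate at any fixed depth is exactly non-decreasing in effort; with
#' `nested = FALSE` each effort is drawn independently, mimicking independent
#' downsampling of the FASTQ.
#'
#' @param reads An alignment tibble.
#' @param target An interval tibble.
#' @param efforts Ascending read-pair counts to simulate.
#' @param thresholds Depths in X (default `c(15, 30, 50, 100)`).
#' @param seed Integer seed for the subsampling.
#' @param dedup Remove duplicates before computing depth (default `TRUE`).
#' @param nested Nested subsamples (default `TRUE`).
#' @param effort_labels Optional labels (e.g. `"40M"`) reported in the
#'   `effort` column instead of the raw pair counts.
#' @return An effort grid: tibble with columns `effort`, `depth`, `rate`.
#' @export
effort_curves <- function(reads, target, efforts, thresholds = c(15, 30, 50, 100),
                          seed = 1, dedup = TRUE, nested = TRUE,
                          effort_labels = NULL) {
  if (is.unsorted(efforts)) stop("efforts must be sorted ascending")
  ids <- unique(reads$qname)
  if (max(efforts) > length(ids)) {
    stop(
      "largest effort (", max(efforts), " pairs) exceeds available pairs (",
      length(ids), ")"
    )
  }
  if (is.null(effort_labels)) effort_labels <- efforts
  perm <- withr::with_seed(seed, sample(ids))
  grids <- lapply(seq_along(efforts), function(i) {
    keep <- if (nested) {
      perm[seq_len(efforts[i])]
    } else {
      withr::with_seed(seed + i, sample(ids, efforts[i]))
    }
    sub <- reads[reads$qname %in% keep, , drop = FALSE]
    if (dedup) sub <- mark_duplicates(sub)
    prof <- depth_profile(sub, target, include_duplicates = !dedup)
    coverage_rate(prof, thresholds, effort = effort_labels[i])
  })
  dplyr::bind_rows(grids)
}

#' Smallest sequencing effort reaching a coverage requirement
#'
#' Looks up the smallest effort in an effort grid whose coverage rate at the
#' given depth meets the requirement ("at least `required_rate` of target
#' bases covered at `depth`X"). Returns `NA` with a message when no tabulated
#' effort reaches it.
#'
#' @param grid An effort grid (columns `effort`, `depth`, `rate`).
#' @param depth Depth threshold in X (e.g. 30).
#' @param required_rate Required fraction of target bases (e.g. 0.90).
#' @return The effort value, or `NA` if not reached.
#' @examples
#' grid <- effort_grid(
#'   efforts = c(40, 60, 80, 100),
#'   rates = c(0.66, 0.83, 0.90, 0.92), depth = 30
#' )
#' minimal_effort(grid, depth = 30, required_rate = 0.90) # 80
#' @export
minimal_effort <- function(grid, depth, required_rate) {
  stopifnot(all(c("effort", "depth", "rate") %in% names(grid)))
  if (nrow(grid) == 0) stop("empty effort grid")
  hit <- grid[grid$depth == depth & grid$rate >= required_rate, , drop = FALSE]
  if (nrow(hit) == 0) {
    message(
      "required rate ", required_rate, " at ", depth,
      "X not reached by any tabulated effort"
    )
    return(NA_real_)
  }
  min(hit$effort)
}

#' Assemble an effort grid from tabulated rates
#'
#' Convenience constructor for effort grids from already-measured coverage
#' rates (e.g. a published per-effort table), for use with
#' [minimal_effort()] and [autoplot()].
#'
#' @param efforts Effort values (one per rate).
#' @param rates Coverage-rate fractions in `[0, 1]`.
#' @param depth The depth the rates refer to (single value or vector).
#' @return A tibble with columns `effort`, `depth`, `rate`.
#' @export
effort_grid <- function(efforts, rates, depth) {
  stopifnot(length(efforts) == length(rates), all(rates >= 0 & rates <= 1))
  tibble::tibble(
    effort = as.numeric(efforts),
    depth = as.numeric(depth),
    rate = as.numeric(rates)
  )
}

#' Coverage-efficiency curves restricted to a gene panel
#'
#' Identical pipeline to [effort_curves()] with depth restricted to the
#' panel's bases -- the clinical-validation view of a capture kit: how much
#' sequencing a diagnostic panel (or the OMIM morbid set) needs before its
#' bases are adequately covered.
#'
#' @inheritParams effort_curves
#' @param panel An interval tibble (e.g. from [build_panel_bed()]); must be
#'   non-empty.
#' @return An effort grid over the panel bases.
#' @export
panel_coverage_report <- function(reads, panel, efforts,
                                  thresholds = c(15, 30, 50, 100), seed = 1,
                                  dedup = TRUE, nested = TRUE,
                                  effort_labels = NULL) {
  panel <- merge_intervals(panel)
  if (nrow(panel) == 0) stop("empty panel after symbol resolution")
  effort_curves(
    reads, panel, efforts,
    thresholds = thresholds, seed = seed,
    dedup = dedup, nested = nested, effort_labels = effort_labels
  )
}
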