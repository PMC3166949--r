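#' SAM pooled scatter for a two-group comparison
#'
#' The gene-specific scatter combining both groups' within-group variation:
#' `s = sqrt( (1/n1 + 1/n2)/(n1 + n2 - 2) * (SS1 + SS2) )`, where SS is the
#' within-group sum of squared deviations. It is the standard error of the
#' difference of the two group means, the denominator of the relative
#' difference statistic.
#'
#' @param group1,group2 Numeric vectors of signals, each of length >= 2.
#' @return Non-negative scalar `s`; 0 iff both groups are internally constant.
#' @export
pooled_scatter <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) {
    stop("SAM requires >= 2 replicates per group (use factor-only analysis for n = 1)",
         call. = FALSE)
  }
  ss <- sum((group1 - mean(group1))^2) + sum((group2 - mean(group2))^2)
  sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
}

#' SAM relative difference
#'
#' `d = (mean(group2) - mean(group1)) / (s + s0)`: the difference of the two
#' group means relative to the gene's scatter, stabilised for small replicate
#' numbers by the fudge factor `s0`.
#'
#' @inheritParams pooled_scatter
#' @param s0 Non-negative fudge factor.
#' @return Scalar `d`; sign equals the sign of the mean difference.
#' @export
relative_difference <- function(group1, group2, s0) {
  stopifnot(s0 >= 0)
  s <- pooled_scatter(group1, group2)
  num <- mean(group2) - mean(group1)
  if (s + s0 == 0) {
    if (num == 0) return(0)
    stop("degenerate scatter: s + s0 = 0 with unequal means", call. = FALSE)
  }
  num / (s + s0)
}

# vectorised per-gene means, scatters and numerators for a genes x samples
# matrix split by two column index sets
sam_gene_stats <- function(values, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  x1 <- values[, idx1, drop = FALSE]
  x2 <- values[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
  list(numerator = m2 - m1, s = s)
}

sam_d <- function(numerator, s, s0) {
  denom <- s + s0
  d <- numerator / denom
  d[denom == 0 & numerator == 0] <- 0
  if (any(denom == 0 & numerator != 0)) {
    stop("degenerate scatter: s + s0 = 0 with unequal means", call. = FALSE)
  }
  d
}

#' Estimate the SAM fudge factor s0
#'
#' The exchangeability factor `s0` damps the relative difference of genes
#' whose scatter is near zero. With `method = "cv_minimizing_percentile"`
#' (the default), each candidate percentile of the scatter distribution is
#' evaluated by recomputing `d`, binning genes into scatter-quantile windows,
#' taking the median absolute deviation of `d` within each window, and
#' scoring the candidate by the coefficient of variation of those MADs across
#' windows; the candidate with the smallest CV wins, ties broken toward the
#' smallest percentile. `"fixed_percentile"` returns a stated percentile of
#' the scatter distribution and `"median"` its median.
#'
#' @param scatters Per-gene scatter values `s` (non-empty).
#' @param numerators Per-gene mean differences; required for the
#'   CV-minimising method (where `d` must be recomputed per candidate).
#' @param method One of `"cv_minimizing_percentile"`, `"fixed_percentile"`,
#'   `"median"`.
#' @param percentile_grid Candidate percentiles in `[0, 1]` (default
#'   `seq(0, 1, by = 0.05)`).
#' @param fixed_percentile Percentile used by `"fixed_percentile"`.
#' @param n_windows Number of scatter-quantile windows for the CV score.
#' @return Non-negative scalar `s0`.
#' @export
estimate_s0 <- function(scatters, numerators = NULL,
                        method = c("cv_minimizing_percentile",
                                   "fixed_percentile", "median"),
                        percentile_grid = seq(0, 1, by = 0.05),
                        fixed_percentile = 0.05,
                        n_windows = 10L) {
  method <- match.arg(method)
  if (length(scatters) == 0L) stop("empty scatter list", call. = FALSE)
  stopifnot(all(percentile_grid >= 0 & percentile_grid <= 1))
  if (method == "median") {
    return(stats::median(scatters))
  }
  if (method == "fixed_percentile") {
    return(unname(stats::quantile(scatters, fixed_percentile)))
  }
  if (is.null(numerators)) {
    stop("the CV-minimising method needs the per-gene numerators", call. = FALSE)
  }
  candidates <- unname(stats::quantile(scatters, percentile_grid))
  cvs <- vapply(candidates, function(s0) {
    s0_window_cv(scatters, numerators, s0, n_windows)
  }, numeric(1))
  if (all(!is.finite(cvs))) {
    return(candidates[1])           # degenerate scatter distribution: any
  }                                 # percentile is the same value
  candidates[which.min(replace(cvs, !is.finite(cvs), Inf))]
}

# CV across scatter-quantile windows of the within-window MAD of d
s0_window_cv <- function(scatters, numerators, s0, n_windows) {
  d <- sam_d(numerators, scatters, s0)
  n_windows <- max(2L, min(n_windows, floor(length(scatters) / 3)))
  breaks <- unique(stats::quantile(scatters, seq(0, 1, length.out = n_windows + 1L)))
  if (length(breaks) < 3L) return(NA_real_)
  bin <- cut(scatters, breaks, include.lowest = TRUE)
  mads <- tapply(d, bin, stats::mad)
  mads <- mads[!is.na(mads)]
  if (length(mads) < 2L || mean(mads) == 0) return(NA_real_)
  stats::sd(mads) / mean(mads)
}

# all balanced relabelings of n = n1 + n2 samples: columns are index sets of
# the permuted "group 2"; includes the identity labelling
balanced_relabelings <- function(n1, n2) {
  utils::combn(n1 + n2, n2)
}

#' Permutation null for the SAM statistic
#'
#' Recomputes the relative difference under relabelings of the sample-group
#' assignment. When the number of distinct balanced relabelings is at most
#' `max_enumerated` they are enumerated exhaustively (a duplicate 2 vs 2
#' design gives choose(4, 2) = 6, including the identity); otherwise
#' relabelings are sampled uniformly under `seed`. For each permutation the
#' per-gene `d` values are sorted; the expected order statistics are their
#' means across permutations.
#'
#' @param values Numeric genes x samples matrix (or [expr_matrix()]).
#' @param group Logical or 0/1 vector over columns: `TRUE`/1 marks group 2.
#' @param s0 Fudge factor used for every permutation.
#' @param max_enumerated Enumeration cap (default 1000).
#' @param seed Integer seed for sampled relabelings.
#' @return List with `dbar` (expected order statistics, ascending),
#'   `perm_d` (genes x permutations matrix of sorted null `d`), and
#'   `n_permutations`.
#' @export
permutation_null <- function(values, group, s0, max_enumerated = 1000L,
                             seed = 1L) {
  values <- unclass(values)
  group <- as.logical(group)
  stopifnot(length(group) == ncol(values))
  n2 <- sum(group); n1 <- sum(!group)
  if (n1 < 2L || n2 < 2L) {
    stop("permutation null needs two groups with >= 2 members each",
         call. = FALSE)
  }
  n_total <- choose(n1 + n2, n2)
  if (n_total <= max_enumerated) {
    sets <- balanced_relabelings(n1, n2)
  } else {
    rs <- local({ set.seed(seed); replicate(max_enumerated,
                                            sort(sample(n1 + n2, n2))) })
    sets <- rs
  }
  perm_d <- apply(sets, 2L, function(idx2) {
    idx1 <- setdiff(seq_len(n1 + n2), idx2)
    st <- sam_gene_stats(values, idx1, idx2)
    sort(sam_d(st$numerator, st$s, s0))
  })
  list(dbar = rowMeans(perm_d), perm_d = perm_d, n_permutations = ncol(perm_d))
}

#' Call significant genes at a given delta
#'
#' Observed `d` values are sorted and paired with the null expected order
#' statistics. The upper cutoff is the smallest positive sorted `d` whose
#' excess over its null expectation reaches `delta`; the lower cutoff is the
#' mirrored rule for negative `d`. Every gene beyond a cutoff is called. The
#' estimated FDR is the median, over permutations, of the number of null `d`
#' values beyond the cutoffs, divided by the number of genes called (0 by
#' convention when nothing is called).
#'
#' @param d Observed per-gene relative differences.
#' @param null Result of [permutation_null()].
#' @param delta Non-negative threshold.
#' @return List with `called` (logical per gene), `cut_up`, `cut_low`,
#'   `n_called`, `estimated_fdr`.
#' @export
call_significant <- function(d, null, delta) {
  stopifnot(delta >= 0, length(d) == length(null$dbar))
  ds <- sort(d)
  dbar <- null$dbar
  diff_up <- ds - dbar
  up_idx <- which(ds > 0 & diff_up >= delta)
  cut_up <- if (length(up_idx)) unname(ds[min(up_idx)]) else Inf
  diff_low <- dbar - ds
  low_idx <- which(ds < 0 & diff_low >= delta)
  cut_low <- if (length(low_idx)) unname(ds[max(low_idx)]) else -Inf
  called <- d >= cut_up | d <= cut_low
  n_called <- sum(called)
  if (n_called == 0L) {
    fdr <- 0
  } else {
    null_counts <- colSums(null$perm_d >= cut_up | null$perm_d <= cut_low)
    fdr <- stats::median(null_counts) / n_called
  }
  list(called = called, cut_up = cut_up, cut_low = cut_low,
       n_called = n_called, estimated_fdr = fdr)
}

#' Pick the smallest delta achieving a target FDR
#'
#' Scans an ascending delta grid (by default 101 values spanning 0 to the
#' largest observed excess |d - dbar|) and returns the smallest delta whose
#' estimated FDR is at or below `target_fdr`. Such a delta always exists:
#' beyond the largest excess nothing is called and the FDR is 0 by
#' convention.
#'
#' @inheritParams call_significant
#' @param target_fdr Target estimated FDR (default 0.05).
#' @param grid Optional ascending vector of candidate deltas.
#' @return List with `delta`, `estimated_fdr` and the `calls` at that delta.
#' @export
choose_delta <- function(d, null, target_fdr = 0.05, grid = NULL) {
  if (is.null(grid)) {
    dmax <- max(abs(sort(d) - null$dbar))
    grid <- seq(0, dmax * (1 + 1e-9), length.out = 101L)[-1]
  }
  for (delta in grid) {
    calls <- call_significant(d, null, delta)
    if (calls$estimated_fdr <= target_fdr) {
      return(list(delta = delta, estimated_fdr = calls$estimated_fdr,
                  calls = calls))
    }
  }
  calls <- call_significant(d, null, max(grid))
  list(delta = max(grid), estimated_fdr = calls$estimated_fdr, calls = calls)
}

#' Two-group SAM analysis
#'
#' Runs the full small-replicate SAM procedure on an expression matrix: the
#' per-gene relative difference with a data-driven fudge factor, an
#' exhaustive (or seeded-sampled) permutation null, and delta-threshold
#' significance calls with a permutation-estimated FDR. `d` is computed on
#' the signal scale by default, matching the ratio-based factors used
#' elsewhere in the pipeline; set `log2 = TRUE` to analyse log2 signals.
#'
#' @param matrix An [expr_matrix()] (typically globally scaled).
#' @param group Logical/0-1 vector over columns (`TRUE` = group 2), or a
#'   character vector of two sample-id sets is not supported — derive the
#'   vector from the sample sheet.
#' @param delta Non-negative threshold; if `NULL`, the smallest delta with
#'   estimated FDR at or below `target_fdr` is chosen.
#' @param target_fdr Target FDR used when `delta` is `NULL`.
#' @param s0_method Passed to [estimate_s0()].
#' @param max_enumerated,seed Passed to [permutation_null()].
#' @param log2 Analyse `log2(signal + 1)` instead of raw signals.
#' @return An object of class `sam_fit`.
#' @export
sam_test <- function(matrix, group, delta = NULL, target_fdr = 0.05,
                     s0_method = "cv_minimizing_percentile",
                     max_enumerated = 1000L, seed = 1L, log2 = FALSE) {
  values <- unclass(matrix)
  if (log2) values <- log2(values + 1)
  group <- as.logical(group)
  idx2 <- which(group); idx1 <- which(!group)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("SAM requires >= 2 replicates per group", call. = FALSE)
  }
  st <- sam_gene_stats(values, idx1, idx2)
  s0 <- estimate_s0(st$s, st$numerator, method = s0_method)
  d <- sam_d(st$numerator, st$s, s0)
  null <- permutation_null(values, group, s0,
                           max_enumerated = max_enumerated, seed = seed)
  if (is.null(delta)) {
    sel <- choose_delta(d, null, target_fdr = target_fdr)
    delta <- sel$delta
    calls <- sel$calls
  } else {
    calls <- call_significant(d, null, delta)
  }
  structure(list(
    d = stats::setNames(d, rownames(values)),
    s = stats::setNames(st$s, rownames(values)),
    s0 = s0,
    dbar = null$dbar,
    n_permutations = null$n_permutations,
    delta = delta,
    called = stats::setNames(calls$called, rownames(values)),
    cut_up = calls$cut_up,
    cut_low = calls$cut_low,
    estimated_fdr = calls$estimated_fdr,
    null = null
  ), class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM two-group analysis\n")
  cat(sprintf("  genes: %d   permutations: %d   s0: %.4g\n",
              length(x$d), x$n_permutations, x$s0))
  cat(sprintf("  delta: %.4g   called: %d   estimated FDR: %.4g\n",
              x$delta, sum(x$called), x$estimated_fdr))
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, ...) {
  up <- sum(object$called & object$d > 0)
  down <- sum(object$called & object$d < 0)
  out <- list(n_genes = length(object$d), s0 = object$s0,
              delta = object$delta, n_called = sum(object$called),
              n_up = up, n_down = down,
              estimated_fdr = object$estimated_fdr,
              cut_up = object$cut_up, cut_low = object$cut_low)
  class(out) <- "summary.sam_fit"
  out
}

#' @export
print.summary.sam_fit <- function(x, ...) {
  cat("SAM summary\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Quantile-quantile SAM plot
#'
#' Observed ordered `d` against the permutation-null expected order
#' statistics, with the delta band and called genes highlighted.
#'
#' @param x A `sam_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.sam_fit <- function(x, ...) {
  ord <- order(x$d)
  ds <- x$d[ord]
  called <- x$called[ord]
  graphics::plot(x$dbar, ds, xlab = "expected d (permutation null)",
                 ylab = "observed d",
                 col = ifelse(called, "firebrick", "grey40"),
                 pch = 20, ...)
  graphics::abline(0, 1, col = "grey60")
  graphics::abline(x$delta, 1, lty = 2, col = "grey60")
  graphics::abline(-x$delta, 1, lty = 2, col = "grey60")
  invisible(x)
}
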