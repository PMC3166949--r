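#' Globally scale each array to a target mean signal
#'
#' Each sample column is multiplied by `target_signal / mean(column)` so that
#' every array's mean signal equals the target (150 signal units by default,
#' the convention for this array generation). Global scaling makes arrays
#' comparable while preserving within-array ratios exactly, so all downstream
#' induction/repression factors are invariant to per-array loading
#' differences.
#'
#' @param matrix An unscaled [expr_matrix()].
#' @param target_signal Positive target mean signal (default 150).
#' @param trim Fraction trimmed from each tail of the per-array mean
#'   (default 0, the plain mean over all gene features; the array vendor's
#'   2 percent trimmed mean is available via `trim = 0.02`).
#' @return A list with `matrix` (the scaled [expr_matrix()]) and `report`, a
#'   data.frame of per-sample pre-scaling means and scale factors.
#' @export
global_scale <- function(matrix, target_signal = 150, trim = 0) {
  stopifnot(inherits(matrix, "expr_matrix"), target_signal > 0)
  if (is_scaled(matrix)) {
    stop("matrix is already globally scaled (scaled = TRUE)", call. = FALSE)
  }
  pre_means <- apply(unclass(matrix), 2L, mean, trim = trim)
  if (any(pre_means <= 0)) {
    stop(sprintf("cannot scale all-zero array '%s'",
                 colnames(matrix)[pre_means <= 0][1]), call. = FALSE)
  }
  factors <- target_signal / pre_means
  out <- sweep(unclass(matrix), 2L, factors, `*`)
  list(
    matrix = expr_matrix(out, scaled = TRUE),
    report = data.frame(sample_id = colnames(matrix),
                        pre_scaling_mean = unname(pre_means),
                        scale_factor = unname(factors))
  )
}

#' Average replicates within each (strain, condition) group
#'
#' Collapses the scaled matrix to one column per (strain, condition), the
#' arithmetic mean over replicates per gene. The pipeline order is fixed as
#' scale-then-average: scaling each array first makes the averages (and hence
#' all factors) invariant to per-array loading differences.
#'
#' @param matrix A scaled [expr_matrix()].
#' @param samples Sample-sheet data.frame covering every matrix column.
#' @return An [expr_matrix()] with columns named `<strain>.<condition>`.
#' @export
average_replicates <- function(matrix, samples) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!is_scaled(matrix)) {
    stop("average_replicates() expects a globally scaled matrix", call. = FALSE)
  }
  desc <- match_samples(matrix, samples)
  group <- paste(desc$strain, desc$condition, sep = ".")
  groups <- unique(group)
  out <- matrix(NA_real_, nrow(matrix), length(groups),
                dimnames = list(rownames(matrix), groups))
  for (g in groups) {
    out[, g] <- rowMeans(unclass(matrix)[, group == g, drop = FALSE])
  }
  expr_matrix(out, scaled = TRUE)
}

#' Replicate-deviation quality check
#'
#' For every gene and (strain, condition) group with at least two replicates,
#' computes each replicate's relative deviation from the replicate mean,
#' `|x_i - xbar| / xbar`. Replicates are expected to lie generally within 25
#' percent of their mean; entries beyond `threshold` are flagged. Groups with
#' a single replicate are skipped (and counted), as are gene/group entries
#' with a zero mean.
#'
#' @param matrix An [expr_matrix()] (scaled or not; deviations are
#'   scale-free within a group only after per-array scaling, so the scaled
#'   matrix is the intended input).
#' @param samples Sample-sheet data.frame.
#' @param threshold Maximum tolerated relative deviation (default 0.25).
#' @return A list with `flagged_fraction`, `n_entries`, `n_flagged`,
#'   `n_zero_mean_skipped`, `n_single_replicate_groups`, and `deviations`,
#'   a data.frame of per-(gene, group) maximum deviations.
#' @export
replicate_qc <- function(matrix, samples, threshold = 0.25) {
  stopifnot(inherits(matrix, "expr_matrix"), threshold > 0)
  desc <- match_samples(matrix, samples)
  group <- paste(desc$strain, desc$condition, sep = ".")
  groups <- unique(group)
  multi <- groups[vapply(groups, function(g) sum(group == g) >= 2L, logical(1))]
  n_single <- length(groups) - length(multi)
  if (length(multi) == 0L) {
    stop("no (strain, condition) group has >= 2 replicates", call. = FALSE)
  }
  if (n_single > 0L) {
    message(sprintf("replicate_qc: skipped %d single-replicate group(s)", n_single))
  }
  rows <- lapply(multi, function(g) {
    sub <- unclass(matrix)[, group == g, drop = FALSE]
    m <- rowMeans(sub)
    dev <- abs(sub - m) / m          # NaN where m == 0
    max_dev <- apply(dev, 1L, max)
    data.frame(gene = rownames(matrix), group = g, max_deviation = max_dev,
               row.names = NULL)
  })
  dev_df <- do.call(rbind, rows)
  zero <- is.na(dev_df$max_deviation)
  n_zero <- sum(zero)
  dev_df <- dev_df[!zero, , drop = FALSE]
  n_flagged <- sum(dev_df$max_deviation > threshold)
  list(
    flagged_fraction = if (nrow(dev_df)) n_flagged / nrow(dev_df) else 0,
    n_entries = nrow(dev_df),
    n_flagged = n_flagged,
    n_zero_mean_skipped = n_zero,
    n_single_replicate_groups = n_single,
    threshold = threshold,
    deviations = dev_df
  )
}
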