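#' Response-strength thresholds
#'
#' The fold-change thresholds of the response taxonomy. A reference-strain
#' gene counts as glucose-induced at a 1.8-fold increase and as strongly
#' induced above 4-fold; repression is binned at 1.8-, 4- and 15-fold tiers.
#' A PKA-null strain's response is "total" when its factor reaches
#' `total_fraction` (70 percent) of the reference strain's factor.
#'
#' @param induction_min Minimum induction factor for a responsive call (1.8).
#' @param strong_induction_min Strong-induction tier (4; counted strictly,
#'   "more than 4-fold").
#' @param repression_min Minimum repression factor for a responsive call
#'   (1.8, mirroring induction; the 4- and 15-fold tiers are reporting bins,
#'   not call thresholds).
#' @param repression_tier_strong,repression_tier_very_strong Repression
#'   reporting tiers (4 and 15; counted inclusively, "at least").
#' @param total_fraction Fraction of the reference factor a PKA-null strain
#'   must reach for a "total" call (0.7).
#' @return A list of validated thresholds, class `response_thresholds`.
#' @export
response_thresholds <- function(induction_min = 1.8,
                                strong_induction_min = 4,
                                repression_min = 1.8,
                                repression_tier_strong = 4,
                                repression_tier_very_strong = 15,
                                total_fraction = 0.7) {
  stopifnot(induction_min > 1, strong_induction_min >= induction_min,
            repression_min > 1,
            repression_tier_strong >= repression_min,
            repression_tier_very_strong >= repression_tier_strong,
            total_fraction > 0, total_fraction <= 1)
  structure(list(induction_min = induction_min,
                 strong_induction_min = strong_induction_min,
                 repression_min = repression_min,
                 repression_tier_strong = repression_tier_strong,
                 repression_tier_very_strong = repression_tier_very_strong,
                 total_fraction = total_fraction),
            class = "response_thresholds")
}

#' Induction and repression factors
#'
#' The induction factor is the quotient of the replicate-averaged signal in
#' the glucose condition over the signal in the ethanol (no-glucose)
#' condition; the repression factor is the reciprocal orientation. The
#' denominator is clamped at `floor` (1 signal unit by default) so that
#' near-zero signals cannot blow the ratio up; clamped entries are flagged
#' `floored` and excluded from "total" support downstream.
#'
#' @param glucose_mean,ethanol_mean Replicate-averaged, scaled signals
#'   (vectorised).
#' @param floor Positive denominator floor in signal units.
#' @return A data.frame with columns `value` (the fold factor) and `floored`.
#' @export
induction_factor <- function(glucose_mean, ethanol_mean, floor = 1) {
  ratio_factor(num = glucose_mean, den = ethanol_mean, floor = floor)
}

#' @rdname induction_factor
#' @export
repression_factor <- function(ethanol_mean, glucose_mean, floor = 1) {
  ratio_factor(num = ethanol_mean, den = glucose_mean, floor = floor)
}

ratio_factor <- function(num, den, floor) {
  stopifnot(floor > 0)
  if (any(num < 0) || any(den < 0)) {
    stop("signal values must be non-negative", call. = FALSE)
  }
  floored <- den < floor
  data.frame(value = num / pmax(den, floor), floored = floored)
}

#' Classify a gene's response strength across strains
#'
#' The reference strain is responsive when its factor reaches the direction's
#' threshold (1.8-fold by default). A responsive gene is "total" when at
#' least one PKA-null strain's factor is no less than 70 percent of the
#' reference factor, "partial" when some PKA-null strain is itself
#' responsive (factor at or above the direction threshold) but below the
#' 70 percent criterion, and "none" otherwise. Floored PKA-null factors do
#' not support a total call.
#'
#' @param ref_value Reference-strain factor.
#' @param null_values Named numeric vector of PKA-null strain factors
#'   (typically both suppressor strains; one is accepted, with a warning).
#' @param direction `"INDUCTION"` or `"REPRESSION"`.
#' @param thresholds A [response_thresholds()] object.
#' @param null_floored Logical vector parallel to `null_values`.
#' @return A list with `ref_responsive`, `strength`
#'   (`"TOTAL"`/`"PARTIAL"`/`"NONE"`, or `NA` when the reference is not
#'   responsive) and `supporting_strain`.
#' @export
classify_response_strength <- function(ref_value, null_values,
                                       direction = c("INDUCTION", "REPRESSION"),
                                       thresholds = response_thresholds(),
                                       null_floored = rep(FALSE, length(null_values))) {
  direction <- match.arg(direction)
  r <- direction_threshold(direction, thresholds)
  if (length(null_values) < 2L) {
    warning("only one PKA-null strain supplied; the 70% rule applies over the strains present")
  }
  ref_responsive <- ref_value >= r
  if (!ref_responsive) {
    return(list(ref_responsive = FALSE, strength = NA_character_,
                supporting_strain = NA_character_))
  }
  eligible <- !null_floored
  total_hit <- eligible & null_values >= thresholds$total_fraction * ref_value
  if (any(total_hit)) {
    support <- names(null_values)[total_hit][which.max(null_values[total_hit])]
    if (is.null(support)) support <- NA_character_
    return(list(ref_responsive = TRUE, strength = "TOTAL",
                supporting_strain = support))
  }
  if (any(null_values >= r)) {
    return(list(ref_responsive = TRUE, strength = "PARTIAL",
                supporting_strain = NA_character_))
  }
  list(ref_responsive = TRUE, strength = "NONE",
       supporting_strain = NA_character_)
}

direction_threshold <- function(direction, thresholds) {
  if (direction == "INDUCTION") thresholds$induction_min else thresholds$repression_min
}

#' Count responders per fold-change tier
#'
#' Cumulative tier counts for one strain and direction. Tiers are counted
#' inclusively ("at least"), except the 4-fold induction tier which is
#' strict ("more than 4-fold").
#'
#' @param values Numeric vector of factors (one strain, one direction).
#' @param direction `"INDUCTION"` or `"REPRESSION"`.
#' @param thresholds A [response_thresholds()] object.
#' @return Named integer vector of cumulative tier counts.
#' @export
count_responders <- function(values, direction = c("INDUCTION", "REPRESSION"),
                             thresholds = response_thresholds()) {
  direction <- match.arg(direction)
  if (direction == "INDUCTION") {
    c(induced_1.8 = sum(values >= thresholds$induction_min),
      induced_over_4 = sum(values > thresholds$strong_induction_min))
  } else {
    c(repressed_1.8 = sum(values >= thresholds$repression_min),
      repressed_4 = sum(values >= thresholds$repression_tier_strong),
      repressed_15 = sum(values >= thresholds$repression_tier_very_strong))
  }
}

#' Per-gene response factors for a condition pair
#'
#' Computes, for every gene and strain present, the induction and repression
#' factors between a baseline condition (ethanol) and a glucose condition,
#' from a replicate-averaged matrix as produced by [average_replicates()].
#'
#' @param avg An averaged [expr_matrix()] with `<strain>.<condition>` columns.
#' @param glucose_condition Condition quoted against the baseline (default
#'   `"GLUCOSE_30MIN"`).
#' @param baseline_condition Default `"ETHANOL"`.
#' @param floor Denominator floor in signal units.
#' @return A list of two gene x strain data structures: `induction` and
#'   `repression`, each a list with `value` and `floored` matrices.
#' @export
response_factors <- function(avg, glucose_condition = "GLUCOSE_30MIN",
                             baseline_condition = "ETHANOL", floor = 1) {
  cols <- strsplit(colnames(avg), ".", fixed = TRUE)
  strains <- vapply(cols, `[[`, character(1), 1L)
  conds <- vapply(cols, `[[`, character(1), 2L)
  present <- intersect(pka_strains(), strains[conds == glucose_condition])
  present <- intersect(present, strains[conds == baseline_condition])
  if (length(present) == 0L) {
    stop(sprintf("no strain has both conditions %s and %s",
                 baseline_condition, glucose_condition), call. = FALSE)
  }
  get_col <- function(strain, cond) unclass(avg)[, paste(strain, cond, sep = ".")]
  build <- function(fun) {
    vals <- matrix(NA_real_, nrow(avg), length(present),
                   dimnames = list(rownames(avg), present))
    flo <- matrix(FALSE, nrow(avg), length(present),
                  dimnames = dimnames(vals))
    for (st in present) {
      f <- fun(get_col(st, glucose_condition), get_col(st, baseline_condition),
               floor)
      vals[, st] <- f$value
      flo[, st] <- f$floored
    }
    list(value = vals, floored = flo)
  }
  list(
    induction = build(function(g, e, f) induction_factor(g, e, f)),
    repression = build(function(g, e, f) repression_factor(e, g, f))
  )
}
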