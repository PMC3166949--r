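#' Four-class PKA-dependence taxonomy
#'
#' Genes responding to glucose in the reference strain fall into four classes
#' according to whether the response survives the loss of PKA and whether it
#' can be elicited by activating PKA without glucose:
#' class 1, PKA-independent (responds without PKA, no response to PKA
#' activation alone); class 2, PKA-only (no response without PKA, responds to
#' PKA activation); class 3, redundant pathways (responds in both probes);
#' class 4, cooperative pathways (responds in neither probe alone; a partial
#' response without PKA is possible).
#'
#' When PKA-activation data are absent the taxonomy degrades gracefully: a
#' full PKA-null response is reported as class 1 with
#' `activation_data_absent = TRUE` (classes 1 and 3 cannot be told apart),
#' and a none/partial PKA-null response is `UNRESOLVED` (classes 2 and 4
#' cannot be told apart).
#'
#' @param ref_responsive Logical: is the reference strain responsive?
#' @param null_strength `"TOTAL"`, `"PARTIAL"` or `"NONE"`: the summarised
#'   PKA-null response (total if either suppressor strain is total).
#' @param activation_responsive Logical or `NA`: response under PKA
#'   activation without glucose.
#' @return List with `pka_class` and `activation_data_absent`.
#' @export
classify_pka_dependence <- function(ref_responsive, null_strength,
                                    activation_responsive = NA) {
  if (!isTRUE(ref_responsive)) {
    return(list(pka_class = "NOT_GLUCOSE_REGULATED",
                activation_data_absent = is.na(activation_responsive)))
  }
  stopifnot(null_strength %in% c("TOTAL", "PARTIAL", "NONE"))
  full_without_pka <- null_strength == "TOTAL"
  if (is.na(activation_responsive)) {
    cls <- if (full_without_pka) "CLASS1_PKA_INDEPENDENT" else "UNRESOLVED"
    return(list(pka_class = cls, activation_data_absent = TRUE))
  }
  cls <- if (full_without_pka) {
    if (activation_responsive) "CLASS3_REDUNDANT" else "CLASS1_PKA_INDEPENDENT"
  } else {
    if (activation_responsive) "CLASS2_PKA_ONLY" else "CLASS4_COOPERATIVE"
  }
  list(pka_class = cls, activation_data_absent = FALSE)
}

#' Transience of the glucose response
#'
#' Compares the short-term factor (30 min after glucose addition vs ethanol)
#' with the growth factor (exponential growth on glucose + ethanol vs
#' ethanol) in one strain. A short-term response (factor at or above the
#' direction's responsiveness threshold `r`) is `SUSTAINED` when the growth
#' factor both stays responsive (`>= r`) and holds at least
#' `sustain_fraction` (70 percent, mirroring the "total" criterion) of the
#' short-term factor; a short-term response that fades below either bar is
#' `TRANSIENT` ("more pronounced in the short-term experiments").
#' `GROWTH_ONLY` is a response present only during growth; `NONE` otherwise.
#'
#' @param short_value,growth_value Factors for the same gene, strain and
#'   direction.
#' @param direction `"INDUCTION"` or `"REPRESSION"`.
#' @param thresholds A [response_thresholds()] object.
#' @param sustain_fraction Fraction of the short-term factor the growth
#'   factor must retain for a sustained call (defaults to the thresholds'
#'   `total_fraction`).
#' @return One of `"TRANSIENT"`, `"SUSTAINED"`, `"GROWTH_ONLY"`, `"NONE"`.
#' @export
classify_transience <- function(short_value, growth_value,
                                direction = c("INDUCTION", "REPRESSION"),
                                thresholds = response_thresholds(),
                                sustain_fraction = thresholds$total_fraction) {
  direction <- match.arg(direction)
  r <- direction_threshold(direction, thresholds)
  short_on <- short_value >= r
  growth_on <- growth_value >= r &
    growth_value >= sustain_fraction * short_value
  if (short_on && growth_on) "SUSTAINED"
  else if (short_on) "TRANSIENT"
  else if (growth_value >= r) "GROWTH_ONLY"
  else "NONE"
}

#' PKA requirement under gluconeogenic growth
#'
#' Compares ethanol-growth expression of the two PKA-null suppressor strains
#' with the reference strain. Expression reduced by at least `fold` in both
#' mutants indicates that PKA is required for full expression under
#' gluconeogenic conditions; a reduction in only the *msn2 msn4* or only the
#' *yak1* background points at the respective suppressor pathway instead.
#'
#' @param ref_signal,msn_signal,yak_signal Replicate-averaged scaled
#'   ethanol-growth signals (vectorised).
#' @param fold Reduction cutoff, > 1 (default 2).
#' @return Character vector over genes: `"PKA_REQUIRED"`, `"MSN_DEPENDENT"`,
#'   `"YAK_DEPENDENT"` or `"UNCHANGED"`.
#' @export
pka_requirement_gluconeogenic <- function(ref_signal, msn_signal, yak_signal,
                                          fold = 2) {
  stopifnot(fold > 1)
  if (any(c(ref_signal, msn_signal, yak_signal) < 0)) {
    stop("signal values must be non-negative", call. = FALSE)
  }
  red_msn <- msn_signal <= ref_signal / fold
  red_yak <- yak_signal <= ref_signal / fold
  ifelse(red_msn & red_yak, "PKA_REQUIRED",
         ifelse(red_msn, "MSN_DEPENDENT",
                ifelse(red_yak, "YAK_DEPENDENT", "UNCHANGED")))
}

#' Divergence between the two suppressor strains
#'
#' Flags genes expressed at clearly different levels in the *msn2 msn4*
#' versus the *yak1* suppressor background under gluconeogenic growth.
#'
#' @param msn_signal,yak_signal Replicate-averaged scaled signals
#'   (vectorised).
#' @param fold Divergence cutoff, > 1 (default 2).
#' @param floor Denominator floor in signal units.
#' @return Character vector: `"HIGHER_IN_MSN"`, `"HIGHER_IN_YAK"` or
#'   `"SIMILAR"`.
#' @export
compare_suppressors <- function(msn_signal, yak_signal, fold = 2, floor = 1) {
  stopifnot(fold > 1, floor > 0)
  if (any(c(msn_signal, yak_signal) < 0)) {
    stop("signal values must be non-negative", call. = FALSE)
  }
  r_msn <- msn_signal / pmax(yak_signal, floor)
  r_yak <- yak_signal / pmax(msn_signal, floor)
  ifelse(r_msn >= fold, "HIGHER_IN_MSN",
         ifelse(r_yak >= fold, "HIGHER_IN_YAK", "SIMILAR"))
}

#' Assemble per-gene regulatory profiles
#'
#' Runs the whole per-gene pipeline: global scaling (unless the matrix is
#' already scaled), replicate averaging, induction/repression factors per
#' strain, response-strength calls, the four-class PKA-dependence taxonomy,
#' transience, and the gluconeogenic PKA-requirement and suppressor
#' comparison. The direction analysed per gene is the stronger of the
#' reference strain's induction and repression factors.
#'
#' @param matrix An [expr_matrix()]; scaled if `is_scaled()`, otherwise
#'   globally scaled to `target_signal` first.
#' @param samples Sample-sheet data.frame; must cover the reference strain
#'   and at least one PKA-null strain in `ETHANOL` and `GLUCOSE_30MIN`.
#' @param thresholds A [response_thresholds()] object.
#' @param floor Denominator floor in signal units (default 1).
#' @param gluconeogenic_fold Reduction / divergence cutoff (default 2).
#' @param target_signal Global-scaling target (default 150).
#' @return A data.frame of class `pka_profiles`, one row per gene.
#' @export
build_profiles <- function(matrix, samples,
                           thresholds = response_thresholds(),
                           floor = 1, gluconeogenic_fold = 2,
                           target_signal = 150) {
  desc <- match_samples(matrix, samples)
  have <- unique(paste(desc$strain, desc$condition, sep = "."))
  need <- c("REF_PKA_PLUS.ETHANOL", "REF_PKA_PLUS.GLUCOSE_30MIN")
  null_strains <- intersect(pka_strains()[-1],
                            unique(desc$strain[desc$condition %in%
                                               c("ETHANOL", "GLUCOSE_30MIN")]))
  missing <- setdiff(need, have)
  if (length(missing) || length(null_strains) == 0L) {
    stop(sprintf("missing required strain/condition combinations: %s",
                 paste(c(missing,
                         if (length(null_strains) == 0L) "a PKA-null strain in ETHANOL + GLUCOSE_30MIN"),
                       collapse = ", ")), call. = FALSE)
  }
  if (!is_scaled(matrix)) {
    matrix <- global_scale(matrix, target_signal = target_signal)$matrix
  }
  avg <- average_replicates(matrix, samples)
  genes <- rownames(avg)
  short <- response_factors(avg, "GLUCOSE_30MIN", "ETHANOL", floor)
  has_growth <- any(grepl("GLUCOSE_GROWTH$", colnames(avg)))
  growth <- if (has_growth)
    response_factors(avg, "GLUCOSE_GROWTH", "ETHANOL", floor) else NULL
  has_activation <- "REF_PKA_PLUS.PKA_ACTIVATED" %in% colnames(avg)
  activation <- if (has_activation)
    response_factors(avg, "PKA_ACTIVATED", "ETHANOL", floor) else NULL

  ref <- "REF_PKA_PLUS"
  nulls <- intersect(c("TPK_NULL_MSN", "TPK_NULL_YAK"),
                     colnames(short$induction$value))
  eth_cols <- paste(pka_strains(), "ETHANOL", sep = ".")
  has_gluconeo <- all(eth_cols %in% colnames(avg))

  profiles <- lapply(seq_along(genes), function(i) {
    ind_ref <- short$induction$value[i, ref]
    rep_ref <- short$repression$value[i, ref]
    direction <- if (ind_ref >= rep_ref) "INDUCTION" else "REPRESSION"
    dirset <- if (direction == "INDUCTION") short$induction else short$repression
    ref_value <- dirset$value[i, ref]
    null_values <- dirset$value[i, nulls]
    null_floored <- dirset$floored[i, nulls]
    call <- suppressWarnings(
      classify_response_strength(ref_value, null_values, direction,
                                 thresholds, null_floored))
    act_value <- NA_real_
    act_responsive <- NA
    if (has_activation) {
      actset <- if (direction == "INDUCTION") activation$induction
                else activation$repression
      act_value <- actset$value[i, ref]
      act_responsive <- act_value >= direction_threshold(direction, thresholds)
    }
    cls <- classify_pka_dependence(
      call$ref_responsive,
      if (is.na(call$strength)) "NONE" else call$strength,
      act_responsive)
    growth_ref <- NA_real_
    trans <- stats::setNames(rep(NA_character_, 1 + length(nulls)),
                             c(ref, nulls))
    if (has_growth) {
      gset <- if (direction == "INDUCTION") growth$induction else growth$repression
      for (st in intersect(c(ref, nulls), colnames(gset$value))) {
        sv <- dirset$value[i, st]
        trans[st] <- classify_transience(sv, gset$value[i, st], direction,
                                         thresholds)
      }
      growth_ref <- gset$value[i, ref]
    }
    data.frame(
      gene = genes[i],
      direction = direction,
      ref_factor = ref_value,
      msn_factor = if ("TPK_NULL_MSN" %in% nulls)
        dirset$value[i, "TPK_NULL_MSN"] else NA_real_,
      yak_factor = if ("TPK_NULL_YAK" %in% nulls)
        dirset$value[i, "TPK_NULL_YAK"] else NA_real_,
      growth_factor_ref = growth_ref,
      activation_factor = act_value,
      ref_responsive = call$ref_responsive,
      null_strength = if (is.na(call$strength)) NA_character_ else call$strength,
      supporting_strain = call$supporting_strain,
      pka_class = cls$pka_class,
      activation_data_absent = cls$activation_data_absent,
      transience_ref = trans[[ref]],
      any_floored = any(dirset$floored[i, c(ref, nulls)]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, profiles)
  if (has_gluconeo) {
    eth <- unclass(avg)[, eth_cols, drop = FALSE]
    out$gluconeogenic <- pka_requirement_gluconeogenic(
      eth[, 1], eth[, 2], eth[, 3], fold = gluconeogenic_fold)
    out$suppressor_comparison <- compare_suppressors(
      eth[, 2], eth[, 3], fold = gluconeogenic_fold, floor = floor)
  } else {
    out$gluconeogenic <- NA_character_
    out$suppressor_comparison <- NA_character_
  }
  rownames(out) <- NULL
  class(out) <- c("pka_profiles", "data.frame")
  out
}

#' @export
print.pka_profiles <- function(x, ...) {
  cat(sprintf("PKA regulatory profiles: %d genes\n", nrow(x)))
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.pka_profiles <- function(object, ...) {
  out <- list(
    n_genes = nrow(object),
    pka_class = table(object$pka_class),
    transience_ref = table(object$transience_ref, useNA = "ifany"),
    gluconeogenic = table(object$gluconeogenic, useNA = "ifany")
  )
  class(out) <- "summary.pka_profiles"
  out
}

#' @export
print.summary.pka_profiles <- function(x, ...) {
  cat(sprintf("PKA regulatory profiles over %d genes\n\nPKA class:\n", x$n_genes))
  print(x$pka_class)
  cat("\nTransience (reference strain):\n")
  print(x$transience_ref)
  cat("\nGluconeogenic PKA requirement:\n")
  print(x$gluconeogenic)
  invisible(x)
}
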