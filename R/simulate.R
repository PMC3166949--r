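#' Simulation configuration
#'
#' Describes a synthetic dataset with the statistical structure the pipeline
#' assumes: a 3-strain design (reference plus the two PKA-null suppressor
#' strains) sampled on ethanol, 30 min after glucose addition and during
#' growth on glucose + ethanol, plus a PKA-activation pseudo-condition for
#' the reference genotype only; biological duplicates; planted regulatory
#' archetypes; multiplicative log-normal replicate noise calibrated so that
#' replicates generally lie within 25 percent of their mean; and per-array
#' scale distortions that global scaling must remove.
#'
#' @param n_genes Number of genes (default 6000, roughly a yeast genome).
#' @param responsive_fraction Fraction of genes with a planted glucose
#'   response (default 0.1).
#' @param class_mix Proportions of the four PKA-dependence classes among
#'   responsive genes (must sum to 1).
#' @param induction_fraction Fraction of responsive genes that are induced
#'   (the rest are repressed).
#' @param transient_fraction Fraction of responsive genes whose response is
#'   transient (reverted during growth on glucose).
#' @param msn_dependent_fraction Fraction of genes whose ethanol baseline
#'   requires Msn2/4 (divided by the effect size in the *msn2 msn4* strain).
#' @param effect_range Range of planted effect sizes; sampled log-uniformly
#'   (default 4 to 20-fold, comfortably above the 1.8-fold call threshold).
#' @param partial_fraction Attenuation of the effect in PKA-null strains for
#'   class-4 genes, on the log-fold scale fraction `[0, 0.7)`.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline signal
#'   distribution (median 100 signal units, sdlog 1).
#' @param replicate_cv Per-measurement coefficient of variation of the
#'   multiplicative noise (default 0.12).
#' @param array_scale_jitter CV of the per-array scale factors (default 0.3).
#' @param n_replicates Replicates per (strain, condition) group (default 2).
#' @param with_activation Generate the PKA-activation pseudo-condition.
#' @param with_growth Generate the glucose-growth condition.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 6000,
                       responsive_fraction = 0.1,
                       class_mix = c(CLASS1_PKA_INDEPENDENT = 0.25,
                                     CLASS2_PKA_ONLY = 0.25,
                                     CLASS3_REDUNDANT = 0.25,
                                     CLASS4_COOPERATIVE = 0.25),
                       induction_fraction = 0.5,
                       transient_fraction = 0.5,
                       msn_dependent_fraction = 0.05,
                       effect_range = c(4, 20),
                       partial_fraction = 0.3,
                       baseline_meanlog = log(100),
                       baseline_sdlog = 1,
                       replicate_cv = 0.12,
                       array_scale_jitter = 0.3,
                       n_replicates = 2L,
                       with_activation = TRUE,
                       with_growth = TRUE) {
  stopifnot(n_genes >= 1,
            responsive_fraction >= 0, responsive_fraction < 1,
            abs(sum(class_mix) - 1) < 1e-9, all(class_mix >= 0),
            induction_fraction >= 0, induction_fraction <= 1,
            transient_fraction >= 0, transient_fraction <= 1,
            msn_dependent_fraction >= 0, msn_dependent_fraction < 1,
            length(effect_range) == 2, effect_range[1] > 1,
            effect_range[2] >= effect_range[1],
            partial_fraction >= 0, partial_fraction < 0.7,
            replicate_cv >= 0, replicate_cv < 1,
            array_scale_jitter >= 0, array_scale_jitter < 1,
            n_replicates >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# mean-1 multiplicative log-normal factors with the given CV
lnorm_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic expression dataset with planted truth
#'
#' Draws gene baselines, assigns regulatory archetypes, builds the noiseless
#' expected signal per (gene, strain, condition) from the archetype rules,
#' then multiplies in per-measurement replicate noise and per-array scale
#' factors. The emitted matrix is unscaled (`scaled = FALSE`): running it
#' through [global_scale()] must remove the array distortions.
#'
#' Archetype rules: class 1 genes respond in every strain under glucose but
#' not under PKA activation; class 2 respond only where PKA is present
#' (reference under glucose, and under PKA activation); class 3 respond
#' everywhere and under PKA activation; class 4 respond fully only in the
#' reference, attenuated by `partial_fraction` (log-fold scale) in the
#' PKA-null strains, and not under PKA activation. Transient genes revert to
#' baseline during growth on glucose. Msn2/4-dependent genes have their
#' ethanol baseline divided by the effect size in the *msn2 msn4* strain.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List with `matrix` (unscaled [expr_matrix()]), `samples`
#'   (sample-sheet data.frame) and `truth` (class `planted_truth`: the
#'   per-gene archetype table and the noiseless expected signals).
#' @export
generate_dataset <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(n))
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)

  n_resp <- round(n * config$responsive_fraction)
  responsive <- seq_len(n) %in% sample.int(n, n_resp)
  pka_class <- rep("NOT_GLUCOSE_REGULATED", n)
  if (n_resp > 0) {
    pka_class[responsive] <- sample(names(config$class_mix), n_resp,
                                    replace = TRUE, prob = config$class_mix)
  }
  direction <- ifelse(responsive,
                      ifelse(stats::runif(n) < config$induction_fraction,
                             "INDUCTION", "REPRESSION"),
                      NA_character_)
  effect <- ifelse(responsive,
                   exp(stats::runif(n, log(config$effect_range[1]),
                                    log(config$effect_range[2]))),
                   1)
  transient <- responsive & stats::runif(n) < config$transient_fraction
  msn_dep <- stats::runif(n) < config$msn_dependent_fraction

  strains <- pka_strains()
  conds <- c("ETHANOL", "GLUCOSE_30MIN",
             if (config$with_growth) "GLUCOSE_GROWTH")
  groups <- expand.grid(strain = strains, condition = conds,
                        stringsAsFactors = FALSE)
  if (config$with_activation) {
    groups <- rbind(groups, data.frame(strain = "REF_PKA_PLUS",
                                       condition = "PKA_ACTIVATED"))
  }

  # attenuated effect for class-4 genes in PKA-null strains (log-fold scale)
  att_effect <- effect^config$partial_fraction

  glucose_effect <- function(strain) {
    e <- rep(1, n)
    is_null <- strain != "REF_PKA_PLUS"
    e[pka_class %in% c("CLASS1_PKA_INDEPENDENT", "CLASS3_REDUNDANT")] <-
      effect[pka_class %in% c("CLASS1_PKA_INDEPENDENT", "CLASS3_REDUNDANT")]
    if (!is_null) {
      sel <- pka_class %in% c("CLASS2_PKA_ONLY", "CLASS4_COOPERATIVE")
      e[sel] <- effect[sel]
    } else {
      sel <- pka_class == "CLASS4_COOPERATIVE"
      e[sel] <- att_effect[sel]
    }
    e
  }

  apply_effect <- function(base, e) {
    out <- base
    ind <- !is.na(direction) & direction == "INDUCTION"
    rep_ <- !is.na(direction) & direction == "REPRESSION"
    out[ind] <- base[ind] * e[ind]
    out[rep_] <- base[rep_] / e[rep_]
    out
  }

  expected <- matrix(NA_real_, n, nrow(groups),
                     dimnames = list(genes,
                                     paste(groups$strain, groups$condition,
                                           sep = ".")))
  for (k in seq_len(nrow(groups))) {
    st <- groups$strain[k]; cond <- groups$condition[k]
    base <- baseline
    if (st == "TPK_NULL_MSN") base <- ifelse(msn_dep, base / effect_or_default(effect, msn_dep), base)
    e <- rep(1, n)
    if (cond == "GLUCOSE_30MIN") {
      e <- glucose_effect(st)
    } else if (cond == "GLUCOSE_GROWTH") {
      e <- glucose_effect(st)
      e[transient] <- 1
    } else if (cond == "PKA_ACTIVATED") {
      sel <- pka_class %in% c("CLASS2_PKA_ONLY", "CLASS3_REDUNDANT")
      e[sel] <- effect[sel]
    }
    expected[, k] <- apply_effect(base, e)
  }

  reps <- seq_len(config$n_replicates)
  samples <- do.call(rbind, lapply(seq_len(nrow(groups)), function(k) {
    data.frame(
      sample_id = sprintf("%s.%s.r%d", groups$strain[k], groups$condition[k], reps),
      strain = groups$strain[k], condition = groups$condition[k],
      replicate = reps, stringsAsFactors = FALSE)
  }))

  col_of <- paste(samples$strain, samples$condition, sep = ".")
  noiseless <- expected[, col_of, drop = FALSE]
  colnames(noiseless) <- samples$sample_id
  noise <- matrix(lnorm_factors(n * nrow(samples), config$replicate_cv),
                  n, nrow(samples))
  array_factors <- lnorm_factors(nrow(samples), config$array_scale_jitter)
  values <- sweep(noiseless * noise, 2L, array_factors, `*`)

  truth <- structure(list(
    archetypes = data.frame(gene = genes, pka_class = pka_class,
                            direction = direction, effect_size = effect,
                            transient = transient,
                            msn_dependent_baseline = msn_dep,
                            stringsAsFactors = FALSE),
    expected = expected,
    array_factors = stats::setNames(array_factors, samples$sample_id)
  ), class = "planted_truth")

  list(matrix = expr_matrix(values, scaled = FALSE),
       samples = samples, truth = truth)
}

# baseline divisor for Msn2/4-dependent genes: responsive genes reuse their
# effect size; constitutive ones use the low end of the effect range
effect_or_default <- function(effect, msn_dep) {
  pmax(effect, 4)
}

#' Planted transience and gluconeogenic labels for a truth object
#'
#' @param truth A `planted_truth` object.
#' @return Data.frame with the per-gene expected calls of the downstream
#'   classifiers (`pka_class`, `transience`, `gluconeogenic`).
#' @export
truth_labels <- function(truth) {
  a <- truth$archetypes
  responsive <- a$pka_class != "NOT_GLUCOSE_REGULATED"
  data.frame(
    gene = a$gene,
    pka_class = a$pka_class,
    transience = ifelse(!responsive, "NONE",
                        ifelse(a$transient, "TRANSIENT", "SUSTAINED")),
    gluconeogenic = ifelse(a$msn_dependent_baseline, "MSN_DEPENDENT",
                           "UNCHANGED"),
    stringsAsFactors = FALSE
  )
}

#' Score recovery of the planted truth
#'
#' Cross-tabulates planted against called PKA classes and reports overall
#' and per-class accuracy, plus transience accuracy (over planted responsive
#' genes, reference strain) and gluconeogenic-category accuracy.
#'
#' @param truth A `planted_truth` object from [generate_dataset()].
#' @param profiles A `pka_profiles` data.frame from [build_profiles()] on the
#'   same gene universe.
#' @return List of class `recovery_score` with `confusion`,
#'   `per_class_accuracy`, `overall_accuracy`, `transience_accuracy` and
#'   `gluconeogenic_accuracy`.
#' @export
score_recovery <- function(truth, profiles) {
  stopifnot(inherits(truth, "planted_truth"), is.data.frame(profiles))
  labels <- truth_labels(truth)
  if (!setequal(labels$gene, profiles$gene)) {
    stop("truth and profiles cover different gene sets", call. = FALSE)
  }
  profiles <- profiles[match(labels$gene, profiles$gene), ]
  lv <- c("CLASS1_PKA_INDEPENDENT", "CLASS2_PKA_ONLY", "CLASS3_REDUNDANT",
          "CLASS4_COOPERATIVE", "NOT_GLUCOSE_REGULATED", "UNRESOLVED")
  confusion <- table(planted = factor(labels$pka_class, lv),
                     called = factor(profiles$pka_class, lv))
  diag_hits <- diag(confusion)[1:5]
  row_n <- rowSums(confusion)[1:5]
  per_class <- ifelse(row_n > 0, diag_hits / row_n, NA_real_)
  responsive <- labels$pka_class != "NOT_GLUCOSE_REGULATED"
  trans_acc <- if (any(responsive)) {
    mean(profiles$transience_ref[responsive] == labels$transience[responsive],
         na.rm = FALSE)
  } else NA_real_
  gluc_acc <- if (!all(is.na(profiles$gluconeogenic))) {
    mean(profiles$gluconeogenic == labels$gluconeogenic)
  } else NA_real_
  structure(list(
    confusion = confusion,
    per_class_accuracy = per_class,
    overall_accuracy = mean(labels$pka_class == profiles$pka_class),
    transience_accuracy = trans_acc,
    gluconeogenic_accuracy = gluc_acc
  ), class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat("Planted-truth recovery\n")
  cat(sprintf("  overall class accuracy: %.3f\n", x$overall_accuracy))
  cat(sprintf("  transience accuracy:    %.3f\n", x$transience_accuracy))
  if (!is.na(x$gluconeogenic_accuracy))
    cat(sprintf("  gluconeogenic accuracy: %.3f\n", x$gluconeogenic_accuracy))
  cat("\nPer-class accuracy:\n")
  print(round(x$per_class_accuracy, 3))
  cat("\nConfusion (planted x called):\n")
  print(x$confusion)
  invisible(x)
}
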