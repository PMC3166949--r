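#' Reported study tables
#'
#' Small tab-delimited tables of the study's reported values, shipped with
#' the package as worked-example inputs:
#'
#' * `"induction_factors"` — short-term (30 min) and growth induction factors
#'   for six representative glucose-induced genes in the three strains.
#' * `"repression_factors"` — the mirrored table for five glucose-repressed
#'   genes.
#' * `"gluconeogenic_signals"` — ethanol-growth signal levels of genes with
#'   different expression across the two suppressor strains.
#' * `"msn_target_profiles"` — expression of Msn2/4-activated, PKA-repressed
#'   genes, normalised to the reference strain's ethanol value (= 100).
#' * `"pka_class_examples"` — the four-class PKA-dependence map
#'   (reference / PKA-null / PKA-activated response pattern per class and
#'   direction) with representative genes.
#'
#' @param name One of the table names above.
#' @return A data.frame.
#' @export
study_table <- function(name = c("induction_factors", "repression_factors",
                                 "gluconeogenic_signals",
                                 "msn_target_profiles",
                                 "pka_class_examples")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "pkaglc",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
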