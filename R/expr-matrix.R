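#' Strain and condition vocabularies
#'
#' The experimental design covers a PKA-proficient reference strain
#' (*TPK1 TPK2 TPK3*) and two PKA-null strains kept alive by suppressor
#' mutations (*tpk1 tpk2 tpk3 msn2 msn4* and *tpk1 tpk2 tpk3 yak1*), sampled
#' on ethanol, 30 min after glucose addition, during exponential growth on
#' glucose + ethanol, and optionally under a PKA-activation pseudo-condition
#' (cAMP-driven PKA activation without glucose).
#'
#' @return Character vector of the admissible tokens.
#' @export
pka_strains <- function() {
  c("REF_PKA_PLUS", "TPK_NULL_MSN", "TPK_NULL_YAK")
}

#' @rdname pka_strains
#' @export
pka_conditions <- function() {
  c("ETHANOL", "GLUCOSE_30MIN", "GLUCOSE_GROWTH", "PKA_ACTIVATED")
}

#' Construct an expression matrix
#'
#' A thin S3 wrapper around a numeric gene x sample matrix of non-negative
#' probe-set signal values. `scaled` records whether global per-array scaling
#' has already been applied (see [global_scale()]).
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames. All values must be finite and non-negative.
#' @param scaled Logical flag; `TRUE` once per-array scaling has been applied.
#' @return An object of class `expr_matrix` (a numeric matrix with a
#'   `scaled` attribute).
#' @export
expr_matrix <- function(values, scaled = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative signal value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  structure(values, scaled = isTRUE(scaled), class = c("expr_matrix", "matrix"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (is_scaled(x)) "scaled" else "unscaled"))
  n <- min(5L, nrow(x)); m <- min(6L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE], ...)
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
is_scaled <- function(x) isTRUE(attr(x, "scaled"))

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) out <- structure(out, scaled = attr(x, "scaled"),
                                       class = c("expr_matrix", "matrix"))
  out
}

# internal: set the scaled flag without revalidating
set_scaled <- function(x, scaled) {
  attr(x, "scaled") <- isTRUE(scaled)
  x
}
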