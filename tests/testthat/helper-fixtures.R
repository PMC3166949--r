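# fixture builders shared across the suite; everything is generated in code

make_matrix <- function(values, genes = sprintf("g%d", seq_len(nrow(values))),
                        samples = sprintf("s%d", seq_len(ncol(values))),
                        scaled = FALSE) {
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scaled = scaled)
}

# full-factorial duplicate design sheet for the given strains x conditions
make_design <- function(strains = pka_strains(),
                        conditions = c("ETHANOL", "GLUCOSE_30MIN"),
                        reps = 2L) {
  g <- expand.grid(replicate = seq_len(reps), condition = conditions,
                   strain = strains, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s.%s.r%d", g$strain, g$condition, g$replicate),
             strain = g$strain, condition = g$condition,
             replicate = g$replicate, stringsAsFactors = FALSE)
}

# noiseless matrix for a design from per-(strain, condition) expected values:
# `expected` is genes x groups with "<strain>.<condition>" columns
make_noiseless <- function(expected, design) {
  cols <- paste(design$strain, design$condition, sep = ".")
  vals <- expected[, cols, drop = FALSE]
  colnames(vals) <- design$sample_id
  expr_matrix(vals, scaled = FALSE)
}

# the scaled flag is metadata; flipping it lets tests exercise idempotence
set_unscaled_for_test <- function(m) {
  attr(m, "scaled") <- FALSE
  m
}

# per-gene SAM pieces computed through the exported scalar operations,
# used to feed oracle comparisons
sam_scatter_vec <- function(vals, group) {
  apply(vals, 1, function(x) pooled_scatter(x[!group], x[group]))
}
sam_num_vec <- function(vals, group) {
  apply(vals, 1, function(x) mean(x[group]) - mean(x[!group]))
}
sam_d_vec <- function(vals, group, s0) {
  apply(vals, 1, function(x) relative_difference(x[!group], x[group], s0))
}
sam_d_for_test <- function(vals, idx1, idx2, s0) {
  apply(vals, 1, function(x) relative_difference(x[idx1], x[idx2], s0))
}
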