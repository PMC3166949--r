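# independent brute-force SAM reference: plain loops, explicit enumeration,
# no code shared with the package internals

oracle_scatter <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- sum(g1) / n1; m2 <- sum(g2) / n2
  ss <- 0
  for (x in g1) ss <- ss + (x - m1)^2
  for (x in g2) ss <- ss + (x - m2)^2
  sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * ss)
}

oracle_d <- function(g1, g2, s0) {
  num <- sum(g2) / length(g2) - sum(g1) / length(g1)
  den <- oracle_scatter(g1, g2) + s0
  if (den == 0 && num == 0) return(0)
  num / den
}

# every balanced relabeling of 1..(n1+n2): list of group-2 index vectors
oracle_relabelings <- function(n1, n2) {
  sets <- utils::combn(n1 + n2, n2)
  lapply(seq_len(ncol(sets)), function(k) sets[, k])
}

# full SAM: per-gene d/s, null order statistics, delta cutoffs, calls, FDR
oracle_sam <- function(values, group2_idx, s0, delta) {
  n <- ncol(values)
  group1_idx <- setdiff(seq_len(n), group2_idx)
  G <- nrow(values)
  d <- s <- numeric(G)
  for (g in seq_len(G)) {
    d[g] <- oracle_d(values[g, group1_idx], values[g, group2_idx], s0)
    s[g] <- oracle_scatter(values[g, group1_idx], values[g, group2_idx])
  }
  labs <- oracle_relabelings(length(group1_idx), length(group2_idx))
  perm_sorted <- matrix(NA_real_, G, length(labs))
  for (k in seq_along(labs)) {
    idx2 <- labs[[k]]; idx1 <- setdiff(seq_len(n), idx2)
    dk <- numeric(G)
    for (g in seq_len(G)) dk[g] <- oracle_d(values[g, idx1], values[g, idx2], s0)
    perm_sorted[, k] <- sort(dk)
  }
  dbar <- apply(perm_sorted, 1, mean)
  ds <- sort(d)
  cut_up <- Inf
  for (i in seq_len(G)) {
    if (ds[i] > 0 && ds[i] - dbar[i] >= delta) { cut_up <- ds[i]; break }
  }
  cut_low <- -Inf
  for (i in rev(seq_len(G))) {
    if (ds[i] < 0 && dbar[i] - ds[i] >= delta) { cut_low <- ds[i]; break }
  }
  called <- d >= cut_up | d <= cut_low
  if (sum(called) == 0) {
    fdr <- 0
  } else {
    counts <- numeric(length(labs))
    for (k in seq_along(labs)) {
      counts[k] <- sum(perm_sorted[, k] >= cut_up | perm_sorted[, k] <= cut_low)
    }
    fdr <- stats::median(counts) / sum(called)
  }
  list(d = d, s = s, dbar = dbar, cut_up = cut_up, cut_low = cut_low,
       called = called, fdr = fdr, n_perm = length(labs))
}

# brute-force CV-minimising s0 over the same percentile grid and window rule
oracle_s0 <- function(s, num, grid = seq(0, 1, by = 0.05), n_windows = 10L) {
  best <- NULL; best_cv <- Inf
  for (a in grid) {
    cand <- unname(stats::quantile(s, a))
    d <- num / (s + cand)
    nw <- max(2L, min(n_windows, floor(length(s) / 3)))
    breaks <- unique(stats::quantile(s, seq(0, 1, length.out = nw + 1L)))
    if (length(breaks) < 3L) next
    bin <- cut(s, breaks, include.lowest = TRUE)
    mads <- c()
    for (b in levels(bin)) {
      if (sum(bin == b, na.rm = TRUE) > 0) mads <- c(mads, stats::mad(d[bin == b]))
    }
    if (length(mads) < 2L || mean(mads) == 0) next
    cv <- stats::sd(mads) / mean(mads)
    if (cv < best_cv) { best_cv <- cv; best <- cand }
  }
  if (is.null(best)) unname(stats::quantile(s, grid[1])) else best
}
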