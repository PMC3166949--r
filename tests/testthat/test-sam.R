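test_that("pooled scatter matches the closed form and its invariances", {
  expect_equal(pooled_scatter(c(1, 3), c(5, 7)), sqrt(2))
  expect_equal(pooled_scatter(c(4, 4), c(9, 9)), 0)
  # shift invariance: within-group spread is all that matters
  for (shift in c(-5, 0, 100)) {
    expect_equal(pooled_scatter(c(1, 3) + shift, c(5, 7)),
                 pooled_scatter(c(1, 3), c(5, 7)))
  }
  expect_error(pooled_scatter(c(1), c(2, 3)), "2 replicates")
})

test_that("relative difference has the right sign, limits and degeneracies", {
  expect_equal(relative_difference(c(1, 3), c(5, 7), s0 = 0), 4 / sqrt(2))
  expect_equal(relative_difference(c(5, 7), c(5, 7), s0 = 0.1), 0)
  expect_lt(abs(relative_difference(c(1, 3), c(500, 900), s0 = 1e9)), 1e-6)
  # constant equal groups: d = 0 by convention; unequal constants error at s0 = 0
  expect_equal(relative_difference(c(4, 4), c(4, 4), s0 = 0), 0)
  expect_error(relative_difference(c(4, 4), c(9, 9), s0 = 0), "degenerate")
  # |d| non-increasing in s0
  d_at <- function(s0) abs(relative_difference(c(1, 3), c(5, 7), s0))
  s0s <- c(0, 0.5, 1, 2, 10)
  expect_true(all(diff(sapply(s0s, d_at)) <= 0))
})

test_that("s0 estimation handles degenerate scatter and matches brute force", {
  expect_equal(estimate_s0(rep(2, 30), numerators = rnorm(30)), 2)
  expect_equal(estimate_s0(rep(2, 5), method = "median"), 2)
  expect_equal(estimate_s0(c(1, 2, 9), method = "median"), 2)
  set.seed(21)
  s <- rlnorm(50, 0, 1)
  num <- rnorm(50, 0, 1 + s)
  expect_equal(estimate_s0(s, num), oracle_s0(s, num))
})

test_that("2v2 permutation null enumerates all six relabelings deterministically", {
  set.seed(3)
  vals <- matrix(rlnorm(40, log(100), 0.3), 10, 4)
  null <- permutation_null(vals, c(0, 0, 1, 1), s0 = 1)
  expect_equal(null$n_permutations, 6L)
  # identity labelling is one of them: its sorted d appears as a column
  d_obs <- sort(sam_d_for_test(vals, 1:2, 3:4, 1))
  expect_true(any(apply(null$perm_d, 2, function(col)
    isTRUE(all.equal(col, d_obs)))))
  # constant genes give an all-zero null
  cst <- matrix(5, 3, 4)
  expect_true(all(permutation_null(cst, c(0, 0, 1, 1), s0 = 1)$perm_d == 0))
  # seeded sampling is reproducible when enumeration is capped
  n1 <- permutation_null(vals, c(0, 0, 1, 1), s0 = 1, max_enumerated = 3, seed = 9)
  n2 <- permutation_null(vals, c(0, 0, 1, 1), s0 = 1, max_enumerated = 3, seed = 9)
  expect_identical(n1$perm_d, n2$perm_d)
})

test_that("full SAM matches the brute-force oracle on small designs", {
  for (case in list(list(n1 = 2, n2 = 2, G = 20, seed = 101),
                    list(n1 = 2, n2 = 2, G = 60, seed = 102),
                    list(n1 = 4, n2 = 4, G = 25, seed = 103),
                    list(n1 = 3, n2 = 3, G = 40, seed = 104))) {
    set.seed(case$seed)
    n <- case$n1 + case$n2
    vals <- matrix(rlnorm(case$G * n, log(100), 0.4), case$G, n)
    # plant a few large effects so calls are non-trivial
    vals[1:3, (case$n1 + 1):n] <- vals[1:3, (case$n1 + 1):n] * 8
    dimnames(vals) <- list(sprintf("g%02d", seq_len(case$G)),
                           sprintf("s%d", seq_len(n)))
    s0 <- 5
    delta <- 0.8
    group <- rep(c(FALSE, TRUE), c(case$n1, case$n2))
    null <- permutation_null(vals, group, s0 = s0)
    calls <- call_significant(sam_d_vec(vals, group, s0), null, delta)
    ora <- oracle_sam(vals, group2_idx = which(group), s0 = s0, delta = delta)
    expect_equal(null$n_permutations, ora$n_perm)
    expect_equal(unname(sam_scatter_vec(vals, group)), ora$s, tolerance = 1e-12)
    expect_equal(unname(sam_d_vec(vals, group, s0)), ora$d, tolerance = 1e-12)
    expect_equal(null$dbar, ora$dbar, tolerance = 1e-12)
    expect_equal(calls$cut_up, ora$cut_up)
    expect_equal(calls$cut_low, ora$cut_low)
    expect_identical(unname(calls$called), ora$called)
    expect_equal(calls$estimated_fdr, ora$fdr)
  }
})

test_that("delta monotonicity: the called set shrinks as delta grows", {
  set.seed(55)
  vals <- matrix(rlnorm(400, log(100), 0.3), 100, 4)
  vals[1:8, 3:4] <- vals[1:8, 3:4] * 5
  group <- c(FALSE, FALSE, TRUE, TRUE)
  s0 <- estimate_s0(sam_scatter_vec(vals, group),
                    sam_num_vec(vals, group))
  null <- permutation_null(vals, group, s0)
  d <- sam_d_vec(vals, group, s0)
  sizes <- sapply(seq(0, 3, by = 0.25), function(delta)
    call_significant(d, null, delta)$n_called)
  expect_true(all(diff(sizes) <= 0))
  # a delta beyond the largest excess calls nothing, FDR 0 by convention
  huge <- call_significant(d, null, max(abs(sort(d) - null$dbar)) + 1)
  expect_equal(huge$n_called, 0L)
  expect_equal(huge$estimated_fdr, 0)
})

test_that("sam_test recovers planted effects and self-null data gets FDR near 1 at delta 0", {
  set.seed(77)
  G <- 150
  vals <- matrix(rlnorm(G * 4, log(100), 0.15), G, 4,
                 dimnames = list(sprintf("g%03d", 1:G), paste0("s", 1:4)))
  vals[1:6, 3:4] <- vals[1:6, 3:4] * 7
  fit <- sam_test(make_matrix(vals, genes = rownames(vals), scaled = TRUE),
                  group = c(0, 0, 1, 1))
  expect_true(all(fit$called[1:6]))
  expect_lte(fit$estimated_fdr, 0.05)
  # delta = 0 on null-structured data: everything off-diagonal is called
  nullvals <- matrix(rlnorm(G * 4, log(100), 0.15), G, 4,
                     dimnames = dimnames(vals))
  nm <- make_matrix(nullvals, genes = rownames(nullvals), scaled = TRUE)
  fit0 <- sam_test(nm, group = c(0, 0, 1, 1), delta = 0)
  expect_gt(fit0$estimated_fdr, 0.5)
})
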