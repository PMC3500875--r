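make_panel <- function(arr, times = NULL) {
  panel_data(arr, times = times %||% seq_len(dim(arr)[2]))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("increment regressions recover exact linear laws", {
  set.seed(2)
  n <- 30; Tn <- 8
  x <- matrix(rnorm(n * Tn), n, Tn)
  # zero response: all coefficients zero
  arr <- array(c(x, matrix(5, n, Tn)), dim = c(n, Tn, 2),
               dimnames = list(NULL, NULL, c("x", "y")))
  s0 <- fit_increment_series(make_panel(arr), "y", c("x"))
  expect_equal(unname(s0$coef), matrix(0, Tn - 1, 2), tolerance = 1e-12)

  # noise-free law dY(t) = 2 x(t-1): coefficient exactly 2, zero residuals
  # (start from random levels so the lagged response is not degenerate)
  y <- matrix(0, n, Tn)
  y[, 1] <- rnorm(n)
  for (j in 2:Tn) y[, j] <- y[, j - 1] + 2 * x[, j - 1]
  arr2 <- array(c(x, y), dim = c(n, Tn, 2),
                dimnames = list(NULL, NULL, c("x", "y")))
  s <- fit_increment_series(make_panel(arr2), "y", c("x", "y"))
  expect_equal(unname(s$coef[, "x"]), rep(2, Tn - 1), tolerance = 1e-10)
  expect_equal(unname(s$coef[, "y"]), rep(0, Tn - 1), tolerance = 1e-10)
})

test_that("coefficients recover the generating coupling under noise", {
  set.seed(31)
  sc <- panel_scenario(n = 300, times = 0:20,
                       coupling = matrix(c(0, 0, 0.8, 0), 2, 2, byrow = TRUE),
                       noise_sd = c(0.5, 1))
  reps <- t(sapply(1:20, function(r) {
    p <- gen_coupled_panel(sc, seed = 400 + r)
    s <- fit_increment_series(p, "cd4", c("rna", "cd4"))
    mean(s$coef[, "rna"])
  }))
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 0.8), 3 * mc_se)
})

test_that("complete-case bookkeeping counts subjects with all required values", {
  p <- gen_coupled_panel(panel_scenario(n = 60, missing_rate = 0.25), seed = 6)
  s <- fit_increment_series(p, "cd4", c("rna", "cd4"))
  V <- p$values
  for (k in seq_along(s$times)) {
    j <- match(s$times[k], p$times)
    need <- cbind(V[, j, "cd4"], V[, j - 1, "cd4"], V[, j - 1, "rna"])
    expect_equal(s$n[k], sum(complete.cases(need)))
  }
})

test_that("times with too few complete cases are skipped and logged", {
  arr <- array(rnorm(5 * 4 * 2), dim = c(5, 4, 2),
               dimnames = list(NULL, NULL, c("x", "y")))
  arr[2:5, 3, ] <- NA  # only one complete case feeding the fit at time 3
  s <- fit_increment_series(make_panel(arr), "y", c("x", "y"))
  expect_true(length(s$skipped_times) >= 1)
  expect_false(3 %in% s$times)
})

test_that("cumulative coefficients are prefix sums with accumulated variance", {
  p <- gen_coupled_panel(panel_scenario(n = 80), seed = 12)
  s <- fit_increment_series(p, "cd4", c("rna", "cd4"))
  cc <- cumulative_coefficients(s)
  for (k in seq_along(s$times)) {
    expect_equal(cc$cumulative[k, ], colSums(s$coef[1:k, , drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(cc$var_cumulative[k, ], colSums(s$se[1:k, , drop = FALSE]^2),
                 tolerance = 1e-12)
  }
  # single fitted time: cumulative equals the per-time coefficient
  one <- s; one$coef <- s$coef[1, , drop = FALSE]
  one$se <- s$se[1, , drop = FALSE]; one$times <- s$times[1]; one$n <- s$n[1]
  cc1 <- cumulative_coefficients(one)
  expect_equal(cc1$cumulative[1, ], s$coef[1, ])
})

test_that("local-dependence test is direction-specific with calibrated null", {
  set.seed(55)
  sc <- panel_scenario()  # one-way coupling rna -> cd4
  p <- gen_coupled_panel(sc, seed = 90)
  coupled <- test_local_dependence(p, "rna", "cd4", adjust_for = "cd4")
  null_dir <- test_local_dependence(p, "cd4", "rna", adjust_for = "rna")
  expect_lt(coupled$p_value, 1e-6)
  expect_gt(null_dir$p_value, 1e-4)

  # permutation method agrees in decision and is seed-deterministic
  perm1 <- test_local_dependence(p, "cd4", "rna", adjust_for = "rna",
                                 method = "permutation", n_perm = 99, seed = 13)
  perm2 <- test_local_dependence(p, "cd4", "rna", adjust_for = "rna",
                                 method = "permutation", n_perm = 99, seed = 13)
  expect_identical(perm1$p_value, perm2$p_value)
  expect_gt(perm1$p_value, 0.05)
})

test_that("permutation test holds level when increments depend only on own lag", {
  set.seed(77)
  sc <- panel_scenario(n = 120, times = 0:10,
                       coupling = matrix(c(0, 0, 0, -0.1), 2, 2, byrow = TRUE),
                       noise_sd = c(0.5, 0.7))
  hits <- 0; runs <- 25
  for (r in 1:runs) {
    p <- gen_coupled_panel(sc, seed = 700 + r)
    tst <- test_local_dependence(p, "rna", "cd4", adjust_for = "cd4",
                                 method = "permutation", n_perm = 99,
                                 seed = 800 + r)
    if (tst$p_value <= 0.05) hits <- hits + 1
  }
  expect_lte(hits, 5)  # ~binomial(25, 0.05) upper tail
})

test_that("chi2 and permutation methods mostly agree in decision", {
  set.seed(91)
  sc <- panel_scenario(n = 150, times = 0:9)
  agree <- 0; runs <- 12
  for (r in 1:runs) {
    p <- gen_coupled_panel(sc, seed = 910 + r)
    for (dir in list(c("rna", "cd4"), c("cd4", "rna"))) {
      a <- test_local_dependence(p, dir[1], dir[2], adjust_for = dir[2])
      b <- test_local_dependence(p, dir[1], dir[2], adjust_for = dir[2],
                                 method = "permutation", n_perm = 99,
                                 seed = 920 + r)
      agree <- agree + ((a$p_value <= 0.05) == (b$p_value <= 0.05))
    }
  }
  expect_gte(agree / (2 * runs), 0.9)
})
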