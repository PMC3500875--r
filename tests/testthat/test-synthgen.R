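test_that("pure-baseline hazard matches the exponential law", {
  sc <- mediation_scenario(n = 2000, beta0 = 0.5, beta1 = 0, beta2 = 0,
                           end_time = 10, update_dt = 0.5, sim_dt = 0.01)
  d <- gen_mediation_survival(sc, seed = 21)
  last <- d[!duplicated(d$id, fromLast = TRUE), ]
  for (tt in c(1, 2, 5)) {
    frac <- mean(last$stop <= tt & last$event == 1)
    truth <- 1 - exp(-0.5 * tt)
    # binomial MC error plus the O(sim_dt) thinning discretization bias
    expect_lt(abs(frac - truth), 4 * sqrt(truth * (1 - truth) / 2000) + 0.01)
  }
})

test_that("unexposed scenarios carry a zero treatment column", {
  sc <- mediation_scenario(n = 100, p_treat = 0, end_time = 1)
  d <- gen_mediation_survival(sc, seed = 2)
  expect_true(all(d$x == 0))
})

test_that("generated data validate, clip negligibly, and are seed-deterministic", {
  sc <- mediation_scenario(n = 200)
  d1 <- gen_mediation_survival(sc, seed = 10)
  d2 <- gen_mediation_survival(sc, seed = 10)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_s3_class(d1, "cpdata")
  expect_lt(attr(d1, "clip_fraction"), 0.01)
  d3 <- gen_mediation_survival(sc, seed = 11)
  expect_false(identical(d1$stop, d3$stop))
})

test_that("scenario graphs encode the censoring structure and match dsep verdicts", {
  ind <- mediation_scenario(censoring = "independent", cens_rate = 0.2)
  g_ind <- scenario_graph(ind)
  # independent censoring: outcome separated from censoring given treatment
  expect_true(delta_separated(g_ind, "c", "y", "x"))

  dep <- mediation_scenario(censoring = "mediator", cens_rate = 0.1,
                            cens_coef = 0.3)
  g_dep <- scenario_graph(dep)
  expect_false(delta_separated(g_dep, "c", "y", "x"))
})

test_that("estimates stay unbiased under independent censoring", {
  # censoring at a constant rate leaves every process locally independent of
  # the censoring process; the dynamic-path slopes still recover the truth
  sc <- mediation_scenario(censoring = "independent", cens_rate = 0.3)
  s <- t(vapply(1:60, function(r) {
    d <- gen_mediation_survival(sc, seed = 3000 + r)
    f <- fit_dynamic_path(d, "x", "z")
    i <- max(which(f$times <= 1))
    j <- max(which(f$full$times <= 1))
    c(direct = f$direct[i], mediator = unname(f$full$cumulative[j, "z"]))
  }, numeric(2)))
  truth <- c(direct = 0.3, mediator = 0.5)
  mc_se <- apply(s, 2, sd) / sqrt(nrow(s))
  for (nm in names(truth)) {
    expect_lt(abs(mean(s[, nm]) - truth[nm]), 4 * mc_se[nm])
  }
})

test_that("mediator-dependent censoring biases the mediator-ignoring analysis", {
  # negative control: censoring driven by a persistent mediator selectively
  # removes high-hazard subjects, so the marginal (mediator-free) cumulative
  # baseline underestimates its uncensored counterpart; with no censoring as
  # the reference, the gap must be clearly nonzero
  baseline <- function(censoring, cens_coef, reps = 40) {
    sc <- mediation_scenario(n = 400, sd_subject = 0.5, sd_within = 0.1,
                             censoring = censoring,
                             cens_rate = if (censoring == "none") 0 else 0.1,
                             cens_coef = cens_coef, end_time = 1.5)
    vapply(seq_len(reps), function(r) {
      d <- gen_mediation_survival(sc, seed = 9000 + r)
      f <- suppressWarnings(fit_additive_hazard(d, "x"))
      i <- max(which(f$times <= 1.5))
      unname(f$cumulative[i, 1])
    }, 0)
  }
  b_none <- baseline("none", 0)
  b_dep <- baseline("mediator", 0.8)
  se_diff <- sqrt(var(b_none) / length(b_none) + var(b_dep) / length(b_dep))
  expect_gt(abs(mean(b_dep) - mean(b_none)), 4 * se_diff)
  expect_lt(mean(b_dep), mean(b_none))  # selection removes high-z subjects
})

test_that("coupled panels freeze without noise and match the SDE flow when discretized", {
  sc <- panel_scenario(n = 5, times = 0:5, coupling = matrix(0, 2, 2),
                       noise_sd = c(0, 0), init_sd = c(1, 1))
  p <- gen_coupled_panel(sc, seed = 1)
  for (j in 2:6) expect_equal(p$values[, j, ], p$values[, 1, ])

  # coupling = A * dt approximates the continuous flow of the same drift
  m <- chain_model(0.5, 0.4, 0.3)
  dt <- 0.01
  sc2 <- panel_scenario(n = 1, times = seq(0, 1, by = dt), vars = c("1", "2", "3"),
                        coupling = m$drift * dt, noise_sd = c(0, 0, 0),
                        init_mean = c(1, 0, 0), init_sd = c(0, 0, 0))
  p2 <- gen_coupled_panel(sc2, seed = 1)
  truth <- expected_state(m, c(1, 0, 0), 1)
  expect_equal(p2$values[1, length(sc2$times), ], truth, tolerance = 5e-3,
               ignore_attr = TRUE)
})

test_that("SDE panels respect observation noise, missingness, and determinism", {
  m <- chain_model()
  p0 <- gen_sde_panel(m, n = 4, times = seq(0, 1, 0.01), x0 = c(1, 0, 0))
  truth <- t(vapply(seq(0, 1, 0.01), function(tt)
    expected_state(m, c(1, 0, 0), tt), numeric(3)))
  for (i in 1:4) expect_equal(unname(p0$values[i, , ]), unname(truth),
                              tolerance = 1e-2)

  set.seed(1)
  p1 <- gen_sde_panel(m, n = 100, times = seq(0, 0.9, 0.1), x0 = c(1, 0, 0),
                      missing_rate = 0.3, seed = 44)
  nmiss <- sum(is.na(p1$values))
  expect_lt(abs(nmiss - 0.3 * length(p1$values)),
            4 * sqrt(length(p1$values) * 0.3 * 0.7))
})

test_that("stochastic ensemble mean reproduces the closed-form total effect", {
  m <- chain_model(noise_cov = diag(0.04, 3))
  times <- seq(0, 1, by = 0.001)
  ens <- simulate(m, nsim = 2000, seed = 123, x0 = c(1, 0, 0), times = times)
  z <- ens$states[, length(times), 3]
  mc_se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - 1.5), 4 * mc_se + 2e-3)
})

test_that("scenario files round-trip through YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("type: mediation", "n: 50", "beta1: 0.2", "end_time: 1.0"), fy)
  sy <- read_scenario(fy)
  expect_s3_class(sy, "mediation_scenario")
  expect_equal(sy$n, 50); expect_equal(sy$beta1, 0.2)

  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(type = "panel", n = 20, times = 0:5,
                            vars = c("rna", "cd4"),
                            coupling = list(c(0, 0), c(0.5, 0))),
                       fj, auto_unbox = TRUE)
  sj <- read_scenario(fj)
  expect_s3_class(sj, "panel_scenario")
  expect_equal(sj$coupling["cd4", "rna"], 0.5)
})
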