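test_that("counting-process validation catches malformed data", {
  ok <- data.frame(id = 1, start = 0, stop = 2, event = 1, x = 1)
  expect_s3_class(counting_process_data(ok), "cpdata")
  expect_error(counting_process_data(data.frame(id = 1, start = 1, stop = 1,
                                                event = 0)),
               "start must be < stop")
  expect_error(counting_process_data(data.frame(id = 1, start = 0, stop = 1)),
               "missing required column")
  bad_overlap <- data.frame(id = c(1, 1), start = c(0, 0.5), stop = c(1, 2),
                            event = c(0, 1))
  expect_error(counting_process_data(bad_overlap), "overlapping")
  bad_event <- data.frame(id = c(1, 1), start = c(0, 1), stop = c(1, 2),
                          event = c(1, 0))
  expect_error(counting_process_data(bad_event), "event before the last")
})

test_that("counting-process CSV round-trips a generated dataset", {
  d <- gen_mediation_survival(mediation_scenario(n = 40), seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_counting_process_csv(d, f)
  d2 <- read_counting_process_csv(f)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
})

test_that("intercept-only fit is the occurrence/exposure step estimator", {
  d <- hand_dataset()
  fit <- fit_additive_hazard(d, character())
  # independent occurrence/exposure computation straight from the data
  ev <- sort(unique(d$stop[d$event == 1]))
  inc <- vapply(ev, function(tk) {
    sum(d$stop == tk & d$event == 1) / sum(d$start < tk & tk <= d$stop)
  }, 0)
  expect_equal(fit$times, ev)
  expect_equal(unname(fit$increments[, 1]), inc, tolerance = 1e-12)
  expect_equal(unname(fit$cumulative[, 1]), cumsum(inc), tolerance = 1e-12)
  # variance of the occurrence/exposure increment is d_k / r_k^2
  expect_equal(unname(fit$var_increments[, 1]),
               vapply(ev, function(tk) {
                 sum(d$stop == tk & d$event == 1) /
                   sum(d$start < tk & tk <= d$stop)^2
               }, 0),
               tolerance = 1e-12)
})

test_that("increments solve the per-event-time normal equations (lm oracle)", {
  d <- hand_dataset()
  fit <- fit_additive_hazard(d, c("x", "z"))
  for (k in seq_along(fit$times)) {
    tk <- fit$times[k]
    at <- d[d$start < tk & tk <= d$stop, ]
    dN <- as.numeric(at$stop == tk & at$event == 1)
    oracle <- lm(dN ~ x + z, data = at)
    expect_equal(unname(fit$increments[k, ]), unname(coef(oracle)),
                 tolerance = 1e-10)
  }
  expect_equal(sum(fit$n_events), sum(d$event))
})

test_that("group-wise events reduce to per-group occurrence/exposure by block-orthogonality", {
  # two groups; all events in group 1 -> with a saturated group design the
  # fitted group-1 increment sum matches the group-1 intercept-only fit
  d <- counting_process_data(data.frame(
    id = 1:6,
    start = 0,
    stop = c(1, 2, 3, 4, 5, 6),
    event = c(1, 1, 1, 0, 0, 0),
    g = c(1, 1, 1, 0, 0, 0)
  ))
  fit <- fit_additive_hazard(d, "g")
  g1 <- counting_process_data(d[d$g == 1, ])
  base1 <- fit_additive_hazard(g1, character())
  fitted_g1 <- fit$cumulative[, "(Intercept)"] + fit$cumulative[, "g"]
  expect_equal(unname(fitted_g1), unname(base1$cumulative[, 1]),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are skipped and logged, not pseudo-inverted", {
  # covariate collinear with the intercept at every event time
  d <- counting_process_data(data.frame(
    id = 1:4, start = 0, stop = 1:4, event = c(1, 1, 0, 0), w = 1
  ))
  expect_warning(fit <- fit_additive_hazard(d, "w"), "skipped")
  expect_equal(length(fit$skipped_times), 2)
  expect_equal(length(fit$times), 0)
  expect_error(fit_additive_hazard(
    counting_process_data(data.frame(id = 1, start = 0, stop = 1, event = 0))),
    "no events")
})

test_that("additive-hazard increments match survival::aareg on single-interval data", {
  skip_if_not_installed("survival")
  set.seed(14)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n, 1, 0.3)
  tt <- round(rexp(n, rate = 0.2 + 0.1 * x + 0.2 * z), 3)
  tt <- pmax(tt, 0.01)
  status <- as.integer(tt < 4)
  tt <- pmin(tt, 4)
  d <- counting_process_data(data.frame(id = 1:n, start = 0, stop = tt,
                                        event = status, x = x, z = z))
  fit <- fit_additive_hazard(d, c("x", "z"))
  ar <- survival::aareg(survival::Surv(tt, status) ~ x + z)
  # aareg reports one row per event; aggregate ties to compare increments
  agg <- rowsum(ar$coefficient, ar$times)
  expect_equal(fit$times, as.numeric(rownames(agg)))
  expect_equal(unname(fit$increments), unname(agg), tolerance = 1e-8)
})

test_that("mediator regressions recover exact and constant relationships", {
  d <- hand_dataset()
  ts <- sort(unique(d$stop[d$event == 1]))
  # constant mediator: intercept c, slope 0
  d$zc <- 2.5
  s <- fit_mediator_series(d, "zc", "x", at_times = ts)
  expect_equal(unname(s$coef[, "(Intercept)"]), rep(2.5, length(s$times)))
  expect_equal(unname(s$coef[, "x"]), rep(0, length(s$times)))
  # noise-free linear law: slope exactly 2
  d$z2 <- 2 * d$x
  s2 <- fit_mediator_series(d, "z2", "x", at_times = ts)
  expect_equal(unname(s2$coef[, "x"]), rep(2, length(s2$times)), tolerance = 1e-12)
  expect_equal(unname(s2$se[, "x"]), rep(0, length(s2$times)), tolerance = 1e-8)
  # at-risk counts are an independent recount
  expect_equal(s$n, vapply(s$times, function(tk) sum(d$start < tk & tk <= d$stop), 0L))
})

test_that("mediator regression slope recovers the generating coefficient", {
  set.seed(8)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  z <- 0.7 + 1.5 * x + rnorm(n, 0, 0.5)
  tt <- rexp(n, 0.5)
  d <- counting_process_data(data.frame(id = 1:n, start = 0,
                                        stop = pmin(tt, 3),
                                        event = as.integer(tt <= 3),
                                        x = x, z = z))
  s <- fit_mediator_series(d, "z", "x", at_times = sort(unique(d$stop[d$event == 1])))
  mc_se <- sd(s$coef[, "x"]) / sqrt(length(s$times))
  # per-time estimates are highly correlated (shared sample), so compare the
  # average against the truth with a generous multiple of the spread
  expect_lt(abs(mean(s$coef[, "x"]) - 1.5), 3 * sd(s$coef[, "x"]))
  expect_gt(mean(s$coef[, "x"]), 1.0)
})
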