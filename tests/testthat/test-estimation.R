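test_that("fit metrics match hand-worked values", {
  # residuals 0.01 and 0.02: SSE = (1e-4 + 4e-4)/2
  expect_equal(solubility_sse(c(0.03, 0.05), c(0.02, 0.03)), 2.5e-4)
  expect_equal(solubility_sse(c(0.1, 0.2), c(0.1, 0.2)), 0)
  # a duplicate record with nonzero residual strictly increases SSE
  expect_gt(solubility_sse(c(0.03, 0.05, 0.05), c(0.02, 0.03, 0.03)),
            solubility_sse(c(0.03, 0.05), c(0.02, 0.03)))

  # log-symmetric two-point case: RMSLE = ln 2
  expect_equal(solubility_rmsle(c(0.01, 0.04), c(0.02, 0.02)), log(2))
  expect_equal(solubility_rmsle(c(0.1, 0.2), c(0.1, 0.2)), 0)
  # scale invariance of the log metric
  expect_equal(solubility_rmsle(c(0.001, 0.004), c(0.002, 0.002)), log(2))
  expect_error(solubility_rmsle(c(0, 0.1), c(0.1, 0.1)), "positive")
})

test_that("exclusion-aware RMSLE reports both metric styles", {
  d <- tibble::tibble(x_exp = c(0.01, 0.04, 0.001), exclude = c(0, 0, 1))
  m <- rmsle_metrics(d, c(0.02, 0.02, 0.01))
  expect_equal(m$rmsle_excluding_flagged, log(2))
  expect_gt(m$rmsle_all, m$rmsle_excluding_flagged)
})

test_that("bound transform maps the box smoothly and invertibly", {
  lb <- c(0, 1, 273.15); ub <- c(5, 1000, 500)
  expect_equal(bound_transform(c(0, 0, 0), lb, ub), lb)
  expect_equal(bound_transform(rep(pi / 2, 3), lb, ub), ub)
  set.seed(3)
  for (i in 1:20) {
    theta <- lb + runif(3) * (ub - lb)
    u <- bound_inverse(theta, lb, ub)
    expect_equal(bound_transform(u, lb, ub), theta, tolerance = 1e-12)
  }
  expect_error(bound_inverse(c(6, 2, 300), lb, ub), "outside bounds")
})

test_that("start sampling is seeded, in-bounds, prefix-stable and uniform", {
  b <- nrtlsac_bounds()
  s1 <- sample_starts(1000, b, seed = 4)
  s2 <- sample_starts(1000, b, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 1000L)
  for (j in seq_len(nrow(b))) {
    expect_true(all(s1[[b$parameter[j]]] >= b$lower[j] &
                      s1[[b$parameter[j]]] <= b$upper[j]))
  }
  # prefix property: the first k of n starts equal a k-start sample
  expect_identical(sample_starts(100, b, seed = 4), s1[1:100, ])

  # per-coordinate empirical means approach the box midpoints
  big <- sample_starts(10000, b, seed = 8)
  mid <- (b$lower + b$upper) / 2
  half <- (b$upper - b$lower) / 2
  expect_true(all(abs(colMeans(as.matrix(big)) - mid) < 0.05 * half))
})

test_that("the SSE objective is zero at the generating parameters", {
  lib <- make_solvent_library()
  sim <- simulate_solubility(sigma = 0, seed = 2)
  tt <- attr(sim, "theta_true")
  expect_lt(sse_objective(tt, sim, lib), 1e-18)
  expect_error(
    sse_objective(tt, dplyr::mutate(sim, solvent = "mystery"), lib),
    "mystery"
  )
})

test_that("a single start at the truth converges immediately on noiseless data", {
  lib <- make_solvent_library()
  sim <- simulate_solubility(sigma = 0, seed = 2)
  tt <- attr(sim, "theta_true")
  fit <- nrtlsac_fit(sim, lib, seed = 1,
                     fix = list(t_mp = tt[["t_mp"]]),
                     starts = tibble::as_tibble(as.list(tt[1:5])))
  expect_equal(fit$n_starts, 1L)
  expect_lt(fit$sse, 1e-12)
  expect_equal(unname(fit$parameters[1:5]), unname(tt[1:5]), tolerance = 1e-4)
})

test_that("fit results are internally consistent and respect bounds", {
  lib <- make_solvent_library()
  sim <- simulate_solubility(sigma = 0.05, seed = 6)
  tt <- attr(sim, "theta_true")
  fit <- nrtlsac_fit(sim, lib, n_starts = 20, seed = 9,
                     fix = list(t_mp = tt[["t_mp"]]))

  expect_equal(fit$sse, min(fit$trace$sse))
  expect_equal(sse_objective(fit$parameters, sim, lib), fit$sse,
               tolerance = 1e-12)
  td <- tidy(fit)
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  expect_true(td$fixed[td$term == "t_mp"])

  g <- glance(fit)
  expect_equal(g$n_starts, 20L)
  expect_equal(g$rmsle, solubility_rmsle(sim$x_exp, fit$data$x_sat))

  au <- augment(fit)
  expect_equal(au$.resid, au$x_exp - au$x_sat)

  land <- export_landscape(fit)
  expect_equal(nrow(land), 20L)
  expect_equal(land$start, 1:20)
  expect_equal(min(land$sse), fit$sse)
})

test_that("more starts never worsen the best objective (same seed)", {
  lib <- make_solvent_library()
  sim <- simulate_solubility(sigma = 0.05, seed = 14)
  tt <- attr(sim, "theta_true")
  f15 <- nrtlsac_fit(sim, lib, n_starts = 15, seed = 33,
                     fix = list(t_mp = tt[["t_mp"]]))
  f30 <- nrtlsac_fit(sim, lib, n_starts = 30, seed = 33,
                     fix = list(t_mp = tt[["t_mp"]]))
  expect_lte(f30$sse, f15$sse)
  # the shared prefix of the trace is identical
  expect_equal(f30$trace$sse[1:15], f15$trace$sse)
})

test_that("excluded records are dropped from the fit by default", {
  lib <- make_solvent_library()
  sim <- simulate_solubility(sigma = 0, seed = 5,
                             degrading_solvent = "polar_attractive_s2",
                             degrading_bias = 0.5)
  tt <- attr(sim, "theta_true")
  # with the biased records excluded, the truth still gives a perfect fit
  expect_lt(sse_objective(tt, sim, lib), 1e-18)
  # counting them in, the bias shows up
  expect_gt(sse_objective(tt, sim, lib, exclude_fit = FALSE), 1e-10)
})

test_that("fitted RMSLE tracks the generating noise level", {
  # the noise is lognormal, so the estimator consistent with it is the
  # log-residual objective; the mole-fraction objective leaves solvents with
  # tiny absolute solubility unweighted and their log errors unconstrained
  lib <- make_solvent_library()
  sigma <- 0.05
  rmsles <- vapply(1:10, function(s) {
    sim <- simulate_solubility(sigma = sigma, seed = 100 + s)
    tt <- attr(sim, "theta_true")
    fit <- nrtlsac_fit(sim, lib, n_starts = 30, seed = 200 + s,
                       fix = list(t_mp = tt[["t_mp"]]), log_residuals = TRUE)
    fit$rmsle
  }, numeric(1))
  expect_true(all(rmsles > sigma / 3 & rmsles < sigma * 3))
})

test_that("landscape band counting separates well-split objective clusters", {
  sse <- c(rep(1e-9, 5) * exp(runif(5, -0.1, 0.1)),
           rep(1e-3, 5) * exp(runif(5, -0.1, 0.1)),
           rep(1e+1, 5) * exp(runif(5, -0.1, 0.1)))
  expect_equal(landscape_bands(sse), 3L)
  expect_equal(landscape_bands(rep(2e-4, 10)), 1L)
  expect_equal(landscape_bands(numeric(0)), 0L)
})
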