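test_that("mixture segment fractions match hand-evaluated cases and normalize", {
  # single hydrophobic molecule: all segments are Z
  one <- tibble::tibble(mole_frac = 1, x = 0, y_minus = 0, y_plus = 0, z = 3.477)
  sf <- segment_fractions(one)
  expect_equal(sf$fraction, c(0, 0, 0, 1))

  # equimolar X / Z single-segment molecules
  eq <- binary_mixture(unit_segment("x"), unit_segment("z"), 0.5)
  expect_equal(segment_fractions(eq)$fraction, c(0.5, 0, 0, 0.5))

  # X:1 at 0.25 vs Z:3 at 0.75 -> 0.25/(0.25 + 2.25) = 0.1
  mix <- tibble::tibble(mole_frac = c(0.25, 0.75),
                        x = c(1, 0), y_minus = 0, y_plus = 0, z = c(0, 3))
  expect_equal(segment_fractions(mix)$fraction, c(0.1, 0, 0, 0.9))

  # normalization over random mixtures
  set.seed(21)
  for (i in 1:10) {
    n <- sample(2:4, 1)
    w <- runif(n); w <- w / sum(w)
    m <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      v <- random_segment_vector()
      tibble::tibble(mole_frac = w[j], x = v[["x"]], y_minus = v[["y_minus"]],
                     y_plus = v[["y_plus"]], z = v[["z"]])
    }))
    expect_equal(sum(segment_fractions(m)$fraction), 1, tolerance = 1e-12)
  }

  zero <- tibble::tibble(mole_frac = 1, x = 0, y_minus = 0, y_plus = 0, z = 0)
  expect_error(segment_fractions(zero), "at least one segment")
})

test_that("pure-component segment fractions are direct ratios", {
  v <- segment_vector(x = 0.488, y_minus = 0.076)
  pf <- pure_component_segment_fractions(v)
  expect_equal(pf$fraction[1], 0.488 / 0.564)
  expect_equal(pf$fraction[2], 0.076 / 0.564)
  expect_equal(sum(pf$fraction), 1, tolerance = 1e-12)

  expect_equal(pure_component_segment_fractions(unit_segment("z"))$fraction,
               c(0, 0, 0, 1))
  expect_equal(pure_component_segment_fractions(segment_vector(x = 2, z = 2))$fraction,
               c(0.5, 0, 0, 0.5))
  expect_error(pure_component_segment_fractions(segment_vector()),
               "zero total segment")
})

test_that("interaction table reproduces the published constants", {
  tbl <- nrtl_interactions()
  expect_equal(tbl$tau["x", "y_minus"], 1.643)
  expect_equal(tbl$tau["y_minus", "x"], 1.834)
  expect_equal(tbl$tau["x", "z"], 6.547)
  expect_equal(tbl$tau["z", "x"], 10.949)
  expect_equal(tbl$tau["y_minus", "z"], -2.000)
  expect_equal(tbl$tau["z", "y_minus"], 1.787)
  expect_equal(tbl$tau["y_plus", "z"], 2.000)
  expect_equal(tbl$tau["z", "y_plus"], 1.787)
  expect_equal(tbl$tau["x", "y_plus"], 1.643)
  expect_equal(tbl$tau["y_plus", "x"], 1.834)
  expect_equal(unname(diag(tbl$tau)), rep(0, 4))
  expect_equal(unname(diag(tbl$G)), rep(1, 4))
  expect_true(isSymmetric(tbl$alpha))
  # unparameterized Y-/Y+ pair: tau = 0, G = 1
  expect_equal(tbl$tau["y_minus", "y_plus"], 0)
  expect_equal(tbl$G["y_plus", "y_minus"], 1)
  expect_equal(tbl$G, exp(-tbl$alpha * tbl$tau), ignore_attr = FALSE)
})

test_that("ln gamma vanishes in the ideal limits", {
  set.seed(7)
  for (i in 1:5) {
    v <- random_segment_vector()
    pure <- binary_mixture(v, v, 1)[1, ]
    ac <- activity_coefficients(pure)
    expect_lt(abs(ac$ln_gamma), 1e-12)

    # two molecules with identical segment vectors, arbitrary composition
    twin <- binary_mixture(v, v, runif(1, 0.05, 0.95))
    ac2 <- activity_coefficients(twin)
    expect_lt(max(abs(ac2$ln_gamma)), 1e-12)
    expect_lt(max(abs(ac2$ln_gamma_residual)), 1e-12)
    expect_lt(max(abs(ac2$ln_gamma_combinatorial)), 1e-12)
  }
})

test_that("residual term matches the classic binary NRTL closed form", {
  pairs <- segment_pair_constants()
  # infinite-dilution limit for the X/Y- pair, evaluated at the floor fraction
  mix <- binary_mixture(unit_segment("x"), unit_segment("y_minus"), 1e-12)
  expect_equal(residual_lngamma(mix, index = 1),
               1.834 + 1.643 * exp(-0.2 * 1.643), tolerance = 1e-9)

  # composition sweep for every parameterized pair
  for (p in seq_len(nrow(pairs))) {
    a <- unit_segment(pairs$seg_1[p])
    b <- unit_segment(pairs$seg_2[p])
    for (x1 in c(0.05, 0.35, 0.65, 0.95)) {
      got <- residual_lngamma(binary_mixture(a, b, x1), index = 1)
      want <- oracle_nrtl_binary_lngamma1(x1, pairs$tau_12[p], pairs$tau_21[p],
                                          pairs$alpha[p])
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("combinatorial term matches the hand-worked Flory-Huggins value", {
  # r1 = 1, r2 = 2 at x1 = 0.5: 1 + ln(2/3) - 2/3
  mix <- binary_mixture(unit_segment("x"), segment_vector(z = 2), 0.5)
  expect_equal(combinatorial_lngamma(mix, index = 1),
               1 + log(2 / 3) - 2 / 3, tolerance = 1e-12)
  # equal total segment numbers -> 0 for every component
  mix2 <- binary_mixture(segment_vector(x = 1, z = 1),
                         segment_vector(y_minus = 2), 0.3)
  expect_lt(max(abs(combinatorial_lngamma(mix2))), 1e-12)
})

test_that("total ln gamma is the residual-combinatorial sum and is label-invariant", {
  set.seed(13)
  v1 <- random_segment_vector(); v2 <- random_segment_vector()
  mix <- binary_mixture(v1, v2, 0.3)
  ac <- activity_coefficients(mix)
  expect_equal(ac$ln_gamma, ac$ln_gamma_residual + ac$ln_gamma_combinatorial)

  # permutation invariance: relabeling components leaves each ln gamma alone
  flipped <- mix[2:1, ]
  ac_f <- activity_coefficients(flipped)
  expect_equal(ac_f$ln_gamma[2:1], ac$ln_gamma, tolerance = 1e-13)
})

test_that("binary mixtures satisfy the Gibbs-Duhem relation", {
  set.seed(31)
  h <- 1e-5
  for (i in 1:5) {
    v1 <- random_segment_vector(); v2 <- random_segment_vector()
    for (x1 in c(0.2, 0.5, 0.8)) {
      lg <- function(xx) lngamma(binary_mixture(v1, v2, xx))
      d <- (lg(x1 + h) - lg(x1 - h)) / (2 * h)
      expect_lt(abs(x1 * d[1] + (1 - x1) * d[2]), 1e-6)
    }
  }
})
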