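# Independent oracles and fixture builders. Nothing here calls the package's
# activity-coefficient or SLE internals; oracle results are compared against
# the package elsewhere.

# Classic two-component NRTL activity coefficient (closed form), for
# component 1 of a binary mixture with parameters tau12, tau21, alpha.
oracle_nrtl_binary_lngamma1 <- function(x1, tau12, tau21, alpha) {
  x2 <- 1 - x1
  G12 <- exp(-alpha * tau12)
  G21 <- exp(-alpha * tau21)
  x2^2 * (tau21 * (G21 / (x1 + x2 * G21))^2 +
            tau12 * G12 / (x2 + x1 * G12)^2)
}

# Root of the SLE residual ln x - ln x_ideal + ln gamma(x) = 0 by uniroot
# on log-composition, refined to a tiny residual tolerance.
oracle_sle_root <- function(ln_x_ideal, ln_gamma_fn) {
  g <- function(l) l - ln_x_ideal + ln_gamma_fn(exp(l))
  lo <- log(1e-12)
  if (g(lo) > 0) stop("no bracket: solubility below floor")
  r <- uniroot(g, c(lo, 0), tol = 1e-15)
  exp(r$root)
}

# Random multi-segment molecule with total segment number bounded away
# from zero.
random_segment_vector <- function() {
  v <- runif(4, 0, 2.5)
  v[runif(4) < 0.3] <- 0
  if (sum(v) < 0.2) v[sample(4, 1)] <- runif(1, 0.5, 2.5)
  segment_vector(x = v[1], y_minus = v[2], y_plus = v[3], z = v[4])
}

# Binary mixture tibble from two segment vectors and a solute fraction.
binary_mixture <- function(vec1, vec2, x1) {
  tibble::tibble(
    mole_frac = c(x1, 1 - x1),
    x = c(vec1[["x"]], vec2[["x"]]),
    y_minus = c(vec1[["y_minus"]], vec2[["y_minus"]]),
    y_plus = c(vec1[["y_plus"]], vec2[["y_plus"]]),
    z = c(vec1[["z"]], vec2[["z"]])
  )
}

# Table of constants for the five parameterized segment pairs, used to drive
# pairwise oracle comparisons.
segment_pair_constants <- function() {
  tibble::tibble(
    seg_1 = c("x", "x", "y_minus", "y_plus", "x"),
    seg_2 = c("y_minus", "z", "z", "z", "y_plus"),
    tau_12 = c(1.643, 6.547, -2.000, 2.000, 1.643),
    tau_21 = c(1.834, 10.949, 1.787, 1.787, 1.834),
    alpha = c(0.2, 0.2, 0.3, 0.3, 0.2)
  )
}

# Single-segment molecule helper.
unit_segment <- function(name) {
  v <- setNames(numeric(4), c("x", "y_minus", "y_plus", "z"))
  v[name] <- 1
  segment_vector(x = v[["x"]], y_minus = v[["y_minus"]],
                 y_plus = v[["y_plus"]], z = v[["z"]])
}
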