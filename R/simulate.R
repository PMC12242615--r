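#' Synthetic solvent library
#'
#' Builds a named library of synthetic solvent segment vectors spanning the
#' four segment characters — one predominantly hydrophilic (X), one
#' polar-attractive (Y-), one polar-repulsive (Y+), and one hydrophobic (Z)
#' profile — mirroring the rationale of a minimal screening panel whose
#' solvents jointly cover the polar, hydrophobic and hydrophilic segment
#' space. For `n > 4`, additional solvents are seeded random blends of the
#' base profiles. All values lie in \[0, 5\].
#'
#' @param n Number of solvents (default 4).
#' @param seed Integer seed (only consumed when `n > 4`).
#' @return Tibble with columns `solvent`, `x`, `y_minus`, `y_plus`, `z`.
#' @examples
#' make_solvent_library()
#' @export
make_solvent_library <- function(n = 4, seed = 1L) {
  stopifnot(n >= 1)
  base <- tibble(
    solvent = c("hydrophilic_s1", "polar_attractive_s2",
                "polar_repulsive_s3", "hydrophobic_s4"),
    x       = c(1.0, 0.0, 0.0, 0.0),
    y_minus = c(0.2, 1.2, 0.0, 0.0),
    y_plus  = c(0.0, 0.0, 1.0, 0.0),
    z       = c(0.0, 0.4, 0.5, 2.0)
  )
  if (n <= 4) return(base[seq_len(n), ])
  extra <- with_seed(seed, {
    purrr::map(seq_len(n - 4L), function(i) {
      w <- runif(4)
      v <- colSums(w / sum(w) * as.matrix(base[, SEGMENTS])) * runif(1, 0.5, 1.5)
      tibble(solvent = sprintf("blend_s%d", i + 4L),
             x = v[[1]], y_minus = v[[2]], y_plus = v[[3]], z = v[[4]])
    })
  })
  dplyr::bind_rows(base, extra)
}

#' Default generating parameters for simulations
#'
#' A mid-box solute: moderately hydrophilic with a dominant hydrophobic
#' segment, enthalpy of fusion 42 kJ/mol and melting temperature 415 K —
#' values typical of small-molecule pharmaceutical intermediates.
#'
#' @return Named numeric vector over `x`, `y_minus`, `y_plus`, `z`,
#'   `dh_fus` (kJ/mol), `t_mp` (K).
#' @export
default_theta_true <- function() {
  c(x = 0.8, y_minus = 0.2, y_plus = 0.1, z = 1.5, dh_fus = 42, t_mp = 415)
}

#' Simulate a solubility screening dataset
#'
#' Generates measured-looking saturation mole fractions with the structure
#' of a small screening study: each solvent of a library measured at each
#' temperature of a short list (default 293.15/303.15/313.15 K, i.e. 12
#' records for the default 4-solvent panel). Noiseless truths come from the
#' solid-liquid-equilibrium solver at `theta_true`; multiplicative lognormal
#' noise \eqn{x^{exp} = x^{true} e^\varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)} reflects that solubilities span
#' orders of magnitude. Optionally one solvent is marked as degrading the
#' solute: its values receive a systematic negative bias and are flagged
#' `exclude = 1`, emulating a measurement the formal analysis must drop.
#'
#' @param theta_true Named generating parameter vector (see
#'   [default_theta_true()]).
#' @param solvent_library Solvent segment library (see
#'   [make_solvent_library()]).
#' @param temperatures Temperatures in K; all must lie below
#'   `theta_true["t_mp"]`.
#' @param sigma Lognormal noise scale (sd of \eqn{\ln x} residuals);
#'   `sigma = 0` gives exact model values.
#' @param degrading_solvent Optional solvent name to bias and flag.
#' @param degrading_bias Multiplicative bias for the degrading solvent
#'   (default 0.5: measured values half the true solubility).
#' @param seed Integer RNG seed; the dataset is fully reproducible.
#' @param interactions Interaction table.
#' @param solute Solute label carried in the output.
#' @return Tibble with columns `solute`, `solvent`, `t_k`, `x_exp`,
#'   `exclude`, `x_true`; attributes `theta_true`, `sigma`, `seed`.
#' @examples
#' sim <- simulate_solubility(sigma = 0.05, seed = 42)
#' nrow(sim)  # 12
#' @export
simulate_solubility <- function(theta_true = default_theta_true(),
                                solvent_library = make_solvent_library(),
                                temperatures = c(293.15, 303.15, 313.15),
                                sigma = 0.05,
                                degrading_solvent = NULL,
                                degrading_bias = 0.5,
                                seed = 1L,
                                interactions = nrtl_interactions(),
                                solute = "synthetic_solute") {
  theta_true <- theta_true[PARAMS]
  if (anyNA(theta_true)) abort("theta_true must name x, y_minus, y_plus, z, dh_fus, t_mp")
  if (sigma < 0) abort("sigma must be >= 0")
  lib <- validate_solvent_library(solvent_library)
  if (nrow(lib) == 0L) abort("solvent library is empty")
  if (any(temperatures >= theta_true[["t_mp"]])) {
    abort("all temperatures must lie below the generating melting temperature")
  }
  if (!is.null(degrading_solvent) && !degrading_solvent %in% lib$solvent) {
    abort(sprintf("degrading solvent '%s' not in library", degrading_solvent))
  }

  truth <- predict_solubility(lib, theta_true[SEGMENTS],
                              dh_fus = theta_true[["dh_fus"]],
                              t_mp = theta_true[["t_mp"]],
                              temperatures = temperatures,
                              interactions = interactions)
  if (any(!truth$converged)) {
    abort("noiseless saturation solve failed for some design points; check theta_true")
  }

  eps <- with_seed(seed, rnorm(nrow(truth), mean = 0, sd = sigma))
  x_exp <- truth$x_sat * exp(eps)
  exclude <- rep(0L, nrow(truth))
  if (!is.null(degrading_solvent)) {
    hit <- truth$solvent == degrading_solvent
    x_exp[hit] <- x_exp[hit] * degrading_bias
    exclude[hit] <- 1L
  }

  out <- tibble(solute = solute, solvent = truth$solvent, t_k = truth$t_k,
                x_exp = x_exp, exclude = exclude, x_true = truth$x_sat)
  attr(out, "theta_true") <- theta_true
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- as.integer(seed)
  out
}
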