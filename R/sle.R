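#' Ideal (van't Hoff) log-solubility
#'
#' The ideal-solution term of the simplified solid-liquid-equilibrium
#' relation, \eqn{\ln x = (\Delta H_{fus}/R)(1/T_{mp} - 1/T)}, obtained by
#' neglecting the sensible-heat (\eqn{\Delta C_p}) contributions. At the
#' melting temperature it is exactly zero (x = 1); below it, negative and
#' increasing in T.
#'
#' @param dh_fus Enthalpy of fusion in kJ/mol (converted to J/mol
#'   internally; R = 8.314 J/mol/K).
#' @param t_mp Melting temperature in K.
#' @param temperature Temperature(s) in K; vectorized.
#' @return \eqn{\ln x} of the ideal saturation mole fraction.
#' @examples
#' exp(ideal_log_solubility(34.920, 405.40, 293.15))  # ~0.019
#' @export
ideal_log_solubility <- function(dh_fus, t_mp, temperature) {
  if (any(temperature <= 0)) abort("temperature must be positive (K)")
  if (t_mp <= 0) abort("melting temperature must be positive (K)")
  if (dh_fus <= 0) abort("enthalpy of fusion must be positive (kJ/mol)")
  (dh_fus * 1000 / R_GAS) * (1 / t_mp - 1 / temperature)
}

#' Saturation mole fraction at solid-liquid equilibrium
#'
#' Solves \eqn{\ln x_{sat} = \ln x_{ideal} - \ln\gamma_{sat}(x_{sat})} for a
#' binary solute/solvent system. Because the activity coefficient depends on
#' the saturation composition, the relation is a fixed-point problem; it is
#' solved by damped successive substitution started at the ideal solubility,
#' with a bisection fallback on the residual when substitution does not
#' contract. Solutions are confined to mole fractions in (1e-12, 1].
#'
#' @param solute,solvent Segment vectors (see [segment_vector()]) or one-row
#'   data frames with segment columns.
#' @param dh_fus Enthalpy of fusion, kJ/mol.
#' @param t_mp Melting temperature, K. Temperatures above `t_mp` are out of
#'   domain (no solid phase) and raise an error.
#' @param temperature Temperature in K (scalar).
#' @param interactions Interaction table from [nrtl_interactions()].
#' @param tol Convergence tolerance on the log-space residual
#'   \eqn{|\ln x - \ln x_{ideal} + \ln\gamma(x)|}.
#' @param max_iter Maximum substitution iterations before the bisection
#'   fallback.
#' @return One-row tibble: `t_k`, `x_sat`, `gamma_sat`, `ln_gamma`,
#'   `converged`, `iterations`.
#' @examples
#' s <- segment_vector(z = 2)
#' solve_saturation(s, s, dh_fus = 30, t_mp = 400, temperature = 300)
#' @export
solve_saturation <- function(solute, solvent, dh_fus, t_mp, temperature,
                             interactions = nrtl_interactions(),
                             tol = 1e-10, max_iter = 500) {
  solute <- coerce_segments(solute, "solute")
  solvent <- coerce_segments(solvent, "solvent")
  tbl <- as_interactions(interactions)
  stopifnot(length(temperature) == 1L)
  lnx_ideal <- ideal_log_solubility(dh_fus, t_mp, temperature)
  if (lnx_ideal > 0) {
    abort(sprintf("T = %.2f K exceeds the melting temperature (%.2f K): no solid phase",
                  temperature, t_mp))
  }
  sol <- .cpp_solve_saturation(solute, solvent, lnx_ideal, tbl$tau, tbl$G,
                               tol, max_iter)
  tibble(t_k = temperature, x_sat = sol[1], gamma_sat = exp(sol[2]),
         ln_gamma = sol[2], converged = sol[3] > 0.5, iterations = as.integer(sol[4]))
}

#' Predict solubility curves over solvents and temperatures
#'
#' Evaluates [solve_saturation()] on the cartesian grid of a solvent library
#' and a temperature list, preserving input order. Per-point solver failures
#' are recorded in the `converged` column rather than raised.
#'
#' @param solvent_library Data frame with a `solvent` name column and segment
#'   columns `x`, `y_minus`, `y_plus`, `z` (see [read_solvent_library()] or
#'   [make_solvent_library()]).
#' @inheritParams solve_saturation
#' @param temperatures Temperatures in K (default: the 293.15/303.15/313.15 K
#'   screening design).
#' @return Tibble with one row per solvent x temperature: `solvent`, `t_k`,
#'   `x_sat`, `gamma_sat`, `converged`, `iterations`.
#' @export
predict_solubility <- function(solvent_library, solute, dh_fus, t_mp,
                               temperatures = c(293.15, 303.15, 313.15),
                               interactions = nrtl_interactions(),
                               tol = 1e-10, max_iter = 500) {
  lib <- validate_solvent_library(solvent_library)
  solute <- coerce_segments(solute, "solute")
  if (nrow(lib) == 0L || length(temperatures) == 0L) {
    return(tibble(solvent = character(), t_k = double(), x_sat = double(),
                  gamma_sat = double(), converged = logical(),
                  iterations = integer()))
  }
  grid <- tidyr::expand_grid(solvent = lib$solvent, t_k = temperatures)
  res <- purrr::pmap(grid, function(solvent, t_k) {
    sv <- unlist(lib[lib$solvent == solvent, SEGMENTS])
    out <- tryCatch(
      solve_saturation(solute, sv, dh_fus, t_mp, t_k, interactions,
                       tol = tol, max_iter = max_iter),
      error = function(e) tibble(t_k = t_k, x_sat = NA_real_,
                                 gamma_sat = NA_real_, ln_gamma = NA_real_,
                                 converged = FALSE, iterations = 0L)
    )
    out$solvent <- solvent
    out
  })
  dplyr::bind_rows(res)[, c("solvent", "t_k", "x_sat", "gamma_sat",
                            "converged", "iterations")]
}

#' Generic fixed-point solver for the SLE relation
#'
#' Solves \eqn{\ln x = \ln x_{ideal} - \ln\gamma(x)} for an arbitrary
#' composition-dependent activity model supplied as a function; the same
#' iteration the NRTL-SAC path uses, exposed so alternative activity models
#' can be plugged in and the solver behavior inspected.
#'
#' @param ln_x_ideal Ideal log-solubility (must be <= 0).
#' @param ln_gamma_fn Function of the solute mole fraction returning
#'   \eqn{\ln\gamma}.
#' @param tol,max_iter,damping Iteration controls.
#' @return List with `x_sat`, `ln_gamma`, `converged`, `iterations`.
#' @export
sle_fixed_point <- function(ln_x_ideal, ln_gamma_fn, tol = 1e-10,
                            max_iter = 500, damping = 0.5) {
  if (ln_x_ideal > 0) abort("ln_x_ideal must be <= 0 (solid phase present)")
  lnlo <- log(1e-12); lnhi <- 0
  lnx <- max(min(ln_x_ideal, lnhi), lnlo)
  it <- 0L; ok <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    target <- ln_x_ideal - ln_gamma_fn(exp(lnx))
    if (abs(lnx - target) <= tol) { ok <- TRUE; break }
    lnx <- max(min(lnx + damping * (target - lnx), lnhi), lnlo)
  }
  if (!ok) {
    g <- function(l) l - ln_x_ideal + ln_gamma_fn(exp(l))
    a <- lnlo; b <- lnhi; ga <- g(a); gb <- g(b)
    if (ga * gb <= 0) {
      for (k in 1:300) {
        m <- (a + b) / 2; gm <- g(m); it <- it + 1L
        if (abs(gm) <= tol) { lnx <- m; ok <- TRUE; break }
        if (ga * gm <= 0) { b <- m; gb <- gm } else { a <- m; ga <- gm }
      }
    }
  }
  list(x_sat = exp(lnx), ln_gamma = ln_gamma_fn(exp(lnx)),
       converged = ok, iterations = it)
}

coerce_segments <- function(v, what) {
  if (is.data.frame(v)) {
    stopifnot(nrow(v) == 1L)
    v <- unlist(v[, SEGMENTS])
  }
  if (is.null(names(v)) && length(v) == 4L) names(v) <- SEGMENTS
  v <- v[SEGMENTS]
  validate_segment_vector(v, what)
  if (sum(v) <= 0) abort(sprintf("%s has zero total segment number", what))
  v
}

validate_solvent_library <- function(lib) {
  if (!is.data.frame(lib)) abort("solvent library must be a data frame")
  missing <- setdiff(c("solvent", SEGMENTS), names(lib))
  if (length(missing)) {
    abort(paste0("solvent library is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(lib$solvent)) abort("duplicate solvent names in library")
  for (i in seq_len(nrow(lib))) {
    coerce_segments(unlist(lib[i, SEGMENTS]), paste0("solvent '", lib$solvent[i], "'"))
  }
  as_tibble(lib)
}
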