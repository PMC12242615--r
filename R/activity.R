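#' Activity coefficients of a mixture
#'
#' Evaluates the NRTL-SAC activity coefficient of every component of a liquid
#' mixture as the sum of a residual (local-composition) part and a
#' Flory-Huggins combinatorial part,
#' \eqn{\ln\gamma_I = \ln\gamma_I^R + \ln\gamma_I^C}.
#'
#' The residual part weighs the segment-level activity coefficients
#' \eqn{\Gamma_m} evaluated at the mixture's segment fractions against the
#' same quantity at the pure component's own segment composition; the
#' combinatorial part accounts for molecular size differences through the
#' segment-number-weighted volume fractions. Both vanish identically for a
#' pure component and for mixtures of molecules with identical segment
#' vectors.
#'
#' @param mixture Data frame with one row per component: `mole_frac` plus
#'   segment columns `x`, `y_minus`, `y_plus`, `z`. Other columns (e.g. a
#'   `component` name) are carried through.
#' @param interactions An interaction table from [nrtl_interactions()].
#' @return The input tibble with columns `ln_gamma_residual`,
#'   `ln_gamma_combinatorial`, `ln_gamma` appended.
#' @examples
#' mix <- tibble::tibble(component = c("solute", "solvent"),
#'                       mole_frac = c(0.1, 0.9),
#'                       x = c(0.5, 0), y_minus = c(0.1, 0),
#'                       y_plus = 0, z = c(1.5, 2))
#' activity_coefficients(mix)
#' @export
activity_coefficients <- function(mixture, interactions = nrtl_interactions()) {
  m <- as_mixture(mixture)
  tbl <- as_interactions(interactions)
  lg <- .cpp_lngamma_components(m$R, m$x, tbl$tau, tbl$G)
  out <- as_tibble(mixture)
  out$ln_gamma_residual <- lg[, 1]
  out$ln_gamma_combinatorial <- lg[, 2]
  out$ln_gamma <- lg[, 3]
  out
}

#' Residual part of the activity coefficient
#'
#' @inheritParams activity_coefficients
#' @param index Component row to return (default: all components).
#' @return Numeric vector of \eqn{\ln\gamma^R} values.
#' @export
residual_lngamma <- function(mixture, interactions = nrtl_interactions(),
                             index = NULL) {
  m <- as_mixture(mixture)
  tbl <- as_interactions(interactions)
  v <- .cpp_lngamma_components(m$R, m$x, tbl$tau, tbl$G)[, 1]
  if (is.null(index)) v else v[index]
}

#' Flory-Huggins combinatorial part of the activity coefficient
#'
#' Uses volume fractions \eqn{\varphi_I = r_I x_I / \sum_J r_J x_J}; at
#' \eqn{x_I = 0} the ratio \eqn{\varphi_I/x_I} is evaluated analytically as
#' \eqn{r_I / \sum_J r_J x_J}.
#'
#' @inheritParams residual_lngamma
#' @return Numeric vector of \eqn{\ln\gamma^C} values.
#' @export
combinatorial_lngamma <- function(mixture, index = NULL) {
  m <- as_mixture(mixture)
  tbl <- nrtl_interactions()
  v <- .cpp_lngamma_components(m$R, m$x, tbl$tau, tbl$G)[, 2]
  if (is.null(index)) v else v[index]
}

#' Total ln(activity coefficient)
#'
#' @inheritParams residual_lngamma
#' @return Numeric vector of \eqn{\ln\gamma = \ln\gamma^R + \ln\gamma^C}.
#' @export
lngamma <- function(mixture, interactions = nrtl_interactions(), index = NULL) {
  m <- as_mixture(mixture)
  tbl <- as_interactions(interactions)
  v <- .cpp_lngamma_components(m$R, m$x, tbl$tau, tbl$G)[, 3]
  if (is.null(index)) v else v[index]
}

# fast path used by the SLE solver: ln gamma of the solute in a binary
# solute/solvent mixture at solute mole fraction x
lngamma_binary_solute <- function(x, solute, solvent, interactions) {
  .cpp_lngamma_binary(x, as.numeric(solute[SEGMENTS]),
                      as.numeric(solvent[SEGMENTS]),
                      interactions$tau, interactions$G)
}
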