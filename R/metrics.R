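#' Half sum-of-squared-error fit metric
#'
#' \eqn{SSE = \tfrac{1}{2}\sum (x^{expt} - x^{model})^2} over paired
#' observed/modeled saturation mole fractions; the objective minimized by the
#' parameter-estimation procedure.
#'
#' @param x_obs,x_model Numeric vectors of equal length.
#' @param log_residuals If `TRUE`, residuals are taken on \eqn{\ln x}
#'   instead of mole fractions (an extension; the default matches the
#'   estimation objective).
#' @return A single non-negative number.
#' @examples
#' solubility_sse(c(0.03, 0.05), c(0.02, 0.03))  # 0.5 * (1e-4 + 4e-4)
#' @export
solubility_sse <- function(x_obs, x_model, log_residuals = FALSE) {
  stopifnot(length(x_obs) == length(x_model))
  r <- if (log_residuals) log(x_obs) - log(x_model) else x_obs - x_model
  0.5 * sum(r^2)
}

#' Root-mean-square log error
#'
#' \eqn{RMSLE = \sqrt{\frac{1}{N}\sum (\ln x^{expt} - \ln x^{model})^2}}; a
#' scale-free metric (multiplying all solubilities by a common factor leaves
#' it unchanged) suited to data spanning orders of magnitude.
#'
#' @param x_obs,x_model Positive numeric vectors of equal length.
#' @return A single non-negative number.
#' @examples
#' solubility_rmsle(c(0.01, 0.04), c(0.02, 0.02))  # log2(): ln 2
#' @export
solubility_rmsle <- function(x_obs, x_model) {
  stopifnot(length(x_obs) == length(x_model))
  if (any(x_obs <= 0) || any(x_model <= 0)) {
    abort("RMSLE requires strictly positive solubilities")
  }
  sqrt(mean((log(x_obs) - log(x_model))^2))
}

#' RMSLE with and without excluded records
#'
#' Datasets may flag records as excluded from formal metrics (e.g. a
#' solute/solvent pair where the compound degrades during measurement).
#' Returns the RMSLE over all records and over the non-excluded subset —
#' the plain and bracketed reporting styles.
#'
#' @param data Solubility data frame with columns `x_exp` and (optionally)
#'   `exclude` (0/1 or logical).
#' @param x_model Modeled saturation mole fractions aligned with `data` rows.
#' @return One-row tibble with `rmsle_all` and `rmsle_excluding_flagged`.
#' @export
rmsle_metrics <- function(data, x_model) {
  stopifnot(nrow(data) == length(x_model))
  excl <- dataset_exclude_flags(data)
  keep <- !excl
  tibble(
    rmsle_all = solubility_rmsle(data$x_exp, x_model),
    rmsle_excluding_flagged =
      if (any(keep)) solubility_rmsle(data$x_exp[keep], x_model[keep]) else NA_real_
  )
}

dataset_exclude_flags <- function(data) {
  if (!"exclude" %in% names(data)) return(rep(FALSE, nrow(data)))
  as.logical(data$exclude)
}
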