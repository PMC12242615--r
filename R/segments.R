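#' Conceptual segment vectors
#'
#' NRTL-SAC describes each molecule by four non-negative conceptual segment
#' numbers: hydrophilic `x` (X), polar-attractive `y_minus` (Y-),
#' polar-repulsive `y_plus` (Y+), and hydrophobic `z` (Z). `segment_vector()`
#' builds a validated named numeric vector in the canonical (X, Y-, Y+, Z)
#' order; unspecified segments default to zero.
#'
#' @param x,y_minus,y_plus,z Non-negative segment numbers (dimensionless).
#' @return Named numeric vector of length four in canonical order.
#' @examples
#' segment_vector(z = 3.477)              # a purely hydrophobic solute
#' segment_vector(x = 0.488, y_minus = 0.076)
#' @export
segment_vector <- function(x = 0, y_minus = 0, y_plus = 0, z = 0) {
  v <- c(x = x, y_minus = y_minus, y_plus = y_plus, z = z)
  validate_segment_vector(v)
  v
}

validate_segment_vector <- function(v, what = "segment vector") {
  if (!is.numeric(v) || length(v) != 4L) {
    abort(sprintf("%s must be numeric of length 4 (X, Y-, Y+, Z)", what))
  }
  if (anyNA(v) || any(!is.finite(v))) {
    abort(sprintf("%s contains non-finite values", what))
  }
  if (any(v < 0)) abort(sprintf("%s has negative segment numbers", what))
  invisible(v)
}

# total segment number r_I; molecules used in mixtures must have r_I > 0
total_segments <- function(v) sum(v)

#' Segment-level mole fractions of a mixture
#'
#' Converts component mole fractions into segment fractions: the fraction of
#' all conceptual segments in the liquid that are of each type,
#' \eqn{x_j = \sum_J x_J r_{j,J} / \sum_I x_I r_I}.
#'
#' @param mixture A data frame with one row per component: a mole-fraction
#'   column `mole_frac` plus segment columns `x`, `y_minus`, `y_plus`, `z`.
#' @return A tibble with columns `segment` and `fraction`; fractions sum to 1.
#' @examples
#' mix <- tibble::tibble(mole_frac = c(0.25, 0.75),
#'                       x = c(1, 0), y_minus = 0, y_plus = 0, z = c(0, 3))
#' segment_fractions(mix)
#' @export
segment_fractions <- function(mixture) {
  m <- as_mixture(mixture)
  num <- colSums(m$x * m$R)
  tot <- sum(num)
  if (tot <= 0) abort("degenerate mixture: total segment number is zero")
  tibble(segment = SEGMENTS, fraction = unname(num / tot))
}

#' Segment fractions of a single pure molecule
#'
#' \eqn{x_{j,I} = r_{j,I} / r_I}: the composition of one molecule expressed in
#' segment space, used as the reference state of the residual term.
#'
#' @param mol A segment vector (see [segment_vector()]) or a one-row data
#'   frame with segment columns.
#' @return A tibble with columns `segment` and `fraction` summing to 1.
#' @export
pure_component_segment_fractions <- function(mol) {
  if (is.data.frame(mol)) {
    stopifnot(nrow(mol) == 1L)
    mol <- unlist(mol[, SEGMENTS])
  }
  validate_segment_vector(mol, "molecule")
  r <- total_segments(mol)
  if (r <= 0) abort("molecule has zero total segment number")
  tibble(segment = SEGMENTS, fraction = unname(mol[SEGMENTS] / r))
}

# ---- internal mixture representation -----------------------------------

# Accepts a tibble with mole_frac + segment columns; returns list(R = n x 4
# matrix in canonical order, x = mole fractions).
as_mixture <- function(mixture) {
  if (!is.data.frame(mixture)) abort("mixture must be a data frame")
  missing <- setdiff(c("mole_frac", SEGMENTS), names(mixture))
  if (length(missing)) {
    abort(paste0("mixture is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(mixture) < 1L) abort("mixture must have at least one component")
  x <- mixture$mole_frac
  if (any(x < 0) || anyNA(x)) abort("mole fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-12) abort("mole fractions must sum to 1 (within 1e-12)")
  R <- as.matrix(mixture[, SEGMENTS])
  storage.mode(R) <- "double"
  apply(R, 1L, validate_segment_vector)
  if (any(rowSums(R) <= 0)) abort("every component must have at least one segment")
  list(R = R, x = as.numeric(x))
}
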