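#' Segment-segment NRTL interaction constants
#'
#' Builds the temperature-independent binary interaction table of the
#' NRTL-SAC model: asymmetric energy parameters \eqn{\tau_{ij}} and symmetric
#' nonrandomness factors \eqn{\alpha_{ij}} for the five allowed segment pairs
#' (X/Y-, X/Z, Y-/Z, Y+/Z, X/Y+), with \eqn{G_{ij} = \exp(-\alpha_{ij}
#' \tau_{ij})}. Pairs the model does not parameterize (Y-/Y+ and the
#' diagonal) get \eqn{\tau = 0}, \eqn{G = 1}. Defaults are the published
#' reference constants of the model; `pairs` lets advanced users override
#' individual pairs.
#'
#' @param pairs Optional data frame of overrides with columns `seg_1`,
#'   `seg_2`, `tau_12`, `tau_21`, `alpha` using segment names
#'   `"x"`, `"y_minus"`, `"y_plus"`, `"z"`.
#' @return An object of class `nrtl_interactions`: a list with 4x4 matrices
#'   `tau`, `alpha`, `G` in canonical segment order, plus the tidy `pairs`
#'   table.
#' @examples
#' tbl <- nrtl_interactions()
#' tbl$tau["x", "z"]   # 6.547
#' @export
nrtl_interactions <- function(pairs = NULL) {
  base <- tibble(
    seg_1  = c("x",     "x",     "y_minus", "y_plus", "x"),
    seg_2  = c("y_minus", "z",   "z",       "z",      "y_plus"),
    tau_12 = c(1.643,  6.547,  -2.000,     2.000,    1.643),
    tau_21 = c(1.834, 10.949,   1.787,     1.787,    1.834),
    alpha  = c(0.200,  0.200,   0.300,     0.300,    0.200)
  )
  if (!is.null(pairs)) {
    need <- c("seg_1", "seg_2", "tau_12", "tau_21", "alpha")
    if (!all(need %in% names(pairs))) {
      abort("pair overrides need columns seg_1, seg_2, tau_12, tau_21, alpha")
    }
    pairs <- as_tibble(pairs[, need])
    bad <- !(pairs$seg_1 %in% SEGMENTS & pairs$seg_2 %in% SEGMENTS)
    if (any(bad)) abort("unknown segment name in pair overrides")
    for (i in seq_len(nrow(pairs))) {
      hit <- which((base$seg_1 == pairs$seg_1[i] & base$seg_2 == pairs$seg_2[i]) |
                   (base$seg_1 == pairs$seg_2[i] & base$seg_2 == pairs$seg_1[i]))
      if (length(hit)) base[hit, ] <- pairs[i, ] else base <- rbind(base, pairs[i, ])
    }
  }

  tau <- matrix(0, 4, 4, dimnames = list(SEGMENTS, SEGMENTS))
  alpha <- matrix(0, 4, 4, dimnames = list(SEGMENTS, SEGMENTS))
  for (i in seq_len(nrow(base))) {
    a <- base$seg_1[i]; b <- base$seg_2[i]
    tau[a, b] <- base$tau_12[i]
    tau[b, a] <- base$tau_21[i]
    alpha[a, b] <- alpha[b, a] <- base$alpha[i]
  }
  G <- exp(-alpha * tau)
  diag(G) <- 1
  structure(list(tau = tau, alpha = alpha, G = G, pairs = base),
            class = "nrtl_interactions")
}

#' @export
print.nrtl_interactions <- function(x, ...) {
  cat("NRTL-SAC segment interaction table (temperature-independent)\n")
  print(x$pairs)
  invisible(x)
}

as_interactions <- function(tbl) {
  if (is.null(tbl)) return(nrtl_interactions())
  if (!inherits(tbl, "nrtl_interactions")) {
    abort("`interactions` must be built with nrtl_interactions()")
  }
  tbl
}
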