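PARAMS <- c("x", "y_minus", "y_plus", "z", "dh_fus", "t_mp")

#' Parameter bounds for NRTL-SAC estimation
#'
#' The physically motivated box constraints applied during fitting: segment
#' numbers in \[0, 5\] (a molecule cannot have negatively many segments, and
#' published pharmaceutical values fall well below 5), enthalpy of fusion in
#' \[1, 1000\] kJ/mol, melting temperature in \[273.15, 500\] K.
#'
#' @return Tibble with columns `parameter`, `lower`, `upper`.
#' @export
nrtlsac_bounds <- function() {
  tibble(
    parameter = PARAMS,
    lower = c(0, 0, 0, 0, 1, 273.15),
    upper = c(5, 5, 5, 5, 1000, 500)
  )
}

#' Smooth box-constraint transform
#'
#' Maps an unconstrained vector onto a bounded box through
#' \eqn{\theta_i = lb_i + (ub_i - lb_i)\sin^2(u_i)}, so an unconstrained
#' simplex optimizer can search while every candidate stays within the
#' physical bounds. `bound_inverse()` is its inverse on \[lb, ub\] (bounds map
#' to the boundary preimages u = 0 and u = \eqn{\pi/2}).
#'
#' @param u,theta Numeric vectors.
#' @param lower,upper Bound vectors recycled to the same length.
#' @return Numeric vector of the same length.
#' @export
bound_transform <- function(u, lower, upper) {
  lower + (upper - lower) * sin(u)^2
}

#' @rdname bound_transform
#' @export
bound_inverse <- function(theta, lower, upper) {
  if (any(theta < lower - 1e-12) || any(theta > upper + 1e-12)) {
    abort("theta outside bounds has no preimage")
  }
  frac <- pmin(pmax((theta - lower) / (upper - lower), 0), 1)
  asin(sqrt(frac))
}

#' Random start points on the bounded parameter box
#'
#' Uniform, seeded draws over the box; the stream is prefix-stable, so the
#' first k of n starts coincide with a k-start sample under the same seed
#' (which makes the best objective monotone in the number of starts).
#'
#' @param n Number of start points.
#' @param bounds Tibble as returned by [nrtlsac_bounds()], possibly
#'   restricted to the free parameters.
#' @param seed Integer RNG seed.
#' @return Tibble with `n` rows and one column per parameter.
#' @export
sample_starts <- function(n, bounds = nrtlsac_bounds(), seed = 1L) {
  stopifnot(n >= 1)
  d <- nrow(bounds)
  draws <- with_seed(seed, runif(n * d))
  m <- matrix(draws, nrow = n, ncol = d, byrow = TRUE)
  m <- sweep(sweep(m, 2L, bounds$upper - bounds$lower, `*`),
             2L, bounds$lower, `+`)
  colnames(m) <- bounds$parameter
  as_tibble(m)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Sum-of-squares objective for a parameter vector
#'
#' Evaluates the estimation objective
#' \eqn{SSE = \tfrac{1}{2}\sum(x^{expt} - x^{model})^2}, with model
#' solubilities from the solid-liquid-equilibrium solver. Records whose SLE
#' solve does not converge (or where the candidate melting temperature falls
#' below the record's temperature) contribute a constant penalty so the
#' objective stays finite everywhere on the box.
#'
#' @param theta Named vector with entries `x`, `y_minus`, `y_plus`, `z`
#'   (segment numbers), `dh_fus` (kJ/mol), `t_mp` (K).
#' @param data Solubility data frame: columns `solvent`, `t_k`, `x_exp`,
#'   optional `exclude` (flagged records are skipped when
#'   `exclude_fit = TRUE`).
#' @param solvent_library Data frame with `solvent` + segment columns
#'   covering every solvent in `data`.
#' @param interactions Interaction table from [nrtl_interactions()].
#' @param penalty Contribution of a failed model point (default 1e6).
#' @param log_residuals Use residuals on \eqn{\ln x} instead of mole
#'   fractions (extension; default matches the printed objective).
#' @param exclude_fit Drop records flagged `exclude` from the objective.
#' @param tol,max_iter SLE solver controls.
#' @return A single non-negative number.
#' @export
sse_objective <- function(theta, data, solvent_library,
                          interactions = nrtl_interactions(),
                          penalty = 1e6, log_residuals = FALSE,
                          exclude_fit = TRUE, tol = 1e-10, max_iter = 500) {
  theta <- theta[PARAMS]
  if (anyNA(theta)) abort("theta must have entries x, y_minus, y_plus, z, dh_fus, t_mp")
  data <- validate_dataset(data)
  lib <- validate_solvent_library(solvent_library)
  unknown <- setdiff(unique(data$solvent), lib$solvent)
  if (length(unknown)) {
    abort(paste0("solvent(s) not in library: ", paste(unknown, collapse = ", ")))
  }
  if (exclude_fit) data <- data[!dataset_exclude_flags(data), , drop = FALSE]
  tbl <- as_interactions(interactions)
  solvR <- solvent_matrix(data$solvent, lib)
  .cpp_sse_objective(as.numeric(theta), solvR, data$t_k, data$x_exp,
                     tbl$tau, tbl$G, tol, max_iter, penalty, log_residuals)
}

solvent_matrix <- function(solvents, lib) {
  m <- as.matrix(lib[match(solvents, lib$solvent), SEGMENTS])
  storage.mode(m) <- "double"
  m
}

validate_dataset <- function(data) {
  if (!is.data.frame(data)) abort("data must be a data frame")
  missing <- setdiff(c("solvent", "t_k", "x_exp"), names(data))
  if (length(missing)) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data)) {
    if (any(!is.finite(data$t_k)) || any(data$t_k <= 0)) {
      abort("temperatures must be positive (K)")
    }
    bad <- which(!is.finite(data$x_exp) | data$x_exp <= 0 | data$x_exp > 1)
    if (length(bad)) {
      abort(sprintf("x_exp outside (0, 1] at row(s) %s",
                    paste(bad, collapse = ", ")))
    }
  }
  as_tibble(data)
}

#' Multistart NRTL-SAC parameter estimation
#'
#' Fits a solute's conceptual segment numbers and melting properties to a
#' small solubility dataset. The bounded, nonconvex objective (see
#' [sse_objective()]) is minimized by Nelder-Mead simplex searches launched
#' from many uniform random start points on the parameter box; box
#' constraints are imposed through the smooth [bound_transform()] so each
#' local search is unconstrained. Every local search restarts the simplex
#' from its own endpoint until the objective stops improving (guarding
#' against premature simplex collapse); the reported solution is the overall
#' minimum, ties broken by first occurrence, and the complete per-start
#' trace is retained for objective-landscape diagnostics.
#'
#' @inheritParams sse_objective
#' @param n_starts Number of random starts (default 1000).
#' @param seed Integer seed controlling the start sample.
#' @param fix Named list/vector of parameters to hold fixed (e.g.
#'   `fix = list(t_mp = 374.15)` when the melting temperature is known from
#'   calorimetry); the rest are estimated.
#' @param bounds Box constraints, see [nrtlsac_bounds()].
#' @param maxit Maximum simplex iterations per start.
#' @param reltol,abstol Simplex convergence tolerances (see
#'   [stats::optim()]).
#' @param starts Optional data frame of start points (one column per free
#'   parameter) overriding the random sample; `n_starts` is then ignored.
#' @param solute Optional solute name carried into reports.
#' @return An object of class `nrtlsac_fit`: best parameters, SSE, RMSLE
#'   (all records and excluding flagged ones), the per-start trace, fitted
#'   values, and the full configuration. Use [tidy()], [glance()],
#'   [augment()], [export_landscape()] and [autoplot()] on it.
#' @examples
#' \donttest{
#' lib <- make_solvent_library()
#' sim <- simulate_solubility(solvent_library = lib, sigma = 0, seed = 7)
#' fit <- nrtlsac_fit(sim, lib, n_starts = 25, seed = 7,
#'                    fix = list(t_mp = attr(sim, "theta_true")[["t_mp"]]))
#' glance(fit)
#' }
#' @export
nrtlsac_fit <- function(data, solvent_library, n_starts = 1000, seed = 1L,
                        fix = list(), bounds = nrtlsac_bounds(),
                        interactions = nrtl_interactions(),
                        penalty = 1e6, log_residuals = FALSE,
                        exclude_fit = TRUE, tol = 1e-10, max_iter = 500,
                        maxit = 2000, reltol = 1e-12, abstol = -Inf,
                        starts = NULL, solute = NULL) {
  data <- validate_dataset(data)
  lib <- validate_solvent_library(solvent_library)
  tbl <- as_interactions(interactions)
  unknown <- setdiff(unique(data$solvent), lib$solvent)
  if (length(unknown)) {
    abort(paste0("solvent(s) not in library: ", paste(unknown, collapse = ", ")))
  }
  if (is.null(solute) && "solute" %in% names(data)) solute <- data$solute[1]

  fix <- unlist(fix)
  if (length(fix) && !all(names(fix) %in% PARAMS)) {
    abort("fix names must be among: x, y_minus, y_plus, z, dh_fus, t_mp")
  }
  free <- setdiff(PARAMS, names(fix))
  if (!length(free)) abort("at least one parameter must be free")

  excl <- dataset_exclude_flags(data)
  fit_data <- if (exclude_fit) data[!excl, , drop = FALSE] else data
  if (nrow(fit_data) < 1L) abort("no records available to fit")
  if (nrow(fit_data) < length(free)) {
    warn(sprintf("only %d record(s) to fit %d free parameters; the fit is underdetermined",
                 nrow(fit_data), length(free)))
  }

  bnd <- bounds[match(PARAMS, bounds$parameter), ]
  free_idx <- match(free, PARAMS)
  lb <- bnd$lower[free_idx]; ub <- bnd$upper[free_idx]
  theta_full <- setNames(numeric(length(PARAMS)), PARAMS)
  theta_full[names(fix)] <- as.numeric(fix)

  solvR <- solvent_matrix(fit_data$solvent, lib)
  objective <- function(u) {
    theta_full[free_idx] <- bound_transform(u, lb, ub)
    .cpp_sse_objective(as.numeric(theta_full), solvR, fit_data$t_k,
                       fit_data$x_exp, tbl$tau, tbl$G, tol, max_iter,
                       penalty, log_residuals)
  }

  if (is.null(starts)) {
    starts <- sample_starts(n_starts, bnd[free_idx, ], seed = seed)
  } else {
    starts <- as_tibble(starts)[, free, drop = FALSE]
    n_starts <- nrow(starts)
  }
  ctrl <- list(maxit = maxit, reltol = reltol, abstol = abstol)

  # each local search restarts the simplex from its own endpoint until the
  # objective stops improving, so the final value is a deterministic function
  # of the start point alone (and the best-of-k-starts is monotone in k)
  local_search <- function(th0) {
    u <- bound_inverse(th0, lb, ub)
    best <- NULL
    fe <- 0L
    for (round in 1:6) {
      res <- optim(u, objective, method = "Nelder-Mead", control = ctrl)
      fe <- fe + unname(res$counts[1])
      if (!is.null(best) && res$value >= best$value - 1e-14) break
      best <- res
      u <- res$par
    }
    list(theta = bound_transform(best$par, lb, ub), sse = best$value,
         fevals = fe, converged = best$convergence == 0L)
  }

  runs <- purrr::map(seq_len(n_starts), function(i) {
    res <- tryCatch(local_search(as.numeric(starts[i, ])), error = function(e) NULL)
    if (is.null(res)) {
      return(list(theta = rep(NA_real_, length(free)), sse = NA_real_,
                  fevals = NA_integer_, converged = FALSE))
    }
    res
  })

  sse_vec <- purrr::map_dbl(runs, "sse")
  trace <- tibble(
    start = seq_len(n_starts),
    sse = sse_vec,
    fevals = purrr::map_int(runs, ~ as.integer(.x$fevals %||% NA_integer_)),
    converged = purrr::map_lgl(runs, "converged")
  )
  start_cols <- setNames(starts, paste0("start_", free))
  final_mat <- do.call(rbind, purrr::map(runs, "theta"))
  colnames(final_mat) <- free
  trace <- dplyr::bind_cols(trace, start_cols, as_tibble(final_mat))

  if (all(is.na(sse_vec))) {
    abort("all multistart runs failed", class = "nrtlsac_fit_error",
          fit_trace = trace)
  }

  best_i <- which.min(sse_vec)   # first occurrence on ties
  best_theta_free <- runs[[best_i]]$theta
  best_sse <- sse_vec[best_i]

  theta_full[free_idx] <- best_theta_free

  preds <- predict_dataset(theta_full, data, lib, tbl, tol, max_iter)
  fitted_ok <- preds$converged & !is.na(preds$x_sat)
  rm <- if (all(fitted_ok)) rmsle_metrics(data, preds$x_sat) else {
    tibble(rmsle_all = NA_real_, rmsle_excluding_flagged = NA_real_)
  }

  structure(list(
    parameters = theta_full,
    free = free,
    fixed = fix,
    sse = best_sse,
    rmsle = rm$rmsle_all,
    rmsle_excluding_flagged = rm$rmsle_excluding_flagged,
    trace = trace,
    data = dplyr::bind_cols(data, preds[, c("x_sat", "gamma_sat", "converged")]),
    bounds = bnd,
    seed = as.integer(seed),
    n_starts = as.integer(n_starts),
    control = c(ctrl, list(sle_tol = tol, sle_max_iter = max_iter,
                           penalty = penalty, log_residuals = log_residuals,
                           exclude_fit = exclude_fit)),
    solute = solute
  ), class = "nrtlsac_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# model predictions for every record of a dataset at a full parameter vector
predict_dataset <- function(theta, data, lib, tbl, tol = 1e-10, max_iter = 500) {
  solvR <- solvent_matrix(data$solvent, lib)
  rs <- as.numeric(theta[SEGMENTS])
  out <- purrr::map(seq_len(nrow(data)), function(i) {
    lnx_ideal <- ideal_log_solubility(theta[["dh_fus"]], theta[["t_mp"]], data$t_k[i])
    if (lnx_ideal > 0) {
      return(c(NA_real_, NA_real_, 0, 0))
    }
    .cpp_solve_saturation(rs, solvR[i, ], lnx_ideal, tbl$tau, tbl$G, tol, max_iter)
  })
  m <- do.call(rbind, out)
  tibble(x_sat = m[, 1], gamma_sat = exp(m[, 2]),
         converged = m[, 3] > 0.5, iterations = as.integer(m[, 4]))
}

#' Per-start objective landscape
#'
#' The final objective value reached from every start point, in start order;
#' the raw material of multistart landscape plots, whose banding reveals the
#' local-minimum structure induced by the bounds.
#'
#' @param fit A [nrtlsac_fit()] result.
#' @return Tibble with columns `start` and `sse` (one row per start).
#' @export
export_landscape <- function(fit) {
  stopifnot(inherits(fit, "nrtlsac_fit"))
  fit$trace[order(fit$trace$start), c("start", "sse")]
}

#' Count bands in a multistart objective landscape
#'
#' Clusters the final objective values on a log scale by splitting at gaps
#' wider than `gap` decades; distinct bands correspond to families of local
#' minima (and bound-induced plateaus).
#'
#' @param sse Numeric vector of final objective values, or a `nrtlsac_fit`.
#' @param gap Minimum log10 separation between bands (decades).
#' @return Integer number of bands.
#' @export
landscape_bands <- function(sse, gap = 1) {
  if (inherits(sse, "nrtlsac_fit")) sse <- sse$trace$sse
  sse <- sse[is.finite(sse)]
  if (!length(sse)) return(0L)
  v <- sort(log10(pmax(sse, 1e-300)))
  sum(diff(v) > gap) + 1L
}

# ---- methods -----------------------------------------------------------

#' @export
print.nrtlsac_fit <- function(x, ...) {
  cat("NRTL-SAC multistart fit",
      if (!is.null(x$solute)) paste0(" for ", x$solute), "\n", sep = "")
  cat(sprintf("  %d starts (seed %d), best SSE = %.4g\n",
              x$n_starts, x$seed, x$sse))
  cat(sprintf("  RMSLE = %.4g (excluding flagged: %.4g)\n",
              x$rmsle, x$rmsle_excluding_flagged))
  cat("  parameters:\n")
  p <- x$parameters
  cat(sprintf("    r_X=%.3f r_Y-=%.3f r_Y+=%.3f r_Z=%.3f dH_fus=%.3f kJ/mol T_mp=%.2f K\n",
              p[["x"]], p[["y_minus"]], p[["y_plus"]], p[["z"]],
              p[["dh_fus"]], p[["t_mp"]]))
  if (length(x$fixed)) {
    cat("  fixed: ", paste(names(x$fixed), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a multistart fit
#'
#' @param x A `nrtlsac_fit` object.
#' @param ... Unused.
#' @return One row per model parameter: `term`, `estimate`, `fixed`,
#'   `lower`, `upper`.
#' @export
tidy.nrtlsac_fit <- function(x, ...) {
  tibble(
    term = PARAMS,
    estimate = unname(x$parameters[PARAMS]),
    fixed = PARAMS %in% names(x$fixed),
    lower = x$bounds$lower,
    upper = x$bounds$upper
  )
}

#' Glance at a multistart fit
#'
#' @inheritParams tidy.nrtlsac_fit
#' @return One-row tibble with fit-level summaries.
#' @export
glance.nrtlsac_fit <- function(x, ...) {
  tibble(
    sse = x$sse,
    rmsle = x$rmsle,
    rmsle_excluding_flagged = x$rmsle_excluding_flagged,
    n_obs = nrow(x$data),
    n_starts = x$n_starts,
    n_converged_starts = sum(x$trace$converged, na.rm = TRUE),
    seed = x$seed
  )
}

#' Augment solubility data with fitted values
#'
#' @inheritParams tidy.nrtlsac_fit
#' @return The fit's dataset with `x_sat` (model), `gamma_sat`, `converged`
#'   and residual columns.
#' @export
augment.nrtlsac_fit <- function(x, ...) {
  out <- x$data
  out$.resid <- out$x_exp - out$x_sat
  out$.log_resid <- log(out$x_exp) - log(out$x_sat)
  out
}
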