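#' Read a solvent segment library
#'
#' Reads a YAML or JSON file mapping solvent names to their four conceptual
#' segment numbers. Accepted per-solvent keys are `x`, `y_minus`, `y_plus`,
#' `z` or the symbol spellings `X`, `Y-`, `Y+`, `Z`; omitted segments
#' default to 0, but at least one must be present and positive. Unknown
#' keys, negative values and duplicate names are rejected with the
#' offending field named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Tibble with columns `solvent`, `x`, `y_minus`, `y_plus`, `z`.
#' @export
read_solvent_library <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(raw)) abort("solvent library file is empty")
  if (is.null(names(raw)) || any(names(raw) == "")) {
    abort("solvent library must map solvent names to segment values")
  }
  if (anyDuplicated(names(raw))) {
    abort(sprintf("duplicate solvent name: %s",
                  names(raw)[duplicated(names(raw))][1]))
  }
  key_map <- c("x" = "x", "X" = "x",
               "y_minus" = "y_minus", "Y-" = "y_minus", "y-" = "y_minus",
               "y_plus" = "y_plus", "Y+" = "y_plus", "y+" = "y_plus",
               "z" = "z", "Z" = "z")
  rows <- purrr::imap(raw, function(entry, nm) {
    if (!is.list(entry) || is.null(names(entry))) {
      abort(sprintf("solvent '%s': expected a map of segment values", nm))
    }
    unknown <- setdiff(names(entry), names(key_map))
    if (length(unknown)) {
      abort(sprintf("solvent '%s': unknown segment key '%s'", nm, unknown[1]))
    }
    v <- setNames(numeric(4L), SEGMENTS)
    for (k in names(entry)) {
      val <- entry[[k]]
      if (is.null(val) || !is.numeric(val) || length(val) != 1L || is.na(val)) {
        abort(sprintf("solvent '%s': segment '%s' must be a number", nm, k))
      }
      if (val < 0) {
        abort(sprintf("solvent '%s': segment '%s' is negative", nm, k))
      }
      v[[key_map[[k]]]] <- val
    }
    if (sum(v) <= 0) {
      abort(sprintf("solvent '%s': all segment numbers are zero", nm))
    }
    tibble(solvent = nm, x = v[["x"]], y_minus = v[["y_minus"]],
           y_plus = v[["y_plus"]], z = v[["z"]])
  })
  validate_solvent_library(dplyr::bind_rows(rows))
}

#' Write a solvent segment library to YAML
#'
#' @param lib Solvent library tibble (columns `solvent` + segments).
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_solvent_library <- function(lib, path) {
  lib <- validate_solvent_library(lib)
  out <- setNames(
    purrr::map(seq_len(nrow(lib)), function(i) {
      as.list(lib[i, SEGMENTS])
    }),
    lib$solvent
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Read a solubility dataset CSV
#'
#' Expected columns: `solute`, `solvent`, `t_k` (Kelvin — no unit
#' auto-detection), `x_exp` (saturation mole fraction in (0, 1\]) and an
#' optional `exclude` 0/1 flag. Malformed numeric fields and out-of-range
#' values are reported with their row number. An empty file yields an empty
#' dataset with a warning.
#'
#' @param path Path to the CSV.
#' @return Tibble with the columns above (`exclude` filled with 0 when
#'   absent).
#' @export
read_solubility_data <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  )
  if (nrow(df) == 0L) {
    warn("solubility dataset is empty")
    return(tibble(solute = character(), solvent = character(),
                  t_k = double(), x_exp = double(), exclude = integer()))
  }
  missing <- setdiff(c("solute", "solvent", "t_k", "x_exp"), names(df))
  if (length(missing)) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  parse_num <- function(col, nm) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col) | is.na(col))
    if (length(bad)) {
      abort(sprintf("column '%s': malformed value at row %d", nm, bad[1]))
    }
    v
  }
  t_k <- parse_num(df$t_k, "t_k")
  x_exp <- parse_num(df$x_exp, "x_exp")
  bad_t <- which(t_k <= 0)
  if (length(bad_t)) {
    abort(sprintf("column 't_k': non-positive temperature at row %d", bad_t[1]))
  }
  bad_x <- which(x_exp <= 0 | x_exp > 1)
  if (length(bad_x)) {
    abort(sprintf("column 'x_exp': value outside (0, 1] at row %d", bad_x[1]))
  }
  exclude <- if ("exclude" %in% names(df)) {
    as.integer(parse_num(df$exclude, "exclude"))
  } else rep(0L, nrow(df))
  tibble(solute = df$solute, solvent = df$solvent, t_k = t_k,
         x_exp = x_exp, exclude = exclude)
}

#' Write a solubility dataset CSV
#'
#' @param data Dataset tibble (columns `solute`, `solvent`, `t_k`, `x_exp`,
#'   optional `exclude`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_solubility_data <- function(data, path) {
  data <- validate_dataset(data)
  cols <- intersect(c("solute", "solvent", "t_k", "x_exp", "exclude"),
                    names(data))
  readr::write_csv(data[, cols], path)
  invisible(path)
}

#' Write predicted solubility curves to CSV
#'
#' Tidy layout: one row per solvent/temperature with columns `solute`,
#' `solvent`, `t_k`, `x_sat_model`, `gamma_sat`, `converged`.
#'
#' @param predictions Output of [predict_solubility()].
#' @param path Output path.
#' @param solute Solute label for the `solute` column.
#' @return `path`, invisibly.
#' @export
write_prediction <- function(predictions, path, solute = "solute") {
  out <- tibble(solute = solute,
                solvent = predictions$solvent,
                t_k = predictions$t_k,
                x_sat_model = predictions$x_sat,
                gamma_sat = predictions$gamma_sat,
                converged = predictions$converged)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a fit report to JSON
#'
#' Serializes the fitted parameters (segment numbers, enthalpy of fusion,
#' melting temperature), objective and RMSLE values, and the estimation
#' configuration (seed, number of starts, bounds, solver settings) so a run
#' is fully documented and reloadable.
#'
#' @param fit A [nrtlsac_fit()] result.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "nrtlsac_fit"))
  p <- fit$parameters
  report <- list(
    solute = fit$solute,
    parameters = list(r_X = p[["x"]], r_Y_minus = p[["y_minus"]],
                      r_Y_plus = p[["y_plus"]], r_Z = p[["z"]],
                      dh_fusion_kj_mol = p[["dh_fus"]], t_mp_k = p[["t_mp"]]),
    fixed = as.list(fit$fixed),
    sse = fit$sse,
    rmsle = fit$rmsle,
    rmsle_excluding_flagged = fit$rmsle_excluding_flagged,
    seed = fit$seed,
    n_starts = fit$n_starts,
    bounds = list(lower = setNames(as.list(fit$bounds$lower), fit$bounds$parameter),
                  upper = setNames(as.list(fit$bounds$upper), fit$bounds$parameter)),
    solver = fit$control
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write the multistart landscape to CSV
#'
#' @param fit A [nrtlsac_fit()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(fit, path) {
  readr::write_csv(export_landscape(fit), path)
  invisible(path)
}
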