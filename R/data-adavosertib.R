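#' Published NRTL-SAC parameters for the Adavosertib-route compounds
#'
#' The fitted segment numbers, enthalpies of fusion, melting temperatures
#' (where estimated from solubility data; `NA` where the melting point was
#' instead measured by DSC) and fit metrics for the six organic compounds of
#' the Adavosertib (AZD1775) manufacturing route, as bundled in
#' `extdata/adavosertib_solutes.yaml`. `rmsle_excluding_flagged` is the
#' bracketed metric excluding the degrading n-BuOAc measurements of
#' compound 3.
#'
#' @return Tibble with one row per solute: `solute`, `name`, segment columns
#'   `x`, `y_minus`, `y_plus`, `z`, `dh_fus` (kJ/mol), `t_mp` (K or `NA`),
#'   `sse`, `rmsle`, `rmsle_excluding_flagged`.
#' @examples
#' adavosertib_parameters()
#' @export
adavosertib_parameters <- function() {
  path <- system.file("extdata", "adavosertib_solutes.yaml",
                      package = "nrtlsac", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  dplyr::bind_rows(purrr::imap(raw, function(e, id) {
    tibble(
      solute = id,
      name = e$name,
      x = e$x, y_minus = e$y_minus, y_plus = e$y_plus, z = e$z,
      dh_fus = e$dh_fus,
      t_mp = if (is.null(e$t_mp)) NA_real_ else e$t_mp,
      sse = e$sse,
      rmsle = e$rmsle,
      rmsle_excluding_flagged =
        if (is.null(e$rmsle_excluding_flagged)) NA_real_ else e$rmsle_excluding_flagged
    )
  }))
}

#' Thermophysical properties of the study compounds
#'
#' Identity and thermophysical data for the six solutes and four screening
#' solvents: molar mass, boiling point and melting point where available;
#' `t_mp_estimated` marks melting points obtained by in-house estimation
#' rather than literature measurement.
#'
#' @return Tibble with columns `species`, `name`, `cas`, `formula`,
#'   `molar_mass` (g/mol), `t_bp` (K), `t_mp` (K), `t_mp_estimated`.
#' @export
adavosertib_compounds <- function() {
  tibble(
    species = c("1", "2", "3", "4", "5", "6",
                "MeCN", "IPA", "n-BuOAc", "PhMe"),
    name = c("AZD1775 pyrimidine", "AZD1775 bromopyridine HBr",
             "AZD1775 hydroxymethylsulfanyl", "AZD1775 nitropip",
             "AZD1775 aniline maleate", "AZD1775 adavosertib maleate",
             "acetonitrile", "isopropyl alcohol", "n-butyl acetate",
             "toluene"),
    cas = c("955368-90-8", NA, "955369-56-9", "16155-03-6", NA, NA,
            "75-05-8", "67-63-0", "123-86-4", "108-88-3"),
    formula = c("C9H10N4OS", "C8H11Br2NO", "C17H19N5O2S", "C11H15N3O2",
                "C15H21N3O4", "C31H36N8O6",
                "C2H3N", "C3H8O", "C6H12O2", "C7H8"),
    molar_mass = c(222.27, 296.99, 357.43, 221.26, 307.35, 616.68,
                   41.05, 60.10, 116.16, 92.14),
    t_bp = c(671.05, NA, 838.75, 642.65, NA, NA,
             354.82, 355.93, 398.71, 384.26),
    t_mp = c(NA, NA, 374.15, 377.15, 390.15, 445.15,
             228.15, 184.82, 195.93, 178.15),
    t_mp_estimated = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, FALSE, FALSE, FALSE)
  )
}

#' Melting properties used for forward prediction
#'
#' Per-solute enthalpy of fusion and melting temperature, combining the
#' solubility-estimated melting points (compounds 1-2, where calorimetry is
#' confounded by reactions near the melting point) with the thermophysical
#' table values for the remaining compounds.
#'
#' @return Tibble with `solute`, `name`, `dh_fus` (kJ/mol), `t_mp` (K),
#'   `t_mp_source` (`"fitted"` or `"measured"`).
#' @export
adavosertib_thermo <- function() {
  pars <- adavosertib_parameters()
  comp <- adavosertib_compounds()
  t_meas <- comp$t_mp[match(sub("solute_", "", pars$solute), comp$species)]
  tibble(
    solute = pars$solute,
    name = pars$name,
    dh_fus = pars$dh_fus,
    t_mp = dplyr::coalesce(pars$t_mp, t_meas),
    t_mp_source = ifelse(is.na(pars$t_mp), "measured", "fitted")
  )
}
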