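#' Gibbs free energy from calorimetric components
#'
#' `dG = dH + (-T dS)`, composing the enthalpic and entropic contributions
#' as tabulated from isothermal titration calorimetry.
#'
#' @param dh Enthalpy change, kJ/mol.
#' @param minus_tds Entropic term `-T dS`, kJ/mol.
#' @return dG in kJ/mol. Vectorised.
#' @export
#' @examples
#' gibbs_from_components(-23.8, -2.0)  # -25.8
gibbs_from_components <- function(dh, minus_tds) {
  stopifnot(all(is.finite(dh)), all(is.finite(minus_tds)))
  dh + minus_tds
}

#' Gibbs free energy from a dissociation constant
#'
#' `dG = R T ln(Kd)` with `Kd` in molar units (1 M reference state).
#'
#' @param kd Dissociation constant, molar.
#' @param temperature Temperature, K (experiments at 20 C: 293.15 K).
#' @return dG in kJ/mol. Vectorised.
#' @export
#' @examples
#' gibbs_from_kd(26e-6)  # about -25.7 kJ/mol
gibbs_from_kd <- function(kd, temperature = 293.15) {
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    stop("Kd must be finite and positive (molar units)", call. = FALSE)
  }
  stopifnot(temperature > 0)
  .r_gas_kj * temperature * log(kd)
}

#' Zinc-binding thermodynamics of Hst5 and single-motif variants
#'
#' Dissociation constants, stoichiometries and thermodynamic components of
#' Zn2+ binding measured by isothermal titration calorimetry at 20 C for
#' wild-type Hst5 and the two single-motif variants.
#'
#' @return Tibble with columns `name`, `kd_um` (dissociation constant, uM),
#'   `kd_se`, `n` (stoichiometry), `dh` (kJ/mol), `minus_tds` (kJ/mol),
#'   `dg` (kJ/mol) and the stated uncertainties `dh_se`, `minus_tds_se`,
#'   `dg_se`, plus `temperature` (K).
#' @export
hst5_thermo <- function() {
  tibble::tibble(
    name = c("WT", "DZM", "ZM"),
    kd_um = c(26, 45, 61),
    kd_se = c(1, 9, 10),
    n = c(1.18, 0.89, 0.94),
    n_se = c(0.01, 0.06, 0.04),
    dh = c(-23.8, -3.1, -2.6),
    dh_se = c(0.3, 0.3, 0.2),
    minus_tds = c(-2.0, -21.3, -21.1),
    minus_tds_se = c(0.3, 0.5, 0.4),
    dg = c(-25.8, -24.4, -23.7),
    dg_se = c(0.1, 0.5, 0.4),
    temperature = 293.15
  )
}

#' Thermodynamic consistency of the binding table
#'
#' Recomputes `dG` two ways for each record: from the calorimetric
#' components (`dH + (-T dS)`) and from the dissociation constant
#' (`RT ln Kd`), alongside the tabulated value.
#'
#' @param tbl A tibble like [hst5_thermo()].
#' @return The table with added columns `dg_components`, `dg_kd`,
#'   `dev_components`, `dev_kd`.
#' @export
#' @examples
#' check_thermo_consistency()
check_thermo_consistency <- function(tbl = hst5_thermo()) {
  dplyr::mutate(
    tbl,
    dg_components = gibbs_from_components(.data$dh, .data$minus_tds),
    dg_kd = gibbs_from_kd(.data$kd_um * 1e-6, .data$temperature),
    dev_components = abs(.data$dg_components - .data$dg),
    dev_kd = abs(.data$dg_kd - .data$dg)
  )
}
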