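#' Substrate-limitation scenario
#'
#' Defines which substrates limit growth and the dimensionless harvest
#' products `V_h [OC]` and `V_h [O2]` (harvest volume times concentration).
#' Only the products matter for the rate law, so they are parameterized
#' directly; 1 corresponds to moderate and 0.2 to severe limitation in the
#' comparative analyses.
#'
#' @param limitation `"C"`, `"O2"`, or `"both"` (carbon and oxygen co-limited;
#'   `"C_and_O2"` is accepted as an alias).
#' @param vh_oc,vh_o2 Dimensionless harvest products for the active
#'   limitation(s); must be positive where used.
#' @return A list of class `sxm_scenario`.
#' @examples
#' scenario("C", vh_oc = 0.2)           # severe carbon limitation
#' scenario("both", vh_oc = 1, vh_o2 = 1)
#' @export
scenario <- function(limitation = c("both", "C", "O2"), vh_oc = NULL,
                     vh_o2 = NULL) {
  if (identical(limitation, "C_and_O2")) limitation <- "both"
  limitation <- match.arg(limitation)
  need_c <- limitation %in% c("C", "both")
  need_o <- limitation %in% c("O2", "both")
  if (need_c && (is.null(vh_oc) || !is.numeric(vh_oc) || vh_oc <= 0)) {
    stop_validation("vh_oc must be a positive number under %s limitation",
                    limitation)
  }
  if (need_o && (is.null(vh_o2) || !is.numeric(vh_o2) || vh_o2 <= 0)) {
    stop_validation("vh_o2 must be a positive number under %s limitation",
                    limitation)
  }
  structure(list(limitation = limitation, vh_oc = vh_oc, vh_o2 = vh_o2),
            class = "sxm_scenario")
}

# Vectorized rate law over absolute metabolic coefficients.
mu_kinetic <- function(abs_y_oc, abs_y_o2, sc, mu_max = 1) {
  mu <- rep(mu_max, length.out = max(length(abs_y_oc), length(abs_y_o2)))
  if (sc$limitation %in% c("C", "both")) mu <- mu * exp(-abs_y_oc / sc$vh_oc)
  if (sc$limitation %in% c("O2", "both")) mu <- mu * exp(-abs_y_o2 / sc$vh_o2)
  mu
}

#' Specific growth rate under substrate limitation
#'
#' Energy-harvest rate law: under carbon and oxygen co-limitation
#' `mu = mu_max exp(-|y_OC| / (V_h[OC])) exp(-|y_O2| / (V_h[O2]))`;
#' single-limitation scenarios drop the other factor. Larger metabolic
#' coefficients (more substrate needed per C-mol biomass) and smaller harvest
#' products both slow growth; `mu -> mu_max` as the harvest products grow
#' without bound.
#'
#' @param y_met Metabolic reaction vector (named, 10-species basis).
#' @param sc A [scenario()].
#' @param mu_max Maximal specific growth rate, 1/time; defaults to 1 for
#'   comparative analyses, which it does not affect.
#' @return Specific growth rate, 1/time.
#' @examples
#' ct <- compound_thermo(parse_formula("C6H12O6"))
#' growth_rate(ct$y_met, scenario("both", vh_oc = 1, vh_o2 = 1))
#' @export
growth_rate <- function(y_met, sc, mu_max = 1) {
  stopifnot(inherits(sc, "sxm_scenario"))
  if (!is.numeric(mu_max) || mu_max <= 0) {
    stop_validation("mu_max must be positive")
  }
  if (is.null(names(y_met))) names(y_met) <- SXM_SPECIES
  mu_kinetic(abs(y_met[["OC"]]), abs(y_met[["O2"]]), sc, mu_max)
}

#' Chemical consumption and production rates of one compound
#'
#' Each chemical rate is the metabolic coefficient times the growth rate:
#' `r_OC = y_OC mu`, `r_O2 = y_O2 mu`, `r_HCO3 = y_HCO3 mu`, and the carbon
#' consumption rate `r_C = a r_OC` where `a` is the compound's carbon count.
#' Consumption rates are negative, production rates positive; all are per
#' C-mol of biomass per unit time.
#'
#' @param y_met Metabolic reaction vector.
#' @param a Carbon count of the compound.
#' @param sc A [scenario()].
#' @param mu_max Maximal specific growth rate.
#' @return Named list: `mu`, `r_oc`, `r_c`, `r_o2`, `r_hco3`.
#' @export
rate_set <- function(y_met, a, sc, mu_max = 1) {
  if (is.null(names(y_met))) names(y_met) <- SXM_SPECIES
  mu <- growth_rate(y_met, sc, mu_max)
  r_oc <- y_met[["OC"]] * mu
  list(mu = mu, r_oc = r_oc, r_c = a * r_oc,
       r_o2 = y_met[["O2"]] * mu, r_hco3 = y_met[["HCO3"]] * mu)
}

#' Rates for every compound in a thermodynamic table
#'
#' Batch version of [rate_set()] over a [compound_thermo_table()] result.
#' Flagged compounds (non-oxidizable, endergonic catabolism, non-positive
#' lambda) get `NA` rates rather than being dropped, so row alignment with
#' the input is preserved.
#'
#' @param thermo Tibble from [compound_thermo_table()].
#' @param sc A [scenario()].
#' @param mu_max Maximal specific growth rate.
#' @return Tibble: `label`, `mu`, `r_oc`, `r_c`, `r_o2`, `r_hco3`, `flags`.
#' @export
rate_table <- function(thermo, sc, mu_max = 1) {
  stopifnot(is.data.frame(thermo),
            all(c("y_oc", "y_o2", "y_hco3", "C", "flags") %in% names(thermo)))
  mu <- mu_kinetic(abs(thermo$y_oc), abs(thermo$y_o2), sc, mu_max)
  mu[nzchar(thermo$flags)] <- NA_real_
  r_oc <- thermo$y_oc * mu
  tibble::tibble(label = thermo$label, mu = mu, r_oc = r_oc,
                 r_c = thermo$C * r_oc, r_o2 = thermo$y_o2 * mu,
                 r_hco3 = thermo$y_hco3 * mu, flags = thermo$flags)
}

#' Cybernetic allocation weights
#'
#' Simplified cybernetic regulation: the relative enzyme level for reaction i
#' is approximated by `u_i = mu_i_kin / sum_j mu_j_kin`, and the regulated
#' rate is `u_i * mu_i_kin`. Weights sum to 1 whenever any kinetic rate is
#' positive; an all-zero input (no activity) returns all-zero weights by
#' design rather than NaN.
#'
#' @param kin_rates Non-negative kinetic rates `mu_i_kin`.
#' @return Weights of the same length as the input.
#' @examples
#' cybernetic_weights(c(3, 1)) # 0.75 0.25
#' @export
cybernetic_weights <- function(kin_rates) {
  if (!is.numeric(kin_rates) || any(!is.finite(kin_rates)) ||
      any(kin_rates < 0)) {
    stop_validation("kinetic rates must be finite and non-negative")
  }
  s <- sum(kin_rates)
  if (s == 0) return(rep(0, length(kin_rates)))
  kin_rates / s
}
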