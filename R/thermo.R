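# Linear NOSC relation for the per-C-mol oxidation half-reaction energy.
DG_COX_INTERCEPT <- 60.3   # kJ/C-mol at NOSC = 0
DG_COX_SLOPE <- -28.5      # kJ/C-mol per unit NOSC

#' Thermodynamic configuration
#'
#' Constants for the Gibbs-energy chain: temperature (25 degC), the gas
#' constant, the TEEM energy-transfer efficiency `eta`, the building-block to
#' biomass synthesis energy `dg_syn`, the pH convention used for the coupling
#' parameter lambda and the metabolic vector, and standard formation energies
#' (kJ/mol) of the nine non-compound species.
#'
#' @param temperature Kelvin; default 298.15 (no enthalpy-based correction is
#'   applied, so other temperatures only rescale the RT terms).
#' @param gas_constant kJ/(K mol).
#' @param eta Energy-transfer efficiency, in (0, 1).
#' @param dg_syn Energy to convert building blocks to biomass, kJ/C-mol.
#' @param ph Either 0 (standard state, unit activities) or 7 (biological
#'   standard state, hydrogen-ion activity 1e-7). Controls which Gibbs
#'   energies feed lambda and the kinetics; both are always reported.
#' @param formation_energies Named vector of standard formation energies for
#'   H2O, HCO3, NH4, HPO4, HS, H, e, O2, Biom. H+ and e- are zero by
#'   convention.
#' @return A list of class `thermo_config`.
#' @export
thermo_config <- function(temperature = 298.15, gas_constant = 0.008314,
                          eta = 0.43, dg_syn = 200, ph = 7,
                          formation_energies = c(
                            H2O = -237.2, HCO3 = -586.9, NH4 = -79.5,
                            HPO4 = -1089.1, HS = 12.0, H = 0, e = 0,
                            O2 = 16.5, Biom = -67)) {
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_validation("temperature must be positive (Kelvin)")
  }
  if (!is.numeric(eta) || eta <= 0 || eta >= 1) {
    stop_validation("eta must lie strictly between 0 and 1")
  }
  if (!ph %in% c(0, 7)) stop_validation("ph must be 0 or 7")
  need <- setdiff(SXM_SPECIES, "OC")
  if (!all(need %in% names(formation_energies))) {
    stop_validation("formation_energies must name all of: %s",
                    paste(need, collapse = ", "))
  }
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 eta = eta, dg_syn = dg_syn, ph = ph,
                 formation_energies = formation_energies[need]),
            class = "thermo_config")
}

# RT ln(1e-7): the biological-standard correction per mole of H+ produced.
ph7_term <- function(cfg) cfg$gas_constant * cfg$temperature * log(1e-7)

#' Per-C-mol oxidation half-reaction energy from NOSC
#'
#' Linear relation `dG0_Cox [kJ/C-mol] = 60.3 - 28.5 * NOSC`: each unit of
#' carbon oxidation state lowers the half-reaction energy by 28.5 kJ/C-mol.
#'
#' @param nosc Nominal oxidation state of carbon (vectorized).
#' @return kJ per C-mol.
#' @examples
#' delta_g_cox(0)    # 60.3
#' delta_g_cox(-4)   # 174.3 (methane)
#' @export
delta_g_cox <- function(nosc) DG_COX_INTERCEPT + DG_COX_SLOPE * nosc

#' Donor half-reaction Gibbs energy
#'
#' `dG0_rD = a * dG0_Cox`; at pH 7 the biological-standard correction
#' `R T y_H+ ln(1e-7)` is added using the proton coefficient of the donor
#' half reaction.
#'
#' @param f A [mol_formula].
#' @param cfg A [thermo_config()].
#' @param ph 0 or 7; defaults to the config's pH convention.
#' @return kJ per mol of compound.
#' @examples
#' delta_g_donor(parse_formula("C6H12O6"), ph = 0) # 361.8
#' @export
delta_g_donor <- function(f, cfg = thermo_config(), ph = cfg$ph) {
  base <- f$C * delta_g_cox(nosc(f))
  if (ph == 7) {
    y_h <- donor_coeffs(f$C, f$H, f$N, f$O, f$P, f$S, f$charge)$h
    base <- base + y_h * ph7_term(cfg)
  }
  base
}

#' Standard formation energy of an organic compound
#'
#' Back-calculates the compound's standard Gibbs energy of formation so that
#' its donor half reaction, evaluated from formation energies, reproduces
#' `a * dG0_Cox` exactly. This sidesteps group-contribution methods, which
#' need structures that formula-level data (e.g. FTICR-MS) cannot provide.
#'
#' @param f A [mol_formula].
#' @param cfg A [thermo_config()].
#' @return kJ/mol.
#' @examples
#' estimate_formation_energy(parse_formula("C6H12O6")) # about -1036.8
#' @export
estimate_formation_energy <- function(f, cfg = thermo_config()) {
  y <- donor_half_reaction(f)
  fe <- cfg$formation_energies
  others <- sum(y[names(fe)] * fe)
  dg_d0 <- f$C * delta_g_cox(nosc(f))
  (dg_d0 - others) / y[["OC"]]
}

#' Gibbs energy of a reaction vector
#'
#' Standard-state energy `sum(y_i dG0_f,i)`, optionally corrected to the
#' biological standard state (pH 7) or to explicit activities through the
#' reaction quotient `R T ln Q`. The electron is never part of the quotient
#' (it is not a solution species); unspecified activities default to 1.
#'
#' @param y Named reaction vector over the 10-species basis.
#' @param cfg A [thermo_config()].
#' @param dg_f_oc Formation energy of the compound in the OC slot; required
#'   when `y["OC"]` is nonzero (see [estimate_formation_energy()]).
#' @param ph 0 or 7 (ignored when `activities` is supplied; put the hydrogen
#'   ion activity in `activities` instead).
#' @param activities Optional named vector of species activities.
#' @return kJ per formula unit of the reaction.
#' @export
reaction_gibbs <- function(y, cfg = thermo_config(), dg_f_oc = NULL,
                           ph = cfg$ph, activities = NULL) {
  stopifnot(is.numeric(y), length(y) == length(SXM_SPECIES))
  if (is.null(names(y))) names(y) <- SXM_SPECIES
  fe <- cfg$formation_energies
  if (abs(y[["OC"]]) > 0) {
    if (is.null(dg_f_oc)) {
      stop_validation("dg_f_oc is required when the reaction involves the compound")
    }
    fe <- c(OC = dg_f_oc, fe)
  } else {
    fe <- c(OC = 0, fe)
  }
  dg0 <- sum(y[names(fe)] * fe)
  rt <- cfg$gas_constant * cfg$temperature
  if (!is.null(activities)) {
    if (any(activities <= 0)) stop_validation("activities must be positive")
    act <- setNames(rep(1, length(SXM_SPECIES)), SXM_SPECIES)
    act[names(activities)] <- activities
    act <- act[setdiff(SXM_SPECIES, "e")]
    return(dg0 + rt * sum(y[names(act)] * log(act)))
  }
  if (ph == 7) dg0 <- dg0 + rt * y[["H"]] * log(1e-7)
  dg0
}

#' TEEM energy coupling parameter
#'
#' Solves the TEEM balance
#' `lambda (eta dG_cat) + eta^m dG_block + dG_syn = 0` for lambda, the number
#' of catabolic turnovers needed per C-mol of biomass synthesized. The
#' exponent `m` is +1 when converting the carbon source to building blocks
#' releases energy (`dG_block <= 0`; the boundary case uses +1 since the term
#' vanishes either way) and -1 when it costs energy. `dG_block` is identified
#' with the anabolic reaction energy, since building blocks share the biomass
#' composition. Endergonic catabolism (`dG_cat >= 0`) yields `NA` with an
#' infeasibility flag downstream; negative lambda is retained but flagged.
#'
#' @param dg_cat Catabolic Gibbs energy, kJ/mol compound (vectorized).
#' @param dg_block Building-block (anabolic) energy, kJ/C-mol biomass.
#' @param cfg A [thermo_config()].
#' @return List with vectors `lambda` and `m`.
#' @export
lambda_coupling <- function(dg_cat, dg_block, cfg = thermo_config()) {
  m <- ifelse(dg_block <= 0, 1, -1)
  lam <- -(cfg$eta^m * dg_block + cfg$dg_syn) / (cfg$eta * dg_cat)
  lam[!is.finite(dg_cat) | dg_cat >= 0] <- NA_real_
  list(lambda = lam, m = m)
}

#' Dissipation energy
#'
#' Free energy dissipated per C-mol of biomass synthesized, obtained by
#' rearranging the coupling definition:
#' `dG_dis = lambda * (-dG_cat) - dG_ana`.
#'
#' @param lambda Coupling parameter.
#' @param dg_cat Catabolic energy, kJ/mol.
#' @param dg_ana Anabolic energy, kJ/C-mol biomass.
#' @return kJ per C-mol biomass (vectorized).
#' @export
dissipation_energy <- function(lambda, dg_cat, dg_ana) {
  lambda * (-dg_cat) - dg_ana
}

# Vectorized thermodynamic chain over a count table. The workhorse behind
# compound_thermo() and compound_thermo_table(); everything here is
# elementwise arithmetic, so thousands of compounds cost milliseconds.
thermo_chain <- function(tab, cfg = thermo_config(), basis = "mol",
                         convention = "donor_scaled",
                         biom = biomass_composition()) {
  fe <- cfg$formation_energies
  ph7 <- ph7_term(cfg)
  C <- tab$C; H <- tab$H; N <- tab$N; O <- tab$O; P <- tab$P; S <- tab$S
  z <- tab$charge

  k <- donor_coeffs(C, H, N, O, P, S, z)
  ne <- k$e
  nosc <- 4 - ne / C
  dg_cox0 <- delta_g_cox(nosc)
  dg_donor0 <- C * dg_cox0
  dg_donor7 <- dg_donor0 + k$h * ph7

  # Formation energy from the donor half reaction (inverts the energy sum).
  others <- k$h2o * fe[["H2O"]] + k$hco3 * fe[["HCO3"]] + k$nh4 * fe[["NH4"]] +
    k$hpo4 * fe[["HPO4"]] + k$hs * fe[["HS"]]
  dg_f_oc <- others - dg_donor0

  # Catabolic vector: donor + (ne/4) * acceptor.
  cat_h2o <- k$h2o + ne / 2
  cat_h <- k$h - ne
  cat_o2 <- -ne / 4
  dg_cat0 <- -dg_f_oc + cat_h2o * fe[["H2O"]] + k$hco3 * fe[["HCO3"]] +
    k$nh4 * fe[["NH4"]] + k$hpo4 * fe[["HPO4"]] + k$hs * fe[["HS"]] +
    cat_o2 * fe[["O2"]]
  dg_cat7 <- dg_cat0 + cat_h * ph7

  # Anabolic vector per 1 C-mol biomass.
  ne_b <- electron_equivalents(biom)
  bh <- donor_coeffs(biom$C, biom$H, biom$N, biom$O, biom$P, biom$S, biom$charge)
  if (convention == "donor_scaled") {
    sc <- (ne_b / (ne / C)) / C        # x / a
    an_o2 <- rep(0, length(C))
  } else {
    sc <- 1 / C
    an_o2 <- -(ne / C - ne_b) / 4
  }
  an_oc <- -sc
  an_h2o <- sc * k$h2o - bh$h2o + (-an_o2) * 2
  an_hco3 <- sc * k$hco3 - bh$hco3
  an_nh4 <- sc * k$nh4 - bh$nh4
  an_hpo4 <- sc * k$hpo4 - bh$hpo4
  an_hs <- sc * k$hs - bh$hs
  an_h <- sc * k$h - bh$h + an_o2 * 4
  fe_biom <- attr(biom, "formation_energy") %||% fe[["Biom"]]
  dg_ana0 <- an_oc * dg_f_oc + an_h2o * fe[["H2O"]] + an_hco3 * fe[["HCO3"]] +
    an_nh4 * fe[["NH4"]] + an_hpo4 * fe[["HPO4"]] + an_hs * fe[["HS"]] +
    an_o2 * fe[["O2"]] + fe_biom
  dg_ana7 <- dg_ana0 + an_h * ph7

  use7 <- cfg$ph == 7
  dg_cat_use <- if (use7) dg_cat7 else dg_cat0
  dg_ana_use <- if (use7) dg_ana7 else dg_ana0
  lc <- lambda_coupling(dg_cat_use, dg_ana_use, cfg)
  lam <- lc$lambda
  dg_dis <- dissipation_energy(lam, dg_cat_use, dg_ana_use)

  # Metabolic vector y = lambda * y_cat + y_an.
  y_oc <- lam * (-1) + an_oc
  y_h2o <- lam * cat_h2o + an_h2o
  y_hco3 <- lam * k$hco3 + an_hco3
  y_nh4 <- lam * k$nh4 + an_nh4
  y_hpo4 <- lam * k$hpo4 + an_hpo4
  y_hs <- lam * k$hs + an_hs
  y_h <- lam * cat_h + an_h
  y_o2 <- lam * cat_o2 + an_o2
  y_biom <- rep(1, length(C))

  flags <- character(length(C))
  add_flag <- function(flags, which, flag) {
    which <- which & !is.na(which)
    ifelse(which, ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag),
           flags)
  }
  flags <- add_flag(flags, ne <= 0, "not_oxidizable")
  flags <- add_flag(flags, nosc < -4 | nosc > 4, "nosc_out_of_range")
  flags <- add_flag(flags, dg_cat_use >= 0, "endergonic_catabolism")
  flags <- add_flag(flags, !is.na(lam) & lam <= 0, "nonpositive_lambda")

  div <- if (basis == "cmol") C else 1
  tibble::tibble(
    label = tab$label, C = C, H = H, N = N, O = O, P = P, S = S, charge = z,
    n_e = ne, nosc = nosc, dg_cox0 = dg_cox0,
    dg_donor0 = dg_donor0 / div, dg_donor7 = dg_donor7 / div,
    dg_f_oc = dg_f_oc,
    dg_cat0 = dg_cat0 / div, dg_cat7 = dg_cat7 / div,
    dg_ana0 = dg_ana0, dg_ana7 = dg_ana7,
    m = lc$m, lambda = lam, dg_dis = dg_dis,
    y_oc = y_oc, y_h2o = y_h2o, y_hco3 = y_hco3, y_nh4 = y_nh4,
    y_hpo4 = y_hpo4, y_hs = y_hs, y_h = y_h, y_e = rep(0, length(C)),
    y_o2 = y_o2, y_biom = y_biom, flags = flags)
}

#' Full thermodynamic profile of one compound
#'
#' Runs the entire chain for a single compound: donor half reaction, NOSC,
#' per-C-mol oxidation energy, formation energy, catabolic and anabolic
#' energies at pH 0 and pH 7, the TEEM coupling parameter lambda, dissipation
#' energy, and the catabolic/anabolic/metabolic reaction vectors.
#'
#' @param f A [mol_formula].
#' @param cfg A [thermo_config()]; its `ph` selects the energies feeding
#'   lambda and the metabolic vector.
#' @param basis `"mol"` reports donor/catabolic energies per mole of compound,
#'   `"cmol"` per C-mol (lambda itself is always computed from per-mol
#'   quantities; anabolic energies are already per C-mol biomass).
#' @param convention Anabolic electron-closure convention, see
#'   [anabolic_reaction()].
#' @return A list of class `compound_thermo`.
#' @examples
#' ct <- compound_thermo(parse_formula("C6H12O6"))
#' ct$lambda
#' @export
compound_thermo <- function(f, cfg = thermo_config(), basis = c("mol", "cmol"),
                            convention = c("donor_scaled", "acceptor_balanced")) {
  basis <- match.arg(basis)
  convention <- match.arg(convention)
  row <- thermo_chain(as_formula_table(f), cfg, basis = basis,
                      convention = convention)
  ne <- row$n_e
  y_cat <- if (ne > 0) catabolic_reaction(f) else empty_rxn() * NA
  y_an <- if (ne > 0) anabolic_reaction(f, convention = convention) else empty_rxn() * NA
  y_met <- empty_rxn()
  y_met[c("OC", "H2O", "HCO3", "NH4", "HPO4", "HS", "H", "e", "O2", "Biom")] <-
    c(row$y_oc, row$y_h2o, row$y_hco3, row$y_nh4, row$y_hpo4, row$y_hs,
      row$y_h, row$y_e, row$y_o2, row$y_biom)
  structure(
    c(list(formula = f, basis = basis, convention = convention,
           y_cat = y_cat, y_an = y_an, y_met = y_met),
      as.list(row[setdiff(names(row), c("label", "C", "H", "N", "O", "P", "S",
                                        "charge"))])),
    class = "compound_thermo")
}

#' @export
print.compound_thermo <- function(x, ...) {
  cat(sprintf("<compound_thermo> %s\n", x$formula$label))
  cat(sprintf("  n_e = %g, NOSC = %.4g, dG0_Cox = %.6g kJ/C-mol\n",
              x$n_e, x$nosc, x$dg_cox0))
  cat(sprintf("  dG_cat (pH0/pH7) = %.6g / %.6g kJ/%s\n",
              x$dg_cat0, x$dg_cat7, if (x$basis == "cmol") "C-mol" else "mol"))
  cat(sprintf("  lambda = %.6g, dG_dis = %.6g kJ/C-mol biomass\n",
              x$lambda, x$dg_dis))
  if (nzchar(x$flags)) cat("  flags:", x$flags, "\n")
  invisible(x)
}

#' Thermodynamic profiles for a table of compounds
#'
#' Vectorized batch version of [compound_thermo()]: accepts a character
#' vector of formula strings, a list of [mol_formula] objects, or a data
#' frame with either a `formula` column or element-count columns
#' C, H, N, O, P, S (case-insensitive, optional `charge` and `label`).
#' Degenerate compounds never abort the batch; they are annotated in the
#' `flags` column (`not_oxidizable`, `endergonic_catabolism`,
#' `nonpositive_lambda`, `nosc_out_of_range`) and excluded from kinetics by
#' default.
#'
#' @inheritParams compound_thermo
#' @param x Compounds in any of the accepted forms.
#' @return A tibble with one row per compound: identifiers, counts, `n_e`,
#'   `nosc`, the Gibbs-energy chain at pH 0 and pH 7, `m`, `lambda`,
#'   `dg_dis`, the ten metabolic coefficients (`y_oc` ... `y_biom`) and
#'   `flags`.
#' @examples
#' compound_thermo_table(c("C6H12O6", "CH4", "C2H5NO2"))
#' @export
compound_thermo_table <- function(x, cfg = thermo_config(),
                                  basis = c("mol", "cmol"),
                                  convention = c("donor_scaled",
                                                 "acceptor_balanced")) {
  basis <- match.arg(basis)
  convention <- match.arg(convention)
  tab <- as_formula_table(x)
  if (nrow(tab) == 0L) stop_validation("no compounds supplied")
  thermo_chain(tab, cfg, basis = basis, convention = convention)
}
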