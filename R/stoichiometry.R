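# Canonical 10-species basis for oxidative degradation of organic carbon.
# Order is fixed package-wide; reaction vectors are named numerics aligned
# to it, negative for reactants and positive for products.
SXM_SPECIES <- c("OC", "H2O", "HCO3", "NH4", "HPO4", "HS", "H", "e", "O2", "Biom")

#' Default biomass composition
#'
#' Per-C-mol biomass building block CH1.8N0.2O0.5 (charge 0), the composition
#' widely used for heterotrophic bacteria, with a standard formation energy of
#' -67 kJ/C-mol. Its oxidation half reaction transfers 4.2 electrons per C-mol.
#'
#' @param h_count,n_count,o_count Per-C-mol H, N, O contents.
#' @param formation_energy Standard Gibbs energy of formation, kJ/C-mol.
#' @return A `mol_formula` (fractional counts) with attribute
#'   `formation_energy`, classed `biomass_composition`.
#' @export
biomass_composition <- function(h_count = 1.8, n_count = 0.2, o_count = 0.5,
                                formation_energy = -67) {
  f <- mol_formula(1, h_count, n_count, o_count, charge = 0,
                   label = "Biom", fractional = TRUE)
  attr(f, "formation_energy") <- formation_energy
  class(f) <- c("biomass_composition", class(f))
  f
}

#' Species composition matrix
#'
#' Composition (C, H, N, O, P, S, charge) of the 10 canonical species involved
#' in oxidative degradation of one organic compound: the compound itself (OC),
#' H2O, HCO3-, NH4+, HPO4 2-, HS-, H+, e-, O2 and biomass. The transpose of
#' this matrix applied to a reaction vector gives its element/charge residual.
#'
#' @param f The organic compound occupying the OC slot.
#' @param biom Biomass composition occupying the Biom slot.
#' @return A 10 x 7 numeric matrix (species x element/charge).
#' @export
species_basis <- function(f, biom = biomass_composition()) {
  stopifnot(inherits(f, "mol_formula"))
  m <- rbind(
    OC   = c(f$C, f$H, f$N, f$O, f$P, f$S, f$charge),
    H2O  = c(0, 2, 0, 1, 0, 0, 0),
    HCO3 = c(1, 1, 0, 3, 0, 0, -1),
    NH4  = c(0, 4, 1, 0, 0, 0, 1),
    HPO4 = c(0, 1, 0, 4, 1, 0, -2),
    HS   = c(0, 1, 0, 0, 0, 1, -1),
    H    = c(0, 1, 0, 0, 0, 0, 1),
    e    = c(0, 0, 0, 0, 0, 0, -1),
    O2   = c(0, 0, 0, 2, 0, 0, 0),
    Biom = c(biom$C, biom$H, biom$N, biom$O, biom$P, biom$S, biom$charge))
  colnames(m) <- c("C", "H", "N", "O", "P", "S", "charge")
  m
}

empty_rxn <- function() setNames(numeric(length(SXM_SPECIES)), SXM_SPECIES)

# Closed-form donor half-reaction coefficients, vectorized over count columns.
# Oxidation to HCO3- with N -> NH4+, P -> HPO4 2-, S -> HS-.
donor_coeffs <- function(C, H, N, O, P, S, charge = 0) {
  list(h2o  = -(3 * C + 4 * P - O),
       hco3 = C,
       nh4  = N,
       hpo4 = P,
       hs   = S,
       h    = 5 * C + H - 4 * N - 2 * O + 7 * P - S,
       e    = ne_counts(C, H, N, O, P, S, charge))
}

#' Electron-donor half reaction of a compound
#'
#' Complete oxidation half reaction of the compound (coefficient -1 on the
#' compound slot), releasing carbon as bicarbonate, nitrogen as ammonium,
#' phosphorus as hydrogen phosphate, sulfur as bisulfide, with protons and
#' electrons as products. Balanced in every element and in charge.
#'
#' @param f A [mol_formula].
#' @param slot Species slot the compound occupies: `"OC"` for substrates,
#'   `"Biom"` for the biomass building block.
#' @return Named reaction vector over the 10-species basis.
#' @examples
#' donor_half_reaction(parse_formula("C6H12O6"))
#' @export
donor_half_reaction <- function(f, slot = c("OC", "Biom")) {
  stopifnot(inherits(f, "mol_formula"))
  slot <- match.arg(slot)
  k <- donor_coeffs(f$C, f$H, f$N, f$O, f$P, f$S, f$charge)
  y <- empty_rxn()
  y[slot] <- -1
  y["H2O"] <- k$h2o
  y["HCO3"] <- k$hco3
  y["NH4"] <- k$nh4
  y["HPO4"] <- k$hpo4
  y["HS"] <- k$hs
  y["H"] <- k$h
  y["e"] <- k$e
  y
}

#' Oxygen electron-acceptor half reaction
#'
#' The aerobic terminal couple `O2 + 4 H+ + 4 e- -> 2 H2O`, used throughout:
#' alternative acceptors (nitrate, sulfate, ferric iron) are out of scope.
#'
#' @return Named reaction vector with `y_e = -4`.
#' @export
acceptor_half_reaction <- function() {
  y <- empty_rxn()
  y["O2"] <- -1
  y["H"] <- -4
  y["e"] <- -4
  y["H2O"] <- 2
  y
}

#' Catabolic reaction (complete aerobic oxidation)
#'
#' Donor half reaction combined with the oxygen couple at ratio `n_e / 4`, so
#' that electrons cancel: one mole of compound is fully oxidized consuming
#' `n_e / 4` moles of O2.
#'
#' @param f A [mol_formula] with positive electron equivalents.
#' @return Named reaction vector with `y_e = 0` and `y_O2 = -n_e / 4`.
#' @examples
#' catabolic_reaction(parse_formula("C6H12O6")) # 6 O2 per glucose
#' @export
catabolic_reaction <- function(f) {
  ne <- electron_equivalents(f)
  if (ne <= 0) {
    stop_validation("'%s' has n_e = %g <= 0: not oxidizable in this framework",
                    f$label, ne)
  }
  donor_half_reaction(f) + (ne / 4) * acceptor_half_reaction()
}

#' Anabolic reaction (biomass synthesis from the compound)
#'
#' Builds the reaction forming one C-mol of biomass from the compound, with
#' ammonium as the sole nitrogen source. Two electron-closure conventions are
#' available, isolated here so either can be selected:
#'
#' * `"donor_scaled"` (default): residual electrons are balanced by scaling
#'   the carbon-source donor half reaction by `x = n_B / (n_e / a)`; the
#'   anabolic reaction then contains neither O2 nor free electrons, and
#'   `y_HCO3 = x - 1` (negative for compounds more reduced than biomass,
#'   i.e. NOSC < -0.2, which then fix inorganic carbon).
#' * `"acceptor_balanced"`: exactly `1/a` mol of compound supplies the carbon
#'   and the electron mismatch with the biomass half reaction is closed by
#'   the O2 couple.
#'
#' @param f Carbon-source [mol_formula].
#' @param biom Biomass composition (see [biomass_composition()]).
#' @param convention Electron-closure convention, see Details.
#' @return Named reaction vector with `y_Biom = +1` and `y_e = 0`.
#' @examples
#' anabolic_reaction(parse_formula("C6H12O6"))
#' @export
anabolic_reaction <- function(f, biom = biomass_composition(),
                              convention = c("donor_scaled", "acceptor_balanced")) {
  convention <- match.arg(convention)
  ne <- electron_equivalents(f)
  if (ne <= 0) {
    stop_validation("'%s' has n_e = %g <= 0: not oxidizable in this framework",
                    f$label, ne)
  }
  ne_b <- electron_equivalents(biom)
  biom_half <- donor_half_reaction(biom, slot = "Biom")
  if (convention == "donor_scaled") {
    x <- ne_b / (ne / f$C)
    if (!is.finite(x)) stop_validation("non-finite anabolic scaling for '%s'", f$label)
    y <- (x / f$C) * donor_half_reaction(f) - biom_half
  } else {
    y <- (1 / f$C) * donor_half_reaction(f) - biom_half +
      ((ne / f$C - ne_b) / 4) * acceptor_half_reaction()
  }
  y
}

#' Metabolic reaction from energy coupling
#'
#' `y = lambda * y_cat + y_an`: the catabolic reaction is run `lambda` times
#' to pay for the synthesis of one C-mol of biomass.
#'
#' @param y_cat,y_an Catabolic and anabolic reaction vectors.
#' @param lambda Energy-coupling parameter (catabolic turnovers per C-mol
#'   biomass).
#' @return Named reaction vector with `y_Biom = 1`.
#' @export
metabolic_reaction <- function(y_cat, y_an, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  lambda * y_cat + y_an
}

#' Element and charge residual of a reaction vector
#'
#' Multiplies the transpose of the species composition matrix by the reaction
#' vector; a balanced reaction returns (numerically) zero in all seven
#' components. This is the oracle used by the property suites.
#'
#' @param y Named reaction vector over the 10-species basis.
#' @param f Compound occupying the OC slot.
#' @param biom Biomass composition occupying the Biom slot.
#' @return Named numeric of length 7: C, H, N, O, P, S, charge.
#' @export
balance_residual <- function(y, f, biom = biomass_composition()) {
  stopifnot(is.numeric(y), length(y) == length(SXM_SPECIES))
  drop(t(species_basis(f, biom)) %*% as.numeric(y))
}
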