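# Shared fixtures and independent oracles for the property suites.

# Independent random CHNOPS formula generator: draws raw element counts
# directly (it deliberately does not reuse the package's synthetic module,
# whose van Krevelen logic is itself under test).
random_counts <- function(n, seed, charged = FALSE) {
  withr::with_seed(seed, {
    tibble::tibble(
      label = paste0("r", seq_len(n)),
      C = sample(1:40, n, replace = TRUE),
      H = sample(1:80, n, replace = TRUE),
      N = sample(0:4, n, replace = TRUE),
      O = sample(0:30, n, replace = TRUE),
      P = sample(0:2, n, replace = TRUE),
      S = sample(0:2, n, replace = TRUE),
      charge = if (charged) sample(-2:2, n, replace = TRUE) else 0L)
  })
}

counts_to_formula <- function(tab, i) {
  mol_formula(tab$C[i], tab$H[i], tab$N[i], tab$O[i], tab$P[i], tab$S[i],
              charge = tab$charge[i], label = tab$label[i])
}

# Element/charge balance oracle built from scratch: literal composition rows
# for the 10 species, written out independently of species_basis().
oracle_residual <- function(y, f) {
  comp <- rbind(
    c(f$C, f$H, f$N, f$O, f$P, f$S, f$charge),  # the compound
    c(0, 2, 0, 1, 0, 0, 0),                     # water
    c(1, 1, 0, 3, 0, 0, -1),                    # bicarbonate
    c(0, 4, 1, 0, 0, 0, 1),                     # ammonium
    c(0, 1, 0, 4, 1, 0, -2),                    # hydrogen phosphate
    c(0, 1, 0, 0, 0, 1, -1),                    # bisulfide
    c(0, 1, 0, 0, 0, 0, 1),                     # proton
    c(0, 0, 0, 0, 0, 0, -1),                    # electron
    c(0, 0, 0, 2, 0, 0, 0),                     # dioxygen
    c(1, 1.8, 0.2, 0.5, 0, 0, 0))               # biomass CH1.8N0.2O0.5
  drop(crossprod(comp, as.numeric(y)))
}

# Frozen glucose reference chain, derived by hand from the Table-1 constants
# before implementation: donor energy 6 * 60.3; formation energy by
# inverting the donor half-reaction energy sum; catabolic/anabolic energies
# by direct formation-energy arithmetic; pH-7 corrections as
# y_H+ * R * T * ln(1e-7) with R = 0.008314, T = 298.15.
glucose_ref <- list(
  n_e = 24, nosc = 0,
  dg_donor0 = 361.8,
  dg_donor7 = 361.8 + 30 * 0.008314 * 298.15 * log(1e-7),   # -836.8
  dg_f_oc = -1036.8,
  dg_cat0 = -2583.6,
  dg_cat7 = -2583.6 + 6 * 0.008314 * 298.15 * log(1e-7),    # -2823.3
  dg_ana0 = 6.115,
  dg_ana7 = 6.115 + 0.25 * 0.008314 * 298.15 * log(1e-7),   # -3.873
  lambda = 0.1633688,
  dg_dis = 465.1163,
  y_oc_abs = 0.3383688,
  y_o2_abs = 0.9802126,
  mu_both_1 = 0.2675145)

glucose <- function() parse_formula("C6H12O6", label = "glucose")

ten_species <- c("OC", "H2O", "HCO3", "NH4", "HPO4", "HS", "H", "e",
                 "O2", "Biom")

met_vector <- function(thermo_row) {
  stats::setNames(as.numeric(thermo_row[1, c("y_oc", "y_h2o", "y_hco3",
                                             "y_nh4", "y_hpo4", "y_hs",
                                             "y_h", "y_e", "y_o2",
                                             "y_biom")]), ten_species)
}
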