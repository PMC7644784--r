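test_that("glucose and methane donor half reactions match hand balancing", {
  y <- donor_half_reaction(glucose())
  # C6H12O6 + 12 H2O -> 6 HCO3- + 30 H+ + 24 e-
  expect_equal(y[["OC"]], -1)
  expect_equal(y[["H2O"]], -12)
  expect_equal(y[["HCO3"]], 6)
  expect_equal(y[["H"]], 30)
  expect_equal(y[["e"]], 24)
  expect_equal(y[["O2"]], 0)
  # CH4 + 3 H2O -> HCO3- + 9 H+ + 8 e-
  y2 <- donor_half_reaction(parse_formula("CH4"))
  expect_equal(unname(y2[c("H2O", "HCO3", "H", "e")]), c(-3, 1, 9, 8))
})

test_that("the oxygen acceptor couple is O2 + 4H+ + 4e- -> 2 H2O", {
  y <- acceptor_half_reaction()
  expect_equal(unname(y[c("O2", "H", "e", "H2O")]), c(-1, -4, -4, 2))
  expect_equal(sum(abs(y[c("OC", "HCO3", "NH4", "HPO4", "HS", "Biom")])), 0)
  expect_equal(max(abs(oracle_residual(y, glucose()))), 0)
  # combining a donor with the couple at ratio n_e/4 cancels the electrons
  f <- parse_formula("C5H8NO4", charge = -1)
  comb <- donor_half_reaction(f) + (electron_equivalents(f) / 4) * y
  expect_equal(comb[["e"]], 0)
})

test_that("catabolic reactions consume n_e/4 O2 and balance", {
  y <- catabolic_reaction(glucose())
  # C6H12O6 + 6 O2 -> 6 HCO3- + 6 H+  (no net water)
  expect_equal(unname(y[c("OC", "O2", "HCO3", "H", "H2O", "e")]),
               c(-1, -6, 6, 6, 0, 0))
  y2 <- catabolic_reaction(parse_formula("CH4"))
  # CH4 + 2 O2 -> HCO3- + H+ + H2O
  expect_equal(unname(y2[c("OC", "O2", "HCO3", "H", "H2O", "e")]),
               c(-1, -2, 1, 1, 1, 0))
})

test_that("the anabolic reaction forms 1 C-mol biomass without O2 or e-", {
  y <- anabolic_reaction(glucose())
  # 0.175 glc + 0.2 NH4+ -> 1 Biom + 0.05 HCO3- + 0.25 H+ + 0.4 H2O
  expect_equal(y[["OC"]], -0.175)
  expect_equal(y[["NH4"]], -0.2)
  expect_equal(y[["Biom"]], 1)
  expect_equal(y[["HCO3"]], 0.05)
  expect_equal(y[["H"]], 0.25)
  expect_equal(y[["H2O"]], 0.4)
  expect_equal(y[["O2"]], 0)
  expect_equal(y[["e"]], 0)
  # a compound at the biomass redox state (NOSC = -0.2) has x = 1, no HCO3
  f <- parse_formula("C10H16N2O4")
  expect_equal(electron_equivalents(f) / f$C, 4.2)
  ya <- anabolic_reaction(f)
  expect_equal(ya[["HCO3"]], 0, tolerance = 1e-12)
})

test_that("both anabolic electron-closure conventions balance", {
  tab <- random_counts(100, seed = 31)
  for (i in seq_len(nrow(tab))) {
    f <- counts_to_formula(tab, i)
    if (electron_equivalents(f) <= 0) next
    for (conv in c("donor_scaled", "acceptor_balanced")) {
      y <- anabolic_reaction(f, convention = conv)
      expect_lt(max(abs(oracle_residual(y, f))), 1e-9)
      expect_equal(y[["e"]], 0, tolerance = 1e-12)
      expect_equal(y[["Biom"]], 1)
    }
    # only the donor-scaled convention is guaranteed acceptor-free
    expect_equal(anabolic_reaction(f)[["O2"]], 0)
  }
})

test_that("every constructed reaction balances to 1e-9 over random formulae", {
  tab <- random_counts(1000, seed = 13, charged = TRUE)
  cfg <- thermo_config()
  worst <- 0
  for (i in seq_len(nrow(tab))) {
    f <- counts_to_formula(tab, i)
    ys <- list(donor_half_reaction(f), acceptor_half_reaction())
    ne <- electron_equivalents(f)
    if (ne > 0) {
      y_cat <- catabolic_reaction(f)
      y_an <- anabolic_reaction(f)
      ct <- compound_thermo(f, cfg)
      ys <- c(ys, list(y_cat, y_an))
      if (is.finite(ct$lambda)) {
        ys <- c(ys, list(metabolic_reaction(y_cat, y_an, ct$lambda)))
      }
    }
    for (y in ys) worst <- max(worst, max(abs(oracle_residual(y, f))))
  }
  expect_lt(worst, 1e-9)
})

test_that("balance_residual reports a corrupted vector linearly", {
  y <- donor_half_reaction(glucose())
  expect_equal(unname(balance_residual(y, glucose())), rep(0, 7))
  y["H"] <- y["H"] + 1
  res <- balance_residual(y, glucose())
  expect_equal(unname(res), c(0, 1, 0, 0, 0, 0, 1))
})

test_that("metabolic vectors obey the coupling identities", {
  g <- glucose()
  y_cat <- catabolic_reaction(g)
  y_an <- anabolic_reaction(g)
  # lambda = 0 reduces to pure anabolism
  expect_equal(metabolic_reaction(y_cat, y_an, 0), y_an)
  ct <- compound_thermo(g)
  y <- ct$y_met
  expect_equal(y[["OC"]], -glucose_ref$y_oc_abs, tolerance = 1e-6)
  expect_equal(y[["O2"]], -glucose_ref$y_o2_abs, tolerance = 1e-6)
  expect_equal(y[["Biom"]], 1)
  expect_equal(y[["e"]], 0)
  # carbon accounting: compound C routed to biomass (1) plus bicarbonate
  expect_equal(abs(y[["OC"]]) * g$C, 1 + y[["HCO3"]], tolerance = 1e-12)
  tab <- random_counts(200, seed = 17)
  for (i in seq_len(nrow(tab))) {
    f <- counts_to_formula(tab, i)
    ct <- compound_thermo(f)
    if (!is.finite(ct$lambda)) next
    expect_equal(abs(ct$y_met[["OC"]]) * f$C, 1 + ct$y_met[["HCO3"]],
                 tolerance = 1e-9)
  }
})
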