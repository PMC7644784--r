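test_that("the NOSC energy relation evaluates as printed", {
  expect_equal(delta_g_cox(0), 60.3)
  expect_equal(delta_g_cox(1), 31.8)
  expect_equal(delta_g_cox(-4), 174.3)
  expect_equal(delta_g_cox(c(0, 2)), c(60.3, 3.3))
})

test_that("donor energies and the pH-7 correction match hand computation", {
  g <- glucose()
  expect_equal(delta_g_donor(g, ph = 0), glucose_ref$dg_donor0)
  expect_equal(delta_g_donor(g, ph = 7), glucose_ref$dg_donor7, tolerance = 1e-9)
  # the correction per reaction is y_H+ * RT ln(1e-7), about -39.95 kJ/mol H+
  cfg <- thermo_config()
  per_h <- cfg$gas_constant * cfg$temperature * log(1e-7)
  expect_equal(per_h, -39.9538, tolerance = 1e-4)
  tab <- random_counts(100, seed = 23)
  for (i in seq_len(nrow(tab))) {
    f <- counts_to_formula(tab, i)
    y_h <- donor_half_reaction(f)[["H"]]
    expect_equal(delta_g_donor(f, ph = 7) - delta_g_donor(f, ph = 0),
                 y_h * per_h, tolerance = 1e-9)
  }
})

test_that("estimated formation energies invert the donor energy sum", {
  expect_equal(estimate_formation_energy(glucose()), glucose_ref$dg_f_oc,
               tolerance = 1e-9)
  cfg <- thermo_config()
  tab <- random_counts(1000, seed = 29, charged = TRUE)
  for (i in seq_len(nrow(tab))) {
    f <- counts_to_formula(tab, i)
    dg <- reaction_gibbs(donor_half_reaction(f), cfg,
                         dg_f_oc = estimate_formation_energy(f, cfg), ph = 0)
    expect_lt(abs(dg - f$C * delta_g_cox(nosc(f))), 1e-9)
  }
})

test_that("reaction_gibbs handles standard, biological and explicit modes", {
  g <- glucose()
  cfg <- thermo_config()
  fe <- estimate_formation_energy(g, cfg)
  y <- catabolic_reaction(g)
  expect_equal(reaction_gibbs(y, cfg, dg_f_oc = fe, ph = 0),
               glucose_ref$dg_cat0, tolerance = 1e-9)
  expect_equal(reaction_gibbs(y, cfg, dg_f_oc = fe, ph = 7),
               glucose_ref$dg_cat7, tolerance = 1e-9)
  # all-unit activities reproduce the standard state
  expect_equal(reaction_gibbs(y, cfg, dg_f_oc = fe, activities = c(H = 1)),
               glucose_ref$dg_cat0, tolerance = 1e-9)
  # explicit hydrogen-ion activity 1e-7 reproduces the biological state
  expect_equal(reaction_gibbs(y, cfg, dg_f_oc = fe, activities = c(H = 1e-7)),
               glucose_ref$dg_cat7, tolerance = 1e-9)
  expect_error(reaction_gibbs(y, cfg, dg_f_oc = fe, activities = c(H = -1)),
               "positive")
  expect_error(reaction_gibbs(y, cfg), "dg_f_oc")
})

test_that("the TEEM coupling gives the frozen glucose lambda chain", {
  ct <- compound_thermo(glucose())
  expect_equal(ct$dg_ana0, glucose_ref$dg_ana0, tolerance = 1e-9)
  expect_equal(ct$dg_ana7, glucose_ref$dg_ana7, tolerance = 1e-9)
  expect_equal(ct$m, 1)
  expect_equal(ct$lambda, glucose_ref$lambda, tolerance = 1e-6)
  expect_equal(ct$dg_dis, glucose_ref$dg_dis, tolerance = 1e-4)
})

test_that("lambda_coupling handles the closed forms and degenerate inputs", {
  cfg <- thermo_config()
  # dg_block = 0 -> lambda = -dG_syn / (eta dG_cat), m = +1 by convention
  lc <- lambda_coupling(-1000, 0, cfg)
  expect_equal(lc$lambda, -cfg$dg_syn / (cfg$eta * -1000))
  expect_equal(lc$m, 1)
  # endergonic catabolism is infeasible
  lc2 <- lambda_coupling(10, -5, cfg)
  expect_true(is.na(lc2$lambda))
  # positive building-block energy flips the efficiency exponent
  expect_equal(lambda_coupling(-1000, 50, cfg)$m, -1)
  expect_equal(lambda_coupling(-1000, 50, cfg)$lambda,
               -(50 / cfg$eta + cfg$dg_syn) / (cfg$eta * -1000))
})

test_that("lambda, dissipation and the two balances agree to 1e-9", {
  cfg <- thermo_config()
  tab <- random_counts(1000, seed = 37)
  th <- compound_thermo_table(tab, cfg)
  ok <- !nzchar(th$flags)
  expect_gt(sum(ok), 500)
  lam <- th$lambda[ok]; cat7 <- th$dg_cat7[ok]; ana7 <- th$dg_ana7[ok]
  dis <- th$dg_dis[ok]; m <- th$m[ok]
  # coupling definition: lambda = (dG_ana + dG_dis) / (-dG_cat)
  expect_lt(max(abs(lam - (ana7 + dis) / (-cat7))), 1e-9)
  # TEEM balance: lambda (eta dG_cat) + eta^m dG_block + dG_syn = 0
  expect_lt(max(abs(lam * (cfg$eta * cat7) + cfg$eta^m * ana7 + cfg$dg_syn)),
            1e-9)
})

test_that("lambda at pH 7 rises with NOSC along a one-carbon series", {
  series <- c("CH4", "CH4O", "CH2O", "CH2O2")
  th <- compound_thermo_table(series)
  expect_equal(th$nosc, c(-4, -2, 0, 2))
  expect_true(all(diff(th$lambda) > 0))
})

test_that("per-C-mol basis rescales donor and catabolic energies only", {
  g <- glucose()
  mol <- compound_thermo(g, basis = "mol")
  cmol <- compound_thermo(g, basis = "cmol")
  expect_equal(cmol$dg_cat0, mol$dg_cat0 / 6)
  expect_equal(cmol$dg_donor7, mol$dg_donor7 / 6)
  expect_equal(cmol$lambda, mol$lambda)
  expect_equal(cmol$dg_ana7, mol$dg_ana7)
})

test_that("batch profiling never aborts on degenerate rows", {
  # carbon dioxide-like over-oxidized rows (n_e <= 0) are flagged, not fatal
  tab <- tibble::tibble(label = c("good", "overox", "glucose"),
                        C = c(5, 1, 6), H = c(8, 0, 12), N = 0,
                        O = c(2, 3, 6), P = 0, S = 0, charge = 0)
  th <- compound_thermo_table(tab)
  expect_equal(nrow(th), 3)
  expect_match(th$flags[2], "not_oxidizable")
  expect_true(is.na(th$lambda[2]))
  expect_equal(th$flags[c(1, 3)], c("", ""))
  # large random batch: all rows come back, flags mark the degenerate ones
  big <- random_counts(500, seed = 41, charged = TRUE)
  thb <- compound_thermo_table(big)
  expect_equal(nrow(thb), 500)
  ne <- sxm:::ne_counts(big$C, big$H, big$N, big$O, big$P, big$S, big$charge)
  expect_identical(grepl("not_oxidizable", thb$flags), ne <= 0)
})

test_that("thermo config rejects unphysical settings", {
  expect_error(thermo_config(temperature = -1), "positive")
  expect_error(thermo_config(eta = 1.2), "between")
  expect_error(thermo_config(ph = 3), "0 or 7")
})
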