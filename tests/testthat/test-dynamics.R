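# Small compound set shared across the simulation tests. Concentrations are
# mol/L with a harvest volume of 1000 L/C-mol so the dimensionless harvest
# products V_h [S] sit near 1, where the kinetics are responsive.
sim_pool <- function() {
  compound_thermo_table(c("C6H12O6", "C5H8O4", "C10H14N2O3"))
}
VH <- 1000

test_that("batch trajectories conserve carbon and respect monotonicity", {
  th <- sim_pool()
  tr <- simulate_batch(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                       times = seq(0, 5, length.out = 41), v_h = VH)
  df <- as.data.frame(tr)
  # the system actually reacts at this scale
  expect_lt(df$oc_1[nrow(df)], 0.9 * df$oc_1[1])
  ctot <- rowSums(sweep(df[, paste0("oc_", 1:3)], 2, th$C, "*")) +
    df$hco3 + df$b
  expect_lt(max(abs(ctot - ctot[1])) / ctot[1], 1e-6)
  expect_true(all(diff(df$o2) <= 1e-12))
  expect_true(all(diff(df$hco3) >= -1e-12))
  expect_true(all(diff(df$b) >= -1e-12))
  for (i in 1:3) expect_true(all(diff(df[[paste0("oc_", i)]]) <= 1e-12))
  expect_true(all(as.matrix(df[, -1]) > -1e-10))
})

test_that("consumed substrate and produced bicarbonate stay in stoichiometric ratio", {
  th <- compound_thermo_table("C6H12O6")
  tr <- simulate_batch(th, oc0 = 5e-4, o2_0 = 1e-2, b0 = 1e-4,
                       times = seq(0, 10, length.out = 81), v_h = VH)
  df <- as.data.frame(tr)
  n <- nrow(df)
  expect_lt(df$oc_1[n], 0.5 * df$oc_1[1])  # substantial consumption
  d_hco3 <- df$hco3[n] - df$hco3[1]
  d_oc <- df$oc_1[1] - df$oc_1[n]
  d_o2 <- df$o2[1] - df$o2[n]
  # per mole of compound consumed: y_HCO3 / |y_OC| bicarbonate, y_O2 / |y_OC| O2
  expect_equal(d_hco3 / d_oc, th$y_hco3[1] / abs(th$y_oc[1]), tolerance = 1e-6)
  expect_equal(d_o2 / d_oc, abs(th$y_o2[1]) / abs(th$y_oc[1]), tolerance = 1e-6)
})

test_that("zero biomass freezes the system", {
  th <- sim_pool()
  tr <- simulate_batch(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = 0,
                       times = seq(0, 5, length.out = 11), v_h = VH)
  expect_equal(max(abs(apply(tr$state, 2, diff))), 0)
})

test_that("identical compounds share cybernetic allocation equally", {
  th <- compound_thermo_table(c("C6H12O6", "C6H12O6"))
  tr <- simulate_batch(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                       times = seq(0, 2, length.out = 21), mode = "sxm_exm",
                       v_h = VH)
  df <- as.data.frame(tr)
  expect_equal(df$u_1, rep(0.5, nrow(df)), tolerance = 1e-9)
  expect_equal(df$u_2, rep(0.5, nrow(df)), tolerance = 1e-9)
})

test_that("one-guild MXM reproduces plain SXM exactly", {
  th <- sim_pool()
  t_grid <- seq(0, 3, length.out = 21)
  tr_sxm <- simulate_batch(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                           times = t_grid, mode = "sxm", v_h = VH)
  tr_mxm <- simulate_batch(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                           times = t_grid, mode = "sxm_mxm", mu_max = 1,
                           v_h = VH)
  expect_lt(max(abs(tr_sxm$state - tr_mxm$state)), 1e-8)
})

test_that("guilds with different mu_max diverge in MXM mode", {
  th <- sim_pool()
  tr <- simulate_batch(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = c(1e-4, 1e-4),
                       times = seq(0, 3, length.out = 21), mode = "sxm_mxm",
                       mu_max = c(1, 2), v_h = VH)
  df <- as.data.frame(tr)
  expect_gt(df$b_2[nrow(df)], 1.5 * df$b_1[nrow(df)])
})

test_that("cybernetic regulation never consumes more than plain SXM", {
  th <- sim_pool()
  t_grid <- seq(0, 3, length.out = 21)
  args <- list(th, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4, times = t_grid,
               v_h = VH)
  plain <- as.data.frame(do.call(simulate_batch, c(args, mode = "sxm")))
  reg <- as.data.frame(do.call(simulate_batch, c(args, mode = "sxm_exm")))
  pool_plain <- rowSums(sweep(plain[, paste0("oc_", 1:3)], 2, th$C, "*"))
  pool_reg <- rowSums(sweep(reg[, paste0("oc_", 1:3)], 2, th$C, "*"))
  expect_lt(pool_plain[length(pool_plain)], pool_plain[1])
  expect_true(all(pool_reg - pool_plain >= -1e-10))
  expect_true(all(reg$o2 - plain$o2 >= -1e-10))
})

test_that("specific rates at t = 0 equal the static rate set", {
  th <- compound_thermo_table("C6H12O6")
  oc0 <- 2e-3; o2_0 <- 3e-3
  tr <- simulate_batch(th, oc0 = oc0, o2_0 = o2_0, b0 = 1e-4,
                       times = c(0, 0.1), v_h = VH)
  s0 <- specific_rates(tr)[1, ]
  rs <- rate_set(met_vector(th), 6,
                 scenario("both", vh_oc = VH * oc0, vh_o2 = VH * o2_0))
  expect_equal(s0$mu, rs$mu, tolerance = 1e-12)
  expect_equal(s0$r_oc, rs$r_oc, tolerance = 1e-12)
  expect_equal(s0$r_o2, rs$r_o2, tolerance = 1e-12)
  expect_equal(s0$r_hco3, rs$r_hco3, tolerance = 1e-12)
})

test_that("n identical compounds scale SXM rates by n but not EXM rates", {
  th1 <- compound_thermo_table("C6H12O6")
  n <- 4
  thn <- compound_thermo_table(rep("C6H12O6", n))
  tr1 <- simulate_batch(th1, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                        times = c(0, 0.1), v_h = VH)
  trn <- simulate_batch(thn, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                        times = c(0, 0.1), v_h = VH)
  expect_equal(specific_rates(trn)$r_o2[1], n * specific_rates(tr1)$r_o2[1],
               tolerance = 1e-12)
  trn_reg <- simulate_batch(thn, oc0 = 1e-3, o2_0 = 5e-3, b0 = 1e-4,
                            times = c(0, 0.1), mode = "sxm_exm", v_h = VH)
  expect_equal(specific_rates(trn_reg)$r_o2[1], specific_rates(tr1)$r_o2[1],
               tolerance = 1e-12)
})

test_that("simulation inputs are validated", {
  th <- sim_pool()
  expect_error(simulate_batch(th, oc0 = -1e-3, o2_0 = 1e-3, b0 = 1e-6),
               "non-negative")
  expect_error(simulate_batch(th, oc0 = 1e-3, o2_0 = 1e-3, b0 = c(1, 1)),
               "single biomass")
  expect_error(simulate_batch(th, oc0 = 1e-3, o2_0 = 1e-3, b0 = c(1, 1),
                              mode = "sxm_mxm", mu_max = 1), "per guild")
  flagged <- compound_thermo_table(
    tibble::tibble(label = "overox", C = 1, H = 0, N = 0, O = 3, P = 0,
                   S = 0, charge = 0))
  expect_error(simulate_batch(flagged, oc0 = 1e-3, o2_0 = 1e-3, b0 = 1e-6),
               "flagged")
})

test_that("the scaling experiment separates regulated from unregulated rates", {
  pool <- compound_thermo_table(generate_formulas(zone_spec(300, seed = 11)))
  sizes <- seq(10, 100, by = 10)
  se <- scaling_experiment(pool, sizes, "sxm", seed = 2)
  # additivity: aggregate rate grows linearly through the origin
  fit <- stats::lm(specific_rate ~ 0 + n, data = se)
  ss_tot <- sum(se$specific_rate^2)
  expect_gt(1 - sum(stats::residuals(fit)^2) / ss_tot, 0.98)
  se_reg <- scaling_experiment(pool, sizes, "sxm_exm", seed = 2)
  expect_lt(max(se_reg$specific_rate) / min(se_reg$specific_rate), 1.5)
  # determinism and homogeneous-pool exactness
  expect_identical(scaling_experiment(pool, sizes, "sxm", seed = 2), se)
  hom <- compound_thermo_table(rep("C6H12O6", 100))
  se_hom <- scaling_experiment(hom, c(10, 40), "sxm", seed = 1)
  expect_equal(se_hom$specific_rate[2] / se_hom$specific_rate[1], 4)
  expect_error(scaling_experiment(pool, c(10, 1000)), "exceeds")
})
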