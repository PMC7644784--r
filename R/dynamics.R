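# Instantaneous rates at a given state, shared by the ODE right-hand side
# and by specific_rates() so the two can never drift apart.
#
# comp: thermo table rows (unflagged); oc: vector of compound concentrations;
# o2: scalar; b: biomass vector (length 1 except in mxm mode).
instant_rates <- function(comp, oc, o2, b, mode, mu_max, v_h) {
  abs_yoc <- abs(comp$y_oc)
  abs_yo2 <- abs(comp$y_o2)
  ocp <- pmax(oc, 0)
  o2p <- max(o2, 0)
  # exp(-|y|/(V_h [S])) -> 0 smoothly as [S] -> 0; guard the 0/0 corner.
  arg_c <- ifelse(ocp > 0, -abs_yoc / (v_h * ocp), -Inf)
  arg_o <- if (o2p > 0) -abs_yo2 / (v_h * o2p) else rep(-Inf, length(abs_yo2))
  ekin <- exp(arg_c + arg_o)

  if (mode == "sxm_mxm") {
    # guilds differ only in mu_max; stoichiometry is shared
    mu <- outer(ekin, mu_max)                  # n x g
    act <- drop(mu %*% b)                      # per-compound activity, conc/time
    db <- colSums(mu) * b
    u <- NULL
  } else {
    mukin <- mu_max[1] * ekin
    if (mode == "sxm_exm") {
      s <- sum(mukin)
      u <- if (s > 0) mukin / s else rep(0, length(mukin))
      mu_i <- u * mukin
    } else {
      u <- NULL
      mu_i <- mukin
    }
    act <- mu_i * b[1]
    db <- sum(mu_i) * b
    mu <- mu_i
  }
  list(doc = comp$y_oc * act,
       do2 = sum(comp$y_o2 * act),
       dhco3 = sum(comp$y_hco3 * act),
       db = db, act = act, mu = mu, u = u)
}

#' Batch simulation of multi-compound oxidative respiration
#'
#' Integrates the mass balances of each compound, dissolved oxygen,
#' bicarbonate and biomass in a homogeneous batch:
#' `d[OC_i]/dt = y_OC,i mu_i [B]`, `d[B]/dt = sum_i mu_i [B]`, and the
#' corresponding O2/HCO3- balances, with both harvest factors active
#' (`V_h [OC_i]` and `V_h [O2]` evolve with the state). Three modes:
#'
#' * `"sxm"`: every compound is consumed at its unregulated kinetic rate.
#' * `"sxm_exm"`: simplified cybernetic regulation; each kinetic rate is
#'   multiplied by the allocation weight `u_i` recomputed from the current
#'   state at every evaluation (no enzyme ODEs are integrated).
#' * `"sxm_mxm"`: multiple microbial guilds sharing stoichiometry but with
#'   guild-specific `mu_max_j`; one guild reproduces `"sxm"` exactly.
#'
#' Exponential kinetics approach zero smoothly with the substrate, so no
#' event handling is needed; concentrations stay non-negative to solver
#' tolerance.
#'
#' @param compounds Unflagged rows of a [compound_thermo_table()].
#' @param oc0 Initial compound concentrations, mol/L (recycled to the number
#'   of compounds if scalar).
#' @param o2_0 Initial dissolved O2, mol/L.
#' @param b0 Initial biomass, C-mol/L; a vector of guild biomasses in
#'   `"sxm_mxm"` mode.
#' @param hco3_0 Initial bicarbonate, mol/L.
#' @param times Output time grid.
#' @param mode Simulation mode, see Details.
#' @param mu_max Maximal specific growth rate (per-guild vector in mxm mode).
#' @param v_h Harvest volume (shared by all compounds and guilds).
#' @param rtol,atol Solver tolerances (deSolve lsoda).
#' @return An object of class `sxm_trajectory`: list with `times`, `state`
#'   (matrix with named columns), `compounds`, `mode`, `mu_max`, `v_h`. In
#'   `"sxm_exm"` mode the state matrix also carries the `u_i` time series.
#' @export
simulate_batch <- function(compounds, oc0, o2_0, b0, hco3_0 = 0,
                           times = seq(0, 1, length.out = 101),
                           mode = c("sxm", "sxm_exm", "sxm_mxm"),
                           mu_max = 1, v_h = 1, rtol = 1e-8, atol = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(compounds), nrow(compounds) >= 1L)
  if (any(nzchar(compounds$flags))) {
    stop_validation("flagged compounds cannot be simulated: %s",
                    paste(head(compounds$label[nzchar(compounds$flags)], 5),
                          collapse = ", "))
  }
  n <- nrow(compounds)
  oc0 <- rep_len(as.numeric(oc0), n)
  if (any(c(oc0, o2_0, hco3_0, b0) < 0)) {
    stop_validation("initial concentrations must be non-negative")
  }
  g <- if (mode == "sxm_mxm") length(b0) else 1L
  if (mode == "sxm_mxm" && length(mu_max) != g) {
    stop_validation("mxm mode needs one mu_max per guild biomass")
  }
  if (mode != "sxm_mxm" && length(b0) != 1L) {
    stop_validation("modes sxm and sxm_exm use a single biomass pool")
  }
  state0 <- c(oc0, o2_0, hco3_0, as.numeric(b0))
  names(state0) <- c(paste0("oc_", seq_len(n)), "o2", "hco3",
                     if (g == 1L) "b" else paste0("b_", seq_len(g)))
  deriv <- function(t, state, parms) {
    oc <- state[seq_len(n)]
    o2 <- state[[n + 1L]]
    b <- state[(n + 3L):(n + 2L + g)]
    r <- instant_rates(compounds, oc, o2, b, mode, mu_max, v_h)
    d <- c(r$doc, r$do2, r$dhco3, r$db)
    if (mode == "sxm_exm") {
      list(d, setNames(r$u, paste0("u_", seq_len(n))))
    } else {
      list(d)
    }
  }
  out <- tryCatch(
    deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol),
    warning = function(w) {
      stop(sprintf("ODE solver failed: %s", conditionMessage(w)))
    })
  m <- unclass(out)
  if (anyNA(m)) stop("ODE solver returned NA states; last valid row kept in output")
  structure(list(times = m[, "time"], state = m[, -1, drop = FALSE],
                 compounds = compounds, mode = mode, mu_max = mu_max,
                 v_h = v_h, n_compounds = n, n_guilds = g),
            class = "sxm_trajectory")
}

#' @export
print.sxm_trajectory <- function(x, ...) {
  cat(sprintf("<sxm_trajectory> mode %s: %d compounds, %d guild(s), %d time points\n",
              x$mode, x$n_compounds, x$n_guilds, length(x$times)))
  invisible(x)
}

#' @export
as.data.frame.sxm_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$state, check.names = FALSE)
}

#' Specific reaction rates along a trajectory
#'
#' Per-C-mol-biomass rates (state derivatives divided by total biomass)
#' recomputed algebraically at every stored state: specific growth `mu`,
#' total organic-carbon consumption `r_oc` (mol OC), carbon consumption
#' `r_c` (C-mol), oxygen consumption `r_o2` and bicarbonate production
#' `r_hco3`. Times with non-positive biomass are masked with `NA`.
#'
#' @param traj An [simulate_batch()] trajectory.
#' @return Tibble: `time`, `mu`, `r_oc`, `r_c`, `r_o2`, `r_hco3`.
#' @export
specific_rates <- function(traj) {
  stopifnot(inherits(traj, "sxm_trajectory"))
  n <- traj$n_compounds
  g <- traj$n_guilds
  comp <- traj$compounds
  rows <- lapply(seq_along(traj$times), function(i) {
    st <- traj$state[i, ]
    oc <- st[seq_len(n)]
    o2 <- st[[n + 1L]]
    b <- st[(n + 3L):(n + 2L + g)]
    btot <- sum(b)
    if (btot <= 0) {
      return(c(mu = NA_real_, r_oc = NA_real_, r_c = NA_real_,
               r_o2 = NA_real_, r_hco3 = NA_real_))
    }
    r <- instant_rates(comp, oc, o2, b, traj$mode, traj$mu_max, traj$v_h)
    c(mu = sum(r$db) / btot, r_oc = sum(r$doc) / btot,
      r_c = sum(comp$C * r$doc) / btot, r_o2 = r$do2 / btot,
      r_hco3 = r$dhco3 / btot)
  })
  m <- do.call(rbind, rows)
  tibble::tibble(time = traj$times, mu = m[, "mu"], r_oc = m[, "r_oc"],
                 r_c = m[, "r_c"], r_o2 = m[, "r_o2"], r_hco3 = m[, "r_hco3"])
}

#' Compound-count scaling of specific respiration
#'
#' Draws subsets of increasing size from a compound pool (seeded, without
#' replacement) and computes the aggregate specific O2 consumption rate at a
#' fixed harvest state for each subset. Without regulation the aggregate
#' specific rate grows linearly with the number of compounds (every compound
#' adds its full rate); under cybernetic regulation the allocation weights
#' renormalize and the rate stays nearly flat.
#'
#' @param pool A [compound_thermo_table()] (unflagged rows are used).
#' @param sizes Subset sizes to evaluate (at least 2, none exceeding the
#'   pool).
#' @param mode `"sxm"` (unregulated) or `"sxm_exm"` (cybernetic weights).
#' @param vh_oc,vh_o2 Fixed dimensionless harvest products applied to every
#'   compound.
#' @param mu_max Maximal specific growth rate.
#' @param seed Integer seed for the subset draws.
#' @return Tibble: `n`, `specific_rate` (|r_O2| per C-mol biomass).
#' @export
scaling_experiment <- function(pool, sizes, mode = c("sxm", "sxm_exm"),
                               vh_oc = 1, vh_o2 = 1, mu_max = 1, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(pool), length(sizes) >= 2L)
  pool <- pool[!nzchar(pool$flags), , drop = FALSE]
  if (max(sizes) > nrow(pool)) {
    stop_validation("requested subset size %d exceeds pool size %d",
                    max(sizes), nrow(pool))
  }
  sc <- scenario("both", vh_oc = vh_oc, vh_o2 = vh_o2)
  rates <- withr::with_seed(seed, {
    vapply(sizes, function(n) {
      idx <- sample.int(nrow(pool), n)
      mukin <- mu_kinetic(abs(pool$y_oc[idx]), abs(pool$y_o2[idx]), sc, mu_max)
      w <- if (mode == "sxm_exm") cybernetic_weights(mukin) else 1
      sum(abs(pool$y_o2[idx]) * w * mukin)
    }, numeric(1))
  })
  tibble::tibble(n = as.integer(sizes), specific_rate = rates)
}

#' Write a trajectory as tidy CSV
#'
#' One row per (time, variable) pair with columns `time`, `variable`,
#' `value`; variables are the state columns of the trajectory.
#'
#' @param traj An `sxm_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sxm_trajectory"))
  df <- as.data.frame(traj)
  long <- do.call(rbind, lapply(setdiff(names(df), "time"), function(v) {
    data.frame(time = df$time, variable = v, value = df[[v]])
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
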