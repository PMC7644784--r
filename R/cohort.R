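#' Standard limitation scenarios at one severity level
#'
#' Convenience set of the three limitation scenarios (C, O2, both) with all
#' active harvest products set to the same value: 1 for moderate and 0.2 for
#' severe limitation in the comparative analyses.
#'
#' @param vh Dimensionless harvest product applied to every active
#'   limitation.
#' @return Named list of [scenario()] objects (`C`, `O2`, `both`).
#' @export
limitation_scenarios <- function(vh = 1) {
  list(C = scenario("C", vh_oc = vh),
       O2 = scenario("O2", vh_o2 = vh),
       both = scenario("both", vh_oc = vh, vh_o2 = vh))
}

#' Per-sample aggregate of thermodynamic and kinetic indicators
#'
#' Aggregates the thermodynamic indicators (lambda, donor and catabolic
#' energies at both pH conventions) and the predicted rates under each
#' scenario (growth rate, |r_C|, |r_O2|, r_HCO3 with `mu_max = 1`) across
#' the compounds detected in one sample. Compounds are weighted equally
#' (presence/absence, as appropriate for normalized occurrence profiles)
#' unless intensity weights are supplied. Flagged compounds are excluded
#' and counted.
#'
#' @param thermo A [compound_thermo_table()] for one sample.
#' @param sample_id Identifier carried into the output.
#' @param stat Aggregation statistic, `"mean"` or `"median"`.
#' @param basis `"mol"` or `"cmol"`: per-C-mol divides each compound's donor
#'   and catabolic energies by its own carbon count before aggregation.
#' @param scenarios Named list of [scenario()] objects.
#' @param mu_max Maximal specific growth rate used for the rate aggregates.
#' @param weights Optional non-negative per-compound weights (e.g. FTICR
#'   intensities); default unweighted.
#' @return One-row tibble: `sample_id`, `n_compounds`, `n_excluded`,
#'   aggregated indicators, and `<scenario>_mu`, `<scenario>_r_c`,
#'   `<scenario>_r_o2`, `<scenario>_r_hco3` per scenario (consumption rates
#'   as absolute values).
#' @export
aggregate_sample <- function(thermo, sample_id = "sample",
                             stat = c("mean", "median"),
                             basis = c("mol", "cmol"),
                             scenarios = limitation_scenarios(1),
                             mu_max = 1, weights = NULL) {
  stat <- match.arg(stat)
  basis <- match.arg(basis)
  ok <- !nzchar(thermo$flags)
  if (!any(ok)) {
    stop_validation("sample '%s' has no usable (unflagged) compounds", sample_id)
  }
  tb <- thermo[ok, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(tb)) else weights[ok]
  if (any(w < 0) || all(w == 0)) {
    stop_validation("weights must be non-negative with a positive sum")
  }
  # weights enter the mean; the median path stays unweighted
  agg <- if (stat == "mean") {
    function(x) sum(w * x) / sum(w)
  } else {
    function(x) median(x)
  }
  div <- if (basis == "cmol") tb$C else 1
  out <- tibble::tibble(
    sample_id = sample_id,
    n_compounds = sum(ok), n_excluded = sum(!ok),
    lambda = agg(tb$lambda),
    dg_donor0 = agg(tb$dg_donor0 / div), dg_donor7 = agg(tb$dg_donor7 / div),
    dg_cat0 = agg(tb$dg_cat0 / div), dg_cat7 = agg(tb$dg_cat7 / div))
  for (nm in names(scenarios)) {
    rt <- rate_table(tb, scenarios[[nm]], mu_max = mu_max)
    out[[paste0(nm, "_mu")]] <- agg(rt$mu)
    out[[paste0(nm, "_r_c")]] <- agg(abs(rt$r_c))
    out[[paste0(nm, "_r_o2")]] <- agg(abs(rt$r_o2))
    out[[paste0(nm, "_r_hco3")]] <- agg(rt$r_hco3)
  }
  out
}

#' Correlate per-sample aggregates with measured respiration
#'
#' Pearson correlation of every numeric aggregate column against a measured
#' per-sample respiration proxy (e.g. a resazurin-reduction assay value).
#' Zero-variance columns (or respiration) yield `NA` with a warning rather
#' than an error. Correlations are reported with the sample count; no
#' p-value gatekeeping is applied.
#'
#' @param aggregates Tibble of per-sample rows (from [aggregate_sample()]),
#'   including `sample_id`.
#' @param respiration Either a numeric vector aligned with `aggregates`
#'   rows, or a data frame with columns `sample_id` and `respiration`.
#' @return Tibble: `metric`, `rho`, `n`.
#' @export
correlate_respiration <- function(aggregates, respiration) {
  stopifnot(is.data.frame(aggregates))
  if (is.data.frame(respiration)) {
    i <- match(aggregates$sample_id, respiration$sample_id)
    if (anyNA(i)) {
      stop_validation("respiration table is missing samples: %s",
                      paste(aggregates$sample_id[is.na(i)], collapse = ", "))
    }
    respiration <- respiration$respiration[i]
  }
  n <- nrow(aggregates)
  if (n < 3L || length(respiration) != n) {
    stop_validation("need >= 3 samples with both aggregates and respiration")
  }
  cols <- setdiff(names(aggregates)[vapply(aggregates, is.numeric, logical(1))],
                  c("n_compounds", "n_excluded"))
  rho <- vapply(cols, function(cn) {
    x <- aggregates[[cn]]
    if (stats::sd(x) == 0 || stats::sd(respiration) == 0 || anyNA(x)) {
      warning(sprintf("correlation undefined for '%s' (zero variance or NA)", cn))
      return(NA_real_)
    }
    cor(x, respiration, method = "pearson")
  }, numeric(1))
  tibble::tibble(metric = cols, rho = unname(rho), n = n)
}

#' Compare two samples (e.g. high- vs low-activity zones)
#'
#' Distribution summaries (quartiles and histograms) of lambda, the
#' catabolic and donor energies, and the predicted |r_O2| under each
#' limitation scenario, plus ratios of aggregate rates between the two
#' samples at each severity level. The empirical ordering of the rate
#' ratios is data-dependent and is reported, not asserted.
#'
#' @param thermo_a,thermo_b [compound_thermo_table()] results for the two
#'   samples.
#' @param sample_names Length-2 labels; ratios are `b / a`.
#' @param vh_levels Named severity levels (harvest products).
#' @param mu_max Maximal specific growth rate.
#' @param stat Aggregation statistic for the ratios.
#' @param bins Number of histogram bins.
#' @return List of class `sxm_zone_comparison`: `summary` (quartiles per
#'   sample and metric), `histograms` (bin mids and counts), `ratios`
#'   (level, limitation, metric, ratio).
#' @export
zone_compare <- function(thermo_a, thermo_b, sample_names = c("A", "B"),
                         vh_levels = c(moderate = 1, severe = 0.2),
                         mu_max = 1, stat = "mean", bins = 30) {
  samples <- list(thermo_a, thermo_b)
  names(samples) <- sample_names

  metric_values <- function(tb, level) {
    tb <- tb[!nzchar(tb$flags), , drop = FALSE]
    vals <- list(lambda = tb$lambda, dg_cat7 = tb$dg_cat7,
                 dg_donor7 = tb$dg_donor7)
    for (nm in names(limitation_scenarios(level))) {
      rt <- rate_table(tb, limitation_scenarios(level)[[nm]], mu_max)
      vals[[paste0("abs_r_o2_", nm)]] <- abs(rt$r_o2)
    }
    vals
  }

  sum_rows <- list(); hist_rows <- list(); ratio_rows <- list()
  for (lv in names(vh_levels)) {
    level <- vh_levels[[lv]]
    vals <- lapply(samples, metric_values, level = level)
    metrics <- names(vals[[1]])
    for (m in metrics) {
      rng <- range(unlist(lapply(vals, `[[`, m)), finite = TRUE)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      brk <- seq(rng[1], rng[2], length.out = bins + 1)
      for (s in sample_names) {
        x <- vals[[s]][[m]]
        q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
        sum_rows[[length(sum_rows) + 1L]] <- tibble::tibble(
          level = lv, sample = s, metric = m, q0 = q[1], q25 = q[2],
          q50 = q[3], q75 = q[4], q100 = q[5], mean = mean(x))
        h <- graphics::hist(x, breaks = brk, plot = FALSE)
        hist_rows[[length(hist_rows) + 1L]] <- tibble::tibble(
          level = lv, sample = s, metric = m, mid = h$mids, count = h$counts)
      }
    }
    aggs <- lapply(sample_names, function(s) {
      aggregate_sample(samples[[s]], sample_id = s, stat = stat,
                       scenarios = limitation_scenarios(level),
                       mu_max = mu_max)
    })
    for (nm in c("C", "O2", "both")) {
      for (m in c("mu", "r_c", "r_o2", "r_hco3")) {
        cn <- paste0(nm, "_", m)
        ratio_rows[[length(ratio_rows) + 1L]] <- tibble::tibble(
          level = lv, limitation = nm, metric = m,
          ratio = aggs[[2]][[cn]] / aggs[[1]][[cn]])
      }
    }
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 histograms = do.call(rbind, hist_rows),
                 ratios = do.call(rbind, ratio_rows),
                 sample_names = sample_names),
            class = "sxm_zone_comparison")
}

#' @export
print.sxm_zone_comparison <- function(x, ...) {
  cat(sprintf("<sxm_zone_comparison> %s vs %s\n", x$sample_names[1],
              x$sample_names[2]))
  cat("rate ratios (", x$sample_names[2], "/", x$sample_names[1], "):\n")
  print(as.data.frame(x$ratios))
  invisible(x)
}
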