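#' Read a table of assigned molecular formulae
#'
#' Reads a CSV (or TSV, auto-detected from the `.tsv`/`.txt` extension) with
#' either a `formula` column in the Hill-style string dialect or
#' element-count columns `C,H,N,O,P,S` (case-insensitive; `N`, `P`, `S`
#' optional), plus optional `charge`, `label`, `sample_id` and `intensity`
#' columns. Exactly one of the two dialects must be present: having both or
#' neither is a configuration error, never a guess. Unparseable rows are
#' collected into a rejects report with their line numbers rather than being
#' silently dropped.
#'
#' @param path Input file.
#' @return List: `formulas` (tibble: `label`, counts, `charge`, plus any
#'   `sample_id`/`intensity` passthrough) and `rejects` (tibble: `line`,
#'   `content`, `reason`).
#' @export
read_formula_table <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop_validation("empty formula table: %s", path)
  lower <- tolower(names(raw))
  has_formula <- "formula" %in% lower
  has_counts <- all(c("c", "h") %in% lower) && "o" %in% lower
  if (has_formula && has_counts) {
    stop_validation("ambiguous dialect in %s: both a formula column and count columns", path)
  }
  if (!has_formula && !has_counts) {
    stop_validation("unresolvable header in %s: need a 'formula' column or C,H,O count columns", path)
  }
  col <- function(nm) if (nm %in% lower) raw[[names(raw)[match(nm, lower)]]] else NULL
  charge <- col("charge") %||% rep(0, nrow(raw))
  labels <- col("label") %||% (if (has_formula) col("formula") else NULL)

  keep <- logical(nrow(raw))
  rej <- list()
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch({
      if (has_formula) {
        f <- parse_formula(col("formula")[i], charge = charge[i],
                           label = if (is.null(labels)) col("formula")[i] else labels[i])
      } else {
        f <- mol_formula(as.numeric(col("c")[i]), as.numeric(col("h")[i]),
                         as.numeric(col("n")[i] %||% 0), as.numeric(col("o")[i]),
                         as.numeric(col("p")[i] %||% 0), as.numeric(col("s")[i] %||% 0),
                         charge = as.numeric(charge[i]),
                         label = if (is.null(labels)) NULL else labels[i])
      }
      f
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rej[[length(rej) + 1L]] <- tibble::tibble(
        line = i + 1L,  # header occupies line 1
        content = if (has_formula) as.character(col("formula")[i])
                  else paste0("C", col("c")[i], "H", col("h")[i], "O", col("o")[i]),
        reason = conditionMessage(res))
    } else {
      keep[i] <- TRUE
      rows[[i]] <- res
    }
  }
  formulas <- as_formula_table(rows[keep])
  for (extra in c("sample_id", "intensity")) {
    v <- col(extra)
    if (!is.null(v)) formulas[[extra]] <- v[keep]
  }
  list(formulas = formulas,
       rejects = if (length(rej)) do.call(rbind, rej)
                 else tibble::tibble(line = integer(), content = character(),
                                     reason = character()))
}

#' Write a thermodynamic profile table
#'
#' One row per compound with a stable column order (identifiers, element
#' counts, charge, electron equivalents, NOSC, the Gibbs-energy chain at
#' both pH conventions, `m`, lambda, dissipation energy, the ten metabolic
#' coefficients and the quality flags), floats at 6 significant digits.
#'
#' @param profiles Tibble from [compound_thermo_table()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_thermo_table <- function(profiles, path) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  cols <- c("label", "C", "H", "N", "O", "P", "S", "charge", "n_e", "nosc",
            "dg_cox0", "dg_donor0", "dg_donor7", "dg_f_oc", "dg_cat0",
            "dg_cat7", "dg_ana0", "dg_ana7", "m", "lambda", "dg_dis",
            "y_oc", "y_h2o", "y_hco3", "y_nh4", "y_hpo4", "y_hs", "y_h",
            "y_e", "y_o2", "y_biom", "flags")
  missing <- setdiff(cols, names(profiles))
  if (length(missing)) {
    stop_validation("profiles table is missing columns: %s",
                    paste(missing, collapse = ", "))
  }
  out <- profiles[, cols]
  for (cn in cols) {
    if (is.numeric(out[[cn]])) out[[cn]] <- signif(out[[cn]], 6)
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [generate_cohort()] result as the same CSV dialect the
#' reader consumes: one formula table per sample under `dir/samples/`, a
#' `respiration.csv` (sample_id, respiration, zone), and a provenance
#' sidecar `truth.csv` recording the generating parameters and per-sample
#' mean lambda.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.list(cohort), all(c("samples", "respiration") %in% names(cohort)))
  sdir <- file.path(dir, "samples")
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$samples)) {
    # formula-string dialect only, so the reader resolves it unambiguously
    tab <- cohort$samples[[id]][, c("label", "formula", "charge")]
    write.csv(tab, file.path(sdir, paste0(id, ".csv")), row.names = FALSE)
  }
  write.csv(cohort$respiration, file.path(dir, "respiration.csv"),
            row.names = FALSE)
  tr <- cohort$truth
  truth <- data.frame(key = c("alpha", "link_strength", "noise_sd", "seed",
                              paste0("lambda_bar_", names(tr$lambda_bar))),
                      value = c(tr$alpha, tr$link_strength, tr$noise_sd,
                                tr$seed, unname(tr$lambda_bar)))
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
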