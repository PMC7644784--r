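#' Molecular formula objects
#'
#' A `mol_formula` holds the CHNOPS element counts and net charge of one
#' organic compound. Counts must be whole numbers unless `fractional = TRUE`,
#' which exists for per-C-mol biomass compositions such as CH1.8N0.2O0.5.
#' Every compound entering the pipeline must contain at least one carbon.
#'
#' @param c_count,h_count,n_count,o_count,p_count,s_count Non-negative element
#'   counts (carbon, hydrogen, nitrogen, oxygen, phosphorus, sulfur).
#' @param charge Net charge of the compound, sign included (anions negative).
#' @param label Free-text identifier; defaults to the canonical formula string.
#' @param fractional Allow non-integer counts (biomass-style compositions).
#'
#' @return An object of class `mol_formula`: a list with fields `C`, `H`, `N`,
#'   `O`, `P`, `S`, `charge`, `label`.
#' @examples
#' mol_formula(6, 12, o_count = 6)          # glucose
#' parse_formula("C2H5NO2", label = "glycine")
#' @export
mol_formula <- function(c_count, h_count = 0, n_count = 0, o_count = 0,
                        p_count = 0, s_count = 0, charge = 0,
                        label = NULL, fractional = FALSE) {
  counts <- c(C = c_count, H = h_count, N = n_count, O = o_count,
              P = p_count, S = s_count)
  if (!all(is.finite(counts)) || any(counts < 0)) {
    stop_validation("element counts must be finite and non-negative")
  }
  if (!fractional && !all(is_whole(counts))) {
    stop_validation("fractional element counts require fractional = TRUE")
  }
  if (counts[["C"]] <= 0) stop_validation("no carbon: every compound must contain C")
  if (!is.finite(charge) || (!fractional && !is_whole(charge))) {
    stop_validation("charge must be a finite integer")
  }
  out <- structure(
    list(C = unname(counts[["C"]]), H = unname(counts[["H"]]),
         N = unname(counts[["N"]]), O = unname(counts[["O"]]),
         P = unname(counts[["P"]]), S = unname(counts[["S"]]),
         charge = unname(charge), label = NULL),
    class = "mol_formula")
  out$label <- label %||% format_formula(out)
  out
}

#' Parse a molecular formula string
#'
#' Accepts the Hill-style single-letter dialect used by FTICR-MS assigned
#' formula reports: element symbols among C, H, N, O, P, S, each followed by
#' an optional count (default 1). No parentheses, isotopes or hydration dots.
#' Symbols outside CHNOPS are rejected rather than silently dropped, since
#' dropping atoms would corrupt every downstream element balance.
#'
#' @param text Formula string, e.g. `"C6H12O6"`.
#' @param charge Net charge (the string itself carries no charge information).
#' @param label Identifier kept with the compound; defaults to `text`.
#' @param fractional Allow decimal counts (biomass compositions only).
#' @return A [mol_formula].
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CHO2", charge = -1, label = "formate")
#' parse_formula("CH1.8N0.2O0.5", fractional = TRUE)
#' @export
parse_formula <- function(text, charge = 0, label = text, fractional = FALSE) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop_validation("formula text must be a single non-empty string")
  }
  pat <- "([A-Z][a-z]?)([0-9]*\\.?[0-9]*)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (paste(tokens, collapse = "") != text) {
    stop_validation("cannot parse formula '%s': unexpected characters", text)
  }
  counts <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  for (tok in tokens) {
    sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    num <- sub("^[A-Z][a-z]?", "", tok)
    if (!sym %in% names(counts)) {
      stop_validation("unknown element symbol '%s' in formula '%s'", sym, text)
    }
    n <- if (nzchar(num)) as.numeric(num) else 1
    if (!fractional && !is_whole(n)) {
      stop_validation("fractional count '%s' in '%s' requires fractional = TRUE",
                      num, text)
    }
    counts[sym] <- counts[sym] + n
  }
  mol_formula(counts[["C"]], counts[["H"]], counts[["N"]], counts[["O"]],
              counts[["P"]], counts[["S"]], charge = charge, label = label,
              fractional = fractional)
}

#' Canonical formula string
#'
#' Formats element counts in Hill order for organic compounds (C, H, then
#' N, O, P, S alphabetically), omitting absent elements and unit counts.
#'
#' @param f A [mol_formula].
#' @return A single string; `format(parse_formula(x)) == x` for canonical input.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  parts <- vapply(c("C", "H", "N", "O", "P", "S"), function(el) {
    n <- f[[el]]
    if (n == 0) return("")
    if (n == 1) return(el)
    paste0(el, format(n, trim = TRUE, scientific = FALSE))
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
format.mol_formula <- function(x, ...) format_formula(x)

#' @export
print.mol_formula <- function(x, ...) {
  chg <- if (x$charge == 0) "" else sprintf(" (charge %+g)", x$charge)
  cat(sprintf("<mol_formula> %s%s  [%s]\n", format_formula(x), chg, x$label))
  invisible(x)
}

# Vectorized electron bookkeeping over raw count columns; shared by the
# scalar accessors and the batch thermodynamic chain.
ne_counts <- function(C, H, N, O, P, S, charge = 0) {
  -charge + 4 * C + H - 3 * N - 2 * O + 5 * P - 2 * S
}

nosc_counts <- function(C, H, N, O, P, S, charge = 0) {
  4 - ne_counts(C, H, N, O, P, S, charge) / C
}

#' Electron equivalents of complete oxidation
#'
#' Number of electrons transferred in the compound's oxidation half reaction
#' (oxidation to bicarbonate, with N released as ammonium, P as hydrogen
#' phosphate and S as bisulfide): `n_e = -z + 4C + H - 3N - 2O + 5P - 2S`.
#' Equals the electron coefficient of [donor_half_reaction()] by construction.
#' Compounds with `n_e <= 0` are not oxidizable in this framework and are
#' flagged (not errored) downstream.
#'
#' @param f A [mol_formula].
#' @return Number of transferred electrons (may be fractional for biomass
#'   compositions, e.g. 4.2 for CH1.8N0.2O0.5).
#' @examples
#' electron_equivalents(parse_formula("C6H12O6")) # 24
#' electron_equivalents(parse_formula("CH4"))     # 8
#' @export
electron_equivalents <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  ne_counts(f$C, f$H, f$N, f$O, f$P, f$S, f$charge)
}

#' Nominal oxidation state of carbon
#'
#' `NOSC = 4 - n_e / C`. Higher values mean more oxidized carbon; values for
#' natural organic matter typically fall in about \[-2, 2\], and anything
#' outside \[-4, 4\] is flagged as a quality warning in batch processing.
#'
#' @param f A [mol_formula].
#' @return NOSC, dimensionless.
#' @examples
#' nosc(parse_formula("CH4"))      # -4
#' nosc(parse_formula("C6H12O6"))  #  0
#' @export
nosc <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  4 - electron_equivalents(f) / f$C
}

# Normalize user input (character vector, data frame of counts or of formula
# strings, list of mol_formula) into a count table with one row per compound.
as_formula_table <- function(x) {
  if (inherits(x, "mol_formula")) x <- list(x)
  if (is.character(x)) {
    x <- lapply(seq_along(x), function(i) parse_formula(x[[i]]))
  }
  if (is.list(x) && !is.data.frame(x)) {
    ok <- vapply(x, inherits, logical(1), what = "mol_formula")
    if (!all(ok)) stop_validation("list input must contain only mol_formula objects")
    return(tibble::tibble(
      label = vapply(x, function(f) f$label, character(1)),
      C = vapply(x, `[[`, numeric(1), "C"),
      H = vapply(x, `[[`, numeric(1), "H"),
      N = vapply(x, `[[`, numeric(1), "N"),
      O = vapply(x, `[[`, numeric(1), "O"),
      P = vapply(x, `[[`, numeric(1), "P"),
      S = vapply(x, `[[`, numeric(1), "S"),
      charge = vapply(x, `[[`, numeric(1), "charge")))
  }
  if (is.data.frame(x)) {
    nm <- names(x)
    lower <- tolower(nm)
    if ("formula" %in% lower) {
      fcol <- nm[match("formula", lower)]
      zcol <- if ("charge" %in% lower) x[[nm[match("charge", lower)]]] else 0
      lab <- if ("label" %in% lower) x[[nm[match("label", lower)]]] else x[[fcol]]
      fl <- lapply(seq_len(nrow(x)), function(i) {
        parse_formula(x[[fcol]][i],
                      charge = if (length(zcol) > 1) zcol[i] else zcol,
                      label = lab[i])
      })
      return(as_formula_table(fl))
    }
    need <- c("c", "h", "n", "o", "p", "s")
    idx <- match(need, lower)
    if (any(is.na(idx[c(1, 2)]))) {
      stop_validation("data frame input needs a 'formula' column or element count columns")
    }
    get0 <- function(i) if (is.na(i)) 0 else x[[nm[i]]]
    tab <- tibble::tibble(
      label = if ("label" %in% lower) as.character(x[[nm[match("label", lower)]]]) else NA_character_,
      C = as.numeric(get0(idx[1])), H = as.numeric(get0(idx[2])),
      N = as.numeric(get0(idx[3])), O = as.numeric(get0(idx[4])),
      P = as.numeric(get0(idx[5])), S = as.numeric(get0(idx[6])),
      charge = as.numeric(if ("charge" %in% lower) x[[nm[match("charge", lower)]]] else 0))
    if (any(!is.finite(tab$C)) || any(tab$C < 1)) {
      stop_validation("no carbon: rows %s have C < 1",
                      paste(which(!is.finite(tab$C) | tab$C < 1), collapse = ", "))
    }
    if (all(is.na(tab$label))) {
      tab$label <- vapply(seq_len(nrow(tab)), function(i) {
        format_formula(mol_formula(tab$C[i], tab$H[i], tab$N[i], tab$O[i],
                                   tab$P[i], tab$S[i], charge = tab$charge[i],
                                   fractional = TRUE))
      }, character(1))
    }
    return(tab)
  }
  stop_validation("unsupported input type for a formula table")
}
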