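#' Grape must composition
#'
#' Bundles the enological characteristics of a grape must: fermentable sugar,
#' yeast-assimilable nitrogen, malic acid, pH and sulfite content. These are
#' the quantities routinely reported by wine analysis laboratories and they
#' drive both the stoichiometric CO2 ceiling of the fermentation
#' ([theoretical_co2_max()]) and the antimicrobial pressure at inoculation
#' ([molecular_so2()]).
#'
#' @param code Short label for the must (e.g. `"M14"` for Merlot 2014).
#' @param sugar Hexose (glucose + fructose) concentration, g/L. Must be >= 0.
#' @param assimilable_nitrogen Yeast-assimilable nitrogen, mg N/L.
#' @param malic_acid Malic acid, g/L.
#' @param ph Must pH (0 < pH < 14).
#' @param total_so2 Total SO2, mg/L.
#' @param free_so2 Free SO2, mg/L; cannot exceed `total_so2`.
#' @param active_so2 Molecular ("active") SO2, mg/L. If `NA` (default) it is
#'   computed from `free_so2` and `ph` with [molecular_so2()].
#'
#' @return An object of class `must_composition`: a one-row list with the
#'   fields above, `active_so2` filled in.
#' @seealso [read_must_table()] to load a laboratory table of musts.
#' @examples
#' m14 <- must_composition("M14", sugar = 207, assimilable_nitrogen = 111,
#'                         malic_acid = 2.1, ph = 3.58,
#'                         total_so2 = 37, free_so2 = 29)
#' m14$active_so2   # 0.54 mg/L
#' @export
must_composition <- function(code, sugar, assimilable_nitrogen = NA_real_,
                             malic_acid = NA_real_, ph, total_so2 = NA_real_,
                             free_so2 = 0, active_so2 = NA_real_) {
  stopifnot(is.character(code), length(code) == 1L)
  sugar <- as.numeric(sugar)
  ph <- as.numeric(ph)
  free_so2 <- as.numeric(free_so2)
  if (!is.finite(sugar) || sugar < 0)
    stop("'sugar' must be a non-negative number (g/L)")
  if (!is.finite(ph) || ph <= 0 || ph >= 14)
    stop("'ph' must lie strictly between 0 and 14")
  if (!is.finite(free_so2) || free_so2 < 0)
    stop("'free_so2' must be a non-negative number (mg/L)")
  if (is.finite(total_so2) && free_so2 > total_so2)
    stop("'free_so2' cannot exceed 'total_so2'")
  if (is.na(active_so2))
    active_so2 <- molecular_so2(free_so2, ph)
  structure(list(code = code, sugar = sugar,
                 assimilable_nitrogen = as.numeric(assimilable_nitrogen),
                 malic_acid = as.numeric(malic_acid), ph = ph,
                 total_so2 = as.numeric(total_so2), free_so2 = free_so2,
                 active_so2 = active_so2),
            class = "must_composition")
}

#' @export
print.must_composition <- function(x, ...) {
  cat(sprintf("Grape must %s: sugar %.0f g/L (tCO2max %.1f g/L), pH %.2f\n",
              x$code, x$sugar, theoretical_co2_max(x$sugar), x$ph))
  cat(sprintf("  N %s mgN/L, malic %s g/L, SO2 total/free/active %s/%s/%.2f mg/L\n",
              format(x$assimilable_nitrogen), format(x$malic_acid),
              format(x$total_so2), format(x$free_so2), x$active_so2))
  invisible(x)
}

#' Theoretical maximum CO2 release of a must
#'
#' The stoichiometric ceiling on CO2 production by complete alcoholic
#' fermentation, `tCO2max = 0.482 * [sugar]` g/L. All threshold-based kinetic
#' parameters (t35, t50, t80 and the derived hexose consumption rate) are
#' defined relative to this quantity, so it is computed from the must
#' composition, never from the observed curve.
#'
#' @param sugar Hexose concentration of the must, g/L (scalar or vector,
#'   all values >= 0).
#' @return Theoretical maximum CO2, g/L (same length as `sugar`).
#' @examples
#' theoretical_co2_max(194)  # 93.508
#' @export
theoretical_co2_max <- function(sugar) {
  sugar <- as.numeric(sugar)
  if (any(!is.finite(sugar)) || any(sugar < 0))
    stop("'sugar' must be finite and non-negative (g/L)")
  0.482 * sugar
}

#' Molecular (active) SO2 from free SO2 and pH
#'
#' Estimates the molecular fraction of free SO2 -- the species with
#' antimicrobial activity against yeast -- by a single Henderson-Hasselbalch
#' dissociation: `free_so2 / (1 + 10^(pH - pKa_eff))`. A single effective
#' pKa folds in the temperature (24 C) and trace-ethanol corrections that a
#' full speciation model would apply; the default `pka_eff = 1.86` is the
#' least-squares calibration of this one-parameter model against the five
#' laboratory-reported active-SO2 values of the reference must panel, which
#' it reproduces within about 0.01 mg/L.
#'
#' @param free_so2 Free SO2, mg/L (scalar or vector, >= 0).
#' @param ph Must pH (recycled against `free_so2`).
#' @param pka_eff Effective dissociation constant. Default 1.86.
#' @param digits Decimal places for the returned value; the laboratory
#'   convention is 2. Use `NULL` to skip rounding.
#' @return Molecular SO2, mg/L.
#' @examples
#' molecular_so2(29, 3.58)  # 0.54 (Merlot 2014)
#' @export
molecular_so2 <- function(free_so2, ph, pka_eff = 1.86, digits = 2) {
  free_so2 <- as.numeric(free_so2)
  ph <- as.numeric(ph)
  if (any(!is.finite(free_so2)) || any(free_so2 < 0))
    stop("'free_so2' must be finite and non-negative (mg/L)")
  if (any(!is.finite(ph))) stop("'ph' must be finite")
  out <- free_so2 / (1 + 10^(ph - pka_eff))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Read a must composition table
#'
#' Reads a CSV/TSV laboratory table with columns `code`, `sugar_g_L`,
#' `nitrogen_mgN_L`, `malic_g_L`, `pH`, `total_SO2_mg_L`, `free_SO2_mg_L`
#' and optionally `active_SO2_mg_L` (computed via [molecular_so2()] when
#' absent). The panel of five Bordeaux musts used throughout the package
#' examples ships as `system.file("extdata", "grape_musts.csv",
#' package = "fermphen")`.
#'
#' @param path Path to the table; the field separator is sniffed from the
#'   header line (comma or tab).
#' @return A list of [must_composition()] objects, named by must code.
#' @export
read_must_table <- function(path) {
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("code", "sugar_g_L", "pH", "free_SO2_mg_L")
  if (!all(req %in% names(df)))
    stop("must table lacks required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  col <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA_real_, nrow(df))
  active <- col("active_SO2_mg_L")
  musts <- lapply(seq_len(nrow(df)), function(i)
    must_composition(code = as.character(df$code[i]), sugar = df$sugar_g_L[i],
                     assimilable_nitrogen = col("nitrogen_mgN_L")[i],
                     malic_acid = col("malic_g_L")[i], ph = df$pH[i],
                     total_so2 = col("total_SO2_mg_L")[i],
                     free_so2 = df$free_SO2_mg_L[i],
                     active_so2 = active[i]))
  names(musts) <- vapply(musts, `[[`, "", "code")
  musts
}
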