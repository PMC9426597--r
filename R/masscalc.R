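# Monoisotopic mass and adduct m/z arithmetic for the LC-MS verification
# of bai pathway intermediates (cholyl-CoA and 3-oxo-cholyl-CoA from
# cholic acid plus coenzyme A). Electron mass is neglected throughout
# (proton-mass convention); printed instrument values carry calibration
# offsets, hence agreement is judged in ppm.

# NIST/CODATA monoisotopic masses (Da)
MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, P = 30.97376163, S = 31.97207100,
               Na = 22.9897692809)
PROTON_MASS <- 1.007276467
# sodium cation = Na minus one electron
NA_CATION_MASS <- 22.9897692809 - 0.00054857991

#' Parse a molecular formula in Hill notation
#'
#' @param x a formula string over C, H, N, O, P, S, Na (e.g.
#'   `"C24H40O5"`), or an already-parsed formula.
#' @return a `mol_formula`: named integer vector of element counts.
#' @export
mol_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  if (is.numeric(x)) {
    counts <- x
  } else {
    if (!grepl("^([A-Z][a-z]?\\d*)+$", x))
      stop("unparseable formula: ", x)
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)(\\d*)", x))[[1]]
    el <- sub("\\d+$", "", toks)
    n <- as.integer(ifelse(grepl("\\d+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
    counts <- tapply(n, el, sum)
  }
  bad <- setdiff(names(counts), names(MONO_MASS))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  counts <- counts[counts > 0]
  if (!length(counts) || sum(counts) < 1) stop("formula has no atoms")
  structure(setNames(as.integer(counts), names(counts)),
            class = "mol_formula")
}

formula_add <- function(a, b, sign = 1L) {
  a <- mol_formula(a); b <- mol_formula(b)
  els <- union(names(a), names(b))
  out <- setNames(integer(length(els)), els)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + sign * b
  if (any(out < 0)) stop("negative element count after arithmetic")
  mol_formula(out[out > 0])
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope masses (NIST values, >= 6 decimals).
#'
#' @param f formula string or `mol_formula`.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  f <- mol_formula(f)
  sum(MONO_MASS[names(f)] * as.numeric(f))
}

#' Thioester condensation of a bile acid with coenzyme A
#'
#' Sum of the two formulas minus H2O (the condensation water). The acid
#' must carry a carboxyl group (at least one O and two H).
#'
#' @param acid formula of the free acid (default cholic acid C24H40O5).
#' @param coa formula of coenzyme A (C21H36N7O16P3S).
#' @return the conjugate `mol_formula` (e.g. cholyl-CoA C45H74N7O20P3S).
#' @export
condense_thioester <- function(acid = "C24H40O5",
                               coa = "C21H36N7O16P3S") {
  acid <- mol_formula(acid); coa <- mol_formula(coa)
  o <- if ("O" %in% names(acid)) acid[["O"]] else 0L
  h <- if ("H" %in% names(acid)) acid[["H"]] else 0L
  if (o < 1 || h < 2)
    stop("acid must contain a carboxyl group (>= 1 O, >= 2 H)")
  formula_add(formula_add(acid, coa), "H2O", sign = -1L)
}

#' Oxidize a 3-hydroxyl to a 3-oxo group (remove H2)
#' @param f formula string or `mol_formula`.
#' @return the dehydrogenated `mol_formula`.
#' @export
oxidize_3oh <- function(f) formula_add(f, "H2", sign = -1L)

#' Adduct m/z of a neutral formula
#'
#' Singly charged adducts: `[M+H]+ = M + 1.007276`,
#' `[M-H]- = M - 1.007276`, `[M+Na]+ = M + 22.989218`.
#'
#' @param f neutral formula string or `mol_formula`.
#' @param adduct one of `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"` (the ASCII
#'   hyphen is accepted for the minus sign).
#' @return m/z (z = 1).
#' @export
adduct_mz <- function(f, adduct = "[M+H]+") {
  m <- monoisotopic_mass(f)
  switch(adduct,
         "[M+H]+" = m + PROTON_MASS,
         "[M-H]-" = m - PROTON_MASS,
         "[M+Na]+" = m + NA_CATION_MASS,
         stop("unsupported adduct: ", adduct))
}

#' Formulas of the verified bai pathway analytes
#'
#' Cholic acid, coenzyme A, and the BaiB/BaiA reaction products
#' cholyl-CoA and 3-oxo-cholyl-CoA.
#'
#' @return named list of `mol_formula` objects.
#' @export
bai_analytes <- function() {
  cholic <- mol_formula("C24H40O5")
  coa <- mol_formula("C21H36N7O16P3S")
  cholyl_coa <- condense_thioester(cholic, coa)
  list(cholic_acid = cholic, coenzyme_a = coa,
       cholyl_coa = cholyl_coa,
       oxo_cholyl_coa = oxidize_3oh(cholyl_coa))
}
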