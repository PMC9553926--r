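#' Element mass table
#'
#' Monoisotopic and average masses (Da) for the elements used in RNA
#' chemistry, plus the stable isotope label \code{"18O"}. The heavy oxygen
#' is carried as a distinct element symbol so that labeled and unlabeled
#' species coexist in one formula without special-casing masses.
#'
#' @param scale `"monoisotopic"` or `"average"`.
#' @return Named numeric vector of element masses in Da.
#' @examples
#' element_masses()[["18O"]] - element_masses()[["O"]]  # ~2.00425
#' @export
element_masses <- function(scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  if (scale == "monoisotopic") {
    c(H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
      P = 30.97376163, S = 31.97207100, `18O` = 17.9991610)
  } else {
    c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
      P = 30.973762, S = 32.065, `18O` = 17.999161)
  }
}

#' Mass of a proton (Da), used for [M-H]- / [M+H]+ ion adjustment.
#' @export
PROTON_MASS <- 1.007276467

#' Parse a molecular formula string
#'
#' Accepts Hill-style formulas such as `"C9H12N3O7P"`. Isotope labels are
#' written in brackets: `"C9H11N2O7[18O]P"` is a uridine residue with one
#' heavy oxygen.
#'
#' @param x Formula string.
#' @return Named integer vector of element counts (class `chem_formula`).
#' @examples
#' parse_formula("C3H3N")   # cyanoethyl adduct
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  counts <- integer(0)
  rest <- x
  pat <- "^(\\[([0-9]+[A-Z][a-z]?)\\]|[A-Z][a-z]?)([0-9]*)"
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec(pat, rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop("malformed formula: '", x, "' (at '", rest, "')")
    sym <- if (nzchar(m[3])) m[3] else m[2]
    n <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    rest <- substr(rest, nchar(m[1]) + 1L, nchar(rest))
  }
  new_formula(counts)
}

new_formula <- function(counts) {
  counts <- counts[counts != 0L]
  storage.mode(counts) <- "integer"
  structure(counts, class = "chem_formula")
}

#' Combine formulas by element-wise addition or subtraction
#'
#' @param f1,f2 Formulas (named integer vectors from [parse_formula()]).
#' @param check If `TRUE` (default for subtraction), negative counts in the
#'   result raise an error — chemistry deltas must never overdraw a molecule.
#' @return A `chem_formula`.
#' @export
formula_add <- function(f1, f2) {
  els <- union(names(f1), names(f2))
  out <- vapply(els, function(e) {
    (if (e %in% names(f1)) f1[[e]] else 0L) +
      (if (e %in% names(f2)) f2[[e]] else 0L)
  }, integer(1))
  new_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2, check = TRUE) {
  els <- union(names(f1), names(f2))
  out <- vapply(els, function(e) {
    (if (e %in% names(f1)) f1[[e]] else 0L) -
      (if (e %in% names(f2)) f2[[e]] else 0L)
  }, integer(1))
  if (check && any(out < 0L))
    stop("formula subtraction yields negative count for: ",
         paste(els[out < 0L], collapse = ", "))
  new_formula(out)
}

#' Mass of a formula
#'
#' @param formula A `chem_formula` or formula string.
#' @param scale `"monoisotopic"` (default) or `"average"`.
#' @return Mass in Da; the empty formula has mass 0.
#' @examples
#' mass_of("H2O")              # 18.01056
#' mass_of("C3H3N")            # 53.0266, the cyanoethyl adduct
#' @export
mass_of <- function(formula, scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  tab <- element_masses(scale)
  unknown <- setdiff(names(formula), names(tab))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(tab[names(formula)] * as.numeric(formula))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0L) return("(empty)")
  ord <- c("C", "H", setdiff(sort(names(x)), c("C", "H")))
  ord <- ord[ord %in% names(x)]
  paste0(vapply(ord, function(e) {
    sym <- if (grepl("^[0-9]", e)) paste0("[", e, "]") else e
    paste0(sym, if (x[[e]] != 1L) x[[e]] else "")
  }, character(1)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (mono ",
      sprintf("%.5f", mass_of(x)), " Da)\n", sep = "")
  invisible(x)
}

# Shared chemistry deltas
CYANOETHYL <- "C3H3N"      # acrylonitrile adduct on Psi, +53.0266 Da
H2O <- "H2O"
HPO3 <- "HO3P"             # phosphate bridge / terminal phosphate
RIBOSE_LOSS <- "C5H8O4"    # default MRM neutral loss (132.0423 Da)

#' Mass difference installed by swapping one 16O for 18O (Da)
#' @export
o18_mass_shift <- function() {
  em <- element_masses()
  em[["18O"]] - em[["O"]]
}
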