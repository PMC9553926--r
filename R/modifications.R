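#' Modification vocabulary
#'
#' The residue-level vocabulary shared by all stages: short codes for
#' canonical and modified residues, their internal-chain residue formulas
#' (nucleoside monophosphate minus water, i.e. one phosphate per residue),
#' and the chemistry flags the pipeline consults (RNase cleavage behaviour,
#' cyanoethylation reactivity, MRM product-ion override). The table ships as
#' a TSV under `extdata/modifications.tsv`; codes map 1:1 onto MODOMICS
#' short names (`Y` = pseudouridine, `D` = dihydrouridine, `Q` = queuosine,
#' `m5U` = 5-methyluridine / ribothymidine, `ms2io6A` =
#' 2-methylthio-N6-(cis-hydroxyisopentenyl)adenosine). Heavy-oxygen
#' deamination products carry the `18` suffix (`U18`, `Y18`).
#'
#' @param path Optional path to an alternative modification table with the
#'   same columns; defaults to the table shipped with the package.
#' @return A data.frame with one row per code.
#' @export
modification_table <- function(path = NULL) {
  if (is.null(path)) {
    cached <- get0("mod_table", envir = .pseudomap_cache)
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "modifications.tsv", package = "pseudomap",
                        mustWork = TRUE)
    tab <- read_mod_table(path)
    assign("mod_table", tab, envir = .pseudomap_cache)
    return(tab)
  }
  read_mod_table(path)
}

.pseudomap_cache <- new.env(parent = emptyenv())

read_mod_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("code", "name", "formula", "parent", "pyrimidine_derived",
            "guanosine_derived", "ce_reactive", "rnase_a_site",
            "rnase_t1_site", "deamination_product", "mrm_loss")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("modification table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$code))
    stop("duplicate codes in modification table")
  tab
}

mod_row <- function(code, table = modification_table()) {
  i <- match(code, table$code)
  if (is.na(i)) stop("unknown residue code: '", code, "'")
  table[i, , drop = FALSE]
}

#' Internal-residue formula for a residue code
#'
#' The residue formula is the nucleoside 5'-monophosphate minus water, so a
#' chain of n residues plus one water gives the neutral 5'-OH /
#' 3'-phosphate oligonucleotide.
#'
#' @param code Residue code present in [modification_table()].
#' @param table Modification table (defaults to the shipped one).
#' @return A `chem_formula`.
#' @examples
#' residue_formula("C")            # C9H12N3O7P
#' mass_of(residue_formula("D")) - mass_of(residue_formula("U"))  # +H2
#' @export
residue_formula <- function(code, table = modification_table()) {
  parse_formula(mod_row(code, table)$formula)
}

#' Chemistry flags for a residue code
#'
#' @inheritParams residue_formula
#' @return One-row data.frame with the code's flags.
#' @export
residue_flags <- function(code, table = modification_table()) {
  mod_row(code, table)
}

codes_known <- function(codes, table = modification_table()) {
  all(codes %in% table$code)
}
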