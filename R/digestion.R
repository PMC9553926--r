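#' Oligo-protection windowing
#'
#' Models oligo protection: complementary DNA oligos shield a window of the
#' tRNA and nucleases remove everything outside it. The result is the
#' subsequence with its original position labels (so the edit site is still
#' "position 32" after protection of 10-46). The window's termini reflect
#' nuclease trimming: 5'-OH and 3'-phosphate.
#'
#' @param seq A [mod_rna_seq()].
#' @param start,end 1-based inclusive window, default 10..46.
#' @return A [mod_rna_seq()] covering `start..end`.
#' @export
protect_window <- function(seq, start = 10L, end = 46L) {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("inverted window: start ", start, " > end ", end)
  if (start < min(seq$positions) || end > max(seq$positions))
    stop("window ", start, "..", end, " outside sequence positions ",
         min(seq$positions), "..", max(seq$positions))
  keep <- seq$positions >= start & seq$positions <= end
  out <- mod_rna_seq(seq$codes[keep], id = seq$id,
                     positions = seq$positions[keep])
  out$five_prime <- "OH"
  out$three_prime <- "p"
  out
}

#' In-silico ribonuclease digestion
#'
#' RNase A cleaves 3' of pyrimidine-derived residues (C, U, Psi, D, m5U by
#' default); RNase T1 cleaves 3' of guanosine (queuosine is non-cleavable by
#' default). 2'-O-methylated residues block cleavage at their position.
#' Products carry 5'-OH and, at internal cut sites, the 3' terminus selected
#' by `phosphate_form` — the linear 3'-phosphate hydrolysis product by
#' default, or the 2',3'-cyclic intermediate (-18.011 Da). The last fragment
#' keeps the parent's own 3' end; the first keeps the parent's 5' end.
#'
#' @param seq A [mod_rna_seq()].
#' @param enzyme `"RNaseA"` or `"RNaseT1"`.
#' @param missed_cleavages Maximum number of internal uncleaved sites per
#'   reported fragment (default 0, a limit digest).
#' @param phosphate_form `"p"` (linear 3'-phosphate, default) or `"cp"`
#'   (2',3'-cyclic phosphate).
#' @return A data.frame of fragments in sequence order with columns
#'   `start`, `end`, `sequence`, `codes` (list), `five_prime`,
#'   `three_prime`, `missed`, `length`.
#' @examples
#' s <- parse_modified_sequence("AAGAA")
#' digest(s, "RNaseT1")   # AAG (3'p) + AA
#' @export
digest <- function(seq, enzyme = c("RNaseA", "RNaseT1"),
                   missed_cleavages = 0L, phosphate_form = c("p", "cp")) {
  enzyme <- match.arg(enzyme)
  phosphate_form <- match.arg(phosphate_form)
  missed_cleavages <- as.integer(missed_cleavages)
  if (missed_cleavages < 0L) stop("missed_cleavages must be >= 0")
  tab <- modification_table()
  flag_col <- if (enzyme == "RNaseA") "rnase_a_site" else "rnase_t1_site"
  cleavable <- vapply(seq$codes,
                      function(code) isTRUE(mod_row(code, tab)[[flag_col]]),
                      logical(1))
  n <- length(seq)
  if (n == 0L) return(empty_fragments())
  # cut after index i when residue i is cleavable (never after the last)
  cuts <- which(cleavable[-n])
  bounds <- c(0L, cuts, n)                  # zero-cleavage segment bounds
  nseg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > nseg) break
      from <- bounds[i] + 1L
      to <- bounds[j + 1L]
      three <- if (to == n) (seq$three_prime %||% "OH") else phosphate_form
      five <- if (from == 1L) (seq$five_prime %||% "OH") else "OH"
      rows[[length(rows) + 1L]] <- list(
        start = seq$positions[from], end = seq$positions[to],
        codes = seq$codes[from:to], five_prime = five, three_prime = three,
        missed = m)
    }
  }
  out <- data.frame(
    start = vapply(rows, `[[`, 1L, "start"),
    end = vapply(rows, `[[`, 1L, "end"),
    sequence = vapply(rows, function(r) fragment_label(r$codes), ""),
    five_prime = vapply(rows, `[[`, "", "five_prime"),
    three_prime = vapply(rows, `[[`, "", "three_prime"),
    missed = vapply(rows, `[[`, 1L, "missed"),
    stringsAsFactors = FALSE)
  out$codes <- lapply(rows, `[[`, "codes")
  out$length <- lengths(out$codes)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_fragments <- function() {
  out <- data.frame(start = integer(), end = integer(),
                    sequence = character(), five_prime = character(),
                    three_prime = character(), missed = integer(),
                    stringsAsFactors = FALSE)
  out$codes <- list()
  out$length <- integer()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compact display label for a run of residue codes
#'
#' Single-letter codes are concatenated; multi-letter codes are bracketed,
#' e.g. `AGA[m5U]`.
#' @param codes Character vector of residue codes.
#' @export
fragment_label <- function(codes) {
  paste(ifelse(nchar(codes) > 1L, paste0("[", codes, "]"), codes),
        collapse = "")
}

#' Neutral monoisotopic (or average) mass of a digest fragment
#'
#' A chain of n internal residues (each carrying one phosphate) plus water
#' is the 5'-OH / 3'-linear-phosphate oligonucleotide. Termini adjust from
#' there: 5'-phosphate adds HPO3; 3'-OH removes HPO3; a 2',3'-cyclic
#' phosphate removes H2O. Cyanoethyl adducts add C3H3N each.
#'
#' @param codes Character vector of residue codes.
#' @param five_prime `"OH"` or `"p"`.
#' @param three_prime `"p"`, `"cp"`, or `"OH"`.
#' @param ce_count Number of cyanoethyl adducts carried.
#' @param scale `"monoisotopic"` or `"average"`.
#' @return Neutral mass in Da.
#' @export
fragment_mass <- function(codes, five_prime = "OH", three_prime = "p",
                          ce_count = 0L, scale = "monoisotopic") {
  f <- fragment_formula(codes, five_prime, three_prime, ce_count)
  mass_of(f, scale)
}

#' @rdname fragment_mass
#' @return `fragment_formula()`: the neutral `chem_formula`.
#' @export
fragment_formula <- function(codes, five_prime = "OH", three_prime = "p",
                             ce_count = 0L) {
  stopifnot(length(codes) >= 1L)
  f <- Reduce(formula_add, lapply(codes, residue_formula))
  f <- formula_add(f, parse_formula(H2O))
  if (five_prime == "p") f <- formula_add(f, parse_formula(HPO3))
  else if (five_prime != "OH") stop("unknown 5' terminus: ", five_prime)
  if (three_prime == "OH") f <- formula_subtract(f, parse_formula(HPO3))
  else if (three_prime == "cp") f <- formula_subtract(f, parse_formula(H2O))
  else if (three_prime != "p") stop("unknown 3' terminus: ", three_prime)
  if (ce_count > 0L)
    for (i in seq_len(ce_count)) f <- formula_add(f, parse_formula(CYANOETHYL))
  f
}

#' Write a digest fragment table as TSV
#'
#' @param fragments Output of [digest()].
#' @param path Output TSV path.
#' @param scale Mass scale for the `neutral_mass` column.
#' @export
write_fragment_table <- function(fragments, path, scale = "monoisotopic") {
  out <- fragments[, c("start", "end", "sequence", "five_prime",
                       "three_prime", "missed", "length")]
  out$neutral_mass <- vapply(seq_len(nrow(fragments)), function(i) {
    fragment_mass(fragments$codes[[i]], fragments$five_prime[i],
                  fragments$three_prime[i], scale = scale)
  }, 1.0)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
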