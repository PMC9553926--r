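#' m/z of a digest fragment
#'
#' Neutral mass from [fragment_mass()] adjusted for the ion: -1.00728 for
#' the singly deprotonated [M-H]- ion (the convention of linear
#' negative-mode MALDI-TOF of oligonucleotides, and the default), +1.00728
#' for [M+H]+.
#'
#' @param codes Character vector of residue codes, or one row of a
#'   [digest()] table via the `fragment` argument.
#' @param five_prime,three_prime,ce_count,scale See [fragment_mass()].
#' @param ion `"[M-H]-"` or `"[M+H]+"`.
#' @return m/z (Da, singly charged).
#' @examples
#' mz_fragment(c("A", "G", "A", "C"))            # 1325.197
#' mz_fragment(c("G", "A", "G", "D"))            # 1344.192
#' mz_fragment(c("A", "G", "A", "Y"), ce_count = 1)  # 1379.208
#' @export
mz_fragment <- function(codes, five_prime = "OH", three_prime = "p",
                        ce_count = 0L, ion = c("[M-H]-", "[M+H]+"),
                        scale = "monoisotopic") {
  ion <- match.arg(ion)
  m <- fragment_mass(codes, five_prime, three_prime, ce_count, scale)
  if (ion == "[M-H]-") m - PROTON_MASS else m + PROTON_MASS
}

#' Read a peak list from TSV or CSV
#'
#' Accepts `mz,intensity` (or tab-separated) with or without a header row.
#' Peaks are validated (m/z > 0, intensity >= 0) and sorted ascending.
#'
#' @param path Input file.
#' @return A data.frame with columns `mz` and `intensity`.
#' @export
read_peak_list <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  header <- grepl("[A-Za-z]", first)
  tab <- utils::read.table(path, sep = sep, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("peak list needs two columns (mz, intensity)")
  peak_list(tab[[1]], tab[[2]])
}

#' Construct a validated, sorted peak list
#'
#' @param mz,intensity Numeric vectors.
#' @return Data.frame sorted ascending by m/z.
#' @export
peak_list <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (any(mz <= 0)) stop("all m/z values must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  out <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  out[order(out$mz), , drop = FALSE]
}

#' Theoretical candidate species for the diagnostic fragment of an edit site
#'
#' Locates the limit-digest fragment covering `position` and enumerates the
#' mass-distinguishable species it can form after cyanoethylation of an
#' editing reaction: unedited C; the +0.984 deamination product without a
#' cyanoethyl shift (a U — a Psi would have been shifted by the CE
#' treatment); its 18O isotopologue U+2; and cyanoethylated Psi with and
#' without the heavy oxygen. Psi without CE is mass-identical to U and is
#' therefore reported as U.
#'
#' @param seq Protected [mod_rna_seq()] (unedited at the site).
#' @param position Edit site.
#' @param enzyme,phosphate_form Passed to [digest()].
#' @param ion Ion mode for m/z.
#' @return Data.frame: `species`, `state`, `o18`, `ce_count`, `mz`, plus
#'   the fragment's `start`/`end` and a `codes` list column.
#' @export
diagnostic_species <- function(seq, position, enzyme = "RNaseA",
                               phosphate_form = "p", ion = "[M-H]-") {
  frags <- digest(seq, enzyme, missed_cleavages = 0L,
                  phosphate_form = phosphate_form)
  hit <- which(frags$start <= position & frags$end >= position)
  if (length(hit) != 1L)
    stop("no diagnostic fragment covers position ", position)
  frag <- frags[hit, , drop = FALSE]
  codes <- frag$codes[[1]]
  at <- position - frag$start + 1L
  variants <- list(
    list(species = "C", state = "C", o18 = FALSE, ce = 0L, code = "C"),
    list(species = "U", state = "U", o18 = FALSE, ce = 0L, code = "U"),
    list(species = "U+2", state = "U", o18 = TRUE, ce = 0L, code = "U18"),
    list(species = "Y+CE", state = "Y", o18 = FALSE, ce = 1L, code = "Y"),
    list(species = "Y+CE+2", state = "Y", o18 = TRUE, ce = 1L, code = "Y18"))
  rows <- lapply(variants, function(v) {
    cc <- codes
    cc[at] <- v$code
    list(species = v$species, state = v$state, o18 = v$o18,
         ce_count = v$ce, codes = cc,
         mz = mz_fragment(cc, frag$five_prime, frag$three_prime,
                          ce_count = v$ce, ion = ion))
  })
  out <- data.frame(
    species = vapply(rows, `[[`, "", "species"),
    state = vapply(rows, `[[`, "", "state"),
    o18 = vapply(rows, `[[`, TRUE, "o18"),
    ce_count = vapply(rows, `[[`, 1L, "ce_count"),
    mz = vapply(rows, `[[`, 1.0, "mz"),
    start = frag$start, end = frag$end,
    stringsAsFactors = FALSE)
  out$codes <- lapply(rows, `[[`, "codes")
  out
}

#' Match observed peaks to theoretical species
#'
#' Greedy nearest-mass matching within a tolerance: candidate pairs are
#' ranked by absolute mass error (ties broken by higher intensity) and
#' accepted one at a time, so each peak is assigned to at most one species
#' and each species to at most one peak.
#'
#' @param theoretical Data.frame with columns `species` and `mz` (e.g. from
#'   [diagnostic_species()]).
#' @param peaks A [peak_list()].
#' @param tolerance_da Match window in Da (default 0.3, linear-MALDI scale).
#' @return Assignment data.frame: `species`, `theoretical_mz`, `peak_mz`,
#'   `intensity`, `error` (observed - theoretical).
#' @export
match_peaks <- function(theoretical, peaks, tolerance_da = 0.3) {
  if (tolerance_da <= 0) stop("tolerance must be positive")
  cand <- expand.grid(t = seq_len(nrow(theoretical)),
                      p = seq_len(nrow(peaks)))
  if (nrow(cand) == 0L) return(empty_assignments())
  cand$error <- peaks$mz[cand$p] - theoretical$mz[cand$t]
  cand <- cand[abs(cand$error) <= tolerance_da, , drop = FALSE]
  cand <- cand[order(abs(cand$error), -peaks$intensity[cand$p]), , drop = FALSE]
  used_t <- logical(nrow(theoretical)); used_p <- logical(nrow(peaks))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ti <- cand$t[i]; pi <- cand$p[i]
    if (!used_t[ti] && !used_p[pi]) {
      keep[i] <- TRUE
      used_t[ti] <- TRUE; used_p[pi] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    species = theoretical$species[cand$t],
    state = if ("state" %in% names(theoretical))
      theoretical$state[cand$t] else rep(NA_character_, nrow(cand)),
    theoretical_mz = theoretical$mz[cand$t],
    peak_mz = peaks$mz[cand$p],
    intensity = peaks$intensity[cand$p],
    error = cand$error,
    stringsAsFactors = FALSE)
  out <- out[order(out$theoretical_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_assignments <- function() {
  data.frame(species = character(), state = character(),
             theoretical_mz = numeric(), peak_mz = numeric(),
             intensity = numeric(), error = numeric(),
             stringsAsFactors = FALSE)
}

#' Infer the editing state at a position from peak assignments
#'
#' The decision mirrors the cyanoethylation readout: a CE-shifted species
#' (in either oxygen channel) demonstrates pseudouridine; a +0.984 species
#' without the CE shift after CE treatment demonstrates uridine; only the
#' unedited species means unedited C. The edited fraction accompanies the
#' call whenever any diagnostic species was observed.
#'
#' @param assignments Output of [match_peaks()] on diagnostic species.
#' @param position Edit site the call refers to.
#' @return An `editing_call`: list with `position`, `state` (`"C"`, `"U"`
#'   or `"Y"`), `fraction`, and the supporting `assignments`.
#' @export
infer_editing_state <- function(assignments, position) {
  obs <- assignments[assignments$intensity > 0, , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("no diagnostic species observed; cannot call position ", position)
  state <- if (any(obs$state == "Y")) "Y"
    else if (any(obs$state == "U")) "U"
    else "C"
  structure(list(position = position, state = state,
                 fraction = estimate_edit_fraction(obs),
                 assignments = assignments),
            class = "editing_call")
}

#' @export
print.editing_call <- function(x, ...) {
  pretty <- c(C = "C (unedited)", U = "U (deaminated)",
              Y = "Ψ (pseudouridine)")
  cat("<editing_call> position ", x$position, ": ", pretty[[x$state]],
      ", edited fraction ", sprintf("%.3f", x$fraction), "\n", sep = "")
  invisible(x)
}

#' Edited fraction from diagnostic species intensities
#'
#' Under the (documented) assumption of equal desorption/ionization
#' efficiency across the diagnostic species, the edited fraction is the
#' intensity of edited species (U or Psi states, any label channel) over
#' the total diagnostic intensity. Invariant to a common intensity scale.
#'
#' @param assignments Output of [match_peaks()] carrying a `state` column.
#' @return Fraction in `[0,1]`.
#' @export
estimate_edit_fraction <- function(assignments) {
  total <- sum(assignments$intensity)
  if (!is.finite(total) || total <= 0)
    stop("zero total diagnostic intensity")
  sum(assignments$intensity[assignments$state %in% c("U", "Y")]) / total
}
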