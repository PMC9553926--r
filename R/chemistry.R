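#' Apply an editing state at a position
#'
#' Replaces the residue at a C/U/Psi site with the given state. When the
#' state is a deamination product (U or Psi) and `o18_labeled` is TRUE, the
#' installed base oxygen is heavy (the deamination reaction takes its oxygen
#' from water, so an 18O-water reaction marks the product +2.00425 Da); the
#' residue is recorded with the labeled code (`U18` / `Y18`).
#'
#' @param seq A [mod_rna_seq()].
#' @param position 1-based position; the residue there must be C, U, or Psi.
#' @param state Target state: `"C"`, `"U"`, or `"Y"` (pseudouridine).
#' @param o18_labeled Whether the deamination-installed oxygen is 18O.
#' @return The edited [mod_rna_seq()].
#' @export
apply_editing <- function(seq, position, state = c("Y", "U", "C"),
                          o18_labeled = FALSE) {
  state <- match.arg(state)
  current <- code_at(seq, position)
  if (!current %in% c("C", "U", "Y", "U18", "Y18"))
    stop("position ", position, " is ", current,
         ", not an editable C/U/Psi site")
  if (o18_labeled && state == "C")
    stop("18O labeling applies only to deamination products (U/Psi)")
  code <- if (o18_labeled) paste0(state, "18") else state
  set_code_at(seq, position, code)
}

#' Cyanoethylation of pseudouridine sites
#'
#' Acrylonitrile attaches a cyanoethyl group (C3H3N, +53.0266 Da)
#' specifically to pseudouridine. Each reactive site reacts independently
#' with the stated efficiency, giving a binomial ensemble over the number of
#' adducts; efficiency 1 collapses to a single fully-labeled species.
#'
#' @param codes Character vector of residue codes (a fragment or sequence).
#' @param efficiency Per-site labeling probability in `[0,1]`.
#' @param reactive_codes Codes that accept the adduct; defaults to the
#'   `ce_reactive` flags of the modification table (Psi only).
#' @return A data.frame with columns `ce_count`, `weight` (summing to 1),
#'   and `mass_shift` (Da).
#' @examples
#' cyanoethylate(c("A", "G", "A", "Y"))                 # one species, +53
#' cyanoethylate(c("A", "G", "A", "Y"), efficiency = 0.5)
#' @export
cyanoethylate <- function(codes, efficiency = 1.0, reactive_codes = NULL) {
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0,1]")
  if (is.null(reactive_codes)) {
    tab <- modification_table()
    reactive_codes <- tab$code[tab$ce_reactive]
  }
  n_sites <- sum(codes %in% reactive_codes)
  k <- 0:n_sites
  w <- stats::dbinom(k, n_sites, efficiency)
  out <- data.frame(ce_count = k, weight = w,
                    mass_shift = k * mass_of(CYANOETHYL))
  out[out$weight > 0, , drop = FALSE]
}

#' Enumerate the molecular species induced by an experimental condition
#'
#' An editing reaction at one site, run at edit fraction `f` in water with
#' 18O fraction `w` and read out after cyanoethylation at efficiency `ce`,
#' yields a weighted mixture: the unedited residue with weight `1 - f`, and
#' edited molecules split independently across the 18O channel (probability
#' `w`) and, for pseudouridine, the cyanoethyl channel (probability `ce`).
#' Weights multiply because the channels are independent.
#'
#' @param seq A [mod_rna_seq()] whose residue at `position` is the unedited
#'   state (typically C).
#' @param position Edit site (1-based).
#' @param f Edited fraction in `[0,1]`.
#' @param ce Cyanoethylation efficiency in `[0,1]`.
#' @param w 18O water fraction in `[0,1]`.
#' @param edit_state Product of the reaction: `"Y"` (full editing, default)
#'   or `"U"` (deamination only, e.g. a pseudouridylase-dead enzyme).
#' @return A data.frame with columns `species` (label such as `"C"`,
#'   `"Y+CE"`, `"Y+CE+2"`), `state`, `o18`, `ce_count`, `weight` (sums
#'   to 1), and a list column `seq` of sequence variants.
#' @examples
#' s <- parse_modified_sequence("AGAC")
#' enumerate_species(s, 4, f = 0.5, ce = 1, w = 0.5)
#' @export
enumerate_species <- function(seq, position, f, ce = 1.0, w = 0.0,
                              edit_state = c("Y", "U")) {
  edit_state <- match.arg(edit_state)
  for (p in c(f, ce, w))
    if (p < 0 || p > 1) stop("f, ce and w must all lie in [0,1]")
  base_code <- code_at(seq, position)
  rows <- list()
  add <- function(state, o18, ce_count, weight) {
    if (weight <= 0) return()
    variant <- if (state == base_code && !o18) seq
      else apply_editing(seq, position, state, o18_labeled = o18)
    label <- paste0(state,
                    if (ce_count > 0L) "+CE",
                    if (o18) "+2")
    rows[[length(rows) + 1L]] <<- list(
      species = label, state = state, o18 = o18,
      ce_count = as.integer(ce_count), weight = weight, seq = variant)
  }
  add(base_code, FALSE, 0L, 1 - f)
  o18_branch <- c(`FALSE` = 1 - w, `TRUE` = w)
  ce_branch <- if (edit_state == "Y") c(`0` = 1 - ce, `1` = ce) else c(`0` = 1)
  for (o18 in c(FALSE, TRUE))
    for (k in as.integer(names(ce_branch)))
      add(edit_state, o18, k,
          f * o18_branch[[as.character(o18)]] * ce_branch[[as.character(k)]])
  out <- data.frame(
    species = vapply(rows, `[[`, "", "species"),
    state = vapply(rows, `[[`, "", "state"),
    o18 = vapply(rows, `[[`, TRUE, "o18"),
    ce_count = vapply(rows, `[[`, 1L, "ce_count"),
    weight = vapply(rows, `[[`, 1.0, "weight"),
    stringsAsFactors = FALSE)
  out$seq <- lapply(rows, `[[`, "seq")
  stopifnot(abs(sum(out$weight) - 1) < 1e-9)
  rownames(out) <- NULL
  out
}
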