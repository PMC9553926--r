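#' Nucleoside inventory of a sequence
#'
#' The multiset of residue codes — the composition a complete digestion to
#' nucleosides (nuclease P1 + phosphodiesterase + phosphatase) presents to
#' LC-MS/MS.
#'
#' @param seq A [mod_rna_seq()].
#' @return Named integer vector of counts per code; total equals the
#'   sequence length.
#' @export
nucleoside_inventory <- function(seq) {
  if (length(seq) == 0L) return(integer(0))
  counts <- table(seq$codes)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Dynamic-MRM transitions for nucleoside codes
#'
#' Precursor is the protonated free nucleoside: residue formula minus the
#' phosphate (HPO3) plus water, plus a proton. The default product ion is
#' the protonated base after neutral loss of the ribose (C5H8O4,
#' 132.0423 Da); C-glycosides and 2'-O-methyl species override the loss in
#' the modification table (pseudouridine fragments by double water loss
#' instead, as its base-ribose bond does not break). The `M+2` channel puts
#' one 18O on the base, so precursor and product both shift +2.00425 —
#' heavy channels are generated only for deamination products (U, Psi),
#' where the label is installed.
#'
#' @param codes Character vector of residue codes.
#' @param channels Channels to emit: subset of `c("M", "M+2")`.
#' @param rt_window Optional named numeric vector of retention-time windows
#'   (min) per code; NA when unspecified.
#' @return Data.frame: `code`, `channel`, `precursor_mz`, `product_mz`,
#'   `rt_window`.
#' @examples
#' mrm_transitions("U")     # 245.077 -> 113.034 and 247.081 -> 115.039
#' @export
mrm_transitions <- function(codes, channels = c("M", "M+2"),
                            rt_window = NULL) {
  channels <- match.arg(channels, c("M", "M+2"), several.ok = TRUE)
  tab <- modification_table()
  shift <- o18_mass_shift()
  rows <- list()
  for (code in codes) {
    row <- mod_row(code, tab)
    res <- parse_formula(row$formula)
    nucleoside <- formula_add(formula_subtract(res, parse_formula(HPO3)),
                              parse_formula(H2O))
    loss <- row$mrm_loss
    if (is.null(loss) || is.na(loss) || !nzchar(loss)) loss <- RIBOSE_LOSS
    prec <- mass_of(nucleoside) + PROTON_MASS
    prod <- prec - mass_of(loss)
    if (prod <= 0) stop("product ion mass non-positive for code ", code)
    for (ch in channels) {
      if (ch == "M+2" && !isTRUE(row$deamination_product)) next
      d <- if (ch == "M+2") shift else 0
      rows[[length(rows) + 1L]] <- list(
        code = code, channel = ch,
        precursor_mz = prec + d, product_mz = prod + d,
        rt_window = if (!is.null(rt_window) && code %in% names(rt_window))
          rt_window[[code]] else NA_real_)
    }
  }
  data.frame(
    code = vapply(rows, `[[`, "", "code"),
    channel = vapply(rows, `[[`, "", "channel"),
    precursor_mz = vapply(rows, `[[`, 1.0, "precursor_mz"),
    product_mz = vapply(rows, `[[`, 1.0, "product_mz"),
    rt_window = vapply(rows, `[[`, 1.0, "rt_window"),
    stringsAsFactors = FALSE)
}

#' Write an MRM transition list as TSV (dynamic-MRM method export)
#'
#' @param transitions Output of [mrm_transitions()].
#' @param path Output path.
#' @export
write_transition_list <- function(transitions, path) {
  utils::write.table(transitions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(transitions)
}

#' Read an MRM signal table
#'
#' TSV with columns `sample`, `code`, `channel`, `intensity`.
#'
#' @param path Input TSV.
#' @return Data.frame with those columns.
#' @export
read_signal_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "code", "channel", "intensity")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("signal table lacks column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Normalize MRM signals to a reference nucleoside
#'
#' Every channel's intensity is divided by the reference nucleoside's M
#' channel within the same sample. m5U (ribothymidine) is the default
#' normalizer: one copy per tRNA, untouched by the editing chemistry, so it
#' cancels sample-loading differences. Scale-invariant per sample by
#' construction.
#'
#' @param signal_table Data.frame with `sample`, `code`, `channel`,
#'   `intensity` (see [read_signal_table()]).
#' @param normalizer Reference code, default `"m5U"`.
#' @return The table with a `normalized` column appended; the normalizer's
#'   own M channel is 1 in every sample.
#' @export
quantify <- function(signal_table, normalizer = "m5U") {
  stopifnot(all(c("sample", "code", "channel", "intensity") %in%
                  names(signal_table)))
  if (any(signal_table$intensity < 0)) stop("negative intensity")
  out <- signal_table
  out$normalized <- NA_real_
  for (s in unique(out$sample)) {
    in_s <- out$sample == s
    ref <- out$intensity[in_s & out$code == normalizer & out$channel == "M"]
    if (length(ref) != 1L)
      stop("sample '", s, "': normalizer '", normalizer,
           "' M channel missing or duplicated")
    if (ref <= 0)
      stop("sample '", s, "': normalizer '", normalizer, "' intensity is zero")
    out$normalized[in_s] <- out$intensity[in_s] / ref
  }
  out
}
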