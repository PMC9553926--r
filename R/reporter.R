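#' Editing fraction from sequencing-trace peak heights
#'
#' C-to-U/Psi editing reads as T in the sequencing trace of the amplified
#' cDNA (both U and Psi template a T), so the edited fraction at the site is
#' the T peak height over the summed C and T heights. Invariant to a common
#' scaling of the heights.
#'
#' @param heights Named numeric vector (or one-row data.frame) with peak
#'   heights for at least `C` and `T` at the queried position.
#' @return Edited fraction in `[0,1]`.
#' @examples
#' editing_fraction_from_trace(c(C = 50, T = 150))  # 0.75
#' @export
editing_fraction_from_trace <- function(heights) {
  if (is.data.frame(heights)) heights <- unlist(heights[1, , drop = TRUE])
  h <- heights[c("C", "T")]
  if (any(is.na(h))) stop("heights must include C and T")
  if (any(h < 0)) stop("negative peak height")
  if (sum(h) == 0) stop("C + T heights are zero at the queried position")
  unname(h[["T"]] / sum(h))
}

#' Read a trace peak-height table
#'
#' TSV with columns `position`, `A`, `C`, `G`, `T`.
#' @param path Input TSV.
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "A", "C", "G", "T")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("trace table lacks column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Relative Rt/Rs decoding score from dual-luciferase reporters
#'
#' For each strain and codon, Rt is the mean firefly/renilla ratio of the
#' in-frame (frame 0) reporter replicates and Rs the mean of the +1
#' frameshift reporter replicates; Rt/Rs estimates decoding efficiency of
#' the test codon. Scores are normalized per codon to the mean of the WT
#' strain, so WT's relative score is 1 by construction.
#'
#' @param measurements Data.frame with columns `strain`, `codon`, `frame`
#'   (0 or 1), `firefly`, `renilla` (one row per replicate culture).
#' @param wt Name of the reference strain (default `"WT"`).
#' @return Data.frame per strain x codon: `Rt`, `Rs`, `rt_rs`,
#'   `relative_score`, `n0`, `n1`.
#' @export
rt_rs <- function(measurements, wt = "WT") {
  need <- c("strain", "codon", "frame", "firefly", "renilla")
  missing <- setdiff(need, names(measurements))
  if (length(missing))
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(measurements$renilla <= 0)) stop("renilla signals must be positive")
  if (!all(measurements$frame %in% c(0, 1)))
    stop("frame must be 0 (in-frame) or 1 (+1 frameshift)")
  measurements$fr <- measurements$firefly / measurements$renilla
  groups <- unique(measurements[, c("strain", "codon")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- measurements[measurements$strain == groups$strain[i] &
                        measurements$codon == groups$codon[i], ]
    f0 <- g$fr[g$frame == 0]; f1 <- g$fr[g$frame == 1]
    if (!length(f0) || !length(f1))
      stop("strain ", groups$strain[i], ", codon ", groups$codon[i],
           ": both frame-0 and frame+1 replicates are required")
    rs <- mean(f1)
    if (rs == 0) stop("zero Rs for strain ", groups$strain[i])
    data.frame(strain = groups$strain[i], codon = groups$codon[i],
               Rt = mean(f0), Rs = rs, rt_rs = mean(f0) / rs,
               n0 = length(f0), n1 = length(f1),
               stringsAsFactors = FALSE)
  }))
  out$relative_score <- NA_real_
  for (cod in unique(out$codon)) {
    in_c <- out$codon == cod
    ref <- out$rt_rs[in_c & out$strain == wt]
    if (!length(ref))
      stop("no WT reference group ('", wt, "') for codon ", cod)
    out$relative_score[in_c] <- out$rt_rs[in_c] / mean(ref)
  }
  rownames(out) <- NULL
  out
}

#' Read a dual-luciferase reporter table
#'
#' TSV with columns `strain`, `codon`, `frame`, `firefly`, `renilla`.
#' @param path Input TSV.
#' @export
read_reporter_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "codon", "frame", "firefly", "renilla")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("reporter table lacks column(s): ", paste(missing, collapse = ", "))
  tab
}
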