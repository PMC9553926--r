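# Independent oracles, deliberately implemented apart from the package code.

# Element monoisotopic masses keyed independently (NIST values).
oracle_element_mass <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                         O = 15.9949146196, P = 30.97376163,
                         S = 31.97207100, O18 = 17.9991610)

# Minimal independent formula-string tally: returns named counts.
# Handles bracketed isotopes by rewriting [18O] -> O18 beforehand.
oracle_tally <- function(formula) {
  formula <- gsub("\\[18O\\]", "Z", formula)  # placeholder single letter
  counts <- c()
  for (m in regmatches(formula,
                       gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]) {
    sym <- gsub("[0-9]", "", m)
    n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", m)))
    if (is.na(n)) n <- 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  names(counts)[names(counts) == "Z"] <- "O18"
  counts
}

oracle_mass <- function(formula) {
  counts <- oracle_tally(formula)
  sum(oracle_element_mass[names(counts)] * counts)
}

# Neutral 5'-OH/3'-p chain mass from the shipped residue formula strings,
# summing element tallies over the whole molecule before taking the mass.
oracle_chain_mass <- function(codes) {
  tab <- modification_table()
  total <- c(H = 2L, O = 1L)  # the water
  for (code in codes) {
    t1 <- oracle_tally(tab$formula[match(code, tab$code)])
    for (e in names(t1))
      total[e] <- (if (e %in% names(total)) total[[e]] else 0L) + t1[[e]]
  }
  sum(oracle_element_mass[names(total)] * total)
}

# Brute-force digestion: scan every position, mark it cleavable from the
# modification-table flags, cut after each cleavable residue except the
# last, and return start/end pairs.
oracle_digest <- function(codes, enzyme) {
  tab <- modification_table()
  col <- if (enzyme == "RNaseA") "rnase_a_site" else "rnase_t1_site"
  n <- length(codes)
  cleavable <- vapply(codes, function(x) tab[[col]][match(x, tab$code)],
                      logical(1))
  starts <- 1L; ends <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (cleavable[i]) {
      ends <- c(ends, i)
      starts <- c(starts, i + 1L)
    }
  }
  ends <- c(ends, n)
  data.frame(start = starts, end = ends)
}

# Random modified sequence over an alphabet including modified codes.
random_mod_codes <- function(n) {
  sample(c("A", "C", "G", "U", "Y", "D", "Q", "m5U", "ms2io6A", "Um", "Gm"),
         n, replace = TRUE,
         prob = c(rep(0.2, 4), rep(0.2 / 7, 7)))
}

trna_like_profile <- function() {
  data.frame(position = c(16L, 32L, 34L, 37L, 54L),
             code = c("D", "C", "Q", "ms2io6A", "m5U"))
}

# An 85-nt base string with the anchors the diagnostic digest relies on.
trna_like_bases <- function() {
  base <- rep("A", 85)
  base[c(5, 7, 20, 25, 42, 50, 60, 70)] <- "G"
  base[12] <- "U"; base[13:16] <- c("G", "A", "G", "U")
  base[28] <- "U"; base[29:32] <- c("A", "G", "A", "C")
  base[33] <- "U"; base[34:37] <- c("G", "U", "A", "A")
  base[54] <- "U"; base[83:85] <- c("C", "C", "A")
  paste(base, collapse = "")
}
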