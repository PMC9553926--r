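#' Simulation configuration
#'
#' Bundles the conditions of one in-vitro editing experiment: an ~85-nt
#' tRNA-Tyr-like substrate with the anticodon-arm modification set (D16,
#' editable C32, Q34, ms2io6A37, m5U54), an editing reaction at fraction
#' `f` producing `edit_state`, cyanoethylation at efficiency `ce`, 50%
#' 18O water by default, and instrument noise (0.1 Da mass error s.d.,
#' 5% intensity CV) typical of linear-mode MALDI-TOF readouts.
#'
#' @param seed Root seed; every generator derives its own stream from it,
#'   so identical seeds give identical outputs.
#' @param length Substrate length (nt).
#' @param profile Modification profile data.frame (`position`, `code`).
#' @param edit_position Edit site (default 32).
#' @param edit_state Editing product, `"Y"` or `"U"`.
#' @param f Edited fraction in `[0,1]`.
#' @param ce Cyanoethylation efficiency in `[0,1]`.
#' @param w 18O water fraction in `[0,1]` (default 0.5).
#' @param mass_error_sd Gaussian m/z error s.d. in Da.
#' @param intensity_cv Multiplicative intensity noise CV.
#' @param replicates Replicate count for table generators.
#' @param window Oligo-protection window (default 10..46).
#' @param enzyme Digestion enzyme for the MALDI readout.
#' @param ion Ion mode.
#' @param tolerance Peak-matching tolerance (Da).
#' @param scale Base intensity scale (arbitrary units).
#' @param decoy_rate Expected number of uniform decoy peaks per spectrum.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, length = 85L,
                       profile = default_profile(),
                       edit_position = 32L, edit_state = c("Y", "U"),
                       f = 0, ce = 1, w = 0.5,
                       mass_error_sd = 0.1, intensity_cv = 0.05,
                       replicates = 1L, window = c(10L, 46L),
                       enzyme = "RNaseA", ion = "[M-H]-",
                       tolerance = 0.3, scale = 1000, decoy_rate = 0) {
  edit_state <- match.arg(edit_state)
  for (p in c(f, ce, w))
    if (p < 0 || p > 1) stop("f, ce and w must lie in [0,1]")
  if (mass_error_sd < 0 || intensity_cv < 0) stop("noise levels must be >= 0")
  profile <- normalize_profile(profile)
  if (any(profile$position > length))
    stop("profile position beyond sequence length ", length)
  if (edit_position > length) stop("edit position beyond sequence length")
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 profile = profile, edit_position = as.integer(edit_position),
                 edit_state = edit_state, f = f, ce = ce, w = w,
                 mass_error_sd = mass_error_sd, intensity_cv = intensity_cv,
                 replicates = as.integer(replicates),
                 window = as.integer(window), enzyme = enzyme, ion = ion,
                 tolerance = tolerance, scale = scale,
                 decoy_rate = decoy_rate),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_profile <- function() {
  data.frame(position = c(16L, 32L, 34L, 37L, 54L),
             code = c("D", "C", "Q", "ms2io6A", "m5U"),
             stringsAsFactors = FALSE)
}

# Derive a per-stream seed (< 2^31) from the root seed, and run code under
# it without disturbing the caller's RNG state.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) %% 65521) * 32749 + stream
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(seed, stream))
  force(code)
}

#' Generate a tRNA-Tyr-like modified substrate
#'
#' A seeded random sequence with the structural anchors the readout relies
#' on: positions 13-16 read G,A,G,D and 29-32 read A,G,A,C, each preceded
#' by a pyrimidine so that a limit RNase A digest of the protected region
#' releases the GAGDp and AGACp diagnostic tetramers; U33, the Tyr
#' anticodon (Q34,U35,A36), ms2io6A37, m5U54 and a 3'-CCA end are fixed.
#' Remaining positions are drawn uniformly, re-drawn (within the protection
#' window) until no non-diagnostic fragment falls within 2 Da of a
#' diagnostic species m/z — emulating the clean spectral neighbourhood of
#' the real substrate.
#'
#' @param config A [sim_config()].
#' @return A [mod_rna_seq()].
#' @export
make_trna_like <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$length
  if (n < 60L) stop("substrate must be at least 60 nt for the fixed anchors")
  with_stream(config$seed, 101L, {
    base <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    fixed <- c(`12` = "U", `13` = "G", `14` = "A", `15` = "G", `16` = "U",
               `28` = "U", `29` = "A", `30` = "G", `31` = "A", `32` = "C",
               `33` = "U", `34` = "G", `35` = "U", `36` = "A", `37` = "A",
               `54` = "U")
    base[as.integer(names(fixed))] <- fixed
    base[(n - 2L):n] <- c("C", "C", "A")
    seq <- parse_modified_sequence(base, config$profile, id = "tRNA-Tyr-like")
    guard <- diagnostic_guard(seq, config)
    tries <- 0L
    while (!is.null(bad <- guard()) && tries < 200L) {
      # resample the free residues of the offending fragment only
      free <- setdiff(bad, c(as.integer(names(fixed)), config$profile$position))
      if (!length(free)) stop("cannot avoid a diagnostic mass collision")
      seq$codes[free] <- sample(c("A", "C", "G", "U"), length(free),
                                replace = TRUE)
      guard <- diagnostic_guard(seq, config)
      tries <- tries + 1L
    }
    if (tries >= 200L) stop("failed to generate a collision-free substrate")
    seq
  })
}

# Returns a closure; calling it gives NULL when the window digest is clean,
# else the positions of a fragment whose mass sits within 2 Da of a
# diagnostic species.
diagnostic_guard <- function(seq, config) {
  function() {
    prot <- protect_window(seq, config$window[1], config$window[2])
    diag <- diagnostic_species(prot, config$edit_position,
                               enzyme = config$enzyme, ion = config$ion)
    frags <- digest(prot, config$enzyme)
    for (i in seq_len(nrow(frags))) {
      if (frags$start[i] <= config$edit_position &&
            frags$end[i] >= config$edit_position) next
      m <- mz_fragment(frags$codes[[i]], frags$five_prime[i],
                       frags$three_prime[i], ion = config$ion)
      if (any(abs(m - diag$mz) < 2)) return(frags$start[i]:frags$end[i])
    }
    NULL
  }
}

#' Simulate a MALDI-TOF peak list of the protected, digested substrate
#'
#' Forward model of the cyanoethylation readout: the diagnostic fragment's
#' species ensemble (from [enumerate_species()], collapsed to
#' mass-distinguishable species) and every other limit-digest fragment emit
#' one peak each at theoretical m/z plus Gaussian mass error, with intensity
#' proportional to abundance times multiplicative Gaussian noise (floored at
#' zero). Optional uniform decoy peaks emulate matrix/background ions.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index (varies the noise stream, not the
#'   substrate).
#' @return A [peak_list()].
#' @export
simulate_maldi <- function(config, replicate = 1L) {
  seq <- make_trna_like(config)
  prot <- protect_window(seq, config$window[1], config$window[2])
  theo <- diagnostic_species(prot, config$edit_position,
                             enzyme = config$enzyme, ion = config$ion)
  weights <- species_weights(prot, config)
  frags <- digest(prot, config$enzyme)
  is_diag <- frags$start <= config$edit_position &
    frags$end >= config$edit_position
  with_stream(config$seed, 211L + 1000L * as.integer(replicate), {
    mzs <- c(); ints <- c()
    for (i in seq_len(nrow(theo))) {
      wgt <- weights[theo$species[i]]
      if (is.na(wgt) || wgt <= 0) next
      mzs <- c(mzs, theo$mz[i] + stats::rnorm(1, 0, config$mass_error_sd))
      ints <- c(ints, max(0, config$scale * wgt *
                            (1 + stats::rnorm(1, 0, config$intensity_cv))))
    }
    for (i in which(!is_diag)) {
      m <- mz_fragment(frags$codes[[i]], frags$five_prime[i],
                       frags$three_prime[i], ion = config$ion)
      mzs <- c(mzs, m + stats::rnorm(1, 0, config$mass_error_sd))
      ints <- c(ints, max(0, config$scale *
                            (1 + stats::rnorm(1, 0, config$intensity_cv))))
    }
    n_decoy <- stats::rpois(1, config$decoy_rate)
    if (n_decoy > 0) {
      mzs <- c(mzs, stats::runif(n_decoy, min(mzs) - 50, max(mzs) + 50))
      ints <- c(ints, stats::runif(n_decoy, 0, config$scale * 0.2))
    }
    peak_list(mzs, ints)
  })
}

# Collapse the condition's species ensemble onto the mass-distinguishable
# diagnostic species labels (Psi without CE is mass-identical to U).
species_weights <- function(prot, config) {
  ens <- enumerate_species(prot, config$edit_position, f = config$f,
                           ce = config$ce, w = config$w,
                           edit_state = config$edit_state)
  lab <- character(nrow(ens))
  for (i in seq_len(nrow(ens))) {
    lab[i] <- if (ens$state[i] == "C") "C"
      else if (ens$ce_count[i] > 0L)
        if (ens$o18[i]) "Y+CE+2" else "Y+CE"
      else if (ens$o18[i]) "U+2" else "U"
  }
  tapply(ens$weight, lab, sum)
}

#' Simulate an MRM nucleoside signal table
#'
#' Per replicate sample, each nucleoside channel's intensity is a random
#' per-sample loading scale times the expected molar abundance (the
#' nucleoside inventory, with the edit site split as `1-f` unedited C and
#' `f` edited product partitioned into 16O/18O channels by `w`) times
#' multiplicative Gaussian noise. The heavy (M+2) channel abundance is
#' `f * w` for the editing product; m5U is one copy per molecule and serves
#' as the normalizer.
#'
#' @param config A [sim_config()].
#' @return Data.frame: `sample`, `code`, `channel`, `intensity`.
#' @export
simulate_mrm <- function(config) {
  seq <- make_trna_like(config)
  counts <- nucleoside_inventory(seq)
  site_code <- code_at(seq, config$edit_position)
  abund <- list()
  for (code in names(counts)) {
    n <- counts[[code]]
    if (code == site_code) n <- n - 1L  # edit site handled separately
    if (n > 0L) abund[[paste0(code, "|M")]] <-
        (abund[[paste0(code, "|M")]] %||% 0) + n
  }
  add <- function(key, x) abund[[key]] <<- (abund[[key]] %||% 0) + x
  add(paste0(site_code, "|M"), 1 - config$f)
  es <- config$edit_state
  add(paste0(es, "|M"), config$f * (1 - config$w))
  add(paste0(es, "|M+2"), config$f * config$w)
  with_stream(config$seed, 307L, {
    rows <- list()
    for (s in seq_len(config$replicates)) {
      loading <- stats::runif(1, 0.5, 2)
      for (key in names(abund)) {
        parts <- strsplit(key, "|", fixed = TRUE)[[1]]
        noise <- 1 + stats::rnorm(1, 0, config$intensity_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = paste0("rep", s), code = parts[1], channel = parts[2],
          intensity = max(0, config$scale * loading * abund[[key]] * noise),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out[order(out$sample, out$code, out$channel), , drop = FALSE]
  })
}

#' Simulate a sequencing-trace peak-height table at the edit site
#'
#' T height proportional to the edited fraction, C to the unedited
#' fraction, with multiplicative noise; A/G are low background.
#'
#' @param config A [sim_config()].
#' @return Data.frame: `position`, `A`, `C`, `G`, `T`.
#' @export
simulate_trace <- function(config) {
  with_stream(config$seed, 401L, {
    noise <- function() max(0, 1 + stats::rnorm(1, 0, config$intensity_cv))
    data.frame(position = config$edit_position,
               A = config$scale * 0.01 * noise(),
               C = config$scale * (1 - config$f) * noise(),
               G = config$scale * 0.01 * noise(),
               `T` = config$scale * config$f * noise())
  })
}

#' Simulate a dual-luciferase reporter table
#'
#' Each strain's in-frame (frame 0) firefly/renilla ratio is the WT ratio
#' times the strain's decoding odds ratio; the +1 frameshift reporter is
#' unaffected. Replicate cultures get independent lognormal noise on both
#' luciferase signals.
#'
#' @param config A [sim_config()] (supplies seed, replicates and noise).
#' @param odds Named numeric vector of decoding odds ratios per strain
#'   (WT = 1).
#' @param codon Codon label.
#' @return Data.frame: `strain`, `codon`, `frame`, `firefly`, `renilla`.
#' @export
simulate_reporter <- function(config, odds = c(WT = 1), codon = "UAU") {
  base_rt <- 2.0    # F/R of the in-frame WT reporter
  base_rs <- 0.05   # F/R of the +1 frameshift reporter
  with_stream(config$seed, 503L, {
    rows <- list()
    for (strain in names(odds)) {
      for (frame in c(0L, 1L)) {
        fr <- if (frame == 0L) base_rt * odds[[strain]] else base_rs
        for (r in seq_len(config$replicates)) {
          ren <- 1e5 * exp(stats::rnorm(1, 0, 0.2))
          ff <- fr * ren * exp(stats::rnorm(1, 0, config$intensity_cv))
          rows[[length(rows) + 1L]] <- data.frame(
            strain = strain, codon = codon, frame = frame,
            firefly = ff, renilla = ren, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
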