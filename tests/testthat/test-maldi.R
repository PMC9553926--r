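test_that("tetramer m/z values reproduce hand-computed [M-H]- masses", {
  expect_equal(mz_fragment(c("A", "G", "A", "C")), 1325.197,
               tolerance = 1e-3)
  expect_equal(mz_fragment(c("G", "A", "G", "D")), 1344.192,
               tolerance = 1e-3)
  expect_equal(mz_fragment(c("A", "G", "A", "Y"), ce_count = 1), 1379.208,
               tolerance = 1e-3)
  # positive mode sits two protons above negative mode
  expect_equal(mz_fragment(c("A", "G", "A", "C"), ion = "[M+H]+") -
                 mz_fragment(c("A", "G", "A", "C")),
               2 * PROTON_MASS, tolerance = 1e-9)
})

test_that("diagnostic species cover the C/U/U+2/Psi+CE channels in order", {
  s <- parse_modified_sequence(trna_like_bases(), trna_like_profile())
  theo <- diagnostic_species(protect_window(s, 10, 46), 32)
  expect_equal(theo$species, c("C", "U", "U+2", "Y+CE", "Y+CE+2"))
  expect_equal(theo$start[1], 29L); expect_equal(theo$end[1], 32L)
  d <- diff(theo$mz)
  expect_equal(d[1], 0.98402, tolerance = 1e-4)   # deamination
  expect_equal(d[2], 2.00425, tolerance = 1e-4)   # 18O
  expect_equal(theo$mz[4] - theo$mz[2], 53.0266, tolerance = 1e-4)  # CE
  # a position outside the protected window has no covering fragment
  expect_error(diagnostic_species(protect_window(s, 10, 46), 2),
               "no diagnostic fragment")
})

test_that("peak matching is greedy-nearest with exclusive pairing", {
  theo <- data.frame(species = c("a", "b"), mz = c(1000, 1000.1))
  # exact peaks -> both matched with zero error
  pk <- peak_list(c(1000, 1000.1), c(5, 9))
  a <- match_peaks(theo, pk, tolerance_da = 0.3)
  expect_equal(nrow(a), 2L)
  expect_equal(a$error, c(0, 0))
  # single peak between two close species goes to the nearer mass
  one <- match_peaks(theo, peak_list(1000.08, 7), tolerance_da = 0.3)
  expect_equal(one$species, "b")
  # a peak offset by twice the tolerance stays unmatched
  far <- match_peaks(theo, peak_list(1000.6, 7), tolerance_da = 0.3)
  expect_equal(nrow(far), 0L)
  expect_error(match_peaks(theo, pk, tolerance_da = 0), "positive")
})

test_that("shrinking the tolerance never adds assignments", {
  set.seed(41)
  theo <- data.frame(species = letters[1:6],
                     mz = sort(runif(6, 1000, 1400)))
  for (i in 1:20) {
    pk <- peak_list(runif(10, 990, 1410), runif(10, 1, 100))
    prev <- Inf
    for (tol in c(1, 0.5, 0.25, 0.1, 0.02)) {
      n <- nrow(match_peaks(theo, pk, tol))
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("assignments reproduce their theoretical masses internally", {
  s <- parse_modified_sequence(trna_like_bases(), trna_like_profile())
  prot <- protect_window(s, 10, 46)
  theo <- diagnostic_species(prot, 32)
  pk <- peak_list(theo$mz, rep(10, nrow(theo)))
  a <- match_peaks(theo, pk, 0.3)
  for (i in seq_len(nrow(a))) {
    j <- match(a$species[i], theo$species)
    recomputed <- mz_fragment(theo$codes[[j]], ce_count = theo$ce_count[j])
    expect_equal(a$theoretical_mz[i], recomputed, tolerance = 1e-6)
  }
})

test_that("editing-state inference mirrors the cyanoethylation readout", {
  theo <- data.frame(species = c("C", "U", "Y+CE"),
                     state = c("C", "U", "Y"),
                     mz = c(1325.197, 1326.181, 1379.208))
  call_of <- function(mz, int) {
    infer_editing_state(match_peaks(theo, peak_list(mz, int), 0.3), 32)
  }
  expect_equal(call_of(1325.197, 10)$state, "C")       # no enzyme
  expect_equal(call_of(1379.208, 10)$state, "Y")       # full editing
  expect_equal(call_of(1326.181, 10)$state, "U")       # deaminase only
  mixed <- call_of(c(1325.197, 1379.208), c(10, 10))
  expect_equal(mixed$state, "Y")
  expect_equal(mixed$fraction, 0.5)
  expect_error(call_of(1326.181, 0), "no diagnostic species observed")
})

test_that("the fraction estimator is a scale-invariant intensity ratio", {
  a <- data.frame(species = c("C", "Y+CE"), state = c("C", "Y"),
                  theoretical_mz = c(1325.2, 1379.2),
                  peak_mz = c(1325.2, 1379.2),
                  intensity = c(1, 1), error = c(0, 0))
  expect_equal(estimate_edit_fraction(a), 0.5)
  a$intensity <- c(0, 1)
  expect_equal(estimate_edit_fraction(a), 1.0)
  a$intensity <- c(30, 90)
  expect_equal(estimate_edit_fraction(a),
               estimate_edit_fraction(transform(a, intensity = intensity * 17)))
  a$intensity <- c(0, 0)
  expect_error(estimate_edit_fraction(a), "zero total")
})

test_that("peak lists load from CSV or TSV, with or without header", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "1325.2,100", "1310.0,30"), p1)
  pk <- read_peak_list(p1)
  expect_equal(pk$mz, c(1310.0, 1325.2))   # sorted ascending
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("1325.2\t100", "1310.0\t30"), p2)
  expect_equal(read_peak_list(p2)$mz, c(1310.0, 1325.2))
  expect_error(peak_list(c(-1, 2), c(1, 1)), "positive")
  expect_error(peak_list(1, -1), "non-negative")
})
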