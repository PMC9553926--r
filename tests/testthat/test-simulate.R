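test_that("the substrate generator plants the diagnostic anchors", {
  cfg <- sim_config(seed = 1)
  s <- make_trna_like(cfg)
  expect_equal(length(s), 85L)
  expect_equal(s$codes[13:16], c("G", "A", "G", "D"))
  expect_equal(s$codes[29:32], c("A", "G", "A", "C"))
  expect_equal(s$codes[34], "Q")
  expect_equal(s$codes[37], "ms2io6A")
  expect_equal(s$codes[54], "m5U")
  expect_equal(s$codes[83:85], c("C", "C", "A"))
  # the diagnostic tetramers really are limit-digest products of the window
  fr <- digest(protect_window(s, 10, 46), "RNaseA")
  expect_true(any(fr$start == 29 & fr$end == 32))
  expect_true(any(fr$start == 13 & fr$end == 16))
})

test_that("generators are deterministic under a fixed root seed", {
  cfg <- sim_config(seed = 42, f = 0.3, replicates = 3)
  expect_identical(make_trna_like(cfg)$codes, make_trna_like(cfg)$codes)
  expect_identical(simulate_maldi(cfg), simulate_maldi(cfg))
  expect_identical(simulate_mrm(cfg), simulate_mrm(cfg))
  expect_identical(simulate_trace(cfg), simulate_trace(cfg))
  # different seeds give different spectra
  cfg2 <- sim_config(seed = 43, f = 0.3)
  expect_false(identical(simulate_maldi(cfg), simulate_maldi(cfg2)))
  # replicates vary the noise stream but not the substrate
  expect_false(identical(simulate_maldi(cfg, replicate = 1),
                         simulate_maldi(cfg, replicate = 2)))
})

test_that("noiseless spectra sit exactly on theoretical masses", {
  cfg <- sim_config(seed = 3, f = 0, mass_error_sd = 0, intensity_cv = 0)
  pk <- simulate_maldi(cfg)
  s <- make_trna_like(cfg)
  theo <- diagnostic_species(protect_window(s, 10, 46), 32)
  # unedited: one peak at the exact unedited m/z, none at edited species
  expect_true(any(abs(pk$mz - theo$mz[theo$species == "C"]) < 1e-9))
  expect_false(any(abs(pk$mz - theo$mz[theo$species == "Y+CE"]) < 0.5))

  cfg1 <- sim_config(seed = 3, f = 1, ce = 1, w = 0,
                     mass_error_sd = 0, intensity_cv = 0)
  pk1 <- simulate_maldi(cfg1)
  hit <- abs(pk1$mz - theo$mz[theo$species == "Y+CE"]) < 1e-9
  expect_true(any(hit))
  # CE-shifted species sits 53.0266 + 0.98402 above the unedited one
  expect_equal(theo$mz[theo$species == "Y+CE"] -
                 theo$mz[theo$species == "C"],
               53.0266 + 0.98402, tolerance = 1e-4)
})

test_that("no non-diagnostic fragment crowds the diagnostic mass region", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed)
    s <- make_trna_like(cfg)
    prot <- protect_window(s, 10, 46)
    theo <- diagnostic_species(prot, 32)
    fr <- digest(prot, "RNaseA")
    other <- fr[!(fr$start <= 32 & fr$end >= 32), ]
    for (i in seq_len(nrow(other))) {
      m <- mz_fragment(other$codes[[i]], other$five_prime[i],
                       other$three_prime[i])
      expect_gt(min(abs(m - theo$mz)), 2)
    }
  }
})

test_that("simulated MRM tables reflect the linear labeling model", {
  # noiseless: normalized U+2 equals f * w exactly
  cfg <- sim_config(seed = 9, f = 0.6, w = 0.5, edit_state = "U",
                    intensity_cv = 0, replicates = 2)
  q <- quantify(simulate_mrm(cfg))
  u2 <- q$normalized[q$code == "U" & q$channel == "M+2"]
  expect_equal(u2, rep(0.6 * 0.5, 2), tolerance = 1e-9)
  expect_equal(q$normalized[q$code == "m5U"], rep(1, 2))
  # f = 0: no heavy signal at all
  q0 <- quantify(simulate_mrm(sim_config(seed = 9, f = 0, intensity_cv = 0)))
  expect_false(any(q0$channel == "M+2" & q0$normalized > 0))
  # halving w halves the normalized heavy channel
  qh <- quantify(simulate_mrm(sim_config(seed = 9, f = 1, w = 0.5,
                                         edit_state = "U",
                                         intensity_cv = 0)))
  qf <- quantify(simulate_mrm(sim_config(seed = 9, f = 1, w = 1,
                                         edit_state = "U",
                                         intensity_cv = 0)))
  expect_equal(qh$normalized[qh$code == "U" & qh$channel == "M+2"] /
                 qf$normalized[qf$code == "U" & qf$channel == "M+2"],
               0.5, tolerance = 1e-9)
})

test_that("trace simulation recovers the edited fraction", {
  cfg <- sim_config(seed = 4, f = 0.75, intensity_cv = 0)
  tr <- simulate_trace(cfg)
  expect_equal(editing_fraction_from_trace(tr[1, c("A", "C", "G", "T")]),
               0.75, tolerance = 1e-9)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(f = 1.2), "\\[0,1\\]")
  expect_error(sim_config(mass_error_sd = -1), ">= 0")
  expect_error(sim_config(length = 85,
                          profile = data.frame(position = 90, code = "D")),
               "beyond sequence length")
  expect_error(sim_config(length = 85, edit_position = 90), "beyond")
})
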