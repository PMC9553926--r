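test_that("protect_window keeps original coordinates and trims inclusively", {
  t <- parse_modified_sequence(trna_like_bases(), trna_like_profile())
  w <- protect_window(t, 10, 46)
  expect_equal(length(w), 37L)           # 46 - 10 + 1
  expect_equal(range(w$positions), c(10L, 46L))
  expect_equal(code_at <- w$codes[w$positions == 32], "C")
  expect_equal(protect_window(t, 1, 85)$codes, t$codes)
  expect_error(protect_window(t, 46, 10), "inverted")
  expect_error(protect_window(t, 0, 46), "outside")
  expect_error(protect_window(t, 10, 86), "outside")
})

test_that("RNase A releases the GAGDp and AGACp diagnostic tetramers", {
  t <- parse_modified_sequence(trna_like_bases(), trna_like_profile())
  w <- protect_window(t, 10, 46)
  fr <- digest(w, "RNaseA")
  gagd <- fr[fr$start == 13 & fr$end == 16, ]
  agac <- fr[fr$start == 29 & fr$end == 32, ]
  expect_equal(nrow(gagd), 1L)
  expect_equal(gagd$codes[[1]], c("G", "A", "G", "D"))
  expect_equal(gagd$three_prime, "p")
  expect_equal(agac$codes[[1]], c("A", "G", "A", "C"))
  expect_equal(agac$five_prime, "OH")
})

test_that("digestion handles no-site and T1 cases", {
  aaaa <- digest(parse_modified_sequence("AAAA"), "RNaseA")
  expect_equal(nrow(aaaa), 1L)
  expect_equal(aaaa$start, 1L); expect_equal(aaaa$end, 4L)

  t1 <- digest(parse_modified_sequence("AAGAA"), "RNaseT1")
  expect_equal(t1$sequence, c("AAG", "AA"))
  expect_equal(t1$three_prime, c("p", "OH"))
  # queuosine is guanosine-derived but non-cleavable by default
  q <- parse_modified_sequence("AAGAA", data.frame(position = 3, code = "Q"))
  expect_equal(nrow(digest(q, "RNaseT1")), 1L)
  # 2'-O-methyl blocks RNase A cleavage
  um <- parse_modified_sequence("AAUAA", data.frame(position = 3, code = "Um"))
  expect_equal(nrow(digest(um, "RNaseA")), 1L)
})

test_that("limit digests tile the input and match the brute-force scan", {
  set.seed(23)
  for (i in 1:200) {
    codes <- random_mod_codes(sample(1:60, 1))
    s <- mod_rna_seq(codes)
    for (enzyme in c("RNaseA", "RNaseT1")) {
      got <- digest(s, enzyme)
      want <- oracle_digest(codes, enzyme)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      # partition: spans tile the sequence exactly
      expect_equal(sum(got$length), length(codes))
      expect_equal(got$start[-1], got$end[-nrow(got)] + 1L,
                   ignore_attr = TRUE)
    }
  }
})

test_that("raising missed_cleavages only adds fragments", {
  set.seed(31)
  for (i in 1:20) {
    s <- mod_rna_seq(random_mod_codes(sample(5:40, 1)))
    prev <- NULL
    for (m in 0:3) {
      fr <- digest(s, "RNaseA", missed_cleavages = m)
      keys <- paste(fr$start, fr$end)
      if (!is.null(prev)) expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
})

test_that("terminal chemistry shifts masses as expected", {
  codes <- c("A", "G", "A", "C")
  linear <- fragment_mass(codes, three_prime = "p")
  expect_equal(linear - fragment_mass(codes, three_prime = "cp"),
               mass_of("H2O"), tolerance = 1e-9)
  expect_equal(linear - fragment_mass(codes, three_prime = "OH"),
               mass_of("HO3P"), tolerance = 1e-9)
  expect_equal(fragment_mass(codes, five_prime = "p") - linear,
               mass_of("HO3P"), tolerance = 1e-9)
  expect_error(fragment_mass(codes, three_prime = "x"), "unknown 3'")
})

test_that("fragment tables are written with neutral masses", {
  s <- mod_rna_seq(c("A", "G", "A", "C", "A", "A"))
  path <- tempfile(fileext = ".tsv")
  out <- write_fragment_table(digest(s, "RNaseA"), path)
  back <- read.delim(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$neutral_mass[1], fragment_mass(c("A", "G", "A", "C")),
               tolerance = 1e-6)
})
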