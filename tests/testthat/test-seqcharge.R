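test_that("parse_sequence tokenizes, normalizes case, and validates", {
  s <- parse_sequence("RKD")
  expect_equal(s$residues, c("R", "K", "D"))
  expect_identical(parse_sequence("rkd")$residues, s$residues)
  expect_error(parse_sequence("RKX"), "invalid residue")
  expect_error(parse_sequence(""), "empty")
  # PTM validation
  expect_error(parse_sequence("RKD", ptm = 2), "not tyrosine")
  expect_error(parse_sequence("RYD", ptm = 9), "out of range")
  expect_true(parse_sequence("RYD", ptm = 2)$ptm[2])
  # inline lowercase-y dialect
  expect_equal(which(parse_sequence("GyGYG")$ptm), 2L)
})

test_that("FASTA text and file round trip with records and PTM sidecar", {
  fa <- ">a first\nGGR\n>b second\nGYy\n"
  expect_equal(parse_sequence(fa)$residues, c("G", "G", "R"))
  s <- parse_sequence(fa, record = "b")
  expect_equal(s$residues, c("G", "Y", "Y"))
  expect_equal(which(s$ptm), 3L)
  expect_error(parse_sequence(fa, record = "zz"), "not found")
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(fa, tf)
  expect_equal(read_fasta_sequence(tf, record = "b")$residues,
               c("G", "Y", "Y"))
  pj <- withr::local_tempfile(fileext = ".json")
  writeLines("[2]", pj)
  expect_equal(which(read_fasta_sequence(tf, record = "b",
                                         ptm_json = pj)$ptm), c(2L, 3L))
})

test_that("Caprin1 fixture reproduces the published composition and charges", {
  wt <- builtin_sequence("caprin1_wt")
  expect_length(wt, 103)
  expect_equal(sum(wt$residues == "R"), 15)
  expect_equal(sum(wt$residues == "K"), 1)
  expect_equal(sum(wt$residues == "D"), 3)
  expect_equal(sum(wt$residues == "Y"), 7)
  expect_equal(wt_cs$Q, 13)
  m <- sequence_metrics(wt_cs)
  expect_equal(m$NCPR, 13 / 103)
  expect_equal(m$FCR, 19 / 103)
  # model pY-Caprin1: 7 pY at -2 each
  expect_equal(py_cs$Q, -1)
  expect_equal(sequence_metrics(py_cs)$NCPR, -1 / 103)
  # poly-G: all neutral
  pg <- charge_sequence(parse_sequence(strrep("G", 20)))
  expect_true(all(pg$sigma == 0) && pg$Q == 0)
})

test_that("RtoK variants substitute only arginines and keep charges", {
  wt <- builtin_sequence("caprin1_wt")
  v15 <- builtin_sequence("15Rto15K")
  expect_equal(sum(v15$residues == "R"), 0)
  expect_equal(sum(v15$residues == "K"), 16)
  expect_identical(charge_sequence(v15)$sigma, wt_cs$sigma)
  for (lab in c("4Rto4K_N", "4Rto4K_M", "4Rto4K_C")) {
    v <- builtin_sequence(lab)
    expect_equal(sum(v$residues != wt$residues), 4, info = lab)
    expect_identical(charge_sequence(v)$sigma, wt_cs$sigma, info = lab)
  }
  # identity and error paths
  expect_identical(make_variant(wt, matrix(numeric(0), 0, 2))$residues,
                   wt$residues)
  expect_error(make_variant(wt, cbind(1, "K"), expect_original = "R"),
               "mismatch")
})

test_that("electroneutrality relation in concentration and count form", {
  expect_equal(neutralize(13, 100, zc = 1, count = TRUE), 1300)
  expect_equal(neutralize(13, 100, zc = 2, count = TRUE), 650)
  # rearrangement rho_c = 13 rho_p + rho_s for monovalent ions
  rp <- runif(1); rs <- runif(1)
  expect_equal(neutralize(13, rp, 1, 1, rs), 13 * rp + rs)
  expect_error(neutralize(13, 3, zc = 2, count = TRUE), "non-integer")
  # residual is identically zero (property over random systems)
  set.seed(42)
  for (i in 1:25) {
    Q <- sample(-20:20, 1); zs <- sample(1:4, 1); zc <- sample(1:4, 1)
    rp <- runif(1, 0, 1e-3); rs <- runif(1, 0, 0.2)
    rc <- neutralize(Q, rp, zs, zc, rs)
    expect_equal(abs(Q) * rp + zs * rs - zc * rc, 0)
  }
})

test_that("charge metrics invariants hold for random sequences", {
  for (seed in 1:20) {
    cs <- random_cs(sample(5:200, 1), seed)
    expect_identical(cs$Q, sum(cs$sigma))
    m <- sequence_metrics(cs)
    expect_lte(abs(m$NCPR), m$FCR)
    expect_lte(m$FCR, 1)
  }
})

test_that("unit conversions are consistent and invertible", {
  mm <- sequence_molar_mass(builtin_sequence("caprin1_wt"))
  expect_gt(mm, 9000)  # ~100-residue IDR
  x <- c(1e-4, 0.2, 3)
  for (u in c("M", "mM", "uM", "b-3", "mg/ml")) {
    back <- convert_conc(convert_conc(x, "M", u, molar_mass = mm),
                         u, "M", molar_mass = mm)
    expect_equal(back, x, tolerance = 1e-12, info = u)
  }
  # mg/ml <-> uM consistency via independently summed residue masses
  wt <- builtin_sequence("caprin1_wt")
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  mm_oracle <- sum(masses[wt$residues]) + 18.0153
  expect_equal(convert_conc(1, "mg/ml", "uM", molar_mass = mm),
               1e6 / mm_oracle)
})

test_that("ion species bookkeeping", {
  atp <- ion_species("ATP-Mg", c(-1, -1, -1, -1, 1, 1), "counterion")
  expect_equal(atp$valency, -2)
  expect_length(atp$bead_charges, 6)
  na <- ion_species("Na", 1, "salt")
  expect_equal(na$valency, 1)
})
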