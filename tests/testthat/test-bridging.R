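test_that("extended-XYZ snapshots round-trip and validate", {
  sn <- ideal_gas_snapshot(20, box = c(30, 40, 50), seed = 7)
  sn2 <- snapshot(matrix(runif(9, 0, 20), 3, 3), c("R", "G", "CL"),
                  c(1L, 1L, NA_integer_), box = c(20, 20, 20))
  tf <- withr::local_tempfile(fileext = ".xyz")
  write_snapshots(list(sn, sn2), tf)
  back <- read_snapshots(tf)
  expect_length(back, 2)
  expect_equal(back[[1]]$coords, sn$coords, tolerance = 1e-6)
  expect_equal(back[[2]]$species, sn2$species)
  expect_equal(back[[2]]$chain, sn2$chain)
  expect_equal(back[[2]]$box, sn2$box)
  # missing chain column is an explicit error
  tf2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", 'box="10 10 10"', "CL 1.0 2.0 3.0"), tf2)
  expect_error(read_snapshots(tf2), "chain")
  # missing box
  tf3 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "frame 1", "CL - 1.0 2.0 3.0"), tf3)
  expect_error(read_snapshots(tf3), "box")
  # truncated frame
  tf4 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", 'box="10 10 10"', "CL - 1 2 3"), tf4)
  expect_error(read_snapshots(tf4), "truncated")
})

test_that("rdf is flat for an ideal gas and localized for a planted pair", {
  sns <- lapply(1:8, function(s) ideal_gas_snapshot(300, box = c(50, 50, 50),
                                                    seed = s))
  # centers: reuse the same beads under a different label in a copy
  sns <- lapply(sns, function(sn) {
    sn$species[1:30] <- "R"
    sn
  })
  g <- rdf(sns, "R", "CL", dr = 2, rmax = 20)
  bulk <- 270 / 50^3
  expect_lt(max(abs(g$rho - bulk)) / bulk, 0.25)        # flat within noise
  expect_lt(abs(mean(g$rho) - bulk) / bulk, 0.05)
  # bin-count total equals brute-force pair count within rmax
  sn <- sns[[1]]
  D <- ionphase:::.pdist_pbc(sn$coords[sn$species == "R", ],
                             sn$coords[sn$species == "CL", ], sn$box)
  expect_equal(sum(rdf(sn, "R", "CL", dr = 2, rmax = 20)$count),
               sum(D > 0 & D <= 20))
  # planted pair at r0 = 7.3: all mass in that bin
  sn1 <- snapshot(rbind(c(10, 10, 10), c(17.3, 10, 10)), c("R", "CL"),
                  box = c(40, 40, 40))
  g1 <- rdf(sn1, "R", "CL", dr = 1, rmax = 15)
  expect_equal(g1$count[g1$r == 7.5], 1)
  expect_equal(sum(g1$count), 1)
})

test_that("fraction_within counts (frame, ion) instances", {
  # planted: 2 frames x 2 ions; 3 of 4 instances in range => 0.75
  mk <- function(d1, d2) snapshot(rbind(c(10, 10, 10), c(10 + d1, 10, 10),
                                        c(30, 30, 30), c(30 + d2, 30, 30)),
                                  c("R", "CL", "R", "CL"),
                                  c(1L, NA, 2L, NA), box = c(60, 60, 60))
  expect_equal(fraction_within(list(mk(5, 5), mk(5, 20)), cutoff = 11), 0.75)
  # all ions on arginines -> 1; none in range -> 0
  expect_equal(fraction_within(mk(0.1, 0.2), cutoff = 11), 1.0)
  expect_equal(fraction_within(mk(20, 25), cutoff = 11), 0.0)
})

test_that("putative bridge enumeration matches a brute-force triple loop", {
  brute <- function(sn, cutoff = 11) {
    ia <- which(sn$species == "R" & !is.na(sn$chain))
    ii <- which(sn$species == "CL")
    n <- 0L
    for (q in ii) for (a in ia) for (b in ia) {
      if (a >= b || sn$chain[a] == sn$chain[b]) next
      da <- sqrt(sum(ionphase:::.min_image(sn$coords[q, ] - sn$coords[a, ],
                                           sn$box)^2))
      db <- sqrt(sum(ionphase:::.min_image(sn$coords[q, ] - sn$coords[b, ],
                                           sn$box)^2))
      if (da <= cutoff && db <= cutoff) n <- n + 1L
    }
    n
  }
  set.seed(5)
  for (rep in 1:5) {
    # box > 2 * (2 cutoff) keeps min-image triangles consistent
    n <- 80
    sn <- snapshot(matrix(runif(3 * n, 0, 50), n, 3),
                   sample(c("R", "G", "CL"), n, replace = TRUE),
                   chain = sample(c(1:4, NA), n, replace = TRUE),
                   box = c(50, 50, 50))
    sn$chain[sn$species == "CL"] <- NA_integer_
    cfg <- enumerate_putative_bridges(sn)
    expect_equal(nrow(cfg), brute(sn))
    if (nrow(cfg)) {
      expect_true(all(cfg$d_near <= cfg$d_far))
      expect_true(all(cfg$d_far <= 11))
      expect_true(all(cfg$d <= cfg$d_near + 1e-9))
      expect_true(all(cfg$R <= 22))
      expect_true(all(sn$chain[cfg$arg_a] != sn$chain[cfg$arg_b]))
    }
  }
})

test_that("combinatorics: one ion near k arginines on distinct chains", {
  # 4 in-range arginines on 4 distinct chains -> choose(4,2) = 6 configs
  ang <- seq(0, 2 * pi, length.out = 5)[1:4]
  coords <- rbind(c(0, 0, 0) + 25,
                  t(vapply(ang, function(a) 25 + 6 * c(cos(a), sin(a), 0),
                           numeric(3))))
  sn <- snapshot(coords, c("CL", rep("R", 4)), c(NA, 1:4), box = c(50, 50, 50))
  expect_equal(nrow(enumerate_putative_bridges(sn)), 6)
  # same chain: zero
  sn2 <- snapshot(coords, c("CL", rep("R", 4)), c(NA, rep(1L, 4)),
                  box = c(50, 50, 50))
  expect_equal(nrow(enumerate_putative_bridges(sn2)), 0)
})

test_that("geometric classification equals the explicit Coulomb-sum rule", {
  set.seed(9)
  for (rep in 1:4) {
    n <- 50
    sn <- snapshot(matrix(runif(3 * n, 0, 30), n, 3),
                   sample(c("R", "CL"), n, replace = TRUE, prob = c(0.6, 0.4)),
                   chain = sample(1:6, n, replace = TRUE),
                   box = c(30, 30, 30))
    sn$chain[sn$species == "CL"] <- NA_integer_
    cfg <- classify_bridges(enumerate_putative_bridges(sn))
    if (!nrow(cfg)) next
    # Coulomb oracle with unit charges: sum u = 1/R - 1/d_far, evaluated at
    # both bin edges (R ranging over the bin, d_far fixed)
    oracle <- vapply(seq_len(nrow(cfg)), function(i) {
      lo <- cfg$R_bin_lo[i]; hi <- cfg$R_bin_hi[i]; df <- cfg$d_far[i]
      # favorable (<0) for ALL R in [lo, hi) iff 1/hi- ... worst case at R=lo
      fav_all <- (1 / lo - 1 / df) < 0
      unfav_all <- (1 / hi - 1 / df) >= 0
      if (fav_all) "true" else if (unfav_all) "neutralizing" else "intermediate"
    }, character(1))
    expect_identical(cfg$class, oracle)
  }
})

test_that("per-ion statistics reproduce the compounding formula", {
  cfg <- data.frame(frame = rep(1:2, each = 5),
                    cl = c(rep(4L, 5), rep(9L, 5)),
                    class = c(rep("true", 4), "intermediate",
                              rep("true", 4), "intermediate"))
  st <- per_ion_statistics(cfg, n_frames = 2, n_ions = 10)
  expect_equal(st$frac_bridging, 2 / 20)
  expect_equal(st$mean_configs_per_ion, 5)
  expect_equal(st$p_true, 0.8)
  expect_equal(st$p_at_least_one, 1 - 0.2^5)
  # degenerate limits
  cfg$class <- "neutralizing"
  expect_equal(per_ion_statistics(cfg, 2, 10)$p_at_least_one, 0)
  cfg$class <- "true"
  expect_equal(per_ion_statistics(cfg, 2, 10)$p_at_least_one, 1)
  empty <- cfg[0, ]
  expect_equal(per_ion_statistics(empty, 2, 10)$frac_bridging, 0)
})

test_that("heat maps are symmetric with conserved mass", {
  cfg <- data.frame(x = c(2.1, 3.7, 5.2), d = c(1.3, 0.4, 2.9))
  hm <- bridge_heatmap(cfg, cell = 0.5)
  expect_equal(hm$P, hm$P[, rev(seq_along(hm$d))])  # P(x,d) = P(x,-d)
  expect_equal(sum(hm$P), nrow(cfg))
  # single config occupies exactly one +-d cell pair
  hm1 <- bridge_heatmap(cfg[1, ], cell = 0.5)
  expect_equal(sum(hm1$P > 0), 2)
  expect_equal(sum(hm1$P), 1)
})

test_that("isolated three-bead reference: flat, symmetric, contact-peaked", {
  # infinite temperature (lB = 0): uniform density over the accessible domain
  hm0 <- isolated_three_bead(R = 8, lB = 0, cell = 0.5)
  dens <- hm0$P_over_d[hm0$P > 0]
  expect_lt(diff(range(dens)) / mean(dens), 0.01)
  # symmetry under x <-> R - x for identical charges
  hm <- isolated_three_bead(R = 8, lB = 20, sigma = 4, cell = 0.5)
  P <- hm$P
  expect_equal(P, P[rev(seq_along(hm$x)), ], tolerance = 1e-9)
  # low temperature: density maximum at contact with an arginine, confirmed
  # by an independent quadrature at doubled resolution
  for (cell in c(0.5, 0.25)) {
    hmc <- isolated_three_bead(R = 8, lB = 60, sigma = 4, cell = cell)
    idx <- which(hmc$P_over_d == max(hmc$P_over_d), arr.ind = TRUE)[1, ]
    rpk <- min(sqrt(hmc$x[idx[1]]^2 + hmc$d[idx[2]]^2),
               sqrt((hmc$x[idx[1]] - 8)^2 + hmc$d[idx[2]]^2))
    expect_lt(abs(rpk - 4 * 12^(1 / 11)), 0.8)  # potential minimum ~ 1.25 sigma
  }
})
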