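test_that("two-body closed forms: Coulomb, LJ minimum, bond", {
  # bare Coulomb recovered with a very large cutoff
  p <- md_params(el_cutoff = 1e5, sr_cutoff = 0.1)
  cfg <- dimer_config(10, c("R", "K"), bonded = FALSE,
                      box = c(4e5, 4e5, 4e5))
  e <- md_energy(cfg, p)
  # documented force-shifted closed form; ~ bare Coulomb at r << cutoff
  rc <- 1e5
  expect_equal(e$U_el,
               332.0637 / 80 * (1 / 10 - 1 / rc + (10 - rc) / rc^2),
               tolerance = 1e-10)
  expect_equal(e$U_el, 332.0637 / 80 / 10, tolerance = 1e-3)
  expect_equal(e$U_el_pp, e$U_el)  # both beads are residues
  # opposite charges attract
  cfg2 <- dimer_config(10, c("R", "D"), bonded = FALSE, box = c(4e5, 4e5, 4e5))
  expect_equal(md_energy(cfg2, p)$U_el, -e$U_el, tolerance = 1e-9)
  # LJ pair at its minimum-energy distance: U_sr = -eps (large cutoff)
  kh <- synthetic_kh_matrix()
  sig <- (5.04 + 6.18) / 2  # A-I pair
  p2 <- md_params(el_cutoff = 1, sr_cutoff = 500)
  cfgLJ <- dimer_config(2^(1 / 6) * sig, c("A", "I"), bonded = FALSE,
                        box = c(2000, 2000, 2000))
  expect_equal(md_energy(cfgLJ, p2)$U_sr, -kh["A", "I"], tolerance = 1e-3)
  # repulsive (WCA) pair: zero beyond r_min, positive inside
  pr <- md_params(kh = synthetic_kh_matrix(eps0 = -1, scale = 0, eps_min = -0.3))
  expect_equal(md_energy(dimer_config(2^(1 / 6) * sig + 0.5, c("A", "I"),
                                      FALSE), pr)$U_sr, 0)
  expect_gt(md_energy(dimer_config(4, c("A", "I"), FALSE), pr)$U_sr, 0)
  # bonded dimer at the equilibrium length: U_bond = 0
  cfgB <- dimer_config(3.8, c("G", "G"), bonded = TRUE)
  expect_equal(md_energy(cfgB, md_params())$U_bond, 0, tolerance = 1e-12)
  expect_equal(md_energy(dimer_config(4.8, c("G", "G")),
                         md_params())$U_bond, 10 * 1^2)
  # decomposition sums to total
  expect_error(md_energy(dimer_config(0), md_params()), "zero distance")
})

test_that("energy decomposition is additive and forces are -grad U", {
  set.seed(21)
  p <- md_params()
  for (rep in 1:4) {
    n <- 14
    sp <- sample(c("R", "D", "G", "S", "NA", "CL"), n, replace = TRUE)
    chain <- c(rep(1L, 5), rep(2L, 4), rep(NA_integer_, n - 9))
    sp[1:9] <- sample(c("R", "D", "G", "S"), 9, replace = TRUE)
    sp[10:n] <- sample(c("NA", "CL"), n - 9, replace = TRUE)
    # chains as random walks, ions scattered
    x <- matrix(0, n, 3)
    x[1, ] <- c(20, 20, 20)
    for (i in 2:5) x[i, ] <- x[i - 1, ] + rnorm(3, sd = 2.5)
    x[6, ] <- c(32, 22, 20)
    for (i in 7:9) x[i, ] <- x[i - 1, ] + rnorm(3, sd = 2.5)
    x[10:n, ] <- matrix(runif(3 * (n - 9), 5, 45), ncol = 3)
    cfg <- snapshot(x, sp, chain, box = c(50, 50, 60))
    e <- md_energy(cfg, p)
    expect_equal(e$U_total, e$U_el + e$U_sr + e$U_bond)
    expect_equal(e$U_el, e$U_el_pp + e$U_el_pi + e$U_el_ii)
    # force vs central finite differences of the energy
    F <- md_forces(cfg, p)
    for (i in sample(n, 3)) for (c in 1:2) {
      h <- 1e-5
      up <- cfg; up$coords[i, c] <- up$coords[i, c] + h
      dn <- cfg; dn$coords[i, c] <- dn$coords[i, c] - h
      fd <- -(md_energy(up, p)$U_total - md_energy(dn, p)$U_total) / (2 * h)
      expect_lt(abs(F[i, c] - fd) / max(abs(fd), 1e-3), 1e-5)
    }
    # Newton's third law: net force vanishes
    expect_lt(max(abs(colSums(F))), 1e-9)
  }
})

test_that("isolated bead feels no force; neutral pair sums to zero", {
  cfg1 <- snapshot(matrix(c(10, 10, 10), 1, 3), "R", NA_integer_,
                   box = c(30, 30, 30))
  expect_equal(md_forces(cfg1, md_params()), matrix(0, 1, 3))
  cfg2 <- dimer_config(8, c("G", "G"), bonded = FALSE)
  expect_lt(max(abs(colSums(md_forces(cfg2, md_params())))), 1e-12)
})

test_that("Langevin thermostat equilibrates an ideal gas to the set T", {
  sn <- ideal_gas_snapshot(150, box = c(80, 80, 80), seed = 2, species = "G")
  run <- langevin_run(sn, md_params(dt = 0.4, friction = 1), T_K = 300,
                      steps = 3000, seed = 4, sample_every = 50,
                      forces_on = FALSE)
  Tkin <- mean(run$kinetic_T[-(1:10)])
  expect_lt(abs(Tkin - 300) / 300, 0.02)
  # seeded reproducibility
  r1 <- langevin_run(sn, md_params(), T_K = 300, steps = 50, seed = 9,
                     sample_every = 50, forces_on = FALSE)
  r2 <- langevin_run(sn, md_params(), T_K = 300, steps = 50, seed = 9,
                     sample_every = 50, forces_on = FALSE)
  expect_identical(r1$config$coords, r2$config$coords)
})

test_that("bonded chain without charges/wells matches Gaussian statistics", {
  # harmonic chain at temperature T: bond-length variance kT/(2k) per
  # dimension around r0; end-to-end distance^2 ~ (Nb-1) * <b^2> for the
  # ideal (non-interacting) chain
  nb <- 12
  set.seed(33)
  steps_xyz <- matrix(rnorm(3 * (nb - 1)), ncol = 3)
  steps_xyz <- steps_xyz / sqrt(rowSums(steps_xyz^2)) * 3.8
  x <- apply(rbind(c(1000, 1000, 1000), steps_xyz), 2, cumsum)
  kh0 <- synthetic_kh_matrix(eps0 = 0, scale = 0, eps_min = 0)
  p <- md_params(kh = kh0, charge = setNames(rep(0, 22),
                                             names(ionphase:::.CG_CHARGE)),
                 dt = 0.25, friction = 0.5)
  sn <- snapshot(x, rep("G", nb), rep(1L, nb), box = c(2000, 2000, 2000))
  run <- langevin_run(sn, p, T_K = 300, steps = 16000, seed = 12,
                      sample_every = 40)
  # discard the first half as equilibration
  frames <- run$frames[-(1:round(length(run$frames) / 2))]
  b2 <- vapply(frames, function(fr) {
    d <- diff(fr$coords)
    mean(rowSums(d^2))
  }, numeric(1))
  kT <- 0.0019872041 * 300
  # <(r - r0)^2> = 3 kT / (2 k_bond); <b^2> = r0^2 + that (tight springs)
  b2_theory <- 3.8^2 + 3 * kT / (2 * 10) + 2 * 3.8 * 0  # leading order
  expect_lt(abs(mean(b2) - b2_theory) / b2_theory, 0.05)
  ree <- vapply(frames, function(fr)
    sum((fr$coords[nb, ] - fr$coords[1, ])^2), numeric(1))
  expect_lt(abs(mean(ree) - (nb - 1) * mean(b2)) / ((nb - 1) * mean(b2)),
            0.35)  # Gaussian chain within sampling error
})

test_that("slab profiles: flat for homogeneous input, conserve mass", {
  sn <- ideal_gas_snapshot(4000, box = c(40, 40, 200), seed = 3, species = "G")
  prof <- slab_profiles(list(sn), bins = 20, recenter = FALSE)$G
  expect_equal(sum(prof$count), 4000)  # conservation, exactly
  expect_lt(stats::sd(prof$count) / mean(prof$count), 0.15)
  # two-plateau recovery within 2%
  slab <- two_plateau_slab(rho_dense = 0.01, rho_dilute = 0.001,
                           box = c(40, 40, 400), seed = 5, chain_len = 10)
  pr <- slab_profiles(list(slab), bins = 40)$G
  pl <- ionphase:::.plateaus(pr)
  bulk_to_mM <- function(rho) rho / 6.02214076e23 / 1e-27 * 1e3
  expect_lt(abs(pl["dense"] - bulk_to_mM(0.01)) / bulk_to_mM(0.01), 0.05)
  expect_lt(abs(pl["dilute"] - bulk_to_mM(0.001)) / bulk_to_mM(0.001), 0.1)
})

test_that("binodal_from_slabs recovers a planted critical point", {
  # plant a binodal: drho = A (1 - T/Tc)^beta, diameter rho_c + B (Tc - T)
  Tc <- 200; A <- 120; B <- 0.08; rho_c <- 30; beta <- 0.325
  Ts <- c(120, 140, 160, 180)
  profs <- lapply(Ts, function(T) {
    dr <- A * (1 - T / Tc)^beta
    mid <- rho_c + B * (Tc - T)
    dense <- mid + dr / 2
    dil <- mid - dr / 2
    z <- seq_len(40)
    mM <- ifelse(z > 15 & z <= 25, dense, dil)
    data.frame(z = z * 10, mM = mM, mg_ml = mM, count = mM)
  })
  fit <- binodal_from_slabs(profs, Ts)
  expect_lt(abs(fit$Tcr - Tc) / Tc, 0.02)
  expect_lt(abs(fit$rho_cr - rho_c) / rho_c, 0.15)
  expect_true(all(fit$binodal$dense > fit$binodal$dilute))
  # near-critical profiles without separation are flagged
  flat <- lapply(profs, function(p) { p$mM <- 30; p })
  expect_error(binodal_from_slabs(flat, Ts), "plateau")
})
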