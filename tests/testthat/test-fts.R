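# small lattices keep these deterministic checks fast; the physics-level
# (scaled-down) properties live in test-acceptance.R

test_that("build_system enforces electroneutrality via the free species", {
  cfg <- fts_config(dims = c(8, 8, 8), n_therm = 10, n_prod = 10,
                    sample_every = 10)
  wt <- charge_sequence(builtin_sequence("caprin1_wt"))
  sys <- build_system(list(species_spec("prot", wt$sigma, 1e-4),
                           species_spec("CL", -1, NA)), cfg)
  expect_equal(sys$species[[2]]$rho, 13 * 1e-4)  # Q = +13 per chain
  expect_equal(sum(atp_mg_species(1)$bead_charges), -2)
  # all-neutral species, no free ion: valid
  s0 <- build_system(list(species_spec("A", 0, 0.1)), cfg)
  expect_equal(s0$species[[1]]$rho, 0.1)
  # unneutralizable compositions
  expect_error(build_system(list(species_spec("prot", wt$sigma, 1e-4),
                                 species_spec("NA", 1, NA)), cfg),
               "negative density")
  expect_error(build_system(list(species_spec("prot", wt$sigma, 1e-4)), cfg),
               "not electroneutral")
})

test_that("single-molecule partition function: limits and gauge identity", {
  dims <- c(8, 8, 8)
  zero <- array(0 + 0i, dims)
  # zero fields -> Q = 1
  wt <- charge_sequence(builtin_sequence("caprin1_wt"))
  out <- single_molecule_partition(zero, zero, wt$sigma)
  expect_equal(out$Q, 1 + 0i, tolerance = 1e-12)
  # single-bead species: Q = spatial mean of exp(i(sigma psi + w)) with the
  # adopted sign convention exp(-i(...))
  set.seed(4)
  w_s <- array(complex(real = rnorm(512, sd = 0.1),
                       imaginary = rnorm(512, sd = 0.1)), dims)
  psi_s <- array(complex(real = rnorm(512, sd = 0.1),
                         imaginary = rnorm(512, sd = 0.1)), dims)
  o1 <- single_molecule_partition(w_s, psi_s, bead_charges = -1)
  expect_equal(o1$Q, mean(exp(-1i * (-1 * psi_s + w_s))), tolerance = 1e-10)
  # gauge: w -> w + c multiplies Q_m by exp(-i M c) for an M-bead species
  cshift <- 0.17
  oM <- single_molecule_partition(w_s, psi_s, wt$sigma)
  oMs <- single_molecule_partition(w_s + cshift, psi_s, wt$sigma)
  expect_equal(oMs$Q, oM$Q * exp(-1i * length(wt$sigma) * cshift),
               tolerance = 1e-8)
  # per-bead densities sum to M * rho on volume average (bookkeeping)
  tot <- Reduce(`+`, lapply(oM$rho_beads, mean))
  expect_equal(tot, complex(real = length(wt$sigma)), tolerance = 1e-8)
})

test_that("CL stepping: determinism, saddle stationarity, linear relaxation", {
  cfg <- fts_config(dims = c(8, 8, 8), lB = 1, v2 = 0.1, dt = 0.01,
                    n_therm = 10, n_prod = 10, sample_every = 1, nblocks = 2,
                    seed = 1)
  sys <- build_system(list(species_spec("A", 0, 0.2)), cfg)
  # identical seeds -> identical trajectories (bitwise)
  a <- fts_cl_steps(sys, nsteps = 40, seed = 7)
  b <- fts_cl_steps(sys, nsteps = 40, seed = 7)
  expect_identical(a$w, b$w)
  expect_identical(a$psi, b$psi)
  expect_false(identical(a$w, fts_cl_steps(sys, nsteps = 40, seed = 8)$w))
  # zero-noise flow from the homogeneous saddle point is stationary
  sad <- array(complex(real = 0, imaginary = -0.1 * 0.2), c(8, 8, 8))
  st <- fts_cl_steps(sys, nsteps = 50, seed = 1, noise = FALSE, w0 = sad)
  expect_lt(max(abs(st$w - sad)), 1e-5)
  expect_lt(max(abs(st$psi)), 1e-6)
  # linearized single-mode decay matches the semi-implicit amplification
  # factor 1/(1 + dt lambda_k), lambda_k = 1/v2 + Gamma^2 rho (exact for a
  # single-bead neutral species)
  # (fields are single precision, so use a perturbation well above the
  # float noise floor and a matching tolerance)
  dims <- c(8, 8, 8)
  xg <- (0:7)
  pert <- 2e-2 * array(rep(cos(2 * pi * xg / 8), 64), dims)
  w0 <- sad + pert
  n <- 15
  out <- fts_cl_steps(sys, nsteps = n, seed = 1, noise = FALSE, w0 = w0)
  amp <- function(w) Re(fft(w - sad)[2, 1, 1]) / 512
  k1 <- 2 * pi / 8
  lam <- 1 / 0.1 + exp(-cfg$a^2 * k1^2) * 0.2
  expect_equal(amp(out$w) / amp(w0), (1 / (1 + 0.01 * lam))^n,
               tolerance = 5e-3)
})

test_that("noninteracting baseline: normalized G = 1 at large r", {
  cfg <- fts_config(dims = c(8, 8, 8), lB = 1, v2 = 0.05, dt = 0.01,
                    n_therm = 200, n_prod = 1000, sample_every = 5,
                    nblocks = 4, seed = 3)
  sys <- build_system(list(species_spec("A", 0, 0.1)), cfg)
  run <- fts_run(sys, pairs = list(c("A", "A")))
  cc <- estimate_correlations(run)
  far <- cc[cc$r >= 3, ]
  expect_true(all(abs(far$G_norm - 1) < 3 * pmax(far$se_norm, 1e-4) + 1e-3))
  # canonical bookkeeping: mean bead density equals the imposed bulk density
  expect_equal(unname(run$mean_rho), 0.1, tolerance = 1e-5)
  expect_lt(abs(run$mean_rho_im), 1e-6)
})

test_that("divergent trajectories abort with a diagnostic", {
  cfg <- fts_config(dims = c(8, 8, 8), lB = 50, v2 = 1e-6, dt = 5,
                    n_therm = 50, n_prod = 100, sample_every = 5,
                    nblocks = 2, seed = 1)
  wt <- charge_sequence(builtin_sequence("caprin1_wt"))
  sys <- build_system(list(species_spec("prot", wt$sigma, 5e-3),
                           species_spec("CL", -1, NA)), cfg)
  expect_error(fts_run(sys, pairs = list(c("prot", "prot"))),
               "diverged|insufficient")
})
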