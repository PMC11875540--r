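#' @title Field-theoretic simulation via complex-Langevin dynamics
#' @name fts
#' @description
#' Lattice field-theoretic simulation (FTS) of mixtures of charge-sequenced
#' polymers, a 6-bead ATP-Mg species, and monovalent ions. Two complex
#' fields -- `w` conjugate to total bead density (excluded volume `v2`) and
#' `psi` conjugate to charge density (Coulomb, Bjerrum length `lB`) -- evolve
#' in fictitious complex-Langevin (CL) time; thermal averages are CL-time
#' averages, whose imaginary parts must vanish within statistical error
#' (asserted as a consistency check). All interactions are regularized by a
#' Gaussian smearing `Gamma` of width `a`. Units: lengths in the Kuhn
#' length b, densities in b^-3.
#'
#' Desk-scale defaults (32^3 lattice, 5e4 thermalization + 2e5 production
#' steps) are documented in [fts_config()]; the package's own tests use
#' aggressively scaled-down lattices and step counts, documented there.
NULL

#' Species specification for FTS
#'
#' @param label species name.
#' @param bead_charges per-bead charge vector: length N for a protein, 6 for
#'   ATP-Mg (`c(-1,-1,-1,-1,+1,+1)`: phosphate tail then two half-Mg beads),
#'   1 for simple ions.
#' @param rho chain (molecule) number density in b^-3; `NA` marks the species
#'   whose density is left free to enforce electroneutrality.
#' @return a `SpeciesSpec`.
#' @export
species_spec <- function(label, bead_charges, rho = NA_real_) {
  structure(list(label = label, bead_charges = as.numeric(bead_charges),
                 rho = rho),
            class = "SpeciesSpec")
}

#' ATP-Mg 6-bead species
#'
#' Four -1 phosphate-tail beads followed by two +1 beads modeling the
#' complexed magnesium; net charge -2.
#'
#' @param rho bead-chain number density (b^-3). Note: the paper-style
#'   concentrations `[(ATP-Mg)2-]/b^-3` quote *bead* densities; divide by 6
#'   for the chain density or use [atp_mg_bead_density()].
#' @export
atp_mg_species <- function(rho = NA_real_) {
  species_spec("ATP-Mg", c(-1, -1, -1, -1, 1, 1), rho)
}

#' Convert an ATP-Mg bead density to a chain density
#' @param rho_beads bead density (b^-3).
#' @export
atp_mg_bead_density <- function(rho_beads) rho_beads / 6

#' FTS configuration
#'
#' @param dims lattice dimensions (powers of two).
#' @param dx lattice spacing (b).
#' @param lB Bjerrum length (b); 7 reproduces the strong-coupling conditions
#'   of the ATP-Mg study.
#' @param v2 excluded-volume parameter (b^3), applied to all bead types.
#' @param a smearing width (b); default `1/sqrt(6)` so smeared monomers have
#'   bond-scale size.
#' @param dt CL timestep.
#' @param n_therm,n_prod thermalization / production step counts.
#' @param sample_every sampling stride during production.
#' @param nblocks block count for error estimation.
#' @param seed RNG seed.
#' @return an `FTSConfig`.
#' @export
fts_config <- function(dims = c(32, 32, 32), dx = 1, lB = 7, v2 = 0.0068,
                       a = 1 / sqrt(6), dt = 0.005, n_therm = 50000,
                       n_prod = 200000, sample_every = 50, nblocks = 8,
                       seed = 1) {
  stopifnot(all(dims > 0), dt > 0, a > 0, n_prod >= sample_every)
  structure(list(dims = as.integer(dims), dx = dx, lB = lB, v2 = v2, a = a,
                 dt = dt, n_therm = as.integer(n_therm),
                 n_prod = as.integer(n_prod),
                 sample_every = as.integer(sample_every),
                 nblocks = as.integer(nblocks), seed = as.integer(seed)),
            class = "FTSConfig")
}

#' Assemble an FTS system, enforcing electroneutrality
#'
#' At most one species may have `rho = NA`; its density is set so the total
#' charge vanishes. If no species is free the composition must already be
#' neutral.
#'
#' @param species list of `SpeciesSpec`.
#' @param config an `FTSConfig`.
#' @return an `FTSSystem` list with resolved species densities.
#' @export
build_system <- function(species, config = fts_config()) {
  qs <- vapply(species, function(s) sum(s$bead_charges), numeric(1))
  rho <- vapply(species, function(s) s$rho, numeric(1))
  free <- which(is.na(rho))
  if (length(free) > 1) stop("at most one species may have free density")
  net <- sum(qs[!is.na(rho)] * rho[!is.na(rho)])
  if (length(free) == 1) {
    if (qs[free] == 0) stop("free species is neutral: cannot neutralize")
    rho[free] <- -net / qs[free]
    if (rho[free] < 0) stop("unneutralizable composition: free species ",
                            "would need negative density")
  } else if (abs(net) > 1e-12) {
    stop("composition is not electroneutral and no species is free")
  }
  for (i in seq_along(species)) species[[i]]$rho <- rho[i]
  structure(list(species = species, config = config,
                 labels = vapply(species, `[[`, character(1), "label")),
            class = "FTSSystem")
}

.sys_cpp_species <- function(system) {
  lapply(system$species, function(s)
    list(charges = s$bead_charges, rho = s$rho))
}

#' Single-molecule partition function and bead densities (reference R path)
#'
#' Pure-R evaluation of the chain propagator recursion for one species in
#' given (already smeared) fields: `Q_m` is the volume average of the final
#' propagator, and the per-bead density operator fields are returned. Used as
#' an independent cross-check of the compiled CL kernel and for the
#' analytical gauge/limit identities.
#'
#' @param w_s,psi_s complex 3-d arrays: smeared fields.
#' @param bead_charges per-bead charges.
#' @param rho chain number density.
#' @param dx lattice spacing (b).
#' @return list with `Q` (complex scalar) and `rho_beads` (list of complex
#'   arrays, one per bead).
#' @export
single_molecule_partition <- function(w_s, psi_s, bead_charges, rho = 1,
                                      dx = 1) {
  dims <- dim(w_s)
  stopifnot(length(dims) == 3, identical(dim(psi_s), dims))
  M <- length(bead_charges)
  kk <- .lattice_k2(dims, dx)
  bond <- exp(-kk / 6)
  conv <- function(f) fft(fft(f) * bond, inverse = TRUE) / prod(dims)
  h <- lapply(bead_charges, function(sg) exp(-1i * (sg * psi_s + w_s)))
  qd <- vector("list", M)  # propagated weight before the local factor
  qd[[1]] <- array(1 + 0i, dims)
  if (M > 1) for (b in 2:M) qd[[b]] <- conv(h[[b - 1]] * qd[[b - 1]])
  Q <- mean(h[[M]] * qd[[M]])
  qb <- vector("list", M)
  qb[[M]] <- h[[M]]
  if (M > 1) for (b in (M - 1):1) qb[[b]] <- h[[b]] * conv(qb[[b + 1]])
  rho_beads <- lapply(seq_len(M), function(b) rho / Q * qd[[b]] * qb[[b]])
  list(Q = Q, rho_beads = rho_beads)
}

.lattice_k2 <- function(dims, dx) {
  kx <- 2 * pi / (dims[1] * dx) *
    ifelse(0:(dims[1] - 1) <= dims[1] / 2, 0:(dims[1] - 1),
           0:(dims[1] - 1) - dims[1])
  ky <- 2 * pi / (dims[2] * dx) *
    ifelse(0:(dims[2] - 1) <= dims[2] / 2, 0:(dims[2] - 1),
           0:(dims[2] - 1) - dims[2])
  kz <- 2 * pi / (dims[3] * dx) *
    ifelse(0:(dims[3] - 1) <= dims[3] / 2, 0:(dims[3] - 1),
           0:(dims[3] - 1) - dims[3])
  outer(outer(kx^2, ky^2, "+"), kz^2, "+")
}

#' Advance the CL fields
#'
#' Runs `nsteps` semi-implicit CL updates from the given field state (or the
#' homogeneous mean-field start) and returns the evolved fields. Bitwise
#' reproducible for a given seed; `noise = FALSE` gives the deterministic
#' drift flow, under which the homogeneous saddle point is stationary.
#'
#' @param system an `FTSSystem`.
#' @param nsteps number of CL steps.
#' @param seed RNG seed.
#' @param noise include the stochastic term.
#' @param w0,psi0 complex arrays (lattice fields) to start from; default is
#'   the homogeneous mean-field saddle.
#' @return list with complex arrays `w`, `psi` and the `diverged` flag.
#' @export
fts_cl_steps <- function(system, nsteps, seed = 1, noise = TRUE,
                         w0 = NULL, psi0 = NULL) {
  cfg <- system$config
  out <- .fts_run_cpp(cfg$dims, cfg$dx, cfg$lB, cfg$v2, cfg$a, cfg$dt,
                      .sys_cpp_species(system),
                      n_therm = as.integer(nsteps), n_prod = 0L,
                      sample_every = 1L, seed = as.integer(seed),
                      pairs = matrix(integer(0), 0, 2),
                      profile_species = -1L, profile_q = -1L,
                      rcontact = 0, nblocks = 1L, noise = noise,
                      w0 = if (!is.null(w0)) as.complex(w0),
                      psi0 = if (!is.null(psi0)) as.complex(psi0))
  list(w = array(out$w, cfg$dims), psi = array(out$psi, cfg$dims),
       diverged = out$diverged)
}

#' Run an FTS production simulation
#'
#' Thermalizes, then accumulates radially averaged density-density
#' correlations `G_mn(r)` for the requested species pairs (and optionally the
#' residue-resolved integrated contact profile against a partner species),
#' with block averaging for errors.
#'
#' @param system an `FTSSystem`.
#' @param pairs character matrix (n x 2) or list of species-label pairs.
#' @param profile label of the chain species for the residue-specific contact
#'   profile (`NULL` for none).
#' @param profile_q partner species label for the profile.
#' @param rcontact contact radius (b) for the integrated profile.
#' @param sample_fields record a few density-field snapshots.
#' @return an `FTSRun` list: `r`, per-pair `G` (mean), `G_se` (block
#'   standard error), `G_im` (imaginary part, consistency check),
#'   normalization densities, `profile` (matrix residue x c(mean, se, im)),
#'   species mean densities, `Q_im` diagnostics, and `diverged`.
#' @export
fts_run <- function(system, pairs = list(), profile = NULL, profile_q = NULL,
                    rcontact = 1.5, sample_fields = FALSE) {
  cfg <- system$config
  labs <- system$labels
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  pidx <- if (length(pairs))
    t(vapply(pairs, function(p) {
      i <- match(p, labs)
      if (any(is.na(i))) stop("unknown species in pair: ",
                              paste(p, collapse = "-"))
      i - 1L
    }, integer(2)))
  else matrix(integer(0), 0, 2)
  prof_i <- if (!is.null(profile)) match(profile, labs) - 1L else -1L
  prof_q <- if (!is.null(profile_q)) match(profile_q, labs) - 1L else -1L
  if (!is.null(profile) && is.na(prof_i)) stop("unknown profile species")
  if (!is.null(profile_q) && is.na(prof_q)) stop("unknown profile_q species")

  out <- .fts_run_cpp(cfg$dims, cfg$dx, cfg$lB, cfg$v2, cfg$a, cfg$dt,
                      .sys_cpp_species(system), cfg$n_therm, cfg$n_prod,
                      cfg$sample_every, cfg$seed,
                      pairs = pidx, profile_species = prof_i,
                      profile_q = prof_q, rcontact = rcontact,
                      nblocks = cfg$nblocks, noise = TRUE,
                      sample_fields = sample_fields)
  if (out$diverged)
    stop("complex-Langevin trajectory diverged; reduce dt or densities")
  ns <- out$nsamp_block
  if (sum(ns > 0) < 2) stop("insufficient production samples for blocking")
  # block means
  npair <- nrow(pidx)
  G <- G_se <- G_im <- NULL
  if (npair) {
    bm <- sweep(out$Gr_re, 3, pmax(ns, 1), "/")        # [nbin, npair, nb]
    bi <- sweep(out$Gr_im, 3, pmax(ns, 1), "/")
    # shell average: accumulators hold sums over the cells of each bin
    bm <- sweep(bm, 1, pmax(out$bincount, 1), "/")
    bi <- sweep(bi, 1, pmax(out$bincount, 1), "/")
    keep <- ns > 0
    G <- apply(bm[, , keep, drop = FALSE], c(1, 2), mean)
    G_se <- apply(bm[, , keep, drop = FALSE], c(1, 2), stats::sd) /
      sqrt(sum(keep))
    G_im <- apply(bi[, , keep, drop = FALSE], c(1, 2), mean)
    G_im_se <- apply(bi[, , keep, drop = FALSE], c(1, 2), stats::sd) /
      sqrt(sum(keep))
    colnames(G) <- colnames(G_se) <- colnames(G_im) <- colnames(G_im_se) <-
      vapply(pairs, paste, character(1), collapse = ":")
  }
  rho_bead <- vapply(system$species, function(s)
    s$rho * length(s$bead_charges), numeric(1))
  names(rho_bead) <- labs
  profile_out <- NULL
  if (prof_i >= 0 && prof_q >= 0) {
    pm <- sweep(out$profile_re, 2, pmax(ns, 1), "/")
    pi_ <- sweep(out$profile_im, 2, pmax(ns, 1), "/")
    keep <- ns > 0
    profile_out <- data.frame(
      i = seq_len(nrow(pm)),
      G = rowMeans(pm[, keep, drop = FALSE]),
      se = apply(pm[, keep, drop = FALSE], 1, stats::sd) / sqrt(sum(keep)),
      G_im = rowMeans(pi_[, keep, drop = FALSE]))
    # normalization: per-residue bulk density is the chain density
    rp_i <- system$species[[prof_i + 1]]$rho
    rq <- rho_bead[[prof_q + 1]]
    profile_out$G_norm <- profile_out$G / (rp_i * rq)
    profile_out$se_norm <- profile_out$se / (rp_i * rq)
  }
  structure(list(r = out$r, G = G, G_se = G_se, G_im = G_im,
                 G_im_se = if (npair) G_im_se,
                 bincount = out$bincount,
                 rho_bead = rho_bead,
                 mean_rho = out$mean_rho_re / out$nsamp,
                 mean_rho_im = out$mean_rho_im / out$nsamp,
                 Q_im = out$Qm_im_abs / out$nsamp,
                 Q_re = out$Qm_re / out$nsamp,
                 profile = profile_out,
                 nsamp = out$nsamp,
                 snapshots = out$snapshots,
                 config = cfg, labels = labs),
            class = "FTSRun")
}

#' Normalized correlation functions from a run
#'
#' Returns `G_mn(r) / (rho_m0 rho_n0)` with block standard errors, the
#' homogeneous baseline being 1 at large r. Values below 1 at large r signal
#' phase separation (a region depleted relative to the bulk density).
#'
#' @param run an `FTSRun`.
#' @return data.frame in long format: `pair`, `r`, `G_norm`, `se_norm`,
#'   `G_im_norm`.
#' @export
estimate_correlations <- function(run) {
  if (is.null(run$G)) stop("run was collected without pairs")
  pairs <- colnames(run$G)
  do.call(rbind, lapply(pairs, function(pp) {
    mn <- strsplit(pp, ":", fixed = TRUE)[[1]]
    norm <- run$rho_bead[[mn[1]]] * run$rho_bead[[mn[2]]]
    data.frame(pair = pp, r = run$r, G_norm = run$G[, pp] / norm,
               se_norm = run$G_se[, pp] / norm,
               G_im_norm = run$G_im[, pp] / norm,
               im_se_norm = run$G_im_se[, pp] / norm)
  }))
}

#' Residue-specific contact profile
#'
#' The integrated correlation `G_pq(i)/(rho_p,i0 rho_q0)` for each residue i
#' of the profiled chain species against the partner species q, i.e. the
#' relative contact frequency within `rcontact`.
#'
#' @param run an `FTSRun` collected with `profile`/`profile_q`.
#' @return data.frame with `i`, `G_norm`, `se_norm`, `G_im`.
#' @export
residue_contact_profile <- function(run) {
  if (is.null(run$profile)) stop("run was collected without a profile")
  run$profile
}
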