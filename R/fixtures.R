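#' @title Deterministic synthetic-input generators
#' @name fixtures
#' @description
#' Pure functions of (parameters, seed) that build test surfaces for every
#' analysis stage: planted-geometry bridging snapshots, ideal-gas
#' configurations, two-plateau slab configurations, and synthetic coexistence
#' datasets generated from known interaction parameters. Each generator
#' seeds R's RNG locally (restoring the caller's RNG state), so identical
#' calls give identical output.
NULL

# run fn with a local RNG state
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' Snapshot with planted bridging configurations
#'
#' Places well-separated Arg+ -- Cl- -- Arg+ triplets with prescribed
#' geometry and class, padding the rest of each "chain" with neutral glycine
#' beads far away, so [enumerate_putative_bridges()] and [classify_bridges()]
#' must recover exactly the planted set.
#'
#' @param planted data.frame with columns `R` (Arg-Arg distance, A), `d`
#'   (perpendicular Cl offset from the midpoint, A) and `class`
#'   (`"true"` or `"neutralizing"`; geometry is derived from the class via
#'   the 2 A binning rule: true plants the ion on the perpendicular bisector
#'   at the midpoint, neutralizing plants it collinear beyond one Arg at
#'   `d_far >=` bin upper edge).
#' @param cutoff bridging cutoff (A).
#' @param seed RNG seed (jitters nothing; kept for interface uniformity).
#' @param box_pad spacing multiplier between planted triplets.
#' @return a `Snapshot` with species `R`, `G`, `CL` and one chain per Arg.
#' @export
planted_bridges_snapshot <- function(planted, cutoff = 11, seed = 1,
                                     box_pad = 3) {
  n <- nrow(planted)
  spacing <- box_pad * 2 * cutoff
  L <- max(spacing * max(n, 1) + spacing, 4 * cutoff)
  coords <- NULL; species <- NULL; chain <- NULL
  next_chain <- 1L
  for (i in seq_len(n)) {
    base <- c((i - 0.5) * spacing, L / 2, L / 2)
    R <- planted$R[i]
    a <- base
    b <- base + c(R, 0, 0)
    cls <- planted$class[i]
    bin_lo <- floor(R / 2) * 2
    bin_hi <- bin_lo + 2
    if (cls == "true") {
      # midpoint placement: d_far = sqrt((R/2)^2 + d^2) must stay below the
      # bin lower edge (which exceeds R/2 for R >= 2)
      d_cap <- sqrt(max((bin_lo - 0.1)^2 - (R / 2)^2, 1e-4))
      dd <- min(planted$d[i], d_cap)
      ion <- base + c(R / 2, dd, 0)
    } else if (cls == "neutralizing") {
      # collinear beyond arg a: d_near = t, d_far = R + t with
      # t in [bin_hi - R, cutoff - R] (needs R <= cutoff - (bin_hi - R))
      if (bin_hi > cutoff)
        stop("neutralizing plant infeasible: R bin exceeds cutoff")
      t_off <- ((bin_hi - R) + (cutoff - R)) / 2
      ion <- a - c(t_off, 0, 0)
    } else stop("plant class must be 'true' or 'neutralizing'")
    coords <- rbind(coords, a, b, ion)
    species <- c(species, "R", "R", "CL")
    chain <- c(chain, next_chain, next_chain + 1L, NA_integer_)
    next_chain <- next_chain + 2L
  }
  if (is.null(coords)) {
    coords <- matrix(c(L / 2, L / 2, L / 2), 1, 3)
    species <- "G"; chain <- NA_integer_
  }
  snapshot(coords, species, chain, box = c(L, L, L))
}

#' Uniform ideal-gas snapshot
#'
#' @param n number of beads.
#' @param box numeric length-3 box (A).
#' @param seed RNG seed.
#' @param species species label for all beads.
#' @return a `Snapshot`.
#' @export
ideal_gas_snapshot <- function(n, box = c(60, 60, 60), seed = 1,
                               species = "CL") {
  stopifnot(n > 0)
  .with_seed(seed, function() {
    coords <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                    stats::runif(n, 0, box[3]))
    snapshot(coords, rep(species, n), rep(NA_integer_, n), box)
  })
}

#' Two-plateau slab configuration
#'
#' Beads are placed uniformly in xy; along z a central slab of width
#' `frac_dense * Lz` holds the dense density and the remainder the dilute
#' density, with an optional linear interface ramp.
#'
#' @param rho_dense,rho_dilute number densities (beads / A^3).
#' @param box numeric length-3 (A), z elongated.
#' @param interface_width ramp width (A), 0 for a sharp step.
#' @param frac_dense fraction of the box length occupied by the dense slab.
#' @param seed RNG seed.
#' @param species species label.
#' @param chain_len if > 0, beads are grouped into chains of this length
#'   (chain ids only; positions stay independent) so slab recentering can
#'   key on chain beads.
#' @return a `Snapshot`.
#' @export
two_plateau_slab <- function(rho_dense, rho_dilute, box = c(40, 40, 400),
                             interface_width = 0, frac_dense = 0.3,
                             seed = 1, species = "G", chain_len = 0) {
  stopifnot(rho_dense > rho_dilute, rho_dilute >= 0)
  .with_seed(seed, function() {
    Lz <- box[3]; A <- box[1] * box[2]
    zmid <- Lz / 2; half <- frac_dense * Lz / 2
    dens_z <- function(z) {
      dz <- abs(z - zmid)
      if (interface_width <= 0) {
        if (dz <= half) rho_dense else rho_dilute
      } else {
        w <- interface_width
        if (dz <= half - w / 2) rho_dense
        else if (dz >= half + w / 2) rho_dilute
        else rho_dilute + (rho_dense - rho_dilute) *
            (half + w / 2 - dz) / w
      }
    }
    # rejection sampling against the max density
    n_target <- round(A * (rho_dense * frac_dense * Lz +
                             rho_dilute * (1 - frac_dense) * Lz))
    zs <- numeric(0)
    while (length(zs) < n_target) {
      cand <- stats::runif(2 * n_target, 0, Lz)
      keep <- stats::runif(length(cand)) <
        vapply(cand, dens_z, numeric(1)) / rho_dense
      zs <- c(zs, cand[keep])
    }
    zs <- zs[seq_len(n_target)]
    coords <- cbind(stats::runif(n_target, 0, box[1]),
                    stats::runif(n_target, 0, box[2]), zs)
    chain <- if (chain_len > 0)
      rep(seq_len(ceiling(n_target / chain_len)), each = chain_len)[seq_len(n_target)]
    else rep(NA_integer_, n_target)
    snapshot(coords, rep(species, n_target), as.integer(chain), box)
  })
}

#' Synthetic coexistence dataset from known parameters
#'
#' Generates dilute/dense coexistence rows by solving the restricted binodal
#' with the given (true) interaction parameters, then applying multiplicative
#' lognormal noise. Round-trips through [write_coexistence()] /
#' [load_coexistence()].
#'
#' @param cs a `ChargeSequence` (its `name` is used as the sequence label).
#' @param params true `EnergyParams`.
#' @param T_grid temperatures (kelvin).
#' @param salt_M salt molarities (recycled against `T_grid` or crossed if
#'   `cross = TRUE`).
#' @param noise lognormal sigma (0 = noiseless).
#' @param seed RNG seed.
#' @param cross logical: full T x salt grid.
#' @param rp_range polymer-concentration window for the binodal solves.
#' @return a `CoexistenceDataset` data.frame.
#' @export
synthetic_coexistence <- function(cs, params, T_grid, salt_M = 0.1,
                                  noise = 0, seed = 1, cross = FALSE,
                                  rp_range = c(2e-6, 4e-3)) {
  conds <- if (cross) expand.grid(T_K = T_grid, salt = salt_M) else
    data.frame(T_K = T_grid, salt = rep(salt_M, length.out = length(T_grid)))
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    rho_s <- convert_conc(conds$salt[i], "M", "b-3")
    bp <- .binodal_point(cs, rho_s, conds$T_K[i], params, rp_range)
    if (is.null(bp)) next
    for (ph in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        sequence = cs$name, T_C = conds$T_K[i] - 273.15,
        salt_M = conds$salt[i],
        phase = c("dilute", "dense")[ph],
        conc = convert_conc(bp[ph], "b-3", "uM"), unit = "uM")
    }
  }
  if (!length(rows)) stop("no LLPS at any requested condition")
  df <- do.call(rbind, rows)
  if (noise > 0)
    df$conc <- .with_seed(seed, function()
      df$conc * exp(stats::rnorm(nrow(df), 0, noise)))
  df$T_K <- df$T_C + 273.15
  df$rho_p <- convert_conc(df$conc, "uM", "b-3")
  df$rho_s <- convert_conc(df$salt_M, "M", "b-3")
  class(df) <- c("CoexistenceDataset", "data.frame")
  df
}
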