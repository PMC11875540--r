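#' @title Counterion bridging analysis
#' @name bridging
#' @description
#' Analysis of counterion-mediated bridging in coarse-grained trajectory
#' snapshots: radial distribution of counterions around arginine charges,
#' enumeration of putative interchain Arg+ -- Cl- -- Arg+ three-bead
#' configurations within a cutoff (default 11 A, the first minimum of the
#' Arg-Cl radial distribution), energetic classification into true-bridging /
#' neutralizing / intermediate classes, per-ion statistics, projected
#' `P(x, d)` heat maps, and the isolated three-bead Boltzmann reference
#' system.
#'
#' Geometry of a configuration: `R` is the Arg-Arg distance, `d` the distance
#' of the Cl- from the line joining the two Arg+, `x` its projection along
#' that line measured from the first Arg, `d_near <= d_far` its distances to
#' the two Arg. With unit-magnitude charges the Coulomb-sum criterion for
#' true bridging (unfavorable Arg-Arg repulsion + favorable far-Arg--Cl
#' attraction summing below zero, i.e. `d_far < R`) evaluated over a whole
#' 2 A bin of `R` reduces to the geometric rule: true if `d_far` is below the
#' bin's lower edge, neutralizing if at or above the bin's upper edge,
#' intermediate otherwise.
NULL

#' Radial density of one species around another
#'
#' Shell-volume-normalized radial distribution `rho(r)` (number density of
#' `around` species at distance r from a `center` bead), averaged over frames
#' and centers with minimum-image distances.
#'
#' @param snapshots list of `Snapshot` objects (or one).
#' @param center species label (or `"R"` for arginine beads).
#' @param around species label (e.g. `"CL"`).
#' @param dr bin width (A).
#' @param rmax maximum distance (A).
#' @return data.frame with `r` (bin centers), `rho` (A^-3), `count`
#'   (pair count per bin, summed over frames).
#' @export
rdf <- function(snapshots, center, around, dr = 0.5, rmax = 30) {
  if (inherits(snapshots, "Snapshot")) snapshots <- list(snapshots)
  edges <- seq(0, rmax, by = dr)
  counts <- numeric(length(edges) - 1)
  n_centers <- 0L
  for (sn in snapshots) {
    ic <- which(sn$species == center)
    ia <- which(sn$species == around)
    if (!length(ic) || !length(ia))
      stop("species not present: ", if (!length(ic)) center else around)
    D <- .pdist_pbc(sn$coords[ic, , drop = FALSE],
                    sn$coords[ia, , drop = FALSE], sn$box)
    counts <- counts + as.numeric(table(cut(D[D > 0 & D <= rmax],
                                            edges, labels = FALSE)) |>
                                    (\(tb) {
                                      out <- numeric(length(edges) - 1)
                                      out[as.integer(names(tb))] <- tb
                                      out
                                    })())
    n_centers <- n_centers + length(ic)
  }
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
             rho = counts / (n_centers * shell),
             count = counts)
}

#' Fraction of counterions with a charged arginine within a cutoff
#'
#' The numerator counts (frame, ion) instances with at least one Arg within
#' `cutoff`; the denominator is `n_frames * n_ions`, following the
#' frames-times-ions convention.
#'
#' @param snapshots list of `Snapshot` objects (or one).
#' @param cutoff distance cutoff (A), default 11.
#' @param ion,arg species labels.
#' @return fraction in `[0, 1]`.
#' @export
fraction_within <- function(snapshots, cutoff = 11, ion = "CL", arg = "R") {
  stopifnot(cutoff > 0)
  if (inherits(snapshots, "Snapshot")) snapshots <- list(snapshots)
  num <- 0L; den <- 0L
  for (sn in snapshots) {
    ii <- which(sn$species == ion)
    ia <- which(sn$species == arg)
    den <- den + length(ii)
    if (!length(ii) || !length(ia)) next
    D <- .pdist_pbc(sn$coords[ii, , drop = FALSE],
                    sn$coords[ia, , drop = FALSE], sn$box)
    num <- num + sum(apply(D <= cutoff, 1, any))
  }
  if (den == 0L) stop("no ions of species ", ion)
  num / den
}

#' Enumerate putative bridging configurations in a snapshot
#'
#' A putative bridging configuration is one counterion whose distance to each
#' of two arginine beads on *different* chains is at most `cutoff`. For an
#' ion with in-range arginine counts `k_c` per chain `c` the number of
#' configurations is `sum_{c<c'} k_c k_c'` (unordered interchain pairs).
#'
#' @param snapshot a `Snapshot`.
#' @param cutoff distance cutoff (A).
#' @param ion,arg species labels.
#' @param include_lysine also treat lysine beads (`"K"`) as bridging centers
#'   (off by default; arginines dominate the positive charge of Caprin1).
#' @return data.frame of `BridgeConfiguration` rows: indices `arg_a`, `cl`,
#'   `arg_b`, distances `d_near`, `d_far`, `R`, geometry `x`, `d`.
#' @export
enumerate_putative_bridges <- function(snapshot, cutoff = 11, ion = "CL",
                                       arg = "R", include_lysine = FALSE) {
  sn <- snapshot
  lab_arg <- if (include_lysine) c(arg, "K") else arg
  ii <- which(sn$species == ion)
  ia <- which(sn$species %in% lab_arg & !is.na(sn$chain))
  if (!length(ii) || !length(ia))
    return(data.frame(arg_a = integer(0), cl = integer(0), arg_b = integer(0),
                      d_near = numeric(0), d_far = numeric(0), R = numeric(0),
                      x = numeric(0), d = numeric(0)))
  D <- .pdist_pbc(sn$coords[ii, , drop = FALSE],
                  sn$coords[ia, , drop = FALSE], sn$box)
  rows <- list()
  for (q in seq_along(ii)) {
    close_idx <- which(D[q, ] <= cutoff)
    if (length(close_idx) < 2) next
    glb <- ia[close_idx]
    chains <- sn$chain[glb]
    cmb <- utils::combn(seq_along(glb), 2)
    keep <- chains[cmb[1, ]] != chains[cmb[2, ]]
    if (!any(keep)) next
    cmb <- cmb[, keep, drop = FALSE]
    for (m in seq_len(ncol(cmb))) {
      a <- glb[cmb[1, m]]; b <- glb[cmb[2, m]]
      da <- D[q, close_idx[cmb[1, m]]]; db <- D[q, close_idx[cmb[2, m]]]
      # geometry from the three pairwise minimum-image distances (law of
      # cosines), so a wrapped image never yields an inconsistent triangle
      vab <- .min_image(sn$coords[b, ] - sn$coords[a, ], sn$box)
      Rab <- sqrt(sum(vab^2))
      xx <- (da^2 + Rab^2 - db^2) / (2 * Rab)
      dd <- sqrt(max(da^2 - xx^2, 0))
      rows[[length(rows) + 1]] <-
        c(arg_a = a, cl = ii[q], arg_b = b,
          d_near = min(da, db), d_far = max(da, db), R = Rab, x = xx, d = dd)
    }
  }
  if (!length(rows))
    return(data.frame(arg_a = integer(0), cl = integer(0), arg_b = integer(0),
                      d_near = numeric(0), d_far = numeric(0), R = numeric(0),
                      x = numeric(0), d = numeric(0)))
  as.data.frame(do.call(rbind, rows))
}

#' Classify bridging configurations
#'
#' Groups configurations by Arg-Arg distance `R` into bins of `bin_width`
#' and applies the Coulomb-sum criterion over the whole bin: with
#' unit-magnitude charges the summed potential `1/R - 1/d_far` is favorable
#' (< 0) for every `R` in the bin iff `d_far <` bin lower edge (true
#' bridging), unfavorable (>= 0) for every `R` iff `d_far >=` bin upper edge
#' (neutralizing), and mixed otherwise (intermediate).
#'
#' @param configs data.frame from [enumerate_putative_bridges()].
#' @param bin_width R-bin width (A), default 2.
#' @return `configs` with added `R_bin_lo`, `R_bin_hi`, `class` columns;
#'   attribute `"counts"` holds the per-class totals.
#' @export
classify_bridges <- function(configs, bin_width = 2) {
  if (!nrow(configs)) {
    configs$class <- character(0)
    attr(configs, "counts") <- c(true = 0, neutralizing = 0, intermediate = 0)
    return(configs)
  }
  lo <- floor(configs$R / bin_width) * bin_width
  hi <- lo + bin_width
  cls <- ifelse(configs$d_far < lo, "true",
                ifelse(configs$d_far >= hi, "neutralizing", "intermediate"))
  configs$R_bin_lo <- lo
  configs$R_bin_hi <- hi
  configs$class <- cls
  attr(configs, "counts") <- c(true = sum(cls == "true"),
                               neutralizing = sum(cls == "neutralizing"),
                               intermediate = sum(cls == "intermediate"))
  configs
}

#' Per-ion bridging statistics
#'
#' @param configs classified configurations, concatenated over frames with a
#'   `frame` column (added automatically when analyzing one frame).
#' @param n_frames number of frames analyzed.
#' @param n_ions number of counterions per frame.
#' @return list with `frac_bridging` (fraction of (frame, ion) instances in
#'   at least one configuration), `mean_configs_per_ion` (n-bar), `p_true`
#'   (fraction of configurations classified true), and `p_at_least_one`
#'   `= 1 - (1 - p_true)^floor(n_bar)` under the documented independence
#'   assumption. All fractions are `NA` when there are no bridging ions.
#' @export
per_ion_statistics <- function(configs, n_frames, n_ions) {
  if (!nrow(configs))
    return(list(frac_bridging = 0, mean_configs_per_ion = NA_real_,
                p_true = NA_real_, p_at_least_one = NA_real_))
  if (is.null(configs$frame)) configs$frame <- 1L
  inst <- unique(configs[, c("frame", "cl")])
  nbar <- nrow(configs) / nrow(inst)
  p_true <- mean(configs$class == "true")
  list(frac_bridging = nrow(inst) / (n_frames * n_ions),
       mean_configs_per_ion = nbar,
       p_true = p_true,
       p_at_least_one = 1 - (1 - p_true)^floor(nbar))
}

#' Projected heat map of counterion positions in bridging configurations
#'
#' Accumulates configurations at `(x, +d)` and `(x, -d)` with half weight
#' each, so `P(x, d) = P(x, -d)` exactly and the total mass equals the number
#' of configurations. Also returns `P(x, d)/|d|`, proportional to the average
#' density on the circle of radius `|d|`.
#'
#' @param configs data.frame with `x`, `d` columns.
#' @param cell cell size (A), default 0.5.
#' @param x_range,d_max grid extents (A); defaults cover the data.
#' @return a `HeatMap` list: `x` and `d` cell centers, matrices `P` and
#'   `P_over_d` (rows = x, cols = d).
#' @export
bridge_heatmap <- function(configs, cell = 0.5, x_range = NULL, d_max = NULL) {
  if (is.null(x_range))
    x_range <- if (nrow(configs)) range(configs$x) + c(-cell, cell) else c(-1, 1)
  if (is.null(d_max))
    d_max <- if (nrow(configs)) max(configs$d) + cell else 1
  xe <- seq(floor(x_range[1] / cell) * cell,
            ceiling(x_range[2] / cell) * cell, by = cell)
  de <- seq(-ceiling(d_max / cell) * cell, ceiling(d_max / cell) * cell,
            by = cell)
  P <- matrix(0, length(xe) - 1, length(de) - 1)
  if (nrow(configs)) {
    ix <- findInterval(configs$x, xe, rightmost.closed = TRUE)
    idp <- findInterval(configs$d, de, rightmost.closed = TRUE)
    idm <- findInterval(-configs$d, de, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nrow(P) & idp >= 1 & idp <= ncol(P)
    for (i in which(ok)) {
      P[ix[i], idp[i]] <- P[ix[i], idp[i]] + 0.5
      P[ix[i], idm[i]] <- P[ix[i], idm[i]] + 0.5
    }
  }
  dc <- (de[-1] + de[-length(de)]) / 2
  structure(list(x = (xe[-1] + xe[-length(xe)]) / 2, d = dc, P = P,
                 P_over_d = sweep(P, 2, pmax(abs(dc), cell / 4), "/")),
            class = "HeatMap")
}

#' Isolated three-bead Arg+ -- Cl- -- Arg+ Boltzmann reference
#'
#' Boltzmann-averaged spatial distribution of a single counterion around two
#' fixed arginine charges a distance `R` apart, using the same Coulomb +
#' short-range-repulsion potential as the coarse-grained MD model, integrated
#' on a cylindrical grid (the azimuthal degree of freedom contributes the
#' `2 pi |d|` circle measure, so the returned `P(x, d)` is comparable to
#' [bridge_heatmap()] output). Configurations with either Arg-Cl distance
#' beyond `cutoff` are excluded, mirroring the putative-bridging condition.
#'
#' @param R Arg-Arg distance (A).
#' @param lB Bjerrum length at the model temperature (A); the effective
#'   inverse temperature. `lB = 0` gives the flat (infinite-temperature)
#'   limit.
#' @param sigma contact diameter for the short-range repulsion (A).
#' @param cutoff maximum Arg-Cl distance (A).
#' @param cell grid cell (A).
#' @param pad grid padding beyond the inter-arg axis (A).
#' @return a `HeatMap` (normalized to unit mass) with the same layout as
#'   [bridge_heatmap()].
#' @export
isolated_three_bead <- function(R, lB = 7.12, sigma = 5.5, cutoff = 11,
                                cell = 0.5, pad = 4) {
  stopifnot(R > 0)
  xe <- seq(-pad, R + pad, by = cell)
  de <- seq(-cutoff - pad, cutoff + pad, by = cell)
  xc <- (xe[-1] + xe[-length(xe)]) / 2
  dc <- (de[-1] + de[-length(de)]) / 2
  X <- matrix(xc, length(xc), length(dc))
  D <- matrix(dc, length(xc), length(dc), byrow = TRUE)
  r1 <- sqrt(X^2 + D^2)
  r2 <- sqrt((X - R)^2 + D^2)
  # unit charges: Cl- attracted to both Arg+; Arg-Arg term is constant in the
  # ion position and drops out of the normalized distribution
  U <- -lB / pmax(r1, 0.1) - lB / pmax(r2, 0.1) +
    lB * ((sigma / pmax(r1, 0.1))^12 + (sigma / pmax(r2, 0.1))^12) / sigma
  W <- exp(-(U - min(U))) * 2 * pi * abs(D)
  W[r1 > cutoff | r2 > cutoff] <- 0
  if (sum(W) > 0) W <- W / sum(W)
  structure(list(x = xc, d = dc, P = W,
                 P_over_d = sweep(W, 2, pmax(abs(dc), cell / 4), "/")),
            class = "HeatMap")
}
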