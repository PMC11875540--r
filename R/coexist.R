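#' @title Phase coexistence: binodals, critical points, tielines
#' @name coexist
#' @description
#' Solvers for liquid-liquid coexistence built on the rG-RPA+FH free energy.
#' Two modes mirror the two ways salt can be treated:
#'
#' * *restricted*: the salt-ion concentration is spatially uniform; the
#'   counterions are slaved to the polymer through local electroneutrality and
#'   coexistence reduces to a common-tangent construction on `f(rho_p)` at
#'   fixed temperature and salt.
#' * *unrestricted*: salt partitions between the phases. Equilibria are
#'   formulated in the two electroneutral components (polymer + `|Q|/zc`
#'   counterions; salt ion + `zs/zc` counterions), which fixes the Donnan
#'   (Galvani) indeterminacy and conditions the Newton solve well. Tielines
#'   in the `(rho_p, rho_s)` plane connect coexisting compositions.
NULL

# restricted free energy: counterions slaved to polymer + salt by neutrality
.f_r <- function(cs, rho_p, rho_s, T_K, params) {
  rho_c <- (abs(cs$Q) * rho_p + params$zs * rho_s) / params$zc
  .f_total(cs, rho_p, rho_c, rho_s, T_K, params)
}

# restricted-path chemical potential muA = mu_p + (|Q|/zc) mu_c and free
# energy from the analytic derivative engine; curvature by log-space FD of muA
.f_r_derivs <- function(cs, rho_p, rho_s, T_K, params, h = 2e-3,
                        curvature = TRUE) {
  QQ <- abs(cs$Q) / params$zc
  muA_f <- function(rp) {
    rc <- (abs(cs$Q) * rp + params$zs * rho_s) / params$zc
    m <- .mu_all(cs, rp, rc, rho_s, T_K, params)
    c(m$mu_p + if (QQ > 0) QQ * m$mu_c else 0, m$f)
  }
  m0 <- muA_f(rho_p)
  if (!curvature) return(list(f = m0[2], f1 = m0[1], f2 = NA_real_))
  mp <- muA_f(rho_p * exp(h))[1]
  mm <- muA_f(rho_p * exp(-h))[1]
  list(f = m0[2], f1 = m0[1],
       f2 = (mp - mm) / (2 * h * rho_p))
}

# scan a log grid for the instability (spinodal) interval; NULL if stable
.spinodal_scan <- function(cs, rho_s, T_K, params,
                           rp_range = c(2e-6, 4e-3), n = 40) {
  grid <- exp(seq(log(rp_range[1]), log(rp_range[2]), length.out = n))
  curv <- vapply(grid, function(r)
    tryCatch(.f_r_derivs(cs, r, rho_s, T_K, params)$f2,
             error = function(e) Inf),  # outside model domain: treat stable
    numeric(1))
  neg <- which(curv < 0)
  if (!length(neg)) return(NULL)
  list(lo = grid[max(1, min(neg) - 1)], hi = grid[min(n, max(neg) + 1)],
       grid = grid, curv = curv)
}

#' Common-tangent construction on a free-energy curve (convex-hull oracle)
#'
#' Locates the double-tangent (coexistence) segment of a sampled free-energy
#' curve `f(rho)` by constructing the lower convex hull of the sampled points
#' and finding the hull edge that skips sampled points. This is the geometric
#' definition of coexistence and serves as an independent check (and Newton
#' seed) for the binodal solvers.
#'
#' @param rho increasing concentration grid.
#' @param fvals free-energy density at `rho`.
#' @return `NULL` if the curve is convex on the grid, else a list with the
#'   grid points `rho_lo`, `rho_hi` spanning the non-convex region.
#' @export
hull_tangent <- function(rho, fvals) {
  stopifnot(length(rho) == length(fvals), !is.unsorted(rho))
  n <- length(rho)
  # lower convex hull by monotone chain
  hull <- integer(0)
  cross <- function(i, j, k)
    (rho[j] - rho[i]) * (fvals[k] - fvals[i]) -
    (fvals[j] - fvals[i]) * (rho[k] - rho[i])
  for (k in seq_len(n)) {
    while (length(hull) >= 2 &&
           cross(hull[length(hull) - 1], hull[length(hull)], k) <= 0)
      hull <- hull[-length(hull)]
    hull <- c(hull, k)
  }
  gaps <- diff(hull)
  if (all(gaps == 1)) return(NULL)
  j <- which.max(gaps)
  list(rho_lo = rho[hull[j]], rho_hi = rho[hull[j + 1]],
       i_lo = hull[j], i_hi = hull[j + 1])
}

# Newton refinement of the restricted common tangent; returns c(ra, rb) or NULL
.tangent_newton <- function(cs, rho_s, T_K, params, seed, tol = 1e-10,
                            maxit = 60) {
  resid <- function(u) {
    ra <- exp(u[1]); rb <- exp(u[2])
    d2 <- tryCatch(list(.f_r_derivs(cs, ra, rho_s, T_K, params,
                                    curvature = FALSE),
                        .f_r_derivs(cs, rb, rho_s, T_K, params,
                                    curvature = FALSE)),
                   error = function(e) NULL)  # outside model domain
    if (is.null(d2)) return(c(1e6, 1e6))
    da <- d2[[1]]; db <- d2[[2]]
    c(da$f1 - db$f1,
      (da$f - ra * da$f1) - (db$f - rb * db$f1))
  }
  u <- log(seed)
  best_u <- u; best_r <- Inf
  for (it in seq_len(maxit)) {
    r0 <- resid(u)
    if (max(abs(r0)) < best_r) { best_r <- max(abs(r0)); best_u <- u }
    if (all(abs(r0) < tol)) break
    J <- matrix(0, 2, 2)
    hj <- 1e-5
    for (j in 1:2) {
      up <- u; up[j] <- up[j] + hj
      J[, j] <- (resid(up) - r0) / hj
    }
    step <- tryCatch(solve(J, r0), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1; moved <- FALSE
    repeat {
      un <- u - lam * step
      if (un[1] < un[2] && all(is.finite(un)) &&
          sum(abs(resid(un))) < sum(abs(r0)) + 1e-15) {
        u <- un; moved <- TRUE; break
      }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (!moved) break  # stalled at the residual noise floor
  }
  if (best_u[2] - best_u[1] < 0.02) return(NULL)  # collapsed (trivial root)
  if (best_r < 1e-8) exp(best_u) else NULL
}

# restricted coexistence at one (T, rho_s); NULL if none found. quick = TRUE
# (used inside fitting loops) skips the spinodal scan and coarsens the hull.
.binodal_point <- function(cs, rho_s, T_K, params, rp_range = c(2e-6, 4e-3),
                           quick = FALSE) {
  if (!quick) {
    sp <- .spinodal_scan(cs, rho_s, T_K, params, rp_range)
    if (is.null(sp)) return(NULL)
  }
  grid <- exp(seq(log(rp_range[1] / 4), log(rp_range[2] * 1.5),
                  length.out = if (quick) 60 else 120))
  fv <- vapply(grid, function(r)
    tryCatch(.f_r(cs, r, rho_s, T_K, params), error = function(e) NA_real_),
    numeric(1))
  keep <- is.finite(fv)
  ht <- hull_tangent(grid[keep], fv[keep])
  if (is.null(ht) && quick) return(NULL)
  seed <- if (is.null(ht)) c(sp$lo / 3, sp$hi * 3) else c(ht$rho_lo, ht$rho_hi)
  .tangent_newton(cs, rho_s, T_K, params, seed)
}

#' Fixed-salt temperature-concentration binodal (restricted mode)
#'
#' For each temperature below the UCST, solves the dilute/dense polymer
#' concentrations that share the same polymer chemical potential and osmotic
#' pressure at spatially uniform salt, with counterions slaved by local
#' electroneutrality. Grid points where the solver fails to converge are
#' dropped with a warning (never interpolated).
#'
#' @param cs a `ChargeSequence`.
#' @param params an `EnergyParams`.
#' @param salt salt-ion concentration (uniform across phases).
#' @param T_grid sorted vector of temperatures (kelvin).
#' @param salt_unit `"b-3"` (default) or `"M"`.
#' @param rp_range polymer-concentration search window (b^-3).
#' @return data.frame with columns `T_K`, `rho_dil`, `rho_den` (chains b^-3),
#'   `rho_c_dil`, `rho_c_den`, `rho_s`; zero rows above the UCST.
#' @export
binodal_fixed_salt <- function(cs, params = energy_params(), salt, T_grid,
                               salt_unit = c("b-3", "M"),
                               rp_range = c(2e-6, 4e-3)) {
  salt_unit <- match.arg(salt_unit)
  rho_s <- if (salt_unit == "M") convert_conc(salt, "M", "b-3") else salt
  stopifnot(!is.unsorted(T_grid))
  rows <- lapply(T_grid, function(T_K) {
    pt <- .binodal_point(cs, rho_s, T_K, params, rp_range)
    if (is.null(pt)) return(NULL)
    data.frame(T_K = T_K, rho_dil = pt[1], rho_den = pt[2],
               rho_c_dil = neutralize(cs$Q, pt[1], params$zs, params$zc, rho_s),
               rho_c_den = neutralize(cs$Q, pt[2], params$zs, params$zc, rho_s),
               rho_s = rho_s)
  })
  n_fail <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(T_K = numeric(0), rho_dil = numeric(0),
                      rho_den = numeric(0), rho_c_dil = numeric(0),
                      rho_c_den = numeric(0), rho_s = numeric(0))
  attr(out, "n_no_coexistence") <- n_fail
  out
}

#' Upper critical solution temperature
#'
#' Bisection on the existence of a restricted-mode instability in temperature;
#' in this mean-field theory the maximum temperature of the binodal coincides
#' with the disappearance of the spinodal. Returns `NA` when no LLPS exists
#' anywhere in the search window.
#'
#' @inheritParams binodal_fixed_salt
#' @param T_window search window in kelvin.
#' @param tol_Tstar bisection tolerance in reduced-temperature units.
#' @return critical temperature in kelvin, or `NA` (absent).
#' @export
ucst <- function(cs, params = energy_params(), salt,
                 salt_unit = c("b-3", "M"), T_window = c(120, 900),
                 tol_Tstar = 1e-3, rp_range = c(2e-6, 4e-3)) {
  salt_unit <- match.arg(salt_unit)
  rho_s <- if (salt_unit == "M") convert_conc(salt, "M", "b-3") else salt
  unstable <- function(T_K)
    !is.null(.spinodal_scan(cs, rho_s, T_K, params, rp_range))
  lo <- T_window[1]; hi <- T_window[2]
  if (!unstable(lo)) return(NA_real_)
  if (unstable(hi)) return(hi)  # window exhausted at the top
  # kelvin tolerance equivalent to tol_Tstar in T* = l/lB units
  tol_K <- tol_Tstar * lo / reduced_temperature(lo, params)
  while (hi - lo > tol_K) {
    mid <- (lo + hi) / 2
    if (unstable(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# -- unrestricted (Donnan) equilibria ---------------------------------------

# neutral-component chemical potentials and osmotic pressure at (rho_p, rho_s):
# muA = mu_p + (|Q|/zc) mu_c (polymer + its counterions), muB = mu_s +
# (zs/zc) mu_c (salt "molecule"); Pi from the full Euler relation
.mu_pi_2d <- function(cs, rho_p, rho_s, T_K, params) {
  rho_c <- (abs(cs$Q) * rho_p + params$zs * rho_s) / params$zc
  m <- .mu_all(cs, rho_p, rho_c, rho_s, T_K, params)
  QQ <- abs(cs$Q) / params$zc
  c(muA = m$mu_p + if (QQ > 0) QQ * m$mu_c else 0,
    muB = m$mu_s + if (rho_c > 0 || params$zs > 0) {
      if (is.finite(m$mu_c)) params$zs / params$zc * m$mu_c else 0
    } else 0,
    Pi = m$Pi)
}

# two-phase split of overall composition (rp0, rs0); returns list or NULL
.tieline_solve <- function(cs, rp0, rs0, T_K, params, seed = NULL,
                           tol = 1e-9, maxit = 80,
                           rp_range = c(2e-6, 4e-3)) {
  resid <- function(y) {
    # y = (log rp_dil, rs_dil, log rp_den, rs_den, nu)
    rpd <- exp(y[1]); rsd <- y[2]; rpc <- exp(y[3]); rsc <- y[4]; nu <- y[5]
    if (rsd < 0 || rsc < 0 || nu <= 0 || nu >= 1) return(rep(1e6, 5))
    ab <- tryCatch(list(.mu_pi_2d(cs, rpd, rsd, T_K, params),
                        .mu_pi_2d(cs, rpc, rsc, T_K, params)),
                   error = function(e) NULL)  # e.g. phi >= 1 trial state
    if (is.null(ab)) return(rep(1e6, 5))
    a <- ab[[1]]; b <- ab[[2]]
    c(a[1] - b[1], a[2] - b[2], a[3] - b[3],
      (nu * rpc + (1 - nu) * rpd - rp0) / max(rp0, 1e-12),
      (nu * rsc + (1 - nu) * rsd - rs0) / max(rs0, rp0, 1e-12))
  }
  if (is.null(seed)) {
    # continuation in overall salt: start from a low-salt anchor where the
    # restricted (uniform-salt) solution seeds the Donnan solve well, then
    # walk the anchor up to rs0 re-seeding from the previous solution
    ladder <- rs0 * c(0.1, 0.25, 0.5, 0.75, 1)
    bp <- .binodal_point(cs, ladder[1], T_K, params, rp_range)
    if (is.null(bp)) bp <- .binodal_point(cs, rs0, T_K, params, rp_range)
    if (is.null(bp)) return(NULL)
    nu0 <- min(max((rp0 - bp[1]) / (bp[2] - bp[1]), 0.02), 0.98)
    seed <- c(log(bp[1]), ladder[1], log(bp[2]), ladder[1], nu0)
    for (rs_i in ladder[-length(ladder)]) {
      sol_i <- .tieline_solve(cs, rp0, rs_i, T_K, params, seed = seed,
                              tol = 1e-7, maxit = maxit,
                              rp_range = rp_range)
      if (!is.null(sol_i)) {
        seed <- c(log(sol_i$dilute[["rho_p"]]), sol_i$dilute[["rho_s"]],
                  log(sol_i$dense[["rho_p"]]), sol_i$dense[["rho_s"]],
                  sol_i$nu_dense)
        # rescale salt entries toward the next anchor
        j <- which(ladder == rs_i)
        fac <- ladder[j + 1] / rs_i
        seed[c(2, 4)] <- seed[c(2, 4)] * fac
      }
    }
  }
  y <- seed
  for (it in seq_len(maxit)) {
    r0 <- resid(y)
    if (all(abs(r0) < tol)) break
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      hj <- if (j %in% c(2, 4)) 1e-6 * max(abs(y[j]), 1e-4) else 1e-5
      yp <- y; yp[j] <- yp[j] + hj
      J[, j] <- (resid(yp) - r0) / hj
    }
    step <- tryCatch(solve(J, r0), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      yn <- y - lam * step
      rn <- resid(yn)
      if (all(is.finite(rn)) && sum(abs(rn)) < sum(abs(r0)) + 1e-13) {
        y <- yn; break
      }
      lam <- lam / 2
      if (lam < 1e-5) return(NULL)
    }
  }
  if (!all(abs(resid(y)) < 1e-6)) return(NULL)
  list(dilute = c(rho_p = exp(y[1]), rho_s = y[2],
                  rho_c = neutralize(cs$Q, exp(y[1]), params$zs, params$zc, y[2])),
       dense = c(rho_p = exp(y[3]), rho_s = y[4],
                 rho_c = neutralize(cs$Q, exp(y[3]), params$zs, params$zc, y[4])),
       nu_dense = y[5],
       slope = (y[4] - y[2]) / (exp(y[3]) - exp(y[1])))
}

#' Two-dimensional salt-polymer phase diagram with tielines
#'
#' Unrestricted rG-RPA+FH equilibria at fixed temperature: for a set of
#' overall compositions (anchors), solves the two-phase split in which all
#' species' chemical potentials and the osmotic pressure match between the
#' phases, each phase is separately electroneutral (Donnan construction), and
#' the lever rule recovers the overall composition. For counterion valency
#' `zc > 1` the minimum-counterion feasibility line `rho_c = |Q| rho_p / zc`
#' (at `rho_s = 0`) bounds the physical region from below.
#'
#' @param cs a `ChargeSequence`.
#' @param params an `EnergyParams`.
#' @param T_K temperature (kelvin), 300 by default.
#' @param salt_anchors overall salt-ion concentrations at which tielines are
#'   computed (b^-3 or M per `salt_unit`); defaults to a log grid.
#' @param rho_p_anchor overall polymer concentration; defaults to the
#'   geometric mean of the restricted dilute/dense solutions per anchor.
#' @param salt_unit `"b-3"` or `"M"`.
#' @return a `PhaseDiagram` list: `mode`, `T_K`, `tielines` (data.frame with
#'   per-phase compositions and slopes), `boundary` (tieline endpoints ordered
#'   by salt), and `params`.
#' @export
salt_polymer_diagram <- function(cs, params = energy_params(), T_K = 300,
                                 salt_anchors = NULL, rho_p_anchor = NULL,
                                 salt_unit = c("b-3", "M")) {
  salt_unit <- match.arg(salt_unit)
  if (is.null(salt_anchors)) {
    salt_anchors <- exp(seq(log(3e-4), log(0.25), length.out = 10))
  } else if (salt_unit == "M") {
    salt_anchors <- convert_conc(salt_anchors, "M", "b-3")
  }
  rows <- list()
  for (rs0 in salt_anchors) {
    bp <- .binodal_point(cs, rs0, T_K, params)
    if (is.null(bp)) next
    rp0 <- if (is.null(rho_p_anchor)) sqrt(bp[1] * bp[2]) else rho_p_anchor
    tl <- .tieline_solve(cs, rp0, rs0, T_K, params)
    if (is.null(tl)) next
    rows[[length(rows) + 1]] <-
      data.frame(rs_anchor = rs0, rp_anchor = rp0,
                 rp_dil = tl$dilute[["rho_p"]], rs_dil = tl$dilute[["rho_s"]],
                 rc_dil = tl$dilute[["rho_c"]],
                 rp_den = tl$dense[["rho_p"]], rs_den = tl$dense[["rho_s"]],
                 rc_den = tl$dense[["rho_c"]],
                 nu_dense = tl$nu_dense, slope = tl$slope)
  }
  tielines <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rs_anchor = numeric(0))
  boundary <- if (nrow(tielines)) {
    rbind(data.frame(rho_p = tielines$rp_dil, rho_s = tielines$rs_dil,
                     branch = "dilute"),
          data.frame(rho_p = tielines$rp_den, rho_s = tielines$rs_den,
                     branch = "dense"))
  } else data.frame(rho_p = numeric(0), rho_s = numeric(0),
                    branch = character(0))
  structure(list(mode = "unrestricted", T_K = T_K, tielines = tielines,
                 boundary = boundary,
                 feasibility_slope = abs(cs$Q) / params$zc,
                 params = params),
            class = "PhaseDiagram")
}

#' Tieline slope through an anchor composition
#'
#' Solves the two-phase split for the given overall composition and returns
#' the slope of the tieline in the `(rho_p, rho_s)` plane. Negative slope
#' means the salt ion is partially excluded from the polymer-dense phase;
#' positive slope means it is enriched there.
#'
#' @param cs a `ChargeSequence`.
#' @param params an `EnergyParams`.
#' @param rho_p_anchor,rho_s_anchor overall composition (b^-3); must lie
#'   inside the coexistence region.
#' @param T_K temperature (kelvin).
#' @param rp_range polymer-concentration window used to seed the solve.
#' @return list with `slope`, `dilute`, `dense`, `nu_dense`.
#' @export
tieline_slope <- function(cs, params = energy_params(), rho_p_anchor,
                          rho_s_anchor, T_K = 300,
                          rp_range = c(2e-6, 4e-3)) {
  tl <- .tieline_solve(cs, rho_p_anchor, rho_s_anchor, T_K, params,
                       rp_range = rp_range)
  if (is.null(tl)) stop("anchor composition is outside the coexistence region ",
                        "or the tieline solve failed")
  tl
}
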