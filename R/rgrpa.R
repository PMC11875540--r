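#' @title rG-RPA+FH free energy of a charged-heteropolymer solution
#' @name rgrpa
#' @description
#' Free-energy engine for a solution of one charged heteropolymer species plus
#' counterions and salt. The model combines (i) exact ideal mixing entropy of
#' chains, ions and implicit solvent, (ii) a Flory-Huggins mean-field term with
#' `chi(T) = eps_h/T* + eps_s` (reduced temperature `T* = l/lB(T)`), (iii) a
#' bare two-body excluded-volume term `v2` acting on polymer beads, (iv) a
#' variational single-chain term in which the Kuhn length is renormalized
#' (`l -> x l`) in response to screened intrachain Coulomb repulsion and
#' excluded volume (the "rG" part), and (v) a random-phase-approximation
#' charge-correlation integral over wavenumber evaluated with the renormalized
#' chain structure factor and with ion/polymer self-energies subtracted, so
#' that `f_el <= 0` always and the Debye-Hueckel limiting law `-kappa^3/12pi`
#' is recovered for dilute pure salt.
#'
#' Internal units: energies in kBT, lengths in the Kuhn length b (= 3.8 A),
#' concentrations as number densities in b^-3.
NULL

#' Interaction parameters for the rG-RPA+FH model
#'
#' @param epsilon_r relative permittivity (dimensionless). The fitted value
#'   for the Caprin1 systems is 80.5, close to bulk water.
#' @param eps_h,eps_s enthalpic and entropic parts of the Flory-Huggins
#'   parameter `chi(T) = eps_h/T* + eps_s`.
#' @param v2 two-body excluded-volume parameter for polymer beads, in b^3.
#' @param zs,zc salt-ion and counterion valencies (positive integers).
#' @param l_A Kuhn length in Angstrom (peptide virtual bond, 3.8 A).
#' @param ion_volume volume of one ion in units of b^3 entering the
#'   free-volume (solvent-entropy) term; 1 treats ions like residue beads,
#'   0 is the point-ion limit in which neutral ions decouple exactly.
#' @return an `EnergyParams` list.
#' @export
energy_params <- function(epsilon_r = 80.5, eps_h = 1.0, eps_s = 0.0,
                          v2 = 4 * pi / 3, zs = 1, zc = 1, l_A = 3.8,
                          ion_volume = 1) {
  stopifnot(epsilon_r > 0, l_A > 0, zs >= 1, zc >= 1, ion_volume >= 0)
  structure(list(epsilon_r = epsilon_r, eps_h = eps_h, eps_s = eps_s,
                 v2 = v2, zs = zs, zc = zc, l_A = l_A,
                 ion_volume = ion_volume),
            class = "EnergyParams")
}

#' Bjerrum length
#'
#' Distance at which the Coulomb energy between two unit charges equals kBT:
#' `lB = e^2 / (4 pi eps0 epsilon_r kB T)`.
#'
#' @param T_K absolute temperature in kelvin.
#' @param epsilon_r relative permittivity.
#' @return Bjerrum length in Angstrom.
#' @examples
#' bjerrum_length(300, 80.5)  # ~6.92 A
#' @export
bjerrum_length <- function(T_K, epsilon_r) {
  stopifnot(all(T_K > 0), all(epsilon_r > 0))
  with(.const, e^2 / (4 * pi * eps0 * epsilon_r * kB * T_K)) * 1e10
}

#' Reduced temperature
#'
#' Convention adopted throughout: `T* = l / lB(T)`, the ratio of the Kuhn
#' length to the Bjerrum length. `T*` is proportional to `T` at fixed
#' permittivity, and with this convention `chi = eps_h lB/l + eps_s`
#' reproduces the standard per-contact energetic equivalences (see
#' [contact_energetics()]).
#'
#' @param T_K temperature in kelvin.
#' @param params an `EnergyParams`.
#' @return dimensionless reduced temperature.
#' @export
reduced_temperature <- function(T_K, params = energy_params()) {
  params$l_A / bjerrum_length(T_K, params$epsilon_r)
}

#' Flory-Huggins parameter
#'
#' `chi(T) = eps_h/T* + eps_s`, with `T*` from [reduced_temperature()].
#' Positive `chi` denotes a favorable residue-residue contact.
#'
#' @param T_K temperature in kelvin.
#' @param eps_h,eps_s enthalpic/entropic components.
#' @param params an `EnergyParams` (supplies the permittivity for `T*`);
#'   `eps_h`/`eps_s` default to the values stored there.
#' @return dimensionless chi.
#' @export
chi_fh <- function(T_K, eps_h = params$eps_h, eps_s = params$eps_s,
                   params = energy_params()) {
  eps_h / reduced_temperature(T_K, params) + eps_s
}

#' Per-contact energetics implied by (eps_h, eps_s)
#'
#' Under the `T* = l/lB` convention, the enthalpic part of chi corresponds to
#' a per-contact enthalpy `dH = -eps_h kB T / T*(T)` (molar) and the entropic
#' part to `dS = eps_s R`. Negative values denote a favorable contact.
#'
#' @param eps_h,eps_s Flory-Huggins components.
#' @param T_ref reference temperature in kelvin (~300 K, the experimental range).
#' @param params an `EnergyParams` (for permittivity and Kuhn length).
#' @return list with `dH_kcal_mol` and `dS_cal_mol_K`.
#' @examples
#' contact_energetics(eps_h = 1.0, eps_s = -1.5)  # ~ -1.1 kcal/mol, -3.0 cal/mol/K
#' @export
contact_energetics <- function(eps_h, eps_s, T_ref = 300,
                               params = energy_params()) {
  Tstar <- reduced_temperature(T_ref, params)
  dH <- -eps_h / Tstar * .const$R_cal * T_ref / 1000  # kcal/mol
  dS <- eps_s * .const$R_cal                          # cal/mol/K
  list(dH_kcal_mol = dH, dS_cal_mol_K = dS)
}

#' Solution state (concentrations + temperature)
#'
#' Builds an electroneutral `SolutionState`. The counterion concentration is
#' slaved to the polymer and salt concentrations through the neutrality
#' relation `|Q| rho_p + zs rho_s = zc rho_c` unless given explicitly.
#'
#' @param cs a `ChargeSequence` (supplies the polymer net charge Q).
#' @param rho_p polymer chain concentration (b^-3).
#' @param rho_s salt-ion concentration (b^-3).
#' @param T_K temperature in kelvin.
#' @param params an `EnergyParams` (supplies zs, zc).
#' @param rho_c counterion concentration; computed by [neutralize()] if `NULL`.
#' @return a `SolutionState` list.
#' @export
solution_state <- function(cs, rho_p, rho_s, T_K, params = energy_params(),
                           rho_c = NULL) {
  if (is.null(rho_c))
    rho_c <- neutralize(cs$Q, rho_p, params$zs, params$zc, rho_s)
  stopifnot(rho_p >= 0, rho_s >= 0, rho_c >= 0, T_K > 0)
  structure(list(rho_p = rho_p, rho_c = rho_c, rho_s = rho_s, T_K = T_K),
            class = "SolutionState")
}

# -- sequence-pattern caches ------------------------------------------------

# c_d = sum_{|i-j|=d} sigma_i sigma_j (both orders for d>=1; c_0 = sum sigma^2)
# n_d = number of ordered pairs at separation d (for v2 intrachain term)
.charge_pattern <- function(cs) {
  # fast path: solvers hammer a single sequence, so compare against the last
  # pattern before building a string key
  if (!is.null(.pkg_cache$last_sigma) &&
      identical(cs$sigma, .pkg_cache$last_sigma))
    return(.pkg_cache$last_pat)
  key <- paste0(".cp_", paste(cs$sigma, collapse = ","))
  cached <- .pkg_cache[[key]]
  if (!is.null(cached)) {
    .pkg_cache$last_sigma <- cs$sigma
    .pkg_cache$last_pat <- cached
    return(cached)
  }
  sig <- cs$sigma
  N <- length(sig)
  cd <- vapply(0:(N - 1), function(d) {
    if (d == 0) sum(sig^2) else 2 * sum(sig[1:(N - d)] * sig[(1 + d):N])
  }, numeric(1))
  nd <- if (N > 1) c(N, 2 * (N - seq_len(N - 1))) else N
  out <- list(N = N, d = 0:(N - 1), cd = cd, nd = nd)
  .pkg_cache[[key]] <- out
  .pkg_cache$last_sigma <- cs$sigma
  .pkg_cache$last_pat <- out
  out
}

.pkg_cache <- new.env(parent = emptyenv())

# scaled complementary error function e^{u^2} erfc(u) for u >= 0,
# overflow-safe and branch-free (a piecewise implementation has a tiny jump
# at the switch point that finite differences of F1 amplify badly)
.erfcx <- function(u) {
  exp(u^2 + log(2) + stats::pnorm(u * sqrt(2), lower.tail = FALSE,
                                  log.p = TRUE))
}

# Gaussian-averaged screened Coulomb <exp(-kappa r)/r> for separation variance
# <r^2> = 3 s^2 (lengths in b)
.yukawa_gauss <- function(s, kappa) {
  sqrt(2 / pi) / s - kappa * .erfcx(kappa * s / sqrt(2))
}

# single-chain variational free energy F1(x) (units kBT per chain), given
# Debye kappa (from small ions), Bjerrum length lB (b units), v2 (b^3)
.F1 <- function(x, pat, kappa, lB, v2) {
  N <- pat$N
  d <- pat$d[-1]                      # d = 1 .. N-1
  elastic <- 1.5 * (N - 1) * (x - 1 - log(x))
  s <- sqrt(d * x / 3)
  e_el <- if (lB > 0) 0.5 * lB * sum(pat$cd[-1] * .yukawa_gauss(s, kappa)) else 0
  e_v2 <- if (v2 != 0) 0.5 * v2 * sum(pat$nd[-1] * (3 / (2 * pi * d * x))^1.5) else 0
  elastic + e_el + e_v2
}

#' Renormalized Kuhn-length factor
#'
#' Variationally determines the factor `x` such that a Gaussian reference
#' chain with Kuhn length `x l` best represents the chain in the given ionic
#' environment: `x` minimizes the Gibbs-Bogoliubov single-chain free energy
#' consisting of the elastic deformation cost `(3/2)(N-1)(x - 1 - ln x)`, the
#' Gaussian-averaged screened intrachain Coulomb energy (Debye screening from
#' the small ions), and the intrachain excluded-volume energy. `x = 1` is the
#' ideal-chain limit (recovered exactly when `lB -> 0` and `v2 = 0`); swollen
#' polyelectrolytes have `x > 1`.
#'
#' @param cs a `ChargeSequence`.
#' @param state a `SolutionState`.
#' @param params an `EnergyParams`.
#' @param full logical; if `TRUE` return diagnostics (minimum value, kappa).
#' @return the factor `x > 0` (or a list when `full = TRUE`).
#' @export
renormalized_kuhn <- function(cs, state, params = energy_params(),
                              full = FALSE) {
  lB <- bjerrum_length(state$T_K, params$epsilon_r) / params$l_A
  kappa <- sqrt(max(4 * pi * lB *
                      (params$zc^2 * state$rho_c + params$zs^2 * state$rho_s),
                    0))
  pat <- .charge_pattern(cs)
  if ((lB == 0 || all(pat$cd == 0)) && params$v2 == 0) {
    x <- 1
    if (!full) return(x)
    return(list(x = 1, F1 = 0, kappa = kappa, lB = lB))
  }
  polish <- function(x) {
    # Newton on dF1/dx = 0, to machine precision (removes optimizer jitter)
    for (i in 1:14) {
      hx <- 1e-5 * x
      fp <- .F1(x + hx, pat, kappa, lB, params$v2)
      fm <- .F1(x - hx, pat, kappa, lB, params$v2)
      f0 <- .F1(x, pat, kappa, lB, params$v2)
      g1 <- (fp - fm) / (2 * hx); g2 <- (fp - 2 * f0 + fm) / hx^2
      if (!is.finite(g1) || !is.finite(g2) || g2 <= 0) return(NA_real_)
      dx <- g1 / g2
      if (abs(dx) > 0.2 * x) dx <- sign(dx) * 0.2 * x
      x <- x - dx
      if (abs(dx) < 1e-13 * x) return(x)
    }
    NA_real_
  }
  # Brent bracket then Newton polish; x is a pure function of the state
  # (no warm starts: stale seeds can polish into a secondary minimum and
  # make downstream curvatures history-dependent)
  obj <- function(lx) .F1(exp(lx), pat, kappa, lB, params$v2)
  opt <- stats::optimize(obj, interval = c(log(0.05), log(400)), tol = 1e-6)
  x <- polish(exp(opt$minimum))
  if (!is.finite(x)) x <- exp(opt$minimum)
  if (!full) return(x)
  list(x = x, F1 = .F1(x, pat, kappa, lB, params$v2), kappa = kappa, lB = lB)
}

# renormalized single-chain charge structure factor S(k; x), vectorized in k
# S(k) = sum_d c_d exp(-k^2 x d / 6), computed by cumulative products so a
# single exp() vector serves all separations d
.Sk <- function(k, pat, x) {
  e1 <- exp(-k^2 * x / 6)
  S <- rep(pat$cd[1], length(k))
  acc <- rep(1, length(k))
  cd <- pat$cd
  for (d in seq_len(pat$N - 1)) {
    acc <- acc * e1
    if (cd[d + 1] != 0) S <- S + cd[d + 1] * acc
  }
  S
}

# fixed universal wavenumber grid (b^-1 units, log spaced) used for all RPA
# integrals: state-independent so the free energy is a smooth deterministic
# function of composition; the truncated tail is added analytically
.kgrid <- local({
  kg <- exp(seq(log(1e-7), log(2000), 0.015))
  list(k = kg, k2 = kg^2, dk = diff(kg), K = kg[length(kg)])
})

# RPA electrostatic free-energy density (kBT / b^3), self-energy subtracted:
# f_el = (1/4pi^2) Int dk k^2 [ln(1+G) - G],  G = (4 pi lB / k^2) * terms(k)
.f_el_rpa <- function(terms_vec, t_inf, lB) {
  if (all(terms_vec <= 0)) return(0)
  G <- 4 * pi * lB * terms_vec / .kgrid$k2
  h <- .kgrid$k2 * (log1p(G) - G)
  integral <- sum(0.5 * (h[-1] + h[-length(h)]) * .kgrid$dk)
  B <- 4 * pi * lB * t_inf  # 1/k^2 tail beyond the grid: h ~ -B^2/(2k^2)
  (integral - B^2 / (2 * .kgrid$K)) / (4 * pi^2)
}

#' rG-RPA+FH free-energy density and its breakdown
#'
#' Evaluates the free-energy density (kBT per b^3) of an electroneutral
#' solution state, returning the component breakdown:
#' `f_ideal` (mixing entropy of chains, counterions, salt and implicit
#' solvent), `f_fh` (`-chi(T) phi_p^2`), `f_ex` (bare excluded volume
#' `v2/2 (N rho_p)^2`), and `f_el` (the rG-RPA charge-correlation integral
#' evaluated with the renormalized single-chain structure factor `S(k; x)`,
#' always `<= 0`). The renormalization factor `x` is re-solved for every
#' state and reported in the breakdown.
#'
#' @param cs a `ChargeSequence`.
#' @param state a `SolutionState`.
#' @param params an `EnergyParams`.
#' @return a `FreeEnergyBreakdown` list with the components above, the
#'   renormalization factor `x`, and `total`.
#' @export
free_energy <- function(cs, state, params = energy_params()) {
  rho_p <- state$rho_p; rho_c <- state$rho_c; rho_s <- state$rho_s
  N <- cs$N
  vi <- if (is.null(params$ion_volume)) 1 else params$ion_volume
  phi_w <- 1 - N * rho_p - vi * (rho_c + rho_s)
  if (phi_w <= 0) stop("total bead volume fraction >= 1: state outside model domain")
  xlx <- function(r) ifelse(r > 0, r * log(r), 0)
  f_ideal <- (xlx(rho_p) - rho_p) + (xlx(rho_c) - rho_c) +
    (xlx(rho_s) - rho_s) + xlx(phi_w) + (1 - phi_w)
  ch <- chi_fh(state$T_K, params = params)
  f_fh <- -ch * (N * rho_p)^2
  f_ex <- 0.5 * params$v2 * (N * rho_p)^2

  pat <- .charge_pattern(cs)
  rk <- renormalized_kuhn(cs, state, params, full = TRUE)
  lB <- rk$lB

  # The variational single-chain free energy determines x (the renormalized
  # reference chain) but is NOT added to the free-energy density: its
  # intrachain screened-Coulomb content is already represented inside the RPA
  # correlation integral through the rho_p S(k; x) term, and adding both
  # double-counts intrachain screening (see the methods vignette).
  f_el <- if (lB > 0) {
    ionic <- params$zc^2 * rho_c + params$zs^2 * rho_s
    tv <- ionic + if (rho_p > 0) rho_p * .Sk(.kgrid$k, pat, rk$x) else 0
    t_inf <- ionic + rho_p * pat$cd[1]
    .f_el_rpa(tv, t_inf, lB)
  } else 0

  total <- f_ideal + f_fh + f_ex + f_el
  structure(list(f_ideal = f_ideal, f_fh = f_fh, f_ex = f_ex,
                 f_el = f_el, x = rk$x, total = total),
            class = "FreeEnergyBreakdown")
}

# scalar total free energy at given concentrations (internal convenience)
.f_total <- function(cs, rho_p, rho_c, rho_s, T_K, params) {
  st <- structure(list(rho_p = rho_p, rho_c = rho_c, rho_s = rho_s, T_K = T_K),
                  class = "SolutionState")
  free_energy(cs, st, params)$total
}

# S(k; x) and dS/dx on the fixed grid, one pass of cumulative products
.Sk_dSdx <- function(k2, pat, x) {
  e1 <- exp(-k2 * x / 6)
  S <- rep(pat$cd[1], length(k2))
  D <- numeric(length(k2))          # sum_d c_d d exp(-k2 x d/6)
  acc <- rep(1, length(k2))
  cd <- pat$cd
  for (d in seq_len(pat$N - 1)) {
    acc <- acc * e1
    if (cd[d + 1] != 0) {
      S <- S + cd[d + 1] * acc
      D <- D + cd[d + 1] * d * acc
    }
  }
  list(S = S, dSdx = -k2 / 6 * D)
}

# Analytic-structure chemical potentials mu_i = df/drho_i (i = p, c, s),
# free energy and osmotic pressure at an arbitrary (not necessarily neutral)
# composition. The entropic/mean-field parts are closed-form; the RPA part is
# differentiated under the (fixed-grid) integral, with the dependence of the
# renormalization factor x on the ionic strength handled by the implicit
# function theorem on the variational condition dF1/dx = 0.
.mu_all <- function(cs, rho_p, rho_c, rho_s, T_K, params) {
  N <- cs$N
  pat <- .charge_pattern(cs)
  lB <- bjerrum_length(T_K, params$epsilon_r) / params$l_A
  zc <- params$zc; zs <- params$zs
  vi <- if (is.null(params$ion_volume)) 1 else params$ion_volume
  phi_w <- 1 - N * rho_p - vi * (rho_c + rho_s)
  if (phi_w <= 0) stop("total bead volume fraction >= 1")
  xlx <- function(r) if (r > 0) r * log(r) else 0
  lg <- function(r) if (r > 0) log(r) else -Inf  # mu at zero conc is -Inf
  ch <- chi_fh(T_K, params = params)

  f_ideal <- (xlx(rho_p) - rho_p) + (xlx(rho_c) - rho_c) +
    (xlx(rho_s) - rho_s) + xlx(phi_w) + (1 - phi_w)
  f_fh <- -ch * (N * rho_p)^2
  f_ex <- 0.5 * params$v2 * (N * rho_p)^2
  mu_p0 <- lg(rho_p) - N * log(phi_w) + (-2 * ch + params$v2) * N^2 * rho_p
  mu_c0 <- lg(rho_c) - vi * log(phi_w)
  mu_s0 <- lg(rho_s) - vi * log(phi_w)

  # variational x and its sensitivity to the Debye kappa
  kap2 <- max(4 * pi * lB * (zc^2 * rho_c + zs^2 * rho_s), 0)
  kappa <- sqrt(kap2)
  st <- structure(list(rho_p = rho_p, rho_c = rho_c, rho_s = rho_s, T_K = T_K),
                  class = "SolutionState")
  x <- renormalized_kuhn(cs, st, params)
  # generous steps: the mixed finite difference divides machine noise by
  # hx*hk, so tiny steps poison the chemical-potential noise floor
  hx <- 1e-3 * x; hk <- 1e-3 * (kappa + 0.05)
  F1x <- function(xx, kk) .F1(xx, pat, kk, lB, params$v2)
  F1_xx <- (F1x(x + hx, kappa) - 2 * F1x(x, kappa) + F1x(x - hx, kappa)) / hx^2
  F1_xk <- (F1x(x + hx, kappa + hk) - F1x(x + hx, kappa - hk) -
              F1x(x - hx, kappa + hk) + F1x(x - hx, kappa - hk)) / (4 * hx * hk)
  dx_dk <- if (abs(F1_xx) > 1e-12) -F1_xk / F1_xx else 0
  dk_dc <- if (kappa > 0) 4 * pi * lB * zc^2 / (2 * kappa) else 0
  dk_ds <- if (kappa > 0) 4 * pi * lB * zs^2 / (2 * kappa) else 0

  # RPA integral and its partial derivatives on the fixed grid
  sd <- .Sk_dSdx(.kgrid$k2, pat, x)
  ionic <- zc^2 * rho_c + zs^2 * rho_s
  tv <- ionic + rho_p * sd$S
  t_inf <- ionic + rho_p * pat$cd[1]
  f_el <- if (lB > 0) .f_el_rpa(tv, t_inf, lB) else 0
  if (lB > 0 && any(tv > 0)) {
    Gfrac <- {
      G <- 4 * pi * lB * tv / .kgrid$k2
      G / (1 + G)
    }
    trap <- function(w) {
      h <- Gfrac * w
      sum(0.5 * (h[-1] + h[-length(h)]) * .kgrid$dk)
    }
    B <- 4 * pi * lB * t_inf
    # d f_el / d t for t entering as + w(k) per unit rho: -(lB/pi) Int Gfrac w dk
    I_S  <- -(lB / pi) * (trap(sd$S) + pat$cd[1] * B / .kgrid$K)
    I_zc <- -(lB / pi) * zc^2 * (trap(rep(1, length(Gfrac))) + B / .kgrid$K)
    I_zs <- I_zc / zc^2 * zs^2
    I_x  <- -(lB / pi) * rho_p * trap(sd$dSdx)
    mu_p_el <- I_S
    mu_c_el <- I_zc + I_x * dx_dk * dk_dc
    mu_s_el <- I_zs + I_x * dx_dk * dk_ds
  } else {
    mu_p_el <- mu_c_el <- mu_s_el <- 0
  }
  f <- f_ideal + f_fh + f_ex + f_el
  mu_p <- mu_p0 + mu_p_el
  mu_c <- mu_c0 + mu_c_el
  mu_s <- mu_s0 + mu_s_el
  rmu <- function(rho, mu) if (rho > 0) rho * mu else 0  # 0 * (-Inf) := 0
  list(mu_p = mu_p, mu_c = mu_c, mu_s = mu_s, f = f,
       Pi = rmu(rho_p, mu_p) + rmu(rho_c, mu_c) + rmu(rho_s, mu_s) - f,
       x = x)
}

#' Chemical potentials and osmotic pressure
#'
#' Thermodynamic derivatives of the free-energy density: `mu_i = df/drho_i`
#' (kBT per molecule) for polymer, counterion and salt, and the osmotic
#' pressure `Pi = sum_i rho_i mu_i - f` (kBT per b^3). The entropic and
#' mean-field contributions are closed-form; the rG-RPA contribution is
#' differentiated analytically under the wavenumber integral, with the
#' ionic-strength dependence of the renormalization factor `x` propagated via
#' the implicit function theorem on the variational condition. A
#' finite-difference evaluation of the same derivatives is available as an
#' independent cross-check via `method = "fd"`.
#'
#' @param cs a `ChargeSequence`.
#' @param state a strictly interior `SolutionState` (all present species > 0).
#' @param params an `EnergyParams`.
#' @param method `"analytic"` (default) or `"fd"` (five-point central
#'   differences of the total free energy, used as the numerical oracle).
#' @param h_rel relative step for `method = "fd"`.
#' @return list with `mu_p`, `mu_c`, `mu_s`, `Pi`, and `f`.
#' @export
chemical_potentials_pressure <- function(cs, state, params = energy_params(),
                                         method = c("analytic", "fd"),
                                         h_rel = 1e-4) {
  method <- match.arg(method)
  if (method == "analytic") {
    out <- .mu_all(cs, state$rho_p, state$rho_c, state$rho_s, state$T_K, params)
    return(out[c("mu_p", "mu_c", "mu_s", "Pi", "f")])
  }
  rho <- c(p = state$rho_p, c = state$rho_c, s = state$rho_s)
  f0 <- .f_total(cs, rho[1], rho[2], rho[3], state$T_K, params)
  d5 <- function(i) {
    h <- h_rel * max(rho[i], 1e-8)
    fs <- vapply(c(-2, -1, 1, 2), function(m) {
      r <- rho; r[i] <- r[i] + m * h
      .f_total(cs, r[1], r[2], r[3], state$T_K, params)
    }, numeric(1))
    (fs[1] - 8 * fs[2] + 8 * fs[3] - fs[4]) / (12 * h)
  }
  mu <- vapply(1:3, d5, numeric(1))
  Pi <- sum(rho * mu) - f0
  list(mu_p = mu[1], mu_c = mu[2], mu_s = mu[3], Pi = Pi, f = f0)
}

#' Local thermodynamic stability
#'
#' Smallest eigenvalue of the free-energy Hessian taken along the two neutral
#' composition directions: (i) polymer plus its `|Q|/zc` counterions and (ii)
#' salt ion plus its `zs/zc` counterions. A negative value means the state is
#' locally unstable (inside the spinodal).
#'
#' @inheritParams chemical_potentials_pressure
#' @return smallest eigenvalue of the 2x2 neutral-component Hessian
#'   (kBT b^3 units).
#' @export
stability <- function(cs, state, params = energy_params(), h_rel = 1e-4) {
  Q <- abs(cs$Q); zs <- params$zs; zc <- params$zc
  # neutral directions in (rho_p, rho_c, rho_s)
  dirs <- rbind(c(1, Q / zc, 0), c(0, zs / zc, 1))
  rho0 <- c(state$rho_p, state$rho_c, state$rho_s)
  fval <- function(a, b) {
    r <- rho0 + a * dirs[1, ] + b * dirs[2, ]
    .f_total(cs, r[1], r[2], r[3], state$T_K, params)
  }
  ha <- h_rel * max(state$rho_p, 1e-7)
  hb <- h_rel * max(state$rho_s, state$rho_c, 1e-7)
  f00 <- fval(0, 0)
  H <- matrix(0, 2, 2)
  H[1, 1] <- (fval(ha, 0) - 2 * f00 + fval(-ha, 0)) / ha^2
  H[2, 2] <- (fval(0, hb) - 2 * f00 + fval(0, -hb)) / hb^2
  H[1, 2] <- H[2, 1] <- (fval(ha, hb) - fval(ha, -hb) -
                           fval(-ha, hb) + fval(-ha, -hb)) / (4 * ha * hb)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  min(ev)
}
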