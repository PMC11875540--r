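// Complex-Langevin field-theoretic simulation kernel.
//
// Two complex lattice fields w (excluded volume) and psi (electrostatic)
// evolve under dphi/dt = -dH/dphi + eta with
//   H = Int dr [ (grad psi)^2/(8 pi lB) + w^2/(2 v2) ] - sum_m n_m ln Q_m
// where Q_m are single-molecule partition functions of Gaussian chains with
// per-bead charges, evaluated with Gamma-smeared fields. First-order
// semi-implicit updates; real Gaussian noise of variance 2 dt / dV per site.
// Lattice dims must be powers of two (radix-2 FFT).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <map>
#include <random>
#include <cstdint>
#include <cmath>

using namespace Rcpp;
typedef float real_t;           // lattice fields in single precision:
                                 // CL averages are noise-dominated, and all
                                 // sample accumulators stay in double
typedef std::complex<real_t> cplx;
static const double PI = 3.14159265358979323846;

// Box-Muller on top of mt19937_64: avoids std::normal_distribution, whose
// stream is implementation-defined; this one is reproducible everywhere.
struct Gauss {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() {
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), t = 2.0 * PI * u2;
    spare = r * std::sin(t); has_spare = true;
    return r * std::cos(t);
  }
};

struct FFT1 {
  int n = 0;
  std::vector<cplx> tw;
  std::vector<int> rev;
  void init(int n_) {
    n = n_;
    rev.assign(n, 0);
    int lg = 0; while ((1 << lg) < n) ++lg;
    for (int i = 0; i < n; ++i) {
      int r = 0;
      for (int b = 0; b < lg; ++b) if (i & (1 << b)) r |= 1 << (lg - 1 - b);
      rev[i] = r;
    }
    tw.assign(n / 2, cplx(1, 0));
    for (int k = 0; k < n / 2; ++k) {
      double a = -2.0 * PI * k / n;
      tw[k] = cplx(std::cos(a), std::sin(a));
    }
  }
  void run(cplx* a, bool inverse) const {
    for (int i = 0; i < n; ++i)
      if (rev[i] > i) std::swap(a[i], a[rev[i]]);
    for (int len = 2; len <= n; len <<= 1) {
      int half = len >> 1, step = n / len;
      for (int i = 0; i < n; i += len) {
        for (int j = 0; j < half; ++j) {
          cplx t = tw[j * step];
          if (inverse) t = std::conj(t);
          cplx u = a[i + j], v = a[i + j + half] * t;
          a[i + j] = u + v;
          a[i + j + half] = u - v;
        }
      }
    }
  }
};

// 3-D FFT by in-place strided radix-2 butterflies over the whole cube:
// for each axis the butterflies run simultaneously over all lines, with the
// inner loop over the contiguous x dimension, which vectorizes well and
// avoids per-line call overhead on small lattices.
struct FFT3 {
  int nx, ny, nz, ncell;
  FFT1 fx, fy, fz;
  void init(int nx_, int ny_, int nz_) {
    nx = nx_; ny = ny_; nz = nz_; ncell = nx * ny * nz;
    fx.init(nx); fy.init(ny); fz.init(nz);
  }
  // swap the two "hyperplanes" with axis-index ia and ib along axis ax
  inline void swap_planes(cplx* a, int ax, int ia, int ib) {
    if (ax == 0) {
      int nl = ny * nz;
      for (int q = 0; q < nl; ++q)
        std::swap(a[ia + (size_t)nx * q], a[ib + (size_t)nx * q]);
    } else if (ax == 1) {
      for (int z = 0; z < nz; ++z) {
        cplx* pa = a + (size_t)nx * (ia + (size_t)ny * z);
        cplx* pb = a + (size_t)nx * (ib + (size_t)ny * z);
        for (int x = 0; x < nx; ++x) std::swap(pa[x], pb[x]);
      }
    } else {
      size_t sl = (size_t)nx * ny;
      cplx* pa = a + sl * ia;
      cplx* pb = a + sl * ib;
      for (size_t q = 0; q < sl; ++q) std::swap(pa[q], pb[q]);
    }
  }
  // butterfly between axis-indices ia, ib with twiddle t
  inline void butterfly_planes(cplx* a, int ax, int ia, int ib, cplx t) {
    if (ax == 0) {
      int nl = ny * nz;
      for (int q = 0; q < nl; ++q) {
        cplx& u = a[ia + (size_t)nx * q];
        cplx& v = a[ib + (size_t)nx * q];
        cplx vv = v * t;
        v = u - vv; u += vv;
      }
    } else if (ax == 1) {
      for (int z = 0; z < nz; ++z) {
        cplx* pa = a + (size_t)nx * (ia + (size_t)ny * z);
        cplx* pb = a + (size_t)nx * (ib + (size_t)ny * z);
        for (int x = 0; x < nx; ++x) {
          cplx vv = pb[x] * t;
          pb[x] = pa[x] - vv; pa[x] += vv;
        }
      }
    } else {
      size_t sl = (size_t)nx * ny;
      cplx* pa = a + sl * ia;
      cplx* pb = a + sl * ib;
      for (size_t q = 0; q < sl; ++q) {
        cplx vv = pb[q] * t;
        pb[q] = pa[q] - vv; pa[q] += vv;
      }
    }
  }
  void axis(std::vector<cplx>& a, int ax, bool inv) {
    const FFT1& f = ax == 0 ? fx : (ax == 1 ? fy : fz);
    int n = f.n;
    cplx* p = a.data();
    for (int i = 0; i < n; ++i)
      if (f.rev[i] > i) swap_planes(p, ax, i, f.rev[i]);
    for (int len = 2; len <= n; len <<= 1) {
      int half = len >> 1, step = n / len;
      for (int j = 0; j < half; ++j) {
        cplx t = f.tw[j * step];
        if (inv) t = std::conj(t);
        for (int i = 0; i < n; i += len)
          butterfly_planes(p, ax, i + j, i + j + half, t);
      }
    }
  }
  void forward(std::vector<cplx>& a) {
    axis(a, 0, false); axis(a, 1, false); axis(a, 2, false);
  }
  void inverse(std::vector<cplx>& a) {
    axis(a, 0, true); axis(a, 1, true); axis(a, 2, true);
    real_t s = (real_t)(1.0 / ncell);
    for (auto& v : a) v *= s;
  }
};

struct Species {
  std::vector<double> charges;
  double rho;  // chain number density, b^-3
};

// [[Rcpp::export(name = ".fts_run_cpp")]]
List fts_run_cpp(IntegerVector dims, double dx, double lB, double v2,
                 double a_smear, double dt, List species,
                 int n_therm, int n_prod, int sample_every, int seed,
                 IntegerMatrix pairs, int profile_species, int profile_q,
                 double rcontact, int nblocks, bool noise,
                 Nullable<ComplexVector> w0 = R_NilValue,
                 Nullable<ComplexVector> psi0 = R_NilValue,
                 bool sample_fields = false) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto pow2 = [](int n) { return n > 0 && (n & (n - 1)) == 0; };
  if (!pow2(nx) || !pow2(ny) || !pow2(nz))
    stop("lattice dims must be powers of two");
  const int nc = nx * ny * nz;
  const double dV = dx * dx * dx;
  FFT3 fft; fft.init(nx, ny, nz);

  std::vector<Species> sp;
  for (R_xlen_t i = 0; i < species.size(); ++i) {
    List s = species[i];
    Species o; o.charges = as<std::vector<double>>(s["charges"]);
    o.rho = as<double>(s["rho"]);
    sp.push_back(o);
  }
  const int nsp = sp.size();
  double rho_beads = 0, rho_sig2 = 0;
  int Mmax = 0;
  for (auto& s : sp) {
    rho_beads += s.rho * s.charges.size();
    for (double c : s.charges) rho_sig2 += s.rho * c * c;
    Mmax = std::max(Mmax, (int)s.charges.size());
  }

  // lattice spectra: k^2, smearing, bond transfer, semi-implicit coefficients
  std::vector<real_t> gam(nc), bond(nc), lam_w(nc), lam_psi(nc), coul(nc);
  for (int z = 0; z < nz; ++z) {
    double kz = 2.0 * PI / (nz * dx) * (z <= nz / 2 ? z : z - nz);
    for (int y = 0; y < ny; ++y) {
      double ky = 2.0 * PI / (ny * dx) * (y <= ny / 2 ? y : y - ny);
      for (int x = 0; x < nx; ++x) {
        double kx = 2.0 * PI / (nx * dx) * (x <= nx / 2 ? x : x - nx);
        size_t id = x + (size_t)nx * (y + (size_t)ny * z);
        double kk = kx * kx + ky * ky + kz * kz;
        gam[id] = (real_t)std::exp(-0.5 * a_smear * a_smear * kk);
        bond[id] = (real_t)std::exp(-kk / 6.0);
        double g2 = (double)gam[id] * gam[id];
        coul[id] = (real_t)(kk / (4.0 * PI * lB));
        lam_w[id] = (real_t)((v2 > 0 ? 1.0 / v2 : 0.0) + g2 * rho_beads);
        lam_psi[id] = (real_t)(kk / (4.0 * PI * lB) + g2 * rho_sig2);
      }
    }
  }

  // radial bins and the r <= rcontact ball
  std::vector<int> binof(nc);
  double rmax = 0.5 * dx * std::min(nx, std::min(ny, nz));
  int nbin = (int)std::floor(rmax / dx) + 1;
  std::vector<int> ball;
  std::vector<int> negi(nc);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int xm = x <= nx / 2 ? x : x - nx;
        int ym = y <= ny / 2 ? y : y - ny;
        int zm = z <= nz / 2 ? z : z - nz;
        double r = dx * std::sqrt((double)(xm * xm + ym * ym + zm * zm));
        size_t id = x + (size_t)nx * (y + (size_t)ny * z);
        int b = (int)std::floor(r / dx + 0.5);
        binof[id] = (b < nbin) ? b : -1;
        if (r <= rcontact) ball.push_back((int)id);
        negi[id] = ((nx - x) % nx) +
          nx * (((ny - y) % ny) + ny * ((nz - z) % nz));
      }
  std::vector<int> bincount(nbin, 0);
  for (int i = 0; i < nc; ++i) if (binof[i] >= 0) bincount[binof[i]]++;

  // fields
  std::vector<cplx> w(nc, cplx(0.0f, (real_t)(-v2 * rho_beads))), psi(nc, cplx(0, 0));
  if (w0.isNotNull()) {
    ComplexVector W(w0);
    for (int i = 0; i < nc; ++i) w[i] = cplx((real_t)W[i].r, (real_t)W[i].i);
  }
  if (psi0.isNotNull()) {
    ComplexVector P(psi0);
    for (int i = 0; i < nc; ++i)
      psi[i] = cplx((real_t)P[i].r, (real_t)P[i].i);
  }
  Gauss rng((uint64_t)seed * 2654435761ull + 1442695040888963407ull);

  const int npair = pairs.nrow();
  const int Mprof = profile_species >= 0 ?
    (int)sp[profile_species].charges.size() : 0;
  std::vector<double> Gr_re((size_t)nbin * npair * nblocks, 0.0);
  std::vector<double> Gr_im((size_t)nbin * npair * nblocks, 0.0);
  std::vector<double> prof_re((size_t)std::max(Mprof, 1) * nblocks, 0.0);
  std::vector<double> prof_im((size_t)std::max(Mprof, 1) * nblocks, 0.0);
  std::vector<int> nsamp_block(nblocks, 0);
  std::vector<double> meanrho_re(nsp, 0.0), meanrho_im(nsp, 0.0);
  std::vector<double> Qm_im_abs(nsp, 0.0), Qm_re(nsp, 0.0);
  int nsamp_tot = 0;
  bool diverged = false;

  // workspaces (allocated once)
  std::vector<cplx> wb(nc), pb(nc), w_k(nc), psi_k(nc);
  std::vector<cplx> rho_tot(nc), rho_chg(nc), tmp(nc), buf(nc);
  std::vector<std::vector<cplx>> rho_sp(nsp, std::vector<cplx>(nc));
  std::vector<std::vector<cplx>> qdiv(Mmax, std::vector<cplx>(nc));
  std::vector<cplx> qb_cur(nc), qb_prev(nc);
  std::vector<cplx> E0(nc), Epsi(nc), Einv(nc);
  std::map<int, std::vector<cplx>> hs;  // per distinct integer charge
  std::vector<std::vector<cplx>> per_bead;
  List snaps;

  // distinct charges across species (assumed near-integer)
  std::vector<int> distinct;
  for (auto& s : sp)
    for (double c : s.charges) {
      int ci = (int)std::lround(c);
      if (std::find(distinct.begin(), distinct.end(), ci) == distinct.end())
        distinct.push_back(ci);
    }
  for (int ci : distinct) hs[ci] = std::vector<cplx>(nc);

  const int total_steps = n_therm + n_prod;
  const int samples_per_block =
    std::max(1, (n_prod / std::max(sample_every, 1)) / nblocks);
  const cplx I(0, 1);

  for (int step = 0; step < total_steps; ++step) {
    // smeared fields (keep spectra for the update)
    w_k = w; fft.forward(w_k);
    psi_k = psi; fft.forward(psi_k);
    wb = w_k; pb = psi_k;
    for (int i = 0; i < nc; ++i) { wb[i] *= gam[i]; pb[i] *= gam[i]; }
    fft.inverse(wb); fft.inverse(pb);

    // local Boltzmann factors per distinct charge: exp(-i(c*psi_b + w_b))
    for (int i = 0; i < nc; ++i) {
      E0[i] = std::exp(-I * wb[i]);
      Epsi[i] = std::exp(-I * pb[i]);
      Einv[i] = 1.0f / Epsi[i];
    }
    for (int ci : distinct) {
      std::vector<cplx>& h = hs[ci];
      if (ci == 0) h = E0;
      else {
        int p = std::abs(ci);
        const std::vector<cplx>& base = ci > 0 ? Epsi : Einv;
        for (int i = 0; i < nc; ++i) {
          cplx v = base[i];
          for (int q = 1; q < p; ++q) v *= base[i];
          h[i] = E0[i] * v;
        }
      }
    }

    bool sampling = step >= n_therm && ((step - n_therm) % sample_every == 0);
    bool want_bead = sampling && profile_species >= 0 && profile_q >= 0;
    std::fill(rho_tot.begin(), rho_tot.end(), cplx(0, 0));
    std::fill(rho_chg.begin(), rho_chg.end(), cplx(0, 0));
    std::vector<cplx> Qs(nsp);

    for (int m = 0; m < nsp && !diverged; ++m) {
      const Species& spc = sp[m];
      const int M = spc.charges.size();
      // forward pass: qdiv[b] = propagated weight BEFORE the local factor
      for (int i = 0; i < nc; ++i) qdiv[0][i] = cplx(1, 0);
      for (int b = 1; b < M; ++b) {
        const std::vector<cplx>& h =
          hs[(int)std::lround(spc.charges[b - 1])];
        for (int i = 0; i < nc; ++i) tmp[i] = h[i] * qdiv[b - 1][i];
        fft.forward(tmp);
        for (int i = 0; i < nc; ++i) tmp[i] *= bond[i];
        fft.inverse(tmp);
        qdiv[b] = tmp;
      }
      const std::vector<cplx>& hM = hs[(int)std::lround(spc.charges[M - 1])];
      cplx Q(0, 0);
      for (int i = 0; i < nc; ++i) Q += hM[i] * qdiv[M - 1][i];
      Q /= (real_t)nc;
      Qs[m] = Q;
      if (!std::isfinite(Q.real()) || !std::isfinite(Q.imag()) ||
          std::abs(Q) < 1e-30f) { diverged = true; break; }
      cplx pref = (real_t)spc.rho / Q;
      // backward pass with on-the-fly density accumulation
      std::vector<cplx>& rs = rho_sp[m];
      std::fill(rs.begin(), rs.end(), cplx(0, 0));
      if (want_bead && m == profile_species)
        per_bead.assign(M, std::vector<cplx>(nc));
      for (int b = M - 1; b >= 0; --b) {
        const std::vector<cplx>& h = hs[(int)std::lround(spc.charges[b])];
        if (b == M - 1) {
          qb_cur = h;
        } else {
          fft.forward(qb_prev);
          for (int i = 0; i < nc; ++i) qb_prev[i] *= bond[i];
          fft.inverse(qb_prev);
          for (int i = 0; i < nc; ++i) qb_cur[i] = h[i] * qb_prev[i];
        }
        real_t sg = (real_t)spc.charges[b];
        for (int i = 0; i < nc; ++i) {
          cplx d = pref * qdiv[b][i] * qb_cur[i];
          rs[i] += d;
          if (sg != 0) rho_chg[i] += sg * d;
          if (want_bead && m == profile_species) per_bead[b][i] = d;
        }
        qb_prev = qb_cur;
      }
      for (int i = 0; i < nc; ++i) rho_tot[i] += rs[i];
    }
    if (diverged) break;

    if (sampling) {
      int iblock = std::min(nblocks - 1,
                            ((step - n_therm) / sample_every) / samples_per_block);
      nsamp_block[iblock]++;
      nsamp_tot++;
      for (int m = 0; m < nsp; ++m) {
        cplx s(0, 0);
        for (int i = 0; i < nc; ++i) s += rho_sp[m][i];
        s /= (real_t)nc;
        meanrho_re[m] += s.real(); meanrho_im[m] += s.imag();
        Qm_im_abs[m] += std::abs(Qs[m].imag());
        Qm_re[m] += Qs[m].real();
      }
      std::vector<std::vector<cplx>> spec(nsp);
      std::vector<bool> need(nsp, false);
      for (int p = 0; p < npair; ++p) {
        need[pairs(p, 0)] = true; need[pairs(p, 1)] = true;
      }
      if (profile_q >= 0) need[profile_q] = true;
      for (int m = 0; m < nsp; ++m) {
        if (!need[m]) continue;
        spec[m] = rho_sp[m];
        fft.forward(spec[m]);
        for (int i = 0; i < nc; ++i) spec[m][i] *= gam[i];
      }
      for (int p = 0; p < npair; ++p) {
        int m = pairs(p, 0), n = pairs(p, 1);
        for (int i = 0; i < nc; ++i) buf[i] = spec[m][negi[i]] * spec[n][i];
        fft.inverse(buf);
        real_t invnc = (real_t)(1.0 / nc);
        for (int i = 0; i < nc; ++i) {
          int bn = binof[i];
          if (bn < 0) continue;
          size_t id = bn + (size_t)nbin * (p + (size_t)npair * iblock);
          Gr_re[id] += buf[i].real() * invnc;
          Gr_im[id] += buf[i].imag() * invnc;
        }
      }
      if (want_bead) {
        for (int b = 0; b < Mprof; ++b) {
          tmp = per_bead[b];
          fft.forward(tmp);
          for (int i = 0; i < nc; ++i)
            buf[i] = (tmp[negi[i]] * gam[negi[i]]) * spec[profile_q][i];
          fft.inverse(buf);
          cplx acc(0, 0);
          for (int id : ball) acc += buf[id];
          acc *= (real_t)(dV / (double)nc);
          prof_re[b + (size_t)Mprof * iblock] += acc.real();
          prof_im[b + (size_t)Mprof * iblock] += acc.imag();
        }
      }
      if (sample_fields && (int)snaps.size() < 8) {
        ComplexVector rp(nc);
        for (int i = 0; i < nc; ++i) {
          rp[i].r = rho_sp[0][i].real();
          rp[i].i = rho_sp[0][i].imag();
        }
        snaps.push_back(rp);
      }
    }

    // semi-implicit update in k-space
    tmp = rho_tot; fft.forward(tmp);          // fft(rho_tot)
    buf = rho_chg; fft.forward(buf);          // fft(rho_chg)
    std::vector<cplx>& ew = rho_tot;          // reuse as noise buffers
    std::vector<cplx>& ep = rho_chg;
    if (noise) {
      double amp = std::sqrt(2.0 * dt / dV);
      for (int i = 0; i < nc; ++i)
        ew[i] = cplx((real_t)(amp * rng()), 0.0f);
      for (int i = 0; i < nc; ++i)
        ep[i] = cplx((real_t)(amp * rng()), 0.0f);
      fft.forward(ew); fft.forward(ep);
    } else {
      std::fill(ew.begin(), ew.end(), cplx(0, 0));
      std::fill(ep.begin(), ep.end(), cplx(0, 0));
    }
    const real_t inv_v2 = (real_t)(v2 > 0 ? 1.0 / v2 : 0.0);
    const real_t dtf = (real_t)dt;
    for (int i = 0; i < nc; ++i) {
      cplx Fw = inv_v2 * w_k[i] + I * gam[i] * tmp[i];
      cplx Fp = coul[i] * psi_k[i] + I * gam[i] * buf[i];
      w_k[i] = (w_k[i] - dtf * (Fw - lam_w[i] * w_k[i]) + ew[i]) /
        (1.0f + dtf * lam_w[i]);
      psi_k[i] = (psi_k[i] - dtf * (Fp - lam_psi[i] * psi_k[i]) + ep[i]) /
        (1.0f + dtf * lam_psi[i]);
    }
    w = w_k; fft.inverse(w);
    psi = psi_k; fft.inverse(psi);
    double mx = 0;
    for (int i = 0; i < nc; ++i)
      mx = std::max(mx, (double)(std::abs(w[i].real()) + std::abs(w[i].imag()) +
                      std::abs(psi[i].real()) + std::abs(psi[i].imag())));
    if (!std::isfinite(mx) || mx > 1e8) { diverged = true; break; }
  }

  NumericVector grre(Gr_re.begin(), Gr_re.end());
  grre.attr("dim") = IntegerVector::create(nbin, npair, nblocks);
  NumericVector grim(Gr_im.begin(), Gr_im.end());
  grim.attr("dim") = IntegerVector::create(nbin, npair, nblocks);
  NumericVector pre(prof_re.begin(), prof_re.end());
  NumericVector pim(prof_im.begin(), prof_im.end());
  if (Mprof > 0) {
    pre.attr("dim") = IntegerVector::create(Mprof, nblocks);
    pim.attr("dim") = IntegerVector::create(Mprof, nblocks);
  }
  NumericVector rvec(nbin);
  for (int b = 0; b < nbin; ++b) rvec[b] = b * dx;
  ComplexVector wout(nc), pout(nc);
  for (int i = 0; i < nc; ++i) {
    wout[i].r = w[i].real(); wout[i].i = w[i].imag();
    pout[i].r = psi[i].real(); pout[i].i = psi[i].imag();
  }
  return List::create(
    _["Gr_re"] = grre, _["Gr_im"] = grim, _["r"] = rvec,
    _["bincount"] = IntegerVector(bincount.begin(), bincount.end()),
    _["profile_re"] = pre, _["profile_im"] = pim,
    _["nsamp_block"] = IntegerVector(nsamp_block.begin(), nsamp_block.end()),
    _["mean_rho_re"] = NumericVector(meanrho_re.begin(), meanrho_re.end()),
    _["mean_rho_im"] = NumericVector(meanrho_im.begin(), meanrho_im.end()),
    _["Qm_im_abs"] = NumericVector(Qm_im_abs.begin(), Qm_im_abs.end()),
    _["Qm_re"] = NumericVector(Qm_re.begin(), Qm_re.end()),
    _["nsamp"] = nsamp_tot, _["diverged"] = diverged,
    _["w"] = wout, _["psi"] = pout, _["snapshots"] = snaps);
}
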