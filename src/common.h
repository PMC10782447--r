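#ifndef IONSOLV_COMMON_H
#define IONSOLV_COMMON_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Internal units: nm, kJ/mol, ps, g/mol, elementary charge.
namespace ionsolv {

static const double KE_COUL = 138.935458;   // kJ mol^-1 nm e^-2
static const double KB = 8.31446e-3;        // kJ mol^-1 K^-1
static const double OVERLAP_FLOOR = 1e-4;   // nm; below this a configuration is invalid

inline double minimg1(double d, double L) {
  // map displacement component into [-L/2, L/2)
  d -= L * std::floor(d / L + 0.5);
  return d;
}

inline void minimg3(double dx[3], const double* box) {
  dx[0] = minimg1(dx[0], box[0]);
  dx[1] = minimg1(dx[1], box[1]);
  dx[2] = minimg1(dx[2], box[2]);
}

// C1 cosine cutoff envelope: fc(0)=1, fc(rc)=0, fc'(rc)=0.
inline double fcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return 0.5 * (std::cos(M_PI * r / rc) + 1.0);
}
inline double dfcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return -0.5 * M_PI / rc * std::sin(M_PI * r / rc);
}

// ---- Lennard-Jones 12-6, optional energy shift at cutoff -------------------
struct LJParams {
  int S;
  std::vector<double> sig, eps;   // S x S, column-major
  double rc, rc2;
  bool shift;
  double sg(int a, int b) const { return sig[a + S * b]; }
  double ep(int a, int b) const { return eps[a + S * b]; }
};

// returns energy; f_over_r receives dU/dr * (-1/r) so F_j = f_over_r * (xj-xi)... sign:
// convention used throughout: for pair (i,j) with dx = xj - xi (min image),
// force on j = fr * dx, force on i = -fr * dx, where fr = -(dU/dr)/r.
inline double lj_pair(double r2, double s, double e, double rc, bool shift, double& fr) {
  double sr2 = s * s / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double u = 4.0 * e * (sr12 - sr6);
  fr = 24.0 * e * (2.0 * sr12 - sr6) / r2;  // = -(dU/dr)/r
  if (shift) {
    double src2 = s * s / (rc * rc);
    double src6 = src2 * src2 * src2;
    u -= 4.0 * e * (src6 * src6 - src6);
  }
  return u;
}

// ---- Wolf electrostatics (damped shifted force / energy-shift variants) ----
struct WolfParams {
  double alpha, rc, keq;   // keq = KE_COUL / eps_r
  int variant;             // 0 = dsf, 1 = energy_shift
  double e_rc, f_rc;       // erfc(a rc)/rc ; force magnitude factor at rc
  void setup() {
    double a = alpha;
    e_rc = std::erfc(a * rc) / rc;
    f_rc = std::erfc(a * rc) / (rc * rc) +
           2.0 * a / std::sqrt(M_PI) * std::exp(-a * a * rc * rc) / rc;
  }
  // self-energy prefactor multiplying sum(q_i^2)
  double self_prefactor() const {
    return -keq * (0.5 * e_rc + alpha / std::sqrt(M_PI));
  }
};

inline double wolf_pair(double r, double qq, const WolfParams& w, double& fr) {
  double a = w.alpha;
  double erfc_r = std::erfc(a * r);
  double gauss = 2.0 * a / std::sqrt(M_PI) * std::exp(-a * a * r * r);
  double u, fmag;
  if (w.variant == 0) {  // damped shifted force
    u = w.keq * qq * (erfc_r / r - w.e_rc + w.f_rc * (r - w.rc));
    fmag = w.keq * qq * (erfc_r / (r * r) + gauss / r - w.f_rc);
  } else {               // energy shift only
    u = w.keq * qq * (erfc_r / r - w.e_rc);
    fmag = w.keq * qq * (erfc_r / (r * r) + gauss / r);
  }
  fr = fmag / r;  // force on j = fr * dx
  return u;
}

// ---- Oracle extra pair term: sum of Gaussians with cosine envelope ---------
struct ExtraPair {
  int S;
  double rc;
  // per unordered species pair p = pairIndex(a,b): packed Gaussian params
  std::vector< std::vector<double> > A, R0, W;
  bool any;
};

inline int sympair(int a, int b, int S) {
  if (a > b) std::swap(a, b);
  return a * S - a * (a - 1) / 2 + (b - a);
}

inline double extra_pair(double r, const std::vector<double>& A,
                         const std::vector<double>& R0,
                         const std::vector<double>& W,
                         double rc, double& fr) {
  double fcv = fcut(r, rc), dfcv = dfcut(r, rc);
  double g = 0.0, dg = 0.0;
  for (size_t k = 0; k < A.size(); ++k) {
    double t = (r - R0[k]) / W[k];
    double e = A[k] * std::exp(-0.5 * t * t);
    g += e;
    dg += e * (-t / W[k]);
  }
  double u = g * fcv;
  double du = dg * fcv + g * dfcv;
  fr = -du / r;
  return u;
}

// ---- Oracle 3-body term: lambda * sum_{j<k} (cos + 1/3)^2 fc(rij) fc(rik) --
// among particles of one species, centered on each such particle.
struct ExtraTriple {
  bool any;
  double lambda, rc;
  int sp;  // species id
};

// Energy + force accumulation for one central particle of the 3-body oracle
// term: lambda * sum_{j<k} (cos(theta_jik) + 1/3)^2 fc(rij) fc(rik).
// Forces are SUBTRACTED gradients (i.e. proper forces) accumulated into F (3N).
struct TripleNb { int j; double dx[3]; double r; };

inline double triple_center(int ic, const std::vector<TripleNb>& nbrs,
                            double lambda, double rc, double* F) {
  double e = 0.0;
  int n = (int)nbrs.size();
  for (int a = 0; a < n; ++a) {
    double ra = nbrs[a].r;
    double fa = fcut(ra, rc), dfa = dfcut(ra, rc);
    for (int b = a + 1; b < n; ++b) {
      double rb = nbrs[b].r;
      double fb = fcut(rb, rc), dfb = dfcut(rb, rc);
      double dot = 0.0;
      for (int x = 0; x < 3; ++x) dot += nbrs[a].dx[x] * nbrs[b].dx[x];
      double c = dot / (ra * rb);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      double B = c + 1.0 / 3.0;
      double val = lambda * B * B * fa * fb;
      e += val;
      double dval_dc = 2.0 * lambda * B * fa * fb;
      double dval_dra = lambda * B * B * dfa * fb;
      double dval_drb = lambda * B * B * fa * dfb;
      for (int x = 0; x < 3; ++x) {
        double dca = nbrs[b].dx[x] / (ra * rb) - c * nbrs[a].dx[x] / (ra * ra);
        double dcb = nbrs[a].dx[x] / (ra * rb) - c * nbrs[b].dx[x] / (rb * rb);
        double dva = dval_dc * dca + dval_dra * nbrs[a].dx[x] / ra;
        double dvb = dval_dc * dcb + dval_drb * nbrs[b].dx[x] / rb;
        if (F) {
          F[3 * nbrs[a].j + x] -= dva;
          F[3 * nbrs[b].j + x] -= dvb;
          F[3 * ic + x] += dva + dvb;
        }
      }
    }
  }
  return e;
}

// ---- Cubic-Hermite pair table in s = r^2 -----------------------------------
// Standard tabulated-potential machinery: values and exact ds-derivatives at
// uniform s nodes; the evaluated force is the exact gradient of the
// interpolant, so tabulated MD remains energy-consistent. Working in s
// avoids a sqrt per pair.
struct PairTable {
  double s0, ds, inv_ds, smax;
  std::vector<double> v, d;   // value and dv/ds at nodes
  bool active = false;
  // energy at s; fr receives force prefactor so F_j = fr * dx
  // (fr = -(1/r) dv/dr = -2 dv/ds)
  inline double eval(double s, double& fr) const {
    double x = (s - s0) * inv_ds;
    int k = (int)x;
    if (k < 0) k = 0;
    int last = (int)v.size() - 2;
    if (k > last) { fr = 0.0; return 0.0; }
    double t = x - k;
    double t2 = t * t, t3 = t2 * t;
    double h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t;
    double h01 = -2 * t3 + 3 * t2, h11 = t3 - t2;
    double e = h00 * v[k] + h10 * ds * d[k] + h01 * v[k + 1] + h11 * ds * d[k + 1];
    double dh00 = 6 * t2 - 6 * t, dh10 = 3 * t2 - 4 * t + 1;
    double dh01 = -6 * t2 + 6 * t, dh11 = 3 * t2 - 2 * t;
    double dvds = (dh00 * v[k] + dh01 * v[k + 1]) * inv_ds +
                  dh10 * d[k] + dh11 * d[k + 1];
    fr = -2.0 * dvds;
    return e;
  }
};

// ---- Descriptor spec -------------------------------------------------------
struct DescSpec {
  double rc, sigb;
  std::vector<double> centers;
  bool ang;
  std::vector<double> zeta, lam, eta;
  int S;            // species vocabulary size (head/channel space)
  int nrad, nang, P, M;
  std::vector<double> pref;   // 2^(1-zeta), precomputed
  double c0, dc;              // uniform radial grid origin/spacing
  bool uniform;
  void finalize() {
    nrad = (int)centers.size();
    nang = ang ? (int)zeta.size() : 0;
    P = S * (S + 1) / 2;
    M = S * nrad + P * nang;
    pref.clear();
    for (size_t q = 0; q < zeta.size(); ++q)
      pref.push_back(std::pow(2.0, 1.0 - zeta[q]));
    c0 = centers.empty() ? 0.0 : centers[0];
    dc = (nrad > 1) ? centers[1] - centers[0] : 1.0;
    uniform = true;
    for (int k = 0; k < nrad; ++k)
      if (std::fabs(centers[k] - (c0 + k * dc)) > 1e-9 * std::max(1.0, std::fabs(dc)))
        uniform = false;
  }
};

struct Neighbor {
  int j;        // index in full system
  int ch;       // channel species id of j
  double dx[3]; // min-image x_j - x_i
  double r;
};

enum DescMode { FEAT, GDOT, RDOT, FGDOT };  // FGDOT = FEAT + GDOT fused

// radial Gaussian basis support (in units of sigma) and the value shift that
// makes each basis function exactly zero at its support boundary, so pair
// energies are continuous there
static const double RAD_SUPPORT = 6.0;
static const double RAD_SHIFT = 1.522997974471263e-08;  // exp(-6^2/2)

// Core descriptor routine for central atom i with neighbor list nbrs.
// FEAT: write features into d[M].
// GDOT: given coefficients g[M], accumulate sum_m g_m * d(d_m)/d(x_row) into
//       acc (3N array, row-major xyz per atom); central atom index ic.
// RDOT: given rho (3N), accumulate u[M] += sum_rows rho_row * d(d_m)/d(x_row).
inline void desc_core(int ic, const std::vector<Neighbor>& nbrs,
                      const DescSpec& ds, DescMode mode,
                      double* d, const double* g, double* acc,
                      const double* rho, double* u, bool do_radial = true) {
  int n = (int)nbrs.size();
  double support = RAD_SUPPORT * ds.sigb;
  // radial channels (skipped when the caller handles them via pair tables)
  for (int a = 0; do_radial && a < n; ++a) {
    const Neighbor& nb = nbrs[a];
    double r = nb.r;
    double fcv = fcut(r, ds.rc), dfcv = dfcut(r, ds.rc);
    int base = nb.ch * ds.nrad;
    int k0 = 0, k1 = ds.nrad - 1;
    if (ds.uniform && ds.nrad > 1) {
      // only centers within the basis support contribute measurably
      k0 = std::max(0, (int)std::ceil((r - support - ds.c0) / ds.dc));
      k1 = std::min(ds.nrad - 1, (int)std::floor((r + support - ds.c0) / ds.dc));
    }
    double rdot = 0.0;
    if (mode == RDOT)
      for (int x = 0; x < 3; ++x)
        rdot += nb.dx[x] * (rho[3 * nb.j + x] - rho[3 * ic + x]);
    for (int k = k0; k <= k1; ++k) {
      double dcen = r - ds.centers[k];
      if (std::fabs(dcen) > support) continue;
      double t = dcen / ds.sigb;
      double gs = std::exp(-0.5 * t * t);
      double gsv = gs - RAD_SHIFT;
      int m = base + k;
      if (mode == FEAT || mode == FGDOT) d[m] += gsv * fcv;
      if (mode != FEAT) {
        double dval = gs * (-t / ds.sigb) * fcv + gsv * dfcv;  // d/dr
        double cr = dval / r;
        if (mode == GDOT || mode == FGDOT) {
          double c = g[m] * cr;
          for (int x = 0; x < 3; ++x) {
            acc[3 * nb.j + x] += c * nb.dx[x];
            acc[3 * ic + x] -= c * nb.dx[x];
          }
        } else {  // RDOT
          u[m] += cr * rdot;
        }
      }
    }
  }
  if (!ds.ang || n < 2) return;
  int abase = ds.S * ds.nrad;
  for (int a = 0; a < n; ++a) {
    const Neighbor& na = nbrs[a];
    double ra = na.r;
    double fa = fcut(ra, ds.rc), dfa = dfcut(ra, ds.rc);
    for (int b = a + 1; b < n; ++b) {
      const Neighbor& nbn = nbrs[b];
      double rb = nbn.r;
      double fb = fcut(rb, ds.rc), dfb = dfcut(rb, ds.rc);
      double dot = na.dx[0] * nbn.dx[0] + na.dx[1] * nbn.dx[1] + na.dx[2] * nbn.dx[2];
      double c = dot / (ra * rb);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      int p = sympair(na.ch, nbn.ch, ds.S);
      int mb = abase + p * ds.nang;
      // dc/da = b/(ra rb) - c a / ra^2 ; dc/db symmetric
      double dca[3], dcb[3];
      for (int x = 0; x < 3; ++x) {
        dca[x] = nbn.dx[x] / (ra * rb) - c * na.dx[x] / (ra * ra);
        dcb[x] = na.dx[x] / (ra * rb) - c * nbn.dx[x] / (rb * rb);
      }
      // pair-level dot products for RDOT, computed once across functions
      double rc_a = 0.0, rc_b = 0.0, rra = 0.0, rrb = 0.0;
      if (mode == RDOT) {
        for (int x = 0; x < 3; ++x) {
          double da_ = rho[3 * na.j + x] - rho[3 * ic + x];
          double db_ = rho[3 * nbn.j + x] - rho[3 * ic + x];
          rc_a += dca[x] * da_;  rc_b += dcb[x] * db_;
          rra += na.dx[x] / ra * da_;  rrb += nbn.dx[x] / rb * db_;
        }
      }
      // function-level scalars accumulated, vectors applied once per pair
      double Ac = 0.0, Ara = 0.0, Arb = 0.0;
      for (int q = 0; q < ds.nang; ++q) {
        double z = ds.zeta[q], l = ds.lam[q], et = ds.eta[q];
        double pref = ds.pref[q];
        double B = 1.0 + l * c;
        if (B < 0) B = 0;  // guards z non-integer; B in [0,2] otherwise
        // fast paths for the common integer exponents
        double Bz = (z == 1.0) ? B : (z == 2.0) ? B * B : std::pow(B, z);
        double ex = (et > 0) ? std::exp(-et * (ra * ra + rb * rb)) : 1.0;
        double val = pref * Bz * ex * fa * fb;
        int m = mb + q;
        if (mode == FEAT || mode == FGDOT) {
          d[m] += val;
          if (mode == FEAT) continue;
        }
        double Bzm1 = (z == 1.0) ? 1.0 : (z == 2.0) ? B : std::pow(B, z - 1.0);
        double dval_dc = pref * z * l * Bzm1 * ex * fa * fb;
        double dval_dra = -2.0 * et * ra * val + pref * Bz * ex * dfa * fb;
        double dval_drb = -2.0 * et * rb * val + pref * Bz * ex * fa * dfb;
        if (mode == RDOT) {
          u[m] += dval_dc * (rc_a + rc_b) + dval_dra * rra + dval_drb * rrb;
        } else {
          double gm = g[m];
          Ac += gm * dval_dc;  Ara += gm * dval_dra;  Arb += gm * dval_drb;
        }
      }
      if (mode != RDOT && mode != FEAT) {
        for (int x = 0; x < 3; ++x) {
          double dva = Ac * dca[x] + Ara * na.dx[x] / ra;
          double dvb = Ac * dcb[x] + Arb * nbn.dx[x] / rb;
          acc[3 * na.j + x] += dva;
          acc[3 * nbn.j + x] += dvb;
          acc[3 * ic + x] -= dva + dvb;
        }
      }
    }
  }
}

// ---- Correction-model heads ------------------------------------------------
struct HeadParams {
  int H;                      // 0 => linear
  std::vector<double> w;      // linear: length M
  std::vector<double> W1;     // H x M column-major
  std::vector<double> b1, w2; // length H
};

struct ModelSpec {
  DescSpec ds;
  std::vector<HeadParams> heads;   // one per vocabulary species
  std::vector<double> scale;       // length M
  // effective (scale-folded) weights for linear heads; enables a fused
  // single-pass feature+force evaluation since the head gradient is constant
  std::vector< std::vector<double> > weff;
  bool all_linear;
  void finalize_weff() {
    all_linear = true;
    weff.clear();
    for (auto& h : heads) {
      if (h.H != 0) { all_linear = false; weff.push_back({}); continue; }
      std::vector<double> w(h.w.size());
      for (size_t m = 0; m < w.size(); ++m) w[m] = h.w[m] / scale[m];
      weff.push_back(w);
    }
  }
};

// Evaluate atomic energy and d(E_atom)/d(d_raw) for features d (raw).
inline double head_eval(const HeadParams& hp, const std::vector<double>& scale,
                        const double* d, int M, double* gout) {
  if (hp.H == 0) {
    double e = 0.0;
    for (int m = 0; m < M; ++m) {
      double weff = hp.w[m] / scale[m];
      e += weff * d[m];
      gout[m] = weff;
    }
    return e;
  }
  int H = hp.H;
  std::vector<double> t(H);
  double e = 0.0;
  for (int h = 0; h < H; ++h) {
    double z = hp.b1[h];
    for (int m = 0; m < M; ++m) z += hp.W1[h + H * m] * (d[m] / scale[m]);
    t[h] = std::tanh(z);
    e += hp.w2[h] * t[h];
  }
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    for (int h = 0; h < H; ++h) s += hp.W1[h + H * m] * hp.w2[h] * (1.0 - t[h] * t[h]);
    gout[m] = s / scale[m];
  }
  return e;
}

}  // namespace ionsolv

#endif
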