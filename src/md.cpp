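// Implicit-solvent MD: BAOAB-split Langevin dynamics (velocity Verlet in the
// gamma -> 0 limit) with a skin-buffered Verlet pair list, frozen scaffolds,
// periodic wrapping with image counters, and forces from the physics prior
// plus optional oracle extra terms and/or a trained correction model.
#include "common.h"
#include "parse.h"
using namespace Rcpp;
using namespace ionsolv;

namespace {

struct ForceCtx {
  int N, S;
  LJParams lj;
  WolfParams wolf;
  bool do_lj, do_coul;
  double wolf_self;
  ExtraPair ep;
  ExtraTriple et;
  bool has_model;
  ModelSpec ms;
  std::vector<int> spid, chid;
  std::vector<char> mlvis;
  std::vector<double> q;
  double bx[3];
  double rmax, skin, rlist2;
  // pair list state
  std::vector<int> pi, pj;
  std::vector<double> pos_build;
  // scratch
  std::vector< std::vector<Neighbor> > mlnb;
  std::vector< std::vector<TripleNb> > tbnb;
  std::vector<double> acc, dbuf, gbuf;

  std::vector<char> mobile;

  // tabulated pair kernels (s = r^2 cubic Hermite); built once per run
  bool use_tables = false;
  double tab_s0 = 0.0016;                 // analytic fallback below 0.04 nm
  std::vector<PairTable> ptab;            // LJ + oracle extra, per spid pair
  PairTable ktab;                         // Wolf kernel (scaled by keq q_i q_j)
  std::vector<PairTable> mtab;            // linear-model radial, per chid pair
  bool ml_tab = false;

  void build_tables(int n_nodes) {
    double rml = has_model ? ms.ds.rc : 0.0;
    ml_tab = has_model && ms.all_linear;
    // per-species-pair LJ + extra
    int P = S * (S + 1) / 2;
    ptab.assign(P, PairTable());
    for (int a = 0; a < S; ++a) for (int b = a; b < S; ++b) {
      int p = sympair(a, b, S);
      double rmaxp = do_lj ? lj.rc : 0.0;
      bool has_ep = ep.any && !ep.A[p].empty();
      if (has_ep) rmaxp = std::max(rmaxp, ep.rc);
      if (rmaxp <= 0) continue;
      PairTable& T = ptab[p];
      T.active = true;
      T.s0 = tab_s0; T.smax = rmaxp * rmaxp;
      T.ds = (T.smax - T.s0) / (n_nodes - 1);
      T.inv_ds = 1.0 / T.ds;
      T.v.resize(n_nodes); T.d.resize(n_nodes);
      for (int k = 0; k < n_nodes; ++k) {
        double s = T.s0 + k * T.ds, r = std::sqrt(s);
        double vv = 0.0, dvdr = 0.0;
        if (do_lj && r < lj.rc) {
          double fr;
          vv += lj_pair(s, lj.sg(a, b), lj.ep(a, b), lj.rc, lj.shift, fr);
          dvdr += -fr * r;
        }
        if (has_ep && r < ep.rc) {
          double fr;
          vv += extra_pair(r, ep.A[p], ep.R0[p], ep.W[p], ep.rc, fr);
          dvdr += -fr * r;
        }
        T.v[k] = vv;
        T.d[k] = dvdr / (2.0 * r);
      }
    }
    // Wolf kernel K(r): energy = keq * q_i q_j * K
    if (do_coul) {
      PairTable& T = ktab;
      T.active = true;
      T.s0 = tab_s0; T.smax = wolf.rc * wolf.rc;
      T.ds = (T.smax - T.s0) / (n_nodes - 1);
      T.inv_ds = 1.0 / T.ds;
      T.v.resize(n_nodes); T.d.resize(n_nodes);
      for (int k = 0; k < n_nodes; ++k) {
        double s = T.s0 + k * T.ds, r = std::sqrt(s);
        double erfc_r = std::erfc(wolf.alpha * r);
        double gauss = 2.0 * wolf.alpha / std::sqrt(M_PI) *
          std::exp(-wolf.alpha * wolf.alpha * r * r);
        double vv, dvdr;
        if (wolf.variant == 0) {
          vv = erfc_r / r - wolf.e_rc + wolf.f_rc * (r - wolf.rc);
          dvdr = -(erfc_r / (r * r) + gauss / r) + wolf.f_rc;
        } else {
          vv = erfc_r / r - wolf.e_rc;
          dvdr = -(erfc_r / (r * r) + gauss / r);
        }
        T.v[k] = vv;
        T.d[k] = dvdr / (2.0 * r);
      }
    }
    // linear-model radial channels, per unordered chid pair; matches the
    // descriptor's basis-support truncation so tabulated and exact model
    // paths agree to interpolation error
    if (ml_tab && rml > 0) {
      const DescSpec& ds = ms.ds;
      int Sml = (int)ms.heads.size();
      int Pm = Sml * (Sml + 1) / 2;
      mtab.assign(Pm, PairTable());
      double support = RAD_SUPPORT * ds.sigb;
      for (int a = 0; a < Sml; ++a) for (int b = a; b < Sml; ++b) {
        PairTable& T = mtab[sympair(a, b, Sml)];
        T.active = true;
        T.s0 = tab_s0; T.smax = rml * rml;
        T.ds = (T.smax - T.s0) / (n_nodes - 1);
        T.inv_ds = 1.0 / T.ds;
        T.v.resize(n_nodes); T.d.resize(n_nodes);
        for (int k = 0; k < n_nodes; ++k) {
          double s = T.s0 + k * T.ds, r = std::sqrt(s);
          double fcv = fcut(r, ds.rc), dfcv = dfcut(r, ds.rc);
          double vv = 0.0, dvdr = 0.0;
          for (int c = 0; c < ds.nrad; ++c) {
            double dcen = r - ds.centers[c];
            if (std::fabs(dcen) > support) continue;
            double t = dcen / ds.sigb;
            double gs = std::exp(-0.5 * t * t);
            double gsv = gs - RAD_SHIFT;
            double w = ms.weff[a][b * ds.nrad + c] +
                       ms.weff[b][a * ds.nrad + c];
            vv += w * gsv * fcv;
            dvdr += w * (gs * (-t / ds.sigb) * fcv + gsv * dfcv);
          }
          T.v[k] = vv;
          T.d[k] = dvdr / (2.0 * r);
        }
      }
    }
    use_tables = true;
  }

  void build_pairs(const std::vector<double>& x) {
    pi.clear(); pj.clear();
    double rl = rmax + skin;
    rlist2 = rl * rl;
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (!mobile[i] && !mobile[j]) continue;
        double dx[3] = {x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2]};
        minimg3(dx, bx);
        double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
        if (r2 < rlist2) { pi.push_back(i); pj.push_back(j); }
      }
    pos_build = x;
  }

  bool needs_rebuild(const std::vector<double>& x) const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      double dx[3] = {x[3*i]-pos_build[3*i], x[3*i+1]-pos_build[3*i+1],
                      x[3*i+2]-pos_build[3*i+2]};
      minimg3(const_cast<double*>(dx), bx);
      if (dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2] > lim2) return true;
    }
    return false;
  }

  double compute(const std::vector<double>& x, std::vector<double>& F, int step) {
    std::fill(F.begin(), F.end(), 0.0);
    double epot = wolf_self;
    bool tab = use_tables;
    bool ml_via_tab = tab && ml_tab;
    // neighbor vectors are needed for the angular invariants (and for any
    // non-linear head, which bypasses the tables)
    bool want_ml = has_model && (!ml_via_tab || ms.ds.ang);
    bool want_tb = et.any;
    double rml2 = has_model ? ms.ds.rc * ms.ds.rc : 0.0;
    double rtb2 = want_tb ? et.rc * et.rc : 0.0;
    int Sml = has_model ? (int)ms.heads.size() : 0;
    if (want_ml) for (auto& v : mlnb) v.clear();
    if (want_tb) for (auto& v : tbnb) v.clear();
    double rclj2 = lj.rc * lj.rc, rccl2 = wolf.rc * wolf.rc;
    double rcep2 = ep.any ? ep.rc * ep.rc : 0.0;
    for (size_t k = 0; k < pi.size(); ++k) {
      int i = pi[k], j = pj[k];
      double dx[3] = {x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2]};
      minimg3(dx, bx);
      double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
      if (r2 >= rlist2) continue;
      if (r2 < OVERLAP_FLOOR * OVERLAP_FLOOR)
        stop("particle overlap below hard floor at MD step %d (atoms %d, %d)",
             step, i + 1, j + 1);
      double fr;
      double qq = q[i] * q[j];
      if (tab && r2 >= tab_s0) {
        const PairTable& T = ptab[sympair(spid[i], spid[j], S)];
        if (T.active && r2 < T.smax) {
          epot += T.eval(r2, fr);
          for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
        }
        if (do_coul && qq != 0.0 && r2 < rccl2) {
          double kq = wolf.keq * qq;
          epot += kq * ktab.eval(r2, fr);
          fr *= kq;
          for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
        }
        if (ml_via_tab && r2 < rml2 && mlvis[i] && mlvis[j]) {
          const PairTable& M = mtab[sympair(chid[i], chid[j], Sml)];
          if (M.active) {
            epot += M.eval(r2, fr);
            for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
          }
        }
      } else {
        if (do_lj && r2 < rclj2) {
          epot += lj_pair(r2, lj.sg(spid[i], spid[j]), lj.ep(spid[i], spid[j]),
                          lj.rc, lj.shift, fr);
          for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
        }
        if (do_coul && qq != 0.0 && r2 < rccl2) {
          double r = std::sqrt(r2);
          epot += wolf_pair(r, qq, wolf, fr);
          for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
        }
        if (ep.any && r2 < rcep2) {
          int p = sympair(spid[i], spid[j], S);
          if (!ep.A[p].empty()) {
            double r = std::sqrt(r2);
            epot += extra_pair(r, ep.A[p], ep.R0[p], ep.W[p], ep.rc, fr);
            for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
          }
        }
        if (tab && ml_via_tab && r2 < rml2 && mlvis[i] && mlvis[j]) {
          // below the table floor: evaluate the radial channels analytically
          const DescSpec& dsp = ms.ds;
          double r = std::sqrt(r2);
          double fcv = fcut(r, dsp.rc), dfcv = dfcut(r, dsp.rc);
          double support = RAD_SUPPORT * dsp.sigb;
          double vv = 0.0, dvdr = 0.0;
          int a = chid[i], b = chid[j];
          for (int c = 0; c < dsp.nrad; ++c) {
            double dcen = r - dsp.centers[c];
            if (std::fabs(dcen) > support) continue;
            double t = dcen / dsp.sigb;
            double gs = std::exp(-0.5 * t * t);
            double gsv = gs - RAD_SHIFT;
            double w = ms.weff[a][b * dsp.nrad + c] + ms.weff[b][a * dsp.nrad + c];
            vv += w * gsv * fcv;
            dvdr += w * (gs * (-t / dsp.sigb) * fcv + gsv * dfcv);
          }
          epot += vv;
          fr = -dvdr / r;
          for (int c = 0; c < 3; ++c) { F[3*j+c] += fr * dx[c]; F[3*i+c] -= fr * dx[c]; }
        }
      }
      if (want_ml && r2 < rml2 && mlvis[i] && mlvis[j]) {
        Neighbor na, nb;
        double r = std::sqrt(r2);
        na.j = j; na.ch = chid[j]; na.r = r;
        nb.j = i; nb.ch = chid[i]; nb.r = r;
        for (int c = 0; c < 3; ++c) { na.dx[c] = dx[c]; nb.dx[c] = -dx[c]; }
        mlnb[i].push_back(na);
        mlnb[j].push_back(nb);
      }
      if (want_tb && r2 < rtb2 && spid[i] == et.sp && spid[j] == et.sp) {
        TripleNb ta, tb;
        double r = std::sqrt(r2);
        ta.j = j; ta.r = r; tb.j = i; tb.r = r;
        for (int c = 0; c < 3; ++c) { ta.dx[c] = dx[c]; tb.dx[c] = -dx[c]; }
        tbnb[i].push_back(ta);
        tbnb[j].push_back(tb);
      }
    }
    if (want_tb) {
      for (int i = 0; i < N; ++i) {
        if (spid[i] != et.sp || tbnb[i].empty()) continue;
        epot += triple_center(i, tbnb[i], et.lambda, et.rc, F.data());
      }
    }
    if (want_ml) {
      std::fill(acc.begin(), acc.end(), 0.0);
      const DescSpec& ds = ms.ds;
      for (int i = 0; i < N; ++i) {
        if (!mlvis[i]) continue;
        std::fill(dbuf.begin(), dbuf.end(), 0.0);
        if (ms.all_linear) {
          // with tables active the radial channels were already summed as
          // pair terms; only the angular invariants remain here
          const std::vector<double>& w = ms.weff[chid[i]];
          desc_core(i, mlnb[i], ds, FGDOT, dbuf.data(), w.data(), acc.data(),
                    nullptr, nullptr, /*do_radial=*/!ml_via_tab);
          double ei = 0.0;
          for (int m = 0; m < ds.M; ++m) ei += w[m] * dbuf[m];
          epot += ei;
        } else {
          desc_core(i, mlnb[i], ds, FEAT, dbuf.data(), nullptr, nullptr, nullptr, nullptr);
          epot += head_eval(ms.heads[chid[i]], ms.scale, dbuf.data(), ds.M, gbuf.data());
          desc_core(i, mlnb[i], ds, GDOT, nullptr, gbuf.data(), acc.data(), nullptr, nullptr);
        }
      }
      for (int i = 0; i < 3 * N; ++i) F[i] -= acc[i];
    }
    return epot;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix vel0, IntegerMatrix img0,
                IntegerVector spid, IntegerVector chid, NumericVector q,
                NumericVector mass, NumericVector box, LogicalVector mobile,
                LogicalVector mlvis, List prior, SEXP extra, SEXP model,
                double dt, int nsteps, int stride, int log_stride,
                double gamma, double temperature, double skin,
                bool save_vel, bool save_forces, bool tabulate) {
  int N = pos0.nrow();
  ForceCtx fc;
  fc.N = N;
  NumericMatrix sig = prior["sig"], eps = prior["eps"];
  fc.S = sig.nrow();
  fc.lj.S = fc.S;
  fc.lj.sig.assign(sig.begin(), sig.end());
  fc.lj.eps.assign(eps.begin(), eps.end());
  fc.lj.rc = as<double>(prior["rc_lj"]);
  fc.lj.rc2 = fc.lj.rc * fc.lj.rc;
  fc.lj.shift = as<bool>(prior["lj_shift"]);
  fc.wolf.alpha = as<double>(prior["alpha"]);
  fc.wolf.rc = as<double>(prior["rc_coul"]);
  fc.wolf.keq = KE_COUL / as<double>(prior["eps_r"]);
  fc.wolf.variant = as<int>(prior["wolf_variant"]);
  fc.wolf.setup();
  fc.do_lj = as<bool>(prior["do_lj"]);
  fc.do_coul = as<bool>(prior["do_coul"]);
  fc.spid.assign(spid.begin(), spid.end());
  fc.chid.assign(chid.begin(), chid.end());
  fc.q.assign(q.begin(), q.end());
  fc.mlvis.assign(N, 0);
  for (int i = 0; i < N; ++i) fc.mlvis[i] = mlvis[i] ? 1 : 0;
  fc.mobile.assign(N, 0);
  for (int i = 0; i < N; ++i) fc.mobile[i] = mobile[i] ? 1 : 0;
  for (int c = 0; c < 3; ++c) fc.bx[c] = box[c];
  parse_extra(extra, fc.S, fc.ep, fc.et);
  fc.has_model = !Rf_isNull(model);
  double rmax = fc.lj.rc;
  if (fc.do_coul) rmax = std::max(rmax, fc.wolf.rc);
  if (fc.ep.any) rmax = std::max(rmax, fc.ep.rc);
  if (fc.et.any) rmax = std::max(rmax, fc.et.rc);
  if (fc.has_model) {
    fc.ms = parse_model(model);
    rmax = std::max(rmax, fc.ms.ds.rc);
    fc.mlnb.assign(N, std::vector<Neighbor>());
    fc.acc.assign(3 * N, 0.0);
    fc.dbuf.assign(fc.ms.ds.M, 0.0);
    fc.gbuf.assign(fc.ms.ds.M, 0.0);
  }
  if (fc.et.any) fc.tbnb.assign(N, std::vector<TripleNb>());
  fc.rmax = rmax;
  fc.skin = skin;
  double minL = std::min(box[0], std::min(box[1], box[2]));
  if (rmax + skin > 0.5 * minL + 1e-12)
    stop("interaction range + skin (%g nm) exceeds half the smallest box edge (%g nm)",
         rmax + skin, 0.5 * minL);
  double sq = 0.0;
  for (int i = 0; i < N; ++i) sq += q[i] * q[i];
  fc.wolf_self = fc.do_coul ? fc.wolf.self_prefactor() * sq : 0.0;
  if (tabulate) fc.build_tables(6000);

  std::vector<double> x(3 * N), v(3 * N), F(3 * N);
  std::vector<int> img(3 * N);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3*i+c] = pos0(i, c);
      v[3*i+c] = vel0(i, c);
      img[3*i+c] = img0(i, c);
    }
  fc.build_pairs(x);
  double epot = fc.compute(x, F, 0);

  int nmob = 0;
  for (int i = 0; i < N; ++i) if (mobile[i]) ++nmob;
  int ndof = (gamma > 0) ? 3 * nmob : std::max(3 * nmob - 3, 3);
  bool thermo = gamma > 0;
  std::vector<double> c1(N), c2(N);
  for (int i = 0; i < N; ++i) {
    if (thermo) {
      c1[i] = std::exp(-gamma * dt);
      c2[i] = std::sqrt(KB * temperature / mass[i] * (1.0 - c1[i] * c1[i]));
    } else { c1[i] = 1.0; c2[i] = 0.0; }
  }

  int nframes = nsteps / stride + 1;
  NumericVector fpos(3 * N * nframes), ftime(nframes);
  IntegerVector fimg(3 * N * nframes);
  NumericVector fvel(save_vel ? 3 * N * nframes : 0);
  NumericVector ffor(save_forces ? 3 * N * nframes : 0);
  int nlog = nsteps / log_stride + 1;
  NumericVector lstep(nlog), ltime(nlog), lepot(nlog), lekin(nlog), ltemp(nlog);

  auto ekin_of = [&](void) {
    double e = 0.0;
    for (int i = 0; i < N; ++i) {
      if (!mobile[i]) continue;
      e += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    }
    return e;
  };
  auto save_frame = [&](int fr, double t) {
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) {
        fpos[(size_t)fr * 3 * N + 3 * i + c] = x[3*i+c];
        fimg[(size_t)fr * 3 * N + 3 * i + c] = img[3*i+c];
        if (save_vel) fvel[(size_t)fr * 3 * N + 3 * i + c] = v[3*i+c];
        if (save_forces) ffor[(size_t)fr * 3 * N + 3 * i + c] = F[3*i+c];
      }
    ftime[fr] = t;
  };
  auto save_log = [&](int lg, int step, double t) {
    double ek = ekin_of();
    lstep[lg] = step; ltime[lg] = t; lepot[lg] = epot; lekin[lg] = ek;
    ltemp[lg] = 2.0 * ek / (KB * ndof);
  };
  save_frame(0, 0.0);
  save_log(0, 0, 0.0);
  int fr = 0, lg = 0;

  for (int step = 1; step <= nsteps; ++step) {
    // B half-kick
    for (int i = 0; i < N; ++i) {
      if (!mobile[i]) continue;
      double hdtm = 0.5 * dt / mass[i];
      for (int c = 0; c < 3; ++c) v[3*i+c] += hdtm * F[3*i+c];
    }
    // A half-drift
    for (int i = 0; i < N; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) x[3*i+c] += 0.5 * dt * v[3*i+c];
    }
    // O (Ornstein-Uhlenbeck)
    if (thermo) {
      for (int i = 0; i < N; ++i) {
        if (!mobile[i]) continue;
        for (int c = 0; c < 3; ++c)
          v[3*i+c] = c1[i] * v[3*i+c] + c2[i] * norm_rand();
      }
    }
    // A half-drift
    for (int i = 0; i < N; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) x[3*i+c] += 0.5 * dt * v[3*i+c];
    }
    // wrap into [0, L), tracking images
    for (int i = 0; i < N; ++i) {
      if (!mobile[i]) continue;
      for (int c = 0; c < 3; ++c) {
        double L = fc.bx[c];
        while (x[3*i+c] >= L) { x[3*i+c] -= L; img[3*i+c] += 1; }
        while (x[3*i+c] < 0.0) { x[3*i+c] += L; img[3*i+c] -= 1; }
      }
    }
    if (fc.needs_rebuild(x)) fc.build_pairs(x);
    epot = fc.compute(x, F, step);
    if (!std::isfinite(epot))
      stop("non-finite potential energy at MD step %d", step);
    // B half-kick with new forces
    for (int i = 0; i < N; ++i) {
      if (!mobile[i]) continue;
      double hdtm = 0.5 * dt / mass[i];
      for (int c = 0; c < 3; ++c) v[3*i+c] += hdtm * F[3*i+c];
    }
    if (step % stride == 0) save_frame(++fr, step * dt);
    if (step % log_stride == 0) save_log(++lg, step, step * dt);
  }

  fpos.attr("dim") = IntegerVector::create(3, N, nframes);
  fimg.attr("dim") = IntegerVector::create(3, N, nframes);
  if (save_vel) fvel.attr("dim") = IntegerVector::create(3, N, nframes);
  if (save_forces) ffor.attr("dim") = IntegerVector::create(3, N, nframes);
  NumericMatrix vfin(N, 3);
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) vfin(i, c) = v[3*i+c];
  return List::create(
    _["pos"] = fpos, _["img"] = fimg, _["vel"] = fvel, _["forces"] = ffor,
    _["times"] = ftime,
    _["log"] = List::create(_["step"] = lstep, _["time"] = ltime,
                            _["epot"] = lepot, _["ekin"] = lekin,
                            _["temp"] = ltemp),
    _["final_vel"] = vfin, _["ndof"] = ndof);
}
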