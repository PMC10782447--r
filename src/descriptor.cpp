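// Invariant atomic-environment descriptors (radial Gaussian basis +
// Behler-style angular invariants), per-species parametric heads, analytic
// forces, and the parameter gradient of the force-matching loss.
#include "common.h"
#include "parse.h"
using namespace Rcpp;
using namespace ionsolv;

// Gather ml-visible neighbors of atom i within rc (minimum image).
static void gather_nbrs(const NumericMatrix& pos, const IntegerVector& chid,
                        const LogicalVector& mlvis, const double* bx,
                        double rc, int i, std::vector<Neighbor>& nbrs) {
  nbrs.clear();
  int N = pos.nrow();
  double rc2 = rc * rc;
  for (int j = 0; j < N; ++j) {
    if (j == i || !mlvis[j]) continue;
    Neighbor nb;
    nb.j = j; nb.ch = chid[j];
    nb.dx[0] = pos(j,0)-pos(i,0); nb.dx[1] = pos(j,1)-pos(i,1); nb.dx[2] = pos(j,2)-pos(i,2);
    minimg3(nb.dx, bx);
    double r2 = nb.dx[0]*nb.dx[0]+nb.dx[1]*nb.dx[1]+nb.dx[2]*nb.dx[2];
    if (r2 >= rc2 || r2 == 0.0) continue;
    nb.r = std::sqrt(r2);
    nbrs.push_back(nb);
  }
}

// [[Rcpp::export]]
NumericVector cpp_descriptor(NumericMatrix pos, IntegerVector chid,
                             LogicalVector mlvis, NumericVector box,
                             int i0, List desc) {
  DescSpec ds = parse_desc(desc);
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<Neighbor> nbrs;
  gather_nbrs(pos, chid, mlvis, bx, ds.rc, i0, nbrs);
  NumericVector d(ds.M);
  desc_core(i0, nbrs, ds, FEAT, REAL(d), nullptr, nullptr, nullptr, nullptr);
  return d;
}

// [[Rcpp::export]]
List cpp_model_ef(NumericMatrix pos, IntegerVector chid, LogicalVector mlvis,
                  NumericVector box, List model, bool want_forces) {
  ModelSpec ms = parse_model(model);
  const DescSpec& ds = ms.ds;
  int N = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  std::vector<double> acc(3 * N, 0.0);
  std::vector<double> d(ds.M), g(ds.M);
  NumericVector eat(N);
  double e = 0.0;
  std::vector<Neighbor> nbrs;
  for (int i = 0; i < N; ++i) {
    if (!mlvis[i]) continue;
    gather_nbrs(pos, chid, mlvis, bx, ds.rc, i, nbrs);
    std::fill(d.begin(), d.end(), 0.0);
    double ei;
    if (want_forces && ms.all_linear) {
      // fused single pass: linear-head gradient is constant
      const std::vector<double>& w = ms.weff[chid[i]];
      desc_core(i, nbrs, ds, FGDOT, d.data(), w.data(), acc.data(),
                nullptr, nullptr);
      ei = 0.0;
      for (int m = 0; m < ds.M; ++m) ei += w[m] * d[m];
    } else {
      desc_core(i, nbrs, ds, FEAT, d.data(), nullptr, nullptr, nullptr, nullptr);
      ei = head_eval(ms.heads[chid[i]], ms.scale, d.data(), ds.M, g.data());
      if (want_forces)
        desc_core(i, nbrs, ds, GDOT, nullptr, g.data(), acc.data(), nullptr, nullptr);
    }
    eat[i] = ei;
    e += ei;
  }
  NumericMatrix F(N, 3);
  if (want_forces)
    for (int i = 0; i < N; ++i)
      for (int x = 0; x < 3; ++x) F(i, x) = -acc[3 * i + x];
  return List::create(_["energy"] = e, _["atomic_energies"] = eat, _["forces"] = F);
}

// Force-matching loss (sum of squared residuals over target components) and
// its parameter gradient, over a batch of configurations.
// Each config: list(pos, chid, mlvis, box, target (N x 3), has_target (lgl N))
// [[Rcpp::export]]
List cpp_fm_loss_grad(List configs, List model, bool want_grad) {
  ModelSpec ms = parse_model(model);
  const DescSpec& ds = ms.ds;
  int M = ds.M;
  int S = (int)ms.heads.size();
  // gradient accumulators mirroring head shapes
  std::vector< std::vector<double> > gw(S), gW1(S), gb1(S), gw2(S);
  for (int s = 0; s < S; ++s) {
    if (ms.heads[s].H == 0) gw[s].assign(M, 0.0);
    else {
      gW1[s].assign(ms.heads[s].H * M, 0.0);
      gb1[s].assign(ms.heads[s].H, 0.0);
      gw2[s].assign(ms.heads[s].H, 0.0);
    }
  }
  double loss = 0.0;
  long ncomp = 0;
  std::vector<Neighbor> nbrs;
  for (int ic = 0; ic < configs.size(); ++ic) {
    List cfg = configs[ic];
    NumericMatrix pos = cfg["pos"];
    IntegerVector chid = cfg["chid"];
    LogicalVector mlvis = cfg["mlvis"];
    NumericVector box = cfg["box"];
    NumericMatrix target = cfg["target"];
    LogicalVector hastg = cfg["has_target"];
    int N = pos.nrow();
    double bx[3] = {box[0], box[1], box[2]};
    std::vector<int> mlidx;
    for (int i = 0; i < N; ++i) if (mlvis[i]) mlidx.push_back(i);
    int nml = (int)mlidx.size();
    // pass 1: descriptors, head gradients, predicted forces
    std::vector<double> dall((size_t)nml * M), gall((size_t)nml * M);
    std::vector< std::vector<Neighbor> > nball(nml);
    std::vector<double> acc(3 * N, 0.0);
    for (int a = 0; a < nml; ++a) {
      int i = mlidx[a];
      gather_nbrs(pos, chid, mlvis, bx, ds.rc, i, nball[a]);
      double* d = &dall[(size_t)a * M];
      double* g = &gall[(size_t)a * M];
      std::fill(d, d + M, 0.0);
      desc_core(i, nball[a], ds, FEAT, d, nullptr, nullptr, nullptr, nullptr);
      head_eval(ms.heads[chid[i]], ms.scale, d, M, g);
      desc_core(i, nball[a], ds, GDOT, nullptr, g, acc.data(), nullptr, nullptr);
    }
    // residual rho = F_pred - target on target rows
    std::vector<double> rho(3 * N, 0.0);
    for (int i = 0; i < N; ++i) {
      if (!hastg[i]) continue;
      for (int x = 0; x < 3; ++x) {
        double r = -acc[3 * i + x] - target(i, x);
        rho[3 * i + x] = r;
        loss += r * r;
        ++ncomp;
      }
    }
    if (!want_grad) continue;
    // pass 2: u_i = J_i^T rho, chain into head parameters
    std::vector<double> u(M);
    for (int a = 0; a < nml; ++a) {
      int i = mlidx[a];
      std::fill(u.begin(), u.end(), 0.0);
      desc_core(i, nball[a], ds, RDOT, nullptr, nullptr, nullptr, rho.data(), u.data());
      int s = chid[i];
      const HeadParams& hp = ms.heads[s];
      if (hp.H == 0) {
        for (int m = 0; m < M; ++m) gw[s][m] += -2.0 * u[m] / ms.scale[m];
      } else {
        int H = hp.H;
        const double* d = &dall[(size_t)a * M];
        std::vector<double> dsc(M), ut(M), t(H), av(H, 0.0);
        for (int m = 0; m < M; ++m) {
          dsc[m] = d[m] / ms.scale[m];
          ut[m] = u[m] / ms.scale[m];
        }
        for (int h = 0; h < H; ++h) {
          double z = hp.b1[h];
          for (int m = 0; m < M; ++m) z += hp.W1[h + H * m] * dsc[m];
          t[h] = std::tanh(z);
        }
        for (int h = 0; h < H; ++h)
          for (int m = 0; m < M; ++m) av[h] += hp.W1[h + H * m] * ut[m];
        for (int h = 0; h < H; ++h) {
          double sp = 1.0 - t[h] * t[h];
          double spp = -2.0 * t[h] * sp;
          gw2[s][h] += -2.0 * av[h] * sp;
          gb1[s][h] += -2.0 * av[h] * hp.w2[h] * spp;
          for (int m = 0; m < M; ++m)
            gW1[s][h + H * m] += -2.0 * hp.w2[h] *
              (ut[m] * sp + av[h] * spp * dsc[m]);
        }
      }
    }
  }
  List grads(S);
  if (want_grad) {
    for (int s = 0; s < S; ++s) {
      if (ms.heads[s].H == 0) {
        grads[s] = List::create(_["w"] = NumericVector(gw[s].begin(), gw[s].end()));
      } else {
        int H = ms.heads[s].H;
        NumericMatrix W1g(H, M);
        std::copy(gW1[s].begin(), gW1[s].end(), W1g.begin());
        grads[s] = List::create(_["W1"] = W1g,
                                _["b1"] = NumericVector(gb1[s].begin(), gb1[s].end()),
                                _["w2"] = NumericVector(gw2[s].begin(), gw2[s].end()));
      }
    }
  }
  return List::create(_["loss_sum"] = loss, _["n_comp"] = (double)ncomp,
                      _["grads"] = grads);
}
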