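// Brute-force O(N^2) evaluators for the physics prior and the oracle extra
// terms. These are the reference path for single configurations (dataset
// construction, gradient checks); the MD engine has its own pair-list path,
// cross-checked against these in the test suite.
#include "common.h"
#include "parse.h"
using namespace Rcpp;
using namespace ionsolv;

// [[Rcpp::export]]
List cpp_prior_ef(NumericMatrix pos, IntegerVector spid, NumericVector q,
                  NumericVector box, NumericMatrix sig, NumericMatrix eps,
                  double rc_lj, double rc_coul, double alpha, double eps_r,
                  bool lj_shift, int wolf_variant, bool do_lj, bool do_coul,
                  LogicalVector mobile) {
  int N = pos.nrow();
  int S = sig.nrow();
  LJParams lj;
  lj.S = S; lj.rc = rc_lj; lj.rc2 = rc_lj * rc_lj; lj.shift = lj_shift;
  lj.sig.assign(sig.begin(), sig.end());
  lj.eps.assign(eps.begin(), eps.end());
  WolfParams w;
  w.alpha = alpha; w.rc = rc_coul; w.keq = KE_COUL / eps_r; w.variant = wolf_variant;
  w.setup();
  double bx[3] = {box[0], box[1], box[2]};
  NumericMatrix F(N, 3);
  double e_lj = 0.0, e_coul = 0.0;
  double rc2max = std::max(rc_lj, rc_coul); rc2max *= rc2max;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      if (!mobile[i] && !mobile[j]) continue;  // rigid-scaffold internal pairs excluded
      double dx[3] = {pos(j,0) - pos(i,0), pos(j,1) - pos(i,1), pos(j,2) - pos(i,2)};
      minimg3(dx, bx);
      double r2 = dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
      if (r2 > rc2max) continue;
      if (r2 < OVERLAP_FLOOR * OVERLAP_FLOOR)
        stop("particle overlap below hard floor between atoms %d and %d (r = %g nm)",
             i + 1, j + 1, std::sqrt(r2));
      double fr = 0.0;
      if (do_lj && r2 < lj.rc2) {
        double e = lj_pair(r2, lj.sg(spid[i], spid[j]), lj.ep(spid[i], spid[j]),
                           rc_lj, lj_shift, fr);
        e_lj += e;
        for (int x = 0; x < 3; ++x) { F(j,x) += fr * dx[x]; F(i,x) -= fr * dx[x]; }
      }
      double qq = q[i] * q[j];
      if (do_coul && qq != 0.0 && r2 < rc_coul * rc_coul) {
        double r = std::sqrt(r2);
        double e = wolf_pair(r, qq, w, fr);
        e_coul += e;
        for (int x = 0; x < 3; ++x) { F(j,x) += fr * dx[x]; F(i,x) -= fr * dx[x]; }
      }
    }
  }
  if (do_coul) {
    double sq = 0.0;
    for (int i = 0; i < N; ++i) sq += q[i] * q[i];
    e_coul += w.self_prefactor() * sq;
  }
  return List::create(_["e_lj"] = e_lj, _["e_coul"] = e_coul, _["forces"] = F);
}

// [[Rcpp::export]]
List cpp_extra_ef(NumericMatrix pos, IntegerVector spid, NumericVector box,
                  SEXP extra, int n_species, LogicalVector mobile) {
  int N = pos.nrow();
  ExtraPair ep; ExtraTriple et;
  parse_extra(extra, n_species, ep, et);
  double bx[3] = {box[0], box[1], box[2]};
  NumericMatrix F(N, 3);
  double e = 0.0;
  if (ep.any) {
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        if (!mobile[i] && !mobile[j]) continue;
        int p = sympair(spid[i], spid[j], n_species);
        if (ep.A[p].empty()) continue;
        double dx[3] = {pos(j,0)-pos(i,0), pos(j,1)-pos(i,1), pos(j,2)-pos(i,2)};
        minimg3(dx, bx);
        double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
        if (r2 >= ep.rc * ep.rc) continue;
        double r = std::sqrt(r2), fr;
        e += extra_pair(r, ep.A[p], ep.R0[p], ep.W[p], ep.rc, fr);
        for (int x = 0; x < 3; ++x) { F(j,x) += fr * dx[x]; F(i,x) -= fr * dx[x]; }
      }
    }
  }
  if (et.any) {
    std::vector<double> Fv(3 * N, 0.0);
    for (int i = 0; i < N; ++i) {
      if (spid[i] != et.sp) continue;
      std::vector<TripleNb> nbrs;
      for (int j = 0; j < N; ++j) {
        if (j == i || spid[j] != et.sp) continue;
        TripleNb nb;
        nb.j = j;
        nb.dx[0] = pos(j,0)-pos(i,0); nb.dx[1] = pos(j,1)-pos(i,1); nb.dx[2] = pos(j,2)-pos(i,2);
        minimg3(nb.dx, bx);
        double r2 = nb.dx[0]*nb.dx[0]+nb.dx[1]*nb.dx[1]+nb.dx[2]*nb.dx[2];
        if (r2 >= et.rc * et.rc) continue;
        nb.r = std::sqrt(r2);
        nbrs.push_back(nb);
      }
      e += triple_center(i, nbrs, et.lambda, et.rc, Fv.data());
    }
    for (int i = 0; i < N; ++i)
      for (int x = 0; x < 3; ++x) F(i,x) += Fv[3*i+x];
  }
  return List::create(_["energy"] = e, _["forces"] = F);
}

// [[Rcpp::export]]
IntegerMatrix cpp_pairs_within(NumericMatrix pos, NumericVector box, double cutoff) {
  int N = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx[3] = {pos(j,0)-pos(i,0), pos(j,1)-pos(i,1), pos(j,2)-pos(i,2)};
      minimg3(dx, bx);
      double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
      if (r2 < c2) { ii.push_back(i + 1); jj.push_back(j + 1); }
    }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) { out(k,0) = ii[k]; out(k,1) = jj[k]; }
  return out;
}

// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix pos, NumericVector box) {
  int N = pos.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  double best = R_PosInf;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j) {
      double dx[3] = {pos(j,0)-pos(i,0), pos(j,1)-pos(i,1), pos(j,2)-pos(i,2)};
      minimg3(dx, bx);
      double r2 = dx[0]*dx[0]+dx[1]*dx[1]+dx[2]*dx[2];
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}
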