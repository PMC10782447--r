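#ifndef IONSOLV_PARSE_H
#define IONSOLV_PARSE_H

#include "common.h"

namespace ionsolv {

inline DescSpec parse_desc(Rcpp::List d) {
  DescSpec ds;
  ds.rc = Rcpp::as<double>(d["r_cut"]);
  ds.sigb = Rcpp::as<double>(d["sigma_basis"]);
  ds.centers = Rcpp::as< std::vector<double> >(d["centers"]);
  ds.ang = Rcpp::as<bool>(d["include_angular"]);
  ds.zeta = Rcpp::as< std::vector<double> >(d["ang_zeta"]);
  ds.lam = Rcpp::as< std::vector<double> >(d["ang_lambda"]);
  ds.eta = Rcpp::as< std::vector<double> >(d["ang_eta"]);
  ds.S = Rcpp::as<int>(d["n_species"]);
  ds.finalize();
  return ds;
}

// heads: list of lists; each either list(w=) or list(W1=,b1=,w2=)
inline ModelSpec parse_model(Rcpp::List m) {
  ModelSpec ms;
  ms.ds = parse_desc(m["descriptor"]);
  ms.scale = Rcpp::as< std::vector<double> >(m["scale"]);
  Rcpp::List heads = m["heads"];
  for (int s = 0; s < heads.size(); ++s) {
    Rcpp::List h = heads[s];
    HeadParams hp;
    if (h.containsElementNamed("w")) {
      hp.H = 0;
      hp.w = Rcpp::as< std::vector<double> >(h["w"]);
    } else {
      Rcpp::NumericMatrix W1 = h["W1"];
      hp.H = W1.nrow();
      hp.W1.assign(W1.begin(), W1.end());
      hp.b1 = Rcpp::as< std::vector<double> >(h["b1"]);
      hp.w2 = Rcpp::as< std::vector<double> >(h["w2"]);
    }
    ms.heads.push_back(hp);
  }
  ms.finalize_weff();
  return ms;
}

// extra: NULL or list(rc=, pairs=list of list(s1=,s2=,A=,r0=,w=) [0-based ids],
//        triple=NULL or list(lambda=, rc=, species=0-based id))
inline void parse_extra(SEXP extraS, int S, ExtraPair& ep, ExtraTriple& et) {
  ep.any = false; et.any = false;
  ep.S = S;
  if (Rf_isNull(extraS)) return;
  Rcpp::List extra(extraS);
  ep.rc = Rcpp::as<double>(extra["rc"]);
  int P = S * (S + 1) / 2;
  ep.A.assign(P, std::vector<double>());
  ep.R0.assign(P, std::vector<double>());
  ep.W.assign(P, std::vector<double>());
  Rcpp::List pl = extra["pairs"];
  for (int k = 0; k < pl.size(); ++k) {
    Rcpp::List pk = pl[k];
    int p = sympair(Rcpp::as<int>(pk["s1"]), Rcpp::as<int>(pk["s2"]), S);
    std::vector<double> A = Rcpp::as< std::vector<double> >(pk["A"]);
    std::vector<double> R0 = Rcpp::as< std::vector<double> >(pk["r0"]);
    std::vector<double> W = Rcpp::as< std::vector<double> >(pk["w"]);
    for (size_t q = 0; q < A.size(); ++q) {
      ep.A[p].push_back(A[q]); ep.R0[p].push_back(R0[q]); ep.W[p].push_back(W[q]);
    }
    if (A.size() > 0) ep.any = true;
  }
  if (extra.containsElementNamed("triple") && !Rf_isNull(extra["triple"])) {
    Rcpp::List t = extra["triple"];
    et.any = true;
    et.lambda = Rcpp::as<double>(t["lambda"]);
    et.rc = Rcpp::as<double>(t["rc"]);
    et.sp = Rcpp::as<int>(t["species"]);
  }
}

}  // namespace ionsolv
#endif
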