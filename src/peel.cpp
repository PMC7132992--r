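// Iterative peeling kernels.
//
// Ordered genotypes are indexed g = 2*pat + mat over alleles {0 = ref,
// 1 = alt}: (aa, aA, Aa, AA). Segregation states are indexed s = 2*u + v
// where u = 0 means the paternal gamete copied the sire's paternal
// haplotype, and v likewise for the dam. Message passing follows the
// anterior / penetrance / posterior factorization of single-locus
// iterative peeling, with proper exclusion of the receiving branch so the
// scheme is exact (at convergence) on loop-free pedigrees and a standard
// loopy approximation otherwise.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

static const double FLOOR = 1e-30;

struct PedC {
  int n, nfam;
  std::vector<int> fs, fd;          // family sire / dam (-1 unknown)
  std::vector<int> famPtr, famChild; // CSR: children of each family
  std::vector<int> childFam;         // family of individual (-1 founder)
  std::vector<int> parPtr, parFam, parRole; // CSR: families where ind is parent
};

static PedC build_ped(List fam) {
  PedC P;
  P.fs = as<std::vector<int>>(fam["fs"]);
  P.fd = as<std::vector<int>>(fam["fd"]);
  P.famPtr = as<std::vector<int>>(fam["fam_ptr"]);
  P.famChild = as<std::vector<int>>(fam["fam_child"]);
  P.childFam = as<std::vector<int>>(fam["child_fam"]);
  P.n = (int)P.childFam.size();
  P.nfam = (int)P.fs.size();
  P.parPtr.assign(P.n + 1, 0);
  for (int f = 0; f < P.nfam; ++f) {
    if (P.fs[f] >= 0) P.parPtr[P.fs[f] + 1]++;
    if (P.fd[f] >= 0) P.parPtr[P.fd[f] + 1]++;
  }
  for (int i = 0; i < P.n; ++i) P.parPtr[i + 1] += P.parPtr[i];
  P.parFam.assign(P.parPtr[P.n], 0);
  P.parRole.assign(P.parPtr[P.n], 0);
  std::vector<int> fill(P.n, 0);
  for (int f = 0; f < P.nfam; ++f) {
    if (P.fs[f] >= 0) {
      int i = P.fs[f];
      P.parFam[P.parPtr[i] + fill[i]] = f;
      P.parRole[P.parPtr[i] + fill[i]] = 0;
      fill[i]++;
    }
    if (P.fd[f] >= 0) {
      int i = P.fd[f];
      P.parFam[P.parPtr[i] + fill[i]] = f;
      P.parRole[P.parPtr[i] + fill[i]] = 1;
      fill[i]++;
    }
  }
  return P;
}

static inline void norm4(double* v) {
  double s = v[0] + v[1] + v[2] + v[3];
  if (s <= 0.0 || !R_finite(s)) { v[0] = v[1] = v[2] = v[3] = 0.25; return; }
  for (int k = 0; k < 4; ++k) {
    v[k] /= s;
    if (v[k] < FLOOR) v[k] = FLOOR;
  }
}

static inline void hw4(double p, double* v) {
  double q = 1.0 - p;
  v[0] = q * q; v[1] = q * p; v[2] = p * q; v[3] = p * p;
}

// product of posterior messages into individual i from families where it
// is a parent
static inline void prodPost(const PedC& P, int i, const double* postS,
                            const double* postD, double* out) {
  out[0] = out[1] = out[2] = out[3] = 1.0;
  for (int k = P.parPtr[i]; k < P.parPtr[i + 1]; ++k) {
    const double* m = (P.parRole[k] == 0 ? postS : postD) + 4 * P.parFam[k];
    for (int g = 0; g < 4; ++g) out[g] *= m[g];
  }
}

// parent's genotype distribution excluding the contribution of family f
static inline void parentExcl(const PedC& P, int i, int f, const double* pen,
                              const double* ant, const double* postS,
                              const double* postD, double* out) {
  for (int g = 0; g < 4; ++g) out[g] = ant[4 * i + g] * pen[4 * i + g];
  for (int k = P.parPtr[i]; k < P.parPtr[i + 1]; ++k) {
    if (P.parFam[k] == f) continue;
    const double* m = (P.parRole[k] == 0 ? postS : postD) + 4 * P.parFam[k];
    for (int g = 0; g < 4; ++g) out[g] *= m[g];
  }
  norm4(out);
}

// m_c(gs, gd) = sum_gc T(gc | gs, gd, seg_c) * lam_c(gc), stored [gs*4+gd]
static inline void childKernel(const double* sg, const double* lam,
                               double* mc) {
  for (int gs = 0; gs < 4; ++gs) {
    int as0 = gs >> 1, as1 = gs & 1;
    for (int gd = 0; gd < 4; ++gd) {
      int ad0 = gd >> 1, ad1 = gd & 1;
      mc[gs * 4 + gd] =
        sg[0] * lam[2 * as0 + ad0] + sg[1] * lam[2 * as0 + ad1] +
        sg[2] * lam[2 * as1 + ad0] + sg[3] * lam[2 * as1 + ad1];
    }
  }
}

// One pass over family f: refresh each child's anterior and the posterior
// messages to sire and dam. If segLik != NULL, also store per-child local
// segregation-state likelihoods (4 per child).
static void processFamily(const PedC& P, int f, const double* pen,
                          const double* seg, double p,
                          double* ant, double* postS, double* postD,
                          double* segLik) {
  static const double unif[4] = {0.25, 0.25, 0.25, 0.25};
  int s = P.fs[f], d = P.fd[f];
  double qs[4], qd[4];
  if (s >= 0) parentExcl(P, s, f, pen, ant, postS, postD, qs);
  else hw4(p, qs);
  if (d >= 0) parentExcl(P, d, f, pen, ant, postS, postD, qd);
  else hw4(p, qd);

  int k0 = P.famPtr[f], k1 = P.famPtr[f + 1], nk = k1 - k0;
  static std::vector<double> lam, mc, pre, suf; // single-threaded reuse
  if ((int)lam.size() < 4 * nk) {
    lam.resize(4 * nk); mc.resize(16 * nk);
  }
  if ((int)pre.size() < 16 * (nk + 1)) {
    pre.resize(16 * (nk + 1)); suf.resize(16 * (nk + 1));
  }
  for (int j = 0; j < nk; ++j) {
    int c = P.famChild[k0 + j];
    double pp[4];
    prodPost(P, c, postS, postD, pp);
    for (int g = 0; g < 4; ++g) lam[4 * j + g] = pen[4 * c + g] * pp[g];
    norm4(&lam[4 * j]);
    const double* sg = seg ? seg + 4 * c : unif;
    childKernel(sg, &lam[4 * j], &mc[16 * j]);
  }
  // prefix/suffix products of the child kernels over (gs, gd)
  for (int t = 0; t < 16; ++t) pre[t] = 1.0;
  for (int j = 0; j < nk; ++j)
    for (int t = 0; t < 16; ++t)
      pre[16 * (j + 1) + t] = pre[16 * j + t] * mc[16 * j + t];
  for (int t = 0; t < 16; ++t) suf[16 * nk + t] = 1.0;
  for (int j = nk - 1; j >= 0; --j)
    for (int t = 0; t < 16; ++t)
      suf[16 * j + t] = suf[16 * (j + 1) + t] * mc[16 * j + t];

  // per-child: joint parent distribution excluding that child
  double Jc[16];
  for (int j = 0; j < nk; ++j) {
    int c = P.famChild[k0 + j];
    for (int gs = 0; gs < 4; ++gs)
      for (int gd = 0; gd < 4; ++gd) {
        int t = gs * 4 + gd;
        Jc[t] = qs[gs] * qd[gd] * pre[16 * j + t] * suf[16 * (j + 1) + t];
      }
    // anterior: accumulate A[u][v][x][y] = sum of Jc with sire allele(u)=x,
    // dam allele(v)=y; then mix over segregation states
    double A[2][2][2][2] = {{{{0}}}};
    for (int gs = 0; gs < 4; ++gs) {
      int as[2] = {gs >> 1, gs & 1};
      for (int gd = 0; gd < 4; ++gd) {
        int ad[2] = {gd >> 1, gd & 1};
        double jt = Jc[gs * 4 + gd];
        for (int u = 0; u < 2; ++u)
          for (int v = 0; v < 2; ++v)
            A[u][v][as[u]][ad[v]] += jt;
      }
    }
    const double* sg = seg ? seg + 4 * c : unif;
    double* ac = ant + 4 * c;
    for (int x = 0; x < 2; ++x)
      for (int y = 0; y < 2; ++y)
        ac[2 * x + y] = sg[0] * A[0][0][x][y] + sg[1] * A[0][1][x][y] +
                        sg[2] * A[1][0][x][y] + sg[3] * A[1][1][x][y];
    norm4(ac);
    if (segLik) {
      double* L = segLik + 4 * c;
      L[0] = L[1] = L[2] = L[3] = 0.0;
      const double* lm = &lam[4 * j];
      for (int gs = 0; gs < 4; ++gs) {
        int as[2] = {gs >> 1, gs & 1};
        for (int gd = 0; gd < 4; ++gd) {
          int ad[2] = {gd >> 1, gd & 1};
          double jt = Jc[gs * 4 + gd];
          L[0] += jt * lm[2 * as[0] + ad[0]];
          L[1] += jt * lm[2 * as[0] + ad[1]];
          L[2] += jt * lm[2 * as[1] + ad[0]];
          L[3] += jt * lm[2 * as[1] + ad[1]];
        }
      }
      norm4(L);
    }
  }
  // posterior messages to the parents
  const double* M = &suf[0]; // product over all children
  if (s >= 0) {
    double* ms = postS + 4 * f;
    for (int gs = 0; gs < 4; ++gs) {
      double acc = 0.0;
      for (int gd = 0; gd < 4; ++gd) acc += qd[gd] * M[gs * 4 + gd];
      ms[gs] = acc;
    }
    norm4(ms);
  }
  if (d >= 0) {
    double* md = postD + 4 * f;
    for (int gd = 0; gd < 4; ++gd) {
      double acc = 0.0;
      for (int gs = 0; gs < 4; ++gs) acc += qs[gs] * M[gs * 4 + gd];
      md[gd] = acc;
    }
    norm4(md);
  }
}

static void beliefs(const PedC& P, const double* pen, const double* ant,
                    const double* postS, const double* postD, double* out) {
  for (int i = 0; i < P.n; ++i) {
    double pp[4];
    prodPost(P, i, postS, postD, pp);
    for (int g = 0; g < 4; ++g)
      out[4 * i + g] = ant[4 * i + g] * pen[4 * i + g] * pp[g];
    norm4(out + 4 * i);
  }
}

static void initState(const PedC& P, double p, double* ant, double* postS,
                      double* postD) {
  for (int i = 0; i < P.n; ++i) hw4(p, ant + 4 * i);
  for (int f = 0; f < P.nfam; ++f)
    for (int g = 0; g < 4; ++g)
      postS[4 * f + g] = postD[4 * f + g] = 1.0;
}

// iterate sweeps until max dosage change < tol; writes beliefs into prob
static int peelLocus(const PedC& P, const double* pen, const double* seg,
                     double p, int maxit, double tol,
                     double* ant, double* postS, double* postD,
                     double* prob, double* segLik = NULL) {
  std::vector<double> dosePrev(P.n, -1.0);
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    for (int f = 0; f < P.nfam; ++f)
      processFamily(P, f, pen, seg, p, ant, postS, postD, segLik);
    for (int f = P.nfam - 1; f >= 0; --f)
      processFamily(P, f, pen, seg, p, ant, postS, postD, segLik);
    beliefs(P, pen, ant, postS, postD, prob);
    double dmax = 0.0;
    for (int i = 0; i < P.n; ++i) {
      double d = prob[4 * i + 1] + prob[4 * i + 2] + 2.0 * prob[4 * i + 3];
      double diff = std::fabs(d - dosePrev[i]);
      if (diff > dmax) dmax = diff;
      dosePrev[i] = d;
    }
    if (dmax < tol) break;
  }
  return it;
}

// [[Rcpp::export(name = ".peel_single_cpp")]]
List peel_single_cpp(List fam, NumericVector pen, Nullable<NumericVector> seg,
                     double p, int maxit, double tol) {
  PedC P = build_ped(fam);
  std::vector<double> ant(4 * P.n), postS(4 * P.nfam), postD(4 * P.nfam);
  initState(P, p, &ant[0], &postS[0], &postD[0]);
  NumericVector prob(4 * P.n);
  const double* segp = NULL;
  NumericVector segv;
  if (seg.isNotNull()) { segv = seg.get(); segp = REAL(segv); }
  int it = peelLocus(P, REAL(pen), segp, p, maxit, tol, &ant[0], &postS[0],
                     &postD[0], REAL(prob));
  prob.attr("dim") = Dimension(4, P.n);
  NumericVector dose(P.n);
  for (int i = 0; i < P.n; ++i)
    dose[i] = prob[4 * i + 1] + prob[4 * i + 2] + 2.0 * prob[4 * i + 3];
  return List::create(_["prob"] = prob, _["dosage"] = dose,
                      _["iterations"] = it);
}

// forward-backward smoothing of segregation states along one chromosome
// for one individual; emis/out are 4 x L, trans r per interval (L-1)
static void fbSeg(int L, const double* emis, const double* r, double* out) {
  std::vector<double> fwd(4 * L), bwd(4 * L);
  for (int s = 0; s < 4; ++s) fwd[s] = 0.25 * emis[s];
  for (int l = 1; l < L; ++l) {
    double rr = r[l - 1];
    double tu[2][2] = {{1 - rr, rr}, {rr, 1 - rr}};
    for (int s = 0; s < 4; ++s) {
      int u = s >> 1, v = s & 1;
      double acc = 0.0;
      for (int s0 = 0; s0 < 4; ++s0)
        acc += fwd[4 * (l - 1) + s0] * tu[s0 >> 1][u] * tu[s0 & 1][v];
      fwd[4 * l + s] = acc * emis[4 * l + s];
    }
    double tot = 0.0;
    for (int s = 0; s < 4; ++s) tot += fwd[4 * l + s];
    if (tot > 0) for (int s = 0; s < 4; ++s) fwd[4 * l + s] /= tot;
  }
  for (int s = 0; s < 4; ++s) bwd[4 * (L - 1) + s] = 1.0;
  for (int l = L - 2; l >= 0; --l) {
    double rr = r[l];
    double tu[2][2] = {{1 - rr, rr}, {rr, 1 - rr}};
    for (int s = 0; s < 4; ++s) {
      int u = s >> 1, v = s & 1;
      double acc = 0.0;
      for (int s1 = 0; s1 < 4; ++s1)
        acc += tu[u][s1 >> 1] * tu[v][s1 & 1] * emis[4 * (l + 1) + s1] *
               bwd[4 * (l + 1) + s1];
      bwd[4 * l + s] = acc;
    }
    double tot = 0.0;
    for (int s = 0; s < 4; ++s) tot += bwd[4 * l + s];
    if (tot > 0) for (int s = 0; s < 4; ++s) bwd[4 * l + s] /= tot;
  }
  for (int l = 0; l < L; ++l) {
    double* o = out + 4 * l;
    for (int s = 0; s < 4; ++s) o[s] = fwd[4 * l + s] * bwd[4 * l + s];
    norm4(o);
  }
}

struct MultiState {
  PedC P;
  int L;
  std::vector<double> ant, postS, postD, seg, segLik, prob;
};

static void multiPeel(MultiState& st, const double* pen, const double* pvec,
                      const double* rvec, int outer_maxit, double tol,
                      int inner_sweeps) {
  PedC& P = st.P;
  int n = P.n, L = st.L;
  st.ant.assign((size_t)4 * n * L, 0.0);
  st.postS.assign((size_t)4 * P.nfam * L, 1.0);
  st.postD.assign((size_t)4 * P.nfam * L, 1.0);
  st.seg.assign((size_t)4 * n * L, 0.25);
  st.segLik.assign((size_t)4 * n * L, 0.25);
  st.prob.assign((size_t)4 * n * L, 0.25);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i)
      hw4(pvec[l], &st.ant[(size_t)4 * (n * l + i)]);

  std::vector<double> emis(4 * L), smoothed(4 * L);
  for (int outer = 0; outer < outer_maxit; ++outer) {
    for (int l = 0; l < L; ++l) {
      size_t o = (size_t)4 * n * l, of = (size_t)4 * P.nfam * l;
      for (int sw = 0; sw < inner_sweeps; ++sw) {
        for (int f = 0; f < P.nfam; ++f)
          processFamily(P, f, pen + o, &st.seg[o], pvec[l], &st.ant[o],
                        &st.postS[of], &st.postD[of], &st.segLik[o]);
        for (int f = P.nfam - 1; f >= 0; --f)
          processFamily(P, f, pen + o, &st.seg[o], pvec[l], &st.ant[o],
                        &st.postS[of], &st.postD[of], &st.segLik[o]);
      }
    }
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      if (P.childFam[i] < 0) continue; // founders stay uniform
      for (int l = 0; l < L; ++l)
        for (int s = 0; s < 4; ++s)
          emis[4 * l + s] = st.segLik[(size_t)4 * (n * l + i) + s];
      fbSeg(L, &emis[0], rvec, &smoothed[0]);
      for (int l = 0; l < L; ++l)
        for (int s = 0; s < 4; ++s) {
          double& cur = st.seg[(size_t)4 * (n * l + i) + s];
          double diff = std::fabs(smoothed[4 * l + s] - cur);
          if (diff > dmax) dmax = diff;
          cur = smoothed[4 * l + s];
        }
    }
    if (dmax < tol) break;
  }
  for (int l = 0; l < L; ++l) {
    size_t o = (size_t)4 * n * l, of = (size_t)4 * P.nfam * l;
    beliefs(P, pen + o, &st.ant[o], &st.postS[of], &st.postD[of],
            &st.prob[o]);
  }
}

// [[Rcpp::export(name = ".peel_multi_cpp")]]
List peel_multi_cpp(List fam, NumericVector pen, NumericVector pos_cm,
                    NumericVector pvec, int outer_maxit, double tol,
                    int inner_sweeps) {
  MultiState st;
  st.P = build_ped(fam);
  st.L = pos_cm.size();
  std::vector<double> rvec(st.L > 1 ? st.L - 1 : 0);
  for (int l = 0; l + 1 < st.L; ++l)
    rvec[l] = 0.5 * (1.0 - std::exp(-2.0 * (pos_cm[l + 1] - pos_cm[l]) / 100.0));
  multiPeel(st, REAL(pen), REAL(pvec), rvec.data(), outer_maxit, tol,
            inner_sweeps);
  NumericVector seg(st.seg.begin(), st.seg.end());
  NumericVector prob(st.prob.begin(), st.prob.end());
  seg.attr("dim") = Dimension(4, st.P.n, st.L);
  prob.attr("dim") = Dimension(4, st.P.n, st.L);
  return List::create(_["seg"] = seg, _["prob"] = prob);
}

// bridge an inheritance indicator between two flanking posteriors
static inline double bridgeInd(double qL, double rL, bool hasL, double qR,
                               double rR, bool hasR) {
  double mL = hasL ? qL * (1 - rL) + (1 - qL) * rL : 0.5;
  double mR = hasR ? qR * (1 - rR) + (1 - qR) * rR : 0.5;
  double num = mL * mR, den = num + (1 - mL) * (1 - mR);
  return den > 0 ? num / den : 0.5;
}

// [[Rcpp::export(name = ".hybrid_chr_cpp")]]
List hybrid_chr_cpp(List fam, NumericVector penPanel, NumericVector panelPos,
                    NumericVector pPanel, NumericVector varPos,
                    NumericVector pAll, IntegerVector panelCol,
                    IntegerVector rcPtr, IntegerVector rcInd,
                    IntegerVector rcRef, IntegerVector rcAlt,
                    double seqError, int outer_maxit, double multi_tol,
                    int inner_sweeps, int maxit, double tol,
                    bool return_probs) {
  MultiState st;
  st.P = build_ped(fam);
  int n = st.P.n, L = panelPos.size(), nv = varPos.size();
  st.L = L;
  std::vector<double> rvec(L > 1 ? L - 1 : 0);
  for (int l = 0; l + 1 < L; ++l)
    rvec[l] = 0.5 * (1.0 - std::exp(-2.0 * (panelPos[l + 1] - panelPos[l]) / 100.0));
  multiPeel(st, REAL(penPanel), REAL(pPanel), rvec.data(), outer_maxit,
            multi_tol, inner_sweeps);

  // indicator marginals at panel loci: pu = P(u = 0), pv = P(v = 0)
  std::vector<double> pu((size_t)n * L), pv((size_t)n * L);
  for (int l = 0; l < L; ++l)
    for (int i = 0; i < n; ++i) {
      const double* s = &st.seg[(size_t)4 * (n * l + i)];
      pu[(size_t)n * l + i] = s[0] + s[1];
      pv[(size_t)n * l + i] = s[0] + s[2];
    }

  NumericMatrix dose(n, nv);
  NumericVector probs;
  if (return_probs) {
    probs = NumericVector((size_t)4 * n * nv);
    probs.attr("dim") = Dimension(4, n, nv);
  }
  std::vector<double> ant(4 * n), postS(4 * st.P.nfam), postD(4 * st.P.nfam),
      pen(4 * n), seg(4 * n), prob(4 * n);
  const double e = seqError;
  for (int v = 0; v < nv; ++v) {
    double x = varPos[v];
    int pc = panelCol[v]; // 0-based panel column or -1
    if (pc >= 0) {
      for (int i = 0; i < n; ++i)
        for (int g = 0; g < 4; ++g)
          seg[4 * i + g] = st.seg[(size_t)4 * (n * pc + i) + g];
      std::copy(REAL(penPanel) + (size_t)4 * n * pc,
                REAL(penPanel) + (size_t)4 * n * (pc + 1), pen.begin());
    } else {
      // flanking panel loci
      int lo = -1, hi = L;
      { // binary search: last panel pos <= x
        int a = 0, b = L - 1;
        while (a <= b) {
          int m = (a + b) / 2;
          if (panelPos[m] <= x) { lo = m; a = m + 1; } else b = m - 1;
        }
        hi = lo + 1;
      }
      bool hasL = lo >= 0, hasR = hi < L;
      double rL = hasL ? 0.5 * (1 - std::exp(-2.0 * (x - panelPos[lo]) / 100.0)) : 0.5;
      double rR = hasR ? 0.5 * (1 - std::exp(-2.0 * (panelPos[hi] - x) / 100.0)) : 0.5;
      for (int i = 0; i < n; ++i) {
        double quu = bridgeInd(hasL ? pu[(size_t)n * lo + i] : 0.5, rL, hasL,
                               hasR ? pu[(size_t)n * hi + i] : 0.5, rR, hasR);
        double qvv = bridgeInd(hasL ? pv[(size_t)n * lo + i] : 0.5, rL, hasL,
                               hasR ? pv[(size_t)n * hi + i] : 0.5, rR, hasR);
        seg[4 * i + 0] = quu * qvv;
        seg[4 * i + 1] = quu * (1 - qvv);
        seg[4 * i + 2] = (1 - quu) * qvv;
        seg[4 * i + 3] = (1 - quu) * (1 - qvv);
      }
      std::fill(pen.begin(), pen.end(), 1.0);
      for (int k = rcPtr[v]; k < rcPtr[v + 1]; ++k) {
        int i = rcInd[k];
        double nr = rcRef[k], na = rcAlt[k];
        double* pi = &pen[4 * i];
        pi[0] *= std::pow(e, na) * std::pow(1 - e, nr);
        pi[1] *= std::pow(0.5, na + nr);
        pi[2] = pi[1];
        pi[3] *= std::pow(1 - e, na) * std::pow(e, nr);
      }
    }
    initState(st.P, pAll[v], &ant[0], &postS[0], &postD[0]);
    peelLocus(st.P, &pen[0], &seg[0], pAll[v], maxit, tol, &ant[0], &postS[0],
              &postD[0], &prob[0]);
    for (int i = 0; i < n; ++i)
      dose(i, v) = prob[4 * i + 1] + prob[4 * i + 2] + 2.0 * prob[4 * i + 3];
    if (return_probs)
      std::copy(prob.begin(), prob.end(), REAL(probs) + (size_t)4 * n * v);
  }
  NumericVector segOut(st.seg.begin(), st.seg.end());
  segOut.attr("dim") = Dimension(4, n, L);
  List out = List::create(_["dosage"] = dose, _["seg_panel"] = segOut);
  if (return_probs) out["prob"] = probs;
  return out;
}

// ---- pedigree numerics: inbreeding (recursive kinship) and the
//      connectedness sums via A = T D T' without materializing A ----

struct Kin {
  const std::vector<int>& s;
  const std::vector<int>& d;
  std::vector<double>& F;
  std::map<std::pair<int, int>, double> memo;
  Kin(const std::vector<int>& s_, const std::vector<int>& d_,
      std::vector<double>& F_) : s(s_), d(d_), F(F_) {}
  // additive relationship a(j, k), 1-based ids, 0 = unknown
  double a(int j, int k) {
    if (j == 0 || k == 0) return 0.0;
    if (j > k) std::swap(j, k);
    if (j == k) return 1.0 + F[j - 1];
    auto key = std::make_pair(j, k);
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    // k is the later individual: recurse on its parents
    double val = 0.5 * (a(j, s[k - 1]) + a(j, d[k - 1]));
    memo[key] = val;
    return val;
  }
};

// [[Rcpp::export(name = ".ped_connectedness_cpp")]]
List ped_connectedness_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  std::vector<int> s(sire.begin(), sire.end()), d(dam.begin(), dam.end());
  std::vector<double> F(n, 0.0);
  Kin kin(s, d, F);
  for (int i = 0; i < n; ++i) {
    if (s[i] > 0 && d[i] > 0) F[i] = 0.5 * kin.a(s[i], d[i]);
  }
  // t = T' 1 (expected long-term genome contributions), reverse sweep
  std::vector<double> t(n, 1.0);
  for (int i = n - 1; i >= 0; --i) {
    if (s[i] > 0) t[s[i] - 1] += 0.5 * t[i];
    if (d[i] > 0) t[d[i] - 1] += 0.5 * t[i];
  }
  // u = T (D t), forward sweep; D = mendelian sampling variances
  std::vector<double> u(n, 0.0);
  NumericVector connect(n), Fout(n);
  for (int i = 0; i < n; ++i) {
    double dv;
    if (s[i] > 0 && d[i] > 0)
      dv = 0.5 - 0.25 * (F[s[i] - 1] + F[d[i] - 1]);
    else if (s[i] > 0) dv = 0.75 - 0.25 * F[s[i] - 1];
    else if (d[i] > 0) dv = 0.75 - 0.25 * F[d[i] - 1];
    else dv = 1.0;
    u[i] = dv * t[i];
    if (s[i] > 0) u[i] += 0.5 * u[s[i] - 1];
    if (d[i] > 0) u[i] += 0.5 * u[d[i] - 1];
    connect[i] = u[i] - (1.0 + F[i]);
    Fout[i] = F[i];
  }
  return List::create(_["f"] = Fout, _["connect"] = connect);
}
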