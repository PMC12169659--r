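// String-based determinant CI over a spin-inversion-closed subspace
// S = U x U (U a set of half-strings).  Matrix elements follow the
// Slater-Condon rules over (h1, eri) with the two-electron part in
// normal-ordered form, so a projected subspace keeps exact full-space
// elements between its determinants (no renormalization).
//
// CI vectors are stored as R matrices with rows indexed by the beta string
// and columns by the alpha string (columns contiguous).
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int popcnt(unsigned int x) { return __builtin_popcount(x); }

// parity of occupied orbitals strictly below orbital p
static inline int par_below(unsigned int str, int p) {
  unsigned int mask = (p == 0) ? 0u : ((1u << p) - 1u);
  return popcnt(str & mask) & 1;
}

// [[Rcpp::export]]
IntegerVector cpp_strings(int norb, int nelec) {
  if (nelec < 0 || nelec > norb) stop("bad electron count");
  std::vector<int> out;
  if (nelec == 0) { out.push_back(0); }
  else {
    unsigned int v = (1u << nelec) - 1u;
    unsigned int lim = 1u << norb;
    while (v < lim) {
      out.push_back((int)v);
      unsigned int t = v | (v - 1u);
      v = (t + 1u) | (((~t & (t + 1u)) - 1u) >> (__builtin_ctz(v) + 1));
      if (v == 0) break;
    }
  }
  return wrap(out);
}

struct Tables {
  int N, norb;
  std::vector<unsigned int> strs;
  // singles grouped by 'from' string: CSR
  std::vector<int> sptr, sto, spq; std::vector<signed char> ssgn;
  // doubles grouped by 'from'
  std::vector<int> dptr, dto, dpq, drs; std::vector<signed char> dsgn;
};

static int lookup(const std::vector<unsigned int>& strs, unsigned int key) {
  int lo = 0, hi = (int)strs.size() - 1;
  while (lo <= hi) {
    int mid = (lo + hi) >> 1;
    if (strs[mid] == key) return mid;
    if (strs[mid] < key) lo = mid + 1; else hi = mid - 1;
  }
  return -1;
}

// [[Rcpp::export]]
List cpp_exc_tables(IntegerVector strings, int norb) {
  int N = strings.size();
  std::vector<unsigned int> strs(N);
  for (int i = 0; i < N; ++i) strs[i] = (unsigned int)strings[i];
  for (int i = 1; i < N; ++i)
    if (strs[i] <= strs[i - 1]) stop("strings must be sorted and unique");
  std::vector<int> sptr(N + 1, 0), sto, spq, dptr(N + 1, 0), dto, dpq, drs;
  std::vector<signed char> ssgn, dsgn;
  std::vector<int> occ, vir;
  for (int I = 0; I < N; ++I) {
    unsigned int s = strs[I];
    occ.clear(); vir.clear();
    for (int p = 0; p < norb; ++p) ((s >> p) & 1u ? occ : vir).push_back(p);
    // singles q(occ) -> p(vir)
    for (size_t iq = 0; iq < occ.size(); ++iq) {
      int q = occ[iq];
      for (size_t ip = 0; ip < vir.size(); ++ip) {
        int p = vir[ip];
        unsigned int j = (s & ~(1u << q)) | (1u << p);
        int J = lookup(strs, j);
        if (J < 0) continue;
        int sg = par_below(s, q);
        sg += par_below(s & ~(1u << q), p);
        sto.push_back(J);
        spq.push_back(p * norb + q);
        ssgn.push_back((sg & 1) ? -1 : 1);
      }
    }
    sptr[I + 1] = (int)sto.size();
    // doubles {q<s occ} -> {p<r vir}, amplitude sign of a+_p a+_r a_s a_q
    for (size_t iq = 0; iq + 1 < occ.size(); ++iq) {
      for (size_t is = iq + 1; is < occ.size(); ++is) {
        int q = occ[iq], s2 = occ[is];
        unsigned int s_q = strs[I] & ~(1u << q);
        unsigned int s_qs = s_q & ~(1u << s2);
        for (size_t ip = 0; ip + 1 < vir.size(); ++ip) {
          for (size_t ir = ip + 1; ir < vir.size(); ++ir) {
            int p = vir[ip], r = vir[ir];
            unsigned int j = s_qs | (1u << p) | (1u << r);
            int J = lookup(strs, j);
            if (J < 0) continue;
            // apply a_q, a_s, a+_r, a+_p in sequence
            int sg = par_below(strs[I], q);
            sg += par_below(s_q, s2);
            sg += par_below(s_qs, r);
            sg += par_below(s_qs | (1u << r), p);
            dto.push_back(J);
            dpq.push_back(p * norb + q);
            drs.push_back(r * norb + s2);
            dsgn.push_back((sg & 1) ? -1 : 1);
          }
        }
      }
    }
    dptr[I + 1] = (int)dto.size();
  }
  // occupation matrix (N x norb)
  IntegerMatrix Occ(N, norb);
  for (int I = 0; I < N; ++I)
    for (int p = 0; p < norb; ++p) Occ(I, p) = (strs[I] >> p) & 1u;
  return List::create(
    _["sptr"] = wrap(sptr), _["sto"] = wrap(sto), _["spq"] = wrap(spq),
    _["ssgn"] = wrap(std::vector<int>(ssgn.begin(), ssgn.end())),
    _["dptr"] = wrap(dptr), _["dto"] = wrap(dto), _["dpq"] = wrap(dpq),
    _["drs"] = wrap(drs),
    _["dsgn"] = wrap(std::vector<int>(dsgn.begin(), dsgn.end())),
    _["occ"] = Occ, _["norb"] = norb, _["nstr"] = N);
}

// doubles amplitude values: sign * [(pq|rs) - (ps|rq)]
// [[Rcpp::export]]
NumericVector cpp_doubles_val(List tab, NumericVector eri) {
  int norb = as<int>(tab["norb"]);
  IntegerVector dpq = tab["dpq"], drs = tab["drs"], dsgn = tab["dsgn"];
  int nd = dpq.size();
  NumericVector val(nd);
  const double* E = eri.begin();
  int n = norb, n2 = n * n, n3 = n2 * n;
  for (int i = 0; i < nd; ++i) {
    int p = dpq[i] / n, q = dpq[i] % n, r = drs[i] / n, s = drs[i] % n;
    double v = E[p + n * q + n2 * r + n3 * s] - E[p + n * s + n2 * r + n3 * q];
    val[i] = dsgn[i] * v;
  }
  return val;
}

// one-electron-like singles coefficients c1(entry) =
//   h[p,q] + sum_{r in occ(I)} [(pq|rr) - (pr|rq)]
// [[Rcpp::export]]
NumericVector cpp_singles_c1(List tab, NumericVector h1, NumericVector eri) {
  int norb = as<int>(tab["norb"]);
  IntegerVector sptr = tab["sptr"], spq = tab["spq"];
  IntegerMatrix Occ = tab["occ"];
  int N = as<int>(tab["nstr"]);
  NumericVector out(spq.size());
  const double* E = eri.begin();
  const double* H = h1.begin();
  int n = norb, n2 = n * n, n3 = n2 * n;
  for (int I = 0; I < N; ++I) {
    for (int e = sptr[I]; e < sptr[I + 1]; ++e) {
      int p = spq[e] / n, q = spq[e] % n;
      double v = H[p + n * q];
      for (int r = 0; r < n; ++r) {
        if (!Occ(I, r)) continue;
        v += E[p + n * q + n2 * r + n3 * r] - E[p + n * r + n2 * r + n3 * q];
      }
      out[e] = v;
    }
  }
  return out;
}

// sigma accumulation, alpha-side: C has dim (N x N), columns = alpha strings.
//  T1: alpha singles with coefficient (c1 + G[Ibeta, pq])   (G is N x norb^2)
//  T3: alpha doubles (precomputed values)
//  T4 (ab_mode = 1): alpha-singles x beta-singles with (pq|rs), assembled as
//  dense (strings x orbital-pair) intermediates contracted with BLAS dgemm.
// [[Rcpp::export]]
List cpp_sigma_side(List tab, NumericVector c1, NumericVector dval,
                    NumericMatrix G, NumericVector eri,
                    NumericMatrix C, int ab_mode) {
  int norb = as<int>(tab["norb"]);
  int N = as<int>(tab["nstr"]);
  IntegerVector sptrV = tab["sptr"], stoV = tab["sto"], spqV = tab["spq"], ssgnV = tab["ssgn"];
  IntegerVector dptrV = tab["dptr"], dtoV = tab["dto"];
  const int *sptr = sptrV.begin(), *sto = stoV.begin(), *spq = spqV.begin(), *ssgn = ssgnV.begin();
  const int *dptr = dptrV.begin(), *dto = dtoV.begin();
  const double *c1p = c1.begin(), *dvalp = dval.begin(), *Gp = G.begin();
  NumericMatrix Sg(N, N);
  const double* Cp = C.begin();
  double* Sp = Sg.begin();
  int n2 = norb * norb;
  const double* E = eri.begin();
  // T1 + T3: column operations
  for (int Ia = 0; Ia < N; ++Ia) {
    const double* cI = Cp + (size_t)Ia * N;
    for (int e = sptr[Ia]; e < sptr[Ia + 1]; ++e) {
      double cc = ssgn[e] * c1p[e];
      double sg = (double)ssgn[e];
      double* sJ = Sp + (size_t)sto[e] * N;
      const double* g = Gp + (size_t)spq[e] * N;   // column pq of G, contiguous
      for (int Ib = 0; Ib < N; ++Ib)
        sJ[Ib] += (cc + sg * g[Ib]) * cI[Ib];
    }
    for (int e = dptr[Ia]; e < dptr[Ia + 1]; ++e) {
      double v = dvalp[e];
      double* sJ = Sp + (size_t)dto[e] * N;
      for (int Ib = 0; Ib < N; ++Ib) sJ[Ib] += v * cI[Ib];
    }
  }
  if (ab_mode > 0) {
    std::vector<double> B((size_t)N * n2), Es, R;
    for (int Ia = 0; Ia < N; ++Ia) {
      int ns = sptr[Ia + 1] - sptr[Ia];
      if (ns == 0) continue;
      const double* cI = Cp + (size_t)Ia * N;
      // B[Jb + N*rs] = sum_{beta exc Ib->Jb via rs} sign * C[Ib, Ia]
      std::fill(B.begin(), B.end(), 0.0);
      for (int Ib = 0; Ib < N; ++Ib) {
        double c = cI[Ib];
        if (c == 0.0) continue;
        for (int e2 = sptr[Ib]; e2 < sptr[Ib + 1]; ++e2)
          B[(size_t)spq[e2] * N + sto[e2]] += ssgn[e2] * c;
      }
      // Es[rs + n2*k] = sign_k * (p_k q_k | rs)
      Es.assign((size_t)n2 * ns, 0.0);
      R.assign((size_t)N * ns, 0.0);
      for (int k = 0; k < ns; ++k) {
        int e = sptr[Ia] + k;
        double sg = (double)ssgn[e];
        const double* row = E + (size_t)spq[e];
        double* es = &Es[(size_t)n2 * k];
        for (int rs = 0; rs < n2; ++rs) es[rs] = sg * row[(size_t)rs * n2];
      }
      {
        const double one = 1.0, zero = 0.0;
        const int m = N, n_ = ns, k_ = n2;
        F77_CALL(dgemm)("N", "N", &m, &n_, &k_, &one, B.data(), &m,
                        Es.data(), &k_, &zero, R.data(), &m FCONE FCONE);
      }
      for (int k = 0; k < ns; ++k) {
        double* sJ = Sp + (size_t)sto[sptr[Ia] + k] * N;
        const double* r = &R[(size_t)N * k];
        for (int Ib = 0; Ib < N; ++Ib) sJ[Ib] += r[Ib];
      }
    }
  }
  return List::create(_["sigma"] = Sg);
}

// dense projected Hamiltonian (electronic part, no string diagonal) for
// small subspaces: d x d with det index i = Ibeta + N * Ialpha
// [[Rcpp::export]]
NumericMatrix cpp_dense_h(List tab, NumericVector c1, NumericVector dval,
                          NumericMatrix G, NumericVector eri) {
  int norb = as<int>(tab["norb"]);
  int N = as<int>(tab["nstr"]);
  IntegerVector sptr = tab["sptr"], sto = tab["sto"], spq = tab["spq"], ssgn = tab["ssgn"];
  IntegerVector dptr = tab["dptr"], dto = tab["dto"];
  size_t d = (size_t)N * N;
  NumericMatrix H(d, d);
  double* Hp = H.begin();
  int n2 = norb * norb;
  const double* E = eri.begin();
  for (int Ia = 0; Ia < N; ++Ia) {
    for (int e = sptr[Ia]; e < sptr[Ia + 1]; ++e) {
      int Ja = sto[e];
      double sg = (double)ssgn[e];
      const double* g = G.begin() + (size_t)spq[e] * N;  // G is N x norb^2
      for (int Ib = 0; Ib < N; ++Ib) {
        double v = sg * (c1[e] + g[Ib]);
        // alpha single x beta diagonal (Ib = beta string)
        Hp[((size_t)Ia * N + Ib) * d + (size_t)Ja * N + Ib] += v;
        // beta single x alpha diagonal (same tables, Ib = alpha string)
        Hp[((size_t)Ib * N + Ia) * d + (size_t)Ib * N + Ja] += v;
      }
      // alpha single x beta single
      for (int Ib = 0; Ib < N; ++Ib) {
        for (int e2 = sptr[Ib]; e2 < sptr[Ib + 1]; ++e2) {
          int Jb = sto[e2];
          double v2 = sg * ssgn[e2] * E[(size_t)spq[e] + (size_t)spq[e2] * n2];
          Hp[((size_t)Ia * N + Ib) * d + (size_t)Ja * N + Jb] += v2;
        }
      }
    }
    for (int e = dptr[Ia]; e < dptr[Ia + 1]; ++e) {
      int Ja = dto[e];
      for (int Ib = 0; Ib < N; ++Ib) {
        Hp[((size_t)Ia * N + Ib) * d + (size_t)Ja * N + Ib] += dval[e];
        Hp[((size_t)Ib * N + Ia) * d + (size_t)Ib * N + Ja] += dval[e];
      }
    }
  }
  return H;
}

// spin-resolved one-particle density (alpha side): gamma[p,q] = <a+_p a_q>
// for the spin whose strings index C's columns.
// [[Rcpp::export]]
NumericMatrix cpp_rdm1_side(List tab, NumericMatrix C) {
  int norb = as<int>(tab["norb"]);
  int N = as<int>(tab["nstr"]);
  IntegerVector sptr = tab["sptr"], sto = tab["sto"], spq = tab["spq"], ssgn = tab["ssgn"];
  IntegerMatrix Occ = tab["occ"];
  NumericMatrix g(norb, norb);
  const double* Cp = C.begin();
  int n = norb;
  // diagonal
  for (int Ia = 0; Ia < N; ++Ia) {
    const double* cI = Cp + (size_t)Ia * N;
    double w = 0.0;
    for (int Ib = 0; Ib < N; ++Ib) w += cI[Ib] * cI[Ib];
    for (int p = 0; p < n; ++p) if (Occ(Ia, p)) g(p, p) += w;
  }
  // off-diagonal: <J| a+_p a_q |I> = sign, J receives
  for (int Ia = 0; Ia < N; ++Ia) {
    const double* cI = Cp + (size_t)Ia * N;
    for (int e = sptr[Ia]; e < sptr[Ia + 1]; ++e) {
      const double* cJ = Cp + (size_t)sto[e] * N;
      double dot = 0.0;
      for (int Ib = 0; Ib < N; ++Ib) dot += cI[Ib] * cJ[Ib];
      int p = spq[e] / n, q = spq[e] % n;
      g(p, q) += ssgn[e] * dot;
    }
  }
  return g;
}
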