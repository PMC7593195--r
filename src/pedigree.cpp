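#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Pedigree kernels. All take 0-based sire/dam indices with -1 for an unknown
// parent, and require parents to precede offspring (the R wrappers
// topologically sort and validate before calling down here).

// Meuwissen & Luo (1992) style computation of inbreeding coefficients,
// together with the within-family segregation variances d_i needed by
// Henderson's rules for the sparse inverse of A.
//
// Uses the decomposition A = L D L' : a_ii = sum_j L_ij^2 d_j over ancestors
// j of i, and F_i = a_ii - 1.
// [[Rcpp::export]]
List ped_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n), D(n);
  std::vector<double> L(n, 0.0);

  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    double fs = (s >= 0) ? F[s] : 0.0;
    double fd = (d >= 0) ? F[d] : 0.0;
    if (s >= 0 && d >= 0)      D[i] = 0.5  - 0.25 * (fs + fd);
    else if (s >= 0 || d >= 0) D[i] = 0.75 - 0.25 * (fs + fd);
    else                       D[i] = 1.0;

    if (s < 0 || d < 0) { F[i] = 0.0; continue; }

    // accumulate a_ii by back-propagating L from i through its ancestors
    double aii = 0.0;
    L[i] = 1.0;
    // consume contributions in decreasing index order; parents precede
    // offspring, so every descendant is processed before its ancestors
    std::priority_queue<int> q;
    q.push(i);
    while (!q.empty()) {
      int j = q.top(); q.pop();
      if (L[j] == 0.0) continue;       // already consumed (duplicate push)
      double lj = L[j];
      L[j] = 0.0;
      aii += lj * lj * D[j];
      int js = sire[j], jd = dam[j];
      if (js >= 0) { if (L[js] == 0.0) q.push(js); L[js] += 0.5 * lj; }
      if (jd >= 0) { if (L[jd] == 0.0) q.push(jd); L[jd] += 0.5 * lj; }
    }
    F[i] = aii - 1.0;
  }
  return List::create(_["F"] = F, _["D"] = D);
}

// Dense additive relationship matrix by the recursive tabular method.
// [[Rcpp::export]]
NumericMatrix ped_tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    double f = (s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0;
    A(i, i) = 1.0 + f;
  }
  return A;
}

// Henderson's rules for the sparse inverse of A, given segregation
// variances d_i from ped_inbreeding_cpp. Returns COO triplets (0-based,
// both triangles accumulated; duplicates summed by the caller).
// [[Rcpp::export]]
List ped_ainverse_cpp(IntegerVector sire, IntegerVector dam, NumericVector D) {
  const int n = sire.size();
  std::vector<int> ii, jj;
  std::vector<double> xx;
  ii.reserve(9 * n); jj.reserve(9 * n); xx.reserve(9 * n);
  auto add = [&](int a, int b, double v) {
    ii.push_back(a); jj.push_back(b); xx.push_back(v);
  };
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    const double w = 1.0 / D[i];
    add(i, i, w);
    if (s >= 0) {
      add(i, s, -0.5 * w); add(s, i, -0.5 * w);
      add(s, s, 0.25 * w);
    }
    if (d >= 0) {
      add(i, d, -0.5 * w); add(d, i, -0.5 * w);
      add(d, d, 0.25 * w);
    }
    if (s >= 0 && d >= 0) {
      add(s, d, 0.25 * w); add(d, s, 0.25 * w);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx));
}

// Monte-Carlo gene dropping: two distinct alleles per founder, Mendelian
// transmission down the pedigree; estimates the kinship matrix theta as the
// probability that one allele drawn from each of two individuals is IBD.
// Independent of the tabular/Henderson code paths, so it serves as an
// oracle for them.
// [[Rcpp::export]]
NumericMatrix ped_gene_drop_cpp(IntegerVector sire, IntegerVector dam,
                                int n_rep) {
  const int n = sire.size();
  if (n > 400) stop("gene dropping oracle is intended for small pedigrees");
  NumericMatrix theta(n, n);
  std::vector<int> a1(n), a2(n);
  for (int r = 0; r < n_rep; ++r) {
    int lab = 0;
    for (int i = 0; i < n; ++i) {
      const int s = sire[i], d = dam[i];
      a1[i] = (s >= 0) ? (unif_rand() < 0.5 ? a1[s] : a2[s]) : lab++;
      a2[i] = (d >= 0) ? (unif_rand() < 0.5 ? a1[d] : a2[d]) : lab++;
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j <= i; ++j) {
        int ibd = (a1[i] == a1[j]) + (a1[i] == a2[j]) +
                  (a2[i] == a1[j]) + (a2[i] == a2[j]);
        theta(i, j) += 0.25 * ibd;
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      theta(i, j) /= n_rep;
      theta(j, i) = theta(i, j);
    }
  return theta;
}
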