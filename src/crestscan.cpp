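#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

namespace {

struct SideResult {
  std::vector<double> values;  // EHHS at successive sites outward of the focal
  std::vector<int> indices;    // 0-based column indices of those sites
  bool censored;               // truncation threshold never reached before edge/gap
};

// Walk outward from the focal site, refining the haplotype partition by the
// allele at each new site. EHHS(x) = h([focal, x]) / h(focal) with
// h = sum_g C(n_g,2) / C(n,2) over haplotype groups g; the profile starts at
// 1 and is non-increasing outward. Stops at a chromosome edge or when the
// inter-site gap exceeds max_gap; with early_stop, also after the first site
// with EHHS < trunc (which is still reported). censored = the threshold was
// never crossed before stopping.
SideResult walk_side(const IntegerMatrix& al, const NumericVector& pos,
                     int focal, int dir, double trunc, double max_gap,
                     bool early_stop) {
  const int n = al.nrow(), L = al.ncol();
  const double pairs = 0.5 * n * (n - 1.0);
  std::vector<int> gid(n), remap(2 * n), cnt(n);
  int ng = 0;
  remap[0] = remap[1] = -1;
  const int* col = &al(0, focal);
  for (int i = 0; i < n; ++i) {
    int a = col[i];
    if (remap[a] < 0) remap[a] = ng++;
    gid[i] = remap[a];
  }
  double h0 = 0.0;
  std::fill(cnt.begin(), cnt.begin() + ng, 0);
  for (int i = 0; i < n; ++i) cnt[gid[i]]++;
  for (int g = 0; g < ng; ++g) h0 += 0.5 * cnt[g] * (cnt[g] - 1.0);
  h0 /= pairs;

  SideResult res;
  res.censored = true;
  int x = focal;
  while (true) {
    int nx = x + dir;
    if (nx < 0 || nx >= L) break;
    if (std::fabs(pos[nx] - pos[x]) > max_gap) break;
    std::fill(remap.begin(), remap.begin() + 2 * ng, -1);
    int ng_new = 0;
    col = &al(0, nx);
    for (int i = 0; i < n; ++i) {
      int key = 2 * gid[i] + col[i];
      if (remap[key] < 0) remap[key] = ng_new++;
      gid[i] = remap[key];
    }
    ng = ng_new;
    double h = 0.0;
    std::fill(cnt.begin(), cnt.begin() + ng, 0);
    for (int i = 0; i < n; ++i) cnt[gid[i]]++;
    for (int g = 0; g < ng; ++g) h += 0.5 * cnt[g] * (cnt[g] - 1.0);
    double e = h / pairs / h0;
    res.values.push_back(e);
    res.indices.push_back(nx);
    x = nx;
    if (e < trunc) {
      res.censored = false;
      if (early_stop) break;
    }
  }
  return res;
}

// trapezoidal area under EHHS vs bp on one side, from the focal site
// (value 1) out to and including the first sub-threshold site
double side_area(const std::vector<double>& v, const std::vector<int>& idx,
                 const NumericVector& pos, int focal, double trunc) {
  double area = 0.0, prev_v = 1.0, prev_p = pos[focal];
  for (size_t j = 0; j < v.size(); ++j) {
    double p = pos[idx[j]];
    area += 0.5 * (prev_v + v[j]) * std::fabs(p - prev_p);
    if (v[j] < trunc) break;
    prev_v = v[j];
    prev_p = p;
  }
  return area;
}

}  // namespace

// [[Rcpp::export]]
List ehhs_profile_cpp(IntegerMatrix alleles, NumericVector positions,
                      int focal0, double trunc, double max_gap,
                      bool early_stop) {
  SideResult l =
      walk_side(alleles, positions, focal0, -1, trunc, max_gap, early_stop);
  SideResult r =
      walk_side(alleles, positions, focal0, +1, trunc, max_gap, early_stop);
  return List::create(
      _["left_values"] = l.values, _["left_indices"] = l.indices,
      _["censored_left"] = l.censored, _["right_values"] = r.values,
      _["right_indices"] = r.indices, _["censored_right"] = r.censored);
}

// [[Rcpp::export]]
List ies_scan_cpp(IntegerMatrix alleles, NumericVector positions,
                  IntegerVector retained0, double trunc, double max_gap) {
  int m = retained0.size();
  NumericVector ies(m);
  LogicalVector cens(m);
  for (int s = 0; s < m; ++s) {
    int f = retained0[s];
    SideResult l = walk_side(alleles, positions, f, -1, trunc, max_gap, true);
    SideResult r = walk_side(alleles, positions, f, +1, trunc, max_gap, true);
    ies[s] = side_area(l.values, l.indices, positions, f, trunc) +
             side_area(r.values, r.indices, positions, f, trunc);
    cens[s] = l.censored || r.censored;
  }
  return List::create(_["ies"] = ies, _["censored"] = cens);
}

namespace {

// inverse-CDF draw from cumulative weights (always one uniform deviate, so
// the RNG stream is identical between neutral and zero-selection configs)
inline int pick_parent(const std::vector<double>& cw, double tot) {
  double u = unif_rand() * tot;
  int lo = 0, hi = (int)cw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cw[mid] < u)
      lo = mid + 1;
    else
      hi = mid;
  }
  return lo;
}

}  // namespace

// Forward Wright-Fisher evolution of a haploid panel of binary haplotypes.
// events: 3 columns (generation 1-based, haplotype 0-based, site 0-based);
// each event sets the derived allele on one haplotype after reproduction.
// sweep_col0 = -1 for neutral evolution. Haplotypes are stored contiguously
// (site-major) internally so copying and crossover are block copies.
// [[Rcpp::export]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix founding, NumericVector positions,
                            double chrom_length, double recomb_rate,
                            int n_generations, double s, int sweep_col0,
                            IntegerMatrix events) {
  const int n = founding.nrow(), L = founding.ncol();
  std::vector<int> cur((size_t)n * L), nxt((size_t)n * L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < n; ++i) cur[(size_t)i * L + j] = founding(i, j);
  std::vector<double> cw(n), bp;
  const double lambda = recomb_rate * chrom_length;
  for (int g = 1; g <= n_generations; ++g) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      double w = (s > 0 && sweep_col0 >= 0 &&
                  cur[(size_t)i * L + sweep_col0] == 1)
                     ? 1.0 + s
                     : 1.0;
      tot += w;
      cw[i] = tot;
    }
    for (int c = 0; c < n; ++c) {
      int p1 = pick_parent(cw, tot);
      int p2 = pick_parent(cw, tot);
      int* child = &nxt[(size_t)c * L];
      const int* a = &cur[(size_t)p1 * L];
      int k = (int)R::rpois(lambda);
      if (k == 0) {
        std::memcpy(child, a, sizeof(int) * L);
      } else {
        const int* b = &cur[(size_t)p2 * L];
        bp.resize(k);
        for (int t = 0; t < k; ++t) bp[t] = R::runif(0.0, chrom_length);
        std::sort(bp.begin(), bp.end());
        // copy alternating blocks of sites, switching parent at each
        // breakpoint (site j takes parent (#breakpoints <= pos[j]) mod 2)
        int j0 = 0;
        bool from_b = false;
        for (int t = 0; t < k; ++t) {
          int j1 = (int)(std::upper_bound(&positions[0], &positions[0] + L,
                                          bp[t]) -
                         &positions[0]);
          if (j1 > j0)
            std::memcpy(child + j0, (from_b ? b : a) + j0,
                        sizeof(int) * (j1 - j0));
          j0 = j1;
          from_b = !from_b;
        }
        if (L > j0)
          std::memcpy(child + j0, (from_b ? b : a) + j0,
                      sizeof(int) * (L - j0));
      }
    }
    std::swap(cur, nxt);
    for (int e = 0; e < events.nrow(); ++e)
      if (events(e, 0) == g) cur[(size_t)events(e, 1) * L + events(e, 2)] = 1;
  }
  IntegerMatrix out(n, L);
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = cur[(size_t)i * L + j];
  return out;
}
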