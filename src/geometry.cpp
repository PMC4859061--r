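#include <Rcpp.h>
#include <functional>
#include <unordered_map>
using namespace Rcpp;

static const double kDegToRad = M_PI / 180.0;

// central angle between two lon/lat points, in degrees of arc (haversine)
static inline double arc_deg(double lon1, double lat1, double lon2, double lat2) {
  double sdlat = std::sin((lat2 - lat1) * kDegToRad * 0.5);
  double sdlon = std::sin((lon2 - lon1) * kDegToRad * 0.5);
  double a = sdlat * sdlat +
    std::cos(lat1 * kDegToRad) * std::cos(lat2 * kDegToRad) * sdlon * sdlon;
  if (a < 0.0) a = 0.0;
  if (a > 1.0) a = 1.0;
  return 2.0 * std::asin(std::sqrt(a)) / kDegToRad;
}

// [[Rcpp::export]]
NumericVector cpp_arc_deg(NumericVector lon1, NumericVector lat1,
                          NumericVector lon2, NumericVector lat2) {
  R_xlen_t n = std::max(lon1.size(), lon2.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = arc_deg(lon1[i % lon1.size()], lat1[i % lat1.size()],
                     lon2[i % lon2.size()], lat2[i % lat2.size()]);
  }
  return out;
}

// |A| x |B| matrix of central angles (degrees)
// [[Rcpp::export]]
NumericMatrix cpp_cross_dist(NumericVector lonA, NumericVector latA,
                             NumericVector lonB, NumericVector latB) {
  R_xlen_t na = lonA.size(), nb = lonB.size();
  NumericMatrix out(na, nb);
  for (R_xlen_t j = 0; j < nb; ++j)
    for (R_xlen_t i = 0; i < na; ++i)
      out(i, j) = arc_deg(lonA[i], latA[i], lonB[j], latB[j]);
  return out;
}

// minimum central angle between two point sets
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericVector lonA, NumericVector latA,
                          NumericVector lonB, NumericVector latB) {
  double best = R_PosInf;
  for (R_xlen_t i = 0; i < lonA.size(); ++i)
    for (R_xlen_t j = 0; j < lonB.size(); ++j) {
      double d = arc_deg(lonA[i], latA[i], lonB[j], latB[j]);
      if (d < best) best = d;
    }
  return best;
}

// Connected components of the graph joining points at central angle <= thr
// (single-linkage blocks at threshold thr). BFS over an implicit adjacency.
// Returns 1-based component labels in first-visited order.
// [[Rcpp::export]]
IntegerVector cpp_threshold_components(NumericVector lon, NumericVector lat,
                                       double thr) {
  int n = lon.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      for (int j = 0; j < n; ++j) {
        if (lab[j]) continue;
        if (arc_deg(lon[i], lat[i], lon[j], lat[j]) <= thr) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// For each habitat point, is the nearest source point within r degrees?
// [[Rcpp::export]]
LogicalVector cpp_reachable(NumericVector slon, NumericVector slat,
                            NumericVector hlon, NumericVector hlat,
                            double r) {
  R_xlen_t ns = slon.size(), nh = hlon.size();
  LogicalVector out(nh, false);
  for (R_xlen_t j = 0; j < nh; ++j) {
    for (R_xlen_t i = 0; i < ns; ++i) {
      if (arc_deg(slon[i], slat[i], hlon[j], hlat[j]) <= r) {
        out[j] = true;
        break;
      }
    }
  }
  return out;
}

// Per-habitat-point minimum distance to the source set (degrees)
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_set(NumericVector slon, NumericVector slat,
                                  NumericVector hlon, NumericVector hlat) {
  R_xlen_t ns = slon.size(), nh = hlon.size();
  NumericVector out(nh);
  for (R_xlen_t j = 0; j < nh; ++j) {
    double best = R_PosInf;
    for (R_xlen_t i = 0; i < ns; ++i) {
      double d = arc_deg(slon[i], slat[i], hlon[j], hlat[j]);
      if (d < best) best = d;
    }
    out[j] = best;
  }
  return out;
}

// ---- fast threshold kernels on precomputed trig ------------------------
// Distance comparisons use the spherical dot product
//   cos(delta) = sin(p1) sin(p2) + cos(p1) cos(p2) cos(l1 - l2)
// with cos(l1 - l2) expanded, so the inner loops are free of
// transcendental calls. A tiny epsilon keeps the closed (<=) threshold
// inclusive under floating-point rounding.
static const double kCosEps = 1e-9;

// [[Rcpp::export]]
LogicalVector cpp_reachable_trig(NumericVector slat,
                                 NumericVector ssp, NumericVector scp,
                                 NumericVector ssl, NumericVector scl,
                                 NumericVector hlat,
                                 NumericVector hsp, NumericVector hcp,
                                 NumericVector hsl, NumericVector hcl,
                                 double r, LogicalVector skip) {
  R_xlen_t ns = slat.size(), nh = hlat.size();
  double cr = std::cos(std::min(r, 180.0) * kDegToRad) - kCosEps;
  double lo = R_PosInf, hi = R_NegInf;
  for (R_xlen_t i = 0; i < ns; ++i) {
    if (slat[i] < lo) lo = slat[i];
    if (slat[i] > hi) hi = slat[i];
  }
  lo -= r; hi += r;
  LogicalVector out(nh, false);
  for (R_xlen_t j = 0; j < nh; ++j) {
    if (skip[j]) { out[j] = true; continue; }
    if (hlat[j] < lo || hlat[j] > hi) continue;
    for (R_xlen_t i = 0; i < ns; ++i) {
      double cd = hsp[j] * ssp[i] +
        hcp[j] * scp[i] * (hcl[j] * scl[i] + hsl[j] * ssl[i]);
      if (cd >= cr) { out[j] = true; break; }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_components_trig(NumericVector lat,
                                  NumericVector sp, NumericVector cp,
                                  NumericVector sl, NumericVector cl,
                                  double thr) {
  int n = lat.size();
  double ct = std::cos(std::min(thr, 180.0) * kDegToRad) - kCosEps;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      for (int j = 0; j < n; ++j) {
        if (lab[j]) continue;
        double dl = lat[i] - lat[j];
        if (dl > thr || dl < -thr) continue;
        double cd = sp[i] * sp[j] + cp[i] * cp[j] * (cl[i] * cl[j] + sl[i] * sl[j]);
        if (cd >= ct) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Connected components of a cell set under 8-neighbour grid adjacency.
// ids are 1-based row-major cell ids; longitude wraps when global.
// [[Rcpp::export]]
IntegerVector cpp_grid_components(IntegerVector ids, int n_lon, bool global) {
  int n = ids.size();
  std::unordered_map<int, int> pos;
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) pos[ids[i]] = i;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      int row = (ids[i] - 1) / n_lon, col = (ids[i] - 1) % n_lon;
      for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int r2 = row + dr, c2 = col + dc;
        if (global) c2 = (c2 + n_lon) % n_lon;
        if (c2 < 0 || c2 >= n_lon || r2 < 0) continue;
        auto it = pos.find(r2 * n_lon + c2 + 1);
        if (it == pos.end() || lab[it->second]) continue;
        lab[it->second] = next;
        stack.push_back(it->second);
      }
    }
  }
  return lab;
}

// Is the minimum central angle between two point sets <= thr degrees?
// [[Rcpp::export]]
bool cpp_sets_within(NumericVector latA, NumericVector spA, NumericVector cpA,
                     NumericVector slA, NumericVector clA,
                     NumericVector latB, NumericVector spB, NumericVector cpB,
                     NumericVector slB, NumericVector clB, double thr) {
  double ct = std::cos(std::min(thr, 180.0) * kDegToRad) - kCosEps;
  for (R_xlen_t i = 0; i < latA.size(); ++i)
    for (R_xlen_t j = 0; j < latB.size(); ++j) {
      double dl = latA[i] - latB[j];
      if (dl > thr || dl < -thr) continue;
      double cd = spA[i] * spB[j] +
        cpA[i] * cpB[j] * (clA[i] * clB[j] + slA[i] * slB[j]);
      if (cd >= ct) return true;
    }
  return false;
}

// splitmix64 avalanche: one well-mixed uniform per (seed, phase, id, step)
static inline double hash_uniform(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  x = x ^ (x >> 31);
  return ((x >> 11) + 0.5) / 9007199254740992.0; // 2^53
}

// [[Rcpp::export]]
NumericVector cpp_stream_uniform(double seed, int phase,
                                 IntegerVector ids, int step) {
  NumericVector out(ids.size());
  uint64_t base = (uint64_t)seed * 2654435761ULL + (uint64_t)phase;
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    uint64_t x = base;
    x = x * 6364136223846793005ULL + (uint64_t)ids[i];
    x = x * 6364136223846793005ULL + (uint64_t)step;
    out[i] = hash_uniform(x);
  }
  return out;
}

// Whole-step parapatric clustering: one element per species, the 1-based
// block label of each range cell (all labels 1 when the range is one
// block). Trig vectors are full-grid, indexed by cell id.
// [[Rcpp::export]]
List cpp_cluster_all(List ranges, int n_lon, bool global, double thr,
                     NumericVector lat, NumericVector sp, NumericVector cp,
                     NumericVector sl, NumericVector cl, double diag_max) {
  int S = ranges.size();
  List out(S);
  double ct = std::cos(std::min(thr, 180.0) * kDegToRad) - kCosEps;
  std::unordered_map<int, int> pos;
  for (int s = 0; s < S; ++s) {
    IntegerVector rng = ranges[s];
    int n = rng.size();
    IntegerVector lab(n, 1);
    if (n < 2) { out[s] = lab; continue; }
    if (thr < diag_max) {
      // small threshold: full pairwise single-linkage BFS
      std::fill(lab.begin(), lab.end(), 0);
      std::vector<int> stack;
      int next = 0;
      for (int s0 = 0; s0 < n; ++s0) {
        if (lab[s0]) continue;
        lab[s0] = ++next;
        stack.push_back(s0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int ci = rng[i] - 1;
          for (int j = 0; j < n; ++j) {
            if (lab[j]) continue;
            int cj = rng[j] - 1;
            double dl = lat[ci] - lat[cj];
            if (dl > thr || dl < -thr) continue;
            double cd = sp[ci] * sp[cj] +
              cp[ci] * cp[cj] * (cl[ci] * cl[cj] + sl[ci] * sl[cj]);
            if (cd >= ct) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
      out[s] = lab;
      continue;
    }
    // flood fill over 8-neighbour adjacency
    pos.clear();
    for (int i = 0; i < n; ++i) pos[rng[i]] = i;
    std::fill(lab.begin(), lab.end(), 0);
    std::vector<int> stack;
    int k = 0;
    for (int s0 = 0; s0 < n; ++s0) {
      if (lab[s0]) continue;
      lab[s0] = ++k;
      stack.push_back(s0);
      while (!stack.empty()) {
        int i = stack.back(); stack.pop_back();
        int row = (rng[i] - 1) / n_lon, col = (rng[i] - 1) % n_lon;
        for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int r2 = row + dr, c2 = col + dc;
          if (global) c2 = (c2 + n_lon) % n_lon;
          if (c2 < 0 || c2 >= n_lon || r2 < 0) continue;
          auto it = pos.find(r2 * n_lon + c2 + 1);
          if (it == pos.end() || lab[it->second]) continue;
          lab[it->second] = k;
          stack.push_back(it->second);
        }
      }
    }
    if (k > 1) {
      // single-linkage merge of adjacency components at threshold thr
      std::vector<int> parent(k + 1);
      for (int i = 0; i <= k; ++i) parent[i] = i;
      std::function<int(int)> find = [&](int i) {
        while (parent[i] != i) i = parent[i] = parent[parent[i]];
        return i;
      };
      std::vector<std::vector<int>> comp(k + 1);
      for (int i = 0; i < n; ++i) comp[lab[i]].push_back(rng[i] - 1);
      for (int a = 1; a < k; ++a) for (int b = a + 1; b <= k; ++b) {
        if (find(a) == find(b)) continue;
        bool hit = false;
        for (size_t i = 0; i < comp[a].size() && !hit; ++i) {
          int ci = comp[a][i];
          for (size_t j = 0; j < comp[b].size(); ++j) {
            int cj = comp[b][j];
            double dl = lat[ci] - lat[cj];
            if (dl > thr || dl < -thr) continue;
            double cd = sp[ci] * sp[cj] +
              cp[ci] * cp[cj] * (cl[ci] * cl[cj] + sl[ci] * sl[cj]);
            if (cd >= ct) { hit = true; break; }
          }
        }
        if (hit) parent[find(b)] = find(a);
      }
      // relabel to 1..m in first-appearance order
      std::vector<int> newlab(k + 1, 0);
      int m = 0;
      for (int i = 0; i < n; ++i) {
        int r = find(lab[i]);
        if (!newlab[r]) newlab[r] = ++m;
        lab[i] = newlab[r];
      }
    }
    out[s] = lab;
  }
  return out;
}

// Whole-step dispersal: for each species, the next-step range (habitat
// cells within reach r of its current range). occ is a reusable scratch
// marker over cells.
// [[Rcpp::export]]
List cpp_dispersal_all(List ranges, IntegerVector hab, NumericVector r,
                       NumericVector lat, NumericVector sp, NumericVector cp,
                       NumericVector sl, NumericVector cl,
                       LogicalVector hmask, double min_spacing) {
  int S = ranges.size();
  int nh = hab.size();
  List out(S);
  std::vector<char> occ((size_t)hmask.size() + 1, 0);
  for (int s = 0; s < S; ++s) {
    IntegerVector rng = ranges[s];
    int n = rng.size();
    std::vector<int> keep;
    if (r[s] < min_spacing) {
      for (int i = 0; i < n; ++i) if (hmask[rng[i] - 1]) keep.push_back(rng[i]);
      out[s] = IntegerVector(keep.begin(), keep.end());
      continue;
    }
    double cr = std::cos(std::min(r[s], 180.0) * kDegToRad) - kCosEps;
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      occ[rng[i]] = 1;
      double la = lat[rng[i] - 1];
      if (la < lo) lo = la;
      if (la > hi) hi = la;
    }
    lo -= r[s]; hi += r[s];
    for (int j = 0; j < nh; ++j) {
      int cj = hab[j] - 1;
      if (occ[hab[j]]) { keep.push_back(hab[j]); continue; }
      if (lat[cj] < lo || lat[cj] > hi) continue;
      for (int i = 0; i < n; ++i) {
        int ci = rng[i] - 1;
        double cd = sp[ci] * sp[cj] +
          cp[ci] * cp[cj] * (cl[ci] * cl[cj] + sl[ci] * sl[cj]);
        if (cd >= cr) { keep.push_back(hab[j]); break; }
      }
    }
    for (int i = 0; i < n; ++i) occ[rng[i]] = 0;
    out[s] = IntegerVector(keep.begin(), keep.end());
  }
  return out;
}
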