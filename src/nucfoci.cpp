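#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// R matrices are column-major: linear index of (r, c) is r + c * h (0-based).
// Scan order throughout is row-major (row by row, left to right), matching
// the labeling contract "top-left-first".

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int ndir = (connectivity == 8) ? 8 : 4;
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  int next = 0;
  std::queue<int> q;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      int i = r + c * h;
      if (!mask[i] || lab[i] != 0) continue;
      ++next;
      lab[i] = next;
      q.push(i);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        int cr = cur % h, cc = cur / h;
        for (int d = 0; d < ndir; ++d) {
          int nr = cr + (ndir == 8 ? DR8[d] : dr4[d]);
          int nc = cc + (ndir == 8 ? DC8[d] : dc4[d]);
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          int j = nr + nc * h;
          if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: flood the complement from the image border with
// 4-connectivity (the dual of 8-connected foreground); anything in the
// complement not reached from the border is a hole and becomes foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  std::vector<char> outside((size_t) h * w, 0);
  std::queue<int> q;
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      if (r != 0 && r != h - 1 && c != 0 && c != w - 1) continue;
      int i = r + c * h;
      if (!mask[i] && !outside[i]) { outside[i] = 1; q.push(i); }
    }
  }
  static const int dr[4] = {-1, 1, 0, 0};
  static const int dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int cr = cur % h, cc = cur / h;
    for (int d = 0; d < 4; ++d) {
      int nr = cr + dr[d], nc = cc + dc[d];
      if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
      int j = nr + nc * h;
      if (!mask[j] && !outside[j]) { outside[j] = 1; q.push(j); }
    }
  }
  LogicalMatrix out(h, w);
  for (int i = 0; i < h * w; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// Noise-tolerance local maxima under the prominence rule.
//
// Candidates are 8-connected plateaus of equal intensity inside the mask
// with no strictly higher masked neighbour AND at least one strictly lower
// masked neighbour (the latter makes a fully flat component, including a
// globally constant plane, yield no maxima). A candidate plateau at
// intensity I is rejected iff a strictly higher masked pixel can be reached
// from it along an 8-connected path whose every pixel has intensity
// > I - tol. Accepted plateaus are represented by the plateau pixel closest
// to the plateau centroid (ties: scan order) and returned sorted by
// descending intensity, ties by scan order of the representative.
// [[Rcpp::export]]
DataFrame cpp_find_maxima(NumericMatrix plane, LogicalMatrix mask,
                          double tol, bool exclude_edge) {
  int h = plane.nrow(), w = plane.ncol();
  int n = h * w;
  std::vector<int> plab((size_t) n, -1);
  std::vector< std::vector<int> > pixels; // per-plateau pixel lists
  std::vector<double> pval;
  std::vector<char> has_higher, has_lower;
  std::queue<int> q;

  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      int i = r + c * h;
      if (!mask[i] || plab[i] >= 0) continue;
      int id = (int) pixels.size();
      double v = plane[i];
      pixels.push_back(std::vector<int>());
      pval.push_back(v);
      has_higher.push_back(0);
      has_lower.push_back(0);
      plab[i] = id;
      q.push(i);
      while (!q.empty()) {
        int cur = q.front(); q.pop();
        pixels[id].push_back(cur);
        int cr = cur % h, cc = cur / h;
        for (int d = 0; d < 8; ++d) {
          int nr = cr + DR8[d], nc = cc + DC8[d];
          if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
          int j = nr + nc * h;
          if (!mask[j]) continue;
          double vj = plane[j];
          if (vj == v) {
            if (plab[j] < 0) { plab[j] = id; q.push(j); }
          } else if (vj > v) {
            has_higher[id] = 1;
          } else {
            has_lower[id] = 1;
          }
        }
      }
    }
  }

  // stamped visited array reused across candidate floods
  std::vector<int> stamp((size_t) n, -1);
  std::vector<int> acc_rep;      // representative linear index
  std::vector<double> acc_val;
  std::queue<int> fq;

  int np = (int) pixels.size();
  for (int id = 0; id < np; ++id) {
    if (has_higher[id] || !has_lower[id]) continue;
    double I = pval[id];
    bool reject = false;
    for (size_t k = 0; k < pixels[id].size(); ++k) {
      stamp[pixels[id][k]] = id;
      fq.push(pixels[id][k]);
    }
    while (!fq.empty()) {
      int cur = fq.front(); fq.pop();
      if (reject) continue; // drain queue
      int cr = cur % h, cc = cur / h;
      for (int d = 0; d < 8; ++d) {
        int nr = cr + DR8[d], nc = cc + DC8[d];
        if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
        int j = nr + nc * h;
        if (!mask[j] || stamp[j] == id) continue;
        double vj = plane[j];
        if (vj > I) { reject = true; break; }
        if (vj > I - tol) { stamp[j] = id; fq.push(j); }
      }
    }
    while (!fq.empty()) fq.pop();
    if (reject) continue;

    // plateau centroid, snapped to the nearest plateau pixel
    double mr = 0.0, mc = 0.0;
    for (size_t k = 0; k < pixels[id].size(); ++k) {
      mr += pixels[id][k] % h;
      mc += pixels[id][k] / h;
    }
    mr /= pixels[id].size();
    mc /= pixels[id].size();
    int best = -1;
    double bestd = 0.0;
    long bestscan = 0;
    for (size_t k = 0; k < pixels[id].size(); ++k) {
      int pr = pixels[id][k] % h, pc = pixels[id][k] / h;
      double d2 = (pr - mr) * (pr - mr) + (pc - mc) * (pc - mc);
      long scan = (long) pr * w + pc;
      if (best < 0 || d2 < bestd - 1e-12 ||
          (std::abs(d2 - bestd) <= 1e-12 && scan < bestscan)) {
        best = pixels[id][k]; bestd = d2; bestscan = scan;
      }
    }
    int br = best % h, bc = best / h;
    if (exclude_edge && (br == 0 || br == h - 1 || bc == 0 || bc == w - 1))
      continue;
    acc_rep.push_back(best);
    acc_val.push_back(I);
  }

  // sort by descending intensity, ties by scan order of representative
  int m = (int) acc_rep.size();
  std::vector<int> ord(m);
  for (int k = 0; k < m; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (acc_val[a] != acc_val[b]) return acc_val[a] > acc_val[b];
    long sa = (long) (acc_rep[a] % h) * w + acc_rep[a] / h;
    long sb = (long) (acc_rep[b] % h) * w + acc_rep[b] / h;
    return sa < sb;
  });
  IntegerVector row(m), col(m);
  NumericVector val(m);
  for (int k = 0; k < m; ++k) {
    int i = acc_rep[ord[k]];
    row[k] = i % h + 1; // 1-based (row, col), the R convention
    col[k] = i / h + 1;
    val[k] = acc_val[ord[k]];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["intensity"] = val);
}
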