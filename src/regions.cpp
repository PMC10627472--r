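// Connected-component labeling and outer-contour tracing for binary masks.
// The contour tracer (Moore neighborhood) yields the closed boundary walk
// through pixel centers; its arc length uses unit steps for 4-neighbor moves
// and sqrt(2) for diagonal moves.

#include <Rcpp.h>
#include <vector>
#include <cmath>

// [[Rcpp::export(name = ".label_components")]]
Rcpp::IntegerMatrix label_components_cpp(Rcpp::IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;

  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      stack.clear();
      stack.push_back(r + H * c);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr_ = p % H, pc_ = p / H;
        for (int k = 0; k < nn; ++k) {
          int nr = pr_ + dr[k], nc = pc_ + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(nr + H * nc);
          }
        }
      }
    }
  }
  return lab;
}

// Trace the outer contour of the component carrying `label`.
// Moore-neighbor tracing starting at the topmost-leftmost pixel with a West
// backtrack; terminates when the walk is back at the start pixel and about to
// repeat its first move (the traversal state recurs, so the closed boundary
// walk is complete). Isolated single pixels get perimeter 1 by convention.
// Returns list(perimeter, contour = k x 2 matrix of 1-based (row, col)).
// [[Rcpp::export(name = ".trace_contour")]]
Rcpp::List trace_contour_cpp(Rcpp::IntegerMatrix lab, int label) {
  const int H = lab.nrow(), W = lab.ncol();
  // clockwise Moore neighborhood starting East
  const int dr[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int dc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  auto dir_index = [&](int ddr, int ddc) {
    for (int k = 0; k < 8; ++k) if (dr[k] == ddr && dc[k] == ddc) return k;
    return -1;
  };

  int r0 = -1, c0 = -1;
  for (int r = 0; r < H && r0 < 0; ++r)       // topmost, then leftmost
    for (int c = 0; c < W; ++c)
      if (lab(r, c) == label) { r0 = r; c0 = c; break; }
  if (r0 < 0) Rcpp::stop("label not present in image");

  std::vector<int> rows(1, r0), cols(1, c0);
  double per = 1.0;                            // single-pixel convention

  bool isolated = true;
  for (int k = 0; k < 8; ++k) {
    int nr = r0 + dr[k], nc = c0 + dc[k];
    if (nr >= 0 && nr < H && nc >= 0 && nc < W && lab(nr, nc) == label) {
      isolated = false; break;
    }
  }

  if (!isolated) {
    per = 0.0;
    int cr = r0, cc = c0;
    int b = 4;                                 // backtrack direction: West
    int k1 = -1;                               // first move direction
    const std::size_t cap = (std::size_t)8 * H * W + 64;
    for (std::size_t steps = 0; steps <= cap; ++steps) {
      int found = -1;
      for (int t = 1; t <= 8; ++t) {           // clockwise scan from backtrack
        int k = (b + t) % 8;
        int nr = cr + dr[k], nc = cc + dc[k];
        if (nr >= 0 && nr < H && nc >= 0 && nc < W && lab(nr, nc) == label) {
          found = k; break;
        }
      }
      if (found < 0) break;                    // cannot happen when not isolated
      if (k1 < 0) k1 = found;
      else if (cr == r0 && cc == c0 && found == k1) break;  // walk complete
      // the neighbor examined just before `found` is background; it becomes
      // the new backtrack, viewed from the new pixel
      int prev = (found + 7) % 8;
      int bgr = cr + dr[prev], bgc = cc + dc[prev];
      int nr = cr + dr[found], nc = cc + dc[found];
      per += (dr[found] != 0 && dc[found] != 0) ? std::sqrt(2.0) : 1.0;
      b = dir_index(bgr - nr, bgc - nc);
      cr = nr; cc = nc;
      if (!(cr == r0 && cc == c0)) { rows.push_back(cr); cols.push_back(cc); }
    }
  }

  Rcpp::IntegerMatrix contour(rows.size(), 2);
  for (std::size_t i = 0; i < rows.size(); ++i) {
    contour(i, 0) = rows[i] + 1;
    contour(i, 1) = cols[i] + 1;
  }
  return Rcpp::List::create(Rcpp::Named("perimeter") = per,
                            Rcpp::Named("contour") = contour);
}

// Fill interior holes: background 4-connected components not reachable from
// the image border become foreground.
// [[Rcpp::export(name = ".fill_holes")]]
Rcpp::IntegerMatrix fill_holes_cpp(Rcpp::IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<char> outside((std::size_t)H * W, 0);
  std::vector<int> stack;
  auto push = [&](int r, int c) {
    if (r < 0 || r >= H || c < 0 || c >= W) return;
    std::size_t i = (std::size_t)r + (std::size_t)H * c;
    if (!outside[i] && mask(r, c) == 0) { outside[i] = 1; stack.push_back((int)i); }
  };
  for (int c = 0; c < W; ++c) { push(0, c); push(H - 1, c); }
  for (int r = 0; r < H; ++r) { push(r, 0); push(r, W - 1); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int r = p % H, c = p / H;
    push(r - 1, c); push(r + 1, c); push(r, c - 1); push(r, c + 1);
  }
  Rcpp::IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = (mask(r, c) != 0 || !outside[(std::size_t)r + (std::size_t)H * c]) ? 1 : 0;
  return out;
}
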