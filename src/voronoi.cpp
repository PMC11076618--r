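#include <Rcpp.h>
using namespace Rcpp;

// Discrete Voronoi assignment on a pixel grid.
//
// For every pixel (row-major over an ny x nx grid, pixel centres at
// (col + 0.5, row + 0.5) in pixel units) find the nearest and second
// nearest seed point. The gap d2 - d1 measures twice the distance to the
// Voronoi boundary, so thresholding it carves an interstitial band of a
// prescribed physical width between neighbouring cells.
//
// Returns a list with integer label (1-based seed index of the nearest
// seed), d1 and d2 (euclidean distances in pixel units).
// [[Rcpp::export]]
List voronoi_assign(int ny, int nx, NumericVector sx, NumericVector sy) {
  const int ns = sx.size();
  if (ns < 1) stop("at least one seed point required");
  IntegerVector label(ny * nx);
  NumericVector d1(ny * nx), d2(ny * nx);

  // Spatial hash: bucket seeds on a coarse grid (~1 seed per cell) and
  // search outward in Chebyshev rings; a ring at distance k+1 cannot hold
  // a point closer than k*g, which bounds the search.
  const double g = std::max(1.0, std::sqrt((double)nx * ny / ns));
  const int gx = (int)std::ceil(nx / g), gy = (int)std::ceil(ny / g);
  std::vector<int> count(gx * gy + 1, 0);
  std::vector<int> cell(ns);
  for (int s = 0; s < ns; ++s) {
    int cx = std::min(gx - 1, std::max(0, (int)(sx[s] / g)));
    int cy = std::min(gy - 1, std::max(0, (int)(sy[s] / g)));
    cell[s] = cy + gy * cx;
    count[cell[s] + 1]++;
  }
  for (int c = 0; c < gx * gy; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(ns);
  {
    std::vector<int> pos(count.begin(), count.end() - 1);
    for (int s = 0; s < ns; ++s) bucket[pos[cell[s]]++] = s;
  }
  const int kmax = std::max(gx, gy);

  for (int row = 0; row < ny; ++row) {
    const double py = row + 0.5;
    const int cy0 = std::min(gy - 1, (int)(py / g));
    for (int col = 0; col < nx; ++col) {
      const double px = col + 0.5;
      const int cx0 = std::min(gx - 1, (int)(px / g));
      double best = R_PosInf, second = R_PosInf;
      int ibest = 0;
      for (int k = 0; k <= kmax; ++k) {
        if (k > 0) {
          const double reach = (k - 1) * g;
          if (second < reach * reach) break;
        }
        for (int cx = cx0 - k; cx <= cx0 + k; ++cx) {
          if (cx < 0 || cx >= gx) continue;
          for (int cy = cy0 - k; cy <= cy0 + k; ++cy) {
            if (cy < 0 || cy >= gy) continue;
            if (std::max(std::abs(cx - cx0), std::abs(cy - cy0)) != k) continue;
            const int c = cy + gy * cx;
            for (int b = count[c]; b < count[c + 1]; ++b) {
              const int s = bucket[b];
              const double dx = px - sx[s], dy = py - sy[s];
              const double dd = dx * dx + dy * dy;
              if (dd < best) {
                second = best;
                best = dd;
                ibest = s;
              } else if (dd < second) {
                second = dd;
              }
            }
          }
        }
      }
      const int idx = row + ny * col;  // column-major, matches R matrices
      label[idx] = ibest + 1;
      d1[idx] = std::sqrt(best);
      d2[idx] = ns > 1 ? std::sqrt(second) : R_PosInf;
    }
  }
  label.attr("dim") = Dimension(ny, nx);
  d1.attr("dim") = Dimension(ny, nx);
  d2.attr("dim") = Dimension(ny, nx);
  return List::create(_["label"] = label, _["d1"] = d1, _["d2"] = d2);
}
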