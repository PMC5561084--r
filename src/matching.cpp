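#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive cube matching in a local search window.
//
// vol: volume as a numeric vector in Fortran (column-major) order
// dim: the three array dimensions
// ref: 1-based corner of the reference cube
// cube: cube side length
// radius: search radius in voxels (window is (2*radius+1)^3 corners,
//         clipped to the volume)
// max_group: number of cubes to keep (smallest distances, reference first)
// Returns corners (G x 3, 1-based) and mean-squared-difference distances
// in ascending order with the reference (distance 0) first.
// [[Rcpp::export]]
List cpp_match_cubes(NumericVector vol, IntegerVector dim, IntegerVector ref,
                     int cube, int radius, int max_group) {
  const int dx = dim[0], dy = dim[1], dz = dim[2];
  const int rx = ref[0] - 1, ry = ref[1] - 1, rz = ref[2] - 1;
  const double *v = REAL(vol);
  const int n3 = cube * cube * cube;

  // gather the reference cube
  std::vector<double> refc(n3);
  {
    int t = 0;
    for (int k = 0; k < cube; ++k)
      for (int j = 0; j < cube; ++j)
        for (int i = 0; i < cube; ++i)
          refc[t++] = v[(rx + i) + (size_t)dx * ((ry + j) + (size_t)dy * (rz + k))];
  }

  const int x0 = std::max(0, rx - radius), x1 = std::min(dx - cube, rx + radius);
  const int y0 = std::max(0, ry - radius), y1 = std::min(dy - cube, ry + radius);
  const int z0 = std::max(0, rz - radius), z1 = std::min(dz - cube, rz + radius);

  struct Cand { double d; int x, y, z; };
  std::vector<Cand> cands;
  cands.reserve((size_t)(x1 - x0 + 1) * (y1 - y0 + 1) * (z1 - z0 + 1));

  for (int cz = z0; cz <= z1; ++cz)
    for (int cy = y0; cy <= y1; ++cy)
      for (int cx = x0; cx <= x1; ++cx) {
        double ss = 0.0;
        int t = 0;
        for (int k = 0; k < cube; ++k)
          for (int j = 0; j < cube; ++j) {
            const double *row =
              v + (cx) + (size_t)dx * ((cy + j) + (size_t)dy * (cz + k));
            for (int i = 0; i < cube; ++i) {
              double df = row[i] - refc[t++];
              ss += df * df;
            }
          }
        Cand c;
        c.d = ss / n3; c.x = cx; c.y = cy; c.z = cz;
        if (cx == rx && cy == ry && cz == rz) c.d = -1.0; // reference sorts first
        cands.push_back(c);
      }

  int keep = std::min((int)cands.size(), max_group);
  std::partial_sort(cands.begin(), cands.begin() + keep, cands.end(),
                    [](const Cand &a, const Cand &b) { return a.d < b.d; });

  IntegerMatrix corners(keep, 3);
  NumericVector dist(keep);
  for (int g = 0; g < keep; ++g) {
    corners(g, 0) = cands[g].x + 1;
    corners(g, 1) = cands[g].y + 1;
    corners(g, 2) = cands[g].z + 1;
    dist[g] = cands[g].d < 0 ? 0.0 : cands[g].d;
  }
  return List::create(_["corners"] = corners, _["distances"] = dist);
}
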