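#include <Rcpp.h>
using namespace Rcpp;

// Minimum distance from each query point to a densely sampled polyline,
// plus the arc-length position of the nearest polyline vertex.  The
// polyline is assumed dense enough (resampled well below voxel spacing)
// that vertex distance is an adequate stand-in for segment distance.
//
// pts:   n x 3 query points (mm)
// curve: m x 3 polyline vertices (mm)
// arc:   length-m cumulative arc length at each vertex (mm)
// [[Rcpp::export(name = ".dist_to_polyline_cpp")]]
List dist_to_polyline_cpp(NumericMatrix pts, NumericMatrix curve,
                          NumericVector arc) {
  const int n = pts.nrow();
  const int m = curve.nrow();
  NumericVector dist(n);
  NumericVector at_arc(n);

  const double *cx = &curve(0, 0);
  const double *cy = &curve(0, 1);
  const double *cz = &curve(0, 2);

  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    int best_j = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - cx[j];
      const double dy = py - cy[j];
      const double dz = pz - cz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        best_j = j;
      }
    }
    dist[i] = std::sqrt(best);
    at_arc[i] = arc[best_j];
  }
  return List::create(_["dist_mm"] = dist, _["arc_mm"] = at_arc);
}
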