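#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// First-interception ray casting of a parallel beam through a triangle scene
// that is doubly periodic in x and y (torus emulation of an infinite stand).
//
// Rays travel downward from direction (zenith, azimuth). Shearing every
// vertex by u = x - z*tan(zen)*cos(az), v = y - z*tan(zen)*sin(az) makes the
// rays vertical in (u, v); a ray indexed by its ground intercept hits a
// triangle iff the point lies inside the sheared triangle, and the first
// interception along the ray is the hit with the largest z. Periodicity is
// handled exactly by replicating each sheared triangle into every unit tile
// its bounding box overlaps (the replication span is capped at max_tiles plot
// widths, the path-length cap for grazing directions).
//
// tris: n x 9 (v1x v1y v1z v2x v2y v2z v3x v3y v3z), metres.
// tri_class: 1-based class per triangle (e.g. species); n_class classes.
// Returns integer counts of first hits per class, plus one trailing entry for
// rays reaching the soil; total equals the number of rays cast
// (nx_rays * ny_rays stratified jittered cells covering the footprint).

struct Copy {
  double u0, v0, u1, v1, u2, v2, z0, z1, z2;
  int cls;
};

// [[Rcpp::export]]
IntegerVector raycast_direction_cpp(NumericMatrix tris, IntegerVector tri_class,
                                    int n_class, double lx, double ly,
                                    double zenith_deg, double azimuth_deg,
                                    int n_rays, int max_tiles = 10) {
  if (lx <= 0.0 || ly <= 0.0) stop("degenerate footprint");
  if (n_rays < 1) stop("n_rays must be >= 1");
  if (zenith_deg < 0.0 || zenith_deg >= 90.0)
    stop("zenith must lie in [0, 90)");
  const int ntri = tris.nrow();
  const double zen = zenith_deg * M_PI / 180.0;
  const double az = azimuth_deg * M_PI / 180.0;
  const double su = std::tan(zen) * std::cos(az);
  const double sv = std::tan(zen) * std::sin(az);

  // Shear and replicate into the base tile.
  std::vector<Copy> copies;
  copies.reserve(ntri * 2);
  for (int i = 0; i < ntri; ++i) {
    double z0 = tris(i, 2), z1 = tris(i, 5), z2 = tris(i, 8);
    double u0 = tris(i, 0) - z0 * su, v0 = tris(i, 1) - z0 * sv;
    double u1 = tris(i, 3) - z1 * su, v1 = tris(i, 4) - z1 * sv;
    double u2 = tris(i, 6) - z2 * su, v2 = tris(i, 7) - z2 * sv;
    double umin = std::min({u0, u1, u2}), umax = std::max({u0, u1, u2});
    double vmin = std::min({v0, v1, v2}), vmax = std::max({v0, v1, v2});
    int iu0 = (int)std::ceil(-umax / lx), iu1 = (int)std::floor((lx - umin) / lx);
    int iv0 = (int)std::ceil(-vmax / ly), iv1 = (int)std::floor((ly - vmin) / ly);
    iu0 = std::max(iu0, -max_tiles); iu1 = std::min(iu1, max_tiles);
    iv0 = std::max(iv0, -max_tiles); iv1 = std::min(iv1, max_tiles);
    for (int iu = iu0; iu <= iu1; ++iu) {
      for (int iv = iv0; iv <= iv1; ++iv) {
        Copy c;
        c.u0 = u0 + iu * lx; c.v0 = v0 + iv * ly;
        c.u1 = u1 + iu * lx; c.v1 = v1 + iv * ly;
        c.u2 = u2 + iu * lx; c.v2 = v2 + iv * ly;
        c.z0 = z0; c.z1 = z1; c.z2 = z2;
        c.cls = tri_class[i];
        copies.push_back(c);
      }
    }
  }

  // Uniform grid over the base tile.
  int g = (int)std::sqrt((double)std::max((size_t)1, copies.size()));
  g = std::max(8, std::min(128, g));
  std::vector<std::vector<int>> cells((size_t)g * g);
  for (size_t k = 0; k < copies.size(); ++k) {
    const Copy &c = copies[k];
    double umin = std::min({c.u0, c.u1, c.u2}), umax = std::max({c.u0, c.u1, c.u2});
    double vmin = std::min({c.v0, c.v1, c.v2}), vmax = std::max({c.v0, c.v1, c.v2});
    int cu0 = std::max(0, (int)std::floor(umin / lx * g));
    int cu1 = std::min(g - 1, (int)std::floor(umax / lx * g));
    int cv0 = std::max(0, (int)std::floor(vmin / ly * g));
    int cv1 = std::min(g - 1, (int)std::floor(vmax / ly * g));
    for (int cu = cu0; cu <= cu1; ++cu)
      for (int cv = cv0; cv <= cv1; ++cv)
        cells[(size_t)cu * g + cv].push_back((int)k);
  }

  // Stratified-jittered ray budget over the footprint.
  int nx = std::max(1, (int)std::lround(std::sqrt((double)n_rays * lx / ly)));
  int ny = std::max(1, (int)(n_rays / nx));
  IntegerVector counts(n_class + 1);
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      double u = (ix + R::unif_rand()) * lx / nx;
      double v = (iy + R::unif_rand()) * ly / ny;
      int cu = std::min(g - 1, (int)(u / lx * g));
      int cv = std::min(g - 1, (int)(v / ly * g));
      const std::vector<int> &cell = cells[(size_t)cu * g + cv];
      double zbest = -1.0;
      int best = -1;
      for (size_t j = 0; j < cell.size(); ++j) {
        const Copy &c = copies[cell[j]];
        double det = (c.v1 - c.v2) * (c.u0 - c.u2) + (c.u2 - c.u1) * (c.v0 - c.v2);
        if (std::fabs(det) < 1e-300) continue;  // edge-on sheared triangle
        double a = ((c.v1 - c.v2) * (u - c.u2) + (c.u2 - c.u1) * (v - c.v2)) / det;
        double b = ((c.v2 - c.v0) * (u - c.u2) + (c.u0 - c.u2) * (v - c.v2)) / det;
        double cc = 1.0 - a - b;
        if (a < 0.0 || b < 0.0 || cc < 0.0) continue;
        double z = a * c.z0 + b * c.z1 + cc * c.z2;
        if (z > zbest) { zbest = z; best = c.cls; }
      }
      if (best > 0) counts[best - 1]++; else counts[n_class]++;
    }
  }
  return counts;
}
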