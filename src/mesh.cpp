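#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Isosurface area by marching tetrahedra: each grid cell is split into six
// tetrahedra sharing the main diagonal; the level set is linearly
// interpolated along tetrahedron edges. Positions are voxel-center
// coordinates scaled by the physical spacing, so the returned area is in
// squared physical units.

struct P3 { double x, y, z; };

static inline P3 lerp(const P3& a, const P3& b, double va, double vb,
                      double level) {
  double t = (level - va) / (vb - va);
  P3 p; p.x = a.x + t * (b.x - a.x); p.y = a.y + t * (b.y - a.y);
  p.z = a.z + t * (b.z - a.z); return p;
}

static inline double tri_area(const P3& a, const P3& b, const P3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static double tet_area(const P3 p[4], const double v[4], double level) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = v[i] >= level; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return 0.0;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) { if (in[i]) a[na++] = i; else b[nb++] = i; }
  if (nin == 1 || nin == 3) {
    int apex = (nin == 1) ? a[0] : b[0];
    int oth[3]; int k = 0;
    for (int i = 0; i < 4; ++i) if (i != apex) oth[k++] = i;
    P3 q0 = lerp(p[apex], p[oth[0]], v[apex], v[oth[0]], level);
    P3 q1 = lerp(p[apex], p[oth[1]], v[apex], v[oth[1]], level);
    P3 q2 = lerp(p[apex], p[oth[2]], v[apex], v[oth[2]], level);
    return tri_area(q0, q1, q2);
  }
  // 2-2 case: quad p(a0,b0) p(a0,b1) p(a1,b1) p(a1,b0)
  P3 q0 = lerp(p[a[0]], p[b[0]], v[a[0]], v[b[0]], level);
  P3 q1 = lerp(p[a[0]], p[b[1]], v[a[0]], v[b[1]], level);
  P3 q2 = lerp(p[a[1]], p[b[1]], v[a[1]], v[b[1]], level);
  P3 q3 = lerp(p[a[1]], p[b[0]], v[a[1]], v[b[0]], level);
  return tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
}

// [[Rcpp::export]]
double mesh_area_cpp(NumericVector field, IntegerVector dim,
                     NumericVector spacing, double level) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* V = REAL(field);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // corner offsets, bit order (x, y, z)
  const int ox[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  const int oy[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  const int oz[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  // six tetrahedra around the 0-7 diagonal
  const int tets[6][4] = {{0, 5, 1, 7}, {0, 1, 3, 7}, {0, 3, 2, 7},
                          {0, 2, 6, 7}, {0, 6, 4, 7}, {0, 4, 5, 7}};
  double total = 0.0;
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double cv[8]; P3 cp[8];
        bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          int xx = x + ox[c], yy = y + oy[c], zz = z + oz[c];
          cv[c] = V[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
          cp[c].x = xx * sx; cp[c].y = yy * sy; cp[c].z = zz * sz;
          if (cv[c] >= level) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          P3 tp[4]; double tv[4];
          for (int i = 0; i < 4; ++i) { tp[i] = cp[tets[t][i]]; tv[i] = cv[tets[t][i]]; }
          total += tet_area(tp, tv, level);
        }
      }
  return total;
}
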