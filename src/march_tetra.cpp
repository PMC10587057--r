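// Iso-surface extraction at level 0 by marching tetrahedra: each grid cube
// is split into six tetrahedra around the 0-6 diagonal and each tetrahedron
// contributes 0, 1 or 2 triangles with linearly interpolated edge crossings.
// Grid values exactly 0 are treated as outside (solid is f > 0), matching
// the strict inequality used for voxelisation.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

inline V3 lerp(const V3& p, const V3& q, double fp, double fq) {
  const double t = fp / (fp - fq);
  V3 r;
  r.x = p.x + t * (q.x - p.x);
  r.y = p.y + t * (q.y - p.y);
  r.z = p.z + t * (q.z - p.z);
  return r;
}

const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};

// cube corner c -> (dx, dy, dz); order 0..7 around the base then top face
const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_march_tetra(const NumericVector& field, int nx, int ny,
                              int nz, double spacing, double origin) {
  std::vector<double> tri;  // 9 doubles per triangle
  auto F = [&](int i, int j, int k) {
    return field[i + nx * (j + ny * k)];
  };
  V3 pos[4];
  double val[4];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        V3 cpos[8];
        double cval[8];
        for (int c = 0; c < 8; ++c) {
          const int ci = i + CORNER[c][0], cj = j + CORNER[c][1],
                    ck = k + CORNER[c][2];
          cpos[c].x = origin + spacing * ci;
          cpos[c].y = origin + spacing * cj;
          cpos[c].z = origin + spacing * ck;
          cval[c] = F(ci, cj, ck);
        }
        for (int t = 0; t < 6; ++t) {
          int npos = 0;
          for (int v = 0; v < 4; ++v) {
            pos[v] = cpos[TETS[t][v]];
            val[v] = cval[TETS[t][v]];
            if (val[v] > 0) ++npos;
          }
          if (npos == 0 || npos == 4) continue;
          int in[4], out[4], ni = 0, no = 0;
          for (int v = 0; v < 4; ++v)
            (val[v] > 0 ? in[ni++] = v : out[no++] = v);
          if (npos == 1 || npos == 3) {
            const int apex = (npos == 1) ? in[0] : out[0];
            const int* base = (npos == 1) ? out : in;
            V3 a = lerp(pos[apex], pos[base[0]], val[apex], val[base[0]]);
            V3 b = lerp(pos[apex], pos[base[1]], val[apex], val[base[1]]);
            V3 c = lerp(pos[apex], pos[base[2]], val[apex], val[base[2]]);
            const double t9[9] = {a.x, a.y, a.z, b.x, b.y, b.z, c.x, c.y, c.z};
            tri.insert(tri.end(), t9, t9 + 9);
          } else {
            // two crossings form a quad: split into two triangles
            V3 a = lerp(pos[in[0]], pos[out[0]], val[in[0]], val[out[0]]);
            V3 b = lerp(pos[in[0]], pos[out[1]], val[in[0]], val[out[1]]);
            V3 c = lerp(pos[in[1]], pos[out[1]], val[in[1]], val[out[1]]);
            V3 d = lerp(pos[in[1]], pos[out[0]], val[in[1]], val[out[0]]);
            const double q1[9] = {a.x, a.y, a.z, b.x, b.y, b.z, c.x, c.y, c.z};
            const double q2[9] = {a.x, a.y, a.z, c.x, c.y, c.z, d.x, d.y, d.z};
            tri.insert(tri.end(), q1, q1 + 9);
            tri.insert(tri.end(), q2, q2 + 9);
          }
        }
      }
  const int ntri = static_cast<int>(tri.size() / 9);
  NumericMatrix out(3 * ntri, 3);
  for (int t = 0; t < ntri; ++t)
    for (int v = 0; v < 3; ++v)
      for (int d = 0; d < 3; ++d)
        out(3 * t + v, d) = tri[9 * t + 3 * v + d];
  return out;
}
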