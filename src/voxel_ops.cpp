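#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D array with reflecting boundaries.
// sigma is in voxels, per axis; kernel truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const long ntot = (long)n1 * n2 * n3;
  std::vector<double> cur(arr.begin(), arr.end()), nxt(ntot);
  const int dims[3] = {n1, n2, n3};

  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0) continue;
    const int n = dims[ax];
    int r = std::max(1, (int)std::ceil(3.0 * s));
    if (r > n - 1) r = n - 1;  // reflecting index must stay in range
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) {
      k[i + r] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + r];
    }
    for (double &v : k) v /= ksum;

    // stride of the axis and iteration over all lines along it
    const long stride = (ax == 0) ? 1 : (ax == 1) ? (long)n1 : (long)n1 * n2;
    const int na = (ax == 0) ? n2 : n1;        // first cross dim
    const int nb = (ax == 2) ? n2 : n3;        // second cross dim
    const long sa = (ax == 0) ? (long)n1 : 1;
    const long sb = (ax == 2) ? (long)n1 : (long)n1 * n2;
    std::vector<double> line(n + 2 * r);
    for (int b = 0; b < nb; ++b) {
      for (int a = 0; a < na; ++a) {
        const long base = a * sa + b * sb;
        for (int q = 0; q < n; ++q) line[r + q] = cur[base + q * stride];
        for (int q = 1; q <= r; ++q) {           // reflect
          line[r - q] = line[r + q - 1];
          line[r + n - 1 + q] = line[r + n - q];
        }
        for (int q = 0; q < n; ++q) {
          double acc = 0;
          const double *lp = &line[q];
          for (int t = 0; t <= 2 * r; ++t) acc += k[t] * lp[t];
          nxt[base + q * stride] = acc;
        }
      }
    }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}

// Block-mean downsampling by integer factors; input dims must be divisible.
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector arr, IntegerVector dim,
                             IntegerVector fac) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int f1 = fac[0], f2 = fac[1], f3 = fac[2];
  const int m1 = n1 / f1, m2 = n2 / f2, m3 = n3 / f3;
  const double w = 1.0 / ((double)f1 * f2 * f3);
  NumericVector out((long)m1 * m2 * m3);
  for (int L = 0; L < m3; ++L)
    for (int J = 0; J < m2; ++J)
      for (int I = 0; I < m1; ++I) {
        double acc = 0;
        for (int dl = 0; dl < f3; ++dl)
          for (int dj = 0; dj < f2; ++dj)
            for (int di = 0; di < f1; ++di) {
              long idx = (long)(I * f1 + di) + (long)n1 * (J * f2 + dj) +
                         (long)n1 * n2 * (L * f3 + dl);
              acc += arr[idx];
            }
        out[(long)I + (long)m1 * J + (long)m1 * m2 * L] = acc * w;
      }
  out.attr("dim") = IntegerVector::create(m1, m2, m3);
  return out;
}

// Marching tetrahedra on a binary mask: the mask is conceptually padded with
// one background voxel per face, each grid cell (corners at voxel centers) is
// split into 6 tetrahedra sharing the main diagonal (Kuhn decomposition, which
// is face-consistent across cells), and the level-0.5 iso-surface is extracted
// with linear interpolation (crossings at edge midpoints on a {0,1} field).
// Every triangle is oriented outward (away from bone) and the enclosed volume
// is accumulated by the divergence theorem as signed tetrahedra to the origin.
// Returns enclosed volume (mm^3), triangle count, and optionally the mesh.
// [[Rcpp::export]]
List cpp_marching_volume(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing, bool return_mesh = false) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  auto val = [&](int i, int j, int l) -> int {
    if (i < 0 || j < 0 || l < 0 || i >= n1 || j >= n2 || l >= n3) return 0;
    return mask[(long)i + (long)n1 * j + (long)n1 * n2 * l] ? 1 : 0;
  };
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  double vol6 = 0;        // 6 x enclosed volume
  long ntri = 0;
  long nflip_pos = 0, nflip_neg = 0;  // orientation bookkeeping
  std::vector<double> mesh;  // x1 y1 z1 x2 y2 z2 x3 y3 z3 per triangle

  for (int l = -1; l < n3; ++l)
    for (int j = -1; j < n2; ++j)
      for (int i = -1; i < n1; ++i) {
        int c[2][2][2], csum = 0;
        for (int dl = 0; dl < 2; ++dl)
          for (int dj = 0; dj < 2; ++dj)
            for (int di = 0; di < 2; ++di) {
              c[di][dj][dl] = val(i + di, j + dj, l + dl);
              csum += c[di][dj][dl];
            }
        if (csum == 0 || csum == 8) continue;

        for (int p = 0; p < 6; ++p) {
          int off[4][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}, {1, 1, 1}};
          off[1][perms[p][0]] = 1;
          off[2][perms[p][0]] = 1;
          off[2][perms[p][1]] = 1;
          int tv[4];
          double tx[4][3];
          for (int v = 0; v < 4; ++v) {
            tv[v] = c[off[v][0]][off[v][1]][off[v][2]];
            tx[v][0] = (i + off[v][0]) * s1;
            tx[v][1] = (j + off[v][1]) * s2;
            tx[v][2] = (l + off[v][2]) * s3;
          }
          int in[4], out_[4], nin = 0, nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (tv[v]) in[nin++] = v; else out_[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;

          auto mid = [&](int a, int b, double *m) {
            for (int d = 0; d < 3; ++d) m[d] = 0.5 * (tx[a][d] + tx[b][d]);
          };
          double tris[2][3][3];
          int nt = 0;
          if (nin == 1) {
            mid(in[0], out_[0], tris[0][0]);
            mid(in[0], out_[1], tris[0][1]);
            mid(in[0], out_[2], tris[0][2]);
            nt = 1;
          } else if (nin == 3) {
            mid(out_[0], in[0], tris[0][0]);
            mid(out_[0], in[1], tris[0][1]);
            mid(out_[0], in[2], tris[0][2]);
            nt = 1;
          } else {  // nin == 2: quad split into two triangles
            double mAC[3], mAD[3], mBD[3], mBC[3];
            mid(in[0], out_[0], mAC);
            mid(in[0], out_[1], mAD);
            mid(in[1], out_[1], mBD);
            mid(in[1], out_[0], mBC);
            std::memcpy(tris[0][0], mAC, sizeof mAC);
            std::memcpy(tris[0][1], mAD, sizeof mAD);
            std::memcpy(tris[0][2], mBD, sizeof mBD);
            std::memcpy(tris[1][0], mAC, sizeof mAC);
            std::memcpy(tris[1][1], mBD, sizeof mBD);
            std::memcpy(tris[1][2], mBC, sizeof mBC);
            nt = 2;
          }

          double ref[3] = {0, 0, 0};  // centroid of bone-side vertices
          for (int v = 0; v < nin; ++v)
            for (int d = 0; d < 3; ++d) ref[d] += tx[in[v]][d] / nin;

          for (int t = 0; t < nt; ++t) {
            double *a = tris[t][0], *b = tris[t][1], *cc = tris[t][2];
            double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
            double w[3] = {cc[0] - a[0], cc[1] - a[1], cc[2] - a[2]};
            double nrm[3] = {u[1] * w[2] - u[2] * w[1],
                             u[2] * w[0] - u[0] * w[2],
                             u[0] * w[1] - u[1] * w[0]};
            double cen[3];
            for (int d = 0; d < 3; ++d)
              cen[d] = (a[d] + b[d] + cc[d]) / 3.0 - ref[d];
            double dot = nrm[0] * cen[0] + nrm[1] * cen[1] + nrm[2] * cen[2];
            if (dot < 0) {  // normal points into bone: flip winding
              for (int d = 0; d < 3; ++d) std::swap(b[d], cc[d]);
              ++nflip_neg;
            } else {
              ++nflip_pos;
            }
            // signed tetra volume to the origin, outward orientation
            double sv =
                a[0] * (b[1] * cc[2] - b[2] * cc[1]) -
                a[1] * (b[0] * cc[2] - b[2] * cc[0]) +
                a[2] * (b[0] * cc[1] - b[1] * cc[0]);
            vol6 += sv;
            ++ntri;
            if (return_mesh) {
              for (int v = 0; v < 3; ++v)
                for (int d = 0; d < 3; ++d) mesh.push_back(tris[t][v][d]);
            }
          }
        }
      }

  List res = List::create(
      Named("enclosed_volume") = vol6 / 6.0,
      Named("n_triangles") = (double)ntri,
      Named("n_oriented") = (double)nflip_pos,
      Named("n_flipped") = (double)nflip_neg);
  if (return_mesh) {
    NumericVector m(mesh.begin(), mesh.end());
    res["triangles"] = m;  // length 9 * n_triangles, row-wise vertices
  }
  return res;
}
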