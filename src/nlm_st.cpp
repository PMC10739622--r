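#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 4D spatiotemporal non-local means.
//
// Offset-difference formulation: for every 4D search offset o the squared
// difference field D_o = (I - shift_o(I))^2 is formed on a replicate-padded
// copy of the series, the neighborhood distance d^2 is its separable box sum,
// and the weight exp(-d^2 / h^2) accumulates the candidate value.  This is
// algebraically identical to the per-voxel definition (candidates outside
// the volume are excluded; neighborhoods are replicate-clamped at borders)
// but costs O(search) instead of O(search x neighborhood) per voxel.
//
// img: numeric 4D array (nx, ny, nz, nt), column-major.
// search_sp / search_tm: full odd extents of the search window.
// nb_sp / nb_tm: full odd extents of the neighborhood window.
// h: per-frame smoothing bandwidth; h <= 0 keeps exact matches only.
// t_lo / t_hi: if >= 0 (0-based, inclusive), candidate frames come from this
// fixed block for every target frame; otherwise the temporal search window
// is centered on the target frame and truncated at the series ends.
// [[Rcpp::export]]
NumericVector nlm_st_cpp(NumericVector img, IntegerVector dims,
                         int search_sp, int search_tm,
                         int nb_sp, int nb_tm,
                         NumericVector h, int t_lo, int t_hi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  const int rs = (search_sp - 1) / 2, rt = (search_tm - 1) / 2;
  const int qs = (nb_sp - 1) / 2, qt = (nb_tm - 1) / 2;
  const double nbsize = (double)nb_sp * nb_sp * nb_sp * nb_tm;

  // replicate-padded copy (qs spatially, qt temporally)
  const int px = nx + 2 * qs, py = ny + 2 * qs, pz = nz + 2 * qs,
            ptn = nt + 2 * qt;
  const R_xlen_t sx = 1, sy = px, sz = (R_xlen_t)px * py,
                 st = (R_xlen_t)px * py * pz;
  const R_xlen_t npad = st * ptn;
  std::vector<double> P(npad);
  const double *in = img.begin();
  for (int t = 0; t < ptn; ++t) {
    int tc = std::min(std::max(t - qt, 0), nt - 1);
    for (int z = 0; z < pz; ++z) {
      int zc = std::min(std::max(z - qs, 0), nz - 1);
      for (int y = 0; y < py; ++y) {
        int yc = std::min(std::max(y - qs, 0), ny - 1);
        const double *row = in + ((R_xlen_t)tc * nz + zc) * ny * nx
                               + (R_xlen_t)yc * nx;
        double *orow = &P[st * t + sz * z + sy * y];
        for (int x = 0; x < px; ++x)
          orow[x] = row[std::min(std::max(x - qs, 0), nx - 1)];
      }
    }
  }
  // padded-coordinate index of unpadded voxel (x,y,z,t)
  auto pidx = [&](int x, int y, int z, int t) {
    return sx * (x + qs) + sy * (y + qs) + sz * (z + qs) + st * (t + qt);
  };

  std::vector<double> D(npad), A(npad), B(npad), wsum(img.size(), 0.0),
                      vsum(img.size(), 0.0);
  std::vector<double> hh(nt);
  for (int t = 0; t < nt; ++t) hh[t] = h[t] > 0 ? h[t] * h[t] * nbsize : 0.0;

  // temporal search offsets: union over target frames of candidate - target
  int ot_min, ot_max;
  if (t_lo >= 0) { ot_min = t_lo - (nt - 1); ot_max = t_hi; }
  else { ot_min = -rt; ot_max = rt; }

  for (int ot = ot_min; ot <= ot_max; ++ot)
  for (int oz = -rs; oz <= rs; ++oz)
  for (int oy = -rs; oy <= rs; ++oy)
  for (int ox = -rs; ox <= rs; ++ox) {
    const int xlo = std::max(0, -ox), xhi = std::min(nx - 1, nx - 1 - ox);
    const int ylo = std::max(0, -oy), yhi = std::min(ny - 1, ny - 1 - oy);
    const int zlo = std::max(0, -oz), zhi = std::min(nz - 1, nz - 1 - oz);
    int tlo, thi;
    if (t_lo >= 0) {
      tlo = std::max(0, t_lo - ot); thi = std::min(nt - 1, t_hi - ot);
    } else {
      tlo = std::max(0, -ot); thi = std::min(nt - 1, nt - 1 - ot);
    }
    if (xlo > xhi || ylo > yhi || zlo > zhi || tlo > thi) continue;
    const R_xlen_t doff = sx * ox + sy * oy + sz * oz + st * ot;

    // D over the neighborhood-expanded box (all reads stay inside P)
    for (int t = tlo - qt; t <= thi + qt; ++t)
    for (int z = zlo - qs; z <= zhi + qs; ++z)
    for (int y = ylo - qs; y <= yhi + qs; ++y) {
      R_xlen_t base = pidx(xlo - qs, y, z, t);
      for (int x = xlo - qs; x <= xhi + qs; ++x, ++base) {
        double d = P[base] - P[base + doff];
        D[base] = d * d;
      }
    }
    // separable neighborhood sums: x, then y, then z, then t
    for (int t = tlo - qt; t <= thi + qt; ++t)
    for (int z = zlo - qs; z <= zhi + qs; ++z)
    for (int y = ylo - qs; y <= yhi + qs; ++y) {
      R_xlen_t base = pidx(xlo, y, z, t);
      for (int x = xlo; x <= xhi; ++x, ++base) {
        double s = 0;
        for (int k = -qs; k <= qs; ++k) s += D[base + k * sx];
        A[base] = s;
      }
    }
    for (int t = tlo - qt; t <= thi + qt; ++t)
    for (int z = zlo - qs; z <= zhi + qs; ++z)
    for (int y = ylo; y <= yhi; ++y) {
      R_xlen_t base = pidx(xlo, y, z, t);
      for (int x = xlo; x <= xhi; ++x, ++base) {
        double s = 0;
        for (int k = -qs; k <= qs; ++k) s += A[base + k * sy];
        B[base] = s;
      }
    }
    for (int t = tlo - qt; t <= thi + qt; ++t)
    for (int z = zlo; z <= zhi; ++z)
    for (int y = ylo; y <= yhi; ++y) {
      R_xlen_t base = pidx(xlo, y, z, t);
      for (int x = xlo; x <= xhi; ++x, ++base) {
        double s = 0;
        for (int k = -qs; k <= qs; ++k) s += B[base + k * sz];
        A[base] = s;
      }
    }
    // final temporal sum, weight, accumulate
    for (int t = tlo; t <= thi; ++t)
    for (int z = zlo; z <= zhi; ++z)
    for (int y = ylo; y <= yhi; ++y) {
      R_xlen_t base = pidx(xlo, y, z, t);
      R_xlen_t out = (R_xlen_t)xlo + (R_xlen_t)nx *
                     (y + (R_xlen_t)ny * (z + (R_xlen_t)nz * t));
      for (int x = xlo; x <= xhi; ++x, ++base, ++out) {
        double d2 = 0;
        for (int k = -qt; k <= qt; ++k) d2 += A[base + k * st];
        double w;
        if (hh[t] > 0) w = std::exp(-d2 / hh[t]);
        else w = d2 <= 0.0 ? 1.0 : 0.0;
        wsum[out] += w;
        vsum[out] += w * P[base + doff];
      }
    }
  }

  NumericVector res(img.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)img.size(); ++i)
    res[i] = wsum[i] > 0 ? vsum[i] / wsum[i] : in[i];
  res.attr("dim") = dims;
  return res;
}
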