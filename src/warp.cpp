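#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3-D volume at (i + dx, j + dy, k + dz), voxel units,
// 0-based internally. clamp_edge = true replicates border values (used for
// vector-field components so compositions stay finite near the faces);
// clamp_edge = false returns `outside` beyond the grid (used for images,
// where beyond-FOV is air).
// Trilinear sampling at arbitrary absolute voxel coordinates (0-based).
// Output has the length of the coordinate vectors.
// [[Rcpp::export]]
NumericVector resample_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                     NumericVector xs, NumericVector ys,
                                     NumericVector zs, bool clamp_edge,
                                     double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = xs.size();
  NumericVector out(n);
  const double *v = REAL(vol);
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    double x = xs[idx], y = ys[idx], z = zs[idx];
    if (clamp_edge) {
      if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
      if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
      if (z < 0) z = 0; else if (z > nz - 1) z = nz - 1;
    } else if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 ||
               z < 0 || z > nz - 1) {
      out[idx] = outside;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 >= nx - 1) x0 = nx - 2;
    if (y0 >= ny - 1) y0 = ny - 2;
    if (z0 >= nz - 1) z0 = nz - 2;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
    R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double c000 = v[base],            c100 = v[base + sx];
    double c010 = v[base + sy],       c110 = v[base + sx + sy];
    double c001 = v[base + sz],       c101 = v[base + sx + sz];
    double c011 = v[base + sy + sz],  c111 = v[base + sx + sy + sz];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    out[idx] = c0 + fz * (c1 - c0);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector warp_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                 NumericVector dx, NumericVector dy,
                                 NumericVector dz, bool clamp_edge,
                                 double outside) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double *v = REAL(vol);
  const double *px = REAL(dx), *py = REAL(dy), *pz = REAL(dz);
  double *o = REAL(out);

  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + px[idx];
        double y = j + py[idx];
        double z = k + pz[idx];
        if (clamp_edge) {
          if (x < 0) x = 0; else if (x > nx - 1) x = nx - 1;
          if (y < 0) y = 0; else if (y > ny - 1) y = ny - 1;
          if (z < 0) z = 0; else if (z > nz - 1) z = nz - 1;
        } else if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 ||
                   z < 0 || z > nz - 1) {
          o[idx] = outside;
          continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 >= nx - 1) x0 = nx - 2;
        if (y0 >= ny - 1) y0 = ny - 2;
        if (z0 >= nz - 1) z0 = nz - 2;
        if (x0 < 0) x0 = 0;
        if (y0 < 0) y0 = 0;
        if (z0 < 0) z0 = 0;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        R_xlen_t base = (R_xlen_t)x0 + (R_xlen_t)nx * (y0 + (R_xlen_t)ny * z0);
        R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
        double c000 = v[base],            c100 = v[base + sx];
        double c010 = v[base + sy],       c110 = v[base + sx + sy];
        double c001 = v[base + sz],       c101 = v[base + sx + sz];
        double c011 = v[base + sy + sz],  c111 = v[base + sx + sy + sz];
        double c00 = c000 + fx * (c100 - c000);
        double c10 = c010 + fx * (c110 - c010);
        double c01 = c001 + fx * (c101 - c001);
        double c11 = c011 + fx * (c111 - c011);
        double c0 = c00 + fy * (c10 - c00);
        double c1 = c01 + fy * (c11 - c01);
        o[idx] = c0 + fz * (c1 - c0);
      }
    }
  }
  return out;
}
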