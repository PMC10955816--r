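// Ray-driven cone-beam projector (Siddon-style incremental traversal).
//
// The forward and adjoint operators share a single traversal routine so the
// pair is exactly matched: <Ax, y> == <x, A'y> up to floating-point rounding.
// Volumes are isotropic voxel grids centred on the isocenter; detector frames
// are nu x nv pixel grids described per frame by the source focal spot, the
// panel centre (lateral offset already applied) and the in-plane unit vectors.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double h;              // isotropic voxel edge, mm
  double ox, oy, oz;     // position of the grid corner (voxel (0,0,0) low corner)
};

// Traverse the segment from s to e through the grid.  If deposit is false,
// accumulate sum(mu * length) from vol; if true, add w * length into acc.
inline double trace_ray(const Grid &g, const double *vol, double *acc,
                        bool deposit, double w,
                        double sx, double sy, double sz,
                        double ex, double ey, double ez) {
  const double dx = ex - sx, dy = ey - sy, dz = ez - sz;
  const double seg = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (seg <= 0.0) return 0.0;

  double tmin = 0.0, tmax = 1.0;
  const double d[3] = {dx, dy, dz};
  const double s[3] = {sx, sy, sz};
  const double o[3] = {g.ox, g.oy, g.oz};
  const int n[3] = {g.nx, g.ny, g.nz};
  for (int a = 0; a < 3; ++a) {
    const double lo = o[a], hi = o[a] + n[a] * g.h;
    if (std::fabs(d[a]) < 1e-12) {
      if (s[a] <= lo || s[a] >= hi) return 0.0;
    } else {
      double t1 = (lo - s[a]) / d[a];
      double t2 = (hi - s[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin >= tmax) return 0.0;

  // entry voxel (nudge inside to avoid landing exactly on a plane)
  const double t0 = tmin + 1e-12;
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    double p = s[a] + t0 * d[a];
    int i = static_cast<int>(std::floor((p - o[a]) / g.h));
    if (i < 0) i = 0;
    if (i >= n[a]) i = n[a] - 1;
    idx[a] = i;
  }

  int step[3];
  double tDelta[3], tNext[3];
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 1e-12) {
      step[a] = 1;
      tDelta[a] = g.h / d[a];
      tNext[a] = (o[a] + (idx[a] + 1) * g.h - s[a]) / d[a];
    } else if (d[a] < -1e-12) {
      step[a] = -1;
      tDelta[a] = -g.h / d[a];
      tNext[a] = (o[a] + idx[a] * g.h - s[a]) / d[a];
    } else {
      step[a] = 0;
      tDelta[a] = 1e30;
      tNext[a] = 1e30;
    }
  }

  double sum = 0.0, t = tmin;
  while (t < tmax) {
    int amin = 0;
    if (tNext[1] < tNext[amin]) amin = 1;
    if (tNext[2] < tNext[amin]) amin = 2;
    double tstop = tNext[amin] < tmax ? tNext[amin] : tmax;
    double len = (tstop - t) * seg;
    if (len > 0.0) {
      const R_xlen_t lin = idx[0] +
        static_cast<R_xlen_t>(g.nx) * (idx[1] + static_cast<R_xlen_t>(g.ny) * idx[2]);
      if (deposit) acc[lin] += w * len;
      else sum += vol[lin] * len;
    }
    t = tstop;
    if (tNext[amin] >= tmax) break;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= n[amin]) break;
    tNext[amin] += tDelta[amin];
  }
  return sum;
}

Grid make_grid(const IntegerVector &dim, double h) {
  Grid g;
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  g.h = h;
  g.ox = -0.5 * g.nx * h;
  g.oy = -0.5 * g.ny * h;
  g.oz = -0.5 * g.nz * h;
  return g;
}

} // namespace

// Forward projection of vol onto all frames.  band holds, per frame, the
// inclusive 0-based first/last illuminated detector row; pixels outside the
// band are left at zero and carry zero weight in the adjoint.
// [[Rcpp::export]]
NumericVector cpp_project_forward(NumericVector vol, IntegerVector dim, double h,
                                  NumericMatrix src, NumericMatrix detc,
                                  NumericMatrix uhat, NumericMatrix vhat,
                                  int nu, int nv, double du, double dv,
                                  IntegerMatrix band) {
  const Grid g = make_grid(dim, h);
  const int nf = src.nrow();
  NumericVector out(static_cast<R_xlen_t>(nu) * nv * nf);
  const double *v = vol.begin();
  double *po = out.begin();
  const double uc = 0.5 * (nu - 1), vc = 0.5 * (nv - 1);

  for (int f = 0; f < nf; ++f) {
    const double sx = src(f, 0), sy = src(f, 1), sz = src(f, 2);
    const double cx = detc(f, 0), cy = detc(f, 1), cz = detc(f, 2);
    const double ux = uhat(f, 0), uy = uhat(f, 1), uz = uhat(f, 2);
    const double wx = vhat(f, 0), wy = vhat(f, 1), wz = vhat(f, 2);
    const int vlo = band(f, 0), vhi = band(f, 1);
    double *frame = po + static_cast<R_xlen_t>(f) * nu * nv;
    for (int iv = vlo; iv <= vhi; ++iv) {
      const double bv = (iv - vc) * dv;
      const double bx = cx + bv * wx, by = cy + bv * wy, bz = cz + bv * wz;
      double *row = frame + static_cast<R_xlen_t>(iv) * nu;
      for (int iu = 0; iu < nu; ++iu) {
        const double bu = (iu - uc) * du;
        row[iu] = trace_ray(g, v, nullptr, false, 0.0, sx, sy, sz,
                            bx + bu * ux, by + bu * uy, bz + bu * uz);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nu, nv, nf);
  return out;
}

// Matched adjoint: smear projection values back along the same rays.
// [[Rcpp::export]]
NumericVector cpp_project_backward(NumericVector proj, IntegerVector dim, double h,
                                   NumericMatrix src, NumericMatrix detc,
                                   NumericMatrix uhat, NumericMatrix vhat,
                                   int nu, int nv, double du, double dv,
                                   IntegerMatrix band) {
  const Grid g = make_grid(dim, h);
  const int nf = src.nrow();
  NumericVector out(static_cast<R_xlen_t>(dim[0]) * dim[1] * dim[2]);
  double *acc = out.begin();
  const double *pp = proj.begin();
  const double uc = 0.5 * (nu - 1), vc = 0.5 * (nv - 1);

  for (int f = 0; f < nf; ++f) {
    const double sx = src(f, 0), sy = src(f, 1), sz = src(f, 2);
    const double cx = detc(f, 0), cy = detc(f, 1), cz = detc(f, 2);
    const double ux = uhat(f, 0), uy = uhat(f, 1), uz = uhat(f, 2);
    const double wx = vhat(f, 0), wy = vhat(f, 1), wz = vhat(f, 2);
    const int vlo = band(f, 0), vhi = band(f, 1);
    const double *frame = pp + static_cast<R_xlen_t>(f) * nu * nv;
    for (int iv = vlo; iv <= vhi; ++iv) {
      const double bv = (iv - vc) * dv;
      const double bx = cx + bv * wx, by = cy + bv * wy, bz = cz + bv * wz;
      const double *row = frame + static_cast<R_xlen_t>(iv) * nu;
      for (int iu = 0; iu < nu; ++iu) {
        const double w = row[iu];
        if (w == 0.0) continue;
        const double bu = (iu - uc) * du;
        trace_ray(g, nullptr, acc, true, w, sx, sy, sz,
                  bx + bu * ux, by + bu * uy, bz + bu * uz);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// 26-connected component labelling of a logical mask (used by threshold
// segmentation to drop speckle components).
// [[Rcpp::export]]
IntegerVector cpp_label_components26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    ++cur;
    stack.clear();
    stack.push_back(start);
    lab[start] = cur;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int k = static_cast<int>(p / (static_cast<R_xlen_t>(nx) * ny));
      const int rem = static_cast<int>(p - static_cast<R_xlen_t>(k) * nx * ny);
      const int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            const R_xlen_t q = ii + static_cast<R_xlen_t>(nx) * (jj + static_cast<R_xlen_t>(ny) * kk);
            if (mask[q] && !lab[q]) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
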