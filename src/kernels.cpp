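// Numerical kernels: tube distance field, grid Dijkstra (wave propagation),
// trilinear sampling, separable convolution, 26-connected labelling.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Distance field of a polyline over a regular grid.
// dims: nx, ny, nz; world = origin + dirmat %*% (spacing * index), index 0-based.
// poly: M x 3 world points, arc: cumulative arc length (mm) per poly point.
// Returns list(dist = per-voxel min distance to polyline (mm),
//              s    = arc length at the closest point (mm)).
// [[Rcpp::export]]
List cpp_polyline_field(IntegerVector dims, NumericVector spacing,
                        NumericVector origin, NumericMatrix dirmat,
                        NumericMatrix poly, NumericVector arc) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int m = poly.nrow();
  NumericVector dist(n), sarc(n);
  // precompute segments
  std::vector<double> ax(m), ay(m), az(m);
  for (int k = 0; k < m; ++k) { ax[k]=poly(k,0); ay[k]=poly(k,1); az[k]=poly(k,2); }
  const int ns = m - 1;
  std::vector<double> dx(ns), dy(ns), dz(ns), len2(ns), mx(ns), my(ns), mz(ns), half(ns);
  for (int k = 0; k < ns; ++k) {
    dx[k]=ax[k+1]-ax[k]; dy[k]=ay[k+1]-ay[k]; dz[k]=az[k+1]-az[k];
    len2[k]=dx[k]*dx[k]+dy[k]*dy[k]+dz[k]*dz[k];
    mx[k]=0.5*(ax[k]+ax[k+1]); my[k]=0.5*(ay[k]+ay[k+1]); mz[k]=0.5*(az[k]+az[k+1]);
    half[k]=0.5*std::sqrt(len2[k]);
  }
  const double d00=dirmat(0,0), d01=dirmat(0,1), d02=dirmat(0,2);
  const double d10=dirmat(1,0), d11=dirmat(1,1), d12=dirmat(1,2);
  const double d20=dirmat(2,0), d21=dirmat(2,1), d22=dirmat(2,2);
  R_xlen_t idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    const double sz = spacing[2]*kz;
    for (int ky = 0; ky < ny; ++ky) {
      const double sy = spacing[1]*ky;
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        const double sx = spacing[0]*kx;
        const double px = origin[0] + d00*sx + d01*sy + d02*sz;
        const double py = origin[1] + d10*sx + d11*sy + d12*sz;
        const double pz = origin[2] + d20*sx + d21*sy + d22*sz;
        double best = std::numeric_limits<double>::infinity();
        double bests = 0.0;
        const double bestr0 = std::sqrt(best);
        (void)bestr0;
        double bestr = std::numeric_limits<double>::infinity();
        for (int k = 0; k < ns; ++k) {
          const double cx = px - mx[k], cy = py - my[k], cz = pz - mz[k];
          const double cm = std::sqrt(cx*cx + cy*cy + cz*cz);
          if (cm - half[k] > bestr) continue;  // lower bound reject
          const double vx = px - ax[k], vy = py - ay[k], vz = pz - az[k];
          double t = 0.0;
          if (len2[k] > 0.0) {
            t = (vx*dx[k] + vy*dy[k] + vz*dz[k]) / len2[k];
            if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
          }
          const double qx = vx - t*dx[k], qy = vy - t*dy[k], qz = vz - t*dz[k];
          const double d2 = qx*qx + qy*qy + qz*qz;
          if (d2 < best) {
            best = d2; bestr = std::sqrt(d2);
            bests = arc[k] + t*(arc[k+1] - arc[k]);
          }
        }
        dist[idx] = bestr;
        sarc[idx] = bests;
      }
    }
  }
  return List::create(_["dist"] = dist, _["s"] = sarc);
}

// Grid Dijkstra on 26-connected voxel graph.
// cost: per-voxel nonnegative cost (Inf/NA = blocked); edge weight =
// 0.5*(c_a + c_b) * euclidean step length (mm).
// start, end: 0-based linear indices. Returns list(path = 1-based linear
// indices start..end, cost = total path cost) or path = empty if unreachable.
// [[Rcpp::export]]
List cpp_dijkstra(NumericVector cost, IntegerVector dims, NumericVector spacing,
                  double start, double end, double length_penalty) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t s0 = (R_xlen_t)start, e0 = (R_xlen_t)end;
  std::vector<double> d(n, std::numeric_limits<double>::infinity());
  std::vector<R_xlen_t> prev(n, -1);
  std::vector<char> done(n, 0);
  // neighbor offsets
  std::vector<int> ox, oy, oz; std::vector<double> olen; std::vector<R_xlen_t> olin;
  for (int az = -1; az <= 1; ++az) for (int ay = -1; ay <= 1; ++ay)
    for (int axx = -1; axx <= 1; ++axx) {
      if (axx == 0 && ay == 0 && az == 0) continue;
      ox.push_back(axx); oy.push_back(ay); oz.push_back(az);
      const double ex = axx*spacing[0], ey = ay*spacing[1], ez = az*spacing[2];
      olen.push_back(std::sqrt(ex*ex + ey*ey + ez*ez));
      olin.push_back((R_xlen_t)axx + (R_xlen_t)ay*nx + (R_xlen_t)az*nx*ny);
    }
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  if (!std::isfinite(cost[s0]) || !std::isfinite(cost[e0]))
    return List::create(_["path"] = IntegerVector(0), _["cost"] = NA_REAL);
  d[s0] = 0.0; pq.push(QE(0.0, s0));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == e0) break;
    const int uz = (int)(u / ((R_xlen_t)nx*ny));
    const R_xlen_t rem = u - (R_xlen_t)uz*nx*ny;
    const int uy = (int)(rem / nx);
    const int ux = (int)(rem - (R_xlen_t)uy*nx);
    const double cu = cost[u];
    for (size_t k = 0; k < ox.size(); ++k) {
      const int vx = ux + ox[k], vy = uy + oy[k], vz = uz + oz[k];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz) continue;
      const R_xlen_t v = u + olin[k];
      if (done[v]) continue;
      const double cv = cost[v];
      if (!std::isfinite(cv)) continue;
      const double w = (0.5*(cu + cv) + length_penalty)*olen[k];
      const double nd = top.first + w;
      if (nd < d[v]) { d[v] = nd; prev[v] = u; pq.push(QE(nd, v)); }
    }
  }
  if (!std::isfinite(d[e0]))
    return List::create(_["path"] = IntegerVector(0), _["cost"] = NA_REAL);
  std::vector<double> rev;
  for (R_xlen_t u = e0; u != -1; u = prev[u]) rev.push_back((double)u + 1.0);
  NumericVector path(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) path[k] = rev[rev.size()-1-k];
  return List::create(_["path"] = path, _["cost"] = d[e0]);
}

// Trilinear (or nearest) sampling at continuous 0-based voxel coordinates.
// coords: N x 3. Out-of-bounds -> background, valid = FALSE.
// [[Rcpp::export]]
List cpp_sample(NumericVector vol, IntegerVector dims, NumericMatrix coords,
                double background, bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sxy = (R_xlen_t)nx*ny;
  const int n = coords.nrow();
  NumericVector out(n);
  LogicalVector valid(n);
  for (int i = 0; i < n; ++i) {
    const double x = coords(i,0), y = coords(i,1), z = coords(i,2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[i] = background; valid[i] = false; continue;
    }
    valid[i] = true;
    if (nearest) {
      const int ix = (int)std::round(x), iy = (int)std::round(y), iz = (int)std::round(z);
      out[i] = vol[(R_xlen_t)ix + (R_xlen_t)iy*nx + (R_xlen_t)iz*sxy];
    } else {
      int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
      if (ix == nx-1) --ix;
      if (iy == ny-1) --iy;
      if (iz == nz-1) --iz;
      const double fx = x - ix, fy = y - iy, fz = z - iz;
      const R_xlen_t b = (R_xlen_t)ix + (R_xlen_t)iy*nx + (R_xlen_t)iz*sxy;
      const double c000 = vol[b],          c100 = vol[b+1];
      const double c010 = vol[b+nx],       c110 = vol[b+nx+1];
      const double c001 = vol[b+sxy],      c101 = vol[b+sxy+1];
      const double c011 = vol[b+sxy+nx],   c111 = vol[b+sxy+nx+1];
      const double c00 = c000*(1-fx)+c100*fx, c10 = c010*(1-fx)+c110*fx;
      const double c01 = c001*(1-fx)+c101*fx, c11 = c011*(1-fx)+c111*fx;
      const double c0 = c00*(1-fy)+c10*fy, c1 = c01*(1-fy)+c11*fy;
      out[i] = c0*(1-fz)+c1*fz;
    }
  }
  return List::create(_["values"] = out, _["valid"] = valid);
}

// Separable 1-D convolution along dimension `dim` (0, 1 or 2) with reflect
// boundary handling. Kernel must have odd length.
// [[Rcpp::export]]
NumericVector cpp_convolve_dim(NumericVector vol, IntegerVector dims,
                               NumericVector kernel, int dim) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sxy = (R_xlen_t)nx*ny;
  const int kl = kernel.size();
  const int kh = kl / 2;
  NumericVector out((R_xlen_t)nx*ny*nz);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, sxy};
  const int N = nd[dim];
  const R_xlen_t st = stride[dim];
  // iterate over all lines along `dim`
  const int n1 = nd[(dim+1)%3], n2 = nd[(dim+2)%3];
  const R_xlen_t st1 = stride[(dim+1)%3], st2 = stride[(dim+2)%3];
  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      const R_xlen_t base = (R_xlen_t)j1*st1 + (R_xlen_t)j2*st2;
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int k = 0; k < kl; ++k) {
          int ii = i + k - kh;
          if (ii < 0) ii = -ii;                    // reflect
          if (ii >= N) ii = 2*N - 2 - ii;
          if (ii < 0) ii = 0;
          acc += kernel[k] * vol[base + (R_xlen_t)ii*st];
        }
        out[base + (R_xlen_t)i*st] = acc;
      }
    }
  }
  return out;
}

// 26-connected component labelling of a logical mask (0/1 int vector).
// Returns integer labels, 0 = background, components numbered from 1.
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx*ny*nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (mask[seed] == 0 || lab[seed] != 0) continue;
    ++cur;
    stack.clear(); stack.push_back(seed); lab[seed] = cur;
    while (!stack.empty()) {
      const R_xlen_t u = stack.back(); stack.pop_back();
      const int uz = (int)(u / ((R_xlen_t)nx*ny));
      const R_xlen_t rem = u - (R_xlen_t)uz*nx*ny;
      const int uy = (int)(rem / nx);
      const int ux = (int)(rem - (R_xlen_t)uy*nx);
      for (int az = -1; az <= 1; ++az) for (int ay = -1; ay <= 1; ++ay)
        for (int axx = -1; axx <= 1; ++axx) {
          if (axx == 0 && ay == 0 && az == 0) continue;
          const int vx = ux+axx, vy = uy+ay, vz = uz+az;
          if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz) continue;
          const R_xlen_t v = (R_xlen_t)vx + (R_xlen_t)vy*nx + (R_xlen_t)vz*(R_xlen_t)nx*ny;
          if (mask[v] != 0 && lab[v] == 0) { lab[v] = cur; stack.push_back(v); }
        }
    }
  }
  return lab;
}
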