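#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Voxel convention: 0-based index i has its center at (i + 0.5) * d physical
// units. Arrays are column-major with dims (nx, ny, nz); linear index
// x + nx * (y + ny * z).

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + (int64_t)ny * z);
}

// ---------------------------------------------------------------------------
// Capsule rasterizer: paint tubes around trace edges into an intensity volume
// and a cell-id label volume. Edges: columns x1,y1,z1,r1,x2,y2,z2,r2,value,cell
// (coordinates and radii in physical units).
// [[Rcpp::export]]
List rasterize_tubes_cpp(IntegerVector dims, NumericMatrix edges,
                         NumericVector voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = voxel[0], dy = voxel[1], dz = voxel[2];
  NumericVector img((R_xlen_t)nx * ny * nz);
  IntegerVector lab((R_xlen_t)nx * ny * nz);

  for (int e = 0; e < edges.nrow(); ++e) {
    const double x1 = edges(e, 0), y1 = edges(e, 1), z1 = edges(e, 2),
                 r1 = edges(e, 3), x2 = edges(e, 4), y2 = edges(e, 5),
                 z2 = edges(e, 6), r2 = edges(e, 7), val = edges(e, 8);
    const int cell = (int)edges(e, 9);
    const double rmax = std::max(r1, r2);
    int ix0 = (int)std::floor((std::min(x1, x2) - rmax) / dx - 0.5);
    int ix1 = (int)std::ceil((std::max(x1, x2) + rmax) / dx + 0.5);
    int iy0 = (int)std::floor((std::min(y1, y2) - rmax) / dy - 0.5);
    int iy1 = (int)std::ceil((std::max(y1, y2) + rmax) / dy + 0.5);
    int iz0 = (int)std::floor((std::min(z1, z2) - rmax) / dz - 0.5);
    int iz1 = (int)std::ceil((std::max(z1, z2) + rmax) / dz + 0.5);
    ix0 = std::max(ix0, 0); iy0 = std::max(iy0, 0); iz0 = std::max(iz0, 0);
    ix1 = std::min(ix1, nx - 1); iy1 = std::min(iy1, ny - 1);
    iz1 = std::min(iz1, nz - 1);
    const double ax = x2 - x1, ay = y2 - y1, az = z2 - z1;
    const double len2 = ax * ax + ay * ay + az * az;
    for (int z = iz0; z <= iz1; ++z) {
      const double pz = (z + 0.5) * dz;
      for (int y = iy0; y <= iy1; ++y) {
        const double py = (y + 0.5) * dy;
        for (int x = ix0; x <= ix1; ++x) {
          const double px = (x + 0.5) * dx;
          double t = 0.0;
          if (len2 > 0)
            t = ((px - x1) * ax + (py - y1) * ay + (pz - z1) * az) / len2;
          t = std::min(1.0, std::max(0.0, t));
          const double qx = x1 + t * ax - px, qy = y1 + t * ay - py,
                       qz = z1 + t * az - pz;
          const double d2 = qx * qx + qy * qy + qz * qz;
          const double r = r1 + t * (r2 - r1);
          if (d2 <= r * r) {
            const R_xlen_t idx = (R_xlen_t)lin(x, y, z, nx, ny);
            if (val >= img[idx]) {
              img[idx] = val;
              lab[idx] = cell;
            } else if (lab[idx] == 0) {
              lab[idx] = cell;
            }
          }
        }
      }
    }
  }
  img.attr("dim") = dims;
  lab.attr("dim") = dims;
  return List::create(_["intensity"] = img, _["labels"] = lab);
}

// ---------------------------------------------------------------------------
// Separable 3-D Gaussian blur, sigma per axis in voxels (<= 0 skips an axis).
// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector arr, IntegerVector dims,
                                  NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  const int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    const int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> k(2 * rad + 1);
    double ksum = 0;
    for (int i = -rad; i <= rad; ++i) {
      k[i + rad] = std::exp(-0.5 * i * i / (s * s));
      ksum += k[i + rad];
    }
    for (double& v : k) v /= ksum;
    const int stride = (axis == 0) ? 1 : (axis == 1 ? nx : nx * ny);
    const int len = n[axis];
    const int ou_n = (axis == 0) ? ny : nx;        // first orthogonal dim
    const int ov_n = (axis == 2) ? ny : nz;        // second orthogonal dim
    for (int ov = 0; ov < ov_n; ++ov)
      for (int ou = 0; ou < ou_n; ++ou) {
        const int base = (axis == 0) ? lin(0, ou, ov, nx, ny)
                       : (axis == 1) ? lin(ou, 0, ov, nx, ny)
                                     : lin(ou, ov, 0, nx, ny);
        {
          for (int i = 0; i < len; ++i) {
            double acc = 0;
            for (int j = -rad; j <= rad; ++j) {
              int ii = i + j;
              if (ii < 0) ii = 0;
              if (ii >= len) ii = len - 1;
              acc += k[j + rad] * a[base + (R_xlen_t)ii * stride];
            }
            b[base + (R_xlen_t)i * stride] = acc;
          }
        }
      }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Topology helpers for 3-D thinning (simple-point test after
// Malandain & Bertrand): a foreground voxel is simple iff its 26-neighbour
// foreground falls in one 26-component and the 6-adjacent background of its
// 18-neighbourhood falls in one 6-component.
namespace {

inline int off_lin(int dx_, int dy_, int dz_) {
  return (dx_ + 1) + 3 * ((dy_ + 1) + 3 * (dz_ + 1));
}

bool simple_point(const bool nb[27]) {
  // C*: 26-components of foreground among the 26 neighbours
  bool seen[27] = {false};
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int ddz = -1; ddz <= 1; ++ddz)
        for (int ddy = -1; ddy <= 1; ++ddy)
          for (int ddx = -1; ddx <= 1; ++ddx) {
            int mx = cx + ddx, my = cy + ddy, mz = cz + ddz;
            if (mx < 0 || mx > 2 || my < 0 || my > 2 || mz < 0 || mz > 2)
              continue;
            int m = mx + 3 * (my + 3 * mz);
            if (m == 13 || m == c || seen[m] || !nb[m]) continue;
            seen[m] = true;
            q.push(m);
          }
    }
  }
  if (ncomp_fg != 1) return false;

  // C-bar: 6-components of background within the 18-neighbourhood that touch
  // the centre by 6-adjacency
  static const int face[6] = {off_lin(1, 0, 0), off_lin(-1, 0, 0),
                              off_lin(0, 1, 0), off_lin(0, -1, 0),
                              off_lin(0, 0, 1), off_lin(0, 0, -1)};
  bool in18[27] = {false};
  for (int dz_ = -1; dz_ <= 1; ++dz_)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_)
        if (std::abs(dx_) + std::abs(dy_) + std::abs(dz_) <= 2 &&
            !(dx_ == 0 && dy_ == 0 && dz_ == 0))
          in18[off_lin(dx_, dy_, dz_)] = true;
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int f = 0; f < 6; ++f) {
    int i = face[f];
    if (nb[i] || seenb[i]) continue;
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    std::queue<int> q;
    q.push(i);
    seenb[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int step[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                                     {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
      for (int s = 0; s < 6; ++s) {
        int mx = cx + step[s][0], my = cy + step[s][1], mz = cz + step[s][2];
        if (mx < 0 || mx > 2 || my < 0 || my > 2 || mz < 0 || mz > 2) continue;
        int m = mx + 3 * (my + 3 * mz);
        if (m == 13 || !in18[m] || seenb[m] || nb[m]) continue;
        seenb[m] = true;
        q.push(m);
      }
    }
  }
  return ncomp_bg == 1;
}

} // namespace

// Sequential 3-D thinning with six directional sub-iterations; endpoints
// (voxels with <= 1 foreground 26-neighbour) are preserved, yielding a curve
// skeleton one voxel wide.
// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> m(mask.begin(), mask.end());
  static const int dir[6][3] = {{0, 0, -1}, {0, 0, 1}, {0, -1, 0},
                                {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return m[(R_xlen_t)lin(x, y, z, nx, ny)];
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // candidate border voxels for this direction
      std::vector<R_xlen_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            const R_xlen_t idx = (R_xlen_t)lin(x, y, z, nx, ny);
            if (!m[idx]) continue;
            if (at(x + dir[d][0], y + dir[d][1], z + dir[d][2])) continue;
            cand.push_back(idx);
          }
      for (R_xlen_t idx : cand) {
        if (!m[idx]) continue;
        const int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
        bool nb[27];
        int nnb = 0;
        for (int dz_ = -1; dz_ <= 1; ++dz_)
          for (int dy_ = -1; dy_ <= 1; ++dy_)
            for (int dx_ = -1; dx_ <= 1; ++dx_) {
              bool v = at(x + dx_, y + dy_, z + dz_);
              nb[off_lin(dx_, dy_, dz_)] = v;
              if (v && !(dx_ == 0 && dy_ == 0 && dz_ == 0)) ++nnb;
            }
        if (nnb <= 1) continue; // endpoint or isolated: keep
        if (simple_point(nb)) {
          m[idx] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(m.begin(), m.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Zhang-Suen 2-D thinning to a one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix thin2d_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> m(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) m[i + nr * j] = mask(i, j);
  auto at = [&](int i, int j) -> char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return m[i + nr * j];
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<int> del;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!m[i + nr * j]) continue;
          // neighbours clockwise from north (p2..p9)
          const char p2 = at(i - 1, j), p3 = at(i - 1, j + 1),
                     p4 = at(i, j + 1), p5 = at(i + 1, j + 1),
                     p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
                     p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          const char seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (!seq[k] && seq[k + 1]) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 && p4 && p6) continue;
            if (p4 && p6 && p8) continue;
          } else {
            if (p2 && p4 && p8) continue;
            if (p2 && p6 && p8) continue;
          }
          del.push_back(i + nr * j);
        }
      if (!del.empty()) changed = true;
      for (int idx : del) m[idx] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = m[i + nr * j] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// 3-D chamfer distance transform (3x3x3 neighbourhood, anisotropic weights):
// distance from each foreground voxel to the nearest background voxel.
// [[Rcpp::export]]
NumericVector chamfer_dt3d_cpp(LogicalVector mask, IntegerVector dims,
                               NumericVector voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double BIG = 1e30;
  NumericVector d((R_xlen_t)nx * ny * nz);
  for (R_xlen_t i = 0; i < d.size(); ++i) d[i] = mask[i] ? BIG : 0.0;
  struct Off { int x, y, z; double w; };
  std::vector<Off> fwd;
  for (int dz_ = -1; dz_ <= 1; ++dz_)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        if (dz_ > 0 || (dz_ == 0 && (dy_ > 0 || (dy_ == 0 && dx_ >= 0))))
          continue; // keep only the backward half-neighbourhood
        fwd.push_back({dx_, dy_, dz_,
                       std::sqrt(std::pow(dx_ * voxel[0], 2) +
                                 std::pow(dy_ * voxel[1], 2) +
                                 std::pow(dz_ * voxel[2], 2))});
      }
  auto relax = [&](int x, int y, int z, int sx, int sy, int sz) {
    const R_xlen_t idx = (R_xlen_t)lin(x, y, z, nx, ny);
    if (d[idx] == 0.0) return;
    double best = d[idx];
    for (const Off& o : fwd) {
      const int qx = x + sx * o.x, qy = y + sy * o.y, qz = z + sz * o.z;
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz) {
        // outside the array counts as background at one step away
        if (o.w < best) best = o.w;
        continue;
      }
      const double v = d[(R_xlen_t)lin(qx, qy, qz, nx, ny)] + o.w;
      if (v < best) best = v;
    }
    d[idx] = best;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) relax(x, y, z, 1, 1, 1);
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) relax(x, y, z, -1, -1, -1);
  d.attr("dim") = dims;
  return d;
}

// ---------------------------------------------------------------------------
// Geodesic tracer: Dijkstra over foreground voxels with distance-transform-
// penalized edge weights (paths prefer tube centerlines), then iterative
// farthest-point path extraction with morphological coverage: the farthest
// uncovered voxel seeds a backtracked path to the growing tree, and every
// path voxel covers a ball of radius cover_k * dt. Terminal paths shorter
// than min_branch are covered but not added (surface-bump suppression).
// Returns the tree as voxel rows (x, y, z 0-based, parent row 0-based or
// -1, dt) plus the covered mask for multi-component looping in R.
// [[Rcpp::export]]
List trace_geodesic_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector voxel, NumericVector dt, int root0,
                        double cover_k, double cover_min,
                        double min_branch) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  const double INF = 1e30;

  // 26-neighbour offsets with physical step lengths
  struct Off { int dx, dy, dz; double step; };
  std::vector<Off> offs;
  for (int dz_ = -1; dz_ <= 1; ++dz_)
    for (int dy_ = -1; dy_ <= 1; ++dy_)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        if (dx_ == 0 && dy_ == 0 && dz_ == 0) continue;
        offs.push_back({dx_, dy_, dz_,
                        std::sqrt(std::pow(dx_ * voxel[0], 2) +
                                  std::pow(dy_ * voxel[1], 2) +
                                  std::pow(dz_ * voxel[2], 2))});
      }
  const double d0 = 0.5; // um; softness of the centerline preference
  auto penal = [&](R_xlen_t i) {
    return 0.1 + d0 / (dt[i] + d0);
  };

  std::vector<double> dist(ntot, INF), plen(ntot, INF);
  std::vector<R_xlen_t> parent(ntot, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[root0] = 0.0;
  plen[root0] = 0.0;
  pq.push({0.0, (R_xlen_t)root0});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    const double dcur = top.first;
    const R_xlen_t c = top.second;
    if (dcur > dist[c]) continue;
    const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
    for (const Off& o : offs) {
      const int qx = x + o.dx, qy = y + o.dy, qz = z + o.dz;
      if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
        continue;
      const R_xlen_t q = (R_xlen_t)lin(qx, qy, qz, nx, ny);
      if (!mask[q]) continue;
      const double nd = dcur + o.step * penal(q);
      if (nd < dist[q]) {
        dist[q] = nd;
        plen[q] = plen[c] + o.step;
        parent[q] = c;
        pq.push({nd, q});
      }
    }
  }

  // order reached voxels by penalized distance, descending
  std::vector<R_xlen_t> reached;
  for (R_xlen_t i = 0; i < ntot; ++i)
    if (mask[i] && dist[i] < INF) reached.push_back(i);
  std::sort(reached.begin(), reached.end(),
            [&](R_xlen_t a, R_xlen_t b) { return dist[a] > dist[b]; });

  std::vector<char> covered(ntot, 0), in_tree(ntot, 0);
  std::vector<int> tree_row(ntot, -1), zone(ntot, -1);
  std::vector<int> out_x, out_y, out_z, out_par;
  std::vector<double> out_dt;
  // mark the tube cross-section of a tree node as its attachment zone, so
  // a later path attaches where it enters an existing tube rather than
  // braiding alongside it
  auto mark_zone = [&](R_xlen_t v, int row) {
    const double r = std::max(dt[v], (double)voxel[0]);
    const int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
    const int rx = (int)std::ceil(r / voxel[0]),
              ry = (int)std::ceil(r / voxel[1]),
              rz = (int)std::ceil(r / voxel[2]);
    for (int dz_ = -rz; dz_ <= rz; ++dz_)
      for (int dy_ = -ry; dy_ <= ry; ++dy_)
        for (int dx_ = -rx; dx_ <= rx; ++dx_) {
          const int qx = x + dx_, qy = y + dy_, qz = z + dz_;
          if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 ||
              qz >= nz) continue;
          const double dd = std::pow(dx_ * voxel[0], 2) +
                            std::pow(dy_ * voxel[1], 2) +
                            std::pow(dz_ * voxel[2], 2);
          const R_xlen_t q = (R_xlen_t)lin(qx, qy, qz, nx, ny);
          if (dd <= r * r && zone[q] < 0) zone[q] = row;
        }
  };
  auto add_node = [&](R_xlen_t v, int par_row) {
    out_x.push_back((int)(v % nx));
    out_y.push_back((int)((v / nx) % ny));
    out_z.push_back((int)(v / ((R_xlen_t)nx * ny)));
    out_par.push_back(par_row);
    out_dt.push_back(dt[v]);
    in_tree[v] = 1;
    tree_row[v] = (int)out_x.size() - 1;
    mark_zone(v, tree_row[v]);
    return tree_row[v];
  };
  auto cover_ball = [&](R_xlen_t v) {
    const double r = cover_k * dt[v] + cover_min;
    const int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
    const int rx = (int)std::ceil(r / voxel[0]),
              ry = (int)std::ceil(r / voxel[1]),
              rz = (int)std::ceil(r / voxel[2]);
    for (int dz_ = -rz; dz_ <= rz; ++dz_)
      for (int dy_ = -ry; dy_ <= ry; ++dy_)
        for (int dx_ = -rx; dx_ <= rx; ++dx_) {
          const int qx = x + dx_, qy = y + dy_, qz = z + dz_;
          if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 ||
              qz >= nz) continue;
          const double dd = std::pow(dx_ * voxel[0], 2) +
                            std::pow(dy_ * voxel[1], 2) +
                            std::pow(dz_ * voxel[2], 2);
          if (dd <= r * r)
            covered[(R_xlen_t)lin(qx, qy, qz, nx, ny)] = 1;
        }
  };

  add_node((R_xlen_t)root0, -1);
  cover_ball((R_xlen_t)root0);

  for (R_xlen_t v : reached) {
    if (covered[v] || in_tree[v]) continue;
    // backtrack until the path enters an existing tree node's tube zone
    std::vector<R_xlen_t> path;
    R_xlen_t c = v;
    while (zone[c] < 0) {
      path.push_back(c);
      c = parent[c];
    }
    const double branch_len = plen[v] - plen[c];
    if (branch_len >= min_branch) {
      int par_row = zone[c];
      for (auto it = path.rbegin(); it != path.rend(); ++it)
        par_row = add_node(*it, par_row);
    }
    for (auto it = path.begin(); it != path.end(); ++it) cover_ball(*it);
  }

  const int n = (int)out_x.size();
  IntegerMatrix nodes(n, 4);
  NumericVector node_dt(n);
  for (int i = 0; i < n; ++i) {
    nodes(i, 0) = out_x[i];
    nodes(i, 1) = out_y[i];
    nodes(i, 2) = out_z[i];
    nodes(i, 3) = out_par[i];
    node_dt[i] = out_dt[i];
  }
  LogicalVector reached_out(ntot);
  for (R_xlen_t i : reached) reached_out[i] = true;
  return List::create(_["nodes"] = nodes, _["dt"] = node_dt,
                      _["reached"] = reached_out);
}

// ---------------------------------------------------------------------------
// 26-connected BFS flood fill restricted to `allowed`, seeded at 0-based
// linear indices.
// [[Rcpp::export]]
LogicalVector floodfill3d_cpp(LogicalVector allowed, IntegerVector dims,
                              IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::queue<R_xlen_t> q;
  for (int s : seeds) {
    if (s < 0 || s >= (R_xlen_t)nx * ny * nz) continue;
    if (allowed[s] && !out[s]) {
      out[s] = true;
      q.push(s);
    }
  }
  while (!q.empty()) {
    const R_xlen_t c = q.front(); q.pop();
    const int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
    for (int dz_ = -1; dz_ <= 1; ++dz_)
      for (int dy_ = -1; dy_ <= 1; ++dy_)
        for (int dx_ = -1; dx_ <= 1; ++dx_) {
          if (dx_ == 0 && dy_ == 0 && dz_ == 0) continue;
          const int qx = x + dx_, qy = y + dy_, qz = z + dz_;
          if (qx < 0 || qx >= nx || qy < 0 || qy >= ny || qz < 0 || qz >= nz)
            continue;
          const R_xlen_t i = (R_xlen_t)lin(qx, qy, qz, nx, ny);
          if (allowed[i] && !out[i]) {
            out[i] = true;
            q.push(i);
          }
        }
  }
  out.attr("dim") = dims;
  return out;
}
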