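// Core geometry kernels for periodic Voronoi tessellations on the unrolled
// vessel surface (a flat torus): hard-core point sampling, cell construction
// by half-plane clipping against 3x3 ghost-replicated generators, and
// orthographic projection of cells onto the image plane of a cylinder.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Poly {
  // polygon vertices (closed implicitly); lab[k] = neighbour id of edge
  // v[k] -> v[k+1], or -1 for a construction-box edge
  std::vector<double> x, y;
  std::vector<int> lab;
  size_t size() const { return x.size(); }
};

// Clip polygon to the half-plane of points nearer `site` than `nbr`
// (signed distance along the unit bisector normal <= 0). New edges created
// on the bisector are labelled `nid`.
void clip_halfplane(Poly &p, double sx, double sy, double nx_, double ny_,
                    int nid, double eps) {
  const size_t m = p.size();
  if (m == 0) return;
  double dx = nx_ - sx, dy = ny_ - sy;
  double len = std::sqrt(dx * dx + dy * dy);
  double ux = dx / len, uy = dy / len;
  double mx = 0.5 * (sx + nx_), my = 0.5 * (sy + ny_);

  std::vector<double> d(m);
  bool all_in = true;
  for (size_t k = 0; k < m; ++k) {
    d[k] = (p.x[k] - mx) * ux + (p.y[k] - my) * uy;
    if (d[k] > eps) all_in = false;
  }
  if (all_in) return;

  Poly out;
  out.x.reserve(m + 2); out.y.reserve(m + 2); out.lab.reserve(m + 2);
  for (size_t k = 0; k < m; ++k) {
    size_t k1 = (k + 1) % m;
    bool ain = d[k] <= eps, bin = d[k1] <= eps;
    if (ain) {
      out.x.push_back(p.x[k]); out.y.push_back(p.y[k]);
      if (bin) {
        out.lab.push_back(p.lab[k]);
      } else {
        out.lab.push_back(p.lab[k]);
        double t = d[k] / (d[k] - d[k1]);
        out.x.push_back(p.x[k] + t * (p.x[k1] - p.x[k]));
        out.y.push_back(p.y[k] + t * (p.y[k1] - p.y[k]));
        out.lab.push_back(nid);
      }
    } else if (bin) {
      double t = d[k] / (d[k] - d[k1]);
      out.x.push_back(p.x[k] + t * (p.x[k1] - p.x[k]));
      out.y.push_back(p.y[k] + t * (p.y[k1] - p.y[k]));
      out.lab.push_back(p.lab[k]);
    }
  }
  p = out;
}

double max_radius2(const Poly &p, double sx, double sy) {
  double r2 = 0.0;
  for (size_t k = 0; k < p.size(); ++k) {
    double dx = p.x[k] - sx, dy = p.y[k] - sy;
    r2 = std::max(r2, dx * dx + dy * dy);
  }
  return r2;
}

double shoelace(const Poly &p, double cx, double cy) {
  // computed relative to (cx, cy) to limit cancellation for small cells
  double a = 0.0;
  const size_t m = p.size();
  for (size_t k = 0; k < m; ++k) {
    size_t k1 = (k + 1) % m;
    a += (p.x[k] - cx) * (p.y[k1] - cy) - (p.x[k1] - cx) * (p.y[k] - cy);
  }
  return 0.5 * a;
}

struct Grid {
  double x0, y0, cs;
  int nx, ny;
  std::vector<std::vector<int>> bins;
  Grid(double x0_, double y0_, double ext_x, double ext_y, double cs_)
      : x0(x0_), y0(y0_), cs(cs_) {
    nx = std::max(1, (int)std::ceil(ext_x / cs));
    ny = std::max(1, (int)std::ceil(ext_y / cs));
    bins.assign((size_t)nx * ny, {});
  }
  void insert(int id, double x, double y) {
    int ix = std::min(nx - 1, std::max(0, (int)std::floor((x - x0) / cs)));
    int iy = std::min(ny - 1, std::max(0, (int)std::floor((y - y0) / cs)));
    bins[(size_t)iy * nx + ix].push_back(id);
  }
  void query(double x, double y, double r, std::vector<int> &out) const {
    int ix0 = std::max(0, (int)std::floor((x - r - x0) / cs));
    int ix1 = std::min(nx - 1, (int)std::floor((x + r - x0) / cs));
    int iy0 = std::max(0, (int)std::floor((y - r - y0) / cs));
    int iy1 = std::min(ny - 1, (int)std::floor((y + r - y0) / cs));
    out.clear();
    for (int iy = iy0; iy <= iy1; ++iy)
      for (int ix = ix0; ix <= ix1; ++ix) {
        const auto &b = bins[(size_t)iy * nx + ix];
        out.insert(out.end(), b.begin(), b.end());
      }
  }
};

} // namespace

// Sequentially sample points uniformly on the torus [0,W)x[0,H), rejecting
// proposals closer (toroidal metric) than `hc` to any accepted point.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_sample_hardcore(int n_target, double W, double H, double hc,
                                  double max_attempts) {
  RNGScope scope;
  std::vector<double> px, py;
  px.reserve(n_target); py.reserve(n_target);

  double cs = std::max(hc, 1e-12);
  int gx = std::max(1, (int)std::floor(W / cs));
  int gy = std::max(1, (int)std::floor(H / cs));
  double csx = W / gx, csy = H / gy;
  std::vector<std::vector<int>> bins((size_t)gx * gy);
  double hc2 = hc * hc;

  double attempts = 0;
  while ((int)px.size() < n_target) {
    if (attempts >= max_attempts)
      stop("hard-core sampling exceeded the attempt budget (%.0f attempts); "
           "density is too high for the requested hard-core distance",
           max_attempts);
    attempts += 1;
    double x = unif_rand() * W, y = unif_rand() * H;
    int ix = std::min(gx - 1, (int)std::floor(x / csx));
    int iy = std::min(gy - 1, (int)std::floor(y / csy));
    // search enough neighbouring bins to cover radius hc (bins >= hc wide
    // unless the domain is narrower than hc, then spans wrap fully)
    int rx = std::min(gx / 2 + 1, (int)std::ceil(hc / csx));
    int ry = std::min(gy / 2 + 1, (int)std::ceil(hc / csy));
    bool ok = true;
    for (int dy = -ry; dy <= ry && ok; ++dy)
      for (int dx = -rx; dx <= rx && ok; ++dx) {
        int jx = ((ix + dx) % gx + gx) % gx;
        int jy = ((iy + dy) % gy + gy) % gy;
        for (int id : bins[(size_t)jy * gx + jx]) {
          double ddx = std::fabs(px[id] - x); ddx = std::min(ddx, W - ddx);
          double ddy = std::fabs(py[id] - y); ddy = std::min(ddy, H - ddy);
          if (ddx * ddx + ddy * ddy < hc2) { ok = false; break; }
        }
      }
    if (ok) {
      px.push_back(x); py.push_back(y);
      bins[(size_t)iy * gx + ix].push_back((int)px.size() - 1);
    }
  }
  NumericMatrix out(n_target, 2);
  for (int i = 0; i < n_target; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}

// Periodic Voronoi tessellation of points on the torus [0,W)x[0,H).
// Each cell is built by clipping a large box around its generator with the
// bisectors of ghost-replicated generators (3x3 copies), processed in order
// of increasing distance with a security-radius stopping rule.
// Returns per-cell areas, flattened cell polygons, and the cell-edge table
// (one row per polygon edge, so each physical bisector appears twice).
// [[Rcpp::export]]
List cpp_periodic_voronoi(NumericVector x, NumericVector y, double W, double H,
                          bool keep_polygons) {
  const int n = x.size();
  if (n < 1) stop("need at least one generator point");
  const double area = W * H;
  const double spacing = std::sqrt(area / n);
  const double scale = std::max(W, H);
  const double eps = 1e-12 * scale;

  // ghost replication
  std::vector<double> gxv; gxv.reserve((size_t)9 * n);
  std::vector<double> gyv; gyv.reserve((size_t)9 * n);
  std::vector<int> gorig; gorig.reserve((size_t)9 * n);
  for (int sy = -1; sy <= 1; ++sy)
    for (int sx = -1; sx <= 1; ++sx)
      for (int i = 0; i < n; ++i) {
        gxv.push_back(x[i] + sx * W);
        gyv.push_back(y[i] + sy * H);
        gorig.push_back(i);
      }
  const int self_offset = 4 * n; // shift (0,0) block start

  Grid grid(-W, -H, 3 * W, 3 * H, std::max(spacing, 1e-9));
  for (size_t g = 0; g < gxv.size(); ++g) grid.insert((int)g, gxv[g], gyv[g]);

  NumericVector areas(n);
  std::vector<double> e_x1, e_y1, e_x2, e_y2;
  std::vector<int> e_cell, e_nbr;
  std::vector<double> poly_x, poly_y;
  IntegerVector poly_off(n + 1);
  poly_off[0] = 0;

  std::vector<int> cand;
  std::vector<std::pair<double, int>> ordered;
  const double r_cap = 3.0 * scale;
  const double min_edge = 1e-9 * spacing;

  for (int i = 0; i < n; ++i) {
    double sx = x[i], sy = y[i];
    Poly p;
    double half = 1.55 * scale;
    p.x = {sx - half, sx + half, sx + half, sx - half};
    p.y = {sy - half, sy - half, sy + half, sy + half};
    p.lab = {-1, -1, -1, -1};

    double r = 4.0 * spacing;
    size_t processed = 0;
    bool done = false;
    while (!done) {
      grid.query(sx, sy, r, cand);
      ordered.clear();
      for (int g : cand) {
        if (g == self_offset + i) continue;
        double dx = gxv[g] - sx, dy = gyv[g] - sy;
        double d2 = dx * dx + dy * dy;
        if (d2 <= r * r) ordered.emplace_back(d2, g);
      }
      std::sort(ordered.begin(), ordered.end());
      for (size_t k = processed; k < ordered.size(); ++k) {
        double d2 = ordered[k].first;
        if (d2 > 4.0 * max_radius2(p, sx, sy)) { done = true; break; }
        int g = ordered[k].second;
        clip_halfplane(p, sx, sy, gxv[g], gyv[g], g, eps);
      }
      if (!done) {
        processed = ordered.size();
        if (4.0 * max_radius2(p, sx, sy) <= r * r) done = true;
        else if (r >= r_cap) done = true; // all ghosts exhausted
        else r = std::min(2.0 * r, r_cap);
      }
    }

    for (size_t k = 0; k < p.size(); ++k)
      if (p.lab[k] == -1)
        stop("Voronoi cell %d is not bounded by bisectors; degenerate input",
             i + 1);

    areas[i] = shoelace(p, sx, sy);
    for (size_t k = 0; k < p.size(); ++k) {
      size_t k1 = (k + 1) % p.size();
      double ex = p.x[k1] - p.x[k], ey = p.y[k1] - p.y[k];
      if (std::sqrt(ex * ex + ey * ey) < min_edge) continue;
      e_cell.push_back(i + 1);
      e_nbr.push_back(gorig[p.lab[k]] + 1);
      e_x1.push_back(p.x[k]); e_y1.push_back(p.y[k]);
      e_x2.push_back(p.x[k1]); e_y2.push_back(p.y[k1]);
    }
    if (keep_polygons) {
      poly_x.insert(poly_x.end(), p.x.begin(), p.x.end());
      poly_y.insert(poly_y.end(), p.y.begin(), p.y.end());
    }
    poly_off[i + 1] = (int)poly_x.size();
  }

  return List::create(
      _["areas"] = areas,
      _["edge_cell"] = wrap(e_cell), _["edge_nbr"] = wrap(e_nbr),
      _["edge_x1"] = wrap(e_x1), _["edge_y1"] = wrap(e_y1),
      _["edge_x2"] = wrap(e_x2), _["edge_y2"] = wrap(e_y2),
      _["poly_x"] = wrap(poly_x), _["poly_y"] = wrap(poly_y),
      _["poly_offsets"] = poly_off);
}

// Orthographically projected (image-plane) area of each cell on the
// cylinder of radius r_o. A cell is "measured" when its generator lies on
// the visible arc |theta| < theta_vis; its polygon is clipped to the
// visible window, curved edges are subdivided, and x = r_o * sin(theta)
// maps the surface into the image plane. Excluded cells yield NA.
// [[Rcpp::export]]
NumericVector cpp_projected_areas(NumericVector poly_x, NumericVector poly_y,
                                  IntegerVector poly_off, NumericVector gen_u,
                                  double r_o, double W, double theta_vis,
                                  double max_dtheta) {
  const int n = gen_u.size();
  NumericVector out(n, NA_REAL);
  const double u_vis = r_o * theta_vis;

  for (int i = 0; i < n; ++i) {
    // shift so the generator's principal circumferential coordinate is used
    double shift = -std::round(gen_u[i] / W) * W;
    double gu = gen_u[i] + shift;
    if (std::fabs(gu) >= u_vis) continue;

    Poly p;
    for (int k = poly_off[i]; k < poly_off[i + 1]; ++k) {
      p.x.push_back(poly_x[k] + shift);
      p.y.push_back(poly_y[k]);
      p.lab.push_back(0);
    }
    if (p.size() < 3) continue;
    // clip to u <= u_vis and u >= -u_vis via two axis-aligned half-planes
    // (the bisector of (0,0) and (2*u_vis, 0) is the line u = u_vis)
    clip_halfplane(p, 0.0, 0.0, 2.0 * u_vis, 0.0, 0, 1e-12 * W);
    clip_halfplane(p, 0.0, 0.0, -2.0 * u_vis, 0.0, 0, 1e-12 * W);
    if (p.size() < 3) { out[i] = 0.0; continue; }

    // subdivide edges so the sin() mapping is well resolved, then shoelace
    std::vector<double> qx, qy;
    const size_t m = p.size();
    for (size_t k = 0; k < m; ++k) {
      size_t k1 = (k + 1) % m;
      double du = p.x[k1] - p.x[k];
      int nsub = std::max(1, (int)std::ceil(std::fabs(du) /
                                            (r_o * max_dtheta)));
      for (int s = 0; s < nsub; ++s) {
        double t = (double)s / nsub;
        qx.push_back(p.x[k] + t * (p.x[k1] - p.x[k]));
        qy.push_back(p.y[k] + t * (p.y[k1] - p.y[k]));
      }
    }
    double a = 0.0;
    for (size_t k = 0; k < qx.size(); ++k) {
      size_t k1 = (k + 1) % qx.size();
      double X0 = r_o * std::sin(qx[k] / r_o);
      double X1 = r_o * std::sin(qx[k1] / r_o);
      a += X0 * qy[k1] - X1 * qy[k];
    }
    out[i] = std::fabs(0.5 * a);
  }
  return out;
}
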