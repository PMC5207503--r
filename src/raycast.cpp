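// Per-pixel ray casting against a triangle mesh.
//
// A median-split BVH over triangle centroids accelerates the per-ray
// nearest-intersection query; intersection itself is the Moller-Trumbore
// test with a small symmetric epsilon on the barycentric bounds so rays
// grazing a shared edge register a hit on at least one of the adjacent
// triangles. Ties in depth are broken toward the lower triangle index so
// results are deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double BARY_EPS = 1e-9;   // slack on barycentric bounds
const double DET_EPS = 1e-12;   // parallel-ray determinant cutoff
const double T_MIN = 1e-9;      // minimum hit distance (avoid self-origin)
const double T_TIE = 1e-12;     // depth tie tolerance for id tie-breaking

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1;  // children; -1 for leaf
  int start = 0, count = 0;   // triangle index range for leaves
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;  // triangle indices, permuted during build
};

const int LEAF_SIZE = 4;

int build_node(BVH& bvh, const std::vector<Vec3>& cent,
               const std::vector<Vec3>& bmin, const std::vector<Vec3>& bmax,
               int start, int count) {
  BVHNode node;
  node.bmin[0] = node.bmin[1] = node.bmin[2] = R_PosInf;
  node.bmax[0] = node.bmax[1] = node.bmax[2] = R_NegInf;
  double cmin[3] = {R_PosInf, R_PosInf, R_PosInf};
  double cmax[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = start; i < start + count; ++i) {
    int t = bvh.order[i];
    const double lo[3] = {bmin[t].x, bmin[t].y, bmin[t].z};
    const double hi[3] = {bmax[t].x, bmax[t].y, bmax[t].z};
    const double cc[3] = {cent[t].x, cent[t].y, cent[t].z};
    for (int a = 0; a < 3; ++a) {
      node.bmin[a] = std::min(node.bmin[a], lo[a]);
      node.bmax[a] = std::max(node.bmax[a], hi[a]);
      cmin[a] = std::min(cmin[a], cc[a]);
      cmax[a] = std::max(cmax[a], cc[a]);
    }
  }
  int idx = (int)bvh.nodes.size();
  bvh.nodes.push_back(node);
  if (count <= LEAF_SIZE) {
    bvh.nodes[idx].start = start;
    bvh.nodes[idx].count = count;
    return idx;
  }
  int axis = 0;
  double ext = cmax[0] - cmin[0];
  for (int a = 1; a < 3; ++a) {
    if (cmax[a] - cmin[a] > ext) {
      ext = cmax[a] - cmin[a];
      axis = a;
    }
  }
  if (ext <= 0) {  // all centroids coincide; make a leaf
    bvh.nodes[idx].start = start;
    bvh.nodes[idx].count = count;
    return idx;
  }
  int mid = start + count / 2;
  auto key = [&](int t) {
    return axis == 0 ? cent[t].x : (axis == 1 ? cent[t].y : cent[t].z);
  };
  std::nth_element(bvh.order.begin() + start, bvh.order.begin() + mid,
                   bvh.order.begin() + start + count,
                   [&](int a, int b) { return key(a) < key(b); });
  int l = build_node(bvh, cent, bmin, bmax, start, mid - start);
  int r = build_node(bvh, cent, bmin, bmax, mid, start + count - mid);
  bvh.nodes[idx].left = l;
  bvh.nodes[idx].right = r;
  return idx;
}

inline bool slab_hit(const BVHNode& n, const Vec3& o, const Vec3& inv_d,
                     double tmax) {
  double t0 = 0.0, t1 = tmax;
  const double omin[3] = {o.x, o.y, o.z};
  const double inv[3] = {inv_d.x, inv_d.y, inv_d.z};
  for (int a = 0; a < 3; ++a) {
    double ta = (n.bmin[a] - omin[a]) * inv[a];
    double tb = (n.bmax[a] - omin[a]) * inv[a];
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta);
    t1 = std::min(t1, tb);
    if (t0 > t1) return false;
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".raycast_cpp")]]
List raycast_cpp(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                 NumericMatrix Rmat, double fx, double fy, double skew,
                 double ox, double oy, int width, int height) {
  const int nf = F.nrow();
  std::vector<Vec3> v0(nf), e1(nf), e2(nf), cent(nf), bmin(nf), bmax(nf),
      nrm(nf);
  for (int t = 0; t < nf; ++t) {
    Vec3 a = {V(F(t, 0), 0), V(F(t, 0), 1), V(F(t, 0), 2)};
    Vec3 b = {V(F(t, 1), 0), V(F(t, 1), 1), V(F(t, 1), 2)};
    Vec3 c = {V(F(t, 2), 0), V(F(t, 2), 1), V(F(t, 2), 2)};
    v0[t] = a;
    e1[t] = vsub(b, a);
    e2[t] = vsub(c, a);
    cent[t] = {(a.x + b.x + c.x) / 3.0, (a.y + b.y + c.y) / 3.0,
               (a.z + b.z + c.z) / 3.0};
    bmin[t] = {std::min({a.x, b.x, c.x}), std::min({a.y, b.y, c.y}),
               std::min({a.z, b.z, c.z})};
    bmax[t] = {std::max({a.x, b.x, c.x}), std::max({a.y, b.y, c.y}),
               std::max({a.z, b.z, c.z})};
    Vec3 n = vcross(e1[t], e2[t]);
    double nn = std::sqrt(vdot(n, n));
    if (nn > 0) {
      n.x /= nn;
      n.y /= nn;
      n.z /= nn;
    }
    nrm[t] = n;
  }

  BVH bvh;
  bvh.order.resize(nf);
  for (int t = 0; t < nf; ++t) bvh.order[t] = t;
  build_node(bvh, cent, bmin, bmax, 0, nf);

  const Vec3 o = {origin[0], origin[1], origin[2]};
  // rows of Rmat are the camera axes (right, down, forward) in world coords
  const Vec3 rx = {Rmat(0, 0), Rmat(0, 1), Rmat(0, 2)};
  const Vec3 ry = {Rmat(1, 0), Rmat(1, 1), Rmat(1, 2)};
  const Vec3 rz = {Rmat(2, 0), Rmat(2, 1), Rmat(2, 2)};

  NumericMatrix depth(height, width), px(height, width), py(height, width),
      pz(height, width), incid(height, width);
  IntegerMatrix hit(height, width);
  std::fill(depth.begin(), depth.end(), NA_REAL);
  std::fill(px.begin(), px.end(), NA_REAL);
  std::fill(py.begin(), py.end(), NA_REAL);
  std::fill(pz.begin(), pz.end(), NA_REAL);
  std::fill(incid.begin(), incid.end(), NA_REAL);
  std::fill(hit.begin(), hit.end(), NA_INTEGER);

  std::vector<int> stack(128);
  for (int u = 0; u < width; ++u) {
    for (int v = 0; v < height; ++v) {
      // invert the intrinsic matrix for the pixel-centre ray direction,
      // expressed in the camera frame with unit forward (z) component
      double yc = (v - oy) / fy;
      double xc = (u - ox - skew * yc) / fx;
      Vec3 d = {xc * rx.x + yc * ry.x + rz.x, xc * rx.y + yc * ry.y + rz.y,
                xc * rx.z + yc * ry.z + rz.z};
      Vec3 inv_d = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
      double best = R_PosInf;
      int best_id = -1;
      int sp = 0;
      stack[sp++] = 0;
      while (sp > 0) {
        const BVHNode& node = bvh.nodes[stack[--sp]];
        if (!slab_hit(node, o, inv_d, best)) continue;
        if (node.left < 0) {
          for (int i = node.start; i < node.start + node.count; ++i) {
            int t = bvh.order[i];
            Vec3 p = vcross(d, e2[t]);
            double det = vdot(e1[t], p);
            if (std::fabs(det) < DET_EPS) continue;
            double inv = 1.0 / det;
            Vec3 s = vsub(o, v0[t]);
            double bu = vdot(s, p) * inv;
            if (bu < -BARY_EPS || bu > 1.0 + BARY_EPS) continue;
            Vec3 q = vcross(s, e1[t]);
            double bv = vdot(d, q) * inv;
            if (bv < -BARY_EPS || bu + bv > 1.0 + BARY_EPS) continue;
            double tt = vdot(e2[t], q) * inv;
            if (tt <= T_MIN) continue;
            if (tt < best - T_TIE ||
                (std::fabs(tt - best) <= T_TIE && t < best_id)) {
              best = tt;
              best_id = t;
            }
          }
        } else {
          stack[sp++] = node.left;
          stack[sp++] = node.right;
        }
      }
      if (best_id >= 0) {
        // d has unit z in the camera frame, so the ray parameter equals the
        // planar depth Z of the hit point
        depth(v, u) = best;
        hit(v, u) = best_id + 1;  // 1-based triangle row
        px(v, u) = best * xc;
        py(v, u) = best * yc;
        pz(v, u) = best;
        double dn = std::sqrt(vdot(d, d));
        double ci = std::fabs(vdot(d, nrm[best_id])) / dn;
        incid(v, u) = std::acos(std::min(1.0, ci));
      }
    }
  }

  return List::create(_["depth"] = depth, _["hit"] = hit, _["px"] = px,
                      _["py"] = py, _["pz"] = pz, _["incidence"] = incid);
}
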