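// Geometry and knot-invariant inner loops.
//
// Three jobs live here because they dominate runtime:
//   1. KMT chain reduction (triangle-elimination with a piercing test),
//   2. crossing detection for a projected closed polygonal curve,
//   3. the Alexander polynomial of the diagram, computed exactly by
//      modular interpolation (two ~2^31 primes, symmetric lift), from
//      which |Delta(-1)| and |Delta(-2)| are read off.
//
// All tolerances are relative to the coordinate spread of the input so
// that angstrom-scale chains and their 100x-radius closure arcs behave
// identically.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

typedef long long ll;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// ---------------------------------------------------------------------------
// segment/triangle piercing test (Moller-Trumbore, conservative)
// ---------------------------------------------------------------------------
// Returns true when segment p->q passes through triangle (a,b,c).  'skip'
// points at a vertex the segment legitimately shares with the triangle
// (adjacent chain segment); a contact at that vertex is not a piercing.
// Near-degenerate configurations answer true (keep the vertex): a missed
// removal costs time, a wrong removal changes the topology.
static bool seg_pierces_tri(const double* p, const double* q,
                            const double* a, const double* b, const double* c,
                            const double* skip, double scale)
{
  double e1[3], e2[3], d[3], n[3];
  vsub(b, a, e1); vsub(c, a, e2); vsub(q, p, d);
  vcross(e1, e2, n);
  double nn = vnorm(n);
  if (nn < 1e-12 * scale * scale) return false;  // flat triangle: caller removes
  double dl = vnorm(d);
  if (dl < 1e-12 * scale) return false;          // zero-length segment

  double pv[3]; vcross(d, e2, pv);
  double det = vdot(e1, pv);
  if (std::fabs(det) < 1e-12 * dl * nn) {
    // segment parallel to the triangle plane
    double ap[3], aq[3];
    vsub(p, a, ap); vsub(q, a, aq);
    double eps = 1e-9 * scale;
    if (std::fabs(vdot(n, ap) / nn) > eps || std::fabs(vdot(n, aq) / nn) > eps)
      return false;
    // coplanar: conservative bounding-box answer
    for (int k = 0; k < 3; k++) {
      double smin = std::min(p[k], q[k]) - eps, smax = std::max(p[k], q[k]) + eps;
      double tmin = std::min(a[k], std::min(b[k], c[k])) - eps;
      double tmax = std::max(a[k], std::max(b[k], c[k])) + eps;
      if (smax < tmin || smin > tmax) return false;
    }
    return true;
  }
  double inv = 1.0 / det;
  double tv[3]; vsub(p, a, tv);
  double u = vdot(tv, pv) * inv;
  double qv[3]; vcross(tv, e1, qv);
  double v = vdot(d, qv) * inv;
  double tt = vdot(e2, qv) * inv;
  const double bt = 1e-10;
  if (u < -bt || v < -bt || u + v > 1.0 + bt) return false;
  if (tt < -bt || tt > 1.0 + bt) return false;
  if (skip) {
    double hit[3] = { p[0] + tt * d[0], p[1] + tt * d[1], p[2] + tt * d[2] };
    double dd[3]; vsub(hit, skip, dd);
    if (vnorm(dd) < 1e-6 * scale) return false;
  }
  return true;
}

static double coord_scale(const std::vector<std::array<double, 3>>& P) {
  double lo[3] = { 1e300, 1e300, 1e300 }, hi[3] = { -1e300, -1e300, -1e300 };
  for (size_t i = 0; i < P.size(); i++)
    for (int k = 0; k < 3; k++) {
      lo[k] = std::min(lo[k], P[i][k]);
      hi[k] = std::max(hi[k], P[i][k]);
    }
  double s = 0;
  for (int k = 0; k < 3; k++) s += (hi[k] - lo[k]) * (hi[k] - lo[k]);
  s = std::sqrt(s);
  return s > 1e-9 ? s : 1.0;
}

// ---------------------------------------------------------------------------
// KMT reduction
// ---------------------------------------------------------------------------
// Returns 1-based indices of the surviving vertices.  Open chains keep both
// endpoints; closed chains stop at 3 vertices.  A vertex goes when the
// triangle spanned with its neighbours is pierced by no other chain segment.

// [[Rcpp::export]]
IntegerVector kmt_indices_cpp(NumericMatrix pts, bool closed) {
  int n = pts.nrow();
  std::vector<std::array<double, 3>> P(n);
  for (int i = 0; i < n; i++) { P[i][0] = pts(i, 0); P[i][1] = pts(i, 1); P[i][2] = pts(i, 2); }
  double scale = coord_scale(P);

  // drop consecutive duplicates up front
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; i++) {
    if (!idx.empty()) {
      double d[3]; vsub(P[i].data(), P[idx.back()].data(), d);
      if (vnorm(d) < 1e-9 * scale) continue;
    }
    idx.push_back(i);
  }

  bool changed = true;
  while (changed) {
    changed = false;
    int i = closed ? 0 : 1;
    while (true) {
      int m = (int)idx.size();
      if (closed) { if (m <= 3 || i >= m) break; }
      else        { if (i >= m - 1) break; }
      int ipr = closed ? (i - 1 + m) % m : i - 1;
      int inx = closed ? (i + 1) % m : i + 1;
      const double* A = P[idx[ipr]].data();
      const double* B = P[idx[i]].data();
      const double* C = P[idx[inx]].data();

      double e1[3], e2[3], nx[3];
      vsub(B, A, e1); vsub(C, A, e2); vcross(e1, e2, nx);
      bool removable;
      if (vnorm(nx) < 1e-12 * scale * scale) {
        removable = true;  // collinear / spike
      } else {
        removable = true;
        int nseg = closed ? m : m - 1;
        for (int k = 0; k < nseg && removable; k++) {
          if (k == ipr || k == i) continue;  // the triangle's own sides
          int k2 = (k + 1) % m;
          const double* skip = NULL;
          if (k2 == ipr) skip = A;           // segment ending at A
          else if (k == inx) skip = C;       // segment starting at C
          if (seg_pierces_tri(P[idx[k]].data(), P[idx[k2]].data(),
                              A, B, C, skip, scale))
            removable = false;
        }
      }
      if (removable) {
        idx.erase(idx.begin() + i);
        changed = true;
        if (closed && i >= (int)idx.size()) break;
      } else {
        i++;
      }
    }
  }

  IntegerVector out(idx.size());
  for (size_t i = 0; i < idx.size(); i++) out[i] = idx[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// crossing detection for a closed projected curve
// ---------------------------------------------------------------------------
struct Crossing { double u, o; int sgn; };

// x,y: projected coordinates; z: height.  Segment i joins vertex i to
// (i+1) mod m.  Returns 0 and fills 'out', or 1 when the projection is not
// generic (crossing at a vertex, tangency, equal heights) so the caller can
// retry with another direction.
static int find_crossings(const std::vector<double>& x, const std::vector<double>& y,
                          const std::vector<double>& z, double scale,
                          std::vector<Crossing>& out)
{
  int m = (int)x.size();
  const double endtol = 1e-6;           // parameter-space band around vertices
  for (int i = 0; i < m; i++) {
    int i2 = (i + 1) % m;
    double rx = x[i2] - x[i], ry = y[i2] - y[i];
    for (int j = i + 2; j < m; j++) {
      if (i == 0 && j == m - 1) continue;  // adjacent through the wrap
      int j2 = (j + 1) % m;
      double sx = x[j2] - x[j], sy = y[j2] - y[j];
      double den = rx * sy - ry * sx;
      double qpx = x[j] - x[i], qpy = y[j] - y[i];
      double rl = std::sqrt(rx * rx + ry * ry), sl = std::sqrt(sx * sx + sy * sy);
      if (rl < 1e-12 * scale || sl < 1e-12 * scale) continue;
      if (std::fabs(den) < 1e-12 * rl * sl) {
        // parallel in projection: degenerate only if collinear and overlapping
        double cr = qpx * ry - qpy * rx;
        if (std::fabs(cr) < 1e-9 * scale * rl) {
          double t0 = (qpx * rx + qpy * ry) / (rl * rl);
          double t1 = t0 + (sx * rx + sy * ry) / (rl * rl);
          if (std::max(0.0, std::min(t0, t1)) <= std::min(1.0, std::max(t0, t1)))
            return 1;
        }
        continue;
      }
      double ti = (qpx * sy - qpy * sx) / den;
      double tj = (qpx * ry - qpy * rx) / den;
      if (ti < -endtol || ti > 1 + endtol || tj < -endtol || tj > 1 + endtol)
        continue;
      if (ti < endtol || ti > 1 - endtol || tj < endtol || tj > 1 - endtol)
        return 1;                         // essentially at a vertex
      double zi = z[i] + ti * (z[(i + 1) % m] - z[i]);
      double zj = z[j] + tj * (z[j2] - z[j]);
      if (std::fabs(zi - zj) < 1e-7 * scale) return 1;
      Crossing c;
      int s = (den > 0) ? 1 : -1;         // sign of cross(dir_i, dir_j)
      if (zi > zj) { c.o = i + ti; c.u = j + tj; c.sgn = s; }
      else         { c.o = j + tj; c.u = i + ti; c.sgn = -s; }
      out.push_back(c);
    }
  }
  return 0;
}

// ---------------------------------------------------------------------------
// modular arithmetic
// ---------------------------------------------------------------------------
static const ll P1 = 2147483647LL;   // 2^31 - 1
static const ll P2 = 2147483629LL;

static inline ll mmod(ll a, ll p) { a %= p; if (a < 0) a += p; return a; }
static ll modpow(ll b, ll e, ll p) {
  ll r = 1; b = mmod(b, p);
  while (e > 0) { if (e & 1) r = (r * b) % p; b = (b * b) % p; e >>= 1; }
  return r;
}
static inline ll minv(ll a, ll p) { return modpow(a, p - 2, p); }

// determinant mod p by Gaussian elimination; M is n x n row-major, destroyed
static ll det_mod(std::vector<ll>& M, int n, ll p) {
  ll det = 1;
  for (int c = 0; c < n; c++) {
    int piv = -1;
    for (int r = c; r < n; r++) if (M[r * n + c] != 0) { piv = r; break; }
    if (piv < 0) return 0;
    if (piv != c) {
      for (int k = c; k < n; k++) std::swap(M[piv * n + k], M[c * n + k]);
      det = p - det; if (det == p) det = 0;
    }
    ll pv = M[c * n + c];
    det = (det * pv) % p;
    ll ip = minv(pv, p);
    for (int r = c + 1; r < n; r++) {
      ll f = M[r * n + c];
      if (f == 0) continue;
      ll fi = (f * ip) % p;
      for (int k = c; k < n; k++) {
        M[r * n + k] = mmod(M[r * n + k] - fi * M[c * n + k] % p, p);
      }
    }
  }
  return det;
}

// Newton interpolation at x = 0..d; returns monomial coefficients mod p
static std::vector<ll> interp_mod(const std::vector<ll>& f, ll p) {
  int d = (int)f.size() - 1;
  std::vector<ll> dd(f);
  for (int l = 1; l <= d; l++) {
    for (int i = d; i >= l; i--) {
      ll num = mmod(dd[i] - dd[i - 1], p);
      dd[i] = (num * minv(l, p)) % p;   // x_i - x_{i-l} = l
    }
  }
  std::vector<ll> poly(d + 1, 0);
  poly[0] = dd[d];
  int deg = 0;
  for (int i = d - 1; i >= 0; i--) {
    // poly <- poly * (t - i) + dd[i]
    for (int k = deg + 1; k >= 1; k--) {
      ll shifted = poly[k - 1];
      ll scaled = (poly[k] == 0) ? 0 : (poly[k] * (ll)i) % p;
      // new coefficient k of poly*(t - i): old[k-1] - i*old[k]
      poly[k] = mmod(shifted - ((k <= deg) ? scaled : 0), p);
    }
    poly[0] = mmod(dd[i] - (poly[0] * (ll)i) % p, p);
    deg++;
  }
  return poly;
}

// ---------------------------------------------------------------------------
// Alexander invariants from a crossing list
// ---------------------------------------------------------------------------
// Returns 0 on success (d1 = |Delta(-1)|, d2 = |Delta(-2)|), 1 when the
// diagram fails internal validity checks and a new projection is needed.
static int alex_pair(std::vector<Crossing>& crs, double& d1, double& d2) {
  int n = (int)crs.size();
  if (n < 3) { d1 = 1; d2 = 1; return 0; }

  std::sort(crs.begin(), crs.end(),
            [](const Crossing& a, const Crossing& b) { return a.u < b.u; });
  std::vector<double> us(n);
  for (int k = 0; k < n; k++) us[k] = crs[k].u;

  // Alexander matrix: row per crossing k (ordered along the curve by its
  // underpass); incoming under-arc k, outgoing under-arc k+1, over-arc o.
  int nm = n - 1;                       // minor size after deleting row/col n-1
  std::vector<int> A(n * n, 0), B(n * n, 0);  // entry = A + B * t
  for (int k = 0; k < n; k++) {
    int k1 = (k + 1) % n;
    int o = (int)(std::upper_bound(us.begin(), us.end(), crs[k].o) - us.begin()) % n;
    if (o == k || o == k1) {
      A[k * n + k] += -1;
      A[k * n + k1] += 1;
    } else if (crs[k].sgn > 0) {
      A[k * n + k] += 1;
      B[k * n + k1] += -1;
      A[k * n + o] += -1; B[k * n + o] += 1;   // t - 1
    } else {
      B[k * n + k] += -1;
      A[k * n + k1] += 1;
      A[k * n + o] += -1; B[k * n + o] += 1;
    }
  }

  const ll primes[2] = { P1, P2 };
  std::vector<ll> coef[2];
  for (int ip = 0; ip < 2; ip++) {
    ll p = primes[ip];
    std::vector<ll> vals(nm + 1);
    std::vector<ll> M(nm * nm);
    for (int xv = 0; xv <= nm; xv++) {
      for (int r = 0; r < nm; r++)
        for (int c = 0; c < nm; c++)
          M[r * nm + c] = mmod((ll)A[r * n + c] + (ll)B[r * n + c] * xv, p);
      vals[xv] = det_mod(M, nm, p);
    }
    coef[ip] = interp_mod(vals, p);
  }

  // symmetric lift, cross-checked between the two primes
  int d = nm;
  std::vector<double> c(d + 1);
  for (int k = 0; k <= d; k++) {
    ll l1 = coef[0][k] > P1 / 2 ? coef[0][k] - P1 : coef[0][k];
    ll l2 = coef[1][k] > P2 / 2 ? coef[1][k] - P2 : coef[1][k];
    if (l1 != l2) return 1;             // coefficient outside lift range
    c[k] = (double)l1;
  }
  int lo = -1, hi = -1;
  for (int k = 0; k <= d; k++) if (c[k] != 0) { if (lo < 0) lo = k; hi = k; }
  if (lo < 0) return 1;                 // identically zero: invalid diagram

  double s1 = 0, s2 = 0, sum = 0, pw1 = 1, pw2 = 1;
  for (int k = lo; k <= hi; k++) {
    s1 += c[k] * pw1;  pw1 *= -1;
    s2 += c[k] * pw2;  pw2 *= -2;
    sum += c[k];
    if (std::fabs(s2) > 4e15) return 1; // out of exact double-integer range
  }
  if (std::fabs(std::fabs(sum) - 1.0) > 1e-9) return 1;  // |Delta(1)| must be 1
  d1 = std::fabs(s1);
  d2 = std::fabs(s2);
  return 0;
}

// ---------------------------------------------------------------------------
// batch driver: closures x projection retries
// ---------------------------------------------------------------------------
// base: open (or closed) chain vertices.  closures: list of k x 3 matrices of
// extra vertices appended to base; the polygon then wraps back to base[0].
// rots: ntries x 9 row-major rotation matrices tried in order until the
// projection is generic.  Returns nclosures x 3: det1, det2, n_crossings
// (NA when every projection failed).

// [[Rcpp::export]]
NumericMatrix alex_batch_cpp(NumericMatrix base, List closures, NumericMatrix rots) {
  int nb = base.nrow();
  int nc = closures.size();
  int ntries = rots.nrow();
  NumericMatrix out(nc, 3);

  for (int ci = 0; ci < nc; ci++) {
    NumericMatrix extra = closures[ci];
    int ne = extra.nrow();
    int m = nb + ne;
    std::vector<std::array<double, 3>> P(m);
    for (int i = 0; i < nb; i++) { P[i][0] = base(i, 0); P[i][1] = base(i, 1); P[i][2] = base(i, 2); }
    for (int i = 0; i < ne; i++) { P[nb + i][0] = extra(i, 0); P[nb + i][1] = extra(i, 1); P[nb + i][2] = extra(i, 2); }
    double scale = coord_scale(P);

    bool done = false;
    for (int r = 0; r < ntries && !done; r++) {
      std::vector<double> x(m), y(m), z(m);
      for (int i = 0; i < m; i++) {
        x[i] = rots(r, 0) * P[i][0] + rots(r, 1) * P[i][1] + rots(r, 2) * P[i][2];
        y[i] = rots(r, 3) * P[i][0] + rots(r, 4) * P[i][1] + rots(r, 5) * P[i][2];
        z[i] = rots(r, 6) * P[i][0] + rots(r, 7) * P[i][1] + rots(r, 8) * P[i][2];
      }
      std::vector<Crossing> crs;
      if (find_crossings(x, y, z, scale, crs) != 0) continue;
      double d1, d2;
      if (alex_pair(crs, d1, d2) != 0) continue;
      out(ci, 0) = d1; out(ci, 1) = d2; out(ci, 2) = (double)crs.size();
      done = true;
    }
    if (!done) { out(ci, 0) = NA_REAL; out(ci, 1) = NA_REAL; out(ci, 2) = NA_REAL; }
  }
  return out;
}
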