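#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Hartigan & Hartigan dip statistic: the sup-norm distance between the
// empirical CDF and the closest unimodal CDF (convex below the mode,
// concave above it, with an atom allowed at the mode).
//
// Derivation used here (counts units; dip = value / n at the end).
// Reduce to distinct values u_1 < ... < u_U with LO_t = #{x <= u_t},
// HI_t = #{x < u_t}.  G fits F within eps iff at each distinct value its
// value r_t and left limit l_t satisfy |LO_t - n r_t| <= n eps and
// |HI_t - n l_t| <= n eps.  For a mode at u_M with an atom, G splits into
// a convex chain through points 1..M-1 ending at (u_M, l) with
// l in [HI_M -/+ e], and a concave chain from (u_M, r), r in [LO_M -/+ e],
// through points M+1..U (e = n eps).  A mode placed inside a gap is never
// strictly better: the minimal convex-side value at mode position m is
// concave in m and the maximal concave-side value is convex in m, so the
// feasible mode positions within a gap form end-intervals and the gap
// endpoints are dominated by the adjacent atom placements.
//
// Each atom placement M requires three things of e:
//  * left band feasibility: a convex chain exists within the bands iff
//    the greatest convex minorant of the upper band edges clears the
//    lower edges; all edges shift linearly with e, so this reads
//    e >= exclL(M)/2 with exclL(M) the worst deviation between lower
//    targets LO_t and the convex hull of upper corners (u_t, HI_t) over
//    t <= M, excluding the knot's own (relaxed) band;
//  * right band feasibility, mirrored: e >= exclR(M)/2;
//  * the link: the minimal value the convex side can attain at u_M
//    (convex extrapolation forces it up) must not exceed the maximal
//    value the concave side can start from.  Both extremes are computed
//    exactly by a dynamic programme whose state is the convex polygon of
//    achievable (last slope, value) pairs.
// The dip is found by bisection on the slack e: at each probe, one
// forward pass yields every placement's minimal left-side end value and
// one backward (reflected) pass every maximal right-side start value;
// the probe is feasible when some placement with adequate side fits has
// a compatible link.  dip = (minimal feasible e) / n.

struct Sweep {
    std::vector<double> excl;   // max deviation excluding the last point
};

// lower-convex-hull sweep over corners (u, hi); deviations lo - hull(u)
static void sweep(const std::vector<double>& u,
                  const std::vector<double>& hi,
                  const std::vector<double>& lo,
                  Sweep& out) {
    const int U = (int) u.size();
    out.excl.assign(U, 0.0);
    std::vector<int> stack;
    std::vector<double> maxUpTo(U, 0.0);
    stack.reserve(U);
    for (int j = 0; j < U; ++j) {
        while (stack.size() >= 2) {
            int m = stack[stack.size() - 1];
            int a = stack[stack.size() - 2];
            double cross = (u[m] - u[a]) * (hi[j] - hi[a])
                         - (hi[m] - hi[a]) * (u[j] - u[a]);
            if (cross <= 0.0) stack.pop_back(); else break;
        }
        double spanMax = 0.0, base = 0.0;
        if (!stack.empty()) {
            int v = stack.back();
            base = maxUpTo[v];
            double du = u[j] - u[v];
            for (int t = v + 1; t < j; ++t) {
                double seg = hi[v] + (hi[j] - hi[v]) * (u[t] - u[v]) / du;
                double dev = lo[t] - seg;
                if (dev > spanMax) spanMax = dev;
            }
        }
        out.excl[j] = std::max(base, spanMax);
        maxUpTo[j] = std::max(out.excl[j], lo[j] - hi[j]);
        stack.push_back(j);
    }
}

// 2-D convex-region DP for the extremal value a convex nondecreasing
// chain can attain at the mode position.  State after point i: the convex
// set of (s, v) = (last segment slope, value at point i) pairs achievable
// by chains through the bands [lo_t - e, hi_t + e] (clipped to
// [gmin, gmax]).  Transitions: relax the slope upward (a following
// segment may be steeper: "shadow" toward +s, capped so a single step
// cannot overshoot the value range), shear v += s * dx, and clip v to the
// next band.  Tracking only a scalar profile is not enough: a chain that
// rides higher early can afford a flatter extrapolation later.

struct P2 { double s, v; };

static double cross2(const P2& o, const P2& a, const P2& b) {
    return (a.s - o.s) * (b.v - o.v) - (a.v - o.v) * (b.s - o.s);
}

// convex hull (CCW), tolerant of duplicates/collinear points
static std::vector<P2> hull2(std::vector<P2> pts) {
    std::sort(pts.begin(), pts.end(), [](const P2& a, const P2& b) {
        return a.s < b.s || (a.s == b.s && a.v < b.v);
    });
    pts.erase(std::unique(pts.begin(), pts.end(), [](const P2& a, const P2& b) {
        return a.s == b.s && a.v == b.v;
    }), pts.end());
    int n = (int) pts.size();
    if (n <= 2) return pts;
    std::vector<P2> h(2 * n);
    int k = 0;
    for (int i = 0; i < n; ++i) {
        while (k >= 2 && cross2(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
        h[k++] = pts[i];
    }
    int lower = k + 1;
    for (int i = n - 2; i >= 0; --i) {
        while (k >= lower && cross2(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
        h[k++] = pts[i];
    }
    h.resize(k - 1);
    return h;
}

// clip polygon to half-plane a*s + b*v <= c
static std::vector<P2> clip2(const std::vector<P2>& poly,
                             double a, double b, double c) {
    std::vector<P2> out;
    int n = (int) poly.size();
    if (n == 0) return out;
    for (int i = 0; i < n; ++i) {
        const P2& p = poly[i];
        const P2& q = poly[(i + 1) % n];
        double dp = a * p.s + b * p.v - c;
        double dq = a * q.s + b * q.v - c;
        if (dp <= 0) out.push_back(p);
        if ((dp < 0 && dq > 0) || (dp > 0 && dq < 0)) {
            double t = dp / (dp - dq);
            out.push_back({p.s + t * (q.s - p.s), p.v + t * (q.v - p.v)});
        }
    }
    if (n == 1) { if (a * poly[0].s + b * poly[0].v - c <= 0) out = poly;
                  else out.clear(); }
    if (n == 2) {
        out.clear();
        double dp = a * poly[0].s + b * poly[0].v - c;
        double dq = a * poly[1].s + b * poly[1].v - c;
        if (dp <= 0) out.push_back(poly[0]);
        if ((dp < 0 && dq > 0) || (dp > 0 && dq < 0)) {
            double t = dp / (dp - dq);
            out.push_back({poly[0].s + t * (poly[1].s - poly[0].s),
                           poly[0].v + t * (poly[1].v - poly[0].v)});
        }
        if (dq <= 0) out.push_back(poly[1]);
    }
    return out;
}

// all-knot extremal end values at slack e in one incremental pass:
// out[M] = minimal value a convex chain through bands at points 0..M-1
// can attain at u_M (gmin for M = 0); +Inf once the prefix is infeasible
static void min_end_all(const std::vector<double>& u,
                        const std::vector<double>& hi,
                        const std::vector<double>& lo,
                        double e, double gmin, double gmax,
                        std::vector<double>& out) {
    const int U = (int) u.size();
    out.assign(U, R_PosInf);
    out[0] = gmin;
    double L0 = std::max(lo[0] - e, gmin), U0 = std::min(hi[0] + e, gmax);
    if (L0 > U0) return;
    std::vector<P2> poly = { {0.0, L0}, {0.0, U0} };
    const double range = gmax - gmin;
    const double slack = 1e-11 * (range + 1.0);
    for (int i = 1; i < U; ++i) {
        double dx = u[i] - u[i - 1];
        if (dx <= 0) dx = 1e-300;
        double cap = range / dx + 1.0;
        poly = clip2(poly, 1.0, 0.0, cap);
        if (poly.empty()) return;
        double vmin = poly[0].v, vmax = poly[0].v;
        for (const P2& p : poly) {
            vmin = std::min(vmin, p.v); vmax = std::max(vmax, p.v);
        }
        poly.push_back({cap, vmin});
        poly.push_back({cap, vmax});
        poly = hull2(poly);
        for (P2& p : poly) p.v += p.s * dx;
        // knot at u_i: minimal end value before applying point i's band
        double best = R_PosInf;
        for (const P2& p : poly) best = std::min(best, p.v);
        out[i] = best;
        double Li = std::max(lo[i] - e, gmin) - slack;
        double Ui = std::min(hi[i] + e, gmax) + slack;
        if (Li > Ui) return;
        poly = clip2(poly, 0.0, 1.0, Ui);
        poly = clip2(poly, 0.0, -1.0, -Li);
        if (poly.empty()) return;
        poly = hull2(poly);
    }
}

// [[Rcpp::export(name = ".dip_cpp")]]
double dip_cpp(NumericVector x_sorted) {
    const int n = x_sorted.size();
    if (n < 1) stop("empty sample");

    std::vector<double> u, LO, HI;
    u.reserve(n); LO.reserve(n); HI.reserve(n);
    int i = 0;
    while (i < n) {
        int k = i;
        while (k + 1 < n && x_sorted[k + 1] == x_sorted[i]) ++k;
        u.push_back(x_sorted[i]);
        HI.push_back((double) i);
        LO.push_back((double) (k + 1));
        i = k + 1;
    }
    const int U = (int) u.size();
    if (U == 1) return 0.0;   // a point mass is exactly unimodal

    Sweep L;
    sweep(u, HI, LO, L);

    // reflected arrays for the concave side
    std::vector<double> ur(U), hir(U), lor(U);
    for (int t = 0; t < U; ++t) {
        ur[t]  = -u[U - 1 - t];
        hir[t] = -LO[U - 1 - t];
        lor[t] = -HI[U - 1 - t];
    }
    Sweep Rrev;
    sweep(ur, hir, lor, Rrev);
    std::vector<double> exclR(U);
    for (int t = 0; t < U; ++t) exclR[t] = Rrev.excl[U - 1 - t];

    const double N = (double) n;

    std::vector<double> base(U);
    double lo_e = R_PosInf;
    for (int M = 0; M < U; ++M) {
        base[M] = std::max(L.excl[M], exclR[M]) / 2.0;
        lo_e = std::min(lo_e, base[M]);
    }

    // feasibility of dip <= e/n: some knot M with base <= e whose convex
    // side can end at or below where its concave side can start
    std::vector<double> lmin, rmin;
    auto feasible = [&](double e) -> bool {
        min_end_all(ur, hir, lor, e, -N, 0.0, rmin);   // -r_max, reflected
        min_end_all(u, HI, LO, e, 0.0, N, lmin);
        for (int M = 0; M < U; ++M) {
            if (base[M] > e) continue;
            double lm = lmin[M], rm = rmin[U - 1 - M];
            if (!R_finite(lm) || !R_finite(rm)) continue;
            if (lm <= -rm) return true;
        }
        return false;
    };

    double hi_e = N;
    if (feasible(lo_e)) return lo_e / N;
    for (int it = 0; it < 80 && hi_e - lo_e > 1e-12 * N; ++it) {
        double mid = 0.5 * (lo_e + hi_e);
        if (feasible(mid)) hi_e = mid; else lo_e = mid;
    }
    return hi_e / N;

}
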