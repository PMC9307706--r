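// Two-boundary Wiener first-passage-time machinery.
//
// Conventions: unit diffusion coefficient; boundary separation a > 0; relative
// start z in (0, 1); drift v in evidence units per second.  The lower boundary
// is the error response under accuracy coding.  Densities are per second.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double SQRT_2PI = 2.5066282746310002;

// Density of the first passage through the LOWER boundary for the normalized
// process (v = 0, a = 1, start w), evaluated at normalized time tt = t / a^2.
// Small-time / large-time series with automatic regime selection; the number
// of terms is chosen so the truncation error of the normalized density is
// below `err` (Navarro & Fuss style bounds).
static double wfpt_f0(double tt, double w, double err) {
    if (tt <= 0.0) return 0.0;

    // number of terms needed by each representation
    double ks, kl;
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt *
                             std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
    } else {
        ks = 2.0;
    }
    if (M_PI * tt * err < 1.0) {
        kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
        kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
        kl = 1.0 / (M_PI * std::sqrt(tt));
    }

    double p = 0.0;
    if (ks < kl) {           // small-time representation
        int K = (int)std::ceil(ks);
        int lo = -((K - 1) / 2);
        int hi = ((K - 1) / 2) + ((K - 1) % 2);
        for (int k = lo; k <= hi; ++k) {
            double u = w + 2.0 * k;
            p += u * std::exp(-u * u / (2.0 * tt));
        }
        p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {                 // large-time representation
        int K = (int)std::ceil(kl);
        for (int k = 1; k <= K; ++k) {
            p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) *
                 std::sin(k * M_PI * w);
        }
        p *= M_PI;
    }
    return p > 0.0 ? p : 0.0;
}

// Lower-boundary density at decision time t with drift variability sv
// integrated out in closed form (Gaussian integral over drift).
static double wfpt_lower_sv(double t, double v, double a, double w,
                            double sv, double err) {
    if (t <= 0.0) return 0.0;
    double tt = t / (a * a);
    double f0 = wfpt_f0(tt, w, err);
    if (f0 <= 0.0) return 0.0;
    double g;
    if (sv > 0.0) {
        double s2t = sv * sv * t;
        g = std::exp((sv * sv * a * a * w * w - 2.0 * v * a * w - v * v * t) /
                     (2.0 * (1.0 + s2t))) /
            std::sqrt(1.0 + s2t);
    } else {
        g = std::exp(-v * a * w - v * v * t / 2.0);
    }
    return f0 * g / (a * a);
}

// Density of hitting `upper` at decision time t, sv integrated analytically.
static double wfpt_boundary(double t, bool upper, double v, double a,
                            double z, double sv, double err) {
    if (upper) return wfpt_lower_sv(t, -v, a, 1.0 - z, sv, err);
    return wfpt_lower_sv(t, v, a, z, sv, err);
}

// Gauss-Legendre nodes/weights on [-1, 1] by Newton iteration.
static void gauss_legendre(int n, std::vector<double>& x,
                           std::vector<double>& w) {
    x.assign(n, 0.0);
    w.assign(n, 0.0);
    int m = (n + 1) / 2;
    for (int i = 0; i < m; ++i) {
        double xi = std::cos(M_PI * (i + 0.75) / (n + 0.5));
        double pp = 0.0;
        for (int it = 0; it < 100; ++it) {
            double p0 = 1.0, p1 = 0.0;
            for (int j = 0; j < n; ++j) {
                double p2 = p1;
                p1 = p0;
                p0 = ((2.0 * j + 1.0) * xi * p1 - j * p2) / (j + 1.0);
            }
            pp = n * (xi * p0 - p1) / (xi * xi - 1.0);
            double dx = p0 / pp;
            xi -= dx;
            if (std::fabs(dx) < 1e-15) break;
        }
        x[i] = -xi;
        x[n - 1 - i] = xi;
        w[i] = 2.0 / ((1.0 - xi * xi) * pp * pp);
        w[n - 1 - i] = w[i];
    }
}

// Full density at observed rt: averages the Wiener density over the uniform
// start-point range (sz) and uniform non-decision-time range (st) with
// nq-point Gauss-Legendre quadrature per active dimension; sv is exact.
static double full_density_1(double rt, bool upper, double v, double a,
                             double ter, double z, double sv, double st,
                             double sz, int nq, double err,
                             const std::vector<double>& qx,
                             const std::vector<double>& qw) {
    if (rt <= 0.0) return 0.0;
    bool has_st = st > 0.0, has_sz = sz > 0.0;

    if (!has_st && !has_sz)
        return wfpt_boundary(rt - ter, upper, v, a, z, sv, err);

    double acc = 0.0;
    if (has_st && has_sz) {
        for (int i = 0; i < nq; ++i) {
            double ti = ter + 0.5 * st * qx[i];
            double td = rt - ti;
            if (td <= 0.0) continue;
            double inner = 0.0;
            for (int j = 0; j < nq; ++j) {
                double zj = z + 0.5 * sz * qx[j];
                inner += 0.5 * qw[j] *
                         wfpt_boundary(td, upper, v, a, zj, sv, err);
            }
            acc += 0.5 * qw[i] * inner;
        }
    } else if (has_st) {
        for (int i = 0; i < nq; ++i) {
            double ti = ter + 0.5 * st * qx[i];
            double td = rt - ti;
            if (td <= 0.0) continue;
            acc += 0.5 * qw[i] * wfpt_boundary(td, upper, v, a, z, sv, err);
        }
    } else {
        double td = rt - ter;
        if (td <= 0.0) return 0.0;
        for (int j = 0; j < nq; ++j) {
            double zj = z + 0.5 * sz * qx[j];
            acc += 0.5 * qw[j] * wfpt_boundary(td, upper, v, a, zj, sv, err);
        }
    }
    return acc;
}

// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, LogicalVector upper, double v,
                               double a, double z, double tol) {
    int n = t.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        bool up = upper.size() == 1 ? upper[0] : upper[i];
        out[i] = wfpt_boundary(t[i], up, v, a, z, 0.0, tol);
    }
    return out;
}

// [[Rcpp::export(name = ".full_density_cpp")]]
NumericVector full_density_cpp(NumericVector rt, LogicalVector upper, double v,
                               double a, double ter, double z, double sv,
                               double st, double sz, int nq, double tol) {
    std::vector<double> qx, qw;
    gauss_legendre(nq, qx, qw);
    int n = rt.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        bool up = upper.size() == 1 ? upper[0] : upper[i];
        out[i] = full_density_1(rt[i], up, v, a, ter, z, sv, st, sz, nq, tol,
                                qx, qw);
    }
    return out;
}

// Summed mixture log-likelihood for blocks of trials sharing parameters.
// Trials are concatenated; block b covers indices start[b] .. start[b]+len[b]-1
// (0-based starts) and uses v[b], a[b], ter[b].  Returns one log-likelihood
// per block.  The contaminant is uniform on (0, rt_ceiling] with its mass
// split over the two responses: density p_outlier / (2 * rt_ceiling).
// [[Rcpp::export(name = ".loglik_blocks_cpp")]]
NumericVector loglik_blocks_cpp(NumericVector rt, LogicalVector upper,
                                IntegerVector start, IntegerVector len,
                                NumericVector v, NumericVector a,
                                NumericVector ter, double z, double sv,
                                double st, double sz, double p_outlier,
                                double rt_ceiling, int nq, double tol) {
    std::vector<double> qx, qw;
    gauss_legendre(nq, qx, qw);
    int nb = start.size();
    NumericVector out(nb);
    double unif = p_outlier / (2.0 * rt_ceiling);
    for (int b = 0; b < nb; ++b) {
        double ll = 0.0;
        for (int i = start[b]; i < start[b] + len[b]; ++i) {
            double f = full_density_1(rt[i], upper[i], v[b], a[b], ter[b], z,
                                      sv, st, sz, nq, tol, qx, qw);
            double mix = (1.0 - p_outlier) * f +
                         (rt[i] <= rt_ceiling ? unif : 0.0);
            if (mix <= 0.0) {
                ll = R_NegInf;
                break;
            }
            ll += std::log(mix);
        }
        out[b] = ll;
    }
    return out;
}

// Euler-Maruyama forward simulation of single trials.  Uses R's RNG so that
// set.seed() governs reproducibility.  Returns rt (NA when no boundary is
// reached before the response window) and the boundary indicator.
// [[Rcpp::export(name = ".simulate_ddm_cpp")]]
List simulate_ddm_cpp(int n, double v, double a, double ter, double z,
                      double sv, double st, double sz, double dt,
                      double response_window) {
    NumericVector rt(n);
    LogicalVector upper(n);
    double sqdt = std::sqrt(dt);
    for (int i = 0; i < n; ++i) {
        double vi = sv > 0.0 ? R::rnorm(v, sv) : v;
        double zi = sz > 0.0 ? R::runif(z - sz / 2.0, z + sz / 2.0) : z;
        double ti = st > 0.0 ? R::runif(ter - st / 2.0, ter + st / 2.0) : ter;
        double x = zi * a;
        double tmax = response_window - ti;
        double t = 0.0;
        bool hit = false, up = false;
        while (t < tmax) {
            x += vi * dt + sqdt * R::norm_rand();
            t += dt;
            if (x >= a) { hit = true; up = true; break; }
            if (x <= 0.0) { hit = true; up = false; break; }
        }
        if (hit) {
            rt[i] = t + ti;
            upper[i] = up;
        } else {
            rt[i] = NA_REAL;
            upper[i] = NA_LOGICAL;
        }
    }
    return List::create(_["rt"] = rt, _["upper"] = upper);
}
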