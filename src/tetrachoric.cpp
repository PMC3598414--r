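#include <Rcpp.h>
using namespace Rcpp;

// Gauss-Legendre nodes/weights on [-1, 1] by Newton iteration on P_n.
static void gauss_legendre(int n, std::vector<double> &x, std::vector<double> &w) {
  x.assign(n, 0.0);
  w.assign(n, 0.0);
  for (int i = 0; i < (n + 1) / 2; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5));
    double z1 = 2.0, pp = 0.0;
    while (std::fabs(z - z1) > 1e-15) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p2 = p1;
        p1 = p0;
        p0 = ((2.0 * j + 1.0) * z * p1 - j * p2) / (j + 1.0);
      }
      pp = n * (z * p0 - p1) / (z * z - 1.0);
      z1 = z;
      z = z1 - p0 / pp;
    }
    x[i] = -z;
    x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp);
    w[n - 1 - i] = w[i];
  }
}

static const int GL_N = 24;
static std::vector<double> gl_x, gl_w;

static void ensure_gl() {
  if ((int)gl_x.size() != GL_N) gauss_legendre(GL_N, gl_x, gl_w);
}

// P(X > h, Y > k) for standard bivariate normal with correlation rho.
// Plackett's identity: d/drho P = phi2(h, k; rho); integrating from rho = 0
// with the substitution t = sin(u) removes the 1/sqrt(1-t^2) singularity:
//   P = Phi(-h) Phi(-k) + (1/2pi) Int_0^{asin(rho)}
//         exp(-(h^2 - 2 h k sin u + k^2) / (2 cos^2 u)) du
static double bvn_upper(double h, double k, double rho) {
  if (rho >= 1.0) return R::pnorm(-std::max(h, k), 0.0, 1.0, 1, 0);
  if (rho <= -1.0) {
    double p = R::pnorm(-h, 0.0, 1.0, 1, 0) - R::pnorm(k, 0.0, 1.0, 1, 0);
    return p > 0.0 ? p : 0.0;
  }
  ensure_gl();
  double p = R::pnorm(-h, 0.0, 1.0, 1, 0) * R::pnorm(-k, 0.0, 1.0, 1, 0);
  if (rho != 0.0) {
    double ub = std::asin(rho);
    double acc = 0.0;
    for (int i = 0; i < GL_N; ++i) {
      double u = 0.5 * ub * (gl_x[i] + 1.0);
      double s = std::sin(u), c2 = std::cos(u) * std::cos(u);
      acc += gl_w[i] * std::exp(-(h * h - 2.0 * s * h * k + k * k) / (2.0 * c2));
    }
    p += ub / (4.0 * M_PI) * acc;
  }
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// Bivariate normal density at (h, k) with correlation rho.
static double bvn_density(double h, double k, double rho) {
  double om = 1.0 - rho * rho;
  return std::exp(-(h * h - 2.0 * rho * h * k + k * k) / (2.0 * om)) /
         (2.0 * M_PI * std::sqrt(om));
}

// [[Rcpp::export(name = ".bvn_upper_cpp")]]
NumericVector bvn_upper_cpp(NumericVector h, NumericVector k, NumericVector rho) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bvn_upper(h[i], k[i], rho[i]);
  return out;
}

// Maximum-likelihood tetrachoric correlation with thresholds fixed at the
// observed margins: solves P(Z1 > h, Z2 > k; rho) = p11 for rho.
// Safeguarded Newton (derivative is the BVN density) inside a bisection
// bracket. Returns NA when a margin is fully degenerate. Boundary solutions
// are clamped to +/- rho_max and flagged by the caller via |rho|.
// [[Rcpp::export(name = ".tetra_ml_cpp")]]
NumericVector tetra_ml_cpp(NumericVector n00, NumericVector n01,
                           NumericVector n10, NumericVector n11) {
  const double rho_max = 0.9999;
  const double tol = 1e-12;
  int m = n00.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double a = n00[i], b = n01[i], c = n10[i], d = n11[i];
    // continuity correction: add 0.5 to empty cells so sparse tables give
    // finite interior estimates instead of boundary jumps
    if (a == 0.0 || b == 0.0 || c == 0.0 || d == 0.0) {
      if (a == 0.0) a = 0.5;
      if (b == 0.0) b = 0.5;
      if (c == 0.0) c = 0.5;
      if (d == 0.0) d = 0.5;
    }
    double n = a + b + c + d;
    double r1 = c + d, c1 = b + d; // positive margins
    if (n < 1 || r1 <= 0 || r1 >= n || c1 <= 0 || c1 >= n) {
      out[i] = NA_REAL;
      continue;
    }
    double h = R::qnorm(1.0 - r1 / n, 0.0, 1.0, 1, 0);
    double k = R::qnorm(1.0 - c1 / n, 0.0, 1.0, 1, 0);
    double p11 = d / n;
    double lo = -rho_max, hi = rho_max;
    double flo = bvn_upper(h, k, lo) - p11;
    double fhi = bvn_upper(h, k, hi) - p11;
    if (flo >= 0.0) { out[i] = -rho_max; continue; }
    if (fhi <= 0.0) { out[i] = rho_max; continue; }
    double rho = 0.0;
    for (int it = 0; it < 100; ++it) {
      double f = bvn_upper(h, k, rho) - p11;
      if (f > 0.0) hi = rho; else lo = rho;
      if (std::fabs(f) < tol || hi - lo < tol) break;
      double dens = bvn_density(h, k, rho);
      double step = (dens > 1e-300) ? f / dens : 0.0;
      double cand = rho - step;
      // fall back to bisection when Newton leaves the bracket
      rho = (cand > lo && cand < hi) ? cand : 0.5 * (lo + hi);
    }
    out[i] = rho;
  }
  return out;
}
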