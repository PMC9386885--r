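#include <Rcpp.h>
using namespace Rcpp;

// Upper-quadrant probability P(X > h, Y > k) of a standard bivariate normal
// with correlation r. Gauss-Legendre quadrature over the angular
// representation (Drezner-Wesolowsky / Genz style): 6, 12 or 20 nodes for
// |r| < 0.925, a singularity-subtracted expansion otherwise. Absolute error
// well below 1e-10 for |r| <= 0.999, which is all the likelihood search uses.

static const double GL_X6[3] = {0.9324695142031522, 0.6612093864662647,
                                0.2386191860831970};
static const double GL_W6[3] = {0.1713244923791705, 0.3607615730481384,
                                0.4679139345726904};
static const double GL_X12[6] = {0.9815606342467191, 0.9041172563704750,
                                 0.7699026741943050, 0.5873179542866171,
                                 0.3678314989981802, 0.1252334085114692};
static const double GL_W12[6] = {0.04717533638651177, 0.1069393259953183,
                                 0.1600783285433464, 0.2031674267230659,
                                 0.2334925365383547, 0.2491470458134029};
static const double GL_X20[10] = {0.9931285991850949, 0.9639719272779138,
                                  0.9122344282513259, 0.8391169718222188,
                                  0.7463319064601508, 0.6360536807265150,
                                  0.5108670019508271, 0.3737060887154196,
                                  0.2277858511416451, 0.07652652113349733};
static const double GL_W20[10] = {0.01761400713915212, 0.04060142980038694,
                                  0.06267204833410906, 0.08327674157670475,
                                  0.1019301198172404, 0.1181945319615184,
                                  0.1316886384491766, 0.1420961093183821,
                                  0.1491729864726037, 0.1527533871307259};

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

double bvn_upper(double h, double k, double r) {
  const double twopi = 2.0 * M_PI;
  if (r < -0.925) {
    // P(X>h, Y>k) = P(X>h) - P(X>h, -Y > -k), corr(X,-Y) = -r
    double p = phid(-h) - bvn_upper(h, -k, -r);
    return p > 0.0 ? p : 0.0;
  }
  if (r >= 1.0) return phid(-std::max(h, k));

  double bvn = 0.0;
  if (std::fabs(r) < 0.925) {
    if (r != 0.0) {
      const double *x, *w;
      int ng;
      double ar = std::fabs(r);
      if (ar < 0.3)       { x = GL_X6;  w = GL_W6;  ng = 3; }
      else if (ar < 0.75) { x = GL_X12; w = GL_W12; ng = 6; }
      else                { x = GL_X20; w = GL_W20; ng = 10; }
      double hk = h * k;
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    return bvn + phid(-h) * phid(-k);
  }

  // 0.925 <= r < 1
  double hk = h * k;
  double as = (1.0 - r) * (1.0 + r);
  double a = std::sqrt(as);
  double bs = (h - k) * (h - k);
  double c = (4.0 - hk) / 8.0;
  double d = (12.0 - hk) / 16.0;
  double asr = -(bs / as + hk) / 2.0;
  if (asr > -100.0)
    bvn = a * std::exp(asr) *
          (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
           c * d * as * as / 5.0);
  if (-hk < 100.0) {
    double b = std::sqrt(bs);
    bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * phid(-b / a) * b *
           (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
  }
  a /= 2.0;
  for (int i = 0; i < 10; i++) {
    for (int is = -1; is <= 1; is += 2) {
      double xs = a * (is * GL_X20[i] + 1.0);
      xs *= xs;
      double rs = std::sqrt(1.0 - xs);
      double asr2 = -(bs / xs + hk) / 2.0;
      if (asr2 > -100.0)
        bvn += a * GL_W20[i] * std::exp(asr2) *
               (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                (1.0 + c * xs * (1.0 + d * xs)));
    }
  }
  bvn = -bvn / twopi + phid(-std::max(h, k));
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

//' @noRd
// [[Rcpp::export(name = ".bvn_upper_cpp")]]
NumericVector bvn_upper_cpp(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvn_upper(h[i], k[i], r[i]);
  return out;
}

// score sign of the pairwise likelihood at rho: d loglik / d rho equals the
// (positive) bivariate-normal density times
//   g(rho) = n11/p11 - n10/p10 - n01/p01 + n00/p00,
// so the MLE is the root of g (Plackett's identity dP11/drho = phi2)
static double tetra_score(double rho, double h, double k, double n00,
                          double n01, double n10, double n11) {
  double p11 = bvn_upper(h, k, rho);
  double p10 = phid(-h) - p11;
  double p01 = phid(-k) - p11;
  double p00 = 1.0 - p11 - p10 - p01;
  const double eps = 1e-12;
  if (p11 < eps) p11 = eps;
  if (p10 < eps) p10 = eps;
  if (p01 < eps) p01 = eps;
  if (p00 < eps) p00 = eps;
  return n11 / p11 - n10 / p10 - n01 / p01 + n00 / p00;
}

// Illinois-damped regula falsi for the score root on (-0.999, 0.999);
// g is decreasing in rho, boundary cases clamp to the interval ends
static double tetra_mle(double h, double k, double n00, double n01, double n10,
                        double n11) {
  double a = -0.999, b = 0.999;
  double fa = tetra_score(a, h, k, n00, n01, n10, n11);
  double fb = tetra_score(b, h, k, n00, n01, n10, n11);
  if (fa <= 0.0) return a;  // likelihood still rising toward -1
  if (fb >= 0.0) return b;
  double side = 0.0;
  for (int it = 0; it < 100 && b - a > 1e-8; it++) {
    double c = (a * fb - b * fa) / (fb - fa);
    if (c <= a || c >= b) c = (a + b) / 2.0;
    double fc = tetra_score(c, h, k, n00, n01, n10, n11);
    if (fc > 0.0) {
      a = c; fa = fc;
      if (side > 0.0) fb /= 2.0;
      side = 1.0;
    } else if (fc < 0.0) {
      b = c; fb = fc;
      if (side < 0.0) fa /= 2.0;
      side = -1.0;
    } else {
      return c;
    }
  }
  return (a + b) / 2.0;
}

//' @noRd
// [[Rcpp::export(name = ".tetrachoric_pairs_cpp")]]
NumericVector tetrachoric_pairs_cpp(NumericVector n00, NumericVector n01,
                                    NumericVector n10, NumericVector n11) {
  int np = n00.size();
  NumericVector rho(np);
  for (int i = 0; i < np; i++) {
    double a = n00[i], b = n01[i], c = n10[i], d = n11[i];
    if (a == 0.0 || b == 0.0 || c == 0.0 || d == 0.0) {
      // continuity correction: keeps the MLE finite with empty cells
      a += 0.5; b += 0.5; c += 0.5; d += 0.5;
    }
    double n = a + b + c + d;
    double px1 = (c + d) / n;  // P(first variable = 1)
    double py1 = (b + d) / n;
    if (px1 <= 0.0 || px1 >= 1.0 || py1 <= 0.0 || py1 >= 1.0)
      stop("degenerate margin in 2x2 table");
    double h = R::qnorm(1.0 - px1, 0.0, 1.0, 1, 0);
    double k = R::qnorm(1.0 - py1, 0.0, 1.0, 1, 0);
    rho[i] = tetra_mle(h, k, a, b, c, d);
  }
  return rho;
}
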