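#include <Rcpp.h>
using namespace Rcpp;

// Kelvin offset used throughout the framework (279 K == 6 degC).
static const double KELVIN = 273.0;

static inline double logistic_stable(double a) {
  if (a > 0) return 1.0 / (1.0 + std::exp(-a));
  double e = std::exp(a);
  return e / (1.0 + e);
}

// One hourly step of the two-step precursor kinetics. Conversion of the
// precursor (x) into accumulated chill (y) happens at most once per step,
// after the kinetic update.
static inline void chill_step_inline(double &x, double &y, double tempK,
                                     double E0, double E1, double A0,
                                     double A1, double TfK, double slope) {
  double xs = (A0 / A1) * std::exp((E1 - E0) / tempK);
  double k1 = A1 * std::exp(-E1 / tempK);
  double xt = xs - (xs - x) * std::exp(-k1);
  if (xt >= 1.0) {
    // xi = s/(1+s), s = exp(slope*TfK*(T-TfK)/T); evaluated in logistic form
    double xi = logistic_stable(slope * TfK * (tempK - TfK) / tempK);
    y += xi * xt;
    x = xt * (1.0 - xi);
  } else {
    x = xt;
  }
}

// [[Rcpp::export]]
NumericVector cpp_chill_accumulate(NumericVector tempC, double E0, double E1,
                                   double A0, double A1, double Tf,
                                   double slope) {
  int n = tempC.size();
  NumericVector y(n);
  double x = 0.0, yy = 0.0, TfK = Tf + KELVIN;
  for (int i = 0; i < n; ++i) {
    chill_step_inline(x, yy, tempC[i] + KELVIN, E0, E1, A0, A1, TfK, slope);
    y[i] = yy;
  }
  return y;
}

static inline double gdh_hour_inline(double t, double Tb, double Tu,
                                     double Tc) {
  if (t <= Tb || t >= Tc) return 0.0;
  if (t <= Tu)
    return 0.5 * (Tu - Tb) * (1.0 + std::cos(M_PI + M_PI * (t - Tb) / (Tu - Tb)));
  return (Tu - Tb) * (1.0 + std::cos(M_PI_2 + M_PI_2 * (t - Tu) / (Tc - Tu)));
}

// [[Rcpp::export]]
NumericVector cpp_gdh_hour(NumericVector tempC, double Tb, double Tu,
                           double Tc) {
  int n = tempC.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = gdh_hour_inline(tempC[i], Tb, Tu, Tc);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gdh_accumulate(NumericVector tempC, double Tb, double Tu,
                                 double Tc, NumericVector weights) {
  int n = tempC.size();
  NumericVector z(n);
  double zz = 0.0;
  for (int i = 0; i < n; ++i) {
    zz += weights[i] * gdh_hour_inline(tempC[i], Tb, Tu, Tc);
    z[i] = zz;
  }
  return z;
}

// Full season loop: chill kinetics, chill-gated heat accumulation, first
// hour at which z >= zc. Returns the 1-based bloom hour or NA.
// [[Rcpp::export]]
List cpp_simulate_season(NumericVector tempC, double E0, double E1, double A0,
                         double A1, double Tf, double slope, double Tb,
                         double Tu, double Tc, double yc, double zc,
                         double s1, bool trajectories) {
  int n = tempC.size();
  double x = 0.0, y = 0.0, z = 0.0, TfK = Tf + KELVIN;
  int bloom = NA_INTEGER;
  NumericVector ytraj, ztraj;
  if (trajectories) {
    ytraj = NumericVector(n);
    ztraj = NumericVector(n);
  }
  for (int i = 0; i < n; ++i) {
    chill_step_inline(x, y, tempC[i] + KELVIN, E0, E1, A0, A1, TfK, slope);
    double w = logistic_stable(s1 * (y - yc));
    z += w * gdh_hour_inline(tempC[i], Tb, Tu, Tc);
    if (trajectories) {
      ytraj[i] = y;
      ztraj[i] = z;
    }
    if (bloom == NA_INTEGER && z >= zc) {
      bloom = i + 1;
      if (!trajectories) break;
    }
  }
  List out = List::create(_["bloom_hour"] = bloom);
  if (trajectories) {
    out["chill"] = ytraj;
    out["heat"] = ztraj;
  }
  return out;
}

// Vectorized bloom prediction over a set of seasons (objective-function
// hot path). temps and doys are parallel lists: hourly temperatures and the
// day-of-year of each hour. Returns predicted bloom DOY, NA for no bloom.
// [[Rcpp::export]]
NumericVector cpp_predict_bloom(List temps, List doys, double E0, double E1,
                                double A0, double A1, double Tf, double slope,
                                double Tb, double Tu, double Tc, double yc,
                                double zc, double s1) {
  int m = temps.size();
  NumericVector out(m);
  double TfK = Tf + KELVIN;
  for (int s = 0; s < m; ++s) {
    NumericVector tc = temps[s];
    NumericVector dd = doys[s];
    int n = tc.size();
    double x = 0.0, y = 0.0, z = 0.0;
    double res = NA_REAL;
    for (int i = 0; i < n; ++i) {
      chill_step_inline(x, y, tc[i] + KELVIN, E0, E1, A0, A1, TfK, slope);
      double w = logistic_stable(s1 * (y - yc));
      z += w * gdh_hour_inline(tc[i], Tb, Tu, Tc);
      if (z >= zc) {
        res = dd[i];
        break;
      }
    }
    out[s] = res;
  }
  return out;
}
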