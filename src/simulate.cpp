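#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Terminal footprint: truncated 2D Gaussian density profile evaluated at the
// centers of the unit squares whose centers lie within the disc, normalised
// to peak weight 1 (sensor amounts are surface densities: the square under
// the disc center carries density ~S). Offsets are stored relative to
// floor(center); they remain valid under the unit displacements of the
// random walk because the fractional part of the center never changes.
struct Footprint {
  std::vector<int> dx, dy;
  std::vector<double> w; // Gaussian profile, max = 1
};

static Footprint make_footprint(double cx, double cy, double radius,
                                double sigma) {
  Footprint fp;
  double fx = cx - std::floor(cx), fy = cy - std::floor(cy);
  int r = (int)std::ceil(radius) + 1;
  double wmax = 0.0;
  for (int dx = -r; dx <= r; ++dx) {
    for (int dy = -r; dy <= r; ++dy) {
      double ox = dx + 0.5 - fx, oy = dy + 0.5 - fy;
      double d2 = ox * ox + oy * oy;
      if (d2 <= radius * radius) {
        double w = std::exp(-d2 / (2.0 * sigma * sigma));
        fp.dx.push_back(dx);
        fp.dy.push_back(dy);
        fp.w.push_back(w);
        if (w > wmax) wmax = w;
      }
    }
  }
  if (wmax > 0) for (size_t k = 0; k < fp.w.size(); ++k) fp.w[k] /= wmax;
  return fp;
}

// [[Rcpp::export]]
List cpp_simulate(List field, List term, List params, int n_iter, int stride) {
  const int W = as<int>(field["width"]);
  const int H = as<int>(field["height"]);
  NumericMatrix LT = field["L_T"], RT = field["R_T"];
  NumericMatrix resL = field["resident_L"], resR = field["resident_R"];

  NumericVector x = clone(as<NumericVector>(term["x"]));
  NumericVector y = clone(as<NumericVector>(term["y"]));
  NumericVector RF = clone(as<NumericVector>(term["R_F"]));
  NumericVector LF = clone(as<NumericVector>(term["L_F"]));
  NumericVector RF0 = term["R_F0"], LF0 = term["L_F0"];
  LogicalVector mobile = term["mobile"];
  const int n = x.size();

  const double mu = as<double>(params["mu"]);
  const double lam = as<double>(params["lambda"]);
  const int h = as<int>(params["h"]);
  const double beta = as<double>(params["beta"]);
  const double qx = as<double>(params["q_x"]);
  const bool qx_everywhere = as<bool>(params["q_x_everywhere"]);
  const double kappa = as<double>(params["kappa"]);
  const double C0 = as<double>(params["C0"]);
  const int j_onset = as<int>(params["j_onset"]);
  const int ramp_len = as<int>(params["ramp_len"]);
  const bool ramp_on = as<bool>(params["ramp_on"]);
  const bool do_move = as<bool>(params["do_move"]);
  // pre-adapting factor in the tract: sensors held while the terminal
  // stands on cue-free ground (tectal-entry scenario)
  const bool hold_off_target = as<bool>(params["hold_off_target"]);
  const double radius = as<double>(params["radius"]);
  const double sigma = as<double>(params["sigma_frac"]) * radius;
  const double sfloor = as<double>(params["sensor_floor"]);
  // 0 = coadaptation, 1 = canonical, 2 = none
  const int mode = as<int>(params["mode"]);

  // fiber-derived cue densities seen by everyone (residents folded in)
  NumericMatrix Lf(W, H), Rf(W, H);
  for (int i = 0; i < W; ++i)
    for (int j = 0; j < H; ++j) {
      Lf(i, j) = resL(i, j);
      Rf(i, j) = resR(i, j);
    }

  std::vector<Footprint> fps(n);
  std::vector<int> bx(n), by(n);
  for (int t = 0; t < n; ++t) {
    fps[t] = make_footprint(x[t], y[t], radius, sigma);
    bx[t] = (int)std::floor(x[t]);
    by[t] = (int)std::floor(y[t]);
  }

  auto infield_wsum = [&](int t, int cbx, int cby) -> double {
    const Footprint &f = fps[t];
    double s = 0.0;
    for (size_t k = 0; k < f.w.size(); ++k) {
      int ix = cbx + f.dx[k], iy = cby + f.dy[k];
      if (ix >= 0 && ix < W && iy >= 0 && iy < H) s += f.w[k];
    }
    return s;
  };

  auto add_contrib = [&](int t, double sgn) {
    const Footprint &f = fps[t];
    for (size_t k = 0; k < f.w.size(); ++k) {
      int ix = bx[t] + f.dx[k], iy = by[t] + f.dy[k];
      if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
        Lf(ix, iy) += sgn * f.w[k] * LF[t];
        Rf(ix, iy) += sgn * f.w[k] * RF[t];
      }
    }
  };

  // the walk bias applies on cue-free ground: the square the terminal
  // center stands on carries no target cue (the footprint may already
  // sense a nearby field)
  auto cue_free = [&](int t) -> bool {
    int ix = bx[t], iy = by[t];
    if (ix < 0 || ix >= W || iy < 0 || iy >= H) return true;
    return LT(ix, iy) + RT(ix, iy) < 1e-9;
  };

  auto local_cues = [&](int t, double &Rt, double &Lt) {
    const Footprint &f = fps[t];
    double s = infield_wsum(t, bx[t], by[t]);
    Rt = 0.0;
    Lt = 0.0;
    if (s <= 0) return;
    for (size_t k = 0; k < f.w.size(); ++k) {
      int ix = bx[t] + f.dx[k], iy = by[t] + f.dy[k];
      if (ix < 0 || ix >= W || iy < 0 || iy >= H) continue;
      double wn = f.w[k] / s;
      Rt += wn * RT(ix, iy);
      Lt += wn * LT(ix, iy);
    }
  };

  // D history ring buffers (zero padded: naive start)
  std::vector<double> hist((size_t)n * h, 0.0);
  int ring = 0;
  const double khsum = h * (h + 1.0) / 2.0;

  std::vector<double> maxx(n), maxdev(n, 0.0), ratio0(n);
  for (int t = 0; t < n; ++t) {
    maxx[t] = x[t];
    ratio0[t] = RF[t] / LF[t];
  }

  const int n_rec = (stride > 0) ? n_iter / stride : 0;
  NumericMatrix trX(n_rec, n), trY(n_rec, n), trRF(n_rec, n), trLF(n_rec, n),
      trD(n_rec, n);
  NumericVector Dcur(n, NA_REAL);

  for (int t = 0; t < n; ++t) add_contrib(t, 1.0);

  // C(i): weight of trans fiber-fiber signals
  auto fiber_C = [&](int it) -> double {
    if (!ramp_on) return C0;
    double r = (it - j_onset) / (double)ramp_len;
    if (r < 0) r = 0;
    if (r > 1) r = 1;
    return C0 * r;
  };

  const int dirx[4] = {1, -1, 0, 0};
  const int diry[4] = {0, 0, 1, -1};
  int rec = 0;

  for (int it = 0; it < n_iter; ++it) {
    double C = fiber_C(it);
    for (int t = 0; t < n; ++t) {
      if (!mobile[t]) continue;
      // remove own contribution: Lf/Rf now hold everybody else (terminals
      // processed earlier this iteration already sit at their new state)
      add_contrib(t, -1.0);

      // Eq. 1 at the current position; own cis term added explicitly
      const Footprint &f = fps[t];
      double s = infield_wsum(t, bx[t], by[t]);
      double D;
      if (s <= 0) {
        D = 0.0; // off-field: no signalling
      } else {
        double num = 0.0, den = 0.0;
        for (size_t k = 0; k < f.w.size(); ++k) {
          int ix = bx[t] + f.dx[k], iy = by[t] + f.dy[k];
          if (ix < 0 || ix >= W || iy < 0 || iy >= H) continue;
          double lf = f.w[k] * LF[t], rf = f.w[k] * RF[t];
          num += lf * (RT(ix, iy) + rf + C * Rf(ix, iy));
          den += rf * (LT(ix, iy) + lf + C * Lf(ix, iy));
        }
        if (num <= 0 || den <= 0)
          stop("guidance potential undefined for terminal %d at iteration %d "
               "(num=%g den=%g R_F=%g L_F=%g)",
               t + 1, it + 1, num, den, RF[t], LF[t]);
        D = std::fabs(std::log(num / den));
      }
      if (!std::isfinite(D))
        stop("non-finite guidance potential for terminal %d at iteration %d",
             t + 1, it + 1);
      Dcur[t] = D;

      hist[(size_t)t * h + ring] = D;
      double ws = 0.0;
      int idx = (ring + 1) % h;
      for (int k = 1; k <= h; ++k) {
        ws += k * hist[(size_t)t * h + idx];
        idx = (idx + 1) % h;
      }
      double wmean = ws / khsum;

      bool held = hold_off_target && cue_free(t);
      if (held) {
        // sensors frozen by the tract's pre-adapting signal
      } else if (mode == 0) { // co-adaptation: same a for both species
        double a = 1.0 + std::log1p(mu * wmean);
        RF[t] = a * RF[t] + lam * (RF0[t] - RF[t]);
        LF[t] = a * LF[t] + lam * (LF0[t] - LF[t]);
      } else if (mode == 1) { // canonical: independent relaxation to cues
        double Rt, Lt;
        local_cues(t, Rt, Lt);
        RF[t] += kappa * (Rt - RF[t]);
        LF[t] += kappa * (Lt - LF[t]);
      }
      if (RF[t] < sfloor) RF[t] = sfloor;
      if (LF[t] < sfloor) LF[t] = sfloor;
      if (!std::isfinite(RF[t]) || !std::isfinite(LF[t]))
        stop("non-finite sensor level for terminal %d at iteration %d", t + 1,
             it + 1);
      double dev = std::fabs(RF[t] / LF[t] - ratio0[t]) / ratio0[t];
      if (dev > maxdev[t]) maxdev[t] = dev;

      if (do_move) {
        bool cf = qx_everywhere || cue_free(t);
        double bD[4];
        double bp[4];
        bool okc[4];
        double mn = R_PosInf;
        for (int d = 0; d < 4; ++d) {
          okc[d] = false;
          double cx2 = x[t] + dirx[d], cy2 = y[t] + diry[d];
          if (cx2 < 0 || cx2 >= W || cy2 < 0 || cy2 >= H) continue;
          int nbx = bx[t] + dirx[d], nby = by[t] + diry[d];
          double sN = infield_wsum(t, nbx, nby);
          double Dc;
          if (sN <= 0) {
            continue; // would lose all signalling: treat as off-field
          } else {
            double num = 0.0, den = 0.0;
            for (size_t k = 0; k < f.w.size(); ++k) {
              int ix = nbx + f.dx[k], iy = nby + f.dy[k];
              if (ix < 0 || ix >= W || iy < 0 || iy >= H) continue;
              double lf = f.w[k] * LF[t], rf = f.w[k] * RF[t];
              num += lf * (RT(ix, iy) + rf + C * Rf(ix, iy));
              den += rf * (LT(ix, iy) + lf + C * Lf(ix, iy));
            }
            if (num <= 0 || den <= 0)
              Dc = R_PosInf;
            else
              Dc = std::fabs(std::log(num / den));
          }
          okc[d] = true;
          bD[d] = Dc;
          if (std::isfinite(Dc) && Dc < mn) mn = Dc;
          bp[d] = cf ? (d == 0 ? qx : (1.0 - qx) / 3.0) : 0.25;
        }
        if (!std::isfinite(mn)) mn = 0.0;
        double wts[4], tot = 0.0;
        for (int d = 0; d < 4; ++d) {
          wts[d] = okc[d] ? bp[d] * std::exp(-beta * (bD[d] - mn)) : 0.0;
          tot += wts[d];
        }
        if (tot > 0) {
          double r = unif_rand() * tot, cum = 0.0;
          int pick = -1;
          for (int d = 0; d < 4; ++d) {
            if (!okc[d]) continue;
            cum += wts[d];
            if (r <= cum) {
              pick = d;
              break;
            }
            pick = d; // fall back to last admissible direction
          }
          x[t] += dirx[pick];
          y[t] += diry[pick];
          bx[t] += dirx[pick];
          by[t] += diry[pick];
          if (x[t] > maxx[t]) maxx[t] = x[t];
        }
      }
      add_contrib(t, 1.0);
    }
    if (stride > 0 && (it + 1) % stride == 0) {
      for (int t = 0; t < n; ++t) {
        trX(rec, t) = x[t];
        trY(rec, t) = y[t];
        trRF(rec, t) = RF[t];
        trLF(rec, t) = LF[t];
        trD(rec, t) = Dcur[t];
      }
      ++rec;
    }
    ring = (ring + 1) % h;
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  List trace = R_NilValue;
  if (stride > 0) {
    IntegerVector iters(n_rec);
    for (int r2 = 0; r2 < n_rec; ++r2) iters[r2] = (r2 + 1) * stride;
    trace = List::create(_["iteration"] = iters, _["x"] = trX, _["y"] = trY,
                         _["R_F"] = trRF, _["L_F"] = trLF, _["D"] = trD);
  }
  return List::create(
      _["x"] = x, _["y"] = y, _["R_F"] = RF, _["L_F"] = LF, _["D"] = Dcur,
      _["max_x"] = NumericVector(maxx.begin(), maxx.end()),
      _["max_ratio_dev"] = NumericVector(maxdev.begin(), maxdev.end()),
      _["trace"] = trace);
}

// Single evaluation of the guidance potential with the same code path as the
// simulation loop; used by tests to cross-check the R implementation.
// [[Rcpp::export]]
double cpp_eval_potential(List field, List term, int which, double C,
                          double radius, double sigma_frac) {
  const int W = as<int>(field["width"]);
  const int H = as<int>(field["height"]);
  NumericMatrix LT = field["L_T"], RT = field["R_T"];
  NumericMatrix resL = field["resident_L"], resR = field["resident_R"];
  NumericVector x = term["x"], y = term["y"];
  NumericVector RF = term["R_F"], LF = term["L_F"];
  const int n = x.size();
  const int t = which - 1;
  const double sigma = sigma_frac * radius;

  NumericMatrix Lf(W, H), Rf(W, H);
  for (int i = 0; i < W; ++i)
    for (int j = 0; j < H; ++j) {
      Lf(i, j) = resL(i, j);
      Rf(i, j) = resR(i, j);
    }
  // accumulate the *other* terminals' densities
  for (int u = 0; u < n; ++u) {
    if (u == t) continue;
    Footprint f = make_footprint(x[u], y[u], radius, sigma);
    int ubx = (int)std::floor(x[u]), uby = (int)std::floor(y[u]);
    for (size_t k = 0; k < f.w.size(); ++k) {
      int ix = ubx + f.dx[k], iy = uby + f.dy[k];
      if (ix >= 0 && ix < W && iy >= 0 && iy < H) {
        Lf(ix, iy) += f.w[k] * LF[u];
        Rf(ix, iy) += f.w[k] * RF[u];
      }
    }
  }
  Footprint f = make_footprint(x[t], y[t], radius, sigma);
  int tbx = (int)std::floor(x[t]), tby = (int)std::floor(y[t]);
  double s = 0.0;
  for (size_t k = 0; k < f.w.size(); ++k) {
    int ix = tbx + f.dx[k], iy = tby + f.dy[k];
    if (ix >= 0 && ix < W && iy >= 0 && iy < H) s += f.w[k];
  }
  if (s <= 0) return NA_REAL;
  double num = 0.0, den = 0.0;
  for (size_t k = 0; k < f.w.size(); ++k) {
    int ix = tbx + f.dx[k], iy = tby + f.dy[k];
    if (ix < 0 || ix >= W || iy < 0 || iy >= H) continue;
    double lf = f.w[k] * LF[t], rf = f.w[k] * RF[t];
    num += lf * (RT(ix, iy) + rf + C * Rf(ix, iy));
    den += rf * (LT(ix, iy) + lf + C * Lf(ix, iy));
  }
  if (num <= 0 || den <= 0) return R_PosInf;
  return std::fabs(std::log(num / den));
}
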