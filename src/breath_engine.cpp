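// Breath-by-breath gas-exchange engine.
//
// One call advances the coupled airway / alveolar / capillary / circulation
// state through a single breath (square-wave inspiratory and expiratory
// flow). Airway and capillary compartments use unconditionally stable
// backward-Euler updates (airways swept root-to-leaf on inhale and
// leaf-to-root on exhale; capillary trains swept inlet-to-outlet with Newton
// iteration on the dissociation curve); alveolar compartments use a
// mass-conserving operator split: advection, then membrane diffusion, then
// arterial/venous mixing.
//
// Units: volumes ml, flows ml/s inside the engine, pressures mmHg, gas
// amounts ml STPD. Gas columns: 0 = O2, 1 = CO2.

#include <Rcpp.h>
using namespace Rcpp;

struct Chem {
  double Hb, P50, hill_n, o2_capacity, beta_O2, co2_intercept, co2_slope;
  bool linear;
  double beta_linear;

  double o2_sat(double p) const {
    double pn = std::pow(p, hill_n), p50n = std::pow(P50, hill_n);
    return pn / (pn + p50n);
  }
  double content(int gas, double p) const {
    if (linear) return beta_linear * p;
    if (gas == 0) return o2_capacity * Hb / 100.0 * o2_sat(p) + beta_O2 * p;
    return co2_intercept + co2_slope * p;
  }
  double dcontent(int gas, double p) const {
    if (linear) return beta_linear;
    if (gas == 1) return co2_slope;
    double s = o2_sat(p);
    double ds = (p > 0) ? hill_n * s * (1.0 - s) / p : 0.0;
    return o2_capacity * Hb / 100.0 * ds + beta_O2;
  }
  // invert content -> pressure by Newton with bisection fallback
  double pressure(int gas, double c, double p_guess) const {
    if (linear) return c / beta_linear;
    if (gas == 1) return std::max((c - co2_intercept) / co2_slope, 0.0);
    double p = std::max(p_guess, 1e-8);
    for (int it = 0; it < 60; ++it) {
      double f = content(0, p) - c;
      double d = dcontent(0, p);
      double step = f / d;
      p -= step;
      if (p < 0) p = 1e-8;
      if (std::fabs(step) < 1e-10) return p;
    }
    // fallback: bisection on [0, 1500]
    double lo = 0.0, hi = 1500.0;
    if (content(0, hi) < c) stop("O2 content above physical maximum");
    for (int it = 0; it < 200; ++it) {
      double mid = 0.5 * (lo + hi);
      if (content(0, mid) < c) lo = mid; else hi = mid;
    }
    return 0.5 * (lo + hi);
  }
};

// Solve one backward-Euler capillary division for end-of-step pressure:
//   C(P)(1+a) - C0 - a*C_in - b*(P_Alv - P) = 0
static double solve_division(const Chem& ch, int gas, double C0, double C_in,
                             double a, double b, double P_Alv,
                             double P_start) {
  if (ch.linear || gas == 1) {
    double beta = ch.linear ? ch.beta_linear : ch.co2_slope;
    double icpt = ch.linear ? 0.0 : ch.co2_intercept;
    // C = icpt + beta*P  ->  (icpt + beta P)(1+a) = C0 + a C_in + b(P_Alv - P)
    double P = (C0 + a * C_in + b * P_Alv - icpt * (1.0 + a)) /
               (beta * (1.0 + a) + b);
    return std::max(P, 0.0);
  }
  // safeguarded Newton: F is strictly increasing in P, so keep a bracket
  double lo = 0.0, hi = 2000.0;
  double P = std::min(std::max(P_start, 1e-8), hi);
  for (int it = 0; it < 120; ++it) {
    double F = ch.content(gas, P) * (1.0 + a) - C0 - a * C_in -
               b * (P_Alv - P);
    if (F > 0) hi = P; else lo = P;
    double dF = ch.dcontent(gas, P) * (1.0 + a) + b;
    double step = F / dF;
    double Pn = P - step;
    if (Pn <= lo || Pn >= hi) Pn = 0.5 * (lo + hi);  // bisect when outside
    if (std::fabs(Pn - P) < 1e-11) return Pn;
    P = Pn;
  }
  if (hi - lo < 1e-6) return 0.5 * (lo + hi);
  stop("capillary dissociation-curve inversion failed");
  return P;
}

// [[Rcpp::export]]
List engine_run_breath(List topo, List state_in, List pars) {
  // topology (0-based indices, precompiled in R)
  IntegerVector aw_parent = topo["aw_parent"];   // -1 for root
  IntegerVector order     = topo["order"];       // root-first topological order
  NumericVector aw_vol    = topo["aw_vol"];
  NumericVector aw_frac   = topo["aw_frac"];     // subtended ventilation frac
  IntegerVector seg_leaf  = topo["seg_leaf"];
  NumericVector ds_vol    = topo["ds_vol"];
  NumericVector f_seg     = topo["f"];
  NumericVector fV        = topo["fV"];
  NumericVector fQ        = topo["fQ"];
  NumericVector alv_floor = topo["alv_floor"];
  const int n_aw = aw_vol.size();
  const int n_seg = f_seg.size();

  // state (cloned: the engine is a pure function of its inputs)
  NumericMatrix aw_C  = clone(as<NumericMatrix>(state_in["aw_C"]));
  NumericMatrix ds_C  = clone(as<NumericMatrix>(state_in["ds_C"]));
  NumericMatrix alv_C = clone(as<NumericMatrix>(state_in["alv_C"]));
  NumericVector alv_V = clone(as<NumericVector>(state_in["alv_V"]));
  NumericVector cap_P = clone(as<NumericVector>(state_in["cap_P"]));
  NumericVector C_ven = clone(as<NumericVector>(state_in["C_ven"]));

  // parameters
  const double dt_req   = as<double>(pars["dt"]);
  const double V_T      = as<double>(pars["V_T"]);
  const double Freq     = as<double>(pars["Freq"]);
  const double insp_fr  = as<double>(pars["insp_fraction"]);
  NumericVector C_insp  = pars["C_insp"];
  const double Q_Tot    = as<double>(pars["Q_Tot"]) / 60.0;   // ml/s
  const double shunt    = as<double>(pars["shunt"]);
  NumericVector dl_red  = pars["dl_red"];
  const double D_L_CO2  = as<double>(pars["D_L_CO2"]);
  const double work     = as<double>(pars["work"]);
  const double dl_floor = as<double>(pars["dl_floor"]);
  const double dl_fixed = as<double>(pars["dl_fixed_o2"]); // <=0: use quadratic
  const double dl_scale = as<double>(pars["dl_scale"]);    // allometric factor
  const double VO2      = as<double>(pars["VO2"]) / 60.0;  // ml/s STPD
  const double VCO2     = as<double>(pars["VCO2"]) / 60.0;
  const double V_ven    = as<double>(pars["V_ven"]);
  const double C_floor  = as<double>(pars["C_floor"]);
  const double V_cap    = as<double>(pars["V_capillary"]);
  const int    n_div    = as<int>(pars["n_div"]);
  const double RT       = as<double>(pars["RT"]);
  const bool   clamp_v  = as<bool>(pars["clamp_venous"]);

  Chem ch;
  List chl = pars["chem"];
  ch.Hb = as<double>(chl["Hb"]); ch.P50 = as<double>(chl["P50"]);
  ch.hill_n = as<double>(chl["hill_n"]);
  ch.o2_capacity = as<double>(chl["o2_capacity"]);
  ch.beta_O2 = as<double>(chl["beta_O2"]);
  ch.co2_intercept = as<double>(chl["co2_intercept"]);
  ch.co2_slope = as<double>(chl["co2_slope"]);
  ch.linear = as<bool>(chl["linear"]);
  ch.beta_linear = as<double>(chl["beta_linear"]);

  const double T = 60.0 / Freq;
  const double T_in = insp_fr * T, T_ex = T - T_in;

  // initial stored gas (for the per-breath mass balance)
  double stored0[2] = {0.0, 0.0};
  for (int g = 0; g < 2; ++g) {
    for (int i = 0; i < n_aw; ++i) stored0[g] += aw_C(i, g) * aw_vol[i];
    for (int k = 0; k < n_seg; ++k)
      stored0[g] += ds_C(k, g) * ds_vol[k] + alv_C(k, g) * alv_V[k];
  }

  double inspired[2] = {0, 0}, expired[2] = {0, 0}, transfer_tot[2] = {0, 0};
  double art_int[2] = {0, 0};            // time integral of arterial content
  double vo2_used_int = 0.0;             // delivered O2, ml
  double C_art[2] = {NA_REAL, NA_REAL};

  std::vector<double> inlet_acc(n_aw);   // exhale: child inflow accumulator

  for (int phase = 0; phase < 2; ++phase) {
    const bool inhale = (phase == 0);
    const double T_ph = inhale ? T_in : T_ex;
    const int n_steps = std::max(1, (int)std::ceil(T_ph / dt_req - 1e-9));
    const double dt = T_ph / n_steps;
    const double flow_tot = V_T / T_ph;  // ml/s

    for (int s = 0; s < n_steps; ++s) {
      // ---- 1. airway transport (implicit sweep) ----
      if (inhale) {
        for (int oi = 0; oi < n_aw; ++oi) {
          int i = order[oi];
          double cin_O2, cin_CO2;
          int p = aw_parent[i];
          if (p < 0) { cin_O2 = C_insp[0]; cin_CO2 = C_insp[1]; }
          else { cin_O2 = aw_C(p, 0); cin_CO2 = aw_C(p, 1); }
          double r = flow_tot * aw_frac[i] * dt / aw_vol[i];
          aw_C(i, 0) = (aw_C(i, 0) + r * cin_O2) / (1.0 + r);
          aw_C(i, 1) = (aw_C(i, 1) + r * cin_CO2) / (1.0 + r);
        }
        inspired[0] += flow_tot * C_insp[0] * dt;
        inspired[1] += flow_tot * C_insp[1] * dt;
        // dead-space compartments then alveolar advection
        for (int k = 0; k < n_seg; ++k) {
          double q = flow_tot * fV[k];
          int leaf = seg_leaf[k];
          for (int g = 0; g < 2; ++g) {
            double r = q * dt / ds_vol[k];
            ds_C(k, g) = (ds_C(k, g) + r * aw_C(leaf, g)) / (1.0 + r);
            double M = alv_C(k, g) * alv_V[k] + q * dt * ds_C(k, g);
            alv_C(k, g) = M / (alv_V[k] + q * dt);
          }
          alv_V[k] += q * dt;
        }
      } else {
        // exhale: alveolus -> dead space -> leaf -> ... -> trachea
        for (int k = 0; k < n_seg; ++k) {
          double q = flow_tot * fV[k];
          double V_new = alv_V[k] - q * dt;
          if (V_new < alv_floor[k])
            stop("alveolar volume underflow in segment %d", k + 1);
          for (int g = 0; g < 2; ++g) {
            double r = q * dt / ds_vol[k];
            ds_C(k, g) = (ds_C(k, g) + r * alv_C(k, g)) / (1.0 + r);
          }
          alv_V[k] = V_new;  // concentration unchanged by outflow
        }
        for (int g = 0; g < 2; ++g) {
          std::fill(inlet_acc.begin(), inlet_acc.end(), 0.0);
          for (int k = 0; k < n_seg; ++k)
            inlet_acc[seg_leaf[k]] += flow_tot * fV[k] * ds_C(k, g);
          for (int oi = n_aw - 1; oi >= 0; --oi) {
            int i = order[oi];
            double q = flow_tot * aw_frac[i];
            double cin = inlet_acc[i] / q;  // flow-weighted child mix
            double r = q * dt / aw_vol[i];
            aw_C(i, g) = (aw_C(i, g) + r * cin) / (1.0 + r);
            int p = aw_parent[i];
            if (p >= 0) inlet_acc[p] += q * aw_C(i, g);
            else expired[g] += q * aw_C(i, g) * dt;
          }
        }
      }

      // ---- 2. membrane diffusion + capillary trains ----
      for (int k = 0; k < n_seg; ++k) {
        double P_alv_O2 = alv_C(k, 0) * RT;
        double dl_o2_whole;
        if (dl_fixed > 0) dl_o2_whole = dl_fixed;
        else {
          // quadratic D_L(P, work), pressure clamped to its validity range
          double Pq = std::min(P_alv_O2, 110.0);
          dl_o2_whole = -0.0078 * Pq * Pq +
                        (0.3 + work / 833.0) * Pq + 76.0 + work / 6.0;
          dl_o2_whole *= dl_scale;
          if (dl_o2_whole < dl_floor) dl_o2_whole = dl_floor;
        }
        double Q_c = (1.0 - shunt) * Q_Tot * fQ[k];  // ml/s
        if (Q_c <= 0) continue;
        double V_div = V_cap * f_seg[k] / n_div;
        for (int g = 0; g < 2; ++g) {
          double dl_seg = (g == 0)
            ? f_seg[k] * dl_o2_whole * (1.0 - dl_red[k])
            : f_seg[k] * D_L_CO2;
          double gdiff = (dl_seg / n_div) / 60.0;     // ml/(mmHg*s)/division
          double a = Q_c * dt / V_div;
          double b = gdiff * dt / V_div;
          double P_alv = alv_C(k, g) * RT;
          double C_in = C_ven[g];
          double transfer = 0.0;
          for (int d = 0; d < n_div; ++d) {
            int idx = k + n_seg * d + n_seg * n_div * g;
            double P0 = cap_P[idx];          // state stored as pressure
            double Cc0 = ch.content(g, P0);
            double P1 = solve_division(ch, g, Cc0, C_in, a, b, P_alv, P0);
            double C1 = ch.content(g, P1);
            transfer += gdiff * (P_alv - P1) * dt;
            cap_P[idx] = P1;
            C_in = C1;
          }
          // remove transferred gas from the alveolus (exact conservation)
          alv_C(k, g) -= transfer / alv_V[k];
          if (alv_C(k, g) < 0) alv_C(k, g) = 0;  // guard (never hit at defaults)
          transfer_tot[g] += transfer;
        }
      }

      // ---- 3. arterial mixing and venous/tissue pool ----
      for (int g = 0; g < 2; ++g) {
        double cap_out = 0.0;
        for (int k = 0; k < n_seg; ++k) {
          int idx = k + n_seg * (n_div - 1) + n_seg * n_div * g;
          cap_out += fQ[k] * ch.content(g, cap_P[idx]);
        }
        C_art[g] = (1.0 - shunt) * cap_out + shunt * C_ven[g];
        art_int[g] += C_art[g] * dt;
      }
      double delivered = std::min(VO2, Q_Tot * std::max(0.0, C_art[0] - C_floor));
      vo2_used_int += delivered * dt;
      if (!clamp_v) {
        C_ven[0] += dt * (Q_Tot * (C_art[0] - C_ven[0]) - delivered) / V_ven;
        C_ven[1] += dt * (Q_Tot * (C_art[1] - C_ven[1]) + VCO2) / V_ven;
        if (C_ven[0] < 0) C_ven[0] = 0;
      }

      for (int i = 0; i < n_aw; ++i)
        if (!std::isfinite(aw_C(i, 0)) || !std::isfinite(aw_C(i, 1)))
          stop("numerical instability: non-finite airway state");
    }
  }

  // per-breath mass balance: in - out - d(storage) - to_blood = residual
  double residual[2];
  for (int g = 0; g < 2; ++g) {
    double stored1 = 0.0;
    for (int i = 0; i < n_aw; ++i) stored1 += aw_C(i, g) * aw_vol[i];
    for (int k = 0; k < n_seg; ++k)
      stored1 += ds_C(k, g) * ds_vol[k] + alv_C(k, g) * alv_V[k];
    residual[g] = inspired[g] - expired[g] - (stored1 - stored0[g]) -
                  transfer_tot[g];
  }

  NumericVector alv_P(n_seg);
  for (int k = 0; k < n_seg; ++k) alv_P[k] = alv_C(k, 0) * RT;

  return List::create(
    _["aw_C"] = aw_C, _["ds_C"] = ds_C, _["alv_C"] = alv_C,
    _["alv_V"] = alv_V, _["cap_P"] = cap_P, _["C_ven"] = C_ven,
    _["C_art"] = NumericVector::create(C_art[0], C_art[1]),
    _["C_art_mean"] = NumericVector::create(art_int[0] / T, art_int[1] / T),
    _["alv_P_O2"] = alv_P,
    _["uptake"] = NumericVector::create(transfer_tot[0], transfer_tot[1]),
    _["inspired"] = NumericVector::create(inspired[0], inspired[1]),
    _["expired"] = NumericVector::create(expired[0], expired[1]),
    _["residual"] = NumericVector::create(residual[0], residual[1]),
    _["vo2_delivered_ml"] = vo2_used_int,
    _["T_breath"] = T);
}
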