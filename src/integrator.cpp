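#include <Rcpp.h>
using namespace Rcpp;

// Joint PK+PD right-hand side.
//
// State layout: y[0..n_pk-1] compartment drug amounts (ug), y[0] = plasma;
// y[n_pk] cumulative degraded amount (ug, mass-balance accumulator);
// y[n_pk+0..5] PD states: N (NK cells), C (CTLs), pN, pC (per-cell
// cytotoxic protein), Mem (memory factor), T (tumor cells).
//
// PD parameter order (fixed, mirrored by pd_param_vector() in R):
//  0 aN   NK influx (cells/day)        1 muN  NK baseline death (1/day)
//  2 iN   max drug-induced NK death    3 KN   its half-saturation (ug/ml)
//  4 qM   max memory accumulation      5 KM   its half-saturation (ug/ml)
//  6 muM  memory decay (1/day)
//  7 sigma CTL expansion intensity     8 Dmax CTL ceiling (cells)
//  9 muC  CTL death (1/day)
// 10 hN   NK protein induction rate   11 KuN  half-saturation (ug/ml)
// 12 mupN NK protein decay (1/day)
// 13 hC   CTL protein induction rate  14 KuC  half-saturation (ug/ml)
// 15 mupC CTL protein decay (1/day)
// 16 k1   NK-tumor kill affinity      17 k2   CTL-tumor kill affinity
// 18 r    tumor growth rate (1/day)   19 K    carrying capacity (cells)
static inline void rhs(const std::vector<double>& y, std::vector<double>& dy,
                       int n_pk,
                       const std::vector<int>& ef, const std::vector<int>& et,
                       const std::vector<double>& w, const std::vector<double>& alpha,
                       const std::vector<int>& dc,
                       const std::vector<double>& d, const std::vector<double>& beta,
                       double V_plasma, double s_factor,
                       const std::vector<double>& pd, bool pd_on) {
  std::fill(dy.begin(), dy.end(), 0.0);
  const int n_edges = (int)ef.size();
  for (int e = 0; e < n_edges; ++e) {
    double xi = y[ef[e]];
    if (xi < 0.0) xi = 0.0;                    // guard transient undershoot
    double J = w[e] * xi / (1.0 + alpha[e] * xi);
    dy[ef[e]] -= J;
    dy[et[e]] += J;
  }
  const int n_deg = (int)dc.size();
  for (int k = 0; k < n_deg; ++k) {
    double xi = y[dc[k]];
    if (xi < 0.0) xi = 0.0;
    double D = d[k] * xi / (1.0 + beta[k] * xi);
    dy[dc[k]] -= D;
    dy[n_pk]  += D;                            // accumulator
  }
  if (!pd_on) return;

  // tissue drug concentration: plasma conc divided by correlation factor s
  double x0 = y[0] > 0.0 ? y[0] : 0.0;
  double u = x0 / (V_plasma * s_factor);

  const double N  = y[n_pk + 1], C  = y[n_pk + 2];
  const double pN = y[n_pk + 3], pC = y[n_pk + 4];
  const double M  = y[n_pk + 5], T  = y[n_pk + 6];

  double dN  = pd[0] - pd[1] * N - pd[2] * (u / (pd[3] + u)) * N;
  double dC  = pd[7] * M * C * (1.0 - C / pd[8]) - pd[9] * C;
  double dpN = pd[10] * (u / (pd[11] + u)) - pd[12] * pN;
  double dpC = pd[13] * (u / (pd[14] + u)) - pd[15] * pC;
  double dM  = pd[4] * (u / (pd[5] + u)) - pd[6] * M;
  double kill = (pd[16] * N * pN + pd[17] * C * pC) * T;
  double dT  = pd[18] * T * (1.0 - T / pd[19]) - kill;

  dy[n_pk + 1] = dN;  dy[n_pk + 2] = dC;
  dy[n_pk + 3] = dpN; dy[n_pk + 4] = dpC;
  dy[n_pk + 5] = dM;  dy[n_pk + 6] = dT;
}

// Fixed-step classical RK4 with bolus dose events snapped to the step grid
// and applied as instantaneous state increments before the step.
// [[Rcpp::export]]
NumericMatrix sim_pkpd_cpp(int n_pk,
                           IntegerVector edge_from, IntegerVector edge_to,
                           NumericVector w, NumericVector alpha,
                           IntegerVector deg_comp,
                           NumericVector d, NumericVector beta,
                           double V_plasma, double s_factor,
                           NumericVector pd_par,
                           NumericVector y0_pk, NumericVector y0_pd,
                           double cum_deg0,
                           double t0, double t_end, double dt,
                           NumericVector event_times, NumericVector event_amounts,
                           int dose_comp, int thin, bool pd_on) {
  if (dt <= 0.0) stop("dt must be positive");
  if (t_end < t0) stop("t_end must be >= t0");
  const int n_state = n_pk + 1 + 6;
  long n_steps = (long)std::lround((t_end - t0) / dt);
  if (n_steps < 1 && t_end > t0) n_steps = 1;
  const double h = n_steps > 0 ? (t_end - t0) / n_steps : dt;

  std::vector<int> ef(edge_from.begin(), edge_from.end());
  std::vector<int> et(edge_to.begin(), edge_to.end());
  std::vector<double> wv(w.begin(), w.end()), av(alpha.begin(), alpha.end());
  std::vector<int> dc(deg_comp.begin(), deg_comp.end());
  std::vector<double> dv(d.begin(), d.end()), bv(beta.begin(), beta.end());
  std::vector<double> pd(pd_par.begin(), pd_par.end());

  std::vector<double> y(n_state, 0.0);
  for (int i = 0; i < n_pk; ++i) y[i] = y0_pk[i];
  y[n_pk] = cum_deg0;
  for (int i = 0; i < 6; ++i) y[n_pk + 1 + i] = y0_pd[i];

  // events snapped to nearest grid step index
  const int n_ev = event_times.size();
  std::vector<long> ev_step(n_ev);
  for (int k = 0; k < n_ev; ++k) {
    long idx = (long)std::lround((event_times[k] - t0) / h);
    if (idx < 0) idx = 0;
    if (idx > n_steps) idx = n_steps;
    ev_step[k] = idx;
  }

  const long n_out = n_steps / thin + 1 + ((n_steps % thin) ? 1 : 0);
  NumericMatrix out((int)n_out, n_state + 1);
  long row = 0;

  std::vector<double> k1(n_state), k2(n_state), k3(n_state), k4(n_state),
      tmp(n_state);

  auto apply_events = [&](long step) {
    for (int k = 0; k < n_ev; ++k)
      if (ev_step[k] == step) y[dose_comp] += event_amounts[k];
  };
  auto record = [&](long step) {
    out(row, 0) = t0 + h * step;
    for (int i = 0; i < n_state; ++i) out(row, i + 1) = y[i];
    ++row;
  };

  apply_events(0);
  record(0);
  for (long step = 0; step < n_steps; ++step) {
    rhs(y, k1, n_pk, ef, et, wv, av, dc, dv, bv, V_plasma, s_factor, pd, pd_on);
    for (int i = 0; i < n_state; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    rhs(tmp, k2, n_pk, ef, et, wv, av, dc, dv, bv, V_plasma, s_factor, pd, pd_on);
    for (int i = 0; i < n_state; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    rhs(tmp, k3, n_pk, ef, et, wv, av, dc, dv, bv, V_plasma, s_factor, pd, pd_on);
    for (int i = 0; i < n_state; ++i) tmp[i] = y[i] + h * k3[i];
    rhs(tmp, k4, n_pk, ef, et, wv, av, dc, dv, bv, V_plasma, s_factor, pd, pd_on);
    for (int i = 0; i < n_state; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < n_pk; ++i)
      if (y[i] < -1e-6)
        stop("drug amount went negative beyond tolerance; use a smaller dt");
    apply_events(step + 1);
    if ((step + 1) % thin == 0 || step + 1 == n_steps) record(step + 1);
  }
  if (row < n_out) out = out(Range(0, (int)row - 1), Range(0, n_state));
  return out;
}
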