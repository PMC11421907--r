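// Compiled numerical cores: adaptive Cash-Karp RK45 integration of the
// coupled extinction (E) / data (D) partial-probability ODEs along a branch
// (forward mode), the adjoint system used for the marginal-reconstruction
// down-pass, and the exact competing-clocks forward simulator.
//
// All state indices arriving from R are 0-based here; the R wrappers
// convert. The D/G block is linear given E, so it may be rescaled freely
// mid-integration; the accumulated log-scaler is returned.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Tables {
  int n;
  const int *afrom, *ato;
  const double *arate;
  int na;
  const int *ep, *ej, *ek;
  const double *erate;
  int ne;
  const double *tot;  // per-state total cladogenetic + anagenetic out-rate
  double mu;
};

// y = [E, D]; dE_i = mu - (tot_i+mu) E_i + sum q_ij E_j + sum lam E_j E_k
//             dD_i = -(tot_i+mu) D_i + sum q_ij D_j + sum lam (D_j E_k + D_k E_j)
static void rhs_forward(const Tables &tb, const double *y, double *dy) {
  const int n = tb.n;
  const double *E = y, *D = y + n;
  double *dE = dy, *dD = dy + n;
  for (int i = 0; i < n; ++i) {
    const double a = tb.tot[i] + tb.mu;
    dE[i] = tb.mu - a * E[i];
    dD[i] = -a * D[i];
  }
  for (int r = 0; r < tb.na; ++r) {
    const int f = tb.afrom[r], t = tb.ato[r];
    const double q = tb.arate[r];
    dE[f] += q * E[t];
    dD[f] += q * D[t];
  }
  for (int r = 0; r < tb.ne; ++r) {
    const int i = tb.ep[r], j = tb.ej[r], k = tb.ek[r];
    const double l = tb.erate[r];
    dE[i] += l * E[j] * E[k];
    dD[i] += l * (D[j] * E[k] + D[k] * E[j]);
  }
}

// Adjoint pass, integrated in tau running from the old end of the branch
// toward the young end. y = [Erev, G] with Erev(tau) = E(t_old - tau);
// G propagates by dG/dtau = M(t)' G where M is the (E-dependent) linear
// generator of the D system, so that G'D stays constant along the branch.
static void rhs_adjoint(const Tables &tb, const double *y, double *dy) {
  const int n = tb.n;
  const double *E = y, *G = y + n;
  double *dE = dy, *dG = dy + n;
  for (int i = 0; i < n; ++i) {
    const double a = tb.tot[i] + tb.mu;
    dE[i] = -(tb.mu - a * E[i]);
    dG[i] = -a * G[i];
  }
  for (int r = 0; r < tb.na; ++r) {
    const int f = tb.afrom[r], t = tb.ato[r];
    const double q = tb.arate[r];
    dE[f] -= q * E[t];
    dG[t] += q * G[f];
  }
  for (int r = 0; r < tb.ne; ++r) {
    const int i = tb.ep[r], j = tb.ej[r], k = tb.ek[r];
    const double l = tb.erate[r];
    dE[i] -= l * E[j] * E[k];
    dG[j] += l * E[k] * G[i];
    dG[k] += l * E[j] * G[i];
  }
}

// Cash-Karp coefficients
static const double CK_A2 = 0.2, CK_A3 = 0.3, CK_A4 = 0.6, CK_A5 = 1.0,
                    CK_A6 = 0.875;
static const double B21 = 0.2;
static const double B31 = 3.0 / 40.0, B32 = 9.0 / 40.0;
static const double B41 = 0.3, B42 = -0.9, B43 = 1.2;
static const double B51 = -11.0 / 54.0, B52 = 2.5, B53 = -70.0 / 27.0,
                    B54 = 35.0 / 27.0;
static const double B61 = 1631.0 / 55296.0, B62 = 175.0 / 512.0,
                    B63 = 575.0 / 13824.0, B64 = 44275.0 / 110592.0,
                    B65 = 253.0 / 4096.0;
static const double C1 = 37.0 / 378.0, C3 = 250.0 / 621.0, C4 = 125.0 / 594.0,
                    C6 = 512.0 / 1771.0;
static const double DC1 = C1 - 2825.0 / 27648.0, DC3 = C3 - 18575.0 / 48384.0,
                    DC4 = C4 - 13525.0 / 55296.0, DC5 = -277.0 / 14336.0,
                    DC6 = C6 - 0.25;

// [[Rcpp::export]]
List branch_ode_cpp(NumericVector y0, double len, double mu,
                    IntegerVector afrom, IntegerVector ato, NumericVector arate,
                    IntegerVector ep, IntegerVector ej, IntegerVector ek,
                    NumericVector erate, NumericVector tot, double rtol,
                    double atol, bool adjoint) {
  const int n = tot.size();
  const int m = 2 * n;
  if (y0.size() != m) stop("state vector has wrong length");
  Tables tb;
  tb.n = n;
  tb.afrom = afrom.begin(); tb.ato = ato.begin(); tb.arate = arate.begin();
  tb.na = afrom.size();
  tb.ep = ep.begin(); tb.ej = ej.begin(); tb.ek = ek.begin();
  tb.erate = erate.begin(); tb.ne = ep.size();
  tb.tot = tot.begin();
  tb.mu = mu;

  std::vector<double> y(y0.begin(), y0.end());
  double dlog = 0.0;
  long steps = 0;
  if (len <= 0.0)
    return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                        _["dlog"] = dlog, _["steps"] = steps);

  double maxrate = mu;
  for (int i = 0; i < n; ++i)
    if (tb.tot[i] + mu > maxrate) maxrate = tb.tot[i] + mu;
  double h = std::min(len, 0.5 / (maxrate + 1e-12));
  if (h <= 0.0 || !std::isfinite(h)) h = len;

  std::vector<double> k1(m), k2(m), k3(m), k4(m), k5(m), k6(m), ytmp(m),
      ynew(m);
  double t = 0.0;
  const long max_steps = 20000000L;
  void (*rhs)(const Tables &, const double *, double *) =
      adjoint ? rhs_adjoint : rhs_forward;

  while (t < len) {
    if (h > len - t) h = len - t;
    rhs(tb, y.data(), k1.data());
    for (int i = 0; i < m; ++i) ytmp[i] = y[i] + h * B21 * k1[i];
    rhs(tb, ytmp.data(), k2.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B31 * k1[i] + B32 * k2[i]);
    rhs(tb, ytmp.data(), k3.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
    rhs(tb, ytmp.data(), k4.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] +
                            B54 * k4[i]);
    rhs(tb, ytmp.data(), k5.data());
    for (int i = 0; i < m; ++i)
      ytmp[i] = y[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] +
                            B64 * k4[i] + B65 * k5[i]);
    rhs(tb, ytmp.data(), k6.data());

    double errmax = 0.0;
    for (int i = 0; i < m; ++i) {
      ynew[i] = y[i] + h * (C1 * k1[i] + C3 * k3[i] + C4 * k4[i] + C6 * k6[i]);
      const double erri = h * (DC1 * k1[i] + DC3 * k3[i] + DC4 * k4[i] +
                               DC5 * k5[i] + DC6 * k6[i]);
      const double sc =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double e = std::fabs(erri) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0 || h <= 1e-14 * len) {
      t += h;
      y.swap(ynew);
      // keep E inside [0,1]; the adjoint Erev integration is mildly
      // anti-stable, the forward one only drifts by solver error
      for (int i = 0; i < n; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        else if (y[i] > 1.0) y[i] = 1.0;
      }
      // rescale linear block if it is drifting out of range
      double mx = 0.0;
      for (int i = n; i < m; ++i)
        if (std::fabs(y[i]) > mx) mx = std::fabs(y[i]);
      if (mx > 0.0 && (mx < 1e-120 || mx > 1e120)) {
        for (int i = n; i < m; ++i) y[i] /= mx;
        dlog += std::log(mx);
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
    }
    if (++steps > max_steps)
      stop("branch integration exceeded the step budget (stiff parameters?)");
  }
  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["dlog"] = dlog, _["steps"] = steps);
}

// Exact competing-exponential-clocks forward simulation of the range
// diversification process. Events are supplied per state in CSR layout;
// each row carries a code (1 dispersal, 2 extirpation, 3 in-situ
// speciation, 4 vicariance, 5 lineage extinction), a rate, and target
// states a (new state, or left daughter) and b (right daughter, clado
// only). States are 1-based in this interface.
// [[Rcpp::export]]
List sim_core_cpp(int n_states, IntegerVector sptr, IntegerVector ev_code,
                  NumericVector ev_rate, IntegerVector ev_a,
                  IntegerVector ev_b, IntegerVector init_states, double max_t,
                  int max_extant, int max_records) {
  std::vector<double> stot(n_states);
  for (int s = 0; s < n_states; ++s) {
    double x = 0.0;
    for (int r = sptr[s]; r < sptr[s + 1]; ++r) x += ev_rate[r];
    stot[s] = x;
  }

  std::vector<int> parent, state_birth, state_cur, status;  // status: 0 dead, 1 extant, 2 speciated
  std::vector<double> t_birth, t_end;
  std::vector<int> alive;
  for (int i = 0; i < init_states.size(); ++i) {
    parent.push_back(0);
    state_birth.push_back(init_states[i]);
    state_cur.push_back(init_states[i]);
    status.push_back(1);
    t_birth.push_back(0.0);
    t_end.push_back(-1.0);
    alive.push_back(i);
  }

  std::vector<double> log_t;
  std::vector<int> log_lin, log_code, log_from, log_j, log_k;

  double t = 0.0;
  bool truncated = false, overflow = false;

  while (!alive.empty()) {
    double total = 0.0;
    for (size_t q = 0; q < alive.size(); ++q)
      total += stot[state_cur[alive[q]] - 1];
    if (total <= 0.0) break;
    const double tn = t + R::exp_rand() / total;
    if (tn >= max_t) break;

    // pick lineage proportional to its total hazard
    double u = unif_rand() * total;
    int pos = -1;
    for (size_t q = 0; q < alive.size(); ++q) {
      u -= stot[state_cur[alive[q]] - 1];
      if (u <= 0.0) { pos = (int)q; break; }
    }
    if (pos < 0) pos = (int)alive.size() - 1;
    const int lin = alive[pos];
    const int s = state_cur[lin];

    // pick event within the lineage's state
    double v = unif_rand() * stot[s - 1];
    int row = sptr[s - 1];
    for (; row < sptr[s] - 1; ++row) {
      v -= ev_rate[row];
      if (v <= 0.0) break;
    }
    const int code = ev_code[row];

    if (code == 3 || code == 4) {  // cladogenesis
      if ((int)alive.size() + 1 > max_extant) {
        // stop just before the event that would exceed the cap; the
        // horizon of the simulation becomes this event's time
        t = tn;
        truncated = true;
        break;
      }
      if ((int)parent.size() + 2 > max_records) {
        overflow = true;
        t = tn;
        break;
      }
      t = tn;
      status[lin] = 2;
      t_end[lin] = t;
      alive[pos] = alive.back();
      alive.pop_back();
      for (int c = 0; c < 2; ++c) {
        parent.push_back(lin + 1);
        const int st = c == 0 ? ev_a[row] : ev_b[row];
        state_birth.push_back(st);
        state_cur.push_back(st);
        status.push_back(1);
        t_birth.push_back(t);
        t_end.push_back(-1.0);
        alive.push_back((int)parent.size() - 1);
      }
      log_t.push_back(t); log_lin.push_back(lin + 1); log_code.push_back(code);
      log_from.push_back(s); log_j.push_back(ev_a[row]); log_k.push_back(ev_b[row]);
    } else if (code == 5) {  // whole-lineage extinction
      t = tn;
      status[lin] = 0;
      t_end[lin] = t;
      alive[pos] = alive.back();
      alive.pop_back();
      log_t.push_back(t); log_lin.push_back(lin + 1); log_code.push_back(code);
      log_from.push_back(s); log_j.push_back(NA_INTEGER); log_k.push_back(NA_INTEGER);
    } else {  // anagenetic range change
      t = tn;
      state_cur[lin] = ev_a[row];
      log_t.push_back(t); log_lin.push_back(lin + 1); log_code.push_back(code);
      log_from.push_back(s); log_j.push_back(ev_a[row]); log_k.push_back(NA_INTEGER);
    }
  }

  const double horizon = alive.empty() ? t : (truncated || overflow ? t : max_t);
  for (size_t q = 0; q < alive.size(); ++q) t_end[alive[q]] = horizon;

  return List::create(
      _["parent"] = IntegerVector(parent.begin(), parent.end()),
      _["state_birth"] = IntegerVector(state_birth.begin(), state_birth.end()),
      _["state_end"] = IntegerVector(state_cur.begin(), state_cur.end()),
      _["status"] = IntegerVector(status.begin(), status.end()),
      _["t_birth"] = NumericVector(t_birth.begin(), t_birth.end()),
      _["t_end"] = NumericVector(t_end.begin(), t_end.end()),
      _["horizon"] = horizon, _["truncated"] = truncated,
      _["overflow"] = overflow,
      _["n_extant"] = (int)alive.size(),
      _["log_t"] = NumericVector(log_t.begin(), log_t.end()),
      _["log_lineage"] = IntegerVector(log_lin.begin(), log_lin.end()),
      _["log_code"] = IntegerVector(log_code.begin(), log_code.end()),
      _["log_from"] = IntegerVector(log_from.begin(), log_from.end()),
      _["log_left"] = IntegerVector(log_j.begin(), log_j.end()),
      _["log_right"] = IntegerVector(log_k.begin(), log_k.end()));
}
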