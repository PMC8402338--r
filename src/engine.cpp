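// Compiled simulation engine.  Semantics and random-stream consumption are
// defined by the pure-R reference engine (R/engine_reference.R); every draw
// here mirrors that file verbatim so that, started from the same R RNG
// state and initial populations, the two produce bit-identical results
// (tested).  All randomness comes from R's own generator (unif_rand /
// rnorm) under an RNGScope.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// uniform integer on 1..n from R's stream, guarding the rounding edge
static inline int rint_(int n) {
  int j = 1 + (int)(unif_rand() * n);
  return j > n ? n : j;
}

struct Pars {
  int np, nd, ni, mm, cap; // cap < 0: no cap
  double init_op, alpha, oc, osd, lo, hi, vt, at, ft, pw, pvd, k;
  double pl, ml, af;
};

static inline double draw_initial(const Pars &P) {
  double x;
  do {
    x = R::rnorm(P.oc, P.osd);
  } while (x < P.lo || x > P.hi);
  return x;
}

static inline double filt(const Pars &P, double oi, double os, bool act,
                          bool msg) {
  double b = P.hi;
  if (std::abs(oi) > b || std::abs(os) > b)
    stop("opinion left the bounds (engine invariant violated)");
  bool same = (oi >= 0 && os >= 0) || (oi <= 0 && os <= 0);
  double disc = (b - std::abs(oi)) / (b - P.ft);
  if (disc > 1) disc = 1;
  if (act) return same ? disc : 0.0;
  if (msg) return 1.0;
  if (std::abs(oi) <= P.ft) return 1.0;
  return same ? 1.0 : disc;
}

static inline void upd(const Pars &P, double &oi, double os, bool msg) {
  double f = filt(P, oi, os, oi < P.at, msg);
  double af = P.alpha * f;
  oi = oi * (1 - af) + os * af;
}

// R's mean() algorithm (long-double accumulation + one refinement pass) so
// the reported mean_opinion is bit-identical to the reference engine's
static double mean_r(const std::vector<double> &x) {
  long double s = 0.0;
  size_t n = x.size();
  for (size_t i = 0; i < n; i++) s += x[i];
  s /= n;
  long double t = 0.0;
  for (size_t i = 0; i < n; i++) t += (x[i] - s);
  s += t / n;
  return (double)s;
}

// [[Rcpp::export]]
List run_engine_cpp(List params, NumericVector p_op0, NumericVector p_age0,
                    NumericVector d_op0, LogicalVector d_unc0, int n_ticks,
                    bool early_stop, double success_threshold,
                    int confirm_ticks, int tick0) {
  Pars P;
  P.np = as<int>(params["n_patients"]);
  P.nd = as<int>(params["n_doctors"]);
  P.ni = as<int>(params["n_initiators"]);
  P.mm = as<int>(params["max_messages_per_author_per_tick"]);
  SEXP capS = params["message_cap"];
  P.cap = Rf_isNull(capS) ? -1 : as<int>(capS);
  P.init_op = as<double>(params["initiator_opinion"]);
  P.alpha = as<double>(params["alpha"]);
  P.oc = as<double>(params["opinion_center"]);
  P.osd = as<double>(params["opinion_sd"]);
  NumericVector b = params["opinion_bounds"];
  P.lo = b[0];
  P.hi = b[1];
  P.vt = as<double>(params["vaccination_threshold"]);
  P.at = as<double>(params["activism_threshold"]);
  P.ft = as<double>(params["filtering_threshold"]);
  P.pw = as<double>(params["writing_probability"]);
  P.pvd = as<double>(params["doctor_visit_ratio"]);
  P.k = as<double>(params["doctor_hesitancy_factor"]);
  P.pl = as<double>(params["patient_lifetime"]);
  P.ml = as<double>(params["message_lifetime"]);
  P.af = as<double>(params["activist_aging_factor"]);
  NumericVector cr = params["committed_doctor_opinion_range"];
  NumericVector ur = params["uncommitted_doctor_opinion_range"];

  std::vector<double> p_op(p_op0.begin(), p_op0.end());
  std::vector<double> p_age(p_age0.begin(), p_age0.end());
  std::vector<double> d_op(d_op0.begin(), d_op0.end());
  std::vector<char> d_unc(P.nd);
  for (int d = 0; d < P.nd; d++) d_unc[d] = d_unc0[d] ? 1 : 0;

  // message pool: born-ordered, so expiry is always a prefix drop; `head`
  // marks the first live message and the store is compacted occasionally
  std::vector<double> msg_op;
  std::vector<int> msg_birth;
  std::vector<char> msg_init;
  size_t head = 0;

  std::vector<char> act(P.np);
  std::vector<int> perm(P.np), idx(P.nd);
  std::vector<char> new_unc(P.nd);

  NumericMatrix metrics(n_ticks, 8);
  RNGScope rng;

  int t_used = 0, runlen = 0;
  for (int t = 1; t <= n_ticks; t++) {
    // (0) doctor-commitment refresh against previous-tick NAV
    int nav_prev = 0;
    for (int i = 0; i < P.np; i++)
      if (p_op[i] < P.vt) nav_prev++;
    int ndu = (int)std::floor((double)P.nd * P.k * nav_prev / P.np + 0.5);
    if (ndu > P.nd) ndu = P.nd;
    for (int d = 0; d < P.nd; d++) idx[d] = d;
    for (int j = 0; j < ndu; j++) {
      int r = j + rint_(P.nd - j) - 1;
      int tmp = idx[j];
      idx[j] = idx[r];
      idx[r] = tmp;
    }
    std::fill(new_unc.begin(), new_unc.end(), 0);
    for (int j = 0; j < ndu; j++) new_unc[idx[j]] = 1;
    for (int d = 0; d < P.nd; d++) {
      if (new_unc[d] != d_unc[d]) {
        d_op[d] = new_unc[d] ? R::runif(ur[0], ur[1]) : R::runif(cr[0], cr[1]);
      }
      d_unc[d] = new_unc[d];
    }

    // tick-start activist flags (after refresh, before ageing)
    for (int i = 0; i < P.np; i++) act[i] = p_op[i] < P.at;

    // (1) ageing and replacement
    for (int i = 0; i < P.np; i++) {
      p_age[i] += act[i] ? P.af : 1.0;
      if (p_age[i] >= P.pl) {
        p_op[i] = draw_initial(P);
        p_age[i] = 0.0;
      }
    }
    // a message born at tick b has age (t - b) after this tick's ageing;
    // expired messages (age >= lifetime) always form a prefix
    while (head < msg_op.size() && t - msg_birth[head] >= P.ml) head++;
    if (head > 4096 && head * 2 > msg_op.size()) {
      msg_op.erase(msg_op.begin(), msg_op.begin() + head);
      msg_birth.erase(msg_birth.begin(), msg_birth.begin() + head);
      msg_init.erase(msg_init.begin(), msg_init.begin() + head);
      head = 0;
    }

    // (2) message writing: initiators, then activists in index order
    int n_new_init = 0, n_new_act = 0;
    for (int ii = 0; ii < P.ni; ii++) {
      for (int tr = 0; tr < P.mm; tr++) {
        if (unif_rand() < P.pw) {
          if (P.cap < 0 || (int)(msg_op.size() - head) < P.cap) {
            msg_op.push_back(P.init_op);
            msg_birth.push_back(t);
            msg_init.push_back(1);
            n_new_init++;
          }
        }
      }
    }
    for (int i = 0; i < P.np; i++) {
      if (act[i]) {
        for (int tr = 0; tr < P.mm; tr++) {
          if (unif_rand() < P.pw) {
            if (P.cap < 0 || (int)(msg_op.size() - head) < P.cap) {
              msg_op.push_back(p_op[i]);
              msg_birth.push_back(t);
              msg_init.push_back(0);
              n_new_act++;
            }
          }
        }
      }
    }

    // (3) doctor visits
    for (int i = 0; i < P.np; i++) {
      if (unif_rand() < P.pvd) {
        int d = rint_(P.nd) - 1;
        if (!d_unc[d]) {
          upd(P, p_op[i], d_op[d], false);
        } else if (msg_op.size() > head) {
          int m = rint_((int)(msg_op.size() - head)) - 1;
          upd(P, p_op[i], msg_op[head + m], true);
        }
      }
    }

    // (4) external exposure, sequential over a fresh permutation
    for (int i = 0; i < P.np; i++) perm[i] = i;
    for (int i = P.np - 1; i >= 1; i--) {
      int j = rint_(i + 1) - 1;
      int tmp = perm[i];
      perm[i] = perm[j];
      perm[j] = tmp;
    }
    // source drawn uniformly over the pooled entities (doctors, the other
    // patients, active messages), so message influence scales with the
    // size of the message pool — the nonlinear feedback channel
    int nm = (int)(msg_op.size() - head);
    int total = P.nd + (P.np - 1) + nm;
    for (int kk = 0; kk < P.np; kk++) {
      int i = perm[kk];
      int pick = rint_(total) - 1;
      if (pick < P.nd) {
        upd(P, p_op[i], d_op[pick], false);
      } else if (pick < P.nd + (P.np - 1)) {
        int j = pick - P.nd;
        if (j >= i) j++;
        upd(P, p_op[i], p_op[j], false);
      } else {
        upd(P, p_op[i], msg_op[head + (pick - P.nd - (P.np - 1))], true);
      }
    }

    // metrics from the post-update state
    int nav = 0, na = 0;
    for (int i = 0; i < P.np; i++) {
      if (p_op[i] < P.vt) nav++;
      if (p_op[i] < P.at) na++;
    }
    metrics(t - 1, 0) = tick0 + t;
    metrics(t - 1, 1) = n_new_act;
    metrics(t - 1, 2) = n_new_act + n_new_init;
    metrics(t - 1, 3) = (double)(msg_op.size() - head);
    metrics(t - 1, 4) = nav;
    metrics(t - 1, 5) = na;
    metrics(t - 1, 6) = ndu;
    metrics(t - 1, 7) = mean_r(p_op);
    t_used = t;

    double frac = (double)nav / P.np;
    runlen = frac >= success_threshold ? runlen + 1 : 0;
    if (early_stop && runlen >= confirm_ticks) break;
  }

  NumericMatrix out(t_used, 8);
  for (int r = 0; r < t_used; r++)
    for (int c = 0; c < 8; c++) out(r, c) = metrics(r, c);

  LogicalVector d_unc_out(P.nd);
  for (int d = 0; d < P.nd; d++) d_unc_out[d] = d_unc[d] != 0;
  size_t n_live = msg_op.size() - head;
  NumericVector msg_op_out(n_live);
  IntegerVector msg_age_out(n_live);
  LogicalVector msg_init_out(n_live);
  for (size_t m = 0; m < n_live; m++) {
    msg_op_out[m] = msg_op[head + m];
    msg_age_out[m] = t_used - msg_birth[head + m];
    msg_init_out[m] = msg_init[head + m] != 0;
  }

  return List::create(
      _["metrics"] = out, _["p_op"] = wrap(p_op), _["p_age"] = wrap(p_age),
      _["d_op"] = wrap(d_op), _["d_unc"] = d_unc_out,
      _["msg_op"] = msg_op_out, _["msg_age"] = msg_age_out,
      _["msg_init"] = msg_init_out, _["ticks_run"] = t_used);
}
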