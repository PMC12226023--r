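// Core numerical routines: pulse-task sampling, Euler simulation of rate
// networks, and backpropagation-through-time training with Adam.
// All randomness is drawn from R's RNG so that set.seed() governs everything.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int ACT_TANH = 0;
static const int ACT_SOFTPLUS = 1;

// Fast exp/tanh used only in the training inner loop, where the activation
// is evaluated ~1e10 times; max abs error vs std::tanh is < 3e-12, far below
// the stochastic-gradient noise. Simulation/analysis paths use std::tanh.
static inline double fexp(double y) {
  const double LOG2E = 1.4426950408889634074;
  const double LN2HI = 6.93147180369123816490e-01;
  const double LN2LO = 1.90821492927058770002e-10;
  double t = y * LOG2E + 6755399441055744.0;   // round-to-nearest-int trick
  long long k;
  std::memcpy(&k, &t, 8);
  k = (k << 13) >> 13;
  double kd = (double) k;
  double r = (y - kd * LN2HI) - kd * LN2LO;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320 + r / 362880))))))));
  long long bits = (k + 1023LL) << 52;
  double two_k;
  std::memcpy(&two_k, &bits, 8);
  return p * two_k;
}
static inline double ftanh(double x) {
  double ax = std::abs(x);
  if (ax < 0.625) {
    double x2 = x * x;
    return x * (135135.0 + x2 * (17325.0 + x2 * (378.0 + x2))) /
               (135135.0 + x2 * (62370.0 + x2 * (3150.0 + 28.0 * x2)));
  }
  if (ax > 19.0) return x > 0 ? 1.0 : -1.0;
  double e = fexp(2.0 * ax);
  double r = 1.0 - 2.0 / (1.0 + e);
  return x > 0 ? r : -r;
}

// in-place activation of a matrix (training path)
static inline void phi_inplace(const arma::mat& x, arma::mat& out, int act) {
  if (out.n_rows != x.n_rows || out.n_cols != x.n_cols)
    out.set_size(arma::size(x));
  const double* xp = x.memptr();
  double* op = out.memptr();
  arma::uword n = x.n_elem;
  if (act == ACT_TANH) {
    for (arma::uword i = 0; i < n; ++i) op[i] = ftanh(xp[i]);
  } else {
    for (arma::uword i = 0; i < n; ++i) {
      double v = xp[i];
      op[i] = std::log1p(std::exp(-std::abs(v))) + (v > 0 ? v : 0.0);
    }
  }
}

static inline int act_code(const std::string& s) {
  if (s == "tanh") return ACT_TANH;
  if (s == "softplus") return ACT_SOFTPLUS;
  stop("unknown activation '%s'", s.c_str());
  return -1;
}

static inline arma::mat phi_of(const arma::mat& x, int act) {
  if (act == ACT_TANH) return arma::tanh(x);
  // softplus, numerically stable: log1p(exp(-|x|)) + max(x, 0)
  arma::mat out = arma::log1p(arma::exp(-arma::abs(x)));
  out += arma::max(x, arma::zeros<arma::mat>(arma::size(x)));
  return out;
}

// derivative recovered from phi itself:
//   tanh:     phi' = 1 - phi^2
//   softplus: phi' = sigmoid(x) = 1 - exp(-phi)
static inline arma::mat dphi_from_phi(const arma::mat& p, int act) {
  if (act == ACT_TANH) return 1.0 - arma::square(p);
  return 1.0 - arma::exp(-p);
}

struct TaskPars {
  int n_fix, n_sti, n_dec;
  double rate, gain;
  arma::vec probs;
};

// Sample a batch of pulse-based CDM trials. Pulses occur only during the
// stimulus period; context channels are on from trial start.
static void sample_batch(const TaskPars& tp, int B,
                         arma::mat& U1, arma::mat& U2,
                         arma::ivec& ctx, arma::vec& target,
                         arma::vec& p_loc, arma::vec& p_frq,
                         arma::imat* NP = nullptr) {
  int T = tp.n_fix + tp.n_sti + tp.n_dec;
  U1.zeros(B, T);
  U2.zeros(B, T);
  if (NP) NP->zeros(B, T);
  ctx.set_size(B);
  target.set_size(B);
  p_loc.set_size(B);
  p_frq.set_size(B);
  int K = tp.probs.n_elem;
  for (int k = 0; k < B; ++k) {
    double p  = tp.probs[(int) std::floor(unif_rand() * K)];
    double ph = tp.probs[(int) std::floor(unif_rand() * K)];
    p_loc[k] = p;
    p_frq[k] = ph;
    ctx[k] = (unif_rand() < 0.5) ? 1 : 2;
    target[k] = (ctx[k] == 1) ? ((p > 0.5) ? 1.0 : -1.0)
                              : ((ph > 0.5) ? 1.0 : -1.0);
    for (int t = tp.n_fix; t < tp.n_fix + tp.n_sti; ++t) {
      int np = (int) R::rpois(tp.rate);
      if (NP) (*NP)(k, t) = np;
      if (np == 0) continue;
      int nr = (int) R::rbinom(np, p);
      int nh = (int) R::rbinom(np, ph);
      U1(k, t) = tp.gain * (2.0 * nr - np);
      U2(k, t) = tp.gain * (2.0 * nh - np);
    }
  }
}

// [[Rcpp::export(name = ".sample_trials_cpp")]]
List sample_trials_cpp(int n_trials, int n_fix, int n_sti, int n_dec,
                       double pulse_rate, double input_gain,
                       arma::vec strength_probs) {
  TaskPars tp{n_fix, n_sti, n_dec, pulse_rate, input_gain, strength_probs};
  arma::mat U1, U2;
  arma::imat NP;
  arma::ivec ctx;
  arma::vec target, p_loc, p_frq;
  sample_batch(tp, n_trials, U1, U2, ctx, target, p_loc, p_frq, &NP);
  return List::create(_["u1"] = U1, _["u2"] = U2,
                      _["context"] = ctx, _["target"] = target,
                      _["p_loc"] = p_loc, _["p_frq"] = p_frq,
                      _["n_pulses"] = NP);
}

// Apply J * P where J is either full (NxN) or low rank (m n^T / N).
static inline arma::mat J_apply(const arma::mat& J, const arma::mat& m,
                                const arma::mat& n, bool lowrank, int N,
                                const arma::mat& P) {
  if (lowrank) return m * (n.t() * P) / (double) N;
  return J * P;
}

// Euler simulation of a batch of trials.
// In: N x 4 input embedding matrix with columns (I1, I2, Ictx1, Ictx2).
// X0: N x B initial states. Records phi(x) at the requested (1-based) steps.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(const arma::mat& In, const arma::vec& w,
                  const arma::mat& J, const arma::mat& m, const arma::mat& n,
                  bool lowrank, std::string activation,
                  double dt, double tau, double noise_std,
                  const arma::mat& U1, const arma::mat& U2,
                  const arma::mat& Uc1, const arma::mat& Uc2,
                  const arma::mat& X0, IntegerVector record_steps) {
  int act = act_code(activation);
  int N = In.n_rows;
  int B = U1.n_rows;
  int T = U1.n_cols;
  double a = dt / tau;
  arma::mat X = X0;
  arma::mat Z(B, T);
  int nrec = record_steps.size();
  arma::cube R_out;
  if (nrec > 0) R_out.set_size(N, B, nrec);
  std::vector<int> recmap(T + 1, -1);
  for (int i = 0; i < nrec; ++i) {
    int s = record_steps[i];
    if (s < 1 || s > T) stop("record step out of range");
    recmap[s] = i;
  }
  for (int t = 0; t < T; ++t) {
    arma::mat P = phi_of(X, act);
    arma::mat drive = J_apply(J, m, n, lowrank, N, P);
    drive += In.col(0) * U1.col(t).t();
    drive += In.col(1) * U2.col(t).t();
    drive += In.col(2) * Uc1.col(t).t();
    drive += In.col(3) * Uc2.col(t).t();
    if (noise_std > 0) {
      arma::mat eps(N, B);
      for (arma::uword i = 0; i < eps.n_elem; ++i) eps[i] = norm_rand();
      drive += noise_std * eps;
    }
    X = (1.0 - a) * X + a * drive;
    if (!X.is_finite())
      stop("state became non-finite at step %d; aborting simulation", t + 1);
    arma::mat Pt = phi_of(X, act);
    Z.col(t) = (Pt.t() * w) / (double) N;
    if (recmap[t + 1] >= 0) R_out.slice(recmap[t + 1]) = Pt;
  }
  List out = List::create(_["z"] = Z);
  if (nrec > 0) out["rates"] = R_out;
  return out;
}

struct Adam {
  double lr, b1, b2, eps;
  long t;
  std::vector<arma::mat> m1, m2;
  Adam(double lr_, double b1_, double b2_) : lr(lr_), b1(b1_), b2(b2_),
                                             eps(1e-8), t(0) {}
  void init(const std::vector<arma::mat*>& ps) {
    for (auto p : ps) {
      m1.push_back(arma::zeros<arma::mat>(arma::size(*p)));
      m2.push_back(arma::zeros<arma::mat>(arma::size(*p)));
    }
  }
  void step(std::vector<arma::mat*>& ps, const std::vector<arma::mat>& gs) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double) t);
    double c2 = 1.0 - std::pow(b2, (double) t);
    for (size_t i = 0; i < ps.size(); ++i) {
      m1[i] = b1 * m1[i] + (1.0 - b1) * gs[i];
      m2[i] = b2 * m2[i] + (1.0 - b2) * arma::square(gs[i]);
      *ps[i] -= lr * (m1[i] / c1) / (arma::sqrt(m2[i] / c2) + eps);
    }
  }
};

// Shared BPTT trainer. If lowrank, J is parameterised as m n^T / N with m, n
// of size N x R; otherwise the full matrix J is trained. Loss: squared output
// error at the decision step plus L2 penalty on the recurrent parameters.
static List train_impl(int N, int R, bool lowrank, const TaskPars& tp,
                       int steps, int batch, double lr, double b1, double b2,
                       double wreg, double init_sd, double noise_std,
                       std::string activation) {
  int act = act_code(activation);
  int T = tp.n_fix + tp.n_sti + tp.n_dec;
  double a = 20.0 / 100.0; // dt / tau, fixed by the task's 20 ms grid
  auto rmat = [&](int r, int c) {
    arma::mat M(r, c);
    for (arma::uword i = 0; i < M.n_elem; ++i) M[i] = init_sd * norm_rand();
    return M;
  };
  arma::mat In = rmat(N, 4), w = rmat(N, 1);
  arma::mat m, n, J;
  if (lowrank) { m = rmat(N, R); n = rmat(N, R); }
  else         { J = rmat(N, N); }

  std::vector<arma::mat*> ps;
  ps.push_back(&In);
  ps.push_back(&w);
  if (lowrank) { ps.push_back(&m); ps.push_back(&n); }
  else         { ps.push_back(&J); }
  Adam opt(lr, b1, b2);
  opt.init(ps);

  arma::vec loss_trace(steps);
  arma::cube Phi(N, batch, T + 1);
  arma::mat U1, U2;
  arma::ivec ctx;
  arma::vec target, p_loc, p_frq;

  for (int it = 0; it < steps; ++it) {
    sample_batch(tp, batch, U1, U2, ctx, target, p_loc, p_frq);
    arma::mat Uc1(batch, T), Uc2(batch, T);
    for (int k = 0; k < batch; ++k) {
      Uc1.row(k).fill(ctx[k] == 1 ? 1.0 : 0.0);
      Uc2.row(k).fill(ctx[k] == 2 ? 1.0 : 0.0);
    }
    // forward
    arma::mat X(N, batch);
    for (int k = 0; k < batch; ++k)
      X.col(k) = (ctx[k] == 1) ? In.col(2) : In.col(3);
    phi_inplace(X, Phi.slice(0), act);
    for (int t = 0; t < T; ++t) {
      arma::mat drive = J_apply(J, m, n, lowrank, N, Phi.slice(t));
      drive += In.col(0) * U1.col(t).t();
      drive += In.col(1) * U2.col(t).t();
      drive += In.col(2) * Uc1.col(t).t();
      drive += In.col(3) * Uc2.col(t).t();
      if (noise_std > 0) {
        arma::mat eps(N, batch);
        for (arma::uword i = 0; i < eps.n_elem; ++i) eps[i] = norm_rand();
        drive += noise_std * eps;
      }
      X = (1.0 - a) * X + a * drive;
      if (!X.is_finite()) stop("training diverged (non-finite state) at step %d", it + 1);
      phi_inplace(X, Phi.slice(t + 1), act);
    }
    arma::vec z = (Phi.slice(T).t() * w) / (double) N; // output at decision step
    arma::vec err = z - target;
    double L = arma::dot(err, err);
    if (wreg > 0) {
      if (lowrank) L += wreg * (arma::accu(arma::square(m)) + arma::accu(arma::square(n)));
      else         L += wreg * arma::accu(arma::square(J));
    }
    loss_trace[it] = L;

    // backward
    arma::mat gIn(N, 4, arma::fill::zeros), gw(N, 1, arma::fill::zeros);
    arma::mat gm, gn, gJ;
    if (lowrank) { gm.zeros(N, R); gn.zeros(N, R); } else gJ.zeros(N, N);
    arma::mat dP = dphi_from_phi(Phi.slice(T), act);
    gw.col(0) = Phi.slice(T) * (2.0 * err) / (double) N;
    // G = dL/dx_T
    arma::mat G = dP % (w * (2.0 * err.t() / (double) N));
    for (int t = T - 1; t >= 0; --t) {
      // parameter gradients from the update x_{t+1} = (1-a) x_t + a * drive(t)
      const arma::mat& Pt = Phi.slice(t);
      if (lowrank) {
        gm += (a / (double) N) * (G * (Pt.t() * n));
        gn += (a / (double) N) * (Pt * (G.t() * m));
      } else {
        gJ += a * (G * Pt.t());
      }
      gIn.col(0) += a * (G * U1.col(t));
      gIn.col(1) += a * (G * U2.col(t));
      gIn.col(2) += a * (G * Uc1.col(t));
      gIn.col(3) += a * (G * Uc2.col(t));
      // propagate to x_t
      arma::mat JtG;
      if (lowrank) JtG = n * (m.t() * G) / (double) N;
      else JtG = J.t() * G;
      G = (1.0 - a) * G + a * (dphi_from_phi(Pt, act) % JtG);
    }
    // x_0 = I_ctx of the trial's context
    for (int k = 0; k < batch; ++k)
      gIn.col(ctx[k] == 1 ? 2 : 3) += G.col(k);
    if (wreg > 0) {
      if (lowrank) { gm += 2.0 * wreg * m; gn += 2.0 * wreg * n; }
      else gJ += 2.0 * wreg * J;
    }
    std::vector<arma::mat> gs;
    gs.push_back(gIn);
    gs.push_back(gw);
    if (lowrank) { gs.push_back(gm); gs.push_back(gn); }
    else gs.push_back(gJ);
    opt.step(ps, gs);
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["In"] = In, _["w"] = w.col(0),
                          _["loss_trace"] = loss_trace);
  if (lowrank) { out["m"] = m; out["n"] = n; }
  else out["J"] = J;
  return out;
}

// [[Rcpp::export(name = ".train_cpp")]]
List train_cpp(int N, int R, bool lowrank,
               int n_fix, int n_sti, int n_dec,
               double pulse_rate, double input_gain, arma::vec strength_probs,
               int steps, int batch, double lr, double b1, double b2,
               double wreg, double init_sd, double noise_std,
               std::string activation) {
  TaskPars tp{n_fix, n_sti, n_dec, pulse_rate, input_gain, strength_probs};
  return train_impl(N, R, lowrank, tp, steps, batch, lr, b1, b2, wreg,
                    init_sd, noise_std, activation);
}
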