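// Photon-loop hot paths: likelihood recursion, Viterbi decoding,
// continuous-time Markov path sampling and recoloring.
//
// Conventions (match the R side):
//  - K[i,j] is the rate j -> i; columns sum to zero.
//  - `eps` is an n_states x n_channels matrix whose column c holds the
//    diagonal of the photon color matrix F(c); rows sum to 1 so that
//    sum_c F(c) = I.
//  - channels are 0-based integer codes on entry.
//  - all randomness uses R's RNG so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Spectral {
  arma::cx_vec lam;
  arma::cx_mat U, Uinv;
  bool ok;
};

// Eigendecomposition of the generator; flagged unusable when the eigenbasis
// is ill-conditioned (near-degenerate spectrum) so callers can fall back to
// scaling-and-squaring.
static Spectral decompose(const arma::mat& K) {
  Spectral s;
  s.ok = false;
  arma::cx_vec lam;
  arma::cx_mat U;
  if (!arma::eig_gen(lam, U, K)) return s;
  double c = arma::cond(U);
  if (!std::isfinite(c) || c > 1e8) return s;
  s.lam = lam;
  s.U = U;
  s.Uinv = arma::inv(U);
  s.ok = true;
  return s;
}

// [[Rcpp::export]]
List cpp_segment_loglik(const arma::vec& times, const arma::ivec& chan,
                        const arma::mat& K, const arma::mat& eps,
                        const arma::vec& p0) {
  const int N = times.n_elem;
  if (N == 0) return List::create(_["loglik"] = 0.0, _["spectral"] = true);
  Spectral sp = decompose(K);
  double logL = 0.0;

  const bool real_spec = sp.ok &&
    arma::abs(arma::imag(sp.lam)).max() <=
      1e-12 * (1.0 + arma::abs(sp.lam).max());

  if (real_spec) {
    // real spectrum: tight preallocated loop, no complex arithmetic
    const int ns = K.n_rows;
    const arma::vec lam = arma::real(sp.lam);
    const arma::mat U = arma::real(sp.U);
    const arma::mat Uinv = arma::real(sp.Uinv);
    arma::vec v = p0 % eps.col(chan(0));
    double s = arma::accu(v);
    if (!(s > 0.0) || !std::isfinite(s))
      stop("non-finite or non-positive likelihood weight at photon 1");
    v /= s;
    logL += std::log(s);
    arma::vec w(ns), x(ns);
    const double* Um = U.memptr();
    const double* Um_inv = Uinv.memptr();
    for (int i = 1; i < N; ++i) {
      const double dt = times(i) - times(i - 1);
      const double* e = eps.colptr(chan(i));
      for (int r = 0; r < ns; ++r) {
        double acc = 0.0;
        for (int c = 0; c < ns; ++c) acc += Um_inv[r + c * ns] * v(c);
        w(r) = acc * std::exp(lam(r) * dt);
      }
      s = 0.0;
      for (int r = 0; r < ns; ++r) {
        double acc = 0.0;
        for (int c = 0; c < ns; ++c) acc += Um[r + c * ns] * w(c);
        acc *= e[r];
        x(r) = acc;
        s += acc;
      }
      if (!(s > 0.0) || !std::isfinite(s))
        stop("non-finite or non-positive likelihood weight at photon %d", i + 1);
      v = x / s;
      logL += std::log(s);
    }
  } else if (sp.ok) {
    arma::cx_vec v = arma::conv_to<arma::cx_vec>::from(p0 % eps.col(chan(0)));
    double s = arma::accu(arma::real(v));
    if (!(s > 0.0) || !std::isfinite(s))
      stop("non-finite or non-positive likelihood weight at photon 1");
    v /= s;
    logL += std::log(s);
    for (int i = 1; i < N; ++i) {
      const double dt = times(i) - times(i - 1);
      arma::cx_vec w = sp.Uinv * v;
      w %= arma::exp(sp.lam * dt);
      v = sp.U * w;
      v %= arma::conv_to<arma::cx_vec>::from(eps.col(chan(i)));
      s = arma::accu(arma::real(v));
      if (!(s > 0.0) || !std::isfinite(s))
        stop("non-finite or non-positive likelihood weight at photon %d", i + 1);
      v /= s;
      logL += std::log(s);
    }
    const double imres = arma::accu(arma::abs(arma::imag(v)));
    if (imres > 1e-8)
      stop("imaginary residue %g of the likelihood recursion exceeds 1e-8", imres);
  } else {
    arma::vec v = p0 % eps.col(chan(0));
    double s = arma::accu(v);
    if (!(s > 0.0) || !std::isfinite(s))
      stop("non-finite or non-positive likelihood weight at photon 1");
    v /= s;
    logL += std::log(s);
    for (int i = 1; i < N; ++i) {
      const double dt = times(i) - times(i - 1);
      const arma::mat P = arma::expmat(K * dt);
      v = P * v;
      v %= eps.col(chan(i));
      s = arma::accu(v);
      if (!(s > 0.0) || !std::isfinite(s))
        stop("non-finite or non-positive likelihood weight at photon %d", i + 1);
      v /= s;
      logL += std::log(s);
    }
  }
  return List::create(_["loglik"] = logL, _["spectral"] = sp.ok);
}

static arma::mat propagator(const Spectral& sp, const arma::mat& K, double dt) {
  arma::mat P;
  if (sp.ok) {
    P = arma::real(sp.U * arma::diagmat(arma::exp(sp.lam * dt)) * sp.Uinv);
  } else {
    P = arma::expmat(K * dt);
  }
  // wash out tiny negative round-off so logs stay defined
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// Most probable state sequence; ties broken toward the lower state index.
// [[Rcpp::export]]
List cpp_viterbi(const arma::vec& times, const arma::ivec& chan,
                 const arma::mat& K, const arma::mat& eps,
                 const arma::vec& p0) {
  const int N = times.n_elem;
  const int ns = K.n_rows;
  if (N == 0)
    return List::create(_["path"] = IntegerVector(0), _["logprob"] = 0.0);
  Spectral sp = decompose(K);

  arma::mat delta(ns, N);
  arma::imat psi(ns, N, arma::fill::zeros);
  delta.col(0) = arma::log(p0) + arma::log(eps.col(chan(0)));
  for (int i = 1; i < N; ++i) {
    const arma::mat logP = arma::log(propagator(sp, K, times(i) - times(i - 1)));
    for (int j = 0; j < ns; ++j) {
      double best = -arma::datum::inf;
      int arg = 0;
      for (int k = 0; k < ns; ++k) {
        const double cand = delta(k, i - 1) + logP(j, k);
        if (cand > best) {  // strict: first (lowest) index wins ties
          best = cand;
          arg = k;
        }
      }
      delta(j, i) = best + std::log(eps(j, chan(i)));
      psi(j, i) = arg;
    }
  }
  IntegerVector path(N);
  int cur = 0;
  double best = -arma::datum::inf;
  for (int j = 0; j < ns; ++j) {
    if (delta(j, N - 1) > best) {
      best = delta(j, N - 1);
      cur = j;
    }
  }
  path[N - 1] = cur + 1;
  for (int i = N - 1; i > 0; --i) {
    cur = psi(cur, i);
    path[i - 1] = cur + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Exact Gillespie path over [0, duration): exponential dwells with the
// state's total exit rate, jumps proportional to the column rates.
// [[Rcpp::export]]
List cpp_state_path(const arma::mat& K, const arma::vec& p0, double duration) {
  const int ns = K.n_rows;
  std::vector<double> ts;
  std::vector<int> ss;
  double u = R::unif_rand(), cum = 0.0;
  int s = ns - 1;
  for (int i = 0; i < ns; ++i) {
    cum += p0(i);
    if (u <= cum) {
      s = i;
      break;
    }
  }
  double t = 0.0;
  ts.push_back(0.0);
  ss.push_back(s + 1);
  for (;;) {
    const double rate = -K(s, s);
    if (rate <= 0.0) break;  // absorbing state
    t += R::exp_rand() / rate;
    if (t >= duration) break;
    double u2 = R::unif_rand() * rate, c2 = 0.0;
    int nxt = -1;
    for (int j = 0; j < ns; ++j) {
      if (j == s) continue;
      c2 += K(j, s);
      if (u2 <= c2) {
        nxt = j;
        break;
      }
    }
    if (nxt < 0) {
      for (int j = ns - 1; j >= 0; --j)
        if (j != s && K(j, s) > 0.0) {
          nxt = j;
          break;
        }
      if (nxt < 0) break;
    }
    s = nxt;
    ts.push_back(t);
    ss.push_back(s + 1);
  }
  return List::create(_["time"] = ts, _["state"] = ss);
}

// Draw a state path over the span of the arrival times, then draw each
// photon's channel from its state's emission fractions. Returns 0-based
// channel codes; arrival times are untouched.
// [[Rcpp::export]]
IntegerVector cpp_recolor(const arma::vec& times, const arma::mat& K,
                          const arma::mat& eps, const arma::vec& p0) {
  const int N = times.n_elem;
  const int nch = eps.n_cols;
  IntegerVector out(N);
  if (N == 0) return out;
  const double t0 = times(0);
  List path = cpp_state_path(K, p0, times(N - 1) - t0 + 1e-12);
  NumericVector pt = path["time"];
  IntegerVector pstate = path["state"];
  const int np = pt.size();
  int idx = 0;
  for (int i = 0; i < N; ++i) {
    const double rel = times(i) - t0;
    while (idx + 1 < np && pt[idx + 1] <= rel) ++idx;
    const int s = pstate[idx] - 1;
    double u = R::unif_rand(), cum = 0.0;
    int c = nch - 1;
    for (int k = 0; k < nch; ++k) {
      cum += eps(s, k);
      if (u <= cum) {
        c = k;
        break;
      }
    }
    out[i] = c;
  }
  return out;
}
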