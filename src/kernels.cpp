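#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward log-likelihood of aggregated-Markov class sequences.
//
// Observations are run-length encoded: segLens / segCls hold the runs of all
// traces back to back, nSegPerTrace says how many runs belong to each trace.
// The emission is a deterministic state -> class map (classOf, 0-based), so
// the forward recursion masks the state vector by the observed class each
// frame; a run of L frames of one class applies the class-masked transition
// matrix L times. Masked-matrix powers are precomputed per class with
// per-power rescaling to avoid underflow on long runs.
//
// [[Rcpp::export]]
double cpp_forward_rle(IntegerVector segLens, IntegerVector segCls,
                       IntegerVector nSegPerTrace, NumericMatrix A,
                       IntegerVector classOf, NumericVector pi0) {
  const int n = A.nrow();
  const int nClass = 3;
  int maxRun = 0;
  for (int i = 0; i < segLens.size(); ++i)
    if (segLens[i] > maxRun) maxRun = segLens[i];

  // masked transition matrices per class (zero columns outside the class)
  std::vector< std::vector<double> > Ac(nClass,
                                        std::vector<double>(n * n, 0.0));
  for (int c = 0; c < nClass; ++c)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (classOf[j] == c) Ac[c][i + n * j] = A(i, j);

  // scaled powers: pow[c][k] = Ac^(k+1) / exp(logScale[c][k])
  std::vector< std::vector< std::vector<double> > > powm(nClass);
  std::vector< std::vector<double> > logScale(nClass);
  for (int c = 0; c < nClass; ++c) {
    powm[c].reserve(maxRun);
    logScale[c].reserve(maxRun);
    std::vector<double> P(Ac[c]);
    double acc = 0.0;
    for (int k = 0; k < maxRun; ++k) {
      if (k > 0) {
        std::vector<double> Q(n * n, 0.0);
        const std::vector<double>& Pm = powm[c][k - 1];
        for (int i = 0; i < n; ++i)
          for (int l = 0; l < n; ++l) {
            double p = Pm[i + n * l];
            if (p == 0.0) continue;
            for (int j = 0; j < n; ++j)
              Q[i + n * j] += p * Ac[c][l + n * j];
          }
        P = Q;
        acc = logScale[c][k - 1];
      } else {
        P = Ac[c];
        acc = 0.0;
      }
      double mx = 0.0;
      for (int i = 0; i < n * n; ++i) if (P[i] > mx) mx = P[i];
      if (mx > 0.0) {
        for (int i = 0; i < n * n; ++i) P[i] /= mx;
        acc += std::log(mx);
      }
      powm[c].push_back(P);
      logScale[c].push_back(acc);
    }
  }

  double total = 0.0;
  int seg = 0;
  std::vector<double> alpha(n), beta(n);
  for (int tr = 0; tr < nSegPerTrace.size(); ++tr) {
    double logl = 0.0;
    bool dead = false;
    // first frame: masked initial distribution
    int c0 = segCls[seg];
    double s0 = 0.0;
    for (int j = 0; j < n; ++j) {
      alpha[j] = (classOf[j] == c0) ? pi0[j] : 0.0;
      s0 += alpha[j];
    }
    if (s0 <= 0.0) dead = true; else {
      logl += std::log(s0);
      for (int j = 0; j < n; ++j) alpha[j] /= s0;
    }
    for (int k = 0; k < nSegPerTrace[tr] && !dead; ++k, ++seg) {
      int L = segLens[seg];
      if (k == 0) L -= 1;          // first frame already absorbed
      if (L <= 0) continue;
      int c = segCls[seg];
      const std::vector<double>& P = powm[c][L - 1];
      double s = 0.0;
      for (int j = 0; j < n; ++j) {
        double v = 0.0;
        for (int i = 0; i < n; ++i) v += alpha[i] * P[i + n * j];
        beta[j] = v;
        s += v;
      }
      if (s <= 0.0) { dead = true; break; }
      logl += std::log(s) + logScale[c][L - 1];
      for (int j = 0; j < n; ++j) alpha[j] = beta[j] / s;
    }
    if (dead) return R_NegInf;  // impossible sequence under this model
    total += logl;
  }
  return total;
}

// EM for a right-censored exponential mixture. x: uncensored dwells,
// cc: censored dwells (contributing survival terms). Returns A, tau,
// logL and convergence flag.
//
// [[Rcpp::export]]
List cpp_em_expmix(NumericVector x, NumericVector cc, NumericVector A0,
                   NumericVector tau0, int maxIter, double tol) {
  const int n = x.size(), m = cc.size(), K = A0.size();
  std::vector<double> A(A0.begin(), A0.end());
  std::vector<double> tau(tau0.begin(), tau0.end());
  std::vector<double> nk(K), num(K), w(K), la(K), las(K), invTau(K);
  double llOld = R_NegInf, ll = R_NegInf;
  bool conv = false;
  // one E-like sweep; accumulates sufficient statistics unless statsOnly
  // is false (final likelihood evaluation)
  auto sweep = [&](bool accumulate) {
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      invTau[k] = 1.0 / tau[k];
      la[k] = std::log(A[k]) - std::log(tau[k]);   // density prefactor
      las[k] = std::log(A[k]);                      // survival prefactor
    }
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        w[k] = la[k] - x[i] * invTau[k];
        if (w[k] > mx) mx = w[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp(w[k] - mx); s += w[k]; }
      acc += mx + std::log(s);
      if (accumulate) {
        for (int k = 0; k < K; ++k) {
          double r = w[k] / s;
          nk[k] += r;
          num[k] += r * x[i];
        }
      }
    }
    for (int i = 0; i < m; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        w[k] = las[k] - cc[i] * invTau[k];
        if (w[k] > mx) mx = w[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp(w[k] - mx); s += w[k]; }
      acc += mx + std::log(s);
      if (accumulate) {
        for (int k = 0; k < K; ++k) {
          double r = w[k] / s;
          nk[k] += r;
          num[k] += r * (cc[i] + tau[k]);  // E[dwell | censored at cc]
        }
      }
    }
    return acc;
  };
  for (int it = 0; it < maxIter; ++it) {
    std::fill(nk.begin(), nk.end(), 0.0);
    std::fill(num.begin(), num.end(), 0.0);
    ll = sweep(true);
    double sumA = 0.0;
    for (int k = 0; k < K; ++k) {
      A[k] = std::max(nk[k] / (n + m), 1e-12);
      sumA += A[k];
    }
    for (int k = 0; k < K; ++k) A[k] /= sumA;
    for (int k = 0; k < K; ++k) {
      double t = num[k] / std::max(nk[k], 1e-12);
      tau[k] = std::min(std::max(t, 1e-6), 1e9);
    }
    if (R_finite(ll) && std::fabs(ll - llOld) < tol * (std::fabs(ll) + 1)) {
      conv = true;
      break;
    }
    llOld = ll;
  }
  // final log-likelihood at the updated parameters
  double llF = sweep(false);
  return List::create(Named("A") = A, Named("tau") = tau,
                      Named("logL") = llF, Named("converged") = conv);
}

// Exact penalized least-squares changepoint segmentation (PELT).
// Minimizes sum of segment SSEs + beta * (number of changepoints) over all
// segmentations. Returns the 1-based start indices of segments after the
// first (empty when no changepoint).
//
// [[Rcpp::export]]
IntegerVector cpp_pelt(NumericVector x, double beta) {
  const int n = x.size();
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    css[i + 1] = css[i] + x[i] * x[i];
  }
  auto segCost = [&](int s, int t) {  // cost of x[s..t-1], 0-based half-open
    double m = t - s;
    double sum = cs[t] - cs[s];
    return (css[t] - css[s]) - sum * sum / m;
  };
  std::vector<double> F(n + 1);
  std::vector<int> last(n + 1, 0);
  std::vector<int> cand;
  F[0] = -beta;
  cand.push_back(0);
  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int arg = 0;
    for (size_t i = 0; i < cand.size(); ++i) {
      int s = cand[i];
      double v = F[s] + segCost(s, t) + beta;
      if (v < best) { best = v; arg = s; }
    }
    F[t] = best;
    last[t] = arg;
    // PELT pruning
    std::vector<int> keep;
    for (size_t i = 0; i < cand.size(); ++i) {
      int s = cand[i];
      if (F[s] + segCost(s, t) <= F[t]) keep.push_back(s);
    }
    keep.push_back(t);
    cand.swap(keep);
  }
  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    int s = last[t];
    if (s > 0) cps.push_back(s + 1);  // 1-based start of the new segment
    t = s;
  }
  std::sort(cps.begin(), cps.end());
  return wrap(cps);
}

// Viterbi path for a Gaussian-emission HMM with per-state means and one
// shared sd; logTrans is the log transition matrix. Returns 0-based states.
//
// [[Rcpp::export]]
IntegerVector cpp_viterbi_gauss(NumericVector x, NumericVector mu, double sd,
                                NumericMatrix logTrans, NumericVector logPi) {
  const int T = x.size(), K = mu.size();
  if (K == 1) return IntegerVector(T, 0);
  std::vector<double> d(T * K);
  std::vector<int> bp(T * K);
  const double inv2s2 = 1.0 / (2.0 * sd * sd);
  for (int k = 0; k < K; ++k) {
    double e = -(x[0] - mu[k]) * (x[0] - mu[k]) * inv2s2;
    d[k] = logPi[k] + e;
  }
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = d[(t - 1) * K + j] + logTrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      double e = -(x[t] - mu[k]) * (x[t] - mu[k]) * inv2s2;
      d[t * K + k] = best + e;
      bp[t * K + k] = arg;
    }
  }
  IntegerVector path(T);
  int best = 0;
  for (int k = 1; k < K; ++k)
    if (d[(T - 1) * K + k] > d[(T - 1) * K + best]) best = k;
  path[T - 1] = best;
  for (int t = T - 1; t > 0; --t)
    path[t - 1] = bp[t * K + path[t]];
  return path;
}
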