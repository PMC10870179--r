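// Panel-likelihood machinery for the 5-state weight-trajectory Markov model.
//
// The model: adjacent-state transitions with proportional intensities
//   q_rs(z) = q0_rs * exp(beta_rs' z_masked),
// observed only at irregular visit times (interval censoring).  Each
// observation interval is split at exposure changepoints; the interval
// transition-probability matrix is the time-ordered product of matrix
// exponentials expm(Q(z_j) * dt_j).
//
// Hot path: the likelihood is evaluated thousands of times by the optimizer
// and by the multivariate-normal CI simulation, so matrix exponentials are
// computed through an eigendecomposition cache keyed on the rate vector.
// Adjacent-state (birth-death) generators with positive rates are
// diagonalizable with real spectrum, so the cache almost always hits the
// cheap path; arma::expmat is the fallback when the eigensystem is
// ill-conditioned.

#include <RcppArmadillo.h>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct EigEntry {
  bool usable;
  arma::cx_mat V;
  arma::cx_vec lam;
  arma::cx_mat Vinv;
  arma::mat Q;
};

typedef std::map<std::vector<double>, EigEntry> EigCache;

// Build the generator from per-transition rates.
arma::mat build_Q(const std::vector<double>& rates,
                  const arma::ivec& from, const arma::ivec& to,
                  int n_states) {
  arma::mat Q(n_states, n_states, arma::fill::zeros);
  for (size_t k = 0; k < rates.size(); ++k) {
    int r = from[k] - 1, s = to[k] - 1;
    Q(r, s) += rates[k];
    Q(r, r) -= rates[k];
  }
  return Q;
}

EigEntry decompose(const arma::mat& Q) {
  EigEntry e;
  e.Q = Q;
  e.usable = false;
  arma::cx_vec lam;
  arma::cx_mat V;
  if (arma::eig_gen(lam, V, Q)) {
    arma::cx_mat Vinv;
    if (arma::inv(Vinv, V)) {
      // Reject near-defective systems: reconstruction must be accurate.
      arma::mat rec = arma::real(V * arma::diagmat(lam) * Vinv);
      double err = arma::norm(rec - Q, "inf");
      double scale = std::max(1.0, arma::norm(Q, "inf"));
      if (err < 1e-9 * scale) {
        e.usable = true;
        e.V = V;
        e.lam = lam;
        e.Vinv = Vinv;
      }
    }
  }
  return e;
}

// expm(Q * dt) via the cached eigensystem (fallback: Pade scaling-squaring).
// Returns false (without throwing) when the exponential is not
// representable, e.g. at the extreme rates an optimizer line search can
// visit; callers treat that as a zero-probability configuration.
bool seg_prob(const EigEntry& e, double dt, arma::mat& P) {
  if (e.usable) {
    arma::cx_vec ex = arma::exp(e.lam * dt);
    P = arma::real(e.V * arma::diagmat(ex) * e.Vinv);
  } else {
    if (!arma::expmat(P, e.Q * dt)) return false;
  }
  if (!P.is_finite()) return false;
  // numerical cleanup: probabilities live in [0,1], rows sum to 1
  P.clamp(0.0, 1.0);
  arma::vec rs = arma::sum(P, 1);
  for (arma::uword i = 0; i < P.n_rows; ++i)
    if (rs(i) > 0) P.row(i) /= rs(i);
  return true;
}

// Per-segment rates from theta = (log_q0, beta) and covariate row z.
// beta_idx(k, j) is the 1-based position of the coefficient of covariate j
// on transition k within the beta block, or 0 when masked out.
void segment_rates(std::vector<double>& rates,
                   const arma::vec& log_q0, const arma::vec& beta,
                   const arma::imat& beta_idx, const arma::mat& Z,
                   arma::uword seg) {
  const int K = log_q0.n_elem;
  for (int k = 0; k < K; ++k) {
    double lp = log_q0[k];
    for (arma::uword j = 0; j < beta_idx.n_cols; ++j) {
      int b = beta_idx(k, j);
      if (b > 0) lp += beta[b - 1] * Z(seg, j);
    }
    // saturate at exp(6)/day: far beyond any plausible weight-transition
    // rate, keeps degenerate (unidentified-coefficient) regions finite
    rates[k] = std::exp(std::min(lp, 6.0));
  }
}

const EigEntry& cache_get(EigCache& cache, const std::vector<double>& rates,
                          const arma::ivec& from, const arma::ivec& to,
                          int n_states) {
  EigCache::iterator it = cache.find(rates);
  if (it == cache.end()) {
    EigEntry e = decompose(build_Q(rates, from, to, n_states));
    it = cache.insert(std::make_pair(rates, e)).first;
  }
  return it->second;
}

} // namespace

// Negative log-likelihood of the panel data.
//
// theta      : c(log_q0 [K], beta [n_beta])
// from, to   : 1-based states of the K allowed transitions
// beta_idx   : K x P integer matrix, 0 = masked, else index into beta block
// Z          : n_seg x P covariate matrix (one row per exposure segment)
// seg_dt     : duration (days) of each segment
// seg_group  : 1-based observation-interval id per segment (sorted, time order)
// obs_from/obs_to : observed state pair per interval (length n_intervals)
// n_states   : number of states (5)
// [[Rcpp::export]]
double cpp_panel_nll(const arma::vec& theta,
                     const arma::ivec& from, const arma::ivec& to,
                     const arma::imat& beta_idx,
                     const arma::mat& Z, const arma::vec& seg_dt,
                     const arma::ivec& seg_group,
                     const arma::ivec& obs_from, const arma::ivec& obs_to,
                     int n_states) {
  const int K = from.n_elem;
  arma::vec log_q0 = theta.subvec(0, K - 1);
  arma::vec beta = (theta.n_elem > (arma::uword)K)
                       ? theta.subvec(K, theta.n_elem - 1)
                       : arma::vec();
  if (!theta.is_finite()) return R_PosInf;

  EigCache cache;
  std::vector<double> rates(K);
  const arma::uword n_seg = seg_dt.n_elem;
  double nll = 0.0;

  arma::uword s = 0;
  while (s < n_seg) {
    int g = seg_group[s];
    arma::mat P;
    bool first = true;
    while (s < n_seg && seg_group[s] == g) {
      segment_rates(rates, log_q0, beta, beta_idx, Z, s);
      const EigEntry& e = cache_get(cache, rates, from, to, n_states);
      if (seg_dt[s] > 0) {
        arma::mat Pseg;
        if (!seg_prob(e, seg_dt[s], Pseg)) return R_PosInf;
        P = first ? Pseg : arma::mat(P * Pseg);
        first = false;
      }
      ++s;
    }
    double p;
    int r = obs_from[g - 1] - 1, c = obs_to[g - 1] - 1;
    if (first) { // zero-length interval: identity
      p = (r == c) ? 1.0 : 0.0;
    } else {
      p = P(r, c);
    }
    if (p <= 0.0 || !std::isfinite(p)) return R_PosInf;
    nll -= std::log(p);
  }
  return nll;
}

// Negative log-likelihood AND its analytic gradient.
//
// Within a segment, with Q = V diag(lam) Vinv, the derivative of
// P = expm(Q dt) in a direction dQ is V ((Vinv dQ V) % Phi) Vinv with
// Phi_ij = (e^{lam_i dt} - e^{lam_j dt}) / (lam_i - lam_j) (dt e^{lam_i dt}
// on the diagonal).  Every parameter direction here is q_k x (E_ft - E_ff),
// a rank-one matrix, so the needed bilinear form
// L[r,:] dP R[:,c] collapses to (a % u)' Phi (w % b) with
// a = V^T L[r,:]', b = Vinv R[:,c], u = Vinv[:,f], w = (V[t,:] - V[f,:])'.
// Interval products enter through prefix rows L and suffix columns R.
// Falls back to success = false (caller uses numeric differentiation) when
// an eigensystem is ill-conditioned.
// [[Rcpp::export]]
List cpp_panel_nll_grad(const arma::vec& theta,
                        const arma::ivec& from, const arma::ivec& to,
                        const arma::imat& beta_idx,
                        const arma::mat& Z, const arma::vec& seg_dt,
                        const arma::ivec& seg_group,
                        const arma::ivec& obs_from, const arma::ivec& obs_to,
                        int n_states) {
  const int K = from.n_elem;
  arma::vec log_q0 = theta.subvec(0, K - 1);
  arma::vec beta = (theta.n_elem > (arma::uword)K)
                       ? theta.subvec(K, theta.n_elem - 1)
                       : arma::vec();
  arma::vec grad(theta.n_elem, arma::fill::zeros);
  if (!theta.is_finite())
    return List::create(_["nll"] = R_PosInf, _["grad"] = grad,
                        _["success"] = false);

  EigCache cache;
  std::vector<double> rates(K);
  const arma::uword n_seg = seg_dt.n_elem;
  double nll = 0.0;
  bool ok = true;

  arma::uword s = 0;
  while (s < n_seg && ok) {
    int g = seg_group[s];
    // collect the interval's segments
    std::vector<arma::uword> segs;
    std::vector<const EigEntry*> ents;
    std::vector<arma::mat> Ps;
    while (s < n_seg && seg_group[s] == g) {
      segment_rates(rates, log_q0, beta, beta_idx, Z, s);
      const EigEntry& e = cache_get(cache, rates, from, to, n_states);
      if (!e.usable) { ok = false; }
      if (ok && seg_dt[s] > 0) {
        arma::mat Pseg;
        if (!seg_prob(e, seg_dt[s], Pseg)) { ok = false; }
        else {
          segs.push_back(s);
          ents.push_back(&e);
          Ps.push_back(Pseg);
        }
      }
      ++s;
    }
    if (!ok) break;
    int r = obs_from[g - 1] - 1, c = obs_to[g - 1] - 1;
    const size_t J = segs.size();
    if (J == 0) { // zero-length interval
      if (r != c) { nll = R_PosInf; break; }
      continue;
    }
    // prefix rows L_j[r,:] and suffix columns R_j[:,c]
    std::vector<arma::rowvec> lrow(J);
    std::vector<arma::vec> rcol(J);
    arma::rowvec lr(n_states, arma::fill::zeros); lr[r] = 1.0;
    for (size_t j = 0; j < J; ++j) { lrow[j] = lr; lr = lr * Ps[j]; }
    arma::vec rc(n_states, arma::fill::zeros); rc[c] = 1.0;
    for (size_t j = J; j-- > 0;) { rcol[j] = rc; rc = Ps[j] * rc; }
    double p = lr[c]; // full product entry [r,c]
    if (p <= 0.0 || !std::isfinite(p)) { nll = R_PosInf; break; }
    nll -= std::log(p);

    for (size_t j = 0; j < J; ++j) {
      const EigEntry& e = *ents[j];
      const double dt = seg_dt[segs[j]];
      const arma::uword srow = segs[j];
      // Phi matrix for this (lam, dt)
      arma::cx_vec el = arma::exp(e.lam * dt);
      arma::cx_mat Phi(n_states, n_states);
      for (int i1 = 0; i1 < n_states; ++i1)
        for (int i2 = 0; i2 < n_states; ++i2) {
          std::complex<double> d = e.lam[i1] - e.lam[i2];
          Phi(i1, i2) = (std::abs(d) > 1e-9)
                            ? (el[i1] - el[i2]) / d
                            : dt * el[i1];
        }
      arma::cx_vec a = e.V.st() * arma::conv_to<arma::cx_vec>::from(lrow[j].t());
      arma::cx_vec b = e.Vinv * arma::conv_to<arma::cx_vec>::from(rcol[j]);
      // per-transition rank-one directions
      std::vector<double> rt(K);
      segment_rates(rt, log_q0, beta, beta_idx, Z, srow);
      for (int k = 0; k < K; ++k) {
        int f = from[k] - 1, t = to[k] - 1;
        arma::cx_vec s1 = a % e.Vinv.col(f);
        arma::cx_vec s2 = (e.V.row(t) - e.V.row(f)).st() % b;
        double val = std::real(arma::as_scalar(s1.st() * Phi * s2)) * rt[k];
        grad[k] -= val / p;
        for (arma::uword jc = 0; jc < beta_idx.n_cols; ++jc) {
          int bi = beta_idx(k, jc);
          if (bi > 0 && Z(srow, jc) != 0.0)
            grad[K + bi - 1] -= val * Z(srow, jc) / p;
        }
      }
    }
  }
  return List::create(_["nll"] = nll, _["grad"] = grad, _["success"] = ok);
}

// State-occupancy probabilities at the end of each group's segment sequence,
// starting from start_state.  Returns an n_groups x n_states matrix; groups
// are typically patients with their first-year exposure segments.
// [[Rcpp::export]]
arma::mat cpp_group_state_probs(const arma::vec& theta,
                                const arma::ivec& from, const arma::ivec& to,
                                const arma::imat& beta_idx,
                                const arma::mat& Z, const arma::vec& seg_dt,
                                const arma::ivec& seg_group,
                                int n_groups, int start_state, int n_states) {
  const int K = from.n_elem;
  arma::vec log_q0 = theta.subvec(0, K - 1);
  arma::vec beta = (theta.n_elem > (arma::uword)K)
                       ? theta.subvec(K, theta.n_elem - 1)
                       : arma::vec();

  EigCache cache;
  std::vector<double> rates(K);
  arma::mat out(n_groups, n_states, arma::fill::zeros);
  const arma::uword n_seg = seg_dt.n_elem;

  arma::uword s = 0;
  while (s < n_seg) {
    int g = seg_group[s];
    arma::rowvec p(n_states, arma::fill::zeros);
    p[start_state - 1] = 1.0;
    while (s < n_seg && seg_group[s] == g) {
      segment_rates(rates, log_q0, beta, beta_idx, Z, s);
      const EigEntry& e = cache_get(cache, rates, from, to, n_states);
      if (seg_dt[s] > 0) {
        arma::mat Pseg;
        if (!seg_prob(e, seg_dt[s], Pseg))
          stop("intensities too extreme: matrix exponential not representable");
        p = p * Pseg;
      }
      ++s;
    }
    out.row(g - 1) = p;
  }
  // groups with no segments keep the degenerate start distribution
  for (int g = 0; g < n_groups; ++g)
    if (arma::accu(out.row(g)) == 0.0) out(g, start_state - 1) = 1.0;
  return out;
}
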