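// Extended-phase-graph (EPG) simulation of the ECG-triggered FISP cardiac
// MRF sequence. States (F+_k, F-_k, Z_k) evolve under per-TR RF pulses,
// relaxation and an unbalanced (spoiler) gradient; magnetization
// preparation (ideal inversion, ideal T2 prep) precedes each heartbeat's
// acquisition window and free relaxation fills the RR gaps.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct EpgState {
  cx_vec Fp, Fm, Z;
  explicit EpgState(int n) : Fp(n, fill::zeros), Fm(n, fill::zeros),
                             Z(n, fill::zeros) {
    Z(0) = 1.0;
  }
};

// relaxation over tau ms with T1 recovery of the k = 0 longitudinal state
inline void relax(EpgState& s, double tau, double t1, double t2) {
  const double e1 = std::exp(-tau / t1), e2 = std::exp(-tau / t2);
  s.Fp *= e2;
  s.Fm *= e2;
  s.Z *= e1;
  s.Z(0) += 1.0 - e1;
}

// unbalanced gradient: dephasing order k increases by one
inline void grad_shift(EpgState& s) {
  const int n = s.Fp.n_elem;
  for (int k = n - 1; k >= 1; --k) s.Fp(k) = s.Fp(k - 1);
  for (int k = 0; k < n - 1; ++k) s.Fm(k) = s.Fm(k + 1);
  s.Fm(n - 1) = 0.0;
  s.Fp(0) = std::conj(s.Fm(0));
}

// RF pulse of flip alpha about the x axis (phase 0)
inline void rf_pulse(EpgState& s, double ca2, double sa2, double sa,
                     double ca) {
  const cx_double i1(0.0, 1.0);
  const int n = s.Fp.n_elem;
  for (int k = 0; k < n; ++k) {
    const cx_double fp = s.Fp(k), fm = s.Fm(k), z = s.Z(k);
    s.Fp(k) = ca2 * fp + sa2 * fm - i1 * sa * z;
    s.Fm(k) = sa2 * fp + ca2 * fm + i1 * sa * z;
    s.Z(k) = -i1 * 0.5 * sa * fp + i1 * 0.5 * sa * fm + ca * z;
  }
}

// spoil transverse pathways (crushers around preparation modules)
inline void spoil(EpgState& s) {
  s.Fp.zeros();
  s.Fm.zeros();
}

}  // namespace

// Simulate fingerprints for p (T1, T2) pairs over one schedule.
// prep_kind: 0 none, 1 inversion (prep_dur = post-inversion delay),
// 2 T2 preparation (prep_dur = echo time tau of the prep).
// rr_ms: gap between end of window h and start of window h+1; the next
// heartbeat's preparation duration is subtracted from this free-relaxation
// gap (the prep sits immediately before the window).
// [[Rcpp::export]]
arma::cx_mat epg_simulate_rr_cpp(const arma::vec& t1, const arma::vec& t2,
                                 const arma::vec& flip_rad, int n_per,
                                 double tr_ms, double te_ms,
                                 const arma::ivec& prep_kind,
                                 const arma::vec& prep_dur,
                                 const arma::mat& rr_ms, int n_states) {
  const int p = t1.n_elem, n_hb = prep_kind.n_elem;
  const int t = n_hb * n_per;
  if ((int)flip_rad.n_elem != t)
    Rcpp::stop("flip series length must equal heartbeats x TRs per heartbeat");
  if ((int)rr_ms.n_cols != n_hb - 1 || (int)rr_ms.n_rows != p)
    Rcpp::stop("rr_ms must be p x (heartbeats - 1)");

  vec ca2(t), sa2(t), sa(t), ca(t);
  for (int j = 0; j < t; ++j) {
    const double a = flip_rad(j);
    ca2(j) = std::cos(a / 2) * std::cos(a / 2);
    sa2(j) = std::sin(a / 2) * std::sin(a / 2);
    sa(j) = std::sin(a);
    ca(j) = std::cos(a);
  }

  cx_mat D(p, t);
  for (int a = 0; a < p; ++a) {
    if (t1(a) <= 0 || t2(a) <= 0) Rcpp::stop("relaxation times must be positive");
    EpgState s(n_states);
    const double T1 = t1(a), T2 = t2(a);
    int j = 0;
    for (int h = 0; h < n_hb; ++h) {
      if (h > 0) {
        double gap = rr_ms(a, h - 1) - prep_dur(h);
        if (gap < 0) gap = 0;
        relax(s, gap, T1, T2);
      }
      if (prep_kind(h) == 1) {            // ideal 180, then inversion delay
        spoil(s);
        s.Z = -s.Z;
        relax(s, prep_dur(h), T1, T2);
      } else if (prep_kind(h) == 2) {     // ideal T2 prep: Mz *= exp(-tau/T2)
        spoil(s);
        s.Z *= std::exp(-prep_dur(h) / T2);
      }
      for (int i = 0; i < n_per; ++i, ++j) {
        rf_pulse(s, ca2(j), sa2(j), sa(j), ca(j));
        D(a, j) = s.Fp(0) * std::exp(-te_ms / T2);
        relax(s, tr_ms, T1, T2);
        grad_shift(s);
      }
    }
  }
  return D;
}

// single shared rhythm for all (T1, T2) atoms
// [[Rcpp::export]]
arma::cx_mat epg_simulate_cpp(const arma::vec& t1, const arma::vec& t2,
                              const arma::vec& flip_rad, int n_per,
                              double tr_ms, double te_ms,
                              const arma::ivec& prep_kind,
                              const arma::vec& prep_dur,
                              const arma::vec& rr_ms, int n_states) {
  arma::mat rr(t1.n_elem, rr_ms.n_elem);
  rr.each_row() = rr_ms.t();
  return epg_simulate_rr_cpp(t1, t2, flip_rad, n_per, tr_ms, te_ms,
                             prep_kind, prep_dur, rr, n_states);
}
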