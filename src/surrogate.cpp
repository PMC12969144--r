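#include <Rcpp.h>
using namespace Rcpp;

// Time-shift surrogate maxima for the group-mean plvs.
//
// zmats: per participant, a (time x trial) complex matrix of unit phase
// vectors; NaN real part marks invalid cells. Each iteration circularly
// shifts every trial's column by an independent uniform lag, recomputes
// the participant plvs trace, averages across participants and returns
// the maximum over time. Uses R's RNG, so results are reproducible under
// set.seed(); the draw order is iteration-major, then participant, then
// trial (one uniform per trial per iteration).
// [[Rcpp::export]]
NumericVector surrogate_max_cpp(List zmats, int n_iter, int min_trials) {
  const int P = zmats.size();
  if (P == 0) stop("no participants");
  std::vector<ComplexMatrix> Z;
  Z.reserve(P);
  int T = -1;
  for (int p = 0; p < P; ++p) {
    ComplexMatrix m = zmats[p];
    if (T < 0) T = m.nrow();
    else if (m.nrow() != T) stop("participants disagree on epoch length");
    Z.push_back(m);
  }
  NumericVector out(n_iter);
  std::vector<double> re(T), im(T), gsum(T);
  std::vector<int> cnt(T), gcnt(T);
  for (int it = 0; it < n_iter; ++it) {
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gcnt.begin(), gcnt.end(), 0);
    for (int p = 0; p < P; ++p) {
      const ComplexMatrix& M = Z[p];
      const int ntr = M.ncol();
      std::fill(re.begin(), re.end(), 0.0);
      std::fill(im.begin(), im.end(), 0.0);
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int j = 0; j < ntr; ++j) {
        int s = (int)(unif_rand() * T);
        if (s >= T) s = T - 1;
        const Rcomplex* col = &M[(R_xlen_t)j * T];
        // surrogate value at time t is the original at (t + s) mod T
        for (int t = 0; t < T; ++t) {
          int src = t + s;
          if (src >= T) src -= T;
          const Rcomplex& z = col[src];
          if (!ISNAN(z.r)) {
            re[t] += z.r;
            im[t] += z.i;
            cnt[t] += 1;
          }
        }
      }
      for (int t = 0; t < T; ++t) {
        if (cnt[t] >= min_trials) {
          gsum[t] += std::sqrt(re[t] * re[t] + im[t] * im[t]) / cnt[t];
          gcnt[t] += 1;
        }
      }
    }
    double mx = R_NegInf;
    for (int t = 0; t < T; ++t) {
      if (gcnt[t] > 0) {
        double v = gsum[t] / gcnt[t];
        if (v > mx) mx = v;
      }
    }
    out[it] = (mx == R_NegInf) ? NA_REAL : mx;
  }
  return out;
}
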