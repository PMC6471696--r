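#include <Rcpp.h>
using namespace Rcpp;

// Scores one window of the integer-encoded sequence (A=0,C=1,G=2,T=3,N=-1)
// against an information-weighted score matrix w (L x 4). Windows containing
// N score 0 by convention (conservative: no imputation).
static double window_raw(const IntegerVector& seq, int start,
                         const NumericMatrix& w) {
  const int L = w.nrow();
  double raw = 0.0;
  for (int i = 0; i < L; ++i) {
    const int b = seq[start + i];
    if (b < 0) return NA_REAL; // N in window -> caller maps to score 0
    raw += w(i, b);
  }
  return raw;
}

// [[Rcpp::export(name = ".cpp_scan_pwm")]]
DataFrame cpp_scan_pwm(IntegerVector seq, NumericMatrix w, NumericMatrix w_rc,
                       double min_raw, double max_raw, double cutoff,
                       bool both_strands) {
  const int L = w.nrow();
  const int n = seq.size();
  std::vector<int> pos;
  std::vector<int> strand; // 0 = '+', 1 = '-'
  std::vector<double> score;
  if (n >= L) {
    const double range = max_raw - min_raw;
    const bool degenerate = !(range > 0);
    for (int p = 0; p <= n - L; ++p) {
      // forward strand
      double raw = window_raw(seq, p, w);
      double sc = 0.0;
      if (!ISNA(raw) && !degenerate) sc = (raw - min_raw) / range;
      if (sc >= cutoff) {
        pos.push_back(p); strand.push_back(0); score.push_back(sc);
      }
      if (both_strands) {
        // reverse strand: scoring the forward window with the
        // reverse-complemented matrix equals scoring the reverse
        // complement of the window with the original matrix
        raw = window_raw(seq, p, w_rc);
        sc = 0.0;
        if (!ISNA(raw) && !degenerate) sc = (raw - min_raw) / range;
        if (sc >= cutoff) {
          pos.push_back(p); strand.push_back(1); score.push_back(sc);
        }
      }
    }
  }
  return DataFrame::create(_["start"] = pos, _["strand"] = strand,
                           _["score"] = score);
}

// Batch variant over a whole sequence set: seqs is a list of integer-
// encoded sequences; returns parallel vectors with a 1-based sequence
// index per hit.
// [[Rcpp::export(name = ".cpp_scan_pwm_set")]]
List cpp_scan_pwm_set(List seqs, NumericMatrix w, NumericMatrix w_rc,
                      double min_raw, double max_raw, double cutoff,
                      bool both_strands) {
  const int L = w.nrow();
  const double range = max_raw - min_raw;
  const bool degenerate = !(range > 0);
  std::vector<int> seq_idx, pos, strand;
  std::vector<double> score;
  for (int si = 0; si < seqs.size(); ++si) {
    IntegerVector seq = seqs[si];
    const int n = seq.size();
    if (n < L) continue;
    for (int p = 0; p <= n - L; ++p) {
      double raw = window_raw(seq, p, w);
      double sc = (!ISNA(raw) && !degenerate) ? (raw - min_raw) / range : 0.0;
      if (sc >= cutoff) {
        seq_idx.push_back(si + 1); pos.push_back(p);
        strand.push_back(0); score.push_back(sc);
      }
      if (both_strands) {
        raw = window_raw(seq, p, w_rc);
        sc = (!ISNA(raw) && !degenerate) ? (raw - min_raw) / range : 0.0;
        if (sc >= cutoff) {
          seq_idx.push_back(si + 1); pos.push_back(p);
          strand.push_back(1); score.push_back(sc);
        }
      }
    }
  }
  return List::create(_["seq_idx"] = seq_idx, _["start"] = pos,
                      _["strand"] = strand, _["score"] = score);
}

// Exhaustive maximisation over every nucleotide position x of the
// Gaussian-weighted sum of match scores: sum_j q_j * dnorm(|x - c_j|, 0, sigma).
// Returns (score, x_max); ties broken to the smallest x.
// [[Rcpp::export(name = ".cpp_cm_score")]]
NumericVector cpp_cm_score(NumericVector centers, NumericVector scores,
                           double sigma, int seq_len) {
  const int m = centers.size();
  if (m == 0 || seq_len < 1)
    return NumericVector::create(0.0, 0.0);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  double best = -1.0;
  int best_x = 0;
  for (int x = 0; x < seq_len; ++x) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      const double d = x - centers[j];
      s += scores[j] * std::exp(-d * d * inv2s2);
    }
    if (s > best) { best = s; best_x = x; }
  }
  return NumericVector::create(best * norm, (double)best_x);
}

// Batch evaluation of reg_score over all sequences for one candidate model.
// cache: list over PWMs; cache[[k]] is a list over sequences of numeric
// matrices with columns (center, score), rows sorted by descending score
// (ties: smaller center, '+' strand first), pre-thresholded at the global
// scan floor. modules: list of lists with elements pwm (1-based int indices
// into cache), cutoff, kappa, sigma.
// [[Rcpp::export(name = ".cpp_model_scores")]]
NumericVector cpp_model_scores(List cache, IntegerVector seq_len,
                               List modules) {
  const int n_seq = seq_len.size();
  const int n_mod = modules.size();
  NumericVector out(n_seq);
  std::vector<double> cen, sco;
  for (int i = 0; i < n_seq; ++i) {
    double reg = 0.0;
    for (int t = 0; t < n_mod; ++t) {
      List mod = modules[t];
      IntegerVector pwm_idx = mod["pwm"];
      NumericVector cutoff = mod["cutoff"];
      IntegerVector kappa = mod["kappa"];
      const double sigma = as<double>(mod["sigma"]);
      cen.clear(); sco.clear();
      for (int k = 0; k < pwm_idx.size(); ++k) {
        List per_seq = cache[pwm_idx[k] - 1];
        NumericMatrix m = per_seq[i];
        int taken = 0;
        for (int r = 0; r < m.nrow() && taken < kappa[k]; ++r) {
          if (m(r, 1) >= cutoff[k]) {
            cen.push_back(m(r, 0));
            sco.push_back(m(r, 1));
            ++taken;
          }
        }
      }
      const int mm = (int)cen.size();
      if (mm == 0) continue;
      const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
      double best = -1.0;
      for (int x = 0; x < seq_len[i]; ++x) {
        double s = 0.0;
        for (int j = 0; j < mm; ++j) {
          const double d = x - cen[j];
          s += sco[j] * std::exp(-d * d * inv2s2);
        }
        if (s > best) best = s;
      }
      reg += best / (sigma * std::sqrt(2.0 * M_PI));
    }
    out[i] = reg;
  }
  return out;
}
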