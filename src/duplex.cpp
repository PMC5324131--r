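#include <Rcpp.h>
using namespace Rcpp;

// Pairing code for an RNA duplex position: 2 = Watson-Crick, 1 = G:U
// wobble, 0 = mismatch. `m` is the miRNA base, `s` the site base.
static inline int pair_code(char m, char s) {
  switch (m) {
    case 'A': return s == 'U' ? 2 : 0;
    case 'U': return s == 'A' ? 2 : (s == 'G' ? 1 : 0);
    case 'G': return s == 'C' ? 2 : (s == 'U' ? 1 : 0);
    case 'C': return s == 'G' ? 2 : 0;
  }
  return 0;
}

struct TargetCosts {
  double mismatch, wobble, indel, core_mult;
  int core_start, core_end; // 1-based miRNA positions, inclusive
};

static inline double pos_weight(const TargetCosts& tc, int pos1) {
  return (pos1 >= tc.core_start && pos1 <= tc.core_end) ? tc.core_mult : 1.0;
}

static inline double base_cost(const TargetCosts& tc, char m, char s,
                               int pos1) {
  int pc = pair_code(m, s);
  double c = pc == 2 ? 0.0 : (pc == 1 ? tc.wobble : tc.mismatch);
  return c * pos_weight(tc, pos1);
}

// Penalty of one site window (already reversed: r[i] faces mir[i]).
// Window length may be L-1, L or L+1; the best single-indel placement is
// taken for the off-by-one lengths. Costs are non-negative, so partial
// sums exceeding `limit` (the hit cutoff) prune the scan; a pruned window
// returns +Inf.
static double window_penalty(const std::string& mir, const std::string& r,
                             const TargetCosts& tc,
                             double limit = R_PosInf) {
  int L = mir.size(), W = r.size();
  if (W == L) {
    double s = 0.0;
    for (int i = 0; i < L; ++i) {
      s += base_cost(tc, mir[i], r[i], i + 1);
      if (s > limit) return R_PosInf;
    }
    return s;
  }
  double best = R_PosInf;
  if (W == L + 1) {
    // one unpaired site base at r index g (target bulge)
    for (int g = 0; g <= L; ++g) {
      double bound = std::min(best, limit);
      double s = tc.indel * pos_weight(tc, std::min(g + 1, L));
      for (int i = 0; i < L && s <= bound; ++i) {
        char sb = (i < g) ? r[i] : r[i + 1];
        s += base_cost(tc, mir[i], sb, i + 1);
      }
      if (s < best) best = s;
    }
    return best > limit ? R_PosInf : best;
  }
  if (W == L - 1) {
    // one unpaired miRNA base at position g + 1 (miRNA bulge)
    for (int g = 0; g < L; ++g) {
      double bound = std::min(best, limit);
      double s = tc.indel * pos_weight(tc, g + 1);
      for (int i = 0; i < L && s <= bound; ++i) {
        if (i == g) continue;
        char sb = (i < g) ? r[i] : r[i - 1];
        s += base_cost(tc, mir[i], sb, i + 1);
      }
      if (s < best) best = s;
    }
    return best > limit ? R_PosInf : best;
  }
  stop("site length must be within one of the miRNA length");
  return best;
}

static std::string rev_window(const std::string& seq, int start0, int w) {
  std::string r(w, 'N');
  for (int i = 0; i < w; ++i) r[i] = seq[start0 + w - 1 - i];
  return r;
}

// [[Rcpp::export]]
double cpp_score_site(std::string mir, std::string site, double mismatch,
                      double wobble, double indel, int core_start,
                      int core_end, double core_mult) {
  TargetCosts tc{mismatch, wobble, indel, core_mult, core_start, core_end};
  std::string r = rev_window(site, 0, site.size());
  return window_penalty(mir, r, tc);
}

// Scan all windows of length L-1, L, L+1 of `seq` (RNA, 5'->3') for
// miRNA target sites with penalty <= cutoff.
// [[Rcpp::export]]
DataFrame cpp_scan_targets(std::string seq, std::string mir, double mismatch,
                           double wobble, double indel, int core_start,
                           int core_end, double core_mult, double cutoff) {
  TargetCosts tc{mismatch, wobble, indel, core_mult, core_start, core_end};
  int n = seq.size(), L = mir.size();
  std::vector<int> starts, widths;
  std::vector<double> penalties;
  for (int w = L - 1; w <= L + 1; ++w) {
    if (w < 1 || w > n) continue;
    for (int s0 = 0; s0 + w <= n; ++s0) {
      std::string r = rev_window(seq, s0, w);
      double p = window_penalty(mir, r, tc, cutoff);
      if (p <= cutoff) {
        starts.push_back(s0 + 1);
        widths.push_back(w);
        penalties.push_back(p);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["width"] = widths,
                           _["penalty"] = penalties);
}

// Endogenous target mimic scan. Site windows have length L+3; the 3-nt
// bulge sits opposite the junction between miRNA positions j and j+1 for
// j in {9, 10, 11}. Rules: miRNA positions 2-8 perfectly Watson-Crick
// paired (G:U does not count as paired); total mismatches + G:U pairs
// over all paired positions outside the bulge <= max_edits.
// [[Rcpp::export]]
DataFrame cpp_scan_etm(std::string seq, std::string mir, int max_edits) {
  int n = seq.size(), L = mir.size(), W = L + 3;
  std::vector<int> starts, junctions, edits_out, gu_out, mm_out;
  if (W <= n) {
    for (int s0 = 0; s0 + W <= n; ++s0) {
      std::string r = rev_window(seq, s0, W);
      for (int j = 9; j <= 11; ++j) {
        bool seed_ok = true;
        int edits = 0, gu = 0, mm = 0;
        for (int i = 0; i < L; ++i) {
          char sb = (i < j) ? r[i] : r[i + 3];
          int pc = pair_code(mir[i], sb);
          if (i >= 1 && i <= 7) { // miRNA positions 2..8
            if (pc != 2) { seed_ok = false; break; }
          } else if (pc != 2) {
            ++edits;
            if (pc == 1) ++gu; else ++mm;
            if (edits > max_edits) break;
          }
        }
        if (seed_ok && edits <= max_edits) {
          starts.push_back(s0 + 1);
          junctions.push_back(j);
          edits_out.push_back(edits);
          gu_out.push_back(gu);
          mm_out.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["junction"] = junctions,
                           _["n_edits"] = edits_out, _["n_gu"] = gu_out,
                           _["n_mismatch"] = mm_out);
}
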