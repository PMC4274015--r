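#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Affine-gap local alignment score (Gotoh). A gap of length L costs
// gap_open + (L-1) * gap_extend, i.e. the first gapped base pays the
// opening penalty. Sequences here are short reads (a few hundred bases),
// so O(nm) memory is fine.
static double sw_full(const std::string& a, const std::string& b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<std::vector<double> > H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double> > E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open, E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open, F[i - 1][j] - gap_extend);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = H[i - 1][j - 1] + s;
      h = std::max(h, E[i][j]);
      h = std::max(h, F[i][j]);
      h = std::max(h, 0.0);
      H[i][j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
NumericVector sw_score_cpp(CharacterVector a, CharacterVector b,
                           double match, double mismatch,
                           double gap_open, double gap_extend) {
  const int n = std::max(a.size(), b.size());
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string sa = as<std::string>(a[k % a.size()]);
    std::string sb = as<std::string>(b[k % b.size()]);
    out[k] = sw_full(sa, sb, match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
NumericMatrix sw_score_matrix_cpp(CharacterVector children, CharacterVector parents,
                                  double match, double mismatch,
                                  double gap_open, double gap_extend) {
  const int nc = children.size(), np = parents.size();
  NumericMatrix out(nc, np);
  std::vector<std::string> ps(np);
  for (int j = 0; j < np; ++j) ps[j] = as<std::string>(parents[j]);
  for (int i = 0; i < nc; ++i) {
    std::string c = as<std::string>(children[i]);
    for (int j = 0; j < np; ++j)
      out(i, j) = sw_full(c, ps[j], match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// Unit-cost global edit distance (substitution = 1, each gap base = 1).
static int lev(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".nw_distance_cpp")]]
IntegerVector nw_distance_cpp(CharacterVector a, CharacterVector b) {
  const int n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    out[k] = lev(as<std::string>(a[k % a.size()]),
                 as<std::string>(b[k % b.size()]));
  }
  return out;
}

// Pairwise distances for an index list over one sequence vector.
// [[Rcpp::export(name = ".nw_distance_pairs_cpp")]]
IntegerVector nw_distance_pairs_cpp(CharacterVector seqs,
                                    IntegerVector i_idx, IntegerVector j_idx) {
  const int np = i_idx.size();
  std::vector<std::string> s(seqs.size());
  for (int k = 0; k < seqs.size(); ++k) s[k] = as<std::string>(seqs[k]);
  IntegerVector out(np);
  for (int k = 0; k < np; ++k)
    out[k] = lev(s[i_idx[k] - 1], s[j_idx[k] - 1]);
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) {
      switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      }
    }
    out[k] = r;
  }
  return out;
}

// Longest suffix whose reverse complement occurs internally, ending at
// least one base before the suffix start; ties to the 5'-most partner.
// Returns c(stem_length, partner_start_1based), or c(0, 0) when no stem of
// at least min_stem bases exists.
// [[Rcpp::export(name = ".stem_search_cpp")]]
IntegerVector stem_search_cpp(std::string seq, int min_stem) {
  const int n = seq.size();
  std::string rc(seq.rbegin(), seq.rend());
  for (size_t i = 0; i < rc.size(); ++i) {
    switch (rc[i]) {
    case 'A': rc[i] = 'T'; break;
    case 'C': rc[i] = 'G'; break;
    case 'G': rc[i] = 'C'; break;
    case 'T': rc[i] = 'A'; break;
    }
  }
  int l_max = (n - 1) / 2;
  for (int L = l_max; L >= min_stem; --L) {
    // revcomp of the L-suffix of seq = first L characters of rc
    // partner must end at index <= n - L - 1 (0-based), i.e. start <= n - 2L
    for (int s = 0; s + L <= n - L; ++s) {
      if (seq.compare(s, L, rc, 0, L) == 0) {
        IntegerVector out = IntegerVector::create(L, s + 1);
        return out;
      }
    }
  }
  return IntegerVector::create(0, 0);
}

// Vectorized 3'-half trimming at restriction cuts: for each sequence,
// collect top-strand cut coordinates implied by every enzyme's recognition
// motif on either strand, then apply the 3'-most cut located in the 3'
// half. Mirrors digest_trim(mode = "three_prime") exactly.
// [[Rcpp::export(name = ".digest3_cpp")]]
CharacterVector digest3_cpp(CharacterVector seqs, CharacterVector recs,
                            CharacterVector rec_rcs, IntegerVector offs) {
  const int n = seqs.size(), ne = recs.size();
  std::vector<std::string> rec(ne), rrc(ne);
  for (int k = 0; k < ne; ++k) {
    rec[k] = as<std::string>(recs[k]);
    rrc[k] = as<std::string>(rec_rcs[k]);
  }
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    // cut repeatedly to a fixed point: dropping a 3' fragment can expose a
    // remaining site whose cut now lies in the shorter 3' half
    for (;;) {
      const int len = s.size();
      int best = -1;
      for (int k = 0; k < ne; ++k) {
        const int w = rec[k].size(), off = offs[k];
        for (size_t p = s.find(rec[k]); p != std::string::npos;
             p = s.find(rec[k], p + 1)) {
          int cut = (int)p + w + off;
          if (cut > 0 && cut < len && 2 * cut >= len && cut > best) best = cut;
        }
        for (size_t p = s.find(rrc[k]); p != std::string::npos;
             p = s.find(rrc[k], p + 1)) {
          int cut = (int)p - off;
          if (cut > 0 && cut < len && 2 * cut >= len && cut > best) best = cut;
        }
      }
      if (best < 0) break;
      s = s.substr(0, best);
    }
    out[i] = s;
  }
  return out;
}

// One mutation pass per daughter strand: k_sub substitutions drawn from the
// cumulative spectrum (rows/cols in ACGT order) at distinct positions, then
// k_ind indel events (insertion or deletion, equally likely, of 1..max_len
// bases) at distinct positions applied 3'-to-5'. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".mutate_batch_cpp")]]
CharacterVector mutate_batch_cpp(CharacterVector parents, IntegerVector k_sub,
                                 IntegerVector k_ind, NumericMatrix spectrum_cum,
                                 int max_len) {
  const int n = parents.size();
  const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(n);
  std::vector<int> pos;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(parents[i]);
    const int ks = k_sub[i], ki = k_ind[i];
    if (ks > 0) {
      int L = s.size();
      // partial Fisher-Yates for ks distinct positions
      pos.resize(L);
      for (int p = 0; p < L; ++p) pos[p] = p;
      for (int d = 0; d < ks && d < L; ++d) {
        int r = d + (int)(unif_rand() * (L - d));
        if (r >= L) r = L - 1;
        std::swap(pos[d], pos[r]);
        int p = pos[d];
        int b;
        switch (s[p]) {
        case 'A': b = 0; break;
        case 'C': b = 1; break;
        case 'G': b = 2; break;
        default:  b = 3; break;
        }
        double u = unif_rand();
        int j = 0;
        while (j < 3 && spectrum_cum(b, j) < u) ++j;
        s[p] = bases[j];
      }
    }
    if (ki > 0) {
      int L = s.size();
      pos.resize(L);
      for (int p = 0; p < L; ++p) pos[p] = p;
      std::vector<int> chosen;
      for (int d = 0; d < ki && d < L; ++d) {
        int r = d + (int)(unif_rand() * (L - d));
        if (r >= L) r = L - 1;
        std::swap(pos[d], pos[r]);
        chosen.push_back(pos[d]);
      }
      std::sort(chosen.rbegin(), chosen.rend());
      for (size_t c = 0; c < chosen.size(); ++c) {
        int p = chosen[c];
        int len = 1 + (int)(unif_rand() * max_len);
        if (len > max_len) len = max_len;
        if (unif_rand() < 0.5) {       // insertion after position p
          std::string ins(len, 'A');
          for (int q = 0; q < len; ++q)
            ins[q] = bases[(int)(unif_rand() * 4) % 4];
          s.insert(p + 1, ins);
        } else {                       // deletion starting at position p
          int last = std::min(p + len, (int)s.size());
          if (last - p < (int)s.size()) s.erase(p, last - p);
        }
      }
    }
    if (s.empty()) s = as<std::string>(parents[i]).substr(0, 1);
    out[i] = s;
  }
  return out;
}
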