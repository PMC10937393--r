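#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Classification of single-end amplicon reads against a ladder of reference
// sequences U + unit^i + P (i = i_min..i_max). The score is the semi-global
// ("infix") edit distance: the read is aligned end to end, the reference may
// be entered and left anywhere, unit costs for mismatch and gap, and N in a
// read mismatches everything. Distances are computed exactly for every
// ladder member with the bit-parallel Myers DP (the algorithm behind edlib),
// one column per reference base, so a read costs O(ref length * m/64) words.
//
// All ladder members share the prefix U + unit^i_max column by column, so a
// single sweep over that trunk serves every member: the DP state is
// snapshotted at column |U| + 3*i and resumed into the shared suffix P for
// member i. This is exactly the full per-member DP, merely deduplicated.

namespace {

const uint64_t ONE = 1;

char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) c = comp_base(c);
  return out;
}

int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1; // N: matches nothing
  }
}

// Bit-parallel column state for one read: W words per vertical delta vector.
struct MyersState {
  std::vector<uint64_t> Pv, Mv;
  int score; // D[m][current column]
};

class MyersScanner {
public:
  MyersScanner(const std::string& U, const std::string& unit,
               const std::string& P, int i_min, int i_max)
      : U_(U), P_(P), i_min_(i_min), i_max_(i_max) {
    trunk_ref_ = U_;
    for (int r = 0; r < i_max_; ++r) trunk_ref_ += unit;
    len_u_ = (int)U_.size();
  }

  int len_upstream() const { return len_u_; }

  // exact semi-global edit distance of the read against every ladder
  // member, in member order i_min..i_max
  std::vector<int> member_costs(const std::string& rd) {
    const int m = (int)rd.size();
    W_ = (m + 63) / 64;
    last_bit_ = ONE << ((m - 1) & 63);
    last_block_ = (m - 1) / 64;
    build_peq(rd, m);

    MyersState st;
    st.Pv.assign(W_, ~(uint64_t)0);
    st.Mv.assign(W_, 0);
    st.score = m;

    const int n_members = i_max_ - i_min_ + 1;
    std::vector<MyersState> snap(n_members);
    std::vector<int> trunk_min(n_members);

    int run_min = st.score;
    int next_member = 0;
    // trunk sweep with snapshots at columns |U| + 3*i
    for (int j = 0; j < (int)trunk_ref_.size(); ++j) {
      advance_column(st, trunk_ref_[j]);
      run_min = std::min(run_min, st.score);
      while (next_member < n_members &&
             len_u_ + 3 * (i_min_ + next_member) == j + 1) {
        snap[next_member] = st;
        trunk_min[next_member] = run_min;
        ++next_member;
      }
    }
    // resume each member into the shared suffix P
    std::vector<int> costs(n_members);
    for (int t = 0; t < n_members; ++t) {
      MyersState bs = snap[t];
      int best = trunk_min[t];
      for (char c : P_) {
        advance_column(bs, c);
        best = std::min(best, bs.score);
      }
      costs[t] = best;
    }
    return costs;
  }

private:
  void build_peq(const std::string& rd, int m) {
    for (int b = 0; b < 4; ++b) peq_[b].assign(W_, 0);
    for (int i = 0; i < m; ++i) {
      const int b = base_index(rd[i]);
      if (b >= 0) peq_[b][i / 64] |= ONE << (i & 63);
    }
  }

  // one Myers column over text char c; free text start (row 0 stays 0)
  void advance_column(MyersState& st, char c) {
    const int b = base_index(c);
    int hin = 0; // semi-global: no penalty for entering the text here
    for (int w = 0; w < W_; ++w) {
      uint64_t Eq = b >= 0 ? peq_[b][w] : 0;
      uint64_t Pv = st.Pv[w], Mv = st.Mv[w];
      const uint64_t Xv = Eq | Mv;
      if (hin < 0) Eq |= ONE;
      const uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      if (w == last_block_) {
        if (Ph & last_bit_) ++st.score;
        else if (Mh & last_bit_) --st.score;
      }
      const int hout = (Ph >> 63) ? 1 : ((Mh >> 63) ? -1 : 0);
      Ph <<= 1;
      Mh <<= 1;
      if (hin > 0) Ph |= ONE;
      else if (hin < 0) Mh |= ONE;
      st.Pv[w] = Mh | ~(Xv | Ph);
      st.Mv[w] = Ph & Xv;
      hin = hout;
    }
  }

  std::string U_, P_, trunk_ref_;
  int i_min_, i_max_, len_u_;
  int W_ = 0, last_block_ = 0;
  uint64_t last_bit_ = 0;
  std::vector<uint64_t> peq_[4];
};

} // namespace

// [[Rcpp::export]]
DataFrame assign_reads_cpp(CharacterVector reads, std::string upstream,
                           std::string unit, std::string post,
                           int i_min, int i_max, double max_error_frac,
                           int delta, int min_post_anchor) {
  const int n = reads.size();
  IntegerVector assigned_i(n, NA_INTEGER), best_score(n, NA_INTEGER),
      margin(n, NA_INTEGER);
  CharacterVector orientation(n, NA_STRING);
  IntegerVector reason(n);
  // reason codes: 0 ok, 1 tie, 2 max_error, 3 too_short, 4 invalid_chars,
  //               5 empty_read
  MyersScanner scanner(upstream, unit, post, i_min, i_max);

  for (int r = 0; r < n; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int m = (int)rd.size();
    if (m == 0) { reason[r] = 5; continue; }
    bool ok_chars = true;
    for (char c : rd)
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N') {
        ok_chars = false; break;
      }
    if (!ok_chars) { reason[r] = 4; continue; }

    const std::vector<int> fw = scanner.member_costs(rd);
    const std::vector<int> rv = scanner.member_costs(revcomp(rd));

    // two best over members (distinct repeat index), both orientations
    int best = INT_MAX, best_t = -1, second = INT_MAX;
    bool best_rev = false;
    for (int t = 0; t < (int)fw.size(); ++t) {
      const int v = std::min(fw[t], rv[t]);
      if (v < best) {
        if (best_t >= 0) second = best;
        best = v; best_t = t; best_rev = rv[t] < fw[t];
      } else if (v < second) {
        second = v;
      }
    }
    const int k = (int)std::ceil(max_error_frac * m - 1e-9);
    best_score[r] = best;
    if (second < INT_MAX) margin[r] = second - best;
    orientation[r] = best_rev ? "reverse" : "forward";
    const int bi = i_min + best_t;
    if (best > k) {
      reason[r] = 2;
    } else if (second - best < delta) {
      reason[r] = 1;
    } else if (m < scanner.len_upstream() + 3 * bi + min_post_anchor) {
      reason[r] = 3;
    } else {
      reason[r] = 0;
      assigned_i[r] = bi;
    }
  }
  return DataFrame::create(
      _["assigned_i"] = assigned_i, _["best_score"] = best_score,
      _["margin"] = margin, _["orientation"] = orientation,
      _["reason"] = reason, _["stringsAsFactors"] = false);
}
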