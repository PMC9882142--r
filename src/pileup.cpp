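// CIGAR-walking primitives shared by the SNP caller, the consensus
// polisher and the allele-support scorer. All coordinates are 0-based
// half-open on the alignment target; query sequences are expected in
// aligned (target-forward) orientation.

#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Iterate CIGAR ops, calling f(op, len, tpos, qpos) before advancing.
template <typename F>
static void walk_cigar(const std::string& cig, long tstart, F f) {
  long t = tstart, q = 0, len = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); continue; }
    f(c, len, t, q);
    switch (c) {
    case '=': case 'X': case 'M': t += len; q += len; break;
    case 'I': case 'S': q += len; break;
    case 'D': case 'N': t += len; break;
    default: break; // H consumes nothing here
    }
    len = 0;
  }
}

// Per-position base counts over a target of length target_len.
// Rows: A, C, G, T, deletion. M ops contribute to the query base.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup_counts(int target_len, IntegerVector starts,
                                CharacterVector cigars, CharacterVector qseqs) {
  IntegerMatrix counts(5, target_len);
  for (int i = 0; i < starts.size(); ++i) {
    std::string cig = as<std::string>(cigars[i]);
    std::string qs = as<std::string>(qseqs[i]);
    walk_cigar(cig, starts[i], [&](char op, long len, long t, long q) {
      if (op == '=' || op == 'X' || op == 'M') {
        for (long k = 0; k < len; ++k) {
          long tp = t + k;
          if (tp < 0 || tp >= target_len) continue;
          int b = base_index(qs[q + k]);
          if (b >= 0) counts(b, tp)++;
        }
      } else if (op == 'D') {
        for (long k = 0; k < len; ++k) {
          long tp = t + k;
          if (tp >= 0 && tp < target_len) counts(4, tp)++;
        }
      }
    });
  }
  return counts;
}

// Column-plurality consensus against a draft sequence.
// Returns per-draft-position consensus bases ("" = deleted), per-position
// coverage, junction spanning-read counts (length target_len + 1), and
// the raw interior insertion votes as parallel vectors (junction, unique
// inserted string, carrier count). Insertion acceptance is decided by the
// caller.
// [[Rcpp::export]]
List cpp_consensus(std::string draft, IntegerVector starts,
                   CharacterVector cigars, CharacterVector qseqs) {
  int L = draft.size();
  std::vector<std::array<int, 5>> counts(L, {0, 0, 0, 0, 0});
  std::vector<int> jcov(L + 2, 0); // junction coverage diff array
  std::map<long, std::map<std::string, int>> ins_votes;
  std::map<long, int> ins_carriers;

  for (int i = 0; i < starts.size(); ++i) {
    std::string cig = as<std::string>(cigars[i]);
    std::string qs = as<std::string>(qseqs[i]);
    long ts = starts[i], te = starts[i];
    walk_cigar(cig, starts[i], [&](char op, long len, long t, long q) {
      if (op == '=' || op == 'X' || op == 'M') {
        for (long k = 0; k < len; ++k) {
          long tp = t + k;
          if (tp < 0 || tp >= L) continue;
          int b = base_index(qs[q + k]);
          if (b >= 0) counts[tp][b]++;
        }
        te = t + len;
      } else if (op == 'D') {
        for (long k = 0; k < len; ++k) {
          long tp = t + k;
          if (tp >= 0 && tp < L) counts[tp][4]++;
        }
        te = t + len;
      } else if (op == 'I') {
        if (t > starts[i] && t < L) { // interior insertions only
          ins_votes[t][qs.substr(q, len)]++;
          ins_carriers[t]++;
        }
      }
    });
    // junctions strictly inside the aligned span
    long lo = starts[i] + 1, hi = te; // junction t spans (t-1, t)
    if (lo < hi) { jcov[lo]++; jcov[hi]--; }
  }
  for (int t = 1; t <= L; ++t) jcov[t] += jcov[t - 1];

  CharacterVector base(L);
  IntegerVector cov(L);
  static const char* letters = "ACGT";
  for (int p = 0; p < L; ++p) {
    int tot = 0, best = -1, bestc = -1;
    for (int b = 0; b < 5; ++b) tot += counts[p][b];
    cov[p] = tot;
    if (tot == 0) { base[p] = std::string(1, draft[p]); continue; }
    int draft_b = base_index(draft[p]);
    for (int b = 0; b < 5; ++b) {
      int c = counts[p][b];
      if (c > bestc || (c == bestc && b == draft_b)) { bestc = c; best = b; }
    }
    // prefer the draft base on exact ties
    if (draft_b >= 0 && counts[p][draft_b] == bestc) best = draft_b;
    base[p] = (best == 4) ? "" : std::string(1, letters[best]);
  }

  std::vector<int> ins_t, ins_n;
  std::vector<std::string> ins_seq;
  for (auto& kv : ins_votes) {
    for (auto& sv : kv.second) {
      ins_t.push_back((int)kv.first);
      ins_seq.push_back(sv.first);
      ins_n.push_back(sv.second);
    }
  }
  IntegerVector jc(L + 1);
  for (int t = 0; t <= L; ++t) jc[t] = jcov[t];
  IntegerVector delc(L);
  for (int p = 0; p < L; ++p) delc[p] = counts[p][4];
  return List::create(_["base"] = base, _["cov"] = cov, _["jcov"] = jc,
                      _["del"] = delc,
                      _["ins_t"] = wrap(ins_t), _["ins_seq"] = wrap(ins_seq),
                      _["ins_n"] = wrap(ins_n));
}

// Query base carried by each alignment at each requested target position.
// positions: sorted 0-based target positions. Returns long-form records
// (alignment index, position, base) where base is "-" for a deletion.
// [[Rcpp::export]]
DataFrame cpp_read_bases_at(IntegerVector starts, IntegerVector ends,
                            CharacterVector cigars, CharacterVector qseqs,
                            IntegerVector positions) {
  std::vector<int> out_aln, out_pos;
  std::vector<std::string> out_base;
  int np = positions.size();
  for (int i = 0; i < starts.size(); ++i) {
    // positions within [starts[i], ends[i])
    int lo = std::lower_bound(positions.begin(), positions.end(), starts[i]) - positions.begin();
    int hi = std::lower_bound(positions.begin(), positions.end(), ends[i]) - positions.begin();
    if (lo >= hi) continue;
    std::string cig = as<std::string>(cigars[i]);
    std::string qs = as<std::string>(qseqs[i]);
    int j = lo;
    walk_cigar(cig, starts[i], [&](char op, long len, long t, long q) {
      if (j >= hi) return;
      if (op == '=' || op == 'X' || op == 'M') {
        while (j < hi && positions[j] < t + len) {
          if (positions[j] >= t) {
            out_aln.push_back(i + 1);
            out_pos.push_back(positions[j]);
            out_base.push_back(std::string(1, qs[q + (positions[j] - t)]));
          }
          ++j;
        }
      } else if (op == 'D' || op == 'N') {
        while (j < hi && positions[j] < t + len) {
          if (positions[j] >= t) {
            out_aln.push_back(i + 1);
            out_pos.push_back(positions[j]);
            out_base.push_back("-");
          }
          ++j;
        }
      }
    });
    (void)np;
  }
  return DataFrame::create(_["aln"] = out_aln, _["pos"] = out_pos,
                           _["base"] = out_base,
                           _["stringsAsFactors"] = false);
}

// Project a target interval [win_start, win_end) into query coordinates
// (aligned orientation, relative to the start of the aligned query span).
// Returns c(q_lo, q_hi), or c(-1, -1) when the alignment does not fully
// span the window.
// [[Rcpp::export]]
IntegerVector cpp_project_interval(int tstart, int tend, std::string cigar,
                                   int win_start, int win_end) {
  if (win_start < tstart || win_end > tend) return IntegerVector::create(-1, -1);
  long q_lo = -1, q_hi = -1;
  walk_cigar(cigar, tstart, [&](char op, long len, long t, long q) {
    bool consumes_t = (op == '=' || op == 'X' || op == 'M' || op == 'D' || op == 'N');
    bool consumes_q = (op == '=' || op == 'X' || op == 'M');
    if (!consumes_t) return;
    long tn = t + len;
    if (q_lo < 0 && win_start >= t && win_start < tn)
      q_lo = consumes_q ? q + (win_start - t) : q;
    if (q_hi < 0 && win_end > t && win_end <= tn)
      q_hi = consumes_q ? q + (win_end - t) : q;
  });
  if (win_end == tend && q_hi < 0) {
    // window ends exactly at the alignment end
    long qspan = 0;
    walk_cigar(cigar, tstart, [&](char op, long len, long, long q) {
      if (op == '=' || op == 'X' || op == 'M') qspan = q + len;
    });
    q_hi = qspan;
  }
  if (q_lo < 0 || q_hi < 0 || q_hi < q_lo) return IntegerVector::create(-1, -1);
  return IntegerVector::create((int)q_lo, (int)q_hi);
}

// Banded unit-cost global alignment machinery for the mini-consensus:
// edit distances for medoid selection and a CIGAR traceback for
// column-wise polishing. Band is widened to cover the length difference;
// costs: match 0, mismatch/indel 1.

static inline long band_width(long n, long m, int band) {
  long b = band + std::labs(n - m);
  if (b < 8) b = 8;
  return b;
}

// [[Rcpp::export]]
IntegerVector cpp_edit_distance(CharacterVector a, std::string b, int band) {
  long m = b.size();
  IntegerVector out(a.size());
  for (int s = 0; s < a.size(); ++s) {
    std::string q = as<std::string>(a[s]);
    long n = q.size();
    long bw = band_width(n, m, band);
    long W = 2 * bw + 1;
    const int INF = 1 << 28;
    std::vector<int> prev(W, INF), cur(W, INF);
    // row 0: dp[0][j] = j for j in band
    for (long k = 0; k < W; ++k) {
      long j = k - bw;
      if (j >= 0 && j <= m) prev[k] = (int)j;
    }
    for (long i = 1; i <= n; ++i) {
      std::fill(cur.begin(), cur.end(), INF);
      for (long k = 0; k < W; ++k) {
        long j = i + k - bw;
        if (j < 0 || j > m) continue;
        int best = INF;
        if (j > 0 && prev[k] < INF) {
          int c = prev[k] + (q[i - 1] == b[j - 1] ? 0 : 1);
          if (c < best) best = c;
        }
        if (k + 1 < W && prev[k + 1] < INF) {
          int c = prev[k + 1] + 1; // consume query
          if (c < best) best = c;
        }
        if (k > 0 && cur[k - 1] < INF) {
          int c = cur[k - 1] + 1; // consume target
          if (c < best) best = c;
        }
        if (j == 0) { int c = (int)i; if (c < best) best = c; }
        cur[k] = best;
      }
      std::swap(prev, cur);
    }
    long kf = m - n + bw;
    out[s] = (kf >= 0 && kf < (long)W) ? prev[kf] : INF;
  }
  return out;
}

// Global banded alignment of `q` against `t`; returns a CIGAR over
// {M, I, D} with I consuming the query, as walk_cigar expects.
// [[Rcpp::export]]
std::string cpp_align_cigar(std::string q, std::string t, int band) {
  long n = q.size(), m = t.size();
  long bw = band_width(n, m, band);
  long W = 2 * bw + 1;
  const int INF = 1 << 28;
  std::vector<int> dp((n + 1) * W, INF);
  std::vector<unsigned char> dir((n + 1) * W, 255);
  auto at = [&](long i, long k) -> long { return i * W + k; };
  for (long k = 0; k < W; ++k) {
    long j = k - bw;
    if (j >= 0 && j <= m) { dp[at(0, k)] = (int)j; dir[at(0, k)] = 2; }
  }
  if (bw <= m) dir[at(0, bw)] = 255; // origin
  for (long i = 1; i <= n; ++i) {
    for (long k = 0; k < W; ++k) {
      long j = i + k - bw;
      if (j < 0 || j > m) continue;
      int best = INF; unsigned char d = 255;
      if (j >= 1 && dp[at(i - 1, k)] < INF) {
        int c = dp[at(i - 1, k)] + (q[i - 1] == t[j - 1] ? 0 : 1);
        if (c < best) { best = c; d = 0; }
      }
      if (k + 1 < W && dp[at(i - 1, k + 1)] < INF) {
        int c = dp[at(i - 1, k + 1)] + 1;
        if (c < best) { best = c; d = 1; } // I
      }
      if (k > 0 && dp[at(i, k - 1)] < INF) {
        int c = dp[at(i, k - 1)] + 1;
        if (c < best) { best = c; d = 2; } // D
      }
      dp[at(i, k)] = best; dir[at(i, k)] = d;
    }
  }
  // traceback
  long i = n, k = m - n + bw;
  std::string ops;
  while (i > 0 || (k - bw + i) > 0) {
    unsigned char d = dir[at(i, k)];
    if (d == 0) { ops.push_back('M'); i--; }
    else if (d == 1) { ops.push_back('I'); i--; k++; }
    else if (d == 2) { ops.push_back('D'); k--; }
    else break;
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cig;
  long run = 0; char cur = 0;
  for (char c : ops) {
    if (c == cur) { run++; continue; }
    if (run > 0) { cig += std::to_string(run); cig.push_back(cur); }
    cur = c; run = 1;
  }
  if (run > 0) { cig += std::to_string(run); cig.push_back(cur); }
  return cig;
}

// Indel ops of length >= min_len with their target coordinates.
// Returns (alignment index, tpos, len, type) where type is "I" or "D";
// for insertions the target interval is the point [tpos, tpos].
// [[Rcpp::export]]
DataFrame cpp_indel_ops(IntegerVector starts, CharacterVector cigars,
                        int min_len) {
  std::vector<int> out_aln, out_pos, out_len;
  std::vector<std::string> out_type;
  for (int i = 0; i < starts.size(); ++i) {
    std::string cig = as<std::string>(cigars[i]);
    walk_cigar(cig, starts[i], [&](char op, long len, long t, long) {
      if ((op == 'I' || op == 'D') && len >= min_len) {
        out_aln.push_back(i + 1);
        out_pos.push_back((int)t);
        out_len.push_back((int)len);
        out_type.push_back(std::string(1, op));
      }
    });
  }
  return DataFrame::create(_["aln"] = out_aln, _["tpos"] = out_pos,
                           _["len"] = out_len, _["type"] = out_type,
                           _["stringsAsFactors"] = false);
}
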