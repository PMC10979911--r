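// Exact k-mer voting quantifier.
//
// Both strands are indexed through canonical k-mers (lexicographic minimum of
// a k-mer and its reverse complement); k must be odd so a k-mer is never its
// own reverse complement. Reads vote with every valid k-mer; votes on a
// consistent diagonal (target offset minus read offset) localize the read on
// its target, so the 5'-most covered base is recovered exactly for error-free
// reads. Negative diagonals are reported as-is and wrapped by the R layer for
// circularly sampled reads.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Hit {
  int32_t seq;
  int32_t offset;
  bool fwd_is_canonical;  // canonical form equals the forward k-mer at offset
};

struct Index {
  int k;
  std::vector<std::string> names;
  std::vector<int> lengths;
  std::unordered_map<uint64_t, std::vector<Hit>> table;
};

// Enumerate canonical k-mers of s; cb(pos, canon, fwd_is_canonical).
template <typename F>
void for_each_kmer(const std::string& s, int k, F cb) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      bool fc = fwd <= rev;
      cb(i - k + 1, fc ? fwd : rev, fc);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  Index* idx = new Index();
  idx->k = k;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    idx->names.push_back(as<std::string>(names[s]));
    idx->lengths.push_back((int)seq.size());
    for_each_kmer(seq, k, [&](int pos, uint64_t canon, bool fc) {
      idx->table[canon].push_back(Hit{(int32_t)s, (int32_t)pos, fc});
    });
  }
  XPtr<Index> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".kmer_index_size")]]
double kmer_index_size(SEXP xp) {
  XPtr<Index> idx(xp);
  double n = 0;
  for (const auto& kv : idx->table) n += kv.second.size();
  return n;
}

// Query a single k-mer (for tests/diagnostics): returns target, offset and
// whether the stored occurrence matches the query in forward orientation.
// [[Rcpp::export(name = ".kmer_index_query")]]
DataFrame kmer_index_query(SEXP xp, std::string kmer) {
  XPtr<Index> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  std::vector<std::string> target;
  std::vector<int> offset;
  std::vector<bool> same_strand;
  for_each_kmer(kmer, idx->k, [&](int pos, uint64_t canon, bool fc) {
    (void)pos;
    auto it = idx->table.find(canon);
    if (it == idx->table.end()) return;
    for (const Hit& h : it->second) {
      target.push_back(idx->names[h.seq]);
      offset.push_back(h.offset);
      same_strand.push_back(h.fwd_is_canonical == fc);
    }
  });
  return DataFrame::create(_["target"] = target, _["offset"] = offset,
                           _["same_strand"] = same_strand,
                           _["stringsAsFactors"] = false);
}

// Assign reads by k-mer voting. min_votes is per read. Returns a list with
// per-read status (0 unassigned / 1 unique / 2 ambiguous) and a long table of
// (read, target, weight, position) for assigned reads.
// [[Rcpp::export(name = ".kmer_assign")]]
List kmer_assign(SEXP xp, CharacterVector reads, IntegerVector min_votes) {
  XPtr<Index> idx(xp);
  const int k = idx->k;
  const int n_reads = reads.size();
  IntegerVector status(n_reads);
  std::vector<int> out_read, out_target, out_pos;
  std::vector<double> out_weight;

  // votes per (target, orientation); per-diagonal tallies carry the vote
  // count and the smallest matched target offset (soft-clip semantics: the
  // reported position is the 5'-most MATCHED base, so unmatched read
  // prefixes — errors, chimeric junctions — never extend the placement)
  struct DiagTally { int count = 0; int64_t min_off = INT64_MAX; };
  std::unordered_map<uint64_t, int> votes;
  std::unordered_map<uint64_t, std::unordered_map<int64_t, DiagTally>> diags;

  for (int r = 0; r < n_reads; ++r) {
    votes.clear();
    diags.clear();
    std::string read = as<std::string>(reads[r]);
    const int L = (int)read.size();
    for_each_kmer(read, k, [&](int pos, uint64_t canon, bool fc) {
      auto it = idx->table.find(canon);
      if (it == idx->table.end()) return;
      for (const Hit& h : it->second) {
        bool same = (h.fwd_is_canonical == fc);
        uint64_t key = ((uint64_t)h.seq << 1) | (same ? 0 : 1);
        // same orientation: read start = offset - pos
        // opposite: read start (leftmost base) = offset - (L - k - pos)
        int64_t d = same ? (int64_t)h.offset - pos
                         : (int64_t)h.offset + pos;  // = start + L - k
        votes[key]++;
        DiagTally& t = diags[key][d];
        t.count++;
        if ((int64_t)h.offset < t.min_off) t.min_off = h.offset;
      }
    });
    int best = 0;
    for (const auto& kv : votes) if (kv.second > best) best = kv.second;
    if (best < std::max(1, (int)min_votes[r]) || best == 0) {
      status[r] = 0;
      continue;
    }
    // collect distinct targets achieving the best vote count
    std::vector<uint64_t> winners;
    std::vector<int> winner_targets;
    for (const auto& kv : votes) {
      if (kv.second == best) {
        int tgt = (int)(kv.first >> 1);
        bool seen = false;
        for (int t : winner_targets) if (t == tgt) { seen = true; break; }
        if (!seen) {
          winners.push_back(kv.first);
          winner_targets.push_back(tgt);
        }
      }
    }
    const int m = (int)winners.size();
    status[r] = (m == 1) ? 1 : 2;
    for (int w = 0; w < m; ++w) {
      uint64_t key = winners[w];
      // majority diagonal within the winning (target, orientation);
      // position = leftmost matched target base on that diagonal
      int64_t best_d = 0, best_off = 0;
      int best_dc = -1;
      for (const auto& dv : diags[key]) {
        if (dv.second.count > best_dc ||
            (dv.second.count == best_dc && dv.first < best_d)) {
          best_dc = dv.second.count;
          best_d = dv.first;
          best_off = dv.second.min_off;
        }
      }
      out_read.push_back(r + 1);
      out_target.push_back((int)(key >> 1) + 1);
      out_weight.push_back(1.0 / m);
      out_pos.push_back((int)best_off);
    }
  }
  return List::create(_["status"] = status,
                      _["read"] = wrap(out_read),
                      _["target"] = wrap(out_target),
                      _["weight"] = wrap(out_weight),
                      _["position"] = wrap(out_pos));
}
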