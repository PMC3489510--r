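// Greedy identity-threshold clustering kernel.
//
// Identity between two contigs is gap-free containment identity: the maximum,
// over all ungapped placements (offsets) of the shorter sequence within the
// longer, of the number of matching bases divided by the shorter length.
// Positions where either base is N never count as matches. With bothStrands,
// the reverse complement of the shorter sequence is also considered.
//
// The clustering loop evaluates, for each contig, candidate representatives
// via word-seeded diagonals: only offsets on which the two sequences share an
// exact word of length w_seed are scored. With
//   m_max  = floor(S * (1 - c))          (max non-matching positions allowed)
//   w_pair = ceil((S - m_max) / (m_max + 1))
// any offset reaching identity >= c must contain a run of at least w_pair
// consecutive matching (non-N) bases, hence a shared word of length
// min(wordSize, w_pair, 12). Seeded evaluation is therefore exact for the
// >= c decision and for the identity recorded for merged members; disabling
// the prefilter (scoring every offset) gives identical results.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int SEED_CAP = 12;

static inline char complement(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = complement(c);
  return r;
}

static inline int base_code(char b) {
  switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N
  }
}

// matches of sh placed at offset off within lo
static int diag_matches(const std::string& sh, const std::string& lo, int off) {
  int m = 0;
  const int S = (int)sh.size();
  for (int i = 0; i < S; ++i) {
    const char a = sh[i], b = lo[off + i];
    if (a != 'N' && b != 'N' && a == b) ++m;
  }
  return m;
}

// exhaustive: best matches over every offset
static int best_matches_full(const std::string& sh, const std::string& lo) {
  const int noff = (int)lo.size() - (int)sh.size() + 1;
  int best = 0;
  for (int o = 0; o < noff; ++o) {
    const int m = diag_matches(sh, lo, o);
    if (m > best) best = m;
  }
  return best;
}

// seeded: score only offsets sharing a clean w-mer
static int best_matches_seeded(const std::string& sh, const std::string& lo, int w) {
  const int S = (int)sh.size(), L = (int)lo.size();
  if (w < 1) w = 1;
  if (w > SEED_CAP) w = SEED_CAP;
  if (S < w) return best_matches_full(sh, lo);

  const uint64_t mask = (1ULL << (2 * w)) - 1;
  std::unordered_map<uint64_t, std::vector<int>> seeds;
  uint64_t h = 0;
  int run = 0;
  for (int i = 0; i < S; ++i) {
    const int c = base_code(sh[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= w) seeds[h].push_back(i - w + 1);
  }

  const int noff = L - S + 1;
  std::unordered_map<int, bool> offsets;
  h = 0; run = 0;
  for (int j = 0; j < L; ++j) {
    const int c = base_code(lo[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= w) {
      auto it = seeds.find(h);
      if (it != seeds.end()) {
        const int js = j - w + 1;
        for (int i : it->second) {
          const int off = js - i;
          if (off >= 0 && off < noff) offsets[off] = true;
        }
      }
    }
  }

  int best = 0;
  for (auto& kv : offsets) {
    const int m = diag_matches(sh, lo, kv.first);
    if (m > best) best = m;
  }
  return best;
}

// seed word length guaranteeing exactness for the >= c decision
static int seed_width(int S, double c, int wordSize) {
  const int m_max = (int)std::floor((double)S * (1.0 - c) + 1e-9);
  int w_pair;
  if (m_max <= 0) {
    w_pair = S;  // exact containment: the whole shorter sequence must match
  } else {
    w_pair = S / (m_max + 1);  // == ceil((S - m_max) / (m_max + 1))
  }
  if (w_pair < 1) w_pair = 1;
  int w = wordSize < w_pair ? wordSize : w_pair;
  if (w > SEED_CAP) w = SEED_CAP;
  return w;
}

// [[Rcpp::export(name = ".cppPairIdentity")]]
double cppPairIdentity(std::string a, std::string b, bool bothStrands) {
  const std::string& sh = (a.size() <= b.size()) ? a : b;
  const std::string& lo = (a.size() <= b.size()) ? b : a;
  if (sh.empty()) return 0.0;
  int best = best_matches_full(sh, lo);
  if (bothStrands) {
    const int b2 = best_matches_full(revcomp(sh), lo);
    if (b2 > best) best = b2;
  }
  return (double)best / (double)sh.size();
}

// Word index over the representatives created so far: word -> (repPos, pos).
// repPos is the representative's creation-order position, which is also the
// first-fit scan order.
struct RepIndex {
  int w;
  uint64_t mask;
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;

  explicit RepIndex(int w_) : w(w_), mask((1ULL << (2 * w_)) - 1) {}

  void add(const std::string& s, int repPos) {
    uint64_t h = 0;
    int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      const int c = base_code(s[j]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= w) map[h].emplace_back(repPos, j - w + 1);
    }
  }

  // candidate (offset, strand) lists per repPos, gathered from the query's
  // clean w-mers; lens[repPos] is needed to bound offsets
  void gather(const std::string& q, bool rc,
              const std::vector<int>& repLen, int qLen,
              std::map<int, std::vector<std::pair<int, bool>>>& out) const {
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < (int)q.size(); ++i) {
      const int c = base_code(q[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= w) {
        auto it = map.find(h);
        if (it == map.end()) continue;
        const int qs = i - w + 1;
        for (auto& pr : it->second) {
          const int off = pr.second - qs;
          if (off >= 0 && off <= repLen[pr.first] - qLen) {
            out[pr.first].emplace_back(off, rc);
          }
        }
      }
    }
  }
};

// Sequences must arrive sorted by decreasing length (ties by id, done in R).
// Returns for each contig the 1-based index of its representative (self for
// representatives) and the identity to it (1.0 for representatives).
// [[Rcpp::export(name = ".cppGreedyCluster")]]
List cppGreedyCluster(CharacterVector seqs, double c, int wordSize,
                      bool bothStrands, bool prefilter) {
  const int n = seqs.size();
  std::vector<std::string> S(n), RC(n);
  for (int i = 0; i < n; ++i) {
    S[i] = as<std::string>(seqs[i]);
    if (bothStrands) RC[i] = revcomp(S[i]);
  }

  int idxW = wordSize > SEED_CAP ? SEED_CAP : wordSize;
  RepIndex index(idxW);
  std::vector<int> reps;      // contig index per repPos
  std::vector<int> repLen;    // length per repPos
  IntegerVector repOf(n);
  NumericVector ident(n);
  LogicalVector tooShort(n);

  for (int i = 0; i < n; ++i) {
    const int len = (int)S[i].size();
    int joined = -1;
    double joinedId = 0.0;

    if (len >= wordSize) {
      const double need = c * (double)len - 1e-9;
      const int w = seed_width(len, c, wordSize);
      if (prefilter && w >= idxW) {
        // the guaranteed clean run is at least idxW long, so every offset
        // reaching identity >= c is seeded in the representative index
        std::map<int, std::vector<std::pair<int, bool>>> cand;
        index.gather(S[i], false, repLen, len, cand);
        if (bothStrands) index.gather(RC[i], true, repLen, len, cand);
        for (auto& kv : cand) {  // std::map iterates repPos ascending = first-fit order
          const int r = reps[kv.first];
          int best = 0;
          std::vector<std::pair<int, bool>>& offs = kv.second;
          std::sort(offs.begin(), offs.end());
          offs.erase(std::unique(offs.begin(), offs.end()), offs.end());
          for (auto& ob : offs) {
            const int m = diag_matches(ob.second ? RC[i] : S[i], S[r], ob.first);
            if (m > best) best = m;
          }
          if ((double)best >= need) {
            joined = r;
            joinedId = (double)best / (double)len;
            break;
          }
        }
      } else {
        // short query (guaranteed run below the index word) or prefilter off:
        // scan representatives in creation order
        for (int r : reps) {
          // reps are never shorter than S[i] (input sorted by length)
          int m = prefilter ? best_matches_seeded(S[i], S[r], w)
                            : best_matches_full(S[i], S[r]);
          if (bothStrands) {
            const int m2 = prefilter ? best_matches_seeded(RC[i], S[r], w)
                                     : best_matches_full(RC[i], S[r]);
            if (m2 > m) m = m2;
          }
          if ((double)m >= need) {
            joined = r;
            joinedId = (double)m / (double)len;
            break;  // first fit
          }
        }
      }
    } else {
      tooShort[i] = true;  // shorter than the word size: own representative
    }

    if (joined >= 0) {
      repOf[i] = joined + 1;
      ident[i] = joinedId;
    } else {
      index.add(S[i], (int)reps.size());
      reps.push_back(i);
      repLen.push_back(len);
      repOf[i] = i + 1;
      ident[i] = 1.0;
    }
  }

  return List::create(_["rep_of"] = repOf, _["identity"] = ident,
                      _["too_short"] = tooShort);
}
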