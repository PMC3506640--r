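// Semiglobal (free end-gap) overlap alignment and the greedy
// overlap-consensus assembler. Alignment identity is computed over the
// aligned overlap columns with internal gaps counted as mismatches; end
// overhangs are not part of the overlap.
#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <queue>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

const int MATCH = 1, MISMATCH = -1, GAP = -2;
const int NEG = INT_MIN / 4;

inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return 4;
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) c = comp(c);
  return r;
}

struct Aln {
  int score = NEG;
  int cols = 0;        // alignment columns in the overlap region
  int matches = 0;
  int a_start = 0, a_end = 0;  // 0-based half-open on a
  int b_start = 0, b_end = 0;  // 0-based half-open on b
  bool ok = false;
  std::vector<uint8_t> path;   // 1 diag, 2 up (consume a), 3 left (consume b)
};

// Semiglobal DP restricted to diagonals d = j - i in [dlo, dhi].
// Free leading/trailing gaps on both sequences; the best end is scanned
// over the last row and last column, ties resolved toward the earlier
// (smaller i, then smaller j) end cell for determinism.
Aln semiglobal(const std::string& a, const std::string& b,
               int dlo, int dhi, bool want_path) {
  const int la = static_cast<int>(a.size());
  const int lb = static_cast<int>(b.size());
  Aln out;
  if (la == 0 || lb == 0) return out;
  if (dlo < -la) dlo = -la;
  if (dhi > lb) dhi = lb;
  if (dlo > dhi) return out;
  const int bw = dhi - dlo + 1;
  const int INVALID = NEG / 2;  // anything below this is unreachable

  std::vector<int8_t> ea(la), eb(lb);
  for (int i = 0; i < la; ++i) ea[i] = static_cast<int8_t>(enc(a[i]));
  for (int j = 0; j < lb; ++j) eb[j] = static_cast<int8_t>(enc(b[j]));

  // rows padded with one sentinel on each side so neighbour lookups
  // never branch on band boundaries
  std::vector<int> prev(bw + 2, NEG), cur(bw + 2, NEG);
  std::vector<uint8_t> tb(static_cast<size_t>(la + 1) * bw, 0);

  int best = NEG, bi = 0, bj = 0;
  for (int j = std::max(0, dlo); j <= std::min(lb, dhi); ++j) {
    prev[j - dlo + 1] = 0;  // row 0: b's head unaligned
    if (j == lb) { best = 0; bi = 0; bj = lb; }
  }

  for (int i = 1; i <= la; ++i) {
    const int off = i + dlo;  // j = off + idx
    int jlo = std::max(0, off), jhi = std::min(lb, i + dhi);
    std::fill(cur.begin(), cur.end(), NEG);
    if (jlo > jhi) { std::swap(prev, cur); continue; }
    uint8_t* tbrow = &tb[static_cast<size_t>(i) * bw];
    const int eai = ea[i - 1];
    int j = jlo;
    if (j == 0) {  // a's head unaligned
      cur[0 - off + 1] = 0;
      tbrow[0 - off] = 0;
      ++j;
    }
    for (; j <= jhi; ++j) {
      const int idx = j - off;
      int s = prev[idx + 1] +
              ((eb[j - 1] == eai && eai < 4) ? MATCH : MISMATCH);
      uint8_t p = 1;
      const int su = prev[idx + 2] + GAP;
      if (su > s) { s = su; p = 2; }
      const int sl = cur[idx] + GAP;
      if (sl > s) { s = sl; p = 3; }
      cur[idx + 1] = s;
      tbrow[idx] = p;
    }
    if (jhi == lb) {  // last column is a free end
      int s = cur[lb - off + 1];
      if (s > best && s > INVALID) { best = s; bi = i; bj = lb; }
    }
    std::swap(prev, cur);
  }
  // free end anywhere on the last row
  {
    const int off = la + dlo;
    int jlo = std::max(0, off), jhi = std::min(lb, la + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      int s = prev[j - off + 1];
      if (s > best && s > INVALID) { best = s; bi = la; bj = j; }
    }
  }
  if (best <= INVALID) return out;

  int i = bi, j = bj, cols = 0, matches = 0;
  std::vector<uint8_t> path;
  while (i > 0 && j > 0) {
    uint8_t p = tb[static_cast<size_t>(i) * bw + (j - (i + dlo))];
    if (p == 0) break;
    if (want_path) path.push_back(p);
    ++cols;
    if (p == 1) {
      int ea = enc(a[i - 1]), eb = enc(b[j - 1]);
      if (ea == eb && ea < 4) ++matches;
      --i; --j;
    } else if (p == 2) {
      --i;
    } else {
      --j;
    }
  }
  if (want_path) std::reverse(path.begin(), path.end());
  out.score = best;
  out.cols = cols;
  out.matches = matches;
  out.a_start = i; out.a_end = bi;
  out.b_start = j; out.b_end = bj;
  out.ok = true;
  out.path = std::move(path);
  return out;
}

inline Aln semiglobal_full(const std::string& a, const std::string& b,
                           bool want_path = false) {
  return semiglobal(a, b, -static_cast<int>(a.size()),
                    static_cast<int>(b.size()), want_path);
}

// Most-voted shared k-mer diagonal (d = pos_b - pos_a). Returns the vote
// count; 0 if the sequences share no k-mer.
int kmer_best_diag(const std::string& a, const std::string& b, int k,
                   int& best_diag) {
  std::unordered_multimap<uint32_t, int> idx;
  const uint32_t mask =
      (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
  uint32_t key = 0;
  int run = 0;
  for (int i = 0; i < static_cast<int>(a.size()); ++i) {
    int e = enc(a[i]);
    if (e > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | static_cast<uint32_t>(e)) & mask;
    if (++run >= k) idx.emplace(key, i - k + 1);
  }
  std::unordered_map<int, int> votes;
  key = 0; run = 0;
  for (int j = 0; j < static_cast<int>(b.size()); ++j) {
    int e = enc(b[j]);
    if (e > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | static_cast<uint32_t>(e)) & mask;
    if (++run >= k) {
      auto r = idx.equal_range(key);
      for (auto it = r.first; it != r.second; ++it)
        ++votes[(j - k + 1) - it->second];
    }
  }
  int bestv = 0;
  best_diag = 0;
  for (const auto& kv : votes) {
    if (kv.second > bestv ||
        (kv.second == bestv && bestv > 0 && kv.first < best_diag)) {
      bestv = kv.second;
      best_diag = kv.first;
    }
  }
  return bestv;
}

List aln_to_list(const Aln& r, bool rc) {
  double id = (r.cols > 0) ? 100.0 * r.matches / r.cols : NA_REAL;
  return List::create(
      _["ok"] = r.ok, _["score"] = r.score, _["length"] = r.cols,
      _["matches"] = r.matches, _["identity"] = id,
      _["a_start"] = r.a_start + 1, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start + 1, _["b_end"] = r.b_end,
      _["reverse"] = rc);
}

}  // namespace

// [[Rcpp::export]]
List cpp_overlap_align(std::string a, std::string b, int band = -1) {
  Aln r;
  if (band < 0) {
    r = semiglobal_full(a, b);
  } else {
    int d = 0;
    if (kmer_best_diag(a, b, 12, d) == 0)
      return List::create(_["ok"] = false);
    r = semiglobal(a, b, d - band, d + band, false);
  }
  return aln_to_list(r, false);
}

// Best overlap over both orientations of b, chosen by alignment score
// (ties go to the forward orientation).
// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int band = -1) {
  Aln fw, rv;
  std::string brc = revcomp_str(b);
  if (band < 0) {
    fw = semiglobal_full(a, b);
    rv = semiglobal_full(a, brc);
  } else {
    int d = 0;
    if (kmer_best_diag(a, b, 12, d) > 0)
      fw = semiglobal(a, b, d - band, d + band, false);
    if (kmer_best_diag(a, brc, 12, d) > 0)
      rv = semiglobal(a, brc, d - band, d + band, false);
  }
  if (!fw.ok && !rv.ok) return List::create(_["ok"] = false);
  bool use_rv = rv.ok && (!fw.ok || rv.score > fw.score);
  return aln_to_list(use_rv ? rv : fw, use_rv);
}

// Best reference for each query by percent identity of the maximal-score
// semiglobal alignment, both orientations, with a minimum-coverage guard
// (overlap must span at least min_cover of the shorter sequence).
// References must be supplied in the tie-break order (lexicographic ids);
// earlier references win ties.
// [[Rcpp::export]]
DataFrame cpp_best_reference(CharacterVector queries, CharacterVector refs,
                             double min_cover = 0.5, int band = -1,
                             int vote_min = 2) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rf(nr), rrc(nr);
  for (int r = 0; r < nr; ++r) {
    rf[r] = as<std::string>(refs[r]);
    rrc[r] = revcomp_str(rf[r]);
  }
  IntegerVector ref_index(nq, NA_INTEGER), q_start(nq, NA_INTEGER),
      q_end(nq, NA_INTEGER);
  NumericVector identity(nq, NA_REAL);
  CharacterVector orientation(nq, NA_STRING);
  for (int q = 0; q < nq; ++q) {
    std::string Q = as<std::string>(queries[q]);
    double bid = -1.0;
    int bref = -1, bqs = 0, bqe = 0;
    bool brc = false;
    // two rounds at most: banded (when requested), then a full-DP
    // fallback for queries the prescreen could not place at all
    for (int round = 0; round < 2 && bref < 0; ++round) {
      bool full = (band < 0) || round == 1;
      for (int r = 0; r < nr; ++r) {
        int minlen = std::min(Q.size(), rf[r].size());
        for (int o = 0; o < 2; ++o) {
          const std::string& R = o ? rrc[r] : rf[r];
          Aln al;
          if (full) {
            al = semiglobal_full(Q, R);
          } else {
            int d = 0;
            if (kmer_best_diag(Q, R, 12, d) < vote_min) continue;
            al = semiglobal(Q, R, d - band, d + band, false);
          }
          if (!al.ok || al.cols == 0) continue;
          if (al.cols < min_cover * minlen) continue;
          double id = 100.0 * al.matches / al.cols;
          if (id > bid + 1e-9) {
            bid = id; bref = r; bqs = al.a_start; bqe = al.a_end; brc = o;
          }
        }
      }
      if (band < 0) break;
    }
    if (q % 64 == 0) Rcpp::checkUserInterrupt();
    if (bref >= 0) {
      ref_index[q] = bref + 1;
      identity[q] = bid;
      q_start[q] = bqs + 1;
      q_end[q] = bqe;
      orientation[q] = brc ? "-" : "+";
    }
  }
  return DataFrame::create(
      _["ref_index"] = ref_index, _["identity"] = identity,
      _["q_start"] = q_start, _["q_end"] = q_end,
      _["orientation"] = orientation, _["stringsAsFactors"] = false);
}

namespace {

struct Node {
  bool alive = true;
  std::vector<int> members;                 // read indices (0-based)
  std::vector<std::array<int, 5>> counts;   // A C G T gap votes per column
  std::string cons;
  std::vector<int> cand;                    // candidate partner nodes
  int key = 0;                              // smallest member read index
};

struct Edge {
  double identity;
  int ovl;
  int key1, key2;
  int na, nb;
  bool rc;
  int diag;
};

struct EdgeCmp {
  bool operator()(const Edge& x, const Edge& y) const {
    if (x.identity != y.identity) return x.identity < y.identity;
    if (x.ovl != y.ovl) return x.ovl < y.ovl;
    if (x.key1 != y.key1) return x.key1 > y.key1;
    return x.key2 > y.key2;
  }
};

std::string counts_consensus(const std::vector<std::array<int, 5>>& counts) {
  // Majority vote per column; base ties broken A<C<G<T; a gap (deletion)
  // vote must strictly exceed the best base to drop the column.
  std::string s;
  s.reserve(counts.size());
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (const auto& c : counts) {
    int bi = 0;
    for (int x = 1; x < 4; ++x)
      if (c[x] > c[bi]) bi = x;
    if (c[4] > c[bi]) continue;
    if (c[bi] > 0) s.push_back(bases[bi]);
  }
  return s;
}

std::vector<std::array<int, 5>> flip_counts(
    const std::vector<std::array<int, 5>>& counts) {
  std::vector<std::array<int, 5>> out(counts.rbegin(), counts.rend());
  for (auto& c : out) {
    std::swap(c[0], c[3]);
    std::swap(c[1], c[2]);
  }
  return out;
}

inline int col_cover(const std::vector<std::array<int, 5>>& counts, int j) {
  if (counts.empty()) return 0;
  j = std::max(0, std::min(j, static_cast<int>(counts.size()) - 1));
  const auto& c = counts[j];
  return c[0] + c[1] + c[2] + c[3] + c[4];
}

// Reusable k-mer index over one sequence (forward strand).
struct KIndex {
  int k;
  uint32_t mask;
  std::unordered_map<uint32_t, std::vector<int>> map;
  void build(const std::string& s, int k_) {
    k = k_;
    mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
    map.clear();
    uint32_t key = 0;
    int run = 0;
    for (int i = 0; i < static_cast<int>(s.size()); ++i) {
      int e = enc(s[i]);
      if (e > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | static_cast<uint32_t>(e)) & mask;
      if (++run >= k) map[key].push_back(i - k + 1);
    }
  }
  // Most-voted diagonal (pos_b - pos_a) of b against this index.
  int scan(const std::string& b, int& best_diag) const {
    std::unordered_map<int, int> votes;
    uint32_t key = 0;
    int run = 0;
    for (int j = 0; j < static_cast<int>(b.size()); ++j) {
      int e = enc(b[j]);
      if (e > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | static_cast<uint32_t>(e)) & mask;
      if (++run >= k) {
        auto it = map.find(key);
        if (it == map.end()) continue;
        for (int pa : it->second) ++votes[(j - k + 1) - pa];
      }
    }
    int bestv = 0;
    best_diag = 0;
    for (const auto& kv : votes) {
      if (kv.second > bestv ||
          (kv.second == bestv && bestv > 0 && kv.first < best_diag)) {
        bestv = kv.second;
        best_diag = kv.first;
      }
    }
    return bestv;
  }
};

}  // namespace

// Greedy overlap-consensus assembly. Reads must arrive sorted in the
// lexicographic order of their ids; ties in edge priority fall back to
// that order. Merging is globally best-first by (identity, overlap
// length, smallest member index); consensus is recomputed by majority
// vote after every merge. A pair qualifies when overlap identity >= mi
// and overlap length >= ml. When exhaustive = true all pairs are
// aligned with a full DP; otherwise candidates come from a shared-k-mer
// prescreen and alignments are banded around the voted diagonal.
// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int ml, double mi,
                  bool exhaustive = false, int k = 12, int band = 16,
                  int vote_min = 3) {
  const int n = reads.size();
  std::vector<Node> nodes;
  nodes.reserve(2 * static_cast<size_t>(std::max(n, 1)));
  for (int i = 0; i < n; ++i) {
    Node nd;
    nd.members = {i};
    nd.key = i;
    nd.cons = as<std::string>(reads[i]);
    nd.counts.resize(nd.cons.size());
    for (size_t p = 0; p < nd.cons.size(); ++p) {
      nd.counts[p] = {0, 0, 0, 0, 0};
      int e = enc(nd.cons[p]);
      if (e < 4) nd.counts[p][e] = 1;
    }
    nodes.push_back(std::move(nd));
  }

  std::vector<int> fwd(2 * static_cast<size_t>(std::max(n, 1)), -1);
  std::priority_queue<Edge, std::vector<Edge>, EdgeCmp> heap;

  auto push_edge = [&](int ia, int ib, double id, int cols, bool rc,
                       int diag) {
    Edge e;
    e.identity = id;
    e.ovl = cols;
    e.key1 = std::min(nodes[ia].key, nodes[ib].key);
    e.key2 = std::max(nodes[ia].key, nodes[ib].key);
    e.na = ia; e.nb = ib;
    e.rc = rc;
    e.diag = diag;
    heap.push(e);
  };

  // A pair whose shared-k-mer density over the estimated overlap is far
  // below what identity >= mi requires cannot qualify: at identity p a
  // fraction ~p^k of k-mer seeds survives, so the vote density for a
  // qualifying pair concentrates near (mi/100)^k and pairs well below a
  // generous margin of it are skipped without alignment.
  const double vote_density_min = 0.75 * std::pow(mi / 100.0, k);
  auto est_overlap = [](int la, int lb, int d) {
    return std::min(la, lb - d) - std::max(0, -d);
  };

  // Banded evaluation of one pair given the voted diagonals per
  // orientation. Returns true while the pair stays a live candidate:
  // qualifying now, no detectable overlap yet (it may appear as contigs
  // extend), or an overlap still shorter than ml. A decisive overlap
  // (>= ml) below the identity floor rules the pair out for good.
  auto eval_oriented = [&](int ia, int ib, int vf, int df, int vr,
                           int dr) -> bool {
    const Node& A = nodes[ia];
    const Node& B = nodes[ib];
    const int la = static_cast<int>(A.cons.size());
    const int lb = static_cast<int>(B.cons.size());
    if (vf < vote_min && vr < vote_min) return true;
    Aln best;
    bool rc = false;
    int bdiag = 0;
    bool aligned = false, undecided_short = false, decisively_bad = false;
    auto screen = [&](int v, int d) -> int {
      // 1 align, 0 undecided (short), -1 decisively bad
      if (v < vote_min) return 0;
      int ov = est_overlap(la, lb, d);
      if (ov < k) return 0;
      double density = static_cast<double>(v) /
                       std::max(ov - k + 1, 1);
      if (density >= vote_density_min) return 1;
      return (ov >= ml) ? -1 : 0;
    };
    int sf = screen(vf, df);
    int sr = screen(vr, dr);
    if (sf == 1) {
      Aln f2 = semiglobal(A.cons, B.cons, df - band, df + band, false);
      if (f2.ok) { best = f2; bdiag = df; aligned = true; }
    } else if (sf == 0 && vf >= vote_min) {
      undecided_short = true;
    } else if (sf == -1) {
      decisively_bad = true;
    }
    if (sr == 1) {
      std::string brc = revcomp_str(B.cons);
      Aln r2 = semiglobal(A.cons, brc, dr - band, dr + band, false);
      if (r2.ok && (!best.ok || r2.score > best.score)) {
        best = r2; rc = true; bdiag = dr;
      }
      aligned = aligned || r2.ok;
    } else if (sr == 0 && vr >= vote_min) {
      undecided_short = true;
    } else if (sr == -1) {
      decisively_bad = true;
    }
    if (!aligned || !best.ok || best.cols == 0) {
      if (undecided_short) return true;
      if (decisively_bad) return false;
      return true;
    }
    double id = 100.0 * best.matches / best.cols;
    if (id + 1e-9 >= mi && best.cols >= ml) {
      push_edge(ia, ib, id, best.cols, rc, bdiag);
      return true;
    }
    return best.cols < ml || undecided_short;
  };

  // Full-DP evaluation (exhaustive mode).
  auto eval_exhaustive = [&](int ia, int ib) -> bool {
    const Node& A = nodes[ia];
    const Node& B = nodes[ib];
    Aln fw = semiglobal_full(A.cons, B.cons);
    Aln rv = semiglobal_full(A.cons, revcomp_str(B.cons));
    bool rc = rv.ok && (!fw.ok || rv.score > fw.score);
    const Aln& best = rc ? rv : fw;
    if (!best.ok || best.cols == 0) return false;
    double id = 100.0 * best.matches / best.cols;
    if (id + 1e-9 >= mi && best.cols >= ml) {
      push_edge(ia, ib, id, best.cols, rc, 0);
      return true;
    }
    return best.cols < ml;
  };

  // Initial candidate discovery.
  if (exhaustive) {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (eval_exhaustive(i, j)) {
          nodes[i].cand.push_back(j);
          nodes[j].cand.push_back(i);
        }
  } else {
    // Global k-mer index over all reads (forward strand); per read,
    // diagonal votes against every partner in both orientations.
    const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xffffffffu;
    std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
    for (int i = 0; i < n; ++i) {
      const std::string& s = nodes[i].cons;
      uint32_t key = 0;
      int run = 0;
      for (int p = 0; p < static_cast<int>(s.size()); ++p) {
        int e = enc(s[p]);
        if (e > 3) { run = 0; key = 0; continue; }
        key = ((key << 2) | static_cast<uint32_t>(e)) & mask;
        if (++run >= k) index[key].push_back({i, p - k + 1});
      }
    }
    const long long DOFF = 8192, DSPAN = 16384;
    for (int i = 0; i < n; ++i) {
      // votes keyed by ((j, orientation), diagonal)
      std::unordered_map<long long, int> votes;
      for (int o = 0; o < 2; ++o) {
        const std::string s =
            o ? revcomp_str(nodes[i].cons) : nodes[i].cons;
        uint32_t key = 0;
        int run = 0;
        for (int p = 0; p < static_cast<int>(s.size()); ++p) {
          int e = enc(s[p]);
          if (e > 3) { run = 0; key = 0; continue; }
          key = ((key << 2) | static_cast<uint32_t>(e)) & mask;
          if (++run >= k) {
            auto it = index.find(key);
            if (it == index.end()) continue;
            int pb = p - k + 1;
            for (const auto& hit : it->second) {
              if (hit.first <= i) continue;
              // diag convention: partner j is `a`, read i (in the
              // scanned orientation) is `b`; diag = pos_b - pos_a
              long long kk = (2LL * hit.first + o) * DSPAN +
                             (pb - hit.second + DOFF);
              ++votes[kk];
            }
          }
        }
      }
      // best diagonal per (partner, orientation)
      std::unordered_map<long long, std::pair<int, int>> best;  // v, diag
      for (const auto& kv : votes) {
        long long po = kv.first / DSPAN;
        int diag = static_cast<int>(kv.first % DSPAN - DOFF);
        auto& b = best[po];
        if (kv.second > b.first ||
            (kv.second == b.first && diag < b.second)) {
          b = {kv.second, diag};
        }
      }
      std::vector<long long> partners;
      partners.reserve(best.size());
      for (const auto& kv : best) partners.push_back(kv.first / 2);
      std::sort(partners.begin(), partners.end());
      partners.erase(std::unique(partners.begin(), partners.end()),
                     partners.end());
      for (long long j : partners) {
        int vf = 0, df = 0, vr = 0, dr = 0;
        auto itf = best.find(2 * j);
        if (itf != best.end()) { vf = itf->second.first; df = itf->second.second; }
        auto itr = best.find(2 * j + 1);
        if (itr != best.end()) { vr = itr->second.first; dr = itr->second.second; }
        if (vf < vote_min && vr < vote_min) continue;
        // pair orientation: node j as `a`, node i as `b`
        if (eval_oriented(static_cast<int>(j), i, vf, df, vr, dr)) {
          nodes[i].cand.push_back(static_cast<int>(j));
          nodes[j].cand.push_back(i);
        }
      }
      if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }

  auto resolve = [&](int x) {
    while (x >= 0 && !nodes[x].alive && fwd[x] >= 0) x = fwd[x];
    return x;
  };

  int iter = 0;
  while (!heap.empty()) {
    Edge e = heap.top();
    heap.pop();
    if (!nodes[e.na].alive || !nodes[e.nb].alive) continue;
    if (++iter % 32 == 0) Rcpp::checkUserInterrupt();

    // Nodes are immutable while alive, so the stored alignment geometry
    // is still current; recompute it (with path) to lay out columns.
    Node& A = nodes[e.na];
    Node& B = nodes[e.nb];
    std::string bcons = e.rc ? revcomp_str(B.cons) : B.cons;
    std::vector<std::array<int, 5>> bcounts =
        e.rc ? flip_counts(B.counts) : B.counts;
    Aln al = exhaustive
                 ? semiglobal_full(A.cons, bcons, true)
                 : semiglobal(A.cons, bcons, e.diag - band, e.diag + band,
                              true);
    if (!al.ok) continue;

    std::vector<std::array<int, 5>> mcounts;
    mcounts.reserve(A.counts.size() + bcounts.size());
    for (int i2 = 0; i2 < al.a_start; ++i2) mcounts.push_back(A.counts[i2]);
    for (int j2 = 0; j2 < al.b_start; ++j2) mcounts.push_back(bcounts[j2]);
    {
      int i2 = al.a_start, j2 = al.b_start;
      for (uint8_t p : al.path) {
        if (p == 1) {
          std::array<int, 5> c = A.counts[i2];
          for (int x = 0; x < 5; ++x) c[x] += bcounts[j2][x];
          mcounts.push_back(c);
          ++i2; ++j2;
        } else if (p == 2) {  // column present in A only: B votes deletion
          std::array<int, 5> c = A.counts[i2];
          c[4] += col_cover(bcounts, j2);
          mcounts.push_back(c);
          ++i2;
        } else {              // column present in B only
          std::array<int, 5> c = bcounts[j2];
          c[4] += col_cover(A.counts, i2);
          mcounts.push_back(c);
          ++j2;
        }
      }
    }
    for (int i2 = al.a_end; i2 < static_cast<int>(A.counts.size()); ++i2)
      mcounts.push_back(A.counts[i2]);
    for (int j2 = al.b_end; j2 < static_cast<int>(bcounts.size()); ++j2)
      mcounts.push_back(bcounts[j2]);

    Node m;
    m.members = A.members;
    m.members.insert(m.members.end(), B.members.begin(), B.members.end());
    m.key = std::min(A.key, B.key);
    m.counts = std::move(mcounts);
    m.cons = counts_consensus(m.counts);

    std::vector<int> cand;
    cand.reserve(A.cand.size() + B.cand.size());
    for (int x : A.cand) cand.push_back(x);
    for (int x : B.cand) cand.push_back(x);

    int mi_idx = static_cast<int>(nodes.size());
    A.alive = false;
    B.alive = false;
    A.counts.clear(); A.counts.shrink_to_fit();
    B.counts.clear(); B.counts.shrink_to_fit();
    A.cand.clear(); A.cand.shrink_to_fit();
    B.cand.clear(); B.cand.shrink_to_fit();
    if (static_cast<size_t>(mi_idx) >= fwd.size())
      fwd.resize(fwd.size() * 2, -1);
    fwd[e.na] = mi_idx;
    fwd[e.nb] = mi_idx;
    nodes.push_back(std::move(m));

    if (exhaustive) {
      std::vector<int> keep;
      for (int x = 0; x < mi_idx; ++x) {
        if (!nodes[x].alive) continue;
        if (eval_exhaustive(mi_idx, x)) keep.push_back(x);
      }
      nodes[mi_idx].cand = std::move(keep);
    } else {
      // index the new consensus once, then scan every candidate
      KIndex idx;
      idx.build(nodes[mi_idx].cons, k);
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      std::vector<int> keep;
      std::vector<int> seen;
      for (int x0 : cand) {
        int x = resolve(x0);
        if (x < 0 || x == mi_idx || !nodes[x].alive) continue;
        if (std::find(seen.begin(), seen.end(), x) != seen.end()) continue;
        seen.push_back(x);
        int df = 0, dr = 0;
        int vf = idx.scan(nodes[x].cons, df);
        int vr = idx.scan(revcomp_str(nodes[x].cons), dr);
        if (eval_oriented(mi_idx, x, vf, df, vr, dr)) keep.push_back(x);
      }
      nodes[mi_idx].cand = std::move(keep);
    }
  }

  // Collect OTUs (>= 2 members) and singletons, ordered by smallest
  // member read index for stable output.
  std::vector<int> alive;
  for (int x = 0; x < static_cast<int>(nodes.size()); ++x)
    if (nodes[x].alive) alive.push_back(x);
  std::sort(alive.begin(), alive.end(),
            [&](int a2, int b2) { return nodes[a2].key < nodes[b2].key; });

  IntegerVector membership(n, NA_INTEGER);
  std::vector<std::string> cons;
  List coverage;
  int otu = 0;
  for (int x : alive) {
    if (nodes[x].members.size() < 2) continue;
    ++otu;
    for (int r : nodes[x].members) membership[r] = otu;
    cons.push_back(nodes[x].cons);
    IntegerVector cov(nodes[x].cons.size());
    int ci = 0;
    const char bases[4] = {'A', 'C', 'G', 'T'};
    for (const auto& c : nodes[x].counts) {
      int bi = 0;
      for (int y = 1; y < 4; ++y)
        if (c[y] > c[bi]) bi = y;
      if (c[4] > c[bi] || c[bi] == 0) continue;  // dropped column
      (void)bases;
      cov[ci++] = c[0] + c[1] + c[2] + c[3];
    }
    coverage.push_back(cov);
  }
  return List::create(_["membership"] = membership,
                      _["consensus"] = wrap(cons),
                      _["coverage"] = coverage);
}

// Full semiglobal alignment with the traceback path exposed
// (1 = aligned column, 2 = consume a only, 3 = consume b only), for the
// star-alignment fallback.
// [[Rcpp::export]]
List cpp_overlap_path(std::string a, std::string b) {
  Aln r = semiglobal_full(a, b, true);
  if (!r.ok) return List::create(_["ok"] = false);
  IntegerVector path(r.path.size());
  for (size_t i = 0; i < r.path.size(); ++i) path[i] = r.path[i];
  List out = aln_to_list(r, false);
  out["path"] = path;
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string x) { return revcomp_str(x); }
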