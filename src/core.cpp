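// Low-level sequence kernels: canonical k-mer counting, seeded De Bruijn
// graph construction with iterative gap filling, unitig extraction,
// affine-gap local alignment, Booth minimal rotation, and six-frame
// protein-word seed harvesting.  All k-mers are handled as upper-case
// ACGT strings; windows containing any other character are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline std::string canon(const std::string &s) {
  std::string r = revcomp(s);
  return (s <= r) ? s : r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(std::string(seqs[i]));
  return out;
}

// ---------------------------------------------------------------------------
// k-mer counting

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  const double cap = 2147483647.0;  // counts saturate rather than wrap
  if (k <= 31) {
    // 2-bit rolling encoding; numeric order of codes equals lexicographic
    // order of the k-mers, so canonicalisation and sorting agree with the
    // string path
    std::unordered_map<uint64_t, double> tab;
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int shift = 2 * (k - 1);
    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
      const char *s = CHAR(STRING_ELT(seqs, r));
      int n = (int)LENGTH(STRING_ELT(seqs, r));
      if (n < k) continue;
      uint64_t fwd = 0, rc = 0;
      int run = 0;
      for (int i = 0; i < n; ++i) {
        int b = base_idx(s[i]);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) tab[fwd < rc ? fwd : rc] += 1.0;
      }
    }
    std::vector<uint64_t> keys;
    keys.reserve(tab.size());
    for (auto &kv : tab) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector km(keys.size());
    IntegerVector ct(keys.size());
    std::string buf(k, 'A');
    static const char B[4] = {'A', 'C', 'G', 'T'};
    for (size_t i = 0; i < keys.size(); ++i) {
      uint64_t v = keys[i];
      for (int j = k - 1; j >= 0; --j) { buf[j] = B[v & 3]; v >>= 2; }
      km[i] = buf;
      double c = tab[keys[i]];
      ct[i] = (int)(c > cap ? cap : c);
    }
    return List::create(_["kmer"] = km, _["count"] = ct);
  }
  std::unordered_map<std::string, double> tab;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    int n = (int)s.size();
    if (n < k) continue;
    // next_bad[i] = smallest j >= i with invalid base, or n
    int bad = n;
    std::vector<int> next_bad(n + 1, n);
    for (int i = n - 1; i >= 0; --i) {
      if (!valid_base(s[i])) bad = i;
      next_bad[i] = bad;
    }
    for (int i = 0; i + k <= n; ++i) {
      if (next_bad[i] < i + k) { i = next_bad[i]; continue; }
      tab[canon(s.substr(i, k))] += 1.0;
    }
  }
  std::vector<std::string> keys;
  keys.reserve(tab.size());
  for (auto &kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    double c = tab[keys[i]];
    ct[i] = (int)(c > cap ? cap : c);
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// Fraction of a read's valid k-mers present in a decoy k-mer set.
// Returns -1 when the read has no valid k-mer.  When threshold >= 0 the
// scan stops early once the final fraction is provably on one side of it
// (the returned value then still compares correctly against threshold).
// [[Rcpp::export]]
NumericVector cpp_kmer_containment(CharacterVector seqs,
                                   CharacterVector decoy_kmers, int k,
                                   double threshold = -1.0) {
  std::unordered_set<std::string> decoy;
  for (R_xlen_t i = 0; i < decoy_kmers.size(); ++i)
    decoy.insert(as<std::string>(decoy_kmers[i]));
  NumericVector out(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    int n = (int)s.size();
    int nw = n - k + 1;
    int tot = 0, shared = 0;
    double res = -2.0;
    for (int i = 0; i + k <= n; ++i) {
      bool ok = true;
      for (int j = i; j < i + k; ++j)
        if (!valid_base(s[j])) { ok = false; break; }
      if (ok) {
        ++tot;
        if (decoy.count(canon(s.substr(i, k)))) ++shared;
      }
      if (threshold >= 0 && tot > 0) {
        int rem = nw - i - 1;
        // best and worst attainable final fractions
        if ((double)(shared + rem) / (double)(tot + rem) < threshold) {
          res = (double)(shared + rem) / (double)(tot + rem);
          break;
        }
        if ((double)shared / (double)(tot + rem) >= threshold) {
          res = 1.0;
          break;
        }
      }
    }
    if (res < -1.5)
      res = (tot == 0) ? -1.0 : (double)shared / (double)tot;
    out[r] = res;
  }
  return out;
}

// per-string minimum character code (for Phred+33 quality strings)
// [[Rcpp::export]]
IntegerVector cpp_min_char(CharacterVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    int n = (int)LENGTH(STRING_ELT(x, i));
    int mn = 255;
    for (int j = 0; j < n; ++j)
      if ((unsigned char)s[j] < mn) mn = (unsigned char)s[j];
    out[i] = (n == 0) ? NA_INTEGER : mn;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded graph construction with gap filling

struct GraphMaps {
  const std::unordered_map<std::string, int> &cnt;
  int k;
  GraphMaps(const std::unordered_map<std::string, int> &c, int kk)
    : cnt(c), k(kk) {}
};

// successors of an oriented k-mer (sequence as read), as oriented sequences
static void oriented_succ(const std::string &s, std::vector<std::string> &out) {
  out.clear();
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string t = s.substr(1) + "A";
  for (int b = 0; b < 4; ++b) { t[t.size() - 1] = B[b]; out.push_back(t); }
}

// [[Rcpp::export]]
List cpp_build_graph(CharacterVector kmers, IntegerVector counts,
                     CharacterVector seed_kmers, int threshold,
                     int max_gap_iterations, double gap_relax_factor,
                     int max_gap_depth) {
  std::unordered_map<std::string, int> cnt;
  cnt.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    cnt[as<std::string>(kmers[i])] = counts[i];
  std::unordered_set<std::string> admitted;
  std::unordered_set<std::string> seedset;

  // initial BFS from seeds through nodes with count >= threshold
  std::queue<std::string> q;
  for (R_xlen_t i = 0; i < seed_kmers.size(); ++i) {
    std::string s = canon(as<std::string>(seed_kmers[i]));
    seedset.insert(s);
    auto it = cnt.find(s);
    if (it != cnt.end() && it->second >= threshold && !admitted.count(s)) {
      admitted.insert(s);
      q.push(s);
    }
  }
  std::vector<std::string> succ;
  auto expand = [&](std::queue<std::string> &qq, int thr) {
    while (!qq.empty()) {
      std::string c = qq.front(); qq.pop();
      for (int ori = 0; ori < 2; ++ori) {
        std::string s = ori ? revcomp(c) : c;
        oriented_succ(s, succ);
        for (auto &t : succ) {
          std::string ct = canon(t);
          if (admitted.count(ct)) continue;
          auto it = cnt.find(ct);
          if (it != cnt.end() && it->second >= thr) {
            admitted.insert(ct);
            qq.push(ct);
          }
        }
      }
    }
  };
  expand(q, threshold);

  // gap filling: per round, relax the threshold and admit only nodes on
  // paths that reconnect a dangling path end to the admitted set within a
  // bounded search depth
  for (int iter = 1; iter <= max_gap_iterations; ++iter) {
    int thr = (int)std::floor((double)threshold *
                              std::pow(gap_relax_factor, iter));
    if (thr < 1) thr = 1;
    // find oriented path ends (sorted canonical order for determinism)
    std::vector<std::string> adm_sorted(admitted.begin(), admitted.end());
    std::sort(adm_sorted.begin(), adm_sorted.end());
    std::vector<std::string> ends;  // oriented sequences
    for (auto &c : adm_sorted) {
      for (int ori = 0; ori < 2; ++ori) {
        std::string s = ori ? revcomp(c) : c;
        oriented_succ(s, succ);
        bool any = false;
        for (auto &t : succ)
          if (admitted.count(canon(t))) { any = true; break; }
        if (!any) ends.push_back(s);
      }
    }
    if (ends.empty()) break;
    bool progress = false;
    for (auto &e : ends) {
      // BFS forward from the end through sub-threshold nodes
      std::unordered_map<std::string, std::string> parent;  // oriented
      std::queue<std::pair<std::string, int> > bq;
      bq.push(std::make_pair(e, 0));
      parent[e] = "";
      bool done = false;
      while (!bq.empty() && !done) {
        std::string u = bq.front().first;
        int d = bq.front().second;
        bq.pop();
        if (d >= max_gap_depth) continue;
        oriented_succ(u, succ);
        std::vector<std::string> ss = succ;  // succ reused in inner calls
        for (auto &t : ss) {
          std::string ct = canon(t);
          if (admitted.count(ct)) {
            if (d == 0) continue;  // immediate neighbour: not a gap
            // reconnected: admit the path
            std::string cur = u;
            while (!cur.empty()) {
              std::string cc = canon(cur);
              if (!admitted.count(cc)) admitted.insert(cc);
              cur = parent[cur];
            }
            progress = true;
            done = true;
            break;
          }
          if (parent.count(t)) continue;
          auto it = cnt.find(ct);
          if (it == cnt.end() || it->second < thr) continue;
          parent[t] = u;
          bq.push(std::make_pair(t, d + 1));
        }
      }
    }
    if (!progress && thr == 1) break;
  }

  std::vector<std::string> out(admitted.begin(), admitted.end());
  std::sort(out.begin(), out.end());
  CharacterVector km(out.size());
  IntegerVector ct(out.size());
  LogicalVector sd(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    km[i] = out[i];
    ct[i] = cnt[out[i]];
    sd[i] = seedset.count(out[i]) > 0;
  }
  return List::create(_["kmer"] = km, _["count"] = ct, _["is_seed"] = sd);
}

// ---------------------------------------------------------------------------
// Unitig extraction

// oriented predecessor candidates
static void oriented_pred(const std::string &s, std::vector<std::string> &out) {
  out.clear();
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string t = "A" + s.substr(0, s.size() - 1);
  for (int b = 0; b < 4; ++b) { t[0] = B[b]; out.push_back(t); }
}

// [[Rcpp::export]]
List cpp_unitigs(CharacterVector kmers, IntegerVector counts) {
  int n = kmers.size();
  std::unordered_map<std::string, int> cnt;
  cnt.reserve(n * 2);
  std::vector<std::string> sorted_k(n);
  for (int i = 0; i < n; ++i) {
    sorted_k[i] = as<std::string>(kmers[i]);
    cnt[sorted_k[i]] = counts[i];
  }
  std::sort(sorted_k.begin(), sorted_k.end());
  std::unordered_set<std::string> inset;
  for (auto &s : sorted_k) inset.insert(s);

  std::vector<std::string> succ, pred;
  auto succ_in = [&](const std::string &s, std::vector<std::string> &res) {
    res.clear();
    oriented_succ(s, succ);
    for (auto &t : succ) if (inset.count(canon(t))) res.push_back(t);
  };
  auto pred_in = [&](const std::string &s, std::vector<std::string> &res) {
    res.clear();
    oriented_pred(s, pred);
    for (auto &t : pred) if (inset.count(canon(t))) res.push_back(t);
  };

  std::unordered_set<std::string> visited;  // canonical
  std::vector<std::string> useq;
  std::vector<double> ucov;
  std::vector<bool> ucirc;
  std::vector<int> unk;
  // extremity oriented k-mers per linear unitig
  std::vector<std::string> first_or, last_or;

  std::vector<std::string> tmp, tmp2;
  for (auto &c0 : sorted_k) {
    if (visited.count(c0)) continue;
    std::string start = c0;  // oriented "+"
    // walk backward to the unitig start
    bool circular = false;
    std::string cur = start;
    std::unordered_set<std::string> walk;  // canonical members seen
    walk.insert(canon(cur));
    while (true) {
      pred_in(cur, tmp);
      if (tmp.size() != 1) break;
      std::string p = tmp[0];
      succ_in(p, tmp2);
      if (tmp2.size() != 1) break;
      if (p == start) { circular = true; break; }
      std::string cp = canon(p);
      if (walk.count(cp)) break;  // safety (hairpin)
      if (visited.count(cp)) break;
      walk.insert(cp);
      cur = p;
    }
    // walk forward from cur collecting the unitig
    std::vector<std::string> nodes;
    nodes.push_back(cur);
    visited.insert(canon(cur));
    std::string w = cur;
    while (true) {
      succ_in(w, tmp);
      if (tmp.size() != 1) break;
      std::string s = tmp[0];
      if (circular && s == cur) break;  // closed the cycle
      pred_in(s, tmp2);
      if (tmp2.size() != 1) break;
      std::string cs = canon(s);
      if (visited.count(cs)) break;
      nodes.push_back(s);
      visited.insert(cs);
      w = s;
    }
    // sequence and coverage
    double cov = 0;
    for (auto &nd : nodes) cov += cnt[canon(nd)];
    cov /= nodes.size();
    std::string seq;
    if (circular) {
      seq.reserve(nodes.size());
      for (auto &nd : nodes) seq.push_back(nd[0]);
    } else {
      seq = nodes.front();
      for (size_t i = 1; i < nodes.size(); ++i)
        seq.push_back(nodes[i][nodes[i].size() - 1]);
    }
    useq.push_back(seq);
    ucov.push_back(cov);
    ucirc.push_back(circular);
    unk.push_back((int)nodes.size());
    first_or.push_back(circular ? "" : nodes.front());
    last_or.push_back(circular ? "" : nodes.back());
  }

  // links between unitig extremities (k-1 overlaps), GFA-style (u, o, w, ow)
  std::unordered_map<std::string, std::pair<int, char> > entry;
  for (size_t u = 0; u < useq.size(); ++u) {
    if (ucirc[u]) continue;
    entry[first_or[u]] = std::make_pair((int)u, '+');
    entry[revcomp(last_or[u])] = std::make_pair((int)u, '-');
  }
  std::vector<int> lf, lt;
  std::vector<std::string> lfo, lto;
  for (size_t u = 0; u < useq.size(); ++u) {
    if (ucirc[u]) continue;
    for (int ori = 0; ori < 2; ++ori) {
      std::string ext = ori ? revcomp(first_or[u]) : last_or[u];
      succ_in(ext, tmp);
      for (auto &t : tmp) {
        auto it = entry.find(t);
        if (it == entry.end()) continue;
        lf.push_back((int)u + 1);
        lfo.push_back(ori ? "-" : "+");
        lt.push_back(it->second.first + 1);
        lto.push_back(std::string(1, it->second.second));
      }
    }
  }
  return List::create(
    _["seq"] = wrap(useq), _["cov"] = wrap(ucov),
    _["circular"] = wrap(ucirc), _["n_kmers"] = wrap(unk),
    _["link_from"] = wrap(lf), _["link_from_or"] = wrap(lfo),
    _["link_to"] = wrap(lt), _["link_to_or"] = wrap(lto));
}

// ---------------------------------------------------------------------------
// Affine-gap local alignment (Smith-Waterman).  Gap of length L costs
// gap_open + (L - 1) * gap_extend (both negative).

// [[Rcpp::export]]
List cpp_smith_waterman(std::string a, std::string b, NumericMatrix score,
                        double gap_open, double gap_extend) {
  CharacterVector rn = rownames(score), cn = colnames(score);
  double lut[256][256];
  for (int i = 0; i < 256; ++i)
    for (int j = 0; j < 256; ++j) lut[i][j] = -1e9;
  for (int i = 0; i < rn.size(); ++i) {
    char ci = as<std::string>(rn[i])[0];
    for (int j = 0; j < cn.size(); ++j) {
      char cj = as<std::string>(cn[j])[0];
      lut[(unsigned char)ci][(unsigned char)cj] = score(i, j);
    }
  }
  int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> TB((n + 1) * (m + 1), 0);  // 0 stop 1 diag 2 up 3 left
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int id = i * (m + 1) + j;
      double e = std::max(H[id - 1] + gap_open, E[id - 1] + gap_extend);
      double f = std::max(H[id - (m + 1)] + gap_open,
                          F[id - (m + 1)] + gap_extend);
      double sc = lut[(unsigned char)a[i - 1]][(unsigned char)b[j - 1]];
      double d = H[id - (m + 1) - 1] + sc;
      double h = std::max(0.0, std::max(d, std::max(e, f)));
      E[id] = e; F[id] = f; H[id] = h;
      if (h == 0) TB[id] = 0;
      else if (h == d) TB[id] = 1;
      else if (h == f) TB[id] = 2;
      else TB[id] = 3;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0.0, _["start1"] = NA_INTEGER,
                        _["end1"] = NA_INTEGER, _["start2"] = NA_INTEGER,
                        _["end2"] = NA_INTEGER, _["matches"] = 0,
                        _["aligned"] = 0,
                        _["idx1"] = IntegerVector(0),
                        _["idx2"] = IntegerVector(0));
  // traceback
  int i = bi, j = bj, matches = 0, aligned = 0;
  std::vector<int> idx1, idx2;
  while (i > 0 && j > 0) {
    int id = i * (m + 1) + j;
    unsigned char t = TB[id];
    if (t == 0) break;
    if (t == 1) {
      idx1.push_back(i); idx2.push_back(j);
      ++aligned;
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
  }
  std::reverse(idx1.begin(), idx1.end());
  std::reverse(idx2.begin(), idx2.end());
  return List::create(
    _["score"] = best,
    _["start1"] = i + 1, _["end1"] = bi,
    _["start2"] = j + 1, _["end2"] = bj,
    _["matches"] = matches, _["aligned"] = aligned,
    _["idx1"] = wrap(idx1), _["idx2"] = wrap(idx2));
}

// ---------------------------------------------------------------------------
// Booth's algorithm: index (0-based) of the lexicographically least rotation

// [[Rcpp::export]]
int cpp_min_rotation(std::string s) {
  std::string t = s + s;
  int n = (int)s.size(), len = 2 * n;
  std::vector<int> f(len, -1);
  int kidx = 0;
  for (int j = 1; j < len; ++j) {
    char sj = t[j];
    int i = f[j - kidx - 1];
    while (i != -1 && sj != t[kidx + i + 1]) {
      if (sj < t[kidx + i + 1]) kidx = j - i - 1;
      i = f[i];
    }
    if (sj != t[kidx + i + 1]) {
      if (sj < t[kidx]) kidx = j;
      f[j - kidx] = -1;
    } else {
      f[j - kidx] = i + 1;
    }
  }
  return kidx;
}

// ---------------------------------------------------------------------------
// Six-frame translation and protein-word seed harvesting

static const char CODON_AA[64] = {
  // index = a*16 + b*4 + c with A=0 C=1 G=2 T=3
  'K','N','K','N','T','T','T','T','R','S','R','S','I','I','M','I',
  'Q','H','Q','H','P','P','P','P','R','R','R','R','L','L','L','L',
  'E','D','E','D','A','A','A','A','G','G','G','G','V','V','V','V',
  '*','Y','*','Y','S','S','S','S','*','C','W','C','L','F','L','F'
};

static std::string translate_dna(const std::string &s) {
  int n = (int)s.size() / 3;
  std::string p(n, 'X');
  for (int i = 0; i < n; ++i) {
    int a = base_idx(s[3 * i]), b = base_idx(s[3 * i + 1]),
        c = base_idx(s[3 * i + 2]);
    if (a >= 0 && b >= 0 && c >= 0) p[i] = CODON_AA[a * 16 + b * 4 + c];
  }
  return p;
}

// [[Rcpp::export]]
CharacterVector cpp_translate(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = translate_dna(as<std::string>(seqs[i]));
  return out;
}

// For every amino-acid word of length word_len in the references, find
// reads whose six-frame translation contains the word and harvest the
// read k-mers overlapping the matched nucleotide span.
// [[Rcpp::export]]
List cpp_protein_seed_harvest(CharacterVector reads, CharacterVector ref_names,
                              CharacterVector ref_seqs, int word_len, int k) {
  struct Prov { int ref; int offset; };
  std::unordered_map<std::string, Prov> words;
  for (R_xlen_t r = 0; r < ref_seqs.size(); ++r) {
    std::string p = as<std::string>(ref_seqs[r]);
    for (int i = 0; i + word_len <= (int)p.size(); ++i) {
      std::string w = p.substr(i, word_len);
      if (w.find('*') != std::string::npos) continue;
      if (!words.count(w)) words[w] = Prov{(int)r, i};
    }
  }
  std::unordered_map<std::string, Prov> found;  // canonical kmer -> provenance
  int span = 3 * word_len;
  for (R_xlen_t rd = 0; rd < reads.size(); ++rd) {
    std::string s = as<std::string>(reads[rd]);
    int L = (int)s.size();
    if (L < span || L < k) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq = strand ? revcomp(s) : s;
      for (int frame = 0; frame < 3; ++frame) {
        std::string aa = translate_dna(seq.substr(frame));
        for (int i = 0; i + word_len <= (int)aa.size(); ++i) {
          auto it = words.find(aa.substr(i, word_len));
          if (it == words.end()) continue;
          // nucleotide span on the oriented read
          int s0 = frame + 3 * i, e0 = s0 + span;  // half-open
          // map to original read coordinates
          int os = strand ? (L - e0) : s0;
          int oe = strand ? (L - s0) : e0;
          // harvest read k-mers overlapping [os, oe)
          int w0 = std::max(0, os - k + 1), w1 = std::min(L - k, oe - 1);
          for (int w = w0; w <= w1; ++w) {
            bool ok = true;
            for (int j = w; j < w + k; ++j)
              if (!valid_base(s[j])) { ok = false; break; }
            if (!ok) continue;
            std::string c = canon(s.substr(w, k));
            if (!found.count(c)) found[c] = it->second;
          }
        }
      }
    }
  }
  std::vector<std::string> keys;
  for (auto &kv : found) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size()), rn(keys.size());
  IntegerVector off(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = keys[i];
    rn[i] = ref_names[found[keys[i]].ref];
    off[i] = found[keys[i]].offset;
  }
  return List::create(_["kmer"] = km, _["ref"] = rn, _["offset"] = off);
}
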