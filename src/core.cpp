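// Hot paths of the simulator: exact k-mer indexing + ungapped seed-and-extend
// mapping over linear contigs and a wrap-extended circular mito contig,
// per-position base pileup, and per-base substitution-error injection.
// All randomness goes through R's RNG so set.seed() governs everything.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <array>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Map reads against a set of contigs. Circular (mito) contigs must be flagged;
// they are extended internally by (max read length - 1) wrap bases and hit
// positions are reported modulo the true length. Positions returned 0-based.
// status: 0 = unmapped, 1 = mapped, 2 = ambiguous (>=2 distinct best loci).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector contigSeqs,
                        LogicalVector isCircular,
                        int k,
                        CharacterVector reads,
                        double minIdentity,
                        int maxCandidates) {
  const int nc = contigSeqs.size();
  const int nr = reads.size();

  int maxReadLen = 0;
  for (int i = 0; i < nr; ++i) {
    int m = LENGTH(STRING_ELT(reads, i));
    if (m > maxReadLen) maxReadLen = m;
  }
  const int W = maxReadLen > 0 ? maxReadLen - 1 : 0;

  std::vector<std::string> seqs(nc);   // extended sequences
  std::vector<int> trueLen(nc);        // un-extended lengths
  for (int i = 0; i < nc; ++i) {
    std::string s = as<std::string>(contigSeqs[i]);
    trueLen[i] = (int)s.size();
    if (isCircular[i]) {
      int w = std::min(W, trueLen[i]);
      s += s.substr(0, w);
    }
    if ((int)s.size() < k)
      stop("contig shorter than k-mer size k");
    seqs[i] = s;
  }

  // exact k-mer index over forward strand of all (extended) contigs
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  index.reserve(1 << 20);
  for (int ci = 0; ci < nc; ++ci) {
    const std::string& s = seqs[ci];
    uint64_t key = 0;
    int run = 0;
    for (int j = 0; j < (int)s.size(); ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        int start = j - k + 1;
        index[key].push_back(((uint64_t)ci << 32) | (uint64_t)start);
      }
    }
  }

  IntegerVector status(nr), contig(nr), pos(nr), score(nr), mism(nr);
  CharacterVector strand(nr);
  NumericVector identity(nr);

  std::vector<std::array<int, 3>> cands;  // (contig, pos, strand)
  std::unordered_set<uint64_t> seen;

  for (int ri = 0; ri < nr; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    const int m = (int)rd.size();
    status[ri] = 0;
    contig[ri] = NA_INTEGER; pos[ri] = NA_INTEGER;
    score[ri] = NA_INTEGER; mism[ri] = NA_INTEGER;
    strand[ri] = NA_STRING; identity[ri] = NA_REAL;
    if (m < k) continue;

    std::string rc = revcomp(rd);
    cands.clear();
    seen.clear();

    // collect candidate loci from all seed hits, deterministic order,
    // capped at maxCandidates distinct loci
    for (int st = 0; st < 2 && (int)cands.size() < maxCandidates; ++st) {
      const std::string& q = (st == 0) ? rd : rc;
      uint64_t key = 0;
      int run = 0;
      for (int j = 0; j < m && (int)cands.size() < maxCandidates; ++j) {
        int b = base2bit(q[j]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run < k) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        const int off = j - k + 1;
        for (uint64_t code : it->second) {
          int ci = (int)(code >> 32);
          int hp = (int)(code & 0xffffffffULL);
          int start = hp - off;
          if (start < 0) continue;
          int p;
          if (isCircular[ci]) {
            p = start % trueLen[ci];
            // extension guarantees [p, p+m) fits in the extended string
            if (p + m > (int)seqs[ci].size()) continue;
          } else {
            if (start + m > trueLen[ci]) continue;
            p = start;
          }
          uint64_t lk = ((uint64_t)ci << 34) | ((uint64_t)p << 1) | (uint64_t)st;
          if (!seen.insert(lk).second) continue;
          cands.push_back({ci, p, st});
          if ((int)cands.size() >= maxCandidates) break;
        }
      }
    }

    int bestScore = INT_MIN, bestCi = -1, bestPos = -1, bestSt = 0;
    int bestMatches = 0, nBest = 0;
    for (const auto& c : cands) {
      const std::string& q = (c[2] == 0) ? rd : rc;
      const std::string& s = seqs[c[0]];
      int matches = 0;
      for (int j = 0; j < m; ++j)
        if (s[c[1] + j] == q[j]) ++matches;
      if ((double)matches / m < minIdentity) continue;
      int sc = 2 * matches - m;  // +1 match, -1 mismatch
      if (sc > bestScore) {
        bestScore = sc; bestCi = c[0]; bestPos = c[1]; bestSt = c[2];
        bestMatches = matches; nBest = 1;
      } else if (sc == bestScore) {
        ++nBest;
      }
    }

    if (nBest == 0) continue;
    status[ri] = (nBest >= 2) ? 2 : 1;
    contig[ri] = bestCi + 1;
    pos[ri] = bestPos;
    strand[ri] = (bestSt == 0) ? "+" : "-";
    score[ri] = bestScore;
    mism[ri] = m - bestMatches;
    identity[ri] = (double)bestMatches / m;
  }

  return DataFrame::create(
    _["status"] = status, _["contig"] = contig, _["pos0"] = pos,
    _["strand"] = strand, _["score"] = score, _["mismatches"] = mism,
    _["identity"] = identity, _["stringsAsFactors"] = false);
}

// Per-position A/C/G/T tally over a circular contig of length L.
// pos0 is the 0-based mapped position; reads on '-' strand were stored as the
// sequenced (reverse-complement) strand, so their bases are complemented and
// reversed back onto the forward reference.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(CharacterVector reads, IntegerVector pos0,
                         LogicalVector isRev, int L) {
  IntegerMatrix counts(4, L);
  const int nr = reads.size();
  for (int ri = 0; ri < nr; ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    const int m = (int)rd.size();
    const int p = pos0[ri];
    if (p < 0 || p >= L) stop("alignment position outside contig bounds");
    for (int j = 0; j < m; ++j) {
      char c = isRev[ri] ? comp_base(rd[m - 1 - j]) : rd[j];
      int b = base2bit(c);
      if (b < 0) continue;
      counts(b, (p + j) % L)++;
    }
  }
  return counts;
}

// Independent per-base substitution errors; bases inside the primer footprint
// masks (first t5 / last t3 bases of each sequence, molecule orientation) use
// primerRate, all others baseRate. Substituted base uniform over the other 3.
// [[Rcpp::export]]
CharacterVector cpp_mutate_bases(CharacterVector seqs, IntegerVector t5,
                                 IntegerVector t3, double baseRate,
                                 double primerRate) {
  const int n = seqs.size();
  CharacterVector out(n);
  const char* bases = "ACGT";
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int m = (int)s.size();
    const int a = t5[i], b = t3[i];
    for (int j = 0; j < m; ++j) {
      double rate = (j < a || j >= m - b) ? primerRate : baseRate;
      if (rate <= 0.0) continue;
      if (unif_rand() < rate) {
        int cur = base2bit(s[j]);
        int nb = (int)(unif_rand() * 3.0);
        if (nb > 2) nb = 2;
        if (nb >= cur) ++nb;  // uniform over the 3 other bases
        s[j] = bases[nb];
      }
    }
    out[i] = s;
  }
  return out;
}

// Hamming mismatch count between two equal-length strings.
// [[Rcpp::export]]
int cpp_mismatch_count(std::string a, std::string b) {
  if (a.size() != b.size()) stop("sequences differ in length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}
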