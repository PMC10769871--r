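#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Plan-7-style local Viterbi over match states (Smith-Waterman entry/exit):
// free entry into any match column, free exit from any match column, insert
// states emit at background (log-odds 0), delete states are silent.  All
// scores are log2 odds.  Columns are 1..L; I_k follows M_k, D_k is entered
// from M_{k-1} or D_{k-1}.
// ---------------------------------------------------------------------------

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// emis: L x A matrix of match emission log-odds; target: 1-based residue codes
// trans: list of per-column transition log2 scores (source-column indexed)
// [[Rcpp::export]]
List viterbi_core(NumericMatrix emis, List trans, IntegerVector target) {
  const int L = emis.nrow();
  const int n = target.size();
  NumericVector tMM = trans["MM"], tMI = trans["MI"], tMD = trans["MD"];
  NumericVector tII = trans["II"], tIM = trans["IM"];
  NumericVector tDD = trans["DD"], tDM = trans["DM"];
  const double NEG = -1e30;

  std::vector<double> VM((n + 1) * (L + 1), NEG);
  std::vector<double> VI((n + 1) * (L + 1), NEG);
  std::vector<double> VD((n + 1) * (L + 1), NEG);
  // pointer codes: 0 none/entry, 1 from M, 2 from I, 3 from D
  std::vector<signed char> PM((n + 1) * (L + 1), 0);
  std::vector<signed char> PI((n + 1) * (L + 1), 0);
  std::vector<signed char> PD((n + 1) * (L + 1), 0);
  #define IX(i, k) ((i) * (L + 1) + (k))

  double best = NEG;
  int bi = 0, bk = 0;
  for (int i = 1; i <= n; ++i) {
    const int a = target[i - 1] - 1;
    for (int k = 1; k <= L; ++k) {
      // match
      double e = emis(k - 1, a);
      double vm = 0.0; signed char pm = 0;   // local entry
      if (k > 1) {
        double fm = VM[IX(i - 1, k - 1)] + tMM[k - 2];
        double fi = VI[IX(i - 1, k - 1)] + tIM[k - 2];
        double fd = VD[IX(i - 1, k - 1)] + tDM[k - 2];
        if (fm > vm) { vm = fm; pm = 1; }
        if (fi > vm) { vm = fi; pm = 2; }
        if (fd > vm) { vm = fd; pm = 3; }
      }
      vm += e;
      VM[IX(i, k)] = vm; PM[IX(i, k)] = pm;
      if (vm > best) { best = vm; bi = i; bk = k; }
      // insert (I_k emits residue i at background: +0)
      double fmi = VM[IX(i - 1, k)] + tMI[k - 1];
      double fii = VI[IX(i - 1, k)] + tII[k - 1];
      if (fmi >= fii) { VI[IX(i, k)] = fmi; PI[IX(i, k)] = 1; }
      else            { VI[IX(i, k)] = fii; PI[IX(i, k)] = 2; }
      // delete (silent)
      if (k > 1) {
        double fmd = VM[IX(i, k - 1)] + tMD[k - 2];
        double fdd = VD[IX(i, k - 1)] + tDD[k - 2];
        if (fmd >= fdd) { VD[IX(i, k)] = fmd; PD[IX(i, k)] = 1; }
        else            { VD[IX(i, k)] = fdd; PD[IX(i, k)] = 3; }
      }
    }
  }

  // traceback from (bi, bk) in M; matchMap: 0 = column outside the aligned
  // region, -1 = delete (column covered, no residue), else target position.
  IntegerVector matchMap(L, 0);
  int tstart = 0, tend = 0, kstart = 0, kend = 0;
  if (best > 0.0 && bi > 0) {
    tend = bi; kend = bk;
    int i = bi, k = bk, st = 1;  // 1 = M, 2 = I, 3 = D
    while (true) {
      if (st == 1) {
        matchMap[k - 1] = i;
        signed char p = PM[IX(i, k)];
        tstart = i; kstart = k;
        if (p == 0) break;
        --i; --k; st = p;
      } else if (st == 2) {
        signed char p = PI[IX(i, k)];
        --i; st = p;
      } else {
        matchMap[k - 1] = -1;
        signed char p = PD[IX(i, k)];
        --k; st = p;
      }
    }
  } else {
    best = 0.0;  // empty local alignment
  }
  #undef IX
  return List::create(_["score"] = best, _["tstart"] = tstart,
                      _["tend"] = tend, _["kstart"] = kstart,
                      _["kend"] = kend, _["matchMap"] = matchMap);
}

// score-only Viterbi for a batch of targets (two rolling rows; calibration path)
// [[Rcpp::export]]
NumericVector viterbi_scores(NumericMatrix emis, List trans, List targets) {
  const int L = emis.nrow();
  NumericVector tMM = trans["MM"], tMI = trans["MI"], tMD = trans["MD"];
  NumericVector tII = trans["II"], tIM = trans["IM"];
  NumericVector tDD = trans["DD"], tDM = trans["DM"];
  const double NEG = -1e30;
  const int nt = targets.size();
  NumericVector out(nt);
  std::vector<double> M0(L + 1), I0(L + 1), D0(L + 1);
  std::vector<double> M1(L + 1), I1(L + 1), D1(L + 1);
  for (int t = 0; t < nt; ++t) {
    IntegerVector target = targets[t];
    const int n = target.size();
    double best = 0.0;
    std::fill(M0.begin(), M0.end(), NEG);
    std::fill(I0.begin(), I0.end(), NEG);
    std::fill(D0.begin(), D0.end(), NEG);
    for (int i = 1; i <= n; ++i) {
      const int a = target[i - 1] - 1;
      M1[0] = I1[0] = D1[0] = NEG;
      for (int k = 1; k <= L; ++k) {
        double vm = 0.0;
        if (k > 1) {
          vm = std::max(vm, max3(M0[k - 1] + tMM[k - 2],
                                 I0[k - 1] + tIM[k - 2],
                                 D0[k - 1] + tDM[k - 2]));
        }
        vm += emis(k - 1, a);
        M1[k] = vm;
        if (vm > best) best = vm;
        I1[k] = std::max(M0[k] + tMI[k - 1], I0[k] + tII[k - 1]);
        D1[k] = (k > 1) ? std::max(M1[k - 1] + tMD[k - 2],
                                   D1[k - 1] + tDD[k - 2]) : NEG;
      }
      std::swap(M0, M1); std::swap(I0, I1); std::swap(D0, D1);
    }
    out[t] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// 2-bit k-mer machinery (ACGT, k <= 32)
// ---------------------------------------------------------------------------

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// enumerate valid k-mers of s, calling f(code_fwd, code_rc, pos)
template <typename F>
static void each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2(s[i]);
    if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) f(fwd, rc, (int)(i + 1 - k));
  }
}

// open-addressing hash set/map over 2-bit k-mer codes (linear probing);
// values: -1 marks "set membership only"
struct KmerTable {
  std::vector<uint64_t> keys;
  std::vector<int> vals;
  uint64_t mask;
  bool hasSentinel;
  int sentinelVal;
  static constexpr uint64_t EMPTY = ~0ULL;
  explicit KmerTable(size_t n) : hasSentinel(false), sentinelVal(-2) {
    size_t cap = 16;
    while (cap < 2 * n + 1) cap <<= 1;
    keys.assign(cap, EMPTY);
    vals.assign(cap, -2);
    mask = cap - 1;
  }
  static inline uint64_t mix(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }
  // inserts key if absent; returns slot value reference semantics via set()
  void set(uint64_t key, int val) {
    if (key == EMPTY) { hasSentinel = true; if (sentinelVal == -2) sentinelVal = val; return; }
    uint64_t i = mix(key) & mask;
    while (keys[i] != EMPTY && keys[i] != key) i = (i + 1) & mask;
    if (keys[i] == EMPTY) { keys[i] = key; vals[i] = val; }
  }
  // -2 = absent
  inline int get(uint64_t key) const {
    if (key == EMPTY) return hasSentinel ? sentinelVal : -2;
    uint64_t i = mix(key) & mask;
    while (keys[i] != EMPTY) {
      if (keys[i] == key) return vals[i];
      i = (i + 1) & mask;
    }
    return -2;
  }
  inline bool contains(uint64_t key) const { return get(key) != -2; }
};

// fraction of each read's k-mers whose canonical form occurs in the host;
// when `decideAt` >= 0 the scan stops as soon as the >= decideAt outcome is
// settled and returns 0/1 accordingly
// [[Rcpp::export]]
NumericVector shared_kmer_fraction(CharacterVector reads, CharacterVector host,
                                   int k, double decideAt = -1.0) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  size_t hostLen = 0;
  for (int h = 0; h < host.size(); ++h) hostLen += LENGTH(STRING_ELT(host, h));
  KmerTable hset(hostLen);
  for (int h = 0; h < host.size(); ++h) {
    SEXP s = STRING_ELT(host, h);
    each_kmer(std::string(CHAR(s), LENGTH(s)), k,
              [&](uint64_t f, uint64_t r, int) {
      hset.set(std::min(f, r), -1);
    });
  }
  NumericVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    SEXP s = STRING_ELT(reads, i);
    std::string rd(CHAR(s), LENGTH(s));
    int n = (int)rd.size();
    int total = (n >= k) ? n - k + 1 : 0;
    if (total == 0) { out[i] = 0.0; continue; }
    if (decideAt >= 0.0) {
      const int need = (int)std::ceil(decideAt * total);
      int hit = 0, seen = 0;
      bool decided = false, removed = false;
      each_kmer(rd, k, [&](uint64_t f, uint64_t r, int) {
        if (decided) return;
        ++seen;
        if (hset.contains(std::min(f, r))) ++hit;
        if (hit >= need) { decided = true; removed = true; }
        else if (hit + (total - seen) < need) { decided = true; }
      });
      out[i] = removed ? 1.0 : 0.0;
    } else {
      int hit = 0;
      each_kmer(rd, k, [&](uint64_t f, uint64_t r, int) {
        if (hset.contains(std::min(f, r))) ++hit;
      });
      out[i] = (double)hit / total;
    }
  }
  return out;
}

// per-base substitution errors at `rate`, drawn from R's RNG stream so the
// result is reproducible under set.seed()
// [[Rcpp::export]]
CharacterVector mutate_reads_core(CharacterVector reads, double rate) {
  if (rate <= 0.0) return reads;
  static const char* B = "ACGT";
  RNGScope scope;
  CharacterVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < rate) {
        int b = base2(s[p]);
        if (b >= 0) {
          int step = 1 + (int)(unif_rand() * 3.0);
          if (step > 3) step = 3;
          s[p] = B[(b + step) % 4];
        }
      }
    }
    out[i] = s;
  }
  return out;
}

static char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// seed-and-extend presence mapper: a read maps iff some exact k-mer seed on
// either strand anchors an ungapped diagonal alignment with identity over the
// full read >= min_identity (positions off the reference count as mismatches)
// [[Rcpp::export]]
LogicalVector map_reads_core(CharacterVector reads, CharacterVector refs,
                             int k, double min_identity) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::vector<std::string> R(refs.size());
  size_t totalRefLen = 0;
  for (int r = 0; r < refs.size(); ++r) {
    SEXP s = STRING_ELT(refs, r);
    R[r].assign(CHAR(s), LENGTH(s));
    totalRefLen += R[r].size();
  }
  // kmer -> head of a postings chain (ref id, pos, next)
  KmerTable index(totalRefLen);
  std::vector<int> postRef, postPos, postNext;
  postRef.reserve(totalRefLen);
  for (int r = 0; r < (int)R.size(); ++r) {
    each_kmer(R[r], k, [&](uint64_t f, uint64_t, int pos) {
      int head = index.get(f);
      postRef.push_back(r); postPos.push_back(pos);
      postNext.push_back(head == -2 ? -1 : head);
      int id = (int)postRef.size() - 1;
      if (head == -2) index.set(f, id);
      else {
        // overwrite chain head
        if (f == KmerTable::EMPTY) index.sentinelVal = id;
        else {
          uint64_t i = KmerTable::mix(f) & index.mask;
          while (index.keys[i] != f) i = (i + 1) & index.mask;
          index.vals[i] = id;
        }
      }
    });
  }
  LogicalVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    SEXP s = STRING_ELT(reads, i);
    std::string fwd(CHAR(s), LENGTH(s));
    std::string rc(fwd.rbegin(), fwd.rend());
    for (size_t j = 0; j < rc.size(); ++j) rc[j] = comp(rc[j]);
    bool mapped = false;
    const int n = (int)fwd.size();
    const int need = (int)std::ceil(min_identity * n);
    for (int strand = 0; strand < 2 && !mapped; ++strand) {
      const std::string& rd = (strand == 0) ? fwd : rc;
      each_kmer(rd, k, [&](uint64_t f, uint64_t, int rpos) {
        if (mapped) return;
        for (int h = index.get(f); h >= 0 && h != -1; h = postNext[h]) {
          const std::string& rf = R[postRef[h]];
          const long off = (long)postPos[h] - rpos;
          int match = 0;
          for (int p = 0; p < n; ++p) {
            long q = off + p;
            if (q >= 0 && q < (long)rf.size() && rf[q] == rd[p]) ++match;
          }
          if (match >= need) { mapped = true; break; }
        }
      });
    }
    out[i] = mapped;
  }
  return out;
}
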