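// Low-level sequence kernels: unit-cost alignment distances, vsearch-style
// greedy centroid clustering with a k-mer prescreen, a k-mer-seeded
// best-hit read mapper, paired-end overlap merging, 3' trimming and
// substitution-error injection. All RNG goes through R's generator so
// results are reproducible under set.seed().
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_reverse_strings(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}

// Full unit-cost (Levenshtein) distance, global.
static int edit_distance_full(const std::string &a, const std::string &b) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min({sub, prev[j] + 1, cur[j - 1] + 1});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Banded Levenshtein; returns band+1 if the true distance exceeds `band`.
static int edit_distance_banded(const std::string &a, const std::string &b,
                                int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > band) return band + 1;
  const int INF = band + 1;
  std::vector<int> prev(m + 1, INF), cur(m + 1, INF);
  for (int j = 0; j <= std::min(m, band); ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i - band), hi = std::min(m, i + band);
    std::fill(cur.begin(), cur.end(), INF);
    if (i - band <= 0) cur[0] = i;
    for (int j = lo; j <= hi; ++j) {
      int best = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      if (prev[j] + 1 < best) best = prev[j] + 1;
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      cur[j] = best > INF ? INF : best;
    }
    std::swap(prev, cur);
  }
  return std::min(prev[m], INF);
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  return edit_distance_full(a, b);
}

// Pairwise identity used for clustering: 1 - d / max(|a|, |b|), where d is
// the unit-cost global alignment distance (end gaps count as edits).
// [[Rcpp::export]]
double cpp_pair_identity(std::string a, std::string b) {
  int L = std::max((int)a.size(), (int)b.size());
  if (L == 0) return 1.0;
  return 1.0 - (double)edit_distance_full(a, b) / (double)L;
}

// Semi-global distance: whole read must align, reference leading/trailing
// gaps are free. Identity = 1 - d / |read|.
// [[Rcpp::export]]
double cpp_semiglobal_identity(std::string read, std::string ref) {
  const int n = (int)read.size(), m = (int)ref.size();
  if (n == 0) return 1.0;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = 0; // free start anywhere in ref
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (read[i - 1] == ref[j - 1] ? 0 : 1);
      cur[j] = std::min({sub, prev[j] + 1, cur[j - 1] + 1});
    }
    std::swap(prev, cur);
  }
  int d = prev[0];
  for (int j = 1; j <= m; ++j) d = std::min(d, prev[j]); // free end
  return 1.0 - (double)d / (double)n;
}

static const uint64_t NOKMER = UINT64_MAX;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t kmer_at(const std::string &s, int pos, int k) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return NOKMER;
    v = (v << 2) | (uint64_t)b;
  }
  return v;
}

// Greedy centroid clustering over sequences already sorted by
// abundance desc / lexicographic. A sequence joins the first-founded
// centroid reaching `id_thr` in either orientation, else founds a new
// centroid. Candidate centroids are prescreened by shared k-mers; a pair
// at >= id_thr identity over typical GBS lengths shares a k-mer with
// near-certainty, unrelated loci essentially never do.
// Returns 1-based index (into seqs) of each sequence's centroid.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double id_thr,
                                 int k = 12, int qstride = 2) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> cent;           // centroid sequences
  std::vector<int> cent_idx;               // founder index (0-based)
  std::unordered_map<uint64_t, std::vector<int>> index; // kmer -> centroid serials
  std::vector<int> seen(0);
  std::vector<int> stamp;                  // per-centroid last-visit stamp

  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string rc = revcomp(s);
    // gather candidate centroids from both orientations
    std::vector<int> cand;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &q = ori ? rc : s;
      int L = (int)q.size();
      for (int p = 0; p + k <= L; p += qstride) {
        uint64_t km = kmer_at(q, p, k);
        if (km == NOKMER) continue;
        auto it = index.find(km);
        if (it == index.end()) continue;
        for (int c : it->second) {
          if ((int)stamp.size() <= c) stamp.resize(c + 1, -1);
          if (stamp[c] != i) { stamp[c] = i; cand.push_back(c); }
        }
      }
    }
    std::sort(cand.begin(), cand.end()); // founding order
    int hit = -1;
    int Ls = (int)s.size();
    for (int c : cand) {
      const std::string &ct = cent[c];
      int L = std::max(Ls, (int)ct.size());
      int band = (int)std::floor((1.0 - id_thr) * L) + 1;
      int d = edit_distance_banded(s, ct, band);
      double id = 1.0 - (double)d / (double)L;
      if (id < id_thr) {
        d = edit_distance_banded(rc, ct, band);
        id = 1.0 - (double)d / (double)L;
      }
      if (id >= id_thr) { hit = c; break; }
    }
    if (hit >= 0) {
      assign[i] = cent_idx[hit] + 1;
    } else {
      int serial = (int)cent.size();
      cent.push_back(s);
      cent_idx.push_back(i);
      assign[i] = i + 1;
      int L = (int)s.size();
      for (int p = 0; p + k <= L; ++p) {
        uint64_t km = kmer_at(s, p, k);
        if (km != NOKMER) index[km].push_back(serial);
      }
    }
  }
  return assign;
}

// Diagonal (ungapped) identity of `read` placed on `ref` at offset `diag`
// (ref position of read base 0). Positions where the read base or the
// aligned in-range reference base is N are excluded from both numerator
// and denominator (joined reads score as two sub-alignments around the N
// junction); read bases falling outside the reference count as mismatches.
static double diag_identity(const char *read, int L, const char *ref, int M,
                            int diag) {
  int match = 0, den = 0;
  for (int i = 0; i < L; ++i) {
    char rc_ = read[i];
    if (rc_ == 'N' || rc_ == 'n') continue;
    int j = diag + i;
    if (j < 0 || j >= M) { den++; continue; }
    char fc = ref[j];
    if (fc == 'N' || fc == 'n') continue;
    den++;
    if (fc == rc_) match++;
  }
  if (den == 0) return 0.0;
  return (double)match / (double)den;
}

// Build + query in one call: best-hit mapping of reads against reference
// centroids. Seeds are exact k-mers (all reference positions indexed, read
// queried at `qstride` spacing, both orientations); each seeded
// (reference, diagonal) placement is scored by ungapped identity with
// N-positions excluded. Returns, per read, the best reference (1-based, NA
// if below min_identity or no seed), the best identity, and the indices of
// all references tying the best identity.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs,
                   double min_identity, int k = 20, int qstride = 11) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  for (int r = 0; r < nref; ++r) {
    R[r] = as<std::string>(refs[r]);
    int M = (int)R[r].size();
    for (int p = 0; p + k <= M; ++p) {
      uint64_t km = kmer_at(R[r], p, k);
      if (km != NOKMER) index[km].emplace_back(r, p);
    }
  }
  int n = reads.size();
  IntegerVector best(n);
  NumericVector ident(n);
  List ties(n);
  const double EPS = 1e-9;

  std::vector<double> refbest(nref, -1.0);
  std::vector<int> touched;
  std::vector<int64_t> cand;
  std::string rc;

  for (int i = 0; i < n; ++i) {
    const char *sp = CHAR(STRING_ELT(reads, i));
    int L = (int)LENGTH(STRING_ELT(reads, i));
    std::string s(sp, L);
    rc = revcomp(s);
    touched.clear();
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &q = ori ? rc : s;
      cand.clear();
      for (int p = 0; p + k <= L; p += qstride) {
        uint64_t km = kmer_at(q, p, k);
        if (km == NOKMER) continue;
        auto it = index.find(km);
        if (it == index.end()) continue;
        for (auto &pr : it->second) {
          int r = pr.first, diag = pr.second - p;
          cand.push_back(((int64_t)r << 24) | (int64_t)(diag + (1 << 22)));
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int64_t key : cand) {
        int r = (int)(key >> 24);
        int diag = (int)(key & ((1 << 24) - 1)) - (1 << 22);
        double id = diag_identity(q.c_str(), L, R[r].c_str(),
                                  (int)R[r].size(), diag);
        if (refbest[r] < 0) touched.push_back(r);
        if (id > refbest[r]) refbest[r] = id;
      }
    }
    double b = -1.0;
    for (int r : touched) if (refbest[r] > b) b = refbest[r];
    if (b >= min_identity) {
      std::vector<int> tied;
      for (int r : touched) if (refbest[r] >= b - EPS) tied.push_back(r);
      std::sort(tied.begin(), tied.end());
      best[i] = tied[0] + 1;
      ident[i] = b;
      IntegerVector tv(tied.size());
      for (size_t t = 0; t < tied.size(); ++t) tv[t] = tied[t] + 1;
      ties[i] = tv;
    } else {
      best[i] = NA_INTEGER;
      ident[i] = NA_REAL;
      ties[i] = R_NilValue;
    }
    for (int r : touched) refbest[r] = -1.0;
  }
  return List::create(_["best"] = best, _["identity"] = ident,
                      _["ties"] = ties);
}

// Overlap-merge mate pairs. mate2 is reverse-complemented internally.
// Overlap lengths are scanned from the longest possible down to
// min_overlap; the first overlap with >= min_frac_id matching bases is
// accepted. Consensus at mismatches takes the higher-quality base
// (mate 1 wins ties); consensus quality is the maximum of the two.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector s1, CharacterVector s2,
                     CharacterVector q1, CharacterVector q2,
                     int min_overlap, double min_frac_id) {
  int n = s1.size();
  LogicalVector merged(n);
  CharacterVector seq(n), qual(n);
  SEXP blank = Rf_mkChar("");
  std::string b, qb, ms, mq;
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(s1, i));
    int L1 = LENGTH(STRING_ELT(s1, i));
    const char *b2 = CHAR(STRING_ELT(s2, i));
    int L2 = LENGTH(STRING_ELT(s2, i));
    b.assign(b2, L2);
    std::reverse(b.begin(), b.end());
    for (auto &c : b) c = comp_base(c);
    const char *qa = CHAR(STRING_ELT(q1, i));
    qb.assign(CHAR(STRING_ELT(q2, i)), L2);
    std::reverse(qb.begin(), qb.end());
    int found = -1;
    for (int o = std::min(L1, L2); o >= min_overlap; --o) {
      int allowed = (int)std::floor((1.0 - min_frac_id) * o);
      int mm = 0;
      bool ok = true;
      const char *at = a + L1 - o;
      for (int p = 0; p < o; ++p) {
        if (at[p] != b[p] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { found = o; break; }
    }
    if (found < 0) {
      merged[i] = false;
      SET_STRING_ELT(seq, i, blank);
      SET_STRING_ELT(qual, i, blank);
      continue;
    }
    int o = found;
    ms.assign(a, L1 - o);
    mq.assign(qa, L1 - o);
    for (int p = 0; p < o; ++p) {
      char ca = a[L1 - o + p], cb = b[p];
      char qca = qa[L1 - o + p], qcb = qb[p];
      if (ca == cb) { ms.push_back(ca); }
      else if (qcb > qca) { ms.push_back(cb); }
      else { ms.push_back(ca); } // tie -> mate 1
      mq.push_back(std::max(qca, qcb));
    }
    ms.append(b, o, std::string::npos);
    mq.append(qb, o, std::string::npos);
    merged[i] = true;
    seq[i] = ms;
    qual[i] = mq;
  }
  return List::create(_["merged"] = merged, _["seq"] = seq, _["qual"] = qual);
}

// Length to keep after removing the maximal 3' suffix of bases with
// quality below `threshold` (phred+offset encoding).
// [[Rcpp::export]]
IntegerVector cpp_trim_qual(CharacterVector quals, int threshold,
                            int offset = 33) {
  int n = quals.size();
  IntegerVector keep(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    int L = (int)q.size();
    int j = L;
    while (j > 0 && ((int)q[j - 1] - offset) < threshold) --j;
    keep[i] = j;
  }
  return keep;
}

// 0-based position where a 3'-terminating adapter occurrence starts
// (occurrence = full adapter, or an adapter prefix of >= min_match bases
// reaching the read end); equals read length when no adapter is found.
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector seqs, std::string adapter,
                               int min_match = 5) {
  int n = seqs.size(), alen = (int)adapter.size();
  IntegerVector cut(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    int pos = L;
    for (int p = 0; p + min_match <= L; ++p) {
      int m = std::min(alen, L - p);
      bool ok = true;
      for (int t = 0; t < m; ++t)
        if (s[p + t] != adapter[t]) { ok = false; break; }
      if (ok) { pos = p; break; }
    }
    cut[i] = pos;
  }
  return cut;
}

// Independent substitution errors at `rate` per base; erroneous bases are
// replaced by a uniform draw from the three other bases. Uses R's RNG.
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    int ne = (int)R::rbinom((double)L, rate);
    for (int e = 0; e < ne; ++e) {
      int p = (int)std::floor(R::unif_rand() * L);
      if (p >= L) p = L - 1;
      int b = base2bits(s[p]);
      if (b < 0) continue;
      int nb = (int)std::floor(R::unif_rand() * 3.0);
      if (nb >= b) nb++;
      s[p] = BASES[nb];
    }
    out[i] = s;
  }
  return out;
}
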