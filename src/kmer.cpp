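// Canonical k-mer index over a pan-assembly and maximum-share read
// attribution. K-mers are 2-bit packed (k <= 31); the canonical form is
// the lexicographic minimum of a k-mer and its reverse complement.
// K-mers containing N (or any non-ACGT base) are skipped.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <string>
using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t revcomp_kmer(uint64_t x, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return r;
}

// distinct canonical k-mers of one sequence, sorted
static void seq_kmers(const std::string& s, int k, std::vector<uint64_t>& out) {
  out.clear();
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2code(s[i]);
    if (c < 0) { valid = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      uint64_t rc = revcomp_kmer(cur, k);
      out.push_back(cur < rc ? cur : rc);
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

struct KmerIndex {
  int k;
  int n_transcripts;
  std::unordered_map<uint64_t, std::vector<int> > map;  // kmer -> 0-based ids
};

// [[Rcpp::export]]
SEXP kx_build(CharacterVector seqs, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->n_transcripts = seqs.size();
  std::vector<uint64_t> kms;
  for (int t = 0; t < seqs.size(); ++t) {
    std::string s = Rcpp::as<std::string>(seqs[t]);
    seq_kmers(s, k, kms);
    for (size_t z = 0; z < kms.size(); ++z) idx->map[kms[z]].push_back(t);
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
double kx_nkmers(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (double)idx->map.size();
}

// [[Rcpp::export]]
IntegerVector kx_postings(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length does not match index k");
  uint64_t cur = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int c = base2code(kmer[i]);
    if (c < 0) return IntegerVector(0);
    cur = (cur << 2) | (uint64_t)c;
  }
  uint64_t rc = revcomp_kmer(cur, idx->k);
  uint64_t key = cur < rc ? cur : rc;
  std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
      idx->map.find(key);
  if (it == idx->map.end()) return IntegerVector(0);
  IntegerVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1;
  return out;
}

// Each read votes for the transcript(s) sharing the most distinct
// canonical k-mers; max share < min_share leaves the read unattributed;
// an m-way tie adds 1/m to each tied transcript.
// [[Rcpp::export]]
NumericVector kx_attribute(SEXP xp, CharacterVector reads, int min_share) {
  XPtr<KmerIndex> idx(xp);
  NumericVector counts(idx->n_transcripts);
  std::vector<uint64_t> kms;
  std::unordered_map<int, int> share;
  std::vector<int> tied;
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = Rcpp::as<std::string>(reads[r]);
    seq_kmers(s, idx->k, kms);
    share.clear();
    for (size_t z = 0; z < kms.size(); ++z) {
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          idx->map.find(kms[z]);
      if (it == idx->map.end()) continue;
      const std::vector<int>& post = it->second;
      for (size_t p = 0; p < post.size(); ++p) share[post[p]] += 1;
    }
    if (share.empty()) continue;
    int best = 0;
    for (std::unordered_map<int, int>::const_iterator it = share.begin();
         it != share.end(); ++it)
      if (it->second > best) best = it->second;
    if (best < min_share) continue;
    tied.clear();
    for (std::unordered_map<int, int>::const_iterator it = share.begin();
         it != share.end(); ++it)
      if (it->second == best) tied.push_back(it->first);
    double w = 1.0 / (double)tied.size();
    for (size_t z = 0; z < tied.size(); ++z) counts[tied[z]] += w;
  }
  return counts;
}

// [[Rcpp::export]]
CharacterVector canonical_kmers_cpp(std::string seq, int k) {
  std::vector<uint64_t> kms;
  seq_kmers(seq, k, kms);
  CharacterVector out(kms.size());
  const char* bases = "ACGT";
  for (size_t i = 0; i < kms.size(); ++i) {
    std::string s(k, 'A');
    uint64_t x = kms[i];
    for (int j = k - 1; j >= 0; --j) {
      s[j] = bases[x & 3ULL];
      x >>= 2;
    }
    out[i] = s;
  }
  return out;
}

// Six-frame translation under the standard genetic code: frames +1,+2,+3
// on the forward strand, -1,-2,-3 on the reverse complement; stops are
// '*', codons containing non-ACGT bases are 'X', trailing partial
// codons dropped. Returns a 6n vector, frame-major (all +1, all +2, ...).
static const char GENETIC_CODE_ACGT[65] =
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

static std::string translate_frame(const std::string& s, int off) {
  const int n = (int)s.size();
  std::string out;
  if (n - off < 3) return out;
  out.reserve((n - off) / 3);
  for (int i = off; i + 2 < n; i += 3) {
    int a = base2code(s[i]), b = base2code(s[i + 1]), c = base2code(s[i + 2]);
    if (a < 0 || b < 0 || c < 0) out.push_back('X');
    else out.push_back(GENETIC_CODE_ACGT[a * 16 + b * 4 + c]);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector six_frames_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(6 * n);
  for (int i = 0; i < n; ++i) {
    std::string s = Rcpp::as<std::string>(seqs[i]);
    std::string rc(s.size(), 'N');
    for (size_t z = 0; z < s.size(); ++z)
      rc[z] = comp_base(s[s.size() - 1 - z]);
    for (int f = 0; f < 3; ++f) {
      out[f * n + i] = translate_frame(s, f);
      out[(f + 3) * n + i] = translate_frame(rc, f);
    }
  }
  return out;
}
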