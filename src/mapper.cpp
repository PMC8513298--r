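// k-mer seeded, ungapped, end-to-end read mapper.
//
// Seeds are taken at every read position; a candidate placement is any
// (target, diagonal) receiving at least one seed, verified by Hamming
// comparison against the reference. With mismatch threshold
// m = floor(rate * len), any qualifying placement contains an exact stretch
// of length >= ceil((len - m) / (m + 1)); as long as k does not exceed that
// bound (k = 15 vs >= 49 for 100-base reads at 1%), every hit at or below
// the threshold is guaranteed to be seeded, so the hit set equals a
// brute-force Hamming scan. Non-ACGT bases never match anything (N is a
// mismatch even against N).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

inline char base_comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // kmer -> packed (target << 32 | pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > post;
};

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = base_comp(r[i]);
  return r;
}

// Hamming distance with early exit; non-ACGT counts as mismatch always.
inline int hamming_capped(const char* a, const char* b, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    char ca = a[i], cb = b[i];
    if (ca != cb || base_code(ca) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Hit {
  int target;
  int offset;
  char strand;
  int mm;
};

// Collect best-stratum hits of one read (both strands).
void map_one(const KmerIndex& idx, const std::string& read,
             double rate, std::vector<Hit>& out) {
  out.clear();
  const int len = (int)read.size();
  const int k = idx.k;
  if (len < k) return;
  const int cap0 = (int)std::floor(rate * len);
  int best = cap0 + 1;

  std::string rc = revcomp(read);
  std::vector<uint64_t> cand;

  for (int s = 0; s < 2; ++s) {
    const std::string& q = s == 0 ? read : rc;
    cand.clear();
    // rolling 2-bit k-mer with validity counter
    uint64_t kmer = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;  // run of valid bases ending here
    for (int i = 0; i < len; ++i) {
      int c = base_code(q[i]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      int start = i - k + 1;
      auto it = idx.post.find(kmer);
      if (it == idx.post.end()) continue;
      for (uint64_t packed : it->second) {
        int t = (int)(packed >> 32);
        int64_t off = (int64_t)(packed & 0xffffffffULL) - start;
        if (off < 0) continue;
        if (off + len > (int64_t)idx.seqs[t].size()) continue;
        cand.push_back(((uint64_t)t << 32) | (uint64_t)off);
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    for (uint64_t pc : cand) {
      int t = (int)(pc >> 32);
      int off = (int)(pc & 0xffffffffULL);
      int mm = hamming_capped(q.c_str(), idx.seqs[t].c_str() + off, len, cap0);
      if (mm > cap0) continue;
      if (mm < best) best = mm;
      Hit h; h.target = t; h.offset = off; h.strand = (s == 0 ? '+' : '-');
      h.mm = mm;
      out.push_back(h);
    }
  }
  // best stratum only
  std::vector<Hit> keep;
  for (const Hit& h : out) if (h.mm == best) keep.push_back(h);
  std::sort(keep.begin(), keep.end(), [](const Hit& a, const Hit& b) {
    if (a.target != b.target) return a.target < b.target;
    if (a.offset != b.offset) return a.offset < b.offset;
    return a.strand < b.strand;
  });
  out.swap(keep);
}

void check_alphabet(const std::string& s, int read_i) {
  for (char c : s) {
    if (base_code(c) < 0 && c != 'N')
      stop("read %d contains non-ACGTN symbol '%c'", read_i + 1, c);
  }
}

}  // namespace

// [[Rcpp::export(name = ".mx_index_build")]]
SEXP mx_index_build(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    idx->names.push_back(as<std::string>(names[i]));
    idx->seqs.push_back(as<std::string>(seqs[i]));
  }
  for (size_t t = 0; t < idx->seqs.size(); ++t) {
    const std::string& s = idx->seqs[t];
    if ((int)s.size() < k) {
      Rf_warning("reference '%s' shorter than k = %d; not seeded",
                 idx->names[t].c_str(), k);
      continue;
    }
    uint64_t kmer = 0;
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      uint64_t pos = (uint64_t)(i - k + 1);
      idx->post[kmer].push_back(((uint64_t)t << 32) | pos);
    }
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export(name = ".mx_ptr_ok")]]
bool mx_ptr_ok(SEXP xp) {
  return TYPEOF(xp) == EXTPTRSXP && R_ExternalPtrAddr(xp) != NULL;
}

// [[Rcpp::export(name = ".mx_index_k")]]
int mx_index_k(SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return p->k;
}

// [[Rcpp::export(name = ".mx_seed_postings")]]
DataFrame mx_seed_postings(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> p(xp);
  if ((int)kmer.size() != p->k) stop("kmer length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return DataFrame::create(_["target"] = IntegerVector(0),
                                        _["pos"] = IntegerVector(0));
    key = (key << 2) | (uint64_t)b;
  }
  std::vector<int> tg, pos;
  auto it = p->post.find(key);
  if (it != p->post.end()) {
    for (uint64_t packed : it->second) {
      tg.push_back((int)(packed >> 32) + 1);
      pos.push_back((int)(packed & 0xffffffffULL));
    }
  }
  return DataFrame::create(_["target"] = wrap(tg), _["pos"] = wrap(pos));
}

// [[Rcpp::export(name = ".mx_map")]]
DataFrame mx_map(SEXP xp, CharacterVector reads, double rate) {
  XPtr<KmerIndex> p(xp);
  std::vector<int> r_read, r_target, r_offset, r_mm;
  std::vector<char> r_strand;
  std::vector<Hit> hits;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    check_alphabet(rd, (int)i);
    map_one(*p, rd, rate, hits);
    for (const Hit& h : hits) {
      r_read.push_back((int)i + 1);
      r_target.push_back(h.target + 1);
      r_offset.push_back(h.offset);
      r_strand.push_back(h.strand);
      r_mm.push_back(h.mm);
    }
  }
  CharacterVector strands(r_strand.size());
  for (size_t i = 0; i < r_strand.size(); ++i)
    strands[i] = std::string(1, r_strand[i]);
  return DataFrame::create(
    _["read"] = wrap(r_read), _["target"] = wrap(r_target),
    _["offset"] = wrap(r_offset), _["strand"] = strands,
    _["mismatches"] = wrap(r_mm), _["stringsAsFactors"] = false);
}

// Pair outcome codes: 0 = unmapped (no end-to-end hit on either mate),
// 1 = concordant (same target, FR orientation, fragment within bounds),
// 2 = orphan/discordant.
// [[Rcpp::export(name = ".mx_pair_class")]]
IntegerVector mx_pair_class(SEXP xp, CharacterVector reads1,
                            CharacterVector reads2, double rate,
                            int frag_min, int frag_max) {
  XPtr<KmerIndex> p(xp);
  if (reads1.size() != reads2.size()) stop("mate vectors differ in length");
  IntegerVector out(reads1.size());
  std::vector<Hit> h1, h2;
  for (R_xlen_t i = 0; i < reads1.size(); ++i) {
    std::string a = as<std::string>(reads1[i]);
    std::string b = as<std::string>(reads2[i]);
    check_alphabet(a, (int)i);
    check_alphabet(b, (int)i);
    map_one(*p, a, rate, h1);
    map_one(*p, b, rate, h2);
    int la = (int)a.size(), lb = (int)b.size();
    if (h1.empty() && h2.empty()) { out[i] = 0; continue; }
    int code = 2;
    for (const Hit& x : h1) {
      for (const Hit& y : h2) {
        if (x.target != y.target) continue;
        if (x.strand == y.strand) continue;
        // FR orientation: forward mate must start at or before reverse mate
        const Hit& fwd = (x.strand == '+') ? x : y;
        const Hit& rev = (x.strand == '+') ? y : x;
        int lf = (x.strand == '+') ? la : lb;
        int lr = (x.strand == '+') ? lb : la;
        if (fwd.offset > rev.offset) continue;
        int frag = (rev.offset + lr) - fwd.offset;
        if (frag < std::max(frag_min, std::max(lf, lr)) || frag > frag_max)
          continue;
        code = 1;
        break;
      }
      if (code == 1) break;
    }
    out[i] = code;
  }
  return out;
}

// Per-base substitution errors at the given rate, using R's RNG.
// An erroneous base is replaced by one of the three other bases; N stays N.
// [[Rcpp::export(name = ".mx_mutate")]]
CharacterVector mx_mutate(CharacterVector reads, double rate) {
  static const char* subs[4] = {"CGT", "AGT", "ACT", "ACG"};
  CharacterVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() >= rate) continue;
      int b = base_code(s[j]);
      if (b < 0) continue;
      int r = (int)(unif_rand() * 3.0);
      if (r > 2) r = 2;
      s[j] = subs[b][r];
    }
    out[i] = s;
  }
  return out;
}
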