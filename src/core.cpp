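#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Hashing: FNV-1a over bytes followed by a 64-bit avalanche finaliser
// (Murmur3 fmix64).  Two seeded base hashes drive the double-hashing scheme
// position_i = (g1 + i*g2) mod m, i = 0..k-1.
// ---------------------------------------------------------------------------

static inline uint64_t fmix64(uint64_t h) {
  h ^= h >> 33;
  h *= 0xff51afd7ed558ccdULL;
  h ^= h >> 33;
  h *= 0xc4ceb9fe1a85ec53ULL;
  h ^= h >> 33;
  return h;
}

static inline uint64_t hash_bytes(const char *s, size_t n, uint64_t seed) {
  uint64_t h = 0xcbf29ce484222325ULL ^ (seed * 0x9e3779b97f4a7c15ULL);
  for (size_t i = 0; i < n; ++i) {
    h ^= (uint64_t)(uint8_t)s[i];
    h *= 0x100000001b3ULL;
  }
  return fmix64(h);
}

static inline void bloom_positions(const char *s, size_t n, int k, uint64_t m,
                                   uint64_t seed, std::vector<uint64_t> &out) {
  uint64_t g1 = hash_bytes(s, n, seed);
  uint64_t g2 = hash_bytes(s, n, seed ^ 0xa5a5a5a55a5a5a5aULL);
  if (m > 1 && g2 % m == 0) g2 = 1;  // keep the stride non-degenerate
  out.resize(k);
  for (int i = 0; i < k; ++i) out[i] = (g1 + (uint64_t)i * g2) % m;
}

// [[Rcpp::export]]
NumericVector hash_positions_cpp(std::string key, int k, double m, int seed) {
  if (k < 1 || m < 1) stop("k and m must be >= 1");
  std::vector<uint64_t> pos;
  bloom_positions(key.data(), key.size(), k, (uint64_t)m, (uint64_t)(uint32_t)seed, pos);
  NumericVector out(k);
  for (int i = 0; i < k; ++i) out[i] = (double)pos[i];
  return out;
}

// ---------------------------------------------------------------------------
// Nucleotide helpers
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Canonical form of a window s[i, i+b): lexicographic min of the window and
// its reverse complement, written into `out`.  Returns false if the window
// contains a non-ACGT character.
static inline bool canonical_window(const char *s, int i, int b, std::string &out) {
  for (int j = 0; j < b; ++j)
    if (!valid_base(s[i + j])) return false;
  // compare forward window with its reverse complement lazily
  bool take_rc = false;
  for (int j = 0; j < b; ++j) {
    char f = s[i + j];
    char r = comp_base(s[i + b - 1 - j]);
    if (f < r) { take_rc = false; break; }
    if (r < f) { take_rc = true; break; }
  }
  out.resize(b);
  if (!take_rc) {
    for (int j = 0; j < b; ++j) out[j] = s[i + j];
  } else {
    for (int j = 0; j < b; ++j) out[j] = comp_base(s[i + b - 1 - j]);
  }
  return true;
}

// [[Rcpp::export]]
CharacterVector canonical_bmer_cpp(CharacterVector s) {
  int n = s.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    if (s[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string x = as<std::string>(s[i]);
    if (canonical_window(x.data(), 0, (int)x.size(), buf)) out[i] = buf;
    else out[i] = NA_STRING;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector s) {
  int n = s.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (s[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(s[i]));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bloom filter bit-array primitives.  Bits live in an R raw vector of
// ceil(m/8) bytes; bit j is byte j>>3, mask 1 << (j & 7).
// ---------------------------------------------------------------------------

static inline void set_bit(Rbyte *bits, uint64_t j) {
  bits[j >> 3] |= (Rbyte)(1u << (j & 7u));
}
static inline bool get_bit(const Rbyte *bits, uint64_t j) {
  return (bits[j >> 3] >> (j & 7u)) & 1u;
}

// [[Rcpp::export]]
RawVector bf_insert_keys_cpp(RawVector bits, double m, int k, int seed,
                             CharacterVector keys) {
  RawVector out = clone(bits);
  uint64_t M = (uint64_t)m;
  std::vector<uint64_t> pos;
  for (int i = 0; i < keys.size(); ++i) {
    if (keys[i] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(keys, i));
    size_t n = LENGTH(STRING_ELT(keys, i));
    bloom_positions(s, n, k, M, (uint64_t)(uint32_t)seed, pos);
    for (int j = 0; j < k; ++j) set_bit(&out[0], pos[j]);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector bf_contains_keys_cpp(RawVector bits, double m, int k, int seed,
                                   CharacterVector keys) {
  uint64_t M = (uint64_t)m;
  int n = keys.size();
  LogicalVector out(n);
  std::vector<uint64_t> pos;
  for (int i = 0; i < n; ++i) {
    if (keys[i] == NA_STRING) { out[i] = NA_LOGICAL; continue; }
    const char *s = CHAR(STRING_ELT(keys, i));
    size_t len = LENGTH(STRING_ELT(keys, i));
    bloom_positions(s, len, k, M, (uint64_t)(uint32_t)seed, pos);
    bool hit = true;
    for (int j = 0; j < k && hit; ++j) hit = get_bit(&bits[0], pos[j]);
    out[i] = hit;
  }
  return out;
}

// [[Rcpp::export]]
double count_valid_bmers_cpp(CharacterVector seqs, int b) {
  double n = 0;
  for (int t = 0; t < seqs.size(); ++t) {
    const char *s = CHAR(STRING_ELT(seqs, t));
    int L = LENGTH(STRING_ELT(seqs, t));
    for (int i = 0; i + b <= L; ++i) {
      bool ok = true;
      for (int j = 0; j < b && ok; ++j) ok = valid_base(s[i + j]);
      if (ok) n += 1;
    }
  }
  return n;
}

// Insert every valid canonical b-mer of every sequence (stride 1) into a
// fresh bit array of m bits.  Returns list(bits, nInserted).
// [[Rcpp::export]]
List bf_build_cpp(CharacterVector seqs, int b, double m, int k, int seed) {
  uint64_t M = (uint64_t)m;
  RawVector bits((R_xlen_t)((M + 7) / 8));
  double inserted = 0;
  std::string canon;
  std::vector<uint64_t> pos;
  for (int t = 0; t < seqs.size(); ++t) {
    const char *s = CHAR(STRING_ELT(seqs, t));
    int L = LENGTH(STRING_ELT(seqs, t));
    for (int i = 0; i + b <= L; ++i) {
      if (!canonical_window(s, i, b, canon)) continue;
      bloom_positions(canon.data(), canon.size(), k, M, (uint64_t)(uint32_t)seed, pos);
      for (int j = 0; j < k; ++j) set_bit(&bits[0], pos[j]);
      inserted += 1;
    }
  }
  return List::create(_["bits"] = bits, _["nInserted"] = inserted);
}

// [[Rcpp::export]]
double popcount_raw_cpp(RawVector bits, double m) {
  uint64_t M = (uint64_t)m;
  double n = 0;
  for (uint64_t j = 0; j < M; ++j) if (get_bit(&bits[0], j)) n += 1;
  return n;
}

// ---------------------------------------------------------------------------
// Dispatch: scan every b-mer of every read against every partition filter
// (canonical form, N-containing windows skipped).  Early exit per partition
// after the first hit; the result is identical to scanning all windows.
// filters: list of list(bits, m, k, seed).
// Returns a list of sorted 1-based partition index vectors, one per read.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dispatch_reads_cpp(CharacterVector reads, List filters, int b) {
  int P = filters.size();
  std::vector<RawVector> fbits;
  std::vector<uint64_t> fm;
  std::vector<int> fk;
  std::vector<uint64_t> fseed;
  for (int p = 0; p < P; ++p) {
    List f = filters[p];
    fbits.push_back(as<RawVector>(f["bits"]));
    fm.push_back((uint64_t)as<double>(f["m"]));
    fk.push_back(as<int>(f["k"]));
    fseed.push_back((uint64_t)(uint32_t)as<int>(f["seed"]));
  }
  int nr = reads.size();
  List out(nr);
  std::string canon;
  std::vector<uint64_t> pos;
  std::vector<std::string> windows;
  for (int ri = 0; ri < nr; ++ri) {
    const char *s = CHAR(STRING_ELT(reads, ri));
    int L = LENGTH(STRING_ELT(reads, ri));
    windows.clear();
    for (int i = 0; i + b <= L; ++i)
      if (canonical_window(s, i, b, canon)) windows.push_back(canon);
    std::vector<int> dest;
    for (int p = 0; p < P; ++p) {
      bool hit_any = false;
      for (size_t w = 0; w < windows.size() && !hit_any; ++w) {
        bloom_positions(windows[w].data(), windows[w].size(), fk[p], fm[p],
                        fseed[p], pos);
        bool hit = true;
        for (int j = 0; j < fk[p] && hit; ++j) hit = get_bit(&fbits[p][0], pos[j]);
        hit_any = hit;
      }
      if (hit_any) dest.push_back(p + 1);
    }
    out[ri] = IntegerVector(dest.begin(), dest.end());
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seed index inspection: every l-mer occurrence of every target, canonical
// key, strand '+' when the forward l-mer equals its canonical form.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame seed_index_entries_cpp(CharacterVector targets, int l) {
  std::vector<std::string> kmer;
  std::vector<int> tgt;
  std::vector<int> offset;
  std::vector<std::string> strand;
  std::string canon;
  for (int t = 0; t < targets.size(); ++t) {
    const char *s = CHAR(STRING_ELT(targets, t));
    int L = LENGTH(STRING_ELT(targets, t));
    for (int i = 0; i + l <= L; ++i) {
      if (!canonical_window(s, i, l, canon)) continue;
      kmer.push_back(canon);
      tgt.push_back(t + 1);
      offset.push_back(i);
      bool fwd = true;
      for (int j = 0; j < l; ++j)
        if (s[i + j] != canon[j]) { fwd = false; break; }
      strand.push_back(fwd ? "+" : "-");
    }
  }
  return DataFrame::create(_["kmer"] = kmer, _["target"] = tgt,
                           _["offset"] = offset, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Exact-match seed-and-extend mapper.
//
// Index: exact forward l-mer -> occurrences (target, offset).  A read is
// queried in both orientations; each seed hit is extended to the maximal
// exact match on its diagonal.  Best record by (length desc, oriented read
// offset asc, target input order, target position, forward strand first).
// MAPQ 60 when the maximal length is achieved at a single (target, pos,
// strand), else 0.  CIGAR = soft-clipped flanks around a single M run.
// ---------------------------------------------------------------------------

struct SeedOcc { int t; int off; };

// [[Rcpp::export]]
DataFrame exact_map_cpp(CharacterVector targets, CharacterVector tnames,
                        CharacterVector reads, CharacterVector rnames, int l) {
  int nt = targets.size();
  std::vector<std::string> tseq(nt);
  for (int t = 0; t < nt; ++t) tseq[t] = as<std::string>(targets[t]);

  // index of exact forward l-mers
  std::unordered_map<std::string, std::vector<SeedOcc> > idx;
  for (int t = 0; t < nt; ++t) {
    const std::string &s = tseq[t];
    for (int i = 0; i + l <= (int)s.size(); ++i) {
      bool ok = true;
      for (int j = 0; j < l && ok; ++j) ok = valid_base(s[i + j]);
      if (!ok) continue;
      SeedOcc o; o.t = t; o.off = i;
      idx[s.substr(i, l)].push_back(o);
    }
  }

  int nr = reads.size();
  CharacterVector out_qname(nr), out_rname(nr), out_cigar(nr), out_seq(nr);
  IntegerVector out_flag(nr), out_pos(nr), out_mapq(nr), out_score(nr), out_nbest(nr);

  struct Cand { int len, qs, t, ts, strand; };

  for (int ri = 0; ri < nr; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string rev = revcomp(fwd);
    int L = (int)fwd.size();
    std::vector<Cand> cands;
    // memo of furthest extension end per (strand, target, diagonal)
    std::unordered_map<uint64_t, int> diag_done;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = (strand == 0) ? fwd : rev;
      for (int i = 0; i + l <= L; ++i) {
        std::unordered_map<std::string, std::vector<SeedOcc> >::iterator it =
            idx.find(q.substr(i, l));
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int t = it->second[h].t;
          int off = it->second[h].off;
          long diag = (long)off - (long)i;
          uint64_t key = ((uint64_t)(unsigned)(t * 2 + strand) << 33) ^
                         (uint64_t)(uint32_t)(diag + (1L << 30));
          std::unordered_map<uint64_t, int>::iterator dd = diag_done.find(key);
          if (dd != diag_done.end() && i < dd->second) continue;  // inside a prior run
          const std::string &T = tseq[t];
          int qs = i, qe = i + l, ts = off;
          while (qs > 0 && ts > 0 && q[qs - 1] == T[ts - 1] &&
                 valid_base(q[qs - 1])) { --qs; --ts; }
          int te = off + l;
          while (qe < L && te < (int)T.size() && q[qe] == T[te] &&
                 valid_base(q[qe])) { ++qe; ++te; }
          diag_done[key] = qe;
          Cand c; c.len = qe - qs; c.qs = qs; c.t = t; c.ts = ts; c.strand = strand;
          cands.push_back(c);
        }
      }
    }

    out_qname[ri] = rnames[ri];
    if (cands.empty()) {
      out_flag[ri] = 4; out_rname[ri] = "*"; out_pos[ri] = 0; out_mapq[ri] = 0;
      out_cigar[ri] = "*"; out_seq[ri] = fwd;
      out_score[ri] = NA_INTEGER; out_nbest[ri] = 0;
      continue;
    }
    int best = 0;
    for (size_t c = 1; c < cands.size(); ++c) {
      const Cand &a = cands[c], &b = cands[best];
      bool better =
          (a.len > b.len) ||
          (a.len == b.len && (a.qs < b.qs ||
           (a.qs == b.qs && (a.t < b.t ||
            (a.t == b.t && (a.ts < b.ts ||
             (a.ts == b.ts && a.strand < b.strand)))))));
      if (better) best = (int)c;
    }
    const Cand &bc = cands[best];
    // count distinct loci achieving the maximal length
    std::unordered_set<uint64_t> loci;
    for (size_t c = 0; c < cands.size(); ++c)
      if (cands[c].len == bc.len)
        loci.insert(((uint64_t)(unsigned)(cands[c].t * 2 + cands[c].strand) << 32) ^
                    (uint64_t)(uint32_t)cands[c].ts);
    int nbest = (int)loci.size();

    const std::string &q = (bc.strand == 0) ? fwd : rev;
    std::string cigar;
    if (bc.qs > 0) cigar += std::to_string(bc.qs) + "S";
    cigar += std::to_string(bc.len) + "M";
    int tail = L - (bc.qs + bc.len);
    if (tail > 0) cigar += std::to_string(tail) + "S";

    out_flag[ri] = (bc.strand == 1) ? 16 : 0;
    out_rname[ri] = tnames[bc.t];
    out_pos[ri] = bc.ts + 1;
    out_mapq[ri] = (nbest == 1) ? 60 : 0;
    out_cigar[ri] = cigar;
    out_seq[ri] = q;
    out_score[ri] = bc.len;
    out_nbest[ri] = nbest;
  }

  return DataFrame::create(
      _["qname"] = out_qname, _["flag"] = out_flag, _["rname"] = out_rname,
      _["pos"] = out_pos, _["mapq"] = out_mapq, _["cigar"] = out_cigar,
      _["seq"] = out_seq, _["AS"] = out_score, _["nbest"] = out_nbest,
      _["stringsAsFactors"] = false);
}
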