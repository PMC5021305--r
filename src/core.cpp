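// Compiled kernels: Phred arithmetic, adapter scanning, substitution noise,
// and the seed-and-extend local aligner (k-mer index + affine-gap
// Smith-Waterman on seed-defined windows).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <algorithm>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char rcbase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 'T';
    case 'C': return 'G'; case 'c': return 'G';
    case 'G': return 'C'; case 'g': return 'C';
    case 'T': return 'A'; case 't': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); i++) out[s.size() - 1 - i] = rcbase(s[i]);
  return out;
}

// ---------------------------------------------------------------- QC helpers

// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector qual) {
  int n = qual.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    const char* q = CHAR(STRING_ELT(qual, i));
    long sum = 0; int len = 0;
    for (; q[len]; len++) sum += q[len] - 33;
    out[i] = len ? (double)sum / len : R_NaN;
  }
  return out;
}

// length to keep after trimming 3' bases with quality < min_phred
// [[Rcpp::export]]
IntegerVector cpp_trim3_length(CharacterVector qual, int min_phred) {
  int n = qual.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    const char* q = CHAR(STRING_ELT(qual, i));
    int len = (int) strlen(q);
    while (len > 0 && (q[len - 1] - 33) < min_phred) len--;
    out[i] = len;
  }
  return out;
}

// leftmost 1-based start of a 3'-anchored adapter occurrence, NA if none
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector reads, std::string adapter,
                               int min_match, double max_mismatch_rate) {
  int n = reads.size();
  int alen = (int) adapter.size();
  IntegerVector out(n, NA_INTEGER);
  for (int r = 0; r < n; r++) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int) strlen(s);
    for (int i = 0; i < len; i++) {
      int ov = std::min(len - i, alen);
      if (ov < min_match) break;  // overlap only shrinks as i grows
      int mism = 0;
      int allowed = (int) std::floor(max_mismatch_rate * ov);
      for (int j = 0; j < ov && mism <= allowed; j++)
        if (s[i + j] != adapter[j]) mism++;
      if (mism <= allowed) { out[r] = i + 1; break; }
    }
  }
  return out;
}

// substitution-only sequencing noise; uses the R RNG for determinism
// [[Rcpp::export]]
CharacterVector cpp_add_substitutions(CharacterVector seqs, double rate) {
  RNGScope scope;
  int n = seqs.size();
  CharacterVector out(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int r = 0; r < n; r++) {
    std::string s = as<std::string>(seqs[r]);
    int len = (int) s.size();
    if (len > 0 && rate > 0) {
      int k = (int) R::rbinom((double) len, rate);
      for (int t = 0; t < k; t++) {
        int pos = (int) (unif_rand() * len);
        if (pos >= len) pos = len - 1;
        int code = base2bit(s[pos]);
        if (code < 0) continue;
        int shift = 1 + (int) (unif_rand() * 3);
        if (shift > 3) shift = 3;
        s[pos] = bases[(code + shift) % 4];
      }
    }
    out[r] = s;
  }
  return out;
}

// ------------------------------------------------------------ seed index

struct SeedIndex {
  int k;
  uint32_t mask;
  std::vector<std::string> fwd, rc;
  std::vector<std::string> names;
  std::unordered_map<uint32_t, std::vector<uint64_t>> post;
  std::vector<uint64_t> bits;   // k-mer presence bitset (k <= 13)
  bool use_bits;

  inline bool present(uint32_t km) const {
    if (!use_bits) return true;
    return (bits[km >> 6] >> (km & 63)) & 1ULL;
  }
};

static void add_kmers(SeedIndex& ix, const std::string& s, uint32_t seq,
                      uint32_t strand) {
  int k = ix.k;
  uint32_t val = 0;
  int run = 0;
  for (int pos = 0; pos < (int) s.size(); pos++) {
    int code = base2bit(s[pos]);
    if (code < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint32_t) code) & ix.mask;
    if (++run >= k) {
      uint64_t p = ((uint64_t) seq << 33) |
                   ((uint64_t) (pos - k + 1) << 1) | strand;
      ix.post[val].push_back(p);
      if (ix.use_bits) ix.bits[val >> 6] |= 1ULL << (val & 63);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 8 || k > 16) stop("seed length k must be in [8, 16]");
  XPtr<SeedIndex> xp(new SeedIndex(), true);
  xp->k = k;
  xp->mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  xp->use_bits = (k <= 13);
  if (xp->use_bits) xp->bits.assign((size_t(1) << (2 * k)) / 64 + 1, 0ULL);
  int n = seqs.size();
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(seqs[i]);
    xp->fwd.push_back(s);
    xp->rc.push_back(revcomp(s));
    xp->names.push_back(as<std::string>(names[i]));
    add_kmers(*xp, xp->fwd[i], (uint32_t) i, 0u);
    add_kmers(*xp, xp->rc[i], (uint32_t) i, 1u);
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xpsexp) {
  XPtr<SeedIndex> xp(xpsexp);
  size_t np = 0;
  for (auto& kv : xp->post) np += kv.second.size();
  return List::create(_["k"] = xp->k,
                      _["n_seqs"] = (int) xp->fwd.size(),
                      _["seq_ids"] = wrap(xp->names),
                      _["n_postings"] = (double) np);
}

// postings for one k-mer string (test/diagnostic surface)
// [[Rcpp::export]]
DataFrame cpp_index_lookup(SEXP xpsexp, std::string kmer) {
  XPtr<SeedIndex> xp(xpsexp);
  if ((int) kmer.size() != xp->k) stop("k-mer length must equal index k");
  uint32_t val = 0;
  for (char c : kmer) {
    int code = base2bit(c);
    if (code < 0)
      return DataFrame::create(_["seq_id"] = CharacterVector(0),
                               _["pos"] = IntegerVector(0),
                               _["strand"] = CharacterVector(0));
    val = (val << 2) | (uint32_t) code;
  }
  std::vector<std::string> sid;
  std::vector<int> pos;
  std::vector<std::string> strand;
  auto it = xp->post.find(val);
  if (it != xp->post.end()) {
    for (uint64_t p : it->second) {
      sid.push_back(xp->names[p >> 33]);
      pos.push_back((int) ((p >> 1) & 0xFFFFFFFFu));
      strand.push_back((p & 1) ? "-" : "+");
    }
  }
  return DataFrame::create(_["seq_id"] = wrap(sid), _["pos"] = wrap(pos),
                           _["strand"] = wrap(strand),
                           _["stringsAsFactors"] = false);
}

// posting counts per (seq, strand)
// [[Rcpp::export]]
DataFrame cpp_index_counts(SEXP xpsexp) {
  XPtr<SeedIndex> xp(xpsexp);
  size_t n = xp->fwd.size();
  std::vector<double> fc(n, 0), rcnt(n, 0);
  for (auto& kv : xp->post)
    for (uint64_t p : kv.second) {
      if (p & 1) rcnt[p >> 33]++; else fc[p >> 33]++;
    }
  CharacterVector sid(2 * n);
  CharacterVector strand(2 * n);
  NumericVector cnt(2 * n);
  for (size_t i = 0; i < n; i++) {
    sid[2 * i] = xp->names[i];     strand[2 * i] = "+"; cnt[2 * i] = fc[i];
    sid[2 * i + 1] = xp->names[i]; strand[2 * i + 1] = "-"; cnt[2 * i + 1] = rcnt[i];
  }
  return DataFrame::create(_["seq_id"] = sid, _["strand"] = strand,
                           _["count"] = cnt, _["stringsAsFactors"] = false);
}

// ------------------------------------------------- local affine-gap aligner

struct Aln {
  int score = 0, matches = 0, cols = 0, qs = 0, qe = 0, ss = 0, se = 0;
};

// local alignment; gap of length L costs go + ge*L
static Aln smith_waterman(const char* q, int m, const char* s, int n,
                          int ma, int mi, int go, int ge) {
  const int NEG = INT_MIN / 4;
  std::vector<int> Hp(n + 1, 0), Hc(n + 1, 0), F(n + 1, NEG);
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0),
      tbE((size_t)(m + 1) * (n + 1), 0), tbF((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; i++) {
    Hc[0] = 0;
    int Ei = NEG;
    size_t row = (size_t) i * (n + 1);
    for (int j = 1; j <= n; j++) {
      int eH = Hc[j - 1] - go - ge;
      int eE = Ei - ge;
      int e = std::max(eH, eE);
      tbE[row + j] = (eE >= eH) ? 1 : 0;
      Ei = e;
      int fH = Hp[j] - go - ge;
      int fF = F[j] - ge;
      int f = std::max(fH, fF);
      tbF[row + j] = (fF >= fH) ? 1 : 0;
      F[j] = f;
      bool match = (q[i - 1] == s[j - 1]) && q[i - 1] != 'N' && s[j - 1] != 'N';
      int diag = Hp[j - 1] + (match ? ma : mi);
      int h = 0; uint8_t mv = 0;
      if (diag > h) { h = diag; mv = 1; }
      if (e > h) { h = e; mv = 2; }
      if (f > h) { h = f; mv = 3; }
      Hc[j] = h; tbH[row + j] = mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hp, Hc);
  }
  Aln a;
  if (best == 0) return a;
  a.score = best; a.qe = bi; a.se = bj;
  int i = bi, j = bj;
  char st = 'H';
  while (true) {
    size_t row = (size_t) i * (n + 1);
    if (st == 'H') {
      uint8_t mv = tbH[row + j];
      if (mv == 0) break;
      if (mv == 1) {
        bool match = (q[i - 1] == s[j - 1]) && q[i - 1] != 'N' && s[j - 1] != 'N';
        a.matches += match; a.cols++; i--; j--;
      } else if (mv == 2) st = 'E';
      else st = 'F';
    } else if (st == 'E') {
      uint8_t ext = tbE[row + j];
      a.cols++; j--;
      if (!ext) st = 'H';
    } else {
      uint8_t ext = tbF[row + j];
      a.cols++; i--;
      if (!ext) st = 'H';
    }
  }
  a.qs = i; a.ss = j;
  return a;
}

struct Seed { uint64_t key; int diag, qpos, spos; };

struct BestHit {
  int score = -1, matches = 0, cols = 0, qs = 0, qe = 0, ss = 0, se = 0;
  char strand = '+';
};

// [[Rcpp::export]]
DataFrame cpp_align_reads(SEXP xpsexp, CharacterVector reads,
                          int min_seed_count, int min_seed_span, int pad,
                          int diag_gap, int ma, int mi, int go, int ge,
                          int min_score) {
  XPtr<SeedIndex> xp(xpsexp);
  SeedIndex& IX = *xp;            // avoid per-k-mer external-pointer derefs
  const int k = IX.k;
  const uint32_t mask = IX.mask;
  std::vector<int> o_read, o_seq, o_score, o_matches, o_cols,
      o_qs, o_qe, o_ss, o_se;
  std::vector<std::string> o_strand;

  std::vector<Seed> seeds;
  for (int r = 0; r < reads.size(); r++) {
    const char* rs = CHAR(STRING_ELT(reads, r));
    int len = (int) strlen(rs);
    if (len < k) continue;
    seeds.clear();
    uint32_t val = 0; int run = 0;
    for (int pos = 0; pos < len; pos++) {
      int code = base2bit(rs[pos]);
      if (code < 0) { run = 0; val = 0; continue; }
      val = ((val << 2) | (uint32_t) code) & mask;
      if (++run >= k) {
        if (!IX.present(val)) continue;
        auto it = IX.post.find(val);
        if (it == IX.post.end()) continue;
        int qpos = pos - k + 1;
        for (uint64_t p : it->second) {
          Seed sd;
          sd.key = (p >> 33) * 2 + (p & 1);
          sd.spos = (int) ((p >> 1) & 0xFFFFFFFFu);
          sd.qpos = qpos;
          sd.diag = sd.spos - qpos;
          seeds.push_back(sd);
        }
      }
    }
    if (seeds.empty()) continue;
    std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
      if (a.key != b.key) return a.key < b.key;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.spos < b.spos;
    });
    std::unordered_map<uint32_t, BestHit> bests;
    size_t i0 = 0;
    while (i0 < seeds.size()) {
      size_t i1 = i0 + 1;
      while (i1 < seeds.size() && seeds[i1].key == seeds[i0].key &&
             seeds[i1].diag - seeds[i1 - 1].diag <= diag_gap &&
             seeds[i1].spos - seeds[i1 - 1].spos <= len + 2 * pad)
        i1++;
      int count = (int) (i1 - i0);
      int qmin = seeds[i0].qpos, qmax = seeds[i0].qpos;
      for (size_t t = i0; t < i1; t++) {
        qmin = std::min(qmin, seeds[t].qpos);
        qmax = std::max(qmax, seeds[t].qpos);
      }
      // overlapping k-mers from one chance match are not independent
      // evidence: demand the cluster's seeds span >= min_seed_span bases
      if (count >= min_seed_count && qmax - qmin >= min_seed_span) {
        uint32_t seq = (uint32_t) (seeds[i0].key >> 1);
        int strand = (int) (seeds[i0].key & 1);
        const std::string& subj = strand ? IX.rc[seq] : IX.fwd[seq];
        int slen = (int) subj.size();
        int dmin = seeds[i0].diag, dmax = seeds[i0].diag;
        for (size_t t = i0; t < i1; t++) {
          dmin = std::min(dmin, seeds[t].diag);
          dmax = std::max(dmax, seeds[t].diag);
        }
        int ws = std::max(0, dmin - pad);
        int we = std::min(slen, dmax + len + pad);
        if (we > ws) {
          Aln a = smith_waterman(rs, len, subj.c_str() + ws, we - ws,
                                 ma, mi, go, ge);
          if (a.score >= min_score) {
            int ss = ws + a.ss, se = ws + a.se;
            if (strand) { int t = ss; ss = slen - se; se = slen - t; }
            BestHit& b = bests[seq];
            bool better = a.score > b.score ||
              (a.score == b.score &&
               (double) a.matches * b.cols > (double) b.matches * a.cols);
            if (better) {
              b.score = a.score; b.matches = a.matches; b.cols = a.cols;
              b.qs = a.qs; b.qe = a.qe; b.ss = ss; b.se = se;
              b.strand = strand ? '-' : '+';
            }
          }
        }
      }
      i0 = i1;
    }
    for (auto& kv : bests) {
      o_read.push_back(r + 1);
      o_seq.push_back((int) kv.first + 1);
      o_score.push_back(kv.second.score);
      o_matches.push_back(kv.second.matches);
      o_cols.push_back(kv.second.cols);
      o_qs.push_back(kv.second.qs);
      o_qe.push_back(kv.second.qe);
      o_ss.push_back(kv.second.ss);
      o_se.push_back(kv.second.se);
      o_strand.push_back(std::string(1, kv.second.strand));
    }
  }
  return DataFrame::create(
      _["read"] = wrap(o_read), _["seq"] = wrap(o_seq),
      _["strand"] = wrap(o_strand), _["raw_score"] = wrap(o_score),
      _["matches"] = wrap(o_matches), _["alignment_length"] = wrap(o_cols),
      _["read_start"] = wrap(o_qs), _["read_end"] = wrap(o_qe),
      _["subject_start"] = wrap(o_ss), _["subject_end"] = wrap(o_se),
      _["stringsAsFactors"] = false);
}
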