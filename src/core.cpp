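// Compiled kernels: 2-bit word encoding, the murmur64 finalizer hash,
// 5-byte hash-table row encoding/decoding with linked lists, query-context
// head fetches, gapless x-drop extension and banded affine semi-global DP.
// Coordinates cross the R boundary as doubles (exact below 2^53).
#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdio>
using namespace Rcpp;

static const double NEG_INF = -1e18;

// ---------------------------------------------------------------- hashing

static inline uint64_t fmix64(uint64_t x) {
  x ^= x >> 33;
  x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33;
  x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}

static inline int base_code(unsigned char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export]]
double encode_word_cpp(std::string word) {
  uint64_t w = 0;
  if (word.size() < 1 || word.size() > 26)
    stop("word length must be in [1, 26] for exact R-side encoding");
  for (size_t i = 0; i < word.size(); ++i) {
    int c = base_code((unsigned char)word[i]);
    if (c < 0) return NA_REAL;
    w = (w << 2) | (uint64_t)c;
  }
  return (double)w;
}

// [[Rcpp::export]]
double revcomp_word_cpp(double wd, int k) {
  uint64_t w = (uint64_t)wd, rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (w & 3ULL));
    w >>= 2;
  }
  return (double)rc;
}

// Hex rendering of the 64-bit finalizer output, for bit-exact comparison
// against an independent implementation.
// [[Rcpp::export]]
std::string fmix64_hex_cpp(double xd) {
  uint64_t x = fmix64((uint64_t)xd);
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export]]
NumericVector hash_slot_cpp(NumericVector words, double Hd) {
  uint64_t H = (uint64_t)Hd;
  if (H < 2) stop("H must be >= 2");
  NumericVector out(words.size());
  for (R_xlen_t i = 0; i < words.size(); ++i) {
    if (NumericVector::is_na(words[i])) { out[i] = NA_REAL; continue; }
    out[i] = (double)(fmix64((uint64_t)words[i]) % H);
  }
  return out;
}

// ---------------------------------------------------------- k-mer census

// Rolling scan of the packed genome: for every N-free k-mer at global
// position i, its plus-strand slot (positions recorded) and the slot of its
// reverse complement (minus-strand abundance only). Contig boundaries are
// handled by the caller inserting 'N' is NOT done; instead boundaries are
// passed so words never span two sequences.
struct Census {
  std::unordered_map<uint64_t, std::vector<uint32_t> > plus;
  std::unordered_map<uint64_t, uint32_t> minus;
};

static void census_scan(const RawVector& genome, int k, uint64_t H,
                        const std::vector<uint64_t>& starts,
                        const std::vector<uint64_t>& lens,
                        Census& cen) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (size_t s = 0; s < starts.size(); ++s) {
    uint64_t beg = starts[s], len = lens[s];
    if (len < (uint64_t)k) continue;
    uint64_t w = 0, rc = 0;
    int valid = 0; // number of consecutive valid bases ending at current
    for (uint64_t i = 0; i < len; ++i) {
      int c = base_code(genome[beg + i]);
      if (c < 0) { valid = 0; w = 0; rc = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t pos = beg + i - (uint64_t)k + 1;
        uint64_t sp = fmix64(w) % H;
        uint64_t sm = fmix64(rc) % H;
        cen.plus[sp].push_back((uint32_t)pos);
        cen.minus[sm] += 1;
      }
    }
  }
}

// Brute-force-comparable census as R lists (used by build and exposable for
// diagnostics; tests use an independent R-level census instead).
// [[Rcpp::export]]
List census_cpp(RawVector genome, int k, double Hd,
                NumericVector seq_starts, NumericVector seq_lens) {
  uint64_t H = (uint64_t)Hd;
  std::vector<uint64_t> st(seq_starts.begin(), seq_starts.end());
  std::vector<uint64_t> ln(seq_lens.begin(), seq_lens.end());
  Census cen;
  census_scan(genome, k, H, st, ln, cen);
  std::vector<uint64_t> slots;
  slots.reserve(cen.plus.size());
  for (auto& kv : cen.plus) slots.push_back(kv.first);
  std::sort(slots.begin(), slots.end());
  NumericVector slot_out(slots.size());
  IntegerVector minus_out(slots.size());
  List pos_out(slots.size());
  for (size_t i = 0; i < slots.size(); ++i) {
    slot_out[i] = (double)slots[i];
    auto& ps = cen.plus[slots[i]];
    std::sort(ps.begin(), ps.end());
    NumericVector pv(ps.size());
    for (size_t j = 0; j < ps.size(); ++j) pv[j] = (double)ps[j];
    pos_out[i] = pv;
    auto it = cen.minus.find(slots[i]);
    minus_out[i] = (it == cen.minus.end()) ? 0 : (int)it->second;
  }
  return List::create(_["slot"] = slot_out, _["positions"] = pos_out,
                      _["minus_count"] = minus_out);
}

// ------------------------------------------------------------- row codec
//
// Tally byte codes (bit 0x80 = slot present):
//   0x00        empty
//   0xFF        pin                     value = coordinate
//   0xFE        singleton               value = coordinate
//   0x81-0xFC   multi head, skip 1-124  value = first coordinate
//   0xFD        multi head, overflow    value = absolute row pointer
//   0x01-0x7D   list interior, skip     value = coordinate
//   0x7E        list end                value = coordinate
//   0x7F        interior overflow       value = absolute row pointer

static inline void put_row(RawVector& rows, uint64_t r, uint8_t tally, uint32_t v) {
  R_xlen_t o = (R_xlen_t)r * 5;
  rows[o] = tally;
  rows[o + 1] = (uint8_t)(v & 0xFF);
  rows[o + 2] = (uint8_t)((v >> 8) & 0xFF);
  rows[o + 3] = (uint8_t)((v >> 16) & 0xFF);
  rows[o + 4] = (uint8_t)((v >> 24) & 0xFF);
}

static inline uint8_t row_tally(const RawVector& rows, uint64_t r) {
  return rows[(R_xlen_t)r * 5];
}

static inline uint32_t row_value(const RawVector& rows, uint64_t r) {
  R_xlen_t o = (R_xlen_t)r * 5;
  return (uint32_t)rows[o + 1] | ((uint32_t)rows[o + 2] << 8) |
         ((uint32_t)rows[o + 3] << 16) | ((uint32_t)rows[o + 4] << 24);
}

static uint64_t next_empty(const std::vector<char>& used, uint64_t from, uint64_t H) {
  uint64_t r = (from + 1) % H;
  uint64_t n = 0;
  while (used[r]) {
    r = (r + 1) % H;
    if (++n > H) stop("hash table full: no empty row for linked list");
  }
  return r;
}

// Encode rows from a classified census. Slots are processed in increasing
// slot order; interior list rows are taken from the nearest empty rows
// scanning forward (wrapping at H). `plus_positions` are sorted 0-based
// global coordinates; over-abundant slots must already be removed.
static RawVector encode_rows(const std::vector<uint64_t>& slots,
                             const std::vector<std::vector<uint32_t> >& pos,
                             uint64_t H) {
  if (H >= (1ULL << 32)) stop("H >= 2^32 not supported by 32-bit row pointers");
  RawVector rows((R_xlen_t)H * 5); // zero-initialised = empty
  std::vector<char> used(H, 0);
  for (size_t i = 0; i < slots.size(); ++i) used[slots[i]] = 1;
  for (size_t i = 0; i < slots.size(); ++i) {
    uint64_t s = slots[i];
    const std::vector<uint32_t>& ps = pos[i];
    size_t m = ps.size();
    if (m == 0) stop("internal: present slot with no positions");
    if (m == 1) continue; // pin/singleton written by caller (needs minus info)
    size_t idx = 0;
    uint64_t cur = s;
    bool head = true;
    while (idx < m) {
      if (head) {
        uint64_t ne = next_empty(used, s, H);
        uint64_t d = (ne + H - s) % H;
        if (d <= 124) {
          put_row(rows, s, (uint8_t)(0x80 | d), ps[0]);
          idx = 1;
        } else {
          put_row(rows, s, 0xFD, (uint32_t)ne);
        }
        used[ne] = 1;
        cur = ne;
        head = false;
      } else {
        size_t rem = m - idx;
        if (rem == 1) {
          put_row(rows, cur, 0x7E, ps[idx]);
          ++idx;
        } else {
          uint64_t ne = next_empty(used, cur, H);
          uint64_t d = (ne + H - cur) % H;
          if (d <= 0x7D) {
            put_row(rows, cur, (uint8_t)d, ps[idx]);
            ++idx;
          } else {
            put_row(rows, cur, 0x7F, (uint32_t)ne);
          }
          used[ne] = 1;
          cur = ne;
        }
      }
    }
  }
  return rows;
}

// Build rows straight from a census given as R vectors (also the entry point
// for adversarial row-layout tests with hand-chosen slots).
// [[Rcpp::export]]
RawVector encode_rows_cpp(NumericVector slots, List plus_positions,
                          IntegerVector minus_counts, double Hd) {
  uint64_t H = (uint64_t)Hd;
  size_t n = slots.size();
  std::vector<uint64_t> sl(n);
  std::vector<std::vector<uint32_t> > ps(n);
  for (size_t i = 0; i < n; ++i) {
    sl[i] = (uint64_t)slots[i];
    if (sl[i] >= H) stop("slot out of range");
    NumericVector pv = plus_positions[i];
    ps[i].assign(pv.size(), 0);
    for (R_xlen_t j = 0; j < pv.size(); ++j) ps[i][j] = (uint32_t)pv[j];
    std::sort(ps[i].begin(), ps[i].end());
  }
  // sort by slot for deterministic list placement
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return sl[a] < sl[b]; });
  std::vector<uint64_t> sl2(n);
  std::vector<std::vector<uint32_t> > ps2(n);
  std::vector<int> mc2(n);
  for (size_t i = 0; i < n; ++i) {
    sl2[i] = sl[ord[i]];
    ps2[i] = ps[ord[i]];
    mc2[i] = minus_counts[ord[i]];
  }
  RawVector rows = encode_rows(sl2, ps2, H);
  for (size_t i = 0; i < n; ++i) {
    if (ps2[i].size() == 1)
      put_row(rows, sl2[i], mc2[i] > 0 ? 0xFE : 0xFF, ps2[i][0]);
  }
  return rows;
}

// [[Rcpp::export]]
List build_rows_cpp(RawVector genome, int k, int t, double Hd,
                    NumericVector seq_starts, NumericVector seq_lens) {
  uint64_t H = (uint64_t)Hd;
  std::vector<uint64_t> st(seq_starts.begin(), seq_starts.end());
  std::vector<uint64_t> ln(seq_lens.begin(), seq_lens.end());
  Census cen;
  census_scan(genome, k, H, st, ln, cen);
  std::vector<uint64_t> slots;
  slots.reserve(cen.plus.size());
  double n_excluded = 0, n_pin = 0, n_single = 0, n_multi = 0;
  for (auto& kv : cen.plus) {
    uint32_t pc = (uint32_t)kv.second.size();
    auto it = cen.minus.find(kv.first);
    uint32_t mc = (it == cen.minus.end()) ? 0 : it->second;
    if (pc > (uint32_t)t || mc > (uint32_t)t) { n_excluded++; continue; }
    slots.push_back(kv.first);
    if (pc == 1 && mc == 0) n_pin++;
    else if (pc == 1) n_single++;
    else n_multi++;
  }
  std::sort(slots.begin(), slots.end());
  std::vector<std::vector<uint32_t> > pos(slots.size());
  for (size_t i = 0; i < slots.size(); ++i) {
    pos[i] = cen.plus[slots[i]];
    std::sort(pos[i].begin(), pos[i].end());
  }
  RawVector rows = encode_rows(slots, pos, H);
  for (size_t i = 0; i < slots.size(); ++i) {
    if (pos[i].size() == 1) {
      auto it = cen.minus.find(slots[i]);
      uint32_t mc = (it == cen.minus.end()) ? 0 : it->second;
      put_row(rows, slots[i], mc > 0 ? 0xFE : 0xFF, pos[i][0]);
    }
  }
  return List::create(_["rows"] = rows,
                      _["n_pin"] = n_pin, _["n_singleton"] = n_single,
                      _["n_multi"] = n_multi, _["n_excluded"] = n_excluded);
}

// status codes: 0 absent, 1 pin, 2 singleton, 3 multi
static int decode_chain(const RawVector& rows, uint64_t H, uint64_t s,
                        std::vector<uint32_t>& out, int* fetched) {
  uint8_t tal = row_tally(rows, s);
  *fetched = 1;
  if (!(tal & 0x80)) return 0;
  if (tal == 0xFF) { out.push_back(row_value(rows, s)); return 1; }
  if (tal == 0xFE) { out.push_back(row_value(rows, s)); return 2; }
  uint64_t cur;
  if (tal == 0xFD) {
    cur = row_value(rows, s);
  } else {
    out.push_back(row_value(rows, s));
    cur = (s + (uint64_t)(tal & 0x7F)) % H;
  }
  uint64_t steps = 0;
  for (;;) {
    if (cur >= H) stop("index corruption: row pointer out of range");
    if (++steps > H) stop("index corruption: linked-list cycle");
    uint8_t ti = row_tally(rows, cur);
    (*fetched)++;
    if (ti & 0x80) stop("index corruption: interior row has present bit set");
    if (ti == 0x7E) { out.push_back(row_value(rows, cur)); break; }
    if (ti == 0x7F) { cur = row_value(rows, cur); continue; }
    if (ti >= 0x01 && ti <= 0x7D) {
      out.push_back(row_value(rows, cur));
      cur = (cur + (uint64_t)ti) % H;
      continue;
    }
    stop("index corruption: empty row inside linked list");
  }
  return 3;
}

// [[Rcpp::export]]
List decode_slot_cpp(RawVector rows, double Hd, double slotd) {
  uint64_t H = (uint64_t)Hd, s = (uint64_t)slotd;
  if (s >= H) stop("slot out of range");
  std::vector<uint32_t> pos;
  int fetched = 0;
  int status = decode_chain(rows, H, s, pos, &fetched);
  NumericVector pv(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) pv[i] = (double)pos[i];
  return List::create(_["status"] = status, _["positions"] = pv,
                      _["rows_fetched"] = fetched);
}

// Decode every present head row in the table (oracle-equivalence tests).
// [[Rcpp::export]]
List decode_all_cpp(RawVector rows, double Hd) {
  uint64_t H = (uint64_t)Hd;
  std::vector<double> slots;
  std::vector<int> status;
  std::vector<std::vector<uint32_t> > pos;
  for (uint64_t r = 0; r < H; ++r) {
    uint8_t tal = row_tally(rows, r);
    if (!(tal & 0x80)) continue;
    std::vector<uint32_t> p;
    int f = 0;
    int st = decode_chain(rows, H, r, p, &f);
    slots.push_back((double)r);
    status.push_back(st);
    pos.push_back(p);
  }
  List pl(pos.size());
  for (size_t i = 0; i < pos.size(); ++i) {
    NumericVector pv(pos[i].size());
    for (size_t j = 0; j < pos[i].size(); ++j) pv[j] = (double)pos[i][j];
    pl[i] = pv;
  }
  return List::create(_["slot"] = NumericVector(slots.begin(), slots.end()),
                      _["status"] = IntegerVector(status.begin(), status.end()),
                      _["positions"] = pl);
}

// ----------------------------------------------------------- query context

// For each scheduled query position, the slot value and head-row summary for
// the plus-strand word and its reverse complement. Only head rows are
// fetched (linked lists are chased lazily in later passes).
// status: -1 word contains N, 0 absent, 1 pin, 2 singleton,
//          3 multi (value = first coordinate), 4 multi overflow head.
// [[Rcpp::export]]
List query_context_cpp(RawVector rows, double Hd, std::string read, int k,
                       IntegerVector sched) {
  uint64_t H = (uint64_t)Hd;
  int L = (int)read.size();
  int n = L - k + 1;
  if (n < 1) stop("read shorter than k");
  // forward-scan all word encodings once
  std::vector<uint64_t> wv(n), rcv(n);
  std::vector<char> ok(n, 0);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t w = 0, rc = 0;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int c = base_code((unsigned char)read[i]);
    if (c < 0) { valid = 0; continue; }
    w = ((w << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) {
      int p = i - k + 1;
      wv[p] = w; rcv[p] = rc; ok[p] = 1;
    }
  }
  int ns = sched.size();
  NumericVector slot_p(ns), slot_m(ns), val_p(ns), val_m(ns);
  IntegerVector st_p(ns), st_m(ns);
  int fetches = 0;
  for (int j = 0; j < ns; ++j) {
    int p = sched[j];
    if (p < 0 || p >= n) stop("scheduled position out of range");
    if (!ok[p]) {
      st_p[j] = st_m[j] = -1;
      slot_p[j] = slot_m[j] = val_p[j] = val_m[j] = NA_REAL;
      continue;
    }
    uint64_t sp = fmix64(wv[p]) % H;
    uint64_t sm = fmix64(rcv[p]) % H;
    slot_p[j] = (double)sp;
    slot_m[j] = (double)sm;
    for (int strand = 0; strand < 2; ++strand) {
      uint64_t s = strand == 0 ? sp : sm;
      uint8_t tal = row_tally(rows, s);
      uint32_t v = row_value(rows, s);
      ++fetches;
      int st;
      double val = NA_REAL;
      if (!(tal & 0x80)) st = 0;
      else if (tal == 0xFF) { st = 1; val = (double)v; }
      else if (tal == 0xFE) { st = 2; val = (double)v; }
      else if (tal == 0xFD) { st = 4; }
      else { st = 3; val = (double)v; }
      if (strand == 0) { st_p[j] = st; val_p[j] = val; }
      else { st_m[j] = st; val_m[j] = val; }
    }
  }
  return List::create(_["pos"] = sched,
                      _["slot_plus"] = slot_p, _["status_plus"] = st_p,
                      _["value_plus"] = val_p,
                      _["slot_minus"] = slot_m, _["status_minus"] = st_m,
                      _["value_minus"] = val_m,
                      _["row_fetches"] = fetches);
}

// ------------------------------------------------------------- alignment

// Gapless x-drop extension of a length-k seed. The seed block itself is
// counted as k matches without verification (collisions are caught by the
// mismatching flanks). Returns the maximal-scoring extension endpoints.
// [[Rcpp::export]]
List xdrop_extend_cpp(std::string query, RawVector genome, int qpos,
                      double rposd, int k, double ref_lo, double ref_hi,
                      double x, int match, int mismatch) {
  int L = (int)query.size();
  int64_t rpos = (int64_t)rposd;
  int64_t lo = (int64_t)ref_lo, hi = (int64_t)ref_hi;
  // left extension
  double run = 0, best = 0;
  int bestL = 0;
  for (int i = 1; qpos - i >= 0 && rpos - i >= lo; ++i) {
    unsigned char qc = query[qpos - i];
    unsigned char gc = genome[(R_xlen_t)(rpos - i)];
    bool m = (base_code(qc) >= 0) && qc == gc;
    run += m ? match : mismatch;
    if (run > best) { best = run; bestL = i; }
    if (run < best - x) break;
  }
  double scoreL = best;
  // right extension
  run = 0; best = 0;
  int bestR = 0;
  for (int i = 0; qpos + k + i < L && rpos + k + i < hi; ++i) {
    unsigned char qc = query[qpos + k + i];
    unsigned char gc = genome[(R_xlen_t)(rpos + k + i)];
    bool m = (base_code(qc) >= 0) && qc == gc;
    run += m ? match : mismatch;
    if (run > best) { best = run; bestR = i + 1; }
    if (run < best - x) break;
  }
  double scoreR = best;
  double score = (double)k * match + scoreL + scoreR;
  return List::create(_["qstart"] = qpos - bestL,
                      _["qend"] = qpos + k + bestR,
                      _["rstart"] = (double)(rpos - bestL),
                      _["score"] = score);
}

// Count identities of query against genome at rstart (rescoring helper).
// [[Rcpp::export]]
double score_identity_cpp(std::string query, RawVector genome, double rstartd,
                          int match, int mismatch) {
  int64_t r = (int64_t)rstartd;
  double s = 0;
  for (size_t i = 0; i < query.size(); ++i) {
    unsigned char qc = query[i];
    unsigned char gc = genome[(R_xlen_t)(r + (int64_t)i)];
    s += ((base_code(qc) >= 0) && qc == gc) ? match : mismatch;
  }
  return s;
}

// Banded affine semi-global alignment: the whole query must be aligned, the
// reference window is free at both ends. Cells are restricted to the band
// around the HSP diagonal. Gap of length g costs gap_open + g * gap_extend.
// [[Rcpp::export]]
List banded_align_cpp(std::string query, RawVector genome, double ref_lo,
                      double ref_hi, double hsp_rstartd, int hsp_qstart,
                      int band, int match, int mismatch, int gap_open,
                      int gap_extend) {
  int m = (int)query.size();
  int64_t lo = (int64_t)ref_lo, hi = (int64_t)ref_hi;
  int64_t d0 = (int64_t)hsp_rstartd - hsp_qstart; // global start diagonal
  int64_t ws = d0 - band; if (ws < lo) ws = lo;
  int64_t we = d0 + m + band; if (we > hi) we = hi;
  int n = (int)(we - ws);
  if (n < 1) return List::create(_["feasible"] = false);
  int off = (int)(d0 - ws); // band centre: j - i == off
  // 3-state DP over (m+1) x (n+1); row-major flattened
  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<double> M(sz, NEG_INF), I(sz, NEG_INF), D(sz, NEG_INF);
  std::vector<int8_t> tbM(sz, -1), tbI(sz, -1), tbD(sz, -1); // 0=M,1=I,2=D
  auto ix = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) M[ix(0, j)] = 0; // free leading reference
  double go = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    int jlo = i + off - band; if (jlo < 1) jlo = 1;
    int jhi = i + off + band; if (jhi > n) jhi = n;
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char qc = query[i - 1];
      unsigned char gc = genome[(R_xlen_t)(ws + j - 1)];
      double sub = ((base_code(qc) >= 0) && qc == gc) ? match : mismatch;
      // M
      double pm = M[ix(i - 1, j - 1)], pi = I[ix(i - 1, j - 1)],
             pd = D[ix(i - 1, j - 1)];
      double pb = std::max(pm, std::max(pi, pd));
      if (pb > NEG_INF / 2) {
        M[ix(i, j)] = pb + sub;
        tbM[ix(i, j)] = (pm >= pi && pm >= pd) ? 0 : (pi >= pd ? 1 : 2);
      }
      // I: consumes query (insertion relative to reference)
      {
        double bm = M[ix(i - 1, j)], bi = I[ix(i - 1, j)], bd = D[ix(i - 1, j)];
        double bprev = std::max(bm, std::max(bi, bd));
        double a = (bprev > NEG_INF / 2) ? bprev + go : NEG_INF;
        double b = (bi > NEG_INF / 2) ? bi + gap_extend : NEG_INF;
        if (a >= b && a > NEG_INF / 2) {
          I[ix(i, j)] = a;
          tbI[ix(i, j)] = (bm >= bi && bm >= bd) ? 0 : (bi >= bd ? 1 : 2);
        } else if (b > NEG_INF / 2) {
          I[ix(i, j)] = b; tbI[ix(i, j)] = 1;
        }
      }
      // D: consumes reference
      {
        double bm = M[ix(i, j - 1)], bi = I[ix(i, j - 1)], bd = D[ix(i, j - 1)];
        double bprev = std::max(bm, std::max(bi, bd));
        double a = (bprev > NEG_INF / 2) ? bprev + go : NEG_INF;
        double b = (bd > NEG_INF / 2) ? bd + gap_extend : NEG_INF;
        if (a >= b && a > NEG_INF / 2) {
          D[ix(i, j)] = a;
          tbD[ix(i, j)] = (bm >= bi && bm >= bd) ? 0 : (bi >= bd ? 1 : 2);
        } else if (b > NEG_INF / 2) {
          D[ix(i, j)] = b; tbD[ix(i, j)] = 2;
        }
      }
    }
  }
  // best end: query fully consumed, any reference end, no trailing D
  double best = NEG_INF;
  int bj = -1, bs = 0;
  for (int j = 0; j <= n; ++j) {
    if (M[ix(m, j)] > best) { best = M[ix(m, j)]; bj = j; bs = 0; }
    if (I[ix(m, j)] > best) { best = I[ix(m, j)]; bj = j; bs = 1; }
  }
  if (bj < 0 || best < NEG_INF / 2)
    return List::create(_["feasible"] = false);
  // traceback
  std::string ops;
  int i = m, j = bj, s = bs;
  while (i > 0) {
    int8_t prev;
    if (s == 0) { prev = tbM[ix(i, j)]; ops.push_back('M'); --i; --j; }
    else if (s == 1) { prev = tbI[ix(i, j)]; ops.push_back('I'); --i; }
    else { prev = tbD[ix(i, j)]; ops.push_back('D'); --j; }
    if (prev < 0) stop("traceback failure");
    s = prev;
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode
  std::string cigar;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
  return List::create(_["feasible"] = true, _["score"] = best,
                      _["cigar"] = cigar, _["ref_start"] = (double)(ws + j),
                      _["ref_end"] = (double)(ws + bj));
}

// [[Rcpp::export]]
std::string revcomp_seq_cpp(std::string s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      default:  out[i] = 'N';
    }
  }
  return out;
}
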