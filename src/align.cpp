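#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// basic sequence utilities
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment, linear gap costs, deterministic tie-break.
// Costs are passed as positive magnitudes; the DP subtracts them.
// Tie-break among co-optimal alignments: smallest (ref_start, read_start),
// then shortest alignment, then earliest end cell.
// ---------------------------------------------------------------------------

struct Aln {
  int score = 0;
  int ref_start = 0, ref_end = 0;     // 0-based half-open on ref
  int read_start = 0, read_end = 0;   // 0-based half-open on query
  int nmatch = 0, ncols = 0;
  std::string cigar;                  // runs of = X I D (I = query insertion)
  bool found = false;
};

static Aln sw_core(const std::string& qry, const std::string& ref,
                   int match, int mismatch, int ins_cost, int del_cost) {
  const int n = (int) qry.size(), m = (int) ref.size();
  Aln best;
  if (n == 0 || m == 0) return best;
  const int W = n + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<int> OI((size_t)(m + 1) * W, 0), OJ((size_t)(m + 1) * W, 0);
  std::vector<uint8_t> DIR((size_t)(m + 1) * W, 0);

  int bs = 0, bi = -1, bj = -1, b_oi = 0, b_oj = 0, blen = 0;

  for (int i = 1; i <= m; ++i) {
    const char rc = ref[i - 1];
    const size_t row = (size_t) i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      const bool eq = (qry[j - 1] == rc) && base2bits(rc) >= 0;
      int val = 0; uint8_t dir = 0; int oi = i, oj = j;

      // candidate from diagonal
      int dsc = H[prow + j - 1] + (eq ? match : -mismatch);
      if (dsc > 0) {
        int poi, poj;
        if (H[prow + j - 1] > 0) { poi = OI[prow + j - 1]; poj = OJ[prow + j - 1]; }
        else { poi = i - 1; poj = j - 1; }
        val = dsc; dir = 1; oi = poi; oj = poj;
      }
      // candidate from above: consumes ref only ('D' = deletion in read)
      int usc = H[prow + j] - del_cost;
      if (usc > 0 && (usc > val ||
          (usc == val && (OI[prow + j] < oi ||
                          (OI[prow + j] == oi && OJ[prow + j] < oj))))) {
        val = usc; dir = 2; oi = OI[prow + j]; oj = OJ[prow + j];
      }
      // candidate from left: consumes query only ('I' = insertion in read)
      int lsc = H[row + j - 1] - ins_cost;
      if (lsc > 0 && (lsc > val ||
          (lsc == val && (OI[row + j - 1] < oi ||
                          (OI[row + j - 1] == oi && OJ[row + j - 1] < oj))))) {
        val = lsc; dir = 3; oi = OI[row + j - 1]; oj = OJ[row + j - 1];
      }

      H[row + j] = val; DIR[row + j] = dir; OI[row + j] = oi; OJ[row + j] = oj;

      if (dir != 0) {
        int len = (i - oi) + (j - oj);
        bool better = false;
        if (val > bs) better = true;
        else if (val == bs) {
          if (oi < b_oi) better = true;
          else if (oi == b_oi) {
            if (oj < b_oj) better = true;
            else if (oj == b_oj) {
              if (len < blen) better = true;
              else if (len == blen && (i < bi || (i == bi && j < bj))) better = true;
            }
          }
        }
        if (better) { bs = val; bi = i; bj = j; b_oi = oi; b_oj = oj; blen = len; }
      }
    }
  }

  if (bs <= 0) return best;
  best.found = true;
  best.score = bs;
  best.ref_start = b_oi; best.ref_end = bi;
  best.read_start = b_oj; best.read_end = bj;

  // traceback along recorded directions
  std::string ops; ops.reserve((size_t) blen);
  int i = bi, j = bj, nm = 0, nc = 0;
  while (i > b_oi || j > b_oj) {
    uint8_t d = DIR[(size_t) i * W + j];
    if (d == 1) {
      bool eq = (qry[j - 1] == ref[i - 1]) && base2bits(ref[i - 1]) >= 0;
      ops.push_back(eq ? '=' : 'X');
      if (eq) ++nm;
      --i; --j;
    } else if (d == 2) { ops.push_back('D'); --i; }
    else if (d == 3)   { ops.push_back('I'); --j; }
    else break;
    ++nc;
  }
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p);
    cig.push_back(ops[p]);
    p = q;
  }
  best.cigar = cig; best.nmatch = nm; best.ncols = nc;
  return best;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string qry, std::string ref,
                  int match, int mismatch, int ins_cost, int del_cost) {
  Aln a = sw_core(qry, ref, match, mismatch, ins_cost, del_cost);
  return List::create(
    _["found"] = a.found, _["score"] = a.score,
    _["ref_start"] = a.ref_start, _["ref_end"] = a.ref_end,
    _["read_start"] = a.read_start, _["read_end"] = a.read_end,
    _["nmatch"] = a.nmatch, _["ncols"] = a.ncols, _["cigar"] = a.cigar);
}

// ---------------------------------------------------------------------------
// k-mer prefilter support
// ---------------------------------------------------------------------------

static void add_kmers(const std::string& s, int k, std::unordered_set<uint32_t>& set) {
  if ((int) s.size() < k) return;
  uint32_t kmer = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int run = 0;
  for (size_t p = 0; p < s.size(); ++p) {
    int b = base2bits(s[p]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) b) & mask;
    if (++run >= k) set.insert(kmer);
  }
}

static bool shares_kmer(const std::string& s, int k,
                        const std::unordered_set<uint32_t>& set) {
  if ((int) s.size() < k) return false;
  uint32_t kmer = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int run = 0;
  for (size_t p = 0; p < s.size(); ++p) {
    int b = base2bits(s[p]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) b) & mask;
    if (++run >= k && set.count(kmer)) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// batch read mapping: align each read (both strands) against every reference,
// keep the best-scoring alignment, apply length/similarity acceptance.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List map_reads_cpp(CharacterVector reads, CharacterVector refs,
                   int match, int mismatch, int ins_cost, int del_cost,
                   double length_fraction, double similarity_fraction,
                   int prefilter_k, bool keep_unmapped) {
  const int nref = refs.size();
  std::vector<std::string> refstr(nref);
  for (int r = 0; r < nref; ++r) refstr[r] = as<std::string>(refs[r]);

  std::unordered_set<uint32_t> seeds;
  if (prefilter_k > 0) {
    if (prefilter_k > 15) stop("prefilter_k must be <= 15");
    for (int r = 0; r < nref; ++r) {
      add_kmers(refstr[r], prefilter_k, seeds);
      add_kmers(revcomp_str(refstr[r]), prefilter_k, seeds);
    }
  }

  std::vector<int> o_idx, o_ref, o_score, o_rs, o_re, o_qs, o_qe;
  std::vector<double> o_id, o_frac;
  std::vector<std::string> o_cigar, o_strand;
  std::vector<int> o_tie;
  int n_prefiltered = 0;

  const double eps = 1e-12;
  for (R_xlen_t q = 0; q < reads.size(); ++q) {
    std::string fwd = as<std::string>(reads[q]);
    const int rl = (int) fwd.size();
    bool mapped = false, tie = false;
    Aln best; int best_ref = -1; char best_strand = '+';

    bool candidate = true;
    if (prefilter_k > 0 && !shares_kmer(fwd, prefilter_k, seeds)) {
      candidate = false;
      ++n_prefiltered;
    }
    if (candidate && rl > 0) {
      std::string rev = revcomp_str(fwd);
      for (int r = 0; r < nref; ++r) {
        for (int s = 0; s < 2; ++s) {
          const std::string& oriented = (s == 0) ? fwd : rev;
          Aln a = sw_core(oriented, refstr[r], match, mismatch, ins_cost, del_cost);
          if (!a.found) continue;
          if (best_ref >= 0 && a.score == best.score && r != best_ref) tie = true;
          if (best_ref < 0 || a.score > best.score) {
            best = a; best_ref = r; best_strand = (s == 0) ? '+' : '-';
          }
        }
      }
      if (best_ref >= 0) {
        double frac = (double)(best.read_end - best.read_start) / rl;
        double id = best.ncols > 0 ? (double) best.nmatch / best.ncols : 0.0;
        if (frac >= length_fraction - eps && id >= similarity_fraction - eps)
          mapped = true;
      }
    }

    if (mapped) {
      double frac = (double)(best.read_end - best.read_start) / rl;
      double id = (double) best.nmatch / best.ncols;
      o_idx.push_back((int) q + 1); o_ref.push_back(best_ref + 1);
      o_strand.push_back(std::string(1, best_strand));
      o_score.push_back(best.score);
      o_rs.push_back(best.ref_start); o_re.push_back(best.ref_end);
      o_qs.push_back(best.read_start); o_qe.push_back(best.read_end);
      o_id.push_back(id); o_frac.push_back(frac);
      o_cigar.push_back(best.cigar); o_tie.push_back(tie ? 1 : 0);
    } else if (keep_unmapped) {
      o_idx.push_back((int) q + 1); o_ref.push_back(NA_INTEGER);
      o_strand.push_back("");
      o_score.push_back(NA_INTEGER);
      o_rs.push_back(NA_INTEGER); o_re.push_back(NA_INTEGER);
      o_qs.push_back(NA_INTEGER); o_qe.push_back(NA_INTEGER);
      o_id.push_back(NA_REAL); o_frac.push_back(NA_REAL);
      o_cigar.push_back(""); o_tie.push_back(0);
    }
  }

  return List::create(
    _["read_index"] = o_idx, _["ref_index"] = o_ref, _["strand"] = o_strand,
    _["score"] = o_score,
    _["ref_start"] = o_rs, _["ref_end"] = o_re,
    _["read_start"] = o_qs, _["read_end"] = o_qe,
    _["identity"] = o_id, _["aligned_fraction"] = o_frac,
    _["cigar"] = o_cigar, _["tie"] = o_tie,
    _["n_total"] = (int) reads.size(), _["n_prefiltered"] = n_prefiltered);
}

// ---------------------------------------------------------------------------
// pileup and reference-frame projection from cigar strings
// ---------------------------------------------------------------------------

// oriented_reads must already be in reference orientation
// [[Rcpp::export]]
IntegerMatrix pileup_cpp(int ref_len, IntegerVector ref_start,
                         IntegerVector read_start, CharacterVector cigar,
                         CharacterVector oriented_reads) {
  IntegerMatrix counts(ref_len, 5);  // A C G T del
  for (R_xlen_t r = 0; r < cigar.size(); ++r) {
    std::string cig = as<std::string>(cigar[r]);
    std::string seq = as<std::string>(oriented_reads[r]);
    int pos = ref_start[r], rpos = read_start[r];
    size_t p = 0;
    while (p < cig.size()) {
      int len = 0;
      while (p < cig.size() && isdigit(cig[p])) { len = len * 10 + (cig[p] - '0'); ++p; }
      if (p >= cig.size()) stop("malformed cigar");
      char op = cig[p++];
      for (int t = 0; t < len; ++t) {
        if (op == '=' || op == 'X') {
          if (pos < 0 || pos >= ref_len) stop("pileup position outside reference");
          int b = base2bits(seq[rpos]);
          if (b >= 0) counts(pos, b) += 1;
          ++pos; ++rpos;
        } else if (op == 'D') {
          if (pos < 0 || pos >= ref_len) stop("pileup position outside reference");
          counts(pos, 4) += 1;
          ++pos;
        } else if (op == 'I') {
          ++rpos;
        } else stop("unknown cigar op");
      }
    }
  }
  return counts;
}

// project aligned reads onto reference coordinates: one character per
// reference position in [ref_start, ref_end); deletions become '-',
// insertions are dropped.
// [[Rcpp::export]]
CharacterVector project_reads_cpp(IntegerVector ref_start, CharacterVector cigar,
                                  IntegerVector read_start,
                                  CharacterVector oriented_reads) {
  CharacterVector out(cigar.size());
  for (R_xlen_t r = 0; r < cigar.size(); ++r) {
    std::string cig = as<std::string>(cigar[r]);
    std::string seq = as<std::string>(oriented_reads[r]);
    std::string proj;
    int rpos = read_start[r];
    size_t p = 0;
    while (p < cig.size()) {
      int len = 0;
      while (p < cig.size() && isdigit(cig[p])) { len = len * 10 + (cig[p] - '0'); ++p; }
      char op = cig[p++];
      for (int t = 0; t < len; ++t) {
        if (op == '=' || op == 'X') { proj.push_back(seq[rpos]); ++rpos; }
        else if (op == 'D') proj.push_back('-');
        else if (op == 'I') ++rpos;
        else stop("unknown cigar op");
      }
    }
    out[r] = proj;
  }
  return out;
}

// ---------------------------------------------------------------------------
// long-read tandem scan: seed-anchored repeated local alignment of short
// gene references against a long read, greedy non-overlapping selection.
// ---------------------------------------------------------------------------

struct Hit {
  int start, end;       // forward-read coordinates, 0-based half-open
  char strand;
  int score;
  double identity;      // identity of the discovery alignment
};

static void scan_one_strand(const std::string& target, char strand, int fwd_len,
                            const std::string& gene, int k,
                            double min_ref_fraction,
                            int match, int mismatch, int ins_cost, int del_cost,
                            std::vector<Hit>& hits) {
  const int glen = (int) gene.size(), tlen = (int) target.size();
  if (tlen < k || glen < k) return;
  // index target k-mers
  std::unordered_map<uint32_t, std::vector<int> > tidx;
  uint32_t kmer = 0, mask = (1u << (2 * k)) - 1u;
  int run = 0;
  for (int p = 0; p < tlen; ++p) {
    int b = base2bits(target[p]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) b) & mask;
    if (++run >= k) tidx[kmer].push_back(p - k + 1);
  }
  // collect seed diagonals
  std::vector<int> diags;
  kmer = 0; run = 0;
  for (int p = 0; p < glen; ++p) {
    int b = base2bits(gene[p]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) b) & mask;
    if (run + 1 >= k) {
      auto it = tidx.find(kmer);
      if (it != tidx.end())
        for (int tp : it->second) diags.push_back(tp - (p - k + 1));
    }
    ++run;
  }
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  // cluster diagonals; clusters separated by > glen/2 start a new window
  size_t c0 = 0;
  for (size_t c = 1; c <= diags.size(); ++c) {
    if (c == diags.size() || diags[c] - diags[c - 1] > glen / 2) {
      int dmin = diags[c0], dmax = diags[c - 1];
      int ws = std::max(0, dmin - 15);
      int we = std::min(tlen, dmax + glen + 15);
      if (we - ws >= k) {
        std::string window = target.substr(ws, we - ws);
        Aln a = sw_core(gene, window, match, mismatch, ins_cost, del_cost);
        if (a.found &&
            (double)(a.read_end - a.read_start) / glen >= min_ref_fraction) {
          int ts = ws + a.ref_start, te = ws + a.ref_end;
          Hit h;
          if (strand == '+') { h.start = ts; h.end = te; }
          else { h.start = fwd_len - te; h.end = fwd_len - ts; }
          h.strand = strand; h.score = a.score;
          h.identity = a.ncols > 0 ? (double) a.nmatch / a.ncols : 0.0;
          hits.push_back(h);
        }
      }
      c0 = c;
    }
  }
}

// [[Rcpp::export]]
List scan_hits_cpp(std::string read, CharacterVector gene_refs, int k,
                   double min_ref_fraction,
                   int match, int mismatch, int ins_cost, int del_cost) {
  const int nref = gene_refs.size();
  const int rl = (int) read.size();
  std::string rev = revcomp_str(read);
  std::vector<Hit> cand;
  for (int r = 0; r < nref; ++r) {
    std::string gene = as<std::string>(gene_refs[r]);
    scan_one_strand(read, '+', rl, gene, k, min_ref_fraction,
                    match, mismatch, ins_cost, del_cost, cand);
    scan_one_strand(rev, '-', rl, gene, k, min_ref_fraction,
                    match, mismatch, ins_cost, del_cost, cand);
  }
  // greedy non-overlapping selection by score, then leftmost, then '+' first
  std::vector<size_t> ord(cand.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (cand[a].score != cand[b].score) return cand[a].score > cand[b].score;
    if (cand[a].start != cand[b].start) return cand[a].start < cand[b].start;
    return cand[a].strand == '+' && cand[b].strand == '-';
  });
  std::vector<Hit> sel;
  for (size_t oi : ord) {
    const Hit& h = cand[oi];
    bool clash = false;
    for (const Hit& s : sel)
      if (h.start < s.end && s.start < h.end) { clash = true; break; }
    if (!clash) sel.push_back(h);
  }
  std::sort(sel.begin(), sel.end(),
            [](const Hit& a, const Hit& b) { return a.start < b.start; });

  const int nh = (int) sel.size();
  IntegerVector start(nh), end(nh), score(nh);
  CharacterVector strand(nh);
  NumericVector identity(nh);
  NumericMatrix pid(nh, nref);
  for (int i = 0; i < nh; ++i) {
    start[i] = sel[i].start; end[i] = sel[i].end;
    score[i] = sel[i].score; identity[i] = sel[i].identity;
    strand[i] = std::string(1, sel[i].strand);
    std::string seg = read.substr(sel[i].start, sel[i].end - sel[i].start);
    if (sel[i].strand == '-') seg = revcomp_str(seg);
    for (int r = 0; r < nref; ++r) {
      Aln a = sw_core(seg, as<std::string>(gene_refs[r]),
                      match, mismatch, ins_cost, del_cost);
      pid(i, r) = (a.found && a.ncols > 0) ? (double) a.nmatch / a.ncols : 0.0;
    }
  }
  return List::create(_["start"] = start, _["end"] = end, _["strand"] = strand,
                      _["score"] = score, _["identity"] = identity,
                      _["parent_identity"] = pid);
}

// ---------------------------------------------------------------------------
// simulation helpers driven by R's RNG (reproducible under set.seed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector random_dna_cpp(int n, int len) {
  static const char bases[] = "ACGT";
  CharacterVector out(n);
  std::string s(len, 'A');
  for (int i = 0; i < n; ++i) {
    for (int p = 0; p < len; ++p)
      s[p] = bases[(int)(unif_rand() * 4.0) & 3];
    out[i] = s;
  }
  return out;
}

// iid substitution errors at rate err per base
// [[Rcpp::export]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double err) {
  static const char bases[] = "ACGT";
  if (err <= 0) return clone(seqs);
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < err) {
        int b = base2bits(s[p]);
        if (b >= 0) {
          int nb = (int)(unif_rand() * 3.0);
          if (nb >= b) ++nb;
          s[p] = bases[nb];
        }
      }
    }
    out[i] = s;
  }
  return out;
}
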