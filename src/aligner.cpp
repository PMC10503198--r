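// Seed-chain-extend aligner used to place a flanking "parent" window onto a
// whole target assembly.  Exact-match k-mer seeds over a prebuilt target
// index, colinear chaining per (sequence, strand), then a banded affine-gap
// (Gotoh) fitting alignment: the parent is global, the target window local.
// A gap of length L costs gap_open + gap_extend * L (defaults 2 and 1),
// matching the convention of Biostrings::pairwiseAlignment so the R-side
// oracle is directly comparable.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

const double NEG = -1e18;

inline int b2i(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

inline char compb(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = compb(s[i]);
  return r;
}

struct KmerIndex {
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<uint64_t> cum;        // cum[i] = global offset of seq i
  int k;
  int stride;
  std::vector<uint64_t> keys;       // sorted
  std::vector<uint64_t> gpos;       // parallel to keys
};

struct Anchor {
  int chrom;
  int64_t q;   // 0-based offset in (oriented) parent
  int64_t t;   // 0-based offset in target sequence
};

struct Run { char op; int len; };   // op in {M,I,D}; I consumes target only

struct Placement {
  int chrom;
  int64_t t_start, t_end;           // 0-based half-open on target
  char strand;
  double identity, coverage, score;
  int nmatch;
  int par_aln_start, par_aln_end;   // 0-based half-open in oriented parent
  std::vector<Run> runs;            // trimmed coordinate map
  bool valid;
};

void index_seq(KmerIndex& ix, int si,
               std::vector<std::pair<uint64_t, uint64_t> >& tab) {
  const std::string& s = ix.seqs[si];
  const int k = ix.k;
  if ((int64_t)s.size() < k) return;
  uint64_t mask = (k == 32) ? ~0ull : ((1ull << (2 * k)) - 1);
  uint64_t key = 0; int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int v = b2i(s[i]);
    if (v < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)v) & mask;
    if (++run >= k) {
      int64_t p0 = (int64_t)i - k + 1;
      if (p0 % ix.stride == 0)
        tab.push_back(std::make_pair(key, ix.cum[si] + (uint64_t)p0));
    }
  }
}

// collect exact-match anchors of q against the index (one orientation)
void collect_anchors(const KmerIndex& ix, const std::string& q,
                     int qstride, int max_occ, std::vector<Anchor>& out) {
  const int k = ix.k;
  if ((int)q.size() < k) return;
  uint64_t mask = (k == 32) ? ~0ull : ((1ull << (2 * k)) - 1);
  uint64_t key = 0; int run = 0;
  int nseq = ix.names.size();
  for (size_t i = 0; i < q.size(); ++i) {
    int v = b2i(q[i]);
    if (v < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)v) & mask;
    if (run >= k - 1) run = k; else ++run;
    if (run < k) continue;
    int64_t p0 = (int64_t)i - k + 1;
    if (p0 % qstride != 0) continue;
    std::vector<uint64_t>::const_iterator lo =
        std::lower_bound(ix.keys.begin(), ix.keys.end(), key);
    if (lo == ix.keys.end() || *lo != key) continue;
    std::vector<uint64_t>::const_iterator hi =
        std::upper_bound(lo, ix.keys.end(), key);
    if ((int)(hi - lo) > max_occ) continue;
    for (std::vector<uint64_t>::const_iterator it = lo; it != hi; ++it) {
      uint64_t g = ix.gpos[it - ix.keys.begin()];
      // locate sequence: last cum <= g
      int c = (int)(std::upper_bound(ix.cum.begin(), ix.cum.begin() + nseq, g)
                    - ix.cum.begin()) - 1;
      Anchor a; a.chrom = c; a.q = p0; a.t = (int64_t)(g - ix.cum[c]);
      out.push_back(a);
    }
  }
}

bool anchor_lt(const Anchor& a, const Anchor& b) {
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  int64_t da = a.t - a.q, db = b.t - b.q;
  if (da != db) return da < db;
  return a.t < b.t;
}

bool anchor_q_lt(const Anchor& a, const Anchor& b) {
  if (a.q != b.q) return a.q < b.q;
  return a.t < b.t;
}

// banded fitting alignment of parent vs window [w0,w1) of chrom sequence.
// anchors: monotone in q and t, give the band centre line.
Placement banded_extend(const std::string& parent, const std::string& tseq,
                        int chrom, int64_t w0, int64_t w1,
                        const std::vector<Anchor>& anc, int band,
                        double go, double ge) {
  Placement pl; pl.valid = false; pl.chrom = chrom; pl.strand = '+';
  int m = (int)parent.size();
  int n = (int)(w1 - w0);
  if (m < 1 || n < 1) return pl;

  // centre line: predicted column j for each row i (prefix semantics)
  std::vector<int> ctr(m + 1);
  {
    size_t a = 0;
    for (int i = 0; i <= m; ++i) {
      while (a + 1 < anc.size() && anc[a + 1].q < i) ++a;
      int j;
      if (anc.empty()) j = i;
      else if (i <= anc.front().q) j = (int)(anc.front().t - w0 - (anc.front().q - i));
      else if (i >= anc.back().q) j = (int)(anc.back().t - w0 + (i - anc.back().q));
      else {
        const Anchor &L = anc[a], &R = anc[a + 1];
        double f = (double)(i - L.q) / (double)(R.q - L.q);
        j = (int)((double)(L.t - w0) + f * (double)(R.t - L.t) + 0.5);
      }
      ctr[i] = std::min(std::max(j, 0), n);
    }
    for (int i = 1; i <= m; ++i) ctr[i] = std::max(ctr[i], ctr[i - 1]);
  }
  const int W = 2 * band + 1;
  std::vector<int> jlo(m + 1), jhi(m + 1);
  for (int i = 0; i <= m; ++i) {
    jlo[i] = std::max(0, ctr[i] - band);
    jhi[i] = std::min(n, ctr[i] + band);
    if (jlo[i] > jhi[i]) jlo[i] = jhi[i];
  }

  // full-row score buffers with a sentinel cell at j = -1 so the inner loop
  // needs no bounds checks; cells outside a row's band stay at NEG
  std::vector<double> bufMp(n + 2, NEG), bufXp(n + 2, NEG), bufYp(n + 2, NEG);
  std::vector<double> bufMc(n + 2, NEG), bufXc(n + 2, NEG), bufYc(n + 2, NEG);
  double *Mp = bufMp.data() + 1, *Xp = bufXp.data() + 1, *Yp = bufYp.data() + 1;
  double *Mc = bufMc.data() + 1, *Xc = bufXc.data() + 1, *Yc = bufYc.data() + 1;
  // dir codes: 2 bits each for M/X/Y source; 0=M 1=X 2=Y
  std::vector<uint8_t> dir((size_t)(m + 1) * W, 0);

  for (int j = jlo[0]; j <= jhi[0]; ++j) Mp[j] = 0.0;

  const double gopen = go + ge;
  const char* win = tseq.data() + w0;
  for (int i = 1; i <= m; ++i) {
    const char pc = parent[i - 1];
    // stale cells: prev row holds row i-2 values outside band(i-1)
    for (int j = jhi[i - 1] + 1; j <= jhi[i]; ++j)
      Mp[j] = Xp[j] = Yp[j] = NEG;
    if (jlo[i] - 1 < jlo[i - 1]) {
      int j = jlo[i] - 1;
      Mp[j] = Xp[j] = Yp[j] = NEG;
    }
    Mc[jlo[i] - 1] = Xc[jlo[i] - 1] = Yc[jlo[i] - 1] = NEG;
    uint8_t* drow = &dir[(size_t)i * W];
    const int lo = jlo[i], hi = jhi[i];
    for (int j = lo; j <= hi; ++j) {
      // M from (i-1, j-1)
      double b = Mp[j - 1]; int src = 0;
      if (Xp[j - 1] > b) { b = Xp[j - 1]; src = 1; }
      if (Yp[j - 1] > b) { b = Yp[j - 1]; src = 2; }
      const char tc = win[j - 1];
      Mc[j] = b + ((pc == tc && pc != 'N') ? 1.0 : -1.0);
      // Y: deletion from parent, from (i-1, j)
      double by = Mp[j] - gopen; int ysrc = 0;
      if (Xp[j] - gopen > by) { by = Xp[j] - gopen; ysrc = 1; }
      if (Yp[j] - ge > by) { by = Yp[j] - ge; ysrc = 2; }
      Yc[j] = by;
      // X: insertion to target, from (i, j-1) same row
      double bx = Mc[j - 1] - gopen; int xsrc = 0;
      if (Yc[j - 1] - gopen > bx) { bx = Yc[j - 1] - gopen; xsrc = 2; }
      if (Xc[j - 1] - ge > bx) { bx = Xc[j - 1] - ge; xsrc = 1; }
      Xc[j] = bx;
      drow[j - lo] = (uint8_t)(src | (xsrc << 2) | (ysrc << 4));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  // free trailing target gap: best over last row, prefer M over Y, low j tiebreak
  double best = NEG / 4; int bj = -1, bstate = 0;
  for (int j = jlo[m]; j <= jhi[m]; ++j) {
    if (Mp[j] > best) { best = Mp[j]; bj = j; bstate = 0; }
    if (Yp[j] > best) { best = Yp[j]; bj = j; bstate = 2; }
  }
  if (bj < 0) return pl;

  // traceback
  std::vector<Run> rev;
  int i = m, j = bj, state = bstate;
  int nmatch = 0;
  // re-run score rows are gone; recover source codes from dir
  while (i > 0) {
    if (j < jlo[i] || j > jhi[i]) return pl;   // defensive: left the band
    uint8_t code = dir[(size_t)i * W + (j - jlo[i])];
    int src;
    char op;
    if (state == 0) {            // M
      src = code & 3;
      op = 'M';
      if (parent[i - 1] == tseq[w0 + j - 1] && parent[i - 1] != 'N') ++nmatch;
      --i; --j;
    } else if (state == 1) {     // X: consumes target
      src = (code >> 2) & 3;
      op = 'I';
      --j;
    } else {                     // Y: consumes parent
      src = (code >> 4) & 3;
      op = 'D';
      --i;
    }
    if (!rev.empty() && rev.back().op == op) rev.back().len++;
    else { Run r; r.op = op; r.len = 1; rev.push_back(r); }
    state = src;   // row 0 exits the loop; its cells are start cells
  }
  int jstart = j;
  std::vector<Run> runs(rev.rbegin(), rev.rend());

  // trim terminal D (parent clip) and I (target shrink) runs
  int lead_clip = 0, trail_clip = 0;
  while (!runs.empty()) {
    if (runs.front().op == 'D') { lead_clip += runs.front().len; runs.erase(runs.begin()); }
    else if (runs.front().op == 'I') { jstart += runs.front().len; runs.erase(runs.begin()); }
    else break;
  }
  int jend = bj;
  while (!runs.empty()) {
    if (runs.back().op == 'D') { trail_clip += runs.back().len; runs.pop_back(); }
    else if (runs.back().op == 'I') { jend -= runs.back().len; runs.pop_back(); }
    else break;
  }
  if (runs.empty()) return pl;

  // recompute stats on trimmed runs
  int ncols = 0, mcols = 0;
  double score = 0.0;
  for (size_t r = 0; r < runs.size(); ++r) {
    ncols += runs[r].len;
    if (runs[r].op == 'M') mcols += runs[r].len;
    else score -= go + ge * runs[r].len;
  }
  score += nmatch - (mcols - nmatch);
  pl.valid = true;
  pl.t_start = w0 + jstart;
  pl.t_end = w0 + jend;
  pl.par_aln_start = lead_clip;
  pl.par_aln_end = m - trail_clip;
  pl.nmatch = nmatch;
  pl.identity = ncols > 0 ? (double)nmatch / ncols : 0.0;
  pl.coverage = (double)(m - lead_clip - trail_clip) / m;
  pl.score = score;
  pl.runs = runs;
  return pl;
}

// cluster anchors and produce placements for one orientation of the parent
void place_oriented(const KmerIndex& ix, const std::string& par, char strand,
                    int qstride, int max_occ, int band, int64_t max_gap,
                    int max_clusters, double go, double ge,
                    std::vector<Placement>& out) {
  std::vector<Anchor> anc;
  collect_anchors(ix, par, qstride, max_occ, anc);
  if (anc.empty()) return;
  std::sort(anc.begin(), anc.end(), anchor_lt);

  int m = (int)par.size();
  int64_t diag_band = band;
  std::vector<std::pair<size_t, size_t> > clusters;  // [begin,end) into anc
  size_t b = 0;
  for (size_t i = 1; i <= anc.size(); ++i) {
    bool brk = (i == anc.size());
    if (!brk) {
      const Anchor &p = anc[i - 1], &c = anc[i];
      int64_t dp = p.t - p.q, dc = c.t - c.q;
      int64_t d0 = anc[b].t - anc[b].q;
      brk = (c.chrom != p.chrom) || (dc - d0 > diag_band) ||
            (dc == dp && c.t - p.t > max_gap);
    }
    if (brk) { clusters.push_back(std::make_pair(b, i)); b = i; }
  }
  if ((int)clusters.size() > max_clusters) {
    std::sort(clusters.begin(), clusters.end(),
              // keep biggest clusters
              [](const std::pair<size_t, size_t>& a,
                 const std::pair<size_t, size_t>& bb) {
                return (a.second - a.first) > (bb.second - bb.first);
              });
    clusters.resize(max_clusters);
  }

  for (size_t ci = 0; ci < clusters.size(); ++ci) {
    std::vector<Anchor> ca(anc.begin() + clusters[ci].first,
                           anc.begin() + clusters[ci].second);
    std::sort(ca.begin(), ca.end(), anchor_q_lt);
    // greedy monotone filter in q and t
    std::vector<Anchor> mono;
    for (size_t i = 0; i < ca.size(); ++i) {
      if (mono.empty() ||
          (ca[i].q > mono.back().q && ca[i].t > mono.back().t))
        mono.push_back(ca[i]);
    }
    if (mono.empty()) continue;
    int chrom = mono[0].chrom;
    const std::string& tseq = ix.seqs[chrom];
    int64_t tlen = (int64_t)tseq.size();

    // exact-substring shortcut: single diagonal, full window in bounds
    int64_t d0 = mono.front().t - mono.front().q;
    bool one_diag = true;
    for (size_t i = 1; i < mono.size(); ++i)
      if (mono[i].t - mono[i].q != d0) { one_diag = false; break; }
    if (one_diag && d0 >= 0 && d0 + m <= tlen &&
        std::memcmp(tseq.data() + d0, par.data(), m) == 0) {
      Placement pl;
      pl.valid = true; pl.chrom = chrom; pl.strand = strand;
      pl.t_start = d0; pl.t_end = d0 + m;
      pl.par_aln_start = 0; pl.par_aln_end = m;
      pl.nmatch = m; pl.identity = 1.0; pl.coverage = 1.0; pl.score = m;
      Run r; r.op = 'M'; r.len = m; pl.runs.push_back(r);
      out.push_back(pl);
      continue;
    }

    int64_t w0 = tlen, w1 = 0;
    for (size_t i = 0; i < mono.size(); ++i) {
      w0 = std::min(w0, mono[i].t - mono[i].q);
      w1 = std::max(w1, mono[i].t + (m - mono[i].q));
    }
    w0 = std::max((int64_t)0, w0 - band - 4);
    w1 = std::min(tlen, w1 + band + 4);
    Placement pl = banded_extend(par, tseq, chrom, w0, w1, mono, band, go, ge);
    if (pl.valid) { pl.strand = strand; out.push_back(pl); }
  }
}

}  // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs,
                     int k, int stride) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  if (stride < 1) stop("stride must be >= 1");
  KmerIndex* ix = new KmerIndex();
  ix->k = k; ix->stride = stride;
  uint64_t cum = 0;
  for (int i = 0; i < names.size(); ++i) {
    ix->names.push_back(as<std::string>(names[i]));
    ix->seqs.push_back(as<std::string>(seqs[i]));
    ix->cum.push_back(cum);
    cum += ix->seqs.back().size();
  }
  ix->cum.push_back(cum);
  std::vector<std::pair<uint64_t, uint64_t> > tab;
  for (size_t i = 0; i < ix->seqs.size(); ++i) index_seq(*ix, (int)i, tab);
  std::sort(tab.begin(), tab.end());
  ix->keys.reserve(tab.size()); ix->gpos.reserve(tab.size());
  for (size_t i = 0; i < tab.size(); ++i) {
    ix->keys.push_back(tab[i].first);
    ix->gpos.push_back(tab[i].second);
  }
  XPtr<KmerIndex> xp(ix, true);
  return xp;
}

// [[Rcpp::export]]
List cpp_align_parent(SEXP xp_, std::string parent,
                      int qstride, int max_occ, int band,
                      double max_gap_mult, int max_clusters,
                      double gap_open, double gap_extend,
                      double min_identity, double min_coverage) {
  XPtr<KmerIndex> xp(xp_);
  for (size_t i = 0; i < parent.size(); ++i)
    parent[i] = (char)toupper((unsigned char)parent[i]);
  int m = (int)parent.size();
  int64_t max_gap = (int64_t)(max_gap_mult * m);

  std::vector<Placement> all;
  place_oriented(*xp, parent, '+', qstride, max_occ, band, max_gap,
                 max_clusters, gap_open, gap_extend, all);
  std::string rc = revcomp(parent);
  place_oriented(*xp, rc, '-', qstride, max_occ, band, max_gap,
                 max_clusters, gap_open, gap_extend, all);

  int n_raw = (int)all.size();
  List res;
  for (size_t i = 0; i < all.size(); ++i) {
    const Placement& p = all[i];
    if (p.identity < min_identity || p.coverage < min_coverage) continue;
    int nr = (int)p.runs.size();
    CharacterVector op(nr); IntegerVector len(nr);
    for (int r = 0; r < nr; ++r) {
      op[r] = std::string(1, p.runs[r].op);
      len[r] = p.runs[r].len;
    }
    res.push_back(List::create(
        _["chrom"] = xp->names[p.chrom],
        _["start"] = (double)p.t_start,
        _["end"] = (double)p.t_end,
        _["strand"] = std::string(1, p.strand),
        _["identity"] = p.identity,
        _["coverage"] = p.coverage,
        _["score"] = p.score,
        _["nmatch"] = p.nmatch,
        _["parent_len"] = m,
        _["parent_aln_start"] = p.par_aln_start,
        _["parent_aln_end"] = p.par_aln_end,
        _["cigar_op"] = op,
        _["cigar_len"] = len));
  }
  res.attr("n_raw") = n_raw;
  return res;
}

// [[Rcpp::export]]
CharacterVector cpp_index_names(SEXP xp_) {
  XPtr<KmerIndex> xp(xp_);
  return wrap(xp->names);
}
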