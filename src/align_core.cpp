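// Core dynamic programming for frameshift-aware local DNA-to-protein
// alignment, plus translated-seed scanning and low-entropy masking.
//
// Scoring model conventions (shared with the R side):
//  - substitution matrix is 64 x 21, rows indexed by codon (A=0,C=1,G=2,T=3;
//    idx = 16*b1 + 4*b2 + b3), columns by amino acid in AA_ORDER
//    "ACDEFGHIKLMNPQRSTVWY*".
//  - a codon containing a non-ACGT base scores the per-aa minimum over all
//    codons (conservative wildcard handling).
//  - gap of length L costs gap_open + L * gap_extend (LAST-style a + b*k).
//  - a frameshift costs fs_cost and shifts the reading frame by +1 nt
//    (one nucleotide skipped) or -1 nt (next codon re-uses one nucleotide);
//    frameshifts occur only between codon columns.
//  - local alignments start and end with a codon<->aa column.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cstdint>
#include <climits>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// op codes shared with the R side
enum OpCode { OP_CODON_AA = 1, OP_CODON_GAP = 2, OP_GAP_AA = 3,
              OP_FS_PLUS = 4, OP_FS_MINUS = 5 };

static inline int base_idx(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Alignment {
  int score, dna_start, dna_end, prot_start, prot_end;
  std::vector<int> ops;
};

// traceback codes for the M (codon column) matrix
enum { TB_NONE = 0, TB_START, TB_M, TB_D, TB_I, TB_FSP, TB_FSM };

// Full local DP over dna[lo, hi) vs prot; returns true and fills `out` when
// an alignment with score >= min_score exists.  Deterministic tie-breaks:
// transition preference START < fromM < fromD < fromI < fs+ < fs- resolved by
// taking the *first* maximal candidate in the order (M, D, I, START, FS+,
// FS-); best cell ties resolved by lower dna end, then lower prot end.
static bool dp_best(const std::string& dna, int lo, int hi,
                    const std::string& prot,
                    const int* subst, const int* minsc,
                    int gap_open, int gap_ext, int fs_cost,
                    int min_score, Alignment& out) {
  int n = hi - lo, m = (int)prot.size();
  if (n < 3 || m < 1) return false;
  size_t W = (size_t)(n + 1) * (m + 1);
  std::vector<int> M(W, NEG), D(W, NEG), I(W, NEG);
  std::vector<unsigned char> tbM(W, TB_NONE), tbD(W, 0), tbI(W, 0);
  std::vector<int> aaidx(m);
  for (int j = 0; j < m; ++j) {
    // amino-acid index is precomputed on the R side into prot as raw bytes
    aaidx[j] = (unsigned char)prot[j];
  }
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  int best = min_score - 1, bi = -1, bj = -1;
  for (int i = 3; i <= n; ++i) {
    int cod = -2; // lazily computed per i
    for (int j = 1; j <= m; ++j) {
      if (cod == -2) {
        int b1 = base_idx(dna[lo + i - 3]), b2 = base_idx(dna[lo + i - 2]),
            b3 = base_idx(dna[lo + i - 1]);
        cod = (b1 < 0 || b2 < 0 || b3 < 0) ? -1 : 16 * b1 + 4 * b2 + b3;
      }
      int a = aaidx[j - 1];
      int s = (cod >= 0) ? subst[cod * 21 + a] : minsc[a];

      // codon column (M)
      int bestp = 0; unsigned char tb = TB_START;
      size_t d = at(i - 3, j - 1);
      if (M[d] > bestp) { bestp = M[d]; tb = TB_M; }
      if (D[d] > bestp) { bestp = D[d]; tb = TB_D; }
      if (I[d] > bestp) { bestp = I[d]; tb = TB_I; }
      int cand = bestp + s; unsigned char ctb = tb;
      if (i >= 4) {
        size_t d4 = at(i - 4, j - 1);
        if (M[d4] > NEG && M[d4] - fs_cost + s > cand) {
          cand = M[d4] - fs_cost + s; ctb = TB_FSP;
        }
      }
      {
        size_t d2 = at(i - 2, j - 1);
        if (M[d2] > NEG && M[d2] - fs_cost + s > cand) {
          cand = M[d2] - fs_cost + s; ctb = TB_FSM;
        }
      }
      size_t h = at(i, j);
      M[h] = cand; tbM[h] = ctb;
      if (cand > best) { best = cand; bi = i; bj = j; }

      // gap <-> aa column (D): protein residue aligned to nothing
      {
        int fromM = (M[at(i, j - 1)] > NEG) ? M[at(i, j - 1)] - gap_open - gap_ext : NEG;
        int fromD = (D[at(i, j - 1)] > NEG) ? D[at(i, j - 1)] - gap_ext : NEG;
        if (fromM >= fromD) { D[h] = fromM; tbD[h] = 1; } else { D[h] = fromD; tbD[h] = 2; }
        if (D[h] < NEG / 2) D[h] = NEG;
      }
      // codon <-> gap column (I): codon aligned to nothing
      {
        int fromM = (M[at(i - 3, j)] > NEG) ? M[at(i - 3, j)] - gap_open - gap_ext : NEG;
        int fromI = (I[at(i - 3, j)] > NEG) ? I[at(i - 3, j)] - gap_ext : NEG;
        if (fromM >= fromI) { I[h] = fromM; tbI[h] = 1; } else { I[h] = fromI; tbI[h] = 2; }
        if (I[h] < NEG / 2) I[h] = NEG;
      }
    }
  }
  if (bi < 0) return false;

  // traceback from M[bi][bj]
  std::vector<int> ops;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = D, 2 = I
  int dstart = -1, pstart = -1;
  while (true) {
    if (state == 0) {
      unsigned char tb = tbM[at(i, j)];
      ops.push_back(OP_CODON_AA);
      if (tb == TB_START) { dstart = i - 3; pstart = j - 1; break; }
      if (tb == TB_M) { i -= 3; j -= 1; state = 0; }
      else if (tb == TB_D) { i -= 3; j -= 1; state = 1; }
      else if (tb == TB_I) { i -= 3; j -= 1; state = 2; }
      else if (tb == TB_FSP) { ops.push_back(OP_FS_PLUS); i -= 4; j -= 1; state = 0; }
      else { ops.push_back(OP_FS_MINUS); i -= 2; j -= 1; state = 0; }
    } else if (state == 1) {
      unsigned char tb = tbD[at(i, j)];
      ops.push_back(OP_GAP_AA);
      j -= 1; state = (tb == 1) ? 0 : 1;
    } else {
      unsigned char tb = tbI[at(i, j)];
      ops.push_back(OP_CODON_GAP);
      i -= 3; state = (tb == 1) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  out.score = best;
  out.dna_start = lo + dstart;
  out.dna_end = lo + bi;
  out.prot_start = pstart;
  out.prot_end = bj;
  out.ops = ops;
  return true;
}

// [[Rcpp::export]]
List pf_dp_align(std::string dna, RawVector prot_aa_idx,
                 IntegerMatrix subst, IntegerVector min_aa_score,
                 int gap_open, int gap_extend, int frameshift,
                 int min_score, int max_alignments) {
  std::string prot((const char*)RAW(prot_aa_idx), prot_aa_idx.size());
  std::vector<int> substv(64 * 21);
  for (int c = 0; c < 64; ++c)
    for (int a = 0; a < 21; ++a) substv[c * 21 + a] = subst(c, a);
  std::vector<int> minsc(21);
  for (int a = 0; a < 21; ++a) minsc[a] = min_aa_score[a];

  List res;
  // greedy: best alignment first, then recurse into the flanking DNA
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, (int)dna.size()});
  std::vector<Alignment> found;
  while (!stack.empty() && (int)found.size() < max_alignments) {
    auto seg = stack.back(); stack.pop_back();
    Alignment a;
    if (!dp_best(dna, seg.first, seg.second, prot, substv.data(), minsc.data(),
                 gap_open, gap_extend, frameshift, min_score, a))
      continue;
    found.push_back(a);
    stack.push_back({seg.first, a.dna_start});
    stack.push_back({a.dna_end, seg.second});
  }
  for (auto& a : found) {
    res.push_back(List::create(
      _["score"] = a.score, _["dna_start"] = a.dna_start, _["dna_end"] = a.dna_end,
      _["prot_start"] = a.prot_start, _["prot_end"] = a.prot_end,
      _["ops"] = IntegerVector(a.ops.begin(), a.ops.end())));
  }
  return res;
}

// Translated seed scan: exact seed_len-aa matches between the DNA's 3-frame
// translation and the protein set, never starting in soft-masked (lowercase)
// or ambiguous DNA, then gapless X-drop extension; survivors above `gate`
// become candidate windows for exact DP.
// [[Rcpp::export]]
DataFrame pf_seed_windows(std::string dna, List prots,
                          IntegerMatrix subst, IntegerVector codon2aa,
                          int seed_len, int gate, int pad, int xdrop) {
  int n = dna.size();
  std::vector<int> sub(64 * 21);
  for (int c = 0; c < 64; ++c)
    for (int a = 0; a < 21; ++a) sub[c * 21 + a] = subst(c, a);

  int np = prots.size();
  std::vector<std::string> paa(np);
  for (int p = 0; p < np; ++p) {
    RawVector rv = prots[p];
    paa[p].assign((const char*)RAW(rv), rv.size());
  }
  // hash protein seed_len-mers
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
  for (int p = 0; p < np; ++p) {
    int m = paa[p].size();
    for (int q = 0; q + seed_len <= m; ++q) {
      uint32_t key = 0;
      for (int k = 0; k < seed_len; ++k)
        key = key * 21u + (unsigned char)paa[p][q + k];
      index[key].push_back({p, q});
    }
  }

  // per-position codon aa translation, masked/ambiguous = -1
  std::vector<int> tr(n >= 2 ? n - 2 : 0, -1);
  std::vector<char> masked(n, 0);
  for (int i = 0; i < n; ++i) {
    char c = dna[i];
    masked[i] = (c >= 'a' && c <= 'z');
  }
  for (int i = 0; i + 3 <= n; ++i) {
    int b1 = base_idx(dna[i]), b2 = base_idx(dna[i + 1]), b3 = base_idx(dna[i + 2]);
    if (b1 >= 0 && b2 >= 0 && b3 >= 0)
      tr[i] = codon2aa[16 * b1 + 4 * b2 + b3];
  }

  std::vector<int> o_prot, o_ws, o_we;
  int span = 3 * seed_len;
  for (int i = 0; i + span <= n; ++i) {
    bool bad = false;
    for (int k = i; k < i + span; ++k)
      if (masked[k]) { bad = true; break; }
    if (bad) continue;
    uint32_t key = 0; bool ok = true;
    for (int k = 0; k < seed_len; ++k) {
      int a = tr[i + 3 * k];
      if (a < 0) { ok = false; break; }
      key = key * 21u + (unsigned)a;
    }
    if (!ok) continue;
    auto it = index.find(key);
    if (it == index.end()) continue;
    for (auto& hit : it->second) {
      int p = hit.first, q = hit.second;
      const std::string& pr = paa[p];
      int m = pr.size();
      // seed score
      int sc = 0;
      for (int k = 0; k < seed_len; ++k) {
        int cod = 16 * base_idx(dna[i + 3 * k]) + 4 * base_idx(dna[i + 3 * k + 1]) +
                  base_idx(dna[i + 3 * k + 2]);
        sc += sub[cod * 21 + (unsigned char)pr[q + k]];
      }
      int best = sc, cur = sc;
      // extend right
      int kr = 0;
      for (int k = seed_len; q + k < m && i + 3 * k + 3 <= n; ++k) {
        int cod;
        {
          int b1 = base_idx(dna[i + 3 * k]), b2 = base_idx(dna[i + 3 * k + 1]),
              b3 = base_idx(dna[i + 3 * k + 2]);
          if (b1 < 0 || b2 < 0 || b3 < 0) break;
          cod = 16 * b1 + 4 * b2 + b3;
        }
        cur += sub[cod * 21 + (unsigned char)pr[q + k]];
        if (cur > best) { best = cur; kr = k - seed_len + 1; }
        if (cur < best - xdrop) break;
      }
      // extend left
      int curL = best, bestL = best, kl = 0;
      for (int k = 1; q - k >= 0 && i - 3 * k >= 0; ++k) {
        int b1 = base_idx(dna[i - 3 * k]), b2 = base_idx(dna[i - 3 * k + 1]),
            b3 = base_idx(dna[i - 3 * k + 2]);
        if (b1 < 0 || b2 < 0 || b3 < 0) break;
        int cod = 16 * b1 + 4 * b2 + b3;
        curL += sub[cod * 21 + (unsigned char)pr[q - k]];
        if (curL > bestL) { bestL = curL; kl = k; }
        if (curL < bestL - xdrop) break;
      }
      if (bestL >= gate) {
        int ws = i - 3 * kl - pad; if (ws < 0) ws = 0;
        int we = i + span + 3 * kr + pad; if (we > n) we = n;
        o_prot.push_back(p); o_ws.push_back(ws); o_we.push_back(we);
      }
    }
  }
  return DataFrame::create(_["prot"] = o_prot, _["wstart"] = o_ws, _["wend"] = o_we);
}

// Lowercase any window of `window` nt whose dinucleotide entropy is below
// min_bits (simple-sequence suppression for unmasked input).
// [[Rcpp::export]]
std::string pf_mask_entropy(std::string dna, int window, double min_bits) {
  int n = dna.size();
  if (n < window) return dna;
  std::vector<char> mask(n, 0);
  std::vector<int> di(n, -1);
  for (int i = 0; i + 2 <= n; ++i) {
    int b1 = base_idx(dna[i]), b2 = base_idx(dna[i + 1]);
    if (b1 >= 0 && b2 >= 0) di[i] = 4 * b1 + b2;
  }
  int counts[16] = {0};
  int valid = 0;
  auto add = [&](int i, int s) {
    if (di[i] >= 0) { counts[di[i]] += s; valid += s; }
  };
  int L = window - 1; // dinucleotides per window
  for (int i = 0; i < L && i < n - 1; ++i) add(i, 1);
  for (int start = 0; start + window <= n; ++start) {
    if (start > 0) { add(start - 1, -1); add(start + L - 1, 1); }
    if (valid == L) {
      double H = 0;
      for (int k = 0; k < 16; ++k)
        if (counts[k] > 0) {
          double p = (double)counts[k] / L;
          H -= p * std::log2(p);
        }
      if (H < min_bits)
        for (int k = start; k < start + window; ++k) mask[k] = 1;
    }
  }
  for (int i = 0; i < n; ++i)
    if (mask[i] && dna[i] >= 'A' && dna[i] <= 'Z') dna[i] = dna[i] - 'A' + 'a';
  return dna;
}
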