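#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Affine-gap local alignment (Gotoh). Penalty convention: a gap of length L
// costs gap_open + (L - 1) * gap_extend, i.e. the first gapped base pays the
// opening penalty. Scores are integers; gap_open/gap_extend are passed as
// positive penalties.

// Score-only Gotoh pass: best local score and its end cell.
static void sw_core(const char* s, int n, const char* p, int m,
                    int ma, int mi, int go, int ge,
                    int& best, int& best_i, int& best_j) {
  const int NEG = -1000000000;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG);
  best = 0; best_i = 0; best_j = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    int E = NEG;
    const char pc = p[i - 1];
    const int* hp = Hprev.data();
    int* hc = Hcur.data();
    int* fc = Fcol.data();
    for (int j = 1; j <= n; ++j) {
      int e_open = hc[j - 1] - go;
      int e_ext = E - ge;
      E = e_open >= e_ext ? e_open : e_ext;
      int f_open = hp[j] - go;
      int f_ext = fc[j] - ge;
      int F = f_open >= f_ext ? f_open : f_ext;
      fc[j] = F;
      int h = hp[j - 1] + (pc == s[j - 1] ? ma : -mi);
      if (h < E) h = E;
      if (h < F) h = F;
      if (h < 0) h = 0;
      hc[j] = h;
      if (h > best) { best = h; best_i = i; best_j = j; }
    }
    std::swap(Hprev, Hcur);
  }
}

// Best local alignment located by two score-only passes: a forward pass
// finds the end cell, a pass over the reversed prefixes finds the start.
// Coordinates are 0-based half-open.
// [[Rcpp::export]]
List cpp_sw_best(std::string subject, std::string pattern,
                 int match, int mismatch, int gap_open, int gap_extend) {
  int best, ei, ej;
  sw_core(subject.c_str(), subject.size(), pattern.c_str(), pattern.size(),
          match, mismatch, gap_open, gap_extend, best, ei, ej);
  if (best <= 0) {
    return List::create(_["score"] = 0, _["subject_start"] = 0,
                        _["subject_end"] = 0, _["pattern_start"] = 0,
                        _["pattern_end"] = 0);
  }
  std::string srev(subject.rbegin() + (subject.size() - ej), subject.rend());
  std::string prev_(pattern.rbegin() + (pattern.size() - ei), pattern.rend());
  int best2, ri, rj;
  sw_core(srev.c_str(), srev.size(), prev_.c_str(), prev_.size(),
          match, mismatch, gap_open, gap_extend, best2, ri, rj);
  return List::create(
    _["score"] = best,
    _["subject_start"] = ej - rj, _["subject_end"] = ej,
    _["pattern_start"] = ei - ri, _["pattern_end"] = ei);
}

// Full traceback local alignment; intended for the rectangle found by
// cpp_sw_best (or for short sequences), so full matrices are affordable.
// Returns alignment statistics needed for identity/coverage.
// [[Rcpp::export]]
List cpp_sw_traceback(std::string subject, std::string pattern,
                      int match, int mismatch, int gap_open, int gap_extend) {
  const int n = subject.size();
  const int m = pattern.size();
  const int NEG = -1000000000;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  auto idx = [&](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[idx(i, j - 1)] - gap_open, E[idx(i, j - 1)] - gap_extend);
      int f = std::max(H[idx(i - 1, j)] - gap_open, F[idx(i - 1, j)] - gap_extend);
      int diag = H[idx(i - 1, j - 1)] + (pc == subject[j - 1] ? match : -mismatch);
      int h = std::max(0, std::max(diag, std::max(e, f)));
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      H[idx(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback
  int i = bi, j = bj, matches = 0, aln_len = 0;
  int state = 0;  // 0 = H, 1 = E (subject gap run), 2 = F (pattern gap run)
  while (i > 0 && j > 0) {
    if (state == 0) {
      int h = H[idx(i, j)];
      if (h == 0) break;
      int diag = H[idx(i - 1, j - 1)] +
                 (pattern[i - 1] == subject[j - 1] ? match : -mismatch);
      if (h == diag) {
        if (pattern[i - 1] == subject[j - 1]) ++matches;
        ++aln_len; --i; --j;
      } else if (h == E[idx(i, j)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // consuming subject only
      ++aln_len;
      if (E[idx(i, j)] == H[idx(i, j - 1)] - gap_open) { --j; state = 0; }
      else { --j; }  // stay in extension
    } else {
      ++aln_len;
      if (F[idx(i, j)] == H[idx(i - 1, j)] - gap_open) { --i; state = 0; }
      else { --i; }
    }
  }
  return List::create(
    _["score"] = best,
    _["subject_start"] = j, _["subject_end"] = bj,
    _["pattern_start"] = i, _["pattern_end"] = bi,
    _["matches"] = matches, _["aln_len"] = aln_len);
}

// Best infix (semi-global) match of pattern within subject under unit-cost
// Levenshtein distance: the whole pattern aligns against some substring of
// the subject. Ties are broken toward the smaller subject start, then the
// smaller end. Coordinates 0-based half-open on the subject.
// [[Rcpp::export]]
List cpp_infix_edit(std::string subject, std::string pattern) {
  const int n = subject.size(), m = pattern.size();
  std::vector<int> Dprev(n + 1), Dcur(n + 1), Sprev(n + 1), Scur(n + 1);
  for (int j = 0; j <= n; ++j) { Dprev[j] = 0; Sprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    Dcur[0] = i; Scur[0] = 0;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int cd = Dprev[j - 1] + (pc == subject[j - 1] ? 0 : 1);  // diagonal
      int sd = Sprev[j - 1];
      int cu = Dprev[j] + 1;  // gap in subject (consume pattern)
      int su = Sprev[j];
      int cl = Dcur[j - 1] + 1;  // consume subject
      int sl = Scur[j - 1];
      int c = cd, s = sd;
      if (cu < c || (cu == c && su < s)) { c = cu; s = su; }
      if (cl < c || (cl == c && sl < s)) { c = cl; s = sl; }
      Dcur[j] = c; Scur[j] = s;
    }
    std::swap(Dprev, Dcur);
    std::swap(Sprev, Scur);
  }
  int bd = Dprev[0], bs = Sprev[0], bj = 0;
  for (int j = 1; j <= n; ++j) {
    if (Dprev[j] < bd || (Dprev[j] == bd && Sprev[j] < bs)) {
      bd = Dprev[j]; bs = Sprev[j]; bj = j;
    }
  }
  return List::create(_["dist"] = bd, _["start"] = bs, _["end"] = bj);
}

// Plain global Levenshtein distance (used for barcode set design).
// [[Rcpp::export]]
int cpp_edit_dist(std::string a, std::string b) {
  const int n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= (int)a.size(); ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1),
                        prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Banded affine-gap local alignment around a seed diagonal, with traceback.
// Cell (i, c) covers subject position j = i + diag0 + c - band. Suitable when
// k-mer seeding has located the approximate diagonal of the true alignment;
// the band must exceed the cumulative indel drift along the path.
// [[Rcpp::export]]
List cpp_sw_banded(std::string subject, std::string pattern,
                   int match, int mismatch, int gap_open, int gap_extend,
                   int diag0, int band) {
  const int n = subject.size(), m = pattern.size();
  const int W = 2 * band + 1;
  const int NEG = -1000000000;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG), F((m + 1) * W, NEG);
  auto idx = [&](int i, int c) { return i * W + c; };
  auto jpos = [&](int i, int c) { return i + diag0 + c - band; };
  // row 0: H = 0 only where j in [0, n]
  for (int c = 0; c < W; ++c) {
    int j = jpos(0, c);
    if (j < 0 || j > n) H[idx(0, c)] = NEG;
  }
  int best = 0, bi = 0, bc = 0;
  for (int i = 1; i <= m; ++i) {
    const char pc = pattern[i - 1];
    for (int c = 0; c < W; ++c) {
      int j = jpos(i, c);
      if (j < 0 || j > n) { H[idx(i, c)] = NEG; continue; }
      if (j == 0) { H[idx(i, c)] = 0; continue; }
      int hl = (c >= 1) ? H[idx(i, c - 1)] : NEG;
      int el = (c >= 1) ? E[idx(i, c - 1)] : NEG;
      int e = std::max(hl == NEG ? NEG : hl - gap_open,
                       el == NEG ? NEG : el - gap_extend);
      int hu = (c + 1 < W) ? H[idx(i - 1, c + 1)] : NEG;
      int fu = (c + 1 < W) ? F[idx(i - 1, c + 1)] : NEG;
      int f = std::max(hu == NEG ? NEG : hu - gap_open,
                       fu == NEG ? NEG : fu - gap_extend);
      int hd = H[idx(i - 1, c)];
      int diag = hd == NEG ? NEG : hd + (pc == subject[j - 1] ? match : -mismatch);
      int h = std::max(0, std::max(diag, std::max(e, f)));
      E[idx(i, c)] = e;
      F[idx(i, c)] = f;
      H[idx(i, c)] = h;
      if (h > best) { best = h; bi = i; bc = c; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0, _["subject_start"] = 0,
                        _["subject_end"] = 0, _["pattern_start"] = 0,
                        _["pattern_end"] = 0, _["matches"] = 0,
                        _["aln_len"] = 0);
  }
  int i = bi, c = bc, matches = 0, aln_len = 0, state = 0;
  while (i > 0) {
    int j = jpos(i, c);
    if (j <= 0) break;
    if (state == 0) {
      int h = H[idx(i, c)];
      if (h <= 0) break;
      int hd = H[idx(i - 1, c)];
      int diag = hd == NEG ? NEG : hd +
        (pattern[i - 1] == subject[j - 1] ? match : -mismatch);
      if (h == diag) {
        if (pattern[i - 1] == subject[j - 1]) ++matches;
        ++aln_len; --i;  // same c: diagonal move
      } else if (h == E[idx(i, c)]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap consuming subject: move left (c - 1)
      ++aln_len;
      int hl = (c >= 1) ? H[idx(i, c - 1)] : NEG;
      bool open = (E[idx(i, c)] == (hl == NEG ? NEG : hl - gap_open));
      --c;
      if (open) state = 0;
    } else {  // gap consuming pattern: move up (i - 1, c + 1)
      ++aln_len;
      int hu = (c + 1 < W) ? H[idx(i - 1, c + 1)] : NEG;
      bool open = (F[idx(i, c)] == (hu == NEG ? NEG : hu - gap_open));
      --i; ++c;
      if (open) state = 0;
    }
  }
  return List::create(
    _["score"] = best,
    _["subject_start"] = jpos(i, c), _["subject_end"] = jpos(bi, bc),
    _["pattern_start"] = i, _["pattern_end"] = bi,
    _["matches"] = matches, _["aln_len"] = aln_len);
}

// Shared k-mer count and median seed diagonal (subject pos - pattern pos)
// for each pattern against the read. diag is NA-coded as -2^30 when there
// are no shared k-mers.
// [[Rcpp::export]]
List cpp_seed_diags(std::string read, CharacterVector patterns, int k) {
  std::unordered_map<uint64_t, std::vector<int> > pos;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  {
    uint64_t cur = 0; int run = 0;
    for (size_t p = 0; p < read.size(); ++p) {
      int c; switch (read[p]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
      }
      if (c < 0) { run = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++run >= k) pos[cur].push_back((int)p - k + 1);
    }
  }
  IntegerVector counts(patterns.size()), diags(patterns.size());
  for (int q = 0; q < patterns.size(); ++q) {
    std::string pat = as<std::string>(patterns[q]);
    std::vector<int> diffs;
    uint64_t cm = 0; int rn = 0;
    for (size_t p = 0; p < pat.size(); ++p) {
      int c; switch (pat[p]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
      }
      if (c < 0) { rn = 0; cm = 0; continue; }
      cm = ((cm << 2) | (uint64_t)c) & mask;
      if (++rn >= k) {
        auto it = pos.find(cm);
        if (it != pos.end()) {
          int pp = (int)p - k + 1;
          for (int sp : it->second) diffs.push_back(sp - pp);
        }
      }
    }
    if (diffs.empty()) { counts[q] = 0; diags[q] = -1073741824; continue; }
    counts[q] = (int)diffs.size();
    std::nth_element(diffs.begin(), diffs.begin() + diffs.size() / 2, diffs.end());
    diags[q] = diffs[diffs.size() / 2];
  }
  return List::create(_["count"] = counts, _["diag"] = diags);
}

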