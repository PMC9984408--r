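#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// Semi-global pairwise alignment (Gotoh, affine gaps): the read is aligned
// end-to-end, the reference contributes a contiguous window with free
// overhangs on both sides.  A gap of length k costs gap_open + k*gap_extend
// (gap_open is the opening surcharge).  Any pair involving N scores as a
// mismatch.  Tie-breaking is deterministic: at equal score the traceback
// prefers a diagonal step (match/mismatch) over a deletion (reference base
// skipped) over an insertion (read base inserted), and the alignment end is
// the leftmost best reference column; gap state entry prefers extending an
// open gap over opening a new one only when strictly better, which together
// with the end rule fixes gap placement.

static const double NEG_INF = -1e18;

// [[Rcpp::export(name = ".align_semiglobal")]]
List align_semiglobal(std::string read, std::string ref,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = (int)read.size();  // rows: read
  const int m = (int)ref.size();   // cols: reference
  if (n == 0) stop("empty read");
  if (m == 0) stop("empty reference");

  std::vector<double> H((n + 1) * (m + 1), NEG_INF);
  std::vector<double> E((n + 1) * (m + 1), NEG_INF); // ends in deletion (ref consumed, read gapped)
  std::vector<double> F((n + 1) * (m + 1), NEG_INF); // ends in insertion (read consumed, ref gapped)
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) H[at(0, j)] = 0.0; // free reference prefix
  for (int i = 1; i <= n; ++i) {
    F[at(i, 0)] = gap_open + i * gap_extend;
    H[at(i, 0)] = F[at(i, 0)];
  }

  for (int i = 1; i <= n; ++i) {
    const char rb = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char cb = ref[j - 1];
      const bool isN = (rb == 'N' || cb == 'N');
      const double s = (!isN && rb == cb) ? match : mismatch;

      const double eo = H[at(i, j - 1)] + gap_open + gap_extend;
      const double ee = E[at(i, j - 1)] + gap_extend;
      E[at(i, j)] = (ee > eo) ? ee : eo;

      const double fo = H[at(i - 1, j)] + gap_open + gap_extend;
      const double fe = F[at(i - 1, j)] + gap_extend;
      F[at(i, j)] = (fe > fo) ? fe : fo;

      double h = H[at(i - 1, j - 1)] + s;
      if (E[at(i, j)] > h) h = E[at(i, j)];
      if (F[at(i, j)] > h) h = F[at(i, j)];
      H[at(i, j)] = h;
    }
  }

  // free reference suffix: best score in the last row, leftmost column on ties
  int jend = 0;
  double best = H[at(n, 0)];
  for (int j = 1; j <= m; ++j) {
    if (H[at(n, j)] > best) { best = H[at(n, j)]; jend = j; }
  }

  // traceback; state 0 = H, 1 = E (deletion), 2 = F (insertion)
  std::string cigar_rev;
  std::vector<int> aligned_pos, del_pos, ins_pos;
  std::string aligned_base;
  int i = n, j = jend, state = 0;
  const double eps = 1e-9;

  while (i > 0) {
    if (state == 0) {
      if (j == 0) { state = 2; continue; }
      const char rb = read[i - 1], cb = ref[j - 1];
      const bool isN = (rb == 'N' || cb == 'N');
      const double s = (!isN && rb == cb) ? match : mismatch;
      if (std::abs(H[at(i, j)] - (H[at(i - 1, j - 1)] + s)) < eps) {
        cigar_rev.push_back('M');
        aligned_pos.push_back(j - 1);
        aligned_base.push_back(rb);
        --i; --j;
      } else if (std::abs(H[at(i, j)] - E[at(i, j)]) < eps) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // deletion: ref base j-1 unmatched
      cigar_rev.push_back('D');
      del_pos.push_back(j - 1);
      if (std::abs(E[at(i, j)] - (E[at(i, j - 1)] + gap_extend)) < eps &&
          E[at(i, j - 1)] > NEG_INF / 2) {
        --j; // keep extending
      } else {
        --j; state = 0;
      }
    } else { // insertion: read base i-1 unmatched; anchored before ref offset j
      cigar_rev.push_back('I');
      ins_pos.push_back(j);
      if (j == 0) { --i; continue; }
      if (std::abs(F[at(i, j)] - (F[at(i - 1, j)] + gap_extend)) < eps &&
          F[at(i - 1, j)] > NEG_INF / 2) {
        --i;
      } else {
        --i; state = 0;
      }
    }
  }
  const int ref_start = j;

  // compress reversed cigar into e.g. "12M1D8M"
  std::string cigar;
  int run = 0; char op = 0;
  for (auto it = cigar_rev.rbegin(); it != cigar_rev.rend(); ++it) {
    if (*it == op) { ++run; }
    else {
      if (run > 0) cigar += std::to_string(run) + op;
      op = *it; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + op;

  std::reverse(aligned_pos.begin(), aligned_pos.end());
  std::reverse(del_pos.begin(), del_pos.end());
  std::reverse(ins_pos.begin(), ins_pos.end());
  std::reverse(aligned_base.begin(), aligned_base.end());

  CharacterVector ab(aligned_base.size());
  for (size_t k = 0; k < aligned_base.size(); ++k)
    ab[k] = std::string(1, aligned_base[k]);

  return List::create(
    _["score"] = best,
    _["ref_start"] = ref_start,
    _["ref_end"] = jend,
    _["cigar"] = cigar,
    _["aligned_pos"] = IntegerVector(aligned_pos.begin(), aligned_pos.end()),
    _["aligned_base"] = ab,
    _["del_pos"] = IntegerVector(del_pos.begin(), del_pos.end()),
    _["ins_pos"] = IntegerVector(ins_pos.begin(), ins_pos.end()));
}
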