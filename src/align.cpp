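#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), tracking the
// number of matched columns and the total alignment length (columns,
// gap columns included) along one optimal path.
//
// Scoring convention follows the usual nucleotide-search defaults: a gap of
// length L costs gapOpen + L * gapExtend. Only exact A/C/G/T equality counts
// as a match; N and other ambiguity codes always score as mismatches.
//
// Tie-break along the path: diagonal > gap-in-subject > gap-in-pattern,
// and the best cell is the first maximal H cell in row-major order, so the
// reported identity and length are deterministic.

struct Cell {
  int sc;   // score
  int nm;   // matches on the path
  int len;  // alignment columns on the path
};

static inline bool better(int sc_new, const Cell &cur) { return sc_new > cur.sc; }

// [[Rcpp::export(name = ".sw_batch")]]
NumericMatrix sw_batch(std::string subject, std::vector<std::string> patterns,
                       int match, int mismatch, int gap_open, int gap_extend) {
  const int ns = subject.size();
  const size_t np = patterns.size();
  NumericMatrix out(np, 3);  // columns: score, nmatch, length
  colnames(out) = CharacterVector::create("score", "nmatch", "length");

  for (size_t p = 0; p < np; ++p) {
    const std::string &pat = patterns[p];
    const int m = pat.size();
    if (m == 0 || ns == 0) { out(p, 0) = 0; out(p, 1) = 0; out(p, 2) = 0; continue; }

    std::vector<Cell> H(m + 1), E(m + 1), Hprev(m + 1), Eprev(m + 1);
    const int NEG = -1000000000;
    for (int j = 0; j <= m; ++j) {
      Hprev[j] = {0, 0, 0};
      Eprev[j] = {NEG, 0, 0};
    }
    Cell best = {0, 0, 0};

    for (int i = 1; i <= ns; ++i) {
      H[0] = {0, 0, 0};
      E[0] = {NEG, 0, 0};
      Cell F = {NEG, 0, 0};  // gap in pattern (consumes subject), along row
      const char sc_i = subject[i - 1];
      for (int j = 1; j <= m; ++j) {
        const char pc = pat[j - 1];
        const bool is_match = (sc_i == pc) &&
          (sc_i == 'A' || sc_i == 'C' || sc_i == 'G' || sc_i == 'T');
        const int sub = is_match ? match : mismatch;

        // E: gap in subject (consumes pattern), along column j
        Cell e_open = {Hprev[j].sc - gap_open - gap_extend, Hprev[j].nm, Hprev[j].len + 1};
        Cell e_ext  = {Eprev[j].sc - gap_extend, Eprev[j].nm, Eprev[j].len + 1};
        Cell Ecur = (e_open.sc >= e_ext.sc) ? e_open : e_ext;

        // F: gap in pattern
        Cell f_open = {H[j - 1].sc - gap_open - gap_extend, H[j - 1].nm, H[j - 1].len + 1};
        Cell f_ext  = {F.sc - gap_extend, F.nm, F.len + 1};
        Cell Fcur = (f_open.sc >= f_ext.sc) ? f_open : f_ext;

        // H: max(0, diag, E, F) with deterministic preference
        Cell diag = {Hprev[j - 1].sc + sub, Hprev[j - 1].nm + (is_match ? 1 : 0),
                     Hprev[j - 1].len + 1};
        Cell h = {0, 0, 0};
        if (diag.sc > h.sc) h = diag;
        if (better(Ecur.sc, h)) h = Ecur;
        if (better(Fcur.sc, h)) h = Fcur;

        H[j] = h;
        E[j] = Ecur;
        F = Fcur;
        if (h.sc > best.sc) best = h;
      }
      std::swap(H, Hprev);
      std::swap(E, Eprev);
    }
    out(p, 0) = best.sc;
    out(p, 1) = best.nm;
    out(p, 2) = best.len;
  }
  return out;
}
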