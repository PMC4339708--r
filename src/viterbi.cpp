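#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local Viterbi over a plan-7-like profile without flanking null states:
// free (cost 0) entry into any match state and free exit from any match
// state, Smith-Waterman style. All scores are log2-odds against the
// background; insert and delete moves pay model transition costs, and
// insert emissions carry their own (usually near-zero) log-odds.
//
// match_lo : L x 20 match-state emission log-odds
// ins_lo   : L x 20 insert-state emission log-odds (row j = insert after match j)
// trans_lo : L x 7 transition log2 probabilities out of node j,
//            columns: MM MI MD IM II DM DD
// seq      : 0-based alphabet indices; -1 encodes the wildcard X
//            (emission log-odds 0 everywhere).
//
// Tie-breaks are fixed (entry preferred over M over I over D predecessors;
// earliest end cell kept) so the traced path is deterministic. Only the
// score is contract-level; ties share the maximal score by construction.
// [[Rcpp::export]]
List viterbi_local(NumericMatrix match_lo, NumericMatrix ins_lo,
                   NumericMatrix trans_lo, IntegerVector seq) {
  const int L = match_lo.nrow();
  const int n = seq.size();
  const double NEG = -1e30;
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;

  // state matrices, 1-based in j (model) and i (sequence)
  std::vector<double> VM((L + 1) * (n + 1), NEG);
  std::vector<double> VI((L + 1) * (n + 1), NEG);
  std::vector<double> VD((L + 1) * (n + 1), NEG);
  // traceback pointers: 0 entry, 1 from M, 2 from I, 3 from D
  std::vector<signed char> PM((L + 1) * (n + 1), -1);
  std::vector<signed char> PI((L + 1) * (n + 1), -1);
  std::vector<signed char> PD((L + 1) * (n + 1), -1);
  #define IX(j, i) ((j) * (n + 1) + (i))

  double best = NEG;
  int best_j = -1, best_i = -1;

  for (int i = 1; i <= n; ++i) {
    const int a = seq[i - 1];
    for (int j = 1; j <= L; ++j) {
      const double em = (a < 0) ? 0.0 : match_lo(j - 1, a);
      // match state: free entry, or continue from node j-1
      double v = 0.0;            // local entry
      signed char p = 0;
      if (j > 1) {
        const double fm = VM[IX(j - 1, i - 1)] + trans_lo(j - 2, MM);
        const double fi = VI[IX(j - 1, i - 1)] + trans_lo(j - 2, IM);
        const double fd = VD[IX(j - 1, i - 1)] + trans_lo(j - 2, DM);
        if (fm > v) { v = fm; p = 1; }
        if (fi > v) { v = fi; p = 2; }
        if (fd > v) { v = fd; p = 3; }
      }
      VM[IX(j, i)] = em + v;
      PM[IX(j, i)] = p;
      if (VM[IX(j, i)] > best) {
        best = VM[IX(j, i)];
        best_j = j; best_i = i;
      }
      // insert state I_j (only meaningful for j < L)
      if (j < L) {
        const double iem = (a < 0) ? 0.0 : ins_lo(j - 1, a);
        const double fm = VM[IX(j, i - 1)] + trans_lo(j - 1, MI);
        const double fi = VI[IX(j, i - 1)] + trans_lo(j - 1, II);
        if (fm >= fi) { VI[IX(j, i)] = iem + fm; PI[IX(j, i)] = 1; }
        else          { VI[IX(j, i)] = iem + fi; PI[IX(j, i)] = 2; }
      }
      // delete state D_j: no emission, same i
      if (j > 1) {
        const double fm = VM[IX(j - 1, i)] + trans_lo(j - 2, MD);
        const double fd = VD[IX(j - 1, i)] + trans_lo(j - 2, DD);
        if (fm >= fd) { VD[IX(j, i)] = fm; PD[IX(j, i)] = 1; }
        else          { VD[IX(j, i)] = fd; PD[IX(j, i)] = 3; }
      }
    }
  }

  if (best_j < 0)
    return List::create(_["score"] = R_NegInf);

  // traceback from (best_j, best_i) in state M
  std::vector<int> st, mo, sp;
  int j = best_j, i = best_i;
  char cur = 'M';
  for (;;) {
    if (cur == 'M') {
      st.push_back(1); mo.push_back(j); sp.push_back(i);
      const signed char p = PM[IX(j, i)];
      if (p == 0) break;
      if (p == 1)      { cur = 'M'; --j; --i; }
      else if (p == 2) { cur = 'I'; --j; --i; }
      else             { cur = 'D'; --j; --i; }
    } else if (cur == 'I') {
      st.push_back(2); mo.push_back(j); sp.push_back(i);
      const signed char p = PI[IX(j, i)];
      if (p == 1) { cur = 'M'; --i; }
      else        { cur = 'I'; --i; }
    } else { // D
      st.push_back(3); mo.push_back(j); sp.push_back(0);
      const signed char p = PD[IX(j, i)];
      if (p == 1) { cur = 'M'; --j; }
      else        { cur = 'D'; --j; }
    }
  }
  const int m = st.size();
  IntegerVector state(m), model(m), seqpos(m);
  for (int k = 0; k < m; ++k) {   // reverse into 5'->3' order
    state[k] = st[m - 1 - k];
    model[k] = mo[m - 1 - k];
    seqpos[k] = sp[m - 1 - k];
  }
  return List::create(_["score"] = best, _["state"] = state,
                      _["model"] = model, _["seqpos"] = seqpos);
}
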