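#include <Rcpp.h>
using namespace Rcpp;

// Local Viterbi over a simplified Plan7-style profile.
//
// States: M_1..M_M (emitting, scored in bits as log2(e/bg)), I_1..I_M
// (emitting at background, 0 bits), D_2..D_M (silent). Entry into any match
// state and exit from any match state are free; transitions are scored
// relative to the all-match baseline, so M->M costs 0 and the arguments
// tMI..tDD are log2(t_xy / t_MM) bit scores. Alignment is local in the
// sequence (fresh starts carry score 0) and must begin and end in a match
// state.
//
// S: M x 20 emission bit-score matrix; seq: residue indices 1..20, 0 for
// unknown ('X' etc., scored 0 bits).
// [[Rcpp::export]]
List viterbi_local_cpp(NumericMatrix S, IntegerVector seq,
                       double tMI, double tIM, double tII,
                       double tMD, double tDM, double tDD) {
  const int M = S.nrow(), L = seq.size();
  std::vector<double> Vm(M + 1, R_NegInf), Vi(M + 1, R_NegInf),
      Vd(M + 1, R_NegInf), pVm(M + 1, R_NegInf), pVi(M + 1, R_NegInf),
      pVd(M + 1, R_NegInf);
  std::vector<int> Bm(M + 1, 0), Bi(M + 1, 0), Bd(M + 1, 0), pBm(M + 1, 0),
      pBi(M + 1, 0), pBd(M + 1, 0);
  double best = R_NegInf;
  int bend = 0, bstate = 0, bstart = 0;
  for (int i = 1; i <= L; i++) {
    std::swap(Vm, pVm); std::swap(Vi, pVi); std::swap(Vd, pVd);
    std::swap(Bm, pBm); std::swap(Bi, pBi); std::swap(Bd, pBd);
    const int a = seq[i - 1];
    for (int j = 1; j <= M; j++) {
      const double e = (a > 0) ? S(j - 1, a - 1) : 0.0;
      double sc = 0.0;            // fresh local start at M_j
      int st = i;
      if (j > 1) {
        if (pVm[j - 1] > sc)       { sc = pVm[j - 1];       st = pBm[j - 1]; }
        if (pVi[j - 1] + tIM > sc) { sc = pVi[j - 1] + tIM; st = pBi[j - 1]; }
        if (pVd[j - 1] + tDM > sc) { sc = pVd[j - 1] + tDM; st = pBd[j - 1]; }
      }
      Vm[j] = sc + e; Bm[j] = st;
      double vi = pVm[j] + tMI;
      int sti = pBm[j];
      if (pVi[j] + tII > vi) { vi = pVi[j] + tII; sti = pBi[j]; }
      Vi[j] = vi; Bi[j] = sti;
      if (Vm[j] > best) { best = Vm[j]; bend = i; bstate = j; bstart = Bm[j]; }
    }
    Vd[1] = R_NegInf; Bd[1] = 0;   // D chains only follow a match
    for (int j = 2; j <= M; j++) {
      double vd = Vm[j - 1] + tMD;
      int std_ = Bm[j - 1];
      if (Vd[j - 1] + tDD > vd) { vd = Vd[j - 1] + tDD; std_ = Bd[j - 1]; }
      Vd[j] = vd; Bd[j] = std_;
    }
  }
  return List::create(_["score"] = best, _["seq_start"] = bstart,
                      _["seq_end"] = bend, _["state_end"] = bstate);
}
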