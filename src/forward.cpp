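#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plan7-style local alignment over match/insert/delete core states.
// Entry: uniform 1/L into any match state at any query position.
// Exit: constant probability pExit from each match state (1 from the last).
// Flank residues emit the background and cancel against the null model, so
// all quantities below are odds ratios; scores are log2(odds).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    double d = a - b;
    if (d > 36.0) return a;
    if (d < -36.0) return b;
    return (a > b) ? a + log1p(exp(-d)) : b + log1p(exp(d));
}

struct CoreParams {
    int L;
    std::vector<double> lMM, lMI, lMD, lIM, lII, lDM, lDD; // size L-1
    std::vector<double> lExit;                              // size L
    std::vector<double> lodM;                               // 20*L match log-odds
    std::vector<double> lodI;                               // 20 insert log-odds
    double lEntry;
};

static CoreParams prep(const NumericMatrix& matEm, const NumericVector& insEm,
                       const NumericMatrix& trans, const NumericVector& bg,
                       double pExit) {
    CoreParams cp;
    int L = matEm.ncol();
    cp.L = L;
    cp.lEntry = -log((double)L);
    cp.lMM.resize(L > 1 ? L - 1 : 0);
    cp.lMI = cp.lMD = cp.lIM = cp.lII = cp.lDM = cp.lDD = cp.lMM;
    cp.lExit.resize(L);
    for (int k = 0; k + 1 < L; ++k) {
        double cont = 1.0 - pExit;
        cp.lMM[k] = log(cont * trans(0, k));
        cp.lMI[k] = log(cont * trans(1, k));
        cp.lMD[k] = log(cont * trans(2, k));
        cp.lIM[k] = log(trans(3, k));
        cp.lII[k] = log(trans(4, k));
        cp.lDM[k] = log(trans(5, k));
        cp.lDD[k] = log(trans(6, k));
        cp.lExit[k] = log(pExit);
    }
    cp.lExit[L - 1] = 0.0;
    cp.lodM.resize(20 * L);
    cp.lodI.resize(20);
    for (int a = 0; a < 20; ++a) {
        double lbg = log(bg[a]);
        cp.lodI[a] = log(insEm[a]) - lbg;
        for (int k = 0; k < L; ++k)
            cp.lodM[a + 20 * k] = log(matEm(a, k)) - lbg;
    }
    return cp;
}

// [[Rcpp::export(name = ".fwdBits")]]
double fwd_bits(NumericMatrix matEm, NumericVector insEm, NumericMatrix trans,
                NumericVector bg, IntegerVector seq, double pExit) {
    CoreParams cp = prep(matEm, insEm, trans, bg, pExit);
    int L = cp.L, N = seq.size();
    std::vector<double> pM(L, NEG_INF), pI(L, NEG_INF), pD(L, NEG_INF);
    std::vector<double> cM(L), cI(L), cD(L);
    double total = NEG_INF;
    for (int i = 0; i < N; ++i) {
        int a = seq[i];
        for (int k = 0; k < L; ++k) {
            double em = (a < 0) ? 0.0 : cp.lodM[a + 20 * k];
            double s = cp.lEntry;
            if (k > 0) {
                s = lse(s, pM[k - 1] + cp.lMM[k - 1]);
                s = lse(s, pI[k - 1] + cp.lIM[k - 1]);
                s = lse(s, pD[k - 1] + cp.lDM[k - 1]);
            }
            cM[k] = em + s;
        }
        for (int k = 0; k < L; ++k) {
            if (k == L - 1) { cI[k] = NEG_INF; continue; }
            double em = (a < 0) ? 0.0 : cp.lodI[a];
            cI[k] = em + lse(pM[k] + cp.lMI[k], pI[k] + cp.lII[k]);
        }
        cD[0] = NEG_INF;
        for (int k = 1; k < L; ++k)
            cD[k] = lse(cM[k - 1] + cp.lMD[k - 1], cD[k - 1] + cp.lDD[k - 1]);
        for (int k = 0; k < L; ++k)
            total = lse(total, cM[k] + cp.lExit[k]);
        pM.swap(cM); pI.swap(cI); pD.swap(cD);
    }
    return total / M_LN2;
}

// Viterbi over the same topology; returns c(bits, start, end) with 1-based
// envelope coordinates (first and last core-emitted query positions).
// [[Rcpp::export(name = ".vitEnvelope")]]
NumericVector vit_envelope(NumericMatrix matEm, NumericVector insEm,
                           NumericMatrix trans, NumericVector bg,
                           IntegerVector seq, double pExit) {
    CoreParams cp = prep(matEm, insEm, trans, bg, pExit);
    int L = cp.L, N = seq.size();
    std::vector<double> pM(L, NEG_INF), pI(L, NEG_INF), pD(L, NEG_INF);
    std::vector<double> cM(L), cI(L), cD(L);
    std::vector<int> pMs(L, 0), pIs(L, 0), pDs(L, 0), cMs(L), cIs(L), cDs(L);
    double best = NEG_INF;
    int bestStart = 0, bestEnd = 0;
    for (int i = 0; i < N; ++i) {
        int a = seq[i];
        for (int k = 0; k < L; ++k) {
            double em = (a < 0) ? 0.0 : cp.lodM[a + 20 * k];
            double s = cp.lEntry;
            int st = i + 1;
            if (k > 0) {
                double v = pM[k - 1] + cp.lMM[k - 1];
                if (v > s) { s = v; st = pMs[k - 1]; }
                v = pI[k - 1] + cp.lIM[k - 1];
                if (v > s) { s = v; st = pIs[k - 1]; }
                v = pD[k - 1] + cp.lDM[k - 1];
                if (v > s) { s = v; st = pDs[k - 1]; }
            }
            cM[k] = em + s; cMs[k] = st;
        }
        for (int k = 0; k < L; ++k) {
            if (k == L - 1) { cI[k] = NEG_INF; cIs[k] = 0; continue; }
            double em = (a < 0) ? 0.0 : cp.lodI[a];
            double v1 = pM[k] + cp.lMI[k], v2 = pI[k] + cp.lII[k];
            if (v1 >= v2) { cI[k] = em + v1; cIs[k] = pMs[k]; }
            else          { cI[k] = em + v2; cIs[k] = pIs[k]; }
        }
        cD[0] = NEG_INF; cDs[0] = 0;
        for (int k = 1; k < L; ++k) {
            double v1 = cM[k - 1] + cp.lMD[k - 1], v2 = cD[k - 1] + cp.lDD[k - 1];
            if (v1 >= v2) { cD[k] = v1; cDs[k] = cMs[k - 1]; }
            else          { cD[k] = v2; cDs[k] = cDs[k - 1]; }
        }
        for (int k = 0; k < L; ++k) {
            double v = cM[k] + cp.lExit[k];
            if (v > best) { best = v; bestStart = cMs[k]; bestEnd = i + 1; }
        }
        pM.swap(cM); pI.swap(cI); pD.swap(cD);
        pMs.swap(cMs); pIs.swap(cIs); pDs.swap(cDs);
    }
    return NumericVector::create(best / M_LN2, (double)bestStart, (double)bestEnd);
}
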