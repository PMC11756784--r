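#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Weighted histograms of peptide-vs-window similarity scores.
//
// pep:    n_pep x L matrix of 0-based alphabet indices
// wts:    per-peptide weight (read count or 1)
// prot:   0-based alphabet indices of one protein sequence
// scores: 20 x 20 integer substitution matrix (non-negative)
// cap:    maximum attainable window score (L * s_max)
//
// Returns (len - L + 1) x (cap + 1) matrix; row w, column s+1 holds the
// total weight of peptides whose ungapped score against the window
// starting at w is exactly s.
// [[Rcpp::export]]
NumericMatrix cpp_window_hist(const IntegerMatrix& pep,
                              const NumericVector& wts,
                              const IntegerVector& prot,
                              const IntegerMatrix& scores,
                              const int cap) {
    const int n_pep = pep.nrow(), L = pep.ncol(), len = prot.size();
    const int n_win = len - L + 1;
    if (n_win < 1) return NumericMatrix(0, cap + 1);
    NumericMatrix out(n_win, cap + 1);

    // cache substitution-matrix rows for each peptide position once per peptide
    std::vector<const int*> row(L);
    const int* S = scores.begin();          // column-major 20x20
    std::vector<int> rowbuf(L * 20);
    for (int p = 0; p < n_pep; ++p) {
        const double w = wts[p];
        for (int j = 0; j < L; ++j) {
            const int a = pep(p, j);
            int* rb = rowbuf.data() + j * 20;
            for (int b = 0; b < 20; ++b) rb[b] = S[a + 20 * b];
        }
        for (int win = 0; win < n_win; ++win) {
            int s = 0;
            const int* pr = prot.begin() + win;
            for (int j = 0; j < L; ++j) s += rowbuf[j * 20 + pr[j]];
            out(win, s) += w;
        }
    }
    return out;
}

// Exact per-window score distribution of a random peptide under independent
// per-site residue frequencies, by integer convolution of site distributions.
//
// site_pmf: 20 x (s_max + 1) matrix; row a = pmf of s(X, a) with X ~ freqs
// Memoised on the window's residue multiset: the distribution of a sum of
// independent site scores does not depend on site order.
// [[Rcpp::export]]
NumericMatrix cpp_pmap_windows(const IntegerVector& prot,
                               const NumericMatrix& site_pmf,
                               const int L,
                               const int cap) {
    const int len = prot.size(), sm = site_pmf.ncol() - 1;
    const int n_win = len - L + 1;
    if (n_win < 1) return NumericMatrix(0, cap + 1);
    NumericMatrix out(n_win, cap + 1);
    std::map<std::string, std::vector<double> > memo;

    std::vector<double> acc(cap + 1), nxt(cap + 1);
    for (int win = 0; win < n_win; ++win) {
        std::string key(L, 0);
        for (int j = 0; j < L; ++j) key[j] = (char)(prot[win + j] + 1);
        std::sort(key.begin(), key.end());
        std::map<std::string, std::vector<double> >::iterator hit = memo.find(key);
        if (hit == memo.end()) {
            std::fill(acc.begin(), acc.end(), 0.0);
            acc[0] = 1.0;
            int reach = 0;
            for (int j = 0; j < L; ++j) {
                const int a = prot[win + j];
                std::fill(nxt.begin(), nxt.end(), 0.0);
                for (int k = 0; k <= sm; ++k) {
                    const double pk = site_pmf(a, k);
                    if (pk == 0.0) continue;
                    for (int s = 0; s <= reach; ++s)
                        if (acc[s] != 0.0) nxt[s + k] += pk * acc[s];
                }
                reach += sm;
                if (reach > cap) reach = cap;
                std::swap(acc, nxt);
            }
            hit = memo.insert(std::make_pair(key, acc)).first;
        }
        const std::vector<double>& pmf = hit->second;
        for (int s = 0; s <= cap; ++s) out(win, s) = pmf[s];
    }
    return out;
}

// Ungapped similarity scores of one peptide against every window of a protein.
// [[Rcpp::export]]
IntegerVector cpp_peptide_window_scores(const IntegerVector& pep,
                                        const IntegerVector& prot,
                                        const IntegerMatrix& scores) {
    const int L = pep.size(), len = prot.size();
    const int n_win = len - L + 1;
    if (n_win < 1) return IntegerVector(0);
    IntegerVector out(n_win);
    for (int win = 0; win < n_win; ++win) {
        int s = 0;
        for (int j = 0; j < L; ++j) s += scores(pep[j], prot[win + j]);
        out[win] = s;
    }
    return out;
}
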