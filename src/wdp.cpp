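#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local wraparound dynamic programming: best-scoring local alignment of a
// sequence against tandem (cyclic) copies of a unit. H[i][j] is the best
// score of a local alignment consuming s[1..i] and ending at unit position
// j; the within-row (insertion) dependency is cyclic, so each row is swept
// twice after the diagonal/deletion pass. B tracks the row where the local
// alignment started, giving the covered segment. 'N' never matches.
//
// [[Rcpp::export]]
List wdp_align(std::string s, std::string unit, double match = 2.0,
               double mismatch = -7.0, double indel = -7.0) {
    int n = (int) s.size(), p = (int) unit.size();
    if (n == 0 || p == 0)
        return List::create(_["score"] = 0.0, _["start"] = 1, _["end"] = 0);
    std::vector<double> Hp(p, 0.0), Hc(p, 0.0);
    std::vector<int> Bp(p, 1), Bc(p, 1);
    double best = 0.0;
    int best_i = 0, best_b = 1;
    for (int i = 1; i <= n; ++i) {
        char si = s[i - 1];
        for (int j = 0; j < p; ++j) {
            int jm = (j - 1 + p) % p;
            double sub = (si == unit[j] && si != 'N') ? match : mismatch;
            double d = Hp[jm] + sub;
            int db = Bp[jm];
            double u = Hp[j] + indel;
            int ub = Bp[j];
            double h;
            int b;
            if (d >= u) { h = d; b = db; } else { h = u; b = ub; }
            if (h <= 0.0) { h = 0.0; b = i + 1; }
            Hc[j] = h;
            Bc[j] = b;
        }
        for (int pass = 0; pass < 2; ++pass) {
            for (int j = 0; j < p; ++j) {
                int jm = (j - 1 + p) % p;
                double l = Hc[jm] + indel;
                if (l > Hc[j]) { Hc[j] = l; Bc[j] = Bc[jm]; }
            }
        }
        for (int j = 0; j < p; ++j) {
            if (Hc[j] > best) { best = Hc[j]; best_i = i; best_b = Bc[j]; }
        }
        std::swap(Hp, Hc);
        std::swap(Bp, Bc);
    }
    return List::create(_["score"] = best, _["start"] = best_b,
                        _["end"] = best_i);
}
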