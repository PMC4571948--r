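#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh three-state DP).
// A gap of length L costs open + ext * L, i.e. the first gap residue costs
// open + ext. Traceback is deterministic: on ties prefer the diagonal
// (match) state, then the vertical state (gap in b, consuming a), then the
// horizontal state (gap in a, consuming b).
//
// a, b: 1-based residue indices into the substitution matrix; sub: square
// score matrix. Returns score and the two gapped index vectors (0 = gap).
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double open, double ext) {
    const int n = a.size(), m = b.size();
    const double NEG = -std::numeric_limits<double>::infinity();
    NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);

    M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
    for (int i = 1; i <= n; ++i) {
        M(i, 0) = NEG; Iy(i, 0) = NEG;
        Ix(i, 0) = -(open + ext * i);
    }
    for (int j = 1; j <= m; ++j) {
        M(0, j) = NEG; Ix(0, j) = NEG;
        Iy(0, j) = -(open + ext * j);
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = sub(a[i - 1] - 1, b[j - 1] - 1);
            double dm = M(i - 1, j - 1), dx = Ix(i - 1, j - 1), dy = Iy(i - 1, j - 1);
            M(i, j) = std::max(dm, std::max(dx, dy)) + s;
            Ix(i, j) = std::max(M(i - 1, j) - open - ext,
                       std::max(Ix(i - 1, j) - ext,
                                Iy(i - 1, j) - open - ext));
            Iy(i, j) = std::max(M(i, j - 1) - open - ext,
                       std::max(Ix(i, j - 1) - open - ext,
                                Iy(i, j - 1) - ext));
        }
    }

    // Final state: prefer M, then Ix, then Iy on ties.
    int state; // 0 = M, 1 = Ix, 2 = Iy
    double best;
    if (M(n, m) >= Ix(n, m) && M(n, m) >= Iy(n, m)) { state = 0; best = M(n, m); }
    else if (Ix(n, m) >= Iy(n, m)) { state = 1; best = Ix(n, m); }
    else { state = 2; best = Iy(n, m); }

    std::vector<int> outA, outB;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == 0) {
            // arrived via diagonal; predecessor state at (i-1, j-1)
            double s = sub(a[i - 1] - 1, b[j - 1] - 1);
            outA.push_back(a[i - 1]); outB.push_back(b[j - 1]);
            double target = M(i, j) - s;
            --i; --j;
            if (i == 0 && j == 0) break;
            if (M(i, j) == target) state = 0;
            else if (Ix(i, j) == target) state = 1;
            else state = 2;
        } else if (state == 1) {
            outA.push_back(a[i - 1]); outB.push_back(0);
            double cur = Ix(i, j);
            --i;
            if (M(i, j) - open - ext == cur) state = 0;
            else if (Ix(i, j) - ext == cur) state = 1;
            else state = 2;
        } else {
            outA.push_back(0); outB.push_back(b[j - 1]);
            double cur = Iy(i, j);
            --j;
            if (M(i, j) - open - ext == cur) state = 0;
            else if (Ix(i, j) - open - ext == cur) state = 1;
            else state = 2;
        }
    }
    std::reverse(outA.begin(), outA.end());
    std::reverse(outB.begin(), outB.end());
    return List::create(_["score"] = best,
                        _["a"] = IntegerVector(outA.begin(), outA.end()),
                        _["b"] = IntegerVector(outB.begin(), outB.end()));
}
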