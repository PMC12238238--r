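#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Global (Needleman-Wunsch) alignment score with affine gaps.
// Gap of length L costs open + ext * L (Biostrings convention).
// Sequences are 0-based integer codes into the rows/cols of S.
// [[Rcpp::export]]
double cpp_affine_global(IntegerVector a, IntegerVector b, NumericMatrix S,
                         double open, double ext) {
    const int n = a.size(), m = b.size();
    if (n == 0 && m == 0) return 0.0;
    if (n == 0) return -(open + ext * m);
    if (m == 0) return -(open + ext * n);
    std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
    std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
    Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG_INF; Xp[j] = NEG_INF; Yp[j] = -(open + ext * j);
    }
    for (int i = 1; i <= n; ++i) {
        M[0] = NEG_INF; Y[0] = NEG_INF; X[0] = -(open + ext * i);
        const int ai = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const double s = S(ai, b[j - 1]);
            M[j] = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1])) + s;
            // X: gap in b (consume a[i])
            X[j] = std::max(Mp[j] - (open + ext),
                            std::max(Xp[j] - ext, Yp[j] - (open + ext)));
            // Y: gap in a (consume b[j])
            Y[j] = std::max(M[j - 1] - (open + ext),
                            std::max(Y[j - 1] - ext, X[j - 1] - (open + ext)));
        }
        std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    }
    return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// All-vs-all score matrix between two lists of encoded sequences.
// [[Rcpp::export]]
NumericMatrix cpp_align_score_matrix(List A, List B, NumericMatrix S,
                                     double open, double ext) {
    const int na = A.size(), nb = B.size();
    NumericMatrix out(na, nb);
    for (int i = 0; i < na; ++i) {
        IntegerVector a = A[i];
        for (int j = 0; j < nb; ++j) {
            IntegerVector b = B[j];
            out(i, j) = cpp_affine_global(a, b, S, open, ext);
        }
    }
    return out;
}

// Profile-profile global alignment with affine gaps for progressive MSA.
// ca, cb: (nsym x L) residue-count matrices per alignment column (gap counts
// included; the substitution matrix S carries zero rows/cols for gap and X).
// Column-pair score is the average pairwise substitution score.
// Returns the merge operation path: 1 = align columns, 2 = column of A
// against new gap in B, 3 = column of B against new gap in A.
// [[Rcpp::export]]
IntegerVector cpp_profile_align(NumericMatrix ca, NumericMatrix cb,
                                NumericMatrix S, double open, double ext,
                                double na, double nb) {
    const int n = ca.ncol(), m = cb.ncol(), ns = S.nrow();
    // precompute column score matrix
    NumericMatrix colsc(n, m);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
            double s = 0.0;
            for (int x = 0; x < ns; ++x) {
                const double cx = ca(x, i);
                if (cx == 0.0) continue;
                double t = 0.0;
                for (int y = 0; y < ns; ++y) {
                    const double cy = cb(y, j);
                    if (cy != 0.0) t += cy * S(x, y);
                }
                s += cx * t;
            }
            colsc(i, j) = s / (na * nb);
        }
    std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, NEG_INF));
    std::vector<std::vector<double> > X = M, Y = M;
    // traceback: 0 from M, 1 from X, 2 from Y
    std::vector<std::vector<signed char> > tM(n + 1, std::vector<signed char>(m + 1, -1));
    std::vector<std::vector<signed char> > tX = tM, tY = tM;
    M[0][0] = 0.0;
    for (int i = 1; i <= n; ++i) { X[i][0] = -(open + ext * i); tX[i][0] = 1; }
    for (int j = 1; j <= m; ++j) { Y[0][j] = -(open + ext * j); tY[0][j] = 2; }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double best = M[i - 1][j - 1]; signed char tb = 0;
            if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; tb = 1; }
            if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; tb = 2; }
            M[i][j] = best + colsc(i - 1, j - 1); tM[i][j] = tb;
            double xo = M[i - 1][j] - (open + ext); signed char xt = 0;
            if (X[i - 1][j] - ext > xo) { xo = X[i - 1][j] - ext; xt = 1; }
            if (Y[i - 1][j] - (open + ext) > xo) { xo = Y[i - 1][j] - (open + ext); xt = 2; }
            X[i][j] = xo; tX[i][j] = xt;
            double yo = M[i][j - 1] - (open + ext); signed char yt = 0;
            if (Y[i][j - 1] - ext > yo) { yo = Y[i][j - 1] - ext; yt = 2; }
            if (X[i][j - 1] - (open + ext) > yo) { yo = X[i][j - 1] - (open + ext); yt = 1; }
            Y[i][j] = yo; tY[i][j] = yt;
        }
    }
    // traceback
    int i = n, j = m, st;
    double best = M[n][m]; st = 0;
    if (X[n][m] > best) { best = X[n][m]; st = 1; }
    if (Y[n][m] > best) { best = Y[n][m]; st = 2; }
    std::vector<int> ops;
    while (i > 0 || j > 0) {
        if (st == 0) {
            st = tM[i][j]; ops.push_back(1); --i; --j;
        } else if (st == 1) {
            st = tX[i][j]; ops.push_back(2); --i;
        } else {
            st = tY[i][j]; ops.push_back(3); --j;
        }
    }
    std::reverse(ops.begin(), ops.end());
    return wrap(ops);
}
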