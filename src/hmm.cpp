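#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    if (a < b) std::swap(a, b);
    return a + std::log1p(std::exp(b - a));
}

// Profile HMM scoring in log-odds space (nats) against the background.
//
// Model: match states M1..Mm with log-odds emissions lme (20 x m); insert
// states I0..Im and the N/C sequence flanks emit the background (log-odds 0).
// ltr is 7 x (m+1), column j = transitions leaving column j (0 = begin):
// rows: MM, MI, MD, IM, II, DM, DD; column m transitions go to End.
// Glocal mode: free flanks (any prefix/suffix outside the model), model
// traversed begin-to-end through M/I/D. Local mode: entry Begin->Mj with
// log(1/m) for every j, exit Mj->End free; deletes/inserts only internal.
// Sequence: 0-based codes, 0..19 standard residues, 20 = X (background).
// [[Rcpp::export]]
List cpp_hmm_score(NumericMatrix lme, NumericMatrix ltr, IntegerVector seq,
                   bool local, bool forward, bool want_env) {
    const int m = lme.ncol(), L = seq.size();
    const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;
    const double entry = local ? -std::log((double)m) : NEG_INF;
    // DP tables over full grid (kept for traceback; sizes are modest)
    std::vector<std::vector<double> > Ms(L + 1, std::vector<double>(m + 1, NEG_INF));
    std::vector<std::vector<double> > Is = Ms, Ds = Ms;
    std::vector<double> Es(L + 1, NEG_INF);

    for (int i = 0; i <= L; ++i) {
        // B score is 0 at every i (free N flank)
        if (!local) {
            // deletes reachable at same i (no emission)
            for (int j = 1; j <= m; ++j) {
                double d = (j == 1) ? ltr(MD, 0)
                                    : std::max(Ms[i][j - 1] + ltr(MD, j - 1),
                                               Ds[i][j - 1] + ltr(DD, j - 1));
                if (forward && j > 1)
                    d = lse(Ms[i][j - 1] + ltr(MD, j - 1), Ds[i][j - 1] + ltr(DD, j - 1));
                Ds[i][j] = d;
            }
        } else {
            for (int j = 2; j <= m; ++j) {
                double d = forward
                    ? lse(Ms[i][j - 1] + ltr(MD, j - 1), Ds[i][j - 1] + ltr(DD, j - 1))
                    : std::max(Ms[i][j - 1] + ltr(MD, j - 1), Ds[i][j - 1] + ltr(DD, j - 1));
                Ds[i][j] = d;
            }
        }
        if (i < L) {
            const int c = seq[i];
            const bool isx = (c >= 20);
            for (int j = 1; j <= m; ++j) {
                const double e = isx ? 0.0 : lme(c, j - 1);
                double frM = Ms[i][j - 1] + ltr(MM, j - 1);
                double frI = Is[i][j - 1] + ltr(IM, j - 1);
                double frD = Ds[i][j - 1] + ltr(DM, j - 1);
                double frB = local ? entry : ((j == 1) ? ltr(MM, 0) : NEG_INF);
                if (!local && j == 1) frM = NEG_INF; // column 0 has no M state
                double v = forward ? lse(lse(frM, frI), lse(frD, frB))
                                   : std::max(std::max(frM, frI), std::max(frD, frB));
                Ms[i + 1][j] = v + e;
            }
            for (int j = 0; j <= m; ++j) {
                if (local && (j == 0 || j == m)) continue; // no flanking inserts in local
                double frM = (j >= 1) ? Ms[i][j] + ltr(MI, j) : ((!local) ? ltr(MI, 0) : NEG_INF);
                double frI = Is[i][j] + ltr(II, j);
                Is[i + 1][j] = forward ? lse(frM, frI) : std::max(frM, frI);
            }
        }
        // E at position i
        double e;
        if (local) {
            e = NEG_INF;
            for (int j = 1; j <= m; ++j)
                e = forward ? lse(e, Ms[i][j]) : std::max(e, Ms[i][j]);
        } else {
            e = forward
                ? lse(lse(Ms[i][m] + ltr(MM, m), Ds[i][m] + ltr(DM, m)),
                      Is[i][m] + ltr(IM, m))
                : std::max(std::max(Ms[i][m] + ltr(MM, m), Ds[i][m] + ltr(DM, m)),
                           Is[i][m] + ltr(IM, m));
        }
        Es[i] = e;
    }
    // free C flank: combine over all exit positions
    double total = NEG_INF;
    int best_i = 0;
    for (int i = 0; i <= L; ++i) {
        if (forward) total = lse(total, Es[i]);
        else if (Es[i] > total) { total = Es[i]; best_i = i; }
    }
    int env_start = NA_INTEGER, env_end = NA_INTEGER;
    if (want_env && !forward && total > NEG_INF) {
        // traceback from E at best_i to the entry, tracking match emissions
        int i = best_i, j = -1; char st;
        if (local) {
            double bb = NEG_INF; int bj = 1;
            for (int jj = 1; jj <= m; ++jj)
                if (Ms[i][jj] > bb) { bb = Ms[i][jj]; bj = jj; }
            j = bj; st = 'M';
        } else {
            const int MMr = 0, DMr = 5, IMr = 3;
            double a = Ms[i][m] + ltr(MMr, m), b = Ds[i][m] + ltr(DMr, m),
                   cc = Is[i][m] + ltr(IMr, m);
            if (a >= b && a >= cc) { st = 'M'; j = m; }
            else if (b >= cc) { st = 'D'; j = m; }
            else { st = 'I'; j = m; }
        }
        int first_m = -1, last_m = -1;
        const double tol = 1e-9;
        while (true) {
            if (st == 'M') {
                if (last_m < 0) last_m = i;
                first_m = i;
                const int c = seq[i - 1];
                const double e = (c >= 20) ? 0.0 : lme(c, j - 1);
                const double v = Ms[i][j] - e;
                double frB = local ? entry : ((j == 1) ? ltr(MM, 0) : NEG_INF);
                if (std::fabs(v - frB) < tol) break; // entered from begin
                if (j > 1 && std::fabs(v - (Ms[i - 1][j - 1] + ltr(MM, j - 1))) < tol) {
                    st = 'M'; --i; --j;
                } else if (j > 1 && std::fabs(v - (Is[i - 1][j - 1] + ltr(IM, j - 1))) < tol) {
                    st = 'I'; --i; --j;
                } else if (std::fabs(v - (Ds[i - 1][j - 1] + ltr(DM, j - 1))) < tol && j > 1) {
                    st = 'D'; --i; --j;
                } else if (!local && j == 1 &&
                           std::fabs(v - (Is[i - 1][0] + ltr(IM, 0))) < tol) {
                    st = 'I'; --i; j = 0;
                } else break;
            } else if (st == 'I') {
                const double v = Is[i][j];
                if (j >= 1 && std::fabs(v - (Ms[i - 1][j] + ltr(MI, j))) < tol) {
                    st = 'M'; --i;
                } else if (std::fabs(v - (Is[i - 1][j] + ltr(II, j))) < tol) {
                    st = 'I'; --i;
                } else if (!local && j == 0 && std::fabs(v - ltr(MI, 0)) < tol) {
                    break; // B -> I0 entry
                } else break;
            } else { // D
                const double v = Ds[i][j];
                if (!local && j == 1) break; // B -> D1
                if (std::fabs(v - (Ms[i][j - 1] + ltr(MD, j - 1))) < tol) {
                    st = 'M'; --j;
                } else if (std::fabs(v - (Ds[i][j - 1] + ltr(DD, j - 1))) < tol) {
                    st = 'D'; --j;
                } else break;
            }
        }
        if (first_m > 0) { env_start = first_m; env_end = last_m; }
    }
    return List::create(_["score"] = total, _["env_start"] = env_start,
                        _["env_end"] = env_end);
}
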