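#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion. Gap cost convention: a gap run of length L costs
// gap_open + (L - 1) * gap_extend (both penalties are <= 0).
// Tie-break on traceback: diagonal (match/mismatch) > up (gap in row_b)
// > left (gap in row_a). 'N' matches nothing (always scores `mismatch`).

static const double NEG_INF = -1e30;

// state codes
enum { ST_M = 0, ST_F = 1, ST_E = 2 };  // F: gap in row_b (consumes a), E: gap in row_a (consumes b)

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string a, std::string b,
               double match, double mismatch,
               double gap_open, double gap_extend) {
    const size_t n = a.size(), m = b.size();
    const size_t ncell = (n + 1) * (m + 1);
    if (ncell > 20000000)
        stop("sequences too long for the built-in aligner (%d x %d); supply a precomputed alignment", (int)n, (int)m);

    std::vector<double> M(ncell, NEG_INF), F(ncell, NEG_INF), E(ncell, NEG_INF);
    std::vector<uint8_t> tM(ncell, 0), tF(ncell, 0), tE(ncell, 0);
    #define IDX(i, j) ((i) * (m + 1) + (j))

    M[IDX(0, 0)] = 0.0;
    for (size_t i = 1; i <= n; ++i) {
        F[IDX(i, 0)] = (double)(gap_open + (double)(i - 1) * gap_extend);
        tF[IDX(i, 0)] = (i == 1) ? ST_M : ST_F;
    }
    for (size_t j = 1; j <= m; ++j) {
        E[IDX(0, j)] = (double)(gap_open + (double)(j - 1) * gap_extend);
        tE[IDX(0, j)] = (j == 1) ? ST_M : ST_E;
    }

    for (size_t i = 1; i <= n; ++i) {
        const char ca = a[i - 1];
        for (size_t j = 1; j <= m; ++j) {
            const char cb = b[j - 1];
            const size_t c = IDX(i, j), d = IDX(i - 1, j - 1),
                         u = IDX(i - 1, j), l = IDX(i, j - 1);
            // M: diagonal step; predecessor preference M > F > E
            {
                double s = (ca == cb && ca != 'N') ? match : mismatch;
                double best = M[d]; uint8_t tb = ST_M;
                if (F[d] > best) { best = F[d]; tb = ST_F; }
                if (E[d] > best) { best = E[d]; tb = ST_E; }
                M[c] = (double)(best + s); tM[c] = tb;
            }
            // F: consume a[i-1], gap in row_b ("up")
            {
                double open_from_M = (double)(M[u] + gap_open);
                double ext        = (double)(F[u] + gap_extend);
                double open_from_E = (double)(E[u] + gap_open);
                double best = open_from_M; uint8_t tb = ST_M;
                if (ext > best)        { best = ext;        tb = ST_F; }
                if (open_from_E > best){ best = open_from_E; tb = ST_E; }
                F[c] = best; tF[c] = tb;
            }
            // E: consume b[j-1], gap in row_a ("left")
            {
                double open_from_M = (double)(M[l] + gap_open);
                double open_from_F = (double)(F[l] + gap_open);
                double ext        = (double)(E[l] + gap_extend);
                double best = open_from_M; uint8_t tb = ST_M;
                if (open_from_F > best){ best = open_from_F; tb = ST_F; }
                if (ext > best)        { best = ext;        tb = ST_E; }
                E[c] = best; tE[c] = tb;
            }
        }
    }

    // final state: prefer M (diagonal) > F (up) > E (left) on ties
    size_t i = n, j = m;
    const size_t endc = IDX(n, m);
    uint8_t state = ST_M;
    double best = M[endc];
    if (F[endc] > best) { best = F[endc]; state = ST_F; }
    if (E[endc] > best) { best = E[endc]; state = ST_E; }
    const double score = best;

    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    while (i > 0 || j > 0) {
        const size_t c = IDX(i, j);
        if (state == ST_M) {
            uint8_t prev = tM[c];
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            --i; --j; state = prev;
        } else if (state == ST_F) {
            uint8_t prev = tF[c];
            ra.push_back(a[i - 1]); rb.push_back('-');
            --i; state = prev;
        } else {
            uint8_t prev = tE[c];
            ra.push_back('-'); rb.push_back(b[j - 1]);
            --j; state = prev;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    return List::create(_["row_a"] = ra, _["row_b"] = rb, _["score"] = score);
}
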