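#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Exact k-mismatch matching statistics by diagonal scan.
//
// For a fixed diagonal (offset between query position i and subject
// position j) the longest substring starting at i with at most k
// mismatches against the aligned subject substring runs up to (but not
// including) the (k+1)-th mismatch on that diagonal.  Scanning every
// diagonal and keeping the per-position maximum gives the exact statistic
// in O(|x|*|y|) time and O(|x|+|y|) memory.
//
// Characters outside the declared alphabet must never match anything
// (ambiguity codes); the caller encodes them as distinct sentinel bytes in
// x and y so the plain byte comparison below enforces this.
// [[Rcpp::export(name = ".exact_ms_cpp")]]
IntegerVector exact_ms_cpp(const std::string& x, const std::string& y,
                           const int k) {
    const int n = (int)x.size(), m = (int)y.size();
    if (n == 0 || m == 0) stop("empty sequence");
    IntegerVector best(n, 0);
    std::vector<int> mis;
    mis.reserve(std::min(n, m) + 1);
    for (int d = -(m - 1); d <= n - 1; ++d) {
        const int i0 = std::max(0, d), j0 = std::max(0, -d);
        const int len = std::min(n - i0, m - j0);
        mis.clear();
        for (int t = 0; t < len; ++t)
            if (x[i0 + t] != y[j0 + t]) mis.push_back(t);
        const int M = (int)mis.size();
        int ptr = 0;
        for (int t = 0; t < len; ++t) {
            while (ptr < M && mis[ptr] < t) ++ptr;
            const int idx = ptr + k;            // (k+1)-th mismatch >= t
            const int reach = (idx < M) ? mis[idx] : len;
            const int l = reach - t;
            if (l > best[i0 + t]) best[i0 + t] = l;
        }
    }
    return best;
}

// Heuristic k-mismatch matching statistics.
//
// Stage 1 finds, for every query position i, the longest exact match
// length and up to max_cand subject start positions attaining it (the role
// a generalized suffix array plays in the original tool).  Stage 2 chains
// longest-common-extension steps from each candidate: consume one mismatch,
// extend exactly, repeat until k mismatches are spent or a sequence end is
// reached.  Every chained extension is a genuine <=k-mismatch match, so the
// heuristic never exceeds the exact statistic, and with k = 0 it equals it.
// [[Rcpp::export(name = ".heuristic_ms_cpp")]]
IntegerVector heuristic_ms_cpp(const std::string& x, const std::string& y,
                               const int k, const int max_cand) {
    const int n = (int)x.size(), m = (int)y.size();
    if (n == 0 || m == 0) stop("empty sequence");

    std::vector<int> best0(n, 0);
    std::vector<std::vector<int> > cand(n);
    std::vector<int> lce;
    lce.reserve(std::min(n, m));

    for (int d = -(m - 1); d <= n - 1; ++d) {
        const int i0 = std::max(0, d), j0 = std::max(0, -d);
        const int len = std::min(n - i0, m - j0);
        lce.assign(len, 0);
        for (int t = len - 1; t >= 0; --t)
            if (x[i0 + t] == y[j0 + t])
                lce[t] = (t + 1 < len ? lce[t + 1] : 0) + 1;
        for (int t = 0; t < len; ++t) {
            const int i = i0 + t, j = j0 + t, l = lce[t];
            if (l > best0[i]) {
                best0[i] = l;
                cand[i].clear();
                cand[i].push_back(j);
            } else if (l == best0[i] && (int)cand[i].size() < max_cand) {
                cand[i].push_back(j);
            }
        }
    }

    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        int h = best0[i];
        if (k > 0) {
            for (size_t c = 0; c < cand[i].size(); ++c) {
                int ii = i + best0[i], jj = cand[i][c] + best0[i];
                int total = best0[i];
                for (int used = 0; used < k; ++used) {
                    if (ii >= n || jj >= m) break;
                    ++total; ++ii; ++jj;        // spend one mismatch
                    while (ii < n && jj < m && x[ii] == y[jj]) {
                        ++total; ++ii; ++jj;
                    }
                }
                if (total > h) h = total;
            }
        }
        out[i] = h;
    }
    return out;
}
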