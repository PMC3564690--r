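#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Occurrence-list intersection for one assembly step. `occ` holds the
// prefix's occurrence tuples (column 0 = sequence index, then one start
// column per placed box in ascending box order), sorted by (seq, first
// start column). `cand` holds the candidate box's occurrences (seq,
// start), sorted by (seq, start). For every prefix tuple, candidate
// starts compatible with the gap constraint towards the nearest placed
// box on each side are located by binary search on the candidate's
// sorted starts; the new start column is inserted at `insertAt` (1-based
// position among the start columns). leftCol/rightCol are 1-based column
// indices into occ, or 0 when there is no placed box on that side.

// [[Rcpp::export(name = ".joinOccCpp")]]
IntegerMatrix joinOccCpp(IntegerMatrix occ, IntegerMatrix cand,
                         int leftCol, int offL, int loL, int hiL,
                         int rightCol, int lenJ, int loR, int hiR,
                         int insertAt) {
    int n = occ.nrow(), k = occ.ncol() - 1; // placed start columns
    int m = cand.nrow();
    std::vector<int> out; // rows of width 2 + k
    int width = 2 + k;

    int cs = 0, ce = 0; // candidate block [cs, ce) for current sequence
    int curSeq = -1;
    for (int i = 0; i < n; ++i) {
        int s = occ(i, 0);
        if (s != curSeq) {
            curSeq = s;
            while (cs < m && cand(cs, 0) < s) ++cs;
            ce = cs;
            while (ce < m && cand(ce, 0) == s) ++ce;
        }
        if (cs >= m || cand(cs, 0) != s) continue;
        long lo = 1, hi = INT_MAX;
        if (leftCol > 0) {
            long e = (long)occ(i, leftCol - 1) + offL - 1;
            lo = std::max(lo, e + 1 + loL);
            hi = std::min(hi, e + 1 + hiL);
        }
        if (rightCol > 0) {
            long sr = occ(i, rightCol - 1);
            lo = std::max(lo, sr - lenJ - hiR);
            hi = std::min(hi, sr - lenJ - loR);
        }
        if (lo > hi) continue;
        // binary search within the block for starts in [lo, hi]
        int a = cs, b = ce;
        while (a < b) { // first start >= lo
            int mid = (a + b) / 2;
            if (cand(mid, 1) < lo) a = mid + 1; else b = mid;
        }
        for (int t = a; t < ce && cand(t, 1) <= hi; ++t) {
            out.push_back(s);
            int col = 0;
            for (int c = 1; c <= k + 1; ++c) {
                if (c == insertAt) out.push_back(cand(t, 1));
                else out.push_back(occ(i, 1 + col++));
            }
        }
    }
    int nr = (int)out.size() / width;
    if (insertAt == 1 && nr > 1) {
        // the new box is now the lowest-indexed one: re-sort rows by
        // (seq, its start), stably
        std::vector<int> idx(nr);
        for (int i = 0; i < nr; ++i) idx[i] = i;
        std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
            if (out[a * width] != out[b * width])
                return out[a * width] < out[b * width];
            return out[a * width + 1] < out[b * width + 1];
        });
        std::vector<int> sorted(out.size());
        for (int i = 0; i < nr; ++i)
            for (int c = 0; c < width; ++c)
                sorted[i * width + c] = out[idx[i] * width + c];
        out.swap(sorted);
    }
    IntegerMatrix res(nr, width);
    for (int i = 0; i < nr; ++i)
        for (int c = 0; c < width; ++c)
            res(i, c) = out[i * width + c];
    return res;
}
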