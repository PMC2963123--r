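#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap of length L costs open + L * ext.
// State M ends in a substitution column, X ends with a gap in b (consumes a),
// Y ends with a gap in a (consumes b). Ties are broken M > X > Y throughout,
// which yields the spec'd deterministic preference match > deletion > insertion.

static const double NEG = -std::numeric_limits<double>::infinity();

// argmax over (m, x, y) with preference M > X > Y on ties
static inline int pick3(double m, double x, double y) {
    double best = m; int k = 0;
    if (x > best) { best = x; k = 1; }
    if (y > best) { best = y; k = 2; }
    return k;
}

// Generic engine over column scores supplied by a callback. La, Lb are the
// numbers of columns in each input; sub(i, j) is the substitution score for
// aligning column i of a (1-based) with column j of b.
template <typename ScoreFun>
static List gotoh_engine(int La, int Lb, ScoreFun sub, double open, double ext) {
    const double gi = open + ext;  // cost of the first residue of a gap
    std::vector<double> M((La + 1) * (Lb + 1), NEG), X = M, Y = M;
    // traceback: which state each cell's max came from, per state
    std::vector<signed char> tbM(M.size(), -1), tbX = tbM, tbY = tbM;
    auto at = [Lb](int i, int j) { return i * (Lb + 1) + j; };

    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= La; ++i) {
        X[at(i, 0)] = -(open + i * ext);
        tbX[at(i, 0)] = 1;
    }
    for (int j = 1; j <= Lb; ++j) {
        Y[at(0, j)] = -(open + j * ext);
        tbY[at(0, j)] = 2;
    }

    for (int i = 1; i <= La; ++i) {
        for (int j = 1; j <= Lb; ++j) {
            const int c = at(i, j), d = at(i - 1, j - 1),
                      u = at(i - 1, j), l = at(i, j - 1);
            double s = sub(i, j);
            int km = pick3(M[d], X[d], Y[d]);
            M[c] = (km == 0 ? M[d] : km == 1 ? X[d] : Y[d]) + s;
            tbM[c] = (signed char) km;
            int kx = pick3(M[u] - gi, X[u] - ext, Y[u] - gi);
            X[c] = (kx == 0 ? M[u] - gi : kx == 1 ? X[u] - ext : Y[u] - gi);
            tbX[c] = (signed char) kx;
            int ky = pick3(M[l] - gi, X[l] - gi, Y[l] - ext);
            Y[c] = (ky == 0 ? M[l] - gi : ky == 1 ? X[l] - gi : Y[l] - ext);
            tbY[c] = (signed char) ky;
        }
    }

    const int e = at(La, Lb);
    int state = pick3(M[e], X[e], Y[e]);
    double score = state == 0 ? M[e] : state == 1 ? X[e] : Y[e];
    if (La == 0 && Lb == 0) { state = 0; score = 0.0; }

    // traceback: build paths of source-column indices, 0 marks a gap
    std::vector<int> pa, pb;
    int i = La, j = Lb;
    while (i > 0 || j > 0) {
        signed char prev;
        if (state == 0) {
            prev = tbM[at(i, j)];
            pa.push_back(i); pb.push_back(j); --i; --j;
        } else if (state == 1) {
            prev = tbX[at(i, j)];
            pa.push_back(i); pb.push_back(0); --i;
        } else {
            prev = tbY[at(i, j)];
            pa.push_back(0); pb.push_back(j); --j;
        }
        state = prev;
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());
    return List::create(_["path_a"] = wrap(pa), _["path_b"] = wrap(pb),
                        _["score"] = score);
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext) {
    const int* pa = a.begin();
    const int* pb = b.begin();
    const int nr = S.nrow();
    const double* ps = S.begin();
    auto sub = [pa, pb, ps, nr](int i, int j) {
        return ps[(pa[i - 1] - 1) + (pb[j - 1] - 1) * nr];
    };
    return gotoh_engine(a.size(), b.size(), sub, open, ext);
}

// Profile columns are passed sparsely: res[k], frq[k] give the nonzero
// residue indices (1-based rows of S) and frequencies, with off[c]..off[c+1]-1
// delimiting column c (0-based offsets, length Lc+1).
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(IntegerVector resA, NumericVector frqA, IntegerVector offA,
                       IntegerVector resB, NumericVector frqB, IntegerVector offB,
                       NumericMatrix S, double open, double ext) {
    const int La = offA.size() - 1, Lb = offB.size() - 1;
    const int nr = S.nrow();
    const double* ps = S.begin();
    const int *ra = resA.begin(), *rb = resB.begin(), *oa = offA.begin(),
              *ob = offB.begin();
    const double *fa = frqA.begin(), *fb = frqB.begin();
    auto sub = [&](int i, int j) {
        double s = 0.0;
        for (int p = oa[i - 1]; p < oa[i]; ++p)
            for (int q = ob[j - 1]; q < ob[j]; ++q)
                s += fa[p] * fb[q] * ps[(ra[p] - 1) + (rb[q] - 1) * nr];
        return s;
    };
    return gotoh_engine(La, Lb, sub, open, ext);
}
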