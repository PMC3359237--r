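// Minimum-free-energy dynamic programming for (a) multiloop-free secondary
// structure folding and (b) intermolecular miRNA:target hybrids, under a
// simplified nearest-neighbour model (WC + G:U stacking, logarithmic loop
// penalties).  Bases are encoded A=1 C=2 G=3 U=4 (0 = unpairable).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// pair code in order AU,UA,GC,CG,GU,UG (1..6); 0 = not a pair
static inline int pair_code(int a, int b) {
    if (a == 1 && b == 4) return 1;
    if (a == 4 && b == 1) return 2;
    if (a == 3 && b == 2) return 3;
    if (a == 2 && b == 3) return 4;
    if (a == 3 && b == 4) return 5;
    if (a == 4 && b == 3) return 6;
    return 0;
}

// [[Rcpp::export]]
List c_fold(IntegerVector bases, NumericMatrix stack,
            NumericVector hairpin_pen, NumericVector bulge_pen,
            NumericVector internal_pen, int max_loop, int min_loop) {
    const int n = bases.size();
    std::vector<double> V((size_t)n * n, INF);
    std::vector<int> tbk((size_t)n * n, -1), tbl((size_t)n * n, -1);
    auto at = [n](int i, int j) { return (size_t)i * n + j; };

    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            const int j = i + len - 1;
            const int pc = pair_code(bases[i], bases[j]);
            if (pc == 0) continue;
            double best = INF;
            int bk = -1, bl = -1;
            const int h = j - i - 1;
            if (h >= min_loop && h <= hairpin_pen.size())
                best = hairpin_pen[h - 1];
            for (int k = i + 1; k <= i + 1 + max_loop && k < j; ++k) {
                const int n1 = k - i - 1;
                for (int l = j - 1; l >= j - 1 - max_loop && l > k; --l) {
                    const int n2 = j - l - 1;
                    const double inner = V[at(k, l)];
                    if (!std::isfinite(inner)) continue;
                    const int pc2 = pair_code(bases[k], bases[l]);
                    double e;
                    if (n1 == 0 && n2 == 0)
                        e = inner + stack(pc - 1, pc2 - 1);
                    else if (n1 == 0 || n2 == 0)
                        e = inner + bulge_pen[n1 + n2 - 1];
                    else
                        e = inner + internal_pen[n1 + n2 - 1];
                    if (e < best) { best = e; bk = k; bl = l; }
                }
            }
            V[at(i, j)] = best;
            tbk[at(i, j)] = bk;
            tbl[at(i, j)] = bl;
        }
    }

    // exterior: W[j] = best energy of prefix 0..j (multiple stems allowed)
    std::vector<double> W(n + 1, 0.0);
    std::vector<int> wfrom(n + 1, -1);  // start i of stem ending at j, or -1
    for (int j = 0; j < n; ++j) {
        double best = W[j];             // j (0-based) unpaired
        int from = -1;
        for (int i = 0; i <= j; ++i) {
            const double v = V[at(i, j)];
            if (std::isfinite(v) && W[i] + v < best) {
                best = W[i] + v;
                from = i;
            }
        }
        W[j + 1] = best;
        wfrom[j + 1] = from;
    }

    // traceback
    IntegerVector pairs(n, 0);
    std::vector<std::pair<int, int>> todo;
    int j = n;
    while (j > 0) {
        if (wfrom[j] < 0) { --j; continue; }
        const int i = wfrom[j];
        todo.push_back(std::make_pair(i, j - 1));
        j = i;
    }
    while (!todo.empty()) {
        const int i = todo.back().first, jj = todo.back().second;
        todo.pop_back();
        pairs[i] = jj + 1;    // 1-based
        pairs[jj] = i + 1;
        const int k = tbk[at(i, jj)], l = tbl[at(i, jj)];
        if (k >= 0) todo.push_back(std::make_pair(k, l));
    }

    return List::create(_["mfe"] = W[n], _["pairs"] = pairs);
}

// Hybrid DP between a miRNA m (5'->3') and the reverse r of a target
// window, so that column index advances together in both.  E[i][j] = best
// energy of a hybrid whose last pair is (m[i], r[j]), including the
// dangling-end cost of m[0..i-1].  Mismatched columns cost `mismatch`
// each; a bulge of b nt costs bulge_open + bulge_ext*b (b <= max_bulge);
// dangling miRNA nt cost `dangle` each.  Wobbles (G:U) are pairs.
// [[Rcpp::export]]
List c_duplex(IntegerVector m, IntegerVector r, NumericMatrix stack,
              double mismatch, double bulge_open, double bulge_ext,
              double dangle, int max_bulge, int max_mm_run) {
    const int M = m.size(), N = r.size();
    const int span = max_mm_run + max_bulge + 1;
    std::vector<double> E((size_t)M * N, INF);
    std::vector<int> tpi((size_t)M * N, -1), tpj((size_t)M * N, -1);
    auto at = [N](int i, int j) { return (size_t)i * N + j; };

    for (int i = 0; i < M; ++i) {
        for (int j = 0; j < N; ++j) {
            if (pair_code(m[i], r[j]) == 0) continue;
            double best = dangle * i;   // open: m[0..i-1] dangling
            int bi = -1, bj = -1;
            for (int p = i - 1; p >= 0 && p >= i - span; --p) {
                for (int q = j - 1; q >= 0 && q >= j - span; --q) {
                    const double prev = E[at(p, q)];
                    if (!std::isfinite(prev)) continue;
                    const int gm = i - p - 1, gw = j - q - 1;
                    const int mm = std::min(gm, gw);
                    const int bu = std::abs(gm - gw);
                    if (mm > max_mm_run || bu > max_bulge) continue;
                    double e = prev + mismatch * mm;
                    if (bu > 0) e += bulge_open + bulge_ext * bu;
                    if (gm == 0 && gw == 0)
                        e += stack(pair_code(m[p], r[q]) - 1,
                                   pair_code(m[i], r[j]) - 1);
                    if (e < best) { best = e; bi = p; bj = q; }
                }
            }
            E[at(i, j)] = best;
            tpi[at(i, j)] = bi;
            tpj[at(i, j)] = bj;
        }
    }

    // close: add right dangling cost of m[i+1..M-1]
    double mfe = INF;
    int ei = -1, ej = -1;
    for (int i = 0; i < M; ++i)
        for (int j = 0; j < N; ++j) {
            if (!std::isfinite(E[at(i, j)])) continue;
            const double e = E[at(i, j)] + dangle * (M - 1 - i);
            if (e < mfe) { mfe = e; ei = i; ej = j; }
        }
    if (ei < 0)
        return List::create(_["mfe"] = R_PosInf);

    // traceback -> column list (pairs and gaps), first..last pair
    std::vector<int> pi, pj;
    for (int i = ei, j = ej; i >= 0;) {
        pi.push_back(i); pj.push_back(j);
        const int ni = tpi[at(i, j)], nj = tpj[at(i, j)];
        if (ni < 0) break;
        i = ni; j = nj;
    }
    std::reverse(pi.begin(), pi.end());
    std::reverse(pj.begin(), pj.end());

    std::string diagram;
    int n_pairs = 0, n_wobble = 0, n_mismatch = 0, n_bulge = 0;
    for (size_t c = 0; c < pi.size(); ++c) {
        if (c > 0) {
            const int gm = pi[c] - pi[c - 1] - 1, gw = pj[c] - pj[c - 1] - 1;
            const int mm = std::min(gm, gw), bu = std::abs(gm - gw);
            for (int t = 0; t < mm; ++t) diagram += '*';
            for (int t = 0; t < bu; ++t) diagram += '-';
            n_mismatch += mm;
            n_bulge += bu;
        }
        const int pc = pair_code(m[pi[c]], r[pj[c]]);
        diagram += (pc >= 5) ? 'x' : '|';
        ++n_pairs;
        if (pc >= 5) ++n_wobble;
    }

    return List::create(
        _["mfe"] = mfe,
        _["mir_first"] = pi.front() + 1, _["mir_last"] = pi.back() + 1,
        _["rev_first"] = pj.front() + 1, _["rev_last"] = pj.back() + 1,
        _["diagram"] = diagram,
        _["n_pairs"] = n_pairs, _["n_wobble"] = n_wobble,
        _["n_mismatch"] = n_mismatch, _["n_bulge"] = n_bulge);
}
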