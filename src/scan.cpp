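// Semi-global sequence-structure scanning DP.
//
// One left-to-right pass over the target evaluates the prefix matrix
// S* with free left-end target deletions; helper slices of the global
// subscore matrix S (fixed right ends) are materialized just long
// enough to derive the sparse base-pair-match entries D, which live in
// a hash keyed by (target pair, query pair) and are freed once their
// target left end falls out of the span band.  Scores are integer
// centi-units with a saturating minus-infinity sentinel; gaps are
// affine (three-state extension; the linear model is gapOpening = 0).
//
// Traceback recomputes S* on a bounded region [i0-1, j] x [0, m]
// (plus the D entries restricted to it) and walks the matrices with a
// fixed deterministic tie order: target deletion, query deletion,
// sequence match, then structure cases by smallest target left end and
// smallest query left end.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstring>
#include "common.h"

using namespace Rcpp;

namespace {

typedef long long ll;

struct Pair4 {
    int a, b;    // left, right (1-based)
    ll psi;      // centi-unit structure contribution
};

struct ScanCtx {
    int n, m, L, nq, ntp;
    ll gamma, go;            // gap extension / opening (centi-units, <= 0)
    bool globalGaps;
    std::vector<int> s;      // 1-based target residues, 0..4
    std::vector<ll> sig;     // 5 * (m+1): sig[b*(m+1)+k]
    std::vector<Pair4> tp, qp;
    std::vector<ll> tau;     // nq * 16 (target residues at pair ends)
    std::vector<std::vector<int> > tpByRight, tpByLeft, qpByRight, qpByLeft;
    std::unordered_map<ll, ll> D;

    // instrumentation
    ll peakLive, cells, bandCells;

    ll dkey(int tpIdx, int qpIdx) const { return (ll)tpIdx * nq + qpIdx; }

    ll sigma(int base, int k) const { return sig[(size_t)base * (m + 1) + k]; }
    ll tauAt(int qpIdx, int ta, int tb) const {
        if (ta > 3 || tb > 3) return 0;
        return tau[(size_t)qpIdx * 16 + ta * 4 + tb];
    }

    void index() {
        ntp = tp.size();
        nq = qp.size();
        tpByRight.assign(n + 2, std::vector<int>());
        tpByLeft.assign(n + 2, std::vector<int>());
        qpByRight.assign(m + 2, std::vector<int>());
        qpByLeft.assign(m + 2, std::vector<int>());
        for (int t = 0; t < ntp; ++t) {
            tpByRight[tp[t].b].push_back(t);
            tpByLeft[tp[t].a].push_back(t);
        }
        // deterministic trace order: ascending left end / right end
        for (int j = 0; j <= n + 1; ++j) {
            std::sort(tpByRight[j].begin(), tpByRight[j].end(),
                      [&](int x, int y) { return tp[x].a < tp[y].a; });
            std::sort(tpByLeft[j].begin(), tpByLeft[j].end(),
                      [&](int x, int y) { return tp[x].b < tp[y].b; });
        }
        for (int t = 0; t < nq; ++t) {
            qpByRight[qp[t].b].push_back(t);
            qpByLeft[qp[t].a].push_back(t);
        }
        for (int l = 0; l <= m + 1; ++l) {
            std::sort(qpByRight[l].begin(), qpByRight[l].end(),
                      [&](int x, int y) { return qp[x].a < qp[y].a; });
            std::sort(qpByLeft[l].begin(), qpByLeft[l].end(),
                      [&](int x, int y) { return qp[x].b < qp[y].b; });
        }
    }

    // ---- S slice with fixed right ends (jr, lr), rows i0..jr+1 ----
    // Global subscore semantics: all gaps inside the block are scored,
    // one opening per maximal run.
    struct Slice {
        int jr, lr, i0, k0, rows, cols;
        std::vector<ll> M, X, Y;
        int idx(int i, int k) const { return (i - i0) * cols + (k - k0); }
        ll best(int i, int k) const {
            if (i == jr + 1 && k == lr + 1) return 0;
            int t = idx(i, k);
            return max3(M[t], X[t], Y[t]);
        }
    };

    // Rows i0..jr+1 and columns k0..lr+1 only: callers restrict the
    // rectangle to the cells reachable from the D entries they derive.
    void computeSlice(Slice& sl, int jr, int lr, int i0, int k0) {
        sl.jr = jr;
        sl.lr = lr;
        sl.i0 = i0;
        sl.k0 = k0;
        sl.rows = jr + 1 - i0 + 1;
        sl.cols = lr + 1 - k0 + 1;
        size_t sz = (size_t)sl.rows * sl.cols;
        sl.M.assign(sz, NEG_SENTINEL);
        sl.X.assign(sz, NEG_SENTINEL);
        sl.Y.assign(sz, NEG_SENTINEL);
        cells += sz;
        for (int i = jr + 1; i >= i0; --i) {
            for (int k = lr + 1; k >= k0; --k) {
                int t = sl.idx(i, k);
                if (i == jr + 1 && k == lr + 1) continue;  // virtual 0 corner
                if (i == jr + 1) {
                    // empty target range: one query-deletion run
                    ll prevM = (k + 1 == lr + 1) ? 0 : NEG_SENTINEL;
                    ll py = sl.Y[sl.idx(i, k + 1)];
                    sl.Y[t] = sat_add(gamma, max2(py, sat_add(go, prevM)));
                    continue;
                }
                if (k == lr + 1) {
                    ll prevM = (i + 1 == jr + 1) ? 0 : NEG_SENTINEL;
                    ll px = sl.X[sl.idx(i + 1, k)];
                    sl.X[t] = sat_add(gamma, max2(px, sat_add(go, prevM)));
                    continue;
                }
                // interior
                ll mv = sat_add(sigma(s[i], k), sl.best(i + 1, k + 1));
                const std::vector<int>& tl = tpByLeft[i];
                if (!tl.empty() && !qpByLeft[k].empty()) {
                    for (size_t a = 0; a < tl.size(); ++a) {
                        int ti = tl[a];
                        int j2 = tp[ti].b;
                        if (j2 > jr) break;
                        const std::vector<int>& ql = qpByLeft[k];
                        for (size_t bq = 0; bq < ql.size(); ++bq) {
                            int qi = ql[bq];
                            int l2 = qp[qi].b;
                            if (l2 > lr) break;
                            std::unordered_map<ll, ll>::const_iterator it =
                                D.find(dkey(ti, qi));
                            if (it == D.end()) continue;
                            ll v = sat_add(it->second, sl.best(j2 + 1, l2 + 1));
                            if (v > mv) mv = v;
                        }
                    }
                }
                sl.M[t] = mv;
                ll m1 = sl.M[sl.idx(i + 1, k)], x1 = sl.X[sl.idx(i + 1, k)],
                   y1 = sl.Y[sl.idx(i + 1, k)];
                sl.X[t] = sat_add(gamma, max2(x1, sat_add(go, max2(m1, y1))));
                ll m2 = sl.M[sl.idx(i, k + 1)], x2 = sl.X[sl.idx(i, k + 1)],
                   y2 = sl.Y[sl.idx(i, k + 1)];
                sl.Y[t] = sat_add(gamma, max2(y2, sat_add(go, max2(m2, x2))));
            }
        }
    }

    // Derive D entries for target pairs ending at j (right end), using
    // slices (j-1, l-1) for every query pair right end l.
    // iMin restricts left ends (traceback regions); 1 during scanning.
    void deriveD(int j, int iMin, ll* liveSlice) {
        const std::vector<int>& tr = tpByRight[j];
        if (tr.empty() || nq == 0) return;
        Slice sl;
        for (int l = 1; l <= m; ++l) {
            const std::vector<int>& qr = qpByRight[l];
            if (qr.empty()) continue;
            int iRegion = std::max(iMin, j - L);
            if (iRegion > j) continue;
            // cells reachable from the derived D entries only
            int minLeft = j, minK = m + 1;
            for (size_t a = 0; a < tr.size(); ++a)
                if (tp[tr[a]].a >= iRegion && tp[tr[a]].a < minLeft)
                    minLeft = tp[tr[a]].a;
            for (size_t bq = 0; bq < qr.size(); ++bq)
                if (qp[qr[bq]].a < minK) minK = qp[qr[bq]].a;
            int i0 = std::max(iRegion, std::min(minLeft + 1, j));
            int k0 = std::min(minK + 1, l);
            computeSlice(sl, j - 1, l - 1, i0, k0);
            if (liveSlice) {
                *liveSlice = (ll)sl.rows * sl.cols;
                ll live = bandCells + *liveSlice + (ll)D.size();
                if (live > peakLive) peakLive = live;
            }
            for (size_t a = 0; a < tr.size(); ++a) {
                int ti = tr[a];
                int i = tp[ti].a;
                if (i < iRegion) continue;
                for (size_t bq = 0; bq < qr.size(); ++bq) {
                    int qi = qr[bq];
                    int k = qp[qi].a;
                    ll inner = sl.best(i + 1, k + 1);
                    ll v = sat_add(inner, sat_add(tp[ti].psi,
                              sat_add(qp[qi].psi, tauAt(qi, s[i], s[j]))));
                    D[dkey(ti, qi)] = v;
                }
            }
        }
    }

    // ---- the scan: band-limited S* over the whole target ----
    void run(std::vector<ll>& sj) {
        index();
        int R = L + 2;  // ring rows: Eq. for S* reads back at most L+1 rows
        std::vector<ll> BM((size_t)R * (m + 1)), BX((size_t)R * (m + 1)),
            BY((size_t)R * (m + 1));
        bandCells = (ll)R * (m + 1);
        peakLive = bandCells;
        cells = 0;
        sj.assign(n + 1, NEG_SENTINEL);
        ll liveSlice = 0;

        for (int j = 0; j <= n; ++j) {
            if (j >= 1) deriveD(j, 1, &liveSlice);
            int r = j % R;
            ll* M = &BM[(size_t)r * (m + 1)];
            ll* X = &BX[(size_t)r * (m + 1)];
            ll* Y = &BY[(size_t)r * (m + 1)];
            const ll* Mp = NULL;
            const ll* Xp = NULL;
            const ll* Yp = NULL;
            if (j >= 1) {
                int rp = (j - 1) % R;
                Mp = &BM[(size_t)rp * (m + 1)];
                Xp = &BX[(size_t)rp * (m + 1)];
                Yp = &BY[(size_t)rp * (m + 1)];
            }
            // l = 0 column
            if (!globalGaps || j == 0) {
                M[0] = 0;
                X[0] = NEG_SENTINEL;
            } else {
                M[0] = NEG_SENTINEL;
                X[0] = sat_add(go, gamma * (ll)j);
            }
            Y[0] = NEG_SENTINEL;
            for (int l = 1; l <= m; ++l) {
                if (j == 0) {
                    M[l] = NEG_SENTINEL;
                    X[l] = NEG_SENTINEL;
                    Y[l] = sat_add(go, gamma * (ll)l);
                    continue;
                }
                ll diag = sat_add(sigma(s[j], l),
                                  max3(Mp[l - 1], Xp[l - 1], Yp[l - 1]));
                ll mv = diag;
                const std::vector<int>& tr = tpByRight[j];
                const std::vector<int>& qr = qpByRight[l];
                if (!tr.empty() && !qr.empty()) {
                    for (size_t a = 0; a < tr.size(); ++a) {
                        int ti = tr[a];
                        int i2 = tp[ti].a;
                        for (size_t bq = 0; bq < qr.size(); ++bq) {
                            int qi = qr[bq];
                            int k2 = qp[qi].a;
                            std::unordered_map<ll, ll>::const_iterator it =
                                D.find(dkey(ti, qi));
                            if (it == D.end()) continue;
                            ll pre = bandBest(BM, BX, BY, i2 - 1, k2 - 1, R);
                            ll v = sat_add(pre, it->second);
                            if (v > mv) mv = v;
                        }
                    }
                }
                M[l] = mv;
                X[l] = sat_add(gamma, max2(Xp[l], sat_add(go, max2(Mp[l], Yp[l]))));
                Y[l] = sat_add(gamma,
                               max2(Y[l - 1], sat_add(go, max2(M[l - 1], X[l - 1]))));
            }
            cells += m + 1;
            sj[j] = max3(M[m], X[m], Y[m]);
            // free D entries whose target left end falls out of the band
            int expire = j - L;
            if (expire >= 1) {
                const std::vector<int>& tl = tpByLeft[expire];
                for (size_t a = 0; a < tl.size(); ++a)
                    for (int q = 0; q < nq; ++q) D.erase(dkey(tl[a], q));
            }
            ll live = bandCells + (ll)D.size();
            if (live > peakLive) peakLive = live;
        }
    }

    ll bandBest(const std::vector<ll>& BM, const std::vector<ll>& BX,
                const std::vector<ll>& BY, int j, int l, int R) const {
        int r = j % R;
        size_t t = (size_t)r * (m + 1) + l;
        return max3(BM[t], BX[t], BY[t]);
    }
};

ScanCtx* build_ctx(IntegerVector seq, int m, NumericMatrix sigma,
                   IntegerVector tpi, IntegerVector tpj, NumericVector tpPsi,
                   IntegerVector qpk, IntegerVector qpl, NumericVector qpPsi,
                   NumericMatrix tau, double gamma, double gapOpen, int L,
                   bool globalGaps) {
    ScanCtx* C = new ScanCtx();
    C->n = seq.size();
    C->m = m;
    C->L = L;
    C->gamma = (ll)llround(gamma);
    C->go = (ll)llround(gapOpen);
    C->globalGaps = globalGaps;
    C->s.assign(C->n + 1, 4);
    for (int i = 0; i < C->n; ++i) C->s[i + 1] = seq[i];
    C->sig.assign((size_t)5 * (m + 1), 0);
    for (int b = 0; b < 5; ++b)
        for (int k = 1; k <= m; ++k) {
            double v = sigma(b, k - 1);
            C->sig[(size_t)b * (m + 1) + k] =
                R_finite(v) ? (ll)llround(v) : NEG_SENTINEL;
        }
    for (int t = 0; t < tpi.size(); ++t) {
        Pair4 p;
        p.a = tpi[t];
        p.b = tpj[t];
        double ps = tpPsi[t];
        p.psi = R_finite(ps) ? (ll)llround(ps) : NEG_SENTINEL;
        C->tp.push_back(p);
    }
    for (int t = 0; t < qpk.size(); ++t) {
        Pair4 p;
        p.a = qpk[t];
        p.b = qpl[t];
        double ps = qpPsi[t];
        p.psi = R_finite(ps) ? (ll)llround(ps) : NEG_SENTINEL;
        C->qp.push_back(p);
    }
    int nq = qpk.size();
    C->tau.assign((size_t)nq * 16, 0);
    for (int q = 0; q < nq; ++q)
        for (int c = 0; c < 16; ++c) {
            double v = tau(q, c);
            C->tau[(size_t)q * 16 + c] =
                R_finite(v) ? (ll)llround(v) : NEG_SENTINEL;
        }
    return C;
}

}  // namespace

// [[Rcpp::export]]
List c_scan(IntegerVector seq, int m, NumericMatrix sigma, IntegerVector tpi,
            IntegerVector tpj, NumericVector tpPsi, IntegerVector qpk,
            IntegerVector qpl, NumericVector qpPsi, NumericMatrix tau,
            double gamma, double gapOpen, int L, bool globalGaps) {
    ScanCtx* C = build_ctx(seq, m, sigma, tpi, tpj, tpPsi, qpk, qpl, qpPsi, tau,
                           gamma, gapOpen, L, globalGaps);
    std::vector<ll> sj;
    C->run(sj);
    NumericVector out(C->n);
    for (int j = 1; j <= C->n; ++j)
        out[j - 1] = (sj[j] <= NEG_SENTINEL) ? R_NegInf : (double)sj[j];
    List res = List::create(_["sj"] = out, _["peak_live"] = (double)C->peakLive,
                            _["cells"] = (double)C->cells,
                            _["n_dpairs"] = (double)0);
    delete C;
    return res;
}

// Global subscore S_{i,j;k,l} for one block, for tests of the slice
// recursion.  Runs the D derivation for all steps up to j (no expiry
// concerns: intended for small inputs only).
// [[Rcpp::export]]
double c_subscore(IntegerVector seq, int m, NumericMatrix sigma,
                  IntegerVector tpi, IntegerVector tpj, NumericVector tpPsi,
                  IntegerVector qpk, IntegerVector qpl, NumericVector qpPsi,
                  NumericMatrix tau, double gamma, double gapOpen, int L,
                  int i, int j, int k, int l) {
    ScanCtx* C = build_ctx(seq, m, sigma, tpi, tpj, tpPsi, qpk, qpl, qpPsi, tau,
                           gamma, gapOpen, L, false);
    C->index();
    C->peakLive = C->cells = C->bandCells = 0;
    for (int jj = 1; jj <= j; ++jj) C->deriveD(jj, 1, NULL);
    ScanCtx::Slice sl;
    C->computeSlice(sl, j, l, std::max(1, std::min(i, j + 1)), 1);
    ll v = (i <= j || k <= l || true) ? sl.best(i, k) : 0;
    delete C;
    return v <= NEG_SENTINEL ? R_NegInf : (double)v;
}

namespace {

struct TraceOut {
    std::vector<int> ei, ek;              // alignment edges
    std::vector<int> pi, pj, pk, pl;      // matched base pairs
};

struct Region {
    int i0, j1, m;  // rows i0-1..j1, cols 0..m
    std::vector<ll> M, X, Y;
    int cols;
    size_t idx(int j, int l) const { return (size_t)(j - (i0 - 1)) * cols + l; }
    ll best(int j, int l) const {
        size_t t = idx(j, l);
        return max3(M[t], X[t], Y[t]);
    }
};

struct Tracer {
    ScanCtx& C;
    TraceOut& out;
    Tracer(ScanCtx& c, TraceOut& o) : C(c), o_(o), out(o) {}
    TraceOut& o_;

    void traceSlice(int jr, int lr, int i0s, int istart, int kstart) {
        ScanCtx::Slice sl;
        C.computeSlice(sl, jr, lr, i0s, kstart);
        int i = istart, k = kstart;
        while (!(i == jr + 1 && k == lr + 1)) {
            if (i == jr + 1) { ++k; continue; }
            if (k == lr + 1) { ++i; continue; }
            ll v = sl.best(i, k);
            if (v <= NEG_SENTINEL)
                stop("internal: slice traceback hit -inf cell");
            size_t t = sl.idx(i, k);
            if (sl.X[t] == v) { ++i; continue; }
            if (sl.Y[t] == v) { ++k; continue; }
            // match state
            if (sat_add(C.sigma(C.s[i], k), sl.best(i + 1, k + 1)) == v) {
                out.ei.push_back(i);
                out.ek.push_back(k);
                ++i;
                ++k;
                continue;
            }
            bool found = false;
            const std::vector<int>& tl = C.tpByLeft[i];
            for (size_t a = 0; a < tl.size() && !found; ++a) {
                int ti = tl[a];
                int j2 = C.tp[ti].b;
                if (j2 > jr) break;
                const std::vector<int>& ql = C.qpByLeft[k];
                for (size_t bq = 0; bq < ql.size() && !found; ++bq) {
                    int qi = ql[bq];
                    int l2 = C.qp[qi].b;
                    if (l2 > lr) break;
                    std::unordered_map<ll, ll>::const_iterator it =
                        C.D.find(C.dkey(ti, qi));
                    if (it == C.D.end()) continue;
                    if (sat_add(it->second, sl.best(j2 + 1, l2 + 1)) == v) {
                        emitPair(ti, qi);
                        traceSlice(j2 - 1, l2 - 1, i + 1, i + 1, k + 1);
                        i = j2 + 1;
                        k = l2 + 1;
                        found = true;
                    }
                }
            }
            if (!found) stop("internal: slice traceback found no predecessor");
        }
    }

    void emitPair(int ti, int qi) {
        out.pi.push_back(C.tp[ti].a);
        out.pj.push_back(C.tp[ti].b);
        out.pk.push_back(C.qp[qi].a);
        out.pl.push_back(C.qp[qi].b);
        out.ei.push_back(C.tp[ti].a);
        out.ek.push_back(C.qp[qi].a);
        out.ei.push_back(C.tp[ti].b);
        out.ek.push_back(C.qp[qi].b);
    }

    void traceRegion(const Region& R, int j, int l) {
        while (l > 0) {
            ll v = R.best(j, l);
            if (v <= NEG_SENTINEL)
                stop("internal: traceback hit -inf cell");
            size_t t = R.idx(j, l);
            if (R.X[t] == v) { --j; continue; }
            if (R.Y[t] == v) { --l; continue; }
            if (sat_add(C.sigma(C.s[j], l), R.best(j - 1, l - 1)) == v) {
                out.ei.push_back(j);
                out.ek.push_back(l);
                --j;
                --l;
                continue;
            }
            bool found = false;
            const std::vector<int>& tr = C.tpByRight[j];
            for (size_t a = 0; a < tr.size() && !found; ++a) {
                int ti = tr[a];
                int i2 = C.tp[ti].a;
                if (i2 - 1 < R.i0 - 1) continue;
                const std::vector<int>& qr = C.qpByRight[l];
                for (size_t bq = 0; bq < qr.size() && !found; ++bq) {
                    int qi = qr[bq];
                    int k2 = C.qp[qi].a;
                    std::unordered_map<ll, ll>::const_iterator it =
                        C.D.find(C.dkey(ti, qi));
                    if (it == C.D.end()) continue;
                    if (sat_add(R.best(i2 - 1, k2 - 1), it->second) == v) {
                        emitPair(ti, qi);
                        traceSlice(j - 1, l - 1, i2 + 1, i2 + 1, k2 + 1);
                        j = i2 - 1;
                        l = k2 - 1;
                        found = true;
                    }
                }
            }
            if (!found) stop("internal: traceback found no predecessor");
        }
    }
};

}  // namespace

// Recompute the S* region [i0-1 .. j] x [0 .. m] and trace the
// occurrence with right end j.  Returns the recomputed score (for the
// consistency check against the recorded s_j), the alignment edges and
// the matched base pairs (all 1-based).
// [[Rcpp::export]]
List c_traceback(IntegerVector seq, int m, NumericMatrix sigma,
                 IntegerVector tpi, IntegerVector tpj, NumericVector tpPsi,
                 IntegerVector qpk, IntegerVector qpl, NumericVector qpPsi,
                 NumericMatrix tau, double gamma, double gapOpen, int L, int j,
                 int i0) {
    ScanCtx* Cp = build_ctx(seq, m, sigma, tpi, tpj, tpPsi, qpk, qpl, qpPsi,
                            tau, gamma, gapOpen, L, false);
    ScanCtx& C = *Cp;
    C.index();
    C.peakLive = C.cells = C.bandCells = 0;
    // D entries restricted to the region
    for (int jj = i0; jj <= j; ++jj) C.deriveD(jj, i0, NULL);

    Region R;
    R.i0 = i0;
    R.j1 = j;
    R.m = m;
    R.cols = m + 1;
    size_t sz = (size_t)(j - (i0 - 1) + 1) * R.cols;
    R.M.assign(sz, NEG_SENTINEL);
    R.X.assign(sz, NEG_SENTINEL);
    R.Y.assign(sz, NEG_SENTINEL);
    R.M[R.idx(i0 - 1, 0)] = 0;
    if (i0 == 1) {
        // the region starts at the true matrix boundary: row 0 carries
        // the query-deletion initialization S*(0, l)
        for (int l = 1; l <= m; ++l)
            R.Y[R.idx(0, l)] = sat_add(C.go, C.gamma * (ll)l);
    }
    for (int jj = i0; jj <= j; ++jj) {
        R.M[R.idx(jj, 0)] = 0;
        for (int l = 1; l <= m; ++l) {
            ll diag = sat_add(C.sigma(C.s[jj], l), R.best(jj - 1, l - 1));
            ll mv = diag;
            const std::vector<int>& tr = C.tpByRight[jj];
            const std::vector<int>& qr = C.qpByRight[l];
            for (size_t a = 0; a < tr.size(); ++a) {
                int ti = tr[a];
                int i2 = C.tp[ti].a;
                if (i2 < i0) continue;
                for (size_t bq = 0; bq < qr.size(); ++bq) {
                    int qi = qr[bq];
                    int k2 = C.qp[qi].a;
                    std::unordered_map<ll, ll>::const_iterator it =
                        C.D.find(C.dkey(ti, qi));
                    if (it == C.D.end()) continue;
                    ll v = sat_add(R.best(i2 - 1, k2 - 1), it->second);
                    if (v > mv) mv = v;
                }
            }
            size_t t = R.idx(jj, l);
            size_t tp_ = R.idx(jj - 1, l);
            R.M[t] = mv;
            R.X[t] = sat_add(C.gamma,
                             max2(R.X[tp_], sat_add(C.go, max2(R.M[tp_], R.Y[tp_]))));
            size_t tl_ = R.idx(jj, l - 1);
            R.Y[t] = sat_add(C.gamma,
                             max2(R.Y[tl_], sat_add(C.go, max2(R.M[tl_], R.X[tl_]))));
        }
    }
    ll score = R.best(j, m);

    TraceOut out;
    Tracer tracer(C, out);
    tracer.traceRegion(R, j, m);

    List res = List::create(
        _["score"] = (score <= NEG_SENTINEL) ? R_NegInf : (double)score,
        _["edge_i"] = wrap(out.ei), _["edge_k"] = wrap(out.ek),
        _["pair_ti"] = wrap(out.pi), _["pair_tj"] = wrap(out.pj),
        _["pair_qk"] = wrap(out.pk), _["pair_ql"] = wrap(out.pl));
    delete Cp;
    return res;
}
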