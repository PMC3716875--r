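// Simplified Nussinov-Boltzmann folding engine.
//
// The model assigns an additive energy to every canonical base pair
// (no stacking or loop terms), a minimum hairpin loop size, and an
// optional exclusion of lonely pairs (every helix must stack at least
// two pairs).  Inside partition values are computed once for the whole
// sequence on a band of widths up to the folding window W; the
// per-window pair probabilities are then obtained by an outside pass
// over each window of length W (step 1) and averaged over all windows
// that fully contain a pair, mirroring sliding-window local folding.
//
// Numerics: values are scaled by s^-length (s = exp(scale_per_nt)) so
// that doubles cover both GC-dense and unstructured windows; all
// reported quantities are ratios in which the scale cancels exactly.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>
#include <cstring>

using namespace Rcpp;

namespace {

struct Model {
    double w[5][5];   // scaled Boltzmann weight exp(-E/RT)/s^2; 0 if not pairable
    double E[5][5];   // energy; 0 if not pairable
    bool canPair[5][5];
    int minLoop;
    bool noLP;
    double RT;
    double sPer;      // per-nucleotide scale factor s
    double invS;
    double helixInit; // energy penalty per helix
    double wInit;     // exp(-helixInit/RT)
};

Model make_model(NumericMatrix pairE, int minLoop, bool noLP, double RT,
                 double scalePerNt, double helixInit) {
    Model m;
    m.minLoop = minLoop;
    m.noLP = noLP;
    m.RT = RT;
    m.helixInit = helixInit;
    m.wInit = std::exp(-helixInit / RT);
    m.sPer = std::exp(scalePerNt);
    m.invS = 1.0 / m.sPer;
    double inv2 = m.invS * m.invS;
    for (int a = 0; a < 5; ++a)
        for (int b = 0; b < 5; ++b) {
            double e = (a < 4 && b < 4) ? pairE(a, b) : 0.0;
            bool can = (a < 4 && b < 4) && (e != 0.0);
            m.canPair[a][b] = can;
            m.E[a][b] = can ? e : 0.0;
            m.w[a][b] = can ? std::exp(-e / RT) * inv2 : 0.0;
        }
    return m;
}

// Inside band: Z over segments of length <= W, helix terms ZH for spans <= L.
struct Inside {
    int n, W, L;
    std::vector<int> s;
    Model mod;
    std::vector<double> Z;    // [i*W + (j-i)], scaled
    std::vector<double> ZH;   // [i*(L+1) + (j-i)]
    std::vector<std::vector<int> > partners;  // k with ZH(i,k) > 0

    double z(int i, int j) const {
        if (i > j) return 1.0;
        return Z[(size_t)i * W + (j - i)];
    }
    double zh(int i, int j) const {
        int d = j - i;
        if (d < 1 || d > L) return 0.0;
        return ZH[(size_t)i * (L + 1) + d];
    }

    void compute() {
        Z.assign((size_t)n * W, 0.0);
        ZH.assign((size_t)n * (L + 1), 0.0);
        partners.assign(n, std::vector<int>());
        int hmin = mod.noLP ? 2 : 1;
        std::vector<double> buf(L / 2 + 2);
        for (int i = n - 1; i >= 0; --i) {
            int dmax = std::min(W - 1, n - 1 - i);
            // helix terms first (depend on strictly inner segments)
            int dmaxH = std::min(L, dmax);
            for (int d = 1; d <= dmaxH; ++d) {
                int j = i + d;
                if (!mod.canPair[s[i]][s[j]]) continue;
                int hmax = (d + 1 - mod.minLoop) / 2;
                if (hmax < hmin) continue;
                double B = 1.0, val = 0.0;
                for (int h = 1; h <= hmax; ++h) {
                    double wp = mod.w[s[i + h - 1]][s[j - h + 1]];
                    if (wp == 0.0) break;
                    B *= wp;
                    if (h < hmin) continue;
                    int x = i + h, y = j - h;
                    double znp = z(x, y) - zh(x, y);
                    val += B * znp;
                }
                if (val > 0.0) {
                    ZH[(size_t)i * (L + 1) + d] = val * mod.wInit;
                    partners[i].push_back(j);
                }
            }
            // segment values
            const std::vector<int>& pt = partners[i];
            for (int d = 0; d <= dmax; ++d) {
                int j = i + d;
                double v = z(i + 1, j) * mod.invS;
                for (size_t t = 0; t < pt.size(); ++t) {
                    int k = pt[t];
                    if (k > j) break;
                    v += zh(i, k) * z(k + 1, j);
                }
                Z[(size_t)i * W + d] = v;
            }
        }
    }
};

Inside build_inside(IntegerVector seq, int W, int L, NumericMatrix pairE,
                    int minLoop, bool noLP, double RT, double scalePerNt,
                    double helixInit) {
    Inside in;
    in.n = seq.size();
    if (W > in.n) W = in.n;
    if (L > W - 1) L = std::max(1, W - 1);
    in.W = W;
    in.L = L;
    in.s.assign(seq.begin(), seq.end());
    in.mod = make_model(pairE, minLoop, noLP, RT, scalePerNt, helixInit);
    in.compute();
    return in;
}

}  // namespace

// Window-averaged base pair probabilities.
// seq: 0=A,1=C,2=G,3=U,4=N (1-based positions on the R side).
// Returns triplets (i, j, p) with p >= floorP, 1-based, i < j, j-i <= L.
// [[Rcpp::export]]
List c_window_bpp(IntegerVector seq, int W, int L, NumericMatrix pairE,
                  int minLoop, bool noLP, double RT, double floorP,
                  double scalePerNt, double helixInit) {
    int n = seq.size();
    if (n < minLoop + 2) {
        return List::create(_["i"] = IntegerVector(0),
                            _["j"] = IntegerVector(0),
                            _["p"] = NumericVector(0));
    }
    Inside in = build_inside(seq, W, L, pairE, minLoop, noLP, RT, scalePerNt,
                             helixInit);
    W = in.W;
    L = in.L;
    const Model& mod = in.mod;
    int hmin = mod.noLP ? 2 : 1;

    std::vector<double> sumP((size_t)n * (L + 1), 0.0);
    size_t wsz = (size_t)W * W;
    std::vector<double> OZ(wsz), OZH(wsz), PA(wsz);
    std::vector<double> buf(L / 2 + 2);

    int nwin = n - W + 1;
    for (int a = 0; a < nwin; ++a) {
        int b = a + W - 1;
        double ztot = in.z(a, b);
        if (!(ztot > 0.0)) continue;
        std::fill(OZ.begin(), OZ.end(), 0.0);
        std::fill(OZH.begin(), OZH.end(), 0.0);
        std::fill(PA.begin(), PA.end(), 0.0);
        OZ[0 * W + (W - 1)] = 1.0;

        for (int len = W; len >= 1; --len) {
            for (int i = a; i + len - 1 <= b; ++i) {
                int j = i + len - 1;
                int ii = i - a, jj = j - a;
                double oz = OZ[(size_t)ii * W + jj];
                if (oz != 0.0) {
                    if (len >= 2) OZ[(size_t)(ii + 1) * W + jj] += oz * mod.invS;
                    const std::vector<int>& pt = in.partners[i];
                    for (size_t t = 0; t < pt.size(); ++t) {
                        int k = pt[t];
                        if (k > j) break;
                        double zhik = in.zh(i, k);
                        OZH[(size_t)ii * W + (k - a)] += oz * in.z(k + 1, j);
                        if (k < j) OZ[(size_t)(k - a + 1) * W + jj] += oz * zhik;
                    }
                }
                // distribute the outside of a helix rooted at (i,j)
                int d = len - 1;
                if (d >= 1 && d <= L && in.zh(i, j) > 0.0) {
                    double ozh = OZH[(size_t)ii * W + jj];
                    if (ozh != 0.0) {
                        int hmax = (d + 1 - mod.minLoop) / 2;
                        double B = mod.wInit;
                        int heff = 0;
                        for (int h = 1; h <= hmax; ++h) {
                            double wp = mod.w[in.s[i + h - 1]][in.s[j - h + 1]];
                            if (wp == 0.0) break;
                            B *= wp;
                            buf[h] = B;
                            heff = h;
                        }
                        double suffix = 0.0;
                        for (int h = heff; h >= hmin; --h) {
                            int x = i + h, y = j - h;
                            double znp = in.z(x, y) - in.zh(x, y);
                            suffix += buf[h] * znp;
                            PA[(size_t)(i + h - 1 - a) * W + (j - h + 1 - a)] +=
                                ozh * suffix;
                            double c = ozh * buf[h];
                            if (x <= y) {
                                OZ[(size_t)(x - a) * W + (y - a)] += c;
                                OZH[(size_t)(x - a) * W + (y - a)] -= c;
                            }
                        }
                        // pairs above the minimal helix depth (with the
                        // lonely-pair exclusion the outermost pair sits in
                        // every admitted helix): full helix weight
                        for (int t = 0; t <= hmin - 2; ++t) {
                            PA[(size_t)(i + t - a) * W + (j - t - a)] +=
                                ozh * suffix;
                        }
                    }
                }
            }
        }
        for (int i = a; i <= b; ++i) {
            int dm = std::min(L, b - i);
            for (int d = 1; d <= dm; ++d) {
                double pa = PA[(size_t)(i - a) * W + (i + d - a)];
                if (pa > 0.0) sumP[(size_t)i * (L + 1) + d] += pa / ztot;
            }
        }
    }

    std::vector<int> oi, oj;
    std::vector<double> op;
    for (int i = 0; i < n; ++i) {
        for (int d = 1; d <= L && i + d < n; ++d) {
            double sp = sumP[(size_t)i * (L + 1) + d];
            if (sp <= 0.0) continue;
            int j = i + d;
            // number of windows fully containing (i, j)
            int lo = std::max(0, j - W + 1), hi = std::min(i, n - W);
            int cnt = hi - lo + 1;
            if (cnt <= 0) continue;
            double p = sp / cnt;
            if (p > 1.0 && p < 1.0 + 1e-9) p = 1.0;  // numeric slack
            if (p >= floorP && p > 0.0) {
                oi.push_back(i + 1);
                oj.push_back(j + 1);
                op.push_back(p);
            }
        }
    }
    return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj), _["p"] = wrap(op));
}

// Ensemble probability of one structure (pairs ri[t]..rj[t], 1-based),
// with the full sequence folded in a single window (W = L = n).
// Validity of the structure (canonical pairs, non-crossing, minimum
// loop, helix support under noLP) is checked on the R side; pairs that
// cannot form under the model make the energy term vanish there.
// [[Rcpp::export]]
double c_structure_prob(IntegerVector seq, IntegerVector ri, IntegerVector rj,
                        NumericMatrix pairE, int minLoop, bool noLP, double RT,
                        double scalePerNt, double helixInit) {
    int n = seq.size();
    Inside in = build_inside(seq, n, n, pairE, minLoop, noLP, RT, scalePerNt,
                             helixInit);
    double zhat = in.z(0, n - 1);
    if (!(zhat > 0.0)) return 0.0;
    double logZ = std::log(zhat) + n * std::log(in.mod.sPer);
    double eR = 0.0;
    std::set<std::pair<int, int> > pset;
    for (int t = 0; t < ri.size(); ++t) pset.insert(std::make_pair(ri[t], rj[t]));
    for (int t = 0; t < ri.size(); ++t) {
        int a = in.s[ri[t] - 1], b = in.s[rj[t] - 1];
        if (!in.mod.canPair[a][b]) return 0.0;
        eR += in.mod.E[a][b];
        // helix start: no outward stacking neighbor in the structure
        if (pset.find(std::make_pair(ri[t] - 1, rj[t] + 1)) == pset.end())
            eR += helixInit;
    }
    return std::exp(-eR / RT - logZ);
}

// Log of the total partition function (natural log), single window.
// [[Rcpp::export]]
double c_log_partition(IntegerVector seq, NumericMatrix pairE, int minLoop,
                       bool noLP, double RT, double scalePerNt,
                       double helixInit) {
    int n = seq.size();
    Inside in = build_inside(seq, n, n, pairE, minLoop, noLP, RT, scalePerNt,
                             helixInit);
    double zhat = in.z(0, n - 1);
    return std::log(zhat) + n * std::log(in.mod.sPer);
}

namespace {

// Constrained minimum-energy folding on the same grammar (max-plus).
struct Mfe {
    int n, minLoop, hmin;
    const std::vector<int>& s;
    const Model& mod;
    const std::vector<int>& partner;   // -1 free, -2 forced unpaired, >=0 forced mate
    std::vector<double> M, MH;         // n*n, huge = +inf
    double bonus;
    static const double HUGE_E;

    Mfe(const std::vector<int>& seq, const Model& m, const std::vector<int>& cons,
        double bonus_)
        : n(seq.size()), minLoop(m.minLoop), hmin(m.noLP ? 2 : 1), s(seq),
          mod(m), partner(cons), bonus(bonus_) {}

    bool allowed(int i, int j) const {
        if (!mod.canPair[s[i]][s[j]]) return false;
        if (partner[i] == -2 || partner[j] == -2) return false;
        if (partner[i] >= 0 && partner[i] != j) return false;
        if (partner[j] >= 0 && partner[j] != i) return false;
        return true;
    }
    double pairE(int i, int j) const {
        double e = mod.E[s[i]][s[j]];
        if (partner[i] == j) e -= bonus;
        return e;
    }
    double m(int i, int j) const { return i > j ? 0.0 : M[(size_t)i * n + j]; }
    double mh(int i, int j) const { return MH[(size_t)i * n + j]; }

    void compute() {
        M.assign((size_t)n * n, 0.0);
        MH.assign((size_t)n * n, HUGE_E);
        for (int i = n - 1; i >= 0; --i) {
            for (int d = 1; d <= n - 1 - i; ++d) {
                int j = i + d;
                if (!allowed(i, j)) continue;
                int hmax = (d + 1 - minLoop) / 2;
                if (hmax < hmin) continue;
                double B = mod.helixInit, best = HUGE_E;
                for (int h = 1; h <= hmax; ++h) {
                    if (!allowed(i + h - 1, j - h + 1)) break;
                    B += pairE(i + h - 1, j - h + 1);
                    if (h < hmin) continue;
                    double inner = mnp(i + h, j - h);
                    if (inner >= HUGE_E / 2) continue;
                    double v = B + inner;
                    if (v < best) best = v;
                }
                MH[(size_t)i * n + j] = best;
            }
            for (int d = 0; d <= n - 1 - i; ++d) {
                int j = i + d;
                double v = m(i + 1, j);
                for (int k = i + 1; k <= j; ++k) {
                    double h = mh(i, k);
                    if (h >= HUGE_E / 2) continue;
                    double c = h + m(k + 1, j);
                    if (c < v) v = c;
                }
                M[(size_t)i * n + j] = v;
            }
        }
    }
    // minimum energy with (x,y) not paired to each other
    double mnp(int x, int y) const {
        if (x > y) return 0.0;
        double v = m(x + 1, y);
        for (int k = x + 1; k < y; ++k) {
            double h = mh(x, k);
            if (h >= HUGE_E / 2) continue;
            double c = h + m(k + 1, y);
            if (c < v) v = c;
        }
        return v;
    }

    void traceM(int i, int j, std::vector<int>& pi, std::vector<int>& pj) const {
        const double eps = 1e-9;
        while (i <= j) {
            double v = m(i, j);
            if (m(i + 1, j) <= v + eps) { ++i; continue; }
            bool found = false;
            for (int k = i + 1; k <= j && !found; ++k) {
                double h = mh(i, k);
                if (h >= HUGE_E / 2) continue;
                if (h + m(k + 1, j) <= v + eps) {
                    traceH(i, k, pi, pj);
                    i = k + 1;
                    found = true;
                }
            }
            if (!found) Rcpp::stop("internal: MFE trace failed");
        }
    }
    void traceH(int i, int j, std::vector<int>& pi, std::vector<int>& pj) const {
        const double eps = 1e-9;
        double v = mh(i, j);
        int d = j - i, hmax = (d + 1 - minLoop) / 2;
        double B = mod.helixInit;
        for (int h = 1; h <= hmax; ++h) {
            if (!allowed(i + h - 1, j - h + 1)) break;
            B += pairE(i + h - 1, j - h + 1);
            if (h < hmin) continue;
            double inner = mnp(i + h, j - h);
            if (inner >= HUGE_E / 2) continue;
            if (B + inner <= v + eps) {
                for (int t = 0; t < h; ++t) {
                    pi.push_back(i + t);
                    pj.push_back(j - t);
                }
                traceNP(i + h, j - h, pi, pj);
                return;
            }
        }
        Rcpp::stop("internal: helix trace failed");
    }
    void traceNP(int x, int y, std::vector<int>& pi, std::vector<int>& pj) const {
        const double eps = 1e-9;
        if (x > y) return;
        double v = mnp(x, y);
        if (m(x + 1, y) <= v + eps) { traceM(x + 1, y, pi, pj); return; }
        for (int k = x + 1; k < y; ++k) {
            double h = mh(x, k);
            if (h >= HUGE_E / 2) continue;
            if (h + m(k + 1, y) <= v + eps) {
                traceH(x, k, pi, pj);
                traceM(k + 1, y, pi, pj);
                return;
            }
        }
        Rcpp::stop("internal: trace failed");
    }
};

const double Mfe::HUGE_E = 1e18;

}  // namespace

// Constrained minimum-energy structure.  constraint: -1 free,
// -2 forced unpaired, >= 0 forced partner (0-based on entry from R side
// wrapper, which also validates feasibility).  Returns 1-based pairs.
// [[Rcpp::export]]
List c_mfe_fold(IntegerVector seq, IntegerVector constraint, NumericMatrix pairE,
                int minLoop, bool noLP, double RT, double helixInit) {
    std::vector<int> s(seq.begin(), seq.end());
    std::vector<int> cons(constraint.begin(), constraint.end());
    Model mod = make_model(pairE, minLoop, noLP, RT, 0.0, helixInit);
    Mfe mfe(s, mod, cons, 1e6);
    mfe.compute();
    std::vector<int> pi, pj;
    mfe.traceM(0, (int)s.size() - 1, pi, pj);
    int nforced = 0;
    for (size_t i = 0; i < cons.size(); ++i)
        if (cons[i] > (int)i) ++nforced;
    double energy = 0.0;
    int gotForced = 0;
    std::set<std::pair<int, int> > pset;
    for (size_t t = 0; t < pi.size(); ++t)
        pset.insert(std::make_pair(pi[t], pj[t]));
    for (size_t t = 0; t < pi.size(); ++t) {
        energy += mod.E[s[pi[t]]][s[pj[t]]];
        if (pset.find(std::make_pair(pi[t] - 1, pj[t] + 1)) == pset.end())
            energy += helixInit;
        if (cons[pi[t]] == pj[t]) ++gotForced;
        ++pi[t];
        ++pj[t];
    }
    return List::create(_["i"] = wrap(pi), _["j"] = wrap(pj),
                        _["energy"] = energy,
                        _["forced_ok"] = (gotForced == nforced));
}
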