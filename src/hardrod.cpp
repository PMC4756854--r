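#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// log(exp(x) + exp(y)) without overflow
static inline double lse2(double x, double y) {
    if (x == R_NegInf) return y;
    if (y == R_NegInf) return x;
    double m = (x > y) ? x : y;
    return m + std::log1p(std::exp(((x > y) ? y : x) - m));
}

// Equilibrium statistics of hard rods of length `a` on a 1D lattice of `L`
// sites with hard-wall boundaries. `logw` holds log statistical weights
// beta*mu - u(s) for each valid start s = 1..L-a+1. All recursions are kept
// in the log domain so that partition functions never overflow on
// chromosome-scale lattices.
//
// Returns log n(s): log probability that a rod starts at s.
// [[Rcpp::export(name = ".hardrod_log_density")]]
NumericVector hardrod_log_density(NumericVector logw, int a, int L) {
    int S = L - a + 1;
    if (S < 1) stop("lattice shorter than the rod footprint");
    if (logw.size() != S) stop("logw must have length L - a + 1");

    // forward: lf[i] = log Z(1..i), lf[0] = 0 (empty lattice)
    std::vector<double> lf(L + 1);
    lf[0] = 0.0;
    for (int i = 1; i <= L; ++i) {
        double v = lf[i - 1];
        if (i >= a) v = lse2(v, logw[i - a] + lf[i - a]); // start s = i-a+1
        lf[i] = v;
    }
    // backward: lb[i] = log Z(i..L), lb[L+1] = 0
    std::vector<double> lb(L + 2);
    lb[L + 1] = 0.0;
    for (int i = L; i >= 1; --i) {
        double v = lb[i + 1];
        if (i <= S) v = lse2(v, logw[i - 1] + lb[i + a]);
        lb[i] = v;
    }

    double logZ = lf[L];
    NumericVector logn(S);
    for (int s = 1; s <= S; ++s)
        logn[s - 1] = logw[s - 1] + lf[s - 1] + lb[s + a] - logZ;
    logn.attr("logZ") = logZ;
    return logn;
}

// Draw `k` exact equilibrium configurations by sequential sampling: walking
// left to right, a rod starts at free position i with probability
// w(i) * Z(i+a..L) / Z(i..L). Uses R's RNG, so results are reproducible
// under set.seed(). Returns sorted 1-based starts with a parallel
// configuration index.
// [[Rcpp::export(name = ".hardrod_sample_configs")]]
List hardrod_sample_configs(NumericVector logw, int a, int L, int k) {
    int S = L - a + 1;
    if (S < 1) stop("lattice shorter than the rod footprint");
    if (logw.size() != S) stop("logw must have length L - a + 1");
    std::vector<double> lb(L + 2);
    lb[L + 1] = 0.0;
    for (int i = L; i >= 1; --i) {
        double v = lb[i + 1];
        if (i <= S) v = lse2(v, logw[i - 1] + lb[i + a]);
        lb[i] = v;
    }
    std::vector<int> starts, config;
    GetRNGstate();
    for (int c = 1; c <= k; ++c) {
        int i = 1;
        while (i <= S) {
            double logp = logw[i - 1] + lb[i + a] - lb[i];
            if (std::log(unif_rand()) < logp) {
                starts.push_back(i);
                config.push_back(c);
                i += a;
            } else {
                ++i;
            }
        }
    }
    PutRNGstate();
    return List::create(_["start"] = wrap(starts),
                        _["config"] = wrap(config));
}
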