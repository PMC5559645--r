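// Dirichlet-process binomial mixture Gibbs sampler for multi-sample
// cancer-cell-fraction clustering.
//
// Emission: X[i,s] ~ Binomial(n[i,s], phi[i,s] * p[k,s]) for mutation i in
// cluster k, where phi[i,s] = rho_s * m_is / (rho_s * c_is + 2(1-rho_s))
// maps a cluster CCF p to an expected VAF. Cluster CCFs live on a discrete
// grid over [0, pmax] so parameter updates are exact draws from the
// discrete posterior (uniform prior). Cluster assignments follow a
// collapsed CRP scan with auxiliary components (Neal 2000, algorithm 8);
// the concentration parameter has a Gamma(1,1) hyperprior resampled by the
// Escobar-West auxiliary-variable move each sweep.
//
// All randomness flows through R's RNG, so set.seed() in R makes runs
// reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static int sample_log_weights(const std::vector<double> &logw) {
    double m = logw[0];
    for (size_t j = 1; j < logw.size(); ++j) if (logw[j] > m) m = logw[j];
    double tot = 0.0;
    std::vector<double> w(logw.size());
    for (size_t j = 0; j < logw.size(); ++j) { w[j] = std::exp(logw[j] - m); tot += w[j]; }
    double u = R::runif(0.0, tot);
    double acc = 0.0;
    for (size_t j = 0; j < logw.size(); ++j) { acc += w[j]; if (u <= acc) return (int)j; }
    return (int)logw.size() - 1;
}

// [[Rcpp::export(name = ".dp_gibbs")]]
List dp_gibbs(IntegerMatrix X, IntegerMatrix n, NumericMatrix phi,
              int iterations, int burnin, int naux, double pmax,
              double gridStep) {
    const int N = X.nrow(), S = X.ncol();
    const int G = (int)std::floor(pmax / gridStep + 1e-9) + 1;

    // Precompute log-likelihood of every mutation/sample at every grid CCF.
    // logL[i][s*G + g]
    std::vector< std::vector<double> > logL(N, std::vector<double>(S * G));
    for (int i = 0; i < N; ++i)
        for (int s = 0; s < S; ++s)
            for (int g = 0; g < G; ++g) {
                double f = phi(i, s) * (g * gridStep);
                if (f >= 1.0) f = 1.0 - 1e-9;
                if (f <= 0.0) f = 1e-12;
                logL[i][s * G + g] = (n(i, s) > 0)
                    ? R::dbinom(X(i, s), n(i, s), f, 1) : 0.0;
            }

    // State: cluster grid indices (per sample), member counts, assignment.
    std::vector< std::vector<int> > cl_g;   // cluster -> S grid indices
    std::vector<int> cl_n;                  // cluster -> size
    std::vector<int> z(N, 0);

    // Initialise: one cluster at the per-sample grand-mean implied CCF.
    {
        std::vector<int> g0(S, G - 1);
        for (int s = 0; s < S; ++s) {
            double num = 0, den = 0;
            for (int i = 0; i < N; ++i) {
                if (n(i, s) > 0 && phi(i, s) > 0) {
                    num += (double)X(i, s) / n(i, s) / phi(i, s);
                    den += 1.0;
                }
            }
            double p = den > 0 ? num / den : 0.5;
            if (p < 0) p = 0;
            if (p > pmax) p = pmax;
            g0[s] = (int)std::floor(p / gridStep + 0.5);
        }
        cl_g.push_back(g0);
        cl_n.push_back(N);
    }
    double alpha = 1.0;

    auto loglik_at = [&](int i, const std::vector<int> &gidx) {
        double ll = 0.0;
        for (int s = 0; s < S; ++s) ll += logL[i][s * G + gidx[s]];
        return ll;
    };

    // Resample one cluster's grid CCFs from the exact discrete posterior.
    auto update_params = [&](int k) {
        for (int s = 0; s < S; ++s) {
            std::vector<double> lp(G, 0.0);
            for (int i = 0; i < N; ++i)
                if (z[i] == k)
                    for (int g = 0; g < G; ++g) lp[g] += logL[i][s * G + g];
            cl_g[k][s] = sample_log_weights(lp);
        }
    };

    const int kept = iterations - burnin;
    IntegerMatrix draws(kept, N);
    NumericVector alphaTrace(iterations), kTrace(iterations);

    for (int it = 0; it < iterations; ++it) {
        // --- CRP scan ---
        for (int i = 0; i < N; ++i) {
            int k0 = z[i];
            cl_n[k0]--;
            std::vector< std::vector<int> > aux(naux, std::vector<int>(S));
            if (cl_n[k0] == 0) {
                // keep the emptied cluster's parameters as the first
                // auxiliary component (Neal alg. 8)
                aux[0] = cl_g[k0];
                cl_g.erase(cl_g.begin() + k0);
                cl_n.erase(cl_n.begin() + k0);
                for (int j = 0; j < N; ++j) if (z[j] > k0) z[j]--;
                for (int a = 1; a < naux; ++a)
                    for (int s = 0; s < S; ++s)
                        aux[a][s] = (int)std::floor(R::runif(0.0, G - 1e-9));
            } else {
                for (int a = 0; a < naux; ++a)
                    for (int s = 0; s < S; ++s)
                        aux[a][s] = (int)std::floor(R::runif(0.0, G - 1e-9));
            }
            const int K = (int)cl_g.size();
            std::vector<double> logw(K + naux);
            for (int k = 0; k < K; ++k)
                logw[k] = std::log((double)cl_n[k]) + loglik_at(i, cl_g[k]);
            for (int a = 0; a < naux; ++a)
                logw[K + a] = std::log(alpha / naux) + loglik_at(i, aux[a]);
            int pick = sample_log_weights(logw);
            if (pick < K) {
                z[i] = pick;
                cl_n[pick]++;
            } else {
                cl_g.push_back(aux[pick - K]);
                cl_n.push_back(1);
                z[i] = K;
            }
        }
        // --- cluster parameter updates ---
        for (int k = 0; k < (int)cl_g.size(); ++k) update_params(k);
        // --- concentration parameter (Escobar & West 1995), Gamma(1,1) ---
        {
            int K = (int)cl_g.size();
            double eta = R::rbeta(alpha + 1.0, (double)N);
            double a = 1.0, b = 1.0;
            double odds = (a + K - 1.0) / (N * (b - std::log(eta)));
            double pi_eta = odds / (1.0 + odds);
            if (R::runif(0.0, 1.0) < pi_eta)
                alpha = R::rgamma(a + K, 1.0 / (b - std::log(eta)));
            else
                alpha = R::rgamma(a + K - 1.0, 1.0 / (b - std::log(eta)));
        }
        alphaTrace[it] = alpha;
        kTrace[it] = (double)cl_g.size();
        if (it >= burnin)
            for (int i = 0; i < N; ++i) draws(it - burnin, i) = z[i];
    }

    // --- summarise: posterior similarity matrix, then the sampled
    // partition maximising the posterior expected adjusted Rand index
    // (Fritsch & Ickstadt 2009) ---
    NumericMatrix psm(N, N);
    for (int d = 0; d < kept; ++d)
        for (int i = 0; i < N; ++i)
            for (int j = i + 1; j < N; ++j)
                if (draws(d, i) == draws(d, j)) psm(i, j) += 1.0;
    double sumPsm = 0.0;
    for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
            psm(i, j) /= kept;
            psm(j, i) = psm(i, j);
            sumPsm += psm(i, j);
        }
    const double nPairs = N * (N - 1.0) / 2.0;
    int best = 0; double bestScore = R_NegInf;
    for (int d = 0; d < kept; ++d) {
        double sumI = 0.0, cross = 0.0;
        for (int i = 0; i < N; ++i)
            for (int j = i + 1; j < N; ++j)
                if (draws(d, i) == draws(d, j)) { sumI += 1.0; cross += psm(i, j); }
        double expv = sumI * sumPsm / nPairs;
        double denom = 0.5 * (sumI + sumPsm) - expv;
        double score = (denom > 1e-12) ? (cross - expv) / denom
                                       : -std::abs(sumI - sumPsm);
        if (score > bestScore) { bestScore = score; best = d; }
    }
    IntegerVector partition(N);
    for (int i = 0; i < N; ++i) partition[i] = draws(best, i) + 1;

    return List::create(_["partition"] = partition,
                        _["psm"] = psm,
                        _["alphaTrace"] = alphaTrace,
                        _["kTrace"] = kTrace,
                        _["pear"] = bestScore);
}

// Exact discrete posterior of one cluster's CCF per sample given member
// rows: returns G x S matrix of probabilities (uniform grid prior).
// [[Rcpp::export(name = ".ccf_grid_posterior")]]
NumericMatrix ccf_grid_posterior(IntegerMatrix X, IntegerMatrix n,
                                 NumericMatrix phi, IntegerVector members,
                                 double pmax, double gridStep) {
    const int S = X.ncol();
    const int G = (int)std::floor(pmax / gridStep + 1e-9) + 1;
    NumericMatrix out(G, S);
    for (int s = 0; s < S; ++s) {
        std::vector<double> lp(G, 0.0);
        for (int mi = 0; mi < members.size(); ++mi) {
            int i = members[mi] - 1;
            for (int g = 0; g < G; ++g) {
                double f = phi(i, s) * (g * gridStep);
                if (f >= 1.0) f = 1.0 - 1e-9;
                if (f <= 0.0) f = 1e-12;
                if (n(i, s) > 0) lp[g] += R::dbinom(X(i, s), n(i, s), f, 1);
            }
        }
        double m = lp[0];
        for (int g = 1; g < G; ++g) if (lp[g] > m) m = lp[g];
        double tot = 0.0;
        for (int g = 0; g < G; ++g) { out(g, s) = std::exp(lp[g] - m); tot += out(g, s); }
        for (int g = 0; g < G; ++g) out(g, s) /= tot;
    }
    return out;
}
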