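// Exhaustive signature-subset search with non-negative least squares.
//
// For a 96-channel spectrum y and catalogue A (96 x K, columns sum to 1),
// every subset of up to maxSize signatures is fitted by NNLS
// (Lawson-Hanson on the normal equations) and scored by the Pearson
// correlation between y and the reconstruction. Because Pearson r only
// needs y'A, A'A and column sums, the inner loop never touches the
// 96-dimensional space, which keeps the full 1,285,623-subset search for a
// 27-signature catalogue in the seconds range.
//
// Admissibility (the 2%-and-50-mutation rule with exempt signatures) is
// evaluated per subset; the best admissible solution of every size is
// returned together with discard tallies.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct BestBySize {
    std::vector<double> r;
    std::vector< std::vector<int> > subset;
    std::vector< std::vector<double> > expo;
};

// Lawson-Hanson NNLS on the normal equations restricted to a subset.
// Gsub = A_P' A_P (k x k), bsub = A_P' y (k). Returns solution x >= 0.
void nnls_subset(const std::vector<double> &Gsub,
                 const std::vector<double> &bsub, int k,
                 std::vector<double> &x) {
    std::vector<bool> passive(k, false);
    std::vector<double> w(k), zsol(k);
    x.assign(k, 0.0);
    for (int outer = 0; outer < 30 * k; ++outer) {
        // gradient w = b - G x
        double wmax = -1.0; int t = -1;
        for (int i = 0; i < k; ++i) {
            if (passive[i]) continue;
            double wi = bsub[i];
            for (int j = 0; j < k; ++j) wi -= Gsub[i * k + j] * x[j];
            w[i] = wi;
            if (wi > wmax) { wmax = wi; t = i; }
        }
        if (t < 0 || wmax <= 1e-10) break;
        passive[t] = true;
        for (int inner = 0; inner < 30 * k; ++inner) {
            // solve G_PP z = b_P by Cholesky (k <= 7)
            std::vector<int> P;
            for (int i = 0; i < k; ++i) if (passive[i]) P.push_back(i);
            int m = (int)P.size();
            std::vector<double> L(m * m, 0.0), yv(m), zz(m);
            bool ok = true;
            for (int i = 0; i < m && ok; ++i) {
                for (int j = 0; j <= i; ++j) {
                    double sum = Gsub[P[i] * k + P[j]];
                    for (int q = 0; q < j; ++q) sum -= L[i * m + q] * L[j * m + q];
                    if (i == j) {
                        if (sum <= 1e-12) { ok = false; break; }
                        L[i * m + i] = std::sqrt(sum);
                    } else L[i * m + j] = sum / L[j * m + j];
                }
            }
            if (!ok) { passive[t] = false; break; }
            for (int i = 0; i < m; ++i) {
                double sum = bsub[P[i]];
                for (int q = 0; q < i; ++q) sum -= L[i * m + q] * yv[q];
                yv[i] = sum / L[i * m + i];
            }
            for (int i = m - 1; i >= 0; --i) {
                double sum = yv[i];
                for (int q = i + 1; q < m; ++q) sum -= L[q * m + i] * zz[q];
                zz[i] = sum / L[i * m + i];
            }
            std::fill(zsol.begin(), zsol.end(), 0.0);
            for (int i = 0; i < m; ++i) zsol[P[i]] = zz[i];
            bool feasible = true;
            for (int i = 0; i < m; ++i) if (zz[i] <= 0) { feasible = false; break; }
            if (feasible) { x = zsol; break; }
            // step toward z, dropping the first variable hitting zero
            double amin = 1.0; int drop = -1;
            for (int i = 0; i < m; ++i) {
                if (zz[i] <= 0) {
                    double a = x[P[i]] / (x[P[i]] - zz[i]);
                    if (a < amin) { amin = a; drop = P[i]; }
                }
            }
            for (int i = 0; i < k; ++i)
                if (passive[i]) x[i] += amin * (zsol[i] - x[i]);
            if (drop >= 0) { passive[drop] = false; x[drop] = 0.0; }
            for (int i = 0; i < k; ++i)
                if (passive[i] && x[i] < 1e-12) { x[i] = 0.0; }
        }
    }
}

} // namespace

// [[Rcpp::export(name = ".sig_search")]]
List sig_search(NumericMatrix G, NumericVector b, double sy, double syy,
                double total, int nChannels, int maxSize,
                LogicalVector exempt, double minShare, double minCount) {
    const int K = G.nrow();
    BestBySize best;
    best.r.assign(maxSize + 1, R_NegInf);
    best.subset.assign(maxSize + 1, std::vector<int>());
    best.expo.assign(maxSize + 1, std::vector<double>());
    // best single-signature fit regardless of admissibility (fallback)
    double fbR = R_NegInf; int fbSig = -1; std::vector<double> fbExpo(1, 0.0);
    long long nEval = 0, nInadmissible = 0;

    const double ybar = sy / nChannels;
    const double yvar = syy - nChannels * ybar * ybar;

    std::vector<int> idx(maxSize, 0);
    std::vector<double> Gsub(maxSize * maxSize), bsub(maxSize), x;

    // iterate over all subsets of each size via lexicographic combinations
    for (int k = 1; k <= maxSize; ++k) {
        for (int i = 0; i < k; ++i) idx[i] = i;
        while (true) {
            // fit this subset
            for (int i = 0; i < k; ++i) {
                bsub[i] = b[idx[i]];
                for (int j = 0; j < k; ++j)
                    Gsub[i * k + j] = G(idx[i], idx[j]);
            }
            nnls_subset(Gsub, bsub, k, x);
            ++nEval;
            // Pearson r from sufficient statistics:
            // recon = A_P x; sum(recon) = sum(x) (columns sum to 1),
            // y'recon = b_P'x, recon'recon = x'G_PP x.
            double sx = 0.0, yr = 0.0, rr = 0.0;
            for (int i = 0; i < k; ++i) {
                sx += x[i];
                yr += bsub[i] * x[i];
                for (int j = 0; j < k; ++j)
                    rr += x[i] * Gsub[i * k + j] * x[j];
            }
            double rvar = rr - sx * sx / nChannels;
            double cov = yr - sx * ybar;
            double r = (rvar > 1e-14 && yvar > 1e-14)
                ? cov / std::sqrt(rvar * yvar) : 0.0;
            if (k == 1 && r > fbR) { fbR = r; fbSig = idx[0]; fbExpo[0] = x[0]; }
            bool admissible = true;
            for (int i = 0; i < k; ++i) {
                if (exempt[idx[i]]) continue;
                if (x[i] < minShare * total || x[i] < minCount) {
                    admissible = false; break;
                }
            }
            if (!admissible) ++nInadmissible;
            else if (r > best.r[k]) {
                best.r[k] = r;
                best.subset[k].assign(idx.begin(), idx.begin() + k);
                best.expo[k].assign(x.begin(), x.begin() + k);
            }
            // next combination
            int pos = k - 1;
            while (pos >= 0 && idx[pos] == K - k + pos) --pos;
            if (pos < 0) break;
            ++idx[pos];
            for (int i = pos + 1; i < k; ++i) idx[i] = idx[i - 1] + 1;
        }
    }

    List perSize(maxSize);
    for (int k = 1; k <= maxSize; ++k) {
        if (best.subset[k].empty()) { perSize[k - 1] = R_NilValue; continue; }
        IntegerVector s(best.subset[k].begin(), best.subset[k].end());
        NumericVector e(best.expo[k].begin(), best.expo[k].end());
        perSize[k - 1] = List::create(_["r"] = best.r[k],
                                      _["subset"] = s + 1,
                                      _["exposures"] = e);
    }
    return List::create(
        _["perSize"] = perSize,
        _["nEvaluated"] = (double)nEval,
        _["nInadmissible"] = (double)nInadmissible,
        _["fallback"] = List::create(_["r"] = fbR, _["signature"] = fbSig + 1,
                                     _["exposure"] = fbExpo[0]));
}

// Plain NNLS exposure fit for one explicit subset (used by fitExposures).
// [[Rcpp::export(name = ".nnls_fit")]]
NumericVector nnls_fit(NumericMatrix A, NumericVector y) {
    const int k = A.ncol(), nr = A.nrow();
    std::vector<double> G(k * k), b(k), x;
    for (int i = 0; i < k; ++i) {
        double bi = 0.0;
        for (int r = 0; r < nr; ++r) bi += A(r, i) * y[r];
        b[i] = bi;
        for (int j = 0; j < k; ++j) {
            double g = 0.0;
            for (int r = 0; r < nr; ++r) g += A(r, i) * A(r, j);
            G[i * k + j] = g;
        }
    }
    nnls_subset(G, b, k, x);
    return NumericVector(x.begin(), x.end());
}
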