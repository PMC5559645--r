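#' @include ccf.R
NULL

## Expected VAFs of the mixture states on tetraploid segments:
## early-clonal (pre-WGD): m = 2, p = 1; late-clonal: m = 1, p = 1;
## subclonal_k: m = 1, p = p_k from the cluster solution.
wgdStates <- function(rho, subclonalCCF = numeric(0), c = 4) {
    p <- c(1, 1, subclonalCCF)
    m <- c(2, 1, rep(1, length(subclonalCCF)))
    f <- expectedVAF(rho, c, m, pmin(p, 1))
    names(f) <- c("early", "late",
                  if (length(subclonalCCF))
                      paste0("subclonal", seq_along(subclonalCCF)))
    f
}

#' EM fit of the WGD binomial mixture
#'
#' Models variant reads of clonal trunk mutations on tetraploid segments as
#' a mixture of binomials, one component per timing state: early-clonal
#' mutations (acquired before duplication, so on 2 copies), late-clonal
#' (1 copy), and optionally subclonal states at CCFs taken from the cluster
#' solution. X|state ~ Binomial(n, f_state); the E-step computes
#' P(state|X) by Bayes' formula and the M-step sets each mixture proportion
#' to the mean posterior. Convergence when max |delta pi| < 1e-8 (at most
#' 1000 iterations); the log-likelihood is checked to be non-decreasing.
#'
#' @param X,n Variant reads and depth of the trunk mutations (one sample).
#' @param rho Sample purity.
#' @param subclonalCCF CCFs of subclonal states to include (often none when
#'   restricted to trunk mutations).
#' @param c Total copy number; the timing model assumes tetraploid segments
#'   (c = 4) and rejects others.
#' @param restarts Random restarts; the best log-likelihood is kept. The
#'   first start is uniform.
#' @param tol,maxIter Convergence controls.
#' @return A list: `pi` (named mixture proportions), `posterior` (mutations
#'   x states), `logLik`, `logLikTrace`, `f` (state VAFs), `converged`.
#' @export
wgdEM <- function(X, n, rho, subclonalCCF = numeric(0), c = 4,
                  restarts = 10, tol = 1e-8, maxIter = 1000) {
    if (c != 4)
        stopf("WGD timing is defined on tetraploid segments (c = 4), got c = %d", c)
    if (length(X) < 1L || all(X == 0)) stopf("no variant reads to time")
    f <- wgdStates(rho, subclonalCCF, c)
    ## states with (numerically) identical expected VAF are not separable
    dup <- duplicated(round(f, 10))
    if (any(dup)) {
        warnf("states with identical expected VAF collapsed: %s",
              paste(names(f)[dup], collapse = ", "))
        f <- f[!dup]
    }
    nStates <- length(f)
    ll <- vapply(seq_len(nStates), function(s)
        stats::dbinom(X, n, f[s], log = TRUE), numeric(length(X)))
    ll <- matrix(ll, ncol = nStates)

    runOne <- function(pi0) {
        pi <- pi0
        trace <- numeric(0)
        for (it in seq_len(maxIter)) {
            lw <- sweep(ll, 2, log(pi), "+")
            mx <- apply(lw, 1, max)
            w <- exp(lw - mx)
            tot <- rowSums(w)
            post <- w / tot
            loglik <- sum(mx + log(tot))
            trace <- c(trace, loglik)
            piNew <- colMeans(post)
            if (max(abs(piNew - pi)) < tol) {
                pi <- piNew
                return(list(pi = pi, posterior = post, logLik = loglik,
                            logLikTrace = trace, converged = TRUE))
            }
            pi <- piNew
        }
        list(pi = pi, posterior = post, logLik = loglik,
             logLikTrace = trace, converged = FALSE)
    }

    if (nStates == 1L) {
        post <- matrix(1, length(X), 1)
        res <- list(pi = 1, posterior = post,
                    logLik = sum(ll), logLikTrace = sum(ll),
                    converged = TRUE)
    } else {
        best <- NULL
        for (r in seq_len(restarts)) {
            pi0 <- if (r == 1L) rep(1 / nStates, nStates)
                   else { d <- stats::rgamma(nStates, 1); d / sum(d) }
            cand <- runOne(pi0)
            if (is.null(best) || cand$logLik > best$logLik) best <- cand
        }
        res <- best
    }
    names(res$pi) <- names(f)
    colnames(res$posterior) <- names(f)
    if (any(diff(res$logLikTrace) < -1e-6))
        stopf("EM log-likelihood decreased; numerical failure")
    res$f <- f
    res
}

#' Relative time of whole-genome duplication
#'
#' Converts the early-clonal and late-clonal mixture proportions to a
#' relative molecular time, t = 2 pi_e / (2 pi_e + pi_l): before the
#' duplication each mutation is observable on two copies, so the early
#' proportion is halved on the pre-WGD time axis.
#'
#' @param piEarly,piLate Non-negative mixture proportions (not both 0).
#' @return t in [0, 1].
#' @export
#' @examples
#' wgdTime(0.25, 0.25)  # 2/3
#' wgdTime(0.4, 0)      # 1
wgdTime <- function(piEarly, piLate) {
    if (piEarly < 0 || piLate < 0)
        stopf("mixture proportions must be non-negative")
    if (piEarly + piLate == 0)
        stopf("timing undefined: no clonal mutations in either state")
    2 * piEarly / (2 * piEarly + piLate)
}

#' Bootstrap confidence interval for the WGD time
#'
#' Resamples the mutations with replacement `B` times, refits the mixture
#' (initialised at the full-data estimate) and takes the percentile 95\%
#' interval of the resampled times.
#'
#' @inheritParams wgdEM
#' @param B Bootstrap replicates, default 100.
#' @param seed Integer seed.
#' @param level Interval coverage, default 0.95.
#' @return A list: `ci` (lower, upper), `t` (bootstrap draws).
#' @export
wgdBootstrap <- function(X, n, rho, subclonalCCF = numeric(0), B = 100,
                         seed = 1, level = 0.95) {
    if (B < 2) stopf("at least 2 bootstrap replicates required")
    set.seed(seed)
    k <- length(X)
    ts <- vapply(seq_len(B), function(b) {
        idx <- sample.int(k, k, replace = TRUE)
        fit <- wgdEM(X[idx], n[idx], rho, subclonalCCF, restarts = 1)
        wgdTime(fit$pi["early"], fit$pi["late"])
    }, numeric(1))
    a <- (1 - level) / 2
    list(ci = stats::quantile(ts, c(a, 1 - a), names = FALSE), t = ts)
}

#' Time whole-genome duplication from trunk mutations
#'
#' End-to-end wrapper: fits the binomial mixture by EM on clonal trunk
#' mutations from tetraploid, copy-number-constant segments, derives
#' t = 2 pi_e / (2 pi_e + pi_l), and attaches a percentile bootstrap 95\%
#' confidence interval.
#'
#' @inheritParams wgdEM
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @param minMutations Minimum mutations required (default 20).
#' @return A [WGDTiming-class].
#' @export
timeWGD <- function(X, n, rho, subclonalCCF = numeric(0), B = 100,
                    seed = 1, minMutations = 20) {
    if (length(X) < minMutations)
        stopf("need at least %d tetraploid trunk mutations, got %d",
              minMutations, length(X))
    fit <- wgdEM(X, n, rho, subclonalCCF)
    t <- wgdTime(fit$pi["early"], fit$pi["late"])
    bs <- wgdBootstrap(X, n, rho, subclonalCCF, B = B, seed = seed)
    methods::new("WGDTiming", t = unname(t),
                 ciLow = min(bs$ci[1], t), ciHigh = max(bs$ci[2], t),
                 pi = fit$pi, logLik = fit$logLik,
                 nMutations = length(X), bootstrapT = bs$t)
}
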