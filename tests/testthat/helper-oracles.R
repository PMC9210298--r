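# Independent brute-force oracles used across the suite.

# exact HMM posteriors by enumeration over all S^M paths
enumPosterior <- function(init, transitions, emissions) {
    M <- nrow(emissions); S <- ncol(emissions)
    paths <- as.matrix(expand.grid(rep(list(seq_len(S)), M)))
    pr <- apply(paths, 1L, function(p) {
        v <- init[p[1L]] * emissions[1L, p[1L]]
        if (M > 1L) for (m in 2:M)
            v <- v * transitions[[m - 1L]][p[m - 1L], p[m]] * emissions[m, p[m]]
        v
    })
    post <- vapply(seq_len(S), function(s)
        vapply(seq_len(M), function(m) sum(pr[paths[, m] == s]), numeric(1)),
        numeric(M))
    post <- matrix(post, nrow = M)
    list(posterior = post / sum(pr), loglik = log(sum(pr)),
         best = paths[which.max(pr), ])
}

randomStochastic <- function(S) {
    m <- matrix(stats::runif(S * S, 0.05, 1), S, S)
    m / rowSums(m)
}

randomAlpha <- function(k) {
    a <- stats::rgamma(k, 2)
    a / sum(a)
}

# direct unordered heterozygous transition (the formula route, used as the
# oracle for the ordered-product-then-collapse implementation)
directUnorderedTransition <- function(alpha, r, n) {
    th <- haplotypeTransition(alpha, r, n)
    k <- length(alpha)
    pairs <- rbind(cbind(seq_len(k), seq_len(k)), t(utils::combn(k, 2)))
    S <- nrow(pairs)
    out <- matrix(0, S, S)
    for (u in seq_len(S)) for (v in seq_len(S)) {
        a <- pairs[u, 1]; b <- pairs[u, 2]
        c <- pairs[v, 1]; d <- pairs[v, 2]
        out[u, v] <- th[a, c] * th[b, d] + if (c != d) th[a, d] * th[b, c] else 0
    }
    out
}
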