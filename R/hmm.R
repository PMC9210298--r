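#' Emission probabilities with genotyping-error tolerance
#'
#' For each position m and hidden state (i, j), the predicted SNP dosage is
#' `f_mi + f_mj`, where f is the founder allele matrix (0/1; founders are
#' inbred). The emission probability is `1 - epsilon` when the observed
#' dosage matches the prediction and `epsilon / 2` otherwise, splitting the
#' error mass over the two wrong dosage categories. A missing observation,
#' or a missing founder allele for either founder of the state, gives an
#' uninformative emission of 1. Markers at which all founders carry the
#' same allele are thereby uninformative for distinguishing states but are
#' kept, preserving position indexing.
#'
#' @param founderAlleles M x k matrix with entries 0, 1 or `NA`
#' @param obs length-M vector of observed dosages in \{0, 1, 2, `NA`\};
#'   haploid and male-X chains expect \{0, 2, `NA`\}
#' @param cross a [CrossModel-class] (defines the state space)
#' @param errorRate genotyping error rate epsilon in [0, 0.5)
#' @return M x S matrix of emission probabilities (never an all-zero value
#'   by construction when `errorRate > 0`)
#' @export
emissionMatrix <- function(founderAlleles, obs, cross, errorRate = 0.002) {
    if (errorRate < 0 || errorRate >= 0.5)
        stop("errorRate must be in [0, 0.5)")
    founderAlleles <- as.matrix(founderAlleles)
    if (ncol(founderAlleles) != length(cross@alpha))
        stop("founder allele matrix must have one column per founder")
    M <- nrow(founderAlleles)
    if (length(obs) != M)
        stop("observed genotypes must match the number of markers")
    bad <- !is.na(obs) & !obs %in% c(0, 1, 2)
    if (any(bad))
        stop("invalid genotype call(s) at marker position(s) ",
             paste(which(bad), collapse = ", "),
             " (expected 0, 1, 2 or missing)")
    states <- stateSpace(cross)
    pairs <- attr(states, "pairs")
    pred <- founderAlleles[, pairs[, 1], drop = FALSE] +
        founderAlleles[, pairs[, 2], drop = FALSE]  # M x S, NA where founder missing
    em <- matrix(1, M, nrow(pairs), dimnames = list(rownames(founderAlleles), states))
    known <- !is.na(obs)
    hit <- pred[known, , drop = FALSE] == obs[known]
    emk <- ifelse(is.na(hit), 1, ifelse(hit, 1 - errorRate, errorRate / 2))
    em[known, ] <- emk
    em
}

#' Forward-backward posterior state probabilities
#'
#' Computes the exact marginal posteriors Pr(G_m = g | O) of the hidden
#' founder-genotype chain given all observations, by the scaled
#' forward-backward algorithm. Per-position scaling constants are retained
#' and their log-sum is returned as the log-likelihood; scaling (rather
#' than log-space arithmetic) keeps the inner loops to matrix products on
#' these small state spaces.
#'
#' @param init length-S initial distribution
#' @param transitions list of M-1 S x S transition matrices (possibly of
#'   length 0 when M = 1)
#' @param emissions M x S emission probability matrix
#' @return list with `posterior` (M x S, rows summing to 1) and `loglik`
#' @export
forwardBackward <- function(init, transitions, emissions) {
    emissions <- as.matrix(emissions)
    M <- nrow(emissions); S <- ncol(emissions)
    if (length(init) != S) stop("init length must match number of states")
    if (length(transitions) != M - 1L)
        stop("need exactly M - 1 transition matrices")
    fwd <- matrix(0, M, S)
    scl <- numeric(M)
    f <- init * emissions[1L, ]
    scl[1L] <- sum(f)
    if (scl[1L] <= 0)
        stop("zero likelihood at position 1: no state is compatible ",
             "with the observed genotype (is the error rate 0?)")
    fwd[1L, ] <- f / scl[1L]
    if (M > 1L) for (m in 2:M) {
        f <- (fwd[m - 1L, ] %*% transitions[[m - 1L]]) * emissions[m, ]
        scl[m] <- sum(f)
        if (scl[m] <= 0)
            stop("zero likelihood at position ", m, ": no state is compatible ",
                 "with the observed genotype (is the error rate 0?)")
        fwd[m, ] <- f / scl[m]
    }
    bwd <- matrix(0, M, S)
    bwd[M, ] <- 1
    if (M > 1L) for (m in (M - 1L):1L) {
        b <- transitions[[m]] %*% (bwd[m + 1L, ] * emissions[m + 1L, ])
        bwd[m, ] <- b / scl[m + 1L]
    }
    post <- fwd * bwd
    post <- post / rowSums(post)  # renormalize to control drift
    colnames(post) <- colnames(emissions)
    list(posterior = post, loglik = sum(log(scl)))
}

#' Viterbi decoding of the founder-genotype chain
#'
#' Returns a maximum-probability joint state path. Ties are broken
#' deterministically toward the lowest state index.
#'
#' @inheritParams forwardBackward
#' @return integer vector of length M of state indices, with state labels
#'   as names when the emissions carry colnames
#' @export
viterbiPath <- function(init, transitions, emissions) {
    emissions <- as.matrix(emissions)
    M <- nrow(emissions); S <- ncol(emissions)
    if (length(init) != S) stop("init length must match number of states")
    if (length(transitions) != M - 1L)
        stop("need exactly M - 1 transition matrices")
    logem <- log(emissions)
    delta <- log(unname(init)) + logem[1L, ]
    back <- matrix(0L, M, S)
    if (M > 1L) for (m in 2:M) {
        cand <- delta + log(transitions[[m - 1L]])  # S x S: row = from
        best <- apply(cand, 2L, which.max)          # ties -> lowest index
        back[m, ] <- best
        delta <- cand[cbind(best, seq_len(S))] + logem[m, ]
    }
    if (all(!is.finite(delta)))
        stop("zero likelihood: no path is compatible with the observations")
    path <- integer(M)
    path[M] <- which.max(delta)
    if (M > 1L) for (m in (M - 1L):1L) path[m] <- back[m + 1L, path[m + 1L]]
    if (!is.null(colnames(emissions))) names(path) <- colnames(emissions)[path]
    path
}

#' Infer haplotype segments and count breakpoints
#'
#' Thresholds the posterior: positions whose maximum posterior probability
#' reaches `threshold` are assigned that state; maximal runs of the same
#' assigned state become segments; positions below threshold are left
#' unassigned and carry no state. Breakpoints are counted as the number of
#' state changes between consecutive assigned segments.
#'
#' @param posterior M x S posterior matrix with state labels as colnames
#' @param map a [GeneticMap-class] for the same M positions (single
#'   chromosome)
#' @param threshold assignment threshold in (0.5, 1]; values at or below
#'   0.5 would be ambiguous and are rejected
#' @return list with `segments` (data.frame `start_cM`, `end_cM`, `state`),
#'   `nBreakpoints` and `threshold`
#' @export
inferSegments <- function(posterior, map, threshold = 0.95) {
    if (threshold <= 0.5 || threshold > 1)
        stop("threshold must be in (0.5, 1]")
    posterior <- as.matrix(posterior)
    pos <- positions(map)
    if (nrow(posterior) != length(pos))
        stop("posterior and map sizes differ")
    mx <- apply(posterior, 1L, max)
    st <- colnames(posterior)[apply(posterior, 1L, which.max)]
    st[mx < threshold] <- NA
    assigned <- which(!is.na(st))
    segs <- data.frame(start_cM = numeric(0), end_cM = numeric(0),
                       state = character(0), stringsAsFactors = FALSE)
    nbp <- 0L
    if (length(assigned)) {
        runStart <- assigned[1L]
        prev <- assigned[1L]
        for (i in assigned[-1L]) {
            # an unassigned gap does not split a run of the same state
            if (st[i] != st[prev]) {
                segs <- rbind(segs, data.frame(start_cM = pos[runStart],
                                               end_cM = pos[prev],
                                               state = st[prev]))
                nbp <- nbp + 1L
                runStart <- i
            }
            prev <- i
        }
        segs <- rbind(segs, data.frame(start_cM = pos[runStart],
                                       end_cM = pos[prev], state = st[prev]))
    }
    list(segments = segs, nBreakpoints = nbp, threshold = threshold)
}
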