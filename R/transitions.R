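#' Two-point haplotype probabilities by generation recursion
#'
#' Iterates the one-generation recursion
#' p_ij(n) = (1 - r) p_ij(n-1) + r alpha_i alpha_j
#' from the founder generation p_ij(0) = alpha_i [i = j], where p_ij(n) is
#' the probability that a random haplotype at generation n carries founder
#' alleles i and j at two loci separated by recombination fraction r. Only
#' defined for integer n; it exists chiefly as the brute-force check of the
#' closed form in [twoPointProbs()].
#'
#' @param alpha founder proportions (non-negative, summing to 1)
#' @param r recombination fraction in [0, 0.5]
#' @param n integer number of generations >= 0
#' @return k x k matrix of two-point probabilities; attributes `"rec_frac"`
#'   and `"n_used"`
#' @export
twoPointRecursion <- function(alpha, r, n) {
    .check_alpha(alpha); .check_r(r)
    if (length(n) != 1L || n < 0 || n != round(n))
        stop("the recursion is defined only for non-negative integer n")
    a <- unname(alpha)
    p <- diag(a, nrow = length(a))
    aa <- outer(a, a)
    for (i in seq_len(n)) p <- (1 - r) * p + r * aa
    dimnames(p) <- list(names(alpha), names(alpha))
    structure(p, rec_frac = r, n_used = n)
}

#' Two-point haplotype probabilities, closed form
#'
#' The closed-form solution of the two-point recursion:
#' \deqn{p_{ii}(n) = \alpha_i^2 + (1-r)^n \alpha_i (1-\alpha_i), \qquad
#'       p_{ij}(n) = \alpha_i \alpha_j [1 - (1-r)^n], \; i \ne j.}
#' Accepts non-integer n, which the X-chromosome adjustment (2/3)n
#' requires. The matrix sums to 1, is symmetric, and both marginals equal
#' `alpha`.
#'
#' @inheritParams twoPointRecursion
#' @param n number of generations >= 0 (real)
#' @return k x k matrix; attributes `"rec_frac"` and `"n_used"`
#' @examples
#' twoPointProbs(c(0.5, 0.5), r = 0.25, n = 1)  # diagonal 0.25 + 0.75*0.25 = 0.4375
#' @export
twoPointProbs <- function(alpha, r, n) {
    .check_alpha(alpha); .check_r(r)
    if (length(n) != 1L || n < 0) stop("n must be a single non-negative number")
    a <- unname(alpha)
    w <- (1 - r)^n
    p <- outer(a, a) * (1 - w)
    diag(p) <- a^2 + w * a * (1 - a)
    dimnames(p) <- list(names(alpha), names(alpha))
    structure(p, rec_frac = r, n_used = n)
}

#' Haplotype transition probabilities
#'
#' Conditional probabilities along a single haplotype, obtained by dividing
#' the two-point probabilities by the marginal alpha_i:
#' \deqn{t(i \to i) = \alpha_i + (1-r)^n (1-\alpha_i), \qquad
#'       t(i \to j) = \alpha_j [1 - (1-r)^n].}
#' Rows for founders with alpha_i = 0 are still defined by the formula
#' (no division is performed); such states are flagged unreachable.
#'
#' @inheritParams twoPointProbs
#' @return k x k stochastic matrix (rows sum to 1); attribute
#'   `"unreachable"` flags rows with alpha_i = 0
#' @export
haplotypeTransition <- function(alpha, r, n) {
    .check_alpha(alpha); .check_r(r)
    if (length(n) != 1L || n < 0) stop("n must be a single non-negative number")
    a <- unname(alpha)
    w <- (1 - r)^n
    tm <- matrix(rep(a * (1 - w), each = length(a)), nrow = length(a))
    diag(tm) <- a + w * (1 - a)
    dimnames(tm) <- list(names(alpha), names(alpha))
    structure(tm, unreachable = a == 0)
}

#' Genotype transition matrix over the HMM state space
#'
#' Transition probabilities between founder-genotype states across an
#' interval with recombination fraction `r`, at the effective number of
#' generations of the cross ((2/3)n on the X). Haploid, homozygous
#' (doubled-haploid) and male-X chains use [haplotypeTransition()]
#' directly. A heterozygous individual carries two independent random
#' haplotypes, so the transition is the product chain over ordered founder
#' pairs, collapsed to the k(k+1)/2 unordered states by summation (SNP data
#' cannot distinguish phase); `ordered = TRUE` returns the uncollapsed
#' k^2 x k^2 chain for debugging.
#'
#' @param cross a [CrossModel-class]
#' @param r recombination fraction in [0, 0.5]
#' @param ordered return the ordered-pair chain instead of collapsing
#' @return S x S stochastic matrix over [stateSpace()] labels
#' @export
genotypeTransition <- function(cross, r, ordered = FALSE) {
    .check_r(r)
    n <- effectiveGenerations(cross)
    th <- haplotypeTransition(cross@alpha, r, n)
    haploidLike <- cross@phase %in% c("haploid", "homozygous") ||
        (cross@chromType == "X" && cross@sex == "male")
    if (haploidLike) return(th)
    k <- length(cross@alpha)
    tOrd <- kronecker(th, th)  # ordered pairs (a,b): index (a-1)*k + b
    fn <- names(cross@alpha)
    ord <- expand.grid(b = seq_len(k), a = seq_len(k))[, c("a", "b")]
    dimnames(tOrd) <- rep(list(paste0(fn[ord$a], fn[ord$b])), 2)
    if (ordered) return(tOrd)
    states <- stateSpace(cross)
    pairs <- attr(states, "pairs")
    # membership of each ordered pair in its unordered state
    ordKey <- paste(pmin(ord$a, ord$b), pmax(ord$a, ord$b))
    unordKey <- paste(pairs[, 1], pairs[, 2])
    memb <- outer(ordKey, unordKey, "==") * 1  # k^2 x S
    # collapse columns by summation; rows by picking one ordered representative
    rep_idx <- match(unordKey, ordKey)
    tm <- (tOrd %*% memb)[rep_idx, , drop = FALSE]
    dimnames(tm) <- list(states, states)
    structure(tm, unreachable = attr(states, "unreachable"))
}

#' Map expansion of the random-mating model
#'
#' The factor by which breakpoint density in the population exceeds that of
#' a single meiosis: the derivative at r = 0 of the exchange probability
#' R(r), which under this model equals `n (1 - sum(alpha^2))`, reducing to
#' `n (k-1)/k` for equal proportions.
#'
#' @param alpha founder proportions
#' @param n generations of random mating (real, >= 0)
#' @return map expansion (dimensionless)
#' @examples
#' mapExpansion(rep(1/8, 8), n = 8)  # 7
#' @export
mapExpansion <- function(alpha, n) {
    .check_alpha(alpha)
    if (n < 0) stop("n must be non-negative")
    n * (1 - sum(alpha^2))
}

#' Probability of an allele exchange across an interval
#'
#' R(r) = 1 - sum_i p_ii(n): the chance that a random haplotype carries
#' different founder alleles at the two ends of an interval with
#' recombination fraction r. Equals
#' `(1 - sum(alpha^2)) (1 - (1-r)^n)`; its derivative at r = 0 is the map
#' expansion.
#'
#' @inheritParams mapExpansion
#' @param r recombination fraction in [0, 0.5]
#' @return probability of exchange
#' @export
exchangeProbability <- function(alpha, n, r) {
    .check_alpha(alpha); .check_r(r)
    if (any(n < 0)) stop("n must be non-negative")
    (1 - sum(alpha^2)) * (1 - (1 - r)^n)
}

#' Calibrate the effective generations from a target map expansion
#'
#' Inverts `mapExpansion()`: given a target map expansion E for a design
#' (e.g. 7 for the Collaborative Cross), returns
#' `n = E / (1 - sum(alpha^2))`, the effective number of generations of
#' random mating for the generic model to match the design's breakpoint
#' density.
#'
#' @param targetExpansion target map expansion >= 0
#' @param alpha founder proportions, not concentrated on a single founder
#' @return effective generations n (real)
#' @examples
#' calibrateNClosedForm(7, rep(1/8, 8))  # 8, the CC calibration
#' @export
calibrateNClosedForm <- function(targetExpansion, alpha) {
    .check_alpha(alpha)
    if (targetExpansion < 0) stop("target expansion must be non-negative")
    denom <- 1 - sum(alpha^2)
    if (denom <= 0)
        stop("degenerate founder proportions: a single founder admits no exchanges")
    targetExpansion / denom
}

.check_alpha <- function(alpha) {
    if (length(alpha) < 2L) stop("at least two founders required")
    if (any(alpha < 0)) stop("founder proportions must be non-negative")
    if (abs(sum(alpha) - 1) > 1e-12) stop("founder proportions must sum to 1")
    invisible(TRUE)
}

.check_r <- function(r) {
    if (any(r < 0) || any(r > 0.5))
        stop("recombination fraction must be in [0, 0.5]")
    invisible(TRUE)
}
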