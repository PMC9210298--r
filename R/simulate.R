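#' Simulate one meiosis (no crossover interference)
#'
#' Produces a gamete from a pair of homologous chromosomes represented as
#' founder mosaics. The crossover count on a chromosome of `chromLength`
#' cM is Poisson with mean `chromLength/100` (one crossover per Morgan),
#' crossover positions are uniform, and the gamete alternates between the
#' two homologs starting from a fair-coin choice. Adjacent gamete segments
#' with the same founder are merged, so crossovers between
#' identical-founder homologs are silent.
#'
#' A founder mosaic is a list with `bp` (strictly increasing breakpoint
#' positions in (0, chromLength)) and `f` (founder index per segment,
#' length `length(bp) + 1`).
#'
#' @param hom1,hom2 parental homolog mosaics
#' @param chromLength chromosome length in cM
#' @return a gamete mosaic
#' @export
simulateMeiosis <- function(hom1, hom2, chromLength) {
    ncx <- stats::rpois(1L, chromLength / 100)
    if (ncx == 0L) return(if (stats::runif(1) < 0.5) hom1 else hom2)
    cuts <- sort(stats::runif(ncx, 0, chromLength))
    cur <- if (stats::runif(1) < 0.5) 1L else 2L
    homs <- list(hom1, hom2)
    bounds <- c(0, cuts, chromLength)
    bp <- numeric(0); f <- integer(0)
    for (s in seq_len(length(bounds) - 1L)) {
        piece <- .mosaicSlice(homs[[cur]], bounds[s], bounds[s + 1L])
        bp <- c(bp, piece$bp)
        f <- c(f, piece$f)
        if (s < length(bounds) - 1L) bp <- c(bp, bounds[s + 1L])
        cur <- 3L - cur
    }
    .mosaicSimplify(list(bp = bp, f = f))
}

# founder content of a mosaic over [a, b): breakpoints relative to the mosaic
.mosaicSlice <- function(m, a, b) {
    if (length(m$bp) == 0L) return(list(bp = numeric(0), f = m$f))
    inside <- m$bp > a & m$bp < b
    first <- findInterval(a, m$bp) + 1L
    list(bp = m$bp[inside], f = m$f[first:(first + sum(inside))])
}

# merge adjacent segments with identical founder (silent crossovers vanish)
.mosaicSimplify <- function(m) {
    if (length(m$bp) == 0L) return(m)
    keep <- m$f[-1L] != m$f[-length(m$f)]
    list(bp = m$bp[keep], f = m$f[c(TRUE, keep)])
}

# founder index at positions pos
.mosaicFounder <- function(m, pos) m$f[findInterval(pos, m$bp) + 1L]

#' Simulate a random-mating multiparent population
#'
#' Emulates the breeding abstraction behind the transition model: a founder
#' generation drawn from `k` inbred lines with probabilities `alpha`,
#' followed by `nGenerations` discrete generations of random mating among
#' `popPairs` mating pairs (parents sampled uniformly with replacement,
#' selfing excluded). Individuals are pairs of founder-mosaic chromosomes.
#' With `phase = "homozygous"` each final individual is returned as a
#' single randomly chosen haplotype doubled (the doubled-haploid treatment
#' of fully inbred populations).
#'
#' @param alpha founder proportions
#' @param nGenerations integer generations of random mating >= 0
#' @param popPairs number of mating pairs (population size is 2 * popPairs)
#' @param chromLength chromosome length in cM
#' @param phase `"heterozygous"` or `"homozygous"`
#' @return list of individuals, each a list of two mosaics `h1`, `h2`
#'   (identical under `"homozygous"`)
#' @export
simulatePopulation <- function(alpha, nGenerations, popPairs = 500,
                               chromLength = 100,
                               phase = c("heterozygous", "homozygous")) {
    phase <- match.arg(phase)
    .check_alpha(alpha)
    if (popPairs < 2) stop("at least two mating pairs required")
    if (nGenerations < 0 || nGenerations != round(nGenerations))
        stop("nGenerations must be a non-negative integer")
    N <- 2L * popPairs
    newFounder <- function() {
        i <- sample.int(length(alpha), 1L, prob = alpha)
        list(bp = numeric(0), f = i)
    }
    pop <- replicate(N, list(h1 = newFounder(), h2 = newFounder()),
                     simplify = FALSE)
    for (g in seq_len(nGenerations)) {
        nxt <- vector("list", N)
        for (i in seq_len(N)) {
            par <- sample.int(N, 2L)  # without replacement: no selfing
            nxt[[i]] <- list(
                h1 = simulateMeiosis(pop[[par[1L]]]$h1, pop[[par[1L]]]$h2,
                                     chromLength),
                h2 = simulateMeiosis(pop[[par[2L]]]$h1, pop[[par[2L]]]$h2,
                                     chromLength))
        }
        pop <- nxt
    }
    if (phase == "homozygous")
        pop <- lapply(pop, function(ind) {
            h <- if (stats::runif(1) < 0.5) ind$h1 else ind$h2
            list(h1 = h, h2 = h)
        })
    pop
}

#' Generate a founder SNP allele matrix
#'
#' Draws biallelic founder genotypes with the coded-allele frequency per
#' marker sampled from `Beta(shape, shape)` (default a broad, symmetric
#' profile), redrawing markers at which all founders are identical with
#' probability `1 - monomorphRate` so most markers are informative.
#'
#' @param nMarkers number of markers
#' @param k number of founders
#' @param shape Beta shape parameter for allele frequencies
#' @param monomorphRate fraction of monomorphic markers tolerated
#' @return nMarkers x k 0/1 matrix
#' @export
simulateFounderAlleles <- function(nMarkers, k, shape = 1, monomorphRate = 0.05) {
    f <- matrix(0L, nMarkers, k)
    for (m in seq_len(nMarkers)) {
        repeat {
            p <- stats::rbeta(1, shape, shape)
            g <- stats::rbinom(k, 1L, p)
            if (length(unique(g)) > 1L || stats::runif(1) < monomorphRate) break
        }
        f[m, ] <- g
    }
    f
}

#' Attach observed SNP genotypes to simulated individuals
#'
#' Reads the true dosage of the coded allele off each individual's mosaic
#' pair at the marker positions, then corrupts each call independently
#' with probability `errorRate`, replacing it by one of the other dosage
#' categories uniformly.
#'
#' @param pop list of individuals from [simulatePopulation()]
#' @param founderAlleles M x k 0/1 matrix
#' @param map single-chromosome [GeneticMap-class] with M markers
#' @param errorRate genotyping error rate in [0, 0.5)
#' @return list with `calls` (M x N dosage matrix) and `truth`
#'   (list per individual of the two founder-index vectors at markers)
#' @export
attachGenotypes <- function(pop, founderAlleles, map, errorRate = 0) {
    if (errorRate < 0 || errorRate >= 0.5)
        stop("errorRate must be in [0, 0.5)")
    pos <- positions(map)
    M <- length(pos); N <- length(pop)
    calls <- matrix(NA_real_, M, N,
                    dimnames = list(markers(map), sprintf("ind%03d", seq_len(N))))
    truth <- vector("list", N)
    for (i in seq_len(N)) {
        f1 <- .mosaicFounder(pop[[i]]$h1, pos)
        f2 <- .mosaicFounder(pop[[i]]$h2, pos)
        truth[[i]] <- cbind(f1, f2)
        d <- founderAlleles[cbind(seq_len(M), f1)] +
            founderAlleles[cbind(seq_len(M), f2)]
        if (errorRate > 0) {
            err <- stats::runif(M) < errorRate
            if (any(err))
                d[err] <- vapply(d[err], function(x)
                    sample(setdiff(c(0, 1, 2), x), 1L), numeric(1))
        }
        calls[, i] <- d
    }
    names(truth) <- colnames(calls)
    list(calls = calls, truth = truth)
}

#' Empirical map expansion of simulated haplotypes
#'
#' Mean number of (non-silent) founder breakpoints per haplotype divided
#' by the chromosome length in Morgans — the simulation counterpart of
#' [mapExpansion()].
#'
#' @param haplotypes list of mosaics
#' @param chromLength chromosome length in cM
#' @return list with `expansion`, `se` (standard error of the mean density)
#'   and `counts` (breakpoints per haplotype)
#' @export
estimateMapExpansion <- function(haplotypes, chromLength) {
    if (length(haplotypes) == 0L) stop("no haplotypes supplied")
    counts <- vapply(haplotypes, function(h) length(h$bp), numeric(1))
    dens <- counts / (chromLength / 100)
    list(expansion = mean(dens),
         se = stats::sd(dens) / sqrt(length(dens)),
         counts = counts)
}

#' Calibrate the effective generations by simulation
#'
#' Increases integer n from 0 until the simulated map expansion's
#' approximate confidence interval (+/- `ciMult` standard errors) covers,
#' or first exceeds, the target expansion. Reports the closed-form
#' solution from [calibrateNClosedForm()] alongside.
#'
#' @param targetExpansion target map expansion >= 0
#' @param alpha founder proportions
#' @param popPairs mating pairs per simulated population
#' @param chromLength chromosome length in cM
#' @param ciMult half-width of the acceptance interval in standard errors
#' @param maxN search cap
#' @return list with `n` (integer), `closedForm` (real), `expansion` and
#'   `se` at the returned n
#' @export
calibrateNBySimulation <- function(targetExpansion, alpha, popPairs = 300,
                                   chromLength = 100, ciMult = 3, maxN = 60) {
    if (targetExpansion < 0) stop("target expansion must be non-negative")
    closed <- calibrateNClosedForm(targetExpansion, alpha)
    if (targetExpansion == 0)
        return(list(n = 0L, closedForm = closed, expansion = 0, se = 0))
    for (n in 0:maxN) {
        pop <- simulatePopulation(alpha, n, popPairs, chromLength)
        hap <- lapply(pop, `[[`, "h1")
        est <- estimateMapExpansion(hap, chromLength)
        lo <- est$expansion - ciMult * est$se
        hi <- est$expansion + ciMult * est$se
        if ((targetExpansion >= lo && targetExpansion <= hi) ||
            est$expansion >= targetExpansion)
            return(list(n = n, closedForm = closed,
                        expansion = est$expansion, se = est$se))
    }
    stop("calibration did not reach the target expansion by n = ", maxN)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper producing everything [reconstruct()] consumes: a
#' marker map, founder dosages, offspring dosages with genotyping errors,
#' and the true founder mosaics for accuracy scoring.
#'
#' @param alpha founder proportions
#' @param nGenerations generations of random mating
#' @param nInd number of offspring to keep
#' @param nMarkers markers, equally spaced over `chromLength`
#' @param chromLength chromosome length in cM
#' @param errorRate genotyping error rate
#' @param phase `"heterozygous"` or `"homozygous"`
#' @param popPairs mating pairs maintained during the simulation
#' @param chr chromosome label for the map
#' @return list with `map` ([GeneticMap-class]), `founders` (M x k dosage
#'   matrix, 0/2), `offspring` (M x nInd dosage matrix), `truth` (founder
#'   index pair matrix per individual at markers), `mosaics` (the kept
#'   individuals), `cross` (a matching [CrossModel-class])
#' @export
simulateCross <- function(alpha = rep(1 / 8, 8), nGenerations = 8, nInd = 20,
                          nMarkers = 1000, chromLength = 100,
                          errorRate = 0.002,
                          phase = c("heterozygous", "homozygous"),
                          popPairs = 200, chr = "1") {
    phase <- match.arg(phase)
    k <- length(alpha)
    pos <- seq(0, chromLength, length.out = nMarkers)
    # keep markers strictly inside segment arithmetic
    pos[nMarkers] <- chromLength - 1e-9 * chromLength
    map <- GeneticMap(sprintf("m%04d", seq_len(nMarkers)), chr, pos)
    fAllele <- simulateFounderAlleles(nMarkers, k)
    rownames(fAllele) <- markers(map)
    pop <- simulatePopulation(alpha, nGenerations, popPairs, chromLength, phase)
    pop <- pop[seq_len(min(nInd, length(pop)))]
    gt <- attachGenotypes(pop, fAllele, map, errorRate)
    founders <- 2 * fAllele
    colnames(founders) <- if (k <= 26) LETTERS[seq_len(k)] else paste0("F", seq_len(k))
    list(map = map, founders = founders, offspring = gt$calls,
         truth = gt$truth, mosaics = pop,
         cross = CrossModel(alpha = alpha, nGenerations = nGenerations,
                            phase = phase))
}
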