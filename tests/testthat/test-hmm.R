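test_that("emission probabilities implement the error-tolerant dosage model", {
    cm <- CrossModel(3, nGenerations = 2)
    fa <- rbind(c(0, 1, 1), c(1, 0, NA), c(0, 0, 0))
    # missing observation -> uninformative row of ones
    em <- emissionMatrix(fa, c(NA, 2, 0), cm, errorRate = 0.002)
    expect_equal(unname(em[1, ]), rep(1, 6))
    # states: AA BB CC AB AC BC; marker 2 dosages: 2,0,NA,1,NA,NA
    expect_equal(unname(em[2, ]), c(0.998, 0.001, 1, 0.001, 1, 1))
    # monomorphic marker: every state predicts 0, so obs 0 is uninformative in shape
    expect_equal(unname(em[3, ]), rep(0.998, 6))
    # error-free consistency: epsilon = 0 zeroes incompatible states
    em0 <- emissionMatrix(fa, c(2, 2, 0), cm, errorRate = 0)
    expect_equal(unname(em0[1, ]), c(0, 1, 1, 0, 0, 1))  # dosages 0,2,2,1,1,2
    expect_error(emissionMatrix(fa, c(3, 0, 0), cm), "invalid genotype")
    expect_error(emissionMatrix(fa, c(0, 0, 0), cm, errorRate = 0.7), "0.5")
})

test_that("forward-backward equals exhaustive path enumeration", {
    set.seed(42)
    for (S in 2:6) for (M in 1:4) for (rep in 1:3) {
        init <- randomAlpha(S)
        tr <- replicate(max(M - 1, 0), randomStochastic(S), simplify = FALSE)
        em <- matrix(runif(M * S), M, S)
        got <- forwardBackward(init, tr, em)
        want <- enumPosterior(init, tr, em)
        expect_equal(unname(got$posterior), want$posterior, tolerance = 1e-10)
        expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
        expect_equal(unname(rowSums(got$posterior)), rep(1, M),
                     tolerance = 1e-9)
    }
})

test_that("uninformative data return the chain marginal; one marker is Bayes rule", {
    a <- c(0.1, 0.2, 0.7)
    tr <- list(haplotypeTransition(a, 0.1, 4), haplotypeTransition(a, 0.3, 4))
    fb <- forwardBackward(a, tr, matrix(1, 3, 3))
    expect_equal(unname(fb$posterior), matrix(rep(a, each = 3), 3, 3),
                 tolerance = 1e-12)  # alpha-stationary chain
    em1 <- matrix(c(0.5, 0.2, 0.1), 1, 3)
    fb1 <- forwardBackward(a, list(), em1)
    expect_equal(unname(fb1$posterior[1, ]), (a * em1[1, ]) / sum(a * em1[1, ]))
})

test_that("zero likelihood raises an informative positional error", {
    a <- c(0.5, 0.5)
    tr <- list(haplotypeTransition(a, 0.1, 2))
    em <- rbind(c(1, 1), c(0, 0))
    expect_error(forwardBackward(a, tr, em), "position 2")
})

test_that("raising the error rate smooths posteriors around an inconsistent call", {
    set.seed(42)
    cm <- CrossModel(4, nGenerations = 4, phase = "homozygous")
    fa <- matrix(rbinom(30 * 4, 1, 0.5), 30, 4)
    truth <- rep(2L, 30)
    obs <- 2 * fa[cbind(1:30, truth)]
    obs[15] <- 2 - obs[15]  # one corrupted call
    rf <- rep(mapDistanceToRecFrac(1, "haldane"), 29)
    sharp <- vapply(c(0.001, 0.01, 0.05, 0.2), function(eps) {
        tr <- lapply(rf, function(r) genotypeTransition(cm, r))
        fb <- forwardBackward(initialDistribution(cm), tr,
                              emissionMatrix(fa, obs, cm, eps))
        c(max(fb$posterior), fb$posterior[15, 2])
    }, numeric(2))
    # a larger error rate softens the sharpest assignment on the chromosome...
    expect_true(all(diff(sharp[1, ]) < 0))
    # ...while absorbing the inconsistent call: the true state's posterior
    # at the corrupted position recovers as epsilon grows
    expect_true(all(diff(sharp[2, ]) > 0))
})

test_that("viterbi matches exhaustive argmax and breaks ties to the lowest state", {
    set.seed(1)
    for (rep in 1:5) {
        S <- sample(2:5, 1); M <- sample(2:4, 1)
        init <- randomAlpha(S)
        tr <- replicate(M - 1, randomStochastic(S), simplify = FALSE)
        em <- matrix(runif(M * S), M, S)
        want <- enumPosterior(init, tr, em)$best
        expect_equal(unname(viterbiPath(init, tr, em)), unname(want))
    }
    # uninformative emissions with equal alpha: constant path at the first state
    a <- rep(1 / 4, 4)
    tr <- replicate(3, haplotypeTransition(a, 0.1, 2), simplify = FALSE)
    expect_equal(unname(viterbiPath(a, tr, matrix(1, 4, 4))), rep(1L, 4))
})

test_that("viterbi recovers the truth from fully informative error-free markers", {
    set.seed(42)
    # two founders, haploid chain, founders differ at every marker
    a <- c(0.5, 0.5)
    M <- 60
    fa <- cbind(rep(0, M), rep(1, M))
    truth <- rep(c(1L, 2L, 1L), times = c(20, 20, 20))
    obs <- 2 * fa[cbind(seq_len(M), truth)]
    cm <- CrossModel(alpha = a, nGenerations = 4, phase = "haploid")
    rf <- rep(mapDistanceToRecFrac(1, "haldane"), M - 1)
    tr <- lapply(rf, function(r) genotypeTransition(cm, r))
    em <- emissionMatrix(fa, obs, cm, errorRate = 0)
    expect_equal(unname(viterbiPath(initialDistribution(cm), tr, em)), truth)
})

test_that("segment inference thresholds, merges runs and counts breakpoints", {
    map <- GeneticMap(paste0("m", 1:6), "1", 0:5)
    p1 <- matrix(c(0.99, 0.01), 6, 2, byrow = TRUE,
                 dimnames = list(NULL, c("A", "B")))
    s1 <- inferSegments(p1, map, 0.95)
    expect_equal(nrow(s1$segments), 1L)
    expect_equal(s1$nBreakpoints, 0L)
    expect_equal(s1$segments$state, "A")
    # switch mid-chromosome
    p2 <- rbind(p1[1:3, ], p1[1:3, c(2, 1)])
    colnames(p2) <- c("A", "B")
    s2 <- inferSegments(p2, map, 0.95)
    expect_equal(nrow(s2$segments), 2L)
    expect_equal(s2$nBreakpoints, 1L)
    expect_equal(s2$segments$start_cM, c(0, 3))
    # below-threshold positions are unassigned and do not split same-state runs
    p3 <- p1; p3[3, ] <- c(0.6, 0.4)
    s3 <- inferSegments(p3, map, 0.95)
    expect_equal(nrow(s3$segments), 1L)
    expect_equal(s3$nBreakpoints, 0L)
    expect_error(inferSegments(p1, map, 0.5), "threshold")
})

test_that("reconstruct is accurate on homozygous doubled-haploid simulations", {
    set.seed(42)
    sim <- simulateCross(nGenerations = 8, nInd = 4, nMarkers = 400,
                         phase = "homozygous", popPairs = 80)
    ps <- reconstruct(sim$founders, sim$offspring, sim$map, sim$cross,
                      errorRate = 0.002)
    expect_s4_class(ps, "PosteriorSet")
    accs <- vapply(seq_along(posteriors(ps)), function(i) {
        p <- posteriors(ps)[[i]]
        expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
        called <- max.col(p, ties.method = "first")
        mx <- apply(p, 1, max)
        mean(called == sim$truth[[i]][, 1] & mx >= 0.95)
    }, numeric(1))
    expect_gt(mean(accs), 0.9)   # aggregate confident-and-correct fraction
    expect_true(all(accs > 0.8)) # no individual collapses
})

test_that("an impossible call with zero error rate fails loudly", {
    set.seed(42)
    sim <- simulateCross(nGenerations = 4, nInd = 2, nMarkers = 50,
                         phase = "homozygous", popPairs = 40, errorRate = 0)
    off <- sim$offspring
    # a heterozygous call is impossible for a doubled haploid: with
    # errorRate = 0 no state can emit it
    off[25, 1] <- 1
    expect_error(
        suppressMessages(reconstruct(sim$founders, off, sim$map, sim$cross,
                                     errorRate = 0)),
        "zero likelihood")
})

test_that("heterozygous-phase analysis of doubled haploids concentrates on homozygote states", {
    set.seed(42)
    sim <- simulateCross(nGenerations = 6, nInd = 3, nMarkers = 300,
                         phase = "homozygous", popPairs = 60)
    crossHet <- CrossModel(alpha = founderProbs(sim$cross),
                           nGenerations = 6, phase = "heterozygous")
    ps <- reconstruct(sim$founders, sim$offspring, sim$map, crossHet,
                      errorRate = 0.002)
    k <- nFounders(crossHet)
    for (p in posteriors(ps))
        expect_gt(mean(rowSums(p[, seq_len(k), drop = FALSE])), 0.9)
})

test_that("marker universes are reconciled by intersection in map order", {
    set.seed(42)
    sim <- simulateCross(nGenerations = 4, nInd = 2, nMarkers = 60,
                         phase = "homozygous", popPairs = 40)
    # shuffle offspring rows and drop some founder rows
    off <- sim$offspring[sample(nrow(sim$offspring)), , drop = FALSE]
    fdr <- sim$founders[-(1:5), , drop = FALSE]
    expect_message(
        ps <- reconstruct(fdr, off, sim$map, sim$cross, errorRate = 0.002),
        "dropped")
    expect_equal(nrow(posteriors(ps)[[1]]), 55L)
    expect_equal(rownames(posteriors(ps)[[1]]), NULL)  # matrices unnamed rows
    expect_equal(nMarkers(ps@map), 55L)
    expect_equal(markers(ps@map), markers(sim$map)[-(1:5)])  # map order kept
})
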