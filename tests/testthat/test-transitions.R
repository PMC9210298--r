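test_that("two-point recursion starts diagonal and iterates one generation at a time", {
    a <- c(0.2, 0.3, 0.5)
    expect_equal(unclass(twoPointRecursion(a, 0.1, 0)), diag(a),
                 ignore_attr = TRUE)
    expect_equal(unclass(twoPointRecursion(a, 0, 10)), diag(a),
                 ignore_attr = TRUE)  # no recombination ever
    # k = 8 equal, r = 0.01, n = 8: p_ii = 1/64 + 0.99^8 * (1/8)(7/8)
    p <- twoPointRecursion(rep(1 / 8, 8), 0.01, 8)
    expect_equal(unname(diag(p)), rep(1 / 64 + 0.99^8 * (1 / 8) * (7 / 8), 8))
    expect_error(twoPointRecursion(a, 0.1, 2.5), "integer")
})

test_that("closed form solves the recursion and handles limits", {
    set.seed(42)
    for (i in 1:25) {
        k <- sample(2:8, 1)
        a <- randomAlpha(k)
        r <- sample(c(0, 0.01, 0.1, 0.5), 1)
        n <- sample(0:20, 1)
        expect_equal(twoPointProbs(a, r, n), twoPointRecursion(a, r, n),
                     tolerance = 1e-12)
    }
    a <- randomAlpha(5)
    # linkage equilibrium limit
    expect_equal(unclass(twoPointProbs(a, 0.1, 1e6)), outer(a, a),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # one generation, two founders: p_ii = 0.25 + 0.75 * 0.25
    p <- twoPointProbs(c(0.5, 0.5), 0.25, 1)
    expect_equal(unname(diag(p)), rep(0.4375, 2))
    expect_error(twoPointProbs(a, 0.1, -1), "non-negative")
})

test_that("two-point tables are symmetric with alpha marginals on both axes", {
    set.seed(7)
    for (i in 1:10) {
        a <- randomAlpha(sample(2:9, 1))
        p <- twoPointProbs(a, runif(1, 0, 0.5), runif(1, 0, 30))
        expect_equal(sum(p), 1, tolerance = 1e-12)
        expect_equal(unclass(p), t(unclass(p)), ignore_attr = TRUE)
        expect_equal(unname(rowSums(p)), a, tolerance = 1e-12)
        expect_equal(unname(colSums(p)), a, tolerance = 1e-12)
        expect_true(all(p >= 0))
    }
})

test_that("haplotype transitions are stochastic, alpha-stationary, with correct limits", {
    a <- rep(1 / 8, 8)
    expect_equal(unclass(haplotypeTransition(a, 0, 5)), diag(8),
                 ignore_attr = TRUE)
    tm <- haplotypeTransition(a, 0.5, 1e6)
    expect_equal(unclass(tm), matrix(1 / 8, 8, 8), tolerance = 1e-12,
                 ignore_attr = TRUE)  # memoryless limit: every row = alpha
    tm2 <- haplotypeTransition(a, 0.01, 8)
    off <- (1 / 8) * (1 - 0.99^8)
    expect_equal(unname(tm2[1, 2]), off)
    set.seed(11)
    for (i in 1:10) {
        aa <- randomAlpha(sample(2:8, 1))
        tt <- haplotypeTransition(aa, runif(1, 0, 0.5), runif(1, 0, 40))
        expect_equal(unname(rowSums(tt)), rep(1, length(aa)), tolerance = 1e-12)
        expect_equal(unname(as.vector(aa %*% tt)), aa, tolerance = 1e-12)
    }
    # conditional of the two-point table where alpha_i > 0
    aa <- c(0.5, 0.3, 0.2, 0)
    tt <- haplotypeTransition(aa, 0.2, 3)
    pp <- twoPointProbs(aa, 0.2, 3)
    expect_equal(unclass(tt[1:3, ]), unclass(pp[1:3, ] / aa[1:3]),
                 ignore_attr = TRUE)
    expect_equal(attr(tt, "unreachable"), c(FALSE, FALSE, FALSE, TRUE))
    expect_equal(unname(rowSums(tt)), rep(1, 4), tolerance = 1e-12)
})

test_that("effective generations apply the (2/3)n X-chromosome substitution", {
    expect_equal(effectiveGenerations(
        CrossModel(8, nGenerations = 24, phase = "homozygous")), 24)
    expect_equal(effectiveGenerations(
        CrossModel(8, nGenerations = 24, phase = "homozygous",
                   chromType = "X")), 16)
    expect_equal(effectiveGenerations(
        CrossModel(8, nGenerations = 8, phase = "homozygous",
                   chromType = "X")), 16 / 3)
})

test_that("state spaces enumerate founders and unordered pairs deterministically", {
    expect_length(stateSpace(CrossModel(8, nGenerations = 8)), 36)
    expect_length(stateSpace(CrossModel(8, nGenerations = 8,
                                        phase = "homozygous")), 8)
    expect_length(stateSpace(CrossModel(2, nGenerations = 8)), 3)
    st <- stateSpace(CrossModel(3, nGenerations = 1))
    expect_equal(as.character(st), c("AA", "BB", "CC", "AB", "AC", "BC"))
    # male X in a heterozygous population is hemizygous
    stx <- stateSpace(CrossModel(8, nGenerations = 8, chromType = "X",
                                 sex = "male"))
    expect_length(stx, 8)
    # alpha = 0 founders kept but flagged
    cm0 <- CrossModel(alpha = c(0.5, 0.5, 0), nGenerations = 2,
                      phase = "haploid")
    expect_equal(unname(attr(stateSpace(cm0), "unreachable")),
                 c(FALSE, FALSE, TRUE))
})

test_that("initial distributions are stationary Hardy-Weinberg products", {
    expect_equal(unname(initialDistribution(
        CrossModel(8, nGenerations = 8, phase = "homozygous"))), rep(1 / 8, 8))
    ip <- initialDistribution(CrossModel(8, nGenerations = 8))
    expect_equal(unname(ip[1:8]), rep(1 / 64, 8))     # homozygotes
    expect_equal(unname(ip[9:36]), rep(2 / 64, 28))   # heterozygotes
    expect_equal(sum(ip), 1, tolerance = 1e-12)
    # point mass when one founder has all the mass
    ip2 <- initialDistribution(CrossModel(alpha = c(1, 0, 0),
                                          nGenerations = 3, phase = "haploid"))
    expect_equal(unname(ip2), c(1, 0, 0))
})

test_that("genotype transitions collapse the ordered product chain correctly", {
    cm <- CrossModel(4, nGenerations = 3)
    expect_equal(unclass(genotypeTransition(cm, 0)), diag(10),
                 ignore_attr = TRUE)
    # matches the direct unordered two-haplotype formula (oracle)
    set.seed(5)
    for (k in c(2, 3, 4)) {
        a <- randomAlpha(k)
        r <- runif(1, 0, 0.5)
        cm2 <- CrossModel(alpha = a, nGenerations = 2)
        got <- genotypeTransition(cm2, r)
        expect_equal(unclass(got), directUnorderedTransition(a, r, 2),
                     tolerance = 1e-12, ignore_attr = TRUE)
        expect_equal(unname(rowSums(got)), rep(1, k * (k + 1) / 2),
                     tolerance = 1e-12)
        # initial distribution is stationary for the diplotype chain
        ip <- initialDistribution(cm2)
        expect_equal(unname(as.vector(ip %*% got)), unname(ip),
                     tolerance = 1e-12)
    }
    # ordered debug mode keeps the full k^2 chain
    expect_equal(dim(genotypeTransition(cm, 0.1, ordered = TRUE)), c(16L, 16L))
    # homozygous populations are doubled haploids: identical to the haplotype chain
    cmh <- CrossModel(alpha = randomAlpha(5), nGenerations = 4,
                      phase = "homozygous")
    expect_equal(unclass(genotypeTransition(cmh, 0.12)),
                 unclass(haplotypeTransition(cmh@alpha, 0.12, 4)),
                 ignore_attr = TRUE)
})

test_that("map expansion, exchange probability and closed-form calibration agree", {
    expect_equal(mapExpansion(rep(1 / 8, 8), 8), 7)
    expect_equal(mapExpansion(randomAlpha(4), 0), 0)
    expect_equal(mapExpansion(c(1, 0, 0), 13), 0)
    a <- rep(1 / 8, 8)
    expect_equal(exchangeProbability(a, 8, 0), 0)
    expect_equal(exchangeProbability(a, 8, 0.01), (7 / 8) * (1 - 0.99^8))
    # derivative at r -> 0 is the map expansion
    h <- 1e-7
    expect_equal((exchangeProbability(a, 8, h) - exchangeProbability(a, 8, 0)) / h,
                 mapExpansion(a, 8), tolerance = 1e-4)
    # monotone in r and in n
    rs <- seq(0, 0.5, length.out = 20)
    expect_true(all(diff(exchangeProbability(a, 8, rs)) > 0))
    expect_true(all(diff(exchangeProbability(a, c(1, 4, 8, 20), 0.1)) > 0))
    expect_equal(calibrateNClosedForm(7, a), 8)
    expect_equal(calibrateNClosedForm(0, randomAlpha(3)), 0)
    expect_equal(calibrateNClosedForm((7 * 23 + 37) / 8, a), 198 / 7)
    expect_error(calibrateNClosedForm(7, c(1, 0)), "degenerate")
})
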