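#' Exchange probability for Collaborative Cross autosomes
#'
#' The published exact result for eight-way recombinant inbred lines by
#' sib mating: the chance that a random CC haplotype has an exchange of
#' founder alleles across an interval with recombination fraction r is
#' R(r) = 7r / (1 + 6r). Its derivative at r = 0 (the CC map expansion)
#' is 7, which calibrates the generic random-mating model to n = 8 for
#' eight equally frequent founders.
#'
#' @param r recombination fraction(s) in [0, 0.5]
#' @return exchange probability
#' @examples
#' ccExchangeProbability(0.5)  # 7/8
#' @export
ccExchangeProbability <- function(r) {
    .check_r(r)
    7 * r / (1 + 6 * r)
}

#' Map expansion of Diversity Outbred mice at outbreeding generation s
#'
#' The DO autosomal map expansion at generation s is
#' (7/8)(s - 1) + M1, where M1 is the weighted average map expansion of
#' the pre-CC founder lines, approximately (7s + 37)/8 — the form used
#' here.
#'
#' @param s DO outbreeding generation (integer >= 1)
#' @return map expansion (dimensionless)
#' @export
doMapExpansion <- function(s) {
    if (any(s < 1)) stop("DO generation must be >= 1")
    (7 * s + 37) / 8
}

#' Effective random-mating generations approximating the DO
#'
#' Equates the generic model's autosomal map expansion for eight equal
#' founders, (7/8) n, with the DO map expansion at generation s, giving
#' n = s + 37/7. Rounded, the offset n - s is 5 for every s, hence the
#' working rule n ~ s + 5.
#'
#' @param s DO outbreeding generation (integer >= 1)
#' @return effective n (real)
#' @examples
#' doEffectiveN(23)  # 198/7 = 28.29, about s + 5
#' @export
doEffectiveN <- function(s) {
    doMapExpansion(s) / (7 / 8)
}

#' X, mitochondrial and Y founder contributions of a CC funnel
#'
#' Exact single-locus founder probabilities on the X chromosome for a
#' Collaborative Cross line with funnel
#' \[(f1 x f2) x (f3 x f4)\] x \[(f5 x f6) x (f7 x f8)\], female parent
#' listed first in each cross. The X of each funnel individual is tracked
#' through the three cross generations (daughters receive a random
#' maternal X plus the paternal X; sons receive a random maternal X), and
#' the fixed X under subsequent sib mating weights the final female's two
#' X copies and the final male's single X by 1/3 each. Only five founders
#' can contribute: positions 1 and 2 get 1/6, position 3 gets 1/3,
#' positions 5 and 6 get 1/6, and positions 4, 7 and 8 get 0. The
#' mitochondria descend from the founder at position 1 and the Y
#' chromosome from the founder at position 8.
#'
#' @param funnel the 8 founder labels in funnel order: a character vector
#'   of length 8, or a single 8-character string
#' @return list with `xProbs` (named length-8 vector summing to 1),
#'   `mito` and `y` (founder labels)
#' @examples
#' ccFunnelXProbs("ABCDEFGH")$xProbs  # 1/6,1/6,1/3,0,1/6,1/6,0,0
#' @export
ccFunnelXProbs <- function(funnel) {
    if (is.character(funnel) && length(funnel) == 1L && nchar(funnel) == 8L)
        funnel <- strsplit(funnel, "")[[1]]
    funnel <- as.character(funnel)
    if (length(funnel) != 8L || anyDuplicated(funnel))
        stop("a funnel must list 8 distinct founder labels")
    # distribution of "a uniformly chosen X copy" of each funnel individual
    unit <- function(i) { v <- numeric(8); v[i] <- 1; v }
    # G1 crosses: female f1 x male f2 etc.
    femAB <- (unit(1) + unit(2)) / 2       # daughter of f1 x f2: X's {f1, f2}
    maleCD <- unit(3)                      # son of f3 x f4: X = f3
    femEF <- (unit(5) + unit(6)) / 2
    maleGH <- unit(7)                      # son of f7 x f8: X = f7 (unused), Y = f8
    # G2 crosses: female(AB) x male(CD) -> female side; female(EF) x male(GH) -> male side
    femABCD <- (femAB + maleCD) / 2        # daughter: random maternal X + paternal X
    maleEFGH <- femEF                      # son: random maternal X (Y from f8 side male)
    # Final cross female(ABCD) x male(EFGH); sib mating fixes one of the
    # three X copies in a sibling pair with probability 1/3 each:
    # daughter = {random X of ABCD female, X of EFGH male}, son = random X of ABCD female
    xProbs <- (2 / 3) * femABCD + (1 / 3) * maleEFGH
    names(xProbs) <- funnel
    list(xProbs = xProbs, mito = funnel[1], y = funnel[8])
}
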