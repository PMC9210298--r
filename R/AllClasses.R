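#' @import methods
NULL

#' Marker map for one or more chromosomes
#'
#' Holds marker names, chromosome assignments and sex-averaged genetic
#' positions in centiMorgans, plus a flag marking pseudomarkers (grid
#' positions without genotype data at which posteriors are still computed).
#' Within each chromosome positions are non-decreasing on input; exact ties
#' are perturbed by successive increments of 1e-6 cM in input order so that
#' marker ordering is strict and deterministic.
#'
#' @slot marker character vector of unique marker names
#' @slot chr character vector of chromosome labels, parallel to `marker`
#' @slot pos numeric vector of positions in cM, parallel to `marker`
#' @slot pseudo logical vector flagging pseudomarkers
#'
#' @exportClass GeneticMap
setClass("GeneticMap",
         representation(marker = "character", chr = "character",
                        pos = "numeric", pseudo = "logical"))

setValidity("GeneticMap", function(object) {
    n <- length(object@marker)
    if (n < 1L) return("map must contain at least one marker")
    if (length(object@chr) != n || length(object@pos) != n ||
        length(object@pseudo) != n)
        return("marker, chr, pos and pseudo must have equal length")
    if (anyNA(object@pos)) return("positions must not be missing")
    for (cc in unique(object@chr)) {
        idx <- object@chr == cc
        if (anyDuplicated(object@marker[idx]))
            return(sprintf("duplicate marker names on chromosome %s", cc))
        if (is.unsorted(object@pos[idx], strictly = TRUE))
            return(sprintf("positions not strictly increasing on chromosome %s", cc))
    }
    TRUE
})

#' Cross model: founder proportions and effective random-mating generations
#'
#' Describes the breeding abstraction behind the transition probabilities:
#' a founder population of `k` inbred lines in proportions `alpha`, followed
#' by `nGenerations` generations of random mating among many mating pairs.
#' `phase` distinguishes haploid chains, homozygous populations (RIL/MAGIC,
#' treated as doubled haploids) and heterozygous populations (AIL/DO/HS).
#' On the X chromosome the effective number of generations becomes (2/3)n,
#' since recombination occurs only in females; `sex` matters only there.
#'
#' @slot alpha numeric vector of founder proportions, summing to 1
#' @slot nGenerations positive real; non-integer values arise from the X
#'   adjustment and are accepted by the closed-form probabilities
#' @slot phase one of "haploid", "homozygous", "heterozygous"
#' @slot chromType "autosome" or "X"
#' @slot sex "female", "male" or "none"; required when `chromType` is "X"
#'   and `phase` is "heterozygous"
#'
#' @exportClass CrossModel
setClass("CrossModel",
         representation(alpha = "numeric", nGenerations = "numeric",
                        phase = "character", chromType = "character",
                        sex = "character"))

setValidity("CrossModel", function(object) {
    a <- object@alpha
    if (length(a) < 2L) return("at least two founders required")
    if (any(a < 0)) return("founder proportions must be non-negative")
    if (abs(sum(a) - 1) > 1e-12) return("founder proportions must sum to 1")
    if (length(object@nGenerations) != 1L || object@nGenerations <= 0)
        return("nGenerations must be a single positive number")
    if (!object@phase %in% c("haploid", "homozygous", "heterozygous"))
        return("phase must be haploid, homozygous or heterozygous")
    if (!object@chromType %in% c("autosome", "X"))
        return("chromType must be autosome or X")
    if (!object@sex %in% c("female", "male", "none"))
        return("sex must be female, male or none")
    if (object@chromType == "X" && object@phase == "heterozygous" &&
        object@sex == "none")
        return("sex is required for the X chromosome in a heterozygous population")
    TRUE
})

#' Posterior founder-genotype probabilities for a set of individuals
#'
#' Container for the output of [reconstruct()]: one M x S posterior matrix
#' per individual (rows = map positions, columns = founder-genotype states;
#' each row sums to 1), plus the map, the cross model and per-individual
#' log-likelihoods.
#'
#' @slot probs named list of posterior matrices, one per individual
#' @slot states character vector of state labels for the full state space;
#'   individual matrices may carry a subset (male X) as their colnames
#' @slot map the [GeneticMap-class] the posteriors are computed on
#' @slot cross the [CrossModel-class] used
#' @slot loglik numeric vector of per-individual log-likelihoods
#'
#' @exportClass PosteriorSet
setClass("PosteriorSet",
         representation(probs = "list", states = "character",
                        map = "GeneticMap", cross = "CrossModel",
                        loglik = "numeric"))

setValidity("PosteriorSet", function(object) {
    if (length(object@probs) == 0L) return("no individuals")
    M <- length(object@map@marker)
    for (nm in names(object@probs)) {
        p <- object@probs[[nm]]
        if (!is.matrix(p) || nrow(p) != M)
            return(sprintf("posterior for %s does not match the map", nm))
        if (any(p < -1e-12))
            return(sprintf("negative posterior for %s", nm))
        if (max(abs(rowSums(p) - 1)) > 1e-6)
            return(sprintf("posterior rows for %s do not sum to 1", nm))
    }
    TRUE
})
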