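#' Construct a CrossModel
#'
#' @param nFounders number of founders k (>= 2); may be omitted when
#'   `alpha` is given
#' @param alpha founder proportions (default equal, 1/k each)
#' @param nGenerations effective number of generations of random mating
#'   (positive; real-valued)
#' @param phase `"haploid"`, `"homozygous"` (RIL/MAGIC, doubled haploids) or
#'   `"heterozygous"` (AIL/DO/HS)
#' @param chromType `"autosome"` or `"X"`
#' @param sex `"female"`, `"male"` or `"none"`; required on the X in a
#'   heterozygous population
#' @param founderNames optional founder labels; defaults to `LETTERS`
#' @return a [CrossModel-class]
#' @examples
#' cc <- CrossModel(nFounders = 8, nGenerations = 8, phase = "homozygous")
#' nFounders(cc)
#' @export
CrossModel <- function(nFounders = NULL, alpha = NULL, nGenerations,
                       phase = c("heterozygous", "homozygous", "haploid"),
                       chromType = c("autosome", "X"),
                       sex = c("none", "female", "male"),
                       founderNames = NULL) {
    phase <- match.arg(phase)
    chromType <- match.arg(chromType)
    sex <- match.arg(sex)
    if (is.null(alpha)) {
        if (is.null(nFounders)) stop("supply nFounders or alpha")
        alpha <- rep(1 / nFounders, nFounders)
    }
    if (!is.null(nFounders) && length(alpha) != nFounders)
        stop("alpha must have length nFounders")
    if (is.null(founderNames))
        founderNames <- if (length(alpha) <= 26) LETTERS[seq_along(alpha)]
                        else paste0("F", seq_along(alpha))
    names(alpha) <- founderNames
    new("CrossModel", alpha = alpha, nGenerations = as.numeric(nGenerations),
        phase = phase, chromType = chromType, sex = sex)
}

#' @describeIn CrossModel founder proportions (named)
#' @param x,object a `CrossModel`
#' @export
founderProbs <- function(x) x@alpha

#' @describeIn CrossModel number of founders
#' @export
nFounders <- function(x) length(x@alpha)

#' @describeIn CrossModel nominal generations of random mating
#' @export
nGenerations <- function(x) x@nGenerations

#' @describeIn CrossModel phase of the population
#' @export
crossPhase <- function(x) x@phase

#' @describeIn CrossModel chromosome type
#' @export
chromType <- function(x) x@chromType

#' @rdname CrossModel
#' @export
setMethod("show", "CrossModel", function(object) {
    cat(sprintf("CrossModel: k = %d founders, n = %g generations, %s phase, %s%s\n",
                length(object@alpha), object@nGenerations, object@phase,
                object@chromType,
                if (object@sex == "none") "" else paste0(" (", object@sex, ")")))
    cat("  alpha:", paste(sprintf("%s=%.4g", names(object@alpha), object@alpha),
                          collapse = " "), "\n")
})

#' Effective number of generations
#'
#' The number of generations actually applied in the transition
#' probabilities: `n` on autosomes and `(2/3) n` on the X chromosome,
#' since recombination occurs only in females (so in 2/3 of X
#' chromosomes). The result is generally non-integer; all closed-form
#' probabilities accept real `n`.
#'
#' @param cross a [CrossModel-class]
#' @return effective generations (real)
#' @examples
#' effectiveGenerations(CrossModel(8, nGenerations = 24, chromType = "X"))  # 16
#' @export
effectiveGenerations <- function(cross) {
    if (cross@chromType == "X") (2 / 3) * cross@nGenerations
    else cross@nGenerations
}

#' Founder-genotype state space
#'
#' Enumerates the hidden-state labels for the HMM. Haploid and homozygous
#' populations (and males on the X) have one state per founder; a
#' heterozygous population has k(k+1)/2 unordered founder pairs, ordered
#' deterministically with the k homozygotes first, then heterozygote pairs
#' in lexicographic order. States whose founder proportion is exactly 0 are
#' retained (so one indexing serves all individuals) but flagged in the
#' `"unreachable"` attribute.
#'
#' @param cross a [CrossModel-class]
#' @return character vector of state labels, with attributes `"pairs"`
#'   (2-column integer matrix of founder indices per state) and
#'   `"unreachable"` (logical)
#' @examples
#' length(stateSpace(CrossModel(8, nGenerations = 8)))  # 36
#' @export
stateSpace <- function(cross) {
    fn <- names(cross@alpha)
    k <- length(fn)
    haploidLike <- cross@phase %in% c("haploid", "homozygous") ||
        (cross@chromType == "X" && cross@sex == "male")
    if (haploidLike) {
        pairs <- cbind(seq_len(k), seq_len(k))
        states <- fn
    } else {
        homo <- cbind(seq_len(k), seq_len(k))
        het <- t(utils::combn(k, 2))
        pairs <- rbind(homo, het)
        states <- c(paste0(fn, fn), paste0(fn[het[, 1]], fn[het[, 2]]))
    }
    attr(states, "pairs") <- pairs
    attr(states, "unreachable") <-
        cross@alpha[pairs[, 1]] == 0 | cross@alpha[pairs[, 2]] == 0
    states
}

#' Initial state distribution
#'
#' The stationary single-locus distribution of the founder-genotype chain:
#' `alpha` itself for haploid/homozygous chains (and males on the X);
#' Hardy-Weinberg products for heterozygous populations, i.e.
#' `alpha_i^2` for homozygote states and `2 alpha_i alpha_j` for
#' unordered heterozygote states.
#'
#' @param cross a [CrossModel-class]
#' @return named numeric vector over [stateSpace()], summing to 1
#' @export
initialDistribution <- function(cross) {
    states <- stateSpace(cross)
    pairs <- attr(states, "pairs")
    a <- unname(cross@alpha)
    p <- ifelse(pairs[, 1] == pairs[, 2],
                a[pairs[, 1]] * a[pairs[, 2]],
                2 * a[pairs[, 1]] * a[pairs[, 2]])
    haploidLike <- cross@phase %in% c("haploid", "homozygous") ||
        (cross@chromType == "X" && cross@sex == "male")
    if (haploidLike) p <- a
    names(p) <- states
    p
}
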