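#' Reconstruct founder genotypes along chromosomes
#'
#' The main entry point: for each individual and each chromosome of the
#' map, builds the emission probabilities from the founder SNP alleles and
#' the individual's observed genotypes, the transition matrices from the
#' cross model and the inter-marker recombination fractions, and runs the
#' forward-backward algorithm to obtain posterior founder-genotype
#' probabilities at every position (markers and pseudomarkers).
#'
#' Marker universes of the founder matrix, the offspring matrix and the map
#' are reconciled by intersection (a message reports how many markers were
#' dropped); the map defines the ordering. On a chromosome named `xChr`
#' the effective generations become (2/3)n, and in a heterozygous
#' population each individual's sex selects the state space: females keep
#' the diplotype states while males use the k hemizygous states, with any
#' heterozygous male-X call set to missing with a warning.
#'
#' @param founders M x k matrix of founder dosages (0/2 or `NA`; coded
#'   alleles, founders are inbred), rownames = marker names
#' @param offspring M x N matrix of observed dosages in \{0, 1, 2, `NA`\},
#'   rownames = marker names
#' @param map a [GeneticMap-class]
#' @param cross a [CrossModel-class] (autosomal description; the X
#'   adjustment is applied per chromosome)
#' @param errorRate genotyping error rate epsilon (default 0.002)
#' @param mapFunction map function for cM -> recombination fraction
#' @param step optional pseudomarker spacing in cM; `NULL` for none
#' @param xChr chromosome label treated as the X, or `NULL`
#' @param sex optional named character vector ("female"/"male") per
#'   individual, used on the X
#' @return a [PosteriorSet-class] per chromosome, returned as a named list
#'   when the map has several chromosomes, or a single `PosteriorSet`
#' @export
reconstruct <- function(founders, offspring, map, cross,
                        errorRate = 0.002,
                        mapFunction = c("carter_falconer", "haldane", "kosambi"),
                        step = NULL, xChr = NULL, sex = NULL) {
    mapFunction <- match.arg(mapFunction)
    founders <- as.matrix(founders); offspring <- as.matrix(offspring)
    if (is.null(rownames(founders)) || is.null(rownames(offspring)))
        stop("founder and offspring matrices need marker rownames")
    keep <- intersect(markers(map)[!isPseudomarker(map)],
                      intersect(rownames(founders), rownames(offspring)))
    if (length(keep) == 0L)
        stop("no markers shared by the map, founder and offspring files")
    dropped <- length(unique(c(markers(map)[!isPseudomarker(map)],
                               rownames(founders), rownames(offspring)))) -
        length(keep)
    if (dropped > 0)
        message(dropped, " marker(s) outside the common marker universe dropped")
    mIdx <- markers(map) %in% keep | isPseudomarker(map)
    map <- GeneticMap(markers(map)[mIdx], chromosomes(map)[mIdx],
                      positions(map)[mIdx], isPseudomarker(map)[mIdx])
    if (!is.null(step)) map <- insertPseudomarkers(map, step)
    if (is.null(sex)) sex <- setNames(rep("none", ncol(offspring)),
                                      colnames(offspring))
    res <- list()
    for (cc in unique(chromosomes(map))) {
        cmap <- subsetChromosome(map, cc)
        isX <- !is.null(xChr) && cc == xChr
        # founder/offspring rows aligned to this chromosome; NA at pseudomarkers
        fa <- matrix(NA_real_, nMarkers(cmap), ncol(founders),
                     dimnames = list(markers(cmap), colnames(founders)))
        ob <- matrix(NA_real_, nMarkers(cmap), ncol(offspring),
                     dimnames = list(markers(cmap), colnames(offspring)))
        real <- markers(cmap)[!isPseudomarker(cmap)]
        fa[real, ] <- founders[real, ]
        ob[real, ] <- offspring[real, ]
        # founders are inbred: convert dosage 0/2 to allele 0/1
        fAllele <- fa / 2
        rf <- mapRecFracs(cmap, mapFunction)[[cc]]
        probs <- list(); ll <- numeric(0)
        for (ind in colnames(ob)) {
            icross <- .chromCross(cross, isX, sex[[ind]])
            o <- ob[, ind]
            if (isX && icross@sex == "male" && any(o == 1, na.rm = TRUE)) {
                warning("individual ", ind, ": heterozygous call(s) on the male ",
                        "X set to missing", call. = FALSE)
                o[!is.na(o) & o == 1] <- NA
            }
            # haploid-like chains predict dosage 2*f via the (i,i) state pairs
            em <- emissionMatrix(fAllele, o, icross, errorRate)
            init <- initialDistribution(icross)
            trans <- lapply(rf, function(r) genotypeTransition(icross, r))
            fb <- tryCatch(forwardBackward(init, trans, em),
                           error = function(e)
                               stop("individual ", ind, ", chromosome ", cc, ": ",
                                    conditionMessage(e), call. = FALSE))
            probs[[ind]] <- fb$posterior
            ll[ind] <- fb$loglik
        }
        states <- stateSpace(.chromCross(cross, isX, "female"))
        res[[cc]] <- new("PosteriorSet", probs = probs,
                         states = as.character(states), map = cmap,
                         cross = cross, loglik = ll)
    }
    if (length(res) == 1L) res[[1L]] else res
}

# per-chromosome, per-individual cross model (X adjustment and sex)
.chromCross <- function(cross, isX, sex) {
    if (!isX) return(cross)
    new("CrossModel", alpha = cross@alpha, nGenerations = cross@nGenerations,
        phase = cross@phase, chromType = "X",
        sex = if (identical(sex, "male")) "male"
              else if (cross@phase == "heterozygous") "female" else "none")
}

#' @describeIn PosteriorSet-class list of per-individual posterior matrices
#' @param x,object a `PosteriorSet`
#' @export
posteriors <- function(x) x@probs

#' @describeIn PosteriorSet-class state labels of the full state space
#' @export
stateNames <- function(x) x@states

#' @describeIn PosteriorSet-class per-individual log-likelihoods
#' @export
logLiks <- function(x) x@loglik

#' @rdname PosteriorSet-class
#' @export
setMethod("show", "PosteriorSet", function(object) {
    cat(sprintf("PosteriorSet: %d individual(s), %d positions, %d states (chr %s)\n",
                length(object@probs), length(object@map@marker),
                length(object@states), unique(object@map@chr)))
})

#' Segment all individuals of a PosteriorSet
#'
#' Applies [inferSegments()] to every individual and stacks the results.
#'
#' @param ps a [PosteriorSet-class]
#' @param threshold assignment threshold in (0.5, 1]
#' @return list with `segments` (data.frame `individual`, `chromosome`,
#'   `start_cM`, `end_cM`, `state`) and `nBreakpoints` (named integer
#'   vector per individual)
#' @export
segmentAll <- function(ps, threshold = 0.95) {
    segs <- list(); nbp <- integer(0)
    cc <- unique(chromosomes(ps@map))
    for (ind in names(ps@probs)) {
        s <- inferSegments(ps@probs[[ind]], ps@map, threshold)
        if (nrow(s$segments))
            segs[[ind]] <- cbind(individual = ind, chromosome = cc,
                                 s$segments, stringsAsFactors = FALSE)
        nbp[ind] <- s$nBreakpoints
    }
    list(segments = if (length(segs)) do.call(rbind, c(segs, make.row.names = FALSE))
                    else data.frame(),
         nBreakpoints = nbp)
}
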