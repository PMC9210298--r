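#' Construct a GeneticMap
#'
#' Builds a [GeneticMap-class] from parallel vectors of marker names,
#' chromosome labels and cM positions. Rows are sorted by (chromosome,
#' position) with input order preserved among ties; coincident positions are
#' then perturbed by successive increments of 1e-6 cM so ordering is strict.
#'
#' @param marker character vector of marker names (unique per chromosome)
#' @param chr chromosome labels (recycled if length 1)
#' @param pos numeric positions in cM
#' @param pseudo logical pseudomarker flags (default all `FALSE`)
#' @return a [GeneticMap-class]
#' @examples
#' gmap <- GeneticMap(c("m1", "m2", "m3"), "1", c(0, 5, 5))
#' positions(gmap)  # tie at 5 cM perturbed to 5 and 5.000001
#' @export
GeneticMap <- function(marker, chr = "1", pos, pseudo = NULL) {
    if (length(chr) == 1L) chr <- rep(chr, length(marker))
    if (is.null(pseudo)) pseudo <- rep(FALSE, length(marker))
    stopifnot(length(marker) == length(pos), length(chr) == length(marker),
              length(pseudo) == length(marker))
    if (anyNA(pos)) stop("marker positions must not be missing")
    chr <- as.character(chr)
    o <- order(factor(chr, levels = unique(chr)), pos)
    marker <- as.character(marker)[o]; chr <- chr[o]
    pos <- as.numeric(pos)[o]; pseudo <- as.logical(pseudo)[o]
    # perturb exact ties in input order so intervals have r >= 0 deterministically
    for (cc in unique(chr)) {
        idx <- which(chr == cc)
        p <- pos[idx]
        if (length(p) > 1L) {
            for (i in seq_along(p)[-1L])
                if (p[i] <= p[i - 1L]) p[i] <- p[i - 1L] + 1e-6
            pos[idx] <- p
        }
    }
    new("GeneticMap", marker = marker, chr = chr, pos = pos, pseudo = pseudo)
}

#' @describeIn GeneticMap marker names
#' @param x,object a `GeneticMap`
#' @export
markers <- function(x) x@marker

#' @describeIn GeneticMap positions in cM
#' @export
positions <- function(x) x@pos

#' @describeIn GeneticMap chromosome label per marker
#' @export
chromosomes <- function(x) x@chr

#' @describeIn GeneticMap pseudomarker flags
#' @export
isPseudomarker <- function(x) x@pseudo

#' @describeIn GeneticMap number of marker positions
#' @export
nMarkers <- function(x) length(x@marker)

#' @rdname GeneticMap
#' @export
setMethod("show", "GeneticMap", function(object) {
    cat("GeneticMap with", length(object@marker), "positions on",
        length(unique(object@chr)), "chromosome(s);",
        sum(object@pseudo), "pseudomarkers\n")
    for (cc in unique(object@chr)) {
        idx <- object@chr == cc
        cat(sprintf("  chr %s: %d markers, %.2f-%.2f cM\n", cc, sum(idx),
                    min(object@pos[idx]), max(object@pos[idx])))
    }
})

#' Subset a map to one chromosome
#'
#' @param x a [GeneticMap-class]
#' @param chr chromosome label
#' @return a `GeneticMap` restricted to `chr`
#' @export
subsetChromosome <- function(x, chr) {
    idx <- x@chr == chr
    if (!any(idx)) stop("no markers on chromosome ", chr)
    new("GeneticMap", marker = x@marker[idx], chr = x@chr[idx],
        pos = x@pos[idx], pseudo = x@pseudo[idx])
}

#' Insert pseudomarkers onto a cM grid
#'
#' Adds pseudomarker positions on a grid with spacing `step`, anchored at the
#' first marker of each chromosome, so that no inter-position gap exceeds
#' `step`. Existing markers are kept; grid points within 1e-6 cM of an
#' existing marker are skipped. Pseudomarkers are named `c{chr}.loc{pos}`.
#'
#' @param map a [GeneticMap-class]
#' @param step grid spacing in cM (> 0)
#' @return a `GeneticMap` including the pseudomarkers
#' @examples
#' gmap <- GeneticMap(c("m1", "m2"), "1", c(0, 10))
#' nMarkers(insertPseudomarkers(gmap, step = 5))  # one grid point at 5 cM
#' @export
insertPseudomarkers <- function(map, step) {
    if (!is.numeric(step) || length(step) != 1L || step <= 0)
        stop("step must be a single positive number of cM")
    out <- list()
    for (cc in unique(map@chr)) {
        idx <- map@chr == cc
        p <- map@pos[idx]
        grid <- if (max(p) > min(p)) seq(min(p), max(p), by = step) else min(p)
        grid <- grid[vapply(grid, function(g) min(abs(g - p)) > 1e-6, logical(1))]
        out[[cc]] <- data.frame(
            marker = c(map@marker[idx],
                       if (length(grid)) sprintf("c%s.loc%s", cc, format(grid, trim = TRUE))
                       else character(0)),
            chr = cc,
            pos = c(p, grid),
            pseudo = c(map@pseudo[idx], rep(TRUE, length(grid))),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, out)
    GeneticMap(out$marker, out$chr, out$pos, out$pseudo)
}

#' Inter-marker recombination fractions
#'
#' Converts adjacent-position cM distances to recombination fractions under
#' the chosen map function, per chromosome.
#'
#' @param map a [GeneticMap-class]
#' @param mapFunction one of `"haldane"`, `"kosambi"`, `"carter_falconer"`
#' @return named list (per chromosome) of numeric vectors of length M-1
#' @export
mapRecFracs <- function(map, mapFunction = c("carter_falconer", "haldane", "kosambi")) {
    mapFunction <- match.arg(mapFunction)
    res <- list()
    for (cc in unique(map@chr)) {
        p <- map@pos[map@chr == cc]
        res[[cc]] <- if (length(p) > 1L)
            mapDistanceToRecFrac(diff(p), mapFunction) else numeric(0)
    }
    res
}
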