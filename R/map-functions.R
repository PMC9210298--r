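#' Convert genetic distance to recombination fraction
#'
#' Maps a distance in cM to a recombination fraction under the Haldane
#' (no interference), Kosambi, or Carter-Falconer map function. All three
#' agree to first order (r ~ d/100) at small distances and approach 0.5 as
#' d grows. The Carter-Falconer function has a closed form only in the
#' r -> d direction, so this direction is computed by bracketed
#' root-finding to 1e-12.
#'
#' @param d genetic distance(s) in cM, >= 0
#' @param mapFunction one of `"haldane"`, `"kosambi"`, `"carter_falconer"`
#' @return recombination fraction(s) in [0, 0.5)
#' @examples
#' mapDistanceToRecFrac(100, "haldane")  # (1 - exp(-2))/2 = 0.4323324
#' @export
mapDistanceToRecFrac <- function(d, mapFunction = c("haldane", "kosambi",
                                                    "carter_falconer")) {
    mapFunction <- match.arg(mapFunction)
    if (any(d < 0)) stop("genetic distance must be non-negative")
    switch(mapFunction,
           haldane = 0.5 * (1 - exp(-2 * d / 100)),
           kosambi = 0.5 * tanh(2 * d / 100),
           carter_falconer = vapply(d, .cf_d2r, numeric(1)))
}

# Carter-Falconer cM as a function of r (the closed-form direction)
.cf_r2d <- function(r) 12.5 * (log(1 + 2 * r) - log(1 - 2 * r)) + 25 * atan(2 * r)

.cf_d2r <- function(d) {
    if (d == 0) return(0)
    upper <- 0.5 - 1e-14
    if (.cf_r2d(upper) <= d) return(0.5 - 1e-14)
    stats::uniroot(function(r) .cf_r2d(r) - d, c(0, upper),
                   tol = 1e-12)$root
}

#' Convert recombination fraction to genetic distance
#'
#' Inverse of [mapDistanceToRecFrac()] on its range.
#'
#' @param r recombination fraction(s) in [0, 0.5)
#' @param mapFunction one of `"haldane"`, `"kosambi"`, `"carter_falconer"`
#' @return genetic distance(s) in cM
#' @export
recFracToMapDistance <- function(r, mapFunction = c("haldane", "kosambi",
                                                    "carter_falconer")) {
    mapFunction <- match.arg(mapFunction)
    if (any(r < 0) || any(r >= 0.5))
        stop("recombination fraction must be in [0, 0.5)")
    switch(mapFunction,
           haldane = -50 * log(1 - 2 * r),
           kosambi = 25 * (log(1 + 2 * r) - log(1 - 2 * r)),
           carter_falconer = .cf_r2d(r))
}
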