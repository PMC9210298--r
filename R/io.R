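#' Read a genotype matrix from CSV
#'
#' Expects a CSV whose first column holds marker names and whose remaining
#' columns hold one individual (or founder) each, with cells in the
#' declared allele coding (default `A/H/B/-` for 0/1/2/missing copies of
#' the coded B allele). Founder files are additionally validated as
#' non-heterozygous: an `H` in a founder file raises a warning and the
#' cell is set missing, since founders are inbred.
#'
#' @param path CSV file path
#' @param coding named numeric vector mapping codes to dosages; names are
#'   the codes, `NA` marks the missing code
#' @param founders validate as founder genotypes
#' @return numeric matrix markers x individuals with dosages 0/1/2/`NA`
#' @export
readGenotypes <- function(path, coding = c(A = 0, H = 1, B = 2, "-" = NA),
                          founders = FALSE) {
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop("genotype file needs a marker column plus individuals")
    mk <- df[[1L]]
    raw <- as.matrix(df[, -1L, drop = FALSE])
    bad <- matrix(!raw %in% names(coding), nrow(raw), ncol(raw))
    if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("unknown genotype code '%s' at marker %s, column %s in %s",
                     raw[bad][1L], mk[idx[1L]], colnames(raw)[idx[2L]], path))
    }
    g <- matrix(coding[raw], nrow(raw), ncol(raw),
                dimnames = list(mk, colnames(raw)))
    if (founders && any(g == 1, na.rm = TRUE)) {
        warning("heterozygous call(s) in founder file ", path,
                " set to missing (founders are inbred)", call. = FALSE)
        g[!is.na(g) & g == 1] <- NA
    }
    g
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [readGenotypes()]: dosages are mapped back to their codes.
#'
#' @param g numeric dosage matrix with marker rownames
#' @param path output CSV path
#' @param coding as in [readGenotypes()]
#' @export
writeGenotypes <- function(g, path, coding = c(A = 0, H = 1, B = 2, "-" = NA)) {
    rev <- names(coding)[match(g, coding)]
    rev[is.na(g)] <- names(coding)[is.na(coding)][1L]
    out <- matrix(rev, nrow(g), ncol(g), dimnames = dimnames(g))
    df <- data.frame(marker = rownames(g), out, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a genetic map from CSV
#'
#' Expects columns `marker,chr,pos` with positions in cM; rows are sorted
#' by (chr, pos) on construction.
#'
#' @param path CSV file path
#' @return a [GeneticMap-class]
#' @export
readGeneticMap <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    need <- c("marker", "chr", "pos")
    if (!all(need %in% names(df)))
        stop("map file must have columns marker, chr, pos")
    GeneticMap(df$marker, df$chr, df$pos)
}

#' Write a genetic map to CSV
#'
#' @param map a [GeneticMap-class] (pseudomarkers are omitted)
#' @param path output CSV path
#' @export
writeGeneticMap <- function(map, path) {
    keep <- !isPseudomarker(map)
    utils::write.csv(data.frame(marker = markers(map)[keep],
                                chr = chromosomes(map)[keep],
                                pos = positions(map)[keep]),
                     path, row.names = FALSE, quote = FALSE)
}

#' Read a control file
#'
#' Reads a YAML control file bundling the input paths and the cross
#' description. Required keys: `founder_file`, `offspring_file`,
#' `map_file`, `n_founders`, `n_generations`, `phase`. Optional keys with
#' defaults: `founder_proportions` (equal), `error_rate` (0.002),
#' `map_function` (`carter_falconer`), `genotype_codes`
#' (`{A: 0, H: 1, B: 2, "-": .na}`), `x_chr`, `sex_file`, `funnel`. File
#' paths are resolved relative to the control file's directory.
#'
#' @param path YAML control file
#' @return validated named list of configuration values
#' @export
readControl <- function(path) {
    ctl <- yaml::read_yaml(path)
    need <- c("founder_file", "offspring_file", "map_file",
              "n_founders", "n_generations", "phase")
    miss <- setdiff(need, names(ctl))
    if (length(miss))
        stop("control file missing required key(s): ", paste(miss, collapse = ", "))
    base <- dirname(normalizePath(path))
    for (key in c("founder_file", "offspring_file", "map_file", "sex_file")) {
        if (is.null(ctl[[key]])) next
        p <- ctl[[key]]
        if (!file.exists(p)) p <- file.path(base, ctl[[key]])
        if (!file.exists(p)) stop("file referenced by ", key, " not found: ", ctl[[key]])
        ctl[[key]] <- p
    }
    k <- as.integer(ctl$n_founders)
    if (is.null(ctl$founder_proportions)) ctl$founder_proportions <- rep(1 / k, k)
    a <- as.numeric(ctl$founder_proportions)
    if (length(a) != k) stop("founder_proportions must have length n_founders")
    if (abs(sum(a) - 1) > 1e-8) stop("founder_proportions must sum to 1")
    ctl$founder_proportions <- a
    if (!ctl$phase %in% c("homozygous", "heterozygous", "haploid"))
        stop("phase must be homozygous, heterozygous or haploid")
    if (is.null(ctl$error_rate)) ctl$error_rate <- 0.002
    if (ctl$error_rate < 0 || ctl$error_rate >= 0.5)
        stop("error_rate must be in [0, 0.5)")
    if (is.null(ctl$map_function)) ctl$map_function <- "carter_falconer"
    if (is.null(ctl$genotype_codes))
        ctl$genotype_codes <- c(A = 0, H = 1, B = 2, "-" = NA)
    else {
        gc <- ctl$genotype_codes
        ctl$genotype_codes <- stats::setNames(
            vapply(gc, function(x) if (is.null(x) || is.na(x)) NA_real_
                   else as.numeric(x), numeric(1)), names(gc))
    }
    if (!is.null(ctl$funnel)) {
        f <- ctl$funnel
        if (is.character(f) && length(f) == 1L) f <- strsplit(f, "")[[1L]]
        if (length(f) != 8L || anyDuplicated(f))
            stop("funnel must list 8 distinct founder labels")
        ctl$funnel <- f
    }
    ctl
}

#' Write posterior probabilities in long format
#'
#' One row per (individual, position, state):
#' `individual,chromosome,position_cM,marker,state,prob`, grouped by
#' position with probabilities per group summing to 1.
#'
#' @param ps a [PosteriorSet-class]
#' @param path output CSV path
#' @export
writePosterior <- function(ps, path) {
    map <- ps@map
    cc <- unique(chromosomes(map))
    rows <- lapply(names(posteriors(ps)), function(ind) {
        p <- posteriors(ps)[[ind]]
        data.frame(individual = ind, chromosome = cc,
                   position_cM = rep(positions(map), each = ncol(p)),
                   marker = rep(markers(map), each = ncol(p)),
                   state = rep(colnames(p), nrow(p)),
                   prob = as.vector(t(p)), stringsAsFactors = FALSE)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
}

#' Read a long-format posterior file
#'
#' @param path CSV written by [writePosterior()]
#' @return data.frame with the columns of the long format
#' @export
readPosterior <- function(path) utils::read.csv(path, check.names = FALSE)

#' Write inferred segments to CSV
#'
#' @param segments data.frame from [segmentAll()] (`individual`,
#'   `chromosome`, `start_cM`, `end_cM`, `state`)
#' @param path output CSV path
#' @export
writeSegments <- function(segments, path) {
    utils::write.csv(segments, path, row.names = FALSE, quote = FALSE)
}
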