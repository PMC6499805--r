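#' Coefficient of variation in percent
#'
#' 100 * sd / mean, with the sample (n - 1) standard deviation by default.
#'
#' @param values numeric vector (>= 2 values, positive mean).
#' @param ddof delta degrees of freedom for the sd: 1 (sample, default)
#'   or 0 (population).
#' @export
coefficientOfVariation <- function(values, ddof = 1) {
    if (length(values) < 2) stop("need >= 2 values")
    m <- mean(values)
    if (m <= 0) stop("mean must be positive")
    s <- stats::sd(values)
    if (ddof == 0) s <- s * sqrt((length(values) - 1) / length(values))
    100 * s / m
}

#' Non-genetic variability fraction
#'
#' The share of between-experiment variability attributable to non-genetic
#' influences: 100 * intra-line CV / inter-line CV, rounded to one decimal
#' for reporting. With the study's printed values, 100 * 70.67 / 86.7 =
#' 81.5%.
#'
#' @param cv_intraline,cv_interline CVs in percent; `cv_interline` > 0.
#' @export
nongeneticFraction <- function(cv_intraline, cv_interline) {
    if (cv_interline <= 0) stop("inter-line CV must be positive")
    round(100 * cv_intraline / cv_interline, 1)
}

#' Inter- versus intra-line CV report for membrane counts
#'
#' The inter-line CV is computed over ALL experiments pooled (every
#' experiment from every line in one vector); the intra-line CV is the
#' focal line's CV over its repeat experiments. The non-genetic fraction is
#' their ratio in percent, flagged (never clipped) when it exceeds 100%.
#'
#' @param table data.frame with columns `line`, `experiment`, `count`
#'   (e.g. from [simulateMembraneCounts()]).
#' @param focal_line line id with >= 2 experiments.
#' @return a [CVReport-class].
#' @export
cvReport <- function(table, focal_line) {
    stopifnot(all(c("line", "experiment", "count") %in% colnames(table)))
    counts <- table$count
    focal <- counts[table$line == focal_line]
    if (length(focal) < 2)
        stop("focal line must have >= 2 experiments")
    per <- do.call(rbind, lapply(split(table$count, table$line), function(v)
        data.frame(cv = if (length(v) >= 2) coefficientOfVariation(v) else NA,
                   n = length(v))))
    inter <- coefficientOfVariation(counts)
    intra <- coefficientOfVariation(focal)
    frac <- nongeneticFraction(intra, inter)
    methods::new("CVReport",
                 perLine = S4Vectors::DataFrame(per),
                 interline = inter, interlineN = length(counts),
                 focalLine = as.character(focal_line), intraline = intra,
                 intralineN = length(focal), nongeneticFraction = frac,
                 flagged = frac > 100)
}
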