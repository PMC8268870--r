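## Second-hit (loss of wild-type allele) scoring from VAF and tumor cell
## content. The score is the observed variant allele fraction divided by the
## pathologist's tumor-cell-content estimate: a heterozygous somatic variant
## with both alleles retained sits at exactly 0.5, loss of the wild-type
## allele pushes the ratio up (germline heterozygotes with loss exceed 1).
## The printed clinical tables only show the resulting scores; the ratio form
## is a reconstruction that reproduces the published heterozygous expectation
## and separates every published green score (>= 0.72) from every red one
## (<= 0.66) at a single threshold, defaulting to 0.7.

#' Expected heterozygous VAF at a given tumor cell content
#'
#' For a heterozygous somatic variant with no allele loss, the variant allele
#' frequency expected in a bulk sample is half the tumor cell fraction: at
#' 60\% tumor cells the VAF should be around 30\%.
#'
#' @param purity tumor cell content as a fraction in (0, 1].
#' @return \code{purity / 2}, vectorized.
#' @examples
#' expectedHetVaf(0.60)   # 0.30
#' @export
expectedHetVaf <- function(purity) {
    if (any(is.na(purity)) || any(purity <= 0 | purity > 1))
        stop("purity must lie in (0, 1]", call. = FALSE)
    purity / 2
}

#' Second-hit score: VAF standardized by tumor cell content
#'
#' \code{vaf / purity}: the fraction of tumor cells that would carry the
#' variant if it were somatic and heterozygous. 0.5 is the no-loss
#' heterozygous baseline; values approaching or exceeding 1 indicate loss of
#' the wild-type allele (a germline heterozygote with loss in a sample of
#' purity p has VAF 1/(2-p), i.e. score 1/(p(2-p)) > 1).
#'
#' @param vaf observed variant allele frequency in [0, 1].
#' @param purity tumor cell content in (0, 1]. Values > 1 are interpreted as
#'   percentages and divided by 100, with a warning.
#' @return Nonnegative score, vectorized.
#' @examples
#' secondHitScore(0.30, 0.60)   # heterozygous baseline, 0.5
#' @export
secondHitScore <- function(vaf, purity) {
    if (any(is.na(vaf)) || any(vaf < 0 | vaf > 1))
        stop("vaf must lie in [0, 1]", call. = FALSE)
    if (any(is.na(purity)) || any(purity <= 0))
        stop("purity must be strictly positive", call. = FALSE)
    pct <- purity > 1
    if (any(pct)) {
        warning("purity > 1 interpreted as a percentage")
        purity[pct] <- purity[pct] / 100
    }
    if (any(purity > 1))
        stop("purity must lie in (0, 1]", call. = FALSE)
    vaf / purity
}

#' Call loss of the wild-type allele from a second-hit score
#'
#' Scores at or above the threshold fall in the green zone of the LOH lookup
#' table (putative loss of the wild-type allele, call D); scores below are
#' red (call B); a missing score is U. The default threshold 0.7 sits in the
#' gap between the largest published red score (0.66) and the smallest
#' published green one (0.72).
#'
#' @param score nonnegative second-hit score(s); NA for missing.
#' @param threshold positive green/red boundary, ties resolved upward (score
#'   equal to the threshold is D).
#' @return Character vector over \code{"B"}, \code{"D"}, \code{"U"}.
#' @examples
#' secondHitCall(c(1.12, 0.19, NA))   # "D" "B" "U"
#' @export
secondHitCall <- function(score, threshold = 0.7) {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
        stop("threshold must be a positive number", call. = FALSE)
    if (any(score < 0, na.rm = TRUE))
        stop("score must be nonnegative", call. = FALSE)
    ifelse(is.na(score), "U", ifelse(score >= threshold, "D", "B"))
}

#' The LOH determination table over purity and VAF
#'
#' Renders the lookup grid relating tumor cell content (rows) and variant
#' allele frequency (columns) to the second-hit score, with each cell
#' colored green (putative loss of the wild-type allele) or red. Cells whose
#' score exceeds 2 are additionally flagged implausible: no diploid model
#' can put more than two variant alleles per tumor cell, so such VAF/purity
#' combinations indicate an inconsistent purity estimate.
#'
#' @param purityStep,vafStep grid steps in percent; must divide 100. The
#'   purity grid runs from one step to 100\%, the VAF grid from 0 to 100\%.
#' @param threshold green/red boundary passed to [secondHitCall()].
#' @return A \linkS4class{SecondHitGrid}.
#' @examples
#' g <- secondHitGrid()
#' g@score["60", "30"]   # 0.5, red: heterozygous expectation
#' @export
secondHitGrid <- function(purityStep = 5, vafStep = 5, threshold = 0.7) {
    for (s in c(purityStep, vafStep))
        if (!is.numeric(s) || length(s) != 1L || s <= 0 || 100 %% s != 0)
            stop("grid steps must be positive divisors of 100",
                 call. = FALSE)
    purityPct <- seq(purityStep, 100, by = purityStep)
    vafPct <- seq(0, 100, by = vafStep)
    purity <- purityPct / 100
    vaf <- vafPct / 100
    score <- outer(purity, vaf, function(p, v) v / p)
    dimnames(score) <- list(purityPct, vafPct)
    zone <- ifelse(score >= threshold, "green", "red")
    methods::new("SecondHitGrid", purity = purity, vaf = vaf,
                 score = score, zone = zone,
                 implausible = score > 2, threshold = threshold)
}

setMethod("show", "SecondHitGrid", function(object) {
    cat("SecondHitGrid: ", length(object@purity), " purity x ",
        length(object@vaf), " VAF cells, threshold ", object@threshold,
        " (", sum(object@zone == "green"), " green, ",
        sum(object@zone == "red"), " red, ",
        sum(object@implausible), " implausible)\n", sep = "")
})

#' Export the LOH grid as a data.frame
#'
#' Long-format view of a \linkS4class{SecondHitGrid} (one row per cell),
#' convenient for TSV export; the CLI \code{loh-table} subcommand writes the
#' wide "score|zone" form.
#'
#' @param grid a \linkS4class{SecondHitGrid}.
#' @return data.frame with columns purity, vaf, score, zone, implausible.
#' @export
gridAsTable <- function(grid) {
    stopifnot(methods::is(grid, "SecondHitGrid"))
    data.frame(purity = rep(grid@purity, times = length(grid@vaf)),
               vaf = rep(grid@vaf, each = length(grid@purity)),
               score = as.vector(grid@score),
               zone = as.vector(grid@zone),
               implausible = as.vector(grid@implausible),
               stringsAsFactors = FALSE)
}
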