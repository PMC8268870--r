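#' Load a packaged clinical fixture cohort
#'
#' The package ships, as plain TSV under \code{inst/extdata}, verbatim
#' transcriptions of the published study tables this tool was built around:
#' \describe{
#'   \item{table2}{41 olaparib-treated metastatic patients with the variants
#'     observed in their tumors (23 ovary, 8 breast, 8 digestive tract,
#'     1 endometrium, 1 skin). Episodes annotated "still under olaparib" and
#'     the day-1 allergic-reaction stop are censored
#'     (\code{pfs_event = FALSE}); one patient re-treated with olaparib
#'     appears as two episodes.}
#'   \item{table3}{the 12 VUS-carrying olaparib patients with second-hit
#'     scores, DANN/PROVEAN calls, performance status and the published
#'     Final Prediction (carried in the extra column
#'     \code{reported_prediction}; "S or R" is transcribed verbatim).}
#'   \item{table5}{the 8 niraparib-treated ovarian-cancer patients with a VUS
#'     (10 variant rows) from the second cohort, with categorical second-hit
#'     calls and the published Final Prediction.}
#'   \item{table1}{aggregate clinical characteristics of the olaparib cohort;
#'     returned as a plain data.frame since it has no per-patient rows.}
#' }
#'
#' HGVS strings are carried exactly as printed (including spacing oddities
#' and one internally inconsistent nucleotide/protein pair); the single
#' unexplained "N" PROVEAN entry is stored verbatim and treated as U by the
#' classifier.
#'
#' @param name one of \code{"table1"}, \code{"table2"}, \code{"table3"},
#'   \code{"table5"}.
#' @return A \linkS4class{ParpCohort} (or a data.frame for
#'   \code{"table1"}).
#' @examples
#' loadFixture("table2")
#' @export
loadFixture <- function(name) {
    known <- c("table1", "table2", "table3", "table5")
    if (length(name) != 1L || !name %in% known)
        stop("unknown fixture '", paste(name, collapse = ","),
             "'; available: ", paste(known, collapse = ", "),
             call. = FALSE)
    ext <- function(f) {
        p <- system.file("extdata", f, package = "parpvus")
        if (!nzchar(p)) stop("packaged fixture missing: ", f, call. = FALSE)
        p
    }
    if (name == "table1")
        return(utils::read.delim(ext("table1_characteristics.tsv"),
                                 sep = "\t", quote = "", check.names = FALSE,
                                 stringsAsFactors = FALSE))
    readCohort(ext(paste0(name, "_patients.tsv")),
               ext(paste0(name, "_variants.tsv")),
               label = name)
}
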