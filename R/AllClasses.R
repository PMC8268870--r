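## Central S4 containers: a clinical cohort (patients + observed variants),
## one treatment episode, per-patient classification results, the LOH lookup
## grid, Kaplan-Meier curves and log-rank results, and the simulator config.

VARIANT_CLASSES <- c("benign", "probably_benign", "unknown", "pathogenic")
CANCER_SITES    <- c("ovary", "breast", "digestive_tract", "endometrium",
                     "skin", "other")
TREATMENTS      <- c("olaparib", "niraparib", "none")
PLATINUM_LEVELS <- c("CR", "PR", "SD", "PD", "none", "missing")
## "N" appears verbatim in one published prediction table with no legend entry;
## it is carried through and interpreted as U wherever a call is consumed.
CALL_LEVELS     <- c("B", "D", "U", "N")

PATIENT_COLUMNS <- c("patient_id", "site", "histology", "ps", "treatment",
                     "platinum_response", "pfs_days", "pfs_event")
VARIANT_COLUMNS <- c("patient_id", "gene", "cdna", "protein", "known_class",
                     "vaf", "purity", "provean_score", "provean_call",
                     "dann_score", "dann_call", "second_hit_score",
                     "second_hit_call")

## Row-addressed validation used both by class validity and by readCohort().
.checkPatients <- function(df) {
    msgs <- character(0)
    miss <- setdiff(PATIENT_COLUMNS, names(df))
    if (length(miss))
        return(sprintf("patients table: missing mandatory column '%s'", miss))
    bad <- function(i, what)
        sprintf("patients row %d (%s): %s", i, df$patient_id[i], what)
    for (i in seq_len(nrow(df))) {
        if (is.na(df$patient_id[i]) || !nzchar(df$patient_id[i]))
            msgs <- c(msgs, sprintf("patients row %d: empty patient_id", i))
        if (!df$site[i] %in% CANCER_SITES)
            msgs <- c(msgs, bad(i, sprintf("unknown site '%s'", df$site[i])))
        if (!is.na(df$ps[i]) && !(df$ps[i] %in% 0:4))
            msgs <- c(msgs, bad(i, "performance status must be in 0..4"))
        if (!df$treatment[i] %in% TREATMENTS)
            msgs <- c(msgs, bad(i, sprintf("unknown treatment '%s'",
                                           df$treatment[i])))
        if (!df$platinum_response[i] %in% PLATINUM_LEVELS)
            msgs <- c(msgs, bad(i, "unparseable platinum_response"))
        if (is.na(df$pfs_days[i]) || df$pfs_days[i] < 1)
            msgs <- c(msgs, bad(i, "pfs_days must be a positive integer"))
        if (is.na(df$pfs_event[i]))
            msgs <- c(msgs, bad(i, "pfs_event must be TRUE/FALSE"))
    }
    msgs
}

.checkVariants <- function(df, patient_ids = NULL) {
    msgs <- character(0)
    miss <- setdiff(VARIANT_COLUMNS, names(df))
    if (length(miss))
        return(sprintf("variants table: missing mandatory column '%s'", miss))
    bad <- function(i, what)
        sprintf("variants row %d (%s %s): %s", i, df$patient_id[i],
                df$gene[i], what)
    in01 <- function(x) is.na(x) | (x >= 0 & x <= 1)
    for (i in seq_len(nrow(df))) {
        if (!df$known_class[i] %in% VARIANT_CLASSES)
            msgs <- c(msgs, bad(i, sprintf("unknown known_class '%s'",
                                           df$known_class[i])))
        if (!in01(df$vaf[i]))
            msgs <- c(msgs, bad(i, "vaf must be in [0,1]"))
        if (!is.na(df$purity[i]) && (df$purity[i] <= 0 || df$purity[i] > 1))
            msgs <- c(msgs, bad(i, "purity must be in (0,1]"))
        if (!in01(df$dann_score[i]))
            msgs <- c(msgs, bad(i, "dann_score must be in [0,1]"))
        if (!is.na(df$second_hit_score[i]) && df$second_hit_score[i] < 0)
            msgs <- c(msgs, bad(i, "second_hit_score must be nonnegative"))
        for (cc in c("provean_call", "dann_call", "second_hit_call"))
            if (!is.na(df[[cc]][i]) && !df[[cc]][i] %in% CALL_LEVELS)
                msgs <- c(msgs, bad(i, sprintf("%s must be one of B/D/U", cc)))
        if (!is.null(patient_ids) && !df$patient_id[i] %in% patient_ids)
            msgs <- c(msgs, bad(i, "patient_id not present in patients table"))
    }
    msgs
}

#' ParpCohort: a clinical cohort with its observed variants
#'
#' Container for one cohort of treatment episodes. The \code{patients} slot
#' holds one row per episode (id, cancer site, ECOG performance status,
#' treatment, platinum response, progression-free survival in days and the
#' progression/death event flag); the \code{variants} slot holds one row per
#' observed variant in a homologous-recombination gene (HGVS strings verbatim,
#' known pathogenicity class, VAF, tumor cell content, PROVEAN/DANN evidence
#' and, when available, the precomputed second-hit score and call). The same
#' patient may appear twice when re-treated; such episodes carry distinct ids.
#'
#' @slot patients data.frame, one row per treatment episode.
#' @slot variants data.frame, one row per variant, keyed by \code{patient_id}.
#' @slot label character scalar naming the cohort.
#' @seealso [readCohort()], [loadFixture()], [getCase()]
#' @export
setClass("ParpCohort",
    representation(patients = "data.frame", variants = "data.frame",
                   label = "character"),
    validity = function(object) {
        msgs <- c(.checkPatients(object@patients),
                  .checkVariants(object@variants,
                                 object@patients$patient_id))
        if (anyDuplicated(object@patients$patient_id))
            msgs <- c(msgs, "duplicated patient_id in patients table")
        if (length(msgs)) msgs else TRUE
    })

#' PatientCase: one treatment episode with its variants
#'
#' @slot patientId character id of the episode.
#' @slot site cancer site (ovary, breast, digestive_tract, endometrium, skin,
#'   other).
#' @slot histology free-text histology (may be empty).
#' @slot ps ECOG performance status 0--4, or NA when not recorded.
#' @slot treatment olaparib, niraparib or none.
#' @slot platinumResponse best response to platinum (CR/PR/SD/PD/none/missing).
#' @slot pfsDays progression-free survival in days (>= 1).
#' @slot pfsEvent TRUE if progression or death was observed, FALSE if censored.
#' @slot variants data.frame of this episode's variants (may be empty).
#' @export
setClass("PatientCase",
    representation(patientId = "character", site = "character",
                   histology = "character", ps = "integer",
                   treatment = "character", platinumResponse = "character",
                   pfsDays = "numeric", pfsEvent = "logical",
                   variants = "data.frame"))

#' SecondHitGrid: the LOH lookup table over purity and VAF
#'
#' A grid of second-hit scores (VAF / tumor cell content) over a purity x VAF
#' lattice, with each cell colored green (putative loss of the wild-type
#' allele, score >= threshold) or red, and flagged implausible where the score
#' exceeds 2 (impossible under any diploid model).
#'
#' @slot purity numeric vector of tumor-cell-content grid values (rows).
#' @slot vaf numeric vector of variant-allele-frequency grid values (columns).
#' @slot score numeric matrix of scores, \code{length(purity)} x
#'   \code{length(vaf)}.
#' @slot zone character matrix ("green"/"red") of the same shape.
#' @slot implausible logical matrix of the same shape.
#' @slot threshold numeric scalar used for the green/red split.
#' @export
setClass("SecondHitGrid",
    representation(purity = "numeric", vaf = "numeric", score = "matrix",
                   zone = "matrix", implausible = "matrix",
                   threshold = "numeric"),
    validity = function(object) {
        d <- c(length(object@purity), length(object@vaf))
        if (!identical(dim(object@score), d)) return("score has wrong shape")
        if (!identical(dim(object@zone), d))  return("zone has wrong shape")
        if (any(object@score < 0, na.rm = TRUE))
            return("negative score cell")
        TRUE
    })

#' ClassificationResult: the per-patient verdict and its evidence trace
#'
#' @slot patientId character id of the classified episode.
#' @slot perVariant data.frame with one row per variant and evidence model:
#'   columns gene, protein, model, class (deleterious/benign/unknown).
#' @slot perModel named character of per-model patient labels, "S" or "R",
#'   names "provean" and "dann".
#' @slot finalLabel "S" or "R" when both models agree, otherwise "U".
#' @slot psGated TRUE when the performance-status gate forced both models to R.
#' @slot rationale character vector of human-readable evidence strings.
#' @export
setClass("ClassificationResult",
    representation(patientId = "character", perVariant = "data.frame",
                   perModel = "character", finalLabel = "character",
                   psGated = "logical", rationale = "character"),
    validity = function(object) {
        pm <- object@perModel
        if (!identical(sort(names(pm)), c("dann", "provean")))
            return("perModel must be named provean/dann")
        if (!all(pm %in% c("S", "R")))
            return("per-model labels must be S or R")
        agree <- pm[["provean"]] == pm[["dann"]]
        if (agree && !identical(object@finalLabel, pm[["provean"]]))
            return("finalLabel must equal the agreed per-model label")
        if (!agree && !identical(object@finalLabel, "U"))
            return("finalLabel must be U when the models disagree")
        if (object@psGated && !all(pm == "R"))
            return("PS gate must force both per-model labels to R")
        TRUE
    })

#' KMCurve: a Kaplan-Meier product-limit curve
#'
#' @slot time numeric vector of distinct observed times (days), increasing.
#' @slot surv numeric survival probabilities S(t) at those times.
#' @slot nRisk integer numbers at risk just before each time.
#' @slot nEvent integer numbers of events at each time.
#' @slot censorTimes numeric times at which censoring occurred.
#' @slot median numeric median survival (smallest event time with
#'   S(t) <= 0.5), NA when the curve never reaches 0.5.
#' @slot n integer number of subjects.
#' @export
setClass("KMCurve",
    representation(time = "numeric", surv = "numeric", nRisk = "integer",
                   nEvent = "integer", censorTimes = "numeric",
                   median = "numeric", n = "integer"),
    validity = function(object) {
        if (length(object@surv) && any(diff(object@surv) > 1e-12))
            return("survival probabilities must be nonincreasing")
        if (any(object@surv < 0 | object@surv > 1))
            return("survival probabilities must lie in [0,1]")
        TRUE
    })

#' LogRankResult: a two-group Mantel-Cox comparison
#'
#' @slot chisq nonnegative chi-squared statistic.
#' @slot df integer degrees of freedom (groups - 1).
#' @slot pValue p-value from the chi-squared reference distribution.
#' @slot groups data.frame with columns label, n, events.
#' @export
setClass("LogRankResult",
    representation(chisq = "numeric", df = "integer", pValue = "numeric",
                   groups = "data.frame"))

#' SimConfig: parameters of the synthetic-cohort generator
#'
#' Defaults mirror the clinical cohort the classifier was developed on:
#' 41 episodes with class mix 3 benign / 12 VUS (split evenly into truly
#' deleterious and truly benign) / 26 pathogenic, pathologist purities between
#' 0.2 and 0.9, ~100x read depth, and progression-free-survival medians
#' ordered benign < deleterious (81 vs 190 days).
#'
#' @slot nPatients integer number of episodes to simulate.
#' @slot classMix named probabilities over benign, vus_benign,
#'   vus_deleterious, pathogenic.
#' @slot purityRange numeric length-2 interval in (0,1] for tumor cell content.
#' @slot readDepth integer sequencing depth for the binomial VAF noise model.
#' @slot germlineProb probability a variant is a germline heterozygote
#'   (otherwise somatic).
#' @slot lossProbDeleterious probability of wild-type-allele loss given the
#'   variant is truly deleterious (pathogenic or vus_deleterious).
#' @slot insilicoFlipProb probability each in-silico call contradicts the
#'   true class.
#' @slot psDistribution named probabilities over performance status 0..4.
#' @slot pfsMedianByClass named median PFS (days) per true class.
#' @slot psPfsFactor multiplier applied to the PFS median when PS >= 3.
#' @slot censorProb probability an episode is censored.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
    representation(nPatients = "integer", classMix = "numeric",
                   purityRange = "numeric", readDepth = "integer",
                   germlineProb = "numeric", lossProbDeleterious = "numeric",
                   insilicoFlipProb = "numeric", psDistribution = "numeric",
                   pfsMedianByClass = "numeric", psPfsFactor = "numeric",
                   censorProb = "numeric", seed = "integer"),
    validity = function(object) {
        msgs <- character(0)
        if (abs(sum(object@classMix) - 1) > 1e-8)
            msgs <- c(msgs, "classMix must sum to 1")
        if (!identical(sort(names(object@classMix)),
                       sort(c("benign", "vus_benign", "vus_deleterious",
                              "pathogenic"))))
            msgs <- c(msgs, "classMix must name the four true classes")
        if (abs(sum(object@psDistribution) - 1) > 1e-8)
            msgs <- c(msgs, "psDistribution must sum to 1")
        if (length(object@psDistribution) != 5)
            msgs <- c(msgs, "psDistribution must cover PS 0..4")
        if (object@readDepth < 1)
            msgs <- c(msgs, "readDepth must be >= 1")
        pr <- object@purityRange
        if (length(pr) != 2 || pr[1] <= 0 || pr[2] > 1 || pr[1] > pr[2])
            msgs <- c(msgs, "purityRange must be an interval within (0,1]")
        probs <- c(object@germlineProb, object@lossProbDeleterious,
                   object@insilicoFlipProb, object@censorProb)
        if (any(probs < 0 | probs > 1))
            msgs <- c(msgs, "probabilities must lie in [0,1]")
        if (length(msgs)) msgs else TRUE
    })
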