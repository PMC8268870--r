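## Kaplan-Meier estimation, two-group log-rank comparison and the 120-day
## benefit dichotomization used to validate the classifier. The estimation
## itself is delegated to the survival package; this module fixes the
## conventions (median = smallest event time with S <= 0.5, events precede
## censorings at tied days) and the result containers.

#' Kaplan-Meier product-limit fit
#'
#' @param times observation times in days (>= 1).
#' @param events logical (or 0/1) vector: TRUE when progression or death was
#'   observed, FALSE when censored.
#' @return A \linkS4class{KMCurve}. The median is the smallest event time at
#'   which the curve drops to 0.5 or below, NA when the curve never reaches
#'   0.5 (e.g. under heavy censoring).
#' @examples
#' kmMedian(kmFit(c(1, 2, 3, 4, 5), rep(TRUE, 5)))   # 3
#' @export
kmFit <- function(times, events) {
    if (!length(times))
        stop("empty survival input", call. = FALSE)
    if (length(times) != length(events))
        stop("times and events must have equal length", call. = FALSE)
    if (any(is.na(times)) || any(times < 1))
        stop("times must be >= 1", call. = FALSE)
    events <- as.logical(events)
    fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                             conf.type = "none")
    evt <- fit$n.event > 0
    med <- if (any(evt & fit$surv <= 0.5 + 1e-12))
        min(fit$time[evt & fit$surv <= 0.5 + 1e-12]) else NA_real_
    methods::new("KMCurve",
                 time = fit$time, surv = fit$surv,
                 nRisk = as.integer(fit$n.risk),
                 nEvent = as.integer(fit$n.event),
                 censorTimes = sort(times[!events]),
                 median = med, n = as.integer(fit$n))
}

#' @rdname parpvus-accessors
#' @export
setMethod("kmMedian", "KMCurve", function(object) object@median)

setMethod("show", "KMCurve", function(object) {
    cat("KMCurve: n=", object@n, ", events=", sum(object@nEvent),
        ", median=", ifelse(is.na(object@median), "not reached",
                            object@median), " days\n", sep = "")
})

#' Survival curve as a step table
#'
#' @param curve a \linkS4class{KMCurve}.
#' @return data.frame with columns time, surv, n_risk, n_event.
#' @export
curveAsTable <- function(curve) {
    stopifnot(methods::is(curve, "KMCurve"))
    data.frame(time = curve@time, surv = curve@surv,
               n_risk = curve@nRisk, n_event = curve@nEvent)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param timesA,eventsA times and event flags of the first group.
#' @param timesB,eventsB times and event flags of the second group.
#' @param labels length-2 character group labels.
#' @return A \linkS4class{LogRankResult} with the chi-squared statistic, its
#'   df = 1 p-value and per-group n/event counts. Symmetric under group
#'   swap.
#' @examples
#' r <- logrankTest(c(10, 12, 15), c(TRUE, TRUE, TRUE),
#'                  c(100, 120, 150), c(TRUE, TRUE, TRUE))
#' r@pValue
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB,
                        labels = c("A", "B")) {
    if (!length(timesA) || !length(timesB))
        stop("both groups must be nonempty", call. = FALSE)
    time <- c(timesA, timesB)
    event <- as.logical(c(eventsA, eventsB))
    group <- rep(labels, c(length(timesA), length(timesB)))
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
    df <- length(sd$n) - 1L
    methods::new("LogRankResult",
                 chisq = unname(sd$chisq), df = as.integer(df),
                 pValue = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 groups = data.frame(label = labels,
                                     n = as.vector(sd$n),
                                     events = as.vector(sd$obs)))
}

setMethod("show", "LogRankResult", function(object) {
    cat("Log-rank (Mantel-Cox): chisq=", signif(object@chisq, 4), ", df=",
        object@df, ", p=", signif(object@pValue, 4), "\n", sep = "")
})

#' 120-day treatment-benefit flag
#'
#' An episode is counted as having benefited from the PARP inhibitor when
#' its progression-free survival strictly exceeds the threshold (default
#' 120 days, the benefit boundary used to validate the classifier; a PFS of
#' exactly 120 days does not count).
#'
#' @param pfsDays positive PFS in days, vectorized.
#' @param thresholdDays benefit boundary in days.
#' @return Logical vector.
#' @examples
#' benefitFlag(c(120, 121, 368))   # FALSE TRUE TRUE
#' @export
benefitFlag <- function(pfsDays, thresholdDays = 120) {
    if (any(is.na(pfsDays)) || any(pfsDays < 1))
        stop("pfsDays must be >= 1", call. = FALSE)
    pfsDays > thresholdDays
}

#' Cross-tabulate predicted labels against the benefit flag
#'
#' The headline validation of the classifier: Resistant-labelled patients
#' should sit below the 120-day benefit boundary and Sensitive-labelled ones
#' above it.
#'
#' @param cohort a \linkS4class{ParpCohort}.
#' @param predictions data.frame as returned by [classifyCohort()]; every
#'   predicted episode must exist in the cohort.
#' @param thresholdDays benefit boundary in days.
#' @return A list with \code{cases} (per-episode data.frame: patient_id,
#'   final_label, pfs_days, benefit, concordant) and \code{counts} (the
#'   label-by-benefit contingency table). Concordance is defined for S and R
#'   labels only; U rows have NA.
#' @examples
#' coh <- loadFixture("table3")
#' concordanceReport(coh, classifyCohort(coh))$counts
#' @export
concordanceReport <- function(cohort, predictions, thresholdDays = 120) {
    stopifnot(methods::is(cohort, "ParpCohort"))
    pat <- patients(cohort)
    if (!nrow(predictions))
        return(list(cases = data.frame(patient_id = character(0),
                                       final_label = character(0),
                                       pfs_days = integer(0),
                                       benefit = logical(0),
                                       concordant = logical(0)),
                    counts = table(label = character(0),
                                   benefit = logical(0))))
    i <- match(predictions$patient_id, pat$patient_id)
    if (anyNA(i))
        stop("prediction for unknown patient: ",
             paste(predictions$patient_id[is.na(i)], collapse = ", "),
             call. = FALSE)
    benefit <- benefitFlag(pat$pfs_days[i], thresholdDays)
    concord <- ifelse(predictions$final_label == "S", benefit,
               ifelse(predictions$final_label == "R", !benefit, NA))
    cases <- data.frame(patient_id = predictions$patient_id,
                        final_label = predictions$final_label,
                        pfs_days = pat$pfs_days[i],
                        benefit = benefit, concordant = concord,
                        stringsAsFactors = FALSE)
    list(cases = cases,
         counts = table(label = predictions$final_label, benefit = benefit))
}
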