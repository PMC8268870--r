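## The core rule-based algorithm: per-variant deleteriousness under two
## evidence models (second hit + PROVEAN, second hit + DANN), any-variant
## aggregation to a patient label, a Performance-Status gate, the two-model
## consensus, and the treatment-decision tree.

EVIDENCE_MODELS <- c("provean", "dann")

.asVariantRow <- function(variant) {
    if (is.data.frame(variant)) {
        stopifnot(nrow(variant) == 1L)
        variant <- as.list(variant)
    }
    defaults <- list(gene = NA_character_, cdna = NA_character_,
                     protein = NA_character_, known_class = "unknown",
                     vaf = NA_real_, purity = NA_real_,
                     provean_score = NA_real_, provean_call = NA_character_,
                     dann_score = NA_real_, dann_call = NA_character_,
                     second_hit_score = NA_real_,
                     second_hit_call = NA_character_)
    defaults[names(variant)] <- variant
    defaults
}

## Resolve the three evidence channels of one variant to B/D/U calls.
.resolveEvidence <- function(v, secondHitThreshold = 0.7,
                             proveanCutoff = -2.5, dannCutoff = 0.96) {
    sh <- if (!is.na(v$second_hit_call)) {
        .normCall(v$second_hit_call)
    } else if (!is.na(v$second_hit_score)) {
        secondHitCall(v$second_hit_score, secondHitThreshold)
    } else if (!is.na(v$vaf) && !is.na(v$purity)) {
        secondHitCall(secondHitScore(v$vaf, v$purity), secondHitThreshold)
    } else "U"
    list(second_hit = sh,
         provean = callProvean(v$provean_score, v$provean_call,
                               proveanCutoff)$call,
         dann = callDann(v$dann_score, v$dann_call, dannCutoff)$call)
}

#' Classify one VUS under one evidence model
#'
#' A variant of unknown significance is deleterious under a model as soon as
#' either the second-hit call or the model's in-silico call is D; it is
#' benign when both resolved calls are B; otherwise (no D, at least one U) it
#' stays unknown. Unknown evidence therefore never argues for sensitivity.
#'
#' @param variant a one-row data.frame or named list following the variants
#'   schema (see \linkS4class{ParpCohort}); missing fields default to NA.
#'   Must have \code{known_class = "unknown"}.
#' @param model \code{"provean"} or \code{"dann"} - which in-silico tool the
#'   second-hit evidence is combined with.
#' @param secondHitThreshold green/red boundary for a score-derived
#'   second-hit call.
#' @param proveanCutoff,dannCutoff score cutoffs for score-derived in-silico
#'   calls (categorical columns take precedence).
#' @return One of \code{"deleterious"}, \code{"benign"}, \code{"unknown"}.
#' @examples
#' v <- list(gene = "BRCA1", protein = "p.Met18Thr", known_class = "unknown",
#'           second_hit_call = "B", provean_call = "D", dann_call = "D")
#' classifyVariant(v, "provean")   # "deleterious"
#' @export
classifyVariant <- function(variant, model = c("provean", "dann"),
                            secondHitThreshold = 0.7, proveanCutoff = -2.5,
                            dannCutoff = 0.96) {
    model <- match.arg(model)
    v <- .asVariantRow(variant)
    if (!identical(v$known_class, "unknown"))
        stop("classifyVariant applies to variants of unknown significance; ",
             "known_class is '", v$known_class, "'", call. = FALSE)
    ev <- .resolveEvidence(v, secondHitThreshold, proveanCutoff, dannCutoff)
    insilico <- ev[[model]]
    if (ev$second_hit == "D" || insilico == "D") "deleterious"
    else if (ev$second_hit == "B" && insilico == "B") "benign"
    else "unknown"
}

.vusRows <- function(case) {
    v <- variants(case)
    v[v$known_class == "unknown", , drop = FALSE]
}

#' Patient-level PARP-inhibitor sensitivity under one evidence model
#'
#' Aggregates a VUS-carrying episode to Sensitive/Resistant: patients at or
#' above the performance-status cutoff are Resistant regardless of molecular
#' evidence (in the development cohort every PS3 patient progressed before
#' 120 days); otherwise the patient is Sensitive as soon as any of their VUS
#' classifies deleterious under the model, else Resistant.
#'
#' @param case a \linkS4class{PatientCase} carrying at least one VUS.
#' @param model \code{"provean"} or \code{"dann"}.
#' @param psCutoff performance-status gate (default 3); \code{Inf} disables
#'   the gate. A missing PS is treated as below the cutoff.
#' @param ... passed to [classifyVariant()].
#' @return \code{"S"} or \code{"R"}.
#' @examples
#' classifyPatient(getCase(loadFixture("table3"), "Skin #1"), "provean")
#' @export
classifyPatient <- function(case, model = c("provean", "dann"),
                            psCutoff = 3, ...) {
    model <- match.arg(model)
    stopifnot(methods::is(case, "PatientCase"))
    vus <- .vusRows(case)
    if (!nrow(vus))
        stop("patient ", case@patientId, " carries no VUS; use ",
             "decisionTree() for known variant classes", call. = FALSE)
    if (!is.na(case@ps) && case@ps >= psCutoff)
        return("R")
    classes <- vapply(seq_len(nrow(vus)), function(i)
        classifyVariant(vus[i, , drop = FALSE], model, ...), character(1))
    if (any(classes == "deleterious")) "S" else "R"
}

#' Dual-model consensus classification of a VUS-carrying episode
#'
#' Runs the second-hit + PROVEAN and second-hit + DANN models and combines
#' them: when both patient-level labels agree that label is final; when they
#' disagree the final label is U (uncertain), mirroring the published
#' "S or R" calls. The returned object carries the per-variant verdicts, the
#' per-model labels, the PS-gate flag and a human-readable evidence trace.
#'
#' @inheritParams classifyPatient
#' @return A \linkS4class{ClassificationResult}.
#' @examples
#' classifyConsensus(getCase(loadFixture("table3"), "Ovarian #23"))
#' @export
classifyConsensus <- function(case, psCutoff = 3, ...) {
    stopifnot(methods::is(case, "PatientCase"))
    vus <- .vusRows(case)
    if (!nrow(vus))
        stop("patient ", case@patientId, " carries no VUS; use ",
             "decisionTree() for known variant classes", call. = FALSE)
    gated <- !is.na(case@ps) && case@ps >= psCutoff

    perVariant <- do.call(rbind, lapply(EVIDENCE_MODELS, function(m) {
        data.frame(gene = vus$gene, protein = vus$protein, model = m,
                   class = vapply(seq_len(nrow(vus)), function(i)
                       classifyVariant(vus[i, , drop = FALSE], m, ...),
                       character(1)),
                   stringsAsFactors = FALSE)
    }))
    perModel <- vapply(EVIDENCE_MODELS, function(m)
        classifyPatient(case, m, psCutoff = psCutoff, ...), character(1))
    final <- if (perModel[["provean"]] == perModel[["dann"]])
        perModel[["provean"]] else "U"

    rationale <- character(0)
    for (i in seq_len(nrow(vus))) {
        ev <- .resolveEvidence(.asVariantRow(vus[i, , drop = FALSE]), ...)
        rationale <- c(rationale, sprintf(
            "%s %s: second-hit=%s, PROVEAN=%s, DANN=%s -> %s (provean) / %s (dann)",
            vus$gene[i], vus$protein[i], ev$second_hit, ev$provean, ev$dann,
            perVariant$class[perVariant$model == "provean"][i],
            perVariant$class[perVariant$model == "dann"][i]))
    }
    if (gated)
        rationale <- c(rationale, sprintf(
            "performance status %d >= %s: gate forces Resistant in both models",
            case@ps, format(psCutoff)))
    rationale <- c(rationale, sprintf(
        "per-model labels provean=%s, dann=%s -> final %s",
        perModel[["provean"]], perModel[["dann"]], final))

    methods::new("ClassificationResult", patientId = case@patientId,
                 perVariant = perVariant, perModel = perModel,
                 finalLabel = final, psGated = gated, rationale = rationale)
}

#' Classify every VUS-carrying episode of a cohort
#'
#' @param cohort a \linkS4class{ParpCohort}.
#' @param psCutoff,... passed to [classifyConsensus()].
#' @return data.frame with one row per episode carrying at least one VUS:
#'   patient_id, provean_label, dann_label, final_label, ps_gated, pfs_days,
#'   pfs_event.
#' @examples
#' classifyCohort(loadFixture("table3"))
#' @export
classifyCohort <- function(cohort, psCutoff = 3, ...) {
    stopifnot(methods::is(cohort, "ParpCohort"))
    pat <- patients(cohort)
    v <- variants(cohort)
    ids <- pat$patient_id[pat$patient_id %in%
                          v$patient_id[v$known_class == "unknown"]]
    rows <- lapply(ids, function(id) {
        res <- classifyConsensus(getCase(cohort, id), psCutoff = psCutoff,
                                 ...)
        i <- match(id, pat$patient_id)
        data.frame(patient_id = id,
                   provean_label = perModelLabels(res)[["provean"]],
                   dann_label = perModelLabels(res)[["dann"]],
                   final_label = finalLabel(res),
                   ps_gated = res@psGated,
                   pfs_days = pat$pfs_days[i],
                   pfs_event = pat$pfs_event[i],
                   stringsAsFactors = FALSE)
    })
    if (!length(rows))
        return(data.frame(patient_id = character(0),
                          provean_label = character(0),
                          dann_label = character(0),
                          final_label = character(0),
                          ps_gated = logical(0), pfs_days = integer(0),
                          pfs_event = logical(0)))
    do.call(rbind, rows)
}

#' Treatment-decision tree for an episode
#'
#' The proposed decision flow for HR-gene variants: a known pathogenic
#' variant indicates PARP-inhibitor sensitivity; only benign (or no)
#' variants indicate no HRD-mediated response to expect; a VUS is routed
#' through the dual-model consensus (S maps to sensitive, R to no expected
#' response, U stays uncertain).
#'
#' @param case a \linkS4class{PatientCase}.
#' @param psCutoff,... passed to the VUS consensus branch.
#' @param gateKnownPathogenic apply the PS gate to known-pathogenic routing
#'   too (default FALSE: the gate belongs to the VUS algorithm only).
#' @return One of \code{"treat_parpi_sensitive"}, \code{"treat_uncertain"},
#'   \code{"do_not_expect_hrd_response"}.
#' @examples
#' decisionTree(getCase(loadFixture("table2"), "Ovarian #1"))
#' @export
decisionTree <- function(case, psCutoff = 3, gateKnownPathogenic = FALSE,
                         ...) {
    stopifnot(methods::is(case, "PatientCase"))
    v <- variants(case)
    if (nrow(v) && "pathogenic" %in% v$known_class) {
        if (gateKnownPathogenic && !is.na(case@ps) && case@ps >= psCutoff)
            return("do_not_expect_hrd_response")
        return("treat_parpi_sensitive")
    }
    if (!nrow(v) || !"unknown" %in% v$known_class)
        return("do_not_expect_hrd_response")
    switch(finalLabel(classifyConsensus(case, psCutoff = psCutoff, ...)),
           S = "treat_parpi_sensitive",
           R = "do_not_expect_hrd_response",
           U = "treat_uncertain")
}

## ---- accessors and show ----

#' @rdname parpvus-accessors
#' @export
setMethod("finalLabel", "ClassificationResult",
          function(object) object@finalLabel)

#' @rdname parpvus-accessors
#' @export
setMethod("perModelLabels", "ClassificationResult",
          function(object) object@perModel)

#' @rdname parpvus-accessors
#' @export
setMethod("rationale", "ClassificationResult",
          function(object) object@rationale)

setMethod("show", "ClassificationResult", function(object) {
    cat("ClassificationResult ", object@patientId, ": final ",
        object@finalLabel, " (provean=", object@perModel[["provean"]],
        ", dann=", object@perModel[["dann"]],
        if (object@psGated) ", PS-gated", ")\n", sep = "")
    for (r in object@rationale) cat("  - ", r, "\n", sep = "")
})
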