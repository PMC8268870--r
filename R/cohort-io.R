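## Reading/writing cohort tables (TSV schema documented in the README) and
## the optional VCF ingestion path for variant allele fractions.

.PATIENT_COLCLASSES <- c(patient_id = "character", site = "character",
                         histology = "character", ps = "integer",
                         treatment = "character",
                         platinum_response = "character",
                         pfs_days = "integer", pfs_event = "logical")
.VARIANT_COLCLASSES <- c(patient_id = "character", gene = "character",
                         cdna = "character", protein = "character",
                         known_class = "character", vaf = "numeric",
                         purity = "numeric", provean_score = "numeric",
                         provean_call = "character", dann_score = "numeric",
                         dann_call = "character",
                         second_hit_score = "numeric",
                         second_hit_call = "character")

.readTsv <- function(path, colclasses) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    ## CLI-written files carry leading "# parpvus" header lines; field values
    ## may contain '#' (patient ids), so only leading lines are skipped.
    head <- readLines(path, n = 10L)
    skip <- 0L
    while (skip < length(head) && startsWith(head[skip + 1L], "#"))
        skip <- skip + 1L
    header <- strsplit(head[skip + 1L], "\t", fixed = TRUE)[[1]]
    ## typed columns are read as character and coerced below, so that empty
    ## strings survive and parse failures get addressable messages
    cc <- ifelse(header %in% names(colclasses), "character", NA)
    df <- utils::read.delim(path, sep = "\t", header = TRUE, skip = skip,
                            na.strings = "NA", quote = "",
                            comment.char = "", check.names = FALSE,
                            colClasses = cc, stringsAsFactors = FALSE)
    for (cn in intersect(names(colclasses), names(df))) {
        raw <- df[[cn]]
        blank <- is.na(raw) | raw == ""
        df[[cn]] <- switch(colclasses[[cn]],
            character = ifelse(is.na(raw), NA_character_, raw),
            integer   = {
                v <- suppressWarnings(as.integer(raw))
                if (any(is.na(v) & !blank))
                    stop(sprintf("column '%s': unparseable integer value",
                                 cn), call. = FALSE)
                v
            },
            numeric   = {
                v <- suppressWarnings(as.numeric(raw))
                if (any(is.na(v) & !blank))
                    stop(sprintf("column '%s': unparseable numeric value",
                                 cn), call. = FALSE)
                v
            },
            logical   = as.logical(raw))
    }
    df
}

#' Read a cohort from TSV (optionally with VAFs from a VCF)
#'
#' Reads the patients table and, when given, the variants table of the
#' documented tab-separated schema, validates every row against the type
#' invariants and returns a \linkS4class{ParpCohort}. HGVS strings are carried
#' verbatim and never normalized. Purity values arriving as percentages
#' (> 1) are divided by 100 with a warning.
#'
#' With \code{vcfFile} (the \code{vcf+tsv} dialect) the variant rows are built
#' from a VCF 4.x file instead: one sample column per patient, variant allele
#' fraction taken from the per-sample \code{AF} FORMAT field or, failing that,
#' computed as alt/(ref+alt) from \code{AD}; gene and HGVS annotation read
#' from the INFO keys \code{GENE}, \code{CDNA}, \code{PROTEIN} and
#' \code{CLASS}. Tumor purity is filled from an optional \code{purity} column
#' of the patients table. Requires the vcfR package.
#'
#' @param patientsFile path to the patients TSV.
#' @param variantsFile path to the variants TSV, or NULL for a variant-free
#'   cohort (e.g. an all-comers arm).
#' @param vcfFile path to a VCF carrying the variants, or NULL.
#' @param label cohort label.
#' @return A validated \linkS4class{ParpCohort}. Rows violating invariants
#'   abort with row-addressed messages.
#' @examples
#' f <- system.file("extdata", package = "parpvus")
#' coh <- readCohort(file.path(f, "table3_patients.tsv"),
#'                   file.path(f, "table3_variants.tsv"))
#' coh
#' @export
readCohort <- function(patientsFile, variantsFile = NULL, vcfFile = NULL,
                       label = "cohort") {
    pat <- .readTsv(patientsFile, .PATIENT_COLCLASSES)
    msgs <- .checkPatients(pat)
    if (length(msgs))
        stop(paste(msgs, collapse = "\n  "), call. = FALSE)

    if (!is.null(vcfFile)) {
        var <- .variantsFromVcf(vcfFile, pat)
    } else if (!is.null(variantsFile)) {
        var <- .readTsv(variantsFile, .VARIANT_COLCLASSES)
    } else {
        var <- .emptyVariants()
    }
    if (nrow(var)) {
        pct <- !is.na(var$purity) & var$purity > 1
        if (any(pct)) {
            warning(sum(pct), " purity value(s) > 1 interpreted as ",
                    "percentages and divided by 100")
            var$purity[pct] <- var$purity[pct] / 100
        }
    }
    msgs <- .checkVariants(var, pat$patient_id)
    if (length(msgs))
        stop(paste(msgs, collapse = "\n  "), call. = FALSE)
    methods::new("ParpCohort", patients = pat, variants = var, label = label)
}

.emptyVariants <- function() {
    df <- lapply(.VARIANT_COLCLASSES, function(cl) vector(cl, 0L))
    as.data.frame(df, stringsAsFactors = FALSE)
}

#' Write a cohort back to the TSV schema
#'
#' Inverse of [readCohort()]: field values round-trip bit-identically.
#'
#' @param cohort a \linkS4class{ParpCohort}.
#' @param patientsFile,variantsFile output paths.
#' @return Invisibly, the cohort.
#' @export
writeCohort <- function(cohort, patientsFile, variantsFile = NULL) {
    stopifnot(methods::is(cohort, "ParpCohort"))
    utils::write.table(patients(cohort), patientsFile, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    if (!is.null(variantsFile))
        utils::write.table(variants(cohort), variantsFile, sep = "\t",
                           quote = FALSE, row.names = FALSE, na = "NA")
    invisible(cohort)
}

.variantsFromVcf <- function(vcfFile, pat) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading variants from VCF requires the vcfR package",
             call. = FALSE)
    vcf <- vcfR::read.vcfR(vcfFile, verbose = FALSE)
    nvar <- nrow(vcf@fix)
    getInfo <- function(key) {
        v <- suppressWarnings(vcfR::extract.info(vcf, element = key))
        if (is.null(v) || !length(v)) rep(NA_character_, nvar) else v
    }
    af <- suppressWarnings(
        vcfR::extract.gt(vcf, element = "AF", as.numeric = TRUE))
    if (is.null(af) || all(is.na(af))) {
        ad <- vcfR::extract.gt(vcf, element = "AD")
        if (is.null(ad))
            stop("VCF has neither AF nor AD per-sample fields", call. = FALSE)
        cnt <- function(x, i) as.numeric(vapply(strsplit(x, ","),
                                                `[`, "", i))
        af <- matrix(NA_real_, nrow(ad), ncol(ad), dimnames = dimnames(ad))
        ok <- !is.na(ad)
        ref <- cnt(ad[ok], 1L); alt <- cnt(ad[ok], 2L)
        af[ok] <- ifelse(ref + alt > 0, alt / (ref + alt), NA_real_)
    }
    gene <- getInfo("GENE"); cdna <- getInfo("CDNA")
    prot <- getInfo("PROTEIN"); klass <- getInfo("CLASS")
    klass[is.na(klass)] <- "unknown"
    rows <- which(!is.na(af), arr.ind = TRUE)
    if (!nrow(rows))
        return(.emptyVariants())
    samp <- colnames(af)[rows[, 2]]
    purity <- if ("purity" %in% names(pat))
        pat$purity[match(samp, pat$patient_id)] else NA_real_
    data.frame(patient_id = samp,
               gene = gene[rows[, 1]], cdna = cdna[rows[, 1]],
               protein = prot[rows[, 1]], known_class = klass[rows[, 1]],
               vaf = af[rows], purity = as.numeric(purity),
               provean_score = NA_real_, provean_call = NA_character_,
               dann_score = NA_real_, dann_call = NA_character_,
               second_hit_score = NA_real_,
               second_hit_call = NA_character_,
               stringsAsFactors = FALSE)
}

#' Extract one treatment episode from a cohort
#'
#' @param cohort a \linkS4class{ParpCohort}.
#' @param patientId an id present in the cohort's patients table.
#' @return A \linkS4class{PatientCase} bundling the episode's clinical fields
#'   with its variant rows.
#' @examples
#' getCase(loadFixture("table3"), "Ovarian #2")
#' @export
getCase <- function(cohort, patientId) {
    stopifnot(methods::is(cohort, "ParpCohort"))
    pat <- patients(cohort)
    i <- match(patientId, pat$patient_id)
    if (is.na(i))
        stop("no such patient in cohort: ", patientId, call. = FALSE)
    v <- variants(cohort)
    methods::new("PatientCase",
        patientId = pat$patient_id[i], site = pat$site[i],
        histology = if (is.na(pat$histology[i])) "" else pat$histology[i],
        ps = as.integer(pat$ps[i]), treatment = pat$treatment[i],
        platinumResponse = pat$platinum_response[i],
        pfsDays = as.numeric(pat$pfs_days[i]),
        pfsEvent = pat$pfs_event[i],
        variants = v[v$patient_id == pat$patient_id[i], , drop = FALSE])
}

## ---- accessors and show methods ----

#' @rdname parpvus-accessors
#' @export
setMethod("patients", "ParpCohort", function(object) object@patients)

#' @rdname parpvus-accessors
#' @export
setMethod("variants", "ParpCohort", function(object) object@variants)

#' @rdname parpvus-accessors
#' @export
setMethod("variants", "PatientCase", function(object) object@variants)

#' @rdname parpvus-accessors
#' @export
setMethod("cohortLabel", "ParpCohort", function(object) object@label)

setMethod("show", "ParpCohort", function(object) {
    cat("ParpCohort '", object@label, "': ", nrow(object@patients),
        " episode(s), ", nrow(object@variants), " variant(s)\n", sep = "")
    if (nrow(object@patients)) {
        tab <- table(object@patients$site)
        cat("  sites:", paste(names(tab), tab, sep = "=", collapse = ", "),
            "\n")
    }
})

setMethod("show", "PatientCase", function(object) {
    cat("PatientCase ", object@patientId, " (", object@site, ", PS ",
        ifelse(is.na(object@ps), "?", object@ps), ", ", object@treatment,
        "): PFS ", object@pfsDays, "d",
        if (!object@pfsEvent) " (censored)", "\n", sep = "")
    if (nrow(object@variants))
        cat("  variants: ",
            paste(object@variants$gene, object@variants$protein,
                  collapse = "; "), "\n", sep = "")
})

#' @rdname patientVariantClass
#' @aliases patientVariantClass,PatientCase-method
#' @export
setMethod("patientVariantClass", "PatientCase", function(object) {
    .classOfVariants(object@variants$known_class, object@patientId)
})

#' @rdname patientVariantClass
#' @aliases patientVariantClass,ParpCohort-method
#' @export
setMethod("patientVariantClass", "ParpCohort", function(object) {
    v <- object@variants
    ids <- unique(v$patient_id)
    vapply(ids, function(id)
        .classOfVariants(v$known_class[v$patient_id == id], id),
        character(1))
})

.classOfVariants <- function(classes, id) {
    if (!length(classes))
        stop("patient-level class undefined: ", id, " has no variants",
             call. = FALSE)
    if ("pathogenic" %in% classes) "pathogenic"
    else if ("unknown" %in% classes) "unknown"
    else "benign"   # benign or probably_benign only
}
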