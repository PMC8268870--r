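## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (and the survival package) so that each check is
## a genuine dual route.

## Allele-count enumeration: lay out one allele vector per cell of a bulk
## sample and count variant alleles directly. Tumor cells are diploid except
## when the wild-type allele is lost; normal cells are diploid wild-type
## unless the variant is germline.
oracleVaf <- function(zygosity, loss, purity, nCells = 2000) {
    nTumor <- round(purity * nCells)
    stopifnot(abs(nTumor - purity * nCells) < 1e-9)   # exact grid only
    alleles <- integer(0)
    for (i in seq_len(nTumor))
        alleles <- c(alleles, if (loss) 1L else c(1L, 0L))
    for (i in seq_len(nCells - nTumor))
        alleles <- c(alleles,
                     if (zygosity == "germline") c(1L, 0L) else c(0L, 0L))
    sum(alleles) / length(alleles)
}

## Empirical survival function (valid oracle when nothing is censored).
oracleEmpiricalSurv <- function(times, t) mean(times > t)

## Hand-rolled Mantel-Cox chi-square from the observed-vs-expected events
## table, written directly from the 2xK hypergeometric construction.
oracleLogrankChisq <- function(time, event, group1) {
    O <- 0; E <- 0; V <- 0
    for (t in sort(unique(time[event]))) {
        atRisk <- time >= t
        n <- sum(atRisk); n1 <- sum(atRisk & group1)
        d <- sum(event & time == t); d1 <- sum(event & time == t & group1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    if (V == 0) 0 else (O - E)^2 / V
}

## Permutation reference for the log-rank p-value.
oraclePermutationP <- function(timeA, eventA, timeB, eventB,
                               nPerm = 2000, seed = 99) {
    set.seed(seed)
    time <- c(timeA, timeB); event <- c(eventA, eventB)
    nA <- length(timeA)
    obs <- oracleLogrankChisq(time, event, seq_along(time) <= nA)
    perm <- replicate(nPerm, {
        g <- logical(length(time))
        g[sample(length(time), nA)] <- TRUE
        oracleLogrankChisq(time, event, g)
    })
    mean(perm >= obs - 1e-12)
}

## Direct transcription of the published combination rule, as a flat lookup
## rather than the package's composed evidence-resolution path.
oracleVariantClass <- function(secondHit, insilico) {
    if (secondHit == "D" || insilico == "D") "deleterious"
    else if (secondHit == "B" && insilico == "B") "benign"
    else "unknown"
}
oraclePatientLabel <- function(secondHit, dann, provean, ps, model,
                               psCutoff = 3) {
    if (ps >= psCutoff) return("R")
    ins <- if (model == "provean") provean else dann
    if (oracleVariantClass(secondHit, ins) == "deleterious") "S" else "R"
}

## Builders for in-code cases and variants.
makeVariant <- function(gene = "BRCA1", protein = "p.Test1Xyz",
                        known_class = "unknown", vaf = NA_real_,
                        purity = NA_real_, provean_score = NA_real_,
                        provean_call = NA_character_,
                        dann_score = NA_real_,
                        dann_call = NA_character_,
                        second_hit_score = NA_real_,
                        second_hit_call = NA_character_) {
    data.frame(patient_id = "T-1", gene = gene, cdna = "c.1A > G",
               protein = protein, known_class = known_class, vaf = vaf,
               purity = purity, provean_score = provean_score,
               provean_call = provean_call, dann_score = dann_score,
               dann_call = dann_call, second_hit_score = second_hit_score,
               second_hit_call = second_hit_call, stringsAsFactors = FALSE)
}

makeCase <- function(variants, ps = 1L, pfs = 100, event = TRUE,
                     id = "T-1", treatment = "olaparib") {
    methods::new("PatientCase", patientId = id, site = "ovary",
                 histology = "", ps = as.integer(ps),
                 treatment = treatment, platinumResponse = "missing",
                 pfsDays = pfs, pfsEvent = event, variants = variants)
}

## Minimal valid cohort TSV writers for IO tests.
writePatientsTsv <- function(path, rows) {
    header <- paste(c("patient_id", "site", "histology", "ps", "treatment",
                      "platinum_response", "pfs_days", "pfs_event"),
                    collapse = "\t")
    writeLines(c(header, rows), path)
}
writeVariantsTsv <- function(path, rows) {
    header <- paste(c("patient_id", "gene", "cdna", "protein", "known_class",
                      "vaf", "purity", "provean_score", "provean_call",
                      "dann_score", "dann_call", "second_hit_score",
                      "second_hit_call"), collapse = "\t")
    writeLines(c(header, rows), path)
}
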