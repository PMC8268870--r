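t3 <- loadFixture("table3")
t5 <- loadFixture("table5")

test_that("per-variant rule: any D is deleterious, all-B is benign", {
    v3 <- variants(t3)
    row <- function(prot) v3[v3$protein == prot, , drop = FALSE]
    ## second hit B but PROVEAN D -> deleterious under the provean model
    expect_equal(classifyVariant(row("p.Met18Thr"), "provean"),
                 "deleterious")
    ## all three calls B -> benign under either model
    expect_equal(classifyVariant(row("p.Glu907Lys"), "provean"), "benign")
    expect_equal(classifyVariant(row("p.Glu907Lys"), "dann"), "benign")
    ## second hit D carries the dann model alone despite DANN = B
    expect_equal(classifyVariant(row("p.Asp219Gly"), "dann"), "deleterious")
    ## U evidence blocks the benign call but never argues deleterious
    expect_equal(classifyVariant(row("p.Glu1786Asp"), "dann"), "unknown")
    expect_error(classifyVariant(makeVariant(known_class = "pathogenic"),
                                 "dann"), "unknown significance")
})

test_that("evidence is resolved from scores when calls are absent", {
    ## VAF/purity pair resolves through the second-hit score
    v <- makeVariant(vaf = 0.56, purity = 0.6)   # score 0.933 -> D
    expect_equal(classifyVariant(v, "provean"), "deleterious")
    v <- makeVariant(vaf = 0.30, purity = 0.6, provean_score = -7.1)
    expect_equal(classifyVariant(v, "provean"), "deleterious")
    v <- makeVariant(vaf = 0.30, purity = 0.6, provean_score = -0.2)
    expect_equal(classifyVariant(v, "provean"), "benign")
    ## nothing at all -> unknown
    expect_equal(classifyVariant(makeVariant(), "provean"), "unknown")
})

test_that("patient labels follow the published per-case outcomes", {
    case <- function(id) getCase(t3, id)
    ## PS 3 forces Resistant despite deleterious evidence
    expect_equal(classifyPatient(case("Digestive tract #2 (pancreas)"),
                                 "provean"), "R")
    ## PS 1 with a green second hit -> Sensitive
    expect_equal(classifyPatient(case("Skin #1"), "provean"), "S")
    expect_equal(classifyPatient(case("Skin #1"), "dann"), "S")
    ## all-benign evidence at PS 0 -> Resistant
    expect_equal(classifyPatient(case("Digestive tract #5 (pancreas)"),
                                 "dann"), "R")
    noVus <- getCase(loadFixture("table2"), "Ovarian #1")
    expect_error(classifyPatient(noVus, "provean"), "decisionTree")
})

test_that("consensus reproduces every published final prediction", {
    pred <- classifyCohort(t3)
    reported <- patients(t3)$reported_prediction[
        match(pred$patient_id, patients(t3)$patient_id)]
    expect_equal(pred$final_label,
                 ifelse(reported == "S or R", "U", reported))
    expect_equal(unname(table(pred$final_label)[c("S", "R", "U")]),
                 c(6, 5, 1), ignore_attr = TRUE)
    ## the PS gate changes exactly the two PS3 pancreatic cases
    ungated <- classifyCohort(t3, psCutoff = Inf)
    flipped <- pred$patient_id[pred$final_label != ungated$final_label]
    expect_setequal(flipped, c("Digestive tract #2 (pancreas)",
                               "Digestive tract #7 (pancreas)"))
    expect_true(all(ungated$final_label[match(flipped,
                                              ungated$patient_id)] == "S"))

    pred5 <- classifyCohort(t5)
    reported5 <- patients(t5)$reported_prediction[
        match(pred5$patient_id, patients(t5)$patient_id)]
    expect_equal(pred5$final_label, reported5)
    expect_equal(unname(table(pred5$final_label)[c("S", "R", "U")]),
                 c(3, 4, 1), ignore_attr = TRUE)
})

test_that("consensus result object is internally consistent", {
    res <- classifyConsensus(getCase(t3, "Ovarian #23"))
    expect_s4_class(res, "ClassificationResult")
    expect_equal(finalLabel(res), "U")   # provean S vs dann R
    expect_equal(perModelLabels(res)[["provean"]], "S")
    expect_equal(perModelLabels(res)[["dann"]], "R")
    expect_false(res@psGated)
    expect_true(any(grepl("PROVEAN=D", rationale(res))))

    gated <- classifyConsensus(getCase(t3, "Digestive tract #7 (pancreas)"))
    expect_true(gated@psGated)
    expect_equal(finalLabel(gated), "R")
    expect_true(any(grepl("gate", rationale(gated))))
})

test_that("classification is invariant to variant order and monotone", {
    skin <- getCase(t3, "Skin #1")
    set.seed(11)
    base <- classifyConsensus(skin)
    for (i in 1:5) {
        shuffled <- skin
        shuffled@variants <- skin@variants[sample(nrow(skin@variants)), ]
        res <- classifyConsensus(shuffled)
        expect_equal(finalLabel(res), finalLabel(base))
        expect_equal(perModelLabels(res), perModelLabels(base))
    }
    ## adding a deleterious variant to a PS<3 case never flips S -> R
    combos <- expand.grid(sh = c("B", "D", "U"), ins = c("B", "D", "U"),
                          stringsAsFactors = FALSE)
    strong <- makeVariant(second_hit_call = "D", provean_call = "D",
                          dann_call = "D")
    for (k in seq_len(nrow(combos))) {
        v <- makeVariant(second_hit_call = combos$sh[k],
                         provean_call = combos$ins[k],
                         dann_call = combos$ins[k])
        before <- classifyPatient(makeCase(v, ps = 1), "provean")
        after <- classifyPatient(makeCase(rbind(v, strong), ps = 1),
                                 "provean")
        expect_equal(after, "S")
        if (before == "S") expect_equal(after, "S")
    }
})

test_that("PS at or above the cutoff dominates any evidence", {
    for (ps in 3:4) {
        for (sh in c("B", "D", "U")) {
            v <- makeVariant(second_hit_call = sh, provean_call = "D",
                             dann_call = "D")
            case <- makeCase(v, ps = ps)
            expect_equal(classifyPatient(case, "provean"), "R")
            expect_equal(classifyPatient(case, "dann"), "R")
            res <- classifyConsensus(case)
            expect_true(res@psGated)
            expect_equal(finalLabel(res), "R")
        }
    }
})

test_that("composed classifier matches the brute-force rule table", {
    calls <- c("B", "D", "U")
    for (sh in calls) for (dn in calls) for (pv in calls) for (ps in 0:4) {
        v <- makeVariant(second_hit_call = sh, provean_call = pv,
                         dann_call = dn)
        case <- makeCase(v, ps = ps)
        for (model in c("provean", "dann")) {
            expect_equal(
                classifyPatient(case, model),
                oraclePatientLabel(sh, dn, pv, ps, model),
                label = sprintf("sh=%s dann=%s provean=%s ps=%d model=%s",
                                sh, dn, pv, ps, model))
        }
    }
})

test_that("decision tree routes known classes before the VUS algorithm", {
    t2 <- loadFixture("table2")
    ## known pathogenic frameshift -> treat as sensitive
    expect_equal(decisionTree(getCase(t2, "Ovarian #1")),
                 "treat_parpi_sensitive")
    ## two benign variants -> no HRD-mediated response expected
    expect_equal(decisionTree(getCase(t2, "Ovarian #12")),
                 "do_not_expect_hrd_response")
    ## consensus U propagates to uncertain (evidence-bearing fixture)
    expect_equal(decisionTree(getCase(t3, "Ovarian #23")),
                 "treat_uncertain")
    ## pathogenic wins over a co-occurring VUS
    expect_equal(decisionTree(getCase(t2, "Ovarian #13")),
                 "treat_parpi_sensitive")
    ## no variants at all -> no HRD response expected
    expect_equal(decisionTree(makeCase(makeVariant()[0, ])),
                 "do_not_expect_hrd_response")
    ## optional gate extension applies PS to known-pathogenic routing
    path <- makeCase(makeVariant(known_class = "pathogenic"), ps = 3)
    expect_equal(decisionTree(path), "treat_parpi_sensitive")
    expect_equal(decisionTree(path, gateKnownPathogenic = TRUE),
                 "do_not_expect_hrd_response")
})
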