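test_that("packaged fixtures load with the published census", {
    t2 <- loadFixture("table2")
    expect_s4_class(t2, "ParpCohort")
    expect_equal(nrow(patients(t2)), 41)
    sites <- table(patients(t2)$site)
    expect_equal(unname(sites[c("ovary", "breast", "digestive_tract",
                                "endometrium", "skin")]),
                 c(23, 8, 8, 1, 1), ignore_attr = TRUE)
    ## censoring: four "still under olaparib" episodes plus the day-1
    ## allergic-reaction stop
    expect_equal(sum(!patients(t2)$pfs_event), 5)
    expect_false(patients(t2)$pfs_event[patients(t2)$patient_id ==
                                        "Ovarian #19"])

    t3 <- loadFixture("table3")
    expect_equal(nrow(patients(t3)), 12)
    expect_true(all(variants(t3)$known_class == "unknown"))

    t5 <- loadFixture("table5")
    expect_equal(nrow(patients(t5)), 8)
    expect_equal(nrow(variants(t5)), 10)

    expect_s3_class(loadFixture("table1"), "data.frame")
    expect_error(loadFixture("table9"), "available.*table1")
})

test_that("patient-level class follows pathogenic > unknown > benign", {
    t2 <- loadFixture("table2")
    cls <- patientVariantClass(t2)
    expect_equal(unname(table(cls)[c("pathogenic", "unknown", "benign")]),
                 c(26, 12, 3), ignore_attr = TRUE)
    ## one VUS plus one pathogenic variant -> pathogenic
    expect_equal(patientVariantClass(getCase(t2, "Ovarian #13")),
                 "pathogenic")
    ## probably benign only -> benign
    expect_equal(patientVariantClass(
        getCase(t2, "Digestive tract #4 (rectum)")), "benign")
    ## benign + unknown -> unknown
    mixed <- makeCase(rbind(makeVariant(known_class = "benign"),
                            makeVariant(known_class = "unknown")))
    expect_equal(patientVariantClass(mixed), "unknown")
    empty <- makeCase(makeVariant()[0, ])
    expect_error(patientVariantClass(empty), "no variants")
})

test_that("cohort TSVs round-trip bit-identically", {
    for (fx in c("table2", "table3")) {
        coh <- loadFixture(fx)
        pf <- withr::local_tempfile(fileext = ".tsv")
        vf <- withr::local_tempfile(fileext = ".tsv")
        writeCohort(coh, pf, vf)
        back <- readCohort(pf, vf, label = fx)
        expect_identical(patients(back), patients(coh))
        expect_identical(variants(back), variants(coh))
    }
})

test_that("readCohort validates rows with addressed messages", {
    pf <- withr::local_tempfile(fileext = ".tsv")
    vf <- withr::local_tempfile(fileext = ".tsv")

    ## empty files with valid headers -> empty cohort
    writePatientsTsv(pf, character(0))
    writeVariantsTsv(vf, character(0))
    empty <- readCohort(pf, vf)
    expect_equal(nrow(patients(empty)), 0)
    expect_equal(nrow(variants(empty)), 0)

    ## invariant violation is row-addressed
    writePatientsTsv(pf, "P1\tovary\t\t1\tolaparib\tmissing\t100\tTRUE")
    writeVariantsTsv(vf, paste("P1\tBRCA1\tc.1A > G\tp.X\tunknown\t1.3\t0.5",
                               "NA\tNA\tNA\tNA\tNA\tNA", sep = "\t"))
    expect_error(readCohort(pf, vf), "row 1.*vaf must be in \\[0,1\\]")

    ## missing mandatory column is named
    writeLines(c("patient_id\tsite", "P1\tovary"), pf)
    expect_error(readCohort(pf), "missing mandatory column 'histology'")

    ## unparseable performance status
    writePatientsTsv(pf, "P1\tovary\t\tbad\tolaparib\tmissing\t100\tTRUE")
    expect_error(readCohort(pf), "unparseable integer")

    ## percentage purity is rescaled with a warning
    writePatientsTsv(pf, "P1\tovary\t\t1\tolaparib\tmissing\t100\tTRUE")
    writeVariantsTsv(vf, paste("P1\tBRCA1\tc.1A > G\tp.X\tunknown\t0.3\t60",
                               "NA\tNA\tNA\tNA\tNA\tNA", sep = "\t"))
    expect_warning(coh <- readCohort(pf, vf), "percentage")
    expect_equal(variants(coh)$purity, 0.6)
})

test_that("VCF dialect pulls VAF from AF or AD per-sample fields", {
    pf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(paste(c("patient_id", "site", "histology", "ps",
                         "treatment", "platinum_response", "pfs_days",
                         "pfs_event", "purity"), collapse = "\t"),
                 "P1\tovary\t\t1\tolaparib\tmissing\t200\tTRUE\t0.6",
                 "P2\tbreast\t\t2\tolaparib\tmissing\t90\tTRUE\t0.5"), pf)

    vcfAF <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
        "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS c.\">",
        "##INFO=<ID=PROTEIN,Number=1,Type=String,Description=\"HGVS p.\">",
        "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Known class\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", "P1", "P2"), collapse = "\t"),
        paste(c("17", "43094464", ".", "T", "C", ".", "PASS",
                "GENE=BRCA1;CDNA=c.53T>C;PROTEIN=p.Met18Thr;CLASS=unknown",
                "GT:AF", "0/1:0.19", "./.:."), collapse = "\t"),
        paste(c("16", "23635000", ".", "A", "G", ".", "PASS",
                "GENE=PALB2;CDNA=c.656A>G;PROTEIN=p.Asp219Gly;CLASS=unknown",
                "GT:AF", "./.:.", "0/1:0.56"), collapse = "\t")), vcfAF)
    coh <- readCohort(pf, vcfFile = vcfAF)
    v <- variants(coh)
    expect_equal(nrow(v), 2)
    expect_equal(v$vaf[v$patient_id == "P1"], 0.19)
    expect_equal(v$gene[v$patient_id == "P2"], "PALB2")
    expect_equal(v$purity[v$patient_id == "P2"], 0.5)   # joined from TSV

    vcfAD <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", "P1", "P2"), collapse = "\t"),
        paste(c("13", "32339000", ".", "G", "T", ".", "PASS", "GENE=BRCA2",
                "GT:AD", "0/1:80,20", "./.:."), collapse = "\t")), vcfAD)
    coh2 <- readCohort(pf, vcfFile = vcfAD)
    expect_equal(variants(coh2)$vaf, 0.2)   # alt / (ref + alt)
    expect_equal(variants(coh2)$known_class, "unknown")
})

test_that("getCase extracts an episode with its variants", {
    t3 <- loadFixture("table3")
    case <- getCase(t3, "Skin #1")
    expect_s4_class(case, "PatientCase")
    expect_equal(nrow(variants(case)), 3)
    expect_equal(case@ps, 1L)
    expect_error(getCase(t3, "Nobody #9"), "no such patient")
})
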