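## Seeded synthetic-cohort generator. Emulates the statistical structure the
## classifier assumes: a class mix of benign / VUS / pathogenic episodes,
## pathologist purities, an allele-count forward model for the true VAF,
## binomial read-depth noise, in-silico calls correct for the true class up
## to a flip rate, and exponential PFS with class- and PS-dependent medians.

.TRUE_CLASSES <- c("benign", "vus_benign", "vus_deleterious", "pathogenic")
.SIM_GENES <- c("BRCA1", "BRCA2", "PALB2", "RAD51C", "RAD51D", "BRIP1",
                "ATM", "RAD50", "FANCF", "CHEK2")

#' Construct a synthetic-cohort configuration
#'
#' Defaults mirror the development cohort: 41 episodes, class mix
#' 3 benign : 6 truly-benign VUS : 6 truly-deleterious VUS : 26 pathogenic,
#' purities 0.2-0.9, read depth 100x, PFS medians 81 days for truly benign
#' and 190 days for truly deleterious classes, an 0.25 PFS multiplier for
#' PS >= 3, and a 12\% censoring rate.
#'
#' @param nPatients number of episodes.
#' @param classMix named probabilities over benign, vus_benign,
#'   vus_deleterious, pathogenic.
#' @param purityRange interval in (0,1] for the uniform purity draw.
#' @param readDepth sequencing depth of the binomial VAF noise model.
#' @param germlineProb probability a variant is a germline heterozygote.
#' @param lossProbDeleterious probability of wild-type loss given a truly
#'   deleterious variant (truly benign variants never lose the allele).
#' @param insilicoFlipProb per-tool probability the categorical call
#'   contradicts the true class.
#' @param psDistribution probabilities over performance status 0..4.
#' @param pfsMedianByClass named PFS medians (days) per true class.
#' @param psPfsFactor PFS-median multiplier when PS >= 3.
#' @param censorProb probability an episode is censored.
#' @param seed RNG seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' simConfig(nPatients = 10, seed = 7)
#' @export
simConfig <- function(nPatients = 41,
                      classMix = c(benign = 3 / 41, vus_benign = 6 / 41,
                                   vus_deleterious = 6 / 41,
                                   pathogenic = 26 / 41),
                      purityRange = c(0.2, 0.9),
                      readDepth = 100,
                      germlineProb = 0.5,
                      lossProbDeleterious = 0.9,
                      insilicoFlipProb = 0.1,
                      psDistribution = c(0.10, 0.55, 0.15, 0.15, 0.05),
                      pfsMedianByClass = c(benign = 81, vus_benign = 81,
                                           vus_deleterious = 190,
                                           pathogenic = 190),
                      psPfsFactor = 0.25,
                      censorProb = 0.12,
                      seed = 1) {
    methods::new("SimConfig", nPatients = as.integer(nPatients),
                 classMix = classMix, purityRange = purityRange,
                 readDepth = as.integer(readDepth),
                 germlineProb = germlineProb,
                 lossProbDeleterious = lossProbDeleterious,
                 insilicoFlipProb = insilicoFlipProb,
                 psDistribution = psDistribution,
                 pfsMedianByClass = pfsMedianByClass,
                 psPfsFactor = psPfsFactor, censorProb = censorProb,
                 seed = as.integer(seed))
}

#' True VAF under the diploid allele-count forward model
#'
#' Closed-form bulk VAF for the four variant states at tumor cell content p
#' (tumor cells diploid except for the lost allele, normal cells diploid
#' wild-type): somatic heterozygote p/2; somatic heterozygote with
#' wild-type loss p/(2-p); germline heterozygote 1/2; germline heterozygote
#' with loss of the wild-type allele in tumor cells 1/(2-p).
#'
#' @param zygosity \code{"somatic"} or \code{"germline"}.
#' @param loss TRUE when the tumor cells lost the wild-type allele.
#' @param purity tumor cell content in (0,1].
#' @return The bulk variant allele frequency.
#' @examples
#' alleleVaf("germline", TRUE, 0.65)   # 1/1.35
#' @export
alleleVaf <- function(zygosity = c("somatic", "germline"), loss = FALSE,
                      purity) {
    zygosity <- match.arg(zygosity)
    if (any(purity <= 0 | purity > 1))
        stop("purity must lie in (0,1]", call. = FALSE)
    if (zygosity == "somatic") {
        if (loss) purity / (2 - purity) else purity / 2
    } else {
        if (loss) 1 / (2 - purity) else 0.5
    }
}

#' Simulate a cohort with known ground truth
#'
#' Per episode: draws the true class, performance status, purity, zygosity
#' and loss state; computes the true VAF from the allele-count forward model
#' ([alleleVaf()]); observes VAF as binomial(readDepth, trueVAF)/readDepth;
#' sets categorical PROVEAN/DANN calls correct for the true class up to the
#' flip probability (truly deleterious -> D, truly benign -> B); draws PFS
#' from an exponential with the class median (shrunk by \code{psPfsFactor}
#' when PS >= 3) and censors at random. Identical seeds give identical
#' output.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A list with \code{cohort} (a \linkS4class{ParpCohort}) and
#'   \code{truth} (data.frame: patient_id, true_class, zygosity, loss,
#'   purity, true_vaf).
#' @examples
#' sim <- simulateCohort(simConfig(nPatients = 5, seed = 42))
#' sim$truth
#' @export
simulateCohort <- function(cfg) {
    stopifnot(methods::is(cfg, "SimConfig"))
    methods::validObject(cfg)
    set.seed(cfg@seed)
    n <- cfg@nPatients
    if (n == 0L) {
        pat <- utils::head(data.frame(patient_id = character(0),
            site = character(0), histology = character(0), ps = integer(0),
            treatment = character(0), platinum_response = character(0),
            pfs_days = integer(0), pfs_event = logical(0)), 0L)
        return(list(cohort = methods::new("ParpCohort", patients = pat,
                                          variants = .emptyVariants(),
                                          label = "simulated"),
                    truth = data.frame(patient_id = character(0),
                                       true_class = character(0),
                                       zygosity = character(0),
                                       loss = logical(0),
                                       purity = numeric(0),
                                       true_vaf = numeric(0))))
    }
    id <- sprintf("SIM-%03d", seq_len(n))
    trueClass <- sample(.TRUE_CLASSES, n, TRUE, cfg@classMix[.TRUE_CLASSES])
    ps <- sample(0:4, n, TRUE, cfg@psDistribution)
    ## pathologist-style purity: two-decimal estimates, never zero
    purity <- pmax(0.01, round(stats::runif(n, cfg@purityRange[1],
                                            cfg@purityRange[2]), 2))
    zygosity <- ifelse(stats::runif(n) < cfg@germlineProb,
                       "germline", "somatic")
    deleterious <- trueClass %in% c("pathogenic", "vus_deleterious")
    loss <- deleterious & stats::runif(n) < cfg@lossProbDeleterious
    trueVaf <- vapply(seq_len(n), function(i)
        alleleVaf(zygosity[i], loss[i], purity[i]), numeric(1))
    obsVaf <- stats::rbinom(n, cfg@readDepth, trueVaf) / cfg@readDepth

    callFor <- function(del) {
        truth <- ifelse(del, "D", "B")
        flip <- stats::runif(n) < cfg@insilicoFlipProb
        ifelse(flip, ifelse(truth == "D", "B", "D"), truth)
    }
    proveanCall <- callFor(deleterious)
    dannCall <- callFor(deleterious)
    knownClass <- c(benign = "benign", vus_benign = "unknown",
                    vus_deleterious = "unknown",
                    pathogenic = "pathogenic")[trueClass]

    med <- cfg@pfsMedianByClass[trueClass] *
        ifelse(ps >= 3, cfg@psPfsFactor, 1)
    pfs <- pmax(1L, as.integer(round(stats::rexp(n, log(2) / med))))
    event <- stats::runif(n) >= cfg@censorProb
    site <- sample(CANCER_SITES[1:5], n, TRUE,
                   c(23, 8, 8, 1, 1) / 41)

    pat <- data.frame(patient_id = id, site = site, histology = "",
                      ps = as.integer(ps), treatment = "olaparib",
                      platinum_response = "missing",
                      pfs_days = pfs, pfs_event = event,
                      stringsAsFactors = FALSE)
    var <- data.frame(patient_id = id,
                      gene = sample(.SIM_GENES, n, TRUE),
                      cdna = sprintf("c.%d_sim", seq_len(n)),
                      protein = sprintf("p.Sim%d", seq_len(n)),
                      known_class = unname(knownClass),
                      vaf = obsVaf, purity = purity,
                      provean_score = NA_real_, provean_call = proveanCall,
                      dann_score = NA_real_, dann_call = dannCall,
                      second_hit_score = NA_real_,
                      second_hit_call = NA_character_,
                      stringsAsFactors = FALSE)
    truth <- data.frame(patient_id = id, true_class = trueClass,
                        zygosity = zygosity, loss = loss, purity = purity,
                        true_vaf = trueVaf, stringsAsFactors = FALSE)
    list(cohort = methods::new("ParpCohort", patients = pat, variants = var,
                               label = "simulated"),
         truth = truth)
}

#' Run the full pipeline on a simulated cohort and score recovery
#'
#' Simulates a cohort, classifies every VUS-carrying episode with the
#' dual-model consensus, and scores the final labels against the simulated
#' truth: sensitivity is the fraction of truly deleterious VUS episodes
#' labelled S, specificity the fraction of truly benign VUS episodes
#' labelled R (U counts as a miss for both), plus the S-vs-R log-rank
#' p-value on the simulated PFS.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param ... tuning parameters passed to [classifyCohort()].
#' @return A list with nPatients, nVus, sensitivity, specificity and
#'   logrankP (NA when either predicted group is empty).
#' @examples
#' recoveryExperiment(simConfig(nPatients = 30, seed = 3))
#' @export
recoveryExperiment <- function(cfg, ...) {
    sim <- simulateCohort(cfg)
    if (cfg@nPatients == 0L)
        return(list(nPatients = 0L, nVus = 0L, sensitivity = NA_real_,
                    specificity = NA_real_, logrankP = NA_real_))
    pred <- classifyCohort(sim$cohort, ...)
    truth <- sim$truth[match(pred$patient_id, sim$truth$patient_id), ]
    del <- truth$true_class == "vus_deleterious"
    ben <- truth$true_class == "vus_benign"
    sens <- if (any(del)) mean(pred$final_label[del] == "S") else NA_real_
    spec <- if (any(ben)) mean(pred$final_label[ben] == "R") else NA_real_
    sGrp <- pred$final_label == "S"
    rGrp <- pred$final_label == "R"
    lrp <- if (any(sGrp) && any(rGrp))
        logrankTest(pred$pfs_days[sGrp], pred$pfs_event[sGrp],
                    pred$pfs_days[rGrp], pred$pfs_event[rGrp],
                    labels = c("S", "R"))@pValue
    else NA_real_
    list(nPatients = cfg@nPatients, nVus = nrow(pred),
         sensitivity = sens, specificity = spec, logrankP = lrp)
}
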