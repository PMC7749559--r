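#' @include kinetics.R
NULL

.FRACTIONS <- c("myofibrillar", "cytosolic", "mitochondrial")

# deterministic per-animal substream: reproducible and insensitive to the
# order in which other streams are consumed
.substream <- function(master, counter) {
    as.integer((as.numeric(master) * 48271 + counter * 16807) %% 2147483647)
}

#' The four demo groups of the 2x2 cachexia design
#'
#' WT/Sod1KO x saline/LLC group specifications with the published
#' degradation constants planted as ground truth for the myofibrillar and
#' mitochondrial fractions, steady-state synthesis in the saline groups and
#' atrophying pools (ksyn below equilibrium) in the tumour-bearing groups.
#' Cytosolic rates, Ct panels and fibre-size distributions are plausible
#' defaults documented in the vignette.
#'
#' @param nAnimals animals per group (default 8).
#' @return list of four [GroupSpec-class] objects.
#' @examples
#' demoGroups()
#' @export
demoGroups <- function(nAnimals = 8L) {
    ctWT <- c(Runx1 = 26, Gadd45a = 27, AchRa = 25, Sln = 24, Rn18s = 12)
    ctKO <- ctWT - c(1, 1, 1, 1.2, 0)   # denervation markers up in Sod1KO
    list(
        groupSpec("WT", "saline", nAnimals,
            trueKsyn = c(myofibrillar = 0.00847, cytosolic = 0.060,
                         mitochondrial = 0.0204),
            trueKdeg = c(myofibrillar = 0.00847, cytosolic = 0.060,
                         mitochondrial = 0.0204),
            meanConductionVelocity = 38.2,
            sdConductionVelocity = 0.861 * sqrt(8),
            ctMeans = ctWT, csaMeanLog = log(2000)),
        groupSpec("WT", "LLC", nAnimals,
            trueKsyn = c(myofibrillar = 0.010, cytosolic = 0.070,
                         mitochondrial = 0.020),
            trueKdeg = c(myofibrillar = 0.0211, cytosolic = 0.070,
                         mitochondrial = 0.167),
            meanConductionVelocity = 28.8,
            sdConductionVelocity = 0.772 * sqrt(8),
            ctMeans = ctWT, csaMeanLog = log(1550)),
        groupSpec("Sod1KO", "saline", nAnimals,
            trueKsyn = c(myofibrillar = 0.0180, cytosolic = 0.065,
                         mitochondrial = 0.0231),
            trueKdeg = c(myofibrillar = 0.0180, cytosolic = 0.065,
                         mitochondrial = 0.0231),
            meanConductionVelocity = 30.6,
            sdConductionVelocity = 2.4,
            ctMeans = ctKO, csaMeanLog = log(1900)),
        groupSpec("Sod1KO", "LLC", nAnimals,
            trueKsyn = c(myofibrillar = 0.020, cytosolic = 0.075,
                         mitochondrial = 0.020),
            trueKdeg = c(myofibrillar = 0.0490, cytosolic = 0.080,
                         mitochondrial = 0.0645),
            meanConductionVelocity = 30.0,
            sdConductionVelocity = 2.4,
            ctMeans = ctKO, csaMeanLog = log(1500))
    )
}

#' Simulate a complete labelling cohort with known ground truth
#'
#' For each animal: the plasma body-water enrichment implied by the
#' protocol, one protein-pool trajectory per fraction from the group's
#' planted (ksyn, kdeg), the resulting protein-bound alanine isotopomer
#' distribution (with measurement noise), pool-size marker ratios (muscle
#' mass for myofibrillar, CoxIV densitometry for mitochondrial, lognormal
#' noise), a qPCR Ct panel, a sciatic-nerve conduction velocity draw and a
#' fibre cross-sectional-area sample. The planted parameters are stored in
#' the \code{truth} table for recovery tests.
#'
#' Randomness is fully reproducible: each animal consumes its own substream
#' derived by counter from \code{noise@seed}, so identical
#' (groups, protocol, noise) yield bit-identical datasets.
#'
#' @param groups list of [GroupSpec-class]; duplicate genotype/treatment
#'   combinations are rejected.
#' @param protocol a [LabelingProtocol-class].
#' @param noise a [NoiseModel-class] (all-zero sds for a noise-free cohort).
#' @param nSites effective exchangeable hydrogens used to derive the true
#'   precursor enrichment (default 3.7).
#' @param naturalDist baseline [IsotopomerDistribution-class].
#' @param intakeFraction drinking-water share of body-water input, passed
#'   to [meanBodyWater()].
#' @return a [StudyDataset-class].
#' @examples
#' ds <- simulateCohort(demoGroups(nAnimals = 3), labelingProtocol(),
#'                      noiseModel(seed = 7))
#' ds
#' @export
simulateCohort <- function(groups, protocol = labelingProtocol(),
                           noise = noiseModel(), nSites = 3.7,
                           naturalDist = naturalIsotopomers(),
                           intakeFraction = 0.55) {
    if (is(groups, "GroupSpec")) groups <- list(groups)
    stopifnot(length(groups) >= 1L,
              all(vapply(groups, is, TRUE, "GroupSpec")),
              is(protocol, "LabelingProtocol"), is(noise, "NoiseModel"))
    labels <- vapply(groups, function(g)
        paste(g@genotype, g@treatment, sep = "/"), "")
    if (anyDuplicated(labels))
        stop("duplicate group labels: ", labels[duplicated(labels)][1])
    bw <- meanBodyWater(protocol, intakeFraction = intakeFraction)
    p <- precursorEnrichment(bw, nSites)@p
    t <- labelDuration(protocol)

    aniRows <- list(); isoRows <- list(); csaRows <- list(); truthRows <- list()
    counter <- 0L
    for (g in groups) {
        validObject(g)
        fractions <- names(g@trueKdeg)
        for (a in seq_len(g@nAnimals)) {
            counter <- counter + 1L
            id <- sprintf("%s_%s_%02d", g@genotype, g@treatment, a)
            set.seed(.substream(noise@seed, counter))
            velocity <- stats::rnorm(1, g@meanConductionVelocity,
                                     g@sdConductionVelocity)
            ct <- g@ctMeans + stats::rnorm(length(g@ctMeans), 0, noise@ctSD)
            csa <- stats::rlnorm(g@csaN, g@csaMeanLog, g@csaSdLog)
            ani <- data.frame(animal_id = id, genotype = g@genotype,
                              treatment = g@treatment, body_water = bw,
                              conduction_velocity = velocity)
            for (gene in names(ct))
                ani[[paste0("ct_", gene)]] <- unname(ct[gene])
            aniRows[[id]] <- ani
            csaRows[[id]] <- data.frame(animal_id = id, area = csa)
            for (fr in fractions) {
                pool <- simulatePool(g@trueKsyn[[fr]], g@trueKdeg[[fr]], 1, t)
                Etrue <- simulateAlanineEnrichment(pool, p)
                dist <- isotopomerize(Etrue, nSites, naturalDist, noise)
                marker <- if (fr == "cytosolic") NA_real_ else {
                    m <- poolRatio(pool)
                    if (noise@poolMarkerCV > 0) {
                        sdlog <- sqrt(log(1 + noise@poolMarkerCV^2))
                        m <- m * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
                    }
                    m
                }
                fracs <- isotopomerFractions(dist)
                iso <- data.frame(animal_id = id, fraction_id = fr,
                                  marker_ratio = marker)
                for (j in seq_along(fracs))
                    iso[[names(fracs)[j]]] <- unname(fracs[j])
                isoRows[[paste(id, fr)]] <- iso
                truthRows[[paste(id, fr)]] <- data.frame(
                    animal_id = id, fraction_id = fr,
                    true_ksyn = g@trueKsyn[[fr]], true_kdeg = g@trueKdeg[[fr]],
                    true_r = poolRatio(pool), true_E = Etrue,
                    true_f = pool@Nt / pool@Pt)
            }
        }
    }
    cfg <- list(seed = noise@seed, nSites = nSites,
                intakeFraction = intakeFraction,
                groups = lapply(groups, function(g) list(
                    genotype = g@genotype, treatment = g@treatment,
                    nAnimals = g@nAnimals,
                    trueKsyn = as.list(g@trueKsyn),
                    trueKdeg = as.list(g@trueKdeg))))
    new("StudyDataset",
        animals = S4Vectors::DataFrame(do.call(rbind, aniRows),
                                       row.names = NULL),
        isotopomers = S4Vectors::DataFrame(do.call(rbind, isoRows),
                                           row.names = NULL),
        fiberCSA = S4Vectors::DataFrame(do.call(rbind, csaRows),
                                        row.names = NULL),
        truth = S4Vectors::DataFrame(do.call(rbind, truthRows),
                                     row.names = NULL),
        protocol = protocol, noise = noise, config = cfg)
}

#' Write a study dataset to plain-text files
#'
#' Emits \code{animals.csv}, \code{isotopomers.csv}, \code{fiber_csa.csv},
#' \code{truth.csv}, a \code{config.yaml} provenance snapshot and a
#' \code{run.log} with the seed, into \code{dir}.
#'
#' @param dataset a [StudyDataset-class].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeStudyDataset <- function(dataset, dir) {
    stopifnot(is(dataset, "StudyDataset"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(animals(dataset)),
                     file.path(dir, "animals.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(isotopomers(dataset)),
                     file.path(dir, "isotopomers.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(fiberAreas(dataset)),
                     file.path(dir, "fiber_csa.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(groundTruth(dataset)),
                     file.path(dir, "truth.csv"), row.names = FALSE)
    pr <- protocol(dataset)
    cfg <- c(dataset@config,
             list(protocol = list(bolusDose = bolusDose(pr),
                                  waterEnrichment = waterEnrichment(pr),
                                  labelDuration = labelDuration(pr),
                                  bodyWaterPool = bodyWaterPool(pr),
                                  waterTurnover = waterTurnover(pr)),
                  noise = list(isotopomerSD = dataset@noise@isotopomerSD,
                               isotopomerCV = dataset@noise@isotopomerCV,
                               poolMarkerCV = dataset@noise@poolMarkerCV,
                               ctSD = dataset@noise@ctSD)))
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
    writeLines(c(sprintf("d2oturnover %s",
                         as.character(utils::packageVersion("d2oturnover"))),
                 sprintf("seed: %d", dataset@noise@seed),
                 sprintf("animals: %d", nrow(animals(dataset)))),
               file.path(dir, "run.log"))
    invisible(dir)
}

#' Read a study dataset written by [writeStudyDataset()]
#'
#' Also accepts user data in the same schema; the \code{truth.csv} table is
#' optional (absent for real experiments).
#'
#' @param dir directory containing the CSV/YAML files.
#' @return a [StudyDataset-class].
#' @export
readStudyDataset <- function(dir) {
    cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
    pr <- do.call(labelingProtocol, cfg$protocol)
    nm <- noiseModel(isotopomerSD = cfg$noise$isotopomerSD,
                     isotopomerCV = cfg$noise$isotopomerCV,
                     poolMarkerCV = cfg$noise$poolMarkerCV,
                     ctSD = cfg$noise$ctSD, seed = cfg$seed)
    rd <- function(f) S4Vectors::DataFrame(
        utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
    truth <- if (file.exists(file.path(dir, "truth.csv"))) rd("truth.csv")
             else S4Vectors::DataFrame(animal_id = character(),
                                       fraction_id = character())
    new("StudyDataset", animals = rd("animals.csv"),
        isotopomers = rd("isotopomers.csv"),
        fiberCSA = rd("fiber_csa.csv"), truth = truth,
        protocol = pr, noise = nm,
        config = cfg[setdiff(names(cfg), c("protocol", "noise"))])
}
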