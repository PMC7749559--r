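#' @include tukey.R
NULL

#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aggregate
NULL

.groupFromList <- function(g) {
    groupSpec(genotype = g$genotype, treatment = g$treatment,
              nAnimals = g$nAnimals,
              trueKsyn = unlist(g$trueKsyn), trueKdeg = unlist(g$trueKdeg),
              meanConductionVelocity = g$meanConductionVelocity %||% 38.2,
              sdConductionVelocity = g$sdConductionVelocity %||% 2.44,
              ctMeans = if (!is.null(g$ctMeans)) unlist(g$ctMeans)
                        else c(Runx1 = 26, Gadd45a = 27, AchRa = 25,
                               Sln = 24, Rn18s = 12),
              csaMeanLog = g$csaMeanLog %||% log(1800),
              csaSdLog = g$csaSdLog %||% 0.45,
              csaN = g$csaN %||% 150L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.groupToList <- function(g) list(
    genotype = g@genotype, treatment = g@treatment, nAnimals = g@nAnimals,
    trueKsyn = as.list(g@trueKsyn), trueKdeg = as.list(g@trueKdeg),
    meanConductionVelocity = g@meanConductionVelocity,
    sdConductionVelocity = g@sdConductionVelocity,
    ctMeans = as.list(g@ctMeans), csaMeanLog = g@csaMeanLog,
    csaSdLog = g@csaSdLog, csaN = g@csaN)

#' Demo run configuration
#'
#' The bundled 2x2 cachexia cohort: published degradation constants planted
#' per group (see [demoGroups()]), the standard labelling protocol, mild
#' measurement noise and the default marker policy.
#'
#' @param seed master seed.
#' @param nAnimals animals per group.
#' @return a run-configuration list accepted by [runPipeline()] and
#'   serialisable with [writeRunConfig()].
#' @examples
#' cfg <- demoConfig(seed = 1)
#' @export
demoConfig <- function(seed = 1L, nAnimals = 8L) {
    list(
        seed = as.integer(seed),
        protocol = list(bolusDose = 20, waterEnrichment = 0.08,
                        labelDuration = 5, bodyWaterPool = 0.6,
                        waterTurnover = 0.3),
        noise = list(isotopomerSD = 2e-4, isotopomerCV = 0,
                     poolMarkerCV = 0.03, ctSD = 0.15),
        groups = lapply(demoGroups(nAnimals), .groupToList),
        nSites = 3.7,
        intakeFraction = 0.55,
        markerPolicy = list(myofibrillar = "marker", cytosolic = "steady",
                            mitochondrial = "marker"),
        stats = list(alpha = 0.05, ssType = "II"),
        referenceGene = "Rn18s",
        calibratorGroup = "WT/saline"
    )
}

#' Read / write a run configuration
#'
#' Run configurations are plain YAML; a snapshot written by the pipeline
#' re-executes to identical outputs.
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return \code{readRunConfig}: the configuration list;
#'   \code{writeRunConfig}: \code{path}, invisibly.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Run the full simulate - enrich - estimate - assays - stats pipeline
#'
#' Executes every stage on a configuration (see [demoConfig()]) and writes
#' per-stage CSV tables, a summary report (turnover by group x protein
#' fraction with group comparisons) and a log into \code{outDir}. All
#' randomness derives from \code{config$seed}; re-running the same
#' configuration reproduces the outputs exactly.
#'
#' @param config run-configuration list or path to its YAML file.
#' @param outDir output directory (created).
#' @return invisibly, a list with the dataset, turnover estimates, group
#'   summary, ANOVA/post hoc tables, assay outputs and the output paths.
#' @examples
#' res <- runPipeline(demoConfig(seed = 1, nAnimals = 3),
#'                    outDir = file.path(tempdir(), "demo_run"))
#' res$summary
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config)) config <- readRunConfig(config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    runLogReset()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }

    ## simulate
    dataset <- stage("simulate", {
        protocol <- do.call(labelingProtocol, config$protocol)
        noise <- noiseModel(
            isotopomerSD = config$noise$isotopomerSD %||% 0,
            isotopomerCV = config$noise$isotopomerCV %||% 0,
            poolMarkerCV = config$noise$poolMarkerCV %||% 0,
            ctSD = config$noise$ctSD %||% 0,
            seed = config$seed)
        groups <- lapply(config$groups, .groupFromList)
        simulateCohort(groups, protocol, noise,
                       nSites = config$nSites %||% 3.7,
                       intakeFraction = config$intakeFraction %||% 0.55)
    })
    writeStudyDataset(dataset, file.path(outDir, "simulated"))

    ## enrich + estimate
    estimates <- stage("estimate", {
        suppressMessages(estimateCohortTurnover(
            dataset, nSites = config$nSites %||% 3.7,
            markerPolicy = unlist(config$markerPolicy %||%
                c(myofibrillar = "marker", cytosolic = "steady",
                  mitochondrial = "marker"))))
    })
    utils::write.csv(estimates, file.path(outDir, "turnover.csv"),
                     row.names = FALSE)
    summary <- summarizeTurnover(estimates)
    utils::write.csv(summary, file.path(outDir, "turnover_summary.csv"),
                     row.names = FALSE)

    ## assays
    ani <- as.data.frame(animals(dataset))
    ctCols <- grep("^ct_", colnames(ani), value = TRUE)
    ctLong <- stage("assays", {
        data.frame(
            animal_id = rep(ani$animal_id, length(ctCols)),
            group = rep(paste(ani$genotype, ani$treatment, sep = "/"),
                        length(ctCols)),
            gene = rep(sub("^ct_", "", ctCols), each = nrow(ani)),
            ct = unlist(ani[, ctCols], use.names = FALSE))
    })
    expression <- ddct(ctLong,
                       referenceGene = config$referenceGene %||% "Rn18s",
                       calibratorGroup = config$calibratorGroup %||%
                           "WT/saline")
    utils::write.csv(expression, file.path(outDir, "expression_ddct.csv"),
                     row.names = FALSE)
    csa <- as.data.frame(fiberAreas(dataset))
    csa$group <- paste(ani$genotype, ani$treatment,
                       sep = "/")[match(csa$animal_id, ani$animal_id)]
    csaBins <- do.call(rbind, lapply(split(csa$area, csa$group),
        function(a) as.data.frame(t(binFiberCsa(a)$frequency))))
    csaBins <- data.frame(group = rownames(csaBins), csaBins,
                          row.names = NULL)
    utils::write.csv(csaBins, file.path(outDir, "fiber_csa_frequency.csv"),
                     row.names = FALSE)

    ## stats: two-way ANOVA + Tukey-Kramer on kdeg per fraction, and on
    ## conduction velocity
    alpha <- config$stats$alpha %||% 0.05
    ssType <- config$stats$ssType %||% "II"
    statRows <- list(); compRows <- list()
    for (fr in unique(estimates$fraction_id)) {
        d <- estimates[estimates$fraction_id == fr & estimates$valid, ]
        fit <- stage("stats", twoWayAnova(d$kdeg, d$genotype, d$treatment,
                                          ssType = ssType,
                                          factorNames = c("genotype",
                                                          "treatment")))
        tt <- anovaTable(fit); tt$response <- paste0("kdeg_", fr)
        statRows[[fr]] <- tt
        cmp <- suppressMessages(tukeyKramer(fit, alpha = alpha))
        if (nrow(cmp)) { cmp$response <- paste0("kdeg_", fr)
                         compRows[[fr]] <- cmp }
    }
    fitV <- stage("stats", twoWayAnova(ani$conduction_velocity,
                                       ani$genotype, ani$treatment,
                                       ssType = ssType,
                                       factorNames = c("genotype",
                                                       "treatment")))
    ttV <- anovaTable(fitV); ttV$response <- "conduction_velocity"
    statRows[["velocity"]] <- ttV
    cmpV <- suppressMessages(tukeyKramer(fitV, alpha = alpha))
    if (nrow(cmpV)) { cmpV$response <- "conduction_velocity"
                      compRows[["velocity"]] <- cmpV }
    anovaTab <- do.call(rbind, statRows); rownames(anovaTab) <- NULL
    utils::write.csv(anovaTab, file.path(outDir, "anova.csv"),
                     row.names = FALSE)
    compTab <- if (length(compRows)) do.call(rbind, compRows) else
        data.frame()
    rownames(compTab) <- NULL
    utils::write.csv(compTab, file.path(outDir, "comparisons.csv"),
                     row.names = FALSE)

    ## report + log
    rpt <- c("Turnover by group and protein fraction",
             "======================================",
             utils::capture.output(print(summary, row.names = FALSE)),
             "", "Run-log event counts:",
             paste(names(runLogCounts()), runLogCounts(), sep = " = "))
    writeLines(rpt, file.path(outDir, "report.txt"))
    writeLines(c(sprintf("d2oturnover %s",
                         as.character(utils::packageVersion("d2oturnover"))),
                 sprintf("R %s", getRversion()),
                 sprintf("seed: %d", config$seed),
                 sprintf("stages: simulate, estimate, assays, stats")),
               file.path(outDir, "run.log"))
    writeRunConfig(config, file.path(outDir, "config.yaml"))

    invisible(list(dataset = dataset, estimates = estimates,
                   summary = summary, anova = anovaTab,
                   comparisons = compTab, expression = expression,
                   csaFrequency = csaBins, outDir = outDir))
}
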