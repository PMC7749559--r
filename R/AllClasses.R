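#' @include AllGenerics.R
NULL

#' Heavy-water labelling protocol
#'
#' Describes how the deuterium label is delivered: an intraperitoneal bolus
#' of 99 atom\% D2O that rapidly equilibrates with the body-water pool,
#' followed by maintenance on D2O-supplemented drinking water for the
#' labelling window.
#'
#' @slot bolusDose bolus volume per body mass (uL of 99\% D2O per g).
#' @slot waterEnrichment molar fraction D2O in the drinking water (0-1).
#' @slot labelDuration labelling window in days.
#' @slot bodyWaterPool body-water volume per body mass (mL/g).
#' @slot waterTurnover first-order body-water turnover rate (1/day).
#'
#' @seealso [labelingProtocol()], [simulateBodyWater()]
#' @export
setClass("LabelingProtocol",
    representation(
        bolusDose      = "numeric",
        waterEnrichment = "numeric",
        labelDuration  = "numeric",
        bodyWaterPool  = "numeric",
        waterTurnover  = "numeric"
    )
)

setValidity("LabelingProtocol", function(object) {
    msg <- character()
    num1 <- function(x) length(x) == 1L && is.finite(x)
    for (s in slotNames(object)) {
        v <- slot(object, s)
        if (!num1(v)) msg <- c(msg, sprintf("'%s' must be a single finite number", s))
        else if (v < 0) msg <- c(msg, sprintf("'%s' must be >= 0", s))
    }
    if (num1(object@waterEnrichment) && object@waterEnrichment >= 0.5)
        msg <- c(msg, "'waterEnrichment' must be < 0.5 (molar fraction)")
    if (num1(object@labelDuration) && object@labelDuration <= 0)
        msg <- c(msg, "'labelDuration' must be > 0 days")
    if (length(msg)) msg else TRUE
})

#' Construct a labelling protocol
#'
#' Defaults follow a standard rodent D2O protocol: ~20 uL/g bolus of 99\%
#' D2O, 8\% D2O drinking water, 5-day label, 0.6 mL/g body water and a
#' body-water turnover of 0.3/day.
#'
#' @param bolusDose uL of 99\% D2O per g body weight.
#' @param waterEnrichment molar fraction D2O in drinking water.
#' @param labelDuration days of labelling.
#' @param bodyWaterPool mL body water per g body weight.
#' @param waterTurnover body-water turnover rate, 1/day.
#' @return a [LabelingProtocol-class] object.
#' @examples
#' labelingProtocol()
#' @export
labelingProtocol <- function(bolusDose = 20, waterEnrichment = 0.08,
                             labelDuration = 5, bodyWaterPool = 0.6,
                             waterTurnover = 0.3) {
    new("LabelingProtocol",
        bolusDose = as.numeric(bolusDose),
        waterEnrichment = as.numeric(waterEnrichment),
        labelDuration = as.numeric(labelDuration),
        bodyWaterPool = as.numeric(bodyWaterPool),
        waterTurnover = as.numeric(waterTurnover))
}

#' @rdname accessors
#' @export
setMethod("bolusDose", "LabelingProtocol", function(x) x@bolusDose)
#' @rdname accessors
#' @export
setMethod("waterEnrichment", "LabelingProtocol", function(x) x@waterEnrichment)
#' @rdname accessors
#' @export
setMethod("labelDuration", "LabelingProtocol", function(x) x@labelDuration)
#' @rdname accessors
#' @export
setMethod("bodyWaterPool", "LabelingProtocol", function(x) x@bodyWaterPool)
#' @rdname accessors
#' @export
setMethod("waterTurnover", "LabelingProtocol", function(x) x@waterTurnover)

setMethod("show", "LabelingProtocol", function(object) {
    cat("LabelingProtocol\n")
    cat(sprintf("  bolus:          %g uL/g of 99%% D2O\n", object@bolusDose))
    cat(sprintf("  drinking water: %g molar fraction D2O\n",
                object@waterEnrichment))
    cat(sprintf("  duration:       %g days\n", object@labelDuration))
    cat(sprintf("  body water:     %g mL/g, turnover %g/day\n",
                object@bodyWaterPool, object@waterTurnover))
})

#' Measurement-noise model for the synthetic cohort
#'
#' @slot isotopomerSD absolute Gaussian sd added to each isotopomer fraction.
#' @slot isotopomerCV Gaussian sd on isotopomer fractions expressed as a
#'   coefficient of variation relative to the true excess enrichment of the
#'   sample (0 disables); models noise that scales with the labelling signal.
#' @slot poolMarkerCV lognormal coefficient of variation on pool-size marker
#'   ratios (CoxIV densitometry, muscle mass ratios).
#' @slot ctSD Gaussian sd on qPCR Ct values, in cycles.
#' @slot seed master seed; per-animal substreams are derived by counter.
#' @seealso [noiseModel()]
#' @export
setClass("NoiseModel",
    representation(
        isotopomerSD = "numeric",
        isotopomerCV = "numeric",
        poolMarkerCV = "numeric",
        ctSD         = "numeric",
        seed         = "integer"
    )
)

setValidity("NoiseModel", function(object) {
    msg <- character()
    for (s in c("isotopomerSD", "isotopomerCV", "poolMarkerCV", "ctSD")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v < 0)
            msg <- c(msg, sprintf("'%s' must be a single number >= 0", s))
    }
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Construct a noise model
#'
#' @param isotopomerSD absolute sd on isotopomer fractions.
#' @param isotopomerCV sd on isotopomer fractions as a fraction of the true
#'   excess enrichment (signal-proportional noise).
#' @param poolMarkerCV lognormal CV on marker ratios.
#' @param ctSD sd on Ct values (cycles).
#' @param seed master random seed (integer).
#' @return a [NoiseModel-class] object. All-zero defaults give a noise-free,
#'   fully deterministic cohort.
#' @examples
#' noiseModel(isotopomerSD = 5e-4, seed = 11)
#' @export
noiseModel <- function(isotopomerSD = 0, isotopomerCV = 0, poolMarkerCV = 0,
                       ctSD = 0, seed = 1L) {
    new("NoiseModel",
        isotopomerSD = as.numeric(isotopomerSD),
        isotopomerCV = as.numeric(isotopomerCV),
        poolMarkerCV = as.numeric(poolMarkerCV),
        ctSD = as.numeric(ctSD),
        seed = as.integer(seed))
}

setMethod("show", "NoiseModel", function(object) {
    cat("NoiseModel\n")
    cat(sprintf("  isotopomer sd: %g (absolute) + %g x excess (CV)\n",
                object@isotopomerSD, object@isotopomerCV))
    cat(sprintf("  marker CV: %g, Ct sd: %g cycles, seed: %d\n",
                object@poolMarkerCV, object@ctSD, object@seed))
})

#' Specification of one experimental group
#'
#' One cell of the 2x2 factorial design (genotype x tumour implantation),
#' with planted kinetic ground truth per protein fraction and the
#' distributional parameters for the auxiliary per-animal measurements.
#'
#' @slot genotype "WT" or "Sod1KO".
#' @slot treatment "saline" or "LLC".
#' @slot nAnimals number of animals in the group.
#' @slot trueKsyn named numeric, synthesis rate per protein fraction
#'   (initial-pool fractions per day).
#' @slot trueKdeg named numeric, degradation rate constant per fraction
#'   (1/day); names must match \code{trueKsyn}.
#' @slot meanConductionVelocity group mean sciatic nerve conduction
#'   velocity (m/s).
#' @slot sdConductionVelocity per-animal sd of conduction velocity (m/s).
#' @slot ctMeans named numeric of mean Ct values per gene (cycles); must
#'   include the reference gene.
#' @slot csaMeanLog,csaSdLog lognormal parameters of the fibre
#'   cross-sectional-area distribution (log um^2).
#' @slot csaN fibres sampled per animal.
#' @seealso [groupSpec()]
#' @export
setClass("GroupSpec",
    representation(
        genotype  = "character",
        treatment = "character",
        nAnimals  = "integer",
        trueKsyn  = "numeric",
        trueKdeg  = "numeric",
        meanConductionVelocity = "numeric",
        sdConductionVelocity   = "numeric",
        ctMeans   = "numeric",
        csaMeanLog = "numeric",
        csaSdLog   = "numeric",
        csaN       = "integer"
    )
)

setValidity("GroupSpec", function(object) {
    msg <- character()
    if (!object@genotype %in% c("WT", "Sod1KO"))
        msg <- c(msg, "'genotype' must be \"WT\" or \"Sod1KO\"")
    if (!object@treatment %in% c("saline", "LLC"))
        msg <- c(msg, "'treatment' must be \"saline\" or \"LLC\"")
    if (length(object@nAnimals) != 1L || is.na(object@nAnimals) ||
        object@nAnimals < 1L)
        msg <- c(msg, "'nAnimals' must be >= 1")
    if (is.null(names(object@trueKsyn)) || is.null(names(object@trueKdeg)) ||
        !identical(names(object@trueKsyn), names(object@trueKdeg)))
        msg <- c(msg, "'trueKsyn' and 'trueKdeg' must share fraction names")
    if (any(object@trueKsyn < 0) || any(object@trueKdeg < 0))
        msg <- c(msg, "kinetic rates must be >= 0")
    if (object@sdConductionVelocity < 0)
        msg <- c(msg, "'sdConductionVelocity' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a group specification
#'
#' @param genotype "WT" or "Sod1KO".
#' @param treatment "saline" or "LLC".
#' @param nAnimals animals per group (the study used 6-8).
#' @param trueKsyn,trueKdeg named numerics over protein fractions
#'   (\code{myofibrillar}, \code{cytosolic}, \code{mitochondrial} or a
#'   subset); pool units are initial-pool fractions.
#' @param meanConductionVelocity,sdConductionVelocity m/s.
#' @param ctMeans named numeric of mean Ct per gene; must include the
#'   reference gene (default panel: Runx1, Gadd45a, AchRa, Sln, Rn18s).
#' @param csaMeanLog,csaSdLog,csaN lognormal fibre-CSA parameters and the
#'   number of fibres sampled per animal.
#' @return a [GroupSpec-class] object.
#' @examples
#' groupSpec("WT", "saline", nAnimals = 8,
#'           trueKsyn = c(myofibrillar = 0.00847),
#'           trueKdeg = c(myofibrillar = 0.00847))
#' @export
groupSpec <- function(genotype, treatment, nAnimals = 8L,
                      trueKsyn, trueKdeg,
                      meanConductionVelocity = 38.2,
                      sdConductionVelocity = 2.44,
                      ctMeans = c(Runx1 = 26, Gadd45a = 27, AchRa = 25,
                                  Sln = 24, Rn18s = 12),
                      csaMeanLog = log(1800), csaSdLog = 0.45,
                      csaN = 150L) {
    new("GroupSpec",
        genotype = genotype, treatment = treatment,
        nAnimals = as.integer(nAnimals),
        trueKsyn = trueKsyn, trueKdeg = trueKdeg,
        meanConductionVelocity = meanConductionVelocity,
        sdConductionVelocity = sdConductionVelocity,
        ctMeans = ctMeans,
        csaMeanLog = csaMeanLog, csaSdLog = csaSdLog,
        csaN = as.integer(csaN))
}

setMethod("show", "GroupSpec", function(object) {
    cat(sprintf("GroupSpec %s/%s (n = %d)\n", object@genotype,
                object@treatment, object@nAnimals))
    cat("  kdeg:", paste(sprintf("%s=%g", names(object@trueKdeg),
                                 object@trueKdeg), collapse = ", "), "\n")
    cat("  ksyn:", paste(sprintf("%s=%g", names(object@trueKsyn),
                                 object@trueKsyn), collapse = ", "), "\n")
})

#' First-order protein pool trajectory
#'
#' State of one protein pool obeying dP/dt = ksyn - kdeg * P over the
#' labelling window: initial and final pool size, the pool ratio
#' r = P(t)/P0, the mass of protein synthesised during the window that
#' survives to time t, and the equilibrium pool ksyn/kdeg.
#'
#' @slot ksyn synthesis rate (pool units/day).
#' @slot kdeg degradation rate constant (1/day).
#' @slot P0 pool size at label start (pool units).
#' @slot t labelling time (days).
#' @slot Pt pool size at time t.
#' @slot Nt new (label-eligible) protein mass at time t; \code{Nt <= Pt}.
#' @slot r pool ratio Pt/P0.
#' @slot Peq equilibrium pool ksyn/kdeg (Inf when kdeg = 0 and ksyn > 0).
#' @seealso [simulatePool()]
#' @export
setClass("PoolTrajectory",
    representation(
        ksyn = "numeric", kdeg = "numeric", P0 = "numeric", t = "numeric",
        Pt = "numeric", Nt = "numeric", r = "numeric", Peq = "numeric"
    )
)

setValidity("PoolTrajectory", function(object) {
    msg <- character()
    if (object@P0 <= 0) msg <- c(msg, "'P0' must be > 0")
    if (object@Pt <= 0) msg <- c(msg, "'Pt' must be > 0")
    if (object@kdeg < 0 || object@ksyn < 0)
        msg <- c(msg, "rates must be >= 0")
    if (abs(object@r - object@Pt / object@P0) > 1e-12 * max(1, object@r))
        msg <- c(msg, "'r' must equal Pt/P0")
    if (object@Nt > object@Pt * (1 + 1e-12))
        msg <- c(msg, "new protein mass cannot exceed the pool")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("kdeg", "PoolTrajectory", function(x) x@kdeg)
#' @rdname accessors
#' @export
setMethod("ksyn", "PoolTrajectory", function(x) x@ksyn)
#' @rdname accessors
#' @export
setMethod("poolRatio", "PoolTrajectory", function(x) x@r)
#' @rdname accessors
#' @export
setMethod("poolSize", "PoolTrajectory", function(x) x@Pt)
#' @rdname accessors
#' @export
setMethod("newProteinMass", "PoolTrajectory", function(x) x@Nt)
#' @rdname accessors
#' @export
setMethod("equilibriumPool", "PoolTrajectory", function(x) x@Peq)
#' @rdname accessors
#' @export
setMethod("labelDuration", "PoolTrajectory", function(x) x@t)

setMethod("show", "PoolTrajectory", function(object) {
    cat("PoolTrajectory\n")
    cat(sprintf("  ksyn = %g /day, kdeg = %g /day, t = %g d\n",
                object@ksyn, object@kdeg, object@t))
    cat(sprintf("  P0 = %g -> P(t) = %g (r = %.6g), new mass N(t) = %g\n",
                object@P0, object@Pt, object@r, object@Nt))
    cat(sprintf("  equilibrium pool = %g\n", object@Peq))
})

#' Mass isotopomer distribution of the alanine derivative
#'
#' Fractional abundances M0..Mk of the GC-MS alanine derivative for one
#' sample. Fractions are non-negative and sum to 1.
#'
#' @slot fractions numeric vector named M0..Mk, summing to 1.
#' @seealso [isotopomerDistribution()], [isotopomerize()],
#'   [correctNaturalAbundance()]
#' @export
setClass("IsotopomerDistribution",
    representation(fractions = "numeric"))

setValidity("IsotopomerDistribution", function(object) {
    f <- object@fractions
    msg <- character()
    if (length(f) < 2L) msg <- c(msg, "need at least M0 and M1")
    if (any(!is.finite(f)) || any(f < 0))
        msg <- c(msg, "fractions must be finite and >= 0")
    else if (abs(sum(f) - 1) > 1e-9)
        msg <- c(msg, sprintf("fractions must sum to 1 (got %.12g)", sum(f)))
    if (!identical(names(f), paste0("M", seq_along(f) - 1L)))
        msg <- c(msg, "fractions must be named M0, M1, ...")
    if (length(msg)) msg else TRUE
})

#' Construct an isotopomer distribution
#'
#' @param fractions numeric vector of fractional abundances (M0 first);
#'   names are (re)set to M0..Mk.
#' @return an [IsotopomerDistribution-class] object.
#' @examples
#' isotopomerDistribution(c(0.75, 0.2, 0.04, 0.01))
#' @export
isotopomerDistribution <- function(fractions) {
    fractions <- as.numeric(fractions)
    names(fractions) <- paste0("M", seq_along(fractions) - 1L)
    new("IsotopomerDistribution", fractions = fractions)
}

#' @rdname accessors
#' @export
setMethod("isotopomerFractions", "IsotopomerDistribution",
          function(x) x@fractions)

setMethod("show", "IsotopomerDistribution", function(object) {
    cat("IsotopomerDistribution:",
        paste(sprintf("%s=%.6g", names(object@fractions), object@fractions),
              collapse = "  "), "\n")
})

#' A simulated labelling cohort with ground truth
#'
#' Container for one in-silico labelling experiment: per-animal
#' measurements, long-format isotopomer and fibre-area tables, the planted
#' kinetic ground truth, and the protocol/noise configuration that produced
#' them. A fixed (configuration, seed) pair regenerates the object
#' bit-identically.
#'
#' @slot animals DataFrame, one row per animal: group labels, plasma
#'   body-water enrichment, marker ratios, Ct values, conduction velocity.
#' @slot isotopomers DataFrame, one row per animal x protein fraction with
#'   M0..M3 columns and the marker pool ratio for that fraction.
#' @slot fiberCSA DataFrame of individual fibre cross-sectional areas.
#' @slot truth DataFrame of planted per-animal kinetic parameters.
#' @slot protocol the [LabelingProtocol-class] used.
#' @slot noise the [NoiseModel-class] used.
#' @slot config list snapshot of generator settings (provenance).
#' @seealso [simulateCohort()]
#' @export
setClass("StudyDataset",
    representation(
        animals     = "DataFrame",
        isotopomers = "DataFrame",
        fiberCSA    = "DataFrame",
        truth       = "DataFrame",
        protocol    = "LabelingProtocol",
        noise       = "NoiseModel",
        config      = "list"
    )
)

setValidity("StudyDataset", function(object) {
    msg <- character()
    need <- c("animal_id", "genotype", "treatment", "body_water")
    if (!all(need %in% colnames(object@animals)))
        msg <- c(msg, paste("animals table must contain:",
                            paste(need, collapse = ", ")))
    if (!all(c("animal_id", "fraction_id") %in%
             colnames(object@isotopomers)))
        msg <- c(msg, "isotopomers table must contain animal_id, fraction_id")
    if (!all(object@isotopomers$animal_id %in% object@animals$animal_id))
        msg <- c(msg, "isotopomer rows reference unknown animals")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("animals", "StudyDataset", function(x) x@animals)
#' @rdname accessors
#' @export
setMethod("isotopomers", "StudyDataset", function(x) x@isotopomers)
#' @rdname accessors
#' @export
setMethod("fiberAreas", "StudyDataset", function(x) x@fiberCSA)
#' @rdname accessors
#' @export
setMethod("groundTruth", "StudyDataset", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("protocol", "StudyDataset", function(x) x@protocol)
#' @rdname accessors
#' @export
setMethod("ctValues", "StudyDataset", function(x) {
    ct <- grep("^ct_", colnames(x@animals), value = TRUE)
    x@animals[, c("animal_id", "genotype", "treatment", ct)]
})

setMethod("show", "StudyDataset", function(object) {
    a <- object@animals
    cat(sprintf("StudyDataset: %d animals, %d groups, %d protein fractions\n",
                nrow(a), length(unique(paste(a$genotype, a$treatment))),
                length(unique(object@isotopomers$fraction_id))))
    cat(sprintf("  label: %g d; seed %d; noise: iso sd %g / CV %g, marker CV %g\n",
                object@protocol@labelDuration, object@noise@seed,
                object@noise@isotopomerSD, object@noise@isotopomerCV,
                object@noise@poolMarkerCV))
})

#' Two-way factorial ANOVA result
#'
#' Decomposition of a two-factor design into main effects, interaction and
#' residual, with cell means retained for post hoc comparison.
#'
#' @slot terms data.frame with one row per term (factorA, factorB,
#'   interaction, residual): df, sum of squares, mean square, F, p.
#' @slot cellMeans data.frame of cell means and counts (factorA, factorB,
#'   mean, n).
#' @slot mse residual mean square.
#' @slot dfResidual residual degrees of freedom.
#' @slot ssTotal total sum of squares.
#' @slot ssType "II" or "III".
#' @slot factorNames names of the two factors.
#' @slot degenerate TRUE when the response is constant (no variance to
#'   partition; F and p are undefined and reported as NA).
#' @seealso [twoWayAnova()], [tukeyKramer()]
#' @export
setClass("AnovaResult",
    representation(
        terms      = "data.frame",
        cellMeans  = "data.frame",
        mse        = "numeric",
        dfResidual = "numeric",
        ssTotal    = "numeric",
        ssType     = "character",
        factorNames = "character",
        degenerate = "logical"
    )
)

setValidity("AnovaResult", function(object) {
    msg <- character()
    if (any(object@terms$df < 0)) msg <- c(msg, "negative degrees of freedom")
    if (!object@ssType %in% c("II", "III"))
        msg <- c(msg, "ssType must be \"II\" or \"III\"")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("anovaTable", "AnovaResult", function(x) x@terms)
#' @rdname accessors
#' @export
setMethod("cellMeans", "AnovaResult", function(x) x@cellMeans)
#' @rdname accessors
#' @export
setMethod("residualDf", "AnovaResult", function(x) x@dfResidual)
#' @rdname accessors
#' @export
setMethod("meanSquaredError", "AnovaResult", function(x) x@mse)
#' @rdname accessors
#' @export
setMethod("isDegenerate", "AnovaResult", function(x) x@degenerate)

setMethod("show", "AnovaResult", function(object) {
    cat(sprintf("Two-way ANOVA (%s x %s), type %s SS%s\n",
                object@factorNames[1], object@factorNames[2], object@ssType,
                if (object@degenerate) " [degenerate: constant response]"
                else ""))
    tt <- object@terms
    tt$SS <- signif(tt$SS, 6); tt$MS <- signif(tt$MS, 6)
    tt$F <- signif(tt$F, 5); tt$p <- signif(tt$p, 5)
    print(tt, row.names = FALSE)
})
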