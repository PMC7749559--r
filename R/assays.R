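#' @include cohort.R
NULL

#' Relative gene expression by the delta-delta-Ct method
#'
#' For each animal and target gene, \eqn{\Delta CT = CT_{target} -
#' CT_{reference}}; \eqn{\Delta\Delta CT} is taken against the calibrator
#' group's mean \eqn{\Delta CT}, and relative quantity is
#' \eqn{2^{-\Delta\Delta CT}}. By construction the calibrator group's mean
#' relative quantity is 1 for every gene (geometric mean scale).
#'
#' Animals missing the reference gene are excluded with a warning.
#'
#' @param ct long-format data.frame with columns \code{animal_id},
#'   \code{group}, \code{gene}, \code{ct} (cycles, > 0).
#' @param referenceGene housekeeping gene name (default \code{"Rn18s"}).
#' @param calibratorGroup group label used as the expression baseline.
#' @return data.frame with \code{animal_id}, \code{group}, \code{gene},
#'   \code{dct}, \code{ddct}, \code{rq} (relative quantity).
#' @examples
#' ct <- data.frame(animal_id = rep(c("a1", "a2"), each = 2),
#'                  group = rep(c("WT", "KO"), each = 2),
#'                  gene = rep(c("Runx1", "Rn18s"), 2),
#'                  ct = c(26, 12, 25, 12))
#' ddct(ct, calibratorGroup = "WT")
#' @export
ddct <- function(ct, referenceGene = "Rn18s", calibratorGroup) {
    stopifnot(all(c("animal_id", "group", "gene", "ct") %in% colnames(ct)))
    if (any(ct$ct <= 0)) stop("Ct values must be > 0 cycles")
    if (!calibratorGroup %in% ct$group)
        stop("calibrator group not present: ", calibratorGroup)
    refCt <- ct[ct$gene == referenceGene, c("animal_id", "ct")]
    hasRef <- ct$animal_id %in% refCt$animal_id
    if (!all(hasRef)) {
        warning(sprintf("%d animal(s) lack the reference gene; excluded",
                        length(unique(ct$animal_id[!hasRef]))))
        ct <- ct[hasRef, , drop = FALSE]
    }
    tgt <- ct[ct$gene != referenceGene, , drop = FALSE]
    tgt$dct <- tgt$ct - refCt$ct[match(tgt$animal_id, refCt$animal_id)]
    calMean <- tapply(tgt$dct[tgt$group == calibratorGroup],
                      tgt$gene[tgt$group == calibratorGroup], mean)
    tgt$ddct <- tgt$dct - calMean[tgt$gene]
    tgt$rq <- 2^(-tgt$ddct)
    tgt[, c("animal_id", "group", "gene", "dct", "ddct", "rq")]
}

#' Normalise a respirometry trace
#'
#' Subtracts the antimycin-A state (non-mitochondrial oxygen consumption)
#' from every respiration state and divides by the fibre-bundle wet weight.
#' The TMPD/complex-IV state follows the same subtraction by default (set
#' \code{subtractTMPD = FALSE} to exempt it, e.g. when handling
#' ascorbate/TMPD autoxidation separately). Negative corrected fluxes are
#' clamped to zero with a warning.
#'
#' @param flux named numeric of raw oxygen fluxes per state; must contain
#'   \code{"antimycinA"}.
#' @param wetWeight bundle wet weight, mg (> 0).
#' @param subtractTMPD apply the antimycin-A subtraction to the TMPD state
#'   (default TRUE).
#' @return named numeric of corrected fluxes per mg wet weight; the
#'   antimycin-A state itself is dropped (it is the zero point).
#' @examples
#' normalizeOcr(c(state1 = 4, CI = 12, antimycinA = 2), wetWeight = 2)
#' @export
normalizeOcr <- function(flux, wetWeight, subtractTMPD = TRUE) {
    stopifnot(is.numeric(flux), !is.null(names(flux)))
    if (!"antimycinA" %in% names(flux))
        stop("trace must contain an 'antimycinA' state")
    if (!is.finite(wetWeight) || wetWeight <= 0)
        stop("'wetWeight' must be > 0 mg")
    ama <- flux[["antimycinA"]]
    out <- flux[setdiff(names(flux), "antimycinA")]
    sub <- rep(ama, length(out))
    if (!subtractTMPD) sub[names(out) == "TMPD"] <- 0
    out <- (out - sub) / wetWeight
    if (any(out < 0)) {
        warning(sprintf("%d state(s) below the antimycin-A floor; clamped to 0",
                        sum(out < 0)))
        out[out < 0] <- 0
    }
    out
}

#' Bin muscle fibre cross-sectional areas
#'
#' Small fibres are 200-1200 um^2 (inclusive at both edges), large fibres
#' are > 2400 um^2, and "average" fibres are the complement (1200, 2400].
#' Areas below 200 um^2 are reported separately as sub-threshold and do not
#' enter the frequency distribution.
#'
#' @param areas numeric vector of fibre areas, um^2 (>= 0).
#' @param edges bin boundaries \code{c(lower, smallUpper, largeLower)},
#'   default \code{c(200, 1200, 2400)}.
#' @return list with \code{counts} (named integer: small, average, large,
#'   subthreshold) and \code{frequency} (small/average/large proportions of
#'   the >= lower-edge fibres).
#' @examples
#' binFiberCsa(c(150, 800, 1200, 2000, 2500))
#' @export
binFiberCsa <- function(areas, edges = c(200, 1200, 2400)) {
    stopifnot(length(edges) == 3L, !is.unsorted(edges))
    if (length(areas) == 0)
        return(list(counts = c(small = 0L, average = 0L, large = 0L,
                               subthreshold = 0L),
                    frequency = c(small = NaN, average = NaN, large = NaN)))
    if (any(!is.finite(areas)) || any(areas < 0))
        stop("'areas' must be finite and >= 0")
    counts <- c(
        small = sum(areas >= edges[1] & areas <= edges[2]),
        average = sum(areas > edges[2] & areas <= edges[3]),
        large = sum(areas > edges[3]),
        subthreshold = sum(areas < edges[1]))
    total <- sum(counts[c("small", "average", "large")])
    freq <- counts[c("small", "average", "large")] / total
    list(counts = vapply(counts, as.integer, 1L), frequency = freq)
}

#' Tumour-free normalised muscle mass
#'
#' Muscle mass per gram of tumour-free body weight,
#' \code{muscleMass / (bodyWeight - tumourWeight)}.
#'
#' @param muscleMass mg.
#' @param bodyWeight g.
#' @param tumourWeight g (0 for saline controls); must be < bodyWeight.
#' @return normalised mass, mg/g (vectorised).
#' @examples
#' normalizeMass(100, 25, 5)  # 5 mg/g
#' @export
normalizeMass <- function(muscleMass, bodyWeight, tumourWeight = 0) {
    n <- max(length(muscleMass), length(bodyWeight), length(tumourWeight))
    muscleMass <- rep_len(muscleMass, n)
    bodyWeight <- rep_len(bodyWeight, n)
    tumourWeight <- rep_len(tumourWeight, n)
    if (any(tumourWeight < 0)) stop("'tumourWeight' must be >= 0")
    if (any(tumourWeight >= bodyWeight))
        stop("'tumourWeight' must be smaller than 'bodyWeight'")
    muscleMass / (bodyWeight - tumourWeight)
}
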