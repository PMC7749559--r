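#' @include assays.R
NULL

#' Two-way factorial ANOVA
#'
#' Decomposes a response over two crossed factors (here genotype and tumour
#' implantation) into main effects, interaction and residual. Balanced
#' designs use the classical cell-means decomposition directly; unbalanced
#' designs (the study had n = 6-8 with mid-study deaths) use Type-II sums
#' of squares by default — each main effect adjusted for the other, the
#' interaction adjusted for both — computed from nested least-squares fits.
#' Type-III (each term adjusted for all others under sum contrasts) is
#' available by flag. On balanced data all types coincide.
#'
#' A constant response has no variance to partition: the result is flagged
#' degenerate and F/p are reported as NA rather than NaN.
#'
#' @param values numeric response vector.
#' @param factorA,factorB factor labels (coerced to factor), same length as
#'   \code{values}; every combination of levels must be observed.
#' @param ssType "II" (default) or "III".
#' @param factorNames length-2 character used in the output table.
#' @return an [AnovaResult-class].
#' @examples
#' d <- expand.grid(g = c("WT", "KO"), tr = c("sal", "LLC"),
#'                  rep = 1:3)
#' y <- rnorm(nrow(d)) + (d$g == "KO") * 2 + (d$tr == "LLC")
#' twoWayAnova(y, d$g, d$tr)
#' @export
twoWayAnova <- function(values, factorA, factorB, ssType = c("II", "III"),
                        factorNames = c("factorA", "factorB")) {
    ssType <- match.arg(ssType)
    stopifnot(length(values) == length(factorA),
              length(values) == length(factorB))
    if (any(!is.finite(values))) stop("'values' must be finite")
    A <- factor(factorA); B <- factor(factorB)
    if (nlevels(A) < 2L || nlevels(B) < 2L)
        stop("each factor needs at least 2 levels")
    tab <- table(A, B)
    if (any(tab == 0))
        stop("empty design cell(s): interaction is inestimable")
    n <- length(values)
    a <- nlevels(A); b <- nlevels(B)
    dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB
    dfE <- n - a * b
    if (dfE < 2L) stop("need at least 2 residual degrees of freedom")

    cm <- aggregate(values, list(A = A, B = B), mean)
    names(cm) <- c(factorNames, "mean")
    cnt <- aggregate(values, list(A = A, B = B), length)
    cm$n <- cnt$x

    ssTotal <- sum((values - mean(values))^2)
    degenerate <- ssTotal <= .Machine$double.eps * n * max(1, mean(values)^2)

    balanced <- length(unique(tab)) == 1L
    if (balanced) {
        # classical decomposition from marginal and cell means
        ni <- tab[1, 1]
        mA <- tapply(values, A, mean); mB <- tapply(values, B, mean)
        mAB <- tapply(values, list(A, B), mean)
        gm <- mean(values)
        ssA <- ni * b * sum((mA - gm)^2)
        ssB <- ni * a * sum((mB - gm)^2)
        ssAB <- ni * sum((outer(mA - gm, mB - gm, `+`) + gm - mAB)^2)
        ssE <- ssTotal - ssA - ssB - ssAB
    } else {
        rss <- function(fml) {
            fit <- stats::lm.fit(stats::model.matrix(fml,
                data.frame(A = A, B = B)), values)
            sum(fit$residuals^2)
        }
        op <- options(contrasts = c("contr.sum", "contr.poly"))
        on.exit(options(op))
        rssFull <- rss(~ A * B)
        if (ssType == "II") {
            rssAB <- rss(~ A + B)
            ssA <- rss(~ B) - rssAB
            ssB <- rss(~ A) - rssAB
            ssAB <- rssAB - rssFull
        } else {
            # Type III under sum-to-zero contrasts: drop one term at a time
            X <- stats::model.matrix(~ A * B, data.frame(A = A, B = B))
            asn <- attr(X, "assign")
            dropSS <- function(term) {
                keep <- asn != term
                fit <- stats::lm.fit(X[, keep, drop = FALSE], values)
                sum(fit$residuals^2) - rssFull
            }
            ssA <- dropSS(1L); ssB <- dropSS(2L); ssAB <- dropSS(3L)
        }
        ssE <- rssFull
    }
    mse <- ssE / dfE
    terms <- data.frame(
        term = c(factorNames[1], factorNames[2],
                 paste(factorNames, collapse = ":"), "residual"),
        df = c(dfA, dfB, dfAB, dfE),
        SS = c(ssA, ssB, ssAB, ssE))
    terms$MS <- terms$SS / terms$df
    if (degenerate || mse <= 0) {
        terms$F <- c(NA_real_, NA_real_, NA_real_, NA_real_)
        terms$p <- terms$F
    } else {
        terms$F <- c(terms$MS[1:3] / mse, NA_real_)
        terms$p <- c(stats::pf(terms$F[1:3],
                               terms$df[1:3], dfE, lower.tail = FALSE),
                     NA_real_)
    }
    new("AnovaResult", terms = terms, cellMeans = cm, mse = mse,
        dfResidual = as.numeric(dfE), ssTotal = ssTotal, ssType = ssType,
        factorNames = factorNames, degenerate = degenerate)
}
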