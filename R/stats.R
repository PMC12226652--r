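#' @include AllClasses.R
NULL

#' Two-way absolute-agreement single-measurement ICC
#'
#' ICC(A,1): the two-way, absolute-agreement, single-measurement intraclass
#' correlation from the two-way ANOVA decomposition of an n x k design
#' (subjects = materials in rows, protocols in columns):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}.}
#' Absolute agreement (rather than consistency) penalizes systematic
#' protocol offsets, paralleling the concordance correlation coefficient.
#'
#' @param values numeric n x k matrix, no missing cells, n >= 2, k >= 2.
#' @return list with `icc`, the mean squares `ms_rows`, `ms_cols`, `ms_err`,
#'   `n`, `k`, and a `degenerate` flag (TRUE when all values are identical,
#'   in which case the ICC is defined as 1).
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
#' iccAbsoluteAgreement(m)$icc
#' @export
iccAbsoluteAgreement <- function(values) {
    values <- as.matrix(values)
    n <- nrow(values)
    k <- ncol(values)
    if (n < 2 || k < 2) stop("need at least 2 subjects and 2 columns")
    if (any(!is.finite(values))) stop("non-finite values in the design")
    grand <- mean(values)
    rm_ <- rowMeans(values)
    cm_ <- colMeans(values)
    msr <- k * sum((rm_ - grand)^2) / (n - 1)
    msc <- n * sum((cm_ - grand)^2) / (k - 1)
    resid <- values - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
    mse <- sum(resid^2) / ((n - 1) * (k - 1))
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    degenerate <- denom <= .Machine$double.eps * max(1, abs(grand))^2
    icc <- if (degenerate) 1 else (msr - mse) / denom
    list(icc = icc, ms_rows = msr, ms_cols = msc, ms_err = mse,
         n = n, k = k, degenerate = degenerate)
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with moment estimators using denominator n (Lin's original definition;
#' the n vs n-1 choice changes values at small n and is therefore fixed and
#' documented).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the CCC; exactly 1 (with attribute `degenerate = TRUE`) when both
#'   inputs are constant and equal.
#' @examples
#' linCCC(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
linCCC <- function(x, y) {
    if (length(x) != length(y)) stop("length mismatch")
    n <- length(x)
    if (n < 2) stop("need at least 2 observations")
    if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
    mx <- mean(x); my <- mean(y)
    sxy <- mean((x - mx) * (y - my))
    sx2 <- mean((x - mx)^2)
    sy2 <- mean((y - my)^2)
    den <- sx2 + sy2 + (mx - my)^2
    if (den <= 0) {
        out <- 1
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    2 * sxy / den
}

#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / |mean(x)|` with the sample SD (denominator n - 1). The
#' absolute value in the denominator keeps the CV sign-free for legitimately
#' negative-valued features; a zero mean makes the CV undefined and `NA` is
#' returned (callers count and exclude such cases).
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent, or `NA_real_` when the mean is 0.
#' @export
coefficientOfVariation <- function(values) {
    if (length(values) < 2) stop("need at least 2 values")
    m <- mean(values)
    if (m == 0) return(NA_real_)
    100 * sd(values) / abs(m)
}

#' Quartile coefficient of dispersion (percent)
#'
#' `100 * (Q3 - Q1) / |Q3 + Q1|` with linear-interpolation (type 7)
#' quantiles — the convention matters at the small sample sizes used here
#' (13 protocols, pairs of 2) and is therefore fixed. `NA` when
#' `Q3 + Q1 = 0`.
#'
#' @param values numeric vector, length >= 2.
#' @return QCD in percent, or `NA_real_` when undefined.
#' @examples
#' quartileCoefficientOfDispersion(1:5)  # 33.33
#' @export
quartileCoefficientOfDispersion <- function(values) {
    if (length(values) < 2) stop("need at least 2 values")
    q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
    den <- q[1] + q[2]
    if (den == 0) return(NA_real_)
    100 * (q[2] - q[1]) / abs(den)
}

#' Interpretation bins for reliability and variability values
#'
#' Reliability (ICC/CCC): poor < 0.50, moderate 0.50-0.75, good 0.75-0.90,
#' excellent >= 0.90. Variability (CV/QCD, percent): acceptable < 10,
#' moderate 10-20, inadequate >= 20 (the half-open `[10, 20)` bin resolves
#' the gap between "< 10" and "11-20" in the textual definition).
#' `NA` values map to the explicit `"undefined"` bin.
#'
#' @param values numeric vector of ICC/CCC or CV/QCD values.
#' @param metric `"reliability"` or `"variability"`.
#' @return character vector of bin labels.
#' @examples
#' classifyRobustness(c(0.95, 0.6), "reliability")  # excellent, moderate
#' classifyRobustness(c(5, 15, 25), "variability")
#' @export
classifyRobustness <- function(values, metric = c("reliability", "variability")) {
    metric <- match.arg(metric)
    out <- character(length(values))
    na <- is.na(values)
    out[na] <- "undefined"
    v <- values[!na]
    out[!na] <- if (metric == "reliability") {
        ifelse(v >= 0.90, "excellent",
            ifelse(v >= 0.75, "good",
                ifelse(v >= 0.50, "moderate", "poor")))
    } else {
        ifelse(v >= 20, "inadequate",
            ifelse(v >= 10, "moderate", "acceptable"))
    }
    out
}

#' Bin labels of each robustness metric
#'
#' @param metric `"reliability"` or `"variability"`.
#' @return character vector of bin labels in display order, including the
#'   explicit `"undefined"` bin.
#' @export
robustnessBins <- function(metric = c("reliability", "variability")) {
    metric <- match.arg(metric)
    if (metric == "reliability")
        c("poor", "moderate", "good", "excellent", "undefined")
    else c("acceptable", "moderate", "inadequate", "undefined")
}
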