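## Power-law depth models S_Z = S_ref * (Z / Z_ref)^b fitted to SASV
## fraction profiles by nonlinear least squares on the linear scale
## (Levenberg-Marquardt, initialized from log-log regression), after the
## Martin-curve description of particle flux attenuation.

#' Fit a power law to a depth profile
#'
#' Fits `S = sRef * (Z/zRef)^b` by unweighted nonlinear least squares on
#' the linear scale, with free parameters `(sRef, b)` initialized from
#' ordinary log-log regression. Depths outside `window` are excluded (the
#' canonical upper-ocean fit excludes depths shallower than the 75 m
#' reference; the deep trap-side fit starts at 250 m). Reports R-squared on
#' the linear scale, a two-sided p-value for b = 0 from the t statistic of
#' b with df = n - 2, and a two-sigma (95 percent) confidence interval
#' `b +/- 2 SE(b)`.
#'
#' Degenerate profiles are handled explicitly: a constant profile returns
#' `b = 0` with undefined R-squared and p = 1; a fit with zero residual and
#' nonzero slope reports the smallest representable p-value; two-point
#' fits are exact and carry no error estimate (`NA`).
#'
#' @param depths numeric depths, metres.
#' @param values profile values (fractions or any positive scale) parallel
#'   to `depths`; a `DepthProfileStat` data.frame from [profileOverTime()]
#'   may be passed as `depths` with `values` omitted.
#' @param zRef reference depth, metres.
#' @param window length-2 numeric, inclusive depth window to fit.
#' @param scale `"fraction"` (default) or `"percent"`, recorded in the
#'   result for display.
#' @return a [PowerLawFit-class].
#' @examples
#' z <- c(75, 150, 300)
#' fitPowerLaw(z, 0.829 * (z / 75)^-1.34, zRef = 75)
#' @export
fitPowerLaw <- function(depths, values = NULL, zRef = 75,
                        window = c(zRef, Inf), scale = "fraction") {
    if (is.data.frame(depths)) {
        values <- depths$mean
        depths <- depths$depth_m
    }
    keep <- depths >= window[1] & depths <= window[2]
    z <- depths[keep]
    y <- values[keep]
    if (length(z) < 2L)
        stop("fewer than 2 depths inside the fit window")
    if (any(y <= 0))
        stop("nonpositive profile value inside the window at depth(s) ",
             paste(z[y <= 0], collapse = ", "), " m")
    ord <- order(z)
    z <- z[ord]; y <- y[ord]
    n <- length(z)

    mkFit <- function(b, s, se, r2, p, note = "") {
        ci <- if (is.na(se)) c(NA_real_, NA_real_) else b + c(-2, 2) * se
        methods::new("PowerLawFit", zRef = zRef, sRef = s, b = b, se = se,
                     r2 = r2, pValue = p, ciB = ci, nPoints = as.integer(n),
                     depthWindow = c(min(z), max(z)), scale = scale,
                     note = note)
    }

    ssTot <- sum((y - mean(y))^2)
    if (ssTot == 0)  # flat profile: b = 0 exactly, R2 undefined
        return(mkFit(0, y[1], 0, NA_real_, 1,
                     note = "constant profile; R2 undefined"))

    x <- z / zRef
    init <- stats::lm(log(y) ~ log(x))
    start <- list(s = exp(stats::coef(init)[[1]]), b = stats::coef(init)[[2]])
    fit <- minpack.lm::nlsLM(y ~ s * x^b, start = start,
                             control = minpack.lm::nls.lm.control(
                                 maxiter = 200))
    cf <- stats::coef(fit)
    b <- cf[["b"]]; s <- cf[["s"]]
    ssRes <- sum(stats::residuals(fit)^2)
    r2 <- 1 - ssRes / ssTot

    if (n == 2L)  # exact interpolation, no residual degrees of freedom
        return(mkFit(b, s, NA_real_, r2, NA_real_,
                     note = "two-point fit; no error estimate"))

    se <- tryCatch(sqrt(stats::vcov(fit)["b", "b"]),
                   error = function(e) NA_real_)
    if (is.na(se) || !is.finite(se)) se <- 0
    if (se == 0) {
        p <- if (b == 0) 1 else .Machine$double.xmin
        note <- if (b == 0) "" else
            "zero-residual fit; p below machine precision"
        return(mkFit(b, s, se, r2, p, note = note))
    }
    tStat <- b / se
    p <- max(2 * stats::pt(-abs(tStat), df = n - 2), .Machine$double.xmin)
    mkFit(b, s, se, r2, p)
}

#' Refit a profile at a different reference depth
#'
#' An independent fit anchored at `newZRef`, with the window moved to start
#' there (the reference-depth sensitivity analysis: on noiseless power-law
#' data b is reference-invariant and `sRef` rescales as `(new/old)^b`; on
#' noisy data both may change). If `newZRef` lies outside the data span the
#' fit still proceeds with an extrapolated reference, with a warning.
#'
#' @param depths,values,scale as in [fitPowerLaw()].
#' @param newZRef new reference depth, metres.
#' @param window fit window; default `c(newZRef, Inf)`.
#' @return a [PowerLawFit-class].
#' @export
refitReference <- function(depths, values = NULL, newZRef,
                           window = c(newZRef, Inf), scale = "fraction") {
    if (is.data.frame(depths)) {
        values <- depths$mean
        depths <- depths$depth_m
    }
    if (newZRef < min(depths) || newZRef > max(depths))
        warning(sprintf(
            "reference depth %g m is outside the data span %g-%g m; sRef extrapolated",
            newZRef, min(depths), max(depths)))
    fitPowerLaw(depths, values, zRef = newZRef, window = window,
                scale = scale)
}

#' Per-interval power-law fits (b time series)
#'
#' Fits one power law per trap collection interval from a per-(interval,
#' depth) fraction table. Intervals with fewer than two usable depths, or
#' whose fit fails, are skipped with a warning; zero fittable intervals is
#' an error.
#'
#' @param tbl fraction table from [sasvFractionTable()].
#' @param zRef,window,value as in [fitPowerLaw()] / [profileOverTime()].
#' @return data.frame (one row per fitted interval) with columns
#'   `sample_id`, `b`, `s_ref`, `se_b`, `r2`, `p_value`, `ci_low`,
#'   `ci_high`, `n_points`; the full [PowerLawFit-class] objects are
#'   attached as `attr(, "fits")`.
#' @export
fitPerInterval <- function(tbl, zRef = 75, window = c(zRef, Inf),
                           value = "water_fraction") {
    ids <- unique(tbl$sample_id)
    rows <- list(); fits <- list()
    for (s in ids) {
        sub <- tbl[tbl$sample_id == s, ]
        f <- tryCatch(
            fitPowerLaw(sub$depth_m, sub[[value]], zRef = zRef,
                        window = window),
            error = function(e) {
                warning(sprintf("interval %s skipped: %s", s,
                                conditionMessage(e)))
                NULL
            })
        if (is.null(f)) next
        fits[[s]] <- f
        rows[[s]] <- data.frame(
            sample_id = s, b = f@b, s_ref = f@sRef, se_b = f@se, r2 = f@r2,
            p_value = f@pValue, ci_low = f@ciB[1], ci_high = f@ciB[2],
            n_points = f@nPoints)
    }
    if (!length(rows))
        stop("no interval had enough usable depths to fit")
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "fits") <- fits
    out
}

#' Correlate per-interval b coefficients with environmental covariates
#'
#' Spearman rank correlation by default (Pearson available), on
#' pairwise-complete observations, two-sided p-values. A constant covariate
#' (or fewer than three complete pairs) is reported as undefined rather
#' than failing.
#'
#' @param bSeries data.frame from [fitPerInterval()], or a numeric vector
#'   of b coefficients.
#' @param covariates data.frame of numeric covariates, rows aligned with
#'   `bSeries`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with columns `covariate`, `n`, `estimate`,
#'   `p_value`, `note`.
#' @export
correlateBCovariates <- function(bSeries, covariates,
                                 method = c("spearman", "pearson")) {
    method <- match.arg(method)
    b <- if (is.data.frame(bSeries)) bSeries$b else bSeries
    if (nrow(covariates) != length(b))
        stop("covariates must have one row per b coefficient")
    rows <- lapply(colnames(covariates), function(nm) {
        v <- covariates[[nm]]
        ok <- stats::complete.cases(b, v)
        if (sum(ok) < 3L)
            return(data.frame(covariate = nm, n = sum(ok),
                              estimate = NA_real_, p_value = NA_real_,
                              note = "fewer than 3 complete pairs"))
        if (stats::sd(v[ok]) == 0)
            return(data.frame(covariate = nm, n = sum(ok),
                              estimate = NA_real_, p_value = NA_real_,
                              note = "constant covariate; undefined"))
        ct <- suppressWarnings(stats::cor.test(
            b[ok], v[ok], method = method, exact = FALSE))
        data.frame(covariate = nm, n = sum(ok),
                   estimate = unname(ct$estimate),
                   p_value = ct$p.value, note = "")
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
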