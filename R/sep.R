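## Summer export pulse (SEP): flagging trap intervals whose particulate C
## and N fluxes both reach 150 percent of the annual reference means, and
## identifying SASVs enriched in the deep trap during SEP via Welch's
## t-test.

#' Flag summer-export-pulse intervals from flux data
#'
#' An interval is SEP when both the particulate carbon and the particulate
#' nitrogen flux reach `factor` (default 1.5, inclusive) times their annual
#' reference means. With `any = TRUE` either flux suffices. Intervals with
#' missing flux are flagged `NA` with a warning and should be excluded
#' downstream.
#'
#' @param flux data.frame as from [readFluxTable()]; reference means are
#'   taken from columns `pc_ref_mean` / `pn_ref_mean` unless supplied.
#' @param factor flux-to-reference ratio threshold (inclusive).
#' @param pcRef,pnRef reference means overriding the table columns.
#' @param any relax the AND of the two ratios to an OR.
#' @return `flux` with added columns `pc_ratio`, `pn_ratio`, `is_sep`.
#' @export
flagSep <- function(flux, factor = 1.5, pcRef = NULL, pnRef = NULL,
                    any = FALSE) {
    if (is.null(pcRef)) pcRef <- flux$pc_ref_mean
    if (is.null(pnRef)) pnRef <- flux$pn_ref_mean
    if (is.null(pcRef) || is.null(pnRef))
        stop("reference means needed: pc_ref_mean/pn_ref_mean columns ",
             "or pcRef/pnRef arguments")
    if (base::any(pcRef <= 0, na.rm = TRUE) ||
        base::any(pnRef <= 0, na.rm = TRUE))
        stop("reference means must be positive")
    out <- flux
    out$pc_ratio <- flux$pc_flux / pcRef
    out$pn_ratio <- flux$pn_flux / pnRef
    out$is_sep <- if (any)
        out$pc_ratio >= factor | out$pn_ratio >= factor
    else
        out$pc_ratio >= factor & out$pn_ratio >= factor
    if (anyNA(out$is_sep))
        warning(sum(is.na(out$is_sep)),
                " interval(s) with missing flux flagged NA and should be ",
                "excluded downstream")
    out
}

#' Welch's unequal-variance t-test
#'
#' Two-sample t statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value. Groups of fewer than two values, or two groups that
#' are both constant, give an undefined (all-`NA`) result with a note
#' rather than an error.
#'
#' @param x,y numeric vectors.
#' @return list with `t`, `df`, `p_value`, `mean_x`, `mean_y`, `note`.
#' @examples
#' welchTTest(c(10, 12, 14), c(1, 2, 3))
#' @export
welchTTest <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    und <- function(note) list(t = NA_real_, df = NA_real_,
                               p_value = NA_real_, mean_x = mean(x),
                               mean_y = mean(y), note = note)
    if (length(x) < 2L || length(y) < 2L)
        return(und("group with fewer than 2 observations"))
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(und("zero variance in both groups"))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y),
         note = "")
}

#' SASVs enriched in the trap during the summer export pulse
#'
#' Per ASV present in any trap sample, compares its relative abundances in
#' SEP versus non-SEP intervals with Welch's t-test. An ASV is enriched
#' when the two-sided p-value is below `alpha` and its mean SEP abundance
#' exceeds its mean non-SEP abundance (direction gate). No multiple-testing
#' correction is applied by default; `fdr = TRUE` switches the decision to
#' Benjamini-Hochberg adjusted p-values (reported in `p_adjusted`).
#'
#' @param trap trap [AsvExperiment-class] in relative mode.
#' @param calendar output of [flagSep()]; rows matched to trap samples by a
#'   `sample_id` column, or by `interval_start` against the samples'
#'   `date_start`. Intervals with `NA` flags are dropped with a warning.
#' @param alpha significance level (default 0.05).
#' @param fdr gate enrichment on BH-adjusted p-values.
#' @return data.frame with columns `asv_id`, `mean_sep`, `mean_nonsep`,
#'   `t_stat`, `df`, `p_value` (and `p_adjusted` if `fdr`), `enriched`,
#'   `note`, in input row order.
#' @export
enrichedSasvs <- function(trap, calendar, alpha = 0.05, fdr = FALSE) {
    if (!identical(abundanceMode(trap), "relative"))
        stop("enrichedSasvs expects the trap matrix in relative mode")
    cd <- SummarizedExperiment::colData(trap)
    if ("sample_id" %in% colnames(calendar)) {
        idx <- match(colnames(trap), calendar$sample_id)
    } else {
        idx <- match(as.character(cd$date_start),
                     as.character(calendar$interval_start))
    }
    if (anyNA(idx))
        stop("no flux interval found for trap sample(s): ",
             paste(colnames(trap)[is.na(idx)], collapse = ", "))
    isSep <- calendar$is_sep[idx]
    if (anyNA(isSep)) {
        warning("dropping ", sum(is.na(isSep)),
                " trap sample(s) with unknown SEP status")
    }
    usable <- !is.na(isSep)
    a <- SummarizedExperiment::assay(trap)[, usable, drop = FALSE]
    isSep <- isSep[usable]
    if (sum(isSep) < 2L || sum(!isSep) < 2L)
        stop("need at least 2 SEP and 2 non-SEP intervals (have ",
             sum(isSep), " and ", sum(!isSep), ")")
    present <- rowSums(a) > 0
    a <- a[present, , drop = FALSE]
    rows <- lapply(seq_len(nrow(a)), function(i) {
        w <- welchTTest(a[i, isSep], a[i, !isSep])
        data.frame(asv_id = rownames(a)[i], mean_sep = w$mean_x,
                   mean_nonsep = w$mean_y, t_stat = w$t, df = w$df,
                   p_value = w$p_value, note = w$note)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    pGate <- out$p_value
    if (fdr) {
        out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
        pGate <- out$p_adjusted
    }
    out$enriched <- !is.na(pGate) & pGate < alpha &
        out$mean_sep > out$mean_nonsep
    out
}
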