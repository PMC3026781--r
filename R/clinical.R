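## Biomarker and outcome analysis: ROC cut-off tables, Kaplan-Meier,
## log-rank and Cox proportional hazards (via the survival package,
## Breslow ties by default).

#' ROC curve with a per-cutoff diagnostic table
#'
#' Builds the full cut-off table (sensitivity, 1-specificity, predictive
#' values, likelihood ratios, accuracy) at every distinct marker value and
#' the trapezoid AUC. Markers carry an orientation: \code{direction =
#' "high"} calls a sample positive when the value is at or above the
#' cutoff (e.g. an up-regulated marker), \code{"low"} when at or below
#' (e.g. a marker lost in tumours).
#'
#' @param values numeric marker values
#' @param labels binary outcome (1/TRUE = positive class)
#' @param direction "high" or "low": which end of the scale is positive
#' @return list of class \code{RocTable}: \code{table} (one row per
#'   cutoff), \code{auc}, \code{direction}, \code{n_pos}, \code{n_neg}
#' @export
rocTable <- function(values, labels, direction = c("high", "low")) {
    direction <- match.arg(direction)
    labels <- as.logical(labels > 0 | labels == TRUE)
    if (length(unique(labels)) < 2L)
        stop("both outcome classes must be present")
    stopifnot(length(values) == length(labels))
    nP <- sum(labels); nN <- sum(!labels)

    cuts <- sort(unique(values), decreasing = (direction == "high"))
    rows <- lapply(cuts, function(ct) {
        pred <- if (direction == "high") values >= ct else values <= ct
        tp <- sum(pred & labels); fp <- sum(pred & !labels)
        fn <- nP - tp; tn <- nN - fp
        sens <- tp / nP; spec <- tn / nN
        data.frame(cutoff = ct, tp = tp, fp = fp, fn = fn, tn = tn,
                   sensitivity = sens, one_minus_specificity = 1 - spec,
                   specificity = spec,
                   ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                   lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
                   lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
                   accuracy = (tp + tn) / (nP + nN))
    })
    tab <- do.call(rbind, rows)

    fpr <- c(0, tab$one_minus_specificity, 1)
    tpr <- c(0, tab$sensitivity, 1)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

    out <- list(table = tab, auc = auc, direction = direction,
                n_pos = nP, n_neg = nN)
    class(out) <- "RocTable"
    out
}

#' Kaplan-Meier survival / recurrence curves
#'
#' Product-limit estimate with right censoring (deaths precede censorings
#' at tied times), per group.
#'
#' @param time follow-up times (months), non-negative
#' @param event event indicator (1 = event, 0 = censored)
#' @param group optional group labels
#' @return list of class \code{SurvivalFit}: \code{curves} (data.frame
#'   group, time, n_risk, n_event, n_censor, survival) and \code{fit}
#'   (the underlying \code{survfit} object)
#' @export
kmFit <- function(time, event, group = NULL) {
    if (any(time < 0)) stop("negative follow-up time")
    df <- data.frame(time = time, event = event)
    if (is.null(group)) {
        fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
        grp <- rep("all", length(fit$time))
    } else {
        df$group <- as.factor(group)
        fit <- survival::survfit(survival::Surv(time, event) ~ group,
                                 data = df)
        grp <- if (is.null(fit$strata)) rep(levels(df$group)[1L],
                                            length(fit$time))
               else rep(sub("^group=", "", names(fit$strata)), fit$strata)
    }
    curves <- data.frame(group = grp, time = fit$time,
                         n_risk = fit$n.risk, n_event = fit$n.event,
                         n_censor = fit$n.censor, survival = fit$surv,
                         stringsAsFactors = FALSE)
    out <- list(curves = curves, fit = fit)
    class(out) <- "SurvivalFit"
    out
}

#' Log-rank test between two (or more) groups
#'
#' @param time follow-up times
#' @param event event indicators
#' @param group group labels
#' @return list: \code{chisq}, \code{df}, \code{p} (NA with
#'   \code{flagged = TRUE} when no usable event times give zero variance)
#' @export
logrankTest <- function(time, event, group) {
    df <- data.frame(time = time, event = event, group = as.factor(group))
    if (sum(event) < 1L) stop("need at least one event")
    sd_ <- tryCatch(
        survival::survdiff(survival::Surv(time, event) ~ group, data = df),
        error = function(e) NULL)
    if (is.null(sd_) || !is.finite(sd_$chisq))
        return(list(chisq = NA_real_, df = NA_integer_, p = NA_real_,
                    flagged = TRUE))
    k <- length(sd_$n)
    list(chisq = sd_$chisq, df = k - 1L,
         p = stats::pchisq(sd_$chisq, k - 1L, lower.tail = FALSE),
         flagged = FALSE)
}

#' Cox proportional hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling (Efron available via
#' \code{ties}); reports per-covariate coefficients, hazard ratios,
#' standard errors from the observed information and Wald p values.
#' Monotone-likelihood (perfect separation) fits fail with the offending
#' covariate named.
#'
#' @param covariates data.frame or matrix of covariates
#' @param time follow-up times
#' @param event event indicators
#' @param ties "breslow" (default) or "efron"
#' @return list of class \code{CoxFit}: \code{coefficients} (data.frame
#'   covariate, coef, hr, se, z, p), \code{loglik}, \code{fit}
#' @export
coxFit <- function(covariates, time, event, ties = "breslow") {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(x) length(unique(x)) > 1L,
                   logical(1))
    if (!all(keep))
        stop("constant covariate(s): ",
             paste(names(covariates)[!keep], collapse = ", "))
    df <- cbind(covariates, .time = time, .event = event)
    fit <- survival::coxph(survival::Surv(.time, .event) ~ .,
                           data = df[c(names(covariates), ".time", ".event")],
                           ties = ties)
    beta <- stats::coef(fit)
    if (any(!is.finite(beta)) || any(abs(beta) > 15))
        stop("monotone partial likelihood (perfect separation) for: ",
             paste(names(beta)[!is.finite(beta) | abs(beta) > 15],
                   collapse = ", "))
    se <- sqrt(diag(fit$var))
    z <- beta / se
    out <- list(coefficients = data.frame(
                    covariate = names(beta), coef = unname(beta),
                    hr = unname(exp(beta)), se = unname(se),
                    z = unname(z),
                    p = unname(2 * stats::pnorm(-abs(z))),
                    stringsAsFactors = FALSE),
                loglik = fit$loglik, fit = fit)
    class(out) <- "CoxFit"
    out
}
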