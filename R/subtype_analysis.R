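# Survival-validated merging of k biclusters into an ultra-high-risk (UHR)
# versus high-risk (HR) dichotomy: Kaplan-Meier estimates at a fixed
# horizon pick the worst cluster, and the dichotomy is validated with the
# log-rank test and a Cox proportional-hazards fit.

#' Kaplan-Meier survival probability at a horizon
#'
#' Product-limit estimate at `horizon` months.  With no censoring before the
#' horizon this equals the empirical fraction surviving past it.
#'
#' @param time follow-up times in months (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @param horizon time at which to evaluate the curve (>= 0).
#' @export
km_estimate <- function(time, event, horizon) {
  if (length(time) == 0) stop("empty group", call. = FALSE)
  if (any(time < 0)) stop("negative survival times", call. = FALSE)
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)
  as.numeric(s$surv)
}

#' Log-rank test across survival groups
#'
#' @inheritParams km_estimate
#' @param group group membership (>= 2 distinct levels).
#' @return list with `statistic` (chi-square), `df`, `p`.
#' @export
logrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(event) < 1) stop("need >= 1 event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Wald summaries
#'
#' Partial-likelihood fit; hazard ratios are `exp(beta)` with normal-
#' approximation 95% confidence intervals `exp(beta +/- 1.96 se)`.
#'
#' @inheritParams km_estimate
#' @param covariates data.frame of numeric or binary-coded covariates.
#' @return object of class `survival_fit`: data.frame `coef` (term, beta,
#'   se, hr, lo95, hi95, p) plus `n` and `n_events`.
#' @export
cox_fit <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(x) length(unique(x)) < 2, logical(1)))) {
    stop("covariate constant across samples: no information", call. = FALSE)
  }
  if (sum(event) < ncol(covariates) + 1) {
    stop("too few events for the number of covariates", call. = FALSE)
  }
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = dat)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("Cox fit did not converge (possible complete separation)", call. = FALSE)
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  coef_tab <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    lo95 = exp(unname(beta) - 1.96 * unname(se)),
    hi95 = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(coef = coef_tab, n = length(time), n_events = sum(event)),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d\n", x$n, x$n_events))
  print(x$coef, digits = 4)
  invisible(x)
}

# restricted mean survival over [0, cap] by integrating the KM curve
.restricted_mean <- function(time, event, cap) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tt <- c(0, fit$time[fit$time <= cap], cap)
  ss <- c(1, fit$surv[fit$time <= cap])
  sum(diff(tt) * ss)
}

#' Define the ultra-high-risk subtype from a fitted bicluster model
#'
#' The UHR cluster is the sample cluster with the lowest Kaplan-Meier
#' survival at `horizon` months (ties broken by lower restricted-mean
#' survival over follow-up); all other clusters are pooled as HR.  The
#' dichotomy is summarized with a two-group log-rank test, a Cox fit
#' (UHR vs HR), KM estimates at the horizon per cluster and per subtype,
#' plus the k-group log-rank test and a secondary log-rank test among the
#' pooled non-UHR clusters (checking that they are NOT distinguishable).
#'
#' @param model a `bicluster_model`, or an integer vector of sample labels.
#' @param time,event survival outcome, one record per clustered sample.
#' @param horizon evaluation horizon in months (default 24, i.e. two-year
#'   survival).
#' @param gap minimal KM gap at the horizon between the worst and the
#'   runner-up cluster below which the designation is flagged
#'   `unstable = TRUE` (default 0.02).
#' @return object of class `subtype_result`: `uhr_cluster`, `labels`
#'   (factor UHR/HR), `km_at` (per cluster), `km_subtype` (UHR, HR),
#'   `logrank_p`, `logrank_k_p`, `logrank_rest_p`, `fit` (a
#'   `survival_fit`), `horizon`, `unstable`.
#' @export
define_uhr <- function(model, time, event, horizon = 24, gap = 0.02) {
  labels <- if (inherits(model, "bicluster_model")) model$sample_labels else model
  labels <- as.integer(labels)
  if (length(labels) != length(time)) {
    stop("need one survival record per clustered sample", call. = FALSE)
  }
  ks <- sort(unique(labels))
  km_at <- vapply(ks, function(cl) {
    km_estimate(time[labels == cl], event[labels == cl], horizon)
  }, numeric(1))
  names(km_at) <- as.character(ks)
  worst_km <- min(km_at)
  cand <- ks[km_at == worst_km]
  if (length(cand) > 1) {
    rm_ <- vapply(cand, function(cl) {
      .restricted_mean(time[labels == cl], event[labels == cl], max(time))
    }, numeric(1))
    cand <- cand[order(rm_, cand)]
  }
  uhr <- cand[1]
  runner_up <- min(km_at[names(km_at) != as.character(uhr)])
  unstable <- (runner_up - worst_km) < gap

  subtype <- factor(ifelse(labels == uhr, "UHR", "HR"), levels = c("HR", "UHR"))
  lr2 <- logrank(time, event, subtype)
  lrk <- if (length(ks) > 2) logrank(time, event, labels) else lr2
  rest <- labels != uhr
  lr_rest <- if (length(unique(labels[rest])) > 1) {
    logrank(time[rest], event[rest], labels[rest])
  } else list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
  fit <- cox_fit(time, event, data.frame(uhr = as.integer(subtype == "UHR")))
  km_subtype <- c(
    UHR = km_estimate(time[subtype == "UHR"], event[subtype == "UHR"], horizon),
    HR = km_estimate(time[subtype == "HR"], event[subtype == "HR"], horizon)
  )
  structure(list(
    uhr_cluster = uhr, labels = subtype, km_at = km_at,
    km_subtype = km_subtype, logrank_p = lr2$p, logrank_k_p = lrk$p,
    logrank_rest_p = lr_rest$p, fit = fit, horizon = horizon,
    unstable = unstable
  ), class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  cat(sprintf("UHR cluster: %d (%d/%d samples)%s\n", x$uhr_cluster,
              sum(x$labels == "UHR"), length(x$labels),
              if (x$unstable) " [unstable designation]" else ""))
  cat(sprintf("KM at %g months: UHR %.3f vs HR %.3f; log-rank p = %.3g\n",
              x$horizon, x$km_subtype[["UHR"]], x$km_subtype[["HR"]],
              x$logrank_p))
  cf <- x$fit$coef
  cat(sprintf("Cox HR (UHR vs HR): %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              cf$hr[1], cf$lo95[1], cf$hi95[1], cf$p[1]))
  cat(sprintf("log-rank among non-UHR clusters: p = %.3g\n", x$logrank_rest_p))
  invisible(x)
}
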