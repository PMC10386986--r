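#' Harrell's concordance index
#'
#' Probability that, of a usable patient pair, the one with the higher risk
#' score fails first. Usable pairs are `(i, j)` with `t_i < t_j` and an
#' event for `i`; a pair is concordant when `score_i > score_j`, and score
#' ties count 1/2. An optional bootstrap percentile CI is attached.
#'
#' @param scores Risk scores (higher = higher risk).
#' @param times,events Survival endpoint.
#' @param ci Compute a bootstrap CI.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return The C-index, with attributes `ci` (2.5/97.5 percentiles) and
#'   `n_pairs` when requested.
#' @export
c_index <- function(scores, times, events, ci = FALSE, n_boot = 1000,
                    seed = 1L) {
  events <- as.logical(events)
  n <- length(scores)
  stopifnot(n >= 2, length(times) == n, length(events) == n)
  core <- function(s, t, e) {
    conc <- 0; pairs <- 0
    for (i in which(e)) {
      later <- t > t[i]
      if (!any(later)) next
      pairs <- pairs + sum(later)
      conc <- conc + sum(s[i] > s[later]) + 0.5 * sum(s[i] == s[later])
    }
    if (pairs == 0) return(c(NA_real_, 0))
    c(conc / pairs, pairs)
  }
  est <- core(scores, times, events)
  if (is.na(est[1])) stop("no usable pairs: C-index undefined")
  out <- est[1]
  attr(out, "n_pairs") <- est[2]
  if (ci) {
    bs <- withr_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        core(scores[i], times[i], events[i])[1]
      }, numeric(1))
    })
    attr(out, "ci") <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
  }
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator (wraps `survival::survfit`).
#'
#' @param times,events Survival endpoint.
#' @return A `km_estimate` list: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor`.
#' @export
km_estimate <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor),
            class = "km_estimate")
}

# KM survival probability at a horizon (1 before the first event time).
km_surv_at <- function(km, t) {
  i <- which(km$time <= t)
  if (!length(i)) 1 else km$surv[max(i)]
}

#' Two-group log-rank test
#'
#' Hand-computed Mantel-Haenszel log-rank: at each distinct event time the
#' observed events in group A are compared with the hypergeometric
#' expectation; the chi-square statistic has one degree of freedom.
#'
#' @param times_a,events_a Group A endpoint.
#' @param times_b,events_b Group B endpoint.
#' @return List: `statistic`, `p_value`, `observed`, `expected` (group A).
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) >= 1, length(times_b) >= 1)
  ea <- as.logical(events_a); eb <- as.logical(events_b)
  if (!any(ea) && !any(eb)) stop("no events: log-rank undefined")
  t_all <- c(times_a, times_b)
  e_all <- c(ea, eb)
  ga <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(t_all[e_all]))) {
    at_risk <- t_all >= t
    n <- sum(at_risk); na <- sum(at_risk & ga)
    d <- sum(e_all & t_all == t)
    da <- sum(e_all & t_all == t & ga)
    O <- O + da
    E <- E + d * na / n
    if (n > 1) V <- V + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = O, expected = E, variance = V)
}

#' Time-dependent ROC AUC
#'
#' Cumulative-cases / dynamic-controls estimator: at horizon `t`, cases are
#' patients with an event by `t`, controls those event-free past `t`;
#' patients censored before `t` are excluded (simple unweighted estimator).
#' AUC is the rank (Mann-Whitney) statistic of the scores.
#'
#' @param scores Risk scores.
#' @param times,events Survival endpoint.
#' @param horizons Evaluation times (defaults 12, 24, 60 months).
#' @return Data frame: `horizon`, `auc` (`NA` where cases or controls are
#'   absent), `n_cases`, `n_controls`.
#' @export
td_roc <- function(scores, times, events, horizons = c(12, 24, 60)) {
  events <- as.logical(events)
  out <- lapply(horizons, function(t) {
    case <- events & times <= t
    ctrl <- times > t
    keep <- case | ctrl
    auc <- if (!any(case) || !any(ctrl)) NA_real_ else
      roc_auc(scores[keep], case[keep])
    data.frame(horizon = t, auc = auc, n_cases = sum(case),
               n_controls = sum(ctrl))
  })
  do.call(rbind, out)
}

#' Calibration of predicted event probabilities
#'
#' Bins patients by predicted risk quantiles and compares the mean
#' predicted event probability with the Kaplan-Meier observed event
#' probability (1 - S(t)) per bin. Bins emptied by tied predictions are
#' merged with their neighbor.
#'
#' @param pred_risk Predicted event probability by `horizon` per patient.
#' @param times,events Survival endpoint.
#' @param horizon Evaluation time.
#' @param n_bins Number of quantile bins (>= 2).
#' @return Data frame: `bin`, `n`, `predicted`, `observed`.
#' @export
calibration <- function(pred_risk, times, events, horizon, n_bins = 4) {
  stopifnot(n_bins >= 2)
  qs <- unique(stats::quantile(pred_risk, seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 3) {
    bins <- factor(rep(1, length(pred_risk)))
  } else {
    bins <- cut(pred_risk, qs, include.lowest = TRUE, labels = FALSE)
    bins <- factor(bins)
  }
  out <- lapply(levels(bins), function(b) {
    i <- bins == b
    km <- km_estimate(times[i], events[i])
    data.frame(bin = as.integer(b), n = sum(i),
               predicted = mean(pred_risk[i]),
               observed = 1 - km_surv_at(km, horizon))
  })
  do.call(rbind, out)
}

#' Cox proportional-hazards fit for tabular covariates
#'
#' Fits `survival::coxph` (Breslow ties) on the given variables and returns
#' the forest-plot quantities: coefficients, hazard ratios with Wald 95%
#' CIs, p-values and the model C-index.
#'
#' @param covariates Data frame of covariates.
#' @param times,events Survival endpoint.
#' @param variables Column names to include (default: all).
#' @return A `survival_fit` list: `table` (term, beta, hr, ci_lower,
#'   ci_upper, z, p_value), `c_index`, `n`, `n_events`, `fit`.
#' @export
cox_fit <- function(covariates, times, events,
                    variables = names(covariates)) {
  stopifnot(length(variables) >= 1)
  X <- covariates[, variables, drop = FALSE]
  num <- vapply(X, is.numeric, logical(1))
  if (sum(num) >= 2) {
    cm <- stats::cor(X[, num, drop = FALSE])
    diag(cm) <- 0
    if (any(abs(cm) > 0.999, na.rm = TRUE)) {
      bad <- which(abs(cm) == max(abs(cm), na.rm = TRUE), arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", colnames(cm)[bad[1]], " and ",
           colnames(cm)[bad[2]])
    }
  }
  if (sum(as.logical(events)) < length(variables)) {
    stop("fewer events than variables")
  }
  dat <- data.frame(.time = times, .event = as.numeric(events), X,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", variables), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) || any(is.na(stats::coef(fit)))) {
    stop("Cox fit failed to converge or produced NA coefficients")
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    beta = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, 3],
                    ci_upper = s$conf.int[, 4],
                    z = s$coefficients[, "z"],
                    p_value = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, c_index = as.numeric(s$concordance[1]),
                 n = s$n, n_events = s$nevent, fit = fit),
            class = "survival_fit")
}

#' Univariate screening then multivariate Cox
#'
#' Screens each candidate covariate with a univariate Cox fit and refits a
#' multivariate model on those significant at `p_threshold`.
#'
#' @inheritParams cox_fit
#' @param p_threshold Univariate significance threshold (default 0.05).
#' @return List: `univariate` (screening table), `selected`,
#'   `multivariate` (a [cox_fit()] result or `NULL` when nothing passes).
#' @export
cox_screen <- function(covariates, times, events,
                       variables = names(covariates), p_threshold = 0.05) {
  uni <- lapply(variables, function(v) {
    f <- cox_fit(covariates, times, events, variables = v)
    cbind(variable = v, f$table)
  })
  uni <- do.call(rbind, uni)
  sel <- unique(uni$variable[uni$p_value < p_threshold])
  multi <- if (length(sel)) cox_fit(covariates, times, events, sel) else NULL
  list(univariate = uni, selected = sel, multivariate = multi)
}
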