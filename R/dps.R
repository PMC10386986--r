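#' Fit deep-pathomics-score weights by multivariate Cox regression
#'
#' Regresses the survival endpoint on the five per-tissue risk scores —
#' every tissue category except normal liver tissue (NLT) — with a Cox
#' proportional-hazards model. The fitted coefficients are the weights of
#' the deep pathomics score.
#'
#' @param profiles Data frame with `patient_id` and one score column per
#'   tissue class (named by class code, e.g. `IC`, or `score_IC`).
#' @param times,events Survival endpoint.
#' @param exclude Classes excluded from the weighting (default `"NLT"`).
#' @return A `dps_weights` object: `beta`, `hr`, `ci_lower`, `ci_upper`,
#'   `p_value`, `z` per included class, training normalization bounds for
#'   the linear predictor and for the immune-cell score, and training
#'   medians for imputation.
#' @export
fit_dps_weights <- function(profiles, times, events, exclude = "NLT") {
  sc <- profile_scores(profiles)
  included <- setdiff(colnames(sc), exclude)
  stopifnot(length(included) >= 1)
  n <- nrow(sc)
  events <- as.logical(events)
  if (n < 20) stop("need >= 20 patients to fit DPS weights, got ", n)
  if (sum(events) < 5) stop("need >= 5 events, got ", sum(events))
  if (any(!is.finite(as.matrix(sc[, included])))) {
    stop("non-finite score values")
  }
  cm <- stats::cor(sc[, included])
  diag(cm) <- 0
  if (any(abs(cm) > 0.999)) {
    bad <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stop("collinear score columns: ", included[bad[1]], " and ",
         included[bad[2]], " (|r| > 0.999)")
  }
  dat <- data.frame(time = times, event = as.numeric(events),
                    sc[, included, drop = FALSE])
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(included, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  s <- summary(fit)
  beta <- stats::coef(fit)
  lp <- drop(as.matrix(sc[, included]) %*% beta)
  ic <- if ("IC" %in% colnames(sc)) sc[, "IC"] else rep(NA_real_, n)
  structure(list(
    included_classes = included,
    beta = beta,
    hr = s$conf.int[, "exp(coef)"],
    ci_lower = s$conf.int[, 3],
    ci_upper = s$conf.int[, 4],
    z = s$coefficients[, "z"],
    p_value = s$coefficients[, "Pr(>|z|)"],
    lp_bounds = c(lo = min(lp), hi = max(lp)),
    ic_bounds = c(lo = suppressWarnings(min(ic, na.rm = TRUE)),
                  hi = suppressWarnings(max(ic, na.rm = TRUE))),
    score_medians = apply(sc, 2, stats::median, na.rm = TRUE),
    fit = fit),
    class = "dps_weights")
}

# Accept either bare class-code columns or score_<class> columns.
profile_scores <- function(profiles) {
  nm <- names(profiles)
  bare <- intersect(TISSUE_CLASSES, nm)
  pref <- intersect(paste0("score_", TISSUE_CLASSES), nm)
  if (length(bare)) {
    as.matrix(profiles[, bare, drop = FALSE])
  } else if (length(pref)) {
    m <- as.matrix(profiles[, pref, drop = FALSE])
    colnames(m) <- sub("^score_", "", colnames(m))
    m
  } else {
    stop("no per-tissue score columns found")
  }
}

#' Compute the deep pathomics score and immune score
#'
#' `dps` is the Cox linear predictor over the included tissue scores,
#' min-max normalized with the *training-cohort* bounds stored in the
#' weights (values outside the training range may fall outside `[0, 1]`).
#' `is_score` is the analogously normalized immune-cell score. Missing
#' class scores are imputed by the training-cohort median (with a warning).
#'
#' @param profiles Data frame of per-tissue scores (see
#'   [fit_dps_weights()]).
#' @param w A `dps_weights`.
#' @param cutoff Optional cutoff; when given, risk groups are assigned via
#'   [assign_groups()].
#' @return Data frame: `patient_id`, `dps`, `is_score`, and `risk_group` /
#'   `cutoff_used` when a cutoff is supplied.
#' @export
compute_dps <- function(profiles, w, cutoff = NULL) {
  stopifnot(inherits(w, "dps_weights"))
  sc <- profile_scores(profiles)
  for (cl in w$included_classes) {
    if (!cl %in% colnames(sc)) {
      warning("profile missing class ", cl,
              ": imputing training median")
      sc <- cbind(sc, matrix(w$score_medians[cl], nrow(sc), 1,
                             dimnames = list(NULL, cl)))
    } else if (anyNA(sc[, cl])) {
      sc[is.na(sc[, cl]), cl] <- w$score_medians[cl]
    }
  }
  lp <- drop(sc[, w$included_classes, drop = FALSE] %*%
               w$beta[w$included_classes])
  b <- w$lp_bounds
  dps <- if (b["hi"] > b["lo"]) (lp - b["lo"]) / (b["hi"] - b["lo"]) else
    rep(0.5, length(lp))
  ic <- if ("IC" %in% colnames(sc)) sc[, "IC"] else rep(NA_real_, nrow(sc))
  bi <- w$ic_bounds
  is_score <- if (is.finite(bi["hi"]) && bi["hi"] > bi["lo"]) {
    (ic - bi["lo"]) / (bi["hi"] - bi["lo"])
  } else ic
  out <- data.frame(patient_id = if ("patient_id" %in% names(profiles))
    profiles$patient_id else seq_len(nrow(sc)),
    dps = as.numeric(dps), is_score = as.numeric(is_score),
    stringsAsFactors = FALSE)
  if (!is.null(cutoff)) {
    out$risk_group <- assign_groups(out$dps, cutoff)
    out$cutoff_used <- cutoff
  }
  out
}

#' Maximally selected log-rank cutoff
#'
#' Scans candidate cutoffs (midpoints between consecutive sorted unique
#' score values whose induced split keeps both groups nonempty, restricted
#' to the inner quantile range) and returns the one maximizing the
#' two-group log-rank statistic. Ties are broken toward the lower cutoff.
#' The selected statistic is maximally selected, so its nominal log-rank
#' p-value is optimistic; significance should be judged with that in mind.
#'
#' @param dps Score vector.
#' @param times,events Survival endpoint.
#' @param minprop Inner quantile restriction (default 0.1: candidates lie
#'   between the 10th and 90th percentile of the scores).
#' @return The selected cutoff, with attributes `statistic` (log-rank
#'   chi-square) and `candidates` (scan table).
#' @export
optimal_cutoff <- function(dps, times, events, minprop = 0.1) {
  stopifnot(length(dps) >= 20)
  events <- as.logical(events)
  u <- sort(unique(dps))
  cand <- (u[-1] + u[-length(u)]) / 2
  qs <- stats::quantile(dps, c(minprop, 1 - minprop))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  cand <- cand[vapply(cand, function(ct) {
    any(dps > ct) && any(dps <= ct)
  }, logical(1))]
  if (!length(cand)) stop("no admissible cutoff candidate")
  stat <- vapply(cand, function(ct) {
    hi <- dps > ct
    lr <- tryCatch(logrank(times[hi], events[hi],
                           times[!hi], events[!hi]),
                   error = function(e) NULL)
    if (is.null(lr)) -Inf else lr$statistic
  }, numeric(1))
  best <- which(stat == max(stat))[1]       # ties -> lower cutoff
  structure(cand[best], statistic = stat[best],
            candidates = data.frame(cutoff = cand, statistic = stat))
}

#' Assign high/low risk groups at a cutoff
#'
#' Strict inequality: `dps > cutoff` is high risk; a value exactly at the
#' cutoff goes to the low-risk group.
#'
#' @param dps Score vector (finite).
#' @param cutoff Scalar cutoff.
#' @return Factor with levels `low`, `high`.
#' @export
assign_groups <- function(dps, cutoff) {
  stopifnot(all(is.finite(dps)), is.finite(cutoff))
  factor(ifelse(dps > cutoff, "high", "low"), levels = c("low", "high"))
}
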