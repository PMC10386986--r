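#' Negative Cox partial log-likelihood
#'
#' The survival half of the joint training loss. For event times the risk
#' set is every patient with time >= that event's time. Ties are handled by
#' Breslow's approximation by default, Efron's optionally.
#'
#' @param scores Per-patient risk scores (linear predictor).
#' @param times Follow-up times.
#' @param events Logical/0-1 event indicators.
#' @param tie_method `"breslow"` or `"efron"`.
#' @return Nonnegative scalar, the negative partial log-likelihood.
#' @export
cox_npll <- function(scores, times, events,
                     tie_method = c("breslow", "efron")) {
  tie_method <- match.arg(tie_method)
  events <- as.logical(events)
  n <- length(scores)
  stopifnot(n >= 2, length(times) == n, length(events) == n)
  if (!any(events)) stop("no events: partial likelihood undefined")
  es <- exp(scores)
  nll <- 0
  for (t in unique(times[events])) {
    D <- which(events & times == t)
    R <- which(times >= t)
    d <- length(D)
    sR <- sum(es[R]); sD <- sum(es[D])
    nll <- nll - sum(scores[D])
    if (tie_method == "breslow") {
      nll <- nll + d * log(sR)
    } else {
      l <- seq_len(d) - 1
      nll <- nll + sum(log(sR - (l / d) * sD))
    }
  }
  nll
}

# Gradient of cox_npll with respect to scores.
cox_npll_grad <- function(scores, times, events,
                          tie_method = c("breslow", "efron")) {
  tie_method <- match.arg(tie_method)
  events <- as.logical(events)
  es <- exp(scores)
  g <- -as.numeric(events)
  for (t in unique(times[events])) {
    D <- which(events & times == t)
    R <- which(times >= t)
    d <- length(D)
    sR <- sum(es[R]); sD <- sum(es[D])
    if (tie_method == "breslow") {
      g[R] <- g[R] + d * es[R] / sR
    } else {
      for (l in seq_len(d) - 1) {
        phi <- sR - (l / d) * sD
        g[R] <- g[R] + es[R] / phi
        g[D] <- g[D] - (l / d) * es[D] / phi
      }
    }
  }
  g
}

#' Binary cross-entropy
#'
#' `-[y log p + (1 - y) log(1 - p)]`, with probabilities clipped to
#' `[1e-7, 1 - 1e-7]`. Vector inputs return the mean over elements.
#'
#' @param prob Predicted probabilities in (0, 1).
#' @param label Logical/0-1 labels.
#' @return Mean nonnegative loss.
#' @export
bce <- function(prob, label) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  y <- as.numeric(label)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Joint loss configuration
#' @param lambda_bce Nonnegative weight of the binary cross-entropy term
#'   added to the Cox partial likelihood (default 1).
#' @param tie_method Tie handling for the Cox term.
#' @return A `joint_loss_config` list.
#' @export
joint_loss_config <- function(lambda_bce = 1,
                              tie_method = c("breslow", "efron")) {
  stopifnot(lambda_bce >= 0)
  structure(list(lambda_bce = lambda_bce,
                 tie_method = match.arg(tie_method)),
            class = "joint_loss_config")
}

#' Risk-network configuration
#' @param hidden Hidden units of the per-tile scoring network.
#' @param epochs Maximum optimization epochs (full-batch Adam).
#' @param learning_rate Adam step size.
#' @param patience Early stopping: epochs of non-improving validation loss
#'   tolerated before stopping (the trigger is the first sustained rise).
#' @param val_frac Fraction of patients held out for validation.
#' @return A `risk_net_config` list.
#' @export
risk_net_config <- function(hidden = 8, epochs = 300, learning_rate = 0.02,
                            patience = 3, val_frac = 0.3) {
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), val_frac = val_frac),
            class = "risk_net_config")
}

#' Summary features of one tile
#'
#' Eight image statistics (per-channel mean and standard deviation, overall
#' luminance mean/sd) feeding the risk network; texture contrast - the
#' carrier of prognostic signal in the synthetic generator - is captured by
#' the standard deviations.
#'
#' @param px Tile pixel array (H x W x 3).
#' @return Numeric vector of length 8.
#' @export
tile_features <- function(px) {
  px <- px * 1.0
  m <- apply(px, 3, mean)
  s <- apply(px, 3, stats::sd)
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  c(m, s, mean(gray), stats::sd(gray))
}

# forward/backward of the tiny scoring MLP (Fin -> H -> 1, ReLU).
risk_fw <- function(p, X) {
  z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  h1 <- relu_fw(z1)
  s <- drop(h1 %*% p$W2) + p$b2
  list(score = s, h1 = h1)
}

risk_bw <- function(p, X, cache, ds) {
  dW2 <- crossprod(cache$h1, ds)
  db2 <- sum(ds)
  dh1 <- ds %*% t(p$W2)
  dz1 <- dh1 * (cache$h1 > 0)
  list(W1 = crossprod(X, dz1), b1 = colSums(dz1),
       W2 = dW2, b2 = db2)
}

#' Train a per-tissue survival risk network
#'
#' For one tissue class, maps every tile of each patient through a small
#' scoring network, pools tile scores to a patient score by the mean, and
#' minimizes `cox_npll(scores) + lambda_bce * bce(sigmoid(score), event)`
#' on the training patients. Training stops early once the validation loss
#' rises for `patience` consecutive epochs; the best validation checkpoint
#' is kept. Scores for the full cohort are returned both raw and min-max
#' normalized to `[0, 1]` over the training cohort, so downstream cutoffs
#' live on a comparable scale.
#'
#' @param cohort A `synthetic_cohort`, or a list with `patients`
#'   (data.frame with patient_id, times and events) and a `tile_list`:
#'   named list (by patient_id) of lists of tiles of class `cls`.
#' @param cls Tissue class to train on.
#' @param loss_cfg A [joint_loss_config()].
#' @param net_cfg A [risk_net_config()].
#' @param seed Integer seed (initialization and patient split).
#' @param time_col,event_col Endpoint columns (default TTR/recurrence).
#' @return A `tissue_risk_model` with `scores` data.frame (patient_id,
#'   class, score, score_raw, n_tiles; `NA` score and a `missing` flag for
#'   patients without tiles of `cls`), the network parameters, the
#'   normalization bounds and the training log.
#' @export
train_tissue_risk <- function(cohort, cls,
                              loss_cfg = joint_loss_config(),
                              net_cfg = risk_net_config(),
                              seed = 1L,
                              time_col = "ttr_months",
                              event_col = "recurrence_event") {
  pats <- cohort$patients
  n <- nrow(pats)
  tl <- cohort_tile_list(cohort, cls)
  n_tiles <- vapply(tl, length, integer(1))
  has <- n_tiles > 0
  if (sum(has) < 10) stop("need >= 10 patients with tiles of class ", cls)
  if (sum(pats[[event_col]][has]) < 3) stop("need >= 3 events")

  feats <- lapply(tl[has], function(tt) {
    t(vapply(tt, function(x) {
      tile_features(if (is.list(x)) x$pixels else x)
    }, numeric(8)))
  })
  Xall <- do.call(rbind, feats)
  mu <- colMeans(Xall); sg <- pmax(apply(Xall, 2, stats::sd), 1e-8)
  feats <- lapply(feats, function(f) sweep(sweep(f, 2, mu), 2, sg, "/"))
  pat_of_tile <- rep(seq_along(feats), vapply(feats, nrow, integer(1)))
  X <- do.call(rbind, feats)
  nt <- vapply(feats, nrow, integer(1))

  times <- pats[[time_col]][has]
  events <- as.logical(pats[[event_col]][has])

  withr_seed(seed, {
    m <- sum(has)
    n_val <- max(2L, round(m * net_cfg$val_frac))
    val <- sample(seq_len(m), n_val)
    is_val <- seq_len(m) %in% val
    if (sum(events[!is_val]) < 1 || sum(events[is_val]) < 1) {
      is_val <- seq_len(m) %in% order(events, decreasing = TRUE)[
        seq(2, m, by = round(1 / net_cfg$val_frac))]
    }
    p <- list(W1 = he_mat(8L, net_cfg$hidden), b1 = rep(0, net_cfg$hidden),
              W2 = he_mat(net_cfg$hidden, 1L), b2 = 0)
    opt <- adam_init(p)
    tlog <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    best <- list(loss = Inf, p = p, epoch = 0L)
    bad <- 0L
    joint_loss <- function(sc, idx) {
      cox_npll(sc[idx], times[idx], events[idx], loss_cfg$tie_method) /
        sum(idx) +
        loss_cfg$lambda_bce * bce(sigmoid(sc[idx]), events[idx])
    }
    for (ep in seq_len(net_cfg$epochs)) {
      fw <- risk_fw(p, X)
      sc <- as.numeric(rowsum(fw$score, pat_of_tile)) / nt
      tr <- !is_val
      gs <- rep(0, m)
      gs[tr] <- cox_npll_grad(sc[tr], times[tr], events[tr],
                              loss_cfg$tie_method) / sum(tr)
      if (loss_cfg$lambda_bce > 0) {
        pr <- sigmoid(sc[tr])
        gs[tr] <- gs[tr] + loss_cfg$lambda_bce * (pr - events[tr]) / sum(tr)
      }
      ds <- matrix(gs[pat_of_tile] / nt[pat_of_tile], ncol = 1)
      gr <- risk_bw(p, X, fw, ds)
      st <- adam_step(p, gr, opt, net_cfg$learning_rate)
      p <- st$params; opt <- st$state
      fw2 <- risk_fw(p, X)
      sc2 <- as.numeric(rowsum(fw2$score, pat_of_tile)) / nt
      vl <- joint_loss(sc2, is_val)
      tlog <- rbind(tlog, data.frame(epoch = ep,
                                     train_loss = joint_loss(sc2, tr),
                                     val_loss = vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, p = p, epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= net_cfg$patience) break
      }
    }
  })
  p <- best$p
  fw <- risk_fw(p, X)
  sc <- as.numeric(rowsum(fw$score, pat_of_tile)) / nt
  lo <- min(sc); hi <- max(sc)
  norm <- if (hi > lo) (sc - lo) / (hi - lo) else rep(0.5, length(sc))
  scores <- data.frame(patient_id = pats$patient_id,
                       class = cls,
                       score = NA_real_, score_raw = NA_real_,
                       n_tiles = n_tiles,
                       missing = !has,
                       stringsAsFactors = FALSE)
  scores$score_raw[has] <- sc
  scores$score[has] <- norm
  structure(list(class = cls, params = p, feat_center = mu, feat_scale = sg,
                 norm_bounds = c(lo = lo, hi = hi), scores = scores,
                 log = tlog, loss_cfg = loss_cfg, net_cfg = net_cfg,
                 best_epoch = best$epoch),
            class = "tissue_risk_model")
}

# Resolve per-patient tile lists for class `cls` from a synthetic_cohort
# (tiles realized on demand) or from a user-provided `tile_list`.
cohort_tile_list <- function(cohort, cls) {
  if (!is.null(cohort$tile_list)) {
    tl <- lapply(cohort$patients$patient_id, function(pid) {
      x <- cohort$tile_list[[pid]]
      if (is.null(x)) list() else x
    })
    return(tl)
  }
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- cohort$tiles[cohort$tiles$class == cls, ]
  lapply(cohort$patients$patient_id, function(pid) {
    rr <- rows[rows$patient_id == pid, ]
    lapply(seq_len(nrow(rr)), function(i) {
      generate_tissue_tile(cls, cohort$spec$tile_size_px, rr$tile_seed[i],
                           contrast = rr$contrast[i])
    })
  })
}

#' Score new tiles with a trained risk network
#' @param model A `tissue_risk_model`.
#' @param tiles List of tiles (one patient).
#' @param normalized Return the training-cohort min-max normalized score.
#' @return Scalar patient score (mean of per-tile scores).
#' @export
predict_tissue_risk <- function(model, tiles, normalized = TRUE) {
  X <- t(vapply(tiles, function(x) {
    tile_features(if (is.list(x)) x$pixels else x)
  }, numeric(8)))
  X <- sweep(sweep(X, 2, model$feat_center), 2, model$feat_scale, "/")
  s <- mean(risk_fw(model$params, X)$score)
  if (!normalized) return(s)
  b <- model$norm_bounds
  if (b["hi"] > b["lo"]) (s - b["lo"]) / (b["hi"] - b["lo"]) else 0.5
}

#' Per-patch attention values
#'
#' Scores each tile/patch with the risk network and min-max normalizes the
#' values to `[0, 1]` per slide (red-high convention for rendering). A
#' constant map has no ordering information and is rendered flat at 0.5.
#'
#' @param model A `tissue_risk_model`.
#' @param tiles List of tiles/patches from one slide.
#' @param grid_dim Optional `c(rows, cols)` to shape the result as a matrix.
#' @return Numeric vector (or matrix) of attention values in `[0, 1]`.
#' @export
attention_map <- function(model, tiles, grid_dim = NULL) {
  X <- t(vapply(tiles, function(x) {
    tile_features(if (is.list(x)) x$pixels else x)
  }, numeric(8)))
  X <- sweep(sweep(X, 2, model$feat_center), 2, model$feat_scale, "/")
  s <- risk_fw(model$params, X)$score
  rng <- max(s) - min(s)
  a <- if (rng < 1e-12) rep(0.5, length(s)) else (s - min(s)) / rng
  if (!is.null(grid_dim)) a <- matrix(a, grid_dim[1], grid_dim[2],
                                      byrow = TRUE)
  a
}
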