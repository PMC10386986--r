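#' Classifier configuration
#'
#' Settings for the squeeze-and-excitation residual tile classifier. The
#' default `"small"` preset (one SE-residual block on a reduced input
#' resolution) trains on a desktop CPU in minutes; `"deep"` stacks a second
#' block for a closer analogue of large residual networks.
#'
#' @param depth `"small"` or `"deep"`.
#' @param input_size Side length tiles are downscaled to before the network
#'   (must be divisible by 4).
#' @param channels Width (feature channels) of the trunk.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param epochs,batch_size,learning_rate Optimization settings (Adam).
#' @param val_frac Fraction of patients held out for validation.
#' @param seed Seed fixing initialization, shuffling and the split.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(depth = c("small", "deep"), input_size = 32,
                              channels = 8, se_reduction = 2, epochs = 10,
                              batch_size = 32, learning_rate = 0.01,
                              val_frac = 0.3, seed = 1L) {
  depth <- match.arg(depth)
  stopifnot(se_reduction >= 1, epochs >= 1, batch_size >= 1,
            learning_rate > 0, input_size %% 4 == 0)
  structure(list(depth = depth, input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 se_reduction = se_reduction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Downscale a tile by block averaging
#' @param px H x W x 3 array; H must be a multiple of `size`.
#' @param size Target side length.
#' @return `size x size x 3` numeric array.
#' @export
downscale_tile <- function(px, size) {
  H <- dim(px)[1]
  if (H == size) return(px * 1.0)
  f <- H / size
  if (f != floor(f)) stop("tile side ", H, " not a multiple of ", size)
  out <- array(0, c(size, size, 3))
  idx <- rep(seq_len(size), each = f)
  for (c in 1:3) {
    out[, , c] <- rowsum(t(rowsum(px[, , c] * 1.0, idx)), idx) / f^2
  }
  out
}

# architecture: conv(3->F) relu pool2 | SE-res block(F) [x2 if deep] pool2 |
# GAP dense(F->K). All convs 3x3 pad 1.
build_clf_arch <- function(cfg, n_classes) {
  S <- cfg$input_size; F <- cfg$channels
  n_blocks <- if (cfg$depth == "deep") 2L else 1L
  list(S = S, F = F, n_blocks = n_blocks, n_classes = n_classes,
       g0 = conv_geom(S, S, 3L),
       p0 = pool_geom(S, S, F),
       gb = conv_geom(S %/% 2L, S %/% 2L, F),
       p1 = pool_geom(S %/% 2L, S %/% 2L, F),
       hw_gap = (S %/% 4L)^2)
}

init_clf_params <- function(arch, cfg) {
  F <- arch$F
  cr <- max(1L, F %/% cfg$se_reduction)
  p <- list(W0 = he_mat(9L * 3L, F), b0 = rep(0, F))
  for (b in seq_len(arch$n_blocks)) {
    p[[paste0("Wa", b)]] <- he_mat(9L * F, F)
    p[[paste0("ba", b)]] <- rep(0, F)
    p[[paste0("Wb", b)]] <- he_mat(9L * F, F)
    p[[paste0("bb", b)]] <- rep(0, F)
    p[[paste0("seW1_", b)]] <- he_mat(F, cr)
    p[[paste0("seb1_", b)]] <- rep(0, cr)
    p[[paste0("seW2_", b)]] <- he_mat(cr, F)
    p[[paste0("seb2_", b)]] <- rep(0, F)
  }
  p$Wd <- he_mat(F, arch$n_classes)
  p$bd <- rep(0, arch$n_classes)
  p
}

clf_forward <- function(params, X, arch, want_cache = FALSE) {
  HWb <- (arch$S %/% 2L)^2
  cv0 <- conv_fw(X, params$W0, params$b0, arch$g0)
  a0 <- relu_fw(cv0$out)
  x <- pool_fw(a0, arch$p0)
  caches <- list(cv0 = cv0, a0 = a0, Xin = X, blocks = list())
  for (b in seq_len(arch$n_blocks)) {
    sp <- list(W1 = params[[paste0("seW1_", b)]],
               b1 = params[[paste0("seb1_", b)]],
               W2 = params[[paste0("seW2_", b)]],
               b2 = params[[paste0("seb2_", b)]])
    c1 <- conv_fw(x, params[[paste0("Wa", b)]], params[[paste0("ba", b)]],
                  arch$gb)
    a1 <- relu_fw(c1$out)
    c2 <- conv_fw(a1, params[[paste0("Wb", b)]], params[[paste0("bb", b)]],
                  arch$gb)
    se <- se_fw(c2$out, sp, HWb, arch$F)
    y <- relu_fw(x + se$out)
    caches$blocks[[b]] <- list(xin = x, c1 = c1, a1 = a1, c2 = c2, se = se,
                               y = y, sp = sp)
    x <- y
  }
  pooled <- pool_fw(x, arch$p1)
  feat <- gap_fw(pooled, arch$hw_gap, arch$F)
  logits <- sweep(feat %*% params$Wd, 2, params$bd, "+")
  caches$pre_pool <- x
  caches$pooled <- pooled
  caches$feat <- feat
  if (want_cache) list(logits = logits, cache = caches) else logits
}

clf_backward <- function(params, arch, cache, dlogits) {
  HWb <- (arch$S %/% 2L)^2
  g <- list()
  g$Wd <- crossprod(cache$feat, dlogits)
  g$bd <- colSums(dlogits)
  dfeat <- dlogits %*% t(params$Wd)
  dpooled <- gap_bw(dfeat, arch$hw_gap, arch$F)
  dx <- pool_bw(dpooled, arch$p1)
  for (b in rev(seq_len(arch$n_blocks))) {
    bc <- cache$blocks[[b]]
    dy <- dx * (bc$y > 0)
    dse_out <- dy
    seb <- se_bw(dse_out, bc$c2$out, bc$sp, bc$se, HWb, arch$F)
    g[[paste0("seW1_", b)]] <- seb$dW1
    g[[paste0("seb1_", b)]] <- seb$db1
    g[[paste0("seW2_", b)]] <- seb$dW2
    g[[paste0("seb2_", b)]] <- seb$db2
    cb2 <- conv_bw(seb$dX, params[[paste0("Wb", b)]], arch$gb, bc$c2$Pm)
    g[[paste0("Wb", b)]] <- cb2$dW
    g[[paste0("bb", b)]] <- cb2$db
    da1 <- cb2$dX * (bc$a1 > 0)
    cb1 <- conv_bw(da1, params[[paste0("Wa", b)]], arch$gb, bc$c1$Pm)
    g[[paste0("Wa", b)]] <- cb1$dW
    g[[paste0("ba", b)]] <- cb1$db
    dx <- dy + cb1$dX          # residual skip
  }
  da0 <- pool_bw(dx, arch$p0)
  da0 <- da0 * (cache$a0 > 0)
  cb0 <- conv_bw(da0, params$W0, arch$g0, cache$cv0$Pm)
  g$W0 <- cb0$dW
  g$b0 <- cb0$db
  g
}

tiles_to_matrix <- function(tiles, input_size) {
  X <- matrix(0, length(tiles), input_size^2 * 3)
  for (i in seq_along(tiles)) {
    px <- if (is.list(tiles[[i]])) tiles[[i]]$pixels else tiles[[i]]
    d <- downscale_tile(px, input_size)
    X[i, ] <- as.numeric(d) / 127.5 - 1
  }
  X
}

#' Train the six-class tile classifier
#'
#' Trains the SE-residual network with Adam on softmax cross-entropy.
#' Tiles are split into training and validation sets *by patient* (never by
#' tile) to prevent leakage; the checkpoint with the lowest validation loss
#' is returned. Deterministic for a fixed seed and BLAS.
#'
#' @param tiles List of tiles (arrays or [extract_patches()] entries).
#' @param labels Character/factor vector of true classes, one per tile.
#' @param patient_ids Patient of each tile; `NULL` treats each tile as its
#'   own patient (plain random split).
#' @param cfg A [classifier_config()].
#' @return A `tissue_classifier` with elements `params`, `arch`, `classes`,
#'   `cfg` and `log` (per-epoch train/validation loss).
#' @export
train_classifier <- function(tiles, labels, patient_ids = NULL,
                             cfg = classifier_config()) {
  labels <- as.character(labels)
  stopifnot(length(tiles) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes present to train")
  if (is.null(patient_ids)) patient_ids <- as.character(seq_along(tiles))
  X <- tiles_to_matrix(tiles, cfg$input_size)
  y <- match(labels, classes)
  arch <- build_clf_arch(cfg, length(classes))

  withr_seed(cfg$seed, {
    pats <- unique(patient_ids)
    n_val <- max(1L, round(length(pats) * cfg$val_frac))
    val_pats <- if (length(pats) > 1) sample(pats, n_val) else character()
    is_val <- patient_ids %in% val_pats
    if (!any(is_val)) {       # single patient: fall back to tile split
      is_val <- seq_along(tiles) %in%
        sample(seq_along(tiles), max(1L, round(length(tiles) * cfg$val_frac)))
      warning("single patient: validation split is by tile, not patient")
    }
    miss <- setdiff(classes, labels[!is_val])
    if (length(miss)) {
      warning("class(es) absent from training split: ",
              paste(miss, collapse = ", "), " (kept in output space)")
    }
    params <- init_clf_params(arch, cfg)
    opt <- adam_init(params)
    tr_idx <- which(!is_val)
    tlog <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    best <- list(loss = Inf, params = params)
    onehot <- diag(length(classes))[y, , drop = FALSE]
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr_idx)
      tl <- 0; nb <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        fw <- clf_forward(params, X[bi, , drop = FALSE], arch,
                          want_cache = TRUE)
        p <- softmax_rows(fw$logits)
        loss <- -mean(log(pmax(p[cbind(seq_along(bi),
                                       y[bi])], 1e-12)))
        dlogits <- (p - onehot[bi, , drop = FALSE]) / length(bi)
        grads <- clf_backward(params, arch, fw$cache, dlogits)
        st <- adam_step(params, grads, opt, cfg$learning_rate)
        params <- st$params; opt <- st$state
        tl <- tl + loss; nb <- nb + 1
      }
      vl <- clf_loss(params, arch, X[is_val, , drop = FALSE], y[is_val])
      tlog <- rbind(tlog, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl))
      if (vl < best$loss) best <- list(loss = vl, params = params)
    }
  })
  structure(list(params = best$params, arch = arch, classes = classes,
                 cfg = cfg, log = tlog, val_loss = best$loss),
            class = "tissue_classifier")
}

clf_loss <- function(params, arch, X, y, chunk = 256L) {
  if (nrow(X) == 0) return(NA_real_)
  tot <- 0
  for (s in seq(1, nrow(X), by = chunk)) {
    i <- s:min(s + chunk - 1, nrow(X))
    p <- softmax_rows(clf_forward(params, X[i, , drop = FALSE], arch))
    tot <- tot + sum(-log(pmax(p[cbind(seq_along(i), y[i])], 1e-12)))
  }
  tot / nrow(X)
}

#' Predict class probabilities for tiles
#' @param model A `tissue_classifier`.
#' @param tiles List of tiles.
#' @return N x K probability matrix (rows sum to 1), columns named by class.
#' @export
predict_classifier <- function(model, tiles, chunk = 256L) {
  X <- tiles_to_matrix(tiles, model$cfg$input_size)
  out <- matrix(0, nrow(X), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (s in seq(1, nrow(X), by = chunk)) {
    i <- s:min(s + chunk - 1, nrow(X))
    out[i, ] <- softmax_rows(clf_forward(model$params,
                                         X[i, , drop = FALSE], model$arch))
  }
  out
}

#' Area under the ROC curve (rank estimator)
#'
#' Mann-Whitney formulation: ties in score contribute 1/2.
#' @param score Numeric scores (higher = more positive).
#' @param truth Logical/0-1 labels.
#' @return AUC in `[0, 1]`, or `NA` if a class is empty.
#' @export
roc_auc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a classifier
#'
#' One-vs-rest ROC AUC per class, micro average (pooling every
#' (tile, class) decision), macro average (mean of per-class AUCs), and the
#' row-normalized confusion matrix.
#'
#' @param model A `tissue_classifier`, or `NULL` when `probs` is given.
#' @param tiles List of tiles (ignored when `probs` is given).
#' @param labels True classes.
#' @param probs Optional precomputed probability matrix.
#' @return List with `auc` (named per class; classes without truth
#'   instances are `NA`), `macro_auc`, `micro_auc`, `confusion`
#'   (row-normalized) and `accuracy`.
#' @export
evaluate_classifier <- function(model, tiles = NULL, labels, probs = NULL) {
  if (is.null(probs)) probs <- predict_classifier(model, tiles)
  labels <- as.character(labels)
  classes <- colnames(probs)
  stopifnot(all(labels %in% classes))
  auc <- vapply(classes, function(k) {
    roc_auc(probs[, k], labels == k)
  }, numeric(1))
  micro <- roc_auc(as.numeric(probs),
                   as.numeric(outer(labels, classes, "==")))
  pred <- classes[max.col(probs, ties.method = "first")]
  cm <- table(factor(labels, classes), factor(pred, classes))
  cm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
  list(auc = auc, macro_auc = mean(auc, na.rm = TRUE), micro_auc = micro,
       confusion = as.matrix(cm), accuracy = mean(pred == labels))
}

#' Segment an image into a tissue-class map
#'
#' Runs the classifier over a patch grid; positions failing the tissue
#' fraction test are labelled `"BG"` (background).
#'
#' @param model A `tissue_classifier`.
#' @param image H x W x 3 array.
#' @param mask Binary tissue mask (e.g. [otsu_mask()]).
#' @param patch_size,stride Grid geometry in pixels.
#' @param min_tissue_frac Minimum in-window tissue fraction.
#' @return A `segmentation_map`: data.frame with 0-based `row`, `col`, the
#'   argmax `class` and one probability column per class (`NA` for BG),
#'   plus attributes `grid_dim`, `patch_size`, `stride`.
#' @export
segment_wsi <- function(model, image, mask, patch_size, stride = patch_size,
                        min_tissue_frac = 0.5) {
  H <- dim(image)[1]; W <- dim(image)[2]
  r0 <- seq(0L, H - patch_size, by = stride)
  c0 <- seq(0L, W - patch_size, by = stride)
  grid <- expand.grid(col = c0, row = r0)[, c("row", "col")]
  keep <- logical(nrow(grid))
  tiles <- list()
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; cc <- grid$col[i]
    win <- mask[(r + 1):(r + patch_size), (cc + 1):(cc + patch_size)]
    if (mean(win) >= min_tissue_frac) {
      keep[i] <- TRUE
      tiles[[length(tiles) + 1L]] <-
        image[(r + 1):(r + patch_size), (cc + 1):(cc + patch_size), ,
              drop = FALSE]
    }
  }
  pm <- matrix(NA_real_, nrow(grid), length(model$classes),
               dimnames = list(NULL, paste0("p_", model$classes)))
  cls <- rep("BG", nrow(grid))
  if (length(tiles)) {
    probs <- predict_classifier(model, tiles)
    pm[keep, ] <- probs
    cls[keep] <- model$classes[max.col(probs, ties.method = "first")]
  }
  out <- cbind(grid, class = cls, as.data.frame(pm))
  structure(out, class = c("segmentation_map", "data.frame"),
            grid_dim = c(length(r0), length(c0)),
            patch_size = patch_size, stride = stride)
}
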