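# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition (explicit pair/term loops),
# not from the package's vectorized implementations.

# Harrell C-index by O(n^2) pair enumeration.
brute_cindex <- function(scores, times, events) {
  conc <- 0; pairs <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (events[i] && times[i] < times[j]) {
      pairs <- pairs + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / pairs
}

# AUC by exhaustive positive/negative pair counting.
brute_auc <- function(score, truth) {
  pos <- score[as.logical(truth)]
  neg <- score[!as.logical(truth)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Two-group log-rank by explicit 2x2 tables at each event time.
brute_logrank <- function(ta, ea, tb, eb) {
  times <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t & ea == 1); d2 <- sum(tb == t & eb == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox negative partial log-likelihood by direct summation.
brute_cox_npll <- function(scores, times, events, tie = "breslow") {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    if (tie == "breslow") {
      ll <- ll + sum(scores[D]) - d * log(sum(exp(scores[R])))
    } else {
      sR <- sum(exp(scores[R])); sD <- sum(exp(scores[D]))
      for (l in seq_len(d) - 1) {
        ll <- ll - log(sR - (l / d) * sD)
      }
      ll <- ll + sum(scores[D])
    }
  }
  -ll
}

# Dunn pairwise z from first principles (explicit mid-ranks and tie sum).
brute_dunn_z <- function(values, groups, g1, g2) {
  N <- length(values)
  srt <- sort(values)
  midrank <- function(v) mean(which(srt == v))
  r <- vapply(values, midrank, numeric(1))
  tie_counts <- as.numeric(table(values))
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
  n1 <- sum(groups == g1); n2 <- sum(groups == g2)
  (m1 - m2) / sqrt((N * (N + 1) / 12 - tie_term) * (1 / n1 + 1 / n2))
}

# Random right-censored survival fixture.
random_surv <- function(n, seed, tie_prob = 0) {
  set.seed(seed)
  times <- rexp(n, 0.1)
  if (tie_prob > 0) times <- round(times)  # induce ties
  times <- pmax(times, 0.5)
  events <- runif(n) < 0.7
  if (!any(events)) events[1] <- TRUE
  list(times = times, events = events, scores = rnorm(n))
}

# Small labelled synthetic tile set.
make_tile_set <- function(n_per_class, size_px = 32, seed0 = 0,
                          classes = TISSUE_CLASSES) {
  tiles <- list(); labels <- character(); pids <- character()
  k <- 0
  for (cls in classes) for (i in seq_len(n_per_class)) {
    k <- k + 1
    tiles[[k]] <- generate_tissue_tile(cls, size_px, seed0 + k)
    labels[k] <- cls
    pids[k] <- paste0("pt", (i - 1) %/% 5)
  }
  list(tiles = tiles, labels = labels, patient_ids = pids)
}
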