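test_that("Cox partial likelihood reduces to risk-set sizes at equal scores", {
  # all events, equal scores: sum of log risk-set sizes
  expect_equal(cox_npll(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)),
               log(3) + log(2) + log(1))
  # one event among n equal-score patients
  n <- 17
  expect_equal(cox_npll(rep(0, n), c(1, 2:n), c(1, rep(0, n - 1))), log(n))
})

test_that("Cox loss matches brute-force summation under both tie rules", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 8
    times <- sample(1:4, n, replace = TRUE)      # heavy ties
    events <- c(1, rbinom(n - 1, 1, 0.7))
    scores <- rnorm(n)
    for (tie in c("breslow", "efron")) {
      expect_equal(cox_npll(scores, times, events, tie),
                   brute_cox_npll(scores, times, events, tie),
                   tolerance = 1e-9)
    }
    # cross-check Breslow against the survival package's log-likelihood
    # at a fixed coefficient (score = 1 * x)
    fit <- survival::coxph(survival::Surv(times, events) ~ x,
                           data = data.frame(times, events, x = scores),
                           init = 1, ties = "breslow",
                           control = survival::coxph.control(iter.max = 0))
    expect_equal(cox_npll(scores, times, events, "breslow"),
                 -fit$loglik[2], tolerance = 1e-8)
  }
})

test_that("Cox loss gradients agree with numerical differentiation", {
  set.seed(2)
  n <- 10
  times <- sample(1:5, n, replace = TRUE)
  events <- c(1, rbinom(n - 1, 1, 0.6))
  scores <- rnorm(n)
  for (tie in c("breslow", "efron")) {
    g <- pathomics:::cox_npll_grad(scores, times, events, tie)
    for (i in c(1, 4, 9)) {
      eps <- 1e-6
      sp <- scores; sp[i] <- sp[i] + eps
      sm <- scores; sm[i] <- sm[i] - eps
      num <- (cox_npll(sp, times, events, tie) -
                cox_npll(sm, times, events, tie)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("Cox loss is shift invariant and rewards raising an event score", {
  set.seed(5)
  n <- 12
  times <- rexp(n) + 0.1
  events <- c(1, rbinom(n - 1, 1, 0.5))
  scores <- rnorm(n)
  expect_equal(cox_npll(scores, times, events),
               cox_npll(scores + 13.7, times, events), tolerance = 1e-9)
  first <- which(events == 1)[which.min(times[events == 1])]
  raised <- scores
  raised[first] <- raised[first] + 1
  expect_lt(cox_npll(raised, times, events), cox_npll(scores, times, events))
  expect_error(cox_npll(scores, times, rep(0, n)), "no events")
})

test_that("binary cross-entropy has its closed-form values", {
  expect_equal(bce(0.5, 1), log(2))
  p <- c(0.6, 0.9, 0.99, 0.9999)
  v <- vapply(p, bce, numeric(1), label = 1)
  expect_true(all(diff(v) < 0))
  set.seed(3)
  probs <- runif(10, 0.05, 0.95)
  labs <- rbinom(10, 1, 0.5)
  expect_equal(bce(probs, labs),
               mean(vapply(seq_len(10), function(i) {
                 bce(probs[i], labs[i])
               }, numeric(1))))
})

test_that("risk-network training is deterministic and flags missing tiles", {
  spec <- cohort_spec(n_patients = 40, tiles_per_patient_per_class = 2,
                      tile_size_px = 32, true_beta = c(IC = 1.5), seed = 6)
  co <- generate_cohort(spec)
  cfg <- risk_net_config(epochs = 40, patience = 5)
  m1 <- train_tissue_risk(co, "IC", net_cfg = cfg, seed = 3)
  m2 <- train_tissue_risk(co, "IC", net_cfg = cfg, seed = 3)
  expect_identical(m1$scores, m2$scores)
  expect_false(any(m1$scores$missing))
  expect_true(all(m1$scores$score >= 0 & m1$scores$score <= 1))
  # drop one patient's tiles: flagged missing, others still scored
  co2 <- co
  co2$tiles <- co2$tiles[co2$tiles$patient_id != "P0003" |
                           co2$tiles$class != "IC", ]
  m3 <- train_tissue_risk(co2, "IC", net_cfg = cfg, seed = 3)
  expect_true(m3$scores$missing[m3$scores$patient_id == "P0003"])
  expect_true(is.na(m3$scores$score[m3$scores$patient_id == "P0003"]))
})

test_that("a strong BCE weight aligns scores with the event labels", {
  spec <- cohort_spec(n_patients = 60, tiles_per_patient_per_class = 2,
                      tile_size_px = 32, true_beta = c(IC = 2.5),
                      baseline_hazard_rate = 0.02, seed = 14)
  co <- generate_cohort(spec)
  m <- train_tissue_risk(co, "IC",
                         loss_cfg = joint_loss_config(lambda_bce = 25),
                         net_cfg = risk_net_config(epochs = 120,
                                                   patience = 10),
                         seed = 2)
  s <- m$scores$score_raw
  ev <- as.numeric(co$patients$recurrence_event)
  r <- cor(pathomics:::sigmoid(s), ev)
  expect_gt(r, 0.5)
})

test_that("attention maps normalize per slide and rank by risk contribution", {
  spec <- cohort_spec(n_patients = 30, tiles_per_patient_per_class = 2,
                      tile_size_px = 32, true_beta = c(IC = 1.5), seed = 8)
  co <- generate_cohort(spec)
  m <- train_tissue_risk(co, "IC", net_cfg = risk_net_config(epochs = 30),
                         seed = 1)
  tiles <- lapply(1:4, function(i) {
    generate_tissue_tile("IC", 32, 900 + i, contrast = c(0.7, 1, 1.3, 1.6)[i])
  })
  a <- attention_map(m, tiles)
  expect_true(all(a >= 0 & a <= 1))
  # leave-one-out contribution oracle: removing the highest-attention tile
  # should lower the pooled patient score the most
  full <- predict_tissue_risk(m, tiles, normalized = FALSE)
  deltas <- vapply(1:4, function(i) {
    full - predict_tissue_risk(m, tiles[-i], normalized = FALSE)
  }, numeric(1))
  expect_identical(order(a), order(deltas))
  # constant input: flat map at the 0.5 midpoint
  same <- rep(tiles[1], 4)
  expect_equal(attention_map(m, same), rep(0.5, 4))
})
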