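# Full predictor: forward contracts, scheduler law, metrics, cross-validation.

small_cfg <- function(...) {
  model_config(n_layers = 2L, hidden_dim = 8L, epochs = 4L, seed = 61L, ...)
}

test_that("forward output is a proper probability aligned with the input", {
  ds <- tiny_dataset(1, c(14, 14), seed = 62)
  g <- protein_graph(ds[[1]]$coords, ds[[1]]$features, labels = ds[[1]]$labels)
  cfg <- small_cfg()
  w <- model_init(cfg, 62L)
  pr <- model_forward(g, w, cfg)
  expect_equal(nrow(pr), 14L)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_identical(pr$call, as.integer(pr$prob >= 0.5))
  expect_equal(sum(pr$sampled), ceiling(0.3 * 14))
  # feature-width mismatch is a shape error
  g2 <- protein_graph(ds[[1]]$coords, ds[[1]]$features, group = "all")
  expect_error(model_forward(g2, w, cfg), "width")
})

test_that("predicted probabilities are invariant to rigid transforms and permute with nodes", {
  ds <- tiny_dataset(1, c(12, 12), seed = 63)
  p <- ds[[1]]
  cfg <- small_cfg()
  w <- model_init(cfg, 62L)
  g <- protein_graph(p$coords, p$features)
  base <- model_forward(g, w, cfg)
  set.seed(64)
  for (t in 1:5) {
    gt <- g
    gt$X <- apply_rigid(g$X, random_rotation(), rnorm(3, sd = 8))
    out <- model_forward(gt, w, cfg)
    expect_equal(out$prob, base$prob, tolerance = 1e-5)
  }
  perm <- sample(12)
  gp <- g
  gp$A <- g$A[perm, perm]; gp$H <- g$H[perm, ]; gp$X <- g$X[perm, ]
  outp <- model_forward(gp, w, cfg)
  expect_equal(outp$prob, base$prob[perm], tolerance = 1e-8)
})

test_that("architecture flags alter the forward pass but keep its contracts", {
  ds <- tiny_dataset(1, c(14, 14), seed = 95)
  p <- ds[[1]]
  g <- protein_graph(p$coords, p$features)
  base_cfg <- small_cfg()
  w <- model_init(base_cfg, 62L)
  # seed nonzero phi_h/phi_x so flag effects are visible
  w <- with_seed(96, function() {
    for (b in seq_along(w$blocks)) for (s in names(w$blocks[[b]])) {
      # small perturbations keep the head unsaturated so flag effects
      # are visible in the probabilities
      w$blocks[[b]][[s]]$phi_h$W2 <- matrix(
        rnorm(length(w$blocks[[b]][[s]]$phi_h$W2), sd = 0.02),
        nrow(w$blocks[[b]][[s]]$phi_h$W2))
      w$blocks[[b]][[s]]$phi_x$W2 <- matrix(
        rnorm(length(w$blocks[[b]][[s]]$phi_x$W2), sd = 0.01),
        nrow(w$blocks[[b]][[s]]$phi_x$W2))
    }
    w
  })
  base <- model_forward(g, w, base_cfg)
  for (cfg in list(small_cfg(coord_stages = "stage1"),
                   small_cfg(regate_per_block = TRUE),
                   small_cfg(recompute_selection = TRUE))) {
    out <- model_forward(g, w, cfg)
    expect_false(isTRUE(all.equal(out$prob, base$prob)))
    expect_true(all(out$prob >= 0 & out$prob <= 1))
    # rigid-transform invariance holds under every flag
    gt <- g
    gt$X <- apply_rigid(g$X, random_rotation(), rnorm(3, sd = 5))
    expect_equal(model_forward(gt, w, cfg)$prob, out$prob, tolerance = 1e-5)
  }
})

test_that("plateau scheduler follows the closed-form decay law", {
  # frozen monitor: lr after epoch t is lr0 * f^floor(t/patience), floored
  lr0 <- 5e-4
  st <- scheduler_init(lr0, factor = 0.6, patience = 10L, lr_min = 1e-6)
  lrs <- numeric(60)
  st <- scheduler_step(st, 0.5)  # epoch 1 sets the incumbent best
  lrs[1] <- st$lr
  for (t in 2:60) {
    st <- scheduler_step(st, 0.5)  # never improves again
    lrs[t] <- st$lr
  }
  expected <- pmax(lr0 * 0.6^(floor(((1:60) - 1) / 10)), 1e-6)
  expect_equal(lrs, expected, tolerance = 1e-12)
  # strictly improving monitor: the rate never decays
  st2 <- scheduler_init(lr0, 0.6, 10L, 1e-6)
  for (t in 1:30) st2 <- scheduler_step(st2, t)
  expect_equal(st2$lr, lr0)
  # the floor binds eventually
  st3 <- scheduler_init(1e-5, 0.1, 1L, 1e-6)
  for (t in 1:10) st3 <- scheduler_step(st3, 0)
  expect_equal(st3$lr, 1e-6)
})

test_that("training runs, logs the schedule, and is deterministic", {
  ds <- tiny_dataset(3, c(10, 14), seed = 65)
  cfg <- small_cfg()
  fit <- train(ds, cfg, val_dataset = ds)
  expect_s3_class(fit, "sc_model")
  expect_equal(nrow(fit$log), cfg$epochs)
  expect_true(all(c("epoch", "loss", "val_auprc", "lr") %in% names(fit$log)))
  expect_equal(fit$log$lr[1], cfg$learning_rate)
  fit2 <- train(ds, cfg, val_dataset = ds)
  expect_equal(fit$weights, fit2$weights, tolerance = 1e-12)
  expect_error(train(list(), cfg), "nonempty")
  # broom-style accessors
  expect_identical(tidy(fit), fit$log)
  expect_equal(glance(fit)$epochs, cfg$epochs)
})

test_that("a tiny high-signal problem is learnable by gradient descent", {
  ds <- generate_dataset(2, c(14, 18), seed = 66, signal_strength = 0.95)
  cfg <- model_config(n_layers = 1L, hidden_dim = 8L, epochs = 25L,
                      learning_rate = 2e-3, seed = 67L)
  fit <- train(ds, cfg, val_dataset = ds)
  pr <- predict(fit, ds)
  labels <- unlist(lapply(ds, function(p) p$labels))
  expect_gte(auroc(labels, pr$prob), 0.95)
})

test_that("models round-trip through JSON checkpoints at double precision", {
  ds <- tiny_dataset(2, c(10, 12), seed = 74)
  cfg <- model_config(n_layers = 1L, hidden_dim = 6L, epochs = 2L, seed = 75L)
  fit <- train(ds, cfg, val_dataset = ds)
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, f)
  back <- read_checkpoint(f)
  expect_equal(unclass(back$weights), unclass(fit$weights),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$feature_group, fit$feature_group)
  expect_equal(back$config$learning_rate, fit$config$learning_rate)
  g <- protein_graph(ds[[1]]$coords, ds[[1]]$features)
  expect_equal(model_forward(g, back)$prob, model_forward(g, fit)$prob,
               tolerance = 1e-9)
})

test_that("rank-based AUROC and step-wise AUPRC match brute-force counting", {
  set.seed(68)
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_equal(auroc(labels, scores), brute_auroc(labels, scores),
                 tolerance = 1e-9)
    expect_equal(auprc(labels, scores), brute_auprc(labels, scores),
                 tolerance = 1e-9)
  }
})

test_that("ranking metrics agree with an independent library implementation", {
  set.seed(69)
  labels <- rbinom(300, 1, 0.2)
  scores <- runif(300) + 0.3 * labels
  expect_equal(auroc(labels, scores),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("evaluate reproduces closed forms and handles degenerate inputs", {
  set.seed(70)
  for (rep in 1:50) {
    n <- 30
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- runif(n)
    ev <- evaluate(labels, scores)
    tp <- sum(scores >= .5 & labels == 1); tn <- sum(scores < .5 & labels == 0)
    fp <- sum(scores >= .5 & labels == 0); fn <- sum(scores < .5 & labels == 1)
    expect_identical(c(ev$TP, ev$TN, ev$FP, ev$FN), c(tp, tn, fp, fn))
    expect_equal(ev$TP + ev$TN + ev$FP + ev$FN, n)
    expect_equal(ev$ACC, (tp + tn) / n, tolerance = 1e-12)
    if (tp + fp > 0) expect_equal(ev$Precision, tp / (tp + fp), tolerance = 1e-12)
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (mcc_den > 0)
      expect_equal(ev$MCC, (tp * tn - fp * fn) / mcc_den, tolerance = 1e-12)
  }
  # perfect separation
  evp <- evaluate(c(0, 0, 1, 1), c(.1, .2, .8, .9))
  expect_equal(c(evp$AUROC, evp$AUPRC, evp$MCC), c(1, 1, 1))
  # everything called positive: recall 1, precision = prevalence
  # (degenerate denominators warn by contract)
  eva <- suppressWarnings(evaluate(c(0, 1, 1, 0), c(.9, .8, .9, .7)))
  expect_equal(eva$Recall, 1)
  expect_equal(eva$Precision, 0.5)
  expect_error(evaluate(c(0, 1), c(.5, .5, .5)), "equal length")
  # single-class labels: ranking metrics are undefined (warned, NA)
  ev1 <- suppressWarnings(evaluate(c(1, 1), c(.4, .6)))
  expect_true(is.na(ev1$AUROC) && is.na(ev1$AUPRC))
  expect_error(auroc(c(1, 1), c(.4, .6)), "single class")
  expect_error(auprc(c(0, 0), c(.4, .6)), "single class")
})

test_that("fold assignment is id-keyed, disjoint and exhaustive", {
  ids <- sprintf("p%02d", 1:10)
  f <- fold_assignment(ids, 5, seed = 71)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 2))
  expect_identical(f, fold_assignment(ids, 5, seed = 71))
  # shuffling the input order permutes the labels consistently with the ids
  perm <- sample(10)
  f2 <- fold_assignment(ids[perm], 5, seed = 71)
  expect_identical(f2, f[perm])
  expect_error(fold_assignment(ids[1:3], 5, seed = 1), "fewer proteins")
})

test_that("cross-validation trains on disjoint folds and aggregates", {
  ds <- tiny_dataset(4, c(10, 12), seed = 72)
  cfg <- model_config(n_layers = 1L, hidden_dim = 6L, epochs = 2L, seed = 73L)
  cv <- suppressWarnings(cross_validate(ds, cfg, k = 2L))  # tiny folds warn
  expect_equal(nrow(cv), 2L)
  expect_true(all(c("fold", "AUROC", "MCC") %in% names(cv)))
  expect_equal(nrow(glance(cv)), 1L)
  folds <- attr(cv, "folds")
  expect_equal(sort(unique(folds)), 1:2)
  expect_error(cross_validate(ds, cfg, k = 1L), "at least 2")
  expect_error(cross_validate(ds, cfg, k = 5L), "fewer proteins")
})
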