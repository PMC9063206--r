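# Three-branch network: gradient correctness, softmax/eval-mode
# contracts, training protocol, permutation null, and the baseline
# family.

tiny_bundle <- function(n, d = c(5, 3, 2), signal = 1, seed = 1) {
  set.seed(seed)
  z <- rnorm(n)
  y <- runif(n) < plogis(signal * z)
  mk <- function(k, s) matrix(rnorm(n * k) + s * z, n, k)
  list(tss = mk(d[1], 0.4 * signal), demographics = mk(d[2], 0.3 * signal),
       severity = mk(d[3], 0.5 * signal), label = y)
}

test_that("analytic gradients match numerical differentiation", {
  for (post in c(8, 0)) {
    cfg <- nn_config(branch_hidden = c(6, 4), post_concat = post,
                     dropout = 0, epochs = 1, seed = 3)
    b <- tiny_bundle(7)
    xs <- dreamHF:::bundle_inputs(b)
    par <- dreamHF:::nn_init(c(5, 3, 2), cfg)
    y <- as.numeric(b$label)
    fc <- dreamHF:::nn_forward(par, xs, cfg, training = TRUE)
    gr <- dreamHF:::nn_backward(par, fc, y, cfg)
    loss_at <- function(p) {
      f <- dreamHF:::nn_forward(p, xs, cfg, training = TRUE)
      dreamHF:::nn_loss(f$p, y)
    }
    eps <- 1e-5
    for (nm in c("b1.W1", "b2.W2", "b1.g", "b3.be", "b2.b1",
                 if (post > 0) "Wc", "Wo", "bo")) {
      th <- par[[nm]]
      idx <- seq_len(min(6, length(th)))
      for (i in idx) {
        pp <- par; pp[[nm]][i] <- th[i] + eps
        pm <- par; pm[[nm]][i] <- th[i] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(as.numeric(gr[[nm]][i]), num, tolerance = 1e-4,
                     info = sprintf("param %s[%d] post=%d", nm, i, post))
      }
    }
  }
})

test_that("softmax rows sum to one and inference is deterministic", {
  cfg <- nn_config(branch_hidden = c(8, 4, 3), epochs = 2, seed = 5)
  b <- tiny_bundle(40)
  m <- build_network(5, 3, 2, cfg)
  fc <- dreamHF:::nn_forward(m$params, dreamHF:::bundle_inputs(b), cfg)
  expect_equal(rowSums(fc$p), rep(1, 40), tolerance = 1e-12)
  expect_identical(predict(m, b), predict(m, b))  # dropout off at inference
})

test_that("training records one validation AUROC per epoch and restores the best epoch", {
  cfg <- nn_config(branch_hidden = c(8, 4, 3), epochs = 6, batch_size = 8,
                   seed = 2)
  tr <- tiny_bundle(120, seed = 1)
  va <- tiny_bundle(60, seed = 2)
  m <- train_network(build_network(5, 3, 2, cfg), tr, va)
  expect_equal(nrow(m$history), 6L)
  expect_equal(m$best_epoch, which.max(m$history$val_auroc))
  # deterministic end to end under the same seed
  m2 <- train_network(build_network(5, 3, 2, cfg), tr, va)
  expect_identical(m$history, m2$history)
  expect_identical(predict(m, va), predict(m2, va))
})

test_that("degenerate inputs are refused", {
  expect_error(build_network(0, 3, 2), class = "dreamHF_config_error")
  tr <- tiny_bundle(30)
  tr$label <- rep(TRUE, 30)
  expect_error(train_network(build_network(5, 3, 2, nn_config(epochs = 1)),
                             tr, tiny_bundle(10)),
               class = "dreamHF_config_error")
  expect_error(nn_config(dropout = 1), class = "dreamHF_config_error")
})

test_that("permuted labels give chance-level validation AUROC at n = 1000", {
  aucs <- vapply(1:3, function(seed) {
    tr <- tiny_bundle(1000, signal = 1.5, seed = seed)
    va <- tiny_bundle(400, signal = 1.5, seed = seed + 100)
    set.seed(seed)
    tr$label <- sample(tr$label)   # break the feature-label link
    va$label <- sample(va$label)
    cfg <- nn_config(branch_hidden = c(16, 8, 4), epochs = 5, batch_size = 20,
                     seed = seed)
    m <- train_network(build_network(5, 3, 2, cfg), tr, va)
    m$history$val_auroc[nrow(m$history)]
  }, numeric(1))
  expect_true(all(aucs > 0.4 & aucs < 0.6))
})

test_that("a signal-bearing bundle is learned well above chance", {
  tr <- tiny_bundle(800, signal = 2, seed = 7)
  va <- tiny_bundle(300, signal = 2, seed = 8)
  te <- tiny_bundle(300, signal = 2, seed = 9)
  cfg <- nn_config(branch_hidden = c(16, 8, 4), epochs = 8, batch_size = 20,
                   seed = 1)
  m <- train_network(build_network(5, 3, 2, cfg), tr, va)
  expect_gt(auroc_delong(predict(m, te), te$label)$auroc, 0.75)
})

test_that("layer-ablation variants are expressible through the config", {
  tr <- tiny_bundle(60); va <- tiny_bundle(30)
  for (cfg in list(nn_config(branch_hidden = c(8, 6, 4, 3), epochs = 1),
                   nn_config(branch_hidden = 8, epochs = 1),
                   nn_config(post_concat = 0, epochs = 1))) {
    m <- train_network(build_network(5, 3, 2, cfg), tr, va)
    expect_length(predict(m, va), 30)
  }
})

# --- baselines ---------------------------------------------------------

fake_feature_bundle <- function(n, seed, signal = 2) {
  set.seed(seed)
  z <- rnorm(n)
  y <- runif(n) < plogis(signal * z)
  structure(list(
    tss = matrix(rnorm(n * 6) + 0.5 * z, n, 6,
                 dimnames = list(NULL, paste0("decay:p", 1:6))),
    demographics = matrix(rnorm(n * 3) + 0.3 * z, n, 3,
                          dimnames = list(NULL, paste0("d", 1:3))),
    severity = matrix(rnorm(n * 2) + 0.6 * z, n, 2,
                      dimnames = list(NULL, c("charlson", "elixhauser"))),
    tabular = matrix(rnorm(n * 5) + 0.5 * z, n, 5,
                     dimnames = list(NULL, paste0("t", 1:5))),
    label = y), class = "feature_bundle")
}

test_that("baselines expose winning hyperparameters and honour the input mode", {
  tr <- fake_feature_bundle(300, 1)
  va <- fake_feature_bundle(150, 2)
  fits <- fit_baselines(tr, va, mode = "tss", seed = 1)
  expect_setequal(names(fits), c("svm", "knn", "decision_tree",
                                 "random_forest", "xgb_tree", "xgb_dart"))
  for (f in fits) {
    expect_true(length(f$params) >= 1)
    expect_true(f$val_auroc > 0 && f$val_auroc < 1)
  }
  # tss-mode width equals the NN's total input width
  expect_equal(ncol(dreamHF:::baseline_input(tr, "tss")),
               ncol(tr$tss) + ncol(tr$demographics) + ncol(tr$severity))
  expect_error(fit_baselines(tr, va, mode = "bogus"))
})

test_that("random forest recovers a planted signal well above chance", {
  tr <- fake_feature_bundle(400, 3)
  va <- fake_feature_bundle(250, 4)
  fit <- fit_baselines(tr, va, mode = "tabular", seed = 1,
                       models = "random_forest")$random_forest
  # 3 permutation-based standard errors above 0.5
  n1 <- sum(va$label); n0 <- sum(!va$label)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_gt(fit$val_auroc, 0.5 + 3 * se)
})
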