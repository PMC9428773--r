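test_that("head_forward matches hand-computed swish/softmax arithmetic", {
  # 2-dim toy: one hidden unit pair, hand-set weights
  W1 <- matrix(c(1, -1, 0.5, 2), nrow = 2)
  b1 <- c(0.1, -0.2)
  W2 <- matrix(c(1, 0, -1, 0.5, 0.3, 0.2), nrow = 2)
  b2 <- c(0, 0.1, -0.1)
  e <- c(0.3, -0.7)
  z1 <- as.numeric(e %*% W1) + b1
  h <- z1 / (1 + exp(-z1))
  z2 <- as.numeric(h %*% W2) + b2
  expected <- exp(z2 - max(z2)) / sum(exp(z2 - max(z2)))
  got <- head_forward(toy_head(W1, b1, W2, b2), e)
  expect_equal(unname(got), expected, tolerance = 1e-9)
})

test_that("head_forward output is a valid distribution; zero head is uniform", {
  zero <- toy_head(matrix(0, 4, 2), c(0, 0), matrix(0, 2, 3), c(0, 0, 0))
  expect_equal(unname(head_forward(zero, rep(1, 4))), rep(1 / 3, 3))
  h <- toy_head(seeded(9, matrix(rnorm(8), 4, 2)), rnorm(2),
                matrix(rnorm(6), 2, 3), rnorm(3))
  P <- head_forward(h, seeded(10, matrix(rnorm(20), 5, 4)))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-9)
  bad <- toy_head(matrix(NaN, 4, 2), c(0, 0), matrix(0, 2, 3), c(0, 0, 0))
  expect_error(head_forward(bad, rep(1, 4)), "non-finite")
})

test_that("training solves a separable problem with high balanced accuracy", {
  tr <- gaussian_clusters(100, seed = 42)
  te <- gaussian_clusters(50, seed = 43)
  fit <- train_head(tr$x, tr$y, te$x, te$y,
                    training_config(init_seed = 5, shuffle_seed = 6))
  pred <- phases[max.col(head_forward(fit$head, te$x))]
  rep <- per_class_metrics(confusion(te$y, pred))
  expect_gte(multiclass_balanced_accuracy(rep, "kelleher"), 0.95)
  expect_equal(fit$history$best_epoch, which.min(fit$history$val_loss))
})

test_that("early stopping halts after `patience` non-improving epochs and restores best weights", {
  tr <- gaussian_clusters(20, seed = 44)
  # learning rate 0: weights never change, so validation loss is flat
  # and epoch 1 is the only improvement over the initial Inf
  fit <- train_head(tr$x, tr$y, tr$x, tr$y,
                    training_config(learning_rate = 0, patience = 3,
                                    max_epochs = 50))
  expect_equal(fit$history$stopped_epoch, 1 + 3)
  expect_equal(fit$history$best_epoch, 1)
  # patience 0: stops at the first non-improving epoch
  fit0 <- train_head(tr$x, tr$y, tr$x, tr$y,
                     training_config(learning_rate = 0, patience = 0,
                                     max_epochs = 50))
  expect_equal(fit0$history$stopped_epoch, 2)
})

test_that("training is reproducible with fixed seeds and validates inputs", {
  tr <- gaussian_clusters(20, seed = 45)
  cfg <- training_config(init_seed = 3, shuffle_seed = 4, max_epochs = 5,
                         patience = 2)
  f1 <- train_head(tr$x, tr$y, tr$x, tr$y, cfg)
  f2 <- train_head(tr$x, tr$y, tr$x, tr$y, cfg)
  expect_identical(f1$head$W1, f2$head$W1)
  expect_identical(f1$history$val_loss, f2$history$val_loss)
  expect_error(train_head(matrix(numeric(0), 0, 4), character(0),
                          tr$x, tr$y, cfg), "empty training set")
  expect_error(train_head(tr$x, tr$y, matrix(numeric(0), 0, 4),
                          character(0), cfg), "non-empty")
  one_class <- tr$x[tr$y == "inhalation", ]
  expect_warning(train_head(one_class, rep("inhalation", nrow(one_class)),
                            tr$x[1:5, ], tr$y[1:5], cfg), "single class")
})

test_that("ensemble selection takes the k lowest validation losses, ties to first", {
  mk <- function(i) toy_head(matrix(i, 2, 2), c(0, 0), matrix(0, 2, 3), numeric(3))
  cands <- Map(function(i, l) list(head = mk(i), val_loss = l),
               1:5, c(0.5, 0.2, 0.9, 0.1, 0.3))
  ens <- select_ensemble(cands, k = 3)
  expect_equal(ens$indices, c(4L, 2L, 5L))
  tie <- Map(function(i, l) list(head = mk(i), val_loss = l),
             1:3, c(0.2, 0.2, 0.5))
  expect_equal(select_ensemble(tie, k = 1)$indices, 1L)
  expect_error(select_ensemble(tie, k = 4), "at least 4")
})

test_that("soft voting averages member probabilities with equal weights", {
  # members engineered to output known probabilities via large logits
  mk_const <- function(p) {
    toy_head(matrix(0, 2, 2), c(0, 0), matrix(0, 2, 3), log(p))
  }
  ens <- structure(list(heads = list(mk_const(c(0.6, 0.2, 0.2)),
                                     mk_const(c(0.5, 0.3, 0.2)),
                                     mk_const(c(0.4, 0.4, 0.2))),
                        val_losses = c(0.1, 0.2, 0.3)),
                   class = "ensemble")
  p <- ensemble_predict(ens, c(0, 0))
  expect_equal(unname(p), c(0.5, 0.3, 0.2), tolerance = 1e-9)
  # idempotence on identical members
  ens1 <- structure(list(heads = list(mk_const(c(0.6, 0.2, 0.2)))),
                    class = "ensemble")
  expect_equal(unname(ensemble_predict(ens1, c(0, 0))), c(0.6, 0.2, 0.2),
               tolerance = 1e-9)
})

test_that("ensemble of top-3 candidates is at least as good as near-best single", {
  tr <- gaussian_clusters(60, seed = 46)
  va <- gaussian_clusters(30, seed = 47)
  ens <- train_ensemble(tr$x, tr$y, va$x, va$y, n_candidates = 20, k = 3,
                        base_seed = 9,
                        cfg = training_config(max_epochs = 15, patience = 3))
  losses <- attr(ens, "candidate_losses")
  P <- ensemble_predict(ens, va$x)
  Y <- outer(va$y, phases, `==`) * 1
  ens_loss <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
  expect_lte(ens_loss, min(losses) + 0.05)
})

test_that("ensembles survive a save/load round trip bit-compatibly", {
  tr <- gaussian_clusters(20, seed = 48)
  ens <- train_ensemble(tr$x, tr$y, tr$x, tr$y, n_candidates = 3, k = 2,
                        base_seed = 1,
                        cfg = training_config(max_epochs = 3, patience = 1))
  path <- withr::local_tempfile(fileext = ".json")
  save_ensemble(ens, path, backend_id = "surrogate")
  back <- load_ensemble(path)
  expect_equal(back$heads[[1]]$W1, ens$heads[[1]]$W1, tolerance = 1e-12)
  expect_equal(back$val_losses, ens$val_losses, tolerance = 1e-12)
  X <- gaussian_clusters(5, seed = 49)$x
  expect_equal(ensemble_predict(back, X), ensemble_predict(ens, X),
               tolerance = 1e-12)
  expect_error(load_ensemble(withr::local_tempfile(fileext = ".json",
                                                   lines = "{}")),
               "not a breathphase weight file")
})
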