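# Tiny-scale trainer checks; architectures and epoch counts are scaled
# to keep each block in the sub-minute range.

tt_tcn_spec <- function(w) encoder_spec(c(w$W, w$n_channels),
                                        embedding_dim = 4,
                                        n_tcn_blocks = 2,
                                        channels_per_block = c(4, 6),
                                        kernel_size = 3, pool_every = 2)

tt_ae_spec <- function(d) encoder_spec(d, embedding_dim = 3,
                                       hidden_dims = c(10, 6))

test_that("pair sampling meets its quota with correct labels", {
  w <- tiny_windows()
  cs <- sample_pairs(w, 100, positive_fraction = 0.5, seed = 3)
  expect_length(cs$ia, 100)
  expect_equal(sum(cs$y_act), 50)
  expect_true(all(cs$ia != cs$ib))
  # oracle re-check: labels recomputed from ground truth
  cs2 <- sample_pairs(w, 1000, seed = 11)
  expect_equal(cs2$y_act,
               as.integer(w$activity[cs2$ia] == w$activity[cs2$ib]))
})

test_that("single-class data cannot produce dissimilar pairs", {
  lab <- rep(0L, 10)
  expect_error(sample_pairs(lab, 10, positive_fraction = 0.5), "single")
  cs <- sample_pairs(lab, 10, positive_fraction = 1.0, seed = 1)
  expect_equal(sum(cs$y_act), 10)
})

test_that("quadruple sampling fills all four label cells", {
  w <- tiny_windows()
  cs <- sample_quadruples(w, 80, seed = 5)
  cells <- table(factor(cs$y_act, 0:1), factor(cs$y_pers, 0:1))
  expect_true(all(cells == 20))
  expect_equal(cs$y_act,
               as.integer(w$activity[cs$ia] == w$activity[cs$ib]))
  expect_equal(cs$y_pers,
               as.integer(w$person[cs$ia] == w$person[cs$ib]))
  one_person <- list(activity = rep(0:1, 10), person = rep(0L, 20))
  expect_error(sample_quadruples(one_person, 10), "single person")
})

test_that("label budgets are stratified with at least one per class", {
  lab <- rep(0:2, each = 200)
  expect_equal(subsample_label_budget(lab, 1.0), seq_along(lab))
  idx <- subsample_label_budget(lab, 0.1, seed = 2)
  expect_length(idx, 60)
  expect_equal(as.vector(table(lab[idx])), rep(20L, 3))
  tiny <- subsample_label_budget(lab, 0.001, seed = 2)
  expect_equal(as.vector(table(lab[tiny])), rep(1L, 3))
})

test_that("every trainer's loss decreases on synthetic data", {
  w <- tiny_windows()
  fs <- extract_features(w)
  nb <- build_neighborhoods(fs, k = 3)
  drop_hist <- function(m) {
    h <- subset(m$history, term == "total" & stage == max(m$history$stage))
    expect_lt(utils::tail(h$value, 1), h$value[1])
  }
  cfgf <- function(p, ...) training_config(paradigm = p, epochs_stage1 = 8,
                                           epochs_stage2 = 8,
                                           batch_size = 32,
                                           learning_rate = 3e-3, seed = 1,
                                           ...)
  drop_hist(train_autoencoder(fs, cfgf("unsupervised"), tt_ae_spec(ncol(fs$X))))
  drop_hist(train_selfsup(fs, nb, cfgf("selfsup"), tt_ae_spec(ncol(fs$X))))
  drop_hist(train_supervised(w, cfgf("supervised"), tt_tcn_spec(w)))
  cs <- sample_pairs(w, 60, seed = 2)
  drop_hist(train_weak_single(w, cs, cfgf("weak_single"), tt_tcn_spec(w)))
  qs <- sample_quadruples(w, 60, seed = 2)
  drop_hist(train_weak_multi(w, qs, cfgf("weak_multi",
                                         weights = loss_weights(0.5, 0.5)),
                             tt_tcn_spec(w)))
  drop_hist(train_weak_selfsup(fs, nb, NULL,
                               cfgf("weak_selfsup", label_fraction = 0.5,
                                    pairs_per_epoch = 60),
                               tt_ae_spec(ncol(fs$X))))
})

test_that("trainers are exactly reproducible under a fixed seed", {
  w <- tiny_windows()
  fs <- extract_features(w)
  cfg <- training_config(paradigm = "unsupervised", epochs_stage1 = 5,
                         seed = 4)
  m1 <- train_autoencoder(fs, cfg, tt_ae_spec(ncol(fs$X)))
  m2 <- train_autoencoder(fs, cfg, tt_ae_spec(ncol(fs$X)))
  expect_identical(m1$history, m2$history)
  expect_equal(harspectrum:::bundle_params(m1),
               harspectrum:::bundle_params(m2), tolerance = 1e-12)
})

test_that("each trainer can drive its loss to near zero on one batch", {
  # a consensus dataset: identical rows, similar pairs only, so every
  # objective has zero as its attainable optimum
  d <- 8
  X <- matrix(rep(stats::rnorm(d), each = 12), 12, d)
  fs <- structure(list(X = X + 1e-3 * matrix(stats::rnorm(12 * d), 12),
                       activity = rep(0L, 12), person = rep(0L, 12),
                       t = 0:11), class = "feature_set")
  nb <- build_neighborhoods(fs, k = 3)
  steps <- function(n) training_config(paradigm = "unsupervised",
                                       epochs_stage1 = n, batch_size = 12,
                                       learning_rate = 3e-3, seed = 1)
  ratio <- function(m) {
    h <- subset(m$history, term == "total" & stage == 1)
    utils::tail(h$value, 1) / h$value[1]
  }
  m <- train_autoencoder(fs, steps(300), tt_ae_spec(d))
  expect_lt(ratio(m), 0.1)
  m <- train_selfsup(fs, nb, steps(300), tt_ae_spec(d))
  expect_lt(ratio(m), 0.1)
})

test_that("the TCN trainers overfit a single repeated batch", {
  cfg0 <- tiny_synth(noise_sigma = 0.4)
  w <- tiny_windows(cfg0)
  # a small fixed subset containing both classes
  keep <- unlist(lapply(split(seq_len(n_windows(w)), w$activity),
                        utils::head, 4))
  w$values <- w$values[keep, , , drop = FALSE]
  w$activity <- w$activity[keep]; w$person <- w$person[keep]
  w$t <- w$t[keep]
  cfg <- training_config(paradigm = "supervised", epochs_stage1 = 120,
                         batch_size = 64, learning_rate = 3e-3, seed = 1)
  m <- train_supervised(w, cfg, tt_tcn_spec(w))
  h <- subset(m$history, term == "total")
  expect_lt(utils::tail(h$value, 1), 0.1 * h$value[1])
  cs <- sample_pairs(w, 32, seed = 1)
  cfg2 <- training_config(paradigm = "weak_single", epochs_stage1 = 120,
                          batch_size = 32, learning_rate = 3e-3, seed = 1)
  m2 <- train_weak_single(w, cs, cfg2, tt_tcn_spec(w))
  h2 <- subset(m2$history, term == "total")
  expect_lt(utils::tail(h2$value, 1), 0.1 * h2$value[1])
})

test_that("multi-task training with beta = 0 reproduces single-task", {
  w <- tiny_windows()
  cs <- sample_pairs(w, 40, seed = 6)
  quad <- structure(list(ia = cs$ia, ib = cs$ib, y_act = cs$y_act,
                         y_pers = as.integer(w$person[cs$ia] ==
                                               w$person[cs$ib]),
                         provenance = "all"),
                    class = "constraint_set")
  cfg1 <- training_config(paradigm = "weak_single", epochs_stage1 = 4,
                          seed = 9, weights = loss_weights(margin_delta = 1))
  cfg2 <- training_config(paradigm = "weak_multi", epochs_stage1 = 4,
                          seed = 9,
                          weights = loss_weights(alpha = 1, beta = 0))
  m1 <- train_weak_single(w, cs, cfg1, tt_tcn_spec(w))
  m2 <- train_weak_multi(w, quad, cfg2, tt_tcn_spec(w))
  h1 <- subset(m1$history, term == "simi_act")$value
  h2 <- subset(m2$history, term == "simi_act")$value
  expect_equal(h1, h2, tolerance = 1e-10)
  p1 <- harspectrum:::nn_collect(m1$trunk, "params")
  p2 <- harspectrum:::nn_collect(m2$trunk, "params")
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("stage-2 constraints stay inside the label budget", {
  w <- tiny_windows()
  fs <- extract_features(w)
  nb <- build_neighborhoods(fs, k = 3)
  cfg <- training_config(paradigm = "weak_selfsup", epochs_stage1 = 3,
                         epochs_stage2 = 3, label_fraction = 0.2,
                         pairs_per_epoch = 40, seed = 2)
  m <- train_weak_selfsup(fs, nb, NULL, cfg, tt_ae_spec(ncol(fs$X)))
  budget <- subsample_label_budget(fs, 0.2, seed = 2)
  expect_equal(m$constraints$provenance, "budget")
  expect_true(all(c(m$constraints$ia, m$constraints$ib) %in% budget))
  expect_setequal(unique(m$history$stage), c(1L, 2L))
})

test_that("loss-term decompositions re-sum to the logged totals", {
  w <- tiny_windows()
  fs <- extract_features(w)
  nb <- build_neighborhoods(fs, k = 3)
  cfg <- training_config(paradigm = "selfsup", epochs_stage1 = 4, seed = 3)
  m <- train_selfsup(fs, nb, cfg, tt_ae_spec(ncol(fs$X)))
  h <- m$history
  for (ep in unique(h$epoch)) {
    parts <- h$value[h$epoch == ep & h$term %in% c("ae", "tc", "fc")]
    total <- h$value[h$epoch == ep & h$term == "total"]
    expect_equal(sum(parts), total, tolerance = 1e-8)
  }
})

test_that("YAML training configs round-trip through the reader", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("paradigm: selfsup", "epochs_stage1: 7",
               "learning_rate: 0.002", "weights:", "  alpha: 0.2",
               "  beta: 0.1", "seed: 12"), path)
  cfg <- read_training_config(path)
  expect_equal(cfg$paradigm, "selfsup")
  expect_equal(cfg$epochs_stage1, 7L)
  expect_equal(cfg$weights$alpha, 0.2)
})
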