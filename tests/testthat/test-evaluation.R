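test_that("embedding a dataset is deterministic with matched rows", {
  w <- tiny_windows()
  fs <- extract_features(w)
  cfg <- training_config(paradigm = "unsupervised", epochs_stage1 = 3,
                         seed = 1)
  m <- train_autoencoder(fs, cfg,
                         encoder_spec(ncol(fs$X), embedding_dim = 3,
                                      hidden_dims = c(10, 6)))
  r1 <- embed_dataset(m, fs)
  r2 <- embed_dataset(m, fs)
  expect_identical(r1$embeddings, r2$embeddings)
  expect_equal(nrow(r1$embeddings), nrow(fs$X))
  expect_equal(r1$activity, fs$activity)
})

test_that("k-means separates two distant blobs and handles k = 1", {
  set.seed(2)
  X <- rbind(matrix(stats::rnorm(40, 0, 0.1), 20),
             matrix(stats::rnorm(40, 10, 0.1), 20))
  cl <- kmeans_cluster(X, k = 2, seed = 1)
  truth <- rep(0:1, each = 20)
  expect_equal(cluster_accuracy(cl$assignments, truth)$accuracy, 1.0)
  # k = 1: inertia equals total scatter about the grand mean
  cl1 <- kmeans_cluster(X, k = 1, seed = 1)
  expect_equal(cl1$inertia,
               sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-8)
  expect_error(kmeans_cluster(X[1:3, ], k = 5, seed = 1), "exceeds")
})

test_that("best-of-restarts inertia never increases with k", {
  set.seed(3)
  X <- matrix(stats::rnorm(40), 20, 2)
  inertias <- vapply(1:5, function(k)
    kmeans_cluster(X, k = k, n_init = 20, seed = 7)$inertia, 0)
  expect_true(all(diff(inertias) <= 1e-8))
})

test_that("cluster accuracy is invariant to relabeling", {
  truth <- rep(0:2, each = 10)
  perm <- c(5L, 9L, 2L)
  assignments <- perm[truth + 1]
  r <- cluster_accuracy(assignments, truth)
  expect_equal(r$accuracy, 1.0)
  expect_equal(r$macro_f1, 1.0)
})

test_that("the contingency [[5,0],[1,4]] example maps to accuracy 0.9", {
  truth <- c(rep(0, 6), rep(1, 4))
  assignments <- c(rep(1, 5), 2, rep(2, 4))
  r <- cluster_accuracy(assignments, truth)
  expect_equal(unname(r$contingency["1", ]), c(5L, 0L))
  expect_equal(r$accuracy, 0.9)
})

test_that("random balanced assignments score near chance", {
  set.seed(4)
  truth <- rep(0:2, each = 2000)
  assignments <- sample(0:2, 6000, replace = TRUE)
  r <- cluster_accuracy(assignments, truth)
  expect_lt(abs(r$accuracy - 1 / 3), 0.02)
})

test_that("Hungarian mapping equals brute force over random tables", {
  set.seed(5)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    M <- sample(2:6, 1)
    n <- sample(20:60, 1)
    assignments <- sample(seq_len(k), n, replace = TRUE)
    truth <- sample(seq_len(M), n, replace = TRUE)
    got <- cluster_accuracy(assignments, truth)$accuracy
    want <- brute_best_accuracy(assignments, truth)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Hungarian accuracy is at least any greedy mapping's", {
  set.seed(6)
  for (rep in 1:25) {
    assignments <- sample(1:4, 50, replace = TRUE)
    truth <- sample(1:4, 50, replace = TRUE)
    r <- cluster_accuracy(assignments, truth)
    cont <- r$contingency
    # greedy: repeatedly take the largest remaining cell
    cont2 <- cont
    matched <- 0
    while (any(cont2 >= 0) && nrow(cont2) > 0 && ncol(cont2) > 0) {
      m <- which(cont2 == max(cont2), arr.ind = TRUE)[1, ]
      matched <- matched + cont2[m[1], m[2]]
      cont2 <- cont2[-m[1], -m[2], drop = FALSE]
      if (nrow(cont2) == 0 || ncol(cont2) == 0) break
    }
    expect_gte(r$accuracy + 1e-12, matched / 50)
  }
})

test_that("macro-F1 matches a hand-tabulated confusion matrix", {
  truth <- c(rep(0, 4), rep(1, 4), rep(2, 4))
  pred <- c(0, 0, 1, 2,  1, 1, 1, 0,  2, 2, 0, 2)
  # class 0: tp 2, fp 2, fn 2 -> f1 = 1/2
  # class 1: tp 3, fp 1, fn 1 -> f1 = 3/4
  # class 2: tp 3, fp 1, fn 1 -> f1 = 3/4
  expect_equal(harspectrum:::macro_f1(truth, pred), mean(c(0.5, 0.75, 0.75)))
  # constant predictor on balanced three classes
  pred_c <- rep(0, 12)
  expect_equal(mean(pred_c == truth), 1 / 3)
  expect_equal(harspectrum:::macro_f1(truth, pred_c), 0.5 / 3)
})

test_that("the supervised report scores a trained classifier sensibly", {
  w <- tiny_windows(tiny_synth(noise_sigma = 0.1))
  cfg <- training_config(paradigm = "supervised", epochs_stage1 = 40,
                         learning_rate = 3e-3, seed = 1)
  spec <- encoder_spec(c(w$W, w$n_channels), embedding_dim = 4,
                       n_tcn_blocks = 2, channels_per_block = c(4, 6),
                       kernel_size = 3, pool_every = 2)
  m <- train_supervised(w, cfg, spec)
  r <- classification_report(m, w)
  expect_gte(r$accuracy, 0.9)
  expect_equal(sum(r$confusion), n_windows(w))
  expect_true(r$macro_f1 >= 0 && r$macro_f1 <= 1)
})

test_that("the experiment harness returns the full grid deterministically", {
  synth <- tiny_synth()
  res <- run_experiment(paradigms = "unsupervised", synth = synth,
                        seeds = 1:2, window_seconds = 1,
                        step_seconds = 0.5, epochs_features = 2)
  expect_equal(nrow(res), 2)
  expect_named(res, c("paradigm", "fraction", "seed", "acc", "f1"))
  res2 <- run_experiment(paradigms = "unsupervised", synth = synth,
                         seeds = 1:2, window_seconds = 1,
                         step_seconds = 0.5, epochs_features = 2)
  expect_identical(res, res2)
})

test_that("the ablation grid emits four variants per seed", {
  res <- run_ablation(synth = tiny_synth(), seeds = 1L,
                      window_seconds = 1, step_seconds = 0.5, epochs = 2)
  expect_equal(nrow(res), 4)
  expect_setequal(res$variant, c("ae", "tc_ae", "fc_ae", "tc_fc_ae"))
})

test_that("embeddings export to the documented CSV layout", {
  reps <- structure(list(embeddings = matrix(1:6, 2, 3),
                         activity = c(0L, 1L), person = c(0L, 0L),
                         paradigm = "test"),
                    class = "representation_set")
  path <- tempfile(fileext = ".csv")
  write_embeddings_csv(reps, path)
  df <- utils::read.csv(path)
  expect_named(df, c("id", "act", "pers", "e0", "e1", "e2"))
  expect_equal(df$e0, c(1, 2))
})
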