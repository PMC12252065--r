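#' Embed a dataset with a trained model
#'
#' Runs a deterministic evaluation-mode forward pass (batch norm uses
#' its running statistics) through the model's encoding path: the
#' encoder for autoencoder bundles, the shared trunk plus activity head
#' for Siamese bundles.  Inputs are standardized with the scaler stored
#' at training time.
#'
#' @param model a trained `model_bundle`
#' @param data a `feature_set` (autoencoder family) or `sensor_windows`
#'   (TCN family)
#' @param person_head use the person head of a multi-task Siamese model
#' @return a `representation_set`: `embeddings` (N x H), `activity`,
#'   `person`, `paradigm`
#' @export
embed_dataset <- function(model, data, person_head = FALSE) {
  stopifnot(inherits(model, "model_bundle"))
  if (inherits(data, "feature_set")) {
    X <- standardize_cols(data$X, model$scaler$center, model$scaler$scale)$X
    r <- bundle_encode(model, X, training = FALSE)
  } else if (inherits(data, "sensor_windows")) {
    X <- standardize_windows(data$values, model$scaler$center,
                             model$scaler$scale)$values
    r <- bundle_encode(model, X, training = FALSE,
                       person_head = person_head)
  } else stop("data must be a feature_set or sensor_windows")
  structure(list(embeddings = r$emb, activity = data$activity,
                 person = data$person,
                 paradigm = model$paradigm %||% model$kind),
            class = "representation_set")
}

#' @export
print.representation_set <- function(x, ...) {
  cat(sprintf("representation_set (%s): %d samples x %d dims\n",
              x$paradigm, nrow(x$embeddings), ncol(x$embeddings)))
  invisible(x)
}

#' Cluster representations with k-means
#'
#' Best-inertia solution over `n_init` restarts of Lloyd's algorithm.
#' `k` defaults to the number of distinct activity labels carried by the
#' representation set.
#'
#' @param reps a `representation_set` (or a plain embedding matrix)
#' @param k number of clusters; must not exceed the sample count
#' @param n_init random restarts (default 10)
#' @param seed RNG seed for the restarts
#' @return list with `assignments` (1-based cluster ids), `k`, `inertia`
#' @export
kmeans_cluster <- function(reps, k = NULL, n_init = 10, seed = 1L) {
  emb <- if (inherits(reps, "representation_set")) reps$embeddings else
    as.matrix(reps)
  if (is.null(k)) {
    if (!inherits(reps, "representation_set"))
      stop("k must be given for a bare embedding matrix")
    k <- length(unique(reps$activity))
  }
  if (k > nrow(emb)) stop("k = ", k, " exceeds the number of samples")
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(emb, centers = k, nstart = n_init, iter.max = 100))
  list(assignments = as.integer(km$cluster), k = as.integer(k),
       inertia = km$tot.withinss)
}

# Minimal-cost assignment (Hungarian algorithm with potentials),
# rows <= columns; returns the column assigned to each row.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]; p[j0 + 1] <- p[j1 + 1]; j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Clustering accuracy via optimal cluster-to-class mapping
#'
#' Builds the k x M contingency matrix of cluster assignments against
#' true labels, finds the injective cluster-to-class mapping that
#' maximizes the matched count (Hungarian assignment), and reports the
#' matched fraction as accuracy plus the macro-F1 of the mapped
#' predictions.  When `k > M`, clusters left unmapped count all their
#' samples as errors; when `k < M`, unmatched classes score zero recall.
#'
#' @param assignments cluster ids (any labeling)
#' @param true_labels ground-truth class labels (any labeling)
#' @return a `clustering_result`: `assignments`, `k`, `mapping` (named
#'   vector cluster -> class, NA for unmapped clusters), `accuracy`,
#'   `macro_f1`, `contingency`
#' @export
cluster_accuracy <- function(assignments, true_labels) {
  stopifnot(length(assignments) == length(true_labels))
  clusters <- sort(unique(assignments))
  classes <- sort(unique(true_labels))
  k <- length(clusters); M <- length(classes)
  cont <- table(factor(assignments, levels = clusters),
                factor(true_labels, levels = classes))
  cont <- matrix(as.integer(cont), k, M,
                 dimnames = list(as.character(clusters),
                                 as.character(classes)))
  big <- max(cont) + 1
  if (k <= M) {
    asg <- hungarian(big - cont)          # cluster -> class
    mapping <- classes[asg]
  } else {
    asg <- hungarian(t(big - cont))       # class -> cluster
    mapping <- rep(NA, k)
    mapping[asg] <- classes
  }
  names(mapping) <- as.character(clusters)
  pred <- mapping[match(assignments, clusters)]
  matched <- sum(pred == true_labels, na.rm = TRUE)
  acc <- matched / length(true_labels)
  structure(list(assignments = assignments, k = k, mapping = mapping,
                 accuracy = acc,
                 macro_f1 = macro_f1(true_labels, pred, classes),
                 contingency = cont),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: k = %d, accuracy %.4f, macro-F1 %.4f\n",
              x$k, x$accuracy, x$macro_f1))
  invisible(x)
}

# Macro (unweighted) F1 over the true classes; NA predictions are pure
# errors (they add false negatives but no false positives).
macro_f1 <- function(truth, pred, classes = sort(unique(truth))) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl, na.rm = TRUE)
    fp <- sum(pred == cl & truth != cl, na.rm = TRUE)
    fn <- sum(truth == cl & (is.na(pred) | pred != cl))
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Supervised classification report
#'
#' Evaluation-mode predictions of a trained TCN classifier, with
#' accuracy, macro-F1 and the confusion matrix.
#'
#' @param model a `model_bundle` from [train_supervised()]
#' @param windows a labeled `sensor_windows`
#' @return list with `accuracy`, `macro_f1`, `confusion`, `predicted`
#' @export
classification_report <- function(model, windows) {
  stopifnot(model$kind == "tcn_classifier")
  X <- standardize_windows(windows$values, model$scaler$center,
                           model$scaler$scale)$values
  fe <- nn_forward(model$encoder, X, training = FALSE)
  fc <- nn_forward(model$classifier, fe$out, training = FALSE)
  pred_idx <- max.col(softmax_rows(fc$out), ties.method = "first")
  pred <- model$classes[pred_idx]
  truth <- windows$activity
  classes <- model$classes
  conf <- table(factor(truth, levels = classes),
                factor(pred, levels = classes))
  list(accuracy = mean(pred == truth),
       macro_f1 = macro_f1(truth, pred, classes),
       confusion = conf, predicted = pred)
}

## ---- experiment harness -------------------------------------------------

# build windows + features + neighborhoods for one synthetic replicate
build_synth_dataset <- function(synth, seed, window_seconds = 2,
                                step_seconds = 1) {
  cfg <- synth
  cfg$seed <- as.integer(seed)
  streams <- generate_streams(cfg)
  windows <- bind_windows(lapply(streams, segment_windows,
                                 window_seconds = window_seconds,
                                 step_seconds = step_seconds))
  features <- extract_features(windows)
  list(windows = windows, features = features,
       neighborhoods = build_neighborhoods(features),
       n_activities = cfg$n_activities)
}

# compact encoder specs used at synthetic scale
synth_tcn_spec <- function(W, C, embedding_dim = 16)
  encoder_spec(c(W, C), embedding_dim = embedding_dim, n_tcn_blocks = 2,
               channels_per_block = c(16, 32), kernel_size = 5,
               pool_every = 2)

synth_feature_spec <- function(d_in)
  encoder_spec(d_in, embedding_dim = 8, hidden_dims = c(32, 16))

#' Run a paradigm-comparison experiment on synthetic data
#'
#' For each seed, generates a fresh synthetic dataset, trains the
#' requested paradigms, embeds the training windows, clusters with
#' k-means (k = number of activities), and scores mapped accuracy and
#' macro-F1.  The weakly self-supervised paradigm is expanded over
#' `label_fractions`; the supervised paradigm reports classification
#' accuracy instead of clustering accuracy.
#'
#' @param paradigms subset of `"unsupervised"`, `"selfsup"`,
#'   `"weak_single"`, `"weak_multi"`, `"weak_selfsup"`, `"supervised"`
#' @param label_fractions label budgets for `"weak_selfsup"`
#' @param synth a [synth_config()] describing the data conditions
#' @param seeds integer vector of replicate seeds
#' @param window_seconds,step_seconds segmentation parameters
#' @param epochs_features epochs for the feature-space trainers
#' @param epochs_tcn epochs for the Siamese/supervised TCN trainers
#' @param learning_rate optimizer step size for all trainers
#' @param consistency_weight weight given to each consistency term of
#'   the self-supervised objective at this scale
#' @param margin contrastive margin for the Siamese TCN trainers
#' @param pairs_per_epoch constraint pairs for the Siamese trainers
#'   (default 2x the window count at this scale)
#' @param verbose print one line per cell
#' @return data.frame with columns `paradigm`, `fraction`, `seed`,
#'   `acc`, `f1`
#' @export
run_experiment <- function(paradigms = c("unsupervised", "selfsup",
                                         "weak_single"),
                           label_fractions = c(0.01, 0.05, 0.10),
                           synth = synth_config(), seeds = 1:3,
                           window_seconds = 2, step_seconds = 1,
                           epochs_features = 300, epochs_tcn = 15,
                           learning_rate = 3e-3,
                           consistency_weight = 0.3, margin = 2,
                           pairs_per_epoch = NULL, verbose = FALSE) {
  rows <- list()
  add <- function(paradigm, fraction, seed, acc, f1) {
    rows[[length(rows) + 1]] <<- data.frame(
      paradigm = paradigm, fraction = fraction, seed = seed,
      acc = acc, f1 = f1)
    if (verbose)
      message(sprintf("%-14s frac=%-5s seed=%d  acc=%.3f f1=%.3f",
                      paradigm, format(fraction), seed, acc, f1))
  }
  for (seed in seeds) {
    ds <- build_synth_dataset(synth, seed, window_seconds, step_seconds)
    M <- ds$n_activities
    np <- pairs_per_epoch %||% (2L * n_windows(ds$windows))
    fcfg <- function(...) training_config(batch_size = 64,
                                          epochs_stage1 = epochs_features,
                                          learning_rate = learning_rate,
                                          seed = seed, ...)
    score <- function(model, data) {
      reps <- embed_dataset(model, data)
      cl <- kmeans_cluster(reps, k = M, seed = seed)
      cluster_accuracy(cl$assignments, reps$activity)
    }
    for (p in paradigms) {
      if (p == "unsupervised") {
        m <- train_autoencoder(ds$features, fcfg(paradigm = "unsupervised"),
                               synth_feature_spec(ncol(ds$features$X)))
        r <- score(m, ds$features)
        add(p, NA_real_, seed, r$accuracy, r$macro_f1)
      } else if (p == "selfsup") {
        m <- train_selfsup(ds$features, ds$neighborhoods,
                           fcfg(paradigm = "selfsup",
                                weights = loss_weights(
                                  alpha = consistency_weight,
                                  beta = consistency_weight)),
                           synth_feature_spec(ncol(ds$features$X)))
        r <- score(m, ds$features)
        add(p, NA_real_, seed, r$accuracy, r$macro_f1)
      } else if (p == "weak_single") {
        cfg <- training_config(paradigm = "weak_single",
                               epochs_stage1 = epochs_tcn,
                               learning_rate = learning_rate,
                               pairs_per_epoch = np, seed = seed,
                               weights = loss_weights(margin_delta = margin))
        m <- train_weak_single(ds$windows, NULL, cfg,
                               synth_tcn_spec(ds$windows$W,
                                              ds$windows$n_channels))
        r <- score(m, ds$windows)
        add(p, NA_real_, seed, r$accuracy, r$macro_f1)
      } else if (p == "weak_multi") {
        cfg <- training_config(paradigm = "weak_multi",
                               epochs_stage1 = epochs_tcn,
                               learning_rate = learning_rate,
                               pairs_per_epoch = np, seed = seed,
                               weights = loss_weights(alpha = 0.5,
                                                      beta = 0.5,
                                                      margin_delta = margin))
        m <- train_weak_multi(ds$windows, NULL, cfg,
                              synth_tcn_spec(ds$windows$W,
                                             ds$windows$n_channels))
        r <- score(m, ds$windows)
        add(p, NA_real_, seed, r$accuracy, r$macro_f1)
      } else if (p == "weak_selfsup") {
        for (frac in label_fractions) {
          cfg <- fcfg(paradigm = "weak_selfsup", label_fraction = frac,
                      epochs_stage2 = 150,
                      pairs_per_epoch = min(600L, np),
                      weights = loss_weights(
                        alpha = consistency_weight,
                        beta = consistency_weight))
          m <- train_weak_selfsup(ds$features, ds$neighborhoods, NULL,
                                  cfg,
                                  synth_feature_spec(ncol(ds$features$X)))
          r <- score(m, ds$features)
          add(p, frac, seed, r$accuracy, r$macro_f1)
        }
      } else if (p == "supervised") {
        cfg <- training_config(paradigm = "supervised",
                               epochs_stage1 = epochs_tcn,
                               learning_rate = learning_rate, seed = seed)
        m <- train_supervised(ds$windows, cfg,
                              synth_tcn_spec(ds$windows$W,
                                             ds$windows$n_channels))
        r <- classification_report(m, ds$windows)
        add(p, NA_real_, seed, r$accuracy, r$macro_f1)
      } else stop("unknown paradigm: ", p)
    }
  }
  do.call(rbind, rows)
}

#' Ablation of the self-supervised loss components
#'
#' Trains the consistency autoencoder under the four loss configurations
#' `ae`, `tc+ae`, `fc+ae` and `tc+fc+ae` on the same synthetic data and
#' scores each by mapped clustering accuracy.
#'
#' @param synth a [synth_config()]
#' @param seeds replicate seeds
#' @param alpha,beta consistency weights used when a term is active
#' @param window_seconds,step_seconds segmentation parameters
#' @param epochs training epochs per variant
#' @param learning_rate optimizer step size
#' @param verbose print one line per cell
#' @return data.frame with columns `variant`, `seed`, `acc`, `f1`
#' @export
run_ablation <- function(synth = synth_config(), seeds = 1:3,
                         alpha = 0.3, beta = 0.3,
                         window_seconds = 2, step_seconds = 1,
                         epochs = 300, learning_rate = 3e-3,
                         verbose = FALSE) {
  variants <- list(ae = c(0, 0), tc_ae = c(alpha, 0),
                   fc_ae = c(0, beta), tc_fc_ae = c(alpha, beta))
  rows <- list()
  for (seed in seeds) {
    ds <- build_synth_dataset(synth, seed, window_seconds, step_seconds)
    for (v in names(variants)) {
      w <- variants[[v]]
      cfg <- training_config(paradigm = "selfsup",
                             epochs_stage1 = epochs, seed = seed,
                             learning_rate = learning_rate,
                             weights = loss_weights(alpha = w[1],
                                                    beta = w[2]))
      m <- train_selfsup(ds$features, ds$neighborhoods, cfg,
                         synth_feature_spec(ncol(ds$features$X)))
      reps <- embed_dataset(m, ds$features)
      cl <- kmeans_cluster(reps, k = ds$n_activities, seed = seed)
      r <- cluster_accuracy(cl$assignments, reps$activity)
      rows[[length(rows) + 1]] <- data.frame(variant = v, seed = seed,
                                             acc = r$accuracy,
                                             f1 = r$macro_f1)
      if (verbose)
        message(sprintf("%-9s seed=%d  acc=%.3f", v, seed, r$accuracy))
    }
  }
  do.call(rbind, rows)
}

#' Export a representation set to CSV
#'
#' Layout: `id,act,pers,e0..e{H-1}`.
#' @param reps a `representation_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_embeddings_csv <- function(reps, path) {
  df <- data.frame(id = seq_len(nrow(reps$embeddings)) - 1L,
                   act = reps$activity, pers = reps$person)
  for (j in seq_len(ncol(reps$embeddings)))
    df[[paste0("e", j - 1)]] <- reps$embeddings[, j]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Quick 2-D scatter of embeddings (visual aid only)
#'
#' Projects the embeddings onto their first two principal components and
#' colors points by activity.
#' @param reps a `representation_set`
#' @param ... passed to [graphics::plot()]
#' @return the projected coordinates, invisibly
#' @export
plot_embeddings <- function(reps, ...) {
  pc <- stats::prcomp(reps$embeddings, rank. = 2)
  xy <- pc$x
  graphics::plot(xy, col = as.integer(factor(reps$activity)), pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = paste("embeddings:", reps$paradigm), ...)
  invisible(xy)
}
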