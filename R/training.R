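#' Training configuration
#'
#' @param paradigm one of `"supervised"`, `"unsupervised"`,
#'   `"weak_single"`, `"weak_multi"`, `"selfsup"`, `"weak_selfsup"`
#' @param epochs_stage1 epochs for the (only, or first) training stage
#' @param epochs_stage2 epochs for the constraint fine-tuning stage of
#'   the weakly self-supervised paradigm
#' @param batch_size minibatch size (samples, or pairs for Siamese
#'   trainers)
#' @param learning_rate optimizer step size
#' @param optimizer `"adam"` (default) or `"sgd"`
#' @param label_fraction fraction of ground-truth labels the constraint
#'   budget may consume, in `(0, 1]`
#' @param pairs_per_epoch number of constraint pairs; defaults to 4x the
#'   window count when a trainer samples its own constraints
#' @param weights a [loss_weights()]
#' @param seed integer seed; identical config + seed + data reproduce the
#'   final parameters exactly
#' @return a `training_config`
#' @export
training_config <- function(paradigm = c("supervised", "unsupervised",
                                         "weak_single", "weak_multi",
                                         "selfsup", "weak_selfsup"),
                            epochs_stage1 = 50, epochs_stage2 = 50,
                            batch_size = 64, learning_rate = 1e-3,
                            optimizer = c("adam", "sgd"),
                            label_fraction = 1.0, pairs_per_epoch = NULL,
                            weights = loss_weights(), seed = 1L) {
  paradigm <- match.arg(paradigm)
  optimizer <- match.arg(optimizer)
  stopifnot(epochs_stage1 >= 1, epochs_stage2 >= 1, batch_size >= 1,
            learning_rate > 0, label_fraction > 0, label_fraction <= 1)
  structure(list(paradigm = paradigm,
                 epochs_stage1 = as.integer(epochs_stage1),
                 epochs_stage2 = as.integer(epochs_stage2),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 label_fraction = label_fraction,
                 pairs_per_epoch = pairs_per_epoch,
                 weights = weights, seed = as.integer(seed)),
            class = "training_config")
}

#' Read a training configuration from a YAML file
#'
#' Keys mirror [training_config()] field names; `weights` may be a
#' nested map with `alpha`, `beta`, `gamma`, `margin_delta`.
#' @param path YAML file
#' @return a `training_config`
#' @export
read_training_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$weights)) y$weights <- do.call(loss_weights, y$weights)
  do.call(training_config, y)
}

## ---- constraint sampling ------------------------------------------------

labels_of <- function(x) {
  if (inherits(x, c("sensor_windows", "feature_set")))
    list(activity = x$activity, person = x$person)
  else if (is.list(x)) x
  else list(activity = as.integer(x), person = NULL)
}

#' Sample pairwise activity constraints
#'
#' Uniformly samples index pairs (with replacement across draws, never
#' pairing a window with itself) and keeps them until the positive /
#' negative quota is met.  `y_act` is 1 when both windows carry the same
#' activity label and 0 otherwise.
#'
#' @param windows a `sensor_windows` / `feature_set` (or a label vector)
#' @param n_pairs pairs to return
#' @param positive_fraction share of similar pairs (default 0.5)
#' @param seed RNG seed
#' @param among optional index subset the pairs must be drawn from
#'   (label-budget support); returned indices stay in the full space
#' @return a `constraint_set`: list with `ia`, `ib`, `y_act`,
#'   `provenance`
#' @export
sample_pairs <- function(windows, n_pairs, positive_fraction = 0.5,
                         seed = 1L, among = NULL) {
  lab <- labels_of(windows)$activity
  pool <- if (is.null(among)) seq_along(lab) else as.integer(among)
  if (length(pool) < 2) stop("need at least 2 windows to form pairs")
  n_pos <- round(positive_fraction * n_pairs)
  n_neg <- n_pairs - n_pos
  tab <- table(lab[pool])
  if (n_pos > 0 && !any(tab >= 2))
    stop("no activity class has two windows: cannot form similar pairs")
  if (n_neg > 0 && length(tab) < 2)
    stop("dataset has a single activity class: cannot form dissimilar pairs")
  set.seed(seed)
  ia <- ib <- integer(0); y <- integer(0)
  got_pos <- 0L; got_neg <- 0L
  while (got_pos < n_pos || got_neg < n_neg) {
    m <- 4L * (n_pairs - got_pos - got_neg) + 8L
    ca <- pool[sample.int(length(pool), m, replace = TRUE)]
    cb <- pool[sample.int(length(pool), m, replace = TRUE)]
    ok <- ca != cb
    ca <- ca[ok]; cb <- cb[ok]
    same <- lab[ca] == lab[cb]
    take_pos <- which(same)[seq_len(min(sum(same), n_pos - got_pos))]
    take_neg <- which(!same)[seq_len(min(sum(!same), n_neg - got_neg))]
    take <- c(take_pos, take_neg)
    ia <- c(ia, ca[take]); ib <- c(ib, cb[take])
    y <- c(y, as.integer(same[take]))
    got_pos <- got_pos + length(take_pos)
    got_neg <- got_neg + length(take_neg)
  }
  structure(list(ia = ia, ib = ib, y_act = y,
                 provenance = if (is.null(among)) "all" else "budget"),
            class = "constraint_set")
}

#' Sample quadruple constraints (activity + person labels)
#'
#' As [sample_pairs()], but each pair carries both an activity-match and
#' a person-match label, sampled to a quota over the four
#' `(y_act, y_pers)` cells (default: balanced quarters).
#'
#' @param windows a `sensor_windows` / `feature_set`
#' @param n_pairs pairs to return
#' @param quota length-4 fractions for cells `(1,1), (1,0), (0,1), (0,0)`
#' @param seed RNG seed
#' @param among optional index subset
#' @return a `constraint_set` with additional `y_pers`
#' @export
sample_quadruples <- function(windows, n_pairs,
                              quota = c(0.25, 0.25, 0.25, 0.25),
                              seed = 1L, among = NULL) {
  stopifnot(length(quota) == 4, abs(sum(quota) - 1) < 1e-9)
  lab <- labels_of(windows)
  act <- lab$activity; pers <- lab$person
  if (is.null(pers)) stop("windows carry no person labels")
  pool <- if (is.null(among)) seq_along(act) else as.integer(among)
  want <- round(quota * n_pairs)
  want[1] <- n_pairs - sum(want[-1])
  # feasibility per cell
  if ((want[3] > 0 || want[4] > 0) && length(unique(act[pool])) < 2)
    stop("single activity class: cells with y_act = 0 are infeasible")
  if ((want[2] > 0 || want[4] > 0) && length(unique(pers[pool])) < 2)
    stop("single person: cells with y_pers = 0 are infeasible")
  set.seed(seed)
  got <- integer(4)
  ia <- ib <- integer(0); ya <- yp <- integer(0)
  guard <- 0L
  while (any(got < want)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("could not satisfy the quadruple quota; ",
                             "check that every (y_act, y_pers) cell is feasible")
    m <- 8L * (n_pairs - sum(got)) + 16L
    ca <- pool[sample.int(length(pool), m, replace = TRUE)]
    cb <- pool[sample.int(length(pool), m, replace = TRUE)]
    ok <- ca != cb
    ca <- ca[ok]; cb <- cb[ok]
    sa <- as.integer(act[ca] == act[cb])
    sp <- as.integer(pers[ca] == pers[cb])
    cell <- 1L + (1L - sa) * 2L + (1L - sp)   # (1,1)=1 (1,0)=2 (0,1)=3 (0,0)=4
    for (cc in 1:4) {
      need <- want[cc] - got[cc]
      if (need <= 0) next
      take <- which(cell == cc)[seq_len(min(sum(cell == cc), need))]
      if (length(take) == 0) next
      ia <- c(ia, ca[take]); ib <- c(ib, cb[take])
      ya <- c(ya, sa[take]); yp <- c(yp, sp[take])
      got[cc] <- got[cc] + length(take)
    }
  }
  structure(list(ia = ia, ib = ib, y_act = ya, y_pers = yp,
                 provenance = if (is.null(among)) "all" else "budget"),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat(sprintf("constraint_set: %d pairs (%d similar), source: %s\n",
              length(x$ia), sum(x$y_act), x$provenance))
  invisible(x)
}

#' Stratified label-budget subsample
#'
#' Per activity class, keeps `ceil(fraction * n_class)` windows (at
#' least one), so every class is represented at any positive fraction.
#'
#' @param windows a `sensor_windows` / `feature_set` (or label vector)
#' @param fraction label fraction in `(0, 1]`
#' @param seed RNG seed
#' @return sorted integer vector of "labeled" window indices
#' @export
subsample_label_budget <- function(windows, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  lab <- labels_of(windows)$activity
  set.seed(seed)
  idx <- integer(0)
  for (cl in sort(unique(lab))) {
    rows <- which(lab == cl)
    take <- max(1L, ceiling(fraction * length(rows)))
    idx <- c(idx, sort(sample(rows, take)))
  }
  sort(idx)
}

## ---- shared trainer plumbing -------------------------------------------

# standardize an (N, W, C) window tensor per channel
standardize_windows <- function(vals, center = NULL, scale = NULL) {
  C <- dim(vals)[3]
  if (is.null(center)) {
    center <- vapply(seq_len(C), function(c) mean(vals[, , c]), 0)
    scale <- vapply(seq_len(C), function(c) stats::sd(as.vector(vals[, , c])), 0)
    scale[scale < 1e-12] <- 1
  }
  for (c in seq_len(C))
    vals[, , c] <- (vals[, , c] - center[c]) / scale[c]
  list(values = vals, center = center, scale = scale)
}

opt_new <- function(config) {
  if (config$optimizer == "adam") adam_new(lr = config$learning_rate)
  else list(lr = config$learning_rate, sgd = TRUE)
}

opt_step <- function(opt, params, grads) {
  if (isTRUE(opt$sgd)) sgd_step(opt, params, grads)
  else adam_step(opt, params, grads)
}

hist_row <- function(stage, epoch, term, value)
  data.frame(stage = stage, epoch = epoch, term = term, value = value)

#' Write a per-epoch loss history to CSV
#' @param history the `history` data.frame of a trained `model_bundle`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

epoch_batches <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

## ---- trainers -----------------------------------------------------------

default_feature_spec <- function(d_in) {
  encoder_spec(input_shape = d_in,
               embedding_dim = max(2L, min(16L, d_in - 1L)),
               hidden_dims = c(64, 32))
}

default_window_spec <- function(W, C) {
  encoder_spec(input_shape = c(W, C))
}

#' Train the unsupervised residual autoencoder
#'
#' Minimizes the mean squared reconstruction error of the (z-scored)
#' handcrafted features.  The encoder half is the representation used
#' for clustering.
#'
#' @param features a `feature_set`
#' @param config a [training_config()]
#' @param spec optional [encoder_spec()]; default: residual blocks
#'   `D -> 64 -> 32` and an embedding of `min(16, D - 1)`
#' @return a trained `model_bundle` with a `history` data.frame
#' @export
train_autoencoder <- function(features, config, spec = NULL) {
  X0 <- features$X
  spec <- spec %||% default_feature_spec(ncol(X0))
  set.seed(config$seed)
  bundle <- build_residual_autoencoder(spec)
  sc <- standardize_cols(X0)
  X <- sc$X
  bundle$scaler <- list(center = sc$center, scale = sc$scale)
  opt <- opt_new(config)
  hist <- list()
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs_stage1)) {
    tot <- 0; nb <- 0
    for (rows in epoch_batches(nrow(X), config$batch_size)) {
      xb <- X[rows, , drop = FALSE]
      fe <- nn_forward(bundle$encoder, xb, training = TRUE)
      bundle$encoder <- fe$net
      fd <- nn_forward(bundle$decoder, fe$out, training = TRUE)
      bundle$decoder <- fd$net
      l <- reconstruction_loss(xb, fd$out, reduction = "mean", grad = TRUE)
      bd <- nn_backward(bundle$decoder, l$grad)
      bundle$decoder <- bd$net
      be <- nn_backward(bundle$encoder, bd$dx)
      bundle$encoder <- be$net
      st <- opt_step(opt, bundle_params(bundle), bundle_grads(bundle))
      opt <- st$opt
      bundle <- bundle_set_params(bundle, st$params)
      tot <- tot + l$value; nb <- nb + 1
    }
    hist[[length(hist) + 1]] <- rbind(
      hist_row(1L, ep, "ae", tot / nb), hist_row(1L, ep, "total", tot / nb))
  }
  bundle$history <- do.call(rbind, hist)
  bundle$paradigm <- "unsupervised"
  bundle
}

#' Train the supervised TCN classifier
#'
#' Residual TCN encoder on raw (per-channel z-scored) windows with a
#' softmax head, minimizing cross-entropy against the activity labels.
#'
#' @param windows a `sensor_windows`
#' @param config a [training_config()]
#' @param spec optional [encoder_spec()]
#' @return a trained `model_bundle` (`encoder` + `classifier`) with
#'   `history` and `n_classes`
#' @export
train_supervised <- function(windows, config, spec = NULL) {
  spec <- spec %||% default_window_spec(windows$W, windows$n_channels)
  classes <- sort(unique(windows$activity))
  M <- length(classes)
  y <- match(windows$activity, classes) - 1L
  set.seed(config$seed)
  base <- build_tcn_encoder(spec)
  bundle <- new_model_bundle("tcn_classifier", spec,
                             encoder = base$encoder,
                             classifier = list(nn_dense(spec$embedding_dim, M)))
  sw <- standardize_windows(windows$values)
  X <- sw$values
  bundle$scaler <- list(center = sw$center, scale = sw$scale)
  bundle$n_classes <- M
  bundle$classes <- classes
  opt <- opt_new(config)
  hist <- list()
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs_stage1)) {
    tot <- 0; nb <- 0
    for (rows in epoch_batches(dim(X)[1], config$batch_size)) {
      xb <- X[rows, , , drop = FALSE]
      fe <- nn_forward(bundle$encoder, xb, training = TRUE)
      bundle$encoder <- fe$net
      fc <- nn_forward(bundle$classifier, fe$out, training = TRUE)
      bundle$classifier <- fc$net
      p <- softmax_rows(fc$out)
      l <- cross_entropy_loss(y[rows], p, grad = TRUE)
      bc <- nn_backward(bundle$classifier, l$grad_logits)
      bundle$classifier <- bc$net
      be <- nn_backward(bundle$encoder, bc$dx)
      bundle$encoder <- be$net
      st <- opt_step(opt, bundle_params(bundle), bundle_grads(bundle))
      opt <- st$opt
      bundle <- bundle_set_params(bundle, st$params)
      tot <- tot + l$value; nb <- nb + 1
    }
    hist[[length(hist) + 1]] <- rbind(
      hist_row(1L, ep, "ce", tot / nb), hist_row(1L, ep, "total", tot / nb))
  }
  bundle$history <- do.call(rbind, hist)
  bundle$paradigm <- "supervised"
  bundle
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# shared Siamese step: one epoch over constraint minibatches.
# Both branches of a pair go through the network as one concatenated
# batch, so batch-norm statistics mix the branches.
siamese_epoch <- function(bundle, X, cons, config, opt, multitask = FALSE) {
  n <- length(cons$ia)
  w <- config$weights
  tot <- tot_act <- tot_pers <- 0; nb <- 0
  for (rows in epoch_batches(n, config$batch_size)) {
    ia <- cons$ia[rows]; ib <- cons$ib[rows]
    xb <- X[c(ia, ib), , , drop = FALSE]
    k <- length(rows)
    rt <- nn_forward(bundle$trunk, xb, training = TRUE)
    bundle$trunk <- rt$net
    ra <- nn_forward(bundle$head_act, rt$out, training = TRUE)
    bundle$head_act <- ra$net
    fa <- ra$out[seq_len(k), , drop = FALSE]
    fb <- ra$out[k + seq_len(k), , drop = FALSE]
    la <- contrastive_loss(fa, fb, cons$y_act[rows],
                           delta = w$margin_delta,
                           reduction = "mean", grad = TRUE)
    dact <- rbind(la$grad_fa, la$grad_fb)
    if (multitask) {
      rp <- nn_forward(bundle$head_pers, rt$out, training = TRUE)
      bundle$head_pers <- rp$net
      pa <- rp$out[seq_len(k), , drop = FALSE]
      pb <- rp$out[k + seq_len(k), , drop = FALSE]
      lp <- contrastive_loss(pa, pb, cons$y_pers[rows],
                             delta = w$margin_delta,
                             reduction = "mean", grad = TRUE)
      ba <- nn_backward(bundle$head_act, w$alpha * dact)
      bundle$head_act <- ba$net
      bp <- nn_backward(bundle$head_pers,
                        w$beta * rbind(lp$grad_fa, lp$grad_fb))
      bundle$head_pers <- bp$net
      bt <- nn_backward(bundle$trunk, ba$dx + bp$dx)
      bundle$trunk <- bt$net
      loss <- multitask_loss(la, lp, w$alpha, w$beta)
      tot_pers <- tot_pers + lp$value
    } else {
      ba <- nn_backward(bundle$head_act, dact)
      bundle$head_act <- ba$net
      bt <- nn_backward(bundle$trunk, ba$dx)
      bundle$trunk <- bt$net
      loss <- la$value
    }
    st <- opt_step(opt, bundle_params(bundle), bundle_grads(bundle))
    opt <- st$opt
    bundle <- bundle_set_params(bundle, st$params)
    tot <- tot + loss; tot_act <- tot_act + la$value; nb <- nb + 1
  }
  list(bundle = bundle, opt = opt, total = tot / nb,
       act = tot_act / nb, pers = tot_pers / nb)
}

#' Train the weakly supervised single-task Siamese TCN
#'
#' Shared-weight TCN branches with an activity head, trained with the
#' margin contrastive loss on pairwise same/different-activity
#' constraints; raw windows in, no explicit class labels consumed.
#'
#' @param windows a `sensor_windows`
#' @param constraints a `constraint_set` from [sample_pairs()]; when
#'   NULL, `pairs_per_epoch` pairs (default 4x the window count) are
#'   sampled with the config seed
#' @param config a [training_config()]
#' @param spec optional [encoder_spec()]
#' @return a trained `model_bundle` (`trunk` + `head_act`)
#' @export
train_weak_single <- function(windows, constraints = NULL, config,
                              spec = NULL) {
  spec <- spec %||% default_window_spec(windows$W, windows$n_channels)
  if (is.null(constraints)) {
    np <- config$pairs_per_epoch %||% (4L * n_windows(windows))
    constraints <- sample_pairs(windows, np, seed = config$seed)
  }
  set.seed(config$seed)
  bundle <- build_siamese(build_tcn_encoder(spec), heads = 1)
  sw <- standardize_windows(windows$values)
  X <- sw$values
  bundle$scaler <- list(center = sw$center, scale = sw$scale)
  opt <- opt_new(config)
  hist <- list()
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs_stage1)) {
    r <- siamese_epoch(bundle, X, constraints, config, opt)
    bundle <- r$bundle; opt <- r$opt
    hist[[length(hist) + 1]] <- rbind(
      hist_row(1L, ep, "simi_act", r$act),
      hist_row(1L, ep, "total", r$total))
  }
  bundle$history <- do.call(rbind, hist)
  bundle$paradigm <- "weak_single"
  bundle
}

#' Train the weakly supervised multi-task Siamese TCN
#'
#' Shared trunk with two heads: activity similarity and person
#' similarity, combined as `alpha * phi_act + beta * phi_pers` on
#' quadruple constraints.  With `beta = 0` and identical seed and pairs
#' this reduces exactly to the single-task trainer's activity-head
#' trajectory.
#'
#' @param windows a `sensor_windows`
#' @param constraints a `constraint_set` from [sample_quadruples()];
#'   sampled with the config seed when NULL
#' @param config a [training_config()]; `weights$alpha` / `weights$beta`
#'   are the task weights (defaults 0.5 / 0.5 are set in
#'   [run_experiment()]-style callers via `loss_weights`)
#' @param spec optional [encoder_spec()]
#' @return a trained `model_bundle` (`trunk`, `head_act`, `head_pers`)
#' @export
train_weak_multi <- function(windows, constraints = NULL, config,
                             spec = NULL) {
  spec <- spec %||% default_window_spec(windows$W, windows$n_channels)
  if (is.null(constraints)) {
    np <- config$pairs_per_epoch %||% (4L * n_windows(windows))
    constraints <- sample_quadruples(windows, np, seed = config$seed)
  }
  if (is.null(constraints$y_pers))
    stop("multi-task training needs quadruple constraints with y_pers")
  set.seed(config$seed)
  bundle <- build_siamese(build_tcn_encoder(spec), heads = 2)
  sw <- standardize_windows(windows$values)
  X <- sw$values
  bundle$scaler <- list(center = sw$center, scale = sw$scale)
  opt <- opt_new(config)
  hist <- list()
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs_stage1)) {
    r <- siamese_epoch(bundle, X, constraints, config, opt, multitask = TRUE)
    bundle <- r$bundle; opt <- r$opt
    hist[[length(hist) + 1]] <- rbind(
      hist_row(1L, ep, "simi_act", r$act),
      hist_row(1L, ep, "simi_pers", r$pers),
      hist_row(1L, ep, "total", r$total))
  }
  bundle$history <- do.call(rbind, hist)
  bundle$paradigm <- "weak_multi"
  bundle
}

# one self-supervised epoch over feature rows; nbstats caches the
# neighbor means for the whole run
selfsup_epoch <- function(bundle, X, neighborhoods, config, opt,
                          nbstats = NULL) {
  w <- config$weights
  sums <- c(ae = 0, tc = 0, fc = 0); tot <- 0; nb <- 0
  for (rows in epoch_batches(nrow(X), config$batch_size)) {
    xb <- X[rows, , drop = FALSE]
    fe <- nn_forward(bundle$encoder, xb, training = TRUE)
    bundle$encoder <- fe$net
    fd <- nn_forward(bundle$decoder, fe$out, training = TRUE)
    bundle$decoder <- fd$net
    l <- selfsup_loss(X, fd$out, neighborhoods, w, idx = rows,
                      reduction = "mean", grad = TRUE, stats = nbstats)
    bd <- nn_backward(bundle$decoder, l$grad)
    bundle$decoder <- bd$net
    be <- nn_backward(bundle$encoder, bd$dx)
    bundle$encoder <- be$net
    st <- opt_step(opt, bundle_params(bundle), bundle_grads(bundle))
    opt <- st$opt
    bundle <- bundle_set_params(bundle, st$params)
    sums <- sums + l$terms; tot <- tot + l$value; nb <- nb + 1
  }
  list(bundle = bundle, opt = opt, terms = sums / nb, total = tot / nb)
}

#' Train the self-supervised consistency autoencoder
#'
#' Residual autoencoder on handcrafted features, trained with the joint
#' objective: reconstruction plus temporal-neighborhood and
#' feature-neighborhood consistency, weighted
#' `(1 - alpha - beta) / alpha / beta`.  No labels are consumed.
#'
#' @param features a `feature_set`
#' @param neighborhoods a `neighborhood_index` from
#'   [build_neighborhoods()]; built with defaults when NULL
#' @param config a [training_config()] (weights default alpha = beta =
#'   0.3)
#' @param spec optional [encoder_spec()]
#' @return a trained `model_bundle`
#' @export
train_selfsup <- function(features, neighborhoods = NULL, config,
                          spec = NULL) {
  spec <- spec %||% default_feature_spec(ncol(features$X))
  neighborhoods <- neighborhoods %||% build_neighborhoods(features)
  set.seed(config$seed)
  bundle <- build_residual_autoencoder(spec)
  sc <- standardize_cols(features$X)
  X <- sc$X
  bundle$scaler <- list(center = sc$center, scale = sc$scale)
  opt <- opt_new(config)
  hist <- list()
  nbstats <- neighborhood_stats(X, neighborhoods)
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs_stage1)) {
    r <- selfsup_epoch(bundle, X, neighborhoods, config, opt, nbstats)
    bundle <- r$bundle; opt <- r$opt
    hist[[length(hist) + 1]] <- rbind(
      hist_row(1L, ep, "ae", r$terms[["ae"]]),
      hist_row(1L, ep, "tc", r$terms[["tc"]]),
      hist_row(1L, ep, "fc", r$terms[["fc"]]),
      hist_row(1L, ep, "total", r$total))
  }
  bundle$history <- do.call(rbind, hist)
  bundle$paradigm <- "selfsup"
  bundle
}

#' Train the two-stage weakly self-supervised model
#'
#' Stage 1 trains the consistency autoencoder on *all* features with no
#' label access.  Stage 2 fine-tunes with the joint pairwise objective:
#' both branches' reconstruction and consistency terms plus a
#' contrastive similarity term on the encoder embeddings, with
#' constraints drawn only from the label-budget subset.  The optimizer
#' is re-initialized between stages.
#'
#' @param features a `feature_set`
#' @param neighborhoods a `neighborhood_index`; built when NULL
#' @param constraints a `constraint_set` whose indices lie in the label
#'   budget; when NULL, a budget of `label_fraction` is drawn and
#'   `pairs_per_epoch` pairs are sampled within it
#' @param config a [training_config()]; stage-2 weights default
#'   `alpha = beta = 0.1, gamma = 0.6` (the similarity term dominates)
#' @param spec optional [encoder_spec()]
#' @param stage2_weights optional [loss_weights()] for stage 2
#' @return a trained `model_bundle`; `history` records both stages
#' @export
train_weak_selfsup <- function(features, neighborhoods = NULL,
                               constraints = NULL, config, spec = NULL,
                               stage2_weights = loss_weights(
                                 alpha = 0.1, beta = 0.1, gamma = 0.6,
                                 margin_delta = config$weights$margin_delta)) {
  spec <- spec %||% default_feature_spec(ncol(features$X))
  neighborhoods <- neighborhoods %||% build_neighborhoods(features)
  if (is.null(constraints)) {
    budget <- subsample_label_budget(features, config$label_fraction,
                                     seed = config$seed)
    np <- config$pairs_per_epoch %||% (4L * nrow(features$X))
    constraints <- tryCatch(
      sample_pairs(features, np, seed = config$seed, among = budget),
      error = function(e) NULL)
  }
  # stage 1: self-supervised pre-training, labels stripped
  unlabeled <- features
  unlabeled$activity <- rep(NA_integer_, length(features$activity))
  bundle <- train_selfsup(unlabeled, neighborhoods, config, spec)
  if (is.null(constraints) || length(constraints$ia) == 0) {
    warning("empty constraint set: returning the stage-1 model")
    bundle$paradigm <- "weak_selfsup"
    return(bundle)
  }
  X <- standardize_cols(features$X, bundle$scaler$center,
                        bundle$scaler$scale)$X
  w2 <- stage2_weights
  opt <- opt_new(config)
  hist <- list(bundle$history)
  nbstats <- neighborhood_stats(X, neighborhoods)
  set.seed(config$seed + 2L)
  for (ep in seq_len(config$epochs_stage2)) {
    sums <- c(ae = 0, tc = 0, fc = 0, simi_act = 0); tot <- 0; nb <- 0
    for (rows in epoch_batches(length(constraints$ia), config$batch_size)) {
      ia <- constraints$ia[rows]; ib <- constraints$ib[rows]
      k <- length(rows)
      xb <- X[c(ia, ib), , drop = FALSE]
      fe <- nn_forward(bundle$encoder, xb, training = TRUE)
      bundle$encoder <- fe$net
      fd <- nn_forward(bundle$decoder, fe$out, training = TRUE)
      bundle$decoder <- fd$net
      emb_a <- fe$out[seq_len(k), , drop = FALSE]
      emb_b <- fe$out[k + seq_len(k), , drop = FALSE]
      l <- weak_selfsup_loss(X, ia, ib,
                             fd$out[seq_len(k), , drop = FALSE],
                             fd$out[k + seq_len(k), , drop = FALSE],
                             emb_a, emb_b, constraints$y_act[rows],
                             neighborhoods, w2,
                             reduction = "mean", grad = TRUE,
                             stats = nbstats)
      bd <- nn_backward(bundle$decoder,
                        rbind(l$grad_recon_a, l$grad_recon_b))
      bundle$decoder <- bd$net
      demb <- bd$dx + rbind(l$grad_emb_a, l$grad_emb_b)
      be <- nn_backward(bundle$encoder, demb)
      bundle$encoder <- be$net
      st <- opt_step(opt, bundle_params(bundle), bundle_grads(bundle))
      opt <- st$opt
      bundle <- bundle_set_params(bundle, st$params)
      sums <- sums + l$terms; tot <- tot + l$value; nb <- nb + 1
    }
    hist[[length(hist) + 1]] <- rbind(
      hist_row(2L, ep, "ae", sums[["ae"]] / nb),
      hist_row(2L, ep, "tc", sums[["tc"]] / nb),
      hist_row(2L, ep, "fc", sums[["fc"]] / nb),
      hist_row(2L, ep, "simi_act", sums[["simi_act"]] / nb),
      hist_row(2L, ep, "total", tot / nb))
  }
  bundle$history <- do.call(rbind, hist)
  bundle$paradigm <- "weak_selfsup"
  bundle$constraints <- constraints
  bundle
}
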