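# Objective functions.  Each is a pure function of embeddings or
# reconstructions, returns the printed (sum-form) quantity or a mean
# reduction, and exposes analytic gradients for the trainers; the
# gradients are verified against central differences in the test suite.

as_row_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
}

#' Loss weights for the composite objectives
#'
#' @param alpha temporal-consistency weight (also the activity weight of
#'   the multi-task loss), in `[0, 1]`
#' @param beta feature-consistency weight (also the person weight of the
#'   multi-task loss), in `[0, 1]`
#' @param gamma pairwise-similarity weight of the two-stage fine-tuning
#'   loss, in `[0, 1]`
#' @param margin_delta contrastive margin `delta` (> 0); dissimilar pairs
#'   farther apart than this contribute nothing
#' @return a `loss_weights` list
#' @export
loss_weights <- function(alpha = 0.3, beta = 0.3, gamma = 0,
                         margin_delta = 1.0) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, margin_delta > 0)
  if (alpha + beta + gamma > 1 + 1e-12)
    stop("alpha + beta (+ gamma) must not exceed 1")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 margin_delta = margin_delta),
            class = "loss_weights")
}

#' Mean squared reconstruction error
#'
#' `(1/N) * sum_i ||x_i - x_recon_i||^2` (squared Euclidean norm per
#' sample, averaged over the batch), or the bare sum with
#' `reduction = "sum"`.
#'
#' @param x original inputs, `N x D` matrix (or vector for one sample)
#' @param x_recon reconstructions, same shape
#' @param reduction `"mean"` (default, as defined) or `"sum"`
#' @param grad if TRUE, also return the gradient with respect to
#'   `x_recon`
#' @return scalar loss, or `list(value, grad)` when `grad = TRUE`
#' @export
reconstruction_loss <- function(x, x_recon, reduction = c("mean", "sum"),
                                grad = FALSE) {
  reduction <- match.arg(reduction)
  x <- as_row_matrix(x); x_recon <- as_row_matrix(x_recon)
  if (!all(dim(x) == dim(x_recon)))
    stop("x and x_recon must have the same shape")
  r <- x_recon - x
  per <- rowSums(r^2)
  val <- if (reduction == "mean") mean(per) else sum(per)
  if (!grad) return(val)
  g <- 2 * r
  if (reduction == "mean") g <- g / nrow(x)
  list(value = val, grad = g)
}

#' Euclidean similarity distance between embeddings
#'
#' `||fa - fb||_2`, the non-squared Euclidean distance; row-wise when
#' given matrices.
#'
#' @param fa,fb embedding vectors, or `N x H` matrices of embeddings
#' @return scalar, or length-N vector of distances
#' @export
similarity_distance <- function(fa, fb) {
  fa <- as_row_matrix(fa); fb <- as_row_matrix(fb)
  stopifnot(all(dim(fa) == dim(fb)))
  d <- sqrt(rowSums((fa - fb)^2))
  if (length(d) == 1) d[[1]] else d
}

#' Pairwise contrastive loss with margin
#'
#' For each pair: `y * D^2/2 + (1 - y) * max(0, delta - D)^2 / 2` with
#' `D = ||fa - fb||`.  The defined quantity is the sum over pairs;
#' `reduction = "mean"` divides by the pair count for batch-size-stable
#' training.  Only dissimilar pairs closer than the margin contribute
#' (hard-negative gating).
#'
#' @param fa,fb embedding batches (`N x H`), one row per pair branch
#' @param y binary labels, 1 = similar, 0 = dissimilar
#' @param delta margin, > 0
#' @param reduction `"sum"` (the defined form) or `"mean"`
#' @param grad if TRUE, include gradients with respect to `fa` and `fb`
#' @return list with `value`, `breakdown` (data.frame `D`, `Ls`, `Ld`,
#'   `per_pair`), and when requested `grad_fa`, `grad_fb`
#' @export
contrastive_loss <- function(fa, fb, y, delta = 1.0,
                             reduction = c("sum", "mean"), grad = FALSE) {
  reduction <- match.arg(reduction)
  if (delta <= 0) stop("delta must be > 0")
  fa <- as_row_matrix(fa); fb <- as_row_matrix(fb)
  stopifnot(all(dim(fa) == dim(fb)), nrow(fa) == length(y))
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  diff <- fa - fb
  D <- sqrt(rowSums(diff^2))
  Ls <- D^2 / 2
  Ld <- pmax(0, delta - D)^2 / 2
  per <- y * Ls + (1 - y) * Ld
  n <- length(y)
  scale <- if (reduction == "mean") 1 / n else 1
  out <- list(value = sum(per) * scale,
              breakdown = data.frame(D = D, Ls = Ls, Ld = Ld,
                                     per_pair = per))
  if (grad) {
    # d per-pair / d fa: y*(fa-fb)  or  -(delta-D)/D*(fa-fb) inside margin
    coef <- ifelse(y == 1, 1,
                   ifelse(D < delta & D > 1e-12, -(delta - D) / D, 0))
    g <- diff * coef * scale
    out$grad_fa <- g
    out$grad_fb <- -g
  }
  class(out) <- "contrastive_result"
  out
}

#' @export
print.contrastive_result <- function(x, ...) {
  cat(sprintf("contrastive loss: %.6g over %d pairs\n",
              x$value, nrow(x$breakdown)))
  invisible(x)
}

#' Multiclass cross-entropy
#'
#' `-sum_j y_j log(y_prob_j)` averaged over the batch; `y_true` may be a
#' one-hot matrix or an integer class vector (0-based).
#'
#' @param y_true one-hot `N x M` matrix or 0-based class vector
#' @param y_prob predicted class probabilities, rows summing to 1
#' @param grad if TRUE, include the gradient with respect to the
#'   pre-softmax logits (the standard `p - y` form, divided by N)
#' @return scalar, or `list(value, grad_logits)` when `grad = TRUE`
#' @export
cross_entropy_loss <- function(y_true, y_prob, grad = FALSE) {
  y_prob <- as_row_matrix(y_prob)
  if (is.null(dim(y_true))) {
    Y <- matrix(0, nrow(y_prob), ncol(y_prob))
    Y[cbind(seq_len(nrow(y_prob)), as.integer(y_true) + 1L)] <- 1
  } else Y <- as.matrix(y_true)
  stopifnot(all(dim(Y) == dim(y_prob)))
  if (any(abs(rowSums(y_prob) - 1) > 1e-6))
    stop("probabilities must sum to 1 per sample")
  val <- -mean(rowSums(Y * log(pmax(y_prob, 1e-300))))
  if (!grad) return(val)
  list(value = val, grad_logits = (y_prob - Y) / nrow(Y))
}

#' Weighted multi-task contrastive loss
#'
#' `alpha * phi_act + beta * phi_pers`, where each term is a contrastive
#' loss evaluated on its own head's embeddings.
#'
#' @param act_breakdown activity-head contrastive result (or a scalar)
#' @param pers_breakdown person-head contrastive result (or a scalar)
#' @param alpha,beta task weights
#' @return scalar combined loss
#' @export
multitask_loss <- function(act_breakdown, pers_breakdown,
                           alpha = 0.5, beta = 0.5) {
  val <- function(x) if (is.list(x)) x$value else x
  alpha * val(act_breakdown) + beta * val(pers_breakdown)
}

#' Temporal consistency loss for one sample
#'
#' `(1/|P|) * sum_{p in P} ||x_p - x_recon||^2`: the reconstruction of a
#' window is pulled toward the *inputs* of its temporal neighbors, which
#' isolates the temporally stationary (activity) component.
#'
#' @param x_recon reconstruction of the center sample (vector)
#' @param neighbors matrix of neighbor input vectors (one per row),
#'   including the center itself
#' @param grad if TRUE, include the gradient with respect to `x_recon`
#' @return scalar, or `list(value, grad)`
#' @export
temporal_consistency_loss <- function(x_recon, neighbors, grad = FALSE) {
  neighbors <- as_row_matrix(neighbors)
  x_recon <- as.numeric(x_recon)
  stopifnot(ncol(neighbors) == length(x_recon), nrow(neighbors) >= 1)
  r <- sweep(neighbors, 2, x_recon)
  val <- mean(rowSums(r^2))
  if (!grad) return(val)
  list(value = val, grad = -2 * colMeans(r))
}

#' Feature consistency loss for one sample
#'
#' Same form as [temporal_consistency_loss()], with the k nearest
#' neighbors in handcrafted-feature space in place of the temporal
#' neighborhood; this suppresses person-specific variation.
#'
#' @inheritParams temporal_consistency_loss
#' @return scalar, or `list(value, grad)`
#' @export
feature_consistency_loss <- function(x_recon, neighbors, grad = FALSE) {
  temporal_consistency_loss(x_recon, neighbors, grad)
}

#' Joint self-supervised loss (reconstruction + consistencies)
#'
#' Per sample `i`:
#' `(1 - alpha - beta) * phi_ae(x_i) + alpha * phi_tc(x_i) +
#'  beta * phi_fc(x_i)`, summed over the batch (or averaged with
#' `reduction = "mean"`).  `phi_ae` here is the per-sample squared
#' reconstruction error.
#'
#' @param x inputs, `N x D` (the full matrix the neighborhood indices
#'   refer into)
#' @param x_recon reconstructions of the rows in `idx`
#' @param neighborhoods a `neighborhood_index` over the rows of `x`
#' @param weights a [loss_weights()]; `alpha + beta <= 1`
#' @param idx rows of `x` that `x_recon` reconstructs (default: all)
#' @param reduction `"sum"` (the defined form) or `"mean"`
#' @param grad if TRUE, include the gradient with respect to `x_recon`
#' @param stats optional precomputed neighbor statistics (internal
#'   training cache); computed from `neighborhoods` when NULL
#' @return list with `value`, `terms` (named vector of the weighted `ae`,
#'   `tc`, `fc` contributions, which re-sum to `value`), and optionally
#'   `grad`
#' @export
selfsup_loss <- function(x, x_recon, neighborhoods, weights,
                         idx = seq_len(nrow(as_row_matrix(x_recon))),
                         reduction = c("sum", "mean"), grad = FALSE,
                         stats = NULL) {
  reduction <- match.arg(reduction)
  x <- as_row_matrix(x); x_recon <- as_row_matrix(x_recon)
  a <- weights$alpha; b <- weights$beta
  if (a + b > 1 + 1e-12) stop("alpha + beta must not exceed 1")
  n <- nrow(x_recon)
  stopifnot(length(idx) == n)
  if (is.null(stats)) stats <- neighborhood_stats(x, neighborhoods)
  Xc <- x[idx, , drop = FALSE]
  mP <- stats$mean_temporal[idx, , drop = FALSE]
  mQ <- stats$mean_feature[idx, , drop = FALSE]
  rsq <- rowSums(x_recon^2)
  ae <- rowSums((Xc - x_recon)^2)
  # mean_p ||x_p - r||^2 = ||r||^2 - 2 r.meanP + mean_p ||x_p||^2
  tc <- rsq - 2 * rowSums(x_recon * mP) + stats$ms_temporal[idx]
  fc <- rsq - 2 * rowSums(x_recon * mQ) + stats$ms_feature[idx]
  scale <- if (reduction == "mean") 1 / n else 1
  terms <- c(ae = (1 - a - b) * sum(ae) * scale,
             tc = a * sum(tc) * scale,
             fc = b * sum(fc) * scale)
  out <- list(value = sum(terms), terms = terms)
  if (grad)
    out$grad <- ((1 - a - b) * 2 * (x_recon - Xc) +
                   a * 2 * (x_recon - mP) +
                   b * 2 * (x_recon - mQ)) * scale
  out
}

# Per-sample neighbor means and mean squared norms; neighborhoods and
# inputs are fixed during training, so trainers compute this once.
neighborhood_stats <- function(x, neighborhoods) {
  x <- as_row_matrix(x)
  n <- nrow(x)
  sq <- rowSums(x^2)
  one <- function(sets) {
    mM <- matrix(0, n, ncol(x))
    ms <- numeric(n)
    for (i in seq_len(n)) {
      s <- sets[[i]]
      mM[i, ] <- colMeans(x[s, , drop = FALSE])
      ms[i] <- mean(sq[s])
    }
    list(m = mM, s = ms)
  }
  tp <- one(neighborhoods$temporal)
  ft <- one(neighborhoods$feature)
  list(mean_temporal = tp$m, ms_temporal = tp$s,
       mean_feature = ft$m, ms_feature = ft$s)
}

#' Joint weakly self-supervised loss (two branches + similarity)
#'
#' Per pair `i`:
#' `(1-alpha-beta-gamma) * (phi_ae(xa) + phi_ae(xb)) +
#'  alpha * (phi_tc(xa) + phi_tc(xb)) + beta * (phi_fc(xa) + phi_fc(xb))
#'  + gamma * phi_simi(f(xa), f(xb), y_act)`, summed over pairs.
#'
#' @param x full input matrix the neighborhood indices refer into
#' @param idx_a,idx_b row indices of the two branches' samples
#' @param recon_a,recon_b reconstructions of those rows
#' @param emb_a,emb_b encoder embeddings of those rows (for the
#'   similarity term)
#' @param y_act binary pair labels (1 same activity)
#' @param neighborhoods a `neighborhood_index` over the rows of `x`
#' @param weights a [loss_weights()] with `alpha + beta + gamma <= 1`
#' @param reduction `"sum"` (defined form) or `"mean"`
#' @param grad if TRUE, include gradients with respect to both
#'   reconstructions and both embeddings
#' @param stats optional precomputed neighbor statistics (internal
#'   training cache)
#' @return list with `value`, `terms` (weighted `ae`, `tc`, `fc`,
#'   `simi_act`; re-sum to `value`), and optionally gradients
#' @export
weak_selfsup_loss <- function(x, idx_a, idx_b, recon_a, recon_b,
                              emb_a, emb_b, y_act, neighborhoods, weights,
                              reduction = c("sum", "mean"), grad = FALSE,
                              stats = NULL) {
  reduction <- match.arg(reduction)
  x <- as_row_matrix(x)
  a <- weights$alpha; b <- weights$beta; g <- weights$gamma
  if (a + b + g > 1 + 1e-12) stop("alpha + beta + gamma must not exceed 1")
  n <- length(y_act)
  if (is.null(stats)) stats <- neighborhood_stats(x, neighborhoods)
  # per-branch unweighted term sums and gradients
  ss <- function(idx, recon) {
    R <- as_row_matrix(recon)
    Xc <- x[idx, , drop = FALSE]
    mP <- stats$mean_temporal[idx, , drop = FALSE]
    mQ <- stats$mean_feature[idx, , drop = FALSE]
    rsq <- rowSums(R^2)
    list(ae = sum(rowSums((Xc - R)^2)),
         tc = sum(rsq - 2 * rowSums(R * mP) + stats$ms_temporal[idx]),
         fc = sum(rsq - 2 * rowSums(R * mQ) + stats$ms_feature[idx]),
         Gae = 2 * (R - Xc), Gtc = 2 * (R - mP), Gfc = 2 * (R - mQ))
  }
  sa <- ss(idx_a, recon_a)
  sb <- ss(idx_b, recon_b)
  simi <- contrastive_loss(emb_a, emb_b, y_act,
                           delta = weights$margin_delta,
                           reduction = "sum", grad = grad)
  scale <- if (reduction == "mean") 1 / n else 1
  terms <- c(ae = (1 - a - b - g) * (sa$ae + sb$ae) * scale,
             tc = a * (sa$tc + sb$tc) * scale,
             fc = b * (sa$fc + sb$fc) * scale,
             simi_act = g * simi$value * scale)
  out <- list(value = sum(terms), terms = terms)
  if (grad) {
    wsum <- function(s) ((1 - a - b - g) * s$Gae + a * s$Gtc + b * s$Gfc) * scale
    out$grad_recon_a <- wsum(sa)
    out$grad_recon_b <- wsum(sb)
    out$grad_emb_a <- g * simi$grad_fa * scale
    out$grad_emb_b <- g * simi$grad_fb * scale
  }
  out
}
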