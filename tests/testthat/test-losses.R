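test_that("reconstruction loss matches hand values and scaling", {
  expect_equal(reconstruction_loss(matrix(1:6, 2), matrix(1:6, 2)), 0)
  expect_equal(reconstruction_loss(c(0, 0), c(3, 4)), 25)
  x <- matrix(stats::rnorm(10), 5)
  xr <- matrix(stats::rnorm(10), 5)
  l1 <- reconstruction_loss(x, xr)
  l2 <- reconstruction_loss(x, x + 2 * (xr - x))
  expect_equal(l2, 4 * l1)
  expect_equal(reconstruction_loss(x, xr, reduction = "sum"), 5 * l1)
  expect_error(reconstruction_loss(matrix(0, 2, 2), matrix(0, 2, 3)),
               "shape")
})

test_that("similarity distance is the non-squared Euclidean metric", {
  expect_equal(similarity_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(similarity_distance(c(0, 0), c(3, 4)), 5)
  a <- stats::rnorm(4); b <- stats::rnorm(4)
  expect_equal(similarity_distance(a, b), similarity_distance(b, a))
})

test_that("contrastive loss matches the margin formulation", {
  f0 <- matrix(0, 1, 2)
  expect_equal(contrastive_loss(f0, f0, 1)$value, 0)
  # y = 0, D = 5 >= delta = 1: hard-negative gate, zero loss
  expect_equal(contrastive_loss(matrix(c(0, 0), 1), matrix(c(3, 4), 1),
                                0, delta = 1)$value, 0)
  # y = 1, D = 5 -> D^2/2 = 12.5
  r <- contrastive_loss(matrix(c(0, 0), 1), matrix(c(3, 4), 1), 1)
  expect_equal(r$value, 12.5)
  expect_equal(r$breakdown$D, 5)
  expect_equal(r$breakdown$Ls, 12.5)
  # y = 0, D = 0.5, delta = 1 -> (1 - 0.5)^2 / 2 = 0.125
  r <- contrastive_loss(matrix(0, 1, 1), matrix(0.5, 1, 1), 0, delta = 1)
  expect_equal(r$value, 0.125)
  expect_error(contrastive_loss(f0, f0, 2), "0 or 1")
  expect_error(contrastive_loss(f0, f0, 1, delta = 0), "delta")
})

test_that("the printed form is a sum over pairs, mean is optional", {
  fa <- matrix(stats::rnorm(8), 4)
  fb <- matrix(stats::rnorm(8), 4)
  y <- c(1, 0, 1, 0)
  s <- contrastive_loss(fa, fb, y)$value
  m <- contrastive_loss(fa, fb, y, reduction = "mean")$value
  expect_equal(s, 4 * m)
  expect_equal(s, sum(contrastive_loss(fa, fb, y)$breakdown$per_pair))
})

test_that("dissimilar pairs beyond the margin contribute exactly zero", {
  for (D in c(1, 1.5, 3, 10)) {
    r <- contrastive_loss(matrix(0, 1, 1), matrix(D, 1, 1), 0, delta = 1)
    expect_identical(r$value, 0)
  }
})

test_that("cross-entropy matches closed forms", {
  expect_equal(cross_entropy_loss(0L, matrix(c(1, 0, 0), 1)), 0)
  M <- 5
  expect_equal(cross_entropy_loss(2L, matrix(1 / M, 1, M)), log(M))
  # only the true-class probability matters
  p1 <- matrix(c(0.5, 0.3, 0.2), 1)
  p2 <- matrix(c(0.5, 0.1, 0.4), 1)
  expect_equal(cross_entropy_loss(0L, p1), cross_entropy_loss(0L, p2))
  expect_error(cross_entropy_loss(0L, matrix(c(0.5, 0.1), 1)), "sum to 1")
})

test_that("multi-task loss is the stated weighted sum", {
  expect_equal(multitask_loss(2, 4, alpha = 0.7, beta = 0.3), 2.6)
  expect_equal(multitask_loss(3, 99, alpha = 0.5, beta = 0), 1.5)
  expect_equal(multitask_loss(2, 4, 0.4, 0.4),
               multitask_loss(4, 2, 0.4, 0.4))
})

test_that("consistency losses average squared neighbor distances", {
  expect_equal(temporal_consistency_loss(c(1, 2), rbind(c(1, 2), c(1, 2))),
               0)
  # single-neighbor case reduces to the plain reconstruction error
  x <- c(0.3, -1)
  xr <- c(1, 1)
  expect_equal(temporal_consistency_loss(xr, matrix(x, 1)),
               sum((x - xr)^2))
  expect_equal(temporal_consistency_loss(0, rbind(1, 3)), 5)
  expect_equal(feature_consistency_loss(0, rbind(1, 3)), 5)
})

test_that("the joint self-supervised loss decomposes as stated", {
  # crafted so the per-sample terms are ae = 1, tc = 2, fc = 3
  x <- matrix(c(0, 3, 1, 3, 1 - sqrt(2)), ncol = 1)
  nb <- manual_neighborhoods(
    temporal = rep(list(c(2L, 3L)), 5), feature = rep(list(c(4L, 5L)), 5))
  w <- loss_weights(alpha = 0.3, beta = 0.3)
  r <- selfsup_loss(x, matrix(1), nb, w, idx = 1L)
  expect_equal(unname(r$terms["ae"]), 0.4 * 1)
  expect_equal(unname(r$terms["tc"]), 0.3 * 2)
  expect_equal(unname(r$terms["fc"]), 0.3 * 3)
  expect_equal(r$value, 1.9)
  expect_lt(abs(sum(r$terms) - r$value), 1e-10)
  # alpha = beta = 0 reduces to the summed reconstruction error
  set.seed(5)
  X <- matrix(stats::rnorm(12), 4)
  R <- matrix(stats::rnorm(12), 4)
  nb4 <- manual_neighborhoods(as.list(1:4), as.list(rep(1L, 4)))
  r0 <- selfsup_loss(X, R, nb4, loss_weights(0, 0))
  expect_equal(r0$value, reconstruction_loss(X, R, reduction = "sum"))
  # alpha = 1, beta = 0 with perfect neighbor consensus is zero
  Xc <- matrix(1, 3, 2)
  nb3 <- manual_neighborhoods(as.list(1:3), as.list(rep(1L, 3)))
  expect_equal(selfsup_loss(Xc, Xc, nb3, loss_weights(1, 0))$value, 0)
})

test_that("the weakly self-supervised loss matches its hand value", {
  # both branches: ae = 1, tc = 2, fc = 3 per pair; simi = 4
  x <- matrix(c(0, 3, 1, 3, 1 - sqrt(2)), ncol = 1)
  nb <- manual_neighborhoods(
    temporal = list(c(2L, 3L), c(2L, 3L), c(2L, 3L), c(2L, 3L), c(2L, 3L)),
    feature = list(c(4L, 5L), c(4L, 5L), c(4L, 5L), c(4L, 5L), c(4L, 5L)))
  w <- loss_weights(alpha = 0.1, beta = 0.1, gamma = 0.6)
  # similar pair with D = 2*sqrt(2): Ls = D^2/2 = 4
  r <- weak_selfsup_loss(x, idx_a = 1L, idx_b = 1L,
                         recon_a = matrix(1), recon_b = matrix(1),
                         emb_a = matrix(0), emb_b = matrix(2 * sqrt(2)),
                         y_act = 1, neighborhoods = nb, weights = w)
  expect_equal(unname(r$terms["ae"]), 0.2 * 2)
  expect_equal(unname(r$terms["tc"]), 0.1 * 4)
  expect_equal(unname(r$terms["fc"]), 0.1 * 6)
  expect_equal(unname(r$terms["simi_act"]), 0.6 * 4)
  expect_equal(r$value, 3.8)
  expect_lt(abs(sum(r$terms) - r$value), 1e-10)
})

test_that("weak self-supervision reduces to its parts at the corners", {
  set.seed(9)
  X <- matrix(stats::rnorm(20), 5, 4)
  nb <- manual_neighborhoods(
    lapply(1:5, function(i) unique(c(i, (i %% 5) + 1L))),
    lapply(1:5, function(i) c((i %% 5) + 1L, ((i + 1) %% 5) + 1L)))
  ia <- c(1L, 2L); ib <- c(3L, 4L)
  Ra <- matrix(stats::rnorm(8), 2, 4); Rb <- matrix(stats::rnorm(8), 2, 4)
  Ea <- matrix(stats::rnorm(6), 2, 3); Eb <- matrix(stats::rnorm(6), 2, 3)
  y <- c(1, 0)
  # gamma = 0: sum of the two branch objectives
  w0 <- loss_weights(alpha = 0.2, beta = 0.3, gamma = 0)
  r <- weak_selfsup_loss(X, ia, ib, Ra, Rb, Ea, Eb, y, nb, w0)
  sa <- selfsup_loss(X, Ra, nb, w0, idx = ia)
  sb <- selfsup_loss(X, Rb, nb, w0, idx = ib)
  expect_equal(r$value, sa$value + sb$value)
  # alpha = beta = 0, gamma = 1: the pure contrastive objective
  w1 <- loss_weights(alpha = 0, beta = 0, gamma = 1)
  r1 <- weak_selfsup_loss(X, ia, ib, Ra, Rb, Ea, Eb, y, nb, w1)
  expect_equal(r1$value, contrastive_loss(Ea, Eb, y)$value)
})

test_that("loss weights enforce the simplex constraints", {
  expect_error(loss_weights(alpha = 0.7, beta = 0.5), "exceed 1")
  expect_error(loss_weights(alpha = 0.5, beta = 0.3, gamma = 0.4),
               "exceed 1")
  expect_error(loss_weights(margin_delta = 0), "margin")
})

test_that("every loss is nonnegative on random inputs", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(stats::rnorm(8), 2)
    xr <- matrix(stats::rnorm(8), 2)
    expect_gte(reconstruction_loss(x, xr), 0)
    y <- sample(0:1, 2, replace = TRUE)
    expect_gte(contrastive_loss(x, xr, y)$value, 0)
    expect_gte(temporal_consistency_loss(xr[1, ], x), 0)
  }
})
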