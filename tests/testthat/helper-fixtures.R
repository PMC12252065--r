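# Small shared fixtures, all generated in code.

tiny_synth <- function(...) {
  args <- list(n_persons = 2, n_activities = 2, n_channels = 2,
               sampling_rate = 20, bout_length = 10,
               n_bouts_per_person = 3, noise_sigma = 0.2,
               person_effect_scale = 0.2, seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

tiny_windows <- function(config = tiny_synth(), window_seconds = 1,
                         step_seconds = 0.5) {
  bind_windows(lapply(generate_streams(config), segment_windows,
                      window_seconds = window_seconds,
                      step_seconds = step_seconds))
}

# a hand-built single-activity stream for segmentation arithmetic
flat_stream <- function(T, C = 2, rate = 10, activity = 0L, person = 0L) {
  harspectrum:::new_sensor_stream(matrix(seq_len(T * C), T, C), rate,
                                  rep(activity, T), rep(person, T))
}

# a minimal neighborhood index over explicit index sets
manual_neighborhoods <- function(temporal, feature) {
  structure(list(temporal = temporal, feature = feature,
                 radius = NA, k = NA),
            class = "neighborhood_index")
}

# Brute-force best injective cluster-to-class mapping by enumeration;
# the independent oracle for the Hungarian path (k, M <= 6).
brute_best_accuracy <- function(assignments, truth) {
  clusters <- sort(unique(assignments))
  classes <- sort(unique(truth))
  k <- length(clusters); M <- length(classes)
  best <- 0
  if (k <= M) {
    perms <- all_arrangements(M, k)
    for (r in seq_len(nrow(perms))) {
      map <- classes[perms[r, ]]
      pred <- map[match(assignments, clusters)]
      best <- max(best, mean(pred == truth))
    }
  } else {
    perms <- all_arrangements(k, M)
    for (r in seq_len(nrow(perms))) {
      map <- rep(NA, k)
      map[perms[r, ]] <- classes
      pred <- map[match(assignments, clusters)]
      best <- max(best, mean(!is.na(pred) & pred == truth))
    }
  }
  best
}

# all ordered arrangements of r elements out of n (n P r), tiny n only
all_arrangements <- function(n, r) {
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- all_arrangements(n - 1, r - 1)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# central-difference gradient of f at x (vector or matrix), step h
numeric_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

expect_grad_close <- function(analytic, numeric, tol = 1e-4) {
  denom <- pmax(abs(numeric), 1e-8)
  expect_lt(max(abs(analytic - numeric) / denom), tol)
}
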