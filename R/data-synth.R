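#' Configuration for the synthetic wearable-sensor generator
#'
#' The generator emulates the statistical structure that label-efficient
#' HAR methods assume: each activity class is a temporally *stationary*
#' signature (an activity-specific base frequency, amplitude and channel
#' mixing pattern), each person modulates that signature with a nuisance
#' gain/phase/offset (the temporally *varying*, person-specific
#' component), activities come in contiguous bouts so that temporal
#' continuity holds, and i.i.d. Gaussian noise is added on top.
#'
#' @param n_persons number of simulated wearers (streams), >= 1
#' @param n_activities number of activity classes M, >= 1
#' @param n_channels number of sensor channels C, >= 1
#' @param sampling_rate sampling rate in Hz
#' @param bout_length length of one contiguous activity bout, seconds
#' @param n_bouts_per_person bouts per person; must be >= `n_activities`
#'   so every class occurs for every person
#' @param noise_sigma standard deviation of the additive Gaussian noise,
#'   in signal units, >= 0
#' @param person_effect_scale magnitude of the per-person nuisance
#'   (gain/phase/offset), dimensionless, >= 0; 0 removes inter-person
#'   variability entirely
#' @param seed integer seed; identical config and seed give bit-identical
#'   streams
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_persons = 4, n_activities = 3, n_channels = 3,
                         sampling_rate = 25, bout_length = 45,
                         n_bouts_per_person = 4, noise_sigma = 0.8,
                         person_effect_scale = 0.3, seed = 1L) {
  stopifnot(n_persons >= 1, n_activities >= 1, n_channels >= 1,
            sampling_rate > 0, bout_length > 0, n_bouts_per_person >= 1,
            noise_sigma >= 0, person_effect_scale >= 0)
  if (round(bout_length * sampling_rate) < 1)
    stop("bout shorter than one sample: increase bout_length or sampling_rate")
  if (n_bouts_per_person < n_activities)
    stop("n_bouts_per_person must be >= n_activities so every class occurs")
  structure(list(n_persons = as.integer(n_persons),
                 n_activities = as.integer(n_activities),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 bout_length = bout_length,
                 n_bouts_per_person = as.integer(n_bouts_per_person),
                 noise_sigma = noise_sigma,
                 person_effect_scale = person_effect_scale,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic sensor-stream configuration\n")
  cat(sprintf("  %d persons x %d activities, %d channels @ %g Hz\n",
              x$n_persons, x$n_activities, x$n_channels, x$sampling_rate))
  cat(sprintf("  %d bouts/person of %g s; noise sd %g; person effect %g\n",
              x$n_bouts_per_person, x$bout_length, x$noise_sigma,
              x$person_effect_scale))
  invisible(x)
}

new_sensor_stream <- function(values, sampling_rate, activity, person) {
  stopifnot(nrow(values) == length(activity),
            nrow(values) == length(person))
  structure(list(values = values, sampling_rate = sampling_rate,
                 activity = as.integer(activity),
                 person = as.integer(person)),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("sensor_stream: %d samples x %d channels @ %g Hz (person %d, %d activities)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              x$person[1], length(unique(x$activity))))
  invisible(x)
}

# Activity signatures: deterministic functions of the class index so that
# the noiseless zero-nuisance case is exactly periodic and analyzable.
# Base frequency f_a = rate/50 * (1 + a) keeps an integer fundamental
# period (50 samples) and stays well below Nyquist for small M.  All
# classes share unit amplitude: class identity lives in the channel
# mixing direction, the harmonic content and the frequency, not in the
# overall signal energy, so that a person's intensity gain is a genuine
# confounder rather than a free ride for amplitude statistics.
activity_signature <- function(a, n_activities, n_channels, sampling_rate) {
  freq <- sampling_rate * (1 + a) / 50
  amp <- 1 + 0.3 * a
  ch <- seq_len(n_channels) - 1
  mix <- amp * (0.55 + 0.45 * cos(2 * pi * ch / n_channels +
                                    2 * pi * a / max(1, n_activities)))
  mix2 <- amp * (0.55 + 0.45 * cos(2 * pi * ch / n_channels +
                                     2 * pi * a / max(1, n_activities) +
                                     pi / 2))
  harm <- 0.3 + 0.4 * a / max(1, n_activities - 1)
  phase_ch <- pi * a * ch / max(1, n_channels)
  list(freq = freq, mix = mix, mix2 = mix2, harm = harm,
       phase_ch = phase_ch)
}

#' Generate synthetic labeled sensor streams
#'
#' Produces one multichannel stream per person.  Each stream is a
#' concatenation of `n_bouts_per_person` contiguous activity bouts; the
#' bout sequence per person is built from shuffled permutations of all
#' classes, so every class appears for every person.  Within a bout,
#' channel `c` carries a two-harmonic sinusoid at the class frequency,
#' mixed across channels by the class-specific pattern, scaled by the
#' person's gain and shifted by the person's offset, plus Gaussian
#' noise.
#'
#' @param config a [synth_config()]
#' @return a list of `sensor_stream` objects, one per person
#' @export
generate_streams <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  M <- config$n_activities
  C <- config$n_channels
  rate <- config$sampling_rate
  bout_n <- round(config$bout_length * rate)
  if (bout_n < 1) stop("bout shorter than one sample")
  sigs <- lapply(seq_len(M) - 1, activity_signature,
                 n_activities = M, n_channels = C, sampling_rate = rate)
  streams <- vector("list", config$n_persons)
  for (p in seq_len(config$n_persons)) {
    # person nuisance: a global intensity gain (people perform the same
    # activity at different intensities), per-channel gain and offset
    # (sensor placement/calibration), and a phase shift; offsets carry
    # half the nuisance budget, gains a quarter each
    # draws are uniform with unit variance (bounded at sqrt(3) sd), so a
    # single extreme person cannot degenerate the class geometry
    pes <- config$person_effect_scale
    runit <- function(n) stats::runif(n, -sqrt(3), sqrt(3))
    g_global <- 1 + 0.5 * pes * runit(1)
    gain <- g_global * (1 + 0.5 * pes * runit(C))
    offset <- 0.5 * pes * runit(C)
    phase <- pes * runit(1)
    # bout sequence: stacked shuffled permutations guarantee coverage
    reps <- ceiling(config$n_bouts_per_person / M)
    seq_act <- unlist(lapply(seq_len(reps), function(i) sample.int(M) - 1L))
    seq_act <- seq_act[seq_len(config$n_bouts_per_person)]
    Tn <- bout_n * config$n_bouts_per_person
    vals <- matrix(0, Tn, C)
    act <- integer(Tn)
    for (b in seq_len(config$n_bouts_per_person)) {
      a <- seq_act[b]
      s <- sigs[[a + 1]]
      rows <- (b - 1) * bout_n + seq_len(bout_n)
      tt <- (seq_len(bout_n) - 1) / rate
      for (ch in seq_len(C)) {
        base <- sin(2 * pi * s$freq * tt + phase + s$phase_ch[ch])
        second <- sin(4 * pi * s$freq * tt + phase + s$phase_ch[ch] + pi / 3)
        vals[rows, ch] <- gain[ch] *
          (s$mix[ch] * base + s$harm * s$mix2[ch] * second) + offset[ch]
      }
      act[rows] <- a
    }
    if (config$noise_sigma > 0)
      vals <- vals + matrix(stats::rnorm(Tn * C, sd = config$noise_sigma),
                            Tn, C)
    streams[[p]] <- new_sensor_stream(vals, rate, act,
                                      rep(p - 1L, Tn))
  }
  streams
}

#' Segment a stream into fixed-length windows
#'
#' Windows are taken left to right with `W = round(window_seconds * rate)`
#' samples and a step of `round(step_seconds * rate)` samples.  A trailing
#' partial window is discarded, as is any window that spans an activity or
#' person change (label purity).  Window ordinals `t` are assigned 0-based
#' in temporal order after discarding.
#'
#' @param stream a `sensor_stream`
#' @param window_seconds window length in seconds
#' @param step_seconds step between window starts in seconds
#' @return a `sensor_windows` container (may hold zero windows)
#' @export
segment_windows <- function(stream, window_seconds, step_seconds) {
  stopifnot(inherits(stream, "sensor_stream"), step_seconds > 0)
  rate <- stream$sampling_rate
  W <- round(window_seconds * rate)
  step <- round(step_seconds * rate)
  if (W < 1) stop("window_seconds * sampling_rate must be >= 1")
  if (step < 1) stop("step_seconds too small for this sampling rate")
  Tn <- nrow(stream$values)
  C <- ncol(stream$values)
  starts <- if (Tn >= W) seq(1L, Tn - W + 1L, by = step) else integer(0)
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i] + seq_len(W) - 1L
    keep[i] <- length(unique(stream$activity[idx])) == 1L &&
      length(unique(stream$person[idx])) == 1L
  }
  starts <- starts[keep]
  n <- length(starts)
  vals <- array(0, c(n, W, C))
  act <- integer(n)
  pers <- integer(n)
  for (i in seq_along(starts)) {
    idx <- starts[i] + seq_len(W) - 1L
    vals[i, , ] <- stream$values[idx, ]
    act[i] <- stream$activity[idx[1]]
    pers[i] <- stream$person[idx[1]]
  }
  new_sensor_windows(vals, act, pers, t = seq_len(n) - 1L,
                     sampling_rate = rate)
}

new_sensor_windows <- function(values, activity, person, t, sampling_rate) {
  structure(list(values = values, activity = as.integer(activity),
                 person = as.integer(person), t = as.integer(t),
                 W = dim(values)[2], n_channels = dim(values)[3],
                 sampling_rate = sampling_rate),
            class = "sensor_windows")
}

#' Number of windows in a container
#' @param x a `sensor_windows` object
#' @export
n_windows <- function(x) dim(x$values)[1]

#' @export
print.sensor_windows <- function(x, ...) {
  cat(sprintf("sensor_windows: %d windows of %d samples x %d channels @ %g Hz\n",
              n_windows(x), x$W, x$n_channels, x$sampling_rate))
  invisible(x)
}

#' Concatenate window containers from several streams
#'
#' Window ordinals `t` are kept per source stream (they restart at 0 for
#' each person), which is what per-stream temporal neighborhoods need.
#'
#' @param windows_list list of `sensor_windows`
#' @return one combined `sensor_windows`
#' @export
bind_windows <- function(windows_list) {
  windows_list <- windows_list[vapply(windows_list, n_windows, 1L) > 0]
  stopifnot(length(windows_list) > 0)
  W <- windows_list[[1]]$W
  C <- windows_list[[1]]$n_channels
  for (w in windows_list) stopifnot(w$W == W, w$n_channels == C)
  n <- sum(vapply(windows_list, n_windows, 1L))
  vals <- array(0, c(n, W, C))
  at <- 0L
  for (w in windows_list) {
    k <- n_windows(w)
    vals[at + seq_len(k), , ] <- w$values
    at <- at + k
  }
  new_sensor_windows(vals,
                     unlist(lapply(windows_list, `[[`, "activity")),
                     unlist(lapply(windows_list, `[[`, "person")),
                     unlist(lapply(windows_list, `[[`, "t")),
                     windows_list[[1]]$sampling_rate)
}

#' Decimate a stream by an integer factor
#'
#' Keeps every `factor`-th sample (starting at the first) of the values,
#' activity labels and person ids, and divides the sampling rate by
#' `factor`.  No anti-alias filter is applied; this is plain decimation.
#'
#' @param stream a `sensor_stream`
#' @param factor integer >= 1
#' @return the decimated `sensor_stream`
#' @export
downsample <- function(stream, factor) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (length(factor) != 1 || is.na(factor) || factor != round(factor) ||
      factor < 1)
    stop("factor must be a single integer >= 1 (e.g. 100 Hz -> 33.3 Hz is factor 3)")
  factor <- as.integer(factor)
  if (factor == 1L) return(stream)
  idx <- seq(1L, nrow(stream$values), by = factor)
  new_sensor_stream(stream$values[idx, , drop = FALSE],
                    stream$sampling_rate / factor,
                    stream$activity[idx], stream$person[idx])
}

## ---- long-format CSV I/O ------------------------------------------------

#' Write sensor streams to a long-format CSV
#'
#' Layout: header `person,activity,sample_index,ch0..ch{C-1}`;
#' `sample_index` is 0-based and contiguous per person.
#'
#' @param streams list of `sensor_stream` (or a single one)
#' @param path output file path
#' @param sampling_rate ignored; kept in the stream objects
#' @return `path`, invisibly
#' @export
write_sensor_csv <- function(streams, path, sampling_rate = NULL) {
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  dfs <- lapply(streams, function(s) {
    C <- ncol(s$values)
    df <- data.frame(person = s$person, activity = s$activity,
                     sample_index = seq_len(nrow(s$values)) - 1L)
    for (ch in seq_len(C)) df[[paste0("ch", ch - 1)]] <- s$values[, ch]
    df
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sensor streams from a long-format CSV
#'
#' @param path CSV written by [write_sensor_csv()] (or any file with the
#'   same header)
#' @param sampling_rate sampling rate in Hz to attach to the streams (the
#'   CSV format does not carry it)
#' @return list of `sensor_stream`, one per person, in person-id order
#' @export
read_sensor_csv <- function(path, sampling_rate) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("person", "activity", "sample_index")
  if (!all(need %in% names(df)))
    stop("CSV must have columns person,activity,sample_index,ch0..")
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  ch_cols <- ch_cols[order(as.integer(sub("ch", "", ch_cols)))]
  if (length(ch_cols) == 0) stop("no channel columns ch0.. found")
  lapply(sort(unique(df$person)), function(p) {
    sub <- df[df$person == p, ]
    sub <- sub[order(sub$sample_index), ]
    if (!all(sub$sample_index == seq_len(nrow(sub)) - 1L))
      stop("sample_index must be 0-based and contiguous per person")
    new_sensor_stream(as.matrix(sub[, ch_cols, drop = FALSE]),
                      sampling_rate, sub$activity, sub$person)
  })
}

#' Write a window container to CSV
#'
#' Long layout with one row per sample: `window,person,activity,t,sample,
#' ch0..`; `window` and `sample` are 0-based, ordering is stable.
#' @param windows a `sensor_windows`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_windows_csv <- function(windows, path) {
  n <- n_windows(windows)
  W <- windows$W
  C <- windows$n_channels
  df <- data.frame(window = rep(seq_len(n) - 1L, each = W),
                   person = rep(windows$person, each = W),
                   activity = rep(windows$activity, each = W),
                   t = rep(windows$t, each = W),
                   sample = rep(seq_len(W) - 1L, n))
  for (ch in seq_len(C)) {
    m <- t(windows$values[, , ch, drop = TRUE])
    if (n == 1) m <- matrix(windows$values[1, , ch], ncol = 1)
    df[[paste0("ch", ch - 1)]] <- as.vector(m)
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a window container written by [write_windows_csv()]
#' @param path CSV path
#' @param sampling_rate sampling rate in Hz to attach
#' @return a `sensor_windows`
#' @export
read_windows_csv <- function(path, sampling_rate = NA_real_) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  ch_cols <- grep("^ch[0-9]+$", names(df), value = TRUE)
  ch_cols <- ch_cols[order(as.integer(sub("ch", "", ch_cols)))]
  ids <- sort(unique(df$window))
  W <- sum(df$window == ids[1])
  n <- length(ids)
  vals <- array(0, c(n, W, length(ch_cols)))
  act <- integer(n); pers <- integer(n); tt <- integer(n)
  for (i in seq_along(ids)) {
    sub <- df[df$window == ids[i], ]
    sub <- sub[order(sub$sample), ]
    vals[i, , ] <- as.matrix(sub[, ch_cols, drop = FALSE])
    act[i] <- sub$activity[1]; pers[i] <- sub$person[1]; tt[i] <- sub$t[1]
  }
  new_sensor_windows(vals, act, pers, tt, sampling_rate)
}
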