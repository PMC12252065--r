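#' Encoder architecture specification
#'
#' One spec type covers both encoder families: the residual TCN that
#' consumes raw `(W, C)` windows and the residual fully connected
#' autoencoder that consumes `7 * C` handcrafted features.
#'
#' @param input_shape `c(W, C)` for raw-signal encoders, or a single
#'   integer (feature width) for feature encoders
#' @param embedding_dim latent width H, >= 2
#' @param n_tcn_blocks number of residual TCN blocks
#' @param channels_per_block output channels per block (recycled to
#'   `n_tcn_blocks`)
#' @param kernel_size convolution kernel length, >= 2
#' @param pool_every insert a temporal max-pool (size 2) after every this
#'   many blocks
#' @param hidden_dims widths of the residual FC encoder stages (the
#'   decoder mirrors them)
#' @return an `encoder_spec`
#' @export
encoder_spec <- function(input_shape, embedding_dim = 32,
                         n_tcn_blocks = 4,
                         channels_per_block = c(32, 32, 64, 64),
                         kernel_size = 5, pool_every = 2,
                         hidden_dims = c(128, 64)) {
  stopifnot(embedding_dim >= 2, kernel_size >= 2, length(channels_per_block) >= 1)
  channels_per_block <- rep_len(channels_per_block, n_tcn_blocks)
  structure(list(input_shape = input_shape,
                 embedding_dim = as.integer(embedding_dim),
                 n_tcn_blocks = as.integer(n_tcn_blocks),
                 channels_per_block = as.integer(channels_per_block),
                 kernel_size = as.integer(kernel_size),
                 pool_every = as.integer(pool_every),
                 hidden_dims = as.integer(hidden_dims)),
            class = "encoder_spec")
}

new_model_bundle <- function(kind, spec, ...) {
  structure(c(list(kind = kind, spec = spec), list(...)),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  np <- 0L
  for (nm in intersect(names(x), c("encoder", "decoder", "trunk",
                                   "head_act", "head_pers", "classifier")))
    if (!is.null(x[[nm]])) np <- np + nn_n_params(x[[nm]])
  cat(sprintf("model_bundle (%s): %d trainable parameters\n", x$kind, np))
  invisible(x)
}

#' Build a residual temporal convolutional encoder
#'
#' A stack of residual TCN blocks (two dilated *causal* conv -> batch
#' norm -> ReLU stages per block, additive skip; identity skip when
#' channel counts match, pointwise linear projection otherwise), with the
#' dilation doubling per block, a temporal max-pool after every
#' `pool_every` blocks, global temporal max-pooling, and a final fully
#' connected layer to the embedding width H.
#'
#' @param spec an [encoder_spec()] with `input_shape = c(W, C)`
#' @return a `model_bundle` with an `encoder` network
#' @export
build_tcn_encoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"), length(spec$input_shape) == 2)
  W <- spec$input_shape[1]; C <- spec$input_shape[2]
  n_pools <- spec$n_tcn_blocks %/% spec$pool_every
  min_W <- 2^n_pools
  if (W < min_W)
    stop("window length W = ", W, " too small for this encoder; ",
         "the pooled receptive field needs W >= ", min_W)
  layers <- list()
  c_in <- C
  for (b in seq_len(spec$n_tcn_blocks)) {
    c_out <- spec$channels_per_block[b]
    layers[[length(layers) + 1]] <-
      nn_tcn_block(c_in, c_out, spec$kernel_size, dilation = 2^(b - 1))
    c_in <- c_out
    if (b %% spec$pool_every == 0)
      layers[[length(layers) + 1]] <- nn_maxpool(2)
  }
  layers[[length(layers) + 1]] <- nn_globalmax()
  layers[[length(layers) + 1]] <- nn_dense(c_in, spec$embedding_dim)
  new_model_bundle("tcn_encoder", spec, encoder = layers)
}

#' Build a residual autoencoder for handcrafted features
#'
#' The encoder is a chain of residual fully connected blocks with
#' decreasing widths ending in a linear map to H; the decoder is a plain
#' fully connected stack widening back to the input width (no residual
#' connections), so the reconstruction has the input shape.
#'
#' @param spec an [encoder_spec()] whose `input_shape` is the feature
#'   width `7 * C`
#' @return a `model_bundle` with `encoder` and `decoder` networks
#' @export
build_residual_autoencoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"), length(spec$input_shape) == 1)
  d_in <- spec$input_shape
  H <- spec$embedding_dim
  if (H >= d_in)
    warning("embedding_dim >= input width: the autoencoder has no bottleneck")
  enc <- list()
  w <- d_in
  for (h in spec$hidden_dims) {
    enc[[length(enc) + 1]] <- nn_resfc_block(w, h)
    w <- h
  }
  enc[[length(enc) + 1]] <- nn_dense(w, H)
  dec <- list()
  w <- H
  for (h in rev(spec$hidden_dims)) {
    dec[[length(dec) + 1]] <- nn_dense(w, h)
    dec[[length(dec) + 1]] <- nn_relu()
    w <- h
  }
  dec[[length(dec) + 1]] <- nn_dense(w, d_in)
  new_model_bundle("residual_autoencoder", spec, encoder = enc, decoder = dec)
}

#' Wrap an encoder as a Siamese model with one or two heads
#'
#' Both branches apply the identical parameter set (weight sharing is by
#' construction: there is only one copy of the trunk and of each head).
#' With one head the bundle exposes `f_act`; with two it adds `f_pers`
#' for person identification, consuming the same trunk output.
#'
#' @param base a `model_bundle` holding an encoder
#' @param heads 1 (activity head only) or 2 (activity + person)
#' @return a `model_bundle` with `trunk`, `head_act` and optionally
#'   `head_pers`
#' @export
build_siamese <- function(base, heads = 1) {
  stopifnot(inherits(base, "model_bundle"), !is.null(base$encoder))
  if (!heads %in% c(1, 2)) stop("heads must be 1 or 2")
  H <- base$spec$embedding_dim
  head_act <- list(nn_dense(H, H))
  head_pers <- if (heads == 2) list(nn_dense(H, H)) else NULL
  new_model_bundle(if (heads == 1) "siamese" else "siamese_multitask",
                   base$spec, trunk = base$encoder,
                   head_act = head_act, head_pers = head_pers)
}

# Forward through a bundle's encoding path in eval or train mode.
# Returns list(bundle, emb [, emb_pers]); for siamese bundles the
# activity head defines the representation.
bundle_encode <- function(bundle, x, training = FALSE, person_head = FALSE) {
  if (!is.null(bundle$trunk)) {
    r <- nn_forward(bundle$trunk, x, training)
    bundle$trunk <- r$net
    h <- r$out
    net_name <- if (person_head) "head_pers" else "head_act"
    if (is.null(bundle[[net_name]]))
      stop("bundle has no ", net_name)
    r2 <- nn_forward(bundle[[net_name]], h, training)
    bundle[[net_name]] <- r2$net
    list(bundle = bundle, emb = r2$out, trunk_out = h)
  } else {
    r <- nn_forward(bundle$encoder, x, training)
    bundle$encoder <- r$net
    list(bundle = bundle, emb = r$out)
  }
}

bundle_params <- function(bundle) {
  nets <- intersect(names(bundle),
                    c("encoder", "decoder", "trunk", "head_act",
                      "head_pers", "classifier"))
  out <- list()
  for (nm in nets)
    if (!is.null(bundle[[nm]]))
      out <- c(out, nn_collect(bundle[[nm]], "params", paste0(nm, ".")))
  out
}

bundle_grads <- function(bundle) {
  nets <- intersect(names(bundle),
                    c("encoder", "decoder", "trunk", "head_act",
                      "head_pers", "classifier"))
  out <- list()
  for (nm in nets)
    if (!is.null(bundle[[nm]]))
      out <- c(out, nn_collect(bundle[[nm]], "grads", paste0(nm, ".")))
  out
}

bundle_set_params <- function(bundle, params) {
  nets <- intersect(names(bundle),
                    c("encoder", "decoder", "trunk", "head_act",
                      "head_pers", "classifier"))
  for (nm in nets)
    if (!is.null(bundle[[nm]]))
      bundle[[nm]] <- nn_set_params(bundle[[nm]], params, paste0(nm, "."))
  bundle
}

#' Save / load a model bundle
#'
#' The checkpoint is a JSON file: every parameter array and batch-norm
#' running statistic flattened with its dimensions, alongside the encoder
#' spec and any scaler the trainer attached.  Plain text, so checkpoints
#' survive text-only pipelines.
#'
#' @param bundle a `model_bundle`
#' @param path output `.json` path
#' @return `path`, invisibly
#' @export
save_model <- function(bundle, path) {
  ser_net <- function(net) lapply(net, ser_layer)
  ser_layer <- function(l) {
    o <- list(type = l$type, meta = l$meta,
              params = lapply(l$params, function(p)
                list(dim = dim(p) %||% length(p), data = as.numeric(p))))
    if (l$type %in% c("bn", "bn_temporal"))
      o$running <- list(mean = l$state$running_mean,
                        var = l$state$running_var)
    if (l$type %in% c("tcn_block", "resfc_block")) {
      o$sub <- ser_net(l$state$sub)
      if (!is.null(l$state$proj)) o$proj <- ser_layer(l$state$proj)
    }
    o
  }
  nets <- intersect(names(bundle),
                    c("encoder", "decoder", "trunk", "head_act",
                      "head_pers", "classifier"))
  obj <- list(kind = bundle$kind,
              spec = unclass(bundle$spec),
              scaler = bundle$scaler,
              n_classes = bundle$n_classes,
              nets = stats::setNames(lapply(nets, function(nm)
                ser_net(bundle[[nm]])), nets))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  de_layer <- function(o) {
    params <- lapply(o$params, function(p) {
      v <- as.numeric(unlist(p$data))
      d <- unlist(p$dim)
      if (length(d) > 1) dim(v) <- d
      v
    })
    state <- list()
    if (!is.null(o$running))
      state <- list(running_mean = as.numeric(unlist(o$running$mean)),
                    running_var = as.numeric(unlist(o$running$var)))
    l <- nn_layer(o$type, params = params, state = state, meta = o$meta)
    if (!is.null(o$sub)) {
      l$state$sub <- lapply(o$sub, de_layer)
      if (!is.null(o$proj)) l$state$proj <- de_layer(o$proj)
    }
    l
  }
  spec <- obj$spec
  spec$input_shape <- unlist(spec$input_shape)
  spec <- do.call(encoder_spec, spec[c("input_shape", "embedding_dim",
                                       "n_tcn_blocks", "channels_per_block",
                                       "kernel_size", "pool_every",
                                       "hidden_dims")])
  args <- lapply(obj$nets, function(net) lapply(net, de_layer))
  bundle <- do.call(new_model_bundle, c(list(kind = obj$kind, spec = spec),
                                        args))
  if (!is.null(obj$scaler))
    bundle$scaler <- lapply(obj$scaler, function(v) as.numeric(unlist(v)))
  if (!is.null(obj$n_classes)) bundle$n_classes <- as.integer(obj$n_classes)
  bundle
}
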