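#' Network configuration for the multi-task U-Net
#'
#' Describes the shared contracting path (encoder), the segmentation
#' decoder and the classification head. The encoder halves the spatial
#' resolution and multiplies the channel count at each level; the
#' bottleneck feeds both output branches.
#'
#' @param input_size Square input resolution in pixels. Must be divisible
#'   by `2^depth`.
#' @param depth Number of down-sampling levels in the contracting path.
#' @param base_channels Channel count of the first encoder level.
#' @param channel_multiplier Channel growth factor per level (2 gives the
#'   classic doubling).
#' @param seg_classes Number of segmentation output channels (1 = binary
#'   instrument mask).
#' @param cls_classes Number of classification classes (2: no blood
#'   accumulation / blood accumulation).
#' @param hidden_units Width of the hidden dense stage in the
#'   classification head.
#' @param in_channels Input image channels (3 for RGB).
#' @return A `net_config` list.
#' @examples
#' cfg <- net_config(input_size = 64, depth = 3, base_channels = 16)
#' @export
net_config <- function(input_size = 64, depth = 3, base_channels = 16,
                       channel_multiplier = 2, seg_classes = 1,
                       cls_classes = 2, hidden_units = 64, in_channels = 3) {
  if (input_size %% (2^depth) != 0) {
    stop_validation("input_size (%d) must be divisible by 2^depth (%d)",
                    input_size, 2^depth)
  }
  if (depth < 1 || base_channels < 1) {
    stop_validation("depth and base_channels must be positive")
  }
  if (cls_classes != 2) {
    stop_validation("the event-detection head is binary (cls_classes = 2)")
  }
  structure(list(
    input_size = as.integer(input_size),
    depth = as.integer(depth),
    base_channels = as.integer(base_channels),
    channel_multiplier = as.integer(channel_multiplier),
    seg_classes = as.integer(seg_classes),
    cls_classes = as.integer(cls_classes),
    hidden_units = as.integer(hidden_units),
    in_channels = as.integer(in_channels)
  ), class = "net_config")
}

# Ordered layer inventory: name, kind and (in, out) channels. The same list
# drives weight creation, the C++ engine lookup and the parameter count.
layer_plan <- function(config) {
  ch <- config$base_channels * config$channel_multiplier^(seq_len(config$depth) - 1)
  cb <- config$base_channels * config$channel_multiplier^config$depth
  plan <- list()
  cin <- config$in_channels
  for (l in seq_len(config$depth)) {
    plan[[length(plan) + 1]] <- list(name = sprintf("enc%d_conv1", l),
                                     kind = "conv3", cin = cin, cout = ch[l])
    plan[[length(plan) + 1]] <- list(name = sprintf("enc%d_conv2", l),
                                     kind = "conv3", cin = ch[l], cout = ch[l])
    cin <- ch[l]
  }
  plan[[length(plan) + 1]] <- list(name = "bott_conv1", kind = "conv3",
                                   cin = ch[config$depth], cout = cb)
  plan[[length(plan) + 1]] <- list(name = "bott_conv2", kind = "conv3",
                                   cin = cb, cout = cb)
  below <- cb
  for (l in rev(seq_len(config$depth))) {
    plan[[length(plan) + 1]] <- list(name = sprintf("up%d", l), kind = "tconv2",
                                     cin = below, cout = ch[l])
    plan[[length(plan) + 1]] <- list(name = sprintf("dec%d_conv1", l),
                                     kind = "conv3", cin = 2 * ch[l], cout = ch[l])
    plan[[length(plan) + 1]] <- list(name = sprintf("dec%d_conv2", l),
                                     kind = "conv3", cin = ch[l], cout = ch[l])
    below <- ch[l]
  }
  plan[[length(plan) + 1]] <- list(name = "seg_out", kind = "conv1",
                                   cin = ch[1], cout = config$seg_classes)
  plan[[length(plan) + 1]] <- list(name = "cls_fc1", kind = "dense",
                                   cin = cb, cout = config$hidden_units)
  plan[[length(plan) + 1]] <- list(name = "cls_fc2", kind = "dense",
                                   cin = config$hidden_units,
                                   cout = config$cls_classes)
  plan
}

kernel_taps <- function(kind) switch(kind, conv3 = 9L, tconv2 = 4L, conv1 = 1L,
                                     dense = 1L)

#' Build a multi-task U-Net with randomly initialised weights
#'
#' Creates the network described by a [net_config()]: a shared contracting
#' path (two 3x3 convolutions + ReLU per level, 2x2 max pooling, channels
#' multiplied per level), a segmentation branch (U-Net expansive path with
#' skip connections from matching encoder levels, 2x2 transposed-convolution
#' up-sampling, terminating in a 1-channel sigmoid map), and a
#' classification branch that global-average-pools the bottleneck feature
#' map through one hidden dense stage into a 2-way softmax.
#'
#' Weights use He-normal initialisation scaled by the kernel fan-in.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mtl_net` with elements `config` and
#'   `weights`.
#' @examples
#' net <- build_network(net_config(input_size = 16, depth = 1,
#'                                 base_channels = 4), seed = 1)
#' print(net)
#' @export
build_network <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  plan <- layer_plan(config)
  weights <- with_seed(seed, {
    out <- list()
    for (ly in plan) {
      fan_in <- kernel_taps(ly$kind) * ly$cin
      sd0 <- sqrt(2 / fan_in)
      out[[ly$name]] <- list(
        W = matrix(rnorm(ly$cout * kernel_taps(ly$kind) * ly$cin, sd = sd0),
                   nrow = ly$cout),
        b = numeric(ly$cout)
      )
    }
    out
  })
  structure(list(config = config, weights = weights), class = "mtl_net")
}

#' Number of trainable parameters
#'
#' @param net An `mtl_net`.
#' @return Integer parameter count (weights + biases over all layers).
#' @export
n_params <- function(net) {
  sum(vapply(net$weights, function(l) length(l$W) + length(l$b), numeric(1)))
}

engine_cfg <- function(config) {
  list(input_size = config$input_size, depth = config$depth,
       base_channels = config$base_channels,
       channel_multiplier = config$channel_multiplier,
       in_channels = config$in_channels, hidden_units = config$hidden_units)
}

#' Forward pass of the multi-task network
#'
#' Runs one inference pass over the shared encoder and both branches.
#'
#' @param net An `mtl_net`.
#' @param image An `H x W x 3` array in `[0, 1]`, or an `H x W x 3 x N`
#'   batch. `H` and `W` must equal `config$input_size`.
#' @return For a single image, a list with `seg_prob` (`H x W` matrix of
#'   instrument probabilities) and `cls_prob` (length-2 vector
#'   `(p_no_blood, p_blood)` summing to 1). For a batch, `seg_prob` is
#'   `H x W x N` and `cls_prob` a `2 x N` matrix.
#' @export
forward <- function(net, image) {
  stopifnot(inherits(net, "mtl_net"))
  d <- dim(image)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop_validation("image must be an H x W x 3 (x N) array")
  }
  s <- net$config$input_size
  if (d[1] != s || d[2] != s || d[3] != net$config$in_channels) {
    stop_validation("image dims (%s) do not match the network input %dx%dx%d",
                    paste(d, collapse = "x"), s, s, net$config$in_channels)
  }
  single <- length(d) == 3L
  out <- eng_forward(net$weights, engine_cfg(net$config), image)
  if (single) {
    list(seg_prob = out$seg[, , 1], cls_prob = as.numeric(out$cls[, 1]))
  } else {
    list(seg_prob = out$seg, cls_prob = out$cls)
  }
}

#' @rdname forward
#' @param object,newdata,... Standard predict arguments; `newdata` is the
#'   image (batch) passed to [forward()].
#' @export
predict.mtl_net <- function(object, newdata, ...) forward(object, newdata)

#' @export
print.mtl_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Multi-task U-Net: %dx%dx%d input, depth %d, base %d channels\n",
    cfg$input_size, cfg$input_size, cfg$in_channels, cfg$depth,
    cfg$base_channels))
  cat(sprintf("  %d layers, %s trainable parameters\n", length(x$weights),
              format(n_params(x), big.mark = ",")))
  cat("  branches: segmentation (sigmoid map), event detection (2-way softmax)\n")
  invisible(x)
}

#' Save or load a network checkpoint
#'
#' Checkpoints are single files holding a format version, the network
#' configuration and all weights.
#'
#' @param net An `mtl_net`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()` returns the restored `mtl_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "mtl_net"))
  obj <- list(format = "bleedwatch-checkpoint", version = 1L,
              config = net$config, weights = net$weights)
  tryCatch(saveRDS(obj, path),
           error = function(e) stop_io("cannot write checkpoint: %s",
                                       conditionMessage(e)))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_io("checkpoint not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "bleedwatch-checkpoint")) {
    stop_io("not a bleedwatch checkpoint: %s", path)
  }
  structure(list(config = obj$config, weights = obj$weights),
            class = "mtl_net")
}
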