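# The pooling-free dilated-bank network ("flat" architecture).
#
# Topology, preserving spatial dimensions everywhere (same-size padding,
# stride 1, no pooling/up-down-sampling/fully-connected layers):
#   L1: 5 parallel branches, each a 9x9 convolution at its dilation rate
#   L2: a second consecutive 9x9 convolution per branch, same rate
#   L3: channel concatenation of the branch outputs
#   L4: 5x5 convolution; L5, L6: 1x1 convolutions       (all ReLU)
#   L7: 1x1 convolution, tanh, one channel per predicted heat-map
# Loss: mean absolute error against the target heat-map channels.
# The 21 landmarks are partitioned across 5 such networks (5 outputs each
# at most), keeping the concatenated L3 tensor at a practical size.

#' Network configuration
#'
#' @param input_channels number of input channels (3: grayscale RGB by
#'   channel repetition).
#' @param dilation_rates exactly five positive integers, one per branch of
#'   the 9x9 bank; the default \{1, 2, 4, 8, 16\} spans receptive fields
#'   from local detail to near-global context so the image is explored at
#'   different resolutions.
#' @param filters named integer vector `c(f1, f2, f4, f5, f6)`: filters per
#'   branch in L1 and L2, and for L4, L5, L6.
#' @param outputs_per_network heat-map channels per sub-network (default 5).
#' @param kernel_l1_l2,kernel_l4 odd kernel sizes (9 and 5 in the reference
#'   architecture).
#' @return A list of class `flatnet_config`.
#' @export
flatnet_config <- function(input_channels = 3L,
                           dilation_rates = c(1L, 2L, 4L, 8L, 16L),
                           filters = c(f1 = 32L, f2 = 64L, f4 = 128L,
                                       f5 = 128L, f6 = 64L),
                           outputs_per_network = 5L,
                           kernel_l1_l2 = 9L, kernel_l4 = 5L) {
  if (length(dilation_rates) != 5L)
    stop("exactly 5 dilation rates are required (one per branch)")
  if (any(dilation_rates < 1) || any(dilation_rates != round(dilation_rates)))
    stop("dilation rates must be positive integers")
  need <- c("f1", "f2", "f4", "f5", "f6")
  if (!all(need %in% names(filters)))
    stop("filters must be named c(f1=, f2=, f4=, f5=, f6=)")
  filters <- filters[need]
  if (any(filters < 1)) stop("all filter counts must be >= 1")
  if (kernel_l1_l2 %% 2 != 1 || kernel_l4 %% 2 != 1 ||
      kernel_l1_l2 < 1 || kernel_l4 < 1)
    stop("kernel sizes must be odd positive integers")
  if (outputs_per_network < 1) stop("outputs_per_network must be >= 1")
  structure(list(input_channels = as.integer(input_channels),
                 dilation_rates = as.integer(dilation_rates),
                 filters = vapply(filters, as.integer, integer(1)),
                 outputs_per_network = as.integer(outputs_per_network),
                 kernel_l1_l2 = as.integer(kernel_l1_l2),
                 kernel_l4 = as.integer(kernel_l4)),
            class = "flatnet_config")
}

#' Partition the landmark schema across sub-networks
#'
#' Greedy split in schema order into `ceiling(21 / max_per_network)`
#' groups; the default of at most 5 heat-maps per network yields 5 groups
#' of sizes 5, 5, 5, 5, 1 (and at most 3 per network yields 7 groups, the
#' split used by three-output architectures).
#'
#' @param schema a [landmark_schema()].
#' @param max_per_network maximum heat-map channels per sub-network.
#' @return List of character vectors of landmark abbreviations.
#' @export
partition_landmarks <- function(schema = landmark_schema(),
                                max_per_network = 5L) {
  stopifnot(max_per_network >= 1)
  ab <- schema$abbrev
  split(ab, ceiling(seq_along(ab) / max_per_network))
}

#' Closed-form trainable-parameter count
#'
#' Sums weight and bias counts over all layers:
#' \deqn{\sum_b (k_1^2 c_{in} f_1 + f_1 + k_1^2 f_1 f_2 + f_2)
#'   + (k_4^2 \cdot n_b f_2 \cdot f_4 + f_4) + (f_4 f_5 + f_5)
#'   + (f_5 f_6 + f_6) + (f_6 K + K)}
#' for `n_b` branches and `K` output channels.
#'
#' @param config a [flatnet_config()].
#' @param n_outputs output channels `K`; defaults to
#'   `config$outputs_per_network`.
#' @return Integer parameter count for one sub-network.
#' @export
flatnet_param_formula <- function(config, n_outputs = config$outputs_per_network) {
  f <- as.numeric(config$filters)
  names(f) <- names(config$filters)
  nb <- length(config$dilation_rates)
  k1 <- config$kernel_l1_l2^2; k4 <- config$kernel_l4^2
  cin <- config$input_channels
  K <- n_outputs
  nb * (k1 * cin * f["f1"] + f["f1"] + k1 * f["f1"] * f["f2"] + f["f2"]) +
    (k4 * (nb * f["f2"]) * f["f4"] + f["f4"]) +
    (f["f4"] * f["f5"] + f["f5"]) +
    (f["f5"] * f["f6"] + f["f6"]) +
    (f["f6"] * K + K) -> total
  unname(total)
}

# internal: He-initialized weight list in the fixed C++ ordering
init_weights <- function(config, n_outputs, seed = 1L) {
  f <- config$filters
  nb <- length(config$dilation_rates)
  k1 <- config$kernel_l1_l2^2; k4 <- config$kernel_l4^2
  with_seed(seed, {
    he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
    w <- list()
    for (b in seq_len(nb)) {
      w[[length(w) + 1L]] <- he(k1 * config$input_channels, f["f1"])
      w[[length(w) + 1L]] <- matrix(0, 1, f["f1"])
      w[[length(w) + 1L]] <- he(k1 * f["f1"], f["f2"])
      w[[length(w) + 1L]] <- matrix(0, 1, f["f2"])
    }
    w[[length(w) + 1L]] <- he(k4 * nb * f["f2"], f["f4"])
    w[[length(w) + 1L]] <- matrix(0, 1, f["f4"])
    w[[length(w) + 1L]] <- he(f["f4"], f["f5"])
    w[[length(w) + 1L]] <- matrix(0, 1, f["f5"])
    w[[length(w) + 1L]] <- he(f["f5"], f["f6"])
    w[[length(w) + 1L]] <- matrix(0, 1, f["f6"])
    # tanh output layer: small init so the initial output is near zero
    # everywhere, matching the heat-map background. A large-scale output
    # init triggers a violent background-suppression phase under the MAE
    # sign gradient whose uniform weight drift can kill entire upstream
    # ReLU banks (all-positive inputs make a whole filter's pre-activation
    # go negative at every pixel simultaneously).
    w[[length(w) + 1L]] <- matrix(rnorm(f["f6"] * n_outputs, 0,
                                        0.1 * sqrt(1 / f["f6"])),
                                  f["f6"], n_outputs)
    w[[length(w) + 1L]] <- matrix(0, 1, n_outputs)
    w
  })
}

#' Build one sub-network
#'
#' Instantiates the weight tensors of a single heat-map generator network
#' for `n_outputs` landmark channels.
#'
#' @param config a [flatnet_config()].
#' @param n_outputs number of output heat-map channels.
#' @param seed initialization seed.
#' @return A list of class `flatnet_net` with elements `weights` (ordered
#'   weight/bias matrices), `config`, `n_outputs`.
#' @export
build_flatnet <- function(config = flatnet_config(),
                          n_outputs = config$outputs_per_network, seed = 1L) {
  stopifnot(inherits(config, "flatnet_config"), n_outputs >= 1)
  structure(list(weights = init_weights(config, n_outputs, seed),
                 config = config, n_outputs = as.integer(n_outputs)),
            class = "flatnet_net")
}

#' Count trainable parameters of a built network
#'
#' @param network a `flatnet_net` (or a `flatnet_localizer`, in which case
#'   counts are summed over its sub-networks).
#' @return Total number of trainable scalars.
#' @export
count_parameters <- function(network) {
  if (inherits(network, "flatnet_localizer"))
    return(sum(vapply(network$nets, count_parameters, numeric(1))))
  stopifnot(inherits(network, "flatnet_net"))
  sum(vapply(network$weights, length, numeric(1)))
}

#' Layer-by-layer description of a built network
#'
#' Walks the network and reports every layer's type, kernel size, dilation
#' rate, stride, padding, activation and channel counts — the basis of the
#' architecture audit (no pooling, striding, up/down-sampling or fully
#' connected layers anywhere; spatial dimensions preserved throughout).
#'
#' @param network a `flatnet_net`.
#' @return data.frame with one row per layer.
#' @export
network_layers <- function(network) {
  stopifnot(inherits(network, "flatnet_net"))
  cfg <- network$config
  f <- cfg$filters; nb <- length(cfg$dilation_rates)
  rows <- list()
  for (b in seq_len(nb)) {
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "L1", branch = b, type = "conv", kernel = cfg$kernel_l1_l2,
      dilation = cfg$dilation_rates[b], stride = 1L, padding = "same",
      activation = "relu", in_channels = cfg$input_channels,
      out_channels = unname(f["f1"]))
    rows[[length(rows) + 1L]] <- data.frame(
      layer = "L2", branch = b, type = "conv", kernel = cfg$kernel_l1_l2,
      dilation = cfg$dilation_rates[b], stride = 1L, padding = "same",
      activation = "relu", in_channels = unname(f["f1"]),
      out_channels = unname(f["f2"]))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "L3", branch = NA_integer_, type = "concat", kernel = NA_integer_,
    dilation = NA_integer_, stride = 1L, padding = "same", activation = "none",
    in_channels = unname(f["f2"]) * nb, out_channels = unname(f["f2"]) * nb)
  lin <- function(layer, k, nin, nout, act) data.frame(
    layer = layer, branch = NA_integer_, type = "conv", kernel = k,
    dilation = 1L, stride = 1L, padding = "same", activation = act,
    in_channels = nin, out_channels = nout)
  rows[[length(rows) + 1L]] <- lin("L4", cfg$kernel_l4, unname(f["f2"]) * nb,
                                   unname(f["f4"]), "relu")
  rows[[length(rows) + 1L]] <- lin("L5", 1L, unname(f["f4"]), unname(f["f5"]), "relu")
  rows[[length(rows) + 1L]] <- lin("L6", 1L, unname(f["f5"]), unname(f["f6"]), "relu")
  rows[[length(rows) + 1L]] <- lin("L7", 1L, unname(f["f6"]), network$n_outputs, "tanh")
  do.call(rbind, rows)
}

# internal: image matrix (0-255) -> HW x 3 input in [0, 1], column-major
# within the frame (pixel index = row + col * rows, 0-based)
prep_input <- function(image) {
  v <- as.numeric(image) / 255
  matrix(rep(v, 3L), ncol = 3L)
}

#' Run one sub-network on an image
#'
#' @param network a `flatnet_net`.
#' @param image numeric matrix (rows x cols, 0-255) or a prepared
#'   HW x 3 input matrix in \[0, 1\].
#' @param image_size required when `image` is already a prepared matrix.
#' @return rows x cols x K array of predicted heat-map channels (tanh
#'   outputs, in (-1, 1)).
#' @export
flatnet_forward <- function(network, image, image_size = dim(image)) {
  stopifnot(inherits(network, "flatnet_net"))
  X <- if (is.matrix(image) && ncol(image) == 3L &&
           nrow(image) == prod(image_size)) image else prep_input(image)
  out <- fn_forward(network$weights, X, image_size[1], image_size[2],
                    network$config$dilation_rates,
                    network$config$kernel_l1_l2, network$config$kernel_l4)
  array(out, dim = c(image_size[1], image_size[2], network$n_outputs))
}

#' @export
print.flatnet_net <- function(x, ...) {
  cat(sprintf("<flatnet_net> %d branches (dilations %s), %d outputs, %s parameters\n",
              length(x$config$dilation_rates),
              paste(x$config$dilation_rates, collapse = "/"),
              x$n_outputs, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
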