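# Model fitting: trains one sub-network per partition group with Adam on
# the mean-absolute-error heat-map loss, with a 5% validation split and
# plateau-based early stopping.

#' Training control parameters
#'
#' @param max_epochs maximum training epochs per sub-network.
#' @param batch_size mini-batch size.
#' @param validation_fraction fraction of the training items randomly set
#'   aside for validation and learning-curve tracking (default 0.05).
#' @param plateau_patience stop when the validation loss has not improved
#'   by at least `plateau_min_delta` for this many consecutive epochs.
#' @param plateau_min_delta minimum improvement counting as progress.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param seed RNG seed for initialization, the validation split and batch
#'   shuffling.
#' @param target_scale `"unit"` keeps targets in \[0, 1\] against the tanh
#'   output; `"symmetric"` rescales them to \[-1, 1\].
#' @return A list of class `train_control`.
#' @export
train_control <- function(max_epochs = 30L, batch_size = 4L,
                          validation_fraction = 0.05, plateau_patience = 5L,
                          plateau_min_delta = 1e-4, learning_rate = 1e-3,
                          optimizer = "adam", seed = 1L,
                          target_scale = c("unit", "symmetric")) {
  stopifnot(max_epochs >= 1, batch_size >= 1,
            validation_fraction > 0, validation_fraction < 1,
            plateau_patience >= 1, plateau_min_delta >= 0, learning_rate > 0)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_min_delta = plateau_min_delta,
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed),
                 target_scale = match.arg(target_scale)),
            class = "train_control")
}

# internal: Adam optimizer state and update
adam_new <- function(weights) {
  list(m = lapply(weights, function(w) array(0, dim(w))),
       v = lapply(weights, function(w) array(0, dim(w))), t = 0L)
}

adam_update <- function(weights, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(weights)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    weights[[i]] <- weights[[i]] -
      lr * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + eps)
  }
  list(weights = weights, state = state)
}

# internal: heat-map target matrix (HW x K) for one item and one group
group_targets <- function(item, group, codec, target_scale) {
  lms <- item$landmarks[match(group, item$landmarks$abbrev), c("abbrev", "x", "y")]
  hm <- encode_heatmaps(lms, dim(item$image), codec, on_outside = "allow")
  v <- hm$values
  dim(v) <- c(prod(dim(item$image)), length(group))
  if (target_scale == "symmetric") v <- 2 * v - 1
  v
}

#' Fit the heat-map landmark localizer
#'
#' Trains one sub-network per partition group on (3-channel image, target
#' heat-map stack) pairs under the mean-absolute-error loss. A fraction of
#' the items (default 5%) is randomly set aside per training session for
#' validation; training stops at `max_epochs` or when the validation loss
#' reaches a plateau.
#'
#' @param corpus non-empty list of [annotated_image()] objects, all of the
#'   same pixel dimensions (typically an augmented corpus).
#' @param partition list of landmark-abbreviation groups; defaults to
#'   [partition_landmarks()] with the config's `outputs_per_network`.
#' @param config a [flatnet_config()].
#' @param control a [train_control()].
#' @param codec a [codec_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `flatnet_localizer` with per-group trained
#'   networks and training histories.
#' @seealso [predict.flatnet_localizer()]
#' @export
flatnet_fit <- function(corpus, partition = NULL, config = flatnet_config(),
                        control = train_control(), codec = codec_config(),
                        verbose = FALSE) {
  if (!is.list(corpus) || length(corpus) == 0L) stop("corpus must be non-empty")
  schema <- landmark_schema()
  if (is.null(partition))
    partition <- partition_landmarks(schema, config$outputs_per_network)
  covered <- unlist(partition)
  if (!setequal(covered, schema$abbrev) || anyDuplicated(covered))
    stop("partition groups must disjointly cover all 21 landmarks")
  dims <- dim(corpus[[1]]$image)
  same <- vapply(corpus, function(it) identical(dim(it$image), dims), logical(1))
  if (!all(same)) stop("all corpus images must share the same dimensions")
  for (it in corpus) check_landmarks(it$landmarks[, c("abbrev", "x", "y")], schema)

  n <- length(corpus)
  inputs <- lapply(corpus, function(it) prep_input(it$image))

  nets <- vector("list", length(partition))
  history <- vector("list", length(partition))
  validation <- vector("list", length(partition))
  names(nets) <- names(history) <- names(validation) <-
    paste0("net", seq_along(partition))

  for (g in seq_along(partition)) {
    group <- partition[[g]]
    targets <- lapply(corpus, group_targets, group = group, codec = codec,
                      target_scale = control$target_scale)
    splits <- with_seed(control$seed + g, {
      n_val <- floor(control$validation_fraction * n)
      val <- if (n_val > 0) sample(n, n_val) else integer(0)
      list(val = val, train = setdiff(seq_len(n), val),
           orders = lapply(seq_len(control$max_epochs),
                           function(e) sample(length(setdiff(seq_len(n), val)))))
    })
    tr <- splits$train; val <- splits$val

    # A network whose output has collapsed to a spatially constant map is
    # provably stuck: the ReLU masks zero every gradient below the output
    # biases. Detect that degenerate state after the first epoch and
    # restart from a fresh initialization (it is seed-dependent).
    for (attempt in 0:2) {
      init_seed <- control$seed + g + 1000L * attempt
      net <- build_flatnet(config, n_outputs = length(group), seed = init_seed)
      weights <- net$weights
      state <- adam_new(weights)
      hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                         val_loss = numeric(0))
      best <- Inf; stale <- 0L
      dead <- FALSE
      for (epoch in seq_len(control$max_epochs)) {
        ord <- tr[splits$orders[[epoch]]]
        batch_losses <- c()
        for (start in seq(1, length(ord), by = control$batch_size)) {
          idx <- ord[start:min(start + control$batch_size - 1L, length(ord))]
          step <- fn_step(weights, inputs[idx], targets[idx], dims[1], dims[2],
                          config$dilation_rates, config$kernel_l1_l2,
                          config$kernel_l4)
          upd <- adam_update(weights, step$grads, state, control$learning_rate)
          weights <- upd$weights; state <- upd$state
          batch_losses <- c(batch_losses, step$loss)
        }
        val_loss <- if (length(val)) {
          mean(vapply(val, function(i) {
            out <- fn_forward(weights, inputs[[i]], dims[1], dims[2],
                              config$dilation_rates, config$kernel_l1_l2,
                              config$kernel_l4)
            mean(abs(out - targets[[i]]))
          }, numeric(1)))
        } else NA_real_
        hist <- rbind(hist, data.frame(epoch = epoch,
                                       train_loss = mean(batch_losses),
                                       val_loss = val_loss))
        if (verbose)
          message(sprintf("net %d (%s) epoch %d: train %.5f val %s",
                          g, paste(group, collapse = ","), epoch,
                          mean(batch_losses),
                          ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
        if (epoch == 1L && attempt < 2L) {
          probe <- fn_forward(weights, inputs[[tr[1]]], dims[1], dims[2],
                              config$dilation_rates, config$kernel_l1_l2,
                              config$kernel_l4)
          ranges <- apply(probe, 2, function(ch) diff(range(ch)))
          if (max(ranges) < 1e-7) {
            dead <- TRUE
            if (verbose)
              message(sprintf(
                "net %d: output collapsed to a constant map; restarting (attempt %d)",
                g, attempt + 1L))
            break
          }
        }
        if (!is.na(val_loss)) {
          if (best - val_loss >= control$plateau_min_delta) {
            best <- val_loss; stale <- 0L
          } else {
            stale <- stale + 1L
            if (stale >= control$plateau_patience) break
          }
        }
      }
      if (!dead) break
    }
    net$weights <- weights
    nets[[g]] <- net
    history[[g]] <- hist
    validation[[g]] <- val
    rm(targets); gc(verbose = FALSE)
  }
  fn_release_workspace()

  structure(list(nets = nets, partition = partition, config = config,
                 control = control, codec = codec, history = history,
                 validation = validation, input_size = dims, schema = schema,
                 n_train = n),
            class = "flatnet_localizer")
}

#' Predict landmark coordinates on new images
#'
#' Runs every sub-network, concatenates the predicted heat-map channels in
#' partition order, decodes each channel by argmax, and reassembles a full
#' 21-point landmark set in schema order.
#'
#' @param object a fitted `flatnet_localizer`.
#' @param newdata a numeric image matrix (rows x cols, 0-255), an
#'   [annotated_image()], or a list of either.
#' @param ... unused.
#' @return A landmark data.frame (`abbrev`, `x`, `y`) for a single image,
#'   or a list of them for a list input.
#' @export
predict.flatnet_localizer <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, "annotated_image"))
    return(lapply(newdata, function(im) predict(object, im)))
  img <- if (inherits(newdata, "annotated_image")) newdata$image else newdata
  stopifnot(is.matrix(img))
  if (!identical(dim(img), object$input_size))
    stop(sprintf("image is %dx%d but the localizer was trained on %dx%d",
                 nrow(img), ncol(img), object$input_size[1], object$input_size[2]))
  X <- prep_input(img)
  preds <- lapply(seq_along(object$nets), function(g) {
    vals <- flatnet_forward(object$nets[[g]], X, object$input_size)
    decode_heatmaps(structure(list(values = vals,
                                   channels = object$partition[[g]]),
                              class = "heatmap_stack"))
  })
  all <- do.call(rbind, preds)
  all <- all[match(object$schema$abbrev, all$abbrev), c("abbrev", "x", "y")]
  rownames(all) <- NULL
  all
}

#' @export
print.flatnet_localizer <- function(x, ...) {
  sizes <- vapply(x$partition, length, integer(1))
  epochs <- vapply(x$history, nrow, integer(1))
  cat(sprintf("<flatnet_localizer> %d sub-networks (%s landmarks), input %dx%d\n",
              length(x$nets), paste(sizes, collapse = "+"),
              x$input_size[1], x$input_size[2]))
  cat(sprintf("  parameters: %s total (%s per 5-output net)\n",
              format(count_parameters(x), big.mark = ","),
              format(count_parameters(x$nets[[1]]), big.mark = ",")))
  cat(sprintf("  trained on %d items; epochs per net: %s\n",
              x$n_train, paste(epochs, collapse = ", ")))
  invisible(x)
}

#' @export
summary.flatnet_localizer <- function(object, ...) {
  final <- lapply(seq_along(object$history), function(g) {
    h <- object$history[[g]]
    data.frame(net = g,
               landmarks = paste(object$partition[[g]], collapse = ","),
               epochs = nrow(h),
               final_train_loss = h$train_loss[nrow(h)],
               final_val_loss = h$val_loss[nrow(h)])
  })
  out <- list(networks = do.call(rbind, final),
              parameters = count_parameters(object),
              input_size = object$input_size)
  class(out) <- "summary.flatnet_localizer"
  out
}

#' @export
print.summary.flatnet_localizer <- function(x, ...) {
  cat(sprintf("Localizer: %s trainable parameters, input %dx%d\n",
              format(x$parameters, big.mark = ","),
              x$input_size[1], x$input_size[2]))
  print(x$networks, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.flatnet_localizer <- function(object, ...) {
  lapply(object$nets, function(n) n$weights)
}

#' Plot training and validation loss curves
#'
#' @param x a fitted `flatnet_localizer`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.flatnet_localizer <- function(x, ...) {
  hs <- x$history
  losses <- do.call(cbind, lapply(hs, function(h) {
    n <- max(vapply(hs, nrow, integer(1)))
    cbind(train = c(h$train_loss, rep(NA, n - nrow(h))),
          val = c(h$val_loss, rep(NA, n - nrow(h))))
  }))
  matplot(losses, type = "l", xlab = "epoch", ylab = "MAE loss",
          main = "Training history", ...)
  legend("topright", legend = paste0(rep(names(hs), each = 2),
                                     c(" train", " val")),
         lty = seq_len(ncol(losses)), col = seq_len(ncol(losses)), cex = 0.7)
  invisible(x)
}
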