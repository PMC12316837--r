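# Model fitting: the convolutional encoder-decoder trained on differential
# scattered-field tensors with binary cross-entropy, SGD with momentum and
# a continuous exponential learning-rate decay.

#' Training control parameters
#'
#' Defaults: binary cross-entropy,
#' SGD with momentum 0.8, initial learning rate 0.01 decaying by a factor
#' 10 over one full training run (`eta(t) = eta0 * r^(t/v)` with
#' `v = floor(epochs * n_train / batch_size)`), batch size 32, 40 epochs.
#'
#' @param epochs number of epochs.
#' @param batch_size minibatch size.
#' @param lr0 initial learning rate.
#' @param decay_rate exponential decay factor `r`.
#' @param momentum SGD momentum.
#' @param bn_momentum running-moment momentum for batch normalisation.
#' @param checkpoint `"best"` keeps the weights with the lowest validation
#'   loss; `"final"` keeps the last epoch.
#' @param seed seed for initialisation and data order.
#' @param verbose print per-epoch progress.
#' @return list of class `train_control`.
#' @export
train_control <- function(epochs = 40, batch_size = 32, lr0 = 0.01,
                          decay_rate = 0.1, momentum = 0.8,
                          bn_momentum = 0.9,
                          checkpoint = c("best", "final"), seed = 1L,
                          verbose = FALSE) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(epochs >= 0, batch_size >= 1, lr0 > 0, decay_rate > 0,
            momentum >= 0, momentum < 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr0 = lr0,
                 decay_rate = decay_rate, momentum = momentum,
                 bn_momentum = bn_momentum, checkpoint = checkpoint,
                 seed = seed, verbose = verbose),
            class = "train_control")
}

#' Learning rate at a training step
#'
#' Continuous exponential decay `eta(t) = eta0 * r^(t/v)`: one full decade
#' over a complete training run when `v` is the total step count.
#'
#' @param t step index (0-based).
#' @param v decay period in steps.
#' @param lr0 initial learning rate.
#' @param decay_rate decay factor `r`.
#' @return learning rate.
#' @export
lr_at_step <- function(t, v, lr0 = 0.01, decay_rate = 0.1) {
  stopifnot(t >= 0, v >= 1)
  lr0 * decay_rate^(t / v)
}

#' Fit the hotspot detection network
#'
#' Trains the encoder-decoder on the training split of a
#' [generate_dataset()] result (inputs noised at the dataset's SNR_train
#' and scaled by the stored global standard deviation), monitors the
#' validation split each epoch, and retains the checkpoint selected by the
#' control.
#'
#' @param dataset a `hotspot_dataset`.
#' @param architecture an [architecture_spec()]; when `NULL`, the
#'   full-scale default for a 16-antenna/50-cell problem, otherwise
#'   [design_architecture()] for the dataset's sizes.
#' @param control a [train_control()].
#' @return object of class `hotspot_cnn` with the trained layers, the
#'   architecture, per-epoch `history`, and the normalisation factor.
#' @export
hotspot_cnn <- function(dataset, architecture = NULL,
                        control = train_control()) {
  in_size <- dim(dataset$hot)[1]
  channels <- 2L * dim(dataset$hot)[3]
  out_size <- dim(dataset$labels)[1]
  if (is.null(architecture)) {
    architecture <- if (in_size == 16 && out_size == 50) fullscale_architecture()
    else design_architecture(in_size, out_size)
  }
  layers <- build_network(architecture, in_size, channels, out_size,
                          seed = derive_seed(control$seed, 11))
  tr <- noised_tensors(dataset, dataset$splits$train, dataset$snr_train,
                       noise_tag = 0L)
  va <- noised_tensors(dataset, dataset$splits$val, dataset$snr_train,
                       noise_tag = 0L)
  ns <- dataset$norm_sd
  tr$X <- tr$X / ns; va$X <- va$X / ns
  n_train <- dim(tr$X)[3]
  v <- max(1, floor(control$epochs * n_train / control$batch_size))
  rng <- local_rng(derive_seed(control$seed, 23))
  vel <- NULL
  t_step <- 0
  history <- NULL
  best <- list(loss = Inf, layers = layers)
  for (ep in seq_len(control$epochs)) {
    ord <- rng$sample(n_train)
    nb <- ceiling(n_train / control$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1) * control$batch_size + 1):min(bi * control$batch_size,
                                                         n_train)]
      xb <- tr$X[, , sel, , drop = FALSE]
      yb <- array(as.numeric(tr$Y[, , sel, drop = FALSE]),
                  c(out_size, out_size, length(sel), 1))
      fw <- network_forward(layers, xb, training = TRUE)
      ls <- bce_with_logits(fw$logits, yb)
      grads <- network_backward(layers, fw$caches, ls$dz)
      lr <- lr_at_step(t_step, v, control$lr0, control$decay_rate)
      upd <- sgd_update(layers, grads, fw$caches, vel, lr, control$momentum)
      layers <- upd$layers; vel <- upd$vel
      t_step <- t_step + 1
      ep_loss <- ep_loss + ls$loss * length(sel)
    }
    ep_loss <- ep_loss / n_train
    vm <- eval_tensors(layers, va$X, va$Y)
    history <- rbind(history,
                     data.frame(epoch = ep, lr = lr_at_step(t_step, v,
                                                            control$lr0,
                                                            control$decay_rate),
                                train_loss = ep_loss, val_loss = vm$loss,
                                val_acc = vm$acc))
    if (vm$loss < best$loss) best <- list(loss = vm$loss, layers = layers)
    if (control$verbose)
      message(sprintf("epoch %2d  train loss %.4f  val loss %.4f  val acc %.4f",
                      ep, ep_loss, vm$loss, vm$acc))
  }
  if (control$checkpoint == "best" && control$epochs > 0) layers <- best$layers
  structure(list(layers = layers, architecture = architecture,
                 control = control, history = history, norm_sd = ns,
                 in_size = in_size, channels = channels, out_size = out_size,
                 snr_train = dataset$snr_train, grid = dataset$phantom$tissue$grid),
            class = "hotspot_cnn")
}

# One SGD-with-momentum step (v <- m v - lr g; w <- w + v), plus write-back
# of the batch-norm running moments collected during the forward pass.
sgd_update <- function(layers, grads, caches, vel, lr, momentum) {
  if (is.null(vel)) vel <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (is.null(vel[[i]]))
      vel[[i]] <- list(W = array(0, dim(layers[[i]]$W)),
                       b = numeric(length(layers[[i]]$b)),
                       gamma = if (!is.null(g$dgamma))
                         numeric(length(layers[[i]]$gamma)),
                       beta = if (!is.null(g$dbeta))
                         numeric(length(layers[[i]]$beta)))
    vel[[i]]$W <- momentum * vel[[i]]$W - lr * g$dW
    vel[[i]]$b <- momentum * vel[[i]]$b - lr * g$db
    layers[[i]]$W <- layers[[i]]$W + vel[[i]]$W
    layers[[i]]$b <- layers[[i]]$b + vel[[i]]$b
    if (!is.null(g$dgamma)) {
      vel[[i]]$gamma <- momentum * vel[[i]]$gamma - lr * g$dgamma
      vel[[i]]$beta <- momentum * vel[[i]]$beta - lr * g$dbeta
      layers[[i]]$gamma <- layers[[i]]$gamma + vel[[i]]$gamma
      layers[[i]]$beta <- layers[[i]]$beta + vel[[i]]$beta
      layers[[i]]$run_mean <- caches[[i]]$bn$run_mean
      layers[[i]]$run_var <- caches[[i]]$bn$run_var
    }
  }
  list(layers = layers, vel = vel)
}

# Loss and pixel accuracy of a tensor stack in inference mode.
eval_tensors <- function(layers, X, Y, chunk = 128) {
  n <- dim(X)[3]
  loss <- 0; correct <- 0
  for (s in seq(1, n, chunk)) {
    sel <- s:min(s + chunk - 1, n)
    xb <- X[, , sel, , drop = FALSE]
    yb <- array(as.numeric(Y[, , sel, drop = FALSE]),
                c(dim(Y)[1], dim(Y)[2], length(sel), 1))
    fw <- network_forward(layers, xb, training = FALSE)
    ls <- bce_with_logits(fw$logits, yb)
    loss <- loss + ls$loss * length(yb)
    correct <- correct + sum((ls$p > 0.5) == (yb > 0.5))
  }
  list(loss = loss / (prod(dim(Y))), acc = correct / prod(dim(Y)))
}

#' Predict hotspot probabilities or classes
#'
#' @param object a fitted `hotspot_cnn`.
#' @param newdata input tensor `H x W x C` (single sample) or
#'   `H x W x N x C` (stack), unnormalised (the stored factor is applied).
#' @param type `"prob"` for probability maps, `"class"` for thresholded
#'   binary images.
#' @param alpha decision threshold in (0, 1) for `type = "class"`.
#' @param ... unused.
#' @return `out x out` matrix for a single sample, or `out x out x N`
#'   array.
#' @export
predict.hotspot_cnn <- function(object, newdata, type = c("prob", "class"),
                                alpha = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(alpha > 0, alpha < 1)
  single <- length(dim(newdata)) == 3
  if (single) dim(newdata) <- c(dim(newdata)[1], dim(newdata)[2], 1,
                                dim(newdata)[3])
  d <- dim(newdata)
  if (d[1] != object$in_size || d[4] != object$channels)
    stop("input tensor shape ", paste(d[c(1, 2, 4)], collapse = "x"),
         " does not match the model input ", object$in_size, "x",
         object$in_size, "x", object$channels)
  n <- d[3]
  out <- array(0, c(object$out_size, object$out_size, n))
  for (s in seq(1, n, 128)) {
    sel <- s:min(s + 127, n)
    fw <- network_forward(object$layers,
                          newdata[, , sel, , drop = FALSE] / object$norm_sd,
                          training = FALSE)
    out[, , sel] <- sigmoid(fw$logits)
  }
  if (type == "class") out <- out > alpha
  if (single) out <- out[, , 1]
  out
}

#' Evaluate a fitted model on a dataset split
#'
#' Re-noises the stored clean hot/cold fields at `snr_test` (independent
#' draws from an evaluation stream), predicts, thresholds at `alpha` and
#' scores pixel- and scenario-level metrics against the true labels.
#'
#' @param object a fitted `hotspot_cnn`.
#' @param dataset the `hotspot_dataset` (must carry clean fields).
#' @param split `"train"`, `"val"` or `"test"`.
#' @param snr_test evaluation SNR in dB.
#' @param alpha decision threshold.
#' @param noise_tag integer selecting the evaluation noise stream.
#' @param return_probs attach the probability maps as attribute `probs`.
#' @return a `metrics_report` (see [score_images()] internals): per-sample
#'   accuracy/Dice/danger records plus means.
#' @export
evaluate_hotspots <- function(object, dataset, split = "test",
                              snr_test = dataset$snr_train, alpha = 0.5,
                              noise_tag = 1L, return_probs = FALSE) {
  idx <- dataset$splits[[split]]
  if (is.null(idx)) stop("unknown split '", split, "'")
  te <- noised_tensors(dataset, idx, snr_test, noise_tag = noise_tag)
  probs <- predict(object, te$X)
  rep <- score_images(probs > alpha, te$Y, tumor_mask(dataset$phantom$tissue))
  rep$split <- split; rep$snr_test <- snr_test; rep$alpha <- alpha
  if (return_probs) attr(rep, "probs") <- probs
  rep
}

#' @export
print.hotspot_cnn <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l)
    if (is.null(l$W)) 0 else length(l$W) + length(l$b) +
      length(l$gamma %||% numeric(0)) + length(l$beta %||% numeric(0)),
    numeric(1)))
  cat(sprintf("<hotspot_cnn> %dx%dx%d -> %dx%d, %d parameters\n",
              x$in_size, x$in_size, x$channels, x$out_size, x$out_size,
              as.integer(np)))
  if (!is.null(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs; final train loss %.4f, val loss %.4f, val acc %.4f\n",
                nrow(x$history), h$train_loss, h$val_loss, h$val_acc))
  }
  invisible(x)
}

#' @export
summary.hotspot_cnn <- function(object, ...) {
  print(object)
  print(object$architecture)
  if (!is.null(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.hotspot_cnn <- function(object, ...) {
  lapply(Filter(function(l) !is.null(l$W), object$layers), function(l)
    list(kind = l$kind, W = l$W, b = l$b, gamma = l$gamma, beta = l$beta))
}

#' @export
plot.hotspot_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "binary cross-entropy", ...)
  graphics::legend("topright", c("training", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}
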