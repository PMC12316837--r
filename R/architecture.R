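# Encoder-decoder architecture specification and construction.
#
# The network maps an n_rx x n_tx x 2 n_freq differential-field tensor to a
# probability image on the phantom grid. Constraints honoured by every
# admissible spec: zero-padded (size-preserving) convolutions with odd
# kernels, unpadded (size-increasing) transposed convolutions, nearest-
# neighbour x2 upsampling, no pooling, ReLU + batch normalisation on all
# hidden layers, a 1x1 sigmoid output layer, and a size trace that ends at
# exactly the output grid.

#' Architecture specification
#'
#' @param layers list of layer descriptors, each a list with `kind`
#'   (`"conv"`, `"tconv"`, `"upsample"`, `"output"`) and, for conv/tconv,
#'   `filters`, `kernel` and optional `rep` (repetition count).
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!l$kind %in% c("conv", "tconv", "upsample", "output"))
      stop("layer ", i, ": unknown kind '", l$kind, "'")
    if (l$kind %in% c("conv", "tconv")) {
      stopifnot(l$filters >= 1, l$kernel >= 1)
      if (l$kind == "conv" && l$kernel %% 2 == 0)
        stop("layer ", i, ": size-preserving convolutions need an odd kernel")
    }
  }
  structure(list(layers = layers), class = "architecture_spec")
}

#' Trace spatial sizes through an architecture
#'
#' Applies the size arithmetic (conv: unchanged; transposed conv:
#' `s + k - 1`; upsample: `2 s`; output: unchanged) and checks the final
#' size. Fails naming the offending layer when the trace cannot reach
#' `out_size`.
#'
#' @param spec an [architecture_spec()].
#' @param in_size input spatial size (antenna count).
#' @param out_size required output spatial size (grid size).
#' @return integer vector of sizes after each layer entry.
#' @export
trace_sizes <- function(spec, in_size, out_size) {
  s <- as.integer(in_size)
  trace <- integer(0)
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    s <- switch(l$kind,
                conv = s,
                tconv = s + as.integer(l$kernel) - 1L,
                upsample = 2L * s,
                output = s)
    trace <- c(trace, s)
  }
  if (s != out_size) {
    stop("architecture size trace ", in_size, " -> ",
         paste(trace, collapse = " -> "), " does not end at ", out_size,
         " (last size-changing layer: ",
         max(c(0, which(diff(c(in_size, trace)) != 0))), ")")
  }
  trace
}

#' The default full-scale architecture (16 -> 50)
#'
#' Encoder of three double conv blocks (64, 128, 256 filters, kernel 3), a
#' x2 upsample bridge (16 -> 32), a transposed-convolution decoder with
#' kernels 5, 5, 5, 4, 4 (32 -> 36 -> 40 -> 44 -> 47 -> 50) and filters
#' 256, 128, 64, 32, 16, then the 1x1 sigmoid output layer.
#'
#' @return an [architecture_spec()].
#' @export
fullscale_architecture <- function() {
  architecture_spec(list(
    list(kind = "conv", filters = 64, kernel = 3, rep = 2),
    list(kind = "conv", filters = 128, kernel = 3, rep = 2),
    list(kind = "conv", filters = 256, kernel = 3, rep = 2),
    list(kind = "upsample"),
    list(kind = "tconv", filters = 256, kernel = 5),
    list(kind = "tconv", filters = 128, kernel = 5),
    list(kind = "tconv", filters = 64, kernel = 5),
    list(kind = "tconv", filters = 32, kernel = 4),
    list(kind = "tconv", filters = 16, kernel = 4),
    list(kind = "output")
  ))
}

#' Design an architecture for arbitrary input/output sizes
#'
#' Same family as [fullscale_architecture()] scaled to the given sizes: a
#' double-conv encoder, as many x2 upsamples as fit, then unpadded
#' transposed convolutions (kernel 5, plus one adjusting kernel) to land
#' exactly on `out_size`.
#'
#' @param in_size input spatial size.
#' @param out_size output spatial size.
#' @param base_filters encoder width of the first block.
#' @return an [architecture_spec()].
#' @export
design_architecture <- function(in_size, out_size, base_filters = 16) {
  stopifnot(out_size >= in_size)
  best <- NULL
  for (u in 3:0) {
    s <- in_size * 2^u
    if (s > out_size) next
    rem <- out_size - s
    t5 <- rem %/% 4L
    r <- rem %% 4L
    best <- list(u = u, t5 = t5, extra = if (r > 0) r + 1L else NULL)
    break
  }
  if (is.null(best)) stop("cannot reach ", out_size, " from ", in_size)
  layers <- list(
    list(kind = "conv", filters = base_filters, kernel = 3, rep = 2),
    list(kind = "conv", filters = 2 * base_filters, kernel = 3, rep = 2)
  )
  for (i in seq_len(best$u)) layers <- c(layers, list(list(kind = "upsample")))
  nt <- best$t5 + as.integer(!is.null(best$extra))
  fi <- 0
  dec_filters <- function() {
    fi <<- fi + 1
    max(8, base_filters %/% 2^(fi - 1))
  }
  for (i in seq_len(best$t5))
    layers <- c(layers, list(list(kind = "tconv", filters = dec_filters(),
                                  kernel = 5)))
  if (!is.null(best$extra))
    layers <- c(layers, list(list(kind = "tconv", filters = dec_filters(),
                                  kernel = best$extra)))
  layers <- c(layers, list(list(kind = "output")))
  spec <- architecture_spec(layers)
  trace_sizes(spec, in_size, out_size)
  spec
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec>\n")
  for (l in x$layers) {
    cat("  ", switch(l$kind,
                     conv = sprintf("conv   %4d filters, kernel %d, x%d", l$filters,
                                    l$kernel, l$rep %||% 1),
                     tconv = sprintf("tconv  %4d filters, kernel %d", l$filters,
                                     l$kernel),
                     upsample = "upsample x2",
                     output = "output 1x1 conv + sigmoid"), "\n")
  }
  invisible(x)
}

# Expand the spec into a flat list of primitive layers with initialised
# parameters (He fan-in init, seeded).
build_network <- function(spec, in_size, in_channels, out_size, seed = 1L) {
  trace_sizes(spec, in_size, out_size)
  rng <- local_rng(seed)
  layers <- list()
  cin <- in_channels
  add_convlike <- function(kind, k, cout, activation) {
    fan_in <- k * k * cin
    W <- array(rng$rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)),
               c(k, k, cin, cout))
    l <- list(kind = kind, k = k, cin = cin, cout = cout, W = W,
              b = numeric(cout), activation = activation)
    if (activation == "relu_bn") {
      l$gamma <- rep(1, cout); l$beta <- numeric(cout)
      l$run_mean <- numeric(cout); l$run_var <- rep(1, cout)
    }
    layers[[length(layers) + 1]] <<- l
    cin <<- cout
  }
  for (l in spec$layers) {
    switch(l$kind,
           conv = for (r in seq_len(l$rep %||% 1))
             add_convlike("conv", l$kernel, l$filters, "relu_bn"),
           tconv = add_convlike("tconv", l$kernel, l$filters, "relu_bn"),
           upsample = layers[[length(layers) + 1]] <- list(kind = "upsample"),
           output = add_convlike("conv", 1L, 1L, "sigmoid"))
  }
  layers
}

# Forward pass through the primitive layers. Returns logits plus caches
# when `training` (inference discards them and uses running BN moments).
network_forward <- function(layers, x, training = FALSE) {
  caches <- if (training) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "upsample") {
      x <- upsample2_forward(x)
      next
    }
    cv <- if (l$kind == "conv") conv_forward(x, l$W, l$b)
    else tconv_forward(x, l$W, l$b)
    x <- cv$out
    if (identical(l$activation, "relu_bn")) {
      bn <- bn_forward(x, l$gamma, l$beta, l$run_mean, l$run_var, training)
      rl <- relu_forward(bn$out)
      x <- rl$out
      if (training) caches[[i]] <- list(cv = cv, bn = bn, rl = rl)
    } else if (training) caches[[i]] <- list(cv = cv)
  }
  list(logits = x, caches = caches)
}

# Backward pass; returns gradients parallel to `layers`.
network_backward <- function(layers, caches, dlogits) {
  grads <- vector("list", length(layers))
  d <- dlogits
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$kind == "upsample") {
      d <- upsample2_backward(d)
      next
    }
    ch <- caches[[i]]
    g <- list()
    if (identical(l$activation, "relu_bn")) {
      d <- relu_backward(ch$rl, d)
      bb <- bn_backward(ch$bn, l$gamma, d)
      d <- bb$dx
      g$dgamma <- bb$dgamma; g$dbeta <- bb$dbeta
    }
    cb <- if (l$kind == "conv") conv_backward(ch$cv, l$W, d)
    else tconv_backward(ch$cv, l$W, d)
    d <- cb$dx
    g$dW <- cb$dW; g$db <- cb$db
    grads[[i]] <- g
  }
  grads
}
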