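# Architecture arithmetic and backpropagation correctness.

test_that("size arithmetic: full-scale default ends at 50, bad specs are rejected", {
  tr <- trace_sizes(fullscale_architecture(), 16, 50)
  expect_identical(utils::tail(tr, 1), 50L)
  expect_identical(tr, c(16L, 16L, 16L, 32L, 36L, 40L, 44L, 47L, 50L, 50L))
  bad <- architecture_spec(list(
    list(kind = "conv", filters = 8, kernel = 3, rep = 1),
    list(kind = "upsample"),
    list(kind = "tconv", filters = 8, kernel = 16),
    list(kind = "output")))
  expect_error(trace_sizes(bad, 16, 50), "does not end at 50")
  expect_error(architecture_spec(list(list(kind = "conv", filters = 4,
                                           kernel = 4))), "odd kernel")
})

test_that("transposed convolution grows size by kernel - 1", {
  # (32, kernel 5) -> 36, checked by running the layer itself
  x <- array(rnorm(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  W <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  out <- tconv_forward(x, W, numeric(2))$out
  expect_identical(dim(out), c(36L, 36L, 2L, 2L))
  # and the generic trace agrees for designed architectures
  spec <- design_architecture(4, 24)
  expect_identical(utils::tail(trace_sizes(spec, 4, 24), 1), 24L)
  spec2 <- design_architecture(4, 27)
  expect_identical(utils::tail(trace_sizes(spec2, 4, 27), 1), 27L)
})

test_that("convolution layers match a direct nested-loop evaluation", {
  rng <- hotspotmon:::local_rng(5)
  H <- 5; N <- 2; Cin <- 3; Cout <- 2; k <- 3
  x <- array(rng$rnorm(H * H * N * Cin), c(H, H, N, Cin))
  W <- array(rng$rnorm(k * k * Cin * Cout), c(k, k, Cin, Cout))
  b <- rng$rnorm(Cout)
  got <- conv_forward(x, W, b)$out
  pad <- (k - 1) / 2
  ref <- array(0, c(H, H, N, Cout))
  for (i in 1:H) for (j in 1:H) for (n in 1:N) for (o in 1:Cout) {
    acc <- b[o]
    for (dy in 1:k) for (dx in 1:k) for (c in 1:Cin) {
      ii <- i + dy - 1 - pad; jj <- j + dx - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= H)
        acc <- acc + x[ii, jj, n, c] * W[dy, dx, c, o]
    }
    ref[i, j, n, o] <- acc
  }
  expect_equal(got, ref, tolerance = 1e-12)

  gotT <- tconv_forward(x, W, b)$out
  refT <- array(0, c(H + k - 1, H + k - 1, N, Cout))
  for (i in 1:H) for (j in 1:H) for (n in 1:N) for (o in 1:Cout)
    for (dy in 1:k) for (dx in 1:k) for (c in 1:Cin)
      refT[i + dy - 1, j + dx - 1, n, o] <-
        refT[i + dy - 1, j + dx - 1, n, o] + x[i, j, n, c] * W[dy, dx, c, o]
  refT <- refT + rep(b, each = (H + k - 1)^2 * N)
  expect_equal(gotT, refT, tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  spec <- architecture_spec(list(
    list(kind = "conv", filters = 3, kernel = 3, rep = 1),
    list(kind = "upsample"),
    list(kind = "tconv", filters = 2, kernel = 3),
    list(kind = "output")))
  layers <- build_network(spec, 3, 4, 8, seed = 9)
  rng <- hotspotmon:::local_rng(31)
  x <- array(rng$rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  y <- array(as.numeric(rng$runif(8 * 8 * 2) > 0.7), c(8, 8, 2, 1))
  loss_of <- function(ls) {
    fw <- network_forward(ls, x, training = TRUE)
    bce_with_logits(fw$logits, y)$loss
  }
  fw <- network_forward(layers, x, training = TRUE)
  ls <- bce_with_logits(fw$logits, y)
  grads <- network_backward(layers, fw$caches, ls$dz)
  eps <- 1e-5
  for (li in c(1, 3, 4)) {
    for (field in c("W", "b", "gamma", "beta")) {
      if (is.null(layers[[li]][[field]])) next
      gname <- paste0("d", if (field %in% c("W", "b")) field else field)
      # probe a few entries of each parameter tensor
      nn <- length(layers[[li]][[field]])
      probe <- unique(c(1, max(1, nn %/% 2), nn))
      for (p in probe) {
        lp <- layers; lm <- layers
        lp[[li]][[field]][p] <- lp[[li]][[field]][p] + eps
        lm[[li]][[field]][p] <- lm[[li]][[field]][p] - eps
        num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
        ana <- grads[[li]][[gname]][p]
        expect_equal(ana, num, tolerance = 1e-4,
                     label = sprintf("layer %d %s[%d] analytic", li, field, p))
      }
    }
  }
})

test_that("batch normalisation backward matches finite differences through inputs", {
  rng <- hotspotmon:::local_rng(8)
  x <- array(rng$rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gamma <- c(1.3, 0.7); beta <- c(0.1, -0.2)
  dout <- array(rng$rnorm(length(x)), dim(x))
  fw <- bn_forward(x, gamma, beta, numeric(2), rep(1, 2), training = TRUE)
  bk <- bn_backward(fw, gamma, dout)
  eps <- 1e-5
  for (p in c(1, 17, 96)) {
    xp <- x; xm <- x
    xp[p] <- xp[p] + eps; xm[p] <- xm[p] - eps
    fp <- sum(bn_forward(xp, gamma, beta, numeric(2), rep(1, 2), TRUE)$out * dout)
    fm <- sum(bn_forward(xm, gamma, beta, numeric(2), rep(1, 2), TRUE)$out * dout)
    expect_equal(bk$dx[p], (fp - fm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("upsampling doubles sizes and its backward is the adjoint", {
  rng <- hotspotmon:::local_rng(2)
  x <- array(rng$rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  up <- upsample2_forward(x)
  expect_identical(dim(up), c(6L, 6L, 2L, 2L))
  expect_true(all(up[1:2, 1:2, 1, 1] == x[1, 1, 1, 1]))
  # adjoint identity <Ax, y> == <x, A'y>
  y <- array(rng$rnorm(length(up)), dim(up))
  expect_equal(sum(up * y), sum(x * upsample2_backward(y)), tolerance = 1e-10)
})

test_that("inference is deterministic and probabilities lie in (0, 1)", {
  spec <- design_architecture(4, 12, base_filters = 4)
  layers <- build_network(spec, 4, 6, 12, seed = 3)
  x <- array(rnorm(4 * 4 * 2 * 6), c(4, 4, 2, 6))
  p1 <- sigmoid(network_forward(layers, x)$logits)
  p2 <- sigmoid(network_forward(layers, x)$logits)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("threshold nesting: lowering alpha never removes a hotspot pixel", {
  rng <- hotspotmon:::local_rng(44)
  probs <- array(rng$runif(10 * 10 * 4), c(10, 10, 4))
  alphas <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  prev <- NULL
  for (a in alphas) {
    cur <- probs > a
    if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
    prev <- cur
  }
  # alpha -> 1 empties any finite-probability map
  expect_true(all(rowSums(probs > 1 - 1e-12) == 0))
})
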