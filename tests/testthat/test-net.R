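test_that("network geometry matches the multi-timescale design", {
  cfg <- net_config()
  expect_equal(cfg$trunk_depth1, 34L)
  expect_equal(cfg$trunk_depth2, 66L)
  expect_equal(cfg$input_len, 1800L)
  expect_equal(cfg$pooled_len, 600L)
  expect_equal(cfg$head_depth, 16L)
  expect_equal(net_config(context = FALSE)$head_depth, 32L)
  expect_error(net_config(dropout = c(0.5, 1, 0.5)))
  expect_error(net_config(sigmoid_slope = 0))
})

test_that("initialization is seed-deterministic and context-aware", {
  m1 <- net_init(seed = 4)
  m2 <- net_init(seed = 4)
  m3 <- net_init(seed = 5)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$conv1.W, m3$params$conv1.W))
  expect_true("ctx.W" %in% names(m1$params))
  ma <- net_init(net_config(context = FALSE), seed = 4)
  expect_false("ctx.W" %in% names(ma$params))
  expect_equal(ncol(ma$params$fc1.W.1), 32L)
  expect_equal(nrow(ma$params$fc2.W.1), 32L)
})

test_that("attention weights form a recency-ordered probability vector", {
  for (n0 in c(5, 15, 30)) {
    w <- sigmoid_pool_weights(n0, 1.5)
    expect_equal(sum(w), 1)
    expect_true(all(w >= 0))
    expect_false(is.unsorted(w))
    # mass concentrates on the most recent n0 seconds (10 Hz positions)
    expect_gt(sum(w[(600 - 10 * n0 + 1):600]), 0.95)
  }
})

test_that("pooling fixes constant sequences and interpolates recent content", {
  v <- matrix(rep(c(2, -1, 0.5), each = 600), 600)
  expect_equal(sigmoid_pool(v, 15, 1.5), c(2, -1, 0.5))
  expect_error(sigmoid_pool(matrix(0, 100, 2), 5, 1.5), "600")
  # recency: moving signal energy to the end increases the pooled value
  early <- c(rep(1, 100), rep(0, 500))
  late <- c(rep(0, 500), rep(1, 100))
  expect_gt(sigmoid_pool(matrix(late), 5, 1.5),
            sigmoid_pool(matrix(early), 5, 1.5))
})

test_that("the loss vanishes at the target and decomposes per sample", {
  p <- rbind(c(0, 0.5, 1, 0.5), c(1, 1, 0, 0))
  expect_lt(drowsiness_loss(p, p), 1e-6)
  expect_gt(drowsiness_loss(1 - p, p), 1)
  ps <- drowsiness_loss(matrix(0.3, 2, 4), p, per_sample = TRUE)
  expect_length(ps, 2)
  expect_equal(mean(ps), drowsiness_loss(matrix(0.3, 2, 4), p))
  # weights scale the per-timescale terms linearly
  w <- matrix(2, 2, 4)
  expect_equal(drowsiness_loss(matrix(0.3, 2, 4), p, weights = w),
               2 * drowsiness_loss(matrix(0.3, 2, 4), p))
})

test_that("channel swap augmentation is an involution that preserves content", {
  x <- array(rnorm(1800 * 2 * 3), c(1800, 2, 3))
  y <- augment_swap(x)
  expect_equal(augment_swap(y), x)
  expect_equal(y[, 1, ], x[, 2, ])
  expect_equal(sort(as.numeric(y)), sort(as.numeric(x)))
})

test_that("the convolution kernel agrees with a direct computation", {
  set.seed(9)
  Cin <- 3L; Cout <- 4L; L <- 11L; B <- 2L; K <- 5L; pad <- 2L
  M <- matrix(rnorm(Cin * L * B), Cin)
  w <- matrix(rnorm(K * Cin * Cout), K * Cin, Cout)
  b <- rnorm(Cout)
  got <- drowsinet:::conv1d_fwd(M, L, B, w, b, K, pad, FALSE, FALSE)
  want <- matrix(0, Cout, L * B)
  for (s in 1:B) for (l in 1:L) for (co in 1:Cout) {
    acc <- b[co]
    for (cc in 1:Cin) for (k in 1:K) {
      li <- l - pad + k - 1
      if (li >= 1 && li <= L)
        acc <- acc + w[(cc - 1) * K + k, co] * M[cc, (s - 1) * L + li]
    }
    want[co, (s - 1) * L + l] <- acc
  }
  expect_equal(got, want, tolerance = 1e-12)
  relu <- drowsinet:::conv1d_fwd(M, L, B, w, b, K, pad, TRUE, FALSE)
  expect_equal(relu, pmax(want, 0), tolerance = 1e-12)
})

test_that("batch normalization matches the biased-moment formula", {
  set.seed(10)
  M <- matrix(rnorm(5 * 40, 2, 3), 5)
  g <- runif(5, 0.5, 2); b <- rnorm(5)
  out <- drowsinet:::bn_fwd_cpp(M, g, b, numeric(5), rep(1, 5), TRUE)
  mu <- rowMeans(M)
  v <- rowMeans((M - mu)^2)
  expect_equal(as.numeric(out$mu), unname(mu))
  expect_equal(as.numeric(out$v), unname(v))
  expect_equal(out$y, g * (M - mu) / sqrt(v + 1e-5) + b, tolerance = 1e-12)
  expect_equal(as.numeric(out$run_mean), unname(0.1 * mu))
  # inference path uses the supplied running statistics
  inf <- drowsinet:::bn_fwd_cpp(M, g, b, mu, v, FALSE)
  expect_equal(inf$y, out$y, tolerance = 1e-12)
})

test_that("max pooling keeps the largest value and routes its gradient", {
  set.seed(11)
  M <- matrix(rnorm(2 * 12), 2)   # 2 channels, L = 6, B = 2
  mp <- drowsinet:::maxpool1d_fwd(M, 6L, 2L, 3L, 3L)
  expect_equal(dim(mp$y), c(2L, 4L))
  expect_equal(mp$y[1, 1], max(M[1, 1:3]))
  expect_equal(mp$y[2, 4], max(M[2, 10:12]))
  G <- matrix(1, 2, 4)
  gx <- drowsinet:::maxpool1d_bwd(mp$idx, G, 2L, 2L, 6L)
  expect_equal(sum(gx), sum(G))
  expect_true(all(rowSums(matrix(gx != 0, 2)) > 0))
})

test_that("forward inference yields per-timescale probabilities, deterministically", {
  model <- net_init(seed = 2, center = 10)
  set.seed(12)
  x <- array(abs(rnorm(1800 * 2 * 3, 10, 2)), c(1800, 2, 3))
  p1 <- predict_drowsiness(model, x)
  p2 <- predict_drowsiness(model, x)
  expect_equal(dim(p1), c(3L, 4L))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  # a single matrix is promoted to a batch of one
  p3 <- predict_drowsiness(model, x[, , 1])
  expect_equal(unname(p3[1, ]), unname(p1[1, ]), tolerance = 1e-5)
  # the ablated network runs too
  ma <- net_init(net_config(context = FALSE), seed = 2, center = 10)
  expect_equal(dim(predict_drowsiness(ma, x)), c(3L, 4L))
})

test_that("analytic gradients match finite differences in double precision", {
  cfg <- net_config(precision = "double", dropout = c(0, 0, 0))
  model <- net_init(cfg, seed = 8, center = 0)
  set.seed(13)
  x <- array(rnorm(1800 * 2 * 2), c(1800, 2, 2))
  pt <- rbind(c(0, 0.5, 1, 1), c(1, 0, 0.5, 0))
  fw <- drowsinet:::net_fwd(model, x, training = TRUE, keep = TRUE)
  gr <- drowsinet:::net_bwd(model, fw$cache, pt)
  loss_at <- function(m) {
    f <- drowsinet:::net_fwd(m, x, training = TRUE)
    drowsiness_loss(f$phat, pt)
  }
  eps <- 1e-6
  checks <- list(
    c("conv1.W", 3), c("conv1.b", 2), c("bn1.g", 5), c("bn1.b", 1),
    c("conv2.W", 17), c("bn2.g", 9), c("convb.W", 101), c("bnb.g", 40),
    c("ctx.W", 12), c("fc1.W.2", 7), c("fc2.W.4", 3), c("fc2.b.1", 2)
  )
  for (ck in checks) {
    nm <- ck[1]; i <- as.integer(ck[2])
    mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - eps
    fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_lt(abs(fd - gr[[nm]][i]) / (abs(fd) + 1e-4), 1e-3,
              label = paste("gradient of", nm))
  }
})

test_that("stratified epochs draw the quota from every stratum", {
  strata <- list(1:10, 11:20, 21:25, 26:40, 41:44)
  set.seed(14)
  idx <- make_epoch(strata, 6)
  expect_length(idx, 30)
  for (k in 1:5)
    expect_equal(sum(idx %in% strata[[k]]), 6)
  expect_error(make_epoch(list(1:3, integer(0), 1:2, 1:2, 1:2), 4),
               "strata sizes: 3, 0, 2, 2, 2")
})

test_that("dropout masks implement inverted scaling at the configured rates", {
  cfg <- net_config()
  set.seed(15)
  masks <- drowsinet:::make_dropout_masks(cfg, 600L, 8L)
  expect_equal(sort(unique(as.numeric(masks$m1))), c(0, 1 / 0.65))
  expect_equal(sort(unique(as.numeric(masks$m2))), c(0, 1 / 0.3))
  expect_length(masks$m3, 4)
  expect_equal(nrow(masks$m3[[1]]), 32L)   # 16 head + 16 context units
  expect_equal(mean(masks$m1 == 0), 0.35, tolerance = 0.01)
})

test_that("one Adam step reproduces the bias-corrected update", {
  params <- list(w = 1)
  grads <- list(w = 0.5)
  st <- drowsinet:::adam_new(params)
  up <- drowsinet:::adam_step(params, grads, st, lr = 0.1, beta1 = 0.9,
                              beta2 = 0.999)
  mhat <- (0.1 * 0.5) / (1 - 0.9)
  vhat <- (0.001 * 0.25) / (1 - 0.999)
  expect_equal(up$params$w, 1 - 0.1 * mhat / (sqrt(vhat) + 1e-8))
})

test_that("batch extraction slices the trailing minute ending at the frame", {
  s <- list(left_dist = as.numeric(1:4000), right_dist = as.numeric(4001:8000))
  rows <- data.frame(session = c(1, 1), frame = c(1800, 2000))
  x <- drowsinet:::extract_batch(list(s), rows)
  expect_equal(dim(x), c(1800L, 2L, 2L))
  expect_equal(x[, 1, 1], as.numeric(1:1800))
  expect_equal(x[1800, 1, 2], 2000)
  expect_equal(x[1, 2, 2], 4201)
})
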