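#' Configuration of the multi-timescale temporal CNN
#'
#' The network maps a centered 1-min eyelid-distance sequence (1800 x 2 at
#' 30 Hz) to four drowsy-class probabilities, one per timescale. Its trunk is
#' two densely connected temporal convolutions (depth 32, receptive field 15,
#' stride 1, zero padding 7, ReLU then batch normalization) separated by a
#' max pooling (field 3, stride 3), giving sequences of depth 2+32 = 34 and
#' then 34+32 = 66 at length 600 (an effective 10 Hz). Four branches (one
#' per timescale) each apply a temporal convolution (depth 32, field 31,
#' padding 15, no skip), a global pooling -- sigmoid-weighted attention over
#' the most recent `n0` seconds for the 5/15/30-s branches, a plain average
#' for the 60-s branch -- and a two-layer head (16 then 2 units, softmax).
#' A shared "multi-timescale context" (a depth-16 layer over the
#' concatenated pooled features of all branches) is concatenated into each
#' head, coupling the branches.
#'
#' @param sigmoid_slope Slope of the attention weights around the cutoff, in
#'   units of inverse pooled positions (default 1.5). The weights fall off
#'   over roughly `4 / slope` positions (0.4 s at 10 Hz for the default), a
#'   sharp yet smooth transition; very large slopes approach a hard window.
#' @param n0_s Pooling cutoffs (seconds) of the first three branches.
#' @param context Logical; `FALSE` builds the ablated network without the
#'   multi-timescale context, with the first head layer doubled to depth 32
#'   to compensate the lost parameters.
#' @param dropout Dropout probabilities at the three training positions:
#'   after the second trunk concatenation, after each global pooling, and
#'   before each final head layer.
#' @param input_len,input_channels,fps Input geometry.
#' @param precision `"single"` (default) or `"double"` arithmetic for the
#'   convolution kernels; `"double"` is used by the gradient tests.
#' @return An object of class `"net_config"`.
#' @export
net_config <- function(sigmoid_slope = 1.5,
                       n0_s = c(5, 15, 30),
                       context = TRUE,
                       dropout = c(0.35, 0.7, 0.35),
                       input_len = 1800L,
                       input_channels = 2L,
                       fps = 30,
                       precision = c("single", "double")) {
  precision <- match.arg(precision)
  stopifnot(length(dropout) == 3, all(dropout >= 0), all(dropout < 1),
            length(n0_s) == 3, sigmoid_slope > 0)
  structure(list(
    sigmoid_slope = sigmoid_slope, n0_s = n0_s, context = isTRUE(context),
    dropout = dropout, input_len = as.integer(input_len),
    input_channels = as.integer(input_channels), fps = fps,
    # derived geometry
    trunk_depth1 = input_channels + 32L,        # dense concat after conv 1
    trunk_depth2 = input_channels + 32L + 32L,  # dense concat after conv 2
    pooled_len = as.integer(input_len %/% 3),
    head_depth = if (isTRUE(context)) 16L else 32L,
    precision = precision
  ), class = "net_config")
}

#' Sigmoid attention weights over pooled positions
#'
#' Normalized weights `w_n` proportional to
#' `sigmoid(slope * (n - len + rate_hz * n0))` for positions `n = 1..len`
#' (position `len` is the present). The weights sum to one, are
#' nondecreasing in `n`, and concentrate the mass on the most recent `n0`
#' seconds; as `slope` grows they approach a hard window over the last
#' `rate_hz * n0` positions.
#'
#' @param n0 Cutoff time in seconds.
#' @param slope Sigmoid slope (inverse positions).
#' @param len Sequence length (default 600).
#' @param rate_hz Effective rate of the pooled sequence (default 10 Hz).
#' @return Numeric weight vector of length `len`.
#' @export
sigmoid_pool_weights <- function(n0, slope, len = 600L, rate_hz = 10) {
  n <- seq_len(len)
  # midpoint between positions len - rate_hz*n0 and len - rate_hz*n0 + 1, so
  # the large-slope limit is exactly the mean of the last rate_hz*n0 positions
  w <- stats::plogis(slope * (n - len + rate_hz * n0 - 0.5))
  w / sum(w)
}

#' Temporal sigmoid-weighted pooling
#'
#' Collapses a pooled-time sequence to a single feature vector as a convex
#' combination of the per-position feature vectors, with the attention
#' weights of [sigmoid_pool_weights()]. A constant sequence is a fixed
#' point; a large slope recovers the plain mean of the last `10 * n0`
#' positions.
#'
#' @param v Matrix `len x C` (rows = positions, oldest first).
#' @param n0 Cutoff time in seconds.
#' @param slope Sigmoid slope.
#' @param rate_hz Effective sequence rate in Hz (default 10).
#' @return Numeric vector of length `C`.
#' @export
sigmoid_pool <- function(v, n0, slope, rate_hz = 10) {
  v <- as.matrix(v)
  if (nrow(v) != 600) stop("sigmoid_pool expects a sequence of length 600, got ", nrow(v))
  w <- sigmoid_pool_weights(n0, slope, nrow(v), rate_hz)
  as.numeric(crossprod(v, w))
}

#' Multi-timescale relative-entropy loss
#'
#' The average over the four timescales of the binary relative entropy
#' between the ternary target `p` and the estimate `p_hat`:
#' `L = -(1/4) sum_i [ p_i ln(p_hat_i / p_i) + (1-p_i) ln((1-p_hat_i)/(1-p_i)) ]`
#' with the convention `0 ln 0 = 0`. This is the binary cross-entropy minus
#' the target entropy, hence zero exactly when `p_hat = p`. Estimates are
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p_hat Matrix `n x 4` of estimated drowsy probabilities (or a
#'   length-4 vector).
#' @param p Matrix `n x 4` of targets in `{0, 0.5, 1}`.
#' @param weights Optional `n x 4` per-sample, per-timescale weights (the
#'   validation balancing weights).
#' @param per_sample Return the `n` per-sample losses instead of their mean.
#' @return Mean loss (scalar), or per-sample losses.
#' @export
drowsiness_loss <- function(p_hat, p, weights = NULL, per_sample = FALSE) {
  if (is.null(dim(p_hat))) p_hat <- matrix(p_hat, nrow = 1)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  eps <- 1e-7
  q <- pmin(pmax(p_hat, eps), 1 - eps)
  xlogx <- function(a) ifelse(a > 0, a * log(a), 0)
  terms <- -(p * log(q) + (1 - p) * log(1 - q)) + xlogx(p) + xlogx(1 - p)
  if (!is.null(weights)) terms <- terms * weights
  ls <- rowMeans(terms)
  if (per_sample) ls else mean(ls)
}

#' Swap the left and right eyelid-distance channels
#'
#' Data augmentation: exchanging the two eye channels leaves the drowsiness
#' label untouched. Applied at load time with probability 0.5 during
#' training.
#'
#' @param x Matrix `len x 2` (or cube `len x 2 x B`).
#' @return Same shape with the two channels exchanged.
#' @export
augment_swap <- function(x) {
  if (length(dim(x)) == 3) x[, 2:1, , drop = FALSE] else x[, 2:1, drop = FALSE]
}

# ---------------------------------------------------------------------------
# internal layout: activations are channels-first matrices C x (L*B), whose
# column l + L*(s-1) holds the feature vector at position l of sample s.
# The compiled kernels (conv1d_*, maxpool1d_*, bn_*) share this layout, so
# no array permutations happen between layers.

he_init <- function(nin, nout, fan) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)
}

#' Initialize a multi-timescale drowsiness network
#'
#' @param config A [net_config()].
#' @param seed Integer seed for the weight initialization.
#' @param center Input centering constant (the training-set mean eyelid
#'   distance, in pixels); stored with the model.
#' @return An object of class `"drowsinet_model"`.
#' @export
net_init <- function(config = net_config(), seed = 1L, center = 0) {
  Ci <- config$input_channels
  d1 <- config$trunk_depth1
  d2 <- config$trunk_depth2
  hd <- config$head_depth
  withr_seed(seed, {
    params <- list(
      conv1.W = he_init(15 * Ci, 32, 15 * Ci), conv1.b = numeric(32),
      bn1.g = rep(1, 32), bn1.b = numeric(32),
      conv2.W = he_init(15 * d1, 32, 15 * d1), conv2.b = numeric(32),
      bn2.g = rep(1, 32), bn2.b = numeric(32),
      convb.W = he_init(31 * d2, 128, 31 * d2), convb.b = numeric(128),
      bnb.g = rep(1, 128), bnb.b = numeric(128)
    )
    if (config$context) {
      params$ctx.W <- he_init(128, 16, 128)
      params$ctx.b <- numeric(16)
    }
    for (i in 1:4) {
      params[[paste0("fc1.W.", i)]] <- he_init(32, hd, 32)
      params[[paste0("fc1.b.", i)]] <- numeric(hd)
      head_in <- if (config$context) hd + 16L else hd
      params[[paste0("fc2.W.", i)]] <- he_init(head_in, 2, head_in)
      params[[paste0("fc2.b.", i)]] <- numeric(2)
    }
    bn_stats <- list(
      bn1 = list(mean = numeric(32), var = rep(1, 32)),
      bn2 = list(mean = numeric(32), var = rep(1, 32)),
      bnb = list(mean = numeric(128), var = rep(1, 128))
    )
    structure(list(config = config, params = params, bn = bn_stats,
                   center = center, seed = seed),
              class = "drowsinet_model")
  })
}

#' @export
print.drowsinet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<drowsinet_model> %s context, %d parameters, center = %.3f px\n",
              if (x$config$context) "with" else "without", np, x$center))
  invisible(x)
}

# Full forward pass. `x` is a cube (input_len, channels, B) of *raw* eyelid
# distances; centering is applied here. Returns the four drowsy
# probabilities and, when `keep = TRUE`, every intermediate needed by the
# backward pass. Dropout masks (already scaled) are supplied by the caller.
net_fwd <- function(model, x, training = FALSE, masks = NULL, keep = FALSE) {
  cfg <- model$config
  single <- cfg$precision == "single"
  L <- dim(x)[1]; B <- dim(x)[3]
  if (L != cfg$input_len || dim(x)[2] != cfg$input_channels)
    stop("input must be ", cfg$input_len, " x ", cfg$input_channels,
         " per sample, got ", L, " x ", dim(x)[2])
  p <- model$params
  M0 <- matrix(aperm(x, c(2, 1, 3)), dim(x)[2], L * B) - model$center

  A1 <- conv1d_fwd(M0, L, B, p$conv1.W, p$conv1.b, 15L, 7L, TRUE, single)
  B1 <- bn_fwd_cpp(A1, p$bn1.g, p$bn1.b, model$bn$bn1$mean,
                   model$bn$bn1$var, training)
  cat1 <- rbind(M0, B1$y)                            # depth 34
  mp <- maxpool1d_fwd(cat1, L, B, 3L, 3L)            # length 600
  Lp <- cfg$pooled_len

  A2 <- conv1d_fwd(mp$y, Lp, B, p$conv2.W, p$conv2.b, 15L, 7L, TRUE, single)
  B2 <- bn_fwd_cpp(A2, p$bn2.g, p$bn2.b, model$bn$bn2$mean,
                   model$bn$bn2$var, training)
  cat2 <- rbind(mp$y, B2$y)                          # depth 66
  if (!is.null(masks$m1)) cat2 <- cat2 * masks$m1

  Ab <- conv1d_fwd(cat2, Lp, B, p$convb.W, p$convb.b, 31L, 15L, TRUE, single)
  Bb <- bn_fwd_cpp(Ab, p$bnb.g, p$bnb.b, model$bn$bnb$mean,
                   model$bn$bnb$var, training)

  # global pooling: branches 1-3 sigmoid-weighted, branch 4 plain average
  wpool <- cbind(
    sigmoid_pool_weights(cfg$n0_s[1], cfg$sigmoid_slope, Lp),
    sigmoid_pool_weights(cfg$n0_s[2], cfg$sigmoid_slope, Lp),
    sigmoid_pool_weights(cfg$n0_s[3], cfg$sigmoid_slope, Lp),
    rep(1 / Lp, Lp)
  )
  ab <- array(Bb$y, c(128, Lp, B))                   # layout already (C, L, B)
  G <- matrix(0, 128, B)
  for (s in seq_len(B)) {
    pw <- ab[, , s] %*% wpool                        # 128 x 4
    for (i in 1:4) G[blk32(i), s] <- pw[blk32(i), i]
  }
  if (!is.null(masks$m2)) G <- G * masks$m2

  if (cfg$context) {
    zc <- crossprod(p$ctx.W, G) + p$ctx.b
    H <- pmax(zc, 0)
  } else { zc <- NULL; H <- NULL }

  zf1 <- vector("list", 4); u <- vector("list", 4)
  zlog <- vector("list", 4); smax <- vector("list", 4)
  phat <- matrix(0, B, 4)
  for (i in 1:4) {
    zf1[[i]] <- crossprod(p[[paste0("fc1.W.", i)]], G[blk32(i), , drop = FALSE]) +
      p[[paste0("fc1.b.", i)]]
    h <- pmax(zf1[[i]], 0)
    ui <- if (cfg$context) rbind(h, H) else h
    if (!is.null(masks$m3)) ui <- ui * masks$m3[[i]]
    u[[i]] <- ui
    z <- crossprod(p[[paste0("fc2.W.", i)]], ui) + p[[paste0("fc2.b.", i)]]
    z <- z - rep(apply(z, 2, max), each = 2)
    ez <- exp(z)
    s2 <- ez / rep(colSums(ez), each = 2)
    zlog[[i]] <- z; smax[[i]] <- s2
    phat[, i] <- s2[2, ]
  }

  out <- list(phat = phat)
  if (training)
    out$bn <- list(bn1 = list(mean = B1$run_mean, var = B1$run_var,
                              batch_mean = B1$mu, batch_var = B1$v),
                   bn2 = list(mean = B2$run_mean, var = B2$run_var,
                              batch_mean = B2$mu, batch_var = B2$v),
                   bnb = list(mean = Bb$run_mean, var = Bb$run_var,
                              batch_mean = Bb$mu, batch_var = Bb$v))
  if (keep)
    out$cache <- list(M0 = M0, A1 = A1, B1 = B1, mp = mp,
                      A2 = A2, B2 = B2, cat2 = cat2,
                      Ab = Ab, Bb = Bb, wpool = wpool, G = G, zc = zc, H = H,
                      zf1 = zf1, u = u, smax = smax, masks = masks,
                      L = L, Lp = Lp, B = B)
  out
}

blk32 <- function(i) ((i - 1) * 32 + 1):(i * 32)

# Backward pass; returns the gradient of the mean loss over the batch with
# respect to every parameter. `p_target` is B x 4 in {0, 0.5, 1};
# `loss_weights` (B x 4) applies the validation balancing (unused during
# training, where strata already balance the epochs).
net_bwd <- function(model, cache, p_target, loss_weights = NULL) {
  cfg <- model$config
  single <- cfg$precision == "single"
  p <- model$params
  B <- cache$B; Lp <- cache$Lp; L <- cache$L
  g <- list()

  dG <- matrix(0, 128, B)
  dH <- if (cfg$context) matrix(0, 16, B) else NULL
  for (i in 1:4) {
    q <- rbind(1 - p_target[, i], p_target[, i])     # target distribution
    dz <- (cache$smax[[i]] - q) / (4 * B)
    if (!is.null(loss_weights)) dz <- dz * rep(loss_weights[, i], each = 2)
    W2 <- p[[paste0("fc2.W.", i)]]
    g[[paste0("fc2.W.", i)]] <- cache$u[[i]] %*% t(dz)
    g[[paste0("fc2.b.", i)]] <- rowSums(dz)
    du <- W2 %*% dz
    if (!is.null(cache$masks$m3)) du <- du * cache$masks$m3[[i]]
    hd <- cfg$head_depth
    dh <- du[seq_len(hd), , drop = FALSE]
    if (cfg$context) dH <- dH + du[(hd + 1):(hd + 16), , drop = FALSE]
    dzf1 <- dh * (cache$zf1[[i]] > 0)
    g[[paste0("fc1.W.", i)]] <- cache$G[blk32(i), , drop = FALSE] %*% t(dzf1)
    g[[paste0("fc1.b.", i)]] <- rowSums(dzf1)
    dG[blk32(i), ] <- dG[blk32(i), ] + p[[paste0("fc1.W.", i)]] %*% dzf1
  }
  if (cfg$context) {
    dzc <- dH * (cache$zc > 0)
    g$ctx.W <- cache$G %*% t(dzc)
    g$ctx.b <- rowSums(dzc)
    dG <- dG + p$ctx.W %*% dzc
  }
  if (!is.null(cache$masks$m2)) dG <- dG * cache$masks$m2

  # back through the pooling: d a[c, l, s] = dG[c, s] * w_l (branch-wise)
  dab <- array(0, c(128, Lp, B))
  for (i in 1:4) {
    tmp <- outer(dG[blk32(i), , drop = FALSE], cache$wpool[, i])  # 32 x B x Lp
    dab[blk32(i), , ] <- aperm(tmp, c(1, 3, 2))
  }
  dBb <- matrix(dab, 128, Lp * B)
  bb <- bn_relu_bwd_cpp(dBb, cache$Ab, cache$Bb$mu, cache$Bb$sd, p$bnb.g)
  g$bnb.g <- bb$dg; g$bnb.b <- bb$db
  cb <- conv1d_bwd(cache$cat2, Lp, B, p$convb.W, bb$dx, 31L, 15L, TRUE, single)
  g$convb.W <- cb$gw; g$convb.b <- cb$gb

  dcat2 <- cb$gx
  if (!is.null(cache$masks$m1)) dcat2 <- dcat2 * cache$masks$m1
  dmpM <- dcat2[seq_len(nrow(dcat2) - 32), , drop = FALSE]
  dB2 <- dcat2[(nrow(dcat2) - 31):nrow(dcat2), , drop = FALSE]
  b2 <- bn_relu_bwd_cpp(dB2, cache$A2, cache$B2$mu, cache$B2$sd, p$bn2.g)
  g$bn2.g <- b2$dg; g$bn2.b <- b2$db
  c2 <- conv1d_bwd(cache$mp$y, Lp, B, p$conv2.W, b2$dx, 15L, 7L, TRUE, single)
  g$conv2.W <- c2$gw; g$conv2.b <- c2$gb

  dmp <- c2$gx + dmpM
  dcat1 <- maxpool1d_bwd(cache$mp$idx, dmp, Lp, B, L)
  Ci <- cfg$input_channels
  dB1 <- dcat1[(Ci + 1):nrow(dcat1), , drop = FALSE]
  b1 <- bn_relu_bwd_cpp(dB1, cache$A1, cache$B1$mu, cache$B1$sd, p$bn1.g)
  g$bn1.g <- b1$dg; g$bn1.b <- b1$db
  c1 <- conv1d_bwd(cache$M0, L, B, p$conv1.W, b1$dx, 15L, 7L, FALSE, single)
  g$conv1.W <- c1$gw; g$conv1.b <- c1$gb
  g
}

# Dropout masks (inverted scaling), drawn from the current RNG stream.
make_dropout_masks <- function(cfg, Lp, B) {
  pr <- cfg$dropout
  masks <- list()
  d2 <- cfg$trunk_depth2
  if (pr[1] > 0)
    masks$m1 <- matrix(stats::rbinom(d2 * Lp * B, 1, 1 - pr[1]), d2) / (1 - pr[1])
  if (pr[2] > 0)
    masks$m2 <- matrix(stats::rbinom(128 * B, 1, 1 - pr[2]), 128) / (1 - pr[2])
  if (pr[3] > 0) {
    hin <- if (cfg$context) cfg$head_depth + 16L else cfg$head_depth
    masks$m3 <- lapply(1:4, function(i)
      matrix(stats::rbinom(hin * B, 1, 1 - pr[3]), hin) / (1 - pr[3]))
  }
  masks
}

#' Forward inference on a batch of sequences
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' dropout) and returns the four estimated drowsy probabilities per sample.
#'
#' @param model A trained (or initialized) [`drowsinet_model`][net_init].
#' @param x Cube `input_len x channels x B` (a single `input_len x channels`
#'   matrix is promoted to a batch of one) of raw eyelid distances.
#' @param batch_size Internal batch size for large inputs.
#' @return Matrix `B x 4` of drowsy probabilities in `(0, 1)`.
#' @export
predict_drowsiness <- function(model, x, batch_size = 64L) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  B <- dim(x)[3]
  out <- matrix(0, B, 4)
  for (s in seq(1, B, by = batch_size)) {
    e <- min(B, s + batch_size - 1)
    out[s:e, ] <- net_fwd(model, x[, , s:e, drop = FALSE])$phat
  }
  colnames(out) <- paste0("p", 1:4)
  out
}

# -------------------------------------------------------------------------
# training

#' Training configuration for the drowsiness network
#'
#' Adam with the published coefficients; epochs are built by stratified
#' sampling with a fixed per-stratum quota, and the left/right channels are
#' swapped with probability `swap_prob` at load time.
#'
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 0.0016029).
#' @param beta1,beta2 Adam moment coefficients.
#' @param quota Sequences drawn per stratum per epoch (default 256; scaled
#'   experiments use less).
#' @param swap_prob Probability of swapping the two eye channels.
#' @param max_epochs,patience Early-stopping schedule on the weighted
#'   validation loss.
#' @param seed Integer seed governing initialization, sampling, dropout and
#'   augmentation.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(batch_size = 32L, lr = 0.0016029,
                         beta1 = 0.9, beta2 = 0.999,
                         quota = 256L, swap_prob = 0.5,
                         max_epochs = 100L, patience = 10L, seed = 1L) {
  stopifnot(quota > 0, batch_size > 0, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr, beta1 = beta1,
                 beta2 = beta2, quota = as.integer(quota),
                 swap_prob = swap_prob, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Compose one stratified training epoch
#'
#' Draws, with replacement, an equal number of samples from each of the five
#' strata (counts of median RTs at or above 470 ms), then shuffles them.
#' Uses the current RNG stream.
#'
#' @param strata_idx List of five integer vectors: the pool row indices
#'   belonging to strata 0..4.
#' @param quota Samples drawn per stratum.
#' @return Integer vector of `5 * quota` pool row indices.
#' @export
make_epoch <- function(strata_idx, quota) {
  if (length(strata_idx) != 5 || any(lengths(strata_idx) == 0))
    stop("all five strata must be populated; enlarge or diversify the ",
         "simulated cohort (strata sizes: ",
         paste(lengths(strata_idx), collapse = ", "), ")")
  idx <- unlist(lapply(strata_idx, function(ix)
    ix[sample.int(length(ix), quota, replace = TRUE)]))
  idx[sample.int(length(idx))]
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# Extract a batch of 1-min sequences as a cube (1800, 2, B).
# `rows` is a data frame with columns session (index) and frame (end frame).
extract_batch <- function(sessions, rows, input_len = 1800L) {
  B <- nrow(rows)
  x <- array(0, c(input_len, 2L, B))
  for (b in seq_len(B)) {
    s <- sessions[[rows$session[b]]]
    f <- rows$frame[b]
    sel <- (f - input_len + 1L):f
    x[, 1, b] <- s$left_dist[sel]
    x[, 2, b] <- s$right_dist[sel]
  }
  x
}

#' Train the drowsiness network on one leave-one-subject-out fold
#'
#' Builds the frame-level training pool of the fold's training subjects,
#' the stimulus-anchored validation pool of its validation subjects, and
#' optimizes the multi-timescale relative-entropy loss with Adam, stratified
#' epochs, channel-swap augmentation and dropout. After each epoch the
#' weighted validation loss (balanced per timescale by the reciprocal
#' occurrence frequencies of the median-RT sides, computed on the validation
#' pool) is evaluated in inference mode; the parameters achieving the lowest
#' weighted validation loss are returned, with the input centering constant
#' (training-set mean eyelid distance) stored in the model.
#'
#' @param sessions Cohort list of [`pvt_session`][simulate_session] objects.
#' @param fold A fold from [make_folds()] (`train`, `val`, `test` subjects).
#' @param norm_model An [`rt_norm_model`][fit_normalization].
#' @param config A [net_config()].
#' @param tc A [train_config()].
#' @param frame_stride Stride (in frames) of the frame-level training pool;
#'   1 reproduces the full frame-level pool, larger values thin it (the
#'   strata still cover the same time span).
#' @param shuffle_labels Negative-control switch: permute the training and
#'   validation labels across samples before training.
#' @return A list with `model` (the trained `drowsinet_model`) and
#'   `history` (per-epoch training loss and weighted validation loss).
#' @export
train_fold <- function(sessions, fold, norm_model, config = net_config(),
                       tc = train_config(), frame_stride = 3L,
                       shuffle_labels = FALSE) {
  subj <- vapply(sessions, function(s) s$subject_id, character(1))
  if (length(intersect(fold$train, fold$val)) ||
      length(intersect(fold$train, fold$test)) ||
      length(intersect(fold$val, fold$test)))
    stop("fold subject sets must be disjoint")

  train_pool <- build_pool(sessions, norm_model, fold$train,
                           anchored = FALSE, frame_stride = frame_stride)
  val_pool <- build_pool(sessions, norm_model, fold$val, anchored = TRUE)
  if (nrow(train_pool) == 0 || nrow(val_pool) == 0)
    stop("empty training or validation pool")

  withr_seed(tc$seed, {
    if (shuffle_labels) {
      perm <- sample.int(nrow(train_pool))
      lab_cols <- c(paste0("m", 1:4), paste0("p", 1:4), "stratum")
      train_pool[lab_cols] <- train_pool[perm, lab_cols]
      permv <- sample.int(nrow(val_pool))
      val_pool[lab_cols] <- val_pool[permv, lab_cols]
    }

    keep <- !is.na(train_pool$stratum)
    train_pool <- train_pool[keep, , drop = FALSE]
    strata_idx <- lapply(0:4, function(k) which(train_pool$stratum == k))

    # centering constant: training-set mean eyelid distance
    tr_sessions <- which(subj %in% fold$train)
    center <- mean(vapply(sessions[tr_sessions], function(s)
      mean(c(s$left_dist, s$right_dist)), numeric(1)))

    # validation balancing weights from the validation pool
    mval <- as.matrix(val_pool[, paste0("m", 1:4)])
    vw <- tryCatch(compute_validation_weights(mval)$weight,
                   error = function(e) NULL)
    if (is.null(vw)) {
      warning("validation pool has an empty median-RT side; ",
              "falling back to unweighted validation loss")
      vw <- matrix(1, 4, 2, dimnames = list(NULL, c("lt470", "ge470")))
    }
    side <- (mval >= 470) + 1L                      # 1 = lt470, 2 = ge470
    wval <- matrix(vw[cbind(rep(1:4, each = nrow(mval)), as.vector(side))],
                   nrow(mval), 4)
    wval[is.na(wval)] <- 0                          # undefined median RT

    pval <- as.matrix(val_pool[, paste0("p", 1:4)])
    xval <- extract_batch(sessions, val_pool, config$input_len)

    model <- net_init(config, seed = sample.int(2^30, 1), center = center)
    st <- adam_new(model$params)
    best <- list(loss = Inf, params = model$params, bn = model$bn)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    bad <- 0L

    for (epoch in seq_len(tc$max_epochs)) {
      idx <- make_epoch(strata_idx, tc$quota)
      ep_loss <- 0; nb <- 0L
      for (s0 in seq(1, length(idx), by = tc$batch_size)) {
        rows <- train_pool[idx[s0:min(length(idx), s0 + tc$batch_size - 1L)], ]
        x <- extract_batch(sessions, rows, config$input_len)
        swap <- stats::runif(nrow(rows)) < tc$swap_prob
        if (any(swap)) x[, , swap] <- x[, 2:1, swap, drop = FALSE]
        masks <- make_dropout_masks(config, config$pooled_len, nrow(rows))
        fw <- net_fwd(model, x, training = TRUE, masks = masks, keep = TRUE)
        model$bn <- fw$bn
        pt <- as.matrix(rows[, paste0("p", 1:4)])
        ep_loss <- ep_loss + drowsiness_loss(fw$phat, pt)
        nb <- nb + 1L
        if (!is.finite(ep_loss)) stop("training loss diverged (NaN/Inf) at epoch ", epoch)
        gr <- net_bwd(model, fw$cache, pt)
        up <- adam_step(model$params, gr, st, tc$lr, tc$beta1, tc$beta2)
        model$params <- up$params
        st <- up$state
      }
      phat_val <- predict_drowsiness(model, xval)
      vloss <- drowsiness_loss(phat_val, pval, weights = wval)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                     val_loss = vloss))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = model$params, bn = model$bn)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= tc$patience) break
      }
    }
    model$params <- best$params
    model$bn <- best$bn
    # Recalibrate the batch-norm running statistics: after a short training
    # run the exponentially averaged statistics still carry their cold-start
    # initialization, which would bias inference. Replace them with plain
    # averages of the batch statistics over a few stratified batches.
    model <- bn_recalibrate(model, sessions, train_pool, strata_idx, tc)
    list(model = model, history = hist, val_weights = vw)
  })
}

# Re-estimate batch-norm running statistics as the average of the batch
# statistics over `n_batches` stratified batches (forward passes only, no
# parameter updates, dropout off).
bn_recalibrate <- function(model, sessions, train_pool, strata_idx, tc,
                           n_batches = 4L) {
  acc <- NULL
  per <- max(8L, ceiling(n_batches * tc$batch_size / 5))
  idx <- make_epoch(strata_idx, per)
  n_batches <- min(n_batches, length(idx) %/% tc$batch_size)
  for (k in seq_len(n_batches)) {
    rows <- train_pool[idx[((k - 1) * tc$batch_size + 1):(k * tc$batch_size)], ]
    x <- extract_batch(sessions, rows, model$config$input_len)
    fw <- net_fwd(model, x, training = TRUE)
    if (is.null(acc)) {
      acc <- fw$bn
      for (nm in names(acc)) {
        acc[[nm]]$mean <- fw$bn[[nm]]$batch_mean
        acc[[nm]]$var <- fw$bn[[nm]]$batch_var
      }
    } else {
      for (nm in names(acc)) {
        acc[[nm]]$mean <- acc[[nm]]$mean + fw$bn[[nm]]$batch_mean
        acc[[nm]]$var <- acc[[nm]]$var + fw$bn[[nm]]$batch_var
      }
    }
  }
  for (nm in names(acc)) {
    model$bn[[nm]] <- list(mean = acc[[nm]]$mean / n_batches,
                           var = acc[[nm]]$var / n_batches)
  }
  model
}

# Build a labeled sample pool for given subjects.
#  anchored = TRUE: one sample per PVT stimulus occurring at or after 60 s.
#  anchored = FALSE: frame-level grid from 60 s to the session end, thinned
#  by `frame_stride`.
build_pool <- function(sessions, norm_model, subjects, anchored,
                       frame_stride = 1L) {
  subj <- vapply(sessions, function(s) s$subject_id, character(1))
  out <- list()
  for (si in which(subj %in% subjects)) {
    s <- sessions[[si]]
    if (!s$subject_id %in% names(norm_model$mu)) next
    n <- length(s$left_dist)
    if (anchored) {
      t_eval <- sample_eval_points(s)
      frames <- round(t_eval * s$fps)
    } else {
      frames <- seq(1800L, n, by = frame_stride)
      t_eval <- frames / s$fps
    }
    if (length(frames) == 0) next
    lab <- label_session(s, norm_model, t_eval)
    lab$session <- si
    lab$frame <- frames
    out[[length(out) + 1L]] <- lab
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}
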