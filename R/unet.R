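# Encoder-decoder vessel segmentation network, implemented directly on
# base-R arrays. Feature maps are [H, W, C]; convolutions run as im2col
# matrix products (BLAS), so a reduced configuration trains in seconds on
# one CPU. Structure: five encoding blocks (two 3x3 conv + batch norm +
# ReLU, then 2x2 max-pool), five decoding blocks (2x nearest upsampling,
# concatenation with the mirrored encoder feature, two 3x3 conv + BN +
# ReLU), and a 1x1 conv + sigmoid head. "Same" padding keeps spatial size.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                          envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- primitive layers -------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; ch <- d[3]
  xp <- array(0, c(h + 2L, w + 2L, ch))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  cols <- vector("list", 9L)
  k <- 1L
  for (dc in 0:2) for (dr in 0:2) {
    cols[[k]] <- matrix(xp[(1:h) + dr, (1:w) + dc, ], h * w, ch)
    k <- k + 1L
  }
  do.call(cbind, cols)
}

col2im3 <- function(dpatch, h, w, ch) {
  dxp <- array(0, c(h + 2L, w + 2L, ch))
  k <- 1L
  for (dc in 0:2) for (dr in 0:2) {
    block <- array(dpatch[, ((k - 1L) * ch + 1L):(k * ch)], c(h, w, ch))
    dxp[(1:h) + dr, (1:w) + dc, ] <-
      dxp[(1:h) + dr, (1:w) + dc, , drop = FALSE] + block
    k <- k + 1L
  }
  dxp[2:(h + 1), 2:(w + 1), , drop = FALSE]
}

conv_init <- function(cin, cout, k = 3L) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                  k * k * cin, cout),
       b = rep(0, cout))
}

conv_fwd <- function(x, p) {
  d <- dim(x)
  X <- im2col3(x)
  y <- X %*% p$W
  y <- sweep(y, 2L, p$b, "+")
  list(out = array(y, c(d[1], d[2], ncol(p$W))), X = X, dims = d)
}

conv_bwd <- function(dy, p, cache) {
  d <- cache$dims
  dym <- matrix(dy, d[1] * d[2], ncol(p$W))
  list(dW = crossprod(cache$X, dym), db = colSums(dym),
       dx = col2im3(dym %*% t(p$W), d[1], d[2], d[3]))
}

conv1x1_init <- function(cin, cout) {
  list(W = matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

conv1x1_fwd <- function(x, p) {
  d <- dim(x)
  X <- matrix(x, d[1] * d[2], d[3])
  y <- sweep(X %*% p$W, 2L, p$b, "+")
  list(out = array(y, c(d[1], d[2], ncol(p$W))), X = X, dims = d)
}

conv1x1_bwd <- function(dy, p, cache) {
  d <- cache$dims
  dym <- matrix(dy, d[1] * d[2], ncol(p$W))
  list(dW = crossprod(cache$X, dym), db = colSums(dym),
       dx = array(dym %*% t(p$W), d))
}

bn_init <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch))

bn_fwd <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(xm)
  ctr <- sweep(xm, 2L, mu)
  va <- colMeans(ctr^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(ctr, 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = array(y, d), xhat = xhat, istd = istd, dims = d)
}

bn_bwd <- function(dy, p, cache) {
  d <- cache$dims
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  coef <- sweep(n * dym, 2L, dbeta) -
    sweep(cache$xhat, 2L, dgamma, "*")
  dx <- sweep(coef, 2L, p$gamma * cache$istd / n, "*")
  list(dgamma = dgamma, dbeta = dbeta, dx = array(dx, d))
}

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, cache) dy * cache$mask

maxpool_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  a <- x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  b <- x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  cc <- x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  dd <- x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out,
       which = (a == out) * 1L + (b == out & a < out) * 2L +
         (cc == out & pmax(a, b) < out) * 3L +
         (dd == out & pmax(a, b, cc) < out) * 4L,
       dims = d)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  w <- cache$which
  dx[seq(1, d[1], 2), seq(1, d[2], 2), ] <- dy * (w == 1L)
  dx[seq(2, d[1], 2), seq(1, d[2], 2), ] <- dy * (w == 2L)
  dx[seq(1, d[1], 2), seq(2, d[2], 2), ] <- dy * (w == 3L)
  dx[seq(2, d[1], 2), seq(2, d[2], 2), ] <- dy * (w == 4L)
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample_bwd <- function(dy, dims) {
  o <- dy[seq(1, 2 * dims[1], 2), seq(1, 2 * dims[2], 2), , drop = FALSE] +
    dy[seq(2, 2 * dims[1], 2), seq(1, 2 * dims[2], 2), , drop = FALSE] +
    dy[seq(1, 2 * dims[1], 2), seq(2, 2 * dims[2], 2), , drop = FALSE] +
    dy[seq(2, 2 * dims[1], 2), seq(2, 2 * dims[2], 2), , drop = FALSE]
  o
}

# ---- double conv block ------------------------------------------------

block_init <- function(cin, cout) {
  list(conv1 = conv_init(cin, cout), bn1 = bn_init(cout),
       conv2 = conv_init(cout, cout), bn2 = bn_init(cout))
}

block_fwd <- function(x, p) {
  c1 <- conv_fwd(x, p$conv1); b1 <- bn_fwd(c1$out, p$bn1)
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, p$conv2); b2 <- bn_fwd(c2$out, p$bn2)
  r2 <- relu_fwd(b2$out)
  list(out = r2$out, cache = list(c1 = c1, b1 = b1, r1 = r1,
                                  c2 = c2, b2 = b2, r2 = r2))
}

block_bwd <- function(dy, p, cache) {
  dy <- relu_bwd(dy, cache$r2)
  g2 <- bn_bwd(dy, p$bn2, cache$b2)
  k2 <- conv_bwd(g2$dx, p$conv2, cache$c2)
  dy <- relu_bwd(k2$dx, cache$r1)
  g1 <- bn_bwd(dy, p$bn1, cache$b1)
  k1 <- conv_bwd(g1$dx, p$conv1, cache$c1)
  list(grads = list(conv1 = list(W = k1$dW, b = k1$db),
                    bn1 = list(gamma = g1$dgamma, beta = g1$dbeta),
                    conv2 = list(W = k2$dW, b = k2$db),
                    bn2 = list(gamma = g2$dgamma, beta = g2$dbeta)),
       dx = k1$dx)
}

# ---- model ------------------------------------------------------------

#' Configuration of the vessel segmentation network
#'
#' Defaults follow the full-scale recipe: 1024-pixel input, encoder
#' channels 32/64/128/256/512 mirrored in the decoder, 3x3 kernels,
#' Adam with learning rate 2e-4, 6 training epochs. Reduced
#' configurations (e.g. side 64, channels 8..128) train quickly for
#' testing.
#'
#' @param input_side input image side; must be divisible by
#'   `2^length(encoder_channels)`.
#' @param encoder_channels output channels of the encoding blocks.
#' @param decoder_channels output channels of the decoding blocks (same
#'   length, typically mirrored).
#' @param learning_rate Adam initial learning rate.
#' @param epochs training epochs.
#' @param seed integer seed controlling initialization and augmentation.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(input_side = 1024L,
                                encoder_channels = c(32L, 64L, 128L,
                                                     256L, 512L),
                                decoder_channels = rev(encoder_channels),
                                learning_rate = 2e-4, epochs = 6L,
                                seed = 1L) {
  stopifnot(length(encoder_channels) >= 1,
            length(decoder_channels) == length(encoder_channels),
            learning_rate > 0, epochs >= 0)
  if (input_side %% 2L^length(encoder_channels) != 0L)
    stop("input side must be divisible by 2^", length(encoder_channels),
         " (one downsampling per encoding block)")
  structure(list(input_side = as.integer(input_side),
                 encoder_channels = as.integer(encoder_channels),
                 decoder_channels = as.integer(decoder_channels),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Build a vessel segmentation model
#'
#' Initializes the encoder-decoder network (He-initialized weights,
#' deterministic under the config seed). The returned model maps an
#' `S x S x 3` standardized image to an `S x S` vessel probability map
#' through a final sigmoid.
#'
#' @param config a [segmentation_config()].
#' @return an object of class `segmentation_model`.
#' @export
build_model <- function(config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  nb <- length(config$encoder_channels)
  with_seed(config$seed, {
    enc <- vector("list", nb)
    cin <- 3L
    for (i in seq_len(nb)) {
      enc[[i]] <- block_init(cin, config$encoder_channels[i])
      cin <- config$encoder_channels[i]
    }
    dec <- vector("list", nb)
    prev <- config$encoder_channels[nb]
    for (j in seq_len(nb)) {
      skip_ch <- config$encoder_channels[nb + 1L - j]
      dec[[j]] <- block_init(prev + skip_ch, config$decoder_channels[j])
      prev <- config$decoder_channels[j]
    }
    head_p <- conv1x1_init(prev, 1L)
    structure(list(enc = enc, dec = dec, head = head_p, config = config),
              class = "segmentation_model")
  })
}

#' @export
print.segmentation_model <- function(x, ...) {
  np <- sum(rapply(unclass(x)[c("enc", "dec", "head")], length,
                   how = "unlist"))
  cat(sprintf(paste0("<segmentation_model> side %d, encoder %s, ",
                     "decoder %s, %d parameters\n"),
              x$config$input_side,
              paste(x$config$encoder_channels, collapse = "/"),
              paste(x$config$decoder_channels, collapse = "/"), np))
  invisible(x)
}

unet_forward <- function(model, x, want_cache = FALSE) {
  nb <- length(model$enc)
  feats <- vector("list", nb)
  caches <- list(enc = vector("list", nb), pool = vector("list", nb),
                 dec = vector("list", nb), updims = vector("list", nb),
                 nskip = integer(nb))
  for (i in seq_len(nb)) {
    bf <- block_fwd(x, model$enc[[i]])
    feats[[i]] <- bf$out
    if (want_cache) caches$enc[[i]] <- bf$cache
    pf <- maxpool_fwd(bf$out)
    if (want_cache) caches$pool[[i]] <- pf[c("which", "dims")]
    x <- pf$out
  }
  for (j in seq_len(nb)) {
    caches$updims[[j]] <- dim(x)
    up <- upsample_fwd(x)
    skip <- feats[[nb + 1L - j]]
    caches$nskip[j] <- dim(skip)[3]
    x <- array(c(up, skip), c(dim(up)[1], dim(up)[2],
                              dim(up)[3] + dim(skip)[3]))
    bf <- block_fwd(x, model$dec[[j]])
    if (want_cache) caches$dec[[j]] <- bf$cache
    x <- bf$out
  }
  hf <- conv1x1_fwd(x, model$head)
  logits <- hf$out[, , 1]
  out <- list(probs = 1 / (1 + exp(-logits)), logits = logits)
  if (want_cache) {
    caches$head <- hf
    out$caches <- caches
  }
  out
}

unet_backward <- function(model, caches, dlogits) {
  nb <- length(model$enc)
  grads <- list(enc = vector("list", nb), dec = vector("list", nb))
  hk <- conv1x1_bwd(array(dlogits, c(dim(dlogits), 1L)), model$head,
                    caches$head)
  grads$head <- list(W = hk$dW, b = hk$db)
  dx <- hk$dx
  dskip <- vector("list", nb)   # gradient flowing into encoder features
  for (j in rev(seq_len(nb))) {
    bb <- block_bwd(dx, model$dec[[j]], caches$dec[[j]])
    grads$dec[[j]] <- bb$grads
    din <- bb$dx
    ch_up <- dim(din)[3] - caches$nskip[j]
    dup <- din[, , seq_len(ch_up), drop = FALSE]
    dskip[[nb + 1L - j]] <- din[, , ch_up + seq_len(caches$nskip[j]),
                                drop = FALSE]
    dx <- upsample_bwd(dup, caches$updims[[j]])
  }
  for (i in rev(seq_len(nb))) {
    dpooled <- maxpool_bwd(dx, caches$pool[[i]])
    bb <- block_bwd(dpooled + dskip[[i]], model$enc[[i]], caches$enc[[i]])
    grads$enc[[i]] <- bb$grads
    dx <- bb$dx
  }
  grads
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "replace", classes = "ANY")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (k in seq_along(p)) {   # by index: block lists are unnamed
        r <- walk(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

#' Train a vessel segmentation model
#'
#' Minimizes the pixelwise binary cross-entropy loss over the training
#' pairs with the Adam update rule, for the configured number of epochs.
#' Deterministic given the config seed (which also drives the per-epoch
#' shuffling).
#'
#' @param model a `segmentation_model` from [build_model()].
#' @param pairs list of training pairs, each a list with `image` (a
#'   `standardized_image` or `[S,S,3]` array) and `mask` (0/1 matrix),
#'   e.g. from [render_phantom()] or [augment()].
#' @param config optional [segmentation_config()]; defaults to the
#'   model's own.
#' @return list with the trained `model` and `losses`, the mean Eq.-style
#'   BCE loss per epoch (empty when `epochs = 0`).
#' @export
train <- function(model, pairs, config = NULL) {
  stopifnot(inherits(model, "segmentation_model"))
  if (length(pairs) < 1) stop("training set is empty")
  if (is.null(config)) config <- model$config
  if (config$epochs == 0L) return(list(model = model, losses = numeric(0)))
  xs <- lapply(pairs, function(p)
    if (inherits(p$image, "standardized_image")) p$image$pixels else p$image)
  ys <- lapply(pairs, function(p) p$mask)
  params <- unclass(model)[c("enc", "dec", "head")]
  state <- adam_init(params)
  losses <- numeric(config$epochs)
  t <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + 1000L * ep,
                     sample.int(length(pairs)))
    ep_loss <- numeric(length(ord))
    for (k in seq_along(ord)) {
      i <- ord[k]
      model$enc <- params$enc; model$dec <- params$dec
      model$head <- params$head
      fw <- unet_forward(model, xs[[i]], want_cache = TRUE)
      gt <- ys[[i]]
      # stable BCE from logits; gradient wrt logits is (p - gt)/n
      z <- fw$logits
      ep_loss[k] <- mean(pmax(z, 0) - z * gt + log1p(exp(-abs(z))))
      dlogits <- (fw$probs - gt) / length(gt)
      grads <- unet_backward(model, fw$caches, dlogits)
      t <- t + 1L
      upd <- adam_step(params, grads, state, config$learning_rate, t)
      params <- upd$p; state <- upd$s
    }
    losses[ep] <- mean(ep_loss)
  }
  model$enc <- params$enc; model$dec <- params$dec; model$head <- params$head
  list(model = model, losses = losses)
}

#' Save / load model weights
#'
#' Weights are serialized with R's native `saveRDS` checkpoint format.
#'
#' @param model a `segmentation_model`.
#' @param path checkpoint file path.
#' @return `save_weights` returns `path` invisibly; `load_weights`
#'   returns the model.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "segmentation_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "segmentation_model"))
    stop("not a segmentation model checkpoint: ", path)
  model
}
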