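# ---------------------------------------------------------------------
# Minimal CNN engine in base R.
#
# No deep-learning runtime exists in the target environment, so the
# layers needed by the pipeline are implemented directly: convolution
# (im2col + BLAS matmul), batch-norm (inference), ReLU, max/avg pooling,
# global average pooling and a fully connected head.  Backpropagation is
# implemented for the sequential "tiny" backbone used in desk-scale
# training; the canonical residual depths support construction,
# parameter counting and inference.
#
# Tensor convention: a batch is an H x W x C x N numeric array.
# ---------------------------------------------------------------------

kaiming_uniform <- function(n, fan_in) {
  bound <- sqrt(6 / fan_in)
  stats::runif(n, -bound, bound)
}

new_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                     bias = FALSE, init = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$cin <- cin; ly$cout <- cout; ly$k <- k
  ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$has_bias <- bias
  if (init) {
    fan_in <- k * k * cin
    ly$W <- matrix(kaiming_uniform(k * k * cin * cout, fan_in), k * k * cin, cout)
    ly$b <- if (bias) numeric(cout) else NULL
  }
  ly
}

new_bn <- function(c, init = TRUE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "bn"; ly$c <- c
  if (init) {
    ly$gamma <- rep(1, c); ly$beta <- numeric(c)
    ly$running_mean <- numeric(c); ly$running_var <- rep(1, c)
  }
  ly
}

new_simple <- function(type) {
  ly <- new.env(parent = emptyenv()); ly$type <- type; ly
}

new_linear <- function(fin, fout, init = TRUE, init_name = "kaiming_uniform") {
  ly <- new.env(parent = emptyenv())
  ly$type <- "linear"; ly$fin <- fin; ly$fout <- fout; ly$init_name <- init_name
  if (init) {
    ly$W <- switch(init_name,
      kaiming_uniform = matrix(kaiming_uniform(fout * fin, fin), fout, fin),
      zeros = matrix(0, fout, fin),
      stop("unknown initializer: ", sQuote(init_name),
           "; known: kaiming_uniform, zeros"))
    ly$b <- numeric(fout)
  }
  ly
}

conv_geometry <- function(ly, H, W) {
  key <- c(H, W)
  if (!is.null(ly$geom_key) && identical(ly$geom_key, key)) return(invisible())
  k <- ly$k; s <- ly$stride; p <- ly$pad; C <- ly$cin
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Hout <- (Hp - k) %/% s + 1L; Wout <- (Wp - k) %/% s + 1L
  oh <- rep(seq_len(Hout), times = Wout); ow <- rep(seq_len(Wout), each = Hout)
  base <- (oh - 1L) * s + 1L + ((ow - 1L) * s) * Hp  # linear idx of window corner
  dh <- rep(0:(k - 1L), times = k * C)
  dw <- rep(rep(0:(k - 1L), each = k), times = C)
  dc <- rep(0:(C - 1L), each = k * k)
  off <- dh + dw * Hp + dc * (Hp * Wp)
  npos <- Hout * Wout
  ly$idx <- matrix(rep(base, times = length(off)), npos) +
    matrix(rep(off, each = npos), npos)
  h <- rep(seq_len(H), times = W * C); w <- rep(rep(seq_len(W), each = H), times = C)
  cc <- rep(0:(C - 1L), each = H * W)
  ly$interior <- (h + p) + (w + p - 1L) * Hp + cc * (Hp * Wp)
  ly$geom_key <- key
  ly$Hin <- H; ly$Win <- W; ly$Hp <- Hp; ly$Wp <- Wp
  ly$Hout <- Hout; ly$Wout <- Wout
  invisible()
}

conv_forward <- function(ly, x, train = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  conv_geometry(ly, H, W)
  MP <- matrix(0, ly$Hp * ly$Wp * ly$cin, N)
  MP[ly$interior, ] <- x
  npos <- ly$Hout * ly$Wout
  out <- array(0, c(ly$Hout, ly$Wout, ly$cout, N))
  cols <- if (train) vector("list", N) else NULL
  step <- npos * ly$cout
  for (n in seq_len(N)) {
    cn <- MP[, n][ly$idx]            # matrix-index gather -> npos x kkC
    dim(cn) <- dim(ly$idx)
    Yn <- cn %*% ly$W
    if (ly$has_bias) Yn <- Yn + rep(ly$b, each = npos)
    out[(n - 1L) * step + seq_len(step)] <- Yn
    if (train) cols[[n]] <- cn
  }
  if (train) { ly$cache_cols <- cols; ly$cache_N <- N }
  out
}

# gradient w.r.t. the input of a stride-1 convolution, computed as a
# convolution of dy with the spatially flipped, channel-transposed kernel
conv_bwd_geometry <- function(ly) {
  if (!is.null(ly$bwd_idx)) return(invisible())
  k <- ly$k; p <- k - 1L - ly$pad
  Hp <- ly$Hout + 2L * p; Wp <- ly$Wout + 2L * p
  oh <- rep(seq_len(ly$Hin), times = ly$Win)
  ow <- rep(seq_len(ly$Win), each = ly$Hin)
  base <- oh + (ow - 1L) * Hp
  dh <- rep(0:(k - 1L), times = k * ly$cout)
  dw <- rep(rep(0:(k - 1L), each = k), times = ly$cout)
  dc <- rep(0:(ly$cout - 1L), each = k * k)
  off <- dh + dw * Hp + dc * (Hp * Wp)
  npos <- ly$Hin * ly$Win
  ly$bwd_idx <- matrix(rep(base, times = length(off)), npos) +
    matrix(rep(off, each = npos), npos)
  h <- rep(seq_len(ly$Hout), times = ly$Wout * ly$cout)
  w <- rep(rep(seq_len(ly$Wout), each = ly$Hout), times = ly$cout)
  cc <- rep(0:(ly$cout - 1L), each = ly$Hout * ly$Wout)
  ly$bwd_interior <- (h + p) + (w + p - 1L) * Hp + cc * (Hp * Wp)
  ly$bwd_Hp <- Hp; ly$bwd_Wp <- Wp
  # flipped kernel: W is (kkCin) x cout ordered (dh, dw, cin); build the
  # (kkCout) x cin matrix ordered (k-1-dh, k-1-dw, cout)
  kk <- k * k
  src_dh <- k - 1L - rep(0:(k - 1L), times = k)
  src_dw <- k - 1L - rep(0:(k - 1L), each = k)
  ly$flip_rows <- 1L + src_dh + src_dw * k   # within one cin block
  invisible()
}

flipped_weight <- function(ly) {
  k <- ly$k; kk <- k * k
  Wf <- matrix(0, kk * ly$cout, ly$cin)
  Warr <- array(ly$W, c(kk, ly$cin, ly$cout))
  for (ci in seq_len(ly$cin))
    Wf[, ci] <- as.vector(Warr[ly$flip_rows, ci, ])
  Wf
}

conv_backward <- function(ly, dy) {
  N <- ly$cache_N
  npos <- ly$Hout * ly$Wout
  dW <- matrix(0, nrow(ly$W), ncol(ly$W))
  db <- if (ly$has_bias) numeric(ly$cout) else NULL
  dYl <- vector("list", N)
  step <- npos * ly$cout
  for (n in seq_len(N)) {
    dYn <- matrix(dy[(n - 1L) * step + seq_len(step)], npos, ly$cout)
    dW <- dW + crossprod(ly$cache_cols[[n]], dYn)
    if (ly$has_bias) db <- db + colSums(dYn)
    dYl[[n]] <- dYn
  }
  ly$dW <- dW
  if (ly$has_bias) ly$db <- db
  ly$cache_cols <- NULL
  if (ly$stride == 1L) {
    conv_bwd_geometry(ly)
    Wf <- flipped_weight(ly)
    MP <- matrix(0, ly$bwd_Hp * ly$bwd_Wp * ly$cout, N)
    for (n in seq_len(N)) MP[ly$bwd_interior, n] <- dYl[[n]]
    dx <- array(0, c(ly$Hin, ly$Win, ly$cin, N))
    npos_in <- ly$Hin * ly$Win
    step_in <- npos_in * ly$cin
    for (n in seq_len(N)) {
      cn <- MP[, n][ly$bwd_idx]
      dim(cn) <- dim(ly$bwd_idx)
      dx[(n - 1L) * step_in + seq_len(step_in)] <- cn %*% Wf
    }
    return(dx)
  }
  # generic (strided) fallback: scatter-add per kernel offset
  dMP <- matrix(0, ly$Hp * ly$Wp * ly$cin, N)
  for (n in seq_len(N)) {
    dcols <- tcrossprod(dYl[[n]], ly$W)
    for (j in seq_len(ncol(ly$idx))) {
      rows <- ly$idx[, j]
      dMP[rows, n] <- dMP[rows, n] + dcols[, j]
    }
  }
  array(dMP[ly$interior, ], c(ly$Hin, ly$Win, ly$cin, N))
}

# training-mode batch norm: batch statistics over (H, W, N) per channel.
# Layout trick: an [H, W, C, N] array viewed as an (H*W) x (C*N) matrix
# has channel c in columns c, c + C, c + 2C, ...; per-channel reductions
# are rowSums over a C x N reshape of the column reductions, and
# per-channel broadcasts are rep(v, times = N) expanded along columns.
bn_train_forward <- function(ly, x) {
  d <- dim(x); A <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- A * N
  mm <- matrix(x, A, C * N)
  mu <- rowSums(matrix(colSums(mm), C, N)) / M
  ex2 <- rowSums(matrix(colSums(mm^2), C, N)) / M
  v <- pmax(ex2 - mu^2, 0)
  invstd <- 1 / sqrt(v + 1e-5)
  xhat <- (mm - rep(rep(mu, times = N), each = A)) *
    rep(rep(invstd, times = N), each = A)
  y <- xhat * rep(rep(ly$gamma, times = N), each = A) +
    rep(rep(ly$beta, times = N), each = A)
  mom <- 0.1
  ly$running_mean <- (1 - mom) * ly$running_mean + mom * mu
  ly$running_var <- (1 - mom) * ly$running_var + mom * v * M / max(1, M - 1)
  ly$cache_xhat <- xhat; ly$cache_invstd <- invstd; ly$cache_dim <- d
  array(y, d)
}

bn_backward <- function(ly, dy) {
  d <- ly$cache_dim; A <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- A * N
  dmm <- matrix(dy, A, C * N)
  xhat <- ly$cache_xhat
  ly$dbeta <- rowSums(matrix(colSums(dmm), C, N))
  ly$dgamma <- rowSums(matrix(colSums(dmm * xhat), C, N))
  dxhat <- dmm * rep(rep(ly$gamma, times = N), each = A)
  mean_dxhat <- rowSums(matrix(colSums(dxhat), C, N)) / M
  mean_dxx <- rowSums(matrix(colSums(dxhat * xhat), C, N)) / M
  dx <- (dxhat - rep(rep(mean_dxhat, times = N), each = A) -
           xhat * rep(rep(mean_dxx, times = N), each = A)) *
    rep(rep(ly$cache_invstd, times = N), each = A)
  ly$cache_xhat <- NULL
  array(dx, d)
}

bn_forward <- function(ly, x) {
  d <- dim(x)
  scale <- ly$gamma / sqrt(ly$running_var + 1e-5)
  shift <- ly$beta - ly$running_mean * scale
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  sc <- rep(scale, times = d[4]); sh <- rep(shift, times = d[4])
  array(m * rep(sc, each = d[1] * d[2]) + rep(sh, each = d[1] * d[2]), d)
}

relu_forward <- function(ly, x, train = FALSE) {
  y <- pmax(x, 0)
  if (train) ly$cache_mask <- x > 0
  y
}

relu_backward <- function(ly, dy) {
  dy * ly$cache_mask
}

# leaky ReLU (slope 0.1): used by the tiny backbone, where a handful of
# dead units out of 12 first-layer channels can cripple a 10-epoch run
lrelu_forward <- function(ly, x, train = FALSE) {
  if (train) ly$cache_mask <- x > 0
  pmax(x, 0) + 0.1 * pmin(x, 0)
}

lrelu_backward <- function(ly, dy) {
  dy * (0.1 + 0.9 * ly$cache_mask)
}

avgpool2_forward <- function(ly, x) {
  d <- dim(x)
  o <- seq(1L, d[1] - 1L, by = 2L); e <- o + 1L
  po <- seq(1L, d[2] - 1L, by = 2L); pe <- po + 1L
  (x[o, po, , , drop = FALSE] + x[e, po, , , drop = FALSE] +
     x[o, pe, , , drop = FALSE] + x[e, pe, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(ly, dy, dim_in) {
  dx <- array(0, dim_in)
  o <- seq(1L, dim_in[1] - 1L, by = 2L); e <- o + 1L
  po <- seq(1L, dim_in[2] - 1L, by = 2L); pe <- po + 1L
  g <- dy / 4
  dx[o, po, , ] <- g; dx[e, po, , ] <- g
  dx[o, pe, , ] <- g; dx[e, pe, , ] <- g
  dx
}

maxpool_forward <- function(x, k = 3L, s = 2L, p = 1L) {
  d <- dim(x)
  Hp <- d[1] + 2L * p; Wp <- d[2] + 2L * p
  xp <- array(-Inf, c(Hp, Wp, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  Hout <- (Hp - k) %/% s + 1L; Wout <- (Wp - k) %/% s + 1L
  out <- array(-Inf, c(Hout, Wout, d[3], d[4]))
  for (dh in 0:(k - 1L)) for (dw in 0:(k - 1L)) {
    sl <- xp[seq(1L + dh, by = s, length.out = Hout),
             seq(1L + dw, by = s, length.out = Wout), , , drop = FALSE]
    out <- pmax(out, sl)
  }
  out
}

gap_forward <- function(ly, x, train = FALSE) {
  d <- dim(x)
  if (train) ly$cache_dim <- d
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

gap_backward <- function(ly, dy) {
  d <- ly$cache_dim
  array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

linear_forward <- function(ly, x, train = FALSE) {
  if (train) ly$cache_x <- x
  ly$W %*% x + ly$b
}

linear_backward <- function(ly, dy) {
  ly$dW <- tcrossprod(dy, ly$cache_x)
  ly$db <- rowSums(dy)
  ly$cache_x <- NULL
  crossprod(ly$W, dy)
}

# ---------------------------------------------------------------------
# Architectures
# ---------------------------------------------------------------------

resnet_layout <- function(depth) {
  switch(as.character(depth),
    "18" = list(block = "basic", nblocks = c(2, 2, 2, 2), expansion = 1L),
    "34" = list(block = "basic", nblocks = c(3, 4, 6, 3), expansion = 1L),
    "50" = list(block = "bottleneck", nblocks = c(3, 4, 6, 3), expansion = 4L),
    "101" = list(block = "bottleneck", nblocks = c(3, 4, 23, 3), expansion = 4L),
    "152" = list(block = "bottleneck", nblocks = c(3, 8, 36, 3), expansion = 4L),
    stop("unsupported residual depth: ", depth,
         "; supported depths are 18, 34, 50, 101, 152 (or 'tiny')"))
}

new_block <- function(kind, cin, planes, stride, expansion, init) {
  blk <- new.env(parent = emptyenv())
  blk$type <- paste0("block_", kind)
  cout <- planes * expansion
  if (kind == "basic") {
    blk$convs <- list(new_conv(cin, planes, 3L, stride, 1L, init = init),
                      new_conv(planes, planes, 3L, 1L, 1L, init = init))
    blk$bns <- list(new_bn(planes, init), new_bn(planes, init))
  } else {
    blk$convs <- list(new_conv(cin, planes, 1L, 1L, 0L, init = init),
                      new_conv(planes, planes, 3L, stride, 1L, init = init),
                      new_conv(planes, cout, 1L, 1L, 0L, init = init))
    blk$bns <- list(new_bn(planes, init), new_bn(planes, init),
                    new_bn(cout, init))
  }
  if (stride != 1L || cin != cout) {
    blk$downsample <- list(conv = new_conv(cin, cout, 1L, stride, 0L, init = init),
                           bn = new_bn(cout, init))
  } else blk$downsample <- NULL
  blk$cout <- cout
  blk
}

build_resnet_layers <- function(depth, init) {
  lay <- resnet_layout(depth)
  layers <- list(new_conv(3L, 64L, 7L, 2L, 3L, init = init), new_bn(64L, init),
                 new_simple("relu"), new_simple("maxpool"))
  cin <- 64L
  planes <- c(64L, 128L, 256L, 512L)
  for (stage in 1:4) {
    for (b in seq_len(lay$nblocks[stage])) {
      stride <- if (stage > 1L && b == 1L) 2L else 1L
      blk <- new_block(lay$block, cin, planes[stage], stride, lay$expansion, init)
      layers[[length(layers) + 1L]] <- blk
      cin <- blk$cout
    }
  }
  layers[[length(layers) + 1L]] <- new_simple("gap")
  list(layers = layers, feature_dim = cin)
}

build_tiny_layers <- function(init, widths = c(12L, 24L, 48L, 96L)) {
  layers <- list()
  cin <- 3L
  for (wd in widths) {
    layers[[length(layers) + 1L]] <- new_conv(cin, wd, 3L, 1L, 1L, bias = TRUE,
                                              init = init)
    layers[[length(layers) + 1L]] <- new_simple("lrelu")
    if (wd != widths[length(widths)]) layers[[length(layers) + 1L]] <- new_simple("avgpool2")
    cin <- wd
  }
  layers[[length(layers) + 1L]] <- new_simple("gap")
  list(layers = layers, feature_dim = widths[length(widths)])
}

#' Network configuration
#'
#' Describes the feature-extraction backbone and classifier head.  The
#' canonical depths are the residual networks 18/34/50/101/152 with the
#' final fully connected classification layer removed (global-average-
#' pooled output of the last convolutional layer is the extracted visual
#' feature: dimension 512 for depths 18/34, 2048 for 50/101/152).  The
#' additional `"tiny"` backbone — a 4-block plain convolutional network
#' (~25k parameters, feature dimension 64) — exists for CPU-scale
#' training on synthetic data; the residual depths remain the canonical
#' configurations.
#'
#' @param depth One of `18, 34, 50, 101, 152` or `"tiny"`.
#' @param pretrained If `TRUE`, initialise from an ImageNet-pretrained
#'   weights asset located at `weights_path` (no layer is frozen);
#'   correctness tests run with `pretrained = FALSE`.
#' @param n_classes Number of score classes (>= 2) for the head.
#' @param head_init Initializer for the head (`"kaiming_uniform"`).
#' @param weights_path Optional path to a serialized weights asset.
#' @return A `leafhair_network_config`.
#' @export
network_config <- function(depth = 34, pretrained = FALSE, n_classes = 9L,
                           head_init = "kaiming_uniform", weights_path = NULL) {
  if (!identical(depth, "tiny")) {
    resnet_layout(depth)  # validates depth
    depth <- as.integer(depth)
  }
  stopifnot(n_classes >= 2)
  structure(list(depth = depth, pretrained = isTRUE(pretrained),
                 n_classes = as.integer(n_classes), head_init = head_init,
                 weights_path = weights_path),
            class = "leafhair_network_config")
}

#' Build the feature-extraction backbone
#'
#' Constructs the backbone named by `config$depth` with its final fully
#' connected layer removed.  With `pretrained = FALSE` and a fixed seed
#' the initial weights are deterministic (Kaiming-Uniform for
#' convolutions, unit-gamma/zero-beta batch norm).  With
#' `pretrained = TRUE` a weights asset must exist at
#' `config$weights_path`; none ships with the package.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialisation.
#' @param init_weights If `FALSE`, build shape metadata only (enough for
#'   [count_trainable_parameters()] and [feature_dim()], not for
#'   [net_forward()]); the deep bottleneck nets allocate tens of
#'   millions of doubles when materialised.
#' @return A `leafhair_extractor`.
#' @export
build_feature_extractor <- function(config, seed = 1L, init_weights = TRUE) {
  stopifnot(inherits(config, "leafhair_network_config"))
  if (config$pretrained) {
    if (is.null(config$weights_path) || !file.exists(config$weights_path))
      stop("pretrained = TRUE but no weights asset found",
           if (!is.null(config$weights_path)) paste0(" at ", config$weights_path),
           "; pretrained ImageNet weights are an optional external asset")
  }
  built <- withr::with_seed(as.integer(seed), {
    if (identical(config$depth, "tiny")) build_tiny_layers(init_weights)
    else build_resnet_layers(config$depth, init_weights)
  })
  if (config$pretrained) {
    w <- readRDS(config$weights_path)
    load_extractor_weights(built$layers, w)
  }
  structure(list(config = config, layers = built$layers,
                 feature_dim = built$feature_dim, seed = as.integer(seed),
                 materialized = init_weights),
            class = "leafhair_extractor")
}

# flat list of trainable layer environments, in order
trainable_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (ly$type %in% c("conv", "bn", "linear")) out[[length(out) + 1L]] <- ly
    else if (startsWith(ly$type, "block_")) {
      out <- c(out, ly$convs, ly$bns)
      if (!is.null(ly$downsample)) out <- c(out, list(ly$downsample$conv, ly$downsample$bn))
    }
  }
  out
}

layer_param_count <- function(ly) {
  switch(ly$type,
    conv = ly$k * ly$k * ly$cin * ly$cout + if (ly$has_bias) ly$cout else 0L,
    bn = 2L * ly$c,
    linear = ly$fout * ly$fin + ly$fout,
    0L)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalar weights: convolution kernels (and
#' biases where present), batch-norm scale/shift pairs, and fully
#' connected weights/biases.  For the headless depth-34 backbone this is
#' exactly 21,284,672 (reported as 21.28M); depth-101 counts 42,500,160
#' (reported as 42.51M, see the package vignette on that discrepancy).
#'
#' @param x A `leafhair_extractor`, a classifier head, or a
#'   [network_config()] (counted without materialising weights).
#' @return Integer-valued numeric count.
#' @export
count_trainable_parameters <- function(x) {
  if (inherits(x, "leafhair_network_config"))
    x <- build_feature_extractor(x, init_weights = FALSE)
  layers <- if (inherits(x, "leafhair_extractor")) trainable_layers(x$layers)
            else if (is.environment(x)) list(x)
            else trainable_layers(x)
  sum(vapply(layers, layer_param_count, numeric(1)))
}

#' Feature dimension of an extractor
#'
#' @param extractor A `leafhair_extractor`.
#' @return 512 for depths 18/34, 2048 for 50/101/152, 64 for `"tiny"`.
#' @export
feature_dim <- function(extractor) extractor$feature_dim

#' Build the classification head
#'
#' A single fully connected layer mapping the extracted visual feature to
#' a prediction vector whose length is the number of classes; weights are
#' drawn with the named initializer (default Kaiming-Uniform, all weights
#' within the scheme's symmetric bound `sqrt(6 / feature_dim)`),
#' deterministic under a fixed seed.
#'
#' @param feature_dim Input feature dimension (>= 1).
#' @param n_classes Output length (>= 1).
#' @param init Initializer name.
#' @param seed Integer seed.
#' @return A linear-layer environment (the classifier head).
#' @export
build_classifier <- function(feature_dim, n_classes, init = "kaiming_uniform",
                             seed = 1L) {
  stopifnot(feature_dim >= 1, n_classes >= 1)
  withr::with_seed(as.integer(seed),
                   new_linear(as.integer(feature_dim), as.integer(n_classes),
                              init = TRUE, init_name = init))
}

# forward through one node (eval or train); train path rejects blocks
node_forward <- function(ly, x, train = FALSE) {
  if (startsWith(ly$type, "block_")) {
    if (train) stop("backpropagation through residual blocks is not supported; ",
                    "use the 'tiny' backbone for training")
    identity_x <- x
    nconv <- length(ly$convs)
    for (i in seq_len(nconv)) {
      x <- conv_forward(ly$convs[[i]], x)
      x <- bn_forward(ly$bns[[i]], x)
      if (i < nconv) x <- relu_forward(ly, x)
    }
    if (!is.null(ly$downsample))
      identity_x <- bn_forward(ly$downsample$bn,
                               conv_forward(ly$downsample$conv, identity_x))
    return(pmax(x + identity_x, 0))
  }
  switch(ly$type,
    conv = conv_forward(ly, x, train),
    bn = if (train) bn_train_forward(ly, x) else bn_forward(ly, x),
    relu = relu_forward(ly, x, train),
    lrelu = lrelu_forward(ly, x, train),
    maxpool = maxpool_forward(x),
    avgpool2 = { if (train) ly$cache_dim_in <- dim(x); avgpool2_forward(ly, x) },
    gap = gap_forward(ly, x, train),
    stop("unknown layer type: ", ly$type))
}

as_batch <- function(images) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    x <- array(0, c(d, length(images)))
    for (i in seq_along(images)) x[, , , i] <- images[[i]]
    x
  } else if (length(dim(images)) == 3L) {
    array(images, c(dim(images), 1L))
  } else images
}

#' Forward pass: images to prediction vectors
#'
#' Runs already resized/normalised images through the extractor and
#' head.  Evaluation mode: deterministic, a pure function of (weights,
#' input); one prediction vector (pre-softmax scores, length
#' `n_classes`) per image, whose argmax defines the predicted class.
#'
#' @param extractor A materialised `leafhair_extractor`.
#' @param head A classifier head from [build_classifier()].
#' @param images An `H x W x 3` image, an `H x W x 3 x N` batch, or a
#'   list of images.
#' @return `N x n_classes` matrix of prediction vectors.
#' @export
net_forward <- function(extractor, head, images) {
  if (!isTRUE(extractor$materialized))
    stop("extractor was built with init_weights = FALSE; rebuild to run forward")
  x <- as_batch(images)
  if (dim(x)[3] != 3L) stop("expected 3-channel images, got ", dim(x)[3])
  for (ly in extractor$layers) x <- node_forward(ly, x, train = FALSE)
  t(linear_forward(head, x))
}

forward_train <- function(extractor, head, x) {
  for (ly in extractor$layers) x <- node_forward(ly, x, train = TRUE)
  logits <- linear_forward(head, x, train = TRUE)
  logits
}

backward_train <- function(extractor, head, dlogits) {
  dx <- linear_backward(head, dlogits)
  for (ly in rev(extractor$layers)) {
    dx <- switch(ly$type,
      conv = conv_backward(ly, dx),
      bn = bn_backward(ly, dx),
      relu = relu_backward(ly, dx),
      lrelu = lrelu_backward(ly, dx),
      avgpool2 = avgpool2_backward(ly, dx, ly$cache_dim_in),
      gap = gap_backward(ly, dx),
      stop("layer type not supported in backward pass: ", ly$type))
  }
  invisible(dx)
}

# cross-entropy over logits [K, N]; targets integer 1..K
cross_entropy <- function(logits, targets) {
  K <- nrow(logits); N <- ncol(logits)
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  lse <- log(colSums(exp(z)))
  picked <- z[cbind(targets, seq_len(N))]
  loss <- mean(lse - picked)
  p <- sweep(exp(z), 2, exp(lse), "/")
  p[cbind(targets, seq_len(N))] <- p[cbind(targets, seq_len(N))] - 1
  list(loss = loss, dlogits = p / N)
}

# serialize / restore extractor + head weights (plain R lists -> RDS)
extractor_state <- function(extractor, head) {
  tl <- trainable_layers(extractor$layers)
  st <- lapply(tl, function(ly) as.list(ly)[c("W", "b", "gamma", "beta",
                                              "running_mean", "running_var")])
  list(config = extractor$config, seed = extractor$seed,
       layers = st, head = list(W = head$W, b = head$b,
                                fin = head$fin, fout = head$fout))
}

load_extractor_weights <- function(layers, state_layers) {
  tl <- trainable_layers(layers)
  if (length(tl) != length(state_layers))
    stop("weights asset does not match architecture (",
         length(state_layers), " vs ", length(tl), " trainable layers)")
  for (i in seq_along(tl)) {
    for (f in c("W", "b", "gamma", "beta", "running_mean", "running_var")) {
      v <- state_layers[[i]][[f]]
      if (!is.null(v)) assign(f, v, envir = tl[[i]])
    }
  }
  invisible(layers)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain R serialisations (RDS) of the weight state plus
#' the network configuration.
#'
#' @param extractor,head A materialised extractor and its head.
#' @param path Checkpoint path.
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`:
#'   a list with elements `extractor` and `head`.
#' @export
save_checkpoint <- function(extractor, head, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(extractor_state(extractor, head), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- readRDS(path)
  ex <- build_feature_extractor(st$config, seed = st$seed, init_weights = TRUE)
  load_extractor_weights(ex$layers, st$layers)
  head <- new_linear(st$head$fin, st$head$fout, init = FALSE)
  head$W <- st$head$W; head$b <- st$head$b
  list(extractor = ex, head = head)
}

#' @export
print.leafhair_extractor <- function(x, ...) {
  cat(sprintf("<feature extractor: depth %s, feature dim %d, %s parameters%s>\n",
              x$config$depth, x$feature_dim,
              format(count_trainable_parameters(x), big.mark = ","),
              if (x$materialized) "" else " (shapes only)"))
  invisible(x)
}
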