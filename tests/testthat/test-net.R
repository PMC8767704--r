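# closed-form parameter count of a headless basic-block residual
# network, written independently of the package's layer walk
resnet_basic_params <- function(nblocks) {
  stem <- 7 * 7 * 3 * 64 + 2 * 64
  planes <- c(64, 128, 256, 512)
  total <- stem
  cin <- 64
  for (stage in 1:4) {
    for (b in seq_len(nblocks[stage])) {
      p <- planes[stage]
      total <- total + 3 * 3 * cin * p + 2 * p + 3 * 3 * p * p + 2 * p
      if (cin != p) total <- total + cin * p + 2 * p  # 1x1 downsample + bn
      cin <- p
    }
  }
  total
}

test_that("parameter counts match architecture arithmetic exactly", {
  # independent closed-form oracle for both basic-block depths
  expect_identical(resnet_basic_params(c(3, 4, 6, 3)), 21284672)
  expect_equal(count_trainable_parameters(network_config(34)), 21284672)
  expect_equal(round(count_trainable_parameters(network_config(34)) / 1e6, 2),
               21.28)
  expect_equal(count_trainable_parameters(network_config(18)),
               resnet_basic_params(c(2, 2, 2, 2)))
  # depth is monotone in parameters
  counts <- vapply(c(18, 34, 50, 101, 152),
                   function(d) count_trainable_parameters(network_config(d)),
                   numeric(1))
  expect_true(all(diff(counts) > 0))
  # a single fully connected 512 -> 9 head
  head <- build_classifier(512, 9)
  expect_equal(count_trainable_parameters(head), 512 * 9 + 9)
})

test_that("feature dimensions follow the depth contract", {
  dims <- vapply(c(18, 34, 50, 101, 152), function(d)
    feature_dim(build_feature_extractor(network_config(d), init_weights = FALSE)),
    numeric(1))
  expect_equal(dims, c(512, 512, 2048, 2048, 2048))
  expect_equal(feature_dim(build_feature_extractor(network_config("tiny"))), 96)
  expect_error(network_config(77), "unsupported residual depth")
})

test_that("classifier head: shape, Kaiming-Uniform bound, determinism", {
  h <- build_classifier(512, 9, seed = 4)
  expect_identical(dim(h$W), c(9L, 512L))
  expect_true(all(abs(h$W) <= sqrt(6 / 512)))
  h2 <- build_classifier(512, 9, seed = 4)
  expect_identical(h$W, h2$W)
  expect_false(identical(h$W, build_classifier(512, 9, seed = 5)$W))
  h1 <- build_classifier(512, 1)
  expect_identical(nrow(h1$W), 1L)
  expect_error(build_classifier(8, 2, init = "glorot"), "unknown initializer")
})

test_that("pretrained weights are an optional external asset", {
  cfg <- network_config(18, pretrained = TRUE, weights_path = "nonexistent.rds")
  expect_error(build_feature_extractor(cfg), "no weights asset")
})

test_that("forward pass: shapes, determinism, batch equivariance", {
  ex <- build_feature_extractor(network_config("tiny"), seed = 1)
  head <- build_classifier(feature_dim(ex), 9, seed = 2)
  x <- withr::with_seed(3, array(runif(48 * 48 * 3 * 4), c(48, 48, 3, 4)))
  p <- net_forward(ex, head, x)
  expect_identical(dim(p), c(4L, 9L))
  # identical images give identical vectors in evaluation mode
  xx <- x; xx[, , , 2] <- x[, , , 1]
  p2 <- net_forward(ex, head, xx)
  expect_equal(p2[1, ], p2[2, ])
  # evaluation is a pure function of (weights, input)
  expect_identical(net_forward(ex, head, x), p)
  # permuting the batch permutes the outputs identically
  perm <- c(3, 1, 4, 2)
  expect_equal(net_forward(ex, head, x[, , , perm]), p[perm, ])
  # initial weights deterministic under a fixed seed
  ex2 <- build_feature_extractor(network_config("tiny"), seed = 1)
  expect_identical(ex$layers[[1]]$W, ex2$layers[[1]]$W)
})

test_that("a materialised residual extractor produces the contracted feature", {
  ex <- build_feature_extractor(network_config(18), seed = 6)
  head <- build_classifier(feature_dim(ex), 5, seed = 7)
  x <- withr::with_seed(8, array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  p <- net_forward(ex, head, x)
  expect_identical(dim(p), c(2L, 5L))
  expect_true(all(is.finite(p)))
})

test_that("backprop gradients match finite differences", {
  ex <- build_feature_extractor(network_config("tiny"), seed = 10)
  head <- build_classifier(feature_dim(ex), 3, seed = 11)
  x <- withr::with_seed(12, array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3)))
  tgt <- c(1L, 2L, 3L)
  eps <- 1e-6
  fwd <- function() leafhair:::cross_entropy(
    leafhair:::forward_train(ex, head, x), tgt)
  check_param <- function(ly, pname, i) {
    ce <- fwd()
    leafhair:::backward_train(ex, head, ce$dlogits)
    g <- ly[[paste0("d", pname)]][i]
    w0 <- ly[[pname]][i]
    ly[[pname]][i] <- w0 + eps
    l1 <- fwd()$loss
    ly[[pname]][i] <- w0 - eps
    l2 <- fwd()$loss
    ly[[pname]][i] <- w0
    expect_equal(g, (l1 - l2) / (2 * eps), tolerance = 1e-4)
  }
  check_param(ex$layers[[1]], "W", 13)    # first conv
  check_param(ex$layers[[1]], "b", 2)
  check_param(ex$layers[[4]], "W", 101)   # a deeper conv
  check_param(head, "W", 7)
  check_param(head, "b", 2)
})

test_that("batch-norm training gradients match finite differences", {
  # hand-built stack exercising the BN train/backward path used by
  # residual architectures
  ex <- withr::with_seed(30, {
    conv <- leafhair:::new_conv(3L, 6L, 3L, 1L, 1L, bias = FALSE, init = TRUE)
    list(layers = list(conv, leafhair:::new_bn(6L),
                       leafhair:::new_simple("relu"),
                       leafhair:::new_simple("gap")),
         feature_dim = 6L, materialized = TRUE)
  })
  head <- build_classifier(6, 3, seed = 31)
  x <- withr::with_seed(32, array(runif(12 * 12 * 3 * 4), c(12, 12, 3, 4)))
  tgt <- c(1L, 2L, 3L, 1L)
  eps <- 1e-6
  for (probe in list(list(ex$layers[[2]], "gamma", 4),
                     list(ex$layers[[2]], "beta", 2),
                     list(ex$layers[[1]], "W", 20))) {
    ly <- probe[[1]]; pname <- probe[[2]]; i <- probe[[3]]
    ce <- leafhair:::cross_entropy(leafhair:::forward_train(ex, head, x), tgt)
    leafhair:::backward_train(ex, head, ce$dlogits)
    g <- ly[[paste0("d", pname)]][i]
    w0 <- ly[[pname]][i]
    ly[[pname]][i] <- w0 + eps
    l1 <- leafhair:::cross_entropy(leafhair:::forward_train(ex, head, x), tgt)$loss
    ly[[pname]][i] <- w0 - eps
    l2 <- leafhair:::cross_entropy(leafhair:::forward_train(ex, head, x), tgt)$loss
    ly[[pname]][i] <- w0
    expect_equal(g, (l1 - l2) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip through disk", {
  ex <- build_feature_extractor(network_config("tiny"), seed = 20)
  head <- build_classifier(feature_dim(ex), 4, seed = 21)
  x <- withr::with_seed(22, array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  p <- net_forward(ex, head, x)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ex, head, ck)
  restored <- load_checkpoint(ck)
  expect_equal(net_forward(restored$extractor, restored$head, x), p)
})
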