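test_that("configuration contract: input size must suit the depth", {
  expect_error(net_config(input_size = 60, depth = 3),
               class = "bw_validation_error")
  expect_error(net_config(cls_classes = 3), class = "bw_validation_error")
  expect_s3_class(net_config(input_size = 64, depth = 3), "net_config")
})

test_that("forward pass obeys the shape and normalisation contracts", {
  for (cfg in list(net_config(input_size = 16, depth = 2, base_channels = 4),
                   net_config(input_size = 32, depth = 3, base_channels = 4),
                   net_config(input_size = 16, depth = 1, base_channels = 8,
                              channel_multiplier = 3))) {
    net <- build_network(cfg, seed = 2)
    s <- cfg$input_size
    x <- array(runif(s * s * 3), dim = c(s, s, 3))
    out <- forward(net, x)
    expect_identical(dim(out$seg_prob), c(s, s))
    expect_true(all(out$seg_prob >= 0 & out$seg_prob <= 1))
    expect_length(out$cls_prob, 2)
    expect_true(all(out$cls_prob >= 0))
    expect_lt(abs(sum(out$cls_prob) - 1), 1e-6)
  }
})

test_that("degenerate and repeated inputs: finite outputs, deterministic", {
  net <- build_network(tiny_net_config(), seed = 4)
  x0 <- array(0, dim = c(16, 16, 3))
  out0 <- forward(net, x0)
  expect_true(all(is.finite(out0$seg_prob)))
  expect_lt(abs(sum(out0$cls_prob) - 1), 1e-6)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_identical(forward(net, x), forward(net, x))
  expect_error(forward(net, array(0, dim = c(8, 8, 3))),
               class = "bw_validation_error")
})

test_that("parameter count matches an independent layer-by-layer tally", {
  # default architecture: 64x64x3 input, depth 3, base 16, x2 per level,
  # bottleneck 128, hidden dense stage 64, 2-way output
  conv <- function(cin, cout) cout * 9 * cin + cout
  tconv <- function(cin, cout) cout * 4 * cin + cout
  dense <- function(cin, cout) cout * cin + cout
  expected <-
    conv(3, 16) + conv(16, 16) +          # encoder level 1
    conv(16, 32) + conv(32, 32) +         # encoder level 2
    conv(32, 64) + conv(64, 64) +         # encoder level 3
    conv(64, 128) + conv(128, 128) +      # bottleneck
    tconv(128, 64) + conv(128, 64) + conv(64, 64) +  # decoder level 3
    tconv(64, 32) + conv(64, 32) + conv(32, 32) +    # decoder level 2
    tconv(32, 16) + conv(32, 16) + conv(16, 16) +    # decoder level 1
    (16 + 1) +                            # 1x1 segmentation output
    dense(128, 64) + dense(64, 2)         # classification head
  net <- build_network(net_config(), seed = 1)
  expect_identical(n_params(net), expected)
})

test_that("every trainable parameter receives gradient on some batch", {
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 6)
  set.seed(10)
  x <- array(runif(16 * 16 * 3 * 4), dim = c(16, 16, 3, 4))
  m <- array(rbinom(16 * 16 * 4, 1, 0.3), dim = c(16, 16, 4))
  y <- c(0L, 1L, 1L, 0L)
  res <- bleedwatch:::eng_train_batch(net$weights,
                                      bleedwatch:::engine_cfg(cfg),
                                      x, m, y, 1e-7)
  for (nm in names(net$weights)) {
    expect_true(any(res$grads[[nm]]$W != 0), label = paste(nm, "W grad"))
    expect_true(any(res$grads[[nm]]$b != 0), label = paste(nm, "b grad"))
  }
})

test_that("the encoder is shared: encoder weights touch both branches", {
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 6)
  set.seed(11)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  base <- forward(net, x)

  enc <- net
  enc$weights$enc1_conv1$W[1, 1] <- enc$weights$enc1_conv1$W[1, 1] + 0.5
  pert <- forward(enc, x)
  expect_gt(max(abs(pert$seg_prob - base$seg_prob)), 0)
  expect_gt(max(abs(pert$cls_prob - base$cls_prob)), 0)

  dec <- net
  dec$weights$dec1_conv2$W[1, 1] <- dec$weights$dec1_conv2$W[1, 1] + 0.5
  pert2 <- forward(dec, x)
  expect_gt(max(abs(pert2$seg_prob - base$seg_prob)), 0)
  expect_identical(pert2$cls_prob, base$cls_prob)

  cls <- net
  cls$weights$cls_fc1$W[1, 1] <- cls$weights$cls_fc1$W[1, 1] + 0.5
  pert3 <- forward(cls, x)
  expect_identical(pert3$seg_prob, base$seg_prob)
  expect_gt(max(abs(pert3$cls_prob - base$cls_prob)), 0)
})

test_that("analytic gradients agree with finite differences on a small net", {
  cfg <- net_config(input_size = 8, depth = 1, base_channels = 2,
                    hidden_units = 3)
  net <- build_network(cfg, seed = 3)
  ecfg <- bleedwatch:::engine_cfg(cfg)
  set.seed(12)
  x <- array(runif(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))
  m <- array(rbinom(8 * 8 * 2, 1, 0.3), dim = c(8, 8, 2))
  y <- c(0L, 1L)
  res <- bleedwatch:::eng_train_batch(net$weights, ecfg, x, m, y, 1e-7)
  h <- 1e-3
  for (nm in c("enc1_conv1", "bott_conv2", "up1", "dec1_conv1", "seg_out",
               "cls_fc2")) {
    i <- which.max(abs(res$grads[[nm]]$W))
    wp <- net$weights; wp[[nm]]$W[i] <- wp[[nm]]$W[i] + h
    wm <- net$weights; wm[[nm]]$W[i] <- wm[[nm]]$W[i] - h
    num <- (bleedwatch:::eng_train_batch(wp, ecfg, x, m, y, 1e-7)$total -
            bleedwatch:::eng_train_batch(wm, ecfg, x, m, y, 1e-7)$total) /
      (2 * h)
    ana <- res$grads[[nm]]$W[i]
    expect_lt(abs(num - ana) / (abs(num) + abs(ana)), 0.02, label = nm)
  }
})

test_that("checkpoints round-trip weights and configuration", {
  dir <- withr::local_tempdir()
  net <- build_network(tiny_net_config(), seed = 9)
  path <- file.path(dir, "ckpt.rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_equal(back$config, net$config)
  expect_equal(back$weights, net$weights)
  expect_error(load_checkpoint(file.path(dir, "nope.rds")),
               class = "bw_io_error")
})
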