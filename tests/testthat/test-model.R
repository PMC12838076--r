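# A tiny configuration used for gradient and wiring checks; topology is the
# full architecture, widths are minimal.
tiny_cfg <- function() model_config(input_length = 128,
                                    width_multiplier = 1 / 32, n_heads = 2)

tiny_batch <- function(B = 3, cfg = tiny_cfg(), seed = 7) {
  set.seed(seed)
  list(
    x = matrix(rnorm(B * cfg$input_length), B),
    aux = matrix(rnorm(B * cfg$aux_dim), B),
    target = do.call(rbind, lapply(seq_len(B) * 30, soft_label))
  )
}

test_that("reference-width model matches the printed layer sizes", {
  cfg <- model_config()
  expect_equal(cfg$stem_channels, 64)
  expect_equal(cfg$stage_channels, c(256, 512, 1024, 2048))
  expect_equal(cfg$d_model, 256)
  expect_equal(cfg$ffn_dim, 2048)
  expect_equal(cfg$aux_embed, 256)
  expect_equal(cfg$n_classes, 180)

  m <- build_model(cfg, seed = 1)
  fw <- model_forward(m, matrix(rnorm(1250), 1), matrix(rnorm(6), 1))
  expect_equal(fw$stem_dim[3], 64)           # stem emits 64 channels
  expect_equal(ncol(fw$pooled), 2048)        # pooled feature length 2048
  expect_equal(ncol(fw$probs), 180)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
  expect_true(all(fw$probs > 0))
})

test_that("parameter count at reference width is the recorded constant", {
  # regression constant, hand-derived once from the layer dimensions
  m <- build_model(model_config(), seed = 1)
  expect_equal(n_parameters(m), 20310198)
})

test_that("too-short inputs fail at build/forward time with a shape error", {
  expect_error(model_config(input_length = 16), "too short")
})

test_that("forward pass is deterministic and seed-reproducible", {
  cfg <- tiny_cfg()
  b <- tiny_batch()
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  f1 <- model_forward(m1, b$x, b$aux)
  f2 <- model_forward(m2, b$x, b$aux)
  expect_identical(f1$probs, f2$probs)
  m3 <- build_model(cfg, seed = 6)
  expect_false(identical(model_forward(m3, b$x, b$aux)$probs, f1$probs))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 2)
  b <- tiny_batch()
  loss_fn <- function(model) {
    fw <- model_forward(model, b$x, b$aux, training = TRUE)
    ppglucose:::kl_batch_loss(b$target, fw$probs)
  }
  fw <- model_forward(m, b$x, b$aux, training = TRUE)
  bw <- ppglucose:::model_backward(m, fw$cache, (fw$probs - b$target) / 3)

  paths <- list(
    c("stages", "1", "1", "conv2", "W"),
    c("stages", "2", "1", "down", "W"),
    c("stages", "4", "2", "bn3", "beta"),
    c("proj", "W"), c("pos"),
    c("tf", "1", "Wq"), c("tf", "1", "ffn1", "W"),
    c("tf", "2", "ln2", "gamma"),
    c("expand", "W"), c("aux", "W"), c("fuse", "W"), c("head", "b")
  )
  get_leaf <- function(p, path) {
    for (k in path) {
      ki <- suppressWarnings(as.integer(k))
      p <- if (is.na(ki)) p[[k]] else p[[ki]]
    }
    p
  }
  set_leaf <- function(p, path, value) {
    if (length(path) == 1) {
      ki <- suppressWarnings(as.integer(path))
      if (is.na(ki)) p[[path]] <- value else p[[ki]] <- value
      return(p)
    }
    k <- path[1]
    ki <- suppressWarnings(as.integer(k))
    if (is.na(ki)) {
      p[[k]] <- set_leaf(p[[k]], path[-1], value)
    } else {
      p[[ki]] <- set_leaf(p[[ki]], path[-1], value)
    }
    p
  }
  set.seed(3)
  for (pt in paths) {
    leaf <- get_leaf(m$params, pt)
    gleaf <- get_leaf(bw$grads, pt)
    i <- sample(length(leaf), 1)
    # piecewise-linear units make single-step finite differences unreliable
    # near kinks; agreement at any step size validates the gradient
    rel <- min(vapply(c(1e-6, 1e-7, 1e-8), function(h) {
      up <- leaf; up[i] <- up[i] + h
      dn <- leaf; dn[i] <- dn[i] - h
      mp <- m; mp$params <- set_leaf(m$params, pt, up)
      mm <- m; mm$params <- set_leaf(m$params, pt, dn)
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * h)
      abs(num - gleaf[i]) / max(1e-8, abs(num) + abs(gleaf[i]))
    }, numeric(1)))
    expect_lt(rel, 1e-4)
  }
})

test_that("gradient flows to the auxiliary inputs", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 2)
  b <- tiny_batch()
  fw <- model_forward(m, b$x, b$aux, training = TRUE)
  bw <- ppglucose:::model_backward(m, fw$cache, (fw$probs - b$target) / 3)
  expect_gt(sqrt(sum(bw$daux^2)), 0)
  expect_equal(dim(bw$daux), dim(b$aux))
})

test_that("glucose predictions map argmax classes to bin centres", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 4)
  b <- tiny_batch(B = 5)
  pred <- predict_glucose(m, b$x, b$aux)
  expect_length(pred, 5)
  expect_true(all(pred >= 70.5 & pred <= 249.5))

  # forcing the head to a one-hot response at class 0 predicts 70.5
  m0 <- m
  m0$params$head$W[] <- 0
  m0$params$head$b <- c(10, rep(0, 179))
  expect_true(all(predict_glucose(m0, b$x, b$aux) == 70.5))
  # uniform logits tie-break to the lowest class
  m0$params$head$b <- rep(0, 180)
  mu <- m0
  mu$params$fuse$W[] <- 0
  mu$params$fuse$b[] <- 0
  expect_true(all(predict_glucose(mu, b$x, b$aux) == 70.5))
})

test_that("width multipliers preserve topology while scaling channels", {
  cfg <- model_config(width_multiplier = 1 / 8)
  expect_equal(cfg$stem_channels, 8)
  expect_equal(cfg$stage_channels, c(32, 64, 128, 256))
  expect_equal(cfg$d_model %% cfg$n_heads, 0)
  expect_equal(cfg$n_classes, 180)
  m <- build_model(cfg, seed = 1)
  fw <- model_forward(m, matrix(rnorm(1250), 1), matrix(rnorm(6), 1))
  expect_equal(ncol(fw$probs), 180)
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
})
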