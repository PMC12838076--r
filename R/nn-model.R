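#' Model configuration for the 1D ResNet-Transformer glucose classifier
#'
#' At `width_multiplier = 1` this reproduces the reference architecture: a
#' 1D convolutional stem (64 kernels of size 7, stride 2) with 3-wide
#' stride-2 max pooling, four bottleneck ResNet stages with output channels
#' (256, 512, 1024, 2048) and block counts (3, 4, 6, 3), a linear
#' projection to 256-wide tokens with learned positional embeddings, two
#' Transformer blocks (4-head self-attention, feed-forward 256 to 2048),
#' expansion back to 2048 channels with global average pooling, a
#' 6-dimensional auxiliary-feature branch embedded to 256, concatenation
#' (2048 + 256), a 256-wide fusion layer and a softmax head over 180
#' glucose classes. `width_multiplier` scales every channel count (and the
#' token width, kept divisible by the head count) while preserving
#' topology, so the same network trains in minutes on a CPU at toy width.
#'
#' @param input_length Waveform samples per segment (default 1250).
#' @param n_classes Output classes (default 180, fixed by the 70-250 mg/dL
#'   grid).
#' @param width_multiplier Channel scaling factor in (0, 1].
#' @param n_heads Attention heads (default 4).
#' @param stage_blocks Bottleneck block counts per stage.
#' @param aux_dim Auxiliary feature dimension (default 6).
#'
#' @return A `model_config` list with derived layer widths.
#' @export
model_config <- function(input_length = 1250, n_classes = 180,
                         width_multiplier = 1, n_heads = 4,
                         stage_blocks = c(3, 4, 6, 3), aux_dim = 6) {
  stopifnot(width_multiplier > 0, width_multiplier <= 1)
  m <- width_multiplier
  ch <- function(x) max(1L, as.integer(round(x * m)))
  d_model <- n_heads * max(1L, as.integer(round(256 * m / n_heads)))
  cfg <- list(
    input_length = as.integer(input_length),
    n_classes = as.integer(n_classes),
    width_multiplier = m,
    n_heads = as.integer(n_heads),
    stage_blocks = as.integer(stage_blocks),
    stem_channels = ch(64),
    stage_channels = vapply(c(256, 512, 1024, 2048), ch, integer(1)),
    d_model = d_model,
    ffn_dim = ch(2048),
    aux_dim = as.integer(aux_dim),
    aux_embed = ch(256),
    fusion_dim = ch(256)
  )
  # length through the stride chain: stem conv s2 (pad 3), max pool s2
  # (pad 1), then one stride-2 block in stages 2-4
  L <- (cfg$input_length + 2 * 3 - 7) %/% 2 + 1
  L <- (L + 2 * 1 - 3) %/% 2 + 1
  lens <- integer(4)
  for (s in 1:4) {
    if (s > 1) L <- (L + 2 * 1 - 3) %/% 2 + 1
    lens[s] <- L
  }
  # at least two tokens must survive the stride chain for the attention
  # stage to model temporal order
  if (any(lens < 1) || lens[4] < 2) {
    stop("input_length ", input_length, " is too short for the stride chain")
  }
  cfg$stage_lengths <- lens
  cfg$n_tokens <- lens[4]
  structure(cfg, class = "model_config")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

init_conv <- function(k, cin, cout) {
  list(W = he_init(c(k, cin, cout), k * cin), b = numeric(cout))
}

init_linear <- function(din, dout) {
  list(W = matrix(rnorm(din * dout, 0, sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

init_bn_param <- function(c) list(gamma = rep(1, c), beta = numeric(c))

init_bn_state <- function(c) list(mean = numeric(c), var = rep(1, c))

#' Build the glucose classification model
#'
#' Initializes all weights (He initialization for convolutions and linear
#' maps, unit batch-norm scales) under a fixed seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `glucose_model`: list with `config`, `params` (nested weight
#'   tree) and `state` (batch-norm running statistics).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  mid_channels <- pmax(1L, config$stage_channels %/% 4L)
  with_seed(seed, {
    params <- list()
    state <- list()
    params$stem <- c(init_conv(7, 1, config$stem_channels),
                     list(bn = init_bn_param(config$stem_channels)))
    state$stem_bn <- init_bn_state(config$stem_channels)

    params$stages <- vector("list", 4)
    state$stages <- vector("list", 4)
    cin <- config$stem_channels
    for (s in 1:4) {
      cout <- config$stage_channels[s]
      mid <- mid_channels[s]
      n_blk <- config$stage_blocks[s]
      params$stages[[s]] <- vector("list", n_blk)
      state$stages[[s]] <- vector("list", n_blk)
      for (blk in seq_len(n_blk)) {
        bp <- list(
          conv1 = init_conv(1, cin, mid), bn1 = init_bn_param(mid),
          conv2 = init_conv(3, mid, mid), bn2 = init_bn_param(mid),
          conv3 = init_conv(1, mid, cout), bn3 = init_bn_param(cout)
        )
        bs <- list(bn1 = init_bn_state(mid), bn2 = init_bn_state(mid),
                   bn3 = init_bn_state(cout))
        if (blk == 1) {
          bp$down <- c(init_conv(1, cin, cout),
                       list(bn = init_bn_param(cout)))
          bs$bnd <- init_bn_state(cout)
        }
        params$stages[[s]][[blk]] <- bp
        state$stages[[s]][[blk]] <- bs
        cin <- cout
      }
    }

    d <- config$d_model
    params$proj <- init_linear(config$stage_channels[4], d)
    params$pos <- matrix(rnorm(config$n_tokens * d, 0, 0.02),
                         config$n_tokens, d)
    params$tf <- lapply(1:2, function(i) {
      list(
        Wq = he_init(c(d, d), d), bq = numeric(d),
        Wk = he_init(c(d, d), d), bk = numeric(d),
        Wv = he_init(c(d, d), d), bv = numeric(d),
        Wo = he_init(c(d, d), d), bo = numeric(d),
        ln1 = list(gamma = rep(1, d), beta = numeric(d)),
        ffn1 = init_linear(d, config$ffn_dim),
        ffn2 = init_linear(config$ffn_dim, d),
        ln2 = list(gamma = rep(1, d), beta = numeric(d))
      )
    })
    params$expand <- init_linear(d, config$stage_channels[4])
    params$aux <- init_linear(config$aux_dim, config$aux_embed)
    # gated fusion: each branch is layer-normalized and carries a learnable
    # scalar gain, so the fusion can reweight the waveform embedding against
    # the auxiliary embedding (the attention-style fusion of the design)
    params$gains <- c(1, 1)
    params$fuse <- init_linear(config$stage_channels[4] + config$aux_embed,
                               config$fusion_dim)
    params$head <- init_linear(config$fusion_dim, config$n_classes)

    structure(list(config = config, params = params, state = state),
              class = "glucose_model")
  })
}

#' @export
print.glucose_model <- function(x, ...) {
  cat(sprintf(
    "<glucose_model> width x%.3g: stem %d ch, stages (%s), %d tokens x %d, %d classes, %s parameters\n",
    x$config$width_multiplier, x$config$stem_channels,
    paste(x$config$stage_channels, collapse = ", "),
    x$config$n_tokens, x$config$d_model, x$config$n_classes,
    format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `glucose_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  tree_sum(model$params, function(x) rep(1, length(x)))
}

block_forward <- function(x, bp, bs, stride, training) {
  c1 <- conv1d_forward(x, bp$conv1$W, bp$conv1$b, 1L, 0L)
  b1 <- bn_forward(c1$out, bp$bn1$gamma, bp$bn1$beta, bs$bn1, training)
  r1 <- relu_forward(b1$out)
  c2 <- conv1d_forward(r1$out, bp$conv2$W, bp$conv2$b, stride, 1L)
  b2 <- bn_forward(c2$out, bp$bn2$gamma, bp$bn2$beta, bs$bn2, training)
  r2 <- relu_forward(b2$out)
  c3 <- conv1d_forward(r2$out, bp$conv3$W, bp$conv3$b, 1L, 0L)
  b3 <- bn_forward(c3$out, bp$bn3$gamma, bp$bn3$beta, bs$bn3, training)
  if (!is.null(bp$down)) {
    cd <- conv1d_forward(x, bp$down$W, bp$down$b, stride, 0L)
    bd <- bn_forward(cd$out, bp$down$bn$gamma, bp$down$bn$beta, bs$bnd,
                     training)
    skip <- bd$out
    bs$bnd <- bd$state
  } else {
    cd <- NULL
    bd <- NULL
    skip <- x
  }
  pre <- b3$out + skip
  ro <- relu_forward(pre)
  bs$bn1 <- b1$state
  bs$bn2 <- b2$state
  bs$bn3 <- b3$state
  list(out = ro$out, state = bs,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    c3 = c3$cache, b3 = b3$cache,
                    cd = if (is.null(cd)) NULL else cd$cache,
                    bd = if (is.null(bd)) NULL else bd$cache,
                    ro = ro$cache, has_down = !is.null(bp$down)))
}

block_backward <- function(dout, bp, cache) {
  dpre <- relu_backward(dout, cache$ro)
  db3 <- bn_backward(dpre, bp$bn3$gamma, cache$b3)
  dc3 <- conv1d_backward(db3$dx, bp$conv3$W, cache$c3)
  dr2 <- relu_backward(dc3$dx, cache$r2)
  db2 <- bn_backward(dr2, bp$bn2$gamma, cache$b2)
  dc2 <- conv1d_backward(db2$dx, bp$conv2$W, cache$c2)
  dr1 <- relu_backward(dc2$dx, cache$r1)
  db1 <- bn_backward(dr1, bp$bn1$gamma, cache$b1)
  dc1 <- conv1d_backward(db1$dx, bp$conv1$W, cache$c1)
  dx <- dc1$dx
  grads <- list(
    conv1 = list(W = dc1$dW, b = dc1$db),
    bn1 = list(gamma = db1$dgamma, beta = db1$dbeta),
    conv2 = list(W = dc2$dW, b = dc2$db),
    bn2 = list(gamma = db2$dgamma, beta = db2$dbeta),
    conv3 = list(W = dc3$dW, b = dc3$db),
    bn3 = list(gamma = db3$dgamma, beta = db3$dbeta)
  )
  if (cache$has_down) {
    dbd <- bn_backward(dpre, bp$down$bn$gamma, cache$bd)
    dcd <- conv1d_backward(dbd$dx, bp$down$W, cache$cd)
    dx <- dx + dcd$dx
    grads$down <- list(W = dcd$dW, b = dcd$db,
                       bn = list(gamma = dbd$dgamma, beta = dbd$dbeta))
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

tf_forward <- function(x, tp, n_heads) {
  at <- mha_forward(x, tp, n_heads)
  s1 <- x + at$out
  l1 <- ln_forward(s1, tp$ln1$gamma, tp$ln1$beta)
  d <- dim(l1$out)
  xm <- as_mat(l1$out)
  f1 <- linear_forward(xm, tp$ffn1$W, tp$ffn1$b)
  fr <- relu_forward(f1$out)
  f2 <- linear_forward(fr$out, tp$ffn2$W, tp$ffn2$b)
  s2 <- l1$out + as_arr(f2$out, d)
  l2 <- ln_forward(s2, tp$ln2$gamma, tp$ln2$beta)
  list(out = l2$out,
       cache = list(at = at$cache, l1 = l1$cache, f1 = f1$cache,
                    fr = fr$cache, f2 = f2$cache, l2 = l2$cache, d = d))
}

tf_backward <- function(dout, tp, cache) {
  dl2 <- ln_backward(dout, tp$ln2$gamma, cache$l2)
  ds2 <- dl2$dx
  df2 <- linear_backward(as_mat(ds2), tp$ffn2$W, cache$f2)
  dfr <- relu_backward(df2$dx, cache$fr)
  df1 <- linear_backward(dfr, tp$ffn1$W, cache$f1)
  dl1_total <- ds2 + as_arr(df1$dx, cache$d)
  dl1 <- ln_backward(dl1_total, tp$ln1$gamma, cache$l1)
  ds1 <- dl1$dx
  dat <- mha_backward(ds1, tp, cache$at)
  dx <- ds1 + dat$dx
  grads <- dat$grads
  grads$ln1 <- list(gamma = dl1$dgamma, beta = dl1$dbeta)
  grads$ffn1 <- list(W = df1$dW, b = df1$db)
  grads$ffn2 <- list(W = df2$dW, b = df2$db)
  grads$ln2 <- list(gamma = dl2$dgamma, beta = dl2$dbeta)
  list(dx = dx, grads = grads)
}

#' Forward pass of the glucose model
#'
#' @param model A `glucose_model`.
#' @param x Waveform matrix (batch x input_length), z-scored segments.
#' @param aux Auxiliary feature matrix (batch x 6), already scaled.
#' @param training Use batch statistics and update running batch-norm
#'   state (`TRUE`) or the stored running statistics (`FALSE`).
#' @return A list: `probs` (batch x n_classes softmax output), `logits`,
#'   `pooled` (batch x 2048-multiplied pooled features), `stem` (stem
#'   activation shape), `cache` (for backward), `state` (updated running
#'   statistics).
#' @export
model_forward <- function(model, x, aux, training = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(aux))) aux <- matrix(aux, 1)
  B <- nrow(x)
  stopifnot(ncol(x) == cfg$input_length, ncol(aux) == cfg$aux_dim,
            nrow(aux) == B)
  cache <- list()

  xa <- array(x, c(B, cfg$input_length, 1L))
  cs <- conv1d_forward(xa, p$stem$W, p$stem$b, 2L, 3L)
  bs <- bn_forward(cs$out, p$stem$bn$gamma, p$stem$bn$beta, st$stem_bn,
                   training)
  st$stem_bn <- bs$state
  rs <- relu_forward(bs$out)
  mp <- maxpool_forward(rs$out, 3L, 2L, 1L)
  h <- mp$out
  stem_dim <- dim(rs$out)
  cache$stem <- list(cs = cs$cache, bs = bs$cache, rs = rs$cache,
                     mp = mp$cache)

  cache$stages <- vector("list", 4)
  for (s in 1:4) {
    n_blk <- cfg$stage_blocks[s]
    cache$stages[[s]] <- vector("list", n_blk)
    for (blk in seq_len(n_blk)) {
      stride <- if (blk == 1 && s > 1) 2L else 1L
      bf <- block_forward(h, p$stages[[s]][[blk]], st$stages[[s]][[blk]],
                          stride, training)
      h <- bf$out
      st$stages[[s]][[blk]] <- bf$state
      cache$stages[[s]][[blk]] <- bf$cache
    }
  }

  # project CNN features to token width, add positional embeddings
  dcnn <- dim(h)
  Tn <- dcnn[2]
  hm <- as_mat(h)
  pj <- linear_forward(hm, p$proj$W, p$proj$b)
  tok <- pj$out + p$pos[rep(seq_len(Tn), each = B), , drop = FALSE]
  tok <- as_arr(tok, c(B, Tn, cfg$d_model))
  cache$proj <- list(x = pj$cache, dcnn = dcnn)

  cache$tf <- vector("list", 2)
  for (i in 1:2) {
    tfw <- tf_forward(tok, p$tf[[i]], cfg$n_heads)
    tok <- tfw$out
    cache$tf[[i]] <- tfw$cache
  }

  # expand back to the pooled feature width, global average pooling
  em <- linear_forward(as_mat(tok), p$expand$W, p$expand$b)
  grp <- rep(seq_len(B), times = Tn)
  pooled <- rowsum(em$out, grp) / Tn
  cache$expand <- list(x = em$cache, Tn = Tn, B = B)

  af <- linear_forward(aux, p$aux$W, p$aux$b)
  ar <- relu_forward(af$out)
  np <- ncol(pooled)
  na <- ncol(ar$out)
  pl <- ln_forward(as_arr(pooled, c(B, 1L, np)), rep(1, np), numeric(np))
  al <- ln_forward(as_arr(ar$out, c(B, 1L, na)), rep(1, na), numeric(na))
  pooled_n <- as_arr(pl$out, c(B, np))
  aux_n <- as_arr(al$out, c(B, na))
  fused_in <- cbind(p$gains[1] * pooled_n, p$gains[2] * aux_n)
  fu <- linear_forward(fused_in, p$fuse$W, p$fuse$b)
  fr <- relu_forward(fu$out)
  hd <- linear_forward(fr$out, p$head$W, p$head$b)
  probs <- softmax_rows(hd$out)
  cache$heads <- list(af = af$cache, ar = ar$cache, fu = fu$cache,
                      fr = fr$cache, hd = hd$cache,
                      pl = pl$cache, al = al$cache,
                      pooled_n = pooled_n, aux_n = aux_n,
                      n_pool = np, n_aux = na)

  list(probs = probs, logits = hd$out, pooled = pooled,
       stem_dim = stem_dim, cache = cache, state = st)
}

# Backward pass from d(loss)/d(logits); returns the full gradient tree
# (mirroring model$params) plus the gradient w.r.t. the auxiliary inputs.
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()

  hd <- linear_backward(dlogits, p$head$W, cache$heads$hd)
  g$head <- list(W = hd$dW, b = hd$db)
  dfr <- relu_backward(hd$dx, cache$heads$fr)
  fu <- linear_backward(dfr, p$fuse$W, cache$heads$fu)
  g$fuse <- list(W = fu$dW, b = fu$db)
  np <- cache$heads$n_pool
  na <- cache$heads$n_aux
  B1 <- nrow(dlogits)
  dfused <- fu$dx
  dpn <- dfused[, seq_len(np), drop = FALSE]
  dan <- dfused[, np + seq_len(na), drop = FALSE]
  g$gains <- c(sum(dpn * cache$heads$pooled_n),
               sum(dan * cache$heads$aux_n))
  dpl <- ln_backward(as_arr(dpn * p$gains[1], c(B1, 1L, np)),
                     rep(1, np), cache$heads$pl)
  dal <- ln_backward(as_arr(dan * p$gains[2], c(B1, 1L, na)),
                     rep(1, na), cache$heads$al)
  dpooled <- as_arr(dpl$dx, c(B1, np))
  dar <- relu_backward(as_arr(dal$dx, c(B1, na)), cache$heads$ar)
  af <- linear_backward(dar, p$aux$W, cache$heads$af)
  g$aux <- list(W = af$dW, b = af$db)
  daux_in <- af$dx

  B <- cache$expand$B
  Tn <- cache$expand$Tn
  dem <- dpooled[rep(seq_len(B), times = Tn), , drop = FALSE] / Tn
  em <- linear_backward(dem, p$expand$W, cache$expand$x)
  g$expand <- list(W = em$dW, b = em$db)
  dtok <- as_arr(em$dx, c(B, Tn, cfg$d_model))

  g$tf <- vector("list", 2)
  for (i in 2:1) {
    tb <- tf_backward(dtok, p$tf[[i]], cache$tf[[i]])
    dtok <- tb$dx
    g$tf[[i]] <- tb$grads
  }

  dtokm <- as_mat(dtok)
  g$pos <- rowsum(dtokm, rep(seq_len(Tn), each = B))
  pj <- linear_backward(dtokm, p$proj$W, cache$proj$x)
  g$proj <- list(W = pj$dW, b = pj$db)
  dh <- as_arr(pj$dx, cache$proj$dcnn)

  g$stages <- vector("list", 4)
  for (s in 4:1) {
    n_blk <- cfg$stage_blocks[s]
    g$stages[[s]] <- vector("list", n_blk)
    for (blk in n_blk:1) {
      bb <- block_backward(dh, p$stages[[s]][[blk]],
                           cache$stages[[s]][[blk]])
      dh <- bb$dx
      g$stages[[s]][[blk]] <- bb$grads
    }
  }

  dmp <- maxpool_backward(dh, cache$stem$mp)
  drs <- relu_backward(dmp, cache$stem$rs)
  dbs <- bn_backward(drs, p$stem$bn$gamma, cache$stem$bs)
  dcs <- conv1d_backward(dbs$dx, p$stem$W, cache$stem$cs)
  g$stem <- list(W = dcs$dW, b = dcs$db,
                 bn = list(gamma = dbs$dgamma, beta = dbs$dbeta))

  list(grads = g, daux = daux_in)
}

#' Predict glucose values in mg/dL
#'
#' Runs the model in inference mode and maps the arg-max class to its bin
#' centre (70.5 + class). Ties resolve to the lowest class index.
#'
#' @param model A `glucose_model` or `glucose_fit`.
#' @param x Waveform matrix (batch x input_length) or a single numeric
#'   vector.
#' @param aux Auxiliary feature matrix (batch x 6), scaled as in training.
#' @return Numeric vector of predicted glucose values in `[70.5, 249.5]`.
#' @export
predict_glucose <- function(model, x, aux) {
  if (inherits(model, "glucose_fit")) model <- model$model
  fw <- model_forward(model, x, aux, training = FALSE)
  cls <- apply(fw$probs, 1, which.max) - 1L
  class_to_glucose(cls)
}
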