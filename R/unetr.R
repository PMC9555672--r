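#' UNETR architecture configuration
#'
#' Hyper-parameters of the 3D UNETR segmentation network: a vision
#' transformer encodes non-overlapping cubic patches of the input window;
#' a convolutional decoder upsamples the bottleneck back to full resolution,
#' merging skip connections taken from intermediate transformer layers (and
#' a full-resolution projection of the raw input at the last stage).
#'
#' The working defaults mirror the published CBCT models: 128-voxel input
#' window, 16-voxel patches (512 tokens), hidden width 768, feed-forward
#' width 3072, 12 heads, 12 layers with skips tapped at layers 3/6/9/12,
#' base decoder width 16, dropout 5%, two output classes. Every dimension is
#' configurable, so a CPU-sized configuration exists for testing and small
#' experiments.
#'
#' @param window_edge input window edge, voxels; divisible by `patch_edge`.
#' @param patch_edge patch edge, voxels; a power of two.
#' @param hidden_dim transformer embedding width; divisible by `num_heads`.
#' @param mlp_dim feed-forward width.
#' @param num_heads attention heads.
#' @param num_layers transformer depth.
#' @param skip_layers strictly increasing encoder layers tapped for skip
#'   connections; the deepest tap feeds the decoder bottleneck.
#' @param feature_size base decoder channel count; stage widths are
#'   `feature_size * {8, 4, 2, 1}` (for 16-voxel patches).
#' @param dropout_rate dropout fraction in `[0, 1)`.
#' @param out_channels output classes (background + structure).
#' @return A `unetr_config` list.
#' @export
unetr_config <- function(window_edge = 128L, patch_edge = 16L,
                         hidden_dim = 768L, mlp_dim = 3072L,
                         num_heads = 12L, num_layers = 12L,
                         skip_layers = NULL, feature_size = 16L,
                         dropout_rate = 0.05, out_channels = 2L) {
  if (is.null(skip_layers))
    skip_layers <- unique(pmax(1L, round(num_layers * (1:4) / 4)))
  window_edge <- as.integer(window_edge); patch_edge <- as.integer(patch_edge)
  if (patch_edge < 2L || bitwAnd(patch_edge, patch_edge - 1L) != 0L)
    abort_cbctseg("patch_edge must be a power of two >= 2",
                  "cbctseg_config_error")
  if (window_edge %% patch_edge != 0L)
    abort_cbctseg("window_edge must be divisible by patch_edge",
                  "cbctseg_config_error")
  if (hidden_dim %% num_heads != 0L)
    abort_cbctseg("hidden_dim must be divisible by num_heads",
                  "cbctseg_config_error")
  skip_layers <- as.integer(skip_layers)
  if (any(diff(skip_layers) <= 0L) || max(skip_layers) > num_layers ||
      min(skip_layers) < 1L)
    abort_cbctseg("skip_layers must be strictly increasing within 1..num_layers",
                  "cbctseg_config_error")
  if (dropout_rate < 0 || dropout_rate >= 1)
    abort_cbctseg("dropout_rate must be in [0, 1)", "cbctseg_config_error")
  if (out_channels < 2L)
    abort_cbctseg("out_channels must be >= 2", "cbctseg_config_error")
  structure(list(
    window_edge = window_edge, patch_edge = patch_edge,
    hidden_dim = as.integer(hidden_dim), mlp_dim = as.integer(mlp_dim),
    num_heads = as.integer(num_heads), num_layers = as.integer(num_layers),
    skip_layers = skip_layers, feature_size = as.integer(feature_size),
    dropout_rate = dropout_rate, out_channels = as.integer(out_channels)),
    class = "unetr_config")
}

# Derived architecture facts shared by init/forward/count.
unetr_plan <- function(config) {
  g <- config$window_edge %/% config$patch_edge     # token grid edge
  K <- as.integer(round(log2(config$patch_edge)))   # decoder stages
  ch <- config$feature_size * 2L^((K - 1L):0L)      # stage output widths
  taps <- sort(config$skip_layers)
  bottleneck <- taps[length(taps)]
  rem <- rev(taps[-length(taps)])                   # deepest-first
  stage_tap <- rep(NA_integer_, K)
  for (i in seq_len(min(K - 1L, length(rem)))) stage_tap[i] <- rem[i]
  list(grid = g, n_tokens = g^3, K = K, ch = ch, ch0 = ch[1],
       bottleneck = bottleneck, stage_tap = stage_tap)
}

# Shapes of every learned parameter matrix (biases are 1 x d rows).
unetr_param_shapes <- function(config) {
  p <- unetr_plan(config)
  h <- config$hidden_dim
  shapes <- list(
    emb_W = c(config$patch_edge^3, h), emb_b = c(1, h),
    pos = c(p$n_tokens, h))
  for (l in seq_len(config$num_layers)) {
    pre <- sprintf("l%02d_", l)
    shapes[[paste0(pre, "ln1_g")]] <- c(1, h)
    shapes[[paste0(pre, "ln1_b")]] <- c(1, h)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) shapes[[paste0(pre, nm)]] <- c(h, h)
    for (nm in c("bq", "bk", "bv", "bo")) shapes[[paste0(pre, nm)]] <- c(1, h)
    shapes[[paste0(pre, "ln2_g")]] <- c(1, h)
    shapes[[paste0(pre, "ln2_b")]] <- c(1, h)
    shapes[[paste0(pre, "W1")]] <- c(h, config$mlp_dim)
    shapes[[paste0(pre, "b1")]] <- c(1, config$mlp_dim)
    shapes[[paste0(pre, "W2")]] <- c(config$mlp_dim, h)
    shapes[[paste0(pre, "b2")]] <- c(1, h)
  }
  shapes$lnf_g <- c(1, h); shapes$lnf_b <- c(1, h)
  shapes$proj0_W <- c(h, p$ch0); shapes$proj0_b <- c(1, p$ch0)
  ch_prev <- p$ch0
  for (i in seq_len(p$K)) {
    pre <- sprintf("d%d_", i)
    shapes[[paste0(pre, "W")]] <- c(ch_prev, 8L * p$ch[i])
    shapes[[paste0(pre, "b")]] <- c(1, p$ch[i])
    if (!is.na(p$stage_tap[i])) {
      shapes[[paste0(pre, "skipproj_W")]] <- c(h, p$ch[i])
      shapes[[paste0(pre, "skipproj_b")]] <- c(1, p$ch[i])
      for (j in seq_len(i)) {
        shapes[[sprintf("%sskipdec%d_W", pre, j)]] <- c(p$ch[i], 8L * p$ch[i])
        shapes[[sprintf("%sskipdec%d_b", pre, j)]] <- c(1, p$ch[i])
      }
      shapes[[paste0(pre, "merge_W")]] <- c(2L * p$ch[i], p$ch[i])
      shapes[[paste0(pre, "merge_b")]] <- c(1, p$ch[i])
    }
    if (i == p$K - 1L && p$K > 1L) {
      # half-resolution skip: 3x3x3 convolution of the 2x mean-pooled input
      shapes$inskip2_W <- c(27, p$ch[i]); shapes$inskip2_b <- c(1, p$ch[i])
      shapes$hmerge_W <- c(2L * p$ch[i], p$ch[i])
      shapes$hmerge_b <- c(1, p$ch[i])
    }
    if (i == p$K) {
      # full-resolution skip: a 3x3x3 convolution of the raw input,
      # expressed as a linear map over each voxel's 27-neighbourhood
      shapes$inskip_W <- c(27, p$ch[i]); shapes$inskip_b <- c(1, p$ch[i])
      shapes$fmerge_W <- c(2L * p$ch[i], p$ch[i])
      shapes$fmerge_b <- c(1, p$ch[i])
    }
    ch_prev <- p$ch[i]
  }
  shapes$head_W <- c(ch_prev, config$out_channels)
  shapes$head_b <- c(1, config$out_channels)
  shapes
}

#' Count the learnable parameters of a configuration
#'
#' @param config a [unetr_config()].
#' @return Integer-valued total count of learnable scalars.
#' @export
count_parameters <- function(config) {
  sum(vapply(unetr_param_shapes(config), prod, 0))
}

#' Initialize a UNETR model
#'
#' Allocates and initializes every weight: Xavier-scaled Gaussian for
#' projection/attention/convolution matrices, 0.02-scaled Gaussian for the
#' position embedding, unit gain / zero bias for layer norms, zero biases.
#'
#' @param config a [unetr_config()].
#' @param seed integer seed for weight initialization.
#' @param prior_foreground initial foreground prior: the output head's
#'   foreground bias starts at the log-odds of this value, so the untrained
#'   network predicts roughly this prevalence instead of 50% — the standard
#'   initialization for heavily imbalanced segmentation, which skips the
#'   early phase of unlearning a uniform prediction.
#' @return A `unetr_model` (config + named parameter list).
#' @export
unetr_init <- function(config, seed = 1L, prior_foreground = 0.05) {
  shapes <- unetr_param_shapes(config)
  params <- with_seed(seed, {
    lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
      d <- shapes[[nm]]
      if (grepl("ln[12f]?_g$", nm)) return(matrix(1, d[1], d[2]))
      if (grepl("_b[a-z0-9]?$", nm)) return(matrix(0, d[1], d[2]))
      if (nm == "pos")
        return(matrix(stats::rnorm(prod(d), sd = 0.02), d[1], d[2]))
      sd <- sqrt(2 / (d[1] + d[2]))
      matrix(stats::rnorm(prod(d), sd = sd), d[1], d[2])
    })
  })
  if (prior_foreground > 0 && prior_foreground < 1)
    params$head_b[1, config$out_channels] <-
      log(prior_foreground / (1 - prior_foreground))
  structure(list(config = config, params = params), class = "unetr_model")
}

#' @export
print.unetr_model <- function(x, ...) {
  cat(sprintf("<unetr_model> window %d^3, patch %d^3, hidden %d, %d layers, %s parameters\n",
              x$config$window_edge, x$config$patch_edge, x$config$hidden_dim,
              x$config$num_layers,
              format(count_parameters(x$config), big.mark = ",")))
  invisible(x)
}

#' Split a cubic crop into a flattened patch sequence
#'
#' Divides a `window_edge`-cubed scalar grid into non-overlapping
#' `patch_edge`-cubed patches and flattens each into a row, yielding the
#' `(window_edge/patch_edge)^3`-token sequence the transformer consumes
#' (the model's embedding layer then projects rows to `hidden_dim` and adds
#' the learned position embedding).
#'
#' @param crop numeric cubic 3D array.
#' @param patch_edge patch edge, voxels; must divide the crop edge.
#' @return Matrix with one row per patch (token) and `patch_edge^3` columns.
#' @export
patchify <- function(crop, patch_edge) {
  d <- dim(crop)
  if (length(d) != 3L || length(unique(d)) != 1L)
    abort_cbctseg("crop must be a cubic 3D array", "cbctseg_shape_error")
  E <- d[1]; pe <- as.integer(patch_edge)
  if (E %% pe != 0L)
    abort_cbctseg(sprintf("crop edge %d is not divisible by patch edge %d",
                          E, pe), "cbctseg_shape_error")
  g <- E %/% pe
  t0 <- 0:(g^3 - 1L)
  gx <- t0 %% g; gy <- (t0 %/% g) %% g; gz <- t0 %/% (g * g)
  base_t <- (gx + E * gy + E^2 * gz) * pe
  p0 <- 0:(pe^3 - 1L)
  px <- p0 %% pe; py <- (p0 %/% pe) %% pe; pz <- p0 %/% (pe * pe)
  base_p <- px + E * py + E^2 * pz
  idx <- outer(base_t, base_p, `+`) + 1L
  matrix(crop[idx], nrow = g^3)
}

# Full network forward pass on the tape. Returns the logits node plus the
# parameter leaves (for gradient collection) and the tape itself.
unetr_forward_tape <- function(model, crop, train = FALSE) {
  config <- model$config
  plan <- unetr_plan(config)
  E <- config$window_edge
  d <- dim(crop)
  if (length(d) != 3L || any(d != E))
    abort_cbctseg(sprintf("crop shape (%s) does not match window edge %d",
                          paste(d, collapse = "x"), E), "cbctseg_shape_error")
  tape <- nn_tape()
  leaves <- lapply(model$params, function(v) tp_leaf(tape, v))
  P <- function(nm) leaves[[nm]]
  rate <- if (train) config$dropout_rate else 0

  tokens <- tp_leaf(tape, patchify(crop, config$patch_edge))
  x <- tp_add(tape, tp_add_bias(tape, tp_matmul(tape, tokens, P("emb_W")),
                                P("emb_b")), P("pos"))
  x <- tp_dropout(tape, x, rate)

  h <- config$hidden_dim
  dk <- h %/% config$num_heads
  zs <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    pre <- sprintf("l%02d_", l)
    a_in <- tp_layernorm(tape, x, P(paste0(pre, "ln1_g")),
                         P(paste0(pre, "ln1_b")))
    q <- tp_add_bias(tape, tp_matmul(tape, a_in, P(paste0(pre, "Wq"))),
                     P(paste0(pre, "bq")))
    k <- tp_add_bias(tape, tp_matmul(tape, a_in, P(paste0(pre, "Wk"))),
                     P(paste0(pre, "bk")))
    v <- tp_add_bias(tape, tp_matmul(tape, a_in, P(paste0(pre, "Wv"))),
                     P(paste0(pre, "bv")))
    heads <- vector("list", config$num_heads)
    for (hh in seq_len(config$num_heads)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      qh <- tp_slice_cols(tape, q, cols)
      kh <- tp_slice_cols(tape, k, cols)
      vh <- tp_slice_cols(tape, v, cols)
      att <- tp_softmax_rows(tape, tp_scale(tape,
        tp_matmul_bt(tape, qh, kh), 1 / sqrt(dk)))
      heads[[hh]] <- tp_matmul(tape, att, vh)
    }
    o <- heads[[1]]
    if (config$num_heads > 1L)
      for (hh in 2:config$num_heads) o <- tp_cbind(tape, o, heads[[hh]])
    o <- tp_add_bias(tape, tp_matmul(tape, o, P(paste0(pre, "Wo"))),
                     P(paste0(pre, "bo")))
    x <- tp_add(tape, x, tp_dropout(tape, o, rate))

    m_in <- tp_layernorm(tape, x, P(paste0(pre, "ln2_g")),
                         P(paste0(pre, "ln2_b")))
    m <- tp_add_bias(tape, tp_matmul(tape, m_in, P(paste0(pre, "W1"))),
                     P(paste0(pre, "b1")))
    m <- tp_gelu(tape, m)
    m <- tp_add_bias(tape, tp_matmul(tape, m, P(paste0(pre, "W2"))),
                     P(paste0(pre, "b2")))
    x <- tp_add(tape, x, tp_dropout(tape, m, rate))
    zs[[l]] <- x
  }

  bott <- tp_layernorm(tape, zs[[plan$bottleneck]], P("lnf_g"), P("lnf_b"))
  dec <- tp_matmul(tape, bott, P("proj0_W"))
  dec <- tp_add_bias(tape, dec, P("proj0_b"))
  grid <- plan$grid
  for (i in seq_len(plan$K)) {
    pre <- sprintf("d%d_", i)
    dec <- tp_deconv2(tape, dec, P(paste0(pre, "W")), P(paste0(pre, "b")),
                      grid, plan$ch[i])
    grid <- grid * 2L
    dec <- tp_gelu(tape, dec)
    if (!is.na(plan$stage_tap[i])) {
      sk <- tp_add_bias(tape,
        tp_matmul(tape, zs[[plan$stage_tap[i]]], P(paste0(pre, "skipproj_W"))),
        P(paste0(pre, "skipproj_b")))
      sgrid <- plan$grid
      for (j in seq_len(i)) {
        sk <- tp_deconv2(tape, sk, P(sprintf("%sskipdec%d_W", pre, j)),
                         P(sprintf("%sskipdec%d_b", pre, j)), sgrid,
                         plan$ch[i])
        sgrid <- sgrid * 2L
        sk <- tp_gelu(tape, sk)
      }
      dec <- tp_add_bias(tape,
        tp_matmul(tape, tp_cbind(tape, dec, sk), P(paste0(pre, "merge_W"))),
        P(paste0(pre, "merge_b")))
      dec <- tp_gelu(tape, dec)
    }
    if (i == plan$K - 1L && plan$K > 1L) {
      ins2 <- tp_add_bias(tape,
        tp_matmul(tape, tp_leaf(tape, neighborhood_matrix(mean_pool2(crop))),
                  P("inskip2_W")), P("inskip2_b"))
      ins2 <- tp_gelu(tape, ins2)
      dec <- tp_add_bias(tape,
        tp_matmul(tape, tp_cbind(tape, dec, ins2), P("hmerge_W")),
        P("hmerge_b"))
      dec <- tp_gelu(tape, dec)
    }
    if (i == plan$K) {
      ins <- tp_add_bias(tape,
        tp_matmul(tape, tp_leaf(tape, neighborhood_matrix(crop)),
                  P("inskip_W")), P("inskip_b"))
      ins <- tp_gelu(tape, ins)
      dec <- tp_add_bias(tape,
        tp_matmul(tape, tp_cbind(tape, dec, ins), P("fmerge_W")),
        P("fmerge_b"))
      dec <- tp_gelu(tape, dec)
    }
  }
  logits <- tp_add_bias(tape, tp_matmul(tape, dec, P("head_W")), P("head_b"))
  list(tape = tape, logits = logits, leaves = leaves)
}

#' Forward pass: per-voxel class probabilities for one crop
#'
#' Runs the network on a `window_edge`-cubed crop and returns softmax
#' probabilities per voxel. Deterministic when `train = FALSE` (dropout
#' disabled).
#'
#' @param model a [unetr_init()] model.
#' @param crop numeric 3D array of shape `window_edge^3`, intensities
#'   normalized to \[0, 1\].
#' @param train enable dropout (training mode).
#' @return 4D array `[x, y, z, class]`; channels sum to 1 per voxel.
#' @export
unetr_forward <- function(model, crop, train = FALSE) {
  if (train) {
    fw <- unetr_forward_tape(model, crop, train = TRUE)
    x <- fw$logits$value
  } else {
    x <- unetr_forward_plain(model, list(crop))
  }
  m <- x - row_max(x)
  e <- exp(m)
  p <- e / rowSums(e)
  E <- model$config$window_edge
  array(p, c(E, E, E, model$config$out_channels))
}

#' Batched inference forward pass over several crops
#'
#' Stacks `B` crops through one pass of the network (attention is computed
#' per crop; all voxel-wise stages are batched), returning each crop's
#' probability field. Used by sliding-window inference to amortize
#' per-window overhead; numerically equivalent to per-crop forwards.
#'
#' @param model a [unetr_init()] model.
#' @param crops list of cubic 3D arrays of shape `window_edge^3`.
#' @return List of 4D `[x, y, z, class]` probability arrays.
#' @export
unetr_forward_batch <- function(model, crops) {
  x <- unetr_forward_plain(model, crops)
  m <- x - row_max(x)
  e <- exp(m)
  p <- e / rowSums(e)
  E <- model$config$window_edge
  nv <- E^3
  C <- model$config$out_channels
  lapply(seq_along(crops), function(b)
    array(p[(b - 1L) * nv + seq_len(nv), ], c(E, E, E, C)))
}

# Inference-only forward over a batch of crops, without the tape: plain
# matrices, rows of all crops stacked (crop-major). Attention is evaluated
# per crop on its token rows; everything else operates row-wise and
# batches exactly. Returns the stacked (B * window^3) x C logits.
unetr_forward_plain <- function(model, crops) {
  config <- model$config
  plan <- unetr_plan(config)
  E <- config$window_edge
  for (cr in crops)
    if (length(dim(cr)) != 3L || any(dim(cr) != E))
      abort_cbctseg(sprintf("crop shape (%s) does not match window edge %d",
                            paste(dim(cr), collapse = "x"), E),
                    "cbctseg_shape_error")
  B <- length(crops)
  P <- model$params
  n_tok <- plan$n_tokens
  h <- config$hidden_dim
  dk <- h %/% config$num_heads

  addb <- function(x, b) x + rep(as.numeric(b), each = nrow(x))
  gelu <- function(v) {
    s <- 1 / (1 + exp(-1.702 * v))
    v * s
  }
  lnorm <- function(v, gamma, beta, eps = 1e-5) {
    mu <- rowMeans(v)
    xc <- v - mu
    istd <- 1 / sqrt(rowMeans(xc^2) + eps)
    nr <- nrow(v)
    (xc * istd) * rep(as.numeric(gamma), each = nr) +
      rep(as.numeric(beta), each = nr)
  }
  softmax_rows <- function(v) {
    e <- exp(v - row_max(v))
    e / rowSums(e)
  }

  tokens <- do.call(rbind, lapply(crops, patchify,
                                  patch_edge = config$patch_edge))
  x <- addb(tokens %*% P$emb_W, P$emb_b) +
    P$pos[rep(seq_len(n_tok), B), , drop = FALSE]

  zs <- vector("list", config$num_layers)
  for (l in seq_len(config$num_layers)) {
    pre <- sprintf("l%02d_", l)
    a_in <- lnorm(x, P[[paste0(pre, "ln1_g")]], P[[paste0(pre, "ln1_b")]])
    q <- addb(a_in %*% P[[paste0(pre, "Wq")]], P[[paste0(pre, "bq")]])
    k <- addb(a_in %*% P[[paste0(pre, "Wk")]], P[[paste0(pre, "bk")]])
    v <- addb(a_in %*% P[[paste0(pre, "Wv")]], P[[paste0(pre, "bv")]])
    o <- matrix(0, nrow(x), h)
    for (b in seq_len(B)) {
      rows <- (b - 1L) * n_tok + seq_len(n_tok)
      for (hh in seq_len(config$num_heads)) {
        cols <- (hh - 1L) * dk + seq_len(dk)
        att <- softmax_rows(tcrossprod(q[rows, cols, drop = FALSE],
                                       k[rows, cols, drop = FALSE]) /
                              sqrt(dk))
        o[rows, cols] <- att %*% v[rows, cols, drop = FALSE]
      }
    }
    x <- x + addb(o %*% P[[paste0(pre, "Wo")]], P[[paste0(pre, "bo")]])
    m_in <- lnorm(x, P[[paste0(pre, "ln2_g")]], P[[paste0(pre, "ln2_b")]])
    m <- gelu(addb(m_in %*% P[[paste0(pre, "W1")]], P[[paste0(pre, "b1")]]))
    x <- x + addb(m %*% P[[paste0(pre, "W2")]], P[[paste0(pre, "b2")]])
    zs[[l]] <- x
  }

  deconv <- function(x, w, b, grid, c_out) {
    n <- grid^3
    rows <- deconv2_rows(grid)
    y <- x %*% w
    bn <- rep(as.numeric(b), each = n)
    z <- matrix(0, 8L * n * B, c_out)
    for (bb in seq_len(B)) {
      yr <- (bb - 1L) * n
      zr <- (bb - 1L) * 8L * n
      for (o in 0:7)
        z[zr + rows[[o + 1L]], ] <-
          y[yr + seq_len(n), o * c_out + seq_len(c_out)] + bn
    }
    z
  }

  bott <- lnorm(zs[[plan$bottleneck]], P$lnf_g, P$lnf_b)
  dec <- addb(bott %*% P$proj0_W, P$proj0_b)
  grid <- plan$grid
  for (i in seq_len(plan$K)) {
    pre <- sprintf("d%d_", i)
    dec <- gelu(deconv(dec, P[[paste0(pre, "W")]], P[[paste0(pre, "b")]],
                       grid, plan$ch[i]))
    grid <- grid * 2L
    if (!is.na(plan$stage_tap[i])) {
      sk <- addb(zs[[plan$stage_tap[i]]] %*% P[[paste0(pre, "skipproj_W")]],
                 P[[paste0(pre, "skipproj_b")]])
      sgrid <- plan$grid
      for (j in seq_len(i)) {
        sk <- gelu(deconv(sk, P[[sprintf("%sskipdec%d_W", pre, j)]],
                          P[[sprintf("%sskipdec%d_b", pre, j)]], sgrid,
                          plan$ch[i]))
        sgrid <- sgrid * 2L
      }
      dec <- gelu(addb(cbind(dec, sk) %*% P[[paste0(pre, "merge_W")]],
                       P[[paste0(pre, "merge_b")]]))
    }
    if (i == plan$K - 1L && plan$K > 1L) {
      nb2 <- do.call(rbind, lapply(crops, function(cr)
        neighborhood_matrix(mean_pool2(cr))))
      ins2 <- gelu(addb(nb2 %*% P$inskip2_W, P$inskip2_b))
      dec <- gelu(addb(cbind(dec, ins2) %*% P$hmerge_W, P$hmerge_b))
    }
    if (i == plan$K) {
      nb <- do.call(rbind, lapply(crops, neighborhood_matrix))
      ins <- gelu(addb(nb %*% P$inskip_W, P$inskip_b))
      dec <- gelu(addb(cbind(dec, ins) %*% P$fmerge_W, P$fmerge_b))
    }
  }
  addb(dec %*% P$head_W, P$head_b)
}

# 27-column matrix of each voxel's 3x3x3 neighbourhood (zero-padded at the
# borders): multiplying it by a (27 x c) weight is a same-size 3^3
# convolution of the single-channel input. Indices memoized per edge.
neighborhood_idx_cache <- new.env(parent = emptyenv())
neighborhood_matrix <- function(crop) {
  E <- dim(crop)[1]
  key <- as.character(E)
  idx <- neighborhood_idx_cache[[key]]
  if (is.null(idx)) {
    n <- E^3
    v <- 0:(n - 1L)
    i <- v %% E; j <- (v %/% E) %% E; k <- v %/% (E * E)
    idx <- matrix(0L, n, 27L)
    col <- 0L
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      col <- col + 1L
      ii <- i + di; jj <- j + dj; kk <- k + dk
      inside <- ii >= 0L & ii < E & jj >= 0L & jj < E & kk >= 0L & kk < E
      lin <- ii + E * (jj + E * kk) + 1L
      lin[!inside] <- n + 1L                 # points at the zero pad row
      idx[, col] <- lin
    }
    neighborhood_idx_cache[[key]] <- idx
  }
  ext <- c(as.numeric(crop), 0)
  matrix(ext[idx], nrow = E^3)
}

# 2x mean pooling of a cubic array (edge must be even).
mean_pool2 <- function(crop) {
  E <- dim(crop)[1]
  h <- E %/% 2L
  a <- array(crop, c(2L, h, 2L, h, 2L, h))
  array(colMeans(aperm(a, c(1, 3, 5, 2, 4, 6)), dims = 3), c(h, h, h))
}

# Run a seeded block of code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic sub-seed derived from a master seed and a stream name.
derive_seed <- function(seed, stream) {
  hs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + hs * 9973) %% 2147483629) + 1L
}
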