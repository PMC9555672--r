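test_that("patchify yields the expected token counts and rejects bad shapes", {
  expect_equal(nrow(patchify(array(0, rep(32, 3)), 16)), 8)
  expect_equal(nrow(patchify(array(0, rep(64, 3)), 16)), 64)
  expect_equal(ncol(patchify(array(0, rep(32, 3)), 16)), 16^3)
  expect_error(patchify(array(0, rep(100, 3)), 16),
               class = "cbctseg_shape_error")
  # deployment-scale token count by the same arithmetic
  cfg <- unetr_config()
  expect_equal((cfg$window_edge / cfg$patch_edge)^3, 512)
})

test_that("patchify rows are the flattened patches at the right locations", {
  crop <- array(seq_len(8^3), c(8, 8, 8))
  P <- patchify(crop, 4)
  expect_equal(dim(P), c(8L, 64L))
  # token 1 is the corner patch, flattened x-fastest
  expect_equal(P[1, ], as.numeric(crop[1:4, 1:4, 1:4]))
  # token 2 advances along x
  expect_equal(P[2, ], as.numeric(crop[5:8, 1:4, 1:4]))
  # last token is the far corner
  expect_equal(P[8, ], as.numeric(crop[5:8, 5:8, 5:8]))
})

test_that("forward output is a normalized probability field of the right shape", {
  cfg <- micro_config()
  model <- unetr_init(cfg, seed = 2)
  set.seed(3)
  for (i in 1:20) {
    crop <- array(runif(8^3), c(8, 8, 8))
    p <- unetr_forward(model, crop)
    expect_equal(dim(p), c(8, 8, 8, 2))
    expect_true(all(p >= 0))
    expect_lt(max(abs(apply(p, 1:3, sum) - 1)), 1e-5)
    model <- unetr_init(cfg, seed = i + 10)   # fresh random weights
  }
  # all-zero input still yields a valid field
  p0 <- unetr_forward(unetr_init(cfg, seed = 1), array(0, c(8, 8, 8)))
  expect_lt(max(abs(apply(p0, 1:3, sum) - 1)), 1e-5)
})

test_that("forward is deterministic with dropout disabled", {
  model <- unetr_init(micro_config(), seed = 4)
  crop <- array(runif(8^3), c(8, 8, 8))
  expect_identical(unetr_forward(model, crop), unetr_forward(model, crop))
  expect_error(unetr_forward(model, array(0, c(6, 6, 6))),
               class = "cbctseg_shape_error")
})

test_that("the small-experiment configuration produces 32^3 x 2 output", {
  model <- unetr_init(tiny_config(), seed = 5)
  p <- unetr_forward(model, array(0.5, c(32, 32, 32)))
  expect_equal(dim(p), c(32, 32, 32, 2))
})

test_that("parameter count is reproducible and monotone in width and depth", {
  base <- micro_config()
  expect_identical(count_parameters(base), count_parameters(base))
  wider <- micro_config(); wider$hidden_dim <- 24L
  expect_gt(count_parameters(wider), count_parameters(base))
  deeper <- micro_config(); deeper$num_layers <- 4L
  deeper$skip_layers <- c(1L, 2L, 3L, 4L)
  expect_gt(count_parameters(deeper), count_parameters(base))
  # counts match the allocated parameters exactly
  model <- unetr_init(base, seed = 1)
  expect_equal(count_parameters(base), sum(lengths(model$params)))
})

test_that("configuration invariants are enforced", {
  expect_error(unetr_config(window_edge = 100, patch_edge = 16),
               class = "cbctseg_config_error")
  expect_error(unetr_config(hidden_dim = 65, num_heads = 4),
               class = "cbctseg_config_error")
  expect_error(unetr_config(patch_edge = 12), class = "cbctseg_config_error")
  expect_error(unetr_config(skip_layers = c(3, 3)),
               class = "cbctseg_config_error")
  expect_error(unetr_config(skip_layers = c(4, 20)),
               class = "cbctseg_config_error")
  expect_error(unetr_config(dropout_rate = 1), class = "cbctseg_config_error")
})

test_that("analytic gradients match finite differences across all groups", {
  cfg <- micro_config()
  model <- unetr_init(cfg, seed = 6)
  set.seed(7)
  crop <- array(runif(8^3), c(8, 8, 8))
  target <- as.numeric(runif(8^3) < 0.2)
  fw <- cbctseg:::unetr_forward_tape(model, crop)
  loss <- cbctseg:::tp_dice_ce(fw$tape, fw$logits, target)
  cbctseg:::tape_backward(fw$tape, loss)
  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    f <- cbctseg:::unetr_forward_tape(m2, crop)
    cbctseg:::tp_dice_ce(f$tape, f$logits, target)$value[1]
  }
  eps <- 1e-5
  for (nm in names(model$params)) {
    gr <- fw$leaves[[nm]]$grad
    expect_false(is.null(gr), label = sprintf("gradient reaches %s", nm))
    i <- sample(length(model$params[[nm]]), 1)
    up <- model$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- model$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_lt(abs(fd - gr[i]) / max(1e-6, abs(fd), abs(gr[i])), 1e-3,
              label = sprintf("finite-difference match for %s", nm))
  }
})

test_that("one optimizer step reduces the loss of a tiny model", {
  cfg <- micro_config()
  model <- unetr_init(cfg, seed = 8)
  set.seed(9)
  crop <- array(runif(8^3), c(8, 8, 8))
  target <- as.numeric(runif(8^3) < 0.3)
  step_loss <- function(model, lr) {
    fw <- cbctseg:::unetr_forward_tape(model, crop)
    loss <- cbctseg:::tp_dice_ce(fw$tape, fw$logits, target)
    cbctseg:::tape_backward(fw$tape, loss)
    grads <- lapply(fw$leaves, function(nd) nd$grad)
    opt <- cbctseg:::adam_init(model$params)
    upd <- cbctseg:::adam_step(opt, model$params, grads, lr, 0)
    model$params <- upd$params
    fw2 <- cbctseg:::unetr_forward_tape(model, crop)
    c(loss$value[1],
      cbctseg:::tp_dice_ce(fw2$tape, fw2$logits, target)$value[1])
  }
  ls <- step_loss(model, 1e-2)
  expect_lt(ls[2], ls[1])
})

test_that("batched inference equals the differentiable forward pass", {
  model <- unetr_init(micro_config(), seed = 11)
  set.seed(12)
  crops <- lapply(1:3, function(i) array(runif(8^3), c(8, 8, 8)))
  batched <- unetr_forward_batch(model, crops)
  for (i in 1:3) {
    fw <- cbctseg:::unetr_forward_tape(model, crops[[i]])
    x <- fw$logits$value
    e <- exp(x - cbctseg:::row_max(x))
    expect_equal(batched[[i]], array(e / rowSums(e), c(8, 8, 8, 2)),
                 tolerance = 1e-12)
    expect_equal(unetr_forward(model, crops[[i]]), batched[[i]],
                 tolerance = 1e-12)
  }
  expect_error(unetr_forward_batch(model, list(array(0, c(4, 4, 4)))),
               class = "cbctseg_shape_error")
})

test_that("dropout is active in training mode only", {
  cfg <- micro_config(dropout = 0.5)
  model <- unetr_init(cfg, seed = 10)
  crop <- array(runif(8^3), c(8, 8, 8))
  expect_identical(unetr_forward(model, crop, train = FALSE),
                   unetr_forward(model, crop, train = FALSE))
  set.seed(1); a <- unetr_forward(model, crop, train = TRUE)
  set.seed(2); b <- unetr_forward(model, crop, train = TRUE)
  expect_gt(max(abs(a - b)), 0)
})
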