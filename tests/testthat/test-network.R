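test_that("graph convolution layer matches dense oracles", {
  # identity propagation
  H <- matrix(stats::rnorm(17 * 3), 17, 3)
  expect_equal(gcn_layer_forward(H, diag(17), diag(3), identity), H)
  # 2-node toy by hand
  A <- matrix(0.5, 2, 2)
  H2 <- matrix(c(1, 3), 2, 1)
  expect_equal(gcn_layer_forward(H2, A, matrix(1), identity),
               matrix(c(2, 2), 2, 1))
  # 3 stacked layers equal the step-by-step dense oracle
  set.seed(8)
  An <- normalized_adjacency(build_skeleton_graph("right"))
  X <- matrix(stats::rnorm(17 * 8), 17, 8)
  W <- replicate(3, matrix(stats::rnorm(64), 8, 8), simplify = FALSE)
  out <- X
  oracle <- X
  for (l in 1:3) {
    out <- gcn_layer_forward(out, An, W[[l]])
    oracle <- pmax(An %*% oracle %*% W[[l]], 0)
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_error(gcn_layer_forward(X, An, matrix(1, 5, 5)), "shape")
})

test_that("graph convolution is equivariant to joint permutation", {
  set.seed(9)
  An <- normalized_adjacency(build_skeleton_graph("left"))
  X <- matrix(stats::rnorm(17 * 6), 17, 6)
  W <- matrix(stats::rnorm(6 * 4), 6, 4)
  p <- sample(17)
  out1 <- gcn_layer_forward(X, An, W)[p, ]
  out2 <- gcn_layer_forward(X[p, ], An[p, p], W)
  expect_equal(out2, out1, tolerance = 1e-12)
})

test_that("receptive field formula matches the perturbation probe on a grid", {
  for (layers in 1:4) {
    for (kernel in c(2L, 3L, 5L)) {
      tcn <- build_tcn(channels = 3, layers = layers, kernel = kernel,
                       seed = layers * 10 + kernel)
      expect_equal(probe_receptive_field(tcn), receptive_field(tcn),
                   label = paste("layers", layers, "kernel", kernel))
    }
  }
  # printed design figures
  expect_equal(receptive_field(list(tcn_kernel = 5L,
                                    tcn_dilations = c(1L, 2L, 4L, 8L))), 61)
  expect_equal(receptive_field(list(tcn_kernel = 3L, tcn_dilations = 1L)), 3)
  expect_equal(receptive_field(list(tcn_kernel = 3L,
                                    tcn_dilations = c(1L, 2L))), 7)
})

test_that("temporal stack is causal and length-preserving", {
  tcn <- build_tcn(channels = 4, layers = 3, kernel = 3, seed = 2)
  set.seed(3)
  x <- matrix(stats::rnorm(20 * 4), 20, 4)
  y <- tcn_forward(x, tcn)
  expect_equal(dim(y), dim(x))
  # zero input, zero bias -> zero output
  expect_equal(tcn_forward(matrix(0, 20, 4), tcn), matrix(0, 20, 4))
  # perturbing frame t+1 leaves outputs at <= t unchanged, for all t
  for (t in c(1, 7, 19)) {
    x2 <- x
    x2[t + 1, ] <- x2[t + 1, ] + 5
    y2 <- tcn_forward(x2, tcn)
    expect_equal(y2[seq_len(t), , drop = FALSE],
                 y[seq_len(t), , drop = FALSE])
  }
  expect_error(tcn_forward(matrix(0, 10, 7), tcn), "channel mismatch")
})

test_that("an impulse propagates to exactly min(RF, remaining frames) outputs", {
  tcn <- build_tcn(channels = 2, layers = 2, kernel = 3,
                   dilations = c(1L, 2L), seed = 5, activation = "linear")
  rf <- receptive_field(tcn)    # 7
  Tn <- 20L
  x <- matrix(0, Tn, 2)
  t0 <- 4L
  x[t0, ] <- 1
  y <- tcn_forward(x, tcn)
  nonzero <- which(rowSums(abs(y)) > 1e-12)
  expect_true(all(nonzero >= t0))
  expect_equal(length(nonzero), min(rf, Tn - t0 + 1L))
})

test_that("cross-modal attention normalizes rows and degenerates correctly", {
  set.seed(11)
  Wq <- matrix(stats::rnorm(8 * 4), 8, 4)
  Wk <- matrix(stats::rnorm(8 * 4), 8, 4)
  Wv <- matrix(stats::rnorm(8 * 8), 8, 8)
  f <- matrix(stats::rnorm(3 * 8), 3, 8)
  r <- cross_modal_attention(f, Wq, Wk, Wv)
  expect_equal(rowSums(r$attention), rep(1, 3), tolerance = 1e-12)
  # identical modality features -> uniform attention 1/3
  f1 <- matrix(rep(stats::rnorm(8), each = 3), 3, 8)
  r1 <- cross_modal_attention(f1, Wq, Wk, Wv)
  expect_equal(r1$attention, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # zeroed keys give equal scores, hence uniform attention
  r2 <- cross_modal_attention(f, Wq, Wk * 0, Wv)
  expect_equal(r2$attention, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # a dominant key score drives its column weight to 1 in every row:
  # queries all positive, key projection singles out modality 2 hugely
  fpos <- matrix(1, 3, 8)
  fpos[2, 1] <- 2                       # modality 2 marked in channel 1
  Wq1 <- matrix(1, 8, 4)                # all queries equal and positive
  Wk1 <- matrix(0, 8, 4); Wk1[1, ] <- 50
  r3 <- cross_modal_attention(fpos, Wq1, Wk1, Wv)
  expect_true(all(r3$attention[, 2] > 1 - 1e-10))
  expect_error(cross_modal_attention(f[1:2, ], Wq, Wk, Wv), "three")
})

test_that("kinematic encoder output has the configured width and is stateless", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 4)
  x <- matrix(stats::rnorm(10 * 12), 10, 12)
  e1 <- kinematic_encoder(x, model)
  expect_equal(dim(e1), c(10, cfg$modal_dim))
  expect_identical(e1, kinematic_encoder(x, model))
  expect_identical(e1[3, ], kinematic_encoder(x[c(3, 3), ], model)[1, ])
  expect_error(kinematic_encoder(matrix(0, 5, 7), model), "12")
  # with identity-like weights and linear path the map equals the matrix
  # product oracle: strip BN (scale 1, shift 0, running stats at init) and
  # use non-negative inputs so the rectifier is inactive
  m2 <- model
  m2$params$kin_W1 <- abs(m2$params$kin_W1)
  m2$params$kin_W2 <- abs(m2$params$kin_W2)
  m2$params$kin_W3 <- abs(m2$params$kin_W3)
  xp <- abs(x)
  oracle <- xp %*% m2$params$kin_W1
  oracle <- oracle / rep(sqrt(1 + 1e-5), each = 10)   # init BN: var 1, mean 0
  oracle <- oracle %*% m2$params$kin_W2 / sqrt(1 + 1e-5)
  oracle <- oracle %*% m2$params$kin_W3
  expect_equal(kinematic_encoder(xp, m2), oracle, tolerance = 1e-10)
})

test_that("full forward pass yields finite logits with unit-sum softmax", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 6)
  batch <- assemble_batch(tiny_samples(3))
  out <- nn_forward(model, batch, training = FALSE)
  expect_equal(dim(out$asym), c(3, 4))
  expect_equal(dim(out$risk), c(3, 3))
  expect_true(all(is.finite(out$asym)) && all(is.finite(out$risk)))
  expect_equal(unname(rowSums(softmax(out$asym))), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(softmax(out$risk))), rep(1, 3),
               tolerance = 1e-12)
})

test_that("single-modality ablation routes around fusion and keeps output shapes", {
  cfg <- tiny_config(modalities = "skeleton")
  model <- init_model(cfg, seed = 6)
  batch <- assemble_batch(tiny_samples(2))
  out <- nn_forward(model, batch, training = FALSE)
  expect_equal(dim(out$asym), c(2, 4))
  expect_equal(dim(out$risk), c(2, 3))
  expect_true(all(is.finite(out$asym)))
  cfg2 <- tiny_config(fusion = "concat")
  model2 <- init_model(cfg2, seed = 6)
  out2 <- nn_forward(model2, batch, training = FALSE)
  expect_true(all(is.finite(out2$asym)))
})

test_that("evaluation-mode forward is deterministic and dropout-free", {
  cfg <- tiny_config()   # dropout 0
  model <- init_model(cfg, seed = 6)
  batch <- assemble_batch(tiny_samples(3))
  o1 <- nn_forward(model, batch)
  o2 <- nn_forward(model, batch)
  expect_identical(o1$asym, o2$asym)
  # dropout config only affects training mode
  cfg2 <- tiny_config(); cfg2$dropout <- 0.5
  model2 <- init_model(cfg2, seed = 6)
  e1 <- nn_forward(model2, batch)
  e2 <- nn_forward(model2, batch)
  expect_identical(e1$risk, e2$risk)
})

test_that("analytic gradients agree with finite differences on a tiny model", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 3)
  batch <- assemble_batch(tiny_samples(4))
  lossfn <- function(m) {
    out <- nn_forward(m, batch, training = TRUE)
    L1 <- cross_entropy_4class(softmax(out$asym), batch$y_asym)
    fr <- ttasym:::.focal_logit_grad(out$risk, batch$y_risk, 2, c(1, 1.5, 3))
    0.7 * L1 + 0.4 * fr$loss
  }
  out <- nn_forward(model, batch, training = TRUE)
  fr <- ttasym:::.focal_logit_grad(out$risk, batch$y_risk, 2, c(1, 1.5, 3))
  G <- ttasym:::nn_backward(model, out$cache,
                            0.7 * ttasym:::.ce_logit_grad(out$asym,
                                                          batch$y_asym),
                            0.4 * fr$grad)
  set.seed(1)
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (k in sample(length(p), min(2, length(p)))) {
      ana <- if (is.null(G[[nm]])) 0 else G[[nm]][k]
      # a step that straddles a rectifier kink corrupts one finite
      # difference; the smallest error over several step sizes isolates
      # genuine gradient bugs, which persist across step sizes
      err <- Inf
      for (eps in c(1e-5, 1e-6, 1e-7)) {
        m2 <- model
        m2$params[[nm]][k] <- p[k] + eps
        f1 <- lossfn(m2)
        m2$params[[nm]][k] <- p[k] - eps
        f0 <- lossfn(m2)
        num <- (f1 - f0) / (2 * eps)
        err <- min(err, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
      }
      expect_lt(err, 1e-4, label = paste("gradient of", nm))
    }
  }
})

test_that("parameter count is a pure function of the configuration", {
  n1 <- n_parameters(model_config())
  n2 <- n_parameters(model_config())
  expect_identical(n1, n2)
  expect_gt(n1, n_parameters(tiny_config()))
  expect_gt(n_parameters(model_config(gcn_hidden = 128L)), n1)
})
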