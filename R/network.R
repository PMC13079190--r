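# ---- multimodal network: config, initialization, forward pass ----
#
# Three modality encoders (skeleton embedding, rendered-visual linear
# encoder, kinematic MLP), cross-modal attention fusion to a 512-d vector,
# a spatiotemporal core (per-frame graph convolutions over the sport-
# weighted skeleton followed by a causal dilated temporal convolution
# stack), temporal pooling, and two classification heads sharing the pooled
# representation.  Implemented directly on BLAS matrix products with
# explicit backward passes (no autodiff dependency).

#' Model architecture configuration
#'
#' @param joint_embed Per-joint coordinate embedding width (default 32).
#' @param kin_mlp Hidden widths of the kinematic encoder MLP
#'   (default `c(64, 128, 128)`, input 12).
#' @param rgb_dim Visual feature input dimension (default 256).
#' @param modal_dim Common modality feature dimension entering fusion
#'   (default 128).
#' @param d_k Attention query/key dimension (default 64).
#' @param fusion_dim Fused representation width (default 512).
#' @param fused_proj Width of the fused vector broadcast to the skeleton
#'   nodes (default 64).
#' @param gcn_layers,gcn_hidden Graph convolution depth (default 3) and
#'   width (default 64).
#' @param tcn_layers,tcn_kernel,tcn_channels Temporal stack depth (default
#'   4), kernel width (default 5, the width for which dilations `2^i` reach
#'   a 61-frame receptive field), channel width (default 64).
#' @param head_dims Hidden widths of each task head (default
#'   `c(256, 128, 64)`).
#' @param n_asym,n_risk Output classes per task (4 and 3).
#' @param dropout Dropout probability in fusion and heads (default 0.5).
#' @param fusion `"attention"` (scaled dot-product cross-modal attention) or
#'   `"concat"` (simple concatenation baseline).
#' @param kin_to_core Feed the frame-aligned kinematic descriptor sequence
#'   into the temporal stack alongside the pooled joint features, so the
#'   core sees indicator dynamics at frame resolution (default TRUE).
#' @param modalities Subset of `c("skeleton", "rgb", "kinematic")`; fewer
#'   than three routes around fusion (ablation configurations).
#' @return Object of class `model_config`.
#' @export
model_config <- function(joint_embed = 32L, kin_mlp = c(64L, 128L, 128L),
                         rgb_dim = 256L, modal_dim = 128L, d_k = 64L,
                         fusion_dim = 512L, fused_proj = 64L,
                         gcn_layers = 3L, gcn_hidden = 64L,
                         tcn_layers = 4L, tcn_kernel = 5L, tcn_channels = 64L,
                         head_dims = c(256L, 128L, 64L),
                         n_asym = 4L, n_risk = 3L, dropout = 0.5,
                         fusion = c("attention", "concat"),
                         kin_to_core = TRUE,
                         modalities = c("skeleton", "rgb", "kinematic")) {
  fusion <- match.arg(fusion)
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)",
                                        call. = FALSE)
  if (fusion_dim <= 0) stop("fusion_dim must be positive", call. = FALSE)
  structure(
    list(n_joints = 17L, coord_dim = 3L, joint_embed = joint_embed,
         kin_dim = 12L, kin_mlp = kin_mlp, rgb_dim = rgb_dim,
         modal_dim = modal_dim, d_k = d_k, fusion_dim = fusion_dim,
         fused_proj = fused_proj, gcn_layers = gcn_layers,
         gcn_hidden = gcn_hidden, tcn_layers = tcn_layers,
         tcn_kernel = tcn_kernel, tcn_channels = tcn_channels,
         tcn_dilations = as.integer(2^(seq_len(tcn_layers) - 1)),
         head_dims = head_dims, n_asym = n_asym, n_risk = n_risk,
         dropout = dropout, fusion = fusion,
         kin_to_core = kin_to_core && "kinematic" %in% modalities,
         modalities = modalities),
    class = "model_config"
  )
}

#' Receptive field of the causal dilated temporal stack
#'
#' `1 + (kernel - 1) * sum(dilations)` frames for stacked causal dilated
#' convolutions.
#'
#' @param config A `model_config`, or a list with `tcn_kernel` and
#'   `tcn_dilations`.
#' @return Receptive field in frames.
#' @export
receptive_field <- function(config) {
  1L + (config$tcn_kernel - 1L) * sum(config$tcn_dilations)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

.he_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# fusion input width given mode and modality count
.fuse_in_dim <- function(cfg) {
  m <- length(cfg$modalities)
  if (m >= 3 && cfg$fusion == "attention") return(cfg$modal_dim)
  if (cfg$fusion == "concat" && m >= 2) return(cfg$modal_dim * m)
  cfg$modal_dim
}

#' Initialize model parameters
#'
#' Fan-in scaled random initialization, seeded; biases zero; batch-norm
#' scale 1 / shift 0; task log-noise parameters initialized at 0 (so both
#' task weights start at the fixed-equal-weighting value 0.5).
#'
#' @param config A `model_config`.
#' @param seed Integer seed.
#' @return Object of class `stroke_model_params`: list with `params`,
#'   `log_sigmas`, `bn` (running statistics environment) and `config`.
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  P <- list()
  if ("skeleton" %in% cfg$modalities) {
    P$sk_emb_W <- .he_mat(cfg$coord_dim, cfg$joint_embed)
    P$sk_emb_b <- numeric(cfg$joint_embed)
    P$sk_mod_W <- .he_mat(cfg$joint_embed, cfg$modal_dim)
    P$sk_mod_b <- numeric(cfg$modal_dim)
  }
  if ("rgb" %in% cfg$modalities) {
    P$rgb_W <- .he_mat(cfg$rgb_dim, cfg$modal_dim)
    P$rgb_b <- numeric(cfg$modal_dim)
  }
  if ("kinematic" %in% cfg$modalities) {
    d <- c(cfg$kin_dim, cfg$kin_mlp)
    for (l in 1:3) {
      P[[paste0("kin_W", l)]] <- .he_mat(d[l], d[l + 1])
      P[[paste0("kin_b", l)]] <- numeric(d[l + 1])
    }
    for (l in 1:2) {
      P[[paste0("kin_bn", l, "_g")]] <- rep(1, d[l + 1])
      P[[paste0("kin_bn", l, "_b")]] <- numeric(d[l + 1])
    }
    if (cfg$kin_mlp[3] != cfg$modal_dim) {
      stop("kinematic encoder output must match modal_dim", call. = FALSE)
    }
  }
  if (length(cfg$modalities) >= 3 && cfg$fusion == "attention") {
    P$att_Wq <- .he_mat(cfg$modal_dim, cfg$d_k)
    P$att_Wk <- .he_mat(cfg$modal_dim, cfg$d_k)
    P$att_Wv <- .he_mat(cfg$modal_dim, cfg$modal_dim)
  }
  P$fuse_W <- .he_mat(.fuse_in_dim(cfg), cfg$fusion_dim)
  P$fuse_b <- numeric(cfg$fusion_dim)
  P$proj_W <- .he_mat(cfg$fusion_dim, cfg$fused_proj)
  P$proj_b <- numeric(cfg$fused_proj)

  g_in <- c(if ("skeleton" %in% cfg$modalities) cfg$joint_embed else 0) +
    cfg$fused_proj
  din <- g_in
  for (l in seq_len(cfg$gcn_layers)) {
    P[[paste0("gcn_W", l)]] <- .he_mat(din, cfg$gcn_hidden)
    P[[paste0("gcn_b", l)]] <- numeric(cfg$gcn_hidden)
    din <- cfg$gcn_hidden
  }
  cin <- cfg$gcn_hidden + if (isTRUE(cfg$kin_to_core)) cfg$kin_dim else 0L
  for (l in seq_len(cfg$tcn_layers)) {
    P[[paste0("tcn_W", l)]] <- .he_mat(cfg$tcn_kernel * cin, cfg$tcn_channels)
    P[[paste0("tcn_b", l)]] <- numeric(cfg$tcn_channels)
    P[[paste0("tcn_bn", l, "_g")]] <- rep(1, cfg$tcn_channels)
    P[[paste0("tcn_bn", l, "_b")]] <- numeric(cfg$tcn_channels)
    cin <- cfg$tcn_channels
  }
  for (task in c("asym", "risk")) {
    d <- c(cfg$tcn_channels, cfg$head_dims)
    for (l in 1:3) {
      P[[paste0(task, "_W", l)]] <- .he_mat(d[l], d[l + 1])
      P[[paste0(task, "_b", l)]] <- numeric(d[l + 1])
    }
    nout <- if (task == "asym") cfg$n_asym else cfg$n_risk
    P[[paste0(task, "_out_W")]] <- .he_mat(d[4], nout)
    P[[paste0(task, "_out_b")]] <- numeric(nout)
  }

  bn <- new.env(parent = emptyenv())
  for (nm in grep("_bn[0-9]+_g$", names(P), value = TRUE)) {
    base <- sub("_g$", "", nm)
    assign(paste0(base, "_mean"), numeric(length(P[[nm]])), envir = bn)
    assign(paste0(base, "_var"), rep(1, length(P[[nm]])), envir = bn)
  }
  structure(list(params = P, log_sigmas = c(0, 0), bn = bn, config = cfg),
            class = "stroke_model_params")
}

#' Number of trainable parameters
#'
#' @param x A `stroke_model_params`, fitted `stroke_model`, or
#'   `model_config`.
#' @return Integer parameter count (including the two task noise
#'   parameters).
#' @export
n_parameters <- function(x) {
  if (inherits(x, "model_config")) x <- init_model(x, seed = 1L)
  sum(vapply(x$params, length, integer(1))) + length(x$log_sigmas)
}

# ---- layer primitives ----

#' Single graph-convolution layer
#'
#' Computes `activation(A_norm %*% H %*% W)` -- node feature aggregation
#' over the normalized weighted adjacency.
#'
#' @param H Node feature matrix (17 x d).
#' @param A_norm Output of [normalized_adjacency()] (or any matching square
#'   matrix).
#' @param W Weight matrix (d x d').
#' @param activation Function applied elementwise (default ReLU).
#' @return 17 x d' matrix.
#' @export
gcn_layer_forward <- function(H, A_norm, W, activation = .relu) {
  if (ncol(A_norm) != nrow(H) || ncol(H) != nrow(W)) {
    stop("shape mismatch in gcn_layer_forward", call. = FALSE)
  }
  activation(A_norm %*% H %*% W)
}

#' Build a standalone causal dilated temporal stack
#'
#' A self-contained TCN usable outside the full model, e.g. for receptive
#' field probing.
#'
#' @param channels Channel width.
#' @param layers Number of layers.
#' @param kernel Kernel width.
#' @param dilations Dilation per layer (default `2^i`).
#' @param seed Init seed.
#' @param activation `"relu"` or `"linear"`.
#' @return Object of class `tcn_stack`.
#' @export
build_tcn <- function(channels = 8L, layers = 4L, kernel = 5L,
                      dilations = as.integer(2^(seq_len(layers) - 1)),
                      seed = 1L, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  set.seed(seed)
  W <- lapply(seq_len(layers), function(l) .he_mat(kernel * channels, channels))
  structure(list(W = W, kernel = kernel, dilations = dilations,
                 channels = channels, activation = activation,
                 tcn_kernel = kernel, tcn_dilations = dilations),
            class = "tcn_stack")
}

# causal dilated convolution of a single sequence: x is T x C
.causal_conv_seq <- function(x, W, kernel, dilation) {
  Tn <- nrow(x)
  C <- ncol(x)
  out <- matrix(0, Tn, ncol(W))
  for (j in seq_len(kernel) - 1L) {
    Wj <- W[(j * C + 1):((j + 1) * C), , drop = FALSE]
    sh <- j * dilation
    if (sh < Tn) {
      out[(sh + 1):Tn, ] <- out[(sh + 1):Tn, ] +
        x[1:(Tn - sh), , drop = FALSE] %*% Wj
    }
  }
  out
}

#' Forward pass through a standalone temporal stack
#'
#' Causal: the output at frame `t` depends only on input frames `<= t`;
#' sequence length is preserved by left zero-padding.
#'
#' @param x `T x channels` input matrix.
#' @param tcn A `tcn_stack`.
#' @return `T x channels` output matrix.
#' @export
tcn_forward <- function(x, tcn) {
  if (ncol(x) != tcn$channels) {
    stop("channel mismatch: input has ", ncol(x), ", stack expects ",
         tcn$channels, call. = FALSE)
  }
  act <- if (tcn$activation == "relu") .relu else identity
  for (l in seq_along(tcn$W)) {
    x <- act(.causal_conv_seq(x, tcn$W[[l]], tcn$kernel, tcn$dilations[l]))
  }
  x
}

#' Empirical receptive field by input-perturbation probing
#'
#' Counts the input frames whose perturbation changes the final-frame output
#' of the built temporal stack.
#'
#' @param tcn A `tcn_stack` (probing uses linear activation regardless, so
#'   no unit can mask an influence).
#' @param n_frames Probe sequence length; defaults to formula receptive
#'   field + 10.
#' @return Number of influencing frames.
#' @export
probe_receptive_field <- function(tcn, n_frames = NULL) {
  tcn$activation <- "linear"
  rf <- receptive_field(tcn)
  if (is.null(n_frames)) n_frames <- rf + 10L
  base <- tcn_forward(matrix(0, n_frames, tcn$channels), tcn)
  last0 <- base[n_frames, ]
  influenced <- logical(n_frames)
  for (t in seq_len(n_frames)) {
    x <- matrix(0, n_frames, tcn$channels)
    x[t, ] <- 1
    y <- tcn_forward(x, tcn)
    influenced[t] <- any(abs(y[n_frames, ] - last0) > 1e-12)
  }
  sum(influenced)
}

#' Cross-modal attention fusion
#'
#' Maps each modality feature to a shared query space, forms the 3 x 3
#' attention matrix `A = softmax_j(Q_i K_j' / sqrt(d_k))` (row-wise softmax
#' over source modalities), and aggregates
#' `fused = (1/3) * sum_ij A_ij V_j`.
#'
#' @param features Matrix `3 x modal_dim`: one row per modality.
#' @param Wq,Wk,Wv Projection matrices.
#' @return List with `fused` (length `ncol(Wv)`) and `attention` (3 x 3,
#'   rows summing to 1).
#' @export
cross_modal_attention <- function(features, Wq, Wk, Wv) {
  if (nrow(features) < 3) {
    stop("cross-modal attention expects the three modality feature rows",
         call. = FALSE)
  }
  Q <- features %*% Wq
  K <- features %*% Wk
  V <- features %*% Wv
  S <- Q %*% t(K) / sqrt(ncol(Q))
  S <- sweep(S, 1, apply(S, 1, max))
  A <- exp(S)
  A <- A / rowSums(A)
  fused <- colSums(A %*% V) / nrow(features)
  list(fused = fused, attention = A)
}

#' Kinematic feature encoder
#'
#' Applies the per-step 3-layer MLP (12 -> 64 -> 128 -> 128 by default) of
#' the trained model to a sequence of 12-dimensional kinematic feature
#' vectors, in evaluation mode.
#'
#' @param features `n x 12` matrix.
#' @param model A `stroke_model_params` (or fitted `stroke_model`).
#' @return `n x modal_dim` encoded matrix.
#' @export
kinematic_encoder <- function(features, model) {
  P <- model$params
  cfg <- model$config
  if (ncol(features) != cfg$kin_dim) {
    stop("kinematic encoder expects ", cfg$kin_dim, "-dimensional input",
         call. = FALSE)
  }
  x <- features %*% P$kin_W1 + rep(P$kin_b1, each = nrow(features))
  x <- .bn_eval(x, P$kin_bn1_g, P$kin_bn1_b, model$bn, "kin_bn1")
  x <- .relu(x)
  x <- x %*% P$kin_W2 + rep(P$kin_b2, each = nrow(x))
  x <- .bn_eval(x, P$kin_bn2_g, P$kin_bn2_b, model$bn, "kin_bn2")
  x <- .relu(x)
  .relu(x %*% P$kin_W3 + rep(P$kin_b3, each = nrow(x)))
}

# ---- batch-norm helpers ----

.bn_eval <- function(x, g, b, bn, key) {
  mu <- get(paste0(key, "_mean"), envir = bn)
  va <- get(paste0(key, "_var"), envir = bn)
  xh <- sweep(x, 2, mu) / rep(sqrt(va + 1e-5), each = nrow(x))
  xh * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
}

.bn_train <- function(x, g, b, bn, key, momentum = 0.1) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  va <- colMeans(xc^2)
  ivar <- 1 / sqrt(va + 1e-5)
  xh <- xc * rep(ivar, each = n)
  out <- xh * rep(g, each = n) + rep(b, each = n)
  mk <- paste0(key, "_mean"); vk <- paste0(key, "_var")
  assign(mk, (1 - momentum) * get(mk, envir = bn) + momentum * mu, envir = bn)
  assign(vk, (1 - momentum) * get(vk, envir = bn) + momentum * va, envir = bn)
  list(out = out, xh = xh, ivar = ivar, xc = xc)
}

.bn_backward <- function(dout, cache, g) {
  n <- nrow(dout)
  dg <- colSums(dout * cache$xh)
  db <- colSums(dout)
  dxh <- dout * rep(g, each = n)
  # standard batch-norm gradient
  dx <- (dxh - rep(colMeans(dxh), each = n) -
           cache$xh * rep(colMeans(dxh * cache$xh), each = n)) *
    rep(cache$ivar, each = n)
  list(dx = dx, dg = dg, db = db)
}
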