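# ---- batched forward and backward passes ----
#
# Tensor layout: batches of B samples, T frames, J = 17 joints.  The
# "spatial" index S = B*T orders samples fastest, frames second, so an
# array (B, T, C) and a matrix (B*T, C) address the same rows.  All heavy
# products are single BLAS calls on matricized arrays.

.addb <- function(x, b) x + rep(b, each = nrow(x))

# (J, S, C) array -> per-spatial-position mean over joints: (S, C)
.pool_joints <- function(H) {
  d <- dim(H)
  matrix(colMeans(matrix(H, d[1], d[2] * d[3])), d[2], d[3])
}

# broadcast an (S, C) matrix over J joints -> (J, S, C)
.bcast_joints <- function(M, J) {
  array(rep(M, each = J), c(J, nrow(M), ncol(M)))
}

#' Assemble a model input batch from stroke samples
#'
#' Normalizes keypoints (mid-hip centered, stature-scaled), stacks the
#' visual and kinematic modalities, and encodes labels and handedness.
#'
#' @param samples List of `stroke_sample` objects.
#' @param scaler Optional kinematic feature scaler (list with `mean`, `sd`)
#'   as stored by a fitted model.
#' @return List with arrays `K` (B,T,17,3), `rgb` (B,T,rgb_dim),
#'   `kin` (B,Tw,12), vector `hand`, and integer labels `y_asym`, `y_risk`.
#' @export
assemble_batch <- function(samples, scaler = NULL) {
  B <- length(samples)
  s1 <- samples[[1]]
  Tn <- n_frames(s1$keypoints)
  Tw <- nrow(s1$kin)
  K <- array(0, c(B, Tn, 17, 3))
  rgb <- array(0, c(B, Tn, ncol(s1$rgb)))
  kin <- array(0, c(B, Tw, ncol(s1$kin)))
  hand <- character(B)
  for (i in seq_len(B)) {
    s <- samples[[i]]
    co <- s$keypoints$coords
    mid <- (co[, .J$left_hip, ] + co[, .J$right_hip, ]) / 2
    for (d in 1:3) K[i, , , d] <- (co[, , d] - mid[, d]) / s$height
    rgb[i, , ] <- s$rgb
    kin[i, , ] <- s$kin
    hand[i] <- s$handedness
  }
  if (!is.null(scaler)) {
    km <- matrix(kin, B * Tw, dim(kin)[3])
    km <- sweep(km, 2, scaler$mean) / rep(scaler$sd, each = nrow(km))
    kin <- array(km, dim(kin))
  }
  list(
    K = K, rgb = rgb, kin = kin, hand = hand,
    y_asym = match(vapply(samples, `[[`, "", "label"), asym_classes()),
    y_risk = match(vapply(samples, `[[`, "", "risk"), risk_classes())
  )
}

# dropout helper: returns list(out, mask); identity in eval mode
.dropout <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - p) / (1 - p),
                 nrow(x), ncol(x))
  list(out = x * mask, mask = mask)
}

# batched causal dilated conv: X (B,T,C) -> (B*T, Cout)
.tcn_conv_batch <- function(X, W, kernel, dilation) {
  d <- dim(X)
  B <- d[1]; Tn <- d[2]; C <- d[3]
  Z <- matrix(0, B * Tn, ncol(W))
  for (j in seq_len(kernel) - 1L) {
    sh <- j * dilation
    if (sh >= Tn) next
    Xs <- array(0, d)
    Xs[, (sh + 1):Tn, ] <- X[, 1:(Tn - sh), , drop = FALSE]
    Wj <- W[(j * C + 1):((j + 1) * C), , drop = FALSE]
    Z <- Z + matrix(Xs, B * Tn, C) %*% Wj
  }
  Z
}

#' Full multimodal forward pass
#'
#' Runs the modality encoders, cross-modal fusion, spatiotemporal core and
#' both task heads for a batch.  With `training = TRUE` batch statistics
#' and dropout are active and a cache for the backward pass is returned.
#'
#' @param model A `stroke_model_params`.
#' @param batch Output of [assemble_batch()].
#' @param training Logical.
#' @return List with `asym` (B x 4 logits), `risk` (B x 3 logits) and,
#'   when training, `cache`.
#' @export
nn_forward <- function(model, batch, training = FALSE) {
  P <- model$params
  cfg <- model$config
  bn <- model$bn
  mods <- cfg$modalities
  B <- dim(batch$K)[1]; Tn <- dim(batch$K)[2]; J <- 17L
  S <- B * Tn
  grp <- rep(seq_len(B), Tn)
  cache <- list(B = B, Tn = Tn, grp = grp)

  feats <- list()

  # skeleton embedding (always computed: the GCN consumes it when present)
  if ("skeleton" %in% mods) {
    Kp <- aperm(batch$K, c(3, 1, 2, 4))        # (J, B, T, 3)
    dim(Kp) <- c(J, S, 3)
    Kpm <- matrix(Kp, J * S, 3)
    emb_pre <- .addb(Kpm %*% P$sk_emb_W, P$sk_emb_b)
    emb <- .relu(emb_pre)
    Hemb <- array(emb, c(J, S, cfg$joint_embed))
    Msk <- .pool_joints(Hemb)
    skm <- rowsum(Msk, grp) / Tn
    sk_pre <- .addb(skm %*% P$sk_mod_W, P$sk_mod_b)
    sk_feat <- .relu(sk_pre)
    feats$skeleton <- sk_feat
    cache$Kpm <- Kpm; cache$emb <- emb; cache$Hemb <- Hemb
    cache$skm <- skm; cache$sk_feat <- sk_feat
  }
  if ("rgb" %in% mods) {
    if (dim(batch$rgb)[3] != cfg$rgb_dim) {
      stop("visual feature dimension ", dim(batch$rgb)[3],
           " does not match the configured rgb_dim ", cfg$rgb_dim,
           call. = FALSE)
    }
    Rm <- matrix(batch$rgb, S, cfg$rgb_dim)
    r_act <- .relu(.addb(Rm %*% P$rgb_W, P$rgb_b))
    rgb_feat <- rowsum(r_act, grp) / Tn
    feats$rgb <- rgb_feat
    cache$Rm <- Rm; cache$r_act <- r_act
  }
  if ("kinematic" %in% mods) {
    Tw <- dim(batch$kin)[2]
    grpw <- rep(seq_len(B), Tw)
    Km <- matrix(batch$kin, B * Tw, cfg$kin_dim)
    z1 <- .addb(Km %*% P$kin_W1, P$kin_b1)
    if (training) {
      bn1 <- .bn_train(z1, P$kin_bn1_g, P$kin_bn1_b, bn, "kin_bn1")
      h1 <- bn1$out
    } else h1 <- .bn_eval(z1, P$kin_bn1_g, P$kin_bn1_b, bn, "kin_bn1")
    a1 <- .relu(h1)
    z2 <- .addb(a1 %*% P$kin_W2, P$kin_b2)
    if (training) {
      bn2 <- .bn_train(z2, P$kin_bn2_g, P$kin_bn2_b, bn, "kin_bn2")
      h2 <- bn2$out
    } else h2 <- .bn_eval(z2, P$kin_bn2_g, P$kin_bn2_b, bn, "kin_bn2")
    a2 <- .relu(h2)
    a3 <- .relu(.addb(a2 %*% P$kin_W3, P$kin_b3))
    kin_feat <- rowsum(a3, grpw) / Tw
    feats$kinematic <- kin_feat
    cache$Km <- Km; cache$a1 <- a1; cache$a2 <- a2; cache$a3 <- a3
    cache$grpw <- grpw; cache$Tw <- Tw
    if (training) { cache$bn1 <- bn1; cache$bn2 <- bn2 }
  }

  m <- length(feats)
  use_att <- m >= 3 && cfg$fusion == "attention"
  if (use_att) {
    Fm <- array(0, c(B, 3, cfg$modal_dim))
    for (i in 1:3) Fm[, i, ] <- feats[[i]]
    Fm2 <- matrix(Fm, B * 3, cfg$modal_dim)
    Qa <- array(Fm2 %*% P$att_Wq, c(B, 3, cfg$d_k))
    Ka <- array(Fm2 %*% P$att_Wk, c(B, 3, cfg$d_k))
    Va <- array(Fm2 %*% P$att_Wv, c(B, 3, cfg$modal_dim))
    Sc <- array(0, c(B, 3, 3))
    for (i in 1:3) for (j in 1:3) {
      Sc[, i, j] <- rowSums(Qa[, i, , drop = FALSE][, 1, ] *
                              Ka[, j, , drop = FALSE][, 1, ]) / sqrt(cfg$d_k)
    }
    A <- Sc
    for (i in 1:3) {
      mx <- pmax(Sc[, i, 1], Sc[, i, 2], Sc[, i, 3])
      e1 <- exp(Sc[, i, 1] - mx); e2 <- exp(Sc[, i, 2] - mx)
      e3 <- exp(Sc[, i, 3] - mx)
      tot <- e1 + e2 + e3
      A[, i, 1] <- e1 / tot; A[, i, 2] <- e2 / tot; A[, i, 3] <- e3 / tot
    }
    fuse_in <- matrix(0, B, cfg$modal_dim)
    for (i in 1:3) for (j in 1:3) {
      fuse_in <- fuse_in + A[, i, j] * Va[, j, , drop = FALSE][, 1, ]
    }
    fuse_in <- fuse_in / 3
    cache$Fm2 <- Fm2; cache$Qa <- Qa; cache$Ka <- Ka; cache$Va <- Va
    cache$A <- A
  } else if (cfg$fusion == "concat" && m >= 2) {
    fuse_in <- do.call(cbind, feats)
  } else {
    fuse_in <- Reduce(`+`, feats) / m
  }
  cache$fuse_in <- fuse_in; cache$m <- m; cache$use_att <- use_att

  fused_pre <- .addb(fuse_in %*% P$fuse_W, P$fuse_b)
  fused <- .relu(fused_pre)
  dr1 <- .dropout(fused, cfg$dropout, training)
  fsm_pre <- .addb(dr1$out %*% P$proj_W, P$proj_b)
  fsmall <- .relu(fsm_pre)
  cache$fused <- fused; cache$dr1 <- dr1$mask; cache$fused_d <- dr1$out
  cache$fsmall <- fsmall

  # spatiotemporal core over node features [joint embedding | fused vector]
  Fb <- fsmall[grp, , drop = FALSE]
  if ("skeleton" %in% mods) {
    H0 <- array(0, c(J, S, cfg$joint_embed + cfg$fused_proj))
    H0[, , seq_len(cfg$joint_embed)] <- cache$Hemb
    H0[, , cfg$joint_embed + seq_len(cfg$fused_proj)] <- .bcast_joints(Fb, J)
  } else {
    H0 <- .bcast_joints(Fb, J)
  }
  A_by_hand <- list(
    right = normalized_adjacency(build_skeleton_graph("right")),
    left = normalized_adjacency(build_skeleton_graph("left"))
  )
  hand_cols <- lapply(c("right", "left"), function(hd) {
    b_idx <- which(batch$hand == hd)
    if (!length(b_idx)) return(integer(0))
    as.vector(outer(b_idx, (seq_len(Tn) - 1L) * B, `+`))
  })
  names(hand_cols) <- c("right", "left")
  cache$A_by_hand <- A_by_hand; cache$hand_cols <- hand_cols

  X <- H0
  gcn_cache <- vector("list", cfg$gcn_layers)
  for (l in seq_len(cfg$gcn_layers)) {
    d <- dim(X)
    AX <- X
    for (hd in c("right", "left")) {
      cols <- hand_cols[[hd]]
      if (!length(cols)) next
      sub <- X[, cols, , drop = FALSE]
      sd2 <- dim(sub)
      AXs <- A_by_hand[[hd]] %*% matrix(sub, J, sd2[2] * sd2[3])
      AX[, cols, ] <- array(AXs, sd2)
    }
    W <- P[[paste0("gcn_W", l)]]
    AXm <- matrix(AX, J * S, d[3])
    pre <- .addb(AXm %*% W, P[[paste0("gcn_b", l)]])
    act <- .relu(pre)
    gcn_cache[[l]] <- list(AXm = AXm, act = act, din = d[3])
    X <- array(act, c(J, S, ncol(W)))
  }
  cache$gcn <- gcn_cache; cache$H0_dims <- dim(H0)

  Pl <- .pool_joints(X)                       # (S, C)
  Xt <- array(Pl, c(B, Tn, cfg$gcn_hidden))
  cache$gcn_out_dims <- dim(X)

  if (isTRUE(cfg$kin_to_core)) {
    # align window descriptors to frames (window w covers frames w..w+4;
    # frame t reads the window centered nearest to it)
    Tw <- dim(batch$kin)[2]
    widx <- pmin(pmax(seq_len(Tn) - 2L, 1L), Tw)
    Xt2 <- array(0, c(B, Tn, cfg$gcn_hidden + cfg$kin_dim))
    Xt2[, , seq_len(cfg$gcn_hidden)] <- Xt
    Xt2[, , cfg$gcn_hidden + seq_len(cfg$kin_dim)] <-
      batch$kin[, widx, , drop = FALSE]
    Xt <- Xt2
  }

  tcn_cache <- vector("list", cfg$tcn_layers)
  for (l in seq_len(cfg$tcn_layers)) {
    W <- P[[paste0("tcn_W", l)]]
    Z <- .addb(.tcn_conv_batch(Xt, W, cfg$tcn_kernel, cfg$tcn_dilations[l]),
               P[[paste0("tcn_b", l)]])
    key <- paste0("tcn_bn", l)
    if (training) {
      bnc <- .bn_train(Z, P[[paste0(key, "_g")]], P[[paste0(key, "_b")]],
                       bn, key)
      h <- bnc$out
    } else {
      bnc <- NULL
      h <- .bn_eval(Z, P[[paste0(key, "_g")]], P[[paste0(key, "_b")]],
                    bn, key)
    }
    act <- .relu(h)
    tcn_cache[[l]] <- list(X = Xt, bn = bnc, act = act)
    Xt <- array(act, c(B, Tn, cfg$tcn_channels))
  }
  cache$tcn <- tcn_cache

  rep_vec <- rowsum(matrix(Xt, S, cfg$tcn_channels), grp) / Tn
  cache$rep <- rep_vec

  heads <- list()
  for (task in c("asym", "risk")) {
    x <- rep_vec
    hc <- list()
    for (l in 1:3) {
      a <- .relu(.addb(x %*% P[[paste0(task, "_W", l)]],
                       P[[paste0(task, "_b", l)]]))
      dr <- .dropout(a, cfg$dropout, training)
      hc[[l]] <- list(x = x, act = a, mask = dr$mask, out = dr$out)
      x <- dr$out
    }
    logits <- .addb(x %*% P[[paste0(task, "_out_W")]],
                    P[[paste0(task, "_out_b")]])
    hc$logits_in <- x
    heads[[task]] <- list(layers = hc, logits = logits)
  }
  cache$heads <- heads

  out <- list(asym = heads$asym$logits, risk = heads$risk$logits)
  if (training) out$cache <- cache
  out
}

#' Backward pass
#'
#' Propagates task logit gradients through the full network, returning
#' parameter gradients named like the parameters.
#'
#' @param model A `stroke_model_params`.
#' @param cache Cache from `nn_forward(..., training = TRUE)`.
#' @param d_asym,d_risk Gradients of the loss w.r.t. the two logit matrices.
#' @return Named list of gradients.
#' @keywords internal
nn_backward <- function(model, cache, d_asym, d_risk) {
  P <- model$params
  cfg <- model$config
  B <- cache$B; Tn <- cache$Tn; J <- 17L
  S <- B * Tn
  grp <- cache$grp
  G <- list()

  # heads
  drep <- matrix(0, B, cfg$tcn_channels)
  for (task in c("asym", "risk")) {
    hd <- cache$heads[[task]]
    dl <- if (task == "asym") d_asym else d_risk
    G[[paste0(task, "_out_W")]] <- t(hd$layers$logits_in) %*% dl
    G[[paste0(task, "_out_b")]] <- colSums(dl)
    dx <- dl %*% t(P[[paste0(task, "_out_W")]])
    for (l in 3:1) {
      lc <- hd$layers[[l]]
      if (!is.null(lc$mask)) dx <- dx * lc$mask
      dpre <- dx * (lc$act > 0)
      G[[paste0(task, "_W", l)]] <- t(lc$x) %*% dpre
      G[[paste0(task, "_b", l)]] <- colSums(dpre)
      dx <- dpre %*% t(P[[paste0(task, "_W", l)]])
    }
    drep <- drep + dx
  }

  # temporal pooling
  dXt_mat <- drep[grp, , drop = FALSE] / Tn

  # TCN stack
  for (l in cfg$tcn_layers:1) {
    lc <- cache$tcn[[l]]
    dact <- dXt_mat
    dpre_bn <- dact * (lc$act > 0)
    key <- paste0("tcn_bn", l)
    bb <- .bn_backward(dpre_bn, lc$bn, P[[paste0(key, "_g")]])
    G[[paste0(key, "_g")]] <- bb$dg
    G[[paste0(key, "_b")]] <- bb$db
    dz <- bb$dx
    G[[paste0("tcn_b", l)]] <- colSums(dz)
    Xl <- lc$X
    d <- dim(Xl)
    C <- d[3]
    W <- P[[paste0("tcn_W", l)]]
    dW <- matrix(0, nrow(W), ncol(W))
    dX <- array(0, d)
    dzA <- array(dz, c(B, Tn, ncol(W)))
    dil <- cfg$tcn_dilations[l]
    for (j in seq_len(cfg$tcn_kernel) - 1L) {
      sh <- j * dil
      if (sh >= Tn) next
      Xs <- array(0, d)
      Xs[, (sh + 1):Tn, ] <- Xl[, 1:(Tn - sh), , drop = FALSE]
      rows <- (j * C + 1):((j + 1) * C)
      dW[rows, ] <- t(matrix(Xs, B * Tn, C)) %*% dz
      dXs <- dz %*% t(W[rows, , drop = FALSE])
      dXsA <- array(dXs, c(B, Tn, C))
      dX[, 1:(Tn - sh), ] <- dX[, 1:(Tn - sh), , drop = FALSE] +
        dXsA[, (sh + 1):Tn, , drop = FALSE]
    }
    G[[paste0("tcn_W", l)]] <- dW
    dXt_mat <- matrix(dX, B * Tn, C)
  }

  # joint pooling -> GCN output (the frame-aligned kinematic channels are
  # network inputs, so their gradient slice is dropped)
  if (isTRUE(cfg$kin_to_core)) {
    dXt_arr <- array(dXt_mat, c(B, Tn, cfg$gcn_hidden + cfg$kin_dim))
    dXt_mat <- matrix(dXt_arr[, , seq_len(cfg$gcn_hidden), drop = FALSE],
                      S, cfg$gcn_hidden)
  }
  dPl <- dXt_mat                               # (S, C)
  dX_arr <- .bcast_joints(dPl, J) / J

  for (l in cfg$gcn_layers:1) {
    lc <- cache$gcn[[l]]
    dact <- matrix(dX_arr, J * S, dim(dX_arr)[3])
    dpre <- dact * (lc$act > 0)
    W <- P[[paste0("gcn_W", l)]]
    G[[paste0("gcn_W", l)]] <- t(lc$AXm) %*% dpre
    G[[paste0("gcn_b", l)]] <- colSums(dpre)
    dAX <- array(dpre %*% t(W), c(J, S, lc$din))
    dXl <- dAX
    for (hd in c("right", "left")) {
      cols <- cache$hand_cols[[hd]]
      if (!length(cols)) next
      sub <- dAX[, cols, , drop = FALSE]
      sd2 <- dim(sub)
      dXs <- cache$A_by_hand[[hd]] %*% matrix(sub, J, sd2[2] * sd2[3])
      dXl[, cols, ] <- array(dXs, sd2)
    }
    dX_arr <- dXl
  }

  # split node input gradient: joint embedding part + broadcast fused part
  if ("skeleton" %in% cfg$modalities) {
    dHemb_gcn <- dX_arr[, , seq_len(cfg$joint_embed), drop = FALSE]
    dtail <- dX_arr[, , cfg$joint_embed + seq_len(cfg$fused_proj),
                    drop = FALSE]
  } else {
    dHemb_gcn <- NULL
    dtail <- dX_arr
  }
  dFb <- matrix(colSums(matrix(dtail, J, S * cfg$fused_proj)), S,
                cfg$fused_proj)
  dfsmall <- rowsum(dFb, grp)

  # fusion projection
  dfsm_pre <- dfsmall * (cache$fsmall > 0)
  G$proj_W <- t(cache$fused_d) %*% dfsm_pre
  G$proj_b <- colSums(dfsm_pre)
  dfused_d <- dfsm_pre %*% t(P$proj_W)
  if (!is.null(cache$dr1)) dfused_d <- dfused_d * cache$dr1
  dfused_pre <- dfused_d * (cache$fused > 0)
  G$fuse_W <- t(cache$fuse_in) %*% dfused_pre
  G$fuse_b <- colSums(dfused_pre)
  dfuse_in <- dfused_pre %*% t(P$fuse_W)

  mods <- cfg$modalities
  dfeats <- list()
  if (cache$use_att) {
    A <- cache$A; Va <- cache$Va; Qa <- cache$Qa; Ka <- cache$Ka
    dfr <- dfuse_in / 3
    dVa <- array(0, dim(Va))
    dA <- array(0, c(B, 3, 3))
    for (j in 1:3) {
      wj <- A[, 1, j] + A[, 2, j] + A[, 3, j]
      dVa[, j, ] <- wj * dfr
      for (i in 1:3) dA[, i, j] <- rowSums(dfr * Va[, j, , drop = FALSE][, 1, ])
    }
    dS <- array(0, c(B, 3, 3))
    for (i in 1:3) {
      dot <- A[, i, 1] * dA[, i, 1] + A[, i, 2] * dA[, i, 2] +
        A[, i, 3] * dA[, i, 3]
      for (j in 1:3) dS[, i, j] <- A[, i, j] * (dA[, i, j] - dot)
    }
    sq <- sqrt(cfg$d_k)
    dQa <- array(0, dim(Qa))
    dKa <- array(0, dim(Ka))
    for (i in 1:3) for (j in 1:3) {
      dQa[, i, ] <- dQa[, i, ] + dS[, i, j] * Ka[, j, , drop = FALSE][, 1, ] / sq
      dKa[, j, ] <- dKa[, j, ] + dS[, i, j] * Qa[, i, , drop = FALSE][, 1, ] / sq
    }
    dQm <- matrix(dQa, B * 3, cfg$d_k)
    dKm <- matrix(dKa, B * 3, cfg$d_k)
    dVm <- matrix(dVa, B * 3, cfg$modal_dim)
    G$att_Wq <- t(cache$Fm2) %*% dQm
    G$att_Wk <- t(cache$Fm2) %*% dKm
    G$att_Wv <- t(cache$Fm2) %*% dVm
    dFm2 <- dQm %*% t(P$att_Wq) + dKm %*% t(P$att_Wk) + dVm %*% t(P$att_Wv)
    dFm <- array(dFm2, c(B, 3, cfg$modal_dim))
    for (i in seq_along(mods)) dfeats[[mods[i]]] <- dFm[, i, ]
  } else if (cfg$fusion == "concat" && cache$m >= 2) {
    for (i in seq_along(mods)) {
      cols <- (i - 1) * cfg$modal_dim + seq_len(cfg$modal_dim)
      dfeats[[mods[i]]] <- dfuse_in[, cols, drop = FALSE]
    }
  } else {
    for (nm in mods) dfeats[[nm]] <- dfuse_in / cache$m
  }

  # modality encoders
  if ("skeleton" %in% mods) {
    dsk <- dfeats$skeleton * (cache$sk_feat > 0)
    G$sk_mod_W <- t(cache$skm) %*% dsk
    G$sk_mod_b <- colSums(dsk)
    dskm <- dsk %*% t(P$sk_mod_W)
    dMsk <- dskm[grp, , drop = FALSE] / Tn
    dHemb <- .bcast_joints(dMsk, J) / J
    if (!is.null(dHemb_gcn)) dHemb <- dHemb + dHemb_gcn
    demb_pre <- matrix(dHemb, J * S, cfg$joint_embed) * (cache$emb > 0)
    G$sk_emb_W <- t(cache$Kpm) %*% demb_pre
    G$sk_emb_b <- colSums(demb_pre)
  }
  if ("rgb" %in% mods) {
    dact <- dfeats$rgb[grp, , drop = FALSE] / Tn
    dpre <- dact * (cache$r_act > 0)
    G$rgb_W <- t(cache$Rm) %*% dpre
    G$rgb_b <- colSums(dpre)
  }
  if ("kinematic" %in% mods) {
    da3 <- dfeats$kinematic[cache$grpw, , drop = FALSE] / cache$Tw
    dpre3 <- da3 * (cache$a3 > 0)
    G$kin_W3 <- t(cache$a2) %*% dpre3
    G$kin_b3 <- colSums(dpre3)
    da2 <- (dpre3 %*% t(P$kin_W3)) * (cache$a2 > 0)
    bb2 <- .bn_backward(da2, cache$bn2, P$kin_bn2_g)
    G$kin_bn2_g <- bb2$dg; G$kin_bn2_b <- bb2$db
    dz2 <- bb2$dx
    G$kin_W2 <- t(cache$a1) %*% dz2
    G$kin_b2 <- colSums(dz2)
    da1 <- (dz2 %*% t(P$kin_W2)) * (cache$a1 > 0)
    bb1 <- .bn_backward(da1, cache$bn1, P$kin_bn1_g)
    G$kin_bn1_g <- bb1$dg; G$kin_bn1_b <- bb1$db
    dz1 <- bb1$dx
    G$kin_W1 <- t(cache$Km) %*% dz1
    G$kin_b1 <- colSums(dz1)
  }
  G
}

#' Forward a single stroke sample through a model
#'
#' Evaluation-mode convenience wrapper: assembles a one-sample batch and
#' returns both heads' logits and class probabilities.
#'
#' @param sample A `stroke_sample`.
#' @param model A `stroke_model_params` or fitted `stroke_model`.
#' @return List with `asym`, `risk` (logit vectors), `p_asym`, `p_risk`
#'   (softmax probabilities).
#' @export
model_forward <- function(sample, model) {
  batch <- assemble_batch(list(sample), scaler = model$scaler)
  out <- nn_forward(model, batch, training = FALSE)
  list(asym = drop(out$asym), risk = drop(out$risk),
       p_asym = drop(softmax(out$asym)), p_risk = drop(softmax(out$risk)))
}

#' Row-wise softmax
#'
#' @param x Matrix of logits (or a vector).
#' @return Matrix (or vector) of probabilities summing to 1 per row.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  e <- exp(sweep(x, 1, apply(x, 1, max)))
  e / rowSums(e)
}
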