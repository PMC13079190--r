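# shared fixtures built in code

# small deterministic sample cache so expensive generation happens once
.fix <- new.env()

fix_sample <- function(seed = 11, type = "forehand_drive",
                       params = asymmetry_params(shoulder_rot = 20,
                                                 pelvic_tilt = 6),
                       noise_sd = 0.01, handedness = "right") {
  key <- paste(seed, type, noise_sd, handedness,
               paste(unlist(params), collapse = ","), sep = "|")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate_stroke(stroke_template(type), params, seed = seed,
                                   noise_sd = noise_sd,
                                   handedness = handedness)
  }
  .fix[[key]]
}

# tiny model configuration for fast network tests
tiny_config <- function(...) {
  model_config(joint_embed = 4, kin_mlp = c(6, 8, 8), rgb_dim = 256,
               modal_dim = 8, d_k = 4, fusion_dim = 10, fused_proj = 6,
               gcn_hidden = 5, tcn_channels = 5, head_dims = c(7, 6, 5),
               dropout = 0, ...)
}

stroke_types <- c("forehand_drive", "backhand_push", "serve", "chop")

tiny_samples <- function(n = 4) {
  lapply(seq_len(n), function(i) {
    generate_stroke(stroke_template(stroke_types[(i %% 4) + 1]),
                    asymmetry_params(shoulder_rot = 5 * i,
                                     pelvic_tilt = 1.5 * i),
                    seed = 100 + i,
                    handedness = if (i %% 2) "right" else "left")
  })
}

# random simplex rows
rand_simplex <- function(n, k) {
  x <- matrix(stats::rexp(n * k), n, k)
  x / rowSums(x)
}
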