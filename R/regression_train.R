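## initial-box jitter used to build regression training pairs: moderate
## perturbations of the truth box, the regime the gated proposals occupy
jitter_box <- function(truth, n) {
  dplyr::bind_rows(lapply(seq_len(n), function(k) {
    bbox(
      truth$x + runif(1, -0.3, 0.3) * truth$w,
      truth$y + runif(1, -0.3, 0.3) * truth$h,
      truth$w * exp(runif(1, -0.35, 0.35)),
      truth$h * exp(runif(1, -0.35, 0.35))
    )
  }))
}

#' Train the iterative box regressor
#'
#' Desk-scale trainable regressor: one ridge-regression head per step
#' `s = 1..S`, fitted on context-window crop features (see the feature
#' extractor: a 2x-expanded crop around the box plus darkness moments that
#' locate the hypoechoic lesion relative to the box).  Training pairs are
#' jittered truth boxes; each step's input boxes are the previous step's
#' stepped targets (teacher forcing), and each step's regression target is
#' the delta to `Phi(B, G, s)`.  Background pairs (Jaccard `< bg_bound`
#' against truth) are excluded, mirroring the indicator in the training
#' loss.  Fully seeded and reproducible.
#'
#' @param samples List of phantom samples with `image` and `truth_box`.
#' @param cfg A [pipeline_config()]; uses `total_steps`,
#'   `background_jaccard`, `rng_seed`.
#' @param n_init Jittered initial boxes per sample (default 4).
#' @param lambda Ridge penalty (default 1).
#' @return A `"box_regressor"`.
#' @export
train_regressor <- function(samples, cfg = pipeline_config(), n_init = 4,
                            lambda = 1) {
  if (length(samples) == 0) abort("no training samples")
  samples <- Filter(function(s) !is.null(s$truth_box) &&
                      nrow(s$truth_box) > 0, samples)
  if (length(samples) == 0) abort("no samples with a truth box")
  set.seed(cfg$rng_seed)
  S <- cfg$total_steps

  cur <- list()  # per sample: boxes for current step
  for (i in seq_along(samples)) cur[[i]] <- jitter_box(samples[[i]]$truth_box, n_init)

  models <- vector("list", S)
  mu <- sg <- NULL
  for (s in seq_len(S)) {
    Xl <- list(); Yl <- list()
    for (i in seq_along(samples)) {
      sm <- samples[[i]]
      B <- cur[[i]]
      keep <- box_jaccard(B, sm$truth_box) >= cfg$background_jaccard
      if (any(keep)) {
        Bk <- B[keep, , drop = FALSE]
        tgt <- step_target(Bk, sm$truth_box, s, S)
        Xl[[length(Xl) + 1]] <- regressor_features(sm$image, Bk)
        Yl[[length(Yl) + 1]] <- as.matrix(encode_delta(Bk, tgt))
      }
      cur[[i]] <- step_target(B, sm$truth_box, s, S)  # teacher forcing
    }
    if (length(Xl) == 0) {
      abort("all training boxes are background; nothing to regress")
    }
    X <- do.call(rbind, Xl)
    Y <- do.call(rbind, Yl)
    if (s == 1) {
      mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
    }
    Xs <- cbind(1, sweep(sweep(X, 2, mu, "-"), 2, sg, "/"))
    P <- diag(c(0, rep(lambda, ncol(Xs) - 1)))
    models[[s]] <- solve(crossprod(Xs) + P, crossprod(Xs, Y))
  }

  new_box_regressor(function(img, boxes, s, S_run) {
    beta <- models[[min(max(s, 1), S)]]
    F <- regressor_features(img, boxes)
    Fs <- cbind(1, sweep(sweep(F, 2, mu, "-"), 2, sg, "/"))
    D <- Fs %*% beta
    tibble(t_x = D[, 1], t_y = D[, 2], t_w = D[, 3], t_h = D[, 4])
  }, "trained-ridge")
}
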