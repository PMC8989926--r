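#' Box-to-delta and delta-to-box transforms
#'
#' `encode_delta()` expresses the discrepancy between a box `B` and a
#' target box `G` as the dimensionless offset
#' `delta = ((x* - x)/w, (y* - y)/h, log(w*/w), log(h*/h))`, with natural
#' logarithms and `B`'s own width and height as the normalizers.
#' `apply_delta()` is its exact inverse:
#' `G = (x + t_x w, y + t_y h, w e^{t_w}, h e^{t_h})`, so
#' `apply_delta(B, encode_delta(B, G)) == G` and the exponential keeps
#' dimensions positive for any finite delta.  Both are vectorized row-wise.
#'
#' @param B,G Box tibbles (recycled row-wise against each other).
#' @param delta A delta tibble with columns `t_x`, `t_y`, `t_w`, `t_h`.
#' @return `encode_delta()`: a delta tibble; `apply_delta()`: a box tibble.
#' @examples
#' encode_delta(bbox(10, 20, 40, 60), bbox(14, 26, 40, 60))
#' @export
encode_delta <- function(B, G) {
  if (any(B$w <= 0) || any(B$h <= 0) || any(G$w <= 0) || any(G$h <= 0)) {
    abort("boxes must have positive dimensions")
  }
  tibble(
    t_x = (G$x - B$x) / B$w,
    t_y = (G$y - B$y) / B$h,
    t_w = log(G$w / B$w),
    t_h = log(G$h / B$h)
  )
}

#' @rdname encode_delta
#' @export
apply_delta <- function(B, delta) {
  if (any(!is.finite(as.matrix(delta[c("t_x", "t_y", "t_w", "t_h")])))) {
    abort("delta components must be finite")
  }
  bbox(
    x = B$x + delta$t_x * B$w,
    y = B$y + delta$t_y * B$h,
    w = B$w * exp(delta$t_w),
    h = B$h * exp(delta$t_h),
    confidence = if ("confidence" %in% names(B)) B$confidence else NA_real_
  )
}

#' Stepped regression target
#'
#' The iterative scheme does not aim at the truth box in one jump: at step
#' `s` of `S` the target is `B + (G - B) / (S - s + 1)`, componentwise — a
#' fraction of the remaining correction.  At `s = S` the denominator is 1
#' and the target is `G` exactly, so a regressor that hits every stepped
#' target lands on the truth after `S` steps.
#'
#' @param B_s Current box (tibble, recycled row-wise with `G`).
#' @param G Truth box.
#' @param s Current step, `1 <= s <= S`.
#' @param S Total steps.
#' @return Box tibble of intermediate targets.
#' @export
step_target <- function(B_s, G, s, S) {
  if (s < 1 || s > S) abort("step index s must satisfy 1 <= s <= S")
  f <- 1 / (S - s + 1)
  bbox(
    x = B_s$x + (G$x - B_s$x) * f,
    y = B_s$y + (G$y - B_s$y) * f,
    w = B_s$w + (G$w - B_s$w) * f,
    h = B_s$h + (G$h - B_s$h) * f
  )
}

#' Smooth L1 loss
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise; quadratic near zero,
#' linear in the tails.  Vectorized.
#'
#' @param x Numeric vector.
#' @return Numeric vector of losses.
#' @export
smooth_l1 <- function(x) {
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

#' Background-masked regression loss
#'
#' The training loss of the box regressor at step `s`: for each box the
#' per-component smooth-L1 of (predicted delta minus the delta to the
#' stepped target `Phi(B, G, s)`), summed over components and boxes.
#' Boxes whose Jaccard index with their truth box is below `bg_bound` are
#' background and contribute exactly zero.
#'
#' @param pred_deltas Delta tibble of predictions, one row per box.
#' @param boxes Box tibble of current boxes `B`.
#' @param truths Box tibble of truth boxes `G`, aligned with `boxes`.
#' @param s,S Current and total step counts.
#' @param bg_bound Background Jaccard bound (default 0.2).
#' @return A list: `total` (the loss), `per_box` tibble with `jaccard`,
#'   `background` flag and each box's summed contribution.
#' @export
regression_loss <- function(pred_deltas, boxes, truths, s, S,
                            bg_bound = 0.2) {
  n <- nrow(boxes)
  if (nrow(pred_deltas) != n || nrow(truths) != n) {
    abort("pred_deltas, boxes and truths must have the same number of rows")
  }
  jac <- box_jaccard(boxes, truths)
  bg <- jac < bg_bound
  tgt <- encode_delta(boxes, step_target(boxes, truths, s, S))
  resid <- as.matrix(pred_deltas[c("t_x", "t_y", "t_w", "t_h")]) -
    as.matrix(tgt)
  contrib <- rowSums(smooth_l1(resid))
  contrib[bg] <- 0
  list(
    total = sum(contrib),
    per_box = tibble(jaccard = jac, background = bg, loss = contrib)
  )
}

## ---- regressor implementations ------------------------------------------
## A regressor is a list of class "box_regressor" with a $predict
## function(img, boxes, s, S) returning a delta tibble (one row per box).

new_box_regressor <- function(predict, kind) {
  structure(list(predict = predict, kind = kind), class = "box_regressor")
}

#' @export
print.box_regressor <- function(x, ...) {
  cat("<box_regressor:", x$kind, ">\n"); invisible(x)
}

#' Stub and oracle box regressors
#'
#' `regressor_zero()` always predicts a zero delta (boxes never move) —
#' the do-nothing baseline.  `regressor_oracle(truth)` knows the truth box
#' and returns the exact delta to the stepped target `Phi(B, G, s)`, so
#' iterating it reaches the truth in exactly `S` steps; it isolates the
#' rest of the pipeline from regressor quality in tests.  With `truth =
#' NULL` the oracle predicts zero deltas.
#'
#' @param truth A one-row box tibble, or `NULL`.
#' @return A `"box_regressor"`.
#' @export
regressor_zero <- function() {
  new_box_regressor(function(img, boxes, s, S) {
    tibble(t_x = rep(0, nrow(boxes)), t_y = 0, t_w = 0, t_h = 0)
  }, "zero")
}

#' @rdname regressor_zero
#' @export
regressor_oracle <- function(truth) {
  new_box_regressor(function(img, boxes, s, S) {
    if (is.null(truth) || nrow(truth) == 0) {
      return(tibble(t_x = rep(0, nrow(boxes)), t_y = 0, t_w = 0, t_h = 0))
    }
    encode_delta(boxes, step_target(boxes, truth, s, S))
  }, "oracle")
}

#' Iterative box refinement
#'
#' Runs the regressor for `S` steps, each time decoding the predicted
#' delta against the current box and feeding the refined box back in:
#' `B^s = Gamma(B^{s-1}, delta^{s-1})`.
#'
#' @param B_init One-row box tibble to start from.
#' @param img Intensity matrix the regressor may look at.
#' @param reg A `"box_regressor"`.
#' @param S Number of steps (default 4).
#' @return A list of `S + 1` one-row box tibbles: the trajectory from
#'   `B_init` to the final box.
#' @export
iterate_regression <- function(B_init, img, reg, S = 4) {
  if (S < 1) abort("S must be >= 1")
  traj <- vector("list", S + 1)
  traj[[1]] <- as_box_tibble(B_init)
  for (s in seq_len(S)) {
    d <- reg$predict(img, traj[[s]], s, S)
    traj[[s + 1]] <- apply_delta(traj[[s]], d)
  }
  traj
}
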