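#' Threshold step of the 10-level quantization
#'
#' The quantization resolution Delta is the absolute maximum over all 106
#' analog parameters of the fold, divided by 5, so that the five positive and
#' five negative levels exactly span the trained parameter range.
#'
#' @param object a fitted `mann` (or any list with `W1`, `b1`, `W2`, `b2`).
#' @return the step Delta (> 0).
#' @export
compute_step <- function(object) {
  par <- object[c("W1", "b1", "W2", "b2")]
  check_params(par)
  m <- max(abs(unlist(par)))
  if (m == 0)
    stop("degenerate network: all parameters are zero, no threshold step exists",
         call. = FALSE)
  m / 5
}

#' Quantize a model for hardware deployment
#'
#' Generic: collapse a trained model's analog parameters onto discrete levels.
#'
#' @param object model to quantize.
#' @param ... method arguments.
#' @export
quantize <- function(object, ...) UseMethod("quantize")

#' Collapse the analog network onto 10 signed levels
#'
#' Each of the 106 parameters is replaced by an integer level in
#' {-5, ..., +5}: magnitudes are shifted up to the next multiple of the
#' threshold step Delta = max|theta|/5 (ceiling semantics; values already on
#' a level boundary keep that level), signs are preserved, and an exact zero
#' maps to level 0 (all devices in the high-resistance state). Only the ten
#' nonzero levels +-1..+-5 are realisable by the synapse hardware; level
#' magnitudes never exceed 5 because Delta is derived from the same
#' parameter set.
#'
#' @param object a fitted [mann()] model.
#' @param n_levels number of nonzero levels (default 10, i.e. +-5); exposed
#'   for resolution sweeps, in which case the step becomes max|theta| /
#'   (n_levels/2).
#' @param ... unused.
#' @return an object of class `mann_q`: integer level matrices/vectors
#'   (`W1`, `b1`, `W2`, `b2`), the step `step`, and `n_levels`. Methods:
#'   [predict.mann_q()], [dequantize()], [coef.mann()] (inherited layout).
#' @export
quantize.mann <- function(object, n_levels = 10, ...) {
  stopifnot(n_levels >= 2, n_levels %% 2 == 0)
  half <- n_levels / 2
  par <- object[c("W1", "b1", "W2", "b2")]
  check_params(par)
  m <- max(abs(unlist(par)))
  if (m == 0)
    stop("degenerate network: all parameters are zero, no threshold step exists",
         call. = FALSE)
  step <- m / half
  lvl <- function(theta) {
    # ceiling with a small guard so fp noise just above an exact multiple of
    # the step does not jump a level; exact multiples map to their own level
    k <- sign(theta) * pmin(ceiling(abs(theta) / step - 1e-9), half)
    storage.mode(k) <- "integer"
    k
  }
  structure(list(W1 = lvl(par$W1), b1 = lvl(par$b1),
                 W2 = lvl(par$W2), b2 = lvl(par$b2),
                 step = step, n_levels = as.integer(n_levels)),
            class = "mann_q")
}

#' @export
print.mann_q <- function(x, ...) {
  lv <- unlist(x[c("W1", "b1", "W2", "b2")])
  cat(sprintf("Quantized 23-4-2 network: %d parameters on %d levels (step Delta = %.5g)\n",
              length(lv), x$n_levels, x$step))
  cat("  level histogram:\n")
  print(table(factor(lv, levels = -(x$n_levels / 2):(x$n_levels / 2))))
  invisible(x)
}

#' Analog surrogate of a quantized network
#'
#' Maps each integer level back to `level * Delta`. This surrogate is the
#' software reference that the simulated hardware must reproduce exactly
#' under nominal currents, no switching failures, linear read-out and
#' unrestricted drive-voltage precision.
#'
#' @param q a `mann_q` object.
#' @return an object of class `c("mann_deq", "mann")` usable with
#'   [predict.mann()].
#' @export
dequantize <- function(q) {
  stopifnot(inherits(q, "mann_q"))
  par <- lapply(q[c("W1", "b1", "W2", "b2")], function(k) k * q$step)
  structure(c(par, list(step = q$step)), class = c("mann_deq", "mann"))
}

#' @export
print.mann_deq <- function(x, ...) {
  cat(sprintf("Dequantized 23-4-2 network (levels x Delta, Delta = %.5g)\n", x$step))
  invisible(x)
}
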