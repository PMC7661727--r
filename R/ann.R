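sigmoid <- function(z) 1 / (1 + exp(-z))

# layer sizes of the neuromorphic-compatible topology
.n_in <- 23L; .n_hidden <- 4L; .n_out <- 2L

#' Training control for [mann()]
#'
#' Defaults reproduce the reference training recipe: mini-batch Adam with
#' learning rate 1e-4, 3000 epochs, batch size 10, and 20% dropout on the
#' hidden layer (inverted scaling, train time only). The Adam moment
#' parameters are the standard (0.9, 0.999, 1e-8).
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size mini-batch size (>= 1); batches are reshuffled each epoch.
#' @param dropout probability of dropping a hidden unit during training,
#'   in [0, 1).
#' @param beta1,beta2,eps Adam first/second-moment decay rates and stabiliser.
#' @return a list of class `mann_control`.
#' @export
mann_control <- function(learning_rate = 1e-4, epochs = 3000, batch_size = 10,
                         dropout = 0.2, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            dropout >= 0, dropout < 1, beta1 >= 0, beta1 < 1,
            beta2 >= 0, beta2 < 1, eps > 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), dropout = dropout,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "mann_control")
}

# Glorot-uniform initialisation; biases start at zero
init_params <- function() {
  gl <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  list(W1 = gl(.n_in, .n_hidden), b1 = numeric(.n_hidden),
       W2 = gl(.n_hidden, .n_out), b2 = numeric(.n_out))
}

check_params <- function(par) {
  stopifnot(is.matrix(par$W1), all(dim(par$W1) == c(.n_in, .n_hidden)),
            length(par$b1) == .n_hidden,
            is.matrix(par$W2), all(dim(par$W2) == c(.n_hidden, .n_out)),
            length(par$b2) == .n_out)
  if (!all(vapply(par, function(p) all(is.finite(p)), logical(1))))
    stop("network parameters must all be finite", call. = FALSE)
  invisible(par)
}

# analog forward pass; X is n x 23. Returns hidden activations and output
# probabilities, both sigmoid-squashed and hence in (0, 1).
forward_analog <- function(par, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(par$W1))
    stop(sprintf("input has %d bits, network expects %d", ncol(X), nrow(par$W1)),
         call. = FALSE)
  H <- sigmoid(sweep(X %*% par$W1, 2, par$b1, "+"))
  O <- sigmoid(sweep(H %*% par$W2, 2, par$b2, "+"))
  colnames(O) <- c("COPD", "HC")
  list(hidden = H, output = O)
}

# mean-over-batch of the per-sample summed binary cross-entropy of the two
# sigmoid outputs; Y is n x 2 one-hot
bce_loss <- function(O, Y) {
  O <- pmin(pmax(O, 1e-12), 1 - 1e-12)
  mean(rowSums(-(Y * log(O) + (1 - Y) * log(1 - O))))
}

# backpropagated gradients of bce_loss through the (optionally dropout-masked)
# forward pass; mask is the inverted-dropout scaling matrix (1/keep or 0)
ann_grads <- function(par, X, Y, mask = NULL) {
  n <- nrow(X)
  H <- sigmoid(sweep(X %*% par$W1, 2, par$b1, "+"))
  Hd <- if (is.null(mask)) H else H * mask
  O <- sigmoid(sweep(Hd %*% par$W2, 2, par$b2, "+"))
  d2 <- (O - Y) / n                      # sigmoid+BCE cancellation
  d1 <- (d2 %*% t(par$W2)) * (if (is.null(mask)) 1 else mask) * H * (1 - H)
  list(W1 = crossprod(X, d1), b1 = colSums(d1),
       W2 = crossprod(Hd, d2), b2 = colSums(d2))
}

#' Fit the 23-4-2 sigmoid classifier
#'
#' Trains the dense neuromorphic-compatible network - 23 input bits, one
#' hidden layer of 4 sigmoid units, 2 sigmoid read-out units (COPD, HC) -
#' by mini-batch Adam on the summed binary cross-entropy of the two outputs,
#' with dropout on the hidden layer during training. The 106 trained analog
#' parameters (23x4 + 4 + 4x2 + 2) are the reference that the quantization
#' ([quantize()]) and hardware ([deploy()]) stages approximate.
#'
#' @param x integer 0/1 matrix of encoded subjects, 23 columns
#'   (see [encode_bits()]).
#' @param y numeric class labels, 1 = COPD, 0 = HC; defaults to the `labels`
#'   attribute attached by [encode_bits()].
#' @param control a [mann_control()].
#' @param seed integer seed governing initialisation, batch shuffling and
#'   dropout masks; identical seeds give bit-identical fits.
#' @return an object of class `mann`: the parameter list (`W1`, `b1`, `W2`,
#'   `b2`), the per-epoch training loss trace, the training data, and the
#'   control settings. Methods: [predict.mann()], [coef.mann()],
#'   [summary.mann()], [residuals.mann()], [plot.mann()].
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_copd = 10, n_hc = 10), seed = 2)
#' bits <- encode_bits(cohort, fit_encoding(encoding_spec(), cohort))
#' fit <- mann(bits, control = mann_control(epochs = 50), seed = 1)
#' table(truth = attr(bits, "labels"), pred = predict(fit, bits))
#' @export
mann <- function(x, y = attr(x, "labels"), control = mann_control(), seed = 1) {
  stopifnot(inherits(control, "mann_control"))
  x <- as.matrix(x)
  if (ncol(x) != .n_in)
    stop(sprintf("x must have %d bit columns, got %d", .n_in, ncol(x)), call. = FALSE)
  if (is.null(y)) stop("class labels are required (y or attr(x, 'labels'))", call. = FALSE)
  y <- as.numeric(y)
  if (nrow(x) == 0) stop("empty training set", call. = FALSE)
  if (length(y) != nrow(x) || !all(y %in% c(0, 1)))
    stop("y must be one 0/1 label per row of x", call. = FALSE)
  Y <- cbind(COPD = y, HC = 1 - y)       # one-hot over the two outputs

  set.seed(as.integer(seed))
  par <- init_params()
  keep <- 1 - control$dropout
  mom <- list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0))
  t_step <- 0
  n <- nrow(x)
  loss_trace <- numeric(control$epochs)

  for (ep in seq_len(control$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = control$batch_size)) {
      idx <- ord[s:min(s + control$batch_size - 1, n)]
      Xb <- x[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      mask <- if (control$dropout > 0)
        matrix(stats::rbinom(length(idx) * .n_hidden, 1, keep), length(idx)) / keep
      else NULL
      g <- ann_grads(par, Xb, Yb, mask)
      t_step <- t_step + 1
      for (nm in names(par)) {
        mom$m[[nm]] <- control$beta1 * mom$m[[nm]] + (1 - control$beta1) * g[[nm]]
        mom$v[[nm]] <- control$beta2 * mom$v[[nm]] + (1 - control$beta2) * g[[nm]]^2
        mhat <- mom$m[[nm]] / (1 - control$beta1^t_step)
        vhat <- mom$v[[nm]] / (1 - control$beta2^t_step)
        par[[nm]] <- par[[nm]] - control$learning_rate * mhat / (sqrt(vhat) + control$eps)
      }
    }
    loss_trace[ep] <- bce_loss(forward_analog(par, x)$output, Y)
    if (!is.finite(loss_trace[ep]))
      stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
  }

  structure(c(lapply(par, unname),
              list(control = control, seed = as.integer(seed),
                   loss = loss_trace, x = x, y = y)),
            class = "mann")
}

#' Extract the analog network parameters
#'
#' @param object a fitted `mann` (or dequantized) model.
#' @param flat return a single named numeric vector of all 106 parameters
#'   instead of the shaped list.
#' @param ... unused.
#' @return list with elements `W1` (23x4), `b1` (4), `W2` (4x2), `b2` (2), or
#'   a length-106 named vector if `flat = TRUE`.
#' @export
coef.mann <- function(object, flat = FALSE, ...) {
  par <- object[c("W1", "b1", "W2", "b2")]
  if (!flat) return(par)
  unlist(par)
}

#' Predict from the analog network
#'
#' @param object a fitted `mann`.
#' @param newdata 0/1 bit matrix (23 columns) or vector (one subject).
#' @param type `"class"` for 1/0 labels (1 = COPD; exact ties break to COPD so
#'   they remain visible), `"prob"` for the two sigmoid outputs, `"hidden"`
#'   for the 4 hidden activations.
#' @param ... unused.
#' @return labels, or an n x 2 (`"prob"`) / n x 4 (`"hidden"`) matrix.
#' @export
predict.mann <- function(object, newdata = object$x,
                         type = c("class", "prob", "hidden"), ...) {
  type <- match.arg(type)
  fwd <- forward_analog(object[c("W1", "b1", "W2", "b2")], newdata)
  switch(type,
         prob   = fwd$output,
         hidden = fwd$hidden,
         class  = classify_outputs(fwd$output))
}

# argmax over (COPD, HC) outputs; ties go to COPD (label 1)
classify_outputs <- function(O) {
  as.integer(O[, 1] >= O[, 2])
}

#' @export
print.mann <- function(x, ...) {
  cat("Sigmoid classifier 23-4-2 (analog parameters)\n")
  cat(sprintf("  106 parameters; trained %d epochs (batch %d, lr %g, dropout %g), seed %d\n",
              x$control$epochs, x$control$batch_size, x$control$learning_rate,
              x$control$dropout, x$seed))
  cat(sprintf("  final training loss %.4f on %d subjects\n",
              x$loss[length(x$loss)], nrow(x$x)))
  invisible(x)
}

#' @export
summary.mann <- function(object, ...) {
  par <- coef(object, flat = TRUE)
  pred <- predict(object, object$x, type = "class")
  out <- list(n_params = length(par), max_abs = max(abs(par)),
              train_acc = mean(pred == object$y) * 100,
              final_loss = object$loss[length(object$loss)],
              control = object$control)
  class(out) <- "summary.mann"
  out
}

#' @export
print.summary.mann <- function(x, ...) {
  cat(sprintf("23-4-2 sigmoid classifier: %d parameters, max |theta| = %.4f\n",
              x$n_params, x$max_abs))
  cat(sprintf("  training accuracy %.2f%%, final loss %.4f\n", x$train_acc, x$final_loss))
  invisible(x)
}

#' Response residuals of the fitted network
#'
#' @param object a fitted `mann`.
#' @param ... unused.
#' @return n x 2 matrix of one-hot targets minus predicted probabilities.
#' @export
residuals.mann <- function(object, ...) {
  cbind(COPD = object$y, HC = 1 - object$y) - predict(object, object$x, "prob")
}

#' Training loss trace
#'
#' @param x a fitted `mann`.
#' @param ... passed to [plot.default()].
#' @export
plot.mann <- function(x, ...) {
  plot(x$loss, type = "l", xlab = "epoch", ylab = "training cross-entropy",
       main = "23-4-2 training loss", ...)
  invisible(x)
}

#' Stratified k-fold cross-validation splits
#'
#' Partitions the sample indices into `n_folds` folds, stratified by label so
#' the class balance is preserved in every test split (with 40 COPD + 40 HC
#' and 5 folds: 8 + 8 test subjects, 64 training). Test sets are pairwise
#' disjoint and their union is the full index set.
#'
#' @param labels 0/1 class labels (or any 2-level vector).
#' @param n_folds number of folds (default 5, i.e. 20% test / 80% train).
#' @param seed integer seed for the within-class shuffling.
#' @return list of `n_folds` elements, each `list(fold, train, test)` of
#'   integer row indices.
#' @export
kfold_split <- function(labels, n_folds = 5, seed = 1) {
  n <- length(labels)
  if (min(table(labels)) < n_folds)
    stop("need at least ", n_folds, " samples per class to split", call. = FALSE)
  set.seed(as.integer(seed))
  fold_of <- integer(n)
  for (lv in unique(labels)) {
    ids <- sample(which(labels == lv))
    fold_of[ids] <- rep_len(seq_len(n_folds), length(ids))
  }
  lapply(seq_len(n_folds), function(k)
    list(fold = k, train = which(fold_of != k), test = which(fold_of == k)))
}
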