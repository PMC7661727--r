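#' Confusion matrix and diagnostic metrics
#'
#' COPD (label 1) is the positive class. Accuracy = (TP+TN)/N, sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), precision = TP/(TP+FP), all as
#' percentages. Ratios with a zero denominator are returned as `NA` and
#' flagged (`undefined` attribute) rather than silently zeroed.
#'
#' @param truth,pred equal-length 0/1 label vectors.
#' @return list with `confusion` (named counts TP, FN, TN, FP) and `metrics`
#'   (named percentages accuracy, sensitivity, specificity, precision).
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  if (!length(truth)) stop("cannot evaluate empty label sequences", call. = FALSE)
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  cm <- c(TP = sum(truth == 1 & pred == 1), FN = sum(truth == 1 & pred == 0),
          TN = sum(truth == 0 & pred == 0), FP = sum(truth == 0 & pred == 1))
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  met <- c(accuracy    = ratio(cm["TP"] + cm["TN"], sum(cm)),
           sensitivity = ratio(cm["TP"], cm["TP"] + cm["FN"]),
           specificity = ratio(cm["TN"], cm["TN"] + cm["FP"]),
           precision   = ratio(cm["TP"], cm["TP"] + cm["FP"]))
  names(met) <- c("accuracy", "sensitivity", "specificity", "precision")
  out <- list(confusion = cm, metrics = met)
  attr(out, "undefined") <- names(met)[is.na(met)]
  out
}

# deterministic fan-out of one master seed into the per-stage seeds
fan_out_seeds <- function(seed, n_folds, n_repeats) {
  set.seed(as.integer(seed))
  list(split = sample.int(2^31 - 1, 1),
       train = sample.int(2^31 - 1, n_folds),
       noise = matrix(sample.int(2^31 - 1, n_folds * n_repeats), n_folds))
}

#' Cross-validated evaluation of the full recognition chain
#'
#' For each of `n_folds` stratified folds: fits the data-dependent encoding
#' edges on the training split, trains the analog 23-4-2 network on the
#' training subjects, evaluates on the held-out test subjects the analog
#' network, its 10-level dequantized surrogate, and `n_repeats` independent
#' hardware deployments (fresh fault injection and current draws each
#' repeat). Hardware fold rows are the average of the repeats. Also records
#' the realized wrong-state device count and the per-sample read energy of
#' every hardware run. The master `seed` fans out deterministically to the
#' split, the per-fold training seeds and the per-repeat programming seeds,
#' so a rerun reproduces every table byte for byte.
#'
#' @param data a cohort data frame ([simulate_cohort()], [read_exasens()]).
#' @param encoding an [encoding_spec()]; unfitted permittivity edges are
#'   fitted per fold on the training split.
#' @param control a [mann_control()].
#' @param noise an [rram_config()].
#' @param iv an [iv_model()].
#' @param n_folds,n_repeats folds (default 5) and hardware repeats per fold
#'   (default 5).
#' @param precision drive-voltage precision (V) for the hardware read-out
#'   layer; `NULL` disables it.
#' @param t_pulse read pulse duration (s) for the energy accounting.
#' @param seed master seed.
#' @return an object of class `copd_experiment` containing the three metric
#'   tables (`analog`, `quantized`, `hardware`; fold rows plus averages), the
#'   per-fold records (confusion matrices, per-repeat hardware rows,
#'   wrong-state counts, energies) and the configuration.
#' @export
run_experiment <- function(data, encoding = encoding_spec(),
                           control = mann_control(), noise = rram_config(),
                           iv = iv_model(), n_folds = 5, n_repeats = 5,
                           precision = 0.01, t_pulse = 500e-6, seed = 1) {
  data <- validate_cohort(data)
  labels <- map_categoricals(data$diagnosis, data$gender, data$smoking)$label
  seeds <- fan_out_seeds(seed, n_folds, n_repeats)
  splits <- kfold_split(labels, n_folds, seeds$split)

  met_names <- c("accuracy", "sensitivity", "specificity", "precision")
  tab <- function() matrix(NA_real_, n_folds, 4,
                           dimnames = list(paste("Fold", seq_len(n_folds)), met_names))
  tabs <- list(analog = tab(), quantized = tab(), hardware = tab())
  folds <- vector("list", n_folds)

  for (k in seq_len(n_folds)) {
    sp <- splits[[k]]
    spec_k <- fit_encoding(encoding, data[sp$train, , drop = FALSE])
    bits <- encode_bits(data, spec_k)
    y <- attr(bits, "labels")
    fit <- mann(bits[sp$train, , drop = FALSE], y[sp$train],
                control = control, seed = seeds$train[k])
    x_test <- bits[sp$test, , drop = FALSE]
    y_test <- y[sp$test]

    q <- quantize(fit)
    ev_analog <- confusion_metrics(y_test, predict(fit, x_test))
    ev_quant  <- confusion_metrics(y_test, predict(dequantize(q), x_test))
    tabs$analog[k, ]    <- ev_analog$metrics
    tabs$quantized[k, ] <- ev_quant$metrics

    repeats <- lapply(seq_len(n_repeats), function(r) {
      net <- deploy(q, noise, iv, seed = seeds$noise[k, r])
      ev <- confusion_metrics(y_test, predict(net, x_test, precision = precision))
      ev$wrong_state <- wrong_state_count(net)
      ev$energy_J <- mean(sample_read_energy(net, x_test, t_pulse, precision))
      ev
    })
    hw_rows <- do.call(rbind, lapply(repeats, `[[`, "metrics"))
    tabs$hardware[k, ] <- colMeans(hw_rows)

    folds[[k]] <- list(fold = k, test = sp$test, encoding = spec_k,
                       analog = ev_analog, quantized = ev_quant,
                       hardware = repeats, step = q$step)
  }

  add_avg <- function(m) {
    if (anyNA(m))
      warning("undefined metrics (zero denominators) excluded from averages",
              call. = FALSE)
    rbind(m, Average = colMeans(m, na.rm = TRUE))
  }
  tabs <- lapply(tabs, add_avg)
  energies <- unlist(lapply(folds, function(f)
    vapply(f$hardware, `[[`, numeric(1), "energy_J")))
  wrong <- unlist(lapply(folds, function(f)
    vapply(f$hardware, `[[`, numeric(1), "wrong_state")))

  structure(list(tables = tabs, folds = folds,
                 energy_nJ = c(mean = mean(energies) * 1e9,
                               sd = stats::sd(energies) * 1e9),
                 wrong_state = c(mean = mean(wrong), sd = stats::sd(wrong)),
                 control = control, noise = noise, iv = iv,
                 n_repeats = n_repeats, t_pulse = t_pulse,
                 precision = precision, seed = seed),
            class = "copd_experiment")
}

fmt_tab <- function(m, digits = 2) {
  out <- format(round(m, digits), nsmall = digits)
  out[is.na(m)] <- "NA"
  out
}

#' @export
print.copd_experiment <- function(x, ...) {
  cat("5-fold cross-validated COPD/HC recognition\n\n")
  cat("Analog network (%):\n")
  print(fmt_tab(x$tables$analog), quote = FALSE)
  cat("\n10-level quantized network (%):\n")
  print(fmt_tab(x$tables$quantized), quote = FALSE)
  cat(sprintf("\nSimulated memristive hardware, average of %d repeats (%%):\n",
              x$n_repeats))
  print(fmt_tab(x$tables$hardware, 0), quote = FALSE)
  cat(sprintf("\nWrong-state devices per run: %.2f (+- %.2f) of %d (%.2f%%)\n",
              x$wrong_state["mean"], x$wrong_state["sd"], 1060,
              100 * x$wrong_state["mean"] / 1060))
  cat(sprintf("Read energy per sample: %.1f (+- %.1f) nJ at %g us pulses\n",
              x$energy_nJ["mean"], x$energy_nJ["sd"], x$t_pulse * 1e6))
  invisible(x)
}

#' @export
summary.copd_experiment <- function(object, ...) {
  lapply(object$tables, function(m) m["Average", ])
}
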