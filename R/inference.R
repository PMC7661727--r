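# default hidden-layer drive precision: 10 mV steps
.V_STEP <- 0.01

#' Drive voltages for a 23-bit input pattern
#'
#' Input bits with value 1 drive their synapse row at the full +-0.2 V read
#' voltage (positive polarity half at +0.2 V, negative at -0.2 V); bits with
#' value 0 apply no voltage and hence draw no current. The four hidden-layer
#' bias groups are always driven at full voltage (constant-1 input).
#'
#' @param x 0/1 vector of length 23, or an n x 23 matrix.
#' @return drive amplitudes in volts: a length-24 vector (23 inputs + bias)
#'   per pattern (matrix input gives an n x 24 matrix).
#' @export
encode_input_voltages <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 23, all(x %in% c(0, 1)))
  v <- cbind(x * .V_READ, bias = .V_READ)
  if (nrow(v) == 1L) drop(v) else v
}

# round drive amplitudes to the finite DAC precision (10 mV by default);
# precision = NULL disables rounding (ideal drive, used by the oracle tests)
apply_precision <- function(V, precision) {
  if (is.null(precision)) return(V)
  round(V / precision) * precision
}

# shared mixed-signal forward pass over an n x 23 bit matrix.
# Layer-1 drives are 0 or full voltage, so the IV non-linearity only rescales
# by (0.2/0.2)^gamma = 1 there; layer-2 drives X_i * 0.2 V are where gamma
# and the finite voltage precision bite.
hnn_forward <- function(net, X, precision = .V_STEP) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != 23)
    stop(sprintf("input has %d bits, network expects 23", ncol(X)), call. = FALSE)
  I_hidden <- sweep(X %*% net$net$W1, 2, net$net$b1, "+")      # uA
  H <- sigmoid(net$n * I_hidden)
  V2 <- apply_precision(H * .V_READ, precision)                # volts, >= 0
  F2 <- (V2 / .V_READ)^net$iv$gamma
  I_out <- sweep(F2 %*% net$net$W2, 2, net$net$b2, "+")        # uA
  O <- sigmoid(net$n * I_out)
  colnames(O) <- c("COPD", "HC")
  list(hidden = H, output = O, V2 = V2)
}

#' Mixed-signal inference on the hardware network
#'
#' Runs the deployed array forward: input bits drive the first synapse layer
#' at 0 / +-0.2 V, the summed group currents are normalized by the factor n
#' and squashed by software sigmoid neurons into hidden activations
#' X_i in [0, 1], which drive the read-out synapse layer as voltage pulses
#' of amplitude X_i * 0.2 V quantized to the drive precision (10 mV by
#' default); the normalized read-out currents through the two output neurons
#' give the COPD / HC probabilities. Repeated prediction on the same
#' programmed network is deterministic - device currents are frozen between
#' reads and only resampled by [deploy()].
#'
#' @param object an `hnn` from [deploy()].
#' @param newdata 0/1 bit matrix (23 columns) or single pattern vector.
#' @param type `"class"` (1 = COPD, ties to COPD), `"prob"` (two sigmoid
#'   outputs) or `"hidden"` (the four X_i).
#' @param precision drive-voltage precision in volts (default 0.01 = 10 mV);
#'   `NULL` disables amplitude quantization.
#' @param ... unused.
#' @return as [predict.mann()].
#' @export
predict.hnn <- function(object, newdata, type = c("class", "prob", "hidden"),
                        precision = .V_STEP, ...) {
  type <- match.arg(type)
  fwd <- hnn_forward(object, newdata, precision)
  switch(type,
         prob   = fwd$output,
         hidden = fwd$hidden,
         class  = classify_outputs(fwd$output))
}

#' Per-sample read energy of a mixed-signal inference
#'
#' Energy of serially reading every device touched by one forward pass:
#' first-layer rows driven by 1-bits plus the always-driven bias rows at
#' full voltage, then the read-out layer at the hidden-activation amplitudes
#' actually applied (including the 10 mV precision). `E = sum |I(V) * V| *
#' t_pulse` over devices.
#'
#' @param net an `hnn`.
#' @param x 0/1 bit matrix (23 columns) or single pattern.
#' @param t_pulse read pulse duration in seconds (default 500 us).
#' @param precision drive precision as in [predict.hnn()].
#' @return energy in Joules, one value per input pattern.
#' @export
sample_read_energy <- function(net, x, t_pulse = 500e-6, precision = .V_STEP) {
  stopifnot(inherits(net, "hnn"), t_pulse > 0)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  fwd <- hnn_forward(net, x, precision)
  gam <- net$iv$gamma
  # layer 1: driven rows at full voltage, factor (V/0.2)^gamma * V = 0.2
  e1 <- (x %*% rowSums(net$tot$W1) + sum(net$tot$b1)) * .V_READ
  # layer 2: amplitudes V2 per hidden unit and output-bias rows at full drive
  e2 <- ((fwd$V2 / .V_READ)^gam * fwd$V2) %*% rowSums(net$tot$W2) +
    sum(net$tot$b2) * .V_READ
  drop(e1 + e2) * t_pulse * 1e-6
}
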