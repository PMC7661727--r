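# nominal single-device read-out currents (uA) at the full read voltage (V)
.I_LRS <- 30; .I_HRS <- 5; .V_READ <- 0.2
# capacity of the 64 x 64 1T-1R array
.ARRAY_CAPACITY <- 64L * 64L

#' Device-array noise configuration
#'
#' Describes how the simulated 1T-1R RRAM array departs from ideal behaviour:
#' per-device read-current variability and switching failures.
#'
#' In `"nominal"` mode every device reads exactly 30 uA (low-resistance
#' state, LRS) or 5 uA (high-resistance state, HRS) at 0.2 V. In
#' `"measured"` mode each device's 0.2 V current is drawn once, at
#' programming time, from a truncated-positive normal with the
#' experimentally characterised moments: LRS 35.5 +- 3.7 uA, HRS 3.9 +- 1.0
#' uA. Independently, each device ends up in the wrong resistance state with
#' probability `p_fail` (symmetric LRS<->HRS flips), emulating failed
#' switching events; the characterised rate is 0.25% of devices per run.
#'
#' @param mode `"measured"` (default) or `"nominal"`.
#' @param lrs_mean,lrs_sd,hrs_mean,hrs_sd measured-mode current moments (uA).
#' @param p_fail per-device wrong-state probability in [0, 1];
#'   default 0.0025.
#' @return an object of class `rram_config`.
#' @export
rram_config <- function(mode = c("measured", "nominal"),
                        lrs_mean = 35.5, lrs_sd = 3.7,
                        hrs_mean = 3.9, hrs_sd = 1.0,
                        p_fail = 0.0025) {
  mode <- match.arg(mode)
  stopifnot(p_fail >= 0, p_fail <= 1, lrs_sd >= 0, hrs_sd >= 0,
            lrs_mean > 0, hrs_mean > 0)
  structure(list(mode = mode, lrs_mean = lrs_mean, lrs_sd = lrs_sd,
                 hrs_mean = hrs_mean, hrs_sd = hrs_sd, p_fail = p_fail),
            class = "rram_config")
}

#' @export
print.rram_config <- function(x, ...) {
  if (x$mode == "nominal")
    cat(sprintf("RRAM read-out model: nominal (%g / %g uA at %g V), p_fail = %g\n",
                .I_LRS, .I_HRS, .V_READ, x$p_fail))
  else
    cat(sprintf("RRAM read-out model: measured (LRS %g +- %g uA, HRS %g +- %g uA), p_fail = %g\n",
                x$lrs_mean, x$lrs_sd, x$hrs_mean, x$hrs_sd, x$p_fail))
  invisible(x)
}

#' Current-voltage read-out model
#'
#' Read current at voltage V relative to the stored 0.2 V current:
#' `I(V) = I(0.2) * sign(V) * (|V| / 0.2)^gamma`. `gamma = 1` is the linear
#' (ohmic) model under which the hardware path reproduces the dequantized
#' software network exactly; `gamma > 1` emulates the sub-linear conduction
#' observed on real devices, distorting parameters read at partial voltage.
#' The model is odd (I(-V) = -I(V)) and vanishes at V = 0.
#'
#' @param gamma non-linearity exponent, >= 1.
#' @return an object of class `iv_model`.
#' @export
iv_model <- function(gamma = 1) {
  stopifnot(gamma >= 1)
  structure(list(gamma = gamma), class = "iv_model")
}

# voltage scaling factor of the IV model (signed); V in volts
iv_scale <- function(iv, V) sign(V) * (abs(V) / .V_READ)^iv$gamma

# sample per-device 0.2 V read currents for a state vector (TRUE = LRS)
sample_currents <- function(state, noise) {
  n <- length(state)
  if (noise$mode == "nominal") return(ifelse(state, .I_LRS, .I_HRS))
  mu <- ifelse(state, noise$lrs_mean, noise$hrs_mean)
  sd <- ifelse(state, noise$lrs_sd, noise$hrs_sd)
  cur <- stats::rnorm(n, mu, sd)
  while (any(cur <= 0)) {                  # truncate to strictly positive
    bad <- cur <= 0
    cur[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  }
  cur
}

#' Deploy a quantized network onto a simulated RRAM synapse array
#'
#' Each of the 106 quantized parameters becomes a synapse group of
#' `n_levels` binary memristive devices, half read at positive and half at
#' negative polarity. A level k > 0 switches k devices of the positive half
#' to LRS (k < 0 mirrored on the negative half; level 0 leaves all devices
#' in HRS), so the group's net nominal current at full read voltage is
#' 25 k uA. Programming then injects faults: every device independently
#' flips to the wrong state with probability `noise$p_fail`, and each
#' device's read current is drawn once from the configured distribution and
#' frozen until the network is re-programmed.
#'
#' Deployments needing more devices than the 64 x 64 (4-kbit) array holds
#' are rejected.
#'
#' @param q a quantized network ([quantize()]).
#' @param noise an [rram_config()].
#' @param iv an [iv_model()].
#' @param seed integer seed for fault injection and current sampling.
#' @return an object of class `hnn` (hardware neural network): per-group
#'   device states and currents, summed polarity currents in the network
#'   layout, the normalization factor `n` mapping the 125 uA full-scale
#'   current to the maximum analog parameter, and the realized wrong-state
#'   device count. Methods: [predict.hnn()], [print.hnn()].
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_copd = 10, n_hc = 10), seed = 3)
#' bits <- encode_bits(cohort, fit_encoding(encoding_spec(), cohort))
#' fit <- mann(bits, control = mann_control(epochs = 30), seed = 1)
#' net <- deploy(quantize(fit), rram_config(), iv_model(), seed = 7)
#' net$n_devices
#' @export
deploy <- function(q, noise = rram_config(), iv = iv_model(), seed = 1) {
  stopifnot(inherits(q, "mann_q"), inherits(noise, "rram_config"),
            inherits(iv, "iv_model"))
  half <- q$n_levels / 2
  levels <- unlist(q[c("W1", "b1", "W2", "b2")])   # 106 levels, W1 column-major
  n_groups <- length(levels)
  n_devices <- n_groups * q$n_levels
  if (n_devices > .ARRAY_CAPACITY)
    stop(sprintf("deployment needs %d devices but the 64x64 array holds %d",
                 n_devices, .ARRAY_CAPACITY), call. = FALSE)

  # intended states: columns 1..half positive polarity, half+1..2*half negative
  intended <- matrix(FALSE, n_groups, q$n_levels)
  for (g in seq_len(n_groups)) {
    k <- levels[g]
    if (k > 0) intended[g, seq_len(k)] <- TRUE
    if (k < 0) intended[g, half + seq_len(-k)] <- TRUE
  }

  set.seed(as.integer(seed))
  flips <- matrix(stats::runif(n_devices) < noise$p_fail, n_groups)
  state <- xor(intended, flips)
  cur <- matrix(sample_currents(as.vector(state), noise), n_groups)

  pos <- seq_len(half); neg <- half + seq_len(half)
  g_pos <- rowSums(cur[, pos, drop = FALSE])
  g_neg <- rowSums(cur[, neg, drop = FALSE])

  # reshape the per-group summed currents back into the network layout
  shape <- function(v) {
    list(W1 = matrix(v[1:92], 23, 4), b1 = v[93:96],
         W2 = matrix(v[97:104], 4, 2), b2 = v[105:106])
  }
  structure(list(levels = q, states = state, intended = intended,
                 currents = cur,
                 net = shape(g_pos - g_neg), tot = shape(g_pos + g_neg),
                 n = 5 * q$step / 125,     # uA^-1; 125 uA -> max |theta|
                 noise = noise, iv = iv, seed = as.integer(seed),
                 n_groups = n_groups, n_devices = n_devices,
                 wrong_state = sum(flips)),
            class = "hnn")
}

#' @export
print.hnn <- function(x, ...) {
  cat(sprintf("Hardware network: %d synapse groups, %d memristive devices\n",
              x$n_groups, x$n_devices))
  print(x$noise)
  cat(sprintf("  IV exponent gamma = %g; normalization n = %.5g per uA\n",
              x$iv$gamma, x$n))
  cat(sprintf("  devices in wrong state after programming: %d (%.2f%%)\n",
              x$wrong_state, 100 * x$wrong_state / x$n_devices))
  invisible(x)
}

#' Net read-out current of one synapse group
#'
#' Sums the sampled device currents of a group with its positive-polarity
#' half driven at `V_pos` and its negative half at `V_neg` (default the
#' mirrored voltage), each scaled through the I-V model. Read voltages above
#' the 0.2 V read-disturb limit are rejected.
#'
#' @param net an `hnn` from [deploy()].
#' @param group group index in 1..106 (order: W1 column-major, b1, W2, b2).
#' @param V_pos,V_neg signed drive voltages (V), magnitude <= 0.2.
#' @return signed net current in uA.
#' @export
read_group_current <- function(net, group, V_pos = .V_READ, V_neg = -V_pos) {
  stopifnot(inherits(net, "hnn"), group >= 1, group <= net$n_groups)
  if (abs(V_pos) > .V_READ + 1e-12 || abs(V_neg) > .V_READ + 1e-12)
    stop("read voltage magnitude exceeds the 0.2 V read-disturb limit",
         call. = FALSE)
  half <- ncol(net$states) / 2
  cur <- net$currents[group, ]
  sum(cur[seq_len(half)]) * iv_scale(net$iv, V_pos) +
    sum(cur[half + seq_len(half)]) * iv_scale(net$iv, V_neg)
}

#' Wrong-state device count of a programmed network
#'
#' @param net an `hnn`.
#' @return number of devices whose realized state differs from the
#'   programmed intention.
#' @export
wrong_state_count <- function(net) {
  stopifnot(inherits(net, "hnn"))
  sum(xor(net$states, net$intended))
}

#' Read-out energy of a set of device reads
#'
#' Serial read-out is assumed, so device energies add:
#' `E = sum |I(V) * V| * t_pulse`, with `I(V)` the I-V-scaled device current.
#' One LRS device (30 uA at 0.2 V) read for 500 us costs 3 nJ; energy is
#' exactly linear in the pulse duration.
#'
#' @param net an `hnn`.
#' @param v_groups numeric vector (recycled over the 106 groups) of drive
#'   amplitudes (V) applied to each group (+v on the positive half, -v on
#'   the negative half), magnitudes <= 0.2.
#' @param t_pulse read pulse duration in seconds (default 500 us).
#' @return total energy in Joules.
#' @export
estimate_read_energy <- function(net, v_groups = .V_READ, t_pulse = 500e-6) {
  stopifnot(inherits(net, "hnn"), t_pulse > 0)
  v <- abs(rep_len(v_groups, net$n_groups))
  if (any(v > .V_READ + 1e-12))
    stop("read voltage magnitude exceeds the 0.2 V read-disturb limit",
         call. = FALSE)
  g_tot <- rowSums(net$currents)           # uA at 0.2 V, all 10 devices
  sum(g_tot * (v / .V_READ)^net$iv$gamma * v) * t_pulse * 1e-6
}
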