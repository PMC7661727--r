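#' Write network parameters to a JSON file
#'
#' Serializes either the analog parameters of a fitted [mann()] (keys `W1`,
#' `b1`, `W2`, `b2` with explicit shapes) or a quantized network's integer
#' levels together with the threshold step, so the quantization and hardware
#' stages can run decoupled from training. Integer levels are stored as
#' integers to keep deployment bit-exact. An [encoding_spec()] can travel in
#' the same file so downstream stages can encode raw subjects consistently.
#'
#' @param object a `mann` or `mann_q`.
#' @param path output path.
#' @param encoding optional fitted [encoding_spec()] to embed.
#' @return `path`, invisibly.
#' @export
write_params <- function(object, path, encoding = NULL) {
  par <- object[c("W1", "b1", "W2", "b2")]
  rec <- if (inherits(object, "mann_q"))
    list(type = "quantized", levels = par, step = object$step,
         n_levels = object$n_levels)
  else {
    check_params(par)
    list(type = "analog", params = par)
  }
  if (!is.null(encoding))
    rec$encoding <- list(age_edges = encoding$age_edges,
                         perm_edges = encoding$perm_edges)
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network parameter file
#'
#' @param path a file written by [write_params()].
#' @return a `mann`-compatible analog network or a `mann_q`, with any
#'   embedded encoding attached as attribute `encoding`.
#' @export
read_params <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  reshape <- function(p, mode) {
    out <- list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2)
    stopifnot(all(dim(out$W1) == c(23, 4)), length(out$b1) == 4,
              all(dim(out$W2) == c(4, 2)), length(out$b2) == 2)
    lapply(out, function(m) { storage.mode(m) <- mode; m })
  }
  out <- if (identical(rec$type, "quantized")) {
    structure(c(reshape(rec$levels, "integer"),
                list(step = rec$step, n_levels = as.integer(rec$n_levels))),
              class = "mann_q")
  } else {
    structure(reshape(rec$params, "double"), class = c("mann_params", "mann"))
  }
  if (!is.null(rec$encoding))
    attr(out, "encoding") <- encoding_spec(rec$encoding$age_edges,
                                           rec$encoding$perm_edges)
  out
}

#' @export
print.mann_params <- function(x, ...) {
  cat("23-4-2 analog network parameters (restored from file)\n")
  invisible(x)
}

#' Dump a programmed hardware network for audit and exact replay
#'
#' Writes every device's realized state and sampled 0.2 V read current, the
#' programmed levels, and the noise / I-V configuration to JSON.
#' [read_hnn()] restores an `hnn` whose predictions are bit-identical to the
#' original.
#'
#' @param net an `hnn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hnn <- function(net, path) {
  stopifnot(inherits(net, "hnn"))
  rec <- list(levels = net$levels[c("W1", "b1", "W2", "b2")],
              step = net$levels$step, n_levels = net$levels$n_levels,
              states = net$states * 1L, intended = net$intended * 1L,
              currents = net$currents,
              noise = unclass(net$noise), gamma = net$iv$gamma,
              seed = net$seed)
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a hardware network dump
#'
#' @param path a file written by [write_hnn()].
#' @return the restored `hnn`.
#' @export
read_hnn <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv <- lapply(rec$levels[c("W1", "b1", "W2", "b2")],
               function(m) { storage.mode(m) <- "integer"; m })
  q <- structure(c(lv, list(step = rec$step, n_levels = as.integer(rec$n_levels))),
                 class = "mann_q")
  noise <- do.call(rram_config, rec$noise[c("mode", "lrs_mean", "lrs_sd",
                                            "hrs_mean", "hrs_sd", "p_fail")])
  net <- deploy(q, noise, iv_model(rec$gamma), seed = rec$seed)
  # overwrite the redeployed randomness with the dumped realization
  as_mat <- function(m, mode) {
    m <- if (is.matrix(m)) m else matrix(unlist(m), length(m), byrow = TRUE)
    storage.mode(m) <- mode
    m
  }
  net$states <- as_mat(rec$states, "logical")
  net$intended <- as_mat(rec$intended, "logical")
  net$currents <- as_mat(rec$currents, "double")
  half <- ncol(net$currents) / 2
  g_pos <- rowSums(net$currents[, seq_len(half), drop = FALSE])
  g_neg <- rowSums(net$currents[, half + seq_len(half), drop = FALSE])
  shape <- function(v) list(W1 = matrix(v[1:92], 23, 4), b1 = v[93:96],
                            W2 = matrix(v[97:104], 4, 2), b2 = v[105:106])
  net$net <- shape(g_pos - g_neg)
  net$tot <- shape(g_pos + g_neg)
  net$wrong_state <- sum(xor(net$states, net$intended))
  net
}
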