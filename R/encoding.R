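#' Map categorical attributes to their numeric codes
#'
#' Applies the study's fixed numeric coding: diagnosis COPD = 1 / HC = 0,
#' gender male = 1 / female = 0, smoking smoker = 3 / ex-smoker = 2 /
#' non-smoker = 1.
#'
#' @param diagnosis,gender,smoking character or factor vectors (recycled to a
#'   common length) with values from the enumerated category sets.
#' @return a data frame with integer columns `label`, `gender_code`,
#'   `smoking_code`.
#' @examples
#' map_categoricals("COPD", "male", "smoker")    # 1, 1, 3
#' map_categoricals("HC", "female", "non-smoker") # 0, 0, 1
#' @export
map_categoricals <- function(diagnosis, gender, smoking) {
  code <- function(x, field, codes) {
    x <- as.character(x)
    out <- codes[x]
    if (anyNA(out))
      stop(sprintf("invalid category value for %s: %s", field,
                   paste(unique(x[is.na(out)]), collapse = ", ")),
           call. = FALSE)
    unname(out)
  }
  data.frame(
    label        = code(diagnosis, "diagnosis", c(COPD = 1L, HC = 0L)),
    gender_code  = code(gender, "gender", c(male = 1L, female = 0L)),
    smoking_code = code(smoking, "smoking",
                        c(smoker = 3L, "ex-smoker" = 2L, "non-smoker" = 1L))
  )
}

#' Thermometer (cumulative) binarization of an analog value
#'
#' Bit i is 1 iff `value >= edges[i]` (closed lower edge). Because the edges
#' are increasing, the output always reads as a run of ones followed by a run
#' of zeros, and raising the value can only turn zeros into ones.
#'
#' @param value numeric scalar or vector.
#' @param edges strictly increasing numeric thresholds.
#' @return for scalar `value` an integer 0/1 vector of `length(edges)`;
#'   for vector input a matrix with one row per value.
#' @examples
#' thermometer(50, seq(35, 75, by = 5))  # 1 1 1 1 0 0 0 0 0
#' @export
thermometer <- function(value, edges) {
  if (length(edges) < 1 || any(diff(edges) <= 0))
    stop("thermometer edges must be strictly increasing", call. = FALSE)
  m <- matrix(as.integer(outer(value, edges, ">=")), nrow = length(value))
  if (length(value) == 1L) drop(m) else m
}

#' Binarization scheme for the 23-bit input pattern
#'
#' Fixes how the four attributes become the 23 input bits, in order: gender
#' (1 bit), smoking status (3 thermometer bits over the ordinal 1/2/3 codes),
#' age (9 thermometer bits), permittivity minimum (10 thermometer bits).
#'
#' The literal bin edges are configurable. Age defaults to 9 uniform edges
#' spanning 35-75 years. Permittivity edges default to `NULL`, meaning they
#' are fitted to a training split by [fit_encoding()] (10 uniform edges over
#' the observed min-max); this keeps the test split encoded on scales learned
#' from training data only.
#'
#' @param age_edges strictly increasing numeric vector of length 9 (years).
#' @param perm_edges strictly increasing numeric vector of length 10, or
#'   `NULL` to fit from data.
#' @return an object of class `encoding_spec`.
#' @export
encoding_spec <- function(age_edges = seq(35, 75, length.out = 9),
                          perm_edges = NULL) {
  if (length(age_edges) != 9 || any(diff(age_edges) <= 0))
    stop("age_edges must be 9 strictly increasing thresholds", call. = FALSE)
  if (!is.null(perm_edges) &&
      (length(perm_edges) != 10 || any(diff(perm_edges) <= 0)))
    stop("perm_edges must be 10 strictly increasing thresholds", call. = FALSE)
  structure(list(age_edges = as.numeric(age_edges),
                 perm_edges = if (is.null(perm_edges)) NULL else as.numeric(perm_edges)),
            class = "encoding_spec")
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat("23-bit input encoding: gender(1) | smoking therm.(3) | age therm.(9) | permittivity therm.(10)\n")
  cat("  age edges: ", paste(signif(x$age_edges, 4), collapse = ", "), "\n")
  if (is.null(x$perm_edges)) cat("  permittivity edges: unfitted (call fit_encoding())\n")
  else cat("  permittivity edges: ", paste(signif(x$perm_edges, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Fit data-dependent encoding edges on a training split
#'
#' Fills unset permittivity edges with 10 uniform thresholds spanning the
#' observed `perm_min` range of `data`. Already-set edges are kept.
#'
#' @param spec an [encoding_spec()].
#' @param data the training-split cohort data frame.
#' @return the completed `encoding_spec`.
#' @export
fit_encoding <- function(spec, data) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (is.null(spec$perm_edges)) {
    data <- validate_cohort(data)
    r <- range(data$perm_min)
    if (diff(r) <= 0)
      stop("cannot fit permittivity edges: training split has no spread", call. = FALSE)
    spec$perm_edges <- seq(r[1], r[2], length.out = 10)
  }
  spec
}

#' Encode subjects as 23-bit input patterns
#'
#' Concatenates, per subject: the gender bit, the smoking thermometer triplet
#' (non-smoker 100, ex-smoker 110, smoker 111), 9 age thermometer bits and 10
#' permittivity thermometer bits - 23 bits total, matching the input layer of
#' the classifier.
#'
#' @param data a cohort data frame ([simulate_cohort()], [read_exasens()]).
#' @param spec a fitted [encoding_spec()].
#' @return an integer 0/1 matrix with `nrow(data)` rows and 23 columns, with
#'   the numeric class labels (COPD = 1, HC = 0) attached as attribute
#'   `labels`.
#' @export
encode_bits <- function(data, spec = encoding_spec()) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (is.null(spec$perm_edges))
    stop("encoding_spec has unfitted permittivity edges; call fit_encoding() first",
         call. = FALSE)
  data <- validate_cohort(data)
  codes <- map_categoricals(data$diagnosis, data$gender, data$smoking)
  n <- nrow(data)
  # smoking is thresholded like the other analog attributes: thermometer over
  # the ordinal codes (non-smoker 100, ex-smoker 110, smoker 111)
  smoke <- matrix(as.integer(outer(codes$smoking_code, 1:3, ">=")), n)
  bits <- cbind(gender = codes$gender_code,
                smoke,
                matrix(as.integer(outer(data$age, spec$age_edges, ">=")), n),
                matrix(as.integer(outer(data$perm_min, spec$perm_edges, ">=")), n))
  colnames(bits) <- c("gender", paste0("smoke_ge", 1:3),
                      paste0("age_", seq_len(9)), paste0("perm_", seq_len(10)))
  stopifnot(ncol(bits) == 23)
  attr(bits, "labels") <- codes$label
  bits
}
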