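#' Specification of a synthetic saliva-screening cohort
#'
#' Describes the joint distribution of the four clinical attributes (age,
#' gender, smoking status, minimum real-part dielectric permittivity of a
#' saliva sample) for the two diagnostic classes, COPD patients and healthy
#' controls (HC). [simulate_cohort()] draws from this specification.
#'
#' The defaults emulate a cohort in which COPD subjects are older, enriched
#' for smokers, and have a lowered saliva permittivity minimum relative to
#' controls; with `d = 1` the class means of `perm_min` are two pooled
#' standard deviations apart, i.e. a well-separated cohort.
#'
#' @param n_copd,n_hc number of COPD and healthy-control subjects.
#' @param age_mean,age_sd,age_bounds length-2 vectors (COPD, HC): mean, sd and
#'   truncation bounds (a 2x2 matrix or list of length-2 vectors) of the
#'   truncated-normal age distributions, in years.
#' @param perm_mean,perm_sd length-2 vectors (COPD, HC): normal mean and sd of
#'   the minimum real-part permittivity (dimensionless).
#' @param smoking_prob 2x3 matrix of class-conditional probabilities over
#'   (smoker, ex-smoker, non-smoker); rows COPD, HC, each summing to 1.
#' @param male_prob length-2 vector: probability of male gender per class.
#' @param d separation scale multiplying the class mean difference of
#'   `perm_min` about the pooled mean: `d = 1` keeps the specified gap,
#'   `d = 0` collapses the classes onto identical permittivity distributions.
#' @return an object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [read_exasens()]
#' @export
cohort_spec <- function(n_copd = 40, n_hc = 40,
                        age_mean = c(65, 50), age_sd = c(8, 10),
                        age_bounds = list(c(40, 85), c(25, 80)),
                        perm_mean = c(14, 18), perm_sd = c(2, 2),
                        smoking_prob = rbind(COPD = c(0.5, 0.4, 0.1),
                                             HC   = c(0.2, 0.3, 0.5)),
                        male_prob = c(0.6, 0.5),
                        d = 1) {
  smoking_prob <- as.matrix(smoking_prob)
  stopifnot(n_copd >= 0, n_hc >= 0, all(age_sd >= 0), all(perm_sd >= 0),
            length(age_mean) == 2, length(perm_mean) == 2,
            nrow(smoking_prob) == 2, ncol(smoking_prob) == 3,
            all(smoking_prob >= 0), length(male_prob) == 2,
            all(male_prob >= 0 & male_prob <= 1), d >= 0)
  if (any(abs(rowSums(smoking_prob) - 1) > 1e-8))
    stop("smoking_prob rows must each sum to 1", call. = FALSE)
  structure(list(n_copd = n_copd, n_hc = n_hc,
                 age_mean = age_mean, age_sd = age_sd,
                 age_bounds = age_bounds,
                 perm_mean = perm_mean, perm_sd = perm_sd,
                 smoking_prob = smoking_prob, male_prob = male_prob, d = d),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic saliva cohort specification\n")
  cat(sprintf("  %d COPD + %d HC subjects\n", x$n_copd, x$n_hc))
  cat(sprintf("  perm_min means (COPD, HC): %.2f, %.2f (sd %.2f, %.2f), separation scale d = %g\n",
              x$perm_mean[1], x$perm_mean[2], x$perm_sd[1], x$perm_sd[2], x$d))
  cat(sprintf("  age means (COPD, HC): %.0f, %.0f years\n", x$age_mean[1], x$age_mean[2]))
  invisible(x)
}

# truncated-normal draws by rejection; bounds are wide enough that this is cheap
rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

.diag_levels    <- c("HC", "COPD")            # numeric codes 0, 1
.gender_levels  <- c("female", "male")        # numeric codes 0, 1
.smoking_levels <- c("non-smoker", "ex-smoker", "smoker")  # numeric codes 1, 2, 3

#' Draw a synthetic cohort
#'
#' Generates `n_copd + n_hc` subject records from a [cohort_spec()]: ages are
#' truncated-normal per class, permittivity minima normal per class with the
#' mean gap scaled by `spec$d`, smoking and gender categorical per class.
#' Fully reproducible from `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return a data frame with columns `diagnosis` (factor COPD/HC), `gender`
#'   (factor male/female), `age` (integer years), `smoking` (factor
#'   smoker/ex-smoker/non-smoker) and `perm_min` (numeric), one row per
#'   subject; COPD rows first.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(), seed = 1)
#' table(cohort$diagnosis)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- c(spec$n_copd, spec$n_hc)
  # class permittivity means pulled toward the pooled mean by d
  mid <- mean(spec$perm_mean)
  pm  <- mid + spec$d * (spec$perm_mean - mid)
  rows <- lapply(1:2, function(k) {
    if (n[k] == 0) return(NULL)
    b <- spec$age_bounds[[k]]
    data.frame(
      diagnosis = factor(if (k == 1) "COPD" else "HC", levels = .diag_levels),
      gender    = factor(ifelse(stats::runif(n[k]) < spec$male_prob[k],
                                "male", "female"), levels = .gender_levels),
      age       = as.integer(round(rtnorm(n[k], spec$age_mean[k], spec$age_sd[k],
                                          b[1], b[2]))),
      smoking   = factor(sample(c("smoker", "ex-smoker", "non-smoker"), n[k],
                                replace = TRUE, prob = spec$smoking_prob[k, ]),
                         levels = .smoking_levels),
      perm_min  = stats::rnorm(n[k], pm[k], spec$perm_sd[k]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_cohort(out)
}

#' Validate a cohort data frame
#'
#' Checks the invariants every downstream stage relies on: required columns,
#' positive ages, finite permittivity, and category levels restricted to the
#' enumerated sets.
#'
#' @param data a data frame of subject records.
#' @return `data`, with the categorical columns coerced to factors with the
#'   canonical level sets.
#' @export
validate_cohort <- function(data) {
  req <- c("diagnosis", "gender", "age", "smoking", "perm_min")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("cohort is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("diagnosis", "gender", "smoking")) {
    lev <- switch(col, diagnosis = .diag_levels, gender = .gender_levels,
                  smoking = .smoking_levels)
    vals <- as.character(data[[col]])
    bad <- setdiff(unique(vals), lev)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
    data[[col]] <- factor(vals, levels = lev)
  }
  if (any(!is.finite(data$age)) || any(data$age <= 0))
    stop("age must be a positive number for every subject", call. = FALSE)
  if (any(!is.finite(data$perm_min)))
    stop("perm_min must be finite for every subject", call. = FALSE)
  data
}

#' Read a cohort from an Exasens-dialect CSV
#'
#' Parses the public Exasens saliva-screening CSV (or a file written by
#' [write_cohort_csv()]): tolerant of the deposited file's multi-line header
#' and repeated permittivity sub-columns, keyed on column names. Keeps only
#' COPD and HC rows, drops rows with a missing permittivity minimum, and
#' reports the counts kept and dropped.
#'
#' The deposited file codes categories numerically (diagnosis COPD=1/HC=0 as
#' text labels, gender male=1/female=0, smoking smoker=3/ex-smoker=2/
#' non-smoker=1); both the numeric codes and the text labels are accepted.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping the internal
#'   attribute names `diagnosis`, `gender`, `age`, `smoking`, `perm_min` to
#'   the file's column names, for deposits whose headers differ.
#' @param quiet suppress the kept/dropped message.
#' @return a validated cohort data frame (see [simulate_cohort()]) with
#'   attributes `n_kept` and `n_dropped`.
#' @export
read_exasens <- function(path, column_map = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # the deposited file carries extra header lines before the per-subject rows;
  # locate the header row as the first line naming the Diagnosis column
  hdr <- grep("(?i)diagnosis", lines, perl = TRUE)[1]
  if (is.na(hdr)) stop("no 'Diagnosis' column found: not an Exasens-dialect CSV",
                       call. = FALSE)
  raw <- utils::read.csv(text = paste(lines[hdr:length(lines)], collapse = "\n"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(raw) <- trimws(names(raw))

  pick <- function(key, patterns) {
    if (!is.null(column_map) && key %in% names(column_map)) {
      nm <- column_map[[key]]
      if (!nm %in% names(raw))
        stop("mapped column not present in file: ", nm, call. = FALSE)
      return(nm)
    }
    hit <- unlist(lapply(patterns, function(p) grep(p, names(raw),
                                                    ignore.case = TRUE, value = TRUE)))
    if (!length(hit))
      stop("required column not found for attribute '", key, "'", call. = FALSE)
    hit[1]
  }
  # "Imaginary" columns exist in the deposit; require Real & Min for perm_min
  cols <- c(diagnosis = pick("diagnosis", "^diagnosis"),
            gender    = pick("gender", "^gender"),
            age       = pick("age", "^age"),
            smoking   = pick("smoking", "^smoking"),
            perm_min  = pick("perm_min", c("min.*real", "real.*min", "^min$")))
  df <- raw[, cols]
  names(df) <- names(cols)

  n0 <- nrow(df)
  df$diagnosis <- toupper(trimws(as.character(df$diagnosis)))
  df <- df[df$diagnosis %in% c("COPD", "HC"), , drop = FALSE]
  n_class <- nrow(df)

  num <- function(x) suppressWarnings(as.numeric(as.character(x)))
  df$perm_min <- num(df$perm_min)
  keep <- is.finite(df$perm_min)
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  decode <- function(x, codes, labels) {
    x <- trimws(as.character(x))
    out <- labels[match(x, codes)]
    out[is.na(out)] <- labels[match(x[is.na(out)], labels)]  # already labelled
    if (anyNA(out))
      stop("invalid category value(s): ", paste(unique(x[is.na(out)]), collapse = ", "),
           call. = FALSE)
    out
  }
  out <- data.frame(
    diagnosis = df$diagnosis,
    gender    = decode(df$gender, c("1", "0"), c("male", "female")),
    age       = as.integer(round(num(df$age))),
    smoking   = decode(df$smoking, c("3", "2", "1"),
                       c("smoker", "ex-smoker", "non-smoker")),
    perm_min  = df$perm_min,
    stringsAsFactors = FALSE
  )
  out <- validate_cohort(out)
  if (!quiet)
    message(sprintf("read_exasens: kept %d COPD/HC rows (%d non-COPD/HC removed, %d dropped for missing permittivity)",
                    nrow(out), n0 - n_class, n_dropped))
  attr(out, "n_kept") <- nrow(out)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cohort in the Exasens CSV dialect
#'
#' Writes the categorical attributes with the deposit's numeric codes
#' (gender male=1/female=0, smoking 3/2/1) so the file round-trips through
#' [read_exasens()].
#'
#' @param data a cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  data <- validate_cohort(data)
  out <- data.frame(
    Diagnosis = as.character(data$diagnosis),
    Gender    = ifelse(data$gender == "male", 1L, 0L),
    Age       = data$age,
    Smoking   = c("non-smoker" = 1L, "ex-smoker" = 2L, "smoker" = 3L)[
      as.character(data$smoking)],
    `Min real permittivity` = data$perm_min,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
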