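test_that("default synthetic cohort has 40 COPD + 40 HC valid records", {
  cohort <- simulate_cohort(cohort_spec(), seed = 1)
  expect_equal(nrow(cohort), 80)
  expect_equal(as.vector(table(cohort$diagnosis)[c("COPD", "HC")]), c(40, 40))
  expect_true(all(cohort$age > 0))
  expect_true(all(is.finite(cohort$perm_min)))
  expect_true(all(cohort$smoking %in% c("smoker", "ex-smoker", "non-smoker")))
  expect_true(all(cohort$gender %in% c("male", "female")))
})

test_that("cohort generation is deterministic in the seed and honours the spec", {
  a <- simulate_cohort(cohort_spec(), seed = 42)
  b <- simulate_cohort(cohort_spec(), seed = 42)
  expect_identical(a, b)
  c <- simulate_cohort(cohort_spec(n_copd = 7, n_hc = 13), seed = 1)
  expect_equal(as.vector(table(c$diagnosis)[c("COPD", "HC")]), c(7, 13))
  # generator output satisfies the record invariants for varied specs
  for (s in 1:5) {
    sp <- cohort_spec(n_copd = 10 + s, n_hc = 10, d = s / 5)
    expect_silent(validate_cohort(simulate_cohort(sp, seed = s)))
  }
  expect_error(cohort_spec(smoking_prob = rbind(c(0.5, 0.5, 0.5), c(0.2, 0.3, 0.5))),
               "sum to 1")
})

test_that("d = 0 collapses the permittivity class gap", {
  sp0 <- cohort_spec(d = 0)
  cohort <- simulate_cohort(sp0, seed = 3)
  gap <- abs(mean(cohort$perm_min[cohort$diagnosis == "COPD"]) -
               mean(cohort$perm_min[cohort$diagnosis == "HC"]))
  expect_lt(gap, 1.5)  # within sampling noise of zero at n = 40/40
})

test_that("Exasens-dialect CSV round-trips through writer and reader", {
  cohort <- simulate_cohort(cohort_spec(n_copd = 15, n_hc = 15), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_exasens(path, quiet = TRUE)
  expect_equal(as.character(back$diagnosis), as.character(cohort$diagnosis))
  expect_equal(as.character(back$gender), as.character(cohort$gender))
  expect_equal(as.character(back$smoking), as.character(cohort$smoking))
  expect_equal(back$age, cohort$age)
  expect_equal(back$perm_min, cohort$perm_min)
})

test_that("reader keeps only complete COPD/HC rows from the deposited dialect", {
  # emulate the public file: leading header junk, extra classes, numeric
  # category codes, a missing permittivity cell, extra permittivity columns
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    ",Saliva attributes,,,,",
    "Diagnosis,ID,Imaginary part Min,Min Real Part,Gender,Age,Smoking",
    "COPD,p1,-300,12.5,1,66,3",
    "COPD,p2,-310,,1,70,2",
    "HC,p3,-250,17.9,0,45,1",
    "Asthma,p4,-280,16.0,0,30,1",
    "Infected,p5,-270,15.0,1,50,2",
    "HC,p6,-255,18.4,1,52,2"
  ), path)
  expect_message(out <- read_exasens(path), "kept 3 .*2 non-COPD/HC.*1 dropped")
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_equal(as.character(out$diagnosis), c("COPD", "HC", "HC"))
  expect_equal(out$perm_min, c(12.5, 17.9, 18.4))
  expect_equal(as.character(out$smoking), c("smoker", "non-smoker", "ex-smoker"))
  # column map override picks a differently named permittivity column
  out2 <- read_exasens(path, column_map = c(perm_min = "Imaginary part Min"),
                       quiet = TRUE)
  expect_equal(out2$perm_min[1], -300)
})

test_that("reader rejects files without the required columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_exasens(path, quiet = TRUE), "Diagnosis")
  writeLines(c("Diagnosis,Gender,Age,Smoking", "COPD,1,60,3"), path)
  expect_error(read_exasens(path, quiet = TRUE), "perm_min")
})

test_that("uninformative permittivity with shuffled covariates yields chance-level accuracy", {
  # d = 0 and class-independent demographics: nothing to learn
  sp <- cohort_spec(d = 0, age_mean = c(55, 55), age_sd = c(10, 10),
                    age_bounds = list(c(25, 85), c(25, 85)),
                    smoking_prob = rbind(c(1, 1, 1) / 3, c(1, 1, 1) / 3),
                    male_prob = c(0.5, 0.5))
  accs <- vapply(1:20, function(s) {
    cohort <- simulate_cohort(sp, seed = s)
    spec <- fit_encoding(encoding_spec(), cohort)
    bits <- encode_bits(cohort, spec)
    y <- attr(bits, "labels")
    fold <- kfold_split(y, 5, seed = s)[[1]]
    fit <- mann(bits[fold$train, ], y[fold$train],
                control = mann_control(epochs = 200), seed = s)
    mean(predict(fit, bits[fold$test, ]) == y[fold$test])
  }, numeric(1))
  expect_gt(mean(accs), 0.40)
  expect_lt(mean(accs), 0.60)
})

test_that("test accuracy increases with the class separation scale d", {
  acc_at_d <- function(d) {
    mean(vapply(1:20, function(s) {
      cohort <- simulate_cohort(cohort_spec(d = d), seed = 300 + s)
      spec <- fit_encoding(encoding_spec(), cohort)
      bits <- encode_bits(cohort, spec)
      y <- attr(bits, "labels")
      fold <- kfold_split(y, 5, seed = s)[[1]]
      fit <- mann(bits[fold$train, ], y[fold$train],
                  control = mann_control(epochs = 200), seed = s)
      mean(predict(fit, bits[fold$test, ]) == y[fold$test])
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.5, 1), acc_at_d, numeric(1))
  expect_true(all(diff(accs) > 0))
})
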