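test_that("input bits translate to full-swing drive voltages plus bias", {
  x <- c(1L, rep(0L, 21), 1L)
  v <- encode_input_voltages(x)
  expect_length(v, 24)
  expect_equal(unname(v[c(1, 23)]), c(0.2, 0.2))
  expect_equal(unname(v["bias"]), 0.2)                # bias always driven
  expect_equal(sum(v > 0), 3)                         # 2 one-bits + bias
  expect_equal(sum(encode_input_voltages(rep(0L, 23)) > 0), 1)
  expect_equal(sum(encode_input_voltages(rep(1L, 23)) > 0), 24)
})

test_that("drive amplitudes are quantized to the 10 mV precision", {
  expect_equal(memsaliva:::apply_precision(0.513 * 0.2, 0.01), 0.10)
  expect_equal(memsaliva:::apply_precision(0.1026, 0.01), 0.10)
  expect_identical(memsaliva:::apply_precision(0.1026, NULL), 0.1026)
  # rounding moves any amplitude by at most half a step (5 mV), hence any
  # nominal group current by at most (5/200) * 125 uA
  set.seed(9)
  X <- runif(200)
  dv <- abs(memsaliva:::apply_precision(X * 0.2, 0.01) - X * 0.2)
  expect_true(all(dv <= 0.005 + 1e-12))
  expect_true(all(dv / 0.2 * 125 <= (5 / 200) * 125 + 1e-9))
})

test_that("ideal hardware reproduces the dequantized software network", {
  q <- quantize(small_fit())
  net <- deploy(q, ideal_noise(), iv_model(1), seed = 1)
  deq <- dequantize(q)
  X <- random_bits(200, 31)
  expect_equal(predict(net, X, type = "hidden", precision = NULL),
               predict(deq, X, type = "hidden"), tolerance = 1e-9)
  expect_equal(predict(net, X, type = "prob", precision = NULL),
               predict(deq, X, type = "prob"), tolerance = 1e-9)
  expect_identical(predict(net, X, precision = NULL), predict(deq, X))
  # the pre-activation of a level-5 group driven alone is 5 * step (plus bias)
  q1 <- q
  q1$W1[] <- 0L; q1$b1[] <- 0L
  q1$W1[1, 1] <- 5L
  net1 <- deploy(q1, ideal_noise(), iv_model(1), seed = 1)
  x <- c(1L, rep(0L, 22))
  h <- predict(net1, x, type = "hidden", precision = NULL)[1, 1]
  expect_equal(h, memsaliva:::sigmoid(net1$n * 125), tolerance = 1e-12)
  expect_equal(net1$n * 125, 5 * q$step, tolerance = 1e-12)
})

test_that("all-zero levels give centred activations", {
  q <- quantize(random_params(6))
  q$W1[] <- 0L; q$b1[] <- 0L; q$W2[] <- 0L; q$b2[] <- 0L
  net <- deploy(q, ideal_noise(), iv_model(), seed = 1)
  fwd <- predict(net, random_bits(4, 1), type = "hidden")
  expect_true(all(fwd == 0.5))
  prob <- predict(net, random_bits(4, 1), type = "prob")
  expect_true(all(prob == 0.5))
  # identical output groups: argmax tie breaks to COPD
  expect_true(all(predict(net, random_bits(4, 1)) == 1L))
})

test_that("probabilities stay in (0,1) and labels in {0,1} under noise", {
  q <- quantize(small_fit())
  net <- deploy(q, rram_config(p_fail = 0.05), iv_model(2), seed = 13)
  X <- random_bits(50, 7)
  p <- predict(net, X, type = "prob")
  expect_true(all(p > 0 & p < 1))
  expect_true(all(predict(net, X) %in% c(0L, 1L)))
})

test_that("test accuracy degrades monotonically with the failure rate", {
  cs <- small_cohort()
  fold <- kfold_split(cs$labels, 5, seed = 2)[[1]]
  fit <- mann(cs$bits[fold$train, ], cs$labels[fold$train],
              control = mann_control(epochs = 600), seed = 3)
  q <- quantize(fit)
  acc_at <- function(p_fail) {
    mean(vapply(1:20, function(s) {
      net <- deploy(q, rram_config(p_fail = p_fail), iv_model(), seed = 700 + s)
      mean(predict(net, cs$bits[fold$test, ]) == cs$labels[fold$test])
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.01, 0.05, 0.2), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 0.02))                # non-increasing trend
  expect_lt(accs[4], accs[1])                         # heavy faults hurt
})

test_that("per-sample read energy accounts for driven rows only", {
  q <- quantize(small_fit())
  net <- deploy(q, ideal_noise(), iv_model(), seed = 1)
  x0 <- rep(0L, 23); x1 <- rep(1L, 23)
  e0 <- sample_read_energy(net, x0)
  e1 <- sample_read_energy(net, x1)
  expect_gt(e1, e0)                                   # more rows driven
  expect_equal(sample_read_energy(net, x1, t_pulse = 10e-6),
               e1 / 50, tolerance = 1e-12)            # linear in pulse length
  # by-hand layer-1 energy for the all-ones input
  gam <- 1
  fwd <- memsaliva:::hnn_forward(net, matrix(x1, 1), 0.01)
  e_byhand <- (sum(net$tot$W1) + sum(net$tot$b1)) * 0.2 +
    sum((fwd$V2 / 0.2)^gam * fwd$V2 * rowSums(net$tot$W2)) +
    sum(net$tot$b2) * 0.2
  expect_equal(e1, e_byhand * 500e-6 * 1e-6, tolerance = 1e-12)
})
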