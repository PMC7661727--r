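# a quantized network whose first groups take the requested levels
q_with_levels <- function(levels) {
  q <- quantize(random_params(1))
  q$W1[seq_along(levels)] <- as.integer(levels)
  q
}

test_that("programmed groups obey the nominal level-current law", {
  net <- deploy(q_with_levels(c(1, 3, 5, 0, -2)), ideal_noise(), iv_model(),
                seed = 1)
  expect_equal(net$n_devices, 1060)
  expect_equal(read_group_current(net, 1), 25)        # 1x30 + 4x5 - 5x5
  expect_equal(read_group_current(net, 2), 75)        # Fig-5 style 3-LRS group
  expect_equal(read_group_current(net, 3), 125)       # 5x30 - 5x5
  expect_equal(read_group_current(net, 4), 0)         # symmetric cancellation
  expect_equal(read_group_current(net, 5), -50)
  # all levels, exactly 25k uA, for an arbitrary IV exponent at full voltage
  for (gam in c(1, 2.3)) {
    net <- deploy(q_with_levels(-5:5), ideal_noise(), iv_model(gam), seed = 1)
    for (g in 1:11)
      expect_equal(read_group_current(net, g), 25 * (-5:5)[g])
  }
})

test_that("read currents scale with voltage through the IV model and stay odd", {
  net1 <- deploy(q_with_levels(3), ideal_noise(), iv_model(1), seed = 1)
  expect_equal(read_group_current(net1, 1, 0.1, -0.1), 75 / 2)  # linear
  net2 <- deploy(q_with_levels(3), rram_config(p_fail = 0.02), iv_model(2),
                 seed = 4)
  for (g in c(1, 50, 106)) {
    i_fwd <- read_group_current(net2, g, 0.15, -0.15)
    i_rev <- read_group_current(net2, g, -0.15, 0.15)
    expect_equal(i_fwd, -i_rev)
    # quadratic model: quarter current at half voltage
    expect_equal(read_group_current(net2, g, 0.1, -0.1),
                 read_group_current(net2, g, 0.2, -0.2) / 4)
  }
  expect_error(read_group_current(net1, 1, 0.25), "0.2 V")
  expect_error(iv_model(0.5))
})

test_that("deployment is reproducible and freezes currents between reads", {
  q <- quantize(small_fit())
  a <- deploy(q, rram_config(), iv_model(), seed = 11)
  b <- deploy(q, rram_config(), iv_model(), seed = 11)
  expect_identical(a$currents, b$currents)
  expect_identical(a$states, b$states)
  x <- random_bits(5, 1)
  expect_identical(predict(a, x, type = "prob"), predict(a, x, type = "prob"))
  # re-programming with another seed resamples
  d <- deploy(q, rram_config(), iv_model(), seed = 12)
  expect_false(identical(a$currents, d$currents))
})

test_that("measured-mode currents match the characterised device moments", {
  state <- rep(c(TRUE, FALSE), each = 10000)
  set.seed(21)
  cur <- memsaliva:::sample_currents(state, rram_config())
  lrs <- cur[state]; hrs <- cur[!state]
  expect_true(all(cur > 0))
  expect_equal(mean(lrs), 35.5, tolerance = 0.02)
  expect_equal(sd(lrs), 3.7, tolerance = 0.10)
  expect_equal(mean(hrs), 3.9, tolerance = 0.02)
  expect_equal(sd(hrs), 1.0, tolerance = 0.10)
})

test_that("switching failures hit the characterised wrong-state rate", {
  q <- quantize(small_fit())
  wrong <- sum(vapply(1:10, function(s)
    wrong_state_count(deploy(q, rram_config(p_fail = 0.0025), iv_model(),
                             seed = 500 + s)), numeric(1)))
  n <- 10 * 1060
  ci <- qbinom(c(0.005, 0.995), n, 0.0025)            # 99% binomial interval
  expect_gte(wrong, ci[1])
  expect_lte(wrong, ci[2])
  # p_fail = 0 never flips
  expect_equal(wrong_state_count(deploy(q, ideal_noise(), iv_model(), seed = 1)), 0)
})

test_that("read energy is |I V| t per device, additive and linear in time", {
  net <- deploy(q_with_levels(0), ideal_noise(), iv_model(), seed = 1)
  # isolate a single LRS device read at 0.2 V for 500 us: 3 nJ
  net$currents[] <- 0
  net$currents[1, 1] <- 30
  expect_equal(estimate_read_energy(net, 0.2, 500e-6), 3e-9)
  expect_equal(estimate_read_energy(net, 0.2, 10e-6), 3e-9 / 50)
  # no voltage applied, no energy
  expect_equal(estimate_read_energy(net, 0), 0)
  # additivity over devices at nominal currents
  net2 <- deploy(q_with_levels(5), ideal_noise(), iv_model(), seed = 1)
  g_tot <- sum(net2$currents[1, ])                     # 5x30 + 5x5 uA
  byhand <- g_tot * 1e-6 * 0.2 * 500e-6
  one_group <- net2
  one_group$currents[-1, ] <- 0
  expect_equal(estimate_read_energy(one_group, 0.2, 500e-6), byhand)
  expect_error(estimate_read_energy(net2, 0.3), "0.2 V")
})

test_that("deployments beyond the 4-kbit array capacity are rejected", {
  q40 <- quantize(random_params(3), n_levels = 40)    # 106 x 40 = 4240 devices
  expect_error(deploy(q40, ideal_noise(), iv_model(), seed = 1), "4096")
  # the default deployment fits: 1060 of 4096 cells
  expect_silent(deploy(quantize(random_params(3)), ideal_noise(), iv_model(),
                       seed = 1))
})

test_that("hardware dump restores an identical network", {
  q <- quantize(small_fit())
  net <- deploy(q, rram_config(p_fail = 0.01), iv_model(1.5), seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_hnn(net, path)
  back <- read_hnn(path)
  expect_equal(back$currents, net$currents, tolerance = 1e-12)
  expect_identical(back$states, net$states)
  expect_equal(wrong_state_count(back), wrong_state_count(net))
  x <- random_bits(8, 2)
  expect_equal(predict(back, x, type = "prob"), predict(net, x, type = "prob"),
               tolerance = 1e-12)
})
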