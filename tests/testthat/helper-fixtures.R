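# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, expr, .fixtures)
  get(key, .fixtures)
}

# default well-separated cohort with its fitted encoding and bit matrix
small_cohort <- function() memo("cohort", {
  cohort <- simulate_cohort(cohort_spec(), seed = 101)
  spec <- fit_encoding(encoding_spec(), cohort)
  bits <- encode_bits(cohort, spec)
  list(cohort = cohort, spec = spec, bits = bits,
       labels = attr(bits, "labels"))
})

# a moderately trained fit on the small cohort (enough to be non-trivial;
# the full default recipe is exercised in the acceptance tests)
small_fit <- function() memo("fit", {
  cs <- small_cohort()
  mann(cs$bits, cs$labels, control = mann_control(epochs = 600), seed = 7)
})

# random analog parameter sets for quantization / oracle properties
random_params <- function(seed, scale = 1) {
  set.seed(seed)
  structure(list(W1 = matrix(rnorm(92, sd = scale), 23, 4),
                 b1 = rnorm(4, sd = scale),
                 W2 = matrix(rnorm(8, sd = scale), 4, 2),
                 b2 = rnorm(2, sd = scale)),
            class = "mann")
}

random_bits <- function(n, seed) {
  set.seed(seed)
  matrix(rbinom(n * 23, 1, 0.5), n, 23)
}

# hardware model under ideal conditions: the software-equivalence regime
ideal_noise <- function() rram_config("nominal", p_fail = 0)
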