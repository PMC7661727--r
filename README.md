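# memsaliva

Software simulator of a mixed-signal memristive (RRAM) neuromorphic
classifier that recognises saliva samples of COPD patients versus healthy
controls (HC) from four clinical attributes: the minimum of the real part of
the saliva dielectric permittivity, age, gender and smoking status.

It is aimed at researchers in hardware-aware machine learning and
point-of-care diagnostics who want to study, end to end and in software, how
a small pre-trained network survives deployment onto binary resistive
memory:

1. **Encoding** — attributes are binarized into a 23-bit pattern
   (gender 1 | smoking thermometer 3 | age thermometer 9 | permittivity
   thermometer 10).
2. **Analog network** — a dense 23–4–2 sigmoid network (106 parameters)
   trained per cross-validation fold with mini-batch Adam (lr 1e-4,
   3000 epochs, batch 10) and 20% hidden-layer dropout on summed binary
   cross-entropy.
3. **10-level quantization** — with Δ = max|θ|/5, magnitudes shift up to
   the next multiple of Δ: signed levels in {−5,…,+5}.
4. **RRAM deployment** — each parameter becomes a group of 10 binary
   devices (5 per read polarity; LRS 30 µA / HRS 5 µA nominal at 0.2 V), so
   level k reads a net 25·k µA; 1060 devices total on a simulated 64×64
   1T-1R array, with device-to-device current variability
   (LRS 35.5 ± 3.7 µA, HRS 3.9 ± 1.0 µA), a 0.25% wrong-state switching
   failure rate, and a configurable power-law I–V non-linearity.
5. **Mixed-signal inference** — 1-bits drive rows at ±0.2 V, summed
   currents are normalized by n = max|θ|/125 µA into software sigmoid
   neurons, hidden activations re-drive the read-out synapses as
   Xi·0.2 V pulses at 10 mV precision; includes per-sample read-energy
   accounting (|I·V|·t per device, serial read-out).
6. **Evaluation** — stratified 5-fold cross-validation (64 train / 16 test
   of 80 subjects), five hardware repeats per fold, accuracy / sensitivity /
   specificity / precision tables for the analog, quantized and hardware
   tiers, confusion matrices, wrong-state counts and energy.

A synthetic cohort generator (40 COPD + 40 HC by default) makes the whole
chain runnable offline; `read_exasens()` ingests the public Exasens CSV
dialect for runs on the real deposit.

## Worked example

```r
library(memsaliva)

cohort <- simulate_cohort(cohort_spec(), seed = 5)  # 40 COPD + 40 HC
exp <- run_experiment(cohort, seed = 5)             # ~20 s on one core
exp
```

```
5-fold cross-validated COPD/HC recognition

Analog network (%):
        accuracy sensitivity specificity precision
Fold 1   93.75    87.50      100.00      100.00
Fold 2  100.00   100.00      100.00      100.00
Fold 3   87.50    87.50       87.50       87.50
Fold 4   75.00    75.00       75.00       75.00
Fold 5   87.50    87.50       87.50       87.50
Average  88.75    87.50       90.00       90.00

10-level quantized network (%):
        accuracy sensitivity specificity precision
...
Average  88.75    87.50       90.00       90.00

Simulated memristive hardware, average of 5 repeats (%):
...
Average  91       92          90          91

Wrong-state devices per run: 3.52 (+- 2.24) of 1060 (0.33%)
Read energy per sample: 587.2 (+- 35.8) nJ at 500 us pulses
```

Each table row is one cross-validation fold evaluated on its 16 held-out
subjects; the hardware rows average five independent programmings of the
simulated array, so they fold in current variability and switching
failures. Here the quantized and hardware tiers track the analog model
within a couple of points — the fault-tolerance property the architecture
is designed for — while each inference costs ~0.5 µJ of read energy at
500 µs pulses.

Individual stages are ordinary S3 steps:

```r
bits <- encode_bits(cohort, fit_encoding(encoding_spec(), cohort))
fit  <- mann(bits, seed = 1)          # analog model
q    <- quantize(fit)                 # 10-level model
net  <- deploy(q, rram_config(), iv_model(), seed = 1)
predict(net, bits, type = "prob")     # mixed-signal inference
```

A thin command-line driver (`exec/memsaliva`) exposes
`generate | train | quantize | deploy | infer | evaluate | pipeline`
subcommands over serialized JSON/CSV artifacts; see `?memsaliva_cli`.

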