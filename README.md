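# semgpe

Gesture recognition from multichannel surface electromyography (sEMG), for
researchers in myoelectric control and biomedical signal processing. The
package implements a complete recognition pipeline — time-frequency
analysis, entropy-based feature compression, and a deep classifier — plus a
synthetic-signal generator so the whole chain can be run, tested and
reproduced without access to laboratory recordings.

## The method

For each channel of a trial:

1. **S-transform.** The discrete Stockwell transform
   `S[jT, n/(NT)] = Σ_m H[(m+n) mod N] · exp(−2π²m²/n²) · exp(i2πmj/N)`
   (with `H` the DFT of the signal) produces a complex time-frequency
   matrix (TFM) over 0–500 Hz whose Gaussian analysis window has standard
   deviation `1/f` in time — fine time resolution at high frequency, fine
   frequency resolution at low frequency.
2. **Multiscale SVD.** From the TFM modulus `A`: the leading 20 global
   singular values `λ_A`; the largest singular value of each of 16
   time-axis blocks, `λ_t`; and of each of 16 frequency-axis blocks, `λ_f`.
3. **Permutation entropy.** Each sequence is compressed to the Shannon
   entropy `H = −Σ p(π) ln p(π)` of its ordinal patterns (embedding
   dimension 3, delay 1), giving the channel feature `F = (Et, Ef, EA)`.
4. **Deep belief network.** The 12 features of the four muscles
   (ECR, ED, FDS, EPB) feed a stack of restricted Boltzmann machines
   (12–300–300–300) pretrained by contrastive divergence
   (`E(v,h) = −a'v − b'h − v'Wh`, sigmoid conditionals), topped with a
   softmax over the nine gesture classes and fine-tuned by gradient
   descent.

The nine classes are the standardized hand shapes FFE, FFC, ET, FT, EIF,
EIMF, ETIF, ETP and FTIF.

## Worked example

```r
library(semgpe)

sig <- default_signatures()[["FFE"]]
rec <- synth_trial(sig, fs = 2000, duration = 1, seed = 42, label = 1)
rec
#> <semg_recording> 2000 samples x 4 channels @ 2000 Hz (1.000 s)
#>   channels: ECR, ED, FDS, EPB
#>   label: 1 (FFE)

tf <- stransform(rec$samples[, "ECR"], st_config(fs = 2000, fmax = 500))
tf
#> <semg_tfm> 501 frequencies x 2000 times, band [0, 500] Hz, fs 2000 Hz

sp <- multiscale_spectrum(tfm_modulus(tf))
round(sp$lambda_A[1:5], 2)
#> [1] 230.07  48.88  42.84  40.44  28.25

round(channel_features(tfm_modulus(tf)), 4)
#>     Et     Ef     EA
#> 1.7348 0.6560 0.0000
```

`Et` near its ln 6 ≈ 1.79 ceiling says the time-block maxima of this steady
contraction are ordinally unstructured; `Ef` ≈ 0.66 reflects the strong,
deterministic spectral peak of a well-recruited muscle; `EA` is 0 because
the global singular values are sorted descending (a single ordinal
pattern). A weakly recruited muscle raises `Ef` toward 1.1; a repetitive
contraction lowers `Et` toward 1.3 — those two effects carry the class code
of `default_signatures()`.

The full study — synthesis, feature extraction, training, evaluation — runs
end to end with one call (about ten minutes):

```r
run <- semg_run_all("study", pipeline_config(), seed = 1, verbose = TRUE)
run$eval$accuracy        # held-out accuracy on 9 classes x 20 test trials
run$eval$per_class       # per-gesture correct counts out of 20
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/semg run-all --out study --seed 1
Rscript inst/cli/semg eval --features study/features_test.csv --model study/dbn_model.json
```

Typical held-out accuracy with the default configuration is 90–94%
depending on the seed.

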