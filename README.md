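# vibralign

Assignment of molecular stereochemistry from vibrational spectroscopy.
`vibralign` compares theoretical IR, Raman, and VCD spectra of candidate
stereoisomers with measured spectra and ranks the candidates
quantitatively. It is aimed at chemists who have harmonic frequency
calculations for each isomer (per conformer, with relative free energies)
and one or more measured spectra, and want an automated, reproducible
answer to "which isomer did I measure?".

## Method

The pipeline has three stages:

1. **Pseudo-Voigt deconvolution.** Every continuous spectrum — the measured
   one and the Boltzmann-weighted, Lorentzian-broadened theoretical one —
   is decomposed into bands `V(x) = η·L(x) + (1−η)·G(x)` (shared height `I`
   and FWHM `w`) by simultaneous bounded least squares, one band per
   detected peak. Fitted heights of strongly overlapping bands are *not*
   inflated by overlap, unlike apparent curve maxima.
2. **Optimal peak alignment.** The experimental and theoretical band lists
   are matched by global dynamic programming with strict frequency-order
   preservation. Each candidate pair is scored by a product of three
   mollifier kernels `φ(δ; C) = exp(1 − 1/(1 − (δ/C)²))` (and exactly 0 for
   `|δ| ≥ C`) in frequency (after scaling theoretical positions by a factor
   μ), max-normalized intensity, and bandwidth. Multiple spectroscopies can
   be aligned jointly; matches across sources are forbidden while the
   common frequency order couples the assignments.
3. **Metrics and screening.** Matched theoretical bands snap onto their
   experimental partners (unmatched bands follow their nearest matched
   neighbour), are re-convoluted, and compared to the measurement by
   Pearson and Spearman correlations on a cubic-spline grid
   (1000–1500 cm⁻¹, 1 cm⁻¹ steps by default). Isomers are ranked by
   `s_comb = s · rP_IR · rS_IR · rP_X · rS_X` (X = Raman or VCD), screened
   over μ ∈ [0.94, 1.02] in steps of 0.005. For VCD, the signs of the
   correlations call the enantiomer: both positive — correct; both
   negative — mirror image.

## Worked example

The package ships a synthetic study generator that emulates the assumed
error structure (systematic frequency scaling 1/0.975, per-mode jitter,
intensity noise, band-shape mismatch, baseline noise) and builds decoy
isomers alongside the true one:

```r
library(vibralign)

study <- make_synthetic_study(synthetic_config(seed = 11), k_decoys = 3)
assessments <- lapply(study$ensembles, function(e) {
  screen_mu(study$experimental, e)
})
rank_isomers(assessments)
```

```
$ranking
   isomer best_mu best_s_comb rank
1 isomer0   0.975  0.34611570    1
2 isomer2   0.970  0.33840381    2
3 isomer3   0.965  0.08585768    3
4 isomer1   0.975  0.07211038    4

$ratio
[1] 1.022789
```

The generating isomer (`isomer0`) ranks first and recovers the built-in
scaling factor 0.975. Its best row reads

```
     mu     s rP_IR rS_IR rP_RAMAN rS_RAMAN s_comb
  0.975 0.506 0.836 0.946    0.905    0.956  0.346
```

i.e. half the alignment's attainable score was realized (`s`), the aligned
IR and Raman spectra correlate strongly with the measurement, and their
product gives the combined score. The ratio 1.02 against the runner-up
warns — correctly, here — that this particular noisy study barely separates
the top two candidates; ratios well above 1 indicate confident assignments.

The same pipeline runs from the shell via the bundled `exec/vibralign`
script (installed under the package's `exec/` directory):

```sh
vibralign=$(Rscript -e 'cat(system.file("exec", "vibralign", package = "vibralign"))')
Rscript "$vibralign" synth  --seed 11 --out demo   # write synthetic fixtures
Rscript "$vibralign" screen --config demo/screen.json   # μ screening + ranking
Rscript "$vibralign" align  --config demo/screen.json --mu 0.975
Rscript "$vibralign" deconvolute --config demo/screen.json
```

Results are written as CSV/JSON (`assessment.csv`, `report.json`,
per-isomer alignment JSON, band-list CSV).

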