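---
title: "Aligning vibrational spectra for stereoisomer assignment: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning vibrational spectra for stereoisomer assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibralign)
```

## The problem

The relative (and, with VCD, absolute) stereochemistry of an organic molecule
can be inferred by computing vibrational spectra for every candidate
stereoisomer and asking which computed spectrum best explains the measured
one. Two obstacles make the comparison non-trivial. First, harmonic
frequencies carry a *systematic* error — correctable by a constant scaling
factor $\mu$ — plus a *stochastic* per-mode error that no global factor can
remove. Second, measured and computed band shapes differ, and neighbouring
bands overlap so strongly in the fingerprint region (1000–1500 cm$^{-1}$)
that apparent peak heights are inflated relative to the heights of the
underlying bands.

`vibralign` addresses both with a three-stage pipeline:

1. **Deconvolution.** Each continuous spectrum is decomposed into
   pseudo-Voigt bands $V(x) = \eta L(x) + (1-\eta) G(x)$, one per detected
   peak, by simultaneous bounded least squares. This recovers the underlying
   band heights $I$, positions $x_0$, widths $w$ (FWHM), and mixing
   fractions $\eta$ even for strongly overlapping bands.
2. **Alignment.** The two band lists are matched by global dynamic
   programming (the sequence-alignment recursion familiar from
   Needleman–Wunsch), preserving frequency order, with the per-pair score

   $$s_{e,t} = \phi\!\left(\tilde\nu_e - \mu\tilde\nu_t;\, C_{\tilde\nu}\right)\cdot
               \phi\!\left(|I_e| - |I_t|;\, C_I\right)\cdot
               \phi\!\left(w_e - w_t;\, C_w\right),$$

   where $\phi(\delta; C) = \exp\!\big(1 - 1/(1 - (\delta/C)^2)\big)$ for
   $|\delta| < C$ and $0$ otherwise — a mollifier: smooth, equal to 1 at
   $\delta = 0$, and *exactly* zero at the cutoff. Peaks that disagree too
   much in any one attribute therefore cannot be matched at all, no matter
   how well the other attributes agree.
3. **Metrics.** Matched theoretical bands are shifted onto their
   experimental partners (unmatched bands follow their nearest matched
   neighbour), re-convoluted, and compared with the experimental spectrum on
   a common grid via Pearson ($r_P$) and Spearman ($r_S$) correlations. The
   alignment also yields a total score $s$; the product
   $s_{\mathrm{comb}} = s \cdot \prod_m r_P^{(m)} r_S^{(m)}$ over the
   modalities $m$ in the run ranks the candidate isomers. A screening of
   $\mu$ over $[0.94, 1.02]$ in steps of $0.005$ selects, per isomer, the
   scaling at which $s_{\mathrm{comb}}$ peaks.

Several spectroscopies (IR with Raman or VCD) can be aligned *jointly*: the
per-source band lists are concatenated with a source label, sorted by
frequency, and aligned in one dynamic program in which cross-source matches
are forbidden. This couples the sources through the common monotone order —
a mode assignment made in IR constrains the Raman assignment — while each
pair is still scored within its own source.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| broadening FWHM | 12 | cm$^{-1}$ | Lorentzian width for theoretical line spectra |
| temperature | 298.15 | K | Boltzmann weighting of conformers |
| $C_{\tilde\nu}$ | 30 | cm$^{-1}$ | frequency-difference cutoff |
| $C_I$ | 0.5 | — | intensity-difference cutoff (max-normalized) |
| $C_w$ | 20 | cm$^{-1}$ | bandwidth-difference cutoff |
| gap score | 0 | — | contribution of an unmatched peak |
| window | 1000–1500 | cm$^{-1}$ | analysis range (1150–1500 for DMSO-d$_6$ data) |
| $\mu$ grid | 0.94–1.02 / 0.005 | — | scaling-factor screening |
| `min_prominence` | 0.02 | fraction of max | peak-detection threshold |
| `min_separation` | 4 | cm$^{-1}$ | minimum distance between detected peaks |

The cutoffs are deliberately user-facing: $C_{\tilde\nu}$ should be of the
order of the stochastic harmonic error of the chosen level of theory; the
defaults suit hybrid-functional frequencies in the fingerprint region.
Intensities are compared after max-normalization within each list, because
measured absorbance and computed intensities live on unrelated scales;
Pearson and Spearman correlations are scale-invariant, so the experimental
spectrum itself is never rescaled.

## Numerical choices

* **Band parameterization.** Both the Lorentzian and the Gaussian are
  height-parameterized with a shared FWHM, so $V(x_0) = I$ and
  $V(x_0 \pm w/2) = I/2$ for every $\eta$. An area-normalized form would
  entangle $I$ with $w$ and $\eta$ and change the meaning of "peak height"
  across shapes.
* **Fit initialization and bounds.** Band positions start at the detected
  peaks, heights at the spectrum value there, widths at the half-maximum
  crossing distance (fallback: the broadening default), $\eta$ at 0.5.
  During fitting $x_0$ may move at most twice its initial width estimate,
  $w$ is confined to [2 × grid spacing, half the window width], and $\eta$
  to [0, 1]; heights are positive except for VCD, where they are signed.
  These bounds keep every band identifiable and attached to its peak. The
  loss is plain least squares (Levenberg–Marquardt via `minpack.lm`); no
  baseline is fitted — spectra are assumed baseline-corrected.
* **Boltzmann weights** are computed with the max-shift trick and are
  invariant under constant energy offsets; whatever energies are supplied
  (free or electronic) are weighted as-is, without degeneracy factors.
* **Dynamic-programming ties** are broken deterministically: match, then
  theoretical gap, then experimental gap. Matches whose pair score is zero
  are recorded as gaps. With the default gap score of 0, gaps are free but
  unrewarded — the cutoffs already prevent bad matches, and a negative gap
  penalty would push the optimum toward exactly those matches the mollifier
  was designed to forbid.
* **Score normalization.** The raw optimum is divided by
  $\max(n_{\mathrm{exp}}, n_{\mathrm{theo}})$, so $s \in [0, 1]$ and is
  comparable across isomers with different band counts; $s = 1$ requires
  every peak matched perfectly. This normalization is a package choice — an
  unnormalized sum would grow with peak count — and can be disabled for
  diagnostics.
* **Cross-source near-ties.** In a joint alignment the same normal mode
  appears in two sources at positions that differ only by fit noise, so
  their relative order in the concatenated string is physically meaningless
  — yet a random order disagreement between the experimental and
  theoretical sides would look like a crossing and force the monotone
  matching to sacrifice a genuine pair. Cross-source neighbours closer than
  2 cm$^{-1}$ (a couple of grid steps, far below band resolvability) are
  therefore ordered canonically by modality on both sides before the
  alignment. Genuinely separated peaks are never reordered.
* **The scaling factor is applied exactly once**, to theoretical positions,
  before scoring and before cutoff evaluation.
* **Per-$\mu$ band selection.** The theoretical spectrum is broadened and
  deconvoluted over the analysis window widened by the $\mu$ range, and for
  each $\mu$ the bands whose *scaled* positions fall in the window enter the
  alignment. The aligned re-convoluted spectrum, however, includes all
  bands — those just outside the window contribute their wings, shifted by
  the same closest-assigned-neighbour rule as any other unmatched band —
  keeping the comparison symmetric with the experimental spectrum, whose
  out-of-window wings are equally present.
* **Degenerate inputs.** Empty line spectra broaden to zero spectra; an
  alignment with no matches shifts nothing and is flagged; constant spectra
  make correlations undefined and raise an error rather than returning
  `NA`.

## The legacy score

For comparison with earlier work a two-term score is provided:
$\exp(-(I_e-I_t)^2/\sigma_1^2)\,\exp(-(\tilde\nu_e-\mu\tilde\nu_t)^2/\sigma_2^2)$,
with spreads $\sigma_1, \sigma_2$ fitted per computational method. The exact
historical form is not pinned down by available sources; this package adopts
the product of Gaussians as the simplest form with the documented
properties — one term for intensities, one for frequencies, maximum 1 at
identity, and a score that reaches zero only at infinite separation. That
last property is precisely its defect: distant peaks can still be dragged
together at tiny but positive reward, which the compactly supported
mollifier score eliminates.

## What the synthetic generator emulates — and what it does not

The generator produces paired experimental/theoretical fixtures with the
error structure the method assumes:

* ground-truth pseudo-Voigt bands with positions uniform in the window
  (minimum separation: half the mean experimental FWHM, so moderately
  overlapping bands occur), heights in (0.2, 1], widths in 8–16 cm$^{-1}$,
  $\eta \in [0.3, 0.7]$;
* theoretical line spectra at `truth position / 0.975` plus Gaussian
  per-mode jitter (sd 3 cm$^{-1}$) and 5% multiplicative intensity noise,
  broadened with a pure 12 cm$^{-1}$ Lorentzian — deliberately *not* the
  experimental band shape, so the deconvolution must absorb the mismatch;
* additive baseline noise (0.5% of the maximum) on the rendered
  experimental spectrum;
* decoy isomers that move a random subset (≥ 30%) of modes by shifts five
  times the jitter scale and reshuffle the subset's intensities, sharing
  the systematic scale — stand-ins for incorrect diastereomers.

The default study pairs IR and Raman, reflecting how assignments are made
in practice: both modalities share mode positions and frequency errors
(frequencies are a property of the mode, not the probe) while band heights
are drawn independently (IR and Raman transition moments are uncorrelated).

Real data differ in ways the generator does not model: DFT frequency errors
correlate between related modes, conformer free-energy errors reweight whole
sub-spectra, solvent shifts are band-specific, and baselines are imperfectly
corrected. A passing synthetic suite therefore demonstrates that the
*algorithmics* — deconvolution, optimal matching, scaling recovery,
ranking — behave as designed, not that any particular level of theory will
assign a particular compound correctly.

Problem sizes used throughout the test-suite experiments: 8-band spectra on
1 cm$^{-1}$ grids over 1000–1500 cm$^{-1}$, 17-point $\mu$ grids, 100-seed
replicate studies with 3 decoys each, and brute-force alignment oracles up
to 7 × 7 peaks. These sizes exercise every code path at full fidelity while
keeping a complete run in the minutes range.

## Known limitations

* **Fused versus split peaks.** When two modes merge into one detected band
  on one side of the comparison but not the other (common when per-mode
  jitter shrinks a gap below the broadening width), the band counts and the
  deconvoluted heights disagree and the alignment score is perturbed. This
  is the dominant failure mode in the synthetic ranking experiment (a few
  losses per hundred studies) and is intrinsic to fixing the number of
  bands at the number of detected peaks.
* The quality of conformer free energies dominates real-world accuracy;
  the package weights whatever energies are supplied and cannot correct
  them.
* Scores of different isomers are comparable; the absolute value of
  $s_{\mathrm{comb}}$ has no meaning on its own. Confidence should be read
  from the best/second-best ratio, and near-unity ratios mean additional
  experimental information is needed.

## A worked run

```{r example, eval = FALSE}
study <- make_synthetic_study(synthetic_config(seed = 11), k_decoys = 3)
assessments <- lapply(study$ensembles, function(e) {
  screen_mu(study$experimental, e)
})
rank_isomers(assessments)
```

The same pipeline is scriptable from a shell through the `vibralign`
executable (`synth`, `deconvolute`, `align`, `screen` subcommands) with a
single declarative JSON configuration in which every default above is a
named key.
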