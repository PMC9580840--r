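---
title: "Hydropathy water-wave profiles and level-set statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydropathy water-wave profiles and level-set statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrolevels)
```

## The model

A hydropathy scale assigns each of the 20 amino acids a number Ψ(aa)
quantifying hydrophobicity. The package orients every scale so that
hydrophobic residues sit at *maxima*; peaks of a profile are therefore
hydrophobic and valleys hydrophilic.

Given a sequence and an odd window width $W = 2N + 1$, the profile value
at center position $i$ is the arithmetic mean of the scale values over
positions $i - N, \ldots, i + N$. Edges are truncated, not padded: a
region of length $n$ yields $n - W + 1$ values, and the first and last
centers sit $N$ residues inside the region. Padding would fabricate
extrema at the boundaries, and boundary extrema are exactly what the
downstream statistic must not see, so no value is emitted where the
window would overrun the region. All positions are reported in 1-based
coordinates of the *full* original sequence even when a sub-region (for
kinesins, the ~350-residue motor domain) is analyzed, so peaks from
different species can be compared on a common axis.

Interior extrema are points strictly greater (peaks) or smaller
(valleys) than both neighbors. A plateau — a maximal run of equal values
above (below) both flanks — is reduced to its central index, ties toward
the smaller index, which keeps the output deterministic. Among peaks
closer than `min_separation` residues, only the higher survives; the rule
is applied iteratively from the highest peak down, and to valleys from
the lowest up. The default `min_separation = 10` suits W = 9 profiles of
~350-residue domains, whose raw profiles jitter at a scale of a few
residues while the biologically discussed peaks are tens of residues
apart; setting it to 1 disables thinning.

The synchronization statistic takes the $k$ highest peaks (default
$k = 5$; ties at the cutoff broken toward the smaller position) and
measures their deviation from the common mean:

$$D = \frac{1}{k} \sum_{j=1}^{k} \lvert v_j - \bar v \rvert
  \qquad (\texttt{definition = "mad"}, \text{ default})$$

or the sample standard deviation (`"sd"`). The published tables this
statistic descends from say only "deviation from the mean", which both
definitions satisfy; the package defaults to the mean absolute deviation
and exposes the choice, and the acceptance suite performs the
disambiguation against the published human value whenever the user
supplies the reference sequences (they are not redistributable, so the
default could not be fixed against them here). $D$ is affine-equivariant:
rescaling the scale by slope $a$ multiplies $D$ by $|a|$, leaving peak
positions and species rankings unchanged. Deviations are therefore only
comparable between runs on the same scale, and the MZ exponents shipped
here (range ≈ 0.07–0.25) give $D$ values roughly 50× smaller than the
same analysis on KD units.

`level_members()` reports how many of the $k$ peaks lie within a band of
half-width ε around the subset mean; because an optimal subset is
contiguous in value order, a scan over value-sorted windows is exact (the
tests verify this against full subset enumeration). ε defaults to the
peak set's own mean absolute deviation — self-scaling, since no leveling
tolerance is published — with a perfectly level set falling back to a
tiny positive band so that all peaks count as members.

## The scales and the power-law fitter

The MZ scale is defined by self-similar occlusion: over segment lengths
$9 \le L \le 35$, the mean solvent-accessible surface area of
$L$-segments centered on a given amino acid follows
$\log \mathrm{SASA}(L) \sim \mathrm{const} - \Psi(aa)\,\log L$.
`fit_psi_exponent()` implements the defining fit as an ordinary
least-squares regression of log SASA on log $L$, restricted to a
configurable range with default [9, 35] — the regime in which the
power law holds in Protein Data Bank statistics; both bounds are exposed
because other corpora may show a different self-similar range. The fitter
recovers noise-free exponents to 1e-10 and is invariant to positive
rescaling of the SASA values (only the intercept shifts). The 20 shipped
MZ values are transcribed constants from the 2007 primary source, and the
KD values from the 1982 one; the package deliberately does not re-derive
the MZ scale from structures (no SASA computation from coordinates).
Residue codes without a scale value (B, Z, X, U, O) raise an error by
default, because a statistic driven by the five highest peak values is
sensitive to imputed heights; `na_action = "impute"` substitutes the
scale mean for users who prefer robustness over strictness.

## The optimal window W\*

Published analyses read the optimal width from graphs of profiles with
$W$ from 7 to 21. The package operationalizes $W^*$ as the width
minimizing the level deviation over the sweep (ties toward the smaller,
higher-resolution window), which is a reproducible proxy for the visual
procedure, not a reimplementation of it. Widths yielding fewer than two
peaks are reported but excluded from the minimization; a constant
sequence yields no $W^*$ at all rather than an arbitrary one.

## The synthetic generator

`generate_sequence()` emulates the one feature of real motor-domain
sequences the pipeline is designed to measure: $k$ well-separated
hydrophobic peaks whose heights share a common level with controllable
spread σ, on a hydrophilic stochastic background. Background residues are
sampled from the six residues nearest the target background level,
excluding the four most hydrophobic of the scale so spurious background
peaks stay far below the planted ones. Each motif is a multiset of
`motif_width` residues chosen greedily against the running remainder of
the target sum — alternating between the nearest value above and below
the remainder, so motifs stay compositionally diverse rather than
collapsing onto one or two residue types — with the most hydrophobic
residue placed centrally and the rest in random order. The full-width
window mean at the center is then order-invariant and lands on the drawn
height up to residue quantization (the scale is a 20-point lattice, so
requested heights are never hit exactly; the truth object reports the
*achieved* window means, which is what any oracle should use). Narrower
windows see a different residue mix per motif, which is what makes the
planted width identifiable in a window sweep.

Defaults are fixed once: length 360 (motor-domain size), $k = 5$,
`motif_width` 9 (the analysis window), `min_spacing` 40 (five
well-separated peaks across ~350 residues), target level 3 and background
−1 on the KD scale, σ = 0. Levels and spreads are expressed in the units
of the generator's scale; the KD default is used because its familiar
[−4.5, 4.5] range makes spreads of 0–2 units meaningful, whereas the raw
MZ exponent range (≈ 0.18 wide) could not accommodate them. What the
generator does *not* emulate: amino-acid composition bias, autocorrelated
hydropathy of real secondary structure, homology between sequences, and
indels. Passing the recovery tests therefore shows the pipeline measures
what it claims on signals of known structure — not that any real protein
family has level sets.

## Numerical choices

- Window means use a linear filter; profile values are means of scale
  values, so they always lie within the scale's range (the tests check
  the contraction property for nested windows).
- Plateau centers, peak-selection ties and matching ties all break toward
  the smaller position, making every output deterministic.
- `match_peaks()` pairs greedily by global nearest position within
  `max_shift`, which is stable and transparent; it is a display aid for
  numbered-peak comparisons, not an alignment.
- Profile export prints doubles with 17 significant digits so that
  exported profiles round-trip bit-exactly.
- Generator determinism: a supplied seed is applied locally and the
  caller's RNG state is restored afterwards.

## Validation problem sizes

The test suite validates extremum detection and level-membership against
brute-force oracles on *every* profile of length 3–12 over a three-value
alphabet (~800,000 cases), the spread-recovery study runs 50 replicates
per σ ∈ {0, 0.25, 0.5, 1, 2} at length 360, and the acceptance script
repeats the headline computations at 50 replicates per condition. These
sizes give exhaustive coverage at small scale and stable medians at study
scale while keeping a full run on a single CPU in the low minutes.

## Known limitations

- Cross-species conclusions inherit the user's choice of motor-domain
  boundaries; published boundaries per species are not available, so
  regions must be supplied (e.g. from UniProt feature annotation) and
  results can shift by a few percent with the region.
- Published deviation tables for kinesins appear to be computed on an
  affinely rescaled variant of the MZ scale whose constants are not
  printed; by affine equivariance this changes only the units of $D$,
  not rankings or ratios, but absolute published values cannot be
  reproduced without that scaling.
- The deviation statistic says nothing about *why* peaks are level;
  it is a descriptive synchronization score, not a test of selection.
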