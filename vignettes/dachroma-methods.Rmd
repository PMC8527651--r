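---
title: "Quantifying differential chromatin accessibility between metaphase homologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential chromatin accessibility between metaphase homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dachroma)
```

## The biological question

During mitosis the two homologous copies of a chromosome condense into
cytologically indistinguishable bodies, yet short sequence-defined FISH
probes (single-copy or *sc* probes, roughly 1.4–4 kb) sometimes
hybridize with reproducibly different intensity on the two homologs of
the same metaphase cell. This *differential accessibility* (DA) — as
opposed to *equivalent accessibility* (EA), where both homologs light
up alike — reflects an allele-specific difference in local chromatin
condensation and behaves like a heritable epigenetic mark. `dachroma`
implements the desk side of a DA study end to end: quantifying homolog
signals in images, turning categorical analyst scores into DA/EA calls
with the accompanying statistics, designing single-copy probe
intervals, aggregating concordant DA probes into chromosomal domains,
relating those domains to open-chromatin marks, and classifying their
overlap with topologically associated domains (TADs).

Because the original microscope images and consortium data pulls are
not redistributable, every pipeline stage is paired with a synthetic
generator that produces inputs with known ground truth. The package's
claims are therefore of two kinds: *exact* reconstructions of the
published probe/domain coordinate arithmetic (shipped as a fixture),
and *property-level* statements ("the quantifier recovers planted
ratios to ±0.05") demonstrated on synthetic data.

## Coordinate conventions

All intervals are 1-based with inclusive printed ends, as in the
published probe table. Interval length is **`end − start`**
(`span_length()`): under this convention every bracketed domain length
in the probe table is reproduced exactly from the printed coordinates
(e.g. chr2:31,545,815–31,571,269 → 25,454 bp). A second dialect
(`end − start + 1`) appears in some per-probe figure captions in the
literature; it is deliberately not used anywhere here. Gap lengths are
`next start − previous end`, and kb strings are rounded half-up to one
decimal (`format_kb(82850)` → `"82.9"`), matching the report style of
the source tables. BED and bedGraph files are 0-based half-open on
disk and converted on read/write (via `rtracklayer`). Track
integration measures overlaps as `min(end) − max(start)` — the same
`end − start` convention — which makes integration additive over
partitions that share an endpoint.

## Image quantification by gradient vector flow

Each metaphase cell image contains two hybridization signals, one per
homolog. Quantification is a five-stage chain (`quantify_cell()`):

1. **Seeds** (`detect_signal_seeds()`): the two brightest separated
   local maxima of the Gaussian-smoothed image, standing in for the
   expected probe target locations. Cells without two separable
   signals are *unscorable* and are tallied as excluded, mirroring the
   exclusion rules of visual scoring.
2. **Edge map** (`edge_map()`): squared gradient magnitude of the
   smoothed image, rescaled to [0, 1] — exposure invariant.
3. **Gradient vector flow** (`gvf_field()`): the edge gradient is
   diffused by iterating
   `u ← u + dt (μ ∇²u − (u − fx)(fx² + fy²))` (likewise `v`), which
   extends the capture range of the contour: near edges the field
   keeps the edge-gradient direction essentially exactly; far away it
   interpolates smoothly. The unit test solves the same Euler–Lagrange
   fixed-point equations as a sparse linear system and confirms the
   iteration converges to it.
4. **Active contour** (`evolve_contour()`): a closed snake initialized
   as a small circle at the seed, relaxed semi-implicitly under
   tension/rigidity and the GVF force, returned as the filled binary
   mask of its interior.
5. **Integration and ratio** (`integrated_intensity()`,
   `intensity_ratio()`): background-corrected signal sums I1 ≥ I2 and
   the normalized homolog intensity ratio |I1 − I2| / (I1 + I2),
   which is 0 for perfectly equivalent homologs and 1 when one signal
   vanishes. The ratio is symmetric and invariant under common
   rescaling, so homolog order and exposure do not matter.

### Numerical choices that matter

* **Per-signal windows.** The edge map and GVF field are computed in a
  21×21 px window around each seed (`window = 10`), with the edge map
  rescaled locally. In a global field, gradients of a bright homolog
  (edge energy scales with amplitude squared — 400-fold at a 5%
  asymmetry) dominate the diffusion around its dim partner and drag
  its contour away. Windowing makes segmentation invariant to each
  homolog's own brightness, which is exactly the property the ratio
  needs.
* **Normalized snake force.** The GVF force is applied as unit vectors
  (`normalize = TRUE`): the attraction toward the boundary ridge is
  then amplitude-independent, so dim and bright signals converge
  alike.
* **Arc-length resampling.** Snake vertices are redistributed along
  the contour every 10 steps. Without this, vertices slide
  tangentially along the boundary ridge and bunch at its strongest
  point, collapsing the polygon.
* **Mask growth.** The converged contour sits on the gradient ridge of
  the point-spread function, at roughly one PSF sigma from the center,
  which encloses only part of the signal photons. The mask is
  therefore dilated by 2 px before integration (`mask_grow`). Because
  both homolog masks grow identically, the *ratio* is robust to this
  choice; the absolute sums benefit from it.
* **Background.** Median intensity of a 2-px annulus dilated around
  the (grown) mask, with a global-percentile fallback for degenerate
  annuli. Median, not mean, so a neighboring signal tail cannot skew
  the estimate.
* **Collapse detection.** A contour that shrinks below 4 px of area is
  unscorable. A flat, featureless field provides no boundary support
  at all; because pure internal-energy shrinkage approaches the area
  floor only asymptotically, the implementation additionally declares
  a contour unscorable when the external force along the final contour
  is numerically zero.
* **Defaults** (`gvf_config()`): μ = 0.2, 80 diffusion iterations,
  tol 1e−3, α = 0.1, β = 0.5, κ = 0.6, initial radius 3 px, 40
  vertices, 400 steps. These are conventional, stable values; the
  recovery tests pass with comfortable margins, indicating the results
  are not delicately tuned.

### What the synthetic images do and do not show

`generate_fish_image()` plants two isotropic Gaussian spots with exact
integrated sums S and ρS (ρ ∈ [0, 1]) on a constant background with
Gaussian or Poisson noise; the true ratio is (1 − ρ)/(1 + ρ). The
default regime (S = 30,000, PSF σ = 2 px, background 20, read noise
σ = 3 on a 64×64 frame) gives a bright-spot peak SNR of ~400 and a
dim-spot peak SNR of ~20 at ρ = 0.05 — a clean epifluorescence
scenario. The generator does **not** model chromosome morphology, DAPI
counterstain, optical aberration, or overlapping chromosomes, so
passing recovery tests demonstrate the correctness and calibration of
the quantification chain, not its performance on degraded real-world
images. The DA/EA batch generator draws per-cell true ratios around
medians 0.8 and 0.2 — the scale of published DA and EA medians — so
the regime-separation test exercises the same contrast the study
reports, on synthetic ground truth.

## Scoring and the statistical battery

Analysts grade each homolog `bright`, `medium`, `dim` or `nil`.
`score_cell()` calls a cell **DA** when the grades differ, **EA** when
both are bright or both medium, and **EXCLUDED** for dim/dim, nil/nil,
dim/nil (uninformative: total signal too weak to compare) or when
chromosomes overlap at the target. `classify_probe()` pools scored
cells across a probe's samples and calls the probe DA (or EA) when
that fraction exceeds 1/2 *and* a two-tailed binomial test against
p₀ = 0.5 is significant at α = 0.05; the "more than 2/3 of cells"
landmark seen in published frequency tables is reported as a flag,
never used as a gate. Scoring fewer than 25 pooled cells attaches an
explicit warning.

The binomial test uses the normal approximation — the form quoted in
the source methods — with a **half-unit continuity correction**. The
correction is the package's own choice: at the cell counts involved
(n ≈ 25–65) it keeps the approximate two-sided p within 0.002 of the
exact binomial p across all outcomes, where the uncorrected statistic
deviates by up to 0.16 near the null; decisions at α = 0.05 are
unaffected in all published comparisons. The Mann–Whitney test
(homolog intensity-ratio comparisons) uses the exact permutation null
for small untied samples and the tie-corrected normal approximation
otherwise, again with a continuity correction by default; the
Kruskal–Wallis H (per-tissue DA fractions) and Welch t (chromatin-mark
means) delegate to the standard R implementations. The classical
identity H = z² for two untied groups holds for the *uncorrected*
Mann–Whitney z, and is verified in that form. The two-proportion
z-test (between-sample DA fractions) uses the pooled-variance
statistic without continuity correction; at the published counts
(49/65 vs 44/48) it gives p = 0.025 where the source prints p = 0.02 —
the same decision, a different test variant, so agreement is claimed
at the decision level only.

No multiple-testing correction is applied across probes, matching the
source analysis; the test objects carry their α so a caller can apply
`p.adjust` externally if desired.

## Single-copy probe design

Probe intervals must behave as unique sequence under hybridization.
`find_sc_intervals()` removes everything overlapping a repeat element
diverged < 20% from its family consensus (younger repeats
cross-hybridize genome-wide; older, > 20%-diverged ones behave as
unique targets) and returns the maximal surviving runs, keeping those
≥ 1400 bp and flagging runs > 4000 bp as oversize rather than
trimming them. Candidates overlapping a copy-number variant of ≥ 1%
population frequency by even one base are excluded
(`filter_cnv()`) — a copy-number difference between homologs would
mimic DA. For cross-tissue work, genic probes must fall in genes with
at most 5 TPM in *every* tissue of interest (`filter_expression()`);
a genic probe without expression records is an error, never a silent
keep.

Primer pairs are evaluated (`evaluate_primer_pair()`) against hard
rules — both Tm in 58–65 °C, |ΔTm| ≤ 2 °C, product no longer than the
sc interval and no more than 500 bp shorter (the slack is
configurable, since the bound could equally be read from the length
cap) — and soft preferences (GC 40–60%, primers > 25 bp) that only
affect ranking, together with self-complementarity scored as the
maximum Watson–Crick match count over all ungapped self-alignments.
Melting temperatures use unified nearest-neighbor thermodynamics
(SantaLucia 1998 parameters, 50 mM monovalent salt, 500 nM total
primer) so the computation is reproducible offline; the original
workflow used a web service whose exact settings are not restated, so
equality with it is not claimed, and the parameters are arguments.

## Domains, marks, and TADs

`build_domains()` aggregates probes into **DA domains**: maximal runs
of ≥ 2 consecutive DA probes with no interspersed EA probe, within one
*analyzed probe set*. Probe sets are delimited by the chromosome-band
column of the probe table (else by chromosome): one chromosome can
carry several independently analyzed loci — chr15 carries three — and
run-scanning across loci would incorrectly merge them. No maximum gap
is imposed (the largest published intra-domain gap is 87,287 bp), but
a configurable `max_gap` warning is available. Isolated DA probes are
reported as singletons, never as domains. Domain boundaries are the
smallest and largest member-probe coordinates; contiguity between
probes is an inference, not an observation — the report therefore
carries the gaps explicitly.

`integrate_track()` accumulates piecewise-constant open-chromatin
signal (DNase I HS, FAIRE, histone-mark ChIP-seq, read from bedGraph)
over intervals; `compare_marks()` Welch-tests DA against EA interval
groups per mark, flags values exceeding 10× their group median
(promoter-like outliers), and censors them **only when asked**,
always reporting what was censored — mirroring the explicit, logged
exclusion of one promoter-proximal probe in the source analysis.

`classify_tad_overlap()` assigns each domain exactly one of four
labels against a TAD partition: `within` (inside one TAD, more than
one boundary window from both edges), `within_boundary_proximal`
(inside but near an edge), `spans_boundary`, or `between_tads`
(overlapping no TAD). The boundary window defaults to the TAD calling
resolution (25 kb — one contact-map bin), since "approaches a
boundary" is only ever described qualitatively. TADs enter as
precomputed intervals (BED or constructed); contact matrices are out
of scope.

## Synthetic generators and reproducibility

All generators (`generate_fish_image()`, `generate_fish_batch()`,
`generate_cell_scores()`, `generate_repeat_landscape()`,
`generate_signal_track()`, `generate_tads()`) are pure functions of
their arguments and seed; reruns are byte-identical. The score-table
generator draws category pairs only from the DA-consistent,
EA-consistent and excluded sets, so generator and scorer agree by
construction. The repeat-landscape generator tiles repeats flush
against the planted single-copy run boundaries and keeps inter-tile
gaps below the probe minimum, so the plantable intervals in its ground
truth are recovered exactly by the finder; its divergence mixture is
controllable so the > 20%-divergence rule can be exercised in both
directions.

Problem sizes used in the shipped tests and acceptance script — 100
cells per asymmetry level, 25-cell DA/EA batches, 500 classification
replicates at 50 scored cells, 1000 Kruskal–Wallis null simulations,
100-case brute-force oracle sweeps — are the package's chosen
trade-off between statistical resolution and a test suite that runs
in minutes on one core.

## Known limitations

* The quantifier assumes two signals per cell (one homolog pair);
  polyploid or overlapping-chromosome cells must be excluded upstream,
  as they are in visual scoring.
* The PSF is isotropic Gaussian; strongly astigmatic optics would
  bias the contour shape, though the ratio is first-order robust.
* Intron-based probe naming requires an intron annotation table;
  naming relative to the centromere requires the centromere
  coordinate, which is assembly-specific.
* Published p-values produced by unspecified test variants are
  matched at the significance-decision level, not digit-for-digit.
* TAD labels depend on the TAD caller and resolution; the package
  classifies against whatever partition it is given.
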