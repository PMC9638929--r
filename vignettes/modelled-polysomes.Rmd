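---
title: "Modelled polysome profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelled polysome profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyprof)
```

## The problem

Polysome profiling and ribosome footprinting (Ribo-Seq) measure the same
underlying quantity — how many ribosomes are loaded on the cell's
transcripts — at different resolutions.  A sucrose-gradient profile
summarises it as a series of absorbance peaks (40S, 60S, 80S monosome,
then the 2-some, 3-some, ... "n-some" peaks), while Ribo-Seq paired with
RNA-Seq yields per-gene ribosome densities.  `polyprof` projects count
data down to the information level of a polysome profile.  Because the
projection is strongly constrained by cell-level physiology, profiles
modelled from sound datasets look like experimental ones, and datasets
with RNA/footprint biases stand out visually and quantitatively — which
makes the modelled profile a convenient integrity check for footprinting
datasets.

## From counts to a modelled profile

Given a table of per-gene CDS lengths, footprint counts and RNA-Seq
counts, `compute_states()` converts both assays to absolute per-cell
numbers:

* RNA counts are length-normalised to reads per kilobase (RPK) and RPK
  shares scaled to the total cellular mRNA count
  (`total_mrna`; 60 000 for yeast, 300 000 for HEK293 cells);
* footprint-count shares are scaled to the translating ribosome pool,
  `total_ribosomes * active_fraction` (200 000 x 0.85 for fast-growing
  yeast; 2 000 000 ribosomes for HEK293);
* the gene's mean ribosome density is the ratio of the two.

Footprint counts are *not* length-normalised: one bound ribosome
protects one footprint, so a gene's expected footprint count is already
proportional to the number of ribosomes bound across all its transcript
copies.

`assign_to_peaks()` then distributes each gene's bound ribosomes onto
the two peaks whose integer indices straddle its mean density `d`: with
`f = d - floor(d)`, a fraction `1 - f` of the ribosome mass goes to peak
`floor(d)` and `f` to peak `ceiling(d)`.  A transcript at 10 copies with
d = 5.8 (58 ribosomes) therefore places 11.6 ribosomes on the 5-some
and 46.4 on the 6-some peak.

Two boundary cases are not forced by that rule and are resolved as
follows:

* **Sub-monosomal densities** (0 < d < 1) use the same rule with
  floor = 0.  The "peak 0" share is ribosome mass attributed to
  transcript copies carrying no ribosome; it is conserved in the
  bookkeeping (so mass-balance checks are exact) but contributes
  nothing to the rendered profile — ribosome-free mRNA is essentially
  invisible at OD254 next to rRNA.
* **Very high densities**: peaks above `n_max` (default 20) are pooled
  into peak `n_max` and the pooled amount reported.  Real gradients
  compress everything beyond roughly the 12-some into an unresolvable
  shoulder, so a terminal catch-all peak loses nothing visible while
  keeping the volume vector finite.  Densities above the packing limit
  of one ribosome per 10 codons (`length_nt / 30`) are *not* truncated;
  their prevalence is reported as a QC metric (`over_cap_fraction`),
  since physically impossible loads are themselves a symptom of biased
  data.

`add_inactive()` completes the profile with the ribosomes Ribo-Seq
cannot see.  The inactive pool `total_ribosomes * (1 - active_fraction)`
is divided by `split_fraction` into free subunits — apportioned to the
40S and 60S peaks by subunit mass (`small_subunit_fraction`, 0.35 in
yeast, 0.37 in mammals) — with the remainder added to the monosome peak
as idle 80S couples.  With yeast defaults and no translating ribosomes
at all this gives 40S : 60S : 80S = 0.105 : 0.195 : 0.700.  Setting
`include_idle = FALSE` skips the completion and normalises the n-some
masses alone, which is the right mode when the inactive proportion is
unknown (e.g. stress conditions).

The yeast `active_fraction` (0.85) and `split_fraction` (0.3) are
literature-anchored defaults for fast growth in rich medium.  The
HEK293 preset inherits the yeast active fraction and ships
`split_fraction = 0.6`, reflecting the visibly larger subunit peaks of
mammalian gradients; both should be treated as tunable against an
experimental profile for serious use.

## Peak locations

Sedimentation compresses successive peaks, and in practice peak
position is linear in the logarithm of the n-some index:
`position = a * ln(index) + b`.  (Equivalently, the index grows
exponentially with position; the package fixes the logarithmic
parameterisation as canonical to avoid ambiguity.)  Free subunits enter
the same fit with fractional indices proportional to subunit mass: 0.35
(yeast 40S) and, by the same mass-proportionality argument, 1 - 0.35 =
0.65 for the 60S; 0.37/0.63 for mammals.  Fitting `a` and `b` to a few
visually separable peaks lets `predict_positions()` extrapolate the
centres of the unresolvable high-polysome peaks.

`detect_peaks()` implements a deliberately simple detector suited to
smooth gradient scans: a candidate peak is a point where at least
`min_run` (default 4) consecutive strictly increasing samples are
immediately followed by at least `min_run` strictly decreasing samples.
Equal consecutive readings break a run, with one exception: a flat
plateau at the apex itself is tolerated and the peak placed at the
plateau midpoint.  Noise-free symmetric signals sampled on a symmetric
grid otherwise produce two equal samples straddling the maximum and the
apex would be missed on a technicality.  The detector assumes
chart-recorder-smooth data; on traces whose per-sample noise approaches
the per-sample signal slope near an apex, runs break and peaks are
missed, so noisy traces should be smoothed (or peak positions supplied
manually) before detection.  The debris region at the top of the
gradient is excluded with the `min_position` cutoff, which is left to
the user because debris extent varies between gradient stations.

## Fitting traces as constrained Gaussian mixtures

A profile is modelled as a sum of scaled normal densities — one per
peak, the scale factor `s_i` equalling the area under the peak — plus an
exponential debris term `A e^(-k x)` and a linear baseline `m x + c`.
`fit_profile()` performs bounded nonlinear least squares
(Levenberg–Marquardt, `minpack.lm`) over the scale factors, widths and
background, with the peak centres *fixed* at the supplied locations.
Fixing the centres is what distinguishes this from a generic Gaussian
mixture: free centres destroy identifiability in the compressed
high-polysome region, while fixed centres leave a well-conditioned,
mostly linear problem.

Width handling: peak widths vary smoothly along a gradient, so the
default ties them to the local inter-peak spacing through one shared
factor `w` (`sigma_i = w * spacing_i`, bounds 1e-3 to 1).  A fully
independent per-peak width mode exists; it initialises from the shared
solution.  Numerical choices: scale factors are bounded below by 0 and
the debris decay rate by 1e-6; convergence tolerance 1e-8 with at most
5000 residual evaluations; scale factors initialise from the trapezoid
signal mass within half a spacing of each centre, the baseline offset
from the trace minimum (endpoint samples sit inside the first and last
peaks and over-estimate it), and the debris amplitude from the first
sample.  The residual surface has a local minimum with over-wide peaks
absorbing the valleys, so the shared-width fit is multi-started over
`w` in {0.1, 0.25, 0.4} (plus the user's `w_init`) and the best
candidate kept.  Non-convergence raises a classed fit-failure error
carrying the last residual.

Normalising the fitted `s_i` (background excluded) gives the
peak-volume vector, the common currency of all comparisons; it is
invariant to uniform rescaling of the trace, as absorbance units are
arbitrary.  `pm_ratio()` reduces it further to the classical
polysome/monosome ratio.

## Comparing and clustering profiles

`rmsd()` computes the root-mean-square deviation between two normalised
volume vectors over the union of their peak labels (absent peaks read
as zero), in the fixed order 40S, 60S, 1..n.  To make RMSDs
interpretable, `fit_null()` computes all pairwise RMSDs within a
"known-good" collection and fits a normal by maximum likelihood (mean
and population standard deviation, matching a `norm.fit`-style
estimate); `rmsd_pvalue()` reports the upper-tail probability of a
given RMSD under that null.  The upper tail is the only direction
consistent with usage — large RMSD means dissimilar, so small P flags a
suspect dataset — and values below the null mean give P > 0.5, reported
as-is since the quantity is a plain tail probability.  A reasonable
working rule is to look harder at any dataset whose P-value against a
known-good collection approaches 0.05.

`cluster_profiles()` clusters aligned volume vectors with Euclidean
distance and complete linkage, choosing the number of clusters by the
Davies–Bouldin validity index over a candidate range.  The standard
index (mean over clusters of the worst (S_i + S_j) / M_ij ratio) is
*minimised* at good partitions; the package's default does exactly
that.  Because the index is sometimes described as a between/within
ratio to be maximised, a `db_mode = "max_inverted"` flag implements
that literal reading (maximising the mean best M_ij / (S_i + S_j));
on clearly separated data the two selections agree.  One caveat
discovered during validation: on *structureless* data (a single tight
cloud) the standard index keeps improving as k grows, because complete
linkage happily carves tight sub-clusters; the index is a tool for
choosing among genuinely distinct partitions, not a test for the
existence of structure.  `meta_profile()` averages and renormalises the
vectors within each cluster.

## The synthetic-data generator

`fixture_spec()` fixes every generator knob so fixtures are reproducible
from (spec, seed) alone.  The defaults emulate a fast-growing yeast
culture: log-normal per-gene densities (median 2 ribosomes/transcript,
log-sd 0.6, capped at the `length/30` packing limit) — which places the
profile maximum around the 2-/3-some as in experimental yeast profiles —
log-normal transcript lengths around 1.5 kb, log-normal expression with
log-sd 1, and a trace geometry of `position = 20 ln(index) + 30` with
width factor 0.25, debris amplitude 2, decay 0.5 per gradient unit, and
a slight linear baseline.  Sequencing is simulated multinomially
(expected footprint reads proportional to `copies * density`, expected
RNA reads proportional to `copies * length / 1000`), so read totals are
exact and conservation tests can be sharp.  `make_count_table()` can
also pin genes to integer densities reproducing a prescribed volume
vector exactly in expectation, which is what the parameter-recovery
tests use (at a simulated depth of 1e7 reads the full pipeline returns
the prescribed vector to within 1% per peak).

What the generator does **not** emulate: UTR-bound or out-of-frame
footprints, isoform mixtures, positional coverage biases along the CDS,
nuclease footprint-end biases, or correlated over-dispersion between
the two assays.  Passing recovery tests therefore demonstrates the
correctness of the inversion arithmetic under the model's own
assumptions — not robustness to every artefact real datasets exhibit.
The `fixture_params()` helper builds cell parameters whose totals match
a fixture's generating truth; absolute density recovery is only defined
when the assumed totals are consistent with the data, which is equally
true of real cells.

Test problem sizes were chosen to keep the suite fast while leaving no
statistical doubt: 30–400 genes per table, depths of 1e6–1e8 reads for
recovery checks, traces of 400–800 samples, and collections of 20–31
vectors for null fitting — the full suite runs in a few seconds.

## Known limitations

* The monotonic-run peak detector needs smooth traces (see above).
* Peak volumes approximate ribosome counts by neglecting mRNA and tRNA
  absorbance; this is excellent for rRNA-dominated absorbance but
  slightly underweights long transcripts.
* The idle-ribosome completion assumes one global active fraction and
  split fraction; conditions that change them (stress, drugs) need
  either measured values or `include_idle = FALSE`.
* The normal RMSD null is a convenience fit to pairwise RMSDs; extreme
  tails of the true pairwise distribution are not guaranteed normal,
  so P-values far below 1e-4 should be read qualitatively.
* The packaged known-good collection is synthetic (generated by
  `make_known_good_collection()`, recorded in its file header); it
  demonstrates the workflow offline and should be replaced with real
  curated datasets for production QC.
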