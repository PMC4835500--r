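---
title: "Methods: cultivar chemistry, ITS2 barcoding and habitat suitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cultivar chemistry, ITS2 barcoding and habitat suitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zanthotools)
```

zanthotools implements a four-stage characterisation of Szechuan pepper
cultivars — two *Zanthoxylum armatum* cultivars (ZA1 Jinyangqing Huajiao,
ZA2 Tengjiao) and four *Z. bungeanum* cultivars (ZB1 Yuexigong Jiao, ZB2
Lingshang Zhenglujiao, ZB3 Da Hongpao, ZB4 Hanyuan Huajiao). The stages
are pericarp chemistry, ITS2 DNA barcoding, chemo-ecological regression,
and habitat-suitability mapping. This vignette explains each model, its
assumptions and tunable parameters, what the synthetic generators do and
do not emulate, and the numerical choices made where the methods leave
room.

## Pericarp chemistry

The two economically decisive contents are the volatile oil (steam
distillation; aroma) and the non-volatile ether extract (Soxhlet
extraction; the numbing amides), both as percent of dry pericarp mass:

* `volatile_oil_content()`: T = V/M × 100, with V the distilled oil
  volume (mL) and M the sample mass (g; 20.00 g in the protocol).
* `ether_extract_content()`: X = (m₂ − m₁)·100/m₀ · 100/(100 − H), the
  extract mass as percent of sample mass m₀, corrected to dry mass by
  the water content H (%).

`group_summary()` reports arithmetic means per cultivar or species, both
at full precision and rounded to two decimals. Rounding is half away
from zero, the commercial convention of the source tables (base R's
`round()` would turn 12.775 into 12.78 or 12.77 depending on binary
representation; a fixed convention keeps reported values reproducible).
The packaged 47-batch table (`table1_path()`) carries its original
degree-minute-second coordinate strings; `parse_dms()` reads them
tolerantly because field tables mix prime and double-prime notation.

`one_way_anova()` is the classic between/within decomposition (via
`stats::aov()`), run per content at batch level. The degenerate
all-identical input returns F = 0, p = 1 instead of erroring, so that
screening loops need no special-casing. `chem_pca()` is an SVD-based
PCA on the centered (optionally unit-scaled) batches × features matrix.
The sign of each loading vector is fixed so its largest-magnitude entry
is positive, which makes scores platform-independent.

One ambiguity is worth stating openly: the published PCA shows
three-dimensional score plots per content variable, but the batch table
carries only two content columns, so the exact feature matrix behind
those plots is not recoverable. `chem_pca()` therefore accepts any
batches × features matrix, and the pipeline default uses the two
standardized content columns. On that default input the two standardized
contents are nearly uncorrelated (r = 0.07), so the leading component is
close to an (oil + ether) average and per-batch sign separation of the
species is weak; the species signal sits on the oil-ether *contrast*
component, where the species centroids differ strongly (t-test
p < 0.001) even though individual ZB batches overlap the ZA range. The
tests assert exactly this computed behaviour rather than a cleaner
separation the two-column input cannot deliver.

## ITS2 barcode analysis

All sequence analysis operates on an aligned set
(`aligned_seq_set()`) over A/C/G/T/N and the gap character; other
ambiguity codes are rejected at construction because the intended inputs
are clean Sanger consensus sequences trimmed to ITS2 (annotation and
alignment are upstream of this package).

**Distances.** `k2p_distance()` implements the Kimura 2-parameter model:
with P and Q the transition and transversion fractions over usable
sites, d = −½ ln[(1 − 2P − Q)·√(1 − 2Q)]. Sites holding a gap or N in
either sequence of a pair are dropped for that pair only (pairwise
deletion, the common default of barcoding software). When the log
argument is non-positive the pair is saturated; the value is returned as
`NA` flagged with a `saturated` attribute rather than a silent `NaN`,
and tree construction refuses saturated matrices explicitly.

**Trees.** `nj_tree()` is Saitou–Nei neighbor joining with the standard
Q-criterion. Two choices make it deterministic and well-behaved:

* ties in the Q-criterion are broken on the lowest index pair, so the
  output is a pure function of the input matrix;
* negative branch lengths are clamped to zero with the excess
  transferred to the sister branch, which preserves path lengths between
  taxa.

On any additive matrix this recovers the generating tree's topology and
path lengths exactly (tested against `ape::cophenetic.phylo()` on random
4–8 taxon trees, and against `ape::nj()` on perturbed matrices).
`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and reports the percentage of
successful replicates containing each internal bipartition of the
full-data tree (bipartition counting via `ape::prop.clades`). Replicates
whose resampled alignment saturates are skipped and counted. Identical
sequences are collapsed before the per-replicate distance computation —
an exact shortcut, since duplicated rows yield duplicated distances.

**Diagnostics.** `diagnostic_sites()` reports 1-based alignment columns
where one group is fixed for a state absent from every other group. A
diagnostic column is classed as an *indel* site when the contrast
involves the gap state; the insert-carrier case (one group fixed for a
base where all others are fixed for gaps) is attributed to the carrier
group, which is how an insert unique to one species is conventionally
described. N is treated as missing. `gap_analysis()` flags, per species,
whether the minimum interspecific distance exceeds the maximum
intraspecific distance (the barcoding gap), with singleton species
flagged undefined rather than silently dropped.

## Synthetic data generators

The generators exist so every downstream stage can be tested against
planted truth, offline.

**Chemistry** (`gen_chem_table()`): Gaussian batches around per-cultivar
means (defaults are the packaged table's cultivar means), truncated at
zero, in the exact column layout of the packaged table.

**Barcode** (`gen_barcode_set()`): one ancestral sequence of length 225
(within the observed 222–227 bp span) with an exact GC count at the
70% target; species differ from it only at planted positions. Defaults
plant the four *Z. bungeanum*-unique substitution sites at alignment
positions 105, 191, 197, 203 and the three *Z. armatum*-unique insert
columns at 29, 165, 215 (represented as gaps in every non-carrier
species — an insert in the carrier and a deletion elsewhere are the same
alignment object, so the orientation choice is free). Planted
substitutions are realised as transitions whose ancestral state is the
transition partner of the planted base; this keeps the realised GC at
the target and guarantees species differ exactly where planted. A
Toddalia asiatica-like outgroup with six private substitutions is
included by default: with only two species every indel column would be
mutually diagnostic and the per-species attribution of the planted
positions would be ambiguous. Within-cultivar divergence defaults to 0
(all cultivars of a species share one haplotype, the published pattern);
setting it per cultivar (e.g. `c(ZB3 = 0.02)`) reproduces the published
exception in which *Z. bungeanum* loses its barcoding gap. Specimen
counts per cultivar are not published; the default is 5 per cultivar and
3 for the outgroup, exposed as a parameter.

The generator does not emulate real ITS2 secondary structure, rate
heterogeneity across sites, or sequencing error — so passing tests show
the analysis machinery is correct on alignments with the published
summary structure, not that the marker itself behaves this cleanly in
new field samples.

**Ecology** (`gen_eco_rasters()`): each factor field x1–x10 is
Gaussian-filtered white noise (filter sigma = the autocorrelation length
in cells, default 5) rescaled to plausible southwest-China ranges
(elevation 200–3500 m, mean annual temperature 8–20 °C, annual
precipitation 600–1400 mm, ...; see `default_factor_ranges()`). The
categorical soil layer x11 is a smoothed field cut into four classes.
January minimum is forced ≤ January mean and July mean ≤ July maximum
after rescaling. Sites are uniform in the extent — no real geography is
claimed — and contents are planted linear responses to the standardized
factors plus Gaussian noise (sd 0.5% by default), with signs mirroring
the reported correlation directions (`default_true_coefficients()`).
Default grids are 60 × 80 cells of 0.1°; tests use 25 × 30 where only
the structure matters, and the test/vignette problem sizes are stated
here as the package's own choices.

## PLSR with VIP scores

`nipals_plsr()` is classical single-response NIPALS on standardized X
and y: per component, weight w ∝ Xᵀy (unit norm), score t = Xw,
loadings by least squares, then deflation of X and y. Coefficients are
assembled as b = W(PᵀW)⁻¹q. The inner iteration uses a residual
tolerance of 1e-10 and a 500-iteration cap (for a single response the
iteration is stationary after one pass; the cap guards the general
contract). With all components the fit equals ordinary least squares,
which the tests use as an independent oracle.

`vip_scores()` implements VIP_j = √(p·Σₐ w²ⱼₐ SSYₐ / Σₐ SSYₐ) with
SSYₐ = qₐ²tₐᵀtₐ, so ΣVIP² = p identically. `classify_factors()` applies
the three published tiers: VIP > 1 most significant, 0.5 ≤ VIP ≤ 1
significant, VIP < 0.5 unimportant. The published wording is ambiguous
at the boundaries; exactly 1 and exactly 0.5 are assigned to the lower
tier here, stated once and kept.

Choices the published analysis leaves open: the number of latent
components is never stated (the analysis was run in SIMCA-P), so the
default is A = 2 — a common SIMCA default for small collinear designs —
with `select_ncomp_loo()` available for leave-one-out selection, and A
exposed everywhere. The soil type x11 is categorical and excluded from
regression (only x1–x10 are regressed; soil enters the habitat stage
instead). One model is fitted per species × response; no pooling. The
published VIP values themselves (1.32, 1.80, 0.43, ...) are not
reproducible without the unreleased per-site factor table, so the tests
check the identities, the OLS equivalence, and planted-sign recovery on
synthetic data at three noise levels instead.

## Habitat suitability

The published habitat prediction used a closed GIS program whose
similarity formula is unpublished; this module is an openly specified
surrogate with the same observable behaviour class (graded 0–100
similarity bands around the envelope of the sample sites).

`build_envelope()` takes, per numeric factor, the [min, max] over sample
sites, plus the set of observed soil classes. `membership()` is
trapezoidal: 1 inside the envelope, linear decay to 0 over a margin of
τ·(hi − lo) on each side (τ·|lo| for degenerate envelopes), 0 beyond.
τ defaults to 0.1 and τ = 0 recovers a crisp BIOCLIM-style box — the
tests exploit this as an oracle. `similarity_index()` aggregates
memberships as a weighted arithmetic mean (×100); a minimum combination
is also available (`combine = "min"`), but the mean is the default
because a minimum collapses SI to the worst single factor and cannot
produce the graded 95–100% bands the method is meant to map. Factor
weights default to equal; VIP scores are a natural alternative. Soil can
be averaged like any factor (default) or applied as a hard constraint
(`soil = "hard"`), since whether the original program treats soil as
exclusionary is unknown.

`si_band_mask()` uses inclusive bounds on both ends, matching the
"95~100%" band notation. Areas are spherical (R = 6371 km):
a cell contributes R²·Δλ·(sin φ_top − sin φ_bottom), the exact
spherical-rectangle area, so equal-degree cells shrink toward the poles;
the error against an ellipsoid is far below other uncertainties at these
latitudes. Grids are cell-edge anchored in the ESRI ASCII convention,
read and written by `read_ascii_grid()`/`write_ascii_grid()`.
`overlay_intersection()` reports |A∩B|/min(|A|,|B|) per mask pair, and
`region_summary()` aggregates suitable area over any categorical region
layer. The published national maps, the 185,506 km² total and the
293-county listing depend on the authors' national climate/soil
databases and are out of reach by design; the acceptance checks for this
stage are property-based (SI = 100 at training sites, monotonicity in τ
and in the band bounds, crisp-envelope equivalence at τ = 0, the exact
equatorial cell area, and disjoint- versus shared-niche overlap
patterns).

## Pipeline and reproducibility

`run_pipeline()` executes chem → barcode → ecology → habitat from a
`pipeline_config()`. A single master seed is expanded into fixed
per-stage offsets so that disabling one stage never shifts another
stage's random stream. The manifest (`manifest.json`) records the
package version, seed, parameters and an MD5 per output file — and
contains no timestamps, so two runs with the same configuration are
byte-identical, which is exactly what the determinism tests assert. The
habitat stage of the pipeline splits the generated sites at the median
mean-annual-temperature into a warm and a cool niche group as a stand-in
for the two species' niches; the dedicated disjoint-niche analyses in
the tests use quartile splits for stronger separation.

## Known limitations

* The chemistry PCA input is the published table's two content columns;
  the original three-component score plots cannot be reconstructed from
  published data.
* K2P and NJ are the only substitution model and tree method offered —
  matching the source analysis, not a model-selection exercise.
* The fuzzy membership functional form is this package's choice
  (trapezoidal); any program with a different unpublished form will
  differ near envelope edges, though both agree at τ = 0.
* Synthetic rasters are statistically, not geographically, realistic;
  computed areas are internally exact but not comparable to national
  figures.
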