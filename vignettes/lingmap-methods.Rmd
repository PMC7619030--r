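---
title: "Methods: retrieving station layouts from distributional semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrieving station layouts from distributional semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingmap)
```

## The problem and the measurement model

A distributional semantic model assigns each word a vector whose geometry
reflects co-occurrence patterns in a corpus. The working hypothesis of this
pipeline is that, for landmarks inside a city (underground stations), that
geometry partially encodes physical position: station names used in similar
spatial contexts acquire similar vectors. Two derived quantities carry the
analysis.

**Linguistic distance.** For a station pair with vectors $v_j$, $v_k$,
$d_{\mathrm{ling}} = 1 - \cos(v_j, v_k) \in [0, 2]$. Zero means positively
collinear vectors, 2 antipodal ones. This is paired with the great-circle
distance in kilometres and modelled with a linear mixed model in which the
two stations of the pair enter as *crossed random intercepts*:

$$\mathrm{geo\_km} \sim \mathrm{ling\_dist} \times \mathrm{city}
  + (1\,|\,\mathrm{station}_1) + (1\,|\,\mathrm{station}_2).$$

The crossed intercepts absorb per-station idiosyncrasies (a station with a
polysemous or very frequent name shifts *all* of its pairs), which is what
makes the per-pair slope interpretable.

**Linguistic coordinates.** With anchor vectors for the four cardinal
direction words of the city's language,
$\mathrm{ling\_lat}(k) = \cos(v_k, v_{\mathrm{north}}) - \cos(v_k, v_{\mathrm{south}})$
and analogously for longitude with east/west. Being differences of two
cosines these lie in $[-2, 2]$; positive values indicate a linguistically
northern (eastern) position. They are regressed on city-level z-scored
geographic coordinates in ordinary interaction models
($z(\mathrm{geo\_lat}) \sim \mathrm{ling\_lat} \times \mathrm{city}$), so a
city contributes only its *internal* north–south ordering, not its absolute
latitude.

**Schematic maps.** Digitized map pixels are calibrated to the geographic
frame by a least-squares affine transform fitted on control stations
(exact interpolation with three non-collinear controls; least squares
beyond). Map-based pair distances then enter the same crossed mixed model
against geographic distance, and map coordinates are compared to
geographic ones by Pearson correlation.

## Label resolution and subword composition

Lookups are byte-exact: no case folding, no Unicode normalization, internal
spaces preserved ("Elephant & Castle" is one token). A label missing from
the embedding store can be composed fastText-style from its character
n-grams: the label is wrapped as `<label>`, all substrings with length in
`[minn, maxn]` (default 5–5) are enumerated shorter-first and
left-to-right, each is hashed with 32-bit FNV-1a (offset basis 2166136261,
prime 16777619) modulo the bucket count, and the bucket vectors are
**summed**. The sum rather than the mean is deliberate — every downstream
quantity is a cosine, which is invariant under positive rescaling, so the
two aggregates are equivalent there; `oov_vector(..., agg = "mean")`
exists for dot-product uses. The wrapped whole word is *not* added as an
extra token: only n-gram buckets are modelled. A label too short to
produce any n-gram yields the zero vector with a warning, and every
cosine consumer rejects zero-norm vectors with an explicit error rather
than a silent `NaN`.

## Parameters that matter

| Parameter | Default | Units / domain | Why |
|---|---|---|---|
| `radius_km` | 6371.0088 | km | IUGG mean Earth radius; the haversine sphere. Exposed because geographic packages differ in their spherical conventions. |
| `minn`, `maxn` | 5, 5 | characters | Subword n-gram lengths; 5 matches the embedding spaces this pipeline targets. |
| `oov_agg` | `"sum"` | sum/mean | See above; cosine-equivalent. |
| `contrasts` | `"sum"` | sum/treatment | Sum-to-zero coding makes the coefficient-block F/χ² tests marginal (Type-III-style); treatment coding is available for coefficient-level replication. Simple slopes are computed as linear contrasts and are invariant to this choice. |
| `map_mode` | `"planar"` | planar/lonlat-compat | Planar Euclidean distance is the defensible metric for a schematic image. `lonlat-compat` feeds map X/Y into the great-circle routine as lon/lat, mirroring analyses that ran geographic distance code directly on digitizer output; its scale is arbitrary, so only standardized or correlational outputs should be compared in that mode. |

Anchor words per language ship as editorial defaults (`north/south/east/
west`, `norden/süden/osten/westen`, `norte/sur/este/oeste`, `nord/sud/est/
ovest`, `nord/sud/est/ouest`), queried lowercase, and are overridable via a
JSON table — both the word choice and their capitalization are analysis
decisions, not constants of the method.

## The synthetic generator

`generate_city()` places `n_stations` uniformly on a square of half-width
`extent` (degrees) about `center`, with unique pronounceable labels, a
fraction `multiword_frac` of them two-word. `generate_embedding_space()`
draws three orthonormal latent directions $u_0, u_N, u_E$ in `dim`
dimensions and sets

$$v_k = \mathrm{normalize}\big(c\,u_0 + a_k(\lambda_k u_N + \varphi_k u_E)
  + \sigma\,\varepsilon_k\big),$$

where $\lambda_k, \varphi_k \in [-1, 1]$ are the station coordinates
rescaled by the extent, $\varepsilon_k$ is standard normal per coordinate
scaled by $1/\sqrt{\mathrm{dim}}$, and $a_k = \alpha$ except that with
probability `polysemy_prob` it is attenuated to $\alpha/10$ — the
polysemy-contamination stand-in: a contaminated name remains weakly
informative rather than spatially mute. Anchors are noisy antipodal copies
of the axes, $\mathrm{normalize}(\pm u_N + \tau\,\zeta)$ (with $\zeta$
scaled $1/\sqrt{\mathrm{dim}}$ like the station noise). The shared base
direction with weight $c$ (default 3) is essential: without it,
normalization erases radial information and cosine distance would encode
*direction* from the centre, not proximity — geographic distance would be
unrecoverable by construction.

Defaults (`n_stations = 120`, `dim = 50`, `alpha = 0.9`, `sigma = 0.05`,
`tau = 0.05`, `polysemy_prob = 0.1`, `extent = 0.15`°, Milan-like centre)
are the conditions under which the recovery experiments are run: a
network of around a hundred stations spanning ~0.3° with a strong but
imperfect spatial signal. A single root seed feeds named substreams
(city, space, anchors), so identical configurations are bit-identical and
components can be varied independently.

What the generator does **not** emulate: corpus frequency effects (rare
station names have noisier vectors in real spaces, uniformly noisy ones
here), the heavy-tailed geometry of real embedding spaces, correlated
polysemy (real contamination pulls a vector *toward* a specific other
meaning, not merely away from the spatial signal), and street-network
anisotropy in station placement. A pipeline that passes the recovery
tests is therefore shown to be *correct* (it recovers planted structure
of the assumed form), not shown to succeed on real corpora.

## Numerical choices

- **Mixed models** are fitted by lme4's profiled REML with `bobyqa`
  tightened to `rhoend = 2e-9`; at that tolerance the balanced one-way
  closed-form REML estimates are reproduced to better than $10^{-8}$
  relative, and the optimum is verified in tests against an independently
  coded dense REML deviance on a variance-ratio grid. Singular
  (boundary) fits are flagged, never errored; with both intercept
  variances at zero the fixed effects coincide with OLS.
- **Inference** is reported as Wald $z$/χ² on coefficient blocks, with a
  marginal likelihood-ratio alternative (REML fits are automatically
  refit by ML for the LRT, since REML criteria are not comparable across
  fixed-effect structures; the term's columns are dropped from the model
  matrix directly, so main effects are tested marginally even in the
  presence of their interaction). Satterthwaite-style denominator degrees
  of freedom are deliberately out of scope: at the sample sizes of
  interest (tens of thousands of pairs) the Wald/LRT and F versions are
  asymptotically equivalent, and the package documents this as its one
  inferential deviation from F-table reporting.
- **Pair enumeration** orders stations by C-locale lexicographic id; each
  unordered pair appears exactly once with `station_i < station_j`, so
  regeneration is deterministic.
- **Within-group z-scoring** uses the sample (n−1) standard deviation and
  refuses constant or singleton groups by name rather than emitting `NaN`.
- **Affine calibration** requires three non-collinear controls (rank
  check) and rejects singular fitted linear parts; the digitizer y-flip
  is absorbed by the linear part, so "north up" targets work with either
  y-axis convention.
- **Degenerate inputs** error early and specifically: zero-norm vectors,
  out-of-range coordinates, duplicate station ids, unresolvable labels
  (the offending label is named; the pair table is never partially
  emitted).

## Design decisions that were genuinely open

- **Recovery-strength metric.** The raw distance-model slope has units km
  per cosine-unit; because the spread of linguistic distances itself
  grows with the spatial-signal weight α, the raw slope is non-monotone
  in α by construction (it peaks at low α and decays roughly as
  $1/\alpha^2$ once signal dominates). Signal-response properties are
  therefore stated on the standardized slope, which is scale-free and
  monotone; the sweep is run at σ = 1, away from the recovery ceiling.
- **Distance-by-type standardization.** In the map-comparison model the
  geographic and map distances are z-scored *within type* before
  stacking, so the type factor tests shape rather than scale.
- **Problem sizes.** The suite verifies variance-component recovery on
  200 replicates of a fully crossed 60×60 design, null calibration on 100
  seeds of 60-station cities, and signal monotonicity on 50 seeds of
  40-station cities — sizes at which Monte-Carlo error is small relative
  to the tested effects while the whole suite stays fast.

## Known limitations

- Only cosine-based quantities are supported; the store does not track
  whether vectors were length-normalized (irrelevant for cosine, relevant
  for any future dot-product statistic).
- One interacting factor and at most two random-intercept factors; no
  random slopes, no non-Gaussian responses.
- `lonlat-compat` map distances are meaningful only up to a monotone
  scale transformation.
- Anchor words are single words; composite anchors (synonym sets,
  diagonal directions) are not modelled.
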