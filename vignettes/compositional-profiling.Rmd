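---
title: "Windowed GC and repeat profiling of soft-masked assemblies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed GC and repeat profiling of soft-masked assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcprofiler)
```

## The problem

Classical chromosome banding (G-, R-, Q-banding) yields no usable
pattern on most fish chromosomes, which are small and compositionally
homogeneous compared with mammalian ones. Chromosome-level assemblies
offer a computational substitute: scan each assembled chromosome in
fixed windows and read base composition and repeat annotation directly
from the sequence. The substrate is the soft-masking convention used by
the public genome databases — repetitive DNA in lowercase, everything
else in uppercase — so a single case-preserving pass yields both GC
content and repeat density, plus GC content *within* each of the two
fractions, which is what distinguishes a fish-type landscape (GC-rich
repeats homogenising the profile) from a mammal-type one (GC-rich
gene-dense peaks, GC-poor repeats).

## The windowed composition model

Each sequence of length $L$ is tiled by consecutive, non-overlapping
windows of nominal size $w$ (window $k$ covers 1-based positions
$(k-1)w + 1 \dots \min(kw, L)$), giving $\lceil L/w \rceil$ windows.
Within a window, let $U_b$ and $M_b$ be the counts of uppercase and
lowercase base $b \in \{A, C, G, T\}$. The counted denominator is
$n = \sum_b (U_b + M_b)$; every other character (N of either case,
IUPAC ambiguity codes, gaps) is excluded from numerator *and*
denominator. Then

$$\mathrm{GC\%} = 100\,\frac{U_G + U_C + M_G + M_C}{n}, \qquad
\mathrm{rep\%} = 100\,\frac{\sum_b M_b}{n},$$

$$\mathrm{GC\%_{masked}} = 100\,\frac{M_G + M_C}{\sum_b M_b}, \qquad
\mathrm{GC\%_{unmasked}} = 100\,\frac{U_G + U_C}{\sum_b U_b},$$

each defined only when its denominator is positive. Overall GC% is by
construction the counted-base-weighted mean of the two fraction GC%
values, a conservation identity the test suite checks window by window.

Conventions, each chosen once:

* **Trailing window.** Emitted, with percentages over its actual
  residues. Dropping it would lose data; padding would bias it.
* **Missing values.** A window with $n = 0$ (gap runs) is emitted with
  missing percentages — never silently dropped, so the positional
  tiling stays exact and row $k$ of every table is always window $k$.
  Missing windows are excluded from plots and correlations.
* **Coordinates.** Internal arithmetic is 0-based half-open; emitted
  tables carry the 1-based window ordinal and 1-based `start_bp`, both,
  because "position" alone is ambiguous across toolchains.
* **Precision.** Full double precision internally; tables round
  percentages to 3 decimals, lossless in practice for $w \le 10^4$
  since window percentages are ratios of small integers.
* **Case is the only mask signal.** Lowercase of *any* letter counts as
  masked (so a lowercase `n` counts toward the masked-base tally of a
  record but never toward any percentage).

Counting is delegated to `Biostrings` (`Views` over a case-preserving
`BStringSet` plus case-sensitive `letterFrequency`), which makes the
55 Mbp-chromosome case a sub-second profiling operation; the test suite
validates it against an independent pure-R per-character oracle on
hundreds of random mixed-alphabet sequences at $w \in \{1, 7, 1000\}$.

## Window size

The default $w = 1000$ bp resolves the repeat architectures typical of
teleost-sized (~1 Gbp) genomes; 3 kb suits genomes roughly three times
larger (polyploid fish, mammals) at matching visual scale; 10 kb is for
extreme downsizing or very large genomes. Any $w \ge 1$ is accepted —
the three values are documented presets, not limits. One property worth
knowing: GC% at $3w$ equals the counted-base-weighted mean of the three
constituent $w$ windows, so coarse profiles are exact aggregations, not
re-estimates.

## Storage

One CSV per chromosome (`<assembly>/<record_id>.w<window>.csv`):
`#`-prefixed metadata lines (record id, record length, window size,
assembly, tool version), one header row, then one row per window.
Comma separator, `.` decimal point, Unix line endings, missing values
as the literal `NA` — fixed so round trips are bit-exact and
distinguishable from true 0% values. Reads validate the column set and
the row count against `ceiling(record_length / window_size)`; a
truncated file is an error, not a shorter profile. For plotting,
tables are ordered by data-row count (descending, ties by record id),
i.e. longest chromosome first.

## Plotting

The plot is a point cloud: one point per informative window, $x$ = the
window's start position, $y$ and color carrying the two measures. Two
modes:

* **Default (`gc_on_y`)** — $y$ = GC% on a fixed 0–100% axis, color =
  rep% through the repeat scale, anchored at (0%, red 255,0,0),
  (50%, orange 255,165,0), (100%, green 0,170,0), linear per RGB
  channel between anchors. The named color roles are the contract; the
  exact RGB values are package constants, user-overridable.
* **Swapped (`rep_on_y`)** — $y$ = rep%, color = GC% through a scale
  running green (0,170,0) at 30% GC to red (255,0,0) at 60% GC,
  clamped outside. The 30–60% clamp brackets the GC range fish
  chromosomes actually occupy, and the red-high/green-low polarity
  makes the rendering mimic CMA3/CDD fluorescence banding.

Panel width is `record_length / bp_per_pixel` (by default scaled so the
longest chromosome spans 10,000 px), so within one assembly chromosome
sizes stay visually comparable. Every render also writes the plotted
point list (x, y, RGB) as a TSV sidecar per panel; that sidecar is the
deterministic, machine-checkable artifact the tests assert on, while
the PNG raster is smoke-tested only (its pixels depend on the graphics
stack). Rendering never mutates profiles.

## The GC–repeat association

Per assembly, all windows of all chromosomes are pooled
(pairwise-complete over GC% and rep%) and summarised by the sample
Pearson coefficient $r$ with the two-sided $p$ from the $t$
transformation on $n - 2$ degrees of freedom (`stats::cor.test`).
Pooling rather than averaging per-chromosome coefficients matches the
one-value-per-species granularity the statistic is used at; the pooled
$r$ is invariant to chromosome order and to how the windows are split
into records. Degenerate inputs are explicit errors: fewer than 3
complete pairs, or zero variance in either measure (e.g. an entirely
unmasked genome), are reported as such rather than surfacing as `NaN`.
Displayed $p$-values floor at `1e-16`. The companion
`compensation_summary()` applies the same machinery to the two
*fraction* GC% series, quantifying whether repeat GC rises where
unique-DNA GC falls (the fish-type homogenisation) or stays below it
(the mammal-type contrast); a zero-variance fraction flags the
correlation as undefined instead of reporting a number.

## Synthetic assemblies

The generator builds chromosomes from ordered segments, each with a
length, a per-base GC probability, and a mask state (lowercase repeat,
uppercase unique, or an N run). G vs C and A vs T are uniform within
their class — strand asymmetry is deliberately out of scope. Segment
boundaries sit at exact offsets, so every window-level expectation is
available in closed form (`expected_window_composition()`), and the
same spec plus seed reproduces the FASTA byte for byte while a
different seed changes only the bases, never the case/N architecture.

What it emulates: chromosome-scale mask architectures (telomeric
blocks, interstitial blocks, dispersed repeats, low-repeat compact
genomes, mammal-like GC peaks over a mixed background), segment-wise GC
levels, gap runs, multi-record assemblies up to hundreds of Mbp. What
it does not: actual repeat sequence (no transposon models — only case
structure matters here), GC gradients within segments, strand bias,
masking errors. Passing tests therefore demonstrate that the profiler
measures designed composition correctly, not that any biological
interpretation of a real genome is right — on real data the profile is
only as good as the assembly's repeat masking.

Preset scale: chromosomes default to 0.75–3 Mbp — deliberately a
scaled-down stand-in for real 15–150 Mbp chromosomes, large enough for
thousands of windows per chromosome yet quick to generate; a `scale`
argument grows them when realism matters more than speed. Fish-like
presets give masked segments GC at or slightly above the unmasked
background (0.44–0.46 vs 0.41–0.42, matching the homogenisation
observation); the mammal-like preset uses 500 bp repeat/unique
alternation (so both fractions coexist within every 1 kb window) under
sharp unmasked 60%-GC peaks.

### Designing a target correlation

`correlated_genome_spec()` constructs per-window (GC probability,
repeat fraction) pairs whose *sample* correlation equals the target
$\rho$ exactly: both marginals start as permutations of a centred
uniform grid (bounded by $\sqrt{3}$ standard deviations, so the linear
maps into probability space can never clip — clipping would leak
correlation), the second is orthogonalised against the first, and the
pair is recombined as $y = \rho x + \sqrt{1 - \rho^2}\,e$. Each window
then becomes a masked run of `round(rep_frac · w)` bases followed by an
unmasked run, both at the window's GC probability, so realised rep% is
exact up to 1 bp rounding while realised GC% fluctuates binomially.
That fluctuation attenuates the observable correlation by the factor
$\sigma_{\text{design}} / \sqrt{\sigma_{\text{design}}^2 + p(1-p)/w}$;
with the default design spread of 8 GC points and $w = 1000$ this is
about 0.98, predictable in closed form and well inside the ±0.03
recovery band checked at $n = 20{,}000$ windows (where the sampling
standard error of $r$ is ~0.007).

## Problem sizes in the checks

The package's own acceptance checks run at: one 55,410,000 bp
chromosome at $w = 1000$ (exactly 55,410 windows — the largest northern
pike linkage group, the canonical sizing example); 200 random
mixed-alphabet sequences of 1–100,000 bp against the brute-force oracle
at $w \in \{1, 7, 1000\}$; all five presets (~25 Mbp total) for exact
mask-structure recovery and 4-binomial-SD GC recovery pooled per
designed composition class; and three 20,000-window assemblies with
designed $\rho \in \{-0.3, 0, 0.2\}$ — the magnitude regime reported
for real species, where fish sit at weakly positive $r$ and mammals at
weakly negative. Species-specific $r$ values from real genomes require
the actual assemblies and are intentionally not reproduced here.

## Retrieval

`fetch_assembly()` is a convenience: it resolves a species against
configurable path templates (Ensembl- or NCBI-style layouts), insists
on the soft-masked (`sm`) artifact — hard-masked files are rejected
because N-replacement destroys the mask signal — verifies a non-empty
transfer, decompresses in place, and skips complete local files. No
analysis depends on it, and its tests run against a local `file://`
mirror of the layout.

## Known limitations

* Repeat classes are invisible: soft-masking carries no Class I/II
  labels, so per-class GC% cannot be computed from FASTA alone.
* Centromere positions are not inferred or drawn.
* No overlapping/rolling windows; the tiling is the model.
* The pooled correlation is descriptive; no phylogenetic correction is
  applied across assemblies.
* Streaming is per-record: one chromosome is held in memory at a time,
  adequate for desk-scale use up to the largest vertebrate chromosomes.
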