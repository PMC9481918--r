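---
title: "Model and methods: guide-abundance inference for in vivo graft survival screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: guide-abundance inference for in vivo graft survival screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletscreen)
```

## The experiment this package models

A genome-wide CRISPR knockout library (Brunello-like: ~19,000 genes at
four guides per gene, plus ~1,000 non-targeting and intergenic control
guides) is transduced into stem-cell-derived islet cells at MOI < 1, so
that most transduced cells carry a single perturbation. The pool is
transplanted under the kidney capsule of immunodeficient MHC-null mice;
half of the cohort then receives allogeneic human PBMCs (the "hPi"
condition) whose T cells attack the graft, while the other half serves as
an unchallenged control. After graft failure, guide abundance is read out
by amplicon sequencing of genomic DNA from each graft.

Because grafted islet cells are post-mitotic, there is no outgrowth phase:
selection is a single episode of cell killing. A knockout that makes cells
easier to tolerate (e.g. loss of antigen presentation) leaves relatively
more of its cells alive in hPi grafts; a knockout that sensitizes cells
leaves fewer. The analysis must separate these per-gene effects from two
large nuisance processes: a *global* depression of all counts in hPi
grafts (most cells die regardless of genotype) and heavy per-mouse
sampling noise from the engraftment bottleneck (each graft is founded by a
random subsample of the pool).

## The gene-level statistic

For gene $g$ with guide set $G_g$ (typically four guides) and the
non-targeting (NT) guide set $N$, counts are summed ("integrated") across
all mice of a condition, and the gene's abundance is expressed relative to
the integrated NT counts of the same condition:

$$
L_g \;=\; \log_2\frac{\left(\sum_{i \in G_g}\sum_{s \in \mathrm{hPi}} c_{is} + pc\right)\big/\left(\sum_{i \in N}\sum_{s \in \mathrm{hPi}} c_{is} + pc\right)}
                     {\left(\sum_{i \in G_g}\sum_{s \in \mathrm{ctrl}} c_{is} + pc\right)\big/\left(\sum_{i \in N}\sum_{s \in \mathrm{ctrl}} c_{is} + pc\right)}
$$

Anchoring on NT guides cancels sequencing depth and the global rejection
thinning, because NT-carrying cells experience exactly the same
environment minus a gene effect. $L_g > 0$ means the knockout is
*protective* (enriched under immune attack), $L_g < 0$ *sensitizing*.
The pseudocount $pc$ (default 1, applied to each of the four sums) keeps
the statistic finite when rejection drives hPi counts to zero; at the
integrated-count magnitudes involved (hundreds to tens of thousands of
reads) its bias is negligible. Summing raw guide counts before forming
ratios is the primary integration rule; a robust alternative (median of
per-guide log2 fold changes) is available via
`gene_log2fc_all(..., method = "median_guide")` for sensitivity analysis.
Counts are pooled across mice by default; per-mouse modeling is available
through the per-guide fits described below.

Guides with zero reads in every sample are dropped (with a logged list)
and genes keep an `n_guides` column, so a three-guide gene is computed,
not rejected. Genes can be restricted to an expressed-gene list supplied
by the user (in the motivating experiment roughly 12,000 genes expressed
in the grafted cells); the threshold defining "expressed" is deliberately
an input, never computed here, since it belongs to the transcriptomic
side of the study.

## Empirical null and FDR

No parametric null for $L_g$ is trustworthy under bottleneck noise, but
the design carries its own: control guides. `build_empirical_null()`
repeatedly samples `set_size` NT guides without replacement, scores the
pseudo-gene against the *remaining* NT guides with the identical formula,
and collects the statistics. This captures guide-level sampling noise,
the engraftment bottleneck, and sequencing overdispersion under no
selection. Two-sided empirical p-values are computed around the null
median with the add-one permutation correction,
$p = (\#\{|L^0_i - m| \ge |L_g - m|\} + 1)/(n + 1)$ — two-sided because
the screen reports both enriched and depleted tails (a one-sided option
exists). Benjamini–Hochberg adjustment then controls the FDR. With 100 NT
guides and 1,000 draws the p-value floor is ~0.001; screens with more
controls support proportionally deeper tails.

The excluded-anchor detail matters at small control pools: scoring a
pseudo-gene against an anchor that contains it would shrink the statistic
toward zero and make the null anti-conservative.

## Per-guide "full model" fits

For replicate-level displays, `fit_guide_nb()` models one guide's counts
across mice as negative binomial with a log link, a condition effect, and
offset $\log f_s$, where $f_s$ are control-anchored size factors
(median-of-ratios over control guides, geometric mean 1; if every control
guide contains a zero the method falls back to total-control-count ratios
with a warning). For a single two-level factor the mean structure's
maximum-likelihood point estimates equal the Poisson GLM solution
(offset-weighted group means), so coefficients come from a Poisson fit
and the NB dispersion $\alpha$ is then estimated by method of moments on
the residuals, floored at $10^{-6}$. With six animals per arm a
mean–dispersion trend across guides would be underdetermined, so no
shrinkage is attempted — a deliberate deviation from heavier RNA-seq
machinery, documented rather than hidden. Non-converged fits are flagged
and excluded, never imputed.

## The synthetic screen generator

`simulate_screen()` composes the generative stages the statistics assume:

1. **Transduction** — integrations per cell are Poisson(`moi`); cells
   with none are unselected, cells with two or more are *discarded*
   rather than modeled, honouring the screen's single-perturbation
   design (the alternative, modeling co-infection interactions, buys
   realism the downstream statistics never use). Retained cells draw one
   guide uniformly.
2. **Engraftment bottleneck** — each mouse's founders are a multinomial
   subsample of the pool (`bottleneck` cells), one independent draw per
   animal.
3. **Selection** — control grafts pass through unchanged; hPi grafts
   binomially thin each guide's founders at
   $\min(1,\; r\,\theta_g)$, where $r$ is the global rejection survival
   and $\theta_g$ the gene's survival multiplier ($\theta = 1$ for
   controls). Selection acts once; no clonal growth.
4. **Sequencing** — negative binomial reads with per-sample expected
   depth scaled by the surviving-cell fraction, so hPi samples show the
   absolute count depression seen in real rejected grafts. An
   `equal_depth` flag disables the scaling for pure-composition
   experiments.

One master seed drives everything; each stage and each mouse runs under a
derived substream (`(master + 1000003 * stage) mod (2^31 - 1)`, with
interleaved stage indices per cohort), so enlarging a cohort never
reshuffles earlier animals and every output is bit-reproducible.

### Default and desk-scale conditions

Full-scale defaults in `sim_config()` mirror the motivating design where
stated: 19,114 genes × 4 guides, 941 NT + 59 intergenic controls
(76,456 targeting guides — the real pool holds 76,441 because a few genes
deviate from four guides per gene), MOI 0.5, six mice per condition. The
design does not state founder population size or sequencing depth;
defaults use round placeholders ($5\times10^5$ founders per graft,
$10^7$ reads per sample) chosen once as plausible for kidney-capsule
grafts and screen sequencing.

`scaled_config()` fixes the desk-scale study conditions used by the
package's own calibration and recovery analyses: 1,000 genes × 4 guides,
100 NT guides, six mice per condition, $r = 0.5$, and per-guide coverage
held at realistic screen levels (~150 transduced cells, ~12 founders per
mouse, ~500 reads per guide), with sequencing dispersion $\alpha = 0.1$,
typical of amplicon screen libraries. These sizes were fixed when the
generator was written and are not tuned.

### What the generator does and does not emulate

It reproduces the statistical structure the inference relies on: control
guides sharing the targeting guides' noise process, per-mouse bottleneck
variance, global condition-wide depletion, and overdispersed counts. It
does **not** emulate guide-efficiency differences, chromatin or
copy-number artifacts, xeno-GVHD, immune-cell dynamics, spatial graft
structure, or clonal growth. Passing recovery tests on simulated screens
therefore demonstrates that the inference is correct *for the stated
generative model*, not that any particular biological hit list is
reproducible — the latter depends on the deposited sequencing data, which
this package deliberately does not require.

## Hit intersection

Cross-assay evidence is combined by thresholded set intersection with
exact Venn-region accounting. Upregulated differential-expression sets
use strict thresholds `log2fc > 1` and `padj < 0.05` (boundary rows
excluded — the inequalities are strict by design); the screen circle uses
`L > 1` with no FDR gate by default, since the intersection rule is
defined by fold change alone (a `q_max` option exists). Gene symbols are
compared case-sensitively after whitespace stripping; alias mapping is
out of scope. When one assay contributes per-cell-type DE tables
(SC-α and SC-β), `merge_hit_sets()` pools them by union (default — a gene
upregulated in either endocrine population counts) or intersection; both
are exposed because the reporting choice is genuinely open.

## Numerical choices and degenerate inputs

* Ranking sorts by $L_g$ descending with lexicographic gene-name
  tie-break, making ranks a deterministic permutation.
* All file readers reject rather than coerce: malformed spacers, unknown
  classes, negative or fractional counts, and sheet/table mismatches are
  errors that name the offending line or ids.
* FASTQ guide counting is exact-match only, on the given strand (an
  optional reverse-complement scan exists), within a user-supplied search
  window; ambiguous multi-spacer reads are unassigned so the assignment
  partition always balances.
* Validation failures carry condition classes
  (`isletscreen_config_error`, `isletscreen_data_error`) so drivers can
  distinguish configuration mistakes from corrupt data.

## Problem sizes used in the package's own studies

The bundled analyses and checks run 20 null screens and 10
planted-effect screens at the desk-scale conditions above, 1,000
null draws per screen; each screen simulates ~2 million transduced cells
and 12 grafts and completes in well under a second on one CPU. These
sizes give stable estimates of the discovery fraction, false discovery
proportion and AUROC while keeping a full run in seconds.

## Known limitations

* The empirical null assumes NT guides are exchangeable with targeting
  guides absent selection; cloning or representation biases specific to
  targeting guides would violate this.
* FDR granularity is limited by `n_draws` and the control-pool size.
* The per-guide NB fit treats mice as independent replicates with a
  shared dispersion per guide; it does not model mouse random effects.
* Essentiality/dropout against the plasmid pool is out of scope: cells
  carrying essential-gene knockouts die before transplantation, and the
  design cannot (and does not try to) measure them.
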