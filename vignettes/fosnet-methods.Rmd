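---
title: "Methods: c-Fos connectivity networks and neurogenesis statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: c-Fos connectivity networks and neurogenesis statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

# The problem

Immediate-early-gene mapping treats the regional density of c-Fos-positive
cells (cells/mm²) as a proxy for recent neuronal activity. When a group of
animals performs the same task, regions whose densities rise and fall
*together across animals* are taken to be functionally coupled. `fosnet`
implements this group-level correlational connectomics together with the
companion statistics used in developmental neurogenesis studies: dentate
gyrus (DG) marker densities (doublecortin for immature neurons, BrdU for
proliferation, pyknotic nuclei for cell death), baseline-normalized
percent-change trajectories, factorial ANOVA with Student–Newman–Keuls
(SNK) post hoc tests, and the group-level correlation between DG network
degree and neurogenesis.

Because animal-level data of this kind is rarely deposited, the package
ships a first-class synthetic cohort generator: a stated world with planted
covariance and planted neurogenesis trajectories against which every stage
of the pipeline is testable.

# Connectivity model

For each group \(g\) (a treatment × age cell, males by default) with
\(n_g\) animals and \(R\) regions, the pipeline computes the Pearson
correlation \(r_{ij}\) of each unordered region pair across animals, its
two-tailed p-value from the exact t transform

\[ t = r\sqrt{\frac{n-2}{1-r^2}}, \qquad t \sim t_{n-2}, \]

and binarizes with a **dual threshold**: an edge requires \(p < \alpha\)
(default \(\alpha = 0.05\), i.e. a 95% confidence level) *and*
\(r \ge r_{\min}\) (default 0.8). The adjacency matrix is symmetric 0/1
with zero diagonal; node degree is the row sum and network density the
realized fraction of the \(R(R-1)/2\) possible edges. Isolated regions stay
in the denominator so densities are comparable across groups.

Numerical and policy choices:

* **Sign convention.** The default takes "r of at least 0.8" literally
  (positive correlations only); `sign_mode = "absolute"` is available. At
  the small n typical of these designs the choice is nearly moot: for
  \(n = 5\), \(p < 0.05\) already implies \(|r| > 0.878\).
* **Multiplicity.** No correction across region pairs by default, matching
  standard practice in this literature; a Benjamini–Hochberg switch exists
  (`p_adjust = "BH"`) but is off.
* **Degenerate pairs.** Zero-variance regions or pairs with fewer than 3
  pairwise-complete animals are *undefined*, carried as `NA` with a logged
  warning, and contribute 0 to the adjacency — never a silent 0 in the
  correlation matrix itself. Groups below 3 animals are a hard error.
* **Strictness.** \(p < \alpha\) is strict; \(r \ge r_{\min}\) is not
  ("at least"). Relaxing either threshold can only add edges (monotone),
  a property the test suite asserts.

# Quantification model

Per-section marker counts \(c_s\) with traced DG areas \(a_s\) (mm²) are
standardized as a **ratio of sums**, \(d = \sum_s c_s / \sum_s a_s\),
not a mean of per-section densities: the ratio of sums weights sections by
their area and is robust to unequal section sizes. Unilateral counting
conventions are absorbed by the area standardization; no hemisphere factor
is applied. A subject with zero total area is a hard error naming the
subject.

Percent change expresses each *animal* relative to the mean of its matched
baseline group:

\[ \mathrm{pc}_i = 100 \cdot \frac{d_i - \bar d_{\text{base}}}{\bar d_{\text{base}}}, \]

where the baseline is the same-treatment, same-sex, same-marker group at
the baseline age (default 4 weeks) — so a germ-free 8-week female is
normalized to germ-free 4-week females. Two open choices were resolved
here: (a) normalization is per animal against the baseline group *mean*
(per-animal values are what group SEMs require); (b) "respective" baseline
matches both sex and treatment. The mean percent change of every baseline
group is identically zero, which the suite asserts.

# Inference

**Two-way ANOVA.** Cohorts of this kind are unbalanced (cells of 3–11
animals), so the package computes Type-III (marginal) sums of squares with
sum-to-zero contrasts: each effect's SS is the increase in residual SS when
its columns are dropped from the full `~ A * B` model matrix. This matches
the conventional default of the commercial package such studies typically
use; in balanced designs it coincides with the classical decomposition and
conserves the total SS, which is tested to 1e-8. Effects are reported in
the `F(df_effect, df_error)` convention. Empty cells are a hard error.

**SNK post hoc.** Cell means are ordered; each pair is tested with the
studentized-range statistic
\(q = (\bar y_{(j)} - \bar y_{(i)})/\sqrt{MS_e/n_h}\), where \(n_h\) is
the harmonic mean of the two group sizes (a Tukey–Kramer-style adaptation
for unequal n; the stretch-k critical value comes from the studentized
range distribution with the ANOVA's error df). Testing is stepwise from
the widest stretch inward and a non-significant span *seals* every nested
comparison non-significant — the defining SNK coherence rule. At k = 2 the
test reduces to \(\sqrt 2\, t\) against the pooled error term, and with
equal n SNK is never more conservative than Tukey HSD; both identities are
tested, the critical values against an independent numerically integrated
studentized-range CDF inverted by root finding.

**Degree–neurogenesis correlation.** Network properties exist per group,
not per animal, so DG node degree is correlated with the group-mean DCX
density across groups (six male groups ⇒ reported as `r(4)` with
`df = points − 2`).

# The synthetic world

The generator's defaults are a single stated world, fixed before the
acceptance measurements and not revisited afterwards.

**Design.** Treatments control/germ-free × ages 4/8/12 weeks × sexes, with
the DCX-cohort group sizes (male 11/11/8 control and 11/11/6 germ-free;
females 5/5/4 in both lines); eight regions with DG focal. Cells below 3
animals are refused; below 5, warned.

**Region densities.** Per group, animal vectors are drawn from a
multivariate normal with a block-structured correlation matrix
(`within_block_r = 0.9`, `between_block_r = 0.1`, unit diagonal — verified
positive semi-definite before sampling, with the offending eigenvalue
reported otherwise), region means 150 cells/mm² and noise SD 40 cells/mm²,
truncated at zero with every clip event counted (truncation perturbs the
planted correlation, so it is surfaced, not hidden). The male block
layouts plant the qualitative connectivity pattern: the control DG block
shrinks with age (6 → 4 → 2 regions, a refining network), while the
germ-free DG block is fixed at 3 regions (initially sparser, flat with
age). Each group consumes an RNG stream derived by hashing its label with
the cohort seed, so adding a group never reshuffles another.

**Marker counts.** Each animal × marker gets 7–10 sections; areas are
Gamma-distributed with mean 0.35 mm² (a realistic traced DG area for a
40-µm section), and counts are Poisson around
`area × target × subject_effect` with a mean-one Gamma subject effect of
variance 0.06 (between-animal CV ≈ 25%) — i.e. negative-binomially
overdispersed integers. The target density is
`baseline × age_factor × offset` with baselines DCX 2400, BrdU 180,
pyknotic 20 cells/mm²; control age factors 1/0.55/0.30 (the established
sharp postnatal decline, strictly decreasing by construction); and
germ-free offsets 0.65 for 4-week males (deficit) and 1.9 for 8-week
females (elevation), which jointly delay the 4→8-week decline in germ-free
animals of both sexes. `dispersion = 0` selects a deterministic degenerate
limit (fixed areas, rounded counts) used to verify the planted
trajectories exactly.

**What the world does *not* emulate.** Real section-level spatial
structure, per-marker age profiles (one decline vector serves all three
markers, so the distinct pyknosis pattern — flat to 8 weeks, drop at 12 —
is not reproduced), exclusion/attrition, heteroscedasticity beyond the
multiplicative model, and the smaller c-Fos-cohort group sizes (one cohort
stands in for both assays). A green test therefore establishes that the
*pipeline* recovers what was planted under these assumptions — not that
the biological effect sizes are those of any real study.

# Known limitations and an honest red

The qualitative-pattern acceptance check asks that ≥ 80% of 200 simulated
cohorts jointly show a control age decline, a female group × age
interaction on the percent-change scale, and a positive DG-degree/DCX
correlation across the six male groups. At the frozen defaults the
measured rates are ≈ 1.00, ≈ 0.73 and ≈ 0.95, so the conjunction lands
near 0.70–0.75 and the criterion fails. The binding constraint is the
female interaction: with 5/5/4 females per cell and CV ≈ 25%, an
interaction driven by a 1.9× elevation in one cell has F(2,22) power of
only ≈ 0.74. A real cohort in which this interaction is clearly detectable
at these sample sizes must carry a larger effect-to-noise ratio than the
simulated default, but no stated magnitude justifies a specific larger
value, and inflating the
planted effect after observing the test outcome would turn a calibration
into a tuning exercise. The criterion is therefore left red, documented,
with the component rates printed by the test for inspection.

Other limitations: correlations are unconditional Pearson (no partial
correlations or covariate adjustment); networks are binary (no weighted
analysis); only degree and density are computed (no path-based metrics);
ANOVA assumes homoscedastic Gaussian residuals and the SNK procedure
controls error only in the stepwise sense.
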