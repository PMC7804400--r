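---
title: "Quantifying allele-specific expression with allele-discrimination qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression with allele-discrimination qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseqpcr)
```

## The measurement and its model

An allele-discrimination qPCR assay reads the two alleles of a
transcribed SNP on separate fluorescent channels (FAM and VIC). The
cycle threshold Ct is, to good approximation, linear in the log of the
starting template quantity: a template at relative quantity $q$
amplified with per-cycle efficiency $E$ crosses threshold at

$$\mathrm{Ct} = C_0 - \frac{\log_2 q}{\log_2(1+E)} + \delta_{\text{dye}} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

where $C_0$ anchors the scale, $\delta$ is an additive channel offset
(dye bias, applied to the FAM channel), and $\varepsilon$ is replicate
noise. This is the standard exponential-amplification relation; the
package's simulator implements exactly this model, which is what makes
every downstream stage checkable against closed forms. Reactions whose
Ct would exceed the cycle limit (default 40) never cross threshold and
are emitted as *undetermined* rather than clamped, matching real
instrument exports.

The within-well allelic ratio statistic is
$\Delta\mathrm{Ct} = \mathrm{Ct}_{FAM} - \mathrm{Ct}_{VIC}$.
Under the model, a FAM:VIC abundance ratio $r$ gives
$\Delta\mathrm{Ct} = -\log_2(r)/\log_2(1+E) + \delta$, i.e. the
measured quantity is $-\log_2 r$ plus assay-specific distortion. The
distortion is removed with an internal control that every ASE study
carries for free: heterozygous genomic DNA, whose true allele ratio is
exactly 1:1. The normalized statistic is

$$n\Delta\mathrm{Ct} = \Delta\mathrm{Ct}^{\text{cDNA}} -
\overline{\Delta\mathrm{Ct}}^{\text{gDNA}},$$

with the mean taken over all heterozygous gDNA replicates of the
assay. $n\Delta\mathrm{Ct} = 0$ is balanced expression; the fold
change is reported as $2^{|n\Delta\mathrm{Ct}|}$ with the direction
carried separately by an allele label ("A>G" etc.), which avoids
sub-unity fold ambiguity. The $2^{|\cdot|}$ reading is exact at
$E = 1$; at lower efficiency the same nΔCt corresponds to a slightly
larger true ratio, which is why fold-change interpretation assumes a
calibrated, near-perfect-efficiency assay (see the calibration
section).

Two structural properties follow from the definitions and are enforced
by the test suite: swapping the channel labels negates every ΔCt and
nΔCt and preserves every p-value, and adding any constant offset to
one channel of *all* wells (gDNA and cDNA alike) leaves nΔCt unchanged
— the normalization is precisely a dye-bias canceller.

## Statistical testing

Normality of ΔCt distributions is screened per group with the
Shapiro–Wilk test (groups of fewer than 3 values are skipped with a
note). The screen is reported but never switches the analysis: the
pipeline always uses the two-sided Mann–Whitney rank-sum test, the
appropriate choice given that the screen routinely rejects normality
for some assays. Two tests are run per assay: each cDNA sample's
replicate ΔCt values against a gDNA comparator, and — the assay-level
verdict — all cDNA replicates pooled against all gDNA replicates. ASE
is called if and only if the pooled p-value is at most α (default
0.05), with no multiple-testing correction across assays by default;
a consistency metric (the fraction of individually significant samples
sharing the pooled direction) is reported but does not gate the call.

The rank-sum implementation uses midranks for ties, the exact null
distribution when both groups are untied and $n+m \le 12$, and the
tie-corrected normal approximation with continuity correction
otherwise. The exact branch is certified against exhaustive
permutation enumeration for every untied input shape with
$n+m \le 10$; the approximate branch against the reference
implementation in `stats::wilcox.test()`. When every pooled value is
identical the p-value is 1 by convention and flagged.

The per-sample comparator is configurable because the natural phrase
"each cDNA sample against the mean of all gDNA samples" admits two
readings: a rank test needs a *set* as comparator, so the default
compares the sample's replicates against the pooled gDNA replicates;
`comparator = "means"` uses the per-sample gDNA mean ΔCt values
instead. Both are implemented; the pooled comparator is the default
because it uses all replicate-level information.

## Marker selection

`run_selection()` composes the filters in a fixed order: LD with the
lead SNP ($r^2 \ge 0.6$, inclusive), transcribed-region annotation
(coding or UTR; intronic and intergenic variants cannot be read in
mRNA), special-region exclusions (inversion-locus candidates, whose
assays are confounded by inversion haplotypes, and isoform-restricted
variants that would report a transcript subset), failed-assay
exclusion, a low-expression rule (an assay is dropped when strictly
more than 50% of its cDNA samples read Ct > 36, undetermined counting
as above), and a one-marker-per-(locus, gene) cap. Every input
candidate lands in exactly one of `selected` / `excluded` with a
reason code from a closed set.

Two deliberate design choices in the cap: first, when several proxies
survive for one gene the marker with maximal $r^2$ wins, with ties
broken coding-over-UTR and then by rsID — the marker closest in LD to
the causal signal is the most faithful reporter; a lead SNP that is
itself transcribed is always preferred outright. Second, the cap
operates per (locus, gene) pair rather than per locus, so a locus
whose lead SNP tags transcribed markers in two genes keeps one marker
for each; independent secondary association signals are exempt from
the cap entirely. The packaged fixture (`pd_candidates()`) encodes the
worked example: 22 candidates reduce to 13 markers in 12 genes.
Attributes that the source study did not print for its excluded
candidates (the inversion-locus proxy identities, their LD values) are
synthetic placeholders and are marked as such in the
`candidate_source` column; selection results for them depend only on
the exclusion flags, not on the placeholder values.

## Assay calibration

The mixture-series experiment checks an assay's ability to resolve
allelic ratios before it is trusted on cDNA: gDNA from the two
homozygotes is mixed at nine fixed ratios (4:1, 2:1, 1.5:1, 1.25:1,
1:1, 1:1.25, 1:1.5, 1:2, 1:4) in triplicate, plus one heterozygous
control for the 1:1 point. `fit_calibration()` regresses mean ΔCt on
$\log_2(\text{ratio})$ — the scale on which the model is linear — and
issues a PASS verdict only if all of: $|$slope$| \in [0.7, 1.3]$
(slope $-1/\log_2(1+E)$ is $-1$ at perfect efficiency and $-1.13$ at
$E = 0.85$, so the window covers realistic assays), $R^2 \ge 0.9$,
strictly monotone mean response, and a heterozygous-control mean
within two standard errors of the fitted value at ratio 1. The source
experiment judged this visually; the thresholds here are an explicit
codification chosen so that the analytic model passes at realistic
noise ($\sigma \le 0.2$ Ct) while flat or shuffled responses fail, and
all four are configurable. The het control participates only in QC,
never in the fit. On noiseless simulated series the fitted slope and
intercept recover $-1/\log_2(1+E)$ and $\delta$ to $10^{-9}$, which is
the package's internal consistency certificate between simulator and
calibrator.

## Genotype calling

Real instruments call genotypes from two-channel endpoint
fluorescence; the pipeline carries only Ct values, so
`call_genotype()` uses a deliberate simplification: a channel
undetermined (or beyond Ct 36) in every replicate while the other
amplifies is a homozygote; two amplifying channels with mean ΔCt
within ±1.5 Ct of the assay's dye-bias estimate is a heterozygote;
everything else is NO_CALL — never a forced call. The dye-bias
estimate is the median ΔCt of confidently bi-allelic gDNA samples,
computed once per assay; the median resists allelic-imbalance
outliers. The 1.5 Ct window sits halfway to the ~3 Ct shift that a
two-fold template difference between heterozygote and homozygote
produces. The rule's adequacy is certified against the simulator's
truth table (100% at $\sigma = 0$, ≥ 95% at $\sigma = 0.1$ with dye
bias 0.3) rather than against cluster plots.

## What the simulator emulates — and what it does not

Defaults are chosen to emulate a post-mortem brain ASE cohort: 101
donors with 37% cases, marker MAF 0.4 (so roughly half the donors are
heterozygous and informative), five cDNA and three gDNA replicates
per sample, replicate noise $\sigma = 0.15$ Ct, dye bias 0.3 Ct,
baseline Ct 26, and a 40-cycle detection limit. Efficiency defaults
to 1 (perfect doubling): validated TaqMan/KASP assays run near 100%
efficiency, and this is the regime in which the $2^{|n\Delta Ct|}$
fold reading is exact.

The simulator deliberately omits: per-cycle fluorescence curves and
probe chemistry, plate-position and batch effects, cross-sample RNA
quality variation, genotyping error in the truth table, and
biological heterogeneity of the imbalance across donors (every
heterozygote shares one $\phi$). Passing tests therefore certify the
*arithmetic and statistics* of the pipeline under a faithful
measurement model — they do not certify robustness to the biological
and technical structure real cohorts add on top.

## Certification problem sizes

The test suite certifies the statistical core at these scales, chosen
as representative of a single-assay cohort: type-I error of the pooled
test from 500 simulated balanced cohorts of 30 heterozygotes × 5
replicates at $\sigma = 0.15$ (rejection rate required inside the 99%
binomial band around 0.05); fold-change recovery and power from 51
cohorts per $\phi \in \{1.25, 1.5, 2, 4\}$ (median recovered
$2^{|\text{mean } n\Delta Ct|}$ within 10% of $\phi$, power ≥ 90% at
$\phi \ge 1.5$); rank-sum exactness by full enumeration up to
$n+m = 10$.

## Numerical and edge-case choices

* Censoring is applied after noise; censored values are `NA`, exported
  as the literal token `Undetermined`.
* The Ct > 36 exclusion is strict (`>`), so 36.0 exactly is retained;
  undetermined channels always drop the replicate. A sample must keep
  at least 3 replicates — the boundary between "replicate exclusion"
  and "sample exclusion" is a package choice that preserves data while
  barring one-replicate samples.
* A flat calibration series would make $R^2$ 0/0; it is scored 0 (no
  ratio response) and fails on slope and monotonicity as well.
* The heterozygote-control QC tolerance carries a $10^{-8}$ absolute
  floor so noiseless series (SE exactly 0) are not failed by
  floating-point residue.
* Selection tie-breaks are total (r², annotation class, rsID), making
  the selected set invariant to input row order.
* All simulation entry points seed the RNG from the config, so
  identical config + seed is byte-identical output.

## Limitations

The pipeline quantifies imbalance at a transcribed *marker*; it
cannot identify the causal regulatory variant, only evidence that one
exists in LD with the marker. When multiple genes at one locus show
ASE, the method cannot arbitrate between them. Power depends directly
on the number of available heterozygotes (hence on MAF) and collapses
for rare markers. The fold-change scale assumes near-perfect
amplification efficiency, which is why uncalibrated assays should not
be interpreted quantitatively. Finally, the per-assay α = 0.05 with
no cross-assay correction mirrors the conventional reporting of
small ASE panels; for larger panels the `p_adjust = "BH"` switch
(off by default) applies Benjamini–Hochberg correction across the
per-sample tests, and assay-level p-values should be corrected by the
caller.
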