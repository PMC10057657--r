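---
title: "Methods: moderated miRNA differential expression and inverse-expression protein attribution"
author: "mirtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moderated miRNA differential expression and inverse-expression protein attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtriage)
```

# The problem

Tumor profiling studies that measure miRNAs, mRNAs and proteins on the
*same* samples can do something purely computational target prediction
cannot: check whether a predicted miRNA-target relationship is actually
visible in the matched protein data. `mirtriage` implements that triage
for a three-cohort design — adjacent normal tissue (N), patient tumor (T)
and first-passage patient-derived xenograft (F1) — with two contrasts of
interest, tumor vs normal (`TvN`) and xenograft vs tumor (`F1vT`).

The chain of reasoning is:

1. call differentially expressed (DE) miRNAs per contrast with
   empirical-Bayes moderated statistics suited to 5-8 samples per group;
2. reduce them to a priority set: the largest changes up and down per
   contrast, plus miRNAs moving in the same direction in both contrasts;
3. keep only well-supported predicted targets (binding probability,
   3'UTR site, validated catalogue entry);
4. attribute a protein change to a miRNA when the protein moved in the
   direction *opposite* to the miRNA (miRNAs are predominantly
   repressive);
5. eliminate attributions whose mRNA moved with the protein — those
   changes are transcriptionally explained, so a miRNA acting on
   translation is a less likely cause;
6. in xenograft comparisons, trust only proteins whose identifying
   peptides prove a human (not murine) origin, because xenograft tissue
   is a human/mouse mixture.

# Differential expression model

For feature $g$, log2 signals follow a one-way layout over the three
cohorts. The fit gives group means, the pooled residual variance $s_g^2$
on $d_g = n - k$ degrees of freedom ($n = 20$ samples, $k = 3$ groups, so
$d_g = 17$ at the default cohort sizes), and contrast estimates
$\hat\beta_g$ (difference of group means; `TvN` uses $1/7 + 1/5$ and
`F1vT` uses $1/8 + 1/7$ as the unscaled contrast variance $v_c$).

Residual variances are shrunk toward a prior
$s_0^2$ with $d_0$ prior degrees of freedom:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
t_g = \frac{\hat\beta_g}{\tilde s_g \sqrt{v_c}} \sim t_{d_0 + d_g},$$

and the overall test across the three groups is the moderated
$F_g = \mathrm{MS}_{between}/\tilde s_g^2$ on $(k-1,\ d_0+d_g)$ degrees of
freedom. $(d_0, s_0^2)$ are estimated by matching the first two moments
of $\log s_g^2$ to the scaled inverse-chi-square model: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$\psi'(d_0/2) = \mathrm{var}(e_g) - \psi'(d_g/2), \qquad
\log s_0^2 = \overline{e} + \psi(d_0/2) - \log(d_0/2),$$

where $\psi$, $\psi'$ are the digamma and trigamma functions. The
trigamma equation is solved by monotone bisection (see *Numerical
choices*). When the observed dispersion of $e_g$ does not exceed
$\psi'(d_g/2)$ there is no evidence of variance heterogeneity and the
prior is taken as $d_0 = \infty$ with $s_0^2 = \exp(\overline e)$; all
features then share one variance and the t reference becomes normal.
The test suite cross-checks both the estimator and the resulting
moderated statistics against `limma` on the same data, and checks the
$d_0 = 0$ limit against the classical pooled t-test and one-way ANOVA.

## The filter cascade

A feature is called DE when all four rules hold:

| rule | default | boundary |
|------|---------|----------|
| absolute signed fold change | $\ge 1.5$ | inclusive |
| contrast p-value | $< 0.05$ | strict |
| overall moderated-F BH FDR | $< 0.005$ | strict |
| feature id prefix | `hsa` | case-sensitive |

Fold changes use the signed linear convention throughout:
$2^d$ for a log2 difference $d \ge 0$ and $-2^{-d}$ otherwise, so the
value $-1.85$ means 1.85-fold down and nothing lies in $(-1, 1)$. The
boundary choices mirror how the thresholds are conventionally printed
("$\pm$1.5 fold change", "p < 0.05", "FDR < 0.005"). BH adjustment is
applied separately per contrast (for the contrast p-values, reported as
`fdr`) and across features for the overall F (`f_fdr`); only the F FDR
takes part in the cascade, the per-contrast `fdr` column is reported for
downstream use. The species prefix filter exists because multi-species
arrays carry mouse and rat probe sets alongside the human ones.

# Priority views

`top_k()` ranks a filtered contrast table by absolute fold change
(descending) within a direction; ties break by ascending p-value, then
feature id. Ranking by magnitude rather than p-value matches the aim of
"largest changes"; p-values at these group sizes order features by
variance as much as by effect. `same_direction()` intersects the two
filtered tables and keeps features whose fold changes share a sign —
these are of special interest because a change that persists from normal
to tumor to xenograft tracks the tumor-cell compartment rather than the
stroma. `priority_universe()` takes the union (top-10 up, top-10 down,
both contrasts, plus the same-direction set), deduplicated by
(miRNA, comparison). The universe is defined constructively from the
data because printed priority lists in the literature are typically
curated and not exactly recoverable by any single rule.

# Target filtering and inverse attribution

`filter_targets()` keeps predicted interactions with binding probability
$\ge 0.95$ (inclusive: the stated value is read as attained), site in
the 3'UTR (the canonical repressive binding location), and a validated
catalogue entry. These are deliberately conservative; the attribution
step is correlational and benefits from a high-precision target list.

`inverse_hits()` emits one attribution per
(miRNA, gene, comparison, fraction) where the protein's signed fold
change opposes the miRNA's. Protein changes are fraction-resolved
(membrane vs cytosolic) because proteins can genuinely move in opposite
directions in the two fractions (relocalization), and a hit in one
fraction says nothing about the other.

**Comparison matching** was a genuinely open design point. The strict
reading — a hit requires the protein entry to sit in the miRNA's own DE
comparison — discards associations in which a priority miRNA's
predicted target shows its inverse change only in the other comparison.
Published integration tables of this design do report such
cross-comparison associations (a miRNA DE only in `F1vT` paired with a
protein entry observed in `TvN`). The default
(`comparison_match = "either"`) therefore judges a protein entry
against the miRNA's fold change in the protein's comparison when the
miRNA is DE there, and otherwise against the miRNA's own-comparison
fold change; `comparison_match = "same"` gives the strict behaviour.
Note the precedence: when the miRNA *is* DE in the protein's
comparison, that fold change is used and no borrowing occurs, so a
same-direction pair in the matching comparison is never rescued by the
other comparison's sign.

`mrna_concordance_filter()` then looks up each hit's gene in the mRNA DE
table for the hit's comparison: same-sign mRNA marks the hit
`concordant` and removes it, opposite sign marks it `discordant`, no
entry marks it `absent`; the latter two survive. Concordance is judged
against the *protein's* sign, not the miRNA's, because the elimination
targets transcriptionally explained protein changes. Whether the
elimination runs before or after building the attribution table is
configurable (`apply_mrna_filter`); the hit records carry `mrna_status`
either way, so both orderings are reconstructible.

`multi_target_summary()` counts distinct target genes per miRNA across
all comparisons and fractions; miRNAs with two or more distinct targets
are the headline shortlist, since multiple independent inverse targets
are much less likely under coincidence.

# Xenograft protein provenance

Xenograft tissue yields peptides of mixed species. `classify_peptides()`
matches each identifying peptide as an exact substring against every
sequence of a human and a mouse protein database — no enzymatic-digest
model, no mass tolerance, because the operation mirrors post-hoc
scrutiny of already-identified peptides, not a re-search.
`call_protein_origin()` then applies: at least one human-only peptide
and no mouse-only peptide gives `human_not_murine`; the mirror case
gives `murine_not_human`; everything else is `ambiguous`, including
proteins with conflicting species-unique evidence (conservative by
design). One human-only peptide suffices even if all other peptides are
shared. Isoleucine/leucine are distinct by default, with
`merge_il = TRUE` for the mass-spectrometry convention; explicit is
safer than silent folding. When origin calls are supplied to the
pipeline, F1vT protein entries not called `human_not_murine` are dropped
before attribution.

# The synthetic generator

`simulate_triomics()` produces the full input bundle with known ground
truth so every stage is testable without any download. Its defaults are
the study conditions: cohorts 5/7/8, 300 miRNA features, baseline log2
signal $\mathcal N(7, 1)$, DE fractions 0.15 (`TvN`) and 0.2 (`F1vT`)
with 6 features shifted in the same direction in both, absolute log2
effects uniform on $[0.7, 3]$ (linear 1.6- to 8-fold, spanning the
cascade boundary), per-sample noise SD 0.3, and 10% `mmu-` features.
Regulated proteins respond with gain $\beta = 0.8$ and opposite sign,
with no mRNA entry; transcriptional decoys (10% of genes, 40 at the
defaults) get same-sign protein and mRNA changes and a filter-passing
target record pointing at a DE miRNA, so they appear as attribution
hits and must be removed by the concordance filter; 100 decoy target
records each violate at least one target-filter rule. Protein and mRNA
layers are emitted directly as DE tables (fold change and p-value)
rather than as raw abundances, because that is the form in which
proteomic and transcriptomic results enter this analysis. Planted
p-values are Uniform(1e-6, 0.01) for true effects and Uniform(0.2, 1)
for nulls; the integration logic uses direction only, so any
sub-threshold scheme is equivalent.

What the generator does *not* emulate: probe-level intensities and
chip normalization, batch effects, correlated features, stromal
admixture, or mass-spectrometry missingness. Passing tests on synthetic
data therefore demonstrate the correctness of the statistical and
set-logic machinery under the stated model, not robustness to those
real-data pathologies.

All draws flow from a single generator seeded once per run, so a
configuration and seed reproduce byte-identical outputs.

# Numerical choices

- Trigamma inversion: bisection on $d_0/2$ over $(10^{-8}, 5\times10^7]$
  with relative tolerance $10^{-8}$; a required $d_0$ beyond $10^8$ is
  treated as infinite. Bisection is used because $\psi'$ is strictly
  decreasing, making the bracket certain.
- Zero-variance features (possible in noiseless synthetic data) are
  excluded from prior estimation with a warning and floored at
  $s_g^2 = 10^{-10}$ for the statistics, so planted effects come out
  maximally significant and exact-null features give $t = 0$, $p = 1$.
- Reported p-values are floored at the smallest positive double so the
  BH step's domain $(0, 1]$ holds even when the t CDF underflows.
- Ties in `top_k` break by ascending p then feature id; report rows sort
  lexicographically over all columns; doubles are written with the
  fewest significant digits (15-17) that reparse exactly. Together these
  make every output file byte-stable across reruns.
- Fold-change threshold inclusive, p and FDR thresholds strict (above).

# Problem sizes in the test suite

The suite exercises the statistics at 2000 null features for calibration
(the observed fraction of contrast p-values below 0.05 must lie in
[0.03, 0.07], and 20 seeds must keep the full cascade empty), 200
simulated variances for hyperparameter recovery (truth $d_0 = 4$,
$s_0^2 = 0.05$, recovered within ±50% / ±25%), the default 300-feature
configuration for end-to-end edge recovery (recall 1.0 noiseless,
$\ge 0.8$ at noise SD 0.3, $\ge 95\%$ of transcriptional decoys
eliminated), and brute-force oracles on small inputs everywhere else.
These sizes were chosen as the smallest at which the distributional
checks are stable.

# Known limitations

- The moderated model assumes independent features; miRNA families with
  shared seeds violate this in real arrays.
- Inverse-direction matching is correlational: a sign-opposed pair is a
  candidate, not a demonstrated regulation.
- The mRNA elimination assumes the mRNA and protein tables cover the
  same genes faithfully; a gene absent from the mRNA table is retained
  as `absent`, which conflates "not measured" with "not changed".
- Cross-comparison matching (`"either"`) raises sensitivity to the
  published tables' behaviour at the cost of admitting associations
  whose miRNA and protein changes were observed in different contrasts;
  use `"same"` for the conservative reading.
- Exact substring peptide matching ignores modified residues and
  near-identical paralogs.
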