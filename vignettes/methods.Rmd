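---
title: "Polarized site patterns and multispecies-coalescent inference for elephantid multilocus data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarized site patterns and MSC inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probmsc)
```

## The study system and the data model

Five proboscidean taxa are analysed: forest elephant (F), savanna
elephant (S), Asian elephant (A), woolly mammoth (M) and the American
mastodon (O) as outgroup. The data are hundreds of short, unlinked
nuclear loci (mean ~106 bp) carrying one diploid individual per
elephantid taxon — two chromosomes each — and a single error-prone
mastodon chromosome from shotgun sequencing. Because loci are short,
recombination within a locus is neglected; because they are far apart
in the genome, loci are treated as independent draws from the
multispecies coalescent (MSC).

All analysis operates on *divergent sites*: alignment columns with
exactly two observed alleles. Polarization takes the mastodon allele
as ancestral, giving each taxon a derived-allele frequency
$f \in \{0, \tfrac12, 1\}$ per site. Two QC rules precede analysis:

* **Paralog guard.** Loci with more than `max_poly_per_locus`
  (default 3) positions polymorphic within the elephantids are dropped
  entirely. This targets false-positive sites from co-amplified
  paralogs in real amplicon data. On clean simulated data it mildly
  truncates the high-polymorphism tail, so simulation-based validation
  uses `max_poly_per_locus = Inf`; the default matches the design of
  the assay the package models.
* **Recurrence filter.** Sites whose derived allele appears on both
  sides of the African/Eurasian split in a configuration that a single
  mutation cannot produce — even allowing one deep-coalescing lineage —
  are removed. Since any partial carrier set on one side can ride a
  single deep lineage across the split, one mutation suffices exactly
  when the other side is fixed derived; the default `two-mutation`
  rule therefore removes cross-clade sites where *neither* side is
  fixed. A weaker `segregating-both-sides` rule (heterozygous on both
  sides) is available; it flags a strict subset. The original study
  states the symptom ("derived alleles seen in both African and
  Eurasian elephants") but not the exact algorithm, so the rule is
  configurable; without the original site table the choice cannot be
  calibrated against the printed removal count, and the default is the
  rule that preserves every single-mutation-explainable configuration.

## Divergence, diversity and rate tests

Cross-taxon divergence uses expected-mismatch (frequency-product)
counting, $t_{xy} = \sum_s f_x(1-f_y) + f_y(1-f_x)$: the probability
that one chromosome drawn from each taxon differs, summed over sites.
This reproduces fractional site counts; sites fixed derived in both
taxa contribute zero, which is why restricting to
elephantid-polymorphic sites leaves cross-taxon divergences unchanged.
Within-taxon diversity is the count of heterozygous genotypes of the
designated individual. Every estimate is normalized by savanna–Asian
divergence $t_{SA}$, which makes the normalizing entry exactly 1 with
zero uncertainty.

The relative-rate test compares lineage-specific derived counts
$n_x = \sum f_x(1-f_y)$ and $n_y$ (polarized on the root), with
statistic $(n_x-n_y)/(n_x+n_y)$. The denominator is the
pairwise-restricted total; this follows the natural reading of
"normalized by the total number of divergent sites" for a two-taxon
comparison, and it makes the statistic exactly 0 under symmetry.

## ILS site classes

For a taxon triple $(1,2,3)$ — where member 3 may be the merged
Eurasian clade $E = \{A,M\}$ or the merged *Loxodonta* clade
$L = \{F,S\}$, with merged frequency the chromosome-weighted mean of
the member frequencies — the rate of class $b = (b_1b_2b_3)$ at a site
is $\prod_i f_i^{b_i}(1-f_i)^{1-b_i}$. The seven non-null classes sum,
per site, to $1 - \prod_i (1-f_i)$. The all-derived class (every
elephantid derived relative to the mastodon) is reported as the
"mastodon" column; it is dominated by fixed elephantid–mastodon
differences and is by far the largest class. Classes 13 and 23 — a
non-sister member sharing the derived allele with member 3 — are the
ILS diagnostics. The headline comparison divides the 13+23 rate for
(S, F, E) by the one for (A, M, L), both normalized by $t_{SA}$. Two
p-values are reported: a one-sided test of the ratio exceeding unity
(z on the log-ratio) and a two-sided test of the rate difference, both
by weighted jackknife. On sparse tables a delete-one subtable can have
a zero rate, making the log-ratio jackknife undefined; the one-sided p
is then `NA` and only the difference test is reported.

## The weighted jackknife

Loci differ greatly in how many divergent sites they carry, so the
uncertainty engine is the weighted delete-one-block jackknife (Busing,
Meijer & van der Leeden 1999). With block weights $m_j$ (divergent
sites in locus $j$), $n = \sum_j m_j$, $g$ blocks and $h_j = n/m_j$:
$$\hat\theta_J = g\hat\theta - \sum_j (1 - m_j/n)\tilde\theta_j,
\qquad
\widehat{\mathrm{var}} = \frac1g \sum_j
\frac{(h_j\hat\theta - (h_j-1)\tilde\theta_j - \hat\theta_J)^2}{h_j-1}.$$
With equal weights this reduces exactly to the classical delete-one
jackknife (verified in the tests against a brute-force transcription
and the closed-form SE of a sample mean). Loci with zero divergent
sites are skipped: they cannot perturb a site-count statistic and
their weight would be degenerate.

## The coalescent simulator

`simulate_dataset()` draws genealogies for 2 chromosomes per
elephantid plus 1 mastodon under the fixed species tree
(((F,S),(A,M)),O), with instantaneous splits at $\tau_{FS}$,
$\tau_{AM}$, $\tau_{LoxEur}$, $\tau_{root}$ and constant
interval-specific sizes $\theta$. Everything is in mutation units
($\tau = T\mu$ per site; $\theta = 4N\mu g$), matching how such models
are reported and avoiding any commitment to a poorly measured absolute
mutation rate; conversions to years and individuals happen only at
reporting time through the generation length (31 years) and a
user-supplied $\mu$. Within an interval holding $k$ lineages of one
population the next coalescence is exponential with rate
$k(k-1)/\theta$ — i.e. $2/\theta$ per pair — so a branch's length *is*
its expected mutations per bp.

Mutations are dropped as a Poisson process per branch. The default
`infinite_sites` mode gives each mutation a fresh column and a
complete mutation ledger (site calling can be validated against the
ledger exactly); a `jc69` mode evolves columns with equal exchange
rates and allows recurrent substitution. An ancient-DNA damage channel
converts mastodon C→T and G→A independently with a given probability,
emulating deamination-driven misincorporation: it inflates apparent
mastodon–elephantid divergence while leaving polarized
elephantid-polymorphic genotype calls essentially unchanged — the
property that justifies using an error-prone outgroup solely for
ancestral-allele assignment.

Defaults are the study conditions: 375 loci, locus lengths drawn as
50 + geometric with mean 106 bp (the source data report only the mean;
the shifted geometric reproduces a realistic right-skewed amplicon
length distribution), model parameters at the published point
estimates. The root interval is not reliably estimable from data of
this kind, so its defaults come from the fossil prior midpoint (26 Mya
at the reference rate $\mu = 3.3\times 10^{-10}$/site/year implied by
placing the African–Eurasian split at the centre of its 4.2–9 Mya
window): $\tau_{root} = 0.0087$, $\theta_{root} = 0.0026$. A single
seed drives per-locus substreams, so datasets are byte-reproducible
and individual loci are insensitive to how many others are simulated.

The simulator is validated three ways: closed-form no-coalescence
probabilities $e^{-2\Delta\tau/\theta}$ and triplet discordance
$\tfrac23 e^{-2\Delta\tau/\theta}$; a Kolmogorov–Smirnov test of
within-interval waiting times against the truncated exponential; and a
distributional comparison of pairwise coalescence times against an
independent coalescent engine (msprime) under matched demography.

## Composite-likelihood model fitting

The full Bayesian gene-tree-sampling MCMC that such data are
classically analysed with is deliberately not re-implemented. The
estimator targets the same parameters through the joint polarized
site-pattern spectrum: each complete polarized site has a derived-copy
pattern $(n_F, n_S, n_A, n_M) \in \{0,1,2\}^4$ (80 non-null patterns).
Under the MSC with infinite sites, the expected per-bp rate of a
pattern equals the expected summed length of genealogy branches whose
descendant sets produce it; branches containing the outgroup fold onto
their complement (a mutation on the mastodon branch looks like an
all-derived elephantid site after polarization). An Rcpp kernel
estimates all 80 rates by Monte Carlo in a fraction of a millisecond
per thousand genealogies.

The objective is the Poisson composite log-likelihood
$\sum_p n_p \log\lambda_p - \lambda_p$ with $\lambda_p = L\,r_p$ for
total length $L$. Monte-Carlo noise is tamed with common random
numbers: the simulation seed is reset at every objective evaluation,
making the objective a deterministic (piecewise-smooth) function of
the parameters. Optimization is Nelder–Mead on log-parameters from a
method-of-moments initialization (current $\theta$'s from
heterozygosity; $\tau$'s from pairwise divergences with the ancestral
size started at the deepest current-taxon diversity, the
least-shrunken available proxy for ancestral sizes), with seeded
jittered restarts and a final polish at four times the Monte-Carlo
resolution. Box constraints implement the fossil-record prior ranges
(African–Eurasian 4.2–9 Mya, Asian–mammoth 3.0–8.5 Mya, forest–savanna
deliberately uninformative at 0.5–9 Mya, root 24–30 Mya, mapped
through the reference $\mu$); out-of-bound or order-violating
proposals are rejected with a penalty, and the estimate respects the
bounds by construction. The unfiltered polarized table is used — deep
coalescence is part of the model, and the recurrence filter would
remove exactly the signal the deep parameters need. $\tau_{root}$ and
$\theta_{root}$ are reported but flagged low-confidence: they are
dominated by the error-prone outgroup branch.

Interval estimates use a weighted delete-one-locus jackknife with
**one-step** (Gauss–Newton) refits: at the optimum the Jacobian of the
pattern rates is measured by common-random-number central differences
at high Monte-Carlo resolution ($1.5\times10^5$ genealogies, step 0.04
on the log scale), the Gauss–Newton information
$H = \sum_p \lambda_p^{-1} d_p d_p^\top$ is inverted once, and each
locus's delete-one estimate is $\hat t + H^{-1} U_\ell$ with $U_\ell$
the locus's score contribution. Full refits per deleted locus would be
both computationally disproportionate and pinned by the residual
Monte-Carlo roughness of the objective (delete-one perturbations are
smaller than the local noise scale, which collapses refit-based
jackknife variance); the one-step jackknife is the standard linearized
alternative and, combined with the Busing weights, is equivalent to a
cluster-robust sandwich over loci. Because every fitted quantity is
positive and ratio-like, delete-one estimates are combined on the log
scale and 90% intervals are symmetric in the log. In calibration
experiments on simulated data the jackknife SE of the forest/savanna
size ratio (≈0.19 on the log scale) matches the empirical
across-dataset scatter (≈0.20).

These intervals are frequentist, not posterior credible intervals — a
deliberate semantic difference from Bayesian MCMC output; both aim at
the same 90% coverage of the generating value.

What the estimator does well, and less well, at the study's data size
(375 short loci, one diploid per taxon): current-size and split-time
*ratios* are recovered essentially without bias (replicated-fit bias
of the forest–savanna to African–Eurasian split ratio is below 0.05
against a generating value of 0.61, with a per-dataset sampling spread
of ±0.08–0.10 — comparable to the width of the published credible
intervals, i.e. the data, not the estimator, limit precision);
absolute $\tau$'s and ancestral $\theta$'s trade off along the
classical $2\tau + \theta_{anc}$ ridge and are individually softer,
exactly as the wide published intervals for ancestral sizes suggest.

## Pipeline and problem sizes

`run_pipeline()` chains QC → polarization → recurrence filter →
divergence report → ILS report → NJ tree (ape's Saitou–Nei
agglomeration on the normalized divergence matrix; negative branches
clamped to zero with the deficit moved to the adjacent branch;
site-bootstrap support via resampling) → composite-likelihood fit,
logs every count transition, and writes TSV/Newick/JSON reports plus
the resolved YAML configuration next to them, so a run is
reproducible from its own output directory. The Neighbor-Joining step
and Newick I/O are delegated to ape; the distance matrix entering NJ
is this package's normalized divergence, not a model-based distance —
a documented difference from distance-software defaults.

Test and validation problem sizes are chosen to exercise the study
scale where it matters (375 loci for parameter recovery, coverage and
topology checks; 10–20 replicate fits; $10^4$ genealogies for
closed-form Monte-Carlo comparisons at 3-SE tolerance; 1,000 bootstrap
replicates for tree support) and smaller sizes for pure contract
tests.

## Known limitations

* One diploid individual per taxon: diversity estimates are sensitive
  to recent inbreeding, and isolation-with-migration models are out of
  reach (as in the source study, which defers gene flow to future
  work). The simulator correspondingly implements no migration.
* No recombination within loci and free recombination between them —
  adequate for ~106 bp amplicons spaced ≥100 kb apart, wrong for long
  loci.
* The composite likelihood ignores the shared genealogy of sites
  within a locus when forming the objective (the jackknife over loci
  restores honest uncertainty, but point estimation is not fully
  efficient).
* The mastodon damage channel models only C/G→T/A misincorporation,
  the dominant ancient-DNA artifact; fragmentation-related errors and
  mismapping are not modelled.
* Real supplementary data ship in formats this package deliberately
  does not parse (spreadsheet/PDF); plain-text re-exports are required
  (`inst/extdata/README.md`), and the checks calibrated against
  printed real-data values run only when those re-exports are present.
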