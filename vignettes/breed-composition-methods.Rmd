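---
title: "Methods: ancestry and breed composition deconvolution in pigs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry and breed composition deconvolution in pigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The breed composition of a pig — how much Duroc, Landrace, Yorkshire and
indigenous ancestry its genome carries — is economically meaningful
(indigenous Chinese breeds carry meat-quality alleles that commercial lines
lack) but unobservable from labels, especially for crossbreds.
`pigdeconv` estimates it from diploid biallelic SNP genotypes by
population-structure analysis against a curated multi-breed reference
panel.

## The admixture model and its estimator

The workhorse is the standard binomial admixture model. Individual $i$ has
ancestry proportions $q_i$ on the $K$-simplex; component $k$ has allele
frequencies $f_k$; the alt-dosage at variant $m$ is

$$d_{im} \sim \mathrm{Binomial}(2,\ p_{im}), \qquad
  p_{im} = \sum_k q_{ik} f_{km}.$$

`fit_admixture()` maximises the likelihood with multiplicative EM updates:
responsibilities split each observed alt copy across components in
proportion to $q_{ik} f_{km}$ (and each ref copy in proportion to
$q_{ik}(1-f_{km})$); the M-step re-estimates $F$ as a ratio of expected
alt copies to expected total copies and $Q$ as the per-sample average
responsibility. These updates never leave the simplex and are monotone in
the log-likelihood, which the tests assert at every iteration. Missing
genotypes are excluded from every sum (a dedicated sentinel in the
compiled core; never $-1$ arithmetic).

Numerical choices:

* $p$ is clamped to $[10^{-9}, 1-10^{-9}]$ inside the likelihood and $F$
  to $[10^{-6}, 1-10^{-6}]$ after each M-step, so fixated variants cannot
  produce infinite terms;
* convergence is declared when the relative log-likelihood increase drops
  below `tol` ($10^{-6}$ by default, iteration cap 2000) — the criterion
  is likelihood-based so the EM engine could be swapped for an accelerated
  optimiser without touching callers;
* initialisation is fully seeded: $Q$ rows from a symmetric Dirichlet(1),
  $F$ as the observed frequencies perturbed by Uniform($-0.05, 0.05$).
  Restarts (off by default, `n_restarts`) keep the best final
  log-likelihood.

The model is fitted unsupervised; components acquire meaning only through
`label_components()`: for each reference group the mean ancestry
proportion per component is computed (candidates excluded), and
(group, component) pairs are assigned greedily by descending mean. Greedy
assignment equals the total-mean-maximising assignment whenever each group
clearly dominates a distinct component — the regime a sound reference
panel produces — and resolves conflicts in favour of the stronger group.
Ties break on a fixed group order (D, L, Y, Indigenous, EUD, ASD) and then
the lower component index. Components no group claims are labelled
*Unknown*, and the Unknown proportion is always reported, never
redistributed.

## The workflow

1. **LD pruning** (`ld_prune`): sliding windows of 50 variants advanced by
   10, pruning one member of every pair with $r^2 > 0.5$ until no such
   pair remains in any window; windows never span chromosomes; $r^2$ is
   the squared Pearson correlation of dosages over pairwise-complete
   samples. The pair-removal dialect (which member goes) is not fixed by
   the published parameters, so this implementation removes the
   lower-MAF member (tie: higher index) — deterministic and
   informativeness-preserving, verified against a naive re-enumeration
   oracle, but not guaranteed variant-for-variant identical to PLINK.
2. **Commercial curation** (`select_commercial`): per-breed PCA
   (Patterson scaling $x = (d-2f)/\sqrt{2f(1-f)}$, missing imputed to the
   mean), sign gates on PC1/PC2, then the `n_select = 30` eligible
   individuals nearest the eligible-set centroid. The centroid rule is
   this package's deterministic reading of "select n credible
   individuals"; the sign gates themselves are configuration because PC
   signs are dataset-specific.
3. **Indigenous curation** (`compute_pib`, `build_panel`): each indigenous
   breed is merged with the 90 selected D/L/Y individuals and fitted at
   $K = 4$; the component with the maximum mean over the breed's
   individuals defines the breed-specific proportion P_IB. Breeds with
   mean P_IB $< 0.50$ are dropped wholesale (no component dominates a
   breed whose commercial admixture spreads over D, L and Y); within
   retained breeds only individuals with P_IB $> 0.80$ are kept. Both
   inequalities are strict, matching the published rules, and the
   boundary arithmetic is unit-tested on constructed reports.
4. **Characterisation** (`pca_genotypes`, `ibs_distance`, `nj_tree`):
   panel PCA, identity-by-state distances $1 - \mathrm{DST}$ (the
   conventional input for distance trees among the statistics PLINK's
   `--genome` reports), and a Saitou–Nei neighbour-joining tree with
   Newick export; negative branch lengths are clamped to zero unless
   disabled.
5. **Identification** (`identify_eud_asd`, `identify_breed`): candidates
   are processed one at a time so they never influence each other's fits.
   EUD/ASD composition comes from a $K=2$ fit on panel + candidate. Breed
   composition runs one $K=5$ fit per indigenous panel breed
   (D, L, Y, that breed, candidate), labels components for the four
   reference groups (the fifth is Unknown), and aggregates the ensemble:
   per-label mean and dispersion, where the dispersion written "SE" is the
   run-to-run *sample standard deviation*. The $\mathrm{SD}/\sqrt{B}$
   reading would make the published 0.2 reliability threshold
   unreachable — proportions are bounded by $[0,1]$ so
   $\mathrm{SD}/\sqrt{38} \le 0.081$ — hence only the plain SD is
   operable. A candidate is unreliable when more than 2 labels exceed
   SE 0.2 (strictly more, so exactly 2 high-SE labels still pass).
   Ensemble size equals the number of indigenous breeds in the panel —
   38 in the original study, 5 in the simulated default world. Raw means
   are reported without renormalising the five labels, since the source
   procedure defines no renormalisation.

## The synthetic world

`simulate_panel()` stands in for the real reference panel. Allele
frequencies follow a two-level Balding–Nichols hierarchy: ancestral
frequencies Uniform(0.05, 0.95); a European (EUD) and an Asian (ASD)
domestic pool each drift from the ancestral pool with $F_{ST}$
`group_fst = 0.2`; each breed drifts from its pool with its own
$F_{ST}$ — defaults 0.20–0.25 for the three commercial-line stand-ins
(strong line drift) and 0.10–0.18 for five indigenous-style breeds. The
group level is this package's extension of the flat Balding–Nichols
draw (which `group_fst = 0` recovers): without a shared within-group
pool, European and Asian breeds would be equidistant and neither the
K = 2 EUD/ASD split nor the ensemble's treatment of an indigenous genome
in runs lacking its parent breed could behave as they do on real pig
data, where the Europe–Asia divergence (pairwise $F_{ST}\sim0.3$) far
exceeds within-continent divergence. The value 0.2 was fixed on that
biology before any acceptance measurement. Genotypes are Hardy–Weinberg
binomial draws per breed; crossbreds are drawn either allele-by-allele
from a two-sided pedigree (`f1_haploid`, covering F1 and
D × (L × Y)-style terminal crosses) or as
$\mathrm{Binomial}(2, \sum_b q_b p_{bm})$ (`binomial_admixed`);
contaminants can vary their admixture per individual via a Dirichlet
draw, mimicking heterogeneously introgressed breeds. Variants are spread
over 18 pseudo-chromosomes (pig autosomes) so pruning's chromosome logic
is exercised; default missingness is 1%, typical of chip data.

What the generator does **not** emulate: linkage and haplotype structure
(acceptable because the pipeline prunes towards marker independence — and
the admixture model itself assumes independent loci), within-breed family
substructure, genotyping batch effects, and ascertainment bias of chip
variants. A green test on this world therefore establishes correctness of
the *procedure*, not field performance on real chip data.

## A real limitation the simulation exposes

In every $K=5$ identification run exactly one component is anchored by no
reference group. On a homogeneous Balding–Nichols panel the likelihood is
maximised by spending that component on splitting the largest unanchored
cluster (typically the 40-member indigenous breed) or on soaking up the
candidate itself; the group that gets split bleeds ancestry into the
Unknown label. The acceptance tests measure the consequences directly: F1
commercial × indigenous candidates receive close to 50% Duroc (the Duroc
component is anchored in every run) but substantially less than 50%
Indigenous, the difference sitting in Unknown; purebred indigenous
candidates likewise fall short of the 0.9 own-proportion mark. A
likelihood comparison in the development notes shows the splitting
solution genuinely dominates the ideally-labelled one, so any correct
maximum-likelihood fitter — including the original ADMIXTURE program —
behaves this way on such data; on real panels the free component instead
absorbs genuine within-breed substructure that candidates do not share.
Three-way commercial crosses (D × (L × Y)) are unaffected because all
three parents are anchored in every run. Consumers of the breed
report should read the Unknown fraction alongside the labelled ones; it
is reported, never silently redistributed.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size`, `step`, `r2_threshold` | 50, 10, 0.5 | variants, variants, $r^2$ | the published pruning filter |
| `K` (group / breed id) | 2 / 5 | components | EUD+ASD; D+L+Y+Indigenous+Unknown |
| `pib_breed_min` | 0.50 | proportion | mean-P_IB cutoff for mixed breeds (strict `<` drops) |
| `pib_ind_min` | 0.80 | proportion | per-individual P_IB cutoff (strict `>` keeps) |
| `se_threshold`, `max_high_se` | 0.2, 2 | SD, labels | reliability rule: unreliable iff more than 2 labels with SD > 0.2 |
| `tol`, `max_iter` | 1e-6, 2000 | relative loglik, iterations | EM stopping; in the spirit of ADMIXTURE defaults |
| `group_fst` | 0.2 | $F_{ST}$ | Europe–Asia divergence of the simulated pools |
| `missing_rate` | 0.01 | fraction | typical chip missingness |

## Degenerate inputs and edge policies

All-missing variants get `NA` frequency and are dropped from PCA;
monomorphic variants are dropped from PCA (zero variance) and defined to
have $r^2 = 0$ in pruning; sample pairs sharing no non-missing variant get
`NA` distance with a warning; merging favours `a`'s allele orientation,
flips swapped pairs, and drops strand-ambiguous (A/T, C/G) mismatches
rather than guessing by frequency; exact ties in the P_IB component choice
go to the lower component index; a failed ensemble run is skipped with a
warning and the result errors when fewer than half the runs survive.
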