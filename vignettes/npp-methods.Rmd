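---
title: "Normalized phylogenetic profiling: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized phylogenetic profiling: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npprofile)
```

## The model

Proteins that act in the same pathway, complex or environmental response
tend to be retained, lost or diverge *together* across species: a lineage
that abandons a pathway sheds or relaxes all of its components. A
phylogenetic profile captures one protein's conservation pattern across a
panel of genomes; correlated profiles are evidence of co-evolution and
hence of functional association.

`npprofile` implements the *normalized* variant of profiling, which works
on a continuous conservation measure instead of binary presence/absence.
For a query proteome searched against a panel of $G$ genomes, the profile
of protein $p$ is built in four steps:

1. **Top hits.** For each genome $g$, take the best BLASTP bit score
   $S_{pg}$ of $p$ against $g$'s full protein set (the "top hit").
2. **Filtering.** Discard scores below 50 bits (too close to noise to
   order homologs reliably), and drop proteins with surviving hits in
   fewer than a fraction `min_fraction` of the genomes (default 0.25) —
   profiles dominated by absences carry no correlation signal.
3. **Self-score normalization.** Divide each row by the protein's
   *self-score* $S_{p,q}$ — its top within-genome score, which may come
   from a close paralog: $u_{pg} = S_{pg} / S_{p,q} \in [0, 1]$. Missing
   hits become 0 (complete divergence); values are capped at 1.
4. **Per-genome standardization.** Each genome column is Z-scored against
   the population of normalized scores of all retained proteins in that
   genome: $z_{pg} = (u_{pg} - \mu_g)/\sigma_g$. This is the step that
   makes profiles comparable across species at very different evolutionary
   distances: a moderately conserved protein in a distant genome can be
   *more* remarkable than a highly conserved one in a close relative.

Similarity between two proteins is the Pearson correlation $r$ of their
Z-profiles. Significance is estimated under a naive species-shuffling
null: shuffle one profile's entries $N = 1000$ times, collect the null
correlations, and report
$Z = (r_{\mathrm{obs}} - \bar r_{\mathrm{null}}) / \mathrm{sd}(r_{\mathrm{null}})$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `score_threshold` | 50 bits | low-score filter; bit scores, so roughly alignment information content |
| `min_fraction` | 0.25 | minimum fraction of genomes with a surviving hit |
| `k` | 50 | hits returned per query (server presets 50/100/150/200; any positive integer works) |
| `n_shuffles` | 1000 | permutation-null sample size per pair |
| `seed` | — | master seed; each (query, subject) pair derives its own stream |

The permutation Z scale has a convenient working calibration, recomputed
by `calibrate_z()` and by `scripts/acceptance.R`: over 86-genome profiles,
a true correlation of 0.5 maps to a mean Z near 5 (a sensible minimum
cutoff) and 0.95 to a mean Z near 8 (extremely significant). With $n = 86$
species the null sd of $r$ is about $1/\sqrt{n-1} \approx 0.109$, so these
values follow directly from $Z \approx r/0.109$ — the permutation machinery
matters because real profiles are not Gaussian and the null mean is not 0
but $\approx -1/(n-1)$.

## Numerical and design choices

* **Population sd everywhere.** Column statistics divide by $n$, not
  $n-1$: the retained proteome *is* the population being standardized. At
  genome scale the difference is invisible, but the choice is fixed so
  results are bit-reproducible. The sampled permutation null also uses the
  population sd, which keeps it consistent with the exact enumerated null
  (`exhaustive_permutation_z`) it converges to.
* **The query-genome column.** Self-score normalization maps it to
  exactly 1 for every protein, so it has no variance and no meaningful
  Z-score. Its statistics are stored as (mean 1, sd `NA`) and its Z-scores
  are 0 by convention: the column stays in every profile (no genome is
  silently dropped from the panel) but contributes no spurious signal.
  Dropping the column instead would change every correlation by a uniform
  amount; the zero convention achieves the same neutrality without
  changing profile length.
* **Missing means zero.** A genome with no surviving hit contributes a
  normalized value of 0 *and is included* in the column statistics.
  Excluding absences would bias the column means upward and erase exactly
  the shared-loss signal the method is designed to detect.
* **Cap at 1.** A cross-genome bit score can exceed the self-score when a
  duplicated domain aligns twice; values are clamped so profiles stay in
  $[0,1]$.
* **Ties and determinism.** Top-hit ties are broken by input-file order;
  ranking ties by protein id; every permutation stream is seeded per
  (query, subject) pair from the master seed, so results are identical
  regardless of evaluation order. Identity and duplicate permutations are
  not excluded from the null — the simplest faithful reading of uniform
  shuffling, and at $n = 86$ the identity is hit with probability
  $1/86! \approx 0$.
* **Degenerate inputs.** Zero-variance profiles have no defined
  correlation: candidate proteins are skipped with a warning; a
  zero-variance *genome column* (other than the query genome's) is an
  error, since it usually means a degenerate input matrix.
* **Sequence mode.** A submitted sequence has no self-score, so its raw
  per-genome scores are normalized by the *best* genome hit, and Z-scored
  with the precomputed column statistics of the whole-genome build.
  Resubmitting a database protein's own scores therefore retrieves it at
  rank 1 with $r$ close to — but not exactly — 1.

## What the synthetic generator emulates

`generate_module_matrix()` produces raw score matrices with the structure
the method assumes: per-genome baseline conservation that falls with
taxonomic distance from the query genome (pushed through a logistic link),
planted modules whose members share a latent conservation signal with
pairwise correlation `within_module_r`, clade-level loss events that
remove whole subtaxa at once (shared among module members, independent for
background proteins), and a per-protein self-score in the query-genome
column. This exercises missing-value handling, per-genome standardization
and module recovery end to end.

It does **not** emulate: paralog interference in self-scores, genome
assembly/annotation quality differences, correlated evolution *between*
background proteins, phylogenetic autocorrelation among related species
(every genome is an independent draw given its clade), or bit-score
length dependence. Passing tests therefore demonstrate the pipeline's
correctness and statistical calibration, not its biological performance on
real proteomes.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to keep the statistics
meaningful: calibration uses 200 replicate pairs of length 86 with 1000
shuffles each; null calibration uses 1000 independent pairs; the
module-recovery fixture is 100 proteins x 86 genomes with one planted
module of 5 at `within_module_r = 0.9`; exact-null convergence uses 20,000
shuffles against full enumeration at profile length <= 6. Monte-Carlo
tolerances follow delta-method standard errors computed from the exact
null moments.

## Known limitations

* The permutation Z is a rough significance scale, not a calibrated
  p-value: profile entries are not exchangeable under phylogeny (related
  species are correlated), and no multiple-testing correction across the
  proteome is applied.
* Normalization by the self-score inherits any paralog bias in the
  within-genome top hit.
* The method sees only what BLASTP sees: fast-evolving orthologs below the
  score threshold read as losses.
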