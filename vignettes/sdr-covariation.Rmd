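---
title: "Scoring covariation between domain alignments and binding profiles"
author: "sdrcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring covariation between domain alignments and binding profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrcov)
```

## The problem

Peptide recognition domains (PRDs) — PDZ, SH3, kinase and related families —
bind short linear peptides, and large-scale assays such as phage display
summarise each domain's preference as a position weight matrix (PWM) over
aligned peptide positions. Which residues of the domain *determine* that
preference (the specificity determining residues, SDRs) is mostly unknown,
and exhaustive mutagenesis is infeasible.

sdrcov ranks candidate SDRs by covariation. The premise: if a domain residue
shapes specificity, then across the family a change of residue at that
alignment site should be accompanied by a coordinated change in the bound
peptides — the binding profile shifts with it. The data are therefore one
multiple sequence alignment $A$ ($n$ domains $\times$ $m$ sites) and one
aligned PWM per domain, $W_i$ ($w$ sites $\times$ 20 residues). Unlike the
classical two-MSA coevolution setting, the peptide side is a distribution,
not a sequence, so the machinery below generalises the usual column-pair
statistics to (alignment column, PWM position) pairs.

## The model

For a site distribution $p$ over the 20 amino acids the entropy is
$H = -\sum_x p(x)\log_b p(x)$, with $0 \log 0 = 0$. The default base is
$b = 20$, the alphabet size, so site entropies live in $[0, 1]$: a fully
conserved site scores 0, a uniform site scores 1. Worked examples and tests
also use base 2 (bits).

With sequence weights $\alpha_i \ge 0$ (see below), the three distributions
for MSA site $j$ and PWM site $k$ are

* $p_j(x) = \sum_i \alpha_i\,[A_{ij} = x] \,/\, \sum_i \alpha_i$ — weighted
  residue frequency of the alignment column;
* $p_k(y) = \sum_i \alpha_i\,W_{ik}(y) \,/\, \sum_i \alpha_i$ — weighted
  average of the PWM columns;
* $p_{jk}(x,y) = \sum_i \alpha_i\,[A_{ij} = x]\,W_{ik}(y) \,/\, \sum_i
  \alpha_i$ — each domain puts its weight on the row of its own residue,
  spread over the columns by its own PWM.

The joint marginals reproduce the two site distributions by construction
(tested to $10^{-9}$). Mutual information is
$MI = H(A_j) + H(W_k) - H(A_j, W_k)$.

Raw MI inflates at diverse sites: in the four-sequence illustration used
throughout the tests, a perfectly covarying pair of two-state sites has
$MI = 1$ bit while an unrelated pair of diverse sites reaches $1.5$ bits
simply because its entropies are larger (2 and 1.5 bits). The uncertainty
coefficient divides that inflation out; the package default is the
symmetric form

$$UC = \frac{2\,MI}{H(A_j) + H(W_k)},$$

which scores the covarying pair 1.0 and the diverse unrelated pair
$3/3.5 \approx 0.857$, restoring the intended ranking. The asymmetric
variants $MI/H(A_j)$ and $MI/H(W_k)$ are selectable (`uc_variant`); the
symmetric form is the default because it treats the two sides evenhandedly
and is bounded by the same $[0,1]$ range. UC is invariant under change of
log base; MI rescales by $\log b_1/\log b_2$ (both tested). When both
entropies are 0 the UC is defined as 0 — a doubly conserved pair carries no
covariation evidence and must not rank.

Two significance tests are available per pair. The chi-square
approximation uses $2\ln(2)\,n\,MI$ (MI in bits) against a chi-square with
$(c_j - 1)(c_k - 1)$ degrees of freedom; the cardinalities are the residues
with nonzero marginal support at each site, i.e. the effective contingency
dimension. The permutation test shuffles the alignment column across rows
(PWMs and weight-row association fixed) — the minimal null that breaks the
pairing — and reports $p = (1 + \#\{MI^* \ge MI\})/(1 + n_\mathrm{perm})$.

## Sequence weighting

Alignments over-represent well-studied clades, and near-duplicate sequences
would otherwise dominate every distribution. `tree_weights()` pushes a total
weight of 1 down a phylogenetic tree, splitting at each node in proportion
to each child subtree's total branch length (child edge included), so
crowded clades share one allocation. All-zero branch lengths fall back to
leaf-count splitting, which makes a star or zero-length tree reproduce
uniform weights. When no tree is given, a UPGMA guide tree is built from
pairwise fractional-identity distances (gaps count as mismatches), with
rows ordered lexicographically by id first so clustering ties resolve
reproducibly. The scheme's contract is qualitative — crowded branches are
down-weighted — and the tests assert exactly that, plus the exact identity
that duplicating any sequence (with its PWM) while halving its weight
changes no score by more than $10^{-9}$.

## Site filtering

Before scoring, MSA sites are dropped if any row carries a gap there, or if
the most frequent residue holds more than half the total sequence weight.
The boundary is inclusive: a majority fraction of exactly 0.5 is kept. The
filter removes sites whose conservation leaves too little variation to
inform covariation; the report records the reason per site, and downstream
prediction treats filtered sites as zero-weight rather than erroring.

## Predicting binding profiles

The profile of a new domain is predicted as a similarity-weighted average of
the known PWMs, $\hat p_k(y) = \sum_i s(q,i) W_{ik}(y) / \sum_i s(q,i)$,
with $s$ the fraction of identical aligned positions over the full
alignment length. The covariation-weighted variant replaces $s$ per target
site $k$ with $s_k(q,i) = \sum_j UC(A_j, W_k) [q_j = A_{ij}] / \sum_j
UC(A_j, W_k)$: alignment sites that covary with $k$ dominate the match.
The per-$k$ weights are renormalised by $\sum_j UC$ so the similarity stays
scale-free; when every UC weight for some $k$ is zero the site falls back
to the uniform similarity (recorded in the result). Prediction error is
$\sqrt{\frac{1}{20w}\sum_k\sum_y (\hat p_k(y) - p_k(y))^2}$ — the RMS
difference per site averaged over all 20 residues, bounded by
$\sqrt{0.1} \approx 0.316$; the constant only matters for comparisons
between methods, which it cannot affect. Left-out validation removes
near-duplicates first (greedy scan, 90% identity default), then repeatedly
splits the rows, recomputing the covariation map from the training rows of
each split. A per-probability regression-tree baseline is exposed as a
named hook only (`predict_pwm_regression_tree()`); it is intentionally not
implemented.

## Structure evaluation

Where a co-crystal structure exists, scores can be checked against residue
proximity: truly covarying pairs should sit close. Three distance metrics
are supported — heavy-atom centroid distance, CA–CA distance, and the
closest-atom distance minus the two Bondi van der Waals radii (possibly
negative for contacts). Hydrogens are excluded (typical crystal structures
lack them), "residue center" is pinned to the heavy-atom centroid, and
alternate conformations resolve to the highest-occupancy altloc (ties to
'A'). Pearson $r$ between score and distance is reported with a two-sided
p-value from the Fisher transformation, $z = \operatorname{atanh}(r)$,
s.e. $1/\sqrt{n-3}$; at least 4 overlapping pairs are required. Because
low-scoring pairs are noise-dominated, the `best_per_msa_site` mode first
reduces the map to each MSA site's top-scoring PWM position (ties to the
smaller index).

## The synthetic generator

`generate()` produces gap-free alignments and PWM sets with planted
covarying pairs, so every stage is testable without external data. For a
planted pair, sequences are assigned hidden states in balanced counts
(shuffled): balanced, equally sized coordinated clades are the scenario the
planted signal emulates, and they keep a two-state site exactly at the
inclusive filter boundary instead of randomly beyond it. The sequence's
residue at MSA site $j$ is its state's residue; its PWM column at site $k$
is `coupling` $\times$ a column concentrated (by `pwm_sharpness`) on the
state's partner residue plus `1 - coupling` $\times$ a shared background
column. Non-planted MSA sites draw independently around a per-site
consensus with probability `background_conservation`; non-planted PWM sites
share a per-site background column.

Every PWM column is then mixed with an independent per-sequence random
column with weight `pwm_noise` (default 0.05). This emulates the
finite-sample noise of assay-derived PWMs and is essential for honest null
behaviour: with exactly shared columns every pair would have MI exactly 0
and permutation p-values identically 1, a degenerate rather than uniform
null. Setting `pwm_noise = 0` with `pwm_sharpness = Inf` recovers exact
delta profiles, under which a fully coupled pair satisfies
$MI = H(A_{j^*})$ exactly.

Defaults, chosen once: `background_conservation = 0.2` (the diversity of
filtered sites in a divergent family), `pwm_sharpness = 8` (strongly peaked
but non-degenerate columns), two-state planted scheme (the smallest scheme
producing coordinated change). What the generator does *not* emulate:
phylogenetic correlation among background sites, indels/gaps, residue
similarity structure, or any biophysics of binding. Passing tests therefore
demonstrate statistical correctness and power under idealised conditions,
not performance on real alignments.

## Problem sizes and numerical choices

The test-suite study conditions, stated as the package's own design:

* Planted-pair recovery: one pair, coupling 0.9, $n = 30$ sequences,
  $10 \times 4$ site map, 100 seeds; ranked first by UC in at least 95.
* Null calibration: coupling 0, 200 seeds, 199 permutations; pair-level
  $p \le 0.05$ in at most 10% of seeds.
* Prediction ordering: three planted pairs with **four** coordinated
  states, coupling 0.95, $n = 30$, 200 validation repeats at 10% and 50%
  left out. Four states rather than two because a balanced two-state site
  sits exactly at the filter's half-weight boundary, so any random training
  subsample tips it out of the kept set and the covariation method is left
  with noise — a knife-edge artifact of the filter boundary, not a property
  of the method.
* Structure evaluation: $15 \times 4$ site map, three planted pairs, 100
  seeds. The size follows a power calculation for the Fisher test:
  detecting $|r| \approx 0.45$ at $\alpha = 0.05$ with 95% power needs
  about 48 score–distance points.

Numerical conventions: probabilities are validated to sum to 1 within
$10^{-9}$ (file input is renormalised when within $10^{-3}$, rejected
beyond); MI values in $(-10^{-9}, 0)$ from floating-point cancellation are
clamped to 0 and anything more negative raises an internal-consistency
error; ranking ties break by ascending site indices; all site indices are
1-based at every interface. Ambiguity codes (B, Z, X, U, O) are rejected at
parse time because a 20-letter alphabet is assumed throughout; `.` is
accepted as a gap alias on input.

## A small worked example

```{r table1}
aln <- domain_alignment(c("AVAC", "AVCD", "TYDE", "TYEC"),
                        ids = c("I", "II", "III", "IV"))
# wrap columns 2 and 4 as per-sequence single-residue profiles
delta <- function(a) matrix(as.numeric(AA20 == a), 20, 1,
                            dimnames = list(AA20, NULL))
prof <- profile_set(lapply(1:4, function(i)
  cbind(delta(aln[i, 2]), delta(aln[i, 4]))), rownames(aln))
cm <- covariation_map(aln, prof, base = 2, apply_filter = FALSE)
cm[, c("j", "k", "H_msa", "H_pwm", "MI", "UC")]
```

The covarying pair (site 1 with peptide position 1) reaches $MI = 1$ bit
with $UC = 1$; the diverse unrelated pair (site 3 with peptide position 2)
has the larger $MI = 1.5$ bits but the smaller $UC \approx 0.857$.

## Known limitations

Pairs are scored independently: indirect covariation through an
intermediate residue is not deconvolved, and residue-group effects are out
of scope. Highly conserved SDRs are invisible by construction — a site the
filter removes cannot rank, however close it sits to the peptide. Results
inherit the alignment's quality; columns that are misaligned will covary
spuriously or not at all. No background correction (e.g. average-product
correction) is applied beyond the uncertainty-coefficient normalisation.
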