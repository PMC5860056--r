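---
title: "Fold recognition by spectral contact map threading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold recognition by spectral contact map threading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmthread)
```

## The problem

When a query protein has a detectable homologue of known structure,
template-based modelling is routine. The hard case is *analogous* fold
recognition: the query's fold exists in the structure databases, but no
sequence relationship survives to point at it. Sequence-profile methods
fail there by construction. What does survive is geometry: two proteins
with the same fold share the same pattern of residue–residue contacts, and
modern co-evolutionary predictors can estimate a query's contact map from
sequence alone. `cmthread` recognises folds by comparing a predicted
contact map directly against a library of contact maps derived from known
structures, with no sequence information at all.

## The model

A protein of $n$ residues is reduced to a contact map $M$: a symmetric
$n \times n$ matrix with $M_{ij} = 1$ when the CB atoms (CA for glycine)
of residues $i$ and $j$ lie within a distance threshold (default 10 Å),
and 0 otherwise. Pairs with $|i - j| < 2$ are excluded: chain connectivity
makes them contacts at any threshold, so they carry no fold information.
Query maps hold predicted contact probabilities in $[0, 1]$ instead of
binary values; no binarisation is applied by default (an option exists for
ablation), since every step below applies to any real symmetric matrix.

The quality of a correspondence $f$ between the two proteins is the
contact map overlap (CMO),

$$ O(M^{q}, M^{t}) \;=\; \sum_{\substack{i<j,\; j>i+1 \\ f(j) > f(i)+1}}
   M^{q}_{ij}\, M^{t}_{f(i)f(j)}, $$

the (probability-weighted) number of query contacts superimposed on
template contacts by an order-preserving, one-to-one partial mapping.
Maximising CMO exactly is NP-hard, so the search uses a spectral
relaxation. Each map is approximated by its leading eigenpairs,
$\bar M = \sum_{k=1}^{t} \lambda_k (v_k \otimes v_k)$, and two proteins
are compared by aligning scaled eigenvectors instead of matrices: with
$u'_k = \sqrt{|\lambda_k|}\, u_k$ for the query and similarly $v'_k$ for
the template, the position-pair score is

$$ S_{ij} \;=\; \sum_{k=1}^{t} s_k\, (u'_k)_i\, (v'_k)_j, $$

which rewards positions whose eigenvector entries agree in sign and
magnitude. A standard global dynamic-programming alignment of $S$ (affine
gaps, free terminal gaps by default) then yields $f$ in polynomial time.

The signs $s_k \in \{\pm 1\}$ are not decoration: an eigenvector is only
defined up to a global sign, and $S$ changes completely when one flips.
Enumerating all $2^t$ assignments is what limited the original spectral
CMO approach to small $t$. Here a greedy search starts from all-plus
signs and sweeps $k = 1, \dots, t$, flipping one sign, realigning, and
recomputing the CMO; a flip is kept only if the CMO strictly increases,
and every acceptance restarts the sweep. Strict increase plus boundedness
guarantees termination, and the number of alignment evaluations grows
quadratically in $t$ in practice. Only the query's signs are searched:
flipping eigenvector $k$ in both maps at once cancels in $S$.

### Ranking matches

CMO alone favours large, contact-rich templates. The final score is
statistical: over all aligned pairs $(i, j)$ with $|i-j| \ge 2$ and
$f(j) > f(i) + 1$, the Pearson correlation $r$ between the query's
contact probability $p_{ij}$ and the template's inter-residue distance
$d_{f(i)f(j)}$. A genuine fold match puts high-probability contacts at
short distances, so $r$ is strongly negative, and
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ makes matches comparable across alignment
lengths. Matches with fewer than 3 usable pairs or zero variance are
unscorable (`NA`); $|r| = 1$ maps to a documented sentinel of $\pm 10^6$.
Templates are ranked by ascending $t$ (most negative first), with ties
broken by template id so results never depend on library order.

Optionally a logistic model calibrates
$(t, \text{frac}_\text{query}, \text{frac}_\text{template})$ into a match
probability. No fitted coefficients are shipped as authoritative — the
model a user fits reflects their own library and benchmark — but
`fit_logistic()` is a deterministic maximum-likelihood fit (with a mild
ridge fallback, flagged, under perfect separation), and the search config
accepts any such model as the ranking key.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 10 Å | contact distance on CB (CA fallback); informative range is roughly 7–11 Å |
| `t` | 20 | eigenpairs per map; quality saturates around 10–20 while runtime grows quadratically in `t` |
| `min_separation` | 2 | smallest \|i−j\| retained in a map |
| `gap_open`, `gap_extend` | −1, −0.1 | affine gap penalties on the $S$ scale; opening must cost at least as much as extending |
| `ends_free` | `TRUE` | free terminal gaps, so a domain is not punished against a longer chain |
| `ss_weight` | 0 | optional bonus added to $S_{ij}$ where 3-state secondary structure matches |

The benchmark functions in this package use `t = 10`: the synthetic
chains are 60–90 residues long and their maps are essentially captured by
ten eigenpairs, which keeps the full test suite fast without changing any
qualitative behaviour.

## Numerical and design choices

**Eigenpair retention order.** Eigenpairs are retained by descending
*signed* eigenvalue, not by magnitude. Contact maps are indefinite, and
one could argue both ways a priori; empirically the choice is not close.
Aligning a template's own long-range-only map back to its full map — a
case where the correct alignment is known to be the identity — recovers
the identity exactly under signed ordering but mis-registers badly under
magnitude ordering, because the large positive eigenvalues carry the
cohesive block structure that sparse and dense versions of the same fold
share, while the large negative ones encode oscillatory components that
differ between them. Magnitude ordering remains available
(`decompose(..., order_by = "magnitude")`) for ablation.

**Deterministic decomposition.** Each eigenvector's first component of
magnitude above $10^{-12}$ is made positive, so identical inputs give
bit-identical bases; the sign search addresses only the *relative* sign
ambiguity between two maps.

**Gap model.** The affine run cost is `gap_open + (len−1)·gap_extend`,
with `gap_open ≤ gap_extend ≤ 0` enforced. Allowing extension to cost
more than opening would make the three-state recursion's path accounting
diverge from the run-based cost definition (an interleaved double gap
could be split into several cheap opens); no practical parameterisation
is lost. Traceback ties prefer the diagonal, then up, then left, so
alignments are deterministic.

**Tie and degenerate handling.** Sign flips that leave the CMO unchanged
are rejected (termination requires strict increase). An all-zero query
map yields zero CMO everywhere, unscorable correlations, and a ranking
defined purely by the id tie-break. Both `r` undefined (zero variance,
$n < 3$) and $|r| = 1$ are handled explicitly rather than propagating
`NaN`.

**Library container.** A fold library is a directory with a versioned
JSON manifest and one JSON file per template, so entries can be iterated
without loading the whole library. Each entry stores the sparse contact
pairs, the *full* distance matrix, and the precomputed scaled
eigenvectors: search never re-decomposes a template, and the correlation
score has distances for every aligned pair, not only for contacts.
Numbers are serialised at 17 significant digits, which round-trips IEEE
doubles exactly.

## The synthetic benchmark

No external data is required: `make_chain()` builds idealised CA traces
with exact 3.8 Å consecutive spacing — packed helix bundles (rise 1.5
Å/residue, radius 2.3 Å, axis spacing 9.5 Å), antiparallel beta meanders
wrapped around a cylinder (strand rise 3.4 Å/residue, sheet spacing 4.8
Å), or self-avoiding random coils — plus Gaussian coordinate jitter. The
meander is deliberately curved so that its first and last strands touch:
a flat sheet has almost no contacts at sequence separation above 21
residues, and a benchmark member without long-range structure could not
exercise sparse-contact recognition the way real beta folds do.

`make_benchmark(n_families, members_per_family, seed)` fixes one
architecture per family (topology alternating by family, segment lengths
drawn once) and realises members as independently jittered copies (0.4 Å
by default), with an extra held-out member per family whose noisy
predicted map is the query. Architecture and jitter derive from separate
seed streams, so family identity and member noise are independent.
Long-range contact sets (separation ≥ 12) overlap by more than 60%
within a family and less than 30% across families, asserted in the test
suite. Labels form a 4-level hierarchy (class = topology; fold,
superfamily, family distinct per generated family) so homology-exclusion
filtering and TPR evaluation are exercisable.

`noisy_predictions()` emulates predictor output: true contacts get
Beta(8, 1) probabilities, 10% are dropped, and an equal expected number
of spurious pairs is added with Beta(1, 8) scores (both rates are the
defaults; all draws hang off one seed). Real predictors additionally emit
near-zero scores for the vast majority of pairs they reject; the optional
`background_rate` reproduces that dense low-confidence tail
(Beta(1, 50) scores). It matters for exactly one experiment: selecting
the top-L long-range contacts versus a *randomized* subset of the
predictor's list. Against a sparse list a random subset is still mostly
true contacts and the comparison is vacuous; against a realistic dense
list, random selection collapses while ranked selection degrades
gracefully — the qualitative shape the sparse-data protocol is meant to
show. The sparse experiment in the acceptance suite therefore uses
`background_rate = 1` and averages TPR@1 over three subset draws per
query.

What the generator does *not* emulate: side chains (maps are CA-trace
based), realistic loop conformations, domain insertions, length
mismatches between query and true template beyond jitter, or the
systematic, spatially correlated error structure of co-evolutionary
predictors. Passing the suite shows the machinery is correct and the
method behaves as designed on idealised folds; it does not certify
recognition rates on real proteins.

## Known limitations

- Short proteins force `t` down to `min(n, t)`; below roughly 5
  eigenpairs alignments are unreliable.
- The greedy sign search is a heuristic: it is guaranteed to terminate
  and never fall below the all-plus baseline, and stays within a few
  percent of the exhaustive optimum on the benchmark, but it can be
  trapped (the acceptance suite measures the gap at $t = 4$ where the
  exhaustive answer is computable).
- CMO-driven alignment inherits CMO's bias toward contact-rich
  templates; the correlation-based ranking compensates but only where an
  alignment with enough usable pairs exists.
- A single distance threshold discards distance information in template
  maps at alignment time (the correlation stage re-introduces it for
  ranking only).
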