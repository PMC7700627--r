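---
title: "Methods: gene-family characterization with genefamr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization with genefamr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamr)
```

genefamr implements the desk workflow used to characterize a multi-gene
protein family — such as the heat-shock protein (HSP) chaperones — in a
newly annotated genome: homology-based identification, physicochemical
profiling, conserved-motif discovery, phylogenetics, and codon-level
divergence against a sister species. This vignette documents the models,
the tunable parameters, the numerical choices, and what the simulators do
and do not emulate.

## Family identification

Family membership is decided by exact Smith-Waterman local alignment with
affine gap penalties; there is no heuristic seeding, so scores are optimal
by construction. Defaults mirror protein BLAST: BLOSUM62, gap open 11, gap
extend 1. Significance uses the Karlin-Altschul formula
$E = K\,m\,n\,e^{-\lambda S}$ with the fixed gapped-BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$; we deliberately do not estimate
composition-based statistics on the fly, so E-values are comparable across
runs. The database size $n$ is the total residue count after removing
exact-duplicate sequences (duplicates collapse to the lexicographically
smallest id, and the collapse is reported). The acceptance gate is
*inclusive*: a subject whose best E-value equals the threshold (default
$10^{-5}$) is retained. Redundancy removal is at 100% identity;
near-duplicate clustering is intentionally out of scope.

One practical caveat: the alignment engine reports a single optimal
traceback. When several co-optimal local alignments exist, which one is
returned is an implementation detail of the underlying aligner; the score,
and therefore the E-value and the membership decision, is unaffected.

## Physicochemical profiling

The five calculators reproduce the standard ProtParam definitions:

- **Molecular weight** — sum of average (not monoisotopic) residue masses
  plus one water (18.0153 Da), in kDa. Reports print it to 2 decimals.
- **Isoelectric point** — the unique zero of the Henderson-Hasselbalch net
  charge over the N-terminus, C-terminus and the D/E/C/Y/H/K/R side
  chains, with the Bjellqvist pKa set including its residue-specific
  terminal values. The charge is strictly decreasing in pH, so bisection
  on [0, 14] converges unconditionally; we iterate to 1e-4 pH, well inside
  the documented 0.001 tolerance, and validate against an independent
  1e-5-step grid scan of the same charge function.
- **GRAVY** — mean Kyte-Doolittle hydropathy; linear under concatenation,
  which the tests exploit as an invariant.
- **Aliphatic index** — Ikai's formula with coefficients a = 2.9,
  b = 3.9, mole percents computed over the full chain length.
- **Instability index** — Guruprasad's dipeptide statistic using the
  published 400-entry DIWV table (shipped as plain text); the scan
  direction makes it order-sensitive, unlike every other calculator.

Classification flags follow the conventions of published family tables:
acidic iff pI < 7.0 (so pI = 7.0 classifies as basic), unstable iff
II > 40 (II = 40 is stable), thermostable iff AI is strictly greater than
65, hydrophilic iff GRAVY < 0. Sequences containing `X` are rejected by
the calculators rather than silently skipped, so a profile row always
reflects the full chain.

## Motif discovery

Motifs are ungapped position-weight matrices fit under the ZOOPS model —
each sequence carries zero or one site — by expectation-maximization with
a 0-order background estimated from the input. ZOOPS was chosen over
OOPS/ANR because in real families many members lack a given motif, and it
is also the common default in the field. Parameters that matter:

- `width` / `widths`: candidate motif widths. The multi-motif default
  {28, 41, 50} covers the width range typical of published chaperone
  motif tables; single-width runs are always available.
- `n_starts` (default 10): EM restarts seeded from random subsequences.
  After convergence a column-shift refinement re-seeds EM from the called
  sites shifted left/right, which reliably escapes phase-shifted local
  optima that plain restarts fall into.
- `pseudocount` (default 0.01 per residue): with this Dirichlet prior the
  EM monotonicity guarantee applies to the penalized (MAP) objective, so
  that objective — not the raw likelihood — drives the stopping rule
  (gain < 1e-4 or 200 iterations) and is asserted non-decreasing on every
  run.
- `ic_floor` (default 8 bits per motif): multi-motif discovery masks the
  sites of each accepted motif and stops once the best remaining motif
  falls below the floor. The floor is applied to *bias-corrected*
  information content: raw maximum-likelihood IC is upward-biased by
  roughly $(A-1)/(2\ln 2\, n)$ bits per column for $n$ effective sites
  and $A = 20$ letters, which on noise with few sites can exceed a naive
  floor; subtracting the bias makes the floor discriminate signal from
  noise at the site counts this package targets.

A sequence is assigned a site when its posterior probability of
containing one exceeds 1/2; masked residues are excluded from window
scoring and background counts, so site lists of distinct motifs can never
overlap. Discovery is a pure function of (sequences, widths, seed).

## Phylogenetics

All likelihood machinery uses the JTT empirical amino-acid model, built
from the published exchangeability matrix and equilibrium frequencies
(shipped as plain-text data) and scaled to one expected substitution per
site per unit branch length. $P(t) = e^{Qt}$ comes from a symmetric
eigendecomposition, computed once and cached. No rate heterogeneity is
modelled — a deliberate simplification matching the plain "JTT
matrix-based model" setting of the workflows this package emulates.

- **Complete deletion** removes every column containing a gap or `X`
  before any distance or likelihood computation; an alignment reduced to
  zero columns is an error (pairwise deletion is out of scope).
- **Pairwise distances** maximize the site-product likelihood
  $\prod_i \pi_{a_i} P_{a_i b_i}(t)$ by golden-section search on
  [0, 10] substitutions/site; identical sequences return exactly 0, and
  the estimate matches an independent 1e-4-step grid scan within 1e-3.
- **Neighbor joining** is the classic Saitou-Nei agglomeration. Negative
  intermediate branch lengths are clamped to 0 with the deficit moved to
  the sister edge, preserving the joined pair's path length; ties in the
  Q-matrix break by the smallest (row, column) index. On additive
  matrices NJ provably recovers the generating topology and path lengths,
  which the tests verify together with an independent NJ implementation.
- **Likelihoods** use Felsenstein pruning with frequencies at an
  arbitrary reference node; by reversibility the result is invariant to
  re-rooting, and it is checked against brute-force state summation on
  small trees.
- **ML search** starts from the NJ tree, optimizes each branch by Brent's
  method (tolerance 1e-6, at most a few coordinate sweeps, which in
  practice converges the length profile), then hill-climbs over
  nearest-neighbor interchanges until no rearrangement improves the
  log-likelihood by more than 1e-6.
- **Bootstrap** resamples alignment columns with replacement (default
  1000 replicates), rebuilds a tree per replicate — NJ by default, since
  full ML per replicate is rarely worth the cost at desk scale, though
  `method = "ml"` enables it — and annotates each internal edge of the
  point-estimate tree with the percentage of replicates containing that
  bipartition. Supports serialize as integer internal node labels in
  Newick.

A minimal progressive aligner (k-mer guide tree, profile
Needleman-Wunsch, linear gaps) is included so the pipeline can run
end-to-end on simulated families; it is a fixture-scale utility, not a
production multiple aligner, and real analyses should feed an external
alignment in via the alignment tibble.

## Codon-level divergence (Ka/Ks tables)

Orthologous CDS pairs are aligned at the protein level (global
Needleman-Wunsch, BLOSUM62, 11/1) and back-translated so gaps are whole
`---` codons; the reading frame is therefore preserved by construction.
Every aligned non-gap codon pair differing at $k$ bases emits $k$
substitution records, each classified by mutating that single position
with the other positions held at the *reference* state (pathway averaging
over multi-base codon changes is deliberately not used). A change to a
stop codon counts as non-synonymous.

Indel records merge maximal runs of gap codons. Deletions are reported on
the ungapped reference CDS, insertions on the alt CDS, both as 1-based
inclusive intervals with `length = end - start + 1`. Because placement of
a gap within a repeat is ambiguous, intervals are *left-aligned* against
the carrying sequence — the standard variant-normalization convention —
which makes coordinates canonical and independent of the aligner's
internal tie-breaking; note this means reported intervals need not sit on
codon boundaries even though the gaps themselves are whole codons.

The reported "Ka/Ks" is the ratio of non-synonymous to synonymous
substitution *counts*, rounded half-away-from-zero to 2 decimals (so
9/24 = 0.375 prints as 0.38), with 0.00 when there are no non-synonymous
changes and `NA` when the synonymous count is zero. This count ratio is
what published family SNP tables of this kind actually tabulate; per-site
estimators (NG86/YN00) answer a different question and are out of scope.
Family `Total` rows recompute the ratio from summed counts, never by
averaging per-gene ratios.

## Simulators and what they (don't) show

The three generators are pure functions of their parameters and seed:

- `simulate_divergent_cds_pair()` draws a stop-free ancestor uniformly
  over sense codons, plants exact numbers of verified synonymous and
  non-synonymous single-base changes at distinct codons (never creating a
  stop, so both CDS stay translatable), and applies whole-codon indels.
  Substitutions are kept two codons clear of indel regions so that
  alignment-based recovery is unambiguous; truth indel coordinates are
  left-aligned with the same rule the caller uses.
- `simulate_protein_family()` mutates a root protein (drawn from JTT
  frequencies) per site with probability 1 − identity to a *different*
  residue, so expected identity equals the target; realized identities
  are recorded in the truth. Motif consensi are written verbatim,
  non-overlapping, with per-member occurrence probability. Gene models
  receive exon counts uniform in the requested range with fixed-size
  introns.
- `evolve_on_tree()` runs site-independent JTT substitution along each
  edge using the same transition matrices as the likelihood code.

These emulate the statistical structure each stage assumes — not real
data. They contain no indel evolution, no rate heterogeneity across
sites, no domain architecture, no GC or codon-usage bias, and no
annotation noise. Passing the recovery tests therefore demonstrates
correctness of the algorithms under their stated models, not performance
on real proteomes.

## Study conditions used by the tests and acceptance script

Problem sizes were chosen once as representative desk-scale conditions:
CDS pairs of 300 codons with (10, 5) planted substitutions over 100
seeds; motif recovery on 20-member families of 100 residues at 50%
identity with a planted 8-mer over 20 seeded runs; topology recovery on
the unrooted quartet ((A:0.15,B:0.18):0.4,C:0.12,D:0.15) — total length
1.0, distinct branch lengths — with 300-site roots over 100 replicates,
scored for both NJ and ML; pI validation on 100 random peptides of 2–60
residues against a 1e-5 grid. Bootstrap defaults stay at 1000 replicates
in the API while tests use 10–200 replicates, which is ample to verify
determinism, range and strong-signal behaviour.

## Known limitations

- Smith-Waterman is exact and therefore quadratic; genome-scale searches
  should pre-filter with a seeded tool and use this package for the final
  decisions.
- The E-value constants assume BLOSUM62/11/1; custom matrices get scores
  and ranks but their E-values should be treated as relative.
- NJ bootstrap supports on very short alignments inherit the variance of
  the distance estimates; the `method = "ml"` bootstrap is available when
  that matters.
- The progressive aligner is fixture-grade (linear gaps, no iterative
  refinement).
- `Ka/Ks` count ratios are descriptive, not per-site selection tests.
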