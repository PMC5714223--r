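---
title: "Joint RNA folding and alignment by iterative message passing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint RNA folding and alignment by iterative message passing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homofold)
```

## The problem

Homologous structured RNAs conserve their secondary structure more
strongly than their sequence: a GC pair may become an AU or CG pair
through compensatory double substitutions without disturbing the fold.
Purely sequence-based aligners lose accuracy exactly where this matters
— below roughly 60% pairwise identity — because the four-letter alphabet
carries little signal. Conversely, folding a single sequence ignores the
evidence carried by its homologs. Simultaneous folding-and-alignment by
full dynamic programming (the Sankoff scheme) is exact but needs
$O(N^{3H})$ time for $H$ sequences of length $N$.

`homofold` takes the message-passing shortcut: it keeps two sets of
probabilistic estimates — pairwise alignment posteriors and per-sequence
base-pair probabilities — and lets each inform the other over a small,
fixed number of iterations, at $O(H^2N^2 + HN^3)$ total cost.

## The two estimators

**Alignment: a three-state pair HMM.** Each sequence pair is modelled
by states ALN (both sequences emit), INS1 and INS2 (one sequence
emits). Forward-backward gives, for positions $i$ of $X_m$ and $k$ of
$X_n$, two posteriors that we keep separate because they feed different
consumers:

* the *co-incidence* posterior $P(i \sim k)$ — the total posterior at
  $(i,k)$ over all three states, i.e. aligned or inside an insert run
  immediately following an aligned position. This relaxed relation is
  the right one for mapping base-pair evidence between sequences;
* the *aligned* posterior $P(i - k)$ — the ALN-state term alone, the
  quantity the consistency transformation and the final alignment are
  built from.

Both use the same normaliser, the total path weight, so any global
scaling of the prior (below) cancels.

**Folding: a partition function.** Per sequence, base-pair
probabilities $P^m(i,j)$ are equilibrium marginals over all non-crossing
structures of canonical pairs (AU, UA, GC, CG, GU, UG), computed by
McCaskill-style inside-outside recursions. The energy model is
deliberately a *pluggable toy*: one equilibrium factor per pair, a
stacking factor for adjacent pairs, exponentially decaying hairpin /
bulge / internal loop factors, and a linear multibranch cost. The
algorithmic content of this package — the information flow between
alignment and folding — is agnostic to the particular table, and every
test oracle enumerates structures under the same model contract, so
fidelity to a published thermodynamic parameter set is intentionally out
of scope.

## The two coupling channels

**Structure → alignment: the match score.** From $P^m$ we compute for
every position the probability of pairing downstream
($P_<(i) = \sum_{j>i} P^m_{ij}$), pairing upstream
($P_>(i) = \sum_{j<i} P^m_{ji}$) and being unpaired
($P_\circ = 1 - P_< - P_>$). The match score between positions of two
sequences,

$$\rho(i,k) = \alpha_1\left(\sqrt{P_<^m(i)P_<^n(k)} +
  \sqrt{P_>^m(i)P_>^n(k)}\right) +
  \alpha_2\sqrt{P_\circ^m(i)P_\circ^n(k)} + \alpha_3,$$

rewards alignment of positions in the same pairing state. It enters the
HMM as a multiplicative prior on the ALN terms of both recursions; no
explicit normalisation is needed because the posterior ratio absorbs
the scale. Setting $\alpha_1=\alpha_2=1,\ \alpha_3=0$ recovers the
PMcomp-style score; the shipped defaults $(1.0, 0.8, 0.5)$ weight
pairing-direction agreement slightly above unpaired agreement and are
exposed as plain configuration values. $\alpha_3$ softens the penalty
where a paired position aligns with an unpaired one — the common
situation at stem-loop boundaries.

**Alignment + structure → folding: extrinsic information.** The pair
evidence of homolog $n$ is mapped onto sequence $m$ through the
co-incidence posteriors,

$$P^{(n\to m)}(i,j) = \sum_{k<l} P^n(k,l)\,P(i\sim k)\,P(j\sim l),$$

restricted to candidate indices with co-incidence at least 0.01 (an
inclusive cutoff: entries *smaller than* 0.01 are excluded; this is an
approximation that prunes negligible terms, not part of the model). The per-sequence extrinsic matrix is the identity-weighted
sum $\tilde P^m = \alpha^m \sum_{n\neq m}(1-\psi_{m,n})P^{(n\to m)}$,
max-normalised to one. Distant homologs weigh more — close ones carry
little independent information. The weighted sum can be identically
zero (single input, or all homologs identical); the zero matrix is then
returned as a valid, neutral result rather than dividing by zero. The
extrinsic term enters the partition function as a per-pair factor
$1 + \kappa\tilde P^m(i,j)$ (default $\kappa = 10$). This multiplier is
the package's own choice of pseudo-energy form, picked for three
properties: neutral at $\tilde P = 0$ (which makes the degenerate cases
above exact no-ops), bounded, and monotone in the proclivity.

## The iteration and its fixed points

After an initial sequence-only HMM pass and a plain folding pass, each
iteration performs, in order: match scores from current pair
probabilities → HMM posteriors with the score as prior → extrinsic
matrices from current pair probabilities and the *new* posteriors →
refolding with the extrinsic term. Three iterations are the default;
there is no convergence test — the loop runs a fixed count, and the
pipeline contains no randomness, so runs are bitwise reproducible.

Pairwise identities $\psi_{m,n}$ are computed once, at initialisation,
by maximum-expected-accuracy decoding of the sequence-only aligned
posteriors (a Needleman-Wunsch on the posterior matrix with gap score
0), with the full decoded alignment length — terminal gaps included —
as the denominator. Holding $\psi$ fixed keeps the extrinsic weights
stable across iterations.

Neutrality is exactly honoured: with $\kappa = 0$ and match weights
$(0, 0, 1)$ one iteration reproduces the initial state to machine
precision. The constant must be 1: a constant prior $c$ multiplies each
path weight by $c^{\#\mathrm{ALN}}$, which reweights paths with
different numbers of aligned columns unless $c = 1$ (pair probabilities
are unchanged for any constant, since $\kappa = 0$ already silences the
other channel).

## Final alignment and structures

The final aligned posteriors pass once through the probabilistic
consistency transformation
$P' (i\sim k) = \frac{1}{H}\sum_{o}\sum_q P(i\sim q|X_m,X_o)
P(q\sim k|X_o,X_n)$, with the endpoint sequences included in the sum
with identity self-posteriors (the ProbCons convention). This makes the
$H = 2$ case exactly the identity, which the tests assert. Entries
below 0.001 are dropped before the cross products (configurable;
endpoint terms stay dense), bounding the $O(H^3N^3)$ cost.

The guide tree is greedy agglomeration on the expected accuracy of the
pairwise decoding of $P'$, normalised by the shorter sequence length,
with average linkage (which makes merge scores non-increasing) and
smallest-index tie-breaking. Progressive profile-profile alignment
maximises the summed $P'$ over all cross-group sequence pairs, gap
score 0, with columns kept atomic — a gap once introduced persists.
Iterative refinement after the progressive pass is deliberately not
implemented.

Structures are predicted per sequence by maximum expected accuracy:
the non-crossing structure maximising
$\sum_{(i,j)\in S} 2P^m(i,j) + \sum_{i\ \mathrm{unpaired}} P^m(i)$,
with the weights fixed at 2 and 1. Ties break toward fewer pairs, then
the smallest partner index. A threshold mode keeps pairs with
probability above $t$ (default 0.5, which makes conflicts impossible
since each position's pairing involvement is at most one).

## Numerical choices

* **HMM stability.** Forward and backward tables are rescaled per
  anti-diagonal ($i + k$ constant). Cells of one anti-diagonal are
  reached by paths of comparable length, so their dynamic range is
  bounded; per-row scaling anchors the scale to the all-gap edge cells
  and underflows the near-diagonal mass for kilobase sequences.
  Posteriors are assembled in log space from the stored tables and the
  cumulative per-diagonal log scale factors. The contract — no
  NaN/Inf up to $N = 1000$ — is what the tests assert; the mechanism is
  an implementation detail.
* **Partition function.** Inside recursions are $O(N^3)$ with the
  two-loop scan capped at 30 unpaired nucleotides (standard practice).
  The outside pass iterates over enclosing canonical pairs only.
  Raw partition values are held in doubles without rescaling, which is
  ample at the few-hundred-nucleotide scale this package targets.
* **Degenerate inputs.** Sequences shorter than 4 nt are rejected
  (nothing can fold above the hairpin minimum of 3). A pair HMM whose
  parameters admit no complete path raises an error rather than
  returning NaN. Ambiguity codes are rejected at parse time rather than
  randomised, keeping every downstream step deterministic.

## What the generator emulates — and what it does not

The test fixtures are synthetic homolog families: a seed sequence with
a known multibranch structure, evolved under a star phylogeny.
Substitutions at paired positions are compensatory (pair-preserving)
with configurable probability; indels are confined to loop regions, so
the true alignment and true structures remain exactly known. Defaults —
5 sequences, ~110 nt, substitution rate 0.35 with full compensation
(mean pairwise identity near 0.5), indel rate 0.03 with indels of at
most 3 nt — put the families in the "twilight zone" where structural
information genuinely decides alignment quality. An analytic
expectation of the pairwise identity under the substitution kernel is
provided and tested against realised families.

The generator does *not* emulate: realistic substitution rate matrices,
length-dependent indel size distributions, non-star phylogenies beyond
an optional two-clade mode, structure rearrangement, or pseudoknots.
Passing the fixture-scale checks therefore demonstrates that the
machinery behaves as designed under conserved-structure conditions; it
does not certify accuracy on curated biological families, which would
require external benchmark data and a published thermodynamic model.

Problem sizes used by the checks: exhaustive oracles run at $N \le 6$
(alignment paths) and $N \le 12$ (structure enumeration, 50 sequences
under 3 models); the pipeline-level properties use 20 families of 5
sequences at ~110 nt — the scale at which the structural signal is
clearly expressed while exhaustive verification remains possible
alongside.

## Known limitations

* The toy energy model under-penalises some competing helices, so MEA
  predictions tend to over-predict pairs relative to the truth
  (sensitivity is high, PPV lower). Swapping in a richer model is a
  matter of constructing an `energy_model()`.
* Alignment accuracy inherits the quality of structure prediction;
  variable structural elements present in only one homolog receive no
  extrinsic support (the generator's `hairpin_insert` option exists to
  study exactly this case).
* The guide tree is built once; there is no post-progressive
  refinement.
* Sequences are limited in practice by the unscaled partition values
  and the $O(HN^3)$ fold cost — a few hundred nucleotides, which covers
  the tRNA / 5S / SRP scale the method is aimed at.
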