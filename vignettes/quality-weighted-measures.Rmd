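---
title: "Quality-weighted alignment-free measures for read clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-weighted alignment-free measures for read clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualmer)
```

## The model

A sequencing read is a string over {A,C,G,T,N} with one phred score per
base, $Q(i) = -10\log_{10} P(\text{base } i \text{ wrong})$. Assuming
base-call errors are independent given the scores, the probability that
the $k$-mer starting at position $i$ was read correctly is

$$P_{w,i} = \prod_{j=0}^{k-1}\bigl(1 - 10^{-Q(i+j)/10}\bigr).$$

Classical alignment-free statistics compare reads through the count
vector $X_w$ (occurrences of each word $w \in \Sigma^k$, overlaps
allowed). The quality-weighted framework replaces each occurrence's
contribution of 1 by $P_{w,i}$:

$$X^q_w = \sum_{i:\,w \text{ at } i} P_{w,i},$$

which degenerates to $X_w$ exactly when every base is certain. The package
implements, on these vectors:

* $D_2 = \sum_w X_w Y_w$ and its weighted form
  $D_2^q = \sum_w X^q_w Y^q_w$;
* the centred forms with $\tilde X^q_w = X^q_w - (n-k+1)\,p_w\,E(P_w)$,
  where $p_w$ is the i.i.d. background probability of $w$ and $E(P_w)$
  the expected probability that an occurrence of $w$ is correct:
  $$D_2^{*q} = \sum_w \frac{\tilde X^q_w \tilde Y^q_w}{(n-k+1) p_w E(P_w)},
  \qquad
  D_2^{sq} = \sum_w \frac{\tilde X^q_w \tilde Y^q_w}
                       {\sqrt{\tilde X^{q2}_w + \tilde Y^{q2}_w}};$$
  with $E \equiv 1$ these are the classical $D_2^*$ and $D_2^s$;
* $L_2$, Kullback–Leibler and symmetrized KL on frequency-normalised
  (for KL, pseudocounted) vectors.

### Estimating $E(P_w)$

$E(P_w)$ depends on the machine and is estimated once on the whole read
set, in two ways:

* **AWP** (average word probability):
  $E(P_w) \approx \sum_x X^q_w / \sum_x X_w$ — the mean occurrence
  probability of $w$;
* **AQP** (average quality probability): the phred scores at each word
  position $j$ are averaged over all occurrences of $w$, giving
  $\bar Q_w[j]$, and $E(P_w) \approx \prod_j (1 - 10^{-\bar Q_w[j]/10})$.

Both estimators use the *non-redistributed* occurrence probabilities even
when redistribution is enabled for the profile vectors: redistribution is
defined as a modification of $X^q_w$, and estimating $E$ from modified
vectors would feed the estimator its own output. Words never observed get
a fallback, the dataset mean per-base correctness raised to the $k$ — a
neutral value that keeps $D_2^{*q}$ denominators finite without asserting
anything about unseen words.

### Quality redistribution

A base called with probability $p$ leaves mass $1-p$ for the three
alternative bases. That mass is split proportionally to base frequencies
in the read: with frequencies A/C/G/T = 20/30/30/20% and $p = 0.7$, the
alternatives receive C = $0.3\cdot 0.3/0.8$ = 11.25%, G = 11.25%,
T = $0.3\cdot 0.2/0.8$ = 7.5%. At the $k$-mer level, each occurrence
credits every single-substitution neighbour word with the product of the
substituted base's redistributed mass and the other $k-1$ bases' own
correctness probabilities. Only one substitution at a time is considered:
double-error words carry negligible mass at realistic qualities, and the
neighbourhood would grow combinatorially.

```{r redistribution}
redistribute_mass(0.7, "A", c(0.2, 0.3, 0.3, 0.2))
```

## Numerical and design choices

* **Coordinates.** Words are indexed lexicographically (A<C<G<T) via 2-bit
  encoding; windows are half-open. Any window covering a non-ACGT base is
  excluded from counts, quality counts and the valid-window total `n`;
  `n − k + 1` in the formulas is always the *valid* window count.
* **Base frequencies** enter twice: as redistribution weights (per read by
  default, pseudocount 0.5 per base when a base is absent, so the weights
  are always defined) and as the background $p_w$ (raw, zeros allowed —
  a zero-background word simply contributes nothing to $D_2^*$-type sums,
  the limit value of its term).
* **Unequal reads in $D_2^*$-type denominators.** The single-sequence form
  $(n-k+1)p_w E(P_w)$ is ambiguous when the two reads differ in length or
  composition; the package uses the geometric mean
  $\sqrt{n_x p_x E_x \cdot n_y p_y E_y}$, which is symmetric and reduces
  to the single-$n$ form whenever the two sides agree. With that pairing
  $D_2^*$ becomes an inner product of per-read transformed vectors
  $u = \tilde X/\sqrt{npE}$, which is also what makes the clustering loop
  cheap.
* **Similarity to dissimilarity.** k-means needs a dissimilarity; D-type
  similarities are converted as $1 - S_{xy}/\sqrt{S_{xx} S_{yy}}$, clamped
  to $[0,2]$ (a cosine on the transformed vectors; 0 for identical
  profiles, 1 at orthogonality). Reads with a zero vector (e.g. $k$ longer
  than the read) sit at distance 1 from everything rather than erroring.
* **KL smoothing** adds $1/4^k$ per word before normalisation, and uses
  $\log_2$; symmetrization averages the two directions. The pseudocount
  only shifts scales, not assignments, but makes every divergence finite.
* **Phred decode** defaults to offset 33, caps scores at 93, and warns
  when >10% of bases exceed 60 (a typical sign of a phred+64 file read as
  phred+33). Internal computations accept non-integer and infinite scores;
  correctness exactly 1 (needed for the exact reduction
  $D^q \equiv D$) is only reachable with $Q = \infty$, which FASTQ cannot
  encode — on-disk scores saturate at 93.

## Clustering

Lloyd-style k-means under any configured measure. Centroids are
arithmetic means of member vectors — quality-weighted vectors for the
quality measures, frequency-normalised vectors for L2/KL — and for the
centred measures the centroid is treated as a pseudo-profile whose
expected-count term uses the mean of its members' window counts and base
frequencies. $E(P_w)$ is estimated once, before clustering, on the full
dataset. Determinism and robustness choices:

* reads are internally sorted by id, so results are invariant to input
  row order;
* initial centroids are `c` distinct reads sampled without replacement
  with sub-seed `seed + r` for restart `r`; ties in assignment go to the
  lowest centroid index;
* an empty cluster is reseeded with the read farthest from its current
  centroid;
* because symmetrized KL and $D_2^*$ need not converge under Lloyd
  iteration, each run tracks its best distortion and stops at an
  assignment fixpoint, at `max_iter` (100), or after `max_no_improve`
  (10) iterations without improving it; the best solution over `runs`
  restarts (default 5) is returned. The no-improvement threshold is a
  package choice; only the mechanism and the 5 restarts are inherited
  from the method.

## What the simulator emulates — and what it does not

`simulate_references()` draws order-1 Markov sequences (500–10000 bases by
default) whose stationary compositions and transition rows are jittered
per reference on a log scale (`composition_sd`, default 0.5 — large enough
that references are clearly distinguishable by their k-mer spectra, the
regime in which clustering reads by composition is meaningful at desk
scale). Order 1 matters: real transcripts carry dinucleotide structure,
and the centred statistics measure exactly the departure of word counts
from the read's own composition — under an i.i.d. reference model that
departure is pure noise and $D_2^*$-type measures have nothing to detect.
Order 0 is kept as a degenerate control (`markov_order = 0`,
`composition_sd = 0` gives compositionally identical references).

`simulate_reads()` draws per-base phred scores from a positional profile
(linear decline 38→20 plus integer Gaussian noise, sd 3, clamped to
[2,40] — an Illumina-like shape) and substitutes every base with its own
quality-implied probability $10^{-Q/10}$, so qualities are informative by
construction. A requested `mismatch_rate` *scales* the position-dependent
error curve so that the mean per-base substitution probability equals the
requested rate, and the emitted qualities re-encode the scaled
probabilities. The scale factor is computed from the exact expectation of
the discretized, clamped quality draw, so the realized rate is unbiased. A
uniform error add-on was rejected: it would flatten the emitted qualities
to near-constancy and erase the positional signal that quality weighting
exists to exploit, which is not how position-dependent sequencer error
profiles behave. Insertions replace an emitted position with a uniform
random base (probability per read position); deletions skip reference
bases (probability per reference base), with the read re-extended from the
reference to keep fixed length.

Not emulated: platform-specific error motifs, paired ends, quality
miscalibration, and coverage biases. Consequently, passing tests show that
the statistics and the clustering behave as designed when qualities are
*honest*; they do not show robustness to miscalibrated quality strings,
which real instruments do produce.

## Evaluation

The recall of a source sequence is the fraction of its reads inside the
cluster that holds the plurality of them (ties toward the lowest cluster
index); the reported recall rate is the unweighted mean over sources. Two
degeneracies follow from the definition and are kept deliberately: a
single all-encompassing cluster scores 1, and two sources may share their
best cluster.

## Problem sizes used in the shipped tests

The test suite exercises the exact worked redistribution example, oracle
equivalence of every statistic against brute-force reimplementations
(50 random read pairs, $k \in \{1,2,3\}$), exact reduction of the weighted
statistics to their classical counterparts on 100 perfect-quality reads,
clustering of 500 error-free reads from 2 references (recall ≥ 0.95 for
all nine measures), and a 10-seed comparison on 3000 reads with 10%
quality-consistent mismatches in which the median recall of
$D_2^{*q}$ (AQP) must not fall below classical $D_2^*$ — a desk-scale
version of the regime where quality weighting pays off. These sizes were
chosen to keep the full suite under a minute of compute while leaving the
statistical assertions comfortably powered.

## Known limitations

* Backgrounds are i.i.d. only; no higher-order Markov null models.
* Redistribution considers substitution neighbours only, not
  insertion/deletion neighbours.
* The AWP/AQP estimators assume the read set is large enough for word
  statistics to stabilise; on very small sets the fallback dominates.
* $D_2^z$ (variance-standardised $D_2$) and consensus clustering are out
  of scope.
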