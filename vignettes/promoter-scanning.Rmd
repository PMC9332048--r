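---
title: "Promoter class discovery and genome scanning with dinucleotide PWMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter class discovery and genome scanning with dinucleotide PWMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Plant promoters are so divergent that direct sequence comparison fails:
two functional promoters of the same genome can differ by several
substitutions per position. `ppscan` implements a promoter-discovery
pipeline built around three ideas:

1. **Dinucleotide position-weight matrices.** A promoter class is
   summarised not by per-base frequencies but by the frequencies of
   *ordered adjacent base pairs*. With bases coded $v(A)=1, v(T)=2,
   v(C)=3, v(G)=4$, the pair at alignment columns $(j-1, j)$ has index
   $s = v_{j-1} + 4(v_j - 1) \in \{1..16\}$, giving a
   $16 \times (L_1 - 1)$ count matrix $M$ for an alignment of length
   $L_1$. The weight matrix standardizes each count against the
   matrix-wide background:
   $$PWM'(i,j) = \frac{M(i,j) - N(j)\,p(i)}{\sqrt{N(j)\,p(i)(1-p(i))}},$$
   with $N(j)$ the column total and $p(i)$ the global frequency of
   dinucleotide $i$. Cells are approximately standard normal for a
   background column, so the matrix is directly interpretable as a field
   of per-cell z values. Capturing adjacent-base correlation is what lets
   profile alignment work at divergences where mononucleotide PWMs carry
   no signal.

2. **Shuffle-calibrated significance.** Every alignment score is reduced
   to a Z score against a Monte-Carlo null obtained by shuffling the
   scored sequence (for class membership) or the chromosome (for genome
   scanning): $Z = (F_{max} - \bar F_r)/\sqrt{Dis(F_r)}$. Nothing about
   the score distribution is assumed; the studentization absorbs sequence
   composition and matrix scale.

3. **Iterative classification.** Classes are discovered greedily: align a
   random sample of the working promoter set, build the class PWM, admit
   every sequence of the working set with $Z > 5$, remove the members and
   repeat, stopping when a candidate class attracts fewer than 100
   members. Classes are therefore disjoint by construction, numbered in
   discovery order, and ordered (softly) by decreasing volume.

## Promoter regions and filters

Regions span $-499..+100$ around the annotated gene start (the start is
used as a TSS proxy), renumbered $1..600$ so the start sits at column
501; reverse-strand regions are stored reverse-complemented so every
promoter reads 5'→3' towards its gene. The window is taken as 500 nt
upstream plus 100 nt from the start — one of several readings of a
"−499..+100" convention that is nominally 599 nt yet used as 600
throughout; this one yields exactly 600 and puts the conserved
start-proximal core near columns 500–505. Windows running off a
chromosome are dropped, not clipped: every downstream matrix assumes the
fixed length.

Four filters clean the training set (`filter_params()`): per-base content
≤ 60% (counted over the full 600 nt), at most one N, no homopolymer run
longer than $m_0 = \{A{:}13, T{:}12, C{:}5, G{:}5\}$, and G+C fraction in
$[0.29, 0.37]$. The $m_0$ defaults were calibrated on experimentally
confirmed dicot promoters; `derive_run_thresholds()` re-derives them from
any reference set as the smallest $m$ whose run-length tail fraction
drops below a per-base cutoff. An N run never counts toward any base's
$m_0$.

## Normalization of the PWM

Class matrices are made comparable by fixing two moments:
$K_d = \sum_{i,k} W(i,k)\,p_1(i)\,p_2(k) = 0$ and
$R^2 = \sum_{i,j} W(i,j)^2 = 75\,L_1$. The transform is center-then-scale:
subtract $\kappa = K_d(PWM')$ (exact, because $p_1$ and $p_2$ each sum
to 1), then scale by $\alpha = \sqrt{75 L_1 / R^2}$. The weight vectors
are not pinned down by the published description; we take $p_1$ = the
dinucleotide background $p$ of the counts and $p_2$ uniform over columns,
the choice under which the centering step zeroes $K_d$ in one move. Any
transform satisfying both constraints is accepted by the contract tests
(tolerance $10^{-9}$ relative); the constant 75 is taken as given. A
constant matrix cannot be normalized (zero variance after centering) and
is an error; a dinucleotide with zero total count would make $p(i)=0$ and
Eq. undefined, so row totals get add-one smoothing in that case only.

Per-column conservation is summarised by
$X(j) = \sqrt{2\sum_i PWM'(i,j)^2} - \sqrt{2n-1}$ with $n = 9$ degrees of
freedom (the stated constant; approximately standard normal for a
background column, so $|X| > 3\text{–}4$ flags conserved positions).

## Alignment scoring

Sequence-vs-PWM alignment is dynamic programming with a linear gap
penalty. Aligning sequence position $t$ to matrix column $l$ scores
$pwm(s(t{-}1,t),\, l)$ where the dinucleotide is formed with the *actual*
previous sequence base — a gap breaks the chain but never re-pairs bases
across the indel, keeping the match score a pure function of the
sequence. Position 1 and N-containing pairs score 0. Class membership
uses global alignment ending at $(600, L_1-1)$; genome scanning uses
local (floored) alignment of windows of length $L_1 + 50$, the slack
absorbing indels. The published method states only the matrix-vs-matrix
indel penalty ($d = 20$); the sequence-vs-PWM penalty is undocumented, so
we default to the same $d_\text{seq} = 20$ (configurable). Gaps are
linear, not affine.

## Genome scanning

For each class and chromosome, windows advanced by `stride` produce an
$E_{max}(k)$ series; per class, candidate hits are reduced to
non-intersecting local maxima (greedy by descending score — a
deterministic realization of "local maxima chosen because they do not
intersect"), studentized against a null built from up to 10,000
non-overlapping windows of the mono-shuffled chromosome, and kept at
$Z \ge 6$. Across classes, any two records overlapping by more than 10%
of the shorter record keep only the larger-Z one (ties: lower class id,
then leftmost — the published rule is silent on ties). Windows with more
than 10% N are skipped, and each window is scored self-contained (its
first position has no previous base). Besides the reverse complement,
two mirror controls can be scanned: complement-only (base substitution
without the 180° flip) and reverse-only (the flip without
complementation); hit coordinates are always mapped back to the forward
frame.

Raising the threshold can only remove records: per class, the Z series
is monotone in $E_{max}$, and the greedy resolution processes candidates
in a fixed order, so the record set at $Z_0 = 6.5$ is a subset of the set
at $6.0$ — the ordering property the scan-count tables rely on.

## The multiple aligner

The class aligner optimizes a population of candidate alignments (gap
patterns over the sampled sequences). An individual's fitness is
$\sum_i F_{max}(i)$, the summed global score of the members against the
PWM rebuilt from the individual's own alignment. Generations alternate
an EM-like step (realign every sequence to the individual's current PWM
by dynamic programming) with random single-column insertions/deletions
($L_1$ confined to $[600, 650]$, consistent with the $L_1+50$ scan
window); selection is elitist, so the best fitness never decreases, and
the run stops at a generation cap or when the gain stays below $10^{-3}$
for 10 generations. The published account sketches only "a genetic
algorithm optimizing the alignment pattern"; population size (20),
generation cap (200), and the operators above are this package's
realization of that sketch. On near-gapless data (the synthetic study)
the EM step converges in a handful of generations, which is why the
validation suite can run with population 3 and 4 generations.

### Leave-one-out membership scoring

One correction to the literal classification loop proved necessary: the
candidate PWM is built *from* the sampled sequences, so each sampled
sequence finds a trace of itself in the matrix. The self-fit inflates
in-sample Z by roughly $\alpha\,(1-p)\sqrt{(L_1-1)/(n\,\bar p)}/sd(F_r)$
— about +5 at sample size 300 and +3 at 1000. With a large working set
this only pads the member list, but when the working set shrinks towards
the sample size (as it must in late rounds), pure-background sequences
begin to clear $Z > 5$ on self-fit alone and coalesce into spurious
accepted classes. `build_classes(loo = TRUE)` (the default) therefore
scores every in-sample sequence against the PWM rebuilt without its own
alignment row; out-of-sample sequences see the full PWM. The procedure's
surface is unchanged — every sequence is scored and eligible — and
`loo = FALSE` restores the literal behaviour.

## Class clustering

Two class count matrices are compared by Needleman-Wunsch over their
columns with boundary $F(i,0) = -d\,i$ and match weight
$w(i,j) = \tfrac{1}{4}\sum_k (S - |m^n_{k,i} - m^q_{k,j}|)/\sigma$, where
$S, \sigma$ are the mean and SD of the absolute element difference under
random column pairing of the two matrices (Monte Carlo, 1000 pairings,
seeded). The printed recurrence contains an obvious typo (the same cell
on both sides); the standard three-way recurrence is implemented. The
distance is $D^{nq} = (\min(F^{nn}, F^{qq}) - F^{nq}) / \min(F^{nn},
F^{qq})$; a trailing exponent in the published rendering could also be
read as squaring the denominator, but the linear reading maps $D$ into
$[0,1]$ and matches the behaviour of shuffled-matrix controls (all
control distances above 0.935, against a grouping cut of 0.8), so it is
the default with `squared = TRUE` as the switch. Grouping is standard
complete linkage (`stats::hclust`) cut at 0.8; row-shuffled controls
(`random_control_distances()`) show where chance similarity sits.
$\sigma = 0$ (constant matrices) degrades the weights to 0 with a
warning.

## Transcriptome support

The two-proportion U test compares the fraction of PPSs with transcript
evidence just downstream of their putative start against random
positions: $U = (m_1/n_1 - m_2/n_2)/\sqrt{\hat p(1-\hat p)(1/n_1+1/n_2)}$,
pooled $\hat p$, two-sided, no continuity correction. For the study's
counts (31/1000 vs 17/1000) the formula gives $U = 2.045$; the source
prints 2.07, which the formula reproduces only if $\hat p(1-\hat p)$ is
rounded to 0.023 mid-calculation, so the package reports the exact value.

# The synthetic study

`synth_spec()`/`synth_generate()` build a fully labelled stand-in for a
real genome so every stage is testable offline. Defaults define the
package's reference conditions:

* one chromosome of 1.2 Mb, iid background at GC = 0.33 (inside the
  promoter filter range; an order-1 background chain is available);
* three planted promoter classes of 600/300/150 members — the ~2:1
  volume decay of real class tables — plus 200 background genes and 30
  intergenic decoys, genes on both strands;
* each class is an inhomogeneous first-order Markov profile over the
  600-nt window: per column and previous base, the next-base distribution
  is a Dirichlet draw centred on the background with concentration 1.6
  (flank) / 0.8 (columns 480–520), the sharper core mimicking the
  conserved start-proximal peak of real promoter classes;
* members are chain samples with 15% iid substitution noise,
  rejection-sampled so every planted member passes the selection filters
  by construction.

The concentrations were fixed so that a planted member scores $Z \approx
8$–$12$ against its round's PWM — deliberately *marginal* significance,
the regime real promoter classes occupy (their shuffled-set control
volumes sit near 16, i.e. barely below the acceptance threshold), and the
regime in which the fixed $Z>5$/volume≥100 iteration meaningfully
separates classes. Much sharper profiles make every class leak into the
first discovery round; much softer ones fall below the membership cut.

What the generator does **not** emulate: transposon/repeat landscapes
(the dominant source of real PPS abundance), CpG-island-like composition
gradients, chromatin context, or annotation error in gene starts.
Passing the validation suite therefore demonstrates the statistical
machinery — calibration, recovery, ordering properties — not biological
performance on a real genome. One consequence is worth spelling out: on
a real genome, locally pair/triplet-shuffled chromosomes retain regional
composition and short-range correlation and therefore yield clearly more
scan hits than a globally mono-shuffled chromosome. The synthetic
background is compositionally homogeneous by design, so pair/triplet
shuffling has nothing extra to preserve — both controls sit at the same
Poisson-level handful of hits as the mono shuffle, and their relative
order on any single run is noise rather than signal.

## Problem sizes in the validation suite

The reference study runs at deliberately reduced Monte-Carlo and
optimizer settings: membership nulls of 130 shuffles (versus the 1000
default), aligner population 3 with 4 generations and a 600-sequence
sample (versus 20/200/1000), scan stride 50 with 2000-window nulls, and
control scans on the single study chromosome. These sizes keep the whole suite in the
tens-of-minutes range on one CPU while leaving every assertion's margin
intact; all are ordinary function arguments, so a larger study is a
parameter change, not a code change.

# Numerical choices

* Normalization contract tolerance: $10^{-9}$ relative on both moments.
* DP tie-breaking: diagonal (match) preferred, then sequence-consuming
  step; traceback comparisons use an absolute $10^{-9}$ epsilon.
* Greedy selection ties: higher score first, then leftmost interval;
  cross-class resolution ties: lower class id, then leftmost.
* All randomness flows through explicit integer seeds; the C++ shuffle
  core draws from R's RNG so `set.seed()` governs everything, and every
  null model records its seed.
* Coordinates are 0-based half-open only inside BED export; everywhere
  else 1-based inclusive.

# Known limitations

* The aligner is a local optimizer; with indel-rich real promoters the
  gap pattern it finds is not guaranteed optimal (elitism only guarantees
  monotone fitness). The published method's exact optimizer is not
  reproducible from its description.
* Scan nulls assume the mono-shuffled chromosome is an adequate
  background; genomes with strong regional composition structure
  (isochores, repeat fields) would need per-region nulls.
* The U test inherits the normal approximation; very small supported
  counts would warrant an exact test.
* Scanning cost is linear in genome length × classes × (window/stride);
  chromosome-scale runs at stride 1 are a compute-budget, not an
  algorithmic, question.
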