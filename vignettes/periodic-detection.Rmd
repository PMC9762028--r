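---
title: "Detecting cell-cycle periodic transcripts and drug-sensitivity-related isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-cycle periodic transcripts and drug-sensitivity-related isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclepeaks)
```

## The problem

After a double-thymidine block, a culture traverses the cell cycle in
lockstep, so a series of harvests at increasing times after G1/S release
samples successive cycle phases. A transcript that is periodically
expressed over the cycle should then show one concentrated expression
bump somewhere along the ordered sample series, with the series treated
as circular — the last harvest is followed, biologically, by the first
phase again. `cyclepeaks` implements a reference-free screen for such
transcripts operating directly on an ordered transcripts × samples FPKM
matrix, plus downstream tools: phase assignment and heatmap row
ordering, cross-cell-line intersection of periodic calls, and a
pharmaco-transcriptomic scan that asks whether individual transcript
isoforms track drug IC50 better than their parent genes.

## The peak screen

Write $a_1, \dots, a_N$ for one transcript's FPKM values over the $N$
ordered samples, extended circularly ($a_0 = a_N$, $a_{N+1} = a_1$,
and so on), and $R_i$ for the within-series rank of $a_i$ (largest
value, largest rank). The screen has two parts.

**Part 1 (3-sample window).** Let $S_3(n) = a_{n-1} + a_n + a_{n+1}$ and
pick $n_3 = \arg\max_n S_3(n)$. The transcript passes if

* $r_3 = R_{n_3-1} + R_{n_3} + R_{n_3+1} > r_{3,\min}$ — the peak window
  must hold the series' largest observations, not merely a local rise; and
* $k_3 = a_{n_3} / S_3(n_3) > 0.3$ — the centre must carry a substantial
  share of the window, which rejects windows that collapse in the middle
  (two separated spikes straddling a trough).

**Part 2 (5-sample window).** The same construction with
$S_5(n) = \sum_{i=n-2}^{n+2} a_i$ and its maximizer $n_5$, passing if
$r_5 = \sum_{i=n_5-2}^{n_5+2} R_i > r_{5,\min}$, if the inner three
samples carry most of the window,
$k_5 = (a_{n_5-1}+a_{n_5}+a_{n_5+1})/S_5(n_5) > 0.6$, and if the centre
carries enough of the inner window,
$a_{n_5} / (a_{n_5-1}+a_{n_5}+a_{n_5+1}) > 0.3$. The wider window
tolerates broader waveforms that a 3-sample window truncates.

The default rank-sum floors are $r_{3,\min} = 3N-6$ and
$r_{5,\min} = 5N-15$, i.e. $r_3 > 18$, $r_5 > 25$ for an 8-sample panel
and $r_3 > 24$, $r_5 > 35$ for a 10-sample panel; the closed forms keep
the same stringency — the window may fall short of the best-possible
rank sum by exactly 3 (or 5) rank units — for any panel length $N \ge 5$.

```{r}
unlist(default_thresholds(8))
unlist(default_thresholds(10))
```

A transcript is called **periodic** under the default `union` policy
when either part passes. The two parts overlap deliberately (part 2
re-tests the centre share of the 3-window), so requiring both would be
largely redundant with part 1 alone while discarding the broad
waveforms part 2 exists to keep; union maximizes sensitivity, which is
the screen's stated purpose. `part1_only`, `part2_only` and
`intersection` are available for stricter analyses. The reported
`peak_index` is $n_3$ when part 1 passes, else $n_5$.

### Numerical choices

* **Rank ties** are averaged by default, so $\sum_i R_i = N(N+1)/2$
  always holds and exactly flat (or all-zero) series produce rank sums
  of $3(N+1)/2 < r_{3,\min}$ — constants can never pass. An `ordinal`
  option gives strict permutations for exact-permutation arguments.
* **Window-sum ties** in the argmax resolve to the smallest index — a
  deterministic, input-order-independent rule.
* **Zero denominators**: $k_3$ and $k_5$ are defined as 0 when their
  window sum is 0, so unexpressed transcripts fail rather than divide
  by zero.
* Indices are 1-based everywhere, matching sample numbering in the
  input matrix.

### What the rank screen does and does not control

The rank-sum floors ask whether the top-ranked samples are circularly
contiguous. For an exactly flat series ties force failure, but for an
*irregular* series — iid noise around a constant baseline — the ranks
are a uniform random permutation whatever the noise amplitude, and a
random permutation places its top ranks in one 3-window often enough
that a substantial fraction of pure-noise series passes (for $N = 8$,
four of the fifty-six 3-subsets of ranks already exceed the $r_3$
floor, and the screen may find any of the $N$ windows). The screen is
therefore a *sensitive* peak finder, not a specificity-controlled
test: it is designed to hand a generous candidate list to downstream
filters such as the cross-cell-line phase-consistency restriction. The
acceptance tooling (`scripts/acceptance.R`) measures this background
call rate on simulated flat-plus-noise transcripts alongside the
near-perfect sensitivity on planted bumps; both numbers should be read
together.

## Phases, ordering, and the cross-line intersection

Each periodic transcript inherits the cell-cycle phase of its peak
sample from the user-supplied sample sheet (the package fixes the phase
vocabulary to G1/S, S, G2/M, M-G1 but the per-sample labels are an
input, since phase boundaries differ between synchronization designs).
Heatmap rows are ordered by ascending peak sample with stable ties.

Calls from several cell lines are intersected as plain transcript-id
sets. The stricter "restricted parallel expression" set keeps only
transcripts whose peak phases agree across all datasets up to a ring
distance of 1 — same or adjacent phase, with M-G1 adjacent to G1/S by
the cyclic biology. Adjacency is evaluated pairwise across all
datasets rather than against a reference line: pairwise agreement is
the symmetric reading of "appeared in the same or adjacent phases" and
does not privilege one dataset's phase labelling. Datasets with
different sample counts are compared only at phase level, never by raw
peak index.

## The drug-sensitivity isoform scan

For each drug with exactly one annotated target gene (multitarget
drugs are excluded up front to avoid attributing a correlation to the
wrong target), the scan correlates the drug's IC50 values across cell
lines with (i) the target gene's expression and (ii) each transcript
isoform of that gene, using Spearman's rank correlation. Both
correlations for a record are computed on the identical cell-line
subset — the matched lines with an IC50 evaluation for that drug — so
the gene/isoform comparison is never confounded by differing panels.
Because Spearman correlation is rank-based, it is indifferent to
whether IC50 is supplied raw or log-transformed.

An isoform is flagged **drug-sensitivity-related** when
$|\rho_{\text{transcript}}| - |\rho_{\text{gene}}| \ge 0.1$
(inclusive). The default direction `higher` follows that definition;
`both` also keeps isoforms at least 0.1 *lower*, for listings of
either direction. Two further choices are deliberate:

* a correlation is only computed from at least `min_n = 10` complete
  pairs (below that, the record is marked unavailable, not an error) —
  rank correlations on a handful of lines are dominated by noise, and
  tissue strata in particular would otherwise produce degenerate
  values;
* p-values are reported unadjusted, with Benjamini–Hochberg columns
  added for information only — flagging uses the correlation gap,
  never a significance cut, so the multiplicity of the scan does not
  change which isoforms are flagged.

GDSC1- and GDSC2-style IC50 tables should be run separately, never
merged; they are different assays. Tissue stratification reruns the
whole scan within each tissue having at least `min_n` matched lines.

## The simulator

`simulate_cycle_matrix()` emulates the synchronized time-course
matrices: a periodic transcript is a circular Gaussian bump,
$b + A\,e^{-d(i,p)^2 / 2\sigma_b^2}$ with circular sample distance $d$,
planted peak $p$, baseline $b \sim U(0.5, 5)$ FPKM, amplitude
$A \sim U(5, 50)$ FPKM and bump width $\sigma_b = 1$ sample; an
aperiodic transcript is its constant baseline. Every value is
multiplied by log-normal noise $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$, keeping FPKM non-negative while
perturbing ranks — the quantity the screen actually consumes. Defaults
($N = 8$ or 10 samples, 100 periodic / 400 aperiodic transcripts,
$\sigma = 0.1$) mirror the two panel designs and give bumps that stand
well clear of baseline, as strong cycle-regulated transcripts do.

`simulate_drug_panel()` emulates matched GDSC/CCLE exports for one
drug and one target gene: isoform expression is iid log-normal
(median 5 FPKM, log-sd 0.8) across `n_cells = 50` lines; one driver
isoform sets $\log \mathrm{IC50} = 1.0 \times \text{driver} +
N(0, 0.3)$; the gene is the *sum* of its `n_inert + 1 = 4` isoforms,
which is precisely how a strong isoform-level signal is diluted at
gene level. Optional tissue labels switch the effect on only in chosen
tissues.

What the simulator does **not** emulate: read-level sampling noise and
its mean-variance structure, transcript-length and library-size
coupling between transcripts, correlated co-expression, imperfect
synchronization (phase drift across the series), multi-modal or
skewed waveforms, and multi-drug/multi-gene panels. Passing recovery
tests on these simulations therefore demonstrates that the
implementation realizes the intended algorithm under its own model
assumptions — not that the algorithm's calls on real RNA-seq data are
correct at the same rates.

## Test problem sizes

The shipped tests validate the screen against an independent
brute-force window enumeration on 1000 random series per panel size
($N = 8$ and 10), check the structural invariances (circular-shift
equivariance, positive-scale invariance, rank-sum conservation and
bounds) on generated series, and measure recovery on ten simulated
500-transcript matrices and 100 simulated 50-line drug panels — sizes
chosen to make the stochastic rates stable to well under the margins
being asserted while keeping the default test run quick.

## Known limitations

* The screen's specificity on irregular but aperiodic series is low by
  construction (see above); downstream consistency filters carry that
  burden.
* Thresholds for panels other than 8 or 10 samples come from the
  closed forms $3N-6$ / $5N-15$; they preserve the rank-slack
  interpretation but have not been validated against data at other
  panel lengths.
* Phase assignment trusts the user's sample sheet; no inference of
  phase boundaries from the expression data is attempted.
* The drug scan takes IC50 tables as given — no dose-response fitting,
  no cross-assay harmonization.
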