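---
title: "Quantifying haplotype network complexity with Hd, Bd, and HBd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying haplotype network complexity with Hd, Bd, and HBd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapnetdiv)
```

## The problem

Haplotype networks are the standard way to display relationships among the
mitochondrial (or other non-recombining) sequence variants sampled from a
set of populations. Two networks with the same haplotype frequencies can
look — and be — very different: a star around a single ancestral haplotype
tells a different demographic story than a long chain or a densely
reticulated web. Yet most studies summarize such data with haplotype
diversity alone, which ignores topology entirely. This package computes a
family of indices that put a single, comparable number on *network
complexity*, combining genetic diversity with topological diversity.

## The metrics

All metrics operate on a network whose nodes are haplotypes (with the
number of individuals carrying each) and whose edges are mutational
connections. The degree of a node — its number of *subtending branches* —
assigns it to a **haplotype class**: all haplotypes with the same degree
form one class. A class is described by its branch count `nbHc`, its
number of haplotypes `nhHc`, and its number of individuals `niHc`.

With $n$ individuals, $f_h$ the frequency of haplotype $h$ and $f_{Hc}$
the fraction of individuals in class $Hc$:

* **Haplotype diversity**
  $Hd = \left(1 - \sum_h f_h^2\right)\frac{n}{n-1}$ — the probability that
  two individuals drawn without replacement carry different haplotypes.
* **Branch diversity**
  $Bd = \left(1 - \sum_{Hc} f_{Hc}^2\right)\frac{n}{n-1}$ — the same
  construction applied to haplotype classes: the probability that two
  individuals drawn without replacement fall in different classes. It is 0
  whenever the network has a single class (one or two haplotypes, or a
  pure cycle), increases with the number of classes and with
  frequency-evenness among them, and decreases toward its asymptote
  $1-\sum f_{Hc}^2$ as $n$ grows at fixed class proportions.
* **Haplotype network branch diversity**
  $HBd = \left(1 - \sum_h f_h^2\right)\left(1 - \sum_{Hc}
  f_{Hc}^2\right)\frac{n}{n-1}$ — the combined complexity metric. Because
  classes partition haplotypes, $Bd \le Hd$ and $HBd \le \min(Hd, Bd)$
  always hold.
* **Node diversity**
  $Nd = \left(1 - \sum_{Hc} nhHc \left(\frac{nbHc}{nH}\right)^2\right)
  \frac{nH}{nH-1}$ — an earlier degree-based index. Its inner terms divide
  branch counts by the number of haplotypes $nH$, which is not a
  frequency, so Nd (and its combination $HNd = Hd \cdot Nd$) has no
  probabilistic interpretation; a two-haplotype network already gives
  $Nd = 1$. Values are reported exactly as computed, never clamped, so
  these pathologies stay visible. **HNd** is reported as the plain product
  of its components; the report's settings record this as an assumption,
  since the original combination rule is only documented through its
  analogy with $HBd = Hd \cdot Bd$.
* **Nucleotide diversity** $\pi$ — mean per-site pairwise difference,
  reported for comparison only (it measures genetic distance, not
  topology). It is computed as a plain mean over all $\binom{n}{2}$ pairs,
  without a sample-size correction; since it feeds no other metric, the
  most common convention is used.

### Why HBd carries a single n/(n-1) correction

$HBd$ is implemented literally as the product of the two *uncorrected*
terms times one factor $n/(n-1)$, not as $Hd \cdot Bd$ (which would carry
the correction twice). The single-correction form is what the metric's
published reference values use: for the star network below it gives
0.3499 (reported as 0.35), while the double-corrected product would give
0.37. The `both_corrected = TRUE` flag exposes the alternative for
sensitivity analyses.

## The pipeline

```{r pipeline}
aln <- hap_realize(model_fixtures()$branched21)  # 21 individuals, 6 haplotypes
tab <- hap_collapse(aln)
net <- build_msn(hap_distances(tab), counts = tab$count)
hap_class_decomposition(net)
```

`hap_complexity()` chains these stages and returns a report object with
`tidy()`/`glance()` methods:

```{r report}
glance(hap_complexity(aln, dataset = "three-class model"))
```

### Haplotype collapsing and ambiguity

Two individuals share a haplotype iff their aligned sequences are
identical under the chosen policy. The default, `strict`, compares
character-for-character: it is fully reproducible because no record's
ambiguity codes can affect how other records collapse. The alternative,
`ignore-ambiguous-sites`, drops every alignment column containing an `N`,
a gap, or an IUPAC code in *any* record (complete deletion) before
comparison, so an ambiguous base call cannot split a haplotype. Distances
follow the same policy: under `strict`, columns where either sequence of
a pair is ambiguous are skipped for that pair (pairwise deletion), which
means two *distinct* haplotypes can sit at distance 0 — the network
builder tolerates 0-weight edges for this reason.

### Network construction

The network is a minimum spanning tree of the haplotype distance matrix
(Kruskal's algorithm, edges sorted by weight then by node indices so that
ties resolve deterministically), augmented with **alternative links**:
every non-tree pair whose distance is within `epsilon` of the largest
weight on the tree path between its endpoints. With the default
`epsilon = 0` these are exactly the equal-cost connections another
tie-break could have chosen — the classic minimum spanning network. Edge
weights are kept for export but enter no metric; only the *number* of
branches at each node matters, just as Hd is blind to the distances
between haplotypes.

Whether alternative links should count toward node degrees (and so toward
haplotype classes) is genuinely open — network drawings display them, but
a degree convention is nowhere fixed. Both behaviors are exposed; the
default (`count_alternative = TRUE`) counts them, matching what a reader
of a drawn network would count, and `--no-alt-links` / `count_alternative
= FALSE` disables them. Metrics can also be computed on networks built by
any other method via `read_network()`, since the indices are agnostic to
how the network was constructed.

### Degenerate inputs

A network needs at least two haplotypes and two individuals. Below that,
the metrics are undefined: the default is an error, and `lenient = TRUE`
instead reports all network metrics as 0 with a `degenerate` flag — a
convention, not a computed value, appropriate when batch-processing many
datasets of which some are monomorphic.

## The synthetic generator

`hap_spec()` describes a network as a tree over haplotype indices plus
individuals-per-haplotype; `hap_realize()` turns it into an alignment by
assigning each tree edge its own block of unique sites (background all
`A`, mutations cycling A→C→G→T). Because no site is reused, pairwise
haplotype distances equal tree path lengths, the MST of the realized
sequences is unique, and the pipeline provably recovers the requested
topology — which is what makes golden tests against fixed reference
values deterministic.

The shipped fixtures (`model_fixtures()`) realize the model networks with
reference class breakdowns: a 21-individual star with classes `(1:15, 5:6)`,
a 21-individual three-class network `(1:15, 2:3, 4:3)`, and a
48-individual two-even-class path `(1:24, 2:24)`. Where a model network's
exact haplotype split is not fixed by the class breakdown, the star's `{6,3,3,3,3,3}` split is
forced: it is the unique integer partition of 15 over five tips consistent
with the reference Hd of 0.86. Parameterized families (`spec_star()`,
`spec_chain()`, `spec_random_tree()`) support the property sweeps: class
count from 2 to 8 at even frequencies, evenness perturbations at fixed
class count, and sample sizes from 10 to 1000 at fixed proportions —
sizes chosen so each sweep isolates one property while remaining
desk-scale.

What the generator does *not* emulate: realistic mutation models
(homoplasy, back-mutation, rate variation), recombination, missing data,
or sampling noise. Passing tests on realized alignments therefore show
that the pipeline computes the metrics correctly on networks whose true
topology is known — not that distance-based networks reconstruct the true
genealogy of real data, which is a property of the data, not of the
metrics.

## Numerical and design choices

* **Rounding for display** is half-away-from-zero to 2 decimals (the
  convention of published diversity tables); full precision is always
  also emitted. One commonly cited reference value (the three-class model network's
  HBd, 0.39) is inconsistent with its own class/haplotype structure, which
  yields 0.3848; the package reports the full-precision value and treats
  the rounded one as a typesetting artifact.
* **Determinism**: identical inputs and settings give byte-identical
  outputs. The only randomness in the package is `spec_random_tree()`,
  which takes an explicit seed.
* **Tie-breaks**: haplotype ordering is by descending count then first
  occurrence; MST edge order is (weight, smaller index, larger index).
* **Scale**: all algorithms are quadratic (or better) in the number of
  haplotypes except MST path queries, which are cubic in the worst case —
  irrelevant at the tens-to-hundreds of haplotypes of real datasets.

## Limitations

* Inputs must be pre-aligned; the package does not align sequences.
* Only distance-based MSN construction is built in; median-joining,
  statistical parsimony and similar methods must be run elsewhere and
  imported via `read_network()`.
* Population labels are carried through for reporting and coloring only;
  no metric is population-stratified.
* No confidence intervals or tests comparing two networks are provided;
  the metrics are point descriptions of a sample.
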