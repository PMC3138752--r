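---
title: "Condensing GO term lists: models, parameters and design choices"
author: "GOcondense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condensing GO term lists: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOcondense)
```

## The problem

Functional-enrichment analyses routinely return dozens to hundreds of
significant Gene Ontology (GO) terms, many of which describe nearly the same
biology at slightly different levels of detail: a parent term such as
*biosynthetic process* fully encompasses each of its children, so reporting
both adds length without adding information. GOcondense reduces such lists by
clustering semantically similar terms and keeping one representative per
cluster, guided by the statistical values (p-values or enrichments) the user
obtained upstream. The package consumes enrichment output; it does not
perform enrichment testing itself.

## Information content

The semantic machinery rests on how specific a term is within an annotation
corpus. After true-path propagation (an annotation to a term implies
annotation to every ancestor, deduplicated per annotated entity), the
relative frequency of term $t$ is

$$p(t) = \frac{\text{propagated count}(t)}{\text{propagated count}(\text{namespace root})},$$

and its information content is $IC(t) = -\log p(t)$. We use the natural
logarithm; no base is canonical in the semantic-similarity literature, and
the base cancels in the ratio-based measures (Lin, SimRel) while only
rescaling Resnik and the Jiang–Conrath distance uniformly. Terms of the
ontology absent from the corpus receive pseudo-count 1 — the largest IC the
corpus can support — so user lists may cite terms the chosen annotation set
never uses. Propagation deduplicates per entity (a protein with two
annotations under one ancestor counts once for that ancestor), matching the
"fraction of annotated proteins" interpretation of term frequency.
Species-specific corpora are obtained by filtering a GAF file on taxon
identifiers rather than by maintaining separate databases; the result is the
same counts.

## Similarity measures

All four supported measures are functions of the most informative common
ancestor (MICA) $m$ of a pair $(a, b)$ — the shared ancestor with maximal
IC, where each term counts among its own ancestors, and IC ties break to the
lexicographically smallest accession:

* Resnik: $IC(m)$;
* Lin: $2\,IC(m) / (IC(a) + IC(b))$, defined as 0 when both IC are 0
  (no shared information, and it avoids 0/0 at the roots);
* SimRel: Lin $\times\ (1 - p(m))$, which pushes pairs whose only common
  ancestors are frequent, shallow terms toward 0 — the default measure;
* Jiang–Conrath: the literature defines a distance
  $d = IC(a) + IC(b) - 2\,IC(m)$; the clustering cutoff and the matrix
  contract need a bounded similarity, so we map it monotonically to
  $1/(1+d) \in (0, 1]$.

GO namespaces share no ancestors, so cross-namespace similarity is defined
as 0, cross-namespace MICA queries are errors, and the pipeline partitions
the user list by namespace. Parent edges traverse `is_a` and `part_of` by
default — `part_of` carries the same containment semantics as `is_a` for
annotation propagation — and the relation set is configurable in
`loadOBO()`.

## The reduction algorithm

`reduceTerms()` is a greedy agglomeration over the user's terms. Repeatedly,
the most similar pair among the current representatives is found (ties break
to the lexicographically smallest pair); if that similarity is below the
cutoff $C$ the procedure stops, otherwise one member of the pair is removed
and its cluster absorbed by the survivor. The removed term's
*dispensability* is the similarity at which it was merged away. On
termination no two representatives are more similar than $C$; a surviving
representative's dispensability is defined as its maximal similarity to any
other final representative (0 when alone), which makes "representatives are
the terms with dispensability below $C$" literally true and testable. Each
term belongs to exactly one cluster. The presets $C \in \{0.9, 0.7, 0.5,
0.4\}$ correspond to progressively shorter lists; 0.7 is the default, and
0.4 should be used cautiously since merges near that level may lack strong
semantic support.

Which member of a merged pair is removed follows a fixed cascade
(`chooseLoser()`):

1. a *pinned* term always survives (merging two pinned terms is an error
   surfaced to the caller);
2. a *very general* term — relative frequency above
   `generalFrequencyThreshold` — is removed; if both are general, the more
   frequent one is. General terms are uninformative as representatives. The
   threshold defaults to 0.25: it excludes near-root terms while keeping
   mid-level biology; the value is a package choice, exposed in
   `reductionConfig()`.
3. if user values differ decisively — more than `valueClosenessLog10`
   (default 1.0, i.e. one order of magnitude) apart on the log10 scale —
   the less significant term is removed. "Quite close" needed an explicit
   quantification; one decade is the coarsest unit practitioners use when
   comparing p-values, and it is configurable. When the list carries no
   values, uniqueness (below) is compared at this step instead, the less
   unique term losing.
4. for close values, ancestry decides: the child is removed so the more
   established parent represents the cluster — unless the child accounts
   for more than `parentAbsorptionRatio` (default 0.75) of the parent's
   annotations, in which case the two are de facto equivalent and the
   parent is rejected instead. The ratio is computed on propagated
   annotation counts.
5. otherwise the term with lower uniqueness is removed;
6. a final tie removes the lexicographically larger accession.

There is no randomness anywhere in the reduction; identical inputs give
identical output.

*Uniqueness* is the negative of a term's mean similarity to all other input
terms, computed on the full input matrix (never on the shrinking
representative set), so it measures outlierness with respect to the whole
list and is independent of the user's values. Dispensability and uniqueness
tend to be anticorrelated but measure different things — dispensability is
also shaped by the supplied values. An optional rescaled uniqueness column
(1 + value) can be derived by the caller; the package reports the value as
defined.

## Calibrating the cutoff against chance

`backgroundQuantile()` draws seeded random within-namespace pairs of
distinct terms and returns the similarity exceeded by a chosen percentage of
pairs (empirical upper quantile, type-1). Setting $C$ at the 1% background
quantile means each within-cluster similarity would arise by chance only 1%
of the time. The resulting threshold depends on the ontology and annotation
snapshot, so the package treats it as a per-corpus calibration to run, not a
constant to hard-code.

## Scatterplot layout

`mdsLayout()` converts similarities to distances via $d = 1 - s$ (the
simplest monotone map onto $[0,1]$; $d = \sqrt{1-s}$ is available since the
squared-distance variant is metric for some measures). Classical scaling —
eigen-decomposition of the double-centred squared-distance matrix, top two
axes — gives the initial configuration, refined by SMACOF stress
majorization. The reported stress is
$\sqrt{\sum_{i<j}(d_{ij}-\delta_{ij})^2 / \sum_{i<j}\delta_{ij}^2}$ with
$\delta$ the fixed target distances; normalizing by the *target* distances
(rather than the moving configuration distances) is what the Guttman
transform provably decreases at every step, so the stress trace is monotone
non-increasing by construction. Convergence: relative stress change below
`tolerance` (default 1e-6) or `maxIterations` (default 300). Degenerate
inputs are defined exactly: one term sits at the origin, two terms sit $d$
apart on the x axis, all-equal terms collapse to the origin, and a rank-1
spectrum yields a zero second axis.

## Similarity graph and exports

`buildGraph()` keeps the strongest `edgeFraction` (default 0.03) of
representative pairs as edges; the fraction is applied after redundancy
reduction, since the graph visualizes the non-redundant set. The edge count
is round-half-up with a floor of one edge whenever any pair exists, and
similarity ties break by lexicographic pair order so the edge set is
invariant under input permutation. Exports are XGMML (Cytoscape) and
GraphML, with node attributes name, value, frequency (bubble-size
semantics), uniqueness, dispensability, and the edge attribute similarity.

## Treemaps and keywords

The treemap is a two-level hierarchy: representatives joined into
*superclusters* of loosely related terms. Rather than invent a second
clustering semantic, the same reduction algorithm is re-run on the
representatives at a much looser cutoff (`superCutoff`, default 0.10);
each survivor labels a supercluster containing the representatives it
absorbed. A non-positive cutoff degenerates to one supercluster per
representative. Rectangle sizes are $-\log_{10} p$ (floored at 0.01 so
sizes stay positive) or the term frequency in percent.

Keyword (tag-cloud) statistics tokenize term *names* on non-alphanumerics,
lowercase, and drop tokens shorter than three characters and stopwords
(standard English plus GO boilerplate: process, regulation, activity,
positive, negative, cell, cellular — configurable). Overrepresentation is
scored by a smoothed log-odds $\log_2((f_\text{list}+0.5)/(f_\text{bg}+0.5))$
on per-term occurrence fractions; a formal test would imply precision the
small user lists cannot support, while the log-odds is monotone and robust.
Only positive (overrepresented) keywords are retained. Value-correlated
keywords use the point-biserial correlation (Pearson on the presence
indicator) against $-\log_{10} p$ or $\log_{10}$ enrichment; tokens present
in all or no terms are skipped. Definitions could be tokenized as well;
names-only is the default because definitions mix in citation and
provenance text.

## Synthetic data

`randomOntology()` grows a rooted single-namespace DAG (every non-root term
attaches to one or, with probability 0.3, two earlier terms) and emits OBO
text that is re-parsed through the production reader. `randomAnnotations()`
assigns one to three annotations per entity with leaf-biased power-law term
popularity (exponent `concentration`, default 1.5) and emits GAF 2.2 text
parsed back through `readGAF()`. Both are fully deterministic under their
mandatory seeds. The generator reproduces the *structural* properties the
algorithms depend on — acyclicity, single roots, true-path-consistent
counts, heavy-tailed term usage — but not real GO topology statistics
(depth distribution, term fan-out, inter-namespace structure) or real
annotation biases; green tests on fixtures therefore demonstrate
correctness of the algorithms, not biological performance on real corpora.

The seven-term worked example (`workedExampleFixture()`) reconstructs the
published toy dataset of brain-development terms co-expressed with the
transcription factor ZNF417. Its similarity matrix contains the four
published SimRel values (0.72, 0.74, 0.62, and 0.40 between the two
non-singleton representatives); all unpublished off-diagonal entries are
set to 0.10, well below every published value and preset cutoff. The
original p-values are not available; the fixture uses synthetic p-values
spaced two decades apart in the published significance order, so every
pairwise comparison is decisively outside the one-decade closeness
tolerance and significance alone selects the representatives — matching
the narrative the dataset illustrates. At $C = 0.5$ this reduces to four
clusters, two of them singletons.

## Worked example

```{r}
fx <- workedExampleFixture()
cl <- reduceTerms(fx$matrix, fx$records, reductionConfig(cutoff = 0.5))
cl
fx$names[representatives(cl)]
dispensability(cl)["GO:0021895"]  # cerebral cortex neuron differentiation
```

## Numerical choices and degenerate inputs

* All tie-breaks are lexicographic on accessions; no operation is random
  except the explicitly seeded background sampling and fixture generation.
* The empirical quantile is type-1 (inverse ECDF), so "percentile 100"
  returns the minimum sampled similarity exactly.
* An empty term list reduces to an empty result; a single-term matrix has
  uniqueness 0; a lone representative has dispensability 0.
* Obsolete terms are kept for identifier resolution (alt-id, replaced-by)
  but excluded from traversal; annotations to unresolvable terms are
  dropped with a warning.
* Frequency tables are validated against parent–child count monotonicity
  when a graph is supplied, with violations reported per edge.

The test suite exercises these paths on fixture ontologies of 40–500 terms
with 80–400 annotated entities and background samples of 400–1000 pairs —
sizes at which every brute-force oracle (recursive ancestor walks,
exhaustive common-ancestor enumeration, per-entity propagation recounts)
remains exact and fast.

## Limitations

* Only OBO 1.2/1.4 flat files are parsed (the GO distribution format); OWL
  is out of scope, as are cross-ontology mappings and GO-slim mapping.
* The flowchart details of the original representative-choice rule are not
  fully published; the cascade above is an explicit reconstruction with
  every threshold configurable, and the two unstated constants (0.25
  general-term frequency, one-decade value closeness) are package choices.
* Cluster membership is exclusive by design; overlapping clusters are
  deliberately not supported.
* The published 1%-background SimRel threshold (0.53 against a 2011
  GO/GOA snapshot) is corpus-dependent; rerun `backgroundQuantile()`
  against your own annotation source instead of reusing that constant.
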