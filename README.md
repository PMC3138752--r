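# GOcondense

Functional-enrichment analyses of gene lists routinely end in a long,
partially redundant list of significant Gene Ontology (GO) terms — parents,
children and siblings describing the same biology at slightly different
granularity. GOcondense condenses such lists for the people who produce
them (anyone running GO enrichment downstream of expression, proteomics or
screening experiments): it clusters semantically similar terms, picks one
representative per cluster guided by the user's p-values or enrichments,
and computes the coordinates and structures behind the standard summary
views — semantic scatterplots, thresholded similarity graphs
(XGMML/GraphML), two-level treemaps and tag-cloud keyword statistics.

## The method in brief

For terms *a*, *b* with most informative common ancestor *m* (the shared
ancestor with maximal information content, IC(t) = −log p(t), where p(t) is
the term's relative annotation frequency in a reference corpus):

- Resnik: IC(m)
- Lin: 2 IC(m) / (IC(a) + IC(b))
- SimRel (default): Lin × (1 − p(m))
- Jiang–Conrath: 1 / (1 + IC(a) + IC(b) − 2 IC(m))

The reduction is greedy agglomeration: while the most similar pair of
remaining representatives is at least the cutoff *C* (presets 0.9, 0.7
(default), 0.5, 0.4), one member is merged away — pinned terms always
survive, very general terms never do, decisively different p-values decide
directly, close p-values defer to ancestry (keep the parent, unless the
child makes up >75% of it), then to uniqueness (negative mean similarity to
the whole list). A removed term's *dispensability* is the similarity at
which it was merged; representatives are exactly the terms with
dispensability below *C*. Layouts come from classical scaling plus SMACOF
stress majorization on d = 1 − similarity.

Inputs: an OBO ontology, annotation evidence as a GAF 2.x file (with
optional taxon/IEA filtering) or a two-column frequency table, and a plain
text term list (`GO:XXXXXXX [value]` per line, `#` comments).

## Worked example

The package ships a seven-term example — gene functions co-expressed with
the human transcription factor ZNF417, a brain-development signature — with
published SimRel similarities:

```r
library(GOcondense)
fx <- workedExampleFixture()
cl <- reduceTerms(fx$matrix, fx$records, reductionConfig(cutoff = 0.5))
cl
#> TermClusters: 7 terms in 4 clusters (2 singletons), cutoff C = 0.5
fx$names[representatives(cl)]
#>                                          GO:0021537
#>                         "telencephalon development"
#>                                          GO:0045686
#> "negative regulation of glial cell differentiation"
#>                                          GO:0042053
#>          "regulation of dopamine metabolic process"
#>                                          GO:0007606
#>           "sensory perception of chemical stimulus"
mergeLog(cl)
#>      removed   absorber similarity
#> 1 GO:0048708 GO:0045686       0.74
#> 2 GO:0021895 GO:0021537       0.72
#> 3 GO:0045665 GO:0045686       0.62
```

The merge log reads: *astrocyte differentiation* (0.74) and *negative
regulation of neuron differentiation* (0.62) fold into the cluster of
*negative regulation of glial cell differentiation*, and *cerebral cortex
neuron differentiation* joins *telencephalon development* at similarity
0.72 — which becomes its dispensability:

```r
dispensability(cl)["GO:0021895"]
#> GO:0021895
#>       0.72
```

The highest remaining pairwise similarity (0.40) is below C = 0.5, so the
clustering stops with four representatives; the two terms never absorbed
into any cluster remain as singletons.

A full run on files goes through `runPipeline()` (or the CLI wrapper in
`inst/cli/gocondense.R`, subcommands `reduce`, `calibrate`, `fixtures`):

```r
bundle <- runPipeline("go.obo", "terms.txt", gafPath = "goa.gaf",
                      config = reductionConfig(cutoff = 0.7),
                      outputDir = "out")
# out/results_<ns>.tsv, graph_<ns>.xgmml, treemap_<ns>.json, keywords_<ns>.tsv
```

The results table columns are term_id, name, value, frequency_percent,
uniqueness, dispensability, representative_id, is_representative, plot_x,
plot_y, with each cluster's representative listed first.

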