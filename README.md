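# ceRNAnet

Inference of lncRNA–mRNA competing endogenous RNA (ceRNA) networks from
shared miRNA interactions.

Under the ceRNA hypothesis, a lncRNA can regulate an mRNA by competing for
the miRNAs both transcripts bind. `ceRNAnet` is an R package for systems
biologists who have (a) candidate lncRNA–miRNA and miRNA–mRNA interaction
tables and (b) a two-group expression profile, and who want the
significance-filtered bipartite lncRNA–mRNA network that those data imply,
together with its key lncRNAs, dense functional modules, enrichment
results, and per-lncRNA ceRNA sub-networks.

## The statistic at the core

For a lncRNA with *n* miRNA partners and an mRNA with *t* partners drawn
from a background universe of *m* miRNAs, sharing *r* partners, the pair's
significance is the hypergeometric upper tail

P = 1 − Σ<sub>i=0</sub><sup>r−1</sup> C(t, i) · C(m−t, n−i) / C(m, n)

computed in log space. Differentially expressed lncRNA/mRNA pairs with
raw P < 0.01 (default) form the ceRNA network. Downstream, the package
checks scale-free topology (log–log OLS of the degree distribution),
selects key lncRNAs as the intersection of the top-10 degree, betweenness
and closeness lists (boundary ties included), finds modules with a
faithful MCODE implementation (vertex weighting by core-clustering
coefficient, seed expansion at node score cutoff 0.2, fluff and haircut),
and runs hypergeometric over-representation analysis against GMT gene-set
collections with Benjamini–Hochberg correction.

A synthetic-data generator (`simulationConfig()`, `simulateCeRNAStudy()`)
produces interaction tables and expression matrices with planted ceRNA
pairs, hub lncRNAs and differential expression, so the entire workflow is
testable without any database downloads.

## Worked example

```r
library(ceRNAnet)
demo <- runSyntheticDemo(seed = 1)   # simulate a study, run the pipeline

demo$result$network
#> CeRNANetwork: 7 lncRNAs + 41 mRNAs, 42 edges (alpha = 0.01, m = 200 miRNAs, 197 pairs tested)

head(cernaEdges(demo$result$network)[, c("lncRNA_id","mRNA_id","t","n","r","p_value")], 3)
#>   lncRNA_id  mRNA_id  t  n r      p_value
#> 1   LNC0044 MRNA0071 16 10 9 9.411463e-11
#> 2   LNC0044 MRNA0057 18 10 9 3.960891e-10
#> 3   LNC0021 MRNA0008 14  9 8 4.768916e-10

demo$result$key_nodes$key_nodes
#> [1] "LNC0002" "LNC0005" "LNC0007" "LNC0021" "LNC0030" "LNC0038" "LNC0044"

demo$result$power_law
#> Power-law degree-distribution fit: slope -0.8501, intercept 1.2503, R^2 = 0.5119 (3 degree classes)
```

Reading this: of 197 differentially expressed lncRNA/mRNA pairs sharing at
least one background miRNA, 42 pass the hypergeometric test at P < 0.01 —
including all 41 planted pairs (the top rows share 8–9 miRNAs out of a
200-miRNA universe, hence P ≈ 10⁻¹⁰). The three planted hub lncRNAs
(`LNC0002`, `LNC0021`, `LNC0044`) all appear in the three-way top-10
centrality intersection, which also admits the lower-degree lncRNAs because
this small network has only seven lncRNA nodes.

Individual stages are exported and composable: `differentialExpression()`,
`filterCandidates()`, `buildTripleNetwork()`, `cernaPValue()`,
`extractCernaNetwork()`, `computeCentralities()`, `fitPowerLaw()`,
`selectKeyNodes()`, `mcodeFindModules()`, `enrichGeneSets()`,
`extractSubnetwork()`, `intersectRegulators()`. `runPipeline()` accepts a
flat YAML configuration and writes every stage's table, a GraphML export,
a Newick clustering tree and a JSON run report. Quick spot checks:

```r
cernaPValue(10, 4, 3, 2)                       # 0.3333333
benjaminiHochberg(c(0.005, 0.011, 0.02, 0.04)) # 0.0200 0.0220 0.0267 0.0400
```

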