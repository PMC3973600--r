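---
title: "Methods: interolog networks and dual-platform differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interolog networks and dual-platform differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

rhizonet reimplements, as reusable and testable functions, the computational
core of a classic systems-biology workflow for rhizobial bacteroids: infer a
protein–protein interaction (PPI) network for a newly sequenced genome by
interolog transfer, call differentially expressed genes between bacteroids and
free-living cells on two platforms, overlay expression on the network to
extract biologically coherent subnetworks, and summarise the results at the
genome level. This vignette records the models behind each stage, the
parameters that matter, and the design choices made where the published
procedure left them open.

## Interolog network inference

Two proteomes are compared by reciprocal similarity search. A hit is retained
when its e-value is strictly below $10^{-5}$ and its fractional identity and
coverage are at least $0.3$ and $0.7$ respectively. Published descriptions of
such filters rarely say which sequence "coverage" refers to; rhizonet computes
it on **both** sequences and takes the minimum,

$$\mathrm{cov} = \min\!\left(\frac{L_{aln}}{L_{query}},
                             \frac{L_{aln}}{L_{subject}}\right)
                 \;\text{clamped to } [0,1],$$

which is conservative, symmetric in the two search directions, and makes the
bidirectional-best-hit (BBH) relation symmetric. Among passing hits the best
hit per query minimises the e-value, with ties broken by the larger bitscore
and then the lexicographically smaller subject identifier; the ordering is
fully deterministic across platforms. A pair $(a, b)$ is an ortholog pair when
each is the other's best hit.

One subtlety uncovered by property testing: *loosening* a threshold is not
guaranteed to preserve BBH pairs. A hit that previously failed the identity
filter can, once admitted, have a smaller e-value than the incumbent best hit,
displace it, and destroy a reciprocal pair. The monotonicity that intuition
expects holds only when every ortholog pair's reciprocal hits dominate all
sub-threshold hits — the regime of genuine proteome comparisons, and the one
the synthetic generator reproduces.

Reference interactions $(x, y)$ transfer to the target as
$(\mathrm{map}[x], \mathrm{map}[y])$ when both endpoints are mapped; edges are
canonicalized ($\mathrm{node}_a < \mathrm{node}_b$ lexicographically),
self-loops arising from endpoint collapse are dropped (every downstream
analysis assumes a simple graph), and merging across reference organisms
unions edge sets while keeping organism labels as provenance. Edges are
deliberately unweighted: the number of supporting organisms is recorded but
never used as a confidence score, matching how such merged networks are
treated downstream. The published network this workflow emulates is reported
once as "10 306" non-redundant interactions and once as 10 307 edges; the
one-edge discrepancy is unexplained in the source and irreproducible without
the original data, so rhizonet simply reports whatever count its own merge
produces.

## Differential expression

### Sequencing arm

Expression level is RPKM, $10^9 C / (N L)$ for $C$ reads on a gene of length
$L$ (annotated nucleotide length, end − start + 1) in a library of $N$ mapped
reads; the per-condition level is the mean over replicates of per-sample RPKM.
The publication era this pipeline reproduces never named its count test;
rhizonet adopts the two-sided exact binomial test on pooled per-condition
counts (the Audic–Claverie-equivalent standard of BGI-style pipelines):
conditional on $c_1 + c_2$, the count $c_1$ is binomial with success
probability $N_1/(N_1+N_2)$ under the null, and the two-sided p-value sums all
outcomes at most as likely as the observed one. Benjamini–Hochberg q-values
are computed across genes, and a gene is called up when
$\log_2 \mathrm{FC} \ge 1$ (the ratio bound "above 2" and the restatement
"$|\log_2| \ge 1$" conflict; the inclusive reading is used) and
$q \le 0.001$; down symmetrically. Genes expressed in only one condition carry
$\pm\infty$ sentinels and are called only when the nonzero side reaches the
expression floor (RPKM 1 by default); they are excluded from correlations.

Two statistical caveats are inherent to this method family and are visible in
the package's own simulations:

* **Overdispersion.** The exact binomial test assumes all variation is
  sampling variation. Under negative-binomial counts its p-values become
  anti-conservative roughly in proportion to the dispersion: in the package's
  simulations, realized false-discovery proportions at nominal $q \le 0.001$
  stay below $2\times$ nominal for dispersions up to about $0.01$
  (technical-replicate scale) but reach several percent at dispersion
  $0.05$–$0.1$ (biological-replicate scale). The study design being emulated
  sequenced one library per condition, so the generator's sequencing arm
  models technical resampling (dispersion $0.01$ by default) and the
  biological replication lives in the array arm.
* **Compositional bias.** Library-total normalisation makes calls relative:
  when strongly expressed genes absorb a large fraction of one condition's
  reads, unchanged genes drift toward "down" calls. The plasmid-biased
  up-regulation scenario triggers exactly this artifact, which is one reason
  modern pipelines use robust size factors. rhizonet reproduces the historical
  behaviour faithfully rather than correcting it.

### Array arm

Intensities are assumed already normalised. The moderated statistic is

$$d = \frac{\bar{x}_b - \bar{x}_a}{s + s_0}, \qquad
  s = \sqrt{\left(\tfrac{1}{n_a} + \tfrac{1}{n_b}\right)
            \frac{SS_a + SS_b}{n_a + n_b - 2}},$$

with the fudge constant $s_0$ defaulting to the median of gene-wise pooled
standard errors — a deterministic one-pass simplification of the original
percentile search, overridable through `sam_params()`. Significance comes from
permuting the sample-to-condition assignment: when the requested permutation
count reaches the number of distinct assignments the enumeration is exhaustive
and $p$ is the fraction of assignments (including the observed one) with
$|d^*| \ge |d|$; otherwise assignments are sampled and the add-one-corrected
$(b+1)/(B+1)$ estimate is used. With three replicates per condition there are
only $\binom{6}{3} = 20$ distinct assignments and, because balanced
assignments pair with their complements, the attainable p-value floor is
$2/20$; BH q-values then essentially never pass $q \le 0.05$. Array calls are
therefore only informative from about five replicates per condition upward —
a granularity property of the permutation procedure itself, worth knowing
before interpreting an empty array call set. Where the original analysis said
"p/q value" without specifying, classification applies the threshold to the
q-value by default; the nominal p is also returned.

### Platform comparison

`compare_platforms()` reports the Venn decomposition of the two call sets and
Pearson's correlation of $\log_2$ fold changes over genes measured on both
platforms with finite values in both. The generator's `array_compression`
parameter (default $0.5$) multiplies true $\log_2$ ratios on the array side to
emulate the well-known dynamic-range compression of hybridisation data; it
changes slopes, not ranks, so correlations remain high.

## Expression overlay and subnetworks

`overlay_expression()` annotates every network node with one platform's
results (sequencing by default — the platform with the greater dynamic range —
or the intersection rule `"both"`); nodes without measurements are flagged and
never seed a subnetwork.

Two extraction procedures are provided because the published 113-node
nitrogen-fixation subnetwork (78 of whose genes passed a 5-fold screen) does
not document how its remaining nodes entered:

* **Fold-change thresholding** (`fold_threshold_subnetwork()`): seeds are
  measured nodes with expression ratio $\ge 5$ or $\le 1/5$ (sentinel ratios
  $0$ and $\infty$ qualify when the nonzero side reaches the floor); non-seed
  *linkers* adjacent to at least two seeds are added; the induced subgraph is
  taken and components with fewer than two seeds are discarded. The
  ≥2-seed-neighbour linker rule is this package's reconstruction of the
  undocumented step — it admits exactly the nodes that connect screened genes
  without letting single attachments balloon the result.
* **Greedy active-module search** (`search_active_modules()`): per-node
  p-values become $z_i = \Phi^{-1}(1 - p_i)$ (p clamped to
  $[10^{-15}, 1 - 10^{-15}]$), a node set scores
  $z_A = \sum z_i / \sqrt{k}$, and the background-corrected score is
  $s_A = (z_A - \mu_k)/\sigma_k$ with $\mu_k, \sigma_k$ estimated from seeded
  Monte-Carlo draws of random $k$-subsets of the measured nodes (1000 draws by
  default; one set of random orderings yields every $k$ via cumulative sums).
  From every seed (measured node with $p < 0.05$) the search greedily adds the
  neighbouring measured node that maximally increases $s_A$ until no addition
  improves the score or `max_k` is reached. Results are ranked by $s_A$ and
  de-duplicated: walking down the ranking, a module is kept only when its
  Jaccard overlap with every kept module is below $0.5$ — a deterministic rule
  chosen because the plugin lineage this follows leaves de-duplication
  unspecified. Simulated annealing, the historical alternative mode, is
  deliberately not implemented: greedy search with a calibrated background is
  deterministic and sufficient at desk scale. Under a uniform-p null the
  $s_A$ of random modules is standardised (mean ≈ 0, SD ≈ 1), which the test
  suite verifies directly.

Regulator-centred subnetworks use `ego_subnetwork()`: all nodes within graph
distance 2 of the focal node (first neighbours, then their first neighbours),
with induced edges — the procedure behind the CtrA cell-cycle subnetwork.

## Enrichment and genome-level summaries

Term enrichment is the exact hypergeometric upper tail
$P(X \ge k)$ for $k$ annotated query genes out of $n$, with $K$ of $M$
universe genes annotated, BH-corrected across retained sets. Annotations are
flat sets (no GO-graph propagation); gene sets are restricted to the universe
before the size filter applies. The universe defaults to the analysis context:
network nodes for module queries, the whole gene table for genome-wide
queries. Weighted running-sum GSEA is out of scope; the hypergeometric test
substitutes for both the GO and the pathway analyses.

Genome summaries follow the printed-table conventions: COG tallies expand
multi-letter category strings to one count per letter; replicon proportion
tables append a Total row and round percentages **half-up** to two decimals
(matching printed precision; note that one published chromosome percentage,
14.56%, recomputes to 14.55% from its own counts — rhizonet reports the
recomputed value). Sliding-window profiles walk genes in genomic order in
windows of 50 genes (step = window by default; whether the original windows
overlapped is not documented, so the step is configurable), reporting per-window
call percentages and pooled GC content; a trailing window is kept when it
holds at least half a window's genes. `topn_share()` computes the fraction of
total expression held by the top-n genes with ties broken by identifier.

## The synthetic-data generator

Every stage above is exercised against `simulate_study()`, whose defaults
encode the structure of the bacteroid study: three replicons (two symbiosis
plasmids of 257 and 447 genes at GC 0.59, one chromosome of 6562 genes at GC
0.63 — the ~0.04 plasmid GC deficit reflecting the observed pattern), planted
up/down fractions per replicon equal to the published proportions (22.96%/7.00%
plasmid-a, 23.49%/5.82% plasmid-b, 10.70%/14.56% chromosome), two reference
proteomes (90% and 60% of the target's size, standing in for a congeneric and
a distant reference), ortholog fraction 0.7, one reference network of 3000
edges per organism (the congeneric reference network literature reports
interaction counts of this order), a planted connected module of 25
ortholog-mapped genes forced to be up-regulated, negative-binomial counts
(dispersion 0.01, see above), log-normal intensities with replicate noise SD
0.25 on the log2 scale, and array compression 0.5. Planted absolute log2 fold
changes are $|N(2, 0.5)|$ floored at 1 so every planted gene is truly
at least 2-fold. Where the study reports no value these defaults were chosen
once as field-realistic and are not tuned.

Spurious similarity hits come in two flavours, each generated explicitly
(sequence search itself is out of scope — the BBH logic, not alignment, is the
computation under test): hits that fail the identity threshold outright, and
hits that pass all thresholds but are non-reciprocal by construction (directed
at an already-mapped reference gene whose best reverse hit is its planted
partner, with e-values above every planted hit). Planted orthology therefore
remains exactly recoverable at any noise rate, and is verified to be recovered
with precision = recall = 1 at noise 0.

All randomness flows from one integer seed through deterministic sub-seed
derivation; identical configurations reproduce byte-identical studies, which
the test suite asserts by serialisation.

**What the generator does not emulate** — and what passing tests therefore do
not show about real data: sequencing reads and mapping artifacts (counts are
drawn, not aligned), probe-level array effects and normalisation, operon
structure and the spatial clustering of differential expression along the
genome (planted DE genes are placed uniformly within a replicon), in-paralog
families (the planted ortholog map is one-to-one), correlated evolution of
interacting proteins, and any host-plant signal.

## Numerical choices and problem sizes

Percentage rounding is half-away-from-zero at two decimals. p-values of
exactly 0 or 1 are clamped to $[10^{-15}, 1-10^{-15}]$ before the normal
transform. Zero-information count pairs ($c_1 + c_2 = 0$) receive $p = 1$ with
a message. All tie-breaks (best hits, top-n, module ranking) resolve through
lexicographic identifiers so results are platform-independent. The test suite
runs its property checks at sizes chosen for tight feedback: 8×8 proteomes for
exhaustive BBH enumeration, universes up to 30 for hypergeometric enumeration,
300-node networks with 15-node planted modules over 10 seeds for module
recovery, and 20 replicate simulations of 2000 genes for error-control and
power checks; the acceptance script additionally runs one full 7266-gene study
at the default configuration.

## Known limitations

* The exact binomial count test is anti-conservative under biological
  overdispersion and subject to compositional bias (discussed above).
* Array permutation p-values are coarse below five replicates per condition.
* Enrichment ignores the GO graph; parent terms must be materialised in the
  GMT file if wanted.
* Neither subnetwork extractor claims to reproduce the published 113-node
  table exactly — the original procedure is under-documented (including how
  ratio-0 genes entered a 5-fold screen); both plausible procedures are
  provided and their parameters exposed.
* Interaction transfer assumes interolog conservation; no attempt is made to
  score transfer reliability by sequence divergence.
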