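# IghClonal

Clonal landscape analysis of immunoglobulin heavy-chain (IgH) B-cell
receptor repertoires from sorted B-cell subsets.

## What it does, and for whom

Autoimmune-prone mice accumulate effector B-cell populations — age-associated
B cells (ABC), CD11c⁺/CD11c⁻ germinal-center B cells (GCB) and
plasmablasts/plasma cells (PB/PC) — whose clonal relationships to each other
and to naive follicular B cells (FoB) are read out by bulk IgH sequencing of
sorted subsets, each amplified as two replicate libraries. `IghClonal` takes
the annotated rearrangements (AIRR Rearrangement TSV: V/J calls, CDR3,
copy counts, sample metadata) and reconstructs the clonal landscape for
immunologists analysing such experiments.

**Clone definition.** Rearrangements belong to one clone when they share the
V gene, J gene and CDR3 length and have ≥ 85 % CDR3 amino-acid identity
(single-linkage clustering within each (mouse, V, J, length) partition).
Clones whose copy-weighted consensus CDR3 nucleotide sequences lie within a
Hamming distance of 2 are then merged across V/J labels, absorbing erroneous
gene calls.

**Statistics.** Per subset: the D20 clonality index
(`D20 = Σ copies of top-20 clones / Σ all copies`), replicate-library
Jaccard overlap (`|A∩B| / |A∪B|` on clone sets), somatic-hypermutation (SHM)
fractions from germline-V comparison (clone-level, recomputed per subset,
unweighted or copy-weighted), CDR3-length distributions, and row-normalized
top-20 VH usage. Across subsets within a mouse: Jaccard and clone-size-aware
cosine similarity matrices, exact Venn region counts, and presence tracks of
shared clones.

**Simulation.** A generator emulates the study design (4 strains × 6 subsets
× duplicate libraries, Zipf clone-size skew, an SHM gradient, tunable clone
sharing with elevated ABC↔PB/PC association, V-gene miscalls) and emits
ground-truth labels, so clone calling is scored with the adjusted Rand index
and merge/split error counts.

## Worked example

```r
library(IghClonal)

sim <- simulateRepertoire(simConfig(seed = 42, strains = "WT",
                                    n_mice_per_strain = 1))
cs  <- callClones(sim$records)        # 0.85 identity, 2-nt collapse
cs
#> CloneSet: 966 clones from 2520 records (1 mice)
#>   identity threshold 0.85, collapse distance 2 nt, single linkage
#>   largest clones:
#>     #1 IGHV7-4/IGHJ1 CPSSEIAPTGISPAREAINKVW (1101 copies)
#>     #2 IGHV11-3/IGHJ4 CKRGSVCASSWQDW (1025 copies)
#>     #3 IGHV13-2/IGHJ1 CGTETGAPIVSW (558 copies)

evaluateRecovery(cs, sim$truth)       # vs ground truth
#> ARI 0.998, merges 0, splits 2

subsetProfiles(cs, sim$germlines)
#>  strain       subset n_clones d20_mean shm_fraction_unweighted ...
#>      WT          FoB      201    0.220                  0.0299
#>      WT          ABC      200    0.514                  0.2350
#>      WT GCB_CD11cpos      200    0.731                  0.9600
#>      WT GCB_CD11cneg      200    0.732                  0.9650
#>      WT  PB_CD11cpos      200    0.872                  0.9350
#>      WT  PB_CD11cneg      201    0.886                  0.9453

round(jaccard(subsetOverlap(cs, "WT_m1")), 3)
#>                FoB   ABC GCB_CD11cpos GCB_CD11cneg PB_CD11cpos PB_CD11cneg
#> FoB          1.000 0.036        0.020        0.023       0.036       0.031
#> ABC          0.036 1.000        0.023        0.036       0.146       0.179
#> ...
```

Reading the numbers: D20 rises FoB → ABC → GCB → PB/PC (FoB is the diversity
baseline, PB/PC the most oligoclonal pool), the fraction of mutated clones
rises FoB → ABC → GCB/PB (ABCs intermediate), and the ABC row of the Jaccard
matrix is most similar to the two PB/PC columns (0.146/0.179 vs ~0.03
baseline sharing) — the elevated ABC↔PB/PC clonal association the simulator
seeds and the pipeline recovers. Clone recovery against ground truth is
near-perfect (ARI 0.998); the two residual splits are V-miscalled variants
whose consensus drifted beyond the 2-nt collapse radius.

File-based runs use the same machinery end to end:

```r
res <- runPipeline(runConfig(airr_tsv = "data.airr.tsv",
                             germline_v = "v.fasta", germline_j = "j.fasta",
                             out_dir = "run"))
```

writing clone tables, metrics TSVs, overlap matrices, Venn JSONs and an MD5
manifest; `inst/scripts/igh-clonal.R` wraps this for the shell.

## Package layout

* `R/` — S4 classes (`CloneSet`, `GermlineSet`, `OverlapResult`, `SimTruth`)
  and the five modules: AIRR/FASTA IO, clone inference, repertoire metrics,
  subset overlap, simulator, plus the pipeline orchestrator.
* `tests/testthat/` — unit, property and acceptance suites, including a
  brute-force clustering oracle.
* `vignettes/clonal-landscape.Rmd` — methods: the clone model, parameter
  meanings and defaults, simulator design, numerical conventions,
  limitations.
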