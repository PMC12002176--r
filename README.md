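# ectopicgc

Quantitative analysis of ectopic (lung) germinal centers versus conventional
lymph-node germinal centers, for immunologists working with the NP-hapten /
B1-8 mouse system and single-cell BCR data. The package implements three
bespoke computations as a tested pipeline, plus seeded synthetic-data
generators with ground truth so everything is verifiable without external
data:

1. **W33L affinity-mutation calling** from Sanger reads of the VH186.2
   heavy-chain region: reads are aligned to a codon-framed germline
   reference, the 33rd codon is classified (W / L / Other / Undetermined —
   the W→L replacement confers ~10-fold higher NP affinity), and
   replacement/silent (R/S) mutations are counted per read and pooled per
   group, with the R/S ratio $\sum R / \sum S$ as the selection index.
2. **GC spatial statistics** from imaging-derived coordinates: polygon area,
   per-type cell density $n/A$, and the *polarization fraction*
   $f = \max(n_+, n_-)/n \in [0.5, 1]$, counting cells on either side of the
   line through the GC centroid perpendicular to the centroid→cell-centroid
   axis (0.5 = even distribution, 1.0 = fully one-sided, e.g. all in the
   light zone).
3. **Clonotype clustering and sharing**: cells join a clonotype when both
   heavy (VDJ) and light (VJ) junctions reach ≥85% normalized Hamming
   similarity (single-linkage components); clones with ≥3 GC members are
   "expanded", and the sharing matrix reports the percentage of each
   tissue's GC clones with a memory B-cell member in each target tissue.

See the vignette (`vignettes/ectopic-gc-analysis.Rmd`) for the models,
conventions, and design decisions.

## Worked example

```r
library(ectopicgc)

# --- SHM / W33L calling on simulated reads with known truth
ref <- make_reference(n_codons = 99, seed = 1)           # 297-nt window, TGG at codon 33
sim <- simulate_shm_reads(ref, n_reads = 200, mu = 0.01, p_w33l = 0.4, seed = 2)
profiles <- shm_call(sim$reads, ref)
summarize_groups(profiles)
#>   n_reads n_excluded n_undetermined n_classified frac_W frac_L frac_Other sum_R sum_S rs_ratio
#> 1     200          0              0          200   0.62  0.375      0.005   532   125     4.26
```

37.5% of reads called leucine at codon 33, consistent with the 40% injected
W33L probability; the pooled R/S ratio 4.26 reflects that most
random coding changes are replacements (~ 3:1) plus the forced replacement
at the key codon.

```r
# --- polarization fraction of a one-sided cell cluster
sq <- gc_region(c(-10, 10, 10, -10), c(-10, -10, 10, 10))
cells <- data.frame(x = c(5, 6, 5, 6), y = c(0, 0, 1, 1), cell_type = "Tfh")
polarization_fraction(spatial_sample("gc1", sq, cells), "Tfh")
#>   cell_type n_cells fraction degenerate
#> 1 Tfh             4        1 FALSE
```

All four cells lie on one side of the splitting line, so the fraction is
exactly 1.0 (fully polarized).

```r
# --- clonotype clustering and GC -> memory sharing
rep <- simulate_repertoire(n_clones = 20, seed = 3)
cs <- cluster_clonotypes(rep$cells)          # 83 cells in 20 clones, 12 expanded
sharing_stats(cs)$pct
#>   source_tissue target_tissue n_source_clones n_shared  pct
#> 1 lung          lung                       17       12 70.6
#> 2 lung          mLN                        17        4 23.5
#> 3 mLN           lung                       16       10 62.5
#> 4 mLN           mLN                        16        4 25.0
```

70.6% of clones with a lung GC member also have a lung MBC member in this
simulated repertoire (sharing is high here because tissues and compartments
are assigned independently at 50/50 and 70/30).

A thin command-line wrapper is installed at `exec/ectopicgc` with
subcommands `shm-call`, `polarize`, `clones`, and `simulate`; each writes
its result tables plus a `manifest.json` recording the seed, configuration,
and input checksums.

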