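# paleomito

Authentication and geographic clade assignment of ancient mitochondrial
genomes, at desk scale.

## What problem this solves

Mitochondrial DNA from mummified and historic museum specimens is short,
damaged, scarce, and contamination-prone. Placing such a specimen
geographically means (i) assembling a trustworthy mitogenome consensus from
degraded reads, (ii) *authenticating* it — showing the reads carry the
post-mortem deamination signature (C→T at 5′ read ends, G→A at 3′ ends)
and agree with the consensus at clade-diagnostic positions — and
(iii) assigning it to a geographic mitochondrial clade. `paleomito`
implements that whole chain for anyone working on museomics / ancient-DNA
mitogenome panels, plus a synthetic ancient-read simulator with complete
ground truth so the pipeline is testable without archival data.

## The statistics at its core

- **Damage profile**: for terminal offset *i*, the conditional frequency
  `f(X→Y, i) = #{reads with Y at offset i | reference base X} /
  #{reads with reference base X at offset i}`, with the deamination model
  `f(C→T, i) ≈ d₅·λⁱ` (5′) and `f(G→A, i) ≈ d₃·λⁱ` (3′).
- **Coverage**: mean depth `Σᵢ depthᵢ / L`; breadth at *k*× =
  fraction of positions with depth ≥ *k*; consensus = per-position
  majority base, `N` when depth < 2 or tied; retain a genome only if
  breadth at 3× ≥ 80%.
- **Diagnostic sites**: alignment columns monomorphic within every clade
  and differing between ≥ 2 clades ("fixed differences"); per-site read
  agreement `aₛ = #{reads carrying the diagnostic base at s} /
  #{reads covering s}`, summarised as median and IQR over sites — low
  agreement flags contamination.
- **Clade assignment**: one vote per diagnostic site for each clade whose
  base matches the query; ties fall back to p-distance.
- **Haplotype networks**: Hamming-distance minimum spanning networks
  (union of all MSTs) and a median-joining algorithm (Steiner-like median
  vectors from coordinate-wise majorities of linked triples).

## Worked example

Simulate a 3-clade panel, sequence a clade-B individual as ancient reads
(15% PCR duplicates, 5% contaminating reads from another clade), and run
the full pipeline:

```r
library(paleomito)
cfg <- pipeline_config(
  seed  = 42,
  panel = panel_config(n_clades = 3, samples_per_clade = 4,
    genome_length = 3000, planted_fixed_diffs_per_clade = 15,
    intra_clade_mut_rate = 0.001, seed = derive_seed(42, "panel")),
  reads = read_sim_params(n_fragments = 2000, dup_rate = 0.15,
    seed = derive_seed(42, "reads")),
  query_clade = "cladeB", contamination_fraction = 0.05
)
rep <- run_pipeline(cfg, verbose = TRUE)
```

```
[simulate] 3 clades, 2000 reads
[trim] 2000 -> 2000 reads
[map] best ref cladeB, 2000 reads retained
[dedup] duplication level 0.159
[damage] 5' C>T 0.0266, 3' G>A 0.0097
[consensus] mean depth 33.5x, breadth3 1.000, retained TRUE
[diagnose] 45 inter-clade sites, median agreement 0.967
[assign] assigned cladeB
[network] 13 haplotypes, 15 nodes
```

Reading the numbers: all reads survive trimming (damaged bases are not
low-quality to a sequencer, so nothing is clipped); mapping against all
three clade references selects the true source clade; the measured
duplication level 0.159 recovers the simulated 15% (plus coincidental
coordinate collisions); the 5′ C→T frequency 0.027 reflects the simulated
d₅ = 0.033 within binomial error at this read count; the consensus covers
the genome completely (breadth at 3× = 1.0, so it passes the 80% retention
gate); read agreement at the 45 inter-clade fixed sites has median 0.967 —
close to 1 − contamination fraction, exactly the contamination diagnostic
the per-site agreement is designed to be; and the query is assigned to
cladeB with 45/45 site votes against 15 for each other clade.

A command-line front end mirrors the stages
(`inst/cli/paleomito.R simulate | trim | map | damage | consensus |
diagnose | assign | network | run`).

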