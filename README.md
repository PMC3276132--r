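# legumap

Translational comparative genomics for crops with a genetic map but no
assembled genome. `legumap` transfers positional information from a
sequenced model relative (the pea–*Medicago truncatula* pair is the
motivating case) by chaining four computations:

1. **Unigene construction** — clean raw transcript/EST sequences
   (vector trimming, repeat masking, poly-A/low-complexity trimming,
   100 bp length filter) and cluster them into a non-redundant Unigene
   set by single-linkage over local-alignment overlaps (identity ≥ 95%
   over ≥ 40 bp), with tiered functional annotation
   (E ≤ 1e-15, identity ≥ 70%; tiers at E < 1e-20 and E < 1e-50).
2. **Best reciprocal homologs (RBH)** — for each Unigene, the best hit
   over the target's predicted genes, transcript contigs and genomic
   sequences at E ≤ 1e-20; genomic hits are re-queried with their
   matched interval ± 2 kb; a pair is accepted only when the unique
   best reverse hit is the original Unigene. E-values follow the
   Karlin–Altschul form `E = K·m·n·e^(−λS)` (λ = 1.28, K = 0.46) over a
   seed-and-extend Smith–Waterman search.
3. **In-silico map placement** — markers whose homologs have
   pseudo-chromosome positions become *anchors* carrying both (linkage
   group, cM) and (chromosome, bp); every other positioned Unigene gets
   a cM estimate by piecewise-linear interpolation between same-LG
   flanking anchors, restricted to its synteny block when available:
   `cM = cM_L + (cM_R − cM_L)·(bp − bp_L)/(bp_R − bp_L)`.
   Forward queries (sequence → five best placed Unigenes) and reverse
   queries (marker interval or position ± 5 cM → candidate genes) run
   on the placement table.
4. **Synteny blocks** — dot-plot points per (LG, chromosome) are
   chained into runs of ≥ 3 homolog pairs, tolerating ≤ 2 intruding
   points, split at cM-direction changes so inversions appear as their
   own `minus` blocks.

A synthetic genome-pair simulator (`simulate_bundle()`) generates every
input with known orthology, rearrangement and map-position truth, so
the whole chain is testable offline.

## Worked example

```r
library(legumap)

cfg <- sim_config(seed = 7, n_chromosomes = 2, genes_per_chromosome = 20,
                  est_per_gene = c(2, 3), marker_fraction = 0.3)
bundle <- simulate_bundle(cfg)

cleaned  <- clean_sequences(bundle$ests, vector_lib = bundle$vector_lib)
unigenes <- cluster_unigenes(cleaned$seqs)
unigenes
#> unigene_set: 40 Unigenes ( 40 contigs, 0 singletons ) from 102 input sequences

rbh <- resolve_position(rbh_search(unigenes, bundle$target), bundle$target)
summarize_rbh(rbh)
#> rbh_summary: 40 reciprocal / 40 unidirectional / 40 Unigenes
#>   hit rate: 100 %  estimated at full coverage: 100 %

marker_rbh <- resolve_position(rbh_search(bundle$marker_seqs, bundle$target),
                               bundle$target)
anchors    <- build_anchor_table(bundle$map, marker_rbh, bundle$assoc)
blocks     <- detect_blocks(make_dotplot_table(anchors = anchors))
placements <- place_all(rbh, anchors, blocks,
                        lg_lengths = attr(bundle$map, "lg_lengths"))
head(placements[, c("unigene_id", "linkage_group", "cM", "status")], 3)
#>   unigene_id linkage_group         cM       status
#> 1     UG0001           LG1 0.01322145 interpolated
#> 2     UG0002           LG1 0.04106355 interpolated
#> 3     UG0003           LG1 0.06454965 interpolated

# forward query: where does this sequence map?
query_position_for_sequence(as.character(bundle$query_genes[[3]]),
                            unigenes, placements)[1, c("unigene_id", "cM")]
#>   unigene_id         cM
#> 1     UG0003 0.06454965
```

The 102 simulated reads collapse into 40 Unigenes — one per simulated
gene — all 40 find their true ortholog reciprocally, and each gets an
interpolated cM position between its flanking anchor markers; the
forward query recovers the right Unigene and position for a raw gene
sequence.

The full pipeline (`run_pipeline()`) chains these stages, writes every
stage's table (cleaning report, Unigene membership, RBH table, anchors,
placements, dot-plot, blocks, summary) and a deterministic run
manifest; reruns are byte-identical.

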