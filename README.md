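# guildphylo

Genome-scale phylogenetics and trophic-guild gene-content analysis for
bacterial proteomes, as one reusable, tested R pipeline.

## The problem

Delineating bacterial orders and families from a single marker gene is
unreliable — 16S rRNA trees of closely related marine
gammaproteobacteria are notoriously unstable, with bootstrap support
below any useful threshold. Whole-proteome data solve this twice over:

* **Supermatrix phylogenetics.** Cluster all proteins into ortholog
  families (reciprocal best hits + Markov clustering, inparalogs
  removed), align each family, filter the alignments to conserved
  blocks, and concatenate them into a taxa × characters supermatrix
  with partitions. Trees inferred from thousands of concatenated
  characters resolve order-level structure with near-maximal support.
* **Gene-content analysis.** Convert homolog/ortholog families into
  binary presence/absence matrices. Trees inferred from gene *content*
  capture ecological signal: they can separate slow-growing oligotrophs
  (*K*-strategists) from fast-responding copiotrophs (*r*-strategists)
  even when the sequence phylogeny says those guilds evolved from
  different ancestors. COG functional-category profiles quantify the
  difference — oligotrophs enriched in lipid transport/metabolism (I)
  and secondary metabolites (Q), copiotrophs in carbohydrate transport
  (G), motility (N), signal transduction (T), transcription (K) — with
  cytochrome-P450 genes (COG2124) around eleven times more abundant in
  the oligotrophic guild.

The core statistics and algorithms are implemented in the package and
validated against independent oracles: exact Smith–Waterman similarity
with Karlin–Altschul E-values (`E = K m n e^{-λS}`, threshold
`E ≤ 10⁻⁵`), TribeMCL-style Markov clustering (symmetrized −log₁₀E
edge weights, inflation 2.0 for homolog and 1.5 for ortholog families),
corrected distances (Felsenstein `d = −B ln(1 − p/B)`; Kimura's PAM
approximation `d = −ln(1 − p − 0.2p²)`), Fitch parsimony, LG+Γ₄ / Mk
likelihood, column-resampling bootstrap, and the composite multi-method
support-dot annotation (black: all m methods ≥ 95%; white:
⌈2m/3⌉ ≤ c < m; hollow: any method ≥ 75%, values printed).

A genome-evolution simulator (known species tree, core/accessory/
guild-specific families, gain–loss dynamics, inparalog duplications,
planted COG profiles and an 11:1 marker family) provides ground truth
for end-to-end recovery experiments; see the methods vignette
(`vignettes/guildphylo-methods.Rmd`) for the model and every default.

## Worked example

Simulate 8 genomes in two guilds, run the whole pipeline, and compare
the recovered trees with the truth:

```r
library(guildphylo)

cfg <- pipeline_config(n_taxa = 8, n_core = 10, n_accessory = 12,
                       bootstrap_reps = 50, seed = 5)
res <- run_pipeline(cfg, out_dir = "run1")

res$matrix_dims$supermatrix
#>      genes characters
#>         20       1983

rf_distance(res$tree_sets$supermatrix$trees$nj, res$truth$species_tree)
#> [1] 0
rf_distance(res$tree_sets$supermatrix$trees$mp, res$truth$species_tree)
#> [1] 0

res$tree_sets$supermatrix$annotated
#> <supported_tree> 8 tips, methods: nj, mp
#> black
#>     5

subset(res$cogs$comparison, label_K != "",
       select = c(category, mean_K, mean_r, label_K, label_r))
#>    category    mean_K    mean_r label_K label_r
#> 3         K  8.762531 16.673669       -       +
#> 8         V  5.006266  8.851541       -       +
#> 14        U  5.006266  8.851541       -       +
#> 16        C 16.268797  9.131653       +       -
#> 21        I  5.006266  0.000000       +       -

res$cogs$marker[c("mean_K", "mean_r", "ratio")]
#> $mean_K
#> [1] 1.25
#> $mean_r
#> [1] 0
#> $ratio
#> [1] Inf
```

Reading this: the supermatrix concatenates 20 ortholog-family
alignments (1983 aligned columns); both the neighbor-joining and
maximum-parsimony supermatrix trees are topologically identical to the
true species tree (Robinson–Foulds distance 0), and every internal edge
earns a black dot (≥ 95% bootstrap support with both methods). The
guild comparison labels lipid metabolism (I) and energy production (C)
as enriched in the K-strategist guild and transcription (K), defense
(V) and trafficking (U) as enriched in the r-strategists — at 8 genomes
the per-category percentages are coarse, so the label set is wider than
the planted guild contrast. The COG2124-like marker family is
absent from the r-guild genomes in this small run, so the K:r copy
ratio is reported as infinite (flagged).

All randomness is seeded: rerunning with the same config reproduces
byte-identical artifacts (compare `manifest.json` digests).

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/guildphylo.R run --out run1 --seed 5
Rscript inst/scripts/guildphylo.R simulate --out sim1 --n-taxa 12
```

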