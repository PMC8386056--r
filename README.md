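# fusionrank

Transfer-learning network fusion for gene prioritization in R.

## The problem

Network-propagation methods rank candidate disease genes by how close they
sit to known pathogenic genes in a gene–gene network. For many cancers —
especially rare ones — there are few or no curated pathogenic genes, so
those methods have nothing to propagate from, and a co-expression network
built from the target cohort alone is noisy. `fusionrank` addresses this by
transferring knowledge from a *source* cohort (expression **and** a
pathogenic-gene list, e.g. a well-studied cancer) into a *target* cohort
that has expression only, over a shared gene universe.

## The model

Let `X⁽ˢ⁾ ∈ ℝ^{n×dₛ}` and `X⁽ᵗ⁾ ∈ ℝ^{n×dₜ}` be source/target expression
(genes × patients), `y ∈ {0,1}ⁿ` the source pathogenic labels. The pipeline:

1. **Affinity** `S`: `s_ij = |Pearson(x_i⁽ᵗ⁾, x_j⁽ˢ⁾)|` — how much knowledge
   target gene *i* can borrow from source gene *j*.
2. **Source representation** `A = X⁽ˢ⁾H`: a large-margin nearest-neighbor
   (LMNN) projection `H` that pulls same-class neighbors together and pushes
   differently-labeled "impostors" outside a unit margin, regularized to
   stay faithful to the expression geometry.
3. **Fusion**: learn the target projection `U` and fused network `W` by
   alternating minimization of

   ```
   ½ Σᵢⱼ [ s_ij ‖x_i⁽ᵗ⁾U − a_j‖² + w_ij ‖(x_i⁽ᵗ⁾ − x_j⁽ᵗ⁾)U‖² + λ(√w_ij − 1)² ]
   ```

   `W` has the closed-form per-pair minimizer
   `w_ij = (λ / (‖(x_i − x_j)U‖² + λ))²`; `U` takes line-searched gradient
   steps. The penalty `Φ(w) = (√w − 1)²` pushes strongly coupled pairs
   toward weight 1 and the rest toward 0.
4. **Ranking**: PRINCE-style propagation `F ← αŴF + (1−α)Y` on the fused
   network (or personalized PageRank), seeded with the source labels.

A seeded synthetic-data generator plants co-expression modules, a ground
truth interaction network, and differentially expressed pathogenic genes so
the whole pipeline is testable without any downloads.

## Worked example

```r
library(fusionrank)

sc  <- scenario_fixture_small(1)          # 120 genes, 4 modules, 12 pathogenic
fit <- fuse_and_rank(sc$source, sc$target, sc$labels)
head(fit$ranking, 5)
#>   rank gene_id      score
#> 1    1    g006 0.03259389
#> 2    2    g012 0.03238771
#> 3    3    g005 0.03229796
#> 4    4    g010 0.03040737
#> 5    5    g001 0.03031983

topk_accuracy(fit$ranking, sc$labels, 20)
#> [1] 0.6        # 12 of the top 20 are planted pathogenic genes (12 exist)

co <- coexpression_network(standardize(sc$target))
edge_overlap_fraction(fit$fusion$W, sc$truth_net, 1.2)   # 0.999
edge_overlap_fraction(co,           sc$truth_net, 1.2)   # 0.788
```

The fused network's strong edges overlap the planted interactions far
better than the target-only co-expression baseline (0.999 vs 0.788 of
above-threshold edges confirmed at 1.2× the mean edge weight), and all 12
planted pathogenic genes land in the top 20 — the ceiling for `k = 20`.
The learned source embedding also improves the between/within class
distance ratio (1.346 → 1.408 on this seed).

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli.R", package="fusionrank"))') \
  simulate --out scenario --seed 1
Rscript .../cli.R prioritize --source scenario/source.tsv \
  --target scenario/target.tsv --pathogenic scenario/pathogenic.txt \
  --out ranking.tsv --network-out fused.tsv
Rscript .../cli.R rank --network fused.tsv --prior scenario/pathogenic.txt \
  --method pagerank --out ranking_pr.tsv
Rscript .../cli.R evaluate --network fused.tsv --reference scenario/truth_net.tsv \
  --ranking ranking.tsv --pathogenic scenario/pathogenic.txt --out report.tsv
```

## File formats

All plain text, tab-separated: expression (header = sample ids, column 1 =
gene id), gene lists (one id per line, `#` comments), networks (gene_a,
gene_b, weight; one line per unordered pair), rankings (rank, gene_id,
score).
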