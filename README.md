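# genefamsim

Simulation of multi-gene-family evolution under a hierarchical
*three-tree* model, for benchmarking species-tree and reconciliation
methods and for studying how incomplete lineage sorting (ILS), gene
duplication and loss (GDL), horizontal gene transfer (HGT) and gene
conversion (GC) interact.

Three nested layers are simulated per replicate:

* a **species tree** from a constant-rate birth–death process (forward
  simulation from an origin time, or conditioned on the number of extant
  tips), each branch carrying an effective population size *Ne*, a
  generation time and a number of sampled individuals;
* per gene family a **locus tree**: a duplication–loss birth–death
  process plus two pure-birth processes for replacing HGT and GC along
  the species tree, with receptor choice (uniform or inverse to the
  phylogenetic distance) and the corresponding subtree-prune-regraft;
* a **gene tree** per locus tree: the multispecies coalescent with rate
  *k(k−1)/(2 p Ne)* per generation, where subtrees founded by a
  duplication/transfer/conversion are *coalescent-bounded* — all sampled
  lineages of the new copy must coalesce to one before the founding
  event. Bounded subtrees are sampled **exactly** (lineage-count dynamic
  program + inverse-transform sampling of counts and conditional times),
  not by rejection.

Gene trees are emitted in time/generation units and in expected
substitutions per site after applying a substitution rate and three
independent mean-one Gamma multiplier layers (species-, family- and
gene-branch-specific uncorrelated relaxed clocks). Every parameter can be
fixed or drawn from a prior (`F`, `U`, `N`, `LN`, `E`, `G`), with
family-level priors able to reference replicate-level draws as
hyperparameters.

## Worked example

```r
library(genefamsim)

cfg <- sim_config(
  n_replicates = 1, n_families = 2,
  speciation_rate = "F:1e-6",       # per time unit
  n_taxa = 5, height = 1e6,         # 5 species, origin 1e6 generations ago
  ne = "F:1000", individuals = 1,
  dup_rate = "U:0,5e-7",            # per generation, drawn per family
  hgt_rate = "F:2e-7",
  subst_rate = 1e-8, alpha_gene = 2 # relaxed clock on gene branches
)
res <- run_simulation(cfg, seed = 42, out_dir = "demo_out")
res$manifest[, c("family", "duplications", "transfers_realized",
                 "extant_leaves", "gene_leaves", "gene_height")]
#>   family duplications transfers_realized extant_leaves gene_leaves gene_height
#> 1      1            0                  1             5           5     1000243
#> 2      2            2                  1             9           9     1000333
```

Family 1 experienced one realized transfer: one species' resident locus
was replaced by a copy from a contemporary donor, so its gene lineage
attaches inside the donor's subtree; copy number is unchanged (replacing
transfer), hence 5 extant locus leaves. Family 2 additionally fixed two
duplications, giving 9 gene copies across the 5 species. `gene_height`
exceeds the species-tree height (1e6) because the root coalescence
predates the root divergence — ILS at the root. `demo_out/1/` contains
`s_tree.trees`, `l_trees.trees` (NHX event annotations), per-family
`g_trees<f>.trees` and `mapping<f>.tsv` tables linking every gene node to
its locus and species branch.

The overestimation of duplication times by locus-tree-unaware
reconciliation (dating a duplication at the first cross-paralog
coalescence) is measured by `duplication_overestimation()`; in the
simplest haploid scenario its expectation is *Ne* generations.

A command-line front end is installed as `exec/genefamsim`:

```sh
Rscript exec/genefamsim -rs 1 -sl 5 -st 1e6 -sb F:1e-6 -sp F:1000 \
    -ld U:0,5e-7 -o demo_out -seed 42
```

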