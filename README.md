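# mitophylo

Tools for whole-mitogenome haplogroup phylogeography, built around the kind
of survey used for barn swallow (*Hirundo rustica*) matrilines: hundreds of
complete mitogenomes expressed as reference-relative haplotypes, organised
into a mutation-annotated maximum-parsimony tree with nested haplogroup
labels, dated with a molecular clock, and summarised with demographic,
selection and population-genetic statistics. A seeded coalescent simulator
generates every input the pipeline consumes together with the generating
truth, so the whole chain can be validated by recovery experiments.

Intended users are molecular ecologists and phylogeographers working with
aligned mitogenome consensus sequences (mtDNA is clonal and non-recombining,
so a single genealogy underlies all sites).

## What it computes

- **Haplotypes.** Each sample is a set of substitutions relative to a
  reference at 1-based positions ("np"), restricted to a region scheme —
  by default the 15,601-bp coding region (nps 1–14,859 + 16,068–16,740 +
  18,075–18,143), excluding the two control regions. Variants can be called
  from per-site read fractions with the standard heteroplasmy rule: an
  alternative allele is called at ≥ 30% of reads and flagged heteroplasmic
  in the closed 30–70% band. Indels are recorded but never enter the tree.
- **Tree.** A maximum-parsimony tree of the distinct haplotypes (Fitch
  score; NJ start with SPR/NNI hill-climbing, or exhaustive enumeration for
  small inputs), rooted through outgroups. Every branch carries its
  reconstructed substitutions; zero-mutation branches collapse into
  multifurcations; nested haplogroups get deterministic labels
  (A, A1, A1a, ...) from their defining mutations.
- **Dating.** The rho statistic (mean mutations from a node to its leaves)
  converts to years via the clock: with the default rate
  μ = 2.45×10⁻⁸ substitutions/site/year on 15,601 bp, one mutation accrues
  every 1/(μL) ≈ 2,616 years. Standard errors follow the genealogy-aware
  (Saillard-type) propagation. Strict-clock maximum likelihood under
  HKY+Γ on the fixed topology provides saturation-corrected ages for deep
  nodes, and rates can be calibrated from an outgroup split
  (default 9.34 Mya, 95% CI 5.8–13.2 Mya).
- **Demography.** Classic/generalized skyline on the dated genealogy:
  per coalescent interval with k lineages and length Δt,
  N̂e = k(k−1)/2 · Δt / generation time (default 1 year).
- **Selection.** Branch mutations are classified synonymous /
  non-synonymous under the vertebrate mitochondrial code (table 2) in their
  ancestral codon context; NG86 fractional site counts normalise dN/dS; the
  statistic is partitioned at a time cutoff (default 11.7 ky, the end of the
  Younger Dryas) by branch midpoint age and contrasted with a two-sided
  Fisher exact test.
- **Population statistics.** Nucleotide diversity π (pairwise deletion),
  haplotype diversity HD, haplogroup frequency tables with χ²
  over-representation tests, AMOVA-based ΦST, haversine geographic
  distances, Mantel isolation-by-distance tests (999 permutations), and
  diversity-versus-latitude regression.

## Worked example

Simulate the default study-like survey (411 samples in four haplogroups:
341 *rustica*, 50 *transitiva*, 5 *gutturalis*, 15 *erythrogaster*; crown
ages A 57.1 ky, B 18.9 ky, C 31.1 ky, D 51.1 ky under a root at 276.9 ky)
and run the full pipeline:

```r
library(mitophylo)
cfg <- sim_config()                       # study-like survey: 411 samples
ds  <- simulate_dataset(cfg, seed = 1)

pc <- pipeline_config(
  input     = list(sequences = ds$sequences, reference = ds$reference,
                   metadata  = ds$metadata),
  outgroups = c("outgroup1", "outgroup2"),
  seed      = 2
)
res <- run_pipeline(pc)

res$tree
#> Mutation-annotated MP tree: 259 tips (2 outgroup), score 5249, 5249 branch mutations
res$haplogroups$definitions
#> Haplogroup definitions: 154 labels under 'root'
#>   top-level: A, B

str(res$summary[c("distinct_haplotypes", "variable_sites", "pi",
                  "mean_pairwise_diff", "root_age_rho")])
#> List of 5
#>  $ distinct_haplotypes: int 257
#>  $ variable_sites     : int 838
#>  $ pi                 : num 0.00321
#>  $ mean_pairwise_diff : num 50
#>  $ root_age_rho       : num 247568

ra <- rho_age(res$tree)
cat(sprintf("root age (rho): %.1f +- %.1f ky\n",
            ra$age_years/1000, ra$se_years/1000))
#> root age (rho): 247.6 +- 21.4 ky

res$dnds$stat
#> Partitioned dN/dS (cutoff 11700 y): young 234 N / 116 S (dN/dS 0.619),
#>   old 212 N / 91 S (dN/dS 0.715), Fisher p = 0.401
```

Reading the output: 411 simulated mitogenomes collapse to 257 distinct
coding-region haplotypes segregating 838 variable sites; average nucleotide
diversity is π ≈ 0.32%. The rho estimate of the root age (247.6 ± 21.4 ky)
sits below the generating 276.9 ky because parsimony undercounts repeat
hits at gamma-hot sites — the strict-clock ML dating (`ml_clock_ages()`)
corrects this, and the per-clade rho ages of the four young haplogroups
recover their generating ages within two standard errors
(`clade_age_recovery()`). The simulation is neutral, so the young/old
dN/dS contrast is flat (Fisher p = 0.40), as it should be.

The same stages run from files (FASTA/TSV/YAML) via the thin CLI in
`inst/scripts/mitophylo_pipeline.R`:

```sh
Rscript inst/scripts/mitophylo_pipeline.R simulate --out sim_out --seed 1
Rscript inst/scripts/mitophylo_pipeline.R run-all --config pipeline.yaml
```

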