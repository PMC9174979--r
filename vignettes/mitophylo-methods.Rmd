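---
title: "Methods: mitogenome haplogroup phylogeography with mitophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitogenome haplogroup phylogeography with mitophylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophylo)
```

# Scope and model

mitophylo analyses surveys of complete mitochondrial genomes from a single
species. Because mtDNA is maternally inherited, clonal and non-recombining,
one genealogy underlies every site, and the analysis chain is: express each
sample as a haplotype relative to a reference; build a rooted,
mutation-annotated maximum-parsimony (MP) tree of the distinct haplotypes;
name nested haplogroups from their defining mutations; convert mutational
depth to time with a molecular clock; and summarise demography, selection
and population structure from the dated genealogy.

All coordinates are 1-based positions ("np") on the reference mitogenome.
Input sequences must be pre-aligned to reference length; a length mismatch
is an error, never an implicit alignment (alignment is out of scope). `N`
is missing data everywhere downstream; `-` is recorded as indel evidence
only and never enters tree construction.

## Region schemes

Analyses run on the concatenation of configured reference intervals. The
default is the 15,601-bp coding region (nps 1–14,859, 16,068–16,740,
18,075–18,143), i.e. the mitogenome minus its two control regions, whose
hypervariability and length variation would otherwise distort both the tree
and the clock. A two-gene ND2+CYB scheme (2,075 bp) is included for
comparisons with partial sequences from older surveys.

## Variant calling

Consensus calling from per-site read fractions uses two thresholds: an
alternative allele is called when its read fraction is at least
`min_fraction` (default 0.30), and a call is flagged heteroplasmic when the
fraction lies in the closed interval 30–70%. We read the band as closed, so
a site at exactly 0.30 is called and flagged. Heteroplasmic calls are kept
in haplotype profiles — the flag travels as metadata — and the flag allows
sensitivity re-runs that exclude them from diversity statistics.

Haplotype identity ignores missing sites: two profiles are the same
haplotype iff their substitution sets are identical. Comparing only over
jointly non-missing positions would make identity non-transitive and the
equivalence classes order-dependent; the chosen rule is deterministic.

# The mutation-annotated MP tree

Scoring is Fitch small parsimony (missing states are unconstrained; the
kernel is a small C++ routine over bitmask-encoded states), generalised to
multifurcations by the Fitch–Hartigan counting rule. The search is a
neighbour-joining start followed by SPR (NNI above 60 taxa) hill-climbing;
small inputs additionally run eight deterministic random-restart climbs
from an internal fixed seed, because high-homoplasy instances have many
local optima. The caller's RNG state is untouched, so a given input always
yields the same tree. Up to ten taxa an exhaustive enumeration over all
unrooted topologies is available and also reports the number of equally
parsimonious trees; the heuristic reports only the first optimum found.

Rooting attaches the outgroup(s) to the branch that minimises total score;
the state reconstructed at the ingroup ancestor stands in for the ancestral
mitogenome. Ancestral states use a deterministic refinement (a child takes
the parental state whenever compatible, otherwise the alphabetically first
candidate), every branch gets its substitution list, positions mutating on
more than one branch are flagged recurrent, and replaying the annotations
root-to-leaf must reproduce every observed haplotype — this round-trip runs
on every pipeline build. Internal branches with zero mutations below the
ingroup ancestor are collapsed into multifurcations, the usual convention
for haplogroup trees.

Haplogroup nomenclature is deterministic: children of the ingroup ancestor
receive capital letters in order of their first-listed haplotype; deeper
levels alternate number and letter suffixes (A, A1, A1a, ...). A node is
labelled when its subtending branch carries at least one defining mutation
and it subtends at least two haplotypes (both configurable). Labels are a
convention, not a claim: clade identity across studies must be established
by defining mutations, which is also how `assign_haplogroup()` works — each
label's cumulative defining path is scored as matches minus mismatches
against a profile, missing positions counting neither way, ties going to
the shallowest label.

Bootstrap support resamples alignment columns with replacement, rebuilds a
(cheap, single-start) MP tree per replicate and reports the percentage of
replicates containing each clade as an unrooted bipartition.

# Clock dating

The clock is a per-site rate μ (default 2.45×10⁻⁸ substitutions/site/year)
on a region of length L, giving 1/(μL) years per mutation — 2,616 years for
the default coding region. The rate can be recalibrated from an
ingroup–outgroup split as rate = distance/split-time (default split
9.34 My); following the standard approach the point estimate ignores the
calibration error, and the interval implied by the calibration CI
(5.8–13.2 My) is reported separately.

Two estimators convert mutations to ages:

- **rho**: the mean number of annotated mutations from a node to its
  descendant leaves, times years-per-mutation. Its standard error uses the
  genealogy-aware propagation `var(rho) = Σ_b (n_b/n)² m_b` over branches
  below the node (each branch count treated as Poisson). rho is unbiased
  under a Poisson clock but undercounts repeat hits at gamma-hot sites, so
  it is biased downward for deep nodes when rate heterogeneity is strong.
- **strict-clock ML**: HKY+Γ(+I) likelihood maximised over ultrametric
  branch lengths on the fixed MP topology (32 gamma categories by default,
  4 in speed-sensitive fits), node heights divided by μ. This corrects
  saturation and is the preferred estimator for deep nodes, mirroring the
  usual practice of likelihood dating on a parsimony topology. A single
  partition is the default; the paper-style many-partition configuration is
  not required for any result here. Node ages are reported to 0.1 ky.

We define a node's "mutational distance" as its height on the
clock-constrained tree (not the mean tip-to-node path), and state this
because the two differ under rate heterogeneity. rho ages are estimated
per node independently, so a child can come out older than its parent;
such violations are reported, never silently clipped. Only when an
ultrametric tree is required downstream (skyline) are parents lifted to
their tallest child, with the number of lifted nodes recorded.

# Skyline demography

The classic skyline estimates `Ne = k(k−1)/2 · Δt / g` per coalescent
interval; the generalized variant pools adjacent intervals whose total
length is below a grouping parameter ε. Interval estimates are
exponentially distributed around the true Ne, so single-interval values are
noisy and their harmonic mean is unstable; for single-number recovery of a
constant population size we therefore pool heavily (ε = root height / 2),
while shape diagnostics (growth versus decline) use the unpooled classic
estimate. This replaces Bayesian skyline posteriors — no MCMC, hence no
credible intervals — and on a haplotype tree dated by rho it inherits that
approximation; trajectories are best read qualitatively (growth, plateau),
not as calibrated Ne values.

# Time-partitioned dN/dS

Every branch mutation inside a protein-coding gene is classified in its
ancestral codon context (strand-aware; the vertebrate mitochondrial code,
table 2 — forced by the taxon: e.g. ATA is Met and AGA/AGG are stops).
Changes creating or destroying stops count as non-synonymous. NG86
fractional site counts (per codon position, the fraction of one-step
changes that are synonymous) normalise the counts, so
`dN/dS = (N/nonsyn sites)/(S/syn sites)`; totals satisfy
nonsyn + syn = coding length. Genes are trimmed of trailing incomplete
codons and terminal stops; an internal stop in user input is an error,
while the pipeline — whose input is a *reconstructed* ancestral sequence
that can carry sparse reconstruction noise — skips such codons and records
them. Both the site-normalised pair and the raw N/S ratios are emitted;
the normalised pair is primary.

The partition assigns each mutation young or old by its branch midpoint age
against a cutoff (default 11,700 years, the end of the Younger Dryas — the
change-point motivating the statistic); midpoint assignment is the default
and pro-rata splitting of straddling branches is a documented alternative
we did not implement, as the midpoint rule is already an approximation at
the same order. The young/old N–S contrast is tested with a two-sided
Fisher exact test (exact hypergeometric enumeration).

# Population statistics

π uses pairwise deletion by default (sites missing in either member of a
pair are excluded for that pair), which maximises data use and matches the
per-pair definition of d_ij; complete deletion is a switch. ΦST is the
AMOVA among-population variance fraction computed from pairwise difference
matrices (differences treated as squared distances, the standard
convention). Geographic distances are haversine on the mean-radius sphere
(R = 6371.0088 km), within 0.6% of the ellipsoidal geodesic — far inside
the noise of any Mantel test. Mantel significance is
`(1 + #{r_perm ≥ r_obs})/(n_perm + 1)` with simultaneous row/column
permutations (999 by default). χ² over-representation tests report the
degrees of freedom implied by the table shape, without continuity
correction. The South/Center/North macro-group mapping ships as an
editable configuration.

# The synthetic-data generator

The generator emulates the study conditions and provides ground truth:

- **Skeleton and ages.** Four clades A–D on the fixed topology
  ((A,B),(C,D)) with crown ages 57.1, 18.9, 31.1 and 51.1 ky, internal
  nodes AB 115.6 ky and CD 156.4 ky, root 276.9 ky. Within each clade a
  coalescent is simulated under the configured demography and its event
  times are rescaled so the crown age equals the skeleton age exactly —
  recovery experiments then have fixed truth. The unconditioned coalescent
  sampler (`simulate_coalescent()`) is exposed separately and carries the
  textbook expectations (e.g. mean pairwise TMRCA = Ne for n = 2).
- **Sample sizes.** 411 samples split 341/50/5/15 across
  rustica/transitiva/gutturalis/erythrogaster, mapped 1:1 to clades A–D.
  The real survey has most transitiva inside haplogroup A; the 1:1 mapping
  is a deliberate simplification so that assignment truth is well defined.
- **Demography.** Constant ancestral size with exponential growth toward
  the present starting 11.7 ky ago (defaults Ne present 2×10⁵, growth rate
  2×10⁻⁴/year), giving skyline experiments a known change-point.
- **Mutation.** Poisson events per branch at rate μ·Δt·Σr_i with gamma
  site multipliers (shape 0.3) and HKY-biased substitutions (κ = 10,
  avian-like base frequencies), on the coding region of an 18,143-bp
  emitted genome; μ defaults to 2.45×10⁻⁸/site/year. Protein-coding frames
  of the root are kept stop-free (a property of real mitogenomes) by
  resampling stop codons. Two outgroups diverge at the 9.34-My calibration
  split, so calibrating on the emitted divergence recovers the configured
  rate by construction.
- **Geography.** Populations with real-world-like coordinates; in IBD mode
  clade-A samples are laid out over latitude-ordered populations following
  the genealogy's tip order with a mixing fraction (0.15), producing
  distance-decaying ΦST; panmictic mode randomises assignment.
- **Read fractions.** True substitutions draw alt fractions near 1,
  designated heteroplasmies draw uniformly in [0.30, 0.70], and noise sites
  stay below 0.30, so the caller recovers profiles exactly absent
  heteroplasmy.

Everything is bit-reproducible given (config, seed). What the generator
does **not** emulate: NUMT contamination, sequencing error above the
read-fraction layer, alignment error, recombination (absent in mtDNA) and
selection (neutral only — the dN/dS contrast is validated on a constructed
fixture at the classification layer instead). Passing recovery tests
therefore demonstrates correctness of the inference machinery under the
stated generating model, not robustness to those real-data artifacts.

# Numerical choices and degenerate inputs

- Fitch ties break alphabetically; equally parsimonious trees are counted
  (exhaustive mode) but not consensus-merged.
- The heuristic search is deterministic for a given input (fixed internal
  restart seed; caller RNG preserved).
- Zero-variation alignments: ML ages all zero; MP build refuses fully
  degenerate input (no variable sites including outgroups).
- Fisher exact sums hypergeometric probabilities ≤ the observed one with a
  10⁻⁷ relative tie tolerance; zero margins give p = 1 with a warning.
- ΦST can be slightly negative by sampling noise (reported as computed);
  populations with fewer than two samples are excluded with a warning.
- Skyline epochs shorter than 10⁻⁹ of tree height (artifacts of resolving
  multifurcations) are dropped.
- The two-taxon ML case uses the closed form (half the ML distance).

# Problem sizes used in validation

The shipped experiments use: 200 random instances (≤ 8 haplotypes,
≤ 30 sites) for heuristic-versus-exhaustive parsimony; 1,000 random 2×2
tables for Fisher; 20 replicates of 50 tips at the full 15.6-kb region for
root-age recovery; 50 replicates each for skyline constant-size and growth
recovery; 200 null datasets for Mantel type-I error; and one seeded
411-sample survey for end-to-end haplogroup and age recovery. These sizes
give each experiment enough replication for its pass band while keeping a
full validation run in the minutes range on one CPU.

# Known limitations

- Bayesian tree/clock inference (relaxed clocks, posterior node ages,
  skyline credible intervals) is out of scope; rho and strict-clock ML are
  the provided approximations, and deep rho ages are biased downward under
  strong rate heterogeneity (use ML there).
- The haplogroup label strings are this package's convention; clade
  correspondence with other nomenclatures must go through defining
  mutations.
- The skyline on a collapsed haplotype tree compresses identical sequences
  into single tips; recent epochs are better estimated from trees that
  retain sample multiplicity.
- χ² degrees of freedom follow the analysed table's shape; published
  subscripts from other software may differ and should be checked against
  the table actually tested.
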