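---
title: "Methods: ancient mtDNA HVS-I haplotyping and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancient mtDNA HVS-I haplotyping and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altaimt)
```

`altaimt` analyses ancient human mitochondrial DNA typed over
hypervariable segment I (HVS-I, rCRS positions 16051--16400, L = 350
sites) together with a panel of coding-region PCR-RFLP markers. This
vignette documents the statistical procedures, the defaults and the
design choices, in the order a dataset flows through the package.

## Data model

A sample is a **variant profile**: the set of rCRS positions at which it
differs from the reference over the inclusive window, with 1-based
coordinates. Published HVS-I tables print bare positions ("minus
16000"); the package interprets a bare position as a **transition**
relative to the reference base (A↔G, C↔T), the standard shorthand
convention. Explicit alleles are supported for transversions; indels,
heteroplasmies and ambiguity codes are rejected with a clear error
rather than silently coerced, since none occur in shorthand tables of
this kind and their semantics (alignment, length changes) are out of
scope.

The packaged reference segment is **synthetic** (a fixed random 350-mer,
labelled as such). This is deliberate: every statistic in the package —
haplotype identity, diversity, distances, networks — is computed on
variant sets, never on sequence content, so the true rCRS segment is
only needed when the user materializes FASTA output from real data, in
which case they should pass their own rCRS slice to
`profile_to_sequence()`.

The embedded fixture (`altai_pazyryk()`) is the published table of 19
Bronze/Iron Age individuals from the Mongolian Altai, with HVS-I
profiles, ten RFLP marker states and period metadata. The RFLP cells
were transcribed so that each row's marker states are classically
consistent with its reported restriction-haplogroup; a handful of cells
whose column alignment is ambiguous in the extracted source were
resolved in favour of that consistency.

## Haplogroup assignment

Two independent evidence sources are called and then reconciled:

**HVS-I motif calling** (`call_from_hvr1()`). A packaged, editable table
of ~30 haplogroup motifs distilled from the standard mtDNA phylogeny is
scored against the profile with a parsimony criterion: each motif
position found in the profile scores +1, each motif position missing
from the profile scores −`penalty` (default 1). Candidates are ranked
by net score, with ties broken by the longer motif (deeper node) and
then lexicographically, which makes the caller fully deterministic.
Profile variants outside the winning motif are reported as private.
Two tie-breaks in the fixture are worth knowing about: profiles carrying
{16223, 16311, 16362} tie D against M10 (both score 2) and resolve to D
lexicographically, and {16223, 16292, 16362} ties D against W likewise —
in both cases the coding-region evidence independently confirms D.
Haplogroups defined only in the coding region (HV, U, R0) carry empty
motifs: they exist as tree nodes for ancestry checks and can never win
the motif ranking. An empty profile is returned as "reference-like
(H2a2-like)" with a low-confidence flag rather than an arbitrary pick.

**RFLP calling** (`call_from_rflp()`). The marker map (663 HaeIII+ → A;
13259 HindII− → C; 5176 AluI− → D; 4830 HaeII+ → G; 4577 NlaIII− → V;
13704 BstOI− → J; 7025 AluI− → H; 9052 HaeII− → K; 12308 HinfI+ → U;
15606 AluI+ → T) ships as a TSV because the classical literature, not
the source table, defines it; it is therefore replaceable data, not
code. Multiple simultaneous diagnostic hits are allowed only when
nested on the haplogroup tree (U and K), in which case the narrowest
label wins; incompatible hits raise an error naming both. When nothing
diagnostic is hit, exclusion logic applies within R0: site 7025 present
excludes H, and with 4577 also present (excluding V) the narrowest
compatible label is HV. An untyped panel returns "undetermined".

**Combination** (`combine_calls()`). Calls are concordant when equal or
when one is an ancestor of the other (RFLP "U" vs HVS-I "U5a1"); the
deeper label is kept. A missing RFLP call leaves concordance
not-evaluable (`NA`). Discordance keeps the HVS-I label and flags
`concordant = FALSE`, since HVS-I carries more resolution in this data
model.

## Geographic lineage classes

`geo_class()` maps haplogroup labels to West Eurasian, East Eurasian,
South Asian or Unclassified by **longest-prefix match** over a flat
table, mirroring the published clustering lists (West: R0/HV, N1, JT,
UK, W, X; East: M with C, D, G, Z, M9–M13, plus A, B, F, N9a; South
Asian: U2a–c, U9, R1–R2, R5–R6, N1d). Longest-match makes
sub-haplogroup overrides (U2a is South Asian although U is West
Eurasian) automatic and auditable. Unlisted labels — including starred
paragroup notations like M* and R*, which a prefix scheme cannot
represent without capturing their named subclades — fall into
`Unclassified` rather than erroring, because comparative datasets
routinely contain haplogroups outside the three lists.

On the fixture this pipeline classifies 11/19 individuals East Eurasian
(58%) and 8/19 West Eurasian (42%), with the 3 Bronze Age samples 100%
East and the 16 Iron Age samples exactly 50/50 — the admixture profile
the acceptance script recomputes.

## Diversity statistics

For a population of N profiles over a common window:

- **K**, distinct haplotypes: identity is equality of variant sets.
- **S**, segregating sites: positions with at least two allelic states
  in the sample. A position carried by *every* sample (e.g. 16223 and
  16362 in the Bronze trio) is monomorphic within the population and
  does not count; this is what makes the Bronze S equal 5 rather than
  the 7-position union. S is defined as 0 for N = 1.
- **Ĥ**, Nei gene diversity: `N/(N−1) · (1 − Σp_i²)` with the standard
  Nei sampling variance
  `V = 2/[N(N−1)] · {2(N−2)[Σp³ − (Σp²)²] + Σp² − (Σp²)²}`.
- **π**, nucleotide diversity: mean pairwise difference count over all
  C(N,2) pairs divided by L = 350, with Tajima's no-recombination
  sampling variance `V(π) = (n+1)π/(3(n−1)L) + 2(n²+n+3)π²/(9n(n−1))`.
  No substitution-model (e.g. Jukes–Cantor) correction is applied; the
  raw estimators are the ones named by the study design.

Pairwise differences are computed as the symmetric difference of
variant sets (positions shared with unequal explicit alleles also
count), which is exactly the Hamming distance of the materialized
sequences; a sequence-based brute-force oracle in the test suite checks
this to 1e-12. One documented discrepancy: the Bronze-trio π computed
from the printed profiles is 10/(3·350) ≈ 0.0095, whereas the source
table prints 0.0106; no documented convention reproduces that cell, so
the package computes from first principles and the tests freeze the
derivable value.

## Population distances and ordination

**ΦST** (`phi_st()`) is the AMOVA fixation index with the pairwise
difference count playing the role of the squared inter-haplotype
distance (the convention of the standard haplotype-data AMOVA): total
and within-group sums of squared distances give variance components
σ²_a and σ²_w, and ΦST = σ²_a/(σ²_a + σ²_w). The raw estimate may be
negative — in degenerate symmetric configurations (two groups with
identical haplotype multisets) it reaches −1 because the among-group
sum of squares is exactly zero — and is reported raw; truncation to 0
happens only in **Slatkin linearization**, `max(F,0)/(1−max(F,0))`,
which maps FST ≥ 1 to `Inf` with a warning. Significance uses a label
permutation test with `p = (1 + #{Φ_perm ≥ Φ_obs})/(n_perm + 1)`; ties
count, so at complete fixation the floor 1/(n_perm+1) is reached only
when no permutation reproduces the observed split. The default is
1000 permutations and an explicit seed is required.

**Ordination** (`classical_mds()`) defaults to classical (Torgerson)
metric MDS — double-centering and eigendecomposition, keeping the top
two non-negative eigenpairs — because it is deterministic and exactly
recovers any rank-≤2 Euclidean configuration, which the tests assert to
1e-9. The originally used software may have run non-metric scaling;
since that variant is iterative and initialization-dependent it is
exposed as `method = "nonmetric"` (isoMDS) rather than the default.
Axes are sign-fixed (first population non-negative) and goodness of
fit is reported as Kruskal stress-1.

## Median-joining networks

Haplotypes are binary presence/absence vectors over variant positions,
adequate because each position carries a single derived allele in this
data model; the quasi-median generalization for multi-state characters
is out of scope. Distances are weighted symmetric differences; the
packaged **weight scheme** down-weights mutational hotspots two-fold
(hotspot weight 1, other positions 2) with the hotspot list editable,
because the cited weighting's exact values are not published — the
defaults declare a scheme rather than inferring one.

The **minimum spanning network** keeps a link (u,v) iff d(u,v) ≤
minimax(u,v) + ε, where minimax is the single-linkage merge level
(bottleneck distance). At ε = 0 this is exactly the union of all
minimum spanning trees (all ties retained); the criterion is monotone
in ε by construction. **Median joining** then iterates: propose the
position-wise majority state of every connected triplet in the current
MSN, add the candidate median that most reduces the total network cost
(MST weight), and stop when no candidate reduces cost, with a
configurable iteration guard that raises a diagnostic error rather
than looping. Finally, unobserved nodes of degree ≤ 2 are pruned and
the MSN rebuilt until stable — a degree-2 latent node never reduces
cost, so nothing informative is lost. Determinism is guaranteed by
sorting input haplotypes (multiplicity descending, then lexicographic
variant string) and resolving candidate ties lexicographically. Edges
carry their mutated positions; export is GML/DOT via igraph and
round-trips node and edge counts.

## Haplotype sharing

`shared_haplotype_matrix()` counts haplotypes (identical variant sets;
windows must match, so trim comparative data to 16051–16400 first)
present in ≥ 2 populations, with a symmetric pairwise matrix whose
diagonal is each population's K. Sharing is counted at the haplotype
level, not the haplogroup level — the stricter and unambiguous reading.
`shared_by_class()` haplogroup-calls each shared haplotype and
partitions by geographic class. The published cross-study sharing
fractions (7/72 etc.) require external comparative datasets and are
deliberately not reproduced; the fixture-level facts the package does
establish are 16 distinct haplotypes among the 19 individuals and zero
sharing between the Bronze and Iron Age groups.

## Synthetic data generator

`generate_admixed()` emulates the two-source admixture structure
hypothesized for the region: each sample draws its source (East with
probability α), a haplogroup uniformly from the source pool, that
haplogroup's motif, `Poisson(private_mutation_rate)` private variants
at non-motif positions, and with probability `damage_rate` one spurious
singleton — damage is modelled only as extra singleton transitions,
never motif erasure, which is what a classifier-robustness test needs
from it. Defaults: pools restricted to the haplogroups observed in the
fixture (East {A, C, D, G2a}; West {HV6, J, T1, U5a1, K} — HV6 stands
in for the HV lineage because plain HV has no HVS-I motif and would be
uncallable from HVS-I alone); `private_mutation_rate = 1`, matching the
1–4 private variants per fixture sample; `damage_rate = 0.02`, a modest
rate for well-preserved cold-climate material; hotspot positions drawn
with a 10× relative rate. The seed is mandatory and the generator is
byte-reproducible given it.

What the simulation does *not* model: coalescent genealogy (samples are
independent draws, so within-pool haplotype frequencies are uniform
rather than skewed), realistic fragment-length or full damage
chemistry, and RFLP typing (synthetic panels are empty, exercising the
not-evaluable concordance path). Passing recovery tests therefore show
that the pipeline inverts its own generative assumptions — caller
accuracy ≥ 95% under the default noise, admixture-fraction error
shrinking with n (checked at n = 50/200/800), ΦST = 1 for disjoint
fixed demes and ≈ 0 for identically configured demes — not that it is
robust to every property of real ancient DNA.

## Problem sizes and determinism

Every analysis in the package is desk-scale: the fixture has 19
samples, simulations in the tests use n ≤ 800, and the property suites
run hundreds of randomized instances in seconds. All stochastic steps
(permutation tests, the generator) require explicit seeds and restore
the caller's RNG state, so results are reproducible to the byte.

## Known limitations

- The motif table is a reduced phylogeny: ~30 Eurasian haplogroups.
  M11/M12 are omitted (no reliable position-only HVS-I motif); extend
  the TSV to add clades.
- Transition-implied alleles mean a printed transversion at a bare
  position would be mis-materialized; profiles with explicit alleles
  avoid this, and the fixture contains none.
- ΦST assumes exactly two groups (pairwise); multi-group AMOVA is out
  of scope.
- The geographic class table cannot express starred paragroups (M*,
  R*); they classify as Unclassified.
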