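---
title: "Mapping equivalent residues across GluN subunits and transferring variant annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping equivalent residues across GluN subunits and transferring variant annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glunmap)
```

## The problem

De novo missense variants in the *GRIN* genes produce dysfunctional GluN
subunits of the NMDA receptor and cause a spectrum of neurodevelopmental
disorders. Choosing a therapeutic direction depends on two annotations per
variant: a pathogenicity class (pathogenic / benign / uncertain) and a
functional class (loss-of-function, gain-of-function, or complex).
Experimental annotation is slow, so annotated variants lag far behind
identified ones.

The GluN1, GluN2A and GluN2B subunits share a conserved domain
architecture — amino-terminal domain (ATD, two sublobes), ligand-binding
domain (LBD), transmembrane domain (TMD), and a structurally unsolved
carboxy-terminal domain (CTD). Structure is conserved far more strongly
than sequence, so a residue in one subunit typically has a well-defined
*equivalent position* in the others. Two variants with the **same**
amino-acid change at equivalent positions in different subunits —
*homologous variants* — tend to share their annotations. `glunmap` builds
the residue-level equivalence map from structural superposition and uses
it to (a) transfer annotations from annotated variants to their
unannotated homologs and (b) measure, database-wide, how concordant
annotations at equivalent positions actually are.

## The procedure

1. **Chains and numbering.** `read_structure()` extracts alpha-carbon
   chain models per polymer chain (PDB or mmCIF). All downstream positions
   are canonical: 1-based over the full-length reference protein, signal
   peptide included — the numbering HGVS `p.` notation uses. Deposited
   constructs (and the rat GluN2B structure) are reconciled with
   `numbering_map_from_alignment()`, which reads a monotone
   construct-to-canonical map off a global sequence alignment; mismatched
   residues of a near-identical orthologue are kept but flagged.
2. **Per-domain superposition.** For each subunit pair and each domain
   block (ATD1 and ATD2 independently, LBD and TMD each as one —
   discontinuous — unit), `superpose()` seeds a correspondence from a
   global sequence alignment, solves the least-squares rigid transform by
   the Kabsch/SVD construction, and iterates outlier rejection: pairs
   farther than `reject_cutoff` after the fit are dropped and the fit
   recomputed, until stable or `cycles` rounds. The reported RMSD is

   $$\mathrm{RMSD} = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}\lVert R\,p_i + t - q_i\rVert^2}$$

   over retained pairs; the all-pair value under the final transform is
   kept alongside because published numbers do not always say which
   convention they use.
3. **Structural alignment.** With both chains in one frame,
   `structural_alignment()` pairs residues by mutual nearest neighbour
   within `pairing_cutoff`, then keeps the maximum-cardinality
   non-crossing subset (longest increasing subsequence over partner
   positions, ties to the smaller summed distance), so the result reads
   like a sequence alignment with no crossings. Identity statistics are
   computed on it.
4. **Equivalence map.** `build_equivalence_map()` merges the per-domain
   structural alignments with whole-sequence fallbacks
   (`global_align()`, Needleman–Wunsch with affine gaps) for regions the
   crystals do not resolve. Structural entries take precedence at any
   contested position; fallback pairs are only admitted inside runs of at
   least `min_fallback_run` consecutive aligned columns, which suppresses
   spurious single-residue matches in low-identity stretches.
   Three-subunit composition consistency is checked
   (`check_three_way_consistency()`) and reported, never auto-repaired.
5. **Transfer.** A *homolog* of a variant is a database variant with the
   same reference **and** alternate residue at an equivalent position.
   `predict_annotations()` transfers pathogenicity and functional classes
   independently: homologs annotated `uncertain`/`unannotated` never
   contribute, unanimity yields a prediction, disagreement yields an
   explicit `conflict` with no call. Predictions stay in a separate table
   with provenance `"inferred-by-homology"` — they are never silently
   merged into observations.
6. **Evaluation.** `group_equivalent_variants()` groups variants at
   equivalent positions into three disjoint comparison categories:
   homologous (same ref, same alt), same-final (different ref, same alt)
   and same-initial (same ref, different alt). `concordance()` calls a
   group coincident when all informative members agree; for pathogenicity
   the uncertain members are discarded first, and a group left with fewer
   than two informative members leaves the denominator.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cycles` | 5 | rounds | rejection rounds of the superposition refinement; mirrors the defaults of align-style superposition tools |
| `reject_cutoff` | 2.0 | Å | post-fit distance beyond which a pair is an outlier |
| `pairing_cutoff` | 4.0 | Å | mutual-NN pairing radius, about one alpha-carbon spacing (3.8 Å) |
| `matrix`, `gap_open`, `gap_extend` | BLOSUM62, 10, 0.5 | — | conventional protein-alignment scoring; a gap of length $L$ costs $10 + 0.5L$ |
| `min_fallback_run` | 5 | columns | minimum consecutive aligned run for sequence-fallback pairs |
| `identity_denominator` | `"columns"` | — | identical residues divided by aligned columns (gaps included); `"pairs"` and `"domain_length"` are available because published "out of N" denominators are ambiguous between these conventions |

Display rounding of identity percentages is half-up to two decimals;
internal values are never rounded.

## The synthetic-data generator

Real structures are large downloads and curated variant tables are
external, so every stage is exercised on synthetic data with known ground
truth:

- `toy_structure_pair()` builds an ideal helix (100° twist, 1.5 Å rise
  per residue, 2.3 Å radius) or a zigzag sheet, applies a seeded random
  rigid transform plus isotropic Gaussian coordinate noise and optional
  per-residue displacements, and stores the true correspondence and
  transform.
- `toy_trio()` makes three rigid, noisy copies with small numbering
  offsets per subunit and runs the *real* pipeline to produce an
  equivalence map.
- `toy_variant_db()` plants homologous variant groups on a map with a
  target agreement rate `p_agree`, and returns a per-group truth ledger.
  Agreement flags are planted as an **exact count** — `round(p_agree * n)`
  agreeing groups in seeded random order — rather than iid coin flips, so
  the realized rate equals the nominal rate and recovery tests are sharp
  (an iid draw at $n = 200$ has a 2.8-point standard deviation, which
  would make a ±3-point recovery check uninformative about the
  measurement machinery).
- `write_demo_workspace()` writes the whole set as plain-text files (PDB,
  FASTA, JSON, TSV) plus the planted-truth ledger.

What the toys deliberately do **not** emulate: real domain shape
(globular packing, secondary-structure diversity), insertions/deletions
between subunits within a domain, unresolved loops of varying length,
low-identity twilight-zone pairs, and the empirical composition of
variant databases. Passing the synthetic suite therefore demonstrates
that the machinery is correct (exact recovery of planted truth), not that
the biological conclusions hold on real structures — those checks run
only when the experimental inputs are supplied (see
`inst/extdata/real/README.md`).

## Numerical choices and degenerate inputs

- Kabsch reflection case: the sign of the smallest singular direction is
  flipped, so the returned matrix is always a proper rotation
  (det = +1), even for near-planar or mirrored clouds.
- Fewer than 3 pairs, or a cloud of coincident points, is an error;
  rejection that would leave fewer than 3 pairs aborts with
  "superposition collapsed" rather than returning a meaningless fit.
- Mutual-NN ties and LIS ties are broken towards the smaller distance;
  with continuous coordinates exact ties have measure zero, so the
  pairing is deterministic in practice and symmetric under swapping the
  chains.
- Rotation-recovery checks use 100-residue helices: a thin helix
  constrains rotation about its own axis only through its 2.3 Å radius,
  so the noise floor of that degree of freedom at σ = 0.3 Å sits safely
  below the 2° bound only once enough residues average it down.
- Alternate locations resolve to the highest occupancy (first in file on
  ties); MSE is read as Met; other non-standard residues are dropped
  with a warning.
- Problem sizes in the shipped tests and acceptance script: toy trios of
  60–320 residues, 200 planted groups, 40 random sequence pairs of
  length ≤ 8 for the alignment oracle, brute-force rotation search on
  4–6-point clouds — the whole suite runs in well under a minute.

## Design decisions that were genuinely open

- **Conflict policy.** Disagreeing homologs produce `status = "conflict"`
  and no call, rather than a majority vote: for a clinically adjacent
  tool an explicit refusal is worth more than a fragile guess.
- **Transfer independence.** Pathogenicity and functional classes
  transfer independently; a homolog may support one and not the other.
- **Three-way composition.** Pairwise maps need not compose exactly over
  a trio; inconsistencies are reported, and the GluN2A–GluN2B direct
  alignment (the highest-identity pair) is what the map stores for that
  pair.
- **Expansion baseline.** The percent increase in pathogenic variants
  depends on the chosen baseline (all observed pathogenic records by
  default); it is a reported, configurable input of
  `annotate_database()`, not an assumption.
- **ATD sublobes.** Superposition and RMSD are per sublobe (ATD1/ATD2),
  identity is reported over the whole ATD; equivalence entries come from
  the sublobe alignments, with whole-ATD alignment available by simply
  defining an `ATD` range instead.
- **Trio counting.** A variant present in all three subunits is one
  group, and coincidence requires all three to agree; pairwise counting
  can be recovered from the group detail if wanted.

## Known limitations

- Rigid-body superposition only — no flexible alignment, no TM-score; a
  domain with a genuine hinge would need splitting into blocks.
- Maps cover GluN1/GluN2A/GluN2B only; GluN2C/2D and GluN3A/3B wait on
  structures.
- The CTD is reachable only through the sequence fallback, and its low
  conservation means fallback coverage there is intentionally sparse.
- Missense substitutions only: truncating, frameshift and splice
  variants are rejected at parse time.
- The transfer rule is purely qualitative; it produces classes, never
  probabilities, and variants without an annotated homolog remain
  unannotated — by design the algorithm cannot exceed the coverage of
  its input database.

## A worked run

```{r demo}
dir <- tempfile("demo-")
ws <- write_demo_workspace(dir, seed = 1)
trio <- ws$trio

# per-domain summary of the toy trio
doms <- read_domain_config(file.path(dir, "domains_synthetic.json"))
domain_summary(trio$chains, doms, pairs = list(c("GluN2A", "GluN2B")))

# query the map and annotate the planted database
map_position(trio$map, "GluN2B", 10)
res <- annotate_database(ws$variants$db, trio$map)
res$expansion

# concordance against the planted truth
g <- group_equivalent_variants(ws$variants$db, trio$map, "homologous")
concordance(g, "pathogenicity")
```
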