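---
title: "Detecting Batrachium hybrids from additive ITS polymorphisms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Batrachium hybrids from additive ITS polymorphisms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridtrace)
```

## The model

Direct Sanger sequencing of a diploid (or polyploid) individual reads both
homoeologous copies of the nuclear ribosomal ITS region in one
chromatogram. In a pure species the two copies are (nearly) identical and
the consensus is an ordinary sequence. In an interspecific hybrid each
parental ribotype contributes its own peak, so at every alignment column
where the parents differ the base caller reports the IUPAC ambiguity code
whose base set is the *union* of the parental bases. Formally, writing
$S(x) \subseteq \{A,C,G,T\}$ for the base set of code $x$, an F1 hybrid of
parents $a, b$ satisfies, column-wise,

$$ S(q_p) \;=\; S(a_p) \cup S(b_p) . $$

This is the entire inferential lever: hybridity is detected as additive
polymorphism, and parentage is inferred by finding the panel pair whose
column-wise union best reproduces the query. Plastid spacers are
maternally inherited in these plants, so a hybrid's plastid haplotype
identifies the seed parent; the other ITS parent must then be the pollen
donor. The package assumes:

* inputs are pre-aligned (alignment is upstream, done in an editor; the
  package validates geometry and alphabet but never aligns);
* ITS is inherited biparentally and not yet homogenised by concerted
  evolution (recent, mostly sterile F1 clones — the study system);
* plastids are strictly maternally inherited;
* the reference panel contains ribotypes of all plausible parents,
  possibly several variants per species.

## Site classification

For a query against an ordered parent pair, every column gets exactly one
label:

| label | condition |
|---|---|
| GAPPED | any comparand is `-`, or any reads `N` |
| INVARIANT | $a_p = b_p$ and $q_p = a_p$ |
| PARENT_A / PARENT_B | $a_p \ne b_p$ and $q_p$ equals that parent |
| ADDITIVE | $a_p \ne b_p$, $q_p \ne a_p, b_p$, $S(q_p) = S(a_p) \cup S(b_p)$ |
| RESIDUAL | everything else |

Two deliberate choices. First, `N` is treated as uninformative and binned
with GAPPED rather than as the 4-base set: a column read as `N` carries no
additive *evidence*, and counting it as a superset match would inflate
additive counts. Second, when a parent itself carries an ambiguity code
and the query equals that parent (so the PARENT and ADDITIVE definitions
overlap), the PARENT label wins; this is consistent with how ambiguity
dropout is handled — a hybrid column that reads as a single parental base
is normal Sanger behaviour (peak-height imbalance), so it counts toward
neither the additive nor the residual tally.

## The single-base indel shift

When two parental ribotypes differ by a 1-bp indel, the two reads run out
of register downstream: at read position $p \ge g$ (the indel column) the
chromatogram superposes the longer parent's base $l_p$ with the shorter
parent's *next* aligned base. With the gap removed from the short parent
(sequence $s$, length $L-1$), the expected consensus is simply
$S(q_p) \supseteq S(l_p) \cup S(s_p)$ for every read position, which in
alignment coordinates means comparing $l_p$ with the short parent's
column $p+1$. `shifted_superposition()` tests exactly this; the shift is
called consistent when at least $1 - \tau_{noise}$ of the testable
downstream columns are explained. `score_pair()` then removes
shift-explained columns from the residual count: they are consequences of
one event (the indel), not independent unexplained sites. The indel
itself remains visible as the reported indel position — it is one
polymorphism, as a hybrid-group description like "21 positions: 20 SNPs
plus one single-base indel" treats it. Multi-column indels between
ribotypes are left as GAPPED columns and excluded from scoring; the shift
model is only physically justified for the single-base case.

## Verdicts and thresholds

`infer_parentage()` proceeds per sample:

1. **Species check.** Distance to each panel ribotype = mismatching
   columns over informative positions (no gap, no `N` on either side). If
   the nearest ribotype is within `tau_species` the sample is that
   species. Default **2**: named ribotypes of one species routinely
   differ by one or two substitutions, so a pure sample should absorb
   that much private variation without being escalated to hybrid status.
2. **Pair search.** All cross-species ribotype pairs are scored; within a
   species pair the best ribotype combination represents it (hybrids
   carry the ITS copies of their local parental populations, so the
   representative variant is chosen freely). Pairs are ranked by fewest
   residuals, then most additive columns, then fewest one-parent-only
   columns, then alphabetically — fully deterministic.
3. **Verdict.** Best pair within `tau_residual` residuals → F1_HYBRID.
   Default **2**: a couple of unexplained columns are plausibly
   unsampled within-species ribotype variation rather than a third
   lineage. Beyond that → COMPLEX_HYBRID, and every third-species
   ribotype is ranked by how many residual columns the three-way union
   $S(a_p) \cup S(b_p) \cup S(c_p) \supseteq S(q_p)$ explains. No additive
   evidence for any pair → UNRESOLVED.

`tau_noise` (default **0.05**) is the tolerated fraction of unexplained
downstream columns in the shift test; `delta_max` (default **2**) is the
maximum accepted distance for plastid haplotype assignment, sized to
accept the "slightly deviating variant" seen within a clade (distance 1)
while rejecting cross-clade matches (clades sit many substitutions
apart). All four live in `ht_config()` and are configurable; none were
stated numerically by the original analysis, which is why they are
explicit here.

## Cross orientation

Each available plastid marker votes for the ITS parent whose species maps
to the sample's assigned haplotype. A haplotype shared by both ITS
parents, or mapping to neither, casts no vote — shared clades cannot
orient a cross. Agreeing votes orient (maternal = voted species);
disagreeing markers are reported CONFLICT rather than resolved by any
precedence, since a conflict indicates a reference or assignment problem
the analyst should see. `directionality()` then reports the fraction of
oriented crosses whose paternal parent is a focal species; the packaged
default focal species is *R. circinatus*, the inferred universal pollen
donor in this system. Unoriented and conflicted crosses are excluded from
the denominator and reported alongside.

## Survey statistics and rounding

`summarize_region()` uses two denominators deliberately: individual
percentages divide by all classified individuals, locality percentages by
the number of *studied* river sites in the region (21 in Lithuania, 19 in
Central European Russia) — not only sites that yielded sequences. This is
the only convention that reproduces the published 76% and 32% figures
from the underlying counts, and it is also the epidemiologically sensible
one (a surveyed site without hybrids is evidence, not missing data).
Reported percentages use half-*up* rounding (`round_half_up()`), not R's
banker's rounding: 48/66 → 72.7 → 73, 16/21 → 76.2 → 76, 15/21 → 71.4 →
71, 13/36 → 36.1 → 36, 6/19 → 31.6 → 32, 3/19 → 15.8 → 16. Raw ratios are
returned alongside the rounded integers.

`batrachium_survey()` ships per-locality tallies *reconstructed* from the
published aggregate counts (66 = 18 + 48 individuals over 6 + 16
localities with one co-occurrence; 36 = 23 + 13 over 16 + 6 with three
co-occurrences). The locality-level structure is exact; the split of
individuals across localities within each class is an even synthetic
reconstruction, which does not affect any statistic the package computes
from it. Whether "constant" additive positions were originally assessed
per group or per locality is ambiguous in the source; the package
therefore makes the group explicit —
`constant_additive_positions()` takes whatever set of samples the analyst
considers a group and intersects their additive position sets.

## The synthetic generator

`generate_panel()` draws each species ribotype independently from one
random ancestral sequence. The per-lineage substitution rate $r$ is
calibrated from the requested *pairwise* divergence $d$ by solving
$2r - \tfrac{4}{3}r^2 = d$ (two lineages differ if exactly one mutated,
or both mutated to different bases, substitutions being uniform over the
three alternatives, Jukes–Cantor-like), so the expected differing-column
count between two species is exactly $dL$ — 19.5 at the defaults
$d = 0.03$, $L = 650$, matching the ~16–21 additive positions reported
for real hybrid groups. Within-species variants mutate at 0.003. Plastid
haplotypes (default length 300) are drawn the same way, one per species;
if a drawn pair happens to sit within the assignment tolerance, each
species receives a private block of diagnostic substitutions so that
nearest-reference assignment is always unambiguous.

`generate_hybrids()` builds F1 consensus sequences as exact column-wise
unions (or the out-of-register trace superposition when the parents
differ by a single-base indel), applies ambiguity dropout independently
per additive column (the column reads as one parent's base with
probability `dropout_noise` — emulating the non-uniform additive patterns
of real traces), adds a third parent's bases at `extra_additive_sites`
(default 6) columns for three-way hybrids, and copies each hybrid's
plastid sequences from its maternal parent. Under
`maternal_rule = "FIXED_NON_FOCAL"` every cross includes the focal
species as pollen donor, emulating strictly unidirectional crossing. All
randomness flows from one integer seed through R's Mersenne-Twister
generator; identical seeds give byte-identical FASTA/TSV bundles.

What the generator does *not* emulate: concerted evolution partially
homogenising hybrid ITS, PCR drift/recombinant chimeras, backcross
gradients in peak heights, alignment error, and phylogenetic structure
among species (the panel is a star phylogeny). Passing recovery tests on
this generator therefore demonstrates the correctness of the additive
logic and the pipeline plumbing, not robustness to every artefact of real
Sanger data.

## An identifiability limit of three-way decomposition

A three-way hybrid built as pair union plus a few third-parent sites is
reliably *detected* (COMPLEX_HYBRID, since the extra sites exceed
`tau_residual`), and the full parental trio — best pair plus top-ranked
third candidate — is recovered in 100% of noise-free simulations. But the
*decomposition* into "primary pair" and "third contributor" is not always
identifiable: if one primary parent happens to have fewer private sites
(sites where it alone differs, Poisson with mean ≈ 9.5 under the default
divergence) than the third parent contributed (6), then swapping that
parent with the third yields strictly fewer residuals, and any
residual-minimising ranking — including this one — prefers the swapped
decomposition. Both decompositions explain every column. Accordingly the
package's tests assert verdict and trio recovery, not the arbitrary
pair/third labelling, and users should read `third_parent` as "one member
of the inferred trio", with `third_parent_candidates` giving the full
ranking.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data at the scale the simulated study conditions prescribe: cohorts of
100 F1 hybrids (4 species, 650 columns, 3% divergence) for recovery and
orientation, 50 three-way hybrids for complex detection, 20 indel-pair
hybrids for the shift model, 200 panel replicates for the divergence
calibration check, and exhaustive enumeration (all $16^3$ symbol triples,
all $15^2$ code pairs) plus 1,000 random 650-column triples for the
classifier and the IUPAC algebra. Everything is seeded; re-running any
stage with the same seed reproduces results exactly, including file
bytes.

## Known limitations

* Parentage is only as good as the panel: a missing true parent surfaces
  as a wrong pair with many residuals or as COMPLEX_HYBRID with no
  convincing third candidate, not as an explicit "unknown parent" call.
* The species check precedes the pair search, so a hybrid of two
  near-identical ribotypes (divergence at or below `tau_species`) is
  invisible by construction — as it is to the underlying laboratory
  method.
* Backcrosses and later-generation hybrids violate the clean F1 union
  model; they will typically appear as F1 with elevated parent-only
  counts or as COMPLEX_HYBRID.
* The plastid logic assumes strict maternal inheritance; paternal
  leakage would silently flip an orientation.
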