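---
title: "Screening endolysin genes for internal translation start sites"
author: "lysinITSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening endolysin genes for internal translation start sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysinITSS)
```

## The problem

Some phage lytic-enzyme genes encode two proteins: the full-length product
(FLP) and, from an in-frame internal translation start site (iTSS) with its
own Shine–Dalgarno (SD) sequence, a shorter C-terminal product (CTP) that is
a suffix of the FLP. The two isoforms can associate into a heteromultimeric
enzyme whose composition is an integer pair (a FLP, b CTP). This package
implements the computational side of finding such genes and characterising
the resulting protein pairs: candidate-site scoring, a filter cascade,
cluster-level consensus, product derivation and architecture grouping, and
the gel-filtration and native-MS arithmetic used to infer stoichiometry.

## The TIR model and its assumptions

Every internal ATG/GTG/TTG codon (1-based codon index ≥ 2, the stop codon
excluded) is a candidate. The built-in scorer assigns

$$\mathrm{TIR} = k \exp(-\beta\,\Delta G_{total}), \qquad
\Delta G_{total} = \Delta G_{SD} + \Delta G_{spacing} + \Delta G_{start}$$

* $\Delta G_{SD}$: for each aligned spacing $s$ in the search window, the
  upstream hexamer facing the anti-SD core (default `CCUCCU`, i.e. the SD
  consensus AGGAGG) is scored by summing per-pair energies over the longest
  contiguous complementary run — G:C −3.0, A:U −2.0, G:U wobble −1.0
  kcal/mol — plus a duplex initiation penalty of +4.1 kcal/mol. Runs shorter
  than two pairs, and any placement whose total is unfavourable, contribute
  nothing (the duplex simply does not form, so $\Delta G_{SD} \le 0$).
* $\Delta G_{spacing}$: zero inside the optimal aligned spacing of 5–10 nt;
  outside it, $0.3\,d^2$ kcal/mol where $d$ is the distance to the optimum.
  Spacings of 4–16 nt are searched; only sequence inside the CDS is used,
  so a candidate at codon 2 simply finds no SD and still gets a finite
  positive score.
* $\Delta G_{start}$: 0 for ATG, +1 for GTG, +2 for TTG (kcal/mol),
  enforcing the canonical start-codon preference.

With $\beta = 0.45$ per kcal/mol and $k = 47.2$ relative units, a canonical
AGGAGG at spacing 7 nt upstream of an ATG scores ≈ 10,000, placing planted
strong sites in the regime of experimentally notable TIRs. The model is
deliberately small: no mRNA folding, no standby sites, no claim of numerical
agreement with full thermodynamic RBS predictors. It exists so that
synthetic cohorts can be scored self-consistently; for real data, external
TIR predictions are supplied as a TSV (`readTirTable()`) and override the
scorer entirely — candidates absent from the table are treated as unscored.
Per-genus parameter overrides mirror the practice of scoring a gene in its
phage host context, falling back to defaults for unknown genera.

## The four filters

The top-scoring candidate of each gene (ties to the 5′-most codon) passes
through four independent flags; a gene is retained only if all four hold.

1. **Background outlier.** "Clearly above background" is formalised as the
   Tukey upper fence: the candidate's TIR must exceed
   $Q_3 + 1.5\,\mathrm{IQR}$ of all scored in-frame candidates of the same
   gene (quartiles by linear interpolation, type-7). The fence is the
   standard box-plot outlier criterion, matching how TIR distributions are
   usually presented. Consequences we accept deliberately: a gene with a
   single candidate, or with all-equal TIRs, can never pass. A z-score rule
   is provided as an alternative since the exact background criterion is a
   modelling choice; note its ceiling of $(n-1)/\sqrt{n}$ on small
   candidate sets.
2. **Gene extremities.** Candidates within the first or last 20 codons fail
   (boundaries inclusive: indices 1–20 and $L-19$ to $L$). 5′ hits are
   likely start-misannotations; 3′ hits would encode peptides smaller than
   the smallest conserved domains. Proteins of length ≤ 40 fail
   automatically.
3. **Conserved-domain overlap.** A candidate inside any domain hit fails,
   with inclusive endpoints — an iTSS at a domain's first or last residue
   still truncates it. Genes with no domain annotation at all pass this
   filter and the next, but are flagged (`no_domain_info`) so downstream
   users can treat them separately.
4. **Tail domains.** Any hit categorised "tail" (or carrying an accession
   from the configured tail list) excludes the gene as a likely
   misannotated virion-associated lysin. The shipped accession list is a
   documented starter set, not a census; it is configuration, because no
   authoritative list exists.

The flags are computed independently and combined by pure conjunction, so
evaluation order is irrelevant — a property the tests exercise explicitly.

## Clustering and positional consensus

Percent identity is computed from a Needleman–Wunsch global alignment under
an identity objective (match +1, mismatch 0, affine gaps: open 2, extend
0.5), with identity = 100 × matches / full alignment length. Counting
terminal gap columns is the conservative choice (a short fragment of a long
protein does not reach high identity); dividing by the shorter sequence is
available as an option. Because co-optimal alignments can differ between
argument orders, arguments are ordered canonically before aligning, making
the function exactly symmetric.

"Over X% identity" is read as a graph threshold: clusters are the
single-linkage connected components of the graph with edges strictly above
the threshold. This makes clustering at 90% a refinement of clustering at
50% on the same cohort (tested), and makes the result independent of input
order (cluster ids are assigned by smallest member id; representatives are
the longest member, ties by id).

For consensus, cluster members are aligned with a built-in center-star
progressive aligner (every member aligned to the longest sequence, gap
patterns merged into common columns, insertions left-aligned within their
gap block). At cluster scale this is entirely adequate; it is not a
general-purpose MSA. Each member's iTSS codon maps to an alignment column,
and the modal column — the value maximising the number of members within ±2
columns — becomes the consensus when that count exceeds half of the members
having a call. The ±2 tolerance for "same relative position" is a
configurable default: exact column equality would be brittle to single
indels, while a large tolerance would dilute the criterion.

## Products, architectures, masses

`deriveProducts()` returns the FLP (whole protein) and CTP (suffix from the
iTSS codon, first residue read as Met regardless of the native codon), with
an optional C-terminal tag — e.g. `PGGGSHHHHHH` — appended to both and
included in the masses. Product masses are *average* isotopic masses, the
convention matched to gel-based size estimates; *monoisotopic* masses (used
for denatured-MS comparisons) come from `sequenceMass(..., "monoisotopic")`.
Both residue tables are standard; the test suite cross-checks the
monoisotopic table against masses rebuilt from elemental composition.

Architecture grouping follows the two patterns recurring among iTSS-bearing
lytic enzymes: group 1 has ≥ 2 catalytic domains with the iTSS strictly
between two consecutive ones (the CTP inherits a complete catalytic domain),
group 2 has exactly one catalytic domain entirely upstream (the CTP carries
only C-terminal, often unannotated, sequence). Everything else is
`unclassified` rather than forced into a group.

Gel-filtration calibration uses $K_{av} = (V_e - V_0)/(V_t - V_0)$ with two
linearisations: $\log_{10}(M)$ linear in $K_{av}$ for mass, and
$\sqrt{-\ln K_{av}}$ linear in the Stokes radius (Laurent–Killander form).
Both fits are exposed and both estimation routes reported, because
published mass estimates commonly differ between them; standards at
$K_{av} = 0$ are excluded from the Stokes fit only (its transform
diverges), and out-of-range standards are dropped with a warning.
Charge-state series invert as $M = z \cdot m/z - z \cdot 1.00728$ Da
(proton mass constant), reporting mean ± sd across peaks. Stoichiometry is
exhaustive enumeration over $0 \le a \le 3$, $0 \le b \le 10$ by default —
bounds that comfortably cover heteromultimers of practical interest — with
ties resolved to smaller $a$, then smaller $b$; the full ranked table is
retained so near-misses are visible.

## The synthetic generator

The generator emulates the features of a real lytic-enzyme cohort that the
pipeline is sensitive to: host-genus labels with configurable weights; the
two architecture layouts above (plus a "none" layout) built from genuine
Pfam accessions; planted in-frame ATGs with a canonical AGGAGG at aligned
spacing 7 (strong) or no SD at all (weak); deliberate single-filter
violations (edge, domain, tail) at configurable rates; and a control family
with no planted sites. Backbone codons are drawn uniformly from the 61
sense codons, with SD-like hexamers (AGGAGG and one-mismatch variants)
rejected outside planted regions and the two codons immediately upstream of
a planted start cleared of competing start codons — both measures make
truth recovery sharp. Internal stops are excluded by construction, and SD
planting re-checks boundary codons so no in-frame stop is created. The
whole cohort is a deterministic function of the config, including the seed.

After generation, each gene is verified by running the actual screen, and
the truth table logs *collisions*: planted genes lost to the screen (e.g. a
spurious backbone site out-scoring the planted one — rare by construction)
and unplanted genes whose strongest background site passes all filters.
The latter are genuine false positives of the screen, not generator errors;
their existence on iTSS-free genes is exactly why real screens are compared
against a control family.

What the generator does **not** emulate: real phage codon usage and GC
content, genus-specific anti-SD variation, overlapping or fragmented domain
annotations, sequencing or annotation errors, and realistic protein-family
phylogenetic structure (clusters arise only from the generator's repetition
of layouts, not from descent). Passing tests on synthetic cohorts therefore
demonstrate the pipeline's internal correctness — filters fire exactly when
their conditions hold, planted truth is recovered — not the field accuracy
of the TIR model on real genes.

## Numerical conventions and degenerate inputs

* Protein coordinates are 1-based inclusive; the iTSS position is the codon
  index of the internal start, so a product named "209–310" spans residues
  209–310 and its CTP is 102 residues before tagging.
* Initiator codons ATG/GTG/TTG are all read as Met at position 1 and at an
  iTSS; internal GTG/TTG translate normally (bacterial code, table 11).
* Validation is collect-and-report: cohort and domain readers return a
  problems table instead of failing on the first bad record.
* Screen percentages round half-up to one decimal (printed-percentage
  convention; base R rounds half-even).
* Ranking ties (equal top TIR across genes) break by gene id for
  reproducible output.
* Empty cohorts, genes with no candidates, clusters with no calls,
  all-equal TIR backgrounds, proteins shorter than twice the edge window,
  and standards outside the fractionation range are all handled explicitly
  rather than erroring.

## Problem sizes in the test suite

The suite validates the screen against an independently coded brute-force
oracle on a hand-built 20-gene cohort (8 retained, 12 single-filter
violations) and on generator cohorts of 15–80 genes; recovery of planted
truth on a 500-gene cohort at planted fraction 0.5 (checked against the
exact binomial 99% interval after accounting for generator-logged
collisions); stoichiometry enumeration against a second, independently
coded loop on 1,000 random instances; monoisotopic masses against an
elemental-composition oracle on 100 random peptides (tolerance 1e-4 Da);
and gel-filtration round-trips to 1e-9. These sizes were chosen so the full
suite exercises every code path at statistical scale while remaining quick
to run routinely.

## Known limitations

* The built-in TIR scorer ranks sites sensibly but its absolute values are
  model-relative units; real screening should use external predictions via
  the TIR-table path.
* Single-candidate genes cannot pass the Tukey background rule; whether
  out-of-frame candidates should contribute to the background is a design
  choice (we use in-frame candidates only).
* The center-star MSA is adequate for within-cluster consensus but should
  not be used as a general aligner; an external MSA can be substituted by
  computing columns from it directly.
* Cluster memberships at a given threshold depend on the identity
  denominator convention; both conventions are exposed.
* The tail-domain accession list is a starter set and should be curated for
  the phage group under study.
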