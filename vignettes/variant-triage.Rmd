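---
title: "Triage of uncertain missense variants in an ion-channel family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of uncertain missense variants in an ion-channel family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vustriage)
```

## The problem

For TRPM4 — a calcium-activated, monovalent-cation-selective channel whose
variants are associated with inherited cardiac conduction disease — the
overwhelming majority of known missense variants are of uncertain clinical
significance (VUS). The same is true across the wider TRP-channel
superfamily. `vustriage` implements a triage pipeline that combines three
independent lines of evidence to nominate the VUSs most likely to be
damaging:

1. a **predictor gate**: the score of the best-benchmarked pathogenicity
   predictor, above a family-calibrated threshold;
2. **paralogue annotation**: a likely-pathogenic/pathogenic (LP/P) variant
   at the aligned position of a related family member, in a
   physicochemically conserved alignment column;
3. **structural contact evidence**: the variant's parental (wild-type)
   residue forms a sidechain contact with another high-scoring candidate
   residue in the tetrameric channel structure, so that either mutation
   would perturb the same inter-segment interaction.

Every stage is driven by plain tabular/FASTA/PDB inputs, and a seeded
synthetic-data module generates all of them, so the whole pipeline runs and
is tested without any database access.

## Catalog classification rules

Variant records from four export dialects (ClinVar-, Humsavar-, Ensembl-
and gnomAD-style tables) are merged on (gene, position, ref, alt) and each
merged record receives exactly one class:

* **LPP** — LP/P in Humsavar or Ensembl, or LP/P in ClinVar with a
  non-empty specific clinical condition. Any ClinVar record calling the
  same variant benign or uncertain *vetoes* the class: a database conflict
  is treated as insufficient evidence of pathogenicity.
* **VUS** — a ClinVar significance containing "Uncertain significance".
* **CIP** — ClinVar "conflicting interpretations"; kept, but never used
  in benchmarking.
* **BENIGN** — population allele frequency strictly greater than
  5 × 10⁻⁵ *and* no ClinVar record at all. Records without a reported
  frequency are never benign, since the rule cannot be evaluated.
* **EXCLUDED** — everything else (e.g. a ClinVar pathogenic assertion
  with no condition, or a population variant at or below the frequency
  threshold).

Both thresholds are strict inequalities; the frequency boundary case
(exactly 5 × 10⁻⁵) is therefore excluded, and tests pin this. When sources
disagree about the reference residue at a position the records are kept
separate and flagged (`ref_conflict`) rather than silently merged.
Coordinates are 1-based protein positions throughout; three-letter residue
codes are accepted on input and normalized to one-letter codes.

## Predictor benchmarking

The benchmark set is the catalog's LPP ∪ BENIGN records; VUS and CIP
records never enter it. For each tool with coverage (fraction of scored
variants) strictly above 30%, predictions are binarized at the tool's
published deleterious threshold (strict `>` or `<` according to the tool's
orientation; categorical tools map their classes through an explicit
table, e.g. merged "probably/possibly damaging", or assessor categories
H/M → Damaging, L/N → Tolerated) and summarized by

$$\mathrm{Sens} = \frac{TP}{TP+FN},\quad
  \mathrm{Spec} = \frac{TN}{TN+FP},\quad
  \mathrm{ACC} = \frac{TP+TN}{TP+FP+TN+FN},$$

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

Missing predictions are **dropped** from the confusion counts and reported
separately, never silently counted as tolerated — published accuracy
figures for such benchmarks often cannot be reproduced from the printed
sensitivity/specificity because this convention is left unstated, so the
coverage is always reported alongside. A zero MCC denominator returns 0 by
the usual convention.

ROC curves sweep every distinct score cut point (midpoints between
consecutive distinct scores plus sentinels, so the curve always contains
(0,0) and (1,1)); the AUC is computed as the Mann–Whitney concordance
probability with ties credited one half, which the tests verify against
exhaustive positive × negative pair counting and against an independent
ROC implementation (pROC). The per-tool "optimal deleterious threshold" is
the cut maximizing Youden's J = sensitivity + specificity − 1, with ties
broken toward higher specificity; Youden's J is the standard choice when a
single operating point must be read off a ROC curve.

## Paralogue annotation and the conservation score

Family members are aligned (the alignment is an input artifact; any MSA
program can produce it) and positions are mapped through shared alignment
columns. The mapping is defined only where neither sequence is gapped, is
injective, and round-trips — properties the tests exercise on a thousand
random positions.

Column conservation uses a ten-property physicochemical score in the
Zvelebil style: each of the twenty residues carries a fixed truth vector
over {small, polar, hydrophobic, tiny, charged, negative, positive,
aromatic, aliphatic, proline}, following the classic Taylor Venn-diagram
assignments ([aa_property_table()]). The column score

$$C_s = \frac{\#\{\text{properties with identical truth value across the
column}\}}{10}$$

is 1 for an identical column and 0 when no property state is shared. Two
deliberate choices:

* **Gap rule.** A gap shares no property state with any residue, so any
  column containing a gap scores 0. The cited methodology penalizes gaps
  but states no exact rule; this is the most conservative choice and makes
  unmapped or partially gapped columns ineligible for transfer.
* **Property-equivalent residues.** Under the fraction definition, a
  column of non-identical residues with identical truth vectors (e.g.
  isoleucine/leucine) also reaches 1.0. Descriptions of the score as
  peaking at "0.8 (high conservation)" below identity suggest the original
  service may cap non-identical columns; we keep the pure fraction and
  document it, since the transfer gate (below) is far from that region.

An LP/P variant of a paralogue transfers onto the reference channel when
its position maps to a reference residue and the column's \(C_s\) is
**strictly greater than 0.3**. A column at exactly 0.3 (e.g. D/K/G) never
transfers; tests pin this boundary. Conservation is computed over the
sequences present in the supplied alignment — the expected practice is to
exclude family members that carry no LP/P variants before aligning.

## Structural contacts

Candidate parental residues (by default the VUSs whose ClinPred score
exceeds 0.6) are examined in a homotetrameric channel structure. For every
unordered pair of candidate positions, over all chain combinations, the
minimum distance between **sidechain heavy atoms** (all atoms except
backbone N, CA, C, O, OXT and hydrogens; glycine has none and can never
form a contact) is computed. A pair is a contact when that distance is at
most 5 Å — the boundary is read inclusively and is configurable — and the
pair is *intersegment*: different topology segments, or any segments on
different subunits. Symmetric copies across the four subunits are merged
into one canonical pair annotated `intra` or `inter`; alternate
conformations are resolved to the highest-occupancy atom (ties prefer
altloc A) at parse time.

Contacts are classified by a configurable rule table keyed on the segment
pair and subunit relation (voltage-sensor activation contacts S1/S2/S3–S4
within a subunit, sensor-to-pore signal S4–S5 across subunits, the
S1–S5 clamp, pore-module folding S5–P1, P-loop folding P1–P2, activation
gating S5–S6), and partitioned into transmembrane/extracellular versus
cytoplasmic by the regions of both segments. A contact spanning the two
regions is assigned cytoplasmic — except pairs within the pore-forming
segments (S5, S6, P1, P2), which remain transmembrane — and flagged, since
published per-region tables place such boundary contacts ambiguously.

The shipped TRPM4 segment map (`trpm4_segments.yaml`) is a curated,
editable artifact: segment boundaries are not printed in most structure
papers, and the S6/TRP-helix boundary in particular is reported
inconsistently (residue M1042 appears under both labels in published
contact tables). This package's map ends S6 at 1044, placing M1042 in S6;
all counts are relative to whatever map the user supplies.

## Consensus tiers

* `consensus_LPP` — gated VUSs whose position received at least one
  conservation-gated paralogue transfer;
* `contact_implicated` — gated VUSs whose parental residue participates in
  at least one detected contact;
* `predictor_only` — the remaining gated VUSs.

The gate is a filter and is never overridden: every call carries a score
above the gate. Because a variant can be supported by both transfers and
contacts, the total candidate count is reported twice — as the
per-analysis sum (which double-counts such variants, the way headline
totals are usually quoted) and as the distinct-variant union. Reports are
byte-deterministic (fixed ordering, no timestamps), and all stages carry a
content hash of the catalog they were computed from; mixing stages from
different catalogs is an error.

## What the synthetic study emulates

`simulate_study()` generates every input from one master seed with fixed
per-generator substreams (catalog, scores, alignment, structure), so adding
a generator never perturbs the others and identical configurations are
byte-identical.

* **Catalog.** The default per-gene layout is the family-wide collection
  observed for TRP channels in the public databases: eight genes, 130 LP/P,
  1117 VUS and 103 benign variants, 565 VUSs on the reference channel.
  Benign frequencies are drawn in (5 × 10⁻⁵, 10⁻³]; one planted
  Humsavar-LP/ClinVar-VUS conflict exercises the veto.
* **Scores.** Per tool, scores come from two unit-variance Gaussians
  whose mean separation δ satisfies Φ(δ/√2) = target concordance; the
  default panel uses the AUC values observed for the 22 predictors on this
  family (0.62–0.90). Draws are mapped monotonically onto each tool's
  published scale with the published threshold at the class boundary, so
  binarization at shipped thresholds behaves sensibly and AUC is
  unchanged. VUSs draw from a latent pathogenic/neutral mixture shared
  across tools; the pathogenic fraction defaults to 0.55, chosen so that
  the expected fraction of VUSs passing the ClinPred gate matches the
  roughly-half observed in this family. A target of 1 is realized as
  δ = 8 (Φ(8/√2) ≈ 1 to twelve digits).
* **Alignment.** Background columns are fully conserved; each paralogue
  carries a private gap block (exercising coordinate mapping); a block of
  reference-gap columns holds paralogue insertions; planted divergent
  columns built from {W, D, G, P} score \(C_s \le 0.2\). 63 transferable
  paralogue LP/P variants are planted on 36 reference positions and the
  remaining paralogue LP/P variants on divergent or reference-gap columns,
  so the expected transfer set is exactly the planted one.
* **Structure.** Residues use idealized reference geometry from the PDB
  chemical component dictionary and are placed as isolated rigid-body
  islands; each planted pair's partner is translated until the minimum
  sidechain heavy-atom distance equals the request (solved numerically to
  10⁻⁶ Å, then nudged 10⁻⁶ Å inward so a pair planted exactly at a cutoff
  is detected under the inclusive boundary). The default layout plants 16
  transmembrane and 24 cytoplasmic pairs below the cutoff and 10 beyond it
  as negative controls, with positions drawn from the shipped TRPM4
  segment map and the contact-position VUSs forced into the pathogenic
  score component (contacts are sought *between high-scoring candidates*).

**What it does not emulate** — and hence what passing tests do and do not
show about real data: realistic sequence divergence (real alignment columns
take the full range of \(C_s\), not mostly 0, 0.2 and 1); realistic
allele-frequency spectra beyond threshold-straddling; correlated errors
between predictors (tools are independent given the latent class, so
real-data consensus counts will differ); real protein folds (islands have
no packing, so there are no near-miss contacts besides the planted ones);
and database idiosyncrasies such as multi-assertion ClinVar records. The
synthetic study validates the *machinery* — classification rules, metric
formulas, mapping, geometry — exactly; it does not validate biological
conclusions.

## Numerical and scale choices

* Strict inequalities at every published threshold (`>0.6`, `>0.00005`,
  `>0.3`, `>30%` coverage); the 5 Å contact cutoff inclusive.
* MCC denominator 0 → MCC 0; ROC ties → half credit; Youden ties → higher
  specificity.
* The unit tests run the full pipeline on a scaled-down family (3 genes,
  300-residue sequences, 6 planted transfers, 6 planted pairs) and the
  generator-recovery and oracle-equality checks at that scale; the
  acceptance script runs the full default (study-scale) configuration,
  which completes in a few seconds.

## Known limitations

* The benchmark's coverage filter is evaluated on the benchmark set
  (labelled variants), not the full catalog; with which set the published
  30% rule was applied is ambiguous, and the choice is configurable via
  the score table passed in.
* Start-loss variants (M1 positions) transfer like any other position;
  no special start-codon logic is applied.
* The segment map, the contact-category rules and the gate are all
  configurable artifacts; published counts can only be compared against
  the same versions of these inputs.
* Paralogue transfer attaches *all* reference-catalog variants at a
  position; it does not check that the reference alternate allele matches
  the paralogue's alternate allele.
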