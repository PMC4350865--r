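---
title: "Methods: provenance-tagged drug knowledge integration and medication analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: provenance-tagged drug knowledge integration and medication analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugkb)
```

## The problem

Drug-safety knowledge is scattered over sources with different evidence
bases: regulatory/package-insert ("pharmaceutical") databases, molecular
databases of drug–protein relations, side-effect catalogues coded in MedDRA
terminology, and pathway/disease resources. These sources overlap only
partially — concordance on the order of 10% of distinct hits is typical —
so any medication check based on a single source is structurally incomplete.
`drugkb` merges such sources into one knowledge base whose assertions all
carry provenance, answers medication-safety queries over the merged
knowledge, and quantifies exactly how much the sources agree.

## The data model

Six entity types: drugs, drug–drug interactions, side effects, molecules
(targets, enzymes, transporters, carriers), pathways, and diseases. The
merged container (`drug_kb`) is a list of tibbles with three structural
invariants enforced at construction:

* every drug referenced by an assertion exists, and every ATC code has the
  full 7-character shape (letter, 2 digits, 2 letters, 2 digits);
* interaction pairs are stored unordered in canonical form — the
  lexicographically smaller drug id first — and no two assertions share a
  canonical pair: re-assertions merge into one row whose `provenance` is the
  union of source tags (effect texts are retained per source, never
  concatenated);
* side effects are stored under canonical terms only; raw synonyms are
  resolved at ingest through a raw→canonical table.

Name matching everywhere uses one normalization: case-fold, trim, collapse
internal whitespace, strip punctuation. We deliberately do not strip salt or
stereo suffixes ("aspirin lysinate" stays distinct from "aspirin"): without a
vetted rule this creates more false fusions than it repairs.

## Cross-source drug mapping

Two mapping routes mirror what the source pairs support:

* `map_by_atc_and_id()` — links drugs sharing a native cross-reference
  identifier (an `xrefs` value equal to the partner's native id, or an
  identical `key:value` xref); among the rest, drugs sharing at least one
  *full* ATC code. Class-level (shorter) ATC codes never match — a 5-character
  class spans many substances and would fuse them.
* `map_by_name()` — links drugs whose normalized names or synonyms are equal,
  for source pairs without corresponding identifiers.

Both resolve conflicts to a 1:1 mapping: candidates are scored (shared
identifier > shared ATC > shared name) and ties are broken by the
lexicographically smallest native-id pair, compared symmetrically so that
`map(a, b)` and `map(b, a)` select identical links. Losers stay unlinked and
enter the knowledge base as single-source drugs — a deterministic, auditable
convention; we make no claim that it reconstructs how any production system
resolved such collisions. Fused drugs get the stable id `"KB:" + smallest
native id`, with a source-tag suffix in the (rare) case of collisions between
id namespaces.

## Medication analysis

A `medication_profile` holds prescribed drugs, diagnoses, observed side
effects and defective CYP enzymes. The composite
`molecular_medication_analysis()` report combines:

* **pairwise interactions** — exactly the assertions whose canonical pair
  lies within the profile;
* **CYP dosage flags** — for ordered drug pairs (P, V) and enzyme M:
  P inducer of M and V substrate of M ⇒ `raise_dose` for V (induction speeds
  the victim's clearance, risking therapeutic failure); P inhibitor ⇒
  `lower_dose`; a defective CYP in the profile flags each of its substrate
  drugs as `risk`. The flag names perpetrator, enzyme and victim and is an
  advisory annotation, not a dose computation — the adjusted drug is always
  the substrate (victim), the pharmacologically standard reading of
  perpetrator/victim interactions;
* **cumulative side effects** — canonical terms asserted for ≥ 2 profile
  drugs; a drug counts once per term regardless of how many sources assert
  it;
* **drug-induced disease screening** — a diagnosis is flagged when its
  normalized name, a synonym of the matching disease record, or its canonical
  form under the side-effect synonym table equals a side-effect term of ≥ 1
  profile drug; flagged by ≥ 2 drugs ⇒ *cumulative*. Matching is exact on
  normalized terms; no fuzzy or hierarchical terminology matching in this
  version, because near-miss matches in a safety context need a vetted
  distance or an ontology, not a heuristic.

Observed side effects in the profile only annotate which findings explain
them; they never create findings. Duplicate drugs are silently deduplicated;
unresolvable names are reported, not fatal.

## Overlap statistics

A *hit* is a distinct canonical assertion key per source — a canonical drug
pair or a (drug, canonical term) pair — not a raw row count; only then do the
identities `union = a_only + b_only + shared` and
`shared = a_total + b_total − union` hold. Two constructors cover the two
counting conventions in circulation (exclusive counts + intersection;
per-source totals + union); they produce field-identical summaries from the
same sets, which the test suite asserts over randomized inputs.
`kb_overlap()` builds the hit sets from assertion provenance and reports
inclusive counts.

Percentages are rounded half-up (so 14.1033 prints as 14.10 and 11.93 as 12),
at integer precision for distribution-style reports and two decimals for
per-drug reports; `rounding = "none"` disables rounding. `a_share`/`b_share`
are per-source totals over the union; the exclusive shares
(`a_only_share`, `b_only_share`) are carried separately because
distribution-style reports print those instead.

## Radial network export

Analysis results serialize to a radial, level-coded document: query inputs at
level 0, results on rings whose level and symbolic color encode support. For
provenance partitions: shared → ring 1 (green), first-source-only → ring 2
(red), second-source-only → ring 3 (yellow). For composite reports:
interacting input drugs red and no-risk drugs blue at level 0, CYP enzymes
ring 1 (violet), cumulative side effects ring 2 (yellow), induced-disease
candidates ring 3 (orange). One edge is emitted per finding (per contributing
drug for cumulative and induced-disease findings). Colors are symbolic names,
not pixel values, and no layout coordinates are computed — both are the
rendering layer's business. Serialization is canonical (sorted keys, nodes by
level then label), so identical documents are byte-identical and
parse→serialize is a fixed point.

## The synthetic source generator

`generate_sources()` emits the four source dialects plus synonym table,
ready-to-use config, and a ground-truth JSON. It emulates the features the
pipeline must survive:

* per-source drug coverage gaps (default 0.8/0.9/0.7/0.3 of a 150-drug
  universe for PHARM/MOLDB/SEDB/PATHDB);
* cross-source identifier gaps: a `mapping_noise` fraction (default 0.2) of
  PHARM∩MOLDB drugs carries no shared identifier and must be recovered via
  ATC codes; SEDB links to MOLDB by names only;
* synonym usage: a `synonym_rate` fraction (default 0.3) of SEDB side-effect
  mentions is written as a raw synonym from a bundled 50-term MedDRA-like
  vocabulary with fixed synonym pairs;
* planted inter-source overlap: the default overlap fractions, 0.12 for
  interactions over a 200-hit universe and 0.09 for side effects over 300,
  reproduce the concordance regime the package is designed to measure.
  Overlap is planted by exact counts (`floor(fraction × universe)`), not by
  per-item coin flips, so recovery checks are exact rather than
  within-sampling-error. The non-shared remainder is split evenly between the
  two exclusive pools (pharmaceutical side gets the odd hit);
* a seven-drug demo profile with planted findings: two pairwise interactions
  (one dual-provenance), one cumulative side effect, one CYP
  inducer/substrate pair, two observed effects and a diagnosis matching a
  planted side-effect term. Expectations are recorded as "must include",
  since unplanted random hits may legitimately add contributors.

Side-effect hits are planted on drugs covered by PHARM, SEDB *and* MOLDB:
the pharmaceutical and MedDRA-style sources are linked through the molecular
source, so only such drugs can fuse across all three — mirroring integration
topologies in which the molecular source is the hub.

All randomness derives from one seed and deterministic ordering uses radix
(locale-independent) sorting, so identical parameters give byte-identical
files. What the generator does **not** emulate: realistic pharmacology,
real database size distributions, many-to-many identifier collisions, and
free-text noise in effect descriptions. Green tests therefore demonstrate
pipeline correctness (no hit loss, exact provenance, exact mapping recovery
under clean identifiers), not robustness to the full messiness of production
databases.

## Numerical and engineering choices

* Rounding is half-away-from-zero via an explicit helper; base R's
  round-half-even would print 11.93% as 12 but 14.105 as 14.10.
* Ingest is strict on schema (missing required column ⇒ error naming it) and
  lenient on content (malformed rows skipped and logged with line numbers;
  all-empty rows surface as rejections rather than vanishing).
* Knowledge-base artifacts persist as a directory of normalized TSVs plus a
  JSON manifest — human-diffable, no database dependency; per-source effect
  texts are JSON-encoded within their cell.
* Merging is order-independent: permuting the input record sets yields an
  identical knowledge base, asserted in the tests.
* Problem sizes in tests and the acceptance script (150-drug universe,
  200/300-hit universes, 100 random profiles against brute-force oracles on a
  50-drug fixture) were chosen as the smallest sizes at which every planted
  structure (coverage gaps, identifier noise, synonym usage, demo findings)
  is simultaneously present with comfortable margin.

## Known limitations

* Severity labels pass through uninterpreted; there is no severity scoring,
  dose computation, or pharmacokinetic modeling.
* Disease↔side-effect matching is exact on normalized canonical terms; a
  diagnosis phrased outside the synonym table will not be flagged.
* Drugs are modeled as active agents; medicinal products (multi-agent
  preparations) are out of scope.
* The 1:1 mapping tie-break is a convention; genuinely many-to-many
  cross-source relations (combination products, salt forms) are not
  represented.
* Absolute hit counts from licensed production databases cannot be
  reproduced here; the package covers their derived arithmetic exactly and
  their structure synthetically.
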