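---
title: "Curating a transcription-factor compendium: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a transcription-factor compendium: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific model behind `tfcompendium`, the
decisions taken where the method left room, and what the synthetic-data
tests do and do not demonstrate about real data.

## The curation model

A transcription factor (TF) is operationalised as a protein-coding gene
carrying at least one *reliable* DNA-binding domain (DBD) — an InterPro
entry curated as conferring sequence-specific DNA binding — whose domain
architecture is consistent with a reference TF of known function. The
pipeline therefore separates three concerns:

* **what counts as a DBD** (the registry): reference-census entries plus
  entries discovered by intersecting external TF databases against the
  census, minus entries found on known non-TFs (the blacklist) and entries
  without a curated sequence-specific function;
* **which genes are candidates** (screening): possession of one or more
  registry DBDs, regardless of anything else;
* **how much to trust each candidate** (the cascade): orthology to the
  reference census, domain-arrangement agreement, similarity-hit rescue,
  and curated literature evidence, resolved in a fixed order.

The cascade order encodes the epistemic priority of the evidence: biotype
(a pseudogene cannot be a functional TF) before orthologue identity
(a known non-TF orthologue is disqualifying) before arrangement comparison
(architecture decides between confirmation and divergence) before
similarity fallback, with curated literature evidence overriding everything
because it is the only step backed by direct experiment. Every candidate
receives exactly one class in `{a, b, c, y}` and one machine-readable
rationale, so classes partition the screened set and every exclusion is
auditable.

## Domain-arrangement similarity

An arrangement is the sequence of InterPro accessions along the protein,
ordered by hit start, with *consecutive* identical accessions collapsed to
one token. Consecutive collapse (rather than global de-duplication) keeps
architectures like zinc-finger–homeobox–zinc-finger intact, which global
de-duplication would destroy.

Similarity between arrangements is the length of their longest common
subsequence divided by the length of the longer arrangement — a global
alignment scoring match 1 and mismatch/indel 0, normalised to `[0, 1]`.
This score is symmetric, equals 1 exactly on identical arrangements, and
is 0 against an empty arrangement. Dedicated domain-alignment significance
algorithms exist; this package deliberately uses a transparent normalised
alignment instead, as its own declared choice. It preserves the operative
trichotomy —
identical (1.0), highly similar (≥ threshold), diverged (< threshold) —
and is fully configurable. The default threshold is 0.8, i.e. an
orthologue pair may disagree in at most one token out of five; with
typical arrangements of one to four tokens this accepts only identical or
near-identical architectures, matching the conservative intent of the
curation. Raising the threshold can only demote candidates
(monotonicity, covered by a property test).

Two degenerate cases are distinguished deliberately: an orthologue present
in the reference gene table but with *no domain hits* yields
`arrangement_unavailable` (class `c`; the comparison could not be made),
whereas an orthologue absent from the table altogether is an input error.
Conflating the two would silently convert missing reference data into
"divergence".

## Conservation grouping

The presence/absence matrix is binary: TF × species, true where at least
one orthology relation of any homology type exists. Clustering uses
Jaccard distance with average linkage — the natural choice for sparse
binary profiles, where double absences carry no signal; since no single
distance/linkage pair is canonical for this kind of matrix, both are
recorded in the output and configurable. Rows are sorted lexicographically before
clustering so the result is invariant to input order; identical rows
(distance 0, including all-false pairs where the Jaccard ratio is 0/0,
defined here as 0) end up adjacent. A constant matrix is returned in
input order with a warning rather than an error.

Groups are assigned per TF: the smallest clade in the nested chain
Mammalia ⊂ Vertebrata ⊂ Metazoa ⊂ Eukaryota containing at least a
fraction τ of the species where the TF is present, with `mammal_only`
reserved for fraction exactly 1. "Predominantly present" needs a
quantitative cutoff; τ = 0.9 is this package's default (with a 10-species
mammal panel it admits exactly one non-mammal stray) and is a recorded
parameter of every group report. The focal species is excluded
from all denominators, since presence in the TF's own genome is trivial;
by the same logic a TF with no orthologue anywhere outside the focal
species is grouped `mammal_only` — it is exclusive to the focal mammal.

## Cofactor identification

Candidate cofactors are non-TF interaction partners of compendium TFs,
restricted to interaction types MI:0195 (covalent binding), MI:0407
(direct interaction) and MI:0915 (physical association); TF–TF edges are
excluded by definition. The GO filter is sequential — nuclear component,
then a transcription-related biological process, then a
transcription-related molecular function — and emits per-stage survivor
counts, which are monotone non-increasing by construction.

Confidence classes use molecular-function evidence only: with N =
experimental evidence (EXP, IDA, IMP, IGI, IEP, IPI) for nuclear
localisation and T = experimental evidence for a listed molecular
function, the classes are high-confidence (N∧T), hypothetical I (T only),
II (N only), III (neither). A protein whose *biological-process*
annotation is experimental but whose molecular function is only
electronically inferred is therefore hypothetical III/II, not I — the
class is meant to certify transcription *function*, and the MF ontology is
where that function is asserted. This rule is recorded in the output
metadata. GO annotations are used as directly asserted, without
ancestor-closure over the ontology graph, because the method is defined on
flat term lists; closure would only add terms outside those lists.
Annotations from a reference species are re-keyed through an explicit
id-mapping table (`map_protein_ids()`); the mapping is an input, never
inferred.

## Expression and coexpression

Gene-level FPKM is the maximum over the gene's isoforms — a
presence-oriented summary (a gene is expressed where any isoform is);
`sum` is available where abundance matters. "Expressed" means FPKM
strictly above a threshold whose default is 0, the same rule the
coexpression definition uses; the threshold is a parameter for users who
prefer, e.g., 0.1 to suppress alignment noise. A TF–cofactor pair is
coexpressed when both genes are expressed in the same tissue, in at least
one tissue. Pairs with a member absent from the expression matrix are set
aside and reported, not silently dropped: the distinction between
"analysed pairs" and "all interaction pairs" is part of the output.

Printed summary percentages use `pct()`, which rounds half away from zero
— the convention of published results tables — rather than R's banker's
rounding; the difference is observable (e.g. 2.5% prints as 3).

## The synthetic-data generator

`generate_world()` emulates every input the pipeline consumes: BioMart-style
gene/domain tables, a reference census with literature updates, three
TF-database snapshots per species round, curated domain-function and
family-map tables, orthology for the reference species and for a
21-species conservation panel, similarity hits, PSI-MITAB interactions,
GAF annotations and an isoform FPKM matrix. Generation is *truth-first*:
the intended evidence class of every candidate, confidence class of every
cofactor, conservation group of every TF and tissue set of every gene are
sampled first, and the tables are synthesised to be consistent with them.
Because the analysis pipeline is deterministic, a correct implementation
recovers every planted label exactly; recovery below 100% is a bug, not
noise. All randomness flows from one seed and the generator restores the
caller's RNG state.

Two presets fix the study conditions. `tiny` (200 genes, 40 screened, 24
compendium TFs, 15 cofactors, 14 tissues) is the unit-test scale.
`paper_scale` reproduces the magnitudes of the full bovine curation: 24,616
genes screened down to 1,525 candidates and 865 compendium TFs (516 + 4
class `a`, 340 + 5 class `b`), conservation groups of 59 / 55 / 202 / 467 /
82 with 15 TFs present in all species, a registry of 76 domain + 57 family
entries with the human round contributing one zinc-finger entry on 26
shared genes and the mouse round five entries, 86 + 8 census
reclassifications, 781 cofactors in classes 248 / 52 / 214 / 267, and
expression profiles with 680 TFs expressed (156 ubiquitous) and 248
ubiquitous cofactors among 781. These counts are the generator's fixed
defaults, not tuned quantities; the acceptance script measures them from
the pipeline's output after running on the raw generated tables. The
reference census is sized at 1,651 entries so that every
arrangement-sensitive candidate can be planted on a *distinct* reference
orthologue — reusing a target across candidates with different
architectures would make the planted arrangements inconsistent.

What passing these tests shows: the set algebra, the cascade logic, the
bookkeeping and every filter behave exactly as specified, at realistic
scale. What it does not show: robustness to the noise of real annotation
pipelines — mis-assembled genes producing spurious domain divergence,
incomplete orthology calls, GO annotation bias, FPKM estimation error, or
a single-animal expression snapshot standing in for a population. The
generator plants clean signals by design; real-data caveats (notably that
apparent arrangement divergence may be an assembly artifact, and that
expression is a one-animal, one-timepoint snapshot without biological
replication) are inherent to the method, not removed by testing.

## Other recorded decisions

* Census updates move classes only toward `a` by default (`force = TRUE`
  permits arbitrary moves); re-applying an update list is idempotent
  because no-op updates are always legal.
* When a domain occurs on both a TF and a census-`x` gene in the
  snapshots, the blacklist wins: the entry is excluded from the registry.
  The alternative (TF-occurrence wins) would admit promiscuous domains the
  published screen removed by hand.
* One-to-many orthology: the best-similarity orthologue decides the class;
  many2many relations are ignored throughout the cascade.
* A no-orthologue candidate similar to a known non-TF is recorded as class
  `c` with rationale `similar_to_non_tf`, keeping `{a, b, c, y}` a true
  partition of the screened set while preserving the exclusion reason.
* The per-gene identifier namespace is whatever the input tables use;
  interactor ids in MITAB files are stripped of their database prefix, and
  cross-namespace joins go through explicit mapping tables.
* The exported functions are the package's interface; the pipeline is a
  library, not a shell tool, and `run_pipeline()` plus the writers cover
  orchestration end to end.

## Problem sizes and runtime

The default test suite runs the tiny preset for unit tests and one
paper-scale world for the end-to-end checks (about half a minute); the
acceptance script generates and analyses one paper-scale world per run.
Clustering a 865 × 21 binary matrix and the 1,500-candidate cascade are
well within interactive time; nothing in the package requires more than a
single CPU core.
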