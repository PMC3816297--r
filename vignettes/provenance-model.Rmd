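---
title: "The provflow provenance model: restrictions, inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The provflow provenance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provflow)
```

## The model

`provflow` represents each execution of a bioinformatics workflow as a
directed, typed provenance graph — an *account* — in the PROV-DM family of
models. Four node kinds carry the metadata a genome project needs to
reconstruct an execution:

* **agent** — a person, institution or service acting in the experiment
  (name, institution, position, function);
* **activity** — one program run (program, version, command line,
  environment, and the only temporal node attributes: start and end time);
* **entity** — a basic data object such as one sequence or one alignment;
* **collection** — a set of entities treated as one node. Because genome
  data comes as files of millions of sequences, collections are the working
  currency; they are modeled as entities whose `size` exceeds 1, and the
  creation API rejects `size <= 1`.

Five relation kinds connect them, with fixed directions and endpoint
signatures (`used`: activity to entity/collection; `wasGeneratedBy`:
entity/collection to activity, at most one per element; `wasAssociatedWith`:
agent to activity, many-to-many; `wasDerivedFrom`: element to element,
origin distinct from destination; `memberOf`: entity to collection).
`wasAssociatedWith` here runs from the agent to the activity — the
convention this model family's bioinformatics adaptation uses, not the
direction the W3C core recommendation draws — and we keep it, since edge
direction is a pure rendering convention as long as it is applied
consistently.

Two container levels sit above the nodes: the account (which is itself an
identified, annotatable element with an execution time window) and the
*project*, which joins re-executions of the same workflow. Two granularity
levels sit below: the graph metadata (bytes) and the payload files the
entities point to via `location` (potentially terabytes). Payloads are
linked, never copied: the functional checker resolves `location` against a
caller-supplied `payload_base`, because XML documents travel between
machines while payload trees tend to stay put.

## Automatic derivation maintenance

The `wasDerivedFrom` relation is the one users are not allowed to write by
hand here. Its semantics are exactly derivable: if activity `A` generated
`Y` and used `X`, then `Y` was derived from `X`. `derive_was_derived_from()`
makes the set of `auto_derived` edges equal that closure after every edge
insertion or removal: new pairs gain an edge (derivation type `other` until
the user reclassifies it as `filtering`, `ordering` or `mixing` via
`set_derivation_type()`), stale edges vanish, manual `wasDerivedFrom` edges
— allowed for lineage the workflow did not capture as used/generated pairs
— are preserved and never duplicated. Self-pairs (`A` both used and
generated the same element cannot happen, since generation is unique, but
`Y = X` pairs are excluded defensively) are skipped. The maintenance is
idempotent, and the test suite holds it against an independent brute-force
enumeration of all (generated, used) pairs on hundreds of randomly edited
accounts.

Auto edges are rendered dashed in DOT output so machine-maintained lineage
is visually distinct; direct removal of an auto edge is refused with a
pointer at the used/wasGeneratedBy pair that sustains it.

## The restriction catalogue

Validation is split into three orthogonal axes, each with fixed rule codes
(see `?rule_catalogue`) so reports are stable and diffable. Checkers return
violation tibbles, sorted by rule code then element id; they re-verify
stored state from zero, because a deserialized or hand-edited XML file can
carry breaches the creation-time API would have refused.

**Structural** (`S1`–`S6`): identifier uniqueness including the account's
own id, endpoint existence, endpoint kind signatures, relation uniqueness by
(kind, origin, destination), single generation, and non-self derivation.

**Temporal** (`T1`–`T8`): the only nodes with intrinsic times are
activities; every other temporal fact is anchored to them. An element's
*start time* is defined operationally as its generator's end time. Then:
activities start strictly before they end (`T1`, strict because a
zero-length program run records nothing); generation completes before any
use begins (`T2`) and, equivalently from the other edge, an activity starts
strictly after the start time of everything it uses (`T3`); a derived
element is generated strictly after its original's start time (`T4`);
account windows are consistent (`T5`, non-strict) and contain their
activities (`T6`); project windows are consistent (`T7`, non-strict) and
contain their accounts (`T8`). The strict-vs-non-strict split follows the
rule wording exactly: activity rules say "less than", window rules "less
than or equal".

Three consequences of anchoring element start times to generators deserve
note:

* *Vacuous satisfaction.* `T2`–`T4` are only evaluable once some element is
  both generated by one activity and used by another. Raw workflow inputs
  (e.g. the original UNIPROT family files) have no generator, hence no
  start time, and satisfy the rules vacuously. An account without such a
  minimum set of elements is automatically temporally sound on those rules.
* *`T2`/`T3` pairing.* The two rules are one predicate — generator end
  versus user start — read from either edge of the same (generator,
  element, user) triple. A breach therefore always reports under both
  codes. The violation-injection generator documents this: asking it for
  `T2` or `T3` produces an account whose temporal report is exactly that
  pair.
* *Temporal validity implies acyclic derivation, on generator-complete
  subgraphs.* Along any `wasDerivedFrom` edge between two generated
  elements, `T4` forces generation times to increase strictly, so a cycle
  of generated elements cannot be temporally clean. A hand-added derivation
  cycle between two never-generated raw inputs, by contrast, is vacuously
  satisfied — the acyclicity property is tested on the subgraphs where the
  model actually defines time, which includes everything automatic
  maintenance can produce.

**Functional** (`F1`): every set `location` must resolve to an existing
file. A missing payload is deliberately a violation and not an error: the
experiment is not wrong, it just cannot be re-executed as recorded, which
is precisely what a biologist deciding whether to keep intermediate files
wants surfaced. Accounts with no located nodes are vacuously functionally
valid.

Validity inference is conjunction: an account is valid on an axis iff that
axis reports nothing; a project is valid on an axis iff its own checks pass
and *every* account is valid on that axis — one bad execution taints the
project, and the empty project is vacuously all-valid.

## Persistence choices

No schema was mandated for this model family, so the package defines one
document per account (`inst/extdata/account.xsd`): account metadata as root
attributes, nodes grouped by kind (collections serialize as entities with a
`size` attribute, mirroring how they are modeled), relations with their
role/derivation-type/auto-derived attributes, annotations in a trailing
block. UTF-8, ISO-8601 timestamps. Timestamps are normalized to
`YYYY-MM-DDTHH:MM:SS` (date-only values anchor at midnight) and compared
lexicographically, which on that form equals chronological comparison;
values are timezone-naive by design — a single lab's execution log gains
nothing from zone arithmetic and loses reproducibility across machines.

Save-time behavior: every save increments the version by exactly one and
restamps `version_date` — a literal reading of "version changes whenever
the file is saved", chosen over change-detection because the version then
doubles as a save counter, which is what a registry wants. Structurally
invalid graphs are refused persistence outright; temporally or functionally
invalid ones persist fine (they are real, analyzable states of an
experiment). The registry is a JSON sidecar with one entry per account
file, replaced by file location on re-save.

Round-trip is lossless field-for-field; save→load→save produces
byte-identical XML apart from the two version stamps. Node order inside the
document groups by kind, so the node *table* order is not part of the
contract — identity is by id.

## Views and rendering

Group labels are free multi-valued node attributes set at creation.
Filtering keeps nodes belonging to at least one selected group and edges
with both endpoints kept (so every view is a well-formed subgraph);
selection is monotone in the group set; `"all"` is the identity and the
only view showing group-less nodes — group filtering is opt-in visibility.
Unknown group names warn and select nothing rather than erroring, because a
typo'd view is a user-interface event, not a data defect.

DOT output is deterministic (sorted ids) and contract-tested as text;
images are delegated to the external GraphViz `dot` binary and only
smoke-tested, since renderer bitmaps are not stable across versions. Node
glyphs follow the provenance-community convention — agents house-shaped,
activities rectangles, entities ellipses, collections double-bordered
ellipses; associations dotted, automatic derivations dashed; roles as edge
labels and annotations as gray boxes, each behind its own toggle.

## The case-study fixture

`build_case_study()` reconstructs the package's running example — a
*B. cereus* genome project comparing alpha-amylase families 13 and 57
against ORFs predicted on the assembled contigs — purely through the
creation-checked API: 2 agents, 11 collections, 8 activities, and 40 edges
of which the 10 `wasDerivedFrom` all arise from automatic maintenance
(filter steps contribute one derivation each, mix steps two, alignment and
graphic steps one each: 2·1 + 2·2 + 2·1 + 2·1 = 10).

Choices where the narrative underdetermines the graph:

* The validating researcher keeps the literal id `C002_Taina` even though
  the agent prefix convention would suggest `AG002` — the source material's
  own naming, prefix inconsistency and all; her association role is the
  string `"Validation"`.
* Family-57 ids (`C004`, `C007`, `C009`, `A002`, `A004`, ...) mirror the
  Family-13 chain, which is described as undergoing "the same processing
  steps".
* Timestamps are fabricated: activities occupy consecutive one-hour slots
  from 08:00 on a fixed date, in workflow order, inside an 08:00–16:00
  account window and a 2012 project window. This makes temporal validity
  deterministic and the times human-readable.
* Group tagging: each family group covers its chain's collections and
  activities; `Filter`, `Mix`, `Multiple Alignment` and `Graphic` cover the
  corresponding steps with their inputs and outputs; both agents carry the
  family and `Multiple Alignment` groups so association edges survive
  filtering; the shared ORF collection is tagged `Mix` only, keeping the
  single-family views to their own chains.
* Payloads are 2-record synthetic FASTA stubs written to a caller-chosen
  directory — enough to exercise second-level linkage and functional
  validation offline; the real amylase sequence sets are deliberately not
  reproduced.

## The account generator

`generate_account()` emulates workflow-shaped executions for property
testing: `n_chains` linear chains of activities over collections, each
activity consuming its predecessor's output plus `fan_in - 1` shared raw
collections, agents round-robined over chains, strictly increasing
half-hour activity slots. Defaults (2 chains × 3 steps, 2 agents, fan-in 2)
give a graph about the shape of one family chain of the case study. The
generator is a pure function of its seed.

What it emulates well: the DAG shape, shared-input fan-in, and temporal
layering of real pipeline runs. What it does not: realistic metadata text,
payload files (generated collections carry no `location`, so functional
checks are vacuous unless a violation is injected), `memberOf` containment,
and multi-account projects. Passing property tests therefore demonstrate
the graph machinery, not fidelity to any particular genome project's
content.

With `violation = <rule code>` the generator first builds the valid account
and then corrupts it by direct table edits — the same path a corrupt or
hand-edited XML document takes around the creation-time checks. Injections
are engineered to breach exactly the targeted rule (the `T2`/`T3` pairing
aside): e.g. the second-generation injection (`S5`) attaches to a terminal
output that nothing uses, so no temporal rule fires alongside; the `T4`
injection adds a manual derivation from an early output to a late one,
which violates derivation ordering without touching any used edge. `T7`/`T8`
are project-level and live in `generate_project()`.

## Problem sizes and limitations

The shipped test suite checks the derivation closure against a brute-force
oracle on 200 generated accounts (up to 3 chains × 4 steps) under random
edit sequences, temporal-acyclicity on 40 accounts, and catalogue coverage
at two seeds per rule — sizes chosen so the whole suite stays in the
low minutes on one core while every code path is crossed; the properties
themselves are size-free.

Known limitations, intentional in scope: provenance is entered or scripted,
never captured automatically from a running workflow; derivation closure is
computed within one account (cross-account lineage is out of model); no
repair or cycle-breaking of invalid graphs — validation reports, the user
decides; no DBMS backend, no concurrent writers, no payload content
hashing; and no PROV-N/RDF serializations, only the package's XML dialect.
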