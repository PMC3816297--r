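# provflow

Provenance graphs for bioinformatics workflow executions.

Genome and transcriptome projects run the same computational workflow many
times — different program versions, parameters, input sets — and most of
what made one execution different from another is lost unless it is recorded
systematically. `provflow` records it as a typed provenance graph in the
style of the W3C PROV-DM model: one **account** per workflow execution,
holding **agents** (people or services), **activities** (program runs with
start/end times), **entities** and **collections** (data files; a collection
is an entity of size > 1, e.g. a FASTA file of many sequences), joined by
directed relations:

| relation | direction | meaning |
|---|---|---|
| `used` | activity → entity/collection | the activity consumed it |
| `wasGeneratedBy` | entity/collection → activity | the activity produced it (at most one per element) |
| `wasAssociatedWith` | agent → activity | the agent acted in the activity |
| `wasDerivedFrom` | derived → original | transformation lineage, typed `filtering`/`ordering`/`mixing`/`other` |
| `memberOf` | entity → collection | containment |

`wasDerivedFrom` edges are **never entered by hand**: whenever an activity
*A* both generated *Y* and used *X*, the edge *Y → X* is created by
automatic maintenance, and it disappears when its generating pair does.

A **project** joins the executions of one genome project. Validity is
inferred on three orthogonal axes:

* **structural** — unique identifiers, existing and kind-correct relation
  endpoints, no duplicate relations, single generation, no self-derivation;
* **temporal** — each activity starts strictly before it ends; an element
  may only be used after the activity that generated it has finished;
  derivations run forward in time; activities fit the account window and
  accounts fit the project window;
* **functional** — every payload file an entity or collection points to
  (the model's second granularity level) still exists. A functionally
  invalid experiment is not wrong — it just can no longer be re-executed
  as recorded.

Accounts persist as versioned XML documents (version bumped and date
restamped on every save, a per-project registry tracks the files; the
dialect's XSD ships in `inst/extdata/account.xsd`), and group-filtered views
render to deterministic GraphViz DOT.

## Worked example

The package ships a builder for its running example: a *Bacillus cereus*
genome project in which alpha-amylase families 13 and 57 are each filtered,
joined with the predicted ORFs, multiply aligned, and plotted.

```r
library(provflow)

payloads <- tempfile("payloads")
prj <- build_case_study(payload_dir = payloads)
acc <- get_account(prj, "Multiple Alignment")
acc
#> <prov_account> WE001 ("Multiple Alignment"), version 1
#>   window: 2012-03-01T08:00:00 .. 2012-03-01T16:00:00
#>   nodes: 21 (agent 2, activity 8, entity 0, collection 11)
#>   edges: 40 (used 10, wasGeneratedBy 8, wasAssociatedWith 12, wasDerivedFrom 10, memberOf 0)
#>   annotations: 5
```

2 agents, 11 collections and 8 activities linked by 40 edges; the 10
`wasDerivedFrom` edges all came from automatic maintenance. Validate, break
the second granularity level, and validate again:

```r
glance(infer_account_validity(acc, payload_base = payloads))
#> # A tibble: 1 × 6
#>   scope   id    structural_valid temporal_valid functional_valid n_violations
#> 1 account WE001 TRUE             TRUE           TRUE                        0

file.remove(file.path(payloads, "family57.fasta"))
infer_account_validity(acc, payload_base = payloads)
#> <prov_validity> account 'WE001'
#>   structural: valid | temporal: valid | functional: INVALID
#>   1 violation(s):
#>   [F1] 'C002_Family57' points to missing payload 'family57.fasta' (resolved '...')
```

Only the functional axis flips. Group attributes give personalized views —
here the Family-57 chain (its filter, mix, alignment and graphic steps plus
the two participating agents):

```r
filter_by_groups(acc, "Family 57")
#> <prov_account> WE001 ("Multiple Alignment"), version 1
#>   nodes: 11 (agent 2, activity 4, entity 0, collection 5)
#>   edges: 18 (used 4, wasGeneratedBy 4, wasAssociatedWith 6, wasDerivedFrom 4, memberOf 0)

cat(to_dot(acc, view_options(groups = "Family 57", show_roles = TRUE)))
autoplot(acc, groups = "Family 57")   # quick ggplot2 layout
```

Tibbles everywhere: `nodes(acc)`, `edges(acc)`, `tidy(validity)` compose
with dplyr directly.

## Command line

`exec/prov` is a thin launcher over `cli_main()`:

```sh
prov init bcereus --name "B. cereus genome" --start 2012-01-01 --end 2013-01-01
prov new-account run1.xml --name "Multiple Alignment" --registry bcereus/registry.json
prov add run1.xml collection --name Family13 --size 40 --location family13.fasta --groups "Family 13,Filter"
prov link run1.xml used A001 C001 --role Input
prov validate run1.xml --payload-base data/        # exit 0 iff all axes valid
prov render run1.xml --groups "Family 57" --roles  # DOT always, image if dot is installed
prov fixture case-study --dir cs/                  # the worked example, on disk
```

Exit codes: 0 success, 1 validation failure, 2 usage/I-O error. Every
mutating subcommand round-trips through the XML file and bumps its version.

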