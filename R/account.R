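#' Create a workflow-execution account
#'
#' An account is one provenance graph: it captures a single execution of a
#' bioinformatics workflow. Nodes (agents, activities, entities, collections)
#' and typed relation edges are held as tibbles, so the graph can be explored
#' with ordinary dplyr verbs via [nodes()] and [edges()].
#'
#' @param id Account identifier (unique within its project). Generated when
#'   `NULL`.
#' @param name Execution name, e.g. `"Multiple Alignment"`.
#' @param description,location,notes Free-text execution metadata.
#' @param execution_date Date the workflow was run.
#' @param start_time,end_time Execution time window (ISO-8601; `end_time` may
#'   be `NULL` for an in-progress execution). When present,
#'   `start_time <= end_time` is required.
#' @param version Positive integer document version; bumped on every save.
#' @param version_date Timestamp of the last save.
#' @return A `prov_account` object.
#' @examples
#' acc <- prov_account(name = "Multiple Alignment",
#'                     start_time = "2012-03-01T08:00",
#'                     end_time = "2012-03-01T16:00")
#' nodes(acc)
#' @seealso [add_node()], [add_relation()], [infer_account_validity()]
#' @export
prov_account <- function(name, id = NULL, description = "", location = "",
                         execution_date = NULL, start_time = NULL,
                         end_time = NULL, notes = "", version = 1L,
                         version_date = NULL) {
  stopifnot(is.character(name), nzchar(name))
  start_time <- normalize_timestamp(start_time)
  end_time <- normalize_timestamp(end_time)
  if (ts_gt(start_time, end_time)) {
    abort("account start time must be less than or equal to its end time",
          class = "provflow_temporal_error")
  }
  if (version < 1) abort("account version must be >= 1")
  structure(
    list(
      id = id %||% paste0("WE_", gsub("[^A-Za-z0-9]+", "_", name)),
      name = name,
      description = description,
      location = location,
      execution_date = normalize_timestamp(execution_date),
      version_date = normalize_timestamp(version_date),
      version = as.integer(version),
      notes = notes,
      start_time = start_time,
      end_time = end_time,
      nodes = empty_nodes(),
      edges = empty_edges(),
      annotations = empty_annotations()
    ),
    class = "prov_account"
  )
}

empty_nodes <- function() {
  tibble(
    id = character(), kind = character(), name = character(),
    description = character(), location = character(), size = integer(),
    institution = character(), position = character(),
    "function" = character(), program = character(),
    program_version = character(), command_line = character(),
    environment = character(), start_time = character(),
    end_time = character(), notes = character(), groups = list()
  )
}

empty_edges <- function() {
  tibble(
    id = character(), kind = character(), source = character(),
    target = character(), role = character(), derivation_type = character(),
    auto_derived = logical()
  )
}

empty_annotations <- function() {
  tibble(element = character(), key = character(), text = character())
}

#' @export
print.prov_account <- function(x, ...) {
  kc <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  ec <- table(factor(x$edges$kind, levels = RELATION_KINDS))
  cat(sprintf("<prov_account> %s (\"%s\"), version %d\n", x$id, x$name, x$version))
  if (!is.na(x$start_time)) {
    cat(sprintf("  window: %s .. %s\n", x$start_time, x$end_time %||% ""))
  }
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(kc), kc), collapse = ", ")))
  cat(sprintf("  edges: %d (%s)\n", nrow(x$edges),
              paste(sprintf("%s %d", names(ec), ec), collapse = ", ")))
  if (nrow(x$annotations)) cat(sprintf("  annotations: %d\n", nrow(x$annotations)))
  invisible(x)
}

#' Access the node and edge tables of an account
#'
#' @param account A `prov_account`.
#' @return A tibble: one row per node (`nodes()`) or per relation edge
#'   (`edges()`). The `groups` column of the node table is a list column of
#'   character vectors.
#' @examples
#' acc <- prov_account(name = "demo")
#' acc <- add_node(acc, "agent", name = "Ana")
#' nodes(acc)
#' @export
nodes <- function(account) {
  stopifnot(inherits(account, "prov_account"))
  account$nodes
}

#' @rdname nodes
#' @export
edges <- function(account) {
  stopifnot(inherits(account, "prov_account"))
  account$edges
}

#' Identifier of the element added by the most recent operation
#'
#' [add_node()] and [add_relation()] return the updated account; the id they
#' assigned (user-supplied or generated) is retrievable here.
#'
#' @param account A `prov_account`.
#' @return Character scalar id, or `NA` if nothing was added yet.
#' @export
last_id <- function(account) {
  attr(account, "last_id") %||% NA_character_
}

all_ids <- function(account) {
  c(account$id, account$nodes$id, account$edges$id)
}

next_id <- function(account, prefix) {
  existing <- grep(paste0("^", prefix, "\\d+$"), all_ids(account), value = TRUE)
  n <- if (length(existing)) {
    max(as.integer(sub(paste0("^", prefix), "", existing))) + 1L
  } else 1L
  sprintf("%s%03d", prefix, n)
}

ID_PREFIX <- c(agent = "AG", activity = "A", entity = "C", collection = "C")

#' Add a node to an account
#'
#' Inserts an agent, activity, entity or collection, enforcing the
#' creation-time structural rules: the id must be unique within the account
#' (including against the account's own id) and a collection's size must
#' exceed 1 — a collection is an entity whose size is greater than 1.
#'
#' @param account A `prov_account`.
#' @param kind One of `"agent"`, `"activity"`, `"entity"`, `"collection"`.
#' @param name Node name (required, nonempty).
#' @param id Identifier; generated from the kind's conventional prefix
#'   (`AG` agents, `A` activities, `C` entities/collections) when `NULL`.
#' @param groups Character vector of group labels for filtered views; may be
#'   empty, and a node may belong to several groups.
#' @param size Integer > 1; required for collections, ignored otherwise.
#' @param location Payload file path (entities/collections); links the graph
#'   to its second granularity level. Checked by [check_functional()].
#' @param description,notes,institution,position,fun,program,program_version,command_line,environment
#'   Kind-specific metadata fields (`fun` fills the "function" field of
#'   agents and activities).
#' @param start_time,end_time Activity execution times (ISO-8601).
#' @return The updated account; the new node's id via [last_id()].
#' @examples
#' acc <- prov_account(name = "demo")
#' acc <- add_node(acc, "collection", name = "Family13", size = 40,
#'                 location = "family13.fasta", groups = c("Family 13", "Filter"))
#' last_id(acc)
#' @export
add_node <- function(account, kind, name, id = NULL, groups = character(),
                     size = NULL, location = NULL, description = "",
                     notes = "", institution = "", position = "", fun = "",
                     program = "", program_version = "", command_line = "",
                     environment = "", start_time = NULL, end_time = NULL) {
  stopifnot(inherits(account, "prov_account"))
  kind <- match.arg(kind, NODE_KINDS)
  if (!is.character(name) || !nzchar(name)) {
    abort("node name must be nonempty", class = "provflow_structural_error")
  }
  id <- id %||% next_id(account, ID_PREFIX[[kind]])
  if (id %in% all_ids(account)) {
    abort(sprintf("identifier '%s' already used in account '%s': each element must have a single identifier",
                  id, account$id),
          class = "provflow_structural_error")
  }
  if (kind == "collection") {
    if (is.null(size) || is.na(size) || size <= 1) {
      abort("a collection is an entity with size greater than 1; supply size > 1",
            class = "provflow_structural_error")
    }
  }
  row <- empty_nodes()[0, ]
  row[1, "id"] <- id
  row[1, "kind"] <- kind
  row[1, "name"] <- name
  row[1, "description"] <- description
  row[1, "location"] <- if (is.null(location)) NA_character_ else location
  row[1, "size"] <- if (kind == "collection") as.integer(size) else NA_integer_
  row[1, "institution"] <- institution
  row[1, "position"] <- position
  row[1, "function"] <- fun
  row[1, "program"] <- program
  row[1, "program_version"] <- program_version
  row[1, "command_line"] <- command_line
  row[1, "environment"] <- environment
  row[1, "start_time"] <- normalize_timestamp(start_time)
  row[1, "end_time"] <- normalize_timestamp(end_time)
  row[1, "notes"] <- notes
  row$groups <- list(as.character(groups))
  account$nodes <- bind_rows(account$nodes, row)
  attr(account, "last_id") <- id
  account
}

node_kind <- function(account, id) {
  k <- account$nodes$kind[account$nodes$id == id]
  if (length(k)) k[[1]] else NA_character_
}

#' Add a typed relation edge to an account
#'
#' Creation-time structural rules are enforced: both endpoints must exist and
#' have the kinds the relation expects (`used`: activity to entity/collection;
#' `wasGeneratedBy`: entity/collection to activity; `wasAssociatedWith`:
#' agent to activity; `wasDerivedFrom`: entity/collection to
#' entity/collection; `memberOf`: entity to collection); no two relations may
#' share kind, origin and destination; each entity or collection may carry at
#' most one `wasGeneratedBy`; a `wasDerivedFrom` may not link an element to
#' itself. After insertion, automatic `wasDerivedFrom` maintenance is re-run
#' (see [derive_was_derived_from()]).
#'
#' @param account A `prov_account`.
#' @param kind Relation kind.
#' @param source,target Node identifiers (edge direction follows the model:
#'   e.g. a `used` edge goes from the activity to what it used).
#' @param role Optional free-text role identifying why the edge exists
#'   (e.g. `"Execution"`, `"Validation"`).
#' @param derivation_type For `wasDerivedFrom` only: `"filtering"`,
#'   `"ordering"`, `"mixing"` or `"other"`.
#' @param id Edge identifier; generated (`R###`) when `NULL`.
#' @return The updated account; the new edge's id via [last_id()].
#' @export
add_relation <- function(account, kind, source, target, role = NULL,
                         derivation_type = NULL, id = NULL) {
  stopifnot(inherits(account, "prov_account"))
  kind <- match.arg(kind, RELATION_KINDS)
  for (endp in c(source, target)) {
    if (!endp %in% account$nodes$id) {
      abort(sprintf("nonexistent node '%s': relations can only be created from existing nodes", endp),
            class = "provflow_structural_error")
    }
  }
  sig <- RELATION_SIGNATURES[[kind]]
  if (!node_kind(account, source) %in% sig$source ||
      !node_kind(account, target) %in% sig$target) {
    abort(sprintf("invalid endpoint kind for %s: expects %s -> %s, got %s -> %s",
                  kind, paste(sig$source, collapse = "|"),
                  paste(sig$target, collapse = "|"),
                  node_kind(account, source), node_kind(account, target)),
          class = "provflow_structural_error")
  }
  dup <- account$edges$kind == kind & account$edges$source == source &
    account$edges$target == target
  if (any(dup)) {
    abort(sprintf("identical relationship exists: %s(%s -> %s)", kind, source, target),
          class = "provflow_structural_error")
  }
  if (kind == "wasGeneratedBy" &&
      any(account$edges$kind == "wasGeneratedBy" & account$edges$source == source)) {
    abort(sprintf("entity already generated: only one wasGeneratedBy is allowed for '%s'", source),
          class = "provflow_structural_error")
  }
  if (kind == "wasDerivedFrom" && source == target) {
    abort("origin equals destination: wasDerivedFrom endpoints must differ",
          class = "provflow_structural_error")
  }
  if (!is.null(derivation_type)) {
    if (kind != "wasDerivedFrom") {
      abort("derivation_type is only meaningful for wasDerivedFrom edges")
    }
    derivation_type <- match.arg(derivation_type, DERIVATION_TYPES)
  }
  id <- id %||% next_id(account, "R")
  if (id %in% all_ids(account)) {
    abort(sprintf("identifier '%s' already used in account '%s'", id, account$id),
          class = "provflow_structural_error")
  }
  account$edges <- bind_rows(account$edges, tibble(
    id = id, kind = kind, source = source, target = target,
    role = role %||% NA_character_,
    derivation_type = derivation_type %||% NA_character_,
    auto_derived = FALSE
  ))
  account <- derive_was_derived_from(account)
  attr(account, "last_id") <- id
  account
}

#' Maintain automatic wasDerivedFrom edges
#'
#' Derivation edges are not entered by the user: whenever an activity both
#' generated an element Y (`wasGeneratedBy(Y -> A)`) and used an element X
#' (`used(A -> X)`), a derived-from link `Y -> X` exists. This function makes
#' the set of `auto_derived` wasDerivedFrom edges exactly equal to that
#' closure: missing edges are created (with derivation type `"other"` until
#' reclassified via [set_derivation_type()]), stale ones — whose generating
#' used/wasGeneratedBy pair has disappeared — are removed. Manually added
#' wasDerivedFrom edges are left untouched, and no auto edge duplicates a
#' manual one. The operation is idempotent and is invoked by
#' [add_relation()] and [remove_relation()]; call it directly after loading
#' or hand-editing a graph.
#'
#' @param account A `prov_account`.
#' @return The updated account.
#' @export
derive_was_derived_from <- function(account) {
  stopifnot(inherits(account, "prov_account"))
  ed <- account$edges
  gen <- ed[ed$kind == "wasGeneratedBy", c("source", "target")]
  names(gen) <- c("generated", "activity")
  use <- ed[ed$kind == "used", c("source", "target")]
  names(use) <- c("activity", "used")
  closure <- inner_join(gen, use, by = "activity",
                        relationship = "many-to-many")
  closure <- distinct(closure[closure$generated != closure$used,
                              c("generated", "used")])
  manual <- ed[ed$kind == "wasDerivedFrom" & !ed$auto_derived, ]
  # drop pairs already covered by a manual derivation edge
  closure <- anti_join(closure, tibble(generated = manual$source, used = manual$target),
                       by = c("generated", "used"))
  auto <- ed[ed$kind == "wasDerivedFrom" & ed$auto_derived, ]
  keep <- semi_join(auto, closure, by = c(source = "generated", target = "used"))
  missing <- anti_join(closure, tibble(generated = auto$source, used = auto$target),
                       by = c("generated", "used"))
  account$edges <- ed[!(ed$kind == "wasDerivedFrom" & ed$auto_derived), ]
  account$edges <- bind_rows(account$edges, keep)
  if (nrow(missing)) {
    for (i in seq_len(nrow(missing))) {
      account$edges <- bind_rows(account$edges, tibble(
        id = next_id(account, "R"), kind = "wasDerivedFrom",
        source = missing$generated[[i]], target = missing$used[[i]],
        role = NA_character_, derivation_type = "other", auto_derived = TRUE
      ))
    }
  }
  account
}

#' Remove a relation edge
#'
#' Automatic wasDerivedFrom edges cannot be removed directly — they exist
#' only while their generating used/wasGeneratedBy pair does, and vanish via
#' maintenance when that pair is removed.
#'
#' @param account A `prov_account`.
#' @param edge Edge identifier.
#' @return The updated account, with derivation maintenance re-run.
#' @export
remove_relation <- function(account, edge) {
  stopifnot(inherits(account, "prov_account"))
  i <- which(account$edges$id == edge)
  if (!length(i)) {
    abort(sprintf("unknown edge id '%s'", edge), class = "provflow_structural_error")
  }
  if (account$edges$auto_derived[[i]]) {
    abort("automatic wasDerivedFrom edges cannot be removed directly; remove the used/wasGeneratedBy pair that originated them",
          class = "provflow_structural_error")
  }
  account$edges <- account$edges[-i, ]
  derive_was_derived_from(account)
}

#' Reclassify the derivation type of a wasDerivedFrom edge
#'
#' Automatic derivation edges default to type `"other"`; the user may record
#' how the derivation happened (`filtering`, `ordering`, `mixing`, `other`)
#' without disturbing automatic maintenance.
#'
#' @param account A `prov_account`.
#' @param edge wasDerivedFrom edge identifier.
#' @param type One of `"filtering"`, `"ordering"`, `"mixing"`, `"other"`.
#' @return The updated account.
#' @export
set_derivation_type <- function(account, edge, type) {
  stopifnot(inherits(account, "prov_account"))
  type <- match.arg(type, DERIVATION_TYPES)
  i <- which(account$edges$id == edge)
  if (!length(i) || account$edges$kind[[i]] != "wasDerivedFrom") {
    abort(sprintf("'%s' is not a wasDerivedFrom edge of this account", edge))
  }
  account$edges$derivation_type[[i]] <- type
  account
}

#' Annotate an element of an account
#'
#' Annotations attach free-text information to any element — a node, an
#' edge, or the account itself. They are optional and repeatable.
#'
#' @param account A `prov_account`.
#' @param element Identifier of a node, an edge, or the account's own id.
#' @param key Short annotation key, e.g. `"origin"`.
#' @param text Annotation text, e.g. `"UNIPROT"`.
#' @return The updated account.
#' @export
annotate <- function(account, element, key, text) {
  stopifnot(inherits(account, "prov_account"))
  if (!element %in% all_ids(account)) {
    abort(sprintf("unknown element '%s': annotations attach to existing elements only", element),
          class = "provflow_structural_error")
  }
  account$annotations <- bind_rows(
    account$annotations,
    tibble(element = element, key = key, text = text)
  )
  account
}
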