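#' Restriction rule catalogue
#'
#' Restrictions on a provenance graph fall on three axes. Each rule has a
#' fixed code so violation reports are diffable:
#'
#' * `S1` every element (including the account itself) has a single,
#'   unique identifier;
#' * `S2` relation endpoints reference existing nodes;
#' * `S3` relation endpoints have the kinds the relation expects;
#' * `S4` no two relations share kind, origin and destination;
#' * `S5` at most one wasGeneratedBy per entity/collection;
#' * `S6` wasDerivedFrom origin and destination differ;
#' * `T1` an activity's start time is strictly less than its end time;
#' * `T2` an element may only be generated by an activity whose end time
#'   precedes every time at which the element begins to be used;
#' * `T3` an activity may only use an element whose start time (its
#'   generator's end time) precedes the activity's start time;
#' * `T4` an element may only be derived from an original whose start time
#'   precedes the derived element's generation time;
#' * `T5` an account's start time is at most its end time;
#' * `T6` an account contains only activities executed within its window;
#' * `T7` a project's start time is at most its end time;
#' * `T8` a project contains only accounts executed within its window;
#' * `F1` every payload location of an entity/collection resolves to an
#'   existing file.
#'
#' `T2`, `T3` and `T4` apply only when the participating elements exist
#' (an element with no generator has no defined start time); absent those,
#' they are vacuously satisfied.
#'
#' @return Character vector of all rule codes.
#' @export
rule_catalogue <- function() {
  c(paste0("S", 1:6), paste0("T", 1:8), "F1")
}

violation <- function(axis, rule, elements, message) {
  tibble(axis = axis, rule = rule, elements = list(as.character(elements)),
         message = message)
}

empty_violations <- function() {
  tibble(axis = character(), rule = character(), elements = list(),
         message = character())
}

# deterministic report order: rule code, then first involved element
sort_violations <- function(v) {
  if (!nrow(v)) return(v)
  first <- map_chr(v$elements, function(e) if (length(e)) e[[1]] else "")
  v[order(v$rule, first, v$message), ]
}

#' Check the structural restrictions of an account
#'
#' Re-verifies the stored graph against rules `S1`-`S6` (see
#' [rule_catalogue()]). Creation-time checks in [add_node()] and
#' [add_relation()] enforce the same rules, but a deserialized or
#' hand-edited graph may have bypassed them, so validation trusts nothing.
#' Violations are data, not errors.
#'
#' @param account A `prov_account`.
#' @return A tibble of violations (`axis`, `rule`, `elements`, `message`),
#'   empty when the account is structurally sound, ordered by rule code then
#'   element id.
#' @export
check_structural <- function(account) {
  stopifnot(inherits(account, "prov_account"))
  v <- empty_violations()
  nd <- account$nodes
  ed <- account$edges
  ids <- all_ids(account)
  for (dup in unique(ids[duplicated(ids)])) {
    v <- bind_rows(v, violation("structural", "S1", dup,
      sprintf("identifier '%s' is used by more than one element", dup)))
  }
  for (i in seq_len(nrow(ed))) {
    for (endp in c(ed$source[[i]], ed$target[[i]])) {
      if (!endp %in% nd$id) {
        v <- bind_rows(v, violation("structural", "S2", c(ed$id[[i]], endp),
          sprintf("relation '%s' references nonexistent node '%s'", ed$id[[i]], endp)))
      }
    }
  }
  for (i in seq_len(nrow(ed))) {
    sig <- RELATION_SIGNATURES[[ed$kind[[i]]]]
    sk <- node_kind(account, ed$source[[i]])
    tk <- node_kind(account, ed$target[[i]])
    if ((!is.na(sk) && !sk %in% sig$source) || (!is.na(tk) && !tk %in% sig$target)) {
      v <- bind_rows(v, violation("structural", "S3", ed$id[[i]],
        sprintf("relation '%s' (%s) has invalid endpoint kind %s -> %s",
                ed$id[[i]], ed$kind[[i]], sk, tk)))
    }
  }
  if (nrow(ed)) {
    trip <- paste(ed$kind, ed$source, ed$target)
    for (d in unique(trip[duplicated(trip)])) {
      dupids <- ed$id[trip == d]
      v <- bind_rows(v, violation("structural", "S4", dupids,
        sprintf("identical relationships %s: %s", paste(dupids, collapse = ", "), d)))
    }
    gensrc <- ed$source[ed$kind == "wasGeneratedBy"]
    for (s in unique(gensrc[duplicated(gensrc)])) {
      v <- bind_rows(v, violation("structural", "S5", s,
        sprintf("'%s' has more than one wasGeneratedBy relation", s)))
    }
    selfd <- ed$kind == "wasDerivedFrom" & ed$source == ed$target
    for (i in which(selfd)) {
      v <- bind_rows(v, violation("structural", "S6", ed$id[[i]],
        sprintf("wasDerivedFrom '%s' has identical origin and destination '%s'",
                ed$id[[i]], ed$source[[i]])))
    }
  }
  sort_violations(v)
}

# generation time of each entity/collection: its generator's end time.
# elements with no generator have undefined (NA) start time.
generation_times <- function(account) {
  nd <- account$nodes
  ed <- account$edges
  gen <- ed[ed$kind == "wasGeneratedBy", c("source", "target")]
  act <- nd[nd$kind == "activity", c("id", "end_time")]
  names(act) <- c("target", "gen_end")
  gen <- left_join(gen, act, by = "target")
  out <- gen$gen_end
  names(out) <- gen$source
  out
}

#' Check the temporal restrictions of an account
#'
#' Applies rules `T1`-`T6` (see [rule_catalogue()]): activity start strictly
#' before end; generation before every use; use after the used element's
#' start (anchored to its generator's end); derivation after the original's
#' start; account window consistency; and containment of every activity
#' within the account window. The relation rules are evaluated only for
#' elements that are both generated and used — a raw workflow input has no
#' defined start time and satisfies them vacuously.
#'
#' @param account A `prov_account`.
#' @return A tibble of violations, empty when temporally sound.
#' @export
check_temporal <- function(account) {
  stopifnot(inherits(account, "prov_account"))
  v <- empty_violations()
  nd <- account$nodes
  ed <- account$edges
  acts <- nd[nd$kind == "activity", ]
  for (i in seq_len(nrow(acts))) {
    if (ts_ge(acts$start_time[[i]], acts$end_time[[i]])) {
      v <- bind_rows(v, violation("temporal", "T1", acts$id[[i]],
        sprintf("activity '%s' starts (%s) at or after its end (%s): start must be less than end",
                acts$id[[i]], acts$start_time[[i]], acts$end_time[[i]])))
    }
  }
  gent <- generation_times(account)
  gen <- ed[ed$kind == "wasGeneratedBy", ]
  use <- ed[ed$kind == "used", ]
  act_start <- acts$start_time
  names(act_start) <- acts$id
  act_end <- acts$end_time
  names(act_end) <- acts$id
  # T2: generator's end must precede every use start of the element
  for (i in seq_len(nrow(gen))) {
    y <- gen$source[[i]]
    a_end <- unname(act_end[gen$target[[i]]])
    users <- use$source[use$target == y]
    for (b in users) {
      if (ts_ge(a_end, unname(act_start[b]))) {
        v <- bind_rows(v, violation("temporal", "T2", c(y, gen$target[[i]], b),
          sprintf("'%s' is generated by '%s' (ends %s) but begins to be used by '%s' at %s",
                  y, gen$target[[i]], a_end, b, unname(act_start[b]))))
      }
    }
  }
  # T3: an activity can only use an element whose start time (= generator
  # end) precedes the activity's start
  for (i in seq_len(nrow(use))) {
    a <- use$source[[i]]
    x <- use$target[[i]]
    x_start <- unname(gent[x])
    if (!is.null(x_start) && !is.na(x_start %||% NA) &&
        ts_le(unname(act_start[a]), x_start)) {
      v <- bind_rows(v, violation("temporal", "T3", c(a, x),
        sprintf("activity '%s' starts at %s, not after the start time %s of used element '%s'",
                a, unname(act_start[a]), x_start, x)))
    }
  }
  # T4: derived element must be generated after the original's start
  der <- ed[ed$kind == "wasDerivedFrom", ]
  for (i in seq_len(nrow(der))) {
    y <- der$source[[i]]
    x <- der$target[[i]]
    y_gen <- if (y %in% names(gent)) unname(gent[y]) else NA_character_
    x_start <- if (x %in% names(gent)) unname(gent[x]) else NA_character_
    if (ts_ge(x_start, y_gen)) {
      v <- bind_rows(v, violation("temporal", "T4", der$id[[i]],
        sprintf("'%s' derived from '%s' but the original's start time %s is not before the derived generation time %s",
                y, x, x_start, y_gen)))
    }
  }
  # T5/T6: account window and activity containment
  if (ts_gt(account$start_time, account$end_time)) {
    v <- bind_rows(v, violation("temporal", "T5", account$id,
      sprintf("account '%s' starts (%s) after its end (%s)",
              account$id, account$start_time, account$end_time)))
  }
  for (i in seq_len(nrow(acts))) {
    before <- ts_lt(acts$start_time[[i]], account$start_time)
    after <- ts_gt(acts$end_time[[i]], account$end_time)
    if (isTRUE(before) || isTRUE(after)) {
      v <- bind_rows(v, violation("temporal", "T6", acts$id[[i]],
        sprintf("activity '%s' [%s .. %s] is not contained in the account window [%s .. %s]",
                acts$id[[i]], acts$start_time[[i]], acts$end_time[[i]],
                account$start_time, account$end_time %||% "")))
    }
  }
  sort_violations(v)
}

#' Check the project-level temporal restrictions
#'
#' Rules `T7` and `T8`: the project's start must be at most its end
#' (non-strict), and every account's execution window must fall within the
#' project window. A project with no end date bounds accounts from the start
#' side only.
#'
#' @param project A `prov_project`.
#' @return A tibble of violations.
#' @export
check_project_temporal <- function(project) {
  stopifnot(inherits(project, "prov_project"))
  v <- empty_violations()
  if (ts_gt(project$start_date, project$end_date)) {
    v <- bind_rows(v, violation("temporal", "T7", project$id,
      sprintf("project '%s' starts (%s) after its end (%s)",
              project$id, project$start_date, project$end_date)))
  }
  for (a in project$accounts) {
    before <- ts_lt(a$start_time, project$start_date)
    after <- ts_gt(a$end_time, project$end_date)
    if (isTRUE(before) || isTRUE(after)) {
      v <- bind_rows(v, violation("temporal", "T8", a$id,
        sprintf("account '%s' [%s .. %s] is not contained in the project window [%s .. %s]",
                a$id, a$start_time %||% "", a$end_time %||% "",
                project$start_date %||% "", project$end_date %||% "")))
    }
  }
  sort_violations(v)
}

#' Check the functional restriction of an account
#'
#' Collections (and entities) may point to payload files — the second
#' granularity level of the model. Rule `F1` requires every set `location`
#' to resolve to an existing file under `payload_base` (absolute locations
#' are checked as-is). A missing payload does not mean the experiment is
#' wrong — only that it cannot be re-executed as recorded — so functional
#' violations are reported, never raised.
#'
#' @param account A `prov_account`.
#' @param payload_base Directory against which relative locations resolve.
#' @return A tibble of violations; nodes with no location are skipped.
#' @export
check_functional <- function(account, payload_base = ".") {
  stopifnot(inherits(account, "prov_account"))
  v <- empty_violations()
  nd <- account$nodes[account$nodes$kind %in% c("entity", "collection"), ]
  for (i in seq_len(nrow(nd))) {
    loc <- nd$location[[i]]
    if (is.na(loc) || !nzchar(loc)) next
    path <- if (grepl("^(/|[A-Za-z]:[/\\\\])", loc)) loc else file.path(payload_base, loc)
    if (!file.exists(path)) {
      v <- bind_rows(v, violation("functional", "F1", nd$id[[i]],
        sprintf("'%s' points to missing payload '%s' (resolved '%s')",
                nd$id[[i]], loc, path)))
    }
  }
  sort_violations(v)
}

new_validity <- function(scope, id, violations) {
  structure(
    list(
      scope = scope, id = id,
      structural_valid = !any(violations$axis == "structural"),
      temporal_valid = !any(violations$axis == "temporal"),
      functional_valid = !any(violations$axis == "functional"),
      violations = violations
    ),
    class = "prov_validity"
  )
}

#' Infer the three-axis validity of an account
#'
#' Runs [check_structural()], [check_temporal()] and [check_functional()];
#' the account is valid on an axis exactly when that axis reports no
#' violations. A functionally invalid account is not necessarily erroneous —
#' it points to at least one data set that is no longer available, so the
#' experiment cannot be re-executed as recorded.
#'
#' @param account A `prov_account`.
#' @param payload_base Passed to [check_functional()].
#' @return A `prov_validity` object; [tidy()] gives the violation tibble,
#'   [glance()] a one-row summary with the three booleans.
#' @examples
#' prj <- build_case_study(payload_dir = tempfile("payloads"))
#' val <- infer_account_validity(get_account(prj, "Multiple Alignment"),
#'                               payload_base = attr(prj, "payload_dir"))
#' glance(val)
#' @export
infer_account_validity <- function(account, payload_base = ".") {
  v <- bind_rows(
    check_structural(account),
    check_temporal(account),
    check_functional(account, payload_base)
  )
  new_validity("account", account$id, v)
}

#' Infer the three-axis validity of a project
#'
#' A project is valid on an axis exactly when the project-level checks pass
#' and every account it contains is valid on that axis — a single invalid
#' account invalidates the whole project on that axis, and an empty project
#' with a consistent window is vacuously valid.
#'
#' @param project A `prov_project`.
#' @param payload_base Passed to [check_functional()] for every account.
#' @return A `prov_validity`; its violation tibble gains a `where` column
#'   naming the account (or the project id for project-level rules).
#' @export
infer_project_validity <- function(project, payload_base = ".") {
  v <- check_project_temporal(project)
  if (nrow(v)) v$where <- project$id else v$where <- character()
  for (a in project$accounts) {
    av <- infer_account_validity(a, payload_base)$violations
    if (nrow(av)) av$where <- a$id else av$where <- character()
    v <- bind_rows(v, av)
  }
  new_validity("project", project$id, v)
}

#' @export
print.prov_validity <- function(x, ...) {
  yn <- function(b) if (b) "valid" else "INVALID"
  cat(sprintf("<prov_validity> %s '%s'\n", x$scope, x$id))
  cat(sprintf("  structural: %s | temporal: %s | functional: %s\n",
              yn(x$structural_valid), yn(x$temporal_valid), yn(x$functional_valid)))
  if (nrow(x$violations)) {
    cat(sprintf("  %d violation(s):\n", nrow(x$violations)))
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  [%s] %s\n", x$violations$rule[[i]], x$violations$message[[i]]))
    }
  }
  invisible(x)
}

#' @rdname infer_account_validity
#' @param x A `prov_validity`.
#' @param ... Unused.
#' @method tidy prov_validity
#' @export
tidy.prov_validity <- function(x, ...) {
  x$violations
}

#' @rdname infer_account_validity
#' @method glance prov_validity
#' @export
glance.prov_validity <- function(x, ...) {
  tibble(
    scope = x$scope, id = x$id,
    structural_valid = x$structural_valid,
    temporal_valid = x$temporal_valid,
    functional_valid = x$functional_valid,
    n_violations = nrow(x$violations)
  )
}
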