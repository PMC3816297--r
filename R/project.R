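#' Create a genome-project provenance container
#'
#' A project joins distinct (re-)executions of one genome-project workflow:
#' it carries the project metadata (funding and partner institutions,
#' coordinator, time window) and an ordered collection of accounts, one per
#' workflow execution.
#'
#' @param name Project name (required, nonempty).
#' @param id Identifier; derived from the name when `NULL`.
#' @param description Free-text description.
#' @param funding_institutions,partner_institutions Character vectors.
#' @param coordinator Project coordinator's name.
#' @param start_date Project start (ISO-8601 date or timestamp).
#' @param end_date Project end, or `NULL` for an ongoing project. When
#'   present, `start_date <= end_date` is required.
#' @return A `prov_project` with no accounts.
#' @examples
#' prj <- new_project("B. cereus genome", start_date = "2012-01-01",
#'                    end_date = "2013-01-01")
#' length(prj$accounts)
#' @export
new_project <- function(name, id = NULL, description = "",
                        funding_institutions = character(),
                        partner_institutions = character(),
                        coordinator = "", start_date = NULL,
                        end_date = NULL) {
  if (!is.character(name) || !nzchar(name)) abort("project name must be nonempty")
  start_date <- normalize_timestamp(start_date)
  end_date <- normalize_timestamp(end_date)
  if (ts_gt(start_date, end_date)) {
    abort("the start time of a project must be less than or equal to its end time",
          class = "provflow_temporal_error")
  }
  structure(
    list(
      id = id %||% paste0("PRJ_", gsub("[^A-Za-z0-9]+", "_", name)),
      name = name,
      description = description,
      funding_institutions = as.character(funding_institutions),
      partner_institutions = as.character(partner_institutions),
      coordinator = coordinator,
      start_date = start_date,
      end_date = end_date,
      accounts = list()
    ),
    class = "prov_project"
  )
}

#' @export
print.prov_project <- function(x, ...) {
  cat(sprintf("<prov_project> %s (\"%s\"), %d account(s)\n",
              x$id, x$name, length(x$accounts)))
  cat(sprintf("  window: %s .. %s\n", x$start_date %||% "",
              if (is.na(x$end_date %||% NA)) "(open)" else x$end_date))
  for (a in x$accounts) {
    cat(sprintf("  - %s (\"%s\"): %d nodes, %d edges\n",
                a$id, a$name, nrow(a$nodes), nrow(a$edges)))
  }
  invisible(x)
}

#' Add a workflow execution to a project
#'
#' Creates an account (see [prov_account()]) and appends it to the project.
#' Account identifiers must be unique within the project — each graph,
#' including the graph itself, has a single identifier.
#'
#' @param project A `prov_project`.
#' @param ... Passed to [prov_account()] (`name`, `id`, time window, ...).
#' @return The updated project; the new account is the last element of
#'   `project$accounts`.
#' @export
new_account <- function(project, ...) {
  stopifnot(inherits(project, "prov_project"))
  acc <- prov_account(...)
  if (acc$id %in% map_chr(project$accounts, "id")) {
    abort(sprintf("account identifier '%s' already used in project '%s'",
                  acc$id, project$id),
          class = "provflow_structural_error")
  }
  project$accounts <- c(project$accounts, list(acc))
  project
}

#' Retrieve an account from a project by id or name
#'
#' @param project A `prov_project`.
#' @param which Account id or name.
#' @return The matching `prov_account`.
#' @export
get_account <- function(project, which) {
  stopifnot(inherits(project, "prov_project"))
  for (a in project$accounts) {
    if (a$id == which || a$name == which) return(a)
  }
  abort(sprintf("no account '%s' in project '%s'", which, project$id))
}

#' Replace an account in a project (matched by id)
#'
#' @param project A `prov_project`.
#' @param account The updated `prov_account`.
#' @return The updated project.
#' @export
set_account <- function(project, account) {
  stopifnot(inherits(project, "prov_project"), inherits(account, "prov_account"))
  ids <- map_chr(project$accounts, "id")
  i <- match(account$id, ids)
  if (is.na(i)) abort(sprintf("no account '%s' in project '%s'", account$id, project$id))
  project$accounts[[i]] <- account
  project
}
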