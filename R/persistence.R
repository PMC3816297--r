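# XML dialect: one document per account. Node kinds are grouped under
# <agents>, <activities> and <entities> (collections are entities whose size
# attribute exceeds 1); groups are child <group> elements; relations carry
# kind/source/target/role/derivation_type/auto_derived attributes;
# annotations live in a trailing <annotations> block. An XSD describing the
# dialect ships at inst/extdata/account.xsd.

ACCOUNT_ATTRS <- c("id", "name", "location", "execution_date",
                   "version_date", "version", "start_time", "end_time")

xml_set_opt <- function(node, attr, value) {
  if (!is.null(value) && !is.na(value) && nzchar(as.character(value))) {
    xml2::xml_set_attr(node, attr, as.character(value))
  }
}

account_to_xml <- function(account) {
  doc <- xml2::xml_new_root("account")
  for (a in ACCOUNT_ATTRS) xml_set_opt(doc, a, account[[a]])
  xml2::xml_add_child(doc, "description", account$description %||% "")
  xml2::xml_add_child(doc, "notes", account$notes %||% "")
  nd <- account$nodes
  write_groups <- function(el, groups) {
    for (g in groups) xml2::xml_add_child(el, "group", g)
  }
  ag <- xml2::xml_add_child(doc, "agents")
  for (i in which(nd$kind == "agent")) {
    el <- xml2::xml_add_child(ag, "agent")
    for (a in c("id", "name", "institution", "position", "function", "notes")) {
      xml_set_opt(el, a, nd[[a]][[i]])
    }
    write_groups(el, nd$groups[[i]])
  }
  ac <- xml2::xml_add_child(doc, "activities")
  for (i in which(nd$kind == "activity")) {
    el <- xml2::xml_add_child(ac, "activity")
    for (a in c("id", "name", "program", "program_version", "command_line",
                "function", "start_time", "end_time", "environment", "notes")) {
      xml_set_opt(el, a, nd[[a]][[i]])
    }
    write_groups(el, nd$groups[[i]])
  }
  en <- xml2::xml_add_child(doc, "entities")
  for (i in which(nd$kind %in% c("entity", "collection"))) {
    el <- xml2::xml_add_child(en, "entity")
    for (a in c("id", "name", "size", "description", "location", "notes")) {
      xml_set_opt(el, a, nd[[a]][[i]])
    }
    write_groups(el, nd$groups[[i]])
  }
  re <- xml2::xml_add_child(doc, "relations")
  ed <- account$edges
  for (i in seq_len(nrow(ed))) {
    el <- xml2::xml_add_child(re, "relation")
    for (a in c("id", "kind", "source", "target", "role", "derivation_type")) {
      xml_set_opt(el, a, ed[[a]][[i]])
    }
    xml2::xml_set_attr(el, "auto_derived", if (ed$auto_derived[[i]]) "true" else "false")
  }
  an <- xml2::xml_add_child(doc, "annotations")
  for (i in seq_len(nrow(account$annotations))) {
    el <- xml2::xml_add_child(an, "annotation", account$annotations$text[[i]])
    xml2::xml_set_attr(el, "element", account$annotations$element[[i]])
    xml2::xml_set_attr(el, "key", account$annotations$key[[i]])
  }
  doc
}

attr_or_na <- function(node, a) {
  v <- xml2::xml_attr(node, a)
  if (is.na(v)) NA_character_ else v
}

#' Load an account from its XML document
#'
#' Reads the package's account dialect back into a `prov_account`.
#' Round-trip with [save_account()] is lossless for every field. Dangling
#' references or other rule breaches in the file are loaded as-is and left
#' to the validation checkers; unknown relation kinds are a schema error.
#'
#' @param path Path to an account XML file.
#' @return A `prov_account`.
#' @export
load_account <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such account file: '%s'", path))
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "account") {
    abort(sprintf("'%s' is not an account document (root <%s>)", path, xml2::xml_name(doc)),
          class = "provflow_schema_error")
  }
  acc <- prov_account(
    name = attr_or_na(doc, "name"),
    id = attr_or_na(doc, "id"),
    location = attr_or_na(doc, "location") %|NA|% "",
    execution_date = attr_or_na(doc, "execution_date"),
    start_time = attr_or_na(doc, "start_time"),
    end_time = attr_or_na(doc, "end_time"),
    version = as.integer(attr_or_na(doc, "version") %|NA|% "1"),
    version_date = attr_or_na(doc, "version_date")
  )
  acc$description <- xml2::xml_text(xml2::xml_find_first(doc, "./description")) %|NA|% ""
  acc$notes <- xml2::xml_text(xml2::xml_find_first(doc, "./notes")) %|NA|% ""

  read_groups <- function(el) {
    as.character(xml2::xml_text(xml2::xml_find_all(el, "./group")))
  }
  rows <- list()
  push <- function(kind, el) {
    row <- empty_nodes()[0, ]
    row[1, "id"] <- attr_or_na(el, "id")
    row[1, "kind"] <- kind
    for (a in c("name", "description", "location", "institution", "position",
                "function", "program", "program_version", "command_line",
                "environment", "start_time", "end_time", "notes")) {
      row[1, a] <- attr_or_na(el, a)
    }
    row[1, "size"] <- suppressWarnings(as.integer(attr_or_na(el, "size")))
    row$groups <- list(read_groups(el))
    row
  }
  for (el in xml2::xml_find_all(doc, "./agents/agent")) rows <- c(rows, list(push("agent", el)))
  for (el in xml2::xml_find_all(doc, "./activities/activity")) rows <- c(rows, list(push("activity", el)))
  for (el in xml2::xml_find_all(doc, "./entities/entity")) {
    sz <- suppressWarnings(as.integer(attr_or_na(el, "size")))
    kind <- if (!is.na(sz) && sz > 1) "collection" else "entity"
    rows <- c(rows, list(push(kind, el)))
  }
  if (length(rows)) acc$nodes <- bind_rows(rows)
  # metadata text fields default to "" rather than NA for round-trip stability
  for (a in c("description", "institution", "position", "function", "program",
              "program_version", "command_line", "environment", "notes")) {
    acc$nodes[[a]][is.na(acc$nodes[[a]])] <- ""
  }

  erows <- list()
  for (el in xml2::xml_find_all(doc, "./relations/relation")) {
    kind <- attr_or_na(el, "kind")
    if (!kind %in% RELATION_KINDS) {
      abort(sprintf("unknown relation kind '%s' in '%s'", kind, path),
            class = "provflow_schema_error")
    }
    erows <- c(erows, list(tibble(
      id = attr_or_na(el, "id"), kind = kind,
      source = attr_or_na(el, "source"), target = attr_or_na(el, "target"),
      role = attr_or_na(el, "role"),
      derivation_type = attr_or_na(el, "derivation_type"),
      auto_derived = identical(attr_or_na(el, "auto_derived"), "true")
    )))
  }
  if (length(erows)) acc$edges <- bind_rows(erows)

  arows <- list()
  for (el in xml2::xml_find_all(doc, "./annotations/annotation")) {
    arows <- c(arows, list(tibble(
      element = attr_or_na(el, "element"), key = attr_or_na(el, "key"),
      text = xml2::xml_text(el)
    )))
  }
  if (length(arows)) acc$annotations <- bind_rows(arows)
  acc
}

`%|NA|%` <- function(a, b) if (length(a) != 1 || is.na(a)) b else a

#' Save an account as a versioned XML document
#'
#' Structurally invalid graphs are never persisted: [check_structural()]
#' must come back clean, otherwise the save is rejected with the violation
#' list (temporal or functional violations do not block saving). On every
#' save the document version is incremented by one and the version date
#' restamped, and the per-project registry — the list of XML files holding
#' each workflow execution — is updated when `registry` is given.
#'
#' @param account A `prov_account`.
#' @param path Output XML path.
#' @param registry Optional path to a project registry JSON file (created if
#'   missing); see [read_registry()].
#' @return The updated account (version bumped, version date stamped),
#'   invisibly.
#' @export
save_account <- function(account, path, registry = NULL) {
  stopifnot(inherits(account, "prov_account"))
  sv <- check_structural(account)
  if (nrow(sv)) {
    abort(paste0("refusing to save a structurally invalid account:\n",
                 paste0("  [", sv$rule, "] ", sv$message, collapse = "\n")),
          class = "provflow_structural_error")
  }
  account$version <- account$version + 1L
  account$version_date <- normalize_timestamp(Sys.time())
  doc <- account_to_xml(account)
  xml2::write_xml(doc, path)
  if (!is.null(registry)) {
    update_registry(registry, account, path)
  }
  invisible(account)
}

#' Read or update a project registry
#'
#' The registry is the project-level list of the XML files representing each
#' workflow execution, stored as a JSON sidecar next to the project
#' document. One entry per account file, keyed by file location.
#'
#' @param registry Path to the registry JSON file.
#' @return `read_registry()`: a tibble with columns `account_id`,
#'   `account_name`, `file_location`, `version`, `version_date`.
#' @export
read_registry <- function(registry) {
  if (!file.exists(registry)) {
    return(tibble(account_id = character(), account_name = character(),
                  file_location = character(), version = integer(),
                  version_date = character()))
  }
  as_tibble(jsonlite::fromJSON(registry, simplifyDataFrame = TRUE))
}

update_registry <- function(registry, account, path) {
  reg <- read_registry(registry)
  loc <- normalizePath(path, winslash = "/", mustWork = FALSE)
  reg <- reg[reg$file_location != loc, ]
  reg <- bind_rows(reg, tibble(
    account_id = account$id, account_name = account$name,
    file_location = loc, version = account$version,
    version_date = account$version_date
  ))
  reg <- reg[order(reg$file_location), ]
  jsonlite::write_json(reg, registry, auto_unbox = FALSE, pretty = TRUE)
  invisible(reg)
}

PROJECT_ATTRS <- c("id", "name", "coordinator", "start_date", "end_date")

#' Save and load project metadata documents
#'
#' A project document stores the Table-style project metadata (name,
#' description, institutions, coordinator, time window); its accounts live
#' in their own XML files tracked by the registry sidecar.
#'
#' @param project A `prov_project`.
#' @param path XML file path.
#' @return `save_project()` the path, invisibly; `load_project()` a
#'   `prov_project` with no accounts attached (attach via [load_account()]
#'   over the registry entries and [new_account()]/[set_account()]).
#' @export
save_project <- function(project, path) {
  stopifnot(inherits(project, "prov_project"))
  doc <- xml2::xml_new_root("project")
  for (a in PROJECT_ATTRS) xml_set_opt(doc, a, project[[a]])
  xml2::xml_add_child(doc, "description", project$description %||% "")
  fi <- xml2::xml_add_child(doc, "funding_institutions")
  for (x in project$funding_institutions) xml2::xml_add_child(fi, "institution", x)
  pi <- xml2::xml_add_child(doc, "partner_institutions")
  for (x in project$partner_institutions) xml2::xml_add_child(pi, "institution", x)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname save_project
#' @export
load_project <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such project file: '%s'", path))
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "project") {
    abort(sprintf("'%s' is not a project document", path), class = "provflow_schema_error")
  }
  new_project(
    name = attr_or_na(doc, "name"),
    id = attr_or_na(doc, "id"),
    description = xml2::xml_text(xml2::xml_find_first(doc, "./description")) %|NA|% "",
    funding_institutions = xml2::xml_text(xml2::xml_find_all(doc, "./funding_institutions/institution")),
    partner_institutions = xml2::xml_text(xml2::xml_find_all(doc, "./partner_institutions/institution")),
    coordinator = attr_or_na(doc, "coordinator") %|NA|% "",
    start_date = attr_or_na(doc, "start_date"),
    end_date = attr_or_na(doc, "end_date")
  )
}

#' Render an account to an image via GraphViz
#'
#' Emits the DOT view of the account (see [to_dot()]) and runs the external
#' `dot` renderer. DOT emission itself never needs the renderer; only the
#' image step does.
#'
#' @param account A `prov_account`.
#' @param path Output image path; format from `format` or the extension
#'   (`gif`, `png` or `svg`).
#' @param options A [view_options()] list.
#' @param format Image format override.
#' @return `path`, invisibly.
#' @export
export_graph_image <- function(account, path, options = view_options(),
                               format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (!format %in% c("gif", "png", "svg")) {
    abort(sprintf("unsupported image format '%s' (use gif, png or svg)", format))
  }
  dot_bin <- Sys.which("dot")
  if (!nzchar(dot_bin)) {
    abort("GraphViz 'dot' renderer not found on PATH; install graphviz (e.g. 'apt install graphviz' or 'conda install graphviz') or emit DOT text with to_dot()",
          class = "provflow_renderer_missing")
  }
  dot_file <- tempfile(fileext = ".dot")
  writeLines(to_dot(account, options), dot_file)
  status <- system2(dot_bin, c(paste0("-T", format), dot_file, "-o", path))
  if (status != 0 || !file.exists(path)) {
    abort(sprintf("dot renderer failed with status %d", status))
  }
  invisible(path)
}
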