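# Case-study fixture: the Bacillus cereus alpha-amylase experiment. Two
# processing chains (alpha-amylase families 13 and 57) each run filter ->
# mix-with-ORFs -> multiple alignment -> graphic; the ORF collection is
# shared by both mix steps. Timestamps are fabricated (one-hour slots in
# workflow order) so temporal validity is deterministic and readable.

CASE_STUDY_EPOCH <- "2012-03-01"

cs_slot <- function(i) {
  c(start = sprintf("%sT%02d:00:00", CASE_STUDY_EPOCH, 7 + i),
    end = sprintf("%sT%02d:00:00", CASE_STUDY_EPOCH, 8 + i))
}

# tiny synthetic FASTA payloads for second-level linkage; the real
# alpha-amylase sequence sets are not reproduced
CASE_STUDY_PAYLOADS <- c(
  "family13.fasta", "family57.fasta", "orfs.fasta",
  "family13_filtered.fasta", "family57_filtered.fasta",
  "family13_orfs.fasta", "family57_orfs.fasta",
  "family13_alignments.aln", "family57_alignments.aln",
  "family13_graph.dat", "family57_graph.dat"
)

write_payload_stub <- function(path) {
  base <- sub("\\..*$", "", basename(path))
  writeLines(c(
    sprintf(">%s_seq1 synthetic placeholder", base),
    "ATGGCTAGCTAGGATCCGATTACA",
    sprintf(">%s_seq2 synthetic placeholder", base),
    "ATGTTTGGCCAATCGATCGATTGA"
  ), path)
}

#' Build the B. cereus alpha-amylase case-study provenance graph
#'
#' Constructs, through the package's own creation-time-checked operations,
#' the provenance graph of one execution of the alpha-amylase comparison
#' workflow: FASTA collections for amylase families 13 and 57 are filtered,
#' joined with the predicted-ORF collection, multiply aligned, and plotted —
#' four activities per family, executed by the student agent AG001_Joao
#' (role `"Execution"` on every association) and validated by the researcher
#' agent C002_Taina (role `"Validation"` on the four alignment/graphic
#' activities). All wasDerivedFrom edges arise from automatic maintenance,
#' never by hand. Group labels (`"Family 13"`, `"Family 57"`, `"Filter"`,
#' `"Mix"`, `"Multiple Alignment"`, `"Graphic"`) support filtered views.
#'
#' The resulting account has 2 agents, 11 collections and 8 activities
#' linked by 40 edges (10 used + 8 wasGeneratedBy + 12 wasAssociatedWith +
#' 10 automatic wasDerivedFrom).
#'
#' @param payload_dir Directory in which tiny synthetic FASTA/alignment
#'   placeholder payloads are written (created if needed), linking the graph
#'   to its second granularity level; `NULL` skips writing them (functional
#'   validation will then report every location as missing).
#' @return A `prov_project` holding the single `"Multiple Alignment"`
#'   account; the payload directory is attached as attribute
#'   `"payload_dir"`.
#' @examples
#' prj <- build_case_study(payload_dir = tempfile("payloads"))
#' acc <- get_account(prj, "Multiple Alignment")
#' table(nodes(acc)$kind)
#' table(edges(acc)$kind)
#' @export
build_case_study <- function(payload_dir = NULL) {
  prj <- new_project(
    name = "B. cereus genome",
    id = "PRJ_BCereus",
    description = "Identification of alpha-amylase genes in a Brazilian Bacillus cereus isolate and comparison with related Bacillus species",
    funding_institutions = "Synthetic funding agency",
    partner_institutions = c("UnB Department of Computer Science",
                             "UnB Department of Cellular Biology"),
    coordinator = "Project coordinator",
    start_date = "2012-01-01", end_date = "2013-01-01"
  )
  prj <- new_account(
    prj, name = "Multiple Alignment", id = "WE001",
    description = "Multiple alignment of alpha-amylase families 13 and 57 against predicted ORFs, with graphics",
    location = "bioinfo-lab-server",
    execution_date = CASE_STUDY_EPOCH,
    start_time = paste0(CASE_STUDY_EPOCH, "T08:00:00"),
    end_time = paste0(CASE_STUDY_EPOCH, "T16:00:00")
  )
  acc <- prj$accounts[[1]]

  both_fam <- c("Family 13", "Family 57")
  acc <- add_node(acc, "agent", id = "AG001_Joao", name = "Joao",
                  institution = "UnB Department of Computer Science",
                  position = "Student", fun = "Executed the workflow",
                  groups = c(both_fam, "Multiple Alignment"))
  acc <- add_node(acc, "agent", id = "C002_Taina", name = "Taina",
                  institution = "UnB Department of Cellular Biology",
                  position = "Researcher", fun = "Validated the analyses",
                  groups = c(both_fam, "Multiple Alignment"))

  coll <- function(acc, id, name, size, location, description, groups) {
    add_node(acc, "collection", id = id, name = name, size = size,
             location = location, description = description, groups = groups)
  }
  acc <- coll(acc, "C001_Family13", "Family13", 40L, "family13.fasta",
              "FASTA DNA sequences of alpha-amylase family 13 (UNIPROT)",
              c("Family 13", "Filter"))
  acc <- coll(acc, "C002_Family57", "Family57", 36L, "family57.fasta",
              "FASTA DNA sequences of alpha-amylase family 57 (UNIPROT)",
              c("Family 57", "Filter"))
  acc <- coll(acc, "C005_ORFS", "ORFS", 120L, "orfs.fasta",
              "FASTA putative proteins predicted on the contigs", "Mix")
  acc <- coll(acc, "C003_Family13_Filtered", "Family13_Filtered", 28L,
              "family13_filtered.fasta", "Filtered family 13 sequences",
              c("Family 13", "Filter"))
  acc <- coll(acc, "C004_Family57_Filtered", "Family57_Filtered", 24L,
              "family57_filtered.fasta", "Filtered family 57 sequences",
              c("Family 57", "Filter"))
  acc <- coll(acc, "C006_Family13_ORFS", "Family13_ORFS", 148L,
              "family13_orfs.fasta", "Family 13 sequences joined with the ORFs",
              c("Family 13", "Mix", "Multiple Alignment"))
  acc <- coll(acc, "C007_Family57_ORFS", "Family57_ORFS", 144L,
              "family57_orfs.fasta", "Family 57 sequences joined with the ORFs",
              c("Family 57", "Mix", "Multiple Alignment"))
  acc <- coll(acc, "C008_Family13_Alignments", "Family13_Alignments", 5L,
              "family13_alignments.aln", "Multiple alignments of family 13 + ORFs",
              c("Family 13", "Multiple Alignment", "Graphic"))
  acc <- coll(acc, "C009_Family57_Alignments", "Family57_Alignments", 5L,
              "family57_alignments.aln", "Multiple alignments of family 57 + ORFs",
              c("Family 57", "Multiple Alignment", "Graphic"))
  acc <- coll(acc, "C010_Family13_Graph", "Family13_Graph", 3L,
              "family13_graph.dat", "Graphics drawn for the family 13 alignments",
              c("Family 13", "Graphic"))
  acc <- coll(acc, "C011_Family57_Graph", "Family57_Graph", 3L,
              "family57_graph.dat", "Graphics drawn for the family 57 alignments",
              c("Family 57", "Graphic"))

  acts <- list(
    list("A001_Family13_Filter", "Family13_Filter", "seqfilter", "Filter family 13 sequences", 1L, c("Family 13", "Filter")),
    list("A002_Family57_Filter", "Family57_Filter", "seqfilter", "Filter family 57 sequences", 2L, c("Family 57", "Filter")),
    list("A003_Family13_Mix", "Family13_Mix", "seqmerge", "Join filtered family 13 with the ORFs", 3L, c("Family 13", "Mix")),
    list("A004_Family57_Mix", "Family57_Mix", "seqmerge", "Join filtered family 57 with the ORFs", 4L, c("Family 57", "Mix")),
    list("A005_Family13_Alignment", "Family13_Alignment", "clustalw", "Multiple alignment of family 13 + ORFs", 5L, c("Family 13", "Multiple Alignment")),
    list("A006_Family57_Alignment", "Family57_Alignment", "clustalw", "Multiple alignment of family 57 + ORFs", 6L, c("Family 57", "Multiple Alignment")),
    list("A007_Family13_Graph", "Family13_Graphic", "alnplot", "Draw graphics for the family 13 alignments", 7L, c("Family 13", "Graphic")),
    list("A008_Family57_Graph", "Family57_Graphic", "alnplot", "Draw graphics for the family 57 alignments", 8L, c("Family 57", "Graphic"))
  )
  for (a in acts) {
    slot <- cs_slot(a[[5]])
    acc <- add_node(acc, "activity", id = a[[1]], name = a[[2]],
                    program = a[[3]], program_version = "1.0",
                    command_line = paste(a[[3]], "--defaults"),
                    fun = a[[4]], environment = "Linux x86_64 lab server",
                    start_time = slot[["start"]], end_time = slot[["end"]],
                    groups = a[[6]])
  }

  used <- list(
    c("A001_Family13_Filter", "C001_Family13"),
    c("A002_Family57_Filter", "C002_Family57"),
    c("A003_Family13_Mix", "C003_Family13_Filtered"),
    c("A003_Family13_Mix", "C005_ORFS"),
    c("A004_Family57_Mix", "C004_Family57_Filtered"),
    c("A004_Family57_Mix", "C005_ORFS"),
    c("A005_Family13_Alignment", "C006_Family13_ORFS"),
    c("A006_Family57_Alignment", "C007_Family57_ORFS"),
    c("A007_Family13_Graph", "C008_Family13_Alignments"),
    c("A008_Family57_Graph", "C009_Family57_Alignments")
  )
  for (u in used) {
    acc <- add_relation(acc, "used", u[[1]], u[[2]], role = "Input")
  }
  generated <- list(
    c("C003_Family13_Filtered", "A001_Family13_Filter"),
    c("C004_Family57_Filtered", "A002_Family57_Filter"),
    c("C006_Family13_ORFS", "A003_Family13_Mix"),
    c("C007_Family57_ORFS", "A004_Family57_Mix"),
    c("C008_Family13_Alignments", "A005_Family13_Alignment"),
    c("C009_Family57_Alignments", "A006_Family57_Alignment"),
    c("C010_Family13_Graph", "A007_Family13_Graph"),
    c("C011_Family57_Graph", "A008_Family57_Graph")
  )
  for (g in generated) {
    acc <- add_relation(acc, "wasGeneratedBy", g[[1]], g[[2]], role = "Output")
  }
  for (a in acts) {
    acc <- add_relation(acc, "wasAssociatedWith", "AG001_Joao", a[[1]],
                        role = "Execution")
  }
  for (aid in c("A005_Family13_Alignment", "A006_Family57_Alignment",
                "A007_Family13_Graph", "A008_Family57_Graph")) {
    acc <- add_relation(acc, "wasAssociatedWith", "C002_Taina", aid,
                        role = "Validation")
  }
  # reclassify the automatic derivation edges by how each step transformed
  # its input: filter steps are filtering, mix steps mixing
  dtype_by_activity <- c(A001_Family13_Filter = "filtering",
                         A002_Family57_Filter = "filtering",
                         A003_Family13_Mix = "mixing",
                         A004_Family57_Mix = "mixing")
  gen_map <- acc$edges[acc$edges$kind == "wasGeneratedBy", c("source", "target")]
  for (i in which(acc$edges$kind == "wasDerivedFrom" & acc$edges$auto_derived)) {
    gact <- gen_map$target[gen_map$source == acc$edges$source[[i]]]
    if (length(gact) && gact %in% names(dtype_by_activity)) {
      acc <- set_derivation_type(acc, acc$edges$id[[i]], dtype_by_activity[[gact]])
    }
  }

  acc <- annotate(acc, "C001_Family13", "origin", "UNIPROT")
  acc <- annotate(acc, "C002_Family57", "origin", "UNIPROT")
  acc <- annotate(acc, "C005_ORFS", "origin", "ORFs predicted on the assembled contigs")
  acc <- annotate(acc, "A005_Family13_Alignment", "program", "clustalw multiple aligner")
  acc <- annotate(acc, "A006_Family57_Alignment", "program", "clustalw multiple aligner")

  if (!is.null(payload_dir)) {
    dir.create(payload_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in CASE_STUDY_PAYLOADS) write_payload_stub(file.path(payload_dir, f))
  }
  prj <- set_account(prj, acc)
  attr(prj, "payload_dir") <- payload_dir
  prj
}

#' Generator parameters for random workflow-shaped accounts
#'
#' @param n_chains Number of independent processing chains.
#' @param chain_length Activities per chain (each uses its predecessor's
#'   output and generates one collection).
#' @param n_agents Number of agents; each is associated with every activity
#'   of one or more chains.
#' @param fan_in Inputs per activity: beyond the chain predecessor, each
#'   activity additionally uses `fan_in - 1` shared raw collections.
#' @param seed Integer seed; the generated account is a pure function of the
#'   parameters.
#' @param violation Optional rule code from [rule_catalogue()]; when given,
#'   exactly one breach of that rule is injected into the otherwise valid
#'   account (codes `T7`/`T8` are project-level: use [generate_project()]).
#' @return A `prov_generator_params` list.
#' @export
generator_params <- function(n_chains = 2, chain_length = 3, n_agents = 2,
                             fan_in = 2, seed = 1, violation = NULL) {
  stopifnot(n_chains >= 1, chain_length >= 1, n_agents >= 1, fan_in >= 1)
  if (!is.null(violation) && !violation %in% rule_catalogue()) {
    abort(sprintf("unknown violation code '%s' (see rule_catalogue())", violation))
  }
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 n_agents = as.integer(n_agents), fan_in = as.integer(fan_in),
                 seed = as.integer(seed), violation = violation),
            class = "prov_generator_params")
}

#' Generate a random workflow-shaped account
#'
#' Produces a pseudo-random but structurally realistic workflow execution:
#' `n_chains` chains of filter/transform/analyze activities over
#' collections, shared raw inputs (`fan_in`), agents associated with the
#' chains, and strictly increasing fabricated timestamps — an account valid
#' on all three axes. When `params$violation` names a rule code, the valid
#' account is then corrupted with exactly one breach of that rule (bypassing
#' the creation-time checks, as a hand-edited or corrupt XML file would).
#' Fully reproducible from `params$seed`.
#'
#' Note that rules `T2` and `T3` are two readings of the same temporal
#' predicate on a (generator, element, user) triple, so injecting either
#' produces the pair of violations.
#'
#' @param params A [generator_params()] list.
#' @return A `prov_account`.
#' @export
generate_account <- function(params = generator_params()) {
  stopifnot(inherits(params, "prov_generator_params"))
  if (!is.null(params$violation) && params$violation %in% c("T7", "T8")) {
    abort(sprintf("'%s' is a project-level rule; use generate_project()", params$violation))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  n_act <- params$n_chains * params$chain_length
  acc <- prov_account(
    name = sprintf("Generated execution seed %d", params$seed),
    id = sprintf("GEN%05d", params$seed %% 100000L),
    execution_date = "2020-01-01",
    start_time = "2020-01-01T00:00:00",
    end_time = sprintf("2020-01-%02dT23:00:00", 1 + (n_act %/% 24) + 1)
  )
  verbs <- c("Filter", "Trim", "Assemble", "Map", "Annotate", "Align", "Plot")
  for (a in seq_len(params$n_agents)) {
    acc <- add_node(acc, "agent", name = sprintf("Agent %d", a),
                    institution = "Synthetic lab", fun = "Execution")
  }
  agent_ids <- acc$nodes$id[acc$nodes$kind == "agent"]
  shared <- character(params$fan_in - 1)
  for (s in seq_len(params$fan_in - 1)) {
    acc <- add_node(acc, "collection", name = sprintf("Shared raw %d", s),
                    size = sample(2:200, 1), groups = "raw")
    shared[[s]] <- last_id(acc)
  }
  slot <- 0L
  for (ch in seq_len(params$n_chains)) {
    grp <- sprintf("chain %d", ch)
    acc <- add_node(acc, "collection", name = sprintf("Raw input %d", ch),
                    size = sample(2:200, 1), groups = c(grp, "raw"))
    prev <- last_id(acc)
    for (st in seq_len(params$chain_length)) {
      t0 <- sprintf("2020-01-%02dT%02d:00:00", 1 + slot %/% 24, slot %% 24)
      t1 <- sprintf("2020-01-%02dT%02d:30:00", 1 + slot %/% 24, slot %% 24)
      slot <- slot + 1L
      acc <- add_node(acc, "activity",
                      name = sprintf("%s chain %d step %d", sample(verbs, 1), ch, st),
                      program = "synthetic", start_time = t0, end_time = t1,
                      groups = grp)
      act <- last_id(acc)
      acc <- add_relation(acc, "used", act, prev, role = "Input")
      for (s in shared) acc <- add_relation(acc, "used", act, s)
      acc <- add_node(acc, "collection", name = sprintf("Output chain %d step %d", ch, st),
                      size = sample(2:200, 1), groups = grp)
      out <- last_id(acc)
      acc <- add_relation(acc, "wasGeneratedBy", out, act, role = "Output")
      ag <- agent_ids[[1 + (ch - 1L) %% length(agent_ids)]]
      acc <- add_relation(acc, "wasAssociatedWith", ag, act, role = "Execution")
      prev <- out
    }
  }
  if (!is.null(params$violation)) acc <- inject_violation(acc, params$violation)
  acc
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# corrupt a valid account with exactly one breach of `code`, editing the
# stored tibbles directly (creation-time checks would refuse all of these)
inject_violation <- function(acc, code) {
  nd <- acc$nodes
  ed <- acc$edges
  acts <- nd$id[nd$kind == "activity"]
  colls <- nd$id[nd$kind == "collection"]
  gen_src <- ed$source[ed$kind == "wasGeneratedBy"]
  gen_end <- generation_times(acc)
  switch(code,
    S1 = {
      # second node reuses the first node's identifier
      i <- which(nd$kind == "collection")[1]
      row <- nd[i, ]
      row$id <- nd$id[[1]]
      row$name <- "duplicate id injection"
      acc$nodes <- bind_rows(nd, row)
    },
    S2 = {
      i <- which(ed$kind == "used")[1]
      acc$edges$target[[i]] <- "GHOST_NODE"
    },
    S3 = {
      # retarget a used edge at an agent: existing node, wrong kind
      i <- which(ed$kind == "used")[1]
      acc$edges$target[[i]] <- nd$id[nd$kind == "agent"][[1]]
    },
    S4 = {
      i <- which(ed$kind == "used")[1]
      row <- ed[i, ]
      row$id <- "R_DUP"
      acc$edges <- bind_rows(ed, row)
    },
    S5 = {
      # second generator on a terminal output: nothing uses it, so the
      # breach stays purely structural (no temporal side effects)
      y <- gen_src[[length(gen_src)]]
      orig <- ed$target[ed$kind == "wasGeneratedBy" & ed$source == y]
      other <- setdiff(acts, orig)[[1]]
      acc$edges <- bind_rows(ed, tibble(
        id = "R_GEN2", kind = "wasGeneratedBy", source = y, target = other,
        role = NA_character_, derivation_type = NA_character_, auto_derived = FALSE))
    },
    S6 = {
      y <- colls[[1]]
      acc$edges <- bind_rows(ed, tibble(
        id = "R_SELF", kind = "wasDerivedFrom", source = y, target = y,
        role = NA_character_, derivation_type = "other", auto_derived = FALSE))
    },
    T1 = {
      i <- which(nd$kind == "activity")[1]
      acc$nodes$end_time[[i]] <- acc$nodes$start_time[[i]]
    },
    T2 = ,
    T3 = {
      # make a user of a generated element start before the generator ends:
      # one predicate, reported under both codes (see rule_catalogue())
      used_gen <- ed[ed$kind == "used" & ed$target %in% names(gen_end), ]
      i <- which(ed$id == used_gen$id[[1]])
      user <- acc$edges$source[[i]]
      j <- which(nd$id == user)
      gend <- unname(gen_end[acc$edges$target[[i]]])
      acc$nodes$start_time[[j]] <- gend  # start == element start: not after
    },
    T4 = {
      # manual derivation from a later element: original's start time is not
      # before the derived element's generation time; no used edge involved
      first <- gen_src[[1]]
      last <- gen_src[[length(gen_src)]]
      acc$edges <- bind_rows(ed, tibble(
        id = "R_T4", kind = "wasDerivedFrom", source = first, target = last,
        role = NA_character_, derivation_type = "other", auto_derived = FALSE))
    },
    T5 = {
      acc$start_time <- "2020-02-01T00:00:00"
      acc$end_time <- "2020-01-01T00:00:00"
      # keep activities inside neither bound violated beyond T5: widen below
      acc$nodes$start_time[acc$nodes$kind == "activity"] <- NA_character_
      acc$nodes$end_time[acc$nodes$kind == "activity"] <- NA_character_
    },
    T6 = {
      # push the last activity's end beyond the account window; last in the
      # workflow, so no later user start is affected
      last_act <- acts[[length(acts)]]
      i <- which(nd$id == last_act)
      acc$nodes$end_time[[i]] <- "2020-03-01T00:00:00"
    },
    F1 = {
      i <- which(nd$kind == "collection")[1]
      acc$nodes$location[[i]] <- "deleted_payload.fasta"
    },
    abort(sprintf("no injection defined for rule '%s'", code))
  )
  acc
}

#' Generate a project, optionally breaching a project-level temporal rule
#'
#' Wraps [generate_account()] output in a project. Codes `T7` (project start
#' after end) and `T8` (account outside the project window) are injected at
#' the project level; any other code is delegated to the account generator.
#'
#' @param params A [generator_params()] list.
#' @return A `prov_project` with one account.
#' @export
generate_project <- function(params = generator_params()) {
  stopifnot(inherits(params, "prov_generator_params"))
  code <- params$violation
  acc_params <- params
  acc_params$violation <- if (!is.null(code) && code %in% c("T7", "T8")) NULL else code
  acc <- generate_account(acc_params)
  prj <- new_project(name = sprintf("Generated project seed %d", params$seed),
                     id = sprintf("GENPRJ%05d", params$seed %% 100000L),
                     start_date = "2019-12-01", end_date = "2020-12-31")
  if (identical(code, "T7")) {
    prj$start_date <- normalize_timestamp("2021-01-01")
    prj$end_date <- normalize_timestamp("2020-12-31")
    acc$start_time <- NA_character_
    acc$end_time <- NA_character_
  }
  if (identical(code, "T8")) {
    acc$start_time <- normalize_timestamp("2019-01-01T00:00:00")
    # keep activities inside the (shifted) account window: loosen their times
    acc$nodes$start_time[acc$nodes$kind == "activity"] <- NA_character_
    acc$nodes$end_time[acc$nodes$kind == "activity"] <- NA_character_
  }
  prj$accounts <- list(acc)
  prj
}
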