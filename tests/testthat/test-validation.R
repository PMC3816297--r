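test_that("a well-formed account re-validates clean on all axes", {
  pd <- withr::local_tempdir()
  acc <- case_study_account(payload_dir = pd)
  expect_identical(nrow(check_structural(acc)), 0L)
  expect_identical(nrow(check_temporal(acc)), 0L)
  expect_identical(nrow(check_functional(acc, pd)), 0L)
})

test_that("structural checks catch rule breaches in deserialized-style graphs", {
  acc <- tiny_account()
  # dangling endpoint, as a corrupt file would produce
  broken <- acc
  broken$edges$target[broken$edges$kind == "used"] <- "DELETED"
  v <- check_structural(broken)
  expect_identical(v$rule, "S2")
  expect_match(v$message, "nonexistent node")

  # used edge whose source is an agent
  broken <- add_node(acc, "agent", id = "AG", name = "a")
  i <- which(broken$edges$kind == "used")
  broken$edges$source[[i]] <- "AG"
  expect_identical(check_structural(broken)$rule, "S3")

  # duplicated relation injected post-hoc
  broken <- acc
  row <- broken$edges[broken$edges$kind == "used", ]
  row$id <- "R_DUP"
  broken$edges <- rbind(broken$edges, row)
  expect_identical(check_structural(broken)$rule, "S4")
})

test_that("activity start must be strictly less than its end", {
  acc <- tiny_account()
  i <- which(acc$nodes$id == "A")
  acc$nodes$end_time[[i]] <- acc$nodes$start_time[[i]]
  v <- check_temporal(acc)
  expect_identical(v$rule, "T1")
})

test_that("generation must finish before use begins (minimal two-activity graph)", {
  build <- function(gen_end, use_start) {
    acc <- prov_account(name = "min", id = "MIN",
                        start_time = "2020-01-01T00:00:00",
                        end_time = "2020-01-01T23:00:00")
    acc <- add_node(acc, "entity", id = "E", name = "E")
    acc <- add_node(acc, "activity", id = "GEN", name = "generator",
                    start_time = "2020-01-01T08:00:00", end_time = gen_end)
    acc <- add_node(acc, "activity", id = "USE", name = "user",
                    start_time = use_start, end_time = "2020-01-01T12:00:00")
    acc <- add_relation(acc, "wasGeneratedBy", "E", "GEN")
    add_relation(acc, "used", "USE", "E")
  }
  # generator ends 10:00 but the user starts 09:30: both readings flag it
  bad <- build("2020-01-01T10:00:00", "2020-01-01T09:30:00")
  expect_setequal(check_temporal(bad)$rule, c("T2", "T3"))
  # user starting strictly after generation is clean
  ok <- build("2020-01-01T10:00:00", "2020-01-01T10:30:00")
  expect_identical(nrow(check_temporal(ok)), 0L)
  # equality is still a breach: strictly-after is required
  eq <- build("2020-01-01T10:00:00", "2020-01-01T10:00:00")
  expect_setequal(check_temporal(eq)$rule, c("T2", "T3"))
})

test_that("relation rules are vacuous without a generated-and-used element", {
  acc <- prov_account(name = "no-min-set",
                      start_time = "2020-01-01T00:00:00",
                      end_time = "2020-01-01T23:00:00")
  acc <- add_node(acc, "collection", id = "RAW", name = "raw", size = 5)
  acc <- add_node(acc, "activity", id = "A", name = "a",
                  start_time = "2020-01-01T01:00:00",
                  end_time = "2020-01-01T02:00:00")
  acc <- add_relation(acc, "used", "A", "RAW")  # RAW has no generator
  expect_identical(nrow(check_temporal(acc)), 0L)
})

test_that("derivation must postdate the original's start time", {
  acc <- case_study_account()
  # manual derivation pointing from an early output to a late one
  acc <- add_relation(acc, "wasDerivedFrom", "C003_Family13_Filtered",
                      "C011_Family57_Graph")
  v <- check_temporal(acc)
  expect_identical(v$rule, "T4")
})

test_that("account window rules bound the activities", {
  acc <- tiny_account()
  acc$start_time <- "2020-01-02T00:00:00"   # after its end
  acc$end_time <- "2020-01-01T23:00:00"
  v <- check_temporal(acc)
  expect_true("T5" %in% v$rule)

  acc <- tiny_account()
  i <- which(acc$nodes$id == "A")
  acc$nodes$end_time[[i]] <- "2020-01-02T05:00:00"  # beyond account end
  expect_true("T6" %in% check_temporal(acc)$rule)

  # absent account end: only the start bound applies
  acc <- tiny_account()
  acc$end_time <- NA_character_
  expect_identical(nrow(check_temporal(acc)), 0L)
})

test_that("project temporal rules follow the non-strict window wording", {
  prj <- new_project("p", start_date = "2012-01-01", end_date = "2013-01-01")
  prj <- new_account(prj, name = "late", id = "W1",
                     start_time = "2014-01-01T00:00:00",
                     end_time = "2014-01-02T00:00:00")
  v <- check_project_temporal(prj)
  expect_identical(v$rule, "T8")

  # start == end with one account exactly at that instant: allowed
  prj <- new_project("instant", start_date = "2012-06-01", end_date = "2012-06-01")
  prj <- new_account(prj, name = "at", id = "W1",
                     start_time = "2012-06-01T00:00:00",
                     end_time = "2012-06-01T00:00:00")
  expect_identical(nrow(check_project_temporal(prj)), 0L)

  expect_identical(nrow(check_project_temporal(new_project("empty"))), 0L)
})

test_that("functional checks verify payload existence and only that", {
  pd <- withr::local_tempdir()
  acc <- case_study_account(payload_dir = pd)
  expect_identical(nrow(check_functional(acc, pd)), 0L)
  # deleting one payload flips exactly the functional axis
  file.remove(file.path(pd, "family13.fasta"))
  v <- check_functional(acc, pd)
  expect_identical(v$rule, "F1")
  expect_identical(v$elements[[1]], "C001_Family13")
  val <- infer_account_validity(acc, pd)
  expect_true(val$structural_valid)
  expect_true(val$temporal_valid)
  expect_false(val$functional_valid)
  # an account with no located nodes is vacuously functionally valid
  expect_identical(nrow(check_functional(tiny_account(), pd)), 0L)
})

test_that("account validity is the conjunction per axis of its checkers", {
  pd <- withr::local_tempdir()
  acc <- case_study_account(payload_dir = pd)
  val <- infer_account_validity(acc, pd)
  expect_true(all(glance(val)[, c("structural_valid", "temporal_valid",
                                  "functional_valid")] == TRUE))
  expect_identical(nrow(tidy(val)), 0L)

  # post-hoc duplicated relation: structural only
  acc$edges <- rbind(acc$edges, transform(acc$edges[1, ], id = "R_DUP"))
  val <- infer_account_validity(acc, pd)
  expect_false(val$structural_valid)
  expect_true(val$temporal_valid)
  expect_true(val$functional_valid)
})

test_that("one invalid account invalidates the project on that axis only", {
  pd <- withr::local_tempdir()
  prj <- build_case_study(payload_dir = pd)
  expect_true(all(glance(infer_project_validity(prj, pd))[
    , c("structural_valid", "temporal_valid", "functional_valid")] == TRUE))

  file.remove(file.path(pd, "orfs.fasta"))
  val <- infer_project_validity(prj, pd)
  expect_true(val$structural_valid)
  expect_true(val$temporal_valid)
  expect_false(val$functional_valid)
  expect_identical(tidy(val)$where, "WE001")

  # empty project with a consistent window: vacuously all-valid
  empty <- new_project("empty", start_date = "2012-01-01", end_date = "2013-01-01")
  expect_identical(nrow(tidy(infer_project_validity(empty))), 0L)
})

test_that("project validity equals explicit conjunction over accounts", {
  pd <- withr::local_tempdir()
  prj <- new_project("multi", start_date = "2019-01-01", end_date = "2021-01-01")
  for (seed in 1:3) {
    acc <- generate_account(generator_params(seed = seed,
      violation = if (seed == 2) "S4" else NULL))
    prj$accounts <- c(prj$accounts, list(acc))
  }
  val <- infer_project_validity(prj, pd)
  per_axis <- function(axis) {
    proj_ok <- nrow(check_project_temporal(prj)) == 0 || axis != "temporal_valid"
    accs_ok <- all(vapply(prj$accounts, function(a)
      glance(infer_account_validity(a, pd))[[axis]], logical(1)))
    proj_ok && accs_ok
  }
  expect_identical(val$structural_valid, per_axis("structural_valid"))
  expect_identical(val$temporal_valid, per_axis("temporal_valid"))
  expect_identical(val$functional_valid, per_axis("functional_valid"))
  expect_false(val$structural_valid)
})

test_that("checkers are pure and report in stable order", {
  acc <- generate_account(generator_params(seed = 5, violation = "S4"))
  acc$edges <- rbind(acc$edges, data.frame(
    id = "R_SELF", kind = "wasDerivedFrom", source = "C001", target = "C001",
    role = NA_character_, derivation_type = "other", auto_derived = FALSE))
  acc$nodes$id[nrow(acc$nodes)] <- acc$nodes$id[[1]]
  v1 <- check_structural(acc)
  v2 <- check_structural(acc)
  expect_identical(v1, v2)
  expect_identical(v1$rule, sort(v1$rule))
})
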