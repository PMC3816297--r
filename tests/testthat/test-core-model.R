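test_that("projects enforce their temporal window at creation", {
  prj <- new_project("B. cereus genome", start_date = "2012-01-01",
                     end_date = "2013-01-01")
  expect_s3_class(prj, "prov_project")
  expect_length(prj$accounts, 0)

  expect_error(new_project("bad", start_date = "2013-01-01",
                           end_date = "2012-01-01"),
               class = "provflow_temporal_error")
  expect_error(new_project("bad", start_date = "2013-01-01",
                           end_date = "2012-01-01"),
               regexp = "less than or equal")

  open_ended <- new_project("ongoing", start_date = "2012-01-01")
  expect_true(is.na(open_ended$end_date))
})

test_that("account identifiers are unique within a project and order is kept", {
  prj <- new_project("p", start_date = "2012-01-01")
  prj <- new_account(prj, name = "Multiple Alignment", id = "WE1")
  expect_length(prj$accounts, 1)
  expect_error(new_account(prj, name = "again", id = "WE1"),
               class = "provflow_structural_error")
  prj <- new_account(prj, name = "Re-run", id = "WE2")
  expect_identical(vapply(prj$accounts, `[[`, "", "id"), c("WE1", "WE2"))
})

test_that("node creation enforces id uniqueness and the collection size rule", {
  acc <- prov_account(name = "t")
  acc <- add_node(acc, "collection", id = "C001_Family13", name = "Family13",
                  size = 40, location = "family13.fasta",
                  groups = c("Family 13", "Filter"))
  expect_identical(last_id(acc), "C001_Family13")
  expect_identical(nodes(acc)$groups[[1]], c("Family 13", "Filter"))

  expect_error(add_node(acc, "collection", name = "singleton", size = 1),
               regexp = "size greater than 1")
  expect_error(add_node(acc, "entity", id = "C001_Family13", name = "dup"),
               class = "provflow_structural_error")
  expect_error(add_node(acc, "entity", id = acc$id, name = "clashes with graph id"),
               class = "provflow_structural_error")

  acc <- add_node(acc, "agent", name = "Joao")   # empty groups are fine
  expect_identical(nodes(acc)$groups[[2]], character(0))
  expect_match(last_id(acc), "^AG\\d{3}$")
})

test_that("relation creation enforces the structural rules", {
  acc <- tiny_account()
  # duplicate (kind, source, target)
  expect_error(add_relation(acc, "used", "A", "X"),
               regexp = "identical relationship")
  # second generation of Y
  acc2 <- add_node(acc, "activity", id = "A2", name = "other",
                   start_time = "2020-01-01T03:00:00",
                   end_time = "2020-01-01T04:00:00")
  expect_error(add_relation(acc2, "wasGeneratedBy", "Y", "A2"),
               regexp = "already generated")
  # self-derivation
  expect_error(add_relation(acc, "wasDerivedFrom", "X", "X"),
               regexp = "origin equals destination")
  # missing endpoint
  expect_error(add_relation(acc, "used", "A", "NOPE"),
               regexp = "nonexistent node")
  # endpoint kind signature: used must go activity -> entity/collection
  expect_error(add_relation(acc, "used", "X", "Y"),
               regexp = "invalid endpoint kind")
})

test_that("memberOf links entities to collections, and only that way", {
  acc <- prov_account(name = "m")
  acc <- add_node(acc, "collection", id = "C", name = "C", size = 3)
  acc <- add_node(acc, "entity", id = "E", name = "E")
  acc <- add_relation(acc, "memberOf", "E", "C")
  expect_identical(edges(acc)$kind, "memberOf")
  expect_error(add_relation(acc, "memberOf", "C", "E"),
               regexp = "invalid endpoint kind")
})

test_that("annotations attach to nodes, edges and the account itself", {
  acc <- tiny_account()
  eid <- edges(acc)$id[[1]]
  acc <- annotate(acc, "X", "origin", "UNIPROT")
  acc <- annotate(acc, eid, "note", "input link")
  acc <- annotate(acc, acc$id, "status", "validated")
  expect_identical(nrow(acc$annotations), 3L)
  # repeatable on the same element
  acc <- annotate(acc, "X", "origin", "release 2012_02")
  expect_identical(sum(acc$annotations$element == "X"), 2L)
  expect_error(annotate(acc, "GHOST", "k", "v"),
               class = "provflow_structural_error")
})

test_that("agents can share activities and activities can share agents", {
  acc <- tiny_account()
  acc <- add_node(acc, "agent", id = "AG1", name = "one")
  acc <- add_node(acc, "agent", id = "AG2", name = "two")
  acc <- add_relation(acc, "wasAssociatedWith", "AG1", "A")
  acc <- add_relation(acc, "wasAssociatedWith", "AG2", "A")
  acc <- add_node(acc, "activity", id = "B", name = "later",
                  start_time = "2020-01-01T03:00:00",
                  end_time = "2020-01-01T04:00:00")
  acc <- add_relation(acc, "wasAssociatedWith", "AG1", "B")
  expect_identical(sum(edges(acc)$kind == "wasAssociatedWith"), 3L)
})

test_that("timestamps normalize to canonical ISO-8601", {
  expect_identical(normalize_timestamp("2012-03-01"), "2012-03-01T00:00:00")
  expect_identical(normalize_timestamp("2012-03-01 08:00"), "2012-03-01T08:00:00")
  expect_identical(normalize_timestamp(as.Date("2012-03-01")), "2012-03-01T00:00:00")
  expect_true(is.na(normalize_timestamp(NULL)))
  expect_error(normalize_timestamp("yesterday"), class = "provflow_bad_timestamp")
})
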