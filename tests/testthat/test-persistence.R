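test_that("save/load round-trips every field of an account", {
  dir <- withr::local_tempdir()
  acc <- case_study_account()
  path <- file.path(dir, "ma.xml")
  saved <- save_account(acc, path)
  expect_true(file.exists(path))
  loaded <- load_account(path)
  # version stamping happens at save; everything else matches field-for-field
  expect_identical(loaded$version, acc$version + 1L)
  for (f in c("id", "name", "description", "location", "execution_date",
              "start_time", "end_time", "notes")) {
    expect_identical(loaded[[f]], acc[[f]])
  }
  reorder <- function(df) {
    df <- df[order(df$id), ]
    rownames(df) <- NULL
    df
  }
  expect_identical(reorder(as.data.frame(nodes(loaded))),
                   reorder(as.data.frame(nodes(acc))))
  expect_identical(reorder(as.data.frame(edges(loaded))),
                   reorder(as.data.frame(edges(acc))))
  expect_identical(as.data.frame(loaded$annotations),
                   as.data.frame(acc$annotations))
})

test_that("saving bumps the version by exactly one and restamps the date", {
  dir <- withr::local_tempdir()
  acc <- prov_account(name = "fresh")
  p1 <- file.path(dir, "a.xml")
  acc2 <- save_account(acc, p1)
  expect_identical(acc2$version, 2L)
  acc3 <- save_account(acc2, p1)
  expect_identical(acc3$version, 3L)
  expect_true(acc3$version_date >= acc2$version_date)
})

test_that("save-load-save is byte-identical modulo the version stamps", {
  dir <- withr::local_tempdir()
  acc <- case_study_account()
  p1 <- file.path(dir, "one.xml")
  p2 <- file.path(dir, "two.xml")
  save_account(acc, p1)
  save_account(load_account(p1), p2)
  strip <- function(path) {
    gsub('version="[0-9]+"|version_date="[^"]*"', "", readLines(path))
  }
  expect_identical(strip(p2), strip(p1))
})

test_that("structurally invalid accounts are refused persistence", {
  dir <- withr::local_tempdir()
  acc <- tiny_account()
  acc$edges$target[acc$edges$kind == "used"] <- "DANGLING"
  expect_error(save_account(acc, file.path(dir, "bad.xml")),
               class = "provflow_structural_error")
  expect_error(save_account(acc, file.path(dir, "bad.xml")),
               regexp = "S2")
  expect_false(file.exists(file.path(dir, "bad.xml")))
})

test_that("temporally or functionally invalid accounts still persist", {
  dir <- withr::local_tempdir()
  acc <- generate_account(generator_params(seed = 3, violation = "T1"))
  out <- save_account(acc, file.path(dir, "t1.xml"))
  expect_true(file.exists(file.path(dir, "t1.xml")))
  expect_identical(check_temporal(load_account(file.path(dir, "t1.xml")))$rule, "T1")
})

test_that("schema errors name the offending relation kind", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.xml")
  save_account(tiny_account(), path)
  txt <- readLines(path)
  writeLines(gsub('kind="used"', 'kind="wasQuotedFrom"', txt), path)
  expect_error(load_account(path), class = "provflow_schema_error")
  expect_error(load_account(path), regexp = "wasQuotedFrom")
  expect_error(load_account(file.path(dir, "nope.xml")), regexp = "no such")
})

test_that("the registry tracks one entry per account file", {
  dir <- withr::local_tempdir()
  reg <- file.path(dir, "registry.json")
  a1 <- prov_account(name = "exec one", id = "W1")
  a2 <- prov_account(name = "exec two", id = "W2")
  a1 <- save_account(a1, file.path(dir, "w1.xml"), registry = reg)
  save_account(a2, file.path(dir, "w2.xml"), registry = reg)
  save_account(a1, file.path(dir, "w1.xml"), registry = reg)  # re-save updates
  tab <- read_registry(reg)
  expect_identical(nrow(tab), 2L)
  expect_false(any(duplicated(tab$file_location)))
  expect_identical(tab$version[tab$account_id == "W1"], 3L)
  # every registry entry loads
  for (f in tab$file_location) expect_s3_class(load_account(f), "prov_account")
})

test_that("project metadata round-trips through its XML document", {
  dir <- withr::local_tempdir()
  prj <- new_project("B. cereus genome", description = "amylase search",
                     funding_institutions = c("agency A", "agency B"),
                     partner_institutions = "UnB",
                     coordinator = "coord",
                     start_date = "2012-01-01", end_date = "2013-01-01")
  path <- file.path(dir, "project.xml")
  save_project(prj, path)
  back <- load_project(path)
  for (f in c("id", "name", "description", "funding_institutions",
              "partner_institutions", "coordinator", "start_date", "end_date")) {
    expect_identical(back[[f]], prj[[f]])
  }
})

test_that("image export needs the renderer but DOT emission never does", {
  dir <- withr::local_tempdir()
  acc <- tiny_account()
  expect_gt(nchar(to_dot(acc)), 0)
  out <- file.path(dir, "g.png")
  if (nzchar(Sys.which("dot"))) {
    export_graph_image(acc, out)
    expect_true(file.exists(out))
  } else {
    expect_error(export_graph_image(acc, out),
                 class = "provflow_renderer_missing")
    expect_error(export_graph_image(acc, out), regexp = "graphviz|dot",
                 ignore.case = TRUE)
  }
  expect_error(export_graph_image(acc, file.path(dir, "g.bmp")),
               regexp = "unsupported image format")
})
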