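# Independent brute-force oracle for the derivation closure: enumerate every
# (wasGeneratedBy, used) pair per activity with plain loops, no joins, no
# package internals.
closure_oracle <- function(account) {
  ed <- edges(account)
  out <- character()
  for (i in seq_len(nrow(ed))) {
    if (ed$kind[[i]] != "wasGeneratedBy") next
    y <- ed$source[[i]]
    a <- ed$target[[i]]
    for (j in seq_len(nrow(ed))) {
      if (ed$kind[[j]] == "used" && ed$source[[j]] == a && ed$target[[j]] != y) {
        out <- c(out, paste(y, ed$target[[j]], sep = " -> "))
      }
    }
  }
  sort(unique(out))
}

auto_derived_pairs <- function(account) {
  ed <- edges(account)
  auto <- ed[ed$kind == "wasDerivedFrom" & ed$auto_derived, ]
  sort(paste(auto$source, auto$target, sep = " -> "))
}

manual_derived_pairs <- function(account) {
  ed <- edges(account)
  man <- ed[ed$kind == "wasDerivedFrom" & !ed$auto_derived, ]
  sort(paste(man$source, man$target, sep = " -> "))
}

# the maintained auto set must equal the closure minus pairs already covered
# by a manual wasDerivedFrom edge
expect_closure_holds <- function(account) {
  expect_identical(auto_derived_pairs(account),
                   setdiff(closure_oracle(account), manual_derived_pairs(account)))
}

# minimal hand-built account: one activity using X, generating Y
tiny_account <- function() {
  acc <- prov_account(name = "tiny", id = "T1",
                      start_time = "2020-01-01T00:00:00",
                      end_time = "2020-01-01T23:00:00")
  acc <- add_node(acc, "collection", id = "X", name = "X", size = 10)
  acc <- add_node(acc, "collection", id = "Y", name = "Y", size = 5)
  acc <- add_node(acc, "activity", id = "A", name = "process",
                  start_time = "2020-01-01T01:00:00",
                  end_time = "2020-01-01T02:00:00")
  acc <- add_relation(acc, "used", "A", "X")
  add_relation(acc, "wasGeneratedBy", "Y", "A")
}

case_study_account <- function(payload_dir = NULL) {
  get_account(build_case_study(payload_dir = payload_dir), "Multiple Alignment")
}

wdf_is_acyclic <- function(account) {
  ed <- edges(account)
  der <- ed[ed$kind == "wasDerivedFrom", ]
  if (!nrow(der)) return(TRUE)
  ids <- unique(c(der$source, der$target))
  g <- igraph::graph_from_data_frame(der[, c("source", "target")],
                                     directed = TRUE, vertices = ids)
  igraph::is_dag(g)
}
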