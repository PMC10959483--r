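test_that("parse_obo reads chains, diamonds and drops obsolete terms", {
  g <- chain_graph()
  expect_setequal(g$terms, c("T:root", "T:A", "T:B"))
  expect_equal(nrow(g$edges), 2)
  expect_equal(g$roots, "T:root")
  expect_equal(unname(g$labels["T:B"]), "b")

  d <- diamond_graph()
  expect_setequal(d$terms, c("T:A", "T:B", "T:C", "T:D"))
  expect_equal(nrow(d$edges), 4)
  expect_setequal(
    paste(d$edges$child, d$edges$parent),
    c("T:B T:A", "T:C T:A", "T:D T:B", "T:D T:C"))
  expect_equal(d$roots, "T:A")

  obs <- paste(obo_chain(),
               "\n[Term]\nid: T:old\nname: gone\nis_obsolete: true\n",
               "is_a: T:root\n", sep = "")
  g2 <- parse_obo(write_obo_text(obs))
  expect_false("T:old" %in% g2$terms)
})

test_that("parse_obo rejects malformed stanzas and cycles", {
  bad <- paste("format-version: 1.2", "", "[Term]", "id: T:x",
               "not a key-value line", sep = "\n")
  expect_error(parse_obo(write_obo_text(bad)), "malformed")

  cyc <- paste("format-version: 1.2", "",
               "[Term]", "id: T:a", "is_a: T:b", "",
               "[Term]", "id: T:b", "is_a: T:a", "", sep = "\n")
  expect_error(parse_obo(write_obo_text(cyc)), "cycle")
})

test_that("alt_id resolves to the primary id in mapping", {
  txt <- paste("format-version: 1.2", "",
               "[Term]", "id: T:root", "",
               "[Term]", "id: T:A", "alt_id: T:Aold", "is_a: T:root", "",
               sep = "\n")
  g <- parse_obo(write_obo_text(txt))
  events <- tibble::tibble(person_id = "p1", code = "c1", age_years = 1)
  cm <- tibble::tibble(source_code = "c1", term_id = "T:Aold")
  ann <- map_concepts(events, cm, g)
  expect_equal(ann$term, "T:A")
})

test_that("write_obo round-trips term and edge sets", {
  for (g in list(chain_graph(), diamond_graph(),
                 simulate_ontology(40, 5, seed = 3))) {
    path <- withr::local_tempfile(fileext = ".obo")
    write_obo(g, path)
    g2 <- parse_obo(path)
    expect_setequal(g2$terms, g$terms)
    expect_setequal(paste(g2$edges$child, g2$edges$parent),
                    paste(g$edges$child, g$edges$parent))
  }
})

test_that("ancestors match brute-force path enumeration", {
  g <- chain_graph()
  expect_setequal(onto_ancestors(g, "T:B"), c("T:A", "T:root"))
  expect_equal(onto_ancestors(g, "T:root"), character(0))

  d <- diamond_graph()
  expect_setequal(onto_ancestors(d, "T:D"), c("T:B", "T:C", "T:A"))
  expect_error(onto_ancestors(d, "T:missing"), "unknown")

  # random ontology: compare to independent path enumeration
  g3 <- simulate_ontology(60, 5, seed = 7)
  for (t in sample(g3$terms, 12)) {
    expect_setequal(onto_ancestors(g3, t), path_ancestors(g3, t))
  }
})

test_that("children and rooted subgraphs follow the edge list", {
  d <- diamond_graph()
  expect_setequal(onto_children(d, "T:A"), c("T:B", "T:C"))
  expect_equal(onto_children(d, "T:D"), character(0))

  sub <- rooted_subgraph(d, "T:B")
  expect_setequal(sub$terms, c("T:B", "T:D"))
  expect_equal(nrow(sub$edges), 1)

  g <- chain_graph()
  sub2 <- rooted_subgraph(g, "T:A")
  expect_setequal(sub2$terms, c("T:A", "T:B"))
  expect_equal(rooted_subgraph(g, "T:B")$terms, "T:B")
})

test_that("propagation closes annotation sets under ancestry", {
  g <- chain_graph()
  ann <- tibble::tibble(person_id = "p1", term = "T:B", age_years = 3)
  pro <- propagate_annotations(ann, g)
  expect_setequal(pro$term, c("T:B", "T:A", "T:root"))

  d <- diamond_graph()
  pro2 <- propagate_annotations(
    tibble::tibble(person_id = "p1", term = "T:D"), d)
  expect_setequal(pro2$term, union("T:D", onto_ancestors(d, "T:D")))

  # idempotence
  expect_equal(propagate_annotations(pro, g), pro)

  # unknown term errors
  expect_error(
    propagate_annotations(tibble::tibble(person_id = "p", term = "T:no"), g),
    "absent")
})

test_that("propagated ancestor ages are the minimum contributing age", {
  d <- diamond_graph()
  ann <- tibble::tibble(person_id = "p1",
                        term = c("T:B", "T:C"),
                        age_years = c(5, 2))
  pro <- propagate_annotations(ann, d)
  expect_equal(pro$age_years[pro$term == "T:A"], 2)
  expect_equal(pro$age_years[pro$term == "T:B"], 5)
})

test_that("propagation yields monotone carrier counts along edges", {
  g <- simulate_ontology(80, 5, seed = 21)
  set.seed(1)
  leaves <- attr(g, "roles")$term[attr(g, "roles")$role == "leaf"]
  ann <- tibble::tibble(
    person_id = rep(sprintf("p%02d", 1:30), each = 4),
    term = sample(leaves, 120, replace = TRUE))
  pro <- propagate_annotations(dplyr::distinct(ann), g)
  counts <- table(factor(pro$term, levels = g$terms))
  for (i in seq_len(nrow(g$edges))) {
    expect_gte(counts[[g$edges$parent[i]]], counts[[g$edges$child[i]]])
  }
  # closure: every ancestor of every annotated term is present
  by_person <- split(pro$term, pro$person_id)
  for (terms in by_person[1:5]) {
    for (t in terms) expect_true(all(onto_ancestors(g, t) %in% terms))
  }
})

test_that("map_concepts fans out multi-target codes and counts unmapped", {
  g <- diamond_graph()
  cm <- tibble::tibble(source_code = c("c1", "c2", "c2"),
                       term_id = c("T:D", "T:B", "T:C"))
  events <- tibble::tibble(
    person_id = c("p1", "p1", "p2"),
    code = c("c1", "c2", "nope"),
    age_years = c(1, 2, 3))
  ann <- map_concepts(events, cm, g)
  expect_equal(nrow(ann), 3)  # 1 + 2 (fan-out), unmapped dropped
  expect_setequal(ann$term[ann$person_id == "p1"], c("T:D", "T:B", "T:C"))
  expect_equal(attr(ann, "n_unmapped"), 1)
  expect_equal(attr(ann, "unmapped_codes"), "nope")
})
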