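two_gene_doc <- function(subtypes = "activation", rel_type = "PPrel") {
  kgml_doc(
    entries = list(list(id = "1", type = "gene", name = "TP53"),
                   list(id = "2", type = "gene", name = "MDM2")),
    relations = list(list(entry1 = "1", entry2 = "2", type = rel_type,
                          subtypes = subtypes)))
}

test_that("parse_kgml transcribes entries, relations and subtypes", {
  p <- write_kgml(two_gene_doc())
  parsed <- parse_kgml(p)
  expect_length(parsed$entries, 2)
  expect_length(parsed$relations, 1)
  expect_equal(parsed$relations[[1]]$subtypes, "activation")
  expect_equal(parsed$entries[["1"]]$names, "TP53")

  pg <- write_kgml(kgml_doc(entries = list(
    list(id = "1", type = "gene", name = "A"),
    list(id = "2", type = "gene", name = "B"),
    list(id = "3", type = "group", components = c("1", "2")))))
  parsed <- parse_kgml(pg)
  expect_length(parsed$entries[["3"]]$component_ids, 2)

  p0 <- write_kgml(kgml_doc(
    entries = list(list(id = "1", type = "gene", name = "A"),
                   list(id = "2", type = "gene", name = "B")),
    relations = list(list(entry1 = "1", entry2 = "2", type = "PPrel",
                          subtypes = character(0)))))
  expect_length(parse_kgml(p0)$relations[[1]]$subtypes, 0)

  bad <- tempfile(fileext = ".xml")
  writeLines("<pathway><entry", bad)
  expect_error(parse_kgml(bad), "malformed KGML")
  notk <- write_kgml("<notes>hi</notes>")
  expect_error(parse_kgml(notk), "no <pathway>")
})

test_that("subtype keywords map to signs, neutral keywords drop", {
  expect_equal(sign_from_subtypes(c("inhibition", "phosphorylation")), "-")
  expect_equal(sign_from_subtypes("expression"), "+")
  expect_equal(sign_from_subtypes("repression"), "-")
  expect_length(sign_from_subtypes("binding/association"), 0)
  expect_length(sign_from_subtypes(character(0)), 0)
  expect_message(both <- sign_from_subtypes(c("activation", "inhibition")),
                 "ambiguous")
  expect_setequal(both, c("+", "-"))
  cfgfile <- tempfile()
  writeLines(c("phosphorylation\t+", "indirect effect\tdrop"), cfgfile)
  cfg <- default_sign_config(cfgfile)
  expect_equal(sign_from_subtypes("phosphorylation", cfg), "+")
  expect_length(sign_from_subtypes("indirect effect", cfg), 0)
})

test_that("PPrel and GErel node splitting follows the suffix rules", {
  g <- build_graph(parse_kgml(write_kgml(two_gene_doc())))
  e <- paste(g$edges$from, g$edges$to)
  expect_true("TP53_prot MDM2_prot" %in% e)
  # every protein node has its formation edge
  expect_true(all(paste(c("TP53_gen", "MDM2_gen"),
                        c("TP53_prot", "MDM2_prot")) %in% e))

  ge <- build_graph(parse_kgml(write_kgml(
    two_gene_doc(subtypes = "expression", rel_type = "GErel"))))
  e <- paste(ge$edges$from, ge$edges$relation, ge$edges$to)
  expect_true("TP53_prot GErel MDM2_gen" %in% e)
  expect_true("TP53_gen GPrel TP53_prot" %in% e)
  expect_true("MDM2_gen GPrel MDM2_prot" %in% e)
})

test_that("group entries become complexes wired from their members", {
  doc <- kgml_doc(entries = list(
    list(id = "1", type = "gene", name = "NFKB1"),
    list(id = "2", type = "gene", name = "BCL3"),
    list(id = "3", type = "group", components = c("1", "2"))))
  g <- build_graph(parse_kgml(write_kgml(doc)))
  cx <- "BCL3_prot::NFKB1_prot"
  expect_true(cx %in% g$nodes$id)
  mem <- in_edges(g, cx)
  expect_equal(nrow(mem), 2)
  expect_true(all(mem$sign == "+"))
  expect_setequal(mem$from, c("BCL3_prot", "NFKB1_prot"))
  expect_setequal(g$nodes$id,
                  c("BCL3_gen", "BCL3_prot", "NFKB1_gen", "NFKB1_prot", cx))
})

test_that("multi-symbol entries expand and merged pathways deduplicate", {
  doc <- kgml_doc(
    entries = list(list(id = "1", type = "gene", name = "PIK3CA, PIK3CB"),
                   list(id = "2", type = "gene", name = "AKT1")),
    relations = list(list(entry1 = "1", entry2 = "2", type = "PPrel",
                          subtypes = "activation")))
  g <- build_graph(parse_kgml(write_kgml(doc)))
  pp <- g$edges[g$edges$relation == "PPrel", ]
  expect_setequal(pp$from, c("PIK3CA_prot", "PIK3CB_prot"))
  # same pathway twice: merged graph identical to single ingest
  g2 <- build_graph(list(parse_kgml(write_kgml(doc)),
                         parse_kgml(write_kgml(doc))))
  expect_equal(g2$edges, g$edges)
})

test_that("compound entries and unsigned relations are excluded", {
  doc <- kgml_doc(
    entries = list(list(id = "1", type = "gene", name = "A"),
                   list(id = "2", type = "compound", name = "C00076",
                        kegg = "cpd:C00076"),
                   list(id = "3", type = "gene", name = "B")),
    relations = list(list(entry1 = "1", entry2 = "2", type = "PPrel",
                          subtypes = "activation"),
                     list(entry1 = "1", entry2 = "3", type = "PPrel",
                          subtypes = "binding/association")))
  g <- build_graph(parse_kgml(write_kgml(doc)))
  expect_false(any(grepl("C00076", g$nodes$id)))
  expect_false(any(g$edges$from == "A_prot" & g$edges$to == "B_prot"))
})

test_that("structural invariants hold on an ingested multi-pathway graph", {
  doc1 <- kgml_doc(
    entries = list(list(id = "1", type = "gene", name = "EGF"),
                   list(id = "2", type = "gene", name = "EGFR"),
                   list(id = "3", type = "gene", name = "MAPK1"),
                   list(id = "4", type = "group", components = c("2", "3"))),
    relations = list(list(entry1 = "1", entry2 = "2", type = "PPrel",
                          subtypes = "activation"),
                     list(entry1 = "2", entry2 = "3", type = "PPrel",
                          subtypes = "phosphorylation"),
                     list(entry1 = "4", entry2 = "1", type = "GErel",
                          subtypes = "expression")))
  doc2 <- kgml_doc(
    entries = list(list(id = "1", type = "gene", name = "EGFR"),
                   list(id = "2", type = "gene", name = "STAT3")),
    relations = list(list(entry1 = "1", entry2 = "2", type = "PPrel",
                          subtypes = "inhibition")))
  g <- ingest_kgml(c(write_kgml(doc1), write_kgml(doc2)))

  prot <- g$nodes$id[g$nodes$kind == "protein"]
  for (p in prot) {
    gp <- in_edges(g, p)
    gp <- gp[gp$relation == "GPrel", ]
    expect_equal(nrow(gp), 1)
    expect_equal(gp$from, sub("_prot$", "_gen", p))
    expect_equal(gp$sign, "+")
  }
  for (cx in g$nodes$id[g$nodes$kind == "complex"]) {
    mem <- in_edges(g, cx)
    expect_equal(nrow(mem), length(pathcons:::complex_members(cx)))
    expect_true(all(mem$sign == "+"))
  }
  expect_false(any(g$edges$sign == "0"))
  expect_false(any(g$edges$relation == "GErel" & grepl("_prot$", g$edges$to)))
  expect_false(any(g$edges$relation == "GPrel" & grepl("_gen$", g$edges$to)))

  # dropping the gene->protein formation edges disconnects the graph
  no_gp <- signed_graph(g$edges[g$edges$relation != "GPrel", ],
                        nodes = g$nodes$id)
  comp_full <- igraph::components(pathcons:::as_igraph(g), mode = "weak")
  comp_cut <- igraph::components(pathcons:::as_igraph(no_gp), mode = "weak")
  expect_gt(comp_cut$no, comp_full$no)
})
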