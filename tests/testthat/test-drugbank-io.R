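fixture_xml_3 <- paste0(
  "<drugbank>",
  "<drug><drugbank-id>DB00001</drugbank-id><name>alpha</name>",
  "<groups><group>Approved</group><group>Illicit</group></groups>",
  "<atc-codes><atc-code code=\"N05BA01\"/></atc-codes>",
  "<targets><target><polypeptide uniprot-id=\"P1\" species=\"Humans\"/></target>",
  "<target><polypeptide uniprot-id=\"P2\" species=\"Humans\"/></target></targets>",
  "</drug>",
  "<drug><drugbank-id>DB00002</drugbank-id><name>beta</name>",
  "<groups><group>approved</group></groups></drug>",
  "<drug><drugbank-id>DB00003</drugbank-id><name>gamma</name>",
  "<groups><group>approved</group></groups>",
  "<targets><target><polypeptide uniprot-id=\"P3\" species=\"Rat\"/></target></targets>",
  "</drug>",
  "</drugbank>")

test_that("DrugBank-dialect XML parses into records in file order", {
  recs <- parse_drugbank(fixture_xml_3)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, "", "drug_id"),
               c("DB00001", "DB00002", "DB00003"))
  expect_equal(recs[[1]]$groups, c("approved", "illicit"))  # lower-cased
  expect_equal(nrow(recs[[1]]$targets), 2)
  expect_equal(recs[[1]]$atc_codes, "N05BA01")
  expect_equal(nrow(recs[[2]]$targets), 0)  # absent <targets>
  expect_equal(recs[[2]]$atc_codes, character())
})

test_that("repeated target accessions deduplicate within a record", {
  xml <- paste0(
    "<drugbank><drug><drugbank-id>DB1</drugbank-id><name>x</name>",
    "<groups><group>approved</group></groups>",
    "<targets>",
    "<target><polypeptide uniprot-id=\"P9\" species=\"Humans\"/></target>",
    "<target><polypeptide uniprot-id=\"P9\" species=\"Humans\"/></target>",
    "<target><polypeptide uniprot-id=\"P8\" species=\"Humans\"/></target>",
    "</targets></drug></drugbank>")
  recs <- parse_drugbank(xml)
  expect_equal(sort(recs[[1]]$targets$uniprot_acc), c("P8", "P9"))
})

test_that("malformed input and duplicate ids are rejected", {
  expect_error(parse_drugbank("<drugbank><drug></drugbank>"))
  dup <- paste0("<drugbank>",
                "<drug><drugbank-id>DB1</drugbank-id><name>a</name></drug>",
                "<drug><drugbank-id>DB1</drugbank-id><name>b</name></drug>",
                "</drugbank>")
  expect_error(parse_drugbank(dup), "duplicate drug ids")
  badatc <- paste0("<drugbank><drug><drugbank-id>DB1</drugbank-id>",
                   "<name>a</name><atc-codes><atc-code code=\"X9\"/>",
                   "</atc-codes></drug></drugbank>")
  expect_error(parse_drugbank(badatc), "malformed ATC")
})

test_that("parse/write round trip is lossless for the dialect fields", {
  recs <- parse_drugbank(fixture_xml_3)
  path <- withr::local_tempfile(fileext = ".xml")
  write_drugbank(recs, path)
  expect_equal(parse_drugbank(path), recs)
})

test_that("gene mapping table loads with set semantics and validation", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("uniprot_acc\tgene_symbol\tentrez_id",
               "P1\tGABRA1\t2554", "P2\tOPRM1\t4988"), path)
  m <- load_gene_mapping(path)
  expect_equal(nrow(m), 2)
  expect_equal(m$gene_symbol[m$uniprot_acc == "P1"], "GABRA1")

  writeLines(c("uniprot_acc\tgene_symbol\tentrez_id",
               "P1\tGABRA1\t2554", "P1\tGABRA1\t2554"), path)
  expect_equal(nrow(load_gene_mapping(path)), 1)  # identical duplicate row

  writeLines(c("uniprot_acc\tgene_symbol\tentrez_id",
               "P1\tGABRA1\t2554", "P1\tOPRM1\t4988"), path)
  expect_error(load_gene_mapping(path), "conflicting")

  writeLines("uniprot_acc\tgene_symbol\tentrez_id", path)
  expect_warning(m0 <- load_gene_mapping(path), "empty")
  expect_equal(nrow(m0), 0)
})

test_that("edge lists round-trip exactly as sets", {
  net <- rand_bipartite(12, 9, 0.35, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_setequal(paste(back$drug_id, back$gene_symbol),
                  paste(net$edges$drug_id, net$edges$gene_symbol))

  writeLines(c("drug_id\tdrug_name\tgene_symbol",
               "DB1\tx\tG1", "DB1\tx\tG1"), path)
  expect_error(read_edge_list(path), "duplicated pair")
  expect_equal(nrow(read_edge_list(path, dedup = TRUE)), 1)

  writeLines(c("drug_id\tdrug_name\tgene_symbol", "DB1\tx\tG1", "DB2\ty\t"),
             path)
  expect_error(read_edge_list(path), "row")
})

test_that("SIF export writes one relation line per edge", {
  net <- dtn_network(c("DB1", "DB2"), "G1",
                     data.frame(drug_id = c("DB1", "DB2"),
                                gene_symbol = "G1"))
  path <- withr::local_tempfile(fileext = ".sif")
  export_sif(net, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_true(all(grepl("\ttargets\t", lines)))
})

test_that("GraphML export carries node attributes through a round trip", {
  net <- rand_bipartite(6, 4, 0.5, seed = 11)
  cent <- centrality_table(net, degree_cutoff = 1, betweenness_cutoff = 0)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, path, cent)
  # generic XML reader sees one <node> per drug and gene
  doc <- xml2::read_xml(path)
  n_nodes <- length(xml2::xml_find_all(doc, "//*[local-name()='node']"))
  expect_equal(n_nodes, length(net$drugs) + length(net$genes))
  # igraph re-parse recovers the attribute map
  g <- igraph::read_graph(path, format = "graphml")
  idx <- match(cent$node_id, igraph::V(g)$name)
  expect_equal(igraph::V(g)$degree[idx], cent$degree)
  expect_equal(igraph::V(g)$betweenness[idx], cent$betweenness)
  expect_equal(as.logical(igraph::V(g)$is_hub[idx]), cent$is_hub)
  expect_equal(igraph::V(g)$kind[idx], cent$node_kind)
  # unknown node in the attribute table is an error
  bad <- cent; bad$node_id[1] <- "nope"
  expect_error(export_graphml(net, path, bad), "unknown node")
})
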