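test_that("illicit selection keys on the group tag, not other statuses", {
  recs <- list(drec("DB1", groups = c("approved", "illicit")),
               drec("DB2", groups = "approved"),
               drec("DB3", groups = "Illicit"),
               drec("DB4", groups = "experimental"),
               drec("DB5", groups = c("withdrawn", "illicit")))
  expect_setequal(select_illicit(recs), c("DB1", "DB3", "DB5"))
})

test_that("network construction collapses symbols and drops unmappable drugs", {
  # two accessions mapping to one symbol give one gene node and one edge
  recs <- list(drec("DB1", targets = tgt(c("P1", "P2"))),
               drec("DB2", targets = tgt("P9")),          # not in mapping
               drec("DB3", targets = tgt("P3", "Rat")))   # non-human
  m <- mapping_of(c("P1", "P2", "P3"), c("GABRA1", "GABRA1", "OPRM1"))
  net <- build_network(recs, m)
  expect_equal(net$drugs, "DB1")
  expect_equal(net$genes, "GABRA1")
  expect_equal(nrow(net$edges), 1)
  expect_equal(attr(net, "unmapped_accessions"), "P9")
})

test_that("edge counts match a hand-enumerated fixture", {
  set.seed(99)
  drugs <- sprintf("DB%02d", 1:10)
  genes <- paste0("G", 1:8)
  pairs <- unique(data.frame(
    drug_id = sample(drugs, 40, replace = TRUE),
    gene_symbol = sample(genes, 40, replace = TRUE),
    stringsAsFactors = FALSE))
  accs <- paste0("P", 1:8)
  recs <- lapply(drugs, function(d) {
    gs <- pairs$gene_symbol[pairs$drug_id == d]
    drec(d, targets = tgt(accs[match(gs, genes)]))
  })
  net <- build_network(recs, mapping_of(accs, genes))
  expect_equal(nrow(net$edges), nrow(pairs))
  # degree sums on both sides equal the edge count
  d <- node_degree(net)
  expect_equal(sum(d[net$drugs]), nrow(net$edges))
  expect_equal(sum(d[net$genes]), nrow(net$edges))
})

test_that("illicit-related drugs share a target gene and exclude illicit drugs", {
  accs <- paste0("P", 1:6)
  syms <- paste0("G", 1:6)
  recs <- c(list(drec("ILL1", groups = "illicit", targets = tgt(c("P1", "P2")))),
            # 3 of 7 non-illicit drugs overlap the illicit target genes
            list(drec("R1", targets = tgt("P1")),
                 drec("R2", targets = tgt("P2")),
                 drec("R3", targets = tgt(c("P2", "P5"))),
                 drec("O1", targets = tgt("P3")),
                 drec("O2", targets = tgt("P4")),
                 drec("O3", targets = tgt("P5")),
                 drec("O4", targets = tgt("P6"))))
  m <- mapping_of(accs, syms)
  rel <- find_illicit_related(recs, m, "ILL1")
  expect_setequal(rel, c("R1", "R2", "R3"))
  expect_false("ILL1" %in% rel)
})

test_that("extended network restricts related drugs to illicit target genes", {
  # related drug hits 5 genes, only 2 of them illicit targets
  accs <- paste0("P", 1:6)
  recs <- list(drec("ILL1", groups = "illicit", targets = tgt(c("P1", "P2"))),
               drec("REL1", targets = tgt(paste0("P", 1:5))),
               drec("OTH1", targets = tgt("P6")))
  m <- mapping_of(accs, paste0("G", 1:6))
  ext <- build_extended(recs, m, "ILL1")
  expect_setequal(ext$genes, c("G1", "G2"))
  expect_equal(sum(ext$edges$drug_id == "REL1"), 2)
  # node count identity: |illicit| + |related| + |illicit target genes|
  expect_equal(length(ext$drugs) + length(ext$genes), 1 + 1 + 2)
})

test_that("extended network contains the illicit network as a subgraph", {
  for (s in 1:5) {
    g <- generate_synthetic(synthetic_config(seed = s))
    ill_ids <- select_illicit(g$records)
    ill <- build_network(g$records, g$mapping, drug_filter = ill_ids)
    ext <- build_extended(g$records, g$mapping, ill_ids)
    key <- function(n) paste(n$edges$drug_id, n$edges$gene_symbol)
    expect_true(all(key(ill) %in% key(ext)))
    # no extended edge touches a gene outside the illicit target set
    expect_true(all(ext$edges$gene_symbol %in% ill$genes))
    # brute-force recount of the extended edge set from the record list
    pairs <- do.call(rbind, lapply(g$records, function(r) {
      h <- r$targets[tolower(r$targets$species) == "humans", , drop = FALSE]
      gs <- g$mapping$gene_symbol[match(h$uniprot_acc, g$mapping$uniprot_acc)]
      if (!length(gs)) return(NULL)
      data.frame(drug_id = r$drug_id, gene_symbol = unique(gs[!is.na(gs)]))
    }))
    ill_genes <- unique(pairs$gene_symbol[pairs$drug_id %in% ill_ids])
    rel <- setdiff(unique(pairs$drug_id[pairs$gene_symbol %in% ill_genes]),
                   ill_ids)
    manual <- pairs[pairs$drug_id %in% c(ill_ids, rel) &
                    pairs$gene_symbol %in% ill_genes, ]
    expect_equal(nrow(ext$edges), nrow(unique(manual)))
  }
})

test_that("drug partition is disjoint and exhaustive over target-bearing drugs", {
  fx <- partition_fixture()
  part <- partition_drugs(fx$records, fx$mapping)
  expect_length(part$illicit, 4)
  expect_length(part$illicit_related, 6)
  expect_length(part$other, 10)
  expect_length(intersect(part$illicit, part$illicit_related), 0)
  expect_length(intersect(part$illicit, part$other), 0)
  expect_length(intersect(part$illicit_related, part$other), 0)

  # a drug with no targets sits in no set but is reported
  recs <- c(fx$records, list(drec("DBNONE")))
  part2 <- partition_drugs(recs, fx$mapping)
  expect_equal(attr(part2, "excluded"), "DBNONE")
  expect_setequal(c(part2$illicit, part2$illicit_related, part2$other),
                  setdiff(vapply(recs, `[[`, "", "drug_id"), "DBNONE"))
})

test_that("network validation enforces the bipartite invariants", {
  expect_error(dtn_network("A", "A", data.frame(drug_id = "A",
                                                gene_symbol = "A")),
               "overlap")
  expect_error(
    validate_dtn(structure(list(drugs = "D", genes = "G",
                                edges = data.frame(drug_id = "X",
                                                   gene_symbol = "G"),
                                drug_labels = c(D = "other"),
                                gene_labels = c(G = "other-target")),
                           class = "dtn")),
    "unknown drug")
})
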