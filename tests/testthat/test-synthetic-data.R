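test_that("the same seed reproduces byte-identical XML", {
  cfg <- synthetic_config(seed = 13)
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_drugbank(generate_synthetic(cfg)$records, p1)
  write_drugbank(generate_synthetic(cfg)$records, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("generated XML re-parses to the in-memory records", {
  g <- generate_synthetic(synthetic_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".xml")
  write_drugbank(g$records, path)
  expect_equal(parse_drugbank(path), g$records)
})

test_that("deterministic blocks: p_within = 1, p_between = 0", {
  cfg <- synthetic_config(
    clusters = list(cluster_spec("c1", 4, 3, p_within = 1),
                    cluster_spec("c2", 5, 2, p_within = 1),
                    cluster_spec("c3", 3, 3, p_within = 1)),
    p_between = 0, n_bridge_genes = 0, bridge_pairs = list(),
    n_hub_drugs_per_cluster = 0, p_decoy_target = 0, seed = 5)
  g <- generate_synthetic(cfg)
  net <- build_network(g$records, g$mapping)
  expect_equal(nrow(net$edges), 4 * 3 + 5 * 2 + 3 * 3)
  comp <- igraph::components(as_igraph(net))
  expect_equal(comp$no, 3)  # disjoint complete bipartite blocks
})

test_that("realized within-cluster edge counts track the binomial expectation", {
  cfg0 <- synthetic_config(n_hub_drugs_per_cluster = 0, n_bridge_genes = 0,
                           bridge_pairs = list(), p_between = 0,
                           p_decoy_target = 0)
  for (s in 1:5) {
    cfg <- cfg0; cfg$seed <- 900L + s
    g <- generate_synthetic(cfg)
    net <- build_network(g$records, g$mapping)
    for (cl in names(cfg$clusters)) {
      drugs <- names(g$ground_truth$drug_clusters)[
        g$ground_truth$drug_clusters == cl]
      n_edges <- sum(net$edges$drug_id %in% drugs)
      spec <- cfg$clusters[[cl]]
      mu <- spec$n_drugs * spec$n_genes * spec$p_within
      sd3 <- 3 * sqrt(mu * (1 - spec$p_within))
      expect_gte(n_edges, mu - sd3)
      expect_lte(n_edges, mu + sd3)
    }
  }
})

test_that("planted structure is present and consistent", {
  g <- generate_synthetic(synthetic_config(seed = 21))
  gt <- g$ground_truth
  all_ids <- vapply(g$records, `[[`, "", "drug_id")
  expect_true(all(gt$hub_drugs %in% all_ids))
  expect_true(all(gt$bridge_genes %in% g$mapping$gene_symbol))
  expect_setequal(gt$illicit_drugs, select_illicit(g$records))
  # every bridge gene touches >= 2 drugs in each of its two clusters
  net <- build_network(g$records, g$mapping)
  for (bg in gt$bridge_genes) {
    touching <- net$edges$drug_id[net$edges$gene_symbol == bg]
    cl <- table(gt$drug_clusters[touching])
    expect_length(cl, 2)
    expect_true(all(cl >= 2))
  }
  # infeasible bridge spec is rejected
  expect_error(synthetic_config(
    clusters = list(cluster_spec("tiny", 2, 2), cluster_spec("c2", 20, 15)),
    bridge_pairs = list(c("tiny", "c2"))), "too small")
})

test_that("candidate lists hit the illicit target set exactly as requested", {
  g <- generate_synthetic(synthetic_config(seed = 2))
  gt <- g$ground_truth
  cand <- generate_candidate_list(gt, overlap_count = 17, decoy_count = 45,
                                  seed = 4)
  expect_length(cand, 62)
  expect_length(intersect(cand, gt$illicit_target_genes), 17)
  # zero overlap propagates to a null overlap test downstream
  cand0 <- generate_candidate_list(gt, overlap_count = 0, decoy_count = 10,
                                   seed = 4)
  net <- build_network(g$records, g$mapping)
  ext <- build_extended(g$records, g$mapping, gt$illicit_drugs)
  p0 <- candidate_overlap_test(cand0, ext$genes, net$genes)
  expect_equal(as.numeric(p0), 1)
  # downstream p is monotone non-increasing in the planted overlap
  ps <- vapply(c(0, 5, 10, length(gt$illicit_target_genes)), function(k) {
    cl <- generate_candidate_list(gt, k, decoy_count = 10, seed = 4)
    as.numeric(candidate_overlap_test(cl, ext$genes, net$genes))
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(generate_candidate_list(gt, overlap_count = 1e4, 5, 1),
               "exceeds")
})

test_that("the dataset bundle round-trips through the file formats", {
  g <- generate_synthetic(synthetic_config(seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_bundle(g, dir)
  expect_true(all(file.exists(paths)))
  m <- load_gene_mapping(paths[["mapping"]])
  expect_equal(m$gene_symbol, g$mapping$gene_symbol)
  recs <- parse_drugbank(paths[["xml"]])
  expect_equal(recs, g$records)
  cfg <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg$seed, 6)
})

test_that("a 5-fold illicit-fraction contrast plants detectable ATC enrichment", {
  clusters <- list(
    cluster_spec("depressants", 100, 15, illicit_fraction = 0.5,
                 atc_pool = c(N05 = 0.8, V03 = 0.2)),
    cluster_spec("stimulants", 100, 15, illicit_fraction = 0.1,
                 atc_pool = c(N06 = 0.8, V03 = 0.2)),
    cluster_spec("analgesics", 100, 15, illicit_fraction = 0.1,
                 atc_pool = c(N02 = 0.8, V03 = 0.2)),
    cluster_spec("steroids", 100, 15, illicit_fraction = 0.1,
                 atc_pool = c(A14 = 0.8, V03 = 0.2)))
  for (s in 1:10) {
    g <- generate_synthetic(synthetic_config(clusters = clusters, seed = s))
    planted <- g$ground_truth$planted_enrichment
    ill <- select_illicit(g$records)
    all_ids <- vapply(g$records, `[[`, "", "drug_id")
    res <- enrich_drug_categories(
      atc_annotated(g$records, ill),
      atc_annotated(g$records, setdiff(all_ids, ill)),
      atc_memberships(g$records))
    cat_dep <- planted$category_id[planted$cluster == "depressants"]
    expect_lt(res$p[res$category_id == cat_dep], 0.001)
  }
})
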