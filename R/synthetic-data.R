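#' Specification for one synthetic drug-category cluster
#'
#' @param name unique cluster name (also used as the drugs' category label).
#' @param n_drugs,n_genes cluster sizes.
#' @param p_within within-cluster drug-gene edge probability.
#' @param illicit_fraction probability that a cluster drug carries the
#'   "illicit" legal-status group.
#' @param atc_pool named numeric vector of ATC second-sublevel codes with
#'   sampling weights; the highest-weight code is the cluster's planted
#'   enriched category.
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(name, n_drugs = 20, n_genes = 15, p_within = 0.3,
                         illicit_fraction = 0.3,
                         atc_pool = c(N05 = 0.8, V03 = 0.2)) {
  stopifnot(n_drugs >= 0, n_genes >= 0,
            p_within >= 0, p_within <= 1,
            illicit_fraction >= 0, illicit_fraction <= 1,
            length(atc_pool) >= 1, all(atc_pool >= 0))
  structure(list(name = name, n_drugs = n_drugs, n_genes = n_genes,
                 p_within = p_within, illicit_fraction = illicit_fraction,
                 atc_pool = atc_pool),
            class = "cluster_spec")
}

#' Synthetic dataset configuration
#'
#' Defines a planted-partition bipartite drug-target world: clustered drug
#' categories with dense within-cluster wiring, sparse cross-cluster edges,
#' designated hub drugs whose edge probability is boosted, bridge genes
#' wired into two clusters each, category-correlated ATC codes and
#' per-cluster illicit fractions. The default emulates the qualitative
#' structure of a curated drug-target database at test scale: four clusters
#' (depressants, stimulants, analgesics, steroids) of 20 drugs x 15 genes,
#' within-cluster edge probability 0.3, cross-cluster 0.01, one boosted hub
#' drug per cluster, and two bridge genes joining
#' depressants-stimulants and analgesics-steroids.
#'
#' @param clusters list of [cluster_spec()]s with unique names.
#' @param p_between cross-cluster drug-gene edge probability.
#' @param n_bridge_genes number of planted bridge genes.
#' @param bridge_pairs list of length-2 character vectors of cluster names;
#'   recycled over the bridge genes.
#' @param bridge_edges_per_side guaranteed drug attachments of each bridge
#'   gene within each of its two clusters (>= 2).
#' @param hub_boost multiplier on `p_within` for hub drugs (capped at 1).
#' @param n_hub_drugs_per_cluster designated hub drugs per cluster.
#' @param p_atc probability a drug carries any ATC annotation.
#' @param p_decoy_target probability a drug carries one non-human decoy
#'   target (exercises the human-species filter).
#' @param seed integer seed governing all randomness.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    clusters = list(
      cluster_spec("depressants", illicit_fraction = 0.5,
                   atc_pool = c(N05 = 0.8, V03 = 0.2)),
      cluster_spec("stimulants", illicit_fraction = 0.4,
                   atc_pool = c(N06 = 0.8, V03 = 0.2)),
      cluster_spec("analgesics", illicit_fraction = 0.3,
                   atc_pool = c(N02 = 0.8, V03 = 0.2)),
      cluster_spec("steroids", illicit_fraction = 0.1,
                   atc_pool = c(A14 = 0.8, V03 = 0.2))),
    p_between = 0.01, n_bridge_genes = 2,
    bridge_pairs = list(c("depressants", "stimulants"),
                        c("analgesics", "steroids")),
    bridge_edges_per_side = 10, hub_boost = 3,
    n_hub_drugs_per_cluster = 1, p_atc = 0.85,
    p_decoy_target = 0.1, seed = 1L) {
  names(clusters) <- vapply(clusters, `[[`, "", "name")
  if (anyDuplicated(names(clusters))) stop("cluster names must be unique")
  stopifnot(p_between >= 0, p_between <= 1, n_bridge_genes >= 0,
            bridge_edges_per_side >= 2, hub_boost >= 1)
  if (n_bridge_genes > 0) {
    for (bp in bridge_pairs) {
      if (length(bp) != 2L || !all(bp %in% names(clusters)))
        stop("bridge_pairs must name two existing clusters")
      if (any(vapply(clusters[bp], `[[`, 0, "n_drugs") < bridge_edges_per_side))
        stop("bridge gene cluster too small for ", bridge_edges_per_side,
             " guaranteed attachments")
    }
    if (length(bridge_pairs) == 0L)
      stop("n_bridge_genes > 0 needs bridge_pairs")
  }
  structure(list(clusters = clusters, p_between = p_between,
                 n_bridge_genes = n_bridge_genes, bridge_pairs = bridge_pairs,
                 bridge_edges_per_side = bridge_edges_per_side,
                 hub_boost = hub_boost,
                 n_hub_drugs_per_cluster = n_hub_drugs_per_cluster,
                 p_atc = p_atc, p_decoy_target = p_decoy_target,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic per-stage sub-seed from the single global seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 101L + stage
}

#' Generate a synthetic DrugBank-dialect dataset with known ground truth
#'
#' Draws drug-gene edges Bernoulli-independently (planted-partition
#' bipartite model): within-cluster pairs at the cluster's `p_within` (hub
#' drugs boosted by `hub_boost`, capped at 1), cross-cluster pairs at
#' `p_between`. Each bridge gene is wired to `bridge_edges_per_side` drugs
#' in each of its two clusters and nothing else. Illicit flags, ATC codes
#' and decoy non-human targets are then drawn per drug. The same seed
#' reproduces the dataset exactly, byte-for-byte once serialized.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (drug records), `mapping` (gene mapping
#'   table), `ground_truth` and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cl <- config$clusters
  n_cl <- length(cl)

  # node frames
  drug_tab <- do.call(rbind, lapply(seq_along(cl), function(i) {
    n <- cl[[i]]$n_drugs
    if (n == 0L) return(NULL)
    data.frame(cluster = names(cl)[i], idx = seq_len(n),
               stringsAsFactors = FALSE)
  }))
  drug_tab$drug_id <- sprintf("DB%05d", seq_len(nrow(drug_tab)))
  gene_tab <- do.call(rbind, lapply(seq_along(cl), function(i) {
    n <- cl[[i]]$n_genes
    if (n == 0L) return(NULL)
    data.frame(cluster = names(cl)[i],
               gene_symbol = sprintf("%sG%02d",
                                     toupper(substr(names(cl)[i], 1, 3)),
                                     seq_len(n)),
               stringsAsFactors = FALSE)
  }))
  if (config$n_bridge_genes > 0) {
    gene_tab <- rbind(gene_tab, data.frame(
      cluster = "bridge",
      gene_symbol = sprintf("BRG%02d", seq_len(config$n_bridge_genes)),
      stringsAsFactors = FALSE))
  }
  gene_tab$uniprot_acc <- sprintf("P%05d", seq_len(nrow(gene_tab)))

  # hub designation: first drugs of each cluster, deterministic
  set.seed(stage_seed(config$seed, 1L))
  hub_ids <- unlist(lapply(names(cl), function(nm) {
    ids <- drug_tab$drug_id[drug_tab$cluster == nm]
    utils::head(ids, min(config$n_hub_drugs_per_cluster, length(ids)))
  }))

  # edges: Bernoulli per drug-gene pair
  set.seed(stage_seed(config$seed, 2L))
  cluster_genes <- gene_tab[gene_tab$cluster != "bridge", , drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(drug_tab))) {
    d <- drug_tab[i, ]
    within <- cl[[d$cluster]]$p_within
    if (d$drug_id %in% hub_ids) within <- min(1, within * config$hub_boost)
    p <- ifelse(cluster_genes$cluster == d$cluster, within, config$p_between)
    hit <- stats::runif(nrow(cluster_genes)) < p
    if (any(hit))
      edges[[length(edges) + 1L]] <-
        data.frame(drug_id = d$drug_id,
                   gene_symbol = cluster_genes$gene_symbol[hit],
                   stringsAsFactors = FALSE)
  }
  # bridge gene guaranteed attachments
  if (config$n_bridge_genes > 0) {
    bridge_syms <- gene_tab$gene_symbol[gene_tab$cluster == "bridge"]
    for (j in seq_along(bridge_syms)) {
      bp <- config$bridge_pairs[[((j - 1L) %% length(config$bridge_pairs)) + 1L]]
      for (side in bp) {
        ids <- drug_tab$drug_id[drug_tab$cluster == side]
        pick <- sample(ids, config$bridge_edges_per_side)
        edges[[length(edges) + 1L]] <-
          data.frame(drug_id = pick, gene_symbol = bridge_syms[j],
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- unique(do.call(rbind, edges))

  # illicit flags
  set.seed(stage_seed(config$seed, 3L))
  frac <- vapply(cl, `[[`, 0, "illicit_fraction")[drug_tab$cluster]
  illicit <- stats::runif(nrow(drug_tab)) < frac

  # ATC codes: 1 full 7-char code from the cluster pool, present w.p. p_atc
  set.seed(stage_seed(config$seed, 4L))
  atc_codes <- character(nrow(drug_tab))
  for (i in seq_len(nrow(drug_tab))) {
    if (stats::runif(1) >= config$p_atc) next
    pool <- cl[[drug_tab$cluster[i]]]$atc_pool
    lvl2 <- sample(names(pool), 1L, prob = pool)
    atc_codes[i] <- sprintf("%sAA%02d", lvl2, sample.int(99L, 1L))
  }

  # decoy non-human targets
  set.seed(stage_seed(config$seed, 5L))
  decoy <- stats::runif(nrow(drug_tab)) < config$p_decoy_target

  edge_by_drug <- split(edges$gene_symbol, edges$drug_id)
  acc_of <- stats::setNames(gene_tab$uniprot_acc, gene_tab$gene_symbol)
  records <- lapply(seq_len(nrow(drug_tab)), function(i) {
    d <- drug_tab[i, ]
    gs <- edge_by_drug[[d$drug_id]]
    targets <- if (is.null(gs)) {
      data.frame(uniprot_acc = character(), species = character(),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(uniprot_acc = unname(acc_of[sort(gs)]),
                 species = "Humans", stringsAsFactors = FALSE)
    }
    if (decoy[i])
      targets <- rbind(targets,
                       data.frame(uniprot_acc = sprintf("Q9%04d", i),
                                  species = "Rat", stringsAsFactors = FALSE))
    structure(list(
      drug_id = d$drug_id,
      name = sprintf("%s_drug_%02d", d$cluster, d$idx),
      groups = if (illicit[i]) c("approved", "illicit") else "approved",
      categories = d$cluster,
      atc_codes = if (nzchar(atc_codes[i])) atc_codes[i] else character(),
      targets = targets), class = "drug_record")
  })

  mapping <- data.frame(uniprot_acc = gene_tab$uniprot_acc,
                        gene_symbol = gene_tab$gene_symbol,
                        entrez_id = 100000L + seq_len(nrow(gene_tab)),
                        stringsAsFactors = FALSE)
  class(mapping) <- c("gene_mapping", "data.frame")

  illicit_ids <- drug_tab$drug_id[illicit]
  illicit_genes <- sort(unique(edges$gene_symbol[edges$drug_id %in% illicit_ids]))
  planted <- data.frame(
    cluster = names(cl),
    category_id = vapply(cl, function(x) names(which.max(x$atc_pool)), ""),
    stringsAsFactors = FALSE)

  ground_truth <- list(
    drug_clusters = stats::setNames(drug_tab$cluster, drug_tab$drug_id),
    gene_clusters = stats::setNames(gene_tab$cluster, gene_tab$gene_symbol),
    hub_drugs = hub_ids,
    bridge_genes = if (config$n_bridge_genes > 0)
      gene_tab$gene_symbol[gene_tab$cluster == "bridge"] else character(),
    illicit_drugs = illicit_ids,
    illicit_target_genes = illicit_genes,
    all_genes = gene_tab$gene_symbol,
    planted_enrichment = planted)

  list(records = records, mapping = mapping,
       ground_truth = ground_truth, config = config)
}

#' Generate an external candidate gene list with controlled overlap
#'
#' Emulates an independently curated addiction-candidate gene list: exactly
#' `overlap_count` genes drawn from the synthetic illicit target-gene set
#' plus `decoy_count` genes absent from it (other generated genes first,
#' then synthetic decoy symbols if needed).
#'
#' @param ground_truth the `ground_truth` element of [generate_synthetic()].
#' @param overlap_count candidates inside the illicit target-gene set.
#' @param decoy_count candidates outside it.
#' @param seed integer seed.
#' @return shuffled character vector of `overlap_count + decoy_count`
#'   symbols.
#' @export
generate_candidate_list <- function(ground_truth, overlap_count = 17,
                                    decoy_count = 45, seed = 1L) {
  pool_in <- ground_truth$illicit_target_genes
  if (overlap_count > length(pool_in))
    stop("overlap_count exceeds the ", length(pool_in),
         " available illicit target genes")
  pool_out <- setdiff(ground_truth$all_genes, pool_in)
  set.seed(stage_seed(seed, 9L))
  hits <- sample(pool_in, overlap_count)
  extra <- max(0L, decoy_count - length(pool_out))
  decoys <- c(sample(pool_out, min(decoy_count, length(pool_out))),
              if (extra > 0) sprintf("CANDX%03d", seq_len(extra)))
  sample(c(hits, decoys))
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits the XML dialect, the mapping TSV, a ground-truth JSON and a config
#' echo YAML under `dir`.
#'
#' @param generated result of [generate_synthetic()].
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic_bundle <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(xml = file.path(dir, "drugbank.xml"),
             mapping = file.path(dir, "gene_mapping.tsv"),
             truth = file.path(dir, "ground_truth.json"),
             config = file.path(dir, "config.yaml"))
  write_drugbank(generated$records, paths[["xml"]])
  utils::write.table(generated$mapping, paths[["mapping"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- generated$ground_truth
  gt$drug_clusters <- as.list(gt$drug_clusters)
  gt$gene_clusters <- as.list(gt$gene_clusters)
  jsonlite::write_json(gt, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  cfg <- generated$config
  cfg$clusters <- lapply(cfg$clusters, function(x) {
    x$atc_pool <- as.list(x$atc_pool); unclass(x)
  })
  yaml::write_yaml(unclass(cfg), paths[["config"]])
  invisible(paths)
}
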