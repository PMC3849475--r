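#' Assemble a pipeline run configuration
#'
#' Exactly one of `xml` (with `mapping_tsv`) or `synthetic` must be given:
#' either a DrugBank-dialect XML file plus a UniProt-to-gene mapping table,
#' or a synthetic-data configuration generated in memory.
#'
#' @param xml path to DrugBank-dialect XML.
#' @param mapping_tsv path to the accession-to-gene mapping TSV.
#' @param synthetic a [synthetic_config()].
#' @param gene_memberships optional long-format term membership table for
#'   the comparative gene-term analysis (data frame or TSV path).
#' @param pathway_memberships optional membership table for the within-set
#'   pathway stage.
#' @param candidate_genes optional character vector (or path to a one-symbol-
#'   per-line file) for the candidate-overlap test.
#' @param degree_cutoff,betweenness_cutoff numeric manual thresholds, or
#'   NULL for knee detection on the corresponding distribution.
#' @param pair_convention betweenness pair convention, "unordered" or
#'   "ordered".
#' @param alpha raw-p significance level; `alpha_adj` the BH-adjusted level.
#' @param out_dir output directory for the report bundle.
#' @param seed integer seed (synthetic generation and any sampling).
#' @return list of class `run_config`.
#' @export
run_config <- function(xml = NULL, mapping_tsv = NULL, synthetic = NULL,
                       gene_memberships = NULL, pathway_memberships = NULL,
                       candidate_genes = NULL,
                       degree_cutoff = NULL, betweenness_cutoff = NULL,
                       pair_convention = "unordered",
                       alpha = 0.05, alpha_adj = 0.05,
                       out_dir = tempfile("illicitnet_run_"), seed = 1L) {
  if (is.null(xml) == is.null(synthetic))
    stop("exactly one of xml or synthetic must be set")
  if (!is.null(xml) && is.null(mapping_tsv))
    stop("xml input needs mapping_tsv")
  structure(list(xml = xml, mapping_tsv = mapping_tsv, synthetic = synthetic,
                 gene_memberships = gene_memberships,
                 pathway_memberships = pathway_memberships,
                 candidate_genes = candidate_genes,
                 degree_cutoff = degree_cutoff,
                 betweenness_cutoff = betweenness_cutoff,
                 pair_convention = pair_convention,
                 alpha = alpha, alpha_adj = alpha_adj,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

mean_degrees <- function(net) {
  e <- nrow(net$edges)
  list(n_drugs = length(net$drugs), n_genes = length(net$genes),
       n_nodes = length(net$drugs) + length(net$genes), n_edges = e,
       mean_drug_degree = if (length(net$drugs)) e / length(net$drugs) else NA_real_,
       mean_drug_degree_1dp = if (length(net$drugs))
         round_half_up(e / length(net$drugs), 1) else NA_real_,
       mean_gene_degree = if (length(net$genes)) e / length(net$genes) else NA_real_,
       mean_gene_degree_1dp = if (length(net$genes))
         round_half_up(e / length(net$genes), 1) else NA_real_)
}

#' Run the full analysis pipeline
#'
#' End to end: parse or generate the drug records, build the illicit,
#' illicit-extended and full drug-target networks, partition the drugs,
#' compute centralities with hub/bridge flags on the extended network, run
#' the ATC second-sublevel comparisons (illicit vs other, illicit-related vs
#' other) and any configured gene-term / pathway / candidate analyses, and
#' write the report bundle (edge lists, GraphML, centrality TSV, enrichment
#' TSVs, summary JSON) under `config$out_dir`. Identical configuration and
#' seed reproduce the bundle byte for byte.
#'
#' @param config a [run_config()].
#' @return invisible list with the in-memory results (`networks`,
#'   `partition`, `centrality`, `cutoffs`, `enrichment`, `summary`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    gen <- generate_synthetic(syn)
    records <- gen$records
    mapping <- gen$mapping
  } else {
    records <- parse_drugbank(config$xml)
    mapping <- load_gene_mapping(config$mapping_tsv)
    gen <- NULL
  }
  drug_names <- stats::setNames(vapply(records, `[[`, "", "name"),
                                vapply(records, `[[`, "", "drug_id"))

  illicit <- select_illicit(records)
  full_net <- build_network(records, mapping)
  illicit_net <- build_network(records, mapping, drug_filter = illicit)
  extended_net <- build_extended(records, mapping, illicit)
  partition <- partition_drugs(records, mapping)

  # centrality and cutoffs on the extended network
  deg <- node_degree(extended_net)
  btw <- node_betweenness(extended_net, config$pair_convention)
  dc <- if (is.null(config$degree_cutoff))
    detect_cutoff(deg, "knee", metric = "degree")
  else detect_cutoff(deg, "manual", config$degree_cutoff, metric = "degree")
  bc <- if (is.null(config$betweenness_cutoff))
    detect_cutoff(btw, "knee", metric = "betweenness")
  else detect_cutoff(btw, "manual", config$betweenness_cutoff,
                     metric = "betweenness")
  cent <- centrality_table(extended_net, dc, bc, config$pair_convention)

  # ATC second-sublevel comparisons on annotated drugs only
  memb <- atc_memberships(records)
  ann <- function(ids) atc_annotated(records, ids)
  atc_illicit <- if (length(ann(partition$illicit)) &&
                     length(ann(partition$other)))
    enrich_drug_categories(ann(partition$illicit), ann(partition$other),
                           memb, config$alpha) else NULL
  atc_related <- if (length(ann(partition$illicit_related)) &&
                     length(ann(partition$other)))
    enrich_drug_categories(ann(partition$illicit_related),
                           ann(partition$other), memb, config$alpha) else NULL

  load_memb <- function(x) {
    if (is.null(x)) NULL
    else if (is.character(x)) read_membership_table(x)
    else x
  }
  gm <- load_memb(config$gene_memberships)
  pm <- load_memb(config$pathway_memberships)
  illicit_genes <- extended_net$genes
  other_genes <- setdiff(full_net$genes, illicit_genes)
  go_comparative <- if (!is.null(gm))
    enrich_gene_terms_comparative(illicit_genes, other_genes, gm,
                                  config$alpha) else NULL
  pathway_within <- if (!is.null(pm))
    enrich_pathways_within_set(illicit_genes, pm, full_net$genes,
                               config$alpha_adj) else NULL

  cand <- config$candidate_genes
  if (is.character(cand) && length(cand) == 1L && file.exists(cand))
    cand <- readLines(cand)
  overlap <- if (!is.null(cand))
    candidate_overlap_test(cand, illicit_genes, full_net$genes) else NULL

  # degree comparisons: illicit-network vs full-network, each side
  wil_drug <- compare_degree_distributions(
    node_degree(illicit_net)[illicit_net$drugs],
    node_degree(full_net)[full_net$drugs])
  wil_gene <- compare_degree_distributions(
    node_degree(illicit_net)[illicit_net$genes],
    node_degree(full_net)[full_net$genes])

  summary <- list(
    seed = config$seed,
    pair_convention = config$pair_convention,
    networks = list(illicit = mean_degrees(illicit_net),
                    extended = mean_degrees(extended_net),
                    full = mean_degrees(full_net)),
    partition = list(illicit = length(partition$illicit),
                     illicit_related = length(partition$illicit_related),
                     other = length(partition$other),
                     excluded_no_target = length(attr(partition, "excluded"))),
    atc_annotated = list(illicit = length(ann(partition$illicit)),
                         illicit_related = length(ann(partition$illicit_related)),
                         other = length(ann(partition$other))),
    cutoffs = list(degree = list(threshold = dc$threshold, method = dc$method),
                   betweenness = list(threshold = bc$threshold,
                                      method = bc$method)),
    hubs = list(n_total = sum(cent$is_hub),
                n_drugs = sum(cent$is_hub & cent$node_kind == "drug"),
                n_genes = sum(cent$is_hub & cent$node_kind == "gene")),
    bridges = list(n_total = sum(cent$is_bridge),
                   n_drugs = sum(cent$is_bridge & cent$node_kind == "drug"),
                   n_genes = sum(cent$is_bridge & cent$node_kind == "gene")),
    wilcoxon = list(drug_degree_p = wil_drug$p_value,
                    gene_degree_p = wil_gene$p_value),
    candidate_overlap_p = if (!is.null(overlap)) as.numeric(overlap) else NULL,
    extended_node_identity =
      length(extended_net$drugs) + length(extended_net$genes) ==
      sum(extended_net$drug_labels == "illicit") +
      sum(extended_net$drug_labels == "illicit-related") +
      length(extended_net$genes)
  )

  paths <- c(illicit_edges = file.path(config$out_dir, "illicit_edges.tsv"),
             extended_edges = file.path(config$out_dir, "extended_edges.tsv"),
             full_edges = file.path(config$out_dir, "full_edges.tsv"),
             graphml = file.path(config$out_dir, "extended.graphml"),
             centrality = file.path(config$out_dir, "centrality.tsv"),
             partition = file.path(config$out_dir, "partition.tsv"),
             summary = file.path(config$out_dir, "summary.json"))
  write_edge_list(illicit_net, paths[["illicit_edges"]], drug_names)
  write_edge_list(extended_net, paths[["extended_edges"]], drug_names)
  write_edge_list(full_net, paths[["full_edges"]], drug_names)
  export_graphml(extended_net, paths[["graphml"]], cent)
  utils::write.table(cent, paths[["centrality"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_partition(partition, paths[["partition"]])
  for (nm in c("atc_illicit", "atc_related", "go_comparative",
               "pathway_within")) {
    tab <- switch(nm, atc_illicit = atc_illicit, atc_related = atc_related,
                  go_comparative = go_comparative,
                  pathway_within = pathway_within)
    if (!is.null(tab)) {
      p <- file.path(config$out_dir, paste0(nm, ".tsv"))
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[nm] <- p
    }
  }
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(
    records = records, mapping = mapping, generated = gen,
    networks = list(illicit = illicit_net, extended = extended_net,
                    full = full_net),
    partition = partition, centrality = cent,
    cutoffs = list(degree = dc, betweenness = bc),
    enrichment = list(atc_illicit = atc_illicit, atc_related = atc_related,
                      go_comparative = go_comparative,
                      pathway_within = pathway_within),
    candidate_overlap = overlap,
    wilcoxon = list(drug = wil_drug, gene = wil_gene),
    summary = summary, paths = paths))
}

#' Format a count with its percentage, report-table style
#'
#' Renders "24 (48.0)": percentage of `count` in `total` at one decimal,
#' rounded half-up; a zero count renders as "0 (0)".
#'
#' @param count integer vector of counts.
#' @param total the set size the percentage refers to.
#' @return character vector.
#' @export
format_count_pct <- function(count, total) {
  ifelse(count == 0, "0 (0)",
         sprintf("%d (%s)", count,
                 formatC(round_half_up(100 * count / total, 1),
                         format = "f", digits = 1)))
}

format_p <- function(p) {
  ifelse(p >= 1e-3, formatC(p, format = "g", digits = 2),
         {
           e <- floor(log10(p))
           sprintf("%.1f × 10^%d", p / 10^e, e)
         })
}

#' Render an enrichment result as a publication-style table
#'
#' Columns: category id, label, "count (pct)" for each set, p-value (and
#' adjusted p where present), percent formatting at one decimal.
#'
#' @param result data frame from one of the enrichment functions.
#' @param n_a,n_b the two set sizes the percentages refer to.
#' @param set_names length-2 character vector of column header names.
#' @return data frame of formatted strings.
#' @export
report_table <- function(result, n_a, n_b,
                         set_names = c("set A", "set B")) {
  out <- data.frame(
    category = result$category_id,
    label = result$label,
    a = format_count_pct(result$count_a, n_a),
    b = format_count_pct(result$count_b, n_b),
    p = format_p(result$p),
    stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("n ", set_names, " (%)")
  if (!is.null(result$p_adj)) out$p_adj <- format_p(result$p_adj)
  out
}

#' Write a data frame as a Markdown pipe table
#'
#' @param tab data frame of display strings.
#' @param path output path, or NULL to return the lines.
#' @return the Markdown lines, invisibly when `path` is given.
#' @export
write_markdown_table <- function(tab, path = NULL) {
  cells <- vapply(tab, as.character, character(nrow(tab)))
  if (nrow(tab) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste0("| ", paste(names(tab), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
             apply(cells, 1L, function(r)
               paste0("| ", paste(r, collapse = " | "), " |")))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
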