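#' Bipartite drug-target network
#'
#' Constructor and validator for the `dtn` class: drug nodes, gene nodes,
#' simple undirected drug-gene edges, and a node set label recording which
#' analysis set each node belongs to ("illicit", "illicit-related", "other"
#' for drugs; "illicit-target", "other-target" for genes).
#'
#' @param drugs character vector of drug ids.
#' @param genes character vector of gene symbols.
#' @param edges data frame with columns `drug_id`, `gene_symbol`.
#' @param drug_labels,gene_labels named character vectors of set labels;
#'   unnamed defaults apply "other" / "other-target".
#' @return validated `dtn` object.
#' @export
dtn_network <- function(drugs, genes, edges,
                        drug_labels = NULL, gene_labels = NULL) {
  drugs <- unique(as.character(drugs))
  genes <- unique(as.character(genes))
  edges <- unique(data.frame(drug_id = as.character(edges$drug_id),
                             gene_symbol = as.character(edges$gene_symbol),
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  if (is.null(drug_labels)) drug_labels <- stats::setNames(rep("other", length(drugs)), drugs)
  if (is.null(gene_labels)) gene_labels <- stats::setNames(rep("other-target", length(genes)), genes)
  x <- structure(list(drugs = drugs, genes = genes, edges = edges,
                      drug_labels = drug_labels, gene_labels = gene_labels),
                 class = "dtn")
  validate_dtn(x)
}

#' @rdname dtn_network
#' @param x object to validate.
#' @export
validate_dtn <- function(x) {
  stopifnot(inherits(x, "dtn"))
  if (length(intersect(x$drugs, x$genes)))
    stop("drug and gene node sets overlap")
  if (nrow(x$edges)) {
    if (!all(x$edges$drug_id %in% x$drugs))
      stop("edge references unknown drug node")
    if (!all(x$edges$gene_symbol %in% x$genes))
      stop("edge references unknown gene node")
    key <- paste(x$edges$drug_id, x$edges$gene_symbol, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  if (!all(x$drugs %in% names(x$drug_labels)) ||
      !all(x$genes %in% names(x$gene_labels)))
    stop("every node needs a set label")
  x
}

#' @export
print.dtn <- function(x, ...) {
  cat("<dtn> bipartite drug-target network:",
      length(x$drugs), "drugs,", length(x$genes), "genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' Undirected simple graph whose vertices carry `kind` and `set_label`
#' attributes and the bipartite `type` flag (TRUE for genes).
#'
#' @param network a `dtn` object.
#' @return an igraph graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "dtn"))
  verts <- data.frame(
    name = c(network$drugs, network$genes),
    kind = rep(c("drug", "gene"),
               c(length(network$drugs), length(network$genes))),
    set_label = c(unname(network$drug_labels[network$drugs]),
                  unname(network$gene_labels[network$genes])),
    type = rep(c(FALSE, TRUE),
               c(length(network$drugs), length(network$genes))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    network$edges[c("drug_id", "gene_symbol")],
    directed = FALSE, vertices = verts)
}

#' Select drugs with illicit legal status
#'
#' A drug is illicit when its `groups` field contains the tag "illicit";
#' other statuses ("approved", "experimental", ...) may be held
#' simultaneously.
#'
#' @param records list of `drug_record`s.
#' @return character vector of drug ids.
#' @export
select_illicit <- function(records) {
  ids <- vapply(records, `[[`, "", "drug_id")
  keep <- vapply(records, function(r) "illicit" %in% tolower(r$groups), NA)
  ids[keep]
}

# drug -> mapped human gene pairs; attrition is kept auditable in attributes
mapped_pairs <- function(records, mapping) {
  stopifnot(inherits(mapping, "gene_mapping"))
  sym <- stats::setNames(mapping$gene_symbol, mapping$uniprot_acc)
  rows <- lapply(records, function(r) {
    t <- r$targets
    t <- t[tolower(t$species) == "humans", , drop = FALSE]
    if (!nrow(t)) return(NULL)
    gs <- sym[t$uniprot_acc]
    unmapped <- t$uniprot_acc[is.na(gs)]
    gs <- unique(gs[!is.na(gs)])
    list(drug_id = r$drug_id, genes = gs, unmapped = unmapped)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  pairs <- do.call(rbind, lapply(rows, function(x) {
    if (!length(x$genes)) return(NULL)
    data.frame(drug_id = x$drug_id, gene_symbol = x$genes,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(drug_id = character(), gene_symbol = character(),
                        stringsAsFactors = FALSE)
  attr(pairs, "unmapped_accessions") <-
    sort(unique(unlist(lapply(rows, `[[`, "unmapped"))))
  pairs
}

#' Build a bipartite drug-target network from records
#'
#' Drug nodes are the (optionally filtered) drugs with at least one mapped
#' human target; gene nodes are the symbols targeted by at least one included
#' drug. Two accessions mapping to one symbol give one gene node, and
#' multiple interactions between a drug and a gene collapse to a single
#' unweighted edge.
#'
#' @param records list of `drug_record`s.
#' @param mapping a `gene_mapping` from [load_gene_mapping()].
#' @param drug_filter optional character vector restricting the drug side.
#' @return a `dtn` network; attribute `unmapped_accessions` lists human
#'   target accessions absent from the mapping table (dropped, but reported).
#' @export
build_network <- function(records, mapping, drug_filter = NULL) {
  pairs <- mapped_pairs(records, mapping)
  if (!is.null(drug_filter))
    pairs <- pairs[pairs$drug_id %in% drug_filter, , drop = FALSE]
  if (!nrow(pairs)) warning("resulting network is empty")
  illicit <- select_illicit(records)
  drugs <- unique(pairs$drug_id)
  genes <- unique(pairs$gene_symbol)
  related <- find_illicit_related(records, mapping, illicit)
  dl <- stats::setNames(ifelse(drugs %in% illicit, "illicit",
                        ifelse(drugs %in% related, "illicit-related", "other")),
                        drugs)
  illicit_genes <- unique(pairs$gene_symbol[pairs$drug_id %in% illicit])
  gl <- stats::setNames(ifelse(genes %in% illicit_genes,
                               "illicit-target", "other-target"), genes)
  net <- dtn_network(drugs, genes, pairs, dl, gl)
  attr(net, "unmapped_accessions") <- attr(pairs, "unmapped_accessions")
  net
}

#' Find illicit-related drugs
#'
#' Non-illicit drugs sharing at least one mapped human target gene with at
#' least one illicit drug.
#'
#' @inheritParams build_network
#' @param illicit_ids drug ids of the illicit set.
#' @return character vector of drug ids (never containing an illicit drug).
#' @export
find_illicit_related <- function(records, mapping, illicit_ids) {
  pairs <- mapped_pairs(records, mapping)
  illicit_genes <- unique(pairs$gene_symbol[pairs$drug_id %in% illicit_ids])
  hit <- pairs$drug_id[pairs$gene_symbol %in% illicit_genes]
  setdiff(unique(hit), illicit_ids)
}

#' Build the illicit-extended network
#'
#' The illicit network plus all illicit-related drugs, with the related
#' drugs' edges restricted to genes already targeted by illicit drugs. The
#' gene side therefore stays the illicit target-gene set, and the illicit
#' network is an exact subgraph of the result.
#'
#' @inheritParams find_illicit_related
#' @return a `dtn` network.
#' @export
build_extended <- function(records, mapping, illicit_ids) {
  pairs <- mapped_pairs(records, mapping)
  illicit_genes <- unique(pairs$gene_symbol[pairs$drug_id %in% illicit_ids])
  related <- find_illicit_related(records, mapping, illicit_ids)
  keep <- (pairs$drug_id %in% c(illicit_ids, related)) &
          (pairs$gene_symbol %in% illicit_genes)
  sub <- pairs[keep, , drop = FALSE]
  drugs <- unique(sub$drug_id)
  dl <- stats::setNames(ifelse(drugs %in% illicit_ids, "illicit",
                               "illicit-related"), drugs)
  gl <- stats::setNames(rep("illicit-target", length(illicit_genes)),
                        illicit_genes)
  dtn_network(drugs, illicit_genes, sub, dl, gl)
}

#' Partition target-bearing drugs into illicit / illicit-related / other
#'
#' Drugs with no mapped human target belong to no set and are reported in
#' the `excluded` attribute.
#'
#' @inheritParams build_network
#' @return list with character vectors `illicit`, `illicit_related`, `other`
#'   (pairwise disjoint, jointly covering all target-bearing drugs) and
#'   attribute `excluded`.
#' @export
partition_drugs <- function(records, mapping) {
  pairs <- mapped_pairs(records, mapping)
  with_targets <- unique(pairs$drug_id)
  all_ids <- vapply(records, `[[`, "", "drug_id")
  illicit <- intersect(select_illicit(records), with_targets)
  related <- intersect(find_illicit_related(records, mapping, illicit),
                       with_targets)
  other <- setdiff(with_targets, c(illicit, related))
  out <- list(illicit = illicit, illicit_related = related, other = other)
  attr(out, "excluded") <- setdiff(all_ids, with_targets)
  class(out) <- "drug_partition"
  out
}

#' @export
print.drug_partition <- function(x, ...) {
  cat("<drug_partition> illicit:", length(x$illicit),
      " illicit-related:", length(x$illicit_related),
      " other:", length(x$other),
      " (excluded, no mapped target:", length(attr(x, "excluded")), ")\n")
  invisible(x)
}

#' Export a drug partition as a two-column table
#'
#' @param partition a `drug_partition`.
#' @param path output TSV path (`drug_id`, `set_label`).
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "drug_partition"))
  tab <- data.frame(
    drug_id = c(partition$illicit, partition$illicit_related, partition$other),
    set_label = rep(c("illicit", "illicit-related", "other"),
                    c(length(partition$illicit),
                      length(partition$illicit_related),
                      length(partition$other))),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$drug_id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
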