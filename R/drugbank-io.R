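ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Parse DrugBank-dialect XML into drug records
#'
#' Reads a minimal DrugBank-style XML document (`<drugbank><drug>...`) and
#' returns one record per `<drug>` element, in file order. Only the six
#' fields the downstream analyses use are read: accession, name, legal-status
#' groups, categories, ATC codes and protein targets. Group strings are
#' lower-cased on ingest so that legal-status membership tests are
#' case-insensitive. Target accessions are deduplicated per drug.
#'
#' @param xml_source path, URL, literal XML string or connection accepted by
#'   [xml2::read_xml()].
#' @return A list of `drug_record` objects, each with elements `drug_id`,
#'   `name`, `groups`, `categories`, `atc_codes` and `targets` (a data frame
#'   with columns `uniprot_acc`, `species`).
#' @export
parse_drugbank <- function(xml_source) {
  doc <- xml2::read_xml(xml_source)
  drugs <- xml2::xml_find_all(doc, "./drug")
  records <- lapply(drugs, function(d) {
    id <- xml2::xml_text(xml2::xml_find_first(d, "./drugbank-id"))
    if (is.na(id) || !nzchar(id))
      stop("drug element without a <drugbank-id>")
    name <- xml2::xml_text(xml2::xml_find_first(d, "./name"))
    groups <- tolower(xml2::xml_text(xml2::xml_find_all(d, "./groups/group")))
    categories <- xml2::xml_text(xml2::xml_find_all(d, "./categories/category"))
    atc <- xml2::xml_attr(xml2::xml_find_all(d, "./atc-codes/atc-code"), "code")
    atc <- atc[!is.na(atc)]
    bad <- atc[!grepl(ATC_PATTERN, atc)]
    if (length(bad))
      stop("drug ", id, ": malformed ATC code(s): ", paste(bad, collapse = ", "))
    polys <- xml2::xml_find_all(d, "./targets/target/polypeptide")
    targets <- data.frame(
      uniprot_acc = xml2::xml_attr(polys, "uniprot-id"),
      species = xml2::xml_attr(polys, "species"),
      stringsAsFactors = FALSE
    )
    targets <- targets[nzchar(targets$uniprot_acc) & !is.na(targets$uniprot_acc), ,
                       drop = FALSE]
    targets <- unique(targets)
    rownames(targets) <- NULL
    structure(
      list(drug_id = id,
           name = if (is.na(name)) "" else name,
           groups = unique(groups),
           categories = unique(categories),
           atc_codes = atc,
           targets = targets),
      class = "drug_record"
    )
  })
  ids <- vapply(records, `[[`, "", "drug_id")
  if (anyDuplicated(ids))
    stop("duplicate drug ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records
}

#' @export
print.drug_record <- function(x, ...) {
  cat("<drug_record>", x$drug_id, x$name, "\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat("  atc:", paste(x$atc_codes, collapse = ", "),
      " targets:", nrow(x$targets), "\n")
  invisible(x)
}

#' Serialize drug records back to the XML dialect
#'
#' Inverse of [parse_drugbank()]; a parse/write round trip is lossless for
#' the dialect fields.
#'
#' @param records list of `drug_record` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drugbank <- function(records, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub("\"", "&quot;", s, fixed = TRUE)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<drugbank>")
  for (r in records) {
    lines <- c(lines, "  <drug>",
               paste0("    <drugbank-id>", esc(r$drug_id), "</drugbank-id>"),
               paste0("    <name>", esc(r$name), "</name>"))
    lines <- c(lines, "    <groups>",
               paste0("      <group>", esc(r$groups), "</group>"),
               "    </groups>")
    if (length(r$categories))
      lines <- c(lines, "    <categories>",
                 paste0("      <category>", esc(r$categories), "</category>"),
                 "    </categories>")
    if (length(r$atc_codes))
      lines <- c(lines, "    <atc-codes>",
                 paste0("      <atc-code code=\"", esc(r$atc_codes), "\"/>"),
                 "    </atc-codes>")
    if (nrow(r$targets))
      lines <- c(lines, "    <targets>",
                 paste0("      <target><polypeptide uniprot-id=\"",
                        esc(r$targets$uniprot_acc), "\" species=\"",
                        esc(r$targets$species), "\"/></target>"),
                 "    </targets>")
    lines <- c(lines, "  </drug>")
  }
  lines <- c(lines, "</drugbank>")
  writeLines(lines, path)
  invisible(path)
}

#' Load a UniProt accession to gene mapping table
#'
#' Reads a TSV with header `uniprot_acc`, `gene_symbol`, `entrez_id` into a
#' mapping used to translate protein targets to gene nodes. The mapping must
#' be functional: the same accession listed twice with conflicting symbols is
#' a validation error; identical duplicate rows collapse to one entry.
#'
#' @param tsv_source path or connection.
#' @return data frame with one row per accession and class `gene_mapping`.
#' @export
load_gene_mapping <- function(tsv_source) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("uniprot_acc", "gene_symbol", "entrez_id")
  if (!all(need %in% names(tab)))
    stop("mapping table must have columns: ", paste(need, collapse = ", "))
  tab <- unique(tab[need])
  if (anyDuplicated(tab$uniprot_acc)) {
    dup <- unique(tab$uniprot_acc[duplicated(tab$uniprot_acc)])
    stop("conflicting gene symbols for accession(s): ",
         paste(dup, collapse = ", "))
  }
  if (nrow(tab) == 0L)
    warning("empty gene mapping table")
  tab$entrez_id <- as.integer(tab$entrez_id)
  rownames(tab) <- NULL
  class(tab) <- c("gene_mapping", "data.frame")
  tab
}

#' Read a drug-gene edge list
#'
#' Reads the tab-separated edge-list format (`drug_id`, `drug_name`,
#' `gene_symbol`, header row) used for the published interaction-pair files.
#'
#' @param tsv_source path or connection.
#' @param dedup drop duplicated (drug_id, gene_symbol) pairs; without the
#'   flag a duplicated pair is an error.
#' @return data frame of pairs in file order.
#' @export
read_edge_list <- function(tsv_source, dedup = FALSE) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("drug_id", "gene_symbol") %in% names(tab)))
    stop("edge list needs columns drug_id and gene_symbol")
  if (!"drug_name" %in% names(tab)) tab$drug_name <- tab$drug_id
  bad <- which(!nzchar(tab$drug_id) | !nzchar(tab$gene_symbol) |
               is.na(tab$drug_id) | is.na(tab$gene_symbol))
  if (length(bad))
    stop("missing column value in edge-list row(s): ",
         paste(bad, collapse = ", "))
  key <- paste(tab$drug_id, tab$gene_symbol, sep = "\r")
  if (anyDuplicated(key)) {
    if (!dedup)
      stop("duplicated pair(s) in edge list (set dedup = TRUE to collapse): row ",
           paste(which(duplicated(key)), collapse = ", "))
    tab <- tab[!duplicated(key), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[c("drug_id", "drug_name", "gene_symbol")]
}

#' Write a network's edges as a drug-gene edge list
#'
#' @param network a `dtn` bipartite network.
#' @param path output TSV path.
#' @param drug_names optional named character vector drug_id -> display name.
#' @return `path`, invisibly. Writing then reading reproduces the edge set
#'   exactly.
#' @export
write_edge_list <- function(network, path, drug_names = NULL) {
  stopifnot(inherits(network, "dtn"))
  e <- network$edges
  nm <- if (is.null(drug_names)) e$drug_id else unname(drug_names[e$drug_id])
  nm[is.na(nm)] <- e$drug_id[is.na(nm)]
  out <- data.frame(drug_id = e$drug_id, drug_name = nm,
                    gene_symbol = e$gene_symbol, stringsAsFactors = FALSE)
  out <- out[order(out$drug_id, out$gene_symbol), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' One line per edge: `drug targets gene`, the relation literal understood by
#' generic network viewers.
#'
#' @inheritParams write_edge_list
#' @export
export_sif <- function(network, path) {
  stopifnot(inherits(network, "dtn"))
  e <- network$edges[order(network$edges$drug_id, network$edges$gene_symbol), ]
  writeLines(paste(e$drug_id, "targets", e$gene_symbol, sep = "\t"), path)
  invisible(path)
}

#' Export a network in GraphML with node attributes
#'
#' Writes the bipartite network through igraph's GraphML writer. Node
#' attributes carried: `kind` (drug/gene), `set_label` (illicit /
#' illicit-related / other and the gene-side analogues), and, when a
#' centrality table is supplied, `degree`, `betweenness`, `is_hub`,
#' `is_bridge`.
#'
#' @param network a `dtn` network.
#' @param path output path.
#' @param centrality optional data frame from [centrality_table()]; its
#'   `node_id` values must all be nodes of the network.
#' @export
export_graphml <- function(network, path, centrality = NULL) {
  g <- as_igraph(network)
  if (!is.null(centrality)) {
    unknown <- setdiff(centrality$node_id, igraph::V(g)$name)
    if (length(unknown))
      stop("centrality table references unknown node(s): ",
           paste(unknown, collapse = ", "))
    idx <- match(igraph::V(g)$name, centrality$node_id)
    igraph::V(g)$degree <- as.integer(centrality$degree[idx])
    igraph::V(g)$betweenness <- as.numeric(centrality$betweenness[idx])
    igraph::V(g)$is_hub <- as.logical(centrality$is_hub[idx])
    igraph::V(g)$is_bridge <- as.logical(centrality$is_bridge[idx])
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
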