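#' ATC second sublevel of a full ATC code
#'
#' The therapeutic-subgroup tier: first letter (anatomical main group) plus
#' the two-digit subgroup, e.g. "N05BA01" -> "N05" (psycholeptics).
#'
#' @param code character vector of 7-character ATC codes.
#' @return character vector of 3-character category ids.
#' @export
atc_second_level <- function(code) {
  bad <- code[!grepl(ATC_PATTERN, code)]
  if (length(bad))
    stop("malformed ATC code(s): ", paste(bad, collapse = ", "))
  substr(code, 1L, 3L)
}

#' ATC second-sublevel memberships of a drug collection
#'
#' Long-format membership table: one row per (category, drug), a drug
#' contributing at most once per category regardless of how many of its ATC
#' codes map there.
#'
#' @param records list of `drug_record`s.
#' @return data frame with columns `category_id`, `label`, `member_id`.
#' @export
atc_memberships <- function(records) {
  rows <- lapply(records, function(r) {
    if (!length(r$atc_codes)) return(NULL)
    data.frame(category_id = unique(atc_second_level(r$atc_codes)),
               member_id = r$drug_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category_id = character(), member_id = character(),
                      stringsAsFactors = FALSE)
  out$label <- out$category_id
  out[c("category_id", "label", "member_id")]
}

#' Drugs carrying at least one ATC classification
#'
#' The category comparisons only count ATC-annotated drugs; this helper
#' applies that restriction to a drug set.
#'
#' @param records list of `drug_record`s.
#' @param ids drug ids to filter.
#' @return the subset of `ids` whose record has >= 1 ATC code.
#' @export
atc_annotated <- function(records, ids) {
  all_ids <- vapply(records, `[[`, "", "drug_id")
  has <- vapply(records, function(r) length(r$atc_codes) > 0L, NA)
  intersect(ids, all_ids[has])
}

#' Read a long-format category membership table
#'
#' TSV with header `category_id`, `label`, `member_id` (GO Slim terms, KEGG
#' pathways or ATC categories against gene symbols or drug ids).
#'
#' @param tsv_source path or connection.
#' @return membership data frame.
#' @export
read_membership_table <- function(tsv_source) {
  tab <- utils::read.delim(tsv_source, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("category_id", "label", "member_id")
  if (!all(need %in% names(tab)))
    stop("membership table must have columns: ", paste(need, collapse = ", "))
  unique(tab[need])
}

#' Contingency table for one category comparison
#'
#' Counts of set-A and set-B members inside and outside a category; the
#' table feeding [fisher_exact_two_sided()].
#'
#' @param set_a,set_b disjoint character vectors of entity ids.
#' @param members character vector: the category's member ids.
#' @return a `contingency_2x2`.
#' @export
category_table <- function(set_a, set_b, members) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(intersect(set_a, set_b)))
    stop("set_a and set_b must be disjoint")
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both comparison sets must be non-empty")
  a <- sum(set_a %in% members)
  b <- sum(set_b %in% members)
  contingency_2x2(a, b, length(set_a) - a, length(set_b) - b)
}

#' @rdname category_table
#' @export
drug_category_table <- category_table

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

comparative_enrichment <- function(set_a, set_b, memberships, alpha) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  cats <- split(memberships$member_id, memberships$category_id)
  labels <- memberships$label[!duplicated(memberships$category_id)]
  names(labels) <- memberships$category_id[!duplicated(memberships$category_id)]
  rows <- lapply(names(cats), function(cid) {
    mem <- cats[[cid]]
    if (!any(c(set_a, set_b) %in% mem)) return(NULL)
    tab <- category_table(set_a, set_b, mem)
    data.frame(
      category_id = cid,
      label = unname(labels[cid]),
      count_a = tab$n_in_a,
      pct_a = round_half_up(100 * tab$n_in_a / length(set_a), 1),
      count_b = tab$n_in_b,
      pct_b = round_half_up(100 * tab$n_in_b / length(set_b), 1),
      p = fisher_exact_two_sided(tab),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category_id = character(), label = character(),
                      count_a = integer(), pct_a = numeric(),
                      count_b = integer(), pct_b = numeric(),
                      p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ATC category over-representation of one drug set against another
#'
#' One two-sided Fisher test per category with at least one member in
#' either set; results sorted by ascending p, flagged significant at
#' `p < alpha`. Only ATC-annotated drugs should be passed (see
#' [atc_annotated()]).
#'
#' @param set_a,set_b disjoint drug-id sets (e.g. illicit vs other).
#' @param memberships long-format membership table
#'   (`category_id`, `label`, `member_id`).
#' @param alpha significance level on the raw p-value.
#' @return data frame of enrichment results.
#' @export
enrich_drug_categories <- function(set_a, set_b, memberships, alpha = 0.05) {
  comparative_enrichment(set_a, set_b, memberships, alpha)
}

#' Comparative term enrichment of two gene sets
#'
#' The comparative Fisher design used for GO Slim terms and for the second
#' stage of the pathway analysis: for each term, set-A genes in/out of the
#' term against set-B genes in/out of it.
#'
#' @param genes_a,genes_b disjoint gene universes (e.g. illicit vs
#'   non-illicit target genes).
#' @inheritParams enrich_drug_categories
#' @return data frame of enrichment results.
#' @export
enrich_gene_terms_comparative <- function(genes_a, genes_b, memberships,
                                          alpha = 0.05) {
  comparative_enrichment(genes_a, genes_b, memberships, alpha)
}

#' Within-set pathway enrichment (hypergeometric + Benjamini-Hochberg)
#'
#' First stage of the two-stage pathway analysis: for each pathway, the
#' upper-tail hypergeometric probability of the observed overlap between the
#' gene set and the pathway, drawn from a stated gene universe; then BH
#' adjustment across the tested pathways.
#'
#' @param genes gene set of interest (must lie inside `universe`).
#' @param memberships long-format pathway membership table.
#' @param universe character vector: the gene universe. Memberships outside
#'   it are ignored.
#' @param alpha_adj significance level on the adjusted p-value.
#' @return data frame: category_id, label, overlap, pathway_size, p, p_adj,
#'   significant; sorted by ascending p_adj.
#' @export
enrich_pathways_within_set <- function(genes, memberships, universe,
                                       alpha_adj = 0.05) {
  genes <- unique(genes); universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  if (!all(genes %in% universe))
    stop("gene set must be a subset of the universe")
  cats <- split(memberships$member_id, memberships$category_id)
  labels <- memberships$label[!duplicated(memberships$category_id)]
  names(labels) <- memberships$category_id[!duplicated(memberships$category_id)]
  rows <- lapply(names(cats), function(cid) {
    mem <- intersect(unique(cats[[cid]]), universe)
    if (!length(mem)) return(NULL)
    k <- length(intersect(genes, mem))
    data.frame(category_id = cid, label = unname(labels[cid]),
               overlap = k, pathway_size = length(mem),
               p = hypergeom_sf(length(universe), length(mem),
                                length(genes), k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category_id = character(), label = character(),
                      overlap = integer(), pathway_size = integer(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out$p_adj <- benjamini_hochberg(out$p)
  out$significant <- out$p_adj < alpha_adj
  out <- out[order(out$p_adj, out$p, out$category_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate gene-set overlap test
#'
#' Upper-tail hypergeometric test of whether an externally curated candidate
#' gene list overlaps a network's gene set more than chance, given a gene
#' universe: population = |universe|, successes = |candidates in universe|,
#' draws = |network genes|, observed = |candidates in network genes|.
#'
#' @param candidate_genes external candidate list (symbols).
#' @param network_genes gene set of the network under test (subset of
#'   `universe_genes`).
#' @param universe_genes the reference gene universe.
#' @return p-value with attribute `query` (the four counts).
#' @export
candidate_overlap_test <- function(candidate_genes, network_genes,
                                   universe_genes) {
  universe_genes <- unique(universe_genes)
  if (length(universe_genes) == 0L) stop("empty gene universe")
  network_genes <- unique(network_genes)
  if (!all(network_genes %in% universe_genes))
    stop("network genes must lie inside the universe")
  cand <- intersect(unique(candidate_genes), universe_genes)
  k <- length(intersect(cand, network_genes))
  p <- hypergeom_sf(length(universe_genes), length(cand),
                    length(network_genes), k)
  attr(p, "query") <- c(population = length(universe_genes),
                        successes = length(cand),
                        draws = length(network_genes), observed = k)
  p
}
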