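#' GO term over-representation by the hypergeometric test
#'
#' Classic per-term one-sided test: for each GO term, the upper-tail
#' hypergeometric probability of drawing at least the observed number of
#' term members when sampling the study set from the universe. The
#' universe is the focal set of the cross (genes that passed the two-step
#' filter), not the whole transcriptome. Terms with fewer than `min_size`
#' universe genes are skipped. If ontology edges (child, parent) are
#' supplied, annotations are first propagated to all ancestors.
#'
#' @param study Character vector of study genes (e.g. SSD transcripts);
#'   must be a subset of `universe`.
#' @param universe Character vector of background genes.
#' @param go_map Data frame with columns `gene_id`, `go_id` (duplicates
#'   are removed).
#' @param min_size Minimum term size in the universe.
#' @param edges Optional data frame (`child`, `parent`) of ontology edges
#'   for ancestor propagation.
#' @return Data frame with columns `go_id`, `term_size`, `count`,
#'   `expected`, `p`, `q`, ordered by `p`.
#' @export
go_overrepresentation <- function(study, universe, go_map, min_size = 5L,
                                  edges = NULL) {
  study <- unique(study)
  universe <- unique(universe)
  if (!all(study %in% universe))
    stop("study set must be a subset of the universe")
  go_map <- unique(go_map[go_map$gene_id %in% universe,
                          c("gene_id", "go_id")])
  if (nrow(go_map) == 0L)
    stop("GO map covers no universe gene")
  if (!is.null(edges))
    go_map <- propagate_go(go_map, edges)
  term_genes <- split(go_map$gene_id, go_map$go_id)
  n_universe <- length(universe)
  n_study <- length(study)
  rows <- lapply(names(term_genes), function(term) {
    members <- term_genes[[term]]
    size <- length(members)
    if (size < min_size) return(NULL)
    k <- sum(study %in% members)
    data.frame(go_id = term, term_size = size, count = k,
               expected = n_study * size / n_universe,
               p = stats::phyper(k - 1L, size, n_universe - size,
                                 n_study, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(go_id = character(0), term_size = integer(0),
                      count = integer(0), expected = numeric(0),
                      p = numeric(0), q = numeric(0)))
  out$q <- storey_qvalue(out$p)
  out[order(out$p, out$go_id), , drop = FALSE]
}

#' Propagate GO annotations to ancestor terms
#' @noRd
propagate_go <- function(go_map, edges) {
  parent_of <- split(edges$parent, edges$child)
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    direct <- parent_of[[term]]
    res <- if (is.null(direct)) character(0) else
      unique(c(direct, unlist(lapply(direct, ancestors))))
    anc_cache[[term]] <- res
    res
  }
  extra <- lapply(seq_len(nrow(go_map)), function(i) {
    anc <- ancestors(go_map$go_id[i])
    if (length(anc) == 0L) return(NULL)
    data.frame(gene_id = go_map$gene_id[i], go_id = anc,
               stringsAsFactors = FALSE)
  })
  unique(rbind(go_map, do.call(rbind, extra)))
}

#' Overlap between two sets of significant terms
#'
#' @param set_a,set_b Character vectors of term ids (or enrichment tables
#'   with a `go_id` column).
#' @return List with `jaccard`, `shared`, `n_a`, `n_b`.
#' @export
compare_term_sets <- function(set_a, set_b) {
  if (is.data.frame(set_a)) set_a <- set_a$go_id
  if (is.data.frame(set_b)) set_b <- set_b$go_id
  set_a <- unique(set_a); set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  un <- union(set_a, set_b)
  jac <- if (length(un) == 0L) NA_real_ else length(shared) / length(un)
  list(jaccard = jac, shared = shared,
       n_a = length(set_a), n_b = length(set_b))
}
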