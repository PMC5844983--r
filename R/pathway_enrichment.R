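#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway, tests whether the selected panel hits more of its
#' members than expected by chance: with `N` metabolites in the universe,
#' `K` of them in the pathway, and a panel of size `n` containing `k`
#' pathway members, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`
#' (exact upper tail). BH-FDR across pathways is appended.
#'
#' @param panel Character set of panel metabolite ids (must lie in
#'   `universe`).
#' @param universe Character set of all candidate metabolite ids (e.g. all
#'   annotated features surviving preprocessing).
#' @param db A `pathway_db` from [read_pathways()]; memberships are
#'   intersected with the universe.
#' @return Tibble (`pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`, `p`,
#'   `p_fdr`).
#' @export
hypergeometric_enrichment <- function(panel, universe, db) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  stray <- setdiff(panel, universe)
  if (length(stray) > 0) {
    stop("panel id not in universe: ", stray[1], call. = FALSE)
  }
  panel <- unique(panel)
  N <- length(universe)
  n <- length(panel)
  rows <- purrr::map(names(db), function(pid) {
    members <- intersect(db[[pid]]$members, universe)
    K <- length(members)
    k <- length(intersect(members, panel))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(pathway_id = pid, pathway_name = db[[pid]]$name,
                   k = k, K = K, n = n, N = N, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- bh_fdr(out$p)
  out
}

#' Topology-based pathway impact of a panel
#'
#' `impact = sum of betweenness centrality over hit nodes / sum over all
#' nodes` of the pathway's undirected member graph (relative-betweenness
#' impact; the normalization constant cancels). Betweenness is exact
#' shortest-path (Brandes) betweenness via igraph. Edgeless pathways or
#' all-zero centralities give impact 0 with a warning.
#'
#' @param panel Character set of metabolite ids.
#' @param pathway One entry of a `pathway_db` (list with `members`,
#'   `edges`).
#' @return Impact in \[0, 1\].
#' @export
pathway_impact <- function(panel, pathway) {
  members <- pathway$members
  if (length(members) == 0) stop("pathway has no members", call. = FALSE)
  hits <- intersect(panel, members)
  if (length(hits) == length(members)) return(1)
  if (nrow(pathway$edges) == 0) {
    warning("pathway has no edges; impact undefined, returning 0")
    return(0)
  }
  g <- igraph::graph_from_edgelist(pathway$edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(members, igraph::V(g)$name)),
                            name = setdiff(members, igraph::V(g)$name))
  bc <- igraph::betweenness(g, directed = FALSE)
  total <- sum(bc)
  if (total == 0) {
    warning("all betweenness centralities are zero; impact 0")
    return(0)
  }
  sum(bc[hits]) / total
}

#' Enrichment report over all pathways
#'
#' Combines [hypergeometric_enrichment()] and [pathway_impact()] into a
#' results table sorted by p-value, flagging pathways with FDR <= 0.05.
#'
#' @inheritParams hypergeometric_enrichment
#' @return Tibble (`pathway_id`, `pathway_name`, `k`, `K`, `p`, `p_fdr`,
#'   `impact`, `significant`), sorted by `p`.
#' @export
enrichment_report <- function(panel, universe, db) {
  if (length(db) == 0) {
    return(tibble::tibble(pathway_id = character(0),
                          pathway_name = character(0), k = integer(0),
                          K = integer(0), p = numeric(0), p_fdr = numeric(0),
                          impact = numeric(0), significant = logical(0)))
  }
  enr <- hypergeometric_enrichment(panel, universe, db)
  enr$impact <- vapply(names(db), function(pid) {
    suppressWarnings(pathway_impact(intersect(panel, universe), db[[pid]]))
  }, numeric(1))[enr$pathway_id]
  enr$significant <- enr$p_fdr <= 0.05
  dplyr::arrange(dplyr::select(enr, -"n", -"N"), .data$p)
}
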