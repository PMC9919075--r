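#' Intersect drug-candidate and disease target sets
#'
#' Identifiers are normalized (whitespace trimmed, upper-cased) before the
#' exact set intersection; Venn counts (drug-only, disease-only, shared) are
#' reported.
#'
#' @param drug character vector of predicted compound targets.
#' @param disease character vector of disease-associated targets.
#' @return object of class `target_sets`: list with `drug`, `disease`,
#'   `intersection` (all normalized, deduplicated) and `venn` counts.
#' @export
intersect_targets <- function(drug, disease) {
  norm <- function(x) unique(toupper(trimws(as.character(x))))
  drug <- norm(drug); disease <- norm(disease)
  if (length(drug) == 0 || length(disease) == 0) {
    warning("empty input target set: intersection is empty", call. = FALSE)
  }
  both <- sort(intersect(drug, disease))
  structure(
    list(drug = sort(drug), disease = sort(disease), intersection = both,
         venn = c(drug_only = length(setdiff(drug, disease)),
                  disease_only = length(setdiff(disease, drug)),
                  both = length(both))),
    class = "target_sets"
  )
}

as_interaction_graph <- function(edges, nodes = NULL) {
  if (igraph::is_igraph(edges)) return(edges)
  em <- as.matrix(edges[, 1:2])
  mode(em) <- "character"
  if (any(em[, 1] == em[, 2])) {
    stop("self-loops are not allowed in an interaction graph", call. = FALSE)
  }
  canon <- t(apply(em, 1, sort))
  if (anyDuplicated(canon)) {
    warning("duplicate edges dropped", call. = FALSE)
    em <- em[!duplicated(canon), , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  if (!is.null(nodes)) {
    extra <- setdiff(nodes, igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra),
                                                 name = extra)
  }
  g
}

#' Size, degree map and average degree of an interaction graph
#'
#' @param edges two-column edge list (data frame or matrix of node ids), or
#'   an igraph object. Self-loops are an error; duplicate undirected edges
#'   are dropped with a warning.
#' @param nodes optional node universe including isolated nodes.
#' @return list with `n_nodes`, `n_edges`, `degree` (named), and
#'   `average_degree` = 2E/N (also `average_degree_rounded`, one decimal).
#' @export
graph_stats <- function(edges, nodes = NULL) {
  g <- as_interaction_graph(edges, nodes)
  n <- igraph::vcount(g)
  if (n == 0) stop("graph has no nodes", call. = FALSE)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  avg <- 2 * e / n
  list(n_nodes = n, n_edges = e, degree = deg,
       average_degree = avg, average_degree_rounded = round(avg, 1))
}

#' Top-k nodes by degree
#'
#' @inheritParams graph_stats
#' @param k number of nodes to return; ties at the cut are broken
#'   lexicographically by node name. `k > N` returns all nodes with a
#'   warning.
#' @return character vector of node names, highest degree first.
#' @export
top_degree <- function(edges, k, nodes = NULL) {
  stopifnot(k >= 1)
  st <- graph_stats(edges, nodes)
  if (k > st$n_nodes) {
    warning(sprintf("k = %d exceeds node count %d; returning all nodes",
                    k, st$n_nodes), call. = FALSE)
    k <- st$n_nodes
  }
  deg <- st$degree
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(k)]
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term with `K` members in a universe of size `N`, the probability
#' of observing at least the actual overlap `k` with a study set of size `n`
#' under uniform sampling: the upper hypergeometric tail
#' `P(X >= k)`. P-values are Benjamini-Hochberg adjusted over all tested
#' terms and the records sorted by ascending p.
#'
#' The conventional significance reading keeps `p_adj < alpha`; raw-p
#' filtering and the reversed inequality are selectable for auditing
#' nonstandard filter conditions.
#'
#' @param study character vector, the study set (must lie in the universe).
#' @param terms named list of term member vectors (each within the
#'   universe).
#' @param universe character vector of all identifiers.
#' @param alpha significance level (default 0.05).
#' @param filter_on `"p_adj"` (default) or `"p"`.
#' @param filter_direction `"less"` keeps values below alpha (default);
#'   `"greater"` reverses the inequality.
#' @return data frame (all terms, sorted by p) with columns `term`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`, `significant`.
#' @export
hypergeom_enrich <- function(study, terms, universe, alpha = 0.05,
                             filter_on = c("p_adj", "p"),
                             filter_direction = c("less", "greater")) {
  filter_on <- match.arg(filter_on)
  filter_direction <- match.arg(filter_direction)
  universe <- unique(universe)
  study <- unique(study)
  off <- setdiff(study, universe)
  if (length(off)) {
    stop(sprintf("study identifiers outside the universe: %s",
                 paste(utils::head(off, 5), collapse = ", ")), call. = FALSE)
  }
  for (nm in names(terms)) {
    if (length(setdiff(terms[[nm]], universe))) {
      stop(sprintf("term '%s' has members outside the universe", nm),
           call. = FALSE)
    }
  }
  N <- length(universe); n <- length(study)
  rec <- lapply(names(terms), function(nm) {
    members <- unique(terms[[nm]])
    K <- length(members)
    k <- length(intersect(members, study))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p = p)
  })
  out <- do.call(rbind, rec)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  crit <- if (filter_on == "p_adj") out$p_adj else out$p
  out$significant <- if (filter_direction == "less") crit < alpha
                     else crit > alpha
  rownames(out) <- NULL
  out
}

#' Assemble a component-target-pathway-disease network
#'
#' Builds the tetrapartite edge list linking one component to its
#' high-degree targets, the top enriched pathways, and disease labels:
#' targets with PPI degree strictly above the average degree are kept;
#' pathways are the `top_pathways` smallest-p enrichment records; edges are
#' component-target, target-pathway (annotation membership) and
#' pathway-disease (supplied map). A selected target with no pathway
#' annotation is kept as a node with a warning.
#'
#' @param component component (compound) identifier.
#' @param targets character vector of candidate target identifiers.
#' @param pathway_annotations named list: pathway id -> member targets.
#' @param enrichment enrichment table from [hypergeom_enrich()] whose terms
#'   are the pathways.
#' @param degree_map named degree vector for the targets (from
#'   [graph_stats()]).
#' @param disease_map named list: pathway id -> disease label(s).
#' @param top_pathways number of pathways retained by ascending p
#'   (default 20).
#' @return list with `nodes` (data frame `id`, `type`) and `edges` (data
#'   frame `from`, `to`, `type`).
#' @export
build_ctpd_network <- function(component, targets, pathway_annotations,
                               enrichment, degree_map, disease_map = list(),
                               top_pathways = 20) {
  stopifnot(length(component) == 1, is.data.frame(enrichment))
  avg <- mean(degree_map)
  sel_targets <- intersect(targets, names(degree_map)[degree_map > avg])
  paths <- utils::head(enrichment$term[order(enrichment$p)], top_pathways)

  edges <- data.frame(from = character(), to = character(),
                      type = character())
  add <- function(e, from, to, type) {
    if (length(from) == 0 || length(to) == 0) return(e)
    rbind(e, data.frame(from = from, to = to, type = type))
  }
  edges <- add(edges, rep(component, length(sel_targets)), sel_targets,
               "component-target")
  unannotated <- character()
  for (tg in sel_targets) {
    hit <- paths[vapply(paths, function(pw) {
      tg %in% pathway_annotations[[pw]]
    }, logical(1))]
    if (length(hit) == 0) {
      unannotated <- c(unannotated, tg)
    } else {
      edges <- add(edges, rep(tg, length(hit)), hit, "target-pathway")
    }
  }
  if (length(unannotated)) {
    warning(sprintf("no retained pathway annotates target(s): %s",
                    paste(unannotated, collapse = ", ")), call. = FALSE)
  }
  diseases <- character()
  for (pw in paths) {
    ds <- disease_map[[pw]]
    if (!is.null(ds) && length(ds)) {
      edges <- add(edges, rep(pw, length(ds)), ds, "pathway-disease")
      diseases <- union(diseases, ds)
    }
  }
  nodes <- rbind(
    data.frame(id = component, type = "component"),
    if (length(sel_targets)) data.frame(id = sel_targets, type = "target"),
    if (length(paths)) data.frame(id = paths, type = "pathway"),
    if (length(diseases)) data.frame(id = diseases, type = "disease")
  )
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
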