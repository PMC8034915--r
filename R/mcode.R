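# Density of a simple undirected graph: |E| / (|V| choose 2); 0 for < 2 nodes.
.graphDensity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  igraph::ecount(g) / (n * (n - 1) / 2)
}

# Highest k-core of a graph: the subgraph induced by vertices of maximal
# coreness. Returns list(k, graph).
.highestKCore <- function(g) {
  if (!igraph::vcount(g)) return(list(k = 0L, graph = g))
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, graph = igraph::induced_subgraph(g, which(core == k)))
}

#' MCODE vertex weighting
#'
#' Core-clustering weight of every vertex: for each node `v`, take the
#' closed neighbourhood `N[v]`, find the highest k-core of the induced
#' subgraph, and set `weight(v) = k * density(highest k-core)` — the core
#' number times the core-clustering coefficient. Isolated nodes weigh 0;
#' every node of a clique of size `c` weighs `c - 1`.
#'
#' @param x an igraph graph, a [CeRNANetwork-class], or a two-column edge
#'   data.frame (undirected, simple).
#' @return named numeric vector of vertex weights.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' mcodeWeight(g) # all 4 x 1.0 = 4
#' @export
mcodeWeight <- function(x) {
  g <- .asUndirectedGraph(x)
  g <- igraph::simplify(g)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    nm <- as.character(seq_len(n))
    igraph::V(g)$name <- nm
  }
  w <- vapply(seq_len(n), function(i) {
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, unique(nb))
    if (igraph::ecount(sub) == 0) return(0)
    hc <- .highestKCore(sub)
    hc$k * .graphDensity(hc$graph)
  }, numeric(1))
  names(w) <- nm
  w
}

#' MCODE seed-expansion module detection
#'
#' Greedy molecular-complex detection: vertices are weighted with
#' [mcodeWeight()]; unvisited vertices are taken as seeds in descending
#' weight order (ties broken by lexicographic node id); from each seed a
#' breadth-first expansion includes a neighbouring vertex when its weight is
#' at least `seed_weight * (1 - node_score_cutoff)`, up to `max_depth` steps
#' from the seed. Expanded vertices are marked visited and belong to at most
#' one module. Post-processing with both options enabled runs fluff first
#' and haircut second: fluff adds unassigned neighbours whose closed
#' neighbourhood density exceeds `fluff_density_cutoff` (fluffed vertices
#' are not marked visited, so they may be shared between modules); haircut
#' then iteratively removes vertices with within-module degree 1 (the
#' module's 2-core), so no emitted module retains a singly-connected node.
#' Modules with fewer than two nodes are discarded. The module score is the
#' density of the module subgraph times its node count.
#'
#' @param x an igraph graph, [CeRNANetwork-class], or edge data.frame.
#' @param node_score_cutoff numeric(1) in `[0, 1)`; default 0.2, the
#'   configuration used for functional-module detection on ceRNA networks.
#' @param haircut logical(1), default `TRUE`.
#' @param fluff logical(1), default `TRUE`.
#' @param fluff_density_cutoff numeric(1) in `[0, 1]`, default 0.2.
#' @param max_depth integer(1), default 100.
#' @return list of modules sorted by descending score, each a list with
#'   elements `nodes` (character), `score` (numeric) and `seed` (character);
#'   classed `MCODEModuleList` with a print method. The weight vector is
#'   attached as attribute `weights`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' g <- igraph::add_vertices(g, 1, name = "pendant")
#' g <- igraph::add_edges(g, c("a", "pendant"))
#' mcodeFindModules(g)[[1]]$nodes # the 5-clique; the pendant is trimmed
#' @export
mcodeFindModules <- function(x, node_score_cutoff = 0.2, haircut = TRUE,
                             fluff = TRUE, fluff_density_cutoff = 0.2,
                             max_depth = 100) {
  if (node_score_cutoff < 0 || node_score_cutoff >= 1)
    stop("node_score_cutoff must be in [0, 1)")
  if (fluff_density_cutoff < 0 || fluff_density_cutoff > 1)
    stop("fluff_density_cutoff must be in [0, 1]")
  g <- .asUndirectedGraph(x)
  g <- igraph::simplify(g)
  n <- igraph::vcount(g)
  if (!n) return(structure(list(), class = "MCODEModuleList",
                           weights = numeric(0)))
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(n))
  nm <- igraph::V(g)$name
  w <- mcodeWeight(g)

  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, as.integer)
  visited <- rep(FALSE, n)
  seedOrder <- order(-w, nm)
  modules <- list()

  for (s in seedOrder) {
    if (visited[s] || w[s] <= 0) next
    thr <- w[s] * (1 - node_score_cutoff)
    members <- s
    visited[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!visited[u] && w[u] >= thr) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }

    if (fluff) {
      boundary <- setdiff(unique(unlist(adj[members])), members)
      fluffed <- boundary[vapply(boundary, function(u) {
        nb <- unique(c(u, adj[[u]]))
        .graphDensity(igraph::induced_subgraph(g, nb)) > fluff_density_cutoff
      }, logical(1))]
      members <- c(members, fluffed) # fluffed nodes stay unvisited (shareable)
    }

    if (haircut && length(members) > 1L) {
      sub <- igraph::induced_subgraph(g, members)
      keep <- igraph::V(sub)$name[igraph::coreness(sub) >= 2] # module 2-core
      members <- members[nm[members] %in% keep]
    }

    if (length(members) >= 2L) {
      sub <- igraph::induced_subgraph(g, members)
      modules[[length(modules) + 1L]] <- list(
        nodes = sort(nm[members]),
        score = .graphDensity(sub) * length(members),
        seed = nm[s]
      )
    }
  }
  ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
               vapply(modules, `[[`, character(1), "seed"))
  structure(modules[ord], class = "MCODEModuleList", weights = w)
}

#' @export
print.MCODEModuleList <- function(x, ...) {
  cat("MCODE modules:", length(x), "\n")
  for (i in seq_along(x)) {
    cat(sprintf("  [%d] score %.3f, seed %s, %d nodes: %s\n", i, x[[i]]$score,
                x[[i]]$seed, length(x[[i]]$nodes),
                paste(utils::head(x[[i]]$nodes, 8L), collapse = ", ")))
  }
  invisible(x)
}

#' Tabulate MCODE modules
#'
#' Flattens an `MCODEModuleList` into a data.frame suitable for TSV export.
#'
#' @param modules result of [mcodeFindModules()].
#' @return data.frame with columns `module_id`, `score`, `seed`, `n_nodes`,
#'   `nodes` (comma-separated).
#' @export
mcodeTable <- function(modules) {
  if (!length(modules))
    return(data.frame(module_id = integer(), score = numeric(),
                      seed = character(), n_nodes = integer(),
                      nodes = character()))
  data.frame(
    module_id = seq_along(modules),
    score = vapply(modules, `[[`, numeric(1), "score"),
    seed = vapply(modules, `[[`, character(1), "seed"),
    n_nodes = vapply(modules, function(m) length(m$nodes), integer(1)),
    nodes = vapply(modules, function(m) paste(m$nodes, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}
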