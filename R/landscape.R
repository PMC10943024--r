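#' Generate a modular random landscape
#'
#' Lays `n_p` habitat sites on the unit square in `n_c` spatial modules,
#' connects them with the Euclidean minimum spanning tree, and then adds
#' random extra edges until the graph has `n_e` edges. Edge weights are the
#' Euclidean distances between sites, which the simulator converts into
#' dispersal rates. One site of a uniformly chosen module is designated the
#' mainland: a permanently active site holding the full regional species pool.
#'
#' Module structure is controlled by the excess factor `f` (>= 1): module
#' centers are drawn uniformly on the square and each site is pulled from a
#' uniform draw `u` toward its module center `c` as `c + (u - c)/f`. At
#' `f = 1` site positions are exactly uniform on the square (no discernible
#' clustering); large `f` gives tight modules of linear extent ~1/f. The
#' distance exponent `x` (>= 0) biases the extra (non-tree) edges toward short
#' distances: candidate pairs are sampled without replacement with probability
#' proportional to d^(-x), so `x = 0` ignores geometry. Spatial modularity
#' therefore increases with both `f` and `x`.
#'
#' @param n_p number of sites.
#' @param n_e total number of edges; must lie in `[n_p - 1, n_p(n_p-1)/2]`.
#'   Defaults to `2 * n_p`.
#' @param n_c number of spatial modules (default 5).
#' @param f excess factor controlling module tightness, `f >= 1`.
#' @param x distance exponent for extra-edge sampling, `x >= 0`.
#' @param seed optional integer seed (independent child streams are used for
#'   placement, tree construction, edge addition and mainland choice).
#' @return an object of class `landscape`: a list with `coords` (n_p x 2),
#'   `module` (integer labels), `edges` (m x 2 integer matrix, each row
#'   sorted), `weights` (Euclidean distances), `mst` (logical, edge is in the
#'   construction tree), `mainland` (site index) and `params`.
#' @examples
#' L <- generate_landscape(25, seed = 1)
#' L
#' @export
generate_landscape <- function(n_p, n_e = 2L * n_p, n_c = 5L, f = 5, x = 2,
                               seed = NULL) {
  stopifnot(n_p >= 2, n_c >= 1, n_c <= n_p, f >= 1, x >= 0)
  if (n_e < n_p - 1)
    stop("infeasible edge count: n_e must be at least n_p - 1 for connectivity")
  if (n_e > n_p * (n_p - 1) / 2)
    stop("n_e exceeds the number of site pairs n_p*(n_p-1)/2")
  with_seed(seed, {
    seeds <- child_seeds(4L)

    # --- site placement -----------------------------------------------------
    set.seed(seeds[1L])
    centers <- matrix(stats::runif(2L * n_c), n_c, 2L)
    module <- sample(rep_len(seq_len(n_c), n_p))   # balanced module sizes
    u <- matrix(stats::runif(2L * n_p), n_p, 2L)
    coords <- centers[module, , drop = FALSE] +
      (u - centers[module, , drop = FALSE]) / f

    # --- Euclidean MST ------------------------------------------------------
    set.seed(seeds[2L])
    D <- as.matrix(stats::dist(coords))
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE)
    tree <- igraph::mst(g)
    mst_edges <- igraph::as_edgelist(tree, names = FALSE)
    mst_edges <- t(apply(mst_edges, 1L, sort))

    # --- extra edges, P(pair) ~ d^(-x) --------------------------------------
    set.seed(seeds[3L])
    pairs <- t(utils::combn(n_p, 2L))
    key <- function(e) paste(e[, 1L], e[, 2L])
    in_tree <- key(pairs) %in% key(mst_edges)
    n_extra <- n_e - (n_p - 1L)
    extra <- matrix(integer(0), 0L, 2L)
    if (n_extra > 0L) {
      cand <- pairs[!in_tree, , drop = FALSE]
      d <- D[cand]
      w <- if (x == 0) rep(1, nrow(cand)) else d^(-x)
      pick <- sample.int(nrow(cand), n_extra, prob = w)
      extra <- cand[pick, , drop = FALSE]
    }
    edges <- rbind(mst_edges, extra)
    weights <- D[edges]
    is_mst <- c(rep(TRUE, nrow(mst_edges)), rep(FALSE, nrow(extra)))

    # --- mainland: uniform module, uniform site within it -------------------
    set.seed(seeds[4L])
    mainland <- resample(which(module == resample(seq_len(n_c))))

    new_landscape(coords, module, edges, weights, is_mst, mainland,
                  params = list(n_p = n_p, n_e = n_e, n_c = n_c, f = f, x = x))
  })
}

#' Generate an idealized star-shaped landscape
#'
#' A mainland at the center connected to `n_leaves` satellite sites, all at
#' the same distance. Used to isolate mainland-to-site colonization dynamics
#' from landscape topology.
#'
#' @param n_leaves number of satellite sites (>= 1).
#' @param radius center-to-leaf distance (> 0).
#' @param seed unused; accepted for interface symmetry with
#'   [generate_landscape()].
#' @return a `landscape` with `n_leaves + 1` sites, mainland at the center,
#'   and only center--leaf edges of weight `radius`.
#' @examples
#' generate_star_landscape(4, 0.2)
#' @export
generate_star_landscape <- function(n_leaves, radius, seed = NULL) {
  stopifnot(n_leaves >= 1)
  if (radius <= 0) stop("radius must be positive")
  theta <- 2 * pi * (seq_len(n_leaves) - 1L) / n_leaves
  coords <- rbind(c(0.5, 0.5),
                  cbind(0.5 + radius * cos(theta), 0.5 + radius * sin(theta)))
  n_p <- n_leaves + 1L
  edges <- cbind(1L, seq_len(n_leaves) + 1L)
  new_landscape(coords, module = rep(1L, n_p), edges = edges,
                weights = rep(radius, n_leaves),
                is_mst = rep(TRUE, n_leaves), mainland = 1L,
                params = list(n_p = n_p, n_e = n_leaves, n_c = 1L,
                              f = NA_real_, x = NA_real_, star = TRUE))
}

new_landscape <- function(coords, module, edges, weights, is_mst, mainland,
                          params) {
  L <- structure(list(coords = coords, module = as.integer(module),
                      edges = matrix(as.integer(edges), ncol = 2L),
                      weights = as.numeric(weights), mst = is_mst,
                      mainland = as.integer(mainland), params = params),
                 class = "landscape")
  validate_landscape(L)
  L
}

validate_landscape <- function(L) {
  n_p <- nrow(L$coords)
  stopifnot(length(L$module) == n_p, length(L$weights) == nrow(L$edges),
            L$mainland >= 1L, L$mainland <= n_p)
  d <- sqrt(rowSums((L$coords[L$edges[, 1L], , drop = FALSE] -
                     L$coords[L$edges[, 2L], , drop = FALSE])^2))
  if (any(abs(d - L$weights) > 1e-9 * pmax(1, d)))
    stop("edge weights do not equal Euclidean distances")
  g <- landscape_igraph(L)
  if (!igraph::is_connected(g)) stop("landscape graph is not connected")
  invisible(L)
}

#' Number of sites in a landscape
#' @param L a `landscape`.
#' @return integer site count.
#' @export
n_sites <- function(L) nrow(L$coords)

#' Convert a landscape to an igraph object
#'
#' Nodes carry `x`, `y`, `module` and `is_mainland` attributes; edges carry
#' `distance` (and `mst` membership). This is also the representation used by
#' [write_landscape()] for GraphML export.
#'
#' @param L a `landscape`.
#' @return an undirected `igraph` graph.
#' @export
landscape_igraph <- function(L) {
  g <- igraph::graph_from_edgelist(L$edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "distance", value = L$weights)
  g <- igraph::set_edge_attr(g, "mst", value = L$mst)
  g <- igraph::set_vertex_attr(g, "x", value = L$coords[, 1L])
  g <- igraph::set_vertex_attr(g, "y", value = L$coords[, 2L])
  g <- igraph::set_vertex_attr(g, "module", value = L$module)
  g <- igraph::set_vertex_attr(g, "is_mainland",
                               value = seq_len(n_sites(L)) == L$mainland)
  g
}

#' @export
print.landscape <- function(x, ...) {
  p <- x$params
  cat(sprintf("landscape: %d sites, %d edges, %d module(s), mainland = site %d\n",
              n_sites(x), nrow(x$edges), length(unique(x$module)), x$mainland))
  if (!is.null(p$f) && !is.na(p$f))
    cat(sprintf("  excess factor f = %g, distance exponent x = %g\n", p$f, p$x))
  invisible(x)
}
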