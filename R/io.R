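#' Export / import landscapes
#'
#' `write_landscape()` writes either GraphML (via igraph; node attributes
#' `x`, `y`, `module`, `is_mainland`, edge attribute `distance`) or a pair
#' of plain CSV files `<path>_nodes.csv` / `<path>_edges.csv`.
#' `read_landscape()` reads either format back into a `landscape` (the MST
#' flag is preserved in CSV, recomputed as all-false from GraphML files that
#' lack it).
#'
#' @param L a `landscape`.
#' @param path file path (GraphML) or path stem (CSV).
#' @param format `"graphml"` or `"csv"`.
#' @return `write_landscape()` the path, invisibly; `read_landscape()` a
#'   `landscape`.
#' @export
write_landscape <- function(L, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(landscape_igraph(L), path, format = "graphml")
  } else {
    utils::write.csv(data.frame(site = seq_len(n_sites(L)),
                                x = L$coords[, 1L], y = L$coords[, 2L],
                                module = L$module,
                                is_mainland = seq_len(n_sites(L)) == L$mainland),
                     paste0(path, "_nodes.csv"), row.names = FALSE)
    utils::write.csv(data.frame(from = L$edges[, 1L], to = L$edges[, 2L],
                                distance = L$weights, mst = L$mst),
                     paste0(path, "_edges.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    coords <- cbind(igraph::vertex_attr(g, "x"), igraph::vertex_attr(g, "y"))
    edges <- igraph::as_edgelist(g, names = FALSE)
    mst <- igraph::edge_attr(g, "mst") %||% rep(FALSE, nrow(edges))
    new_landscape(coords, igraph::vertex_attr(g, "module"), edges,
                  igraph::edge_attr(g, "distance"), as.logical(mst),
                  which(as.logical(igraph::vertex_attr(g, "is_mainland")))[1L],
                  params = list(n_p = nrow(coords), n_e = nrow(edges),
                                n_c = length(unique(igraph::vertex_attr(g, "module"))),
                                f = NA_real_, x = NA_real_))
  } else {
    nodes <- utils::read.csv(paste0(path, "_nodes.csv"))
    edges <- utils::read.csv(paste0(path, "_edges.csv"))
    new_landscape(cbind(nodes$x, nodes$y), nodes$module,
                  cbind(edges$from, edges$to), edges$distance,
                  as.logical(edges$mst), which(nodes$is_mainland)[1L],
                  params = list(n_p = nrow(nodes), n_e = nrow(edges),
                                n_c = length(unique(nodes$module)),
                                f = NA_real_, x = NA_real_))
  }
}

#' Export an equilibrium result as JSON
#'
#' Survivors, biomasses and the cascade removal order of a
#' [local_equilibrium()] result.
#'
#' @param eq an `equilibrium_result`.
#' @param file path to write.
#' @return the path, invisibly.
#' @export
write_equilibrium <- function(eq, file) {
  stopifnot(inherits(eq, "equilibrium_result"))
  jsonlite::write_json(
    list(survivors = eq$survivors, biomass = unname(eq$biomass),
         extinctions = eq$extinctions, iterations = eq$iterations),
    file, digits = NA)
  invisible(file)
}

#' Export a parameterized community
#'
#' Writes the community matrix and growth-rate/equilibrium vectors of a
#' `local_dynamics` object as CSV: `<stem>_matrix.csv` and
#' `<stem>_params.csv` (columns `species`, `r`, `x_star`, `is_basal`).
#'
#' @param dyn a `local_dynamics` object.
#' @param stem path stem.
#' @return the stem, invisibly.
#' @export
write_community <- function(dyn, stem) {
  stopifnot(inherits(dyn, "local_dynamics"))
  utils::write.csv(as.data.frame(dyn$M), paste0(stem, "_matrix.csv"),
                   row.names = FALSE)
  n <- length(dyn$r)
  utils::write.csv(data.frame(species = seq_len(n), r = dyn$r,
                              x_star = dyn$x_star,
                              is_basal = seq_len(n) %in% dyn$basal),
                   paste0(stem, "_params.csv"), row.names = FALSE)
  invisible(stem)
}
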