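#' Contact networks
#'
#' A `contact_network` is a simple undirected graph over the blastomeres of
#' one embryo: node `i` is blastomere `i` (1-based, in embryo order) and an
#' edge means the two inflated cell surfaces overlap. No self-loops, no
#' duplicate edges.
#'
#' @param n_nodes Number of nodes (blastomeres).
#' @param edges Two-column integer matrix of node index pairs (may have zero
#'   rows); order within a pair is irrelevant.
#' @param node_ids Optional character vector of cell ids, length `n_nodes`.
#' @return An object of class `contact_network`.
#' @export
contact_network_obj <- function(n_nodes, edges = matrix(integer(), 0, 2),
                                node_ids = NULL) {
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 1L) abort("`n_nodes` must be >= 1", "invalid_parameter")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (min(edges) < 1L || max(edges) > n) {
      abort("edge indices out of range", "invalid_parameter")
    }
    if (any(edges[, 1] == edges[, 2])) {
      abort("self-loops are not allowed", "invalid_parameter")
    }
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (!is.null(node_ids) && length(node_ids) != n) {
    abort("`node_ids` must have length `n_nodes`", "invalid_parameter")
  }
  structure(list(n_nodes = n, edges = edges, node_ids = node_ids),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network: %d nodes, %d edges>\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Node degrees of a contact network
#'
#' @param net A `contact_network`.
#' @return Integer vector of length `n_nodes`: the number of contacts of each
#'   blastomere.
#' @export
network_degrees <- function(net) {
  tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = net$n_nodes)
}

#' Do two blastomere meshes overlap?
#'
#' True iff the closed volumes intersect: any pair of surface triangles
#' intersects, or one mesh's volume centroid lies inside the other (which
#' catches full engulfment, where the surfaces never cross). Symmetric in its
#' arguments. Surfaces that merely touch (tangency) have measure zero under
#' floating point and are not treated specially; near-tangent configurations
#' within the tessellation tolerance band may resolve either way.
#'
#' @param a,b `blastomere_mesh` objects.
#' @return Logical scalar.
#' @export
meshes_overlap <- function(a, b) {
  if (!inherits(a, "blastomere_mesh") || !inherits(b, "blastomere_mesh")) {
    abort("both arguments must be blastomere_mesh objects", "invalid_parameter")
  }
  ca <- mesh_centroid(a) # errors on degenerate meshes
  cb <- mesh_centroid(b)
  cpp_meshes_overlap(a$vertices, a$faces - 1L, b$vertices, b$faces - 1L, ca, cb)
}

#' Build the cell-contact network of an embryo
#'
#' Scales every blastomere mesh by `scale_factor` about its own volume
#' centroid (both members of each pair are scaled) and links two blastomeres
#' when the inflated surfaces overlap. The default factor 1.05 inflates each
#' cell by 5%, so cells whose surfaces are within roughly 5% of their
#' combined radius of each other register as touching.
#'
#' @param emb An `embryo`.
#' @param scale_factor Positive scale factor applied to every mesh
#'   (default 1.05).
#' @return A `contact_network` with one node per blastomere, in embryo order.
#' @export
contact_network <- function(emb, scale_factor = 1.05) {
  if (!inherits(emb, "embryo")) {
    abort("`emb` must be an embryo", "invalid_parameter")
  }
  check_positive_scalar(scale_factor, "scale_factor")
  n <- emb$stage
  ids <- vapply(emb$blastomeres, `[[`, character(1), "cell_id")
  scaled <- vector("list", n)
  for (i in seq_len(n)) {
    scaled[[i]] <- tryCatch(
      scale_mesh(emb$blastomeres[[i]], scale_factor),
      blastonet_error = function(e) {
        abort(sprintf("blastomere '%s': %s", ids[i], conditionMessage(e)),
              "invalid_mesh")
      }
    )
  }
  edges <- matrix(integer(), 0, 2)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (meshes_overlap(scaled[[i]], scaled[[j]])) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  contact_network_obj(n, edges, node_ids = ids)
}

#' Convert a contact network to an igraph graph
#'
#' @param net A `contact_network`.
#' @return An [igraph::graph] object with a `name` vertex attribute when node
#'   ids are available.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$n_nodes, directed = FALSE)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, t(net$edges))
  }
  if (!is.null(net$node_ids)) {
    g <- igraph::set_vertex_attr(g, "name", value = net$node_ids)
  }
  g
}
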