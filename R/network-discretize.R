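#' Discretize every vessel into short segments
#'
#' Each vessel is split into equal segments so that it carries at least
#' `min_nodes` nodes (default 3, i.e. two segments) and no segment exceeds
#' `max_dx_mm` (default 2.5 mm). Total length and radii are preserved
#' exactly. Lumped outlet elements are left as single segments: their
#' hydraulics are a prescribed resistance, not a geometric one.
#'
#' @param network a `vascular_network`.
#' @param max_dx_mm maximum segment length, mm.
#' @param min_nodes minimum number of nodes per vessel (>= 2).
#' @return The network with a `segments` tibble (`seg_id`, `vessel_id`,
#'   `from`, `to`, `r0_mm`, `length_mm`, `E_Pa`, `type`, `territory`) and
#'   nodes augmented with the interior discretization nodes.
#' @export
discretize_network <- function(network,
                               max_dx_mm = network$meta$config$solver$max_dx_mm,
                               min_nodes = network$meta$config$solver$min_nodes) {
  if (is.null(max_dx_mm)) max_dx_mm <- 2.5
  if (is.null(min_nodes)) min_nodes <- 3L
  stopifnot(max_dx_mm > 0, min_nodes >= 2)
  v <- network$vessels
  nodes <- network$nodes
  is_lumped <- v$type == "outlet"
  n_seg <- ifelse(is_lumped, 1L,
                  pmax(min_nodes - 1L, ceiling(v$length_mm / max_dx_mm)))
  total <- sum(n_seg)
  vessel_row <- rep(seq_len(nrow(v)), n_seg)
  k <- sequence(n_seg)                      # segment index within vessel
  nv <- n_seg[vessel_row]                   # segments in this vessel
  # interior nodes: n_seg - 1 per vessel, ids appended after existing ones
  n_interior <- pmax(n_seg - 1L, 0L)
  first_interior <- max(nodes$id) + c(0L, cumsum(n_interior))[seq_len(nrow(v))]
  from_id <- ifelse(k == 1L, v$from[vessel_row],
                    first_interior[vessel_row] + k - 1L)
  to_id <- ifelse(k == nv, v$to[vessel_row],
                  first_interior[vessel_row] + k)
  segments <- tibble::tibble(
    seg_id = seq_len(total),
    vessel_id = v$id[vessel_row],
    from = as.integer(from_id),
    to = as.integer(to_id),
    r0_mm = v$r0_mm[vessel_row],
    length_mm = v$length_mm[vessel_row] / nv,
    E_Pa = v$E_Pa[vessel_row],
    type = v$type[vessel_row],
    territory = v$territory[vessel_row],
    is_collateral = v$is_collateral[vessel_row]
  )
  # interior node positions interpolated along the vessel chord
  int_sel <- k < nv
  if (any(int_sel)) {
    vr <- vessel_row[int_sel]
    frac <- k[int_sel] / nv[int_sel]
    a <- match(v$from[vr], nodes$id)
    b <- match(v$to[vr], nodes$id)
    interior_nodes <- tibble::tibble(
      id = as.integer(first_interior[vr] + k[int_sel]),
      x = nodes$x[a] + frac * (nodes$x[b] - nodes$x[a]),
      y = nodes$y[a] + frac * (nodes$y[b] - nodes$y[a]),
      z = nodes$z[a] + frac * (nodes$z[b] - nodes$z[a]),
      role = "internal",
      territory = v$territory[vr]
    )
    nodes <- dplyr::bind_rows(nodes, interior_nodes)
  }
  network$nodes <- nodes
  network$segments <- segments
  network
}

#' Serialize a vascular network to CSV tables
#'
#' Writes `nodes.csv` (`id,x,y,z,role,territory`), `vessels.csv`
#' (`id,node_a,node_b,r0_mm,length_mm,E_Pa,is_collateral,territory` plus
#' `type` and `name`) and `meta.json` into a directory; `read_network()`
#' reconstructs the network (outlet bookkeeping is re-derived).
#'
#' @param network a `vascular_network` (pre-discretization tables are
#'   written; discretize after reading).
#' @param dir output directory (created if needed).
#' @return `write_network()` the directory, invisibly; `read_network()` a
#'   `vascular_network`.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(network$nodes, file.path(dir, "nodes.csv"))
  v <- dplyr::rename(network$vessels, node_a = "from", node_b = "to")
  readr::write_csv(v, file.path(dir, "vessels.csv"))
  meta <- network$meta
  meta$config <- unclass(meta$config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"), show_col_types = FALSE)
  vessels <- readr::read_csv(file.path(dir, "vessels.csv"), show_col_types = FALSE)
  vessels <- dplyr::rename(vessels, from = "node_a", to = "node_b")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  meta$config <- do.call(model_config, meta$config)
  meta$territory_outlet_counts <- unlist(meta$territory_outlet_counts)
  out_vessels <- vessels[vessels$type == "outlet" & vessels$territory != "systemic", ]
  outlets <- tibble::tibble(
    node = out_vessels$to, pial_node = out_vessels$from,
    vessel = out_vessels$id, territory = out_vessels$territory,
    resistance_Pa_s_ml = NA_real_
  )
  structure(list(nodes = tibble::as_tibble(nodes),
                 vessels = tibble::as_tibble(vessels),
                 outlets = outlets, meta = meta),
            class = "vascular_network")
}

#' Convert a vascular network to an igraph object
#'
#' Vessel-level graph with node and vessel attributes carried over; used
#' for connectivity checks and GraphML export.
#'
#' @param network a `vascular_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(network) {
  verts <- data.frame(name = as.character(network$nodes$id),
                      network$nodes[, c("x", "y", "z", "role", "territory")])
  if (!is.null(network$segments)) {
    # segment-level graph: includes the interior discretization nodes
    edges <- data.frame(from = as.character(network$segments$from),
                        to = as.character(network$segments$to),
                        network$segments[, c("vessel_id", "r0_mm", "length_mm",
                                             "type", "territory")])
  } else {
    edges <- data.frame(from = as.character(network$vessels$from),
                        to = as.character(network$vessels$to),
                        network$vessels[, c("id", "r0_mm", "length_mm", "E_Pa",
                                            "type", "is_collateral", "territory")])
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Export a vascular network as GraphML
#'
#' @param network a `vascular_network`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
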