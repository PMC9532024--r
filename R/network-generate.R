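#' Daughter radii at a Murray bifurcation
#'
#' Murray's law at a bifurcation conserves the n-th power of the radius:
#' \eqn{R^n = r_i^n + r_j^n} with n = 3 for the classical optimum. The
#' split fraction sets the share of the parent's \eqn{R^n} carried by the
#' first daughter, so \eqn{r_i = R f^{1/n}}, \eqn{r_j = R (1-f)^{1/n}}.
#'
#' @param parent_radius parent radius, mm (> 0).
#' @param split_fraction fraction in (0, 1) of the conserved quantity taken
#'   by the first daughter; 0.5 gives the symmetric bifurcation with both
#'   daughters at `parent_radius * 2^(-1/n)`.
#' @param exponent Murray exponent n (> 0, default 3).
#' @return Numeric length-2 vector `c(r_i, r_j)` in mm.
#' @examples
#' murray_daughter_radii(1, 0.5) # both 2^(-1/3) = 0.7937
#' @export
murray_daughter_radii <- function(parent_radius, split_fraction = 0.5,
                                  exponent = 3) {
  if (any(parent_radius <= 0)) {
    stop("murray_daughter_radii: parent_radius must be positive", call. = FALSE)
  }
  if (any(exponent <= 0)) {
    stop("murray_daughter_radii: exponent must be positive", call. = FALSE)
  }
  if (any(split_fraction <= 0) || any(split_fraction >= 1)) {
    stop("murray_daughter_radii: split_fraction must lie in (0, 1)", call. = FALSE)
  }
  c(parent_radius * split_fraction^(1 / exponent),
    parent_radius * (1 - split_fraction)^(1 / exponent))
}

#' Build a Murray-law bifurcating tree
#'
#' Generates a binary arterial tree from a root radius down to a terminal
#' radius. Each generation splits by Murray's law; a branch becomes a leaf
#' as soon as its radius is less than or equal to `terminal_radius`
#' (inclusive tie, for determinism). Branch length is
#' `length_radius_ratio * radius`.
#'
#' @param root_radius root branch radius, mm.
#' @param terminal_radius radius at which branches terminate, mm
#'   (must be < `root_radius`).
#' @param config a [model_config()]; uses `network.length_radius_ratio` and
#'   `network.murray_exponent`.
#' @param split_jitter half-width of a uniform perturbation of the 0.5
#'   split fraction (0 = symmetric tree).
#' @param seed RNG seed, used only when `split_jitter > 0`.
#' @return Tibble with one row per branch: `id`, `parent` (NA for the
#'   root), `depth` (root = 0), `radius_mm`, `length_mm`, `is_leaf`.
#' @export
build_bifurcating_tree <- function(root_radius, terminal_radius,
                                   config = model_config(),
                                   split_jitter = 0, seed = NULL) {
  if (terminal_radius >= root_radius) {
    stop("build_bifurcating_tree: terminal_radius must be smaller than root_radius",
         call. = FALSE)
  }
  if (terminal_radius <= 0) {
    stop("build_bifurcating_tree: terminal_radius must be positive", call. = FALSE)
  }
  lr <- config$network$length_radius_ratio
  n_exp <- config$network$murray_exponent
  build <- function() {
    id <- 1L
    rows <- list(list(id = 1L, parent = NA_integer_, depth = 0L, radius_mm = root_radius))
    queue <- list(rows[[1]])
    while (length(queue) > 0L) {
      node <- queue[[1]]; queue <- queue[-1]
      # inclusive tie, robust to round-off from repeated Murray splitting
      if (node$radius_mm <= terminal_radius * (1 + 1e-9)) next
      f <- if (split_jitter > 0) {
        min(max(0.5 + stats::runif(1, -split_jitter, split_jitter), 0.05), 0.95)
      } else 0.5
      rr <- murray_daughter_radii(node$radius_mm, f, n_exp)
      for (r in rr) {
        id <- id + 1L
        child <- list(id = id, parent = node$id, depth = node$depth + 1L,
                      radius_mm = r)
        rows[[id]] <- child
        queue[[length(queue) + 1L]] <- child
      }
    }
    rows
  }
  rows <- if (!is.null(seed)) withr::with_seed(seed, build()) else build()
  tb <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  tb$length_mm <- lr * tb$radius_mm
  tb$is_leaf <- !(tb$id %in% tb$parent)
  tb
}

#' Assign a synthetic perfusion territory from a surface position
#'
#' Fixed angular sectors on the unit sphere approximating the eight major
#' perfusion territories: a polar cap for the brainstem (z < -0.88), a band
#' for the cerebellum (-0.88 <= z < -0.55), and six cerebral sectors above,
#' split into left/right by the y coordinate and anterior/middle/posterior
#' (ACA/MCA/PCA) by bands of the x coordinate.
#'
#' @param x,y,z coordinates on (or near) the unit sphere; vectors.
#' @return Character vector of territory labels.
#' @export
assign_territory <- function(x, y, z) {
  n <- sqrt(x^2 + y^2 + z^2)
  x <- x / n; y <- y / n; z <- z / n
  ifelse(z < -0.88, "brainstem",
  ifelse(z < -0.55, "cerebellum",
    paste0(ifelse(y >= 0, "L", "R"), "-",
           ifelse(x > 0.35, "ACA", ifelse(x < -0.35, "PCA", "MCA")))))
}

#' Major cerebral perfusion territories
#'
#' The eight territory labels used by the generator, plus the `systemic`
#' label of the extracranial outlet.
#' @return Character vector.
#' @export
territory_levels <- function() {
  c("L-MCA", "R-MCA", "L-ACA", "R-ACA", "L-PCA", "R-PCA",
    "cerebellum", "brainstem", "systemic")
}

#' Build the synthetic pial surface network
#'
#' The pial vessel network is the dual graph of a uniformly triangulated
#' closed surface (an icosphere standing in for the brain surface): one
#' node per triangle, one vessel per adjacent triangle pair, giving a
#' hexagonal mesh in which every node has degree 3. All pial vessels get
#' the pial reference radius; vessels whose endpoints lie in different
#' perfusion territories are marked as leptomeningeal collateral
#' candidates.
#'
#' @param config a [model_config()]; uses `network.surface_resolution`,
#'   `network.sphere_radius_mm`, `network.pial_radius_mm`.
#' @return List with `nodes` (tibble: `id`, `x`, `y`, `z` in mm, `role`,
#'   `territory`) and `vessels` (tibble: `id`, `from`, `to`, `r0_mm`,
#'   `length_mm`, `E_Pa`, `type`, `is_collateral`, `territory`, `name`).
#' @export
build_pial_network <- function(config = model_config()) {
  net_cfg <- config$network
  mesh <- icosphere(net_cfg$surface_resolution)
  dual <- dual_mesh(mesh)
  R <- net_cfg$sphere_radius_mm
  pos <- dual$positions * R
  terr <- assign_territory(dual$positions[, 1], dual$positions[, 2],
                           dual$positions[, 3])
  nodes <- tibble::tibble(
    id = seq_len(nrow(pos)),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    role = "pial", territory = terr
  )
  e <- dual$edges
  len <- sqrt(rowSums((pos[e[, 1], , drop = FALSE] - pos[e[, 2], , drop = FALSE])^2))
  crossing <- terr[e[, 1]] != terr[e[, 2]]
  vessels <- tibble::tibble(
    id = seq_len(nrow(e)),
    from = as.integer(e[, 1]), to = as.integer(e[, 2]),
    r0_mm = net_cfg$pial_radius_mm,
    length_mm = len,
    E_Pa = config$solver$young_modulus_Pa,
    type = "pial",
    is_collateral = crossing,
    territory = ifelse(crossing, "collateral", terr[e[, 1]]),
    name = NA_character_
  )
  list(nodes = nodes, vessels = vessels)
}

#' Randomly thin the leptomeningeal collateral candidates
#'
#' Each territory-crossing pial vessel is retained independently with the
#' given probability; all other vessels are untouched. This is how the
#' clinical collateral score (absent / poor / moderate / good) enters the
#' model: as the inclusion probability of collateral vessels.
#'
#' @param network a `vascular_network` or a `nodes`/`vessels` list whose
#'   vessels carry an `is_collateral` column with the full candidate set.
#' @param probability retention probability in [0, 1].
#' @param seed integer RNG seed (reproducible thinning).
#' @return The network with non-retained collateral vessels removed.
#' @export
select_collaterals <- function(network, probability, seed = 1L) {
  if (probability < 0 || probability > 1) {
    stop("select_collaterals: probability must lie in [0, 1]", call. = FALSE)
  }
  v <- network$vessels
  cand <- which(v$is_collateral)
  keep_cand <- withr::with_seed(seed,
    cand[stats::runif(length(cand)) < probability])
  drop <- setdiff(cand, keep_cand)
  if (length(drop) > 0L) network$vessels <- v[-drop, , drop = FALSE]
  network
}

#' Attach penetrating-artery outlets to the pial surface
#'
#' Every pial node receives one penetrating artery represented by a lumped
#' outlet element ending in an outlet node just below the surface. The
#' outlet elements are the loci of the autoregulated resistances; their
#' hydraulic resistance is set by calibration and autoregulation, not by
#' their geometry.
#'
#' @param network `nodes`/`vessels` list containing pial nodes.
#' @param config a [model_config()].
#' @return The network with outlet nodes and outlet elements appended, plus
#'   an `outlets` tibble (`node`, `pial_node`, `vessel`, `territory`).
#' @export
attach_outlets <- function(network, config = model_config()) {
  pial <- network$nodes[network$nodes$role == "pial", ]
  n0 <- max(network$nodes$id)
  v0 <- if (nrow(network$vessels) > 0L) max(network$vessels$id) else 0L
  out_nodes <- tibble::tibble(
    id = n0 + seq_len(nrow(pial)),
    x = pial$x * 0.95, y = pial$y * 0.95, z = pial$z * 0.95,
    role = "outlet", territory = pial$territory
  )
  out_vessels <- tibble::tibble(
    id = v0 + seq_len(nrow(pial)),
    from = pial$id, to = out_nodes$id,
    r0_mm = config$network$pial_radius_mm,
    length_mm = 2.5, # nominal cortical thickness; hydraulics are lumped
    E_Pa = config$solver$young_modulus_Pa,
    type = "outlet",
    is_collateral = FALSE,
    territory = pial$territory,
    name = NA_character_
  )
  network$nodes <- dplyr::bind_rows(network$nodes, out_nodes)
  network$vessels <- dplyr::bind_rows(network$vessels, out_vessels)
  network$outlets <- tibble::tibble(
    node = out_nodes$id, pial_node = pial$id,
    vessel = out_vessels$id, territory = pial$territory
  )
  network
}

#' Surrogate systemic arterial tree
#'
#' The large systemic arteries (heart to circle of Willis) with
#' literature-typical radii, lengths and Young's moduli. These values are a
#' synthetic surrogate table shipped with the package
#' (`systemic_vessels_synthetic.csv`): absolute systemic resistances are
#' non-critical because the inlet boundary calibration uniformly rescales
#' all outlet resistances. Users may supply their own table via
#' `network.systemic_table`.
#'
#' @param path optional path to a replacement CSV with columns `name`,
#'   `from`, `to`, `r0_mm`, `length_mm`, `E_Pa`, `territory`.
#' @return Tibble of systemic vessels.
#' @export
systemic_vessel_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "systemic_vessels_synthetic.csv",
                        package = "collatflow", mustWork = TRUE)
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    name = readr::col_character(),
                    from = readr::col_character(),
                    to = readr::col_character(),
                    r0_mm = readr::col_double(),
                    length_mm = readr::col_double(),
                    E_Pa = readr::col_double(),
                    territory = readr::col_character()
                  ))
}

# Recursive spatial-bisection Murray tree feeding one territory.
# Splits the territory's pial nodes by the median of their most spread-out
# coordinate; daughter radii follow Murray's law with the split fraction
# equal to the share of pial nodes (flow demand) in each half. A branch
# terminates when it serves a single pial node or its radius has reached
# the terminal radius; each leaf is tied to its remaining pial nodes by
# short connector vessels at the pial radius.
build_territory_tree <- function(root_node_id, root_radius, pial_nodes,
                                 territory, config, next_node_id,
                                 next_vessel_id) {
  lr <- config$network$length_radius_ratio
  n_exp <- config$network$murray_exponent
  term_r <- config$network$terminal_radius_mm
  R_sph <- config$network$sphere_radius_mm
  E <- config$solver$young_modulus_Pa
  pial_r <- config$network$pial_radius_mm

  nodes <- list(); vessels <- list()
  nid <- next_node_id; vid <- next_vessel_id
  add_node <- function(pos, role = "internal") {
    nid <<- nid + 1L
    nodes[[length(nodes) + 1L]] <<- tibble::tibble(
      id = nid, x = pos[1], y = pos[2], z = pos[3],
      role = role, territory = territory)
    nid
  }
  add_vessel <- function(from, to, r, len, type) {
    vid <<- vid + 1L
    vessels[[length(vessels) + 1L]] <<- tibble::tibble(
      id = vid, from = from, to = to, r0_mm = r,
      length_mm = len, E_Pa = E, type = type,
      is_collateral = FALSE, territory = territory, name = NA_character_)
    vid
  }
  pos_mat <- as.matrix(pial_nodes[, c("x", "y", "z")])

  recurse <- function(parent_id, idx, radius) {
    centroid <- colMeans(pos_mat[idx, , drop = FALSE])
    if (length(idx) == 1L || radius <= term_r) {
      # leaf just above the surface, connectors down to each pial node
      leaf_pos <- centroid / sqrt(sum(centroid^2)) * R_sph * 1.03
      leaf <- add_node(leaf_pos)
      add_vessel(parent_id, leaf, radius, lr * radius, "tree")
      for (k in idx) {
        d <- sqrt(sum((leaf_pos - pos_mat[k, ])^2))
        add_vessel(leaf, pial_nodes$id[k], pial_r, max(d, 0.5), "connector")
      }
      return(invisible(NULL))
    }
    node_pos <- centroid / sqrt(sum(centroid^2)) * R_sph * 1.1
    here <- add_node(node_pos)
    add_vessel(parent_id, here, radius, lr * radius, "tree")
    spread <- apply(pos_mat[idx, , drop = FALSE], 2, function(u) diff(range(u)))
    ax <- which.max(spread)
    ord <- idx[order(pos_mat[idx, ax])]
    n1 <- floor(length(ord) / 2)
    f <- n1 / length(ord)
    rr <- murray_daughter_radii(radius, f, n_exp)
    recurse(here, ord[seq_len(n1)], rr[1])
    recurse(here, ord[(n1 + 1):length(ord)], rr[2])
    invisible(NULL)
  }
  recurse(root_node_id, seq_len(nrow(pial_nodes)), root_radius)
  list(nodes = dplyr::bind_rows(nodes), vessels = dplyr::bind_rows(vessels),
       next_node_id = nid, next_vessel_id = vid)
}

#' Generate a synthetic cerebral vascular network
#'
#' Assembles the full model vasculature: a surrogate systemic tree (heart
#' to circle of Willis), one Murray-law bifurcating tree per perfusion
#' territory, the hexagonal pial surface network (dual of a triangulated
#' sphere) with randomly thinned leptomeningeal collaterals, and one
#' penetrating-artery outlet per pial node. The systemic circulation is
#' closed by a lumped extracranial outlet so that the heart inlet carries
#' the full cardiac output.
#'
#' @param config a [model_config()]; the generator reads
#'   `network.surface_resolution` (outlet count = `20 * 4^resolution`),
#'   `network.collateral_probability` and `network.seed`.
#' @return A `vascular_network`: list with tibbles `nodes`, `vessels`,
#'   `outlets` and a `meta` list (`N_total` pial outlets, territory outlet
#'   counts, brain volume, seed, config).
#' @examples
#' \donttest{
#' net <- generate_network(model_config("network.surface_resolution" = 1))
#' net$meta$N_total
#' }
#' @export
generate_network <- function(config = model_config()) {
  net_cfg <- config$network
  pial <- build_pial_network(config)
  pial <- select_collaterals(pial, net_cfg$collateral_probability,
                             seed = net_cfg$seed)
  pial <- attach_outlets(pial, config)
  nodes <- pial$nodes
  vessels <- pial$vessels
  outlets <- pial$outlets

  # systemic tree: named nodes resolved to ids, placed below the sphere
  sys_path <- net_cfg$systemic_table
  if (length(sys_path) != 1L || is.na(sys_path)) sys_path <- NULL
  sys_tab <- systemic_vessel_table(sys_path)
  sys_names <- unique(c(sys_tab$from, sys_tab$to))
  nid <- max(nodes$id)
  sys_ids <- stats::setNames(nid + seq_along(sys_names), sys_names)
  depth <- bfs_depth(sys_tab, "heart")
  R_sph <- net_cfg$sphere_radius_mm
  sys_pos <- t(vapply(sys_names, function(nm) {
    d <- depth[[nm]]; if (is.null(d)) d <- 5
    c(0, 0, -R_sph * (2.6 - 0.25 * d))
  }, numeric(3)))
  terr_root <- !is.na(sys_tab$territory) & sys_tab$territory != "systemic"
  # territory-root distal nodes sit near their territory's centroid
  for (i in which(terr_root)) {
    tpos <- nodes[nodes$role == "pial" & nodes$territory == sys_tab$territory[i], ]
    if (nrow(tpos) > 0L) {
      cen <- c(mean(tpos$x), mean(tpos$y), mean(tpos$z))
      sys_pos[match(sys_tab$to[i], sys_names), ] <-
        cen / sqrt(sum(cen^2)) * R_sph * 1.2
    }
  }
  sys_nodes <- tibble::tibble(
    id = unname(sys_ids[sys_names]),
    x = sys_pos[, 1], y = sys_pos[, 2], z = sys_pos[, 3],
    role = ifelse(sys_names == "heart", "inlet", "internal"),
    territory = "systemic"
  )
  vid <- max(vessels$id)
  sys_vessels <- tibble::tibble(
    id = vid + seq_len(nrow(sys_tab)),
    from = unname(sys_ids[sys_tab$from]),
    to = unname(sys_ids[sys_tab$to]),
    r0_mm = sys_tab$r0_mm, length_mm = sys_tab$length_mm,
    E_Pa = sys_tab$E_Pa,
    type = ifelse(!is.na(sys_tab$territory) & sys_tab$territory == "systemic",
                  "outlet", "systemic"),
    is_collateral = FALSE,
    territory = ifelse(is.na(sys_tab$territory), "systemic", sys_tab$territory),
    name = sys_tab$name
  )
  # extracranial outlet node
  body_row <- which(sys_vessels$type == "outlet")
  if (length(body_row) != 1L) {
    stop("systemic table must contain exactly one row with territory 'systemic' (the extracranial outlet)",
         call. = FALSE)
  }
  sys_nodes$role[match(sys_vessels$to[body_row], sys_nodes$id)] <- "outlet"
  nodes <- dplyr::bind_rows(nodes, sys_nodes)
  vessels <- dplyr::bind_rows(vessels, sys_vessels)
  nid <- max(nodes$id); vid <- max(vessels$id)

  # one Murray tree per territory, rooted at the territory root's distal node
  for (i in which(terr_root)) {
    terr <- sys_tab$territory[i]
    pn <- nodes[nodes$role == "pial" & nodes$territory == terr, ]
    if (nrow(pn) == 0L) next
    root_id <- unname(sys_ids[sys_tab$to[i]])
    tr <- build_territory_tree(root_id, sys_tab$r0_mm[i], pn, terr,
                               config, nid, vid)
    nodes <- dplyr::bind_rows(nodes, tr$nodes)
    vessels <- dplyr::bind_rows(vessels, tr$vessels)
    nid <- tr$next_node_id; vid <- tr$next_vessel_id
  }

  # strip stray element names picked up from geometric helpers
  nodes[] <- lapply(nodes, unname)
  vessels[] <- lapply(vessels, unname)
  outlets$resistance_Pa_s_ml <- NA_real_
  counts <- table(outlets$territory)
  meta <- list(
    N_total = nrow(outlets),
    territory_outlet_counts = stats::setNames(as.integer(counts), names(counts)),
    brain_volume_ml = net_cfg$brain_volume_ml,
    seed = net_cfg$seed,
    collateral_probability = net_cfg$collateral_probability,
    config = config,
    body_outlet_vessel = sys_vessels$id[body_row]
  )
  structure(list(nodes = nodes, vessels = vessels, outlets = outlets,
                 meta = meta),
            class = "vascular_network")
}

bfs_depth <- function(edge_tab, root) {
  depth <- list(); depth[[root]] <- 0
  queue <- root
  while (length(queue) > 0L) {
    cur <- queue[[1]]; queue <- queue[-1]
    nxt <- edge_tab$to[edge_tab$from == cur]
    for (nm in nxt) {
      if (is.null(depth[[nm]])) {
        depth[[nm]] <- depth[[cur]] + 1
        queue <- c(queue, nm)
      }
    }
  }
  depth
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network>\n")
  cat("  nodes:   ", nrow(x$nodes), "\n")
  cat("  vessels: ", nrow(x$vessels),
      sprintf(" (%d collateral)", sum(x$vessels$is_collateral)), "\n")
  cat("  pial outlets (N_total): ", x$meta$N_total, "\n")
  cat("  collateral probability: ", x$meta$collateral_probability, "\n")
  if (!is.null(x$segments)) cat("  discretized segments: ", nrow(x$segments), "\n")
  invisible(x)
}
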