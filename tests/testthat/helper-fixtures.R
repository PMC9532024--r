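# Shared fixtures, built lazily and cached for the whole test run.
# Networks are generated in code (no stored fixtures); the small
# resolution-1 network (80 pial outlets) serves most tests, the
# resolution-3 network (1280 outlets) the boundary-condition and
# autoregulation checks at study scale.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_config <- function(...) {
  model_config("network.surface_resolution" = 1,
               "network.collateral_probability" = 0.25,
               "network.seed" = 1L, ...)
}

small_network <- function() cached("small_network", {
  discretize_network(generate_network(small_config()))
})

small_calibrated <- function() cached("small_calibrated", {
  calibrate_network(small_network(), small_config())
})

small_healthy <- function() cached("small_healthy", {
  autoregulate(small_calibrated(), small_config())
})

big_config <- function() model_config() # resolution 3: 1280 pial outlets

big_calibrated <- function() cached("big_calibrated", {
  calibrate_network(discretize_network(generate_network(big_config())),
                    big_config())
})

big_healthy <- function() cached("big_healthy", {
  autoregulate(big_calibrated(), big_config())
})

# A hand-built chain network: inlet - (n_seg compliant segments) - pial
# node - lumped outlet element - outlet node. Exercises the solver without
# the generator.
line_network <- function(n_seg = 4, r0_mm = 1, L_mm = 10, E_Pa = 1.6e6,
                         config = model_config()) {
  n_nodes <- n_seg + 2L # inlet, interior..., pial, outlet
  nodes <- tibble::tibble(
    id = seq_len(n_nodes),
    x = seq(0, L_mm * n_seg + 2.5, length.out = n_nodes), y = 0, z = 0,
    role = c("inlet", rep("internal", n_seg - 1L), "pial", "outlet"),
    territory = "L-MCA"
  )
  segments <- tibble::tibble(
    seg_id = seq_len(n_seg + 1L),
    vessel_id = c(rep(1L, n_seg), 2L),
    from = seq_len(n_seg + 1L),
    to = seq_len(n_seg + 1L) + 1L,
    r0_mm = r0_mm, length_mm = c(rep(L_mm, n_seg), 2.5),
    E_Pa = E_Pa,
    type = c(rep("tree", n_seg), "outlet"),
    territory = "L-MCA",
    is_collateral = FALSE
  )
  outlets <- tibble::tibble(node = n_nodes, pial_node = n_nodes - 1L,
                            vessel = 2L, territory = "L-MCA",
                            resistance_Pa_s_ml = NA_real_)
  structure(list(
    nodes = nodes,
    vessels = tibble::tibble(
      id = 1:2, from = c(1L, n_nodes - 1L), to = c(n_nodes - 1L, n_nodes),
      r0_mm = r0_mm, length_mm = c(L_mm * n_seg, 2.5), E_Pa = E_Pa,
      type = c("tree", "outlet"), is_collateral = FALSE,
      territory = "L-MCA", name = NA_character_),
    segments = segments, outlets = outlets,
    meta = list(N_total = 1L, brain_volume_ml = 1390, config = config)
  ), class = "vascular_network")
}

# Random connected conductance network for oracle comparisons: a spanning
# tree plus extra edges, random conductances.
random_conductance_network <- function(n_nodes, n_extra = n_nodes, seed = 1) {
  withr::with_seed(seed, {
    from <- c(seq_len(n_nodes - 1L),
              sample.int(n_nodes, n_extra, replace = TRUE))
    to <- c(2:n_nodes, sample.int(n_nodes, n_extra, replace = TRUE))
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    G <- stats::runif(length(from), 0.1, 10)
    list(
      network = list(nodes = tibble::tibble(id = seq_len(n_nodes)),
                     segments = tibble::tibble(from = from, to = to)),
      from = from, to = to, G = G
    )
  })
}

# Independent dense-matrix oracle for the pinned Laplacian solve.
dense_pressure_oracle <- function(n, from, to, G, fixed_idx, fixed_val) {
  L <- matrix(0, n, n)
  for (k in seq_along(from)) {
    i <- from[k]; j <- to[k]
    L[i, j] <- L[i, j] - G[k]; L[j, i] <- L[j, i] - G[k]
    L[i, i] <- L[i, i] + G[k]; L[j, j] <- L[j, j] + G[k]
  }
  U <- setdiff(seq_len(n), fixed_idx)
  P <- numeric(n)
  P[fixed_idx] <- fixed_val
  P[U] <- solve(L[U, U], -L[U, fixed_idx, drop = FALSE] %*% fixed_val)
  P
}
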