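# Shared fixtures and independent oracles used across the suite.

# A small, fast profile for image tests: few cells, small image.
tiny_profile <- function(condition = "test", ...) {
  args <- list(condition_name = condition, cells_per_image = 4,
               nucleus_radius_mean = 12, nucleus_radius_sd = 1,
               fiber_count_mean = 2, fiber_length_mean = 30,
               fiber_length_sd = 4, noise_sd = 0)
  do.call(effect_profile, modifyList(args, list(...)))
}

# Concentric-circles fixture: nucleus centred in a circular cell.
concentric_profile <- function(...) {
  tiny_profile(condition = "concentric", cells_per_image = 1,
               nucleus_displacement_frac_mean = 0,
               nucleus_axis_ratio_mean = 1, nucleus_radius_sd = 0,
               fiber_count_mean = 0, ...)
}

# --- independent graph oracles (no igraph) ---------------------------------

# Random directed edge list on node names; plain base R.
random_edge_df <- function(n_nodes, p, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# Exhaustive simple-path enumeration by recursive DFS over an edge list.
brute_force_paths <- function(edges, source, target, max_len) {
  adj <- split(edges$to, edges$from)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == target && length(path) >= 2) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    if (length(path) - 1 >= max_len) return(invisible())
    for (nxt in adj[[last]]) {
      if (nxt %in% path) next
      if (nxt == target) out[[length(out) + 1]] <<- c(path, nxt)
      else walk(c(path, nxt))
    }
  }
  walk(source)
  unique(out)
}

# Undirected BFS distances from a set of start nodes over an edge list.
bfs_dist_from_set <- function(edges, nodes, start_set) {
  nbr <- lapply(setNames(nodes, nodes), function(v) {
    unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))
  })
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[start_set] <- 0
  frontier <- start_set
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(nbr[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# First-match assignment scoring oracle: c1 = on route, c2 = undirected
# distance 1 from the route, c3 = distance 2.
brute_force_score <- function(route, edges, nodes, ranked) {
  ranked <- unique(ranked)
  c1 <- sum(ranked %in% route)
  rest <- setdiff(intersect(ranked, nodes), route)
  dist <- bfs_dist_from_set(edges, nodes, route)
  c(c1 = c1, c2 = sum(dist[rest] == 1), c3 = sum(dist[rest] == 2))
}
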