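# Shared fixtures, all built in code.

# Hand-drawn element network used to exercise the osteoconnectivity gate:
# element 3 neighbors elements 1, 2 and 5; elements 2, 3 and 4 are the
# neighbors of element 1.
toy_adjacency <- function() {
  list(c(2L, 3L, 4L),      # 1
       c(1L, 3L),          # 2
       c(1L, 2L, 5L),      # 3
       c(1L),              # 4
       c(3L))              # 5
}

# Small porous quarter-slice used for ingrowth property tests:
# radius 2 mm anchor (a 20 x 20 cell cross-section at h = 0.1 mm).
small_porous_mesh <- function(seed = 3, porosity = 0.6, mean_um = 300,
                              h = 0.1) {
  dom <- generate_porous_domain(
    pore_spec(mean_um, 100, porosity, rng_seed = seed),
    anchor_radius = 2, slice_thickness = 2, bone_layer = 0.5)
  mesh_domain(dom, h, include_bone = FALSE)
}

# Domain with one pore open to the anchor surface and one isolated interior
# pore (a pore island by construction).
island_domain <- function() {
  generate_porous_domain(
    pore_spec(600, 100, 0.5, rng_seed = 1),
    anchor_radius = 2, slice_thickness = 2, bone_layer = 0.5,
    pores = data.frame(x = c(1.95, 0.8), y = c(0.3, 0.8),
                       diameter = c(600, 600)))
}

# Brute-force shared-edge adjacency: all element pairs, O(n^2).
brute_adjacency <- function(mesh) {
  nel <- nrow(mesh$elems)
  edges_of <- function(e) {
    v <- mesh$elems[e, ]
    n <- length(v)
    vapply(seq_len(n), function(a) {
      p <- sort(c(v[a], v[a %% n + 1]))
      paste(p, collapse = "-")
    }, character(1))
  }
  el <- lapply(seq_len(nel), edges_of)
  adj <- vector("list", nel)
  for (i in seq_len(nel)) {
    nb <- integer(0)
    for (j in seq_len(nel)) {
      if (i != j && length(intersect(el[[i]], el[[j]])) > 0) nb <- c(nb, j)
    }
    adj[[i]] <- sort(nb)
  }
  adj
}

# Brute-force BFS over VOID elements from the interface throats.
brute_reachable_void <- function(mesh) {
  void <- which(mesh$region == "VOID")
  seed <- intersect(mesh$interface$elements, void)
  seen <- rep(FALSE, nrow(mesh$elems))
  seen[seed] <- TRUE
  frontier <- seed
  while (length(frontier) > 0) {
    nxt <- unique(unlist(mesh$adjacency[frontier]))
    nxt <- nxt[!seen[nxt] & mesh$region[nxt] == "VOID"]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}
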