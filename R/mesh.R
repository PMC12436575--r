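# Structured background-grid (pixel/voxel) meshing of porous domains.
# Elements are labeled by centroid membership: a centroid inside any pore is
# VOID, inside the anchor disk ANCHOR, outside it BONE. This is the standard
# voxel-FEM approach of the bone remodeling literature; body-fitted meshing
# is out of scope.

.region_levels <- c("ANCHOR", "VOID", "BONE")

#' Mesh a porous domain on a structured background grid
#'
#' Rasterizes the quarter-slice geometry into square cells of side
#' `element_size` and labels each element by the region its centroid falls
#' in. 2D meshes use bilinear quadrilaterals by default (one adjacency layer
#' of elements then corresponds to one grid cell, the natural unit of the
#' ingrowth front); `element = "tri"` splits each cell into two linear
#' triangles. 3D domains are meshed with 8-node hexahedral voxels.
#'
#' The element size must resolve the pores: it is refused if it exceeds half
#' the smallest possible pore diameter of the domain's `pore_spec`.
#'
#' @param domain A [generate_porous_domain()] result.
#' @param element_size Grid seed size, mm (e.g. 0.05).
#' @param element `"quad"` (default) or `"tri"`; ignored for 3D domains.
#' @param include_bone Include the surrounding bone layer (default TRUE).
#'   Use `FALSE` for the anchor-only models of the ingrowth, compression and
#'   push-out stages.
#' @param keep_void Keep VOID elements in the mesh (default TRUE; the
#'   ingrowth model needs them as dummy material). `FALSE` removes them,
#'   which is useful for benchmark geometries with true holes.
#'
#' @return An object of class `fe_mesh`. Key fields: `nodes` (n x dim),
#'   `elems` (element connectivity), `region`, `centroid`, `volume` (mm^3,
#'   including the slice thickness in 2D), `adjacency` (osteoconnectivity
#'   neighbor lists), `boundary` (2D: boundary face table and node sets) and
#'   `interface` (interface face table and element ids).
#' @export
mesh_domain <- function(domain, element_size,
                        element = c("quad", "tri"),
                        include_bone = TRUE, keep_void = TRUE) {
  stopifnot(inherits(domain, "porous_domain"), element_size > 0)
  element <- match.arg(element)
  if (nrow(domain$pores) > 0) {
    min_d <- (domain$spec$mean_diameter - domain$spec$half_band) / 1000
    if (!is.null(domain$pores$diameter))
      min_d <- min(min_d, min(domain$pores$diameter) / 1000)
    if (element_size > min_d / 2 + 1e-12)
      stop(sprintf(paste0("element_size %.3g mm exceeds half the minimum ",
                          "pore diameter (%.3g mm); the geometry would be ",
                          "unresolved"), element_size, min_d))
  }
  if (domain$dim == 3) {
    return(.mesh_domain_3d(domain, element_size, include_bone, keep_void))
  }
  .mesh_domain_2d(domain, element_size, element, include_bone, keep_void)
}

.label_cells <- function(domain, grid) {
  R <- domain$anchor_radius
  region <- ifelse(grid$cx^2 + grid$cy^2 <= R^2, "ANCHOR", "BONE")
  void <- logical(length(grid$cx))
  if (nrow(domain$pores) > 0) {
    for (i in seq_len(nrow(domain$pores))) {
      p <- domain$pores[i, ]
      void[.cells_in_ball(grid, p$x, p$y, p$z %||% 0,
                          p$diameter / 2000)] <- TRUE
    }
  }
  region[void & region == "ANCHOR"] <- "VOID"
  region
}

.cell_grid <- function(ci, cj, ck, cx, cy, cz, s, nx, nz, dim) {
  lookup <- integer(nx * nx * nz)
  lookup[ci + (cj - 1L) * nx + (ck - 1L) * nx * nx] <- seq_along(cx)
  list(ci = ci, cj = cj, ck = ck, cx = cx, cy = cy, cz = cz,
       s = s, nx = nx, nz = nz, dim = dim, lookup = lookup)
}

.mesh_domain_2d <- function(domain, h, element, include_bone, keep_void) {
  R <- domain$anchor_radius
  extent <- R + if (include_bone) domain$bone_layer else 0
  nc <- ceiling(extent / h - 1e-9)
  ci <- rep(seq_len(nc), times = nc)
  cj <- rep(seq_len(nc), each = nc)
  ccx <- (ci - 0.5) * h
  ccy <- (cj - 0.5) * h
  keep <- ccx^2 + ccy^2 <= extent^2
  ci <- ci[keep]; cj <- cj[keep]; ccx <- ccx[keep]; ccy <- ccy[keep]
  grid <- .cell_grid(ci, cj, rep(1L, length(ci)), ccx, ccy,
                     rep(0, length(ci)), h, nc, 1L, 2L)
  region <- .label_cells(domain, grid)
  if (!keep_void) {
    k2 <- region != "VOID"
    ci <- ci[k2]; cj <- cj[k2]; ccx <- ccx[k2]; ccy <- ccy[k2]
    region <- region[k2]
  }
  ncell <- length(ci)
  if (ncell == 0) stop("empty mesh: element_size larger than the domain?")

  # grid node ids -> compact ids
  nn <- nc + 1L
  gn <- function(i, j) i + (j - 1L) * nn
  quad <- cbind(gn(ci, cj), gn(ci + 1L, cj), gn(ci + 1L, cj + 1L),
                gn(ci, cj + 1L))
  used <- sort(unique(as.vector(quad)))
  remap <- integer(nn * nn)
  remap[used] <- seq_along(used)
  quad[] <- remap[quad]
  ui <- (used - 1L) %% nn
  uj <- (used - 1L) %/% nn
  nodes <- cbind(x = ui * h, y = uj * h)

  if (element == "quad") {
    elems <- quad
    centroid <- cbind(ccx, ccy)
    volume <- rep(h * h * domain$slice_thickness, ncell)
    cell_of <- seq_len(ncell)
  } else {
    # split along the (n1, n3) diagonal; both halves stay counter-clockwise
    elems <- rbind(quad[, c(1, 2, 3)], quad[, c(1, 3, 4)])
    region <- rep(region, 2)
    centroid <- rbind(
      cbind(ccx + h / 6, ccy - h / 6),   # lower-right triangle
      cbind(ccx - h / 6, ccy + h / 6))   # upper-left triangle
    volume <- rep(h * h * domain$slice_thickness / 2, 2 * ncell)
    cell_of <- rep(seq_len(ncell), 2)
  }

  mesh <- structure(list(
    dim = 2L, elem_type = element, h = h,
    thickness = domain$slice_thickness,
    anchor_radius = R, bone_layer = domain$bone_layer,
    include_bone = include_bone,
    nodes = nodes, elems = elems, region = region,
    centroid = centroid, volume = volume,
    cell = cbind(i = ci[cell_of], j = cj[cell_of])), class = "fe_mesh")
  .finalize_mesh_2d(mesh, classify = "anchor")
}

# Edge machinery: adjacency, boundary faces with outward normals, interface.
.edge_table <- function(mesh) {
  el <- mesh$elems
  nel <- nrow(el)
  if (mesh$elem_type == "tri") {
    a <- c(el[, 1], el[, 2], el[, 3])
    b <- c(el[, 2], el[, 3], el[, 1])
    eid <- rep(seq_len(nel), 3)
  } else {
    a <- c(el[, 1], el[, 2], el[, 3], el[, 4])
    b <- c(el[, 2], el[, 3], el[, 4], el[, 1])
    eid <- rep(seq_len(nel), 4)
  }
  big <- nrow(mesh$nodes) + 1
  key <- pmin(a, b) * big + pmax(a, b)
  list(a = a, b = b, elem = eid, key = key)
}

.finalize_mesh_2d <- function(mesh, classify) {
  et <- .edge_table(mesh)
  o <- order(et$key)
  k <- et$key[o]
  dup_lead <- which(k[-1] == k[-length(k)])        # first of each shared pair
  e1 <- et$elem[o][dup_lead]
  e2 <- et$elem[o][dup_lead + 1]
  shared_a <- et$a[o][dup_lead]
  shared_b <- et$b[o][dup_lead]
  # boundary edges appear exactly once
  is_int <- logical(length(k))
  is_int[dup_lead] <- TRUE
  is_int[dup_lead + 1] <- TRUE
  bnd <- which(!is_int)
  ba <- et$a[o][bnd]; bb <- et$b[o][bnd]; belem <- et$elem[o][bnd]

  pairs <- cbind(e1, e2)
  adjacency <- .pairs_to_adj(pairs, nrow(mesh$elems))

  nx_ <- mesh$nodes[bb, 2] - mesh$nodes[ba, 2]     # ccw edge -> outward (dy,-dx)
  ny_ <- -(mesh$nodes[bb, 1] - mesh$nodes[ba, 1])
  len <- sqrt(nx_^2 + ny_^2)
  nx_ <- nx_ / len; ny_ <- ny_ / len
  mx <- (mesh$nodes[ba, 1] + mesh$nodes[bb, 1]) / 2
  my <- (mesh$nodes[ba, 2] + mesh$nodes[bb, 2]) / 2

  set <- .classify_faces(mesh, classify, mx, my, nx_, ny_)
  faces <- data.frame(elem = belem, n1 = ba, n2 = bb, nx = nx_, ny = ny_,
                      cx = mx, cy = my, len = len, set = set,
                      stringsAsFactors = FALSE)

  mesh$adjacency <- adjacency
  mesh$adj_pairs <- pairs
  mesh$boundary <- list(
    faces = faces,
    sym_x_nodes = which(abs(mesh$nodes[, 2]) < 1e-9),
    sym_y_nodes = which(abs(mesh$nodes[, 1]) < 1e-9),
    outer_nodes = sort(unique(c(faces$n1[faces$set == "outer"],
                                faces$n2[faces$set == "outer"]))))
  mesh$interface <- .build_interface_2d(mesh, e1, e2, shared_a, shared_b)
  mesh
}

.classify_faces <- function(mesh, classify, mx, my, nx_, ny_) {
  tol <- 1e-9
  if (classify == "rect") {
    w <- max(mesh$nodes[, 1]); hgt <- max(mesh$nodes[, 2])
    set <- rep("ymax", length(mx))
    set[abs(my) < tol] <- "ymin"
    set[abs(mx) < tol] <- "xmin"
    set[abs(mx - w) < tol] <- "xmax"
    set[abs(my - hgt) < tol & abs(mx) >= tol & abs(mx - w) >= tol] <- "ymax"
    return(set)
  }
  R <- mesh$anchor_radius
  r <- sqrt(mx^2 + my^2)
  set <- rep("inner", length(mx))
  if (mesh$include_bone) {
    set[r > R] <- "outer"
    set[r <= R] <- "interface"    # only present when voids are removed
  } else {
    set[r > R - 1.5 * mesh$h] <- "interface"
  }
  set[abs(my) < tol] <- "sym_x"
  set[abs(mx) < tol] <- "sym_y"
  set
}

# Interface face table: outward normals, lengths and cylinder-projected
# weights w = len * thickness * |n . r_hat| so that summed weights
# approximate the true cylindrical interface area despite the staircase.
.build_interface_2d <- function(mesh, e1, e2, sa, sb) {
  if (mesh$include_bone) {
    bone1 <- mesh$region[e1] == "BONE"
    bone2 <- mesh$region[e2] == "BONE"
    sel <- xor(bone1, bone2)
    if (!any(sel)) {
      return(list(faces = data.frame(), elements = integer(0), area = 0))
    }
    ea <- ifelse(bone1[sel], e2[sel], e1[sel])   # anchor-side element
    eb <- ifelse(bone1[sel], e1[sel], e2[sel])
    a <- sa[sel]; b <- sb[sel]
    dx <- mesh$nodes[b, 1] - mesh$nodes[a, 1]
    dy <- mesh$nodes[b, 2] - mesh$nodes[a, 2]
    len <- sqrt(dx^2 + dy^2)
    nx_ <- dy / len; ny_ <- -dx / len            # orient from anchor to bone
    dirx <- mesh$centroid[eb, 1] - mesh$centroid[ea, 1]
    diry <- mesh$centroid[eb, 2] - mesh$centroid[ea, 2]
    flip <- nx_ * dirx + ny_ * diry < 0
    nx_[flip] <- -nx_[flip]; ny_[flip] <- -ny_[flip]
    mx <- (mesh$nodes[a, 1] + mesh$nodes[b, 1]) / 2
    my <- (mesh$nodes[a, 2] + mesh$nodes[b, 2]) / 2
    faces <- data.frame(elem = ea, elem_bone = eb, n1 = a, n2 = b,
                        nx = nx_, ny = ny_, cx = mx, cy = my, len = len)
  } else {
    bf <- mesh$boundary$faces
    faces <- bf[bf$set == "interface",
                c("elem", "n1", "n2", "nx", "ny", "cx", "cy", "len")]
  }
  r <- sqrt(faces$cx^2 + faces$cy^2)
  rhx <- faces$cx / r; rhy <- faces$cy / r
  faces$w <- faces$len * mesh$thickness * abs(faces$nx * rhx + faces$ny * rhy)
  list(faces = faces, elements = sort(unique(faces$elem)),
       area = sum(faces$w))
}

.pairs_to_adj <- function(pairs, nel) {
  adj <- vector("list", nel)
  if (nrow(pairs) > 0) {
    from <- c(pairs[, 1], pairs[, 2])
    to <- c(pairs[, 2], pairs[, 1])
    o <- order(from)
    adj_s <- split(to[o], from[o])
    adj[as.integer(names(adj_s))] <- lapply(adj_s, function(v) sort(v))
  }
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(integer(0))
  adj
}

.mesh_domain_3d <- function(domain, h, include_bone, keep_void) {
  R <- domain$anchor_radius
  extent <- R + if (include_bone) domain$bone_layer else 0
  nc <- ceiling(extent / h - 1e-9)
  nz <- max(1L, ceiling(domain$slice_thickness / h - 1e-9))
  ci <- rep(seq_len(nc), times = nc)
  cj <- rep(seq_len(nc), each = nc)
  ccx <- (ci - 0.5) * h
  ccy <- (cj - 0.5) * h
  keep_xy <- ccx^2 + ccy^2 <= extent^2
  ci <- ci[keep_xy]; cj <- cj[keep_xy]
  ccx <- ccx[keep_xy]; ccy <- ccy[keep_xy]
  nxy <- length(ci)
  ci <- rep(ci, nz); cj <- rep(cj, nz)
  ck <- rep(seq_len(nz), each = nxy)
  ccx <- rep(ccx, nz); ccy <- rep(ccy, nz)
  ccz <- (ck - 0.5) * h
  grid <- .cell_grid(ci, cj, ck, ccx, ccy, ccz, h, nc, nz, 3L)
  region <- .label_cells(domain, grid)
  if (!keep_void) {
    k2 <- region != "VOID"
    ci <- ci[k2]; cj <- cj[k2]; ck <- ck[k2]
    ccx <- ccx[k2]; ccy <- ccy[k2]; ccz <- ccz[k2]
    region <- region[k2]
  }
  ncell <- length(ci)
  nn <- nc + 1L; nnz <- nz + 1L
  gn <- function(i, j, k) i + (j - 1L) * nn + (k - 1L) * nn * nn
  hex <- cbind(gn(ci, cj, ck), gn(ci + 1L, cj, ck),
               gn(ci + 1L, cj + 1L, ck), gn(ci, cj + 1L, ck),
               gn(ci, cj, ck + 1L), gn(ci + 1L, cj, ck + 1L),
               gn(ci + 1L, cj + 1L, ck + 1L), gn(ci, cj + 1L, ck + 1L))
  used <- sort(unique(as.vector(hex)))
  remap <- integer(nn * nn * nnz)
  remap[used] <- seq_along(used)
  hex[] <- remap[hex]
  ui <- (used - 1L) %% nn
  uj <- ((used - 1L) %/% nn) %% nn
  uk <- (used - 1L) %/% (nn * nn)
  nodes <- cbind(x = ui * h, y = uj * h, z = uk * h)

  # voxel face adjacency through grid arithmetic
  cid <- ci + (cj - 1) * (nc + 1) + (ck - 1) * (nc + 1)^2
  lookup <- integer(0)
  lookup[cid] <- seq_len(ncell)    # sparse-ish; NA elsewhere
  pair_dir <- function(di, dj, dk) {
    nid <- (ci + di) + (cj + dj - 1) * (nc + 1) + (ck + dk - 1) * (nc + 1)^2
    valid <- ci + di >= 1 & ci + di <= nc & cj + dj >= 1 & cj + dj <= nc &
      ck + dk >= 1 & ck + dk <= nz
    nid <- nid[valid]
    nb <- rep(NA_integer_, length(nid))
    inrange <- nid <= length(lookup)
    nb[inrange] <- lookup[nid[inrange]]
    cbind(which(valid)[!is.na(nb) & nb != 0],
          nb[!is.na(nb) & nb != 0])
  }
  pairs <- rbind(pair_dir(1, 0, 0), pair_dir(0, 1, 0), pair_dir(0, 0, 1))
  adjacency <- .pairs_to_adj(pairs, ncell)

  # interface elements: cells facing the lateral anchor surface (anchor-only)
  # or touching BONE cells (with bone layer)
  if (include_bone) {
    bone <- region == "BONE"
    touch <- (bone[pairs[, 1]] & !bone[pairs[, 2]])
    touch2 <- (!bone[pairs[, 1]] & bone[pairs[, 2]])
    iface_elems <- sort(unique(c(pairs[touch, 2], pairs[touch2, 1])))
  } else {
    # cells whose outward (+x or +y) ghost neighbor falls outside the disk
    out_xp <- ((ci + 0.5) * h)^2 + ((cj - 0.5) * h)^2 > R^2
    out_yp <- ((ci - 0.5) * h)^2 + ((cj + 0.5) * h)^2 > R^2
    iface_elems <- which(out_xp | out_yp)
  }
  structure(list(
    dim = 3L, elem_type = "hex", h = h, thickness = domain$slice_thickness,
    anchor_radius = R, bone_layer = domain$bone_layer,
    include_bone = include_bone,
    nodes = nodes, elems = hex, region = region,
    centroid = cbind(ccx, ccy, ccz), volume = rep(h^3, ncell),
    cell = cbind(i = ci, j = cj, k = ck),
    adjacency = adjacency, adj_pairs = pairs,
    interface = list(faces = data.frame(), elements = iface_elems,
                     area = NA_real_)), class = "fe_mesh")
}

#' Structured rectangular benchmark mesh
#'
#' A `nx` by `ny` grid of square elements of side `h`, all labeled ANCHOR.
#' Boundary face sets are `xmin`, `xmax`, `ymin`, `ymax`. Used for patch
#' tests and analytic benchmarks.
#'
#' @param nx,ny Number of cells per side.
#' @param h Element side, mm.
#' @param thickness Out-of-plane thickness, mm.
#' @param element `"quad"` or `"tri"`.
#' @return An `fe_mesh`.
#' @export
rect_mesh <- function(nx, ny, h = 1, thickness = 1,
                      element = c("quad", "tri")) {
  element <- match.arg(element)
  ci <- rep(seq_len(nx), times = ny)
  cj <- rep(seq_len(nx * 0 + ny), each = nx)
  nn <- nx + 1L
  gn <- function(i, j) i + (j - 1L) * nn
  quad <- cbind(gn(ci, cj), gn(ci + 1L, cj), gn(ci + 1L, cj + 1L),
                gn(ci, cj + 1L))
  nodes <- cbind(x = rep(0:nx, times = ny + 1) * h,
                 y = rep(0:ny, each = nx + 1) * h)
  ncell <- nx * ny
  if (element == "quad") {
    elems <- quad
    region <- rep("ANCHOR", ncell)
    centroid <- cbind((ci - 0.5) * h, (cj - 0.5) * h)
    volume <- rep(h * h * thickness, ncell)
    cell_of <- seq_len(ncell)
  } else {
    elems <- rbind(quad[, c(1, 2, 3)], quad[, c(1, 3, 4)])
    region <- rep("ANCHOR", 2 * ncell)
    centroid <- rbind(cbind((ci - 0.5) * h + h / 6, (cj - 0.5) * h - h / 6),
                      cbind((ci - 0.5) * h - h / 6, (cj - 0.5) * h + h / 6))
    volume <- rep(h * h * thickness / 2, 2 * ncell)
    cell_of <- rep(seq_len(ncell), 2)
  }
  mesh <- structure(list(
    dim = 2L, elem_type = element, h = h, thickness = thickness,
    anchor_radius = NA_real_, bone_layer = 0, include_bone = FALSE,
    nodes = nodes, elems = elems, region = region, centroid = centroid,
    volume = volume, cell = cbind(i = ci[cell_of], j = cj[cell_of])),
    class = "fe_mesh")
  .finalize_mesh_2d(mesh, classify = "rect")
}

#' @export
print.fe_mesh <- function(x, ...) {
  tab <- table(factor(x$region, levels = .region_levels))
  cat(sprintf("<fe_mesh> %dD %s mesh, h = %g mm: %d elements, %d nodes\n",
              x$dim, x$elem_type, x$h, nrow(x$elems), nrow(x$nodes)))
  cat(sprintf("  regions: ANCHOR %d, VOID %d, BONE %d; interface elements %d\n",
              tab["ANCHOR"], tab["VOID"], tab["BONE"],
              length(x$interface$elements)))
  invisible(x)
}

#' Element adjacency (the osteoconnectivity matrix)
#'
#' Neighbor lists by shared edge (2D) or shared face (3D voxels). The
#' structure is symmetric (`j` in `adj[[i]]` iff `i` in `adj[[j]]`) and
#' irreflexive. This is the matrix that gates sequential bone ingrowth: a
#' void element can densify only after a neighbor in this graph has.
#'
#' @param mesh An `fe_mesh`.
#' @return A list of sorted integer neighbor vectors, one per element.
#' @export
build_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"))
  if (mesh$dim == 3) return(mesh$adjacency)
  et <- .edge_table(mesh)
  o <- order(et$key)
  k <- et$key[o]
  dup <- which(k[-1] == k[-length(k)])
  .pairs_to_adj(cbind(et$elem[o][dup], et$elem[o][dup + 1]),
                nrow(mesh$elems))
}

#' Find pore islands
#'
#' Connected components of the VOID region (through the element adjacency
#' graph) that have no element on the bone-anchor interface. Bone cannot
#' reach such components, so they never capture ingrowth; they are flagged,
#' not treated as errors.
#'
#' @param mesh An `fe_mesh` with adjacency and interface information.
#' @return A list of integer vectors, one per island (element ids). Empty
#'   list if every void component reaches the interface or there are no
#'   voids.
#' @export
find_pore_islands <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"))
  void <- which(mesh$region == "VOID")
  if (length(void) == 0) return(list())
  pairs <- mesh$adj_pairs
  vp <- pairs[mesh$region[pairs[, 1]] == "VOID" &
                mesh$region[pairs[, 2]] == "VOID", , drop = FALSE]
  idx <- integer(nrow(mesh$elems))
  idx[void] <- seq_along(void)
  g <- igraph::make_empty_graph(n = length(void), directed = FALSE)
  if (nrow(vp) > 0) {
    g <- igraph::add_edges(g, rbind(idx[vp[, 1]], idx[vp[, 2]]))
  }
  comp <- igraph::components(g)
  iface <- intersect(mesh$interface$elements, void)
  reach <- unique(comp$membership[idx[iface]])
  islands <- lapply(setdiff(seq_len(comp$no), reach),
                    function(cm) void[comp$membership == cm])
  islands
}
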