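#' Threshold-segment a voxel image
#'
#' @param img a `voxel_image`.
#' @param threshold intensity cut; voxels with intensity >= threshold are
#'   foreground.
#' @return logical 3D array with `spacing`/`origin` attributes.
#' @export
segment_image <- function(img, threshold) {
  stopifnot(inherits(img, "voxel_image"))
  stopifnot_scalar(threshold)
  mask <- img$intensities >= threshold
  attr(mask, "spacing") <- img$spacing
  attr(mask, "origin") <- img$origin
  mask
}

#' Hexahedral mesh constructor
#'
#' Nodes in um; elements as 8-node connectivity in the usual trilinear
#' corner ordering (bottom face counter-clockwise, then top face), which
#' gives positive Jacobians on voxel bricks.
#' @param nodes numeric matrix n x 3, um.
#' @param elements integer matrix E x 8.
#' @param element_size length-3 (or scalar) nominal element edge length, um.
#' @param region_labels optional per-element region tag.
#' @return object of class `hex_mesh`.
#' @export
hex_mesh <- function(nodes, elements, element_size,
                     region_labels = NULL) {
  nodes <- as.matrix(nodes)
  elements <- matrix(as.integer(as.matrix(elements)), nrow = nrow(elements))
  stopifnot(ncol(nodes) == 3L, ncol(elements) == 8L,
            all(element_size > 0))
  if (length(element_size) == 1L) element_size <- rep(element_size, 3L)
  if (!is.null(region_labels)) stopifnot(length(region_labels) == nrow(elements))
  structure(list(nodes = nodes, elements = elements,
                 element_size = element_size,
                 region_labels = region_labels),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh> %d nodes, %d hexahedra, element size %s um\n",
              nrow(x$nodes), nrow(x$elements),
              paste(signif(x$element_size, 4), collapse = "x")))
  invisible(x)
}

# reference shape-function derivatives dN/dxi at a natural point (8 x 3)
hex_dshape <- function(xi) {
  sg <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                 -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
               8, 3, byrow = TRUE)
  d <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- sg[a, ]
    d[a, 1] <- s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]) / 8
    d[a, 2] <- (1 + s[1] * xi[1]) * s[2] * (1 + s[3] * xi[3]) / 8
    d[a, 3] <- (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) * s[3] / 8
  }
  d
}

hex_shape <- function(xi) {
  sg <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                 -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
               8, 3, byrow = TRUE)
  (1 + sg[, 1] * xi[1]) * (1 + sg[, 2] * xi[2]) * (1 + sg[, 3] * xi[3]) / 8
}

# per-element Jacobian determinants at the given natural points, vectorized
# over elements; returns E x length(points) matrix
hex_jacobians_at <- function(mesh, points = list(c(0, 0, 0))) {
  E <- nrow(mesh$elements)
  out <- matrix(0, E, length(points))
  X <- lapply(1:3, function(a) {
    matrix(mesh$nodes[mesh$elements, a], E, 8)
  })
  for (p in seq_along(points)) {
    d <- hex_dshape(points[[p]])
    J <- vector("list", 9)
    k <- 1
    for (a in 1:3) for (b in 1:3) {
      J[[k]] <- X[[a]] %*% d[, b, drop = FALSE]
      k <- k + 1
    }
    # J index (a,b): k = (a-1)*3 + b
    out[, p] <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
      J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
      J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  }
  out
}

#' Per-element Jacobian determinants (centroid) of a hex mesh
#' @param mesh a `hex_mesh`.
#' @return numeric vector of centroid Jacobian determinants (um^3 / 8).
#' @export
hex_jacobians <- function(mesh) {
  as.vector(hex_jacobians_at(mesh, list(c(0, 0, 0))))
}

#' Per-element volumes by 2x2x2 Gauss integration (exact for trilinear hexes)
#' @param mesh a `hex_mesh`.
#' @return numeric vector of element volumes, um^3.
#' @export
hex_volumes <- function(mesh) {
  g <- 1 / sqrt(3)
  pts <- lapply(seq_len(8), function(i) {
    c((-1)^((i - 1) %% 2), (-1)^(((i - 1) %/% 2) %% 2),
      (-1)^((i - 1) %/% 4)) * g
  })
  rowSums(hex_jacobians_at(mesh, pts))
}

#' Build a hexahedral mesh from a binary voxel mask
#'
#' Coarse cells of `coarsen`^3 voxels become one element when at least
#' `min_fill` of their voxels are foreground (majority vote by default).
#' Shared nodes are merged exactly through integer lattice indexing.
#'
#' @param mask logical 3D array (from [segment_image()]), or any 3D array
#'   coercible to logical.
#' @param spacing voxel spacing, um; defaults to the mask's attribute.
#' @param coarsen integer >= 1, voxels per element edge.
#' @param origin mesh origin, um.
#' @param min_fill inclusion fraction for a coarse cell.
#' @return a [hex_mesh()].
#' @export
voxelize <- function(mask, spacing = attr(mask, "spacing"), coarsen = 1L,
                     origin = attr(mask, "origin") %||% c(0, 0, 0),
                     min_fill = 0.5) {
  stopifnot(length(dim(mask)) == 3L, coarsen >= 1)
  coarsen <- as.integer(coarsen)
  if (is.null(spacing)) stop("voxel spacing must be supplied")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dims <- dim(mask)
  nc <- as.integer(ceiling(dims / coarsen))
  # coarse cell id per voxel (0-based per axis), vectorized tabulation
  cix <- (seq_len(dims[1]) - 1L) %/% coarsen
  ciy <- (seq_len(dims[2]) - 1L) %/% coarsen
  ciz <- (seq_len(dims[3]) - 1L) %/% coarsen
  cell <- 1L + rep(cix, times = dims[2] * dims[3]) +
    nc[1] * rep(rep(ciy, each = dims[1]), times = dims[3]) +
    nc[1] * nc[2] * rep(ciz, each = dims[1] * dims[2])
  ncell <- prod(nc)
  fg <- tabulate(cell[as.logical(mask)], nbins = ncell)
  tot <- tabulate(cell, nbins = ncell)
  keep <- which(fg >= min_fill * tot & tot > 0)
  if (length(keep) == 0L) stop("voxelize: empty mesh (no foreground cells)")
  k0 <- keep - 1L
  i <- k0 %% nc[1]
  j <- (k0 %/% nc[1]) %% nc[2]
  k <- k0 %/% (nc[1] * nc[2])
  np1 <- nc + 1L
  corner_key <- function(ci, cj, ck) 1L + ci + np1[1] * (cj + np1[2] * ck)
  conn_keys <- cbind(corner_key(i,     j,     k),
                     corner_key(i + 1L, j,     k),
                     corner_key(i + 1L, j + 1L, k),
                     corner_key(i,     j + 1L, k),
                     corner_key(i,     j,     k + 1L),
                     corner_key(i + 1L, j,     k + 1L),
                     corner_key(i + 1L, j + 1L, k + 1L),
                     corner_key(i,     j + 1L, k + 1L))
  used_keys <- sort(unique(as.vector(conn_keys)))
  remap <- integer(prod(np1))
  remap[used_keys] <- seq_along(used_keys)
  elements <- matrix(remap[conn_keys], ncol = 8L)
  uk0 <- used_keys - 1L
  gi <- uk0 %% np1[1]
  gj <- (uk0 %/% np1[1]) %% np1[2]
  gk <- uk0 %/% (np1[1] * np1[2])
  nodes <- cbind(origin[1] + gi * spacing[1] * coarsen,
                 origin[2] + gj * spacing[2] * coarsen,
                 origin[3] + gk * spacing[3] * coarsen)
  hex_mesh(nodes, elements, spacing * coarsen)
}

# local corner indices of the six faces of a hex (VTK-ordered corners)
.hex_faces <- matrix(c(1, 2, 3, 4,
                       5, 6, 7, 8,
                       1, 2, 6, 5,
                       2, 3, 7, 6,
                       3, 4, 8, 7,
                       4, 1, 5, 8), 6, 4, byrow = TRUE)

# boundary quad faces (rows of global node ids) of a hex mesh
boundary_quads <- function(mesh) {
  E <- nrow(mesh$elements)
  quads <- do.call(rbind, lapply(1:6, function(f) {
    mesh$elements[, .hex_faces[f, ], drop = FALSE]
  }))
  key <- apply(quads, 1, function(r) paste(sort(r), collapse = "_"))
  quads[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Laplacian smoothing of the outer mesh surface
#'
#' Moves boundary nodes toward the mean of their boundary-edge neighbours,
#' rescaling the boundary about the mesh centroid each iteration to hold the
#' total volume; interior nodes and connectivity are untouched. Fails if any
#' element Jacobian becomes non-positive or if the volume drifts by more
#' than 5%.
#'
#' @param mesh a `hex_mesh`.
#' @param iterations number of smoothing sweeps (0 = identity).
#' @param strength relaxation factor in (0, 1\].
#' @return the smoothed `hex_mesh`.
#' @export
smooth_outer_surface <- function(mesh, iterations = 5L, strength = 0.5) {
  stopifnot(inherits(mesh, "hex_mesh"), iterations >= 0, strength > 0,
            strength <= 1)
  if (iterations == 0L) return(mesh)
  quads <- boundary_quads(mesh)
  bnodes <- sort(unique(as.vector(quads)))
  edges <- rbind(quads[, c(1, 2)], quads[, c(2, 3)],
                 quads[, c(3, 4)], quads[, c(4, 1)])
  edges <- unique(rbind(edges, edges[, 2:1]))
  v0 <- sum(hex_volumes(mesh))
  ctr <- colMeans(mesh$nodes)
  pos <- mesh$nodes
  for (it in seq_len(iterations)) {
    sums <- rowsum(pos[edges[, 2], , drop = FALSE], edges[, 1])
    cnt <- as.vector(rowsum(rep(1, nrow(edges)), edges[, 1]))
    ids <- as.integer(rownames(sums))
    target <- sums / cnt
    pos[ids, ] <- (1 - strength) * pos[ids, ] + strength * target
    m2 <- mesh
    m2$nodes <- pos
    v <- sum(hex_volumes(m2))
    f <- (v0 / v)^(1 / 3)
    pos[bnodes, ] <- sweep(sweep(pos[bnodes, , drop = FALSE], 2, ctr) * f,
                           2, ctr, `+`)
    m2$nodes <- pos
    jac <- hex_jacobians_at(m2, list(c(0, 0, 0)))
    if (any(jac <= 0)) {
      stop("smoothing inverted element ", which(jac <= 0)[1],
           " at iteration ", it)
    }
  }
  out <- mesh
  out$nodes <- pos
  vfin <- sum(hex_volumes(out))
  if (abs(vfin - v0) / v0 > 0.05) {
    stop("smoothing changed mesh volume by more than 5% (",
         signif(100 * abs(vfin - v0) / v0, 3), "%)")
  }
  out
}

#' Beam mesh constructor
#' @param nodes data.frame with x, y, z, radius (um).
#' @param elements data.frame with node_a, node_b, source_segment.
#' @return object of class `beam_mesh`.
#' @export
beam_mesh <- function(nodes, elements) {
  stopifnot(all(c("x", "y", "z", "radius") %in% names(nodes)),
            all(c("node_a", "node_b") %in% names(elements)))
  if (any(nodes$radius <= 0)) stop("beam nodal radii must be > 0")
  structure(list(nodes = nodes, elements = elements), class = "beam_mesh")
}

#' @export
print.beam_mesh <- function(x, ...) {
  cat(sprintf("<beam_mesh> %d nodes, %d beam elements\n",
              nrow(x$nodes), nrow(x$elements)))
  invisible(x)
}

beam_lengths <- function(beams) {
  a <- beams$elements$node_a
  b <- beams$elements$node_b
  sqrt((beams$nodes$x[a] - beams$nodes$x[b])^2 +
       (beams$nodes$y[a] - beams$nodes$y[b])^2 +
       (beams$nodes$z[a] - beams$nodes$z[b])^2)
}

beam_volumes <- function(beams) {
  ra <- beams$nodes$radius[beams$elements$node_a]
  rb <- beams$nodes$radius[beams$elements$node_b]
  pi * beam_lengths(beams) / 3 * (ra^2 + ra * rb + rb^2)
}

#' Discretize a vessel network into two-node beam elements
#'
#' Each network segment is split into `ceiling(length / max_len)` beams with
#' nodal radii linearly interpolated along the segment; the summed beam
#' length conserves the segment length.
#'
#' @param net a `vessel_network`.
#' @param max_len maximum beam element length, um.
#' @return a [beam_mesh()] whose elements carry their source segment id.
#' @export
discretize_network <- function(net, max_len) {
  stopifnot(inherits(net, "vessel_network"), max_len > 0)
  lens <- segment_lengths(net)
  nsub <- pmax(1L, as.integer(ceiling(lens / max_len)))
  nodes <- data.frame(x = net$nodes$x, y = net$nodes$y, z = net$nodes$z,
                      radius = net$nodes$radius)
  ea <- integer(0); eb <- integer(0); src <- integer(0)
  for (s in seq_len(nrow(net$segments))) {
    ia <- net$segments$node_a[s]
    ib <- net$segments$node_b[s]
    n <- nsub[s]
    if (n == 1L) {
      ea <- c(ea, ia); eb <- c(eb, ib); src <- c(src, s)
      next
    }
    t <- seq_len(n - 1L) / n
    new_idx <- nrow(nodes) + seq_len(n - 1L)
    nodes <- rbind(nodes, data.frame(
      x = net$nodes$x[ia] + t * (net$nodes$x[ib] - net$nodes$x[ia]),
      y = net$nodes$y[ia] + t * (net$nodes$y[ib] - net$nodes$y[ia]),
      z = net$nodes$z[ia] + t * (net$nodes$z[ib] - net$nodes$z[ia]),
      radius = net$nodes$radius[ia] +
        t * (net$nodes$radius[ib] - net$nodes$radius[ia])))
    chain <- c(ia, new_idx, ib)
    ea <- c(ea, chain[-length(chain)])
    eb <- c(eb, chain[-1])
    src <- c(src, rep(s, n))
  }
  rownames(nodes) <- NULL
  beam_mesh(nodes, data.frame(node_a = ea, node_b = eb,
                              source_segment = src))
}

#' Submodel specification
#' @param box_min,box_max corners of the axis-aligned region of interest, um.
#' @param refinement integer subdivision factor per axis.
#' @param allow_small suppress the warning when the refined element size
#'   falls below the 20 um floor.
#' @return object of class `submodel_spec`.
#' @export
submodel_spec <- function(box_min, box_max, refinement = 2L,
                          allow_small = FALSE) {
  stopifnot(length(box_min) == 3L, length(box_max) == 3L,
            all(box_max > box_min), refinement >= 1)
  structure(list(box_min = box_min, box_max = box_max,
                 refinement = as.integer(refinement),
                 allow_small = allow_small),
            class = "submodel_spec")
}

#' Extract a refined submodel from a macro mesh
#'
#' Parent elements lying fully inside the box are split `refinement`^3-fold;
#' beams are clipped to the box with cut-point nodes inserted (radii
#' interpolated at the cut); every refined node is linked back to its parent
#' element and trilinear natural coordinates, and the nodes on the box
#' boundary are flagged for displacement boundary conditions.
#'
#' @param mesh parent `hex_mesh`.
#' @param beams parent `beam_mesh` (may be `NULL`).
#' @param spec a [submodel_spec()].
#' @return list with `mesh`, `beams`, `boundary` (data.frame: node,
#'   parent_element, xi1..xi3), `parent_elements`, `spec`.
#' @export
extract_submodel <- function(mesh, beams, spec) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(spec, "submodel_spec"))
  tol <- 1e-9 * max(abs(c(spec$box_min, spec$box_max, 1)))
  nx <- mesh$nodes
  inside_node <- nx[, 1] >= spec$box_min[1] - tol &
    nx[, 2] >= spec$box_min[2] - tol & nx[, 3] >= spec$box_min[3] - tol &
    nx[, 1] <= spec$box_max[1] + tol & nx[, 2] <= spec$box_max[2] + tol &
    nx[, 3] <= spec$box_max[3] + tol
  in_elem <- which(rowSums(matrix(inside_node[mesh$elements],
                                  nrow(mesh$elements), 8)) == 8L)
  if (length(in_elem) == 0L) stop("submodel box contains no parent element")
  r <- spec$refinement
  sub_size <- mesh$element_size / r
  if (any(sub_size < 20) && !spec$allow_small) {
    warning("refined element size ", paste(signif(sub_size, 4), collapse = "x"),
            " um is below the 20 um floor")
  }
  key_env <- new.env(hash = TRUE)
  nodes <- list(); parent_of <- list(); xi_of <- list()
  n_nodes <- 0L
  node_id <- function(pos, pe, xi) {
    key <- paste(round(pos / 1e-6), collapse = "_")
    id <- key_env[[key]]
    if (is.null(id)) {
      n_nodes <<- n_nodes + 1L
      id <- n_nodes
      key_env[[key]] <- id
      nodes[[id]] <<- pos
      parent_of[[id]] <<- pe
      xi_of[[id]] <<- xi
    }
    id
  }
  elems <- matrix(0L, length(in_elem) * r^3, 8L)
  labels <- if (is.null(mesh$region_labels)) NULL else
    rep(mesh$region_labels[in_elem], each = r^3)
  erow <- 0L
  fr <- (0:r) / r
  for (pe in in_elem) {
    Xe <- mesh$nodes[mesh$elements[pe, ], , drop = FALSE]
    # lattice of (r+1)^3 sub-node ids for this parent
    lat <- array(0L, c(r + 1, r + 1, r + 1))
    for (kk in 0:r) for (jj in 0:r) for (ii in 0:r) {
      xi <- 2 * c(fr[ii + 1], fr[jj + 1], fr[kk + 1]) - 1
      pos <- as.vector(crossprod(hex_shape(xi), Xe))
      lat[ii + 1, jj + 1, kk + 1] <- node_id(pos, pe, xi)
    }
    for (kk in 1:r) for (jj in 1:r) for (ii in 1:r) {
      erow <- erow + 1L
      elems[erow, ] <- c(lat[ii, jj, kk], lat[ii + 1, jj, kk],
                         lat[ii + 1, jj + 1, kk], lat[ii, jj + 1, kk],
                         lat[ii, jj, kk + 1], lat[ii + 1, jj, kk + 1],
                         lat[ii + 1, jj + 1, kk + 1], lat[ii, jj + 1, kk + 1])
    }
  }
  node_mat <- do.call(rbind, nodes)
  sub_mesh <- hex_mesh(node_mat, elems, sub_size, labels)
  # boundary nodes: on the exterior surface of the refined mesh
  bquads <- boundary_quads(sub_mesh)
  bnd_nodes <- sort(unique(as.vector(bquads)))
  boundary <- data.frame(node = bnd_nodes,
                         parent_element = unlist(parent_of)[bnd_nodes],
                         xi1 = vapply(xi_of[bnd_nodes], `[`, 0, 1),
                         xi2 = vapply(xi_of[bnd_nodes], `[`, 0, 2),
                         xi3 = vapply(xi_of[bnd_nodes], `[`, 0, 3))
  sub_beams <- NULL
  if (!is.null(beams)) {
    sub_beams <- clip_beams_to_box(beams, spec$box_min, spec$box_max)
  }
  list(mesh = sub_mesh, beams = sub_beams, boundary = boundary,
       parent_elements = in_elem, spec = spec)
}

# slab-method clipping of beam elements to an axis-aligned box, radii
# interpolated at the cut points
clip_beams_to_box <- function(beams, box_min, box_max) {
  pa <- as.matrix(beams$nodes[beams$elements$node_a, c("x", "y", "z")])
  pb <- as.matrix(beams$nodes[beams$elements$node_b, c("x", "y", "z")])
  ra <- beams$nodes$radius[beams$elements$node_a]
  rb <- beams$nodes$radius[beams$elements$node_b]
  key_env <- new.env(hash = TRUE)
  nodes <- list(); n_nodes <- 0L
  node_id <- function(pos, rad) {
    key <- paste(round(pos / 1e-6), collapse = "_")
    id <- key_env[[key]]
    if (is.null(id)) {
      n_nodes <<- n_nodes + 1L
      id <- n_nodes
      key_env[[key]] <- id
      nodes[[id]] <<- c(pos, rad)
    }
    id
  }
  ea <- integer(0); eb <- integer(0); src <- integer(0)
  for (e in seq_len(nrow(pa))) {
    d <- pb[e, ] - pa[e, ]
    t0 <- 0; t1 <- 1
    for (ax in 1:3) {
      if (abs(d[ax]) < 1e-300) {
        if (pa[e, ax] < box_min[ax] || pa[e, ax] > box_max[ax]) {
          t0 <- 1; t1 <- 0
          break
        }
      } else {
        ta <- (box_min[ax] - pa[e, ax]) / d[ax]
        tb <- (box_max[ax] - pa[e, ax]) / d[ax]
        t0 <- max(t0, min(ta, tb))
        t1 <- min(t1, max(ta, tb))
      }
    }
    if (t1 <= t0) next
    qa <- pa[e, ] + t0 * d
    qb <- pa[e, ] + t1 * d
    ia <- node_id(qa, ra[e] + t0 * (rb[e] - ra[e]))
    ib <- node_id(qb, ra[e] + t1 * (rb[e] - ra[e]))
    if (ia == ib) next
    ea <- c(ea, ia); eb <- c(eb, ib)
    src <- c(src, beams$elements$source_segment[e] %||% e)
  }
  if (length(ea) == 0L) return(NULL)
  nm <- do.call(rbind, nodes)
  beam_mesh(data.frame(x = nm[, 1], y = nm[, 2], z = nm[, 3],
                       radius = nm[, 4]),
            data.frame(node_a = ea, node_b = eb, source_segment = src))
}
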