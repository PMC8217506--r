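#' Construct a voxel image
#'
#' A 3D scalar intensity volume with voxel spacing (um per voxel per axis)
#' and an origin (um position of the corner of voxel \[1,1,1\]).
#' @param intensities 3D numeric array.
#' @param spacing length-1 or length-3 positive spacing, um.
#' @param origin length-3 origin, um.
#' @return object of class `voxel_image`.
#' @export
voxel_image <- function(intensities, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  if (!all(is.finite(intensities))) stop("voxel intensities must be finite")
  structure(list(intensities = intensities, spacing = spacing,
                 origin = origin),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("<voxel_image> %s voxels, spacing %s um\n",
              paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Generate a synthetic tissue-block intensity volume
#'
#' Stand-in for a segmented high-resolution imaging stack: tissue foreground
#' is strictly above the default segmentation threshold, background strictly
#' below it. `shape = "block"` fills the whole domain (optionally with a
#' smooth inset boundary), `shape = "sphere"` fills a ball of `sphere_radius`
#' centred in the domain. When a network and `vessel_channel = TRUE` are
#' given, voxels within a nodal radius of a segment centreline are marked
#' with `vessel_intensity`.
#'
#' @param domain_size length-3 domain, um.
#' @param spacing voxel spacing, um (default 5.92, the emulated stack
#'   resolution).
#' @param net optional `vessel_network` for the vessel channel.
#' @param seed seed for the intensity noise.
#' @param shape "block" or "sphere".
#' @param sphere_radius radius in um for `shape = "sphere"`.
#' @param boundary_margin inset of the smooth block boundary, um (0 = fill
#'   the whole domain).
#' @param foreground,background,noise_sd intensity levels.
#' @param vessel_channel logical; rasterize the network.
#' @param vessel_intensity intensity written into vessel voxels.
#' @return a `voxel_image`.
#' @export
generate_tissue_image <- function(domain_size, spacing = 5.92, net = NULL,
                                  seed = 1L,
                                  shape = c("block", "sphere"),
                                  sphere_radius = NULL,
                                  boundary_margin = 0,
                                  foreground = 200, background = 10,
                                  noise_sd = 5,
                                  vessel_channel = FALSE,
                                  vessel_intensity = 255) {
  shape <- match.arg(shape)
  stopifnot(length(domain_size) == 3L, all(domain_size > 0), spacing > 0)
  dims <- pmax(1L, as.integer(round(domain_size / spacing)))
  cx <- (seq_len(dims[1]) - 0.5) * spacing
  cy <- (seq_len(dims[2]) - 0.5) * spacing
  cz <- (seq_len(dims[3]) - 0.5) * spacing
  img <- array(background, dim = dims)
  if (shape == "sphere") {
    if (is.null(sphere_radius)) sphere_radius <- min(domain_size) / 2
    ctr <- domain_size / 2
    d2 <- outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, `+`),
                (cz - ctr[3])^2, `+`)
    img[d2 <= sphere_radius^2] <- foreground
  } else if (boundary_margin <= 0) {
    img[] <- foreground
  } else {
    m <- boundary_margin
    # distance to the inset box boundary, smooth roll-off across the margin
    dx <- pmin(cx, domain_size[1] - cx)
    dy <- pmin(cy, domain_size[2] - cy)
    dz <- pmin(cz, domain_size[3] - cz)
    dmin <- outer(outer(dx, dy, pmin), dz, pmin)
    w <- pmin(1, pmax(0, dmin / m))
    ss <- w * w * (3 - 2 * w)  # smoothstep roll-off across the margin
    img[] <- background + (foreground - background) * ss
  }
  if (noise_sd > 0) {
    with_seed(seed, {
      img <- img + array(rnorm(prod(dims), 0, noise_sd), dims)
    })
  }
  if (!is.null(net) && vessel_channel) {
    if (spacing > 2 * min(net$nodes$radius)) {
      warning("voxel spacing coarser than the smallest vessel radius; ",
              "some vessels may not be rasterized")
    }
    img <- rasterize_network(img, net, spacing, vessel_intensity)
  }
  voxel_image(img, spacing)
}

# paint voxels whose centre lies within the local vessel radius of a segment
rasterize_network <- function(img, net, spacing, value) {
  dims <- dim(img)
  for (s in seq_len(nrow(net$segments))) {
    a <- as.numeric(net$nodes[net$segments$node_a[s], c("x", "y", "z")])
    b <- as.numeric(net$nodes[net$segments$node_b[s], c("x", "y", "z")])
    ra <- net$nodes$radius[net$segments$node_a[s]]
    rb <- net$nodes$radius[net$segments$node_b[s]]
    rmax <- max(ra, rb)
    lo <- pmax(1L, floor((pmin(a, b) - rmax) / spacing))
    hi <- pmin(dims, ceiling((pmax(a, b) + rmax) / spacing))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    g <- expand.grid(x = (ix - 0.5) * spacing, y = (iy - 0.5) * spacing,
                     z = (iz - 0.5) * spacing)
    ab <- b - a
    l2 <- sum(ab^2)
    t <- pmin(1, pmax(0, ((g$x - a[1]) * ab[1] + (g$y - a[2]) * ab[2] +
                            (g$z - a[3]) * ab[3]) / l2))
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]; pz <- a[3] + t * ab[3]
    r_here <- ra + t * (rb - ra)
    hit <- (g$x - px)^2 + (g$y - py)^2 + (g$z - pz)^2 <= r_here^2
    if (any(hit)) {
      idx <- expand.grid(ix, iy, iz)[hit, , drop = FALSE]
      img[as.matrix(idx)] <- value
    }
  }
  img
}

#' Write / read a voxel image as a raw array with a JSON sidecar
#'
#' The intensities go to a flat text array (one value per line, x fastest);
#' dimensions, spacing and origin go to `<path>.json`.
#' @param img a `voxel_image`.
#' @param path output path for the array file.
#' @return written path, invisibly.
#' @export
write_voxel_image <- function(img, path) {
  writeLines(format(as.vector(img$intensities), digits = 17), path)
  jsonlite::write_json(list(dim = dim(img$intensities),
                            spacing = img$spacing, origin = img$origin),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- as.numeric(readLines(path))
  voxel_image(array(v, dim = meta$dim), meta$spacing, meta$origin)
}
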