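#' Default calibration for the synthetic angioarchitecture generator
#'
#' The reconstructed rodent angioarchitecture this generator emulates has
#' vessel diameters between 10 and 100 um with a mean of 17.85 um and a
#' vascular volume fraction of 5.4%. Diameters follow a lognormal law
#' truncated to \[10, 100\] um whose location parameter is solved numerically
#' so that the truncated mean equals `diameter_mean`.
#'
#' @param volume_fraction target vessel volume / domain volume (default 0.054).
#' @param diameter_mean target mean vessel diameter, um.
#' @param diameter_range hard truncation bounds on the diameter, um.
#' @param diameter_sdlog log-scale spread of the lognormal diameter law.
#' @param segment_length_mean,segment_length_sd segment length law, um.
#' @param bifurcation_prob probability that a growing tip bifurcates after
#'   laying down a segment.
#' @param bifurcation_angle,bifurcation_angle_sd branch angle law, degrees.
#' @param direction_noise tip direction perturbation per step (radians sd).
#' @param murray_exponent radius-decay exponent used when `murray_taper` is
#'   enabled; with the default iid nodal diameters it is unused.
#' @param murray_taper logical; decay radii down the tree instead of drawing
#'   iid nodal diameters (morphological mode, not calibrated to the printed
#'   diameter statistics).
#' @param cross_link_fraction fraction of extra capillary cross-link segments
#'   added after tree growth.
#' @param max_active_tips cap on simultaneously growing tips.
#' @return a named list of class `vessel_calibration`.
#' @export
vessel_calibration <- function(volume_fraction = 0.054,
                               diameter_mean = 17.85,
                               diameter_range = c(10, 100),
                               diameter_sdlog = 0.45,
                               segment_length_mean = 60,
                               segment_length_sd = 15,
                               bifurcation_prob = 0.25,
                               bifurcation_angle = 35,
                               bifurcation_angle_sd = 10,
                               direction_noise = 0.25,
                               murray_exponent = 3,
                               murray_taper = FALSE,
                               cross_link_fraction = 0.02,
                               max_active_tips = 512) {
  stopifnot(volume_fraction > 0, diameter_mean > 0,
            length(diameter_range) == 2L, diameter_range[1] > 0,
            diameter_range[2] > diameter_range[1],
            diameter_mean > diameter_range[1],
            diameter_mean < diameter_range[2])
  cal <- list(volume_fraction = volume_fraction,
              diameter_mean = diameter_mean,
              diameter_range = diameter_range,
              diameter_sdlog = diameter_sdlog,
              diameter_meanlog = truncated_lognormal_meanlog(
                diameter_mean, diameter_sdlog, diameter_range[1],
                diameter_range[2]),
              segment_length_mean = segment_length_mean,
              segment_length_sd = segment_length_sd,
              bifurcation_prob = bifurcation_prob,
              bifurcation_angle = bifurcation_angle,
              bifurcation_angle_sd = bifurcation_angle_sd,
              direction_noise = direction_noise,
              murray_exponent = murray_exponent,
              murray_taper = murray_taper,
              cross_link_fraction = cross_link_fraction,
              max_active_tips = max_active_tips)
  class(cal) <- "vessel_calibration"
  cal
}

# location parameter of a lognormal whose [lower, upper]-truncated mean equals
# `target`; closed-form truncated moments + uniroot
truncated_lognormal_meanlog <- function(target, sdlog, lower, upper) {
  tmean <- function(mu) {
    za <- (log(lower) - mu) / sdlog
    zb <- (log(upper) - mu) / sdlog
    exp(mu + sdlog^2 / 2) *
      (pnorm(zb - sdlog) - pnorm(za - sdlog)) / (pnorm(zb) - pnorm(za))
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 interval = log(c(lower / 2, upper)),
                 tol = 1e-12)$root
}

sample_diameters <- function(n, cal) {
  lo <- plnorm(cal$diameter_range[1], cal$diameter_meanlog, cal$diameter_sdlog)
  hi <- plnorm(cal$diameter_range[2], cal$diameter_meanlog, cal$diameter_sdlog)
  qlnorm(runif(n, lo, hi), cal$diameter_meanlog, cal$diameter_sdlog)
}

#' Generate a synthetic branching vascular network
#'
#' Grows a forest of bifurcating, tortuous vessel trees inside a rectangular
#' domain until the target vascular volume fraction is reached, then adds a
#' small number of capillary cross-links. Nodal diameters are drawn iid from
#' the calibrated truncated lognormal so the printed diameter statistics
#' (mean, hard bounds) hold by construction; segment volumes are conical
#' frustra between the two nodal radii.
#'
#' @param domain_size length-3 vector, um.
#' @param calibration a [vessel_calibration()] object.
#' @param seed integer seed; same seed and calibration give an identical
#'   network.
#' @return object of class `vessel_network`: `nodes` (data.frame x, y, z,
#'   radius in um), `segments` (data.frame node_a, node_b), `metadata`.
#' @export
generate_network <- function(domain_size, calibration = vessel_calibration(),
                             seed = 1L) {
  stopifnot(length(domain_size) == 3L, all(domain_size > 0))
  cal <- calibration
  if (cal$volume_fraction > 0.3) {
    stop("infeasible calibration: volume fraction ", cal$volume_fraction,
         " exceeds the packing limit of this generator (0.3)")
  }
  if (any(domain_size < 2 * cal$segment_length_mean)) {
    stop("infeasible calibration: domain too small for the mean segment ",
         "length (need >= ", 2 * cal$segment_length_mean, " um per axis)")
  }
  target_volume <- cal$volume_fraction * prod(domain_size)

  with_seed(seed, {
    margin <- 2
    center <- domain_size / 2
    n_roots <- max(4L, round(prod(domain_size / 500)))

    # growable node storage
    cap <- 4096L
    npos <- matrix(0, cap, 3)
    nrad <- numeric(cap)
    n_nodes <- 0L
    seg_a <- integer(0)
    seg_b <- integer(0)
    add_nodes <- function(pos, rad) {
      k <- nrow(pos)
      while (n_nodes + k > cap) {
        cap <<- cap * 2L
        npos2 <- matrix(0, cap, 3)
        npos2[seq_len(n_nodes), ] <- npos[seq_len(n_nodes), ]
        npos <<- npos2
        nrad <<- c(nrad, numeric(cap - length(nrad)))
      }
      idx <- n_nodes + seq_len(k)
      npos[idx, ] <<- pos
      nrad[idx] <<- rad
      n_nodes <<- n_nodes + k
      idx
    }

    root_pos <- cbind(runif(n_roots, 0.1, 0.9) * domain_size[1],
                      runif(n_roots, 0.1, 0.9) * domain_size[2],
                      runif(n_roots, 0.1, 0.9) * domain_size[3])
    root_dir <- normalize_rows(matrix(rnorm(3 * n_roots), n_roots, 3))
    root_d <- sample_diameters(n_roots, cal)
    tip_node <- add_nodes(root_pos, root_d / 2)
    tip_pos <- root_pos
    tip_dir <- root_dir
    tip_diam <- root_d

    volume <- 0
    max_iter <- 100000L
    iter <- 0L
    while (volume < target_volume) {
      iter <- iter + 1L
      if (iter > max_iter || length(tip_node) == 0L) {
        stop("infeasible calibration: target volume fraction ",
             cal$volume_fraction, " unreachable in this domain")
      }
      nt <- length(tip_node)
      len <- pmax(10, rnorm(nt, cal$segment_length_mean,
                            cal$segment_length_sd))
      dirs <- normalize_rows(tip_dir +
        matrix(rnorm(3 * nt, 0, cal$direction_noise), nt, 3))
      ends <- tip_pos + dirs * len
      # redirect tips that would leave the domain back toward the interior
      out <- ends[, 1] < margin | ends[, 2] < margin | ends[, 3] < margin |
        ends[, 1] > domain_size[1] - margin |
        ends[, 2] > domain_size[2] - margin |
        ends[, 3] > domain_size[3] - margin
      if (any(out)) {
        inward <- normalize_rows(matrix(center, sum(out), 3, byrow = TRUE) -
                                   tip_pos[out, , drop = FALSE])
        dirs[out, ] <- normalize_rows(inward +
          matrix(rnorm(3 * sum(out), 0, cal$direction_noise), sum(out), 3))
        ends[out, ] <- tip_pos[out, , drop = FALSE] +
          dirs[out, , drop = FALSE] * len[out]
        ends[, 1] <- pmin(pmax(ends[, 1], margin), domain_size[1] - margin)
        ends[, 2] <- pmin(pmax(ends[, 2], margin), domain_size[2] - margin)
        ends[, 3] <- pmin(pmax(ends[, 3], margin), domain_size[3] - margin)
        len <- rownorms(ends - tip_pos)
      }
      alive <- len >= 5
      if (!any(alive)) next
      ends <- ends[alive, , drop = FALSE]
      dirs <- dirs[alive, , drop = FALSE]
      len <- len[alive]
      tip_node <- tip_node[alive]
      tip_pos <- tip_pos[alive, , drop = FALSE]
      tip_diam <- tip_diam[alive]
      nt <- length(tip_node)

      if (cal$murray_taper) {
        new_d <- pmax(cal$diameter_range[1],
                      tip_diam * 2^(-1 / cal$murray_exponent))
      } else {
        new_d <- sample_diameters(nt, cal)
      }
      ra <- nrad[tip_node]
      rb <- new_d / 2
      seg_vol <- pi * len / 3 * (ra^2 + ra * rb + rb^2)
      # cut within the iteration so we overshoot by at most one segment
      keep <- which(volume + cumsum(seg_vol) - seg_vol < target_volume)
      ends <- ends[keep, , drop = FALSE]
      dirs <- dirs[keep, , drop = FALSE]
      new_d <- new_d[keep]
      seg_vol <- seg_vol[keep]
      tip_node_k <- tip_node[keep]
      new_idx <- add_nodes(ends, new_d / 2)
      seg_a <- c(seg_a, tip_node_k)
      seg_b <- c(seg_b, new_idx)
      volume <- volume + sum(seg_vol)

      # continuing tips plus spawned branches
      tip_node <- new_idx
      tip_pos <- ends
      tip_dir <- dirs
      tip_diam <- new_d
      bif <- runif(length(new_idx)) < cal$bifurcation_prob
      if (any(bif)) {
        nb <- sum(bif)
        axis <- normalize_rows(matrix(rnorm(3 * nb), nb, 3))
        # make axis perpendicular to the parent direction
        par <- tip_dir[bif, , drop = FALSE]
        axis <- normalize_rows(axis - par * rowSums(axis * par))
        ang <- rnorm(nb, cal$bifurcation_angle, cal$bifurcation_angle_sd) *
          pi / 180
        bdir <- rotate_rows(par, axis, ang)
        tip_node <- c(tip_node, tip_node[bif])
        tip_pos <- rbind(tip_pos, tip_pos[bif, , drop = FALSE])
        tip_dir <- rbind(tip_dir, bdir)
        tip_diam <- c(tip_diam, tip_diam[bif])
      }
      if (length(tip_node) > cal$max_active_tips) {
        keep_t <- sample.int(length(tip_node), cal$max_active_tips)
        tip_node <- tip_node[keep_t]
        tip_pos <- tip_pos[keep_t, , drop = FALSE]
        tip_dir <- tip_dir[keep_t, , drop = FALSE]
        tip_diam <- tip_diam[keep_t]
      }
    }

    nodes <- data.frame(x = npos[seq_len(n_nodes), 1],
                        y = npos[seq_len(n_nodes), 2],
                        z = npos[seq_len(n_nodes), 3],
                        radius = nrad[seq_len(n_nodes)])
    segments <- data.frame(node_a = seg_a, node_b = seg_b)

    # capillary cross-links between nearby nodes
    n_cross <- round(cal$cross_link_fraction * nrow(segments))
    if (n_cross > 0) {
      cand_a <- sample.int(n_nodes, 4L * n_cross, replace = TRUE)
      cand_b <- sample.int(n_nodes, 4L * n_cross, replace = TRUE)
      d <- sqrt((nodes$x[cand_a] - nodes$x[cand_b])^2 +
                (nodes$y[cand_a] - nodes$y[cand_b])^2 +
                (nodes$z[cand_a] - nodes$z[cand_b])^2)
      ok <- which(cand_a != cand_b & d > 10 &
                    d < 2 * cal$segment_length_mean)
      ok <- utils::head(ok, n_cross)
      if (length(ok) > 0) {
        key_new <- paste(pmin(cand_a[ok], cand_b[ok]),
                         pmax(cand_a[ok], cand_b[ok]))
        key_old <- paste(pmin(segments$node_a, segments$node_b),
                         pmax(segments$node_a, segments$node_b))
        fresh <- !(key_new %in% key_old) & !duplicated(key_new)
        segments <- rbind(segments,
                          data.frame(node_a = cand_a[ok][fresh],
                                     node_b = cand_b[ok][fresh]))
      }
    }

    # drop nodes never referenced (killed root tips)
    used <- sort(unique(c(segments$node_a, segments$node_b)))
    remap <- integer(n_nodes)
    remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    rownames(nodes) <- NULL
    segments$node_a <- remap[segments$node_a]
    segments$node_b <- remap[segments$node_b]

    net <- structure(list(nodes = nodes, segments = segments,
                          metadata = list(domain_size = domain_size,
                                          seed = seed,
                                          calibration = cal)),
                     class = "vessel_network")
    validate_network(net)
    net
  })
}

#' Validate vessel network invariants
#'
#' Checks nodal radii against the hard minimum (5 um radius, i.e. the 10 um
#' reconstruction floor), distinct segment endpoints, strictly positive
#' segment lengths, and that every node is referenced by a segment.
#' @param net a `vessel_network`.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "vessel_network"))
  if (nrow(net$segments) == 0) stop("network has no segments")
  if (any(net$nodes$radius < 5)) {
    stop("network invariant violated: nodal radius below 5 um")
  }
  if (any(net$segments$node_a == net$segments$node_b)) {
    stop("network invariant violated: segment with identical endpoints")
  }
  len <- segment_lengths(net)
  if (any(len <= 0)) stop("network invariant violated: zero-length segment")
  used <- unique(c(net$segments$node_a, net$segments$node_b))
  if (length(used) != nrow(net$nodes)) {
    stop("network invariant violated: orphan node(s)")
  }
  invisible(net)
}

segment_lengths <- function(net) {
  a <- net$segments$node_a
  b <- net$segments$node_b
  sqrt((net$nodes$x[a] - net$nodes$x[b])^2 +
       (net$nodes$y[a] - net$nodes$y[b])^2 +
       (net$nodes$z[a] - net$nodes$z[b])^2)
}

segment_volumes <- function(net) {
  ra <- net$nodes$radius[net$segments$node_a]
  rb <- net$nodes$radius[net$segments$node_b]
  pi * segment_lengths(net) / 3 * (ra^2 + ra * rb + rb^2)
}

#' Summary statistics of a vessel network
#'
#' Per-segment volumes are conical frustra between the two nodal radii; the
#' per-segment diameter is the mean of the two nodal diameters.
#'
#' @param net a `vessel_network`.
#' @param domain_volume domain volume in um^3 for the volume fraction;
#'   defaults to the generation domain recorded in the metadata.
#' @return list with `n_segments`, `mean_diameter`, `min_diameter`,
#'   `max_diameter` (um), `total_volume`, `mean_segment_volume` (um^3),
#'   `volume_fraction`.
#' @export
network_stats <- function(net, domain_volume = NULL) {
  stopifnot(inherits(net, "vessel_network"))
  if (nrow(net$segments) == 0) stop("network_stats: empty network")
  if (is.null(domain_volume)) {
    ds <- net$metadata$domain_size
    domain_volume <- if (is.null(ds)) NA_real_ else prod(ds)
  }
  da <- 2 * net$nodes$radius[net$segments$node_a]
  db <- 2 * net$nodes$radius[net$segments$node_b]
  vols <- segment_volumes(net)
  list(n_segments = nrow(net$segments),
       mean_diameter = mean((da + db) / 2),
       min_diameter = min(da, db),
       max_diameter = max(da, db),
       total_volume = sum(vols),
       mean_segment_volume = mean(vols),
       volume_fraction = sum(vols) / domain_volume)
}

#' @export
print.vessel_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(paste0("<vessel_network> %d nodes, %d segments\n",
                     "  diameters %.2f-%.2f um (mean %.2f), volume fraction %s\n"),
              nrow(x$nodes), s$n_segments, s$min_diameter, s$max_diameter,
              s$mean_diameter,
              if (is.na(s$volume_fraction)) "n/a"
              else sprintf("%.2f%%", 100 * s$volume_fraction)))
  invisible(x)
}

#' Write / read a vessel network as a CSV pair or JSON
#'
#' `write_network` writes `<basename>_nodes.csv` (id, x, y, z, radius) and
#' `<basename>_segments.csv` (id, node_a, node_b). `write_network_json`
#' stores the same content plus metadata in one JSON document.
#' @param net a `vessel_network`.
#' @param basename path prefix for the CSV pair.
#' @return written paths, invisibly.
#' @export
write_network <- function(net, basename) {
  nodes <- cbind(id = seq_len(nrow(net$nodes)), net$nodes)
  segs <- cbind(id = seq_len(nrow(net$segments)), net$segments)
  pn <- paste0(basename, "_nodes.csv")
  ps <- paste0(basename, "_segments.csv")
  write.csv(nodes, pn, row.names = FALSE)
  write.csv(segs, ps, row.names = FALSE)
  invisible(c(pn, ps))
}

#' @rdname write_network
#' @export
read_network <- function(basename) {
  nodes <- read.csv(paste0(basename, "_nodes.csv"))
  segs <- read.csv(paste0(basename, "_segments.csv"))
  net <- structure(list(nodes = nodes[, c("x", "y", "z", "radius")],
                        segments = segs[, c("node_a", "node_b")],
                        metadata = list()),
                   class = "vessel_network")
  validate_network(net)
}

#' @rdname write_network
#' @param path JSON file path.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(list(nodes = net$nodes, segments = net$segments,
                            metadata = net$metadata[c("domain_size", "seed")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(nodes = as.data.frame(d$nodes),
                        segments = as.data.frame(d$segments),
                        metadata = as.list(d$metadata)),
                   class = "vessel_network")
  validate_network(net)
}
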