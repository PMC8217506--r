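#' Map peak vessel axial stress onto tissue elements
#'
#' For every tissue element, gathers the beam elements whose undeformed
#' midpoint lies within `radius` of the element centroid and assigns the
#' maximum over those beams of their maximum-over-time axial stress. By
#' default only tensile peaks enter the injury map (`mode = "tensile"`:
#' compressive-only beams contribute 0); `mode = "signed"` keeps the signed
#' maximum. Elements with no beam in their neighbourhood are marked
#' explicitly (`has_vessel = FALSE`, value `NA`), not zero.
#'
#' @param history a `sim_history` containing beam stresses.
#' @param mesh the tissue `hex_mesh`.
#' @param beams the `beam_mesh`.
#' @param radius neighbourhood radius, um; defaults to one element edge.
#' @param mode "tensile" or "signed".
#' @return object of class `vessel_stress_map`: data.frame with `element`,
#'   `value` (kPa), `beam` (provenance beam id), `n_beams`, `has_vessel`.
#' @export
map_vessel_stress <- function(history, mesh, beams,
                              radius = min(mesh$element_size),
                              mode = c("tensile", "signed")) {
  mode <- match.arg(mode)
  stopifnot(radius > 0)
  bs <- history$beam_stress
  if (is.null(dim(bs))) bs <- matrix(bs, ncol = length(bs))
  peak <- apply(bs, 2, max)
  if (mode == "tensile") peak <- pmax(peak, 0)

  a <- beams$elements$node_a
  b <- beams$elements$node_b
  mid <- cbind((beams$nodes$x[a] + beams$nodes$x[b]) / 2,
               (beams$nodes$y[a] + beams$nodes$y[b]) / 2,
               (beams$nodes$z[a] + beams$nodes$z[b]) / 2)
  cent <- element_centroids(mesh)

  E <- nrow(cent)
  value <- rep(NA_real_, E)
  prov <- rep(NA_integer_, E)
  nb <- integer(E)
  # spatial binning of beam midpoints at the neighbourhood radius
  lo <- apply(rbind(mid, cent), 2, min) - radius
  binsz <- radius
  key <- function(p) {
    floor(sweep(p, 2, lo) / binsz)
  }
  bkey <- key(mid)
  bid <- paste(bkey[, 1], bkey[, 2], bkey[, 3])
  bins <- split(seq_len(nrow(mid)), bid)
  ckey <- key(cent)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (e in seq_len(E)) {
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      kk <- ckey[e, ] + offs[o, ]
      hit <- bins[[paste(kk[1], kk[2], kk[3])]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0) next
    d2 <- (mid[cand, 1] - cent[e, 1])^2 + (mid[cand, 2] - cent[e, 2])^2 +
      (mid[cand, 3] - cent[e, 3])^2
    inr <- cand[d2 <= radius^2]
    if (length(inr) == 0) next
    nb[e] <- length(inr)
    best <- inr[which.max(peak[inr])]
    value[e] <- peak[best]
    prov[e] <- best
  }
  out <- data.frame(element = seq_len(E), value = value, beam = prov,
                    n_beams = nb, has_vessel = nb > 0)
  attr(out, "radius") <- radius
  attr(out, "mode") <- mode
  class(out) <- c("vessel_stress_map", "data.frame")
  out
}

element_centroids <- function(mesh) {
  E <- nrow(mesh$elements)
  cbind(rowMeans(matrix(mesh$nodes[mesh$elements, 1], E, 8)),
        rowMeans(matrix(mesh$nodes[mesh$elements, 2], E, 8)),
        rowMeans(matrix(mesh$nodes[mesh$elements, 3], E, 8)))
}

#' Exceedance area of the mapped vessel stress on a coronal slice
#'
#' Intersects the element stress map with the element layer nearest to the
#' slice coordinate, restricts to a region of interest when given, and
#' reports for each threshold the area of elements whose mapped vessel
#' stress exceeds it (count x element face area) together with the fraction
#' of the ROI slice area. Monotone non-increasing in the threshold.
#'
#' @param map a `vessel_stress_map`.
#' @param mesh the tissue `hex_mesh`.
#' @param thresholds ascending stress thresholds, kPa (default
#'   150/200/250/300).
#' @param roi optional region label (matched against
#'   `mesh$region_labels`); unknown labels fail.
#' @param slice list with `axis` (1-3) and `coordinate` (um); the default
#'   slices the mid-plane normal to y.
#' @return data.frame with `threshold`, `n_exceed`, `area_mm2`, `fraction`.
#' @export
threshold_area <- function(map, mesh, thresholds = c(150, 200, 250, 300),
                           roi = NULL, slice = list(axis = 2,
                                                    coordinate = NULL)) {
  stopifnot(inherits(map, "vessel_stress_map"))
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  cent <- element_centroids(mesh)
  ax <- slice$axis %||% 2
  coord <- slice$coordinate %||% mean(range(cent[, ax]))
  layers <- sort(unique(round(cent[, ax], 6)))
  nearest <- layers[which.min(abs(layers - coord))]
  on_slice <- abs(cent[, ax] - nearest) < 1e-6 + 1e-9 * abs(nearest)
  sel <- on_slice
  if (!is.null(roi)) {
    if (is.null(mesh$region_labels)) stop("mesh has no region labels")
    if (!roi %in% mesh$region_labels) stop("unknown ROI label: ", roi)
    sel <- sel & (mesh$region_labels == roi)
  }
  es <- mesh$element_size[setdiff(1:3, ax)]
  face_mm2 <- prod(es) / 1e6
  total <- sum(sel)
  vals <- map$value[sel]
  n_ex <- vapply(thresholds, function(th) sum(vals > th, na.rm = TRUE),
                 numeric(1))
  data.frame(threshold = thresholds, n_exceed = n_ex,
             area_mm2 = n_ex * face_mm2,
             fraction = if (total > 0) n_ex / total else 0)
}

#' Linear regression between exceedance area and an observed injury measure
#'
#' Ordinary least squares of the observation on the exceedance area, with
#' R-squared and the two-sided p-value for the slope — the quantitative
#' comparison used between high-vessel-stress area and extravasation area.
#'
#' @param areas numeric predictor (per-sample exceedance areas).
#' @param observations numeric response of the same length (>= 3 pairs).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
regress_area_vs_observation <- function(areas, observations) {
  ok <- complete.cases(areas, observations)
  x <- areas[ok]; y <- observations[ok]
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (var(x) == 0) stop("zero variance in the predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4], n = length(x))
}
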