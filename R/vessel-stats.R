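#' Unit direction of a beam from its end nodes
#' @param node_a,node_b length-3 positions.
#' @return unit 3-vector (sign-free downstream: d and -d are equivalent).
#' @export
beam_direction <- function(node_a, node_b) {
  d <- node_b - node_a
  l <- sqrt(sum(d^2))
  if (l == 0) stop("coincident beam nodes")
  d / l
}

#' Eigendecomposition of a symmetric stress/strain tensor
#'
#' Principal values sorted descending with orthonormal principal
#' directions; the first principal value/direction is the injury-relevant
#' maximal stress or strain and its axis.
#' @param tensor symmetric 3x3 matrix.
#' @return list with `values` (descending) and `vectors` (columns).
#' @export
principal_decomposition <- function(tensor) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == c(3, 3)))
  nrm <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > 1e-9 * nrm) {
    stop("tensor is not symmetric")
  }
  e <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Deviatoric part of a tensor
#'
#' dev(A) = A - tr(A)/3 I: the shear-carrying component; the removed
#' hydrostatic part drives volume change only.
#' @param tensor symmetric 3x3 matrix.
#' @return traceless 3x3 matrix.
#' @export
deviatoric_part <- function(tensor) {
  tensor - sum(diag(tensor)) / 3 * diag(3)
}

#' Angle between a vessel direction and a principal direction
#'
#' acos(|d . p|) in degrees, in \[0, 90\] by construction (sign-free).
#' @param direction,principal_direction unit 3-vectors.
#' @return angle in degrees.
#' @export
vessel_angle <- function(direction, principal_direction) {
  if (abs(sum(direction^2) - 1) > 1e-6 ||
      abs(sum(principal_direction^2) - 1) > 1e-6) {
    stop("vessel_angle expects unit vectors")
  }
  acos(min(1, abs(sum(direction * principal_direction)))) * 180 / pi
}

#' Build the per-beam, per-frame vessel stress record table
#'
#' One record per (beam element, output frame), joining the beam axial
#' stress and current direction with the stress and strain state of the
#' neighbouring tissue — taken as the beam midpoint's host element — and
#' the derived principal quantities: first principal stress/strain, their
#' deviatoric first principal values (same eigenvectors, eigenvalues
#' shifted by the hydrostatic part), and the vessel angle to the first
#' principal stress and strain directions.
#'
#' @param history a `sim_history`.
#' @param mesh the tissue `hex_mesh`.
#' @param beams the `beam_mesh`.
#' @return data.frame with columns time, beam, axial_stress (kPa),
#'   dir_x/y/z, p1_stress, p1_stress_dev (kPa), p1_strain, p1_strain_dev,
#'   angle_stress, angle_strain (degrees).
#' @export
build_records <- function(history, mesh, beams) {
  if (is.null(history$beam_stress) || length(history$beam_stress) == 0) {
    stop("history carries no beam stresses; was the run coupled?")
  }
  a <- beams$elements$node_a
  b <- beams$elements$node_b
  mid <- cbind((beams$nodes$x[a] + beams$nodes$x[b]) / 2,
               (beams$nodes$y[a] + beams$nodes$y[b]) / 2,
               (beams$nodes$z[a] + beams$nodes$z[b]) / 2)
  loc <- cpp_locate_points(mesh$nodes, mesh$elements, mid)
  if (any(loc$elem == 0)) {
    stop("beam midpoint(s) outside the tissue mesh: ",
         paste(utils::head(which(loc$elem == 0), 5), collapse = ", "))
  }
  host <- loc$elem
  nf <- length(history$times)
  B <- nrow(beams$elements)

  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    sig <- matrix(history$stress[f, host, ], length(host), 6)
    eps <- matrix(history$strain[f, host, ], length(host), 6)
    es <- cpp_eig_batch(sig)
    ee <- cpp_eig_batch(eps)
    dirs <- matrix(history$beam_dir[f, , ], B, 3)
    v1s <- es$vectors[, 1:3, drop = FALSE]
    v1e <- ee$vectors[, 1:3, drop = FALSE]
    ang_s <- acos(pmin(1, abs(rowSums(dirs * v1s)))) * 180 / pi
    ang_e <- acos(pmin(1, abs(rowSums(dirs * v1e)))) * 180 / pi
    tr_s3 <- rowSums(sig[, 1:3, drop = FALSE]) / 3
    tr_e3 <- rowSums(eps[, 1:3, drop = FALSE]) / 3
    out[[f]] <- data.frame(
      time = history$times[f],
      beam = seq_len(B),
      axial_stress = history$beam_stress[f, ],
      dir_x = dirs[, 1], dir_y = dirs[, 2], dir_z = dirs[, 3],
      p1_stress = es$values[, 1],
      p1_stress_dev = es$values[, 1] - tr_s3,
      p1_strain = ee$values[, 1],
      p1_strain_dev = ee$values[, 1] - tr_e3,
      angle_stress = ang_s,
      angle_strain = ang_e)
  }
  records <- do.call(rbind, out)
  attr(records, "host_element") <- host
  records
}

#' Correlation, partial correlation and regression between record fields
#'
#' Pearson R with its two-sided p-value; when a control field is given,
#' the first-order partial correlation
#' r_xy.z = (r_xy - r_xz r_zy) / sqrt((1 - r_xz^2)(1 - r_zy^2)); plus the
#' OLS fit of (optionally log10-transformed) y on x. The log transform
#' drops non-positive y values and reports the count.
#'
#' @param records data.frame from [build_records()] (or any data.frame).
#' @param x,y,control column names; `control = NULL` for no partial.
#' @param transform "none" or "log10" (applied to y).
#' @return list with `r`, `p`, `partial_r`, `slope`, `intercept`,
#'   `r_squared`, `n`, `n_dropped`.
#' @export
correlation_suite <- function(records, x, y, control = NULL,
                              transform = c("none", "log10")) {
  transform <- match.arg(transform)
  xv <- records[[x]]
  yv <- records[[y]]
  zv <- if (!is.null(control)) records[[control]] else NULL
  n0 <- length(xv)
  keep <- is.finite(xv) & is.finite(yv) &
    (if (is.null(zv)) TRUE else is.finite(zv))
  if (transform == "log10") keep <- keep & yv > 0
  n_dropped <- n0 - sum(keep)
  xv <- xv[keep]; yv <- yv[keep]
  if (!is.null(zv)) zv <- zv[keep]
  if (length(xv) < 3) stop("fewer than 3 records after filtering")
  if (transform == "log10") yv <- log10(yv)
  if (sd(xv) == 0 || sd(yv) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(xv, yv)
  partial_r <- NA_real_
  if (!is.null(zv)) {
    if (sd(zv) == 0) stop("zero variance in the control variable")
    rxy <- cor(xv, yv); rxz <- cor(xv, zv); rzy <- cor(zv, yv)
    partial_r <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  }
  fit <- lm(yv ~ xv)
  list(r = unname(ct$estimate), p = ct$p.value, partial_r = partial_r,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(xv), n_dropped = n_dropped)
}

# rank-statistic AUC of `score` for predicting `label` (ties counted half);
# counts as doubles so large record tables do not overflow integer products
auc_rank <- function(score, label) {
  n1 <- as.numeric(sum(label))
  n0 <- as.numeric(sum(!label))
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC analysis: can the vessel angle separate tension from compression?
#'
#' Labels records as tension (axial stress > 0) or compression (< 0;
#' exactly zero excluded), scores them with the negated angle field
#' (smaller angle predicts tension), and computes the AUC by the rank
#' statistic with a stratified bootstrap confidence interval.
#'
#' @param records data.frame from [build_records()].
#' @param predictor angle column name (default `angle_stress`).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list with `auc`, `ci` (length 2), `n_tension`, `n_compression`.
#' @export
tension_compression_roc <- function(records, predictor = "angle_stress",
                                    n_boot = 2000, seed = 1L, conf = 0.95) {
  s <- records$axial_stress
  keep <- is.finite(s) & s != 0 & is.finite(records[[predictor]])
  label <- s[keep] > 0
  score <- -records[[predictor]][keep]
  if (!any(label) || all(label)) {
    stop("both tension and compression records are required")
  }
  auc <- auc_rank(score, label)
  ipos <- which(label)
  ineg <- which(!label)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bp <- sample(ipos, length(ipos), replace = TRUE)
      bn <- sample(ineg, length(ineg), replace = TRUE)
      idx <- c(bp, bn)
      auc_rank(score[idx], c(rep(TRUE, length(bp)), rep(FALSE, length(bn))))
    }, numeric(1))
  })
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(auc = auc, ci = qs, n_tension = sum(label),
       n_compression = sum(!label))
}
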