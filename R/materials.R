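#' Hyper-viscoelastic tissue material (Ogden + Prony series)
#'
#' Long-term behaviour is an Ogden hyperelastic law in principal stretches,
#' Psi = sum_p mu_p/alpha_p (l1^a_p + l2^a_p + l3^a_p - 3), applied to the
#' isochoric stretches with a volumetric penalty K(J-1) enforcing near
#' incompressibility. Rate dependence enters through a Prony-series
#' relaxation modulus G(t) = sum_i G_i exp(-t/tau_i) convolved with the
#' deviatoric Green-Lagrange strain rate.
#'
#' The shipped constants are representative rodent-brain values at impact
#' rates; they are package assumptions exposed through this constructor (see
#' the methods vignette), not fitted quantities.
#'
#' @param ogden data.frame with columns `mu` (kPa) and `alpha`.
#' @param prony data.frame with columns `G` (kPa) and `tau` (ms); may have
#'   zero rows for a purely hyperelastic material.
#' @param density kg/m^3.
#' @param bulk_modulus volumetric penalty modulus, kPa.
#' @return object of class `ogden_prony_material`.
#' @export
ogden_prony_material <- function(ogden = data.frame(mu = 1.2, alpha = 4.5),
                                 prony = data.frame(G = c(2.4, 1.2),
                                                    tau = c(0.1, 1.0)),
                                 density = 1040,
                                 bulk_modulus = 1e5) {
  stopifnot(all(c("mu", "alpha") %in% names(ogden)),
            density > 0, bulk_modulus > 0)
  if (nrow(prony) > 0) {
    stopifnot(all(c("G", "tau") %in% names(prony)), all(prony$tau > 0))
  }
  mu0 <- sum(ogden$mu * ogden$alpha) / 2
  if (mu0 <= 0) stop("ground-state shear modulus sum(mu*alpha)/2 must be > 0")
  if (bulk_modulus < 50 * mu0) {
    warning("bulk modulus is less than 50x the ground-state shear modulus; ",
            "the material is not nearly incompressible")
  }
  structure(list(ogden = ogden, prony = prony, density = density,
                 bulk_modulus = bulk_modulus, mu0 = mu0),
            class = "ogden_prony_material")
}

#' Default brain-tissue material
#' @param ... overrides passed to [ogden_prony_material()].
#' @return an `ogden_prony_material`.
#' @export
brain_material <- function(...) ogden_prony_material(...)

#' Linear elastic vessel material
#'
#' Defaults transcribe the printed vessel constants: 1.4 MPa modulus, 0.38
#' Poisson ratio, 104 kg/m^3 density. The density is suspiciously low for
#' soft tissue (plausibly a typesetting slip for 1040) but is kept as
#' printed; override `density` if desired.
#' @param elastic_modulus kPa.
#' @param poisson_ratio dimensionless, in \[0, 0.5).
#' @param density kg/m^3.
#' @return object of class `vessel_material`.
#' @export
vessel_material <- function(elastic_modulus = 1400, poisson_ratio = 0.38,
                            density = 104) {
  stopifnot(elastic_modulus > 0, poisson_ratio >= 0, poisson_ratio < 0.5,
            density > 0)
  structure(list(elastic_modulus = elastic_modulus,
                 poisson_ratio = poisson_ratio, density = density),
            class = "vessel_material")
}

#' Principal Cauchy stresses of the (long-term) Ogden law
#'
#' Deviatoric response from the Ogden energy applied to isochoric stretches
#' plus the volumetric penalty K(J-1). For an incompressible uniaxial state
#' (lambda, lambda^-1/2, lambda^-1/2) the axial-minus-lateral difference
#' equals the textbook closed form mu (lambda^alpha - lambda^(-alpha/2)).
#'
#' @param stretches length-3 positive principal stretches.
#' @param mat an `ogden_prony_material`.
#' @return length-3 principal Cauchy stresses, kPa, in the order of
#'   `stretches`.
#' @export
ogden_principal_stress <- function(stretches, mat) {
  stopifnot(length(stretches) == 3L)
  if (any(!is.finite(stretches)) || any(stretches <= 0)) {
    stop("principal stretches must be positive")
  }
  J <- prod(stretches)
  lb <- stretches * J^(-1 / 3)
  tau_dev <- numeric(3)
  for (p in seq_len(nrow(mat$ogden))) {
    mu <- mat$ogden$mu[p]
    al <- mat$ogden$alpha[p]
    pow <- lb^al
    tau_dev <- tau_dev + mu * (pow - mean(pow))
  }
  tau_dev / J + mat$bulk_modulus * (J - 1)
}

#' Uniaxial Cauchy stress of the incompressible Ogden law
#'
#' Convenience wrapper: evaluates [ogden_principal_stress()] at the
#' isochoric uniaxial state and returns axial minus lateral stress, which
#' eliminates the indeterminate incompressibility pressure.
#' @param lambda axial stretch (scalar or vector).
#' @param mat an `ogden_prony_material`.
#' @return axial Cauchy stress, kPa.
#' @export
ogden_uniaxial_stress <- function(lambda, mat) {
  vapply(lambda, function(l) {
    s <- ogden_principal_stress(c(l, 1 / sqrt(l), 1 / sqrt(l)), mat)
    s[1] - s[2]
  }, numeric(1))
}

#' Prony-series relaxation modulus G(t)
#' @param t time(s), ms; must be >= 0.
#' @param mat an `ogden_prony_material`.
#' @return G(t) in kPa; `sum(G_i)` at t = 0, monotone non-increasing, 0 as
#'   t -> Inf (the series has no constant term).
#' @export
prony_relaxation_modulus <- function(t, mat) {
  if (any(t < 0)) stop("relaxation modulus requires t >= 0")
  if (nrow(mat$prony) == 0) return(rep(0, length(t)))
  vapply(t, function(ti) sum(mat$prony$G * exp(-ti / mat$prony$tau)),
         numeric(1))
}

#' Initialize the viscoelastic internal state
#' @param mat an `ogden_prony_material`.
#' @return object of class `visco_state`: one 3x3 internal stress variable
#'   per Prony term plus the previous Green-Lagrange strain, all zero.
#' @export
visco_state <- function(mat) {
  n <- nrow(mat$prony)
  structure(list(h = replicate(n, matrix(0, 3, 3), simplify = FALSE),
                 E_prev = matrix(0, 3, 3)),
            class = "visco_state")
}

#' One step of the viscoelastic stress update
#'
#' Implements the hereditary integral S(t) = S_inf + int G(t-T) dE/dT dT
#' with the standard recursive exponential update per Prony term, applied to
#' the deviatoric part of the Green-Lagrange strain increment (exact for
#' strain varying linearly within the step). When `S_inf` is not supplied, a
#' small-strain long-term stress 2 mu0 dev(E) + K tr(E) I is used, which
#' makes the function self-contained for relaxation and step-response
#' studies; the dynamic solver supplies its finite-deformation Ogden S_inf.
#'
#' @param state a [visco_state()].
#' @param E_new 3x3 Green-Lagrange strain tensor.
#' @param dt time step, ms (> 0).
#' @param mat an `ogden_prony_material`.
#' @param S_inf optional 3x3 long-term second Piola-Kirchhoff stress, kPa.
#' @return list with `S` (3x3 second Piola-Kirchhoff stress, kPa) and
#'   `state` (updated).
#' @export
viscoelastic_stress_update <- function(state, E_new, dt, mat, S_inf = NULL) {
  stopifnot(inherits(state, "visco_state"), dt > 0)
  if (!is.matrix(E_new) || any(dim(E_new) != c(3, 3))) {
    stop("strain tensor must be 3x3")
  }
  if (length(state$h) != nrow(mat$prony)) {
    stop("viscoelastic state does not match the material's Prony terms")
  }
  if (is.null(S_inf)) {
    S_inf <- 2 * mat$mu0 * deviatoric_part(E_new) +
      mat$bulk_modulus * sum(diag(E_new)) * diag(3)
  }
  dE_dev <- deviatoric_part(E_new - state$E_prev)
  S_over <- matrix(0, 3, 3)
  for (i in seq_along(state$h)) {
    tau <- mat$prony$tau[i]
    G <- mat$prony$G[i]
    ef <- exp(-dt / tau)
    state$h[[i]] <- ef * state$h[[i]] +
      G * (tau / dt) * (1 - ef) * dE_dev
    S_over <- S_over + state$h[[i]]
  }
  state$E_prev <- E_new
  list(S = S_inf + S_over, state = state)
}

#' Axial stress of the linear elastic vessel law
#'
#' stress = E * strain, tension positive; 200 kPa at the default 1.4 MPa
#' modulus corresponds to 14% axial strain.
#' @param axial_strain engineering axial strain (> -1).
#' @param mat a `vessel_material`.
#' @return axial stress, kPa.
#' @export
beam_axial_stress <- function(axial_strain, mat) {
  if (any(axial_strain <= -1)) stop("axial strain must exceed -1")
  mat$elastic_modulus * axial_strain
}
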