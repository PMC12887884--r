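## Debye-Hueckel screened-Coulomb electrostatics: the long-range steering
## field acting on the glycan. All energies kcal/mol, lengths Angstrom,
## charges in units of e.

#' Solvent parameters
#'
#' Continuum solvent description: temperature, dielectric constant,
#' viscosity relative to water, and ionic strength setting the Debye
#' screening length. Defaults are physiological saline at body
#' temperature (310.15 K, dielectric 78, relative viscosity 1, 150 mM).
#'
#' @param temperature K.
#' @param dielectric relative permittivity (dimensionless).
#' @param relative_viscosity viscosity / viscosity of water (dimensionless).
#' @param ionic_strength mol/L; `0` selects unscreened Coulomb mode.
#' @return object of class `solvent_params`.
#' @export
solvent_params <- function(temperature = 310.15, dielectric = 78,
                           relative_viscosity = 1, ionic_strength = 0.150) {
  stopifnot(temperature > 0, dielectric > 0, relative_viscosity > 0,
            ionic_strength >= 0)
  structure(list(temperature = temperature, dielectric = dielectric,
                 relative_viscosity = relative_viscosity,
                 ionic_strength = ionic_strength),
            class = "solvent_params")
}

#' @export
print.solvent_params <- function(x, ...) {
  cat("<solvent_params>", x$temperature, "K, eps", x$dielectric,
      ", eta_rel", x$relative_viscosity, ",", x$ionic_strength, "M",
      "(Debye length", signif(debye_length(x), 4), "A)\n")
  invisible(x)
}

#' Debye screening length
#'
#' \eqn{\kappa^{-1} = \sqrt{\epsilon \epsilon_0 k_B T / (2 N_A e^2 I)}}
#' for a 1:1 electrolyte of ionic strength I. At zero ionic strength the
#' length is infinite and the field reduces to unscreened Coulomb; this is
#' signalled by returning `Inf`.
#'
#' @param solvent a [solvent_params()].
#' @return screening length in Angstrom (`Inf` for pure Coulomb).
#' @examples
#' debye_length(solvent_params())  # ~8 A at 150 mM, 310 K
#' @export
debye_length <- function(solvent) {
  stopifnot(inherits(solvent, "solvent_params"))
  if (solvent$ionic_strength <= 0) return(Inf)
  I_m3 <- solvent$ionic_strength * 1000          # mol/m^3
  kappa2 <- 2 * .NA_mol * .e_C^2 * I_m3 /
    (solvent$dielectric * .eps0 * .kB_J * solvent$temperature)  # 1/m^2
  1e10 / sqrt(kappa2)
}

.kappa <- function(solvent) {
  dl <- debye_length(solvent)
  if (is.finite(dl)) 1 / dl else 0
}

#' Screened-Coulomb potential of a set of point charges
#'
#' \eqn{\phi(x) = \sum_i k_e q_i e^{-\kappa r_i} / (\epsilon r_i)} in
#' kcal/mol/e.
#'
#' @param points n x 3 matrix of source positions (Angstrom).
#' @param charges length-n source charges (e).
#' @param query m x 3 matrix (or length-3 vector) of query points.
#' @param solvent a [solvent_params()].
#' @return length-m potential vector, kcal/mol/e.
#' @export
potential_at <- function(points, charges, query, solvent = solvent_params()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  stopifnot(nrow(points) == length(charges))
  kap <- .kappa(solvent)
  out <- numeric(nrow(query))
  for (j in seq_len(nrow(query))) {
    d <- sqrt((points[, 1] - query[j, 1])^2 +
                (points[, 2] - query[j, 2])^2 +
                (points[, 3] - query[j, 3])^2)
    if (any(d < 1e-6))
      stop("query point coincides with a source charge")
    out[j] <- .kcoul / solvent$dielectric *
      sum(charges * exp(-kap * d) / d)
  }
  out
}

## point-charge lists used by the energy/force kernels -------------------

.fibril_charge_sites <- function(fibril) {
  a <- fibril$atoms[fibril$atoms$charge != 0, ]
  list(pos = as.matrix(a[, c("x", "y", "z")]), q = a$charge)
}

.fibril_repulsion_sites <- function(fibril) {
  as.matrix(fibril$atoms[, c("x", "y", "z")])
}

.glycan_charge_sites <- function(glycan) {
  list(pos = as.matrix(glycan$hcgs[, c("qx", "qy", "qz")]),
       q = glycan$hcgs$charge)
}

# soft-core wall keeping beads from interpenetrating: E = eps*(d0/r)^12
.softcore_d0  <- 3.5   # pair contact distance, A (1.75 A bead radius)
.softcore_eps <- 0.3   # kcal/mol at contact

#' Screened-Coulomb interaction energy of a posed glycan with a fibril
#'
#' Total pairwise Debye-Hueckel energy between the glycan charged groups
#' and the fibril formal charges, plus a short-range r^-12 soft-core
#' repulsion that stands in for excluded volume. More negative is more
#' favorable; the energy tends to 0 at infinite separation.
#'
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @param pose a [rigid_pose()] of the glycan.
#' @param solvent a [solvent_params()].
#' @param soft_core include the soft-core wall (default TRUE).
#' @return energy in kcal/mol.
#' @export
interaction_energy <- function(fibril, glycan, pose,
                               solvent = solvent_params(),
                               soft_core = TRUE) {
  fc <- .fibril_charge_sites(fibril)
  gc <- .glycan_charge_sites(glycan)
  g <- pose_apply(pose, gc$pos)
  kap <- .kappa(solvent)
  e <- 0
  for (j in seq_len(nrow(g))) {
    d <- sqrt((fc$pos[, 1] - g[j, 1])^2 + (fc$pos[, 2] - g[j, 2])^2 +
                (fc$pos[, 3] - g[j, 3])^2)
    e <- e + .kcoul / solvent$dielectric *
      sum(fc$q * gc$q[j] * exp(-kap * d) / d)
  }
  if (soft_core) {
    rep_pos <- .fibril_repulsion_sites(fibril)
    for (j in seq_len(nrow(g))) {
      d <- sqrt((rep_pos[, 1] - g[j, 1])^2 + (rep_pos[, 2] - g[j, 2])^2 +
                  (rep_pos[, 3] - g[j, 3])^2)
      d <- pmax(d, 0.5)   # clamp deep overlap so the energy stays finite
      e <- e + .softcore_eps * sum((.softcore_d0 / d)^12)
    }
  }
  e
}

#' Force and torque on a posed glycan
#'
#' Negative gradient of [interaction_energy()] with respect to rigid
#' translation, and the torque of the per-charge forces about the glycan
#' body origin (its centroid). Newton's third law holds: the fibril feels
#' the opposite force.
#'
#' @inheritParams interaction_energy
#' @return list with `force` (kcal/mol/A, length 3), `torque`
#'   (kcal/mol, about the pose origin) and `energy` (kcal/mol).
#' @export
force_torque_on_glycan <- function(fibril, glycan, pose,
                                   solvent = solvent_params(),
                                   soft_core = TRUE) {
  fc <- .fibril_charge_sites(fibril)
  gc <- .glycan_charge_sites(glycan)
  rep_pos <- if (soft_core) .fibril_repulsion_sites(fibril) else
    matrix(numeric(0), 0, 3)
  g <- pose_apply(pose, gc$pos)
  kap <- .kappa(solvent)
  force <- c(0, 0, 0); torque <- c(0, 0, 0); energy <- 0
  for (j in seq_len(nrow(g))) {
    dx <- g[j, 1] - fc$pos[, 1]; dy <- g[j, 2] - fc$pos[, 2]
    dz <- g[j, 3] - fc$pos[, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    A <- .kcoul / solvent$dielectric * fc$q * gc$q[j]
    energy <- energy + sum(A * exp(-kap * r) / r)
    # F = A e^{-kr}(kr+1)/r^2 rhat, rhat pointing fibril -> glycan
    fmag <- A * exp(-kap * r) * (kap * r + 1) / r^2
    fj <- c(sum(fmag * dx / r), sum(fmag * dy / r), sum(fmag * dz / r))
    if (nrow(rep_pos)) {
      rx <- g[j, 1] - rep_pos[, 1]; ry <- g[j, 2] - rep_pos[, 2]
      rz <- g[j, 3] - rep_pos[, 3]
      rr <- pmax(sqrt(rx^2 + ry^2 + rz^2), 0.5)
      energy <- energy + .softcore_eps * sum((.softcore_d0 / rr)^12)
      smag <- 12 * .softcore_eps * .softcore_d0^12 / rr^13
      fj <- fj + c(sum(smag * rx / rr), sum(smag * ry / rr),
                   sum(smag * rz / rr))
    }
    force <- force + fj
    arm <- g[j, ] - pose$t
    torque <- torque + c(arm[2] * fj[3] - arm[3] * fj[2],
                         arm[3] * fj[1] - arm[1] * fj[3],
                         arm[1] * fj[2] - arm[2] * fj[1])
  }
  list(force = force, torque = torque, energy = energy)
}

## ---- potential grid ---------------------------------------------------

#' Precompute a potential grid around a fibril
#'
#' Evaluates the screened-Coulomb potential of the fibril charges on a
#' regular grid covering the fibril bounding box plus `padding`, for cheap
#' trilinear interpolation. Queries outside the grid fall back to the
#' direct sum.
#'
#' @param fibril a `fibril_model`.
#' @param solvent a [solvent_params()].
#' @param spacing grid spacing, Angstrom.
#' @param padding margin beyond the atom bounding box, Angstrom.
#' @return object of class `potential_grid` (fields `origin`, `spacing`,
#'   `dims`, `values` array, and the source charges for fallback).
#' @export
precompute_grid <- function(fibril, solvent = solvent_params(),
                            spacing = 1.0, padding = 10) {
  stopifnot(spacing > 0, padding >= 0)
  fc <- .fibril_charge_sites(fibril)
  lo <- unname(apply(fc$pos, 2, min)) - padding
  hi <- unname(apply(fc$pos, 2, max)) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  kap <- .kappa(solvent)
  vals <- array(0, dims)
  pref <- .kcoul / solvent$dielectric
  for (i in seq_len(nrow(fc$pos))) {
    dx2 <- (xs - fc$pos[i, 1])^2
    dy2 <- (ys - fc$pos[i, 2])^2
    dz2 <- (zs - fc$pos[i, 3])^2
    r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    r[r < 1e-6] <- 1e-6
    vals <- vals + pref * fc$q[i] * exp(-kap * r) / r
  }
  structure(list(origin = lo, spacing = rep(spacing, 3), dims = dims,
                 values = vals, sources = fc, solvent = solvent),
            class = c("potential_grid", "volume_grid"))
}

#' Trilinear interpolation of a potential grid
#'
#' Exact at grid nodes and exact for fields linear in position; queries
#' outside the grid are answered by the direct screened-Coulomb sum over
#' the stored sources.
#'
#' @param grid a [precompute_grid()] result.
#' @param point length-3 query position (or m x 3 matrix).
#' @return potential(s) in kcal/mol/e.
#' @export
interpolate_potential <- function(grid, point) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  out <- numeric(nrow(point))
  for (m in seq_len(nrow(point))) {
    u <- (point[m, ] - grid$origin) / grid$spacing
    i0 <- floor(u)
    if (any(i0 < 0) || any(i0 > grid$dims - 2)) {
      out[m] <- potential_at(grid$sources$pos, grid$sources$q,
                             point[m, ], grid$solvent)
      next
    }
    f <- u - i0; i <- as.integer(i0) + 1L
    v <- grid$values
    c00 <- v[i[1], i[2], i[3]] * (1 - f[1]) + v[i[1] + 1, i[2], i[3]] * f[1]
    c10 <- v[i[1], i[2] + 1, i[3]] * (1 - f[1]) + v[i[1] + 1, i[2] + 1, i[3]] * f[1]
    c01 <- v[i[1], i[2], i[3] + 1] * (1 - f[1]) + v[i[1] + 1, i[2], i[3] + 1] * f[1]
    c11 <- v[i[1], i[2] + 1, i[3] + 1] * (1 - f[1]) +
      v[i[1] + 1, i[2] + 1, i[3] + 1] * f[1]
    c0 <- c00 * (1 - f[2]) + c10 * f[2]
    c1 <- c01 * (1 - f[2]) + c11 * f[2]
    out[m] <- c0 * (1 - f[3]) + c1 * f[3]
  }
  out
}
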