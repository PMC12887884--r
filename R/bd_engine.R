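## Rigid-body Brownian dynamics of the glycan around a fixed fibril, with
## the Northrup-Allison-McCammon b/q-surface bookkeeping and the
## geometric reaction criterion (>= 3 reference-atom contacts within
## 7.5 A).

#' Brownian dynamics parameters
#'
#' Simulation constants. Defaults follow the BD protocol for
#' heparin-fibril association: 1.0 ps far timestep, 0.01 ps near
#' timestep, reaction when at least three glycan-sulfur / basic-residue
#' reference-atom pairs are simultaneously within 7.5 A. The near regime
#' engages when any reference pair is within `near_shell` (default 15 A,
#' twice the reaction distance). `b_radius` (start sphere) defaults to the
#' fibril bounding radius plus three Debye lengths; `q_radius` (escape
#' sphere) defaults to ten times `b_radius`.
#'
#' @param solvent a [solvent_params()].
#' @param dt_far far-field timestep, ps.
#' @param dt_near near-field timestep, ps.
#' @param near_shell distance activating the near timestep, A.
#' @param reaction_distance reference-atom contact threshold, A.
#' @param reaction_min_contacts simultaneous contacts required to react.
#' @param b_radius start-sphere radius, A (`NULL` = auto).
#' @param q_radius escape-sphere radius, A (`NULL` = 10 b).
#' @param max_steps per-trajectory step cap.
#' @param hydrodynamic_radius Stokes radius of the glycan, A.
#' @param seed base seed for the ensemble substreams.
#' @return object of class `bd_params`.
#' @export
bd_params <- function(solvent = solvent_params(), dt_far = 1.0,
                      dt_near = 0.01, near_shell = 15,
                      reaction_distance = 7.5, reaction_min_contacts = 3L,
                      b_radius = NULL, q_radius = NULL, max_steps = 1e7,
                      hydrodynamic_radius = 8, seed = 1L) {
  stopifnot(dt_near > 0, dt_near <= dt_far, reaction_min_contacts >= 1,
            reaction_distance > 0, near_shell > 0, max_steps >= 0,
            hydrodynamic_radius > 0)
  if (!is.null(b_radius) && !is.null(q_radius) && b_radius >= q_radius)
    stop("b_radius must be smaller than q_radius")
  structure(list(solvent = solvent, dt_far = dt_far, dt_near = dt_near,
                 near_shell = near_shell,
                 reaction_distance = reaction_distance,
                 reaction_min_contacts = as.integer(reaction_min_contacts),
                 b_radius = b_radius, q_radius = q_radius,
                 max_steps = max_steps,
                 hydrodynamic_radius = hydrodynamic_radius,
                 seed = as.integer(seed)),
            class = "bd_params")
}

#' Translational diffusion coefficient (Stokes-Einstein)
#'
#' @param solvent a [solvent_params()].
#' @param radius hydrodynamic radius, A.
#' @return D_t in A^2/ps.
#' @export
translational_diffusion <- function(solvent, radius) {
  eta <- solvent$relative_viscosity * water_viscosity(solvent$temperature)
  (.kB_J * solvent$temperature / (6 * pi * eta * radius * 1e-10)) * 1e8
}

#' Rotational diffusion coefficient (Stokes-Einstein-Debye)
#'
#' @inheritParams translational_diffusion
#' @return D_r in rad^2/ps.
#' @export
rotational_diffusion <- function(solvent, radius) {
  eta <- solvent$relative_viscosity * water_viscosity(solvent$temperature)
  (.kB_J * solvent$temperature / (8 * pi * eta * (radius * 1e-10)^3)) * 1e-12
}

#' Reference atom sets for the reaction criterion
#'
#' Glycan side: the sulfate/sulfamido sulfurs (S2 and S6 of each
#' glucosamine, S2 of each iduronate, minus any removed by desulfation).
#' Fibril side: NZ of each solvent-exposed lysine and CZ of each
#' solvent-exposed arginine, across all layers.
#'
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @return list with `glycan_local` (k x 3 body-frame sulfur positions),
#'   `fibril_pos` (m x 3), `fibril_res` (residue number per fibril ref).
#' @export
reference_atom_sets <- function(fibril, glycan) {
  f <- fibril$atoms[fibril$atoms$bd_ref, ]
  if (!nrow(f)) stop("fibril has no reference atoms (no exposed basic residues)")
  if (!nrow(glycan$sulfurs)) stop("glycan has no sulfur reference atoms")
  list(glycan_local = as.matrix(glycan$sulfurs[, c("x", "y", "z")]),
       fibril_pos = as.matrix(f[, c("x", "y", "z")]),
       fibril_res = as.integer(f$resno))
}

#' Test the reaction criterion for a pose
#'
#' Counts glycan-reference / fibril-reference pairs within
#' `reaction_distance` (inclusive); if at least `reaction_min_contacts`
#' pairs exist, returns the residue number (pooled across layers) owning
#' the most pairs, ties broken toward the lowest residue number.
#'
#' @param pose a [rigid_pose()].
#' @param refs a [reference_atom_sets()] list.
#' @param params a [bd_params()].
#' @return reacted residue number, or `NA_integer_` if no reaction.
#' @export
check_reaction <- function(pose, refs, params = bd_params()) {
  g <- pose_apply(pose, refs$glycan_local)
  f <- refs$fibril_pos
  d2 <- outer(rowSums(f^2), rowSums(g^2), "+") - 2 * f %*% t(g)
  hit <- d2 <= params$reaction_distance^2 + 1e-12
  if (sum(hit) < params$reaction_min_contacts) return(NA_integer_)
  counts <- rowSums(hit)
  per_res <- tapply(counts, refs$fibril_res, sum)
  resn <- as.integer(names(per_res))
  best <- resn[per_res == max(per_res)]
  min(best)
}

#' One Brownian dynamics step (reference implementation)
#'
#' Ermak-McCammon overdamped update of a rigid pose:
#' translation `(D_t/k_B T) F dt + sqrt(2 D_t dt) xi` and rotation by the
#' axis-angle of the analogous angular update. Draws 3 + 3 standard
#' normals from the R stream, in the same order as the compiled
#' trajectory kernel, so single steps are exactly reproducible.
#'
#' @param pose a [rigid_pose()].
#' @param force length-3 force, kcal/mol/A.
#' @param torque length-3 torque about the pose origin, kcal/mol.
#' @param dt timestep, ps.
#' @param D_t,D_r diffusion coefficients (A^2/ps, rad^2/ps).
#' @param kBT thermal energy, kcal/mol.
#' @return the updated `rigid_pose`.
#' @export
bd_step <- function(pose, force = c(0, 0, 0), torque = c(0, 0, 0),
                    dt = 1.0, D_t, D_r, kBT) {
  xi <- rnorm(3)
  t_new <- pose$t + (D_t / kBT) * force * dt + sqrt(2 * D_t * dt) * xi
  w <- (D_r / kBT) * torque * dt + sqrt(2 * D_r * dt) * rnorm(3)
  rigid_pose(.orthonormalize(rotation_about(w, sqrt(sum(w^2))) %*% pose$R),
             t_new)
}

.resolve_bq <- function(fibril, params) {
  b <- params$b_radius
  if (is.null(b)) {
    dl <- debye_length(params$solvent)
    b <- fibril$bounding_radius + 3 * (if (is.finite(dl)) dl else 10)
  }
  q <- params$q_radius
  if (is.null(q)) q <- 10 * b
  if (b >= q) stop("b_radius must be smaller than q_radius")
  c(b = b, q = q)
}

# deterministic substream seed from (base seed, pair, replicate);
# kept below 2^31 - 1 and nonzero
.substream_seed <- function(seed, pair, replicate) {
  m <- 2147483647
  s <- (abs(seed) %% m)
  s <- (s * 69069 + pair * 7919) %% m
  s <- (s * 69069 + replicate) %% m
  as.integer(if (s == 0) 1 else s)
}

#' Run one association trajectory
#'
#' The glycan starts uniformly distributed on the b-sphere around the
#' fibril with a uniformly random orientation and is propagated with the
#' adaptive timestep (near timestep whenever any reference pair is within
#' `near_shell`) until it reacts, escapes through the q-sphere, or
#' exhausts `max_steps`.
#'
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @param params a [bd_params()].
#' @param stream_id integer replicate label; together with `params$seed`
#'   it fixes the trajectory's random substream.
#' @param pair_id integer label of the (fibril, glycan) pair.
#' @param record_stride if > 0, record the pose every this many steps
#'   (diagnostics; returned as `positions`/`orientations`).
#' @return object of class `trajectory_outcome`: `status` ("reacted",
#'   "escaped" or "max_steps"), `site` (residue number or NA), `n_steps`,
#'   `final_pose`, `stream_id`.
#' @export
run_trajectory <- function(fibril, glycan, params = bd_params(),
                           stream_id = 1L, pair_id = 1L,
                           record_stride = 0L) {
  prep <- .bd_prepare(fibril, glycan, params)
  .run_trajectory_prepared(prep, params, stream_id, pair_id, record_stride)
}

# precompute everything reusable across trajectories of one pair
.bd_prepare <- function(fibril, glycan, params) {
  fc <- .fibril_charge_sites(fibril)
  refs <- reference_atom_sets(fibril, glycan)
  gcs <- .glycan_charge_sites(glycan)
  bq <- .resolve_bq(fibril, params)
  solv <- params$solvent
  list(fib_charge_pos = fc$pos, fib_charge_q = fc$q,
       fib_rep_pos = .fibril_repulsion_sites(fibril),
       fib_ref_pos = refs$fibril_pos, fib_ref_res = refs$fibril_res,
       gly_charge_local = gcs$pos, gly_charge_q = gcs$q,
       gly_ref_local = refs$glycan_local,
       kappa = .kappa(solv),
       coul_pref = .kcoul / solv$dielectric,
       D_t = translational_diffusion(solv, params$hydrodynamic_radius),
       D_r = rotational_diffusion(solv, params$hydrodynamic_radius),
       kBT = .kB_kcal * solv$temperature,
       center = as.numeric(fibril$center), b = bq[["b"]], q = bq[["q"]])
}

.run_trajectory_prepared <- function(prep, params, stream_id, pair_id,
                                     record_stride = 0L) {
  seed <- .substream_seed(params$seed, pair_id, stream_id)
  set.seed(seed)
  # uniform point on the b-sphere (3 normals), then uniform orientation
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  t0 <- prep$center + prep$b * u
  R0 <- random_orientation()
  res <- .bd_run_cpp(prep$fib_charge_pos, prep$fib_charge_q,
                     prep$fib_rep_pos, prep$fib_ref_pos, prep$fib_ref_res,
                     prep$gly_charge_local, prep$gly_charge_q,
                     prep$gly_ref_local, R0, t0,
                     prep$kappa, prep$coul_pref,
                     prep$D_t, prep$D_r, prep$kBT,
                     params$dt_far, params$dt_near, params$near_shell,
                     params$reaction_distance, params$reaction_min_contacts,
                     prep$q, prep$center, params$max_steps,
                     as.integer(record_stride))
  out <- list(status = c("reacted", "escaped", "max_steps")[res$status + 1L],
              site = if (res$status == 0L) res$site else NA_integer_,
              n_steps = res$n_steps,
              final_pose = rigid_pose(res$R, res$t),
              stream_id = seed)
  if (record_stride > 0) {
    out$positions <- res$positions
    out$orientations <- res$orientations
    out$start <- t0
  }
  class(out) <- "trajectory_outcome"
  out
}

#' @export
print.trajectory_outcome <- function(x, ...) {
  cat("<trajectory_outcome>", x$status,
      if (!is.na(x$site)) paste("at residue", x$site) else "",
      "after", format(x$n_steps, big.mark = ","), "steps\n")
  invisible(x)
}

#' Run an ensemble of association trajectories
#'
#' For every (fibril conformation, glycan pose) pair, `n_per_pair`
#' independent trajectories are generated. Each trajectory draws from its
#' own random substream derived from `(params$seed, pair index, replicate
#' index)`, so the ensemble is reproducible and independent of execution
#' order.
#'
#' @param fibrils a `fibril_model` or list of them.
#' @param glycans a `glycan_model` or list of them.
#' @param n_per_pair trajectories per pair.
#' @param params a [bd_params()].
#' @return object of class `bd_outcomes`: a data frame with columns
#'   `pair`, `replicate`, `status`, `site`, `n_steps`, `stream_id`, with
#'   the final poses in `attr(, "poses")` and the inputs recorded in
#'   attributes.
#' @examples
#' \donttest{
#' fib <- build_fibril(build_cross_section("KAAAE", "ladder_line"),
#'                     n_layers = 6)
#' out <- run_ensemble(fib, build_glycan(4), n_per_pair = 5,
#'                     params = bd_params(max_steps = 100))
#' table(out$status)
#' }
#' @export
run_ensemble <- function(fibrils, glycans, n_per_pair,
                         params = bd_params()) {
  if (inherits(fibrils, "fibril_model")) fibrils <- list(fibrils)
  if (inherits(glycans, "glycan_model")) glycans <- list(glycans)
  stopifnot(length(fibrils) >= 1, length(glycans) >= 1, n_per_pair >= 1)
  pairs <- expand.grid(fi = seq_along(fibrils), gi = seq_along(glycans))
  n_total <- nrow(pairs) * n_per_pair
  status <- character(n_total); site <- integer(n_total)
  n_steps <- numeric(n_total); stream <- integer(n_total)
  pair_col <- integer(n_total); repl <- integer(n_total)
  poses <- vector("list", n_total)
  k <- 0L
  for (p in seq_len(nrow(pairs))) {
    prep <- .bd_prepare(fibrils[[pairs$fi[p]]], glycans[[pairs$gi[p]]],
                        params)
    for (r in seq_len(n_per_pair)) {
      o <- .run_trajectory_prepared(prep, params, r, p)
      k <- k + 1L
      status[k] <- o$status; site[k] <- o$site; n_steps[k] <- o$n_steps
      stream[k] <- o$stream_id; pair_col[k] <- p; repl[k] <- r
      poses[[k]] <- o$final_pose
    }
  }
  df <- data.frame(pair = pair_col, replicate = repl, status = status,
                   site = site, n_steps = n_steps, stream_id = stream)
  attr(df, "poses") <- poses
  attr(df, "pair_table") <- pairs
  attr(df, "params") <- params
  class(df) <- c("bd_outcomes", "data.frame")
  df
}

#' @export
print.bd_outcomes <- function(x, ...) {
  cat("<bd_outcomes>", nrow(x), "trajectories:",
      sum(x$status == "reacted"), "reacted,",
      sum(x$status == "escaped"), "escaped,",
      sum(x$status == "max_steps"), "hit the step cap\n")
  if (any(x$status == "reacted")) {
    tb <- sort(table(x$site[x$status == "reacted"]), decreasing = TRUE)
    cat("  top sites:", paste(names(tb)[seq_len(min(5, length(tb)))],
                              tb[seq_len(min(5, length(tb)))],
                              sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a trajectory outcome log as TSV
#'
#' @param outcomes a [run_ensemble()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_outcomes <- function(outcomes, path) {
  write.table(as.data.frame(outcomes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Northrup-Allison-McCammon association rate
#'
#' Converts the reacted fraction `beta` of trajectories started on the
#' b-sphere into an association rate:
#' \eqn{k = k_D(b) \beta / (1 - (1 - \beta) k_D(b)/k_D(q))} with
#' \eqn{k_D(r) = 4 \pi D_t r}, the diffusion-limited rate to an absorbing
#' sphere in the absence of interactions beyond it.
#'
#' @param beta reacted fraction in `[0, 1]`.
#' @param b_radius,q_radius start and escape sphere radii, A.
#' @param D_t relative translational diffusion coefficient, A^2/ps.
#' @return rate in A^3/ps.
#' @export
nam_rate <- function(beta, b_radius, q_radius, D_t) {
  stopifnot(beta >= 0, beta <= 1, b_radius > 0, D_t > 0)
  if (q_radius <= b_radius) stop("q_radius must exceed b_radius")
  kd <- function(r) 4 * pi * D_t * r
  kd(b_radius) * beta / (1 - (1 - beta) * kd(b_radius) / kd(q_radius))
}
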