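## Bound-pose geometry: orientation of the glycan chain relative to the
## fibril axis, per-sulfur nearest-atom distance features, and Ward
## clustering of poses with medoid selection.

#' Fibril principal axis
#'
#' Unit vector from the centroid of the third layer to the centroid of
#' the third-to-last layer. Fibrils with fewer than six layers cannot
#' give distinct endpoints under that rule, so the first and last layer
#' centroids are used instead (documented fallback).
#'
#' @param fibril a `fibril_model`.
#' @return unit length-3 vector.
#' @export
fibril_axis <- function(fibril) {
  cent <- layer_centroids(fibril)
  n <- nrow(cent)
  if (n >= 6) { a <- cent[3, ]; b <- cent[n - 2, ] }
  else { a <- cent[1, ]; b <- cent[n, ] }
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate fibril axis: coincident layer centroids")
  v / nv
}

#' Glycan chain axis
#'
#' Unit vector from the first to the last ring centroid, in the world
#' frame of the given pose.
#'
#' @param glycan a `glycan_model`.
#' @param pose a [rigid_pose()] (default: identity).
#' @return unit length-3 vector.
#' @export
glycan_axis <- function(glycan, pose = rigid_pose()) {
  u <- glycan$units
  if (nrow(u) < 2) stop("glycan axis needs at least two units")
  ends <- pose_apply(pose, rbind(as.numeric(u[1, c("cx", "cy", "cz")]),
                                 as.numeric(u[nrow(u), c("cx", "cy", "cz")])))
  v <- ends[2, ] - ends[1, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("degenerate glycan axis: coincident ring centroids")
  v / nv
}

#' Orientation angle of a posed glycan relative to the fibril axis
#'
#' Arc-cosine of the absolute dot product of the two unit axes, so the
#' angle lies in `[0, 90]` degrees and is insensitive to the direction
#' either axis is traversed.
#'
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @param pose a [rigid_pose()].
#' @return angle in degrees.
#' @export
orientation_angle <- function(fibril, glycan, pose) {
  d <- abs(sum(fibril_axis(fibril) * glycan_axis(glycan, pose)))
  acos(min(1, d)) * 180 / pi
}

#' Axis-alignment filter for bound poses
#'
#' A bound pose is kept when its orientation angle is at most
#' `threshold` degrees (inclusive; default 45).
#'
#' @inheritParams orientation_angle
#' @param threshold degrees.
#' @return logical.
#' @export
is_aligned <- function(fibril, glycan, pose, threshold = 45) {
  orientation_angle(fibril, glycan, pose) <= threshold
}

#' Distance features of a bound pose
#'
#' For each glycan sulfur (in the fixed order of `glycan$sulfurs`), the
#' distance to the nearest atom belonging to the binding-site residues,
#' pooled across all layers. This is the feature vector the pose
#' clustering operates on.
#'
#' @param pose a [rigid_pose()].
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @param site_residues residue numbers defining the binding site (a
#'   composite site passes several, e.g. `c(317, 321)`).
#' @return numeric vector, one distance (A) per glycan sulfur.
#' @export
pose_features <- function(pose, fibril, glycan, site_residues) {
  stopifnot(length(site_residues) >= 1)
  fa <- fibril$atoms[fibril$atoms$resno %in% site_residues, ]
  if (!nrow(fa)) stop("no fibril atoms in the requested site residues")
  f <- as.matrix(fa[, c("x", "y", "z")])
  s <- pose_apply(pose, as.matrix(glycan$sulfurs[, c("x", "y", "z")]))
  d2 <- outer(rowSums(s^2), rowSums(f^2), "+") - 2 * s %*% t(f)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Distance RMSD between two feature vectors
#'
#' `sqrt(mean((f1 - f2)^2))`; symmetric, zero iff the vectors are equal.
#'
#' @param f1,f2 equal-length numeric vectors.
#' @return RMSD in the feature units (A).
#' @export
distance_rmsd <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("feature vectors differ in length")
  sqrt(mean((f1 - f2)^2))
}

#' Ward clustering of pose feature vectors with medoid selection
#'
#' Agglomerative clustering under Ward's minimum-variance criterion,
#' applied to the pairwise distance-RMSD matrix of the feature vectors
#' (Lance-Williams update on the precomputed dissimilarity), cut at `k`
#' clusters. Each cluster is represented by its medoid, the member
#' minimizing the summed distance to its co-members.
#'
#' @param features n x p matrix, one feature vector per row (a list of
#'   equal-length vectors is accepted).
#' @param k number of clusters, `1 <= k <= n`.
#' @return object of class `cluster_result`: `labels` (1..k per pose),
#'   `k`, `medoid_indices`, `merge`, `height` (the linkage record).
#' @export
ward_cluster <- function(features, k) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1 || k > n) stop("k must be between 1 and the number of poses")
  # distance-RMSD = euclidean / sqrt(p)
  D <- dist(features) / sqrt(ncol(features))
  if (n == 1) {
    return(structure(list(labels = 1L, k = 1L, medoid_indices = 1L,
                          merge = matrix(integer(0), 0, 2),
                          height = numeric(0)),
                     class = "cluster_result"))
  }
  hc <- hclust(D, method = "ward.D2")
  labels <- cutree(hc, k = k)
  Dm <- as.matrix(D)
  medoids <- vapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(colSums(Dm[idx, idx, drop = FALSE]))]
  }, integer(1))
  structure(list(labels = labels, k = as.integer(k),
                 medoid_indices = medoids,
                 merge = hc$merge, height = hc$height),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> k =", x$k, "; sizes:",
      paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Local rigid-body pose refinement
#'
#' Steepest-descent relaxation of a bound pose on the screened-Coulomb +
#' soft-core energy surface, with backtracking step control and a fixed
#' iteration cap. This is a desk-scale stand-in for all-atom refinement:
#' it tightens contacts of a docked pose but samples no internal
#' flexibility.
#'
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @param pose starting [rigid_pose()].
#' @param solvent a [solvent_params()].
#' @param n_iter iteration cap.
#' @param trans_step,rot_step initial step sizes (A, rad).
#' @return list with the refined `pose`, final `energy` (kcal/mol) and
#'   `n_iter` performed.
#' @export
refine_pose <- function(fibril, glycan, pose, solvent = solvent_params(),
                        n_iter = 100, trans_step = 0.25, rot_step = 0.02) {
  e <- interaction_energy(fibril, glycan, pose, solvent)
  for (it in seq_len(n_iter)) {
    ft <- force_torque_on_glycan(fibril, glycan, pose, solvent)
    fn <- sqrt(sum(ft$force^2)); tn <- sqrt(sum(ft$torque^2))
    if (fn < 1e-8 && tn < 1e-8) break
    improved <- FALSE
    for (half in 0:4) {
      sc <- 0.5^half
      dt_ <- if (fn > 0) sc * trans_step * ft$force / fn else c(0, 0, 0)
      w <- if (tn > 0) sc * rot_step * ft$torque / tn else c(0, 0, 0)
      cand <- rigid_pose(
        .orthonormalize(rotation_about(w, sqrt(sum(w^2))) %*% pose$R),
        pose$t + dt_)
      ec <- interaction_energy(fibril, glycan, cand, solvent)
      if (ec < e) { pose <- cand; e <- ec; improved <- TRUE; break }
    }
    if (!improved) break
  }
  list(pose = pose, energy = e, n_iter = it)
}
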