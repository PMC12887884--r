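## Volumetric accumulation of final glycan sulfur positions from reacted
## BD trajectories, with Gaussian smoothing and OpenDX export.

#' Create an empty density grid
#'
#' Voxels are half-open intervals `[lo, hi)` per axis; a point exactly on
#' a boundary belongs to the higher-index voxel.
#'
#' @param origin length-3 lower corner, A.
#' @param spacing voxel edge, A (default 1).
#' @param dims length-3 integer voxel counts.
#' @return object of class `density_grid` with zero `counts` and zero
#'   `overflow`.
#' @export
density_grid <- function(origin, spacing = 1.0, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3, spacing > 0,
            all(dims >= 2))
  structure(list(origin = as.numeric(origin), spacing = rep(spacing, 3),
                 dims = as.integer(dims),
                 counts = array(0, as.integer(dims)), overflow = 0),
            class = c("density_grid", "volume_grid"))
}

#' Density grid covering a fibril
#'
#' @param fibril a `fibril_model`.
#' @param spacing voxel edge, A.
#' @param padding margin beyond the atom bounding box, A.
#' @return an empty [density_grid()].
#' @export
density_grid_for <- function(fibril, spacing = 1.0, padding = 15) {
  a <- fibril$atoms
  lo <- c(min(a$x), min(a$y), min(a$z)) - padding
  hi <- c(max(a$x), max(a$y), max(a$z)) + padding
  density_grid(lo, spacing, pmax(2L, ceiling((hi - lo) / spacing)))
}

#' Accumulate final sulfur positions into a density grid
#'
#' Every sulfur of every reacted final pose deposits one count into its
#' containing voxel. Escaped and step-capped trajectories are excluded.
#' Points falling outside the grid are tallied in `overflow`, never
#' silently dropped, so in-grid counts plus overflow always equal the
#' number of deposited points.
#'
#' @param outcomes a [run_ensemble()] result.
#' @param glycan the `glycan_model` the ensemble was run with.
#' @param grid a [density_grid()] (e.g. from [density_grid_for()]).
#' @return the grid with updated `counts` and `overflow`.
#' @export
accumulate_density <- function(outcomes, glycan, grid) {
  stopifnot(inherits(grid, "density_grid"))
  poses <- attr(outcomes, "poses")
  idx <- which(outcomes$status == "reacted")
  s_local <- as.matrix(glycan$sulfurs[, c("x", "y", "z")])
  counts <- grid$counts; overflow <- grid$overflow
  for (i in idx) {
    w <- pose_apply(poses[[i]], s_local)
    v <- floor(sweep(sweep(w, 2, grid$origin, "-"), 2, grid$spacing, "/"))
    inside <- v[, 1] >= 0 & v[, 1] < grid$dims[1] &
      v[, 2] >= 0 & v[, 2] < grid$dims[2] &
      v[, 3] >= 0 & v[, 3] < grid$dims[3]
    overflow <- overflow + sum(!inside)
    if (any(inside)) {
      vi <- v[inside, , drop = FALSE] + 1
      for (r in seq_len(nrow(vi)))
        counts[vi[r, 1], vi[r, 2], vi[r, 3]] <-
          counts[vi[r, 1], vi[r, 2], vi[r, 3]] + 1
    }
  }
  grid$counts <- counts; grid$overflow <- overflow
  grid
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>", paste(x$dims, collapse = " x "), "voxels at",
      x$spacing[1], "A;", sum(x$counts), "counts in grid,",
      x$overflow, "overflow\n")
  invisible(x)
}

#' Gaussian smoothing of a density grid
#'
#' Separable Gaussian convolution with standard deviation `sigma`
#' (Angstrom). `sigma = 0` is the identity. The result is rescaled so the
#' total in-grid count is conserved.
#'
#' @param grid a [density_grid()].
#' @param sigma kernel standard deviation, A.
#' @return the smoothed grid.
#' @export
smooth_density <- function(grid, sigma) {
  stopifnot(inherits(grid, "density_grid"), sigma >= 0)
  if (sigma == 0) return(grid)
  total <- sum(grid$counts)
  half <- max(1L, ceiling(3 * sigma / grid$spacing[1]))
  kx <- exp(-((-half:half) * grid$spacing[1])^2 / (2 * sigma^2))
  kx <- kx / sum(kx)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in seq_along(kx)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok] <- out[ok] + kx[j] * v[src[ok]]
    }
    out
  }
  a <- grid$counts
  a <- apply(a, c(2, 3), conv1)                       # along x
  a <- aperm(apply(a, c(1, 3), conv1), c(2, 1, 3))    # along y
  a <- aperm(apply(a, c(1, 2), conv1), c(2, 3, 1))    # along z
  if (sum(a) > 0) a <- a * (total / sum(a))
  grid$counts <- a
  grid
}

## ---- OpenDX export ----------------------------------------------------

.grid_values <- function(grid) {
  if (inherits(grid, "density_grid")) grid$counts else grid$values
}

#' Write a grid in OpenDX scalar-field format
#'
#' The APBS-compatible OpenDX dialect readable by standard molecular
#' viewers (regular positions/connections, data follows in C order:
#' z fastest).
#'
#' @param grid a `density_grid` or `potential_grid`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dx <- function(grid, path) {
  vals <- .grid_values(grid)
  d <- dim(vals)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by fibrilBD",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste("object 3 class array type double rank 0 items %d",
                  "data follows"), prod(d))), con)
  # C order: z fastest, then y, then x
  flat <- as.numeric(aperm(vals, c(3, 2, 1)))
  n <- length(flat)
  n3 <- (n %/% 3) * 3
  if (n3 > 0)
    writeLines(sprintf("%.6e %.6e %.6e",
                       flat[seq(1, n3, 3)], flat[seq(2, n3, 3)],
                       flat[seq(3, n3, 3)]), con)
  if (n > n3)
    writeLines(paste(sprintf("%.6e", flat[(n3 + 1):n]), collapse = " "),
               con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"regular positions regular connections\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' Counterpart of [write_dx()]; parses the regular-grid dialect.
#'
#' @param path a DX file.
#' @return a `volume_grid` list (`origin`, `spacing`, `dims`, `values`).
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX grid: no gridpositions object")
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "\\s+")[[1]])
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", org)), "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)[1:3]
  dm <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  spacing <- diag(dm)
  start <- grep("data follows", lines)[1] + 1L
  end <- grep("^attribute", lines)[1]
  if (is.na(end)) end <- length(lines) + 1L
  nums <- as.numeric(unlist(strsplit(trimws(lines[start:(end - 1L)]),
                                     "\\s+")))
  nums <- nums[!is.na(nums)]
  if (length(nums) != prod(dims)) stop("DX data length mismatch")
  vals <- aperm(array(nums, rev(dims)), c(3, 2, 1))
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = vals),
            class = "volume_grid")
}
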