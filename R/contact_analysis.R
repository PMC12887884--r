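## Salt-bridge contact detection (cationic N within 4.5 A of an anionic
## HCG oxygen) and per-frame statistics: unique-residue and unique-HCG
## bound counts, medians, and unit/group-resolved contact frequency maps.

#' Salt-bridge contact parameters
#'
#' @param cutoff contact distance, A (default 4.5, inclusive).
#' @return object of class `contact_params`.
#' @export
contact_params <- function(cutoff = 4.5) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff), class = "contact_params")
}

#' Detect salt-bridge contacts for one frame
#'
#' All pairs of a fibril cationic nitrogen (NZ of lysine, NH1/NH2 of
#' arginine) and a glycan HCG oxygen (sulfate, sulfamido and carboxylate
#' oxygens) within the cutoff, inclusive. Contacts are reported at
#' residue x layer x HCG granularity: a pair is collapsed onto its
#' charged group, so several oxygens of one sulfate touching the same
#' side chain count once.
#'
#' @param pose glycan [rigid_pose()].
#' @param fibril a `fibril_model`.
#' @param glycan a `glycan_model`.
#' @param params a [contact_params()].
#' @return data frame with columns `resno`, `layer`, `hcg_id`, `unit`,
#'   `group_type`, `distance` (closest pair, A); zero rows when no
#'   contact exists.
#' @export
detect_contacts <- function(pose, fibril, glycan,
                            params = contact_params()) {
  fa <- fibril$atoms[fibril$atoms$contact_ref, ]
  ga <- glycan$atoms[!is.na(glycan$atoms$hcg_id), ]
  empty <- data.frame(resno = integer(), layer = integer(),
                      hcg_id = integer(), unit = integer(),
                      group_type = character(), distance = numeric())
  if (!nrow(fa) || !nrow(ga)) return(empty)
  f <- as.matrix(fa[, c("x", "y", "z")])
  g <- pose_apply(pose, as.matrix(ga[, c("x", "y", "z")]))
  d2 <- outer(rowSums(f^2), rowSums(g^2), "+") - 2 * f %*% t(g)
  d2 <- pmax(d2, 0)
  hit <- which(d2 <= params$cutoff^2 + 1e-12, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  pairs <- data.frame(resno = fa$resno[hit[, 1]],
                      layer = fa$layer[hit[, 1]],
                      hcg_id = ga$hcg_id[hit[, 2]],
                      unit = ga$unit[hit[, 2]],
                      group_type = ga$group_type[hit[, 2]],
                      distance = sqrt(d2[hit]))
  key <- paste(pairs$resno, pairs$layer, pairs$hcg_id)
  keep <- !duplicated(key)
  out <- pairs[keep, , drop = FALSE]
  out$distance <- as.numeric(tapply(pairs$distance, key, min)[key[keep]])
  out <- out[order(out$resno, out$layer, out$hcg_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a contact series from a set of frames
#'
#' @param frames list of [detect_contacts()] data frames (one per frame).
#' @return object of class `contact_series`.
#' @export
contact_series <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 1)
  structure(list(frames = frames, n_frames = length(frames)),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("<contact_series>", x$n_frames, "frames, mean contacts/frame",
      signif(mean(vapply(x$frames, nrow, integer(1))), 3), "\n")
  invisible(x)
}

#' Per-frame unique bound counts
#'
#' Residues are counted at residue x layer granularity (each rung of a
#' ladder counts separately); HCGs are counted once each regardless of
#' how many side chains they touch.
#'
#' @param contacts a [detect_contacts()] frame.
#' @return named integer vector `c(residues = ..., hcgs = ...)`.
#' @export
frame_counts <- function(contacts) {
  c(residues = length(unique(paste(contacts$resno, contacts$layer))),
    hcgs = length(unique(contacts$hcg_id)))
}

# lower median: for even-length samples take the lower of the two central
# order statistics, matching integer-valued count reporting
.lower_median <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

#' Median number of residues or charged groups bound per frame
#'
#' Lower-median convention for even frame counts, so the reported median
#' of integer counts is itself an integer.
#'
#' @param series a [contact_series()].
#' @param which `"residues"` or `"hcgs"`.
#' @param sites optional residue numbers restricting the count to one
#'   (possibly composite) binding site.
#' @return list with `median` and `distribution` (normalized histogram of
#'   per-frame counts, named by count).
#' @export
median_bound <- function(series, which = c("residues", "hcgs"),
                         sites = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(series, "contact_series"))
  if (series$n_frames < 1) stop("empty contact series")
  counts <- vapply(series$frames, function(fr) {
    if (!is.null(sites)) fr <- fr[fr$resno %in% sites, , drop = FALSE]
    frame_counts(fr)[[which]]
  }, integer(1))
  tab <- table(factor(counts, levels = 0:max(counts)))
  list(median = .lower_median(counts),
       distribution = as.numeric(tab) / length(counts),
       counts = counts)
}

#' Ensemble-averaged contact frequency map
#'
#' For each (glycan unit, functional group) and each binding residue, the
#' fraction of frames with at least one contact, pooled over fibril
#' layers. By default the N-sulfamido column is reported alongside the
#' OS2X/OS6X/O6X groups; `include_sulfamido = FALSE` restricts the map to
#' the sulfate and carboxylate groups.
#'
#' @param series a [contact_series()].
#' @param glycan a `glycan_model`.
#' @param fibril a `fibril_model`.
#' @param include_sulfamido keep the N_sulfamido rows (default TRUE).
#' @return object of class `frequency_map`: a matrix with rows
#'   `unit:group` and one column per binding-site residue, values in
#'   `[0, 1]`.
#' @export
frequency_map <- function(series, glycan, fibril,
                          include_sulfamido = TRUE) {
  stopifnot(inherits(series, "contact_series"))
  groups <- unique(glycan$hcgs[, c("unit", "group_type")])
  if (!include_sulfamido)
    groups <- groups[groups$group_type != "N_sulfamido", , drop = FALSE]
  groups <- groups[order(groups$unit, groups$group_type), ]
  rows <- paste0(groups$unit, ":", groups$group_type)
  resn <- sort(unique(fibril$atoms$resno[fibril$atoms$contact_ref]))
  m <- matrix(0, nrow(groups), length(resn),
              dimnames = list(rows, as.character(resn)))
  for (fr in series$frames) {
    if (!nrow(fr)) next
    key <- unique(data.frame(unit = fr$unit, group_type = fr$group_type,
                             resno = fr$resno))
    ri <- match(paste0(key$unit, ":", key$group_type), rows)
    ci <- match(as.character(key$resno), colnames(m))
    ok <- !is.na(ri) & !is.na(ci)
    m[cbind(ri[ok], ci[ok])] <- m[cbind(ri[ok], ci[ok])] + 1
  }
  m <- m / series$n_frames
  structure(m, class = c("frequency_map", "matrix"))
}

#' @export
#' @importFrom graphics axis image
plot.frequency_map <- function(x, main = "contact frequency", ...) {
  m <- unclass(x)
  image(seq_len(nrow(m)), seq_len(ncol(m)), m, zlim = c(0, 1),
        xlab = "glycan unit:group", ylab = "residue", axes = FALSE,
        main = main, ...)
  axis(1, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
       cex.axis = 0.7)
  axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 1,
       cex.axis = 0.7)
  invisible(x)
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("<frequency_map>", nrow(x), "unit:group rows x", ncol(x),
      "residues; max", signif(max(x), 3), "\n")
  invisible(x)
}

#' Write a contact series as TSV
#'
#' One row per contact with its frame index.
#'
#' @param series a [contact_series()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_contact_series <- function(series, path) {
  rows <- lapply(seq_along(series$frames), function(i) {
    fr <- series$frames[[i]]
    if (!nrow(fr)) return(NULL)
    cbind(frame = i, fr)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(frame = integer(), resno = integer(),
                     layer = integer(), hcg_id = integer(),
                     unit = integer(), group_type = character(),
                     distance = numeric())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
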