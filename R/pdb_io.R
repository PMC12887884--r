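## PDB import/export, layered on bio3d. Fibrils are written one chain per
## layer (protofilament 2 continues the chain alphabet); glycans as HETATM
## records on chain "G" with heparin residue names SGN/IDS.

.chain_ids <- c(LETTERS, letters, as.character(0:9))

#' Write a model to a PDB file
#'
#' @param x a `fibril_model` or `glycan_model`, optionally posed.
#' @param path output file.
#' @param pose optional [rigid_pose()] applied to a glycan before writing.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(x, path, pose = NULL) UseMethod("write_pdb")

#' @export
write_pdb.fibril_model <- function(x, path, pose = NULL) {
  a <- x$atoms
  key <- (a$protofilament - 1L) * x$n_layers + a$layer + 1L
  if (max(key) > length(.chain_ids))
    stop("too many layers for distinct PDB chain identifiers")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(a$x, a$y, a$z))),
                   resno = a$resno, resid = a$resname,
                   elety = a$atom_name, chain = .chain_ids[key],
                   o = as.numeric(a$exposed), b = a$charge)
  invisible(path)
}

#' @export
write_pdb.glycan_model <- function(x, path, pose = NULL) {
  resid <- ifelse(x$units$kind == "glucosamine", "SGN", "IDS")
  at <- rbind(
    data.frame(atom_name = x$atoms$atom_name, unit = x$atoms$unit,
               x = x$atoms$x, y = x$atoms$y, z = x$atoms$z,
               charge = ifelse(is.na(x$atoms$hcg_id), 0,
                               -1 / tapply(x$atoms$hcg_id, x$atoms$hcg_id,
                                           length)[as.character(x$atoms$hcg_id)]),
               stringsAsFactors = FALSE),
    data.frame(atom_name = x$sulfurs$atom_name, unit = x$sulfurs$unit,
               x = x$sulfurs$x, y = x$sulfurs$y, z = x$sulfurs$z, charge = 0))
  at <- at[order(at$unit, at$atom_name), ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (!is.null(pose)) xyz <- pose_apply(pose, xyz)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = rep("HETATM", nrow(at)),
                   resno = at$unit, resid = resid[at$unit],
                   elety = at$atom_name, chain = rep("G", nrow(at)),
                   o = rep(1, nrow(at)), b = at$charge)
  invisible(path)
}

## quick structural validation of ATOM/HETATM records before handing the
## file to bio3d, so malformed lines are reported with their line number
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in '", path, "'")
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords))
      stop("malformed ATOM record at line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

#' Read a fibril from a PDB file
#'
#' Reconstructs a `fibril_model` from standard ATOM records. Layers are
#' assigned one-per-chain when the file has multiple chains of equal
#' residue composition (the layout [write_pdb()] produces and the layout
#' of per-monomer-chain fibril depositions); otherwise residues are binned
#' axially by projecting onto the principal axis of the CA trace and
#' splitting at gaps larger than half the expected rise. Charges and atom
#' roles are re-derived from residue and atom names; solvent exposure
#' defaults to exposed, or to an outward-side-chain heuristic when
#' `exposure = "heuristic"`.
#'
#' @param path PDB file with a single model.
#' @param rise expected layer spacing (used only for axial binning).
#' @param exposure `"all"` (every basic residue exposed) or `"heuristic"`
#'   (side-chain tip must point away from the layer centroid). Files
#'   written by [write_pdb()] carry the exposure flag in the occupancy
#'   column; when a file contains zero occupancies that flag wins, making
#'   the write/read cycle lossless.
#' @return a `fibril_model`.
#' @export
read_pdb <- function(path, rise = 4.8, exposure = c("all", "heuristic")) {
  exposure <- match.arg(exposure)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), ]
  if (!nrow(a)) stop("no atoms parsed from '", path, "'")

  atoms <- data.frame(atom_name = a$elety, resno = a$resno,
                      resname = a$resid,
                      x = a$x, y = a$y, z = a$z, chain = a$chain,
                      stringsAsFactors = FALSE)

  # layer assignment
  chains <- unique(atoms$chain)
  if (length(chains) > 1L) {
    ord <- order(vapply(chains,
                        function(ch) mean(atoms$z[atoms$chain == ch]),
                        numeric(1)))
    layer_of <- match(atoms$chain, chains[ord]) - 1L
  } else {
    ca <- atoms[atoms$atom_name == "CA", ]
    if (!nrow(ca)) ca <- atoms
    ax <- prcomp(cbind(ca$x, ca$y, ca$z))$rotation[, 1]
    proj <- cbind(atoms$x, atoms$y, atoms$z) %*% ax
    rkey <- paste(atoms$chain, atoms$resno)
    rproj <- tapply(as.numeric(proj), rkey, mean)
    o <- order(rproj)
    gap <- c(FALSE, diff(rproj[o]) > rise / 2)
    lab <- cumsum(gap)
    layer_of <- lab[match(rkey, names(rproj)[o])]
  }
  atoms$layer <- as.integer(layer_of)
  atoms$chain <- NULL

  chg <- .default_charge_rules[match(atoms$resname,
                                     unname(.aa3[names(.default_charge_rules)]))]
  rescharge <- ifelse(is.na(chg), 0, chg)
  atoms$charge <- 0
  atoms$charge[atoms$resname == "LYS" & atoms$atom_name == "NZ"] <- 1
  atoms$charge[atoms$resname == "ARG" & atoms$atom_name == "CZ"] <- 1
  atoms$charge[atoms$resname == "ASP" & atoms$atom_name == "OD1"] <- -1
  atoms$charge[atoms$resname == "GLU" & atoms$atom_name == "OE1"] <- -1
  atoms$role <- ifelse(atoms$atom_name %in%
                         c("CA", "C", "N", "O", "CB"), "backbone",
                       "charged_sidechain")

  # exposure
  res <- unique(atoms[, c("resno", "resname")])
  res <- res[order(res$resno), ]
  exposed_res <- rep(TRUE, nrow(res))
  occ <- suppressWarnings(as.numeric(a$o))
  if (any(!is.na(occ) & occ == 0)) {
    # occupancy column written by write_pdb carries the exposure flag
    buried <- unique(atoms$resno[!is.na(occ) & occ == 0])
    exposed_res <- !(res$resno %in% buried)
  } else if (exposure == "heuristic") {
    for (i in seq_len(nrow(res))) {
      tip <- switch(res$resname[i], LYS = "NZ", ARG = "CZ",
                    ASP = "OD1", GLU = "OE1", NA)
      if (is.na(tip)) next
      sel <- atoms$resno == res$resno[i]
      votes <- vapply(unique(atoms$layer[sel]), function(L) {
        lsel <- atoms$layer == L
        ctr <- c(mean(atoms$x[lsel]), mean(atoms$y[lsel]))
        cai <- sel & lsel & atoms$atom_name == "CA"
        tpi <- sel & lsel & atoms$atom_name == tip
        if (!any(cai) || !any(tpi)) return(NA)
        v_sc <- c(atoms$x[tpi][1] - atoms$x[cai][1],
                  atoms$y[tpi][1] - atoms$y[cai][1])
        v_out <- c(atoms$x[cai][1] - ctr[1], atoms$y[cai][1] - ctr[2])
        sum(v_sc * v_out) > 0
      }, logical(1))
      votes <- votes[!is.na(votes)]
      if (length(votes)) exposed_res[i] <- mean(votes) > 0.5
    }
  }
  atoms$exposed <- exposed_res[match(atoms$resno, res$resno)]
  rchg <- rescharge[match(res$resno, atoms$resno)]
  atoms$bd_ref <- ((atoms$resname == "LYS" & atoms$atom_name == "NZ") |
                     (atoms$resname == "ARG" & atoms$atom_name == "CZ")) &
    atoms$exposed
  atoms$contact_ref <- (atoms$resname == "LYS" & atoms$atom_name == "NZ") |
    (atoms$resname == "ARG" & atoms$atom_name %in% c("NH1", "NH2"))
  atoms$protofilament <- 1L

  site_list <- sort(unique(atoms$resno[atoms$bd_ref]))
  n_layers <- length(unique(atoms$layer))
  center <- colMeans(atoms[, c("x", "y", "z")])
  # synthesize a minimal residue table standing in for the template
  tpl <- structure(list(
    residues = data.frame(resno = res$resno, resname = res$resname,
                          letter = names(.aa3)[match(res$resname, .aa3)],
                          charge = rchg,
                          exposed = exposed_res),
    atoms = atoms[atoms$layer == min(atoms$layer), ],
    layout = "imported", spacing = NA_real_),
    class = "cross_section_template")
  structure(list(atoms = atoms, template = tpl, n_layers = n_layers,
                 rise = rise, twist = 0, n_protofilaments = 1L,
                 protofilament_transform = NULL, site_list = site_list,
                 center = center,
                 bounding_radius = sqrt(max((atoms$x - center[1])^2 +
                                              (atoms$y - center[2])^2 +
                                              (atoms$z - center[3])^2))),
            class = "fibril_model")
}
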