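## Synthetic structure generators: an idealized parallel in-register fibril
## built by stacking a charged cross-section template, and a linear sulfated
## glycan chain of alternating glucosamine / iduronic-acid units.

# one-letter -> three-letter code for the 20 standard amino acids
.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.default_charge_rules <- c(K = 1, R = 1, D = -1, E = -1)

## Side-chain atom geometry, in a local frame where +y is the outward
## direction of the cross-section and +x runs along the chain. Offsets are
## coarse side-chain lengths (A), not real rotamer geometry: only the tip
## atoms that carry charge or serve as reference/contact atoms are built.
.sidechain_atoms <- function(resname) {
  switch(resname,
    LYS = data.frame(atom_name = "NZ", dx = 0, dy = 5.4, dz = 0,
                     charge = 1, bd_ref = TRUE, contact_ref = TRUE),
    ARG = data.frame(atom_name = c("CZ", "NH1", "NH2"),
                     dx = c(0, 1.0, -1.0), dy = c(6.2, 6.9, 6.9), dz = 0,
                     charge = c(1, 0, 0),
                     bd_ref = c(TRUE, FALSE, FALSE),
                     contact_ref = c(FALSE, TRUE, TRUE)),
    ASP = data.frame(atom_name = "OD1", dx = 0, dy = 3.7, dz = 0,
                     charge = -1, bd_ref = FALSE, contact_ref = FALSE),
    GLU = data.frame(atom_name = "OE1", dx = 0, dy = 4.9, dz = 0,
                     charge = -1, bd_ref = FALSE, contact_ref = FALSE),
    NULL)
}

#' Build a fibril cross-section template
#'
#' One layer of a parallel in-register beta-sheet fibril: a CA trace laid
#' out either on a line (`ladder_line`) or on an open arc (`C_shape`), with
#' coarse charged side-chain tips pointing outward. Charges follow the
#' residue identity: Lys/Arg +1 e, Asp/Glu -1 e, all else neutral.
#'
#' @param sequence one-letter amino-acid string for the layer.
#' @param layout `"C_shape"` (default, open arc) or `"ladder_line"`.
#' @param start_resno residue number of the first residue.
#' @param buried residue numbers to mark as not solvent exposed. Binding
#'   sites are the solvent-exposed basic residues, so burying a Lys removes
#'   it from the site list.
#' @param spacing CA-CA spacing along the layout, Angstrom.
#' @param charge_rules named numeric vector mapping one-letter codes to
#'   formal side-chain charges.
#' @return object of class `cross_section_template` with elements
#'   `residues` (data frame: resno, resname, letter, charge, exposed) and
#'   `atoms` (CA trace plus side-chain tips with roles).
#' @examples
#' tpl <- build_cross_section("KAK", layout = "ladder_line")
#' tpl$residues$charge   # +1, 0, +1
#' @export
build_cross_section <- function(sequence,
                                layout = c("C_shape", "ladder_line"),
                                start_resno = 1L, buried = integer(),
                                spacing = 3.8,
                                charge_rules = .default_charge_rules) {
  layout <- match.arg(layout)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence),
            is.finite(spacing), spacing > 0)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(letters1 %in% names(.aa3)))
  if (length(bad))
    stop("unknown residue letter '", letters1[bad[1]], "' at position ", bad[1])

  n <- length(letters1)
  resno <- seq.int(start_resno, length.out = n)
  resname <- unname(.aa3[letters1])
  charge <- unname(ifelse(letters1 %in% names(charge_rules),
                          charge_rules[letters1], 0))
  exposed <- !(resno %in% buried)

  if (layout == "ladder_line") {
    ca <- cbind(x = (seq_len(n) - 1) * spacing, y = 0)
    outward <- cbind(rep(0, n), rep(1, n))
    tangent <- cbind(rep(1, n), rep(0, n))
  } else {
    # open arc spanning 300 degrees so the shape reads as a "C"
    span <- 300 * pi / 180
    radius <- if (n > 1) (n - 1) * spacing / span else spacing
    theta <- if (n > 1) seq(0, span, length.out = n) else 0
    ca <- cbind(x = radius * cos(theta), y = radius * sin(theta))
    outward <- cbind(cos(theta), sin(theta))
    tangent <- cbind(-sin(theta), cos(theta))
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    at <- data.frame(atom_name = "CA", dx = 0, dy = 0, dz = 0, charge = 0,
                     bd_ref = FALSE, contact_ref = FALSE)
    sc <- .sidechain_atoms(resname[i])
    if (!is.null(sc)) at <- rbind(at, sc)
    # local (dx, dy) -> plane via tangent/outward basis
    px <- ca[i, 1] + at$dx * tangent[i, 1] + at$dy * outward[i, 1]
    py <- ca[i, 2] + at$dx * tangent[i, 2] + at$dy * outward[i, 2]
    rows[[i]] <- data.frame(
      atom_name = at$atom_name, resno = resno[i], resname = resname[i],
      x = px, y = py, z = at$dz, charge = at$charge,
      role = ifelse(at$atom_name == "CA", "backbone", "charged_sidechain"),
      bd_ref = at$bd_ref & exposed[i] & charge[i] > 0,
      contact_ref = at$contact_ref & charge[i] > 0,
      exposed = exposed[i])
  }
  atoms <- do.call(rbind, rows)
  atoms$charge <- atoms$charge * (atoms$atom_name != "CA")

  structure(list(
    residues = data.frame(resno = resno, resname = resname, letter = letters1,
                          charge = charge, exposed = exposed),
    atoms = atoms, layout = layout, spacing = spacing),
    class = "cross_section_template")
}

#' @export
print.cross_section_template <- function(x, ...) {
  cat("<cross_section_template>", nrow(x$residues), "residues (",
      x$residues$resno[1], "-", max(x$residues$resno), "), layout",
      x$layout, "\n")
  cat("  basic:", sum(x$residues$charge > 0),
      " acidic:", sum(x$residues$charge < 0),
      " buried:", sum(!x$residues$exposed), "\n")
  invisible(x)
}

#' Packaged tau-like fibril core template
#'
#' Cross-section template for the 73-residue amyloid core of the tau
#' microtubule-binding region (residues 306-378, 2N4R numbering), arranged
#' as a C-shaped layer. K370, D314 and E372 are marked buried, so the site
#' list is the eleven solvent-exposed basic residues K311, K317, K321,
#' K331, K340, K343, K347, R349, K353, K369 and K375.
#'
#' @return a [build_cross_section()] template.
#' @export
tau_template <- function() {
  seq306 <- paste0("VQIVYKPVDLSKVTSKCGSLGNIHHKPGGGQVEVKSEKLDFKDRVQSKIG",
                   "SLDNITHVPGGGNKKIETHKLTF")
  build_cross_section(seq306, layout = "C_shape", start_resno = 306L,
                      buried = c(314L, 370L, 372L))
}

#' Stack a cross-section template into a fibril
#'
#' Layers are congruent copies of the template, translated by `rise` along
#' z (the fibril axis) with an optional per-layer twist about the axis. A
#' second protofilament, if requested, is a rigid copy of the first.
#'
#' @param template a [build_cross_section()] template.
#' @param n_layers number of stacked layers (>= 3).
#' @param rise axial spacing between successive layers, Angstrom
#'   (default 4.8, the cross-beta interstrand spacing).
#' @param twist per-layer twist in degrees about the axis (default 0).
#' @param n_protofilaments 1 or 2.
#' @param protofilament_transform a [rigid_pose()] mapping protofilament 1
#'   onto protofilament 2; default is a C2 rotation about z plus a lateral
#'   offset clearing the first protofilament.
#' @return object of class `fibril_model`: `atoms` data frame (atom_name,
#'   resno, resname, layer 0-based, protofilament, x/y/z, charge, role,
#'   bd_ref, contact_ref, exposed), the generating parameters, and
#'   `site_list` (solvent-exposed basic residue numbers).
#' @examples
#' fib <- build_fibril(tau_template(), n_layers = 10)
#' fib$site_list
#' @export
build_fibril <- function(template, n_layers = 10L, rise = 4.8, twist = 0,
                         n_protofilaments = 1L,
                         protofilament_transform = NULL) {
  stopifnot(inherits(template, "cross_section_template"))
  if (n_layers < 3)
    stop("n_layers must be >= 3 (fibril axis needs distinct layer centroids)")
  stopifnot(rise > 0, n_protofilaments %in% c(1L, 2L))

  base <- template$atoms
  layers <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    a <- base
    if (twist != 0) {
      ang <- (k - 1) * twist * pi / 180
      xy <- cbind(a$x, a$y) %*% t(matrix(c(cos(ang), sin(ang),
                                           -sin(ang), cos(ang)), 2, 2))
      a$x <- xy[, 1]; a$y <- xy[, 2]
    }
    a$z <- a$z + (k - 1) * rise
    a$layer <- k - 1L
    layers[[k]] <- a
  }
  atoms <- do.call(rbind, layers)
  atoms$protofilament <- 1L

  if (n_protofilaments == 2L) {
    if (is.null(protofilament_transform)) {
      off <- 2 * max(sqrt(atoms$x^2 + atoms$y^2)) + 8
      protofilament_transform <- rigid_pose(rotation_about(c(0, 0, 1), pi),
                                            c(off, 0, 0))
    }
    p2 <- atoms
    w <- pose_apply(protofilament_transform, cbind(p2$x, p2$y, p2$z))
    p2$x <- w[, 1]; p2$y <- w[, 2]; p2$z <- w[, 3]
    p2$protofilament <- 2L
    atoms <- rbind(atoms, p2)
  }
  rownames(atoms) <- NULL

  site_list <- template$residues$resno[template$residues$charge > 0 &
                                         template$residues$exposed]
  center <- colMeans(atoms[, c("x", "y", "z")])
  structure(list(atoms = atoms, template = template, n_layers = n_layers,
                 rise = rise, twist = twist,
                 n_protofilaments = n_protofilaments,
                 protofilament_transform = protofilament_transform,
                 site_list = site_list, center = center,
                 bounding_radius = sqrt(max((atoms$x - center[1])^2 +
                                              (atoms$y - center[2])^2 +
                                              (atoms$z - center[3])^2))),
            class = "fibril_model")
}

#' @export
print.fibril_model <- function(x, ...) {
  cat("<fibril_model>", x$n_layers, "layers x",
      nrow(x$template$residues), "residues, rise", x$rise, "A,",
      x$n_protofilaments, "protofilament(s)\n")
  cat("  sites:", paste0(x$template$residues$letter[
    match(x$site_list, x$template$residues$resno)], x$site_list,
    collapse = " "), "\n")
  invisible(x)
}

#' Per-layer centroids of a fibril
#'
#' @param fibril a `fibril_model`.
#' @return n_layers x 3 matrix of layer centroids (protofilaments pooled).
#' @export
layer_centroids <- function(fibril) {
  stopifnot(inherits(fibril, "fibril_model"))
  a <- fibril$atoms
  sp <- split(seq_len(nrow(a)), a$layer)
  t(vapply(sp, function(i) colMeans(cbind(a$x[i], a$y[i], a$z[i])),
           numeric(3)))
}

## ---- glycan -----------------------------------------------------------

# local atom geometry of one saccharide, relative to the ring centroid.
# Sulfate/sulfamido groups carry a sulfur plus terminal oxygens; the
# iduronate carboxylate has two oxygens and no sulfur.
.glcn_geometry <- function() {
  list(
    ring = c(0, 0, 0),
    S2 = c(-1.0, 1.7, 0.8),
    N_sulfamido_O = rbind(c(-1.0, 3.0, 1.2), c(-1.9, 1.3, 1.9)),
    S6 = c(1.2, -1.7, 0.9),
    OS6X_O = rbind(c(1.2, -3.0, 1.3), c(2.1, -1.3, 1.9), c(0.3, -1.3, 2.0)))
}

.idoa_geometry <- function() {
  list(
    ring = c(0, 0, 0),
    S2 = c(-1.0, 1.7, -0.8),
    OS2X_O = rbind(c(-1.0, 3.0, -1.2), c(-1.9, 1.3, -1.9), c(-0.1, 1.3, -2.0)),
    O6X_O = rbind(c(1.1, -1.5, -0.9), c(1.9, -1.0, -1.7)))
}

#' Build a linear sulfated glycan chain
#'
#' Heparin-like chain of alternating glucosamine (odd units, GlcNS(6S))
#' and iduronic-acid (even units, IdoA(2S)) saccharides laid out along x.
#' Each glucosamine carries an N-sulfamido group (sulfur S2) and a
#' 6-O-sulfate (sulfur S6); each iduronate carries a 2-O-sulfate (sulfur
#' S2) and a carboxylate. Every charged group (HCG) carries a formal -1 e
#' located at the centroid of its terminal oxygens. A fully sulfated
#' octasaccharide therefore carries 16 HCGs. Desulfation variants remove
#' the 2-O-sulfates (`desulfated_2O`) or 6-O-sulfates (`desulfated_6O`)
#' together with their sulfurs.
#'
#' @param n_saccharides even chain length >= 2 (4, 8 or 10 in typical use).
#' @param sulfation `"full"`, `"desulfated_2O"` or `"desulfated_6O"`.
#' @param repeat_rise length of one disaccharide repeat along the chain,
#'   Angstrom (default 8.7, the helical heparin repeat).
#' @return object of class `glycan_model` with `units`, `atoms` (ring
#'   carbons, sulfurs, HCG oxygens), `hcgs` (one row per charged group with
#'   its charge center), `sulfurs` (reference atoms), `net_charge`.
#'   Coordinates are a body frame centred on the mean ring centroid.
#' @examples
#' gly <- build_glycan(8)
#' nrow(gly$hcgs)       # 16
#' gly$net_charge       # -16
#' @export
build_glycan <- function(n_saccharides = 8L,
                         sulfation = c("full", "desulfated_2O",
                                       "desulfated_6O"),
                         repeat_rise = 8.7) {
  sulfation <- match.arg(sulfation)
  if (n_saccharides < 2 || n_saccharides %% 2 != 0)
    stop("n_saccharides must be an even number >= 2")
  stopifnot(repeat_rise > 0)

  step <- repeat_rise / 2
  units <- data.frame(
    unit = seq_len(n_saccharides),
    kind = ifelse(seq_len(n_saccharides) %% 2 == 1,
                  "glucosamine", "iduronic_acid"),
    cx = (seq_len(n_saccharides) - 1) * step, cy = 0, cz = 0)

  atoms <- list(); hcgs <- list(); sulfurs <- list()
  hid <- 0L
  add_hcg <- function(unit, type, omat) {
    hid <<- hid + 1L
    oxy <- data.frame(atom_name = paste0("O", hid,
                                         LETTERS[seq_len(nrow(omat))]),
                      unit = unit, element = "O",
                      x = omat[, 1], y = omat[, 2], z = omat[, 3],
                      hcg_id = hid, group_type = type)
    ctr <- colMeans(omat)
    list(oxy = oxy,
         hcg = data.frame(hcg_id = hid, unit = unit, group_type = type,
                          charge = -1, qx = ctr[1], qy = ctr[2], qz = ctr[3]))
  }

  for (i in seq_len(n_saccharides)) {
    ctr <- as.numeric(units[i, c("cx", "cy", "cz")])
    shift <- function(v) sweep(rbind(v), 2, ctr, "+")
    if (units$kind[i] == "glucosamine") {
      g <- .glcn_geometry()
      atoms[[length(atoms) + 1L]] <- data.frame(
        atom_name = "C1", unit = i, element = "C",
        x = ctr[1], y = ctr[2], z = ctr[3], hcg_id = NA_integer_,
        group_type = NA_character_)
      # N-sulfamido: always present
      s2 <- shift(g$S2)
      sulfurs[[length(sulfurs) + 1L]] <- data.frame(
        atom_name = "S2", unit = i, x = s2[1], y = s2[2], z = s2[3])
      r <- add_hcg(i, "N_sulfamido", shift(g$N_sulfamido_O))
      atoms[[length(atoms) + 1L]] <- r$oxy; hcgs[[length(hcgs) + 1L]] <- r$hcg
      if (sulfation != "desulfated_6O") {
        s6 <- shift(g$S6)
        sulfurs[[length(sulfurs) + 1L]] <- data.frame(
          atom_name = "S6", unit = i, x = s6[1], y = s6[2], z = s6[3])
        r <- add_hcg(i, "OS6X", shift(g$OS6X_O))
        atoms[[length(atoms) + 1L]] <- r$oxy
        hcgs[[length(hcgs) + 1L]] <- r$hcg
      }
    } else {
      g <- .idoa_geometry()
      atoms[[length(atoms) + 1L]] <- data.frame(
        atom_name = "C1", unit = i, element = "C",
        x = ctr[1], y = ctr[2], z = ctr[3], hcg_id = NA_integer_,
        group_type = NA_character_)
      if (sulfation != "desulfated_2O") {
        s2 <- shift(g$S2)
        sulfurs[[length(sulfurs) + 1L]] <- data.frame(
          atom_name = "S2", unit = i, x = s2[1], y = s2[2], z = s2[3])
        r <- add_hcg(i, "OS2X", shift(g$OS2X_O))
        atoms[[length(atoms) + 1L]] <- r$oxy
        hcgs[[length(hcgs) + 1L]] <- r$hcg
      }
      r <- add_hcg(i, "O6X", shift(g$O6X_O))
      atoms[[length(atoms) + 1L]] <- r$oxy; hcgs[[length(hcgs) + 1L]] <- r$hcg
    }
  }
  atoms <- do.call(rbind, atoms); rownames(atoms) <- NULL
  hcgs <- do.call(rbind, hcgs); rownames(hcgs) <- NULL
  sulfurs <- do.call(rbind, sulfurs); rownames(sulfurs) <- NULL

  # body frame centred on the mean ring centroid (independent of sulfation)
  ctr0 <- colMeans(units[, c("cx", "cy", "cz")])
  for (cc in c("x", "y", "z")) atoms[[cc]] <- atoms[[cc]] - ctr0[[paste0("c", cc)]]
  for (cc in c("x", "y", "z")) sulfurs[[cc]] <- sulfurs[[cc]] - ctr0[[paste0("c", cc)]]
  hcgs$qx <- hcgs$qx - ctr0[["cx"]]; hcgs$qy <- hcgs$qy - ctr0[["cy"]]
  hcgs$qz <- hcgs$qz - ctr0[["cz"]]
  units$cx <- units$cx - ctr0[["cx"]]; units$cy <- units$cy - ctr0[["cy"]]
  units$cz <- units$cz - ctr0[["cz"]]

  structure(list(units = units, atoms = atoms, hcgs = hcgs,
                 sulfurs = sulfurs, sulfation = sulfation,
                 n_saccharides = n_saccharides, repeat_rise = repeat_rise,
                 net_charge = sum(hcgs$charge)),
            class = "glycan_model")
}

#' @export
print.glycan_model <- function(x, ...) {
  cat("<glycan_model>", x$n_saccharides, "saccharides (",
      x$sulfation, "),", nrow(x$hcgs), "HCGs, net charge",
      x$net_charge, "e\n")
  invisible(x)
}

#' Enumerate the charged groups of a glycan
#'
#' Deterministic ordering by unit index, then group type (alphabetical:
#' N_sulfamido, O6X, OS2X, OS6X).
#'
#' @param glycan a `glycan_model`.
#' @return data frame of HCGs in canonical order (hcg_id, unit,
#'   group_type, charge, charge-center coordinates).
#' @export
enumerate_hcgs <- function(glycan) {
  stopifnot(inherits(glycan, "glycan_model"))
  h <- glycan$hcgs
  h <- h[order(h$unit, h$group_type), , drop = FALSE]
  rownames(h) <- NULL
  h
}
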