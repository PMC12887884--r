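# Shared fixtures (built in code) and brute-force oracles.

# two-ladder benchmark fibril: one Lys ladder, one Glu ladder, 10 layers
two_ladder_fibril <- function(n_layers = 10) {
  build_fibril(build_cross_section("KAAAE", layout = "ladder_line"),
               n_layers = n_layers)
}

# BD settings for the desk-scale steering benchmark (fixed once)
steering_params <- function(seed = 11) {
  bd_params(max_steps = 2e4, b_radius = 45, q_radius = 120, seed = seed)
}

random_pose_near <- function(center, radius = 20) {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  rigid_pose(random_orientation(), center + radius * u)
}

# O(N*M) double-loop oracle for salt-bridge contact detection
oracle_contacts <- function(pose, fibril, glycan, cutoff = 4.5) {
  fa <- fibril$atoms[fibril$atoms$contact_ref, ]
  ga <- glycan$atoms[!is.na(glycan$atoms$hcg_id), ]
  g <- pose_apply(pose, as.matrix(ga[, c("x", "y", "z")]))
  seen <- character()
  out <- list()
  for (i in seq_len(nrow(fa))) for (j in seq_len(nrow(ga))) {
    d <- sqrt((fa$x[i] - g[j, 1])^2 + (fa$y[i] - g[j, 2])^2 +
                (fa$z[i] - g[j, 3])^2)
    if (d <= cutoff) {
      key <- paste(fa$resno[i], fa$layer[i], ga$hcg_id[j])
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- data.frame(
          resno = fa$resno[i], layer = fa$layer[i], hcg_id = ga$hcg_id[j])
      }
    }
  }
  if (!length(out)) return(data.frame(resno = integer(), layer = integer(),
                                      hcg_id = integer()))
  df <- do.call(rbind, out)
  df <- df[order(df$resno, df$layer, df$hcg_id), ]
  rownames(df) <- NULL
  df
}

# double-loop oracle for per-sulfur nearest-site-atom features
oracle_features <- function(pose, fibril, glycan, site_residues) {
  fa <- fibril$atoms[fibril$atoms$resno %in% site_residues, ]
  s <- pose_apply(pose, as.matrix(glycan$sulfurs[, c("x", "y", "z")]))
  vapply(seq_len(nrow(s)), function(j) {
    best <- Inf
    for (i in seq_len(nrow(fa))) {
      d <- sqrt((fa$x[i] - s[j, 1])^2 + (fa$y[i] - s[j, 2])^2 +
                  (fa$z[i] - s[j, 3])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# double-loop oracle for the reaction criterion
oracle_reaction <- function(pose, refs, params) {
  g <- pose_apply(pose, refs$glycan_local)
  count <- integer(0); resn <- integer(0); total <- 0L
  for (i in seq_len(nrow(refs$fibril_pos))) for (j in seq_len(nrow(g))) {
    d <- sqrt(sum((refs$fibril_pos[i, ] - g[j, ])^2))
    if (d <= params$reaction_distance) {
      total <- total + 1L
      r <- refs$fibril_res[i]
      k <- match(r, resn)
      if (is.na(k)) { resn <- c(resn, r); count <- c(count, 1L) }
      else count[k] <- count[k] + 1L
    }
  }
  if (total < params$reaction_min_contacts) return(NA_integer_)
  min(resn[count == max(count)])
}

# exhaustive-scan oracle for cluster medoids
oracle_medoid <- function(features, members) {
  best <- members[1]; bestsum <- Inf
  for (i in members) {
    s <- 0
    for (j in members) s <- s + distance_rmsd(features[i, ], features[j, ])
    if (s < bestsum) { bestsum <- s; best <- i }
  }
  best
}

# minimal hand-built structures giving exact control over geometry:
# a fibril of bare cationic nitrogens and a glycan of bare HCG oxygens
fake_fibril <- function(nz) {
  # nz: data.frame resno, layer, x, y, z
  atoms <- data.frame(atom_name = "NZ", resno = nz$resno,
                      resname = "LYS", x = nz$x, y = nz$y, z = nz$z,
                      charge = 1, role = "charged_sidechain",
                      bd_ref = TRUE, contact_ref = TRUE, exposed = TRUE,
                      layer = nz$layer, protofilament = 1L)
  structure(list(atoms = atoms, n_layers = length(unique(nz$layer)),
                 site_list = sort(unique(nz$resno)),
                 center = colMeans(atoms[, c("x", "y", "z")])),
            class = "fibril_model")
}

fake_glycan <- function(ox) {
  # ox: data.frame hcg_id, unit, group_type, x, y, z
  atoms <- data.frame(atom_name = paste0("O", seq_len(nrow(ox))),
                      unit = ox$unit, element = "O",
                      x = ox$x, y = ox$y, z = ox$z,
                      hcg_id = ox$hcg_id, group_type = ox$group_type)
  hcgs <- unique(ox[, c("hcg_id", "unit", "group_type")])
  hcgs$charge <- -1
  hcgs$qx <- tapply(ox$x, ox$hcg_id, mean)[as.character(hcgs$hcg_id)]
  hcgs$qy <- tapply(ox$y, ox$hcg_id, mean)[as.character(hcgs$hcg_id)]
  hcgs$qz <- tapply(ox$z, ox$hcg_id, mean)[as.character(hcgs$hcg_id)]
  structure(list(atoms = atoms, hcgs = hcgs,
                 sulfurs = data.frame(atom_name = character(),
                                      unit = integer(), x = numeric(),
                                      y = numeric(), z = numeric()),
                 net_charge = -nrow(hcgs)),
            class = "glycan_model")
}
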