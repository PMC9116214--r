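#' Generate a toy protein pocket with a bound ligand
#'
#' Builds a fully synthetic, self-contained protein--ligand complex: a
#' connected small-molecule ligand (random tree bond graph, bond lengths
#' ~1.5 Å, elements drawn with organic-chemistry-like frequencies) centered
#' at the origin, surrounded by a shell of amino-acid residues (backbone
#' N/CA/C/O plus a side-chain carbon) placed so that no protein atom comes
#' closer than 1.5 Å to the ligand and the nearest residues sit at
#' contact distances. The generator is deterministic given the seed.
#'
#' These complexes carry the geometric statistics the contact featurizer
#' needs (occupied inner shells, residue-class diversity) but no real
#' physics: no secondary structure, protonation or force-field realism.
#'
#' @param seed Integer seed.
#' @param n_residues Number of pocket residues (5--50).
#' @param n_ligand_atoms Number of ligand heavy atoms (5--40).
#' @return List with `receptor` (atom tibble as from [read_receptor()]) and
#'   `ligand` (an `sfct_poses` with the single pose `"native"`).
#' @export
generate_toy_complex <- function(seed, n_residues = 20L, n_ligand_atoms = 20L) {
  if (n_residues < 5 || n_residues > 50) {
    sfct_abort("n_residues must be in 5..50", "sfct_error_domain")
  }
  if (n_ligand_atoms < 5 || n_ligand_atoms > 40) {
    sfct_abort("n_ligand_atoms must be in 5..40", "sfct_error_domain")
  }
  withr::with_seed(seed, {
    lig <- build_random_ligand(n_ligand_atoms)
    receptor <- build_pocket(lig$coords, n_residues)
    atoms <- tibble(
      pose_id = "native", atom = seq_len(n_ligand_atoms),
      name = paste0(lig$elements, seq_len(n_ligand_atoms)),
      element = lig$elements,
      x = lig$coords[, 1], y = lig$coords[, 2], z = lig$coords[, 3]
    )
    list(
      receptor = receptor,
      ligand = pose_set(atoms, lig$bonds,
        tibble(pose_id = "native", source_score = NA_real_))
    )
  })
}

LIGAND_ELEMENT_POOL <- c("C", "N", "O", "S", "Cl", "F", "P")
LIGAND_ELEMENT_FREQ <- c(0.60, 0.12, 0.12, 0.04, 0.05, 0.04, 0.03)

build_random_ligand <- function(n_atoms, max_tries = 60L) {
  elements <- sample(LIGAND_ELEMENT_POOL, n_atoms, replace = TRUE,
    prob = LIGAND_ELEMENT_FREQ)
  elements[1] <- "C" # root is carbon so double bonds stay plausible
  order <- ifelse(runif(n_atoms - 1) < 0.12, 2L, 1L)
  parent <- rep(NA_integer_, n_atoms)
  coords <- matrix(0, n_atoms, 3)
  for (i in 2:n_atoms) {
    placed <- FALSE
    # prefer a random parent, but fall back to any earlier atom if crowded
    candidates <- sample.int(i - 1L)
    for (p in candidates) {
      for (try in seq_len(max_tries)) {
        dir <- random_unit_vector()
        cand <- coords[p, ] + 1.5 * dir
        d <- sqrt(rowSums((coords[seq_len(i - 1), , drop = FALSE] -
          matrix(cand, i - 1, 3, byrow = TRUE))^2))
        d[p] <- Inf
        if (all(d > 1.2)) {
          coords[i, ] <- cand
          parent[i] <- p
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      sfct_abort("could not place ligand atom without clashes",
        "sfct_error_generation")
    }
  }
  coords <- sweep(coords, 2, colMeans(coords))
  list(
    elements = elements,
    coords = coords,
    bonds = tibble(from = parent[-1], to = 2:n_atoms, order = order)
  )
}

# Simplified residue geometry: backbone + one side-chain carbon.
residue_template <- function() {
  matrix(c(
    0.0, 0.0, 0.0, # N
    1.46, 0.0, 0.0, # CA
    2.0, 1.3, 0.0, # C
    3.22, 1.45, 0.0, # O
    1.95, -0.77, 1.2 # CB
  ), ncol = 3, byrow = TRUE)
}

build_pocket <- function(ligand_coords, n_residues, max_tries = 200L) {
  template <- residue_template()
  atom_names <- c("N", "CA", "C", "O", "CB")
  atom_elements <- c("N", "C", "C", "O", "C")
  lig_radius <- max(sqrt(rowSums(ligand_coords^2)))
  rows <- vector("list", n_residues)
  for (r in seq_len(n_residues)) {
    resid <- sample(RESIDUE_CLASSES[1:20], 1)
    # the first residues hug the ligand so that inner shells are occupied
    offset_range <- if (r <= 3) c(2.5, 4.0) else c(2.5, 7.5)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- random_unit_vector()
      center <- u * (lig_radius + runif(1, offset_range[1], offset_range[2]))
      rot <- random_rotation_matrix()
      atoms <- template %*% t(rot)
      atoms <- sweep(atoms, 2, colMeans(atoms))
      atoms <- sweep(atoms, 2, center, "+")
      dmin <- min(cross_distances(atoms, ligand_coords))
      if (dmin >= 1.5) {
        rows[[r]] <- tibble(
          chain = "A", resno = r, resid = resid,
          atom = atom_names, element = atom_elements,
          x = atoms[, 1], y = atoms[, 2], z = atoms[, 3]
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      sfct_abort("could not place pocket residue without clashes",
        "sfct_error_generation")
    }
  }
  bind_rows(rows)
}

cross_distances <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation_matrix <- function(max_angle = pi) {
  rotation_about_axis(random_unit_vector(), runif(1, 0, max_angle))
}

# Rodrigues rotation matrix.
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate decoy poses with a controlled RMSD spectrum
#'
#' Produces `n_decoys` perturbed copies of a native ligand pose. Target
#' RMSDs are stratified uniformly over `rmsd_range` (so the spectrum covers
#' both near-native and far-off poses, mirroring a docking decoy corpus of
#' ~90 poses per complex); each decoy is built from an optional torsion
#' perturbation about acyclic single bonds, a rigid rotation about the
#' centroid whose magnitude is bisected against the target, and a final
#' translation sized so the naive RMSD equals the target. Labels are then
#' recomputed from coordinates with [rmsd_to_reference()] (symmetry
#' corrected), guaranteeing label/coordinate self-consistency.
#'
#' With `rotation = FALSE` and `torsion_sd = 0` each decoy is a pure
#' translation and its label equals the target distance exactly.
#'
#' @param native An `sfct_poses` holding the native pose (first pose used).
#' @param n_decoys Number of decoys (default 90).
#' @param rmsd_range Target RMSD range in Å (default 0.2--12).
#' @param torsion_sd Torsion perturbation scale in degrees (0 disables).
#' @param rotation Apply the rigid-rotation component.
#' @param seed Integer seed.
#' @return List with `poses` (an `sfct_poses`, ids `"decoy_001"`, ...) and
#'   `labels` (tibble `pose_id`, `rmsd`, `naive_rmsd`).
#' @export
generate_decoys <- function(native, n_decoys = 90L, rmsd_range = c(0.2, 12),
                            torsion_sd = 10, rotation = TRUE, seed = 1L) {
  if (rmsd_range[1] >= rmsd_range[2] || rmsd_range[1] < 0) {
    sfct_abort("rmsd_range must satisfy 0 <= lo < hi", "sfct_error_domain")
  }
  if (n_decoys < 1) sfct_abort("n_decoys must be >= 1", "sfct_error_domain")
  ref_id <- pose_ids(native)[[1]]
  ref <- pose_coords(native, ref_id)
  elements <- pose_atoms(native, ref_id)$element
  bonds <- native$bonds
  withr::with_seed(seed, {
    # stratified targets: one per equal-width slice, shuffled
    u <- runif(n_decoys)
    targets <- rmsd_range[1] +
      (rmsd_range[2] - rmsd_range[1]) * (seq_len(n_decoys) - 1 + u) / n_decoys
    targets <- sample(targets)
    decoys <- lapply(targets, function(t) {
      perturb_to_target(ref, bonds, t, torsion_sd = torsion_sd,
        rotation = rotation)
    })
  })
  ids <- sprintf("decoy_%03d", seq_len(n_decoys))
  atoms <- bind_rows(lapply(seq_len(n_decoys), function(i) {
    tibble(
      pose_id = ids[[i]], atom = seq_along(elements),
      name = paste0(elements, seq_along(elements)), element = elements,
      x = decoys[[i]][, 1], y = decoys[[i]][, 2], z = decoys[[i]][, 3]
    )
  }))
  poses <- pose_set(atoms, bonds, tibble(pose_id = ids, source_score = NA_real_))
  labels <- rmsd_to_reference(poses, ref)
  list(poses = poses, labels = labels)
}

# Deform toward a target naive RMSD: torsion + rotation supply at most ~70%
# of the target (bisected), translation orthogonal to the mean displacement
# supplies the remainder, so rmsd_total^2 = rmsd_deform^2 + |v|^2.
perturb_to_target <- function(ref, bonds, target, torsion_sd = 10,
                              rotation = TRUE) {
  n <- nrow(ref)
  centroid <- colMeans(ref)
  tors <- if (torsion_sd > 0) sample_torsions(ref, bonds) else NULL
  tor_scale <- if (!is.null(tors)) min(target / 4, 1) else 0
  axis <- random_unit_vector()
  max_angle <- if (rotation) pi / 3 else 0
  deform <- function(s) {
    out <- ref
    if (!is.null(tors) && tor_scale > 0) {
      out <- apply_torsions(out, tors, s * tor_scale * torsion_sd * pi / 180)
    }
    if (rotation) {
      rot <- rotation_about_axis(axis, s * max_angle)
      out <- sweep(sweep(out, 2, centroid) %*% t(rot), 2, centroid, "+")
    }
    out
  }
  cap <- 0.7 * target
  s <- 1
  pose <- deform(1)
  r <- heavy_atom_rmsd(pose, ref)
  if (r > cap) {
    lo <- 0; hi <- 1
    for (it in 1:25) {
      s <- (lo + hi) / 2
      pose <- deform(s)
      r <- heavy_atom_rmsd(pose, ref)
      if (r > cap) hi <- s else lo <- s
    }
  }
  need <- sqrt(max(target^2 - r^2, 0))
  if (need > 0) {
    disp <- colMeans(pose - ref)
    v <- random_unit_vector()
    if (sqrt(sum(disp^2)) > 1e-9) {
      d_hat <- disp / sqrt(sum(disp^2))
      v <- v - sum(v * d_hat) * d_hat
      if (sqrt(sum(v^2)) < 1e-6) v <- random_unit_vector()
      v <- v / sqrt(sum(v^2))
    }
    pose <- sweep(pose, 2, need * v, "+")
  }
  pose
}

# Rotatable bonds: acyclic (bridge) single bonds with >= 2 atoms on each side.
sample_torsions <- function(ref, bonds, max_bonds = 5L) {
  if (is.null(bonds) || nrow(bonds) == 0) return(NULL)
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("from", "to")]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(ref) - igraph::vcount(g)))
  br <- igraph::bridges(g)
  if (length(br) == 0) return(NULL)
  ends <- igraph::ends(g, br)
  rotatable <- list()
  for (i in seq_len(nrow(ends))) {
    e <- ends[i, ]
    bi <- which((bonds$from == e[1] & bonds$to == e[2]) |
      (bonds$from == e[2] & bonds$to == e[1]))
    if (length(bi) == 0 || bonds$order[bi[[1]]] != 1) next
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, e))
    comp <- igraph::components(g2)$membership
    moving <- which(comp == comp[e[2]])
    if (length(moving) >= 2 && length(moving) <= nrow(ref) - 2) {
      rotatable[[length(rotatable) + 1L]] <-
        list(a = e[1], b = e[2], moving = moving)
    }
  }
  if (length(rotatable) == 0) return(NULL)
  picked <- rotatable[sample.int(length(rotatable),
    min(length(rotatable), max_bonds))]
  for (i in seq_along(picked)) picked[[i]]$angle_sign <- sample(c(-1, 1), 1)
  picked
}

apply_torsions <- function(coords, tors, angle_scale) {
  for (t in tors) {
    axis <- coords[t$b, ] - coords[t$a, ]
    if (sqrt(sum(axis^2)) < 1e-9) next
    rot <- rotation_about_axis(axis, t$angle_sign * angle_scale)
    moved <- sweep(coords[t$moving, , drop = FALSE], 2, coords[t$a, ])
    coords[t$moving, ] <- sweep(moved %*% t(rot), 2, coords[t$a, ], "+")
  }
  coords
}

#' Pseudo docking score coupled to pose RMSD
#'
#' Stand-in for an engine score: an affine function of the true pose RMSD
#' plus Gaussian noise, `P = base_affinity + rmsd_coupling * rmsd +
#' N(0, noise_sd)`. With `rmsd_coupling = 0` the score carries no pose
#' information -- the hard case in which only the correction term can
#' recover the near-native pose.
#'
#' @param true_rmsd Numeric vector of pose RMSDs (Å, `>= 0`).
#' @param base_affinity Baseline score, kcal/mol (default -8).
#' @param rmsd_coupling Slope, kcal/mol per Å (default 0.3).
#' @param noise_sd Gaussian noise SD, kcal/mol (default 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of pseudo scores (lower = better).
#' @export
pseudo_docking_score <- function(true_rmsd, base_affinity = -8,
                                 rmsd_coupling = 0.3, noise_sd = 1,
                                 seed = NULL) {
  if (any(true_rmsd < 0)) {
    sfct_abort("true_rmsd must be non-negative", "sfct_error_domain")
  }
  if (noise_sd < 0) sfct_abort("noise_sd must be >= 0", "sfct_error_domain")
  draw <- function() {
    base_affinity + rmsd_coupling * true_rmsd +
      if (noise_sd > 0) rnorm(length(true_rmsd), 0, noise_sd) else 0
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Build the packaged synthetic training corpus
#'
#' Generates `n_natives` toy complexes, each with its crystal pose (label
#' 0 Å) and `n_decoys_per_native` perturbed decoys spanning `rmsd_range`,
#' featurizes every pose, and returns one tidy table ready for
#' [filter_training_poses()] and [train_sfct()]. Complex identity is kept in
#' `complex_id` for group-aware train/test splitting (splitting by pose
#' would leak near-duplicate decoys of the same complex across the split).
#'
#' @param n_natives Number of native complexes (default 200).
#' @param n_decoys_per_native Decoys per native (default 20).
#' @param seed Integer seed (drives every complex deterministically).
#' @param scheme The [shell_scheme()] to featurize under.
#' @param n_residues,n_ligand_atoms Length-2 ranges to sample sizes from.
#' @param rmsd_range Decoy RMSD target range, Å.
#' @param torsion_sd Decoy torsion scale, degrees.
#' @return Tibble `complex_id`, `pose_id`, `label` plus the feature columns,
#'   with a `schema_id` attribute.
#' @export
simulate_training_corpus <- function(n_natives = 200L, n_decoys_per_native = 20L,
                                     seed = 1L, scheme = shell_scheme(),
                                     n_residues = c(8L, 20L),
                                     n_ligand_atoms = c(8L, 25L),
                                     rmsd_range = c(0.2, 12),
                                     torsion_sd = 10) {
  sizes <- withr::with_seed(seed, tibble(
    n_res = sample(n_residues[1]:n_residues[2], n_natives, replace = TRUE),
    n_lig = sample(n_ligand_atoms[1]:n_ligand_atoms[2], n_natives, replace = TRUE)
  ))
  blocks <- lapply(seq_len(n_natives), function(i) {
    # modulo keeps derived seeds inside the 32-bit range for any user seed
    cseed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    cpx <- generate_toy_complex(cseed, sizes$n_res[[i]], sizes$n_lig[[i]])
    dec <- generate_decoys(cpx$ligand, n_decoys = n_decoys_per_native,
      rmsd_range = rmsd_range, torsion_sd = torsion_sd, seed = cseed + 1L)
    feats_native <- featurize_poses(cpx$receptor, cpx$ligand, scheme)
    feats_decoy <- featurize_poses(cpx$receptor, dec$poses, scheme)
    labels <- bind_rows(
      tibble(pose_id = "native", label = 0),
      tibble(pose_id = dec$labels$pose_id, label = dec$labels$rmsd)
    )
    out <- bind_rows(feats_native, feats_decoy)
    bind_cols(
      tibble(complex_id = sprintf("cpx%04d", i), pose_id = out$pose_id),
      tibble(label = labels$label[match(out$pose_id, labels$pose_id)]),
      out[, setdiff(names(out), "pose_id")]
    )
  })
  out <- bind_rows(blocks)
  attr(out, "schema_id") <- schema_id(scheme)
  out
}

#' Simulate an active/decoy screening library
#'
#' Emulates the tabular structure of a docking-based screening benchmark:
#' each ligand (active or decoy) receives a set of pose records with a true
#' RMSD-like quality and a pseudo docking score. Actives draw low-RMSD,
#' favorable-score poses; decoy ligands high-RMSD, unfavorable ones. With
#' `noise_sd = 0` and disjoint affinities the ranking separates perfectly
#' (EF at the theoretical maximum); with heavy noise EF approaches 1.
#'
#' @param n_actives,n_decoy_ligands Library composition.
#' @param n_poses Poses per ligand (default 20).
#' @param seed Integer seed.
#' @param active_affinity,decoy_affinity Baseline scores, kcal/mol.
#' @param rmsd_coupling Score/RMSD slope, kcal/mol per Å.
#' @param noise_sd Score noise SD, kcal/mol.
#' @return Tibble `ligand_id`, `active`, `pose_id`, `rmsd`, `score` (pose
#'   level; collapse with [screening_scores()]).
#' @export
simulate_screening_library <- function(n_actives = 30L, n_decoy_ligands = 300L,
                                       n_poses = 20L, seed = 1L,
                                       active_affinity = -9, decoy_affinity = -7,
                                       rmsd_coupling = 0.25, noise_sd = 1) {
  if (n_actives < 1 || n_decoy_ligands < 1) {
    sfct_abort("need at least one active and one decoy ligand",
      "sfct_error_domain")
  }
  withr::with_seed(seed, {
    n_lig <- n_actives + n_decoy_ligands
    active <- c(rep(TRUE, n_actives), rep(FALSE, n_decoy_ligands))
    blocks <- lapply(seq_len(n_lig), function(i) {
      rmsd <- if (active[[i]]) {
        c(runif(1, 0.3, 2), runif(n_poses - 1, 1, 8))
      } else {
        runif(n_poses, 3, 12)
      }
      base <- if (active[[i]]) active_affinity else decoy_affinity
      score <- pseudo_docking_score(rmsd, base_affinity = base,
        rmsd_coupling = rmsd_coupling, noise_sd = noise_sd)
      tibble(
        ligand_id = sprintf("lig%04d", i), active = active[[i]],
        pose_id = as.character(seq_len(n_poses)), rmsd = rmsd, score = score
      )
    })
    bind_rows(blocks)
  })
}

#' Compare engine-only and hybrid pose rankings per complex
#'
#' For each complex, ranks the poses by the docking score alone and by the
#' hybrid score, and reports the true RMSD of the top-ranked pose under
#' each. The per-complex table feeds [success_rate()] / [average_topk_rmsd()]
#' directly.
#'
#' @param data Tibble with columns `complex_id`, `pose_id`, `label` (true
#'   RMSD, Å), `P` (docking score) and `S` (predicted RMSD).
#' @param alpha,beta Hybrid weights.
#' @return Tibble `complex_id`, `top1_rmsd_engine`, `top1_rmsd_hybrid`.
#' @export
compare_rankings <- function(data, alpha = 0.5, beta = 0.5) {
  needed <- c("complex_id", "pose_id", "label", "P", "S")
  if (!all(needed %in% names(data))) {
    sfct_abort("compare_rankings needs columns complex_id, pose_id, label, P, S",
      "sfct_error_domain")
  }
  data |>
    group_by(.data$complex_id) |>
    summarise(
      top1_rmsd_engine = top1_label(.data$pose_id, .data$label, .data$P,
        .data$S, 1, 0),
      top1_rmsd_hybrid = top1_label(.data$pose_id, .data$label, .data$P,
        .data$S, alpha, beta),
      .groups = "drop"
    )
}

top1_label <- function(pose_id, label, P, S, alpha, beta) {
  top <- rank_poses(tibble(pose_id = pose_id, P = P, S = S),
    alpha = alpha, beta = beta)$pose_id[[1]]
  label[pose_id == top][[1]]
}
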