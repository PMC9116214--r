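# Text fixtures are written by code at test time; nothing binary is stored.

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.300   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       3.200   1.450   0.000  1.00  0.00           O",
    "ATOM      5  N   ASP B   2       5.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  ASP B   2       6.450   0.000   0.000  1.00  0.00           C",
    "ATOM      7  N   LYS B   3       9.000   0.000   0.000  1.00  0.00           N",
    "ATOM      8  CA  LYS B   3      10.450   0.000   0.000  1.00  0.00           C",
    "HETATM    9  O   HOH A 101       4.000   4.000   4.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

write_water_only_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

# Two-model Vina-style PDBQT with the energies typed into the REMARK lines.
write_vina_pdbqt <- function(path = tempfile(fileext = ".pdbqt")) {
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:      -8.6      0.000      0.000",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  0.00  0.00    +0.000 C ",
    "ATOM      2  O1  LIG A   1       1.400   0.000   0.000  0.00  0.00    -0.350 OA",
    "ATOM      3  H1  LIG A   1       2.000   0.700   0.000  0.00  0.00    +0.200 HD",
    "ENDMDL",
    "MODEL 2",
    "REMARK VINA RESULT:      -7.1      1.800      2.400",
    "ATOM      1  C1  LIG A   1       0.500   0.000   0.000  0.00  0.00    +0.000 C ",
    "ATOM      2  O1  LIG A   1       1.900   0.000   0.000  0.00  0.00    -0.350 OA",
    "ATOM      3  H1  LIG A   1       2.500   0.700   0.000  0.00  0.00    +0.200 HD",
    "ENDMDL"
  ), path)
  path
}

write_polar_h_receptor_pdbqt <- function(path = tempfile(fileext = ".pdbqt")) {
  writeLines(c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  0.00  0.00    -0.350 N ",
    "ATOM      2  HN  SER A   1       0.500   0.800   0.000  0.00  0.00    +0.160 HD",
    "ATOM      3  CA  SER A   1       1.450   0.000   0.000  0.00  0.00    +0.200 C ",
    "ATOM      4  OG  SER A   1       2.100   1.200   0.500  0.00  0.00    -0.390 OA",
    "END"
  ), path)
  path
}

write_single_mol2 <- function(path = tempfile(fileext = ".mol2")) {
  writeLines(c(
    "@<TRIPOS>MOLECULE",
    "lig",
    " 4 3 0 0 0",
    "SMALL",
    "NO_CHARGES",
    "",
    "@<TRIPOS>ATOM",
    "  1 C1    0.000  0.000  0.000 C.3  1 LIG 0.000",
    "  2 N1    1.500  0.000  0.000 N.3  1 LIG 0.000",
    "  3 C2    3.000  0.000  0.000 C.2  1 LIG 0.000",
    "  4 O1    3.700  1.200  0.000 O.2  1 LIG 0.000",
    "@<TRIPOS>BOND",
    " 1 1 2 1",
    " 2 2 3 1",
    " 3 3 4 2"
  ), path)
  path
}

# Multi-conformer SDF of one 3-atom ligand: conformer i translated by (i-1) A.
write_multi_sdf <- function(n_conf = 9, path = tempfile(fileext = ".sdf")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_conf)) {
    dx <- i - 1
    writeLines(c(
      as.character(i), "  test", "",
      "  3  2  0  0  0  0  0  0  0  0999 V2000",
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        c(0 + dx, 1.5 + dx, 3.0 + dx), c(0, 0, 0), c(0, 0, 0),
        c("C", "N", "O")),
      "  1  2  1  0",
      "  2  3  1  0",
      "M  END", "$$$$"
    ), con)
  }
  path
}

# Independent brute-force featurizer: explicit double loop over atom pairs.
brute_force_featurize <- function(receptor, ligand_atoms, scheme = shell_scheme()) {
  schema <- feature_schema(scheme)
  counts <- setNames(integer(nrow(schema)), schema$bin)
  for (i in seq_len(nrow(receptor))) {
    rc <- classify_residue(receptor$resid[[i]])
    for (j in seq_len(nrow(ligand_atoms))) {
      ec <- classify_element(ligand_atoms$element[[j]])
      d <- sqrt((receptor$x[[i]] - ligand_atoms$x[[j]])^2 +
        (receptor$y[[i]] - ligand_atoms$y[[j]])^2 +
        (receptor$z[[i]] - ligand_atoms$z[[j]])^2)
      k <- shell_index(d, scheme)
      if (!is.na(k)) {
        bin <- sprintf("%s_%s_s%02d", rc, ec, k)
        counts[[bin]] <- counts[[bin]] + 1L
      }
    }
  }
  counts
}

# Exhaustive symmetry-RMSD oracle: minimum over every permutation that
# preserves the element multiset and the adjacency (+ bond order) matrix.
exhaustive_symmetry_rmsd <- function(a, b, elements, bonds) {
  n <- length(elements)
  adj <- matrix(0L, n, n)
  if (nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      adj[bonds$from[[i]], bonds$to[[i]]] <- bonds$order[[i]]
      adj[bonds$to[[i]], bonds$from[[i]]] <- bonds$order[[i]]
    }
  }
  perms <- all_permutations(n)
  best <- Inf
  for (p in perms) {
    if (!all(elements[p] == elements)) next
    if (!all(adj[p, p] == adj)) next
    r <- heavy_atom_rmsd(a[p, , drop = FALSE], b)
    if (r < best) best <- r
  }
  best
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# Small random complex for featurizer property tests.
random_toy_complex <- function(seed) {
  n_res <- 5 + (seed %% 10)
  n_lig <- 5 + (seed %% 12)
  generate_toy_complex(seed, n_res, n_lig)
}

translate_pose_set <- function(poses, v) {
  atoms <- poses$atoms
  atoms$x <- atoms$x + v[[1]]
  atoms$y <- atoms$y + v[[2]]
  atoms$z <- atoms$z + v[[3]]
  pose_set(atoms, poses$bonds, poses$poses)
}
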