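#' Read a receptor structure into an atom table
#'
#' Parses a protein receptor from PDB (via \pkg{bio3d}) or PDBQT (AutoDock
#' dialect) and applies the standard docking preparation filters: water
#' molecules, monatomic ions and hetero small molecules are removed, and all
#' hydrogens are dropped so that only heavy atoms remain. Non-standard
#' residues that are part of the polymer (default: selenomethionine `MSE`)
#' are retained and classify as `OTH` downstream.
#'
#' @param path Path to a `.pdb` or `.pdbqt` file.
#' @param format One of `"auto"` (default, by extension), `"pdb"`, `"pdbqt"`.
#' @param exclude Character vector of HETATM residue names to always remove.
#'   Defaults to waters and common monatomic ions.
#' @param keep_hetero HETATM residue names to retain as part of the polymer.
#' @return A tibble with one row per heavy atom: `chain`, `resno`, `resid`,
#'   `atom` (atom name), `element`, `x`, `y`, `z`. Residues are identified by
#'   `(chain, resno)`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
#'   "END"
#' ), pdb)
#' read_receptor(pdb)
#' @export
read_receptor <- function(path, format = c("auto", "pdb", "pdbqt"),
                          exclude = default_hetero_exclusions(),
                          keep_hetero = "MSE") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    sfct_abort(paste0("receptor file not found: ", path), "sfct_error_parse")
  }
  if (format == "auto") {
    format <- if (grepl("\\.pdbqt$", path, ignore.case = TRUE)) "pdbqt" else "pdb"
  }
  atoms <- if (format == "pdb") read_pdb_atoms(path) else read_pdbqt_atoms(path)
  atoms <- atoms |>
    filter(toupper(.data$element) != "H", toupper(.data$element) != "D") |>
    filter(!(toupper(.data$resid) %in% toupper(exclude))) |>
    filter(.data$record == "ATOM" | toupper(.data$resid) %in% toupper(keep_hetero)) |>
    select(-"record")
  if (nrow(atoms) == 0) {
    sfct_abort("no protein heavy atoms remain after preparation filters",
      "sfct_error_empty")
  }
  atoms
}

#' @rdname read_receptor
#' @export
default_hetero_exclusions <- function() {
  c(
    "HOH", "WAT", "DOD", "H2O", # waters
    "NA", "K", "CL", "CA", "MG", "ZN", "MN", "FE", "CU", "CO", "NI", "CD",
    "HG", "LI", "RB", "CS", "SR", "BA", "BR", "IOD", "F" # monatomic ions
  )
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) {
      sfct_abort(paste0("failed to parse PDB file '", path, "': ",
        conditionMessage(e)), "sfct_error_parse")
    }
  )
  a <- pdb$atom
  ele <- a$elesy
  missing_ele <- is.na(ele) | trimws(ele) == ""
  ele[missing_ele] <- guess_element_from_name(a$elety[missing_ele])
  tibble(
    record = a$type,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    resno = as.integer(a$resno),
    resid = toupper(trimws(a$resid)),
    atom = trimws(a$elety),
    element = toupper(trimws(ele)),
    x = a$x, y = a$y, z = a$z
  )
}

read_pdbqt_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM|HETATM)", lines)
  if (!any(sel)) {
    sfct_abort(paste0("no ATOM/HETATM records in PDBQT file '", path, "'"),
      "sfct_error_parse")
  }
  parse_pdbqt_atom_lines(lines[sel], which(sel))
}

# Fixed-width PDB columns; the trailing token is the AutoDock atom type.
parse_pdbqt_atom_lines <- function(lines, line_numbers) {
  coords <- lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
    if (anyNA(c(x, y, z))) {
      sfct_abort(paste0("unparseable coordinates at line ", line_numbers[[i]]),
        "sfct_error_parse")
    }
    c(x, y, z)
  })
  xyz <- do.call(rbind, coords)
  toks <- strsplit(trimws(lines), "\\s+")
  ad_type <- vapply(toks, function(t) t[[length(t)]], character(1))
  tibble(
    record = ifelse(grepl("^ATOM", lines), "ATOM", "HETATM"),
    chain = substr(lines, 22, 22),
    resno = as.integer(suppressWarnings(as.numeric(substr(lines, 23, 26)))),
    resid = toupper(trimws(substr(lines, 18, 20))),
    atom = trimws(substr(lines, 13, 16)),
    element = autodock_type_to_element(ad_type),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# AutoDock atom types: A = aromatic carbon; NA/NS, OA/OS, SA are acceptor
# variants; HD/HS are polar hydrogens.
autodock_type_to_element <- function(type) {
  up <- toupper(type)
  out <- up
  out[up %in% c("A", "C")] <- "C"
  out[up %in% c("N", "NA", "NS")] <- "N"
  out[up %in% c("O", "OA", "OS")] <- "O"
  out[up %in% c("S", "SA")] <- "S"
  out[up %in% c("H", "HD", "HS")] <- "H"
  out
}

guess_element_from_name <- function(name) {
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA", "MN", "CU"),
    two, one)
}

# ---- pose sets -------------------------------------------------------------

#' Construct a pose set
#'
#' A pose set holds every docked conformer of one ligand topology: an atom
#' table (one row per atom per pose, identical atom ordering across poses), a
#' bond table shared by all poses, and per-pose metadata including any
#' docking score embedded in the source file.
#'
#' @param atoms Tibble with columns `pose_id`, `atom` (1-based index within
#'   the pose), `name`, `element`, `x`, `y`, `z`.
#' @param bonds Tibble with columns `from`, `to` (atom indices), `order`.
#' @param poses Optional tibble with columns `pose_id`, `source_score`.
#' @return An object of class `sfct_poses`.
#' @export
pose_set <- function(atoms, bonds = empty_bonds(), poses = NULL) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  ids <- unique(atoms$pose_id)
  counts <- atoms |> dplyr::count(.data$pose_id)
  if (length(unique(counts$n)) > 1) {
    sfct_abort("inconsistent atom counts across poses", "sfct_error_topology")
  }
  n_atoms <- counts$n[[1]]
  ref_elem <- atoms$element[atoms$pose_id == ids[[1]]]
  for (id in ids) {
    if (!identical(atoms$element[atoms$pose_id == id], ref_elem)) {
      sfct_abort("atom ordering/elements differ across poses",
        "sfct_error_topology")
    }
  }
  if (nrow(bonds) > 0 &&
    (max(bonds$from, bonds$to) > n_atoms || min(bonds$from, bonds$to) < 1)) {
    sfct_abort("bond indices out of range", "sfct_error_topology")
  }
  if (is.null(poses)) {
    poses <- tibble(pose_id = ids, source_score = NA_real_)
  }
  structure(
    list(atoms = atoms, bonds = bonds, poses = as_tibble(poses)),
    class = "sfct_poses"
  )
}

empty_bonds <- function() {
  tibble(from = integer(), to = integer(), order = integer())
}

#' @export
print.sfct_poses <- function(x, ...) {
  cat(sprintf(
    "<sfct_poses> %d pose(s), %d heavy atoms, %d bonds\n",
    n_poses(x), nrow(x$atoms) / max(1L, n_poses(x)), nrow(x$bonds)
  ))
  invisible(x)
}

#' Pose set accessors
#'
#' @param x An `sfct_poses` object.
#' @param pose_id A pose identifier present in `pose_ids(x)`.
#' @return `n_poses()` the number of poses; `pose_ids()` their identifiers in
#'   file order; `pose_coords()` an n-atom x 3 coordinate matrix;
#'   `pose_atoms()` the atom tibble for one pose.
#' @export
n_poses <- function(x) nrow(x$poses)

#' @rdname n_poses
#' @export
pose_ids <- function(x) x$poses$pose_id

#' @rdname n_poses
#' @export
pose_coords <- function(x, pose_id) {
  a <- pose_atoms(x, pose_id)
  as.matrix(a[, c("x", "y", "z")])
}

#' @rdname n_poses
#' @export
pose_atoms <- function(x, pose_id) {
  a <- x$atoms[x$atoms$pose_id == pose_id, ]
  if (nrow(a) == 0) {
    sfct_abort(paste0("no pose with id '", pose_id, "'"), "sfct_error_parse")
  }
  a
}

#' Read ligand poses from SDF, MOL2 or multi-model PDBQT
#'
#' Reads every conformer of a single ligand topology into a [pose_set()],
#' preserving file order. Hydrogens are removed (heavy-atom contract) and
#' bonds re-indexed accordingly. For Vina-style multi-model PDBQT files the
#' `REMARK VINA RESULT` energy is captured into `source_score`; PDBQT carries
#' no bond block, so symmetry-aware RMSD falls back to the identity mapping
#' for such poses.
#'
#' @param path Path to a `.sdf`, `.mol2` or `.pdbqt` file.
#' @param format One of `"auto"`, `"sdf"`, `"mol2"`, `"pdbqt"`.
#' @return An `sfct_poses` object; `pose_id` is `"1"`, `"2"`, ... in file
#'   order.
#' @export
read_ligand_poses <- function(path, format = c("auto", "sdf", "mol2", "pdbqt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    sfct_abort(paste0("ligand file not found: ", path), "sfct_error_parse")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      sdf = "sdf", sd = "sdf", mol2 = "mol2", pdbqt = "pdbqt",
      sfct_abort(paste0("cannot infer ligand format from extension '.", ext, "'"),
        "sfct_error_parse")
    )
  }
  recs <- switch(format,
    sdf = read_sdf_records(path),
    mol2 = read_mol2_records(path),
    pdbqt = read_pdbqt_models(path)
  )
  records_to_pose_set(recs)
}

# recs: list of list(atoms = tibble(name, element, x, y, z),
#                    bonds = tibble(from, to, order), score = numeric or NA)
records_to_pose_set <- function(recs) {
  if (length(recs) == 0) {
    sfct_abort("no ligand conformers found", "sfct_error_empty")
  }
  recs <- lapply(recs, drop_hydrogens_record)
  ref <- recs[[1]]
  if (nrow(ref$atoms) == 0) {
    sfct_abort("ligand has no heavy atoms", "sfct_error_empty")
  }
  for (r in recs) {
    if (nrow(r$atoms) != nrow(ref$atoms) ||
      !identical(r$atoms$element, ref$atoms$element)) {
      sfct_abort("conformers in file do not share one ligand topology",
        "sfct_error_topology")
    }
  }
  atoms <- bind_rows(lapply(seq_along(recs), function(i) {
    a <- recs[[i]]$atoms
    tibble(
      pose_id = as.character(i), atom = seq_len(nrow(a)),
      name = a$name, element = a$element, x = a$x, y = a$y, z = a$z
    )
  }))
  poses <- tibble(
    pose_id = as.character(seq_along(recs)),
    source_score = vapply(recs, function(r) r$score %||% NA_real_, numeric(1))
  )
  pose_set(atoms, ref$bonds, poses)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

drop_hydrogens_record <- function(rec) {
  heavy <- toupper(rec$atoms$element) != "H" & toupper(rec$atoms$element) != "D"
  if (all(heavy)) return(rec)
  new_index <- cumsum(heavy)
  bonds <- rec$bonds |>
    filter(heavy[.data$from], heavy[.data$to]) |>
    mutate(from = new_index[.data$from], to = new_index[.data$to])
  rec$atoms <- rec$atoms[heavy, ]
  rec$bonds <- bonds
  rec
}

read_sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # records are delimited by $$$$; a final record may omit it
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, head(ends, -1) + 1L)
  if (length(ends) == 0 || max(ends) < length(lines)) {
    starts <- c(starts, if (length(ends)) max(ends) + 1L else 1L)
    ends <- c(ends, length(lines) + 1L)
    starts <- unique(starts)
  }
  recs <- list()
  for (i in seq_along(starts)) {
    block <- lines[starts[[i]]:(ends[[i]] - 1L)]
    block <- block[cumsum(trimws(block) != "") > 0 | trimws(block) != ""]
    if (length(block) < 4) next
    recs[[length(recs) + 1L]] <- parse_sdf_block(lines[starts[[i]]:(ends[[i]] - 1L)],
      starts[[i]])
  }
  recs
}

parse_sdf_block <- function(block, offset) {
  if (length(block) < 4) {
    sfct_abort(paste0("truncated SDF record near line ", offset),
      "sfct_error_parse")
  }
  counts <- block[[4]]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || is.na(n_bonds)) {
    sfct_abort(paste0("bad V2000 counts line at line ", offset + 3),
      "sfct_error_parse")
  }
  atom_lines <- block[4 + seq_len(n_atoms)]
  bond_lines <- if (n_bonds > 0) block[4 + n_atoms + seq_len(n_bonds)] else character()
  atoms <- tibble(
    name = character(n_atoms), element = character(n_atoms),
    x = numeric(n_atoms), y = numeric(n_atoms), z = numeric(n_atoms)
  )
  for (j in seq_len(n_atoms)) {
    f <- strsplit(trimws(atom_lines[[j]]), "\\s+")[[1]]
    if (length(f) < 4) {
      sfct_abort(paste0("bad atom line at line ", offset + 3 + j),
        "sfct_error_parse")
    }
    atoms$x[[j]] <- as.numeric(f[[1]])
    atoms$y[[j]] <- as.numeric(f[[2]])
    atoms$z[[j]] <- as.numeric(f[[3]])
    atoms$element[[j]] <- f[[4]]
    atoms$name[[j]] <- paste0(f[[4]], j)
  }
  bonds <- empty_bonds()
  if (n_bonds > 0) {
    bm <- do.call(rbind, lapply(bond_lines, function(ln) {
      as.integer(c(substr(ln, 1, 3), substr(ln, 4, 6), substr(ln, 7, 9)))
    }))
    bonds <- tibble(from = bm[, 1], to = bm[, 2], order = bm[, 3])
  }
  list(atoms = atoms, bonds = bonds, score = NA_real_)
}

read_mol2_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) {
    sfct_abort(paste0("no @<TRIPOS>MOLECULE record in '", path, "'"),
      "sfct_error_parse")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    tf <- tempfile(fileext = ".mol2")
    on.exit(unlink(tf))
    writeLines(lines[starts[[i]]:ends[[i]]], tf)
    mol <- tryCatch(bio3d::read.mol2(tf),
      error = function(e) {
        sfct_abort(paste0("failed to parse MOL2 record ", i, " in '", path,
          "': ", conditionMessage(e)), "sfct_error_parse")
      }
    )
    a <- mol$atom
    element <- toupper(sub("\\..*$", "", a$elety))
    atoms <- tibble(
      name = a$elena, element = element,
      x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z)
    )
    bonds <- empty_bonds()
    if (!is.null(mol$bond) && nrow(mol$bond) > 0) {
      bonds <- tibble(
        from = as.integer(mol$bond$origin),
        to = as.integer(mol$bond$target),
        order = mol2_bond_order(mol$bond$type)
      )
    }
    list(atoms = atoms, bonds = bonds, score = NA_real_)
  })
}

mol2_bond_order <- function(type) {
  t <- tolower(trimws(as.character(type)))
  out <- suppressWarnings(as.integer(t))
  out[t == "ar"] <- 4L # aromatic
  out[t == "am"] <- 1L # amide
  out[is.na(out)] <- 1L
  out
}

read_pdbqt_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    starts <- 1L
    ends <- length(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts)) ends <- c(ends, length(lines))
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[[i]]:ends[[i]]]
    sel <- grepl("^(ATOM|HETATM)", block)
    if (!any(sel)) {
      sfct_abort(paste0("MODEL ", i, " has no atoms in '", path, "'"),
        "sfct_error_parse")
    }
    at <- parse_pdbqt_atom_lines(block[sel], starts[[i]] - 1L + which(sel))
    score <- NA_real_
    rem <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (length(rem) > 0) {
      toks <- strsplit(trimws(sub("^REMARK VINA RESULT:", "", rem[[1]])), "\\s+")[[1]]
      score <- suppressWarnings(as.numeric(toks[[1]]))
    }
    list(
      atoms = tibble(name = at$atom, element = at$element,
        x = at$x, y = at$y, z = at$z),
      bonds = empty_bonds(),
      score = score
    )
  })
}

# ---- writers ---------------------------------------------------------------

#' Write a receptor atom table to a PDB file
#'
#' @param receptor Receptor tibble as returned by [read_receptor()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(receptor[, c("x", "y", "z")]))),
    resno = receptor$resno,
    resid = receptor$resid,
    eleno = seq_len(nrow(receptor)),
    elety = receptor$atom,
    chain = receptor$chain,
    elesy = receptor$element
  )
  invisible(path)
}

#' Write a pose set to a multi-record SDF (V2000) file
#'
#' One molecule record per pose, in pose order, delimited by `$$$$`. Used by
#' the synthetic-data presets and the CLI so that generated fixtures are
#' readable by standard cheminformatics tools.
#'
#' @param poses An `sfct_poses` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_poses_sdf <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in pose_ids(poses)) {
    a <- pose_atoms(poses, id)
    b <- poses$bonds
    writeLines(c(
      id, "  sfct", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
    ), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, a$element), con)
    if (nrow(b) > 0) {
      writeLines(sprintf("%3d%3d%3d  0", b$from, b$to, b$order), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read a pose-score table
#'
#' Scores are exchanged as TSV with a header `pose_id<TAB>score`, the score
#' being the docking engine's energy in kcal/mol (lower is better).
#'
#' @param path Path to the TSV file.
#' @return Tibble with character `pose_id` and numeric `score`.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("pose_id", "score") %in% names(df))) {
    sfct_abort("scores table must have columns 'pose_id' and 'score'",
      "sfct_error_parse")
  }
  tibble(pose_id = as.character(df$pose_id), score = as.numeric(df$score))
}
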