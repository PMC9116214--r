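#' Heavy-atom RMSD between two poses (fixed receptor frame)
#'
#' Computes `sqrt(mean(|a_i - b_i|^2))` over matched heavy atoms with no
#' superposition: docking poses live in the common receptor frame, and
#' fitting before measuring would hide translation errors.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (or atom tibbles with
#'   `x`, `y`, `z` columns) with identical atom ordering.
#' @return RMSD in Å.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' heavy_atom_rmsd(a, a + rep(c(3, 0, 0), each = 5)) # 3 exactly
#' @export
heavy_atom_rmsd <- function(coords_a, coords_b) {
  a <- as_coord_matrix(coords_a)
  b <- as_coord_matrix(coords_b)
  if (nrow(a) != nrow(b)) {
    sfct_abort("poses have different atom counts", "sfct_error_topology")
  }
  sqrt(mean(rowSums((a - b)^2)))
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(x)
  }
  as.matrix(x[, c("x", "y", "z")])
}

#' Graph automorphisms of a ligand
#'
#' Enumerates the atom permutations that preserve both elements and the bond
#' graph (including bond orders), via colored VF2 isomorphism search on the
#' molecular graph. Used to make RMSD invariant to chemically equivalent atom
#' numberings (e.g. the two-fold flip of a phenyl ring), the role `obrms`
#' plays in Open Babel pipelines.
#'
#' @param elements Character vector of atom elements.
#' @param bonds Tibble with `from`, `to`, `order`.
#' @param cap Maximum number of automorphisms to enumerate; beyond it only
#'   the identity is returned (with attribute `capped = TRUE`).
#' @return List of integer permutations (each maps atom `i` of the reference
#'   numbering onto atom `perm[i]`), always including the identity.
#' @export
ligand_automorphisms <- function(elements, bonds, cap = 10000L) {
  n <- length(elements)
  identity_perm <- seq_len(n)
  if (is.null(bonds) || nrow(bonds) == 0) {
    # No bond graph (e.g. PDBQT input): only the identity is trustworthy.
    out <- list(identity_perm)
    attr(out, "capped") <- FALSE
    return(out)
  }
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("from", "to")]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  vcol <- as.integer(factor(toupper(elements)))
  ecol <- as.integer(bonds$order)
  n_auto <- igraph::count_isomorphisms(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol
  )
  if (n_auto > cap) {
    warn(sprintf(
      "ligand has %d graph automorphisms (cap %d); using identity mapping only",
      n_auto, cap))
    out <- list(identity_perm)
    attr(out, "capped") <- TRUE
    return(out)
  }
  maps <- igraph::isomorphisms(
    g, g, vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol
  )
  out <- lapply(maps, as.integer)
  attr(out, "capped") <- FALSE
  out
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' Minimum [heavy_atom_rmsd()] over all element- and bond-preserving graph
#' automorphisms of the ligand. The naive (identity-mapping) RMSD is always
#' an upper bound and is reported alongside.
#'
#' @param pose_a,pose_b Atom tibbles or coordinate matrices with identical
#'   atom ordering (same molecular graph).
#' @param elements Atom elements (taken from `pose_a$element` when omitted).
#' @param bonds Bond tibble (`from`, `to`, `order`).
#' @param cap Automorphism enumeration cap, see [ligand_automorphisms()].
#' @return One-row tibble: `naive_rmsd`, `symmetry_rmsd`, `capped`, and the
#'   minimizing `mapping` (list column holding an integer permutation).
#' @export
symmetry_corrected_rmsd <- function(pose_a, pose_b, elements = NULL,
                                    bonds = empty_bonds(), cap = 10000L) {
  if (is.null(elements)) {
    if (!is.matrix(pose_a) && "element" %in% names(pose_a)) {
      elements <- pose_a$element
    } else {
      sfct_abort("elements must be supplied when poses are bare matrices",
        "sfct_error_topology")
    }
  }
  a <- as_coord_matrix(pose_a)
  b <- as_coord_matrix(pose_b)
  if (nrow(a) != nrow(b) || nrow(a) != length(elements)) {
    sfct_abort("poses have different atom counts", "sfct_error_topology")
  }
  perms <- ligand_automorphisms(elements, bonds, cap = cap)
  naive <- heavy_atom_rmsd(a, b)
  best <- naive
  best_perm <- seq_len(nrow(a))
  for (p in perms) {
    r <- heavy_atom_rmsd(a[p, , drop = FALSE], b)
    if (r < best) {
      best <- r
      best_perm <- p
    }
  }
  tibble(
    naive_rmsd = naive, symmetry_rmsd = best,
    capped = isTRUE(attr(perms, "capped")), mapping = list(best_perm)
  )
}

#' Symmetry-corrected RMSD of every pose against a reference
#'
#' Computes the symmetry-corrected heavy-atom RMSD of each pose in a pose
#' set against a reference (native) pose, enumerating the ligand's graph
#' automorphisms once and reusing them for all poses.
#'
#' @param poses An `sfct_poses` object.
#' @param reference Reference pose: an `sfct_poses` with one pose, or an
#'   atom tibble / coordinate matrix in the same atom order.
#' @param cap Automorphism cap.
#' @return Tibble `pose_id`, `rmsd` (symmetry-corrected, Å), `naive_rmsd`.
#' @export
rmsd_to_reference <- function(poses, reference, cap = 10000L) {
  ref <- if (inherits(reference, "sfct_poses")) {
    pose_coords(reference, pose_ids(reference)[[1]])
  } else {
    as_coord_matrix(reference)
  }
  first <- pose_atoms(poses, pose_ids(poses)[[1]])
  if (nrow(first) != nrow(ref)) {
    sfct_abort("reference and poses have different atom counts",
      "sfct_error_topology")
  }
  perms <- ligand_automorphisms(first$element, poses$bonds, cap = cap)
  res <- lapply(pose_ids(poses), function(id) {
    a <- pose_coords(poses, id)
    naive <- heavy_atom_rmsd(a, ref)
    best <- naive
    if (length(perms) > 1) {
      for (p in perms) {
        r <- heavy_atom_rmsd(a[p, , drop = FALSE], ref)
        if (r < best) best <- r
      }
    }
    c(best, naive)
  })
  m <- do.call(rbind, res)
  tibble(pose_id = pose_ids(poses), rmsd = m[, 1], naive_rmsd = m[, 2])
}
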