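#' Define a contact-shell scheme
#'
#' Protein--ligand contacts are counted in concentric distance shells around
#' each ligand atom. The default scheme uses 14 shells of width 1.5 Å
#' starting at 0 Å, so contacts are counted out to 21 Å -- wide enough to
#' capture both the first coordination shells and the longer-range context of
#' a binding pocket.
#'
#' @param n_shells Number of shells (default 14).
#' @param shell_width Shell width in Å (default 1.5).
#' @param origin Inner edge of the first shell in Å (default 0).
#' @return An object of class `shell_scheme`.
#' @export
shell_scheme <- function(n_shells = 14L, shell_width = 1.5, origin = 0) {
  n_shells <- as.integer(n_shells)
  if (is.na(n_shells) || n_shells < 1) {
    sfct_abort("n_shells must be a positive integer", "sfct_error_domain")
  }
  if (!is.finite(shell_width) || shell_width <= 0) {
    sfct_abort("shell_width must be positive", "sfct_error_domain")
  }
  if (!is.finite(origin) || origin < 0) {
    sfct_abort("origin must be non-negative", "sfct_error_domain")
  }
  structure(
    list(n_shells = n_shells, shell_width = shell_width, origin = origin),
    class = "shell_scheme"
  )
}

#' @export
print.shell_scheme <- function(x, ...) {
  cat(sprintf("<shell_scheme> %d shells x %.2f A from %.2f A (max %.2f A)\n",
    x$n_shells, x$shell_width, x$origin, max_shell_distance(x)))
  invisible(x)
}

#' @rdname shell_scheme
#' @export
max_shell_distance <- function(scheme) {
  scheme$origin + scheme$n_shells * scheme$shell_width
}

#' Shell index of a distance
#'
#' Shells are half-open intervals `[origin + (k-1) w, origin + k w)`. A
#' distance at or beyond the outermost edge falls in no shell and returns
#' `NA`.
#'
#' @param distance Numeric vector of distances in Å (must be `>= 0`).
#' @param scheme A [shell_scheme()].
#' @return Integer vector of shell indices in `1..n_shells`, `NA` for
#'   out-of-range distances.
#' @examples
#' shell_index(c(0, 2, 21), shell_scheme())
#' @export
shell_index <- function(distance, scheme = shell_scheme()) {
  if (any(!is.finite(distance)) || any(distance < 0)) {
    sfct_abort("distances must be finite and non-negative", "sfct_error_domain")
  }
  k <- floor((distance - scheme$origin) / scheme$shell_width) + 1L
  k <- as.integer(k)
  k[distance < scheme$origin] <- NA_integer_
  k[k > scheme$n_shells] <- NA_integer_
  k
}

#' Feature schema: the ordered contact bins
#'
#' The feature vector is ordered residue class (alphabetical, then `OTH`)
#' slowest, then element class (C, N, O, S, P, HAL, OTH), then shell
#' ascending -- the first bin is `(ALA, C, 1)`. The default scheme yields
#' 21 x 7 x 14 = 2058 bins.
#'
#' @param scheme A [shell_scheme()].
#' @return Tibble with columns `residue_class`, `element_class`, `shell` and
#'   the bin name `bin`, in feature-vector order; carries a `schema_id`
#'   attribute.
#' @export
feature_schema <- function(scheme = shell_scheme()) {
  grid <- expand.grid(
    shell = seq_len(scheme$n_shells),
    element_class = ELEMENT_CLASSES,
    residue_class = RESIDUE_CLASSES,
    stringsAsFactors = FALSE
  )
  out <- tibble(
    residue_class = grid$residue_class,
    element_class = grid$element_class,
    shell = as.integer(grid$shell),
    bin = sprintf("%s_%s_s%02d", grid$residue_class, grid$element_class, grid$shell)
  )
  attr(out, "schema_id") <- schema_id(scheme)
  out
}

#' @rdname feature_schema
#' @export
schema_id <- function(scheme = shell_scheme()) {
  hash(list(
    residues = RESIDUE_CLASSES, elements = ELEMENT_CLASSES,
    n_shells = scheme$n_shells, shell_width = scheme$shell_width,
    origin = scheme$origin, order = "residue>element>shell"
  ))
}

#' Contact-count featurization of a protein--ligand pose
#'
#' For every (protein heavy atom, ligand heavy atom) pair whose Euclidean
#' distance falls inside the shell scheme, the bin
#' `(residue class of the protein atom, element class of the ligand atom,
#' shell)` is incremented by one. The sum of all counts therefore equals the
#' number of atom pairs closer than the outermost shell edge.
#'
#' `featurize_complex()` featurizes a single pose given its atom table;
#' `featurize_poses()` featurizes every pose of a pose set and returns one
#' row per pose.
#'
#' @param receptor Receptor tibble from [read_receptor()] (columns `resid`,
#'   `x`, `y`, `z` required).
#' @param ligand_atoms Tibble of ligand heavy atoms (columns `element`, `x`,
#'   `y`, `z`).
#' @param scheme A [shell_scheme()].
#' @return `featurize_complex()`: a named integer vector of length
#'   `nrow(feature_schema(scheme))`. `featurize_poses()`: a tibble with
#'   `pose_id` followed by the count columns, with a `schema_id` attribute.
#' @examples
#' rec <- tibble::tibble(resid = "GLY", x = c(0, 1.5), y = 0, z = 0)
#' lig <- tibble::tibble(element = "C", x = 3, y = 0, z = 0)
#' f <- featurize_complex(rec, lig)
#' f[f > 0]
#' @export
featurize_complex <- function(receptor, ligand_atoms, scheme = shell_scheme()) {
  if (is.null(receptor) || nrow(receptor) == 0) {
    sfct_abort("empty protein structure", "sfct_error_empty")
  }
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0) {
    sfct_abort("empty ligand pose", "sfct_error_empty")
  }
  res_idx <- match(classify_residue(receptor$resid), RESIDUE_CLASSES)
  ele_idx <- match(classify_element(ligand_atoms$element), ELEMENT_CLASSES)
  n_sh <- scheme$n_shells
  n_ele <- length(ELEMENT_CLASSES)

  px <- receptor$x; py <- receptor$y; pz <- receptor$z
  lx <- ligand_atoms$x; ly <- ligand_atoms$y; lz <- ligand_atoms$z
  # np x nl distance matrix; pocket-scale problems keep this small
  d <- sqrt(outer(px, lx, "-")^2 + outer(py, ly, "-")^2 + outer(pz, lz, "-")^2)
  k <- floor((d - scheme$origin) / scheme$shell_width) + 1
  in_range <- d >= scheme$origin & k <= n_sh
  res_m <- matrix(res_idx, nrow = length(px), ncol = length(lx))
  ele_m <- matrix(ele_idx, nrow = length(px), ncol = length(lx), byrow = TRUE)
  lin <- (res_m[in_range] - 1L) * (n_ele * n_sh) +
    (ele_m[in_range] - 1L) * n_sh + as.integer(k[in_range])
  counts <- tabulate(lin, nbins = length(RESIDUE_CLASSES) * n_ele * n_sh)
  names(counts) <- feature_schema(scheme)$bin
  counts
}

#' @rdname featurize_complex
#' @param poses An `sfct_poses` object.
#' @export
featurize_poses <- function(receptor, poses, scheme = shell_scheme()) {
  schema <- feature_schema(scheme)
  rows <- lapply(pose_ids(poses), function(id) {
    featurize_complex(receptor, pose_atoms(poses, id), scheme)
  })
  mat <- do.call(rbind, rows)
  out <- bind_cols(
    tibble(pose_id = pose_ids(poses)),
    as_tibble(as.data.frame(mat))
  )
  attr(out, "schema_id") <- attr(schema, "schema_id")
  out
}
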