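#' Form-factor table
#'
#' Per-bead-type form factors on a discretized q-grid: one row per bead
#' label, one column per grid point. Values must lie in `[0, f_max]`.
#'
#' @param values Numeric matrix, `length(alphabet$labels)` rows by
#'   `grid$n_bins` columns. Row names are set to the alphabet labels.
#' @param alphabet A [bead_alphabet()].
#' @param grid A [q_grid()].
#' @param f_max Upper bound on form-factor values (default 40).
#' @return An object of class `fftable`.
#' @export
form_factor_table <- function(values, alphabet, grid, f_max = 40) {
  stopifnot(inherits(alphabet, "bead_alphabet"), inherits(grid, "qgrid"))
  values <- as.matrix(values)
  if (nrow(values) != length(alphabet$labels))
    stop("table must have one row per alphabet label")
  if (ncol(values) != grid$n_bins)
    stop("table must have one column per grid point")
  if (any(!is.finite(values)) || any(values < 0) || any(values > f_max))
    stop("form-factor values must lie in [0, f_max]")
  rownames(values) <- alphabet$labels
  structure(list(values = values, alphabet = alphabet, grid = grid,
                 f_max = f_max),
            class = "fftable")
}

#' Write a form-factor table as TSV
#'
#' First column is the left-edge q value (3 decimals); remaining columns are
#' one per bead label, with `*` marking whole-residue beads.
#'
#' @param table An `fftable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fftable <- function(table, path) {
  stopifnot(inherits(table, "fftable"))
  df <- data.frame(q = sprintf("%.3f", table$grid$q),
                   t(table$values), check.names = FALSE)
  colnames(df) <- c("q", table$alphabet$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a form-factor table from TSV
#'
#' @param path Input path (layout of [write_fftable()]).
#' @param f_max Upper bound used to validate values.
#' @return An `fftable`. The granularity is inferred from the label set.
#' @export
read_fftable <- function(path, f_max = 40) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  q <- df[[1L]]
  labels <- colnames(df)[-1L]
  two <- bead_alphabet("two"); one <- bead_alphabet("one")
  alphabet <- if (identical(labels, two$labels)) two
  else if (identical(labels, one$labels)) one
  else stop("column labels match neither the one-body nor the two-body alphabet")
  dq <- diff(q)
  if (length(dq) < 1L || any(abs(dq - dq[1L]) > 1e-9))
    stop("q column is not an evenly spaced grid")
  grid <- q_grid(q_min = q[1L], dq = dq[1L], n_bins = length(q))
  form_factor_table(t(as.matrix(df[, -1L, drop = FALSE])), alphabet, grid,
                    f_max = f_max)
}

# map bead labels to alphabet indices, erroring on unknown labels
bead_type_index <- function(labels, alphabet) {
  idx <- match(labels, alphabet$labels)
  if (anyNA(idx))
    stop("unknown bead label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

new_curve_with_pairs <- function(q, I, n_scatterers) {
  curve <- scattering_curve(q, pmax(I, 0))
  attr(curve, "pair_evaluations") <- as.numeric(n_scatterers)^2
  curve
}

#' Debye intensity of a coarse-grained structure
#'
#' Evaluates the Debye formula
#' \deqn{I(q) = \sum_i \sum_j F_i(q) F_j(q) \frac{\sin(q r_{ij})}{q r_{ij}}}
#' over all bead pairs (diagonal included, with sinc(0) = 1) at every grid
#' point. At q = 0 this reduces to \eqn{I(0) = (\sum_i F_i(0))^2}.
#'
#' @param structure A `coarse_structure`.
#' @param table An `fftable` whose alphabet covers every bead label and
#'   whose grid is used for evaluation.
#' @param grid Optional [q_grid()]; defaults to the table's grid, and must
#'   match it.
#' @return A `saxs_curve` over the grid, with attribute `pair_evaluations`
#'   = M^2 recording the cost of the double sum.
#' @export
debye_intensity <- function(structure, table, grid = table$grid) {
  stopifnot(inherits(structure, "coarse_structure"), inherits(table, "fftable"))
  if (!grids_match(grid$q, table$grid$q))
    stop("evaluation grid does not match the form-factor table grid")
  if (structure$granularity != table$alphabet$granularity)
    stop("granularity mismatch: structure is ", structure$granularity,
         "-body but table is ", table$alphabet$granularity, "-body")
  idx <- bead_type_index(structure$beads$label, table$alphabet)
  coords <- as.matrix(structure$beads[, c("x", "y", "z")])
  fmat <- table$values[idx, , drop = FALSE]
  I <- cpp_debye_curve(coords, fmat, grid$q)
  new_curve_with_pairs(grid$q, I, nrow(coords))
}

#' Per-element scattering factors for the all-atom oracle
#'
#' Electron counts of the heavy elements common in proteins, used as
#' q-independent scattering factors by [all_atom_debye()]. This is a
#' geometric reference model, not a vacuum-plus-excluded-volume solution
#' scattering model.
#'
#' @return Named numeric vector (C, N, O, S, SE, P).
#' @export
electron_factors <- function() {
  c(C = 6, N = 7, O = 8, S = 16, SE = 34, P = 15)
}

#' All-atom Debye intensity
#'
#' Applies the Debye formula with one scatterer per heavy atom and constant
#' (q-independent) per-element factors. Serves as the reference-curve
#' generator for synthetic fixtures and as the all-atom baseline for
#' pair-count comparisons.
#'
#' @param atoms An `atom_records` data frame.
#' @param element_factors Named vector mapping element symbol to factor;
#'   defaults to [electron_factors()].
#' @param grid A [q_grid()].
#' @return A `saxs_curve` with attribute `pair_evaluations` = (atom count)^2.
#' @export
all_atom_debye <- function(atoms, element_factors = electron_factors(),
                           grid = q_grid()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L, inherits(grid, "qgrid"))
  f <- element_factors[atoms$elem]
  if (anyNA(f))
    stop("no scattering factor for element(s): ",
         paste(unique(atoms$elem[is.na(f)]), collapse = ", "))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  fmat <- matrix(f, nrow = nrow(coords), ncol = grid$n_bins)
  I <- cpp_debye_curve(coords, fmat, grid$q)
  new_curve_with_pairs(grid$q, I, nrow(coords))
}

#' Debye intensity at an off-grid q value
#'
#' Linearly interpolates the form factors between neighboring grid points
#' and applies the Debye formula at the requested q. At exact grid points
#' this equals [debye_intensity()]. No extrapolation outside the grid range.
#'
#' @param structure A `coarse_structure`.
#' @param table An `fftable`.
#' @param q Scalar momentum value within the table's grid range.
#' @return Scalar intensity.
#' @export
evaluate_offgrid <- function(structure, table, q) {
  stopifnot(inherits(structure, "coarse_structure"), inherits(table, "fftable"),
            is.numeric(q), length(q) == 1L)
  gq <- table$grid$q
  if (q < gq[1L] || q > gq[length(gq)])
    stop("q = ", q, " outside the grid range [", gq[1L], ", ",
         gq[length(gq)], "]; no extrapolation")
  if (structure$granularity != table$alphabet$granularity)
    stop("granularity mismatch between structure and table")
  idx <- bead_type_index(structure$beads$label, table$alphabet)
  fq <- apply(table$values, 1L, function(row) stats::approx(gq, row, xout = q)$y)
  coords <- as.matrix(structure$beads[, c("x", "y", "z")])
  fmat <- matrix(fq[idx], ncol = 1L)
  as.numeric(cpp_debye_curve(coords, fmat, q))
}

# Per-structure type-pair cross terms G_tu(q) = sum over ordered bead pairs
# (i in type t, j in type u) of sinc(q r_ij), so I(q) = F' G(q) F. Returned
# as a list of L x L matrices, one per grid point. This regrouping makes a
# posterior evaluation O(L^2) in the number of bead types instead of
# O(M^2) in the number of beads.
structure_cross_terms <- function(structure, alphabet, grid) {
  idx <- bead_type_index(structure$beads$label, alphabet)
  coords <- as.matrix(structure$beads[, c("x", "y", "z")])
  L <- length(alphabet$labels)
  flat <- cpp_cross_terms(coords, as.integer(idx), L, grid$q)
  lapply(seq_len(grid$n_bins), function(k) matrix(flat[, k], L, L))
}
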