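#' Parse heavy atoms from a PDB structure
#'
#' Reads ATOM records from PDB-format text and returns the heavy (non-
#' hydrogen) atoms of a single chain. HETATM records, waters and hydrogens
#' are dropped; alternate locations are resolved by keeping altloc ' ' or
#' 'A' (the standard single-conformer convention).
#'
#' Parsing is delegated to [bio3d::read.pdb()]; a pre-validation pass
#' reports malformed ATOM records by line number.
#'
#' @param pdb Path to a PDB file, or PDB text (a character vector of lines
#'   or a single string containing newlines).
#' @param chain Chain identifier. `NULL` selects the first chain in the
#'   file (with a warning if there are several).
#' @return A data frame of class `atom_records` with columns `elem` (element
#'   symbol), `name` (PDB atom name), `resid` (3-letter residue type),
#'   `chain`, `resno` and coordinates `x`, `y`, `z` in Angstrom.
#' @export
parse_structure <- function(pdb, chain = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
  }
  atom_idx <- grep("^ATOM  ", lines)
  if (length(atom_idx) == 0L) stop("no ATOM records found in PDB input")
  for (i in atom_idx) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords) || any(!is.finite(coords)))
      stop("malformed ATOM record at line ", i, ": ", trimws(ln))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  log <- utils::capture.output(
    pdbobj <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE,
                                               verbose = FALSE)))
  at <- pdbobj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records found in PDB input")
  # element: PDB element column when present, else first letter of the
  # atom name with leading digits stripped
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) {
    nm <- gsub("^[0-9]+", "", trimws(at$elety[miss]))
    elem[miss] <- substr(nm, 1L, 1L)
  }
  keep <- !(elem %in% c("H", "D"))
  alt <- trimws(at$alt)
  keep <- keep & (is.na(alt) | alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      warning("multiple chains present (", paste(chains, collapse = ", "),
              "); using chain ", chains[1L])
    chain <- chains[1L]
  }
  sel <- at$chain == chain
  if (!any(sel)) stop("chain '", chain, "' has no heavy atoms in this file")
  at <- at[sel, , drop = FALSE]
  out <- data.frame(elem = elem[sel], name = trimws(at$elety),
                    resid = trimws(at$resid), chain = at$chain,
                    resno = at$resno, x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  class(out) <- c("atom_records", "data.frame")
  out
}

#' Dummy-atom bead alphabet
#'
#' The label set of a coarse-grained representation. The one-body alphabet
#' has one label per amino-acid type (20 labels). The two-body alphabet has
#' 21 labels: a generic backbone bead `BB`, whole-residue beads `ALA*` and
#' `GLY*` (the `*` marks beads covering backbone plus side chain), and 18
#' side-chain beads.
#'
#' @param granularity `"two"` (two-body, default) or `"one"` (one-body).
#' @return An object of class `bead_alphabet`: list with `granularity` and
#'   the ordered `labels`.
#' @export
bead_alphabet <- function(granularity = c("two", "one")) {
  granularity <- match.arg(granularity)
  labels <- if (granularity == "two") {
    c("BB", "ALA*", "GLY*", setdiff(AA_CODES, c("ALA", "GLY")))
  } else {
    AA_CODES
  }
  structure(list(granularity = granularity, labels = labels),
            class = "bead_alphabet")
}

residue_bead_labels <- function(resid, granularity) {
  if (granularity == "one") return(resid)
  if (resid %in% c("ALA", "GLY")) paste0(resid, "*") else resid
}

#' Coarse-grain an all-atom structure into dummy atoms
#'
#' Reduces heavy atoms to the one-body or two-body dummy-atom model. In the
#' two-body model each residue other than glycine and alanine contributes a
#' backbone bead (unweighted centroid of its N, CA, C, O, CB and OXT atoms;
#' CB counts to the backbone, not the side chain) followed by a side-chain
#' bead (centroid of the remaining heavy atoms); glycine and alanine
#' contribute a single whole-residue bead at the centroid of all their heavy
#' atoms. In the one-body model every residue contributes one bead at the
#' centroid of all its heavy atoms. Beads follow residue order.
#'
#' Centroids are unweighted means of heavy-atom coordinates. A non-Gly/Ala
#' residue with no side-chain heavy atoms (truncated side chain) is emitted
#' as a backbone-only bead with a warning.
#'
#' @param atoms An `atom_records` data frame from [parse_structure()].
#' @param granularity `"two"` or `"one"`.
#' @param residue_map Optional named character vector mapping nonstandard
#'   residue names to standard ones (e.g. `c(MSE = "MET")`). Unknown residue
#'   types error.
#' @return An object of class `coarse_structure`: list with `beads` (data
#'   frame `label`, `x`, `y`, `z`, `res_index`), `granularity`, `alphabet`
#'   and `n_beads`.
#' @export
coarse_grain <- function(atoms, granularity = c("two", "one"),
                         residue_map = NULL) {
  granularity <- match.arg(granularity)
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  alphabet <- bead_alphabet(granularity)
  resid <- atoms$resid
  if (!is.null(residue_map)) {
    mapped <- resid %in% names(residue_map)
    resid[mapped] <- unname(residue_map[resid[mapped]])
  }
  unknown <- setdiff(unique(resid), AA_CODES)
  if (length(unknown) > 0L)
    stop("unknown residue type(s): ", paste(unknown, collapse = ", "),
         " (provide residue_map to translate them)")
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  key <- factor(key, levels = unique(key))  # residue order as encountered
  groups <- split(seq_len(nrow(atoms)), key)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    rtype <- resid[idx[1L]]
    xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
    if (nrow(xyz) == 0L) stop("residue with zero heavy atoms")
    if (granularity == "one" || rtype %in% c("ALA", "GLY")) {
      cen <- colMeans(xyz)
      rows[[gi]] <- data.frame(label = residue_bead_labels(rtype, granularity),
                               x = cen[1L], y = cen[2L], z = cen[3L],
                               res_index = gi, stringsAsFactors = FALSE)
    } else {
      bb <- atoms$name[idx] %in% BACKBONE_ATOMS
      if (!any(bb)) stop("residue ", key[idx[1L]], " has no backbone heavy atoms")
      cen_bb <- colMeans(xyz[bb, , drop = FALSE])
      if (any(!bb)) {
        cen_sc <- colMeans(xyz[!bb, , drop = FALSE])
        rows[[gi]] <- data.frame(
          label = c("BB", rtype),
          x = c(cen_bb[1L], cen_sc[1L]), y = c(cen_bb[2L], cen_sc[2L]),
          z = c(cen_bb[3L], cen_sc[3L]),
          res_index = gi, stringsAsFactors = FALSE)
      } else {
        warning("residue ", as.character(key[idx[1L]]), " (", rtype,
                ") has no side-chain heavy atoms; emitting backbone bead only")
        rows[[gi]] <- data.frame(label = "BB", x = cen_bb[1L], y = cen_bb[2L],
                                 z = cen_bb[3L], res_index = gi,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  structure(list(beads = beads, granularity = granularity,
                 alphabet = alphabet, n_beads = nrow(beads),
                 source = attr(atoms, "source", exact = TRUE)),
            class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat(sprintf("coarse structure: %d beads (%s-body model, %d residues)\n",
              x$n_beads, x$granularity, max(x$beads$res_index)))
  invisible(x)
}

#' Atoms-per-bead coarse-graining ratio
#'
#' Ratio k of heavy atoms to dummy-atom beads. The Debye double sum over
#' pairs shrinks by k^2 when atoms are replaced by beads.
#'
#' @param atoms The `atom_records` the structure was derived from.
#' @param structure The derived `coarse_structure`.
#' @return Scalar k = (number of heavy atoms) / (number of beads).
#' @export
coarse_ratio <- function(atoms, structure) {
  stopifnot(is.data.frame(atoms), inherits(structure, "coarse_structure"))
  nrow(atoms) / structure$n_beads
}
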