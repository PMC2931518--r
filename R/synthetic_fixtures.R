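#' Specification of a synthetic protein fixture
#'
#' Parameters of the fixture generator that stands in for curated PDB
#' training/validation sets and decoy ensembles: protein-like all-atom
#' structures built on a self-avoiding C-alpha walk, matched reference
#' curves from the all-atom Debye oracle, and perturbation decoys.
#'
#' @param n_residues Number of residues (>= 2).
#' @param composition Named amino-acid frequency vector; defaults to
#'   [aa_frequencies()] (about 8 heavy atoms per residue on average).
#' @param seed Integer RNG seed; every generator output is deterministic
#'   given the seed.
#' @param noise_level Reference-curve noise in multiples of the model
#'   sigma_q (>= 0).
#' @param n_decoys Number of decoys produced by [generate_decoys()].
#' @param perturbation Decoy perturbation scale (Angstrom-like; 0 means
#'   exact copies of the native). The default ladder reaches misfolded
#'   conformations around 15-20 A RMSD, mirroring decoy sets of widely
#'   varying similarity to the native.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues, composition = aa_frequencies(),
                         seed = 1L, noise_level = 0, n_decoys = 100L,
                         perturbation = 20) {
  stopifnot(n_residues >= 2, noise_level >= 0, n_decoys >= 0,
            perturbation >= 0)
  stopifnot(all(names(composition) %in% AA_CODES), all(composition >= 0),
            sum(composition) > 0)
  structure(list(n_residues = as.integer(n_residues),
                 composition = composition / sum(composition),
                 seed = as.integer(seed), noise_level = noise_level,
                 n_decoys = as.integer(n_decoys), perturbation = perturbation),
            class = "fixture_spec")
}

unit_vec <- function(v) v / sqrt(sum(v^2))
random_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# self-avoiding C-alpha walk: 3.8 A steps, >= 4.0 A clearance between
# non-neighboring positions, mild persistence plus a pull toward the
# running centroid to keep the chain compact
ca_walk <- function(n, step = 3.8, clearance = 4.0, max_retry = 500L) {
  ca <- matrix(NA_real_, n, 3L)
  ca[1L, ] <- c(0, 0, 0)
  dir <- random_unit()
  ca[2L, ] <- ca[1L, ] + step * dir
  for (i in seq_len(n - 2L) + 2L) {
    centroid <- colMeans(ca[seq_len(i - 1L), , drop = FALSE])
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      pull <- centroid - ca[i - 1L, ]
      pn <- sqrt(sum(pull^2))
      pull <- if (pn > 1e-8) pull / pn else c(0, 0, 0)
      cand_dir <- unit_vec(0.55 * dir + 1.0 * random_unit() + 0.25 * pull)
      cand <- ca[i - 1L, ] + step * cand_dir
      prev <- ca[seq_len(i - 2L), , drop = FALSE]
      d2 <- rowSums((prev - matrix(cand, nrow(prev), 3L, byrow = TRUE))^2)
      if (all(d2 >= clearance^2)) {
        ca[i, ] <- cand
        dir <- cand_dir
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("self-avoiding walk failed at residue ", i,
           " after ", max_retry, " retries; use a larger clearance box ",
           "(fewer residues or smaller clearance)")
  }
  ca
}

#' Generate a protein-like all-atom structure
#'
#' Builds an all-atom heavy-atom model on a self-avoiding C-alpha walk with
#' 3.8 A steps and >= 4.0 A non-neighbor clearance. Backbone N, C, O and CB
#' atoms are placed at fixed ideal offsets in a local frame along the walk;
#' the remaining side-chain heavy atoms of each residue type (real per-type
#' counts and elements) form a compact random cluster 1.5-3.5 A from CB.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return An `atom_records` data frame (chain "A").
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_residues
    seq_aa <- sample(names(spec$composition), n, replace = TRUE,
                     prob = spec$composition)
    ca <- ca_walk(n)
    rows <- vector("list", n)
    e2_prev <- c(0, 0, 1)
    for (i in seq_len(n)) {
      e1 <- if (i < n) unit_vec(ca[i + 1L, ] - ca[i, ]) else
        unit_vec(ca[i, ] - ca[i - 1L, ])
      ref <- e2_prev - sum(e2_prev * e1) * e1
      if (sqrt(sum(ref^2)) < 1e-6) ref <- c(0, 1, 0) - sum(c(0, 1, 0) * e1) * e1
      e2 <- unit_vec(ref)
      e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
              e1[3L] * e2[1L] - e1[1L] * e2[3L],
              e1[1L] * e2[2L] - e1[2L] * e2[1L])
      e2_prev <- e2
      p <- ca[i, ]
      rtype <- seq_aa[i]
      nm <- c("N", "CA", "C", "O")
      el <- c("N", "C", "C", "O")
      pos <- rbind(p - 0.70 * e1 - 1.25 * e2,
                   p,
                   p + 0.70 * e1 + 1.35 * e2,
                   p + 1.00 * e1 + 2.40 * e2 - 0.30 * e3)
      sc <- AA_SIDECHAIN[[rtype]]
      if (length(sc) > 0L) {
        cb <- p - 0.55 * e1 - 0.75 * e2 - 1.20 * e3
        nm <- c(nm, names(sc)[1L]); el <- c(el, unname(sc[1L]))
        pos <- rbind(pos, cb)
        if (length(sc) > 1L) {
          for (j in seq.int(2L, length(sc))) {
            r <- stats::runif(1L, 1.5, 3.5)
            pos <- rbind(pos, cb + r * random_unit())
          }
          nm <- c(nm, names(sc)[-1L]); el <- c(el, unname(sc[-1L]))
        }
      }
      rows[[i]] <- data.frame(elem = el, name = nm, resid = rtype,
                              chain = "A", resno = i,
                              x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("atom_records", "data.frame")
    out
  })
}

#' Generate a synthetic reference scattering curve
#'
#' Computes the all-atom Debye oracle curve with electron-count factors,
#' then adds Gaussian noise with standard deviation
#' `noise_level * sigma_q` (sigma_q from the error model applied to the
#' noiseless curve), clipping at zero. The sigma column is filled from the
#' noiseless intensity.
#'
#' @param atoms An `atom_records` data frame.
#' @param grid A [q_grid()].
#' @param model An [error_model()].
#' @param noise_level Noise in multiples of sigma_q (0 gives the exact
#'   oracle curve).
#' @param seed Optional integer seed for the noise draw.
#' @return A `saxs_curve` with sigma.
#' @export
generate_reference <- function(atoms, grid = q_grid(), model = error_model(),
                               noise_level = 0, seed = NULL) {
  base <- all_atom_debye(atoms, grid = grid)
  sig <- sigma_values(base$q, base$I, model)
  I <- if (noise_level > 0) {
    with_local_seed(seed,
      pmax(base$I + stats::rnorm(length(base$I), 0, noise_level * sig), 0))
  } else base$I
  scattering_curve(base$q, I, sig)
}

rotation_matrix <- function(axis, angle) {
  u <- unit_vec(axis)
  c <- cos(angle); s <- sin(angle)
  matrix(c(c + u[1L]^2 * (1 - c), u[1L] * u[2L] * (1 - c) - u[3L] * s,
           u[1L] * u[3L] * (1 - c) + u[2L] * s,
           u[1L] * u[2L] * (1 - c) + u[3L] * s, c + u[2L]^2 * (1 - c),
           u[2L] * u[3L] * (1 - c) - u[1L] * s,
           u[1L] * u[3L] * (1 - c) - u[2L] * s,
           u[2L] * u[3L] * (1 - c) + u[1L] * s, c + u[3L]^2 * (1 - c)),
         3L, 3L, byrow = TRUE)
}

#' Generate decoy structures from a native
#'
#' Produces decoys by seeded hinge perturbations: random downstream
#' sub-segment rotations about axes through randomly chosen C-alpha hinge
#' positions. Within a set the perturbation magnitude increases linearly
#' from `spec$perturbation / n_decoys` to `spec$perturbation` (decoys of
#' varying similarity to the native, an RMSD ladder); scale 0 reproduces
#' the native exactly. The native is never included among the decoys.
#'
#' @param atoms Native `atom_records`.
#' @param spec A [fixture_spec()] providing `n_decoys`, `perturbation` and
#'   `seed`.
#' @param n_hinges Hinge rotations applied per decoy (default 4).
#' @return List of `atom_records`, one per decoy.
#' @export
generate_decoys <- function(atoms, spec, n_hinges = 4L) {
  stopifnot(inherits(spec, "fixture_spec"))
  resno <- atoms$resno
  residues <- sort(unique(resno))
  nres <- length(residues)
  with_local_seed(spec$seed + 1000L, {
    lapply(seq_len(spec$n_decoys), function(d) {
      angle_sd <- (spec$perturbation * d / spec$n_decoys) / 20
      out <- atoms
      xyz <- as.matrix(out[, c("x", "y", "z")])
      for (h in seq_len(n_hinges)) {
        hinge <- sample(residues[-c(1L, nres)], 1L)
        angle <- stats::rnorm(1L, 0, angle_sd)
        axis <- random_unit()
        pivot_idx <- which(resno == hinge & atoms$name == "CA")[1L]
        pivot <- xyz[pivot_idx, ]
        move <- resno > hinge
        if (angle != 0 && any(move)) {
          R <- rotation_matrix(axis, angle)
          xyz[move, ] <- sweep(sweep(xyz[move, , drop = FALSE], 2L, pivot) %*%
                                 t(R), 2L, pivot, "+")
        }
      }
      out$x <- xyz[, 1L]; out$y <- xyz[, 2L]; out$z <- xyz[, 3L]
      out
    })
  })
}

#' Root-mean-square deviation between two conformations
#'
#' RMSD over matched atoms after optimal superposition (Kabsch fit via
#' [bio3d::rmsd()]).
#'
#' @param a,b `atom_records` data frames with identical atom ordering.
#' @param fit Superpose before measuring (default `TRUE`).
#' @return Scalar RMSD in Angstrom.
#' @export
rmsd_atoms <- function(a, b, fit = TRUE) {
  stopifnot(nrow(a) == nrow(b))
  xa <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  xb <- as.numeric(t(as.matrix(b[, c("x", "y", "z")])))
  as.numeric(bio3d::rmsd(xa, xb, fit = fit))
}

#' Write atom records as a PDB file
#'
#' @param atoms An `atom_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_atoms <- function(atoms, path) {
  n <- nrow(atoms)
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = xyz, type = rep("ATOM", n),
    resno = atoms$resno, resid = atoms$resid, chain = atoms$chain,
    elety = atoms$name, elesy = atoms$elem,
    eleno = seq_len(n), o = rep(1, n), b = rep(0, n)))
  invisible(path)
}

element_electrons <- c(C = 6, N = 7, O = 8, S = 16)

#' Synthetic generating form-factor table
#'
#' A smooth synthetic table used as ground truth by the parameter-recovery
#' harness: each bead type gets an electron-count-scale amplitude at q = 0
#' (scaled to fit inside the box prior) with a Gaussian decay in q whose
#' radius grows across the alphabet. This is a synthetic stand-in chosen
#' for realism of scale and smoothness; it is not an estimate of physical
#' dummy-atom form factors.
#'
#' @param alphabet A [bead_alphabet()].
#' @param grid A [q_grid()].
#' @param f_max Box bound the amplitudes must respect.
#' @return An `fftable`.
#' @export
synthetic_table <- function(alphabet = bead_alphabet("two"), grid = q_grid(),
                            f_max = 40) {
  backbone_e <- sum(element_electrons[c("N", "C", "C", "O")])  # N, CA, C, O
  cb_e <- element_electrons[["C"]]
  side_e <- vapply(AA_SIDECHAIN, function(sc)
    if (length(sc) > 1L) sum(element_electrons[sc[-1L]]) else 0, 0)  # beyond CB
  has_cb <- vapply(AA_SIDECHAIN, function(sc) length(sc) > 0L, TRUE)
  amps <- if (alphabet$granularity == "two") {
    a <- c(BB = backbone_e + cb_e,
           `ALA*` = backbone_e + cb_e,
           `GLY*` = backbone_e)
    sc_labels <- setdiff(alphabet$labels, names(a))
    0.6 * c(a, side_e[sc_labels])[alphabet$labels]
  } else {
    0.35 * (backbone_e + ifelse(has_cb[alphabet$labels], cb_e, 0) +
              side_e[alphabet$labels])
  }
  amps <- pmin(amps, 0.975 * f_max)
  radii <- seq(1.2, 2.8, length.out = length(alphabet$labels))
  vals <- outer(seq_along(amps), seq_len(grid$n_bins), function(t, k)
    amps[t] * exp(-(grid$q[k] * radii[t])^2 / 2))
  form_factor_table(vals, alphabet, grid, f_max = f_max)
}
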