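# Independent brute-force oracles and small fixture builders shared by the
# tests. The Debye oracle here is a plain R double loop, written separately
# from the package kernel on purpose.

naive_sinc <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / x)

# naive Debye double sum: coords M x 3, fmat M x Q, qvec length Q
naive_debye <- function(coords, fmat, qvec) {
  m <- nrow(coords)
  out <- numeric(length(qvec))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      out <- out + fmat[i, ] * fmat[j, ] * naive_sinc(qvec * r)
    }
  }
  out
}

# wrap a bare bead table into a coarse_structure without going through
# coarse_grain (labels must belong to the granularity's alphabet)
make_structure <- function(labels, coords, granularity = "two") {
  beads <- data.frame(label = labels, x = coords[, 1], y = coords[, 2],
                      z = coords[, 3],
                      res_index = seq_along(labels))
  structure(list(beads = beads, granularity = granularity,
                 alphabet = bead_alphabet(granularity), n_beads = nrow(beads),
                 source = "test"),
            class = "coarse_structure")
}

random_coarse_structure <- function(m, granularity = "two", spread = 15) {
  alpha <- bead_alphabet(granularity)
  make_structure(sample(alpha$labels, m, replace = TRUE),
                 matrix(runif(3 * m, -spread, spread), m, 3),
                 granularity)
}

random_table <- function(grid = q_grid(), granularity = "two", fmax = 40) {
  alpha <- bead_alphabet(granularity)
  form_factor_table(
    matrix(runif(length(alpha$labels) * grid$n_bins, 0, 0.9 * fmax),
           length(alpha$labels), grid$n_bins),
    alpha, grid, f_max = fmax)
}

# one toy residue: 4 ideal-name backbone atoms plus the residue's real
# side-chain heavy atoms, all at distinct positions around `origin`
toy_residue <- function(resno, rtype, origin = c(0, 0, 0)) {
  sc <- cgsaxs:::AA_SIDECHAIN[[rtype]]
  nm <- c("N", "CA", "C", "O", names(sc))
  el <- c("N", "C", "C", "O", unname(sc))
  n <- length(nm)
  pos <- matrix(origin, n, 3, byrow = TRUE) +
    cbind(seq_len(n), seq_len(n)^2 %% 5, seq_len(n) %% 3) * 0.9
  out <- data.frame(elem = el, name = nm, resid = rtype, chain = "A",
                    resno = resno, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("atom_records", "data.frame")
  out
}

toy_chain <- function(rtypes) {
  out <- do.call(rbind, lapply(seq_along(rtypes), function(i)
    toy_residue(i, rtypes[i], origin = c(5 * i, 0, 0))))
  class(out) <- c("atom_records", "data.frame")
  out
}

# fixed-width PDB ATOM line builder for parser edge cases
pdb_line <- function(eleno, name, resid, chain, resno, x, y, z,
                     elem = substr(name, 1, 1), altloc = " ",
                     record = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, name, altloc, resid, chain, resno, x, y, z, 1, 0,
          elem)
}
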