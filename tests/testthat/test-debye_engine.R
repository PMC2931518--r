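test_that("Debye closed forms hold on the grid", {
  grid <- q_grid()
  alpha <- bead_alphabet("two")
  # single bead with constant factor 2 -> I = 4 everywhere
  tab2 <- form_factor_table(matrix(2, 21, 51), alpha, grid)
  s1 <- make_structure("BB", matrix(c(1, 2, 3), 1, 3))
  expect_equal(debye_intensity(s1, tab2)$I, rep(4, 51))

  # two unit beads at r = pi / 0.3: the cross term vanishes at q = 0.3
  tab1 <- form_factor_table(matrix(1, 21, 51), alpha, grid)
  s2 <- make_structure(c("BB", "BB"),
                       rbind(c(0, 0, 0), c(pi / 0.3, 0, 0)))
  cv <- debye_intensity(s2, tab1)
  expect_equal(cv$I[cv$q == 0.3], 2, tolerance = 1e-14)
  expect_equal(cv$I[1], 4)  # I(0) = (1 + 1)^2

  # I(0) = (sum of F(0))^2 for random structures/tables
  set.seed(42)
  for (rep in 1:5) {
    st <- random_coarse_structure(30)
    tab <- random_table()
    idx <- match(st$beads$label, tab$alphabet$labels)
    expect_equal(debye_intensity(st, tab)$I[1],
                 sum(tab$values[idx, 1])^2, tolerance = 1e-12)
  }
})

test_that("production kernel matches the naive double-loop oracle", {
  set.seed(7)
  grid <- q_grid(n_bins = 17)
  for (rep in 1:12) {
    m <- sample(2:60, 1)
    st <- random_coarse_structure(m)
    tab <- random_table(grid)
    idx <- match(st$beads$label, tab$alphabet$labels)
    got <- debye_intensity(st, tab)$I
    want <- naive_debye(as.matrix(st$beads[, c("x", "y", "z")]),
                        tab$values[idx, , drop = FALSE], grid$q)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-300)), 1e-12)
  }
})

test_that("all-atom oracle obeys closed forms and matches the naive loop", {
  grid <- q_grid(n_bins = 11)
  carbon <- data.frame(elem = "C", name = "CA", resid = "GLY", chain = "A",
                       resno = 1, x = 0, y = 0, z = 0)
  class(carbon) <- c("atom_records", "data.frame")
  expect_equal(all_atom_debye(carbon, grid = grid)$I, rep(36, 11))

  # n coincident atoms with factor f scatter as (n f)^2
  n <- 5
  co <- carbon[rep(1, n), ]
  class(co) <- c("atom_records", "data.frame")
  expect_equal(all_atom_debye(co, grid = grid)$I, rep((n * 6)^2, 11))

  set.seed(3)
  atoms <- generate_structure(fixture_spec(4, seed = 12))
  got <- all_atom_debye(atoms, grid = grid)$I
  f <- electron_factors()[atoms$elem]
  want <- naive_debye(as.matrix(atoms[, c("x", "y", "z")]),
                      matrix(f, nrow(atoms), 11), grid$q)
  expect_lt(max(abs(got - want) / abs(want)), 1e-12)

  atoms$elem[1] <- "XX"
  expect_error(all_atom_debye(atoms, grid = grid), "XX")
})

test_that("off-grid evaluation interpolates the form factors", {
  grid <- q_grid()
  st <- make_structure(c("BB", "LEU"), rbind(c(0, 0, 0), c(4, 1, -2)))
  # constant-in-q table: interpolation is a no-op at any q
  tabc <- form_factor_table(matrix(3, 21, 51), bead_alphabet("two"), grid)
  on_grid <- debye_intensity(st, tabc)
  expect_equal(evaluate_offgrid(st, tabc, 0.3), on_grid$I[on_grid$q == 0.3],
               tolerance = 1e-14)
  qmid <- 0.3 + 0.0075
  idx <- match(st$beads$label, tabc$alphabet$labels)
  coords <- as.matrix(st$beads[, c("x", "y", "z")])
  expect_equal(evaluate_offgrid(st, tabc, qmid),
               naive_debye(coords, matrix(3, 2, 1), qmid), tolerance = 1e-12)

  # table linear in q: midpoint value equals the Debye sum with averaged factors
  vals <- outer(1:21, seq_len(51), function(t, k) 0.5 * t + 0.3 * k)
  tabl <- form_factor_table(vals, bead_alphabet("two"), grid)
  k0 <- which(grid$q == 0.3)
  fmid <- (vals[idx, k0] + vals[idx, k0 + 1]) / 2
  expect_equal(evaluate_offgrid(st, tabl, qmid),
               naive_debye(coords, matrix(fmid, 2, 1), qmid),
               tolerance = 1e-12)
  expect_error(evaluate_offgrid(st, tabl, 0.76), "outside")
})

test_that("intensities are rigid-motion invariant and nonnegative", {
  set.seed(21)
  grid <- q_grid(n_bins = 21)
  st <- random_coarse_structure(40)
  tab <- random_table(grid)
  base <- debye_intensity(st, tab)$I
  theta <- 1.1
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  xyz <- as.matrix(st$beads[, c("x", "y", "z")]) %*% t(R)
  st2 <- make_structure(st$beads$label,
                        xyz + matrix(c(-7, 2, 30), 40, 3, byrow = TRUE))
  moved <- debye_intensity(st2, tab)$I
  expect_lt(max(abs(moved - base) / pmax(abs(base), 1e-300)), 1e-9)
  for (rep in 1:5) {
    st <- random_coarse_structure(25)
    I <- debye_intensity(st, tab)$I
    expect_true(all(I >= -1e-9 * I[1]))
  }
})

test_that("pair-evaluation accounting gives the k^2 reduction", {
  atoms <- generate_structure(fixture_spec(20, seed = 2))
  cs <- coarse_grain(atoms, "two")
  tab <- random_table()
  pe_bead <- attr(debye_intensity(cs, tab), "pair_evaluations")
  pe_atom <- attr(all_atom_debye(atoms), "pair_evaluations")
  expect_equal(pe_bead, cs$n_beads^2)
  expect_equal(pe_atom, nrow(atoms)^2)
  expect_equal(pe_atom / pe_bead, coarse_ratio(atoms, cs)^2)
})

test_that("curve and table files round-trip", {
  set.seed(5)
  cv <- scattering_curve(q_grid()$q, runif(51, 10, 100), runif(51, 1, 2))
  f <- withr::local_tempfile(fileext = ".dat")
  write_dat(cv, f)
  back <- read_dat(f)
  expect_equal(back$q, cv$q, tolerance = 1e-6)
  expect_equal(back$I, cv$I, tolerance = 1e-6)
  expect_equal(back$sigma, cv$sigma, tolerance = 1e-6)

  # 2-column file (no sigma)
  writeLines(c("# hdr", sprintf("%g %g", cv$q, cv$I)), f)
  expect_null(read_dat(f)$sigma)

  # CRYSOL-style 5-column file: q from column 1, total intensity column 2
  writeLines(c(" Dif/Atom/Shape intensities",
               sprintf("%g %g %g %g %g", cv$q, cv$I, cv$I / 2, cv$I / 3,
                       cv$I / 4)), f)
  int <- read_crysol_int(f)
  expect_equal(int$I, cv$I, tolerance = 1e-6)

  tab <- random_table()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fftable(tab, tf)
  first <- readLines(tf, n = 1)
  expect_match(first, "ALA\\*")
  back <- read_fftable(tf)
  expect_equal(back$values, tab$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$alphabet$labels, tab$alphabet$labels)
})

test_that("engine rejects mismatched inputs", {
  st <- random_coarse_structure(5, granularity = "one")
  tab <- random_table(granularity = "two")
  expect_error(debye_intensity(st, tab), "granularity")
  st2 <- make_structure("BAD", matrix(0, 1, 3))
  expect_error(debye_intensity(st2, random_table()), "BAD")
  expect_error(form_factor_table(matrix(50, 21, 51), bead_alphabet("two"),
                                 q_grid()), "f_max")
})
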