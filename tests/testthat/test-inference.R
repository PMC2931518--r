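# small helper: a training set with a single one-bead structure of type `lab`
single_bead_train <- function(lab = "BB", iref = 400, grid = q_grid(n_bins = 3)) {
  st <- make_structure(lab, matrix(0, 1, 3))
  cv <- scattering_curve(grid$q, rep(iref, grid$n_bins))
  training_set(list(st), list(cv), grid)
}

test_that("bin posterior peaks at the closed-form solution for one bead", {
  train <- single_bead_train("BB", iref = 400)
  alpha <- bead_alphabet("two")
  base <- rep(10, 21)
  at <- function(f) {
    v <- base
    v[match("BB", alpha$labels)] <- f
    bin_log_posterior(v, 1, train)
  }
  # I' = f^2 for a single bead, so the posterior peaks at f = sqrt(400) = 20
  expect_gt(at(20), at(19))
  expect_gt(at(20), at(21))
  opt <- optimize(function(f) at(f), c(5, 39), maximum = TRUE)
  expect_equal(opt$maximum, 20, tolerance = 1e-3)
  # box prior support
  v <- base; v[1] <- 41
  expect_equal(bin_log_posterior(v, 1, train), -Inf)
  v <- base; v[2] <- -0.1
  expect_equal(bin_log_posterior(v, 1, train), -Inf)
  expect_error(bin_log_posterior(base, 9, train), "out of range")
})

test_that("regrouped cross-term posterior matches a direct Debye evaluation", {
  set.seed(31)
  grid <- q_grid(n_bins = 7)
  structs <- lapply(1:3, function(i) random_coarse_structure(25))
  curves <- lapply(1:3, function(i)
    scattering_curve(grid$q, runif(7, 1e3, 1e5)))
  train <- training_set(structs, curves, grid)
  m <- error_model()
  fvec <- runif(21, 0, 35)
  tab <- form_factor_table(matrix(fvec, 21, 7), bead_alphabet("two"), grid)
  for (bin in c(1L, 4L, 7L)) {
    direct <- 0
    for (i in 1:3) {
      Ip <- debye_intensity(structs[[i]], tab)$I[bin]
      sig <- curves[[i]]$I[bin] * (grid$q[bin] + m$alpha)^m$beta
      direct <- direct + dnorm(curves[[i]]$I[bin], Ip, sig, log = TRUE)
    }
    expect_equal(bin_log_posterior(fvec, bin, train, m), direct,
                 tolerance = 1e-10)
  }
})

test_that("proposal windows follow the truncated-uniform rule", {
  cfg <- mcmc_config(m = 1.5, f_max = 40)
  # interior: window [18.5, 21.5], width 3
  set.seed(2)
  for (rep in 1:50) {
    p <- propose_formfactor(rep(20, 4), cfg)
    expect_equal(p$log_q_forward, -log(3))
    expect_true(p$fvec[p$component] >= 18.5 && p$fvec[p$component] <= 21.5)
    # reverse probability evaluated at the proposed value's own window
    f2 <- p$fvec[p$component]
    expect_equal(p$log_q_reverse,
                 -log(min(40, f2 + 1.5) - max(0, f2 - 1.5)))
    expect_equal(sum(p$fvec != 20), 1L)  # exactly one component moved
  }
  # boundary: f = 0.5 -> window [0, 2], width 2 -> selection probability 1/2
  p <- propose_formfactor(c(0.5), cfg)
  expect_equal(p$log_q_forward, -log(2))
  # a proposed interior value f' = 1.9 would have window [0.4, 3.4], width 3
  expect_equal(-log(min(40, 1.9 + 1.5) - max(0, 1.9 - 1.5)), -log(3))
  # proposals always stay inside the box
  set.seed(3)
  v <- c(0.2, 39.9, 20)
  for (rep in 1:200) {
    v <- propose_formfactor(v, cfg)$fvec
    expect_true(all(v >= 0 & v <= 40))
  }
})

test_that("chains are seed-deterministic and respect the box", {
  train <- single_bead_train()
  cfg <- mcmc_config(iterations = 4000, burnin = 1000, thin = 3, seed = 77)
  a <- mh_sample_bin(1, train, config = cfg)
  b <- mh_sample_bin(1, train, config = cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$acceptance_rate, b$acceptance_rate)
  expect_true(all(a$samples >= 0 & a$samples <= 40))
  expect_equal(nrow(a$samples), 1000L)
})

test_that("a razor-sharp posterior triggers the low-acceptance warning", {
  # zero reference intensity floors sigma, collapsing the posterior
  train <- single_bead_train("BB", iref = 0)
  cfg <- mcmc_config(iterations = 3000, burnin = 500, thin = 5, seed = 1)
  expect_warning(mh_sample_bin(1, train, config = cfg), "acceptance rate")
})

test_that("medoid minimizes the summed Euclidean distance", {
  expect_equal(medoid(matrix(5, 1, 1)), 5, ignore_attr = TRUE)
  expect_equal(medoid(matrix(c(0, 1, 2), 3, 1)), 1, ignore_attr = TRUE)
  set.seed(13)
  x <- matrix(runif(200 * 6), 200, 6)
  d <- as.matrix(dist(x))
  expect_equal(medoid(x), x[which.min(rowSums(d)), ], ignore_attr = TRUE)
  expect_error(medoid(matrix(numeric(0), 0, 3)), "empty")
})

test_that("transition flow on a discretized 1-D toy target is balanced", {
  # single-bead posterior in 1 effective dimension, per-step states
  grid <- q_grid(n_bins = 1)
  st <- make_structure("ALA", matrix(0, 1, 3), granularity = "one")
  cv <- scattering_curve(grid$q, 500)
  train <- training_set(list(st), list(cv), grid)
  cfg <- mcmc_config(iterations = 110000, burnin = 5000, thin = 1, seed = 6)
  ss <- mh_sample_bin(1, train, config = cfg)
  comp <- ss$samples[, "ALA"]
  bins <- cut(comp, breaks = seq(0, 40, by = 2), labels = FALSE,
              include.lowest = TRUE)
  from <- bins[-length(bins)]
  to <- bins[-1]
  for (i in 1:19) {
    nij <- sum(from == i & to == i + 1)
    nji <- sum(from == i + 1 & to == i)
    tot <- nij + nji
    if (tot >= 20)
      expect_lt(abs(nij - nji), 3 * sqrt(tot) + 1)
  }
})

test_that("types absent from the training structures reproduce the box prior", {
  grid <- q_grid(n_bins = 1)
  st <- make_structure(c("BB", "BB", "LEU"),
                       rbind(c(0, 0, 0), c(6, 0, 0), c(3, 4, 0)))
  cv <- scattering_curve(grid$q, 1500)
  train <- training_set(list(st), list(cv), grid)
  cfg <- mcmc_config(iterations = 2e6, burnin = 1e5, thin = 200, seed = 10)
  ss <- mh_sample_bin(1, train, config = cfg)
  trp <- ss$samples[, "TRP"]  # absent from the structure
  # moments and histogram flatness of the U(0, 40) prior (the chain's
  # autocorrelation rules out a calibrated KS p-value at this budget; the
  # exactly-flat-posterior chain is KS-tested elsewhere with a long chain)
  expect_equal(mean(trp), 20, tolerance = 0.15)
  expect_equal(sd(trp), 40 / sqrt(12), tolerance = 0.15)
  h <- tabulate(cut(trp, seq(0, 40, by = 5), labels = FALSE), nbins = 8)
  expect_lt(max(abs(h / length(trp) - 1 / 8)), 0.04)
})

test_that("estimate_table is reproducible and independent of bin order", {
  grid <- q_grid(n_bins = 4)
  set.seed(15)
  structs <- lapply(1:3, function(i) random_coarse_structure(15))
  curves <- lapply(1:3, function(i)
    scattering_curve(grid$q, runif(4, 1e3, 1e4)))
  train <- training_set(structs, curves, grid)
  cfg <- mcmc_config(iterations = 8000, burnin = 2000, thin = 10, seed = 50)
  fit1 <- estimate_table(train, config = cfg)
  fit2 <- estimate_table(train, config = cfg)
  expect_identical(fit1$table$values, fit2$table$values)
  # bin 3 alone, with the derived per-bin seed, reproduces the table column
  ss <- mh_sample_bin(3, train, config = mcmc_config(
    iterations = 8000, burnin = 2000, thin = 10, seed = 52))
  expect_identical(unname(fit1$table$values[, 3]), unname(medoid(ss)))
  expect_named(fit1$diagnostics, c("bin", "q", "acceptance_rate",
                                   "mean_sample_sd"))
})
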