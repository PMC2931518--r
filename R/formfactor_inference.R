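#' MCMC configuration for form-factor sampling
#'
#' @param f_max Upper bound of the box prior on each form-factor component
#'   (default 40, well beyond plausible dummy-atom factors).
#' @param m Half-width of the truncated-uniform component proposal
#'   (default 1.5).
#' @param iterations Total chain length per bin.
#' @param burnin Iterations discarded before recording.
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param seed Optional integer seed; per-bin chains derive their own seed
#'   as `seed + bin - 1`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(f_max = 40, m = 1.5, iterations = 120000L,
                        burnin = 20000L, thin = 50L, seed = NULL) {
  stopifnot(f_max > 0, m > 0, m <= f_max, iterations > burnin, burnin >= 0,
            thin >= 1)
  structure(list(f_max = f_max, m = m, iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mcmc_config")
}

#' Training set of structures with reference curves
#'
#' Pairs each coarse-grained structure with its reference intensity curve
#' on a common q-grid, and precomputes the per-structure type-pair cross
#' terms G_tu(q) so that a curve evaluation during sampling costs O(L^2) in
#' the number of bead types.
#'
#' @param structures List of `coarse_structure` objects, all of the same
#'   granularity.
#' @param curves List of matching reference `saxs_curve`s on one shared grid.
#' @param grid The common [q_grid()].
#' @return An object of class `training_set`.
#' @export
training_set <- function(structures, curves, grid = q_grid()) {
  stopifnot(length(structures) == length(curves), length(structures) >= 1L)
  gran <- unique(vapply(structures, function(s) s$granularity, ""))
  if (length(gran) != 1L) stop("all structures must share one granularity")
  for (cv in curves) {
    if (!grids_match(cv$q, grid$q)) stop("all curves must share the q grid")
    if (any(cv$I < 0)) stop("reference intensities must be nonnegative")
  }
  alphabet <- bead_alphabet(gran)
  cross <- lapply(structures, structure_cross_terms, alphabet = alphabet,
                  grid = grid)
  iref <- do.call(rbind, lapply(curves, function(cv) cv$I))  # N x Q
  structure(list(structures = structures, curves = curves, grid = grid,
                 alphabet = alphabet, cross_terms = cross, iref = iref,
                 n = length(structures)),
            class = "training_set")
}

# per-structure model sigmas at one bin (from the reference intensities)
bin_sigmas <- function(train, bin, model) {
  I <- train$iref[, bin]
  sigma_values(train$grid$q[bin], I, model,
               floor_eps = 1e-12 * max(train$iref, 1e-300))
}

#' Log-posterior of a form-factor vector at one q-bin
#'
#' Product-of-Gaussians likelihood over the training structures with a
#' uniform box prior on `[0, f_max]^L`:
#' \deqn{\log P(\bar F_q \mid \cdot) = \sum_i \log N(I_{q,i} \mid
#'   I'_{q,i}(\bar F_q, X_i), \sigma_{q,i}) + const}
#' where sigma_{q,i} comes from structure i's own reference intensity via
#' the error model. Returns `-Inf` outside the box.
#'
#' @param fvec Form-factor vector, one component per alphabet label.
#' @param bin q-bin index (1-based).
#' @param train A [training_set()].
#' @param model An [error_model()].
#' @param f_max Box-prior upper bound.
#' @return Scalar log-posterior (up to the prior's constant).
#' @export
bin_log_posterior <- function(fvec, bin, train, model = error_model(),
                              f_max = 40) {
  stopifnot(inherits(train, "training_set"))
  bin <- as.integer(bin)
  if (bin < 1L || bin > train$grid$n_bins) stop("bin index out of range")
  L <- length(train$alphabet$labels)
  if (length(fvec) != L) stop("fvec must have one component per bead label")
  if (any(fvec < 0) || any(fvec > f_max)) return(-Inf)
  sig <- bin_sigmas(train, bin, model)
  lp <- 0
  for (i in seq_len(train$n)) {
    G <- train$cross_terms[[i]][[bin]]
    Iprime <- as.numeric(fvec %*% G %*% fvec)
    lp <- lp + stats::dnorm(train$iref[i, bin], mean = Iprime, sd = sig[i],
                            log = TRUE)
  }
  lp
}

#' Truncated-uniform single-component proposal
#'
#' Re-samples one randomly chosen component f of the vector uniformly from
#' `[max(0, f - m), min(f_max, f + m)]`. The selection probability is the
#' reciprocal window width, evaluated at the current value (forward) and at
#' the proposed value (reverse) so that border effects respect detailed
#' balance.
#'
#' @param fvec Current form-factor vector (inside the box).
#' @param config An [mcmc_config()] providing `m` and `f_max`.
#' @return List with `fvec` (proposed vector), `component` (index changed),
#'   `log_q_forward` and `log_q_reverse` (log selection probabilities).
#' @export
propose_formfactor <- function(fvec, config = mcmc_config()) {
  stopifnot(all(fvec >= 0), all(fvec <= config$f_max))
  t <- sample.int(length(fvec), 1L)
  f <- fvec[t]
  lo <- max(0, f - config$m); hi <- min(config$f_max, f + config$m)
  fnew <- stats::runif(1L, lo, hi)
  lo2 <- max(0, fnew - config$m); hi2 <- min(config$f_max, fnew + config$m)
  out <- fvec
  out[t] <- fnew
  list(fvec = out, component = t,
       log_q_forward = -log(hi - lo), log_q_reverse = -log(hi2 - lo2))
}

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Metropolis-Hastings sampling of one q-bin's form-factor vector
#'
#' Runs a Metropolis-Hastings chain on the bin posterior of
#' [bin_log_posterior()] using the truncated-uniform component proposal and
#' the acceptance probability
#' `min(1, P(F')Q(F' -> F) / (P(F)Q(F -> F')))`. The chain is initialized
#' by sampling each component uniformly on `[0, f_max]` and is deterministic
#' given `config$seed`.
#'
#' @inheritParams bin_log_posterior
#' @param config An [mcmc_config()].
#' @return An object of class `sample_set`: list with `bin`, `samples`
#'   (matrix, one row per kept draw, one column per label) and
#'   `acceptance_rate`. A warning is raised if the acceptance rate falls
#'   below 1 percent.
#' @export
mh_sample_bin <- function(bin, train, model = error_model(),
                          config = mcmc_config()) {
  stopifnot(inherits(train, "training_set"), inherits(config, "mcmc_config"))
  bin <- as.integer(bin)
  if (bin < 1L || bin > train$grid$n_bins) stop("bin index out of range")
  L <- length(train$alphabet$labels)
  sig <- bin_sigmas(train, bin, model)
  glist <- lapply(train$cross_terms, function(ct) ct[[bin]])
  res <- with_local_seed(config$seed, {
    init <- stats::runif(L, 0, config$f_max)
    cpp_mh_chain(glist, train$iref[, bin], sig, init, config$f_max, config$m,
                 config$iterations, config$burnin, config$thin)
  })
  if (res$acceptance_rate < 0.01)
    warning(sprintf("bin %d: acceptance rate %.2f%% is below 1%%", bin,
                    100 * res$acceptance_rate))
  colnames(res$samples) <- train$alphabet$labels
  structure(list(bin = bin, samples = res$samples,
                 acceptance_rate = res$acceptance_rate),
            class = "sample_set")
}

#' Medoid of a sample set
#'
#' The sampled vector with the lowest summed Euclidean distance to all
#' other sampled vectors (the point estimate used for each q-bin); ties are
#' broken by the first index.
#'
#' @param samples A `sample_set`, or a numeric matrix with one sample per
#'   row.
#' @return The medoid vector.
#' @export
medoid <- function(samples) {
  x <- if (inherits(samples, "sample_set")) samples$samples else as.matrix(samples)
  if (nrow(x) < 1L) stop("empty sample set")
  x[cpp_medoid(x), ]
}

#' Estimate the full form-factor table
#'
#' Samples the posterior of every q-bin independently (per-bin seeds
#' `seed + bin - 1`, so results do not depend on execution order) and
#' assembles the per-bin medoids into a form-factor table.
#'
#' @param train A [training_set()].
#' @param model An [error_model()].
#' @param config An [mcmc_config()]; its `seed` governs all bins.
#' @param keep_samples Keep the per-bin `sample_set`s in the result
#'   (memory permitting)? Default `FALSE`.
#' @return List with `table` (an `fftable`), `diagnostics` (data frame with
#'   per-bin acceptance rate and mean per-component sample sd) and, when
#'   requested, `sample_sets`.
#' @export
estimate_table <- function(train, model = error_model(),
                           config = mcmc_config(), keep_samples = FALSE) {
  stopifnot(inherits(train, "training_set"))
  nb <- train$grid$n_bins
  L <- length(train$alphabet$labels)
  values <- matrix(NA_real_, L, nb)
  acc <- numeric(nb)
  spread <- numeric(nb)
  sets <- if (keep_samples) vector("list", nb) else NULL
  for (bin in seq_len(nb)) {
    cfg_bin <- config
    if (!is.null(config$seed)) cfg_bin$seed <- config$seed + bin - 1L
    ss <- mh_sample_bin(bin, train, model, cfg_bin)
    values[, bin] <- medoid(ss)
    acc[bin] <- ss$acceptance_rate
    spread[bin] <- mean(apply(ss$samples, 2L, stats::sd))
    if (keep_samples) sets[[bin]] <- ss
  }
  table <- form_factor_table(values, train$alphabet, train$grid,
                             f_max = config$f_max)
  diagnostics <- data.frame(bin = seq_len(nb), q = train$grid$q,
                            acceptance_rate = acc, mean_sample_sd = spread)
  out <- list(table = table, diagnostics = diagnostics)
  if (keep_samples) out$sample_sets <- sets
  out
}
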