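# Mismatch distributions and the Rogers-Harpending sudden-expansion model.
#
# Model: a population at scaled size theta0 grew instantaneously to theta1
# at tau/2 units of per-lineage mutational time ago (tau = 2*u*t is the
# pair-divergence clock). The distribution of pairwise difference counts
# has the closed form
#   F(i) = G(i, theta1) * P[Gamma(i+1, rate=(1+theta1)/theta1) <= tau]
#        + exp(-tau/theta1) * sum_j Pois(i-j; tau) * G(j, theta0)
# where G(i, theta) = theta^i / (1+theta)^(i+1) is the equilibrium
# geometric, obtained by conditioning on whether the pair coalesced before
# or after the expansion. At tau = 0 (or theta0 = theta1) it reduces to the
# equilibrium geometric exactly.

THETA1_CAP <- 99999

#' Observed mismatch distribution
#'
#' Relative frequencies of pairwise difference counts (classes `0..max`)
#' over all `n(n-1)/2` pairs, on included (complete-deletion) sites.
#'
#' @param aln A `coi_alignment` with `n >= 2` sequences.
#' @return Numeric vector of frequencies; names are the difference classes
#'   starting at 0.
#' @export
mismatch_histogram <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  n <- length(aln$ids)
  if (n < 2) stop("mismatch distribution needs n >= 2")
  inc <- included_sites(aln)
  d <- pairdiff_matrix(aln$seqs[, inc, drop = FALSE])
  diffs <- d[upper.tri(d)]
  tab <- tabulate(diffs + 1L, max(diffs) + 1L)
  stats::setNames(tab / sum(tab), 0:max(diffs))
}

# equilibrium geometric mismatch term
geom_mismatch <- function(i, theta) {
  if (theta <= 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' @param tau Expansion age in mutational units (>= 0).
#' @param theta0 Pre-expansion scaled size (>= 0).
#' @param theta1 Post-expansion scaled size (>= 0).
#' @param classes Difference classes to evaluate (default `0:50`).
#' @return Numeric vector of expected frequencies `F(i)` for `i` in
#'   `classes` (sums to 1 over the full infinite support).
#' @export
expected_mismatch <- function(tau, theta0, theta1, classes = 0:50) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0)
  imax <- max(classes)
  i <- 0:imax
  g1 <- geom_mismatch(i, theta1)
  g0 <- geom_mismatch(i, theta0)
  recent <- if (theta1 > 0) {
    g1 * stats::pgamma(tau, shape = i + 1, rate = (1 + theta1) / theta1)
  } else rep(0, imax + 1L)
  surv <- if (theta1 > 0) exp(-tau / theta1) else as.numeric(tau == 0)
  pois <- stats::dpois(i, tau)
  old <- vapply(i, function(ii) {
    sum(pois[seq_len(ii + 1L)] * g0[(ii + 1L):1L])
  }, numeric(1L))
  (recent + surv * old)[classes + 1L]
}

sum_sq_dev <- function(obs, tau, theta0, theta1) {
  classes <- seq_along(obs) - 1L
  # optimizers may probe marginally outside their boxes when taking
  # finite-difference gradients; clamp to the model's domain
  sum((obs - expected_mismatch(max(tau, 0), max(theta0, 0),
                               max(theta1, 0), classes))^2)
}

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Minimizes the sum of squared deviations `SSD` between observed and
#' expected class frequencies over `(tau, theta0, theta1)` by a coarse grid
#' search followed by box-constrained local refinement. `theta1` is capped
#' at 99,999 (and reported at the cap when effectively unbounded), `theta0`
#' is floored at 0, and `theta0 <= theta1` is enforced.
#'
#' @param observed Observed mismatch frequency vector (classes `0..max`,
#'   sums to 1), e.g. from [mismatch_histogram()].
#' @param theta1_cap Upper bound for `theta1` (default 99,999).
#' @return A `coi_mismatchfit`: list with `tau`, `theta0`, `theta1`, `SSD`,
#'   `observed`, `expected`.
#' @export
fit_sudden_expansion <- function(observed, theta1_cap = THETA1_CAP) {
  stopifnot(is.numeric(observed), all(observed >= 0))
  if (abs(sum(observed) - 1) > 1e-6) stop("observed must sum to 1")
  classes <- seq_along(observed) - 1L
  if (sum(observed > 0) <= 1L) {
    warning("degenerate mismatch distribution (single class): tau = 0 fit")
    fit <- list(tau = 0, theta0 = 0, theta1 = 0,
                SSD = sum_sq_dev(observed, 0, 0, 0))
    return(structure(c(fit, list(
      observed = observed,
      expected = expected_mismatch(0, 0, 0, classes))),
      class = "coi_mismatchfit"))
  }
  mean_d <- sum(classes * observed)
  dmax <- max(classes)
  grid_tau <- seq(0, 2 * dmax, length.out = 25)
  grid_t0 <- unique(c(0, mean_d / 4, mean_d / 2, mean_d))
  grid_t1 <- unique(c(0.5, 1, 2, 5, 10, 25, 50, 100, 1000, theta1_cap))
  best <- NULL
  for (tau in grid_tau) for (t0 in grid_t0) for (t1 in grid_t1) {
    if (t0 > t1) next
    ssd <- sum_sq_dev(observed, tau, t0, t1)
    if (is.null(best) || ssd < best$SSD) {
      best <- list(tau = tau, theta0 = t0, theta1 = t1, SSD = ssd)
    }
  }
  obj <- function(par) {
    if (par[2] > par[3]) return(1e6)
    sum_sq_dev(observed, par[1], par[2], par[3])
  }
  opt <- stats::optim(c(best$tau, best$theta0, best$theta1), obj,
                      method = "L-BFGS-B",
                      lower = c(0, 0, 1e-6),
                      upper = c(4 * dmax, theta1_cap, theta1_cap),
                      control = list(factr = 10))
  # polish with Nelder-Mead from the box optimum (flat theta1 surfaces)
  opt2 <- stats::optim(opt$par, function(p) {
    if (any(p < 0) || p[3] > theta1_cap || p[2] > p[3]) return(1e6)
    sum_sq_dev(observed, p[1], p[2], p[3])
  }, control = list(reltol = 1e-12, maxit = 2000))
  par <- if (opt2$value <= opt$value) opt2$par else opt$par
  ssd <- min(opt2$value, opt$value)
  if (par[3] > 0.95 * theta1_cap) par[3] <- theta1_cap
  structure(list(tau = par[1], theta0 = max(par[2], 0), theta1 = par[3],
                 SSD = ssd, observed = observed,
                 expected = expected_mismatch(par[1], max(par[2], 0),
                                              par[3], classes)),
            class = "coi_mismatchfit")
}

#' @export
print.coi_mismatchfit <- function(x, ...) {
  cat(sprintf("<coi_mismatchfit> tau=%.3f theta0=%.3f theta1=%.3f SSD=%.5f\n",
              x$tau, x$theta0, x$theta1, x$SSD))
  invisible(x)
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the occupied class range
#' with one zero-padded class beyond the largest observed difference.
#'
#' @param observed Mismatch frequency vector (classes `0..d`).
#' @return The raggedness index.
#' @export
harpending_raggedness <- function(observed) {
  x <- c(observed, 0)
  sum(diff(x)^2)
}

#' Parametric-bootstrap goodness of fit for the sudden-expansion model
#'
#' Coalescent samples of size `n` are simulated under the fitted expansion
#' (recent scaled size `theta1`, size `theta0` before `tau`), the model is
#' refitted to each simulated mismatch distribution, and p-values are the
#' fraction of simulated statistics at least as large as the observed ones
#' (for both SSD and the raggedness index).
#'
#' @param observed Observed mismatch frequency vector.
#' @param fit A `coi_mismatchfit` for `observed`.
#' @param n Sample size behind `observed`.
#' @param reps Bootstrap replicates (>= 100; default 1000).
#' @param seed Optional integer seed.
#' @return List with `SSD`, `SSD_p`, `HRI`, `HRI_p`.
#' @export
goodness_of_fit <- function(observed, fit, n, reps = 1000, seed = NULL) {
  stopifnot(inherits(fit, "coi_mismatchfit"))
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  hri_obs <- harpending_raggedness(observed)
  ssd_sim <- numeric(reps)
  hri_sim <- numeric(reps)
  for (r in seq_len(reps)) {
    hist_r <- simulate_mismatch(n, fit$tau, fit$theta0, fit$theta1)
    f <- suppressWarnings(fit_sudden_expansion(hist_r))
    ssd_sim[r] <- f$SSD
    hri_sim[r] <- harpending_raggedness(hist_r)
  }
  list(SSD = fit$SSD, SSD_p = mean(ssd_sim >= fit$SSD),
       HRI = hri_obs, HRI_p = mean(hri_sim >= hri_obs))
}

# one coalescent sample under the sudden-expansion model, returned as a
# mismatch frequency vector. Engine time is in units where a pair
# coalesces at rate 1/sigma; mutational pair-time tau corresponds to
# engine time tau/theta1 with branch mutation rate theta1/2.
simulate_mismatch <- function(n, tau, theta0, theta1) {
  theta1 <- max(theta1, 1e-6)
  fold <- theta1 / max(theta0, 1e-4)
  g <- sim_genealogy(n, expansion = list(time = tau / theta1, fold = fold))
  m <- branch_mutations(g, theta = theta1)
  d <- genealogy_pairdiffs(g, m)
  diffs <- d[upper.tri(d)]
  tab <- tabulate(diffs + 1L, max(diffs) + 1L)
  stats::setNames(tab / sum(tab), 0:max(diffs))
}

#' Mutational clock for expansion-time conversion
#'
#' `mu` is the per-sequence, per-generation mutation rate:
#' `generation_time * sites * rate_per_site_per_year`.
#'
#' @param rate_per_site_per_year Substitution rate per site per year
#'   (default `1.4e-8`, i.e. 1.4% per million years, a standard arthropod
#'   COI clock).
#' @param generation_time_years Generation time in years (default 1.5).
#' @param sites Locus length in base pairs (default 674).
#' @return A `coi_clock` list with the three fields plus `mu`.
#' @export
mutation_clock <- function(rate_per_site_per_year = 1.4e-8,
                           generation_time_years = 1.5,
                           sites = 674) {
  if (rate_per_site_per_year <= 0 || generation_time_years <= 0 ||
      sites <= 0) {
    stop("all clock fields must be strictly positive")
  }
  structure(list(rate_per_site_per_year = rate_per_site_per_year,
                 generation_time_years = generation_time_years,
                 sites = sites,
                 mu = generation_time_years * sites *
                   rate_per_site_per_year),
            class = "coi_clock")
}

#' Convert a fitted tau to an expansion time
#'
#' `T = tau / (2 * mu)` with `mu` from [mutation_clock()]; reported in
#' years and millions of years (Ma).
#'
#' @param tau Expansion age in mutational units (>= 0).
#' @param clock A `coi_clock`.
#' @return List with `t_years` and `t_Ma`.
#' @export
expansion_time <- function(tau, clock = mutation_clock()) {
  stopifnot(inherits(clock, "coi_clock"))
  if (tau < 0) stop("tau must be >= 0")
  t <- tau / (2 * clock$mu)
  list(t_years = t, t_Ma = t / 1e6)
}

#' Mismatch analysis table for every population (plus pooled)
#'
#' @param aln A `coi_alignment`.
#' @param pm A `coi_popmap`.
#' @param clock A `coi_clock` for expansion-time conversion.
#' @param reps Bootstrap replicates for goodness of fit.
#' @param seed Integer seed.
#' @param pooled_label Label for the pooled row.
#' @return List with `table` (data.frame: Population, tau, theta0, theta1,
#'   SSD, SSD_p, HRI, HRI_p, t_years, t_Ma) and `histograms` (named list
#'   of observed/expected vectors per population).
#' @export
mismatch_table <- function(aln, pm, clock = mutation_clock(),
                           reps = 1000, seed = 1,
                           pooled_label = "Pooled") {
  pops <- pop_labels(aln, pm)
  set.seed(seed)
  hists <- list()
  one <- function(sub, label) {
    obs <- mismatch_histogram(sub)
    fit <- suppressWarnings(fit_sudden_expansion(obs))
    gof <- goodness_of_fit(obs, fit, n = length(sub$ids), reps = reps)
    tt <- expansion_time(fit$tau, clock)
    hists[[label]] <<- list(observed = obs, expected = fit$expected)
    data.frame(Population = label, tau = fit$tau, theta0 = fit$theta0,
               theta1 = fit$theta1, SSD = gof$SSD, SSD_p = gof$SSD_p,
               HRI = gof$HRI, HRI_p = gof$HRI_p,
               t_years = tt$t_years, t_Ma = tt$t_Ma,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(unique(pops), function(p) {
    one(subset_alignment(aln, pops == p), p)
  })
  tab <- rbind(do.call(rbind, rows), one(aln, pooled_label))
  list(table = tab, histograms = hists)
}
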