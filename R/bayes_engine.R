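## log offspring-cell probabilities for a matrix of parameter points;
## columns follow the 11-cell flat order of .cell_index
## (ABxAA: AA,AB | ABxBB: AB,BB | AAxAB: AA,AB | BBxAB: AB,BB | ABxAB: AA,AB,BB)
.logp_cells <- function(model, theta) {
  theta <- as.matrix(theta)
  n <- nrow(theta)
  if (model == "null") {
    return(matrix(rep(log(c(.5, .5, .5, .5, .5, .5, .5, .5, .25, .5, .25)), each = n), n))
  }
  if (model %in% c("allelic_overall", "allelic_parent_specific")) {
    ps <- 0.5 + theta[, 1]
    pd <- 0.5 + theta[, if (model == "allelic_overall") 1 else 2]
    return(cbind(log(ps), log(1 - ps), log(ps), log(1 - ps),
                 log(pd), log(1 - pd), log(pd), log(1 - pd),
                 log(ps * pd), log(ps * (1 - pd) + (1 - ps) * pd),
                 log((1 - ps) * (1 - pd))))
  }
  if (model == "genotypic") {
    a <- theta[, 1]; d <- theta[, 2]
    A <- 1 + a - d; B <- 1 + d; C <- 1 - a - d
    A[A < 0] <- 0; B[B < 0] <- 0; C[C < 0] <- 0
    za <- 2 * (1 + a / 2); zb <- 2 * (1 - a / 2)
    return(cbind(log(A / za), log(B / za), log(B / zb), log(C / zb),
                 log(A / za), log(B / za), log(B / zb), log(C / zb),
                 log(A / 4), log(B / 2), log(C / 4)))
  }
  stop("unknown model: ", model)
}

## parameter grids with trapezoid quadrature weights, cached per
## (model, resolution); prior is flat over the model's space, normalized
.grid_cache <- new.env(parent = emptyenv())

.model_grid <- function(model, resolution) {
  key <- paste(model, resolution)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  trap_w <- function(x) {
    h <- diff(x)
    c(h[1] / 2, (h[-1] + h[-length(h)]) / 2, h[length(h)] / 2)
  }
  if (model == "null") {
    g <- list(theta = matrix(0, 1, 0), prior_w = 1, param_names = character())
  } else if (model == "allelic_overall") {
    x <- seq(-0.5, 0.5, length.out = resolution)
    g <- list(theta = matrix(x, ncol = 1, dimnames = list(NULL, "alpha")),
              prior_w = trap_w(x), param_names = "alpha")
  } else if (model == "allelic_parent_specific") {
    x <- seq(-0.5, 0.5, length.out = resolution)
    th <- as.matrix(expand.grid(alpha_s = x, alpha_d = x))
    g <- list(theta = th, prior_w = as.vector(outer(trap_w(x), trap_w(x))),
              param_names = c("alpha_s", "alpha_d"))
  } else if (model == "genotypic") {
    x <- seq(-1, 1, length.out = resolution)
    th <- as.matrix(expand.grid(alpha_g = x, delta_g = x))
    w <- as.vector(outer(trap_w(x), trap_w(x)))
    keep <- genotypic_valid(th[, 1], th[, 2])
    th <- th[keep, , drop = FALSE]
    w <- w[keep]
    g <- list(theta = th, prior_w = w, param_names = c("alpha_g", "delta_g"))
  } else stop("unknown model: ", model)
  g$prior_w <- g$prior_w / sum(g$prior_w)
  g$logp <- .logp_cells(model, g$theta)
  .grid_cache[[key]] <- g
  g
}

.counts_vector <- function(counts) unclass(counts)[.cell_index]

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Deterministic grid posterior for a TRD model
#'
#' Reference inference path: the flat prior over the model's parametric space
#' is discretized on a regular grid with trapezoid quadrature weights, the
#' multinomial likelihood is evaluated at every admissible point, and the
#' marginal likelihood, posterior masses and posterior summaries follow by
#' quadrature. Deterministic for fixed inputs; the MCMC sampler
#' ([run_mcmc()]) is checked against it.
#'
#' @param counts a [mating_counts()] table.
#' @param model one of `"allelic_overall"`, `"allelic_parent_specific"`,
#'   `"genotypic"` (or `"null"`, which has an empty grid).
#' @param resolution grid points per dimension (>= 101; use >= 1001 for
#'   3-significant-digit marginal likelihoods).
#' @return A `grid_posterior`: grid `theta`, normalized `prior_w`, `log_lik`
#'   per point, `log_marginal`, posterior masses `post_mass`.
#' @export
grid_fit <- function(counts, model, resolution = 201) {
  stopifnot(model == "null" || resolution >= 101)
  g <- .model_grid(model, resolution)
  n <- .counts_vector(counts)
  nz <- n > 0
  log_lik <- if (any(nz)) drop(g$logp[, nz, drop = FALSE] %*% n[nz]) else
    rep(0, nrow(g$theta))
  log_joint <- log_lik + log(g$prior_w)
  log_marg <- .logsumexp(log_joint)
  post <- exp(log_joint - log_marg)
  post <- post / sum(post)
  structure(list(model = model, theta = g$theta, prior_w = g$prior_w,
                 log_lik = log_lik, log_marginal = log_marg, post_mass = post,
                 resolution = resolution, param_names = g$param_names),
            class = "grid_posterior")
}

#' Posterior summaries of a fit
#'
#' Mean, sd, median, equal-tailed 95% credible interval and coefficient of
#' variation (`sd / |mean|`, `Inf` when the mean is 0) per parameter.
#'
#' @param fit a `grid_posterior` from [grid_fit()] or `mcmc_chain` from
#'   [run_mcmc()].
#' @param level credible-interval mass (default 0.95).
#' @return data.frame with one row per parameter: `param`, `mean`, `sd`,
#'   `median`, `lower`, `upper`, `cv`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  lo_p <- (1 - level) / 2
  if (inherits(fit, "grid_posterior")) {
    theta <- fit$theta
    w <- fit$post_mass
    rows <- lapply(seq_along(fit$param_names), function(j) {
      ## exact marginal over the 1-D axis (grid values repeat across the
      ## other dimension)
      xs <- sort(unique(theta[, j]))
      mj <- rowsum(w, group = match(theta[, j], xs), reorder = TRUE)[, 1]
      m <- sum(mj * xs)
      s <- sqrt(max(0, sum(mj * (xs - m)^2)))
      cw <- cumsum(mj)
      qfun <- function(q) xs[min(length(xs), findInterval(q, cw) + 1L)]
      data.frame(param = fit$param_names[j], mean = m, sd = s,
                 median = qfun(0.5), lower = qfun(lo_p),
                 upper = qfun(1 - lo_p),
                 cv = if (m == 0) Inf else s / abs(m))
    })
  } else {
    sm <- fit$samples
    rows <- lapply(colnames(sm), function(nm) {
      x <- sm[, nm]
      m <- mean(x)
      data.frame(param = nm, mean = m, sd = stats::sd(x),
                 median = stats::median(x),
                 lower = unname(stats::quantile(x, lo_p)),
                 upper = unname(stats::quantile(x, 1 - lo_p)),
                 cv = if (m == 0) Inf else stats::sd(x) / abs(m))
    })
  }
  do.call(rbind, rows)
}

#' Bayes factor of a TRD model against the Mendelian point null
#'
#' `BF = m(y) / p(y | theta = 0)`: the model's marginal likelihood over the
#' likelihood at the Mendelian point (which has no free parameters). Under a
#' flat prior this equals the Savage-Dickey density ratio at the null point
#' (see [savage_dickey_bf()]). `BF >= 100` is decisive on Jeffreys' scale.
#'
#' @param counts a [mating_counts()] table.
#' @param fit a `grid_posterior` for the model (or the model name, in which
#'   case a grid fit at `resolution` is computed).
#' @param resolution grid resolution when `fit` is a model name.
#' @return the Bayes factor (`Inf` when the null likelihood is 0 with
#'   nonzero-likelihood data).
#' @export
bayes_factor <- function(counts, fit, resolution = 201) {
  if (is.character(fit)) fit <- grid_fit(counts, fit, resolution)
  ll0 <- trd_loglik(counts, "null")
  if (!is.finite(ll0)) {
    return(if (is.finite(fit$log_marginal)) Inf else NaN)
  }
  exp(fit$log_marginal - ll0)
}

#' Savage-Dickey Bayes factor estimate
#'
#' Cross-check of [bayes_factor()]: the prior-to-posterior density ratio at
#' the null point, with the posterior density at 0 estimated by a local
#' quadratic fit to the log posterior density over grid cells near the null
#' (a numerically different route than the marginal-likelihood quadrature).
#'
#' @param fit a `grid_posterior`.
#' @param halfwidth number of grid cells around the null used in the local
#'   fit (default 5 per side).
#' @return Bayes-factor estimate.
#' @export
savage_dickey_bf <- function(fit, halfwidth = 5) {
  d <- length(fit$param_names)
  stopifnot(d >= 1)
  theta <- fit$theta
  ## cell spacing per dimension
  h <- vapply(seq_len(d), function(j) min(diff(sort(unique(theta[, j])))), numeric(1))
  near <- rep(TRUE, nrow(theta))
  for (j in seq_len(d)) near <- near & abs(theta[, j]) <= halfwidth * h[j] + 1e-12
  dens_post <- fit$post_mass[near] / prod(h)
  dens_prior <- fit$prior_w[near] / prod(h)
  df <- data.frame(lg = log(pmax(dens_post, 1e-300)))
  for (j in seq_len(d)) {
    df[[paste0("x", j)]] <- theta[near, j]
  }
  terms <- unlist(lapply(seq_len(d), function(j) {
    c(paste0("x", j), paste0("I(x", j, "^2)"))
  }))
  if (d == 2) terms <- c(terms, "I(x1 * x2)")
  form <- stats::as.formula(paste("lg ~", paste(terms, collapse = " + ")))
  fit0 <- stats::lm(form, data = df)
  nd <- as.data.frame(as.list(stats::setNames(rep(0, d), paste0("x", seq_len(d)))))
  post0 <- exp(unname(stats::predict(fit0, nd)))
  ## flat prior: density at 0 from the same local cells (constant inside space)
  prior0 <- mean(dens_prior)
  prior0 / post0
}

#' Random-walk Metropolis sampler for a TRD model
#'
#' Adaptive Gaussian random-walk Metropolis on the identity scale: the step
#' size is tuned toward a 30% acceptance rate during burn-in, proposals are
#' reflected at the box bounds of the parameter space and (genotypic model)
#' rejected outside the admissible simplex via the flat prior. A single
#' chain; defaults mirror the scan protocol (110,000 iterations, 10,000
#' burn-in).
#'
#' @param counts a [mating_counts()] table.
#' @param model TRD model name.
#' @param iterations,burn_in chain length and discarded prefix.
#' @param seed integer seed (chains with the same seed are identical).
#' @param start optional start point (defaults to the null point).
#' @return An `mcmc_chain`: post-burn-in `samples`, `acceptance_rate`,
#'   `n_effective` per parameter.
#' @export
run_mcmc <- function(counts, model, iterations = 110000, burn_in = 10000,
                     seed = NULL, start = NULL) {
  stopifnot(iterations > burn_in)
  if (!is.null(seed)) set.seed(seed)
  bounds <- switch(model,
    allelic_overall = cbind(-0.5, 0.5),
    allelic_parent_specific = cbind(c(-0.5, -0.5), c(0.5, 0.5)),
    genotypic = cbind(c(-1, -1), c(1, 1)),
    stop("no free parameters to sample for model ", model))
  d <- nrow(bounds)
  pnames <- switch(model, allelic_overall = "alpha",
                   allelic_parent_specific = c("alpha_s", "alpha_d"),
                   genotypic = c("alpha_g", "delta_g"))
  n_cells <- .counts_vector(counts)
  nz <- n_cells > 0
  loglik <- function(th) {
    if (model == "genotypic" && !genotypic_valid(th[1], th[2])) return(-Inf)
    lp <- .logp_cells(model, matrix(th, 1))
    sum(lp[nz] * n_cells[nz])
  }
  reflect <- function(x, lo, hi) {
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    lo + ifelse(y > span, 2 * span - y, y)
  }
  cur <- start %||% rep(0, d)
  cur_ll <- loglik(cur)
  step <- rep(0.1, d)
  out <- matrix(NA_real_, iterations - burn_in, d, dimnames = list(NULL, pnames))
  acc_post <- 0L
  acc_win <- 0L
  for (i in seq_len(iterations)) {
    prop <- reflect(cur + stats::rnorm(d, 0, step), bounds[, 1], bounds[, 2])
    prop_ll <- loglik(prop)
    if (log(stats::runif(1)) < prop_ll - cur_ll) {
      cur <- prop
      cur_ll <- prop_ll
      acc_win <- acc_win + 1L
      if (i > burn_in) acc_post <- acc_post + 1L
    } else if (i > burn_in) NULL
    if (i <= burn_in && i %% 100 == 0) {
      rate <- acc_win / 100
      step <- step * exp(rate - 0.3)
      acc_win <- 0L
    }
    if (i > burn_in) out[i - burn_in, ] <- cur
  }
  rate <- acc_post / (iterations - burn_in)
  if (rate < 0.05 || rate > 0.95) {
    warning("MCMC acceptance rate ", round(rate, 3), " outside [0.05, 0.95]")
  }
  ess <- apply(out, 2, function(x) {
    v <- stats::var(x)
    if (v == 0) return(length(x))
    ac <- stats::acf(x, lag.max = min(1000, length(x) - 1), plot = FALSE)$acf[-1]
    pos <- which(ac < 0)[1]
    if (!is.na(pos)) ac <- ac[seq_len(pos - 1)]
    length(x) / (1 + 2 * sum(ac))
  })
  structure(list(model = model, samples = out, acceptance_rate = rate,
                 n_effective = ess), class = "mcmc_chain")
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `D(theta) = -2 log p(y | theta)`, `Dbar` the
#' posterior expectation of `D` and `pD = Dbar - D(posterior mean)`
#' (Spiegelhalter's form). The multinomial constant is omitted consistently
#' across models, so DIC *differences* are exact. For the null model (no
#' parameters) `DIC = D(null)` with `pD = 0`.
#'
#' @param counts a [mating_counts()] table.
#' @param model model name.
#' @param fit a `grid_posterior` or `mcmc_chain`; ignored for `"null"`.
#' @return the DIC value.
#' @export
dic <- function(counts, model, fit = NULL) {
  if (model == "null") return(-2 * trd_loglik(counts, "null"))
  stopifnot(!is.null(fit))
  if (inherits(fit, "grid_posterior")) {
    w <- fit$post_mass
    keep <- w > 0
    dbar <- sum(w[keep] * (-2 * fit$log_lik[keep]))
    theta_bar <- colSums(fit$theta * w)
  } else {
    n_cells <- .counts_vector(counts)
    nz <- n_cells > 0
    lp <- .logp_cells(model, fit$samples)
    ll <- drop(lp[, nz, drop = FALSE] %*% n_cells[nz])
    dbar <- mean(-2 * ll)
    theta_bar <- colMeans(fit$samples)
  }
  d_at_mean <- -2 * trd_loglik(counts, model, theta_bar)
  if (!is.finite(d_at_mean)) stop("posterior mean outside the parametric space")
  pd <- dbar - d_at_mean
  dbar + pd
}

#' Select among fitted TRD models by DIC
#'
#' The minimum-DIC model wins; differences smaller than 3 DIC units are not
#' considered relevant, so among all models within 3 units of the minimum the
#' one with fewest parameters (ties broken toward the simpler
#' parameterization in the order null, overall, parent-specific, genotypic)
#' is selected.
#'
#' @param dics named numeric vector of DIC values (names are model names).
#' @param margin relevance margin in DIC units (default 3).
#' @return list with `selected` (model name) and `delta` (DIC differences
#'   from the minimum).
#' @export
select_model <- function(dics, margin = 3) {
  stopifnot(length(dics) >= 2, !is.null(names(dics)))
  delta <- dics - min(dics)
  contenders <- names(dics)[delta < margin]
  order_pref <- c("null", "allelic_overall", "allelic_parent_specific", "genotypic")
  npar <- .model_npar[contenders]
  contenders <- contenders[npar == min(npar)]
  selected <- order_pref[order_pref %in% contenders][1]
  list(selected = selected, delta = delta)
}

#' Classify the inheritance pattern of a TRD fit
#'
#' Allelic branch: with the parent-specific model selected, the 95% credible
#' intervals of sire and dam TRD decide between `sire-TRD` (only the sire CI
#' excludes 0), `dam-TRD`, and `sire+dam-TRD`; the overall model maps to
#' `overall-TRD`. Genotypic branch: `recessive` when dominance TRD is
#' positive and the surviving fraction of the disadvantaged homozygote,
#' `1 - |alpha_g| - delta_g`, is below the lethality margin (default 0.5);
#' otherwise dominance TRD at or beyond the dominance split (default 0.10)
#' gives `heterosis excess` / `heterosis deficiency` and smaller departures
#' give `homozygote disadvantage` / `homozygote advantage`.
#'
#' @param model selected model name.
#' @param summary posterior summary data.frame ([posterior_summary()]).
#' @param lethal_margin,dominance_split classification thresholds.
#' @return a pattern label.
#' @export
classify_pattern <- function(model, summary,
                             lethal_margin = 0.5, dominance_split = 0.10) {
  if (model == "null") return("none")
  if (model == "allelic_overall") return("overall-TRD")
  get <- function(p) summary[summary$param == p, , drop = FALSE]
  if (model == "allelic_parent_specific") {
    s <- get("alpha_s"); d <- get("alpha_d")
    s_sig <- s$lower > 0 || s$upper < 0
    d_sig <- d$lower > 0 || d$upper < 0
    if (s_sig && d_sig) return("sire+dam-TRD")
    if (s_sig) return("sire-TRD")
    if (d_sig) return("dam-TRD")
    return("overall-TRD")
  }
  a <- get("alpha_g")$mean
  d <- get("delta_g")$mean
  if (d > 0 && 1 - abs(a) - d < lethal_margin) return("recessive")
  if (d >= dominance_split) return("heterosis excess")
  if (d > 0) return("homozygote disadvantage")
  if (d <= -dominance_split) return("heterosis deficiency")
  if (d < 0) return("homozygote advantage")
  "overall-TRD"
}

#' Fit all TRD models to one mating-count table
#'
#' Convenience wrapper running the null model and the requested TRD models
#' (grid quadrature by default, optionally MCMC), computing Bayes factors,
#' DIC, the DIC-selected model and its inheritance-pattern label.
#'
#' @param counts a [mating_counts()] table.
#' @param models TRD models to fit.
#' @param method `"grid"` (reference) or `"mcmc"`.
#' @param resolution grid resolution.
#' @param iterations,burn_in,seed MCMC controls.
#' @param bf_decisive decisive Bayes-factor threshold (default 100).
#' @return A `fit_result` list: per-model `fits`, `summaries`, `bf`, `dic`,
#'   `selected`, `delta_dic`, `pattern`, `bf_best`, `decisive`.
#' @export
fit_models <- function(counts,
                       models = c("allelic_overall", "allelic_parent_specific",
                                  "genotypic"),
                       method = c("grid", "mcmc"), resolution = 201,
                       iterations = 110000, burn_in = 10000, seed = NULL,
                       bf_decisive = 100) {
  method <- match.arg(method)
  fits <- list()
  summaries <- list()
  bf <- numeric()
  dics <- c(null = dic(counts, "null"))
  for (m in models) {
    gfit <- grid_fit(counts, m, resolution)
    fit <- if (method == "grid") gfit else
      run_mcmc(counts, m, iterations, burn_in, seed = seed)
    fits[[m]] <- fit
    summaries[[m]] <- posterior_summary(fit)
    bf[m] <- bayes_factor(counts, gfit)
    dics[m] <- dic(counts, m, fit)
  }
  sel <- select_model(dics)
  pattern <- if (sel$selected == "null") "none" else
    classify_pattern(sel$selected, summaries[[sel$selected]])
  structure(list(fits = fits, summaries = summaries, bf = bf, dic = dics,
                 selected = sel$selected, delta_dic = sel$delta,
                 pattern = pattern,
                 bf_best = if (length(bf)) max(bf) else NA_real_,
                 decisive = any(bf >= bf_decisive)),
            class = "fit_result")
}
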