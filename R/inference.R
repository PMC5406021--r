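# ABC inference from a reference table: rejection sampling on
# MAD-normalized summary statistics, multinomial-logistic scenario
# posteriors with delta-method confidence intervals, Beaumont local-linear
# parameter adjustment, scenario-choice error rates from pseudo-observed
# datasets (PODs), and a PCA model check.

#' Build an ABC reference table
#'
#' For each scenario, draws parameter vectors from the priors, simulates
#' a dataset under the shared sample design, and records the
#' summary-statistic vector. Every scenario gets equal weight (uniform
#' scenario prior).
#'
#' @param scenarios named list of `scenario` objects.
#' @param n_per_scenario simulated datasets per scenario.
#' @param panel a [locus_panel()].
#' @param include_seq simulate the mtDNA locus?
#' @param seq_L sequence length.
#' @param seed RNG seed.
#' @param progress print a progress line per scenario?
#' @return A `reference_table`: `scenario` (index per row), `stats`
#'   (matrix), `mask` (logical matrix), `params` (list of per-scenario
#'   parameter matrices), `scenarios`, `panel`, `include_seq`, `seq_L`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario,
                                  panel = default_panel(),
                                  include_seq = TRUE, seq_L = 445,
                                  seed = NULL, progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stats <- NULL
  mask <- NULL
  scen_id <- integer(0)
  params <- vector("list", length(scenarios))
  names(params) <- names(scenarios)
  row <- 0L
  for (si in seq_along(scenarios)) {
    s <- scenarios[[si]]
    draws <- sample_priors(s, n_per_scenario)
    params[[si]] <- draws
    for (i in seq_len(n_per_scenario)) {
      cs <- compile_scenario(s, draws[i, ])
      sim <- simulate_dataset(cs, panel = panel, include_seq = include_seq,
                              seq_L = seq_L)
      st <- summary_stats(sim, include_seq = include_seq)
      if (is.null(stats)) {
        stats <- matrix(NA_real_, n_per_scenario * length(scenarios),
                        length(st$stats),
                        dimnames = list(NULL, names(st$stats)))
        mask <- matrix(FALSE, nrow(stats), ncol(stats),
                       dimnames = dimnames(stats))
      }
      row <- row + 1L
      stats[row, ] <- st$stats
      mask[row, ] <- st$mask
      scen_id <- c(scen_id, si)
    }
    if (progress)
      message(sprintf("scenario %s: %d simulations done", s$id,
                      n_per_scenario))
  }
  structure(list(scenario = scen_id, stats = stats, mask = mask,
                 params = params, scenarios = scenarios, panel = panel,
                 include_seq = include_seq, seq_L = seq_L),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d rows (%d scenarios x %d), %d statistics\n",
              nrow(x$stats), length(x$scenarios),
              nrow(x$stats) / length(x$scenarios), ncol(x$stats)))
  invisible(x)
}

# Project a normalized-difference design onto its leading principal axes
# when it is too wide for the retained sample size. The rotation is
# applied without centering so the observed point (the zero vector) stays
# at the origin, where the regressions are evaluated.
.reduce_predictors <- function(X, n, max_predictors = NULL) {
  if (is.null(max_predictors))
    max_predictors <- max(3, min(15, n %/% 25))
  if (ncol(X) <= max_predictors) return(X)
  rot <- prcomp(X, center = TRUE, scale. = FALSE)$rotation
  k <- min(max_predictors, ncol(rot))
  X %*% rot[, seq_len(k), drop = FALSE]
}

# MAD normalization factors over unmasked entries; columns with no spread
# get scale NA and are dropped from distances
.mad_scales <- function(stats, mask) {
  vapply(seq_len(ncol(stats)), function(j) {
    v <- stats[!mask[, j], j]
    if (!length(v)) return(NA_real_)
    m <- mad(v)
    if (m > 0) m else {
      s <- sd(v)
      if (!is.na(s) && s > 0) s else NA_real_
    }
  }, 0)
}

#' ABC rejection step
#'
#' Euclidean distance between each reference-table row and the observed
#' vector over MAD-normalized statistics (masked entries carry their
#' imputed 0; statistics with no spread or masked in the observed data
#' are dropped), retaining the closest `ceiling(tolerance * N)` rows.
#'
#' @param rt a `reference_table`.
#' @param observed observed statistics list (`stats`, `mask`) from
#'   [summary_stats()].
#' @param tolerance retained fraction (DIYABC's logistic default is the
#'   closest 1%).
#' @return List with `idx` (row indices, closest first), `dist`,
#'   `scenario` (per retained row), `z` (normalized stat differences,
#'   retained rows x used stats), `used` (names of statistics entering
#'   the distance).
#' @export
rejection_sample <- function(rt, observed, tolerance = 0.01) {
  stopifnot(tolerance > 0, tolerance <= 1)
  scales <- .mad_scales(rt$stats, rt$mask)
  use <- !is.na(scales) & !observed$mask[colnames(rt$stats)]
  z <- sweep(rt$stats[, use, drop = FALSE], 2,
             observed$stats[colnames(rt$stats)[use]], `-`)
  z <- sweep(z, 2, scales[use], `/`)
  d <- sqrt(rowSums(z^2))
  nkeep <- ceiling(tolerance * nrow(rt$stats))
  if (nkeep < 10)
    warning("fewer than 10 retained simulations; increase the table or ",
            "tolerance")
  idx <- order(d)[seq_len(nkeep)]
  list(idx = idx, dist = d[idx], scenario = rt$scenario[idx],
       z = z[idx, , drop = FALSE], used = colnames(rt$stats)[use])
}

#' Scenario posterior probabilities by multinomial logistic regression
#'
#' Fits a multinomial logistic regression of scenario label on the
#' normalized statistic differences over the retained rows and evaluates
#' it at the observed point (the zero vector); 95% confidence intervals
#' come from the fit's asymptotic covariance by the delta method (at the
#' observed point only the intercept block contributes). Falls back to
#' rejection proportions with a normal-approximation CI when the fit
#' degenerates (complete separation or fewer than 2 retained scenarios).
#'
#' When the statistic space is large relative to the retained set, the
#' regression runs on the leading principal components of the normalized
#' differences instead of the raw statistics (the probabilities stay
#' invariant to affine rescaling of any statistic because MAD
#' normalization precedes the projection).
#'
#' @param ret result of [rejection_sample()].
#' @param scenario_names optional labels (defaults to indices).
#' @param max_predictors cap on regression covariates; defaults to
#'   `max(3, min(15, n_retained %/% 25))`.
#' @return Data frame `scenario`, `prob`, `lo`, `hi`, `method`, plus
#'   attribute `"chosen"` (label of the highest-posterior scenario).
#' @export
logistic_scenario_posterior <- function(ret, scenario_names = NULL,
                                        max_predictors = NULL) {
  scen <- sort(unique(ret$scenario))
  if (is.null(scenario_names))
    scenario_names <- as.character(seq_len(max(ret$scenario)))
  labs <- scenario_names[scen]
  fallback <- function(note) {
    n <- length(ret$scenario)
    p <- as.numeric(table(factor(ret$scenario, levels = scen))) / n
    se <- sqrt(p * (1 - p) / n)
    out <- data.frame(scenario = labs, prob = p,
                      lo = pmax(0, p - 1.96 * se),
                      hi = pmin(1, p + 1.96 * se), method = note,
                      stringsAsFactors = FALSE)
    attr(out, "chosen") <- labs[which.max(p)]
    out
  }
  if (length(scen) < 2) return(fallback("proportion"))
  # drop collinear/zero-variance columns to help the optimizer
  keepcol <- apply(ret$z, 2, function(v) sd(v) > 1e-10)
  X <- ret$z[, keepcol, drop = FALSE]
  X <- .reduce_predictors(X, nrow(X), max_predictors)
  y <- factor(ret$scenario, levels = scen)
  fit <- tryCatch(
    nnet::multinom(y ~ ., data = data.frame(y = y, X), trace = FALSE,
                   maxit = 300, MaxNWts = 5000),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback("proportion (fit failed)"))
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  if (any(abs(cf[, 1]) > 30))
    return(fallback("proportion (separation)"))
  eta <- c(0, cf[, 1])                       # linear predictors at x = 0
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  V <- tryCatch(vcov(fit), error = function(e) NULL)
  lo <- hi <- rep(NA_real_, length(p))
  if (!is.null(V)) {
    # intercept entries come first within each class block
    npred <- ncol(X) + 1
    int_idx <- seq(1, by = npred, length.out = length(scen) - 1)
    Vi <- V[int_idx, int_idx, drop = FALSE]
    # dp_k / d eta_j over the free classes j = 2..K
    for (k in seq_along(p)) {
      gkj <- vapply(seq_along(p)[-1], function(j)
        p[k] * ((k == j) - p[j]), 0)
      sek <- sqrt(max(0, t(gkj) %*% Vi %*% gkj))
      lo[k] <- max(0, p[k] - 1.96 * sek)
      hi[k] <- min(1, p[k] + 1.96 * sek)
    }
  }
  out <- data.frame(scenario = labs, prob = p, lo = lo, hi = hi,
                    method = "logistic", stringsAsFactors = FALSE)
  attr(out, "chosen") <- labs[which.max(p)]
  out
}

#' Local-linear (Beaumont) parameter adjustment
#'
#' Regresses each (optionally transformed) parameter of the retained rows
#' of one scenario on the normalized statistic differences with
#' Epanechnikov weights by rejection distance; the adjusted posterior
#' draws are the fitted values at the observed point plus the residuals,
#' back-transformed. Rank-deficient designs fall back to a small ridge
#' penalty.
#'
#' @param rt a `reference_table`.
#' @param ret result of [rejection_sample()].
#' @param scenario_index scenario whose parameters to estimate.
#' @param transform `"log"`, `"logit"` or `"none"`; recycled over
#'   parameters.
#' @param min_retained minimum retained rows of the scenario.
#' @param max_predictors cap on regression covariates (leading principal
#'   axes are used beyond it; see [logistic_scenario_posterior()]).
#' @return List with `draws` (matrix of adjusted posterior samples) and
#'   `summary` (median and 2.5/97.5% quantiles per parameter).
#' @export
local_linear_adjust <- function(rt, ret, scenario_index,
                                transform = "log", min_retained = 50,
                                max_predictors = NULL) {
  sel <- ret$scenario == scenario_index
  if (sum(sel) < min_retained)
    stop("only ", sum(sel), " retained rows for scenario ", scenario_index,
         "; need at least ", min_retained)
  # map retained global row indices into the scenario's parameter matrix
  n_per <- nrow(rt$params[[scenario_index]])
  gidx <- ret$idx[sel]
  local <- gidx - (scenario_index - 1L) * n_per
  theta <- rt$params[[scenario_index]][local, , drop = FALSE]
  X <- ret$z[sel, , drop = FALSE]
  d <- ret$dist[sel]
  h <- max(d) * 1.0001
  w <- 1 - (d / h)^2
  transform <- rep_len(transform, ncol(theta))
  fwd <- function(v, tr) switch(tr, log = log(v),
                                logit = log(v / (1 - v)), none = v)
  bwd <- function(v, tr) switch(tr, log = exp(v),
                                logit = 1 / (1 + exp(-v)), none = v)
  keepcol <- apply(X, 2, function(v) sd(v) > 1e-10)
  Xr <- .reduce_predictors(X[, keepcol, drop = FALSE], nrow(X),
                           max_predictors)
  Xk <- cbind(1, Xr)
  adj <- matrix(NA_real_, nrow(theta), ncol(theta),
                dimnames = dimnames(theta))
  for (j in seq_len(ncol(theta))) {
    yj <- fwd(theta[, j], transform[j])
    fit <- tryCatch(stats::lm.wfit(Xk, yj, w), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) {
      # ridge fallback for rank-deficient designs
      lam <- 1e-6
      A <- crossprod(Xk * sqrt(w)) + lam * diag(ncol(Xk))
      b <- crossprod(Xk * w, yj)
      beta <- solve(A, b)
      fitted <- drop(Xk %*% beta)
      resid <- yj - fitted
      adj[, j] <- bwd(beta[1] + resid, transform[j])
    } else {
      adj[, j] <- bwd(fit$coefficients[1] + fit$residuals, transform[j])
    }
  }
  qs <- t(apply(adj, 2, quantile, c(0.5, 0.025, 0.975), na.rm = TRUE))
  colnames(qs) <- c("median", "q2.5", "q97.5")
  list(draws = adj, summary = data.frame(param = colnames(theta), qs,
                                         row.names = NULL))
}

#' Scenario-choice error rates from pseudo-observed datasets
#'
#' Simulates `n_pods` datasets from each scenario's prior, runs the full
#' scenario-choice pipeline (summary statistics, rejection, logistic
#' posterior) on each, and reports: type I error per scenario (fraction
#' of its own PODs in which it is not chosen) and type II error per
#' scenario (fraction of other scenarios' PODs in which it is chosen).
#'
#' @param rt a `reference_table` (carries the scenarios and design).
#' @param n_pods PODs per scenario (>= 20 recommended).
#' @param tolerance rejection tolerance.
#' @param seed RNG seed.
#' @return List with `rates` data frame (`scenario`, `type1`, `type2`)
#'   and `choices` matrix (true scenario x chosen scenario counts).
#' @export
confidence_error_rates <- function(rt, n_pods = 20, tolerance = 0.01,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(rt$scenarios)
  choices <- matrix(0L, S, S,
                    dimnames = list(names(rt$scenarios),
                                    names(rt$scenarios)))
  for (si in seq_len(S)) {
    s <- rt$scenarios[[si]]
    draws <- sample_priors(s, n_pods)
    for (i in seq_len(n_pods)) {
      cs <- compile_scenario(s, draws[i, ])
      sim <- simulate_dataset(cs, panel = rt$panel,
                              include_seq = rt$include_seq,
                              seq_L = rt$seq_L)
      obs <- summary_stats(sim, include_seq = rt$include_seq)
      ret <- suppressWarnings(rejection_sample(rt, obs, tolerance))
      post <- logistic_scenario_posterior(ret)
      ch <- as.integer(attr(post, "chosen"))
      choices[si, ch] <- choices[si, ch] + 1L
    }
  }
  type1 <- 1 - diag(choices) / rowSums(choices)
  type2 <- vapply(seq_len(S), function(s)
    sum(choices[-s, s]) / sum(choices[-s, ]), 0)
  list(rates = data.frame(scenario = names(rt$scenarios), type1 = type1,
                          type2 = type2, row.names = NULL),
       choices = choices)
}

#' PCA model check in summary-statistic space
#'
#' Projects the observed vector (and optionally posterior-predictive
#' simulations) onto the principal components of the normalized
#' reference-table statistics; an observed dataset falling inside the
#' simulated cloud on the leading components indicates the model can
#' reproduce the data.
#'
#' @param rt a `reference_table`.
#' @param observed observed statistics list.
#' @param posterior_stats optional matrix of posterior-predictive
#'   statistic vectors (columns matching `rt$stats`).
#' @param n_pc leading components to report.
#' @return List with `var_explained`, `observed_scores`,
#'   `observed_percentile` (per PC, within the prior cloud),
#'   `posterior_percentile` (when supplied), and the `prcomp` fit.
#' @export
pca_model_check <- function(rt, observed, posterior_stats = NULL,
                            n_pc = 3) {
  scales <- .mad_scales(rt$stats, rt$mask)
  use <- !is.na(scales) & !observed$mask[colnames(rt$stats)]
  Z <- sweep(rt$stats[, use, drop = FALSE], 2, scales[use], `/`)
  pc <- prcomp(Z, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pc$x))
  proj <- function(v) {
    z <- v[colnames(rt$stats)[use]] / scales[use]
    drop((z - pc$center) %*% pc$rotation[, seq_len(n_pc), drop = FALSE])
  }
  obs_scores <- proj(observed$stats)
  pct <- vapply(seq_len(n_pc), function(k)
    mean(pc$x[, k] <= obs_scores[k]), 0)
  out <- list(
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pc)],
    observed_scores = obs_scores,
    observed_percentile = pct,
    fit = pc)
  if (!is.null(posterior_stats)) {
    ps <- t(apply(posterior_stats, 1, proj))
    out$posterior_scores <- ps
    out$posterior_percentile <- vapply(seq_len(n_pc), function(k)
      mean(ps[, k] <= obs_scores[k]), 0)
  }
  out
}
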