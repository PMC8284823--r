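#' Mixture decomposition configuration
#'
#' Settings for the Bayesian decomposition of a copying vector into
#' candidate-source contributions. Proportions live on a grid of
#' `n_slots` slots (a source's proportion is its slot count / `n_slots`);
#' the prior on the number of contributing ("active") sources is Poisson
#' with mean `t_expected`, truncated to \[1, `t_eligible`\], uniform over
#' source subsets of each size and over slot compositions. The likelihood
#' treats the `c`-scaled target copying vector as multinomial counts under
#' the slot mixture of surrogate vectors; `c` therefore controls posterior
#' concentration and defaults, at run time, to the painted map length in
#' cM.
#'
#' @param n_slots proportion grid size (default 100).
#' @param t_eligible maximum number of contributing sources (default 8).
#' @param t_expected prior mean number of contributing sources (default 4;
#'   a sparser alternative is 2).
#' @param c concentration constant (NULL: supplied at run time).
#' @return An object of class `mixture_config`.
#' @export
mixture_config <- function(n_slots = 100, t_eligible = 8, t_expected = 4,
                           c = NULL) {
  if (t_expected < 1 || t_expected > t_eligible)
    stop("need 1 <= t_expected <= t_eligible")
  if (n_slots < t_eligible) stop("n_slots must be >= t_eligible")
  structure(list(n_slots = as.integer(n_slots),
                 t_eligible = as.integer(t_eligible),
                 t_expected = t_expected, c = c),
            class = "mixture_config")
}

#' Sample the posterior of source contributions for one target
#'
#' Runs independent Metropolis-Hastings chains over slot assignments (see
#' [mixture_config()]) and summarizes the thinned post-burn-in draws:
#' posterior means, exceedance probabilities P(beta_s >= t) for
#' t in {0.01, 0.05, 0.20}, 95% credible intervals and the split-chain
#' Rhat convergence diagnostic per source.
#'
#' @param target copying vector (length = number of reference populations;
#'   nonnegative, normalized internally to sum 1).
#' @param surrogates sources x populations matrix of surrogate copying
#'   vectors (row names are the candidate source names); its columns must
#'   match `target`'s populations.
#' @param config a [mixture_config()].
#' @param n_iter iterations per chain (default 1e5).
#' @param burn_in discarded initial iterations (default 1e4).
#' @param thin thinning interval (default 100).
#' @param n_chains number of chains (default 5; at least 2 required for
#'   Rhat).
#' @param seed integer seed; chain i uses seed + i - 1.
#' @param c concentration override (otherwise `config$c`).
#' @return An object of class `mixture_posterior`.
#' @export
run_mixture_mcmc <- function(target, surrogates, config = mixture_config(),
                             n_iter = 1e5, burn_in = 1e4, thin = 100,
                             n_chains = 5, seed = 1, c = NULL) {
  stopifnot(inherits(config, "mixture_config"))
  c <- c %||% config$c
  if (is.null(c) || c <= 0) stop("concentration constant c must be > 0")
  if (any(target < 0)) stop("target vector has negative components")
  if (n_chains < 2) stop("at least 2 chains are required for Rhat")
  surrogates <- as.matrix(surrogates)
  S <- nrow(surrogates)
  if (config$t_eligible > S)
    stop("t_eligible exceeds the number of candidate sources")
  if (!is.null(names(target)) && !is.null(colnames(surrogates)))
    target <- target[colnames(surrogates)]
  x <- target / sum(target)
  cx <- c * x
  M <- t(surrogates)                       # populations x sources
  sources <- rownames(surrogates) %||% paste0("S", seq_len(S))
  n_keep <- (n_iter - burn_in) %/% thin
  chains <- vector("list", n_chains)
  acc <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    a0 <- max(1L, min(as.integer(round(config$t_expected)), config$t_eligible))
    picks <- sample.int(S, a0)
    init <- integer(S)
    base <- config$n_slots %/% a0
    init[picks] <- base
    init[picks[1]] <- init[picks[1]] + config$n_slots - base * a0
    r <- mixture_chain_cpp(cx, M, config$n_slots, config$t_eligible,
                           config$t_expected, as.integer(n_iter),
                           as.integer(burn_in), as.integer(thin), init)
    colnames(r$samples) <- sources
    chains[[ch]] <- r$samples
    acc[ch] <- r$acceptance_rate
  }
  all_draws <- do.call(rbind, chains)
  thresholds <- c(0.01, 0.05, 0.20)
  probs <- vapply(thresholds, function(t) colMeans(all_draws >= t),
                  numeric(S))
  colnames(probs) <- paste0("p_ge_", thresholds)
  ci <- t(apply(all_draws, 2, quantile, probs = c(0.025, 0.975)))
  rh <- compute_rhat(chains)
  structure(list(chains = chains, mean = colMeans(all_draws),
                 prob_ge = probs, ci95 = ci, rhat = rh$rhat,
                 rhat_degenerate = rh$degenerate,
                 acceptance_rate = acc, sources = sources,
                 config = config, c = c, n_keep = n_keep),
            class = "mixture_posterior")
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat("mixture_posterior over", length(x$sources), "sources,",
      length(x$chains), "chains x", x$n_keep, "draws\n")
  tab <- data.frame(mean = round(x$mean, 4),
                    ci_lo = round(x$ci95[, 1], 4),
                    ci_hi = round(x$ci95[, 2], 4),
                    rhat = round(x$rhat, 4))
  print(tab[order(-tab$mean), ])
  invisible(x)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' The classic (non-rank-normalized) Gelman-Rubin diagnostic computed on
#' split chains: each chain is halved, the between- and within-chain
#' variances B and W of the resulting 2m half-chains give
#' Rhat = sqrt(((n-1)/n W + B/n) / W). When all draws of a source are
#' identical (degenerate variance) the value is defined as 1 and flagged.
#'
#' @param chains list of draw matrices (iterations x sources), or a list
#'   of numeric vectors for a single quantity.
#' @return List with `rhat` (per source) and `degenerate` (logical).
#' @export
compute_rhat <- function(chains) {
  if (length(chains) < 2) stop("need at least 2 chains")
  if (is.null(dim(chains[[1]])))
    chains <- lapply(chains, function(x) matrix(x, ncol = 1))
  n <- nrow(chains[[1]])
  if (n < 4) stop("need at least 4 draws per chain")
  half <- n %/% 2
  splits <- list()
  for (ch in chains) {
    splits[[length(splits) + 1]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1]] <- ch[half + seq_len(half), , drop = FALSE]
  }
  m <- length(splits)
  means <- do.call(rbind, lapply(splits, colMeans))
  vars <- do.call(rbind, lapply(splits, function(s) apply(s, 2, var)))
  W <- colMeans(vars)
  B <- half * apply(means, 2, var)
  degenerate <- W < .Machine$double.eps
  rhat <- ifelse(degenerate, 1,
                 sqrt(((half - 1) / half * W + B / half) / W))
  names(rhat) <- colnames(chains[[1]])
  list(rhat = rhat, degenerate = degenerate)
}

#' Exact posterior over all slot states (small problems)
#'
#' Exhaustively enumerates every assignment of `n_slots` slots to the
#' candidate sources with between 1 and `t_eligible` active sources and
#' computes each state's exact posterior probability under the model of
#' [run_mixture_mcmc()]. Feasible only for small `n_slots` and few
#' sources; used as the independent reference for the sampler.
#'
#' @inheritParams run_mixture_mcmc
#' @return List with `states` (matrix of slot counts), `prob` (posterior
#'   probability per state) and `mean` (posterior mean of beta).
#' @export
enumerate_mixture_posterior <- function(target, surrogates,
                                        config = mixture_config(), c = NULL) {
  c <- c %||% config$c
  if (is.null(c) || c <= 0) stop("concentration constant c must be > 0")
  surrogates <- as.matrix(surrogates)
  S <- nrow(surrogates)
  x <- target / sum(target)
  cx <- c * x
  M <- t(surrogates)
  states <- compositions(config$n_slots, S)
  active <- rowSums(states > 0)
  keep <- active >= 1 & active <= config$t_eligible
  states <- states[keep, , drop = FALSE]
  active <- active[keep]
  lp <- vapply(seq_len(nrow(states)), function(i) {
    beta <- states[i, ] / config$n_slots
    p <- as.vector(M %*% beta)
    if (any(p <= 0 & cx > 0)) return(-Inf)
    ll <- sum(cx[cx > 0] * log(p[cx > 0]))
    a <- active[i]
    ll + a * log(config$t_expected) - lgamma(a + 1) -
      lchoose(S, a) - lchoose(config$n_slots - 1, a - 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  mean_beta <- colSums(states * pr) / config$n_slots
  names(mean_beta) <- rownames(surrogates)
  list(states = states, prob = pr, mean = mean_beta)
}

# all compositions of n into S nonnegative parts
compositions <- function(n, S) {
  if (S == 1) return(matrix(n, 1, 1))
  out <- list()
  for (k in 0:n) {
    rest <- compositions(n - k, S - 1)
    out[[k + 1]] <- cbind(k, rest)
  }
  unname(do.call(rbind, out))
}

#' Threshold table across individually analysed targets
#'
#' For each candidate source and ancestry threshold t in
#' {0.01, 0.05, 0.20}, counts the targets assigned at least t ancestry
#' from that source with high posterior probability
#' (P(beta_s >= t) > `prob_cut`, strict).
#'
#' @param posteriors list of `mixture_posterior` objects (one per target).
#' @param prob_cut posterior probability cut (default 0.99).
#' @return List with `table` (data frame: source, n and percentage at each
#'   threshold) and `means` (targets x sources posterior-mean matrix).
#' @export
summarize_individuals <- function(posteriors, prob_cut = 0.99) {
  stopifnot(length(posteriors) >= 1)
  sources <- posteriors[[1]]$sources
  n <- length(posteriors)
  means <- t(vapply(posteriors, `[[`, numeric(length(sources)), "mean"))
  colnames(means) <- sources
  counts <- sapply(seq_along(c(0.01, 0.05, 0.20)), function(ti) {
    colSums(t(vapply(posteriors, function(p) p$prob_ge[, ti],
                     numeric(length(sources)))) > prob_cut)
  })
  tab <- data.frame(source = sources,
                    n_ge_1pct = counts[, 1], pct_ge_1pct = 100 * counts[, 1] / n,
                    n_ge_5pct = counts[, 2], pct_ge_5pct = 100 * counts[, 2] / n,
                    n_ge_20pct = counts[, 3], pct_ge_20pct = 100 * counts[, 3] / n,
                    mean_pct = 100 * colMeans(means),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, means = means)
}

#' Group-level source decomposition
#'
#' Averages the targets' copying vectors component-wise — the
#' "mathematically average" target — and decomposes the mean vector,
#' reducing the noise of averaging many individual posteriors. Because the
#' mean vector summarizes the summed painted genome of all group members,
#' the concentration constant defaults to the per-target value times the
#' group size (i.e. the group's total painted map length).
#'
#' @param copy_vectors targets x populations matrix of copying vectors.
#' @param surrogates sources x populations surrogate matrix.
#' @param c concentration constant for the group (default: per-target
#'   `config$c` times the number of targets).
#' @inheritParams run_mixture_mcmc
#' @return A `mixture_posterior` for the group.
#' @export
summarize_group <- function(copy_vectors, surrogates,
                            config = mixture_config(), c = NULL, ...) {
  copy_vectors <- as.matrix(copy_vectors)
  if (nrow(copy_vectors) == 0) stop("empty target set")
  if (is.null(c) && !is.null(config$c)) c <- config$c * nrow(copy_vectors)
  run_mixture_mcmc(colMeans(copy_vectors), surrogates, config, c = c, ...)
}
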