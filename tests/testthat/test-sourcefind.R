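# well-separated surrogate fixture on 6 populations
fixture_surrogates <- function(S = 8, J = 6, seed = 71) {
  set.seed(seed)
  m <- matrix(runif(S * J), S, J)
  m <- m / rowSums(m)
  dimnames(m) <- list(paste0("S", seq_len(S)), paste0("p", seq_len(J)))
  m
}

test_that("mixture configuration enforces its invariants", {
  expect_error(mixture_config(t_expected = 9, t_eligible = 8), "t_expected")
  expect_error(mixture_config(n_slots = 4, t_eligible = 8), "n_slots")
  sur <- fixture_surrogates()
  expect_error(run_mixture_mcmc(sur[1, ], sur, mixture_config(c = -1)),
               "c must be")
  expect_error(run_mixture_mcmc(-sur[1, ], sur, mixture_config(c = 10)),
               "negative")
  expect_error(run_mixture_mcmc(sur[1, ], sur, mixture_config(c = 10),
                                n_chains = 1), "chains")
  expect_error(run_mixture_mcmc(sur[1, ], fixture_surrogates(S = 4),
                                mixture_config(t_eligible = 8, c = 10)),
               "candidate sources")
})

test_that("a target equal to one surrogate is assigned to it", {
  sur <- fixture_surrogates()
  post <- run_mixture_mcmc(sur["S3", ], sur, mixture_config(c = 3000),
                           n_iter = 5e4, burn_in = 5e3, thin = 50,
                           n_chains = 2, seed = 72)
  expect_gte(post$mean[["S3"]], 0.95)
})

test_that("a constructed two-source mixture is recovered", {
  sur <- fixture_surrogates()
  target <- 0.7 * sur["S1", ] + 0.3 * sur["S2", ]
  post <- run_mixture_mcmc(target, sur, mixture_config(c = 3000),
                           n_iter = 1e5, burn_in = 1e4, thin = 100,
                           n_chains = 3, seed = 73)
  expect_lt(abs(post$mean[["S1"]] - 0.7), 0.05)
  expect_lt(abs(post$mean[["S2"]] - 0.3), 0.05)
  expect_lte(max(post$mean[setdiff(names(post$mean), c("S1", "S2"))]), 0.02)
  # grid search over all 2-source slot allocations confirms the mode
  cfg <- mixture_config(c = 3000)
  best <- -Inf; best_ab <- NULL
  for (a in 0:cfg$n_slots) {
    p <- (a * sur["S1", ] + (cfg$n_slots - a) * sur["S2", ]) / cfg$n_slots
    ll <- sum(3000 * target / sum(target) * log(p))
    if (ll > best) { best <- ll; best_ab <- a }
  }
  expect_equal(best_ab, 70)
})

test_that("every sampled state is a valid sparse composition", {
  sur <- fixture_surrogates()
  cfg <- mixture_config(n_slots = 20, t_eligible = 5, t_expected = 2,
                        c = 500)
  post <- run_mixture_mcmc(sur["S1", ] * 0.5 + sur["S4", ] * 0.5, sur, cfg,
                           n_iter = 2e4, burn_in = 1e3, thin = 20,
                           n_chains = 2, seed = 74)
  draws <- do.call(rbind, post$chains)
  expect_equal(unname(rowSums(draws)), rep(1, nrow(draws)), tolerance = 1e-12)
  expect_lte(max(rowSums(draws > 0)), 5)
})

test_that("the sampler reproduces the exhaustively enumerated posterior", {
  sur <- fixture_surrogates(S = 3, J = 3, seed = 75)
  cfg <- mixture_config(n_slots = 4, t_eligible = 3, t_expected = 2, c = 40)
  target <- c(0.45, 0.35, 0.20)
  en <- enumerate_mixture_posterior(target, sur, cfg)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  post <- run_mixture_mcmc(target, sur, cfg, n_iter = 3e5, burn_in = 1e4,
                           thin = 10, n_chains = 2, seed = 76)
  expect_lt(max(abs(post$mean - en$mean)), 0.01)
})

test_that("larger concentration tightens the posterior", {
  sur <- fixture_surrogates()
  target <- 0.6 * sur["S1", ] + 0.4 * sur["S2", ]
  sds <- vapply(c(300, 3000, 30000), function(cc) {
    post <- run_mixture_mcmc(target, sur, mixture_config(c = cc),
                             n_iter = 1e5, burn_in = 1e4, thin = 100,
                             n_chains = 2, seed = 77)
    sd(do.call(rbind, post$chains)[, "S1"])
  }, numeric(1))
  expect_true(all(diff(sds) <= 1e-3))
})

test_that("split-chain Rhat flags disagreement and guards degeneracy", {
  set.seed(78)
  same <- lapply(1:4, function(i) matrix(rnorm(400), ncol = 2))
  r1 <- compute_rhat(same)
  expect_true(all(r1$rhat < 1.05))
  shifted <- list(matrix(rnorm(200), ncol = 1),
                  matrix(rnorm(200, mean = 5), ncol = 1))
  expect_gt(compute_rhat(shifted)$rhat, 1.5)
  const <- list(matrix(1, 100, 1), matrix(1, 100, 1))
  rc <- compute_rhat(const)
  expect_equal(unname(rc$rhat), 1)
  expect_true(rc$degenerate)
  expect_error(compute_rhat(same[1]), "2 chains")
  expect_error(compute_rhat(list(matrix(1:3, 3, 1), matrix(1:3, 3, 1))),
               "4 draws")
})

test_that("MCMC posteriors carry convergent Rhat on a realistic target", {
  sur <- fixture_surrogates()
  target <- 0.65 * sur["S1", ] + 0.35 * sur["S5", ]
  post <- run_mixture_mcmc(target, sur, mixture_config(c = 3000),
                           n_iter = 1e5, burn_in = 1e4, thin = 100,
                           n_chains = 4, seed = 79)
  expect_true(all(post$rhat[post$mean > 0.05] < 1.1))
  expect_true(all(post$ci95[, 1] <= post$mean & post$mean <= post$ci95[, 2]))
})

test_that("individual summaries count strict high-probability assignments", {
  sources <- c("A", "B")
  fake <- function(pA) {
    structure(list(mean = c(A = pA, B = 1 - pA),
                   prob_ge = matrix(c(pA >= 0.01, pA >= 0.05, pA >= 0.20,
                                      0.98, 0.98, 0.98), 2, 3, byrow = TRUE,
                                    dimnames = list(sources, NULL)),
                   sources = sources), class = "mixture_posterior")
  }
  s <- summarize_individuals(list(fake(1), fake(1)), prob_cut = 0.99)
  expect_equal(s$table$n_ge_1pct, c(2, 0))
  expect_equal(s$table$n_ge_20pct, c(2, 0))   # B at 0.98 is never counted
  expect_equal(s$table$pct_ge_5pct, c(100, 0))
})

test_that("group decomposition analyses the component-wise mean vector", {
  sur <- fixture_surrogates()
  v <- 0.8 * sur["S1", ] + 0.2 * sur["S2", ]
  w <- 0.4 * sur["S1", ] + 0.6 * sur["S2", ]
  g1 <- summarize_group(rbind(v, w), sur, mixture_config(c = 3000), c = 3000,
                        n_iter = 5e4, burn_in = 5e3, thin = 50,
                        n_chains = 2, seed = 80)
  g2 <- run_mixture_mcmc((v + w) / 2, sur, mixture_config(c = 3000),
                         n_iter = 5e4, burn_in = 5e3, thin = 50,
                         n_chains = 2, seed = 80, c = 3000)
  expect_identical(g1$mean, g2$mean)
  # a group of one reduces to the individual analysis under equal seeds
  g3 <- summarize_group(rbind(v), sur, mixture_config(c = 3000),
                        n_iter = 5e4, burn_in = 5e3, thin = 50,
                        n_chains = 2, seed = 81)
  g4 <- run_mixture_mcmc(v, sur, mixture_config(c = 3000), n_iter = 5e4,
                         burn_in = 5e3, thin = 50, n_chains = 2, seed = 81)
  expect_identical(g3$mean, g4$mean)
  expect_error(summarize_group(rbind(v)[0, ], sur, mixture_config(c = 10)),
               "empty")
})
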