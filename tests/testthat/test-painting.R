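test_that("a single donor receives the whole painted genome", {
  map <- uniform_genetic_map(2, 0.5, 5)
  set.seed(61)
  tgt <- rbinom(10, 1, 0.5)
  don <- matrix(rbinom(10, 1, 0.5), ncol = 1)
  r <- paint_haplotype(tgt, don, painting_params(Ne = 50, mu = 0.01), map)
  expect_equal(unname(r$chunk_lengths), map_total_cm(map))
  expect_equal(unname(r$chunk_counts), 2)  # one chunk entry per chromosome
})

test_that("forward-backward matches exhaustive path enumeration", {
  # fixed 4-site fixture from the copying-model contract
  map <- tiny_map(4)
  tgt <- c(0L, 1L, 1L, 0L)
  don <- cbind(c(0L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L))
  pp <- painting_params(Ne = 50, mu = 0.01)
  r <- paint_haplotype(tgt, don, pp, map)
  o <- paint_oracle(tgt, don, 50, 0.01, map$cm,
                    admixpaint:::site_weights_cm(map))
  expect_lt(max(abs(r$chunk_lengths - o$lengths)), 1e-10)
  expect_lt(max(abs(r$chunk_counts - o$counts)), 1e-10)
  expect_lt(abs(r$loglik - o$loglik), 1e-10)
  # random small instances, including uneven gaps and K = 1..3
  set.seed(62)
  for (i in 1:40) {
    L <- sample(2:6, 1); K <- sample(1:3, 1)
    cm <- sort(runif(L, 0, 5)); cm <- cm - cm[1]
    if (diff(range(cm)) <= 0) next
    m <- genetic_map(rep("1", L), seq_len(L) * 1000L, cm)
    tgt <- rbinom(L, 1, 0.5)
    don <- matrix(rbinom(L * K, 1, 0.5), ncol = K)
    Ne <- runif(1, 10, 300); mu <- runif(1, 0.001, 0.2)
    r <- paint_haplotype(tgt, don, painting_params(Ne, mu), m)
    o <- paint_oracle(tgt, don, Ne, mu, m$cm, admixpaint:::site_weights_cm(m))
    expect_lt(max(abs(r$chunk_lengths - o$lengths)), 1e-10)
    expect_lt(max(abs(r$chunk_counts - o$counts)), 1e-10)
  }
})

test_that("a perfectly matching donor dominates the painting", {
  map <- uniform_genetic_map(1, 1, 200)
  set.seed(63)
  tgt <- rbinom(200, 1, 0.5)
  don <- cbind(tgt, 1L - tgt)
  r <- paint_haplotype(tgt, don, painting_params(Ne = 100, mu = 1e-12), map)
  expect_gte(r$chunk_lengths[1] / sum(r$chunk_lengths), 0.999)
})

test_that("painting rejects malformed inputs", {
  map <- uniform_genetic_map(1, 1, 10)
  pp <- painting_params()
  expect_error(paint_haplotype(rbinom(10, 1, .5),
                               matrix(integer(0), 10, 0), pp, map), "empty")
  expect_error(paint_haplotype(c(rep(0L, 9), 2L),
                               matrix(0L, 10, 2), pp, map), "biallelic")
  expect_error(painting_params(Ne = -1), "Ne")
  expect_error(painting_params(mu = 0.7), "mu")
})

test_that("scaled recursions stay finite on long chromosomes", {
  map <- uniform_genetic_map(1, 1, 1e5)
  set.seed(64)
  tgt <- rbinom(1e5, 1, 0.5)
  don <- matrix(rbinom(4e5, 1, 0.5), ncol = 4)
  r <- paint_haplotype(tgt, don, painting_params(), map)
  expect_true(is.finite(r$loglik))
  expect_equal(sum(r$chunk_lengths), map_total_cm(map), tolerance = 1e-6)
})

test_that("EM parameter estimation behaves at its contract edges", {
  map <- uniform_genetic_map(1, 1, 50)
  # identical haplotypes: zero mismatches drive mu to its floor
  haps <- matrix(rep(rbinom(50, 1, 0.5), 8), ncol = 8)
  panel <- admixpaint:::new_haplotype_panel(haps, paste0("s", 1:4),
                                            rep("P", 4), map)
  p1 <- em_estimate_params(panel, n_iter = 3)
  expect_equal(p1$mu, 1e-9)
  # n_iter = 0 returns the starting parameters unchanged
  p0 <- painting_params(Ne = 77, mu = 0.01)
  expect_identical(em_estimate_params(panel, params = p0, n_iter = 0), p0)
})

test_that("EM recovers the generating parameters from simulated copying", {
  set.seed(65)
  map <- uniform_genetic_map(2, 1, 2500)
  don <- matrix(rbinom(5000 * 20, 1, runif(5000, 0.1, 0.9)), ncol = 20)
  # the first four individuals' haplotypes are generated by copying from
  # the 20 donor haplotypes with Ne = 100, mu = 1e-3
  copies <- vapply(1:16, function(i)
    simulate_copying_target(don, 100, 1e-3, map), integer(5000))
  haps <- cbind(copies, don)
  panel <- admixpaint:::new_haplotype_panel(haps, paste0("s", 1:18),
                                            rep("P", 18), map)
  est <- em_estimate_params(panel, individuals = paste0("s", 1:8),
                            params = painting_params(Ne = 30, mu = 0.01),
                            n_iter = 10)
  expect_lt(abs(est$Ne - 100) / 100, 0.25)
  expect_lt(abs(est$mu - 1e-3) / 1e-3, 0.25)
  ll <- attr(est, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

make_paint_cohort <- function(n_ref = 3, n_adm = 2, seed = 66) {
  map <- uniform_genetic_map(2, 1, 300)
  pm <- default_population_model(nrow(map), seed = seed)
  fr <- draw_population_frequencies(pm, seed = seed + 1)
  ref <- combine_panels(
    simulate_reference_panel(fr[, "INUIT"], n_ref, map, "INUIT",
                             seed = seed + 2),
    simulate_reference_panel(fr[, "EUR_A"], n_ref, map, "EUR_A",
                             seed = seed + 3))
  genomes <- simulate_admixed_cohort(canonical_histories()["one_parent"],
                                     n_adm, fr, map, seed = seed + 4)
  list(ref = ref, targets = genomes_to_panel(genomes), genomes = genomes)
}

test_that("cohort painting conserves chunk length and excludes self-copying", {
  co <- make_paint_cohort()
  res <- paint_cohort(co$ref, co$targets, painting_params())
  # every painted diploid row sums to twice the map length
  expect_equal(unname(rowSums(res$chunk_lengths)),
               rep(2 * res$map_cm, nrow(res$chunk_lengths)),
               tolerance = 1e-6)
  # a reference individual never copies from itself
  for (id in co$ref$sample_ids)
    expect_equal(res$chunk_lengths[id, id], 0)
  expect_error(paint_cohort(co$ref, co$ref), "overlap")
})

test_that("copying proportions track true European ancestry", {
  # two-source design at the default site density (30 sites per cM)
  set.seed(67)
  map <- uniform_genetic_map(2, 1.5, 4500)
  pm <- default_population_model(nrow(map))
  fr <- draw_population_frequencies(pm)
  ref <- combine_panels(
    simulate_reference_panel(fr[, "INUIT"], 15, map, "INUIT"),
    simulate_reference_panel(fr[, "EUR_C"], 15, map, "EUR_C"))
  hists <- list(
    admixture_history(c("EUR_C", "INUIT"), "EUR_C"),
    admixture_history(c("EUR_C", rep("INUIT", 3)), "EUR_C"),
    admixture_history(c("EUR_C", rep("INUIT", 7)), "EUR_C"))
  genomes <- simulate_admixed_cohort(hists, 24, fr, map)
  res <- paint_cohort(ref, genomes_to_panel(genomes), painting_params(),
                      paint_reference = FALSE)
  cv <- condense_copying_vectors(res)
  # realized European genome fraction, cM-weighted, from the truth labels
  true_eur <- vapply(genomes, function(g) {
    f <- true_ternary(g)
    f[["f_IE"]] / 2 + f[["f_EE"]]
  }, numeric(1))
  expect_gte(cor(cv[, "EUR_C"], true_eur), 0.9)
  # one-European-parent targets draw a large share from European donors
  f1 <- vapply(genomes, function(g) g$history$a_m == 1, logical(1))
  expect_gte(min(cv[f1, "EUR_C"]), 0.4)
})

test_that("outlier references are flagged from total chunk counts", {
  co <- make_paint_cohort(n_ref = 6)
  res <- paint_cohort(co$ref, targets = NULL, painting_params())
  expect_length(detect_outlier_references(res, z_threshold = Inf), 0)
  # equal totals within a population yield no exclusions
  res2 <- res
  res2$chunk_counts[res$is_reference, ] <- 1
  expect_length(detect_outlier_references(res2, z_threshold = 5), 0)
  # one planted inflated individual is exactly the excluded one
  res3 <- res
  victim <- co$ref$sample_ids[2]
  res3$chunk_counts[victim, ] <- res3$chunk_counts[victim, ] * 10
  out <- detect_outlier_references(res3, z_threshold = 2)
  expect_equal(out, victim, ignore_attr = TRUE)
  # tiny populations are skipped with a warning
  res4 <- paint_cohort(subset_panel(co$ref, co$ref$sample_ids[1:4]),
                       targets = NULL, painting_params())
  res4$donor_populations[] <- c("A", "A", "B", "B")
  expect_warning(expect_warning(detect_outlier_references(res4),
                                "population A"), "population B")
})

test_that("copying vectors condense and average into surrogates", {
  co <- make_paint_cohort()
  res <- paint_cohort(co$ref, co$targets, painting_params())
  cv <- condense_copying_vectors(res)
  expect_equal(unname(rowSums(cv)), rep(1, nrow(cv)), tolerance = 1e-8)
  sur <- surrogate_vectors(cv, res)
  expect_equal(unname(rowSums(sur)), rep(1, nrow(sur)), tolerance = 1e-8)
  # hand-computed average of two member vectors
  toy <- res
  toy$chunk_lengths <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE,
                              dimnames = list(c("x", "y"), c("x", "y")))
  toy$is_reference <- c(TRUE, TRUE)
  toy$donor_populations <- c(x = "P", y = "P")
  cv2 <- condense_copying_vectors(toy)
  expect_equal(unname(cv2[, 1]), c(1, 1))   # single population
  sur2 <- surrogate_vectors(cv2, toy)
  expect_equal(unname(sur2["P", ]), 1)
})
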