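test_that("fully diagnostic heterozygous genotypes force the z=1 state", {
  map <- uniform_genetic_map(1, 1, 200)
  w <- infer_diploid_ancestry(rep(1L, 200), 0.5, rep(1, 200), rep(0, 200),
                              map, local_ancestry_model(g = 3,
                                                        window_cm = 5))
  expect_true(all(w$post1 >= 0.999))
  expect_true(all(w$call == 1L))
})

test_that("window posteriors equal exhaustive path enumeration", {
  set.seed(91)
  for (i in 1:12) {
    L <- 6
    cm <- c(0, sort(runif(L - 1, 0.5, 60)))
    map <- genetic_map(rep("1", L), seq_len(L) * 1000L, cm)
    fE <- runif(L, 0.1, 0.9); fI <- runif(L, 0.1, 0.9)
    geno <- sample(0:2, L, TRUE)
    q <- runif(1, 0.1, 0.9); g <- sample(3:8, 1)
    win <- infer_diploid_ancestry(geno, q, fE, fI, map,
             local_ancestry_model(g = g, window_cm = diff(range(cm)) / 3))
    o <- diploid_oracle(geno, q, fE, fI, cm, g)
    ws <- admixpaint:::site_weights_cm(map)
    brk <- c(win$start_cm, win$end_cm[nrow(win)])
    bin <- pmin(findInterval(cm, brk, rightmost.closed = TRUE), nrow(win))
    for (b in unique(bin)) {
      ow <- colSums(o[bin == b, , drop = FALSE] * ws[bin == b]) /
        sum(ws[bin == b])
      expect_lt(max(abs(ow - as.numeric(win[b, c("post0", "post1",
                                                 "post2")]))), 1e-10)
    }
  }
})

test_that("an F1 genome is called heterozygous-ancestry almost everywhere", {
  set.seed(92)
  map <- uniform_genetic_map(5, 1, 3000)
  pm <- default_population_model(nrow(map))
  fr <- draw_population_frequencies(pm)
  g <- simulate_pedigree_genome(canonical_histories()$one_parent, fr, map)
  win <- infer_diploid_ancestry(genotypes(g), 0.5, fr[, "EUR_A"],
                                fr[, "INUIT"], map, local_ancestry_model())
  f <- compute_ternary(win)
  expect_gte(f[["f_IE"]], 0.95)
})

test_that("inference rejects invalid window and model settings", {
  map <- uniform_genetic_map(1, 1, 50)
  expect_error(local_ancestry_model(g = 0.5), "g must be")
  expect_error(local_ancestry_model(window_cm = 0), "window")
  expect_error(infer_diploid_ancestry(rep(1L, 50), 0.5, rep(0.5, 50),
                                      rep(0.5, 50), map,
                                      local_ancestry_model(window_cm = 500)),
               "exceeds chromosome")
})

test_that("cohort window filtering removes outlying windows only", {
  wins <- data.frame(chrom = "1", start_cm = 0:9, end_cm = 1:10, cm = 1,
                     post0 = 0.1, post1 = 0.8, post2 = 0.1, call = 1L)
  # 12 individuals with mean Inuit allele fraction 0.66 in every window
  calls <- c(replicate(4, transform(wins, call = 0L), simplify = FALSE),
             replicate(8, transform(wins, call = 1L), simplify = FALSE))
  filt <- filter_windows(calls)
  expect_equal(filt$n_removed, 0)
  expect_equal(unname(filt$window_mean_inuit[1]), (4 * 1 + 8 * 0.5) / 12)
  # forcing one window to 50% Inuit in everyone removes exactly it
  calls2 <- lapply(calls, function(d) { d$call[4] <- 1L; d })
  filt2 <- filter_windows(calls2)
  expect_false(filt2$retained[4])
  expect_equal(filt2$n_removed, 1)
  expect_equal(filt2$fraction_removed, 1 / 10)
  expect_error(filter_windows(calls, low = 0.8, high = 0.7), "low")
  # cohort-centred mode adapts the band
  filtc <- filter_windows(calls, center = "cohort", delta = 0.05)
  expect_equal(filtc$n_removed, 0)
})

test_that("ternary fractions aggregate retained windows by cM", {
  wins <- data.frame(chrom = "1", start_cm = 0:3, end_cm = 1:4,
                     cm = c(1, 1, 1, 1), post0 = NA, post1 = NA, post2 = NA,
                     call = c(1L, 1L, 1L, 1L))
  expect_equal(as.numeric(compute_ternary(wins)), c(0, 1, 0))
  wins$call <- c(0L, 0L, 2L, 2L)
  expect_equal(as.numeric(compute_ternary(wins)), c(0.5, 0, 0.5))
  expect_error(compute_ternary(wins, retained = rep(FALSE, 4)), "zero")
  # retained mask drops windows from the average
  wins$call <- c(0L, 1L, 1L, 1L)
  expect_equal(as.numeric(compute_ternary(wins, c(FALSE, TRUE, TRUE, TRUE))),
               c(0, 1, 0))
})

test_that("expected ternary fractions follow the closed form", {
  expect_equal(as.numeric(expected_ternary(1, 0)), c(0, 1, 0))
  expect_equal(as.numeric(expected_ternary(0.5, 0)), c(0.5, 0.5, 0))
  expect_equal(as.numeric(expected_ternary(0.5, 0.5)), c(0.25, 0.5, 0.25))
  h <- canonical_histories()$three_greatgrandparents
  expect_equal(as.numeric(expected_ternary(h)), c(0.25, 0.75, 0))
  expect_error(expected_ternary(1.2, 0), "must be in")
  # algebraic identity: components always sum to 1
  set.seed(93)
  for (i in 1:50) {
    f <- expected_ternary(runif(1), runif(1))
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("history classification applies its rules in order", {
  expect_equal(classify_history(ternary_fractions(0, 1, 0))$category,
               "one_european_parent")
  expect_equal(classify_history(ternary_fractions(0, 0.01, 0.99))$category,
               "two_european_parents")
  expect_equal(classify_history(ternary_fractions(0.3, 0.6, 0.1))$category,
               "other")
  expect_equal(classify_history(ternary_fractions(0.019, 0.95, 0.031),
                                tol = 0.02)$category, "one_european_parent")
  expect_error(classify_history(c(f_II = 0.5, f_IE = 0.2, f_EE = 0.2)),
               "sum to 1")
})

test_that("parent accounting reproduces its arithmetic contract", {
  pa <- parent_accounting(223, 27, 1582, 0.344)
  expect_equal(pa$n_parents, 277)
  expect_equal(pa$ancestor_fraction, 277 / (2 * 1582))
  expect_equal(pa$euro_ancestry_share, 0.5 * 277 / (1582 * 0.344))
  z <- parent_accounting(0, 0, 100, 0.3)
  expect_equal(unlist(z), c(n_parents = 0, ancestor_fraction = 0,
                            euro_ancestry_share = 0))
  expect_error(parent_accounting(1, 1, 0), "n_admixed")
  expect_error(parent_accounting(1, 1, 10, 1.5), "mean_euro_fraction")
})

test_that("inferred ternary fractions are invariant to phase errors", {
  set.seed(94)
  map <- uniform_genetic_map(4, 1, 1200)
  pm <- default_population_model(nrow(map))
  fr <- draw_population_frequencies(pm)
  h <- canonical_histories()$one_grandparent
  model <- local_ancestry_model()
  for (i in 1:5) {
    g <- simulate_pedigree_genome(h, fr, map)
    g2 <- inject_switch_errors(g, 0.05)
    w1 <- infer_diploid_ancestry(genotypes(g), 0.25, fr[, "EUR_A"],
                                 fr[, "INUIT"], map, model)
    w2 <- infer_diploid_ancestry(genotypes(g2), 0.25, fr[, "EUR_A"],
                                 fr[, "INUIT"], map, model)
    expect_lte(max(abs(as.numeric(compute_ternary(w1)) -
                       as.numeric(compute_ternary(w2)))), 1e-6)
  }
})
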