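#' Variant filtering for cohort construction
#'
#' Applies the standard pre-analysis site filters, in a fixed order:
#' region mask, multi-allelic sites, per-site missingness, singletons
#' (minor allele count 1), then minor allele frequency. Each filter's
#' removal count is reported against the sites that survived the previous
#' filters.
#'
#' @param geno sites x individuals matrix of allele-1 dosages (0/1/2, NA
#'   for missing).
#' @param miss_max maximum per-site missing rate (default 0.02).
#' @param maf_min minimum minor allele frequency; 0 disables (default 0).
#' @param remove_singletons drop sites with minor allele count 1.
#' @param mask logical vector per site: TRUE = masked region, removed
#'   first (e.g. MHC-like regions); NULL disables.
#' @param multiallelic logical vector per site: TRUE = more than two
#'   alleles observed upstream; NULL disables.
#' @param hwe_p if non-NULL, additionally remove sites with exact
#'   Hardy-Weinberg test p below this value. Note this is a standard exact
#'   HWE test assuming a homogeneous population, not an admixture-aware
#'   test; it is off by default.
#' @return A `variant_filter_report`: list with `removed` (named counts per
#'   filter), `surviving` (site indices), `n_input`.
#' @export
filter_variants <- function(geno, miss_max = 0.02, maf_min = 0,
                            remove_singletons = TRUE, mask = NULL,
                            multiallelic = NULL, hwe_p = NULL) {
  if (miss_max < 0 || miss_max > 1 || maf_min < 0 || maf_min > 1)
    stop("thresholds must be in [0, 1]")
  n_input <- nrow(geno)
  alive <- rep(TRUE, n_input)
  removed <- c(region_mask = 0L, multiallelic = 0L, missingness = 0L,
               singleton = 0L, maf = 0L, hwe = 0L)
  drop <- function(bad, what) {
    bad <- bad & alive
    removed[what] <<- sum(bad)
    alive[bad] <<- FALSE
  }
  if (!is.null(mask)) drop(mask, "region_mask")
  if (!is.null(multiallelic)) drop(multiallelic, "multiallelic")
  missr <- rowMeans(is.na(geno))
  drop(missr > miss_max, "missingness")
  ac <- rowSums(geno, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(geno))
  mac <- pmin(ac, an - ac)
  if (remove_singletons) drop(mac == 1L, "singleton")
  if (maf_min > 0) {
    maf <- ifelse(an > 0, mac / an, 0)
    drop(maf < maf_min, "maf")
  }
  if (!is.null(hwe_p)) {
    p <- apply(geno, 1, function(g) hwe_exact_p(sum(g == 1, na.rm = TRUE),
                                                sum(g == 0, na.rm = TRUE),
                                                sum(g == 2, na.rm = TRUE)))
    drop(p < hwe_p, "hwe")
  }
  structure(list(removed = removed, surviving = which(alive),
                 n_input = n_input),
            class = "variant_filter_report")
}

#' @export
print.variant_filter_report <- function(x, ...) {
  cat("variant_filter_report:", x$n_input, "sites in,",
      length(x$surviving), "surviving\n")
  print(x$removed)
  invisible(x)
}

# Exact Hardy-Weinberg test (two-sided, conditional on allele counts).
hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  if (n == 0) return(1)
  n1 <- n_het + 2 * min(n_hom_ref, n_hom_alt)  # minor allele count
  hets <- seq(n1 %% 2, n1, by = 2)
  logp <- lchoose(n, hets) + lgamma(n - hets + 1) -
    lgamma((n1 - hets) / 2 + 1) - lgamma(n - (n1 + hets) / 2 + 1) +
    hets * log(2)
  # probability of each heterozygote count given allele counts
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  sum(pr[pr <= pr[hets == n_het] * (1 + 1e-12)])
}

#' Supervised two-way global ancestry estimation
#'
#' Maximizes the binomial likelihood of an individual's genotypes under
#' per-site frequencies h_j = q f_Ej + (1-q) f_Ij by EM, where f_E and f_I
#' are the European-like and Inuit-like reference frequencies and q is the
#' individual's European ancestry proportion. The likelihood is
#' nondecreasing across iterations by construction of EM.
#'
#' @param geno allele-1 dosage vector (0/1/2, NA allowed) for one
#'   individual, or a sites x individuals matrix.
#' @param f_eur,f_inuit reference allele frequencies on the same sites.
#' @param tol convergence tolerance on q (default 1e-7).
#' @param max_iter maximum EM iterations.
#' @param eps frequency clipping bound avoiding log(0) (default 1e-6).
#' @return For a vector: list with `q`, `loglik`, `n_iter`, `flat`
#'   (TRUE when f_E = f_I everywhere and q is unidentifiable), and
#'   `loglik_trace`. For a matrix: data frame with one row per individual.
#' @export
estimate_global_ancestry <- function(geno, f_eur, f_inuit, tol = 1e-7,
                                     max_iter = 500, eps = 1e-6) {
  if (is.matrix(geno)) {
    res <- lapply(seq_len(ncol(geno)), function(i)
      estimate_global_ancestry(geno[, i], f_eur, f_inuit, tol, max_iter, eps))
    return(data.frame(sample = colnames(geno) %||% seq_len(ncol(geno)),
                      q = vapply(res, `[[`, numeric(1), "q"),
                      loglik = vapply(res, `[[`, numeric(1), "loglik"),
                      flat = vapply(res, `[[`, logical(1), "flat"),
                      stringsAsFactors = FALSE))
  }
  keep <- !is.na(geno)
  g <- geno[keep]
  fE <- pmin(pmax(f_eur[keep], eps), 1 - eps)
  fI <- pmin(pmax(f_inuit[keep], eps), 1 - eps)
  if (!length(g)) stop("no overlapping sites")
  ll <- function(q) {
    h <- q * fE + (1 - q) * fI
    sum(g * log(h) + (2 - g) * log(1 - h))
  }
  if (all(abs(fE - fI) < 1e-12))
    return(list(q = 0.5, loglik = ll(0.5), n_iter = 0L, flat = TRUE,
                loglik_trace = ll(0.5)))
  q <- 0.5
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    h <- q * fE + (1 - q) * fI
    trace <- c(trace, sum(g * log(h) + (2 - g) * log(1 - h)))
    a <- g * (q * fE / h) + (2 - g) * (q * (1 - fE) / (1 - h))
    q_new <- sum(a) / (2 * length(g))
    if (!is.finite(q_new)) stop("non-finite likelihood in ancestry EM")
    done <- abs(q_new - q) < tol
    q <- q_new
    if (done) break
  }
  list(q = q, loglik = ll(q), n_iter = it, flat = FALSE, loglik_trace = trace)
}

#' Split a cohort into unadmixed and admixed sets
#'
#' An individual is *unadmixed* when its Inuit ancestry (1 - q) strictly
#' exceeds `unadmixed_min_inuit`, and *admixed* when its European ancestry
#' q strictly exceeds `admixed_min_euro`. Individuals exactly at a
#' threshold fall into neither set (strict inequalities).
#'
#' @param q named vector of European ancestry proportions.
#' @param unadmixed_min_inuit default 0.99.
#' @param admixed_min_euro default 0.01.
#' @return List with `unadmixed`, `admixed` and `excluded` id vectors.
#' @export
split_cohort <- function(q, unadmixed_min_inuit = 0.99,
                         admixed_min_euro = 0.01) {
  if (unadmixed_min_inuit < 0 || unadmixed_min_inuit > 1 ||
      admixed_min_euro < 0 || admixed_min_euro > 1)
    stop("thresholds must be in [0, 1]")
  ids <- names(q) %||% as.character(seq_along(q))
  unad <- (1 - q) > unadmixed_min_inuit
  adm <- !unad & q > admixed_min_euro
  list(unadmixed = ids[unad], admixed = ids[adm],
       excluded = ids[!unad & !adm])
}

#' Admixture-aware pairwise relatedness
#'
#' Method-of-moments estimate of the IBD-sharing coefficients (k0, k1, k2)
#' for a pair of possibly admixed individuals. Expected genotype-pair
#' probabilities at each site are computed from individual-specific allele
#' frequencies h_i = q_i f_E + (1 - q_i) f_I (alleles shared identical by
#' descent are drawn at the pair-average frequency), and (k1, k2) solve a
#' variance-weighted least-squares fit of the observed 3 x 3
#' genotype-combination counts to their expectations under IBD 0/1/2
#' subject to k0 + k1 + k2 = 1.
#' Negative estimates are truncated to zero and the triple renormalized.
#' The coefficient of relatedness is r = k1/2 + k2.
#'
#' @param g1,g2 dosage vectors (0/1/2, NA allowed).
#' @param q1,q2 European ancestry proportions of the two individuals.
#' @param f_eur,f_inuit reference allele frequencies.
#' @param eps frequency clipping bound.
#' @return List with `k0`, `k1`, `k2`, `r`, `n_sites`.
#' @export
estimate_relatedness <- function(g1, g2, q1, q2, f_eur, f_inuit,
                                 eps = 1e-6) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  h1 <- pmin(pmax(q1 * f_eur[keep] + (1 - q1) * f_inuit[keep], eps), 1 - eps)
  h2 <- pmin(pmax(q2 * f_eur[keep] + (1 - q2) * f_inuit[keep], eps), 1 - eps)
  if (!length(g1) || all(h1 %in% c(eps, 1 - eps)))
    stop("no informative sites for relatedness")
  hs <- (h1 + h2) / 2
  d2 <- function(i, p) dbinom(i, 2, p)
  d1 <- function(i, p) if (i < 0 || i > 1) rep(0, length(p)) else dbinom(i, 1, p)
  O <- numeric(9); E0 <- numeric(9); E1 <- numeric(9); E2 <- numeric(9)
  idx <- 0L
  for (i in 0:2) for (j in 0:2) {
    idx <- idx + 1L
    O[idx] <- sum(g1 == i & g2 == j)
    E0[idx] <- sum(d2(i, h1) * d2(j, h2))
    E1[idx] <- sum((1 - hs) * d1(i, h1) * d1(j, h2) +
                   hs * d1(i - 1, h1) * d1(j - 1, h2))
    E2[idx] <- if (i == j) sum(d2(i, hs)) else 0
  }
  # weight combos by inverse expected count (Poisson-scale variance)
  w <- sqrt(1 / pmax((E0 + E1 + E2) / 3, 1))
  X <- cbind(E1 - E0, E2 - E0) * w
  k <- tryCatch(qr.solve(X, (O - E0) * w), error = function(e) c(0, 0))
  k <- c(1 - sum(k), k)
  k <- pmax(k, 0)
  k <- k / sum(k)
  list(k0 = k[1], k1 = k[2], k2 = k[3],
       r = min(max(k[2] / 2 + k[3], 0), 1), n_sites = length(g1))
}

#' Pairwise relatedness for a cohort
#'
#' @param geno sites x individuals dosage matrix with sample ids as
#'   column names.
#' @param q named European ancestry vector per individual.
#' @param f_eur,f_inuit reference allele frequencies.
#' @return Data frame with `id1`, `id2`, `k0`, `k1`, `k2`, `r`.
#' @export
pairwise_relatedness <- function(geno, q, f_eur, f_inuit) {
  ids <- colnames(geno)
  pairs <- combn(ids, 2)
  out <- apply(pairs, 2, function(p) {
    r <- estimate_relatedness(geno[, p[1]], geno[, p[2]],
                              q[[p[1]]], q[[p[2]]], f_eur, f_inuit)
    c(r$k0, r$k1, r$k2, r$r)
  })
  data.frame(id1 = pairs[1, ], id2 = pairs[2, ], k0 = out[1, ],
             k1 = out[2, ], k2 = out[3, ], r = out[4, ],
             stringsAsFactors = FALSE)
}

#' Prune related individuals
#'
#' Greedy removal: repeatedly drop the individual participating in the
#' most pairs with relatedness above the threshold; ties are broken by
#' lowest call rate (when supplied), then lexicographically smallest id.
#' Stops when no pair above the threshold remains.
#'
#' @param pairs data frame with columns `id1`, `id2`, `r`.
#' @param threshold relatedness cutoff (default 0.2, i.e. closer than
#'   second-degree relatives).
#' @param ids full id set to retain from (default: ids seen in `pairs`).
#' @param call_rate optional named per-individual call rates for
#'   tie-breaking.
#' @return Character vector of retained ids.
#' @export
prune_relatives <- function(pairs, threshold = 0.2, ids = NULL,
                            call_rate = NULL) {
  ids <- ids %||% sort(unique(c(pairs$id1, pairs$id2)))
  bad <- pairs[pairs$r > threshold, c("id1", "id2"), drop = FALSE]
  dropped <- character(0)
  while (nrow(bad) > 0) {
    counts <- table(c(bad$id1, bad$id2))
    cand <- names(counts)[counts == max(counts)]
    if (length(cand) > 1 && !is.null(call_rate)) {
      cr <- call_rate[cand]
      cand <- cand[cr == min(cr)]
    }
    victim <- sort(cand)[1]
    dropped <- c(dropped, victim)
    bad <- bad[bad$id1 != victim & bad$id2 != victim, , drop = FALSE]
  }
  setdiff(ids, dropped)
}
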