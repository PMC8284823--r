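#' Painting model parameters
#'
#' The haplotype-copying HMM has two global parameters: `Ne`, a unitless
#' switch-rate scale multiplying genetic distance (the probability that the
#' copied donor switches across a gap of d Morgans is 1 - exp(-Ne d)), and
#' `mu`, the per-site probability of copying a mismatching allele. The
#' defaults are the values estimated by EM on the cohort this model family
#' was developed for (Ne = 103.35, mu = 2.04e-5).
#'
#' @param Ne switch-rate scale, > 0.
#' @param mu mismatch probability in \[0, 0.5\].
#' @return An object of class `painting_params`.
#' @export
painting_params <- function(Ne = 103.35, mu = 2.04e-5) {
  if (!is.finite(Ne) || Ne <= 0) stop("Ne must be > 0")
  if (!is.finite(mu) || mu < 0 || mu > 0.5) stop("mu must be in [0, 0.5]")
  structure(list(Ne = Ne, mu = mu), class = "painting_params")
}

# Forward-backward painting of one haplotype on one chromosome.
# target: length-L 0/1 vector; donorsT: K_all x L transposed donor matrix;
# use0: 0-based rows of donorsT forming the donor set; cm: length-L map
# positions; w: per-site cM weights. Returns expected chunk lengths and
# counts per used donor haplotype, the log-likelihood, and the E-step
# expectations needed for EM (expected mismatch count, per-gap expected
# switch-event probabilities).
paint_hap_chrom <- function(target, donorsT, use0, cm, w, Ne, mu) {
  d <- diff(cm) / 100                       # gap lengths in Morgans
  rho <- 1 - exp(-Ne * d)
  r <- paint_fb_cpp(donorsT, as.integer(target), as.integer(use0), rho, w, mu)
  list(lengths = r$lengths, counts = r$counts, loglik = r$loglik,
       mismatch_exp = r$mismatch_exp, switch_d = d, switch_e = r$switch_e)
}

# transposed per-chromosome donor matrices (site = contiguous column)
transpose_by_chrom <- function(haps, map) {
  lapply(map_chrom_index(map), function(idx)
    t(haps[idx, , drop = FALSE]))
}

#' Paint a target haplotype against a reference panel
#'
#' Runs the haplotype-copying HMM (hidden state = which donor haplotype is
#' being copied; uniform initial and re-selection distribution over donors;
#' emission 1-mu on allele match, mu on mismatch) by scaled
#' forward-backward, chromosome by chromosome, and returns each donor
#' haplotype's expected chunk length (cM of genome copied from it; each
#' site owns half the map gap to each neighbour, so lengths sum exactly to
#' the painted map length) and expected chunk count (expected number of
#' distinct copied segments; a chromosome start counts as one segment
#' entry and switch events that re-select the same donor do not).
#'
#' @param target 0/1 allele vector over the map's sites.
#' @param donors sites x K matrix of donor haplotypes (the target must not
#'   be among them).
#' @param params a [painting_params()].
#' @param map `genetic_map` with one row per site.
#' @return List with `chunk_lengths` (K), `chunk_counts` (K), `loglik`, and
#'   internal E-step accumulators used by [em_estimate_params()].
#' @export
paint_haplotype <- function(target, donors, params, map) {
  stopifnot(inherits(params, "painting_params"))
  donors <- as.matrix(donors)
  if (ncol(donors) < 1) stop("donor panel is empty")
  if (length(target) != nrow(map) || nrow(donors) != nrow(map))
    stop("target/donors must have one row per map site")
  if (!all(target %in% c(0L, 1L)) || !all(donors %in% c(0L, 1L)))
    stop("painting requires biallelic 0/1 haplotypes")
  if (map_total_cm(map) <= 0) stop("zero-length genetic map")
  w <- site_weights_cm(map)
  K <- ncol(donors)
  donorsT <- transpose_by_chrom(donors, map)
  lengths <- numeric(K); counts <- numeric(K); loglik <- 0
  mism <- 0; n_painted <- 0L
  sw_d <- list(); sw_e <- list()
  chroms <- map_chrom_index(map)
  for (ci in seq_along(chroms)) {
    idx <- chroms[[ci]]
    r <- paint_hap_chrom(target[idx], donorsT[[ci]], seq_len(K) - 1L,
                         map$cm[idx], w[idx], params$Ne, params$mu)
    lengths <- lengths + r$lengths
    counts <- counts + r$counts
    loglik <- loglik + r$loglik
    mism <- mism + r$mismatch_exp
    n_painted <- n_painted + length(idx)
    sw_d[[length(sw_d) + 1L]] <- r$switch_d
    sw_e[[length(sw_e) + 1L]] <- r$switch_e
  }
  names(lengths) <- names(counts) <- colnames(donors)
  list(chunk_lengths = lengths, chunk_counts = counts, loglik = loglik,
       mismatch_exp = mism, n_sites = n_painted,
       switch_d = unlist(sw_d), switch_e = unlist(sw_e))
}

# M-step for Ne: maximize sum_t [ s_t log(1-exp(-Ne d_t)) - (1-s_t) Ne d_t ]
# over log10(Ne) in [-3, 6]. s_t = expected switch probability at gap t.
mstep_ne <- function(d, s) {
  if (!length(d)) return(NA_real_)
  obj <- function(lne) {
    ne <- 10^lne
    q <- pmax(1 - exp(-ne * d), 1e-300)
    sum(s * log(q) - (1 - s) * ne * d)
  }
  10^optimize(obj, c(-3, 6), maximum = TRUE)$maximum
}

#' EM estimation of the painting parameters
#'
#' Paints each selected individual's haplotypes leave-own-individual-out
#' against the panel, accumulates the expected numbers of switch events and
#' allele mismatches (E-step), and updates `Ne` and `mu` in closed form /
#' by one-dimensional maximization (M-step). Per-chromosome estimates are
#' combined by a map-length-weighted mean. The observed-data log-likelihood
#' is tracked and must be nondecreasing (up to numerical tolerance).
#'
#' @param panel a `haplotype_panel` of reference individuals.
#' @param individuals sample ids to use (default: all panel members).
#' @param params starting [painting_params()].
#' @param n_iter number of EM iterations (0 returns `params` unchanged).
#' @param mu_floor lower bound for the mismatch estimate (default 1e-9).
#' @return A [painting_params()] with attributes `loglik` (trajectory) and
#'   `per_chrom` (final per-chromosome estimates).
#' @export
em_estimate_params <- function(panel, individuals = panel$sample_ids,
                               params = painting_params(Ne = 100, mu = 1e-3),
                               n_iter = 10, mu_floor = 1e-9) {
  stopifnot(n_iter >= 0)
  if (n_iter == 0) return(params)
  map <- panel$map
  chrom_idx <- map_chrom_index(map)
  chroms <- names(chrom_idx)
  wchr <- map_lengths(map)[chroms]
  w <- site_weights_cm(map)
  logliks <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    mism <- setNames(numeric(length(chroms)), chroms)
    nsite <- setNames(numeric(length(chroms)), chroms)
    sw_d <- setNames(vector("list", length(chroms)), chroms)
    sw_e <- setNames(vector("list", length(chroms)), chroms)
    total_ll <- 0
    if (it == 1) donorsT <- transpose_by_chrom(panel$haps, map)
    for (id in individuals) {
      own <- panel$hap_sample == id
      use0 <- which(!own) - 1L
      for (h in which(own)) {
        target <- panel$haps[, h]
        for (ci in seq_along(chroms)) {
          idx <- chrom_idx[[ci]]
          r <- paint_hap_chrom(target[idx], donorsT[[ci]], use0,
                               map$cm[idx], w[idx], params$Ne, params$mu)
          total_ll <- total_ll + r$loglik
          mism[ci] <- mism[ci] + r$mismatch_exp
          nsite[ci] <- nsite[ci] + length(idx)
          sw_d[[ci]] <- c(sw_d[[ci]], r$switch_d)
          sw_e[[ci]] <- c(sw_e[[ci]], r$switch_e)
        }
      }
    }
    logliks[it] <- total_ll
    if (it > 1 && total_ll < logliks[it - 1] - 1e-6 * abs(logliks[it - 1]))
      stop("EM log-likelihood decreased; model assumptions violated")
    mu_chr <- pmin(pmax(mism / nsite, mu_floor), 0.5)
    ne_chr <- vapply(chroms, function(ch) mstep_ne(sw_d[[ch]], sw_e[[ch]]),
                     numeric(1))
    ne_chr <- pmin(pmax(ne_chr, 1e-3), 1e6)
    params <- painting_params(Ne = sum(wchr * ne_chr) / sum(wchr),
                              mu = max(sum(wchr * mu_chr) / sum(wchr),
                                       mu_floor))
  }
  attr(params, "loglik") <- logliks
  attr(params, "per_chrom") <- data.frame(chrom = chroms, Ne = ne_chr,
                                          mu = mu_chr, weight_cm = wchr)
  params
}

#' Convert simulated genomes to a haplotype panel
#'
#' @param genomes list of `simulated_genome` objects sharing a map.
#' @param population label assigned to all individuals (default "ADMIXED").
#' @return A `haplotype_panel`.
#' @export
genomes_to_panel <- function(genomes, population = "ADMIXED") {
  stopifnot(length(genomes) >= 1)
  haps <- do.call(cbind, lapply(genomes, `[[`, "haps"))
  ids <- vapply(genomes, `[[`, character(1), "sample_id")
  new_haplotype_panel(haps, ids, rep(population, length(ids)),
                      genomes[[1]]$map)
}

#' Paint a whole cohort and assemble the coancestry matrix
#'
#' Reference individuals are painted leave-own-individual-out (both of
#' their own haplotypes excluded from the donor set); admixed targets are
#' painted against the full reference panel. A diploid individual's result
#' is the sum over its two haplotypes, and donor haplotypes are aggregated
#' to donor individuals.
#'
#' @param reference `haplotype_panel` of reference individuals.
#' @param targets optional `haplotype_panel` of admixed targets (no sample
#'   id may collide with a reference id).
#' @param params a [painting_params()].
#' @param paint_reference also paint the reference individuals themselves
#'   (default TRUE).
#' @return An object of class `coancestry` with matrices `chunk_lengths`
#'   and `chunk_counts` ((n_ref + n_target) x n_ref, rows = painted
#'   individuals, columns = donor individuals), logical `is_reference` per
#'   row, `donor_populations`, and `map_cm` (painted map length).
#' @export
paint_cohort <- function(reference, targets = NULL, params = painting_params(),
                         paint_reference = TRUE) {
  map <- reference$map
  n_ref <- length(reference$sample_ids)
  tids <- character(0)
  if (!is.null(targets)) {
    if (length(intersect(targets$sample_ids, reference$sample_ids)))
      stop("target ids overlap reference ids")
    tids <- targets$sample_ids
  }
  rows <- c(if (paint_reference) reference$sample_ids else character(0), tids)
  CL <- matrix(0, length(rows), n_ref,
               dimnames = list(rows, reference$sample_ids))
  CC <- CL
  chrom_idx <- map_chrom_index(map)
  w <- site_weights_cm(map)
  donorsT <- transpose_by_chrom(reference$haps, map)
  all0 <- seq_len(2L * n_ref) - 1L
  agg <- function(x) # donor haplotype totals -> donor individual totals
    x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]
  # paint one diploid individual: sum chunk lengths/counts over both
  # haplotypes, expanded back onto the full donor-haplotype axis
  paint_ind <- function(haps2, use0) {
    cl <- numeric(2L * n_ref)
    cc <- numeric(2L * n_ref)
    for (h in 1:2) for (ci in seq_along(chrom_idx)) {
      idx <- chrom_idx[[ci]]
      r <- paint_hap_chrom(haps2[idx, h], donorsT[[ci]], use0,
                           map$cm[idx], w[idx], params$Ne, params$mu)
      cl[use0 + 1L] <- cl[use0 + 1L] + r$lengths
      cc[use0 + 1L] <- cc[use0 + 1L] + r$counts
    }
    list(cl = cl, cc = cc)
  }
  if (paint_reference) {
    for (id in reference$sample_ids) {
      own <- reference$hap_sample == id
      r <- paint_ind(reference$haps[, own, drop = FALSE],
                     all0[!own])
      CL[id, ] <- agg(r$cl)
      CC[id, ] <- agg(r$cc)
    }
  }
  for (id in tids) {
    own <- targets$hap_sample == id
    r <- paint_ind(targets$haps[, own, drop = FALSE], all0)
    CL[id, ] <- agg(r$cl)
    CC[id, ] <- agg(r$cc)
  }
  structure(list(chunk_lengths = CL, chunk_counts = CC,
                 is_reference = rows %in% reference$sample_ids,
                 donor_populations = reference$populations,
                 map_cm = map_total_cm(map)),
            class = "coancestry")
}

#' @export
print.coancestry <- function(x, ...) {
  cat("coancestry:", nrow(x$chunk_lengths), "painted individuals x",
      ncol(x$chunk_lengths), "donors;",
      sum(x$is_reference), "reference rows; map",
      round(x$map_cm, 1), "cM\n")
  invisible(x)
}

#' Detect outlier reference individuals from total chunk counts
#'
#' Within each reference population, z-scores each member's total chunk
#' count against the population mean and standard deviation; individuals
#' with atypically high totals (z above the threshold; optionally
#' two-sided) are flagged for exclusion. Populations with fewer than three
#' members are skipped with a warning.
#'
#' @param coancestry a `coancestry` from [paint_cohort()].
#' @param z_threshold exclusion threshold (default 5).
#' @param two_sided also exclude atypically low totals (default FALSE).
#' @return Character vector of excluded sample ids (with a `zscore`
#'   attribute giving all reference z-scores).
#' @export
detect_outlier_references <- function(coancestry, z_threshold = 5,
                                      two_sided = FALSE) {
  ref <- rownames(coancestry$chunk_counts)[coancestry$is_reference]
  totals <- rowSums(coancestry$chunk_counts[ref, , drop = FALSE])
  pops <- coancestry$donor_populations[ref]
  z <- setNames(rep(NA_real_, length(ref)), ref)
  for (p in unique(pops)) {
    members <- ref[pops == p]
    if (length(members) < 3) {
      warning("population ", p, " has fewer than 3 members; skipped")
      next
    }
    mu <- mean(totals[members]); s <- sd(totals[members])
    z[members] <- if (s > 0) (totals[members] - mu) / s else 0
  }
  zz <- if (two_sided) abs(z) else z
  excluded <- names(z)[!is.na(zz) & zz > z_threshold]
  attr(excluded, "zscore") <- z
  excluded
}

#' Condense a coancestry matrix into per-population copying vectors
#'
#' Sums each painted individual's donor-individual chunk lengths within
#' donor populations and normalizes to 1, giving the proportion of the
#' genome painted by each reference population (normalization is
#' genome-wide, not per chromosome).
#'
#' @param coancestry a `coancestry` object.
#' @param use counts instead of lengths if `"counts"`.
#' @return Matrix, painted individuals x reference populations, rows
#'   summing to 1.
#' @export
condense_copying_vectors <- function(coancestry, use = c("lengths", "counts")) {
  use <- match.arg(use)
  M <- if (use == "lengths") coancestry$chunk_lengths else coancestry$chunk_counts
  pops <- coancestry$donor_populations[colnames(M)]
  if (anyNA(pops)) stop("population label missing for some donors")
  bypop <- t(rowsum(t(M), group = pops, reorder = TRUE))
  sweep(bypop, 1, rowSums(bypop), "/")
}

#' Per-population surrogate copying vectors
#'
#' Averages the normalized copying vectors of each reference population's
#' own members, yielding one surrogate vector per candidate source — the
#' mixture components used by the source-decomposition MCMC.
#'
#' @param copy_vectors matrix from [condense_copying_vectors()].
#' @param coancestry the `coancestry` the vectors came from.
#' @return Matrix, reference populations (rows) x populations (columns);
#'   each row sums to 1.
#' @export
surrogate_vectors <- function(copy_vectors, coancestry) {
  ref <- rownames(copy_vectors)[coancestry$is_reference]
  pops <- coancestry$donor_populations[ref]
  out <- rowsum(copy_vectors[ref, , drop = FALSE], group = pops,
                reorder = TRUE)
  sweep(out, 1, as.vector(table(pops)[rownames(out)]), "/")
}
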