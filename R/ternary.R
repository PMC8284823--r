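#' Ternary ancestry fractions
#'
#' The cM-weighted fractions of a genome carrying two Inuit alleles
#' (`f_II`), one Inuit and one European allele (`f_IE`), and two European
#' alleles (`f_EE`). They sum to 1 and are robust to phasing switch errors
#' because they depend only on unordered per-site ancestry.
#'
#' @param f_II,f_IE,f_EE fractions in \[0, 1\] summing to 1.
#' @return Named numeric vector of class `ternary_fractions`.
#' @export
ternary_fractions <- function(f_II, f_IE, f_EE) {
  f <- c(f_II = unname(f_II), f_IE = unname(f_IE), f_EE = unname(f_EE))
  if (any(f < -1e-8) || any(f > 1 + 1e-8))
    stop("ternary fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-6)
    stop("ternary fractions must sum to 1")
  structure(pmin(pmax(f, 0), 1), class = "ternary_fractions")
}

#' Local-ancestry model settings
#'
#' @param g generations since admixture (>= 1); per-haplotype ancestry
#'   switches occur at intensity g per Morgan. The timing analysis is run
#'   at both g = 3 and g = 8 to check robustness; the default is 8.
#' @param window_cm width of the reporting windows in cM (default 0.2).
#' @return An object of class `local_ancestry_model`.
#' @export
local_ancestry_model <- function(g = 8, window_cm = 0.2) {
  if (g < 1) stop("g must be >= 1")
  if (window_cm <= 0) stop("window size must be > 0")
  structure(list(g = g, window_cm = window_cm),
            class = "local_ancestry_model")
}

# 3x3 diploid transition matrix over a gap of d Morgans: two independent
# per-haplotype 2-state chains (switch rate g per Morgan, stationary
# European probability q), lumped to z = number of European alleles.
diploid_transition <- function(d, g, q) {
  r <- 1 - exp(-g * d)
  hEE <- 1 - r + r * q; hEI <- r * (1 - q)
  hIE <- r * q;         hII <- 1 - r + r * (1 - q)
  rbind(c(hII^2, 2 * hIE * hII, hIE^2),
        c(hEI * hII, hEE * hII + hEI * hIE, hEE * hIE),
        c(hEI^2, 2 * hEE * hEI, hEE^2))
}

# site x 3 emission matrix P(genotype | z European alleles)
diploid_emission <- function(geno, f_eur, f_inuit, eps = 1e-6) {
  fE <- pmin(pmax(f_eur, eps), 1 - eps)
  fI <- pmin(pmax(f_inuit, eps), 1 - eps)
  E <- cbind(dbinom(geno, 2, fI),
             ifelse(geno == 0, (1 - fE) * (1 - fI),
                    ifelse(geno == 1, fE * (1 - fI) + fI * (1 - fE),
                           fE * fI)),
             dbinom(geno, 2, fE))
  E[is.na(geno), ] <- 1
  E
}

#' Diploid local-ancestry inference on unphased genotypes
#'
#' A 3-state HMM on z = the number of European alleles at each site.
#' Phase is deliberately ignored: each haplotype's ancestry switches at
#' intensity g per Morgan and the two haplotypes are combined
#' independently, so the transition matrix is the binomial combination of
#' two 2-state chains with stationary European probability q. Emissions
#' convolve allele draws from the European and Inuit reference
#' frequencies. Site posteriors from forward-backward are cM-weight
#' averaged within fixed windows; each window's call is the argmax state.
#'
#' @param geno dosage vector (0/1/2, NA allowed) over the map's sites.
#' @param q the individual's global European ancestry proportion (used as
#'   the per-haplotype stationary probability).
#' @param f_eur,f_inuit per-site reference allele frequencies.
#' @param map `genetic_map`.
#' @param model a [local_ancestry_model()].
#' @return Data frame with one row per window: `chrom`, `start_cm`,
#'   `end_cm`, `cm`, `post0`, `post1`, `post2`, `call` (0/1/2; NA for
#'   windows containing no site).
#' @export
infer_diploid_ancestry <- function(geno, q, f_eur, f_inuit, map,
                                   model = local_ancestry_model()) {
  stopifnot(inherits(model, "local_ancestry_model"),
            length(geno) == nrow(map))
  q <- min(max(q, 1e-6), 1 - 1e-6)
  Emat <- diploid_emission(geno, f_eur, f_inuit)
  out <- list()
  loglik_total <- 0
  wsite_all <- site_weights_cm(map)
  chrom_idx <- map_chrom_index(map)
  for (ch in names(chrom_idx)) {
    idx <- chrom_idx[[ch]]
    cm <- map$cm[idx]
    chrom_len <- diff(range(cm))
    if (model$window_cm > chrom_len)
      stop("window size exceeds chromosome ", ch, " length")
    E <- Emat[idx, , drop = FALSE]
    L <- length(idx)
    d <- diff(cm) / 100
    fb <- diploid_fb_cpp(E, d, model$g, q)
    gam <- fb$gamma
    loglik_total <- loglik_total + fb$loglik
    # windows on the cM axis
    brk <- seq(cm[1], cm[L], by = model$window_cm)
    if (brk[length(brk)] < cm[L]) brk <- c(brk, cm[L])
    wsite <- wsite_all[idx]
    bin <- pmin(findInterval(cm, brk, rightmost.closed = TRUE),
                length(brk) - 1)
    nwin <- length(brk) - 1
    P <- matrix(NA_real_, nwin, 3)
    ww <- rowsum(wsite, bin)
    agg <- rowsum(gam * wsite, bin)
    filled <- as.integer(rownames(agg))
    P[filled, ] <- agg / as.vector(ww)
    call <- ifelse(is.na(P[, 1]), NA_integer_,
                   max.col(replace(P, is.na(P), 0), ties.method = "first") - 1L)
    out[[ch]] <- data.frame(chrom = ch, start_cm = brk[-length(brk)],
                            end_cm = brk[-1], cm = diff(brk),
                            post0 = P[, 1], post1 = P[, 2], post2 = P[, 3],
                            call = call, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "loglik") <- loglik_total
  res
}

#' Filter outlier local-ancestry windows across a cohort
#'
#' Computes, per window, the cohort-mean Inuit allele fraction from the
#' window calls ((2 - call)/2 averaged over individuals) and removes
#' windows whose cohort mean falls outside the accepted band — regions
#' where local-ancestry inference misbehaves systematically (e.g.
#' chromosome edges). The default band is the absolute interval
#' \[0.625, 0.725\]; alternatively the band can be centred on the cohort
#' mean (`center = "cohort"`) with half-width `delta`.
#'
#' @param calls list of per-individual window data frames from
#'   [infer_diploid_ancestry()] (identical window layout).
#' @param low,high absolute band bounds (defaults 0.625 and 0.725).
#' @param center `"absolute"` (default) or `"cohort"`.
#' @param delta half-width of the band in cohort mode (default 0.05).
#' @return List with `retained` (logical per window), `window_mean_inuit`,
#'   `n_removed`, `fraction_removed`.
#' @export
filter_windows <- function(calls, low = 0.625, high = 0.725,
                           center = c("absolute", "cohort"), delta = 0.05) {
  center <- match.arg(center)
  if (low >= high) stop("low must be < high")
  cmat <- vapply(calls, function(d) d$call, numeric(nrow(calls[[1]])))
  inuit <- rowMeans((2 - cmat) / 2, na.rm = TRUE)
  if (center == "cohort") {
    mid <- mean(inuit, na.rm = TRUE)
    low <- mid - delta; high <- mid + delta
  }
  retained <- !is.na(inuit) & inuit >= low & inuit <= high
  list(retained = retained, window_mean_inuit = inuit,
       n_removed = sum(!retained), n_windows = length(retained),
       fraction_removed = mean(!retained), low = low, high = high)
}

#' Ternary fractions from window calls
#'
#' cM-weighted fractions of retained windows called z = 0, 1 and 2
#' European alleles.
#'
#' @param windows per-individual window data frame.
#' @param retained logical per window (default: all with a call).
#' @return A [ternary_fractions()] vector.
#' @export
compute_ternary <- function(windows, retained = NULL) {
  keep <- !is.na(windows$call)
  if (!is.null(retained)) keep <- keep & retained
  w <- windows$cm[keep]
  if (sum(w) <= 0) stop("zero retained cM")
  z <- windows$call[keep]
  ternary_fractions(sum(w[z == 0]) / sum(w), sum(w[z == 1]) / sum(w),
                    sum(w[z == 2]) / sum(w))
}

#' Expected ternary fractions under a pedigree history
#'
#' With a_m and a_f the expected European ancestry of the maternally and
#' paternally transmitted gametes, the expected fractions are
#' f_II = (1-a_m)(1-a_f), f_IE = a_m(1-a_f) + (1-a_m)a_f, f_EE = a_m a_f.
#' An individual with one fully European parent (a = 1 on one side) has
#' f_II = 0 and so lies on the ternary plot's European-parent axis.
#'
#' @param history an [admixture_history()], or a numeric `a_m`.
#' @param a_f paternal-gamete European ancestry when `history` is numeric.
#' @return A [ternary_fractions()] vector.
#' @export
expected_ternary <- function(history, a_f = NULL) {
  if (inherits(history, "admixture_history")) {
    a_m <- history$a_m; a_f <- history$a_f
  } else {
    a_m <- history
  }
  if (a_m < 0 || a_m > 1 || a_f < 0 || a_f > 1)
    stop("gamete ancestry fractions must be in [0, 1]")
  ternary_fractions((1 - a_m) * (1 - a_f),
                    a_m * (1 - a_f) + (1 - a_m) * a_f,
                    a_m * a_f)
}

#' Classify an individual's recent admixture history
#'
#' Rules, applied in order: `two_european_parents` when f_EE >= 1 - tol
#' (two European alleles at nearly every position); else
#' `one_european_parent` when f_II <= tol (no genomic region with two
#' Inuit alleles, the signature of at least one fully European parent);
#' else `other`.
#'
#' @param fractions a [ternary_fractions()] vector.
#' @param tol classification tolerance (default 0.02).
#' @return An object of class `history_call`: list with `category` and the
#'   supporting `fractions`.
#' @export
classify_history <- function(fractions, tol = 0.02) {
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1")
  category <- if (fractions[["f_EE"]] >= 1 - tol) "two_european_parents"
  else if (fractions[["f_II"]] <= tol) "one_european_parent"
  else "other"
  structure(list(category = category, fractions = fractions, tol = tol),
            class = "history_call")
}

#' European-parent accounting
#'
#' Given the number of admixed individuals classified as having exactly
#' one fully European parent and as having two, computes the implied
#' number of European-ancestry parents, the fraction those parents make up
#' of all parents of the admixed set, and (when the cohort's mean European
#' ancestry fraction is supplied) the share of the total European ancestry
#' attributable to those parents.
#'
#' @param n_one_parent individuals with exactly one European parent.
#' @param n_two_parents individuals with two European parents.
#' @param n_admixed total admixed individuals (> 0).
#' @param mean_euro_fraction cohort mean European ancestry in (0, 1\];
#'   optional.
#' @return List with `n_parents`, `ancestor_fraction`,
#'   `euro_ancestry_share` (NA when `mean_euro_fraction` is missing).
#' @examples
#' parent_accounting(223, 27, 1582, 0.344)
#' @export
parent_accounting <- function(n_one_parent, n_two_parents, n_admixed,
                              mean_euro_fraction = NULL) {
  if (n_admixed <= 0) stop("n_admixed must be > 0")
  n_parents <- n_one_parent + 2 * n_two_parents
  if (n_parents == 0)
    return(list(n_parents = 0, ancestor_fraction = 0,
                euro_ancestry_share = 0))
  share <- NA_real_
  if (!is.null(mean_euro_fraction)) {
    if (mean_euro_fraction <= 0 || mean_euro_fraction > 1)
      stop("mean_euro_fraction must be in (0, 1]")
    # each European parent contributes half its child's genome
    share <- 0.5 * n_parents / (n_admixed * mean_euro_fraction)
  }
  list(n_parents = n_parents,
       ancestor_fraction = n_parents / (2 * n_admixed),
       euro_ancestry_share = share)
}
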