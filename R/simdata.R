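#' Population allele-frequency model
#'
#' Describes a set of source populations that drifted independently from a
#' shared ancestral population under the Balding-Nichols model: population
#' frequencies at a site with ancestral frequency p are
#' Beta(p(1-F)/F, (1-p)(1-F)/F), where F is an FST-like drift parameter.
#' F = 0 means no drift (population frequencies equal the ancestral ones).
#'
#' @param ancestral numeric vector of ancestral allele frequencies, all
#'   strictly inside (0, 1).
#' @param F named numeric vector of per-population drift parameters
#'   (>= 0); the names are the population labels.
#' @return An object of class `population_model`.
#' @examples
#' pm <- population_model(runif(100, 0.1, 0.9), c(POP_A = 0.02, POP_B = 0.1))
#' freqs <- draw_population_frequencies(pm, seed = 1)
#' @export
population_model <- function(ancestral, F) {
  if (any(!is.finite(ancestral)) || any(ancestral <= 0) || any(ancestral >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1)")
  if (any(F < 0)) stop("drift parameter F must be >= 0")
  if (is.null(names(F)) || anyDuplicated(names(F)))
    stop("F must be a named vector with unique population labels")
  structure(list(ancestral = as.numeric(ancestral), F = F,
                 n_sites = length(ancestral),
                 populations = names(F)),
            class = "population_model")
}

#' Draw per-population allele frequencies
#'
#' Samples each population's site frequencies under the Balding-Nichols
#' model of the supplied [population_model()]. Deterministic given `seed`.
#'
#' @param model a `population_model`.
#' @param seed optional integer seed.
#' @return Numeric matrix, sites x populations, with population labels as
#'   column names.
#' @export
draw_population_frequencies <- function(model, seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  p <- model$ancestral
  out <- vapply(model$populations, function(pop) {
    F <- model$F[[pop]]
    if (F == 0) return(p)
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }, numeric(length(p)))
  colnames(out) <- model$populations
  out
}

#' Default synthetic study design
#'
#' One strongly diverged "Inuit-like" source plus several weakly diverged
#' "European-like" country sources, mirroring the reference structure the
#' painting and source-decomposition analyses assume. All parameters are
#' overridable.
#'
#' @param n_sites number of sites.
#' @param inuit_F drift of the Inuit-like source vs the ancestral
#'   population (default 0.15).
#' @param euro_F drift parameters of the European-like sources; the default
#'   five values step by 0.02 so that pairwise differentiation among them
#'   stays weak (Hudson FST on the order of 0.002-0.05) while keeping the
#'   sources statistically separable at desk scale.
#' @param seed seed for the ancestral frequency draw.
#' @return A `population_model` with populations `INUIT`, `EUR_A`, ...
#' @export
default_population_model <- function(n_sites = 2000, inuit_F = 0.15,
                                     euro_F = c(0.020, 0.040, 0.060,
                                                0.080, 0.100),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- runif(n_sites, 0.05, 0.95)
  F <- c(inuit_F, euro_F)
  names(F) <- c("INUIT", paste0("EUR_", LETTERS[seq_along(euro_F)]))
  population_model(anc, F)
}

#' Simulate a phased reference panel for one population
#'
#' Haplotypes are drawn site-wise independently from the population's
#' allele frequencies (founders carry no background linkage disequilibrium;
#' linkage enters only through pedigree recombination in admixed genomes).
#'
#' @param freqs numeric vector of allele-1 frequencies, one per site.
#' @param n_individuals number of diploid individuals (>= 1).
#' @param map `genetic_map` with one row per site.
#' @param population population label for all individuals.
#' @param prefix sample-id prefix.
#' @param seed optional integer seed.
#' @return A `haplotype_panel`: list with `haps` (sites x 2n 0/1 matrix),
#'   `sample_ids`, `hap_sample` (sample id per haplotype column),
#'   `populations` (per sample), and `map`.
#' @export
simulate_reference_panel <- function(freqs, n_individuals, map,
                                     population = "POP", prefix = population,
                                     seed = NULL) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  stopifnot(length(freqs) == nrow(map))
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  H <- 2L * as.integer(n_individuals)
  haps <- matrix(rbinom(L * H, 1L, rep(freqs, H)), nrow = L, ncol = H)
  ids <- sprintf("%s_%03d", prefix, seq_len(n_individuals))
  new_haplotype_panel(haps, ids, rep(population, n_individuals), map)
}

new_haplotype_panel <- function(haps, sample_ids, populations, map) {
  stopifnot(ncol(haps) == 2L * length(sample_ids),
            length(populations) == length(sample_ids))
  colnames(haps) <- paste0(rep(sample_ids, each = 2), c("_a", "_b"))
  structure(list(haps = haps, sample_ids = sample_ids,
                 hap_sample = rep(sample_ids, each = 2),
                 populations = setNames(populations, sample_ids),
                 map = map),
            class = "haplotype_panel")
}

#' Combine haplotype panels over the same sites
#'
#' @param ... `haplotype_panel` objects sharing one map.
#' @return A single `haplotype_panel`.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  if (length(panels) == 1 && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "haplotype_panel"))
    panels <- panels[[1]]
  stopifnot(length(panels) >= 1)
  L <- nrow(panels[[1]]$haps)
  for (p in panels) stopifnot(nrow(p$haps) == L)
  ids <- unlist(lapply(panels, `[[`, "sample_ids"))
  if (anyDuplicated(ids)) stop("duplicate sample ids across panels")
  new_haplotype_panel(do.call(cbind, lapply(panels, `[[`, "haps")),
                      ids,
                      unlist(lapply(panels, function(p) unname(p$populations))),
                      panels[[1]]$map)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$sample_ids), "individuals,",
      nrow(x$haps), "sites,",
      length(unique(x$populations)), "population(s)\n")
  invisible(x)
}

#' Pedigree admixture history
#'
#' A pedigree G generations deep is described by its 2^G founders, ordered
#' so the first half is the maternal side. Each founder carries a source
#' population label. The derived quantities `a_m` and `a_f` are the
#' expected European ancestry fractions of the maternally and paternally
#' transmitted gametes: the fraction of European-labelled founders on each
#' side (each founder contributes 1/2^(G-1) of a gamete in expectation).
#'
#' @param founders character vector of 2^G founder population labels,
#'   maternal side first.
#' @param european_sources labels counted as European-like.
#' @param name optional history name.
#' @return An object of class `admixture_history` with fields `founders`,
#'   `generations`, `a_m`, `a_f`.
#' @examples
#' # one European grandparent (maternal side), three Inuit grandparents
#' h <- admixture_history(c("EUR_A", "INUIT", "INUIT", "INUIT"),
#'                        european_sources = "EUR_A")
#' h$a_m  # 0.5
#' @export
admixture_history <- function(founders, european_sources,
                              name = NULL) {
  n <- length(founders)
  if (n < 2 || bitwAnd(n, n - 1L) != 0)
    stop("number of founders must be a power of two >= 2")
  G <- as.integer(round(log2(n)))
  is_eur <- founders %in% european_sources
  half <- n %/% 2L
  structure(list(founders = founders, generations = G,
                 european_sources = european_sources,
                 a_m = mean(is_eur[seq_len(half)]),
                 a_f = mean(is_eur[half + seq_len(half)]),
                 name = name %||% paste0("G", G, "_", sum(is_eur), "eur")),
            class = "admixture_history")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seven canonical recent-admixture histories
#'
#' The pedigree configurations whose expected ternary fractions anchor the
#' timing analysis: one European parent; one European grandparent; two
#' European grandparents (one per side); three European grandparents; one
#' European great-grandparent; two European great-grandparents (one per
#' side); three European great-grandparents (same side). All other founders
#' are Inuit-like.
#'
#' @param european label used for European founders (default `"EUR_A"`).
#' @param inuit label used for Inuit founders (default `"INUIT"`).
#' @return Named list of `admixture_history` objects.
#' @export
canonical_histories <- function(european = "EUR_A", inuit = "INUIT") {
  f <- function(n, idx, name) {
    founders <- rep(inuit, n)
    founders[idx] <- european
    admixture_history(founders, european, name = name)
  }
  list(
    one_parent        = f(2, 1, "one_parent"),
    one_grandparent   = f(4, 1, "one_grandparent"),
    two_grandparents  = f(4, c(1, 3), "two_grandparents"),
    three_grandparents = f(4, c(1, 2, 3), "three_grandparents"),
    one_greatgrandparent  = f(8, 1, "one_greatgrandparent"),
    two_greatgrandparents = f(8, c(1, 5), "two_greatgrandparents"),
    three_greatgrandparents = f(8, c(1, 2, 3), "three_greatgrandparents")
  )
}

#' Simulate an admixed genome down a pedigree
#'
#' Founder haplotypes are drawn fresh from their source population's allele
#' frequencies; meiosis is simulated down the pedigree with a Poisson number
#' of crossovers per chromosome (no interference), crossover positions
#' uniform on the cM scale, and random starting haplotype. True local
#' ancestry is tracked per site on both haplotypes.
#'
#' @param history an [admixture_history()].
#' @param source_freqs sites x populations frequency matrix; must contain a
#'   column for every founder label.
#' @param map `genetic_map`, one row per site; every chromosome must have
#'   positive genetic length.
#' @param sample_id identifier for the simulated individual.
#' @param seed optional integer seed.
#' @return A `simulated_genome`: list with `haps` (sites x 2 alleles),
#'   `anc` (sites x 2 ancestry labels), `sample_id`, `history`, `map`.
#' @export
simulate_pedigree_genome <- function(history, source_freqs, map,
                                     sample_id = "ADM_001", seed = NULL) {
  stopifnot(inherits(history, "admixture_history"))
  if (length(history$founders) == 0) stop("empty pedigree")
  missing_pop <- setdiff(unique(history$founders), colnames(source_freqs))
  if (length(missing_pop))
    stop("founder population(s) missing from source_freqs: ",
         paste(missing_pop, collapse = ", "))
  if (any(map_lengths(map) <= 0)) stop("chromosome with zero map length")
  stopifnot(nrow(source_freqs) == nrow(map))
  if (!is.null(seed)) set.seed(seed)

  chrom_idx <- map_chrom_index(map)
  founder_genome <- function(pop) {
    f <- source_freqs[, pop]
    L <- length(f)
    list(haps = matrix(rbinom(2L * L, 1L, rep(f, 2L)), ncol = 2),
         anc = matrix(pop, nrow = L, ncol = 2))
  }
  # transmit one recombinant gamete from a diploid genome
  gamete <- function(g) {
    L <- nrow(g$haps)
    hap <- integer(L); anc <- character(L)
    for (idx in chrom_idx) {
      cm <- map$cm[idx]
      len_m <- diff(range(cm)) / 100
      n_cross <- rpois(1, len_m)
      cuts <- sort(runif(n_cross, min(cm), max(cm)))
      phase <- (findInterval(cm, cuts) + sample.int(2L, 1L)) %% 2L + 1L
      take <- cbind(idx, phase)
      hap[idx] <- g$haps[take]
      anc[idx] <- g$anc[take]
    }
    list(hap = hap, anc = anc)
  }
  descend <- function(founders) {
    if (length(founders) == 1) return(founder_genome(founders))
    half <- length(founders) %/% 2L
    gm <- gamete(descend(founders[seq_len(half)]))
    gf <- gamete(descend(founders[half + seq_len(half)]))
    list(haps = cbind(gm$hap, gf$hap), anc = cbind(gm$anc, gf$anc))
  }
  g <- descend(history$founders)
  structure(list(haps = g$haps, anc = g$anc, sample_id = sample_id,
                 history = history, map = map),
            class = "simulated_genome")
}

#' True ternary ancestry fractions of a simulated genome
#'
#' cM-weighted genome fractions carrying 0, 1 or 2 European alleles,
#' computed from the recorded true local ancestry.
#'
#' @param genome a `simulated_genome`.
#' @param european_sources labels counted as European; defaults to the
#'   genome's own history.
#' @return A `ternary_fractions` vector `(f_II, f_IE, f_EE)`.
#' @export
true_ternary <- function(genome, european_sources = NULL) {
  european_sources <- european_sources %||% genome$history$european_sources
  w <- site_weights_cm(genome$map)
  n_eur <- (genome$anc[, 1] %in% european_sources) +
    (genome$anc[, 2] %in% european_sources)
  tot <- sum(w)
  ternary_fractions(sum(w[n_eur == 0]) / tot,
                    sum(w[n_eur == 1]) / tot,
                    sum(w[n_eur == 2]) / tot)
}

#' True ancestry tracts of a simulated genome
#'
#' Converts the per-site ancestry labels into tract intervals per
#' haplotype. Boundaries between differing adjacent sites are placed at the
#' inter-site midpoint; tracts tile each chromosome exactly.
#'
#' @param genome a `simulated_genome`.
#' @return data frame with columns `sample`, `haplotype`, `chrom`,
#'   `start_bp`, `end_bp`, `start_cm`, `end_cm`, `ancestry`.
#' @export
true_tracts <- function(genome) {
  map <- genome$map
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$pos_bp[idx]; cm <- map$cm[idx]
    mid_bp <- c(bp[1], (head(bp, -1) + tail(bp, -1)) / 2, bp[length(bp)])
    mid_cm <- c(cm[1], (head(cm, -1) + tail(cm, -1)) / 2, cm[length(cm)])
    for (h in 1:2) {
      r <- rle(genome$anc[idx, h])
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      out[[length(out) + 1L]] <- data.frame(
        sample = genome$sample_id, haplotype = h, chrom = ch,
        start_bp = mid_bp[starts], end_bp = mid_bp[ends + 1L],
        start_cm = mid_cm[starts], end_cm = mid_cm[ends + 1L],
        ancestry = r$values, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Inject phasing switch errors
#'
#' At each heterozygous site, independently with the given probability, the
#' two haplotypes are swapped from that site to the end of the chromosome —
#' the signature error mode of statistical phasing. Unordered genotypes are
#' unchanged at every site; true ancestry labels travel with their alleles.
#'
#' @param genome a `simulated_genome`.
#' @param rate per-heterozygous-site switch probability in \[0, 1\].
#' @param seed optional integer seed.
#' @return A `simulated_genome` with perturbed phase.
#' @export
inject_switch_errors <- function(genome, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  haps <- genome$haps; anc <- genome$anc
  for (idx in map_chrom_index(genome$map)) {
    het <- haps[idx, 1] != haps[idx, 2]
    toggle <- integer(length(idx))
    toggle[het] <- rbinom(sum(het), 1L, rate)
    swap <- cumsum(toggle) %% 2L == 1L
    sw <- idx[swap]
    if (length(sw)) {
      haps[sw, ] <- haps[sw, 2:1]
      anc[sw, ] <- anc[sw, 2:1]
    }
  }
  genome$haps <- haps
  genome$anc <- anc
  genome
}

#' Unordered genotype dosages of a simulated genome
#' @param genome a `simulated_genome`.
#' @return Integer vector of allele-1 counts (0/1/2) per site.
#' @export
genotypes <- function(genome) as.integer(rowSums(genome$haps))

#' Simulate an admixed cohort
#'
#' Draws a cohort of admixed genomes whose pedigree histories are sampled
#' from a supplied list (with replacement, given weights).
#'
#' @param histories list of [admixture_history()] objects.
#' @param n number of individuals.
#' @param source_freqs sites x populations frequency matrix.
#' @param map `genetic_map`.
#' @param weights sampling weight per history (default uniform).
#' @param prefix sample-id prefix.
#' @param seed optional integer seed.
#' @return List of `simulated_genome` objects.
#' @export
simulate_admixed_cohort <- function(histories, n, source_freqs, map,
                                    weights = NULL, prefix = "ADM",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(histories, "admixture_history")) histories <- list(histories)
  pick <- sample.int(length(histories), n, replace = TRUE, prob = weights)
  lapply(seq_len(n), function(i)
    simulate_pedigree_genome(histories[[pick[i]]], source_freqs, map,
                             sample_id = sprintf("%s_%03d", prefix, i)))
}
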