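#' Genetic map
#'
#' A genetic map ties physical site coordinates (bp) to genetic coordinates
#' (cM) per chromosome. Internally it is a data frame with one row per site
#' and columns `chrom`, `pos_bp` and `cm`; cumulative cM positions must be
#' nondecreasing within a chromosome and each chromosome must span a
#' positive genetic length.
#'
#' @param chrom character or integer chromosome identifier per site.
#' @param pos_bp integer physical positions, strictly increasing within a
#'   chromosome.
#' @param cm numeric cumulative genetic positions (cM), nondecreasing within
#'   a chromosome.
#' @return An object of class `genetic_map` (a data frame).
#' @examples
#' gm <- genetic_map(rep("1", 3), c(100L, 200L, 300L), c(0, 0.5, 1.2))
#' map_lengths(gm)
#' @export
genetic_map <- function(chrom, pos_bp, cm) {
  stopifnot(length(chrom) == length(pos_bp), length(pos_bp) == length(cm))
  m <- data.frame(chrom = as.character(chrom), pos_bp = as.integer(pos_bp),
                  cm = as.numeric(cm), stringsAsFactors = FALSE)
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (is.unsorted(m$pos_bp[i], strictly = TRUE))
      stop("physical positions must be strictly increasing on chromosome ", ch)
    if (is.unsorted(m$cm[i]))
      stop("cM positions must be nondecreasing on chromosome ", ch)
    if (diff(range(m$cm[i])) <= 0 && sum(i) > 1)
      stop("chromosome ", ch, " has zero genetic length")
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Uniform synthetic genetic map
#'
#' Builds a map with equally spaced sites and a constant recombination rate,
#' a stand-in for an empirical recombination map when simulating cohorts.
#'
#' @param n_chrom number of chromosomes.
#' @param morgans_per_chrom genetic length of each chromosome, in Morgans
#'   (recycled to `n_chrom`).
#' @param sites_per_chrom number of sites per chromosome (recycled).
#' @param bp_per_cm physical bp per cM (default 1e6, i.e. ~1 cM/Mb).
#' @return A `genetic_map`.
#' @export
uniform_genetic_map <- function(n_chrom = 3, morgans_per_chrom = 1,
                                sites_per_chrom = 500, bp_per_cm = 1e6) {
  morgans <- rep_len(morgans_per_chrom, n_chrom)
  nsites <- rep_len(as.integer(sites_per_chrom), n_chrom)
  pieces <- lapply(seq_len(n_chrom), function(i) {
    cm <- seq(0, morgans[i] * 100, length.out = nsites[i])
    data.frame(chrom = as.character(i),
               pos_bp = as.integer(round(cm * bp_per_cm)) + 1L,
               cm = cm, stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, pieces)
  genetic_map(m$chrom, m$pos_bp, m$cm)
}

#' Genetic length per chromosome
#'
#' @param map a `genetic_map`.
#' @return Named numeric vector of cM lengths per chromosome.
#' @export
map_lengths <- function(map) {
  vapply(split(map$cm, map$chrom), function(x) diff(range(x)), numeric(1))
}

#' Total genetic length of a map in cM
#' @param map a `genetic_map`.
#' @export
map_total_cm <- function(map) sum(map_lengths(map))

# Per-site cM weights: each site owns half the gap to each neighbour;
# chromosome end sites own only their interior half-gap. Weights sum to the
# chromosome's genetic length exactly.
site_weights_cm <- function(map) {
  w <- numeric(nrow(map))
  for (i in map_chrom_index(map)) {
    cm <- map$cm[i]
    if (length(cm) == 1) { w[i] <- 0; next }
    gaps <- diff(cm)
    w[i] <- c(gaps / 2, 0) + c(0, gaps / 2)
  }
  w
}

# split row indices of a map by chromosome, preserving chromosome order
# of first appearance
map_chrom_index <- function(map) {
  f <- factor(map$chrom, levels = unique(map$chrom))
  split(seq_len(nrow(map)), f)
}
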