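#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased GT fields ("0|1"). Site identifiers
#' are taken from the panel's map (chromosome and bp position); REF/ALT
#' are written as A/G placeholders since only biallelic 0/1 alleles are
#' modelled.
#'
#' @param panel a `haplotype_panel` (or list of `simulated_genome`s, which
#'   is converted first).
#' @param path output file path (plain text).
#' @export
write_phased_vcf <- function(panel, path) {
  if (!inherits(panel, "haplotype_panel")) panel <- genomes_to_panel(panel)
  if (length(panel$sample_ids) == 0) stop("empty cohort")
  map <- panel$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixpaint",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  h <- panel$haps
  gt <- matrix(paste(h[, c(TRUE, FALSE)], h[, c(FALSE, TRUE)], sep = "|"),
               nrow = nrow(h))
  lines <- paste(map$chrom, map$pos_bp,
                 paste0("snp", seq_len(nrow(map))), "A", "G", ".", "PASS",
                 ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Parses a VCF (via the vcfR package), requires fully phased biallelic
#' GT fields, and attaches genetic-map coordinates and population labels.
#'
#' @param path VCF file path.
#' @param map `genetic_map` covering the VCF's sites (same order); when
#'   NULL a bp-proportional map (1 cM/Mb) is constructed.
#' @param labels optional named character vector (or data frame with
#'   columns `sample_id`, `population`) of population labels.
#' @return A `haplotype_panel`.
#' @export
read_phased_vcf <- function(path, map = NULL, labels = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("VCF contains unphased genotypes")
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  if (is.null(map))
    map <- genetic_map(chrom, pos, stats::ave(pos / 1e6, chrom,
                                              FUN = function(x) x - x[1]))
  stopifnot(nrow(map) == nrow(gt))
  ids <- colnames(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  haps <- matrix(0L, nrow(gt), 2 * length(ids))
  haps[, c(TRUE, FALSE)] <- a1
  haps[, c(FALSE, TRUE)] <- a2
  if (is.data.frame(labels))
    labels <- setNames(labels$population, labels$sample_id)
  pops <- if (is.null(labels)) rep(NA_character_, length(ids))
          else unname(labels[ids])
  new_haplotype_panel(haps, ids, pops, map)
}

#' Write a genetic map in HapMap format
#'
#' Tab-separated columns: chromosome, position (bp), recombination rate
#' (cM/Mb, derived from consecutive map points; the last site of each
#' chromosome repeats the previous rate), cumulative genetic position (cM).
#'
#' @param map a `genetic_map`.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  rate <- numeric(nrow(map))
  for (idx in map_chrom_index(map)) {
    r <- diff(map$cm[idx]) / (diff(map$pos_bp[idx]) / 1e6)
    rate[idx] <- c(r, r[length(r)])
  }
  d <- data.frame(chr = map$chrom, position = map$pos_bp,
                  rate_cM_Mb = rate, cM = map$cm)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a HapMap-format genetic map
#'
#' @param path tab-separated file with columns chromosome, position,
#'   rate (cM/Mb) and cumulative cM.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  genetic_map(d[[1]], d[[2]], d[[4]])
}

#' Write / read sample population labels
#'
#' Tab-separated columns `sample_id`, `population`.
#'
#' @param labels named character vector (names = sample ids) or a
#'   `haplotype_panel`.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "haplotype_panel")) labels <- labels$populations
  write.table(data.frame(sample_id = names(labels),
                         population = unname(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  setNames(d$population, d$sample_id)
}

#' Write a synthetic cohort to standard input formats
#'
#' Emits the reference panel and admixed genomes as one phased VCF, the
#' genetic map in HapMap format, population labels as TSV, and the truth
#' files (true ancestry tracts per haplotype, and per-individual pedigree
#' summaries a_m / a_f). Reading the files back reproduces the allele
#' matrix bit-exactly.
#'
#' @param reference a `haplotype_panel`.
#' @param genomes list of `simulated_genome`s (may be empty).
#' @param dir output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_cohort <- function(reference, genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(reference$sample_ids) == 0 && length(genomes) == 0)
    stop("empty cohort")
  panel <- reference
  labels <- reference$populations
  if (length(genomes)) {
    adm <- genomes_to_panel(genomes)
    panel <- combine_panels(list(reference, adm))
    labels <- c(labels, adm$populations)
  }
  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                map = file.path(dir, "map.txt"),
                labels = file.path(dir, "labels.tsv"),
                tracts = file.path(dir, "truth_tracts.tsv"),
                pedigrees = file.path(dir, "truth_pedigrees.tsv"))
  write_phased_vcf(panel, paths$vcf)
  write_genetic_map(reference$map, paths$map)
  write_labels(labels, paths$labels)
  if (length(genomes)) {
    tr <- do.call(rbind, lapply(genomes, true_tracts))
    write.table(tr, paths$tracts, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ped <- data.frame(
      sample = vapply(genomes, `[[`, character(1), "sample_id"),
      history = vapply(genomes, function(g) g$history$name, character(1)),
      a_m = vapply(genomes, function(g) g$history$a_m, numeric(1)),
      a_f = vapply(genomes, function(g) g$history$a_f, numeric(1)))
    write.table(ped, paths$pedigrees, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
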