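#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. A
#' configuration is a nested list (readable from YAML via
#' [read_pipeline_config()]) with blocks `simulate` (or `paths` for
#' pre-existing inputs), `qc`, `painting`, `sources` and `ternary`; any
#' omitted setting takes its default. All analysis thresholds live here,
#' none are hard-coded in the stages.
#'
#' @param config nested list of overrides (may be empty).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  def <- list(
    seed = 1L,
    simulate = list(
      n_chrom = 4L, morgans_per_chrom = 1.5, sites_per_chrom = 4500L,
      inuit_F = 0.15, euro_F = c(0.020, 0.040, 0.060, 0.080, 0.100),
      n_ref_per_pop = 40L, n_admixed = 80L, switch_error_rate = 0.02,
      histories = list(
        list(founders = 2L, n_euro = 1L, source = "EUR_A", weight = 0.25),
        list(founders = 4L, n_euro = 1L, source = "EUR_A", weight = 0.50),
        list(founders = 4L, n_euro = 1L, source = "EUR_B", weight = 0.25))),
    paths = NULL,
    qc = list(miss_max = 1.0, maf_min = 0, remove_singletons = FALSE,
              unadmixed_min_inuit = 0.99, admixed_min_euro = 0.01,
              relatedness_threshold = 0.2, run_relatedness = FALSE),
    painting = list(Ne = 103.35, mu = 2.04e-5, em_iterations = 0L,
                    em_individuals = 10L, outlier_z = 5),
    sources = list(n_slots = 100L, t_eligible = 8L, t_expected = 4,
                   n_iter = 1e5, burn_in = 1e4, thin = 100L, n_chains = 5L,
                   individual = TRUE, prob_cut = 0.99),
    ternary = list(g = 8, g_check = 3, window_cm = 0.2,
                   filter_center = "cohort", filter_low = 0.625,
                   filter_high = 0.725, filter_delta = 0.05,
                   classification_tol = 0.02))
  cfg <- modify_defaults(def, config)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

modify_defaults <- function(def, new) {
  for (nm in names(new)) {
    if (is.list(def[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(def[[nm]])) && nm != "histories")
      def[[nm]] <- modify_defaults(def[[nm]], new[[nm]])
    else def[[nm]] <- new[[nm]]
  }
  def
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$paths))
    stop("config must provide either a 'simulate' block or a 'paths' block")
  if (!is.null(cfg$paths)) {
    for (f in c("vcf", "map", "labels")) {
      if (is.null(cfg$paths[[f]]))
        stop("config field paths$", f, " is missing")
      if (!file.exists(cfg$paths[[f]]))
        stop("config field paths$", f, ": file not found: ", cfg$paths[[f]])
    }
  }
  for (f in c("unadmixed_min_inuit", "admixed_min_euro"))
    if (cfg$qc[[f]] < 0 || cfg$qc[[f]] > 1)
      stop("config field qc$", f, " must be in [0, 1]")
  if (cfg$ternary$filter_low >= cfg$ternary$filter_high)
    stop("config field ternary$filter_low must be < filter_high")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

history_from_spec <- function(h) {
  founders <- rep("INUIT", h$founders)
  founders[seq_len(h$n_euro)] <- h$source
  admixture_history(founders, european_sources = grep("^EUR",
                    unique(founders), value = TRUE),
                    name = sprintf("G%d_%d%s", log2(h$founders), h$n_euro,
                                   h$source))
}

# expected per-source ancestry of a genome from its pedigree founders
true_source_fractions <- function(genome, sources) {
  f <- genome$history$founders
  vapply(sources, function(s) mean(f == s), numeric(1))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (when configured) -> QC -> painting -> source
#' decomposition -> ternary timing -> report. Every stage's outputs are
#' written under `outdir` as plain-text tables and are re-loadable
#' independently; a stage failure aborts with the stage name attached.
#'
#' @param config a [pipeline_config()] (or list of overrides).
#' @param outdir output directory.
#' @param seed overrides `config$seed`.
#' @param threads number of worker processes for the painting stage
#'   (results are invariant to this setting).
#' @param verbose emit timestamped stage logs (default TRUE).
#' @return A report list with elements `threshold_table`, `group`
#'   (posterior mean, CI and Rhat per source), `ternary` (classification
#'   counts and fractions), `parent_accounting`, `ancestry`, `truth` (when
#'   simulated), `files` and `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run"),
                         seed = NULL, threads = 1L, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, ...) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste0(...))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  stage <- function(name, expr) {
    say(name, "start")
    r <- tryCatch(expr, error = function(e) {
      call_txt <- paste(deparse(conditionCall(e)), collapse = " ")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           if (nzchar(call_txt)) paste0(" [in ", call_txt, "]"),
           call. = FALSE)
    })
    say(name, "done")
    r
  }
  set.seed(config$seed)

  # --- simulate or load -----------------------------------------------
  truth <- NULL
  data <- stage("simulate", {
    if (!is.null(config$paths)) {
      labels <- read_labels(config$paths$labels)
      map <- read_genetic_map(config$paths$map)
      panel <- read_phased_vcf(config$paths$vcf, map = map, labels = labels)
      ref_ids <- names(labels)[!is.na(labels) & labels != "ADMIXED"]
      list(reference = subset_panel(panel, ref_ids),
           targets = subset_panel(panel, setdiff(panel$sample_ids, ref_ids)),
           genomes = NULL)
    } else {
      sc <- config$simulate
      map <- uniform_genetic_map(sc$n_chrom, sc$morgans_per_chrom,
                                 sc$sites_per_chrom)
      pm <- default_population_model(nrow(map), sc$inuit_F, sc$euro_F)
      freqs <- draw_population_frequencies(pm)
      panels <- lapply(pm$populations, function(p)
        simulate_reference_panel(freqs[, p], sc$n_ref_per_pop, map,
                                 population = p))
      reference <- combine_panels(panels)
      histories <- lapply(sc$histories, history_from_spec)
      wts <- vapply(sc$histories, `[[`, numeric(1), "weight")
      genomes <- simulate_admixed_cohort(histories, sc$n_admixed, freqs,
                                         map, weights = wts)
      if (sc$switch_error_rate > 0)
        genomes <- lapply(genomes, inject_switch_errors,
                          rate = sc$switch_error_rate)
      write_cohort(reference, genomes, file.path(outdir, "input"))
      list(reference = reference, targets = genomes_to_panel(genomes),
           genomes = genomes, freqs = freqs)
    }
  })
  reference <- data$reference
  targets <- data$targets

  # --- QC: global ancestry and cohort split ---------------------------
  qc <- stage("qc", {
    pops <- reference$populations
    eur_ids <- names(pops)[grepl("^EUR", pops)]
    inu_ids <- names(pops)[pops == "INUIT"]
    f_eur <- rowMeans(reference$haps[, reference$hap_sample %in% eur_ids,
                                     drop = FALSE])
    f_inu <- rowMeans(reference$haps[, reference$hap_sample %in% inu_ids,
                                     drop = FALSE])
    geno <- panel_genotypes(targets)
    anc <- estimate_global_ancestry(geno, f_eur, f_inu)
    q <- setNames(anc$q, anc$sample)
    split <- split_cohort(q, config$qc$unadmixed_min_inuit,
                          config$qc$admixed_min_euro)
    if (isTRUE(config$qc$run_relatedness)) {
      rel <- pairwise_relatedness(geno, q, f_eur, f_inu)
      keep <- prune_relatives(rel, config$qc$relatedness_threshold,
                              ids = colnames(geno))
      split$admixed <- intersect(split$admixed, keep)
      write.table(rel, file.path(outdir, "relatedness.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write.table(anc, file.path(outdir, "ancestry.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(q = q, split = split, f_eur = f_eur, f_inu = f_inu, geno = geno)
  })
  adm_ids <- qc$split$admixed
  say("qc", length(adm_ids), " of ", length(targets$sample_ids),
      " targets enter the admixed set")

  # --- painting --------------------------------------------------------
  paint <- stage("painting", {
    params <- painting_params(config$painting$Ne, config$painting$mu)
    if (config$painting$em_iterations > 0) {
      sub <- head(reference$sample_ids, config$painting$em_individuals)
      params <- em_estimate_params(reference, individuals = sub,
                                   params = params,
                                   n_iter = config$painting$em_iterations)
      say("painting", "EM params: Ne=", signif(params$Ne, 6),
          " mu=", signif(params$mu, 4))
    }
    adm_panel <- subset_panel(targets, adm_ids)
    co <- paint_cohort_threads(reference, adm_panel, params, threads)
    out <- detect_outlier_references(co, config$painting$outlier_z)
    if (length(out)) {
      say("painting", "excluding outlier references: ",
          paste(out, collapse = ", "))
      reference2 <- subset_panel(reference, setdiff(reference$sample_ids, out))
      co <- paint_cohort_threads(reference2, adm_panel, params, threads)
    }
    cv <- condense_copying_vectors(co)
    sur <- surrogate_vectors(cv, co)
    write.table(co$chunk_lengths, file.path(outdir, "coancestry_lengths.tsv"),
                sep = "\t", quote = FALSE)
    write.table(cv, file.path(outdir, "copying_vectors.tsv"),
                sep = "\t", quote = FALSE)
    list(co = co, cv = cv, surrogates = sur, params = params,
         outliers = out)
  })

  # --- source decomposition -------------------------------------------
  src <- stage("sources", {
    sc <- config$sources
    t_el <- min(sc$t_eligible, nrow(paint$surrogates))
    cfg_mix <- mixture_config(sc$n_slots, t_el,
                              min(sc$t_expected, t_el),
                              c = paint$co$map_cm)
    tv <- paint$cv[adm_ids, , drop = FALSE]
    posteriors <- NULL
    tab <- NULL
    if (isTRUE(sc$individual)) {
      posteriors <- lapply(seq_len(nrow(tv)), function(i)
        run_mixture_mcmc(tv[i, ], paint$surrogates, cfg_mix,
                         n_iter = sc$n_iter, burn_in = sc$burn_in,
                         thin = sc$thin, n_chains = sc$n_chains,
                         seed = config$seed + 1000L + i))
      names(posteriors) <- rownames(tv)
      si <- summarize_individuals(posteriors, prob_cut = sc$prob_cut)
      tab <- si$table
      write.table(tab, file.path(outdir, "threshold_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(si$means, file.path(outdir, "posterior_means.tsv"),
                  sep = "\t", quote = FALSE)
      rh <- t(vapply(posteriors, `[[`, numeric(ncol(tv)), "rhat"))
      write.table(rh, file.path(outdir, "rhat.tsv"), sep = "\t",
                  quote = FALSE)
    }
    grp <- summarize_group(tv, paint$surrogates, cfg_mix,
                           n_iter = sc$n_iter, burn_in = sc$burn_in,
                           thin = sc$thin, n_chains = sc$n_chains,
                           seed = config$seed + 500L)
    list(posteriors = posteriors, table = tab, group = grp)
  })

  # --- ternary timing --------------------------------------------------
  tern <- stage("ternary", {
    tc <- config$ternary
    model <- local_ancestry_model(g = tc$g, window_cm = tc$window_cm)
    calls <- lapply(adm_ids, function(id)
      infer_diploid_ancestry(qc$geno[, id], qc$q[[id]], qc$f_eur, qc$f_inu,
                             targets$map, model))
    names(calls) <- adm_ids
    filt <- filter_windows(calls, low = tc$filter_low, high = tc$filter_high,
                           center = tc$filter_center, delta = tc$filter_delta)
    fr <- t(vapply(calls, function(d)
      as.numeric(compute_ternary(d, filt$retained)), numeric(3)))
    colnames(fr) <- c("f_II", "f_IE", "f_EE")
    cats <- apply(fr, 1, function(f)
      classify_history(ternary_fractions(f[1], f[2], f[3]),
                       tol = tc$classification_tol)$category)
    out <- data.frame(sample = adm_ids, fr, category = cats,
                      stringsAsFactors = FALSE)
    write.table(out, file.path(outdir, "ternary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(fractions = out, filter = filt)
  })

  # --- report ----------------------------------------------------------
  report <- stage("report", {
    n_adm <- length(adm_ids)
    cats <- tern$fractions$category
    n_one <- sum(cats == "one_european_parent")
    n_two <- sum(cats == "two_european_parents")
    mean_q <- mean(qc$q[adm_ids])
    pa <- parent_accounting(n_one, n_two, n_adm,
                            if (mean_q > 0) mean_q else NULL)
    truth <- NULL
    if (!is.null(data$genomes)) {
      gsub <- data$genomes[vapply(data$genomes, `[[`, character(1),
                                  "sample_id") %in% adm_ids]
      srcs <- src$group$sources
      truth_mat <- t(vapply(gsub, true_source_fractions, numeric(length(srcs)),
                            sources = srcs))
      truth <- list(group_fractions = colMeans(truth_mat),
                    per_individual = truth_mat)
    }
    rep <- list(threshold_table = src$table,
                group = list(mean = src$group$mean, ci95 = src$group$ci95,
                             rhat = src$group$rhat),
                ternary = list(counts = c(one_european_parent = n_one,
                                          two_european_parents = n_two,
                                          other = sum(cats == "other")),
                               fractions = tern$fractions,
                               windows_removed = tern$filter$n_removed,
                               windows_total = tern$filter$n_windows),
                parent_accounting = pa,
                ancestry = list(q = qc$q, mean_euro = mean_q,
                                split = qc$split),
                truth = truth,
                params = paint$params,
                files = list(outdir = outdir),
                log = NULL)
    saveRDS_free_summary(rep, file.path(outdir, "report.txt"))
    rep
  })
  report$log <- log_lines
  report
}

# plain-text report summary (no binary artifacts)
saveRDS_free_summary <- function(rep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("== group-level source posterior (mean [95% CI]) ==", con)
  for (s in names(rep$group$mean))
    writeLines(sprintf("  %-10s %6.3f [%5.3f, %5.3f] Rhat %.4f", s,
                       rep$group$mean[[s]], rep$group$ci95[s, 1],
                       rep$group$ci95[s, 2], rep$group$rhat[[s]]), con)
  writeLines("== ternary classification ==", con)
  for (nm in names(rep$ternary$counts))
    writeLines(sprintf("  %-22s %d", nm, rep$ternary$counts[[nm]]), con)
  pa <- rep$parent_accounting
  writeLines(sprintf("== parent accounting: %d parents, %.2f%% of ancestors ==",
                     pa$n_parents, 100 * pa$ancestor_fraction), con)
  invisible(path)
}

paint_cohort_threads <- function(reference, targets, params, threads) {
  if (threads <= 1L || length(targets$sample_ids) < 2)
    return(paint_cohort(reference, targets, params))
  co_ref <- paint_cohort(reference, targets = NULL, params)
  parts <- parallel::mclapply(targets$sample_ids, function(id)
    paint_cohort(reference, subset_panel(targets, id), params,
                 paint_reference = FALSE), mc.cores = threads)
  CL <- rbind(co_ref$chunk_lengths,
              do.call(rbind, lapply(parts, `[[`, "chunk_lengths")))
  CC <- rbind(co_ref$chunk_counts,
              do.call(rbind, lapply(parts, `[[`, "chunk_counts")))
  structure(list(chunk_lengths = CL, chunk_counts = CC,
                 is_reference = rownames(CL) %in% reference$sample_ids,
                 donor_populations = reference$populations,
                 map_cm = co_ref$map_cm),
            class = "coancestry")
}

#' Subset a haplotype panel by sample ids
#' @param panel a `haplotype_panel`.
#' @param ids sample ids to keep (order preserved).
#' @export
subset_panel <- function(panel, ids) {
  stopifnot(all(ids %in% panel$sample_ids))
  keep <- panel$hap_sample %in% ids
  new_haplotype_panel(panel$haps[, keep, drop = FALSE],
                      panel$sample_ids[panel$sample_ids %in% ids],
                      unname(panel$populations[panel$sample_ids %in% ids]),
                      panel$map)
}

#' Unphased genotype dosages of a panel
#' @param panel a `haplotype_panel`.
#' @return sites x individuals matrix of 0/1/2 dosages.
#' @export
panel_genotypes <- function(panel) {
  g <- panel$haps[, c(TRUE, FALSE), drop = FALSE] +
    panel$haps[, c(FALSE, TRUE), drop = FALSE]
  colnames(g) <- panel$sample_ids
  g
}
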