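#' Read a pipeline run configuration
#'
#' A single YAML file drives [run_pipeline()]: stage toggles, the AIL /
#' phenotype / expression simulation designs, scan settings and the
#' scoring scheme, plus one root seed from which every stage seed is
#' derived. See `inst/extdata/demo_config.yaml` for a complete example.
#'
#' @param path YAML file path.
#' @return config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("run_config", class(cfg)))
}

.stage_seed <- function(root, offset) (as.integer(root) + offset) %% .Machine$integer.max

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate genotypes
#' and phenotypes with planted QTL, phenotype QC, two-stage QTL scan under
#' selective genotyping, pairwise causal modeling of QTL shared between
#' traits, expression normalization + differential expression, and
#' candidate-gene prioritization — writing every table as TSV into
#' `out_dir` together with a manifest (seeds, thresholds, and marker/gene
#' counts at each filter). Runs are idempotent for a fixed seed.
#'
#' @param config a list from [read_run_config()] (or an equivalent list).
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly; tables on disk.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir %||% "ailqtl_run") {
  stages <- config$stages %||%
    list(simulate = TRUE, qc = TRUE, scan = TRUE, causal = TRUE,
         de = TRUE, prioritize = TRUE)
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = stages, counts = list(),
                   thresholds = list())
  sim <- config$simulate %||% list()
  if (isTRUE(stages$prioritize) && !isTRUE(stages$simulate) &&
      is.null(config$files$variants))
    stopf("prioritization enabled but no variants input configured")

  # --- simulate ------------------------------------------------------------
  if (!isTRUE(stages$simulate))
    stopf("only fully simulated runs are supported by this driver; enable the simulate stage")
  chrs <- unlist(sim$chromosomes %||%
                   c(chr1 = 1e8, chr2 = 1e8, chr3 = 1e8))
  design <- ail_design(
    n_individuals = sim$n_individuals %||% 397,
    n_generations = sim$n_generations %||% 9,
    chromosomes = chrs,
    marker_positions = even_marker_map(chrs, sim$markers_per_chr %||% 100),
    recombination_rate = sim$recombination_rate %||% 0.5,
    seed = .stage_seed(seed, 1L))
  g <- simulate_ail_genotypes(design)
  specs <- lapply(sim$qtl %||% list(
    list(trait = "gonat_weight", marker_index = 50, additive = -0.4, noise = 1),
    list(trait = "blood_glucose", mediator = "gonat_weight", slope = -0.6,
         noise = 1)), function(s) {
      qtl_spec(target_trait = s$trait,
               marker = if (!is.null(s$marker_index))
                 g$map$marker[s$marker_index] else NA_character_,
               additive_effect = s$additive %||% 0,
               dominance_effect = s$dominance %||% 0,
               mediator = s$mediator, slope = s$slope %||% 0,
               noise_sd = s$noise %||% 1)
    })
  covspec <- list(traits = sim$litter_traits %||% "liver_weight",
                  effect = sim$litter_effect %||% 0, range = 4:12)
  ph <- simulate_phenotypes(g, specs, covariate_spec = covspec,
                            seed = .stage_seed(seed, 2L))
  write_genotypes(g, file.path(out_dir, "genotypes.tsv"))
  write_phenotypes(ph, file.path(out_dir, "phenotypes.tsv"))
  manifest$counts$markers_simulated <- nrow(g$geno)
  manifest$counts$individuals <- ncol(g$geno)

  # --- qc ------------------------------------------------------------------
  traits <- unique(vapply(specs, `[[`, "", "target_trait"))
  if (isTRUE(stages$qc)) {
    qc <- remove_outliers(ph, traits, k = config$qc$k %||% 4)
    ph <- qc$table
    write_phenotypes(ph, file.path(out_dir, "phenotypes_clean.tsv"))
    write.table(qc$log, file.path(out_dir, "outliers_removed.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    corr <- correlation_matrix(ph, traits)
    write.table(corr, file.path(out_dir, "trait_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$counts$outliers_masked <- nrow(qc$log)
  }

  # --- scan ----------------------------------------------------------------
  qtl_tables <- list()
  if (isTRUE(stages$scan)) {
    cfg_scan <- do.call(scan_config, config$scan %||% list())
    inf <- informative_markers(g, config$max_missing %||% 0.1)
    manifest$counts$markers_informative <- nrow(inf$geno$geno)
    sel_ids <- select_tails(ph, traits[1],
                            n_select = sim$n_select %||%
                              min(200L, ncol(g$geno)))
    g_sel <- subset_geno(inf$geno, individuals = sel_ids)
    for (tr in traits) {
      scr <- screen_covariates(ph, tr, "litter_size",
                               alpha = cfg_scan$covariate_alpha)
      covs <- scr$covariate[scr$included]
      qtl_tables[[tr]] <- two_stage_scan(g_sel, inf$geno, ph, tr, covs,
                                         cfg_scan, qtl_prefix = tr)
    }
    qtl_tab <- do.call(rbind, qtl_tables)
    rownames(qtl_tab) <- NULL
    write.table(qtl_tab, file.path(out_dir, "qtl.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    meff <- simple_m(inf$geno, cfg_scan$simplem_window, cfg_scan$simplem_C)
    manifest$thresholds <- list(
      meff = as.integer(meff),
      lod_significant = bonferroni_lod_threshold(cfg_scan$alpha_significant, meff),
      lod_highly = bonferroni_lod_threshold(cfg_scan$alpha_highly, meff))
    manifest$counts$qtl_detected <- nrow(qtl_tab)
  }

  # --- causal --------------------------------------------------------------
  if (isTRUE(stages$causal) && isTRUE(stages$scan) && length(traits) >= 2) {
    qtl_tab <- do.call(rbind, qtl_tables)
    verdicts <- list()
    if (!is.null(qtl_tab) && nrow(qtl_tab)) {
      # trait pairs whose intervals overlap on a chromosome share a QTL
      for (ch in unique(qtl_tab$chr)) {
        rows <- qtl_tab[qtl_tab$chr == ch, , drop = FALSE]
        if (nrow(rows) < 2) next
        for (i in seq_len(nrow(rows) - 1)) for (j in (i + 1):nrow(rows)) {
          if (rows$start[i] > rows$stop[j] || rows$start[j] > rows$stop[i]) next
          mk <- g$map$marker[which.min(abs(g$map$pos - rows$top[i]) +
                                         (g$map$chr != ch) * 1e18)]
          qv <- g$geno[mk, match(ph$id, colnames(g$geno))]
          v <- fit_causal_models(qv, ph[[rows$trait[i]]], ph[[rows$trait[j]]],
                                 gap = config$causal$gap %||% 2,
                                 trait_names = c(rows$trait[i], rows$trait[j]))
          verdicts[[length(verdicts) + 1L]] <- data.frame(
            chr = ch, marker = mk, trait1 = rows$trait[i],
            trait2 = rows$trait[j], verdict = v$verdict, margin = v$margin)
        }
      }
    }
    vt <- if (length(verdicts)) do.call(rbind, verdicts) else
      data.frame(chr = character(), marker = character(), trait1 = character(),
                 trait2 = character(), verdict = character(), margin = numeric())
    write.table(vt, file.path(out_dir, "causal_verdicts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$counts$causal_pairs <- nrow(vt)
  }

  # --- expression ----------------------------------------------------------
  de_genes <- NULL
  if (isTRUE(stages$de)) {
    ed <- do.call(expression_design,
                  c(config$expression %||% list(),
                    list(seed = .stage_seed(seed, 3L))))
    ex <- simulate_expression(ed)
    norm <- normalize_expression(ex$x)
    de <- differential_expression(norm)
    write.table(de, file.path(out_dir, "differential_expression.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    de_genes <- de_by_gene(de)
    manifest$counts$probes_tested <- length(unique(de$probe))
    manifest$counts$probes_significant <- sum(de$significant)
  }

  # --- prioritize ----------------------------------------------------------
  if (isTRUE(stages$prioritize) && isTRUE(stages$scan)) {
    qtl_tab <- do.call(rbind, qtl_tables)
    genes <- simulate_gene_models(g, config$genes_per_chr %||% 50,
                                  seed = .stage_seed(seed, 4L))
    variants <- simulate_variant_annotations(genes,
                                             seed = .stage_seed(seed, 5L))
    manifest$counts$genes_total <- nrow(genes)
    if (!is.null(qtl_tab) && nrow(qtl_tab)) {
      ivs <- unique(qtl_tab[, c("qtl", "chr", "start", "stop")])
      scheme <- do.call(scoring_scheme, config$scoring %||% list())
      # map simulated gene "names" onto DE gene ids by position for the demo
      kegg <- genes$gene[seq_len(nrow(genes)) %% 3 == 0]
      cards <- prioritize_candidates(ivs, genes, variants, de_genes, kegg,
                                     scheme)
      write.table(cards, file.path(out_dir, "gene_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      manifest$counts$genes_scored <- nrow(cards)
    }
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
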