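# End-to-end pipeline: counts -> fitness -> beneficial DFE -> specificity,
# with a machine-readable provenance manifest.

#' Pipeline configuration
#'
#' Describes a multi-selection analysis: one entry per selection (substrate)
#' with its count-table paths (or in-memory tables) and doublings, shared
#' thresholds, an optional structure block, and the seed recorded in every
#' output.
#'
#' @param selections named list; each element a list with fields `counts`
#'   (path or `count_table`), optional `g_p` (default from `g_p` argument)
#'   and optional `dialect`.
#' @param g_p default population doublings.
#' @param beneficial_threshold beneficial threshold on zeta.
#' @param floor_reads post-selection read floor for the detection limit.
#' @param structure optional list with `pdb` (path) and `active_site`
#'   (an [active_site_spec()]).
#' @param seed integer seed for every stochastic step (bootstraps).
#' @param dfe_bootstrap bootstrap replicates for DFE tests (0 disables).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(selections, g_p = 8, beneficial_threshold = 0.15,
                            floor_reads = 10, structure = NULL, seed = 1L,
                            dfe_bootstrap = 199L) {
  if (length(selections) < 1L || is.null(names(selections)) ||
      anyDuplicated(names(selections))) {
    stop("selections must be a uniquely named list")
  }
  base::structure(list(selections = selections, g_p = g_p,
                       beneficial_threshold = beneficial_threshold,
                       floor_reads = floor_reads, structure = structure,
                       seed = as.integer(seed),
                       dfe_bootstrap = dfe_bootstrap),
                  class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' For every selection: read (or accept) the count table, pool replicates,
#' compute the fitness table and write it with its summary.  Then fit the
#' beneficial-DFE model family per selection, and, when two or more
#' selections are present, build the multi-substrate matrix, pairwise
#' correlations, PCA, Venn bins, specificity-determining calls and hotspots.
#' With a structure block, minimum active-site distances and the beneficial
#' shell histogram are added.  A JSON manifest records package version,
#' seed, parameters and a config hash so reruns are reproducible.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if absent).
#' @return (invisibly) list of class `pipeline_result` with elements
#'   `fitness` (named list of tables), `dfe` (named list of `dfe_report`),
#'   `specificity` (or NULL), `structure` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  labels <- names(config$selections)
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  fits <- list()
  for (lab in labels) {
    sel <- config$selections[[lab]]
    counts <- step(paste0("read:", lab), {
      if (is.character(sel$counts)) {
        read_count_table(sel$counts, dialect = sel$dialect %||% "tsv")
      } else sel$counts
    })
    fits[[lab]] <- step(paste0("fitness:", lab), {
      pooled <- combine_replicates(counts)
      fit <- compute_fitness(pooled, g_p = sel$g_p %||% config$g_p,
                             floor_reads = config$floor_reads, label = lab)
      aggregate_synonymous(fit)
    })
    write_fitness_table(fits[[lab]], file.path(outdir,
                                               paste0("fitness_", lab,
                                                      ".tsv")))
  }
  dfe <- list()
  for (lab in labels) {
    dfe[[lab]] <- step(paste0("dfe:", lab), {
      s <- extract_exceedances(fits[[lab]],
                               threshold = config$beneficial_threshold,
                               label = lab)
      if (s$n >= 10L) {
        fit_dfe_models(s, ad_bootstrap = config$dfe_bootstrap,
                       gof_bootstrap = config$dfe_bootstrap,
                       seed = config$seed)
      } else NULL
    })
  }
  jsonlite::write_json(dfe_report_json(dfe),
                       file.path(outdir, "dfe_fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  specificity <- NULL
  struct_out <- NULL
  if (length(labels) >= 2L) {
    specificity <- step("specificity", {
      mat <- substrate_matrix(fits)
      mat$venn_bin <- classify_bins(mat, config$beneficial_threshold)
      mat$specificity_determining <-
        specificity_determining(mat, config$beneficial_threshold)
      list(matrix = mat,
           correlations = pairwise_correlation(mat),
           pca = pca_fitness(mat),
           hotspots = hotspot_positions(mat))
    })
    write.table(as.data.frame(specificity$matrix),
                file.path(outdir, "specificity_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    if (!is.null(config$structure)) {
      struct_out <- step("structure", {
        mat <- specificity$matrix
        benef_any <- rowSums(as.matrix(mat[, labels]) >
                               config$beneficial_threshold) > 0
        positions <- sort(unique(mat$position[!is.na(mat$position)]))
        d <- min_distance_to_active_site(config$structure$pdb, positions,
                                         config$structure$active_site)
        d <- d[!is.na(d)]
        mut_pos <- mat$position[benef_any &
                                  mat$position %in% as.integer(names(d))]
        shells <- shell_histogram(d, mut_pos)
        list(distances = d, shells = shells)
      })
      write.table(struct_out$shells,
                  file.path(outdir, "shell_histogram.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  cfg_json <- jsonlite::toJSON(config_fingerprint(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(package = "dfescan",
                   version = as.character(packageVersion("dfescan")),
                   seed = config$seed,
                   g_p = config$g_p,
                   beneficial_threshold = config$beneficial_threshold,
                   floor_reads = config$floor_reads,
                   selections = labels,
                   config_hash = unname(md5sum(cfg_file)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(structure(list(fitness = fits, dfe = dfe,
                           specificity = specificity,
                           structure = struct_out, manifest = manifest),
                      class = "pipeline_result"))
}

# Serializable fingerprint of a config (drops in-memory tables, keeps
# everything that determines the numbers).
config_fingerprint <- function(config) {
  sels <- lapply(config$selections, function(s) {
    list(counts = if (is.character(s$counts)) s$counts else "<in-memory>",
         g_p = s$g_p %||% config$g_p)
  })
  list(selections = sels, g_p = config$g_p,
       beneficial_threshold = config$beneficial_threshold,
       floor_reads = config$floor_reads, seed = config$seed,
       dfe_bootstrap = config$dfe_bootstrap)
}

# JSON-ready layout of per-selection DFE reports, mirroring the usual
# model-comparison table (per family: params, LL, AD P; LRT block; GPD GOF).
dfe_report_json <- function(dfe) {
  lapply(dfe, function(rep) {
    if (is.null(rep)) return(NULL)
    fams <- lapply(rep$fits, function(f) {
      list(params = as.list(f$estimate), loglik = f$loglik,
           ad_p = if (!is.null(f$ad)) f$ad$p)
    })
    list(n_exceedances = rep$n, threshold = rep$threshold,
         families = fams,
         lrt = lapply(rep$lrt, function(l) list(h0 = l$h0, ha = l$ha,
                                                llr = l$llr, p = l$p)),
         gpd_gof_p = if (!is.null(rep$gpd_gof)) rep$gpd_gof$p)
  })
}
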