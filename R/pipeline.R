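# ---- input loading ---------------------------------------------------------

load_inputs <- function(tree_path, landmarks_path, ecology_path,
                        modules_path = NULL) {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop_validation("could not read tree from %s", tree_path)
  lm <- read_landmark_file(landmarks_path)
  if (!is.null(modules_path))
    lm$module_of <- read_module_map(modules_path, n_landmarks(lm))
  eco <- read_ecology_csv(ecology_path)
  list(tree = tree, landmarks = lm, ecology = eco)
}

# ---- full analysis ---------------------------------------------------------

#' Run the full comparative analysis pipeline
#'
#' Orchestrates the whole analysis graph: taxon matching, per-module
#' Generalized Procrustes alignment, shape PCA, multivariate PGLS with RRPP
#' on the full aligned shape (`shape ~ habitat + primary_diet + size`),
#' univariate GLS term tests on PC1 and PC2, and phylogenetic two-block PLS
#' of shape against diet proportions on the quantitative-diet subset. One
#' combined results table per module is written (plus a morphospace table),
#' mirroring the usual summary layout of such studies, together with a run
#' manifest carrying the seeds.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `input` (paths `tree`, `landmarks`, `ecology`, optional `modules`) or
#'   `simulate` (a [sim_config()] argument list, or TRUE for defaults);
#'   `n_perm` (default 999); `term_order` (default habitat, primary_diet,
#'   size); `min_diet_records` (default 10); `seed` (default 1); `outdir`
#'   (default `"phylomorph_results"`).
#' @return invisibly, a named list (per module) of the combined tables, with
#'   the matched dataset and alignments attached as attributes.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  n_perm <- config$n_perm %||% 999
  seed <- config$seed %||% 1
  min_rec <- config$min_diet_records %||% 10
  term_order <- config$term_order %||% c("habitat", "primary_diet", "size")
  outdir <- config$outdir %||% "phylomorph_results"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$input)) {
    inp <- load_inputs(config$input$tree, config$input$landmarks,
                       config$input$ecology, config$input$modules)
  } else {
    sim_args <- if (isTRUE(config$simulate)) list() else config$simulate %||% list()
    cfg <- do.call(sim_config, sim_args)
    tree <- simulate_tree(cfg$n_taxa, cfg$birth_rate, seed = seed)
    eco <- simulate_ecology(tree, cfg, seed = seed + 1)
    lm <- simulate_landmark_dataset(tree, eco, cfg, seed = seed + 2)
    inp <- list(tree = tree, landmarks = lm, ecology = eco)
  }
  message(sprintf("[match] %d landmark taxa, %d ecology rows, %d tree tips",
                  n_taxa(inp$landmarks), nrow(inp$ecology),
                  length(inp$tree$tip.label)))
  md <- match_and_prune(inp$landmarks, inp$ecology, inp$tree)
  message(sprintf("[match] %d taxa retained", length(md$taxa)))
  C <- bm_covariance(md$tree, md$taxa)
  alignments <- module_alignments(md$landmarks)
  eco_q <- tryCatch(filter_quantitative_diet(md$ecology, min_rec),
                    phylomorph_validation_error = function(e) NULL)
  results <- list()
  for (mod in names(alignments)) {
    aln <- alignments[[mod]]
    message(sprintf("[%s] GPA: %d iterations", mod, aln$n_iterations))
    pca <- shape_pca(aln)
    pred_all <- data.frame(habitat = md$ecology$habitat,
                           primary_diet = md$ecology$primary_diet,
                           size = aln$log_centroid_size)[term_order]
    pg <- fit_pgls_rrpp(flatten_shapes(aln), pred_all, C,
                        n_perm = n_perm, seed = seed, drop_aliased = TRUE)
    g1 <- fit_gls_terms(pca$scores[, 1], pred_all, C, drop_aliased = TRUE)
    g2 <- if (pca$n_components >= 2)
      fit_gls_terms(pca$scores[, 2], pred_all, C, drop_aliased = TRUE) else NULL
    pls <- NULL
    if (!is.null(eco_q) && nrow(eco_q) >= 4) {
      qt <- eco_q$taxon
      idx <- match(qt, md$taxa)
      pls <- ppls_integration(flatten_shapes(aln)[idx, , drop = FALSE],
                              diet_proportion_matrix(eco_q),
                              C[idx, idx], n_perm = n_perm, seed = seed)
    }
    nt <- length(term_order)
    tab <- rbind(
      data.frame(analysis = "pgls_multivariate", term = pg$term[seq_len(nt)],
                 df = pg$df[seq_len(nt)], statistic = pg$F[seq_len(nt)],
                 Z = pg$Z[seq_len(nt)], p = pg$p[seq_len(nt)]),
      data.frame(analysis = "gls_PC1", term = g1$table$term,
                 df = g1$table$df, statistic = g1$table$chisq,
                 Z = NA, p = g1$table$p),
      if (!is.null(g2))
        data.frame(analysis = "gls_PC2", term = g2$table$term,
                   df = g2$table$df, statistic = g2$table$chisq,
                   Z = NA, p = g2$table$p),
      if (!is.null(pls))
        data.frame(analysis = "ppls_diet", term = "diet_proportions",
                   df = NA, statistic = pls$r_pls, Z = NA, p = pls$p))
    utils::write.csv(tab, file.path(outdir, paste0("table1_", mod, ".csv")),
                     row.names = FALSE, quote = FALSE)
    ms <- morphospace_table(pca, md$ecology)
    utils::write.csv(ms$table,
                     file.path(outdir, paste0("morphospace_", mod, ".csv")),
                     row.names = FALSE, quote = FALSE)
    results[[mod]] <- tab
  }
  jsonlite::write_json(list(seed = seed, n_perm = n_perm,
                            term_order = term_order,
                            n_taxa = length(md$taxa),
                            modules = names(alignments)),
                       file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(results, "matched") <- md
  attr(results, "alignments") <- alignments
  invisible(results)
}

# ---- command-line interface ------------------------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a fixture bundle), `gpa`, `pca`, `pgls`,
#' `gls`, `ppls` (single stages on input files), `robustness` (the
#' label-permutation sweep) and `all` (the full pipeline,
#' [run_full_analysis()]). Options are `--key value` pairs; common ones are
#' `--tree`, `--landmarks`, `--ecology`, `--modules`, `--out`, `--seed`,
#' `--n_perm`, `--config` (YAML, for `all`). Logs go to stderr, results to
#' files only.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 success, 2 validation error, 3 numerical
#'   failure.
#' @export
phylomorph_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    .cli_dispatch(args)
    0L
  }, phylomorph_validation_error = function(e) {
    message("validation error: ", conditionMessage(e)); 2L
  }, phylomorph_numerical_error = function(e) {
    message("numerical failure: ", conditionMessage(e)); 3L
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 3L
  })
  code
}

.cli_dispatch <- function(args) {
  if (!length(args)) stop_validation("usage: phylomorph <subcommand> [--options]")
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1)
  out <- opt$out %||% "phylomorph_out"
  n_perm <- as.integer(opt$n_perm %||% 999)
  stage_inputs <- function() {
    for (need in c("tree", "landmarks", "ecology"))
      if (is.null(opt[[need]])) stop_validation("missing --%s", need)
    load_inputs(opt$tree, opt$landmarks, opt$ecology, opt$modules)
  }
  switch(cmd,
    simulate = {
      cfg <- if (identical(opt$profile, "paper")) paper_scale_config()
             else sim_config()
      write_fixture_bundle(out, cfg, seed = seed)
      message("fixture bundle written to ", out)
    },
    all = {
      config <- if (!is.null(opt$config)) yaml::read_yaml(opt$config)
                else list(input = list(tree = opt$tree,
                                       landmarks = opt$landmarks,
                                       ecology = opt$ecology,
                                       modules = opt$modules))
      config$outdir <- config$outdir %||% out
      config$n_perm <- config$n_perm %||% n_perm
      config$seed <- config$seed %||% seed
      run_full_analysis(config)
    },
    gpa = {
      inp <- stage_inputs()
      md <- match_and_prune(inp$landmarks, inp$ecology, inp$tree)
      alns <- module_alignments(md$landmarks)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (mod in names(alns)) {
        flat <- flatten_shapes(alns[[mod]])
        utils::write.csv(
          data.frame(taxon = rownames(flat),
                     log_centroid_size = alns[[mod]]$log_centroid_size, flat,
                     check.names = FALSE),
          file.path(out, paste0("aligned_", mod, ".csv")), row.names = FALSE)
        jsonlite::write_json(
          list(module = mod, n_iterations = alns[[mod]]$n_iterations,
               converged = alns[[mod]]$converged,
               objective = alns[[mod]]$objective),
          file.path(out, paste0("gpa_report_", mod, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    },
    pca = {
      inp <- stage_inputs()
      md <- match_and_prune(inp$landmarks, inp$ecology, inp$tree)
      alns <- module_alignments(md$landmarks)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (mod in names(alns))
        write_pca_csv(shape_pca(alns[[mod]]),
                      file.path(out, paste0("pca_", mod, ".csv")))
    },
    pgls = , gls = , ppls = {
      inp <- stage_inputs()
      md <- match_and_prune(inp$landmarks, inp$ecology, inp$tree)
      C <- bm_covariance(md$tree, md$taxa)
      alns <- module_alignments(md$landmarks)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      for (mod in names(alns)) {
        aln <- alns[[mod]]
        pred <- data.frame(habitat = md$ecology$habitat,
                           primary_diet = md$ecology$primary_diet,
                           size = aln$log_centroid_size)
        fit <- switch(cmd,
          pgls = fit_pgls_rrpp(flatten_shapes(aln), pred, C,
                               n_perm = n_perm, seed = seed,
                               drop_aliased = TRUE),
          gls = fit_gls_terms(shape_pca(aln)$scores[, 1], pred, C,
                              drop_aliased = TRUE),
          ppls = {
            eco_q <- filter_quantitative_diet(md$ecology)
            idx <- match(eco_q$taxon, md$taxa)
            ppls_integration(flatten_shapes(aln)[idx, , drop = FALSE],
                             diet_proportion_matrix(eco_q), C[idx, idx],
                             n_perm = n_perm, seed = seed)
          })
        write_fit(fit, file.path(out, paste0(cmd, "_", mod, ".csv")))
      }
    },
    robustness = {
      inp <- stage_inputs()
      md <- match_and_prune(inp$landmarks, inp$ecology, inp$tree)
      aln <- module_alignments(md$landmarks)[[1]]
      sizes <- as.integer(strsplit(opt$subset_sizes %||% "25,50,75", ",")[[1]])
      n_reps <- as.integer(opt$n_reps %||% 200)
      grid <- rbind(
        robustness_sweep(flatten_shapes(aln), md$ecology, md$tree,
                         aln$log_centroid_size, sizes, n_reps,
                         "true_labels", n_perm = n_perm, seed = seed),
        robustness_sweep(flatten_shapes(aln), md$ecology, md$tree,
                         aln$log_centroid_size, sizes, n_reps,
                         "permuted_labels", n_perm = n_perm, seed = seed + 1))
      summ <- summarize_pvalues(grid)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(grid, file.path(out, "robustness_grid.csv"),
                       row.names = FALSE)
      utils::write.csv(summ$summary, file.path(out, "robustness_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(summ$histogram,
                       file.path(out, "robustness_histogram.csv"),
                       row.names = FALSE)
    },
    stop_validation("unknown subcommand '%s'", cmd))
  invisible(NULL)
}
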