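#' Run the full per-species association pipeline
#'
#' End-to-end driver mirroring the three-step flow: read and align the
#' inputs, filter low-variability genes, compute the genetic relatedness
#' matrix, run the permutation population-structure test, run the per-gene
#' score tests, fit the empirical-null localFDR model on the signed z-values
#' (when enough genes are available), and write a result bundle to
#' `out_dir`: `grm.tsv`, `tau_results.tsv`, `gene_results.tsv`,
#' `fdr_model.json` and a `MANIFEST.json` run log with the seed, filter
#' counts and convergence diagnostics. On a stage failure the partial
#' outputs are preserved and the manifest records the failed stage before
#' the error is re-signalled.
#'
#' @param pangenome_path TSV path for the presence/absence matrix.
#' @param metadata_path TSV path for the sample metadata.
#' @param trait trait column name in the metadata.
#' @param covariates covariate column names (may be NULL).
#' @param out_dir output directory (created if needed).
#' @param B permutations for the population-structure test.
#' @param seed integer seed.
#' @param orientation pangenome file orientation (see [read_pangenome()]).
#' @param link model link (see [fit_null_model()]).
#' @param min_absent,min_present gene variability filter thresholds.
#' @param fdr_threshold_beta localFDR cutoff for gene calls.
#' @param spa apply the saddlepoint correction.
#' @return Invisibly, a list with `tau`, `genes`, `fdr_model`, `Psi`,
#'   `filter_counts` and the output paths.
#' @export
run_species_pipeline <- function(pangenome_path, metadata_path, trait,
                                 covariates = NULL, out_dir = ".",
                                 B = 1000, seed = 1,
                                 orientation = "samples_in_rows",
                                 link = "auto",
                                 min_absent = 10, min_present = 30,
                                 fdr_threshold_beta = 0.2, spa = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, B = B, trait = trait,
                   covariates = covariates, stages = list())
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  inputs <- stage("read", {
    G <- read_pangenome(pangenome_path, orientation = orientation)
    traits <- read_trait_table(metadata_path, trait = trait,
                               covariates = covariates)
    align_samples(G, traits)
  })
  G <- stage("filter", {
    filter_variable_genes(inputs$G, min_absent = min_absent,
                          min_present = min_present)
  })
  filter_counts <- attr(G, "removed")
  manifest$filter_counts <- as.list(filter_counts)
  Psi <- stage("grm", {
    Psi <- compute_grm(G)
    write_grm(Psi, file.path(out_dir, "grm.tsv"))
    Psi
  })
  tau <- stage("tau_test", {
    res <- tau_test(inputs$traits, Psi, B = B, seed = seed, link = link)
    write_tau_results(res, file.path(out_dir, "tau_results.tsv"))
    res
  })
  manifest$tau <- list(tau_hat = tau$tau_hat, p_value = tau$p_value,
                       auc = tau$auc, converged = tau$fit$converged)
  genes <- stage("beta_tests", {
    run_beta_tests(tau$fit, G, spa = spa)
  })
  fdr_model <- stage("local_fdr", {
    testable <- genes$z_signed[!genes$untestable]
    if (length(testable) >= 200) {
      m <- fit_local_fdr(testable)
      genes <<- call_significant(genes, m, threshold = fdr_threshold_beta)
      write_fdr_model(m, file.path(out_dir, "fdr_model.json"))
      m
    } else {
      manifest$notes <<- c(manifest$notes,
                           "fewer than 200 testable genes: localFDR skipped")
      NULL
    }
  })
  stage("write_genes", {
    data.table::fwrite(genes, file.path(out_dir, "gene_results.tsv"),
                       sep = "\t")
  })
  manifest$n_samples <- length(inputs$traits$sample_ids)
  manifest$n_genes_tested <- nrow(genes)
  manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  manifest$status <- "ok"
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(tau = tau, genes = genes, fdr_model = fdr_model, Psi = Psi,
                 filter_counts = filter_counts, out_dir = out_dir))
}
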