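#' Run the full analysis pipeline
#'
#' Chains the stages — simulate (or load) a dataset, call haplotypes,
#' compute diversity, run the spatial randomization test, validate the
#' null model, and summarise population structure — writing every
#' artifact under `output_dir` together with a JSON manifest recording
#' stage provenance, the seed, and the software version. All stages are
#' deterministic given `seed`.
#'
#' @param config a named list; recognised fields (all optional unless
#'   noted):
#'   \describe{
#'     \item{fasta, metadata}{paths to an input FASTA + TSV; if absent a
#'       dataset is simulated from `sim` (a [sim_config()]) instead.}
#'     \item{sim}{a [sim_config()] used when no input files are given
#'       (default study-scale null configuration).}
#'     \item{stages}{character subset of `c("haplotypes", "diversity",
#'       "spatial_test", "validate_null", "structure")`; default all.}
#'     \item{M}{random tables for the spatial test (default 10000).}
#'     \item{fdr}{FDR rate for cell calls (default 0.10).}
#'     \item{pool}{optional named location -> group vector; adds a pooled
#'       spatial test.}
#'     \item{validation_tests, validation_reps}{harness sizes (default
#'       1000 x 1000).}
#'     \item{alpha}{validation significance level (default 0.05).}
#'     \item{n_perm}{permutations for structure statistics (default 1000).}
#'     \item{seed}{integer master seed (required).}
#'     \item{output_dir}{output directory (required).}
#'   }
#' @return invisibly, the manifest (named list of artifact paths by
#'   stage), also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed),
            !is.null(config$output_dir))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stages <- config$stages %||% c("haplotypes", "diversity", "spatial_test",
                                 "validate_null", "structure")
  M <- config$M %||% 10000L
  fdr <- config$fdr %||% 0.10
  alpha <- config$alpha %||% 0.05
  n_perm <- config$n_perm %||% 1000L
  seed <- as.integer(config$seed)
  set.seed(seed)
  stage_seeds <- stats::setNames(sample.int(.Machine$integer.max, 6L),
                                 c("simulate", "haplotypes", "spatial_test",
                                   "validate_null", "structure", "spare"))
  manifest <- list(seed = seed, M = M, fdr = fdr,
                   version = as.character(utils::packageVersion("haplospat")),
                   artifacts = list())
  log_line <- function(...) message("[haplospat] ", sprintf(...))

  run_stage <- function(name, fn) {
    log_line("stage %s (seed %d, M = %d, fdr = %.2f)", name, seed, M, fdr)
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # inputs: load or simulate
  if (!is.null(config$fasta)) {
    if (!file.exists(config$fasta))
      stop("input file not found: ", config$fasta)
    if (is.null(config$metadata) || !file.exists(config$metadata %||% ""))
      stop("input file not found: ", config$metadata %||% "<metadata>")
    records <- run_stage("load", function()
      read_fasta_with_metadata(config$fasta, config$metadata))
  } else {
    cfg <- config$sim %||% sim_config(seed = stage_seeds[["simulate"]])
    cfg$seed <- cfg$seed %||% stage_seeds[["simulate"]]
    ds <- run_stage("simulate", function() simulate_coi_dataset(cfg))
    paths <- write_coi_dataset(ds, file.path(out, "simulated"))
    manifest$artifacts$simulate <- as.list(paths)
    records <- read_fasta_with_metadata(paths[["fasta"]],
                                        paths[["metadata"]])
  }

  catalog <- NULL
  if ("haplotypes" %in% stages) {
    catalog <- run_stage("haplotypes", function()
      call_haplotypes(records, trim_to_common_region = TRUE))
    qc <- qc_report(catalog)
    # NUMT-flagged sequences are excluded from downstream counts
    bad <- qc$haplotype[qc$has_premature_stop]
    if (length(bad)) {
      log_line("excluding %d haplotype(s) failing stop-codon QC",
               length(bad))
      keep_ids <- names(catalog$members)[!(catalog$members %in% bad)]
      records <- records[records$id %in% keep_ids, , drop = FALSE]
      catalog <- call_haplotypes(records, trim_to_common_region = TRUE)
      qc <- qc_report(catalog)
    }
    p_counts <- file.path(out, "haplotype_counts.csv")
    write_count_matrix(catalog$counts, p_counts)
    p_qc <- file.path(out, "qc_report.json")
    jsonlite::write_json(qc, p_qc, auto_unbox = TRUE, digits = NA)
    manifest$artifacts$haplotypes <- list(counts = p_counts, qc = p_qc)
  }

  if ("diversity" %in% stages && !is.null(catalog)) {
    div <- run_stage("diversity", function() {
      hd <- haplotype_diversity(rowSums(catalog$counts))
      nd <- nucleotide_diversity(catalog)
      list(overall = list(h = hd[["h"]], h_se = hd[["se"]],
                          pi = nd[["pi"]], pi_se = nd[["se"]],
                          n = catalog$n),
           by_location = diversity_by_group(records))
    })
    p_div <- file.path(out, "diversity.json")
    jsonlite::write_json(div, p_div, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    manifest$artifacts$diversity <- list(diversity = p_div)
  }

  st <- NULL
  if ("spatial_test" %in% stages && !is.null(catalog)) {
    st <- run_stage("spatial_test", function()
      spatial_test(catalog$counts, M = M, fdr = fdr,
                   seed = stage_seeds[["spatial_test"]]))
    p_st <- file.path(out, "spatial_test.json")
    write_spatial_test(st, p_st, heat_csv = file.path(out, "heat_table.csv"))
    manifest$artifacts$spatial_test <-
      list(result = p_st, heat = file.path(out, "heat_table.csv"))
    if (!is.null(config$pool)) {
      stp <- spatial_test(catalog$counts, M = M, fdr = fdr,
                          seed = stage_seeds[["spatial_test"]],
                          pool = config$pool)
      p_stp <- file.path(out, "spatial_test_pooled.json")
      write_spatial_test(stp, p_stp)
      manifest$artifacts$spatial_test$pooled <- p_stp
    }
  }

  if ("validate_null" %in% stages && !is.null(catalog)) {
    v <- run_stage("validate_null", function()
      validate_null(catalog$counts,
                    n_tests = config$validation_tests %||% 1000L,
                    reps_per_test = config$validation_reps %||% 1000L,
                    alpha = alpha, seed = stage_seeds[["validate_null"]]))
    p_val <- file.path(out, "validation.json")
    write_validation_report(v, p_val)
    manifest$artifacts$validate_null <- list(report = p_val)
  }

  if ("structure" %in% stages && !is.null(catalog)) {
    res <- run_stage("structure", function() {
      d2 <- catalog_pairwise_differences(catalog)
      pops <- records$location[match(names(catalog$members), records$id)]
      pw <- pairwise_phist_matrix(d2, pops, n_perm = n_perm,
                                  seed = stage_seeds[["structure"]])
      am <- amova(d2, pops, group = config$group %||% NULL,
                  n_perm = n_perm, seed = stage_seeds[["structure"]])
      list(pw = pw, am = am)
    })
    p_phi <- file.path(out, "pairwise_phist.csv")
    utils::write.csv(res$pw$phist, p_phi, quote = FALSE)
    p_phip <- file.path(out, "pairwise_phist_p.csv")
    utils::write.csv(res$pw$p, p_phip, quote = FALSE)
    p_am <- file.path(out, "amova.json")
    jsonlite::write_json(
      list(components = res$am$components, phi = as.list(res$am$phi),
           p = as.list(res$am$p)),
      p_am, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest$artifacts$structure <-
      list(phist = p_phi, phist_p = p_phip, amova = p_am)
  }

  p_manifest <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
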