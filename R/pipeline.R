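#' Run the full radiomic analysis pipeline
#'
#' Executes the stages extract -> select -> classify -> prognosis ->
#' radiogenomics on in-memory inputs and writes each stage's artifacts to a
#' run directory. All randomness flows from \code{config$seed}, so a run is
#' a pure function of (inputs, config). Any stage failure aborts with the
#' stage name and cause.
#'
#' @param config an \code{\link{analysis_config}}.
#' @param inputs list with \code{volumes}, \code{masks} (named lists),
#'   \code{clinical} (\code{\link{clinical_cohort}}), optional
#'   \code{expression} (\code{\link{expression_matrix}}), optional
#'   \code{annotation} (term -> genes list for enrichment), optional
#'   precomputed \code{features} (\code{\link{feature_table}}, skips
#'   extraction).
#' @param out_dir run directory (created if missing).
#' @param stages character subset of
#'   c("extract", "select", "classify", "prognosis", "radiogenomics").
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, inputs, out_dir,
                         stages = c("extract", "select", "classify",
                                    "prognosis", "radiogenomics")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  features <- inputs$features
  if ("extract" %in% stages && is.null(features)) {
    features <- run_stage("extract", extract_cohort(
      inputs$volumes, inputs$masks, config = config))
    write_feature_table(features, file.path(out_dir, "features.csv"))
  }
  res$features <- features
  if (is.null(features)) stop("pipeline stage 'extract' failed: no features",
                              call. = FALSE)
  clinical <- inputs$clinical

  sam <- NULL
  selected <- NULL
  if ("select" %in% stages) {
    sam <- run_stage("select", {
      if (is.null(clinical$label)) stop("selection requires phenotype labels")
      sam_select(features, clinical$label[match(features$sample_ids,
                                                clinical$sample_id)],
                 fdr_threshold = config$fdr_threshold,
                 n_permutations = config$n_permutations,
                 seed = config$seed)
    })
    utils::write.csv(sam, file.path(out_dir, "sam_results.csv"),
                     row.names = FALSE)
    selected <- sam$item[sam$selected]
    res$sam <- sam
  }

  if ("classify" %in% stages) {
    elim <- run_stage("classify", {
      if (is.null(clinical$label))
        stop("classification requires phenotype labels")
      feats <- if (length(selected)) selected else features$feature_names
      y <- as.numeric(clinical$label[match(features$sample_ids,
                                           clinical$sample_id)] == "MUT")
      backward_eliminate(features$values[, feats, drop = FALSE], y,
                         lambda = config$ridge)
    })
    utils::write.csv(elim$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(features = elim$selected_features,
           coefficients = as.list(elim$model$coefficients),
           intercept = elim$model$intercept,
           center = as.list(elim$model$center),
           scale = as.list(elim$model$scale),
           lambda = elim$model$lambda),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    res$classifier <- elim
  }

  if ("prognosis" %in% stages) {
    prog <- run_stage("prognosis", {
      if (is.null(clinical$os_days)) stop("prognosis requires survival data")
      feats <- if (length(selected)) selected else features$feature_names
      ord <- match(features$sample_ids, clinical$sample_id)
      rm_mod <- select_prognostic_features(
        feature_table(features$values[, feats, drop = FALSE],
                      features$sample_ids, feats),
        clinical$os_days[ord], clinical$event[ord],
        alpha = config$cox_pvalue_threshold,
        min_days = config$min_survival_days)
      if (!length(rm_mod$feature_names))
        stop("no prognostic features at alpha = ",
             config$cox_pvalue_threshold)
      scores <- risk_score(features, rm_mod)
      cut <- optimal_cutoff(scores, clinical$os_days[ord],
                            clinical$event[ord])
      rm_mod$cutoff <- cut$cutoff
      list(model = rm_mod, scores = scores, cut = cut, ord = ord)
    })
    utils::write.csv(prog$model$univariate,
                     file.path(out_dir, "cox_univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = features$sample_ids,
                                risk_score = prog$scores,
                                risk_group = ifelse(prog$scores >
                                                      prog$model$cutoff,
                                                    "high", "low")),
                     file.path(out_dir, "risk_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(cutoff = prog$model$cutoff,
                              logrank_p = prog$cut$p),
                         file.path(out_dir, "cutoff.json"),
                         auto_unbox = TRUE, digits = NA)
    res$prognosis <- prog
  }

  if ("radiogenomics" %in% stages && !is.null(inputs$expression)) {
    rg <- run_stage("radiogenomics", {
      feats <- if (length(selected)) selected else features$feature_names
      tab <- pearson_feature_gene(
        feature_table(features$values[, feats, drop = FALSE],
                      features$sample_ids, feats),
        inputs$expression,
        r_threshold = config$correlation_threshold)
      enr <- NULL
      if (!is.null(inputs$annotation)) {
        sig_genes <- unique(tab$gene[tab$significant])
        if (length(sig_genes))
          enr <- hypergeometric_enrichment(sig_genes, inputs$annotation,
                                           inputs$expression$gene_ids)
      }
      list(correlations = tab, enrichment = enr)
    })
    utils::write.csv(rg$correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    if (!is.null(rg$enrichment))
      utils::write.csv(rg$enrichment, file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE)
    res$radiogenomics <- rg
  }
  invisible(res)
}
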