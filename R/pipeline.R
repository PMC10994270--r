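default_config <- function() {
  list(
    seed = 1L,
    design = list(n_subclones = 3, concentrations = c(100, 300, 1000),
                  n_compounds = 330, wt_vehicle_wells_per_plate = 24,
                  ko_vehicle_wells_per_plate = 16,
                  ko_untreated_wells_per_plate = 6, fields_per_well = 4),
    simulation = list(n_features = 1100, affected_fraction = 0.2,
                      genotype_effect = 1.0, n_reverters = 10,
                      reverter_rho_min = 0.8, null_rho_max = 0.15,
                      rho_star = 0.8, offtarget_max = 0.2, n_latent = 20,
                      block_r = 0.3, sigma_plate = 0.1, sigma_well = 0.1,
                      sigma_field = 1.0, toxic_fraction = 0,
                      dose_scaling = TRUE),
    qc = list(statistic = "median", anchor = "ko_vehicle", rank_tol = 1e-8,
              r_threshold = 0.95, alpha = 0.05),
    reduction = list(rule = "fixed", k = 50, rotation = "oblimin", gamma = 0),
    separation = list(metric = "bray_curtis", n_perm = 999),
    classifier = list(algorithm = "nn", size_grid = c(4, 8),
                      decay_grid = c(0.01, 0.1), cv_folds = 2,
                      test_fraction = 0.2, focus_class = "WT", maxit = 300),
    hits = list(tau = 0.505, mode = "any_conc"),
    enrichment = list(enabled = TRUE, gmt = NULL, expressed = NULL,
                      targets = NULL)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop("configuration key ", full, " must be a list")
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[key] <- list(override[[key]])  # keeps explicit NULLs in place
    }
  }
  base
}

#' Build a pipeline configuration
#'
#' Returns the full default configuration of the end-to-end screen pipeline
#' with any overrides merged in. Unknown keys are rejected. One root `seed`
#' deterministically derives the per-stage seeds, so a single integer
#' reproduces an entire screen.
#'
#' @param seed Root seed.
#' @param ... Named stage override lists (`design`, `simulation`, `qc`,
#'   `reduction`, `separation`, `classifier`, `hits`, `enrichment`).
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 7, reduction = list(k = 20))
pipeline_config <- function(seed = 1, ...) {
  cfg <- merge_config(default_config(), list(...))
  cfg$seed <- as.integer(seed)
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @param config Configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- if (!is.null(raw$seed)) raw$seed else 1
  raw$seed <- NULL
  do.call(pipeline_config, c(list(seed = seed), raw))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "morphoscreen", mustWork = TRUE)
}

#' Run the full screen pipeline
#'
#' One-command end-to-end run: simulate the screen, feature QC, dimension
#' reduction, control separation test, classifier training/evaluation,
#' compound scoring, hit calling with salt-form collapsing and mechanism
#' grouping, and gene-set enrichment of the hit drugs' annotated targets.
#' When `output_dir` is given, stage outputs (CSV/TSV/JSON) are written
#' there; the returned report embeds the exact configuration used.
#'
#' @param config List from [pipeline_config()].
#' @param output_dir Optional directory for stage outputs.
#' @param input Optional pre-simulated screen (list with `table` and
#'   optionally `truth`, as from [simulate_screen()]); when supplied the
#'   simulate stage is skipped and the tables are analysed as-is.
#' @return A `screen_report` list with elements `config`, `design`,
#'   `truth`, `qc`, `reduction` (k, eigenvalue head), `separation`,
#'   `classifier`, `scores`, `hits`, `drugs`, `mechanism`, `recovery`,
#'   `enrichment`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         input = NULL) {
  stage <- "design"
  report <- list(config = config)
  stage_warnings <- character(0)
  res <- withCallingHandlers(tryCatch({
    design <- do.call(screen_design, config$design)
    manifest <- default_library_manifest(config$design$n_compounds)

    stage <- "simulate"
    if (is.null(input)) {
      sp <- do.call(sim_params,
                    c(config$simulation,
                      list(seed = derive_seed(config$seed, "simulate"))))
      input <- simulate_screen(design, sp)
    }
    tab <- input$table
    truth <- input$truth

    stage <- "qc"
    qc <- do.call(run_feature_qc, c(list(tab = tab), config$qc))

    stage <- "reduce"
    red <- do.call(reduce_profiles, c(list(tab = qc$wells), config$reduction))

    stage <- "separate"
    ctrl <- red$scores$treatment == "VEHICLE"
    sep <- permutation_test(
      as.matrix(red$scores[ctrl, score_columns(red$scores), drop = FALSE]),
      red$scores$genotype[ctrl],
      metric = config$separation$metric,
      n_perm = config$separation$n_perm,
      seed = derive_seed(config$seed, "separate"))

    stage <- "train"
    spec <- do.call(classifier_spec,
                    c(config$classifier,
                      list(seed = derive_seed(config$seed, "train"))))
    img <- apply_feature_qc(qc, tab)
    img_scores <- predict(red, img)
    controls <- img_scores[img_scores$treatment == "VEHICLE", , drop = FALSE]
    split <- split_controls(controls, spec)
    model <- train_classifier(split$train, spec)
    eval <- evaluate_classifier(model, split$test)

    stage <- "score"
    compound_ids <- manifest$compound_id
    treated <- img_scores[img_scores$treatment %in% compound_ids, , drop = FALSE]
    scores <- score_treated(model, treated)

    stage <- "hits"
    hits <- call_hits(scores, tau = config$hits$tau, mode = config$hits$mode,
                      subclones = sprintf("SC%d", seq_len(design$n_subclones)))
    collapsed <- collapse_salt_forms(hits, manifest)
    mech <- summarize_by_mechanism(collapsed$drugs)
    recovery <- if (!is.null(truth)) hit_recovery(hits, truth) else NULL

    stage <- "enrich"
    enrich <- NULL
    if (isTRUE(config$enrichment$enabled) && collapsed$n_drug_hits > 0) {
      gmt <- if (is.null(config$enrichment$gmt))
        fixture_path("synthetic_gene_sets.gmt") else config$enrichment$gmt
      expr_path <- if (is.null(config$enrichment$expressed))
        fixture_path("synthetic_expressed_genes.txt") else config$enrichment$expressed
      tgt_path <- if (is.null(config$enrichment$targets))
        fixture_path("synthetic_drug_targets.tsv") else config$enrichment$targets
      collection <- read_gmt(gmt)
      expressed <- readLines(expr_path, warn = FALSE)
      targets <- read_drug_targets(tgt_path)
      query0 <- unlist(targets[collapsed$drugs$parent_drug], use.names = FALSE)
      query <- filter_by_expression(unique(query0), expressed)
      enrich <- if (length(query))
        hypergeometric_enrichment(query, collection, expressed) else NULL
    }

    list(design = design, truth = truth, qc = qc, red = red, sep = sep,
         model = model, eval = eval, scores = scores, hits = hits,
         collapsed = collapsed, mech = mech, recovery = recovery,
         enrich = enrich)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }), warning = function(w) {
    stage_warnings <<- c(stage_warnings,
                         paste0(stage, ": ", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })

  report <- c(report, list(
    design = list(n_plates = nrow(res$design$plates),
                  wells_per_plate = nrow(res$design$layout),
                  fields_per_well = res$design$fields_per_well),
    truth = res$truth,
    qc = list(n_input_features = config$simulation$n_features,
              n_retained = length(res$qc$retained),
              dropped = lapply(res$qc$dropped, length),
              n_significant = res$qc$report$n_significant,
              n_tested = res$qc$report$n_tested),
    reduction = list(k = res$red$k, rule = res$red$rule,
                     rotation = res$red$rotation,
                     eigenvalues_head = head(res$red$eigenvalues, 10)),
    separation = res$sep[c("metric", "D", "p", "n_perm", "group_sizes")],
    classifier = unclass(res$eval),
    hits = list(n_compound_hits = res$collapsed$n_compound_hits,
                n_drug_hits = res$collapsed$n_drug_hits,
                tau = config$hits$tau, mode = config$hits$mode,
                hit_compounds = res$hits$compound_id[res$hits$hit]),
    mechanism = res$mech,
    recovery = res$recovery,
    enrichment = list(
      n_sets_tested = if (!is.null(res$enrich)) nrow(res$enrich) else 0L,
      n_sets_q05 = if (!is.null(res$enrich)) sum(res$enrich$q < 0.05) else 0L,
      top = if (!is.null(res$enrich)) head(res$enrich, 5) else NULL),
    stage_warnings = stage_warnings))
  class(report) <- "screen_report"

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(output_dir, f)
    data.table::fwrite(res$qc$wells, out("wells_qc.csv"))
    data.table::fwrite(res$red$scores, out("component_scores.csv"))
    data.table::fwrite(res$scores, out("compound_scores.csv"))
    data.table::fwrite(as.data.frame(res$hits), out("hit_table.csv"))
    data.table::fwrite(res$collapsed$drugs, out("hit_drugs.csv"))
    data.table::fwrite(res$mech, out("mechanism_summary.csv"))
    if (!is.null(res$enrich)) write_enrichment(res$enrich, out("enrichment.tsv"))
    if (!is.null(res$truth)) write_ground_truth(res$truth, out("ground_truth.json"))
    jsonlite::write_json(report_for_json(report), out("screen_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  attr(report, "objects") <- res
  report
}

report_for_json <- function(report) {
  r <- unclass(report)
  attr(r, "objects") <- NULL
  r
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report\n")
  cat(sprintf("  design: %d plates, %d wells/plate, %d fields/well\n",
              x$design$n_plates, x$design$wells_per_plate,
              x$design$fields_per_well))
  cat(sprintf("  qc: %d -> %d features retained, %d significant (ANOVA+BH)\n",
              x$qc$n_input_features, x$qc$n_retained, x$qc$n_significant))
  cat(sprintf("  reduction: k = %d (%s, %s)\n", x$reduction$k,
              x$reduction$rule, x$reduction$rotation))
  cat(sprintf("  separation (%s): D = %.3f, p = %.3g\n",
              x$separation$metric, x$separation$D, x$separation$p))
  cat(sprintf("  classifier accuracy %.3f (sens %.3f, spec %.3f)\n",
              x$classifier$accuracy, x$classifier$sensitivity,
              x$classifier$specificity))
  cat(sprintf("  hits: %d compounds -> %d drugs (tau = %.3f, %s)\n",
              x$hits$n_compound_hits, x$hits$n_drug_hits, x$hits$tau,
              x$hits$mode))
  if (!is.null(x$recovery))
    cat(sprintf("  recovery: %d/%d true reverters, %d false positives\n",
                x$recovery$recovered, x$recovery$n_true_reverters,
                x$recovery$false_positives))
  invisible(x)
}

#' Read a synthetic drug-to-target annotation table
#'
#' Tab-separated with columns `parent_drug` and `targets` (semicolon-joined
#' gene symbols). This is packaged synthetic annotation for the fixture
#' library; see `inst/extdata/synthetic_drug_targets.tsv`.
#'
#' @param path TSV path.
#' @return Named list: parent drug -> character vector of target genes.
#' @export
read_drug_targets <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!all(c("parent_drug", "targets") %in% names(dt)))
    stop("drug-target table needs columns parent_drug and targets")
  setNames(lapply(strsplit(dt$targets, ";", fixed = TRUE),
                  function(g) toupper(trimws(g))),
           dt$parent_drug)
}
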