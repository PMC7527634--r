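#' Default end-to-end run configuration
#'
#' A nested list mirroring every stage's parameters; [run_pipeline()]
#' validates it and rejects unknown keys. By default the pipeline simulates
#' a planted-signal dataset, extracts the blocks the chosen hybrid group
#' needs, ranks them by SVM-RFE, combines them (G3 by default) and
#' cross-validates the network classifier.
#'
#' @return a named list; edit fields or supply the same structure as YAML.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    input = list(fasta = NULL, label_source = "header-token", sidecar = NULL),
    simulate = list(n_pos = 200, n_neg = 200, length_low = 500,
                    length_high = 500, effect = 0.15,
                    planted_kmers = c("AAA", "TTT"), gc_shift = 0),
    features = list(gdc_gaps = 0:7, rcc_ks = c(3, 4, 5),
                    psetnc_lam = 2, psetnc_w = 0.1, bank_ks = 1:5),
    selection = list(sizes = list(G = 5, R = 12, P = 66, H = 425),
                     cost = 1, step = NULL),
    hybrid = list(group = "G3", a = NULL, lam_mix = NULL),
    classifier = list(kind = "dnn", hidden_widths = c(64, 32),
                      activation = "tanh", learning_rate = 0.1,
                      iterations = 300, seed = 6),
    cv = list(k = 10, leakage_mode = "fold-internal-selection")
  )
}

.validate_config <- function(config) {
  ref <- default_run_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (section in setdiff(names(config), "classifier")) {
    if (is.list(ref[[section]]) && is.list(config[[section]])) {
      bad <- setdiff(names(config[[section]]), names(ref[[section]]))
      if (length(bad))
        stop(sprintf("unknown config keys in `%s`: %s", section,
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(config$classifier)) {
    # the classifier section is replaced wholesale, not merged: its keys
    # depend on the kind (dnn_config arguments vs baseline params)
    allowed <- c("kind", "params", setdiff(names(formals(dnn_config)),
                                           "input_width"))
    bad <- setdiff(names(config$classifier), allowed)
    if (length(bad))
      stop("unknown config keys in `classifier`: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(ref, config)
  if (!is.null(config$classifier)) merged$classifier <- config$classifier
  merged
}

#' Run the full pipeline and write a reproducible run directory
#'
#' Stages: simulate (or read FASTA) -> extract the needed blocks -> rank ->
#' combine -> cross-validate -> report. Every intermediate is written to
#' `out_dir` (FASTA, block and hybrid matrices as TSV, rankings as TSV,
#' the CV report as JSON + TSV) together with a manifest recording package
#' version, seeds and parameters; a rerun with the same config reproduces
#' the outputs.
#'
#' @param config a config list as from [default_run_config()], or a path to
#'   a YAML file with the same structure. Unknown keys are rejected.
#' @param out_dir output directory (created if needed).
#' @return the `cv_report`, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("recspot_run_")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  dataset <- stage("input", {
    if (!is.null(config$input$fasta)) {
      read_fasta(config$input$fasta,
                 label_source = config$input$label_source,
                 sidecar = config$input$sidecar)
    } else {
      sim <- config$simulate
      generate_synthetic_dataset(simulation_spec(
        n_pos = sim$n_pos, n_neg = sim$n_neg,
        length_low = sim$length_low, length_high = sim$length_high,
        effect = sim$effect, planted_kmers = sim$planted_kmers,
        gc_shift = sim$gc_shift, seed = config$seed))
    }
  })
  write_fasta(dataset, file.path(out_dir, "dataset.fa"))

  pipeline <- stage("configure", {
    fe <- config$features
    cls <- config$classifier
    hy <- config$hybrid
    args <- list(selection_sizes = config$selection$sizes,
                 gdc_gaps = fe$gdc_gaps, rcc_ks = fe$rcc_ks,
                 bank_ks = fe$bank_ks,
                 psetnc = psetnc_params(lam = fe$psetnc_lam, w = fe$psetnc_w),
                 rfe_cost = config$selection$cost,
                 rfe_step = config$selection$step,
                 classifier = cls)
    # explicit weights override the named group
    if (!is.null(hy$a) && !is.null(hy$lam_mix)) {
      args$a <- hy$a; args$lam_mix <- hy$lam_mix
    } else args$group <- hy$group
    do.call(pipeline_spec, args)
  })

  hspec <- hybrid_spec(pipeline$a, pipeline$lam_mix, pipeline$selection_sizes)
  blocks <- stage("extract",
                  .extract_needed_blocks(dataset, pipeline, hspec$takes))
  y01 <- ifelse(dataset$label == "hotspot", 0L, 1L)
  for (b in names(blocks))
    write_feature_tsv(blocks[[b]], file.path(out_dir, paste0("block_", b, ".tsv")),
                      labels = dataset$label)

  rankings <- stage("select",
                    .rank_blocks(blocks, y01, seq_along(y01), hspec$takes,
                                 pipeline))
  for (b in names(rankings))
    write_ranking_tsv(rankings[[b]],
                      file.path(out_dir, paste0("ranking_", b, ".tsv")))

  hybrid <- stage("combine", build_hybrid(blocks, hspec, rankings))
  write_feature_tsv(hybrid, file.path(out_dir, "hybrid.tsv"),
                    labels = dataset$label)

  report <- stage("evaluate",
                  cross_validate(dataset, pipeline, k = config$cv$k,
                                 seed = config$seed,
                                 leakage_mode = config$cv$leakage_mode))
  utils::write.table(report$per_fold, file.path(out_dir, "cv_per_fold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$roc$points, file.path(out_dir, "roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    pooled = report$pooled[c("acc", "sn", "sp", "mcc")],
    auc = report$roc$auc,
    per_fold = report$per_fold,
    leakage_mode = report$leakage_mode,
    hybrid_dim = report$hybrid$dim), file.path(out_dir, "cv_report.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    package = "recspot",
    version = as.character(utils::packageVersion("recspot")),
    r_version = R.version.string,
    seed = config$seed,
    config = config), file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
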