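#' Confusion counts in hotspot-centric notation
#'
#' `h_pos` / `h_neg` are the total numbers of true hotspots / coldspots;
#' `pos_as_neg` counts hotspots predicted coldspot and `neg_as_pos`
#' coldspots predicted hotspot.
#'
#' @param truth,predicted equal-length label vectors (0/1 with 0 = hotspot,
#'   or `"hotspot"`/`"coldspot"`).
#' @return a `confusion_counts` list.
#' @export
confusion <- function(truth, predicted) {
  t01 <- .as_binary_labels(truth)
  p01 <- .as_binary_labels(predicted)
  if (length(t01) != length(p01))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  structure(list(h_pos = sum(t01 == 0L),
                 h_neg = sum(t01 == 1L),
                 pos_as_neg = sum(t01 == 0L & p01 == 1L),
                 neg_as_pos = sum(t01 == 1L & p01 == 0L)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity and MCC
#'
#' Hotspot-centric formulations: `ACC = 1 - (H-+ + H+-) / (H+ + H-)`,
#' `SN = 1 - H-+/H+`, `SP = 1 - H+-/H-`, and
#' `MCC = (1 - (H-+/H+ + H+-/H-)) /
#'   sqrt((1 + (H+- - H-+)/H+) * (1 + (H-+ - H+-)/H-))`,
#' algebraically identical to the standard TP/TN/FP/FN forms with hotspot as
#' the positive class. A zero factor in the MCC denominator (a degenerate
#' prediction) yields MCC = 0 by convention; an absent class makes SN or SP
#' `NA` with a warning, never a silent NaN.
#'
#' @param counts a [confusion()] result.
#' @return a `recspot_metrics` list: `acc`, `sn`, `sp`, `mcc`.
#' @examples
#' compute_metrics(confusion(c(0, 0, 0, 0, 1, 1), c(0, 0, 0, 1, 1, 0)))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  hp <- counts$h_pos; hn <- counts$h_neg
  fn <- counts$pos_as_neg; fp <- counts$neg_as_pos
  if (hp + hn == 0) stop("empty confusion table", call. = FALSE)
  acc <- 1 - (fn + fp) / (hp + hn)
  sn <- if (hp > 0) 1 - fn / hp else {
    warning("no hotspot records; SN undefined", call. = FALSE); NA_real_
  }
  sp <- if (hn > 0) 1 - fp / hn else {
    warning("no coldspot records; SP undefined", call. = FALSE); NA_real_
  }
  if (hp > 0 && hn > 0) {
    f1 <- 1 + (fp - fn) / hp
    f2 <- 1 + (fn - fp) / hn
    mcc <- if (f1 <= 0 || f2 <= 0) 0 else (1 - (fn / hp + fp / hn)) / sqrt(f1 * f2)
  } else mcc <- 0
  structure(list(acc = acc, sn = sn, sp = sp, mcc = mcc,
                 counts = counts),
            class = "recspot_metrics")
}

#' @export
print.recspot_metrics <- function(x, ...) {
  cat(sprintf("ACC %.4f  SN %s  SP %s  MCC %.4f\n", x$acc,
              ifelse(is.na(x$sn), "NA", sprintf("%.4f", x$sn)),
              ifelse(is.na(x$sp), "NA", sprintf("%.4f", x$sp)), x$mcc))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> H+ %d, H- %d, H-+ %d, H+- %d\n",
              x$h_pos, x$h_neg, x$pos_as_neg, x$neg_as_pos))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Scores are hotspot-class probabilities (larger = more hotspot-like);
#' every unique score is a threshold and tied scores move as one step, so
#' the curve runs from (0, 0) to (1, 1) with nondecreasing FPR. AUC is the
#' trapezoidal area, equal to the normalized Mann-Whitney U count (ties
#' counted half).
#'
#' @param scores finite numeric scores.
#' @param truth labels (0/1 with 0 = hotspot, or `"hotspot"`/`"coldspot"`);
#'   both classes must be present.
#' @return a `roc_curve`: list with `points` (data frame `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  t01 <- .as_binary_labels(truth)
  if (length(scores) != length(t01))
    stop("`scores` and `truth` must have equal length", call. = FALSE)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  npos <- sum(t01 == 0L); nneg <- sum(t01 == 1L)
  if (npos == 0 || nneg == 0)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- t01[ord] == 0L
  steps <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(pos)[steps] / npos)
  fpr <- c(0, cumsum(!pos)[steps] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Stratified fold assignment
#'
#' Shuffles each class under the seed and deals indices round-robin, so
#' every fold's class ratio is within one sample of the overall ratio.
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return integer fold ids in `1..k`, aligned with `y`.
#' @export
make_folds <- function(y, k, seed = 1) {
  y <- factor(y)
  if (any(table(y) < k))
    stop(sprintf("smallest class has fewer than k = %d samples; use smaller k", k),
         call. = FALSE)
  fold <- integer(length(y))
  .with_seed(seed, for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

#' Describe an end-to-end classification pipeline
#'
#' Bundles the feature, selection, hybrid and classifier settings consumed
#' by [cross_validate()]. Only blocks with a nonzero hybrid take-count are
#' extracted and ranked.
#'
#' @param a,lam_mix hybrid mixing weights (see [hybrid_spec()]); the
#'   default (1, 0) is the G3 configuration of record. `group` may be given
#'   instead (e.g. `"G4"`) to use one of the nine catalogued combinations.
#' @param group optional group name `"G1"`..`"G9"` overriding `a`/`lam_mix`.
#' @param selection_sizes selected-block sizes (see [hybrid_spec()]).
#' @param gdc_gaps,rcc_ks,bank_ks extractor parameters.
#' @param psetnc a [psetnc_params()].
#' @param rfe_cost,rfe_step SVM-RFE parameters (see [svm_rfe_rank()]).
#' @param classifier list: `kind` one of `"dnn"`, `"svm"`, `"knn"`, `"rf"`;
#'   for `"dnn"` any [dnn_config()] arguments except `input_width`; for
#'   baselines their `params`.
#' @return a `pipeline_spec` list.
#' @export
pipeline_spec <- function(a = 1, lam_mix = 0, group = NULL,
                          selection_sizes = c(G = 5, R = 12, P = 66, H = 425),
                          gdc_gaps = 0:7, rcc_ks = c(3, 4, 5), bank_ks = 1:5,
                          psetnc = psetnc_params(),
                          rfe_cost = 1, rfe_step = NULL,
                          classifier = list(kind = "dnn")) {
  if (!is.null(group)) {
    cat9 <- catalog_groups(selection_sizes)
    row <- cat9[cat9$group == group, ]
    if (nrow(row) != 1) stop("unknown group: ", group, call. = FALSE)
    a <- row$a; lam_mix <- row$lam
  }
  if (is.null(classifier$kind)) stop("classifier$kind required", call. = FALSE)
  structure(list(a = a, lam_mix = lam_mix,
                 selection_sizes = selection_sizes,
                 gdc_gaps = gdc_gaps, rcc_ks = rcc_ks, bank_ks = bank_ks,
                 psetnc = psetnc, rfe_cost = rfe_cost, rfe_step = rfe_step,
                 classifier = classifier),
            class = "pipeline_spec")
}

# Extract the raw matrices for every block the hybrid spec actually uses.
.extract_needed_blocks <- function(dataset, pipeline, takes) {
  blocks <- list()
  if (takes[["G"]] > 0)
    blocks$G <- extract_block(dataset, "gdc", list(gaps = pipeline$gdc_gaps))
  if (takes[["R"]] > 0)
    blocks$R <- extract_block(dataset, "rcc", list(ks = pipeline$rcc_ks))
  if (takes[["P"]] > 0)
    blocks$P <- extract_block(dataset, "psetnc", pipeline$psetnc)
  if (takes[["H"]] > 0)
    blocks$H <- extract_block(dataset, "bank", list(ks = pipeline$bank_ks))
  blocks
}

# Rank each block on the given training rows; NULL when no ranking is
# needed (take covers the whole raw block, prefix order irrelevant).
.rank_blocks <- function(blocks, y01, rows, takes, pipeline) {
  rankings <- list()
  for (b in names(blocks)) {
    if (takes[[b]] < ncol(blocks[[b]])) {
      rankings[[b]] <- svm_rfe_rank(blocks[[b]][rows, , drop = FALSE],
                                    factor(y01[rows]),
                                    step = pipeline$rfe_step,
                                    cost = pipeline$rfe_cost)
    }
  }
  rankings
}

.fit_predict_classifier <- function(pipeline, Xtr, ytr, Xte, fold_seed) {
  cl <- pipeline$classifier
  if (cl$kind == "dnn") {
    args <- cl[setdiff(names(cl), "kind")]
    args$input_width <- ncol(Xtr)
    config <- do.call(dnn_config, args)
    net <- train_dnn(Xtr, ytr, config)
    P <- forward(net, Xte)
    list(pred = as.integer(P[, 1] < P[, 2]), score = P[, 1])
  } else {
    params <- cl$params %||% cl[setdiff(names(cl), "kind")]
    yf <- factor(ytr, levels = c(0, 1))
    switch(cl$kind,
      svm = {
        m <- e1071::svm(Xtr, yf, kernel = "radial",
                        cost = params$cost %||% 1,
                        gamma = params$gamma %||% (1 / ncol(Xtr)),
                        probability = TRUE)
        pr <- stats::predict(m, Xte, probability = TRUE)
        prob <- attr(pr, "probabilities")[, "0"]
        list(pred = as.integer(as.character(pr)), score = prob)
      },
      knn = {
        pr <- .with_seed(fold_seed,
          class::knn(Xtr, Xte, yf, k = params$k %||% 5, prob = TRUE))
        win <- attr(pr, "prob")
        score <- ifelse(pr == "0", win, 1 - win)
        list(pred = as.integer(as.character(pr)), score = score)
      },
      rf = {
        m <- .with_seed(fold_seed, randomForest::randomForest(
          Xtr, yf, ntree = params$ntree %||% 500,
          mtry = params$mtry %||% max(1, floor(sqrt(ncol(Xtr))))))
        prob <- stats::predict(m, Xte, type = "prob")[, "0"]
        list(pred = as.integer(prob < 0.5), score = prob)
      },
      stop("unknown classifier kind: ", cl$kind, call. = FALSE))
  }
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Runs extraction, SVM-RFE selection, hybrid combination and the chosen
#' classifier under stratified, seeded folds. Under the default
#' `"fold-internal-selection"` the rankings and the feature
#' standardization are re-fit inside each training fold;
#' `"whole-dataset-selection"` ranks once on the full dataset (the
#' optimistic protocol sometimes used for benchmark replication). Pooled
#' metrics come from the union of held-out predictions, and the pooled
#' confusion equals the sum of per-fold confusions.
#'
#' @param dataset a fully labeled [recspot_dataset].
#' @param pipeline a [pipeline_spec()].
#' @param k number of folds (each class must have >= k records).
#' @param seed seed for fold assignment.
#' @param leakage_mode `"fold-internal-selection"` or
#'   `"whole-dataset-selection"`.
#' @return a `cv_report`: `pooled` metrics, `per_fold` metric table,
#'   `predictions` (id, fold, truth, pred, score), `roc`, `folds`, and the
#'   settings used.
#' @export
cross_validate <- function(dataset, pipeline, k = 10, seed = 1,
                           leakage_mode = c("fold-internal-selection",
                                            "whole-dataset-selection")) {
  stopifnot(inherits(dataset, "recspot_dataset"),
            inherits(pipeline, "pipeline_spec"))
  leakage_mode <- match.arg(leakage_mode)
  if (any(is.na(dataset$label)))
    stop("all records must be labeled for cross-validation", call. = FALSE)
  y01 <- ifelse(dataset$label == "hotspot", 0L, 1L)
  hspec <- hybrid_spec(pipeline$a, pipeline$lam_mix, pipeline$selection_sizes)
  takes <- hspec$takes
  blocks <- .extract_needed_blocks(dataset, pipeline, takes)
  fold_id <- make_folds(y01, k, seed)
  global_rankings <- if (leakage_mode == "whole-dataset-selection")
    .rank_blocks(blocks, y01, seq_along(y01), takes, pipeline) else NULL
  pred <- integer(length(y01))
  score <- numeric(length(y01))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    rankings <- if (is.null(global_rankings))
      .rank_blocks(blocks, y01, tr, takes, pipeline) else global_rankings
    Xall <- build_hybrid(blocks, hspec, rankings)
    Xtr <- Xall[tr, , drop = FALSE]
    Xte <- Xall[te, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdev <- apply(Xtr, 2, stats::sd); sdev[sdev == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdev, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdev, "/")
    out <- .fit_predict_classifier(pipeline, Xtr, y01[tr], Xte,
                                   fold_seed = seed * 1000L + f)
    pred[te] <- out$pred
    score[te] <- out$score
    per_fold[[f]] <- compute_metrics(confusion(y01[te], out$pred))
  }
  pooled <- compute_metrics(confusion(y01, pred))
  per_fold_df <- data.frame(fold = seq_len(k),
                            acc = vapply(per_fold, `[[`, numeric(1), "acc"),
                            sn = vapply(per_fold, `[[`, numeric(1), "sn"),
                            sp = vapply(per_fold, `[[`, numeric(1), "sp"),
                            mcc = vapply(per_fold, `[[`, numeric(1), "mcc"))
  structure(list(pooled = pooled, per_fold = per_fold_df,
                 predictions = data.frame(id = dataset$id, fold = fold_id,
                                          truth = y01, pred = pred,
                                          score = score,
                                          stringsAsFactors = FALSE),
                 roc = roc_auc(score, y01),
                 folds = fold_id, k = k, seed = seed,
                 leakage_mode = leakage_mode, hybrid = hspec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold (%s), hybrid dim %d\n",
              x$k, x$leakage_mode, x$hybrid$dim))
  cat("pooled: "); print(x$pooled)
  cat(sprintf("AUC %.4f\n", x$roc$auc))
  invisible(x)
}

#' Grid search over learning rates and activations
#'
#' Cross-validates the pipeline's network at every (learning rate,
#' activation) cell and reports pooled accuracy per cell. The best cell
#' attains the maximum accuracy; ties go to the lowest learning rate, then
#' to the earlier activation in `activations`.
#'
#' @param dataset a labeled [recspot_dataset].
#' @param rates numeric learning rates.
#' @param activations character activations (subset of tanh/relu/sigmoid).
#' @param pipeline a [pipeline_spec()] with a `"dnn"` classifier.
#' @param k,seed,leakage_mode passed to [cross_validate()].
#' @return a `grid_search_result`: `grid` data frame (`learning_rate`,
#'   `activation`, `acc`) and `best` row.
#' @export
grid_search <- function(dataset, rates, activations, pipeline,
                        k = 10, seed = 1,
                        leakage_mode = "fold-internal-selection") {
  if (!length(rates) || !length(activations))
    stop("empty grid", call. = FALSE)
  if (!identical(pipeline$classifier$kind, "dnn"))
    stop("grid search tunes the dnn classifier", call. = FALSE)
  grid <- expand.grid(learning_rate = rates, activation = activations,
                      stringsAsFactors = FALSE)
  grid$acc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- pipeline
    p$classifier$learning_rate <- grid$learning_rate[i]
    p$classifier$activation <- grid$activation[i]
    rep <- cross_validate(dataset, p, k = k, seed = seed,
                          leakage_mode = leakage_mode)
    grid$acc[i] <- rep$pooled$acc
  }
  act_rank <- match(grid$activation, activations)
  best <- grid[order(-grid$acc, grid$learning_rate, act_rank)[1], ]
  structure(list(grid = grid, best = best), class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d cells; best: lr %g, %s (ACC %.4f)\n",
              nrow(x$grid), x$best$learning_rate, x$best$activation,
              x$best$acc))
  invisible(x)
}
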