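#' Rank features by SVM recursive feature elimination
#'
#' Repeatedly fits a linear soft-margin SVM, scores each remaining feature by
#' its squared weight, and removes the lowest-scoring `step` features until
#' none remain; the elimination order read backwards is the ranking. Features
#' are standardized (zero mean, unit variance on the supplied data) before
#' fitting; ties in squared weight are broken by original column order, so
#' the procedure is deterministic for a given input.
#'
#' @param x numeric matrix, samples x features, with colnames.
#' @param y two-class labels (factor or coercible); both classes must be
#'   present with >= 2 samples each.
#' @param step features removed per iteration: a count (`>= 1`) or a fraction
#'   in `(0, 1)` of the remaining features. Default: 1 for blocks of at most
#'   200 features, 10% otherwise.
#' @param cost regularization strength of the linear SVM.
#' @param standardize standardize columns before ranking.
#' @return a `feature_ranking`: list with `ordered_names` (best first),
#'   `elimination_trace` (features removed at each iteration) and
#'   `params_used`.
#' @examples
#' x <- cbind(sig = rep(c(0, 3), each = 10) + rnorm(20, sd = .1),
#'            noise = rnorm(20))
#' r <- svm_rfe_rank(x, rep(c("hotspot", "coldspot"), each = 10))
#' r$ordered_names[1]  # "sig"
#' @export
svm_rfe_rank <- function(x, y, step = NULL, cost = 1, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) != 2 || any(table(y) < 2))
    stop("need two classes with >= 2 samples each", call. = FALSE)
  if (length(y) != nrow(x)) stop("label/row length mismatch", call. = FALSE)
  if (is.null(step)) step <- if (ncol(x) <= 200) 1 else 0.1
  if (standardize) {
    mu <- colMeans(x)
    sdev <- apply(x, 2, stats::sd)
    sdev[sdev == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  }
  remaining <- seq_len(ncol(x))
  eliminated <- integer(0)
  trace <- list()
  while (length(remaining) > 0) {
    if (length(remaining) == 1L) {
      drop_idx <- remaining
    } else {
      fit <- e1071::svm(x[, remaining, drop = FALSE], y, kernel = "linear",
                        cost = cost, scale = FALSE)
      w <- drop(crossprod(fit$coefs, fit$SV))
      score <- w^2
      n_rm <- if (step < 1) max(1L, floor(step * length(remaining)))
              else min(as.integer(step), length(remaining))
      # worst first; ties -> larger original index removed first, so the
      # reversed elimination order ranks tied columns in original order
      ord <- order(score, -remaining)
      drop_idx <- remaining[ord[seq_len(n_rm)]]
    }
    eliminated <- c(eliminated, drop_idx)
    trace[[length(trace) + 1L]] <- colnames(x)[drop_idx]
    remaining <- setdiff(remaining, drop_idx)
  }
  structure(list(ordered_names = colnames(x)[rev(eliminated)],
                 elimination_trace = trace,
                 params_used = list(cost = cost, step = step,
                                    standardize = standardize)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %d features; top: %s\n",
              length(x$ordered_names),
              paste(utils::head(x$ordered_names, 5), collapse = ", ")))
  invisible(x)
}

#' Take the top-n features of a ranking
#'
#' @param ranking a [svm_rfe_rank()] result (or a plain character vector of
#'   names, best first).
#' @param n how many features, `0 <= n <= length(ranking)`.
#' @return character vector of the first `n` names, order preserved.
#' @export
select_top <- function(ranking, n) {
  nm <- if (inherits(ranking, "feature_ranking")) ranking$ordered_names
        else as.character(ranking)
  n <- as.integer(n)
  if (n < 0 || n > length(nm))
    stop(sprintf("`n` must be in [0, %d]", length(nm)), call. = FALSE)
  nm[seq_len(n)]
}

#' Serialize / read a feature ranking as TSV
#' @param ranking a `feature_ranking`.
#' @param path file path.
#' @return `path` invisibly; `read_ranking_tsv` returns a character vector.
#' @export
write_ranking_tsv <- function(ranking, path) {
  nm <- if (inherits(ranking, "feature_ranking")) ranking$ordered_names
        else as.character(ranking)
  utils::write.table(data.frame(rank = seq_along(nm), feature_name = nm),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$feature_name[order(df$rank)]
}
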