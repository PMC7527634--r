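#' Weighted take-count for one feature block
#'
#' How many top-ranked features a block contributes at a given mixing
#' weight: `round_half_up(weight * block_size)` — 0 at weight 0, the full
#' block at weight 1, with exact halves rounded up (e.g. `block_take(5, 0.5)
#' = 3`, `block_take(425, 0.5) = 213`).
#'
#' @param block_size nonnegative feature count of the block.
#' @param weight mixing weight in `[0, 1]`.
#' @return integer take-count.
#' @export
block_take <- function(block_size, weight) {
  if (any(weight < 0 | weight > 1))
    stop("`weight` must be in [0, 1]", call. = FALSE)
  if (any(block_size < 0)) stop("`block_size` must be >= 0", call. = FALSE)
  as.integer(floor(weight * block_size + 0.5))
}

#' Specify a hybrid feature combination
#'
#' The hybrid vector `F = aG + lam*(R + P) + (1 - lam)*H` concatenates
#' ranked-prefix subsets of the four selected blocks: the top
#' `block_take(|G|, a)` of the gapped dinucleotide block, the top
#' `block_take(|R|, lam)` and `block_take(|P|, lam)` of the canonical k-mer
#' and pseudo trinucleotide blocks, and the top `block_take(|H|, 1 - lam)`
#' of the composition bank block.
#'
#' @param a contribution weight of the G block, in `[0, 1]`.
#' @param lam_mix mixing weight between (R, P) and H, in `[0, 1]` (distinct
#'   from the pseudo-composition tier count `lam`).
#' @param block_sizes named sizes of the selected blocks; defaults
#'   `c(G = 5, R = 12, P = 66, H = 425)`.
#' @return a `hybrid_spec` list with the per-block take-counts.
#' @examples
#' hybrid_spec(1, 0)$takes  # G3: 5 + 0 + 0 + 425 = 430 features
#' @export
hybrid_spec <- function(a, lam_mix,
                        block_sizes = c(G = 5, R = 12, P = 66, H = 425)) {
  block_sizes <- unlist(block_sizes)  # accept list form (e.g. from YAML)
  if (is.null(names(block_sizes)) && length(block_sizes) == 4)
    names(block_sizes) <- c("G", "R", "P", "H")
  if (!setequal(names(block_sizes), c("G", "R", "P", "H")))
    stop("`block_sizes` must be named G, R, P, H", call. = FALSE)
  block_sizes <- block_sizes[c("G", "R", "P", "H")]
  takes <- c(G = block_take(block_sizes[["G"]], a),
             R = block_take(block_sizes[["R"]], lam_mix),
             P = block_take(block_sizes[["P"]], lam_mix),
             H = block_take(block_sizes[["H"]], 1 - lam_mix))
  structure(list(a = a, lam_mix = lam_mix, block_sizes = block_sizes,
                 takes = takes, dim = sum(takes)),
            class = "hybrid_spec")
}

#' Build a hybrid feature matrix
#'
#' Concatenates ranked prefixes of the per-block matrices according to a
#' [hybrid_spec()]. Each block matrix must cover identical samples in
#' identical order; a block's columns are reordered by its ranking (best
#' first) before the prefix is taken. Blocks with a take-count of 0 may be
#' omitted from `blocks`.
#'
#' @param blocks named list (`G`, `R`, `P`, `H`) of selected block matrices
#'   (samples x block_size, rownames = sample ids).
#' @param spec a [hybrid_spec()].
#' @param rankings optional named list of rankings ([svm_rfe_rank()] results
#'   or character vectors, best first) for the blocks; a block without a
#'   ranking uses its current column order.
#' @return samples x `spec$dim` matrix with `block_tag = "hybrid"`.
#' @export
build_hybrid <- function(blocks, spec, rankings = list()) {
  stopifnot(inherits(spec, "hybrid_spec"))
  used <- names(spec$takes)[spec$takes > 0]
  missing_blocks <- setdiff(used, names(blocks))
  if (length(missing_blocks))
    stop("missing block matrices: ", paste(missing_blocks, collapse = ", "),
         call. = FALSE)
  ref_ids <- rownames(blocks[[used[1]]])
  parts <- lapply(used, function(b) {
    m <- as.matrix(blocks[[b]])
    if (spec$block_sizes[[b]] > ncol(m))
      stop(sprintf("block %s has %d features but block_sizes says %d",
                   b, ncol(m), spec$block_sizes[[b]]), call. = FALSE)
    if (!identical(rownames(m), ref_ids))
      stop("sample mismatch across blocks (block ", b, ")", call. = FALSE)
    if (!is.null(rankings[[b]])) {
      nm <- if (inherits(rankings[[b]], "feature_ranking"))
        rankings[[b]]$ordered_names else as.character(rankings[[b]])
      nm <- nm[nm %in% colnames(m)]
      if (length(nm) < spec$takes[[b]])
        stop("ranking for block ", b, " does not cover its take-count",
             call. = FALSE)
      m <- m[, nm, drop = FALSE]
    }
    m[, seq_len(spec$takes[[b]]), drop = FALSE]
  })
  out <- do.call(cbind, parts)
  rownames(out) <- ref_ids
  attr(out, "block_tag") <- "hybrid"
  attr(out, "hybrid_spec") <- spec
  out
}

#' The nine canonical hybrid feature groups
#'
#' Enumerates the nine (a, lam) combinations G1..G9 —
#' (0,0), (0,1), (1,0), (1,1), (0.5,0), (0,0.5), (0.5,0.5), (0.5,1),
#' (1,0.5) — with the hybrid dimension each produces. Under the default
#' block sizes these are 425, 78, 430, 83, 428, 252, 255, 81, 257; G3
#' (a = 1, lam = 0; 430 features) is the configuration of record.
#'
#' @param block_sizes as in [hybrid_spec()].
#' @return data frame with columns `group`, `a`, `lam`, `dim`.
#' @examples
#' catalog_groups()
#' @export
catalog_groups <- function(block_sizes = c(G = 5, R = 12, P = 66, H = 425)) {
  combos <- data.frame(
    group = paste0("G", 1:9),
    a   = c(0, 0, 1, 1, 0.5, 0, 0.5, 0.5, 1),
    lam = c(0, 1, 0, 1, 0, 0.5, 0.5, 1, 0.5))
  combos$dim <- vapply(seq_len(nrow(combos)), function(i)
    hybrid_spec(combos$a[i], combos$lam[i], block_sizes)$dim, integer(1))
  combos
}
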