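NUCS <- c("A", "C", "G", "T")

#' All k-mers over A/C/G/T in lexicographic order
#' @param k k-mer size.
#' @return character vector of length `4^k`.
#' @keywords internal
kmer_registry <- function(k) {
  out <- ""
  for (i in seq_len(k)) out <- as.vector(t(outer(out, NUCS, paste0)))
  out
}

.validate_seq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("`seq` must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq))
    stop("sequence contains residues outside {A,C,G,T}", call. = FALSE)
  seq
}

#' Gapped dinucleotide composition
#'
#' For each gap size `kappa` and each of the 16 ordered nucleotide pairs,
#' the fraction of positions `(i, i + kappa + 1)` carrying that pair:
#' `g = observed / windows` with `windows = L - kappa - 1`. The 16 values of
#' each gap with at least one window sum to 1. Gaps too large for the
#' sequence contribute 16 zeros with a warning.
#'
#' @param seq a DNA string over A/C/G/T.
#' @param gaps ordered integer gap sizes (interposed bases); default `0:7`
#'   gives the conventional 128-dimensional vector.
#' @return named numeric vector, names `GDC|<pair>|g<gap>`.
#' @examples
#' gdc_features("ACGTACGT", gaps = 0)["GDC|AC|g0"]  # 2/7
#' @export
gdc_features <- function(seq, gaps = 0:7) {
  seq <- .validate_seq(seq)
  gaps <- as.integer(gaps)
  if (any(gaps < 0)) stop("gaps must be >= 0", call. = FALSE)
  L <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  pairs16 <- kmer_registry(2)
  out <- numeric(0)
  for (g in gaps) {
    w <- L - g - 1L
    if (w < 1L) {
      warning(sprintf("sequence too short for gap %d (L = %d); 16 zeros emitted",
                      g, L), call. = FALSE)
      vals <- numeric(16)
    } else {
      pr <- paste0(v[seq_len(w)], v[seq.int(g + 2L, L)])
      vals <- tabulate(match(pr, pairs16), nbins = 16L) / w
    }
    out <- c(out, setNames(vals, paste0("GDC|", pairs16, "|g", g)))
  }
  out
}

#' Canonical form of a k-mer
#'
#' The lexicographically smaller of a k-mer and its reverse complement under
#' A < C < G < T; idempotent, and identical for a k-mer and its reverse
#' complement, so counts pooled by canonical form are strand-invariant.
#'
#' @param kmer character vector of k-mers over A/C/G/T.
#' @return character vector of canonical forms.
#' @examples
#' canonical_kmer("CGT")  # "ACG"
#' @export
canonical_kmer <- function(kmer) {
  rc <- reverse_complement(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

#' Canonical k-mer classes in lexicographic order
#' @param k k-mer size.
#' @return character vector of distinct canonical forms (e.g. 32 for k = 3,
#'   136 for k = 4, 512 for k = 5).
#' @keywords internal
canonical_classes <- function(k) {
  sort(unique(canonical_kmer(kmer_registry(k))), method = "radix")
}

#' Reverse-complement (canonical) k-mer composition
#'
#' Counts k-mer windows pooled by canonical class (strand-merged) for each
#' `k` in `ks`, normalized by sequence length `L` (`normalization =
#' "per-L"`, the default) or by window count `L - k + 1` (`"per-window"`).
#' The default `ks = c(3, 4, 5)` yields a fixed 680-dimensional vector
#' (32 + 136 + 512 canonical classes).
#'
#' @param seq a DNA string over A/C/G/T.
#' @param ks ordered k-mer sizes.
#' @param normalization `"per-L"` or `"per-window"`.
#' @return named numeric vector, names `RCC|<k>|<class>`.
#' @examples
#' rcc_features("ACG", ks = 3)["RCC|3|ACG"]  # 1/3
#' @export
rcc_features <- function(seq, ks = c(3, 4, 5),
                         normalization = c("per-L", "per-window")) {
  seq <- .validate_seq(seq)
  normalization <- match.arg(normalization)
  L <- nchar(seq)
  out <- numeric(0)
  for (k in as.integer(ks)) {
    cls <- canonical_classes(k)
    if (L < k) {
      warning(sprintf("sequence too short for k = %d (L = %d); zeros emitted",
                      k, L), call. = FALSE)
      vals <- numeric(length(cls))
    } else {
      cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                  width = k)
      pooled <- rowsum(as.numeric(cnt), canonical_kmer(names(cnt)))
      vals <- setNames(numeric(length(cls)), cls)
      vals[rownames(pooled)] <- pooled[, 1]
      denom <- if (normalization == "per-L") L else L - k + 1L
      vals <- vals / denom
    }
    out <- c(out, setNames(vals, paste0("RCC|", k, "|", cls)))
  }
  out
}

#' Trinucleotide composition
#'
#' The 64 normalized trinucleotide window frequencies: counts divided by the
#' number of windows `L - 2`; values sum to 1.
#'
#' @param seq a DNA string over A/C/G/T, length >= 3.
#' @return named numeric vector of length 64, names `TNC|<3-mer>`.
#' @export
tnc_frequencies <- function(seq) {
  seq <- .validate_seq(seq)
  L <- nchar(seq)
  if (L < 3) stop("sequence shorter than 3 nt", call. = FALSE)
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                              width = 3)
  setNames(as.numeric(cnt) / (L - 2L), paste0("TNC|", names(cnt)))
}

#' Default trinucleotide property table
#'
#' Three simple composition descriptors per trinucleotide — G+C fraction,
#' purine (A/G) fraction and keto (G/T) fraction — each standardized to mean
#' 0, variance 1 over the 64 trinucleotides. These are deliberately generic
#' placeholders for physicochemical scales: supply your own table (any
#' numeric 64 x mu matrix with trinucleotide rownames) to encode real
#' dinucleotide/trinucleotide properties.
#'
#' @return a 64 x 3 numeric matrix, rownames the trinucleotides, columns
#'   standardized.
#' @export
default_property_table <- function() {
  kmers <- kmer_registry(3)
  m <- do.call(rbind, strsplit(kmers, ""))
  raw <- cbind(gc = rowMeans(m == "G" | m == "C"),
               purine = rowMeans(m == "A" | m == "G"),
               keto = rowMeans(m == "G" | m == "T"))
  rownames(raw) <- kmers
  scale(raw)[, , drop = FALSE]
}

#' Parameters for pseudo trinucleotide composition
#'
#' @param lam number of sequence-order correlation tiers (lambda >= 0);
#'   the feature vector has `64 + lam` entries (default 2 gives 66).
#' @param w weight factor in `(0, 1]` balancing composition against the
#'   correlation tiers.
#' @param property_table numeric matrix of per-trinucleotide property values
#'   (64 rows named by trinucleotide); columns are standardized to mean 0,
#'   variance 1 if not already.
#' @return a `psetnc_params` list.
#' @export
psetnc_params <- function(lam = 2, w = 0.1,
                          property_table = default_property_table()) {
  lam <- as.integer(lam)
  if (lam < 0) stop("`lam` must be >= 0", call. = FALSE)
  if (w <= 0 || w > 1) stop("`w` must be in (0, 1]", call. = FALSE)
  property_table <- as.matrix(property_table)
  if (nrow(property_table) != 64 ||
      !setequal(rownames(property_table), kmer_registry(3)))
    stop("`property_table` must have the 64 trinucleotides as rownames",
         call. = FALSE)
  property_table <- property_table[kmer_registry(3), , drop = FALSE]
  # standardize columns with spread; constant columns only get centered
  for (u in seq_len(ncol(property_table))) {
    col <- property_table[, u] - mean(property_table[, u])
    s <- stats::sd(col)
    property_table[, u] <- if (s > 0) col / s else col
  }
  structure(list(lam = lam, w = w,
                 property_table = property_table[, , drop = FALSE]),
            class = "psetnc_params")
}

#' Tier-j sequence-order correlation factor
#'
#' The mean, over the `L* - j` trinucleotide pairs at offset `j`
#' (`L* = L - 2` trinucleotide positions), of the squared property distance
#' `(1/mu) * sum_u (P_u(T_i) - P_u(T_(i+j)))^2`; nonnegative, and 0 for
#' homopolymers or an all-zero property table.
#'
#' @param seq a DNA string over A/C/G/T.
#' @param j tier index, `1 <= j < L*`.
#' @param params a [psetnc_params()].
#' @return scalar `theta_j >= 0`.
#' @export
theta_correlation <- function(seq, j, params = psetnc_params()) {
  seq <- .validate_seq(seq)
  L <- nchar(seq)
  Lstar <- L - 2L
  j <- as.integer(j)
  if (j < 1L || j >= Lstar)
    stop(sprintf("tier index j = %d must satisfy 1 <= j < L* = %d", j, Lstar),
         call. = FALSE)
  tri <- substring(seq, seq_len(Lstar), seq_len(Lstar) + 2L)
  P <- params$property_table
  d <- P[tri[seq_len(Lstar - j)], , drop = FALSE] -
       P[tri[seq.int(j + 1L, Lstar)], , drop = FALSE]
  mean(rowMeans(d^2))
}

#' Pseudo trinucleotide composition
#'
#' A `64 + lam` feature vector: the 64 trinucleotide frequencies and `lam`
#' weighted correlation tiers, jointly normalized so all entries are
#' nonnegative and sum to 1 — entry `v <= 64` is
#' `f_v / (sum f + w * sum theta)` and tier entry `64 + j` is
#' `w * theta_j / (sum f + w * sum theta)`. With `lam = 0` this reduces
#' exactly to [tnc_frequencies()].
#'
#' @param seq a DNA string over A/C/G/T with `L >= 3 + lam`.
#' @param params a [psetnc_params()].
#' @return named numeric vector of length `64 + lam`
#'   (`PseTNC|<3-mer>` then `PseTNC|theta<j>`).
#' @export
psetnc_features <- function(seq, params = psetnc_params()) {
  seq <- .validate_seq(seq)
  L <- nchar(seq)
  if (L < 3L + params$lam)
    stop(sprintf("sequence too short: need L >= %d for lam = %d",
                 3L + params$lam, params$lam), call. = FALSE)
  f <- tnc_frequencies(seq)
  theta <- if (params$lam > 0)
    vapply(seq_len(params$lam), theta_correlation, numeric(1),
           seq = seq, params = params)
  else numeric(0)
  denom <- sum(f) + params$w * sum(theta)
  d <- c(f / denom, params$w * theta / denom)
  names(d) <- c(paste0("PseTNC|", kmer_registry(3)),
                if (params$lam > 0) paste0("PseTNC|theta", seq_len(params$lam)))
  d
}

#' Plain k-mer composition bank
#'
#' The union of k-mer compositions for each `k` in `ks` (default `1:5`,
#' 4 + 16 + 64 + 256 + 1024 = 1364 raw features), each k's block normalized
#' by its window count `L - k + 1` so per-k sums are 1. Serves as the raw
#' composition bank from which a selected block (e.g. 425 features) is cut
#' by SVM-RFE.
#'
#' @param seq a DNA string over A/C/G/T.
#' @param ks k-mer sizes.
#' @return named numeric vector, names `KMER|<k>|<kmer>`.
#' @export
kmer_bank_features <- function(seq, ks = 1:5) {
  seq <- .validate_seq(seq)
  L <- nchar(seq)
  out <- numeric(0)
  for (k in as.integer(ks)) {
    reg <- kmer_registry(k)
    if (L < k) {
      warning(sprintf("sequence too short for k = %d (L = %d); zeros emitted",
                      k, L), call. = FALSE)
      vals <- numeric(length(reg))
    } else {
      cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                  width = k)
      vals <- as.numeric(cnt[reg]) / (L - k + 1L)
    }
    out <- c(out, setNames(vals, paste0("KMER|", k, "|", reg)))
  }
  out
}

#' Extract a feature block for a whole dataset
#'
#' Applies one extractor to every record; rows align with dataset order and
#' the column registry is identical for all rows.
#'
#' @param dataset a [recspot_dataset].
#' @param method one of `"gdc"`, `"rcc"`, `"psetnc"`, `"bank"`.
#' @param params extractor parameters: a list of arguments for `gdc`
#'   (`gaps`), `rcc` (`ks`, `normalization`), `bank` (`ks`), or a
#'   [psetnc_params()] for `psetnc`.
#' @return numeric matrix (samples x features) with rownames = record ids
#'   and attribute `block_tag` in `G`, `R`, `P`, `H`.
#' @examples
#' d <- generate_synthetic_dataset(simulation_spec(5, 5, 60, 90, seed = 1))
#' dim(extract_block(d, "gdc"))  # 10 x 128
#' @export
extract_block <- function(dataset, method = c("gdc", "rcc", "psetnc", "bank"),
                          params = NULL) {
  stopifnot(inherits(dataset, "recspot_dataset"))
  method <- match.arg(method)
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  fun <- switch(method,
    gdc = function(s) do.call(gdc_features, c(list(s), params)),
    rcc = function(s) do.call(rcc_features, c(list(s), params)),
    psetnc = function(s)
      psetnc_features(s, params = if (is.null(params)) psetnc_params() else params),
    bank = function(s) do.call(kmer_bank_features, c(list(s), params)))
  first <- fun(dataset$seq[[1]])
  m <- matrix(0, nrow(dataset), length(first),
              dimnames = list(dataset$id, names(first)))
  m[1, ] <- first
  for (i in seq_len(nrow(dataset))[-1]) m[i, ] <- fun(dataset$seq[[i]])
  attr(m, "block_tag") <- switch(method, gdc = "G", rcc = "R",
                                 psetnc = "P", bank = "H")
  m
}

#' Write / read a feature matrix as TSV
#'
#' Columns: `id`, optional `label`, then the named features; floats carry 12
#' significant digits so a round trip is value-stable.
#'
#' @param mat numeric matrix with rownames (sample ids) and colnames.
#' @param path file path.
#' @param labels optional label vector aligned with rows.
#' @return `path` invisibly (`write_feature_tsv`); a list with `matrix` and
#'   `labels` (`read_feature_tsv`).
#' @export
write_feature_tsv <- function(mat, path, labels = NULL) {
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- as.character(labels)
  num <- as.data.frame(signif(mat, 12))
  names(num) <- colnames(mat)
  utils::write.table(cbind(df, num), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  feat <- df[, setdiff(names(df), c("id", "label")), drop = FALSE]
  m <- as.matrix(feat)
  rownames(m) <- df$id
  list(matrix = m, labels = labels)
}
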