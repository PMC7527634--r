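#' @title Labeled DNA sequence datasets
#' @name recspot_dataset
#' @description A `recspot_dataset` is a data frame with columns `id`
#'   (unique identifiers), `seq` (uppercase DNA over A/C/G/T, length >= 3)
#'   and `label` (factor with levels `hotspot`, `coldspot`; `NA` for
#'   unlabeled records). Hotspots are the positive class.
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of DNA sequences (same length as `id`).
#' @param label optional labels: `"hotspot"`, `"coldspot"` or `NA`.
#' @return A `recspot_dataset` data frame.
#' @examples
#' d <- recspot_dataset(c("h1", "c1"), c("ACGTACGT", "AAATTTGG"),
#'                      c("hotspot", "coldspot"))
#' n_pos(d); n_neg(d)
#' @export
recspot_dataset <- function(id, seq, label = NA) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate record ids: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  label <- factor(rep_len(as.character(label), length(id)),
                  levels = c("hotspot", "coldspot"))
  bad <- grepl("[^ACGT]", seq)
  if (any(bad))
    stop("record(s) with residues outside {A,C,G,T}: ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  short <- nchar(seq) < 3L
  if (any(short) && length(seq))
    stop("record(s) shorter than 3 nt: ", paste(id[short], collapse = ", "),
         call. = FALSE)
  structure(data.frame(id = id, seq = seq, label = label,
                       stringsAsFactors = FALSE),
            class = c("recspot_dataset", "data.frame"))
}

#' @rdname recspot_dataset
#' @param x a `recspot_dataset`.
#' @export
n_pos <- function(x) sum(x$label == "hotspot", na.rm = TRUE)

#' @rdname recspot_dataset
#' @export
n_neg <- function(x) sum(x$label == "coldspot", na.rm = TRUE)

#' @export
print.recspot_dataset <- function(x, ...) {
  cat(sprintf("<recspot_dataset> %d records (%d hotspot, %d coldspot, %d unlabeled)\n",
              nrow(x), n_pos(x), n_neg(x), sum(is.na(x$label))))
  if (nrow(x)) {
    rng <- range(nchar(x$seq))
    cat(sprintf("  lengths: %d-%d nt\n", rng[1], rng[2]))
    print(utils::head(data.frame(id = x$id, length = nchar(x$seq),
                                 label = x$label), 6))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTA file into a labeled dataset
#'
#' Labels travel either as a `|hotspot` / `|coldspot` suffix on the FASTA
#' header (`label_source = "header-token"`), in a two-column sidecar TSV of
#' `id<TAB>label` with no header row (`"sidecar-table"`), or not at all
#' (`"none"`). Sequences are uppercased on read; residues outside A/C/G/T
#' are an error unless `strip_ambiguous = TRUE`, which drops the offending
#' records with a message.
#'
#' @param path path to a FASTA file.
#' @param label_source one of `"header-token"`, `"sidecar-table"`, `"none"`.
#' @param sidecar path to the label TSV when `label_source = "sidecar-table"`.
#' @param strip_ambiguous drop records containing ambiguity codes instead of
#'   raising an error.
#' @return A [recspot_dataset].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">h1|hotspot", "ACGTACGT", ">c1|coldspot", "AAATTTGG"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path,
                       label_source = c("header-token", "sidecar-table", "none"),
                       sidecar = NULL, strip_ambiguous = FALSE) {
  label_source <- match.arg(label_source)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    return(recspot_dataset(character(0), character(0), character(0)))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(trimws(lines[nonempty[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d: expected '>' header before sequence data",
                 nonempty[1]), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA (", conditionMessage(e), ")",
                         call. = FALSE))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(headers, "|", fixed = TRUE), `[`, "", 1L)
  ids <- vapply(strsplit(trimws(ids), "[ \t]"), `[`, "", 1L)
  labels <- rep(NA_character_, length(ids))
  if (label_source == "header-token") {
    tok <- sub("^[^|]*\\|?", "", headers)
    labels[tok %in% c("hotspot", "coldspot")] <-
      tok[tok %in% c("hotspot", "coldspot")]
  } else if (label_source == "sidecar-table") {
    if (is.null(sidecar)) stop("`sidecar` path required", call. = FALSE)
    tab <- utils::read.table(sidecar, sep = "\t", header = FALSE,
                             col.names = c("id", "label"),
                             stringsAsFactors = FALSE)
    labels <- tab$label[match(ids, tab$id)]
  }
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (strip_ambiguous) {
      message("stripped ", sum(bad), " record(s) with ambiguous residues: ",
              paste(ids[bad], collapse = ", "))
      keep <- !bad
      ids <- ids[keep]; seqs <- seqs[keep]; labels <- labels[keep]
    } else {
      stop("record(s) with residues outside {A,C,G,T}: ",
           paste(ids[bad], collapse = ", "),
           " (use strip_ambiguous = TRUE to drop them)", call. = FALSE)
    }
  }
  recspot_dataset(ids, seqs, labels)
}

#' Write a dataset to FASTA
#'
#' Headers are `id|label` for labeled records and bare `id` otherwise;
#' sequence lines are wrapped at 60 columns, uppercase. Reading the file back
#' with [read_fasta()] reproduces ids, residues and labels.
#'
#' @param dataset a [recspot_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "recspot_dataset"))
  if (nrow(dataset) == 0) {
    file.create(path)
    return(invisible(path))
  }
  hdr <- ifelse(is.na(dataset$label), dataset$id,
                paste0(dataset$id, "|", dataset$label))
  set <- Biostrings::DNAStringSet(dataset$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Exchanges A with T and C with G, then reverses. Applying twice returns the
#' input.
#'
#' @param residues character vector of DNA strings over A/C/G/T.
#' @return character vector of the same length.
#' @examples
#' reverse_complement(c("ACGT", "AAAC"))  # "ACGT" "GTTT"
#' @export
reverse_complement <- function(residues) {
  if (any(grepl("[^ACGT]", residues)))
    stop("input contains residues outside {A,C,G,T}", call. = FALSE)
  if (!length(residues)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(residues)))
}

#' Specify a synthetic two-class sequence simulation
#'
#' Sequences are concatenations of i.i.d. trinucleotide tokens. Coldspots draw
#' tokens from a background distribution (independent bases, uniform unless
#' shifted). Hotspots place exactly `effect` excess probability mass on the
#' planted trinucleotide set, spread uniformly across it, with the non-planted
#' background renormalized, so the expected planted-token frequency difference
#' between classes equals `effect`. `gc_shift` moves the hotspot background
#' G+C mass from 0.5 to 0.5 + `gc_shift`. With `effect = 0` and
#' `gc_shift = 0` the two classes are exchangeable in distribution.
#'
#' Default class sizes (478/572) mirror a published yeast hotspot/coldspot
#' benchmark; default lengths span 200-3000 nt.
#'
#' @param n_pos,n_neg number of hotspot / coldspot records.
#' @param length_low,length_high sequence length range (uniform integer draw).
#' @param effect excess planted-token probability mass in `[0, 1]`.
#' @param planted_kmers character vector of planted 3-mers.
#' @param gc_shift hotspot G+C shift in `[-0.2, 0.2]`.
#' @param seed integer RNG seed; identical specs give byte-identical datasets.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_pos = 478, n_neg = 572,
                            length_low = 200, length_high = 3000,
                            effect = 0.15, planted_kmers = c("AAA", "TTT"),
                            gc_shift = 0, seed = 1) {
  if (effect < 0 || effect > 1)
    stop("`effect` must be in [0, 1]", call. = FALSE)
  if (gc_shift < -0.2 || gc_shift > 0.2)
    stop("`gc_shift` must be in [-0.2, 0.2]", call. = FALSE)
  if (n_pos < 0 || n_neg < 0) stop("class sizes must be >= 0", call. = FALSE)
  if (length_low > length_high)
    stop("`length_low` must be <= `length_high`", call. = FALSE)
  if (length_low < 3) stop("`length_low` must be >= 3", call. = FALSE)
  if (any(nchar(planted_kmers) != 3L) || any(grepl("[^ACGT]", planted_kmers)))
    stop("`planted_kmers` must be 3-mers over {A,C,G,T}", call. = FALSE)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_low = as.integer(length_low),
                 length_high = as.integer(length_high),
                 effect = effect, planted_kmers = unique(planted_kmers),
                 gc_shift = gc_shift, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Per-class trinucleotide token distributions of a simulation
#'
#' Returns the exact 64-length probability vectors the generator samples
#' tokens from, for Monte-Carlo checks against the generator's own
#' probabilities.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `hotspot` and `coldspot`, each a named
#'   probability vector over the 64 trinucleotides.
#' @export
token_distributions <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  kmers <- kmer_registry(3)
  base_cold <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  gc <- 0.5 + spec$gc_shift
  base_hot <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  prod_probs <- function(base) {
    m <- do.call(rbind, strsplit(kmers, ""))
    setNames(base[m[, 1]] * base[m[, 2]] * base[m[, 3]], kmers)
  }
  q_cold <- prod_probs(base_cold)
  q_hot <- prod_probs(base_hot)
  planted <- kmers %in% spec$planted_kmers
  q_planted <- sum(q_hot[planted])
  if (spec$effect > 1 - q_planted)
    stop("`effect` exceeds available non-planted background mass", call. = FALSE)
  p_hot <- q_hot
  p_hot[!planted] <- q_hot[!planted] * (1 - spec$effect / (1 - q_planted))
  p_hot[planted] <- q_hot[planted] + spec$effect / sum(planted)
  list(hotspot = p_hot, coldspot = q_cold)
}

#' Generate a synthetic hotspot/coldspot dataset
#'
#' @param spec a [simulation_spec()].
#' @return A [recspot_dataset] with `n_pos` hotspot records (ids `hot...`)
#'   followed by `n_neg` coldspot records (ids `cold...`).
#' @examples
#' d <- generate_synthetic_dataset(simulation_spec(n_pos = 5, n_neg = 7,
#'   length_low = 50, length_high = 80, seed = 1))
#' table(d$label)
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  dists <- token_distributions(spec)
  kmers <- names(dists$hotspot)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  gen_class <- function(n, prob, prefix) {
    if (n == 0) return(list(id = character(0), seq = character(0)))
    lens <- spec$length_low +
      sample.int(spec$length_high - spec$length_low + 1L, n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L) {
      toks <- sample(kmers, ceiling(L / 3), replace = TRUE, prob = prob)
      substr(paste(toks, collapse = ""), 1L, L)
    }, character(1))
    list(id = sprintf("%s%04d", prefix, seq_len(n)), seq = seqs)
  }
  hot <- gen_class(spec$n_pos, dists$hotspot, "hot")
  cold <- gen_class(spec$n_neg, dists$coldspot, "cold")
  recspot_dataset(c(hot$id, cold$id), c(hot$seq, cold$seq),
                  c(rep("hotspot", spec$n_pos), rep("coldspot", spec$n_neg)))
}
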