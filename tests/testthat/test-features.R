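test_that("gapped dinucleotide composition matches brute-force enumeration", {
  g0 <- gdc_features("AAAA", gaps = 0)
  expect_equal(unname(g0["GDC|AA|g0"]), 1)
  expect_equal(sum(g0), 1)

  g <- gdc_features("ACGTACGT", gaps = 0)
  expect_equal(unname(g[c("GDC|AC|g0", "GDC|CG|g0", "GDC|GT|g0", "GDC|TA|g0")]),
               c(2 / 7, 2 / 7, 2 / 7, 1 / 7))
  expect_equal(sum(g != 0), 4)

  g1 <- gdc_features("ACGTACGT", gaps = 1)
  expect_equal(unname(g1[c("GDC|AG|g1", "GDC|CT|g1", "GDC|GA|g1", "GDC|TC|g1")]),
               c(2 / 6, 2 / 6, 1 / 6, 1 / 6))

  set.seed(21)
  for (rep in 1:10) {
    s <- random_dna(sample(12:30, 1))
    gap <- sample(0:4, 1)
    v <- gdc_features(s, gaps = gap)
    pair <- sample(c("AA", "AC", "GT", "TG", "CC"), 1)
    expect_equal(unname(v[paste0("GDC|", pair, "|g", gap)]),
                 naive_gdc_pair(s, pair, gap))
    expect_equal(sum(v), 1, tolerance = 1e-12)  # per-gap sum over 16 pairs
  }
})

test_that("gaps longer than the sequence allows yield zeros with a warning", {
  expect_warning(v <- gdc_features("ACGT", gaps = c(0, 5)), "gap 5")
  expect_equal(sum(v[17:32]), 0)
  expect_equal(sum(v[1:16]), 1)
})

test_that("canonical k-mers collapse strand-equivalent classes", {
  expect_equal(canonical_kmer("CGT"), "ACG")
  expect_equal(canonical_kmer("ACGT"), "ACGT")
  expect_equal(canonical_kmer(canonical_kmer("TTTT")), canonical_kmer("TTTT"))
  all4 <- recspot:::kmer_registry(4)
  canon <- unique(canonical_kmer(all4))
  expect_length(canon, 136)
  pal <- all4[all4 == vapply(all4, naive_revcomp, character(1))]
  expect_length(pal, 16)
  expect_length(unique(canonical_kmer(recspot:::kmer_registry(3))), 32)
})

test_that("canonical composition has fixed length 680 and is strand-invariant", {
  v <- rcc_features("ACG", ks = 3)
  expect_equal(unname(v["RCC|3|ACG"]), 1 / 3)
  expect_equal(sum(v != 0), 1)

  set.seed(31)
  for (rep in 1:25) {
    s <- random_dna(sample(10:200, 1))
    v <- rcc_features(s)
    expect_length(v, 680)
    expect_equal(v, rcc_features(naive_revcomp(s)))
  }
})

test_that("per-window normalization divides by window count instead of L", {
  s <- "ACGTAC"
  v_l <- rcc_features(s, ks = 3, normalization = "per-L")
  v_w <- rcc_features(s, ks = 3, normalization = "per-window")
  expect_equal(sum(v_w), 1)          # 4 windows / 4
  expect_equal(sum(v_l), 4 / 6)      # 4 windows / L
})

test_that("trinucleotide frequencies are window counts over L - 2", {
  v <- tnc_frequencies("AAAA")
  expect_equal(unname(v["TNC|AAA"]), 1)
  v2 <- tnc_frequencies("ACGTA")
  expect_equal(unname(v2[c("TNC|ACG", "TNC|CGT", "TNC|GTA")]), rep(1 / 3, 3))
  set.seed(41)
  for (rep in 1:10) {
    s <- random_dna(sample(3:30, 1))
    v <- tnc_frequencies(s)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    cnt <- naive_kmer_counts(s, 3)
    expect_equal(unname(v[paste0("TNC|", names(cnt))]),
                 as.numeric(cnt) / (nchar(s) - 2))
  }
})

test_that("correlation tiers match a brute-force loop and its degenerate cases", {
  p <- psetnc_params()
  expect_equal(theta_correlation("AAAAAA", 1, p), 0)
  expect_equal(theta_correlation("AAAAAA", 3, p), 0)
  zero_tab <- psetnc_params(
    property_table = matrix(0, 64, 2,
                            dimnames = list(recspot:::kmer_registry(3), NULL)))
  expect_equal(theta_correlation("ACGTACGT", 1, zero_tab), 0)
  expect_error(theta_correlation("ACGTA", 5, p), "L\\*")

  set.seed(51)
  P <- p$property_table
  for (rep in 1:10) {
    s <- random_dna(sample(10:30, 1))
    j <- sample(1:2, 1)
    Lstar <- nchar(s) - 2
    tri <- substring(s, 1:Lstar, 3:nchar(s))
    acc <- 0
    for (i in 1:(Lstar - j))
      acc <- acc + mean((P[tri[i], ] - P[tri[i + j], ])^2)
    expect_equal(theta_correlation(s, j, p), acc / (Lstar - j))
  }
})

test_that("pseudo trinucleotide composition normalizes to 1 and nests TNC", {
  v <- psetnc_features("ACGTACGTACGT")
  expect_length(v, 66)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_true(all(v >= 0))

  v0 <- psetnc_features("ACGTACGTACGT", psetnc_params(lam = 0))
  expect_equal(unname(v0), unname(tnc_frequencies("ACGTACGTACGT")))

  # more weight on the tiers when any theta > 0
  s <- "ACGGTTACGGAA"
  tiers <- function(w) sum(psetnc_features(s, psetnc_params(lam = 2, w = w))[65:66])
  expect_true(tiers(0.1) < tiers(0.5) && tiers(0.5) < tiers(1))
  expect_error(psetnc_features("ACG", psetnc_params(lam = 2)), "too short")
})

test_that("k-mer bank covers 1364 features with per-k normalization", {
  v <- kmer_bank_features("ACGTACGTAC")
  expect_length(v, 4 + 16 + 64 + 256 + 1024)
  for (k in 1:5)
    expect_equal(sum(v[startsWith(names(v), paste0("KMER|", k, "|"))]), 1,
                 tolerance = 1e-12)
  vA <- kmer_bank_features("AAAA", ks = 1:3)
  expect_equal(sum(vA[!names(vA) %in% c("KMER|1|A", "KMER|2|AA", "KMER|3|AAA")]), 0)
})

test_that("block extraction aligns rows with dataset order and tags blocks", {
  d <- tiny_dataset(n_per = 5, L = 70, seed = 2)
  G <- extract_block(d, "gdc")
  expect_equal(dim(G), c(10, 128))
  expect_equal(rownames(G), d$id)
  expect_equal(attr(G, "block_tag"), "G")
  expect_equal(dim(extract_block(d, "rcc")), c(10, 680))
  P <- extract_block(d, "psetnc")
  expect_equal(dim(P), c(10, 66))
  expect_equal(attr(P, "block_tag"), "P")
  expect_equal(unname(P[3, ]), unname(psetnc_features(d$seq[3])))
  expect_error(extract_block(recspot_dataset(character(0), character(0),
                                             character(0)), "gdc"), "empty")
})

test_that("feature matrices survive a TSV round trip", {
  d <- tiny_dataset(n_per = 3, L = 50, seed = 4)
  m <- extract_block(d, "gdc")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(m, f, labels = d$label)
  back <- read_feature_tsv(f)
  expect_equal(back$matrix, structure(m, block_tag = NULL),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(colnames(back$matrix), colnames(m))
  expect_equal(back$labels, as.character(d$label))
})

test_that("extractors agree with naive recounting on short sequences", {
  set.seed(61)
  for (rep in 1:8) {
    s <- random_dna(sample(15:30, 1))
    L <- nchar(s)
    # bank vs naive counts for every k
    v <- kmer_bank_features(s)
    for (k in 1:5) {
      cnt <- naive_kmer_counts(s, k)
      expect_equal(unname(v[paste0("KMER|", k, "|", names(cnt))]),
                   as.numeric(cnt) / (L - k + 1))
    }
    # rcc vs naive canonical pooling
    r <- rcc_features(s, ks = 3)
    cnt3 <- naive_kmer_counts(s, 3)
    pooled <- tapply(as.numeric(cnt3),
                     vapply(names(cnt3), function(x)
                       min(x, naive_revcomp(x)), character(1)), sum)
    expect_equal(unname(r[paste0("RCC|3|", names(pooled))]),
                 as.numeric(pooled) / L)
  }
})
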