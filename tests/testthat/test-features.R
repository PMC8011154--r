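test_that("homopolymer context length follows the flanking-run rules", {
  # insertion of A anchored at the start of a 5-A run
  expect_identical(homopolymer_length("CCAAAAACC", 2L, "insertion", "A"), 5L)
  # anchored just past the run: the run ends at pos-1
  expect_identical(homopolymer_length("CCAAAAACC", 7L, "insertion", "A"), 5L)
  # neither neighbour matches the allele: a new run of length 1
  expect_identical(homopolymer_length("ACGT", 2L, "insertion", "A"), 1L)
  # deletion candidates use the run containing the draft base
  expect_identical(homopolymer_length("ACGT", 2L, "deletion"), 1L)
  expect_identical(homopolymer_length(strrep("T", 12), 5L, "deletion"), 12L)
})

test_that("homopolymer one-hot has ten categories with a single hot slot", {
  v <- encode_homopolymer(5L)
  expect_length(v, 10L)
  expect_equal(sum(v), 1)
  expect_equal(unname(v[5]), 1)
  expect_equal(unname(encode_homopolymer(1L)[1]), 1)
  expect_equal(unname(encode_homopolymer(47L)[10]), 1)  # >=10 bucket
  m <- encode_homopolymer(1:12)
  expect_identical(dim(m), c(12L, 10L))
  expect_equal(rowSums(m), rep(1, 12))
  expect_error(encode_homopolymer(0L), ">= 1")
})

make_fake_pileup <- function(spans) {
  structure(list(spans = spans), class = "homolog_pileup")
}

cand_row <- function(pos, supporters, kind = "insertion") {
  data.table::data.table(contig = "chr", pos = pos, kind = kind,
                         allele = "A", supporters = list(supporters))
}

test_that("paired ambiguous loci get major=1 / minor=2, others 0", {
  spans <- data.table::data.table(
    homolog = sprintf("h%d", 1:20), contig = "chr", start = 0L, end = 1000L)
  pile <- make_fake_pileup(spans)

  lone <- cand_row(100L, sprintf("h%d", 1:10))
  expect_identical(detect_paired_ambiguity(lone, pile), 0L)

  pair <- rbind(cand_row(100L, sprintf("h%d", 1:15)),
                cand_row(112L, sprintf("h%d", 16:20)))
  expect_identical(detect_paired_ambiguity(pair, pile), c(1L, 2L))
  # swapped majority
  expect_identical(detect_paired_ambiguity(
    rbind(cand_row(100L, sprintf("h%d", 16:20)),
          cand_row(112L, sprintf("h%d", 1:15))), pile), c(2L, 1L))

  # overlapping supporters never pair
  overlap <- rbind(cand_row(100L, sprintf("h%d", 1:15)),
                   cand_row(112L, sprintf("h%d", 14:20)))
  expect_identical(detect_paired_ambiguity(overlap, pile), c(0L, 0L))

  # insufficient joint coverage never pairs (5 + 3 of 20 < 0.8)
  sparse <- rbind(cand_row(100L, sprintf("h%d", 1:5)),
                  cand_row(112L, sprintf("h%d", 6:8)))
  expect_identical(detect_paired_ambiguity(sparse, pile), c(0L, 0L))

  # beyond the window no pair forms
  far <- rbind(cand_row(100L, sprintf("h%d", 1:15)),
               cand_row(300L, sprintf("h%d", 16:20)))
  expect_identical(detect_paired_ambiguity(far, pile), c(0L, 0L))
})

test_that("greedy pairing is leftmost-first and nearest-partner", {
  spans <- data.table::data.table(
    homolog = sprintf("h%d", 1:20), contig = "chr", start = 0L, end = 1000L)
  pile <- make_fake_pileup(spans)
  trio <- rbind(cand_row(100L, sprintf("h%d", 1:15)),
                cand_row(140L, sprintf("h%d", 16:20)),
                cand_row(120L, sprintf("h%d", 16:20)))
  data.table::setorder(trio, pos)
  # leftmost locus pairs with its nearest exclusive partner (120), the
  # leftover locus stays unpaired
  expect_identical(detect_paired_ambiguity(trio, pile), c(1L, 2L, 0L))
})

test_that("raw feature vectors reproduce hand-computed pileup counts", {
  draft <- c(chr = strrep("ACGTT", 12))
  L <- nchar(draft[[1]])
  seg_del <- paste0(substr(draft[[1]], 1, 30), substr(draft[[1]], 32, L))
  alns <- c(
    lapply(sprintf("d%02d", 1:12), function(id)
      homolog_alignment(id, "chr", 0L, L, "+",
                        paste0("30=1D", L - 31, "="), seg_del)),
    lapply(sprintf("m%02d", 1:8), match_alignment, draft = draft))
  pile <- build_pileup(draft, alns)
  cand <- call_candidates(pile)
  feat <- extract_features(cand, pile)
  expect_identical(nrow(feat), 1L)
  expect_identical(ncol(feat) - 4L, 21L)  # 4 meta + 21 numeric dims
  expect_equal(feat$del, 12)
  expect_equal(feat$cov, 20)
  expect_equal(feat$m_A + feat$m_T + feat$m_C + feat$m_G, 8)
  expect_equal(feat$i_A + feat$i_T + feat$i_C + feat$i_G, 0)
  hp <- as.matrix(feat[, c(paste0("hp_", 1:9), "hp_ge10"), with = FALSE])
  expect_equal(sum(hp), 1)
})

test_that("feature vectors are pure, 21-dimensional and one-hot-consistent", {
  fx <- tiny_fixture()
  pile <- build_pileup(fx$draft, fx$alignments)
  cand <- call_candidates(pile)
  f1 <- extract_features(cand, pile)
  f2 <- extract_features(cand, pile)
  expect_identical(f1, f2)
  dims <- setdiff(names(f1), c("contig", "pos", "kind", "allele"))
  expect_length(dims, 21L)
  hp <- as.matrix(f1[, c(paste0("hp_", 1:9), "hp_ge10"), with = FALSE])
  expect_equal(rowSums(hp), rep(1, nrow(f1)))
  expect_true(all(f1$amb %in% c(0, 1, 2)))
})

test_that("systematic-error loci dominate strain-variation loci in counts", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  sys_ins <- feat[grepl("^INS_", label)]
  var_ins <- feat[label == "NO_INSERTION"]
  dominant <- function(d) pmax(d$i_A, d$i_T, d$i_C, d$i_G)
  expect_gt(min(dominant(sys_ins) / sys_ins$cov),
            max(dominant(var_ins) / var_ins$cov))
  sys_del <- feat[label == "DELETION"]
  var_del <- feat[label == "NO_DELETION"]
  expect_gt(min(sys_del$del / sys_del$cov), max(var_del$del / var_del$cov))
})

test_that("min-max scaling maps to [0,1], clamps, and handles degeneracy", {
  base <- data.table::data.table(
    contig = "chr", pos = 1:3, kind = "insertion", allele = "A",
    m_A = c(0, 10, 20), m_T = 5, m_C = c(1, 2, 3), m_G = 0,
    i_A = c(0, 1, 2), i_T = 0, i_C = 0, i_G = 0, del = c(0, 5, 10),
    cov = c(10, 20, 30))
  base <- cbind(base, data.table::as.data.table(encode_homopolymer(c(1, 2, 3))))
  base$amb <- 0
  sc <- fit_scaler(base)
  scaled <- apply_scaler(base, sc)
  expect_equal(scaled$m_A, c(0, 0.5, 1))
  expect_equal(scaled$m_T, c(0, 0, 0))  # constant dimension maps to 0
  expect_equal(scaled$hp_1, base$hp_1)  # one-hot passes through untouched

  unseen <- data.table::copy(base)[1]
  unseen$m_A <- 40  # above the training max
  expect_equal(apply_scaler(unseen, sc)$m_A, 1)
  unseen$m_A <- -5
  expect_equal(apply_scaler(unseen, sc)$m_A, 0)

  expect_error(apply_scaler(base, list()), "not a fitted")
  expect_error(fit_scaler(base[1]), ">= 2")
})

test_that("feature tables round-trip through TSV with schema validation", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(feat, path)
  back <- read_feature_tsv(path)
  expect_equal(as.data.frame(back[, names(feat), with = FALSE]),
               as.data.frame(feat), ignore_attr = TRUE)
  bad <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(feat[, 1:6], bad, sep = "\t")
  expect_error(read_feature_tsv(bad), "lacks columns")
})
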