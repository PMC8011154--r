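test_that("fixture worlds are byte-identical under a fixed seed", {
  spec <- fixture_spec(genome_length = 15000L, n_strains = 5L,
                       error_count = 40L, strain_indel_events = 30L,
                       seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture_bundle(spec, d1)
  make_fixture_bundle(spec, d2)
  files <- c("truth.fa", "draft.fa", "alignments.paf", "labels.tsv",
             "spec.json", file.path("strains", "strain01.fa"))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  d3 <- withr::local_tempdir()
  make_fixture_bundle(fixture_spec(genome_length = 15000L, n_strains = 5L,
                                   error_count = 40L,
                                   strain_indel_events = 30L, seed = 43L), d3)
  expect_false(identical(readLines(file.path(d1, "truth.fa")),
                         readLines(file.path(d3, "truth.fa"))))
})

test_that("truth genomes hit the requested GC and skewed run lengths", {
  spec <- fixture_spec(genome_length = 100000L, gc = 0.5, seed = 3L)
  g <- simulate_truth(spec)[[1]]
  chars <- strsplit(g, "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  runs <- rle(chars)$lengths
  # right-skewed: most runs short, hardly any beyond ten
  expect_gt(mean(runs < 3), 0.8)
  expect_lt(mean(runs > 10), 1e-3)
  expect_gt(max(runs), 4)  # enrichment produces real homopolymers
})

test_that("zero homopolymer enrichment matches the i.i.d. geometric law", {
  spec <- fixture_spec(genome_length = 200000L, gc = 0.5,
                       homopolymer_weight = 0, seed = 4L)
  runs <- rle(strsplit(simulate_truth(spec)[[1]], "")[[1]])$lengths
  # run length ~ Geometric(p = 3/4) at equal base frequencies
  cap <- 6L
  obs <- tabulate(pmin(runs, cap), nbins = cap)
  p <- 0.75
  probs <- p * (1 - p)^(0:(cap - 2))
  probs <- c(probs, 1 - sum(probs))
  chi <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(chi$p.value, 0.001)
})

test_that("injected systematic errors are exactly booked and homopolymer-biased", {
  spec <- fixture_spec(genome_length = 50000L, error_count = 500L, seed = 5L)
  truth <- simulate_truth(spec)
  inj <- inject_systematic_errors(truth, spec)
  expect_identical(nrow(inj$errors), 500L)
  expect_identical(anyDuplicated(inj$errors$pos), 0L)
  expect_identical(nchar(inj$draft[[1]]),
                   nchar(truth[[1]]) - sum(inj$errors$type == "del") +
                     sum(inj$errors$type == "dup"))
  chars <- strsplit(truth[[1]], "")[[1]]
  run_len <- rep(rle(chars)$lengths, rle(chars)$lengths)
  expect_gt(mean(run_len[inj$errors$pos + 1L] >= 2), 0.8)
  # zero errors leave the draft untouched
  spec0 <- fixture_spec(genome_length = 50000L, error_count = 0L, seed = 5L)
  expect_identical(inject_systematic_errors(truth, spec0)$draft[[1]],
                   truth[[1]])
})

test_that("strains hit their identity target and record exact edits", {
  spec <- fixture_spec(genome_length = 100000L, n_strains = 10L,
                       strain_identity = 0.98, strain_indel_events = 60L,
                       seed = 6L)
  truth <- simulate_truth(spec)
  sv <- simulate_strains(truth, spec)
  # per-strain edit counts from the recorded sharing
  edits_per_strain <- vapply(seq_len(10L), function(j)
    sum(vapply(sv$variations$strains, function(s) j %in% s, logical(1))),
    numeric(1))
  observed_identity <- 1 - edits_per_strain / 100000
  expect_lt(abs(mean(observed_identity) - 0.98), 0.002)
  # identity target 1.0 gives truth back (SNP count 0)
  spec1 <- fixture_spec(genome_length = 100000L, n_strains = 3L,
                        strain_identity = 1, strain_indel_events = 0L,
                        seed = 6L)
  sv1 <- simulate_strains(truth, spec1)
  expect_identical(sv1$strains[[1]][[1]], truth[[1]])
})

test_that("composed cigars are consistent with draft and strain sequences", {
  fx <- tiny_fixture()
  for (a in fx$alignments[1:3]) {
    dchars <- strsplit(fx$draft[[a$draft_contig]], "")[[1]]
    schars <- strsplit(a$homolog_segment, "")[[1]]
    dp <- a$draft_start; qp <- 0L
    for (i in seq_len(nrow(a$cigar))) {
      op <- a$cigar$op[i]; l <- a$cigar$len[i]
      if (op == "=") {
        expect_identical(dchars[dp + seq_len(l)], schars[qp + seq_len(l)])
        dp <- dp + l; qp <- qp + l
      } else if (op == "X") {
        expect_true(all(dchars[dp + seq_len(l)] != schars[qp + seq_len(l)]))
        dp <- dp + l; qp <- qp + l
      } else if (op == "D") dp <- dp + l
      else if (op == "I") qp <- qp + l
    }
    expect_identical(dp, a$draft_end)
    expect_identical(qp, length(schars))
  }
})

test_that("fixture ground truth is closed and unambiguous", {
  fx <- tiny_fixture()
  # systematic-error and variation positions are disjoint (truth coords)
  expect_length(intersect(fx$errors$pos, fx$variations$pos), 0L)
  # label classes are drawn from the seven-class alphabet
  expect_true(all(fx$labels$class %in% class_labels()))
  # labels imply edits that reproduce the truth genome exactly
  calls <- fx$labels[, list(contig, pos, kind,
                            allele = sub("^INS_", "", class),
                            label = class, score = 0)]
  expect_identical(apply_edits(fx$draft, edits_from_predictions(calls))[[1]],
                   fx$truth[[1]])
  # every systematic error is absent from every strain: all alignments carry
  # the complementary indel at the error anchor
  pile <- build_pileup(fx$draft, fx$alignments)
  cand <- call_candidates(pile)
  sys <- fx$labels[!grepl("^NO_", class)]
  m <- merge(cand, sys, by = c("contig", "pos", "kind"))
  expect_identical(nrow(m), nrow(sys))
  expect_true(all(m$n_support == fx$spec$n_strains))
})

test_that("default-spec bundles build quickly enough for routine use", {
  t0 <- Sys.time()
  fx <- make_fixture_bundle(fixture_spec(seed = 99L))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_identical(nchar(fx$truth[[1]]), 200000L)
  expect_length(fx$strains, 20L)
  expect_identical(nrow(fx$errors), 500L)
})
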