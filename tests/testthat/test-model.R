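test_that("truth labeling recovers generator classes exactly", {
  fx <- tiny_fixture()
  cand <- call_candidates(build_pileup(fx$draft, fx$alignments))
  labels <- label_loci(cand, fx$draft, fx$truth_alignment)
  expect_identical(attr(labels, "n_unaligned"), 0L)
  merged <- merge(
    data.table::data.table(contig = cand$contig, pos = cand$pos,
                           kind = cand$kind, label = as.character(labels)),
    fx$labels, by = c("contig", "pos", "kind"))
  expect_identical(nrow(merged), nrow(cand))
  expect_identical(merged$label, merged$class)
  expect_true(all(labels %in% class_labels()))
})

test_that("a draft identical to truth labels everything as retain", {
  draft <- c(chr = random_dna(500, seed = 9L))
  truth_aln <- list(match_alignment("truth", draft))
  seg <- paste0(substr(draft[[1]], 1, 100), "A", substr(draft[[1]], 101, 500))
  alns <- list(
    homolog_alignment("h1", "chr", 0L, 500L, "+", "100=1I400=", seg),
    homolog_alignment("h2", "chr", 0L, 500L, "+",
                      paste0("200=1D299="),
                      paste0(substr(draft[[1]], 1, 200),
                             substr(draft[[1]], 202, 500))))
  cand <- call_candidates(build_pileup(draft, alns))
  labels <- label_loci(cand, draft, truth_aln)
  expect_setequal(unique(labels), c("NO_INSERTION", "NO_DELETION"))
})

test_that("no-deletion deduplication collapses exact duplicates only", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  nd <- feat[label == "NO_DELETION"][1]
  dup_nd <- data.table::rbindlist(rep(list(nd), 1000L))
  ins <- feat[label == "INS_A"][1]
  dup_ins <- data.table::rbindlist(rep(list(ins), 3L))
  table <- data.table::rbindlist(list(feat, dup_nd, dup_ins))
  out <- dedupe_no_deletion(table)
  dims <- homologpolish:::FEATURE_DIMS
  n_distinct_nd <- nrow(unique(table[label == "NO_DELETION", ..dims]))
  expect_identical(nrow(out[label == "NO_DELETION"]), n_distinct_nd)
  # all other classes keep their duplicates
  expect_identical(nrow(out[label != "NO_DELETION"]),
                   nrow(table[label != "NO_DELETION"]))
})

test_that("the 9:1 split is stratified, seeded and keeps small classes", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  sp <- split_train_test(feat, seed = 17L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(feat))
  ratio <- nrow(sp$test) / nrow(feat)
  expect_gte(ratio, 0.05)  # floor() per stratum shaves a little off 10%
  expect_lte(ratio, 0.12)
  sp2 <- split_train_test(feat, seed = 17L)
  expect_identical(sp$test, sp2$test)
  expect_false(identical(sp$test, split_train_test(feat, seed = 99L)$test))
  # a 3-member class is never emptied from train
  small <- data.table::copy(feat)
  small$label[1:3] <- "INS_T"
  small <- small[c(1:3, which(small$label == "NO_INSERTION")[1:30])]
  spx <- split_train_test(small, seed = 17L)
  expect_identical(sum(spx$train$label == "INS_T"), 3L)
})

test_that("100 rows split 90/10", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)[label == "NO_INSERTION"]
  feat <- data.table::rbindlist(rep(list(feat), ceiling(100 / nrow(feat))))[1:100]
  sp <- split_train_test(feat, seed = 17L)
  expect_identical(nrow(sp$train), 90L)
  expect_identical(nrow(sp$test), 10L)
})

test_that("training rejects degenerate inputs", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  expect_error(train_classifier(feat[label == "DELETION"]), "single class")
  bad <- data.table::copy(feat)
  bad$label[1] <- "WAT"
  expect_error(train_classifier(bad), "unknown class")
})

test_that("a separable two-class toy reaches perfect accuracy", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)[label %in% c("DELETION", "NO_DELETION")]
  bundle <- train_classifier(feat)
  rep <- evaluate_classifier(bundle, feat)
  expect_equal(rep$macro$f1, 1)
  expect_true(all(rep$confusion["DELETION", "NO_DELETION"] == 0))
})

test_that("prediction is kind-masked and deterministic", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  bundle <- train_classifier(feat)
  calls <- predict_classes(bundle, feat)
  ins_calls <- calls[feat$kind == "insertion"]$label
  del_calls <- calls[feat$kind == "deletion"]$label
  expect_true(all(ins_calls %in% c("INS_A", "INS_T", "INS_C", "INS_G",
                                   "NO_INSERTION")))
  expect_true(all(del_calls %in% c("DELETION", "NO_DELETION")))
  expect_identical(calls, predict_classes(bundle, feat))
  # training accuracy at least matches held-out accuracy
  sp <- split_train_test(feat, seed = 17L)
  b2 <- train_classifier(sp$train)
  acc <- function(d) mean(predict_classes(b2, d)$label == d$label)
  expect_gte(acc(sp$train), acc(sp$test) - 1e-9)
})

test_that("model bundles round-trip through serialization unchanged", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  bundle <- train_classifier(feat)
  path <- withr::local_tempfile(fileext = ".bin")
  save_model(bundle, path)
  back <- load_model(path)
  expect_identical(predict_classes(back, feat), predict_classes(bundle, feat))
  expect_identical(back$gamma, bundle$gamma)
  wrong <- withr::local_tempfile(fileext = ".bin")
  saveRDS(list(a = 1), wrong)
  expect_error(load_model(wrong), "not a homologpolish model")
})

test_that("classifier metrics match hand arithmetic on a small case", {
  fx <- tiny_fixture()
  feat <- featurize_fixture(fx)
  bundle <- train_classifier(feat)
  rep <- evaluate_classifier(bundle, feat)
  # confusion rows sum to class supports
  supports <- table(factor(feat$label, levels = class_labels()))
  expect_equal(unname(rowSums(rep$confusion)), as.vector(supports))
  # recompute macro F1 from the confusion matrix independently
  cm <- rep$confusion
  f1s <- vapply(rownames(cm), function(cl) {
    tp <- cm[cl, cl]; fp <- sum(cm[, cl]) - tp; fn <- sum(cm[cl, ]) - tp
    if (sum(cm[cl, ]) == 0) return(NA_real_)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- tp / (tp + fn)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }, numeric(1))
  expect_equal(rep$macro$f1, mean(f1s, na.rm = TRUE))
})

test_that("held-out performance on the small world is strong", {
  fx <- tiny_fixture()
  feat <- dedupe_no_deletion(featurize_fixture(fx))
  sp <- split_train_test(feat, seed = 17L)
  bundle <- train_classifier(sp$train)
  rep <- evaluate_classifier(bundle, sp$test)
  expect_gte(rep$macro$f1, 0.9)
})
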