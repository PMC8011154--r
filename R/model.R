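#' Seven-class SVM over candidate loci
#'
#' Candidate indel loci are classified into seven classes: insertion of
#' A/T/C/G (the draft is missing a base; correct it), deletion (the draft
#' carries an extra base; remove it), and the two retain classes
#' no-insertion / no-deletion (the homolog signal reflects strain variation;
#' leave the draft alone). Insertion candidates can only take insertion-side
#' classes and deletion candidates deletion-side classes; prediction is
#' masked accordingly.
#'
#' @name svm_model
NULL

#' The seven class labels
#'
#' @return character vector of the seven class labels in canonical order.
#' @export
class_labels <- function() {
  c("INS_A", "INS_T", "INS_C", "INS_G", "DELETION",
    "NO_INSERTION", "NO_DELETION")
}

INSERTION_CLASSES <- c("INS_A", "INS_T", "INS_C", "INS_G", "NO_INSERTION")
DELETION_CLASSES <- c("DELETION", "NO_DELETION")

#' Label candidate loci against a truth genome
#'
#' Uses an exact truth-vs-draft alignment (the truth genome playing the role
#' of a single homolog) to decide, per candidate: an insertion candidate is
#' `INS_X` when the truth inserts a base (first base X) at the anchor,
#' otherwise `NO_INSERTION`; a deletion candidate is `DELETION` when the
#' truth deletes the draft base, otherwise `NO_DELETION`. Candidates in
#' regions not covered by the truth alignment are labeled `NA` and should be
#' dropped by the caller; the number dropped is attached as attribute
#' `n_unaligned`.
#'
#' @param candidates candidate table from [call_candidates()].
#' @param draft named character vector of draft sequences.
#' @param truth_alignment list of [homolog_alignment()] of the truth genome
#'   against the draft.
#' @return character vector of labels (NA where unaligned), with attribute
#'   `n_unaligned`.
#' @export
label_loci <- function(candidates, draft, truth_alignment) {
  tp <- build_pileup(draft, truth_alignment)
  n <- nrow(candidates)
  labels <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ctg <- candidates$contig[i]; p <- candidates$pos[i]
    pc <- tp$contigs[[ctg]]
    if (is.null(pc) || pc$cov[p + 1L] == 0L) next
    if (candidates$kind[i] == "insertion") {
      ins <- pc$ins[pc$ins$pos == p]
      labels[i] <- if (nrow(ins)) paste0("INS_", substr(ins$seq[1], 1, 1))
                   else "NO_INSERTION"
    } else {
      labels[i] <- if (any(pc$del$pos == p)) "DELETION" else "NO_DELETION"
    }
  }
  n_unaligned <- sum(is.na(labels))
  if (n_unaligned > 0L)
    message(n_unaligned, " candidate loci fell outside the truth alignment ",
            "and were left unlabeled")
  attr(labels, "n_unaligned") <- n_unaligned
  labels
}

#' Deduplicate the no-deletion class
#'
#' The no-deletion class dominates the raw training data by orders of
#' magnitude; exact-duplicate 21-dimension vectors within that class are
#' collapsed to one row. All other classes are left untouched.
#'
#' @param features labeled feature table (column `label`).
#' @return deduplicated feature table.
#' @export
dedupe_no_deletion <- function(features) {
  stopifnot("label" %in% names(features))
  nd <- features$label == "NO_DELETION"
  keep_nd <- features[nd][!duplicated(features[nd, FEATURE_DIMS, with = FALSE])]
  out <- data.table::rbindlist(list(features[!nd], keep_nd))
  data.table::setorder(out, contig, pos, kind)
  out[]
}

#' Stratified train/test split
#'
#' Splits rows into train and test sets at the given test ratio (default
#' one-tenth, i.e. a nine-to-one split), stratified by class for classes with
#' at least 10 members; smaller classes contribute `floor(n * ratio)` test
#' rows, which keeps them in the training set rather than emptying them.
#' Deterministic under a fixed seed.
#'
#' @param features labeled feature table.
#' @param test_ratio fraction of rows held out (default 0.1).
#' @param seed RNG seed (default 17).
#' @return list with elements `train` and `test`.
#' @export
split_train_test <- function(features, test_ratio = 0.1, seed = 17L) {
  stopifnot(nrow(features) > 0L, "label" %in% names(features))
  with_seed(seed, {
    test_idx <- integer(0)
    for (cl in unique(features$label)) {
      rows <- which(features$label == cl)
      n_test <- floor(length(rows) * test_ratio)
      if (n_test > 0L)
        test_idx <- c(test_idx, sample(rows, n_test))
    }
    list(train = features[-test_idx][order(contig, pos, kind)],
         test = if (length(test_idx)) features[sort(test_idx)]
                else features[0])
  })
}

# gamma under the "scale" policy: 1 / (n_dims * pooled variance of X)
gamma_scale <- function(x) {
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(x) * v)
}

#' Train the seven-class RBF-SVM
#'
#' Fits the min-max scaler on the training rows, then trains a radial-basis
#' SVM (cost `C = 1.0` by default, one-vs-one multiclass) on the 21 scaled
#' dimensions. Class imbalance is handled only by the upstream no-deletion
#' deduplication; no class weights are applied.
#'
#' @param features labeled feature table (raw counts; column `label`).
#' @param C regularization constant (default 1.0).
#' @param gamma kernel width: `"scale"` (1 / (n_dims * var(X))) or a number.
#' @param seed seed recorded in the bundle and used for any stochastic solver
#'   component (default 17).
#' @return a `polish_model` bundle embedding the SVM, the fitted scaler, the
#'   feature schema version and training metadata.
#' @export
train_classifier <- function(features, C = 1.0, gamma = "scale", seed = 17L) {
  stopifnot("label" %in% names(features))
  features <- features[!is.na(label)]
  classes <- sort(unique(features$label))
  if (length(classes) < 2L)
    stop("training data contains a single class (", classes,
         "); at least two classes are required")
  bad <- setdiff(classes, class_labels())
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  scaler <- fit_scaler(features)
  x <- as.matrix(apply_scaler(features, scaler)[, FEATURE_DIMS, with = FALSE])
  y <- factor(features$label, levels = intersect(class_labels(), classes))
  g <- if (identical(gamma, "scale")) gamma_scale(x) else as.numeric(gamma)
  fit <- with_seed(seed, e1071::svm(x = x, y = y, scale = FALSE,
                                    kernel = "radial", cost = C, gamma = g))
  structure(
    list(model = fit, scaler = scaler, C = C, gamma_policy = gamma,
         gamma = g, classes = levels(y), seed = seed,
         feature_version = feature_schema()$version,
         class_counts = as.list(table(features$label)),
         bundle_version = "homologpolish-model-1"),
    class = "polish_model")
}

#' @export
print.polish_model <- function(x, ...) {
  cat(sprintf("<polish_model> RBF SVM, C=%g, gamma=%.4g, %d classes, %d SVs\n",
              x$C, x$gamma, length(x$classes), nrow(x$model$SV)))
  invisible(x)
}

#' Predict classes for candidate loci
#'
#' Scales features with the bundle's scaler and predicts with the SVM's
#' one-vs-one decision values, masked by candidate kind: insertion candidates
#' choose among {INS_A, INS_T, INS_C, INS_G, NO_INSERTION}, deletion
#' candidates among {DELETION, NO_DELETION}. The admissible class with the
#' most pairwise votes wins; ties break by summed decision margin.
#'
#' @param bundle a `polish_model`.
#' @param features feature table (raw counts) with meta columns.
#' @return `data.table` of meta columns plus `label` and `score` (mean
#'   decision margin in favour of the winning class).
#' @export
predict_classes <- function(bundle, features) {
  stopifnot(inherits(bundle, "polish_model"))
  if (!identical(attr(features, "feature_version"), bundle$feature_version) &&
      !all(FEATURE_DIMS %in% names(features)))
    stop("feature table does not match the model's feature schema (",
         bundle$feature_version, ")")
  out <- features[, META_COLS, with = FALSE]
  if (nrow(features) == 0L) {
    out[, `:=`(label = character(), score = numeric())]
    return(out[])
  }
  x <- as.matrix(apply_scaler(features, bundle$scaler)[, FEATURE_DIMS,
                                                       with = FALSE])
  pred <- predict(bundle$model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
  classes <- bundle$classes
  n <- nrow(x)
  label <- character(n)
  score <- numeric(n)
  for (side in c("insertion", "deletion")) {
    rows <- which(features$kind == side)
    if (!length(rows)) next
    admissible <- intersect(classes, if (side == "insertion")
      INSERTION_CLASSES else DELETION_CLASSES)
    if (length(admissible) == 0L)
      stop("model has no admissible class for ", side, " candidates")
    votes <- matrix(0, nrow = n, ncol = length(admissible),
                    dimnames = list(NULL, admissible))
    margin <- matrix(0, nrow = n, ncol = length(admissible),
                     dimnames = list(NULL, admissible))
    n_pairs <- 0L
    for (pi in seq_along(pairs)) {
      a <- pairs[[pi]][1]; b <- pairs[[pi]][2]
      if (!(a %in% admissible && b %in% admissible)) next
      n_pairs <- n_pairs + 1L
      d <- dv[, pi]
      votes[, a] <- votes[, a] + (d > 0)
      votes[, b] <- votes[, b] + (d <= 0)
      margin[, a] <- margin[, a] + d
      margin[, b] <- margin[, b] - d
    }
    if (n_pairs == 0L) {  # single admissible class in this model
      label[rows] <- admissible[1]
      next
    }
    for (i in rows) {
      w <- which(votes[i, ] == max(votes[i, ]))
      if (length(w) > 1L) w <- w[which.max(margin[i, w])]
      label[i] <- admissible[w]
      score[i] <- margin[i, w] / max(1L, n_pairs)
    }
  }
  out[, `:=`(label = label, score = score)]
  out[]
}

#' Evaluate the classifier on a labeled test set
#'
#' Standard per-class precision/recall/F1 with macro averaging over classes
#' present in the test truth, plus the 7x7 confusion matrix (rows = truth,
#' columns = predicted).
#'
#' @param bundle a `polish_model`.
#' @param test labeled feature table.
#' @return list of class `classifier_report` with `per_class`, `macro`
#'   (precision/recall/f1) and `confusion`.
#' @export
evaluate_classifier <- function(bundle, test) {
  stopifnot("label" %in% names(test))
  pred <- predict_classes(bundle, test)$label
  lv <- class_labels()
  confusion <- table(truth = factor(test$label, levels = lv),
                     predicted = factor(pred, levels = lv))
  per <- data.table::rbindlist(lapply(lv, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (precision + recall == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.table::data.table(class = cl, support = sum(confusion[cl, ]),
                           precision = precision, recall = recall, f1 = f1)
  }))
  present <- per[per$support > 0]
  macro <- list(precision = mean(present$precision),
                recall = mean(present$recall), f1 = mean(present$f1))
  structure(list(per_class = per, macro = macro, confusion = confusion),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> macro P=%.3f R=%.3f F1=%.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  print(x$per_class)
  invisible(x)
}

#' Save / load a model bundle
#'
#' The bundle (SVM, scaler, schema version, metadata) is written as a single
#' versioned RDS artifact; loading verifies the bundle version. Round-trips
#' are bit-identical.
#'
#' @param bundle a `polish_model`.
#' @param path file path.
#' @return `path` (save) or the `polish_model` (load).
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "polish_model"))
  saveRDS(bundle, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "polish_model") ||
      !identical(bundle$bundle_version, "homologpolish-model-1"))
    stop("not a homologpolish model bundle: ", path)
  bundle
}
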