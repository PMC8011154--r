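#' Synthetic fixture worlds
#'
#' Generates a self-contained, seed-deterministic test world: a truth genome
#' with right-skewed homopolymer run lengths, a set of related strains
#' carrying shared SNPs and occasional true indels, a draft derived from the
#' truth by injecting systematic homopolymer indel errors, and the exact
#' strain-vs-draft and truth-vs-draft alignments implied by the recorded
#' edits. Systematic errors are absent from every strain (the homolog
#' consensus signal); strain variations are carried by small strain subsets,
#' so correction and retention are unambiguously scoreable.
#'
#' @name synthetic_fixtures
NULL

#' Fixture specification
#'
#' @param genome_length truth genome length in bp (default 200000).
#' @param gc GC fraction (default 0.5).
#' @param homopolymer_weight probability that a truth base repeats its
#'   predecessor, enriching homopolymer runs (default 0.15; 0 gives i.i.d.
#'   draws).
#' @param n_strains number of related strains (default 20).
#' @param strain_identity target strain-vs-truth identity (default 0.99).
#' @param strain_indel_events number of shared true-indel variation events
#'   (default 300, half insertions / half deletions).
#' @param error_count systematic errors injected into the draft (default 500).
#' @param error_del_frac fraction of errors that delete a truth base from the
#'   draft, i.e. require an insertion fix (default 0.7; the rest duplicate a
#'   base and require a deletion fix).
#' @param error_hp_bias exponent of the run-length sampling weight for error
#'   sites (default 2; errors concentrate in homopolymers).
#' @param min_gap minimum distance between any two event positions (default
#'   10 bp, so events never interact).
#' @param margin event-free margin at each contig end (default 100 bp).
#' @param contig contig name (default "chr1").
#' @param seed master seed (default 17).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(genome_length = 200000L, gc = 0.5,
                         homopolymer_weight = 0.15, n_strains = 20L,
                         strain_identity = 0.99, strain_indel_events = 300L,
                         error_count = 500L, error_del_frac = 0.7,
                         error_hp_bias = 2, min_gap = 10L, margin = 100L,
                         contig = "chr1", seed = 17L) {
  spec <- list(genome_length = as.integer(genome_length), gc = gc,
               homopolymer_weight = homopolymer_weight,
               n_strains = as.integer(n_strains),
               strain_identity = strain_identity,
               strain_indel_events = as.integer(strain_indel_events),
               error_count = as.integer(error_count),
               error_del_frac = error_del_frac,
               error_hp_bias = error_hp_bias, min_gap = as.integer(min_gap),
               margin = as.integer(margin), contig = contig,
               seed = as.integer(seed))
  stopifnot(spec$genome_length >= 1000L, gc > 0, gc < 1,
            homopolymer_weight >= 0, homopolymer_weight < 1,
            strain_identity >= 0.9, strain_identity <= 1)
  structure(spec, class = "fixture_spec")
}

#' Simulate a truth genome
#'
#' Bases are drawn i.i.d. at the given GC content, except that with
#' probability `homopolymer_weight` a base repeats its predecessor, which
#' lengthens homopolymer runs and produces the right-skewed run-length
#' distribution typical of microbial genomes (most runs shorter than three,
#' very few beyond ten).
#'
#' @param spec a [fixture_spec()].
#' @return named character vector with one truth contig.
#' @export
simulate_truth <- function(spec) {
  with_seed(spec$seed, {
    L <- spec$genome_length
    p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
           G = spec$gc / 2, T = (1 - spec$gc) / 2)
    draw <- sample(BASES, L, replace = TRUE, prob = p)
    if (spec$homopolymer_weight > 0) {
      rep_flag <- runif(L) < spec$homopolymer_weight
      rep_flag[1L] <- FALSE
      anchor <- cumsum(!rep_flag)  # index of the base each position copies
      draw <- draw[!rep_flag][anchor]
    }
    stats::setNames(paste(draw, collapse = ""), spec$contig)
  })
}

# weighted, minimum-gap event placement; deterministic under the caller's RNG
pick_spaced <- function(pool, n, min_gap, prob = NULL,
                        existing = integer(0)) {
  if (n == 0L) return(integer(0))
  cand <- sort(sample(pool, min(length(pool), 6L * n), prob = prob))
  ex <- sort(existing)
  acc <- integer(0)
  last <- -Inf
  for (p in cand) {
    if (p - last < min_gap) next
    if (length(ex)) {
      i <- findInterval(p, ex)
      if (i >= 1L && p - ex[i] < min_gap) next
      if (i < length(ex) && ex[i + 1L] - p < min_gap) next
    }
    acc <- c(acc, p)
    last <- p
  }
  if (length(acc) < n)
    stop("could not place ", n, " events at min_gap ", min_gap,
         "; genome too small or too many events")
  sort(sample(acc, n))
}

#' Inject systematic homopolymer indel errors into a truth genome
#'
#' Samples error sites preferentially inside homopolymer runs (weight
#' `run_length^error_hp_bias`), then either deletes the truth base from the
#' draft (an insertion must be predicted to fix it) or duplicates it (a
#' deletion must be predicted). Emits the exact edit list in truth and draft
#' coordinates — the labeling oracle.
#'
#' @param truth named truth sequence from [simulate_truth()].
#' @param spec a [fixture_spec()].
#' @param avoid truth positions (0-based) events must keep `min_gap` away
#'   from.
#' @return list with `draft` (named sequence) and `errors` (`data.table`:
#'   truth `pos`, `type` (`del`/`dup`), `base`, draft-coordinate `anchor`,
#'   required `class`, required `action`).
#' @export
inject_systematic_errors <- function(truth, spec, avoid = integer(0)) {
  seq <- truth[[1L]]
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  run_len <- rep(r$lengths, r$lengths)
  with_seed(spec$seed + 1L, {
    pool <- (spec$margin):(L - spec$margin - 1L)
    w <- run_len[pool + 1L] ^ spec$error_hp_bias
    pos <- pick_spaced(pool, spec$error_count, spec$min_gap, prob = w,
                       existing = avoid)
    type <- ifelse(runif(length(pos)) < spec$error_del_frac, "del", "dup")
    errors <- data.table::data.table(pos = pos, type = type,
                                     base = chars[pos + 1L])
  })
  if (nrow(errors)) {
    dels <- sort(errors$pos[errors$type == "del"])
    dups <- sort(errors$pos[errors$type == "dup"])
    # draft coordinate of truth base p (kept bases): p + #dup<p - #del<p
    off <- function(p) findInterval(p - 0.5, dups) - findInterval(p - 0.5, dels)
    # del: anchor is the draft position of truth base p+1 (off() already
    # discounts the deleted base); dup: the extra copy sits one past the
    # original's draft position
    errors[, anchor := ifelse(type == "del",
                              pos + 1L + off(pos + 1L),
                              pos + off(pos) + 1L)]
    errors[, `:=`(class = ifelse(type == "del", paste0("INS_", base),
                                 "DELETION"),
                  action = ifelse(type == "del", "insert_before",
                                  "delete_at"))]
  }
  draft <- apply_point_edits(seq, errors[, list(
    pos, text = ifelse(type == "del", "",
                       paste0(base, base)))])
  list(draft = stats::setNames(draft, names(truth)),
       errors = errors[order(pos)])
}

# replace single truth bases: each row consumes the base at pos and emits text
apply_point_edits <- function(seq, edits) {
  if (nrow(edits) == 0L) return(seq)
  edits <- edits[order(pos)]
  L <- nchar(seq)
  starts <- c(0L, edits$pos + 1L)
  ends <- c(edits$pos, L)
  pieces <- substring(seq, starts + 1L, ends)
  paste0(paste0(pieces[-length(pieces)], edits$text, collapse = ""),
         pieces[length(pieces)])
}

#' Simulate related strains
#'
#' Generates shared variation events: SNPs (placed to hit the identity
#' target; shared by a uniform 1..n-1 strain subset) and occasional true
#' indels (shared by small, geometrically distributed subsets — true indels
#' segregate at low frequency under frameshift-purifying selection). Every
#' edit is recorded, so exact alignments are emitted downstream.
#'
#' @param truth named truth sequence.
#' @param spec a [fixture_spec()].
#' @param avoid truth positions to stay clear of (e.g. systematic error
#'   sites).
#' @return list with `strains` (named list of named sequence vectors) and
#'   `variations` (`data.table`: `pos`, `type` (`snp`/`ins`/`del`), `alt`,
#'   `strains` list-column of carrier indices).
#' @export
simulate_strains <- function(truth, spec, avoid = integer(0)) {
  seq <- truth[[1L]]
  L <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- spec$n_strains
  with_seed(spec$seed + 2L, {
    # average SNP sharing is (n-1+1)/2 / n ~ 1/2, so double the event count
    n_snp <- max(0L, round(2 * (1 - spec$strain_identity) * L))
    n_indel <- spec$strain_indel_events
    pool <- (spec$margin):(L - spec$margin - 1L)
    pos <- pick_spaced(pool, n_snp + n_indel, spec$min_gap,
                       existing = avoid)
    idx <- sample(length(pos))  # which positions become SNPs vs indels
    snp_pos <- sort(pos[idx[seq_len(n_snp)]])
    ind_pos <- sort(pos[idx[-seq_len(n_snp)]])
    var_snp <- data.table::data.table(
      pos = snp_pos, type = "snp",
      alt = vapply(chars[snp_pos + 1L], function(b)
        sample(setdiff(BASES, b), 1L), character(1)),
      size = sample(max(1L, n - 1L), length(snp_pos), replace = TRUE))
    ind_type <- sample(c("ins", "del"), length(ind_pos), replace = TRUE)
    ins_len <- 1L + (runif(length(ind_pos)) < 0.1)  # 10% are 2-bp insertions
    var_ind <- data.table::data.table(
      pos = ind_pos, type = ind_type,
      alt = ifelse(ind_type == "ins",
                   vapply(seq_along(ind_pos), function(i)
                     paste(sample(BASES, ins_len[i], replace = TRUE),
                           collapse = ""), character(1)),
                   NA_character_),
      size = pmin(max(1L, n - 1L), 1L + rgeom(length(ind_pos), 0.6)))
    variations <- data.table::rbindlist(list(var_snp, var_ind))
    variations[, strains := lapply(size, function(k) sort(sample(n, k)))]
    variations[, size := NULL]
    data.table::setorder(variations, pos)
    strains <- lapply(seq_len(n), function(j) {
      mine <- variations[vapply(strains, function(s) j %in% s, logical(1))]
      text <- ifelse(mine$type == "snp", mine$alt,
              ifelse(mine$type == "ins", paste0(chars[mine$pos + 1L], mine$alt),
                     ""))
      id <- sprintf("strain%02d", j)
      stats::setNames(apply_point_edits(seq, data.table::data.table(
        pos = mine$pos, text = text)), id)
    })
    names(strains) <- sprintf("strain%02d", seq_len(n))
    list(strains = strains, variations = variations[])
  })
}

# compose the exact strain-vs-draft (or truth-vs-draft) alignment from the
# recorded truth-coordinate edits; draft is the reference
compose_alignment <- function(truth_len, errors, events, homolog_id,
                              contig, segment) {
  ev <- data.table::rbindlist(list(
    if (nrow(errors)) errors[, list(pos, what = paste0("sys", type),
                                    text = base)],
    if (nrow(events)) events[, list(pos, what = type, text = alt)]),
    use.names = TRUE)
  op <- character(0); len <- integer(0)
  push <- function(o, l) { op <<- c(op, o); len <<- c(len, l) }
  last <- 0L
  if (!is.null(ev) && nrow(ev)) {
    data.table::setorder(ev, pos)
    for (i in seq_len(nrow(ev))) {
      p <- ev$pos[i]
      if (p > last) push("=", p - last)
      switch(ev$what[i],
        sysdel = push("I", 1L),
        sysdup = { push("=", 1L); push("D", 1L) },
        snp = push("X", 1L),
        ins = { push("=", 1L); push("I", nchar(ev$text[i])) },
        del = push("D", 1L))
      last <- p + 1L
    }
  }
  if (truth_len > last) push("=", truth_len - last)
  grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
  cigar <- data.table::data.table(op = op, len = len)[,
    list(op = op[1L], len = sum(len)), by = grp][, grp := NULL]
  dlen <- sum(cigar$len[cigar$op %in% REF_CONSUMING])
  homolog_alignment(homolog_id = homolog_id, draft_contig = contig,
                    draft_start = 0L, draft_end = dlen, strand = "+",
                    cigar = cigar, homolog_segment = segment)
}

#' Build a complete fixture bundle
#'
#' Orchestrates [simulate_truth()], [inject_systematic_errors()] and
#' [simulate_strains()], composes the exact strain-vs-draft and
#' truth-vs-draft alignments from the recorded edits, and derives the
#' per-locus truth label table. Optionally writes everything to a directory
#' (`truth.fa`, `draft.fa`, `strains/*.fa`, `alignments.paf`, `labels.tsv`,
#' `spec.json`). Byte-identical for a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @return list with `spec`, `truth`, `draft`, `strains`, `errors`,
#'   `variations`, `alignments` (strain-vs-draft), `truth_alignment`
#'   (truth-vs-draft), and `labels` (`contig`, `pos`, `kind`, `class`).
#' @export
make_fixture_bundle <- function(spec = fixture_spec(), dir = NULL) {
  truth <- simulate_truth(spec)
  inj <- inject_systematic_errors(truth, spec)
  sv <- simulate_strains(truth, spec, avoid = inj$errors$pos)
  L <- spec$genome_length
  none <- data.table::data.table(pos = integer(), type = character(),
                                 alt = character())
  alignments <- lapply(names(sv$strains), function(id) {
    j <- as.integer(sub("strain", "", id))
    mine <- sv$variations[vapply(strains, function(s) j %in% s, logical(1)),
                          list(pos, type, alt)]
    compose_alignment(L, inj$errors, mine, id, spec$contig,
                      sv$strains[[id]][[1L]])
  })
  names(alignments) <- names(sv$strains)
  truth_alignment <- compose_alignment(L, inj$errors, none, "truth",
                                       spec$contig, truth[[1L]])

  # variation loci in draft coordinates (indels only; SNPs make no candidate)
  dels <- sort(inj$errors$pos[inj$errors$type == "del"])
  dups <- sort(inj$errors$pos[inj$errors$type == "dup"])
  off <- function(p) findInterval(p - 0.5, dups) - findInterval(p - 0.5, dels)
  var_ind <- sv$variations[type != "snp"]
  var_loci <- if (nrow(var_ind)) data.table::data.table(
    contig = spec$contig,
    pos = ifelse(var_ind$type == "ins",
                 var_ind$pos + 1L + off(var_ind$pos + 1L),
                 var_ind$pos + off(var_ind$pos)),
    kind = ifelse(var_ind$type == "ins", "insertion", "deletion"),
    class = ifelse(var_ind$type == "ins", "NO_INSERTION", "NO_DELETION"),
    n_carriers = vapply(var_ind$strains, length, integer(1)))
  else data.table::data.table(contig = character(), pos = integer(),
    kind = character(), class = character(), n_carriers = integer())
  err_loci <- data.table::data.table(
    contig = spec$contig, pos = inj$errors$anchor,
    kind = ifelse(inj$errors$type == "del", "insertion", "deletion"),
    class = inj$errors$class,
    n_carriers = spec$n_strains)
  labels <- data.table::rbindlist(list(err_loci, var_loci))
  data.table::setorder(labels, contig, pos, kind)

  bundle <- list(spec = spec, truth = truth, draft = inj$draft,
                 strains = sv$strains, errors = inj$errors,
                 variations = sv$variations, alignments = alignments,
                 truth_alignment = list(truth_alignment), labels = labels)
  if (!is.null(dir)) write_fixture_bundle(bundle, dir)
  bundle
}

write_fixture_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "strains"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(bundle$truth, file.path(dir, "truth.fa"))
  write_fasta(bundle$draft, file.path(dir, "draft.fa"))
  for (id in names(bundle$strains))
    write_fasta(bundle$strains[[id]],
                file.path(dir, "strains", paste0(id, ".fa")))
  write_paf(bundle$alignments, file.path(dir, "alignments.paf"))
  data.table::fwrite(bundle$labels, file.path(dir, "labels.tsv"), sep = "\t")
  jsonlite::write_json(unclass(bundle$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write alignments as PAF with cg tags
#'
#' @param alignments list of [homolog_alignment()] (forward-strand, global).
#' @param path output PAF path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alignments, path) {
  lines <- vapply(alignments, function(a) {
    qlen <- nchar(a$homolog_segment)
    nmatch <- sum(a$cigar$len[a$cigar$op %in% c("=", "M")])
    alen <- sum(a$cigar$len)
    paste(a$homolog_id, qlen, 0L, qlen, a$strand, a$draft_contig,
          a$draft_end, a$draft_start,
          a$draft_end, nmatch, alen, 60L, "tp:A:P",
          paste0("cg:Z:", cigar_string(a$cigar)), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Labeled feature table from a fixture bundle
#'
#' Runs pileup construction, candidate calling, feature extraction and
#' truth labeling for one fixture world. Tables from several bundles can be
#' pooled (rbind) for multi-genome training.
#'
#' @param bundle fixture bundle from [make_fixture_bundle()].
#' @param min_support minimum homolog support per candidate (default 1).
#' @return raw feature `data.table` with a `label` column.
#' @export
featurize_fixture <- function(bundle, min_support = 1L) {
  pile <- build_pileup(bundle$draft, bundle$alignments)
  cand <- call_candidates(pile, min_support = min_support)
  feat <- extract_features(cand, pile)
  feat[, label := label_loci(cand, bundle$draft, bundle$truth_alignment)]
  feat[!is.na(label)]
}

#' Score a polishing run against fixture ground truth
#'
#' Compares the applied edits with the exact edits required to turn the
#' draft back into the truth genome. Because all fixture events are spaced
#' apart, residual errors decompose exactly into unfixed injections plus
#' spurious edits, giving draft-vs-truth Q before and after without any
#' aligner.
#'
#' @param bundle fixture bundle from [make_fixture_bundle()].
#' @param edits applied edit table from [edits_from_predictions()].
#' @return list: `n_injected`, `n_corrected`, `correction_rate` (%),
#'   `n_variation_loci`, `n_variation_altered`, `variation_alteration_rate`
#'   (%), `residual_errors`, `q_before`, `q_after`, `delta_q`.
#' @export
score_against_truth <- function(bundle, edits) {
  required <- bundle$errors[, list(contig = bundle$spec$contig, pos = anchor,
                                   action, base = ifelse(type == "del", base,
                                                         NA_character_))]
  ed <- data.table::as.data.table(edits)
  key_req <- required[, paste(contig, pos, action,
                              data.table::fcoalesce(base, "-"))]
  key_app <- if (nrow(ed)) ed[, paste(contig, pos, action,
                                      data.table::fcoalesce(base, "-"))]
             else character(0)
  n_inj <- nrow(required)
  n_corr <- sum(key_req %in% key_app)
  spurious <- sum(!key_app %in% key_req)
  var_loci <- bundle$labels[grepl("^NO_", class)]
  altered <- if (nrow(ed))
    sum(var_loci[, paste(contig, pos)] %in% ed[, paste(contig, pos)])
  else 0L
  L <- bundle$spec$genome_length
  residual <- (n_inj - n_corr) + spurious
  q_before <- q_from_counts(n_inj, L)
  q_after <- q_from_counts(residual, L)
  list(n_injected = n_inj, n_corrected = n_corr,
       correction_rate = 100 * n_corr / max(1L, n_inj),
       n_variation_loci = nrow(var_loci), n_variation_altered = altered,
       variation_alteration_rate = 100 * altered / max(1L, nrow(var_loci)),
       residual_errors = residual, q_before = q_before, q_after = q_after,
       delta_q = q_after - q_before)
}
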