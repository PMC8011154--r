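#' Applying predicted corrections to the draft
#'
#' Predicted classes become edits: `INS_X` inserts base X immediately before
#' the anchor, `DELETION` removes the draft base at the locus, and the two
#' retain classes produce no edit. Edits are applied per contig so that only
#' systematic errors are corrected while strain variation is retained.
#'
#' @name polisher
NULL

#' Convert per-locus predictions into correction edits
#'
#' @param calls prediction table from [predict_classes()] (meta columns plus
#'   `label`, optionally `score`).
#' @return `data.table` with columns `contig`, `pos`, `action`
#'   (`"insert_before"`/`"delete_at"`), `base` (NA for deletions), `label`,
#'   `score`, sorted by (contig, pos).
#' @export
edits_from_predictions <- function(calls) {
  calls <- data.table::as.data.table(calls)
  if (!"score" %in% names(calls)) calls$score <- NA_real_
  ins <- calls[grepl("^INS_", label)]
  del <- calls[label == "DELETION"]
  edits <- data.table::rbindlist(list(
    if (nrow(ins)) ins[, list(contig, pos, action = "insert_before",
                              base = sub("^INS_", "", label), label, score)],
    if (nrow(del)) del[, list(contig, pos, action = "delete_at",
                              base = NA_character_, label, score)]))
  if (is.null(edits) || nrow(edits) == 0L)
    return(data.table::data.table(contig = character(), pos = integer(),
      action = character(), base = character(), label = character(),
      score = numeric()))
  stopifnot(all(is.na(edits$base) | edits$base %in% BASES))
  dup <- edits[, .N, by = list(contig, pos, action)][N > 1L]
  if (nrow(dup))
    stop("conflicting duplicate edits at ", dup$contig[1], ":", dup$pos[1])
  data.table::setorder(edits, contig, pos, action)
  edits[]
}

#' Apply correction edits to draft sequences
#'
#' Per contig, edits are applied so that coordinates always refer to the
#' original draft: at one anchor a deletion is applied before an insertion
#' (they address independent coordinates: the base versus the gap preceding
#' it). Output length = input length + #inserts - #deletes.
#'
#' @param draft named character vector of sequences.
#' @param edits edit table from [edits_from_predictions()].
#' @return polished named character vector.
#' @export
apply_edits <- function(draft, edits) {
  stopifnot(!is.null(names(draft)))
  if (nrow(edits) == 0L) return(draft)
  unknown <- setdiff(unique(edits$contig), names(draft))
  if (length(unknown)) stop("edit references unknown contig '", unknown[1], "'")
  out <- draft
  for (ctg in unique(edits$contig)) {
    s <- draft[[ctg]]
    L <- nchar(s)
    e <- edits[contig == ctg]
    if (any(e$action == "delete_at" & (e$pos < 0L | e$pos >= L)) ||
        any(e$action == "insert_before" & (e$pos < 0L | e$pos > L)))
      stop("edit out of bounds on ", ctg, ":",
           e$pos[which(e$pos < 0L | e$pos >= L + (e$action != "delete_at"))][1])
    # single left-to-right pass over edit anchors
    data.table::setorder(e, pos, action)  # "delete_at" < "insert_before"
    pieces <- character(0)
    cursor <- 0L  # 0-based next unread draft position
    for (i in seq_len(nrow(e))) {
      p <- e$pos[i]
      if (p > cursor) pieces <- c(pieces, substr(s, cursor + 1L, p))
      if (e$action[i] == "delete_at") {
        cursor <- p + 1L
      } else {
        pieces <- c(pieces, e$base[i])
        cursor <- max(cursor, p)
      }
    }
    if (cursor < L) pieces <- c(pieces, substr(s, cursor + 1L, L))
    out[[ctg]] <- paste(pieces, collapse = "")
  }
  out
}

#' Chop a contig into fixed-size segments
#'
#' Half-open ranges tiling `[0, contig_length)`, all of `segment_bp` except a
#' shorter final one. Features are computed genome-wide before chopping;
#' segments only partition the prediction work.
#'
#' @param contig_length contig length in bp.
#' @param segment_bp segment size (default 10000).
#' @return `data.table` with 0-based half-open `start`, `end`.
#' @export
chop_segments <- function(contig_length, segment_bp = 10000L) {
  stopifnot(segment_bp >= 1, contig_length >= 0)
  if (contig_length == 0L)
    return(data.table::data.table(start = integer(), end = integer()))
  starts <- seq.int(0L, contig_length - 1L, by = segment_bp)
  data.table::data.table(start = starts,
                         end = pmin(starts + segment_bp, contig_length))
}

# predict in parallel over 10-kbp segments; deterministic in thread count
predict_segments <- function(bundle, features, segment_bp = 10000L,
                             threads = 1L) {
  if (nrow(features) == 0L) return(predict_classes(bundle, features))
  seg_of <- features[, paste(contig, pos %/% segment_bp)]
  chunks <- split(seq_len(nrow(features)), seg_of)
  runner <- function(idx) predict_classes(bundle, features[idx])
  calls <- if (threads > 1L)
    parallel::mclapply(chunks, runner, mc.cores = threads)
  else lapply(chunks, runner)
  out <- data.table::rbindlist(calls)
  data.table::setorder(out, contig, pos, kind)
  out[]
}

#' Polish a draft genome with a trained model
#'
#' Full pipeline: sketch and screen the genome database against the draft,
#' select related genomes (identity >= `p`, top `t`), align them onto the
#' draft (external aligner or precomputed PAF/SAM), build the homologous
#' pileup, call and featurize candidate indel loci, predict classes per
#' 10-kbp segment, and apply the resulting edits. Contigs shorter than `k`
#' are passed through unpolished with a warning.
#'
#' @param draft draft FASTA path, or named character vector of sequences.
#' @param genome_db directory of FASTA files, vector of FASTA paths, or named
#'   list of sequence vectors, acting as the related-genome database.
#' @param model a `polish_model` bundle (or path to one).
#' @param p identity threshold, fraction or percent (default 0.95).
#' @param t maximum homolog count (default 20).
#' @param k sketch k-mer length (default 21).
#' @param s sketch size (default 1000).
#' @param seed hash / pipeline seed (default 42).
#' @param threads prediction threads (default 1; results are identical for
#'   any thread count).
#' @param min_support minimum homolog support per candidate (default 1).
#' @param segment_bp prediction segment size (default 10000).
#' @param alignment_mode `"external"` (run the aligner) or `"precomputed"`.
#' @param alignment_path PAF/SAM path when `alignment_mode = "precomputed"`.
#' @param out optional path for the polished FASTA (80-column wrap).
#' @param report_path optional path for the JSON run report.
#' @return list with `polished` (named sequences), `edits`, `calls`,
#'   `screen` (screen table) and `report` (the run-report list).
#' @export
polish_genome <- function(draft, genome_db, model, p = 0.95, t = 20L,
                          k = 21L, s = 1000L, seed = 42L, threads = 1L,
                          min_support = 1L, segment_bp = 10000L,
                          alignment_mode = c("external", "precomputed"),
                          alignment_path = NULL, out = NULL,
                          report_path = NULL) {
  t0 <- Sys.time()
  alignment_mode <- match.arg(alignment_mode)
  if (is.character(model) && length(model) == 1L && file.exists(model))
    model <- load_model(model)
  stopifnot(inherits(model, "polish_model"))
  if (!identical(model$feature_version, feature_schema()$version))
    stop("model bundle feature schema (", model$feature_version,
         ") does not match this package (", feature_schema()$version, ")")

  draft_path <- NULL
  if (is.character(draft) && length(draft) == 1L && file.exists(draft)) {
    draft_path <- draft
    draft <- read_fasta(draft)
  }
  db <- load_genome_db(genome_db)

  # --- screen ---------------------------------------------------------------
  sketches <- lapply(names(db$seqs), function(id)
    build_sketch(db$seqs[[id]], k = k, s = s, seed = seed, genome_id = id))
  screen <- screen_sketches(draft, sketches)
  related <- select_related(screen, p = p, t = t)

  # --- align ----------------------------------------------------------------
  short <- names(draft)[nchar(draft) < k]
  if (length(short))
    warning("contig(s) shorter than k=", k, " passed through unpolished: ",
            paste(short, collapse = ", "))
  if (alignment_mode == "external") {
    if (is.null(draft_path)) {
      draft_path <- tempfile(fileext = ".fa")
      write_fasta(draft, draft_path)
    }
    alns <- acquire_alignments(draft_path, db$paths[related],
                               mode = "external")
  } else {
    stopifnot(!is.null(alignment_path))
    homolog_seqs <- do.call(c, unname(db$seqs))
    first <- readLines(alignment_path, n = 5L)
    is_sam <- any(startsWith(first, "@")) ||
      any(vapply(strsplit(first, "\t"), function(f)
        length(f) >= 11L && !grepl("^[+-]$", f[5]), logical(1)))
    alns <- if (is_sam) read_sam_alignments(alignment_path)
            else read_paf(alignment_path, homolog_seqs)
    allowed <- unlist(lapply(db$seqs[related], names))
    alns <- drop_overlapping_primaries(
      Filter(function(a) a$homolog_id %in% allowed, alns))
  }

  # --- pileup, features, prediction ----------------------------------------
  pileup <- build_pileup(draft, alns)
  candidates <- call_candidates(pileup, min_support = min_support)
  features <- extract_features(candidates, pileup)
  calls <- predict_segments(model, features, segment_bp = segment_bp,
                            threads = threads)
  edits <- edits_from_predictions(calls)
  polished <- apply_edits(draft, edits)

  report <- list(
    tool = "homologpolish", report_version = 1L,
    parameters = list(p = if (p > 1) p / 100 else p, t = t, k = k, s = s,
                      seed = seed, threads = threads,
                      min_support = min_support, segment_bp = segment_bp,
                      C = model$C, gamma = model$gamma),
    screen_hits = nrow(screen), homologs_used = related,
    n_candidates = as.list(table(candidates$kind)),
    n_edits_by_class = as.list(table(edits$label)),
    edits_per_contig = as.list(table(edits$contig)),
    contig_lengths = as.list(nchar(draft)),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out)) write_fasta(polished, out)
  if (!is.null(report_path))
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  list(polished = polished, edits = edits, calls = calls, screen = screen,
       report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# normalize the genome database argument to named sequence sets + FASTA paths
load_genome_db <- function(genome_db) {
  if (is.list(genome_db) && !is.null(names(genome_db)))
    return(list(seqs = genome_db,
                paths = stats::setNames(rep(NA_character_,
                  length(genome_db)), names(genome_db))))
  stopifnot(is.character(genome_db))
  if (length(genome_db) == 1L && dir.exists(genome_db))
    genome_db <- list.files(genome_db, pattern = "\\.(fa|fasta|fna)$",
                            full.names = TRUE)
  if (!length(genome_db)) stop("no related genomes found in the database")
  ids <- sub("\\.(fa|fasta|fna)$", "", basename(genome_db))
  list(seqs = stats::setNames(lapply(genome_db, read_fasta), ids),
       paths = stats::setNames(genome_db, ids))
}
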