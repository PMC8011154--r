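#' Homologous pileup of whole-genome alignments
#'
#' Stacks all homolog-vs-draft alignments into per-position observations over
#' the draft: counts of homologs matching each base, deleting the draft base,
#' or inserting sequence immediately before a position. Candidate indel loci
#' are read off this pileup.
#'
#' @name pileup
NULL

BASES <- c("A", "C", "G", "T")

#' Build a homologous pileup
#'
#' @param draft named character vector of draft sequences.
#' @param alignments list of [homolog_alignment()] records.
#' @return an object of class `homolog_pileup` holding, per contig, coverage
#'   and match-observation vectors plus mismatch / deletion / insertion event
#'   tables, and the alignment span index.
#' @export
build_pileup <- function(draft, alignments) {
  stopifnot(!is.null(names(draft)))
  lens <- nchar(draft)
  acc <- lapply(lens, function(L) list(
    cov_delta = numeric(L + 1L), eq_delta = numeric(L + 1L),
    eq_extra = list(), mism = list(), del = list(), ins = list()))
  spans <- vector("list", length(alignments))
  draft_chars <- lapply(draft, function(s) strsplit(s, "", fixed = TRUE)[[1]])

  for (ai in seq_along(alignments)) {
    a <- alignments[[ai]]
    ctg <- a$draft_contig
    if (!ctg %in% names(draft))
      stop("alignment references unknown contig '", ctg, "'")
    L <- lens[[ctg]]
    if (a$draft_start < 0L || a$draft_end > L)
      stop("alignment out of bounds on ", ctg, ": [", a$draft_start, ",",
           a$draft_end, ") vs length ", L)
    spans[[ai]] <- data.table::data.table(
      homolog = a$homolog_id, contig = ctg,
      start = a$draft_start, end = a$draft_end)
    ops <- a$cigar
    rcons <- ifelse(ops$op %in% REF_CONSUMING, ops$len, 0L)
    qcons <- ifelse(ops$op %in% QRY_CONSUMING, ops$len, 0L)
    rpos <- a$draft_start + cumsum(c(0L, rcons[-length(rcons)]))
    qpos <- cumsum(c(0L, qcons[-length(qcons)]))
    A <- acc[[ctg]]
    A$cov_delta[a$draft_start + 1L] <- A$cov_delta[a$draft_start + 1L] + 1
    A$cov_delta[a$draft_end + 1L] <- A$cov_delta[a$draft_end + 1L] - 1

    eq <- which(ops$op == "=")
    if (length(eq)) {
      st <- rpos[eq] + 1L; en <- rpos[eq] + ops$len[eq] + 1L
      for (j in seq_along(st)) {
        A$eq_delta[st[j]] <- A$eq_delta[st[j]] + 1
        A$eq_delta[en[j]] <- A$eq_delta[en[j]] - 1
      }
    }
    xi <- which(ops$op == "X")
    segchars <- NULL
    if (length(xi)) {
      segchars <- strsplit(a$homolog_segment, "", fixed = TRUE)[[1]]
      p <- rep(rpos[xi], ops$len[xi]) + sequence(ops$len[xi]) - 1L
      q <- rep(qpos[xi], ops$len[xi]) + sequence(ops$len[xi]) - 1L
      A$mism[[length(A$mism) + 1L]] <- data.table::data.table(
        pos = p, base = segchars[q + 1L], homolog = a$homolog_id)
    }
    mi <- which(ops$op == "M")
    if (length(mi)) {
      # M hides match/mismatch: compare segment and draft base-by-base
      if (is.null(segchars))
        segchars <- strsplit(a$homolog_segment, "", fixed = TRUE)[[1]]
      p <- rep(rpos[mi], ops$len[mi]) + sequence(ops$len[mi]) - 1L
      q <- rep(qpos[mi], ops$len[mi]) + sequence(ops$len[mi]) - 1L
      same <- draft_chars[[ctg]][p + 1L] == segchars[q + 1L]
      if (any(same)) A$eq_extra[[length(A$eq_extra) + 1L]] <- p[same]
      if (any(!same)) A$mism[[length(A$mism) + 1L]] <- data.table::data.table(
        pos = p[!same], base = segchars[q[!same] + 1L], homolog = a$homolog_id)
    }
    di <- which(ops$op == "D")
    if (length(di)) {
      p <- rep(rpos[di], ops$len[di]) + sequence(ops$len[di]) - 1L
      A$del[[length(A$del) + 1L]] <- data.table::data.table(
        pos = p, homolog = a$homolog_id)
    }
    ii <- which(ops$op == "I")
    if (length(ii)) {
      A$ins[[length(A$ins) + 1L]] <- data.table::data.table(
        pos = rpos[ii],
        seq = substring(a$homolog_segment, qpos[ii] + 1L, qpos[ii] + ops$len[ii]),
        homolog = a$homolog_id)
    }
    acc[[ctg]] <- A
  }

  contigs <- lapply(names(draft), function(ctg) {
    A <- acc[[ctg]]
    L <- lens[[ctg]]
    eq <- cumsum(A$eq_delta)[seq_len(L)]
    if (length(A$eq_extra)) {
      extra <- unlist(A$eq_extra)
      eq <- eq + tabulate(extra + 1L, nbins = L)
    }
    empty_mism <- data.table::data.table(pos = integer(), base = character(),
                                         homolog = character())
    empty_del <- data.table::data.table(pos = integer(), homolog = character())
    empty_ins <- data.table::data.table(pos = integer(), seq = character(),
                                        homolog = character())
    list(len = L,
         cov = as.integer(cumsum(A$cov_delta)[seq_len(L)]),
         eq = as.integer(eq),
         mism = if (length(A$mism)) data.table::rbindlist(A$mism) else empty_mism,
         del = if (length(A$del)) data.table::rbindlist(A$del) else empty_del,
         ins = if (length(A$ins)) data.table::rbindlist(A$ins) else empty_ins)
  })
  names(contigs) <- names(draft)
  structure(list(contigs = contigs, draft = draft,
                 spans = if (length(spans)) data.table::rbindlist(spans)
                         else data.table::data.table(homolog = character(),
                           contig = character(), start = integer(),
                           end = integer()),
                 n_alignments = length(alignments)),
            class = "homolog_pileup")
}

#' @export
print.homolog_pileup <- function(x, ...) {
  cat(sprintf("<homolog_pileup> %d contigs, %d alignments\n",
              length(x$contigs), x$n_alignments))
  invisible(x)
}

#' Extract one pileup column
#'
#' Assembles the full per-position record: match counts for A/C/G/T,
#' deletion count, anchored insertions, and the set of covering homologs.
#'
#' @param pileup a `homolog_pileup`.
#' @param contig contig name.
#' @param pos 0-based draft position.
#' @return list with fields `contig`, `pos`, `draft_base`, `matches` (named
#'   numeric, A/C/G/T), `deletions`, `insertions_before` (named counts by
#'   inserted string), `covering` (character vector of homolog ids).
#' @export
pileup_column <- function(pileup, contig, pos) {
  pc <- pileup$contigs[[contig]]
  if (is.null(pc)) stop("unknown contig '", contig, "'")
  stopifnot(pos >= 0, pos < pc$len)
  draft_base <- substr(pileup$draft[[contig]], pos + 1L, pos + 1L)
  matches <- stats::setNames(numeric(4), BASES)
  if (draft_base %in% BASES)
    matches[draft_base] <- pc$eq[pos + 1L]
  mi <- which(pc$mism$pos == pos)  # plain indices: `pos` is also a column
  if (length(mi)) {
    tb <- table(pc$mism$base[mi])
    for (b in intersect(names(tb), BASES)) matches[b] <- matches[b] + tb[[b]]
  }
  ii <- which(pc$ins$pos == pos)
  ins <- pc$ins[ii]
  ins_tab <- if (nrow(ins)) {
    tb <- table(ins$seq); stats::setNames(as.numeric(tb), names(tb))
  } else stats::setNames(numeric(0), character(0))
  si <- which(pileup$spans$contig == contig &
              pileup$spans$start <= pos & pileup$spans$end > pos)
  sp <- pileup$spans[si]
  list(contig = contig, pos = pos, draft_base = draft_base,
       matches = matches, deletions = sum(pc$del$pos == pos),
       insertions_before = ins_tab, covering = sp$homolog)
}

#' Call candidate indel loci from a pileup
#'
#' Emits one insertion candidate per anchor where at least `min_support`
#' homologs insert sequence, and one deletion candidate per draft position
#' deleted by at least `min_support` homologs. Candidates anchored on an
#' ambiguous (N) draft base are skipped, as are insertion anchors at the very
#' end of a contig (no base to define homopolymer context).
#'
#' @param pileup a `homolog_pileup`.
#' @param min_support minimum number of supporting homologs (default 1).
#' @return `data.table` with columns `contig`, `pos`, `kind`
#'   (`"insertion"`/`"deletion"`), `allele` (majority inserted first base, or
#'   the draft base for deletions), per-base inserted first-base counts
#'   `iA,iC,iG,iT`, `del_count`, `n_support`, `coverage` and a `supporters`
#'   list-column, ordered by (contig, pos, kind).
#' @export
call_candidates <- function(pileup, min_support = 1L) {
  stopifnot(min_support >= 1)
  res <- list()
  for (ctg in names(pileup$contigs)) {
    pc <- pileup$contigs[[ctg]]
    dchars <- strsplit(pileup$draft[[ctg]], "", fixed = TRUE)[[1]]
    if (nrow(pc$ins)) {
      it <- data.table::copy(pc$ins)
      it[, base := substr(seq, 1L, 1L)]
      ic <- it[, {
        bt <- stats::setNames(numeric(4), BASES)
        tb <- table(base)
        bt[intersect(names(tb), BASES)] <- tb[intersect(names(tb), BASES)]
        list(iA = bt[["A"]], iC = bt[["C"]], iG = bt[["G"]], iT = bt[["T"]],
             n_support = length(unique(homolog)),
             supporters = list(sort(unique(homolog))))
      }, by = pos]
      ic <- ic[n_support >= min_support & pos < pc$len]
      if (nrow(ic)) {
        ic[, allele := BASES[max.col(cbind(iA, iC, iG, iT),
                                     ties.method = "first")]]
        ic[, `:=`(contig = ctg, kind = "insertion", del_count = 0,
                  coverage = pc$cov[pos + 1L])]
        ic <- ic[dchars[pos + 1L] %in% BASES]
        res[[length(res) + 1L]] <- ic
      }
    }
    if (nrow(pc$del)) {
      dc <- pc$del[, list(del_count = as.numeric(length(unique(homolog))),
                          n_support = length(unique(homolog)),
                          supporters = list(sort(unique(homolog)))),
                   by = pos]
      dc <- dc[n_support >= min_support]
      if (nrow(dc)) {
        dc[, `:=`(contig = ctg, kind = "deletion",
                  allele = dchars[pos + 1L],
                  iA = 0, iC = 0, iG = 0, iT = 0,
                  coverage = pc$cov[pos + 1L])]
        dc <- dc[allele %in% BASES]
        res[[length(res) + 1L]] <- dc
      }
    }
  }
  cols <- c("contig", "pos", "kind", "allele", "iA", "iC", "iG", "iT",
            "del_count", "n_support", "coverage", "supporters")
  if (!length(res))
    return(data.table::data.table(contig = character(), pos = integer(),
      kind = character(), allele = character(), iA = numeric(),
      iC = numeric(), iG = numeric(), iT = numeric(), del_count = numeric(),
      n_support = integer(), coverage = integer(), supporters = list()))
  out <- data.table::rbindlist(res, use.names = TRUE)[, cols, with = FALSE]
  data.table::setorder(out, contig, pos, kind)
  out[]
}

#' Dump a pileup to TSV (debugging aid)
#'
#' One row per covered draft position: base, match counts, deletion count,
#' anchored insertions as JSON, coverage.
#'
#' @param pileup a `homolog_pileup`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  rows <- list()
  for (ctg in names(pileup$contigs)) {
    pc <- pileup$contigs[[ctg]]
    covered <- which(pc$cov > 0L) - 1L
    if (!length(covered)) next
    dchars <- strsplit(pileup$draft[[ctg]], "", fixed = TRUE)[[1]]
    cnt <- matrix(0, nrow = pc$len, ncol = 4, dimnames = list(NULL, BASES))
    inb <- dchars %in% BASES
    idx <- which(inb)
    cnt[cbind(idx, match(dchars[idx], BASES))] <- pc$eq[idx]
    if (nrow(pc$mism)) {
      mm <- pc$mism[base %in% BASES, .N, by = list(pos, base)]
      cnt[cbind(mm$pos + 1L, match(mm$base, BASES))] <-
        cnt[cbind(mm$pos + 1L, match(mm$base, BASES))] + mm$N
    }
    delc <- tabulate(pc$del$pos + 1L, nbins = pc$len)
    ins_json <- rep("{}", pc$len)
    if (nrow(pc$ins)) {
      ij <- pc$ins[, list(json = as.character(jsonlite::toJSON(
        as.list(table(seq)), auto_unbox = TRUE))), by = pos]
      ins_json[ij$pos + 1L] <- ij$json
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      contig = ctg, pos = covered, base = dchars[covered + 1L],
      A = cnt[covered + 1L, "A"], C = cnt[covered + 1L, "C"],
      G = cnt[covered + 1L, "G"], T = cnt[covered + 1L, "T"],
      del = delc[covered + 1L], ins_json = ins_json[covered + 1L],
      coverage = pc$cov[covered + 1L])
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}
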