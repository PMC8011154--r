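#' Assembly quality evaluation
#'
#' Counts mismatches, inserted bases and deleted bases from assembly-vs-
#' reference alignments, converts pooled error rates to Phred Q scores
#' (capped at Q90, the sentinel for an error-free alignment), and partitions
#' error loci into coding and non-coding compartments from a BED annotation.
#'
#' @name evaluation
NULL

#' Count alignment errors against a reference
#'
#' Over primary alignments with =/X CIGARs (`--eqx`): mismatches are X bases,
#' insertions are I bases (present in the assembly, absent from the
#' reference), deletions are D bases; `aligned_bases` counts
#' reference-consuming ops. Error loci are recorded in reference coordinates
#' for downstream partitioning.
#'
#' @param alignments list of [homolog_alignment()] records of the assembly
#'   aligned against the reference (reference in the `draft_*` slots), or
#'   `NULL` to run the external aligner.
#' @param assembly,reference named sequence vectors or FASTA paths (used only
#'   when `alignments` is NULL).
#' @return object of class `quality_report`: counts, `avg_q` (pooled),
#'   `median_q` (median of per-contig Q), per-contig breakdown, and an
#'   `error_loci` table (`contig`, `pos`, `type`).
#' @export
count_errors <- function(alignments = NULL, assembly = NULL,
                         reference = NULL) {
  if (is.null(alignments)) {
    stopifnot(!is.null(assembly), !is.null(reference))
    asm_path <- if (is.character(assembly) && length(assembly) == 1L &&
                    file.exists(assembly)) assembly
      else { p <- tempfile(fileext = ".fa"); write_fasta(assembly, p); p }
    ref_path <- if (is.character(reference) && length(reference) == 1L &&
                    file.exists(reference)) reference
      else { p <- tempfile(fileext = ".fa"); write_fasta(reference, p); p }
    alignments <- acquire_alignments(ref_path, asm_path, mode = "external")
  }
  if (length(alignments) == 0L) {
    rep0 <- list(aligned_bases = 0L, mismatches = 0L, insertions = 0L,
                 deletions = 0L, avg_q = NA_real_, median_q = NA_real_,
                 per_contig = data.table::data.table(), unalignable = TRUE,
                 error_loci = data.table::data.table(contig = character(),
                   pos = integer(), type = character()))
    return(structure(rep0, class = "quality_report"))
  }
  per <- list(); loci <- list()
  for (a in alignments) {
    ops <- a$cigar
    rcons <- ifelse(ops$op %in% REF_CONSUMING, ops$len, 0L)
    rpos <- a$draft_start + cumsum(c(0L, rcons[-length(rcons)]))
    xi <- which(ops$op == "X"); di <- which(ops$op == "D")
    ii <- which(ops$op == "I")
    if (length(xi)) loci[[length(loci) + 1L]] <- data.table::data.table(
      contig = a$draft_contig,
      pos = rep(rpos[xi], ops$len[xi]) + sequence(ops$len[xi]) - 1L,
      type = "mismatch")
    if (length(di)) loci[[length(loci) + 1L]] <- data.table::data.table(
      contig = a$draft_contig,
      pos = rep(rpos[di], ops$len[di]) + sequence(ops$len[di]) - 1L,
      type = "deletion")
    if (length(ii)) loci[[length(loci) + 1L]] <- data.table::data.table(
      contig = a$draft_contig, pos = rpos[ii], type = "insertion")
    per[[length(per) + 1L]] <- data.table::data.table(
      contig = a$draft_contig,
      aligned = sum(ops$len[ops$op %in% REF_CONSUMING]),
      mismatches = sum(ops$len[ops$op == "X"]),
      insertions = sum(ops$len[ops$op == "I"]),
      deletions = sum(ops$len[ops$op == "D"]))
  }
  per <- data.table::rbindlist(per)[, lapply(.SD, sum), by = contig]
  per[, q := q_from_counts(mismatches + insertions + deletions, aligned),
      by = contig]
  tot <- per[, lapply(.SD, sum), .SDcols = c("aligned", "mismatches",
                                             "insertions", "deletions")]
  structure(list(
    aligned_bases = tot$aligned, mismatches = tot$mismatches,
    insertions = tot$insertions, deletions = tot$deletions,
    avg_q = q_from_counts(tot$mismatches + tot$insertions + tot$deletions,
                          tot$aligned),
    median_q = stats::median(per$q),
    per_contig = per[], unalignable = FALSE,
    error_loci = if (length(loci)) {
      l <- data.table::rbindlist(loci); data.table::setorder(l, contig, pos)
      l[]
    } else data.table::data.table(contig = character(), pos = integer(),
                                  type = character())),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("<quality_report> aligned=%d mism=%d ins=%d del=%d ",
                     "avgQ=%.2f medianQ=%.2f\n"),
              x$aligned_bases, x$mismatches, x$insertions, x$deletions,
              x$avg_q, x$median_q))
  invisible(x)
}

#' Phred Q score from error counts
#'
#' `Q = -10 log10(errors / aligned_bases)`, capped at 90; zero errors map to
#' the Q90 cap (the sentinel for an error-free alignment).
#'
#' @param errors total error count (mismatches + inserted + deleted bases).
#' @param aligned_bases reference bases aligned (> 0).
#' @return Q score in `[0, 90]`.
#' @export
q_from_counts <- function(errors, aligned_bases) {
  if (any(aligned_bases <= 0)) stop("aligned_bases must be positive")
  stopifnot(all(errors >= 0))
  ifelse(errors == 0, 90, pmin(90, -10 * log10(errors / aligned_bases)))
}

#' Read a BED file of coding intervals
#'
#' Tolerates 3- and 6-column forms; intervals are 0-based, half-open.
#'
#' @param path BED path.
#' @return `data.table` with `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  out <- bed[, 1:3]
  data.table::setnames(out, c("contig", "start", "end"))
  out[, `:=`(start = as.integer(start), end = as.integer(end))]
  stopifnot(all(out$end >= out$start))
  out[]
}

#' Partition error loci into coding and non-coding compartments
#'
#' An error locus is coding when it intersects any annotated interval.
#'
#' @param error_loci `data.table` with `contig`, `pos` (reference coords).
#' @param bed coding intervals from [read_bed()] (0-based half-open).
#' @return list with `coding`, `noncoding` counts and the per-locus flags.
#' @export
partition_errors <- function(error_loci, bed) {
  loci <- data.table::as.data.table(error_loci)
  if (nrow(loci) == 0L)
    return(list(coding = 0L, noncoding = 0L,
                flags = logical(0)))
  flags <- logical(nrow(loci))
  for (ctg in unique(loci$contig)) {
    li <- which(loci$contig == ctg)
    b <- bed[bed$contig == ctg]
    if (nrow(b) == 0L) next
    q <- IRanges::IRanges(start = loci$pos[li] + 1L, width = 1L)
    s <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    flags[li] <- IRanges::overlapsAny(q, s)
  }
  list(coding = sum(flags), noncoding = sum(!flags), flags = flags)
}

#' Correction ratio
#'
#' Percentage of errors removed: `100 * (before - after) / before`, rounded
#' half-up to 2 decimals (the convention of reported percentages, e.g.
#' 88.125 prints as 88.13). Undefined (NA) when `before` is 0.
#'
#' @param before,after error counts before and after polishing.
#' @return percentage (may be negative if errors were added), or NA.
#' @export
correction_ratio <- function(before, after) {
  pct <- 100 * (before - after) / before
  ifelse(before == 0, NA_real_, floor(pct * 100 + 0.5) / 100)
}

#' Coding / non-coding error partition report
#'
#' Compares error loci before and after polishing within and outside coding
#' regions, with per-compartment correction ratios.
#'
#' @param before_loci,after_loci error-locus tables (`contig`, `pos`).
#' @param bed coding intervals from [read_bed()].
#' @return list of class `partition_report`.
#' @export
partition_report <- function(before_loci, after_loci, bed) {
  pb <- partition_errors(before_loci, bed)
  pa <- partition_errors(after_loci, bed)
  structure(list(
    coding_before = pb$coding, coding_after = pa$coding,
    coding_ratio = correction_ratio(pb$coding, pa$coding),
    noncoding_before = pb$noncoding, noncoding_after = pa$noncoding,
    noncoding_ratio = correction_ratio(pb$noncoding, pa$noncoding)),
    class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf("<partition_report> coding %d -> %d (%.2f%%), noncoding %d -> %d (%.2f%%)\n",
              x$coding_before, x$coding_after, x$coding_ratio,
              x$noncoding_before, x$noncoding_after, x$noncoding_ratio))
  invisible(x)
}
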