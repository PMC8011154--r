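#' Whole-genome alignments of homologs against a draft
#'
#' A `homolog_alignment` records one primary alignment of a related genome
#' (the homolog) against the draft: draft interval (0-based, half-open),
#' original strand, CIGAR, and the aligned homolog subsequence already
#' projected onto the draft forward strand. All downstream pileup code works
#' in draft forward coordinates only.
#'
#' @name alignments
NULL

CIGAR_OPS <- c("M", "=", "X", "I", "D")
REF_CONSUMING <- c("M", "=", "X", "D")
QRY_CONSUMING <- c("M", "=", "X", "I")

#' Parse a CIGAR string into an op/length table
#'
#' @param cigar CIGAR string over ops M,=,X,I,D (S/H clips allowed when
#'   `allow_clips`).
#' @param allow_clips keep soft/hard clip ops in the output (SAM reader trims
#'   them itself).
#' @return `data.table` with columns `op`, `len`.
#' @export
parse_cigar <- function(cigar, allow_clips = FALSE) {
  m <- gregexpr("\\d+[A-Z=]", cigar)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("unparseable CIGAR string: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1]]
  op <- substring(toks, nchar(toks), nchar(toks))
  ok <- c(CIGAR_OPS, if (allow_clips) c("S", "H"))
  bad <- setdiff(unique(op), ok)
  if (length(bad))
    stop("unsupported CIGAR op '", bad[1], "' in: ", cigar)
  data.table::data.table(op = op,
                         len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigar_string <- function(ops) paste0(ops$len, ops$op, collapse = "")

#' Construct a homolog-vs-draft alignment record
#'
#' @param homolog_id homolog identifier.
#' @param draft_contig draft contig name.
#' @param draft_start,draft_end 0-based half-open draft interval.
#' @param strand original mapping strand, `"+"` or `"-"`.
#' @param cigar op/length table (or CIGAR string) over M,=,X,I,D.
#' @param homolog_segment aligned homolog subsequence, projected to the draft
#'   forward strand.
#' @return object of class `homolog_alignment`.
#' @export
homolog_alignment <- function(homolog_id, draft_contig, draft_start, draft_end,
                              strand, cigar, homolog_segment) {
  if (is.character(cigar)) cigar <- parse_cigar(cigar)
  ref_len <- sum(cigar$len[cigar$op %in% REF_CONSUMING])
  qry_len <- sum(cigar$len[cigar$op %in% QRY_CONSUMING])
  if (ref_len != draft_end - draft_start)
    stop("cigar reference span (", ref_len, ") != draft interval (",
         draft_end - draft_start, ") for ", homolog_id)
  if (qry_len != nchar(homolog_segment))
    stop("cigar query span (", qry_len, ") != homolog segment length (",
         nchar(homolog_segment), ") for ", homolog_id)
  structure(list(homolog_id = homolog_id, draft_contig = draft_contig,
                 draft_start = as.integer(draft_start),
                 draft_end = as.integer(draft_end), strand = strand,
                 cigar = cigar, homolog_segment = homolog_segment),
            class = "homolog_alignment")
}

#' @export
print.homolog_alignment <- function(x, ...) {
  cat(sprintf("<homolog_alignment> %s -> %s:[%d,%d) %s  %d ops\n",
              x$homolog_id, x$draft_contig, x$draft_start, x$draft_end,
              x$strand, nrow(x$cigar)))
  invisible(x)
}

#' Read homolog alignments from a PAF file
#'
#' Requires the `cg:Z` CIGAR tag (minimap2 `-c`; `--eqx` recommended so ops
#' are =/X rather than M). Secondary alignments (`tp:A:S`) are dropped. For
#' minus-strand records the query segment is reverse-complemented so that the
#' stored segment reads along the draft forward strand; PAF `cg` ops are
#' already in target-forward order.
#'
#' @param path PAF file path.
#' @param homolog_seqs named character vector with the full homolog sequences
#'   (needed to extract aligned segments; PAF carries no sequence).
#' @return list of `homolog_alignment`.
#' @export
read_paf <- function(path, homolog_seqs) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12L)
      stop("PAF record on line ", i, " has fewer than 12 fields")
    tags <- f[-(1:12)]
    tp <- grep("^tp:A:", tags, value = TRUE)
    if (length(tp) && substring(tp[1], 6) == "S") next  # secondary
    cg <- grep("^cg:Z:", tags, value = TRUE)
    if (!length(cg))
      stop("PAF record on line ", i, " lacks the cg:Z CIGAR tag ",
           "(run the aligner with -c)")
    qname <- f[1]; qstart <- as.integer(f[3]); qend <- as.integer(f[4])
    strand <- f[5]
    if (!qname %in% names(homolog_seqs))
      stop("PAF query '", qname, "' not found in supplied homolog sequences")
    seg <- substr(homolog_seqs[[qname]], qstart + 1L, qend)
    if (strand == "-") seg <- revcomp(seg)
    cigar <- tryCatch(parse_cigar(substring(cg[1], 6)),
                      error = function(e)
                        stop("line ", i, ": ", conditionMessage(e)))
    out[[length(out) + 1L]] <- homolog_alignment(
      homolog_id = qname, draft_contig = f[6],
      draft_start = as.integer(f[8]), draft_end = as.integer(f[9]),
      strand = strand, cigar = cigar, homolog_segment = seg)
  }
  out
}

#' Read homolog alignments from a SAM file
#'
#' Plain-text SAM reader. Unmapped (0x4), secondary (0x100) and supplementary
#' (0x800) records are dropped. The SAM SEQ field is already stored in
#' reference (draft) forward orientation, so for reverse-strand hits the
#' segment equals the reverse complement of the homolog's own sequence; soft
#' clips are trimmed from the segment, hard clips ignored.
#'
#' @param path SAM file path.
#' @return list of `homolog_alignment`.
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("SAM record on line ", i, " has fewer than 11 fields")
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4L) > 0L) next
    if (bitwAnd(flag, 0x100L) > 0L || bitwAnd(flag, 0x800L) > 0L) next
    cigar <- tryCatch(parse_cigar(f[6], allow_clips = TRUE),
                      error = function(e)
                        stop("line ", i, ": ", conditionMessage(e)))
    seq <- toupper(f[10])
    # trim soft clips off the segment, drop clip ops from the cigar
    nops <- nrow(cigar)
    lead <- if (cigar$op[1] == "S") cigar$len[1] else 0L
    trail <- if (cigar$op[nops] == "S") cigar$len[nops] else 0L
    if (lead || trail) seq <- substr(seq, lead + 1L, nchar(seq) - trail)
    cigar <- cigar[!op %in% c("S", "H")]
    pos0 <- as.integer(f[4]) - 1L  # SAM POS is 1-based
    ref_span <- sum(cigar$len[cigar$op %in% REF_CONSUMING])
    out[[length(out) + 1L]] <- homolog_alignment(
      homolog_id = f[1], draft_contig = f[3],
      draft_start = pos0, draft_end = pos0 + ref_span,
      strand = if (bitwAnd(flag, 0x10L) > 0L) "-" else "+",
      cigar = cigar, homolog_segment = seq)
  }
  out
}

#' Acquire homolog-vs-draft alignments
#'
#' In `external` mode the configured aligner (default `minimap2` with an
#' assembly-to-assembly preset and `--eqx` CIGARs) is invoked per homolog; in
#' `precomputed` mode a user-supplied PAF (with `cg` tag) or SAM is parsed.
#' When one homolog yields several primary alignments overlapping on the same
#' draft region, the longest is kept.
#'
#' @param draft_path draft FASTA path.
#' @param homolog_paths FASTA paths of the homolog genomes.
#' @param mode `"external"` or `"precomputed"`.
#' @param alignment_path PAF or SAM path (precomputed mode).
#' @param aligner_cmd command template with `{draft}`, `{homolog}` and
#'   `{preset}` placeholders.
#' @param preset aligner preset name (default `"asm5"`).
#' @return list of `homolog_alignment`.
#' @export
acquire_alignments <- function(draft_path, homolog_paths,
                               mode = c("external", "precomputed"),
                               alignment_path = NULL,
                               aligner_cmd = "minimap2 -c --eqx -x {preset} {draft} {homolog}",
                               preset = "asm5") {
  mode <- match.arg(mode)
  homolog_seqs <- unlist(lapply(homolog_paths, read_fasta))
  if (mode == "precomputed") {
    stopifnot(!is.null(alignment_path))
    first <- readLines(alignment_path, n = 50L)
    is_sam <- any(startsWith(first, "@")) ||
      any(vapply(strsplit(first, "\t"), function(f)
        length(f) >= 11L && grepl("^\\d+$", f[2]) && grepl("^\\d+$", f[4]) &&
          !grepl("^[+-]$", f[5]), logical(1)))
    alns <- if (is_sam) read_sam_alignments(alignment_path)
            else read_paf(alignment_path, homolog_seqs)
  } else {
    alns <- list()
    for (hp in homolog_paths) {
      cmd <- gsub("{draft}", shQuote(draft_path),
             gsub("{homolog}", shQuote(hp),
             gsub("{preset}", preset, aligner_cmd, fixed = TRUE),
             fixed = TRUE), fixed = TRUE)
      paf <- tempfile(fileext = ".paf")
      status <- system(paste(cmd, ">", shQuote(paf)), ignore.stderr = TRUE)
      if (status != 0L) stop("aligner failed (exit ", status, "): ", cmd)
      alns <- c(alns, read_paf(paf, unlist(lapply(hp, read_fasta))))
      unlink(paf)
    }
  }
  drop_overlapping_primaries(alns)
}

# per homolog+contig, keep the longest alignment among mutually overlapping
# primaries (deterministic: length desc, then start asc)
drop_overlapping_primaries <- function(alns) {
  if (length(alns) <= 1L) return(alns)
  key <- vapply(alns, function(a)
    paste(a$homolog_id, a$draft_contig, sep = "\r"), character(1))
  keep <- logical(length(alns))
  for (grp in split(seq_along(alns), key)) {
    lens <- vapply(alns[grp], function(a) a$draft_end - a$draft_start, integer(1))
    starts <- vapply(alns[grp], `[[`, integer(1), "draft_start")
    ord <- grp[order(-lens, starts)]
    kept <- list()
    for (i in ord) {
      a <- alns[[i]]
      clash <- any(vapply(kept, function(b)
        a$draft_start < b$draft_end && b$draft_start < a$draft_end, logical(1)))
      if (!clash) { kept[[length(kept) + 1L]] <- a; keep[i] <- TRUE }
    }
  }
  alns[keep]
}
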