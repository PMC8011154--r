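#' Feature encoding of candidate indel loci
#'
#' Each candidate locus is encoded as twelve features spanning 21 numeric
#' dimensions: matched allele counts of A,T,C,G; inserted allele counts of
#' A,T,C,G; the deletion allele count; homologous coverage (ten count
#' dimensions, min-max normalized into \[0,1\]); the homopolymer length of the
#' flanking run, one-hot encoded into ten categories {1,...,9,>=10}; and a
#' three-valued paired-ambiguity code (0 unpaired, 1 major allele of a pair,
#' 2 minor allele).
#'
#' @name features
NULL

SCALED_DIMS <- c("m_A", "m_T", "m_C", "m_G",
                 "i_A", "i_T", "i_C", "i_G", "del", "cov")
HP_DIMS <- c(paste0("hp_", 1:9), "hp_ge10")
FEATURE_DIMS <- c(SCALED_DIMS, HP_DIMS, "amb")
META_COLS <- c("contig", "pos", "kind", "allele")

#' Feature schema
#'
#' @return list with the schema `version` and the 21 feature dimension names
#'   in canonical order.
#' @export
feature_schema <- function() {
  list(version = "hfv1", dims = FEATURE_DIMS)
}

#' Homopolymer length flanking a candidate locus
#'
#' For an insertion candidate the length of the run of the inserted base
#' immediately adjacent to the anchor (the longer of the run ending just
#' before the anchor and the run starting at it; 1 if neither neighbour
#' matches the allele). For a deletion candidate the length of the run
#' containing the draft base.
#'
#' @param draft one draft sequence (character scalar).
#' @param pos 0-based anchor position.
#' @param kind `"insertion"` or `"deletion"`.
#' @param allele inserted base (insertion candidates).
#' @return integer run length >= 1.
#' @export
homopolymer_length <- function(draft, pos, kind, allele = NULL) {
  chars <- strsplit(draft, "", fixed = TRUE)[[1]]
  stopifnot(pos >= 0, pos < length(chars))
  r <- rle(chars)
  run_len <- rep(r$lengths, r$lengths)
  if (kind == "deletion") return(run_len[pos + 1L])
  stopifnot(allele %in% BASES)
  best <- 1L
  if (chars[pos + 1L] == allele) best <- max(best, run_len[pos + 1L])
  if (pos > 0L && chars[pos] == allele) best <- max(best, run_len[pos])
  best
}

#' One-hot encode a homopolymer length
#'
#' Ten categories {1, 2, ..., 9, >=10}: lengths 1..9 map to slots 1..9, any
#' length of 10 or more to slot 10.
#'
#' @param length integer homopolymer length >= 1 (vectorized).
#' @return for scalar input a named 10-dim 0/1 vector; for vector input a
#'   matrix with one row per length.
#' @export
encode_homopolymer <- function(length) {
  if (any(length < 1)) stop("homopolymer length must be >= 1")
  slot <- pmin(as.integer(length), 10L)
  m <- matrix(0, nrow = length(slot), ncol = 10L,
              dimnames = list(NULL, HP_DIMS))
  m[cbind(seq_along(slot), slot)] <- 1
  if (length(slot) == 1L) m[1L, ] else m
}

#' Detect paired ambiguous loci and assign ambiguity codes
#'
#' Scans same-contig candidates within `window` bp of each other for pairs
#' whose supporter sets are mutually exclusive and jointly account for at
#' least `min_frac` of the homologs covering both loci. Such pairs arise when
#' major and minor alleles of a strain variation align equally well against
#' the draft at two nearby anchors. In a qualifying pair the majority locus
#' is coded 1 and the minority locus 2; all other loci are coded 0. Pairing
#' is greedy, leftmost-first, nearest-partner, each locus in at most one pair.
#'
#' @param candidates candidate table from [call_candidates()].
#' @param pileup the `homolog_pileup` (for covering sets).
#' @param window maximum pair distance in bp (default 100).
#' @param min_frac minimum fraction of shared coverage jointly explained
#'   (default 0.8).
#' @return integer vector of codes in {0,1,2}, one per candidate row.
#' @export
detect_paired_ambiguity <- function(candidates, pileup, window = 100L,
                                    min_frac = 0.8) {
  n <- nrow(candidates)
  code <- integer(n)
  if (n < 2L) return(code)
  covering <- vector("list", n)
  for (ctg in unique(candidates$contig)) {
    idx <- which(candidates$contig == ctg)
    sp <- pileup$spans[pileup$spans$contig == ctg]
    for (i in idx)
      covering[[i]] <- sp$homolog[sp$start <= candidates$pos[i] &
                                  sp$end > candidates$pos[i]]
  }
  paired <- logical(n)
  ord <- order(candidates$contig, candidates$pos)
  for (oi in seq_len(n)) {
    i <- ord[oi]
    if (paired[i]) next
    best_j <- NA_integer_; best_d <- Inf
    for (oj in seq_len(n - oi) + oi) {
      j <- ord[oj]
      if (candidates$contig[j] != candidates$contig[i]) break
      d <- candidates$pos[j] - candidates$pos[i]
      if (d > window) break
      if (paired[j] || d >= best_d) next
      si <- candidates$supporters[[i]]; sj <- candidates$supporters[[j]]
      if (length(intersect(si, sj))) next
      shared_cov <- length(intersect(covering[[i]], covering[[j]]))
      if (shared_cov == 0L) next
      if (length(union(si, sj)) < min_frac * shared_cov) next
      best_j <- j; best_d <- d
    }
    if (!is.na(best_j)) {
      paired[i] <- paired[best_j] <- TRUE
      ni <- length(candidates$supporters[[i]])
      nj <- length(candidates$supporters[[best_j]])
      if (ni >= nj) { code[i] <- 1L; code[best_j] <- 2L }
      else          { code[i] <- 2L; code[best_j] <- 1L }
    }
  }
  code
}

#' Extract raw (unscaled) feature vectors for candidate loci
#'
#' Builds the full 21-dimension encoding for every candidate: matched and
#' inserted allele counts, deletion count and coverage as raw counts (scaled
#' later by the fitted min-max scaler), the homopolymer one-hot, and the
#' paired-ambiguity code.
#'
#' @param candidates candidate table from [call_candidates()].
#' @param pileup the `homolog_pileup` the candidates came from.
#' @param window ambiguity pairing window in bp (default 100).
#' @param min_frac ambiguity pairing coverage fraction (default 0.8).
#' @return `data.table` with meta columns (`contig`, `pos`, `kind`, `allele`)
#'   followed by the 21 numeric feature columns of [feature_schema()].
#' @export
extract_features <- function(candidates, pileup, window = 100L,
                             min_frac = 0.8) {
  cand <- data.table::as.data.table(candidates)
  empty <- data.table::as.data.table(
    stats::setNames(rep(list(numeric(0)), length(FEATURE_DIMS)), FEATURE_DIMS))
  if (nrow(cand) == 0L)
    return(cbind(data.table::data.table(contig = character(), pos = integer(),
      kind = character(), allele = character()), empty))
  mA <- mT <- mC <- mG <- numeric(nrow(cand))
  hp <- integer(nrow(cand))
  for (ctg in unique(cand$contig)) {
    idx <- which(cand$contig == ctg)
    pc <- pileup$contigs[[ctg]]
    chars <- strsplit(pileup$draft[[ctg]], "", fixed = TRUE)[[1]]
    r <- rle(chars)
    run_len <- rep(r$lengths, r$lengths)
    p <- cand$pos[idx]
    db <- chars[p + 1L]
    eqc <- pc$eq[p + 1L]
    mm <- if (nrow(pc$mism)) pc$mism[base %in% BASES, .N, by = list(pos, base)]
          else NULL
    for (b in BASES) {
      v <- eqc * (db == b)
      if (!is.null(mm) && nrow(mm)) {
        mb <- mm[base == b]
        add <- mb$N[match(p, mb$pos)]
        add[is.na(add)] <- 0L
        v <- v + add
      }
      switch(b, A = mA[idx] <- v, T = mT[idx] <- v,
                C = mC[idx] <- v, G = mG[idx] <- v)
    }
    # homopolymer context
    is_del <- cand$kind[idx] == "deletion"
    h <- rep(1L, length(idx))
    h[is_del] <- run_len[p[is_del] + 1L]
    ii <- which(!is_del)
    if (length(ii)) {
      al <- cand$allele[idx][ii]
      right <- ifelse(db[ii] == al, run_len[p[ii] + 1L], 1L)
      left <- ifelse(p[ii] > 0L & chars[pmax(p[ii], 1L)] == al,
                     run_len[pmax(p[ii], 1L)], 1L)
      h[ii] <- pmax(right, left)
    }
    hp[idx] <- h
  }
  amb <- detect_paired_ambiguity(cand, pileup, window = window,
                                 min_frac = min_frac)
  out <- data.table::data.table(
    contig = cand$contig, pos = cand$pos, kind = cand$kind,
    allele = cand$allele,
    m_A = mA, m_T = mT, m_C = mC, m_G = mG,
    i_A = cand$iA, i_T = cand$iT, i_C = cand$iC, i_G = cand$iG,
    del = cand$del_count, cov = as.numeric(cand$coverage))
  hpm <- encode_homopolymer(hp)
  if (is.null(dim(hpm)))
    hpm <- matrix(hpm, nrow = 1L, dimnames = list(NULL, names(hpm)))
  out <- cbind(out, data.table::as.data.table(hpm))
  out[, amb := as.numeric(amb)]
  data.table::setattr(out, "feature_version", feature_schema()$version)
  out[]
}

#' Fit a min-max scaler on training feature vectors
#'
#' Per-dimension minima and maxima over the ten count/coverage dimensions.
#' One-hot and ambiguity dimensions are left untouched by scaling.
#'
#' @param features raw feature table from [extract_features()] (>= 2 rows).
#' @return object of class `minmax_scaler`.
#' @export
fit_scaler <- function(features) {
  stopifnot(nrow(features) >= 2L)
  m <- as.matrix(features[, SCALED_DIMS, with = FALSE])
  structure(list(dims = SCALED_DIMS,
                 min = apply(m, 2, min), max = apply(m, 2, max)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Maps each scaled dimension through `(x - min) / (max - min)` and clamps
#' into \[0, 1\]; dimensions constant in training map to 0.
#'
#' @param features raw feature table.
#' @param scaler a fitted `minmax_scaler`.
#' @return copy of `features` with scaled count dimensions.
#' @export
apply_scaler <- function(features, scaler) {
  if (!inherits(scaler, "minmax_scaler"))
    stop("scaler is not a fitted minmax_scaler")
  out <- data.table::copy(data.table::as.data.table(features))
  for (d in scaler$dims) {
    rng <- scaler$max[[d]] - scaler$min[[d]]
    v <- if (rng == 0) rep(0, nrow(out))
         else pmin(1, pmax(0, (out[[d]] - scaler$min[[d]]) / rng))
    data.table::set(out, j = d, value = v)
  }
  out[]
}

#' Write / read a feature table TSV
#'
#' Meta columns plus the 21 numeric feature columns with stable header names.
#'
#' @param features feature table.
#' @param path TSV path.
#' @return `path` (writer) or the feature `data.table` (reader).
#' @export
write_feature_tsv <- function(features, path) {
  keep <- c(META_COLS, if ("label" %in% names(features)) "label", FEATURE_DIMS)
  data.table::fwrite(features[, keep, with = FALSE], path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  ft <- data.table::fread(path, sep = "\t")
  missing <- setdiff(c(META_COLS, FEATURE_DIMS), names(ft))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  data.table::setattr(ft, "feature_version", feature_schema()$version)
  ft[]
}
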