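#' MinHash sketching and containment screening
#'
#' A genome is reduced to the `s` smallest 53-bit hash values over its
#' canonical k-mers (the lexicographic minimum of each k-mer and its reverse
#' complement). Screening a sketch against the full k-mer hash set of a draft
#' genome yields a containment index from which average nucleotide identity is
#' estimated under a Poisson model of k-mer survival. This is the fast
#' pre-filter that picks the closely related genomes used for polishing.
#'
#' @name sketching
NULL

#' Full canonical k-mer hash set of one or more sequences
#'
#' @param sequences character vector of nucleotide sequences.
#' @param k k-mer length (1..31 recommended; any k >= 1 accepted).
#' @param seed hash seed.
#' @return sorted numeric vector of distinct canonical k-mer hashes.
#' @export
kmer_hash_set <- function(sequences, k = 21L, seed = 42L) {
  stopifnot(k >= 1, length(sequences) >= 1)
  hs <- lapply(toupper(sequences), kmer_hash_set_cpp, k = as.integer(k),
               seed = as.numeric(seed))
  sort(unique(unlist(hs)))
}

#' Build a MinHash sketch of a genome
#'
#' Returns the `s` smallest distinct canonical k-mer hashes. K-mers containing
#' non-ACGT characters are skipped. Genomes with fewer than `s` distinct valid
#' canonical k-mers yield a shorter sketch; the containment denominator is
#' always the actual sketch length.
#'
#' @param sequences character vector of nucleotide sequences (one genome).
#' @param k k-mer length (default 21).
#' @param s target sketch size (default 1000).
#' @param seed hash seed (default 42).
#' @param genome_id identifier stored in the sketch.
#' @return an object of class `kmer_sketch` with fields `genome_id`, `k`, `s`,
#'   `seed`, `hashes` (strictly increasing, length <= s).
#' @export
build_sketch <- function(sequences, k = 21L, s = 1000L, seed = 42L,
                         genome_id = "genome") {
  stopifnot(s >= 1)
  if (length(sequences) == 0L || all(!nzchar(sequences)))
    stop("no valid k-mers: empty sequence set")
  hashes <- kmer_hash_set(sequences, k = k, seed = seed)
  if (length(hashes) == 0L)
    stop("no valid k-mers: input shorter than k or all-ambiguous (N) bases")
  structure(
    list(genome_id = genome_id, k = as.integer(k), s = as.integer(s),
         seed = as.numeric(seed), hashes = head(hashes, s)),
    class = "kmer_sketch"
  )
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("<kmer_sketch> %s  k=%d  |hashes|=%d/%d  seed=%s\n",
              x$genome_id, x$k, length(x$hashes), x$s,
              format(x$seed)))
  invisible(x)
}

#' Estimate sequence identity from a containment index
#'
#' Under a Poisson model where each of the k bases of a k-mer independently
#' survives mutation with probability equal to the identity `a`, the expected
#' containment is `a^k`, so `a = exp(log(c)/k)`; the commonly used first-order
#' form `1 + log(c)/k` is adopted (clamped at 0).
#'
#' @param containment containment index in `[0, 1]`.
#' @param k k-mer length.
#' @return estimated identity in `[0, 1]`; 0 when containment is 0.
#' @export
estimate_identity <- function(containment, k) {
  stopifnot(all(containment >= 0), all(containment <= 1), k >= 1)
  ifelse(containment == 0, 0, pmax(0, 1 + log(containment) / k))
}

#' Estimate identity from a Jaccard index (sketch-vs-sketch)
#'
#' Mash-distance style estimator for symmetric sketch comparison:
#' `D = -(1/k) * log(2J/(1+J))`, identity `= 1 - D`, clamped to `[0, 1]`.
#'
#' @param jaccard Jaccard index in `[0, 1]`.
#' @param k k-mer length.
#' @return estimated identity in `[0, 1]`.
#' @export
mash_identity <- function(jaccard, k) {
  stopifnot(all(jaccard >= 0), all(jaccard <= 1), k >= 1)
  ifelse(jaccard == 0, 0,
         pmin(1, pmax(0, 1 + log(2 * jaccard / (1 + jaccard)) / k)))
}

#' Jaccard index between two sketches
#'
#' Computed on the merged bottom-s sketch (s = min of the two sketch sizes),
#' the standard MinHash estimator of the true k-mer Jaccard index.
#'
#' @param a,b `kmer_sketch` objects sharing `k` and `seed`.
#' @return estimated Jaccard index in `[0, 1]`.
#' @export
sketch_jaccard <- function(a, b) {
  stopifnot(inherits(a, "kmer_sketch"), inherits(b, "kmer_sketch"))
  if (a$k != b$k) stop("sketches have mismatched k: ", a$k, " vs ", b$k)
  if (a$seed != b$seed) stop("sketches have mismatched hash seed")
  s <- min(a$s, b$s)
  merged <- head(sort(unique(c(a$hashes, b$hashes))), s)
  if (length(merged) == 0L) return(0)
  sum(merged %in% a$hashes & merged %in% b$hashes) / length(merged)
}

#' Screen sketches against a draft genome
#'
#' For each sketch, counts how many of its hashes occur in the draft's full
#' canonical k-mer hash set, converts the containment index to an identity
#' estimate, and ranks genomes by identity.
#'
#' @param draft character vector of draft sequences.
#' @param sketches list of `kmer_sketch` objects sharing `k` and `seed`.
#' @return `data.table` with columns `genome_id`, `shared`, `containment`,
#'   `identity`, `rank`, sorted by identity descending.
#' @export
screen_sketches <- function(draft, sketches) {
  stopifnot(length(sketches) >= 1)
  if (inherits(sketches, "kmer_sketch")) sketches <- list(sketches)
  ks <- vapply(sketches, `[[`, integer(1), "k")
  seeds <- vapply(sketches, `[[`, numeric(1), "seed")
  if (length(unique(ks)) != 1L)
    stop("sketches have mixed k: ", paste(unique(ks), collapse = ", "))
  if (length(unique(seeds)) != 1L)
    stop("sketches have mixed hash seeds")
  k <- ks[[1L]]
  draft_set <- kmer_hash_set(draft, k = k, seed = seeds[[1L]])
  res <- data.table::rbindlist(lapply(sketches, function(sk) {
    shared <- sum(sketch_in_set(sk$hashes, draft_set))
    cont <- if (length(sk$hashes)) shared / length(sk$hashes) else 0
    data.table::data.table(genome_id = sk$genome_id, shared = shared,
                           containment = cont,
                           identity = estimate_identity(cont, k))
  }))
  data.table::setorder(res, -identity, -shared, genome_id)
  res[, rank := seq_len(.N)]
  res[]
}

# membership of sorted query hashes in a sorted reference set (binary search)
sketch_in_set <- function(hashes, sorted_set) {
  if (length(hashes) == 0L || length(sorted_set) == 0L)
    return(logical(length(hashes)))
  idx <- findInterval(hashes, sorted_set)
  idx > 0L & sorted_set[pmax(idx, 1L)] == hashes
}

#' Select related genomes passing the identity threshold
#'
#' Keeps screen results with identity at least `p` (given as a fraction such
#' as 0.95, or a percentage such as 95), sorts by identity (then shared count,
#' then id) and returns at most the top `t` genome ids.
#'
#' @param results `data.table` from [screen_sketches()].
#' @param p minimum identity, fraction or percent (default 0.95).
#' @param t maximum number of genomes to keep (default 20).
#' @return character vector of genome ids, length <= t.
#' @export
select_related <- function(results, p = 0.95, t = 20L) {
  stopifnot(t >= 1, p >= 0)
  if (p > 1) p <- p / 100
  stopifnot(p <= 1)
  keep <- data.table::as.data.table(results)[identity >= p]
  if (nrow(keep) == 0L)
    stop("no related genomes found at identity >= ", format(p),
         "; supply homologs explicitly (e.g. a local genome directory or a ",
         "genus/species override)")
  data.table::setorder(keep, -identity, -shared, genome_id)
  head(keep$genome_id, t)
}

#' Write sketches to a JSON-lines sketch file
#'
#' One JSON object per line recording `genome_id`, `k`, `s`, `seed` and the
#' hash values. Hashes are 53-bit integers and round-trip exactly.
#'
#' @param sketches list of `kmer_sketch` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sketches <- function(sketches, path) {
  if (inherits(sketches, "kmer_sketch")) sketches <- list(sketches)
  lines <- vapply(sketches, function(sk) {
    # hashes are 53-bit integers: serialize as decimal strings so the
    # round-trip is exact regardless of JSON number formatting
    jsonlite::toJSON(list(format = "homologpolish-sketch-1",
                          genome_id = sk$genome_id, k = sk$k, s = sk$s,
                          seed = sk$seed,
                          hashes = sprintf("%.0f", sk$hashes)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines sketch file
#'
#' @param path sketch file written by [write_sketches()].
#' @return list of `kmer_sketch` objects.
#' @export
read_sketches <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    if (is.null(x$format) || !identical(x$format, "homologpolish-sketch-1"))
      stop("not a homologpolish sketch file: ", path)
    structure(list(genome_id = x$genome_id, k = as.integer(x$k),
                   s = as.integer(x$s), seed = as.numeric(x$seed),
                   hashes = as.numeric(x$hashes)),
              class = "kmer_sketch")
  })
}
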