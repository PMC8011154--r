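# shared fixture cache: bundles are deterministic, build each once per run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, maker(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small world: quick enough for unit tests, rich enough for all 7 classes
tiny_fixture <- function() {
  cached("tiny", function() make_fixture_bundle(fixture_spec(
    genome_length = 20000L, n_strains = 8L, error_count = 80L,
    strain_indel_events = 60L, seed = 7L)))
}

random_dna <- function(n, seed = 1L, gc = 0.5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# independent canonical-k-mer enumeration (string-level, no sliding hash):
# every substring, canonicalized by explicit revcomp comparison, hashed with
# the shared hash primitive
brute_force_hashes <- function(seq, k, seed = 42L) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  sort(unique(hash_kmer(canon, seed)))
}

brute_force_sketch <- function(seq, k, s, seed = 42L) {
  head(brute_force_hashes(seq, k, seed), s)
}

# independent pileup oracle: a plain per-base re-walk of every cigar,
# accumulating observations position by position
naive_pileup <- function(draft, alignments) {
  cols <- list()
  key <- function(ctg, p) paste0(ctg, ":", p)
  blank <- function() list(
    matches = c(A = 0, C = 0, G = 0, T = 0), deletions = 0,
    ins = character(0), covering = character(0))
  for (a in alignments) {
    dchars <- strsplit(draft[[a$draft_contig]], "", fixed = TRUE)[[1]]
    schars <- strsplit(a$homolog_segment, "", fixed = TRUE)[[1]]
    dp <- a$draft_start  # 0-based
    qp <- 0L
    for (i in seq_len(nrow(a$cigar))) {
      op <- a$cigar$op[i]; l <- a$cigar$len[i]
      if (op %in% c("M", "=", "X")) {
        for (j in seq_len(l)) {
          kk <- key(a$draft_contig, dp)
          if (is.null(cols[[kk]])) cols[[kk]] <- blank()
          b <- schars[qp + 1L]
          if (b %in% names(cols[[kk]]$matches))
            cols[[kk]]$matches[b] <- cols[[kk]]$matches[b] + 1
          dp <- dp + 1L; qp <- qp + 1L
        }
      } else if (op == "D") {
        for (j in seq_len(l)) {
          kk <- key(a$draft_contig, dp)
          if (is.null(cols[[kk]])) cols[[kk]] <- blank()
          cols[[kk]]$deletions <- cols[[kk]]$deletions + 1
          dp <- dp + 1L
        }
      } else if (op == "I") {
        kk <- key(a$draft_contig, dp)
        if (is.null(cols[[kk]])) cols[[kk]] <- blank()
        cols[[kk]]$ins <- c(cols[[kk]]$ins,
                            paste(schars[qp + seq_len(l)], collapse = ""))
        qp <- qp + l
      }
    }
    for (p in a$draft_start:(a$draft_end - 1L)) {
      kk <- key(a$draft_contig, p)
      if (is.null(cols[[kk]])) cols[[kk]] <- blank()
      cols[[kk]]$covering <- c(cols[[kk]]$covering, a$homolog_id)
    }
  }
  cols
}

# hand-built alignments: n_match homologs matching the draft plus custom ones
match_alignment <- function(id, draft, contig = names(draft)[1]) {
  homolog_alignment(id, contig, 0L, nchar(draft[[contig]]), "+",
                    paste0(nchar(draft[[contig]]), "="), draft[[contig]])
}
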