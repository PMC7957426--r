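#' Append the 3' CCA end to a tRNA sequence if missing
#'
#' Mature tRNAs carry a 3' CCA; reference tRNA entries that lack it cannot
#' receive reads from the acceptor end. Idempotent.
#'
#' @param trna_sequence character vector of sequences over \{A,C,G,T\}.
#' @return Sequences guaranteed to end in "CCA".
#' @export
append_cca <- function(trna_sequence) {
  stopifnot(is.character(trna_sequence))
  bad <- grepl("[^ACGT]", trna_sequence)
  if (any(bad)) stop("input must be over {A,C,G,T}")
  ifelse(endsWith(trna_sequence, "CCA"), trna_sequence,
         paste0(trna_sequence, "CCA"))
}

#' Merge bisulfite-identical reference sequences
#'
#' Sequences that differ only by C>T point substitutions are indistinguishable
#' after bisulfite conversion; keeping them separate would destroy unique
#' alignment. Such sequences are merged into one representative that keeps the
#' C polymorphism (C wherever any member had C). Merging is performed within
#' a transcript class; equal-length is implied by the C>T-only criterion.
#'
#' @param refs a `RefSet` or a named character vector of sequences.
#' @return For a `RefSet`, a `RefSet` with merged entries and an added
#'   `merge_map` element (data.frame member -> representative); for a plain
#'   vector, a list(seq, merge_map).
#' @export
merge_bisulfite_identical <- function(refs) {
  if (inherits(refs, "RefSet")) {
    seqs <- refs$seq
    cls <- refs$info$class[match(names(seqs), refs$info$id)]
  } else {
    stopifnot(is.character(refs), !is.null(names(refs)))
    seqs <- refs
    cls <- rep("seq", length(seqs))
  }
  key <- paste(cls, chartr("C", "T", seqs), sep = "|")
  groups <- split(seq_along(seqs), key)
  rep_idx <- integer(0)
  out_seq <- character(0)
  map_member <- character(0)
  map_rep <- character(0)
  for (g in groups) {
    g <- sort(g)
    rep_id <- names(seqs)[g[1]]
    if (length(g) == 1L) {
      merged <- seqs[[g[1]]]
    } else {
      m <- do.call(rbind, strsplit(seqs[g], ""))
      consensus <- apply(m, 2, function(col) if (any(col == "C")) "C" else col[1])
      merged <- paste(consensus, collapse = "")
      map_member <- c(map_member, names(seqs)[g])
      map_rep <- c(map_rep, rep(rep_id, length(g)))
    }
    rep_idx <- c(rep_idx, g[1])
    out_seq[rep_id] <- merged
  }
  ord <- order(rep_idx)
  out_seq <- out_seq[ord]
  merge_map <- data.frame(member = map_member, representative = map_rep,
                          stringsAsFactors = FALSE)
  if (inherits(refs, "RefSet")) {
    out <- refs
    out$info <- refs$info[match(names(out_seq), refs$info$id), , drop = FALSE]
    rownames(out$info) <- NULL
    out$seq <- out_seq
    out$merge_map <- merge_map
    out
  } else {
    list(seq = out_seq, merge_map = merge_map)
  }
}

# Internal: named sequence vector from RefSet or plain vector.
ref_seqs <- function(refs) {
  if (inherits(refs, "RefSet")) refs$seq
  else if (is.character(refs) && (!length(refs) || !is.null(names(refs)))) refs
  else stop("refs must be a RefSet or a named character vector")
}

#' Uniquely align reads to a small transcriptome
#'
#' Exact seed-and-verify alignment over a desk-scale reference. Candidate
#' locations are found by hashing k-mers; with a mismatch budget of m, m+1
#' non-overlapping seeds guarantee (pigeonhole) that every location within
#' budget is examined. In bisulfite mode, candidate search runs in
#' C->T-collapsed space and verification applies the asymmetric bisulfite
#' rule: a read T matches a reference C (conversion), but a read C does not
#' match a reference T.
#'
#' A read is retained only if it has exactly one best-scoring location;
#' reads with two or more equally good locations are discarded, not
#' tie-broken.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param refs a `RefSet` or named character vector of reference sequences
#'   (merge bisulfite-identical entries first in bisulfite mode).
#' @param max_mismatch maximum verified mismatches (default 2).
#' @param bisulfite_mode apply the asymmetric C/T matching rule.
#' @return data.frame(read_id, transcript, start, width, mismatches) with
#'   0-based start offsets; one row per retained (uniquely aligned) read.
#' @export
align_unique <- function(reads, refs, max_mismatch = 2L,
                         bisulfite_mode = FALSE) {
  seqs <- ref_seqs(refs)
  if (!length(seqs)) stop("empty reference set")
  if (!length(reads)) stop("no reads supplied")
  stopifnot(max_mismatch >= 0L)
  if (is.null(names(reads))) names(reads) <- sprintf("read_%d", seq_along(reads))

  tx_len <- nchar(seqs)
  tx_off <- c(0L, cumsum(tx_len))[seq_along(seqs)] # global offset per tx
  genome <- paste(seqs, collapse = "")
  gchar <- strsplit(genome, "")[[1]]
  search_space <- if (bisulfite_mode) chartr("C", "T", genome) else genome

  read_len <- nchar(reads)
  too_long <- read_len > max(tx_len)
  if (any(too_long)) {
    warning(sum(too_long), " read(s) longer than every transcript; dropped")
    reads <- reads[!too_long]
    read_len <- read_len[!too_long]
    if (!length(reads)) {
      return(data.frame(read_id = character(0), transcript = character(0),
                        start = integer(0), width = integer(0),
                        mismatches = integer(0)))
    }
  }

  n_seeds <- max_mismatch + 1L
  kmer_cache <- new.env(parent = emptyenv())
  kmer_index <- function(k) {
    key <- as.character(k)
    if (!is.null(kmer_cache[[key]])) return(kmer_cache[[key]])
    starts <- unlist(lapply(seq_along(seqs), function(i) {
      if (tx_len[i] < k) return(integer(0))
      tx_off[i] + seq_len(tx_len[i] - k + 1L) # global 1-based kmer starts
    }))
    kmers <- substring(search_space, starts, starts + k - 1L)
    idx <- split(starts, kmers)
    kmer_cache[[key]] <- idx
    idx
  }

  out <- vector("list", 0L)
  for (L in sort(unique(read_len))) {
    sel <- which(read_len == L)
    rds <- reads[sel]
    n <- length(rds)
    k <- L %/% n_seeds
    if (k < 4L) {
      stop("reads of length ", L, " too short for mismatch budget ",
           max_mismatch)
    }
    idx <- kmer_index(k)
    creads <- if (bisulfite_mode) chartr("C", "T", rds) else rds

    cand_read <- integer(0)
    cand_start <- integer(0) # global 1-based alignment starts
    for (j in seq_len(n_seeds) - 1L) {
      seed <- substring(creads, j * k + 1L, j * k + k)
      hits <- idx[seed] # hash lookup; NULL name -> NULL entry
      nh <- lengths(hits)
      if (!sum(nh)) next
      cand_read <- c(cand_read, rep(seq_len(n), nh))
      cand_start <- c(cand_start, unlist(hits, use.names = FALSE) - j * k)
    }
    if (!length(cand_read)) next
    keep <- !duplicated(cbind(cand_read, cand_start))
    cand_read <- cand_read[keep]
    cand_start <- cand_start[keep]
    # candidate must lie fully within one transcript
    tx_i <- findInterval(cand_start - 1L, c(tx_off, sum(tx_len)))
    ok <- cand_start >= tx_off[tx_i] + 1L &
      (cand_start + L - 1L) <= tx_off[tx_i] + tx_len[tx_i]
    cand_read <- cand_read[ok]
    cand_start <- cand_start[ok]
    tx_i <- tx_i[ok]
    if (!length(cand_read)) next

    rmat <- matrix(unlist(strsplit(rds, ""), use.names = FALSE),
                   nrow = n, ncol = L, byrow = TRUE)
    nc <- length(cand_read)
    mm <- integer(nc)
    chunk <- max(1L, floor(5e6 / L))
    for (lo in seq(1L, nc, by = chunk)) {
      hi <- min(lo + chunk - 1L, nc)
      cs <- cand_start[lo:hi]
      im <- matrix(cs, length(cs), L) +
        matrix(0L:(L - 1L), length(cs), L, byrow = TRUE)
      refm <- matrix(gchar[im], length(cs), L)
      readm <- rmat[cand_read[lo:hi], , drop = FALSE]
      neq <- readm != refm
      if (bisulfite_mode) neq <- neq & !(readm == "T" & refm == "C")
      mm[lo:hi] <- as.integer(rowSums(neq))
    }
    pass <- mm <= max_mismatch
    cand_read <- cand_read[pass]
    cand_start <- cand_start[pass]
    tx_i <- tx_i[pass]
    mm <- mm[pass]
    if (!length(cand_read)) next

    # retain reads with a unique best-scoring location
    best <- tapply(mm, cand_read, min)
    best_of <- best[as.character(cand_read)]
    at_best <- mm == best_of
    n_best <- tapply(at_best, cand_read, sum)
    uniq_reads <- as.integer(names(n_best)[n_best == 1L])
    sel2 <- at_best & cand_read %in% uniq_reads
    out[[length(out) + 1L]] <- data.frame(
      read_id = names(rds)[cand_read[sel2]],
      transcript = names(seqs)[tx_i[sel2]],
      start = cand_start[sel2] - tx_off[tx_i[sel2]] - 1L,
      width = rep.int(L, sum(sel2)),
      mismatches = mm[sel2],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(read_id = character(0), transcript = character(0),
                      start = integer(0), width = integer(0),
                      mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pile up read bases over reference cytosines
#'
#' Produces the per-sample cytosine report consumed by methylation calling:
#' for every reference C position, the number of reads calling C
#' (non-converted), T (converted) and anything else. Non-C/T calls are
#' sequencing errors, not conversion evidence, and are excluded from
#' coverage.
#'
#' @param alignments alignment table from [align_unique()].
#' @param reads the named read vector the alignments refer to.
#' @param refs reference (`RefSet` or named character vector).
#' @return data.frame(transcript, pos, coverage, nonconverted, converted,
#'   other) over all reference C positions (0-based `pos`), class
#'   `"CytosineReport"`. `coverage = nonconverted + converted`.
#' @export
pileup_cytosines <- function(alignments, reads, refs) {
  seqs <- ref_seqs(refs)
  tx_len <- nchar(seqs)
  tx_off <- c(0L, cumsum(tx_len))[seq_along(seqs)]
  names(tx_off) <- names(seqs)
  gchar <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  c_glob <- which(gchar == "C")
  pos2c <- integer(length(gchar))
  pos2c[c_glob] <- seq_along(c_glob)

  nonconv <- integer(length(c_glob))
  conv <- integer(length(c_glob))
  other <- integer(length(c_glob))

  if (nrow(alignments)) {
    if (is.null(names(reads))) stop("reads must be named")
    a_tx <- alignments$transcript
    if (!all(a_tx %in% names(seqs))) stop("alignments refer to unknown refs")
    if (any(alignments$start < 0L |
            alignments$start + alignments$width > tx_len[a_tx])) {
      stop("alignment beyond transcript bounds: corrupt input")
    }
    rseq <- reads[alignments$read_id]
    if (anyNA(rseq)) stop("alignments refer to unknown read ids")
    for (L in sort(unique(alignments$width))) {
      sel <- which(alignments$width == L)
      base <- unlist(strsplit(unname(rseq[sel]), ""), use.names = FALSE)
      gstart <- tx_off[a_tx[sel]] + alignments$start[sel] # 0-based global
      gpos <- rep(gstart, each = L) + rep(0L:(L - 1L), times = length(sel)) + 1L
      ci <- pos2c[gpos]
      on_c <- ci > 0L
      ci <- ci[on_c]
      base <- base[on_c]
      nonconv <- nonconv + tabulate(ci[base == "C"], length(c_glob))
      conv <- conv + tabulate(ci[base == "T"], length(c_glob))
      other <- other + tabulate(ci[!base %in% c("C", "T")], length(c_glob))
    }
  }

  tx_i <- findInterval(c_glob - 1L, c(tx_off, sum(tx_len)))
  rep_df <- data.frame(
    transcript = names(seqs)[tx_i],
    pos = c_glob - tx_off[tx_i] - 1L,
    coverage = nonconv + conv,
    nonconverted = nonconv,
    converted = conv,
    other = other,
    stringsAsFactors = FALSE)
  class(rep_df) <- c("CytosineReport", "data.frame")
  rep_df
}
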