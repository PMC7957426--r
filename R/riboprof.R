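#' Filter footprint lengths by 3-nt periodicity
#'
#' Ribosome-protected fragments of a given length share a fixed distance
#' between the 5' end and the ribosome P-site, so within a length stratum the
#' 5' ends fall overwhelmingly into one frame relative to the CDS start.
#' Lengths whose modal frame holds at least `min_frame_fraction` of
#' CDS-overlapping reads are retained.
#'
#' @param alignments alignment table from [align_unique()].
#' @param cds CDS annotation from [cds_annotation()].
#' @param lengths candidate footprint lengths (must lie within 20-40 nt).
#' @param min_frame_fraction retention cutoff on the modal-frame fraction.
#' @return list(retained = integer vector of lengths, frame_table =
#'   data.frame(length, n, frame0, frame1, frame2, modal_fraction)).
#' @export
periodicity_filter <- function(alignments, cds, lengths = 26:32,
                               min_frame_fraction = 0.5) {
  if (any(lengths < 20L | lengths > 40L)) {
    stop("candidate lengths must lie within 20-40 nt")
  }
  i <- match(alignments$transcript, cds$transcript)
  keep <- !is.na(i) & alignments$width %in% lengths
  a <- alignments[keep, , drop = FALSE]
  cs <- cds$cds_start[i[keep]]
  ce <- cds$cds_end[i[keep]]
  in_cds <- a$start >= cs & a$start < ce
  if (!any(in_cds)) stop("no CDS-overlapping reads")
  frame <- (a$start[in_cds] - cs[in_cds]) %% 3L
  len <- a$width[in_cds]
  rows <- lapply(sort(intersect(unique(len), lengths)), function(L) {
    f <- tabulate(frame[len == L] + 1L, 3L)
    data.frame(length = L, n = sum(f), frame0 = f[1], frame1 = f[2],
               frame2 = f[3], modal_fraction = max(f) / sum(f))
  })
  tab <- do.call(rbind, rows)
  list(retained = tab$length[tab$modal_fraction >= min_frame_fraction],
       frame_table = tab)
}

#' Assign ribosome P-sites and build the per-codon footprint table
#'
#' The P-site first nucleotide is the footprint 5' end shifted `shift` nt
#' towards the 3' end (default 12). Footprints whose P-site falls inside a
#' CDS and in frame are assigned the codon index `(p - cds_start) / 3`;
#' in-CDS but off-frame footprints are dropped and counted.
#'
#' @param alignments alignment table, already restricted to retained lengths.
#' @param cds CDS annotation from [cds_annotation()].
#' @param shift P-site offset in nt (>= 0).
#' @return data.frame(transcript, gene, codon, count), class `"PsiteTable"`,
#'   with attributes `shift`, `lengths`, `n_in_cds` (footprints with P-site
#'   in a CDS), `n_offframe` (dropped), `n_first_removed` (0 until
#'   [drop_first_codons()]), and `cds`.
#' @export
assign_psites <- function(alignments, cds, shift = 12L) {
  if (shift < 0L) stop("shift must be non-negative")
  i <- match(alignments$transcript, cds$transcript)
  keep <- !is.na(i)
  a <- alignments[keep, , drop = FALSE]
  cs <- cds$cds_start[i[keep]]
  ce <- cds$cds_end[i[keep]]
  p <- a$start + as.integer(shift)
  in_cds <- p >= cs & p < ce
  rel <- p[in_cds] - cs[in_cds]
  off <- rel %% 3L != 0L
  tx <- a$transcript[in_cds][!off]
  ci <- rel[!off] %/% 3L
  agg <- stats::aggregate(list(count = rep(1L, length(ci))),
                          by = list(transcript = tx, codon = ci), FUN = sum)
  agg <- agg[order(agg$transcript, agg$codon), , drop = FALSE]
  if (!nrow(agg)) {
    agg <- data.frame(transcript = character(0), codon = integer(0),
                      count = integer(0))
  }
  agg$gene <- cds$gene[match(agg$transcript, cds$transcript)]
  agg <- agg[c("transcript", "gene", "codon", "count")]
  rownames(agg) <- NULL
  structure(agg, class = c("PsiteTable", "data.frame"),
            shift = as.integer(shift),
            lengths = sort(unique(a$width)),
            n_in_cds = sum(in_cds), n_offframe = sum(off),
            n_first_removed = 0L, cds = cds)
}

#' Remove footprints on the first codons of every gene
#'
#' Initiating and early-elongating ribosomes inflate 5'-proximal counts; the
#' analysis discards the first `n` codons (default 10) of every CDS before
#' any occupancy or gene-level quantification.
#'
#' @param table a `PsiteTable`.
#' @param n number of leading codons to remove.
#' @return The filtered `PsiteTable`; attribute `n_first_removed` records the
#'   removed footprint count, `drop_first` the cutoff.
#' @export
drop_first_codons <- function(table, n = 10L) {
  stopifnot(inherits(table, "PsiteTable"), n >= 0L)
  at <- attributes(table)
  removed <- sum(table$count[table$codon < n])
  out <- table[table$codon >= n, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("shift", "lengths", "n_in_cds", "n_offframe", "cds")) {
    attr(out, a) <- at[[a]]
  }
  attr(out, "n_first_removed") <- at$n_first_removed + removed
  attr(out, "drop_first") <- as.integer(n)
  class(out) <- c("PsiteTable", "data.frame")
  out
}

# Codon identity lookup for all (transcript, codon index) rows of a table.
codon_identity <- function(refs, table) {
  out <- character(nrow(table))
  for (tx in unique(table$transcript)) {
    sel <- table$transcript == tx
    out[sel] <- cds_codons(refs, tx)[table$codon[sel] + 1L]
  }
  out
}

#' Bulk P-site codon occupancy with downstream-codon normalization
#'
#' For each of the 61 sense codons, the P-site count is the number of shifted
#' footprints whose P-site codon has that identity. The background is the
#' count of the same codon identity at the +1, +2 and +3 codons relative to
#' the A-site (nucleotide offsets +6, +9, +12 from the P-site first
#' nucleotide; the A-site is P + 3 nt). Normalized occupancy is
#' `p_count / (background_sum / 3)`, so a uniform ribosome distribution
#' normalizes to 1. Positions whose three background codons would run past
#' the last sense codon are skipped from both tallies.
#'
#' @param table a filtered `PsiteTable`.
#' @param refs the `RefSet` providing CDS sequences.
#' @return data.frame(codon, p_count, bg_count, occupancy, defined) over all
#'   61 sense codons; `occupancy` is `NA` where the background is empty.
#' @export
codon_occupancy <- function(table, refs) {
  stopifnot(inherits(table, "PsiteTable"))
  cds <- attr(table, "cds")
  ncod <- setNames(cds$n_codons, cds$transcript)
  p_count <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  bg_count <- p_count
  for (tx in unique(table$transcript)) {
    sel <- table$transcript == tx
    ci <- table$codon[sel]
    cnt <- table$count[sel]
    codons <- cds_codons(refs, tx)
    # eligibility: bg codons at ci+2, ci+3, ci+4 must all be sense codons
    elig <- ci + 4L <= ncod[tx] - 2L
    ci <- ci[elig]; cnt <- cnt[elig]
    if (!length(ci)) next
    pc <- codons[ci + 1L]
    valid <- pc %in% SENSE_CODONS
    if (any(!valid)) {
      warning("skipping ", sum(!valid), " position(s) with non-sense or ",
              "ambiguous P-site codon in ", tx)
      ci <- ci[valid]; cnt <- cnt[valid]; pc <- pc[valid]
    }
    if (!length(ci)) next
    pt <- tapply(cnt, pc, sum)
    p_count[names(pt)] <- p_count[names(pt)] + pt
    for (k in 2:4) {
      bc <- codons[ci + k + 1L]
      bt <- tapply(cnt, bc, sum)
      keep <- names(bt) %in% SENSE_CODONS
      bg_count[names(bt)[keep]] <- bg_count[names(bt)[keep]] + bt[keep]
    }
  }
  occupancy <- ifelse(bg_count > 0, p_count / (bg_count / 3), NA_real_)
  data.frame(codon = SENSE_CODONS, p_count = unname(p_count),
             bg_count = unname(bg_count), occupancy = unname(occupancy),
             defined = unname(bg_count > 0), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-codon occupancy fold changes between genotypes
#'
#' Fold change is the mean normalized occupancy in the knockout over the mean
#' in the wild type; per-codon significance by Welch's two-sample t-test on
#' log2 occupancies across replicates. Codons with an undefined or
#' non-positive occupancy in any replicate are flagged and excluded from
#' testing (their FC is reported when computable).
#'
#' @param ko_tables,wt_tables lists (>= 2 each) of [codon_occupancy()]
#'   tables for knockout and wild-type replicates.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame(codon, wt_mean, ko_mean, fold_change, p_value,
#'   significant, tested).
#' @export
occupancy_fold_change <- function(ko_tables, wt_tables, alpha = 0.05) {
  if (length(ko_tables) < 2L || length(wt_tables) < 2L) {
    stop("need at least 2 replicates per genotype")
  }
  occ_mat <- function(tabs) {
    do.call(cbind, lapply(tabs, function(t) {
      stopifnot(identical(t$codon, SENSE_CODONS))
      t$occupancy
    }))
  }
  ko <- occ_mat(ko_tables)
  wt <- occ_mat(wt_tables)
  ko_mean <- rowMeans(ko)
  wt_mean <- rowMeans(wt)
  fc <- ko_mean / wt_mean
  testable <- rowSums(!is.finite(ko) | ko <= 0) == 0L &
    rowSums(!is.finite(wt) | wt <= 0) == 0L
  p <- rep(NA_real_, length(SENSE_CODONS))
  for (i in which(testable)) {
    p[i] <- tryCatch(
      stats::t.test(log2(ko[i, ]), log2(wt[i, ]))$p.value,
      error = function(e) NA_real_) # zero-variance degenerate input
  }
  data.frame(codon = SENSE_CODONS, wt_mean = wt_mean, ko_mean = ko_mean,
             fold_change = fc, p_value = p,
             significant = !is.na(p) & p < alpha, tested = testable,
             stringsAsFactors = FALSE)
}

#' Per-gene ribosome occupancy
#'
#' Sum of in-frame shifted footprints over the CDS of each gene, after the
#' first-codon exclusion carried by the input table.
#'
#' @param table a `PsiteTable` (typically after [drop_first_codons()]).
#' @return named numeric vector over all annotated genes (zeros included).
#' @export
gene_occupancy <- function(table) {
  stopifnot(inherits(table, "PsiteTable"))
  cds <- attr(table, "cds")
  counts <- setNames(numeric(nrow(cds)), cds$gene)
  if (nrow(table)) {
    s <- tapply(table$count, table$gene, sum)
    counts[names(s)] <- s
  }
  counts
}

#' Footprint profile of one gene with highlighted codon positions
#'
#' @param table a `PsiteTable`.
#' @param refs the `RefSet`.
#' @param gene gene id (or its transcript id).
#' @param highlight_codon codon whose positions along the CDS are reported.
#' @return list(counts = per-codon count vector (0-based codon index order,
#'   full CDS length), highlight = 0-based codon indices carrying the codon).
#' @export
profile_gene <- function(table, refs, gene, highlight_codon = "TTG") {
  stopifnot(inherits(table, "PsiteTable"))
  cds <- attr(table, "cds")
  row <- cds[cds$gene == gene | cds$transcript == gene, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown gene: ", gene)
  codons <- cds_codons(refs, row$transcript)
  counts <- setNames(numeric(row$n_codons), seq_len(row$n_codons) - 1L)
  sel <- table$transcript == row$transcript
  if (any(sel)) {
    agg <- tapply(table$count[sel], table$codon[sel], sum)
    counts[names(agg)] <- agg
  }
  list(counts = counts, highlight = which(codons == highlight_codon) - 1L)
}

#' Polysomal fraction of an absorbance trace
#'
#' Trapezoidal area of the polysomal part of a sucrose-gradient absorbance
#' trace (x at or beyond the monosome/polysome boundary) divided by the area
#' under the entire curve. The trace is linearly interpolated at the boundary
#' so piecewise-linear traces integrate exactly.
#'
#' @param trace data.frame or list with numeric `x` (sorted ascending) and
#'   `absorbance` (baseline-corrected, >= 0).
#' @param boundary x coordinate of the monosome/polysome split; must lie
#'   within the trace range.
#' @return scalar fraction in [0, 1].
#' @export
polysome_fraction <- function(trace, boundary) {
  x <- trace$x
  y <- trace$absorbance
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (is.unsorted(x, strictly = FALSE)) stop("trace must be sorted in x")
  if (any(y < 0)) stop("absorbance must be baseline-corrected to >= 0")
  if (boundary < x[1] || boundary > x[length(x)]) {
    stop("boundary outside trace range")
  }
  if (!boundary %in% x) {
    yb <- stats::approx(x, y, xout = boundary)$y
    i <- findInterval(boundary, x)
    x <- append(x, boundary, after = i)
    y <- append(y, yb, after = i)
  }
  trap <- function(x, y) {
    if (length(x) < 2L) return(0)
    sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  }
  total <- trap(x, y)
  if (total <= 0) stop("trace has zero total area")
  poly <- trap(x[x >= boundary], y[x >= boundary])
  poly / total
}
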