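#' Per-gene translation efficiency
#'
#' Ribosome occupancy of each gene (first-codon-excluded footprint counts)
#' divided by the mRNA abundance of the same gene, after normalizing both
#' libraries to counts per million over the included genes. Genes below the
#' RNA abundance floor are excluded; TE is scale-invariant under per-library
#' rescaling by construction.
#'
#' @param ribo_counts named numeric vector of per-gene footprint counts
#'   (e.g. from [gene_occupancy()]).
#' @param rna_abundance named numeric vector of per-gene RNA-seq counts.
#' @param min_rna minimum RNA count for a gene to be evaluable (default 10).
#' @return data.frame(gene, rpf, rna, rpf_cpm, rna_cpm, te, log2_te),
#'   class `"TETable"`.
#' @export
translation_efficiency <- function(ribo_counts, rna_abundance, min_rna = 10) {
  genes <- intersect(names(ribo_counts), names(rna_abundance))
  if (!length(genes)) stop("no genes shared between inputs")
  rpf <- ribo_counts[genes]
  rna <- rna_abundance[genes]
  keep <- rna >= min_rna
  if (!any(keep)) stop("all genes excluded by the RNA abundance floor")
  rpf <- rpf[keep]
  rna <- rna[keep]
  rpf_cpm <- rpf / sum(rpf) * 1e6
  rna_cpm <- rna / sum(rna) * 1e6
  te <- rpf_cpm / rna_cpm
  out <- data.frame(gene = names(rpf), rpf = unname(rpf), rna = unname(rna),
                    rpf_cpm = unname(rpf_cpm), rna_cpm = unname(rna_cpm),
                    te = unname(te), log2_te = unname(log2(te)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("TETable", "data.frame")
  out
}

#' Codon-enrichment gene sets
#'
#' A gene is enriched in a codon (or a pooled group of synonymous codons)
#' when the proportion of that codon among the gene's sense codons is at
#' least `factor`-fold higher than the proportion of the same codon across
#' the transcriptome (pooled over all CDSs, stops excluded). The boundary
#' case (ratio exactly `factor`) counts as enriched.
#'
#' @param refs a `RefSet`, or a named character vector of CDS sequences
#'   (names = gene ids, each length divisible by 3).
#' @param codons one or more sense codons; amino-acid-level sets pool
#'   synonymous codons by passing them together.
#' @param factor fold-enrichment cutoff (default 3).
#' @return data.frame(gene, count, sense_codons, proportion,
#'   transcriptome_proportion, ratio, enriched).
#' @export
codon_enrichment_sets <- function(refs, codons, factor = 3) {
  if (!all(codons %in% SENSE_CODONS)) {
    stop("codon(s) must be sense codons: ",
         paste(setdiff(codons, SENSE_CODONS), collapse = ", "))
  }
  if (inherits(refs, "RefSet")) {
    cds <- cds_annotation(refs)
    seqs <- lapply(cds$transcript, function(tx) cds_codons(refs, tx))
    names(seqs) <- cds$gene
  } else {
    stopifnot(is.character(refs), !is.null(names(refs)),
              all(nchar(refs) %% 3 == 0))
    seqs <- lapply(refs, function(s)
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
  }
  count <- vapply(seqs, function(cv) sum(cv %in% codons), numeric(1))
  sense_n <- vapply(seqs, function(cv) sum(cv %in% SENSE_CODONS), numeric(1))
  prop <- count / sense_n
  pool <- sum(count) / sum(sense_n)
  ratio <- prop / pool
  data.frame(gene = names(seqs), count = unname(count),
             sense_codons = unname(sense_n), proportion = unname(prop),
             transcriptome_proportion = pool, ratio = unname(ratio),
             enriched = unname(ratio >= factor),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare translation efficiency of gene sets against random controls
#'
#' Welch's t-test of log2 TE between each gene set and a seeded,
#' size-matched random gene sample drawn from the evaluable genes. Sets
#' smaller than 3 genes after TE filtering are skipped with a warning;
#' zero-variance (degenerate) comparisons are flagged, not tested.
#'
#' @param te a `TETable`.
#' @param sets named list of gene-id vectors.
#' @param seed RNG seed for the random control draws.
#' @param exclude_from_random genes never drawn into the random control
#'   (e.g. members of planted enriched sets, so the control tests the null).
#' @return data.frame(set, n, set_mean, random_mean, difference, p_value,
#'   tested).
#' @export
compare_te_groups <- function(te, sets, seed = 1L,
                              exclude_from_random = NULL) {
  stopifnot(inherits(te, "TETable"))
  set.seed(derive_seed(seed, 0L))
  pool <- te$gene
  if (!is.null(exclude_from_random)) pool <- setdiff(pool, exclude_from_random)
  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], te$gene)
    n <- length(genes)
    if (n < 3L) {
      warning("set '", nm, "' has fewer than 3 evaluable genes; test skipped")
      return(data.frame(set = nm, n = n, set_mean = NA_real_,
                        random_mean = NA_real_, difference = NA_real_,
                        p_value = NA_real_, tested = FALSE))
    }
    rnd <- sample(pool, min(n, length(pool)))
    a <- te$log2_te[te$gene %in% genes]
    b <- te$log2_te[te$gene %in% rnd]
    res <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    ok <- !is.null(res) && is.finite(res$p.value) # zero variance -> flagged
    data.frame(set = nm, n = n, set_mean = mean(a), random_mean = mean(b),
               difference = mean(a) - mean(b),
               p_value = if (ok) res$p.value else NA_real_,
               tested = ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare one gene set's translation efficiency between two samples
#'
#' Welch's t-test on the log2 TE values of a gene set in two TE tables
#' (e.g. knockout-heat versus wild-type-heat), the directional comparison
#' behind gene-set TE shifts.
#'
#' @param te_a,te_b `TETable`s of the two samples or replicate-averaged
#'   conditions.
#' @param genes gene ids of the set (default: all shared genes).
#' @return list(mean_a, mean_b, difference = mean_a - mean_b, p_value, n).
#' @export
compare_te_conditions <- function(te_a, te_b, genes = NULL) {
  stopifnot(inherits(te_a, "TETable"), inherits(te_b, "TETable"))
  shared <- intersect(te_a$gene, te_b$gene)
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3L) stop("fewer than 3 evaluable genes in the set")
  a <- te_a$log2_te[match(shared, te_a$gene)]
  b <- te_b$log2_te[match(shared, te_b$gene)]
  res <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
  list(mean_a = mean(a), mean_b = mean(b), difference = mean(a) - mean(b),
       p_value = if (is.null(res)) NA_real_ else res$p.value,
       n = length(shared))
}

#' Average replicate TE tables into one per-gene table
#'
#' Per-gene mean log2 TE across replicate `TETable`s (genes evaluable in
#' every replicate).
#'
#' @param te_list list of `TETable`s.
#' @return A `TETable` with `log2_te` the replicate mean and `te = 2^log2_te`.
#' @export
average_te <- function(te_list) {
  stopifnot(length(te_list) >= 1L)
  genes <- Reduce(intersect, lapply(te_list, function(t) t$gene))
  m <- vapply(te_list, function(t) t$log2_te[match(genes, t$gene)],
              numeric(length(genes)))
  l2 <- if (length(genes) == 1L) mean(m) else rowMeans(m)
  out <- data.frame(gene = genes,
                    rpf = NA_real_, rna = NA_real_,
                    rpf_cpm = NA_real_, rna_cpm = NA_real_,
                    te = 2^l2, log2_te = l2,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("TETable", "data.frame")
  out
}
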