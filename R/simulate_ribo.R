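#' Simulate ribosome-profiling footprints and matched RNA-seq for one sample
#'
#' Footprint P-sites are sampled over (gene, codon) positions with probability
#' proportional to expression x ribosome loading x per-codon dwell time, where
#' dwell multipliers come from `config$dwell_multipliers` for the requested
#' genotype and condition (codons not listed dwell at 1). The footprint 5' end
#' is placed 12 nt upstream of the P-site first nucleotide, its length drawn
#' from `rpf_len_dist`, and with probability `frame_noise` the 5' end is
#' jittered off-frame by +/-1 nt. The stop codon never holds a P-site.
#'
#' Genes at least `enrich_factor`-fold enriched in a dwell-elevated codon have
#' their ribosome loading multiplied by `stall_te_factor` under the matching
#' genotype/condition, planting the reduced translational output of
#' stall-prone transcripts; RNA abundance is independent of dwell, so this is
#' the planted gene-level translation-efficiency effect.
#'
#' @param ref a `RefSet`.
#' @param config a [simulation_config()].
#' @param genotype "WT" or "noNSUN".
#' @param condition "control" or "heat".
#' @param stream RNG stream offset; defaults to replicate 1 of the
#'   genotype/condition ribosome-profiling stream.
#' @param rna_as_counts if TRUE (fast path) RNA-seq is emitted as per-gene
#'   Poisson counts; otherwise as uniformly sampled full-path reads.
#' @return list(rpf_reads, provenance, rna_counts or rna_reads + rna_provenance).
#'   `provenance` has one row per footprint: read_id, transcript, start
#'   (true 0-based 5' position after jitter), psite_codon (true P-site codon
#'   index), genotype, condition.
#' @export
simulate_ribo_and_rna <- function(ref, config, genotype, condition,
                                  stream = NULL, rna_as_counts = TRUE) {
  stopifnot(inherits(ref, "RefSet"))
  genotype <- match.arg(genotype, c("WT", "noNSUN"))
  condition <- match.arg(condition, c("control", "heat"))
  validate_sim_config(config)
  if (is.null(stream)) stream <- sample_stream("ribo", genotype, condition)
  set.seed(derive_seed(config$seed, stream))

  cds <- cds_annotation(ref)
  if (!nrow(cds)) stop("reference contains no mRNA")
  expr <- ref$info$expression[match(cds$transcript, ref$info$id)]

  dm <- config$dwell_multipliers
  mult <- setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  if (!is.null(dm) && nrow(dm)) {
    here <- dm[dm$genotype == genotype & dm$condition == condition, ,
               drop = FALSE]
    if (nrow(here)) {
      if (any(here$multiplier <= 0)) stop("dwell multiplier must be > 0")
      mult[here$codon] <- here$multiplier
    }
  }
  planted <- names(mult)[mult != 1] # planted effects, before replicate jitter
  if (config$dwell_cv > 0) { # biological replicate variability of decoding
    mult <- mult * stats::rlnorm(length(mult), 0, config$dwell_cv)
  }

  # gene-level ribosome loading: stall-prone (codon-enriched) genes load less
  load <- rep(1, nrow(cds))
  elevated <- planted
  if (length(elevated) && config$stall_te_factor != 1) {
    enr <- codon_enrichment_sets(ref, elevated,
                                 factor = config$enrich_factor)
    load[cds$gene %in% enr$gene[enr$enriched]] <- config$stall_te_factor
  }

  # position table: one row per (transcript, sense codon index)
  codon_list <- lapply(cds$transcript, function(tx) cds_codons(ref, tx))
  n_sense <- cds$n_codons - 1L # stop codon excluded from P-site sampling
  pos_tx <- rep(seq_len(nrow(cds)), n_sense)
  pos_ci <- unlist(lapply(n_sense, function(k) seq_len(k) - 1L))
  pos_codon <- unlist(lapply(seq_len(nrow(cds)),
                             function(i) codon_list[[i]][seq_len(n_sense[i])]))
  w <- expr[pos_tx] * load[pos_tx] * mult[pos_codon]

  n <- config$ribo_depth
  pick <- sample.int(length(w), n, replace = TRUE, prob = w)
  ci <- pos_ci[pick]
  txi <- pos_tx[pick]
  lens <- as.integer(sample(names(config$rpf_len_dist), n, replace = TRUE,
                            prob = config$rpf_len_dist))
  jitter <- integer(n)
  off <- stats::runif(n) < config$frame_noise
  if (any(off)) jitter[off] <- sample(c(-1L, 1L), sum(off), replace = TRUE)
  start <- cds$cds_start[txi] + 3L * ci - 12L + jitter
  txid <- cds$transcript[txi]
  tx_len <- nchar(ref$seq)[txid]
  ok <- start >= 0L & (start + lens) <= tx_len
  if (!all(ok)) { # only possible with very short UTRs
    start <- start[ok]; lens <- lens[ok]; txid <- txid[ok]; ci <- ci[ok]
    n <- sum(ok)
  }
  reads <- substring(ref$seq[txid], start + 1L, start + lens)

  if (config$seq_error_rate > 0) {
    nerr <- stats::rbinom(n, lens, config$seq_error_rate)
    hit <- which(nerr > 0L)
    others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
    for (i in hit) {
      p <- sample.int(lens[i], nerr[i])
      ch <- strsplit(reads[i], "")[[1]]
      for (pp in p) ch[pp] <- sample(others[[ch[pp]]], 1)
      reads[i] <- paste(ch, collapse = "")
    }
  }

  ids <- sprintf("rpf_%s_%s_s%d_%07d", genotype, condition, stream, seq_len(n))
  names(reads) <- ids
  prov <- data.frame(read_id = ids, transcript = txid, start = start,
                     psite_codon = ci, genotype = genotype,
                     condition = condition, stringsAsFactors = FALSE)

  out <- list(rpf_reads = reads, provenance = prov)

  ## matched RNA-seq: abundance independent of dwell ------------------------
  rna_stream <- stream + (.STREAMS$rna - .STREAMS$ribo)
  set.seed(derive_seed(config$seed, rna_stream))
  if (rna_as_counts) {
    mu <- config$rna_depth * expr / sum(expr)
    out$rna_counts <- setNames(stats::rpois(nrow(cds), mu), cds$gene)
  } else {
    rl <- min(config$bs_read_len, min(tx_len))
    wgt <- expr * (nchar(ref$seq)[cds$transcript] - rl + 1L)
    nr <- stats::rpois(1, config$rna_depth)
    txi2 <- sample.int(nrow(cds), nr, replace = TRUE, prob = wgt)
    tx2 <- cds$transcript[txi2]
    st2 <- floor(stats::runif(nr) * (nchar(ref$seq)[tx2] - rl + 1L))
    rr <- substring(ref$seq[tx2], st2 + 1L, st2 + rl)
    names(rr) <- sprintf("rna_%s_%s_s%d_%07d", genotype, condition,
                         rna_stream, seq_len(nr))
    out$rna_reads <- rr
    out$rna_provenance <- data.frame(read_id = names(rr), transcript = tx2,
                                     start = st2, gene = cds$gene[txi2],
                                     stringsAsFactors = FALSE)
  }
  out
}
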