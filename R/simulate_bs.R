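#' Simulate bisulfite-sequencing reads for one sample
#'
#' Generative inverse of the deamination-rate formula: each molecule draws a
#' methylation state per planted site (Bernoulli with the site stoichiometry;
#' zero at methyltransferase-dependent sites in the null genotype), every
#' unmethylated C converts to T with probability `deamination_rate`,
#' methylated Cs are protected, and uniform substitution errors are applied
#' after conversion. Reads are sense-strand fragments of fixed length
#' (`bs_read_len`, truncated to the transcript for short transcripts) with
#' uniformly sampled start positions; RNA bisulfite chemistry is
#' strand-preserving, so only the sense strand is simulated.
#'
#' @param ref a `RefSet`.
#' @param plan a `MethylationPlan` (may be empty).
#' @param genotype "WT" or "noNSUN".
#' @param config a [simulation_config()].
#' @param stream RNG stream offset; defaults to the bisulfite stream for
#'   replicate 1 of the genotype.
#' @return list(reads = named character vector, provenance = data.frame(
#'   read_id, transcript, start, genotype, meth_states)) where `meth_states`
#'   encodes the molecule-level methylation of covered planted sites as
#'   "pos:0/1" pairs separated by ";". Exactly one provenance row per read.
#' @export
simulate_bisulfite_reads <- function(ref, plan, genotype, config,
                                     stream = NULL) {
  stopifnot(inherits(ref, "RefSet"))
  genotype <- match.arg(genotype, c("WT", "noNSUN"))
  validate_sim_config(config)
  if (is.null(stream)) stream <- sample_stream("bs", genotype)
  set.seed(derive_seed(config$seed, stream))

  d <- config$deamination_rate
  e <- config$seq_error_rate
  others <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))

  all_reads <- vector("list", length(ref$seq))
  all_prov <- vector("list", length(ref$seq))
  counter <- 0L
  for (t in seq_along(ref$seq)) {
    id <- names(ref$seq)[t]
    s <- ref$seq[[t]]
    len <- nchar(s)
    L <- min(config$bs_read_len, len)
    n <- stats::rpois(1, config$bs_depth * len / L)
    if (n == 0L) next
    starts <- sample.int(len - L + 1L, n, replace = TRUE) - 1L
    sv <- strsplit(s, "")[[1]]
    im <- outer(starts, 0L:(L - 1L), "+") + 1L
    m <- matrix(sv[im], n, L)
    isC <- m == "C"

    protected <- matrix(FALSE, n, L)
    meth_states <- rep("", n)
    sites <- if (is.null(plan) || !nrow(plan)) NULL else
      plan[plan$transcript == id, , drop = FALSE]
    if (!is.null(sites) && nrow(sites)) {
      for (si in seq_len(nrow(sites))) {
        stoich <- sites$stoichiometry[si]
        if (genotype == "noNSUN" && sites$nsun_dependent[si]) stoich <- 0
        col <- sites$pos[si] - starts + 1L
        cov <- which(col >= 1L & col <= L)
        if (!length(cov)) next
        meth <- stats::runif(length(cov)) < stoich
        protected[cbind(cov, col[cov])] <- meth
        tag <- paste0(sites$pos[si], ":", as.integer(meth))
        meth_states[cov] <- ifelse(meth_states[cov] == "", tag,
                                   paste(meth_states[cov], tag, sep = ";"))
      }
    }

    convert <- isC & !protected &
      matrix(stats::runif(n * L) < d, n, L)
    m[convert] <- "T"

    if (e > 0) {
      err <- matrix(stats::runif(n * L) < e, n, L)
      pos <- which(err)
      if (length(pos)) {
        curb <- m[pos]
        newb <- character(length(pos))
        for (b in c("A", "C", "G", "T")) {
          sb <- curb == b
          if (any(sb)) newb[sb] <- sample(others[[b]], sum(sb), replace = TRUE)
        }
        m[pos] <- newb
      }
    }

    reads <- do.call(paste0, lapply(seq_len(L), function(j) m[, j]))
    ids <- sprintf("bs_%s_s%d_%07d", genotype, stream, counter + seq_len(n))
    counter <- counter + n
    names(reads) <- ids
    all_reads[[t]] <- reads
    all_prov[[t]] <- data.frame(read_id = ids, transcript = id,
                                start = starts, genotype = genotype,
                                meth_states = meth_states,
                                stringsAsFactors = FALSE)
  }
  reads <- unlist(all_reads)
  if (is.null(reads)) reads <- character(0)
  prov <- if (counter) do.call(rbind, all_prov[!vapply(all_prov, is.null,
                                                       logical(1))]) else
    data.frame(read_id = character(0), transcript = character(0),
               start = integer(0), genotype = character(0),
               meth_states = character(0))
  rownames(prov) <- NULL
  list(reads = reads, provenance = prov)
}
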