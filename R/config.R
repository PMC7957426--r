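#' Genetic code tables used throughout the package
#'
#' `SENSE_CODONS` holds the 61 sense codons of the standard genetic code in
#' alphabetical order; `STOP_CODONS` the three stop triplets. All codon-level
#' results (occupancy tables, enrichment sets) are keyed on `SENSE_CODONS`.
#'
#' @format Character vectors of codon strings over \{A,C,G,T\}.
#' @export
SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sort(setdiff(all64, c("TAA", "TAG", "TGA")))
}

#' @rdname SENSE_CODONS
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Derive a reproducible per-sample RNG seed from a master seed
#'
#' One master seed drives a whole simulated experiment; each sample (genotype
#' x condition x replicate x assay) draws from its own stream identified by an
#' integer offset. Streams are derived with a fixed integer mix so that adding
#' a sample (a new offset) never perturbs the reads of an existing one.
#'
#' @param seed master seed (integer-valued scalar).
#' @param stream non-negative integer stream offset.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, stream >= 0)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; products stay exact in doubles
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 16807) %% m
  s <- (s + as.numeric(stream) * 127773 + 1) %% m
  as.integer(if (s == 0) 1 else s)
}

# Fixed stream offsets per assay; replicate/genotype/condition indices are
# added on top. Documented here so users can reproduce any single sample.
.STREAMS <- list(reference = 1L, plan = 2L, bs = 100L, ribo = 500L, rna = 700L,
                 report = 900L)

#' Stream offset for one simulated sample
#'
#' @param assay one of "bs", "ribo", "rna".
#' @param genotype "WT" or "noNSUN".
#' @param condition "control" or "heat" (ignored for "bs").
#' @param replicate replicate number (1-based).
#' @return Integer stream offset for [derive_seed()].
#' @export
sample_stream <- function(assay = c("bs", "ribo", "rna"),
                          genotype = c("WT", "noNSUN"),
                          condition = c("control", "heat"),
                          replicate = 1L) {
  assay <- match.arg(assay)
  genotype <- match.arg(genotype)
  condition <- match.arg(condition)
  g <- if (genotype == "WT") 0L else 1L
  cc <- if (condition == "control") 0L else 1L
  base <- .STREAMS[[assay]]
  as.integer(base + 40L * g + 20L * cc + (replicate - 1L))
}

#' Default codon dwell-time multipliers
#'
#' The default planted effect mirrors the study design this generator
#' emulates: loss of wobble m5C on the UUG-decoding tRNA slows UUG (TTG on the
#' coding strand) decoding in the null genotype under heat stress, modelled as
#' a 2.5-fold dwell-time increase.
#'
#' @return data.frame with columns genotype, condition, codon, multiplier.
#' @export
default_dwell_multipliers <- function() {
  data.frame(genotype = "noNSUN", condition = "heat",
             codon = "TTG", multiplier = 2.5,
             stringsAsFactors = FALSE)
}

#' Build and validate a simulation configuration
#'
#' Parameterizes the synthetic two-genotype experiment: reference composition,
#' bisulfite chemistry, sequencing noise, footprint geometry and planted
#' codon-level translation effects. Defaults describe the emulated study:
#' a wild-type and a methyltransferase-null ("noNSUN") genotype, ~50x
#' bisulfite coverage, 99% deamination efficiency, 26-32 nt footprints with a
#' 12-nt P-site offset upstream, and a 2.5-fold UUG dwell increase in the null
#' genotype under heat.
#'
#' @param seed master RNG seed (required; every downstream stream derives
#'   from it via [derive_seed()]).
#' @param n_mrna,cds_len_range number of mRNAs and CDS length range in codons
#'   (start and stop included). CDSs shorter than 12 codons are rejected:
#'   the first-10-codon exclusion of the profiling analysis would empty them.
#' @param utr5_len,utr3_len UTR lengths in nt flanking each CDS.
#' @param n_rich_mrna,rich_codon,rich_codon_prop number of mRNAs deliberately
#'   enriched in a focal codon, the codon, and its target per-gene proportion.
#' @param n_trna,trna_len tRNA count and body length (nt) before the 3' CCA.
#' @param n_rrna,rrna_len rRNA count and length (nt).
#' @param gc_content GC fraction of untranslated sequence.
#' @param deamination_rate probability an unmethylated C reads as T after
#'   bisulfite conversion; must exceed 0.5 (bisulfite regime).
#' @param seq_error_rate per-base uniform substitution error probability,
#'   applied after conversion.
#' @param bs_read_len,bs_depth bisulfite fragment length (nt) and mean
#'   per-transcript coverage.
#' @param rpf_len_dist named probability vector over footprint lengths 26-32.
#' @param frame_noise probability a footprint 5' end is jittered off-frame.
#' @param ribo_depth total footprints per ribosome-profiling sample.
#' @param rna_depth expected total RNA-seq counts per sample.
#' @param expression_sdlog sdlog of the lognormal mRNA abundance distribution.
#' @param expression_levels optional explicit named relative-abundance vector
#'   for mRNAs; overrides the lognormal draw.
#' @param dwell_multipliers data.frame(genotype, condition, codon, multiplier)
#'   of relative codon dwell times; all multipliers must be > 0.
#' @param dwell_cv biological replicate variability of decoding speed:
#'   every sample multiplies each codon's dwell by an independent
#'   lognormal(0, `dwell_cv`) factor. Set to 0 for a strictly uniform-dwell
#'   simulation.
#' @param stall_te_factor ribosome-loading multiplier applied to genes at
#'   least `enrich_factor`-fold enriched in a dwell-elevated codon under the
#'   matching genotype/condition; models the reduced translational output of
#'   stall-prone transcripts.
#' @param enrich_factor fold-enrichment defining a codon-rich gene.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(seed,
                              n_mrna = 80L,
                              cds_len_range = c(150L, 300L),
                              utr5_len = 30L,
                              utr3_len = 30L,
                              n_rich_mrna = 6L,
                              rich_codon = "TTG",
                              rich_codon_prop = 0.10,
                              n_trna = 20L,
                              trna_len = 72L,
                              n_rrna = 4L,
                              rrna_len = 500L,
                              gc_content = 0.42,
                              deamination_rate = 0.99,
                              seq_error_rate = 0.001,
                              bs_read_len = 75L,
                              bs_depth = 50,
                              rpf_len_dist = c("26" = 0.05, "27" = 0.10,
                                               "28" = 0.30, "29" = 0.30,
                                               "30" = 0.15, "31" = 0.05,
                                               "32" = 0.05),
                              frame_noise = 0.05,
                              ribo_depth = 120000L,
                              rna_depth = 150000L,
                              expression_sdlog = 0.75,
                              expression_levels = NULL,
                              dwell_multipliers = default_dwell_multipliers(),
                              dwell_cv = 0.05,
                              stall_te_factor = 0.5,
                              enrich_factor = 3) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required; the generator never uses a silent default")
  }
  cfg <- list(seed = seed, n_mrna = as.integer(n_mrna),
              cds_len_range = as.integer(cds_len_range),
              utr5_len = as.integer(utr5_len), utr3_len = as.integer(utr3_len),
              n_rich_mrna = as.integer(n_rich_mrna), rich_codon = rich_codon,
              rich_codon_prop = rich_codon_prop,
              n_trna = as.integer(n_trna), trna_len = as.integer(trna_len),
              n_rrna = as.integer(n_rrna), rrna_len = as.integer(rrna_len),
              gc_content = gc_content, deamination_rate = deamination_rate,
              seq_error_rate = seq_error_rate,
              bs_read_len = as.integer(bs_read_len), bs_depth = bs_depth,
              rpf_len_dist = rpf_len_dist, frame_noise = frame_noise,
              ribo_depth = as.integer(ribo_depth),
              rna_depth = as.integer(rna_depth),
              expression_sdlog = expression_sdlog,
              expression_levels = expression_levels,
              dwell_multipliers = dwell_multipliers,
              dwell_cv = dwell_cv,
              stall_te_factor = stall_te_factor,
              enrich_factor = enrich_factor)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  prob_in_01 <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)
  if (!prob_in_01(cfg$gc_content) || !prob_in_01(cfg$deamination_rate) ||
      !prob_in_01(cfg$seq_error_rate) || !prob_in_01(cfg$frame_noise) ||
      !prob_in_01(cfg$rich_codon_prop)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$deamination_rate <= 0.5) {
    stop("deamination_rate must exceed 0.5 (bisulfite conversion regime)")
  }
  if (abs(sum(cfg$rpf_len_dist) - 1) > 1e-8) {
    stop("rpf_len_dist must sum to 1")
  }
  lens <- as.integer(names(cfg$rpf_len_dist))
  if (anyNA(lens) || any(lens < 26L | lens > 32L)) {
    stop("rpf_len_dist lengths must be named 26..32")
  }
  if (length(cfg$cds_len_range) != 2L || any(cfg$cds_len_range < 12L)) {
    stop("cds_len_range must span at least 12 codons: shorter genes would be ",
         "emptied by the first-10-codon exclusion")
  }
  if (cfg$cds_len_range[1] > cfg$cds_len_range[2]) {
    stop("cds_len_range must be non-decreasing")
  }
  if (!cfg$rich_codon %in% SENSE_CODONS) {
    stop("rich_codon must be a sense codon")
  }
  if (cfg$n_rich_mrna > cfg$n_mrna) stop("n_rich_mrna cannot exceed n_mrna")
  if (!is.numeric(cfg$dwell_cv) || cfg$dwell_cv < 0) {
    stop("dwell_cv must be a non-negative number")
  }
  dm <- cfg$dwell_multipliers
  if (!is.null(dm) && nrow(dm)) {
    stopifnot(all(c("genotype", "condition", "codon", "multiplier") %in%
                    names(dm)))
    if (any(dm$multiplier <= 0)) stop("dwell multipliers must be > 0")
    if (!all(dm$codon %in% SENSE_CODONS)) {
      stop("dwell multipliers must address sense codons")
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  reference: ", x$n_mrna, " mRNA (", x$cds_len_range[1], "-",
      x$cds_len_range[2], " codons, ", x$n_rich_mrna, " ", x$rich_codon,
      "-rich), ", x$n_trna, " tRNA, ", x$n_rrna, " rRNA\n", sep = "")
  cat("  bisulfite: deamination ", x$deamination_rate, ", depth ", x$bs_depth,
      "x, read ", x$bs_read_len, " nt\n", sep = "")
  cat("  profiling: ", x$ribo_depth, " footprints, frame noise ",
      x$frame_noise, "\n", sep = "")
  nd <- nrow(x$dwell_multipliers)
  if (nd) {
    cat("  planted dwell effects:", nd, "codon multiplier(s)\n")
  }
  invisible(x)
}
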