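# Shared fixtures, memoized across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

# Seed used by the acceptance suite's benchmark runs.
ACCEPT_SEED <- 101

# Small configuration for fast unit tests.
tiny_config <- function(seed = 5, ...) {
  args <- list(seed = seed, n_mrna = 12L, cds_len_range = c(60L, 100L),
               n_rich_mrna = 2L, n_trna = 8L, n_rrna = 2L,
               rrna_len = 300L, bs_depth = 30, ribo_depth = 20000L,
               rna_depth = 30000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

tiny_ref <- function() fixture("tiny_ref", function() {
  make_reference(tiny_config())
})

tiny_plan <- function() fixture("tiny_plan", function() {
  plant_methylation(tiny_ref(), trna_sites = 6L, rrna_sites = 2L,
                    mrna_sites = 3L, artifact_sites = 4L)
})

# Minimal hand-built RefSet for controlled occupancy/profile tests.
# seqs: named character vector of mRNA sequences; cds interval spans the
# whole sequence unless utr5/utr3 given.
toy_ref <- function(seqs, utr5 = 0L, utr3 = 0L) {
  info <- data.frame(
    id = names(seqs), class = "mRNA", gene = names(seqs),
    length = nchar(seqs),
    cds_start = utr5, cds_end = nchar(seqs) - utr3,
    isoacceptor = NA_character_, anticodon = NA_character_,
    expression = 1 / length(seqs), stringsAsFactors = FALSE)
  stopifnot((info$cds_end - info$cds_start) %% 3 == 0)
  structure(list(info = info, seq = seqs,
                 config = tiny_config()), class = "RefSet")
}

# Build a PsiteTable directly from per-(transcript, codon) counts.
toy_psites <- function(ref, transcript, codon, count) {
  cds <- cds_annotation(ref)
  tab <- data.frame(transcript = transcript,
                    gene = cds$gene[match(transcript, cds$transcript)],
                    codon = as.integer(codon), count = as.integer(count),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("PsiteTable", "data.frame"), shift = 12L,
            lengths = 28L, n_in_cds = sum(count), n_offframe = 0L,
            n_first_removed = 0L, cds = cds)
}

# Build a CytosineReport data.frame from vectors.
toy_report <- function(transcript, pos, nonconverted, converted, other = 0L) {
  df <- data.frame(transcript = transcript, pos = as.integer(pos),
                   coverage = nonconverted + converted,
                   nonconverted = as.integer(nonconverted),
                   converted = as.integer(converted),
                   other = as.integer(rep_len(other, length(pos))),
                   stringsAsFactors = FALSE)
  class(df) <- c("CytosineReport", "data.frame")
  df
}
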