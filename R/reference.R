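#' Generate a synthetic transcriptome reference
#'
#' Builds a desk-scale transcriptome emulating the structure of a metazoan
#' RNA reference: mRNAs (UTR + CDS + UTR, one transcript per gene), cytoplasmic
#' tRNAs ending in CCA, one mitochondrial tRNA-Met, and nuclear plus
#' mitochondrial rRNAs. Sense codons of each CDS are sampled uniformly over
#' the 61-codon table so every codon carries comparable statistical power in
#' downstream occupancy analyses; a configurable subset of mRNAs is enriched
#' in a focal codon (default TTG) to provide stall-prone transcripts.
#'
#' Structural guarantees used by downstream stages:
#' * every CDS starts with ATG, ends with a stop, and has no internal stop;
#' * every tRNA ends in CCA;
#' * tRNA positions 48-50 (1-based) carry C (canonical variable-loop targets);
#' * exactly one tRNA (Leu-CAA) carries a C at the wobble position 34
#'   (0-based 33); all other tRNAs carry a non-C base there.
#'
#' @param config a [simulation_config()] object.
#' @return An object of class `"RefSet"`: a list with `info` (data.frame of
#'   id, class, gene, length, cds_start, cds_end (0-based half-open),
#'   isoacceptor, anticodon, expression) and `seq` (named character vector).
#' @export
make_reference <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, .STREAMS$reference))
  gc <- config$gc_content
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rand_bases <- function(n) {
    if (n <= 0) return(character(0))
    sample(names(base_probs), n, replace = TRUE, prob = base_probs)
  }

  info <- list()
  seqs <- character(0)

  ## mRNAs ------------------------------------------------------------------
  if (config$n_mrna > 0) {
    u61 <- 1 / length(SENSE_CODONS)
    repl_prob <- 0
    if (config$n_rich_mrna > 0 && config$rich_codon_prop > u61) {
      repl_prob <- (config$rich_codon_prop - u61) / (1 - u61)
    }
    for (i in seq_len(config$n_mrna)) {
      ncod <- sample(seq(config$cds_len_range[1], config$cds_len_range[2]), 1)
      internal <- sample(SENSE_CODONS, ncod - 2L, replace = TRUE)
      if (i <= config$n_rich_mrna && repl_prob > 0) {
        hit <- stats::runif(length(internal)) < repl_prob
        internal[hit] <- config$rich_codon
      }
      cds <- c("ATG", internal, sample(STOP_CODONS, 1))
      utr5 <- paste(rand_bases(config$utr5_len), collapse = "")
      utr3 <- paste(rand_bases(config$utr3_len), collapse = "")
      seq <- paste0(utr5, paste(cds, collapse = ""), utr3)
      id <- sprintf("mRNA_%03d", i)
      info[[length(info) + 1L]] <- data.frame(
        id = id, class = "mRNA", gene = sprintf("gene_%03d", i),
        length = nchar(seq),
        cds_start = config$utr5_len, cds_end = config$utr5_len + 3L * ncod,
        isoacceptor = NA_character_, anticodon = NA_character_,
        expression = NA_real_, stringsAsFactors = FALSE)
      seqs[id] <- seq
    }
  }

  ## tRNAs ------------------------------------------------------------------
  # Roster of isoacceptor labels; the first entry is the obligate wobble-site
  # carrier (Leu-CAA decodes UUG), the second the mitochondrial tRNA-Met.
  roster <- data.frame(
    aa = c("Leu", "Met", "Pro", "Pro", "Leu", "Leu", "Gly", "Ala", "Glu",
           "Lys", "Arg", "Ser", "Ser", "Val", "Thr", "Ile", "Phe", "Asp",
           "Asn", "His", "Gln", "Tyr", "Cys", "Trp"),
    anticodon = c("CAA", "CAT", "AGG", "TGG", "AAG", "TAG", "GCC", "AGC",
                  "TTC", "TTT", "ACG", "AGA", "GCT", "AAC", "AGT", "AAT",
                  "GAA", "GTC", "GTT", "GTG", "TTG", "GTA", "GCA", "CCA"),
    stringsAsFactors = FALSE)
  if (config$n_trna > 0) {
    n <- config$n_trna
    picks <- roster[((seq_len(n) - 1L) %% nrow(roster)) + 1L, ]
    dup <- stats::ave(seq_len(n), paste(picks$aa, picks$anticodon),
                      FUN = seq_along)
    for (i in seq_len(n)) {
      body <- rand_bases(config$trna_len)
      vl <- 48:50 # 1-based variable-loop positions, canonical m5C targets
      body[vl[vl <= length(body)]] <- "C"
      if (34 <= length(body)) {
        body[34] <- if (i == 1L) "C" else sample(c("A", "G", "T"), 1)
      }
      seq <- append_cca(paste(body, collapse = ""))
      cls <- if (i == 2L) "mt-tRNA" else "tRNA"
      id <- sprintf("%s-%s-%s-%d", cls, picks$aa[i], picks$anticodon[i],
                    dup[i])
      info[[length(info) + 1L]] <- data.frame(
        id = id, class = cls, gene = id, length = nchar(seq),
        cds_start = NA_integer_, cds_end = NA_integer_,
        isoacceptor = picks$aa[i], anticodon = picks$anticodon[i],
        expression = NA_real_, stringsAsFactors = FALSE)
      seqs[id] <- seq
    }
  }

  ## rRNAs ------------------------------------------------------------------
  if (config$n_rrna > 0) {
    for (i in seq_len(config$n_rrna)) {
      cls <- if (i %% 2L == 0L) "mt-rRNA" else "rRNA"
      id <- sprintf("%s_%02d", cls, i)
      seq <- paste(rand_bases(config$rrna_len), collapse = "")
      info[[length(info) + 1L]] <- data.frame(
        id = id, class = cls, gene = id, length = nchar(seq),
        cds_start = NA_integer_, cds_end = NA_integer_,
        isoacceptor = NA_character_, anticodon = NA_character_,
        expression = NA_real_, stringsAsFactors = FALSE)
      seqs[id] <- seq
    }
  }

  info <- if (length(info)) do.call(rbind, info) else
    data.frame(id = character(0), class = character(0), gene = character(0),
               length = integer(0), cds_start = integer(0),
               cds_end = integer(0), isoacceptor = character(0),
               anticodon = character(0), expression = numeric(0))
  stopifnot(!anyDuplicated(info$id))

  ## mRNA expression levels -------------------------------------------------
  is_m <- info$class == "mRNA"
  if (any(is_m)) {
    if (!is.null(config$expression_levels)) {
      expr <- config$expression_levels[info$id[is_m]]
      if (anyNA(expr)) stop("expression_levels must name every mRNA")
    } else {
      expr <- stats::rlnorm(sum(is_m), meanlog = 0,
                            sdlog = config$expression_sdlog)
    }
    info$expression[is_m] <- expr / sum(expr)
  }

  structure(list(info = info, seq = seqs, config = config), class = "RefSet")
}

#' @export
print.RefSet <- function(x, ...) {
  cat("RefSet:", nrow(x$info), "transcripts\n")
  print(table(x$info$class))
  invisible(x)
}

#' Extract the CDS annotation table of a reference set
#'
#' @param refs a `RefSet`.
#' @return data.frame(transcript, cds_start, cds_end, gene, n_codons) with
#'   0-based half-open CDS coordinates; one transcript per gene.
#' @export
cds_annotation <- function(refs) {
  info <- refs$info
  m <- info[info$class == "mRNA", , drop = FALSE]
  data.frame(transcript = m$id, cds_start = m$cds_start, cds_end = m$cds_end,
             gene = m$gene, n_codons = (m$cds_end - m$cds_start) %/% 3L,
             stringsAsFactors = FALSE)
}

# Split CDS of one transcript into its codon vector.
cds_codons <- function(refs, transcript) {
  info <- refs$info[refs$info$id == transcript, ]
  if (nrow(info) != 1L || info$class != "mRNA") {
    stop("unknown mRNA transcript: ", transcript)
  }
  cds <- substr(refs$seq[[transcript]], info$cds_start + 1L, info$cds_end)
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

#' Plant ground-truth methylation sites into a reference
#'
#' Chooses cytosine positions and per-site stoichiometries emulating the
#' m5C landscape the generator targets: high-stoichiometry tRNA sites in the
#' variable loop (positions 48-50), exactly one wobble-position site (C34 of
#' tRNA Leu-CAA, 0-based position 33), rRNA sites, rare low-stoichiometry mRNA
#' sites, and methyltransferase-independent "artifact" sites that resist
#' conversion identically in both genotypes.
#'
#' Sites are placed at least `margin` nt from transcript ends (default: the
#' bisulfite read length) so that uniform fragment sampling gives them full
#' coverage; positions inside the terminal coverage ramp would mostly be
#' removed by the coverage filter anyway.
#'
#' @param ref a `RefSet` from [make_reference()].
#' @param trna_sites,trna_stoich count and stoichiometry range for
#'   variable-loop tRNA sites.
#' @param wobble_sites 0 or 1: whether to plant the single wobble-34 site.
#' @param rrna_sites,rrna_stoich count and range for rRNA sites.
#' @param mrna_sites,mrna_stoich count and range for mRNA sites.
#' @param artifact_sites,artifact_stoich count and range for
#'   genotype-independent conversion-resistant sites (any class).
#' @param margin minimum distance (nt) from transcript ends; `NULL` uses the
#'   configured bisulfite read length.
#' @param seed RNG seed; defaults to the plan stream of the reference's
#'   master seed.
#' @return data.frame(transcript, pos, stoichiometry, nsun_dependent, type)
#'   with 0-based positions; class `"MethylationPlan"`.
#' @export
plant_methylation <- function(ref,
                              trna_sites = 20L,
                              trna_stoich = c(0.5, 1.0),
                              wobble_sites = 1L,
                              rrna_sites = 4L,
                              rrna_stoich = c(0.8, 1.0),
                              mrna_sites = 5L,
                              mrna_stoich = c(0.05, 0.3),
                              artifact_sites = 10L,
                              artifact_stoich = c(0.1, 0.5),
                              margin = NULL,
                              seed = NULL) {
  stopifnot(inherits(ref, "RefSet"))
  if (is.null(seed)) seed <- derive_seed(ref$config$seed, .STREAMS$plan)
  set.seed(seed)
  if (is.null(margin)) margin <- ref$config$bs_read_len
  info <- ref$info
  used <- character(0) # "transcript:pos" keys already planted
  rows <- list()

  draw_stoich <- function(n, range) stats::runif(n, range[1], range[2])

  c_positions <- function(id, lo = 0L, hi = NULL) {
    s <- ref$seq[[id]]
    p <- which(strsplit(s, "")[[1]] == "C") - 1L
    len <- nchar(s)
    m <- min(margin, floor((len - 1) / 2))
    if (is.null(hi)) hi <- len - 1L - m
    p[p >= max(lo, m) & p <= hi]
  }

  add <- function(df) rows[[length(rows) + 1L]] <<- df

  ## wobble site: forced to position 33 of the unique C34-bearing tRNA
  trna_ids <- info$id[info$class %in% c("tRNA", "mt-tRNA")]
  if (wobble_sites > 0L) {
    if (wobble_sites > 1L) stop("at most one wobble site can be planted")
    has_c34 <- trna_ids[vapply(trna_ids, function(id)
      substr(ref$seq[[id]], 34, 34) == "C", logical(1))]
    if (length(has_c34) != 1L) {
      stop("reference must carry exactly one tRNA with C at position 34")
    }
    add(data.frame(transcript = has_c34, pos = 33L,
                   stoichiometry = draw_stoich(1, trna_stoich),
                   nsun_dependent = TRUE, type = "wobble34",
                   stringsAsFactors = FALSE))
    used <- c(used, paste0(has_c34, ":", 33L))
  }

  ## variable-loop tRNA sites (1-based 48-50 -> 0-based 47-49)
  if (trna_sites > 0L) {
    pool <- do.call(rbind, lapply(trna_ids, function(id) {
      p <- which(strsplit(ref$seq[[id]], "")[[1]] == "C") - 1L
      p <- p[p %in% 47:49]
      if (!length(p)) return(NULL)
      data.frame(transcript = id, pos = p, stringsAsFactors = FALSE)
    }))
    if (is.null(pool) || nrow(pool) < trna_sites) {
      stop("tRNA class lacks enough variable-loop C positions (have ",
           if (is.null(pool)) 0L else nrow(pool), ", need ", trna_sites, ")")
    }
    sel <- pool[sample.int(nrow(pool), trna_sites), ]
    add(data.frame(transcript = sel$transcript, pos = sel$pos,
                   stoichiometry = draw_stoich(trna_sites, trna_stoich),
                   nsun_dependent = TRUE, type = "variable_loop",
                   stringsAsFactors = FALSE))
    used <- c(used, paste0(sel$transcript, ":", sel$pos))
  }

  ## class-level random sites
  plant_class <- function(classes, n, range, type, dependent) {
    if (n <= 0L) return()
    ids <- info$id[info$class %in% classes]
    pool <- do.call(rbind, lapply(ids, function(id) {
      p <- c_positions(id)
      if (!length(p)) return(NULL)
      data.frame(transcript = id, pos = p, stringsAsFactors = FALSE)
    }))
    if (!is.null(pool)) {
      pool <- pool[!paste0(pool$transcript, ":", pool$pos) %in% used, ,
                   drop = FALSE]
    }
    if (is.null(pool) || nrow(pool) < n) {
      stop("class '", paste(classes, collapse = "/"),
           "' lacks enough C positions (have ",
           if (is.null(pool)) 0L else nrow(pool), ", need ", n, ")")
    }
    sel <- pool[sample.int(nrow(pool), n), ]
    add(data.frame(transcript = sel$transcript, pos = sel$pos,
                   stoichiometry = draw_stoich(n, range),
                   nsun_dependent = dependent, type = type,
                   stringsAsFactors = FALSE))
    used <<- c(used, paste0(sel$transcript, ":", sel$pos))
  }

  plant_class(c("rRNA", "mt-rRNA"), rrna_sites, rrna_stoich, "rrna", TRUE)
  plant_class("mRNA", mrna_sites, mrna_stoich, "mrna", TRUE)
  plant_class(unique(info$class), artifact_sites, artifact_stoich,
              "artifact", FALSE)

  plan <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript = character(0), pos = integer(0),
               stoichiometry = numeric(0), nsun_dependent = logical(0),
               type = character(0), stringsAsFactors = FALSE)
  rownames(plan) <- NULL
  # every planted position must hold a reference C
  ok <- vapply(seq_len(nrow(plan)), function(i)
    substr(ref$seq[[plan$transcript[i]]], plan$pos[i] + 1L,
           plan$pos[i] + 1L) == "C", logical(1))
  stopifnot(all(ok))
  class(plan) <- c("MethylationPlan", "data.frame")
  plan
}
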