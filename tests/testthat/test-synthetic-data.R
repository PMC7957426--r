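test_that("reference generation is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 1)
  r1 <- make_reference(cfg)
  r2 <- make_reference(cfg)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$info, r2$info)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_fasta(r1$seq, f1)
  write_fasta(r2$seq, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("reference respects structural contracts", {
  ref <- tiny_ref()
  info <- ref$info
  # tRNAs end in CCA
  trna <- info$id[info$class %in% c("tRNA", "mt-tRNA")]
  expect_true(all(endsWith(ref$seq[trna], "CCA")))
  # CDS starts ATG, ends with stop, no internal stops (brute-force scan)
  for (tx in info$id[info$class == "mRNA"]) {
    codons <- substring(
      substr(ref$seq[[tx]], info$cds_start[info$id == tx] + 1L,
             info$cds_end[info$id == tx]),
      seq(1, info$cds_end[info$id == tx] - info$cds_start[info$id == tx], 3),
      seq(3, info$cds_end[info$id == tx] - info$cds_start[info$id == tx], 3))
    expect_identical(codons[1], "ATG")
    expect_true(codons[length(codons)] %in% STOP_CODONS)
    expect_equal(sum(codons[-length(codons)] %in% STOP_CODONS), 0)
  }
  # exactly one tRNA carries C at the wobble position 34
  c34 <- vapply(trna, function(id) substr(ref$seq[[id]], 34, 34) == "C",
                logical(1))
  expect_equal(sum(c34), 1)
})

test_that("empty mRNA class and degenerate CDS ranges are handled", {
  ref0 <- make_reference(tiny_config(n_mrna = 0L, n_rich_mrna = 0L))
  expect_true(all(ref0$info$class %in% c("tRNA", "mt-tRNA", "rRNA",
                                         "mt-rRNA")))
  expect_error(simulation_config(seed = 1, cds_len_range = c(8L, 20L)),
               "12 codons")
})

test_that("planted sites sit on reference cytosines with forced wobble", {
  ref <- tiny_ref()
  plan <- tiny_plan()
  for (i in seq_len(nrow(plan))) {
    expect_identical(substr(ref$seq[[plan$transcript[i]]], plan$pos[i] + 1L,
                            plan$pos[i] + 1L), "C")
  }
  wob <- plan[plan$type == "wobble34", ]
  expect_equal(nrow(wob), 1)
  expect_equal(wob$pos, 33L)
  # stoichiometry honoured
  hi <- plant_methylation(ref, trna_sites = 5L, trna_stoich = c(0.9, 1.0),
                          wobble_sites = 0L, rrna_sites = 0L,
                          mrna_sites = 0L, artifact_sites = 0L, seed = 9)
  expect_true(all(hi$stoichiometry >= 0.9))
  # a class without enough cytosines fails loudly
  expect_error(plant_methylation(ref, trna_sites = 500L, seed = 9),
               "lacks enough")
})

test_that("bisulfite conversion follows the per-molecule methylation model", {
  seqs <- c(tx1 = paste0("ATG", strrep("GCAT", 39), "TAA"))
  ref <- toy_ref(seqs)
  # full conversion, no sites: every reference C reads T
  cfg <- tiny_config(seed = 3, deamination_rate = 1.0, seq_error_rate = 0)
  empty_plan <- tiny_plan()[0, ]
  sim <- simulate_bisulfite_reads(ref, empty_plan, "WT", cfg)
  sv <- strsplit(seqs[["tx1"]], "")[[1]]
  for (i in seq_along(sim$reads)) {
    rv <- strsplit(sim$reads[[i]], "")[[1]]
    at_c <- sv[sim$provenance$start[i] + seq_along(rv)] == "C"
    expect_true(all(rv[at_c] == "T"))
  }
  # one fully methylated site is protected in every covering read
  site <- data.frame(transcript = "tx1", pos = 60L, stoichiometry = 1.0,
                     nsun_dependent = TRUE, type = "mrna")
  stopifnot(sv[61] == "C")
  sim2 <- simulate_bisulfite_reads(ref, site, "WT", cfg)
  covering <- sim2$provenance$start <= 60 &
    sim2$provenance$start + nchar(sim2$reads) > 60
  base_at <- substr(sim2$reads[covering],
                    61 - sim2$provenance$start[covering],
                    61 - sim2$provenance$start[covering])
  expect_true(all(base_at == "C"))
  # provenance conservation: one record per read
  expect_equal(nrow(sim2$provenance), length(sim2$reads))
})

test_that("observed non-conversion matches the binomial stoichiometry oracle", {
  seqs <- c(tx1 = paste0("ATG", strrep("GCAT", 39), "TAA"))
  ref <- toy_ref(seqs)
  cfg <- tiny_config(seed = 8, bs_depth = 5000, seq_error_rate = 0)
  site <- data.frame(transcript = "tx1", pos = 60L, stoichiometry = 0.7,
                     nsun_dependent = TRUE, type = "mrna")
  sim <- simulate_bisulfite_reads(ref, site, "WT", cfg)
  covering <- sim$provenance$start <= 60 &
    sim$provenance$start + nchar(sim$reads) > 60
  base_at <- substr(sim$reads[covering],
                    61 - sim$provenance$start[covering],
                    61 - sim$provenance$start[covering])
  n <- length(base_at)
  # non-conversion = methylated + unmethylated that escaped conversion
  p_exp <- 0.7 + 0.3 * (1 - cfg$deamination_rate)
  obs <- mean(base_at == "C")
  expect_lt(abs(obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  # and the null genotype shows background only at this dependent site
  simko <- simulate_bisulfite_reads(ref, site, "noNSUN", cfg)
  covko <- simko$provenance$start <= 60 &
    simko$provenance$start + nchar(simko$reads) > 60
  bko <- substr(simko$reads[covko], 61 - simko$provenance$start[covko],
                61 - simko$provenance$start[covko])
  p_bg <- 1 - cfg$deamination_rate
  expect_lt(abs(mean(bko == "C") - p_bg),
            3 * sqrt(p_bg * (1 - p_bg) / length(bko)) + 1e-9)
})

test_that("genotype-independent artifact sites behave identically", {
  seqs <- c(tx1 = paste0("ATG", strrep("GCAT", 39), "TAA"))
  ref <- toy_ref(seqs)
  cfg <- tiny_config(seed = 12, bs_depth = 3000, seq_error_rate = 0)
  site <- data.frame(transcript = "tx1", pos = 60L, stoichiometry = 0.4,
                     nsun_dependent = FALSE, type = "artifact")
  ratios <- vapply(c("WT", "noNSUN"), function(g) {
    sim <- simulate_bisulfite_reads(ref, site, g, cfg)
    cov <- sim$provenance$start <= 60 &
      sim$provenance$start + nchar(sim$reads) > 60
    b <- substr(sim$reads[cov], 61 - sim$provenance$start[cov],
                61 - sim$provenance$start[cov])
    mean(b == "C")
  }, numeric(1))
  p_exp <- 0.4 + 0.6 * (1 - cfg$deamination_rate)
  n <- 3000 # approximate covering depth; 3-SD band is conservative
  expect_lt(abs(ratios[1] - ratios[2]),
            4 * sqrt(2 * p_exp * (1 - p_exp) / n))
})

test_that("footprints are in frame and follow the codon census", {
  cfg <- tiny_config(seed = 21, frame_noise = 0, seq_error_rate = 0,
                     dwell_cv = 0, n_rich_mrna = 0L,
                     dwell_multipliers = default_dwell_multipliers()[0, ],
                     expression_levels = NULL)
  # equal expression so the P-site census is the plain codon census
  ref0 <- make_reference(cfg)
  m <- ref0$info$id[ref0$info$class == "mRNA"]
  cfg$expression_levels <- setNames(rep(1, length(m)), m)
  ref <- make_reference(cfg)
  sim <- simulate_ribo_and_rna(ref, cfg, "WT", "control")
  cds <- cds_annotation(ref)
  cs <- cds$cds_start[match(sim$provenance$transcript, cds$transcript)]
  expect_true(all((sim$provenance$start - cs + 12L) %% 3L == 0))
  # chi-square against the exact eligible-codon census
  census <- table(unlist(lapply(cds$transcript, function(tx) {
    cv <- cds_codons(ref, tx)
    cv[seq_len(length(cv) - 1L)] # stop codon holds no P-site
  })))
  truth <- table(unlist(lapply(seq_len(nrow(cds)), function(i) {
    cds_codons(ref, cds$transcript[i])[sim$provenance$psite_codon[
      sim$provenance$transcript == cds$transcript[i]] + 1L]
  })))
  codons <- names(census)
  obs <- as.numeric(truth[codons])
  obs[is.na(obs)] <- 0
  p <- suppressWarnings(
    stats::chisq.test(obs, p = as.numeric(census) / sum(census))$p.value)
  expect_gt(p, 1e-4)
  # gene-level neutrality: counts proportional to expression x sense codons
  gene_n <- table(factor(sim$provenance$transcript, levels = cds$transcript))
  p2 <- suppressWarnings(stats::chisq.test(
    as.numeric(gene_n),
    p = (cds$n_codons - 1L) / sum(cds$n_codons - 1L))$p.value)
  expect_gt(p2, 1e-4)
  # frame noise jitters 5' ends off frame at the configured rate
  cfg2 <- tiny_config(seed = 22, frame_noise = 0.2, dwell_cv = 0)
  ref2 <- make_reference(cfg2)
  sim2 <- simulate_ribo_and_rna(ref2, cfg2, "WT", "control")
  cds2 <- cds_annotation(ref2)
  cs2 <- cds2$cds_start[match(sim2$provenance$transcript, cds2$transcript)]
  in_frame <- (sim2$provenance$start - cs2 + 12L) %% 3L == 0
  expect_lt(abs(mean(in_frame) - 0.8),
            4 * sqrt(0.8 * 0.2 / length(in_frame)))
})

test_that("simulation streams are independent and reproducible", {
  ref <- tiny_ref()
  plan <- tiny_plan()
  cfg <- tiny_config()
  a <- simulate_bisulfite_reads(ref, plan, "WT", cfg, stream = 100L)
  b <- simulate_bisulfite_reads(ref, plan, "WT", cfg, stream = 100L)
  expect_identical(a$reads, b$reads)
  c <- simulate_bisulfite_reads(ref, plan, "WT", cfg, stream = 101L)
  expect_false(identical(unname(a$reads), unname(c$reads)))
  expect_error(simulation_config(), "seed")
})
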