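# A controlled mRNA: 40 codons, known composition.
controlled_ref <- function() {
  set.seed(99)
  internal <- sample(SENSE_CODONS, 38, replace = TRUE)
  seqs <- c(g1 = paste0(strrep("A", 30), "ATG",
                        paste(internal, collapse = ""), "TAA",
                        strrep("A", 30)))
  toy_ref(seqs, utr5 = 30L, utr3 = 30L)
}

test_that("periodicity filter retains frame-coherent lengths only", {
  ref <- controlled_ref()
  cds <- cds_annotation(ref)
  # 60 in-frame 28-mers, 30 uniform-frame 31-mers
  aln <- data.frame(
    read_id = sprintf("r%03d", 1:90),
    transcript = "g1",
    start = c(30L + 3L * (0:59 %% 15), 30L + (0:29 %% 3)),
    width = rep(c(28L, 31L), c(60, 30)),
    mismatches = 0L, stringsAsFactors = FALSE)
  out <- periodicity_filter(aln, cds, min_frame_fraction = 0.5)
  expect_equal(out$retained, 28L)
  tab <- out$frame_table
  expect_equal(tab$modal_fraction[tab$length == 28], 1.0)
  expect_lt(tab$modal_fraction[tab$length == 31], 0.5)
  expect_error(periodicity_filter(aln, cds, lengths = 10:15), "20-40")
  none <- aln
  none$start <- 0L # all 5' ends upstream of the CDS
  expect_error(periodicity_filter(none, cds), "no CDS-overlapping")
})

test_that("P-site assignment shifts 12 nt and drops off-frame reads", {
  ref <- controlled_ref()
  cds <- cds_annotation(ref)
  aln <- data.frame(
    read_id = c("a", "b"), transcript = "g1",
    start = c(30L, 31L), # at cds_start, and off-frame by one
    width = 28L, mismatches = 0L, stringsAsFactors = FALSE)
  pst <- assign_psites(aln, cds, shift = 12L)
  expect_equal(pst$codon, 4L) # +12 nt = codon index 4
  expect_equal(attr(pst, "n_offframe"), 1L)
  expect_equal(attr(pst, "n_in_cds"), 2L)
  expect_error(assign_psites(aln, cds, shift = -1), "non-negative")
})

test_that("first-codon exclusion removes exactly the leading codons", {
  ref <- controlled_ref()
  pst <- toy_psites(ref, rep("g1", 12), codon = c(0:9, 15, 20),
                    count = c(rep(2L, 10), 7L, 3L))
  total <- sum(pst$count)
  cut <- drop_first_codons(pst, 10L)
  expect_true(all(cut$codon >= 10))
  expect_equal(attr(cut, "n_first_removed"), 20L)
  expect_equal(sum(cut$count), total - 20L)
  ident <- drop_first_codons(pst, 0L)
  expect_equal(sum(ident$count), total)
  only_head <- toy_psites(ref, rep("g1", 3), codon = 0:2, count = c(1L, 1L, 1L))
  expect_equal(nrow(drop_first_codons(only_head, 10L)), 0)
})

test_that("count conservation holds through the P-site chain", {
  cfg <- tiny_config(seed = 51)
  ref <- make_reference(cfg)
  cds <- cds_annotation(ref)
  sim <- simulate_ribo_and_rna(ref, cfg, "WT", "control")
  aln <- align_unique(sim$rpf_reads, ref, max_mismatch = 1)
  per <- periodicity_filter(aln, cds)
  aln <- aln[aln$width %in% per$retained, , drop = FALSE]
  pst <- drop_first_codons(assign_psites(aln, cds), 10L)
  expect_identical(attr(pst, "n_in_cds"),
                   attr(pst, "n_offframe") + attr(pst, "n_first_removed") +
                     as.integer(sum(pst$count)))
})

test_that("noise-free footprints reproduce the provenance census exactly", {
  cfg <- tiny_config(seed = 52, frame_noise = 0, seq_error_rate = 0)
  ref <- make_reference(cfg)
  cds <- cds_annotation(ref)
  sim <- simulate_ribo_and_rna(ref, cfg, "WT", "control")
  aln <- align_unique(sim$rpf_reads, ref, max_mismatch = 0)
  pst <- assign_psites(aln, cds)
  expect_equal(attr(pst, "n_offframe"), 0L)
  census <- stats::aggregate(
    list(count = rep(1L, nrow(sim$provenance))),
    by = list(transcript = sim$provenance$transcript,
              codon = sim$provenance$psite_codon), FUN = sum)
  key <- function(d) paste(d$transcript, d$codon)
  census <- census[order(key(census)), ]
  got <- pst[order(key(pst)), c("transcript", "codon", "count")]
  expect_equal(got$count, census$count)
  expect_equal(key(got), key(census))
  # gene occupancy equals the provenance census per gene
  cut <- drop_first_codons(pst, 10L)
  oracle <- table(factor(
    sim$provenance$transcript[sim$provenance$psite_codon >= 10],
    levels = cds$transcript))
  genes <- cds$gene[match(names(oracle), cds$transcript)]
  expect_equal(unname(gene_occupancy(cut)[genes]), as.numeric(oracle))
})

test_that("codon occupancy equals the brute-force recount oracle", {
  ref <- controlled_ref()
  codons <- cds_codons(ref, "g1")
  ncod <- length(codons)
  set.seed(17)
  elig <- 10:(ncod - 6) # positions whose background stays within sense codons
  counts <- rpois(length(elig), 20)
  pst <- toy_psites(ref, rep("g1", length(elig)), codon = elig,
                    count = counts)
  occ <- codon_occupancy(pst, ref)
  # independent recount: tally P-site and +2/+3/+4 codon identities by hand
  p_oracle <- setNames(numeric(length(SENSE_CODONS)), SENSE_CODONS)
  bg_oracle <- p_oracle
  for (j in seq_along(elig)) {
    i <- elig[j]
    p_oracle[codons[i + 1]] <- p_oracle[codons[i + 1]] + counts[j]
    for (k in 2:4) {
      b <- codons[i + k + 1]
      if (b %in% SENSE_CODONS) bg_oracle[b] <- bg_oracle[b] + counts[j]
    }
  }
  expect_equal(occ$p_count, unname(p_oracle))
  expect_equal(occ$bg_count, unname(bg_oracle))
  expect_equal(occ$occupancy[occ$defined],
               unname(p_oracle / (bg_oracle / 3))[occ$defined])
  # p_count 0 with background > 0 gives occupancy 0; empty background is NA
  zero <- occ$p_count == 0 & occ$bg_count > 0
  expect_true(all(occ$occupancy[zero] == 0))
  expect_true(all(is.na(occ$occupancy[!occ$defined])))
})

test_that("uniform-count occupancy is exactly 1 on a periodic CDS", {
  # CDS = ATG + 60 repeats of a 4-codon block + TAA: each block codon sees
  # the same downstream composition, so uniform counts normalize to 1
  block <- c("GCT", "TGG", "AAA", "CCC")
  seqs <- c(g1 = paste0("ATG", strrep(paste(block, collapse = ""), 60), "TAA"))
  ref <- toy_ref(seqs)
  ncod <- nchar(seqs[[1]]) / 3
  elig <- 10:(ncod - 6)
  pst <- toy_psites(ref, rep("g1", length(elig)), codon = elig,
                    count = rep(10L, length(elig)))
  occ <- codon_occupancy(pst, ref)
  in_block <- occ$codon %in% block
  expect_true(all(abs(occ$occupancy[in_block] - 1) < 0.05))
})

test_that("fold changes behave under identity and genotype swap", {
  ref <- controlled_ref()
  codons <- cds_codons(ref, "g1")
  ncod <- length(codons)
  elig <- 10:(ncod - 6)
  mk <- function(counts) {
    occ <- codon_occupancy(
      toy_psites(ref, rep("g1", length(elig)), elig, counts), ref)
    occ
  }
  set.seed(5)
  a1 <- mk(rpois(length(elig), 50) + 1L)
  a2 <- mk(rpois(length(elig), 50) + 1L)
  ident <- occupancy_fold_change(list(a1, a2), list(a1, a2))
  def <- ident$tested
  expect_true(all(abs(ident$fold_change[def] - 1) < 1e-12))
  expect_equal(sum(ident$significant), 0) # degenerate: flagged, not tested
  b1 <- mk(rpois(length(elig), 80) + 1L)
  b2 <- mk(rpois(length(elig), 80) + 1L)
  fwd <- occupancy_fold_change(list(a1, a2), list(b1, b2))
  rev <- occupancy_fold_change(list(b1, b2), list(a1, a2))
  def <- fwd$tested
  expect_equal(fwd$fold_change[def], 1 / rev$fold_change[def])
  expect_error(occupancy_fold_change(list(a1), list(b1, b2)), "2 replicates")
})

test_that("gene profiles sum to gene occupancy and flag codon positions", {
  ref <- controlled_ref()
  pst <- toy_psites(ref, rep("g1", 3), codon = c(12L, 20L, 20L),
                    count = c(4L, 2L, 1L))
  prof <- profile_gene(pst, ref, "g1", highlight_codon = "TAA")
  expect_equal(sum(prof$counts), unname(gene_occupancy(pst)["g1"]))
  codons <- cds_codons(ref, "g1")
  expect_equal(prof$highlight, which(codons == "TAA") - 1L)
  prof2 <- profile_gene(pst, ref, "g1", highlight_codon = "NNN")
  expect_equal(length(prof2$highlight), 0)
  expect_error(profile_gene(pst, ref, "nope"), "unknown gene")
})

test_that("polysome fraction is the trapezoid area ratio", {
  # rectangular trace: polysomal area 30 of total 100
  tr <- list(x = c(0, 70, 70, 100), absorbance = c(1, 1, 1, 1))
  expect_equal(polysome_fraction(tr, 70), 0.3)
  expect_equal(polysome_fraction(tr, 0), 1.0)
  expect_error(polysome_fraction(tr, -5), "outside")
  expect_error(polysome_fraction(list(x = c(0, 1), absorbance = c(-1, 1)), 0.5),
               "baseline")
  # piecewise-linear trace vs the closed-form integral, to 1e-9
  x <- c(0, 2, 5, 9, 12)
  y <- c(0, 4, 1, 3, 0)
  seg_area <- function(x1, x2, y1, y2) (x2 - x1) * (y1 + y2) / 2
  total <- sum(mapply(seg_area, head(x, -1), x[-1], head(y, -1), y[-1]))
  b <- 6.5 # inside segment [5, 9]: y(b) = 1 + 2 * 1.5 / 4
  yb <- 1 + (3 - 1) * (b - 5) / (9 - 5)
  poly <- seg_area(b, 9, yb, 3) + seg_area(9, 12, 3, 0)
  expect_equal(polysome_fraction(list(x = x, absorbance = y), b),
               poly / total, tolerance = 1e-9)
})
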