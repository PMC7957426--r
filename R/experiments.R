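#' Benchmark experiments with planted ground truth
#'
#' Each function runs one self-contained synthetic benchmark end to end
#' through the package's own pipeline (simulate, align, pile up / assign
#' P-sites, call / quantify) and returns the measured quantities next to the
#' planted truth. They define the package's reference evaluation conditions;
#' the problem sizes are chosen so each benchmark completes in minutes on
#' one CPU (see the methods vignette for the power reasoning behind the
#' defaults).
#'
#' @name benchmarks
NULL

# Shared helper: simulate + align + pile up one bisulfite genotype series.
bs_replicate_reports <- function(ref, plan, genotype, config, n_reps = 3L) {
  lapply(seq_len(n_reps), function(r) {
    sim <- simulate_bisulfite_reads(
      ref, plan, genotype, config,
      stream = sample_stream("bs", genotype, replicate = r))
    aln <- align_unique(sim$reads, ref, max_mismatch = 2L,
                        bisulfite_mode = TRUE)
    pileup_cytosines(aln, sim$reads, ref)
  })
}

# Shared helper: one ribosome-profiling sample through codon occupancy + TE.
ribo_replicate_run <- function(ref, cds, config, genotype, condition, rep,
                               shift = 12L, drop_first = 10L,
                               lengths = 26:32, min_frame_fraction = 0.5,
                               min_rna = 10) {
  s <- simulate_ribo_and_rna(
    ref, config, genotype, condition,
    stream = sample_stream("ribo", genotype, condition, rep))
  aln <- align_unique(s$rpf_reads, ref, max_mismatch = 1L)
  per <- periodicity_filter(aln, cds, lengths, min_frame_fraction)
  aln <- aln[aln$width %in% per$retained, , drop = FALSE]
  pst <- drop_first_codons(assign_psites(aln, cds, shift), drop_first)
  list(occupancy = codon_occupancy(pst, ref),
       te = translation_efficiency(gene_occupancy(pst), s$rna_counts,
                                   min_rna),
       psites = pst, periodicity = per)
}

#' @describeIn benchmarks Knockout-controlled m5C caller recovery: 100
#'   planted methyltransferase-dependent sites (stoichiometry 0.5-1.0,
#'   ~50x coverage, deamination 0.99) plus 20 genotype-independent artifact
#'   sites, 3+3 replicates. Returns recall, artifact mislabelling, the
#'   per-replicate deamination-rate estimates (rRNA-based, planted sites
#'   excluded) and the full call/truth tables.
#' @param seed master seed for the benchmark.
#' @export
bs_calling_benchmark <- function(seed) {
  config <- simulation_config(seed = seed)
  ref <- make_reference(config)
  ref <- merge_bisulfite_identical(ref)
  plan <- plant_methylation(
    ref,
    trna_sites = 20L, trna_stoich = c(0.5, 1.0), wobble_sites = 1L,
    rrna_sites = 4L, rrna_stoich = c(0.5, 1.0),
    mrna_sites = 75L, mrna_stoich = c(0.5, 1.0),
    artifact_sites = 20L, artifact_stoich = c(0.2, 0.8))
  wt <- bs_replicate_reports(ref, plan, "WT", config)
  ko <- bs_replicate_reports(ref, plan, "noNSUN", config)
  calls <- call_sites(wt, ko)
  truth <- recovery_vs_truth(calls, plan)
  rrna_ids <- ref$info$id[ref$info$class %in% c("rRNA", "mt-rRNA")]
  deam <- vapply(c(wt, ko), deamination_rate, numeric(1),
                 exclude = plan, transcripts = rrna_ids)
  list(config = config, ref = ref, plan = plan,
       wt_reports = wt, ko_reports = ko, calls = calls,
       recall = truth$recall,
       artifact_mislabelled = truth$artifact_mislabelled,
       n_planted = sum(plan$nsun_dependent),
       deamination = deam, truth_table = truth$table)
}

#' @describeIn benchmarks Threshold-sweep behaviour on site-free symmetric
#'   noise: no planted sites, both genotypes statistically identical.
#'   Returns the sweep table over thresholds 0.25-0.40.
#' @export
sweep_symmetry_benchmark <- function(seed) {
  config <- simulation_config(seed = seed)
  ref <- make_reference(config)
  ref <- merge_bisulfite_identical(ref)
  plan <- plant_methylation(ref, trna_sites = 0L, wobble_sites = 0L,
                            rrna_sites = 0L, mrna_sites = 0L,
                            artifact_sites = 0L)
  wt <- bs_replicate_reports(ref, plan, "WT", config)
  ko <- bs_replicate_reports(ref, plan, "noNSUN", config)
  sweep <- threshold_sweep(wt, ko, seq(0.25, 0.40, by = 0.05))
  list(config = config, sweep = sweep, wt_reports = wt, ko_reports = ko)
}

#' @describeIn benchmarks Occupancy-normalization neutrality under strictly
#'   uniform dwell (no planted multipliers, no replicate dwell variability):
#'   3+3 replicates at the default footprint depth. Returns per-replicate
#'   occupancy tables, the per-genotype mean occupancies, the fold-change
#'   table and the TE tables (the null material for TE calibration).
#' @export
neutrality_benchmark <- function(seed) {
  config <- simulation_config(
    seed = seed,
    dwell_multipliers = default_dwell_multipliers()[0, ],
    dwell_cv = 0)
  ref <- make_reference(config)
  cds <- cds_annotation(ref)
  runs <- list(WT = list(), noNSUN = list())
  for (g in c("WT", "noNSUN")) {
    runs[[g]] <- lapply(1:3, function(r)
      ribo_replicate_run(ref, cds, config, g, "heat", r))
  }
  occ <- lapply(runs, lapply, `[[`, "occupancy")
  te <- lapply(runs, lapply, `[[`, "te")
  mean_occ <- lapply(occ, function(tabs)
    rowMeans(vapply(tabs, `[[`, numeric(length(SENSE_CODONS)), "occupancy")))
  fc <- occupancy_fold_change(occ$noNSUN, occ$WT)
  list(config = config, ref = ref, occupancy = occ, mean_occupancy = mean_occ,
       fold_change = fc, te = te)
}

#' @describeIn benchmarks Recovery of a planted 2.5-fold UUG (TTG) dwell
#'   increase in the null genotype under heat, 3v3 replicates at default
#'   depth, in a transcriptome without deliberately codon-biased genes and
#'   without the gene-loading effect (the dwell-only generative model).
#'   Returns the fold-change table sorted by FC.
#' @export
dwell_recovery_benchmark <- function(seed) {
  config <- simulation_config(seed = seed, n_rich_mrna = 0L,
                              stall_te_factor = 1)
  ref <- make_reference(config)
  cds <- cds_annotation(ref)
  occ <- list()
  for (g in c("WT", "noNSUN")) {
    occ[[g]] <- lapply(1:3, function(r)
      ribo_replicate_run(ref, cds, config, g, "heat", r)$occupancy)
  }
  fc <- occupancy_fold_change(occ$noNSUN, occ$WT)
  fc <- fc[order(-fc$fold_change), ]
  rownames(fc) <- NULL
  list(config = config, fold_change = fc, occupancy = occ,
       planted_codon = "TTG", planted_multiplier = 2.5)
}

#' @describeIn benchmarks Gene-level translation-efficiency direction under
#'   the full planted model (TTG-rich genes, 2.5-fold dwell, reduced
#'   ribosome loading of rich genes in the null genotype under heat):
#'   Welch's test of the TTG-enriched set's log2 TE between genotypes, and
#'   the same test for a seeded random control set drawn outside the
#'   enriched genes. Returns both tests plus the replicate TE tables.
#' @param control_seed seed for the random control draw.
#' @export
te_direction_benchmark <- function(seed, control_seed = seed + 1) {
  config <- simulation_config(seed = seed)
  ref <- make_reference(config)
  cds <- cds_annotation(ref)
  te <- list()
  for (g in c("WT", "noNSUN")) {
    te[[g]] <- lapply(1:3, function(r)
      ribo_replicate_run(ref, cds, config, g, "heat", r)$te)
  }
  te_wt <- average_te(te$WT)
  te_ko <- average_te(te$noNSUN)
  enr <- codon_enrichment_sets(ref, config$rich_codon,
                               factor = config$enrich_factor)
  set <- enr$gene[enr$enriched]
  enriched_test <- compare_te_conditions(te_ko, te_wt, set)
  pool <- setdiff(intersect(te_wt$gene, te_ko$gene), set)
  set.seed(derive_seed(control_seed, 0L))
  rnd <- sample(pool, length(set))
  random_test <- compare_te_conditions(te_ko, te_wt, rnd)
  list(config = config, ref = ref, enriched_set = set, random_set = rnd,
       enriched_test = enriched_test, random_test = random_test,
       te_wt = te_wt, te_ko = te_ko, te_reps = te)
}

#' @describeIn benchmarks Null calibration of the between-genotype gene-set
#'   TE test: on uniform-dwell (null) TE tables, draws `n_seeds` seeded
#'   random gene sets of size `set_size` and records the Welch rejection
#'   rate at alpha = 0.05 (expected ~5%).
#' @param te_wt,te_ko replicate-averaged null `TETable`s (e.g. from
#'   [neutrality_benchmark()]).
#' @param n_seeds number of random-set draws.
#' @param set_size genes per random set.
#' @export
te_null_calibration <- function(te_wt, te_ko, seed, n_seeds = 20L,
                                set_size = 6L) {
  pool <- intersect(te_wt$gene, te_ko$gene)
  p <- vapply(seq_len(n_seeds), function(i) {
    set.seed(derive_seed(seed, 1000L + i))
    genes <- sample(pool, set_size)
    compare_te_conditions(te_ko, te_wt, genes)$p_value
  }, numeric(1))
  list(p_values = p, rejection_rate = mean(p < 0.05))
}
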