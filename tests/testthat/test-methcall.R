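test_that("deamination rate is converted over converted plus non-converted", {
  rep1 <- toy_report("t1", 0:1, nonconverted = c(5, 5),
                     converted = c(495, 495))
  expect_equal(deamination_rate(rep1), 0.99)
  # excluding the only non-converted site from a perfect-conversion run
  rep2 <- toy_report("t1", 0:1, nonconverted = c(40, 0),
                     converted = c(0, 100))
  excl <- data.frame(transcript = "t1", pos = 0L)
  expect_equal(deamination_rate(rep2, exclude = excl), 1.0)
  expect_error(deamination_rate(rep2[0, ]), "no evaluable")
  expect_error(deamination_rate(rep2, exclude = data.frame(
    transcript = "t1", pos = 0:1)), "no evaluable")
})

make_reps <- function(nonconv_wt, nonconv_ko, cov = 100L, n = 3L) {
  pos <- seq_along(nonconv_wt) - 1L
  wt <- lapply(seq_len(n), function(i)
    toy_report("t1", pos, nonconv_wt, cov - nonconv_wt))
  ko <- lapply(seq_len(n), function(i)
    toy_report("t1", pos, nonconv_ko, cov - nonconv_ko))
  list(wt = wt, ko = ko)
}

test_that("calling rule labels the canonical input patterns", {
  # 94.7% wild-type non-conversion, fully converted in the knockout:
  # the high-stoichiometry mitochondrial tRNA-Met pattern
  r <- make_reps(nonconv_wt = c(95, 35, 5, 0),
                 nonconv_ko = c(0, 33, 4, 0))
  calls <- call_sites(r$wt, r$ko)
  expect_equal(calls$label,
               c("nsun_dependent",             # 0.95 vs 0.00
                 "nsun_independent_artifact",  # 0.35 vs 0.33
                 "unmethylated",               # 0.05 vs 0.04
                 "unmethylated"))
  expect_equal(calls$wt_ratio[1], 0.95)
  # a replicate below the coverage floor marks the site insufficient
  low <- r
  low$wt[[2]]$coverage[1] <- 10L
  low$wt[[2]]$converted[1] <- 10L - low$wt[[2]]$nonconverted[1]
  calls2 <- call_sites(low$wt, low$ko)
  expect_equal(calls2$label[1], "insufficient_coverage")
  expect_error(call_sites(r$wt[1:2], r$ko), "at least 3")
  mismatched <- r$ko
  mismatched[[1]]$pos <- mismatched[[1]]$pos + 1L
  expect_error(call_sites(r$wt, mismatched), "different references")
})

test_that("swapping genotypes swaps exclusivity labels", {
  set.seed(7)
  n <- 60
  wt_nc <- rbinom(n, 100, runif(n, 0, 0.6))
  ko_nc <- rbinom(n, 100, runif(n, 0, 0.6))
  r <- make_reps(wt_nc, ko_nc)
  fwd <- call_sites(r$wt, r$ko)
  rev <- call_sites(r$ko, r$wt)
  params <- calling_params()
  # what is knockout-exclusive in the forward orientation becomes the
  # dependent call after the swap
  ko_exclusive <- fwd$ko_ratio > params$wt_ratio_threshold &
    fwd$wt_ratio <= params$ko_max_ratio
  expect_identical(rev$label == "nsun_dependent", ko_exclusive)
  expect_identical(rev$label == "nsun_independent_artifact",
                   fwd$label == "nsun_independent_artifact")
})

test_that("raising the coverage floor never creates new dependent calls", {
  set.seed(11)
  n <- 50
  cov <- 100L
  r <- make_reps(rbinom(n, cov, 0.2), rbinom(n, cov, 0.05), cov = cov)
  for (mc in c(11L, 50L, 101L)) {
    calls <- call_sites(r$wt, r$ko, calling_params(min_coverage = mc))
    base <- call_sites(r$wt, r$ko)
    gained <- calls$label == "nsun_dependent" & base$label != "nsun_dependent"
    expect_equal(sum(gained), 0)
  }
})

test_that("threshold sweep counts exclusive positions monotonically", {
  r <- make_reps(nonconv_wt = 30, nonconv_ko = 5)
  sw <- threshold_sweep(r$wt, r$ko, c(0.25, 0.40))
  expect_equal(sw$wt_exclusive, c(1, 0))
  expect_equal(sw$ko_exclusive, c(0, 0))
  expect_error(threshold_sweep(r$wt, r$ko, c(0, 0.5)), "inside")
  expect_error(threshold_sweep(r$wt, r$ko, c(0.4, 0.2)), "ascending")
  # monotone non-increasing while counterpart ratios stay below the lowest
  # threshold (the bisulfite calling regime: knockout background ~1%)
  set.seed(3)
  n <- 80
  r2 <- make_reps(rbinom(n, 100, runif(n, 0, 0.8)),
                  rbinom(n, 100, 0.01))
  sw2 <- threshold_sweep(r2$wt, r2$ko, seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(sw2$wt_exclusive) <= 0))
  expect_true(all(diff(sw2$ko_exclusive) <= 0))
})

test_that("isoacceptor summary counts qualifying calls by family", {
  ref <- tiny_ref()
  trna <- ref$info[ref$info$class %in% c("tRNA", "mt-tRNA"), ]
  leu <- trna$id[trna$isoacceptor == "Leu"][1]
  calls <- data.frame(
    transcript = c(rep(leu, 5), leu, trna$id[trna$isoacceptor == "Pro"][1],
                   ref$info$id[ref$info$class == "mRNA"][1]),
    pos = c(10:14, 20L, 47L, 60L),
    wt_ratio = c(rep(0.9, 5), 0.3, 0.8, 0.9),
    ko_ratio = 0.01,
    label = c(rep("nsun_dependent", 7), "nsun_dependent"),
    stringsAsFactors = FALSE)
  iso <- summarize_isoacceptors(calls, ref, min_stoichiometry = 0.5)
  expect_equal(iso$n_sites[iso$isoacceptor == "Leu"], 5) # 0.3 site excluded
  expect_equal(iso$n_sites[iso$isoacceptor == "Pro"], 1)
  # recount oracle: total equals qualifying tRNA calls
  qualifying <- sum(calls$label == "nsun_dependent" & calls$wt_ratio > 0.5 &
                      calls$transcript %in% trna$id)
  expect_equal(sum(iso$n_sites), qualifying)
})

test_that("site-free symmetric noise yields few false dependent calls", {
  cfg <- tiny_config(seed = 44)
  ref <- merge_bisulfite_identical(tiny_ref())
  empty_plan <- tiny_plan()[0, ]
  wt <- lapply(1:3, function(r) {
    sim <- simulate_bisulfite_reads(ref, empty_plan, "WT", cfg,
                                    stream = sample_stream("bs", "WT",
                                                           replicate = r))
    aln <- align_unique(sim$reads, ref, max_mismatch = 2,
                        bisulfite_mode = TRUE)
    pileup_cytosines(aln, sim$reads, ref)
  })
  ko <- lapply(1:3, function(r) {
    sim <- simulate_bisulfite_reads(ref, empty_plan, "noNSUN", cfg,
                                    stream = sample_stream("bs", "noNSUN",
                                                           replicate = r))
    aln <- align_unique(sim$reads, ref, max_mismatch = 2,
                        bisulfite_mode = TRUE)
    pileup_cytosines(aln, sim$reads, ref)
  })
  calls <- call_sites(wt, ko)
  tested <- calls$label != "insufficient_coverage"
  fp <- sum(calls$label == "nsun_dependent") / sum(tested)
  expect_lte(fp, 0.01)
})
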