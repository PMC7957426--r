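#' Calling parameters for knockout-controlled m5C detection
#'
#' Defaults encode the published rule: a cytosine is evaluable when its
#' coverage is higher than 10 in every replicate of both genotypes, and a
#' site is methylated when its bisulfite non-conversion ratio exceeds 0.1 in
#' the wild type while remaining at background in the null genotype. The
#' knockout-exclusivity cutoff reuses the 0.1 threshold symmetrically.
#'
#' @param min_coverage minimum per-replicate coverage ("higher than 10" read
#'   strictly, i.e. >= 11).
#' @param wt_ratio_threshold pooled wild-type non-conversion ratio above which
#'   a site counts as methylated.
#' @param ko_max_ratio maximum pooled null-genotype ratio for a site to count
#'   as knockout-exclusive (methyltransferase-dependent).
#' @param n_replicates_required minimum replicates per genotype.
#' @return list of class `"CallingParams"`.
#' @export
calling_params <- function(min_coverage = 11L, wt_ratio_threshold = 0.1,
                           ko_max_ratio = 0.1, n_replicates_required = 3L) {
  stopifnot(min_coverage >= 1L,
            wt_ratio_threshold > 0, wt_ratio_threshold < 1,
            ko_max_ratio > 0, ko_max_ratio < 1,
            n_replicates_required >= 1L)
  structure(list(min_coverage = as.integer(min_coverage),
                 wt_ratio_threshold = wt_ratio_threshold,
                 ko_max_ratio = ko_max_ratio,
                 n_replicates_required = as.integer(n_replicates_required)),
            class = "CallingParams")
}

# Align a list of CytosineReports on a common (transcript, pos) key; errors
# if replicates were produced over different references.
check_same_reference <- function(reports) {
  keys <- lapply(reports, function(r) paste(r$transcript, r$pos))
  if (!all(vapply(keys[-1], identical, logical(1), keys[[1]]))) {
    stop("replicate reports cover different references")
  }
  keys[[1]]
}

#' Estimate the bisulfite deamination (conversion) rate
#'
#' Converted cytosines divided by the sum of converted and non-converted
#' cytosines, after removing known methylation sites from the calculation
#' (otherwise genuine methylation deflates the efficiency estimate).
#'
#' @param report a `CytosineReport`.
#' @param exclude optional data.frame with `transcript` and `pos` columns of
#'   sites to exclude (e.g. a `MethylationPlan` or known rRNA sites).
#' @param transcripts optional character vector restricting the estimate to
#'   specific transcripts (the published QC uses rRNA only).
#' @return scalar conversion rate in [0, 1].
#' @export
deamination_rate <- function(report, exclude = NULL, transcripts = NULL) {
  r <- report
  if (!is.null(transcripts)) r <- r[r$transcript %in% transcripts, ]
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(r$transcript, r$pos)
    xkey <- paste(exclude$transcript, exclude$pos)
    r <- r[!key %in% xkey, ]
  }
  tot <- sum(r$converted) + sum(r$nonconverted)
  if (!nrow(r) || tot == 0) stop("no evaluable cytosines after exclusion")
  sum(r$converted) / tot
}

#' Call m5C sites from paired wild-type / knockout cytosine reports
#'
#' Implements the knockout-controlled calling rule: positions covered deeply
#' enough in every replicate of both genotypes are labelled
#' `nsun_dependent` when the pooled wild-type non-conversion ratio exceeds
#' the threshold while the pooled knockout ratio stays at background,
#' `nsun_independent_artifact` when both genotypes exceed the threshold,
#' and `unmethylated` otherwise. Pooled ratios are computed on summed counts
#' across replicates; per-replicate ratios are retained for audit.
#'
#' @param wt_reports list of wild-type `CytosineReport`s (>= required reps).
#' @param ko_reports list of knockout `CytosineReport`s.
#' @param params a [calling_params()] object.
#' @return data.frame(transcript, pos, wt_cov, ko_cov, wt_ratio, ko_ratio,
#'   label) plus per-replicate ratio columns; class `"MethylationCalls"`.
#' @export
call_sites <- function(wt_reports, ko_reports, params = calling_params()) {
  stopifnot(inherits(params, "CallingParams"))
  if (length(wt_reports) < params$n_replicates_required ||
      length(ko_reports) < params$n_replicates_required) {
    stop("need at least ", params$n_replicates_required,
         " replicates per genotype")
  }
  check_same_reference(c(wt_reports, ko_reports))
  base <- wt_reports[[1]][c("transcript", "pos")]

  cov_mat <- function(reports, col) {
    do.call(cbind, lapply(reports, function(r) r[[col]]))
  }
  wt_cov <- cov_mat(wt_reports, "coverage")
  ko_cov <- cov_mat(ko_reports, "coverage")
  wt_nc <- cov_mat(wt_reports, "nonconverted")
  ko_nc <- cov_mat(ko_reports, "nonconverted")

  covered <- rowSums(wt_cov >= params$min_coverage) == ncol(wt_cov) &
    rowSums(ko_cov >= params$min_coverage) == ncol(ko_cov)

  wt_pool_cov <- rowSums(wt_cov)
  ko_pool_cov <- rowSums(ko_cov)
  wt_ratio <- ifelse(wt_pool_cov > 0, rowSums(wt_nc) / wt_pool_cov, NA_real_)
  ko_ratio <- ifelse(ko_pool_cov > 0, rowSums(ko_nc) / ko_pool_cov, NA_real_)

  label <- rep("unmethylated", nrow(base))
  label[wt_ratio > params$wt_ratio_threshold &
          ko_ratio > params$wt_ratio_threshold] <- "nsun_independent_artifact"
  label[wt_ratio > params$wt_ratio_threshold &
          ko_ratio <= params$ko_max_ratio] <- "nsun_dependent"
  label[!covered] <- "insufficient_coverage"

  out <- data.frame(base, wt_cov = wt_pool_cov, ko_cov = ko_pool_cov,
                    wt_ratio = wt_ratio, ko_ratio = ko_ratio,
                    label = label, stringsAsFactors = FALSE)
  rmat <- function(nc, cov, prefix) {
    m <- nc / ifelse(cov > 0, cov, NA_real_)
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    m
  }
  out <- cbind(out, rmat(wt_nc, wt_cov, "wt_ratio_rep"),
               rmat(ko_nc, ko_cov, "ko_ratio_rep"))
  class(out) <- c("MethylationCalls", "data.frame")
  out
}

#' Sweep the non-conversion threshold over genotype-exclusive site counts
#'
#' For each threshold t, counts positions whose pooled wild-type ratio is at
#' least t while the knockout ratio stays below t (wild-type exclusive,
#' putative m5C) and the symmetric knockout-exclusive count (an artifact
#' estimate). Both counts are non-increasing in t by construction. Only
#' positions passing the per-replicate coverage filter are considered.
#'
#' @param wt_reports,ko_reports replicate `CytosineReport` lists.
#' @param thresholds ascending numeric vector inside (0, 1).
#' @param params a [calling_params()] (coverage filter only).
#' @return data.frame(threshold, wt_exclusive, ko_exclusive).
#' @export
threshold_sweep <- function(wt_reports, ko_reports,
                            thresholds = seq(0.25, 0.40, by = 0.05),
                            params = calling_params()) {
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be sorted ascending")
  }
  calls <- call_sites(wt_reports, ko_reports, params)
  ok <- calls$label != "insufficient_coverage"
  wt <- calls$wt_ratio[ok]
  ko <- calls$ko_ratio[ok]
  data.frame(
    threshold = thresholds,
    wt_exclusive = vapply(thresholds, function(t)
      sum(wt >= t & ko < t, na.rm = TRUE), numeric(1)),
    ko_exclusive = vapply(thresholds, function(t)
      sum(ko >= t & wt < t, na.rm = TRUE), numeric(1)))
}

#' Summarize methylated tRNA sites by isoacceptor family
#'
#' Counts knockout-dependent calls on tRNAs exceeding a stoichiometry floor
#' (pooled wild-type non-conversion ratio), grouped by amino-acid family
#' parsed from the transcript id (e.g. "tRNA-Leu-CAA-1" -> "Leu").
#'
#' @param calls a `MethylationCalls` table.
#' @param refs the `RefSet` the calls refer to.
#' @param min_stoichiometry stoichiometry floor (default 0.5, "higher than
#'   50%").
#' @return data.frame(isoacceptor, n_sites), descending by count.
#' @export
summarize_isoacceptors <- function(calls, refs, min_stoichiometry = 0.5) {
  info <- refs$info
  trna_ids <- info$id[info$class %in% c("tRNA", "mt-tRNA")]
  sel <- calls$label == "nsun_dependent" &
    calls$wt_ratio > min_stoichiometry &
    calls$transcript %in% trna_ids
  hits <- calls[sel, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(isoacceptor = character(0), n_sites = integer(0)))
  }
  iso <- info$isoacceptor[match(hits$transcript, info$id)]
  parsed <- sub("^(mt-)?tRNA-([A-Za-z]{3})-.*$", "\\2", hits$transcript)
  iso[is.na(iso)] <- parsed[is.na(iso)]
  bad <- is.na(iso) | !grepl("^[A-Za-z]{3}$", iso)
  if (any(bad)) {
    warning(sum(bad), " tRNA id(s) without a parseable isoacceptor; ",
            "grouped as 'unknown'")
    iso[bad] <- "unknown"
  }
  tab <- sort(table(iso), decreasing = TRUE)
  data.frame(isoacceptor = names(tab), n_sites = as.integer(tab),
             stringsAsFactors = FALSE)
}
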