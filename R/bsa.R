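#' Allele-observation ratio for one bulk at one site
#'
#' AO/DP estimates the mutant-allele frequency in a bulk. Zero-depth sites
#' return `NA` (they carry no information and are skipped by smoothing
#' rather than imputed).
#'
#' @param ao Alternate-allele read count (0 <= ao <= dp).
#' @param dp Read depth.
#' @return Numeric fraction, or `NA` where `dp` is 0 or `ao` missing.
#' @export
#' @examples
#' allele_ratio(40, 60) # 0.667
allele_ratio <- function(ao, dp) {
  # zero-depth sites are missing by policy, whatever their AO claims
  bad <- !is.na(ao) & !is.na(dp) &
    ((dp > 0 & (ao > dp | ao < 0)) | dp < 0)
  if (any(bad))
    stop_bsaseq("data-integrity error: AO > DP (or negative) at %d site(s)",
                sum(bad))
  out <- ifelse(!is.na(dp) & dp > 0, ao / dp, NA_real_)
  ifelse(is.na(ao), NA_real_, out)
}

#' Per-site Delta track from bulk counts
#'
#' Delta is the yellow-bulk AO/DP minus the green-bulk AO/DP; it approaches
#' 0.66 over a fully dominant causal locus (the yellow bulk is a 1:2 mix of
#' homozygous mutant and heterozygous plants) and 0 at unlinked sites.
#' Sites with a missing ratio in either bulk carry a missing Delta.
#'
#' @param counts A `bulk_counts` data frame (chrom, pos, AO_yellow,
#'   DP_yellow, AO_green, DP_green).
#' @return A `delta_track` data frame sorted by chromosome and position with
#'   ratio_yellow, ratio_green and delta columns.
#' @export
delta_track <- function(counts) {
  need <- c("chrom", "pos", "AO_yellow", "DP_yellow", "AO_green", "DP_green")
  if (!all(need %in% names(counts)))
    stop_bsaseq("counts must have columns %s", paste(need, collapse = ", "))
  dup <- duplicated(counts[, c("chrom", "pos")])
  if (any(dup))
    stop_bsaseq("data-integrity error: duplicate positions (%d) on a chromosome",
                sum(dup))
  out <- counts[order(counts$chrom, counts$pos), , drop = FALSE]
  out$ratio_yellow <- allele_ratio(out$AO_yellow, out$DP_yellow)
  out$ratio_green <- allele_ratio(out$AO_green, out$DP_green)
  out$delta <- out$ratio_yellow - out$ratio_green
  rownames(out) <- NULL
  class(out) <- c("delta_track", "data.frame")
  out
}

#' Moving-average smoothing of a Delta track
#'
#' Trailing moving average in SNP-index order (default window 4): the
#' smoothed value at SNP i is the mean of the last up-to-`window`
#' non-missing Delta values at or before i on the same chromosome. Missing
#' Deltas are skipped, never zero-filled; output length equals input length.
#' A trailing (rather than centered) window is used because an even window
#' has no well-defined center.
#'
#' @param track A [delta_track()] result.
#' @param window Positive integer window size (default 4).
#' @return The track with a `smoothed_delta` column.
#' @export
smooth_track <- function(track, window = 4L) {
  if (length(window) != 1L || is.na(window) || window < 1)
    stop_bsaseq("config error: window must be >= 1")
  window <- as.integer(window)
  track$smoothed_delta <- NA_real_
  for (ch in unique(track$chrom)) {
    ii <- which(track$chrom == ch)
    d <- track$delta[ii]
    sm <- rep(NA_real_, length(d))
    obs <- numeric(0)
    for (j in seq_along(d)) {
      if (!is.na(d[j])) obs <- c(obs, d[j])
      if (length(obs))
        sm[j] <- mean(obs[max(1L, length(obs) - window + 1L):length(obs)])
    }
    track$smoothed_delta[ii] <- sm
  }
  class(track) <- c("delta_track", "data.frame")
  track
}

#' Call Delta-enriched regions
#'
#' Maximal runs of consecutive SNPs (in SNP order, per chromosome) whose
#' smoothed Delta is at or above the threshold; runs with fewer than
#' `min_snps` SNPs are discarded. The 0.5 default is the conservative limit
#' used to declare a region enriched for the mutant allele.
#'
#' @param track A smoothed [delta_track()].
#' @param threshold Delta threshold (default 0.5).
#' @param min_snps Minimum SNPs per region (default 3, suppressing
#'   single-SNP artifacts).
#' @param use_smoothed Apply the threshold to the smoothed track (default)
#'   or to raw Delta.
#' @return Data frame of regions: chrom, start, end (positions of first and
#'   last member SNP), n_snps, max_delta.
#' @export
call_enriched_regions <- function(track, threshold = 0.5, min_snps = 3L,
                                  use_smoothed = TRUE) {
  val_col <- if (use_smoothed) "smoothed_delta" else "delta"
  if (use_smoothed && is.null(track$smoothed_delta))
    stop_bsaseq("track has no smoothed_delta; call smooth_track() first")
  out <- list()
  for (ch in unique(track$chrom)) {
    tt <- track[track$chrom == ch, , drop = FALSE]
    v <- tt[[val_col]]
    above <- !is.na(v) & v >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_snps)) {
      ii <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = tt$pos[starts[k]], end = tt$pos[ends[k]],
        n_snps = length(ii), max_delta = max(v[ii]))
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      max_delta = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected mutant-allele fraction of a pooled bulk
#'
#' Under equal-DNA pooling and unbiased sampling, the expected AO/DP of a
#' bulk equals the mutant-allele frequency among its members:
#' f_hom_mut + f_het / 2. For the yellow bulk of a dominant F2 (hom-mutant
#' and heterozygous plants in 1:2 proportion) this gives 2/3, i.e. the 0.66
#' expected at the causal SNP; for the green bulk (all homozygous wild
#' type) it gives 0.
#'
#' @param freq_hom_mut,freq_het,freq_hom_wt Genotype-class frequencies;
#'   must be non-negative and sum to 1 (tolerance 1e-9).
#' @return Expected allele fraction in \[0, 1\].
#' @export
#' @examples
#' expected_allele_fraction(1 / 3, 2 / 3, 0) # 0.667
expected_allele_fraction <- function(freq_hom_mut, freq_het, freq_hom_wt) {
  if (any(c(freq_hom_mut, freq_het, freq_hom_wt) < 0))
    stop_bsaseq("input error: genotype frequencies must be >= 0")
  if (abs(freq_hom_mut + freq_het + freq_hom_wt - 1) > 1e-9)
    stop_bsaseq("input error: genotype frequencies must sum to 1")
  freq_hom_mut + freq_het / 2
}

#' Pearson chi-square test of a phenotypic segregation ratio
#'
#' Tests observed yellow/green counts against an expected ratio (default
#' 3:1, the dominant single-locus expectation in an F2).
#'
#' @param n_yellow,n_green Observed counts.
#' @param ratio Length-2 expected ratio (default `c(3, 1)`).
#' @return List with `statistic` (1 df Pearson chi-square) and `p_value`
#'   (upper tail).
#' @export
#' @examples
#' segregation_chi2(75, 25) # perfect 3:1 fit
segregation_chi2 <- function(n_yellow, n_green, ratio = c(3, 1)) {
  n <- n_yellow + n_green
  if (n <= 0) stop_bsaseq("input error: both counts are zero")
  p <- ratio / sum(ratio)
  expd <- n * p
  stat <- sum((c(n_yellow, n_green) - expd)^2 / expd)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}
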