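#' Simulate per-site AO/DP counts for the two bulks
#'
#' Site-level sampling model for pooled sequencing under equal-DNA pooling:
#' at each site the true mutant-allele fraction in a bulk is
#' f = (sum of member allele counts) / (2 x bulk size); the site depth is
#' Poisson(`mean_depth`) and the alternate observation count is
#' Binomial(DP, f(1-e) + (1-f)e) with per-base error rate e. An empty bulk
#' yields missing (NA) AO for that bulk.
#'
#' @param population Population with genotypes.
#' @param bulks List from [build_bulks()].
#' @param sites Data frame (chrom, pos) of sites to emit; default all loci.
#' @param mean_depth,error_rate Coverage model parameters.
#' @param seed Optional seed.
#' @return A `bulk_counts` data frame: chrom, pos, AO_yellow, DP_yellow,
#'   AO_green, DP_green.
#' @export
simulate_bulk_counts <- function(population, bulks, sites = NULL,
                                 mean_depth = population$config$mean_depth,
                                 error_rate = population$config$sequencing_error_rate,
                                 seed = NULL) {
  loci <- population$loci
  if (is.null(sites)) {
    sidx <- seq_len(nrow(loci))
  } else {
    sidx <- match(paste(sites$chrom, sites$pos),
                  paste(loci$chrom, loci$pos))
    if (anyNA(sidx))
      stop_bsaseq("%d requested site(s) are not simulated loci", sum(is.na(sidx)))
  }
  with_seed_or_current(seed, {
    ns <- length(sidx)
    draw_bulk <- function(members) {
      dp <- rpois(ns, mean_depth)
      if (length(members) == 0L)
        return(list(ao = rep(NA_integer_, ns), dp = dp))
      f <- colSums(population$genotypes[members, sidx, drop = FALSE]) /
        (2 * length(members))
      p <- f * (1 - error_rate) + (1 - f) * error_rate
      list(ao = rbinom(ns, dp, p), dp = dp)
    }
    y <- draw_bulk(bulks$yellow)
    g <- draw_bulk(bulks$green)
    out <- data.frame(chrom = loci$chrom[sidx], pos = loci$pos[sidx],
                      AO_yellow = y$ao, DP_yellow = y$dp,
                      AO_green = g$ao, DP_green = g$dp)
    class(out) <- c("bulk_counts", "data.frame")
    out
  })
}

#' Loci segregating in the F2 population
#'
#' Sites at which at least one F2 plant carries a mutant allele. Mutations
#' lost before the F2 produce no alternate reads in the bulks and would not
#' be called as SNPs, so the Delta scan is computed over this set.
#'
#' @param population A `bsa_population`.
#' @return Data frame (chrom, pos) of segregating loci.
#' @export
segregating_sites <- function(population) {
  keep <- colSums(population$genotypes) > 0L
  population$loci[keep, c("chrom", "pos")]
}

#' Simulate variant calls from a flow-sorted chromosome sample
#'
#' Models sequencing of a flow-sorted chromosome fraction from the mutant
#' parent line against the reference genome. Sites on the target chromosome
#' receive depth Poisson(`mean_depth` x purity), contaminant-chromosome
#' sites Poisson(`mean_depth` x (1 - purity)). Emitted records cover the
#' parent's induced mutations (alternate fraction 1/2 for heterozygous, 1
#' for homozygous loci), all varietal sites on the two chromosomes
#' (alternate fraction 1, since the line carries the cultivar allele), and
#' optional clusters of dense spurious EMS-like calls that exercise density
#' masking. Quality is the monotone stand-in QUAL = min(60, 4 x AO);
#' zygosity is called "hom" when AO/DP >= 0.8, else "het". Records with
#' AO = 0 are not emitted (no variant would be called).
#'
#' @param parent_counts Integer vector of mutant-allele counts (0/1/2) per
#'   locus for the sequenced line, aligned with `loci` rows (e.g. the `m4`
#'   field of a population).
#' @param loci Mutation truth table (chrom, pos, ref, alt).
#' @param genome The reference genome (for noise-cluster reference bases).
#' @param config A [sim_config()] (depth, error rate, purity).
#' @param target_chrom,contaminant_chrom Chromosome names for the sorted
#'   target and its contaminant.
#' @param varietal Varietal truth table (chrom, pos, ref, alt) or NULL.
#' @param noise_clusters Number of spurious high-density windows per
#'   chromosome (default 0).
#' @param cluster_snps,cluster_width Size of each spurious cluster.
#' @param purity,seed Overrides.
#' @return List with `variants` (chrom, pos, ref, alt, qual, dp, zygosity)
#'   and `truth` (chrom, pos, class in {mutation, varietal, noise}).
#' @export
simulate_flowsort_variants <- function(parent_counts, loci, genome, config,
                                       target_chrom, contaminant_chrom,
                                       varietal = NULL,
                                       noise_clusters = 0L,
                                       cluster_snps = 30L,
                                       cluster_width = 5000L,
                                       purity = config$flowsort_purity,
                                       seed = NULL) {
  if (purity < 0 || purity > 1)
    stop_bsaseq("config error: purity must lie in [0, 1]")
  chroms <- c(target_chrom, contaminant_chrom)
  with_seed_or_current(seed, {
    rows <- list(); truth <- list()
    emit <- function(chrom, pos, ref, alt, frac, klass) {
      depth_scale <- if (chrom[1] == target_chrom) purity else 1 - purity
      dp <- rpois(length(pos), config$mean_depth * depth_scale)
      e <- config$sequencing_error_rate
      ao <- rbinom(length(pos), dp, frac * (1 - e) + (1 - frac) * e)
      keep <- ao > 0L
      if (!any(keep)) return(invisible(NULL))
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = chrom[keep], pos = pos[keep], ref = ref[keep], alt = alt[keep],
        qual = pmin(60, 4 * ao[keep]), dp = dp[keep],
        zygosity = ifelse(ao[keep] / pmax(dp[keep], 1L) >= 0.8, "hom", "het"))
      truth[[length(truth) + 1L]] <<- data.frame(
        chrom = chrom[keep], pos = pos[keep], class = klass)
      invisible(NULL)
    }
    for (ch in chroms) {
      ii <- which(loci$chrom == ch & parent_counts > 0L)
      if (length(ii))
        emit(rep(ch, length(ii)), loci$pos[ii], loci$ref[ii], loci$alt[ii],
             parent_counts[ii] / 2, "mutation")
      if (!is.null(varietal)) {
        v <- varietal[varietal$chrom == ch, , drop = FALSE]
        if (nrow(v))
          emit(rep(ch, nrow(v)), v$pos, v$ref, v$alt, rep(1, nrow(v)),
               "varietal")
      }
      if (noise_clusters > 0L) {
        len <- as.numeric(config$chromosomes[[ch]])
        for (k in seq_len(noise_clusters)) {
          wstart <- sample.int(max(1, len - cluster_width), 1)
          cand <- sort(sample(seq(wstart, wstart + cluster_width - 1L),
                              min(cluster_snps * 3L, cluster_width)))
          b <- base_at(genome, ch, cand)
          gc <- cand[b %in% c("G", "C")]
          if (length(gc) < 1) next
          cpos <- sort(sample(gc, min(cluster_snps, length(gc))))
          cref <- base_at(genome, ch, cpos)
          emit(rep(ch, length(cpos)), cpos, cref,
               ifelse(cref == "G", "A", "T"), rep(1, length(cpos)), "noise")
        }
      }
    }
    variants <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), qual = numeric(), dp = integer(),
                 zygosity = character())
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(), pos = integer(), class = character())
    ord <- order(match(variants$chrom, chroms), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    truth <- truth[order(match(truth$chrom, chroms), truth$pos), , drop = FALSE]
    rownames(variants) <- rownames(truth) <- NULL
    list(variants = variants, truth = truth)
  })
}
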