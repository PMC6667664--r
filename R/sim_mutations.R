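#' Induce EMS point mutations on a genome
#'
#' EMS alkylates guanine, producing almost exclusively G>A and C>T
#' transitions. The number of mutations per chromosome is Poisson with mean
#' `density` per Mb of sequence; positions are sampled uniformly over G/C
#' reference bases (without duplicates) and the alternate allele is forced
#' by the reference base (G>A, C>T).
#'
#' @param genome A [generate_genome()] result.
#' @param density Mutations per Mb (>= 0).
#' @param seed Optional seed.
#' @return Data frame (chrom, pos, ref, alt, is_causal) sorted by
#'   chromosome then position; `is_causal` is all-`FALSE` (see
#'   [mark_causal()]).
#' @export
induce_ems_mutations <- function(genome, density, seed = NULL) {
  if (density < 0) stop_bsaseq("config error: density must be >= 0")
  with_seed_or_current(seed, {
    out <- list()
    for (chrom in names(genome$sequences)) {
      len <- Biostrings::width(genome$sequences)[names(genome$sequences) == chrom]
      gc <- Biostrings::letterFrequency(genome$sequences[[chrom]],
                                        letters = c("G", "C"))
      if (sum(gc) == 0)
        stop_bsaseq("spectrum error: chromosome %s has no G/C bases to mutate",
                    chrom)
      n <- rpois(1, density * len / 1e6)
      if (n == 0) next
      pos <- integer(0)
      guard <- 0L
      while (length(pos) < n && guard < 1000L) {
        cand <- sample.int(len, min(len, max(4L * n, 100L)), replace = TRUE)
        b <- base_at(genome, chrom, cand)
        pos <- unique(c(pos, cand[b %in% c("G", "C")]))
        guard <- guard + 1L
      }
      if (length(pos) < n)
        stop_bsaseq("spectrum error: could not sample %d G/C positions on %s",
                    n, chrom)
      pos <- sort(pos[seq_len(n)])
      ref <- base_at(genome, chrom, pos)
      out[[chrom]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                                 alt = ifelse(ref == "G", "A", "T"),
                                 is_causal = FALSE)
    }
    if (!length(out))
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        is_causal = logical()))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Mark one mutation as the causal locus
#'
#' @param mutations Data frame from [induce_ems_mutations()].
#' @param chrom Chromosome carrying the causal mutation.
#' @param near Position; the mutation on `chrom` closest to `near` is
#'   flagged. Defaults to the chromosome midpoint of the listed mutations.
#' @return The mutations data frame with exactly one `is_causal = TRUE` row.
#' @export
mark_causal <- function(mutations, chrom, near = NULL) {
  idx <- which(mutations$chrom == chrom)
  if (!length(idx))
    stop_bsaseq("no mutations on chromosome %s to mark as causal", chrom)
  if (is.null(near)) near <- mean(range(mutations$pos[idx]))
  pick <- idx[which.min(abs(mutations$pos[idx] - near))]
  mutations$is_causal <- FALSE
  mutations$is_causal[pick] <- TRUE
  mutations
}
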