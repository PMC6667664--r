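# Fixtures are built in code; no binary data.

make_sim_genome <- function(seqs, genes = NULL, exons = NULL, cds = NULL) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer())
  structure(list(
    sequences = Biostrings::DNAStringSet(seqs),
    genes = genes %||% cbind(empty, strand = character()),
    exons = exons %||% empty,
    cds = cds %||% empty
  ), class = "sim_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 4 kb chromosome with one two-exon gene; known codons are planted at the
# CDS start so effect classes are predictable:
#   cds positions 1-3 "GGA", 4-6 "CTG", 7-9 "TGG".
# Gene (+): utr5 1001-1100, cds1 1101-1400, intron 1401-1600,
# cds2 1601-1900, utr3 1901-2000 (exons 1001-1400 and 1601-2000).
make_effect_genome <- function(seed = 42) {
  s <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), 4000, replace = TRUE), collapse = ""))
  substr(s, 1101, 1109) <- "GGACTGTGG"
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1001L,
                      end = 2000L, strand = "+")
  exons <- data.frame(gene_id = "g1", chrom = "chr1",
                      start = c(1001L, 1601L), end = c(1400L, 2000L))
  cds <- data.frame(gene_id = "g1", chrom = "chr1",
                    start = c(1101L, 1601L), end = c(1400L, 1900L))
  make_sim_genome(c(chr1 = s), genes, exons, cds)
}

# Mirror a genome: reverse-complement every chromosome and flip all
# annotation coordinates/strands. The same biological variant is then
# represented at the mirrored position with complemented alleles.
mirror_genome <- function(genome) {
  lens <- Biostrings::width(genome$sequences)
  names(lens) <- names(genome$sequences)
  seqs <- as.character(Biostrings::reverseComplement(genome$sequences))
  flip <- function(df) {
    if (!nrow(df)) return(df)
    L <- lens[df$chrom]
    ns <- L - df$end + 1L
    ne <- L - df$start + 1L
    df$start <- as.integer(ns); df$end <- as.integer(ne)
    df
  }
  genes <- flip(genome$genes)
  if (nrow(genes)) genes$strand <- ifelse(genome$genes$strand == "+", "-", "+")
  make_sim_genome(seqs, genes, flip(genome$exons), flip(genome$cds))
}

mirror_pos <- function(genome, chrom, pos) {
  L <- Biostrings::width(genome$sequences)[names(genome$sequences) == chrom]
  L - pos + 1L
}

# Build a delta_track-shaped data frame directly from smoothed values.
track_from_smoothed <- function(smoothed, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length(smoothed)),
             pos = seq_along(smoothed) * 1000L,
             delta = smoothed, smoothed_delta = smoothed)
}

# Brute-force trailing-window smoothing oracle.
smooth_oracle <- function(deltas, window) {
  out <- rep(NA_real_, length(deltas))
  for (i in seq_along(deltas)) {
    obs <- deltas[seq_len(i)]
    obs <- obs[!is.na(obs)]
    if (length(obs))
      out[i] <- mean(tail(obs, window))
  }
  out
}

# Brute-force run-enumeration oracle for region calling (single chromosome).
regions_oracle <- function(pos, smoothed, threshold, min_snps) {
  above <- !is.na(smoothed) & smoothed >= threshold
  out <- list()
  i <- 1L
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_snps)
        out[[length(out) + 1L]] <- c(start = pos[i], end = pos[j],
                                     n = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Brute-force fine-mapping oracle: per-marker inconsistency counts and the
# qualifying runs, straight from the rule's definition.
finemap_oracle <- function(phenotype, calls, min_independent) {
  counts <- vapply(seq_len(ncol(calls)), function(j) {
    sum(ifelse(phenotype == "yellow",
               !is.na(calls[, j]) & calls[, j] == "WT",
               !is.na(calls[, j]) & calls[, j] %in% c("HET", "MUT")))
  }, integer(1))
  qualify <- counts < min_independent
  runs <- list()
  i <- 1L
  while (i <= length(qualify)) {
    if (qualify[i]) {
      j <- i
      while (j < length(qualify) && qualify[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  list(counts = counts, runs = runs)
}

# Small F2 helper for tests needing a quick population with one causal locus.
quick_population <- function(seed, f2 = 400L, chrom_len = 1e6,
                             extra_loci = integer(0), penetrance = 1,
                             yellow_n = 75L, green_n = 16L,
                             mean_depth = 100, error_rate = 0) {
  cfg <- sim_config(seed = seed, chromosomes = c(chr1 = chrom_len),
                    f2_size = f2, yellow_bulk_n = yellow_n,
                    green_bulk_n = green_n, mean_depth = mean_depth,
                    sequencing_error_rate = error_rate,
                    penetrance = penetrance)
  pos <- sort(unique(c(round(chrom_len / 2), extra_loci)))
  mut <- data.frame(chrom = "chr1", pos = pos, ref = "G", alt = "A",
                    is_causal = pos == round(chrom_len / 2))
  pop <- propagate_pedigree(mut, cfg, seed = seed)
  assign_phenotypes(pop, penetrance, seed = seed + 1L)
}
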