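#' Generate a random annotated genome
#'
#' Builds uniform-random nucleotide sequences of the configured lengths and
#' places the configured number of non-overlapping gene models on each
#' chromosome. Each gene has 1-3 exons, 5' and 3' UTRs, and a CDS whose
#' length is a multiple of 3; strand is random. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return A `sim_genome`: list with `sequences` (a
#'   [Biostrings::DNAStringSet]), `genes`, `exons` and `cds` data frames
#'   (1-based inclusive coordinates).
#' @export
generate_genome <- function(config, seed = config$seed) {
  with_seed_or_current(seed, {
    seqs <- Biostrings::DNAStringSet(vapply(
      as.numeric(config$chromosomes), random_dna, character(1)))
    names(seqs) <- names(config$chromosomes)
    ann <- list()
    gid <- 0L
    for (chrom in names(config$chromosomes)) {
      n <- config$n_genes_per_chromosome
      if (n > 0) {
        ann[[chrom]] <- place_genes(chrom, config$chromosomes[[chrom]], n,
                                    first_id = gid + 1L)
        gid <- gid + n
      }
    }
    genes <- do.call(rbind, lapply(ann, `[[`, "genes"))
    exons <- do.call(rbind, lapply(ann, `[[`, "exons"))
    cds <- do.call(rbind, lapply(ann, `[[`, "cds"))
    if (is.null(genes)) {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character())
      exons <- cds <- data.frame(gene_id = character(), chrom = character(),
                                 start = integer(), end = integer())
    }
    rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
    structure(list(sequences = seqs, genes = genes, exons = exons, cds = cds),
              class = "sim_genome")
  })
}

# Uniform random DNA of length n, built in 1 Mb chunks to keep paste() calls
# bounded.
random_dna <- function(n) {
  n <- as.numeric(n)
  chunks <- character(0)
  left <- n
  while (left > 0) {
    k <- min(left, 1e6)
    chunks <- c(chunks,
                paste(c("A", "C", "G", "T")[sample.int(4L, k, replace = TRUE)],
                      collapse = ""))
    left <- left - k
  }
  paste(chunks, collapse = "")
}

# Draw one gene structure in transcript coordinates and return its segment
# layout: utr5 | cds/intron alternation | utr3.
draw_gene_structure <- function() {
  utr5 <- sample(60:200, 1)
  utr3 <- sample(60:200, 1)
  n_exon <- sample(1:3, 1)
  cds_total <- 3L * sample(100:400, 1)
  cds_parts <- if (n_exon == 1) cds_total else {
    cut <- sort(sample(seq_len(cds_total - 1), n_exon - 1))
    diff(c(0L, cut, cds_total))
  }
  introns <- if (n_exon > 1) sample(60:300, n_exon - 1, replace = TRUE) else integer(0)
  list(utr5 = utr5, utr3 = utr3, cds_parts = as.integer(cds_parts),
       introns = as.integer(introns))
}

# Place n non-overlapping genes on one chromosome; errors if they cannot fit.
place_genes <- function(chrom, chrom_len, n, first_id) {
  structs <- replicate(n, draw_gene_structure(), simplify = FALSE)
  lens <- vapply(structs, function(s)
    s$utr5 + s$utr3 + sum(s$cds_parts) + sum(s$introns), integer(1))
  # require at least 1 bp between genes and 1 kb free at each chromosome end
  pad <- 1000L
  free <- chrom_len - sum(lens) - (n - 1L) - 2L * pad
  if (free < 0)
    stop_bsaseq("gene placement error: %d genes (total %d bp) do not fit on %s (%d bp)",
                n, sum(lens), chrom, chrom_len)
  gaps <- diff(c(0, sort(runif(n, 0, free)), free))
  starts <- pad + cumsum(gaps[seq_len(n)]) + c(0, cumsum(lens[-n] + 1L))
  starts <- as.integer(floor(starts)) + 1L
  strands <- sample(c("+", "-"), n, replace = TRUE)
  genes <- exons <- cds <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("gene%04d", first_id + i - 1L)
    g <- layout_gene(structs[[i]], starts[i], strands[i])
    genes[[i]] <- data.frame(gene_id = id, chrom = chrom, start = starts[i],
                             end = starts[i] + lens[i] - 1L,
                             strand = strands[i])
    exons[[i]] <- data.frame(gene_id = id, chrom = chrom,
                             start = g$exons$start, end = g$exons$end)
    cds[[i]] <- data.frame(gene_id = id, chrom = chrom,
                           start = g$cds$start, end = g$cds$end)
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons),
       cds = do.call(rbind, cds))
}

# Map a transcript-coordinate structure onto the genome. For "-" strand the
# transcript runs from the genomic end of the gene toward its start.
layout_gene <- function(s, gstart, strand) {
  n_exon <- length(s$cds_parts)
  # transcript segments in order: utr5, (cds_i, intron_i)..., utr3
  seg_len <- integer(0); seg_type <- character(0)
  seg_len <- c(seg_len, s$utr5); seg_type <- c(seg_type, "utr5")
  for (i in seq_len(n_exon)) {
    seg_len <- c(seg_len, s$cds_parts[i]); seg_type <- c(seg_type, "cds")
    if (i < n_exon) { seg_len <- c(seg_len, s$introns[i]); seg_type <- c(seg_type, "intron") }
  }
  seg_len <- c(seg_len, s$utr3); seg_type <- c(seg_type, "utr3")
  tend <- cumsum(seg_len); tstart <- tend - seg_len + 1L
  total <- sum(seg_len)
  if (strand == "+") {
    gs <- gstart + tstart - 1L; ge <- gstart + tend - 1L
  } else {
    gend <- gstart + total - 1L
    gs <- gend - tend + 1L; ge <- gend - tstart + 1L
  }
  segs <- data.frame(type = seg_type, start = pmin(gs, ge), end = pmax(gs, ge))
  cdss <- segs[segs$type == "cds", c("start", "end")]
  # exons = maximal runs of non-intron segments, merged on the genome
  keep <- segs$type != "intron"
  segs <- segs[order(segs$start), ]
  keep <- segs$type != "intron"
  ex <- list(); cur <- NULL
  for (i in seq_len(nrow(segs))) {
    if (!keep[i]) { if (!is.null(cur)) ex[[length(ex) + 1]] <- cur; cur <- NULL; next }
    if (is.null(cur)) cur <- c(segs$start[i], segs$end[i])
    else if (segs$start[i] == cur[2] + 1L) cur[2] <- segs$end[i]
    else { ex[[length(ex) + 1]] <- cur; cur <- c(segs$start[i], segs$end[i]) }
  }
  if (!is.null(cur)) ex[[length(ex) + 1]] <- cur
  exdf <- data.frame(start = vapply(ex, `[`, numeric(1), 1),
                     end = vapply(ex, `[`, numeric(1), 2))
  list(exons = exdf[order(exdf$start), , drop = FALSE],
       cds = cdss[order(cdss$start), , drop = FALSE])
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s), %d gene model(s)\n",
              length(x$sequences), nrow(x$genes)))
  for (i in seq_along(x$sequences))
    cat(sprintf("  %s: %d bp\n", names(x$sequences)[i],
                Biostrings::width(x$sequences)[i]))
  invisible(x)
}

# Bases of chromosome `chrom` at 1-based positions `pos`.
base_at <- function(genome, chrom, pos) {
  seq <- genome$sequences[[chrom]]
  as.character(Biostrings::extractAt(seq, IRanges::IRanges(pos, pos)))
}

#' Fragment a genome into draft-assembly scaffolds with varietal divergence
#'
#' Models the alternate-cultivar draft assembly: each chromosome is cut into
#' scaffolds at random breakpoints (exponential lengths with the configured
#' mean), and cultivar ("varietal") substitutions are injected at the
#' configured per-Mb density. The scaffold-to-chromosome coordinates and all
#' injected SNPs are recorded in truth tables; with zero varietal density
#' every scaffold is an exact substring of its source chromosome.
#'
#' @param genome A [generate_genome()] result.
#' @param config A [sim_config()]; uses `scaffold_mean_length` and
#'   `varietal_snp_density`.
#' @param seed Optional seed override.
#' @return List of class `sim_assembly`: `scaffolds` (DNAStringSet),
#'   `scaffold_map` truth table (scaffold, chrom, start, end), and
#'   `varietal` truth table (chrom, pos, ref, alt) where `ref` is the
#'   reference-genome base and `alt` the cultivar base.
#' @export
fragment_assembly <- function(genome, config, seed = config$seed) {
  if (config$scaffold_mean_length <= 0)
    stop_bsaseq("config error: scaffold_mean_length must be > 0")
  with_seed_or_current(seed, {
    maps <- list(); var_tab <- list()
    for (chrom in names(genome$sequences)) {
      len <- Biostrings::width(genome$sequences)[names(genome$sequences) == chrom]
      # breakpoints from exponential scaffold lengths (min 1 kb)
      cuts <- integer(0); at <- 0
      while (TRUE) {
        step <- max(1000, stats::rexp(1, 1 / config$scaffold_mean_length))
        at <- at + step
        if (at >= len) break
        cuts <- c(cuts, as.integer(floor(at)))
      }
      starts <- c(1L, cuts + 1L); ends <- c(cuts, as.integer(len))
      maps[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends)
      n_var <- rpois(1, config$varietal_snp_density * len / 1e6)
      if (n_var > 0) {
        pos <- sort(sample.int(len, min(n_var, len)))
        ref <- base_at(genome, chrom, pos)
        alt <- vapply(ref, function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
          USE.NAMES = FALSE)
        var_tab[[chrom]] <- data.frame(chrom = chrom, pos = pos,
                                       ref = ref, alt = alt)
      }
    }
    smap <- do.call(rbind, maps)
    smap$scaffold <- sprintf("scaffold%05d", seq_len(nrow(smap)))
    smap <- smap[, c("scaffold", "chrom", "start", "end")]
    rownames(smap) <- NULL
    varietal <- if (length(var_tab)) do.call(rbind, var_tab) else
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character())
    rownames(varietal) <- NULL
    scaffolds <- Biostrings::DNAStringSet(vapply(seq_len(nrow(smap)), function(i) {
      chrom <- smap$chrom[i]
      s <- as.character(Biostrings::subseq(genome$sequences[[chrom]],
                                           smap$start[i], smap$end[i]))
      v <- varietal[varietal$chrom == chrom &
                      varietal$pos >= smap$start[i] &
                      varietal$pos <= smap$end[i], ]
      if (nrow(v)) {
        off <- v$pos - smap$start[i] + 1L
        sv <- strsplit(s, "", fixed = TRUE)[[1]]
        sv[off] <- v$alt
        s <- paste(sv, collapse = "")
      }
      s
    }, character(1)))
    names(scaffolds) <- smap$scaffold
    structure(list(scaffolds = scaffolds, scaffold_map = smap,
                   varietal = varietal),
              class = "sim_assembly")
  })
}
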