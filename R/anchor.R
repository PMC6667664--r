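#' Anchor gene sequences onto draft-assembly scaffolds
#'
#' Seeded local matching in the spirit of a BLAST of reference gene
#' sequences against unplaced scaffolds: fixed-length exact seeds
#' (default 31 bp) locate candidate placements in both orientations, each
#' candidate is scored by ungapped comparison of the full gene against the
#' scaffold, and at most one anchor — the highest-scoring — is reported per
#' (gene, scaffold) pair. Anchors shorter than `min_match` or below
#' `min_identity` are discarded. The divergence model is substitution-only,
#' so ungapped extension is sufficient.
#'
#' @param scaffolds Named [Biostrings::DNAStringSet] (or `sim_assembly`).
#' @param gene_sequences Named [Biostrings::DNAStringSet] of gene sequences
#'   in reference-forward orientation (see [gene_sequences()]).
#' @param min_match Minimum matched length in bp (default 200).
#' @param min_identity Minimum identity fraction (default 0.95).
#' @param seed_length Exact-seed length (default 31).
#' @param n_seeds Number of (evenly spaced) seed positions tried per gene
#'   and orientation (default 8; under substitution-only divergence a few
#'   seeds suffice to hit a clean 31-mer).
#' @return Data frame of anchors: gene_id, scaffold, offset (1-based
#'   scaffold start of the match), orientation ("+"/"-"), match_length,
#'   identity, gmatch_start/gmatch_end (gene-forward coordinates covered by
#'   the match).
#' @export
find_gene_anchors <- function(scaffolds, gene_sequences, min_match = 200L,
                              min_identity = 0.95, seed_length = 31L,
                              n_seeds = 8L) {
  scaffolds <- as_seqset(scaffolds)
  out <- list()
  scaf_chars <- lapply(as.character(scaffolds), charToRaw)
  for (gi in seq_along(gene_sequences)) {
    gid <- names(gene_sequences)[gi]
    gseq <- gene_sequences[[gi]]
    glen <- length(gseq)
    if (glen < seed_length) next
    for (orient in c("+", "-")) {
      pat <- if (orient == "+") gseq else Biostrings::reverseComplement(gseq)
      praw <- charToRaw(as.character(pat))
      stride <- max(seed_length,
                    as.integer(ceiling((glen - seed_length + 1L) / n_seeds)))
      seed_starts <- unique(c(seq(1L, glen - seed_length + 1L, by = stride),
                              glen - seed_length + 1L))
      cands <- list()
      for (ss in seed_starts) {
        seed <- Biostrings::subseq(pat, ss, ss + seed_length - 1L)
        m <- Biostrings::vmatchPattern(seed, scaffolds)
        for (si in seq_along(scaffolds)) {
          for (hs in BiocGenerics::start(m[[si]]))
            cands[[length(cands) + 1L]] <- c(si, hs - (ss - 1L))
        }
      }
      if (!length(cands)) next
      cands <- unique(do.call(rbind, cands))
      for (k in seq_len(nrow(cands))) {
        si <- cands[k, 1]; off <- cands[k, 2]
        sraw <- scaf_chars[[si]]
        slen <- length(sraw)
        p_from <- max(1L, 2L - off)            # pattern coordinate
        p_to <- min(glen, slen - off + 1L)
        if (p_to - p_from + 1L < min_match) next
        s_from <- off + p_from - 1L
        s_to <- off + p_to - 1L
        matches <- sum(praw[p_from:p_to] == sraw[s_from:s_to])
        olen <- p_to - p_from + 1L
        identity <- matches / olen
        if (identity < min_identity) next
        # gene-forward coordinates of the matched pattern stretch
        if (orient == "+") {
          gm <- c(p_from, p_to)
        } else {
          gm <- c(glen - p_to + 1L, glen - p_from + 1L)
        }
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gid, scaffold = names(scaffolds)[si],
          offset = s_from, orientation = orient,
          match_length = olen, identity = identity,
          gmatch_start = gm[1], gmatch_end = gm[2],
          score = matches)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), scaffold = character(),
                      offset = integer(), orientation = character(),
                      match_length = integer(), identity = numeric(),
                      gmatch_start = integer(), gmatch_end = integer()))
  res <- do.call(rbind, out)
  # at most one anchor per (gene, scaffold): keep the highest score
  res <- res[order(res$gene_id, res$scaffold, -res$score), , drop = FALSE]
  res <- res[!duplicated(res[, c("gene_id", "scaffold")]), , drop = FALSE]
  res$score <- NULL
  rownames(res) <- NULL
  res
}

#' Extract gene sequences from an annotated genome
#'
#' Returns each gene's genomic interval in reference-forward orientation
#' (anchors and lifts then compose without strand bookkeeping).
#'
#' @param genome A `sim_genome`.
#' @param gene_ids Optional subset of gene ids.
#' @return Named [Biostrings::DNAStringSet].
#' @export
gene_sequences <- function(genome, gene_ids = genome$genes$gene_id) {
  g <- genome$genes[match(gene_ids, genome$genes$gene_id), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(g)), function(i)
    as.character(Biostrings::subseq(genome$sequences[[g$chrom[i]]],
                                    g$start[i], g$end[i])), character(1)))
  names(seqs) <- g$gene_id
  seqs
}

#' Define the physical search region around flanking markers
#'
#' The region spans `upstream` bp before the left marker to `downstream` bp
#' past the right marker (defaults 3 Mb each), clipped to the chromosome.
#'
#' @param markers Data frame with chrom and pos for the flanking markers
#'   (the leftmost and rightmost positions are used).
#' @param chrom_length Chromosome length for clipping.
#' @param upstream,downstream Flank sizes in bp.
#' @return List (class `search_region`) with chrom, start, end, markers.
#' @export
define_search_region <- function(markers, chrom_length,
                                 upstream = 3e6, downstream = 3e6) {
  if (length(unique(markers$chrom)) != 1L)
    stop_bsaseq("input error: markers lie on different chromosomes")
  left <- min(markers$pos); right <- max(markers$pos)
  structure(list(chrom = markers$chrom[1],
                 start = max(1, left - upstream),
                 end = min(chrom_length, right + downstream),
                 markers = markers),
            class = "search_region")
}

#' Select scaffolds informative for the search region
#'
#' A scaffold is selected iff it carries at least one passing variant and at
#' least one anchor to a gene inside the search region. Both conditions are
#' required; the selection is monotone in variants and anchors.
#'
#' @param anchors Anchor table from [find_gene_anchors()].
#' @param scaffold_variants Data frame of passing variants with a `chrom`
#'   column naming the scaffold.
#' @param region_genes Character vector of gene ids inside the region.
#' @return Character vector of selected scaffold ids.
#' @export
select_scaffolds <- function(anchors, scaffold_variants, region_genes) {
  with_var <- unique(scaffold_variants$chrom)
  with_anchor <- unique(anchors$scaffold[anchors$gene_id %in% region_genes])
  sort(intersect(with_var, with_anchor))
}

#' Lift a scaffold variant to approximate reference coordinates
#'
#' Uses a gene anchor as the bridge: for a "+" anchor the reference position
#' is `gene_ref_start + (gmatch_start - 1) + (variant_pos - offset)`; for a
#' "-" anchor, `gene_ref_start + (gmatch_end - 1) - (variant_pos - offset)`
#' with complemented alleles. Positions outside the anchored match are still
#' lifted but flagged "extrapolated".
#'
#' @param variant List/row with chrom (scaffold id), pos, ref, alt.
#' @param anchor One anchor row linking the variant's scaffold to a gene.
#' @param gene_ref Single-row gene table entry (chrom, start, end) on the
#'   reference.
#' @return List with chrom, pos, ref, alt and `confidence`
#'   ("anchored"/"extrapolated").
#' @export
lift_scaffold_snp <- function(variant, anchor, gene_ref) {
  if (variant$chrom != anchor$scaffold)
    stop_bsaseq("unliftable: variant scaffold %s has no anchor", variant$chrom)
  inside <- variant$pos >= anchor$offset &
    variant$pos <= anchor$offset + anchor$match_length - 1L
  d <- variant$pos - anchor$offset
  if (anchor$orientation == "+") {
    pos <- gene_ref$start + (anchor$gmatch_start - 1L) + d
    ref <- variant$ref; alt <- variant$alt
  } else {
    pos <- gene_ref$start + (anchor$gmatch_end - 1L) - d
    ref <- comp_base(variant$ref); alt <- comp_base(variant$alt)
  }
  list(chrom = gene_ref$chrom, pos = pos, ref = ref, alt = alt,
       confidence = if (inside) "anchored" else "extrapolated")
}
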