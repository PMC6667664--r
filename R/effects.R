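#' Extract one gene's model from an annotated genome
#'
#' @param genome A `sim_genome`.
#' @param gene_id Gene identifier.
#' @return List with `gene` (single-row data frame), `exons` and `cds`
#'   (interval data frames sorted by genomic start).
#' @export
gene_model <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop_bsaseq("gene %s not found", gene_id)
  list(gene = g,
       exons = genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE],
       cds = genome$cds[genome$cds$gene_id == gene_id, , drop = FALSE])
}

#' Classify the effect of an SNV relative to one gene model
#'
#' Strand-aware classification into promoter (within `promoter_size` bp
#' upstream of the transcription start), 5'/3' UTR, intron, downstream
#' (within `promoter_size` bp past the transcription end), intergenic, or —
#' for coding positions — synonymous / missense / stop-gained by translating
#' the reference and mutated codon with the standard nuclear genetic code.
#'
#' @param variant List or single-row data frame with chrom, pos, ref, alt.
#' @param model A [gene_model()] result.
#' @param genome The `sim_genome` providing sequence context.
#' @param promoter_size Upstream window defining the promoter (default
#'   1000 bp, mirroring the gene-proximity window).
#' @return One of "promoter", "five_prime_utr", "cds_synonymous",
#'   "cds_missense", "cds_stop_gained", "intron", "three_prime_utr",
#'   "downstream", "intergenic".
#' @export
classify_effect <- function(variant, model, genome, promoter_size = 1000L) {
  g <- model$gene
  pos <- variant$pos
  if (variant$chrom != g$chrom) return("intergenic")
  in_iv <- function(iv) any(pos >= iv$start & pos <= iv$end)
  if (in_iv(model$cds))
    return(classify_cds(variant, model, genome))
  if (pos >= g$start && pos <= g$end) {
    if (in_iv(model$exons)) {
      # exonic but not coding: UTR side depends on strand
      cds_lo <- min(model$cds$start); cds_hi <- max(model$cds$end)
      before <- pos < cds_lo
      if (g$strand == "+") return(if (before) "five_prime_utr" else "three_prime_utr")
      return(if (before) "three_prime_utr" else "five_prime_utr")
    }
    return("intron")
  }
  upstream <- if (g$strand == "+")
    pos < g$start && pos >= g$start - promoter_size
  else pos > g$end && pos <= g$end + promoter_size
  if (upstream) return("promoter")
  downstream <- if (g$strand == "+")
    pos > g$end && pos <= g$end + promoter_size
  else pos < g$start && pos >= g$start - promoter_size
  if (downstream) return("downstream")
  "intergenic"
}

classify_cds <- function(variant, model, genome) {
  g <- model$gene
  cds <- model$cds[order(model$cds$start), , drop = FALSE]
  total <- sum(cds$end - cds$start + 1)
  if (total %% 3 != 0)
    stop_bsaseq("annotation error: CDS length of %s is not a multiple of 3",
                g$gene_id)
  # genomic -> transcript-order CDS coordinate
  pos <- variant$pos
  if (g$strand == "+") {
    off <- 0L; cds_pos <- NA_integer_
    for (i in seq_len(nrow(cds))) {
      if (pos >= cds$start[i] && pos <= cds$end[i]) {
        cds_pos <- off + (pos - cds$start[i]) + 1L; break
      }
      off <- off + (cds$end[i] - cds$start[i] + 1L)
    }
  } else {
    off <- 0L; cds_pos <- NA_integer_
    for (i in rev(seq_len(nrow(cds)))) {
      if (pos >= cds$start[i] && pos <= cds$end[i]) {
        cds_pos <- off + (cds$end[i] - pos) + 1L; break
      }
      off <- off + (cds$end[i] - cds$start[i] + 1L)
    }
  }
  if (is.na(cds_pos)) stop_bsaseq("internal error: position not in CDS")
  codon_idx <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  tx_positions <- codon_idx * 3L + 1:3  # transcript CDS coords of the codon
  gpos <- vapply(tx_positions, function(tp) cds_tx_to_genomic(tp, cds, g$strand),
                 numeric(1))
  bases <- base_at(genome, g$chrom, gpos)
  if (g$strand == "-") bases <- comp_base(bases)
  ref_codon <- bases
  if (g$strand == "+") {
    if (ref_codon[within] != variant$ref)
      stop_bsaseq("annotation error: reference base mismatch at %s:%d",
                  variant$chrom, pos)
    alt_base <- variant$alt
  } else {
    if (ref_codon[within] != comp_base(variant$ref))
      stop_bsaseq("annotation error: reference base mismatch at %s:%d",
                  variant$chrom, pos)
    alt_base <- comp_base(variant$alt)
  }
  alt_codon <- ref_codon
  alt_codon[within] <- alt_base
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[paste(ref_codon, collapse = "")])
  aa_alt <- unname(code[paste(alt_codon, collapse = "")])
  if (aa_alt == "*" && aa_ref != "*") return("cds_stop_gained")
  if (aa_alt == aa_ref) return("cds_synonymous")
  "cds_missense"
}

# transcript-order CDS coordinate -> genomic position
cds_tx_to_genomic <- function(tp, cds, strand) {
  if (strand == "+") {
    off <- 0L
    for (i in seq_len(nrow(cds))) {
      w <- cds$end[i] - cds$start[i] + 1L
      if (tp <= off + w) return(cds$start[i] + (tp - off - 1L))
      off <- off + w
    }
  } else {
    off <- 0L
    for (i in rev(seq_len(nrow(cds)))) {
      w <- cds$end[i] - cds$start[i] + 1L
      if (tp <= off + w) return(cds$end[i] - (tp - off - 1L))
      off <- off + w
    }
  }
  stop_bsaseq("internal error: CDS coordinate %d out of range", tp)
}
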