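#' Lift a SNP between assemblies by exact flank matching
#'
#' Extracts the `flank`-bp window around the SNP in the source assembly and
#' searches for it, exactly, in the target assembly in both orientations. A
#' unique forward hit lifts the SNP with unchanged alleles; a unique
#' reverse-complement hit lifts it with complemented alleles; multiple hits
#' return "ambiguous" and none "not_found". When the window runs off a
#' contig end it is shortened with a warning, down to a minimum of 20 bp on
#' each side (below which the SNP is "not_found").
#'
#' @param chrom,pos,ref,alt The SNP on source coordinates.
#' @param source_genome,target_genome `sim_genome` objects or named
#'   [Biostrings::DNAStringSet]s.
#' @param flank Flank length in bp on each side (default 100).
#' @return List with `status` ("lifted", "ambiguous", "not_found") and, when
#'   lifted, `chrom`, `pos`, `ref`, `alt` on target coordinates plus
#'   `orientation` ("+" or "-").
#' @export
lift_by_flank <- function(chrom, pos, ref, alt, source_genome, target_genome,
                          flank = 100L) {
  src <- as_seqset(source_genome)
  tgt <- as_seqset(target_genome)
  if (!chrom %in% names(src))
    stop_bsaseq("lift error: %s not in source assembly", chrom)
  len <- Biostrings::width(src)[names(src) == chrom]
  left <- min(flank, pos - 1L)
  right <- min(flank, len - pos)
  if (left < 20L || right < 20L)
    return(list(status = "not_found"))
  if (left < flank || right < flank)
    warning(sprintf("flank shortened to %d/%d bp at %s:%d", left, right,
                    chrom, pos), call. = FALSE)
  win <- Biostrings::subseq(src[[chrom]], pos - left, pos + right)
  fwd <- Biostrings::vmatchPattern(win, tgt)
  rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(win), tgt)
  hits <- list()
  for (i in seq_along(tgt)) {
    for (s in BiocGenerics::start(fwd[[i]]))
      hits[[length(hits) + 1L]] <- list(chrom = names(tgt)[i],
                                        start = s, orient = "+")
    for (s in BiocGenerics::start(rev[[i]]))
      hits[[length(hits) + 1L]] <- list(chrom = names(tgt)[i],
                                        start = s, orient = "-")
  }
  if (length(hits) == 0L) return(list(status = "not_found"))
  if (length(hits) > 1L) return(list(status = "ambiguous"))
  h <- hits[[1]]
  if (h$orient == "+") {
    list(status = "lifted", chrom = h$chrom, pos = h$start + left,
         ref = ref, alt = alt, orientation = "+")
  } else {
    wlen <- left + right + 1L
    list(status = "lifted", chrom = h$chrom,
         pos = h$start + (wlen - 1L - left),
         ref = comp_base(ref), alt = comp_base(alt), orientation = "-")
  }
}

as_seqset <- function(x) {
  if (inherits(x, "sim_genome")) x$sequences
  else if (inherits(x, "DNAStringSet")) x
  else if (inherits(x, "sim_assembly")) x$scaffolds
  else stop_bsaseq("expected a sim_genome, sim_assembly or DNAStringSet")
}

#' Build a flank-match lifter closure for [intersect_parent()]
#'
#' @param source_genome,target_genome Assemblies as in [lift_by_flank()].
#' @param flank Flank length.
#' @return A function (chrom, pos, ref, alt) -> lift result.
#' @export
make_flank_lifter <- function(source_genome, target_genome, flank = 100L) {
  function(chrom, pos, ref, alt)
    lift_by_flank(chrom, pos, ref, alt, source_genome, target_genome, flank)
}
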