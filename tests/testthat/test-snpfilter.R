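vt <- function(chrom = "c1", pos, ref = "G", alt = "A", qual = 60, dp = 50,
               zygosity = "hom") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos,
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             qual = rep_len(qual, n), dp = rep_len(dp, n),
             zygosity = rep_len(zygosity, n))
}

test_that("the EMS filter keeps only reference G>A and C>T transitions", {
  v <- rbind(vt(pos = 1, ref = "G", alt = "A"),
             vt(pos = 2, ref = "C", alt = "T"),
             vt(pos = 3, ref = "A", alt = "C"),
             vt(pos = 4, ref = "A", alt = "G"),  # reverse pair rejected
             vt(pos = 5, ref = "T", alt = "C"))
  r <- filter_ems_like(v)
  expect_identical(r$retained$pos, c(1, 2))
  expect_identical(r$dropped$pos, c(3, 4, 5))
  expect_true(all(r$dropped$reason == "not-ems-like"))
  expect_error(filter_ems_like(vt(pos = 1, ref = "GG", alt = "A")),
               "non-SNV")
})

test_that("quality thresholds follow the printed boundary conventions", {
  v <- rbind(vt(pos = 1, qual = 20, dp = 11),          # boundary pass
             vt(pos = 2, qual = 19.99, dp = 50),       # QUAL below 20
             vt(pos = 3, qual = 60, dp = 10),          # DP not > 10
             vt(pos = 4, qual = 60, dp = 50, zygosity = "het"),
             vt(pos = 5, qual = NA, dp = 50))
  r <- filter_quality(v)
  expect_identical(r$retained$pos, 1)
  expect_identical(r$dropped$reason[r$dropped$pos == 5], "missing-field")
  # zygosity filter can be disabled
  r2 <- filter_quality(v, homozygous_only = FALSE)
  expect_identical(r2$retained$pos, c(1, 4))
})

test_that("varietal subtraction matches on position only", {
  v <- rbind(vt(pos = 100, ref = "G", alt = "A"),
             vt(pos = 200, ref = "G", alt = "A"))
  varietal <- data.frame(chrom = "c1", pos = 200)
  r <- subtract_varietal(v, varietal)
  expect_identical(r$retained$pos, 100)
  expect_identical(r$dropped$pos, 200)
  # empty varietal set is the identity
  r0 <- subtract_varietal(v, data.frame(chrom = character(), pos = integer()))
  expect_identical(nrow(r0$retained), 2L)
})

test_that("parent intersection matches lifted SNPs and logs failures", {
  v <- rbind(vt(pos = 10, ref = "G", alt = "A"),
             vt(pos = 20, ref = "C", alt = "T"),
             vt(pos = 30, ref = "G", alt = "A"))
  parents <- data.frame(chrom = "c1", pos = c(10, 20, 99),
                        ref = c("G", "C", "G"), alt = c("A", "T", "A"))
  r <- intersect_parent(v, parents)
  expect_identical(r$retained$pos, c(10, 20))
  expect_identical(r$dropped$pos, 30)
  # an ambiguous lifter never matches and is logged
  amb_lifter <- function(chrom, pos, ref, alt) {
    if (pos == 10) list(status = "ambiguous")
    else identity_lifter(chrom, pos, ref, alt)
  }
  r2 <- intersect_parent(v, parents, amb_lifter)
  expect_identical(r2$retained$pos, 20)
  expect_identical(r2$unlifted$pos, 10)
  expect_identical(r2$unlifted$status, "ambiguous")
})

test_that("flank lifting finds unique placements in both orientations", {
  withr::with_seed(77, {
    core <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                  collapse = "")
    src <- make_sim_genome(c(s1 = core))
    pad <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                 collapse = "")
    # forward copy at offset 1501 in the target
    tgt_f <- make_sim_genome(c(t1 = paste0(pad, core)))
    r <- lift_by_flank("s1", 2000L, "G", "A", src, tgt_f)
    expect_identical(r$status, "lifted")
    expect_identical(r$pos, 3500L)
    expect_identical(r$orientation, "+")
    expect_identical(c(r$ref, r$alt), c("G", "A"))
    # reverse-complement copy: alleles complemented (G>A becomes C>T)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(core)))
    tgt_r <- make_sim_genome(c(t1 = paste0(pad, rc)))
    r2 <- lift_by_flank("s1", 2000L, "G", "A", src, tgt_r)
    expect_identical(r2$status, "lifted")
    expect_identical(r2$orientation, "-")
    expect_identical(c(r2$ref, r2$alt), c("C", "T"))
    expect_identical(r2$pos, 1500L + (4000L - 2000L + 1L))
    # duplicated window: ambiguous
    tgt_dup <- make_sim_genome(c(t1 = paste0(core, core)))
    expect_identical(lift_by_flank("s1", 2000L, "G", "A", src, tgt_dup)$status,
                     "ambiguous")
    # absent window: not_found
    other <- make_sim_genome(c(t1 = pad))
    expect_identical(lift_by_flank("s1", 2000L, "G", "A", src, other)$status,
                     "not_found")
    # too close to the contig end for even a 20 bp flank
    expect_identical(lift_by_flank("s1", 5L, "G", "A", src, tgt_f)$status,
                     "not_found")
  })
})

test_that("lift round trip returns the original position when unique", {
  withr::with_seed(78, {
    core <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                  collapse = "")
    src <- make_sim_genome(c(s1 = core))
    tgt <- make_sim_genome(c(t1 = paste0(
      paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = ""),
      core)))
    for (pos in as.integer(seq(200, 5800, length.out = 15))) {
      ref <- bsaseq:::base_at(src, "s1", pos)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      fwd <- lift_by_flank("s1", pos, ref, alt, src, tgt)
      if (fwd$status != "lifted") next
      back <- lift_by_flank(fwd$chrom, fwd$pos, fwd$ref, fwd$alt, tgt, src)
      expect_identical(back$status, "lifted")
      expect_identical(back$pos, pos)
      expect_identical(back$ref, ref)
    }
  })
})

test_that("density masking drops implausibly dense windows only", {
  # 15 SNPs inside one 10 kb window: Poisson tail at lambda 0.23 is tiny
  dense <- vt(pos = seq(20001, 20290, by = 20), ref = "G", alt = "A")
  sparse <- vt(pos = c(100000, 220000, 340000), ref = "G", alt = "A")
  r <- mask_dense_regions(rbind(dense, sparse))
  expect_identical(nrow(r$masked_windows), 1L)
  expect_identical(r$masked_windows$start, 20001L)
  expect_identical(sort(r$retained$pos), sparse$pos)
  expect_identical(nrow(r$dropped), nrow(dense))
  expect_lt(ppois(14, 0.23, lower.tail = FALSE), 1e-4)
  # one SNP per window genome-wide: nothing masked
  r2 <- mask_dense_regions(sparse)
  expect_identical(nrow(r2$masked_windows), 0L)
  expect_identical(nrow(r2$retained), 3L)
  # empty input
  r3 <- mask_dense_regions(vt(pos = 1)[0, ])
  expect_identical(nrow(r3$retained), 0L)
  expect_error(mask_dense_regions(sparse, window = 0), "window")
})

test_that("gene proximity keeps variants within 1 kb and annotates all genes", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      start = c(5000L, 8500L), end = c(7000L, 9500L))
  v <- rbind(vt(pos = 4200, ref = "G", alt = "A"),   # 800 bp upstream of gA
             vt(pos = 3900, ref = "G", alt = "A"),   # 1100 bp: too far
             vt(pos = 7800, ref = "G", alt = "A"))   # within 1 kb of both
  r <- select_gene_proximal(v, genes)
  expect_identical(r$retained$pos, c(4200, 7800))
  expect_identical(r$dropped$pos, 3900)
  expect_identical(r$retained$gene_ids, c("gA", "gA;gB"))
})

test_that("effect classification is codon-aware and strand-consistent", {
  genome <- make_effect_genome()
  model <- gene_model(genome, "g1")
  # planted codons: GGA (Gly) | CTG (Leu) | TGG (Trp) at CDS start 1101
  cases <- list(
    list(pos = 1102L, ref = "G", alt = "A", class = "cds_missense"),   # GGA>GAA
    list(pos = 1106L, ref = "G", alt = "A", class = "cds_synonymous"), # CTG>CTA
    list(pos = 1109L, ref = "G", alt = "A", class = "cds_stop_gained"),# TGG>TGA
    list(pos = 1050L, ref = "N", alt = "N", class = "five_prime_utr"),
    list(pos = 1500L, ref = "N", alt = "N", class = "intron"),
    list(pos = 1950L, ref = "N", alt = "N", class = "three_prime_utr"),
    list(pos = 701L,  ref = "N", alt = "N", class = "promoter"),
    list(pos = 2500L, ref = "N", alt = "N", class = "downstream"),
    list(pos = 3500L, ref = "N", alt = "N", class = "intergenic"))
  for (cs in cases) {
    v <- list(chrom = "chr1", pos = cs$pos, ref = cs$ref, alt = cs$alt)
    if (cs$ref == "N") {
      v$ref <- bsaseq:::base_at(genome, "chr1", cs$pos)
      v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
    }
    expect_identical(classify_effect(v, model, genome), cs$class,
                     label = sprintf("pos %d", cs$pos))
    # strand consistency: the mirrored representation classifies identically
    mg <- mirror_genome(genome)
    mv <- list(chrom = "chr1", pos = mirror_pos(genome, "chr1", cs$pos),
               ref = bsaseq:::comp_base(v$ref),
               alt = bsaseq:::comp_base(v$alt))
    expect_identical(classify_effect(mv, gene_model(mg, "g1"), mg), cs$class,
                     label = sprintf("mirrored pos %d", cs$pos))
  }
})

test_that("the cascade conserves records, is idempotent, and matches truth", {
  cfg <- sim_config(seed = 61, chromosomes = c(cA = 5e5, cB = 5e5),
                    n_genes_per_chromosome = 0L, mean_depth = 100,
                    varietal_snp_density = 2500)
  genome <- generate_genome(cfg)
  mut <- induce_ems_mutations(genome, 150, seed = 62)
  mut <- mark_causal(mut, "cA")
  pop <- propagate_pedigree(mut, cfg, seed = 63)
  asm <- fragment_assembly(genome, cfg, seed = 64)
  fl <- simulate_flowsort_variants(pop$m4, pop$loci, genome, cfg,
                                   target_chrom = "cA",
                                   contaminant_chrom = "cB",
                                   varietal = asm$varietal,
                                   noise_clusters = 2L, seed = 65)
  casc <- filter_cascade(fl$variants, varietal_sites = asm$varietal)
  # conservation: every record is retained or attributed to one filter
  expect_identical(casc$input_count,
                   casc$retained_count + sum(casc$report$dropped))
  expect_identical(casc$input_count,
                   casc$retained_count + nrow(casc$dropped))
  # idempotence: re-filtering the output changes nothing
  again <- filter_cascade(casc$retained, varietal_sites = asm$varietal)
  expect_identical(again$retained_count, casc$retained_count)
  expect_identical(sum(again$report$dropped), 0L)
  # truth agreement: varietal and noise records are dropped; true mutations
  # that pass coverage/zygosity on their own and sit outside masked windows
  # survive (>= 99% agreement; a noise cluster straddling a window boundary
  # can leak a couple of sub-threshold calls)
  vidx <- fl$variants
  vidx$.idx <- seq_len(nrow(vidx))
  casc2 <- filter_cascade(vidx, varietal_sites = asm$varietal)
  got_keep <- seq_len(nrow(vidx)) %in% casc2$retained$.idx
  truth_class <- fl$truth$class
  masked <- rep(FALSE, nrow(vidx))
  if (nrow(casc2$masked_windows)) {
    for (i in seq_len(nrow(casc2$masked_windows))) {
      mw <- casc2$masked_windows[i, ]
      masked <- masked | (vidx$chrom == mw$chrom & vidx$pos >= mw$start &
                            vidx$pos <= mw$end)
    }
  }
  expected_keep <- truth_class == "mutation" &
    vidx$zygosity == "hom" & vidx$qual >= 20 & vidx$dp > 10 & !masked &
    !(paste(vidx$chrom, vidx$pos) %in% paste(asm$varietal$chrom,
                                             asm$varietal$pos))
  expect_gte(mean(expected_keep == got_keep), 0.99)
  expect_gte(mean(!got_keep[truth_class != "mutation"]), 0.99)
  # true mutations passing coverage survive in full
  expect_true(all(got_keep[expected_keep]))
})
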