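test_that("generated genomes respect bounds, structure and determinism", {
  cfg <- sim_config(seed = 3, chromosomes = c(c1 = 2e5, c2 = 2e5),
                    n_genes_per_chromosome = 6L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$genes, g2$genes)
  expect_equal(nrow(g1$genes), 12L)
  for (i in seq_len(nrow(g1$genes))) {
    g <- g1$genes[i, ]
    expect_gte(g$start, 1)
    expect_lte(g$end, cfg$chromosomes[[g$chrom]])
    ex <- g1$exons[g1$exons$gene_id == g$gene_id, ]
    expect_gte(nrow(ex), 1)
    ex <- ex[order(ex$start), ]
    expect_true(all(ex$start >= g$start & ex$end <= g$end))
    if (nrow(ex) > 1)
      expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
    cd <- g1$cds[g1$cds$gene_id == g$gene_id, ]
    expect_identical(sum(cd$end - cd$start + 1) %% 3, 0)
  }
  # genes on one chromosome never overlap
  for (ch in c("c1", "c2")) {
    gg <- g1$genes[g1$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
})

test_that("impossible gene placement raises a placement error", {
  cfg <- sim_config(seed = 1, chromosomes = c(tiny = 1000),
                    n_genes_per_chromosome = 100L)
  expect_error(generate_genome(cfg), "placement")
})

test_that("EMS mutations follow the G>A / C>T spectrum on G/C bases", {
  cfg <- sim_config(seed = 5, chromosomes = c(c1 = 5e5),
                    n_genes_per_chromosome = 0L)
  genome <- generate_genome(cfg)
  expect_identical(nrow(induce_ems_mutations(genome, 0, seed = 1)), 0L)
  mut <- induce_ems_mutations(genome, 100, seed = 2)
  expect_gt(nrow(mut), 0)
  expect_true(all((mut$ref == "G" & mut$alt == "A") |
                    (mut$ref == "C" & mut$alt == "T")))
  expect_false(any(duplicated(paste(mut$chrom, mut$pos))))
  # positions really carry the claimed reference base
  expect_identical(bsaseq:::base_at(genome, "c1", mut$pos), mut$ref)
  # determinism
  expect_identical(mut, induce_ems_mutations(genome, 100, seed = 2))
})

test_that("a genome without G/C bases cannot be mutagenized", {
  genome <- make_sim_genome(c(at = strrep("AT", 5000)))
  expect_error(induce_ems_mutations(genome, 10, seed = 1), "spectrum")
})

test_that("realized mutation counts match the Poisson model", {
  cfg <- sim_config(seed = 7, chromosomes = c(c1 = 1e6),
                    n_genes_per_chromosome = 0L)
  genome <- generate_genome(cfg)
  counts <- vapply(1:200, function(s)
    nrow(induce_ems_mutations(genome, 23, seed = s)), integer(1))
  se <- sqrt(23 / 200)
  expect_lt(abs(mean(counts) - 23), 3 * se)
})

test_that("fragmented assemblies partition the genome and log varietal SNPs", {
  cfg0 <- sim_config(seed = 9, chromosomes = c(c1 = 3e5, c2 = 2e5),
                     n_genes_per_chromosome = 0L, varietal_snp_density = 0,
                     scaffold_mean_length = 5e4)
  genome <- generate_genome(cfg0)
  asm <- fragment_assembly(genome, cfg0)
  # no-edit case: every scaffold is an exact substring of its source
  for (i in seq_len(nrow(asm$scaffold_map))) {
    m <- asm$scaffold_map[i, ]
    expect_identical(
      as.character(asm$scaffolds[[m$scaffold]]),
      as.character(Biostrings::subseq(genome$sequences[[m$chrom]],
                                      m$start, m$end)))
  }
  # partition round trip reconstructs each chromosome exactly
  for (ch in names(genome$sequences)) {
    m <- asm$scaffold_map[asm$scaffold_map$chrom == ch, ]
    m <- m[order(m$start), ]
    expect_identical(m$start, c(1L, head(m$end, -1) + 1L))
    expect_identical(m$end[nrow(m)],
                     as.integer(cfg0$chromosomes[[ch]]))
    expect_identical(
      paste(vapply(m$scaffold, function(s)
        as.character(asm$scaffolds[[s]]), character(1)), collapse = ""),
      as.character(genome$sequences[[ch]]))
  }
  # injected SNP count within the central 99% Poisson interval
  cfg1 <- sim_config(seed = 10, chromosomes = c(c1 = 1e7),
                     n_genes_per_chromosome = 0L, varietal_snp_density = 100)
  genome1 <- generate_genome(cfg1)
  asm1 <- fragment_assembly(genome1, cfg1)
  expect_gte(nrow(asm1$varietal), qpois(0.005, 1000))
  expect_lte(nrow(asm1$varietal), qpois(0.995, 1000))
  # and the recorded alleles really differ from the reference
  expect_true(all(asm1$varietal$ref != asm1$varietal$alt))
  expect_identical(bsaseq:::base_at(genome1, "c1", asm1$varietal$pos),
                   asm1$varietal$ref)
})

test_that("heterozygosity decays as 2^-n across selfing generations", {
  # 10 unlinked loci (one per 1 Mb chromosome); measured on non-causal
  # chromosomes so the causal conditioning cannot bias the estimate
  chroms <- setNames(rep(1e6, 10), paste0("c", 1:10))
  mut <- data.frame(chrom = names(chroms), pos = 5e5, ref = "G", alt = "A",
                    is_causal = c(TRUE, rep(FALSE, 9)))
  for (n in 1:3) {
    cfg <- sim_config(seed = 1, chromosomes = chroms, f2_size = 4L,
                      yellow_bulk_n = 1L, green_bulk_n = 1L,
                      selfing_generations_to_M4 = n)
    het <- vapply(1:250, function(s) {
      pop <- propagate_pedigree(mut, cfg, seed = s)
      mean(pop$m4[pop$loci$chrom != "c1"] == 1L)
    }, numeric(1))
    p <- 2^(-n)
    se <- sqrt(p * (1 - p) / (250 * 9))
    expect_lt(abs(mean(het) - p), 3 * se)
  }
})

test_that("the causal locus segregates 1:2:1 in a large F2", {
  pop <- quick_population(seed = 21, f2 = 30000L)
  counts <- table(factor(pop$genotypes[, pop$causal], 0:2))
  p <- c(0.25, 0.5, 0.25)
  for (k in 1:3) {
    se <- sqrt(p[k] * (1 - p[k]) / 30000)
    expect_lt(abs(counts[k] / 30000 - p[k]), 4 * se)
  }
  # F1 carries the causal allele by construction
  expect_gte(pop$f1[pop$causal], 1L)
})

test_that("phenotypes follow dominance and penetrance", {
  pop <- quick_population(seed = 22, f2 = 20000L)
  yfrac <- mean(pop$plants$phenotype == "yellow")
  expect_lt(abs(yfrac - 0.75), 4 * sqrt(0.75 * 0.25 / 20000))
  # homozygous wild type is never yellow
  homwt <- pop$genotypes[, pop$causal] == 0L
  expect_true(all(pop$plants$phenotype[homwt] == "green"))
  # penetrance 0: the phenotype vanishes entirely
  pop0 <- assign_phenotypes(pop, penetrance = 0, seed = 1)
  expect_true(all(pop0$plants$phenotype == "green"))
  expect_error(assign_phenotypes(pop, penetrance = 1.2), "penetrance")
})

test_that("bulks are disjoint random samples of the requested sizes", {
  pop <- quick_population(seed = 23, f2 = 400L)
  b <- build_bulks(pop, 75L, 16L, seed = 1)
  expect_length(b$yellow, 75L)
  expect_length(b$green, 16L)
  expect_length(intersect(b$yellow, b$green), 0L)
  expect_true(all(pop$plants$phenotype[b$yellow] == "yellow"))
  expect_true(all(pop$plants$phenotype[b$green] == "green"))
  b0 <- build_bulks(pop, 0L, 5L, seed = 1)
  expect_length(b0$yellow, 0L)
  expect_error(build_bulks(pop, 75L, 5000L, seed = 1), "available")
})

test_that("bulk count sampling follows the binomial read model", {
  pop <- quick_population(seed = 24, f2 = 3000L, mean_depth = 10000,
                          error_rate = 0)
  b <- build_bulks(pop, 1000L, 300L, seed = 2)
  cnt <- simulate_bulk_counts(pop, b, mean_depth = 10000, error_rate = 0,
                              seed = 3)
  # error-free green bulk at the causal site: all members are hom WT
  expect_identical(cnt$AO_green, 0L)
  # yellow bulks of 1000 plants at depth 10,000: AO/DP within 0.01 of 2/3
  # (averaged over bulk redraws; a single bulk's allele frequency varies)
  ratios <- vapply(1:6, function(s) {
    bb <- build_bulks(pop, 1000L, 300L, seed = s + 10L)
    cc <- simulate_bulk_counts(pop, bb, mean_depth = 10000, error_rate = 0,
                               seed = s + 20L)
    cc$AO_yellow / cc$DP_yellow
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2 / 3), 0.01)
  # error only: AO/DP ~ e
  cnt2 <- simulate_bulk_counts(pop, list(yellow = b$yellow, green = b$green),
                               mean_depth = 10000, error_rate = 0.01,
                               seed = 4)
  expect_lt(abs(cnt2$AO_green / cnt2$DP_green - 0.01), 0.005)
  # determinism
  expect_identical(cnt, simulate_bulk_counts(pop, b, mean_depth = 10000,
                                             error_rate = 0, seed = 3))
  # empty bulk: depth still drawn, AO flagged missing
  cnt3 <- simulate_bulk_counts(pop, list(yellow = b$yellow,
                                         green = integer(0)),
                               mean_depth = 100, error_rate = 0, seed = 5)
  expect_true(all(is.na(cnt3$AO_green)))
  expect_true(all(cnt3$DP_green >= 0))
})

test_that("flow-sort simulation reflects purity and keeps truth complete", {
  cfg <- sim_config(seed = 31, chromosomes = c(cA = 4e5, cB = 4e5),
                    n_genes_per_chromosome = 0L, mean_depth = 100,
                    varietal_snp_density = 50)
  genome <- generate_genome(cfg)
  mut <- induce_ems_mutations(genome, 200, seed = 32)
  mut <- mark_causal(mut, "cA")
  pop <- propagate_pedigree(mut, cfg, seed = 33)
  asm <- fragment_assembly(genome, cfg, seed = 34)
  fl <- simulate_flowsort_variants(pop$m4, pop$loci, genome, cfg,
                                   target_chrom = "cA",
                                   contaminant_chrom = "cB",
                                   varietal = asm$varietal,
                                   noise_clusters = 1L, seed = 35)
  # every record is classifiable from the truth table alone
  expect_identical(nrow(fl$variants), nrow(fl$truth))
  expect_true(all(fl$truth$class %in% c("mutation", "varietal", "noise")))
  expect_identical(paste(fl$variants$chrom, fl$variants$pos),
                   paste(fl$truth$chrom, fl$truth$pos))
  # mean depth ratio target:contaminant ~ 4:1 at purity 0.8
  rat <- mean(fl$variants$dp[fl$variants$chrom == "cA"]) /
    mean(fl$variants$dp[fl$variants$chrom == "cB"])
  expect_lt(abs(rat - 4), 0.8)
  # QUAL is the documented monotone stand-in, capped at 60
  expect_true(all(fl$variants$qual <= 60))
  # purity 1: no contaminant records
  fl1 <- simulate_flowsort_variants(pop$m4, pop$loci, genome, cfg,
                                    target_chrom = "cA",
                                    contaminant_chrom = "cB",
                                    purity = 1, seed = 36)
  expect_false(any(fl1$variants$chrom == "cB"))
  # no noise clusters requested: no noise truth rows
  expect_false(any(fl1$truth$class == "noise"))
  expect_error(
    simulate_flowsort_variants(pop$m4, pop$loci, genome, cfg, "cA", "cB",
                               purity = 1.5, seed = 1), "purity")
})

test_that("sim_config rejects invalid parameter combinations", {
  expect_error(sim_config(penetrance = 2), "penetrance")
  expect_error(sim_config(flowsort_purity = -0.1), "purity")
  expect_error(sim_config(f2_size = 10, yellow_bulk_n = 75), "bulk")
  expect_error(sim_config(chromosomes = c(a = -5)), "length")
  expect_error(sim_config(scaffold_mean_length = 0), "scaffold_mean_length")
})
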