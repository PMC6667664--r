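# Pedigree machinery: haplotypes are logical vectors over the mutation loci
# of one chromosome (TRUE = mutant allele). Meiosis draws a Poisson number
# of crossovers (map_length_per_mb x length, no interference) with uniform
# positions; gametes are generated in bulk, vectorized over individuals.

# n gametes from one parent for one chromosome.
# hapA/hapB: parental haplotypes; pos: locus positions; len: chromosome bp.
make_gametes <- function(hapA, hapB, pos, len, n, morgans_per_mb) {
  L <- length(pos)
  if (L == 0L) return(matrix(logical(0), n, 0L))
  rate <- morgans_per_mb * len / 1e6
  K <- rpois(n, rate)
  xo <- runif(sum(K), 0, len)
  g <- rep.int(seq_len(n), K)
  s0 <- sample(0:1, n, replace = TRUE)
  cnt <- vapply(pos, function(p) tabulate(g[xo <= p], nbins = n), integer(n))
  if (n == 1L) cnt <- matrix(cnt, nrow = 1L)
  strand <- (s0 + cnt) %% 2
  out <- matrix(rep(hapA, each = n), n, L)
  altm <- matrix(rep(hapB, each = n), n, L)
  sel <- strand == 1
  out[sel] <- altm[sel]
  out
}

#' Propagate an EMS pedigree from the M2 to an F2 population
#'
#' The M2 is heterozygous at every induced locus (one fully mutant and one
#' wild-type haplotype). It is selfed for `selfing_generations_to_M4` rounds
#' (default two, giving the M4), crossed to wild type to produce one F1 that
#' is conditioned to carry the causal mutant allele (the study's F1 was
#' phenotypically mutant), and the F1 is selfed to give `f2_size` F2 plants.
#' Crossovers are Poisson with uniform positions and no interference. If the
#' causal allele is lost during selfing the whole M-lineage is redrawn
#' (bounded retries); non-causal loci are never conditioned.
#'
#' @param mutations Data frame (chrom, pos, ...) of induced loci; one row
#'   must be the causal mutation.
#' @param config A [sim_config()] (chromosome lengths, selfing rounds,
#'   `f2_size`, `map_length_per_mb`).
#' @param causal A single-row data frame (or list) with `chrom` and `pos`
#'   identifying the causal locus; defaults to the `is_causal` row of
#'   `mutations`.
#' @param seed Optional seed.
#' @return A `bsa_population`: plants data frame (id, generation,
#'   phenotype), F2 `genotypes` matrix (plants x loci, mutant-allele counts
#'   0/1/2), `loci` table, `causal` locus index, and `m2`/`m4`/`f1` genotype
#'   vectors (allele counts per locus).
#' @export
propagate_pedigree <- function(mutations, config, causal = NULL, seed = NULL) {
  if (is.null(causal)) {
    ci <- which(mutations$is_causal)
    if (length(ci) != 1L)
      stop_bsaseq("exactly one causal mutation required (see mark_causal())")
  } else {
    ci <- which(mutations$chrom == causal$chrom & mutations$pos == causal$pos)
    if (length(ci) != 1L)
      stop_bsaseq("causal locus (%s:%s) not found among mutations",
                  causal$chrom, format(causal$pos, scientific = FALSE))
  }
  ord <- order(match(mutations$chrom, names(config$chromosomes)), mutations$pos)
  loci <- mutations[ord, , drop = FALSE]
  rownames(loci) <- NULL
  ci <- match(ci, ord)
  loci$is_causal <- FALSE
  loci$is_causal[ci] <- TRUE
  chroms <- unique(loci$chrom)
  idx_by_chrom <- lapply(chroms, function(ch) which(loci$chrom == ch))
  names(idx_by_chrom) <- chroms

  with_seed_or_current(seed, {
    mpm <- config$map_length_per_mb
    # self one individual (per-chromosome haplotype pairs) once
    self_once <- function(ind) {
      lapply(chroms, function(ch) {
        ii <- idx_by_chrom[[ch]]
        gs <- make_gametes(ind[[ch]][[1]], ind[[ch]][[2]], loci$pos[ii],
                           config$chromosomes[[ch]], 2L, mpm)
        list(gs[1, ], gs[2, ])
      }) |> stats::setNames(chroms)
    }
    m2 <- lapply(chroms, function(ch) {
      L <- length(idx_by_chrom[[ch]])
      list(rep(TRUE, L), rep(FALSE, L))
    }) |> stats::setNames(chroms)

    cch <- loci$chrom[ci]
    cpos_in_chrom <- match(ci, idx_by_chrom[[cch]])
    m4 <- NULL
    for (try in seq_len(100L)) {
      cand <- m2
      for (g in seq_len(config$selfing_generations_to_M4)) cand <- self_once(cand)
      if (cand[[cch]][[1]][cpos_in_chrom] || cand[[cch]][[2]][cpos_in_chrom]) {
        m4 <- cand; break
      }
    }
    if (is.null(m4))
      stop_bsaseq("pedigree error: causal allele lost from the M4 lineage after 100 redraws")

    # F1: one gamete from the M4 (conditioned on carrying the causal allele)
    # crossed to wild type.
    f1 <- NULL
    for (try in seq_len(1000L)) {
      gam <- lapply(chroms, function(ch) {
        ii <- idx_by_chrom[[ch]]
        make_gametes(m4[[ch]][[1]], m4[[ch]][[2]], loci$pos[ii],
                     config$chromosomes[[ch]], 1L, mpm)[1, ]
      }) |> stats::setNames(chroms)
      if (gam[[cch]][cpos_in_chrom]) { f1 <- gam; break }
    }
    if (is.null(f1))
      stop_bsaseq("pedigree error: could not draw an F1 gamete carrying the causal allele")

    n <- config$f2_size
    geno <- matrix(0L, n, nrow(loci))
    for (ch in chroms) {
      ii <- idx_by_chrom[[ch]]
      zero <- rep(FALSE, length(ii))
      g1 <- make_gametes(f1[[ch]], zero, loci$pos[ii],
                         config$chromosomes[[ch]], n, mpm)
      g2 <- make_gametes(f1[[ch]], zero, loci$pos[ii],
                         config$chromosomes[[ch]], n, mpm)
      geno[, ii] <- g1 + g2
    }
    counts_of <- function(ind) {
      v <- integer(nrow(loci))
      for (ch in chroms) {
        ii <- idx_by_chrom[[ch]]
        v[ii] <- as.integer(ind[[ch]][[1]]) + as.integer(ind[[ch]][[2]])
      }
      v
    }
    f1_counts <- integer(nrow(loci))
    for (ch in chroms) f1_counts[idx_by_chrom[[ch]]] <- as.integer(f1[[ch]])
    plants <- data.frame(id = sprintf("F2_%04d", seq_len(n)),
                         generation = "F2", phenotype = NA_character_)
    structure(list(plants = plants, genotypes = geno, loci = loci,
                   causal = ci,
                   m2 = counts_of(m2), m4 = counts_of(m4), f1 = f1_counts,
                   config = config),
              class = "bsa_population")
  })
}

#' @export
print.bsa_population <- function(x, ...) {
  ph <- table(factor(x$plants$phenotype, levels = c("yellow", "green")))
  cat(sprintf("bsa_population: %d F2 plants, %d loci (causal %s:%s)\n",
              nrow(x$plants), nrow(x$loci), x$loci$chrom[x$causal],
              format(x$loci$pos[x$causal], scientific = FALSE)))
  if (any(!is.na(x$plants$phenotype)))
    cat(sprintf("  phenotypes: %d yellow / %d green\n", ph[1], ph[2]))
  invisible(x)
}

#' Assign phenotypes under a dominant single-locus model
#'
#' Plants carrying at least one causal mutant allele are scored "yellow"
#' with probability `penetrance` and "green" otherwise; homozygous wild-type
#' plants are always green. Penetrance below 1 models environments in which
#' the phenotype does not express.
#'
#' @param population A [propagate_pedigree()] result.
#' @param penetrance Probability in \[0, 1\].
#' @param seed Optional seed.
#' @return The population with `plants$phenotype` filled in.
#' @export
assign_phenotypes <- function(population, penetrance = population$config$penetrance,
                              seed = NULL) {
  if (penetrance < 0 || penetrance > 1)
    stop_bsaseq("config error: penetrance must lie in [0, 1]")
  with_seed_or_current(seed, {
    carrier <- population$genotypes[, population$causal] >= 1L
    yellow <- carrier & (runif(length(carrier)) < penetrance)
    population$plants$phenotype <- ifelse(yellow, "yellow", "green")
    population
  })
}

#' Draw phenotypic bulks from an F2 population
#'
#' Simple random samples, without replacement, from the yellow and green
#' phenotype classes; each member contributes equal weight downstream
#' (equal-DNA pooling).
#'
#' @param population Population with phenotypes assigned.
#' @param yellow_n,green_n Bulk sizes.
#' @param seed Optional seed.
#' @return List with `yellow` and `green` integer vectors of plant row
#'   indices (disjoint).
#' @export
build_bulks <- function(population,
                        yellow_n = population$config$yellow_bulk_n,
                        green_n = population$config$green_bulk_n,
                        seed = NULL) {
  ph <- population$plants$phenotype
  if (all(is.na(ph)))
    stop_bsaseq("phenotypes not assigned; call assign_phenotypes() first")
  ycand <- which(ph == "yellow"); gcand <- which(ph == "green")
  if (yellow_n > length(ycand))
    stop_bsaseq("sampling error: %d yellow plants requested but only %d available",
                yellow_n, length(ycand))
  if (green_n > length(gcand))
    stop_bsaseq("sampling error: %d green plants requested but only %d available",
                green_n, length(gcand))
  with_seed_or_current(seed, {
    list(yellow = sort(sample(ycand, yellow_n)),
         green = sort(sample(gcand, green_n)))
  })
}
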