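#' Configuration for the synthetic TILLING/BSA experiment
#'
#' Bundles every tunable of the synthetic data generator. Defaults encode the
#' study conditions of the experiment the package emulates: an EMS mutation
#' density of 23 mutations/Mb, two generations of selfing between the M2 and
#' the M4, an F2 of 214 plants scored for a fully penetrant dominant trait,
#' phenotypic bulks of 75 (mutant, "yellow") and 16 (wild-type, "green")
#' plants, and a flow-sorted chromosome fraction of 80% purity. Sizes not
#' fixed by the experiment (chromosome lengths, depth, varietal density) are
#' set to desk-scale values discussed in the methods vignette.
#'
#' @param seed Integer seed; every generator stage is deterministic given the
#'   config and its seed.
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param n_genes_per_chromosome Number of non-overlapping gene models to
#'   place on each chromosome.
#' @param mutation_density EMS mutations per Mb (default 23).
#' @param selfing_generations_to_M4 Selfing rounds between M2 and M4
#'   (default 2).
#' @param f2_size Number of F2 plants.
#' @param yellow_bulk_n,green_bulk_n Bulk sizes for the mutant-phenotype and
#'   wild-type-phenotype pools (defaults 75 and 16).
#' @param mean_depth Mean sequencing depth per site (Poisson).
#' @param sequencing_error_rate Per-base miscall fraction.
#' @param varietal_snp_density Cultivar-vs-reference SNPs per Mb injected
#'   into the alternate assembly.
#' @param scaffold_mean_length Mean scaffold length (bp) of the fragmented
#'   alternate assembly.
#' @param flowsort_purity Fraction of the flow-sorted sample deriving from
#'   the target chromosome (default 0.80; the remainder is contaminant).
#' @param penetrance Probability that a plant carrying at least one mutant
#'   causal allele expresses the mutant phenotype (default 1; lower values
#'   model environments where the phenotype vanishes).
#' @param map_length_per_mb Genetic map length in Morgans per Mb
#'   (default 0.02); crossovers are Poisson with uniform positions and no
#'   interference.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, chromosomes = c(chrA = 2e6, chrB = 2e6))
sim_config <- function(seed = 1L,
                       chromosomes = c(chrA = 8e6, chrB = 8e6),
                       n_genes_per_chromosome = 40L,
                       mutation_density = 23,
                       selfing_generations_to_M4 = 2L,
                       f2_size = 214L,
                       yellow_bulk_n = 75L,
                       green_bulk_n = 16L,
                       mean_depth = 200,
                       sequencing_error_rate = 0.005,
                       varietal_snp_density = 2500,
                       scaffold_mean_length = 1e5,
                       flowsort_purity = 0.80,
                       penetrance = 1.0,
                       map_length_per_mb = 0.02) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop_bsaseq("config error: chromosomes must be a named vector of lengths")
  if (any(chromosomes <= 0))
    stop_bsaseq("config error: chromosome lengths must be > 0")
  for (nm in c("mutation_density", "sequencing_error_rate",
               "varietal_snp_density", "map_length_per_mb", "mean_depth"))
    if (get(nm) < 0) stop_bsaseq("config error: %s must be >= 0", nm)
  if (penetrance < 0 || penetrance > 1)
    stop_bsaseq("config error: penetrance must lie in [0, 1]")
  if (flowsort_purity < 0 || flowsort_purity > 1)
    stop_bsaseq("config error: flowsort_purity must lie in [0, 1]")
  if (yellow_bulk_n > f2_size || green_bulk_n > f2_size)
    stop_bsaseq("config error: bulk sizes cannot exceed f2_size")
  if (scaffold_mean_length <= 0)
    stop_bsaseq("config error: scaffold_mean_length must be > 0")
  if (selfing_generations_to_M4 < 0)
    stop_bsaseq("config error: selfing_generations_to_M4 must be >= 0")
  structure(list(
    seed = as.integer(seed),
    chromosomes = chromosomes,
    n_genes_per_chromosome = as.integer(n_genes_per_chromosome),
    mutation_density = mutation_density,
    selfing_generations_to_M4 = as.integer(selfing_generations_to_M4),
    f2_size = as.integer(f2_size),
    yellow_bulk_n = as.integer(yellow_bulk_n),
    green_bulk_n = as.integer(green_bulk_n),
    mean_depth = mean_depth,
    sequencing_error_rate = sequencing_error_rate,
    varietal_snp_density = varietal_snp_density,
    scaffold_mean_length = scaffold_mean_length,
    flowsort_purity = flowsort_purity,
    penetrance = penetrance,
    map_length_per_mb = map_length_per_mb
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  chromosomes: %s\n",
              paste(sprintf("%s (%.1f Mb)", names(x$chromosomes),
                            x$chromosomes / 1e6), collapse = ", ")))
  cat(sprintf("  mutation density: %g/Mb; varietal density: %g/Mb\n",
              x$mutation_density, x$varietal_snp_density))
  cat(sprintf("  F2 size %d; bulks %d yellow / %d green; depth %gX\n",
              x$f2_size, x$yellow_bulk_n, x$green_bulk_n, x$mean_depth))
  cat(sprintf("  penetrance %g; flow-sort purity %g; map %g M/Mb; seed %d\n",
              x$penetrance, x$flowsort_purity, x$map_length_per_mb, x$seed))
  invisible(x)
}
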