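#' Configuration for the end-to-end pipeline
#'
#' Aggregates the analysis parameters at their canonical defaults —
#' smoothing window 4, Delta threshold 0.5, QUAL >= 20, DP > 10,
#' homozygous-only, 1 kb gene flank, 3 Mb search-region flanks, two
#' independent plants to define a mapping boundary — together with a
#' [sim_config()] for the synthetic stages. Any override is echoed in the
#' run log.
#'
#' @param sim A [sim_config()].
#' @param out_dir Output directory for stage artifacts (created).
#' @param seed Master seed; stage seeds are derived from it.
#' @param stages Character subset of
#'   `c("simulate", "scan", "filter", "anchor", "finemap")` (in order).
#' @param window,threshold,min_snps Delta-scan parameters.
#' @param min_qual,min_depth,homozygous_only Variant quality thresholds.
#' @param mask_window,mask_alpha,mask_min_count Density-mask parameters.
#' @param gene_flank Gene-proximity distance in bp.
#' @param region_flank_upstream,region_flank_downstream Search-region
#'   flanks in bp.
#' @param min_independent Fine-mapping exclusion rule.
#' @param causal_chrom Chromosome carrying the causal mutation (defaults to
#'   the first configured chromosome).
#' @param noise_clusters Spurious dense-SNP clusters per chromosome in the
#'   flow-sort simulation (default 2, exercising density masking).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("bsaseq_run_"),
                            seed = sim$seed,
                            stages = c("simulate", "scan", "filter",
                                       "anchor", "finemap"),
                            window = 4L, threshold = 0.5, min_snps = 3L,
                            min_qual = 20, min_depth = 10,
                            homozygous_only = TRUE,
                            mask_window = 10000L, mask_alpha = 1e-4,
                            mask_min_count = 5L,
                            gene_flank = 1000L,
                            region_flank_upstream = 3e6,
                            region_flank_downstream = 3e6,
                            min_independent = 2L,
                            causal_chrom = names(sim$chromosomes)[1],
                            noise_clusters = 2L) {
  if (!inherits(sim, "sim_config"))
    stop_bsaseq("config validation failure: sim must be a sim_config")
  if (window < 1) stop_bsaseq("config validation failure: window must be >= 1")
  if (threshold < -1 || threshold > 1)
    stop_bsaseq("config validation failure: threshold must lie in [-1, 1]")
  if (min_snps < 1) stop_bsaseq("config validation failure: min_snps must be >= 1")
  if (mask_window <= 0) stop_bsaseq("config validation failure: mask_window must be > 0")
  if (min_independent < 1)
    stop_bsaseq("config validation failure: min_independent must be >= 1")
  if (!causal_chrom %in% names(sim$chromosomes))
    stop_bsaseq("config validation failure: causal_chrom %s not in chromosomes",
                causal_chrom)
  bad <- setdiff(stages, c("simulate", "scan", "filter", "anchor", "finemap"))
  if (length(bad))
    stop_bsaseq("config validation failure: unknown stage(s) %s",
                paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the simulate / scan / filter / anchor / finemap pipeline
#'
#' Executes the requested stages in order, persisting intermediate
#' artifacts (FASTA, GFF3, VCF, TSV, BED) under `config$out_dir` and a
#' machine-readable `summary.json` plus a `run_log.txt` with the full
#' effective parameter set. Fully deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_bsaseq("config validation failure: expected a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("bsaseq pipeline run")
  logf("effective parameters:")
  for (nm in setdiff(names(config), "sim"))
    logf("  %s = %s", nm, paste(format(config[[nm]]), collapse = ","))
  for (nm in names(config$sim))
    logf("  sim.%s = %s", nm, paste(format(config$sim[[nm]]), collapse = ","))

  seed <- config$seed
  sim <- config$sim
  summary <- list(seed = seed)
  state <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop_bsaseq("stage '%s' failed: %s", name, conditionMessage(e)))
    logf("stage %s: done", name)
    res
  }

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() {
      genome <- generate_genome(sim, seed = seed)
      mutations <- induce_ems_mutations(genome, sim$mutation_density,
                                        seed = seed + 1L)
      mutations <- mark_causal(mutations, config$causal_chrom)
      pop <- propagate_pedigree(mutations, sim, seed = seed + 2L)
      pop <- assign_phenotypes(pop, seed = seed + 3L)
      ph <- table(factor(pop$plants$phenotype, c("yellow", "green")))
      chi <- segregation_chi2(ph[["yellow"]], ph[["green"]])
      bulks <- build_bulks(pop, seed = seed + 4L)
      sites <- segregating_sites(pop)
      counts <- simulate_bulk_counts(pop, bulks, sites, seed = seed + 5L)
      write_fasta(genome, file.path(config$out_dir, "reference.fasta"))
      write_gff3(genome, file.path(config$out_dir, "genes.gff3"))
      write.table(pop$loci, file.path(config$out_dir, "truth_mutations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(plant_id = pop$plants$id,
                             phenotype = pop$plants$phenotype),
                  file.path(config$out_dir, "phenotypes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      for (b in c("yellow", "green")) {
        v <- data.frame(chrom = counts$chrom, pos = counts$pos,
                        ref = pop$loci$ref[match(paste(counts$chrom, counts$pos),
                                                 paste(pop$loci$chrom, pop$loci$pos))],
                        alt = pop$loci$alt[match(paste(counts$chrom, counts$pos),
                                                 paste(pop$loci$chrom, pop$loci$pos))],
                        qual = 60,
                        dp = counts[[paste0("DP_", b)]],
                        ao = counts[[paste0("AO_", b)]])
        write_vcf(v, file.path(config$out_dir, paste0("bulk_", b, ".vcf")),
                  sample_name = paste0(b, "_bulk"))
      }
      state$genome <<- genome
      state$pop <<- pop
      state$counts <<- counts
      summary$n_mutations <<- nrow(mutations)
      summary$causal <<- list(chrom = pop$loci$chrom[pop$causal],
                              pos = pop$loci$pos[pop$causal])
      summary$phenotypes <<- list(yellow = unname(ph[["yellow"]]),
                                  green = unname(ph[["green"]]),
                                  chi2 = chi$statistic, p = chi$p_value)
      summary$n_segregating_sites <<- nrow(counts)
    })
  }

  if ("scan" %in% config$stages) {
    run_stage("scan", function() {
      if (is.null(state$counts))
        stop_bsaseq("scan requires bulk counts (run the simulate stage or load data)")
      track <- smooth_track(delta_track(state$counts), config$window)
      regions <- call_enriched_regions(track, config$threshold,
                                       config$min_snps)
      write_track_tsv(track, file.path(config$out_dir, "delta_track.tsv"))
      write.table(regions, file.path(config$out_dir, "regions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(regions, file.path(config$out_dir, "regions.bed"))
      state$track <<- track
      state$regions <<- regions
      summary$regions <<- regions
    })
  }

  if ("filter" %in% config$stages) {
    run_stage("filter", function() {
      genome <- state$genome; pop <- state$pop
      assembly <- fragment_assembly(genome, sim, seed = seed + 6L)
      other <- setdiff(names(sim$chromosomes), config$causal_chrom)[1]
      flow <- simulate_flowsort_variants(
        pop$m4, pop$loci, genome, sim,
        target_chrom = config$causal_chrom,
        contaminant_chrom = other,
        varietal = assembly$varietal,
        noise_clusters = config$noise_clusters,
        seed = seed + 7L)
      casc <- filter_cascade(
        flow$variants, varietal_sites = assembly$varietal,
        min_qual = config$min_qual, min_depth_exclusive = config$min_depth,
        homozygous_only = config$homozygous_only,
        mask_window = config$mask_window, mask_density_prior = sim$mutation_density,
        mask_alpha = config$mask_alpha, mask_min_count = config$mask_min_count)
      write_vcf(cbind(casc$retained, ao = NA_integer_)[,
                c("chrom", "pos", "ref", "alt", "qual", "dp", "ao", "zygosity")],
                file.path(config$out_dir, "flowsort_filtered.vcf"))
      write.table(casc$report, file.path(config$out_dir, "filter_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      state$assembly <<- assembly
      state$cascade <<- casc
      summary$filter <<- list(input = casc$input_count,
                              retained = casc$retained_count,
                              drops = stats::setNames(as.list(casc$report$dropped),
                                                      casc$report$filter),
                              masked_windows = nrow(casc$masked_windows))
    })
  }

  if ("anchor" %in% config$stages) {
    run_stage("anchor", function() {
      genome <- state$genome; pop <- state$pop
      regs <- state$regions[state$regions$chrom == config$causal_chrom, ,
                            drop = FALSE]
      if (!nrow(regs))
        stop_bsaseq("no enriched region on %s to anchor around",
                    config$causal_chrom)
      top <- regs[which.max(regs$max_delta), ]
      region <- define_search_region(
        data.frame(chrom = top$chrom, pos = c(top$start, top$end)),
        chrom_length = sim$chromosomes[[config$causal_chrom]],
        upstream = config$region_flank_upstream,
        downstream = config$region_flank_downstream)
      region_genes <- genome$genes[genome$genes$chrom == region$chrom &
                                     genome$genes$end >= region$start &
                                     genome$genes$start <= region$end, ]
      # scaffold-branch variant calls: the parent line's mutations seen on
      # the cultivar assembly (no varietal background on this branch)
      smap <- state$assembly$scaffold_map
      hom <- which(pop$m4 > 0L)
      sv <- list()
      for (i in hom) {
        sc <- smap[smap$chrom == pop$loci$chrom[i] &
                     smap$start <= pop$loci$pos[i] &
                     smap$end >= pop$loci$pos[i], ]
        if (!nrow(sc)) next
        sv[[length(sv) + 1L]] <- data.frame(
          chrom = sc$scaffold, pos = pop$loci$pos[i] - sc$start + 1L,
          ref = pop$loci$ref[i], alt = pop$loci$alt[i],
          truth_chrom = pop$loci$chrom[i], truth_pos = pop$loci$pos[i],
          count = pop$m4[i])
      }
      sv <- do.call(rbind, sv)
      scaffold_variants <- withr::with_seed(seed + 8L, {
        dp <- rpois(nrow(sv), sim$mean_depth)
        ao <- rbinom(nrow(sv), dp, sv$count / 2)
        data.frame(chrom = sv$chrom, pos = sv$pos, ref = sv$ref,
                   alt = sv$alt, qual = pmin(60, 4 * ao), dp = dp,
                   zygosity = ifelse(ao / pmax(dp, 1) >= 0.8, "hom", "het"))
      })
      sfilt <- filter_cascade(scaffold_variants,
                              min_qual = config$min_qual,
                              min_depth_exclusive = config$min_depth,
                              homozygous_only = config$homozygous_only,
                              mask_window = NA)
      anchors <- find_gene_anchors(state$assembly$scaffolds,
                                   gene_sequences(genome, region_genes$gene_id))
      selected <- select_scaffolds(anchors, sfilt$retained,
                                   region_genes$gene_id)
      # lift passing variants on selected scaffolds via the best anchor
      lifted <- list()
      for (scf in selected) {
        a <- anchors[anchors$scaffold == scf &
                       anchors$gene_id %in% region_genes$gene_id, ]
        a <- a[which.max(a$identity * a$match_length), ]
        gref <- genome$genes[genome$genes$gene_id == a$gene_id, ]
        vv <- sfilt$retained[sfilt$retained$chrom == scf, , drop = FALSE]
        for (k in seq_len(nrow(vv))) {
          lf <- lift_scaffold_snp(vv[k, ], a, gref)
          lifted[[length(lifted) + 1L]] <- data.frame(
            scaffold = scf, scaffold_pos = vv$pos[k], chrom = lf$chrom,
            pos = lf$pos, ref = lf$ref, alt = lf$alt,
            confidence = lf$confidence)
        }
      }
      lifted <- if (length(lifted)) do.call(rbind, lifted) else
        data.frame(scaffold = character(), scaffold_pos = integer(),
                   chrom = character(), pos = integer(), ref = character(),
                   alt = character(), confidence = character())
      write.table(anchors, file.path(config$out_dir, "anchors.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(lifted, file.path(config$out_dir, "lifted_scaffold_snps.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      state$region <<- region
      state$region_genes <<- region_genes
      state$lifted <<- lifted
      summary$search_region <<- list(chrom = region$chrom,
                                     start = region$start, end = region$end)
      summary$anchoring <<- list(n_anchors = nrow(anchors),
                                 n_selected_scaffolds = length(selected),
                                 selected_scaffolds = selected,
                                 n_lifted_snps = nrow(lifted))
    })
  }

  if ("finemap" %in% config$stages) {
    run_stage("finemap", function() {
      genome <- state$genome; pop <- state$pop
      region <- state$region
      # marker set: loci segregating in the F2 (scorable in the mapping
      # population, as for KASP markers designed on parent SNPs), plus
      # cascade-passing reference SNPs and lifted scaffold SNPs; restricted
      # to the search region and to simulated loci
      cand <- rbind(segregating_sites(pop),
                    state$cascade$retained[, c("chrom", "pos")],
                    state$lifted[state$lifted$confidence == "anchored",
                                 c("chrom", "pos")])
      cand <- unique(cand[cand$chrom == region$chrom &
                            cand$pos >= region$start &
                            cand$pos <= region$end, ])
      li <- match(paste(cand$chrom, cand$pos),
                  paste(pop$loci$chrom, pop$loci$pos))
      li <- sort(unique(li[!is.na(li)]))
      if (length(li) < 2L)
        stop_bsaseq("fewer than 2 markers available in the search region")
      markers <- data.frame(id = sprintf("M%s_%d",
                                         sub("^chr", "", pop$loci$chrom[li]),
                                         pop$loci$pos[li]),
                            chrom = pop$loci$chrom[li], pos = pop$loci$pos[li])
      calls <- matrix(c("WT", "HET", "MUT")[pop$genotypes[, li] + 1L],
                      nrow = nrow(pop$plants))
      mat <- marker_genotype_matrix(markers, pop$plants[, c("id", "phenotype")],
                                    calls)
      interval <- map_interval(mat, config$min_independent,
                               multiple_runs = "largest")
      if (nrow(interval$satellite_runs))
        logf("finemap: %d satellite qualifying run(s) set aside",
             nrow(interval$satellite_runs))
      classes <- graphical_genotypes(mat)
      gin <- genes_in_interval(interval, genome$genes)
      # gene-proximal SNP report with effect classes
      prox <- select_gene_proximal(state$cascade$retained,
                                   state$region_genes, config$gene_flank)
      effects <- character(0)
      if (nrow(prox$retained)) {
        effects <- vapply(seq_len(nrow(prox$retained)), function(k) {
          v <- prox$retained[k, ]
          gid <- strsplit(v$gene_ids, ";", fixed = TRUE)[[1]][1]
          classify_effect(v, gene_model(genome, gid), genome,
                          promoter_size = config$gene_flank)
        }, character(1))
      }
      write.table(cbind(prox$retained,
                        effect = if (length(effects)) effects else character(0)),
                  file.path(config$out_dir, "gene_proximal_snps.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(classes, file.path(config$out_dir, "genotype_classes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      idf <- data.frame(chrom = interval$chrom, start = interval$start,
                        end = interval$end)
      write.table(idf, file.path(config$out_dir, "interval.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(idf, file.path(config$out_dir, "interval.bed"))
      summary$interval <<- list(
        chrom = interval$chrom, start = interval$start, end = interval$end,
        size_mb = (interval$end - interval$start + 1) / 1e6,
        n_markers = length(interval$retained_markers),
        left_marker = interval$left_marker,
        right_marker = interval$right_marker,
        contains_causal = interval$chrom == pop$loci$chrom[pop$causal] &&
          interval$start <= pop$loci$pos[pop$causal] &&
          interval$end >= pop$loci$pos[pop$causal])
      summary$genes_in_interval <<- list(n = nrow(gin), ids = gin$gene_id)
      summary$gene_proximal_snps <<- list(
        n = nrow(prox$retained),
        effects = as.list(table(effects)))
    })
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, file.path(config$out_dir, "summary.json"))
  logf("summary written")
  invisible(summary)
}
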