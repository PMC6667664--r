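# Variant tables are plain data frames with columns
# chrom, pos, ref, alt, qual, dp, zygosity; filters return
# list(retained, dropped) where dropped carries a `reason` column.

check_snv <- function(variants) {
  if (!nrow(variants)) return(invisible(variants))
  bad <- nchar(variants$ref) != 1L | nchar(variants$alt) != 1L |
    variants$ref == variants$alt
  if (any(bad))
    stop_bsaseq("integrity error: %d non-SNV record(s) (multi-base or ref == alt)",
                sum(bad))
  invisible(variants)
}

empty_like <- function(variants) variants[0, , drop = FALSE]

split_filter <- function(variants, keep, reason) {
  dropped <- variants[!keep, , drop = FALSE]
  reason <- rep_len(reason, nrow(variants))
  dropped$reason <- reason[!keep]
  list(retained = variants[keep, , drop = FALSE], dropped = dropped)
}

#' Retain EMS-like SNPs (reference G>A or C>T)
#'
#' EMS induces almost exclusively G>A and C>T transitions; calls against the
#' reference the mutant was aligned to are therefore EMS-like only when the
#' reference allele is G with alternate A, or reference C with alternate T.
#' The reverse pairs (A>G, T>C) are rejected.
#'
#' @param variants SNV data frame (chrom, pos, ref, alt, ...).
#' @return List with `retained` and `dropped` (reason "not-ems-like").
#' @export
filter_ems_like <- function(variants) {
  check_snv(variants)
  keep <- (variants$ref == "G" & variants$alt == "A") |
    (variants$ref == "C" & variants$alt == "T")
  split_filter(variants, keep, "not-ems-like")
}

#' Quality / depth / zygosity filter
#'
#' Retains records with QUAL >= `min_qual`, DP strictly greater than
#' `min_depth_exclusive`, and (optionally) homozygous calls only. The
#' boundary conventions (QUAL >= 20 inclusive, DP > 10 exclusive) follow
#' the printed thresholds exactly. Records missing QUAL or DP are dropped
#' with reason "missing-field".
#'
#' @param variants Variant data frame.
#' @param min_qual Minimum quality, inclusive (default 20).
#' @param min_depth_exclusive Depth must exceed this value (default 10).
#' @param homozygous_only Keep only `zygosity == "hom"` (default TRUE).
#' @return List with `retained` and `dropped`.
#' @export
filter_quality <- function(variants, min_qual = 20, min_depth_exclusive = 10,
                           homozygous_only = TRUE) {
  missing <- is.na(variants$qual) | is.na(variants$dp)
  pass <- !missing & variants$qual >= min_qual &
    variants$dp > min_depth_exclusive &
    (!homozygous_only | variants$zygosity == "hom")
  reason <- ifelse(missing, "missing-field", "quality-depth-zygosity")
  split_filter(variants, pass, reason)
}

#' Subtract varietal (cultivar background) SNPs
#'
#' Natural polymorphisms between the mutant line's cultivar and the
#' reference cultivar are not induced mutations and are removed. Matching is
#' by (chromosome, position) only: any cultivar polymorphism at a site makes
#' a mutant call there untrustworthy regardless of allele.
#'
#' @param variants Variant data frame.
#' @param varietal_sites Data frame with chrom and pos columns.
#' @return List with `retained` and `dropped` (reason "varietal").
#' @export
subtract_varietal <- function(variants, varietal_sites) {
  hit <- paste(variants$chrom, variants$pos) %in%
    paste(varietal_sites$chrom, varietal_sites$pos)
  split_filter(variants, !hit, "varietal")
}

#' Intersect variants with a lifted parent SNP list
#'
#' Retains only variants matching a parent-line SNP on (chromosome,
#' position, ref, alt) after lifting the parent SNPs from their source
#' assembly to the working reference with `lifter` (see
#' [make_flank_lifter()]). Parent SNPs that lift ambiguously or not at all
#' are logged and never match.
#'
#' @param variants Variant data frame on reference coordinates.
#' @param parent_snps Data frame (chrom, pos, ref, alt) on source-assembly
#'   coordinates.
#' @param lifter Function taking (chrom, pos, ref, alt) and returning a list
#'   with `status` ("lifted", "ambiguous" or "not_found") and, when lifted,
#'   reference chrom/pos/ref/alt. Use `identity_lifter` when parent SNPs are
#'   already on reference coordinates.
#' @return List with `retained`, `dropped` (reason "not-in-parent") and
#'   `unlifted` (parent SNPs that failed to lift, with their status).
#' @export
intersect_parent <- function(variants, parent_snps, lifter = identity_lifter) {
  lifted <- list(); unlifted <- list()
  for (i in seq_len(nrow(parent_snps))) {
    r <- lifter(parent_snps$chrom[i], parent_snps$pos[i],
                parent_snps$ref[i], parent_snps$alt[i])
    if (identical(r$status, "lifted")) {
      lifted[[length(lifted) + 1L]] <- data.frame(
        chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt)
    } else {
      unlifted[[length(unlifted) + 1L]] <- cbind(
        parent_snps[i, c("chrom", "pos", "ref", "alt"), drop = FALSE],
        status = r$status)
    }
  }
  lifted <- if (length(lifted)) do.call(rbind, lifted) else
    data.frame(chrom = character(), pos = integer(),
               ref = character(), alt = character())
  unlifted <- if (length(unlifted)) do.call(rbind, unlifted) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), status = character())
  keep <- paste(variants$chrom, variants$pos, variants$ref, variants$alt) %in%
    paste(lifted$chrom, lifted$pos, lifted$ref, lifted$alt)
  out <- split_filter(variants, keep, "not-in-parent")
  out$unlifted <- unlifted
  out
}

#' Trivial lifter for parent SNPs already on reference coordinates
#' @param chrom,pos,ref,alt One SNP.
#' @return A "lifted" result echoing the input.
#' @export
identity_lifter <- function(chrom, pos, ref, alt) {
  list(status = "lifted", chrom = chrom, pos = pos, ref = ref, alt = alt)
}

#' Mask windows of implausibly high SNP density
#'
#' Automated proxy for manual curation of repeat-driven spurious calls:
#' chromosomes are tiled in fixed windows and a window is masked when its
#' SNP count is at least `min_count` and the Poisson upper-tail probability
#' of that count, at the expected TILLING density, falls below `alpha`. All
#' variants in masked windows are dropped.
#'
#' @param variants Variant data frame.
#' @param window Window size in bp (default 10,000).
#' @param density_prior Expected mutations per Mb (default 23).
#' @param alpha Upper-tail significance level (default 1e-4).
#' @param min_count Minimum count for masking (default 5).
#' @return List with `retained`, `dropped` (reason "dense-region") and
#'   `masked_windows` (chrom, start, end, n_snps).
#' @export
mask_dense_regions <- function(variants, window = 10000L, density_prior = 23,
                               alpha = 1e-4, min_count = 5L) {
  if (window <= 0) stop_bsaseq("config error: window must be > 0")
  if (!nrow(variants)) {
    out <- split_filter(variants, logical(0), "dense-region")
    out$masked_windows <- data.frame(chrom = character(), start = integer(),
                                     end = integer(), n_snps = integer())
    return(out)
  }
  lambda <- density_prior * window / 1e6
  win <- (variants$pos - 1L) %/% as.integer(window)
  key <- paste(variants$chrom, win)
  counts <- table(key)
  tail_p <- ppois(as.integer(counts) - 1L, lambda, lower.tail = FALSE)
  masked_keys <- names(counts)[as.integer(counts) >= min_count & tail_p < alpha]
  hit <- key %in% masked_keys
  out <- split_filter(variants, !hit, "dense-region")
  if (length(masked_keys)) {
    parts <- do.call(rbind, strsplit(masked_keys, " (?=[0-9]+$)", perl = TRUE))
    w0 <- as.integer(parts[, 2])
    mw <- data.frame(chrom = parts[, 1], start = w0 * window + 1L,
                     end = (w0 + 1L) * window,
                     n_snps = as.integer(counts[masked_keys]))
    mw <- mw[order(mw$chrom, mw$start), , drop = FALSE]
    rownames(mw) <- NULL
    out$masked_windows <- mw
  } else {
    out$masked_windows <- data.frame(chrom = character(), start = integer(),
                                     end = integer(), n_snps = integer())
  }
  out
}

#' Retain variants near annotated genes
#'
#' Keeps variants lying within `flank` bp (default 1 kb) of a gene interval
#' (gene body included) and annotates each with all qualifying gene ids —
#' a variant between two close gene models is associated with both. Output
#' is deduplicated by variant.
#'
#' @param variants Variant data frame.
#' @param genes Gene table (gene_id, chrom, start, end).
#' @param flank Distance in bp (default 1000).
#' @return List with `retained` (with a `gene_ids` column,
#'   semicolon-separated) and `dropped` (reason "not-gene-proximal").
#' @export
select_gene_proximal <- function(variants, genes, flank = 1000L) {
  if (!nrow(variants)) {
    out <- split_filter(variants, logical(0), "not-gene-proximal")
    out$retained$gene_ids <- character(0)
    return(out)
  }
  gene_ids <- rep(NA_character_, nrow(variants))
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    vr <- IRanges::IRanges(variants$pos[vi], variants$pos[vi])
    gr <- IRanges::IRanges(pmax(1L, g$start - as.integer(flank)),
                           g$end + as.integer(flank))
    ov <- IRanges::findOverlaps(vr, gr)
    if (!length(ov)) next
    hits <- split(g$gene_id[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
    for (q in names(hits))
      gene_ids[vi[as.integer(q)]] <- paste(hits[[q]], collapse = ";")
  }
  keep <- !is.na(gene_ids)
  out <- split_filter(variants, keep, "not-gene-proximal")
  out$retained$gene_ids <- gene_ids[keep]
  out
}

#' Run the full SNP filter cascade with an auditable report
#'
#' Applies, in fixed order, the stages for which inputs are supplied:
#' parent-SNP intersection, EMS spectrum, quality/depth/zygosity, varietal
#' subtraction, density masking, gene proximity. Every input record is
#' attributed to exactly one outcome (retained, or dropped by the first
#' rejecting filter), so the report always balances.
#'
#' @param variants Variant data frame.
#' @param parent_snps,lifter Parent SNP list and coordinate lifter
#'   (stage skipped when `parent_snps` is NULL).
#' @param varietal_sites Varietal site table (stage skipped when NULL).
#' @param genes Gene table for the proximity stage (skipped when NULL).
#' @param min_qual,min_depth_exclusive,homozygous_only Quality thresholds.
#' @param mask_window,mask_density_prior,mask_alpha,mask_min_count Density
#'   masking parameters; set `mask_window = NA` to skip masking.
#' @param gene_flank Proximity distance in bp.
#' @return List of class `filter_report`: `retained`, `dropped` (with
#'   per-record reasons), `report` (per-filter drop counts),
#'   `masked_windows`, `unlifted_parent_snps`.
#' @export
filter_cascade <- function(variants,
                           parent_snps = NULL, lifter = identity_lifter,
                           varietal_sites = NULL, genes = NULL,
                           min_qual = 20, min_depth_exclusive = 10,
                           homozygous_only = TRUE,
                           mask_window = 10000L, mask_density_prior = 23,
                           mask_alpha = 1e-4, mask_min_count = 5L,
                           gene_flank = 1000L) {
  input_n <- nrow(variants)
  dropped <- list(); report <- list()
  masked_windows <- NULL; unlifted <- NULL
  cur <- variants
  step <- function(name, res) {
    dropped[[name]] <<- res$dropped
    report[[name]] <<- nrow(res$dropped)
    res$retained
  }
  if (!is.null(parent_snps)) {
    res <- intersect_parent(cur, parent_snps, lifter)
    unlifted <- res$unlifted
    cur <- step("parent-intersection", res)
  }
  cur <- step("ems-spectrum", filter_ems_like(cur))
  cur <- step("quality", filter_quality(cur, min_qual, min_depth_exclusive,
                                        homozygous_only))
  if (!is.null(varietal_sites))
    cur <- step("varietal-subtraction", subtract_varietal(cur, varietal_sites))
  if (!is.na(mask_window)) {
    res <- mask_dense_regions(cur, mask_window, mask_density_prior,
                              mask_alpha, mask_min_count)
    masked_windows <- res$masked_windows
    cur <- step("density-mask", res)
  }
  if (!is.null(genes))
    cur <- step("gene-proximity", select_gene_proximal(cur, genes, gene_flank))
  all_dropped <- do.call(rbind, lapply(dropped, function(d)
    d[, c(intersect(names(variants), names(d)), "reason"), drop = FALSE]))
  rownames(all_dropped) <- NULL
  structure(list(
    retained = cur,
    dropped = all_dropped,
    report = data.frame(filter = names(report),
                        dropped = unlist(report, use.names = FALSE)),
    input_count = input_n,
    retained_count = nrow(cur),
    masked_windows = masked_windows,
    unlifted_parent_snps = unlifted
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter cascade: %d in -> %d retained\n",
              x$input_count, x$retained_count))
  for (i in seq_len(nrow(x$report)))
    cat(sprintf("  %-20s dropped %d\n", x$report$filter[i], x$report$dropped[i]))
  if (!is.null(x$masked_windows) && nrow(x$masked_windows))
    cat(sprintf("  masked windows: %d\n", nrow(x$masked_windows)))
  invisible(x)
}
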