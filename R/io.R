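# Readers and writers for the interchange formats: VCF v4.2 subset (INFO
# keys DP and AO, optional GT), FASTA, GFF3, TSV tables and BED. All
# VCF/GFF3/TSV coordinates are 1-based inclusive; BED is 0-based half-open.

#' Write variants as a minimal VCF v4.2 file
#'
#' @param variants Data frame (chrom, pos, ref, alt, qual, dp and either an
#'   `ao` column or AO implied absent). Optional `zygosity` emits a GT
#'   sample column ("1/1" hom, "0/1" het).
#' @param path Output path.
#' @param sample_name Sample column name when GT is written.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_name = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsaseq",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"), con)
  has_gt <- "zygosity" %in% names(variants)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) header <- c(header, "FORMAT", sample_name)
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(variants)) {
    ao <- if ("ao" %in% names(variants)) variants$ao else NA_integer_
    info <- ifelse(is.na(ao),
                   sprintf("DP=%d", variants$dp),
                   sprintf("DP=%d;AO=%d", variants$dp, ao))
    qual <- ifelse(is.na(variants$qual), ".",
                   format(variants$qual, trim = TRUE, scientific = FALSE))
    fields <- cbind(variants$chrom, variants$pos, ".", variants$ref,
                    variants$alt, qual, "PASS", info)
    if (has_gt)
      fields <- cbind(fields, "GT",
                      ifelse(variants$zygosity == "hom", "1/1", "0/1"))
    writeLines(apply(fields, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF v4.2 subset into a variant data frame
#'
#' Parses CHROM/POS/REF/ALT/QUAL plus the INFO keys DP and AO; a GT sample
#' column, when present, provides zygosity. Multi-allelic records are split
#' into one row per alternate allele with AO matched per alternate. An AO
#' exceeding DP is a data-integrity error.
#'
#' @param path VCF path (plain text).
#' @return Data frame (chrom, pos, ref, alt, qual, dp, ao, zygosity).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  n <- nrow(fx)
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), dp = integer(),
                      ao = integer(), zygosity = character()))
  info <- v@fix[, "INFO"]
  getkey <- function(key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, n)
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info)))
    out
  }
  dp <- suppressWarnings(as.integer(getkey("DP")))
  ao_raw <- getkey("AO")
  zyg <- rep(NA_character_, n)
  if (ncol(v@gt) >= 2) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gtv <- gt[, 1]
    zyg <- ifelse(gtv %in% c("1/1", "1|1"), "hom",
                  ifelse(gtv %in% c("0/1", "0|1", "1/0", "1|0"), "het",
                         NA_character_))
  }
  rows <- list()
  for (i in seq_len(n)) {
    alts <- strsplit(fx[i, "ALT"], ",", fixed = TRUE)[[1]]
    aos <- if (is.na(ao_raw[i])) rep(NA_integer_, length(alts)) else
      suppressWarnings(as.integer(strsplit(ao_raw[i], ",", fixed = TRUE)[[1]]))
    if (length(aos) < length(alts)) aos <- rep(aos, length.out = length(alts))
    for (k in seq_along(alts)) {
      if (!is.na(aos[k]) && !is.na(dp[i]) && aos[k] > dp[i])
        stop_bsaseq("integrity error: AO (%d) > DP (%d) in record %d (%s:%s)",
                    aos[k], dp[i], i, fx[i, "CHROM"], fx[i, "POS"])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fx[i, "CHROM"], pos = as.integer(fx[i, "POS"]),
        ref = fx[i, "REF"], alt = alts[k],
        qual = suppressWarnings(as.numeric(fx[i, "QUAL"])),
        dp = dp[i], ao = aos[k], zygosity = zyg[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge per-bulk variant tables into shared-site bulk counts
#'
#' Delta is computed per shared site only: sites present in one bulk's
#' calls but not the other are dropped and counted.
#'
#' @param yellow,green Data frames from [read_vcf()] (need chrom, pos, ao,
#'   dp).
#' @return A `bulk_counts` data frame; attribute `n_unshared` records the
#'   number of dropped one-sided sites.
#' @export
merge_bulk_counts <- function(yellow, green) {
  ky <- paste(yellow$chrom, yellow$pos)
  kg <- paste(green$chrom, green$pos)
  shared <- intersect(ky, kg)
  y <- yellow[match(shared, ky), ]
  g <- green[match(shared, kg), ]
  out <- data.frame(chrom = y$chrom, pos = y$pos,
                    AO_yellow = y$ao, DP_yellow = y$dp,
                    AO_green = g$ao, DP_green = g$dp)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("bulk_counts", "data.frame")
  attr(out, "n_unshared") <- (length(ky) - length(shared)) +
    (length(kg) - length(shared))
  out
}

#' Read a marker genotype matrix and marker map from TSV
#'
#' The matrix file has columns plant_id, phenotype, then one column per
#' marker with calls in WT/HET/MUT/NA (case-insensitive). Markers are
#' ordered by the map file (marker, chrom, pos), not by column order.
#'
#' @param matrix_path,map_path File paths.
#' @return A [marker_genotype_matrix()].
#' @export
read_marker_table <- function(matrix_path, map_path) {
  tab <- read.delim(matrix_path, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", "na", ""))
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop_bsaseq("map file must have columns %s", paste(need, collapse = ", "))
  marker_cols <- setdiff(names(tab), c("plant_id", "phenotype"))
  missing_map <- setdiff(marker_cols, map$marker)
  if (length(missing_map))
    stop_bsaseq("marker(s) absent from map: %s",
                paste(missing_map, collapse = ", "))
  map <- map[map$marker %in% marker_cols, ]
  map <- map[order(map$chrom, map$pos), ]
  raw <- as.matrix(tab[, map$marker, drop = FALSE])
  calls <- toupper(trimws(raw))
  calls[calls == "NA" | calls == ""] <- NA_character_
  bad <- !is.na(calls) & !(calls %in% c("WT", "HET", "MUT"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_bsaseq("parse error: unknown call token '%s' at plant %s, marker %s",
                raw[bad][1], tab$plant_id[w[1]], map$marker[w[2]])
  }
  marker_genotype_matrix(
    markers = data.frame(id = map$marker, chrom = map$chrom, pos = map$pos),
    plants = data.frame(id = tab$plant_id, phenotype = tolower(tab$phenotype)),
    calls = calls)
}

#' Write a Delta track as a plotting-ready TSV
#' @param track A `delta_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  cols <- intersect(c("chrom", "pos", "ratio_yellow", "ratio_green",
                      "delta", "smoothed_delta"), names(track))
  write.table(track[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive regions to BED (0-based half-open)
#' @param regions Data frame with chrom, start, end (1-based inclusive).
#' @return Data frame with chrom, start (0-based), end (exclusive).
#' @export
regions_to_bed <- function(regions) {
  data.frame(chrom = regions$chrom, start = regions$start - 1L,
             end = regions$end)
}

#' Write regions as BED
#' @param regions 1-based inclusive region table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  write.table(regions_to_bed(regions), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genome sequences as FASTA
#' @param x A `sim_genome`, `sim_assembly` or DNAStringSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(as_seqset(x), path)
  invisible(path)
}

#' Write gene annotation as GFF3
#'
#' Emits gene, exon and CDS features with ID/Parent attributes, 1-based
#' inclusive per the GFF3 convention.
#'
#' @param genome A `sim_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tbsaseq\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    writeLines(fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   sprintf("ID=%s", g$gene_id)), con)
    ex <- genome$exons[genome$exons$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(ex)))
      writeLines(fmt(g$chrom, "exon", ex$start[j], ex$end[j], g$strand,
                     sprintf("Parent=%s", g$gene_id)), con)
    cd <- genome$cds[genome$cds$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(cd)))
      writeLines(fmt(g$chrom, "CDS", cd$start[j], cd$end[j], g$strand,
                     sprintf("Parent=%s", g$gene_id)), con)
  }
  invisible(path)
}

#' Read gene intervals from a GFF3 file
#'
#' @param path GFF3 path.
#' @return Gene table (gene_id, chrom, start, end, strand) from `gene`
#'   features.
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  keep <- f[, 3] == "gene"
  f <- f[keep, , drop = FALSE]
  ids <- sub(".*ID=([^;]+).*", "\\1", f[, 9])
  data.frame(gene_id = ids, chrom = f[, 1], start = as.integer(f[, 4]),
             end = as.integer(f[, 5]), strand = f[, 7])
}
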