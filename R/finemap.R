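#' Construct a marker genotype matrix
#'
#' Plants x ordered markers with a binary phenotype per plant, the input to
#' recombinant fine-mapping. Markers must lie on one chromosome and be
#' strictly position-sorted; calls are WT / HET / MUT / NA.
#'
#' @param markers Data frame (id, chrom, pos).
#' @param plants Data frame (id, phenotype in {"yellow","green"} or NA).
#' @param calls Character matrix, plants x markers.
#' @return List of class `marker_matrix`.
#' @export
marker_genotype_matrix <- function(markers, plants, calls) {
  if (length(unique(markers$chrom)) > 1L)
    stop_bsaseq("markers must lie on a single chromosome")
  if (is.unsorted(markers$pos, strictly = TRUE))
    stop_bsaseq("markers must be strictly position-sorted")
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(plants) || ncol(calls) != nrow(markers))
    stop_bsaseq("calls must be %d plants x %d markers",
                nrow(plants), nrow(markers))
  ok <- calls %in% c("WT", "HET", "MUT") | is.na(calls)
  if (!all(ok))
    stop_bsaseq("invalid call token(s): %s",
                paste(unique(calls[!ok]), collapse = ", "))
  dimnames(calls) <- list(plants$id, markers$id)
  structure(list(markers = markers, plants = plants, calls = calls),
            class = "marker_matrix")
}

#' Per-marker inconsistent plants under full dominance
#'
#' A yellow (mutant-phenotype) plant is inconsistent with a marker iff its
#' call there is WT — heterozygotes express the dominant phenotype, so HET
#' and MUT are both consistent. A green plant is inconsistent iff its call
#' is HET or MUT. Missing calls are never inconsistent; plants with no
#' phenotype are excluded with a warning.
#'
#' @param mat A [marker_genotype_matrix()].
#' @return Named list (one element per marker) of inconsistent plant ids.
#' @export
score_marker_consistency <- function(mat) {
  ph <- mat$plants$phenotype
  unscored <- is.na(ph) | !(ph %in% c("yellow", "green"))
  if (any(unscored))
    warning(sprintf("%d plant(s) without phenotype excluded", sum(unscored)),
            call. = FALSE)
  use <- which(!unscored)
  lapply(seq_len(nrow(mat$markers)), function(j) {
    calls <- mat$calls[use, j]
    bad <- ifelse(ph[use] == "yellow", !is.na(calls) & calls == "WT",
                  !is.na(calls) & calls %in% c("HET", "MUT"))
    mat$plants$id[use][bad]
  }) |> stats::setNames(mat$markers$id)
}

#' Map the causal interval from recombinant genotypes
#'
#' A marker is excluded from the interval when at least `min_independent`
#' independent plants are inconsistent with it (default 2 — a single plant,
#' possibly a genotyping error, never defines a boundary). The interval is
#' the maximal run of consecutive non-excluded markers; its boundary
#' markers are the nearest flanking excluded markers, and a side with no
#' excluded flanking marker is reported open-ended. The physical interval
#' spans the positions of the first and last retained marker (inclusive).
#' Plants inconsistent at a single isolated marker but consistent at both
#' neighbours are flagged as possible genotyping errors (they still count).
#'
#' @param mat A [marker_genotype_matrix()].
#' @param min_independent Minimum independent inconsistent plants to
#'   exclude a marker (default 2).
#' @param multiple_runs Policy when disjoint qualifying runs occur:
#'   "error" (default; disjoint runs signal a genotyping problem or a
#'   second locus) or "largest" (keep the longest run — ties broken to the
#'   first — and report the others in `satellite_runs`).
#' @return List of class `mapped_interval`: chrom, start, end, retained
#'   marker ids, left/right boundary marker ids (NA when open), open_left /
#'   open_right flags, per-marker inconsistency counts, and flagged
#'   possible genotyping errors.
#' @export
map_interval <- function(mat, min_independent = 2L,
                         multiple_runs = c("error", "largest")) {
  multiple_runs <- match.arg(multiple_runs)
  inc <- score_marker_consistency(mat)
  counts <- lengths(inc)
  qualify <- counts < min_independent
  if (!any(qualify))
    stop_bsaseq("mapping failure: no marker has fewer than %d inconsistent plants",
                min_independent)
  r <- rle(qualify)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  satellites <- data.frame(start_marker = character(), end_marker = character())
  if (length(runs) > 1L) {
    if (multiple_runs == "error")
      stop_bsaseq("mapping error: %d disjoint qualifying marker runs (%s) — genotyping error or second locus?",
                  length(runs),
                  paste(sprintf("%s-%s", mat$markers$id[starts[runs]],
                                mat$markers$id[ends[runs]]), collapse = ", "))
    main <- runs[which.max(r$lengths[runs])]
    others <- setdiff(runs, main)
    satellites <- data.frame(start_marker = mat$markers$id[starts[others]],
                             end_marker = mat$markers$id[ends[others]])
    runs <- main
  }
  i1 <- starts[runs]; i2 <- ends[runs]
  nm <- nrow(mat$markers)
  # possible genotyping errors: plant inconsistent at one marker but
  # consistent at both neighbours
  flags <- list()
  for (j in seq_len(nm)) {
    for (p in inc[[j]]) {
      left_ok <- j == 1L || !(p %in% inc[[j - 1L]])
      right_ok <- j == nm || !(p %in% inc[[j + 1L]])
      if (left_ok && right_ok && nm > 1L)
        flags[[length(flags) + 1L]] <- data.frame(plant = p,
                                                  marker = mat$markers$id[j])
    }
  }
  structure(list(
    chrom = mat$markers$chrom[1],
    start = mat$markers$pos[i1],
    end = mat$markers$pos[i2],
    retained_markers = mat$markers$id[i1:i2],
    left_marker = if (i1 > 1L) mat$markers$id[i1 - 1L] else NA_character_,
    right_marker = if (i2 < nm) mat$markers$id[i2 + 1L] else NA_character_,
    open_left = i1 == 1L,
    open_right = i2 == nm,
    inconsistency_counts = counts,
    satellite_runs = satellites,
    possible_genotyping_errors = if (length(flags)) do.call(rbind, flags)
      else data.frame(plant = character(), marker = character())
  ), class = "mapped_interval")
}

#' @export
print.mapped_interval <- function(x, ...) {
  cat(sprintf("mapped interval: %s:%s-%s (%.2f Mb, %d markers)\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), (x$end - x$start + 1) / 1e6,
              length(x$retained_markers)))
  cat(sprintf("  boundaries: %s%s / %s%s\n",
              ifelse(is.na(x$left_marker), "(chromosome start)", x$left_marker),
              ifelse(x$open_left, " [open]", ""),
              ifelse(is.na(x$right_marker), "(chromosome end)", x$right_marker),
              ifelse(x$open_right, " [open]", "")))
  invisible(x)
}

#' Group plants into graphical-genotype recombination classes
#'
#' Plants with identical marker call vectors form one class; missing calls
#' act as wildcards and are merged greedily into the first compatible class
#' in discovery order (a missing slot in a class representative is filled
#' from the first member that observes it).
#'
#' @param mat A [marker_genotype_matrix()].
#' @return Data frame: one row per class with the representative call
#'   vector (markers pasted with "/"), plant count, member ids, and
#'   phenotype composition.
#' @export
graphical_genotypes <- function(mat) {
  reps <- list(); members <- list()
  for (i in seq_len(nrow(mat$plants))) {
    v <- mat$calls[i, ]
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[[k]]
      both <- !is.na(v) & !is.na(r)
      if (all(v[both] == r[both])) {
        fill <- is.na(r) & !is.na(v)
        r[fill] <- v[fill]
        reps[[k]] <- r
        members[[k]] <- c(members[[k]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- v
      members[[length(members) + 1L]] <- i
    }
  }
  data.frame(
    class = seq_along(reps),
    genotype = vapply(reps, function(r)
      paste(ifelse(is.na(r), ".", r), collapse = "/"), character(1)),
    n_plants = lengths(members),
    n_yellow = vapply(members, function(m)
      sum(mat$plants$phenotype[m] == "yellow", na.rm = TRUE), integer(1)),
    n_green = vapply(members, function(m)
      sum(mat$plants$phenotype[m] == "green", na.rm = TRUE), integer(1)),
    plants = vapply(members, function(m)
      paste(mat$plants$id[m], collapse = ","), character(1)))
}

#' Genes overlapping a mapped interval
#'
#' Any overlap (down to 1 bp) counts; genes are returned in physical order.
#'
#' @param interval A [map_interval()] result or list with chrom/start/end.
#' @param genes Gene table (gene_id, chrom, start, end).
#' @return Data frame of overlapping genes, physically ordered.
#' @export
genes_in_interval <- function(interval, genes) {
  g <- genes[genes$chrom == interval$chrom &
               genes$end >= interval$start &
               genes$start <= interval$end, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  rownames(g) <- NULL
  g
}
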