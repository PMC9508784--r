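# Recombinant-based interval narrowing from marker-genotype matrices, and
# screening/validation of diagnostic indel markers by genotype-phenotype
# co-segregation. All rules assume the single-locus recessive model:
# a weeping individual must be homozygous mutant (code B) at a fully
# linked marker.

#' Count recombinant individuals at a marker
#'
#' Under the recessive model an individual is recombinant at a marker iff
#' (phenotype weeping and genotype != B) or (phenotype standard and
#' genotype == B). Missing genotypes (`-`) are uninformative and excluded.
#'
#' @param mm A `marker_matrix`.
#' @param marker Marker name present in `mm`.
#' @return A list: `n_recombinant`, `n_informative`, `ids` (individual
#'   names of the recombinants).
#' @export
count_recombinants <- function(mm, marker) {
  stopifnot(inherits(mm, "marker_matrix"))
  if (!marker %in% mm$markers$marker) stop("marker ", marker, " not in matrix")
  g <- mm$geno[match(marker, rownames(mm$geno)), ]
  informative <- g != "-"
  weeping <- mm$phenotype == "weeping"
  rec <- informative & ((weeping & g != "B") | (!weeping & g == "B"))
  ids <- names(mm$phenotype)[rec]
  if (is.null(ids)) ids <- which(rec)
  list(n_recombinant = sum(rec), n_informative = sum(informative), ids = ids)
}

#' Localize the causal interval from per-marker recombinant counts
#'
#' Markers with zero recombinants form the linked block; the interval runs
#' from the nearest marker with at least one recombinant on the left of
#' that block to the nearest such marker on the right (closed at the
#' flanking markers, matching how fine-mapped intervals are reported by
#' their recombinant-bearing bounds). A side with no flanking recombinant
#' marker is open and flagged.
#'
#' @param mm A `marker_matrix` (one chromosome's markers, sorted by
#'   position).
#' @return A list of class `recombinant_report`: `per_marker` (tibble
#'   `marker`, `chrom`, `pos`, `n_recombinant`, `n_informative`),
#'   `interval` (tibble `chrom`, `start`, `end`, 0-based half-open spanning
#'   the 1-based flank positions, or `NULL` when no zero-recombinant marker
#'   exists), and `open_left`/`open_right` flags.
#' @export
localize_interval <- function(mm) {
  stopifnot(inherits(mm, "marker_matrix"))
  counts <- purrr::map(mm$markers$marker, ~ count_recombinants(mm, .x))
  per_marker <- dplyr::mutate(mm$markers,
    n_recombinant = purrr::map_int(counts, "n_recombinant"),
    n_informative = purrr::map_int(counts, "n_informative")
  )
  zero <- which(per_marker$n_recombinant == 0)
  if (!length(zero)) {
    return(structure(list(per_marker = per_marker, interval = NULL,
                          open_left = NA, open_right = NA),
                     class = "recombinant_report"))
  }
  block <- range(zero)
  left <- if (block[1] > 1) block[1] - 1L else NA_integer_
  right <- if (block[2] < nrow(per_marker)) block[2] + 1L else NA_integer_
  open_left <- is.na(left)
  open_right <- is.na(right)
  lo_pos <- per_marker$pos[if (open_left) block[1] else left]
  hi_pos <- per_marker$pos[if (open_right) block[2] else right]
  interval <- interval_from_1based(per_marker$chrom[block[1]], lo_pos, hi_pos)
  structure(list(per_marker = per_marker, interval = interval,
                 open_left = open_left, open_right = open_right),
            class = "recombinant_report")
}

#' @export
print.recombinant_report <- function(x, ...) {
  cat("<recombinant_report>\n")
  print(x$per_marker)
  if (is.null(x$interval)) {
    cat("no zero-recombinant marker; interval undefined\n")
  } else {
    cat("localized interval: ", x$interval$chrom, ":", x$interval$start, "-",
        x$interval$end,
        if (x$open_left) " (open left)" else "",
        if (x$open_right) " (open right)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' @describeIn localize_interval Per-marker recombinant counts as a tibble.
#' @param x A `recombinant_report`.
#' @param ... Unused.
#' @method tidy recombinant_report
#' @export
tidy.recombinant_report <- function(x, ...) x$per_marker

#' Screen a region for diagnostic indel candidates
#'
#' Returns the indel records inside `region` whose bulks are near-fixed for
#' opposite alleles: weeping-bulk (mutant-oriented) index at least
#' `min_mut_index` and standard-bulk index inside the heterozygous-mixture
#' band expected for an AA:Aa = 1:2 pool (centred on 1/3, default
#' 0.15–0.55 to allow sampling noise). SNP records are never returned.
#'
#' @param sites Allele-depth tibble including indel records.
#' @param region Tibble row or list with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_mut_index Weeping-bulk fixation cutoff (default 0.95).
#' @param het_band Length-2 standard-bulk index band (default `c(0.15, 0.55)`).
#' @return A tibble of candidates: `chrom`, `pos`, `ref`, `alt`,
#'   `length_diff_bp`, `index_st`, `index_pl`.
#' @export
find_diagnostic_indels <- function(sites, region, min_mut_index = 0.95,
                                   het_band = c(0.15, 0.55)) {
  idx <- compute_snp_index(sites)
  keep <- idx$kind == "indel" &
    idx$chrom == region$chrom &
    idx$pos > region$start & idx$pos <= region$end &
    !is.na(idx$index_pl) & idx$index_pl >= min_mut_index &
    !is.na(idx$index_st) & idx$index_st >= het_band[1] & idx$index_st <= het_band[2]
  hit <- sites[keep, , drop = FALSE]
  tibble::tibble(
    chrom = hit$chrom, pos = hit$pos, ref = hit$ref, alt = hit$alt,
    length_diff_bp = abs(nchar(hit$ref) - nchar(hit$alt)),
    index_st = idx$index_st[keep], index_pl = idx$index_pl[keep]
  )
}

#' Co-segregation accuracy of a diagnostic marker
#'
#' Predicts weeping for individuals homozygous for the weeping-linked
#' allele (code `B`) and standard otherwise, then scores the prediction
#' against the recorded phenotypes. Individuals with missing genotype
#' (`-` or `NA`) are excluded from numerator and denominator.
#'
#' @param genotype Character vector of codes `A`/`H`/`B`/`-`.
#' @param phenotype Character vector, `"weeping"`/`"standard"`, same length.
#' @return A one-row tibble: `concordant`, `informative`, `accuracy`
#'   (percent, `100 * concordant / informative`).
#' @export
co_segregation_accuracy <- function(genotype, phenotype) {
  stopifnot(length(genotype) == length(phenotype))
  informative <- !is.na(genotype) & genotype != "-"
  if (!any(informative)) stop("no informative individuals")
  g <- genotype[informative]
  p <- phenotype[informative]
  predicted <- ifelse(g == "B", "weeping", "standard")
  concordant <- sum(predicted == p)
  tibble::tibble(
    concordant = concordant,
    informative = sum(informative),
    accuracy = 100 * concordant / sum(informative)
  )
}
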