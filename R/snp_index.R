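# Per-site SNP-index computation and the standard site filters.
#
# The SNP-index of a pool at a site is the fraction of its reads carrying
# the mutant allele; Delta(SNP-index) = index(weeping) - index(standard).
# Because the F1 parent is heterozygous its phase is unobservable from a
# single sample, so the mutant allele is oriented by the bulk contrast
# (the allele enriched in the weeping bulk); the parent serves only as the
# heterozygosity filter.

#' Site filter settings
#'
#' Defaults are the conventional BSA-seq criteria: per-pool depth of at
#' least 7, SNP-index at least 0.3, both pools present, parent observed
#' heterozygous (parent index within 0.3–0.7).
#'
#' @param min_depth Minimum total depth required in each pool (fold).
#' @param min_index Low-index cutoff (fraction, in (0, 0.5)).
#' @param parent_het_band Length-2 numeric: the parent-index band accepted
#'   as heterozygous.
#' @param index_filter_mode `"both"` (default): a site fails the low-index
#'   filter only when *both* pools are below `min_index` — the QTL-seq
#'   convention, which keeps truly linked sites whose standard-bulk index is
#'   expected at 1/3. `"either"`: the literal reading that discards a site
#'   when any pool is below the cutoff.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 7, min_index = 0.3,
                          parent_het_band = c(0.3, 0.7),
                          index_filter_mode = c("both", "either")) {
  if (!(min_index > 0 && min_index < 0.5) && min_index != 0) {
    stop("`min_index` must be in (0, 0.5) (or 0 to disable)")
  }
  if (length(parent_het_band) != 2 || parent_het_band[1] < 0 ||
      parent_het_band[2] > 1 || parent_het_band[1] >= parent_het_band[2]) {
    stop("`parent_het_band` must satisfy 0 <= low < high <= 1")
  }
  structure(list(min_depth = min_depth, min_index = min_index,
                 parent_het_band = parent_het_band,
                 index_filter_mode = match.arg(index_filter_mode)),
            class = "filter_config")
}

#' Orient each site's mutant allele by the bulk contrast
#'
#' The mutant (weeping-derived) allele at a site is defined as the allele
#' enriched in the weeping bulk relative to the standard bulk; ties resolve
#' to the alt allele. After orientation all indices count mutant reads over
#' total reads, so the result is invariant to how ref/alt were labelled in
#' the input. Sites where the contrast is undefined (a pool missing) keep
#' the alt allele as mutant; they are flagged downstream.
#'
#' @param sites Allele-depth tibble (see [read_allele_depths()]).
#' @return The tibble with an added `mutant_allele` column (`"alt"`/`"ref"`)
#'   and `*_mut`/`*_oth` oriented depth columns for parent, st, pl.
#' @export
orient_mutant_allele <- function(sites) {
  pl_tot <- sites$pl_ref + sites$pl_alt
  st_tot <- sites$st_ref + sites$st_alt
  idx_pl <- ifelse(pl_tot > 0, sites$pl_alt / pl_tot, NA_real_)
  idx_st <- ifelse(st_tot > 0, sites$st_alt / st_tot, NA_real_)
  contrast <- idx_pl - idx_st
  flip <- !is.na(contrast) & contrast < 0
  orient2 <- function(ref, alt) {
    list(mut = ifelse(flip, ref, alt), oth = ifelse(flip, alt, ref))
  }
  p <- orient2(sites$parent_ref, sites$parent_alt)
  s <- orient2(sites$st_ref, sites$st_alt)
  w <- orient2(sites$pl_ref, sites$pl_alt)
  dplyr::mutate(sites,
    mutant_allele = ifelse(flip, "ref", "alt"),
    parent_mut = p$mut, parent_oth = p$oth,
    st_mut = s$mut, st_oth = s$oth,
    pl_mut = w$mut, pl_oth = w$oth
  )
}

#' Compute per-site SNP-indices and Delta(SNP-index)
#'
#' @param sites An oriented site tibble from [orient_mutant_allele()] (a raw
#'   allele-depth tibble is oriented automatically).
#' @return A tibble of SNP-index records: `chrom`, `pos`, `kind`,
#'   `mutant_allele`, `index_st`, `index_pl`, `depth_st`, `depth_pl`,
#'   `parent_index`, `parent_depth`, `delta`. A pool with zero or missing
#'   depth has an `NA` index — absence of reads is treated as missing, not
#'   as index 0 — and `delta` is `NA` for such sites.
#' @export
compute_snp_index <- function(sites) {
  if (!"mutant_allele" %in% names(sites)) sites <- orient_mutant_allele(sites)
  depth_st <- sites$st_mut + sites$st_oth
  depth_pl <- sites$pl_mut + sites$pl_oth
  depth_parent <- sites$parent_mut + sites$parent_oth
  index_st <- ifelse(!is.na(depth_st) & depth_st > 0, sites$st_mut / depth_st, NA_real_)
  index_pl <- ifelse(!is.na(depth_pl) & depth_pl > 0, sites$pl_mut / depth_pl, NA_real_)
  parent_index <- ifelse(!is.na(depth_parent) & depth_parent > 0,
                         sites$parent_mut / depth_parent, NA_real_)
  tibble::tibble(
    chrom = sites$chrom, pos = sites$pos,
    kind = if ("kind" %in% names(sites)) sites$kind else "snp",
    mutant_allele = sites$mutant_allele,
    index_st = index_st, index_pl = index_pl,
    depth_st = ifelse(is.na(depth_st), 0L, depth_st),
    depth_pl = ifelse(is.na(depth_pl), 0L, depth_pl),
    parent_index = parent_index,
    delta = index_pl - index_st
  )
}

#' Apply the BSA-seq site filters
#'
#' A record passes iff both pools reach `min_depth`, both pools are present,
#' the parent looks heterozygous (when `parent_required`), and the site is
#' not low-index (under the configured mode). Each failing record carries a
#' single `filter_status` label under the precedence
#' `low_depth > one_pool_missing > parent_not_het > low_index`, so the
#' per-reason counts in the attached report sum to `total - passing`.
#'
#' @param records SNP-index tibble from [compute_snp_index()].
#' @param config A [filter_config()].
#' @param parent_required If `TRUE` (default) records whose parent is
#'   missing or outside the heterozygous band are excluded from the scan.
#' @return The records tibble with a `filter_status` column; the per-reason
#'   count report is attached as attribute `"filter_report"` (also
#'   retrievable with [filter_report()]).
#' @export
apply_site_filters <- function(records, config = filter_config(),
                               parent_required = TRUE) {
  pool_missing <- is.na(records$index_st) | is.na(records$index_pl)
  low_depth <- (records$depth_st > 0 & records$depth_st < config$min_depth) |
               (records$depth_pl > 0 & records$depth_pl < config$min_depth)
  parent_bad <- if (parent_required) {
    is.na(records$parent_index) |
      records$parent_index < config$parent_het_band[1] |
      records$parent_index > config$parent_het_band[2]
  } else {
    rep(FALSE, nrow(records))
  }
  below <- function(x) !is.na(x) & x < config$min_index
  low_index <- if (config$index_filter_mode == "both") {
    below(records$index_st) & below(records$index_pl)
  } else {
    below(records$index_st) | below(records$index_pl)
  }
  status <- dplyr::case_when(
    low_depth ~ "low_depth",
    pool_missing ~ "one_pool_missing",
    parent_bad ~ "parent_not_het",
    low_index ~ "low_index",
    TRUE ~ "pass"
  )
  out <- dplyr::mutate(records, filter_status = status)
  report <- dplyr::count(out, .data$filter_status, name = "n") |>
    tidyr::complete(filter_status = c("pass", "low_depth", "one_pool_missing",
                                      "parent_not_het", "low_index"),
                    fill = list(n = 0L)) |>
    dplyr::arrange(dplyr::desc(.data$filter_status == "pass"))
  attr(out, "filter_report") <- report
  out
}

#' @rdname apply_site_filters
#' @export
filter_report <- function(records) attr(records, "filter_report")

#' Keep only records that passed all site filters
#'
#' @param records Output of [apply_site_filters()].
#' @return The passing subset, sorted by (chrom, pos).
#' @export
passing_records <- function(records) {
  dplyr::filter(records, .data$filter_status == "pass") |>
    dplyr::arrange(.data$chrom, .data$pos)
}
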