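#' Define the marker coordinate frame for a simulated cross
#'
#' A genome model holds the chromosome lengths, the 1-based positions of the
#' segregating SNP markers the F1 parent is heterozygous for, and a uniform
#' recombination rate used to convert physical to genetic distance.
#'
#' The default is a deliberately desk-scale genome: two 25 Mb chromosomes
#' with a marker every 10 kb and 4 cM/Mb, large enough to exercise 1 Mb
#' windowing while keeping simulations fast. Genome-scale coordinates (e.g.
#' the eight peach chromosomes) are reachable by supplying `chrom_lengths`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param marker_spacing Distance in bp between consecutive markers laid on a
#'   regular grid (ignored for a chromosome listed in `marker_positions`).
#' @param cm_per_mb Recombination rate in centiMorgan per megabase (> 0).
#' @param marker_positions Optional named list of sorted 1-based marker
#'   positions overriding the regular grid for some or all chromosomes.
#'
#' @return An object of class `genome_model`: a list with `markers` (a tibble
#'   with columns `marker`, `chrom`, `pos`, `cm`), `chrom_lengths` and
#'   `cm_per_mb`.
#' @export
#' @examples
#' g <- genome_model(c(chrA = 1e6), marker_spacing = 1e5)
#' g$markers
genome_model <- function(chrom_lengths = c(chr1 = 25e6, chr2 = 25e6),
                         marker_spacing = 1e4,
                         cm_per_mb = 4,
                         marker_positions = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("`chrom_lengths` must be a named vector of chromosome lengths")
  }
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")
  if (!is.numeric(cm_per_mb) || cm_per_mb <= 0) stop("`cm_per_mb` must be > 0")

  markers <- purrr::map2_dfr(names(chrom_lengths), chrom_lengths, function(chrom, len) {
    pos <- marker_positions[[chrom]]
    if (is.null(pos)) pos <- seq(marker_spacing, len, by = marker_spacing)
    pos <- as.numeric(pos)
    if (length(pos) == 0) stop("chromosome ", chrom, " has no markers")
    if (any(diff(pos) <= 0)) stop("marker positions on ", chrom, " must be strictly increasing")
    if (pos[1] < 1 || pos[length(pos)] > len) {
      stop("marker positions on ", chrom, " fall outside [1, ", len, "]")
    }
    tibble::tibble(chrom = chrom, pos = pos)
  })
  markers <- dplyr::mutate(markers,
    marker = paste0(.data$chrom, "_", format(.data$pos, scientific = FALSE, trim = TRUE)),
    cm = .data$pos / 1e6 * cm_per_mb,
    .before = 1
  )

  structure(
    list(markers = markers, chrom_lengths = chrom_lengths, cm_per_mb = cm_per_mb),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_lengths), " chromosome(s), ",
      nrow(x$markers), " markers, ", x$cm_per_mb, " cM/Mb\n", sep = "")
  invisible(x)
}

#' Configure a simulated F2 cross and its pooled sequencing
#'
#' Defaults follow the study design the package targets: an F2 population of
#' 395 individuals segregating 3:1 for a single recessive (weeping) locus,
#' two phenotype-selected bulks of 15 individuals, and roughly 100-fold
#' pooled read depth per bulk.
#'
#' @param n_f2 F2 population size (>= 1).
#' @param bulk_size Individuals per phenotype bulk; `2 * bulk_size` must not
#'   exceed `n_f2`.
#' @param causal_chrom,causal_pos Location of the recessive causal locus;
#'   must coincide with a marker of the genome model used.
#' @param depth_mean Mean pooled sequencing depth per site (fold, > 0).
#' @param error_rate Per-read symmetric allele-flip probability in [0, 0.5).
#' @param pheno_error Probability that an individual's phenotype is
#'   misclassified (default 0: phenotyping is error-free).
#' @param seed Integer RNG seed recorded in outputs; every simulation
#'   operation derives its randomness from this.
#'
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_f2 = 395,
                         bulk_size = 15,
                         causal_chrom = "chr1",
                         causal_pos = 12.5e6,
                         depth_mean = 100,
                         error_rate = 0.001,
                         pheno_error = 0,
                         seed = 1L) {
  if (n_f2 < 1) stop("`n_f2` must be >= 1")
  if (2 * bulk_size > n_f2) stop("2 * bulk_size must not exceed n_f2")
  if (depth_mean <= 0) stop("`depth_mean` must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("`error_rate` must be in [0, 0.5)")
  if (pheno_error < 0 || pheno_error > 1) stop("`pheno_error` must be in [0, 1]")
  structure(
    list(n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
         causal_chrom = causal_chrom, causal_pos = as.numeric(causal_pos),
         depth_mean = depth_mean, error_rate = error_rate,
         pheno_error = pheno_error, seed = as.integer(seed)),
    class = "cross_config"
  )
}
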