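# Shared desk-scale fixtures, built in code.

toy_genome <- function(n_chr = 2, len = 1e6, spacing = 1e5, cm_per_mb = 4) {
  lens <- stats::setNames(rep(len, n_chr), paste0("chr", seq_len(n_chr)))
  genome_model(lens, marker_spacing = spacing, cm_per_mb = cm_per_mb)
}

toy_cross <- function(n_f2 = 200, bulk_size = 15, causal_chrom = "chr1",
                      causal_pos = 5e5, depth_mean = 100, error_rate = 0,
                      pheno_error = 0, seed = 1) {
  cross_config(n_f2 = n_f2, bulk_size = bulk_size,
               causal_chrom = causal_chrom, causal_pos = causal_pos,
               depth_mean = depth_mean, error_rate = error_rate,
               pheno_error = pheno_error, seed = seed)
}

# random allele-depth table for io / index tests
random_sites <- function(n, seed = 1, chrom = "chr1") {
  withr::with_seed(seed, {
    tibble::tibble(
      chrom = chrom,
      pos = sort(sample.int(1e6, n)),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      kind = "snp",
      parent_ref = rpois(n, 50), parent_alt = rpois(n, 50),
      st_ref = rpois(n, 50), st_alt = rpois(n, 50),
      pl_ref = rpois(n, 50), pl_alt = rpois(n, 50)
    )
  })
}

# marker matrix built directly from code vectors (markers x individuals)
toy_marker_matrix <- function(geno_rows, phenotype, pos = NULL, chrom = "chr1") {
  geno <- do.call(rbind, geno_rows)
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 1e5
  markers <- paste0("M", seq_len(nrow(geno)), "-", pos)
  rownames(geno) <- markers
  ids <- sprintf("I%02d", seq_along(phenotype))
  colnames(geno) <- ids
  tmp <- tempfile(fileext = ".tsv")
  lines <- c(
    paste(c("marker", "chrom", "pos", ids), collapse = "\t"),
    paste(c("phenotype", "NA", "NA", phenotype), collapse = "\t"),
    vapply(seq_len(nrow(geno)), function(i) {
      paste(c(markers[i], chrom, pos[i], geno[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, tmp)
  read_marker_genotypes(tmp)
}

# a threshold curve with known bounds, for region-calling unit tests
fixed_curve <- function(upper, lower = -upper, depth = 100) {
  structure(tibble::tibble(depth = depth, lower = lower, upper = upper),
            class = c("threshold_curve", class(tibble::tibble())),
            bulk_size = 15L, confidence = 0.95, n_sim = NA_integer_, seed = NA_integer_)
}
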