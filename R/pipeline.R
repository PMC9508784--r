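# End-to-end orchestration: simulate -> index -> scan -> finemap, with a
# manifest, per-stage logging and a machine-readable summary.

#' Configure a full BSA-seq pipeline run
#'
#' Defaults reproduce the study-design settings the stage functions
#' document: depth filter 7, index filter 0.3, 1 Mb windows at 1 kb steps,
#' 1000 null simulations at 95% confidence, an F2 of 395 with bulks of 15
#' at 100-fold depth.
#'
#' @param genome A [genome_model()].
#' @param cross A [cross_config()]; its `seed` drives every stage.
#' @param filter A [filter_config()].
#' @param window_bp,step_bp Scan window and step (bp).
#' @param n_sim,confidence Null-threshold simulation settings.
#' @param max_gap Omitted-window gap tolerated inside a region run.
#' @param n_fine_markers Markers genotyped for the fine-mapping stage.
#' @param embed_indel Embed the fully linked diagnostic indel (default TRUE).
#' @param stages Character subset of
#'   `c("simulate", "index", "scan", "finemap")`; later stages require the
#'   earlier ones.
#' @return A list of class `bsa_config`.
#' @export
bsa_config <- function(genome = genome_model(),
                       cross = cross_config(),
                       filter = filter_config(),
                       window_bp = 1e6, step_bp = 1e3,
                       n_sim = 1000, confidence = 0.95, max_gap = 1,
                       n_fine_markers = 15,
                       embed_indel = TRUE,
                       stages = c("simulate", "index", "scan", "finemap")) {
  stages <- match.arg(stages, several.ok = TRUE)
  need <- c("simulate", "index", "scan", "finemap")
  ranks <- match(stages, need)
  if (any(diff(sort(ranks)) > 1) || !1 %in% ranks) {
    stop("stages must be a prefix of simulate < index < scan < finemap")
  }
  structure(list(genome = genome, cross = cross, filter = filter,
                 window_bp = window_bp, step_bp = step_bp, n_sim = n_sim,
                 confidence = confidence, max_gap = max_gap,
                 n_fine_markers = n_fine_markers, embed_indel = embed_indel,
                 stages = stages),
            class = "bsa_config")
}

config_manifest <- function(config) {
  list(
    package = "bsascan",
    version = as.character(utils::packageVersion("bsascan")),
    seed = config$cross$seed,
    genome = list(chrom_lengths = as.list(config$genome$chrom_lengths),
                  n_markers = nrow(config$genome$markers),
                  cm_per_mb = config$genome$cm_per_mb),
    cross = unclass(config$cross),
    filter = unclass(config$filter),
    scan = list(window_bp = config$window_bp, step_bp = config$step_bp,
                n_sim = config$n_sim, confidence = config$confidence,
                max_gap = config$max_gap),
    finemap = list(n_fine_markers = config$n_fine_markers,
                   embed_indel = config$embed_indel),
    stages = config$stages
  )
}

#' Run the BSA-seq pipeline end to end
#'
#' Executes the enabled stages in order on a simulated cross: population
#' and bulk simulation, pooled allele depths (with the embedded diagnostic
#' indel), SNP-index computation and filtering, the windowed delta scan
#' against simulated null thresholds, and recombinant fine mapping plus
#' diagnostic-marker validation. Deterministic given the cross seed; when
#' `out_dir` is given, the manifest and every stage table are written there.
#'
#' @param config A [bsa_config()].
#' @param out_dir Optional output directory (created if needed): writes
#'   `manifest.yaml`, `sites.tsv`, `index.tsv`, `windows.tsv`,
#'   `regions.bed` and `summary.json` for the stages that ran.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `bsa_run`: a list with (depending on stages)
#'   `population`, `bulks`, `sites`, `records`, `scan`, `segregation`,
#'   `finemap`, `marker_accuracy`, `config`, `manifest`.
#' @export
run_bsa_pipeline <- function(config = bsa_config(), out_dir = NULL,
                             quiet = FALSE) {
  stopifnot(inherits(config, "bsa_config"))
  say <- function(...) if (!quiet) message("[bsascan] ", ...)
  run <- list(config = config, manifest = config_manifest(config))
  cross <- config$cross

  # -- simulate ---------------------------------------------------------
  say("simulate: F2 n=", cross$n_f2, ", bulks of ", cross$bulk_size,
      ", depth ", cross$depth_mean, "x")
  run$population <- simulate_f2_population(config$genome, cross)
  run$bulks <- make_bulks(run$population)
  sites <- simulate_bulk_depths(run$population, run$bulks)
  if (config$embed_indel) {
    sites <- embed_diagnostic_indel(sites, run$population, run$bulks)
  }
  run$sites <- sites
  say("simulate: ", nrow(sites), " sites (",
      sum(run$population$phenotype == "weeping"), " weeping individuals)")

  # -- index ------------------------------------------------------------
  if ("index" %in% config$stages) {
    records <- compute_snp_index(orient_mutant_allele(sites)) |>
      apply_site_filters(config$filter)
    run$records <- records
    say("index: ", nrow(records), " records, ",
        sum(records$filter_status == "pass"), " pass filters")
  }

  # -- scan -------------------------------------------------------------
  if ("scan" %in% config$stages) {
    passing <- passing_records(run$records)
    windows <- sliding_windows(passing, config$window_bp, config$step_bp,
                               chrom_lengths = config$genome$chrom_lengths)
    depth_grid <- unique(round(quantile(windows$mean_depth,
                                        probs = seq(0.05, 0.95, by = 0.1),
                                        names = FALSE)))
    curve <- simulate_null_thresholds(cross$bulk_size, depth_grid,
                                      n_sim = config$n_sim,
                                      confidence = config$confidence,
                                      seed = cross$seed + 10L)
    run$scan <- call_candidate_regions(windows, curve,
                                       step_bp = config$step_bp,
                                       max_gap = config$max_gap)
    say("scan: ", nrow(run$scan$windows), " windows, ",
        nrow(run$scan$regions), " region(s)")
  }

  # -- finemap ----------------------------------------------------------
  if ("finemap" %in% config$stages) {
    ph <- run$population$phenotype
    run$segregation <- chi_square_ratio(c(sum(ph == "weeping"),
                                          sum(ph == "standard")), c(1, 3))
    run$finemap <- localize_interval(finemap_marker_matrix(run, config))
    if (!is.null(run$scan) && nrow(run$scan$regions)) {
      run$indel_candidates <- find_diagnostic_indels(sites, run$scan$regions[1, ])
    }
    if (config$embed_indel) {
      run$marker_accuracy <- co_segregation_accuracy(
        indel_genotypes(run$population), run$population$phenotype)
    }
    say("finemap: chi2=", round(run$segregation$chi2, 2),
        if (!is.null(run$marker_accuracy)) {
          paste0(", diagnostic marker accuracy ", run$marker_accuracy$accuracy, "%")
        })
  }

  run <- structure(run, class = "bsa_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Markers genotyped for fine mapping, mimicking the two-round marker
# screen: a coarse set evenly spread across the scan's top region (plus
# 1 Mb flanks; the whole causal chromosome when no scan ran), then every
# available marker within one coarse spacing of the coarse marker with the
# fewest recombinants, so a zero-recombinant block and its recombinant-
# bearing flanks can be resolved at marker resolution.
finemap_marker_matrix <- function(run, config, max_dense = 400) {
  map <- run$population$map
  chrom <- config$cross$causal_chrom
  lo <- 1
  hi <- config$genome$chrom_lengths[[chrom]]
  if (!is.null(run$scan) && nrow(run$scan$regions)) {
    top <- run$scan$regions[1, ]
    if (top$chrom %in% map$chrom) {
      chrom <- top$chrom
      lo <- max(1, top$start - 1e6)
      hi <- min(config$genome$chrom_lengths[[chrom]], top$end + 1e6)
    }
  }
  cand <- map[map$chrom == chrom, ]
  targets <- seq(lo, hi, length.out = config$n_fine_markers)
  pick <- unique(vapply(targets, function(t) which.min(abs(cand$pos - t)), integer(1)))
  coarse <- genotype_markers(run$population, cand$marker[pick])
  counts <- vapply(coarse$markers$marker,
                   function(m) count_recombinants(coarse, m)$n_recombinant,
                   integer(1))
  best_pos <- coarse$markers$pos[which.min(counts)]
  spacing <- if (length(targets) > 1) diff(targets[1:2]) else hi - lo
  dense <- cand[abs(cand$pos - best_pos) <= spacing, ]
  if (nrow(dense) > max_dense) {
    dense <- dense[unique(round(seq(1, nrow(dense), length.out = max_dense))), ]
  }
  genotype_markers(run$population,
                   union(cand$marker[pick], dense$marker))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  write_allele_depths(run$sites, file.path(out_dir, "sites.tsv"))
  if (!is.null(run$records)) {
    readr::write_tsv(run$records, file.path(out_dir, "index.tsv"))
  }
  if (!is.null(run$scan)) {
    readr::write_tsv(run$scan$windows, file.path(out_dir, "windows.tsv"))
    write_bed(run$scan$regions[, c("chrom", "start", "end")],
              file.path(out_dir, "regions.bed"))
  }
  jsonlite::write_json(summary_list(run), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}

summary_list <- function(run) {
  out <- list(
    seed = run$config$cross$seed,
    n_sites = nrow(run$sites),
    n_weeping = sum(run$population$phenotype == "weeping"),
    n_standard = sum(run$population$phenotype == "standard")
  )
  if (!is.null(run$records)) {
    out$n_passing <- sum(run$records$filter_status == "pass")
  }
  if (!is.null(run$scan)) {
    out$n_windows <- nrow(run$scan$windows)
    out$n_regions <- nrow(run$scan$regions)
    if (nrow(run$scan$regions)) {
      top <- run$scan$regions[1, ]
      out$top_region <- list(chrom = top$chrom, start = top$start,
                             end = top$end, peak_delta = top$peak_delta,
                             length_kb = top$length_kb)
    }
  }
  if (!is.null(run$segregation)) {
    out$segregation <- list(chi2 = run$segregation$chi2,
                            p_value = run$segregation$p_value)
  }
  if (!is.null(run$marker_accuracy)) {
    out$marker_accuracy_pct <- run$marker_accuracy$accuracy
  }
  out
}

#' @export
print.bsa_run <- function(x, ...) {
  cat("<bsa_run> stages: ", paste(x$config$stages, collapse = " -> "), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @describeIn run_bsa_pipeline One-row run summary (counts per stage, top
#'   region, segregation test, diagnostic-marker accuracy).
#' @param x A `bsa_run`.
#' @param ... Unused.
#' @method glance bsa_run
#' @export
glance.bsa_run <- function(x, ...) {
  top <- if (!is.null(x$scan) && nrow(x$scan$regions)) x$scan$regions[1, ] else NULL
  tibble::tibble(
    n_sites = nrow(x$sites),
    n_passing = if (!is.null(x$records)) sum(x$records$filter_status == "pass") else NA_integer_,
    n_windows = if (!is.null(x$scan)) nrow(x$scan$windows) else NA_integer_,
    n_regions = if (!is.null(x$scan)) nrow(x$scan$regions) else NA_integer_,
    top_chrom = if (!is.null(top)) top$chrom else NA_character_,
    top_start = if (!is.null(top)) top$start else NA_real_,
    top_end = if (!is.null(top)) top$end else NA_real_,
    top_length_kb = if (!is.null(top)) top$length_kb else NA_real_,
    chi2 = if (!is.null(x$segregation)) x$segregation$chi2 else NA_real_,
    segregation_p = if (!is.null(x$segregation)) x$segregation$p_value else NA_real_,
    marker_accuracy = if (!is.null(x$marker_accuracy)) x$marker_accuracy$accuracy else NA_real_
  )
}

#' @describeIn run_bsa_pipeline Candidate regions of the run as a tibble.
#' @method tidy bsa_run
#' @export
tidy.bsa_run <- function(x, ...) {
  if (is.null(x$scan)) stop("run has no scan stage")
  x$scan$regions
}
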