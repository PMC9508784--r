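# Sliding-window Delta(SNP-index) scan: window means, simulation-based
# null confidence thresholds per read depth, and candidate-region calling.

#' Slide windows of Delta(SNP-index) along each chromosome
#'
#' Windows of `window_bp` tile each chromosome at `step_bp` (the large
#' window / small step convention: default 1 Mb windows advanced 1 kb).
#' `mean_delta` is the unweighted mean of per-site delta over sites with
#' 1-based position in `(start, start + window_bp]`; `mean_depth` is the
#' mean per-site `min(depth_st, depth_pl)`. Windows containing no site are
#' omitted rather than imputed.
#'
#' @param records Passing SNP-index records (see [passing_records()]),
#'   sorted by (chrom, pos).
#' @param window_bp,step_bp Window and step sizes in bp; `window_bp` must be
#'   >= `step_bp`.
#' @param chrom_lengths Optional named lengths used to bound the tiling;
#'   defaults to the last site position per chromosome.
#' @return A tibble of windows: `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites`, `mean_delta`, `mean_depth`.
#' @export
sliding_windows <- function(records, window_bp = 1e6, step_bp = 1e3,
                            chrom_lengths = NULL) {
  if (window_bp < step_bp) stop("`window_bp` must be >= `step_bp`")
  records <- dplyr::arrange(records, .data$chrom, .data$pos)
  records <- dplyr::filter(records, !is.na(.data$delta))
  purrr::map_dfr(split(records, records$chrom), function(d) {
    chrom <- d$chrom[1]
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(d$pos)
    }
    starts <- seq(0, max(0, ceiling(len / step_bp) - 1) * step_bp, by = step_bp)
    pos <- d$pos
    cs_delta <- c(0, cumsum(d$delta))
    cs_depth <- c(0, cumsum(pmin(d$depth_st, d$depth_pl)))
    lo <- findInterval(starts, pos)            # sites with pos <= start
    hi <- findInterval(starts + window_bp, pos) # sites with pos <= start + window
    n <- hi - lo
    keep <- n > 0
    tibble::tibble(
      chrom = chrom,
      start = starts[keep],
      end = starts[keep] + window_bp,
      n_sites = n[keep],
      mean_delta = (cs_delta[hi + 1] - cs_delta[lo + 1])[keep] / n[keep],
      mean_depth = (cs_depth[hi + 1] - cs_depth[lo + 1])[keep] / n[keep]
    )
  })
}

#' Simulate null Delta(SNP-index) confidence thresholds by depth
#'
#' For each depth in `depth_grid`, repeats `n_sim` times: draw each pool's
#' mutant-allele frequency from the null F2 composition of `bulk_size`
#' individuals (genotypes 1:2:1 in both pools, since without linkage
#' phenotype selection does not constrain a site — equivalently the pool's
#' mutant-allele count is Binomial(2 x bulk_size, 1/2)), then draw
#' Binomial(depth, frequency) reads per pool and record the resulting
#' delta. The curve stores the empirical `(1 - confidence)/2` and
#' `1 - (1 - confidence)/2` quantiles; region calling uses the upper tail.
#'
#' @param bulk_size Individuals per bulk.
#' @param depth_grid Integer vector of read depths (fold) to tabulate.
#' @param n_sim Replicates per depth (>= 100).
#' @param confidence Confidence level (default 0.95).
#' @param seed RNG seed; the simulation is deterministic given it.
#' @return A tibble of class `threshold_curve` with columns `depth`,
#'   `lower`, `upper`; `bulk_size`, `confidence`, `n_sim` and `seed` are
#'   attached as attributes.
#' @export
simulate_null_thresholds <- function(bulk_size, depth_grid, n_sim = 1000,
                                     confidence = 0.95, seed = 1L) {
  if (!length(depth_grid)) stop("`depth_grid` must not be empty")
  if (n_sim < 100) stop("`n_sim` must be >= 100")
  if (confidence < 0 || confidence >= 1) stop("`confidence` must be in [0, 1)")
  depth_grid <- sort(unique(as.integer(round(depth_grid))))
  if (any(depth_grid < 1)) stop("depths must be >= 1")
  alpha <- (1 - confidence) / 2
  out <- withr::with_seed(seed, {
    purrr::map_dfr(depth_grid, function(d) {
      f_pl <- rbinom(n_sim, 2L * bulk_size, 0.5) / (2 * bulk_size)
      f_st <- rbinom(n_sim, 2L * bulk_size, 0.5) / (2 * bulk_size)
      delta <- rbinom(n_sim, d, f_pl) / d - rbinom(n_sim, d, f_st) / d
      q <- quantile(delta, c(alpha, 1 - alpha), names = FALSE)
      tibble::tibble(depth = d, lower = q[1], upper = q[2])
    })
  })
  structure(out, class = c("threshold_curve", class(out)),
            bulk_size = as.integer(bulk_size), confidence = confidence,
            n_sim = as.integer(n_sim), seed = as.integer(seed))
}

# nearest-grid-point threshold lookup
lookup_threshold <- function(curve, depth) {
  idx <- vapply(depth, function(d) which.min(abs(curve$depth - d)), integer(1))
  curve$upper[idx]
}

#' Call candidate regions from significant windows
#'
#' Each window receives the upper null threshold of the nearest depth in
#' the curve and is significant when `mean_delta` exceeds it (one-sided:
#' the two-bulk design makes delta positive at linked sites). Maximal runs
#' of consecutive significant windows merge into regions; runs may bridge
#' up to `max_gap` *omitted* (zero-site) steps but never an emitted
#' non-significant window. Regions are sorted by `peak_delta` descending.
#'
#' @param windows Window tibble from [sliding_windows()].
#' @param curve A `threshold_curve` from [simulate_null_thresholds()].
#' @param step_bp Step used to build the windows.
#' @param max_gap Number of omitted steps a run may bridge (default 1).
#' @return A list with `windows` (the input plus `threshold` and
#'   `significant` columns) and `regions` (tibble `chrom`, `start`, `end`,
#'   `peak_delta`, `n_windows`, `length_kb`), of class `delta_scan`.
#' @export
call_candidate_regions <- function(windows, curve, step_bp = 1e3, max_gap = 1) {
  windows <- dplyr::mutate(windows,
    threshold = lookup_threshold(curve, .data$mean_depth),
    significant = .data$mean_delta > .data$threshold
  )
  regions <- purrr::map_dfr(split(windows, windows$chrom), function(w) {
    w <- dplyr::arrange(w, .data$start)
    sig <- which(w$significant)
    if (!length(sig)) return(NULL)
    emitted <- w$start
    # break a run when starts are farther apart than max_gap omitted steps
    # or when any emitted (necessarily non-significant) window lies between
    new_run <- c(TRUE, vapply(seq_along(sig)[-1], function(k) {
      gap_steps <- (w$start[sig[k]] - w$start[sig[k - 1]]) / step_bp - 1
      emitted_between <- sum(emitted > w$start[sig[k - 1]] & emitted < w$start[sig[k]])
      emitted_between > 0 || gap_steps - emitted_between > max_gap
    }, logical(1)))
    run_id <- cumsum(new_run)
    purrr::map_dfr(split(sig, run_id), function(run) {
      tibble::tibble(
        chrom = w$chrom[1],
        start = w$start[run[1]],
        end = w$end[run[length(run)]],
        peak_delta = max(w$mean_delta[run]),
        n_windows = length(run)
      )
    })
  })
  if (nrow(regions)) {
    regions <- merge_overlapping_regions(regions)
    regions <- dplyr::mutate(regions, length_kb = interval_length_kb(regions)) |>
      dplyr::arrange(dplyr::desc(.data$peak_delta))
  } else {
    regions <- tibble::tibble(chrom = character(), start = double(),
                              end = double(), peak_delta = double(),
                              n_windows = integer(), length_kb = double())
  }
  structure(list(windows = windows, regions = regions, curve = curve),
            class = "delta_scan")
}

# Two runs of significant windows separated by a sub-window significance
# gap have overlapping extents (extent = run span + window size); such
# intervals describe one candidate and are coalesced. n_windows counts the
# significant member windows of the merged runs.
merge_overlapping_regions <- function(regions) {
  purrr::map_dfr(split(regions, regions$chrom), function(r) {
    r <- dplyr::arrange(r, .data$start)
    r$grp <- cumsum(c(TRUE, r$start[-1] > cummax(r$end)[-nrow(r)]))
    dplyr::summarise(dplyr::group_by(r, .data$grp),
                     chrom = .data$chrom[1],
                     start = min(.data$start), end = max(.data$end),
                     peak_delta = max(.data$peak_delta),
                     n_windows = sum(.data$n_windows), .groups = "drop") |>
      dplyr::select(-"grp")
  })
}

#' @export
print.delta_scan <- function(x, ...) {
  cat("<delta_scan> ", nrow(x$windows), " windows, ",
      sum(x$windows$significant), " significant, ",
      nrow(x$regions), " candidate region(s)\n", sep = "")
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' @describeIn call_candidate_regions Candidate regions as a tibble.
#' @param x A `delta_scan`.
#' @param ... Unused.
#' @method tidy delta_scan
#' @export
tidy.delta_scan <- function(x, ...) x$regions

#' @describeIn call_candidate_regions One-row scan summary.
#' @method glance delta_scan
#' @export
glance.delta_scan <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows),
    n_significant = sum(x$windows$significant),
    n_regions = nrow(x$regions),
    top_peak_delta = if (nrow(x$regions)) x$regions$peak_delta[1] else NA_real_,
    confidence = attr(x$curve, "confidence")
  )
}

#' Interval length in kilobases
#'
#' `(end - start) / 1000`, rounded to the nearest integer kb, on 0-based
#' half-open intervals. The flanking-marker interval 20,839,173–20,998,220
#' (1-based) thus measures 159 kb.
#'
#' @param region Tibble with `start` and `end` columns (0-based half-open).
#' @return Numeric vector of lengths in kb.
#' @export
interval_length_kb <- function(region) {
  round((region$end - region$start) / 1000)
}
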