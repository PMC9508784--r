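# Readers and writers for the formats the pipeline touches: VCF 4.2 with
# per-sample AD, the plain allele-depth TSV dialect, BED3 intervals and
# marker-genotype tables.
#
# Coordinate conventions: sites are 1-based inclusive (VCF); intervals are
# 0-based half-open (BED). Conversions live in interval_from_1based() /
# interval_to_1based().

DEPTH_COLS <- c("parent_ref", "parent_alt", "st_ref", "st_alt", "pl_ref", "pl_alt")
VCF_SAMPLES <- c(parent = "PARENT", st = "ST_POOL", pl = "PL_POOL")

#' Read per-site bulk allele depths
#'
#' Accepts either a VCF 4.2 with per-sample `AD` FORMAT fields for samples
#' `PARENT`, `ST_POOL` and `PL_POOL` (any subset may be present), or the
#' package's plain TSV dialect (`chrom, pos, ref, alt, kind, parent_ref,
#' parent_alt, st_ref, st_alt, pl_ref, pl_alt`; `#`-prefixed header lines
#' allowed). Missing sample calls come back as `NA` pairs, never as zero
#' depths. Multi-allelic VCF rows are skipped with a message; unsorted
#' input is sorted with a warning.
#'
#' @param path File to read.
#' @param format `"auto"` (default: by extension/peek), `"vcf"` or `"tsv"`.
#' @return A tibble of sites sorted by (chrom, pos) with the dialect's
#'   columns; `kind` is `"indel"` iff ref and alt lengths differ.
#' @export
read_allele_depths <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_allele_depths_vcf(path) else read_allele_depths_tsv(path)
  ord <- order(out$chrom, out$pos)
  if (!identical(ord, seq_len(nrow(out)))) {
    warning("input sites were not sorted by (chrom, pos); sorting")
    out <- out[ord, ]
  }
  out
}

read_allele_depths_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_double(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           kind = readr::col_character(),
                           .default = readr::col_integer()
                         ))
  need <- c("chrom", "pos", "ref", "alt", DEPTH_COLS)
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop("allele-depth TSV ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(is.na(out$pos) | out$pos < 1)
  if (length(bad)) stop("malformed record at data line ", bad[1], " of ", path)
  out$kind <- ifelse(nchar(out$ref) != nchar(out$alt), "indel", "snp")
  out <- tibble::as_tibble(out[, c("chrom", "pos", "ref", "alt", "kind", DEPTH_COLS)])
  head_lines <- readLines(path, n = 10)
  seed_line <- grep("^# seed=", head_lines, value = TRUE)
  if (length(seed_line)) {
    attr(out, "seed") <- as.integer(sub("^# seed=", "", seed_line[1]))
  }
  out
}

parse_ad <- function(x) {
  # "ref,alt" -> c(ref, alt); "." / NA -> c(NA, NA)
  if (is.na(x) || x == "." || x == "") return(c(NA_integer_, NA_integer_))
  parts <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  if (length(parts) < 2 || anyNA(parts[1:2])) return(c(NA_integer_, NA_integer_))
  parts[1:2]
}

read_allele_depths_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble::tibble(chrom = character(), pos = double(),
                          ref = character(), alt = character(), kind = character(),
                          parent_ref = integer(), parent_alt = integer(),
                          st_ref = integer(), st_alt = integer(),
                          pl_ref = integer(), pl_alt = integer()))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("skipping ", sum(multi), " multi-allelic record(s)")
  }
  keep <- !multi
  ad <- vcfR::extract.gt(v, element = "AD")
  grab <- function(role) {
    sample <- VCF_SAMPLES[[role]]
    if (!sample %in% colnames(ad)) {
      return(matrix(NA_integer_, sum(keep), 2))
    }
    t(vapply(ad[keep, sample], parse_ad, integer(2), USE.NAMES = FALSE))
  }
  p <- grab("parent"); s <- grab("st"); w <- grab("pl")
  ref <- fix$REF[keep]; alt <- fix$ALT[keep]
  seed_line <- grep("^##bsascan_seed=", v@meta, value = TRUE)
  out <- tibble::tibble(
    chrom = fix$CHROM[keep], pos = as.numeric(fix$POS[keep]),
    ref = ref, alt = alt,
    kind = ifelse(nchar(ref) != nchar(alt), "indel", "snp"),
    parent_ref = p[, 1], parent_alt = p[, 2],
    st_ref = s[, 1], st_alt = s[, 2],
    pl_ref = w[, 1], pl_alt = w[, 2]
  )
  if (length(seed_line)) {
    attr(out, "seed") <- as.integer(sub("^##bsascan_seed=", "", seed_line[1]))
  }
  out
}

#' Write bulk allele depths
#'
#' `format = "tsv"` writes the plain dialect (with `#`-prefixed provenance
#' header lines carrying the recorded simulation seed, if any);
#' `format = "vcf"` writes a minimal VCF 4.2 whose only FORMAT field is `AD`,
#' with samples `PARENT`, `ST_POOL`, `PL_POOL` (missing calls are `.`).
#'
#' @param sites Allele-depth tibble (dialect columns).
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(sites, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  sites <- dplyr::arrange(sites, .data$chrom, .data$pos)
  if (format == "tsv") {
    hdr <- "# bsascan allele-depth table"
    if (!is.null(attr(sites, "seed"))) {
      hdr <- c(hdr, paste0("# seed=", attr(sites, "seed")))
    }
    writeLines(hdr, path)
    readr::write_tsv(sites[, c("chrom", "pos", "ref", "alt", "kind", DEPTH_COLS)],
                     path, append = TRUE, col_names = TRUE)
  } else {
    fmt_ad <- function(r, a) ifelse(is.na(r) | is.na(a), ".", paste0(r, ",", a))
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=bsascan",
      if (!is.null(attr(sites, "seed"))) paste0("##bsascan_seed=", attr(sites, "seed")),
      paste0("##contig=<ID=", unique(sites$chrom), ">"),
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", unname(VCF_SAMPLES)), collapse = "\t")
    )
    body <- paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                  ".", sites$ref, sites$alt, ".", "PASS", ".", "AD",
                  fmt_ad(sites$parent_ref, sites$parent_alt),
                  fmt_ad(sites$st_ref, sites$st_alt),
                  fmt_ad(sites$pl_ref, sites$pl_alt),
                  sep = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' @param chrom Chromosome name(s).
#' @param start1,end1 1-based inclusive endpoints.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
interval_from_1based <- function(chrom, start1, end1) {
  stopifnot(all(start1 >= 1), all(end1 >= start1))
  tibble::tibble(chrom = chrom, start = as.numeric(start1) - 1, end = as.numeric(end1))
}

#' @rdname interval_from_1based
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return For `interval_to_1based()`: a tibble with 1-based inclusive
#'   `start1`, `end1`.
#' @export
interval_to_1based <- function(intervals) {
  tibble::tibble(chrom = intervals$chrom,
                 start1 = intervals$start + 1, end1 = intervals$end)
}

#' Write and read BED3 interval files
#'
#' Standard 3-column BED: 0-based half-open coordinates, no header.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open,
#'   `0 <= start < end`).
#' @param path File path.
#' @return `write_bed()`: `path`, invisibly. `read_bed()`: the interval
#'   tibble.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals)) {
    stopifnot(all(intervals$start >= 0), all(intervals$start < intervals$end))
  }
  lines <- if (nrow(intervals)) {
    paste(intervals$chrom,
          format(intervals$start, scientific = FALSE, trim = TRUE),
          format(intervals$end, scientific = FALSE, trim = TRUE), sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = double(), end = double()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[`, character(1), 3))
  )
}

# --- marker-genotype matrices -----------------------------------------------

MARKER_CODES <- c("A", "H", "B", "-")

new_marker_matrix <- function(markers, geno, phenotype) {
  stopifnot(nrow(geno) == nrow(markers), ncol(geno) == length(phenotype))
  structure(list(markers = markers, geno = geno, phenotype = phenotype),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("<marker_matrix> ", nrow(x$markers), " markers x ", length(x$phenotype),
      " individuals\n", sep = "")
  invisible(x)
}

#' Parse a physical position from a mapping-marker name
#'
#' Marker names conventionally end in the 1-based bp position, e.g.
#' `CZ2-40F-20839173` sits at 20,839,173 bp.
#'
#' @param name Character vector of marker names of the form `NAME-<pos>`.
#' @return Numeric positions; `NA` where no trailing number is found.
#' @export
marker_position_from_name <- function(name) {
  hit <- grepl("[0-9]+$", name)
  out <- rep(NA_real_, length(name))
  out[hit] <- as.numeric(sub(".*?([0-9]+)$", "\\1", name[hit]))
  out
}

#' Read a marker-genotype table for fine mapping
#'
#' Expects a TSV whose first column (`marker`) names the markers, optionally
#' followed by `chrom` and/or `pos` columns, then one column per individual.
#' One row with marker name `phenotype` carries each individual's phenotype
#' (`weeping`/`standard`). Genotype codes are the mapping-population
#' alphabet: `A` = homozygous wild, `H` = heterozygous, `B` = homozygous
#' mutant, `-` = missing. When no `pos` column exists, positions are parsed
#' from the `NAME-<pos>` suffix of the marker names.
#'
#' @param path TSV file.
#' @return A `marker_matrix`: list with `markers` (tibble `marker`, `chrom`,
#'   `pos`, sorted by position), `geno` (character matrix markers x
#'   individuals) and `phenotype` (named character vector).
#' @export
read_marker_genotypes <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"marker" %in% names(raw)) stop("marker-genotype TSV must have a `marker` column")
  meta_cols <- intersect(c("marker", "chrom", "pos"), names(raw))
  ind_cols <- setdiff(names(raw), meta_cols)
  if (!length(ind_cols)) stop("no individual columns found in ", path)

  ph_row <- which(raw$marker == "phenotype")
  if (length(ph_row) != 1) stop("expected exactly one `phenotype` row in ", path)
  phenotype <- unlist(raw[ph_row, ind_cols])
  bad_ph <- which(!phenotype %in% c("weeping", "standard"))
  if (length(bad_ph)) {
    stop("unknown phenotype ", phenotype[bad_ph[1]], " for individual ",
         ind_cols[bad_ph[1]])
  }
  dat <- raw[-ph_row, , drop = FALSE]

  pos <- if ("pos" %in% names(dat)) as.numeric(dat$pos) else marker_position_from_name(dat$marker)
  if (anyNA(pos)) {
    stop("no position for marker(s): ",
         paste(dat$marker[is.na(pos)], collapse = ", "),
         " (provide a `pos` column or NAME-<pos> names)")
  }
  chrom <- if ("chrom" %in% names(dat)) dat$chrom else rep("chrU", nrow(dat))
  if (anyDuplicated(paste(chrom, pos))) {
    dup <- which(duplicated(paste(chrom, pos)))[1]
    stop("duplicate marker position ", chrom[dup], ":", pos[dup])
  }
  geno <- as.matrix(dat[, ind_cols, drop = FALSE])
  rownames(geno) <- dat$marker
  bad <- which(matrix(!geno %in% MARKER_CODES, nrow = nrow(geno)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("unknown genotype code '", geno[bad[1, 1], bad[1, 2]], "' at marker ",
         rownames(geno)[bad[1, 1]], ", individual ", ind_cols[bad[1, 2]])
  }
  ord <- order(chrom, pos)
  new_marker_matrix(
    markers = tibble::tibble(marker = dat$marker, chrom = chrom, pos = pos)[ord, ],
    geno = geno[ord, , drop = FALSE],
    phenotype = phenotype
  )
}

#' Write a marker-genotype table
#'
#' Inverse of [read_marker_genotypes()].
#'
#' @param mm A `marker_matrix`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_marker_genotypes <- function(mm, path) {
  ids <- names(mm$phenotype)
  if (is.null(ids)) ids <- paste0("ind", seq_along(mm$phenotype))
  header <- c("marker", "chrom", "pos", ids)
  ph <- c("phenotype", "NA", "NA", unname(mm$phenotype))
  rows <- vapply(seq_len(nrow(mm$markers)), function(i) {
    paste(c(mm$markers$marker[i], mm$markers$chrom[i],
            format(mm$markers$pos[i], scientific = FALSE, trim = TRUE),
            mm$geno[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(paste(header, collapse = "\t"), paste(ph, collapse = "\t"), rows), path)
  invisible(path)
}
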