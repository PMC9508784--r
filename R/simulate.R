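# F2 cross and pooled-read simulator.
#
# The F1 parent is heterozygous (Aa) at every marker; the mutant (weeping)
# haplotype carries allele 1 everywhere. A gamete is a Markov walk along the
# markers of a chromosome: the phase starts 0/1 with probability 1/2 and
# switches between adjacent markers with the Haldane recombination fraction
# r = 0.5 * (1 - exp(-2 d / 100)), d the inter-marker distance in cM.
# No crossover interference is modelled.

# one chromosome's worth of gamete phases: n_gametes x n_markers logical
sim_gamete_phases <- function(n_gametes, r) {
  m <- length(r) + 1L
  ph <- matrix(FALSE, n_gametes, m)
  ph[, 1L] <- runif(n_gametes) < 0.5
  if (m > 1L) {
    sw <- matrix(runif(n_gametes * (m - 1L)) < rep(r, each = n_gametes),
                 n_gametes, m - 1L)
    for (j in 2:m) ph[, j] <- xor(ph[, j - 1L], sw[, j - 1L])
  }
  ph
}

haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Simulate an F2 population segregating for a single recessive locus
#'
#' Each individual is the fusion of two independent gametes of the
#' heterozygous F1; gametes recombine along each chromosome under the
#' Haldane map function (no interference) at the genome's `cm_per_mb` rate.
#' The phenotype is weeping if and only if the individual is homozygous for
#' the mutant allele at the causal locus (optionally misclassified at rate
#' `config$pheno_error`).
#'
#' @param genome A [genome_model()].
#' @param config A [cross_config()]; `causal_chrom`/`causal_pos` must name a
#'   marker of `genome`.
#'
#' @return An object of class `f2_pop`: a list with `genotypes` (integer
#'   matrix, individuals x markers, entries 0/1/2 = copies of the mutant
#'   allele), `phenotype` (character vector, `"weeping"`/`"standard"`),
#'   `map` (the marker tibble), `causal_marker`, `genome` and `config`.
#'   Deterministic given `config$seed`.
#' @export
#' @examples
#' pop <- simulate_f2_population(
#'   genome_model(c(chrA = 1e6), marker_spacing = 1e5),
#'   cross_config(n_f2 = 50, bulk_size = 10, causal_chrom = "chrA",
#'                causal_pos = 5e5, seed = 7)
#' )
#' table(pop$phenotype)
simulate_f2_population <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "cross_config"))
  map <- genome$markers
  causal <- which(map$chrom == config$causal_chrom & map$pos == config$causal_pos)
  if (length(causal) != 1) {
    stop("causal locus ", config$causal_chrom, ":", config$causal_pos,
         " is not a marker of the genome model")
  }
  n <- config$n_f2
  withr::with_seed(config$seed, {
    geno <- matrix(0L, n, nrow(map))
    for (chrom in unique(map$chrom)) {
      idx <- which(map$chrom == chrom)
      r <- haldane_r(diff(map$cm[idx]))
      ph <- sim_gamete_phases(2L * n, r)
      geno[, idx] <- ph[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
                     ph[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    }
    phenotype <- ifelse(geno[, causal] == 2L, "weeping", "standard")
    if (config$pheno_error > 0) {
      flip <- runif(n) < config$pheno_error
      phenotype[flip] <- ifelse(phenotype[flip] == "weeping", "standard", "weeping")
    }
  })
  colnames(geno) <- map$marker
  rownames(geno) <- sprintf("F2_%04d", seq_len(n))
  structure(
    list(genotypes = geno, phenotype = phenotype, map = map,
         causal_marker = map$marker[causal], genome = genome, config = config),
    class = "f2_pop"
  )
}

#' @export
print.f2_pop <- function(x, ...) {
  cat("<f2_pop> ", nrow(x$genotypes), " individuals x ", ncol(x$genotypes),
      " markers; weeping: ", sum(x$phenotype == "weeping"), "\n", sep = "")
  invisible(x)
}

#' @describeIn simulate_f2_population Long-format view of the population:
#'   one row per individual x marker with the mutant-allele dosage.
#' @param x An `f2_pop`.
#' @param ... Unused.
#' @method tidy f2_pop
#' @export
tidy.f2_pop <- function(x, ...) {
  tibble::tibble(
    id = rep(rownames(x$genotypes), times = ncol(x$genotypes)),
    marker = rep(colnames(x$genotypes), each = nrow(x$genotypes)),
    dosage = as.integer(x$genotypes),
    phenotype = rep(x$phenotype, times = ncol(x$genotypes))
  ) |>
    dplyr::left_join(x$map, by = "marker") |>
    dplyr::select("id", "chrom", "pos", "marker", "dosage", "phenotype")
}

#' Draw phenotype-selected bulks from an F2 population
#'
#' Bulks are uniform random subsets, without replacement, of the individuals
#' of each phenotype class, mirroring the equal-amount DNA pooling of
#' phenotype-selected plants.
#'
#' @param population An `f2_pop`.
#' @param bulk_size Individuals per bulk (default: the population config's).
#' @param seed RNG seed for the subset draw (default: config seed + 1).
#' @param ignore_phenotype If `TRUE`, both bulks are drawn from the whole
#'   population regardless of phenotype — the null cross used to check
#'   false-positive control.
#'
#' @return A list of class `f2_bulks` with integer index vectors `weeping`
#'   and `standard` (rows of the genotype matrix) plus `bulk_size` and `seed`.
#' @export
make_bulks <- function(population, bulk_size = NULL, seed = NULL,
                       ignore_phenotype = FALSE) {
  stopifnot(inherits(population, "f2_pop"))
  if (is.null(bulk_size)) bulk_size <- population$config$bulk_size
  if (is.null(seed)) seed <- population$config$seed + 1L
  n <- nrow(population$genotypes)
  if (ignore_phenotype) {
    if (2 * bulk_size > n) stop("need ", 2 * bulk_size, " individuals, have ", n)
    withr::with_seed(seed, {
      pick <- sample.int(n, 2L * bulk_size)
    })
    w <- pick[seq_len(bulk_size)]
    s <- pick[bulk_size + seq_len(bulk_size)]
  } else {
    w_all <- which(population$phenotype == "weeping")
    s_all <- which(population$phenotype == "standard")
    for (cls in list(c("weeping", length(w_all)), c("standard", length(s_all)))) {
      have <- as.integer(cls[2])
      if (have < bulk_size) {
        stop("cannot draw a bulk of ", bulk_size, " ", cls[1],
             " individuals: only ", have, " available (short by ",
             bulk_size - have, ")")
      }
    }
    withr::with_seed(seed, {
      w <- sort(sample(w_all, bulk_size))
      s <- sort(sample(s_all, bulk_size))
    })
  }
  structure(list(weeping = w, standard = s,
                 bulk_size = as.integer(bulk_size), seed = as.integer(seed)),
            class = "f2_bulks")
}

#' Per-marker mutant-allele frequency of a set of individuals
#'
#' @param population An `f2_pop`.
#' @param ids Row indices (as stored in an `f2_bulks`) of the pooled
#'   individuals.
#' @return Numeric vector of allele frequencies, one per marker.
#' @export
bulk_allele_freq <- function(population, ids) {
  colSums(population$genotypes[ids, , drop = FALSE]) / (2 * length(ids))
}

#' Simulate pooled read depths over a set of sites
#'
#' Per site, the total depth is Poisson(`depth_mean`) and the mutant-read
#' count is Binomial(depth, f') with f' = f(1 - e) + (1 - f)e, where f is the
#' pool's true mutant-allele frequency and e the symmetric per-read
#' allele-flip error rate. No base-quality model is applied.
#'
#' @param freq Numeric vector of true mutant-allele frequencies, one per site.
#' @param depth_mean Mean pooled depth (fold).
#' @param error_rate Per-read allele-flip probability.
#' @param seed RNG seed.
#' @return A tibble with columns `depth` and `mutant` (reads carrying the
#'   mutant allele); `0 <= mutant <= depth` always holds.
#' @export
simulate_pool_reads <- function(freq, depth_mean, error_rate = 0, seed = 1L) {
  stopifnot(depth_mean > 0, all(freq >= 0 & freq <= 1))
  f_obs <- freq * (1 - error_rate) + (1 - freq) * error_rate
  withr::with_seed(seed, {
    depth <- rpois(length(freq), depth_mean)
    mutant <- rbinom(length(freq), depth, f_obs)
  })
  tibble::tibble(depth = as.integer(depth), mutant = as.integer(mutant))
}

# deterministic but non-constant base pair per marker index
ref_alt_bases <- function(k) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[(k - 1L) %% 4L + 1L]
  alt <- bases[k %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Simulate the bulk allele-depth table of a BSA-seq experiment
#'
#' Produces the tabular equivalent of the variant calls the analysis
#' consumes: per-site ref/alt read depths for the heterozygous parent
#' (true frequency 1/2 everywhere) and the two phenotype bulks. By
#' construction the alt allele is the mutant (weeping-derived) allele.
#'
#' @param population An `f2_pop`.
#' @param bulks An `f2_bulks` drawn from it.
#' @param depth_mean,error_rate Sequencing model; default from the
#'   population's `cross_config`.
#' @param seed RNG seed; default config seed + 2.
#' @return A tibble in the package's allele-depth dialect: `chrom`, `pos`,
#'   `ref`, `alt`, `kind`, and `(parent|st|pl)_(ref|alt)` integer depths,
#'   sorted by (chrom, pos). The seed used is attached as attribute `seed`.
#' @export
simulate_bulk_depths <- function(population, bulks,
                                 depth_mean = NULL, error_rate = NULL,
                                 seed = NULL) {
  stopifnot(inherits(population, "f2_pop"), inherits(bulks, "f2_bulks"))
  cfg <- population$config
  if (is.null(depth_mean)) depth_mean <- cfg$depth_mean
  if (is.null(error_rate)) error_rate <- cfg$error_rate
  if (is.null(seed)) seed <- cfg$seed + 2L
  map <- population$map
  m <- nrow(map)
  f_pl <- bulk_allele_freq(population, bulks$weeping)
  f_st <- bulk_allele_freq(population, bulks$standard)
  pl <- simulate_pool_reads(f_pl, depth_mean, error_rate, seed = seed)
  st <- simulate_pool_reads(f_st, depth_mean, error_rate, seed = seed + 1L)
  parent <- simulate_pool_reads(rep(0.5, m), depth_mean, error_rate, seed = seed + 2L)
  b <- ref_alt_bases(seq_len(m))
  out <- tibble::tibble(
    chrom = map$chrom, pos = map$pos, ref = b$ref, alt = b$alt, kind = "snp",
    parent_ref = parent$depth - parent$mutant, parent_alt = parent$mutant,
    st_ref = st$depth - st$mutant, st_alt = st$mutant,
    pl_ref = pl$depth - pl$mutant, pl_alt = pl$mutant
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Describe a diagnostic indel linked to the causal locus
#'
#' By default a 35 bp deletion carried on the standard (non-weeping)
#' haplotype, so that weeping individuals are homozygous for the
#' full-length (non-deleted) allele.
#'
#' @param chrom,pos Location of the indel (defaults: at the causal locus of
#'   the population it is embedded into).
#' @param deleted_length Length of the deleted segment in bp (> 0).
#' @param carrier_haplotype Which parental haplotype lacks the segment:
#'   `"standard"` (default) or `"weeping"`.
#' @return A list of class `diagnostic_indel`.
#' @export
diagnostic_indel <- function(chrom = NULL, pos = NULL, deleted_length = 35,
                             carrier_haplotype = c("standard", "weeping")) {
  if (deleted_length <= 0) stop("`deleted_length` must be > 0")
  carrier_haplotype <- match.arg(carrier_haplotype)
  structure(list(chrom = chrom, pos = pos,
                 deleted_length = as.integer(deleted_length),
                 carrier_haplotype = carrier_haplotype),
            class = "diagnostic_indel")
}

indel_alleles <- function(indel) {
  # short allele = haplotype carrying the deletion; long allele = intact.
  anchor <- "G"
  long <- paste0(anchor, strrep("A", indel$deleted_length))
  list(short = anchor, long = long)
}

#' Embed a fully linked diagnostic indel into an allele-depth table
#'
#' Adds one indel record whose alleles co-segregate perfectly with the
#' causal-locus haplotypes: the haplotype named by `carrier_haplotype` lacks
#' a `deleted_length` bp segment. With the default standard-haplotype
#' carrier, the mutant (weeping-linked) allele is the full-length one, so
#' the alt column again counts the weeping-linked allele.
#'
#' @param depths An allele-depth tibble from [simulate_bulk_depths()].
#' @param population,bulks The population and bulks the table was simulated
#'   from (the indel's bulk frequencies are the causal-locus haplotype
#'   frequencies).
#' @param indel A [diagnostic_indel()]; `chrom`/`pos` default to the causal
#'   locus shifted by +1 bp so it does not collide with the causal SNP.
#' @param depth_mean,error_rate,seed Sequencing model for the indel record;
#'   defaults mirror [simulate_bulk_depths()].
#' @return The input tibble with one additional indel row, re-sorted by
#'   (chrom, pos).
#' @export
embed_diagnostic_indel <- function(depths, population, bulks,
                                   indel = diagnostic_indel(),
                                   depth_mean = NULL, error_rate = NULL,
                                   seed = NULL) {
  stopifnot(inherits(population, "f2_pop"), inherits(bulks, "f2_bulks"))
  cfg <- population$config
  if (is.null(indel$chrom)) indel$chrom <- cfg$causal_chrom
  if (is.null(indel$pos)) indel$pos <- cfg$causal_pos + 1
  if (is.null(depth_mean)) depth_mean <- cfg$depth_mean
  if (is.null(error_rate)) error_rate <- cfg$error_rate
  if (is.null(seed)) seed <- cfg$seed + 5L
  if (!indel$chrom %in% names(population$genome$chrom_lengths)) {
    stop("indel chromosome ", indel$chrom, " is not in the simulated genome")
  }
  if (indel$pos < 1 || indel$pos > population$genome$chrom_lengths[[indel$chrom]]) {
    stop("indel position outside chromosome ", indel$chrom)
  }
  if (any(depths$chrom == indel$chrom & depths$pos == indel$pos)) {
    stop("indel position ", indel$chrom, ":", indel$pos,
         " collides with an existing site")
  }
  # weeping-linked allele frequency at the indel = causal-locus frequency
  causal_col <- which(population$map$marker == population$causal_marker)
  g <- population$genotypes[, causal_col]
  f_link <- function(ids) sum(g[ids]) / (2 * length(ids))
  f_pl <- f_link(bulks$weeping)
  f_st <- f_link(bulks$standard)
  al <- indel_alleles(indel)
  # ref = reference-genome allele; mutant (weeping-linked) allele is intact
  # when the deletion rides the standard haplotype, deleted otherwise
  if (indel$carrier_haplotype == "standard") {
    ref_seq <- al$short; alt_seq <- al$long
  } else {
    ref_seq <- al$long; alt_seq <- al$short
  }
  pl <- simulate_pool_reads(f_pl, depth_mean, error_rate, seed = seed)
  st <- simulate_pool_reads(f_st, depth_mean, error_rate, seed = seed + 1L)
  parent <- simulate_pool_reads(0.5, depth_mean, error_rate, seed = seed + 2L)
  row <- tibble::tibble(
    chrom = indel$chrom, pos = as.numeric(indel$pos),
    ref = ref_seq, alt = alt_seq, kind = "indel",
    parent_ref = parent$depth - parent$mutant, parent_alt = parent$mutant,
    st_ref = st$depth - st$mutant, st_alt = st$mutant,
    pl_ref = pl$depth - pl$mutant, pl_alt = pl$mutant
  )
  out <- dplyr::bind_rows(depths, row) |>
    dplyr::arrange(.data$chrom, .data$pos)
  attr(out, "seed") <- attr(depths, "seed")
  out
}

#' Genotype individuals at the embedded diagnostic indel
#'
#' Maps each individual's causal-locus haplotypes through the indel's
#' carrier rule and reports mapping-population codes for the weeping-linked
#' allele: `B` = homozygous weeping-linked, `H` = heterozygous, `A` =
#' homozygous standard-linked.
#'
#' @param population An `f2_pop`.
#' @param indel A [diagnostic_indel()] (only the carrier rule is used; the
#'   indel is fully linked to the causal locus by construction).
#' @return Character vector of codes, one per individual.
#' @export
indel_genotypes <- function(population, indel = diagnostic_indel()) {
  causal_col <- which(population$map$marker == population$causal_marker)
  g <- population$genotypes[, causal_col]
  c("A", "H", "B")[g + 1L]
}

#' Genotype a population at chosen markers as a marker-genotype matrix
#'
#' @param population An `f2_pop`.
#' @param markers Character vector of marker ids (columns of the genotype
#'   matrix) to score.
#' @return A `marker_matrix` (see [read_marker_genotypes()]) with codes
#'   `A`/`H`/`B` for 0/1/2 copies of the mutant allele.
#' @export
genotype_markers <- function(population, markers) {
  missing <- setdiff(markers, colnames(population$genotypes))
  if (length(missing)) stop("unknown markers: ", paste(missing, collapse = ", "))
  map <- population$map[match(markers, population$map$marker), ]
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  geno <- t(population$genotypes[, map$marker, drop = FALSE])
  codes <- matrix(c("A", "H", "B")[geno + 1L], nrow = nrow(geno),
                  dimnames = dimnames(geno))
  new_marker_matrix(
    markers = tibble::tibble(marker = map$marker, chrom = map$chrom, pos = map$pos),
    geno = codes,
    phenotype = stats::setNames(population$phenotype, rownames(population$genotypes))
  )
}
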