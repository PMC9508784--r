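# Recombinant screening, interval localization and diagnostic markers.

test_that("a fully linked marker has zero recombinants", {
  ph <- c(rep("weeping", 3), rep("standard", 5))
  geno <- ifelse(ph == "weeping", "B", "H")
  mm <- toy_marker_matrix(list(geno), phenotype = ph)
  res <- count_recombinants(mm, mm$markers$marker[1])
  expect_equal(res$n_recombinant, 0)
  expect_equal(res$n_informative, 8)
})

test_that("planted discordances are recovered by id; missing are excluded", {
  ph <- c(rep("weeping", 4), rep("standard", 4))
  geno <- c("B", "H", "B", "B", "A", "B", "-", "H")  # I02 and I06 discordant
  mm <- toy_marker_matrix(list(geno), phenotype = ph)
  res <- count_recombinants(mm, mm$markers$marker[1])
  expect_equal(res$n_recombinant, 2)
  expect_setequal(res$ids, c("I02", "I06"))
  expect_equal(res$n_informative, 7)
  # exhaustive-rule oracle over every individual
  oracle <- sum(vapply(seq_along(ph), function(i) {
    g <- geno[i]
    g != "-" && ((ph[i] == "weeping" && g != "B") ||
                   (ph[i] == "standard" && g == "B"))
  }, logical(1)))
  expect_equal(res$n_recombinant, oracle)
  expect_error(count_recombinants(mm, "nope"), "not in matrix")
})

test_that("recombinant counts grow with map distance from the causal locus", {
  pop <- simulate_f2_population(toy_genome(n_chr = 1, len = 20e6, spacing = 1e6),
                                toy_cross(causal_pos = 1e6, n_f2 = 395, seed = 18))
  mm <- genotype_markers(pop, pop$map$marker)
  counts <- vapply(mm$markers$marker,
                   function(m) count_recombinants(mm, m)$n_recombinant,
                   integer(1))
  dist <- abs(mm$markers$pos - 1e6)
  expect_gt(stats::cor(dist, counts, method = "spearman"), 0)
  # zero recombinants at the causal marker itself, by construction
  expect_equal(unname(counts[mm$markers$pos == 1e6]), 0)
})

test_that("the localized interval spans the recombinant-bearing flanks", {
  ph <- c(rep("weeping", 2), rep("standard", 6))
  linked <- ifelse(ph == "weeping", "B", "A")
  left <- linked; left[c(1, 5)] <- c("H", "B")       # 2 recombinants
  right <- linked; right[c(2, 6, 7)] <- c("A", "B", "B")  # 3 recombinants
  mm <- toy_marker_matrix(list(left, linked, right), phenotype = ph,
                          pos = c(1e6, 2e6, 3e6))
  rep_ <- localize_interval(mm)
  expect_equal(rep_$per_marker$n_recombinant, c(2, 0, 3))
  expect_equal(rep_$interval$start, 1e6 - 1)
  expect_equal(rep_$interval$end, 3e6)
  expect_false(rep_$open_left)
  expect_false(rep_$open_right)
})

test_that("degenerate recombinant patterns are flagged", {
  ph <- c("weeping", "standard", "standard", "standard")
  linked <- c("B", "A", "H", "A")
  # all markers zero-recombinant: open on both sides
  mm <- toy_marker_matrix(list(linked, linked, linked), phenotype = ph)
  rep_ <- localize_interval(mm)
  expect_true(rep_$open_left)
  expect_true(rep_$open_right)
  # no zero-recombinant marker: undefined interval, counts still reported
  broken <- c("H", "A", "H", "A")
  mm2 <- toy_marker_matrix(list(broken, broken), phenotype = ph)
  rep2 <- localize_interval(mm2)
  expect_null(rep2$interval)
  expect_equal(nrow(rep2$per_marker), 2)
})

test_that("removing markers never shrinks the localized interval", {
  pop <- simulate_f2_population(toy_genome(n_chr = 1, len = 20e6, spacing = 5e5),
                                toy_cross(causal_pos = 10e6, n_f2 = 395, seed = 19))
  mm_full <- genotype_markers(pop, pop$map$marker)
  full <- localize_interval(mm_full)
  expect_false(is.null(full$interval))
  width <- function(r) r$interval$end - r$interval$start
  withr::with_seed(20, {
    for (k in 1:10) {
      keep <- sort(sample(seq_len(nrow(mm_full$markers)), 20))
      sub <- localize_interval(genotype_markers(pop, mm_full$markers$marker[keep]))
      if (!is.null(sub$interval) && !sub$open_left && !sub$open_right &&
          !full$open_left && !full$open_right) {
        expect_gte(width(sub), width(full))
      }
    }
  })
})

test_that("the fine-mapped interval contains the causal locus across seeds", {
  genome <- toy_genome(n_chr = 1, len = 20e6, spacing = 2e5)
  hits <- vapply(1:20, function(s) {
    pop <- simulate_f2_population(genome, toy_cross(causal_pos = 10e6,
                                                    n_f2 = 300, seed = s))
    rep_ <- localize_interval(genotype_markers(pop, pop$map$marker))
    !is.null(rep_$interval) &&
      rep_$interval$start <= 10e6 - 1 && rep_$interval$end >= 10e6
  }, logical(1))
  expect_true(all(hits))
})

test_that("diagnostic indel screening keeps only the co-segregating indel", {
  pop <- simulate_f2_population(toy_genome(), toy_cross(n_f2 = 200, seed = 22))
  b <- make_bulks(pop)
  s <- embed_diagnostic_indel(simulate_bulk_depths(pop, b), pop, b)
  region <- tibble::tibble(chrom = "chr1", start = 4e5, end = 6e5)
  hits <- find_diagnostic_indels(s, region)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length_diff_bp, 35)
  # SNPs are never returned even when fixed in the weeping bulk
  expect_false(any(hits$pos %in% s$pos[s$kind == "snp"]))

  # toy set: only the indel matching the fixation pattern survives
  toy <- tibble::tibble(
    chrom = "chr1", pos = c(1000, 2000, 3000),
    ref = c("G", "GAAAA", "G"), alt = c("GTTTTT", "G", "GCC"),
    kind = "indel",
    parent_ref = 30L, parent_alt = 30L,
    st_ref = c(40L, 10L, 38L), st_alt = c(20L, 50L, 22L),
    pl_ref = c(0L, 30L, 25L), pl_alt = c(60L, 30L, 35L)
  )
  got <- find_diagnostic_indels(toy, tibble::tibble(chrom = "chr1", start = 0, end = 5000))
  expect_equal(got$pos, 1000)
  expect_equal(got$length_diff_bp, 5)
})

test_that("co-segregation accuracy is 100% for the embedded indel and drops by k with k discordances", {
  pop <- simulate_f2_population(toy_genome(), toy_cross(n_f2 = 395, seed = 23))
  gt <- indel_genotypes(pop)
  res <- co_segregation_accuracy(gt, pop$phenotype)
  expect_equal(res$accuracy, 100)
  expect_equal(res$informative, 395)

  for (k in c(1, 5, 12)) {
    gt2 <- gt
    flip <- which(pop$phenotype == "weeping")[seq_len(k)]
    gt2[flip] <- "H"
    res2 <- co_segregation_accuracy(gt2, pop$phenotype)
    expect_equal(res2$concordant, res$concordant - k)
  }

  # missing genotypes leave numerator and denominator
  gt3 <- gt
  gt3[1:10] <- "-"
  res3 <- co_segregation_accuracy(gt3, pop$phenotype)
  expect_equal(res3$informative, 385)
  expect_equal(res3$accuracy, 100)

  expect_equal(co_segregation_accuracy("B", "weeping")$accuracy, 100)
  expect_error(co_segregation_accuracy(c("-", "-"), c("weeping", "standard")),
               "informative")
})

test_that("a phenotype-independent marker scores near the 62.5% chance level", {
  withr::with_seed(24, {
    n <- 20000
    gt <- sample(c("A", "H", "B"), n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    ph <- sample(c("weeping", "standard"), n, replace = TRUE, prob = c(0.25, 0.75))
  })
  res <- co_segregation_accuracy(gt, ph)
  # closed form under independence: 0.25 * 0.25 + 0.75 * 0.75 = 0.625
  expect_lt(abs(res$accuracy - 62.5), 3 * 100 * sqrt(0.625 * 0.375 / n))
})
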