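prot20 <- paste(rep("A", 20), collapse = "")

test_that("neopeptide windows cover exactly the mutation-spanning peptides", {
  mid <- enumerate_neopeptides(prot20, 10, "V", 9)
  expect_equal(nrow(mid), 9L)
  expect_equal(mid$start, 2:10)
  expect_true(all(vapply(seq_len(nrow(mid)), function(i) {
    substr(mid$peptide[i], 10 - mid$start[i] + 1, 10 - mid$start[i] + 1) == "V"
  }, TRUE)))

  left <- enumerate_neopeptides(prot20, 3, "V", 9)
  expect_equal(left$start, 1:3)
  right <- enumerate_neopeptides(prot20, 20, "V", 9)
  expect_equal(right$start, 12L)

  expect_error(enumerate_neopeptides(prot20, 0, "V"), "out of")
  expect_error(enumerate_neopeptides(prot20, 21, "V"), "out of")
  expect_error(enumerate_neopeptides(prot20, 5, "A"), "equals")
})

test_that("effective affinity aggregates harmonic binding channels", {
  expect_equal(effective_affinity(500), 500)
  expect_equal(effective_affinity(c(500, 500)), 250)
  expect_equal(effective_affinity(c(100, 50000)), 1 / (0.01 + 0.00002))
  expect_error(effective_affinity(numeric(0)), "no dissociation")
  expect_error(effective_affinity(c(100, -1)), "positive")

  # adding a channel never worsens the effective affinity
  set.seed(4)
  kd <- rlnorm(10, log(1000), 1)
  for (i in 2:10) {
    expect_lte(effective_affinity(kd[1:i]), effective_affinity(kd[1:(i - 1)]))
  }
})

test_that("presentation probability sits on the saturation curve", {
  expect_equal(presentation_probability(500, 1, 500), 0.5)
  expect_equal(presentation_probability(50000, 1, 500), 1 / 101)
  expect_equal(presentation_probability(500, 2, 500), 2 / 3)
  expect_error(presentation_probability(-1, 1), "positive")
})

test_that("single-haplotype populations average to their own probability", {
  aff <- affinity_table(data.frame(peptide = "PEPTIDEKL",
                                   allele = paste0("AL", 1:6),
                                   kd_nm = c(100, 200, 400, 800, 1600, 3200)))
  hap <- haplotype_model(haplotypes = data.frame(
    allele1 = "AL1", allele2 = "AL2", allele3 = "AL3",
    allele4 = "AL4", allele5 = "AL5", allele6 = "AL6", weight = 1))
  got <- haplotype_average("PEPTIDEKL", aff, hap, n_draws = 50, seed = 1)
  k_exp <- effective_affinity(c(100, 200, 400, 800, 1600, 3200))
  expect_equal(got$p_pres_mean, presentation_probability(k_exp))
  expect_equal(got$p_pres_se, 0)

  # determinism under a fixed seed
  again <- haplotype_average("PEPTIDEKL", aff, hap, n_draws = 50, seed = 1)
  expect_identical(got$p_pres_mean, again$p_pres_mean)
})

test_that("unknown peptide-allele pairs score the non-binder cap", {
  aff <- affinity_table(data.frame(peptide = "AAAAAAAAA", allele = "X",
                                   kd_nm = 100), kd_cap = 50000)
  expect_equal(freefit:::lookup_kd(aff, "AAAAAAAAA", "Y"), 50000)
  expect_equal(freefit:::lookup_kd(aff, "AAAAAAAAA", "X"), 100)
})

# Exact mean over the three genotypes of one biallelic locus (other loci
# fixed), computed by direct enumeration with Hardy-Weinberg weights.
enumeration_mean <- function(kd_by_allele, p_a) {
  strengths <- 1 / kd_by_allele
  keff <- function(alleles) 1 / sum(strengths[alleles])
  fixed <- c("B1", "B1", "C1", "C1")
  geno <- list(c("A1", "A1"), c("A1", "A2"), c("A2", "A2"))
  w <- c(p_a^2, 2 * p_a * (1 - p_a), (1 - p_a)^2)
  sum(w * vapply(geno, function(g) {
    presentation_probability(keff(c(g, fixed)))
  }, 0))
}

test_that("Monte Carlo haplotype average converges to exact enumeration", {
  kd <- c(A1 = 300, A2 = 5000, B1 = 2000, C1 = 20000)
  aff <- affinity_table(data.frame(peptide = "QQQQQQQQQ",
                                   allele = names(kd), kd_nm = unname(kd)))
  hap <- haplotype_model(freqs = data.frame(
    locus = c("A", "A", "B", "C"),
    allele = c("A1", "A2", "B1", "C1"),
    freq = c(0.5, 0.5, 1, 1)))
  exact <- enumeration_mean(kd, 0.5)

  got <- haplotype_average("QQQQQQQQQ", aff, hap, n_draws = 10000, seed = 99)
  expect_lt(abs(got$p_pres_mean - exact), 3 * got$p_pres_se)

  # within 3 standard errors in at least 95 of 100 seeds
  hits <- 0L
  for (s in 1:100) {
    g <- haplotype_average("QQQQQQQQQ", aff, hap, n_draws = 2000, seed = s)
    if (abs(g$p_pres_mean - exact) <= 3 * g$p_pres_se) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("allele order within a haplotype does not change the probability", {
  aff <- affinity_table(data.frame(peptide = "WWWWWWWWW",
                                   allele = c("X1", "X2"),
                                   kd_nm = c(150, 9000)))
  hap1 <- haplotype_model(haplotypes = data.frame(
    allele1 = "X1", allele2 = "X2", allele3 = "X1",
    allele4 = "X2", allele5 = "X1", allele6 = "X2", weight = 1))
  hap2 <- haplotype_model(haplotypes = data.frame(
    allele1 = "X2", allele2 = "X1", allele3 = "X2",
    allele4 = "X1", allele5 = "X2", allele6 = "X1", weight = 1))
  a <- haplotype_average("WWWWWWWWW", aff, hap1, n_draws = 10, seed = 1)
  b <- haplotype_average("WWWWWWWWW", aff, hap2, n_draws = 10, seed = 1)
  expect_equal(a$p_pres_mean, b$p_pres_mean)
})

test_that("immune profile stays within [0, 1] and respects concentration", {
  study <- synthesize_study(synth_config(seed = 8, n_codons = 12,
                                         n_hap_draws = 50, cohort_n = 20))
  expect_true(all(study$immune$p_pres >= 0 & study$immune$p_pres <= 1))
  hi <- immune_profile(study$catalog, study$gene$protein, study$affinities,
                       study$hap, c_m = 10, n_draws = 50, seed = 2)
  lo <- immune_profile(study$catalog, study$gene$protein, study$affinities,
                       study$hap, c_m = 0.1, n_draws = 50, seed = 2)
  expect_true(all(hi$p_pres > lo$p_pres))
})

test_that("affinity and allele-frequency TSV readers accept the layouts", {
  dir <- withr::local_tempdir()
  ap <- file.path(dir, "aff.tsv")
  write.table(data.frame(peptide = "KKKKKKKKK", allele = "HLA-A*02:01",
                         kd_nm = 42), ap, sep = "\t", quote = FALSE,
              row.names = FALSE)
  aff <- read_affinity_tsv(ap)
  expect_equal(freefit:::lookup_kd(aff, "KKKKKKKKK", "HLA-A*02:01"), 42)

  fp <- file.path(dir, "freq.tsv")
  write.table(data.frame(locus = rep(c("A", "B", "C"), each = 2),
                         allele = paste0("al", 1:6), freq = rep(0.5, 6)),
              fp, sep = "\t", quote = FALSE, row.names = FALSE)
  hap <- read_allele_freq_tsv(fp)
  expect_s3_class(hap, "haplotype_model")
  expect_equal(dim(sample_haplotypes(hap, 5, seed = 1)), c(5L, 6L))
})
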