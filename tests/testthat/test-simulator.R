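test_that("identical configurations give identical cohorts and files", {
  cfg <- sim_config(n_trios = 15, seed = 99)
  c1 <- simulate_trio_cohort(cfg)
  c2 <- simulate_trio_cohort(cfg)
  expect_identical(c1$panel$a1, c2$panel$a1)
  expect_identical(c1$truth, c2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_cohort(c1, d1); p2 <- write_cohort(c2, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("haplotype generation follows density and frequency spectrum", {
  cfg <- sim_config(n_trios = 30, snp_density = 1, seed = 6)
  mh <- simulate_maternal_haplotypes(cfg)
  # ~20 kb of window per locus at 1 SNP/kb over 25 loci: Poisson around 500
  expect_gt(nrow(mh$sites), 350); expect_lt(nrow(mh$sites), 650)
  expect_true(all(mh$sites$freq >= 0.05 & mh$sites$freq <= 0.5))
  expect_equal(ncol(mh$hap), 60L)
  # degenerate spectrum at 0.5
  cfg2 <- sim_config(n_trios = 200, maf_range = c(0.5, 0.5), seed = 6)
  mh2 <- simulate_maternal_haplotypes(cfg2, n_haplotypes = 400L)
  expect_lt(abs(mean(mh2$hap) - 0.5), 0.02)
  # zero density is valid and empty
  cfg0 <- sim_config(n_trios = 5, snp_density = 0, seed = 1)
  expect_equal(nrow(simulate_maternal_haplotypes(cfg0)$sites), 0L)
})

test_that("meiosis engine: boundary thetas and switch-rate calibration", {
  set.seed(10)
  h1 <- rep(0L, 6); h2 <- rep(1L, 6)
  site_locus <- rep(1:3, each = 2)
  # theta = 0 everywhere: gamete equals one parental haplotype exactly
  for (i in 1:10) {
    m <- simulate_meiosis(h1, h2, site_locus, genetic_map = c(0, 0))
    expect_true(all(m$gamete == h1) || all(m$gamete == h2))
    expect_equal(length(unique(m$hap_at_locus)), 1L)
  }
  # theta = 0.5, single interval: switch fraction within 3 SD of 0.5
  set.seed(11)
  sw <- replicate(10000, {
    m <- simulate_meiosis(c(0L, 0L), c(1L, 1L), 1:2, 0.5)
    m$hap_at_locus[1] != m$hap_at_locus[2]
  })
  expect_lt(abs(mean(sw) - 0.5), 3 * sqrt(0.25 / 10000))
  # theta = 0.02: observed fraction inside its own exact 95% CI of 0.02
  set.seed(12)
  sw2 <- replicate(5000, {
    m <- simulate_meiosis(c(0L, 0L), c(1L, 1L), 1:2, 0.02)
    m$hap_at_locus[1] != m$hap_at_locus[2]
  })
  ci <- clopper_pearson(sum(sw2), 5000)
  expect_gte(0.02, ci$low); expect_lte(0.02, ci$high)
})

test_that("cohorts are Mendelian-consistent and truth matches crossovers", {
  cfg <- sim_config(n_trios = 40, seed = 23)
  co <- simulate_trio_cohort(cfg)
  fit <- trio_recomb(co$panel, co$ped, co$markers)
  expect_equal(sum(fit$qc$n_mendel), 0L)
  # truth recombinant indicator = odd number of interval switches
  jp <- junction_pairs(co$markers)
  for (i in seq_len(nrow(jp))) {
    la <- jp$locus_a[i]; lb <- jp$locus_b[i]
    ia <- which(co$markers$name == la); ib <- which(co$markers$name == lb)
    hap_path <- as.matrix(co$truth[, 1 + (ia:ib), drop = FALSE])
    switches <- colSums(abs(diff(t(hap_path))) != 0)
    expect_equal(unname(truth_recombinant(co, la, lb)),
                 unname(switches %% 2 == 1))
  }
})

test_that("simulated cohorts round-trip through the file readers", {
  cfg <- sim_config(n_trios = 10, seed = 31)
  co <- simulate_trio_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  males <- co$ped$sample_id[co$ped$sex == "male"]
  p <- read_phased_vcf(paths["vcf"], males = males)
  expect_equal(p$sites$pos, co$panel$sites$pos)
  expect_equal(unname(p$a1[, co$panel$samples]), unname(co$panel$a1))
  expect_equal(unname(p$a2[, co$panel$samples]), unname(co$panel$a2))
  ped <- read_ped(paths["ped"])
  expect_equal(trios_from_ped(ped)$child, sprintf("C%04d", 1:10))
  mk <- read_marker_table(paths["markers"])
  expect_equal(mk$name, co$markers$name)
  # and the pipeline gives identical results from files and from memory
  fit_mem <- trio_recomb(co$panel, co$ped, co$markers)
  fit_file <- trio_recomb(paths[["vcf"]], paths[["ped"]], paths[["markers"]])
  expect_equal(fit_file$pairs, fit_mem$pairs)
})

test_that("family simulator reproduces composition spec and clean inheritance", {
  cfg <- sim_config(seed = 41, theta_str = 0, mutation_rate = 0)
  fs <- simulate_str_families(cfg)
  fam <- fs$families
  expect_equal(length(unique(fam$family_id)), 66L)
  # 22 families composed of father + mother + 2 daughters
  per <- split(fam, fam$family_id)
  comp <- t(sapply(per, function(f)
    c(fa = sum(f$role == "father"),
      dau = sum(f$role == "child" & f$sex == "female"),
      son = sum(f$role == "child" & f$sex == "male"))))
  expect_equal(sum(comp[, "fa"] == 1 & comp[, "dau"] == 2 & comp[, "son"] == 0),
               22L)
  expect_equal(sum(comp[, "fa"] == 0 & comp[, "son"] == 2 & comp[, "dau"] == 0),
               21L)
  # theta 0, mutation 0: every child's maternal alleles form one maternal
  # haplotype, and no meiosis is Mendelian-flagged
  for (f in per[1:10]) {
    m <- extract_maternal_meioses(f, "STR_A", "STR_B")
    expect_false(any(m$mendel))
    mA <- attr(m, "mother_a"); mB <- attr(m, "mother_b")
    for (i in which(m$informative)) {
      h <- if (m$allele_a[i] == mA[1]) 1L else 2L
      expect_equal(m$allele_b[i], mB[h])
    }
  }
  expect_false(any(unlist(fs$truth[, -(1:2)])))
})

test_that("gene-conversion mode produces conservative exclusions", {
  cfg_gc <- sim_config(n_trios = 60, seed = 19, gene_conversion_rate = 0.3)
  co <- simulate_trio_cohort(cfg_gc)
  fit <- trio_recomb(co$panel, co$ped, co$markers)
  # short double-switch tracts create discordant segments -> EXCLUDED calls
  expect_gt(sum(fit$calls$verdict == "EXCLUDED"), 0)
})
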