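make_family <- function(fid, mother, father = NULL, kids) {
  # kids: list of list(id, sex, A, B); genotypes as "a/b" or "a"
  rows <- list(data.frame(family_id = fid, member_id = paste0(fid, "_M"),
                          role = "mother", sex = "female", A = mother[1],
                          B = mother[2], stringsAsFactors = FALSE))
  if (!is.null(father))
    rows <- c(rows, list(data.frame(family_id = fid,
                                    member_id = paste0(fid, "_F"),
                                    role = "father", sex = "male",
                                    A = father[1], B = father[2],
                                    stringsAsFactors = FALSE)))
  for (k in kids)
    rows <- c(rows, list(data.frame(family_id = fid, member_id = k$id,
                                    role = "child", sex = k$sex, A = k$A,
                                    B = k$B, stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  attr(out, "loci") <- c("A", "B")
  class(out) <- c("family_table", "data.frame")
  out
}

test_that("maternal meiosis extraction: sons, daughters, informativeness", {
  fam <- make_family("F1", mother = c("12/14", "8/9"),
                     father = c("14", "9"),
                     kids = list(list(id = "S1", sex = "male", A = "12", B = "8"),
                                 list(id = "D1", sex = "female", A = "12/14",
                                      B = "9/9")))
  m <- extract_maternal_meioses(fam, "A", "B")
  expect_equal(m$allele_a, c("12", "12"))  # daughter: 14 is paternal
  expect_equal(m$allele_b, c("8", "9"))
  expect_true(all(m$informative))
  # homozygous mother at one locus -> uninformative
  fam2 <- make_family("F2", mother = c("12/12", "8/9"),
                      kids = list(list(id = "S1", sex = "male", A = "12",
                                       B = "8")))
  expect_false(extract_maternal_meioses(fam2, "A", "B")$informative)
  # transmitted allele absent from the mother: Mendelian flag (mutation)
  fam3 <- make_family("F3", mother = c("12/14", "8/9"),
                      kids = list(list(id = "S1", sex = "male", A = "15",
                                       B = "8")))
  m3 <- extract_maternal_meioses(fam3, "A", "B")
  expect_true(m3$mendel)
  expect_false(m3$informative)
})

test_that("phase-marginalised likelihood closed forms", {
  # a single meiosis carries no linkage information: L = 1/4 for every theta
  for (th in c(0, 0.1, 0.3, 0.5))
    expect_equal(two_point_loglik(list(TRUE), th), log(0.25), tolerance = 1e-12)
  # n phase-consistent meioses in one family at theta = 0: L = (1/2)(1/2)^n
  for (n in c(2, 5, 10))
    expect_equal(two_point_loglik(list(rep(TRUE, n)), 0),
                 log(0.5 * 0.5^n), tolerance = 1e-12)
  expect_error(two_point_loglik(list(TRUE), 0.6))
})

test_that("likelihood equals exhaustive phase enumeration and is phase-symmetric", {
  set.seed(31)
  for (rep in 1:5) {
    fams <- lapply(1:3, function(i) runif(sample(1:3, 1)) < 0.5)
    for (th in c(0.05, 0.2, 0.5)) {
      expect_equal(two_point_loglik(fams, th),
                   log(oracle_marginal_lik(fams, th)), tolerance = 1e-10)
      # relabeling both phases (flip every indicator) leaves L unchanged
      expect_equal(two_point_loglik(fams, th),
                   two_point_loglik(lapply(fams, `!`), th), tolerance = 1e-12)
    }
  }
})

test_that("MLOD estimation: closed forms and boundary behaviour", {
  # phase-unknown, 10 meioses, no recombinant: MLOD = 9 log10 2
  r <- estimate_theta_mlod(list(rep(TRUE, 10)))
  expect_equal(r$theta_hat, 0, tolerance = 1e-5)
  expect_equal(r$mlod, 9 * log10(2), tolerance = 1e-6)
  # 50/50 split: no linkage signal
  r2 <- estimate_theta_mlod(list(rep(c(TRUE, FALSE), 10)))
  expect_equal(r2$theta_hat, 0.5)
  expect_equal(r2$mlod, 0, tolerance = 1e-9)
  expect_true(is.na(r2$kosambi_cm))
  # no informative meioses
  r3 <- estimate_theta_mlod(list())
  expect_true(is.na(r3$theta_hat)); expect_equal(r3$mlod, 0)
  # MLOD is never negative (property over random inputs)
  set.seed(5)
  for (i in 1:10) {
    fams <- lapply(1:4, function(j) runif(sample(1:4, 1)) < runif(1))
    expect_gte(estimate_theta_mlod(fams)$mlod, 0)
  }
})

test_that("phase-known limit: theta_hat equals the recombinant proportion", {
  set.seed(8)
  fams <- lapply(1:10, function(i) runif(4) < 0.8)
  prop_inconsistent <- 1 - mean(unlist(fams))
  r <- estimate_theta_mlod(fams, phase_prior = c(1, 0))
  expect_equal(r$theta_hat, prop_inconsistent, tolerance = 1e-5)
})

test_that("kosambi map and its inverse", {
  expect_equal(kosambi_map(0), 0)
  expect_equal(kosambi_map(0.25), 25 * log(3), tolerance = 1e-12)
  expect_true(is.na(kosambi_map(0.5)))
  th <- seq(0, 0.49, length.out = 100)
  expect_lt(max(abs(kosambi_theta(kosambi_map(th)) - th)), 1e-9)
  expect_true(all(diff(kosambi_map(th)) > 0))  # monotone in theta
})

test_that("simulated families recover theta and flag significant linkage", {
  cfg <- sim_config(n_families = 40, theta_str = 0.05, seed = 17,
                    family_structures = data.frame(father = 1, mother = 1,
                                                   daughter = 1, son = 2,
                                                   n = 1))
  fs <- simulate_str_families(cfg)
  tp <- xstr_twopoint(fs$families, "STR_A", "STR_B")
  ci <- clopper_pearson(round(0.05 * tp$n_informative), tp$n_informative)
  expect_gte(tp$theta_hat, ci$low)
  expect_lte(tp$theta_hat, ci$high)
  expect_gt(tp$mlod, 3)
  # Rc with exact CI covers the simulated truth
  pr <- family_recomb_fraction(fs$families, "STR_A", "STR_B")
  expect_gte(0.05, pr$ci_low)
  expect_lte(0.05, pr$ci_high)
})

test_that("all-consistent family data give Rc = 0 with CI lower bound 0", {
  cfg <- sim_config(n_families = 20, theta_str = 0, seed = 2)
  fs <- simulate_str_families(cfg)
  pr <- family_recomb_fraction(fs$families, "STR_A", "STR_B")
  expect_equal(pr$fraction, 0, tolerance = 1e-6)
  expect_equal(pr$ci_low, 0)
  expect_lte(pr$twopoint$theta_hat, 1e-6)
})

test_that("twopoint scan reports every adjacent pair", {
  cfg <- sim_config(n_families = 15, seed = 3,
                    str_loci = c("L1", "L2", "L3"), theta_str = c(0.02, 0.5))
  fs <- simulate_str_families(cfg)
  sc <- twopoint_scan(fs$families)
  expect_equal(sc$pair, c("L1-L2", "L2-L3"))
  expect_true(all(sc$theta_hat >= 0 & sc$theta_hat <= 0.5, na.rm = TRUE))
})
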