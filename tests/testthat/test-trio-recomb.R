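test_that("maternal allele tracing follows the X-inheritance subtraction rule", {
  # son: hemizygous pass-through
  r <- maternal_allele_of_child(m1 = 0L, m2 = 1L, c1 = 0L, child_sex = "male")
  expect_equal(r$allele, 0L); expect_equal(r$status, "determined")
  # daughter het, father hemizygous G -> maternal allele is the other one
  r <- maternal_allele_of_child(0L, 1L, c1 = 0L, c2 = 1L, f1 = 1L,
                                child_sex = "female")
  expect_equal(r$allele, 0L)
  # daughter homozygous: her only allele, father consistent
  r <- maternal_allele_of_child(0L, 1L, c1 = 1L, c2 = 1L, f1 = 1L,
                                child_sex = "female")
  expect_equal(r$allele, 1L)
  # daughter homozygous for a non-paternal allele: no consistent assignment
  r <- maternal_allele_of_child(0L, 1L, c1 = 0L, c2 = 0L, f1 = 1L,
                                child_sex = "female")
  expect_equal(r$status, "mendelian_error")
  # daughter het with father missing: undetermined, not an error
  r <- maternal_allele_of_child(0L, 1L, c1 = 0L, c2 = 1L, f1 = NA_integer_,
                                child_sex = "female")
  expect_equal(r$status, "undetermined")
  # father's allele in neither daughter allele
  r <- maternal_allele_of_child(0L, 1L, c1 = 0L, c2 = 0L, f1 = 1L,
                                child_sex = "female")
  expect_equal(r$status, "mendelian_error")
  # son allele absent from the mother
  r <- maternal_allele_of_child(0L, 0L, c1 = 1L, child_sex = "male")
  expect_equal(r$status, "mendelian_error")
})

test_that("segment origin requires at least one vote and unanimity", {
  # one SNP, mother A|G phased, son carries hap1 allele
  sc <- call_segment_origin(m1 = 0L, m2 = 1L, c1 = 0L, child_sex = "male")
  expect_equal(sc$verdict, "HAP1")
  expect_equal(sc$n_informative_snps, 1L)
  # three unanimous HAP2 votes
  sc <- call_segment_origin(m1 = c(0L, 1L, 0L), m2 = c(1L, 0L, 1L),
                            c1 = c(1L, 0L, 1L), child_sex = "male")
  expect_equal(sc$verdict, "HAP2")
  expect_equal(sc$n_informative_snps, 3L)
  # conflicting votes -> DISCORDANT with the minority counted
  sc <- call_segment_origin(m1 = c(0L, 0L), m2 = c(1L, 1L),
                            c1 = c(0L, 1L), child_sex = "male")
  expect_equal(sc$verdict, "DISCORDANT")
  expect_equal(sc$n_conflicting_snps, 1L)
  # homozygous mother everywhere: transmission indistinguishable
  sc <- call_segment_origin(m1 = c(0L, 1L), m2 = c(0L, 1L),
                            c1 = c(0L, 1L), child_sex = "male")
  expect_equal(sc$verdict, "UNINFORMATIVE")
  expect_equal(sc$n_informative_snps, 0L)
  # majority mode takes a strict majority instead
  sc <- call_segment_origin(m1 = c(0L, 0L, 0L), m2 = c(1L, 1L, 1L),
                            c1 = c(0L, 0L, 1L), child_sex = "male",
                            conflict = "majority")
  expect_equal(sc$verdict, "HAP1")
  # mendelian-error site dropped from voting and tallied
  sc <- call_segment_origin(m1 = c(0L, 0L), m2 = c(1L, 0L),
                            c1 = c(0L, 1L), child_sex = "male")
  expect_equal(sc$verdict, "HAP1")
  expect_equal(sc$n_mendel, 1L)
})

test_that("region verdict truth table over all 16 segment combinations", {
  lv <- c("HAP1", "HAP2", "UNINFORMATIVE", "DISCORDANT")
  grid <- expand.grid(up = lv, down = lv, stringsAsFactors = FALSE)
  expected <- function(up, down) {
    if (up == "DISCORDANT" || down == "DISCORDANT") return("EXCLUDED")
    hap_u <- up %in% c("HAP1", "HAP2"); hap_d <- down %in% c("HAP1", "HAP2")
    if (hap_u && hap_d) { if (up == down) up else "EXCLUDED" }
    else "UNINFORMATIVE"
  }
  got <- call_region_origin(grid$up, grid$down)
  want <- mapply(expected, grid$up, grid$down)
  expect_equal(unname(got), unname(want))
})

test_that("junction pair construction over linkage groups", {
  mk <- xstr25_markers()
  jp <- junction_pairs(mk)
  expect_equal(nrow(jp), 6L)
  expect_equal(jp$group_a, paste0("LG", 1:6))
  expect_equal(jp$group_b, paste0("LG", 2:7))
  jpw <- junction_pairs(mk, within = TRUE)
  expect_equal(sum(jpw$type == "within"), 18L)  # sum over groups of size-1
  one <- marker_table("A", "chrX", 1, 2, "G1")
  expect_equal(nrow(junction_pairs(one)), 0L)
  inter <- marker_table(c("A", "B", "C"), "chrX", c(1, 10, 20), c(2, 11, 21),
                        c("G1", "G2", "G1"))
  expect_error(junction_pairs(inter), "interleaved")
})

test_that("pair recombination counting, CI and conservation", {
  a <- c("HAP1", "HAP1", "HAP2", "HAP1")
  b <- c("HAP1", "HAP2", "HAP2", "UNINFORMATIVE")
  pr <- pair_recombination(a, b)
  expect_equal(pr$k_recomb, 1L)
  expect_equal(pr$n_informative, 3L)
  expect_equal(pr$fraction, 1 / 3)
  # identical verdicts -> zero recombinants
  pr0 <- pair_recombination(a, a)
  expect_equal(pr0$k_recomb, 0L)
  expect_equal(pr0$fraction, 0)
  expect_equal(pr0$ci_low, 0)
  # no informative trios -> NA fraction, no error
  prna <- pair_recombination("UNINFORMATIVE", "HAP1")
  expect_true(is.na(prna$fraction))
  # conservation: informative + uninformative + excluded = total
  set.seed(9)
  lv <- c("HAP1", "HAP2", "UNINFORMATIVE", "EXCLUDED")
  for (i in 1:25) {
    x <- sample(lv, 30, replace = TRUE); y <- sample(lv, 30, replace = TRUE)
    pr <- pair_recombination(x, y)
    expect_equal(pr$n_informative + pr$n_uninformative + pr$n_excluded, 30L)
    expect_true(pr$k_recomb <= pr$n_informative)
  }
})

test_that("informative-SNP selection filters by window and MAF monotonically", {
  rp <- random_trio_panel(n_snps = 40, n_trios = 6, seed = 4, freq = 0.3)
  win <- c(500L, 2000L)
  sel0 <- select_informative_snps(rp$panel, "chrX", win, maf_min = 0)
  expect_true(all(sel0$sites$pos >= 500 & sel0$sites$pos <= 2000))
  counts <- sapply(c(0, 0.1, 0.2, 0.3, 0.5),
                   function(m) nrow(select_informative_snps(rp$panel, "chrX",
                                                           win, m)$sites))
  expect_true(all(diff(counts) <= 0))
  none <- select_informative_snps(rp$panel, "chrX", c(100000L, 200000L))
  expect_equal(nrow(none$sites), 0L)
})

test_that("segment verdicts equal brute-force enumeration on random fixtures", {
  for (seed in 1:8) {
    rp <- random_trio_panel(n_snps = 5, n_trios = 10, seed = seed, freq = 0.4)
    p <- rp$panel
    for (t in seq_len(nrow(rp$trios))) {
      mo <- rp$trios$mother[t]; fa <- rp$trios$father[t]
      ch <- rp$trios$child[t]; sex <- rp$trios$child_sex[t]
      got <- call_segment_origin(p$a1[, mo], p$a2[, mo], p$a1[, ch],
                                 p$a2[, ch], p$a1[, fa], sex)$verdict
      want <- oracle_segment_verdict(p$a1[, mo], p$a2[, mo], p$a1[, ch],
                                     p$a2[, ch], p$a1[, fa], sex)
      expect_equal(got, want)
    }
  }
})

test_that("relabeling the mother's haplotypes flips verdicts but not fractions", {
  cfg <- sim_config(n_trios = 40, seed = 21)
  co <- simulate_trio_cohort(cfg)
  fit1 <- trio_recomb(co$panel, co$ped, co$markers)
  flipped <- co$panel
  mo <- grep("^M", flipped$samples, value = TRUE)
  tmp <- flipped$a1[, mo]
  flipped$a1[, mo] <- flipped$a2[, mo]
  flipped$a2[, mo] <- tmp
  fit2 <- trio_recomb(flipped, co$ped, co$markers)
  v1 <- fit1$verdicts; v2 <- fit2$verdicts
  swap <- c(HAP1 = "HAP2", HAP2 = "HAP1", UNINFORMATIVE = "UNINFORMATIVE",
            EXCLUDED = "EXCLUDED")
  expect_equal(unname(swap[v1]), unname(c(v2)))
  expect_equal(fit1$pairs$k_recomb, fit2$pairs$k_recomb)
  expect_equal(fit1$pairs$n_informative, fit2$pairs$n_informative)
  expect_equal(fit1$pairs$fraction_pct, fit2$pairs$fraction_pct)
})

test_that("trio pipeline verdicts agree with simulation truth", {
  cfg <- sim_config(n_trios = 60, seed = 13)
  co <- simulate_trio_cohort(cfg)
  fit <- trio_recomb(co$panel, co$ped, co$markers)
  expect_equal(sum(fit$qc$n_mendel), 0L)  # clean inheritance, no errors
  v <- fit$verdicts
  tr <- as.matrix(co$truth[, -1]); rownames(tr) <- co$truth$trio
  for (l in colnames(v)) {
    def <- v[, l] %in% c("HAP1", "HAP2")
    est <- ifelse(v[def, l] == "HAP1", 1L, 2L)
    expect_equal(unname(est), unname(tr[rownames(v)[def], l]))
  }
  # per-pair conservation holds in the report
  expect_true(all(fit$pairs$n_informative + fit$pairs$n_uninformative +
                    fit$pairs$n_excluded == cfg$n_trios))
})
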