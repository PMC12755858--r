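# fixtures and independent oracles shared by the suite -----------------------

# hand-written phased VCF: 5 biallelic SNVs + 1 multiallelic site on chrX.
# samples: MOM (phased diploid), DAD (male, mixed haploid/diploid coding),
# SON (male), DAU (phased diploid)
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "MOM", "DAD", "SON", "DAU", sep = "\t"),
    "chrX\t1000\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t0\t1\t1|0",
    "chrX\t2000\trs2\tC\tT\t.\tPASS\t.\tGT\t1|0\t1|1\t0\t1|1",
    "chrX\t3000\trs3\tG\tA\t.\tPASS\t.\tGT\t0|0\t0|0\t0\t0|0",
    "chrX\t4000\trs4\tT\tC\t.\tPASS\t.\tGT\t0/1\t1\t1\t0|1",
    "chrX\t5000\trs5\tA\tC,G\t.\tPASS\t.\tGT\t1|2\t0\t1\t2|0",
    "chrX\t6000\trs6\tG\tC\t.\tPASS\t.\tGT\t0|1\t.\t.\t./."),
    path)
  path
}

# deterministic random snp_panel of unrelated trios for property tests;
# genotypes drawn freely (no inheritance model)
random_trio_panel <- function(n_snps, n_trios, seed, freq = 0.5) {
  set.seed(seed)
  mo <- sprintf("M%d", seq_len(n_trios))
  fa <- sprintf("F%d", seq_len(n_trios))
  ch <- sprintf("C%d", seq_len(n_trios))
  sex <- sample(c("male", "female"), n_trios, replace = TRUE)
  draw <- function() matrix(rbinom(n_snps * n_trios, 1L, freq), n_snps)
  a1 <- cbind(draw(), draw(), draw())
  a2 <- cbind(draw(), matrix(NA_integer_, n_snps, n_trios),
              ifelse(matrix(sex == "female", n_snps, n_trios, byrow = TRUE),
                     draw(), NA_integer_))
  colnames(a1) <- colnames(a2) <- c(mo, fa, ch)
  panel <- snp_panel(chrom = "chrX", pos = seq_len(n_snps) * 100L,
                     a1 = a1, a2 = a2,
                     males = c(fa, ch[sex == "male"]))
  trios <- data.frame(trio_id = ch, mother = mo, father = fa, child = ch,
                      child_sex = sex, stringsAsFactors = FALSE)
  list(panel = panel, trios = trios)
}

# independent brute-force oracle for a segment verdict: enumerate which of
# the mother's two haplotypes are consistent with every informative SNP
oracle_segment_verdict <- function(m1, m2, c1, c2, f1, child_sex) {
  votes <- integer(0)
  for (i in seq_along(m1)) {
    if (is.na(m1[i]) || is.na(m2[i]) || m1[i] == m2[i]) next
    # determine the child's maternal allele by enumeration of consistent
    # parental assignments
    cand <- c()
    for (mat in c(m1[i], m2[i])) {
      ok <- if (child_sex == "male") !is.na(c1[i]) && c1[i] == mat
      else {
        if (is.na(c1[i]) || is.na(c2[i])) FALSE
        else if (is.na(f1[i])) {
          # paternal allele unknown: consistent if mat is one of the pair
          mat %in% c(c1[i], c2[i]) &&
            (c1[i] != c2[i] || c1[i] == mat)
        } else sort(c(mat, f1[i])) == sort(c(c1[i], c2[i]))
      }
      if (all(ok)) cand <- c(cand, mat)
    }
    cand <- unique(cand)
    if (length(cand) == 1L) votes <- c(votes, if (cand == m1[i]) 1L else 2L)
  }
  if (!length(votes)) "UNINFORMATIVE"
  else if (all(votes == 1L)) "HAP1"
  else if (all(votes == 2L)) "HAP2"
  else "DISCORDANT"
}

# exhaustive-phase-enumeration oracle for the two-point likelihood:
# sum over every joint phase assignment of all families
oracle_marginal_lik <- function(fam_indicators, theta, prior = c(0.5, 0.5)) {
  prior <- prior / sum(prior)
  nf <- length(fam_indicators)
  grid <- expand.grid(rep(list(1:2), nf))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    p <- 1
    for (f in seq_len(nf)) {
      cons <- fam_indicators[[f]]
      phase <- grid[r, f]
      agree <- if (phase == 1) cons else !cons
      p <- p * prior[phase] *
        prod(ifelse(agree, (1 - theta) / 2, theta / 2))
    }
    total <- total + p
  }
  total
}

# direct hypergeometric enumeration for Fisher's exact test (2x2)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  amin <- max(0, c1 - (n - r1)); amax <- min(r1, c1)
  probs <- dhyper(amin:amax, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}
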