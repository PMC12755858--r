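#' Read a two-generation family X-STR genotype table
#'
#' Tab-separated with header: `family_id`, `member_id`, `role`
#' (`mother`/`father`/`child`), `sex` (`male`/`female` or `1`/`2`), then one
#' column per locus holding `"a"` (hemizygous) or `"a/b"` allele calls;
#' missing genotypes are `"."` or empty. Allele designations are kept as
#' character (STR nomenclature allows non-integer labels such as `"12.3"`).
#'
#' @param path Path to the table.
#' @return A data frame of class `"family_table"`; the locus column names are
#'   in `attr(x, "loci")`.
#' @export
read_family_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", colClasses = "character")
  required <- c("family_id", "member_id", "role", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("family table missing column(s): ", paste(missing_cols, collapse = ", "))
  df$sex <- .norm_sex(df$sex)
  if (any(!df$role %in% c("mother", "father", "child")))
    stop("role must be mother/father/child")
  attr(df, "loci") <- setdiff(names(df), required)
  class(df) <- c("family_table", "data.frame")
  df
}

#' Write a family genotype table
#' @param fam A `"family_table"` data frame.
#' @param path Output path.
#' @export
write_family_table <- function(fam, path) {
  utils::write.table(as.data.frame(fam), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.split_gt <- function(x) {
  # "a/b" -> c(a, b); "a" -> c(a, NA); "." -> c(NA, NA)
  x <- as.character(x)
  if (is.na(x) || x %in% c(".", "", "./.")) return(c(NA_character_, NA_character_))
  p <- strsplit(x, "/", fixed = TRUE)[[1L]]
  if (length(p) == 1L) c(p, NA_character_) else p[1:2]
}

#' Extract maternal meioses for a locus pair from one family
#'
#' For each child, determines the maternally transmitted allele at both loci
#' (sons: their hemizygous allele; daughters: paternal-allele subtraction as
#' in [maternal_allele_of_child()]). A meiosis is informative when the mother
#' is heterozygous at both loci and both transmitted alleles are determined.
#' A transmitted allele absent from the mother's genotype flags the meiosis
#' as a Mendelian inconsistency (possible mutation); it is excluded from
#' estimation and tallied.
#'
#' @param family Rows of a `"family_table"` belonging to one family.
#' @param locus_a,locus_b Locus column names.
#' @return A data frame: `child_id`, `allele_a`, `allele_b`, `informative`,
#'   `mendel`.
#' @export
extract_maternal_meioses <- function(family, locus_a, locus_b) {
  mo <- family[family$role == "mother", , drop = FALSE]
  if (nrow(mo) != 1L) stop("family must contain exactly one mother")
  fa <- family[family$role == "father", , drop = FALSE]
  kids <- family[family$role == "child", , drop = FALSE]
  mA <- .split_gt(mo[[locus_a]]); mB <- .split_gt(mo[[locus_b]])
  fA <- if (nrow(fa)) .split_gt(fa[[locus_a]])[1L] else NA_character_
  fB <- if (nrow(fa)) .split_gt(fa[[locus_b]])[1L] else NA_character_
  het_a <- !anyNA(mA) && mA[1L] != mA[2L]
  het_b <- !anyNA(mB) && mB[1L] != mB[2L]
  one <- function(child_gt, f_allele, sex, m) {
    g <- .split_gt(child_gt)
    if (sex == "male") {
      t <- g[1L]
      if (!is.na(g[2L]) && g[2L] != g[1L]) return(list(NA_character_, TRUE))
    } else {
      if (anyNA(g)) return(list(NA_character_, FALSE))
      if (g[1L] == g[2L]) {
        t <- g[1L]
        if (!is.na(f_allele) && f_allele != t) return(list(NA_character_, TRUE))
      } else if (is.na(f_allele)) {
        return(list(NA_character_, FALSE))
      } else if (f_allele == g[1L]) t <- g[2L]
      else if (f_allele == g[2L]) t <- g[1L]
      else return(list(NA_character_, TRUE))
    }
    if (is.na(t)) return(list(NA_character_, FALSE))
    if (!anyNA(m) && !t %in% m) return(list(t, TRUE))
    list(t, FALSE)
  }
  res <- lapply(seq_len(nrow(kids)), function(i) {
    ra <- one(kids[[locus_a]][i], fA, kids$sex[i], mA)
    rb <- one(kids[[locus_b]][i], fB, kids$sex[i], mB)
    mend <- ra[[2L]] || rb[[2L]]
    inf <- het_a && het_b && !is.na(ra[[1L]]) && !is.na(rb[[1L]]) && !mend
    data.frame(child_id = kids$member_id[i], allele_a = ra[[1L]],
               allele_b = rb[[1L]], informative = inf, mendel = mend,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(child_id = character(), allele_a = character(),
               allele_b = character(), informative = logical(),
               mendel = logical(), stringsAsFactors = FALSE)
  attr(out, "mother_a") <- mA
  attr(out, "mother_b") <- mB
  out
}

# reduce one family's informative meioses to phase-1 consistency indicators:
# TRUE when the transmitted two-locus pair lies on a haplotype of phase
# configuration 1 = (mA1-mB1, mA2-mB2); mother het at both loci guarantees
# the complement is consistency with configuration 2.
.phase1_consistent <- function(meioses) {
  mA <- attr(meioses, "mother_a"); mB <- attr(meioses, "mother_b")
  m <- meioses[meioses$informative, , drop = FALSE]
  if (!nrow(m)) return(logical(0))
  hA <- ifelse(m$allele_a == mA[1L], 1L, 2L)
  m$allele_b == mB[hA]
}

#' Phase-marginalised two-point log-likelihood
#'
#' The likelihood of the recombination fraction for maternal meioses at two
#' X-STR loci when the mother's phase is unknown. Within a family all
#' meioses share the mother's phase, so the family likelihood sums over her
#' two phase configurations, weighting each by its prior and multiplying
#' `(1 - theta)/2` per phase-consistent and `theta/2` per phase-inconsistent
#' transmission; the total is the sum of per-family log marginal likelihoods.
#' Under linkage equilibrium the two configurations' haplotype-frequency
#' products are identical, so the LE prior reduces to the uniform 1/2-1/2
#' default.
#'
#' @param fam_indicators List with one logical vector per family: per
#'   informative meiosis, is the transmission consistent with phase
#'   configuration 1? (From [extract_maternal_meioses()] via the internal
#'   reduction, or constructed directly.)
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @param phase_prior Length-2 prior over the two phase configurations.
#' @return The log-likelihood (natural log).
#' @export
two_point_loglik <- function(fam_indicators, theta,
                             phase_prior = c(0.5, 0.5)) {
  stopifnot(theta >= 0, theta <= 0.5, length(phase_prior) == 2L,
            all(phase_prior >= 0))
  phase_prior <- phase_prior / sum(phase_prior)
  per_fam <- vapply(fam_indicators, function(cons) {
    c1 <- sum(cons); c2 <- length(cons) - c1
    l1 <- phase_prior[1L] * ((1 - theta) / 2)^c1 * (theta / 2)^c2
    l2 <- phase_prior[2L] * ((1 - theta) / 2)^c2 * (theta / 2)^c1
    log(l1 + l2)
  }, numeric(1L))
  sum(per_fam)
}

#' Maximum-likelihood recombination fraction and MLOD score
#'
#' Maximises the phase-marginalised likelihood over `theta` in `[0, 0.5]`
#' (bounded scalar optimisation, tolerance 1e-6, boundary candidates checked
#' explicitly; likelihood ties resolved toward 0.5). The MLOD score is
#' `log10 L(theta_hat) - log10 L(0.5)`, hence non-negative, with 0.5 the
#' free-recombination null; MLOD > 3 is the conventional significance
#' threshold for linkage. The map distance is the Kosambi transform of
#' `theta_hat`.
#'
#' @inheritParams two_point_loglik
#' @return An object of class `"twopoint"`: `theta_hat`, `mlod`,
#'   `kosambi_cm` (`NA` at `theta_hat = 0.5`), `n_informative`, `n_families`.
#'   With no informative meioses, `theta_hat` is `NA` and `mlod` 0.
#' @export
estimate_theta_mlod <- function(fam_indicators, phase_prior = c(0.5, 0.5)) {
  fam_indicators <- fam_indicators[lengths(fam_indicators) > 0L]
  n_inf <- sum(lengths(fam_indicators))
  if (n_inf == 0L) {
    out <- list(theta_hat = NA_real_, mlod = 0, kosambi_cm = NA_real_,
                n_informative = 0L, n_families = 0L)
    class(out) <- "twopoint"
    return(out)
  }
  f <- function(th) two_point_loglik(fam_indicators, th, phase_prior)
  opt <- stats::optimize(f, c(0, 0.5), maximum = TRUE, tol = 1e-6)
  cand_th <- c(opt$maximum, 0, 0.5)
  cand_ll <- c(opt$objective, f(0), f(0.5))
  # resolve ties (within optimiser tolerance) toward 0.5: conservative
  best_ll <- max(cand_ll)
  ok <- cand_ll >= best_ll - 1e-9
  theta_hat <- max(cand_th[ok])
  ll_half <- cand_ll[3L]
  mlod <- max(0, (f(theta_hat) - ll_half) / log(10))
  out <- list(theta_hat = theta_hat, mlod = mlod,
              kosambi_cm = kosambi_map(theta_hat),
              n_informative = n_inf, n_families = length(fam_indicators))
  class(out) <- "twopoint"
  out
}

#' @export
print.twopoint <- function(x, ...) {
  cat("Two-point X-STR linkage (phase-marginalised ML)\n")
  cat(sprintf("  theta_hat = %s, MLOD = %.4f, Kosambi d = %s cM  (n = %d informative meioses, %d families)\n",
              if (is.na(x$theta_hat)) "NA" else sprintf("%.4f", x$theta_hat),
              x$mlod,
              if (is.na(x$kosambi_cm)) "NA" else sprintf("%.3f", x$kosambi_cm),
              x$n_informative, x$n_families))
  invisible(x)
}

#' @export
coef.twopoint <- function(object, ...) {
  c(theta = object$theta_hat, mlod = object$mlod)
}

#' Two-point analysis of a locus pair over a set of families
#'
#' Extracts maternal meioses from every family, reduces them to shared-phase
#' consistency indicators, and runs [estimate_theta_mlod()].
#'
#' @param families A `"family_table"`.
#' @param locus_a,locus_b Locus column names.
#' @param phase_prior Prior over the mother's two phase configurations.
#' @return A `"twopoint"` object, with the meiosis QC tally in
#'   `attr(, "n_mendel")`.
#' @export
xstr_twopoint <- function(families, locus_a, locus_b,
                          phase_prior = c(0.5, 0.5)) {
  fams <- split(seq_len(nrow(families)), families$family_id)
  mend <- 0L
  ind <- lapply(fams, function(ix) {
    m <- extract_maternal_meioses(families[ix, , drop = FALSE],
                                  locus_a, locus_b)
    mend <<- mend + sum(m$mendel)
    .phase1_consistent(m)
  })
  res <- estimate_theta_mlod(ind, phase_prior)
  attr(res, "n_mendel") <- mend
  res
}

#' Family-based recombination fraction with exact CI
#'
#' The recombination fraction Rc between two X-STR loci from two-generation
#' family data: the phase-marginalised ML estimate, with an exact binomial
#' interval on `(round(theta_hat * n), n)` informative meioses. When one
#' phase configuration's prior weight exceeds 0.99 the phase is treated as
#' known and the recombinant count is the direct tally against that phase.
#'
#' @inheritParams xstr_twopoint
#' @param alpha CI error rate.
#' @return A list of class `"pair_recomb"` (see [pair_recombination()]) with
#'   the `"twopoint"` fit in `$twopoint`.
#' @export
family_recomb_fraction <- function(families, locus_a, locus_b,
                                   phase_prior = c(0.5, 0.5), alpha = 0.05) {
  tp <- xstr_twopoint(families, locus_a, locus_b, phase_prior)
  n <- tp$n_informative
  pp <- phase_prior / sum(phase_prior)
  k <- if (n == 0L) 0L else if (max(pp) > 0.99) {
    fams <- split(seq_len(nrow(families)), families$family_id)
    known <- which.max(pp)
    sum(vapply(fams, function(ix) {
      cons <- .phase1_consistent(
        extract_maternal_meioses(families[ix, , drop = FALSE],
                                 locus_a, locus_b))
      if (known == 1L) sum(!cons) else sum(cons)
    }, numeric(1L)))
  } else as.integer(round(tp$theta_hat * n))
  ci <- clopper_pearson(k, n, alpha)
  out <- list(k_recomb = k, n_informative = n,
              fraction = if (n > 0) tp$theta_hat else NA_real_,
              ci_low = ci$low, ci_high = ci$high, alpha = alpha,
              n_excluded = attr(tp, "n_mendel"), n_uninformative = NA_integer_,
              n_total = n, twopoint = tp)
  class(out) <- "pair_recomb"
  out
}

#' Scan all adjacent locus pairs of a family table
#'
#' Runs [xstr_twopoint()] on every adjacent pair of the given locus order
#' (by default the column order of the table) and returns the two-point
#' report used to judge within- versus between-group linkage.
#'
#' @param families A `"family_table"`.
#' @param loci Character vector of locus names in chromosomal order.
#' @param phase_prior Prior over phase configurations.
#' @return A data frame: `pair`, `theta_hat`, `mlod`, `kosambi_cm`,
#'   `n_informative`.
#' @export
twopoint_scan <- function(families, loci = attr(families, "loci"),
                          phase_prior = c(0.5, 0.5)) {
  stopifnot(length(loci) >= 2L)
  rows <- lapply(seq_len(length(loci) - 1L), function(i) {
    tp <- xstr_twopoint(families, loci[i], loci[i + 1L], phase_prior)
    data.frame(pair = paste0(loci[i], "-", loci[i + 1L]),
               theta_hat = tp$theta_hat, mlod = tp$mlod,
               kosambi_cm = tp$kosambi_cm, n_informative = tp$n_informative,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kosambi mapping function
#'
#' Converts a recombination fraction to genetic map distance,
#' `d = 25 * ln((1 + 2 theta) / (1 - 2 theta))` centiMorgans, and back.
#' The Kosambi map accounts for crossover interference implicitly;
#' `theta = 0.5` maps to infinite distance (returned as `NA`).
#'
#' @param theta Recombination fraction(s) in `[0, 0.5]`.
#' @return `kosambi_map`: map distance in cM (`NA` at `theta = 0.5`).
#' @export
kosambi_map <- function(theta) {
  stopifnot(all(theta >= 0 & theta <= 0.5))
  out <- 25 * log((1 + 2 * theta) / (1 - 2 * theta))
  out[theta == 0.5] <- NA_real_
  out
}

#' @rdname kosambi_map
#' @param cm Map distance(s) in centiMorgans.
#' @return `kosambi_theta`: recombination fraction in `[0, 0.5)`.
#' @export
kosambi_theta <- function(cm) {
  stopifnot(all(cm >= 0))
  0.5 * tanh(2 * cm / 100)
}

#' Write the two-point linkage report
#' @param scan Data frame from [twopoint_scan()].
#' @param path Output path (tab-separated).
#' @export
write_twopoint_report <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
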