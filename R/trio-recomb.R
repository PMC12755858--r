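#' Select informative SNPs for a flanking segment
#'
#' Restricts a panel to the biallelic SNPs inside a window whose cohort minor
#' allele frequency reaches `maf_min`. High-MAF sites are the ones likely to
#' be heterozygous in a given mother and thus informative for transmission
#' tracing; the trio pipeline defaults to `maf_min = 0.2`.
#'
#' @param panel A `"snp_panel"`.
#' @param chrom Chromosome label of the window.
#' @param window Integer `c(lo, hi)`, 1-based inclusive.
#' @param maf_min Minimum minor allele frequency (sites with `NA` MAF drop).
#' @return The subset `"snp_panel"` (possibly with zero sites), site order
#'   preserved.
#' @export
select_informative_snps <- function(panel, chrom, window, maf_min = 0.2) {
  idx <- .sites_in_window(panel, chrom, window[1L], window[2L])
  idx <- idx[!is.na(panel$sites$maf[idx]) & panel$sites$maf[idx] >= maf_min]
  .subset_sites(panel, idx)
}

.subset_sites <- function(panel, idx) {
  panel$sites <- panel$sites[idx, , drop = FALSE]
  rownames(panel$sites) <- NULL
  for (f in c("a1", "a2", "phased", "usable", "male_het"))
    panel[[f]] <- panel[[f]][idx, , drop = FALSE]
  panel
}

#' Maternal allele transmitted to a child at a SNP
#'
#' Determines, per site, which allele the child received from its mother.
#' Sons are hemizygous, so their single X allele is maternal by definition.
#' A homozygous daughter's maternal allele is her only allele. A heterozygous
#' daughter's maternal allele is obtained by subtracting the father's
#' hemizygous allele from her pair; with the father missing it is
#' undetermined. A configuration admitting no consistent parental assignment
#' (e.g. daughter homozygous for an allele the father does not carry, or a
#' child allele absent from the mother) is a Mendelian error.
#'
#' All genotype arguments are integer allele-index vectors over the same
#' sites; `NA` means missing.
#'
#' @param m1,m2 Mother's phased alleles (haplotype 1, haplotype 2).
#' @param c1,c2 Child's alleles (`c2` ignored/`NA` for sons).
#' @param f1 Father's hemizygous allele (`NULL` or `NA` when absent).
#' @param child_sex `"male"` or `"female"`.
#' @return A list with integer vector `allele` (`NA` when not determined) and
#'   character vector `status` in `"determined"`, `"undetermined"`,
#'   `"mendelian_error"`.
#' @export
maternal_allele_of_child <- function(m1, m2, c1, c2 = NULL, f1 = NULL,
                                     child_sex) {
  n <- length(c1)
  if (is.null(c2)) c2 <- rep(NA_integer_, n)
  if (is.null(f1)) f1 <- rep(NA_integer_, n)
  allele <- rep(NA_integer_, n)
  status <- rep("undetermined", n)
  mother_known <- !is.na(m1) & !is.na(m2)
  if (child_sex == "male") {
    det <- !is.na(c1)
    allele[det] <- c1[det]
    status[det] <- "determined"
    bad <- det & mother_known & c1 != m1 & c1 != m2
    status[bad] <- "mendelian_error"; allele[bad] <- NA_integer_
  } else {
    both <- !is.na(c1) & !is.na(c2)
    hom <- both & c1 == c2
    allele[hom] <- c1[hom]; status[hom] <- "determined"
    # homozygous daughter: paternal allele must equal hers
    badp <- hom & !is.na(f1) & f1 != c1
    het <- both & c1 != c2
    fa <- het & !is.na(f1) & f1 == c1   # father's allele is c1 -> maternal c2
    fb <- het & !is.na(f1) & f1 == c2
    allele[fa] <- c2[fa]; status[fa] <- "determined"
    allele[fb] <- c1[fb]; status[fb] <- "determined"
    badf <- het & !is.na(f1) & f1 != c1 & f1 != c2
    badm <- status == "determined" & mother_known &
      allele != m1 & allele != m2
    bad <- badp | badf | badm
    status[bad] <- "mendelian_error"; allele[bad] <- NA_integer_
  }
  list(allele = allele, status = status)
}

#' Haplotype-of-origin call for one flanking segment
#'
#' Votes each informative SNP in the segment: a SNP is informative when the
#' mother is heterozygous (with known phase) and the child's maternal allele
#' is determined. A vote is `HAP1` when the transmitted allele matches the
#' mother's first phased allele, `HAP2` otherwise. At least one informative
#' SNP is required; unanimous votes give the corresponding verdict, zero
#' votes give `UNINFORMATIVE`, and conflicting votes give `DISCORDANT`
#' (under the default unanimity rule; `conflict = "majority"` instead takes a
#' strict majority, still `DISCORDANT` on a tie). Mendelian-error sites are
#' dropped from voting and tallied.
#'
#' @inheritParams maternal_allele_of_child
#' @param mother_usable Logical vector: mother's genotype usable (phased when
#'   heterozygous). Defaults to all `TRUE`.
#' @param conflict `"unanimous"` (default, conservative) or `"majority"`.
#' @return A list of class `"segment_call"`: `verdict` in `"HAP1"`, `"HAP2"`,
#'   `"UNINFORMATIVE"`, `"DISCORDANT"`; `n_informative_snps`;
#'   `n_conflicting_snps` (votes for the minority haplotype); `n_mendel`.
#' @export
call_segment_origin <- function(m1, m2, c1, c2 = NULL, f1 = NULL, child_sex,
                                mother_usable = NULL,
                                conflict = c("unanimous", "majority")) {
  conflict <- match.arg(conflict)
  if (is.null(mother_usable)) mother_usable <- rep(TRUE, length(m1))
  ma <- maternal_allele_of_child(m1, m2, c1, c2, f1, child_sex)
  n_mendel <- sum(ma$status == "mendelian_error")
  het <- !is.na(m1) & !is.na(m2) & m1 != m2 & mother_usable
  vote_ok <- het & ma$status == "determined"
  votes <- ifelse(ma$allele[vote_ok] == m1[vote_ok], 1L, 2L)
  n1 <- sum(votes == 1L); n2 <- sum(votes == 2L)
  verdict <- if (n1 + n2 == 0L) "UNINFORMATIVE"
  else if (conflict == "unanimous") {
    if (n1 > 0L && n2 > 0L) "DISCORDANT" else if (n1 > 0L) "HAP1" else "HAP2"
  } else {
    if (n1 > n2) "HAP1" else if (n2 > n1) "HAP2" else "DISCORDANT"
  }
  structure(list(verdict = verdict, n_informative_snps = n1 + n2,
                 n_conflicting_snps = min(n1, n2), n_mendel = n_mendel),
            class = "segment_call")
}

#' Combine upstream and downstream segment calls into a region verdict
#'
#' The region harbouring a target locus is assigned a maternal haplotype only
#' when its upstream and downstream flanking segments were synchronously
#' transmitted from the same maternal haplotype. Segments naming different
#' haplotypes indicate a crossover within the region spanning the locus, so
#' the locus's own phase is ambiguous and the trio is conservatively
#' `EXCLUDED` (likewise when either segment is internally `DISCORDANT`).
#' Otherwise, with at least one uninformative segment, the region is
#' `UNINFORMATIVE`.
#'
#' @param up,down Segment verdict strings (vectorised), from
#'   [call_segment_origin()].
#' @return Character vector of region verdicts: `"HAP1"`, `"HAP2"`,
#'   `"UNINFORMATIVE"`, `"EXCLUDED"`.
#' @export
call_region_origin <- function(up, down) {
  if (inherits(up, "segment_call")) up <- up$verdict
  if (inherits(down, "segment_call")) down <- down$verdict
  out <- rep("UNINFORMATIVE", length(up))
  out[up == "DISCORDANT" | down == "DISCORDANT"] <- "EXCLUDED"
  hap <- up %in% c("HAP1", "HAP2") & down %in% c("HAP1", "HAP2")
  out[hap & up == down] <- up[hap & up == down]
  out[hap & up != down] <- "EXCLUDED"
  out
}

#' Recombination fraction between two loci from per-trio region calls
#'
#' A trio is informative for a locus pair when both loci received a definite
#' haplotype verdict (`HAP1`/`HAP2`); it is recombinant when the two verdicts
#' name different maternal haplotypes. The fraction `k/n` with its exact
#' Clopper-Pearson interval is the between-locus recombination estimate.
#'
#' @param calls_a,calls_b Character vectors of region verdicts for the two
#'   loci, aligned by trio (same order, or both named by trio id).
#' @param alpha CI error rate.
#' @return A list of class `"pair_recomb"`: `k_recomb`, `n_informative`,
#'   `fraction` (`NA` when `n = 0`), `ci_low`, `ci_high`, `n_excluded`
#'   (trios with either locus `EXCLUDED`), `n_uninformative`, `n_total`.
#' @export
pair_recombination <- function(calls_a, calls_b, alpha = 0.05) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b)))
    calls_b <- calls_b[names(calls_a)]
  stopifnot(length(calls_a) == length(calls_b))
  def_a <- calls_a %in% c("HAP1", "HAP2")
  def_b <- calls_b %in% c("HAP1", "HAP2")
  informative <- def_a & def_b
  n <- sum(informative)
  k <- sum(informative & calls_a != calls_b)
  excl <- !informative & (calls_a == "EXCLUDED" | calls_b == "EXCLUDED")
  ci <- clopper_pearson(k, n, alpha)
  structure(list(k_recomb = k, n_informative = n,
                 fraction = if (n > 0) k / n else NA_real_,
                 ci_low = ci$low, ci_high = ci$high, alpha = alpha,
                 n_excluded = sum(excl),
                 n_uninformative = sum(!informative & !excl),
                 n_total = length(calls_a)),
            class = "pair_recomb")
}

#' @export
print.pair_recomb <- function(x, ...) {
  cat(sprintf("recombinants k/n = %d/%d = %s%%,  %g%% CI [%s%%, %s%%]\n",
              x$k_recomb, x$n_informative,
              if (is.na(x$fraction)) "NA" else sprintf("%.2f", 100 * x$fraction),
              100 * (1 - x$alpha),
              if (is.na(x$ci_low)) "NA" else sprintf("%.2f", 100 * x$ci_low),
              if (is.na(x$ci_high)) "NA" else sprintf("%.2f", 100 * x$ci_high)))
  invisible(x)
}

#' Trio-based recombination analysis of target loci from phased SNPs
#'
#' The full SNP-trio pipeline: for every trio and every target locus, call
#' the maternal haplotype-of-origin of the chromosomal region harbouring the
#' locus from the phased SNPs in its upstream and downstream flanking
#' windows, then estimate recombination fractions between the junction loci
#' of adjacent linkage groups (and, optionally, between adjacent loci within
#' groups). Trios whose Mendelian-error rate across assessed sites exceeds
#' `mendel_max` are excluded wholesale.
#'
#' @param panel A `"snp_panel"` (from [read_phased_vcf()] or the simulator),
#'   or a path to a VCF file.
#' @param ped A `"pedigree"` (from [read_ped()]) or a path to a PED file.
#' @param markers A `"marker_table"` or a path to a marker table file.
#' @param window_bp Flanking-window size in bp on each side of a locus
#'   (loci with their own `window_bp` column value keep it).
#' @param maf_min Minimum cohort MAF for a SNP to enter voting.
#' @param alpha CI error rate for the recombination fractions.
#' @param within Also analyse within-group adjacent pairs?
#' @param conflict Segment conflict rule, see [call_segment_origin()].
#' @param mendel_max Maximum tolerated per-trio Mendelian-error rate.
#' @return An object of class `"trio_recomb"` with components `calls`
#'   (data frame: `trio`, `locus`, `up_verdict`, `down_verdict`, `verdict`,
#'   `n_snps_up`, `n_snps_down`), `pairs` (data frame: `pair`, `k_recomb`,
#'   `n_informative`, `fraction_pct`, `ci_low_pct`, `ci_high_pct`, plus
#'   bookkeeping columns), `qc` (per-trio Mendelian tallies and exclusions)
#'   and `params`. Methods: `print`, `summary`, `coef`.
#' @export
trio_recomb <- function(panel, ped, markers, window_bp = 10000L,
                        maf_min = 0.2, alpha = 0.05, within = FALSE,
                        conflict = c("unanimous", "majority"),
                        mendel_max = 0.1) {
  conflict <- match.arg(conflict)
  if (is.character(markers)) markers <- read_marker_table(markers, window_bp)
  if (is.character(ped)) ped <- read_ped(ped)
  trios <- trios_from_ped(ped)
  if (is.character(panel)) {
    males <- ped$sample_id[ped$sex == "male"]
    need <- unique(stats::na.omit(c(trios$mother, trios$father, trios$child)))
    panel <- read_phased_vcf(panel, samples = need, males = males)
  }
  missing_s <- setdiff(stats::na.omit(c(trios$mother, trios$father, trios$child)),
                       panel$samples)
  if (length(missing_s))
    stop("sample id(s) not in panel: ", paste(missing_s, collapse = ", "))

  w <- ifelse(is.na(markers$window_bp), window_bp, markers$window_bp)
  maf_ok <- !is.na(panel$sites$maf) & panel$sites$maf >= maf_min
  n_trio <- nrow(trios); n_loc <- nrow(markers)
  seg_idx <- lapply(seq_len(n_loc), function(l) {
    win <- marker_windows(markers$start[l], markers$end[l], w[l])
    list(up = .sites_in_window(panel, markers$chrom[l], win$up[1L], win$up[2L]),
         down = .sites_in_window(panel, markers$chrom[l], win$down[1L],
                                 win$down[2L]))
  })
  seg_idx <- lapply(seg_idx, lapply, function(ix) ix[maf_ok[ix]])

  up_v <- down_v <- matrix("UNINFORMATIVE", n_trio, n_loc)
  n_up <- n_down <- matrix(0L, n_trio, n_loc)
  mendel <- assessed <- integer(n_trio)
  for (t in seq_len(n_trio)) {
    mo <- trios$mother[t]; ch <- trios$child[t]; fa <- trios$father[t]
    sex <- trios$child_sex[t]
    has_f <- !is.na(fa)
    for (l in seq_len(n_loc)) {
      for (side in c("up", "down")) {
        ix <- seg_idx[[l]][[side]]
        sc <- call_segment_origin(
          m1 = panel$a1[ix, mo], m2 = panel$a2[ix, mo],
          c1 = panel$a1[ix, ch], c2 = panel$a2[ix, ch],
          f1 = if (has_f) panel$a1[ix, fa] else NULL,
          child_sex = sex,
          mother_usable = panel$usable[ix, mo],
          conflict = conflict)
        if (side == "up") {
          up_v[t, l] <- sc$verdict; n_up[t, l] <- sc$n_informative_snps
        } else {
          down_v[t, l] <- sc$verdict; n_down[t, l] <- sc$n_informative_snps
        }
        mendel[t] <- mendel[t] + sc$n_mendel
        assessed[t] <- assessed[t] + length(ix)
      }
    }
  }
  verdict <- matrix(call_region_origin(up_v, down_v), n_trio, n_loc)
  mendel_rate <- ifelse(assessed > 0, mendel / assessed, 0)
  trio_excluded <- mendel_rate > mendel_max
  verdict[trio_excluded, ] <- "EXCLUDED"

  calls <- data.frame(
    trio = rep(trios$trio_id, n_loc),
    locus = rep(markers$name, each = n_trio),
    up_verdict = as.vector(up_v), down_verdict = as.vector(down_v),
    verdict = as.vector(verdict),
    n_snps_up = as.vector(n_up), n_snps_down = as.vector(n_down),
    stringsAsFactors = FALSE)

  jp <- junction_pairs(markers, within = within)
  colnames(verdict) <- markers$name
  rownames(verdict) <- trios$trio_id
  pair_rows <- lapply(seq_len(nrow(jp)), function(i) {
    pr <- pair_recombination(verdict[, jp$locus_a[i]], verdict[, jp$locus_b[i]],
                             alpha)
    data.frame(pair = paste0(jp$locus_a[i], "-", jp$locus_b[i]),
               group_pair = if (jp$type[i] == "between")
                 paste0(jp$group_a[i], "-", jp$group_b[i]) else jp$group_a[i],
               type = jp$type[i],
               k_recomb = pr$k_recomb, n_informative = pr$n_informative,
               fraction_pct = 100 * pr$fraction,
               ci_low_pct = 100 * pr$ci_low, ci_high_pct = 100 * pr$ci_high,
               n_excluded = pr$n_excluded,
               n_uninformative = pr$n_uninformative,
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(pair = character(), group_pair = character(), type = character(),
               k_recomb = integer(), n_informative = integer(),
               fraction_pct = numeric(), ci_low_pct = numeric(),
               ci_high_pct = numeric(), n_excluded = integer(),
               n_uninformative = integer(), stringsAsFactors = FALSE)

  out <- list(calls = calls, pairs = pairs, verdicts = verdict,
              qc = data.frame(trio = trios$trio_id, n_mendel = mendel,
                              n_sites_assessed = assessed,
                              excluded = trio_excluded,
                              stringsAsFactors = FALSE),
              params = list(window_bp = window_bp, maf_min = maf_min,
                            alpha = alpha, within = within,
                            conflict = conflict, mendel_max = mendel_max,
                            n_trios = n_trio, n_loci = n_loc))
  class(out) <- "trio_recomb"
  out
}

#' @export
print.trio_recomb <- function(x, ...) {
  cat(sprintf("Trio-based X recombination analysis: %d trios x %d loci\n",
              x$params$n_trios, x$params$n_loci))
  cat(sprintf("  window %d bp each side, MAF >= %g, %s voting\n",
              x$params$window_bp, x$params$maf_min, x$params$conflict))
  if (any(x$qc$excluded))
    cat(sprintf("  %d trio(s) excluded for Mendelian-error rate > %g\n",
                sum(x$qc$excluded), x$params$mendel_max))
  if (nrow(x$pairs)) {
    cat("Pair recombination fractions:\n")
    print(x$pairs[, c("pair", "k_recomb", "n_informative", "fraction_pct",
                      "ci_low_pct", "ci_high_pct")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.trio_recomb <- function(object, ...) {
  v <- object$calls$verdict
  cat("Region-origin verdicts across trio x locus calls:\n")
  print(table(factor(v, levels = c("HAP1", "HAP2", "UNINFORMATIVE",
                                   "EXCLUDED"))))
  print(object)
  invisible(object)
}

#' @export
coef.trio_recomb <- function(object, ...) {
  stats::setNames(object$pairs$fraction_pct / 100, object$pairs$pair)
}

#' Write the pair-level recombination report
#'
#' Tab-separated report with the exact columns `pair`, `k_recomb`,
#' `n_informative`, `fraction_pct`, `ci_low_pct`, `ci_high_pct`, preceded by
#' `#`-prefixed header lines recording the parameter set (window size, MAF
#' threshold, alpha, exclusion counts) so a result is reproducible from the
#' report alone.
#'
#' @param fit A `"trio_recomb"` object.
#' @param path Output path.
#' @export
write_pair_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- fit$params
  writeLines(sprintf("# window_bp=%d maf_min=%g alpha=%g conflict=%s n_trios=%d n_trios_excluded=%d",
                     p$window_bp, p$maf_min, p$alpha, p$conflict, p$n_trios,
                     sum(fit$qc$excluded)), con)
  df <- fit$pairs[, c("pair", "k_recomb", "n_informative", "fraction_pct",
                      "ci_low_pct", "ci_high_pct")]
  df$fraction_pct <- round(df$fraction_pct, 2)
  df$ci_low_pct <- round(df$ci_low_pct, 2)
  df$ci_high_pct <- round(df$ci_high_pct, 2)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-trio, per-locus call table
#' @param fit A `"trio_recomb"` object.
#' @param path Output path.
#' @export
write_call_table <- function(fit, path) {
  utils::write.table(fit$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
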