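#' Pairwise linkage disequilibrium between two sites on phased haplotypes
#'
#' Computes the classical haplotype-based LD statistics for two biallelic
#' sites: `D = p_AB - p_A p_B`, the normalised `|D'| = |D| / D_max`, and the
#' squared allelic correlation `r2 = D^2 / (p_A q_A p_B q_B)`. `D_max` is
#' `min(p_A (1 - p_B), (1 - p_A) p_B)` for positive `D` and
#' `min(p_A p_B, (1 - p_A)(1 - p_B))` otherwise.
#'
#' @param hap_a,hap_b Equal-length 0/1 vectors: the allele carried by each
#'   haplotype at the two sites (length >= 2).
#' @return A list of class `"ld_pair"`: `d`, `d_prime`, `r2`, `p_a`, `p_b`,
#'   `n`, `defined`. Monomorphic sites give `defined = FALSE` with `NA`
#'   statistics (such pairs are excluded from decay curves).
#' @export
pairwise_ld <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b), length(hap_a) >= 2L)
  keep <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[keep]; b <- hap_b[keep]
  n <- length(a)
  pa <- mean(a); pb <- mean(b)
  if (n < 2L || pa %in% c(0, 1) || pb %in% c(0, 1)) {
    out <- list(d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                p_a = pa, p_b = pb, n = n, defined = FALSE)
    class(out) <- "ld_pair"
    return(out)
  }
  pab <- mean(a == 1 & b == 1)
  d <- pab - pa * pb
  dmax <- if (d > 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  d_prime <- if (dmax == 0) NA_real_ else abs(d) / dmax
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  out <- list(d = d, d_prime = d_prime, r2 = r2, p_a = pa, p_b = pb, n = n,
              defined = TRUE)
  class(out) <- "ld_pair"
  out
}

#' @export
print.ld_pair <- function(x, digits = 4, ...) {
  if (!x$defined) cat("LD undefined (monomorphic site)\n")
  else cat(sprintf("D = %s, |D'| = %s, r2 = %s  (n = %d haplotypes)\n",
                   format(x$d, digits = digits),
                   format(x$d_prime, digits = digits),
                   format(x$r2, digits = digits), x$n))
  invisible(x)
}

#' Distance-binned LD decay curve
#'
#' For every site pair within `max_dist` whose minor allele frequencies both
#' reach `maf_min`, computes `r2` and assigns it to a half-open distance bin
#' `[k w, (k+1) w)`. Reports the per-bin mean `r2` and pair count, and the
#' distance at which LD has decayed to a threshold: the midpoint of the first
#' bin whose mean `r2` falls to or below the threshold (no interpolation).
#'
#' @param haplotypes Matrix of 0/1 alleles, sites in rows, haplotypes in
#'   columns (or a `"snp_panel"`, whose haplotype columns are taken from all
#'   non-missing allele copies).
#' @param positions bp positions per site, ascending (taken from the panel
#'   when a `"snp_panel"` is given).
#' @param maf_min Minimum MAF per site (default 0.05, the usual decay-curve
#'   filter).
#' @param max_dist Maximum pair distance in bp.
#' @param bin_width Bin width in bp.
#' @param threshold Decay threshold on mean `r2` (default 0.1).
#' @return An object of class `"ld_decay"`: data frame `curve` (`bin_start`,
#'   `bin_end`, `mean_r2`, `n_pairs`), `crossing_bp` (bin midpoint, `NA` when
#'   never reached), `n_pairs_total`, and the parameters.
#' @export
ld_decay <- function(haplotypes, positions = NULL, maf_min = 0.05,
                     max_dist = 300000L, bin_width = 500L, threshold = 0.1) {
  if (inherits(haplotypes, "snp_panel")) {
    panel <- haplotypes
    positions <- panel$sites$pos
    haplotypes <- cbind(panel$a1, panel$a2)
  }
  stopifnot(nrow(haplotypes) == length(positions),
            !is.unsorted(positions))
  f <- rowMeans(haplotypes, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  keep <- which(!is.na(maf) & maf >= maf_min)
  nb <- as.integer(ceiling(max_dist / bin_width))
  sums <- numeric(nb); counts <- integer(nb)
  if (length(keep) >= 2L) {
    for (ii in seq_len(length(keep) - 1L)) {
      i <- keep[ii]
      js <- keep[keep > i & positions[keep] - positions[i] <= max_dist]
      for (j in js) {
        ld <- pairwise_ld(haplotypes[i, ], haplotypes[j, ])
        if (!ld$defined) next
        bin <- as.integer((positions[j] - positions[i]) %/% bin_width) + 1L
        if (bin >= 1L && bin <= nb) {
          sums[bin] <- sums[bin] + ld$r2
          counts[bin] <- counts[bin] + 1L
        }
      }
    }
  }
  curve <- data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
                      bin_end = seq_len(nb) * bin_width,
                      mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
                      n_pairs = counts)
  curve <- curve[curve$n_pairs > 0L, , drop = FALSE]
  rownames(curve) <- NULL
  hit <- which(curve$mean_r2 <= threshold)
  crossing <- if (length(hit))
    (curve$bin_start[hit[1L]] + curve$bin_end[hit[1L]]) / 2 else NA_real_
  out <- list(curve = curve, crossing_bp = crossing,
              n_pairs_total = sum(counts),
              params = list(maf_min = maf_min, max_dist = max_dist,
                            bin_width = bin_width, threshold = threshold))
  class(out) <- "ld_decay"
  out
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay: %d pair(s) in %d occupied bin(s) (width %d bp)\n",
              x$n_pairs_total, nrow(x$curve), x$params$bin_width))
  cat(sprintf("  mean r2 reaches <= %g at ~%s bp\n", x$params$threshold,
              if (is.na(x$crossing_bp)) "NA" else format(x$crossing_bp)))
  invisible(x)
}

#' @export
plot.ld_decay <- function(x, ...) {
  mid <- (x$curve$bin_start + x$curve$bin_end) / 2
  plot(mid / 1000, x$curve$mean_r2, type = "b", pch = 16, cex = 0.6,
       xlab = "inter-marker distance (kb)", ylab = expression(mean ~ r^2), ...)
  graphics::abline(h = x$params$threshold, lty = 2)
  if (!is.na(x$crossing_bp))
    graphics::abline(v = x$crossing_bp / 1000, lty = 3)
  invisible(x)
}

#' Write the LD decay curve report
#'
#' Tab-separated `bin_start`, `bin_end`, `mean_r2`, `n_pairs`, preceded by a
#' `#` summary line with the parameters and the threshold-crossing distance.
#'
#' @param decay An `"ld_decay"` object.
#' @param path Output path.
#' @export
write_ld_report <- function(decay, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- decay$params
  writeLines(sprintf("# maf_min=%g max_dist=%d bin_width=%d threshold=%g crossing_bp=%s",
                     p$maf_min, p$max_dist, p$bin_width, p$threshold,
                     if (is.na(decay$crossing_bp)) "NA"
                     else format(decay$crossing_bp)), con)
  utils::write.table(decay$curve, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
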