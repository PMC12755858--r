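#' Read phased biallelic SNPs from a VCF into an allele-matrix panel
#'
#' Reads a VCF 4.x file (via vcfR), keeps biallelic SNVs, optionally restricts
#' to a region and a sample subset, and returns the genotypes as a pair of
#' allele-index matrices suitable for transmission tracing. Phase is taken
#' from the GT separator: `a|b` is phased with the first allele on haplotype
#' 1. Unphased heterozygous diploid calls are kept but flagged unusable for
#' origin calling. Samples listed in `males` are hemizygous on X: haploid
#' calls (`"1"`) and homozygous diploid codings (`"1|1"`, `"1/1"`) are both
#' accepted and normalised to a single allele; a heterozygous diploid call in
#' a male is flagged as a Mendelian inconsistency at that site and never used.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param region Optional `"chrom:start-end"` string (1-based inclusive).
#' @param samples Optional character vector of sample ids to keep (order
#'   preserved). An id absent from the VCF is an error naming the sample.
#' @param males Character vector of sample ids to treat as hemizygous males.
#' @return An object of class `"snp_panel"`: a list with `sites` (data frame
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `maf`), matrices `a1`, `a2` (integer
#'   allele indices, `a2` is `NA` for hemizygous or missing calls), logical
#'   matrices `phased`, `usable`, `male_het`, and the `samples` / `males`
#'   character vectors. `maf` is recomputed from the allele counts of the
#'   panel itself (all non-missing allele copies), not read from INFO.
#' @export
read_phased_vcf <- function(path, region = NULL, samples = NULL,
                            males = character()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- if (nrow(fix) && ncol(vcf@gt) > 1L)
    vcfR::extract.gt(vcf, element = "GT") else
    matrix(character(), nrow = nrow(fix), ncol = 0L)
  vcf_samples <- colnames(gt_raw)
  if (is.null(samples)) samples <- vcf_samples
  missing_s <- setdiff(samples, vcf_samples)
  if (length(missing_s))
    stop("sample id(s) not in VCF: ", paste(missing_s, collapse = ", "))
  keep <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"]) &
    fix[, "ALT"] != "." & nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  if (!is.null(region)) {
    reg <- .parse_region(region)
    keep <- keep & fix[, "CHROM"] == reg$chrom &
      as.integer(fix[, "POS"]) >= reg$start &
      as.integer(fix[, "POS"]) <= reg$end
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt_raw[keep, samples, drop = FALSE]
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      id = as.character(fix[, "ID"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"]),
                      maf = rep(NA_real_, nrow(fix)), stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]; rownames(sites) <- NULL
  gt <- gt[ord, , drop = FALSE]
  panel <- .parse_gt_matrix(gt, samples, males)
  panel$sites <- sites
  panel <- recompute_maf(panel)
  class(panel) <- "snp_panel"
  panel
}

.parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must be 'chrom:start-end', got: ", region)
  list(chrom = m[2L], start = as.integer(m[3L]), end = as.integer(m[4L]))
}

.parse_gt_matrix <- function(gt, samples, males) {
  dims <- dim(gt)
  gt <- sub(":.*$", "", as.character(gt))
  diploid <- grepl("[|/]", gt)
  phased <- grepl("|", gt, fixed = TRUE) | !diploid  # haploid calls are phased
  al1 <- ifelse(diploid, sub("^([^|/]*)[|/].*$", "\\1", gt), gt)
  al2 <- ifelse(diploid, sub("^[^|/]*[|/](.*)$", "\\1", gt), NA_character_)
  to_int <- function(x) suppressWarnings(as.integer(ifelse(x %in% c(".", ""), NA, x)))
  a1 <- matrix(to_int(al1), dims[1L], dims[2L])
  a2 <- matrix(to_int(al2), dims[1L], dims[2L])
  phased <- matrix(phased, dims[1L], dims[2L])
  male_het <- matrix(FALSE, dims[1L], dims[2L])
  is_male <- samples %in% males
  if (any(is_male) && dims[1L]) {
    mh <- !is.na(a1[, is_male, drop = FALSE]) &
      !is.na(a2[, is_male, drop = FALSE]) &
      a1[, is_male, drop = FALSE] != a2[, is_male, drop = FALSE]
    male_het[, is_male] <- mh
    # normalise hom-diploid male codings to a single allele
    a2m <- a2[, is_male, drop = FALSE]
    a2m[!mh] <- NA_integer_
    a2[, is_male] <- a2m
    a1m <- a1[, is_male, drop = FALSE]
    a1m[mh] <- NA_integer_
    a1[, is_male] <- a1m
  }
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  usable <- !(het & !phased) & !male_het
  colnames(a1) <- colnames(a2) <- colnames(phased) <-
    colnames(male_het) <- colnames(usable) <- samples
  list(a1 = a1, a2 = a2, phased = phased, usable = usable,
       male_het = male_het, samples = samples, males = males)
}

#' Construct a SNP panel from allele matrices
#'
#' Programmatic counterpart of [read_phased_vcf()] for genotypes already in
#' memory: allele-index matrices with sites in rows and samples in columns.
#' Hemizygous/missing second alleles are `NA` in `a2`. All diploid genotypes
#' are taken as phased unless `phased` says otherwise; MAF is recomputed
#' from the matrices.
#'
#' @param chrom,pos,ref,alt Per-site fields (recycled where scalar).
#' @param a1,a2 Integer allele matrices (sites x samples); `a1` must have
#'   column names (the sample ids) unless `samples` is given.
#' @param samples Sample ids (default: column names of `a1`).
#' @param males Sample ids to record as hemizygous males.
#' @param phased Optional logical matrix; default all phased.
#' @return A `"snp_panel"`.
#' @export
snp_panel <- function(chrom, pos, a1, a2, ref = "A", alt = "G",
                      samples = colnames(a1), males = character(),
                      phased = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  ns <- nrow(a1)
  stopifnot(length(pos) == ns, all(dim(a1) == dim(a2)),
            !is.null(samples))
  if (is.null(phased)) phased <- matrix(TRUE, ns, ncol(a1))
  colnames(a1) <- colnames(a2) <- colnames(phased) <- samples
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  male_het <- het & matrix(samples %in% males, ns, ncol(a1), byrow = TRUE)
  usable <- !(het & !phased) & !male_het
  colnames(usable) <- colnames(male_het) <- samples
  panel <- list(sites = data.frame(chrom = rep_len(as.character(chrom), ns),
                                   pos = as.integer(pos),
                                   id = sprintf("s%d", seq_len(ns)),
                                   ref = rep_len(ref, ns),
                                   alt = rep_len(alt, ns),
                                   maf = NA_real_, stringsAsFactors = FALSE),
                a1 = a1, a2 = a2, phased = phased, usable = usable,
                male_het = male_het, samples = samples, males = males)
  class(panel) <- "snp_panel"
  recompute_maf(panel)
}

#' Recompute per-site minor allele frequency from the panel's allele counts
#' @param panel A `"snp_panel"`.
#' @return The panel with `sites$maf` filled in (`NA` when no alleles observed).
#' @export
recompute_maf <- function(panel) {
  n1 <- rowSums(panel$a1 == 1L, na.rm = TRUE) + rowSums(panel$a2 == 1L, na.rm = TRUE)
  nt <- rowSums(!is.na(panel$a1)) + rowSums(!is.na(panel$a2))
  f <- ifelse(nt > 0, n1 / nt, NA_real_)
  panel$sites$maf <- pmin(f, 1 - f)
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d biallelic site(s) x %d sample(s) (%d male)\n",
              nrow(x$sites), length(x$samples), length(x$males)))
  if (nrow(x$sites))
    cat(sprintf("  %s:%d-%d, median MAF %.3f\n", x$sites$chrom[1L],
                min(x$sites$pos), max(x$sites$pos),
                stats::median(x$sites$maf, na.rm = TRUE)))
  invisible(x)
}

# indices of panel sites inside [lo, hi] on chrom
.sites_in_window <- function(panel, chrom, lo, hi) {
  which(panel$sites$chrom == chrom & panel$sites$pos >= lo &
          panel$sites$pos <= hi)
}

#' Write a panel of phased genotypes to a VCF 4.2 file
#'
#' Hemizygous calls (males, `a2` missing) are written haploid (`"1"`); phased
#' diploid calls as `a1|a2`; missing as `"."` / `"./."`.
#'
#' @param panel A `"snp_panel"`.
#' @param path Output path (plain-text `.vcf`).
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=xstrlink-simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"), con)
  if (nrow(panel$sites)) {
    a1c <- ifelse(is.na(panel$a1), ".", as.character(panel$a1))
    gtm <- matrix(ifelse(is.na(panel$a2), a1c,
                         paste0(a1c, "|", ifelse(is.na(panel$a2), ".",
                                                 as.character(panel$a2)))),
                  nrow(panel$sites))
    body <- paste(panel$sites$chrom, panel$sites$pos, panel$sites$id,
                  panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
                  apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
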