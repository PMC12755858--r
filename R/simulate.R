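#' The 25-locus, 7-linkage-group X-STR marker layout
#'
#' The default target-locus layout shipped with the package: 25 X-STR loci in
#' 7 linkage groups on chrX (hg38), with locus coordinates reconstructed as
#' the midpoints of the published searched SNP ranges (a synthetic
#' point-locus approximation; the flanking windows, not the STR bounds,
#' drive the analysis).
#'
#' @param window_bp Default flanking-window size.
#' @return A `"marker_table"` with 25 loci, groups LG1..LG7.
#' @export
xstr25_markers <- function(window_bp = 10000L) {
  read_marker_table(system.file("extdata", "xstr25_markers.tsv",
                                package = "xstrlink", mustWork = TRUE),
                    window_bp = window_bp)
}

#' Simulation configuration for synthetic trio cohorts and STR families
#'
#' Collects the generative parameters of the meiosis simulator. The defaults
#' reproduce the study conditions of the method's validation setting: a
#' 602-trio phased SNP cohort over the 25-locus/7-group layout with 10 kb
#' flanking windows, SNP allele frequencies uniform on [0.05, 0.5], free
#' recombination (theta = 0.5) between linkage groups and tight linkage
#' (theta = 0.02) within them, and 66 two-generation STR families with the
#' canonical composition table (e.g. 22 families of father + mother + 2
#' daughters).
#'
#' @param markers A `"marker_table"` (default [xstr25_markers()]).
#' @param n_trios Number of trios in the SNP cohort.
#' @param snp_density Expected SNPs per kb inside each flanking window.
#' @param maf_range Range of the uniform allele-frequency spectrum.
#' @param theta_within,theta_between Per-interval recombination probability
#'   for adjacent loci in the same / in different linkage groups.
#' @param genetic_map Optional explicit numeric vector of per-interval
#'   theta values (length `nrow(markers) - 1`), overriding the two defaults.
#' @param window_bp Flanking-window size in bp.
#' @param child_sex_ratio Probability a simulated child is male.
#' @param gene_conversion_rate Per-meiosis, per-locus probability of a short
#'   (<= 1 kb) double-switch tract inside a flanking window (off by default;
#'   mimics non-crossover gene conversion).
#' @param n_families Number of STR families (composition recycled from
#'   `family_structures`).
#' @param family_structures Data frame with columns `father`, `mother`,
#'   `daughter`, `son`, `n` giving family compositions and their counts.
#' @param str_loci Names of the simulated STR loci.
#' @param str_allele_freqs List (one element per STR locus) of named numeric
#'   allele-frequency vectors summing to 1.
#' @param theta_str Per-interval theta between adjacent STR loci.
#' @param mutation_rate Per-locus, per-meiosis STR mutation probability
#'   (single repeat-unit step).
#' @param seed Integer seed; fully determines every simulated output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(markers = xstr25_markers(), n_trios = 602L,
                       snp_density = 1, maf_range = c(0.05, 0.5),
                       theta_within = 0.02, theta_between = 0.5,
                       genetic_map = NULL, window_bp = 10000L,
                       child_sex_ratio = 0.5, gene_conversion_rate = 0,
                       n_families = 66L,
                       family_structures = NULL,
                       str_loci = c("STR_A", "STR_B"),
                       str_allele_freqs = NULL,
                       theta_str = 0.02, mutation_rate = 0, seed = 1L) {
  if (is.null(genetic_map)) {
    g <- markers$linkage_group
    genetic_map <- ifelse(g[-length(g)] == g[-1L], theta_within,
                          theta_between)
  }
  stopifnot(length(genetic_map) == nrow(markers) - 1L,
            all(genetic_map >= 0 & genetic_map <= 0.5))
  if (is.null(family_structures))
    family_structures <- data.frame(
      father = c(1, 0, 1, 0, 1, 1), mother = 1,
      daughter = c(2, 0, 1, 0, 1, 2), son = c(0, 2, 1, 3, 2, 1),
      n = c(22, 21, 20, 1, 1, 1))
  if (is.null(str_allele_freqs)) {
    fr <- stats::setNames(c(0.05, 0.15, 0.3, 0.25, 0.15, 0.1),
                          as.character(8:13))
    str_allele_freqs <- rep(list(fr), length(str_loci))
    names(str_allele_freqs) <- str_loci
  }
  stopifnot(all(abs(vapply(str_allele_freqs, sum, numeric(1L)) - 1) < 1e-8),
            length(theta_str) %in% c(1L, length(str_loci) - 1L),
            all(theta_str >= 0 & theta_str <= 0.5))
  out <- list(markers = markers, n_trios = as.integer(n_trios),
              snp_density = snp_density, maf_range = maf_range,
              genetic_map = genetic_map, window_bp = as.integer(window_bp),
              child_sex_ratio = child_sex_ratio,
              gene_conversion_rate = gene_conversion_rate,
              n_families = as.integer(n_families),
              family_structures = family_structures,
              str_loci = str_loci, str_allele_freqs = str_allele_freqs,
              theta_str = rep_len(theta_str, max(1L, length(str_loci) - 1L)),
              mutation_rate = mutation_rate, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

# window intervals and site->locus assignment for a marker table
.sim_layout <- function(markers, window_bp) {
  w <- ifelse(is.na(markers$window_bp), window_bp, markers$window_bp)
  lo <- pmax(1L, markers$start - w)
  hi <- markers$end + w
  list(lo = lo, hi = hi, w = w)
}

#' Simulate maternal founder haplotypes over the marker layout
#'
#' Places SNPs inside each locus's flanking span (locus +/- window) at the
#' configured density (Poisson count per window, uniform positions), draws a
#' per-site allele frequency from the MAF spectrum, and samples each
#' haplotype independently per site (linkage-equilibrium founders). SNPs
#' outside the flanking windows would enter no analysis and are not
#' generated. For LD-structured haplotypes see [simulate_ld_panel()].
#'
#' @param config A `"sim_config"`.
#' @param n_haplotypes Number of haplotypes to draw (default: two per trio
#'   mother).
#' @return A list: `sites` (data frame `chrom`, `pos`, `freq`, `locus`),
#'   `hap` (0/1 matrix, sites x haplotypes).
#' @export
simulate_maternal_haplotypes <- function(config,
                                         n_haplotypes = 2L * config$n_trios) {
  set.seed(config$seed)
  .sim_sites_and_haps(config, n_haplotypes)
}

.sim_sites_and_haps <- function(config, n_haplotypes) {
  mk <- config$markers
  lay <- .sim_layout(mk, config$window_bp)
  pos <- integer(0); locus <- integer(0)
  for (l in seq_len(nrow(mk))) {
    width <- lay$hi[l] - lay$lo[l] + 1L
    k <- stats::rpois(1L, config$snp_density * width / 1000)
    if (k > 0L) {
      p <- sort(sample.int(width, min(k, width)) + lay$lo[l] - 1L)
      pos <- c(pos, p); locus <- c(locus, rep(l, length(p)))
    }
  }
  ord <- order(pos)
  pos <- pos[ord]; locus <- locus[ord]
  dup <- duplicated(pos)
  pos <- pos[!dup]; locus <- locus[!dup]
  freq <- stats::runif(length(pos), config$maf_range[1L], config$maf_range[2L])
  hap <- matrix(stats::rbinom(length(pos) * n_haplotypes, 1L, rep(freq, n_haplotypes)),
                nrow = length(pos))
  list(sites = data.frame(chrom = rep(mk$chrom[1L], length(pos)), pos = pos,
                          freq = freq, locus = locus, stringsAsFactors = FALSE),
       hap = hap)
}

#' Simulate one maternal meiosis over the marker layout
#'
#' Draws the transmitted gamete from a mother's phased haplotype pair under a
#' no-interference crossover process: the starting haplotype is chosen fairly
#' and each inter-locus interval switches haplotype independently with its
#' map probability `theta_i`; a crossover is placed uniformly within the gap
#' between the two loci's windows. All SNPs in a locus's flanking span are
#' transmitted from that locus's haplotype.
#'
#' @param hap1,hap2 The mother's two haplotypes (0/1 vectors over sites).
#' @param site_locus Integer vector: index of the locus whose span contains
#'   each site.
#' @param genetic_map Per-interval theta values (length `n_loci - 1`).
#' @param interval_gaps Optional 2-column matrix of bp gap bounds per
#'   interval, for crossover placement.
#' @return A list: `gamete` (0/1 vector), `hap_at_locus` (1/2 per locus),
#'   `crossovers` (bp positions, possibly empty).
#' @export
simulate_meiosis <- function(hap1, hap2, site_locus, genetic_map,
                             interval_gaps = NULL) {
  n_loci <- length(genetic_map) + 1L
  start <- sample(1:2, 1L)
  switches <- stats::rbinom(length(genetic_map), 1L, genetic_map)
  hap_at_locus <- 1L + (start - 1L + cumsum(c(0L, switches))) %% 2L
  xo <- which(switches == 1L)
  crossovers <- if (length(xo) && !is.null(interval_gaps))
    vapply(xo, function(i) {
      # adjacent loci with overlapping windows leave no gap; place the
      # crossover at the boundary region regardless of orientation
      b <- range(interval_gaps[i, ])
      stats::runif(1L, b[1L], b[2L])
    }, numeric(1L))
  else numeric(0)
  hap_site <- hap_at_locus[site_locus]
  gamete <- ifelse(hap_site == 1L, hap1, hap2)
  list(gamete = gamete, hap_at_locus = hap_at_locus, crossovers = crossovers)
}

#' Simulate a phased trio cohort with known crossover truth
#'
#' Generates mothers as linkage-equilibrium founder haplotype pairs over the
#' marker layout, independent single paternal haplotypes, and one child per
#' trio: sons receive only the maternal gamete (hemizygous), daughters the
#' maternal gamete plus the full paternal haplotype. The truth table records
#' the maternal haplotype transmitted at every locus, from which the true
#' recombinant status of any locus pair follows (an odd number of
#' interval switches between them). Output round-trips through the package's
#' VCF/PED readers via [write_cohort()].
#'
#' @param config A `"sim_config"`.
#' @return A list of class `"sim_cohort"`: `panel` (a `"snp_panel"`; mothers'
#'   haplotype order is their phased genotype), `ped` (a `"pedigree"`),
#'   `markers`, `truth` (data frame `trio`, one column per locus with the
#'   transmitted haplotype index), `config`.
#' @export
simulate_trio_cohort <- function(config) {
  set.seed(config$seed)
  mk <- config$markers
  n <- config$n_trios
  sh <- .sim_sites_and_haps(config, 0L)  # sites only; haplotypes drawn below
  sites <- sh$sites
  ns <- nrow(sites)
  freq <- sites$freq
  draw <- function(cols) matrix(stats::rbinom(ns * cols, 1L, rep(freq, cols)),
                                nrow = ns)
  m1 <- draw(n); m2 <- draw(n); fh <- draw(n)
  lay <- .sim_layout(mk, config$window_bp)
  gaps <- cbind(utils::head(lay$hi, -1L), utils::tail(lay$lo, -1L))
  sex <- ifelse(stats::runif(n) < config$child_sex_ratio, "male", "female")
  hap_at_locus <- matrix(0L, n, nrow(mk))
  child <- matrix(0L, ns, n)
  for (t in seq_len(n)) {
    mei <- simulate_meiosis(m1[, t], m2[, t], sites$locus, config$genetic_map,
                            gaps)
    gam <- mei$gamete
    if (config$gene_conversion_rate > 0)
      gam <- .apply_gene_conversion(gam, m1[, t], m2[, t], mei$hap_at_locus,
                                    sites, lay, config$gene_conversion_rate)
    child[, t] <- gam
    hap_at_locus[t, ] <- mei$hap_at_locus
  }
  mo_id <- sprintf("M%04d", seq_len(n))
  fa_id <- sprintf("F%04d", seq_len(n))
  ch_id <- sprintf("C%04d", seq_len(n))
  samples <- c(mo_id, fa_id, ch_id)
  a1 <- cbind(m1, fh, child)
  a2 <- cbind(m2, matrix(NA_integer_, ns, n),
              ifelse(matrix(sex == "female", ns, n, byrow = TRUE),
                     fh, NA_integer_))
  colnames(a1) <- colnames(a2) <- samples
  males <- c(fa_id, ch_id[sex == "male"])
  tmpl <- matrix(TRUE, ns, length(samples), dimnames = list(NULL, samples))
  panel <- list(sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                                   id = sprintf("snp%05d", seq_len(ns)),
                                   ref = "A", alt = "G", maf = NA_real_,
                                   stringsAsFactors = FALSE),
                a1 = a1, a2 = a2, phased = tmpl, usable = tmpl,
                male_het = !tmpl, samples = samples, males = males)
  class(panel) <- "snp_panel"
  panel <- recompute_maf(panel)
  ped <- data.frame(
    family_id = rep(sprintf("FAM%04d", seq_len(n)), 3L),
    sample_id = samples,
    father_id = c(rep(NA_character_, 2L * n), fa_id),
    mother_id = c(rep(NA_character_, 2L * n), mo_id),
    sex = c(rep("female", n), rep("male", n), sex),
    father_external = FALSE, mother_external = FALSE,
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  truth <- data.frame(trio = ch_id, hap_at_locus, stringsAsFactors = FALSE)
  names(truth)[-1L] <- mk$name
  out <- list(panel = panel, ped = ped, markers = mk, truth = truth,
              config = config)
  class(out) <- "sim_cohort"
  out
}

# short double-switch tract (<= 1 kb) inside a random flanking window:
# transmits the opposite haplotype for the covered sites only
.apply_gene_conversion <- function(gam, h1, h2, hap_at_locus, sites, lay,
                                   rate) {
  n_loci <- length(lay$lo)
  hit <- which(stats::runif(n_loci) < rate)
  for (l in hit) {
    tract_len <- stats::runif(1L, 50, 1000)
    t0 <- stats::runif(1L, lay$lo[l], lay$hi[l] - tract_len)
    in_tract <- sites$locus == l & sites$pos >= t0 &
      sites$pos <= t0 + tract_len
    other <- ifelse(hap_at_locus[l] == 1L, h2[in_tract], h1[in_tract])
    gam[in_tract] <- other
  }
  gam
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Simulated trio cohort: %d trios, %d SNPs over %d loci (seed %d)\n",
              x$config$n_trios, nrow(x$panel$sites), nrow(x$markers),
              x$config$seed))
  invisible(x)
}

#' True recombinant status of a locus pair from a cohort truth table
#' @param cohort A `"sim_cohort"`.
#' @param locus_a,locus_b Locus names.
#' @return Logical vector per trio: transmitted maternal haplotype differs
#'   between the two loci.
#' @export
truth_recombinant <- function(cohort, locus_a, locus_b) {
  cohort$truth[[locus_a]] != cohort$truth[[locus_b]]
}

#' Write a simulated cohort to VCF + PED + marker/truth tables
#'
#' @param cohort A `"sim_cohort"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the paths written (`vcf`, `ped`,
#'   `markers`, `truth`).
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             ped = file.path(dir, paste0(prefix, ".ped")),
             markers = file.path(dir, paste0(prefix, "_markers.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_vcf(cohort$panel, paths["vcf"])
  write_ped(cohort$ped, paths["ped"])
  write_marker_table(cohort$markers, paths["markers"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Simulate two-generation STR families with known recombination truth
#'
#' Draws maternal STR haplotypes under linkage equilibrium from the
#' configured allele-frequency tables, paternal single alleles likewise, and
#' children according to the family-composition table; transmissions use the
#' same no-interference meiosis engine (per-interval `theta_str`). An
#' optional mutation model perturbs a transmitted allele by one repeat unit.
#' Daughter genotypes are reported unordered (sorted), as capillary
#' electrophoresis would.
#'
#' @param config A `"sim_config"`.
#' @return A list of class `"sim_families"`: `families` (a
#'   `"family_table"`), `truth` (data frame `family_id`, `child_id`, one
#'   logical column `rec_<i>` per interval: was the transmission
#'   recombinant?), `config`.
#' @export
simulate_str_families <- function(config) {
  set.seed(config$seed + 1L)
  loci <- config$str_loci
  nl <- length(loci)
  freqs <- config$str_allele_freqs
  st <- config$family_structures
  comp <- st[rep(seq_len(nrow(st)), st$n), c("father", "mother", "daughter",
                                             "son"), drop = FALSE]
  comp <- comp[rep_len(seq_len(nrow(comp)), config$n_families), , drop = FALSE]
  draw_allele <- function(l, k = 1L)
    sample(names(freqs[[l]]), k, replace = TRUE, prob = freqs[[l]])
  mutate <- function(a, l) {
    if (config$mutation_rate <= 0 ||
        stats::runif(1L) >= config$mutation_rate) return(a)
    alle <- as.numeric(a) + sample(c(-1, 1), 1L)
    as.character(alle)
  }
  rows <- list(); truths <- list()
  for (f in seq_len(nrow(comp))) {
    fid <- sprintf("FAM%03d", f)
    mh1 <- vapply(loci, draw_allele, character(1L))
    mh2 <- vapply(loci, draw_allele, character(1L))
    pat <- vapply(loci, draw_allele, character(1L))
    fam_rows <- list(data.frame(
      family_id = fid, member_id = paste0(fid, "_M"), role = "mother",
      sex = "female", stringsAsFactors = FALSE))
    fam_rows[[1L]][loci] <- paste0(mh1, "/", mh2)
    if (comp$father[f] > 0) {
      fr <- data.frame(family_id = fid, member_id = paste0(fid, "_F"),
                       role = "father", sex = "male", stringsAsFactors = FALSE)
      fr[loci] <- pat
      fam_rows <- c(fam_rows, list(fr))
    }
    kids_sex <- c(rep("female", comp$daughter[f]), rep("male", comp$son[f]))
    for (k in seq_along(kids_sex)) {
      start <- sample(1:2, 1L)
      switches <- stats::rbinom(nl - 1L, 1L, config$theta_str)
      hap_idx <- 1L + (start - 1L + cumsum(c(0L, switches))) %% 2L
      gam <- ifelse(hap_idx == 1L, mh1, mh2)
      gam <- vapply(seq_len(nl), function(l) mutate(gam[l], loci[l]),
                    character(1L))
      kid <- data.frame(family_id = fid,
                        member_id = sprintf("%s_C%d", fid, k),
                        role = "child", sex = kids_sex[k],
                        stringsAsFactors = FALSE)
      if (kids_sex[k] == "male") kid[loci] <- gam
      else kid[loci] <- vapply(seq_len(nl), function(l) {
        pair <- c(gam[l], pat[l])
        paste(pair[order(suppressWarnings(as.numeric(pair)), pair)],
              collapse = "/")
      }, character(1L))
      fam_rows <- c(fam_rows, list(kid))
      tr <- data.frame(family_id = fid, child_id = kid$member_id,
                       stringsAsFactors = FALSE)
      if (nl > 1L) tr[paste0("rec_", seq_len(nl - 1L))] <-
        as.list(switches == 1L)
      truths <- c(truths, list(tr))
    }
    rows <- c(rows, fam_rows)
  }
  families <- do.call(rbind, rows)
  attr(families, "loci") <- loci
  class(families) <- c("family_table", "data.frame")
  truth <- do.call(rbind, truths)
  out <- list(families = families, truth = truth, config = config)
  class(out) <- "sim_families"
  out
}

#' Simulate an LD-structured haplotype panel (founder-mosaic mode)
#'
#' Generates haplotypes as mosaics of two complementary founder haplotypes,
#' switching founder along the chromosome as a symmetric two-state Markov
#' chain with per-bp switch rate `switch_rate`. The equilibrium pairwise
#' `r2` between sites at distance `d` is `(1 - 2 rho)^(2d)`, so the decay
#' curve crosses `r2 = 0.1` at `ln(0.1) / (2 ln(1 - 2 rho))` bp; the default
#' rate puts that crossing at 3.7 kb, the scale observed for X-chromosome
#' SNP panels.
#'
#' @param n_hap Number of haplotypes.
#' @param length_bp Span of the simulated region.
#' @param density Expected SNPs per kb.
#' @param switch_rate Per-bp founder switch probability `rho`.
#' @param seed Integer seed.
#' @return A list: `haplotypes` (0/1 matrix, sites x haplotypes),
#'   `positions`, `expected_crossing_bp`.
#' @export
simulate_ld_panel <- function(n_hap = 200L, length_bp = 30000L, density = 4,
                              switch_rate = (1 - 0.1^(1 / 7400)) / 2,
                              seed = 1L) {
  set.seed(seed)
  k <- stats::rpois(1L, density * length_bp / 1000)
  positions <- sort(sample.int(length_bp, min(k, length_bp)))
  ns <- length(positions)
  gaps <- diff(positions)
  p_switch <- (1 - (1 - 2 * switch_rate)^gaps) / 2
  haps <- matrix(0L, ns, n_hap)
  for (h in seq_len(n_hap)) {
    state <- stats::rbinom(1L, 1L, 0.5)
    s <- integer(ns)
    s[1L] <- state
    if (ns > 1L) {
      flips <- stats::rbinom(ns - 1L, 1L, p_switch)
      s <- (state + cumsum(c(0L, flips))) %% 2L
    }
    haps[, h] <- s
  }
  list(haplotypes = haps, positions = positions,
       expected_crossing_bp = log(0.1) / (2 * log(1 - 2 * switch_rate)))
}
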