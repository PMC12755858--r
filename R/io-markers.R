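#' Read a marker (target locus) table
#'
#' Reads the tab-separated table of target STR loci. Required columns:
#' `name`, `chrom`, `start`, `end`, `linkage_group`; an optional `window_bp`
#' column overrides the flanking-window size per locus. Coordinates are
#' 1-based inclusive (VCF convention). Loci are returned sorted by
#' `(chrom, start)`.
#'
#' @param path Path to the tab-separated file (with header).
#' @param window_bp Default flanking-window size in bp for loci without their
#'   own `window_bp` column value.
#' @return A data frame of class `"marker_table"` with columns `name`,
#'   `chrom`, `start`, `end`, `linkage_group`, `window_bp`.
#' @export
read_marker_table <- function(path, window_bp = 10000L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  required <- c("name", "chrom", "start", "end", "linkage_group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("marker table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"window_bp" %in% names(df)) df$window_bp <- rep(window_bp, nrow(df))
  df$window_bp[is.na(df$window_bp)] <- window_bp
  marker_table(df$name, df$chrom, df$start, df$end, df$linkage_group,
               df$window_bp)
}

#' Construct a marker table
#'
#' @param name Locus names (unique).
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive bp coordinates, `start <= end`.
#' @param linkage_group Linkage-group label per locus.
#' @param window_bp Flanking-window size in bp (recycled).
#' @return A `"marker_table"` data frame sorted by `(chrom, start)`.
#' @export
marker_table <- function(name, chrom, start, end, linkage_group,
                         window_bp = 10000L) {
  df <- data.frame(name = as.character(name), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   linkage_group = as.character(linkage_group),
                   window_bp = as.integer(rep_len(window_bp, length(name))),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate locus name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad <- df$start > df$end
  if (any(bad))
    stop("start > end for locus ", paste(df$name[bad], collapse = ", "))
  if (any(df$window_bp <= 0)) stop("window_bp must be positive")
  known <- c(paste0("chr", c(1:22, "X", "Y")), c(1:22, "X", "Y"))
  if (any(!df$chrom %in% known))
    warning("unknown chromosome label(s): ",
            paste(unique(df$chrom[!df$chrom %in% known]), collapse = ", "))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Write a marker table
#' @param markers A `"marker_table"` data frame.
#' @param path Output path (tab-separated, with header).
#' @export
write_marker_table <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flanking windows of a locus
#'
#' The upstream and downstream flanking segments used for origin calling:
#' `[start - w, start - 1]` and `[end + 1, end + w]`, clamped at position 1.
#' The searched span (upstream window start through downstream window end)
#' therefore covers the locus plus `w` bp on each side.
#'
#' @param start,end 1-based inclusive locus coordinates.
#' @param window_bp Window size `w` in bp.
#' @return A list with integer vectors `up = c(lo, hi)` and `down = c(lo, hi)`.
#' @export
marker_windows <- function(start, end, window_bp = 10000L) {
  list(up = c(max(1L, as.integer(start) - as.integer(window_bp)),
              max(1L, as.integer(start) - 1L)),
       down = c(as.integer(end) + 1L, as.integer(end) + as.integer(window_bp)))
}

#' Junction locus pairs between (and optionally within) linkage groups
#'
#' For each pair of adjacent linkage groups along the chromosome, returns the
#' boundary pair (last locus of the first group, first locus of the next):
#' the two junction loci whose transmission decides between-group
#' recombination. With `within = TRUE`, also returns every adjacent locus pair
#' inside each group.
#'
#' @param markers A `"marker_table"` (sorted by position; each group's loci
#'   must be contiguous along the chromosome).
#' @param within Also emit within-group adjacent pairs?
#' @return A data frame with columns `locus_a`, `locus_b`, `group_a`,
#'   `group_b`, `type` (`"between"` or `"within"`).
#' @export
junction_pairs <- function(markers, within = FALSE) {
  g <- markers$linkage_group
  runs <- rle(g)
  if (length(runs$values) != length(unique(g)))
    stop("linkage groups are interleaved: each group's loci must be contiguous")
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  if (length(runs$values) > 1L) {
    i <- seq_len(length(runs$values) - 1L)
    out[[1L]] <- data.frame(
      locus_a = markers$name[ends[i]], locus_b = markers$name[starts[i + 1L]],
      group_a = runs$values[i], group_b = runs$values[i + 1L],
      type = "between", stringsAsFactors = FALSE)
  }
  if (within) {
    w <- lapply(seq_along(runs$values), function(j) {
      idx <- starts[j]:ends[j]
      if (length(idx) < 2L) return(NULL)
      data.frame(locus_a = markers$name[idx[-length(idx)]],
                 locus_b = markers$name[idx[-1L]],
                 group_a = runs$values[j], group_b = runs$values[j],
                 type = "within", stringsAsFactors = FALSE)
    })
    out <- c(out, w)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(locus_a = character(), locus_b = character(),
                      group_a = character(), group_b = character(),
                      type = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
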