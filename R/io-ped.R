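#' Read a 5-column pedigree file
#'
#' Reads a PED-like whitespace-separated file with columns
#' `family_id sample_id father_id mother_id sex`. Missing parents are coded
#' `0` (or `.`); sex is `1`/`M`/`male` for males and `2`/`F`/`female` for
#' females. Parent ids that do not resolve to a record in the file are kept
#' and flagged `external`.
#'
#' @param path Path to the pedigree file. A header line starting with `#` or
#'   with the literal column names is skipped.
#' @return A data frame of class `"pedigree"` with character columns
#'   `family_id`, `sample_id`, `father_id`, `mother_id` (NA when missing),
#'   `sex` (`"male"`/`"female"`), and logical `father_external`,
#'   `mother_external`.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^family_id\\b", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) {
    df <- data.frame(family_id = character(), sample_id = character(),
                     father_id = character(), mother_id = character(),
                     sex = character(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(trimws(lines), "[ \t]+")
    if (any(lengths(parts) < 5L)) stop("pedigree rows must have 5 columns")
    m <- do.call(rbind, lapply(parts, `[`, 1:5))
    df <- data.frame(family_id = m[, 1L], sample_id = m[, 2L],
                     father_id = m[, 3L], mother_id = m[, 4L], sex = m[, 5L],
                     stringsAsFactors = FALSE)
  }
  df$father_id[df$father_id %in% c("0", ".", "")] <- NA_character_
  df$mother_id[df$mother_id %in% c("0", ".", "")] <- NA_character_
  df$sex <- .norm_sex(df$sex)
  df$father_external <- !is.na(df$father_id) & !df$father_id %in% df$sample_id
  df$mother_external <- !is.na(df$mother_id) & !df$mother_id %in% df$sample_id
  class(df) <- c("pedigree", "data.frame")
  df
}

.norm_sex <- function(x) {
  out <- rep(NA_character_, length(x))
  out[x %in% c("1", "M", "m", "male")] <- "male"
  out[x %in% c("2", "F", "f", "female")] <- "female"
  if (anyNA(out) && length(x)) stop("unrecognised sex code(s): ",
                                    paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Extract trios from a pedigree
#'
#' A trio is a child with its mother present in the pedigree; the father is
#' required only for female children (a son's hemizygous X comes entirely
#' from his mother, so paternal genotypes are not needed to trace it).
#' Daughters without a recorded father are dropped with a warning.
#'
#' @param ped A `"pedigree"` data frame from [read_ped()].
#' @return A data frame with columns `trio_id` (the child's sample id),
#'   `mother`, `father` (NA for sons without one), `child`, `child_sex`.
#' @export
trios_from_ped <- function(ped) {
  kid <- ped[!is.na(ped$mother_id), , drop = FALSE]
  need_father <- kid$sex == "female" & is.na(kid$father_id)
  if (any(need_father)) {
    warning(sum(need_father), " daughter(s) without a recorded father dropped")
    kid <- kid[!need_father, , drop = FALSE]
  }
  data.frame(trio_id = kid$sample_id, mother = kid$mother_id,
             father = ifelse(kid$sex == "female", kid$father_id,
                             kid$father_id),
             child = kid$sample_id, child_sex = kid$sex,
             stringsAsFactors = FALSE)
}

#' Write a 5-column pedigree file
#' @param ped A `"pedigree"` data frame.
#' @param path Output path.
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(
    family_id = ped$family_id, sample_id = ped$sample_id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = ifelse(ped$sex == "male", "1", "2"), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
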