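#' Read a per-CpG methylation bedGraph
#'
#' Reads the bedGraph dialect emitted by common methylation callers:
#' tab-separated `chrom, start, end, ratio, meth, unmeth`, 0-based
#' half-open coordinates, one CpG per line (strands pre-collapsed
#' upstream). The ratio column is ignored and recomputed downstream; the
#' stored total is `meth + unmeth`.
#'
#' @param path file path.
#' @param entity label for the entity the file describes; defaults to the
#'   file name without extension.
#' @return A [cpg_table()].
#' @export
read_bedgraph <- function(path, entity = NULL) {
  if (is.null(entity))
    entity <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(cpg_table(entity = entity))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- which(nf < 6)[1]
    stop(sprintf("malformed bedGraph line %d in '%s': expected >= 6 fields, got %d",
                 bad, path, nf[bad]))
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:6))
  pos <- suppressWarnings(as.integer(mat[, 2]))
  meth <- suppressWarnings(as.numeric(mat[, 5]))
  unmeth <- suppressWarnings(as.numeric(mat[, 6]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth))
  if (length(bad) > 0)
    stop(sprintf("malformed bedGraph line %d in '%s': non-numeric coordinate or count",
                 bad[1], path))
  bad <- which(meth < 0 | unmeth < 0)
  if (length(bad) > 0)
    stop(sprintf("invalid bedGraph line %d in '%s': negative count", bad[1], path))
  cpg_table(chrom = mat[, 1], pos = pos, meth = meth,
            total = meth + unmeth, entity = entity)
}

#' Write a per-CpG methylation bedGraph
#'
#' Inverse of [read_bedgraph()]; the ratio column is recomputed as
#' `meth/total` (0 where total is 0) and the end coordinate as `pos + 1`.
#'
#' @param x a [cpg_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "cpg_table"))
  ratio <- ifelse(x$total > 0, x$meth / x$total, 0)
  df <- data.frame(x$chrom, x$pos, x$pos + 1L,
                   formatC(ratio, format = "g", digits = 6),
                   x$meth, x$total - x$meth)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.region_columns <- c("chrom", "start", "end", "name", "score", "strand",
                     "target_entity", "direction")

#' Read a marker-region BED file
#'
#' BED6-compatible with two extra annotation columns: `target_entity` (the
#' entity the region marks) and `direction` (`hyper` or `hypo`). 0-based
#' half-open coordinates.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `target_entity`, `direction`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = .region_columns,
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "character", "character"))
  if (nrow(df) > 0) {
    if (any(df$start >= df$end))
      stop("region file: start must be < end")
    if (anyDuplicated(df$name))
      stop("region file: region names must be unique")
    if (!all(df$direction %in% c("hyper", "hypo")))
      stop("region file: direction must be 'hyper' or 'hypo'")
  }
  df
}

#' Write a marker-region BED file
#' @param regions data.frame as returned by [read_regions()] or
#'   [extend_to_regions()]; missing `score`/`strand` columns are filled.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  if (is.null(regions$score)) regions$score <- 0
  if (is.null(regions$strand)) regions$strand <- "."
  if (is.null(regions$target_entity)) regions$target_entity <- "."
  if (is.null(regions$direction)) regions$direction <- "hyper"
  utils::write.table(regions[, .region_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a region-level CpG count matrix
#'
#' TSV with header `chrom  start  end  <name>_meth  <name>_total ...`, one
#' row per marker region. Every `<name>_meth` column must have a matching
#' `<name>_total` column and vice versa; `meth <= total` cell-wise.
#'
#' @param path file path.
#' @param role `"atlas"` or `"mixture"`: which container to return.
#' @return A [count_atlas()] or [mixture_counts()] whose rows follow the
#'   column-pair order of the file and whose columns follow the row order.
#' @export
read_count_matrix <- function(path, role = c("atlas", "mixture")) {
  role <- match.arg(role)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cols <- colnames(df)
  if (length(cols) < 3 || !identical(cols[1:3], c("chrom", "start", "end")))
    stop("count matrix: header must start with chrom, start, end")
  count_cols <- cols[-(1:3)]
  meth_names <- sub("_meth$", "", grep("_meth$", count_cols, value = TRUE))
  total_names <- sub("_total$", "", grep("_total$", count_cols, value = TRUE))
  orphan <- c(setdiff(meth_names, total_names), setdiff(total_names, meth_names))
  if (length(orphan) > 0)
    stop("count matrix: incomplete column pair for '", orphan[1], "'")
  stray <- setdiff(count_cols,
                   c(paste0(meth_names, "_meth"), paste0(total_names, "_total")))
  if (length(stray) > 0)
    stop("count matrix: unrecognized column '", stray[1], "'")
  labels <- meth_names
  M <- t(as.matrix(df[, paste0(labels, "_meth"), drop = FALSE]))
  D <- t(as.matrix(df[, paste0(labels, "_total"), drop = FALSE]))
  if (any(M > D))
    stop("count matrix: methylated count exceeds total count")
  regions <- data.frame(chrom = as.character(df$chrom),
                        start = as.integer(df$start),
                        end = as.integer(df$end),
                        name = paste0(df$chrom, ":", df$start, "-", df$end),
                        stringsAsFactors = FALSE)
  if (role == "atlas")
    count_atlas(D, M, regions, entities = labels)
  else
    mixture_counts(D, M, regions, samples = labels)
}

#' Write a region-level CpG count matrix
#' @param x a [count_atlas()] or [mixture_counts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "methyl_counts"))
  df <- data.frame(chrom = x$regions$chrom, start = x$regions$start,
                   end = x$regions$end, stringsAsFactors = FALSE)
  for (j in seq_along(x$labels)) {
    df[[paste0(x$labels[j], "_meth")]] <- x$M[j, ]
    df[[paste0(x$labels[j], "_total")]] <- x$D[j, ]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write estimated proportions to TSV
#'
#' One row per sample: sample id, one column per atlas entity, then one per
#' unknown contributor (`unknown_1`, ...). Rows must lie on the simplex.
#'
#' @param result a [deconvolve()] result, or a proportion matrix with
#'   column names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(result, path) {
  A <- if (inherits(result, "deconv_result")) result$proportions else as.matrix(result)
  if (nrow(A) > 0) {
    if (any(A < -1e-9) || any(abs(rowSums(A) - 1) > 1e-6))
      stop("proportion rows must be non-negative and sum to 1")
  }
  df <- if (nrow(A) == 0)
    data.frame(sample = character(0),
               matrix(numeric(0), 0, ncol(A),
                      dimnames = list(NULL, colnames(A))),
               check.names = FALSE)
  else
    data.frame(sample = rownames(A) %||% paste0("sample_", seq_len(nrow(A))),
               as.data.frame(A, check.names = FALSE),
               check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
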