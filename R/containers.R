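#' Per-CpG methylation count table
#'
#' Holds one entity's genome-wide per-CpG methylated/total counts, the unit
#' of input for atlas construction. Records are kept sorted by
#' (chrom, pos) with 0-based positions and must satisfy `meth <= total`.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based CpG positions.
#' @param meth integer vector of methylated CpG counts.
#' @param total integer vector of total CpG counts.
#' @param entity single label naming the cell/tissue type (or replicate).
#' @return An object of class `cpg_table`: a data.frame with columns
#'   `chrom`, `pos`, `meth`, `total` and an `entity` attribute.
#' @export
cpg_table <- function(chrom = character(), pos = integer(),
                      meth = integer(), total = integer(),
                      entity = "unnamed") {
  n <- length(pos)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(meth) != n || length(total) != n)
    stop("cpg_table: column lengths differ")
  if (any(meth < 0) || any(total < 0))
    stop("cpg_table: negative counts")
  if (any(meth > total))
    stop("cpg_table: meth > total at ",
         sum(meth > total), " record(s)")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   meth = as.numeric(meth), total = as.numeric(total),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("cpg_table: duplicated (chrom, pos) records")
  structure(df, entity = entity, class = c("cpg_table", "data.frame"))
}

#' @export
print.cpg_table <- function(x, ...) {
  cat(sprintf("<cpg_table> entity '%s': %d CpG sites on %d chromosome(s)\n",
              attr(x, "entity"), nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

.new_count_pair <- function(D, M, regions, labels, class1) {
  D <- as.matrix(D); M <- as.matrix(M)
  if (!all(dim(D) == dim(M)))
    stop("D and M dimensions differ")
  if (nrow(D) != length(labels))
    stop("row count does not match number of labels")
  if (!is.null(regions) && ncol(D) != nrow(regions))
    stop("column count does not match number of regions")
  if (any(D < 0) || any(M < 0)) stop("negative counts")
  if (any(M > D + 1e-9)) stop("methylated count exceeds total count")
  dimnames(D) <- dimnames(M) <- list(labels, regions$name)
  structure(list(D = D, M = M, regions = regions, labels = labels),
            class = c(class1, "methyl_counts"))
}

#' Reference atlas of region-level methylation counts
#'
#' Paired integer matrices (entities x marker regions): `D` holds total CpG
#' counts summed over the CpGs of each region, `M` the methylated counts.
#' A CpG spanned by several reads contributes once per read, so these are
#' CpG counts, not genomic coverage.
#'
#' @param D,M numeric matrices, entities x regions, `M <= D` cell-wise.
#' @param regions data.frame with at least `chrom`, `start`, `end`, `name`.
#' @param entities character vector of row labels.
#' @param tissue_map optional character vector mapping each row (replicate)
#'   to a tissue label, for "full" (per-replicate) atlases.
#' @return An object of class `count_atlas`.
#' @export
count_atlas <- function(D, M, regions, entities = rownames(D),
                        tissue_map = NULL) {
  if (is.null(entities)) entities <- paste0("entity_", seq_len(nrow(D)))
  out <- .new_count_pair(D, M, regions, entities, "count_atlas")
  if (!is.null(tissue_map)) {
    if (length(tissue_map) != length(entities))
      stop("tissue_map length must match number of rows")
    out$tissue_map <- tissue_map
  }
  out
}

#' cfDNA mixture count matrices
#'
#' Same layout as [count_atlas()] but rows are cfDNA samples.
#'
#' @inheritParams count_atlas
#' @param samples character vector of sample labels.
#' @return An object of class `mixture_counts`.
#' @export
mixture_counts <- function(D, M, regions, samples = rownames(D)) {
  if (is.null(samples)) samples <- paste0("sample_", seq_len(nrow(D)))
  .new_count_pair(D, M, regions, samples, "mixture_counts")
}

#' @export
print.methyl_counts <- function(x, ...) {
  cat(sprintf("<%s> %d row(s) x %d region(s)\n",
              class(x)[1], nrow(x$D), ncol(x$D)))
  invisible(x)
}

#' @export
dim.methyl_counts <- function(x) dim(x$D)

#' Blood-cell entity labels of the default 13-entity atlas
#' @return Character vector of the seven hematopoietic entities.
#' @export
blood_entities <- function() {
  c("B", "CD4T", "CD8T", "NK", "monocytes", "neutrophils", "erythroblasts")
}

#' Cancer entity labels of the default 13-entity atlas
#' @return Character vector of the six tumor entities.
#' @export
cancer_entities <- function() {
  c("BRCA", "OVCA", "CEAD", "CESC", "COAD", "READ")
}

#' Cancer subtype grouping used for tissue-of-origin reporting
#'
#' Cervical adeno/squamous carcinoma collapse to CERCA and colon/rectum
#' adenocarcinoma to COLCA; other labels map to themselves.
#' @param labels character vector of entity labels.
#' @return Character vector of grouped labels.
#' @export
group_cancer_subtypes <- function(labels) {
  map <- c(CEAD = "CERCA", CESC = "CERCA", COAD = "COLCA", READ = "COLCA")
  out <- labels
  hit <- labels %in% names(map)
  out[hit] <- map[labels[hit]]
  out
}
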