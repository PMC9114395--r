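# The pipeline's universal substrate: a variants x samples grid of
# (alt reads, total depth) with variant and sample metadata.

#' Construct a count matrix
#'
#' @param alt,depth Integer matrices (variants x samples), `alt <= depth`
#'   elementwise; rownames are variant ids, colnames sample ids.
#' @param variants Data frame of variant metadata with an `id` column matching
#'   `rownames(alt)` (typically also chrom, pos, ref, alt, kind, context or
#'   flanks, and caller annotations ASMD/CLPM/Qual/site_depth).
#' @param samples Data frame of sample metadata: `id`, `patient`, `tissue`,
#'   `crypt_type`, `age` (years, > 0), and logical `cnv` (samples carrying
#'   copy-number variants, excluded from germline-test aggregation).
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(alt, depth, variants, samples) {
  stopifnot(is.matrix(alt), is.matrix(depth), all(dim(alt) == dim(depth)))
  if (any(alt < 0) || any(depth < 0) || any(alt > depth)) {
    stop("count_matrix: need 0 <= alt <= depth elementwise")
  }
  # a 0-row matrix legitimately has NULL rownames
  rn <- if (is.null(rownames(alt))) character(0) else rownames(alt)
  stopifnot(identical(rn, as.character(variants$id)),
            identical(colnames(alt), samples$id))
  if (!"cnv" %in% names(samples)) samples$cnv <- FALSE
  if (any(samples$age <= 0)) stop("count_matrix: ages must be > 0")
  out <- list(alt = alt, depth = depth, variants = variants, samples = samples)
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$alt), "variants x", ncol(x$alt), "samples (",
      paste(names(table(x$variants$kind)), table(x$variants$kind),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Subset a count matrix by variant index
#'
#' @param x A `count_matrix`.
#' @param i Row (variant) index: logical, integer, or variant ids.
#' @return A `count_matrix` over the selected variants.
#' @export
cm_subset <- function(x, i) {
  if (is.character(i)) {
    i <- match(i, x$variants$id)
    if (anyNA(i)) stop("cm_subset: unknown variant ids")
  }
  count_matrix(x$alt[i, , drop = FALSE], x$depth[i, , drop = FALSE],
               x$variants[i, , drop = FALSE], x$samples)
}

#' Variant allele fractions
#'
#' @param x A `count_matrix`.
#' @return Numeric matrix alt/depth with NA where depth is 0.
#' @export
cm_vaf <- function(x) {
  v <- x$alt / x$depth
  v[x$depth == 0] <- NA_real_
  v
}

#' Write / read a count matrix as paired tab-separated files
#'
#' Four files under `dir`: `alt.tsv`, `depth.tsv`, `variants.tsv`,
#' `samples.tsv`.
#'
#' @param x A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @export
write_count_matrix <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$alt, file.path(dir, "alt.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(x$depth, file.path(dir, "depth.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(x$variants, file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  alt <- as.matrix(utils::read.delim(file.path(dir, "alt.tsv"), check.names = FALSE))
  depth <- as.matrix(utils::read.delim(file.path(dir, "depth.tsv"), check.names = FALSE))
  variants <- utils::read.delim(file.path(dir, "variants.tsv"),
                                stringsAsFactors = FALSE)
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  count_matrix(alt, depth, variants, samples)
}
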