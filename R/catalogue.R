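# Reference signature catalogues: named probability vectors over the SBS96 or
# ID83 channels, stored column-wise, read/written in the COSMIC tab-separated
# layout (channel label column + one column per signature).

#' Construct a signature catalogue
#'
#' @param vectors Numeric matrix, channels x signatures; rownames are channel
#'   labels and colnames are signature names. Columns must be non-negative and
#'   sum to 1 within 1e-6 (they are renormalized exactly).
#' @return Object of class `sig_catalogue`: list(names, labels, vectors).
#' @export
signature_catalogue <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            !is.null(colnames(vectors)))
  if (any(vectors < 0)) stop("signature_catalogue: negative entries")
  cs <- colSums(vectors)
  if (any(abs(cs - 1) > 1e-6)) {
    stop("signature_catalogue: columns must sum to 1 within 1e-6")
  }
  vectors <- sweep(vectors, 2, cs, "/")
  out <- list(names = colnames(vectors), labels = rownames(vectors),
              vectors = vectors)
  class(out) <- "sig_catalogue"
  out
}

#' @export
print.sig_catalogue <- function(x, ...) {
  cat("Signature catalogue:", length(x$names), "signatures over",
      length(x$labels), "channels\n")
  invisible(x)
}

#' Read a COSMIC-format signature table
#'
#' Tab-separated, one header row of signature names, first column the channel
#' labels.
#'
#' @param path File path.
#' @param labels Optional expected channel order; rows are reordered to match
#'   and an error is raised on any mismatch.
#' @return A `sig_catalogue`.
#' @export
read_signature_catalogue <- function(path, labels = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  chan <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- chan
  if (!is.null(labels)) {
    if (!setequal(chan, labels)) {
      stop("read_signature_catalogue: channel labels do not match the scheme")
    }
    m <- m[labels, , drop = FALSE]
  }
  signature_catalogue(m)
}

#' Write a catalogue in COSMIC layout
#'
#' @param cat A `sig_catalogue`.
#' @param path Output path.
#' @export
write_signature_catalogue <- function(cat, path) {
  df <- data.frame(Type = cat$labels, cat$vectors, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Synthetic sparse signatures for simulation and testing
#'
#' Each signature concentrates ~`(1 - background)` of its mass on `sparsity`
#' dominant channels; dominant channels are sampled without replacement across
#' signatures, so pairwise cosines are low (typically < 0.1).
#'
#' @param labels Channel labels ([sbs96_labels()] or [id83_labels()]).
#' @param n_sig Number of signatures.
#' @param seed Integer seed.
#' @param sparsity Dominant channels per signature.
#' @param background Fraction of mass spread uniformly over all channels.
#' @param prefix Signature name prefix.
#' @return A `sig_catalogue`.
#' @export
synthetic_signatures <- function(labels, n_sig, seed = 1L, sparsity = 6L,
                                 background = 0.02, prefix = "SIG") {
  stopifnot(n_sig * sparsity <= length(labels))
  set.seed(seed)
  C <- length(labels)
  dom <- matrix(sample.int(C, n_sig * sparsity), nrow = n_sig)
  m <- matrix(background / C, nrow = C, ncol = n_sig,
              dimnames = list(labels, paste0(prefix, seq_len(n_sig))))
  for (k in seq_len(n_sig)) {
    w <- stats::rgamma(sparsity, shape = 2)
    m[dom[k, ], k] <- m[dom[k, ], k] + (1 - background) * w / sum(w)
  }
  signature_catalogue(m)
}

# Dirichlet draws (rows) used by the simulator and samplers.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  x / rowSums(x)
}
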