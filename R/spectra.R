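# Mutation spectrum channels: SBS96 trinucleotide classes and the PCAWG/COSMIC
# ID83 indel classes, plus per-branch spectrum matrices.

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical SBS96 channel labels
#'
#' Labels follow the COSMIC convention \code{"5'[REF>ALT]3'"} with the six
#' pyrimidine substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) varying
#' slowest and the 5' then 3' flanking base (A, C, G, T) varying fastest.
#'
#' @return Character vector of length 96, the fixed channel order used by all
#'   spectrum matrices in this package.
#' @export
sbs96_labels <- function() {
  unlist(lapply(SBS_CLASSES, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(BASES, BASES, function(f5, f3) {
      paste0(f5, "[", cl, "]", f3)
    })))
  }))
}

#' Canonical ID83 channel labels
#'
#' The PCAWG 83-channel indel scheme in COSMIC label order:
#' 1 bp deletions at C/T homopolymers (run length 1..6+, encoded 0..5),
#' 1 bp insertions (pre-existing run 0..5+), deletions and insertions of
#' length 2,3,4,5+ at tandem repeats (repeat units encoded 0..5), and
#' deletions of length 2..5+ with microhomology (MH length 1..5+).
#'
#' @return Character vector of length 83.
#' @export
id83_labels <- function() {
  lab <- character(0)
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) lab <- c(lab, paste0("1:Ins:", b, ":", 0:5))
  for (L in 2:5) lab <- c(lab, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) lab <- c(lab, paste0(L, ":Ins:R:", 0:5))
  lab <- c(lab, "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  lab
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

#' Classify single base substitutions into SBS96 channels
#'
#' Purine reference alleles are strand-normalized by reverse complementing
#' ref, alt and the trinucleotide context, so each substitution maps to one of
#' the 96 pyrimidine-centred channels.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param context Trinucleotide context centred on the site.
#' @return Character vector of channel labels (levels of [sbs96_labels()]).
#' @export
sbs_channel <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  bad <- !grepl("^[ACGT]$", ref) | !grepl("^[ACGT]$", alt) |
    !grepl("^[ACGT]{3}$", context) | substr(context, 2, 2) != ref | ref == alt
  if (any(bad)) {
    stop("sbs_channel: invalid ref/alt/context at entries ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ref[pur] <- chartr("ACGT", "TGCA", ref[pur])
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
    context[pur] <- revcomp(context[pur])
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

#' Count adjacent full copies of a motif at the start of the 3' flank
#'
#' Only complete, immediately adjacent copies count; partial copies and
#' interrupted repeats do not.
#'
#' @param motif Non-empty repeat unit.
#' @param flank_3prime Sequence immediately 3' of the event.
#' @return Integer count of adjacent copies (vectorized).
#' @export
repeat_units <- function(motif, flank_3prime) {
  stopifnot(all(nchar(motif) > 0))
  mapply(function(m, f) {
    k <- nchar(m)
    n <- 0L
    while (nchar(f) >= k && substr(f, 1, k) == m) {
      n <- n + 1L
      f <- substr(f, k + 1L, nchar(f))
    }
    n
  }, motif, flank_3prime, USE.NAMES = FALSE)
}

mh_length <- function(seq, flank5, flank3) {
  L <- nchar(seq)
  mh3 <- 0L
  while (mh3 < L - 1L && mh3 < nchar(flank3) &&
         substr(seq, 1, mh3 + 1L) == substr(flank3, 1, mh3 + 1L)) {
    mh3 <- mh3 + 1L
  }
  mh5 <- 0L
  n5 <- nchar(flank5)
  while (mh5 < L - 1L && mh5 < n5 &&
         substr(seq, L - mh5, L) == substr(flank5, n5 - mh5, n5)) {
    mh5 <- mh5 + 1L
  }
  max(mh3, mh5)
}

#' Classify an indel into the ID83 scheme
#'
#' Repeats of multi-base motifs are counted on the 3' flank (left-alignment of
#' the event is assumed upstream); for 1 bp events the homopolymer run is
#' counted on both flanks, since strand normalization may reflect the tract.
#' Deletions whose motif has no adjacent copy are checked for
#' microhomology: the longest prefix of the deleted sequence matching the
#' start of the 3' flank, or suffix matching the end of the 5' flank.
#' 1 bp events are strand-normalized to C/T.
#'
#' @param kind "INS" or "DEL" (vectorized).
#' @param seq Inserted or deleted sequence.
#' @param flank5,flank3 Flanking sequence on each side (>= 6 motif copies'
#'   worth recommended).
#' @return Character vector of channel labels (levels of [id83_labels()]).
#' @export
id_channel <- function(kind, seq, flank5, flank3) {
  n <- length(kind)
  stopifnot(length(seq) == n, length(flank5) == n, length(flank3) == n)
  out <- character(n)
  for (i in seq_len(n)) {
    k <- kind[i]; s <- seq[i]; f5 <- flank5[i]; f3 <- flank3[i]
    L <- nchar(s)
    if (L < 1L || !k %in% c("INS", "DEL") ||
        !grepl("^[ACGT]+$", s) || !grepl("^[ACGT]*$", f5) ||
        !grepl("^[ACGT]*$", f3)) {
      stop("id_channel: invalid indel at entry ", i)
    }
    if (L == 1L) {
      if (s %in% c("A", "G")) {
        s <- chartr("ACGT", "TGCA", s)
        tmp <- revcomp(f5); f5 <- revcomp(f3); f3 <- tmp
      }
      # homopolymer tracts are strand symmetric: count adjacent copies on
      # both flanks (strand normalization may have moved the run 5' of the
      # event, where a 3'-only count would miss it)
      f5_rev <- paste(rev(strsplit(f5, NULL)[[1]]), collapse = "")
      run <- repeat_units(s, f3) + repeat_units(s, f5_rev)
      if (k == "DEL") {
        out[i] <- paste0("1:Del:", s, ":", min(run, 5L))  # run+1 bases incl. deleted
      } else {
        out[i] <- paste0("1:Ins:", s, ":", min(run, 5L))
      }
    } else {
      u <- repeat_units(s, f3)
      Lc <- min(L, 5L)
      if (k == "INS") {
        out[i] <- paste0(Lc, ":Ins:R:", min(u, 5L))
      } else if (u >= 1L) {
        out[i] <- paste0(Lc, ":Del:R:", min(u, 5L))  # u+1 units incl. deleted copy
      } else {
        mh <- mh_length(s, f5, f3)
        if (mh >= 1L) {
          out[i] <- paste0(Lc, ":Del:M:", min(mh, L - 1L, 5L))
        } else {
          out[i] <- paste0(Lc, ":Del:R:0")
        }
      }
    }
  }
  out
}

#' Flag frameshift-prone indels at microsatellite tracts
#'
#' TRUE when the event lies in a repeat tract of at least `min_units` units
#' (for homopolymers, run length counted in bases). The tract includes the
#' event's own copy plus adjacent copies on the 3' flank.
#'
#' @param kind,seq,flank3 As in [id_channel()].
#' @param min_units Tract size threshold (default 5).
#' @return Logical vector.
#' @export
microsatellite_frameshift_flag <- function(kind, seq, flank3, min_units = 5L) {
  units <- repeat_units(seq, flank3) + 1L
  units >= min_units
}

#' Build per-branch spectrum matrices
#'
#' Branches with fewer than `min_mutations` classified mutations are excluded;
#' branches with more than `cap` are randomly subsampled to `cap` (seeded), so
#' the capped spectrum is unbiased in expectation.
#'
#' @param channel Channel label per mutation.
#' @param branch Branch id per mutation (same length).
#' @param labels Channel order, e.g. [sbs96_labels()] or [id83_labels()].
#' @param min_mutations Minimum mutations for a branch row (default 100).
#' @param cap Maximum mutations per branch row (default 2500).
#' @param seed Integer seed for the subsampling.
#' @param patient Optional patient id per mutation (hierarchy metadata).
#' @return List with `counts` (branch x channel integer matrix), `patient`
#'   (named vector, patient per retained branch) and `excluded` (branch ids
#'   below the inclusion threshold).
#' @export
branch_spectra <- function(channel, branch, labels,
                           min_mutations = 100L, cap = 2500L, seed = 1L,
                           patient = NULL) {
  stopifnot(length(channel) == length(branch))
  bad <- !channel %in% labels
  if (any(bad)) stop("branch_spectra: unknown channel labels")
  branch <- as.character(branch)
  tab <- table(branch)
  keep <- names(tab)[tab >= min_mutations]
  excluded <- setdiff(names(tab), keep)
  counts <- matrix(0L, nrow = length(keep), ncol = length(labels),
                   dimnames = list(keep, labels))
  set.seed(seed)
  for (b in keep) {
    idx <- which(branch == b)
    if (length(idx) > cap) idx <- sample(idx, cap)
    counts[b, ] <- tabulate(match(channel[idx], labels), nbins = length(labels))
  }
  pat <- NULL
  if (!is.null(patient)) {
    pat <- vapply(keep, function(b) as.character(patient[match(b, branch)]), "")
    names(pat) <- keep
  }
  list(counts = counts, patient = pat, excluded = excluded)
}
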