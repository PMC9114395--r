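# Variant filtering: caller-annotation quality predicates, exact-binomial
# germline removal on aggregated counts, and the beta-binomial overdispersion
# (rho) filter that removes low-VAF artifacts shared across crypts.

default_quality_rules <- function() {
  list(
    SBS = list(ASMD = list(op = ">=", value = 140), CLPM = list(op = "==", value = 0)),
    indel = list(Qual = list(op = ">=", value = 300),
                 site_depth = list(op = ">=", value = 15))
  )
}

#' Quality predicates on caller annotations
#'
#' A variant passes iff all rules for its kind hold. Defaults: SBS require
#' ASMD >= 140 and CLPM == 0; indels require Qual >= 300 and site depth >= 15.
#'
#' @param variants Variant data frame with a `kind` column (SBS/INS/DEL) and
#'   annotation columns named by the rules.
#' @param rules Named list (`SBS`, `indel`) of rules, each
#'   `list(op = ">="|"==", value = )`, keyed by annotation column.
#' @param on_missing "fail" (default): a variant whose annotation is missing
#'   fails; "skip": the rule is ignored for that variant.
#' @return Logical pass flag per variant.
#' @export
quality_filter <- function(variants, rules = default_quality_rules(),
                           on_missing = c("fail", "skip")) {
  on_missing <- match.arg(on_missing)
  pass <- rep(TRUE, nrow(variants))
  kind_rules <- ifelse(variants$kind == "SBS", "SBS", "indel")
  for (grp in unique(kind_rules)) {
    idx <- which(kind_rules == grp)
    for (key in names(rules[[grp]])) {
      r <- rules[[grp]][[key]]
      if (!key %in% names(variants)) {
        if (on_missing == "fail") pass[idx] <- FALSE
        next
      }
      x <- variants[[key]][idx]
      ok <- switch(r$op, ">=" = x >= r$value, "==" = x == r$value,
                   stop("quality_filter: unsupported op ", r$op))
      ok[is.na(ok)] <- on_missing == "skip"
      pass[idx] <- pass[idx] & ok
    }
  }
  pass
}

#' One-sided exact binomial germline test
#'
#' Probability of an aggregate alt count this low or lower under a germline
#' heterozygous site, P(X <= alt_sum | X ~ Binomial(depth_sum, p0)); exact,
#' no normal approximation. Small p-values mean the aggregate VAF is
#' significantly below p0, i.e. the variant is a candidate somatic mutation.
#'
#' @param alt_sum,depth_sum Aggregated alt and total read counts (vectorized).
#' @param p0 Null heterozygous fraction (default 0.5).
#' @return One-sided p-value(s).
#' @export
binomial_germline_test <- function(alt_sum, depth_sum, p0 = 0.5) {
  stopifnot(all(alt_sum >= 0), all(alt_sum <= depth_sum))
  if (any(depth_sum == 0)) {
    stop("binomial_germline_test: undefined for depth_sum = 0")
  }
  stats::pbinom(alt_sum, depth_sum, p0)
}

#' Flag germline variants in a per-patient count matrix
#'
#' Counts are aggregated over samples without copy-number variants; one-sided
#' exact binomial p-values are Benjamini-Hochberg adjusted; variants whose
#' adjusted p is >= `alpha` are flagged germline (only variants with aggregate
#' VAF significantly below `p0` are retained as candidate somatic).
#'
#' @param matrix A `count_matrix` for one patient.
#' @param alpha Adjusted-p threshold (default 1e-5).
#' @param p0 Null heterozygous fraction.
#' @return Data frame: id, alt_sum, depth_sum, germline_p, germline_q,
#'   germline (logical).
#' @export
classify_germline <- function(matrix, alpha = 1e-5, p0 = 0.5) {
  use <- !matrix$samples$cnv
  if (!any(use)) stop("classify_germline: no CNV-free samples to aggregate")
  alt_sum <- rowSums(matrix$alt[, use, drop = FALSE])
  depth_sum <- rowSums(matrix$depth[, use, drop = FALSE])
  p <- ifelse(depth_sum > 0, stats::pbinom(alt_sum, depth_sum, p0), NA_real_)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(id = matrix$variants$id, alt_sum = alt_sum,
             depth_sum = depth_sum, germline_p = p, germline_q = q,
             germline = is.na(q) | q >= alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Beta-binomial log-pmf with mean mu and overdispersion rho
# (alpha = mu(1-rho)/rho, beta = (1-mu)(1-rho)/rho).
dbetabinom_log <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Maximum-likelihood beta-binomial overdispersion (rho)
#'
#' The beta-binomial mean is plugged in as the pooled alt fraction and rho is
#' maximized by a bounded one-dimensional search (coarse bracket followed by
#' golden-section refinement, tolerance 1e-8).
#'
#' @param alt,depth Integer vectors over samples (length >= 2, depth > 0 in at
#'   least 2 samples).
#' @param lower,upper Search bounds in (0, 1).
#' @return rho estimate in `(lower, upper)`.
#' @export
estimate_rho <- function(alt, depth, lower = 1e-6, upper = 1 - 1e-6) {
  stopifnot(length(alt) == length(depth), length(alt) >= 2)
  if (sum(depth > 0) < 2) stop("estimate_rho: need depth > 0 in >= 2 samples")
  use <- depth > 0
  alt <- alt[use]; depth <- depth[use]
  mu <- sum(alt) / sum(depth)
  mu <- min(max(mu, 1e-6), 1 - 1e-6)
  nll <- function(rho) -sum(dbetabinom_log(alt, depth, mu, rho))
  # coarse bracket (log-spaced; the likelihood is effectively unimodal in rho
  # but can be very flat near the bounds)
  grid <- unique(c(lower, exp(seq(log(lower), log(0.5), length.out = 40)),
                   seq(0.5, upper, length.out = 20), upper))
  vals <- vapply(grid, nll, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(grid[i])
  opt <- stats::optimize(nll, interval = c(lo, hi), tol = 1e-8)
  if (vals[i] < opt$objective) grid[i] else opt$minimum
}

#' Overdispersion keep/drop decision
#'
#' Shared artifacts have uniformly low VAF across crypts (low rho); true
#' somatic variants concentrate in a subset of crypts (high rho). Variants
#' with rho strictly below the threshold are dropped: 0.1 for SBS, 0.2 for
#' indels.
#'
#' @param rho Estimated overdispersion (vectorized).
#' @param kind "SBS" or "indel" (vectorized or scalar).
#' @param thresholds Named thresholds (default c(SBS = 0.1, indel = 0.2)).
#' @return Logical: TRUE = keep.
#' @export
overdispersion_filter <- function(rho, kind,
                                  thresholds = c(SBS = 0.1, indel = 0.2)) {
  kind <- ifelse(kind == "SBS", "SBS", "indel")
  rho >= thresholds[kind]
}

#' Per-crypt clonality summary
#'
#' Median VAF over somatic variants present in the crypt (>= 1 alt read),
#' a VAF histogram binned at 0.05, and the clonality flag (median VAF > 0.3).
#'
#' @param matrix A `count_matrix`.
#' @param sample Sample id.
#' @param somatic_ids Variant ids with somatic status (defaults to all rows).
#' @return list(median_vaf, histogram, is_clonal).
#' @export
clonality_summary <- function(matrix, sample, somatic_ids = NULL) {
  s <- match(sample, matrix$samples$id)
  if (is.na(s)) stop("clonality_summary: unknown sample ", sample)
  ids <- if (is.null(somatic_ids)) matrix$variants$id else somatic_ids
  i <- match(ids, matrix$variants$id)
  alt <- matrix$alt[i, s]
  depth <- matrix$depth[i, s]
  present <- alt >= 1 & depth > 0
  vaf <- alt[present] / depth[present]
  if (length(vaf) == 0) {
    warning("clonality_summary: no somatic variants present in ", sample)
    return(list(median_vaf = NA_real_, histogram = NULL, is_clonal = NA))
  }
  breaks <- seq(0, 1, by = 0.05)
  h <- graphics::hist(pmin(vaf, 1), breaks = breaks, plot = FALSE)
  list(median_vaf = stats::median(vaf), histogram = h,
       is_clonal = stats::median(vaf) > 0.3)
}

#' Full per-patient variant filtering
#'
#' Applies, in order, the annotation quality predicates, the exact-binomial
#' germline test (BH-adjusted) and the beta-binomial rho filter. Every variant
#' receives exactly one status: `low_quality`, `germline`, `artifact` or
#' `somatic`; rho is estimated only for variants passing the germline test.
#'
#' @param matrix A `count_matrix` for one patient.
#' @param alpha Adjusted-p threshold for the germline test.
#' @param rho_thresholds Named rho thresholds (SBS, indel).
#' @param rules Quality rules (see [quality_filter()]).
#' @return Data frame: id, kind, germline_p, germline_q, rho, status.
#' @export
filter_variants <- function(matrix, alpha = 1e-5,
                            rho_thresholds = c(SBS = 0.1, indel = 0.2),
                            rules = default_quality_rules()) {
  v <- matrix$variants
  n <- nrow(v)
  status <- rep(NA_character_, n)
  qpass <- quality_filter(v, rules)
  status[!qpass] <- "low_quality"

  germ <- classify_germline(matrix, alpha = alpha)
  status[qpass & germ$germline] <- "germline"

  rho <- rep(NA_real_, n)
  cand <- which(is.na(status))
  for (i in cand) {
    rho[i] <- estimate_rho(matrix$alt[i, ], matrix$depth[i, ])
  }
  kind <- ifelse(v$kind == "SBS", "SBS", "indel")
  keep <- overdispersion_filter(rho[cand], kind[cand], rho_thresholds)
  status[cand] <- ifelse(keep, "somatic", "artifact")

  data.frame(id = v$id, kind = v$kind, germline_p = germ$germline_p,
             germline_q = germ$germline_q, rho = rho, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}
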