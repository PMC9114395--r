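# Per-crypt mutation burdens and per-year rates, tissue medians, the
# LS-vs-wild-type mixed-model likelihood-ratio test, tumour/normal fold
# statistics, and driver-mutation flagging and summary.

#' Per-crypt burden table
#'
#' A crypt's burden is the number of variants assigned to branches on its
#' root-to-leaf path (mutations placed on the root trunk count for every
#' crypt); the per-year rate is burden / age.
#'
#' @param tree The patient's `ctree`.
#' @param samples Sample metadata data frame (id, patient, tissue, crypt_type,
#'   age, optionally cohort).
#' @param sbs_assignment Assignment from [assign_variants_ml()] on SBS.
#' @param id_assignment Optional assignment for indels.
#' @param sensitivity Burden divisor for a sensitivity correction (default 1,
#'   i.e. uncorrected).
#' @return Data frame, one row per crypt: burdens, ages and per-year rates.
#' @export
burden_table <- function(tree, samples, sbs_assignment, id_assignment = NULL,
                         sensitivity = 1) {
  if (any(is.na(samples$age))) stop("burden_table: missing ages")
  path_count <- function(assignment) {
    if (is.null(assignment)) return(rep(0L, tree$nleaf))
    tab <- table(assignment$assignment$branch)
    vapply(seq_len(tree$nleaf), function(leaf) {
      cnt <- 0L
      v <- leaf
      while (v != tree$nleaf + 1L) {
        cnt <- cnt + (if (as.character(v) %in% names(tab)) tab[[as.character(v)]] else 0L)
        v <- tree$parent[v]
      }
      cnt + (if ("root" %in% names(tab)) tab[["root"]] else 0L)
    }, 0L)
  }
  sbs <- path_count(sbs_assignment) / sensitivity
  id <- path_count(id_assignment) / sensitivity
  i <- match(tree$labels, samples$id)
  out <- data.frame(
    id = tree$labels, patient = samples$patient[i], tissue = samples$tissue[i],
    crypt_type = samples$crypt_type[i], age = samples$age[i],
    cohort = if ("cohort" %in% names(samples)) samples$cohort[i] else NA_character_,
    sbs_burden = sbs, id_burden = id,
    stringsAsFactors = FALSE
  )
  out$sbs_rate <- out$sbs_burden / out$age
  out$id_rate <- out$id_burden / out$age
  out
}

#' Median per-year mutation rates by tissue
#'
#' @param table A burden table.
#' @param group_by Grouping column (default "tissue").
#' @param crypt_types Crypt types to include (default "survey").
#' @return Data frame: group, n, median sbs_rate and id_rate.
#' @export
tissue_median_rates <- function(table, group_by = "tissue",
                                crypt_types = "survey") {
  t <- table[table$crypt_type %in% crypt_types, , drop = FALSE]
  if (nrow(t) == 0) {
    warning("tissue_median_rates: no crypts of the requested type")
    return(data.frame(group = character(0), n = integer(0),
                      sbs_rate = numeric(0), id_rate = numeric(0)))
  }
  g <- split(t, t[[group_by]])
  data.frame(
    group = names(g),
    n = vapply(g, nrow, 0L),
    sbs_rate = vapply(g, function(d) stats::median(d$sbs_rate), 0),
    id_rate = vapply(g, function(d) stats::median(d$id_rate), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mixed-model likelihood-ratio test for a cohort effect on burden
#'
#' Null model: burden ~ age with a per-patient random intercept; alternative
#' adds a cohort fixed effect. Both are fit by maximum likelihood and compared
#' with a likelihood-ratio test on 1 df.
#'
#' @param table Burden table for the combined cohorts, with a `cohort` column.
#' @param response "sbs_burden" or "id_burden" (or any numeric column).
#' @return list(statistic, p_value, coefficients, singular).
#' @export
lmm_lrt <- function(table, response = "sbs_burden") {
  stopifnot(response %in% names(table), "cohort" %in% names(table))
  if (length(unique(table$cohort)) < 2) stop("lmm_lrt: need both cohorts")
  table$.y <- table[[response]]
  m0 <- lme4::lmer(.y ~ age + (1 | patient), data = table, REML = FALSE)
  m1 <- lme4::lmer(.y ~ age + cohort + (1 | patient), data = table,
                   REML = FALSE)
  stat <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                        as.numeric(stats::logLik(m0))))
  singular <- lme4::isSingular(m0) || lme4::isSingular(m1)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       coefficients = lme4::fixef(m1),
       singular = singular)
}

#' Fold difference between group median burdens
#'
#' @param table Burden table.
#' @param group_a,group_b Crypt types (e.g. "tumour" vs "survey").
#' @return list(sbs_fold, id_fold, n_a, n_b).
#' @export
fold_difference <- function(table, group_a = "tumour", group_b = "survey") {
  a <- table[table$crypt_type %in% group_a, , drop = FALSE]
  b <- table[table$crypt_type %in% group_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("fold_difference: empty group")
  med <- function(x) stats::median(x)
  if (med(b$sbs_burden) == 0 || med(b$id_burden) == 0) {
    stop("fold_difference: zero median in denominator group")
  }
  list(sbs_fold = med(a$sbs_burden) / med(b$sbs_burden),
       id_fold = med(a$id_burden) / med(b$id_burden),
       n_a = nrow(a), n_b = nrow(b))
}

#' Flag driver mutations by rule
#'
#' Rules in priority order: (1) (gene, change) in the known-driver list;
#' (2) truncating consequence (nonsense, frameshift, splice) in a tumour
#' suppressor; (3) missense at a listed hotspot position. Synonymous and
#' other consequences are never flagged. Frameshift calls are annotated with
#' the microsatellite flag (repeat tract >= 5 units).
#'
#' @param variants Data frame with columns id, gene, change, consequence and,
#'   for indels, indel_seq/flank3 (for the microsatellite flag) plus a sample
#'   (crypt) column.
#' @param known_list Character vector of "GENE CHANGE" known driver events.
#' @param tsg_list Character vector of tumour suppressor genes.
#' @param hotspot_list Character vector of "GENE POS" hotspot residues; the
#'   position is parsed from the change string (e.g. "G12V" -> 12).
#' @return Data frame of driver calls: id, sample, gene, change, consequence,
#'   rule_fired, microsatellite_flag.
#' @export
flag_drivers <- function(variants, known_list = character(0),
                         tsg_list = character(0),
                         hotspot_list = character(0)) {
  need <- c("id", "gene", "change", "consequence")
  if (!all(need %in% names(variants))) {
    stop("flag_drivers: variants need columns ",
         paste(setdiff(need, names(variants)), collapse = ", "))
  }
  truncating <- c("nonsense", "frameshift", "splice")
  key <- paste(variants$gene, variants$change)
  pos <- suppressWarnings(as.integer(gsub("[^0-9]", "", variants$change)))
  hkey <- paste(variants$gene, pos)

  rule <- rep(NA_character_, nrow(variants))
  rule[variants$consequence == "missense" & hkey %in% hotspot_list] <- "hotspot-missense"
  rule[variants$consequence %in% truncating & variants$gene %in% tsg_list] <- "truncating-TSG"
  rule[key %in% known_list] <- "known"
  rule[variants$consequence %in% c("synonymous", "other")] <- NA_character_

  hit <- !is.na(rule)
  calls <- variants[hit, intersect(c("id", "sample", "gene", "change",
                                     "consequence"), names(variants)),
                    drop = FALSE]
  calls$rule_fired <- rule[hit]
  ms <- rep(FALSE, nrow(calls))
  fs <- calls$consequence == "frameshift"
  if (any(fs) && all(c("indel_seq", "flank3") %in% names(variants))) {
    vi <- match(calls$id[fs], variants$id)
    ok <- !is.na(variants$indel_seq[vi])
    ms[fs][ok] <- microsatellite_frameshift_flag(
      kind = "DEL", seq = variants$indel_seq[vi][ok],
      flank3 = variants$flank3[vi][ok])
  }
  calls$microsatellite_flag <- ms
  rownames(calls) <- NULL
  calls
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize driver calls over a cohort of crypts
#'
#' @param calls Driver calls with a `sample` column linking each call to a
#'   crypt.
#' @param n_crypts_total Total number of crypts screened.
#' @return list of counts and percentages: crypts with >= 1, exactly 1 and
#'   exactly 2 drivers, unique events (gene, change) and unique genes.
#'   Percentages are 100 x count / total, rounded half-up to 1 decimal.
#' @export
driver_summary <- function(calls, n_crypts_total) {
  if (n_crypts_total <= 0) stop("driver_summary: n_crypts_total must be > 0")
  per_crypt <- if (nrow(calls)) table(calls$sample) else table(character(0))
  n_ge1 <- sum(per_crypt >= 1)
  n_1 <- sum(per_crypt == 1)
  n_2 <- sum(per_crypt == 2)
  pct <- function(k) round_half_up(100 * k / n_crypts_total, 1)
  list(
    n_crypts = n_crypts_total,
    crypts_with_driver = n_ge1, pct_with_driver = pct(n_ge1),
    crypts_one_driver = n_1, pct_one_driver = pct(n_1),
    crypts_two_drivers = n_2, pct_two_drivers = pct(n_2),
    unique_events = if (nrow(calls)) length(unique(paste(calls$gene, calls$change))) else 0L,
    unique_genes = if (nrow(calls)) length(unique(calls$gene)) else 0L
  )
}

#' Simulate per-crypt burden tables for cohort comparisons
#'
#' Two generative models. `family = "gaussian"` draws burdens from the mixed
#' model's own assumptions (linear-in-age mean, additive Gaussian per-patient
#' intercept and residual) and is the appropriate generator for calibration
#' experiments — a likelihood-ratio test is only guaranteed calibrated when
#' the null model is correctly specified. `family = "poisson"` uses Poisson
#' counts with a multiplicative log-normal patient effect, a more realistic
#' count model used for power checks.
#'
#' @param n_patients Patients per cohort (vector of 2 or scalar).
#' @param crypts_per_patient Crypts sampled per patient.
#' @param rates Per-year mutation rate per cohort (length 2).
#' @param age_range Patient ages drawn uniformly in this range.
#' @param patient_sd SD of the patient effect: on the log scale for "poisson"
#'   (multiplicative); for "gaussian" the patient intercept sd is
#'   `patient_sd * rates[1] * mean(age_range)` burden units and the residual
#'   sd is half that.
#' @param family "poisson" (default) or "gaussian".
#' @param seed Integer seed.
#' @return A burden table with cohorts "A" and "B".
#' @export
simulate_burden_cohort <- function(n_patients = c(10L, 10L),
                                   crypts_per_patient = 5L,
                                   rates = c(55, 55),
                                   age_range = c(25, 75),
                                   patient_sd = 0.2,
                                   family = c("poisson", "gaussian"),
                                   seed = 1L) {
  family <- match.arg(family)
  set.seed(seed)
  if (length(n_patients) == 1L) n_patients <- rep(n_patients, 2L)
  sd_pat <- patient_sd * rates[1] * mean(age_range)
  rows <- list()
  for (co in 1:2) {
    for (p in seq_len(n_patients[co])) {
      age <- stats::runif(1, age_range[1], age_range[2])
      if (family == "poisson") {
        eff <- exp(stats::rnorm(1, 0, patient_sd))
        lam <- rates[co] * age * eff
        burden <- stats::rpois(crypts_per_patient, lam)
      } else {
        lam <- rates[co] * age
        mu <- lam + stats::rnorm(1, 0, sd_pat)
        burden <- mu + stats::rnorm(crypts_per_patient, 0, sd_pat / 2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("c%d_%d_%d", co, p, seq_len(crypts_per_patient)),
        patient = sprintf("P%d_%02d", co, p),
        tissue = "colon", crypt_type = "survey", age = age,
        cohort = c("A", "B")[co],
        sbs_burden = burden, id_burden = stats::rpois(crypts_per_patient, lam / 25),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$sbs_rate <- out$sbs_burden / out$age
  out$id_rate <- out$id_burden / out$age
  out
}
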