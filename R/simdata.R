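# Synthetic crypt cohorts: a rooted lineage tree over crypts, somatic
# mutations drawn per branch from signature-specific channel distributions,
# germline SNPs at VAF ~0.5 in all crypts, shared low-VAF low-overdispersion
# artifact sites, and ~30X read counts per variant x crypt cell. Ground truth
# is returned for every downstream stage.

#' Simulation configuration
#'
#' @param n_crypts Number of normal crypts (>= 2).
#' @param patient_age Age at sampling, years.
#' @param depth_mean Mean sequencing depth per cell (Poisson).
#' @param clonal_vaf Expected VAF of a clonal heterozygous variant in carrier
#'   crypts (default 0.5).
#' @param seq_error Per-read alt probability at sites a crypt does not carry.
#' @param n_germline Number of germline heterozygous SNPs.
#' @param n_artifact Number of shared artifact sites.
#' @param artifact_vaf_mean Mean VAF of artifact sites (all crypts).
#' @param artifact_rho Beta-binomial overdispersion of artifact sites, in (0,1).
#' @param signature_activities Named vector: SBS signature -> mutations/year.
#' @param id_signature_activities Named vector: ID signature -> mutations/year
#'   (NULL for no indels).
#' @param embryonic_mutation_count Mutations distributed over early internal
#'   branches (shared by crypt subsets).
#' @param dev_frac Fraction of lifetime in which crypt lineages diverge; all
#'   internal splits happen before this depth (default 0.02, i.e. lineage
#'   divergence is essentially developmental).
#' @param mmrd_crypt Optional list(crypt, multiplier, mix, id_mix): one crypt
#'   whose terminal branch is hypermutated by `multiplier` with signature mix
#'   overridden.
#' @param tumour_clade Optional list(n_crypts, trunk_mutations, trunk_mix,
#'   branch_mutations, branch_mix, trunk_id_mutations, branch_id_mutations,
#'   id_mix, mrca_frac): a tumour clade attached at the root whose trunk
#'   carries `trunk_mutations` shared mutations.
#' @param patient,tissue Metadata for the sample table.
#' @param seed Default seed used by `simulate_cohort`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_crypts = 8L,
                       patient_age = 50,
                       depth_mean = 30,
                       clonal_vaf = 0.5,
                       seq_error = 0.001,
                       n_germline = 2000L,
                       n_artifact = 500L,
                       artifact_vaf_mean = 0.15,
                       artifact_rho = 0.02,
                       signature_activities = NULL,
                       id_signature_activities = NULL,
                       embryonic_mutation_count = 30L,
                       dev_frac = 0.02,
                       mmrd_crypt = NULL,
                       tumour_clade = NULL,
                       patient = "P1",
                       tissue = "colon",
                       seed = 1L) {
  stopifnot(n_crypts >= 2L, patient_age > 0, depth_mean > 0,
            clonal_vaf > 0, clonal_vaf <= 1,
            seq_error >= 0, seq_error < 1,
            n_germline >= 0L, n_artifact >= 0L,
            artifact_vaf_mean > 0, artifact_vaf_mean < 1,
            artifact_rho > 0, artifact_rho < 1,
            embryonic_mutation_count >= 0L,
            dev_frac > 0, dev_frac < 1)
  if (!is.null(signature_activities)) {
    stopifnot(!is.null(names(signature_activities)),
              all(signature_activities >= 0))
  }
  if (!is.null(id_signature_activities)) {
    stopifnot(!is.null(names(id_signature_activities)),
              all(id_signature_activities >= 0))
  }
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

#' Simulate a crypt lineage tree
#'
#' Random resolved rooted topology; internal splits are placed within the
#' first `dev_frac` of the lifetime (shared-early / private-late structure),
#' so branch time-fractions are positive and every root-to-leaf path sums
#' to 1.
#'
#' @param n_crypts Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param dev_frac Developmental window as a fraction of lifetime.
#' @param labels Optional leaf labels (default crypt01, crypt02, ...).
#' @return A `ctree` with `$frac` branch time-fractions and a `depth`
#'   attribute (node depths in [0, 1]).
#' @export
simulate_tree <- function(n_crypts, seed = 1L, dev_frac = 0.02,
                          labels = NULL) {
  if (n_crypts < 2L) stop("simulate_tree: n_crypts must be >= 2")
  set.seed(seed)
  if (is.null(labels)) labels <- sprintf("crypt%02d", seq_len(n_crypts))
  tree <- random_topology(labels)
  assign_depths(tree, dev_frac)
}

# Assign node depths: internal nodes within (parent_depth, upper), leaves at 1.
# `upper` per node defaults to dev_frac; callers may pass a vector (tumour
# clades use a late window). Uses the current RNG state.
assign_depths <- function(tree, dev_frac, upper = NULL, fixed = NULL) {
  nn <- length(tree$parent)
  n <- tree$nleaf
  root <- n + 1L
  if (is.null(upper)) upper <- rep(dev_frac, nn)
  depth <- rep(NA_real_, nn)
  depth[root] <- 0
  for (v in rev(ct_postorder(tree))) {  # preorder: parents first
    if (v == root) next
    d_p <- depth[tree$parent[v]]
    if (v <= n) {
      depth[v] <- 1
    } else if (!is.null(fixed) && !is.na(fixed[v])) {
      depth[v] <- fixed[v]
    } else {
      depth[v] <- d_p + (upper[v] - d_p) * stats::runif(1, min = 0.05, max = 0.95)
    }
  }
  frac <- depth - depth[pmax(tree$parent, 1L)]
  frac[root] <- NA_real_
  tree$frac <- frac
  attr(tree, "depth") <- depth
  tree
}

# --- channel realization -----------------------------------------------------

rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

base_not <- function(avoid) sample(setdiff(BASES, avoid), 1L)

# Turn an SBS96 label into (ref, alt, context); a random half are emitted on
# the purine strand so the classifier's strand normalization is exercised.
realize_sbs_channel <- function(labels) {
  n <- length(labels)
  ref <- substr(labels, 3, 3)
  alt <- substr(labels, 5, 5)
  ctx <- paste0(substr(labels, 1, 1), ref, substr(labels, 7, 7))
  flip <- stats::runif(n) < 0.5
  ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- revcomp(ctx[flip])
  data.frame(ref = ref, alt = alt, context = ctx, stringsAsFactors = FALSE)
}

# Turn one ID83 label into an indel (kind, seq, flank5, flank3) that
# id_channel() maps back to the same label.
realize_id_channel1 <- function(label) {
  p <- strsplit(label, ":", fixed = TRUE)[[1]]
  Lf <- as.integer(p[1]); type <- p[2]; cls <- p[3]; fld <- as.integer(p[4])
  kind <- if (type == "Del") "DEL" else "INS"
  if (cls %in% c("C", "T")) {
    base <- cls
    copies <- if (fld >= 5L) sample(5:7, 1L) else fld
    f3 <- paste0(strrep(base, copies), base_not(base), rand_bases(8))
    f5 <- paste0(rand_bases(8), base_not(base))
    seq <- base
    if (stats::runif(1) < 0.5) {  # emit on the purine strand
      seq <- chartr("ACGT", "TGCA", seq)
      tmp <- revcomp(f3); f3 <- revcomp(f5); f5 <- tmp
    }
    return(list(kind = kind, seq = seq, flank5 = f5, flank3 = f3))
  }
  L <- if (Lf >= 5L) sample(5:7, 1L) else Lf
  repeat {
    seq <- rand_bases(L)
    s <- strsplit(seq, NULL)[[1]]
    if (s[1] != s[L]) break
  }
  s1 <- substr(seq, 1, 1)
  sL <- substr(seq, L, L)
  if (cls == "R") {
    copies <- if (fld >= 5L) sample(5:7, 1L) else fld
    if (copies == 0L) {
      f3 <- paste0(base_not(s1), rand_bases(3 * L + 6))
    } else {
      f3 <- paste0(strrep(seq, copies), base_not(s1), rand_bases(2 * L + 6))
    }
    f5 <- paste0(rand_bases(2 * L + 6), base_not(sL))
  } else {  # microhomology deletion
    m <- fld
    if (m >= 5L) L <- max(L, 6L)
    if (m > L - 1L) L <- m + 1L
    repeat {
      seq <- rand_bases(L)
      s <- strsplit(seq, NULL)[[1]]
      if (s[1] != s[L]) break
    }
    nxt <- base_not(substr(seq, m + 1L, m + 1L))
    f3 <- paste0(substr(seq, 1, m), nxt, rand_bases(2 * L + 6))
    f5 <- paste0(rand_bases(2 * L + 6), base_not(substr(seq, L, L)))
  }
  list(kind = kind, seq = seq, flank5 = f5, flank3 = f3)
}

realize_id_channel <- function(labels) {
  rows <- lapply(labels, realize_id_channel1)
  data.frame(kind = vapply(rows, `[[`, "", "kind"),
             seq = vapply(rows, `[[`, "", "seq"),
             flank5 = vapply(rows, `[[`, "", "flank5"),
             flank3 = vapply(rows, `[[`, "", "flank3"),
             stringsAsFactors = FALSE)
}

# --- mutation drawing --------------------------------------------------------

draw_channels <- function(n, mix, catalogue) {
  if (n == 0L) return(list(sig = character(0), channel = character(0)))
  missing <- setdiff(names(mix), catalogue$names)
  if (length(missing)) {
    stop("unknown signature name(s): ", paste(missing, collapse = ", "))
  }
  sig <- sample(names(mix), n, replace = TRUE, prob = mix / sum(mix))
  channel <- vapply(sig, function(s) {
    sample(catalogue$labels, 1L, prob = catalogue$vectors[, s])
  }, "")
  list(sig = unname(sig), channel = unname(channel))
}

#' Draw somatic mutations on a crypt tree
#'
#' Per branch, the somatic mutation count of each signature is Poisson with
#' mean `branch time-fraction x age x activity`; each mutation's channel is
#' drawn from its generating signature's probability vector and realized as a
#' concrete variant (trinucleotide context for SBS; indel with flanking
#' sequence for ID) such that the spectra classifiers re-derive the channel.
#'
#' @param tree A `ctree` with branch fractions (from [simulate_tree()]).
#' @param config A `sim_config`.
#' @param catalogue SBS `sig_catalogue` (96 channels).
#' @param id_catalogue Optional ID `sig_catalogue` (83 channels).
#' @param seed Integer seed.
#' @param overrides Optional named list (by branch node id) of per-branch
#'   overrides: list(mean_sbs, mix_sbs, mean_id, mix_id).
#' @param embryonic_branches Internal branch nodes eligible for embryonic
#'   mutations (default: all internal non-root nodes).
#' @return list(variants = data.frame, truth = `sim_truth`).
#' @export
draw_mutations <- function(tree, config, catalogue, id_catalogue = NULL,
                           seed = config$seed, overrides = NULL,
                           embryonic_branches = NULL) {
  set.seed(seed)
  n <- tree$nleaf
  branches <- setdiff(seq_along(tree$parent), n + 1L)
  age <- config$patient_age
  act <- config$signature_activities
  id_act <- config$id_signature_activities

  if (is.null(embryonic_branches)) {
    embryonic_branches <- branches[branches > n + 1L]
  }

  branch_of <- character(0); sig_of <- character(0)
  chan_of <- character(0); kind_class <- character(0)

  add <- function(b, k, mix, cat) {
    if (k == 0L) return(invisible(NULL))
    d <- draw_channels(k, mix, cat)
    branch_of <<- c(branch_of, rep(as.character(b), k))
    sig_of <<- c(sig_of, d$sig)
    chan_of <<- c(chan_of, d$channel)
    kind_class <<- c(kind_class, rep(if (length(cat$labels) == 96L) "SBS" else "ID", k))
    invisible(NULL)
  }

  for (b in branches) {
    ov <- if (!is.null(overrides)) overrides[[as.character(b)]] else NULL
    # SBS
    if (!is.null(ov) && !is.null(ov$mean_sbs)) {
      add(b, stats::rpois(1, ov$mean_sbs), ov$mix_sbs, catalogue)
    } else if (!is.null(act)) {
      for (s in names(act)) {
        add(b, stats::rpois(1, tree$frac[b] * age * act[[s]]),
            stats::setNames(1, s), catalogue)
      }
    }
    # ID
    if (!is.null(id_catalogue)) {
      if (!is.null(ov) && !is.null(ov$mean_id)) {
        add(b, stats::rpois(1, ov$mean_id), ov$mix_id, id_catalogue)
      } else if (!is.null(id_act)) {
        for (s in names(id_act)) {
          add(b, stats::rpois(1, tree$frac[b] * age * id_act[[s]]),
              stats::setNames(1, s), id_catalogue)
        }
      }
    }
  }

  # embryonic mutations: uniform over early internal branches
  if (config$embryonic_mutation_count > 0L && length(embryonic_branches) > 0L &&
      !is.null(act)) {
    eb <- embryonic_branches[sample.int(length(embryonic_branches),
                                        config$embryonic_mutation_count,
                                        replace = TRUE)]
    for (b in unique(eb)) add(b, sum(eb == b), act, catalogue)
  }

  n_som <- length(branch_of)
  n_g <- config$n_germline
  n_a <- config$n_artifact
  # germline SNPs and shared artifacts: uniform SBS channels
  g_chan <- if (n_g) sample(catalogue$labels, n_g, replace = TRUE) else character(0)
  a_chan <- if (n_a) sample(catalogue$labels, n_a, replace = TRUE) else character(0)

  chan_all <- c(chan_of, g_chan, a_chan)
  kind_all <- c(kind_class, rep("SBS", n_g + n_a))
  class_all <- c(rep("somatic", n_som), rep("germline", n_g),
                 rep("artifact", n_a))
  V <- length(chan_all)
  ids <- sprintf("v%06d", seq_len(V))

  variants <- data.frame(
    id = ids,
    chrom = sample(1:22, V, replace = TRUE),
    pos = sample.int(1e8, V, replace = TRUE),
    ref = NA_character_, alt = NA_character_, kind = kind_all,
    context = NA_character_, indel_seq = NA_character_,
    flank5 = NA_character_, flank3 = NA_character_,
    channel = chan_all, class = class_all,
    ASMD = round(stats::runif(V, 140, 170), 1), CLPM = 0,
    Qual = round(stats::runif(V, 300, 600)),
    stringsAsFactors = FALSE
  )
  is_sbs <- kind_all == "SBS"
  if (any(is_sbs)) {
    r <- realize_sbs_channel(chan_all[is_sbs])
    variants$ref[is_sbs] <- r$ref
    variants$alt[is_sbs] <- r$alt
    variants$context[is_sbs] <- r$context
  }
  if (any(!is_sbs)) {
    r <- realize_id_channel(chan_all[!is_sbs])
    variants$kind[!is_sbs] <- r$kind
    variants$indel_seq[!is_sbs] <- r$seq
    variants$flank5[!is_sbs] <- r$flank5
    variants$flank3[!is_sbs] <- r$flank3
    # VCF-style ref/alt with the last 5' flank base as anchor
    anchor <- substr(r$flank5, nchar(r$flank5), nchar(r$flank5))
    del <- r$kind == "DEL"
    variants$ref[!is_sbs] <- ifelse(del, paste0(anchor, r$seq), anchor)
    variants$alt[!is_sbs] <- ifelse(del, anchor, paste0(anchor, r$seq))
  }

  som_ids <- ids[seq_len(n_som)]
  branch_variants <- split(som_ids, branch_of)
  truth <- list(
    tree = tree,
    branch_variants = branch_variants,
    variant_class = stats::setNames(class_all, ids),
    variant_signature = stats::setNames(sig_of, som_ids),
    seed = seed
  )
  class(truth) <- "sim_truth"
  list(variants = variants, truth = truth)
}

#' Sample per-crypt read counts
#'
#' Depth per cell is Poisson around `depth_mean`. Crypts descending from a
#' somatic variant's branch draw alt reads as binomial(depth, clonal_vaf) and
#' all others binomial(depth, seq_error); germline sites use `clonal_vaf` in
#' every crypt; artifact sites draw a per-cell VAF from a beta distribution
#' with mean `artifact_vaf_mean` and overdispersion `artifact_rho`, in every
#' crypt.
#'
#' @param truth A `sim_truth` from [draw_mutations()].
#' @param config The `sim_config`.
#' @param seed Integer seed.
#' @return list(alt, depth): integer matrices, variants x crypts.
#' @export
sample_reads <- function(truth, config, seed = config$seed) {
  set.seed(seed)
  tree <- truth$tree
  ids <- names(truth$variant_class)
  V <- length(ids)
  S <- tree$nleaf
  leafsets <- ct_leafsets(tree)

  depth <- matrix(stats::rpois(V * S, config$depth_mean), nrow = V,
                  dimnames = list(ids, tree$labels))
  alt <- matrix(stats::rbinom(V * S, depth, config$seq_error), nrow = V,
                dimnames = list(ids, tree$labels))

  # somatic carriers
  for (b in names(truth$branch_variants)) {
    vs <- truth$branch_variants[[b]]
    carriers <- leafsets[[as.integer(b)]]
    d <- depth[vs, carriers, drop = FALSE]
    alt[vs, carriers] <- stats::rbinom(length(d), d, config$clonal_vaf)
  }
  # germline: clonal VAF everywhere
  g <- names(truth$variant_class)[truth$variant_class == "germline"]
  if (length(g)) {
    d <- depth[g, , drop = FALSE]
    alt[g, ] <- stats::rbinom(length(d), d, config$clonal_vaf)
  }
  # artifacts: beta-binomial everywhere
  a <- names(truth$variant_class)[truth$variant_class == "artifact"]
  if (length(a)) {
    rho <- config$artifact_rho
    mu <- config$artifact_vaf_mean
    al <- mu * (1 - rho) / rho
    be <- (1 - mu) * (1 - rho) / rho
    d <- depth[a, , drop = FALSE]
    p <- stats::rbeta(length(d), al, be)
    alt[a, ] <- stats::rbinom(length(d), d, p)
  }
  list(alt = alt, depth = depth)
}

#' Simulate a full synthetic crypt cohort
#'
#' Orchestrates [simulate_tree()], [draw_mutations()] and [sample_reads()]
#' into a `count_matrix` plus ground truth, including the optional
#' MMR-deficient crypt and tumour clade.
#'
#' @param config A `sim_config`.
#' @param catalogue SBS `sig_catalogue`.
#' @param id_catalogue Optional ID `sig_catalogue`.
#' @param seed Integer seed (default `config$seed`).
#' @return List of class `sim_cohort`: `matrix` (a `count_matrix` over all
#'   variants), `truth` (a `sim_truth`) and `config`.
#' @export
simulate_cohort <- function(config, catalogue, id_catalogue = NULL,
                            seed = config$seed) {
  set.seed(seed)
  n_norm <- config$n_crypts
  tc <- config$tumour_clade
  crypt_type <- rep("survey", n_norm)
  norm_labels <- sprintf("crypt%02d", seq_len(n_norm))

  if (is.null(tc)) {
    tree <- simulate_tree(n_norm, seed = seed, dev_frac = config$dev_frac,
                          labels = norm_labels)
    tumour_nodes <- integer(0)
    labels <- norm_labels
  } else {
    n_tum <- tc$n_crypts
    stopifnot(n_tum >= 2L)
    tum_labels <- sprintf("tumour%02d", seq_len(n_tum))
    labels <- c(norm_labels, tum_labels)
    crypt_type <- c(crypt_type, rep("tumour", n_tum))
    t1 <- random_topology(norm_labels)
    t2 <- random_topology(tum_labels)
    tree <- join_at_root(t1, t2, labels)
    # depths: normal splits early; tumour MRCA late (recent clonal expansion)
    nn <- length(tree$parent)
    N <- tree$nleaf
    sets <- ct_leafsets(tree)
    tum_leaves <- (n_norm + 1L):N
    tumour_nodes <- which(vapply(sets, function(s) all(s %in% tum_leaves), TRUE))
    mrca_frac <- if (!is.null(tc$mrca_frac)) tc$mrca_frac else 0.95
    upper <- rep(config$dev_frac, nn)
    upper[tumour_nodes] <- 0.999
    fixed <- rep(NA_real_, nn)
    tum_root <- tumour_nodes[which.max(vapply(sets[tumour_nodes], length, 1L))]
    fixed[tum_root] <- mrca_frac
    tree <- assign_depths(tree, config$dev_frac, upper = upper, fixed = fixed)
  }

  # per-branch overrides: MMR-deficient crypt, tumour trunk and branches
  overrides <- list()
  if (!is.null(config$mmrd_crypt)) {
    mc <- config$mmrd_crypt
    leaf <- if (!is.null(mc$crypt)) match(mc$crypt, labels) else n_norm
    crypt_type[leaf] <- "mmrd"
    base_rate <- sum(config$signature_activities)
    overrides[[as.character(leaf)]] <- list(
      mean_sbs = tree$frac[leaf] * config$patient_age * base_rate * mc$multiplier,
      mix_sbs = mc$mix,
      mean_id = if (!is.null(mc$id_mix) && !is.null(config$id_signature_activities)) {
        tree$frac[leaf] * config$patient_age *
          sum(config$id_signature_activities) * mc$multiplier
      } else NULL,
      mix_id = mc$id_mix
    )
  }
  if (!is.null(tc)) {
    tum_root <- tumour_nodes[which.max(vapply(ct_leafsets(tree)[tumour_nodes],
                                              length, 1L))]
    # mixes default to the cohort-wide activity proportions
    tmix <- if (!is.null(tc$trunk_mix)) tc$trunk_mix
            else config$signature_activities
    imix <- if (!is.null(tc$id_mix)) tc$id_mix
            else config$id_signature_activities
    for (b in tumour_nodes) {
      if (b == tum_root) {
        overrides[[as.character(b)]] <- list(
          mean_sbs = tc$trunk_mutations, mix_sbs = tmix,
          mean_id = tc$trunk_id_mutations, mix_id = imix)
      } else {
        overrides[[as.character(b)]] <- list(
          mean_sbs = if (!is.null(tc$branch_mutations)) tc$branch_mutations
                     else tc$trunk_mutations * 0.02,
          mix_sbs = if (!is.null(tc$branch_mix)) tc$branch_mix else tmix,
          mean_id = tc$branch_id_mutations, mix_id = imix)
      }
    }
  }
  embryonic <- setdiff(which(seq_along(tree$parent) > tree$nleaf + 1L),
                       if (is.null(tc)) integer(0) else tumour_nodes)

  dm <- draw_mutations(tree, config, catalogue, id_catalogue,
                       seed = seed + 1L, overrides = overrides,
                       embryonic_branches = embryonic)
  reads <- sample_reads(dm$truth, config, seed = seed + 2L)
  dm$variants$site_depth <- rowSums(reads$depth)

  samples <- data.frame(
    id = labels, patient = config$patient, tissue = config$tissue,
    crypt_type = crypt_type, age = config$patient_age, cnv = FALSE,
    stringsAsFactors = FALSE
  )
  cm <- count_matrix(reads$alt, reads$depth, dm$variants, samples)
  out <- list(matrix = cm, truth = dm$truth, config = config)
  class(out) <- "sim_cohort"
  out
}

# Join two subtrees under a fresh root (zygote); labels = c(labels1, labels2).
join_at_root <- function(t1, t2, labels) {
  n1 <- t1$nleaf; n2 <- t2$nleaf
  m1 <- length(t1$parent); m2 <- length(t2$parent)
  # raw ids: root = 1, t1 nodes = 1+1..1+m1, t2 nodes = 1+m1+1..1+m1+m2
  parent_raw <- integer(1L + m1 + m2)
  parent_raw[1L] <- 0L
  for (v in seq_len(m1)) {
    parent_raw[1L + v] <- if (t1$parent[v] == 0L) 1L else 1L + t1$parent[v]
  }
  for (v in seq_len(m2)) {
    parent_raw[1L + m1 + v] <- if (t2$parent[v] == 0L) 1L else 1L + m1 + t2$parent[v]
  }
  leaves <- c(1L + seq_len(n1), 1L + m1 + seq_len(n2))
  ct_renumber(parent_raw, leaves, labels)
}

#' Write a simulated cohort to disk
#'
#' Variant table and count matrices as tab-separated files, the truth as JSON
#' and the tree as Newick.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(cohort$matrix, dir)
  writeLines(ct_newick(cohort$truth$tree, lengths = cohort$truth$tree$frac),
             file.path(dir, "tree.nwk"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(branch_variants = truth$branch_variants,
         variant_class = as.list(truth$variant_class),
         variant_signature = as.list(truth$variant_signature),
         seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
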