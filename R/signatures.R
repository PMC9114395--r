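# De novo mutational signature extraction over the patient -> branch
# hierarchy (hierarchical Dirichlet process sampler, with an NMF backend for
# validation), EM deconvolution of components into a reference catalogue,
# residual ("unknown") signature construction, and per-branch exposure refits.

#' Cosine similarity
#'
#' @param u,v Non-negative vectors of equal length, not both zero.
#' @return u.v / (|u||v|), in [0, 1] for non-negative inputs.
#' @export
cosine <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine: undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

# Greedy one-to-one matching of columns of `a` to columns of `b` by cosine;
# returns an integer map (per column of a, the matched column of b or NA).
greedy_cosine_match <- function(a, b, min_cos = 0) {
  ka <- ncol(a); kb <- ncol(b)
  cm <- matrix(0, ka, kb)
  for (i in seq_len(ka)) for (j in seq_len(kb)) cm[i, j] <- cosine(a[, i], b[, j])
  map <- rep(NA_integer_, ka)
  repeat {
    m <- which.max(cm)
    if (length(m) == 0 || cm[m] < min_cos || !is.finite(cm[m]) || cm[m] == -Inf) break
    i <- (m - 1) %% ka + 1
    j <- (m - 1) %/% ka + 1
    if (cm[i, j] <= -1) break
    map[i] <- j
    cm[i, ] <- -Inf
    cm[, j] <- -Inf
    if (all(is.infinite(cm))) break
  }
  map
}

#' De novo extraction with a hierarchical Dirichlet process sampler
#'
#' Mutations are channel-categorical draws; the mixture hierarchy is top ->
#' patient -> branch with a uniform Dirichlet base over channels and one
#' concentration parameter per level (vague gamma hyperpriors, resampled
#' during Gibbs sampling). Per-sample cluster spectra are matched across
#' retained posterior samples by cosine and averaged into components;
#' components with pairwise cosine >= `cos_merge` are merged, and components
#' with non-trivial exposure (> 1% of a branch) in fewer than `min_sample`
#' branches are dropped. Exposures are refit by EM against the final
#' components. Deterministic under a fixed seed.
#'
#' @param spectra Branch x channel count matrix (from [branch_spectra()]).
#' @param hierarchy Patient id per branch (named by branch, or in row order).
#' @param mcmc list(burnin, n_samples, spacing); defaults are desk-scale
#'   (2000 / 50 / 10).
#' @param cos_merge Merge threshold (default 0.9).
#' @param min_sample Minimum branches with non-trivial exposure (default 2).
#' @param seed Integer seed.
#' @param eta Dirichlet pseudo-count of the channel base (default 1).
#' @param init_k Number of random dishes at initialization (default 10);
#'   starting from a dispersed partition mixes far better than growing from
#'   one dish.
#' @return list(components, exposures, provenance, diagnostics): components is
#'   a channel x K matrix with columns summing to 1; exposures is a branch x K
#'   matrix with rows summing to 1.
#' @export
hdp_extract <- function(spectra, hierarchy,
                        mcmc = list(burnin = 2000L, n_samples = 50L, spacing = 10L),
                        cos_merge = 0.9, min_sample = 2L, seed = 1L, eta = 1,
                        init_k = 10L) {
  stopifnot(is.matrix(spectra), nrow(spectra) >= 1)
  if (sum(spectra) == 0) stop("hdp_extract: empty spectra")
  stopifnot(all(unlist(mcmc) > 0))
  J <- nrow(spectra); C <- ncol(spectra)
  if (is.null(names(hierarchy))) names(hierarchy) <- rownames(spectra)
  pat <- as.integer(factor(hierarchy[rownames(spectra)])) - 1L

  # expand to mutation level
  x <- integer(0); br <- integer(0)
  for (j in seq_len(J)) {
    cnt <- spectra[j, ]
    x <- c(x, rep.int(seq_len(C) - 1L, cnt))
    br <- c(br, rep.int(j - 1L, sum(cnt)))
  }
  set.seed(seed)
  res <- hdp_gibbs_cpp(x, br, pat, C,
                       as.integer(mcmc$burnin), as.integer(mcmc$n_samples),
                       as.integer(mcmc$spacing), eta, 1, 1,
                       as.integer(init_k))
  S <- length(res$spectra)
  Ks <- vapply(res$spectra, nrow, 0L)
  K_mode <- as.integer(names(sort(table(Ks), decreasing = TRUE))[1])
  ref_i <- which(Ks == K_mode)[1]
  ref <- t(res$spectra[[ref_i]])           # C x K counts
  acc_sp <- ref
  acc_ex <- res$exposures[[ref_i]]         # J x K counts
  for (s in seq_len(S)) {
    if (s == ref_i) next
    sp <- t(res$spectra[[s]])
    map <- greedy_cosine_match(sp, ref, min_cos = 0.5)
    for (i in seq_len(ncol(sp))) {
      if (!is.na(map[i])) {
        acc_sp[, map[i]] <- acc_sp[, map[i]] + sp[, i]
        acc_ex[, map[i]] <- acc_ex[, map[i]] + res$exposures[[s]][, i]
      }
    }
  }
  n_raw <- ncol(acc_sp)

  # merge near-duplicate components (counts add, i.e. exposure-weighted mean)
  merges <- 0L
  repeat {
    K <- ncol(acc_sp)
    if (K < 2) break
    best <- c(0, 0); bc <- -1
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      cc <- cosine(acc_sp[, i], acc_sp[, j])
      if (cc > bc) { bc <- cc; best <- c(i, j) }
    }
    if (bc < cos_merge) break
    i <- best[1]; j <- best[2]
    acc_sp[, i] <- acc_sp[, i] + acc_sp[, j]
    acc_ex[, i] <- acc_ex[, i] + acc_ex[, j]
    acc_sp <- acc_sp[, -j, drop = FALSE]
    acc_ex <- acc_ex[, -j, drop = FALSE]
    merges <- merges + 1L
  }

  # min_sample rule on exposure fractions
  frac <- acc_ex / pmax(rowSums(acc_ex), 1)
  keep <- colSums(frac > 0.01) >= min_sample
  if (!any(keep)) keep[which.max(colSums(acc_ex))] <- TRUE
  comp <- acc_sp[, keep, drop = FALSE]
  comp <- sweep(comp, 2, colSums(comp), "/")
  colnames(comp) <- paste0("N", seq_len(ncol(comp)))
  rownames(comp) <- colnames(spectra)

  expo <- refit_exposures(spectra, comp)$fractions
  list(components = comp, exposures = expo, provenance = "hdp",
       diagnostics = list(n_raw = n_raw, merges = merges, K_samples = Ks,
                          concentrations = res$conc))
}

# One KL-NMF run (multiplicative updates) on counts V (J x C).
kl_nmf <- function(V, k, max_iter = 600, tol = 1e-6) {
  J <- nrow(V); C <- ncol(V)
  W <- matrix(stats::runif(J * k, 0.1, 1), J, k)
  H <- matrix(stats::runif(k * C, 0.1, 1), k, C)
  eps <- 1e-12
  kl_old <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H), J, k, byrow = TRUE)
    if (it %% 25 == 0) {
      WH <- W %*% H + eps
      kl <- sum(V * log((V + eps) / WH) - V + WH)
      if (abs(kl_old - kl) < tol * abs(kl_old + eps)) break
      kl_old <- kl
    }
  }
  WH <- W %*% H + eps
  kl <- sum(V * log((V + eps) / WH) - V + WH)
  # scale so signature rows sum to 1
  s <- rowSums(H)
  H <- H / s
  W <- W * matrix(s, J, k, byrow = TRUE)
  list(W = W, H = H, kl = kl)
}

#' De novo extraction by NMF with stability-based rank selection
#'
#' For each rank k, `restarts` seeded multiplicative-update NMF runs minimize
#' the generalized Kullback-Leibler divergence; restart components are
#' clustered by cosine matching to the best-loss solution, and the solution's
#' stability is scored by the mean cosine silhouette of the clusters. The
#' chosen rank is the largest k whose mean silhouette exceeds `sil_threshold`.
#'
#' @param spectra Branch x channel count matrix.
#' @param k_range Candidate ranks (default 1:5).
#' @param restarts Restarts per rank (default 10).
#' @param seed Integer seed.
#' @param sil_threshold Stability threshold (default 0.8).
#' @return list(components, exposures, provenance, diagnostics) as in
#'   [hdp_extract()]; diagnostics holds per-rank silhouettes.
#' @export
nmf_extract <- function(spectra, k_range = 1:5, restarts = 10L, seed = 1L,
                        sil_threshold = 0.8) {
  stopifnot(is.matrix(spectra), all(k_range >= 1), all(k_range <= nrow(spectra)))
  set.seed(seed)
  V <- spectra + 0.0
  sils <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    runs <- lapply(seq_len(restarts), function(r) kl_nmf(V, k))
    best <- runs[[which.min(vapply(runs, `[[`, 0, "kl"))]]
    fits[[ki]] <- best
    if (k == 1) {
      sils[ki] <- 1
      next
    }
    # cluster all restart components by matching to the best solution
    ref <- t(best$H)                       # C x k
    members <- vector("list", k)
    for (r in runs) {
      m <- greedy_cosine_match(t(r$H), ref)
      for (i in seq_len(k)) {
        if (!is.na(m[i])) members[[m[i]]] <- c(members[[m[i]]], list(t(r$H)[, i]))
      }
    }
    # cosine silhouette per member
    centroid <- lapply(members, function(ms) {
      if (length(ms) == 0) return(NULL)
      v <- Reduce(`+`, ms) / length(ms); v / sum(v)
    })
    sil <- c()
    for (i in seq_len(k)) {
      for (v in members[[i]]) {
        a <- 1 - cosine(v, centroid[[i]])
        b <- min(vapply(setdiff(seq_len(k), i), function(j) {
          if (is.null(centroid[[j]])) return(Inf)
          1 - cosine(v, centroid[[j]])
        }, 0))
        sil <- c(sil, (b - a) / max(a, b, 1e-12))
      }
    }
    sils[ki] <- mean(sil)
  }
  ok <- which(sils >= sil_threshold)
  chosen <- if (length(ok)) max(ok) else which.max(sils)
  best <- fits[[chosen]]
  comp <- t(best$H)
  comp <- sweep(comp, 2, colSums(comp), "/")
  colnames(comp) <- paste0("N", seq_len(ncol(comp)))
  rownames(comp) <- colnames(spectra)
  expo <- best$W / pmax(rowSums(best$W), 1e-12)
  rownames(expo) <- rownames(spectra)
  colnames(expo) <- colnames(comp)
  list(components = comp, exposures = expo, provenance = "nmf",
       diagnostics = list(silhouettes = sils, chosen_k = k_range[chosen]))
}

#' EM deconvolution of a component into reference signatures
#'
#' Maximizes sum_c x_c log(sum_k w_k R_ck) over the simplex by EM
#' (responsibilities z_ck = w_k R_ck / sum_j w_j R_cj, then
#' w_k <- sum_c x_c z_ck / sum_c x_c). The objective is non-decreasing.
#'
#' @param component Probability (or count) vector over channels.
#' @param catalogue A `sig_catalogue` with matching channels.
#' @param tol Convergence on max |delta w| (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return Named weight vector summing to 1; attribute "objective" holds the
#'   per-iteration log-likelihood trace.
#' @export
em_deconvolute <- function(component, catalogue, tol = 1e-8, max_iter = 10000L) {
  R <- catalogue$vectors
  if (length(component) != nrow(R)) {
    stop("em_deconvolute: channel mismatch between component and catalogue")
  }
  x <- component / sum(component)
  K <- ncol(R)
  w <- rep(1 / K, K)
  eps <- 1e-300
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    mix <- as.vector(R %*% w) + eps
    obj <- c(obj, sum(x * log(mix)))
    w_new <- w * as.vector(t(R) %*% (x / mix))
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  names(w) <- catalogue$names
  attr(w, "objective") <- obj
  w
}

#' Reconstitute a component from its thresholded decomposition
#'
#' References with weight strictly above `contribution_threshold` are kept
#' and renormalized; the reconstruction is their weighted sum and is accepted
#' when its cosine with the original component exceeds 0.9.
#'
#' @param weights Weights from [em_deconvolute()].
#' @param catalogue The reference catalogue.
#' @param component The original component.
#' @param contribution_threshold 0.15 for SBS, 0.2 for ID (strict >).
#' @return list(cosine, accepted, kept, kept_weights, reconstruction).
#' @export
reconstitute <- function(weights, catalogue, component,
                         contribution_threshold = 0.15) {
  kept <- names(weights)[weights > contribution_threshold]
  if (length(kept) == 0) {
    return(list(cosine = NA_real_, accepted = FALSE, kept = character(0),
                kept_weights = numeric(0), reconstruction = NULL))
  }
  w <- weights[kept] / sum(weights[kept])
  recon <- as.vector(catalogue$vectors[, kept, drop = FALSE] %*% w)
  cs <- cosine(recon, component / sum(component))
  list(cosine = cs, accepted = cs > 0.9, kept = kept, kept_weights = w,
       reconstruction = recon)
}

#' Residual ("unknown") signature after subtracting selected references
#'
#' residue_c = max(0, component_c - sum_k w_k R_ck) over the selected
#' references with their unrenormalized EM weights, renormalized to sum 1.
#'
#' @param component Probability vector.
#' @param catalogue Reference catalogue.
#' @param selected_refs Names of the references to subtract.
#' @param weights EM weights (the full vector; only the selected entries are
#'   used, without renormalization).
#' @return Probability vector over channels.
#' @export
residual_signature <- function(component, catalogue, selected_refs, weights) {
  stopifnot(all(selected_refs %in% catalogue$names))
  x <- component / sum(component)
  sub <- as.vector(catalogue$vectors[, selected_refs, drop = FALSE] %*%
                     weights[selected_refs])
  res <- pmax(0, x - sub)
  # the floor must sit above the EM convergence tolerance (1e-8), otherwise
  # in-span components leave a numerical-noise "residual" instead of erroring
  if (sum(res) <= 1e-6) {
    stop("residual_signature: degenerate residual (component lies in the catalogue span)")
  }
  res / sum(res)
}

#' Refit per-branch exposures against a fixed signature set
#'
#' Per branch, the same EM updates as [em_deconvolute()] with the branch
#' spectrum as data. Returns exposure fractions (rows sum to 1) and absolute
#' mutation counts (fraction x branch total).
#'
#' @param spectra Branch x channel count matrix.
#' @param signatures Channel x signature matrix (columns sum to 1), e.g. a
#'   catalogue subset plus accepted residual signatures.
#' @param tol,max_iter EM controls.
#' @return list(fractions, counts), branch x signature matrices.
#' @export
refit_exposures <- function(spectra, signatures, tol = 1e-8, max_iter = 10000L) {
  if (is.null(dim(signatures)) || ncol(signatures) == 0) {
    stop("refit_exposures: empty signature set")
  }
  stopifnot(ncol(spectra) == nrow(signatures))
  cat <- signature_catalogue(signatures)
  K <- ncol(signatures)
  fr <- matrix(0, nrow(spectra), K,
               dimnames = list(rownames(spectra), colnames(signatures)))
  for (j in seq_len(nrow(spectra))) {
    w <- em_deconvolute(spectra[j, ], cat, tol = tol, max_iter = max_iter)
    fr[j, ] <- w
  }
  list(fractions = fr, counts = fr * rowSums(spectra))
}

#' Full deconvolution workflow for a set of extracted components
#'
#' For each component: EM deconvolution against the catalogue, thresholded
#' reconstitution, and — when reconstitution fails (cosine <= 0.9) — residual
#' construction from the selected references, yielding an "unknown" signature
#' named after the component. The final signature set is the union of
#' selected references over all components plus accepted residuals; exposures
#' are refit per branch with that set.
#'
#' @param components Channel x K component matrix.
#' @param catalogue Reference catalogue.
#' @param spectra Branch x channel counts for the final refit.
#' @param contribution_threshold Reconstitution threshold (0.15 SBS, 0.2 ID).
#' @param exposure_threshold Minimum component exposure for a component's
#'   references to enter a branch's refit set (default 0.1); applied on the
#'   component exposures supplied in `component_exposures`.
#' @param component_exposures Branch x component exposure fractions (from the
#'   extraction); NULL means all components count everywhere.
#' @return list(per_component = list of deconvolution results, signatures =
#'   final channel x signature matrix, exposures = refit result).
#' @export
deconvolute_components <- function(components, catalogue, spectra,
                                   contribution_threshold = 0.15,
                                   exposure_threshold = 0.1,
                                   component_exposures = NULL) {
  sig_set <- character(0)
  residuals <- list()
  per_comp <- list()
  active <- colnames(components)
  if (!is.null(component_exposures)) {
    active <- colnames(components)[
      apply(component_exposures > exposure_threshold, 2, any)]
  }
  for (nm in colnames(components)) {
    comp <- components[, nm]
    w <- em_deconvolute(comp, catalogue)
    rec <- reconstitute(w, catalogue, comp, contribution_threshold)
    res_sig <- NULL
    if (!isTRUE(rec$accepted) && length(rec$kept)) {
      res_sig <- tryCatch(
        residual_signature(comp, catalogue, rec$kept, w),
        error = function(e) NULL)
    }
    per_comp[[nm]] <- list(weights = w, reconstitution = rec,
                           residual = res_sig)
    if (nm %in% active) {
      sig_set <- union(sig_set, rec$kept)
      if (!is.null(res_sig)) residuals[[paste0(nm, "_residual")]] <- res_sig
    }
  }
  sigs <- catalogue$vectors[, sig_set, drop = FALSE]
  if (length(residuals)) {
    sigs <- cbind(sigs, do.call(cbind, residuals))
  }
  if (ncol(sigs) == 0) stop("deconvolute_components: no signatures selected")
  expo <- refit_exposures(spectra, sigs)
  list(per_component = per_comp, signatures = sigs, exposures = expo)
}
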