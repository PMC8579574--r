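# Method-similarity meta-analysis: per-method performance profiles over
# ten accuracy measures, classical (Torgerson) MDS of the Euclidean
# distances between standardized profiles, complete-linkage clustering,
# and majority-vote selection of the number of homogeneous method groups.

PROFILE_MEASURES <- c("sensitivity", "specificity", "ppv", "npv", "youden",
                      "accuracy", "plr", "nlr", "f_measure", "auc")

#' Per-method performance profiles
#'
#' Builds the 10-measure profile (sensitivity, specificity, PPV, NPV,
#' Youden, accuracy, PLR, NLR, F-measure, AUC) used for the similarity
#' analysis from a named list of confusion matrices.
#'
#' @param cms Named list of [confusion_matrix()] objects.
#' @return A tibble: `method` plus one column per measure.
#' @export
performance_profiles <- function(cms) {
  stopifnot(is.list(cms), !is.null(names(cms)))
  purrr::imap(cms, function(cm, nm) {
    ms <- metric_set(cm)
    dplyr::bind_cols(tibble::tibble(method = nm),
                     tibble::as_tibble(as.list(unlist(ms[PROFILE_MEASURES]))))
  }) |> dplyr::bind_rows()
}

#' Standardized profile matrix and Euclidean distances
#'
#' Columns are z-standardized by default so that unbounded measures (PLR)
#' do not dominate the Euclidean metric; constant columns standardize to 0.
#' Non-finite entries are an error unless `cap_quantile` is set, in which
#' case entries above that quantile of the finite values in their column
#' (including infinities) are capped at it.
#'
#' @param profiles Tibble from [performance_profiles()] (`method` column
#'   plus numeric measure columns).
#' @param standardize Z-standardize columns (default TRUE).
#' @param cap_quantile Optional quantile in (0, 1) for capping extreme or
#'   infinite entries, e.g. `0.95`. Default `NULL` (disabled).
#' @return A list: `matrix` (methods x measures, possibly standardized)
#'   and `dist` (a `dist` object of Euclidean distances).
#' @export
profile_matrix <- function(profiles, standardize = TRUE, cap_quantile = NULL) {
  stopifnot(is.data.frame(profiles), "method" %in% names(profiles))
  if (nrow(profiles) < 3) abort("At least 3 methods are required.")
  m <- as.matrix(profiles[setdiff(names(profiles), "method")])
  rownames(m) <- profiles$method
  if (anyNA(m)) abort("Profiles contain missing entries.")
  if (!is.null(cap_quantile)) {
    stopifnot(cap_quantile > 0, cap_quantile < 1)
    for (j in seq_len(ncol(m))) {
      fin <- m[, j][is.finite(m[, j])]
      if (length(fin) == 0) abort("A profile column has no finite entries.")
      cap <- quantile(fin, cap_quantile, names = FALSE)
      m[, j] <- pmin(m[, j], cap)
    }
  }
  if (any(!is.finite(m))) {
    abort("Profiles contain non-finite entries; enable `cap_quantile` or exclude the measure.")
  }
  if (standardize) {
    m <- apply(m, 2, function(col) {
      s <- sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    rownames(m) <- profiles$method
  }
  list(matrix = m, dist = dist(m))
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and
#' embeds the methods in `k` dimensions ordered by decreasing eigenvalue.
#' When the input distances are Euclidean of rank at most `k`, the
#' embedded pairwise distances reproduce the input exactly (up to
#' rotation/reflection).
#'
#' @param distances A `dist` object or symmetric distance matrix.
#' @param k Target dimension, default 2.
#' @return A `method_map` object: `points` (tibble `method`, `dim1`, ...),
#'   `eigenvalues`, and `gof` (share of positive eigenvalue mass captured).
#' @export
#' @examples
#' d <- dist(cbind(c(0, 3, 0), c(0, 0, 4)))  # 3-4-5 triangle
#' classical_mds(d)$points
classical_mds <- function(distances, k = 2) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0)) {
    abort("`distances` must be a symmetric matrix with zero diagonal.")
  }
  n <- nrow(d)
  if (k >= n) {
    warn(sprintf("k reduced to %d (at most n - 1 dimensions are available).", n - 1))
    k <- n - 1
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values[1], 0) * 1e-12)
  k_eff <- min(k, length(pos))
  if (k_eff < k) {
    warn(sprintf("Distance matrix has rank %d; returning %d dimension(s).",
                 length(pos), k_eff))
  }
  coords <- eig$vectors[, seq_len(k_eff), drop = FALSE] %*%
    diag(sqrt(eig$values[seq_len(k_eff)]), k_eff)
  coords <- sweep(coords, 2, colMeans(coords))  # centered at origin
  pts <- tibble::as_tibble(coords, .name_repair = ~ paste0("dim", seq_len(k_eff)))
  pts <- dplyr::bind_cols(
    tibble::tibble(method = rownames(d) %||% paste0("m", seq_len(n))), pts)
  posmass <- sum(pmax(eig$values, 0))
  structure(list(points = pts, eigenvalues = eig$values,
                 gof = if (posmass > 0) sum(pmax(eig$values[seq_len(k_eff)], 0)) / posmass else NA_real_,
                 k = k_eff),
            class = "method_map")
}

#' @export
print.method_map <- function(x, ...) {
  cat(sprintf("Classical MDS map: %d methods in %d dimension(s); GOF %.3f\n",
              nrow(x$points), x$k, x$gof))
  invisible(x)
}

#' @method tidy method_map
#' @export
tidy.method_map <- function(x, ...) x$points

#' @method glance method_map
#' @export
glance.method_map <- function(x, ...) {
  tibble::tibble(n_methods = nrow(x$points), k = x$k, gof = x$gof,
                 eig1 = x$eigenvalues[1], eig2 = x$eigenvalues[2])
}

#' Complete-linkage hierarchical clustering of methods
#'
#' Agglomerative clustering with maximum inter-cluster distance (complete
#' linkage), whose merge heights are monotone non-decreasing; cutting the
#' dendrogram at height `h` yields clusters of internal diameter at most
#' `h`.
#'
#' @param distances A `dist` object or symmetric distance matrix
#'   (at least 2 methods).
#' @return An `hclust` object.
#' @seealso [select_k_majority()], [dendrogram_newick()]
#' @export
complete_linkage <- function(distances) {
  d <- stats::as.dist(distances)
  if (attr(d, "Size") < 2) abort("At least 2 methods are required.")
  hclust(d, method = "complete")
}

#' Export a dendrogram as a Newick tree with heights
#'
#' @param hc An `hclust` object.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# ---- internal cluster-validity indices --------------------------------

validity_calinski_harabasz <- function(m, cl) {
  n <- nrow(m); k <- length(unique(cl))
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(m)
  W <- 0; B <- 0
  for (g in unique(cl)) {
    mg <- m[cl == g, , drop = FALSE]
    cg <- colMeans(mg)
    W <- W + sum(sweep(mg, 2, cg)^2)
    B <- B + nrow(mg) * sum((cg - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

validity_silhouette <- function(d, cl) {
  if (length(unique(cl)) < 2) return(NA_real_)
  mean(cluster::silhouette(as.integer(factor(cl)), d)[, "sil_width"])
}

validity_dunn <- function(d, cl) {
  dm <- as.matrix(d)
  gs <- unique(cl)
  if (length(gs) < 2) return(NA_real_)
  min_between <- Inf; max_diam <- 0
  for (i in seq_along(gs)) {
    ii <- cl == gs[i]
    if (sum(ii) > 1) max_diam <- max(max_diam, max(dm[ii, ii]))
    for (j in seq_along(gs)) {
      if (j <= i) next
      jj <- cl == gs[j]
      min_between <- min(min_between, min(dm[ii, jj]))
    }
  }
  if (max_diam == 0) return(Inf)
  min_between / max_diam
}

validity_davies_bouldin <- function(m, cl) {
  gs <- unique(cl)
  k <- length(gs)
  if (k < 2) return(NA_real_)
  cent <- do.call(rbind, lapply(gs, function(g)
    colMeans(m[cl == g, , drop = FALSE])))
  s <- vapply(seq_along(gs), function(i) {
    mg <- m[cl == gs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(mg, 2, cent[i, ])^2)))
  }, numeric(1))
  db <- 0
  for (i in seq_len(k)) {
    r <- vapply(setdiff(seq_len(k), i), function(j) {
      mij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (mij == 0) Inf else (s[i] + s[j]) / mij
    }, numeric(1))
    db <- db + max(r)
  }
  db / k
}

validity_c_index <- function(d, cl) {
  dv <- as.vector(d)
  dm <- as.matrix(d)
  within <- unlist(lapply(unique(cl), function(g) {
    ii <- which(cl == g)
    if (length(ii) < 2) return(numeric(0))
    dm[ii, ii][lower.tri(dm[ii, ii])]
  }))
  nw <- length(within)
  if (nw == 0) return(NA_real_)
  sorted <- sort(dv)
  smin <- sum(sorted[seq_len(nw)])
  smax <- sum(sorted[seq(length(sorted) - nw + 1, length(sorted))])
  if (smax == smin) return(0)
  (sum(within) - smin) / (smax - smin)
}

VALIDITY_INDICES <- list(
  calinski_harabasz = list(fn = "ch", better = "higher"),
  silhouette = list(fn = "sil", better = "higher"),
  dunn = list(fn = "dunn", better = "higher"),
  davies_bouldin = list(fn = "db", better = "lower"),
  c_index = list(fn = "cindex", better = "lower")
)

#' Majority-vote selection of the number of method clusters
#'
#' Cuts the complete-linkage dendrogram of the profile distances at each
#' candidate `k`; each enabled cluster-validity index votes for the `k`
#' it scores best (higher-is-better: Calinski-Harabasz, mean silhouette
#' width, Dunn; lower-is-better: Davies-Bouldin, C-index). The majority
#' vote wins; ties go to the smallest `k`. Hierarchical cuts cannot return
#' `k = 1`, so a single tight cluster surfaces as a small-`k` choice with
#' a weak (tied or sub-majority) tally, flagged in the result.
#'
#' @param profiles Tibble from [performance_profiles()], or a
#'   pre-computed list from [profile_matrix()].
#' @param k_candidates Candidate cluster counts, default `2:8`
#'   (truncated when there are too few methods).
#' @param indices Subset of
#'   `c("calinski_harabasz", "silhouette", "dunn", "davies_bouldin",
#'   "c_index")`; at least 5 by default.
#' @param standardize Passed to [profile_matrix()] when `profiles` is a
#'   profile tibble.
#' @return A list: `k` (chosen count), `tally` (votes per candidate),
#'   `votes` (index-level scores and choices), `clusters` (membership at
#'   the chosen `k`), `weak_evidence` (logical), `hclust`.
#' @export
select_k_majority <- function(profiles, k_candidates = 2:8,
                              indices = names(VALIDITY_INDICES),
                              standardize = TRUE) {
  indices <- match.arg(indices, names(VALIDITY_INDICES), several.ok = TRUE)
  pm <- if (is.list(profiles) && !is.data.frame(profiles) &&
            all(c("matrix", "dist") %in% names(profiles))) {
    profiles
  } else {
    profile_matrix(profiles, standardize = standardize)
  }
  m <- pm$matrix; d <- pm$dist
  n <- nrow(m)
  k_candidates <- k_candidates[k_candidates >= 2 & k_candidates <= n - 1]
  if (length(k_candidates) == 0) abort("No feasible candidate k.")
  hc <- complete_linkage(d)

  score_one <- function(idx, cl) {
    switch(idx,
           calinski_harabasz = validity_calinski_harabasz(m, cl),
           silhouette = validity_silhouette(d, cl),
           dunn = validity_dunn(d, cl),
           davies_bouldin = validity_davies_bouldin(m, cl),
           c_index = validity_c_index(d, cl))
  }
  cuts <- lapply(k_candidates, function(k) cutree(hc, k = k))
  votes <- purrr::map(indices, function(idx) {
    sc <- vapply(cuts, function(cl) score_one(idx, cl), numeric(1))
    better <- VALIDITY_INDICES[[idx]]$better
    ranked <- if (better == "higher") sc else -sc
    best <- k_candidates[which.max(ranked)]  # first (smallest k) on ties
    tibble::tibble(index = idx, k = k_candidates, score = sc,
                   chosen = k_candidates == best)
  }) |> dplyr::bind_rows()

  tally <- votes |>
    dplyr::filter(.data$chosen) |>
    dplyr::count(.data$k, name = "votes") |>
    dplyr::right_join(tibble::tibble(k = k_candidates), by = "k") |>
    dplyr::mutate(votes = dplyr::coalesce(.data$votes, 0L)) |>
    dplyr::arrange(.data$k)

  top <- max(tally$votes)
  winners <- tally$k[tally$votes == top]
  k_star <- min(winners)
  weak <- length(winners) > 1 || top <= length(indices) / 2
  list(k = k_star, tally = tally, votes = votes,
       clusters = cutree(hc, k = k_star),
       weak_evidence = weak, hclust = hc)
}
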