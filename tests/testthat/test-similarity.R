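test_that("profile distances are a metric and match hand computation", {
  profiles <- tibble::tibble(
    method = c("a", "b", "c"),
    m1 = c(0.9, 0.9, 0.1), m2 = c(0.8, 0.8, 0.2), m3 = c(5, 5, 1))
  pm <- profile_matrix(profiles, standardize = TRUE)
  d <- as.matrix(pm$dist)
  expect_equal(d["a", "b"], 0)          # identical methods
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  # hand computation: z-scores of each column, Euclidean norm of difference
  z <- apply(profiles[-1], 2, function(x) (x - mean(x)) / sd(x))
  expect_equal(d["a", "c"], sqrt(sum((z[1, ] - z[3, ])^2)))
  # triangle inequality
  expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
})

test_that("profile matrix rejects non-finite entries unless the cap rule is on", {
  profiles <- tibble::tibble(method = c("a", "b", "c"),
                             m1 = c(1, 2, Inf), m2 = c(0, 1, 2))
  expect_error(profile_matrix(profiles), "non-finite")
  pm <- profile_matrix(profiles, cap_quantile = 0.5)
  expect_true(all(is.finite(pm$matrix)))
})

test_that("classical MDS reproduces exact Euclidean geometry", {
  # 3-4-5 right triangle given only as distances
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  mm <- classical_mds(d, k = 2)
  emb <- as.matrix(mm$points[c("dim1", "dim2")])
  expect_equal(as.matrix(dist(emb)), unname(d) * (diag(3) * 0 + 1),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(colMeans(emb), c(dim1 = 0, dim2 = 0), ignore_attr = TRUE)

  # recovery of a random 2-D configuration up to rotation/reflection
  set.seed(5)
  X <- matrix(rnorm(20), 10, 2)
  mm2 <- classical_mds(dist(X), k = 2)
  emb2 <- as.matrix(mm2$points[c("dim1", "dim2")])
  expect_lt(procrustes_error(X, emb2), 1e-8)

  # independent implementation cross-check
  ref <- cmdscale(dist(X), k = 2)
  expect_lt(procrustes_error(ref, emb2), 1e-8)

  # all-equal distances: equilateral triangle, two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  mm3 <- classical_mds(d3, k = 2)
  expect_equal(mm3$eigenvalues[1], mm3$eigenvalues[2])
  emb3 <- as.matrix(mm3$points[c("dim1", "dim2")])
  expect_equal(as.vector(dist(emb3)), rep(1, 3))
})

test_that("MDS warns when asking for more dimensions than the data support", {
  X <- cbind(1:5)  # rank-1 configuration
  expect_warning(mm <- classical_mds(dist(X), k = 3), "rank")
  expect_lte(mm$k, 2)
})

test_that("complete linkage agrees with the brute-force oracle on small problems", {
  set.seed(13)
  for (n in c(4, 6, 8)) {
    X <- matrix(rnorm(n * 3), n)
    d <- dist(X)
    hc <- complete_linkage(d)
    oracle <- brute_complete_linkage(d)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    for (k in 2:(n - 1)) {
      ours <- cutree(hc, k = k)
      theirs <- oracle$memberships[[n - k]]
      # same partition up to label permutation
      theirs_vec <- integer(n)
      for (g in seq_along(theirs)) theirs_vec[theirs[[g]]] <- g
      expect_equal(length(unique(paste(ours, theirs_vec))),
                   length(unique(ours)))
    }
  }
})

test_that("dendrogram heights are monotone and cuts behave at the extremes", {
  pm <- profile_matrix(performance_profiles(lapply(
    setNames(1:8, paste0("m", 1:8)),
    function(i) new_confusion_matrix(600 + 10 * i, 50 + 5 * i, 108 - 10 * i,
                                     420 - 5 * i))))
  hc <- complete_linkage(pm$dist)
  expect_equal(length(hc$height), 7)  # n - 1 merges
  expect_true(all(diff(hc$height) >= 0))
  expect_equal(length(unique(cutree(hc, h = max(hc$height)))), 1)
  expect_equal(length(unique(cutree(hc, h = 0))), 8)
  # cutting at h: every cluster diameter <= h
  h <- stats::median(hc$height)
  cl <- cutree(hc, h = h)
  dm <- as.matrix(pm$dist)
  for (g in unique(cl)) {
    ii <- which(cl == g)
    if (length(ii) > 1) expect_lte(max(dm[ii, ii]), h + 1e-12)
  }
})

test_that("two well-separated pairs merge internally before merging together", {
  d <- dist(c(0, 0.1, 10, 10.1))
  hc <- complete_linkage(d)
  expect_equal(sort(hc$height)[1:2], c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(length(unique(cutree(hc, k = 2)[1:2])), 1)
})

test_that("method order permutation does not change geometry or memberships", {
  cms <- lapply(setNames(1:6, paste0("m", 1:6)), function(i)
    new_confusion_matrix(500 + 30 * i, 40 + 8 * i, 208 - 30 * i, 430 - 8 * i))
  prof <- performance_profiles(cms)
  perm <- prof[c(4, 2, 6, 1, 3, 5), ]
  pm1 <- profile_matrix(prof); pm2 <- profile_matrix(perm)
  d1 <- as.matrix(pm1$dist); d2 <- as.matrix(pm2$dist)
  expect_equal(d2[prof$method, prof$method], d1)
  k1 <- select_k_majority(pm1, k_candidates = 2:4)
  k2 <- select_k_majority(pm2, k_candidates = 2:4)
  expect_equal(k2$k, k1$k)
  # memberships agree up to relabeling
  m1 <- k1$clusters[prof$method]; m2 <- k2$clusters[prof$method]
  expect_equal(length(unique(paste(m1, m2))), length(unique(m1)))
})

test_that("majority vote recovers three well-separated profile clusters", {
  set.seed(2024)
  mk <- function(center, j) {
    v <- pmin(pmax(center + rnorm(10, 0, 0.01), 0.01), 0.99)
    names(v) <- c("sensitivity", "specificity", "ppv", "npv", "youden",
                  "accuracy", "plr", "nlr", "f_measure", "auc")
    dplyr::bind_cols(tibble::tibble(method = j), tibble::as_tibble(as.list(v)))
  }
  prof <- dplyr::bind_rows(
    purrr::map(1:5, ~ mk(0.10, paste0("lo", .x))),
    purrr::map(1:5, ~ mk(0.50, paste0("mid", .x))),
    purrr::map(1:5, ~ mk(0.90, paste0("hi", .x))))
  sel <- select_k_majority(prof, k_candidates = 2:8)
  expect_equal(sel$k, 3)
  expect_gte(max(sel$tally$votes), 3)  # clear majority of the 5 indices
  # the recovered groups coincide with the construction
  cl <- sel$clusters
  expect_equal(length(unique(cl[paste0("lo", 1:5)])), 1)
  expect_equal(length(unique(cl[paste0("mid", 1:5)])), 1)
  expect_equal(length(unique(cl[paste0("hi", 1:5)])), 1)
})

test_that("a single diffuse cluster yields a weak-evidence small-k choice", {
  set.seed(77)
  prof <- tibble::tibble(method = paste0("m", 1:12)) |>
    dplyr::bind_cols(tibble::as_tibble(matrix(rnorm(12 * 10, 0.5, 0.02), 12,
                                              dimnames = list(NULL, paste0("v", 1:10)))))
  sel <- select_k_majority(prof, k_candidates = 2:6)
  expect_true(sel$k >= 2)  # hierarchical cuts cannot return k = 1
  expect_true(is.logical(sel$weak_evidence))
})

test_that("ties between candidate counts resolve to the smaller k", {
  # direct check of the tie rule on the tally logic: construct four tight
  # pairs; CH/silhouette-type indices split their votes across k values,
  # the documented rule then picks the smallest tied k
  d <- dist(c(0, 0.01, 1, 1.01, 2, 2.01, 3, 3.01))
  m <- cbind(c(0, 0.01, 1, 1.01, 2, 2.01, 3, 3.01))
  sel <- select_k_majority(list(matrix = m, dist = d), k_candidates = 2:4)
  tally <- sel$tally
  top <- max(tally$votes)
  expect_equal(sel$k, min(tally$k[tally$votes == top]))
})

test_that("newick export carries the leaves and parses back", {
  pmx <- matrix(rnorm(15), 5, dimnames = list(paste0("m", 1:5), NULL))
  hc <- complete_linkage(dist(pmx))
  nwk <- dendrogram_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("m", 1:5))
  expect_equal(ape::Ntip(phy), 5)
})
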