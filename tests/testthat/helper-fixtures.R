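# Shared fixtures, all built in code.

# one patient record with plausible defaults, overridable per test
make_record <- function(...) {
  rec <- list(hb = 10, hct = 32, mcv = 70, mch = 22, mchc = 31.4, rbc = 4.8,
              rdw = 16, hba2 = 2.5, ferritin = 10, serum_iron = 40,
              tibc = 400, sex = "female")
  over <- list(...)
  rec[names(over)] <- over
  tibble::as_tibble(rec)
}

make_records <- function(...) dplyr::bind_rows(...)

# small deterministic labeled cohort for fast pipeline checks
tiny_cohort <- function(n_btt = 40, n_ida = 30, seed = 42) {
  generate_cohort(simulation_config(n_btt = n_btt, n_ida = n_ida, seed = seed))
}

random_confusion <- function() {
  new_confusion_matrix(tp = sample(1:200, 1), fp = sample(1:200, 1),
                       fn = sample(1:200, 1), tn = sample(1:200, 1))
}

# brute-force complete linkage: recompute the max inter-cluster distance
# between every cluster pair at each step (oracle for hclust)
brute_complete_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  memberships <- list()
  for (step in seq_len(n - 1)) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(dm[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights[step] <- best[1]
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
    memberships[[step]] <- clusters
  }
  list(heights = heights, memberships = memberships)
}

# align configuration B onto A by translation + orthogonal Procrustes and
# return the residual error
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(t(B) %*% A)
  R <- s$u %*% t(s$v)
  sqrt(sum((B %*% R - A)^2))
}
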