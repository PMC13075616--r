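#' Cluster-based sign-flip permutation test on time-frequency maps
#'
#' Paired one-sided t-tests per pixel across patients; pixels whose
#' one-sided p falls below `alpha_form` are grouped into 4-connected
#' clusters whose mass is the summed t-value. The null distribution is the
#' maximum cluster mass over sign flips of the per-patient difference maps:
#' all `2^n` flips (identity included, so the smallest attainable p is
#' `1/2^n`) when `n <= max_exhaustive`, otherwise `n_perm` seeded random
#' flips. A cluster is significant when its permutation p is below
#' `alpha_cluster`.
#'
#' @param maps_cond1,maps_cond2 Lists of per-patient `tfmap`s (or plain
#'   matrices) on identical axes; the contrast is cond1 - cond2.
#' @param alpha_form Cluster-forming pixel threshold (one-sided p).
#' @param alpha_cluster Significance level for the cluster mass.
#' @param side `"greater"` tests cond1 > cond2, `"less"` the reverse.
#' @param max_exhaustive Largest n for exhaustive sign enumeration.
#' @param n_perm Random flips when n exceeds `max_exhaustive`.
#' @param seed Seed for random flips.
#' @param coi Optional logical matrix (see [coi_mask()]); per-cluster
#'   overlap with the cone of influence is reported but does not gate
#'   cluster formation.
#' @return Object of class `cluster_test`: the t map, a `clusters`
#'   data.frame (`id`, `n_pixels`, `mass`, `p`, `significant`,
#'   `coi_fraction`), the cluster label matrix, and the permutation null.
#' @export
cluster_permutation <- function(maps_cond1, maps_cond2,
                                alpha_form = 0.05, alpha_cluster = 0.05,
                                side = c("greater", "less"),
                                max_exhaustive = 20L, n_perm = 1024L,
                                seed = 1L, coi = NULL) {
  side <- match.arg(side)
  sgn <- if (side == "greater") 1L else -1L
  as_mat <- function(m) if (inherits(m, "tfmap")) m$values else m
  n <- length(maps_cond1)
  if (n < 2L || length(maps_cond2) != n) stop("need >= 2 paired patients")
  m1 <- lapply(maps_cond1, as_mat)
  m2 <- lapply(maps_cond2, as_mat)
  dims <- dim(m1[[1]])
  if (!all(vapply(c(m1, m2), function(m) identical(dim(m), dims), logical(1)))) {
    stop("map axes differ across patients or conditions")
  }
  D <- t(vapply(seq_len(n), function(i) as.numeric(m1[[i]] - m2[[i]]),
                numeric(prod(dims))))
  ss <- colSums(D^2)
  thr <- stats::qt(1 - alpha_form, df = n - 1L)
  tvec <- function(s) {
    m <- as.numeric(s %*% D) / n
    v <- (ss - n * m^2) / (n - 1L)
    v[v < .Machine$double.eps] <- .Machine$double.eps
    m / sqrt(v / n)
  }
  t_obs <- tvec(rep(1, n))
  tmat <- matrix(t_obs, dims[1], dims[2])
  lab <- .cc_label(sgn * tmat, thr, 1L)
  ids <- seq_len(max(lab))
  mass <- if (length(ids)) vapply(ids, function(k) {
    sum(sgn * tmat[lab == k])
  }, numeric(1)) else numeric(0)
  if (n <= max_exhaustive) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    S <- with_seed(seed, matrix(sample(c(1, -1), n_perm * n, replace = TRUE),
                                nrow = n_perm))
    S[1, ] <- 1  # keep the identity assignment in the null
  }
  null <- vapply(seq_len(nrow(S)), function(r) {
    .cc_max_mass(sgn * tvec(S[r, ]), dims[1], dims[2], thr, 1L)
  }, numeric(1))
  # tolerance: the identity flip recomputes the observed mass with a
  # different summation order; p can never fall below 1/n_perm
  p <- vapply(mass, function(ms) {
    mean(null >= ms - 1e-9 * (1 + abs(ms)))
  }, numeric(1))
  coi_frac <- if (is.null(coi)) rep(NA_real_, length(ids)) else
    vapply(ids, function(k) mean(coi[lab == k]), numeric(1))
  clusters <- data.frame(id = ids, n_pixels = tabulate(lab, length(ids)),
                         mass = mass, p = p,
                         significant = p < alpha_cluster,
                         coi_fraction = coi_frac)
  clusters <- clusters[order(clusters$p, -clusters$mass), , drop = FALSE]
  structure(list(t = tmat, clusters = clusters, labels = lab, null = null,
                 alpha_form = alpha_form, alpha_cluster = alpha_cluster,
                 side = side, n_patients = n, n_permutations = nrow(S)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> n = %d patients, %d permutations, %d cluster(s), %d significant\n",
              x$n_patients, x$n_permutations, nrow(x$clusters),
              sum(x$clusters$significant)))
  invisible(x)
}

#' One-sided Wilcoxon signed-rank test for paired condition values
#'
#' Tests the primary expectation of an increase (`cond1 > cond2`) with the
#' exact signed-rank distribution for n <= 25 after discarding zero
#' differences.
#'
#' @param values_cond1,values_cond2 Paired per-patient values.
#' @return List with `median_diff` (median of cond1 - cond2) and `p`.
#' @export
wilcoxon_one_sided <- function(values_cond1, values_cond2) {
  stopifnot(length(values_cond1) == length(values_cond2))
  if (length(values_cond1) < 5L) stop("need at least 5 pairs")
  d <- values_cond1 - values_cond2
  dnz <- d[d != 0]
  if (length(dnz) == 0L) stop("all differences are zero")
  n <- length(dnz)
  if (n <= 25L) {
    # exact sign-flip distribution of the signed-rank sum, valid under
    # ties (average ranks): dynamic-programming convolution over the 2^n
    # equiprobable sign assignments
    r2 <- round(2 * rank(abs(dnz)))          # doubled ranks are integers
    v2 <- sum(r2[dnz > 0])
    counts <- c(1, numeric(sum(r2)))
    for (r in r2) {
      shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
      counts <- counts + shifted
    }
    p <- sum(counts[seq(v2 + 1L, length(counts))]) / 2^n
  } else {
    p <- stats::wilcox.test(dnz, alternative = "greater", mu = 0,
                            exact = FALSE, correct = TRUE)$p.value
  }
  list(median_diff = stats::median(d), p = unname(p))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return data.frame with `p`, `p_adj` (BH step-up adjusted) and
#'   `significant` (`p_adj <= q`).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  data.frame(p = p_values, p_adj = adj, significant = !is.na(adj) & adj <= q)
}
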