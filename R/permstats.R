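# Shared statistical machinery: cluster-mass permutation tests, percentile
# nulls, and Fisher's z-transform.

#' Cluster-mass permutation test between two trial sets
#'
#' Condition labels are permuted at the trial level to build a null
#' distribution of mean-difference time series. Pointwise t-like scores are
#' the observed (or null) difference standardised by the permutation
#' distribution at each time point. Contiguous supra-threshold runs of the
#' same sign form clusters whose mass is the summed score; the corrected p
#' of each observed cluster is the fraction of permutations whose maximum
#' absolute cluster mass is at least as large.
#'
#' @param trials_a,trials_b trials x samples matrices (equal sample counts).
#' @param n_perm number of label permutations (default 1000).
#' @param alpha cluster-forming two-sided alpha (default 0.05).
#' @param seed RNG seed.
#' @return list of class `cluster_test`: `clusters` (data frame with
#'   `start`, `end`, `mass`, `p`), `t` (pointwise scores), `threshold`,
#'   `null_max_mass`, `n_perm`.
#' @export
cluster_permutation_test <- function(trials_a, trials_b, n_perm = 1000,
                                     alpha = 0.05, seed = NULL) {
  trials_a <- as.matrix(trials_a); trials_b <- as.matrix(trials_b)
  stopifnot(ncol(trials_a) == ncol(trials_b),
            nrow(trials_a) >= 2, nrow(trials_b) >= 2)
  na <- nrow(trials_a); nb <- nrow(trials_b); n <- na + nb
  X <- rbind(trials_a, trials_b)
  obs_diff <- colMeans(trials_a) - colMeans(trials_b)
  with_seed(seed, {
    W <- matrix(-1 / nb, nrow = n_perm, ncol = n)
    for (p in seq_len(n_perm)) {
      W[p, sample.int(n, na)] <- 1 / na
    }
    null_diff <- W %*% X
  })
  mu <- colMeans(null_diff)
  sdv <- sqrt(pmax(colMeans(null_diff^2) - mu^2, 0)) *
    sqrt(n_perm / (n_perm - 1))
  col_var <- colMeans(X^2) - colMeans(X)^2
  ok <- sdv > 0 & col_var > 0
  score <- function(d) {
    out <- numeric(length(d))
    out[ok] <- (d[ok] - mu[ok]) / sdv[ok]
    out
  }
  t_obs <- score(obs_diff)
  thr <- qnorm(1 - alpha / 2)
  null_max <- vapply(seq_len(n_perm), function(p) {
    tp <- score(null_diff[p, ])
    cl <- .find_clusters(tp, thr)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  }, numeric(1))
  clusters <- .find_clusters(t_obs, thr)
  clusters$p <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, numeric(1))
  structure(
    list(clusters = clusters, t = t_obs, threshold = thr,
         null_max_mass = null_max, n_perm = n_perm, alpha = alpha),
    class = "cluster_test"
  )
}

# contiguous supra-threshold runs, sign-separated
.find_clusters <- function(tt, thr) {
  lab <- ifelse(tt > thr, 1L, ifelse(tt < -thr, -1L, 0L))
  out <- data.frame(start = integer(0), end = integer(0), mass = numeric(0))
  if (!any(lab != 0L)) return(out)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(start = starts[keep], end = ends[keep],
             mass = mapply(function(s, e) sum(tt[s:e]), starts[keep], ends[keep]))
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' First and last significant sample from a cluster test
#'
#' @param result a [cluster_permutation_test()] result.
#' @param alpha significance level for corrected cluster p-values.
#' @return integer vector `c(onset, offset)` in samples, or `NULL` when no
#'   cluster is significant.
#' @export
onset_offset_from_clusters <- function(result, alpha = 0.05) {
  sig <- result$clusters[result$clusters$p < alpha, , drop = FALSE]
  if (!nrow(sig)) return(NULL)
  c(onset = min(sig$start), offset = max(sig$end))
}

#' Percentile threshold of a statistic under permutation
#'
#' @param stat_fn function computing the statistic from (permuted) data.
#' @param permute_fn zero-argument function returning one permuted replicate
#'   of the data.
#' @param q percentile in (0, 100) (default 99).
#' @param n_perm number of permutations (>= 100 recommended for q >= 99).
#' @param seed RNG seed.
#' @return the q-th percentile (linear interpolation) of the null statistic.
#' @export
percentile_null <- function(stat_fn, permute_fn, q = 99, n_perm = 1000,
                            seed = NULL) {
  if (q <= 0 || q >= 100) stop("q must lie strictly between 0 and 100")
  with_seed(seed, {
    vals <- vapply(seq_len(n_perm), function(i) stat_fn(permute_fn()),
                   numeric(1))
  })
  quantile(vals, q / 100, names = FALSE, type = 7)
}

#' Fisher's z-transform of a correlation coefficient
#'
#' Values with `|rho| >= 1` are clipped just inside the open interval with a
#' warning.
#'
#' @param rho correlation coefficient(s).
#' @return `atanh(rho)`.
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) {
    warning("|rho| >= 1 clipped before the z-transform")
    rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(rho)
}

#' Difference of Fisher-z-transformed correlations
#'
#' @param rho1,rho2 correlation coefficients.
#' @return `z(rho1) - z(rho2)`.
#' @export
z_difference <- function(rho1, rho2) fisher_z(rho1) - fisher_z(rho2)
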