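#' Simulate reference individuals from pooled allele frequencies
#'
#' Hardy-Weinberg draws: for each reference pool, `m` diploid genotypes per
#' site with dosage ~ Binomial(2, p). This reproduces the construction of a
#' reference database of simulated individuals from per-location pooled
#' frequencies.
#'
#' @param pool_freqs pools x sites frequency matrix (row names = pool ids).
#' @param m individuals per pool (default 8).
#' @param seed optional integer seed.
#' @return list with `genotypes` ((pools*m) x sites dosage matrix) and `pool`
#'   (pool id per simulated individual).
#' @export
simulate_reference_individuals <- function(pool_freqs, m = 8, seed = NULL) {
  pool_freqs <- as.matrix(pool_freqs)
  if (any(pool_freqs < 0 | pool_freqs > 1, na.rm = TRUE))
    stop("frequencies must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rownames(pool_freqs)))
    rownames(pool_freqs) <- paste0("pool", seq_len(nrow(pool_freqs)))
  L <- ncol(pool_freqs)
  g <- do.call(rbind, lapply(rownames(pool_freqs), function(pl) {
    p <- pool_freqs[pl, ]
    gm <- matrix(NA_integer_, m, L)
    ok <- !is.na(p)
    gm[, ok] <- matrix(stats::rbinom(m * sum(ok), 2, rep(p[ok], each = m)),
                       nrow = m)
    gm
  }))
  list(genotypes = g, pool = rep(rownames(pool_freqs), each = m))
}

#' Per-pool genotype log-likelihoods under Hardy-Weinberg
#'
#' For each query individual and reference pool, sums per-site log genotype
#' probabilities `(1-p)^2, 2p(1-p), p^2` by dosage, with pool frequencies
#' clamped to `[eps, 1-eps]` (so a single genotyping error against a fixed
#' pool is penalised finitely). Missing query sites are skipped.
#'
#' @param query dosage matrix (individuals x sites) or a single dosage vector.
#' @param pool_freqs pools x sites frequency matrix over the same site set.
#' @param eps clamping constant in (0, 0.5); default 0.01.
#' @return matrix of log-likelihoods, individuals x pools.
#' @export
genotype_loglik <- function(query, pool_freqs, eps = 0.01) {
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  pool_freqs <- as.matrix(pool_freqs)
  if (ncol(query) != ncol(pool_freqs))
    stop("query and reference must share the same site set")
  if (ncol(query) == 0) stop("zero shared sites between query and reference")
  if (eps <= 0 || eps >= 0.5) stop("eps must lie in (0, 0.5)")
  pf <- pmin(pmax(pool_freqs, eps), 1 - eps)
  ll <- matrix(0, nrow(query), nrow(pool_freqs),
               dimnames = list(rownames(query), rownames(pool_freqs)))
  lp <- log(pf); lq <- log(1 - pf); l2 <- log(2)
  panel_ok <- colSums(is.na(pool_freqs)) == 0
  for (i in seq_len(nrow(query))) {
    g <- query[i, ]
    ok <- !is.na(g) & panel_ok
    if (!any(ok)) stop("query individual ", i, " shares no scored sites")
    gd <- g[ok]
    ll[i, ] <- as.numeric(
      lp[, ok, drop = FALSE] %*% gd +
        lq[, ok, drop = FALSE] %*% (2 - gd) +
        sum(gd == 1) * l2)
  }
  ll
}

#' Assign individuals to population clusters
#'
#' Pool log-likelihoods are aggregated to clusters by the best pool (a cluster
#' is as likely as its most likely member pool), converted to posterior
#' probabilities under a uniform prior, and an individual is labelled with the
#' top cluster only when its posterior strictly exceeds `threshold`
#' (default 2/3, the "two-thirds more likely than any alternative" rule);
#' otherwise it is `unassigned`.
#'
#' @param loglik individuals x pools log-likelihood matrix from
#'   [genotype_loglik()].
#' @param clusters named character vector mapping pool id -> cluster label.
#' @param threshold posterior threshold (strict); default `2/3`.
#' @return data.frame: `sample_id`, `best_cluster`, `posterior`, `margin`
#'   (over the runner-up), `status`; the full individuals x clusters posterior
#'   matrix is attached as attribute `posterior`.
#' @export
assign_individuals <- function(loglik, clusters, threshold = 2 / 3) {
  loglik <- as.matrix(loglik)
  pools <- colnames(loglik)
  if (is.null(pools)) pools <- names(clusters)[seq_len(ncol(loglik))]
  cl <- clusters[pools]
  if (anyNA(cl)) stop("every pool needs a cluster label")
  labs <- unique(unname(cl))
  # with a single cluster every individual with data is assigned to it
  # (posterior 1); >= 2 clusters is the usual case
  cl_ll <- sapply(labs, function(lb)
    apply(loglik[, cl == lb, drop = FALSE], 1, max))
  if (is.null(dim(cl_ll))) cl_ll <- matrix(cl_ll, nrow = 1,
                                           dimnames = list(NULL, labs))
  mx <- apply(cl_ll, 1, max)
  post <- exp(cl_ll - mx)
  post <- post / rowSums(post)
  top <- apply(post, 1, which.max)
  top_p <- post[cbind(seq_len(nrow(post)), top)]
  runner <- apply(post, 1, function(v) sort(v, decreasing = TRUE)[2])
  runner[is.na(runner)] <- 0
  assigned <- top_p > threshold
  ids <- rownames(loglik)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(loglik)))
  out <- data.frame(sample_id = ids,
                    best_cluster = labs[top],
                    posterior = top_p,
                    margin = top_p - runner,
                    status = ifelse(assigned, "assigned", "unassigned"),
                    stringsAsFactors = FALSE)
  out$best_cluster[!assigned] <- "unassigned"
  attr(out, "posterior") <- post
  out
}
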