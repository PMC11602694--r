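# Population genetics on microsatellites: diversity summaries, Weir-Cockerham
# F_ST with permutation differentiation tests, DAPC-style clustering, sMLH,
# and the Monte-Carlo heterosis test.

# Weir & Cockerham (1984) variance components summed over alleles, one locus.
# a1/a2: allele codes (NA = missing), pop: integer population codes.
wc_locus_components <- function(a1, a2, pop) {
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]; pop <- pop[typed]
  if (length(a1) == 0L) return(c(a = 0, b = 0, c = 0))
  lev <- sort(unique(pop))
  r <- length(lev)
  if (r < 2L) return(c(a = 0, b = 0, c = 0))
  pop <- match(pop, lev)
  n_i <- tabulate(pop, nbins = r)
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)

  alleles <- sort(unique(c(a1, a2)))
  K <- length(alleles)
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  # per-population allele counts and heterozygote-carrier counts
  cnt <- matrix(tabulate(pop + (i1 - 1L) * r, nbins = r * K) +
                  tabulate(pop + (i2 - 1L) * r, nbins = r * K), r, K)
  hz <- i1 != i2
  het <- matrix(tabulate(pop[hz] + (i1[hz] - 1L) * r, nbins = r * K) +
                  tabulate(pop[hz] + (i2[hz] - 1L) * r, nbins = r * K), r, K)
  p_ia <- cnt / (2 * n_i)
  h_ia <- het / n_i
  pbar <- colSums(n_i * p_ia) / (r * nbar)
  s2 <- colSums(n_i * (p_ia - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_ia) / (r * nbar)

  a_c <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b_c <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_c <- hbar / 2
  c(a = sum(a_c), b = sum(b_c), c = sum(c_c))
}

wc_theta <- function(calls, pop) {
  comp <- rowSums(vapply(seq_len(dim(calls)[2]), function(l) {
    wc_locus_components(calls[, l, 1], calls[, l, 2], pop)
  }, numeric(3)))
  denom <- sum(comp)
  if (denom == 0) return(NA_real_)
  comp[["a"]] / denom
}

#' Weir-Cockerham F_ST with permutation differentiation tests
#'
#' Estimates the multi-allelic, multi-locus Weir-Cockerham (1984) theta by
#' summing the among-population (a), among-individual (b) and within-
#' individual (c) variance components over alleles and loci, globally and for
#' every population pair. Differentiation is tested by permuting individuals
#' among populations and recomputing theta; p-values use the
#' `(1 + exceedances) / (1 + permutations)` estimator and are therefore never
#' exactly zero. (The permutation test replaces the Markov-chain exact test of
#' the GENEPOP program: same null hypothesis of no genotypic differentiation,
#' no external binary.)
#'
#' @param gm a [genotype_matrix()] with at least two populations.
#' @param n_permutations permutations per test (default 1000).
#' @param seed optional integer seed for the permutations.
#' @return an object of class `fst_estimates`: list with `global_theta`,
#'   `global_p`, `pairwise` (symmetric matrix, NA diagonal), `pairwise_p`,
#'   `n_permutations`.
#' @export
wc_fst <- function(gm, n_permutations = 1000L, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(gm$populations)
  if (length(pops) < 2L) stop("need at least two populations", call. = FALSE)
  typed_per_pop <- vapply(pops, function(p) {
    idx <- gm$populations == p
    max(colSums(!is.na(gm$calls[idx, , 1, drop = FALSE])))
  }, numeric(1))
  if (any(typed_per_pop < 2)) {
    stop("population(s) with fewer than 2 typed individuals at every locus: ",
         paste(pops[typed_per_pop < 2], collapse = ", "),
         "; F_ST is undefined", call. = FALSE)
  }
  pop_codes <- match(gm$populations, pops)

  perm_p <- function(calls, codes, observed) {
    if (n_permutations < 1L) return(NA_real_)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      th <- wc_theta(calls, sample(codes))
      if (!is.na(th) && th >= observed) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_permutations)
  }

  global <- wc_theta(gm$calls, pop_codes)
  global_p <- perm_p(gm$calls, pop_codes, global)

  np <- length(pops)
  pair <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  pair_p <- pair
  for (i in seq_len(np - 1)) {
    for (j in seq(i + 1, np)) {
      idx <- gm$populations %in% pops[c(i, j)]
      calls <- gm$calls[idx, , , drop = FALSE]
      codes <- match(gm$populations[idx], pops[c(i, j)])
      th <- wc_theta(calls, codes)
      pair[i, j] <- pair[j, i] <- th
      pv <- perm_p(calls, codes, th)
      pair_p[i, j] <- pair_p[j, i] <- pv
    }
  }
  structure(list(global_theta = global, global_p = global_p,
                 pairwise = pair, pairwise_p = pair_p,
                 n_permutations = as.integer(n_permutations)),
            class = "fst_estimates")
}

#' Per-locus, per-population diversity summary
#'
#' Observed heterozygosity, unbiased expected heterozygosity (Nei's gene
#' diversity with the `2n/(2n-1)` small-sample correction) and allelic
#' richness by hypergeometric rarefaction to a common number of gene copies
#' (by default the smallest per-population typed sample at each locus).
#' Monomorphic loci return `He = 0`.
#'
#' @param gm a [genotype_matrix()].
#' @param rarefy_to optional number of gene copies to rarefy richness to;
#'   default is the per-locus minimum of `2 * n_typed` across populations.
#' @return a `data.frame` with columns `locus`, `population`, `n_typed`,
#'   `n_alleles`, `Ho`, `He`, `richness`, `rarefied_to`.
#' @export
diversity_summary <- function(gm, rarefy_to = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$populations)
  rows <- list()
  for (l in seq_along(gm$loci)) {
    a1 <- gm$calls[, l, 1]; a2 <- gm$calls[, l, 2]
    n_typed <- vapply(pops, function(p) sum(!is.na(a1[gm$populations == p])), numeric(1))
    if (all(n_typed == 0)) {
      warning(sprintf("locus %s has no typed individuals", gm$loci[l]))
    }
    g <- rarefy_to %||% max(2L, 2L * min(n_typed[n_typed > 0]))
    for (p in pops) {
      idx <- gm$populations == p & !is.na(a1)
      n <- sum(idx)
      if (n == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = gm$loci[l], population = p, n_typed = 0L, n_alleles = 0L,
          Ho = NA_real_, He = NA_real_, richness = NA_real_, rarefied_to = g)
        next
      }
      al <- c(a1[idx], a2[idx])
      counts <- table(al)
      freqs <- counts / length(al)
      ho <- mean(a1[idx] != a2[idx])
      he <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(freqs^2)) else NA_real_
      gg <- min(g, length(al))
      rich <- sum(1 - exp(lchoose(length(al) - counts, gg) - lchoose(length(al), gg)))
      rows[[length(rows) + 1L]] <- data.frame(
        locus = gm$loci[l], population = p, n_typed = n,
        n_alleles = length(counts), Ho = ho, He = he,
        richness = rich, rarefied_to = gg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# individuals x allele-dosage matrix (one column per locus-allele, 0/1/2)
dosage_matrix <- function(gm) {
  cols <- list()
  for (l in seq_along(gm$loci)) {
    a1 <- gm$calls[, l, 1]; a2 <- gm$calls[, l, 2]
    alleles <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    for (a in alleles) {
      v <- (a1 == a) + (a2 == a)
      cols[[paste0(gm$loci[l], ".", a)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- gm$ids
  X
}

#' DAPC-style clustering of genotypes
#'
#' The discriminant analysis of principal components workflow: the centred
#' allele-dosage matrix (missing dosages imputed to the column mean) is
#' reduced by PCA; k-means (multiple restarts) is run on the retained PCs for
#' each candidate number of clusters K, scored by
#' `BIC = n log(WSS/n) + K log(n)`; the K minimising BIC is kept and a linear
#' discriminant analysis on the retained PCs yields per-individual cluster
#' membership probabilities.
#'
#' @param gm a [genotype_matrix()].
#' @param max_k maximum number of clusters to try (default 3).
#' @param max_pcs maximum PCs retained for the cluster search (default 100).
#' @param n_da_pcs PCs used by the discriminant step; default
#'   `min(retained, floor(n/3))` to avoid overfitting the LDA.
#' @param n_start k-means restarts (default 20).
#' @param seed optional seed for the k-means restarts.
#' @return an object of class `dapc_result`: list with `bic_curve`,
#'   `chosen_k`, `retained_pcs`, `memberships` (n x K, rows sum to 1),
#'   `assignments`, `mean_membership` (of the assigned cluster) and
#'   `cluster_by_population` cross-table.
#' @export
dapc_clusters <- function(gm, max_k = 3L, max_pcs = 100L, n_da_pcs = NULL,
                          n_start = 20L, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(gm$ids)
  if (max_k > n) stop("max_k exceeds the number of individuals", call. = FALSE)
  X <- dosage_matrix(gm)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  npc <- min(max_pcs, n - 1L, ncol(pca$x))
  S <- pca$x[, seq_len(npc), drop = FALSE]

  wss <- numeric(max_k)
  clusterings <- vector("list", max_k)
  for (K in seq_len(max_k)) {
    if (K == 1L) {
      wss[K] <- sum(sweep(S, 2, colMeans(S))^2)
      clusterings[[K]] <- rep(1L, n)
    } else {
      km <- stats::kmeans(S, centers = K, nstart = n_start, iter.max = 100)
      wss[K] <- km$tot.withinss
      clusterings[[K]] <- km$cluster
    }
  }
  bic <- n * log(wss / n) + seq_len(max_k) * log(n)
  chosen_k <- which.min(bic)

  if (chosen_k == 1L) {
    memb <- matrix(1, n, 1, dimnames = list(gm$ids, "cluster1"))
    assign <- rep(1L, n)
  } else {
    grp <- factor(clusterings[[chosen_k]])
    nda <- n_da_pcs %||% max(1L, min(npc, floor(n / 3)))
    memb <- tryCatch({
      ld <- MASS::lda(S[, seq_len(nda), drop = FALSE], grouping = grp)
      predict(ld, S[, seq_len(nda), drop = FALSE])$posterior
    }, error = function(e) {
      warning("LDA failed (", conditionMessage(e), "); using hard memberships")
      m <- matrix(0, n, chosen_k)
      m[cbind(seq_len(n), as.integer(grp))] <- 1
      m
    })
    colnames(memb) <- paste0("cluster", seq_len(chosen_k))
    rownames(memb) <- gm$ids
    assign <- max.col(memb)
  }
  structure(list(
    bic_curve = data.frame(k = seq_len(max_k), bic = bic),
    chosen_k = chosen_k, retained_pcs = npc,
    memberships = memb, assignments = assign,
    mean_membership = mean(memb[cbind(seq_len(n), assign)]),
    cluster_by_population = table(population = gm$populations, cluster = assign)
  ), class = "dapc_result")
}

#' Standardized multilocus heterozygosity (sMLH)
#'
#' For each individual, the proportion of its typed loci that are
#' heterozygous, divided by the mean locus heterozygosity (computed over all
#' individuals typed at each locus) averaged over the loci typed in that
#' individual. On complete data the mean sMLH over individuals is exactly 1.
#' Individuals typed at no locus are excluded with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @return a `data.frame` with columns `colony_id`, `population`, `n_typed`,
#'   `mlh` (raw heterozygous proportion) and `smlh`.
#' @export
compute_smlh <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  het <- gm$calls[, , 1] != gm$calls[, , 2]        # n x L, NA where untyped
  if (is.null(dim(het))) het <- matrix(het, nrow = length(gm$ids))
  n_typed <- rowSums(!is.na(het))
  locus_mean <- colMeans(het, na.rm = TRUE)
  keep <- n_typed > 0
  if (any(!keep)) {
    warning(sprintf("excluding %d individual(s) typed at no locus", sum(!keep)))
  }
  mlh <- rowMeans(het, na.rm = TRUE)
  denom <- vapply(seq_len(nrow(het)), function(i) {
    mean(locus_mean[!is.na(het[i, ])])
  }, numeric(1))
  out <- data.frame(colony_id = gm$ids, population = gm$populations,
                    n_typed = n_typed, mlh = mlh, smlh = mlh / denom,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo heterosis test (nec-int on sMLH)
#'
#' Tests for a heterozygosity-fitness correlation: the observed OLS slope of
#' the individual thermotolerance baseline (`nec_int`, the mixed-model random
#' intercept) on sMLH is compared to a null distribution built by permuting
#' the sMLH values across individuals. The two-sided p-value uses the
#' `(1 + exceedances) / (1 + permutations)` estimator.
#'
#' @param nec_int named numeric vector (from [fit_response_models()]) or a
#'   data frame with columns `colony_id`, `nec_int`.
#' @param smlh a [compute_smlh()] result or a data frame with `colony_id`,
#'   `smlh`.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return an object of class `heterosis_result`: list with `observed_slope`,
#'   `null_slopes`, `p_value`, `n_permutations`, `n`.
#' @export
heterosis_test <- function(nec_int, smlh, n_perm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(nec_int)) {
    nec_int <- stats::setNames(nec_int$nec_int, nec_int$colony_id)
  }
  if (is.data.frame(smlh)) smlh <- stats::setNames(smlh$smlh, smlh$colony_id)
  ids <- intersect(names(nec_int), names(smlh))
  if (length(ids) < 10L) {
    stop("need at least 10 individuals with both nec-int and sMLH", call. = FALSE)
  }
  y <- as.numeric(nec_int[ids])
  x <- as.numeric(smlh[ids])
  if (stats::sd(x) == 0) stop("sMLH has zero variance", call. = FALSE)
  slope <- function(xx) stats::cov(xx, y) / stats::var(xx)
  obs <- slope(x)
  null <- vapply(seq_len(n_perm), function(b) slope(sample(x)), numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  structure(list(observed_slope = obs, null_slopes = null, p_value = p,
                 n_permutations = as.integer(n_perm), n = length(ids)),
            class = "heterosis_result")
}
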