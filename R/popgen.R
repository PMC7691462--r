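#' Construct a genotype set
#'
#' Bundles a diploid biallelic genotype matrix (individuals x loci, entries
#' 0/1/2 = copies of the alternate allele, `NA` = missing) with per-individual
#' population (site) labels and an optional locus -> RAD-locus grouping used
#' by the one-SNP-per-locus filter.
#'
#' @param G integer matrix, individuals x loci; dimnames are kept.
#' @param pops character vector of site ids, one per individual.
#' @param locus_groups optional character vector, one per locus.
#' @return object of class `genotypes`.
#' @export
genotypes <- function(G, pops, locus_groups = NULL) {
  G <- as.matrix(G)
  if (length(pops) != nrow(G))
    stop("pops must have one label per individual (row of G)", call. = FALSE)
  if (!all(G %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be 0, 1, 2 or NA", call. = FALSE)
  if (!is.null(locus_groups) && length(locus_groups) != ncol(G))
    stop("locus_groups must have one entry per locus", call. = FALSE)
  if (is.null(rownames(G))) rownames(G) <- paste0("ind", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <- paste0("L", seq_len(ncol(G)))
  storage.mode(G) <- "integer"
  structure(list(G = G, pops = as.character(pops),
                 locus_groups = locus_groups),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d individuals x %d loci, %d sites, %.1f%% missing\n",
              nrow(x$G), ncol(x$G), length(unique(x$pops)),
              100 * mean(is.na(x$G))))
  invisible(x)
}

## per-population, per-locus summaries used by every estimator:
## n (genotyped individuals), x (alt allele count), het (observed hets)
pop_locus_stats <- function(gt) {
  pops <- sort(unique(gt$pops))
  G <- gt$G
  per_pop <- function(f) {
    m <- do.call(rbind, lapply(pops, function(p) f(G[gt$pops == p, , drop = FALSE])))
    rownames(m) <- pops
    m
  }
  n <- per_pop(function(g) colSums(!is.na(g)))
  x <- per_pop(function(g) colSums(g, na.rm = TRUE))
  het <- per_pop(function(g) colSums(g == 1L, na.rm = TRUE))
  list(pops = pops, n = n, x = x, het = het)
}

#' Filter a SNP panel on missingness, allele frequency and locus duplication
#'
#' Applies, in order: (1) a call-rate filter -- a locus is kept when it is
#' genotyped in at least `min_ind_frac` of all individuals and its within-site
#' call rate reaches `min_ind_frac` in at least `min_pop_frac` of sites;
#' (2) a global minor-allele-frequency filter (loci with MAF strictly below
#' `min_maf` are removed); (3) optionally one SNP per RAD locus, keeping the
#' SNP with the highest call rate (first in column order on ties). Each locus
#' is attributed to the first filter that removes it.
#'
#' @param gt a [genotypes] object.
#' @param min_ind_frac minimum call rate (default 0.70).
#' @param min_pop_frac minimum fraction of sites passing the within-site call
#'   rate (default 0.70).
#' @param min_maf minimum global minor allele frequency (default 0.05).
#' @param one_per_locus keep a single SNP per `locus_groups` group.
#' @return list with the filtered `genotypes` and a `filter_report` (counts
#'   per filter and retained/removed locus ids).
#' @export
filter_snps <- function(gt, min_ind_frac = 0.70, min_pop_frac = 0.70,
                        min_maf = 0.05, one_per_locus = TRUE) {
  stopifnot(inherits(gt, "genotypes"))
  G <- gt$G
  loci <- colnames(G)
  n_input <- ncol(G)
  st <- pop_locus_stats(gt)

  call_rate <- colMeans(!is.na(G))
  pop_sizes <- as.vector(table(gt$pops)[st$pops])
  pop_ok <- colMeans(st$n / pop_sizes >= min_ind_frac)
  pass_miss <- call_rate >= min_ind_frac & pop_ok >= min_pop_frac

  p <- colSums(G, na.rm = TRUE) / (2 * colSums(!is.na(G)))
  maf <- pmin(p, 1 - p)
  pass_maf <- !is.na(maf) & maf >= min_maf

  removed_miss <- loci[!pass_miss]
  removed_maf <- loci[pass_miss & !pass_maf]
  keep <- pass_miss & pass_maf

  removed_dup <- character(0)
  if (one_per_locus && !is.null(gt$locus_groups)) {
    grp <- gt$locus_groups[keep]
    idx <- which(keep)
    ## within each group keep the best-called SNP, ties -> first column
    ord <- order(grp, -call_rate[idx], idx)
    first <- !duplicated(grp[ord])
    chosen <- idx[ord][first]
    removed_dup <- loci[setdiff(idx, chosen)]
    keep[] <- FALSE
    keep[chosen] <- TRUE
  }
  retained <- loci[keep]
  if (!length(retained))
    warning("no loci retained by filter_snps", call. = FALSE)

  report <- structure(list(
    n_input_loci = n_input,
    n_removed_missingness = length(removed_miss),
    n_removed_maf = length(removed_maf),
    n_removed_duplicate = length(removed_dup),
    n_removed_hwe = 0L,
    n_retained = length(retained),
    retained = retained,
    removed = list(missingness = removed_miss, maf = removed_maf,
                   duplicate = removed_dup)), class = "filter_report")
  out <- genotypes(G[, keep, drop = FALSE], gt$pops,
                   if (is.null(gt$locus_groups)) NULL else gt$locus_groups[keep])
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("SNP filter: %d loci in; removed %d (missingness), ",
                     "%d (MAF), %d (duplicate SNP per locus), %d (HWE); ",
                     "%d retained\n"),
              x$n_input_loci, x$n_removed_missingness, x$n_removed_maf,
              x$n_removed_duplicate, x$n_removed_hwe, x$n_retained))
  invisible(x)
}

## exact conditional Hardy-Weinberg test for a biallelic SNP (mid-p,
## two-sided by probability ordering). Enumeration over all heterozygote
## counts compatible with the observed allele count.
hwe_exact_midp <- function(n_het, n_ind, n_alt) {
  n_rare <- min(n_alt, 2L * n_ind - n_alt)
  if (n_ind == 0L || n_rare == 0L) return(1)
  hs <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  ## log P(h | n, n_rare) up to a constant: from the conditional distribution
  lp <- lgamma(n_ind + 1) - lgamma((n_rare - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma(n_ind - (n_rare + hs) / 2 + 1) + hs * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hs)]
  if (is.na(p_obs)) stop("impossible heterozygote count", call. = FALSE)
  sum(pr[pr <= p_obs + 1e-12]) - 0.5 * p_obs
}

hwe_cache <- new.env(parent = emptyenv())

hwe_exact_cached <- function(n_het, n_ind, n_alt) {
  key <- paste(n_het, n_ind, n_alt, sep = ":")
  v <- hwe_cache[[key]]
  if (is.null(v)) {
    v <- hwe_exact_midp(n_het, n_ind, n_alt)
    hwe_cache[[key]] <- v
  }
  v
}

#' Screen loci for Hardy-Weinberg departures across populations
#'
#' Runs an exact conditional HWE test (mid-p) per locus within every site,
#' applies Benjamini-Hochberg FDR control within each site, and removes loci
#' flagged in strictly more than `max_prop_pops` of the sites in which they
#' could be tested. Sites with fewer than 2 genotyped individuals at a locus
#' are skipped for that locus.
#'
#' @param gt a [genotypes] object.
#' @param fdr within-site FDR level (default 0.10).
#' @param max_prop_pops removal requires being flagged in more than this
#'   proportion of testable sites (default 0.50, strict inequality).
#' @return list: filtered `genotypes`, `removed` locus ids, and the per-site
#'   matrix of BH-adjusted p-values.
#' @export
hwe_screen <- function(gt, fdr = 0.10, max_prop_pops = 0.50) {
  stopifnot(inherits(gt, "genotypes"))
  st <- pop_locus_stats(gt)
  L <- ncol(gt$G)
  n_pops <- length(st$pops)
  padj <- matrix(NA_real_, n_pops, L, dimnames = list(st$pops, colnames(gt$G)))
  for (i in seq_len(n_pops)) {
    testable <- st$n[i, ] >= 2
    if (!any(testable)) next
    p <- vapply(which(testable), function(l)
      hwe_exact_cached(st$het[i, l], st$n[i, l], st$x[i, l]), numeric(1))
    padj[i, testable] <- stats::p.adjust(p, method = "BH")
  }
  flagged <- padj <= fdr
  n_tested <- colSums(!is.na(padj))
  prop <- ifelse(n_tested > 0, colSums(flagged, na.rm = TRUE) / n_tested, 0)
  remove <- prop > max_prop_pops
  removed <- colnames(gt$G)[remove]
  out <- genotypes(gt$G[, !remove, drop = FALSE], gt$pops,
                   if (is.null(gt$locus_groups)) NULL else gt$locus_groups[!remove])
  list(genotypes = out, removed = removed, p_adjusted = padj)
}

#' Per-site expected heterozygosity
#'
#' Unbiased expected heterozygosity per site, averaged over loci:
#' `2p(1-p) * 2n/(2n-1)` with `n` the number of genotyped individuals at that
#' site and locus (allele-count small-sample correction). Missing genotypes
#' are excluded locus-wise; loci with no data at a site are skipped.
#'
#' @param gt a [genotypes] object.
#' @return named numeric vector, one value per site.
#' @export
expected_heterozygosity <- function(gt) {
  stopifnot(inherits(gt, "genotypes"))
  st <- pop_locus_stats(gt)
  he <- vapply(seq_along(st$pops), function(i) {
    n <- st$n[i, ]
    ok <- n >= 1
    if (!any(ok)) stop(sprintf("site %s has no genotyped data", st$pops[i]),
                       call. = FALSE)
    p <- st$x[i, ok] / (2 * n[ok])
    mean(2 * p * (1 - p) * (2 * n[ok]) / (2 * n[ok] - 1))
  }, numeric(1))
  stats::setNames(he, st$pops)
}

## Weir & Cockerham (1984) multi-locus theta (ratio of sums) from
## per-pop x per-locus summary matrices: n (diploid individuals genotyped),
## x (alt allele count), het (heterozygote count). Vectorized over loci;
## populations without data at a locus drop out of that locus.
## Returns a/(a+b+c) with components summed over usable loci, or the raw
## per-locus component sums when sums_only = TRUE.
theta_from_stats <- function(n, x, het, sums_only = FALSE) {
  valid <- n > 0
  p <- ifelse(valid, x / (2 * n), 0)
  h <- ifelse(valid, het / pmax(n, 1), 0)
  rl <- colSums(valid)
  sumn <- colSums(n)
  nbar <- sumn / pmax(rl, 1)
  usable <- rl >= 2 & nbar > 1
  nc <- (sumn - colSums(n^2) / pmax(sumn, 1)) / pmax(rl - 1, 1)
  pbar <- colSums(n * p) / pmax(sumn, 1)
  dev2 <- n * sweep(p, 2, pbar, "-")^2
  s2 <- colSums(dev2) / (pmax(rl - 1, 1) * pmax(nbar, 1))
  hbar <- colSums(n * h) / pmax(sumn, 1)
  pq <- pbar * (1 - pbar)
  a <- nbar / nc * (s2 - (pq - (rl - 1) / rl * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pq - (rl - 1) / rl * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!usable] <- b[!usable] <- cc[!usable] <- 0
  A <- sum(a); den <- sum(a + b + cc)
  if (sums_only) return(c(a = A, total = den))
  if (den == 0) return(NA_real_)
  A / den
}

#' Pairwise and global Weir-Cockerham FST
#'
#' Multi-locus Weir-Cockerham (1984) theta for every pair of sites and
#' globally across all sites, using the ratio-of-sums estimator (variance
#' components summed over loci before forming the ratio; locus-wise pairwise
#' deletion of missing genotypes). Negative estimates are reported as
#' computed, not truncated. Optional permutation significance: individuals of
#' the two sites are shuffled between them `n_perm` times and the p-value is
#' `(1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`.
#'
#' @param gt a [genotypes] object with at least 2 sites.
#' @param n_perm permutations per pair (0 skips permutation testing).
#' @param seed RNG seed, required when `n_perm > 0`.
#' @return object of class `pairwise_fst`: `fst` matrix, `p_values` matrix (or
#'   `NULL`), `global` theta, `n_perm`.
#' @export
pairwise_fst_wc <- function(gt, n_perm = 0, seed = NULL) {
  stopifnot(inherits(gt, "genotypes"))
  st <- pop_locus_stats(gt)
  pops <- st$pops
  k <- length(pops)
  if (k < 2) stop("need at least 2 sites", call. = FALSE)
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required when n_perm > 0", call. = FALSE)
    set.seed(seed)
  }
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- if (n_perm > 0) matrix(NA_real_, k, k, dimnames = list(pops, pops)) else NULL
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    ii <- c(i, j)
    if (min(rowSums(st$n[ii, , drop = FALSE] > 0)) == 0 ||
        sum(gt$pops == pops[i]) < 2 || sum(gt$pops == pops[j]) < 2) {
      fst[i, j] <- fst[j, i] <- NA_real_
      next
    }
    th <- theta_from_stats(st$n[ii, , drop = FALSE], st$x[ii, , drop = FALSE],
                           st$het[ii, , drop = FALSE])
    fst[i, j] <- fst[j, i] <- th
    if (n_perm > 0) {
      sel <- gt$pops %in% pops[ii]
      Gp <- gt$G[sel, , drop = FALSE]
      n1 <- sum(gt$pops == pops[i])
      m <- nrow(Gp)
      ge <- sum(vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(m)
        g1 <- idx[seq_len(n1)]
        n_ <- rbind(colSums(!is.na(Gp[g1, , drop = FALSE])),
                    colSums(!is.na(Gp[-g1, , drop = FALSE])))
        x_ <- rbind(colSums(Gp[g1, , drop = FALSE], na.rm = TRUE),
                    colSums(Gp[-g1, , drop = FALSE], na.rm = TRUE))
        h_ <- rbind(colSums(Gp[g1, , drop = FALSE] == 1L, na.rm = TRUE),
                    colSums(Gp[-g1, , drop = FALSE] == 1L, na.rm = TRUE))
        theta_from_stats(n_, x_, h_) >= th
      }, logical(1)), na.rm = TRUE)
      pmat[i, j] <- pmat[j, i] <- (1 + ge) / (n_perm + 1)
    }
  }
  global <- theta_from_stats(st$n, st$x, st$het)
  structure(list(fst = fst, p_values = pmat, global = global,
                 n_perm = n_perm, labels = pops),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, digits = 3, ...) {
  cat(sprintf("Weir-Cockerham FST, %d sites; global theta = %.3f\n",
              length(x$labels), x$global))
  print(round(x$fst, digits))
  if (!is.null(x$p_values))
    cat(sprintf("permutation p-values from %d permutations available\n",
                x$n_perm))
  invisible(x)
}

#' Population-specific FST (Weir-Hill beta)
#'
#' Per-site divergence coefficients relative to the pooled total, using the
#' allele-matching formulation of the Weir-Hill population-specific FST:
#' `beta_i = (M_i - M_B) / (1 - M_B)`, where `M_i` is the unbiased
#' within-site allele matching proportion and `M_B` the mean between-site
#' matching, accumulated over loci as a ratio of sums. Values can be negative
#' for sites less diverged than the average pair.
#'
#' @param gt a [genotypes] object with at least 2 sites.
#' @return named numeric vector of per-site beta estimates.
#' @export
popspecific_fst_wh <- function(gt) {
  stopifnot(inherits(gt, "genotypes"))
  st <- pop_locus_stats(gt)
  k <- length(st$pops)
  if (k < 2) stop("need at least 2 sites", call. = FALSE)
  a2 <- 2 * st$n                       # allele counts per pop x locus
  x <- st$x; y <- a2 - x
  ## unbiased within-pop matching per pop x locus
  Mw <- (x * (x - 1) + y * (y - 1)) / (a2 * (a2 - 1))
  Mw[a2 < 2] <- NA
  p <- ifelse(a2 > 0, x / a2, NA_real_)
  ## mean between-pop matching per locus (pairs with data at the locus)
  num_b <- den_b <- numeric(ncol(x))
  for (l in seq_len(ncol(x))) {
    ok <- which(a2[, l] > 0)
    if (length(ok) < 2) next
    pl <- p[ok, l]
    s1 <- sum(pl); s2 <- sum(pl^2)
    npair <- length(ok) * (length(ok) - 1)
    ## sum over ordered pairs of p_i p_j + q_i q_j
    num_b[l] <- (s1^2 - s2) + ((length(ok) - s1)^2 - sum((1 - pl)^2))
    den_b[l] <- npair
  }
  MB <- ifelse(den_b > 0, num_b / den_b, NA_real_)
  beta <- vapply(seq_len(k), function(i) {
    ok <- !is.na(Mw[i, ]) & !is.na(MB)
    sum(Mw[i, ok] - MB[ok]) / sum(1 - MB[ok])
  }, numeric(1))
  stats::setNames(beta, st$pops)
}
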