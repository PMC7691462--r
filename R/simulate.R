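#' Configuration for a stepping-stone fragmentation simulation
#'
#' Describes one scenario of the forward-time experiment: a 1-D
#' stepping-stone metapopulation of constant total size `ne_total` split
#' into `n_demes` equal demes, burned in to migration-drift equilibrium at a
#' migration rate of `burnin_migration` between adjacent demes, then
#' fragmented by setting migration to `frag_migration` (0: impassable
#' barriers) for `frag_generations` generations while the multi-deme
#' Weir-Cockerham FST is recorded every generation.
#'
#' Two engines are available. `"individual"` is a diploid Wright-Fisher
#' simulation over `n_loci` sites spread across `n_elements` genomic
#' elements of `element_length_bp` bp (a finite-sites representation of the
#' genome: per-site mutation rates are scaled so the genome-wide mutation
#' rate is preserved, and recombination between adjacent sites follows their
#' physical spacing, with free recombination between elements).
#' `"frequency"` tracks per-locus allele frequencies with deterministic
#' migration mixing and binomial drift; loci are unlinked and mutation-free,
#' and the mutation-driven burn-in is replaced by initialising all demes
#' with identical frequencies drawn from a neutral site-frequency spectrum
#' (density proportional to 1/p), followed by `freq_burnin_generations` of
#' migration-drift to settle the equilibrium. The frequency engine is the
#' workhorse for ensemble runs; the individual engine is the full-fidelity
#' reference at small scale.
#'
#' @param ne_total total metapopulation size (e.g. 100, 500, 1000).
#' @param n_demes number of demes (>= 2); must divide `ne_total`.
#' @param engine `"frequency"` or `"individual"`.
#' @param n_loci loci tracked (default 2000, the order of a typical
#'   reduced-representation SNP panel).
#' @param n_elements,element_length_bp genome layout (individual engine).
#' @param mutation_rate,recombination_rate per-bp per-generation rates
#'   (individual engine).
#' @param burnin_generations burn-in length for the individual engine
#'   (default 20000).
#' @param freq_burnin_generations settling generations for the frequency
#'   engine after SFS initialisation (default 50).
#' @param burnin_migration migration rate between adjacent demes during
#'   burn-in (default 0.5).
#' @param frag_generations fragmentation phase length (default 300).
#' @param frag_migration migration rate after fragmentation (default 0).
#' @param n_replicates ensemble size (default 100).
#' @param fst_threshold differentiation threshold whose first crossing is
#'   recorded (default 0.2).
#' @param seed master RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(ne_total = 500, n_demes = 2,
                       engine = c("frequency", "individual"),
                       n_loci = 2000, n_elements = 4,
                       element_length_bp = 1e5,
                       mutation_rate = 1e-7, recombination_rate = 1e-8,
                       burnin_generations = 20000,
                       freq_burnin_generations = 50,
                       burnin_migration = 0.5,
                       frag_generations = 300, frag_migration = 0,
                       n_replicates = 100, fst_threshold = 0.2,
                       seed = 1L) {
  engine <- match.arg(engine)
  if (n_demes < 2) stop("need >=2 demes", call. = FALSE)
  if (ne_total %% n_demes != 0)
    stop("ne_total must be divisible by n_demes (equal deme sizes)",
         call. = FALSE)
  for (r in c(burnin_migration, frag_migration, mutation_rate,
              recombination_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  if (frag_generations <= 0 || burnin_generations <= 0)
    stop("generation counts must be positive", call. = FALSE)
  structure(list(ne_total = ne_total, n_demes = n_demes,
                 deme_size = ne_total %/% n_demes, engine = engine,
                 n_loci = n_loci, n_elements = n_elements,
                 element_length_bp = element_length_bp,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 burnin_generations = burnin_generations,
                 freq_burnin_generations = freq_burnin_generations,
                 burnin_migration = burnin_migration,
                 frag_generations = frag_generations,
                 frag_migration = frag_migration,
                 n_replicates = n_replicates,
                 fst_threshold = fst_threshold,
                 seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("stepping-stone fragmentation scenario: Ne=%d as %d ",
                     "deme(s) of %d, %s engine\n  burn-in m=%.2f, then m=%.2f ",
                     "for %d generations; threshold FST=%.2f; %d replicates\n"),
              x$ne_total, x$n_demes, x$deme_size, x$engine,
              x$burnin_migration, x$frag_migration, x$frag_generations,
              x$fst_threshold, x$n_replicates))
  invisible(x)
}

## neutral SFS draw: allele frequencies on the grid i/(2N), weight 1/i
sfs_frequencies <- function(n_loci, two_n) {
  i <- seq_len(two_n - 1)
  sample(i, n_loci, replace = TRUE, prob = 1 / i) / two_n
}

## stepping-stone mixing matrix (rows: destination deme composition)
migration_matrix <- function(n_demes, m) {
  M <- diag(1 - m, n_demes)
  if (n_demes >= 2 && m > 0) {
    for (d in seq_len(n_demes)) {
      nb <- c(d - 1, d + 1)
      nb <- nb[nb >= 1 & nb <= n_demes]
      M[d, nb] <- m / length(nb)
    }
  }
  M
}

## ---- frequency engine ------------------------------------------------

freq_generation <- function(P, M, two_nd) {
  Pm <- M %*% P
  matrix(stats::rbinom(length(Pm), two_nd, as.vector(Pm)),
         nrow(Pm), ncol(Pm)) / two_nd
}

## WC theta over demes from a frequency matrix, assuming HWE within demes
## (ratio of sums over loci; loci monomorphic in the pooled sample drop out)
fst_from_freqs <- function(P, deme_size) {
  nd <- nrow(P)
  n <- matrix(deme_size, nd, ncol(P))
  x <- 2 * deme_size * P
  het <- deme_size * 2 * P * (1 - P)
  theta_from_stats(n, x, het)
}

## ---- individual engine -----------------------------------------------

## genome layout: loci evenly spaced over the elements; recombination
## probability between adjacent tracked sites, free between elements
indiv_genome <- function(cfg) {
  per_el <- ceiling(cfg$n_loci / cfg$n_elements)
  n_loci <- per_el * cfg$n_elements
  spacing <- cfg$element_length_bp / per_el
  r_adj <- rep(1 - exp(-cfg$recombination_rate * spacing), n_loci - 1)
  r_adj[per_el * seq_len(cfg$n_elements - 1)] <- 0.5
  mu_site <- cfg$mutation_rate * spacing
  list(n_loci = n_loci, r_adj = r_adj, mu_site = mu_site)
}

## one meiosis per row of `parents`: recombinant gamete + mutation
make_gametes <- function(H1, H2, parents, r_adj, mu_site) {
  n <- length(parents)
  L <- ncol(H1)
  if (all(r_adj == 0.5)) {
    mask <- matrix(stats::rbinom(n * L, 1L, 0.5), n, L)
  } else {
    start <- stats::rbinom(n, 1L, 0.5)
    C <- matrix(stats::rbinom(n * (L - 1), 1L, rep(r_adj, each = n)),
                n, L - 1)
    mask <- (start + cbind(0L, t(apply(C, 1, cumsum)))) %% 2L
  }
  gam <- mask * H1[parents, , drop = FALSE] +
    (1L - mask) * H2[parents, , drop = FALSE]
  if (mu_site > 0) {
    flips <- matrix(stats::rbinom(n * L, 1L, mu_site), n, L)
    gam <- (gam + flips) %% 2L
  }
  gam
}

## one Wright-Fisher generation for a list of demes (each a list(H1, H2))
indiv_generation <- function(demes, M, genome) {
  nd <- length(demes)
  N <- nrow(demes[[1]]$H1)
  out <- vector("list", nd)
  for (d in seq_len(nd)) {
    src <- sample.int(nd, N, replace = TRUE, prob = M[d, ])
    H1 <- matrix(0L, N, genome$n_loci)
    H2 <- matrix(0L, N, genome$n_loci)
    for (s in unique(src)) {
      rows <- which(src == s)
      p1 <- sample.int(N, length(rows), replace = TRUE)
      p2 <- sample.int(N, length(rows), replace = TRUE)
      H1[rows, ] <- make_gametes(demes[[s]]$H1, demes[[s]]$H2, p1,
                                 genome$r_adj, genome$mu_site)
      H2[rows, ] <- make_gametes(demes[[s]]$H1, demes[[s]]$H2, p2,
                                 genome$r_adj, genome$mu_site)
    }
    out[[d]] <- list(H1 = H1, H2 = H2)
  }
  out
}

fst_from_demes <- function(demes) {
  nd <- length(demes)
  N <- nrow(demes[[1]]$H1)
  L <- ncol(demes[[1]]$H1)
  n <- matrix(N, nd, L)
  x <- t(vapply(demes, function(d) colSums(d$H1 + d$H2), numeric(L)))
  het <- t(vapply(demes, function(d) colSums(d$H1 != d$H2), numeric(L)))
  theta_from_stats(n, x, het)
}

#' Burn a metapopulation in to migration-drift equilibrium
#'
#' Frequency engine: draws locus frequencies from a neutral site-frequency
#' spectrum, replicates them across demes (zero initial differentiation) and
#' runs `freq_burnin_generations` of stepping-stone migration and drift.
#' Individual engine: initialises haplotypes from the same spectrum and runs
#' `burnin_generations` of diploid Wright-Fisher reproduction with
#' migration, mutation and recombination. At the default burn-in migration
#' rate of 0.5 the among-deme FST at the end of burn-in is ~0.
#'
#' @param config a [sim_config].
#' @param seed optional seed overriding `config$seed`.
#' @return object of class `metapop_state`.
#' @export
run_burnin <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed) else set.seed(config$seed)
  two_nd <- 2L * config$deme_size
  M <- migration_matrix(config$n_demes, config$burnin_migration)
  if (config$engine == "frequency") {
    p0 <- sfs_frequencies(config$n_loci, 2L * config$ne_total)
    P <- matrix(rep(p0, each = config$n_demes), config$n_demes,
                config$n_loci)
    for (g in seq_len(config$freq_burnin_generations))
      P <- freq_generation(P, M, two_nd)
    state <- list(engine = "frequency", P = P, config = config)
  } else {
    genome <- indiv_genome(config)
    p0 <- sfs_frequencies(genome$n_loci, 2L * config$ne_total)
    demes <- lapply(seq_len(config$n_demes), function(d) {
      list(H1 = matrix(stats::rbinom(config$deme_size * genome$n_loci, 1L,
                                     rep(p0, each = config$deme_size)),
                       config$deme_size, genome$n_loci),
           H2 = matrix(stats::rbinom(config$deme_size * genome$n_loci, 1L,
                                     rep(p0, each = config$deme_size)),
                       config$deme_size, genome$n_loci))
    })
    for (g in seq_len(config$burnin_generations))
      demes <- indiv_generation(demes, M, genome)
    state <- list(engine = "individual", demes = demes, genome = genome,
                  config = config)
  }
  class(state) <- "metapop_state"
  state
}

#' @export
print.metapop_state <- function(x, ...) {
  f <- metapop_fst(x)
  cat(sprintf("metapopulation state (%s engine): %d demes of %d; FST = %.4f\n",
              x$engine, x$config$n_demes, x$config$deme_size,
              f))
  invisible(x)
}

#' Current among-deme Weir-Cockerham FST of a metapopulation state
#' @param state a `metapop_state`.
#' @export
metapop_fst <- function(state) {
  if (state$engine == "frequency")
    fst_from_freqs(state$P, state$config$deme_size)
  else
    fst_from_demes(state$demes)
}

#' Mean expected heterozygosity of a metapopulation state
#'
#' `2p(1-p)` averaged over loci and demes (deme allele frequencies; no
#' sample-size correction -- demes are censused).
#' @param state a `metapop_state`.
#' @export
metapop_het <- function(state) {
  P <- if (state$engine == "frequency") state$P else
    t(vapply(state$demes,
             function(d) colSums(d$H1 + d$H2) / (2 * nrow(d$H1)),
             numeric(ncol(state$demes[[1]]$H1))))
  mean(2 * P * (1 - P))
}

## one fragmentation trajectory from a prepared state; returns the
## per-generation FST vector
frag_trajectory <- function(state, config) {
  M <- migration_matrix(config$n_demes, config$frag_migration)
  fst <- numeric(config$frag_generations)
  last <- 0
  if (state$engine == "frequency") {
    two_nd <- 2L * config$deme_size
    P <- state$P
    for (g in seq_len(config$frag_generations)) {
      P <- freq_generation(P, M, two_nd)
      f <- fst_from_freqs(P, config$deme_size)
      if (is.na(f)) {
        warning("all loci fixed globally; carrying previous FST",
                call. = FALSE)
        f <- last
      }
      fst[g] <- last <- f
    }
  } else {
    demes <- state$demes
    for (g in seq_len(config$frag_generations)) {
      demes <- indiv_generation(demes, M, state$genome)
      f <- fst_from_demes(demes)
      if (is.na(f)) {
        warning("all loci fixed globally; carrying previous FST",
                call. = FALSE)
        f <- last
      }
      fst[g] <- last <- f
    }
  }
  fst
}

#' Fragmentation-phase FST trajectories and generations-to-threshold
#'
#' Runs the fragmentation phase (migration set to `frag_migration`,
#' normally 0) for `n_replicates` independent replicates and records the
#' global Weir-Cockerham FST after every generation, the per-replicate first
#' generation at which FST reaches `fst_threshold`, and the ensemble mean of
#' those crossing generations (replicates that never cross within
#' `frag_generations` are excluded from the mean and counted).
#'
#' Each replicate re-runs its own burn-in so replicates are fully
#' independent; `state` supplies the template (engine and configuration).
#' Replicate seeds are derived deterministically from `config$seed`.
#'
#' @param state a `metapop_state` from [run_burnin] (used as the template
#'   and as replicate 1's starting state).
#' @param config optional [sim_config] override (default: the state's).
#' @return object of class `fst_trajectory_ensemble`: `fst` (replicates x
#'   generations matrix), `crossing` (integer vector, `NA` when not
#'   reached), `mean_crossing`, `n_not_crossed`, `threshold`, `config`.
#' @export
run_fragmentation <- function(state, config = NULL) {
  stopifnot(inherits(state, "metapop_state"))
  if (is.null(config)) config <- state$config
  reps <- config$n_replicates
  fst <- matrix(NA_real_, reps, config$frag_generations)
  for (r in seq_len(reps)) {
    st <- if (r == 1) state else
      run_burnin(config, seed = replicate_seed(config$seed, r))
    set.seed(replicate_seed(config$seed, r) + 1L)
    fst[r, ] <- frag_trajectory(st, config)
  }
  crossing <- apply(fst, 1, function(v) {
    w <- which(v >= config$fst_threshold)
    if (length(w)) w[1] else NA_integer_
  })
  structure(list(fst = fst, crossing = crossing,
                 mean_crossing = mean(crossing, na.rm = TRUE),
                 n_not_crossed = sum(is.na(crossing)),
                 threshold = config$fst_threshold, config = config),
            class = "fst_trajectory_ensemble")
}

## deterministic per-replicate seed below 2^31
replicate_seed <- function(master, r) {
  as.integer((as.numeric(master) * 1009 + 97 * r) %% 2147483647)
}

#' @export
print.fst_trajectory_ensemble <- function(x, ...) {
  cat(sprintf(paste0("fragmentation ensemble: %d replicates x %d generations ",
                     "(Ne=%d, %d demes)\n"),
              nrow(x$fst), ncol(x$fst), x$config$ne_total, x$config$n_demes))
  if (all(is.na(x$crossing))) {
    cat(sprintf("  FST=%.2f never reached\n", x$threshold))
  } else {
    cat(sprintf("  mean generations to FST=%.2f: %.1f (%d/%d replicates crossed)\n",
                x$threshold, x$mean_crossing,
                sum(!is.na(x$crossing)), nrow(x$fst)))
  }
  invisible(x)
}

#' @export
plot.fst_trajectory_ensemble <- function(x, ...) {
  t <- seq_len(ncol(x$fst))
  graphics::matplot(t, t(x$fst), type = "l", lty = 1,
                    col = grDevices::adjustcolor("grey50", 0.25),
                    xlab = "generations since fragmentation",
                    ylab = "global FST", ...)
  graphics::lines(t, colMeans(x$fst), col = "firebrick", lwd = 2)
  graphics::lines(t, analytic_expected_fst(t, x$config$deme_size),
                  col = "dodgerblue3", lty = 2)
  graphics::abline(h = x$threshold, lty = 3)
  invisible(x)
}

#' Pure-drift expectation for FST after complete isolation
#'
#' Closed-form expectation for fully isolated demes of constant size
#' starting from zero differentiation, ignoring mutation:
#' `1 - (1 - 1/(2*deme_size))^t`.
#'
#' @param t generations since isolation (vectorised).
#' @param deme_size diploid individuals per deme.
#' @export
analytic_expected_fst <- function(t, deme_size) {
  stopifnot(all(t >= 0), deme_size >= 1)
  1 - (1 - 1 / (2 * deme_size))^t
}

#' Sweep fragmentation scenarios over metapopulation sizes and deme counts
#'
#' Runs the full burn-in + fragmentation experiment for every combination of
#' `ne_totals` and `demes` (skipping combinations where the total is not
#' divisible) and tabulates the ensemble mean generations-to-threshold.
#' Scenario seeds are derived deterministically from the master seed.
#'
#' @param ne_totals total metapopulation sizes (default `c(100, 500, 1000)`).
#' @param demes deme counts (default `2:10`).
#' @param n_replicates replicates per scenario.
#' @param seed master seed.
#' @param ... further arguments to [sim_config].
#' @return data.frame `ne_total, n_demes, mean_crossing, n_crossed,
#'   n_replicates`.
#' @export
scenario_sweep <- function(ne_totals = c(100, 500, 1000), demes = 2:10,
                           n_replicates = 100, seed = 1L, ...) {
  grid <- expand.grid(ne_total = ne_totals, n_demes = demes)
  grid <- grid[grid$ne_total %% grid$n_demes == 0, , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- sim_config(ne_total = grid$ne_total[i], n_demes = grid$n_demes[i],
                      n_replicates = n_replicates,
                      seed = replicate_seed(seed, i), ...)
    ens <- run_fragmentation(run_burnin(cfg), cfg)
    data.frame(ne_total = cfg$ne_total, n_demes = cfg$n_demes,
               mean_crossing = ens$mean_crossing,
               n_crossed = sum(!is.na(ens$crossing)),
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}

#' Single-population Wright-Fisher genotype simulator
#'
#' Small diploid Wright-Fisher simulator (one panmictic population,
#' unlinked biallelic loci by default) used to study drift-generated
#' linkage disequilibrium, e.g. for validating LD-based effective-size
#' estimation. Loci start in linkage equilibrium at the supplied
#' frequencies; each generation every offspring draws two uniformly chosen
#' parents and one recombinant gamete from each.
#'
#' @param n_ind population size (diploid individuals).
#' @param n_loci number of loci.
#' @param generations generations to run.
#' @param init_freq initial allele frequencies (scalar, vector, or function
#'   of `n_loci`; default uniform on 0.2-0.8).
#' @param recomb recombination probability between adjacent loci (0.5 =
#'   unlinked).
#' @param mu per-locus mutation probability per gamete.
#' @param seed RNG seed.
#' @return list with genotype matrix `G` (individuals x loci, 0/1/2) and the
#'   final haplotypes.
#' @export
wf_population <- function(n_ind, n_loci, generations,
                          init_freq = function(L) stats::runif(L, 0.2, 0.8),
                          recomb = 0.5, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p0 <- if (is.function(init_freq)) init_freq(n_loci) else
    rep_len(init_freq, n_loci)
  H1 <- matrix(stats::rbinom(n_ind * n_loci, 1L, rep(p0, each = n_ind)),
               n_ind, n_loci)
  H2 <- matrix(stats::rbinom(n_ind * n_loci, 1L, rep(p0, each = n_ind)),
               n_ind, n_loci)
  genome <- list(n_loci = n_loci, r_adj = rep(recomb, n_loci - 1),
                 mu_site = mu)
  for (g in seq_len(generations)) {
    p1 <- sample.int(n_ind, n_ind, replace = TRUE)
    p2 <- sample.int(n_ind, n_ind, replace = TRUE)
    N1 <- make_gametes(H1, H2, p1, genome$r_adj, genome$mu_site)
    N2 <- make_gametes(H1, H2, p2, genome$r_adj, genome$mu_site)
    H1 <- N1; H2 <- N2
  }
  list(G = H1 + H2, H1 = H1, H2 = H2)
}
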