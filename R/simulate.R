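#' Forward-simulate two demes with migration and epoch-switched selection
#'
#' Runs the discrete-generation life cycle: for every offspring slot in
#' deme i, (1) a source deme j is chosen with probability
#' `migration[i, j]`; (2) two parents are drawn (uniformly, with
#' replacement) from deme j, weighted by the current epoch's viability of
#' their candidate-locus genotype; (3) each parent transmits one
#' uniformly chosen allele per locus (all loci unlinked); (4) stepwise
#' mutation is applied to microsatellite alleles. Deme sizes are
#' constant; there is no mutation at the candidate locus.
#'
#' @param config A [simulation_config()].
#' @return A list of [genotype_sample()] objects, one per row of
#'   `config$sampling_plan`, in plan order. The same config (including
#'   seed) always yields identical output.
#' @export
simulate_two_deme <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- 1L + config$n_microsats            # locus 1 = candidate
  n <- config$deme_sizes
  K <- length(config$candidate_alleles)

  init_deme <- function(d) {
    G <- matrix(0L, n[d], 2L * L)
    G[, 1:2] <- sample.int(K, 2L * n[d], replace = TRUE,
                           prob = config$candidate_init_freqs[d, ])
    if (config$n_microsats > 0L) {
      for (m in seq_len(config$n_microsats)) {
        ms <- config$microsat_init[[m]]
        cols <- 2L * m + 1:2
        G[, cols] <- ms$alleles[
          sample.int(length(ms$alleles), 2L * n[d], replace = TRUE,
                     prob = ms$freqs)]
      }
    }
    G
  }
  state <- list(init_deme(1L), init_deme(2L))

  # viability matrices cached per (deme, epoch)
  Vcache <- lapply(1:2, function(d)
    list(before = viability_matrix(config, d, "before"),
         after  = viability_matrix(config, d, "after")))

  plan <- config$sampling_plan
  out <- vector("list", nrow(plan))

  take_samples <- function(gen) {
    hit <- which(plan$generation == gen)
    for (k in hit) {
      d <- plan$deme[k]
      idx <- sample.int(n[d], plan$size[k])     # without replacement
      out[[k]] <<- state_to_sample(config, state[[d]][idx, , drop = FALSE],
                                   d, plan$year[k])
    }
  }
  take_samples(0L)

  for (t in seq_len(config$n_generations)) {
    ep <- epoch_of(config, t)
    # parent viabilities in each (source) deme under the current epoch
    w <- lapply(1:2, function(j) {
      V <- Vcache[[j]][[ep]]
      wj <- V[cbind(state[[j]][, 1L], state[[j]][, 2L])]
      if (all(wj <= 0))
        stop(sprintf("no viable parents in deme %s at generation %d",
                     config$deme_names[j], t))
      wj
    })
    new_state <- vector("list", 2L)
    for (i in 1:2) {
      src <- sample(1:2, n[i], replace = TRUE, prob = config$migration[i, ])
      child <- matrix(0L, n[i], 2L * L)
      for (j in 1:2) {
        slots <- which(src == j)
        k <- length(slots)
        if (!k) next
        p1 <- sample.int(n[j], k, replace = TRUE, prob = w[[j]])
        p2 <- sample.int(n[j], k, replace = TRUE, prob = w[[j]])
        # each parent passes one random allele per locus
        pick1 <- matrix(sample(0:1, k * L, replace = TRUE), k, L)
        pick2 <- matrix(sample(0:1, k * L, replace = TRUE), k, L)
        for (l in seq_len(L)) {
          child[slots, 2L * l - 1L] <- state[[j]][cbind(p1, 2L * l - 1L + pick1[, l])]
          child[slots, 2L * l] <- state[[j]][cbind(p2, 2L * l - 1L + pick2[, l])]
        }
      }
      new_state[[i]] <- child
    }
    if (config$mu_stepwise > 0 && config$n_microsats > 0L) {
      ms_cols <- 3:(2L * L)
      for (i in 1:2) {
        block <- new_state[[i]][, ms_cols, drop = FALSE]
        hit <- which(stats::runif(length(block)) < config$mu_stepwise)
        if (length(hit)) {
          step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
          val <- block[hit] + step
          below <- val < config$microsat_floor
          val[below] <- 2L * config$microsat_floor - val[below]  # reflect
          block[hit] <- val
          new_state[[i]][, ms_cols] <- block
        }
      }
    }
    state <- new_state
    take_samples(t)
  }
  out
}

# integer state rows -> genotype_sample (labels, pair-normalized)
state_to_sample <- function(config, G, deme, year) {
  L <- 1L + config$n_microsats
  lab <- function(col) {
    if (col <= 2L) config$candidate_alleles[G[, col]]
    else as.character(G[, col])
  }
  nm <- c("candidate",
          if (config$n_microsats > 0L)
            sprintf("msat%02d", seq_len(config$n_microsats)))
  a1 <- matrix(NA_character_, nrow(G), L, dimnames = list(NULL, nm))
  a2 <- a1
  for (l in seq_len(L)) {
    a1[, l] <- lab(2L * l - 1L)
    a2[, l] <- lab(2L * l)
  }
  # microsatellite labels zero-padded so lexicographic pair order is numeric
  if (config$n_microsats > 0L) {
    a1[, -1L] <- sprintf("%03d", as.integer(a1[, -1L]))
    a2[, -1L] <- sprintf("%03d", as.integer(a2[, -1L]))
  }
  genotype_sample(config$deme_names[deme], year, a1, a2,
                  locus_type = c("candidate",
                                 rep("microsatellite", config$n_microsats)))
}

#' Deterministic (infinite-population) candidate-allele trajectory
#'
#' Iterates the expected allele-frequency recursion implied by the same
#' life-cycle order as [simulate_two_deme()] (selection within the source
#' deme, then backward migration, then random union of gametes), ignoring
#' drift. Serves as the analytical oracle for the stochastic simulator.
#'
#' @param config A [simulation_config()]; microsatellites are ignored.
#' @return A 3-d array `(n_generations + 1) x 2 x n_alleles` of expected
#'   candidate allele frequencies, generations 0..n in rows.
#' @export
deterministic_trajectory <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- length(config$candidate_alleles)
  p <- config$candidate_init_freqs          # 2 x K
  Vcache <- lapply(1:2, function(d)
    list(before = viability_matrix(config, d, "before"),
         after  = viability_matrix(config, d, "after")))
  traj <- array(NA_real_, c(config$n_generations + 1L, 2L, K),
                dimnames = list(NULL, config$deme_names,
                                config$candidate_alleles))
  traj[1L, , ] <- p
  for (t in seq_len(config$n_generations)) {
    ep <- epoch_of(config, t)
    pstar <- matrix(0, 2L, K)
    for (j in 1:2) {
      V <- Vcache[[j]][[ep]]
      wbar <- as.numeric(p[j, ] %*% V %*% p[j, ])
      if (wbar <= 0)
        stop(sprintf("mean fitness is zero in deme %s at generation %d",
                     config$deme_names[j], t))
      pstar[j, ] <- p[j, ] * as.numeric(V %*% p[j, ]) / wbar
    }
    p <- config$migration %*% pstar
    traj[t + 1L, , ] <- p
  }
  traj
}
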