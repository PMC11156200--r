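#' Run length rule for coefficient-of-variation scans
#'
#' Reliable gap statistics need more generations when the mutation supply
#' `N * u * L` is small, so scans use
#' `T = max(T_budget / (N * u * L), 10^4)` generations, always rounded up
#' to the nearest power of ten.  The full-scale budget is `T_budget = 10^6`.
#'
#' @param N,u,L population size, per-site mutation rate, genome length.
#' @param t_budget numerator of the rule (default `1e6`).
#' @return run length in generations (a power of ten).
#' @export
cv_run_length <- function(N, u, L, t_budget = 1e6) {
  raw <- max(t_budget / (N * u * L), 1e4)
  10^ceiling(log10(raw) - 1e-9)
}

phi_of <- function(map, nc, phenotype) {
  phi <- if (!is.null(nc) && !is.null(nc$phi)) nc$phi else map$phi
  if (is.null(phi)) stop("no mutation spectrum available: pass an nc with ",
                         "statistics or a map with a phi")
  if (!phenotype %in% names(phi) || phi[[phenotype]] <= 0) {
    stop("tracked phenotype ", phenotype, " has zero mutation probability")
  }
  phi
}

#' Burst-histogram experiment
#'
#' The core overdispersion design: a population evolves under strong
#' stabilizing selection (every non-initial phenotype unviable), the
#' appearances of one tracked phenotype are logged, and the per-window
#' counts are compared against (i) the Poisson distribution with the same
#' mean and (ii) the approximate Poisson-mixture prediction built from the
#' per-genotype neighbour counts.  Defaults are the full-scale design
#' (`N = 1000`, `u = 2e-5`, `dt = 3000`); pass a smaller `generations` for
#' desk-scale runs.
#'
#' @param map a `gp_map` (or the string `"average_rate"` for the matched
#'   Poisson control).
#' @param tracked the phenotype whose appearances are analysed.
#' @param nc the initial neutral component with statistics (required for
#'   structured maps; optional for random maps and the average-rate
#'   control, whose spectrum comes from `phi`).
#' @param phi spectrum for the average-rate control / random map; defaults
#'   to `nc$phi` or the map's own spectrum.
#' @param N,u population size and per-site mutation rate.
#' @param generations logged generations.
#' @param dt window length.
#' @param seed RNG seed.
#' @param initial initial phenotype; defaults to `nc$phenotype` or the
#'   spectrum's first entry.
#' @return list with `counts` (per-window), `V_t`, `summary` (below /
#'   within / above fractions), `poisson_mean`, `poisson_band_mass`,
#'   `mixture` (predicted count distribution, when neighbour counts are
#'   available), `n_events`, and `params`.
#' @export
run_burst_histogram <- function(map, tracked, nc = NULL, phi = NULL,
                                N = 1000, u = 2e-5, generations = 1e7,
                                dt = 3000, seed = 1, initial = NULL) {
  average_rate <- identical(map, "average_rate")
  if (is.null(phi)) {
    phi <- if (average_rate) stop("phi is required for the average-rate model")
    else phi_of(map, nc, tracked)
  }
  if (is.null(initial)) {
    initial <- if (!is.null(nc)) nc$phenotype else names(phi)[1]
  }
  L <- if (average_rate) 12 else map$L
  scheme <- fitness_scheme(initial,
                           restrict_to_nc = !average_rate &&
                             !inherits(map, "random_gp_map"))
  run <- if (average_rate) {
    average_rate_run(phi, scheme, N = N, u = u, L = L,
                     generations = generations, seed = seed,
                     tracked = tracked)
  } else {
    wright_fisher_run(map, scheme, N = N, u = u, generations = generations,
                      seed = seed, tracked = tracked, nc = nc)
  }
  counts <- interval_counts(run, tracked, dt)
  times <- unique(run$events$generation[run$events$phenotype == tracked])
  vt <- if (length(times) >= 3) coefficient_of_variation(times) else NA_real_
  mu <- mean(counts)
  mixture <- NULL
  if (!is.null(nc) && !is.null(nc$n_counts)) {
    mixture <- poisson_mixture_prediction(
      portal_count_distribution(nc, tracked), N = N, u = u,
      K = if (average_rate) 4 else map$K, dt = dt)
  } else if (inherits(map, "random_gp_map")) {
    # iid map: neighbour counts are Binomial(L(K-1), phi_tracked)
    D <- map$L * (map$K - 1)
    w <- stats::dbinom(0:D, D, phi[[tracked]])
    names(w) <- 0:D
    mixture <- poisson_mixture_prediction(w[w > 1e-12], N = N, u = u,
                                          K = map$K, dt = dt)
  }
  list(counts = counts,
       V_t = vt,
       summary = if (mu > 0) burst_summary(counts, mu) else NULL,
       poisson_mean = mu,
       poisson_band_mass = if (mu > 0) poisson_band_mass(mu) else NA_real_,
       mixture = mixture,
       n_events = sum(counts),
       params = list(model = if (average_rate) "average_rate" else map$type,
                     tracked = tracked, N = N, u = u,
                     generations = generations, dt = dt, seed = seed))
}

#' Coefficient-of-variation scan over population parameters
#'
#' Repeats the burst design across a grid of `(N, u)` values and summarises
#' each run by `V_t` of the tracked phenotype's inter-appearance times.
#' Run lengths follow [cv_run_length()].
#'
#' @inheritParams run_burst_histogram
#' @param grid data frame with columns `N` and `u`.
#' @param t_budget run-length budget passed to [cv_run_length()] (`1e6` is
#'   the full-scale value; smaller values give desk-scale scans).
#' @return data frame with `N`, `u`, `NuL`, `T`, `n_events`, `V_t`.
#' @export
run_cv_scan <- function(map, tracked, grid, nc = NULL, phi = NULL,
                        seed = 1, t_budget = 1e6, initial = NULL) {
  average_rate <- identical(map, "average_rate")
  L <- if (average_rate) 12 else map$L
  out <- grid
  out$NuL <- grid$N * grid$u * L
  out$T <- mapply(cv_run_length, grid$N, grid$u,
                  MoreArgs = list(L = L, t_budget = t_budget))
  out$n_events <- NA_integer_
  out$V_t <- NA_real_
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- run_burst_histogram(map, tracked, nc = nc, phi = phi,
                             N = grid$N[i], u = grid$u[i],
                             generations = out$T[i], dt = max(out$T[i] / 1e4, 1),
                             seed = seeds[i], initial = initial)
    out$n_events[i] <- r$n_events
    out$V_t[i] <- r$V_t
  }
  out
}

#' Fixation-time scan over selection coefficients
#'
#' A single phenotype `target` has selective advantage `s` over the initial
#' phenotype; all other phenotypic changes are unviable.  For every `s` in
#' the grid the simulation is repeated until the fixation criterion fires
#' (or a generation cap is hit, recorded as censored), and the mean
#' fixation time - introduction plus fixation - is reported next to the
#' origin-fixation prediction [t_fix_average_rate()].
#'
#' @inheritParams run_burst_histogram
#' @param target the adaptive phenotype.
#' @param s_grid selection coefficients to scan.
#' @param reps repetitions per grid point (the full-scale design uses
#'   `10^3`).
#' @param cap_generations per-run generation cap; runs that do not fix are
#'   censored and flagged.
#' @return data frame with `s`, `mean_t_fix`, `n_fixed`, `n_censored`,
#'   `t_fix_theory`.
#' @export
run_fixation_time_scan <- function(map, target, s_grid, reps, nc = NULL,
                                   phi = NULL, N = 1000, u = 2e-5,
                                   seed = 1, cap_generations = 1e7,
                                   initial = NULL) {
  average_rate <- identical(map, "average_rate")
  phi <- if (is.null(phi)) phi_of(map, nc, target) else phi
  if (is.null(initial)) {
    initial <- if (!is.null(nc)) nc$phenotype else names(phi)[1]
  }
  L <- if (average_rate) 12 else map$L
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, length(s_grid) * reps),
                  nrow = length(s_grid))
  out <- data.frame(s = s_grid, mean_t_fix = NA_real_, n_fixed = 0L,
                    n_censored = 0L,
                    t_fix_theory = t_fix_average_rate(phi[[target]], s_grid,
                                                      N, u, L))
  for (i in seq_along(s_grid)) {
    scheme <- fitness_scheme(initial, s = setNames(s_grid[i], target),
                             restrict_to_nc = !average_rate &&
                               !inherits(map, "random_gp_map"))
    t_fix <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      run <- if (average_rate) {
        average_rate_run(phi, scheme, N = N, u = u, L = L,
                         generations = cap_generations, seed = seeds[i, r],
                         stop_at_fixation = TRUE)
      } else {
        wright_fisher_run(map, scheme, N = N, u = u,
                          generations = cap_generations, seed = seeds[i, r],
                          nc = nc, stop_at_fixation = TRUE)
      }
      if (nrow(run$fixations)) t_fix[r] <- run$fixations$generation[1]
    }
    out$mean_t_fix[i] <- mean(t_fix, na.rm = TRUE)
    out$n_fixed[i] <- sum(!is.na(t_fix))
    out$n_censored[i] <- sum(is.na(t_fix))
  }
  out
}

#' Two-peak first-fixation experiment
#'
#' Two phenotypes are fitter than the initial one: a mutationally frequent
#' peak `p_f` (spectrum entry `phi_f`, advantage `s_f`) and a rare peak
#' `p_r` (`phi_r`, advantage `s_r`).  All other phenotypic changes are
#' unviable.  Each repetition runs until the first fixation; the fraction
#' of runs won by `p_r` is reported with a binomial confidence interval,
#' next to the origin-fixation predictions (the closed-form ratio and the
#' general fixation-time form, which coincide for the average-rate model).
#'
#' @inheritParams run_fixation_time_scan
#' @param p_f,p_r identifiers of the frequent and rare phenotypes.
#' @param s_f advantage of `p_f`.
#' @param s_r_grid advantages of `p_r` to scan (the selective bias is
#'   `s_r / s_f`).
#' @param N population size (the full-scale design uses 500).
#' @return data frame with `s_r`, `bias` (`s_r/s_f`), `p_r_first`,
#'   `ci_lo`, `ci_hi`, `n_decided`, `n_censored`, and the predictions
#'   `theory_ratio` and `theory_times`.
#' @export
run_two_peak <- function(map, p_f, p_r, s_f, s_r_grid, reps, nc = NULL,
                         phi = NULL, N = 500, u = 2e-5, seed = 1,
                         cap_generations = 1e7, initial = NULL) {
  average_rate <- identical(map, "average_rate")
  if (is.null(phi)) {
    phi <- phi_of(map, nc, p_f)
    phi_of(map, nc, p_r)  # validates
  }
  if (is.null(initial)) {
    initial <- if (!is.null(nc)) nc$phenotype else names(phi)[1]
  }
  L <- if (average_rate) 12 else map$L
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, length(s_r_grid) * reps),
                  nrow = length(s_r_grid))
  out <- data.frame(s_r = s_r_grid, bias = s_r_grid / s_f,
                    p_r_first = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    n_decided = 0L, n_censored = 0L)
  out$theory_ratio <- p_r_fixes_origin_fixation(phi[[p_f]], phi[[p_r]],
                                                s_f, s_r_grid, N)
  t_f <- t_fix_average_rate(phi[[p_f]], s_f, N, u, L)
  out$theory_times <- vapply(s_r_grid, function(sr) {
    first_fixation_probability(
      c(t_fix_average_rate(phi[[p_r]], sr, N, u, L), t_f))[1]
  }, numeric(1))
  for (i in seq_along(s_r_grid)) {
    scheme <- fitness_scheme(initial,
                             s = setNames(c(s_f, s_r_grid[i]), c(p_f, p_r)),
                             restrict_to_nc = !average_rate &&
                               !inherits(map, "random_gp_map"))
    winner <- character(reps)
    for (r in seq_len(reps)) {
      run <- if (average_rate) {
        average_rate_run(phi, scheme, N = N, u = u, L = L,
                         generations = cap_generations, seed = seeds[i, r],
                         stop_at_fixation = TRUE)
      } else {
        wright_fisher_run(map, scheme, N = N, u = u,
                          generations = cap_generations, seed = seeds[i, r],
                          nc = nc, stop_at_fixation = TRUE)
      }
      winner[r] <- if (nrow(run$fixations)) run$fixations$phenotype[1] else
        NA_character_
    }
    dec <- !is.na(winner)
    k <- sum(winner[dec] == p_r)
    n <- sum(dec)
    out$n_decided[i] <- n
    out$n_censored[i] <- reps - n
    if (n > 0) {
      out$p_r_first[i] <- k / n
      ci <- stats::binom.test(k, n)$conf.int
      out$ci_lo[i] <- ci[1]
      out$ci_hi[i] <- ci[2]
    }
  }
  out
}

#' Generate a small self-contained fixture GP map
#'
#' Builds an exhaustively enumerated random GP map over a small genotype
#' space (`K^L <= 10^6`), extracts a reference neutral component with
#' statistics, and optionally writes all artifacts (map table, NC node and
#' edge files) in the standard formats.  With `portal_clustering > 0` a
#' fraction of each non-initial phenotype's genotypes is re-placed by
#' breadth-first growth around seed genotypes (label swaps, so phenotype
#' frequencies are exactly preserved), emulating the clustered portals that
#' non-neutral correlations create in real maps.
#'
#' @param L,K genotype space shape (`K^L <= 1e6`).
#' @param n_phenotypes number of phenotypes `P0 ... P<n-1>`; `P0` is the
#'   initial phenotype.
#' @param phi_profile `"uniform"`, or a numeric vector of `n_phenotypes`
#'   relative frequencies.
#' @param portal_clustering fraction in `[0, 1)` of non-initial labels
#'   placed by clustered growth instead of independently.
#' @param seed RNG seed fixing the map.
#' @param min_nc_size smallest acceptable component; seeds of `P0` are
#'   tried in deterministic order until one qualifies.
#' @param out_dir optional directory to write artifacts into.
#' @return list with `map` (a [table_gp_map()]), `nc` (with statistics),
#'   and `files` (paths, when written).
#' @export
make_fixture_map <- function(L, K, n_phenotypes = 4,
                             phi_profile = "uniform",
                             portal_clustering = 0, seed = 1,
                             min_nc_size = 2, out_dir = NULL) {
  stopifnot(K^L <= 1e6, n_phenotypes >= 2,
            portal_clustering >= 0, portal_clustering < 1)
  phens <- paste0("P", seq_len(n_phenotypes) - 1)
  phi <- if (identical(phi_profile, "uniform")) {
    rep(1 / n_phenotypes, n_phenotypes)
  } else {
    stopifnot(length(phi_profile) == n_phenotypes)
    phi_profile / sum(phi_profile)
  }
  alphabet <- default_alphabet(K)
  proto <- new_gp_map("proto", L = L, K = as.integer(K), alphabet = alphabet)
  genotypes <- all_genotypes(proto)
  set.seed(seed)
  labels <- sample(phens, length(genotypes), replace = TRUE, prob = phi)
  if (portal_clustering > 0) {
    nbr_codes <- function(code) {
      sym <- integer(L)
      c0 <- code
      for (j in seq_len(L)) { sym[j] <- c0 %% K; c0 <- c0 %/% K }
      unlist(lapply(seq_len(L) - 1, function(j) {
        code + ((0:(K - 1))[-(sym[j + 1] + 1)] - sym[j + 1]) * K^j
      }))
    }
    for (p in phens[-1]) {
      idx <- which(labels == p)          # 1-based; code = idx - 1
      k <- round(portal_clustering * length(idx))
      if (k < 2) next
      start <- idx[sample.int(length(idx), 1)]
      cluster <- start
      frontier <- start
      moved <- 0L
      while (moved < k && length(frontier)) {
        cand <- unique(unlist(lapply(frontier - 1, nbr_codes))) + 1
        cand <- setdiff(cand, cluster)
        if (!length(cand)) break
        frontier <- integer(0)
        for (g in cand) {
          if (moved >= k) break
          if (labels[g] == p) { cluster <- c(cluster, g); frontier <- c(frontier, g); next }
          donors <- setdiff(idx, cluster)
          if (!length(donors)) break
          d <- donors[sample.int(length(donors), 1)]
          # swap labels: g becomes p, the remote donor takes g's label
          labels[d] <- labels[g]
          labels[g] <- p
          idx <- c(setdiff(idx, d), g)
          cluster <- c(cluster, g)
          frontier <- c(frontier, g)
          moved <- moved + 1L
        }
      }
    }
  }
  map <- table_gp_map(setNames(labels, genotypes), alphabet = alphabet)
  seeds_p0 <- genotypes[labels == "P0"]
  nc <- NULL
  for (g in utils::head(seeds_p0, 50)) {
    cand <- build_neutral_component(g, map)
    if (length(cand$genotypes) >= min_nc_size) { nc <- cand; break }
  }
  if (is.null(nc)) {
    stop("no neutral component of size >= ", min_nc_size,
         " found among the first 50 seeds")
  }
  nc <- nc_statistics(nc, map)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    map_file <- file.path(out_dir, "map.tsv")
    write_gp_map_table(map, genotypes, map_file)
    nc_files <- write_neutral_component(nc, file.path(out_dir, "nc"))
    files <- c(map_file, nc_files)
  }
  list(map = map, nc = nc, files = files)
}

#' Read an experiment configuration file
#'
#' YAML (when the yaml package is installed) or JSON, with keys matching
#' the experiment functions' arguments (`map`, `seed_genotype`, `N`, `u`,
#' `generations`, `fitness`, `tracked`, `rng_seed`, ...).
#'
#' @param file path to a `.yaml`/`.yml` or `.json` configuration.
#' @return a named list.
#' @export
read_experiment_config <- function(file) {
  if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package; use JSON instead")
    }
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
}
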