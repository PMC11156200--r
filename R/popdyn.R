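#' Fitness schemes over phenotypes
#'
#' Fitness is assigned per phenotype: the initial phenotype has fitness 1, a
#' phenotype with selective advantage `s` has fitness `1 + s`, and every
#' other phenotype defaults to fitness 0 (unviable).  With
#' `restrict_to_nc = TRUE` (the default, matching the simulation protocol on
#' structured maps) genotypes that carry the initial phenotype but lie
#' outside the initial neutral component also get fitness 0, which excludes
#' irreproducible jumps to other NCs of the initial phenotype's neutral set.
#'
#' @param initial identifier of the initial (resident) phenotype.
#' @param s named numeric vector of selective advantages (`fitness = 1 + s`)
#'   for adaptive phenotypes.
#' @param default_fitness fitness of unnamed phenotypes (0 = lethal).
#' @param restrict_to_nc confine fitness 1 for the initial phenotype to the
#'   initial NC's genotypes (ignored by the random map and the average-rate
#'   model, which carry no NC structure).
#' @return an object of class `fitness_scheme`.
#' @export
fitness_scheme <- function(initial, s = numeric(0), default_fitness = 0,
                           restrict_to_nc = TRUE) {
  stopifnot(is.character(initial), length(initial) == 1)
  if (length(s) && is.null(names(s))) stop("s must be a named vector")
  structure(list(initial = initial, s = s,
                 default_fitness = default_fitness,
                 restrict_to_nc = restrict_to_nc),
            class = "fitness_scheme")
}

fitness_of_phenotypes <- function(scheme, phens) {
  out <- rep(scheme$default_fitness, length(phens))
  out[phens == scheme$initial] <- 1
  hit <- match(phens, names(scheme$s))
  out[!is.na(hit)] <- 1 + scheme$s[hit[!is.na(hit)]]
  out
}

#' Fixation criterion
#'
#' A fixation event has occurred when strictly less than 25% of the
#' population carries the initial phenotype.  The winner is the most
#' abundant non-initial phenotype; exact ties are broken deterministically
#' by phenotype identifier order.
#'
#' @param state named integer vector (or data frame with `phenotype` and
#'   `count`) of phenotype counts.
#' @param initial_phenotype the resident phenotype identifier.
#' @param threshold fraction below which fixation is declared (default
#'   0.25, strict inequality).
#' @return list with `fixed` (logical) and `winner` (phenotype id or `NA`).
#' @export
detect_fixation <- function(state, initial_phenotype, threshold = 0.25) {
  if (is.data.frame(state)) {
    state <- tapply(state$count, state$phenotype, sum)
  }
  total <- sum(state)
  init <- if (initial_phenotype %in% names(state))
    state[[initial_phenotype]] else 0
  fixed <- init < threshold * total
  winner <- NA_character_
  if (fixed) {
    rest <- state[names(state) != initial_phenotype]
    rest <- rest[rest > 0]
    if (length(rest)) {
      rest <- rest[order(names(rest))]
      winner <- names(rest)[which.max(rest)]
    }
  }
  list(fixed = fixed, winner = winner)
}

# ---------------------------------------------------------------------------
# simulation views: how a GP map is presented to the compiled engine
# ---------------------------------------------------------------------------

# local view: NC members with full adjacency + their 1-mutation boundary;
# boundary genotypes of viable phenotypes get adjacency too (one more shell)
build_local_view <- function(map, nc, scheme) {
  interior <- nc$genotypes
  p0 <- nc$phenotype
  nb_list <- lapply(interior, point_mutation_neighbors, map = map)
  all_nb <- unique(unlist(nb_list, use.names = FALSE))
  boundary <- setdiff(all_nb, interior)
  ph_boundary <- map_phenotype(map, boundary)
  viable_b <- boundary[fitness_of_phenotypes(scheme, ph_boundary) > 0 &
                         ph_boundary != p0]
  shell2 <- character(0)
  nb2_list <- list()
  if (length(viable_b)) {
    nb2_list <- lapply(viable_b, point_mutation_neighbors, map = map)
    shell2 <- setdiff(unique(unlist(nb2_list, use.names = FALSE)),
                      c(interior, boundary))
  }
  nodes <- c(interior, boundary, shell2)
  phen <- c(rep(p0, length(interior)), ph_boundary,
            if (length(shell2)) map_phenotype(map, shell2) else character(0))
  idx <- seq_along(nodes)
  names(idx) <- nodes
  D <- map$L * (map$K - 1L)
  adj <- matrix(0L, nrow = length(nodes), ncol = D)
  has_adj <- logical(length(nodes))
  fill <- function(node, nb) {
    i <- idx[[node]]
    hit <- idx[nb]
    hit[is.na(hit)] <- 0L
    adj[i, ] <<- as.integer(hit)
    has_adj[i] <<- TRUE
  }
  for (k in seq_along(interior)) fill(interior[k], nb_list[[k]])
  for (k in seq_along(viable_b)) fill(viable_b[k], nb2_list[[k]])
  list(nodes = nodes, phen = phen, adj = adj, has_adj = has_adj,
       in_nc = c(rep(TRUE, length(interior)),
                 rep(FALSE, length(boundary) + length(shell2))))
}

# all K^L genotypes of a sequence map, in engine code order
all_genotypes <- function(map) {
  g <- expand.grid(rep(list(map$alphabet), map$L),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(paste0, g)
}

# mean-spectrum fallback rows for phenotype-only individuals: the initial
# phenotype mutates along phi; any other phenotype keeps itself with the
# same generic robustness rho and otherwise becomes the undefined phenotype
# (a deliberate coarse approximation, see the methods vignette)
fallback_spectrum <- function(phen_levels, p0, phi) {
  P <- length(phen_levels)
  S <- matrix(0, P, P, dimnames = list(phen_levels, phen_levels))
  rho <- if (p0 %in% names(phi)) unname(phi[p0]) else 0
  none_col <- if (PHENOTYPE_NONE %in% phen_levels) PHENOTYPE_NONE else p0
  for (p in phen_levels) {
    if (p == p0) {
      row <- rep(0, P)
      hit <- match(names(phi), phen_levels)
      row[hit[!is.na(hit)]] <- phi[!is.na(hit)]
      row[phen_levels == none_col] <-
        row[phen_levels == none_col] + sum(phi[is.na(hit)])
      S[p, ] <- row / sum(row)
    } else {
      S[p, p] <- rho
      S[p, none_col] <- S[p, none_col] + (1 - rho)
    }
  }
  S
}

# ---------------------------------------------------------------------------
# Wright-Fisher simulation on a GP map
# ---------------------------------------------------------------------------

#' Wright-Fisher simulation on a GP map
#'
#' Simulates a haploid population of fixed size `N` under Wright-Fisher
#' resampling with fitness-weighted multinomial selection.  Each offspring
#' site mutates independently with probability `u` to a uniformly random
#' different symbol.  The run is preceded by a burn-in of `10 * N`
#' generations of neutral drift on the initial NC (all non-initial
#' phenotypes treated as unviable, no logging) to randomise the forced
#' initial condition; logged generations then start at 0.  Every offspring
#' whose phenotype is in `tracked` and differs from its parent's phenotype
#' is logged as one appearance; unviable mutants are logged before selection
#' removes them in the next resampling.
#'
#' How the map is presented to the engine is chosen automatically: seeded
#' random maps are evaluated lazily by their hash; small sequence spaces
#' (`K^L <= 2^16`) are materialised exhaustively; otherwise a local view
#' around the initial NC (members, their mutational boundary, and the
#' boundary of viable boundary genotypes) is materialised, which is exact
#' for the strong-stabilizing-selection and single-sweep designs studied
#' here.
#'
#' @param map a `gp_map`.
#' @param fitness a [fitness_scheme()]; its initial phenotype must be the
#'   NC's phenotype.
#' @param N population size.
#' @param u per-site, per-generation mutation probability.
#' @param generations number of logged generations.
#' @param seed RNG seed for the whole run (burn-in included).
#' @param tracked character vector of phenotypes whose appearances are
#'   logged.
#' @param nc the initial [neutral_component][build_neutral_component]
#'   (required unless the map is a random map).
#' @param init_genotype starting genotype; defaults to the first NC member
#'   (random maps: a genotype of the initial phenotype found by scanning).
#' @param burn_in burn-in generations (default `10 * N`).
#' @param stop_at_fixation stop once the fixation criterion fires.
#' @param track_substitutions also record genotype-level substitutions (the
#'   generation at which the population becomes fully monomorphic on a new
#'   genotype), used for neutral-clock diagnostics in the weak-mutation
#'   regime.
#' @param max_events cap on logged events.
#' @return an object of class `popdyn_run`: list with `events` (data frame
#'   `generation, event_type, parent_genotype, mutant_genotype, phenotype`),
#'   `fixations`, `substitutions`, `final` (genotype counts), and `params`.
#' @export
wright_fisher_run <- function(map, fitness, N, u, generations, seed,
                              tracked = character(0), nc = NULL,
                              init_genotype = NULL, burn_in = 10 * N,
                              stop_at_fixation = FALSE,
                              track_substitutions = FALSE,
                              max_events = 5e6) {
  stopifnot(N >= 1, u >= 0, u <= 1)
  set.seed(seed)
  p0 <- fitness$initial

  if (inherits(map, "random_gp_map")) {
    phen_levels <- names(map$phi)
    if (is.null(init_genotype)) {
      init_genotype <- find_genotype_with_phenotype(map, p0)
    }
    run1 <- function(fit_phen, gens, init_key, init_n, log_ev, stop_fix) {
      .sim_engine(2L, integer(0), matrix(0L, 0, 0), logical(0),
                  map$cum_phi, map$map_seed, map$L, map$K,
                  fit_phen, numeric(0), matrix(0, 0, 0),
                  init_key, init_n, as.integer(N), u, gens,
                  if (log_ev) match(tracked, phen_levels) else integer(0),
                  match(p0, phen_levels),
                  stop_fix, 0.25, FALSE, track_substitutions && log_ev,
                  as.integer(max_events))
    }
    decode <- function(keys) code_to_genotype(keys, map)
    init_key <- genotype_to_code(init_genotype, map)
  } else {
    small <- !is.na(map$K) && map$K^map$L <= 2^16
    if (small) {
      nodes <- all_genotypes(map)
      phen_chr <- map_phenotype(map, nodes)
      view <- NULL
    } else {
      if (is.null(nc)) stop("a neutral component is required for this map")
      view <- build_local_view(map, nc, fitness)
      nodes <- view$nodes
      phen_chr <- view$phen
    }
    phen_levels <- sort(unique(c(phen_chr, p0, tracked, names(fitness$s))))
    phen_idx <- match(phen_chr, phen_levels)
    fit_phen_tpl <- fitness_of_phenotypes(fitness, phen_levels)
    if (is.null(init_genotype)) {
      init_genotype <- if (!is.null(nc)) nc$genotypes[1] else
        nodes[match(p0, phen_chr)]
    }
    spec <- fallback_spectrum(phen_levels, p0,
                              if (!is.null(nc) && !is.null(nc$phi)) nc$phi
                              else setNames(1, p0))
    run1 <- function(fit_phen, gens, init_key, init_n, log_ev, stop_fix) {
      fit_node <- fit_phen[phen_idx]
      if (fitness$restrict_to_nc && !is.null(view)) {
        fit_node[!view$in_nc & phen_chr == p0] <- 0
      }
      if (small) {
        .sim_engine(1L, phen_idx, matrix(0L, 0, 0), logical(0),
                    numeric(0), 0, map$L, map$K,
                    fit_phen, numeric(0), spec,
                    init_key, init_n, as.integer(N), u, gens,
                    if (log_ev) match(tracked, phen_levels) else integer(0),
                    match(p0, phen_levels),
                    stop_fix, 0.25, FALSE, track_substitutions && log_ev,
                    as.integer(max_events))
      } else {
        .sim_engine(0L, phen_idx, view$adj, view$has_adj,
                    numeric(0), 0, map$L, map$K,
                    fit_phen, fit_node, spec,
                    init_key, init_n, as.integer(N), u, gens,
                    if (log_ev) match(tracked, phen_levels) else integer(0),
                    match(p0, phen_levels),
                    stop_fix, 0.25, FALSE, track_substitutions && log_ev,
                    as.integer(max_events))
      }
    }
    decode <- if (small) function(keys) code_to_genotype(keys, map) else
      function(keys) nodes[keys + 1]
    init_key <- if (small) genotype_to_code(init_genotype, map) else
      match(init_genotype, nodes) - 1
    if (is.na(init_key)) stop("init_genotype is not in the simulated view")
  }

  fit_main <- fitness_of_phenotypes(fitness, phen_levels)
  fit_burn <- ifelse(phen_levels == p0, 1, 0)

  state_key <- init_key
  state_n <- as.integer(N)
  if (burn_in > 0) {
    rb <- run1(fit_burn, as.double(burn_in), state_key, state_n,
               log_ev = FALSE, stop_fix = FALSE)
    if (nzchar(rb$error)) {
      stop("burn-in failed at generation ", rb$error_gen, ": ", rb$error)
    }
    state_key <- rb$final_key
    state_n <- rb$final_n
  }
  res <- run1(fit_main, as.double(generations), state_key, state_n,
              log_ev = TRUE, stop_fix = stop_at_fixation)
  if (nzchar(res$error)) {
    stop("population lost all viable individuals at generation ",
         res$error_gen, ": ", res$error)
  }
  assemble_run(res, decode, phen_levels, list(
    model = "wright_fisher", map_type = map$type, N = N, u = u, L = map$L,
    K = map$K, generations = generations, burn_in = burn_in, seed = seed,
    tracked = tracked, initial = p0))
}

# scan genotypes deterministically (code order) for one with phenotype p
find_genotype_with_phenotype <- function(map, p, limit = 1e6) {
  batch <- 4096
  for (start in seq(0, limit - 1, by = batch)) {
    codes <- start:(start + batch - 1)
    codes <- codes[codes < map$K^map$L]
    if (!length(codes)) break
    g <- code_to_genotype(codes, map)
    hit <- which(map_phenotype(map, g) == p)
    if (length(hit)) return(g[hit[1]])
  }
  stop("no genotype with phenotype ", p, " found among the first ",
       limit, " codes")
}

assemble_run <- function(res, decode, phen_levels, params) {
  dec_or_na <- function(keys) {
    out <- rep(NA_character_, length(keys))
    ok <- !is.na(keys)
    if (any(ok)) out[ok] <- decode(keys[ok])
    out
  }
  events <- data.frame(
    generation = res$event_gen,
    event_type = rep("appearance", length(res$event_gen)),
    parent_genotype = dec_or_na(res$event_parent_key),
    mutant_genotype = dec_or_na(res$event_child_key),
    phenotype = phen_levels[res$event_child_phen],
    stringsAsFactors = FALSE)
  fixations <- data.frame(generation = res$fix_gen,
                          phenotype = phen_levels[res$fix_phen],
                          stringsAsFactors = FALSE)
  substitutions <- data.frame(generation = res$sub_gen,
                              genotype = dec_or_na(res$sub_key),
                              stringsAsFactors = FALSE)
  final <- data.frame(genotype = dec_or_na(res$final_key),
                      phenotype = phen_levels[res$final_phen],
                      count = res$final_n, stringsAsFactors = FALSE)
  po <- res$final_phen_only
  if (sum(po) > 0) {
    final <- rbind(final, data.frame(genotype = NA_character_,
                                     phenotype = phen_levels[po > 0],
                                     count = po[po > 0]))
  }
  structure(list(events = events, fixations = fixations,
                 substitutions = substitutions, final = final,
                 generations_run = res$generations_run,
                 event_overflow = res$event_overflow,
                 params = params),
            class = "popdyn_run")
}

#' @export
print.popdyn_run <- function(x, ...) {
  cat(sprintf("<%s run>  N = %d, u = %g, %g generations: %d appearances, %d fixation(s)\n",
              x$params$model, x$params$N, x$params$u, x$generations_run,
              nrow(x$events), nrow(x$fixations)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# average-rate model
# ---------------------------------------------------------------------------

#' Average-rate (Poisson) null simulation
#'
#' The matched null model without genotype state: Wright-Fisher resampling
#' is identical, but `L * u` mutations occur per individual and generation
#' in expectation (the per-offspring number of mutations is Binomial(L, u))
#' and each mutation turns the offspring's phenotype into an independent
#' draw from the mean mutation spectrum of its current phenotype.  For the
#' initial phenotype that spectrum is `phi`, whose diagonal entry
#' `phi[initial]` is the robustness `rho` (a draw equal to the current
#' phenotype is a neutral mutation).  For any other phenotype the default
#' spectrum keeps the phenotype with probability `rho` and otherwise yields
#' the undefined phenotype; pass `spectra` to override.
#'
#' Because the model carries no genotype state its appearance statistics
#' are stationary from generation 0, so no burn-in is applied.
#'
#' @param phi named spectrum of the initial phenotype (must include the
#'   initial phenotype itself; entries sum to 1).
#' @param fitness a [fitness_scheme()] whose initial phenotype is in
#'   `names(phi)`.
#' @param N,u,L population size, per-site mutation rate, genome length.
#' @param generations run length.
#' @param seed RNG seed.
#' @param tracked phenotypes whose appearances are logged.
#' @param spectra optional named list of named spectra overriding the
#'   default rows for non-initial phenotypes.
#' @param init_counts optional named initial counts (default: all `N`
#'   individuals carry the initial phenotype).
#' @param stop_at_fixation,stop_when_monomorphic early-stopping switches.
#' @param max_events cap on logged events.
#' @return a `popdyn_run` (genotype columns are `NA`: the model has no
#'   genotypes).
#' @export
average_rate_run <- function(phi, fitness, N, u, L, generations, seed,
                             tracked = character(0), spectra = NULL,
                             init_counts = NULL,
                             stop_at_fixation = FALSE,
                             stop_when_monomorphic = FALSE,
                             max_events = 5e6) {
  p0 <- fitness$initial
  if (!p0 %in% names(phi)) stop("phi must contain the initial phenotype")
  if (abs(sum(phi) - 1) > 1e-9) stop("phi must sum to 1")
  phen_levels <- union(names(phi), c(names(fitness$s), tracked))
  if (!PHENOTYPE_NONE %in% phen_levels) {
    phen_levels <- c(phen_levels, PHENOTYPE_NONE)
  }
  P <- length(phen_levels)
  rho <- unname(phi[p0])
  S <- matrix(0, P, P, dimnames = list(phen_levels, phen_levels))
  for (p in phen_levels) {
    if (p == p0) {
      S[p, names(phi)] <- phi
    } else if (!is.null(spectra) && p %in% names(spectra)) {
      sp <- spectra[[p]]
      S[p, names(sp)] <- sp / sum(sp)
    } else {
      S[p, p] <- rho
      S[p, PHENOTYPE_NONE] <- S[p, PHENOTYPE_NONE] + 1 - rho
    }
  }
  fit_phen <- fitness_of_phenotypes(fitness, phen_levels)
  init <- integer(P)
  if (is.null(init_counts)) {
    init[match(p0, phen_levels)] <- as.integer(N)
  } else {
    init[match(names(init_counts), phen_levels)] <- as.integer(init_counts)
    if (sum(init) != N) stop("init_counts must sum to N")
  }
  set.seed(seed)
  res <- .avgrate_engine(S, fit_phen, init, as.integer(N), u, as.integer(L),
                         as.double(generations),
                         match(tracked, phen_levels), match(p0, phen_levels),
                         stop_at_fixation, 0.25, stop_when_monomorphic,
                         as.integer(max_events))
  if (nzchar(res$error)) {
    stop("population lost all viable individuals at generation ",
         res$error_gen, ": ", res$error)
  }
  events <- data.frame(
    generation = res$event_gen,
    event_type = rep("appearance", length(res$event_gen)),
    parent_genotype = rep(NA_character_, length(res$event_gen)),
    mutant_genotype = rep(NA_character_, length(res$event_gen)),
    phenotype = phen_levels[res$event_child_phen],
    stringsAsFactors = FALSE)
  final <- data.frame(genotype = NA_character_, phenotype = phen_levels,
                      count = res$final_counts, stringsAsFactors = FALSE)
  structure(list(events = events,
                 fixations = data.frame(
                   generation = res$fix_gen,
                   phenotype = phen_levels[res$fix_phen],
                   stringsAsFactors = FALSE),
                 substitutions = data.frame(generation = numeric(0),
                                            genotype = character(0)),
                 final = final[final$count > 0, ],
                 generations_run = res$generations_run,
                 event_overflow = res$event_overflow,
                 params = list(model = "average_rate", N = N, u = u, L = L,
                               generations = generations, seed = seed,
                               tracked = tracked, initial = p0)),
            class = "popdyn_run")
}

#' Single-mutant fixation frequency by simulation
#'
#' Repeated absorption trials of one mutant with selective advantage `s` in
#' a resident population of size `N` under the same Wright-Fisher engine
#' (mutation switched off), used to check the Kimura fixation probability.
#'
#' @param s selective advantage of the mutant.
#' @param N population size.
#' @param trials number of independent trials.
#' @param seed RNG seed.
#' @return fraction of trials in which the mutant reached fixation.
#' @export
single_mutant_fixation_frequency <- function(s, N, trials, seed) {
  scheme <- fitness_scheme("p0", s = c(p1 = s), restrict_to_nc = FALSE)
  phi <- c(p0 = 1)
  fixed <- logical(trials)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, trials)
  for (i in seq_len(trials)) {
    r <- average_rate_run(phi, scheme, N = N, u = 0, L = 1,
                          generations = 1e8, seed = seeds[i],
                          init_counts = c(p0 = N - 1, p1 = 1),
                          stop_when_monomorphic = TRUE)
    fixed[i] <- any(r$final$phenotype == "p1" & r$final$count > 0)
  }
  mean(fixed)
}

#' Write / read an event log as TSV
#'
#' Columns: `generation, event_type, parent_genotype, mutant_genotype,
#' phenotype_id`.  Fixation records are appended with
#' `event_type = "fixation"`.
#'
#' @param run a `popdyn_run`.
#' @param file path.
#' @export
write_event_log <- function(run, file) {
  ev <- run$events
  names(ev)[names(ev) == "phenotype"] <- "phenotype_id"
  if (nrow(run$fixations)) {
    fx <- data.frame(generation = run$fixations$generation,
                     event_type = "fixation",
                     parent_genotype = NA_character_,
                     mutant_genotype = NA_character_,
                     phenotype_id = run$fixations$phenotype)
    ev <- rbind(ev, fx)
    ev <- ev[order(ev$generation), ]
  }
  utils::write.table(ev, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    colClasses = c(generation = "numeric",
                                   event_type = "character",
                                   parent_genotype = "character",
                                   mutant_genotype = "character",
                                   phenotype_id = "character"))
}
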