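#' Appearance counts per time window
#'
#' Splits the logged span into consecutive windows of `dt` generations and
#' counts the appearances of one phenotype in each.  The window grid starts
#' at generation 0 and covers the full run length (empty windows count 0); a
#' trailing partial window is discarded.
#'
#' @param run a `popdyn_run` (or a data frame of events with `generation`
#'   and `phenotype` columns).
#' @param phenotype the tracked phenotype to count.
#' @param dt window length in generations (>= 1).
#' @param span total number of generations covered by the log; defaults to
#'   the run's `generations_run`.
#' @return integer vector of per-window counts.
#' @export
interval_counts <- function(run, phenotype, dt, span = NULL) {
  stopifnot(dt >= 1)
  events <- if (is.data.frame(run)) run else run$events
  if (is.null(span)) {
    # a simulation run has a definite span (trailing partial window
    # dropped); for a bare event table the window holding the last event
    # is included
    span <- if (is.data.frame(run)) {
      if (nrow(events)) ceiling((max(events$generation) + 1) / dt) * dt
      else 0
    } else run$generations_run
  }
  nwin <- floor(span / dt)
  if (nwin == 0) return(integer(0))
  times <- events$generation[events$phenotype == phenotype]
  times <- times[times < nwin * dt]
  win <- floor(times / dt) + 1
  as.integer(tabulate(win, nbins = nwin))
}

#' Coefficient of variation of inter-event times
#'
#' Collapses same-generation events to one event time, then returns
#' `V_t = sigma / mu` of the successive inter-event gaps (population
#' standard deviation).  A Poisson process gives `V_t = 1`; values above 1
#' indicate overdispersed ("bursty") appearances.  `V_t` is scale-invariant:
#' rescaling all times leaves it unchanged.
#'
#' @param event_times numeric vector of event times (generations); at least
#'   3 distinct times are required.
#' @return the coefficient of variation of the gap distribution.
#' @export
coefficient_of_variation <- function(event_times) {
  t <- sort(unique(event_times))
  if (length(t) < 3) {
    stop("coefficient of variation undefined: need >= 3 distinct event times")
  }
  gaps <- diff(t)
  mu <- mean(gaps)
  sigma <- sqrt(mean((gaps - mu)^2))
  sigma / mu
}

#' Poisson-mixture prediction for windowed appearance counts
#'
#' On a map with discrete mutational neighbourhoods, a perfectly monomorphic
#' population sitting on a genotype with exactly `n` mutations to the
#' tracked phenotype produces on average `n * dt / t_gene` copies of it per
#' window, with `t_gene = (K - 1) / (N * u)` the time for each specific
#' neighbour mutation to occur once.  Averaging over the residence
#' probabilities of genotypes with different `n` gives a weighted sum of
#' Poisson distributions - a peak at zero, then successively smaller peaks
#' near `n * dt / t_gene`.  This is the main-text approximation: it ignores
#' portal escape during a window and residual polymorphism, and is labelled
#' approximate in outputs.
#'
#' @param n_distribution named numeric vector: weights of each neighbour
#'   count `n` (names `"0"`, `"1"`, ...; see
#'   [portal_count_distribution()]); must sum to 1.
#' @param N,u,K population size, per-site mutation rate, alphabet size.
#' @param dt window length.
#' @param max_count highest count to evaluate (default: generous upper
#'   tail).
#' @return data frame with `count`, `probability`, and attribute
#'   `"approximation"`.
#' @export
poisson_mixture_prediction <- function(n_distribution, N, u, K, dt,
                                       max_count = NULL) {
  w <- n_distribution / sum(n_distribution)
  n_vals <- as.numeric(names(w))
  if (anyNA(n_vals)) stop("n_distribution must be named by integer counts")
  t_gene <- (K - 1) / (N * u)
  lambdas <- n_vals * dt / t_gene
  if (is.null(max_count)) {
    max_count <- max(5, ceiling(max(lambdas) + 5 * sqrt(max(lambdas) + 1)))
  }
  counts <- 0:max_count
  p <- vapply(counts, function(cc) sum(w * stats::dpois(cc, lambdas)),
              numeric(1))
  out <- data.frame(count = counts, probability = p)
  attr(out, "approximation") <- "main-text Poisson mixture (no portal escape or polymorphism corrections)"
  out
}

#' Classify interval counts against the matched Poisson band
#'
#' For a Poisson distribution with the same mean `mu`, counts in
#' `[mu - sigma, mu + sigma]` (with `sigma = sqrt(mu)`) are "typical".
#' Overdispersed data pile up below the band (quiet periods between bursts)
#' and above it (the bursts).  Counts equal to a boundary are classified as
#' within the band.
#'
#' @param counts integer vector of per-window counts.
#' @param poisson_mean the matched Poisson mean `mu` (> 0); defaults to
#'   `mean(counts)`.
#' @return named numeric vector `c(below, within, above)`, summing to 1.
#' @export
burst_summary <- function(counts, poisson_mean = mean(counts)) {
  stopifnot(poisson_mean > 0)
  mu <- poisson_mean
  sigma <- sqrt(mu)
  below <- mean(counts < mu - sigma)
  above <- mean(counts > mu + sigma)
  c(below = below, within = 1 - below - above, above = above)
}

#' Poisson probability mass inside the mu +/- sigma band
#'
#' The analytic "within" fraction expected from a Poisson process with mean
#' `mu`, using the same boundary convention as [burst_summary()].
#'
#' @param mu Poisson mean.
#' @return probability that a Poisson(mu) draw lies in `[mu - sigma,
#'   mu + sigma]`.
#' @export
poisson_band_mass <- function(mu) {
  sigma <- sqrt(mu)
  lo <- ceiling(mu - sigma)
  hi <- floor(mu + sigma)
  if (hi < lo) return(0)
  sum(stats::dpois(lo:hi, mu))
}
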