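#' Characteristic time scales of the monomorphic regime
#'
#' In the weak-mutation (monomorphic) regime `N * u * L < 1` a population
#' drifting on a neutral component is localised on a single genotype and:
#' \describe{
#'   \item{`t_ne = 1 / (L * u * rho)`}{mean generations between neutral
#'     fixations through drift (`rho` = NC robustness);}
#'   \item{`t_gene = (K - 1) / (N * u)`}{generations for each *specific*
#'     point mutation of the resident genotype to be produced once;}
#'   \item{`M = t_ne / t_gene = N / ((K - 1) * L * rho)`}{the burst size:
#'     expected number of times the same mutational neighbour (and hence
#'     the same novel phenotype) is produced while the population sits on
#'     one portal genotype; roughly `N / L` since `(K - 1) * rho` is of
#'     order one;}
#'   \item{`t_port = t_ne / P_g`}{waiting time for the population to drift
#'     onto a portal genotype of the target phenotype, with `P_g` the
#'     portal probability.}
#' }
#'
#' @param N,u,L,K population size, per-site mutation rate, sequence length,
#'   alphabet size.
#' @param rho robustness of the neutral component (> 0).
#' @param portal_prob portal probability `P_g` of the target phenotype
#'   (optional; `t_port` is `NA` when missing).
#' @return named list with `t_ne`, `t_gene`, `M`, `t_port`.
#' @export
scaling_times <- function(N, u, L, K, rho, portal_prob = NULL) {
  if (rho <= 0) stop("rho must be > 0")
  if (u <= 0 || N < 1 || L < 1 || K < 2) stop("invalid parameters")
  t_ne <- 1 / (L * u * rho)
  t_gene <- (K - 1) / (N * u)
  M <- t_ne / t_gene
  t_port <- if (is.null(portal_prob)) NA_real_ else {
    if (portal_prob <= 0) stop("portal probability must be > 0 for t_port")
    t_ne / portal_prob
  }
  list(t_ne = t_ne, t_gene = t_gene, M = M, t_port = t_port)
}

#' Kimura single-mutant fixation probability
#'
#' `P_fix = (1 - exp(-2 s)) / (1 - exp(-2 N s))` for a single mutant with
#' selective advantage `s` in a haploid population of size `N` (census size
#' is used for both drift and selection).  The neutral limit `s -> 0`
#' returns `1 / N`.
#'
#' @param s selective advantage (may be a vector).
#' @param N population size.
#' @return fixation probability.
#' @export
p_fix_kimura <- function(s, N) {
  stopifnot(N >= 1)
  out <- ifelse(abs(s) < 1e-12, 1 / N, -expm1(-2 * s) / -expm1(-2 * N * s))
  unname(out)
}

#' Probability of fixation by the end of a burst
#'
#' Once a portal genotype fixes, a burst of on average `M` mutants of the
#' novel phenotype is produced.  The probability that at least one of them
#' fixes before the burst ends is
#' `P_portal_fix = (1 + 1 / (P_fix * M))^-1`, which saturates toward 1 when
#' `P_fix * M >> 1`: above that point the fixation time is set by the
#' timing of the first burst, not by the strength of selection.
#'
#' @param p_fix single-mutant fixation probability, in (0, 1].
#' @param M burst size (> 0).
#' @return probability in (0, 1).
#' @export
p_portal_fix <- function(p_fix, M) {
  stopifnot(all(p_fix > 0), all(p_fix <= 1), all(M > 0))
  1 / (1 + 1 / (p_fix * M))
}

#' Selection threshold above which bursts saturate fixation
#'
#' Since `P_fix ~ s` in the regime `1/N << s << 1`, the saturation of
#' [p_portal_fix()] becomes relevant above `s* = 1 / M` - of order `L / N`
#' in the simplest case, a remarkably low threshold.
#'
#' @param M burst size.
#' @return the threshold selection coefficient `s* = 1 / M`.
#' @export
selection_threshold <- function(M) {
  stopifnot(all(M > 0))
  1 / M
}

#' Origin-fixation expected fixation time (average-rate model)
#'
#' In the average-rate model, a phenotype introduced at rate
#' `phi * N * u * L` with single-mutant fixation probability `P_fix`
#' fixes after an expected `t_fix = 1 / (r * P_fix)` generations, as in a
#' classic origin-fixation model.
#'
#' @param phi mutation probability of the target phenotype.
#' @param s its selective advantage.
#' @param N,u,L population size, per-site mutation rate, genome length.
#' @return expected fixation time in generations (`Inf` when `phi = 0`).
#' @export
t_fix_average_rate <- function(phi, s, N, u, L) {
  r <- phi * N * u * L
  p <- p_fix_kimura(s, N)
  ifelse(r * p > 0, 1 / (r * p), Inf)
}

#' First-fixation probabilities from individual fixation times
#'
#' When `n` adaptive phenotypes appear and fix independently, the
#' probability that phenotype 1 (with expected fixation time `t1`) fixes
#' before the others is `(1 + t1 * sum_{i>=2} 1 / t_i)^-1`.  With two peaks
#' this reduces to `(1 + t1/t2)^-1`, and feeding in the origin-fixation
#' times of [t_fix_average_rate()] recovers the classic origin-fixation
#' ratio (see [p_r_fixes_origin_fixation()]).
#'
#' @param t_fix numeric vector of expected fixation times (> 0).
#' @return vector of first-fixation probabilities, one per phenotype,
#'   summing to 1.
#' @export
first_fixation_probability <- function(t_fix) {
  if (any(t_fix <= 0)) stop("fixation times must be > 0")
  inv <- 1 / t_fix
  vapply(seq_along(t_fix), function(i) {
    1 / (1 + t_fix[i] * (sum(inv) - inv[i]))
  }, numeric(1))
}

#' Origin-fixation probability that the rare, fitter phenotype fixes first
#'
#' Two-peak landscape: a frequent phenotype `p_f` (mutation probability
#' `phi_f`, advantage `s_f`) and a rare one `p_r` (`phi_r`, `s_r`) compete
#' to fix first.  In the origin-fixation regime
#' `P(p_r first) = (1 + P_fix(s_f) phi_f / (P_fix(s_r) phi_r))^-1`, with
#' Kimura fixation probabilities: a single effective parameter, the ratio
#' of the two origin-fixation terms.
#'
#' @param phi_f,phi_r mutation probabilities of the two phenotypes.
#' @param s_f,s_r their selective advantages.
#' @param N population size.
#' @return probability that `p_r` is the first to fix.
#' @export
p_r_fixes_origin_fixation <- function(phi_f, phi_r, s_f, s_r, N) {
  1 / (1 + (p_fix_kimura(s_f, N) * phi_f) / (p_fix_kimura(s_r, N) * phi_r))
}

#' Closed-form theory report for one parameter set
#'
#' Evaluates all closed-form quantities for a parameter set and, when a
#' target phenotype is given, its introduction rate, fixation time and
#' burst-saturation numbers.  The result is a plain list, convenient to
#' serialise as JSON.
#'
#' @param N,u,L,K population/genome parameters.
#' @param rho neutral-component robustness.
#' @param phi named mutation spectrum (optional).
#' @param s named selective advantages (optional).
#' @param portal_prob named portal probabilities (optional).
#' @param target phenotype to specialise to (optional).
#' @return named list of theory quantities.
#' @export
theory_report <- function(N, u, L, K, rho, phi = NULL, s = NULL,
                          portal_prob = NULL, target = NULL) {
  pg <- if (!is.null(target) && !is.null(portal_prob))
    unname(portal_prob[target]) else NULL
  st <- scaling_times(N, u, L, K, rho, portal_prob = pg)
  rep <- list(params = list(N = N, u = u, L = L, K = K, rho = rho,
                            NuL = N * u * L),
              t_ne = st$t_ne, t_gene = st$t_gene, M = st$M,
              t_port = st$t_port,
              selection_threshold = selection_threshold(st$M))
  if (!is.null(target) && !is.null(phi) && target %in% names(phi)) {
    s_t <- if (!is.null(s) && target %in% names(s)) unname(s[target]) else 0
    p_fix <- p_fix_kimura(s_t, N)
    rep$target <- list(
      phenotype = target,
      phi = unname(phi[target]),
      s = s_t,
      introduction_rate = unname(phi[target]) * N * u * L,
      p_fix = p_fix,
      p_portal_fix = p_portal_fix(p_fix, st$M),
      t_fix_average_rate = t_fix_average_rate(unname(phi[target]),
                                              s_t, N, u, L))
  }
  rep
}
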