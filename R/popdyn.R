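# Competition between cells carrying an element at its primary attachment
# site and cells carrying it at a secondary site from which it cannot
# excise.  Spontaneous activation of element gene expression kills a
# fraction D of the secondary-site subpopulation each generation (stuck
# rolling-circle replication), while the primary-site subpopulation is
# unaffected.  Sizes follow P = P0 * 2^G * (1 - D)^G, so the ratio of
# primary- to secondary-site populations grows as R = 1 / (1 - D)^G.

check_death <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d >= 1) {
    stop("death fraction must satisfy 0 <= D < 1")
  }
  d
}

#' Population size under a per-generation death fraction
#'
#' Evaluates P = P0 * 2^G * (1 - D)^G: exponential doubling with a
#' fraction D of cells lost each generation.
#'
#' @param p0 Initial population size (> 0).
#' @param generations Number of generations G (non-negative).
#' @param death_fraction Per-generation dead fraction D, 0 <= D < 1.
#' @return Expected population size.
#' @examples
#' population_size(1, 10, 0.1)  # 2^10 * 0.9^10
#' @export
population_size <- function(p0, generations, death_fraction) {
  check_death(death_fraction)
  if (!is.numeric(p0) || any(p0 <= 0)) {
    stop("p0 must be positive")
  }
  if (!is.numeric(generations) || any(generations < 0)) {
    stop("generations must be non-negative")
  }
  p0 * 2^generations * (1 - death_fraction)^generations
}

#' Primary:secondary population ratio after G generations
#'
#' R = 1 / (1 - D)^G, the ratio of a population doubling without loss to
#' one paying a per-generation death fraction D.  Independent of the
#' (common) initial size, which cancels.
#'
#' @inheritParams population_size
#' @return The ratio R (>= 1).
#' @export
competition_ratio <- function(generations, death_fraction) {
  check_death(death_fraction)
  if (!is.numeric(generations) || any(generations < 0)) {
    stop("generations must be non-negative")
  }
  (1 - death_fraction)^(-generations)
}

#' Generations needed to reach a given population ratio
#'
#' Inverts the ratio model: G = log(1/R) / log(1 - D) (base-independent).
#' With D = 1e-4 the ratio R = 10 takes about 23,000 generations; with
#' D = 1e-3, about 2,300.  Headline values are conventionally reported to
#' two significant figures (`signif(g, 2)`); this function returns the raw
#' value.
#'
#' @param ratio Target ratio R >= 1.
#' @param death_fraction Per-generation dead fraction D, 0 <= D < 1.
#' @return Generations G (0 when R = 1; Inf, with a warning, when D = 0
#'   and R > 1, where no finite solution exists).
#' @examples
#' generations_to_ratio(10, 1e-4)  # ~23,026; ~23,000 at 2 sig. figures
#' @export
generations_to_ratio <- function(ratio, death_fraction) {
  check_death(death_fraction)
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio < 1) {
    stop("ratio must be >= 1")
  }
  if (ratio == 1) {
    return(0)
  }
  if (death_fraction == 0) {
    warning("D = 0: populations never diverge; no finite G reaches R > 1")
    return(Inf)
  }
  log(1 / ratio) / log(1 - death_fraction)
}

#' Effective death fraction from activation and viability
#'
#' Decomposes the per-generation death fraction as D = a * (1 - v): cells
#' activate element gene expression with frequency `a` per generation, and
#' a fraction `v` of activated cells survive.  The all-die assumption
#' (v = 0) gives D = a; full viability (v = 1) gives no cost.
#'
#' @param activation Activation frequency per generation, in 0..1
#'   (spontaneous activation is of order 1e-4 to 1e-5 in exponential
#'   growth).
#' @param viability Fraction of activated secondary-site cells that
#'   survive, in 0..1.  Default 0 (the literal all-die model).
#' @return The effective death fraction D.
#' @export
effective_death <- function(activation, viability = 0) {
  if (!is.numeric(activation) || any(activation < 0 | activation > 1)) {
    stop("activation must lie in 0..1")
  }
  if (!is.numeric(viability) || any(viability < 0 | viability > 1)) {
    stop("viability must lie in 0..1")
  }
  activation * (1 - viability)
}

#' Stochastic competition simulator
#'
#' Individual-based counterpart of the closed-form model.  Each
#' generation, both subpopulations double; each secondary-site cell then
#' dies independently with probability D (a binomial draw); when the total
#' exceeds `cap`, the population is down-sampled to `cap` by a neutral
#' multinomial bottleneck (added purely to keep simulations at desk scale
#' -- it is unbiased in expectation).  Replicate r uses `seed + r`, so a
#' fixed seed gives bit-identical trajectories.
#'
#' @param death_fraction Per-generation dead fraction D, 0 <= D < 1.
#' @param generations Number of generations to simulate.
#' @param cap Population cap (>= 1000 to control resampling noise).
#' @param n_replicates Number of independent replicate trajectories.
#' @param n0 Length-2 vector of initial counts (primary, secondary);
#'   default an even split of `cap`.
#' @param checkpoint_every Record the ratio every this many generations
#'   (the final generation is always recorded).  Default records ~25
#'   checkpoints.
#' @param seed Master seed for all draws.
#' @return An object of class `competition_sim`: `ratio` (replicates x
#'   checkpoints matrix of primary/secondary ratios), `checkpoints`,
#'   `params`.  See [summary.competition_sim()].
#' @examples
#' sim <- simulate_competition(0.01, generations = 100, cap = 1e4,
#'                             n_replicates = 5, seed = 1)
#' summary(sim)
#' @export
simulate_competition <- function(death_fraction, generations, cap = 1e6,
                                 n_replicates = 50, n0 = NULL,
                                 checkpoint_every = NULL, seed = 1) {
  check_death(death_fraction)
  if (cap < 1000) {
    stop("cap must be >= 1000 to control resampling noise")
  }
  if (is.null(n0)) {
    n0 <- c(floor(cap / 2), floor(cap / 2))
  }
  if (length(n0) != 2L || any(n0 < 1)) {
    stop("n0 must be two positive counts (primary, secondary)")
  }
  if (sum(n0) > cap) {
    stop("cap too small to hold both subpopulations at start")
  }
  if (is.null(checkpoint_every)) {
    checkpoint_every <- max(1L, ceiling(generations / 25))
  }
  checkpoints <- unique(c(seq(checkpoint_every, generations,
                              by = checkpoint_every), generations))
  ratio <- matrix(NA_real_, nrow = n_replicates,
                  ncol = length(checkpoints),
                  dimnames = list(NULL, paste0("g", checkpoints)))
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    n1 <- n0[1L]
    n2 <- n0[2L]
    ci <- 1L
    for (g in seq_len(generations)) {
      n1 <- 2 * n1
      n2 <- 2 * n2
      if (death_fraction > 0 && n2 > 0) {
        n2 <- n2 - stats::rbinom(1L, n2, death_fraction)
      }
      tot <- n1 + n2
      if (tot > cap) {
        n1 <- stats::rbinom(1L, cap, n1 / tot)
        n2 <- cap - n1
      }
      if (ci <= length(checkpoints) && g == checkpoints[ci]) {
        ratio[r, ci] <- if (n2 > 0) n1 / n2 else Inf
        ci <- ci + 1L
      }
    }
  }
  structure(
    list(ratio = ratio, checkpoints = checkpoints,
         params = list(death_fraction = death_fraction,
                       generations = generations, cap = cap,
                       n_replicates = n_replicates, n0 = n0,
                       seed = seed)),
    class = "competition_sim"
  )
}

#' Summarize a competition simulation
#'
#' Per checkpoint: mean and standard error of the simulated ratio across
#' replicates, a normal-approximation 95% interval, and the closed-form
#' expectation 1/(1-D)^G for comparison.
#'
#' @param object A `competition_sim`.
#' @param ... Unused.
#' @return Data.frame with columns `generation`, `mean_ratio`, `se`,
#'   `lo95`, `hi95`, `expected_ratio`.
#' @export
summary.competition_sim <- function(object, ...) {
  m <- colMeans(object$ratio)
  s <- apply(object$ratio, 2L, stats::sd)
  se <- s / sqrt(nrow(object$ratio))
  data.frame(
    generation = object$checkpoints,
    mean_ratio = unname(m),
    se = unname(se),
    lo95 = unname(m - 1.96 * se),
    hi95 = unname(m + 1.96 * se),
    expected_ratio = competition_ratio(object$checkpoints,
                                       object$params$death_fraction)
  )
}

#' @export
print.competition_sim <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "competition_sim: D = %g, %d generations, cap %g, %d replicates\n",
    p$death_fraction, p$generations, p$cap, p$n_replicates))
  last <- summary(x)
  last <- last[nrow(last), ]
  cat(sprintf("final ratio: %.3f +/- %.3f (expected %.3f)\n",
              last$mean_ratio, last$se, last$expected_ratio))
  invisible(x)
}
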