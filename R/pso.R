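#' PSO control parameters
#'
#' Classical inertia-weight particle swarm constants. The defaults
#' w = 0.729, c1 = c2 = 1.49445 are the constriction-equivalent values from
#' the PSO literature.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param iterations Number of update iterations (>= 1).
#' @param w Inertia weight in (0, 1].
#' @param c1,c2 Cognitive and social acceleration constants (> 0).
#' @param v_clamp Velocity clamp as a fraction of each dimension's range.
#' @param seed Integer seed (NULL = use current RNG state).
#' @return A list of class `pso_control`.
#' @export
pso_control <- function(swarm_size = 20L, iterations = 30L, w = 0.729,
                        c1 = 1.49445, c2 = 1.49445, v_clamp = 0.5,
                        seed = NULL) {
  if (swarm_size < 2L) stop_arg("`swarm_size` must be >= 2")
  if (iterations < 1L) stop_arg("`iterations` must be >= 1")
  if (w <= 0 || w > 1) stop_arg("`w` must be in (0, 1]")
  if (c1 <= 0 || c2 <= 0) stop_arg("`c1` and `c2` must be > 0")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 w = w, c1 = c1, c2 = c2, v_clamp = v_clamp, seed = seed),
            class = "pso_control")
}

#' Bounded particle swarm optimization
#'
#' Minimizes `objective` over a box. Standard velocity update with inertia,
#' cognitive and social terms; positions are clamped to the bounds and
#' velocities to `v_clamp` times each dimension's range. Dimensions flagged
#' in `integer_mask` stay continuous internally but are rounded before each
#' objective evaluation (and in the returned position), which preserves
#' swarm dynamics on mixed integer/continuous spaces. Non-finite objective
#' values are treated as +Inf rather than crashing the swarm. Optionally the
#' first particle is pinned to `incumbent`, guaranteeing the returned
#' fitness is never worse than the incumbent's.
#'
#' @param objective Function position -> scalar fitness (lower is better).
#' @param lower,upper Numeric vectors of per-dimension bounds (finite).
#' @param integer_mask Logical vector: which dimensions are integer-valued.
#' @param control A [pso_control()] list.
#' @param incumbent Optional starting position seeded as one particle.
#' @return List with `position`, `fitness`, `history` (global best fitness
#'   per iteration, non-increasing), `evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' pso_optimize(sphere, rep(-5, 3), rep(5, 3),
#'              control = pso_control(seed = 1))$fitness
#' @export
pso_optimize <- function(objective, lower, upper, integer_mask = NULL,
                         control = pso_control(), incumbent = NULL) {
  check_numeric_vector(lower, "lower"); check_numeric_vector(upper, "upper")
  D <- length(lower)
  if (length(upper) != D) stop_arg("bound lengths differ")
  if (any(upper <= lower)) stop_arg("need upper > lower in every dimension")
  if (is.null(integer_mask)) integer_mask <- rep(FALSE, D)
  stopifnot(length(integer_mask) == D)
  rng <- upper - lower
  vmax <- control$v_clamp * rng
  evals <- 0L
  eval_pos <- function(p) {
    p[integer_mask] <- round(p[integer_mask])
    f <- tryCatch(objective(p), error = function(e) Inf)
    evals <<- evals + 1L
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) Inf else f
  }
  with_seed(control$seed, {
    S <- control$swarm_size
    pos <- matrix(stats::runif(S * D, lower, upper), nrow = D)
    if (!is.null(incumbent)) {
      stopifnot(length(incumbent) == D)
      pos[, 1L] <- pmin(pmax(incumbent, lower), upper)
    }
    vel <- matrix(stats::runif(S * D, -vmax, vmax), nrow = D)
    pbest <- pos
    pfit <- apply(pos, 2L, eval_pos)
    gbest_i <- which.min(pfit)
    gbest <- pbest[, gbest_i]
    gfit <- pfit[gbest_i]
    history <- numeric(control$iterations)
    for (it in seq_len(control$iterations)) {
      r1 <- matrix(stats::runif(S * D), nrow = D)
      r2 <- matrix(stats::runif(S * D), nrow = D)
      vel <- control$w * vel +
        control$c1 * r1 * (pbest - pos) +
        control$c2 * r2 * (gbest - pos)
      vel <- pmin(pmax(vel, -vmax), vmax)
      pos <- pmin(pmax(pos + vel, lower), upper)
      fit <- apply(pos, 2L, eval_pos)
      improved <- fit < pfit
      pbest[, improved] <- pos[, improved]
      pfit[improved] <- fit[improved]
      if (min(pfit) < gfit) {
        gbest_i <- which.min(pfit)
        gbest <- pbest[, gbest_i]
        gfit <- pfit[gbest_i]
      }
      history[it] <- gfit
    }
    best <- gbest
    best[integer_mask] <- round(best[integer_mask])
    list(position = best, fitness = gfit, history = history,
         evaluations = evals)
  })
}
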