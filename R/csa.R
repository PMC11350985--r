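#' Initialize a chicken swarm
#'
#' The chicken swarm algorithm (CSA) is a population metaheuristic in which
#' members hold one of three roles by fitness rank: roosters (best fitness)
#' explore by multiplicative Gaussian perturbation, hens follow their
#' group's rooster and another random member, and chicks (worst fitness)
#' follow their mother hen. Fitness is minimized throughout.
#'
#' @param objective Function mapping a numeric vector of length `ds` to a
#'   scalar fitness (lower is better).
#' @param ds Search-space dimension.
#' @param n Swarm size (`>= 4` so every role is populated).
#' @param fractions Length-3 numeric `(rooster, hen, chick)` proportions.
#' @param bounds Length-2 search box, recycled over dimensions.
#' @param mother_fraction Fraction of hens acting as mothers.
#' @param G Role-refresh period in steps (default 10).
#' @param init Optional `n x ds` matrix of starting positions (clamped to
#'   the bounds); by default positions are drawn uniformly in the bounds.
#'   Seeding the swarm around a known good solution turns the algorithm
#'   into a refinement search whose archive can never fall behind that
#'   solution.
#' @param seed Integer seed; the swarm and all subsequent [csa_step()]
#'   draws are reproducible from it.
#' @return An object of class `"chicken_swarm"`: positions (`n x ds`),
#'   fitness, role/assignment vectors, archive of the best-ever position
#'   and fitness, and the step counter `ts`.
#' @export
csa_init <- function(objective, ds, n = 30L,
                     fractions = c(0.2, 0.6, 0.2),
                     bounds = c(-1, 1), mother_fraction = 0.5,
                     G = 10L, init = NULL, seed = 1L) {
  stopifnot(n >= 4L, ds >= 1L, length(fractions) == 3L,
            all(fractions > 0), length(bounds) == 2L, bounds[1] < bounds[2])
  fractions <- fractions / sum(fractions)
  nr <- max(1L, round(n * fractions[1]))
  nc_ <- max(1L, round(n * fractions[3]))
  if (nr + nc_ >= n) stop("role fractions leave no hens", call. = FALSE)
  nh <- n - nr - nc_
  set.seed(seed)
  pos <- if (is.null(init)) {
    matrix(stats::runif(n * ds, bounds[1], bounds[2]), n, ds)
  } else {
    stopifnot(is.matrix(init), nrow(init) == n, ncol(init) == ds)
    pmin(pmax(init, bounds[1]), bounds[2])
  }
  fv <- apply(pos, 1, objective)
  s <- list(pos = pos, fv = fv, n = n, ds = ds,
            nr = nr, nh = nh, nc = nc_,
            nm = max(1L, round(nh * mother_fraction)),
            bounds = bounds, G = as.integer(G), ts = 0L,
            eps = 1e-12)
  s <- assign_roles(s)
  s$best_fv <- min(fv)
  s$best_pos <- pos[which.min(fv), ]
  class(s) <- "chicken_swarm"
  s
}

# rank by fitness: best nr are roosters, worst nc are chicks, rest hens;
# mothers sampled uniformly from hens; each hen gets a group rooster and a
# random other member; each chick gets a mother
assign_roles <- function(s) {
  rk <- order(s$fv)                      # ascending: best first
  roosters <- rk[seq_len(s$nr)]
  chicks <- rk[seq.int(s$n - s$nc + 1L, s$n)]
  hens <- setdiff(rk, c(roosters, chicks))
  mothers <- if (length(hens) == 1L) hens else sample(hens, s$nm)
  s$roosters <- roosters
  s$hens <- hens
  s$chicks <- chicks
  s$mothers <- mothers
  s$hen_rooster <- if (s$nr == 1L) rep(roosters, length(hens)) else
    sample(roosters, length(hens), replace = TRUE)
  s$chick_mother <- if (length(mothers) == 1L) rep(mothers, length(chicks)) else
    sample(mothers, length(chicks), replace = TRUE)
  s
}

#' Advance a chicken swarm by one step
#'
#' Updates positions in role order. A rooster `m` perturbs itself
#' multiplicatively, `A * (1 + Randn(0, sigma^2))`, where against a random
#' other rooster `l`:
#' \deqn{\sigma^2 = 1 \text{ if } fv_m \le fv_l, \quad
#'   \exp\{(fv_l - fv_m)/(|fv_m| + \epsilon)\} \text{ otherwise.}}
#' A hen moves toward its group rooster (`S1` term) and a random other
#' member (`S2` term), with `S1 = exp((fv_m - fv_ro1)/(|fv_m| + eps))` and
#' `S2 = exp(fv_ro2 - fv_m)`; for a hen worse than both, `S2 < 1 < S1`.
#' A chick follows its mother with factor `FL` drawn uniformly in `[0, 2]`
#' per chick per step. Positions are clamped to the bounds, fitness is
#' re-evaluated, roles are refreshed every `G` steps, and the best-ever
#' position is archived (elitism), so the archived fitness is monotone
#' non-increasing.
#'
#' @param s A `"chicken_swarm"`.
#' @param objective The fitness function being minimized.
#' @return The advanced swarm.
#' @export
csa_step <- function(s, objective) {
  stopifnot(inherits(s, "chicken_swarm"))
  pos <- s$pos
  # roosters first (hens follow the updated rooster positions)
  for (i in seq_along(s$roosters)) {
    m <- s$roosters[i]
    l <- if (s$nr == 1L) m else sample(s$roosters[-i], 1L)
    sig2 <- rooster_sigma2(s$fv[m], s$fv[l], s$eps)
    pos[m, ] <- s$pos[m, ] * (1 + stats::rnorm(s$ds, 0, sqrt(sig2)))
  }
  for (i in seq_along(s$hens)) {
    m <- s$hens[i]
    ro1 <- s$hen_rooster[i]
    others <- setdiff(seq_len(s$n), c(m, ro1))
    ro2 <- if (length(others) == 1L) others else sample(others, 1L)
    s1 <- exp((s$fv[m] - s$fv[ro1]) / (abs(s$fv[m]) + s$eps))
    s2 <- exp(s$fv[ro2] - s$fv[m])
    pos[m, ] <- s$pos[m, ] +
      s1 * stats::runif(s$ds) * (pos[ro1, ] - s$pos[m, ]) +
      s2 * stats::runif(s$ds) * (s$pos[ro2, ] - s$pos[m, ])
  }
  for (i in seq_along(s$chicks)) {
    m <- s$chicks[i]
    fl <- stats::runif(1, 0, 2)
    pos[m, ] <- s$pos[m, ] + fl * (s$pos[s$chick_mother[i], ] - s$pos[m, ])
  }
  pos <- pmin(pmax(pos, s$bounds[1]), s$bounds[2])
  s$pos <- pos
  s$fv <- apply(pos, 1, objective)
  s$ts <- s$ts + 1L
  if (s$ts %% s$G == 0L) s <- assign_roles(s)
  b <- which.min(s$fv)
  if (s$fv[b] < s$best_fv) {
    s$best_fv <- s$fv[b]
    s$best_pos <- s$pos[b, ]
  }
  s
}

# rooster variance case split, exposed for direct testing
rooster_sigma2 <- function(fv_m, fv_l, eps = 1e-12) {
  if (fv_m <= fv_l) 1 else exp((fv_l - fv_m) / (abs(fv_m) + eps))
}

#' Run the chicken swarm optimizer
#'
#' Convenience driver: [csa_init()] followed by `steps` calls of
#' [csa_step()].
#'
#' @inheritParams csa_init
#' @param steps Number of steps.
#' @param ... Passed to [csa_init()].
#' @return List with `par` (best-ever position), `value` (its fitness),
#'   `trace` (archived best fitness after every step) and the final swarm.
#' @examples
#' sphere <- function(w) sum(w^2)
#' res <- csa_optimize(sphere, ds = 5, n = 12, steps = 50, seed = 1)
#' res$value < sphere(rep(0.5, 5))
#' @export
csa_optimize <- function(objective, ds, steps = 200L, n = 30L, seed = 1L,
                         ...) {
  s <- csa_init(objective, ds, n = n, seed = seed, ...)
  trace <- numeric(steps)
  for (i in seq_len(steps)) {
    s <- csa_step(s, objective)
    trace[i] <- s$best_fv
  }
  list(par = s$best_pos, value = s$best_fv, trace = trace, swarm = s)
}
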