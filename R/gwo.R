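#' Bounded search space for grey wolf optimization
#'
#' Defines the box the pack moves in: one lower and one upper bound per
#' dimension. All GWO position updates are clamped back into this box.
#'
#' @param lower Numeric vector of per-dimension lower bounds.
#' @param upper Numeric vector of per-dimension upper bounds, same length as
#'   `lower`, with `upper[i] > lower[i]` everywhere.
#' @return An object of class `"gwo_space"` with elements `lower`, `upper`
#'   and `n_dims`.
#' @examples
#' search_space(c(-5, -5), c(5, 5))
#' @export
search_space <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) == 0L) {
    stop("`lower` and `upper` must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, n_dims = length(lower)),
            class = "gwo_space")
}

#' Linear decay schedule for the exploration coefficient
#'
#' The control scalar p decreases linearly from 2 at the start of the run to
#' 0 at the final iteration; it scales the random step coefficient U and so
#' moves the pack from exploration (|U| can exceed 1) to exploitation.
#'
#' @param t Iteration index, `0 <= t <= t_max`.
#' @param t_max Total number of iterations, at least 1.
#' @return The decay scalar `2 * (1 - t / t_max)`.
#' @examples
#' linear_decay(0, 30)   # 2
#' linear_decay(15, 30)  # 1
#' linear_decay(30, 30)  # 0
#' @export
linear_decay <- function(t, t_max) {
  if (length(t_max) != 1L || !is.finite(t_max) || t_max < 1) {
    stop("invalid decay schedule: `t_max` must be a positive count",
         call. = FALSE)
  }
  if (any(t < 0) || any(t > t_max)) {
    stop("invalid decay schedule: `t` must lie in [0, t_max]", call. = FALSE)
  }
  2 * (1 - t / t_max)
}

#' Draw the stochastic coefficients of one encircling step
#'
#' For each dimension draws q1, q2 uniform on \[0, 1\] and forms
#' `U = 2 * p * q1 - p` (so U is uniform on \[-p, p\]) and `S = 2 * q2`
#' (uniform on \[0, 2\]). One call produces the coefficient vectors used
#' against a single leader; callers draw independently per wolf, per leader.
#' Consumes 2 * n_dims uniforms from R's RNG stream: first the q1 vector,
#' then the q2 vector.
#'
#' @param p Decay scalar in \[0, 2\] from [linear_decay()].
#' @param n_dims Number of dimensions to draw for.
#' @return List with numeric vectors `U`, `S` and the raw draws `q1`, `q2`.
#' @export
draw_coefficients <- function(p, n_dims) {
  if (p < 0 || p > 2) stop("`p` must lie in [0, 2]", call. = FALSE)
  q1 <- stats::runif(n_dims)
  q2 <- stats::runif(n_dims)
  list(U = 2 * p * q1 - p, S = 2 * q2, q1 = q1, q2 = q2)
}

#' One encircling step toward a leader
#'
#' Componentwise distance `V = |S * leader - position|` followed by the move
#' `candidate = leader - U * V`. This is the elementary update each omega
#' wolf performs against each of the three leaders.
#'
#' @param position Current position vector of the moving wolf.
#' @param leader Position vector of the leader being encircled.
#' @param U,S Coefficient vectors (or scalars, recycled) from
#'   [draw_coefficients()].
#' @return The candidate position vector.
#' @examples
#' encircle_step(c(0), c(4), U = 0.5, S = 1)  # 2
#' @export
encircle_step <- function(position, leader, U, S) {
  if (length(position) != length(leader)) {
    stop("`position` and `leader` must have the same length", call. = FALSE)
  }
  V <- abs(S * leader - position)
  leader - U * V
}

#' Project a position back into the search box
#'
#' Hard componentwise projection: coordinates below the lower bound are set
#' to it, coordinates above the upper bound likewise; in-bounds coordinates
#' are untouched.
#'
#' @param position Numeric vector.
#' @param space A [search_space()].
#' @return The clamped position vector.
#' @export
clamp_position <- function(position, space) {
  stopifnot(inherits(space, "gwo_space"))
  if (length(position) != space$n_dims) {
    stop("position length does not match the search space", call. = FALSE)
  }
  pmin(pmax(position, space$lower), space$upper)
}

#' Rank a pack and identify its leaders
#'
#' Orders wolves by fitness (minimization); the three lowest-fitness wolves
#' become alpha, beta and delta. Ties are broken by lower wolf index so that
#' ranking is stable and runs are reproducible.
#'
#' @param fitness Numeric vector of evaluated fitness values, one per wolf.
#' @return Integer vector `c(alpha, beta, delta)` of wolf indices.
#' @export
rank_pack <- function(fitness) {
  if (length(fitness) < 3L) {
    stop("a pack needs at least 3 wolves to form its leader hierarchy",
         call. = FALSE)
  }
  order(fitness)[1:3]  # order() is a stable sort: index breaks ties
}

# One hunting update for a single wolf: three encircling steps against
# alpha/beta/delta with independent coefficient draws, averaged, clamped.
# Draw order (fixed, relied on by the transcription oracle in the tests):
# q1 then q2 per leader, leaders visited alpha, beta, delta.
hunt_update <- function(position, leaders, p, space) {
  n <- length(position)
  cand <- vector("list", 3L)
  for (k in 1:3) {
    cf <- draw_coefficients(p, n)
    cand[[k]] <- encircle_step(position, leaders[[k]], cf$U, cf$S)
  }
  clamp_position((cand[[1L]] + cand[[2L]] + cand[[3L]]) / 3, space)
}

#' Grey wolf optimization of a bounded objective
#'
#' Population metaheuristic in which the three best solutions found so far
#' (alpha, beta, delta) steer the remaining wolves through randomized
#' encircling moves whose amplitude decays linearly over the run. Minimizes
#' `objective` over the box given by `space`; maximize by negating.
#'
#' The update loop per iteration: compute the decay scalar p, re-rank the
#' pack, move every wolf to the clamped average of its three leader-directed
#' encircling steps, re-evaluate. The returned optimum is the best position
#' ever evaluated (tracked separately from the current alpha, so it can
#' never regress). All randomness comes from `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param objective Function mapping a numeric vector to a finite scalar.
#' @param space A [search_space()].
#' @param n_wolves Pack size, at least 3 (typical packs run 5 to 12).
#' @param n_iterations Number of update iterations, at least 1.
#' @param seed Integer seed driving all draws.
#' @param tolerance Optional early-stop threshold: the run ends once the
#'   global best fitness drops to or below it. `NULL` (default) disables it.
#' @return An object of class `"gwo"`: list with `best_position`,
#'   `best_fitness`, `positions` and `fitness` (the final pack), `history`
#'   (data frame of per-iteration global best fitness and leader
#'   positions), `n_evaluations`, `config`.
#' @examples
#' sp <- search_space(c(-5, -5), c(5, 5))
#' fit <- gwo(function(x) sum(x^2), sp, n_wolves = 10, n_iterations = 25,
#'            seed = 1)
#' fit$best_fitness
#' @export
gwo <- function(objective, space, n_wolves = 8L, n_iterations = 50L,
                seed = 1L, tolerance = NULL) {
  stopifnot(inherits(space, "gwo_space"), is.function(objective))
  n_wolves <- as.integer(n_wolves)
  n_iterations <- as.integer(n_iterations)
  if (n_wolves < 3L) stop("`n_wolves` must be at least 3", call. = FALSE)
  if (n_iterations < 1L) stop("`n_iterations` must be positive", call. = FALSE)

  eval_count <- 0L
  evaluate <- function(x) {
    eval_count <<- eval_count + 1L
    fx <- objective(x)
    if (length(fx) != 1L || !is.finite(fx)) {
      stop("objective returned a non-finite value at position (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    }
    as.numeric(fx)
  }

  n <- space$n_dims
  with_preserved_seed(seed, {
    # init: uniform in the box, one draw vector per wolf
    pos <- matrix(0, nrow = n_wolves, ncol = n)
    for (i in seq_len(n_wolves)) {
      pos[i, ] <- space$lower + stats::runif(n) * (space$upper - space$lower)
    }
    fit <- apply(pos, 1L, evaluate)

    leaders_idx <- rank_pack(fit)
    best_fit <- fit[leaders_idx[1L]]
    best_pos <- pos[leaders_idx[1L], ]

    hist_best <- numeric(n_iterations + 1L)
    hist_alpha <- matrix(0, nrow = n_iterations + 1L, ncol = n)
    hist_best[1L] <- best_fit
    hist_alpha[1L, ] <- pos[leaders_idx[1L], ]
    t_done <- 0L

    for (t in seq_len(n_iterations)) {
      if (!is.null(tolerance) && best_fit <= tolerance) break
      p <- linear_decay(t, n_iterations)
      leaders_idx <- rank_pack(fit)
      leaders <- list(pos[leaders_idx[1L], ], pos[leaders_idx[2L], ],
                      pos[leaders_idx[3L], ])
      for (i in seq_len(n_wolves)) {
        pos[i, ] <- hunt_update(pos[i, ], leaders, p, space)
        fit[i] <- evaluate(pos[i, ])
        if (fit[i] < best_fit) {
          best_fit <- fit[i]
          best_pos <- pos[i, ]
        }
      }
      t_done <- t
      hist_best[t + 1L] <- best_fit
      hist_alpha[t + 1L, ] <- pos[rank_pack(fit)[1L], ]
    }

    keep <- seq_len(t_done + 1L)
    history <- data.frame(iteration = keep - 1L, best_fitness = hist_best[keep])
    history$alpha_position <- I(lapply(keep, function(r) hist_alpha[r, ]))

    structure(list(
      best_position = best_pos,
      best_fitness = best_fit,
      positions = pos,
      fitness = fit,
      history = history,
      n_evaluations = eval_count,
      config = list(n_wolves = n_wolves, n_iterations = n_iterations,
                    seed = seed, tolerance = tolerance,
                    lower = space$lower, upper = space$upper)
    ), class = "gwo")
  })
}

#' @export
print.gwo <- function(x, ...) {
  cat("Grey wolf optimization result\n")
  cat(sprintf("  %d wolves, %d iterations (seed %d), %d evaluations\n",
              x$config$n_wolves, x$config$n_iterations, x$config$seed,
              x$n_evaluations))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.gwo <- function(object, ...) {
  h <- object$history$best_fitness
  cat("Convergence of global best fitness\n")
  print(stats::quantile(h, c(0, .25, .5, .75, 1)))
  cat(sprintf("initial %.6g -> final %.6g (reduction factor %.3g)\n",
              h[1L], h[length(h)],
              if (h[length(h)] > 0) h[1L] / h[length(h)] else Inf))
  invisible(object)
}

#' @export
plot.gwo <- function(x, ...) {
  graphics::plot(x$history$iteration, x$history$best_fitness, type = "s",
                 xlab = "iteration", ylab = "global best fitness",
                 main = "GWO convergence", log = if (all(x$history$best_fitness > 0)) "y" else "", ...)
  invisible(x)
}

#' Serialize a GWO result to JSON
#'
#' @param x A `"gwo"` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
gwo_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "gwo"))
  obj <- list(
    best_position = x$best_position,
    best_fitness = x$best_fitness,
    n_evaluations = x$n_evaluations,
    config = x$config,
    history = list(iteration = x$history$iteration,
                   best_fitness = x$history$best_fitness)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Benchmark objectives registered by name
#'
#' Standard test functions for the command-line benchmark runner: `"sphere"`
#' (sum of squares, minimum 0 at the origin), `"absdev"` (`sum(|x - c|)`,
#' minimum 0 at `c`) and `"rastrigin"` (multimodal, minimum 0 at the origin).
#'
#' @param name One of `"sphere"`, `"absdev"`, `"rastrigin"`.
#' @param center Offset vector `c` for `"absdev"` (recycled; default 1).
#' @return A function mapping a numeric vector to a scalar.
#' @export
gwo_objective <- function(name = c("sphere", "absdev", "rastrigin"),
                          center = 1) {
  name <- match.arg(name)
  switch(name,
    sphere = function(x) sum(x^2),
    absdev = function(x) sum(abs(x - center)),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
  )
}
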