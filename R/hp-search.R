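#' Mixed integer/continuous hyperparameter search space
#'
#' Declares the named, bounded, typed dimensions the optimizer moves in. The
#' default space is the one used for all five architectures: learning rate
#' \[0.001, 0.01\] (continuous), batch size \[32, 128\] (integer), momentum
#' \[0.9, 0.99\] (continuous), dense units \[128, 512\] (integer, the first
#' head layer; the second is fixed at half of it, matching the 256/128
#' head), epochs \[10, 50\] (integer).
#'
#' @param dims Data frame with columns `name`, `kind` (`"continuous"` or
#'   `"integer"`), `lower`, `upper`. Defaults to the standard five-dimension
#'   space above.
#' @return An object of class `"hp_space"`.
#' @export
hp_space <- function(dims = NULL) {
  if (is.null(dims)) {
    dims <- data.frame(
      name = c("learning_rate", "batch_size", "momentum", "dense_units",
               "epochs"),
      kind = c("continuous", "integer", "continuous", "integer", "integer"),
      lower = c(0.001, 32, 0.9, 128, 10),
      upper = c(0.01, 128, 0.99, 512, 50),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(dims),
            all(c("name", "kind", "lower", "upper") %in% names(dims)))
  if (nrow(dims) == 0L) stop("hyperparameter space is empty", call. = FALSE)
  if (anyDuplicated(dims$name)) {
    stop("dimension names must be unique", call. = FALSE)
  }
  if (!all(dims$kind %in% c("continuous", "integer"))) {
    stop("`kind` must be 'continuous' or 'integer'", call. = FALSE)
  }
  if (any(dims$lower > dims$upper)) {
    stop("every lower bound must not exceed its upper bound", call. = FALSE)
  }
  int <- dims$kind == "integer"
  if (any(dims$lower[int] != round(dims$lower[int])) ||
      any(dims$upper[int] != round(dims$upper[int]))) {
    stop("integer dimensions need integer bounds", call. = FALSE)
  }
  structure(list(dims = dims, n_dims = nrow(dims)), class = "hp_space")
}

#' @export
print.hp_space <- function(x, ...) {
  cat("Hyperparameter search space:\n")
  print(x$dims, row.names = FALSE)
  invisible(x)
}

# The continuous box the GWO pack actually moves in. Degenerate (pinned)
# dimensions get an epsilon width so the engine has a valid box; decoding
# clamps them back to the pinned value.
hp_to_gwo_space <- function(space) {
  lo <- space$dims$lower
  up <- space$dims$upper
  pinned <- up <= lo
  up[pinned] <- lo[pinned] + pmax(abs(lo[pinned]), 1) * 1e-9
  search_space(lo, up)
}

#' Decode a continuous optimizer position into hyperparameters
#'
#' The optimizer itself moves in continuous space; integer dimensions are
#' rounded to the nearest integer only at decode time, then clamped back
#' into their bounds. Decoding is idempotent: decoding an already-decoded
#' assignment returns it unchanged.
#'
#' @param position Numeric vector, one coordinate per dimension of `space`.
#' @param space An [hp_space()].
#' @return Named list of hyperparameter values (class `"hp_params"`).
#' @export
decode_position <- function(position, space) {
  stopifnot(inherits(space, "hp_space"))
  d <- space$dims
  if (length(position) != nrow(d)) {
    stop("position length does not match the hyperparameter space",
         call. = FALSE)
  }
  vals <- as.numeric(position)
  int <- d$kind == "integer"
  vals[int] <- round(vals[int])
  vals <- pmin(pmax(vals, d$lower), d$upper)
  structure(as.list(stats::setNames(vals, d$name)), class = "hp_params")
}

#' @export
print.hp_params <- function(x, ...) {
  cat("Hyperparameters:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %g\n", nm, x[[nm]]))
  invisible(x)
}

hp_key <- function(hp) paste(names(hp), vapply(hp, format, ""), sep = "=",
                             collapse = ";")

#' Cached fitness of a hyperparameter assignment
#'
#' Evaluates `1 - validation accuracy` for a decoded assignment, training at
#' most once per distinct assignment: re-queries of an identical decoded
#' assignment are served from `cache` without calling the trainer.
#'
#' @param hp An `"hp_params"` assignment from [decode_position()].
#' @param trainer Function `(hp, train, validation, seed)` returning a list
#'   with at least `accuracy` and `loss`, deterministic given its seed.
#' @param data List with elements `train` and `validation`.
#' @param cache Environment used as the fitness cache (create with
#'   `new.env()`); also accumulates the evaluation log.
#' @param seed Seed forwarded to the trainer.
#' @return Scalar fitness `1 - accuracy`.
#' @export
fitness_of <- function(hp, trainer, data, cache, seed = 1L) {
  key <- hp_key(hp)
  hit <- cache$store[[key]]
  if (!is.null(hit)) return(hit$fitness)
  res <- tryCatch(trainer(hp, data$train, data$validation, seed),
                  error = function(e) {
                    stop("trainer failed for assignment [", key, "]: ",
                         conditionMessage(e), call. = FALSE)
                  })
  fitness <- 1 - res$accuracy
  cache$calls <- (cache$calls %||% 0L) + 1L
  entry <- c(as.list(hp), list(loss = res$loss %||% NA_real_,
                               accuracy = res$accuracy, fitness = fitness))
  cache$store[[key]] <- list(fitness = fitness, entry = entry)
  cache$log[[length(cache$log) + 1L]] <- entry
  fitness
}

new_fitness_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- list()
  e$log <- list()
  e$calls <- 0L
  e
}

#' Hyperparameter optimization by grey wolf search
#'
#' Wraps a training callback as the GWO objective: each wolf position is
#' decoded into a hyperparameter assignment, the trainer is run (once per
#' distinct assignment, thanks to the fitness cache), and `1 - validation
#' accuracy` is minimized. The reported best assignment is the log entry
#' with minimal fitness, ties broken by lower validation loss.
#'
#' @inheritParams fitness_of
#' @param space An [hp_space()].
#' @param n_wolves,n_iterations,seed GWO engine settings (see [gwo()]).
#' @param trainer_seed Seed forwarded to every trainer call.
#' @return Object of class `"hp_search"`: list with `best` (the winning
#'   `"hp_params"`), `best_score` (validation accuracy), `gwo` (the raw
#'   [gwo()] result), `log` (data frame, one row per trainer call) and
#'   `n_trainer_calls`.
#' @export
hp_search <- function(trainer, space = hp_space(), data,
                      n_wolves = 5L, n_iterations = 5L, seed = 1L,
                      trainer_seed = seed) {
  stopifnot(inherits(space, "hp_space"), is.function(trainer))
  cache <- new_fitness_cache()
  objective <- function(position) {
    hp <- decode_position(position, space)
    fitness_of(hp, trainer, data, cache, seed = trainer_seed)
  }
  gwo_fit <- gwo(objective, hp_to_gwo_space(space),
                 n_wolves = n_wolves, n_iterations = n_iterations,
                 seed = seed)
  log <- do.call(rbind, lapply(cache$log, function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
  ord <- order(log$fitness, log$loss)  # accuracy first, loss breaks ties
  best_row <- log[ord[1L], , drop = FALSE]
  best <- structure(as.list(best_row[, space$dims$name, drop = FALSE]),
                    class = "hp_params")
  structure(list(
    best = best,
    best_score = best_row$accuracy,
    best_fitness = best_row$fitness,
    gwo = gwo_fit,
    log = log,
    n_trainer_calls = cache$calls,
    space = space
  ), class = "hp_search")
}

#' @export
print.hp_search <- function(x, ...) {
  cat("GWO hyperparameter search\n")
  cat(sprintf("  %d trainer calls (%d objective evaluations)\n",
              x$n_trainer_calls, x$gwo$n_evaluations))
  cat(sprintf("  best validation accuracy: %.4f\n", x$best_score))
  print(x$best)
  invisible(x)
}

#' Write the evaluation log of a search as CSV
#'
#' One row per trainer call: the decoded assignment, validation loss,
#' validation accuracy and fitness.
#'
#' @param x An `"hp_search"` result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
hp_log_csv <- function(x, path) {
  stopifnot(inherits(x, "hp_search"))
  utils::write.csv(x$log, path, row.names = FALSE)
  invisible(path)
}

#' Random-search baseline with the same evaluation budget
#'
#' Draws assignments uniformly from the box (integer dimensions decoded the
#' same way as in GWO search) and trains each once. Used as the paired
#' baseline when judging whether the guided search earns its keep.
#'
#' @inheritParams hp_search
#' @param n_draws Number of assignments to evaluate.
#' @return Same shape as [hp_search()] minus the `gwo` element.
#' @export
random_search <- function(trainer, space = hp_space(), data, n_draws,
                          seed = 1L, trainer_seed = seed) {
  stopifnot(inherits(space, "hp_space"))
  cache <- new_fitness_cache()
  d <- space$dims
  with_preserved_seed(seed, {
    for (i in seq_len(n_draws)) {
      pos <- d$lower + stats::runif(nrow(d)) * (d$upper - d$lower)
      hp <- decode_position(pos, space)
      fitness_of(hp, trainer, data, cache, seed = trainer_seed)
    }
  })
  log <- do.call(rbind, lapply(cache$log, function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
  ord <- order(log$fitness, log$loss)
  best_row <- log[ord[1L], , drop = FALSE]
  list(best = structure(as.list(best_row[, d$name, drop = FALSE]),
                        class = "hp_params"),
       best_score = best_row$accuracy, log = log,
       n_trainer_calls = cache$calls)
}

#' Tiny deterministic trainer for desk-scale search
#'
#' A one-layer logistic classifier trained by minibatch gradient descent
#' with classical momentum. It consumes the hyperparameters the search
#' space exposes (`learning_rate`, `epochs`, `batch_size`, `momentum`) and
#' is deterministic given its seed, giving the search a cheap but
#' non-degenerate response surface: too few epochs or too small a learning
#' rate underfit. `dense_units` is accepted and ignored — a single-layer
#' model has no hidden width. Momentum maps to the first-moment decay and
#' is applied as given (values below 0.9 cannot arise inside the default
#' space).
#'
#' @param hp An `"hp_params"` assignment.
#' @param train,validation Lists with `x` (numeric feature matrix, rows =
#'   samples) and `y` (0/1 labels).
#' @param seed Integer seed for weight init and batch shuffling.
#' @return List with `accuracy` and `loss` on the validation set.
#' @export
tiny_trainer <- function(hp, train, validation, seed = 1L) {
  x <- as.matrix(train$x); y <- as.numeric(train$y)
  xv <- as.matrix(validation$x); yv <- as.numeric(validation$y)
  # standardize on train statistics so gradient scale is feature-free
  mu <- colMeans(x)
  sd <- pmax(apply(x, 2L, stats::sd), 1e-8)
  x <- sweep(sweep(x, 2L, mu), 2L, sd, "/")
  xv <- sweep(sweep(xv, 2L, mu), 2L, sd, "/")
  n <- nrow(x); p <- ncol(x)
  lr <- hp$learning_rate
  epochs <- as.integer(hp$epochs %||% 20L)
  bs <- max(1L, min(n, as.integer(hp$batch_size %||% 32L)))
  mom <- hp$momentum %||% 0

  with_preserved_seed(seed, {
    w <- stats::rnorm(p, sd = 0.01); b <- 0
    vw <- numeric(p); vb <- 0
    for (e in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        batch <- idx[start:min(start + bs - 1L, n)]
        z <- x[batch, , drop = FALSE] %*% w + b
        pr <- 1 / (1 + exp(-z))
        err <- pr - y[batch]
        gw <- crossprod(x[batch, , drop = FALSE], err) / length(batch)
        gb <- mean(err)
        vw <- mom * vw + lr * as.numeric(gw)
        vb <- mom * vb + lr * gb
        w <- w - vw
        b <- b - vb
      }
    }
    zv <- as.numeric(xv %*% w + b)
    prv <- 1 / (1 + exp(-zv))
    eps <- 1e-12
    list(
      accuracy = mean((prv >= 0.5) == (yv == 1)),
      loss = -mean(yv * log(prv + eps) + (1 - yv) * log(1 - prv + eps))
    )
  })
}
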