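test_that("the default search space mirrors the published tuning ranges", {
  sp <- hp_space()
  d <- sp$dims
  expect_equal(d$name, c("learning_rate", "batch_size", "momentum",
                         "dense_units", "epochs"))
  expect_equal(d$lower, c(0.001, 32, 0.9, 128, 10))
  expect_equal(d$upper, c(0.01, 128, 0.99, 512, 50))
  expect_equal(d$kind[c(1, 3)], rep("continuous", 2))
  expect_equal(d$kind[c(2, 4, 5)], rep("integer", 3))
  expect_error(hp_space(data.frame(name = c("a", "a"), kind = "integer",
                                   lower = 1, upper = 2)), "unique")
  expect_error(hp_space(data.frame(name = "a", kind = "integer",
                                   lower = 1.5, upper = 3)), "integer")
})

test_that("decoding rounds integers, clamps, and is idempotent", {
  sp <- hp_space()
  # the optimized assignment reported for the GWO-tuned VGG16 decodes
  # to itself: lr 0.001, batch 128, momentum 0.9, dense 256, epochs 30
  hp <- decode_position(c(0.001, 128, 0.9, 256, 30), sp)
  expect_equal(hp$learning_rate, 0.001)
  expect_equal(hp$batch_size, 128)
  expect_equal(hp$momentum, 0.9)
  expect_equal(hp$dense_units, 256)
  expect_equal(hp$epochs, 30)

  expect_equal(decode_position(c(0.005, 64.4, 0.95, 300, 20), sp)$batch_size,
               64)
  expect_equal(decode_position(c(0.005, 64, 0.95, 300, 49.6), sp)$epochs, 50)
  expect_equal(decode_position(c(0.005, 64, 0.95, 300, 50.4), sp)$epochs, 50)
  # idempotence: decode(decode(x)) == decode(x)
  once <- decode_position(c(0.0071, 77.7, 0.93, 300.2, 33.3), sp)
  twice <- decode_position(unlist(once), sp)
  expect_identical(once, twice)
  expect_error(decode_position(c(1, 2), sp), "length")
})

test_that("the fitness cache prevents duplicate training", {
  calls <- new.env(); calls$n <- 0L
  trainer <- function(hp, train, val, seed) {
    calls$n <- calls$n + 1L
    list(accuracy = 0.75, loss = 0.5)
  }
  cache <- pdgwo:::new_fitness_cache()
  hp <- decode_position(c(0.005, 64, 0.95, 256, 30), hp_space())
  f1 <- fitness_of(hp, trainer, list(), cache)
  f2 <- fitness_of(hp, trainer, list(), cache)
  expect_equal(f1, 0.25)
  expect_identical(f1, f2)
  expect_equal(calls$n, 1L)
  # perfect and chance-level accuracies map to fitness 0 and 0.5
  perfect <- function(hp, tr, va, s) list(accuracy = 1, loss = 0)
  chance <- function(hp, tr, va, s) list(accuracy = 0.5, loss = 0.7)
  expect_equal(fitness_of(decode_position(c(0.002, 40, .91, 200, 12),
                                          hp_space()),
                          perfect, list(), pdgwo:::new_fitness_cache()), 0)
  expect_equal(fitness_of(decode_position(c(0.002, 40, .91, 200, 12),
                                          hp_space()),
                          chance, list(), pdgwo:::new_fitness_cache()), 0.5)
})

test_that("trainer errors carry the offending assignment", {
  bad <- function(hp, tr, va, s) stop("exploded")
  hp <- decode_position(c(0.002, 40, 0.91, 200, 12), hp_space())
  expect_error(fitness_of(bad, trainer = bad, data = list(),
                          cache = pdgwo:::new_fitness_cache(), hp = hp),
               "learning_rate=0.002.*exploded")
})

test_that("search recovers a unimodal optimum and logs every evaluation", {
  toy <- make_toy_trainer(lr_opt = 0.004)
  fit <- hp_search(toy, hp_space(), data = list(), n_wolves = 5,
                   n_iterations = 5, seed = 2)
  expect_lt(abs(fit$best$learning_rate - 0.004) / 0.004, 0.10)
  # log invariants: bounds respected, integral integer dims, best = min
  d <- hp_space()$dims
  for (k in seq_len(nrow(d))) {
    v <- fit$log[[d$name[k]]]
    expect_true(all(v >= d$lower[k] & v <= d$upper[k]))
    if (d$kind[k] == "integer") expect_true(all(v == round(v)))
  }
  expect_equal(fit$best_fitness, min(fit$log$fitness))
  expect_lte(fit$n_trainer_calls, 5 * (5 + 1))
  expect_lt(fit$n_trainer_calls, fit$gwo$n_evaluations)  # cache hits

  rerun <- hp_search(toy, hp_space(), data = list(), n_wolves = 5,
                     n_iterations = 5, seed = 2)
  expect_identical(fit$log, rerun$log)
})

test_that("a single-point space is evaluated once and returned", {
  sp <- hp_space(data.frame(
    name = c("learning_rate", "epochs"),
    kind = c("continuous", "integer"),
    lower = c(0.005, 20), upper = c(0.005, 20),
    stringsAsFactors = FALSE))
  toy <- make_toy_trainer()
  fit <- hp_search(toy, sp, data = list(), n_wolves = 4, n_iterations = 3,
                   seed = 1)
  expect_equal(fit$n_trainer_calls, 1L)
  expect_equal(fit$best$learning_rate, 0.005)
  expect_equal(fit$best$epochs, 20)
})

test_that("guided search does at least as well as equal-budget random search", {
  data <- make_phantom_features(n_per_class = 25L, seed = 11L, size = 128L)
  diffs <- vapply(1:10, function(s) {
    g <- hp_search(tiny_trainer, hp_space(), data, n_wolves = 5,
                   n_iterations = 5, seed = s)
    r <- random_search(tiny_trainer, hp_space(), data,
                       n_draws = g$n_trainer_calls, seed = s + 1000)
    g$best_score - r$best_score
  }, numeric(1))
  expect_gte(median(diffs), 0)
})

test_that("the evaluation log round-trips through CSV", {
  fit <- hp_search(make_toy_trainer(), hp_space(), data = list(),
                   n_wolves = 4, n_iterations = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  hp_log_csv(fit, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(fit$log))
  expect_equal(back$accuracy, fit$log$accuracy)
})
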