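# Shared fixtures, all generated in code at test time.

# Phantom-derived feature sets for the tiny trainer: n images per class,
# default-separation phantoms, split in half train/validation.
make_phantom_features <- function(n_per_class = 30L, seed = 11L,
                                  size = 256L) {
  spec <- phantom_spec(size = size, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- 2L * n_per_class
  imgs <- vector("list", n)
  labs <- integer(n)
  for (i in seq_len(n)) {
    lab <- if (i %% 2L) "PD" else "HC"
    imgs[[i]] <- generate_image(spec, lab)$pixels
    labs[i] <- as.integer(lab == "PD")
  }
  x <- image_features(imgs)
  tr <- seq_len(n) <= n_per_class  # alternating labels: both halves balanced
  list(train = list(x = x[tr, , drop = FALSE], y = labs[tr]),
       validation = list(x = x[!tr, , drop = FALSE], y = labs[!tr]))
}

# Toy trainer whose validation accuracy is a known concave parabola in
# learning rate only, peaking at lr_opt.
make_toy_trainer <- function(lr_opt = 0.004) {
  function(hp, train, validation, seed) {
    acc <- 0.95 - 8000 * (hp$learning_rate - lr_opt)^2
    list(accuracy = acc, loss = 1 - acc)
  }
}

# md5 of a set of files, for byte-identity checks
files_md5 <- function(paths) unname(tools::md5sum(sort(paths)))
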