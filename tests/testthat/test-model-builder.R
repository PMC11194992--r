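test_that("shape arithmetic matches the convolution formula", {
  # 3x3 max pool, stride 2, valid on 7x7: floor((7-3)/2)+1 = 3
  expect_equal(ref_axis(7, 3, 2, "valid"), 3)
  g <- pdgwo:::new_graph(c(7L, 7L, 96L))
  pdgwo:::add_pool(g, "mp", kernel = c(3L, 3L), stride = c(2L, 2L),
                   padding = "valid")
  sp <- infer_shapes(pdgwo:::as_model_spec(g, "t"))
  expect_equal(sp$mp, c(3L, 3L, 96L))

  # pointwise conv preserves space, sets channels
  g2 <- pdgwo:::new_graph(c(13L, 9L, 5L))
  pdgwo:::add_conv(g2, "pw", 77L, kernel = c(1L, 1L))
  expect_equal(infer_shapes(pdgwo:::as_model_spec(g2, "t"))$pw,
               c(13L, 9L, 77L))

  # dropout and batch norm leave shapes unchanged; dense yields units
  g3 <- pdgwo:::new_graph(c(4L, 4L, 8L))
  pdgwo:::add_layer(g3, "dropout", "dr", rate = 0.2)
  pdgwo:::add_layer(g3, "global_avg_pool", "gap")
  pdgwo:::add_layer(g3, "dense", "fc", units = 11L)
  sp3 <- infer_shapes(pdgwo:::as_model_spec(g3, "t"))
  expect_equal(sp3$dr, c(4L, 4L, 8L))
  expect_equal(sp3$gap, c(1L, 1L, 8L))
  expect_equal(sp3$fc, c(1L, 1L, 11L))

  # a window larger than its input names the offending layer
  g4 <- pdgwo:::new_graph(c(2L, 2L, 3L))
  pdgwo:::add_conv(g4, "too_big", 8L, kernel = c(5L, 5L), padding = "valid")
  expect_error(infer_shapes(pdgwo:::as_model_spec(g4, "t")), "too_big")
})

test_that("the VGG16 backbone has 13 convs and lands on 7x7x512", {
  bb <- build_vgg16_backbone()
  ops <- vapply(bb$layers, function(l) l$op, "")
  convs <- bb$layers[ops == "conv"]
  expect_length(convs, 13L)
  expect_equal(convs[[1]]$filters, 64L)
  expect_true(all(vapply(convs, function(l) all(l$kernel == c(3L, 3L)),
                         TRUE)))
  expect_equal(sum(ops == "maxpool"), 5L)
  shapes <- infer_shapes(bb)
  expect_equal(shapes[[bb$blocks$block1_vgg16]], c(7L, 7L, 512L))
})

test_that("Block-2 preserves 7x7 and concatenates to 640 channels", {
  b2 <- build_block2()
  shapes <- infer_shapes(b2)
  out <- shapes[[b2$blocks$block2_inception_reduction]]
  expect_equal(out, c(7L, 7L, 640L))
  # every layer in the block stays 7x7
  expect_true(all(vapply(shapes, function(s) all(s[1:2] == 7L), TRUE)))
  # concat channels are conserved sums of their branch channels
  for (nm in names(b2$layers)) {
    ly <- b2$layers[[nm]]
    if (ly$op == "concat") {
      expect_equal(shapes[[nm]][3],
                   sum(vapply(ly$inputs, function(i) shapes[[i]][3], 0L)))
    }
  }
})

test_that("Block-3 factorizes 7x7 windows and reduces to 3x3x832", {
  b3 <- build_block3()
  shapes <- infer_shapes(b3)
  expect_equal(shapes[[b3$blocks$block3_inception_reduction]],
               c(3L, 3L, 832L))
  kernels <- lapply(b3$layers, function(l) l$kernel)
  has_7x1 <- any(vapply(kernels, function(k)
    !is.null(k) && all(k == c(7L, 1L)), TRUE))
  has_1x7 <- any(vapply(kernels, function(k)
    !is.null(k) && all(k == c(1L, 7L)), TRUE))
  has_7x7 <- any(vapply(kernels, function(k)
    !is.null(k) && all(k == c(7L, 7L)), TRUE))
  expect_true(has_7x1 && has_1x7)
  expect_false(has_7x7)
  # a same-padded stride-1 factorized pair preserves space like 7x7 would
  g <- pdgwo:::new_graph(c(7L, 7L, 64L))
  pdgwo:::add_conv(g, "v", 32L, kernel = c(7L, 1L))
  pdgwo:::add_conv(g, "h", 32L, kernel = c(1L, 7L))
  expect_equal(infer_shapes(pdgwo:::as_model_spec(g, "t"))$h,
               c(7L, 7L, 32L))
})

test_that("the hybrid model honours every block contract", {
  m <- build_hybrid()
  bs <- block_shapes(m)
  expect_equal(bs$block1_vgg16, c(7L, 7L, 512L))
  expect_equal(bs$block2_inception_reduction, c(7L, 7L, 640L))
  expect_equal(bs$block3_inception_reduction, c(3L, 3L, 832L))
  expect_equal(bs$block4_global_avg_pool, c(1L, 1L, 1024L))
  expect_equal(bs$block4_fully_connected, c(1L, 1L, 1024L))
  expect_equal(bs$output_sigmoid, c(1L, 1L, 1L))
})

test_that("every buildable model ends in one sigmoid unit with a dropout pair", {
  for (nm in c("vgg16", "densenet", "densenet_lstm", "inceptionv3",
               "hybrid")) {
    m <- build_model(nm)
    shapes <- infer_shapes(m)
    last <- m$layers[[length(m$layers)]]
    expect_equal(last$op, "dense")
    expect_equal(last$activation, "sigmoid")
    expect_equal(shapes[[length(shapes)]], c(1L, 1L, 1L))
    sig_units <- vapply(m$layers, function(l)
      identical(l$activation, "sigmoid"), TRUE)
    expect_equal(sum(sig_units), 1L)
    drops <- m$layers[vapply(m$layers, function(l) l$op == "dropout", TRUE)]
    expect_length(drops, 2L)
    expect_true(all(vapply(drops, function(l) l$rate == 0.20, TRUE)))
  }
  expect_error(build_model("resnet"), "unknown model")
})

test_that("named backbones expose their published stem facts", {
  v <- build_model("vgg16")
  dense_units <- vapply(v$layers[vapply(v$layers, function(l)
    l$op == "dense", TRUE)], function(l) l$units, 0L)
  expect_equal(unname(dense_units), c(256L, 128L, 1L))

  iv <- build_model("inceptionv3")
  stems <- iv$layers[grep("stem_conv", names(iv$layers))]
  expect_equal(unname(vapply(stems, function(l) l$filters, 0L)),
               c(32L, 32L, 64L))

  dn <- build_model("densenet")
  expect_equal(infer_shapes(dn)[[dn$blocks$backbone]], c(7L, 7L, 1024L))

  dl <- build_model("densenet_lstm")
  shapes <- infer_shapes(dl)
  expect_equal(shapes$to_sequence, c(1L, 7L, 7L * 1024L))
  expect_equal(shapes$lstm, c(1L, 1L, 128L))
})

test_that("hyperparameters resize the head with d2 = d1/2", {
  hp <- decode_position(c(0.001, 64, 0.9, 384, 30), hp_space())
  m <- build_model("vgg16", hp = hp)
  units <- vapply(m$layers[vapply(m$layers, function(l) l$op == "dense",
                                  TRUE)], function(l) l$units, 0L)
  expect_equal(unname(units), c(384L, 192L, 1L))
  expect_error(head_spec(c(64, 128)), "d1 >= d2")
  expect_error(head_spec(c(256, 128), dropout_rate = 1), "dropout")
})

test_that("parameter counting follows the dense formula", {
  g <- pdgwo:::new_graph(c(1L, 1L, 1024L))
  pdgwo:::add_layer(g, "dense", "fc", units = 256L)
  m <- pdgwo:::as_model_spec(g, "t")
  expect_equal(count_params(m), 1024 * 256 + 256)
})

test_that("model specs round-trip through YAML", {
  m <- build_hybrid()
  f <- withr::local_tempfile(fileext = ".yaml")
  model_to_yaml(m, f)
  back <- model_from_yaml(f)
  expect_equal(back$name, m$name)
  expect_equal(names(back$layers), names(m$layers))
  expect_identical(infer_shapes(back), infer_shapes(m))
  expect_equal(back$blocks, m$blocks)
})

test_that("materialize needs an adapter and cross-checks its shapes", {
  m <- build_block2()
  expect_error(materialize(m), class = "pdgwo_optional_dependency")

  # an adapter reporting shapes computed by the reference arithmetic
  probe_adapter <- function(model) {
    shapes <- list()
    cur <- list(".input" = model$input_shape)
    for (nm in names(model$layers)) {
      ly <- model$layers[[nm]]
      ins <- lapply(ly$inputs, function(i) cur[[i]])
      s <- ins[[1]]
      cur[[nm]] <- switch(ly$op,
        conv = c(ref_axis(s[1], ly$kernel[1], ly$stride[1], ly$padding),
                 ref_axis(s[2], ly$kernel[2], ly$stride[2], ly$padding),
                 ly$filters),
        maxpool = ,
        avgpool = c(ref_axis(s[1], ly$kernel[1], ly$stride[1], ly$padding),
                    ref_axis(s[2], ly$kernel[2], ly$stride[2], ly$padding),
                    s[3]),
        concat = c(s[1], s[2], sum(vapply(ins, function(x) x[3],
                                          numeric(1)))),
        s)
      shapes[[nm]] <- as.integer(cur[[nm]])
    }
    list(shapes = shapes, framework = "probe")
  }
  h <- materialize(m, probe_adapter)
  expect_equal(h$framework, "probe")

  lying_adapter <- function(model) {
    s <- probe_adapter(model)$shapes
    s[[length(s)]] <- c(1L, 1L, 1L)
    list(shapes = s)
  }
  expect_error(materialize(m, lying_adapter), "shape mismatch")
})
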