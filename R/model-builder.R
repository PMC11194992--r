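#' @title Declarative model specs with exact shape inference
#' @description
#' The five classifier architectures are expressed as framework-independent
#' layer graphs (`"model_spec"` objects) whose per-layer output shapes are
#' inferred by standard convolution arithmetic. The hybrid design — a VGG16
#' backbone followed by two inception-reduction blocks — carries hard
#' feature-map contracts at its block boundaries: 7x7x512 after the
#' backbone, 7x7x640 after the first inception-reduction block, 3x3x832
#' after the second, a 1024-long globally averaged feature vector, a
#' 1024-unit fully connected layer, and a single sigmoid output.
#' @name model_builder
NULL

# Branch channel allocations for the two inception-reduction blocks. The
# published design fixes only the layer-type counts per sub-block and the
# concatenated totals (640 and 832); the per-branch widths below are this
# package's allocation satisfying both constraints.
#   Block-2 inception  (in 512): 1x1[128] | 1x1[128]>3x3[192]
#                                | 1x1[64]>3x3[96]>3x3[96]
#                                | maxpool3x3>1x1[128]          -> 544
#   Block-2 reduction  (in 544): 3x3[256] | 3x3[96]>3x3[128]
#                                | maxpool3x3>1x1[256]          -> 640
#   Block-3 inception  (in 640): 1x1[128] | 1x1[96]>7x1[96]>1x7[128]
#                                | 1x1[96]>(7x1>1x7)x2[...128]
#                                | avgpool3x3>1x1[128]          -> 512
#   Block-3 reduction  (in 512): 1x1[96]>3x3[128]/s2v
#                                | 1x1[96]>7x1[96]>1x7[96]>3x3[192]/s2v
#                                | maxpool3x3/s2v (pass 512)    -> 832
hybrid_block_channels <- list(
  block2_inception = list(a = 128, b = c(128, 192), c = c(64, 96, 96),
                          pool_proj = 128),
  block2_reduction = list(a = 256, b = c(96, 128), pool_proj = 256),
  block3_inception = list(a = 128, b = c(96, 96, 128),
                          c = c(96, 96, 96, 96, 128), pool_proj = 128),
  block3_reduction = list(a = c(96, 128), b = c(96, 96, 96, 192))
)

# ---- graph construction ----------------------------------------------------

new_graph <- function(input_shape = c(224L, 224L, 3L)) {
  g <- new.env(parent = emptyenv())
  g$layers <- list()
  g$last <- ".input"
  g$input_shape <- as.integer(input_shape)
  g$blocks <- list()
  g
}

add_layer <- function(g, op, name, inputs = NULL, ...) {
  if (name %in% names(g$layers)) {
    stop("duplicate layer name: ", name, call. = FALSE)
  }
  layer <- c(list(op = op, inputs = inputs %||% g$last), list(...))
  g$layers[[name]] <- layer
  g$last <- name
  name
}

add_conv <- function(g, name, filters, kernel = c(3L, 3L),
                     stride = c(1L, 1L), padding = "same",
                     activation = "relu", inputs = NULL) {
  add_layer(g, "conv", name, inputs = inputs, filters = as.integer(filters),
            kernel = as.integer(kernel), stride = as.integer(stride),
            padding = padding, activation = activation)
}

add_pool <- function(g, name, op = "maxpool", kernel = c(2L, 2L),
                     stride = kernel, padding = "valid", inputs = NULL) {
  add_layer(g, op, name, inputs = inputs, kernel = as.integer(kernel),
            stride = as.integer(stride), padding = padding)
}

mark_block <- function(g, block) g$blocks[[block]] <- g$last

as_model_spec <- function(g, name) {
  structure(list(name = name, input_shape = g$input_shape,
                 layers = g$layers, blocks = g$blocks),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec '%s': %d layers, input %s\n", x$name,
              length(x$layers), paste(x$input_shape, collapse = "x")))
  if (length(x$blocks)) {
    shapes <- infer_shapes(x)
    for (b in names(x$blocks)) {
      cat(sprintf("  %-28s -> %s\n", b,
                  paste(shapes[[x$blocks[[b]]]], collapse = "x")))
    }
  }
  invisible(x)
}

# ---- shape inference -------------------------------------------------------

conv_axis <- function(n, k, s, padding) {
  if (padding == "same") as.integer(ceiling(n / s))
  else as.integer(floor((n - k) / s) + 1L)
}

#' Infer the output shape of every layer in a model spec
#'
#' Walks the layer graph in declaration order applying standard output-size
#' arithmetic: for a convolution or pooling window of size k and stride s,
#' `"valid"` padding yields `floor((n - k) / s) + 1` along each spatial
#' axis while `"same"` padding yields `ceiling(n / s)` (so size is
#' preserved at stride 1); concatenation requires equal spatial dimensions
#' and sums channels; global average pooling collapses to `1 x 1 x C`;
#' dense and LSTM layers yield their unit counts.
#'
#' @param model A `"model_spec"`.
#' @return Named list mapping each layer name to an integer
#'   `c(height, width, channels)` triple. Vector-valued layers (dense,
#'   flatten, LSTM) report `c(1, 1, units)`.
#' @export
infer_shapes <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  shapes <- list(".input" = model$input_shape)
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    ins <- lapply(ly$inputs, function(i) {
      s <- shapes[[i]]
      if (is.null(s)) stop("layer '", nm, "' references unknown input '",
                           i, "'", call. = FALSE)
      s
    })
    s <- ins[[1L]]
    out <- switch(ly$op,
      conv = ,
      maxpool = ,
      avgpool = {
        h <- conv_axis(s[1L], ly$kernel[1L], ly$stride[1L], ly$padding)
        w <- conv_axis(s[2L], ly$kernel[2L], ly$stride[2L], ly$padding)
        ch <- if (ly$op == "conv") ly$filters else s[3L]
        c(h, w, ch)
      },
      global_avg_pool = c(1L, 1L, s[3L]),
      flatten = c(1L, 1L, prod(s)),
      dense = c(1L, 1L, as.integer(ly$units)),
      lstm = c(1L, 1L, as.integer(ly$units)),
      reshape_seq = c(1L, s[1L], s[2L] * s[3L]),  # rows become timesteps
      dropout = ,
      batch_norm = ,
      activation = s,
      concat = {
        spatial <- vapply(ins, function(x) x[1:2], integer(2))
        if (any(spatial[1, ] != s[1L]) || any(spatial[2, ] != s[2L])) {
          stop("concat '", nm, "' has branches with mismatched spatial ",
               "dimensions", call. = FALSE)
        }
        c(s[1L], s[2L], sum(vapply(ins, function(x) x[3L], integer(1))))
      },
      stop("unknown op '", ly$op, "' in layer '", nm, "'", call. = FALSE)
    )
    if (any(out < 1L)) {
      stop("layer '", nm, "' produces a non-positive dimension (",
           paste(out, collapse = "x"), ")", call. = FALSE)
    }
    shapes[[nm]] <- as.integer(out)
  }
  shapes[-1L]
}

#' Per-block output shapes of a model spec
#'
#' @param model A `"model_spec"` with declared block boundaries.
#' @return Named list of `c(height, width, channels)` at each boundary.
#' @export
block_shapes <- function(model) {
  shapes <- infer_shapes(model)
  lapply(model$blocks, function(nm) shapes[[nm]])
}

# ---- backbone emitters -----------------------------------------------------

# 13 convolutions (3x3, stride 1, same, ReLU) in widths
# 64,64 | 128,128 | 256x3 | 512x3 | 512x3 with a 2x2/2 max pool after each
# group: 224x224x3 -> 7x7x512.
emit_vgg16 <- function(g, prefix = "vgg") {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  for (b in seq_along(widths)) {
    for (i in seq_along(widths[[b]])) {
      add_conv(g, sprintf("%s_b%d_conv%d", prefix, b, i), widths[[b]][i])
    }
    add_pool(g, sprintf("%s_b%d_pool", prefix, b))
  }
  invisible(g)
}

emit_branch <- function(g, prefix, stages) {
  # stages: list of lists(op, filters, kernel, stride, padding)
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    nm <- sprintf("%s_%d", prefix, i)
    if (st$op == "conv") {
      add_conv(g, nm, st$filters, kernel = st$kernel,
               stride = st$stride %||% c(1L, 1L),
               padding = st$padding %||% "same")
    } else {
      add_pool(g, nm, op = st$op, kernel = st$kernel,
               stride = st$stride %||% c(1L, 1L),
               padding = st$padding %||% "same")
    }
  }
  g$last
}

cv <- function(filters, kernel = c(1L, 1L), stride = NULL, padding = NULL) {
  list(op = "conv", filters = filters, kernel = kernel, stride = stride,
       padding = padding)
}
pl <- function(op = "maxpool", kernel = c(3L, 3L), stride = NULL,
               padding = NULL) {
  list(op = op, kernel = kernel, stride = stride, padding = padding)
}

emit_parallel <- function(g, prefix, branches) {
  root <- g$last
  ends <- character(length(branches))
  for (i in seq_along(branches)) {
    g$last <- root
    ends[i] <- emit_branch(g, sprintf("%s_br%d", prefix, i), branches[[i]])
  }
  add_layer(g, "concat", paste0(prefix, "_concat"), inputs = ends)
}

# Block-2: inception sub-block (four 1x1 convs, three 3x3 convs, one 3x3
# max pool) then reduction sub-block (three 3x3 convs, one 1x1 conv, max
# pool), everything stride 1 / same so 7x7 is preserved; channels 512 ->
# 544 -> 640.
emit_block2 <- function(g, prefix = "b2") {
  ch <- hybrid_block_channels
  i <- ch$block2_inception
  emit_parallel(g, paste0(prefix, "_inc"), list(
    list(cv(i$a)),
    list(cv(i$b[1]), cv(i$b[2], kernel = c(3L, 3L))),
    list(cv(i$c[1]), cv(i$c[2], kernel = c(3L, 3L)),
         cv(i$c[3], kernel = c(3L, 3L))),
    list(pl("maxpool"), cv(i$pool_proj))
  ))
  r <- ch$block2_reduction
  emit_parallel(g, paste0(prefix, "_red"), list(
    list(cv(r$a, kernel = c(3L, 3L))),
    list(cv(r$b[1], kernel = c(3L, 3L)), cv(r$b[2], kernel = c(3L, 3L))),
    list(pl("maxpool"), cv(r$pool_proj))
  ))
  invisible(g)
}

# Block-3: inception sub-block (four 1x1 convs, three factorized 7x1/1x7
# pairs replacing 7x7 windows, 3x3 average pool) at stride 1 / same, then
# reduction sub-block (two 1x1, two 3x3, one 7x1/1x7 pair, 3x3 max pool)
# whose final stage runs stride 2 / valid: 7x7x640 -> 7x7x512 -> 3x3x832.
emit_block3 <- function(g, prefix = "b3") {
  ch <- hybrid_block_channels
  i <- ch$block3_inception
  emit_parallel(g, paste0(prefix, "_inc"), list(
    list(cv(i$a)),
    list(cv(i$b[1]), cv(i$b[2], kernel = c(7L, 1L)),
         cv(i$b[3], kernel = c(1L, 7L))),
    list(cv(i$c[1]), cv(i$c[2], kernel = c(7L, 1L)),
         cv(i$c[3], kernel = c(1L, 7L)), cv(i$c[4], kernel = c(7L, 1L)),
         cv(i$c[5], kernel = c(1L, 7L))),
    list(pl("avgpool"), cv(i$pool_proj))
  ))
  r <- ch$block3_reduction
  emit_parallel(g, paste0(prefix, "_red"), list(
    list(cv(r$a[1]),
         cv(r$a[2], kernel = c(3L, 3L), stride = c(2L, 2L),
            padding = "valid")),
    list(cv(r$b[1]), cv(r$b[2], kernel = c(7L, 1L)),
         cv(r$b[3], kernel = c(1L, 7L)),
         cv(r$b[4], kernel = c(3L, 3L), stride = c(2L, 2L),
            padding = "valid")),
    list(pl("maxpool", stride = c(2L, 2L), padding = "valid"))
  ))
  invisible(g)
}

# Classifier head shared by every model: dense(d1)+BN+dropout,
# dense(d2)+BN+dropout, dense(1, sigmoid).
emit_head <- function(g, head, prefix = "head") {
  add_layer(g, "dense", paste0(prefix, "_dense1"),
            units = as.integer(head$dense_units[1L]), activation = "relu")
  add_layer(g, "batch_norm", paste0(prefix, "_bn1"))
  add_layer(g, "dropout", paste0(prefix, "_drop1"), rate = head$dropout_rate)
  add_layer(g, "dense", paste0(prefix, "_dense2"),
            units = as.integer(head$dense_units[2L]), activation = "relu")
  add_layer(g, "batch_norm", paste0(prefix, "_bn2"))
  add_layer(g, "dropout", paste0(prefix, "_drop2"), rate = head$dropout_rate)
  add_layer(g, "dense", paste0(prefix, "_sigmoid"), units = 1L,
            activation = "sigmoid")
  invisible(g)
}

# ---- public builders -------------------------------------------------------

#' Classifier head specification
#'
#' Two fully connected hidden layers (defaults 256 and 128 units, ReLU,
#' each followed by batch normalization and 20% dropout) and a single
#' sigmoid output unit for the binary PD/HC decision.
#'
#' @param dense_units Integer pair `(d1, d2)`, `d1 >= d2 >= 1`.
#' @param dropout_rate Dropout fraction in `[0, 1)`.
#' @return An object of class `"head_spec"`.
#' @export
head_spec <- function(dense_units = c(256L, 128L), dropout_rate = 0.20) {
  dense_units <- as.integer(dense_units)
  stopifnot(length(dense_units) == 2L)
  if (dense_units[1L] < dense_units[2L] || dense_units[2L] < 1L) {
    stop("head units must satisfy d1 >= d2 >= 1", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(dense_units = dense_units, dropout_rate = dropout_rate),
            class = "head_spec")
}

#' VGG16 convolutional backbone
#'
#' Thirteen 3x3 stride-1 same-padded ReLU convolutions in widths
#' 64,64 / 128,128 / 256x3 / 512x3 / 512x3, a 2x2 stride-2 max pool after
#' each width group. On a 224x224x3 input the output feature map is
#' 7x7x512.
#'
#' @return A `"model_spec"` fragment.
#' @export
build_vgg16_backbone <- function() {
  g <- new_graph(c(224L, 224L, 3L))
  emit_vgg16(g)
  mark_block(g, "block1_vgg16")
  as_model_spec(g, "vgg16_backbone")
}

#' First inception-reduction block of the hybrid model
#'
#' Parallel-branch inception sub-block (four 1x1 convolutions, three 3x3
#' convolutions, one 3x3 max pool) concatenated on channels, followed by a
#' reduction sub-block (three 3x3 convolutions, one 1x1 convolution, max
#' pool), all stride 1 / same padding. Takes the backbone's 7x7x512 map to
#' 7x7x640.
#'
#' @return A `"model_spec"` fragment with input shape 7x7x512.
#' @export
build_block2 <- function() {
  g <- new_graph(c(7L, 7L, 512L))
  emit_block2(g)
  mark_block(g, "block2_inception_reduction")
  as_model_spec(g, "hybrid_block2")
}

#' Second inception-reduction block of the hybrid model
#'
#' Inception sub-block using factorized 7x1 and 1x7 convolution pairs in
#' place of full 7x7 windows (cheaper at equal receptive field) plus 3x3
#' average pooling, then a reduction sub-block whose final stage runs at
#' stride 2 with valid padding so the 7x7 grid drops to 3x3. Takes
#' 7x7x640 to 3x3x832.
#'
#' @return A `"model_spec"` fragment with input shape 7x7x640.
#' @export
build_block3 <- function() {
  g <- new_graph(c(7L, 7L, 640L))
  emit_block3(g)
  mark_block(g, "block3_inception_reduction")
  as_model_spec(g, "hybrid_block3")
}

#' Hybrid VGG16 + inception-reduction classifier
#'
#' Block-1 is the full VGG16 backbone (7x7x512), Block-2 and Block-3 are
#' the two inception-reduction blocks (7x7x640, then 3x3x832), a 1x1
#' channel projection lifts 832 to 1024 so that Block-4's global average
#' pooling yields the contracted 1024-long feature vector, which feeds a
#' 1024-unit fully connected layer and then the standard classifier head
#' ending in one sigmoid unit.
#'
#' @param head A [head_spec()].
#' @return A `"model_spec"` whose block boundaries carry the contracts
#'   7x7x512 / 7x7x640 / 3x3x832 / 1024 / 1024 / 1.
#' @export
build_hybrid <- function(head = head_spec()) {
  stopifnot(inherits(head, "head_spec"))
  g <- new_graph(c(224L, 224L, 3L))
  emit_vgg16(g)
  mark_block(g, "block1_vgg16")
  emit_block2(g)
  mark_block(g, "block2_inception_reduction")
  emit_block3(g)
  mark_block(g, "block3_inception_reduction")
  add_conv(g, "channel_projection", 1024L, kernel = c(1L, 1L))
  add_layer(g, "global_avg_pool", "block4_gap")
  mark_block(g, "block4_global_avg_pool")
  add_layer(g, "dense", "block4_fc", units = 1024L, activation = "relu")
  mark_block(g, "block4_fully_connected")
  emit_head(g, head)
  mark_block(g, "output_sigmoid")
  as_model_spec(g, "hybrid_vgg16_inception")
}

# DenseNet-121 topology: stem (7x7/2 conv, 3x3/2 pool), four dense blocks
# of 6/12/24/16 layers at growth 32 (each layer 1x1 bottleneck 128 then
# 3x3 growth conv, concatenated), 1x1 half-width transition + 2x2/2 avg
# pool between blocks; ends 7x7x1024 on a 224 input.
emit_densenet <- function(g, prefix = "dn") {
  add_conv(g, paste0(prefix, "_stem_conv"), 64L, kernel = c(7L, 7L),
           stride = c(2L, 2L))
  add_pool(g, paste0(prefix, "_stem_pool"), kernel = c(3L, 3L),
           stride = c(2L, 2L), padding = "same")
  n_layers <- c(6L, 12L, 24L, 16L)
  channels <- 64L
  growth <- 32L
  for (b in seq_along(n_layers)) {
    for (l in seq_len(n_layers[b])) {
      block_in <- g$last
      nm <- sprintf("%s_db%d_l%d", prefix, b, l)
      add_conv(g, paste0(nm, "_bottleneck"), 4L * growth,
               kernel = c(1L, 1L), inputs = block_in)
      add_conv(g, paste0(nm, "_growth"), growth)
      add_layer(g, "concat", paste0(nm, "_concat"),
                inputs = c(block_in, g$last))
      channels <- channels + growth
    }
    if (b < length(n_layers)) {
      channels <- channels %/% 2L
      add_conv(g, sprintf("%s_trans%d_conv", prefix, b), channels,
               kernel = c(1L, 1L))
      add_pool(g, sprintf("%s_trans%d_pool", prefix, b), op = "avgpool",
               kernel = c(2L, 2L))
    }
  }
  invisible(g)
}

# InceptionV3-style backbone: the stem follows the published facts (three
# convolutions of 32, 32 and 64 filters with 3x3 kernels, then a 3x3
# stride-2 max pool); the module body is a configurable stand-in of
# standard parallel-branch modules, not a re-derivation of the full stem
# topology.
emit_inceptionv3 <- function(g, prefix = "iv3", n_modules = 3L) {
  add_conv(g, paste0(prefix, "_stem_conv1"), 32L, stride = c(2L, 2L),
           padding = "valid")
  add_conv(g, paste0(prefix, "_stem_conv2"), 32L, padding = "valid")
  add_conv(g, paste0(prefix, "_stem_conv3"), 64L)
  add_pool(g, paste0(prefix, "_stem_pool"), kernel = c(3L, 3L),
           stride = c(2L, 2L), padding = "valid")
  for (m in seq_len(n_modules)) {
    emit_parallel(g, sprintf("%s_mod%d", prefix, m), list(
      list(cv(64L)),
      list(cv(48L), cv(64L, kernel = c(5L, 5L))),
      list(cv(64L), cv(96L, kernel = c(3L, 3L)),
           cv(96L, kernel = c(3L, 3L))),
      list(pl("avgpool"), cv(64L))
    ))
  }
  invisible(g)
}

#' Build one of the five classifier architectures
#'
#' Assembles the named backbone plus the shared classifier head. When a
#' hyperparameter assignment is supplied, its `dense_units` value sets the
#' first head layer and the second is fixed at half of it (matching the
#' 256/128 default).
#'
#' @param name One of `"vgg16"`, `"densenet"`, `"densenet_lstm"`,
#'   `"inceptionv3"`, `"hybrid"`.
#' @param head A [head_spec()]; ignored for the units when `hp` supplies
#'   `dense_units`.
#' @param hp Optional `"hp_params"` assignment from [decode_position()].
#' @return A `"model_spec"`.
#' @export
build_model <- function(name, head = head_spec(), hp = NULL) {
  if (!is.null(hp) && !is.null(hp$dense_units)) {
    d1 <- as.integer(hp$dense_units)
    head <- head_spec(c(d1, max(1L, d1 %/% 2L)), head$dropout_rate)
  }
  known <- c("vgg16", "densenet", "densenet_lstm", "inceptionv3", "hybrid")
  if (length(name) != 1L || !name %in% known) {
    stop("unknown model name; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (name == "hybrid") return(build_hybrid(head))
  g <- new_graph(c(224L, 224L, 3L))
  switch(name,
    vgg16 = {
      emit_vgg16(g)
      mark_block(g, "backbone")
      add_layer(g, "flatten", "flatten")
    },
    densenet = {
      emit_densenet(g)
      mark_block(g, "backbone")
      add_layer(g, "global_avg_pool", "gap")
    },
    densenet_lstm = {
      emit_densenet(g)
      mark_block(g, "backbone")
      # rows of the final 7x7 map become 7 timesteps of 7*C features
      add_layer(g, "reshape_seq", "to_sequence")
      add_layer(g, "lstm", "lstm", units = head$dense_units[2L])
    },
    inceptionv3 = {
      emit_inceptionv3(g)
      mark_block(g, "backbone")
      add_layer(g, "global_avg_pool", "gap")
    }
  )
  emit_head(g, head)
  mark_block(g, "output_sigmoid")
  as_model_spec(g, name)
}

# ---- parameters, serialization, materialization ----------------------------

#' Count trainable parameters of a model spec
#'
#' Convolution: `(kh*kw*c_in + 1) * filters`; dense: `(n_in + 1) * units`;
#' LSTM: `4 * (n_in + units + 1) * units`; batch normalization: `2 * C`.
#'
#' @param model A `"model_spec"`.
#' @return Total parameter count (double, to avoid integer overflow).
#' @export
count_params <- function(model) {
  shapes <- infer_shapes(model)
  shapes[[".input"]] <- model$input_shape
  total <- 0
  for (nm in names(model$layers)) {
    ly <- model$layers[[nm]]
    s_in <- shapes[[ly$inputs[[1L]]]]
    total <- total + switch(ly$op,
      conv = (prod(ly$kernel) * s_in[3L] + 1) * ly$filters,
      dense = (prod(s_in) + 1) * ly$units,
      lstm = 4 * (s_in[3L] + ly$units + 1) * ly$units,
      batch_norm = 2 * s_in[3L],
      0)
  }
  total
}

#' Serialize a model spec to YAML
#'
#' The YAML document carries the layer graph plus the inferred shape of
#' every layer, so architecture contracts are diffable and reviewable
#' without any training framework.
#'
#' @param model A `"model_spec"`.
#' @param path Optional output path; when `NULL` the YAML string is
#'   returned.
#' @return YAML string (invisibly when written to `path`).
#' @export
model_to_yaml <- function(model, path = NULL) {
  shapes <- infer_shapes(model)
  doc <- list(
    name = model$name,
    input_shape = as.integer(model$input_shape),
    blocks = model$blocks,
    layers = lapply(names(model$layers), function(nm) {
      c(list(name = nm), model$layers[[nm]],
        list(output_shape = as.integer(shapes[[nm]])))
    })
  )
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a model spec back from YAML
#'
#' @param path Path to a YAML file written by [model_to_yaml()].
#' @return A `"model_spec"`.
#' @export
model_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  layers <- list()
  for (ly in doc$layers) {
    nm <- ly$name
    ly$name <- NULL
    ly$output_shape <- NULL
    ly$inputs <- unlist(ly$inputs)
    for (f in c("kernel", "stride")) {
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(unlist(ly[[f]]))
    }
    layers[[nm]] <- ly
  }
  structure(list(name = doc$name,
                 input_shape = as.integer(unlist(doc$input_shape)),
                 layers = layers,
                 blocks = doc$blocks %||% list()),
            class = "model_spec")
}

#' Materialize a model spec as a trainable model
#'
#' Hands the declarative spec to a framework adapter (for example a
#' user-supplied keras/tensorflow builder) and cross-checks the adapter's
#' reported per-layer output shapes against [infer_shapes()]. Training a
#' materialized model uses the Adam optimizer with binary cross-entropy
#' loss. No deep-learning framework ships with this package; without an
#' adapter this function raises an optional-dependency error.
#'
#' @param model A `"model_spec"`.
#' @param adapter Function taking the spec and returning a handle; if the
#'   handle has a `shapes` element (named list of layer output shapes) it
#'   is verified against the spec's inferred shapes.
#' @return The adapter's handle.
#' @export
materialize <- function(model, adapter = NULL) {
  stopifnot(inherits(model, "model_spec"))
  if (is.null(adapter)) {
    stop(structure(class = c("pdgwo_optional_dependency", "error",
                             "condition"),
                   list(message = paste0(
                     "no framework adapter supplied: materializing '",
                     model$name, "' needs a training backend (e.g. a ",
                     "keras/tensorflow adapter function); pass it as ",
                     "`adapter`. Model training uses Adam with binary ",
                     "cross-entropy."),
                     call = sys.call())))
  }
  handle <- adapter(model)
  if (!is.null(handle$shapes)) {
    want <- infer_shapes(model)
    for (nm in intersect(names(handle$shapes), names(want))) {
      got <- as.integer(unlist(handle$shapes[[nm]]))
      if (!identical(got, want[[nm]])) {
        stop("adapter shape mismatch at layer '", nm, "': adapter ",
             paste(got, collapse = "x"), " vs inferred ",
             paste(want[[nm]], collapse = "x"), call. = FALSE)
      }
    }
  }
  handle
}
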