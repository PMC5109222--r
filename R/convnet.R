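#' ConvNet architecture specification
#'
#' The eight-layer network used for per-frame sEMG-image classification:
#' two 3x3 convolutional layers (64 filters, stride 1, zero "same"
#' padding), two locally connected layers of 64 non-overlapping 1x1
#' filters with position-specific (unshared) weights, three fully
#' connected layers of 512, 512 and 128 units, and a G-way softmax
#' output. ReLU follows every hidden layer; batch normalisation is
#' applied to the input and before every non-linearity; dropout with
#' probability 0.5 acts on the fourth, fifth and sixth hidden layers
#' (second local layer and the first two fully connected layers).
#'
#' @param input_shape `(rows, cols, channels)` of the input image;
#'   channels is 1 for grayscale (default) or 3 for replicated RGB.
#' @param n_classes Number G of gestures (>= 2).
#' @param conv_filters,local_filters Filter counts (64 in the reference
#'   architecture).
#' @param dense_units Fully connected layer widths.
#' @param dropout_p Dropout probability on hidden layers 4-6.
#' @param remove_local Tuning-baseline variant with the two locally
#'   connected layers removed.
#' @return An object of class `convnet_spec`.
#' @export
convnet_spec <- function(input_shape, n_classes, conv_filters = 64L,
                         local_filters = 64L, dense_units = c(512L, 512L, 128L),
                         dropout_p = 0.5, remove_local = FALSE) {
  stopifnot(length(input_shape) %in% c(2L, 3L), n_classes >= 2)
  if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
  structure(list(rows = as.integer(input_shape[1]),
                 cols = as.integer(input_shape[2]),
                 channels = as.integer(input_shape[3]),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 local_filters = as.integer(local_filters),
                 dense_units = as.integer(dense_units),
                 dropout_p = dropout_p,
                 remove_local = isTRUE(remove_local)),
            class = "convnet_spec")
}

#' SGD training specification
#'
#' The reference recipe: batch size 1000, 28 epochs, weight decay 1e-4,
#' learning rate starting at 0.1 and divided by 10 after the 16th and
#' 24th epochs (1-based epoch indexing).
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of epochs.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @param lr Initial learning rate (> 0).
#' @param lr_drops Epochs after which the rate is divided by 10.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @param pretrain Initialise by pre-training on the union of all
#'   subjects' training sets (see [pretrain_union()]).
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(batch_size = 1000L, epochs = 28L,
                       weight_decay = 1e-4, lr = 0.1, lr_drops = c(16L, 24L),
                       seed = 1L, pretrain = FALSE) {
  stopifnot(batch_size >= 1, lr > 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 lr = lr, lr_drops = lr_drops, seed = as.integer(seed),
                 pretrain = isTRUE(pretrain)),
            class = "train_spec")
}

#' Build the sEMG-image ConvNet
#'
#' Instantiates the architecture of [convnet_spec()] with He-style
#' initialisation (zero-mean Gaussians scaled by `sqrt(2 / fan_in)`).
#'
#' @param spec A [convnet_spec()].
#' @param seed RNG seed for the weight initialisation.
#' @return An untrained model (list of layers plus metadata).
#' @export
build_convnet <- function(spec, seed = 1L) {
  set.seed(seed)
  H <- spec$rows; W <- spec$cols; Cin <- spec$channels
  HW <- H * W
  src <- conv_src_table(H, W)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  add(new_bn(Cin))                                    # input BN
  cf <- spec$conv_filters
  for (cin in c(Cin, cf)) {                           # two conv layers
    add(list(type = "conv", src = src,
             W = he_init(cf, nrow(src) * cin, fan_in = nrow(src) * cin),
             b = rep(0, cf)))
    add(new_bn(cf)); add(list(type = "relu"))
  }
  lf <- spec$local_filters
  if (!spec$remove_local) {
    for (j in 1:2) {                                  # two local layers
      cin <- if (j == 1L) cf else lf
      Wl <- array(0, c(lf, cin, HW))
      for (p in seq_len(HW)) Wl[, , p] <- he_init(lf, cin, fan_in = cin)
      add(list(type = "local", W = Wl, b = matrix(0, lf, HW)))
      add(new_bn(lf)); add(list(type = "relu"))
      if (j == 2L) add(list(type = "dropout", p = spec$dropout_p))
    }
    feat <- lf
  } else feat <- cf
  add(list(type = "flatten"))
  d_in <- HW * feat
  for (j in seq_along(spec$dense_units)) {            # fully connected
    du <- spec$dense_units[j]
    add(list(type = "dense", W = he_init(du, d_in, fan_in = d_in),
             b = rep(0, du)))
    add(new_bn(du)); add(list(type = "relu"))
    if (j <= 2L) add(list(type = "dropout", p = spec$dropout_p))
    d_in <- du
  }
  add(list(type = "dense",                            # G-way output
           W = he_init(spec$n_classes, d_in, fan_in = d_in),
           b = rep(0, spec$n_classes)))

  structure(list(layers = layers, spec = spec, HW = HW, Cin = Cin,
                 D_in = HW * Cin, G = spec$n_classes, spatial_in = TRUE,
                 classes = NULL, history = numeric(0)),
            class = c("semg_convnet", "semg_model"))
}

#' Train the ConvNet on labelled sEMG images
#'
#' @param model A model from [build_convnet()] (or from
#'   [pretrain_union()] for fine-tuning).
#' @param x Image matrix, frames x pixels (see [as_image_matrix()]).
#' @param y Integer gesture labels, one per frame.
#' @param tspec A [train_spec()].
#' @return The trained model with its per-epoch loss trace in `$history`.
#' @export
train_convnet <- function(model, x, y, tspec = train_spec()) {
  nn_train(model, x, y, tspec)
}

#' Pre-train on the union of all subjects' training sets
#'
#' Initialises the network by training once on the pooled training data
#' of every subject, the initialisation then fine-tuned per subject.
#' With a single subject this is ordinary training on that subject.
#'
#' @param model An initialised (untrained) model.
#' @param training_sets Non-empty list of `list(x = , y = )` per subject.
#' @param tspec A [train_spec()].
#' @return The pre-trained model, usable as initialisation for
#'   [train_convnet()].
#' @export
pretrain_union <- function(model, training_sets, tspec = train_spec()) {
  if (length(training_sets) == 0L) stop("empty union of training sets")
  x <- do.call(rbind, lapply(training_sets, `[[`, "x"))
  y <- unlist(lapply(training_sets, `[[`, "y"))
  nn_train(model, x, y, tspec)
}

#' Per-frame gesture probabilities from the ConvNet
#'
#' @param model A trained model.
#' @param x Image matrix, frames x pixels.
#' @return Matrix frames x G of softmax probabilities (columns named by
#'   gesture class); the row-wise argmax is the frame-level decision.
#' @export
predict_convnet <- function(model, x) nn_predict(model, x)

#' Save / load a model checkpoint (HDF5)
#'
#' Serialises every layer's parameters and batch-norm statistics to an
#' HDF5 container.
#' @param model A model.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_model_h5 <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    grp <- sprintf("layer_%03d", i)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(ly$type, path, file.path(grp, "type"))
    for (nm in setdiff(names(ly), c("type", "src")))
      rhdf5::h5write(ly[[nm]], path, file.path(grp, nm))
  }
  if (!is.null(model$classes))
    rhdf5::h5write(model$classes, path, "classes")
  rhdf5::h5write(model$history, path, "history")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_model_h5
#' @param template A freshly built model of the same architecture whose
#'   parameters will be overwritten from the checkpoint.
#' @export
load_model_h5 <- function(path, template) {
  model <- template
  for (i in seq_along(model$layers)) {
    grp <- sprintf("layer_%03d", i)
    stored <- rhdf5::h5read(path, grp)
    if (!identical(as.character(stored$type), model$layers[[i]]$type))
      stop("checkpoint layer types do not match the template")
    for (nm in setdiff(names(stored), "type")) {
      v <- stored[[nm]]
      if (is.null(dim(model$layers[[i]][[nm]]))) v <- as.vector(v)
      model$layers[[i]][[nm]] <- v
    }
  }
  root <- rhdf5::h5ls(path, recursive = FALSE)$name
  if ("classes" %in% root)
    model$classes <- as.vector(rhdf5::h5read(path, "classes"))
  model$history <- as.vector(rhdf5::h5read(path, "history"))
  rhdf5::h5closeAll()
  model
}
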