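#' Extract the 775-dimensional feature vector of one image
#'
#' Runs the full feature pipeline on a single image: optional
#' preprocessing (crop + background unification), HSI transform, the
#' three-channel Gabor texture histogram (768 values) and the seven Hu
#' invariant moments of the grayscale crop, concatenated texture-first.
#'
#' @param img `H x W x 3` RGB array in `[0, 255]`.
#' @param cfg a [berry_config()].
#' @return named numeric vector of length 775 (`f1..f768`, `h1..h7`).
#' @export
extract_features <- function(img, cfg = berry_config()) {
  assert_rgb(img)
  if (isTRUE(cfg$preprocess)) {
    pp <- preprocess_image(img, cfg)
    img <- pp$img
  }
  hsi <- rgb_to_hsi(img)
  tex <- gabor_features(hsi, bank = cfg$gabor_bank,
                        normalize = cfg$gabor_normalize,
                        fuse = cfg$gabor_fuse)
  gray <- to_grayscale(img, cfg$grayscale_coeffs)
  hu <- hu_moments(gray)
  c(tex, hu)
}

#' Extract features for a whole dataset
#'
#' Applies [extract_features()] to every image of a synthetic dataset (or
#' any list of RGB arrays) and assembles the labeled feature matrix.
#'
#' @param images list of RGB arrays, or a [generate_dataset()] result.
#' @param labels class label per image (taken from the manifest when
#'   `images` is a dataset).
#' @param ids sample identifier per image.
#' @param cfg a [berry_config()].
#' @return object of class `berry_dataset`: list with `X` (`N x 775`
#'   matrix), `y` (factor), `ids` (character).
#' @export
extract_dataset <- function(images, labels = NULL, ids = NULL,
                            cfg = berry_config()) {
  if (is.list(images) && !is.null(images$manifest)) {
    labels <- images$manifest$label
    ids <- images$manifest$id
    images <- images$images
  }
  n <- length(images)
  stopifnot(n == length(labels))
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  X <- matrix(NA_real_, n, 775L)
  for (k in seq_len(n)) {
    fv <- tryCatch(extract_features(images[[k]], cfg),
                   error = function(e)
                     stop("sample ", ids[k], ": ", conditionMessage(e),
                          call. = FALSE))
    X[k, ] <- fv
  }
  colnames(X) <- c(paste0("f", 1:768), paste0("h", 1:7))
  rownames(X) <- ids
  structure(list(X = X, y = factor(labels), ids = as.character(ids)),
            class = "berry_dataset")
}

#' Write/read a labeled feature table
#'
#' One row per image: `id`, `label`, `f1..f768`, `h1..h7`.
#'
#' @param ds a `berry_dataset`.
#' @param path CSV path.
#' @return `path` (write) or a `berry_dataset` (read).
#' @export
write_features <- function(ds, path) {
  df <- data.frame(id = ds$ids, label = as.character(ds$y),
                   ds$X, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, !(names(df) %in% c("id", "label")), drop = FALSE])
  rownames(X) <- df$id
  structure(list(X = X, y = factor(df$label), ids = df$id),
            class = "berry_dataset")
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into disjoint, exhaustive train and test sets,
#' drawing `round(train_fraction * n_c)` samples per class `c` without
#' replacement. Reproducible under `seed`.
#'
#' @param ds a `berry_dataset`.
#' @param train_fraction fraction of each class used for training, in
#'   `(0, 1)`.
#' @param seed integer seed for the split.
#' @return list with `train` and `test`, both `berry_dataset`s.
#' @export
split_dataset <- function(ds, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(as.integer(seed))
  idx_train <- integer(0)
  for (cl in levels(ds$y)) {
    members <- which(ds$y == cl)
    ntr <- round(train_fraction * length(members))
    if (ntr < 1L || ntr >= length(members))
      stop("class ", cl, ": stratified split impossible at fraction ",
           train_fraction, call. = FALSE)
    idx_train <- c(idx_train, sample(members, ntr))
  }
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_along(ds$y), idx_train)
  subset_ds <- function(i)
    structure(list(X = ds$X[i, , drop = FALSE], y = droplevels(ds$y[i]),
                   ids = ds$ids[i]), class = "berry_dataset")
  list(train = subset_ds(idx_train), test = subset_ds(idx_test))
}

#' Train a random-forest origin classifier
#'
#' Thin seeded wrapper around [randomForest::randomForest()]. `n_trees` is
#' the number of trees in the ensemble and `mtry` the number of candidate
#' features examined at each node split. Majority-vote ties between classes
#' are resolved by the forest implementation (uniformly at random among the
#' tied classes, using the seeded RNG, so results stay reproducible).
#'
#' @param train a `berry_dataset` with at least two classes.
#' @param n_trees number of trees (default 2000).
#' @param mtry candidate features per split (default 50; must be between 1
#'   and the number of feature columns).
#' @param seed integer seed for the forest's randomness.
#' @return a `randomForest` model object.
#' @export
train_rf <- function(train, n_trees = 2000L, mtry = 50L, seed = 1L) {
  if (nlevels(droplevels(train$y)) < 2L)
    stop("training set must contain at least 2 classes", call. = FALSE)
  if (mtry < 1L || mtry > ncol(train$X))
    stop("mtry must be in [1, ", ncol(train$X), "]", call. = FALSE)
  set.seed(as.integer(seed))
  randomForest::randomForest(x = train$X, y = droplevels(train$y),
                             ntree = as.integer(n_trees),
                             mtry = as.integer(mtry))
}

#' Predict origin labels for a feature matrix
#'
#' @param model a forest from [train_rf()].
#' @param X `N x 775` feature matrix (column count must match training).
#' @return factor of N predicted labels.
#' @export
predict_labels <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = if (length(X)) 1 else 0,
                                 dimnames = list(NULL, names(X)))
  if (nrow(X) == 0L) return(factor(character(0), levels = model$classes))
  if (ncol(X) != length(model$forest$xlevels))
    stop("feature length mismatch: model expects ",
         length(model$forest$xlevels), " columns", call. = FALSE)
  stats::predict(model, X)
}

#' Classification accuracy in percent
#'
#' `100 * (number correct) / (number of test samples)`.
#'
#' @param predicted,actual equal-length label vectors.
#' @return accuracy in percent.
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length", call. = FALSE)
  100 * sum(as.character(predicted) == as.character(actual)) /
    length(actual)
}

#' Repeated split-train-test evaluation
#'
#' Repeats the full protocol `repeats` times: a fresh stratified split
#' (split seed = master seed + repeat index), a freshly trained forest
#' (independently seeded), prediction on the held-out set. Aggregates the
#' per-repeat accuracies, a pooled predicted-by-actual confusion matrix,
#' and per-sample misclassification statistics (how often each sample fell
#' into a test set and how often it was then misclassified) — the basis for
#' flagging chronically confusable samples.
#'
#' @param ds a `berry_dataset`.
#' @param train_fraction per-class training fraction (default 0.8).
#' @param n_trees,mtry forest hyperparameters.
#' @param repeats number of repetitions (default 200).
#' @param seed master seed.
#' @return object of class `eval_report`: list with `mean_accuracy`,
#'   `per_repeat_accuracy`, `confusion` (predicted x actual counts),
#'   `per_sample` (data.frame id, label, times_drawn, times_wrong,
#'   error_rate), and the protocol settings.
#' @export
repeated_eval <- function(ds, train_fraction = 0.8, n_trees = 2000L,
                          mtry = 50L, repeats = 200L, seed = 1L) {
  stopifnot(repeats >= 1L)
  seed <- as.integer(seed)
  classes <- levels(ds$y)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(predicted = classes, actual = classes))
  drawn <- wrong <- setNames(integer(length(ds$ids)), ds$ids)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    sp <- split_dataset(ds, train_fraction, seed = seed + r)
    model <- train_rf(sp$train, n_trees = n_trees, mtry = mtry,
                      seed = seed + r + 500000L)
    pl <- predict_labels(model, sp$test$X)
    acc[r] <- accuracy(pl, sp$test$y)
    for (k in seq_along(pl))
      conf[as.character(pl[k]), as.character(sp$test$y[k])] <-
        conf[as.character(pl[k]), as.character(sp$test$y[k])] + 1L
    drawn[sp$test$ids] <- drawn[sp$test$ids] + 1L
    bad <- sp$test$ids[as.character(pl) != as.character(sp$test$y)]
    wrong[bad] <- wrong[bad] + 1L
  }
  per_sample <- data.frame(
    id = ds$ids, label = as.character(ds$y),
    times_drawn = as.integer(drawn[ds$ids]),
    times_wrong = as.integer(wrong[ds$ids]),
    error_rate = ifelse(drawn[ds$ids] > 0,
                        wrong[ds$ids] / drawn[ds$ids], 0),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(mean_accuracy = mean(acc), per_repeat_accuracy = acc,
                 confusion = conf, per_sample = per_sample,
                 settings = list(train_fraction = train_fraction,
                                 n_trees = n_trees, mtry = mtry,
                                 repeats = repeats, seed = seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Repeated evaluation: %d repeats, %.0f%%/%.0f%% split, nTree=%d, mtry=%d\n",
    s$repeats, 100 * s$train_fraction, 100 * (1 - s$train_fraction),
    s$n_trees, s$mtry))
  cat(sprintf("Mean accuracy: %.2f%% (sd %.2f)\n",
              x$mean_accuracy, sd(x$per_repeat_accuracy)))
  cat("Pooled confusion matrix (predicted x actual):\n")
  print(x$confusion)
  hi <- x$per_sample[x$per_sample$error_rate > 0.9 &
                       x$per_sample$times_drawn > 0, ]
  cat(sprintf("Samples with error rate > 90%%: %d\n", nrow(hi)))
  invisible(x)
}

#' Mean accuracy as a function of training-set size
#'
#' Runs [repeated_eval()] at each training fraction and tabulates the mean
#' accuracies, showing how quickly the classifier saturates as labeled
#' data grows.
#'
#' @param ds a `berry_dataset`.
#' @param fractions training fractions in `(0, 1)`
#'   (default `seq(0.1, 0.9, 0.1)`).
#' @param n_trees,mtry,repeats,seed as in [repeated_eval()].
#' @return data.frame with `train_fraction`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
proportion_sweep <- function(ds, fractions = seq(0.1, 0.9, by = 0.1),
                             n_trees = 2000L, mtry = 50L, repeats = 200L,
                             seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  rows <- lapply(seq_along(fractions), function(j) {
    rep <- repeated_eval(ds, train_fraction = fractions[j],
                         n_trees = n_trees, mtry = mtry,
                         repeats = repeats, seed = seed + 1000L * (j - 1L))
    data.frame(train_fraction = fractions[j],
               mean_accuracy = rep$mean_accuracy,
               sd_accuracy = sd(rep$per_repeat_accuracy))
  })
  do.call(rbind, rows)
}

#' Hyperparameter grid evaluation
#'
#' Evaluates each `(n_trees, mtry)` combination under the repeated 8:2
#' protocol and reports the mean accuracy per row plus the best row (ties
#' broken toward the smaller `n_trees`, then smaller `mtry`).
#'
#' @param ds a `berry_dataset`.
#' @param grid data.frame with columns `n_trees` and `mtry`.
#' @param train_fraction,repeats,seed protocol settings.
#' @return data.frame `n_trees, mtry, mean_accuracy` with attribute
#'   `"best"` holding the winning row index.
#' @export
hyperparameter_grid <- function(ds,
                                grid = data.frame(
                                  n_trees = c(1000, 2000, 3000, 2000, 2000),
                                  mtry = c(50, 50, 50, 40, 60)),
                                train_fraction = 0.8, repeats = 10L,
                                seed = 1L) {
  stopifnot(nrow(grid) >= 1L, all(c("n_trees", "mtry") %in% names(grid)))
  if (any(grid$mtry > ncol(ds$X)))
    stop("mtry exceeds the number of features (", ncol(ds$X), ")",
         call. = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(j) {
    repeated_eval(ds, train_fraction = train_fraction,
                  n_trees = grid$n_trees[j], mtry = grid$mtry[j],
                  repeats = repeats, seed = seed)$mean_accuracy
  }, numeric(1))
  out <- data.frame(n_trees = grid$n_trees, mtry = grid$mtry,
                    mean_accuracy = acc)
  ord <- order(-out$mean_accuracy, out$n_trees, out$mtry)
  attr(out, "best") <- ord[1]
  out
}
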