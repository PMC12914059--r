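# Image-based and feature-based classification: a compact residual network
# trained natively on pooled crop pixels, a linear-discriminant baseline with
# the same metric interface, stratified splits/folds, and sample-composition
# estimation.

#' Training configuration
#'
#' @param split Train fraction of the stratified train/test split.
#' @param epochs Training epochs (default 30).
#' @param augment_translation,augment_reflection Augmentation flags.
#' @param folds Number of stratified cross-validation folds (>= 2).
#' @param seed Integer seed controlling splits, folds, initialization and
#'   augmentation.
#' @param hidden Width of the residual blocks.
#' @param pool_side Crops are mean-pooled to `pool_side x pool_side` before
#'   entering the network.
#' @param learning_rate,batch_size Optimizer settings.
#' @return Object of class `train_config`.
#' @export
train_config <- function(split = 0.8, epochs = 30, augment_translation = TRUE,
                         augment_reflection = TRUE, folds = 5, seed = 1L,
                         hidden = 64, pool_side = 32, learning_rate = 1e-3,
                         batch_size = 32) {
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(split = split, epochs = as.integer(epochs),
                 augment_translation = augment_translation,
                 augment_reflection = augment_reflection,
                 folds = as.integer(folds), seed = as.integer(seed),
                 hidden = as.integer(hidden), pool_side = as.integer(pool_side),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size)),
            class = "train_config")
}

#' Build classifier input crops
#'
#' One-channel crops (attenuation only) for the viability/activation task, or
#' four-channel crops `[attenuation, phasor g, phasor s, beta]` for subtyping
#' when dynamic maps are supplied. All channels are zero outside the cell mask.
#'
#' @param frame Background-corrected frame.
#' @param mask Integer label mask.
#' @param maps Optional [dynamic_maps()] for the same field; required for
#'   4-channel crops.
#' @param cell_ids Labels to crop (default: all).
#' @param side Crop side length.
#' @return Named list of crops (`side x side` matrices or
#'   `side x side x 4` arrays), names = cell ids.
#' @export
build_crops <- function(frame, mask, maps = NULL, cell_ids = NULL, side = 128) {
  if (is.null(cell_ids)) cell_ids <- sort(unique(mask[mask > 0]))
  out <- lapply(cell_ids, function(k) {
    att <- crop_and_pad(frame, mask, k, side = side)
    if (is.null(maps)) return(att)
    chans <- lapply(list(maps$g, maps$s, maps$beta), function(m) {
      m2 <- m; m2[!is.finite(m2)] <- 0
      crop_and_pad(m2, mask, k, side = side)
    })
    arr <- array(0, dim = c(side, side, 4))
    arr[, , 1] <- att
    for (i in 1:3) arr[, , i + 1] <- chans[[i]]
    attr(arr, "cell_id") <- k
    arr
  })
  names(out) <- cell_ids
  out
}

# Mean-pool a matrix to out_side x out_side (zero-padding to a multiple).
.pool <- function(m, out_side) {
  s <- nrow(m)
  f <- ceiling(s / out_side)
  target <- f * out_side
  if (target != s) {
    p <- matrix(0, target, target)
    p[seq_len(s), seq_len(s)] <- m
    m <- p
  }
  # block mean via row/col group sums
  rg <- rep(seq_len(out_side), each = f)
  t(rowsum(t(rowsum(m, rg)), rg)) / f^2
}

# Crop list -> n x d matrix of pooled, flattened pixels (channels concatenated).
.crops_to_matrix <- function(crops, pool_side) {
  rows <- lapply(crops, function(cr) {
    if (length(dim(cr)) == 3) {
      unlist(lapply(seq_len(dim(cr)[3]),
                    function(c) as.vector(.pool(cr[, , c], pool_side))))
    } else as.vector(.pool(cr, pool_side))
  })
  do.call(rbind, rows)
}

# Integer shift with zero fill, and reflections, applied to a pooled square
# channel image (d = side^2 per channel).
.augment_row <- function(x, side, n_chan, dr, dc, flip_h, flip_v) {
  out <- numeric(length(x))
  for (c in seq_len(n_chan)) {
    m <- matrix(x[((c - 1) * side^2 + 1):(c * side^2)], side, side)
    if (flip_h) m <- m[, rev(seq_len(side))]
    if (flip_v) m <- m[rev(seq_len(side)), ]
    if (dr != 0 || dc != 0) {
      sh <- matrix(0, side, side)
      src_r <- seq_len(side) - dr; src_c <- seq_len(side) - dc
      ok_r <- src_r >= 1 & src_r <= side; ok_c <- src_c >= 1 & src_c <= side
      sh[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
      m <- sh
    }
    out[((c - 1) * side^2 + 1):(c * side^2)] <- as.vector(m)
  }
  out
}

#' Stratified train/test split
#'
#' @param labels Factor or character labels.
#' @param split Train fraction.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, split = 0.8, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(split * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("class '", cl, "' would be absent from a split (n = ",
           length(idx), ")")
    train <- c(train, sample(idx, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

#' Stratified fold assignment
#'
#' @inheritParams stratified_split
#' @param folds Number of folds.
#' @return Integer vector of fold ids (1..folds), one per label.
#' @export
stratified_folds <- function(labels, folds = 5, seed = 1L) {
  labels <- as.factor(labels)
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < folds)
      stop("class '", cl, "' has fewer examples than folds")
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Confusion matrix and summary metrics
#'
#' Rows are true classes, columns predicted. For two classes, sensitivity and
#' specificity are reported with the first factor level as the positive class.
#'
#' @param truth,pred Label vectors of equal length.
#' @return List with `confusion`, `accuracy`, `per_class` (precision/recall),
#'   and for two classes `sensitivity` and `specificity`.
#' @export
classification_metrics <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  cm <- table(truth = truth, pred = pred)
  acc <- sum(diag(cm)) / sum(cm)
  per_class <- data.frame(
    class = levels(truth),
    precision = diag(cm) / pmax(colSums(cm), 1),
    recall = diag(cm) / pmax(rowSums(cm), 1), row.names = NULL)
  out <- list(confusion = cm, accuracy = acc, per_class = per_class)
  if (nlevels(truth) == 2) {
    pos <- levels(truth)[1]
    out$sensitivity <- cm[pos, pos] / sum(cm[pos, ])
    neg <- levels(truth)[2]
    out$specificity <- cm[neg, neg] / sum(cm[neg, ])
  }
  out
}

# ---- compact residual network -------------------------------------------

.relu <- function(x) pmax(x, 0)

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.init_net <- function(d, h, k, seed) {
  set.seed(seed)
  g <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W0 = g(d, h), b0 = numeric(h),
       W1 = g(h, h), b1 = numeric(h),
       W2 = g(h, h), b2 = numeric(h),
       W3 = g(h, k), b3 = numeric(k))
}

# Forward pass; returns activations needed for backprop.
.forward <- function(par, X) {
  a0 <- X %*% par$W0; a0 <- sweep(a0, 2, par$b0, `+`); z0 <- .relu(a0)
  a1 <- z0 %*% par$W1; a1 <- sweep(a1, 2, par$b1, `+`); z1 <- z0 + .relu(a1)
  a2 <- z1 %*% par$W2; a2 <- sweep(a2, 2, par$b2, `+`); z2 <- z1 + .relu(a2)
  logits <- sweep(z2 %*% par$W3, 2, par$b3, `+`)
  list(a0 = a0, z0 = z0, a1 = a1, z1 = z1, a2 = a2, z2 = z2, logits = logits)
}

.backward <- function(par, X, fw, Y) {
  n <- nrow(X)
  P <- .softmax(fw$logits)
  dL <- (P - Y) / n                       # d loss / d logits
  gr <- list()
  gr$W3 <- crossprod(fw$z2, dL); gr$b3 <- colSums(dL)
  dz2 <- dL %*% t(par$W3)
  da2 <- dz2 * (fw$a2 > 0)
  gr$W2 <- crossprod(fw$z1, da2); gr$b2 <- colSums(da2)
  dz1 <- dz2 + da2 %*% t(par$W2)          # skip connection
  da1 <- dz1 * (fw$a1 > 0)
  gr$W1 <- crossprod(fw$z0, da1); gr$b1 <- colSums(da1)
  dz0 <- dz1 + da1 %*% t(par$W1)
  da0 <- dz0 * (fw$a0 > 0)
  gr$W0 <- crossprod(X, da0); gr$b0 <- colSums(da0)
  gr
}

#' Train the compact residual image classifier
#'
#' Crops are mean-pooled to `pool_side x pool_side` per channel, standardized
#' with training-set statistics, and fed to a small fully-connected network
#' with two residual blocks, trained with Adam on the cross-entropy loss.
#' Augmentation (random translations up to +/- 2 pooled pixels, i.e. ~8 raw
#' pixels at the default pooling, and horizontal/vertical reflection) is
#' resampled every epoch. A stratified 80/20 split is drawn from the config
#' seed; metrics are reported on the held-out part.
#'
#' @param crops List of crops from [build_crops()].
#' @param labels One label per crop.
#' @param config A [train_config()].
#' @return List of class `uv_resnet_fit`: `model` (weights, scaler, classes,
#'   pooling), `split`, `confusion`, `accuracy`, `per_class`, and for two
#'   classes sensitivity/specificity.
#' @export
train_cnn <- function(crops, labels, config = train_config()) {
  labels <- as.factor(labels)
  if (length(crops) != length(labels)) stop("crops and labels lengths differ")
  sp <- stratified_split(labels, config$split, config$seed)
  X <- .crops_to_matrix(crops, config$pool_side)
  model <- .fit_resnet(X[sp$train, , drop = FALSE], labels[sp$train], config,
                       n_chan = length(X[1, ]) %/% config$pool_side^2)
  pred <- .predict_resnet(model, X[sp$test, , drop = FALSE])
  met <- classification_metrics(labels[sp$test], pred)
  structure(c(list(model = model, split = sp), met), class = "uv_resnet_fit")
}

.fit_resnet <- function(X, labels, config, n_chan) {
  labels <- droplevels(as.factor(labels))
  classes <- levels(labels)
  mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  n <- nrow(Xs); d <- ncol(Xs); k <- length(classes)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), as.integer(labels))] <- 1
  par <- .init_net(d, config$hidden, k, config$seed)
  mstate <- lapply(par, function(p) p * 0)
  vstate <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  step <- 0
  side <- config$pool_side
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    Xa <- Xs
    if (config$augment_translation || config$augment_reflection) {
      for (i in seq_len(n)) {
        dr <- dc <- 0L; fh <- fv <- FALSE
        if (config$augment_translation) {
          dr <- sample(-2:2, 1); dc <- sample(-2:2, 1)
        }
        if (config$augment_reflection) {
          fh <- runif(1) < 0.5; fv <- runif(1) < 0.5
        }
        if (dr != 0 || dc != 0 || fh || fv)
          Xa[i, ] <- .augment_row(Xs[i, ], side, n_chan, dr, dc, fh, fv)
      }
    }
    ord <- sample(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      fw <- .forward(par, Xa[idx, , drop = FALSE])
      gr <- .backward(par, Xa[idx, , drop = FALSE], fw, Y[idx, , drop = FALSE])
      step <- step + 1
      for (nm in names(par)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gr[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gr[[nm]]^2
        mh <- mstate[[nm]] / (1 - b1^step)
        vh <- vstate[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
  list(par = par, mu = mu, sigma = sg, classes = classes,
       pool_side = side, n_chan = n_chan)
}

.predict_resnet <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sigma, `/`)
  fw <- .forward(model$par, Xs)
  factor(model$classes[max.col(fw$logits)], levels = model$classes)
}

#' Predict classes for new crops with a trained residual network
#'
#' @param object A `uv_resnet_fit` from [train_cnn()].
#' @param crops List of crops.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.uv_resnet_fit <- function(object, crops, ...) {
  X <- .crops_to_matrix(crops, object$model$pool_side)
  .predict_resnet(object$model, X)
}

# ---- linear-discriminant baseline ----------------------------------------

# Columns usable for modeling: numeric, finite, non-constant.
.model_columns <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  keep <- num & !(names(table) %in% c("cell", "valid", "sample"))
  nm <- names(table)[keep]
  nm[vapply(nm, function(n) {
    v <- table[[n]]
    all(is.finite(v)) && sd(v) > 0
  }, logical(1))]
}

#' Feature-based linear-discriminant baseline classifier
#'
#' Standardizes the usable numeric features and fits a linear discriminant.
#' If the within-class covariance is singular, a ridge-regularized
#' discriminant (pooled covariance + lambda I) is fitted instead, with a
#' warning. Serves as the deterministic counterpart to [train_cnn()] with the
#' same metric interface.
#'
#' @param features Data frame of per-cell features.
#' @param labels Class label per row.
#' @param ridge Ridge coefficient used by the fallback, as a fraction of the
#'   mean covariance diagonal.
#' @return Object of class `uv_baseline` with `columns`, `center`, `scale`,
#'   the fitted discriminant, and `classes`.
#' @export
baseline_classifier <- function(features, labels, ridge = 1e-3) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  cols <- .model_columns(features)
  if (!length(cols)) stop("no usable numeric feature columns")
  X <- as.matrix(features[, cols, drop = FALSE])
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  fit <- tryCatch(
    suppressWarnings(MASS::lda(Xs, grouping = labels)),
    error = function(e) NULL)
  kind <- "lda"
  if (is.null(fit)) {
    warning("singular within-class covariance; using ridge discriminant")
    kind <- "ridge"
    means <- t(vapply(levels(labels),
                      function(cl) colMeans(Xs[labels == cl, , drop = FALSE]),
                      numeric(ncol(Xs))))
    resid <- Xs - means[as.integer(labels), , drop = FALSE]
    S <- crossprod(resid) / (nrow(Xs) - nlevels(labels))
    lam <- ridge * mean(diag(S))
    Sinv <- solve(S + diag(lam, ncol(S)))
    priors <- as.numeric(table(labels)) / length(labels)
    fit <- list(means = means, Sinv = Sinv, log_priors = log(priors))
  }
  structure(list(kind = kind, fit = fit, columns = cols, center = ctr,
                 scale = scl, classes = levels(labels)),
            class = "uv_baseline")
}

#' @export
predict.uv_baseline <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$columns, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  if (object$kind == "lda") {
    factor(as.character(predict(object$fit, Xs)$class),
           levels = object$classes)
  } else {
    f <- object$fit
    # linear discriminant score per class: x' Sinv mu - mu' Sinv mu / 2 + log prior
    sc <- Xs %*% f$Sinv %*% t(f$means)
    sc <- sweep(sc, 2, 0.5 * rowSums((f$means %*% f$Sinv) * f$means))
    sc <- sweep(sc, 2, f$log_priors, `+`)
    factor(object$classes[max.col(sc)], levels = object$classes)
  }
}

#' Stratified k-fold cross-validation
#'
#' Pools held-out predictions over stratified folds and reports the pooled
#' confusion matrix, accuracy and (for two classes) sensitivity/specificity,
#' plus per-fold accuracies. `method = "baseline"` expects a feature table;
#' `method = "cnn"` expects a crop list.
#'
#' @param x Feature data frame or crop list.
#' @param labels Class label per row/crop.
#' @param config A [train_config()] (supplies `folds` and `seed`).
#' @param method `"baseline"` or `"cnn"`.
#' @return List with pooled metrics, `fold_accuracy` and `folds`.
#' @export
cross_validate <- function(x, labels, config = train_config(),
                           method = c("baseline", "cnn")) {
  method <- match.arg(method)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n != length(labels)) stop("x and labels lengths differ")
  fold_of <- stratified_folds(labels, config$folds, config$seed)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  fold_acc <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    if (method == "baseline") {
      mdl <- baseline_classifier(x[tr, , drop = FALSE], labels[tr])
      p <- predict(mdl, x[te, , drop = FALSE])
    } else {
      cfg <- config; cfg$seed <- config$seed + f
      mdl <- .fit_resnet(.crops_to_matrix(x[tr], config$pool_side), labels[tr],
                         cfg, n_chan = ncol(.crops_to_matrix(x[tr][1],
                                            config$pool_side)) %/%
                           config$pool_side^2)
      p <- .predict_resnet(mdl, .crops_to_matrix(x[te], config$pool_side))
    }
    pred[te] <- p
    fold_acc[f] <- mean(p == labels[te])
  }
  met <- classification_metrics(labels, pred)
  c(met, list(fold_accuracy = fold_acc, folds = fold_of))
}

#' Sample composition from per-cell class predictions
#'
#' Viability is the percentage of cells not predicted dead; activation is the
#' percentage of activated cells among the predicted-live
#' (activated + quiescent) cells.
#'
#' @param model A fitted classifier (`uv_baseline` or `uv_resnet_fit`).
#' @param cells Feature data frame (baseline) or crop list (network) for the
#'   cells of one sample.
#' @return List with `viability_pct`, `activation_pct` and the predicted
#'   class table.
#' @export
predict_composition <- function(model, cells) {
  n <- if (is.data.frame(cells)) nrow(cells) else length(cells)
  if (n == 0) stop("empty sample")
  cl <- as.character(predict(model, cells))
  n_dead <- sum(cl == "dead")
  live <- cl[cl != "dead"]
  n_act <- sum(live == "activated")
  n_qui <- sum(live == "quiescent")
  list(viability_pct = 100 * (1 - n_dead / length(cl)),
       activation_pct = if (n_act + n_qui == 0) NA_real_ else
         100 * n_act / (n_act + n_qui),
       classes = table(cl))
}

#' Linear agreement between predicted and reference percentages
#'
#' Ordinary least squares of `predicted` on `reference`.
#'
#' @param predicted,reference Paired numeric vectors, length >= 3.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
agreement_fit <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) < 3)
    stop("need at least 3 paired samples")
  if (sd(reference) == 0) stop("reference has zero variance")
  fit <- lm(predicted ~ reference)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}
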