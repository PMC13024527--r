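#' Training configuration
#'
#' Defaults follow the training protocol of the method: Adam with first-moment
#' coefficient 0.9 and weight decay 1e-4, batch size 32, an initial learning
#' rate of 0.005 cosine-annealed to 1e-5 over 100 epochs, early stopping
#' after 10 epochs without validation improvement, and an 8:2 train/test
#' split with 10% of the training images held out for validation.
#'
#' @param epochs total epoch budget.
#' @param batch_size images per optimization step.
#' @param lr_init,lr_final initial / final learning rate of the cosine
#'   schedule (`lr_final < lr_init`).
#' @param beta1,beta2 Adam moment coefficients.
#' @param weight_decay L2 penalty applied to convolution and linear weights.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param val_metric `"accuracy"` (default) or `"loss"`.
#' @param shuffle_seed seed for the per-epoch batch order.
#' @return configuration list.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr_init = 0.005,
                         lr_final = 1e-5, beta1 = 0.9, beta2 = 0.999,
                         weight_decay = 1e-4, patience = 10L,
                         val_metric = c("accuracy", "loss"),
                         shuffle_seed = 1L) {
  if (lr_final >= lr_init) stop("train_config: lr_final must be < lr_init")
  if (patience < 1L) stop("train_config: patience must be >= 1")
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_init = lr_init, lr_final = lr_final, beta1 = beta1, beta2 = beta2,
       weight_decay = weight_decay, patience = as.integer(patience),
       val_metric = match.arg(val_metric),
       shuffle_seed = as.integer(shuffle_seed))
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_final + (lr_init - lr_final) * (1 + cos(pi * e / epochs)) / 2`,
#' evaluated per epoch: the rate starts at `lr_init`, passes the midpoint of
#' the two rates halfway through, and ends at `lr_final`.
#'
#' @param epoch epoch index in `[0, epochs]`.
#' @param epochs total epochs of the schedule.
#' @param lr_init,lr_final schedule endpoints.
#' @return learning rate at `epoch`.
#' @export
cosine_lr <- function(epoch, epochs = 100L, lr_init = 0.005, lr_final = 1e-5) {
  if (any(epoch < 0 | epoch > epochs))
    stop("cosine_lr: epoch out of [0, epochs]")
  lr_final + 0.5 * (lr_init - lr_final) * (1 + cos(pi * epoch / epochs))
}

# Adam with classic (non-decoupled) weight decay on weight matrices.
adam_new <- function(model, cfg) {
  layers <- collect_layers(model)
  states <- lapply(layers, function(l)
    list(m = zero_like(l$par), v = zero_like(l$par)))
  list(layers = layers, states = states, t = 0L,
       beta1 = cfg$beta1, beta2 = cfg$beta2,
       weight_decay = cfg$weight_decay, eps = 1e-8)
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    st <- opt$states[[i]]
    for (nm in names(l$par)) {
      g <- l$gr[[nm]]
      if (is.null(g)) next
      if (opt$weight_decay > 0 && nm %in% c("W", "Wt"))
        g <- g + opt$weight_decay * l$par[[nm]]
      st$m[[nm]] <- opt$beta1 * st$m[[nm]] + (1 - opt$beta1) * g
      st$v[[nm]] <- opt$beta2 * st$v[[nm]] + (1 - opt$beta2) * g * g
      l$par[[nm]] <- l$par[[nm]] -
        lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + opt$eps)
    }
    opt$states[[i]] <- st
  }
  opt
}

#' Fit a model on a labeled image set
#'
#' Full training loop: per-epoch cosine learning rate, Adam updates, masked
#' composite loss (cross-entropy plus lambda times Smooth-L1 box loss on
#' lesion images), validation after every epoch, early stopping on the
#' validation metric, and retention of the best-validation parameters (which
#' are restored into the returned model). Fully reproducible given the seed.
#'
#' Passing a warm-started model implements secondary fine-tuning: the same
#' loop simply resumes from the given weights.
#'
#' @param model model from [build_variant()].
#' @param train data list with `x` `(3,H,W,N)`, `labels` (1-based), `bbox`
#'   (`4 x N`), `mask` (logical lesion indicator).
#' @param val validation data list of the same shape.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model`, `history` (per-epoch data frame with train
#'   loss components, validation metric and learning rate), `best_epoch`,
#'   `best_metric`.
#' @export
fit <- function(model, train, val, cfg = train_config(), verbose = FALSE) {
  n <- length(train$labels)
  if (n == 0L) stop("fit: empty training set")
  if (length(unique(train$labels)) < 2L)
    stop("fit: training data must contain at least two classes")
  weights <- switch(as.character(model$config$loss$class_weights),
    auto = inverse_frequency_weights(train$labels, model$config$K),
    off = NULL,
    as.numeric(model$config$loss$class_weights))
  opt <- adam_new(model, cfg)
  best <- list(metric = -Inf, epoch = 0L, state = NULL)
  hist <- list()
  set.seed(cfg$shuffle_seed)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg$epochs, cfg$lr_init, cfg$lr_final)
    ord <- sample.int(n)
    tot <- cls <- reg <- 0
    nb <- 0L
    i <- 1L
    while (i <= n) {
      j <- min(i + cfg$batch_size - 1L, n)
      idx <- ord[i:j]
      lb <- model_train_step(model,
                             train$x[, , , idx, drop = FALSE],
                             train$labels[idx],
                             train$bbox[, idx, drop = FALSE],
                             train$mask[idx], weights)
      opt <- adam_step(opt, lr)
      tot <- tot + lb$total; cls <- cls + lb$classification
      reg <- reg + lb$regression; nb <- nb + 1L
      i <- j + 1L
    }
    ev <- evaluate_model(model, val$x, val$labels)
    vmetric <- if (cfg$val_metric == "accuracy") ev$accuracy else -ev$nll
    hist[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = tot / nb, train_cls = cls / nb,
      train_reg = reg / nb, val_accuracy = ev$accuracy, val_metric = vmetric)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  loss %.4f  val acc %.3f",
                      epoch, lr, tot / nb, ev$accuracy))
    if (vmetric > best$metric) {
      best <- list(metric = vmetric, epoch = epoch, state = get_state(model))
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  if (!is.null(best$state)) set_state(model, best$state)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best$epoch, best_metric = best$metric)
}

#' Train/validation/test split
#'
#' Splits image indices 8:2 into training and test sets, then holds out a
#' fraction of the training set for validation. When a grouping vector is
#' supplied (e.g. patient ids), whole groups are assigned to one side only.
#'
#' @param n number of images, or a manifest data frame with `n` rows.
#' @param train_frac fraction assigned to training (before validation
#'   hold-out).
#' @param val_frac fraction of the training images held out for validation.
#' @param seed RNG seed for the assignment.
#' @param groups optional grouping vector of length `n`.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, train_frac = 0.8, val_frac = 0.1, seed = 1L,
                          groups = NULL) {
  if (is.data.frame(n)) {
    if (is.null(groups) && "group" %in% names(n)) groups <- n$group
    n <- nrow(n)
  }
  set.seed(seed)
  if (is.null(groups)) {
    ord <- sample.int(n)
    ntr <- round(train_frac * n)
    tr <- ord[seq_len(ntr)]
    te <- ord[setdiff(seq_len(n), seq_len(ntr))]
  } else {
    g <- unique(groups)
    gs <- sample(g)
    ngr <- round(train_frac * length(gs))
    tr <- which(groups %in% gs[seq_len(ngr)])
    te <- which(!groups %in% gs[seq_len(ngr)])
    tr <- sample(tr)
  }
  nval <- round(val_frac * length(tr))
  val <- tr[seq_len(nval)]
  tr <- tr[setdiff(seq_along(tr), seq_len(nval))]
  list(train = sort(tr), val = sort(val), test = sort(te))
}

#' Evaluate a model on labeled images
#'
#' Inference-mode evaluation: overall accuracy, the K x K confusion matrix,
#' mean negative log-likelihood and the per-image lesion score
#' `1 - P(normal)` used for binary (lesion vs normal) ROC analysis.
#'
#' @param model model object.
#' @param x image tensor `(3, H, W, N)`.
#' @param labels true class labels (1-based, class 1 = normal).
#' @return list with `accuracy`, `confusion`, `nll`, `lesion_score`,
#'   `pred`, `probs`.
#' @export
evaluate_model <- function(model, x, labels) {
  out <- model_forward(model, x)
  pred <- apply(out$probs, 2L, which.max)
  K <- model$config$K
  cm <- confusion(labels, pred, K, model$config$class_names)
  p <- pmax(out$probs[cbind(labels, seq_along(labels))], 1e-12)
  list(accuracy = mean(pred == labels), confusion = cm, nll = mean(-log(p)),
       lesion_score = 1 - out$probs[1L, ], pred = pred, probs = out$probs,
       bbox = out$bbox)
}

#' Repeat training over several seeds
#'
#' Re-initializes, trains and evaluates a variant once per seed, reporting
#' per-seed test accuracy and the mean and standard deviation across seeds.
#'
#' @param variant variant id.
#' @param config model configuration.
#' @param train,val,test data lists as in [fit()].
#' @param cfg training configuration.
#' @param seeds integer seeds, one run each.
#' @return list with `runs` (data frame: seed, test accuracy, best epoch)
#'   and `summary` (mean, sd).
#' @export
repeat_runs <- function(variant, config, train, val, test, cfg, seeds) {
  rows <- lapply(seeds, function(s) {
    set.seed(s)
    model <- build_variant(variant, config)
    cfg$shuffle_seed <- s + 1L
    res <- fit(model, train, val, cfg)
    ev <- evaluate_model(res$model, test$x, test$labels)
    data.frame(seed = s, test_accuracy = ev$accuracy,
               best_epoch = res$best_epoch)
  })
  runs <- do.call(rbind, rows)
  list(runs = runs,
       summary = c(mean = mean(runs$test_accuracy),
                   sd = stats::sd(runs$test_accuracy)))
}
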