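#' A labeled configuration: snapshot plus reference ion forces
#'
#' Reference forces are stored for the mobile, ML-visible subset (the ions);
#' rows for all other particles are NA.
#'
#' @param sys a [particle_system] snapshot.
#' @param forces N x 3 matrix of reference forces (kJ/mol/nm); rows for
#'   particles outside the mobile & ML-visible subset are ignored/NA.
#' @param index configuration index.
#' @param meta metadata list (e.g. concentration, source tag).
#' @return Object of class `labeled_configuration`.
#' @export
labeled_configuration <- function(sys, forces, index = NA_integer_,
                                  meta = list()) {
  stopifnot(inherits(sys, "particle_system"))
  forces <- as.matrix(forces)
  stopifnot(nrow(forces) == n_particles(sys), ncol(forces) == 3)
  tgt <- sys$mobile & sys$ml_visible
  if (any(!is.finite(forces[tgt, ])))
    stop("non-finite reference forces on the mobile ML-visible subset")
  forces[!tgt, ] <- NA_real_
  structure(list(system = sys, forces = forces, index = index, meta = meta),
            class = "labeled_configuration")
}

#' Build a delta-learning dataset from labeled configurations
#'
#' Subtracts the physics prior's forces from the reference forces on the
#' mobile ML-visible subset: the correction potential is trained on the
#' residual (delta learning), evaluated at exactly the coordinates and
#' cutoffs MD will use.
#'
#' @param configs list of [labeled_configuration] objects.
#' @param params a [species_params] object for the prior.
#' @param prior_cfg a [prior_config].
#' @return Object of class `delta_dataset` (configurations with `delta`
#'   targets; no split yet).
#' @export
make_delta_dataset <- function(configs, params = default_species_params(),
                               prior_cfg = prior_config()) {
  stopifnot(length(configs) >= 1)
  items <- vector("list", length(configs))
  for (k in seq_along(configs)) {
    lc <- configs[[k]]
    stopifnot(inherits(lc, "labeled_configuration"))
    pr <- tryCatch(
      evaluate_prior(lc$system, params, prior_cfg),
      error = function(e) stop("prior evaluation failed on configuration ",
                               k, ": ", conditionMessage(e)))
    delta <- lc$forces - pr$forces
    tgt <- lc$system$mobile & lc$system$ml_visible
    delta[!tgt, ] <- 0
    items[[k]] <- list(system = lc$system, delta = delta, has_target = tgt,
                       meta = lc$meta)
  }
  structure(list(items = items, split = NULL,
                 params = params, prior_cfg = prior_cfg),
            class = "delta_dataset")
}

#' @export
print.delta_dataset <- function(x, ...) {
  cat(sprintf("<delta_dataset> %d configurations", length(x$items)))
  if (!is.null(x$split))
    cat(sprintf(" (%d train / %d val, seed %d)", length(x$split$train),
                length(x$split$val), x$split$seed))
  cat("\n")
  invisible(x)
}

#' Randomly split a delta dataset into training and validation parts
#'
#' @param dataset a `delta_dataset`.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed RNG seed; the partition is reproducible for a fixed seed.
#' @return The dataset with a `split` field (disjoint, exhaustive indices).
#' @export
split_dataset <- function(dataset, fraction = 0.8, seed = 1) {
  stopifnot(inherits(dataset, "delta_dataset"))
  n <- length(dataset$items)
  if (n < 2) stop("need at least 2 configurations to split")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  set.seed(seed)
  ntrain <- round(fraction * n)
  ntrain <- min(max(ntrain, 1), n - 1)
  train <- sort(sample.int(n, ntrain))
  dataset$split <- list(train = train, val = setdiff(seq_len(n), train),
                        fraction = fraction, seed = seed)
  dataset
}

#' Force-matching loss
#'
#' Mean (default) or sum of squared deviations between predicted and target
#' force components, over all configurations, ions and Cartesian directions.
#'
#' @param predicted,target numeric arrays of matching shape
#'   (kJ/mol/nm).
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return Scalar loss, (kJ/mol/nm)^2.
#' @export
force_matching_loss <- function(predicted, target,
                                reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target))
    stop("shape mismatch between predicted and target forces")
  ss <- sum((predicted - target)^2)
  if (reduction == "mean") ss / length(predicted) else ss
}

# C++-ready views of dataset items for a model vocabulary.
dataset_cpp_items <- function(dataset, model, idx) {
  lapply(dataset$items[idx], function(it) {
    tg <- it$delta
    tg[!it$has_target, ] <- 0
    list(pos = it$system$positions,
         chid = model_chid(model, it$system),
         mlvis = it$system$ml_visible,
         box = it$system$box,
         target = tg,
         has_target = it$has_target)
  })
}

# Loss (mean) of a model over dataset items (no gradient).
dataset_loss <- function(cppitems, model) {
  r <- cpp_fm_loss_grad(cppitems, model_cpp(model), FALSE)
  r$loss_sum / max(r$n_comp, 1)
}

#' Predicted correction forces on a dataset item
#'
#' @keywords internal
predict_delta_forces <- function(model, sys) model_forces(sys, model)

#' Train the correction potential by force matching
#'
#' Adam optimization of the force-matching loss over whole-configuration
#' mini-batches, with per-epoch train/validation loss curves, early stopping
#' on validation loss, and return of the best-validation parameters. Feature
#' standardization (per-feature RMS over the training set) is computed once
#' before optimization and stored in the model.
#'
#' @param model a [correction_model] (initial parameters).
#' @param data a `delta_dataset` with a split (see [split_dataset()]).
#' @param epochs maximum epochs (default 200).
#' @param lr Adam learning rate (default 0.02).
#' @param batch_size configurations per mini-batch (default 32).
#' @param beta1,beta2,adam_eps Adam moments (cited defaults).
#' @param weight_decay decoupled (AdamW-style) weight decay, default 1e-4;
#'   keeps weights of rarely-activated features near zero so the correction
#'   stays small outside the training distribution.
#' @param patience early-stopping patience in epochs (default 30).
#' @param seed seed controlling batch shuffling (default 1).
#' @param verbose print per-epoch losses every `verbose` epochs (0 = quiet).
#' @return list(`model` = best-validation model, `history` = data.frame with
#'   epoch, train and validation loss, `best_epoch`, `diverged`).
#' @export
train_model <- function(model, data, epochs = 200, lr = 0.02, batch_size = 32,
                        beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                        weight_decay = 1e-4, patience = 30, seed = 1,
                        verbose = 0) {
  stopifnot(inherits(model, "correction_model"), inherits(data, "delta_dataset"))
  if (is.null(data$split)) data <- split_dataset(data, seed = seed)
  tr_idx <- data$split$train
  if (length(tr_idx) < 1) stop("empty training partition")
  tr <- dataset_cpp_items(data, model, tr_idx)
  va <- dataset_cpp_items(data, model, data$split$val)
  # feature standardization from the training set
  M <- n_features(model$descriptor, length(model$species))
  dc <- desc_cpp(model$descriptor, length(model$species))
  ssum <- numeric(M); cnt <- 0
  for (it in tr[seq_len(min(length(tr), 200))]) {
    for (i in which(it$mlvis)) {
      d <- cpp_descriptor(it$pos, it$chid, it$mlvis, it$box, i - 1L, dc)
      ssum <- ssum + d^2; cnt <- cnt + 1
    }
  }
  scale <- sqrt(ssum / max(cnt, 1))
  # floor rarely-active features at 1% of the strongest channel: their
  # effective weights (w/scale) stay bounded, so the correction cannot build
  # large terms in regions the training distribution never visits (the prior
  # alone governs off-distribution geometry, as delta learning intends)
  if (max(scale) > 0) scale <- pmax(scale, 0.01 * max(scale))
  scale[scale < 1e-10] <- 1
  model$scale <- scale

  theta <- flatten_params(model)
  m <- numeric(length(theta)); v <- numeric(length(theta)); tstep <- 0
  val_loss <- function(mod) if (length(va)) dataset_loss(va, mod) else
    dataset_loss(tr, mod)
  hist_ep <- integer(0); hist_tr <- numeric(0); hist_va <- numeric(0)
  v0 <- val_loss(model)
  best <- list(theta = theta, val = v0, epoch = 0L)
  hist_ep <- 0L; hist_tr <- dataset_loss(tr, model); hist_va <- v0
  set.seed(seed)
  bad <- 0; diverged <- FALSE
  for (ep in seq_len(epochs)) {
    ord <- sample(length(tr))
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0; ep_n <- 0
    for (b in batches) {
      cur <- unflatten_params(model, theta)
      r <- cpp_fm_loss_grad(tr[b], model_cpp(cur), TRUE)
      if (!is.finite(r$loss_sum)) { diverged <- TRUE; break }
      g <- unlist(lapply(r$grads, function(h) {
        if (!is.null(h[["w"]])) h[["w"]] else c(as.numeric(h$W1), h$b1, h$w2)
      }), use.names = FALSE) / max(r$n_comp, 1)
      ep_loss <- ep_loss + r$loss_sum; ep_n <- ep_n + r$n_comp
      tstep <- tstep + 1
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^tstep)
      vhat <- v / (1 - beta2^tstep)
      theta <- theta - lr * (mhat / (sqrt(vhat) + adam_eps) +
                               weight_decay * theta)
    }
    if (diverged) {
      warning("training diverged (non-finite loss) at epoch ", ep,
              "; returning last finite best state")
      break
    }
    cur <- unflatten_params(model, theta)
    vl <- val_loss(cur)
    hist_ep <- c(hist_ep, ep)
    hist_tr <- c(hist_tr, ep_loss / max(ep_n, 1))
    hist_va <- c(hist_va, vl)
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %4d  train %.6g  val %.6g", ep,
                      ep_loss / max(ep_n, 1), vl))
    if (vl < best$val) { best <- list(theta = theta, val = vl, epoch = ep); bad <- 0 }
    else bad <- bad + 1
    if (bad >= patience) break
  }
  out <- unflatten_params(model, best$theta)
  out$meta$trained <- TRUE
  out$meta$best_epoch <- best$epoch
  list(model = out,
       history = data.frame(epoch = hist_ep, train = hist_tr, val = hist_va),
       best_epoch = best$epoch, best_val = best$val, diverged = diverged)
}

#' Force RMSE of a model (prior + correction) against a delta dataset
#'
#' Computes the root-mean-square residual between the correction forces and
#' the delta targets over the selected configurations; `model = NULL` gives
#' the prior-only baseline (the RMS of the delta targets themselves).
#'
#' @param data a `delta_dataset`.
#' @param model a [correction_model] or NULL.
#' @param idx configuration indices (default: validation split if present,
#'   else all).
#' @return RMSE in kJ/mol/nm.
#' @export
force_rmse <- function(data, model = NULL, idx = NULL) {
  stopifnot(inherits(data, "delta_dataset"))
  if (is.null(idx))
    idx <- if (!is.null(data$split)) data$split$val else
      seq_along(data$items)
  ss <- 0; n <- 0
  for (it in data$items[idx]) {
    tgt <- it$delta[it$has_target, , drop = FALSE]
    if (is.null(model)) res <- tgt
    else {
      f <- model_forces(it$system, model)
      res <- f[it$has_target, , drop = FALSE] - tgt
    }
    ss <- ss + sum(res^2); n <- n + length(res)
  }
  sqrt(ss / max(n, 1))
}
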