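#' 3D U-Net segmentation: model, training protocol, prediction, ensembling
#'
#' The network is a 3D U-Net variant operating on 2-channel (out-of-phase,
#' in-phase) single-leg patches: 3x3x3 kernels throughout, two convolutions
#' per resolution level, four at the deepest level, stride-2 3x3x3
#' down-sampling, nearest-neighbour x2 up-sampling followed by a 3x3x3
#' convolution, instance normalization + ReLU after every convolution, and a
#' softmax over n_muscles + 1 classes at the input resolution. Training uses
#' plain cross-entropy, Adam at 1e-4, batch size 1, two randomly positioned
#' axial slabs per image per epoch, a halve-on-plateau learning-rate schedule
#' (patience 25), and optional early stopping; the parameters with the best
#' validation loss are kept.
#'
#' @name segnet
NULL

#' Segmentation model specification
#'
#' @param depth number of resolution levels (encoder levels incl. deepest)
#' @param base_filters channels at the highest resolution
#' @param n_classes output classes (muscles + background)
#' @param in_channels input channels (2: out-of-phase, in-phase)
#' @param growth channel multiplier per level
#' @return object of class \code{seg_model_spec}
#' @export
seg_model_spec <- function(depth = 3, base_filters = 8, n_classes,
                           in_channels = 2, growth = 2) {
  stopifnot(depth >= 2, base_filters >= 1, n_classes >= 2,
            in_channels >= 1, growth >= 1)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 growth = as.integer(growth)),
            class = "seg_model_spec")
}

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: cross-entropy loss, Adam with
#' initial learning rate 1e-4 halved when the validation loss has not
#' improved for 25 consecutive epochs, batch size 1, and 2 patches sampled
#' from each training image per epoch.
#'
#' @param max_epochs hard epoch limit
#' @param lr0 initial learning rate
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate is halved
#' @param lr_factor multiplicative learning-rate reduction (0.5 = halving)
#' @param batch_size fixed at 1 (one patch per optimizer step)
#' @param patches_per_image random patches drawn from each training image in
#'   every epoch
#' @param patch_slices slab thickness; NULL clamps the reference 81 to the
#'   volume depth, \code{min(81, Z)}
#' @param early_stop_patience stop after this many epochs without validation
#'   improvement (NULL disables; 40 in the fine-tuning protocol)
#' @param val_patches_per_image patches per validation image used for the
#'   validation loss (sampled with a fixed seed, so the loss is comparable
#'   across epochs)
#' @param improve_tol minimal decrease of the validation loss that counts as
#'   an improvement
#' @param augment NULL or \code{\link{augment_params}} applied to training
#'   patches
#' @param seed seed for patch sampling and augmentation
#' @return object of class \code{train_config}
#' @export
train_config <- function(max_epochs, lr0 = 1e-4, plateau_patience = 25,
                         lr_factor = 0.5, batch_size = 1,
                         patches_per_image = 2, patch_slices = NULL,
                         early_stop_patience = NULL,
                         val_patches_per_image = 1, improve_tol = 1e-6,
                         augment = NULL, seed = 1) {
  stopifnot(max_epochs >= 0, lr0 > 0, plateau_patience >= 1,
            lr_factor > 0, lr_factor < 1, patches_per_image >= 1,
            val_patches_per_image >= 1, improve_tol >= 0)
  if (batch_size != 1) stop("the training protocol uses batch size 1")
  if (!is.null(augment) && !inherits(augment, "augment_params"))
    stop("augment must be NULL or augment_params()")
  structure(list(max_epochs = as.integer(max_epochs), lr0 = lr0,
                 plateau_patience = as.integer(plateau_patience),
                 lr_factor = lr_factor, batch_size = 1L,
                 patches_per_image = as.integer(patches_per_image),
                 patch_slices = patch_slices,
                 early_stop_patience = early_stop_patience,
                 val_patches_per_image = as.integer(val_patches_per_image),
                 improve_tol = improve_tol, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

# He-normal initial parameters for a model, deterministic under seed
init_params <- function(ptr, seed) {
  info <- unet_param_info(ptr)
  with_seed(seed, {
    p <- vector("list", length(info$name))
    names(p) <- info$name
    for (i in seq_along(info$name)) {
      sz <- info$size[i]
      p[[i]] <- switch(info$kind[i],
                       weight = rnorm(sz, 0, sqrt(2 / info$fan_in[i])),
                       bias = rep(0, sz),
                       scale = rep(1, sz),
                       shift = rep(0, sz))
    }
    p
  })
}

#' Build a Dixon muscle segmentation network
#'
#' @param spec \code{\link{seg_model_spec}}
#' @param seed seed for the (He-normal) weight initialization
#' @param label short name used in provenance records
#' @return object of class \code{dixon_unet}
#' @export
#' @examples
#' net <- dixon_unet(seg_model_spec(depth = 2, base_filters = 4, n_classes = 3),
#'                   seed = 1)
#' net
dixon_unet <- function(spec, seed = 1, label = "unet") {
  stopifnot(inherits(spec, "seg_model_spec"))
  ptr <- unet_create(spec$depth, spec$base_filters, spec$growth,
                     spec$in_channels, spec$n_classes)
  unet_set_params(ptr, init_params(ptr, seed))
  structure(list(ptr = ptr, spec = spec, seed = as.integer(seed),
                 label = label, trained = FALSE, history = NULL,
                 provenance = NULL),
            class = "dixon_unet")
}

#' @export
print.dixon_unet <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<dixon_unet '%s'> depth %d, base %d (growth %d), %d -> %d channels, %s parameters\n",
              x$label, s$depth, s$base_filters, s$growth, s$in_channels,
              s$n_classes, format(unet_n_params(x$ptr), big.mark = ",")))
  if (x$trained && !is.null(x$history))
    cat(sprintf("  trained %d epochs, best val loss %.5f\n",
                nrow(x$history), min(x$history$val_loss)))
  if (!is.null(x$provenance))
    cat("  fine-tuned from '", x$provenance$parent, "'\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#' @param model \code{dixon_unet}
#' @return parameter count
#' @export
n_params <- function(model) unet_n_params(model$ptr)

#' Extract / restore model weights
#' @param model \code{dixon_unet}
#' @return named list of numeric parameter vectors
#' @export
model_weights <- function(model) unet_get_params(model$ptr)

#' @rdname model_weights
#' @param weights list as returned by \code{model_weights}
#' @export
set_model_weights <- function(model, weights) {
  unet_set_params(model$ptr, weights)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture spec, weights, training history,
#' and provenance, so loading fully reconstructs the network.
#'
#' @param model \code{dixon_unet}
#' @param path file path (.rds)
#' @export
save_model <- function(model, path) {
  saveRDS(list(spec = model$spec, weights = model_weights(model),
               seed = model$seed, label = model$label,
               trained = model$trained, history = model$history,
               provenance = model$provenance), path)
  invisible(path)
}

#' @rdname save_model
#' @return \code{dixon_unet}
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  m <- dixon_unet(ck$spec, seed = ck$seed, label = ck$label)
  set_model_weights(m, ck$weights)
  m$trained <- ck$trained
  m$history <- ck$history
  m$provenance <- ck$provenance
  m
}

# fresh network carrying another model's weights (new optimizer state)
clone_model <- function(model, label = model$label) {
  m <- dixon_unet(model$spec, seed = model$seed, label = label)
  set_model_weights(m, model_weights(model))
  m$trained <- model$trained
  m$history <- model$history
  m
}

#' Subject-grouped cross-validation folds
#'
#' Subjects are shuffled under the seed and dealt round-robin to k folds;
#' every scan follows its subject, so no subject's data ever crosses folds.
#'
#' @param subjects vector of subject ids, or a data frame with columns
#'   \code{subject_id} and \code{scan_id} when subjects have several scans
#' @param k number of folds (2 <= k <= number of subjects)
#' @param seed shuffle seed
#' @return object of class \code{fold_split}: list with \code{folds} (subject
#'   ids per fold) and \code{scans} (scan ids per fold, when given)
#' @export
make_folds <- function(subjects, k, seed = 1) {
  if (is.data.frame(subjects)) {
    stopifnot(all(c("subject_id", "scan_id") %in% names(subjects)))
    tab <- subjects
    ids <- unique(tab$subject_id)
  } else {
    ids <- unique(subjects)
    tab <- NULL
  }
  n <- length(ids)
  if (k < 2) stop("need at least 2 folds")
  if (k > n) stop("more folds (", k, ") than subjects (", n, ")")
  shuffled <- with_seed(seed, sample(ids))
  folds <- lapply(seq_len(k), function(i) shuffled[seq(i, n, by = k)])
  scans <- if (!is.null(tab))
    lapply(folds, function(f) tab$scan_id[tab$subject_id %in% f])
  structure(list(folds = folds, scans = scans, k = k, seed = seed),
            class = "fold_split")
}

#' Learning-rate schedule and early stopping from a validation-loss sequence
#'
#' Pure function of the validation losses: an epoch improves when its loss
#' is below the running best by more than \code{tol}; after
#' \code{patience} consecutive non-improving epochs the rate is multiplied by
#' \code{lr_factor} (and the plateau counter resets); training stops once
#' \code{early_stop_patience} epochs pass without improvement.
#'
#' @param val_losses numeric vector, one loss per epoch
#' @param lr0 initial learning rate
#' @param patience plateau patience (epochs)
#' @param lr_factor reduction factor
#' @param tol improvement tolerance
#' @param early_stop_patience epochs without improvement before stopping
#'   (NULL = never)
#' @return list: \code{lr} (rate in effect after each epoch),
#'   \code{best_epoch}, and \code{stop_epoch} (NA when no stop triggered)
#' @export
#' @examples
#' lr_schedule(rep(1, 26))$lr[26]  # 5e-05: one halving at patience 25
lr_schedule <- function(val_losses, lr0 = 1e-4, patience = 25,
                        lr_factor = 0.5, tol = 1e-6,
                        early_stop_patience = NULL) {
  n <- length(val_losses)
  lr <- numeric(n)
  cur <- lr0
  best <- Inf
  best_epoch <- NA_integer_
  since_best <- 0
  since_plateau <- 0
  stop_epoch <- NA_integer_
  for (e in seq_len(n)) {
    v <- val_losses[e]
    if (v < best - tol) {
      best <- v
      best_epoch <- e
      since_best <- 0
      since_plateau <- 0
    } else {
      since_best <- since_best + 1
      since_plateau <- since_plateau + 1
    }
    if (since_plateau >= patience) {
      cur <- cur * lr_factor
      since_plateau <- 0
    }
    lr[e] <- cur
    if (!is.null(early_stop_patience) && is.na(stop_epoch) &&
        since_best >= early_stop_patience)
      stop_epoch <- e
  }
  list(lr = lr, best_epoch = best_epoch, stop_epoch = stop_epoch)
}

# one patch -> one optimizer step; labels are passed as flat 0-based classes
step_on_patch <- function(ptr, patch, lr) {
  d <- dim(patch$x)
  unet_train_step(ptr, as.numeric(patch$x), d[1:3],
                  as.integer(patch$labels), lr)
}

#' Train a segmentation network
#'
#' Scans are single-leg images as produced by \code{\link{leg_scans}} (left
#' legs already mirrored). In every epoch, \code{patches_per_image} axial
#' slabs are drawn from each training scan at uniformly random positions and
#' each is one Adam step at the current learning rate. The validation loss is
#' computed on patches drawn with a fixed seed (identical across epochs), and
#' the parameters achieving the best validation loss are restored at the end.
#'
#' @param model \code{dixon_unet} (mutated in place and returned)
#' @param train_scans,val_scans non-empty lists of scans, each a list with
#'   \code{channels} (X, Y, Z, 2) and \code{labels} (X, Y, Z)
#' @param config \code{\link{train_config}}
#' @param verbose print one line per epoch
#' @return the trained model, with \code{history} (epoch, train_loss,
#'   val_loss, lr)
#' @export
train_unet <- function(model, train_scans, val_scans, config, verbose = FALSE) {
  stopifnot(inherits(model, "dixon_unet"), inherits(config, "train_config"))
  if (length(train_scans) == 0) stop("empty training set")
  if (length(val_scans) == 0) stop("empty validation set")
  Z <- dim(train_scans[[1]]$channels)[3]
  S <- config$patch_slices %||% min(81L, Z)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  best_val <- Inf
  best_weights <- NULL
  val_losses <- numeric()
  cur_lr <- config$lr0
  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    tl <- numeric()
    for (scan in train_scans) {
      for (p in seq_len(config$patches_per_image)) {
        patch <- sample_patch(scan$channels, scan$labels, S)
        if (!is.null(config$augment))
          patch <- augment_patch(patch, config$augment)
        tl <- c(tl, step_on_patch(model$ptr, patch, cur_lr))
      }
    }
    vl <- with_seed(config$seed + 9999L, {
      v <- numeric()
      for (scan in val_scans)
        for (p in seq_len(config$val_patches_per_image)) {
          patch <- sample_patch(scan$channels, scan$labels, S)
          d <- dim(patch$x)
          v <- c(v, unet_eval_loss(model$ptr, as.numeric(patch$x), d[1:3],
                                   as.integer(patch$labels)))
        }
      mean(v)
    })
    val_losses <- c(val_losses, vl)
    sched <- lr_schedule(val_losses, lr0 = config$lr0,
                         patience = config$plateau_patience,
                         lr_factor = config$lr_factor,
                         tol = config$improve_tol,
                         early_stop_patience = config$early_stop_patience)
    if (vl < best_val - config$improve_tol) {
      best_val <- vl
      best_weights <- model_weights(model)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(tl),
                                   val_loss = vl, lr = cur_lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                      epoch, mean(tl), vl, cur_lr))
    cur_lr <- sched$lr[epoch]
    if (!is.na(sched$stop_epoch) && sched$stop_epoch == epoch) break
  }
  if (!is.null(best_weights)) set_model_weights(model, best_weights)
  model$trained <- TRUE
  model$history <- if (is.null(model$history)) hist else rbind(model$history, hist)
  model
}

#' Fine-tune a trained model on a new cohort
#'
#' Continues training from the given model's parameters with a fresh
#' optimizer state; provenance (the parent model's label) is recorded. With
#' \code{max_epochs = 0} the parameters are returned unchanged.
#'
#' @inheritParams train_unet
#' @param label label of the fine-tuned model
#' @return new \code{dixon_unet} (the parent model is left untouched)
#' @export
finetune_unet <- function(model, train_scans, val_scans, config,
                          label = paste0(model$label, "-ft"), verbose = FALSE) {
  stopifnot(inherits(model, "dixon_unet"))
  m <- clone_model(model, label = label)
  m$history <- NULL
  m$provenance <- list(parent = model$label,
                       parent_epochs = if (!is.null(model$history))
                         nrow(model$history) else 0L)
  if (config$max_epochs == 0) return(m)
  train_unet(m, train_scans, val_scans, config, verbose = verbose)
}

#' Patch-based whole-volume prediction
#'
#' Runs the network on axial slabs covering the volume and averages the class
#' probabilities voxel-wise over the covering patches (renormalized to a
#' probability simplex). The default policy is deterministic tiling with at
#' least 50\% overlap between consecutive slabs; \code{policy = "random"}
#' draws uniformly positioned slabs until every slice is covered.
#'
#' @param model \code{dixon_unet} or list of them (probabilities averaged)
#' @param channels single-leg input, 4-D array (X, Y, Z, 2)
#' @param patch_slices slab thickness (default \code{min(81, Z)})
#' @param policy "tile" or "random"
#' @param overlap minimal fractional overlap between tiles (tile policy)
#' @param max_draws cap for the random policy
#' @return list with \code{probs} (X, Y, Z, n_classes) and per-slice
#'   \code{coverage} counts (>= 1 everywhere)
#' @export
predict_volume <- function(model, channels, patch_slices = NULL,
                           policy = c("tile", "random"), overlap = 0.5,
                           max_draws = 1000) {
  policy <- match.arg(policy)
  models <- if (inherits(model, "dixon_unet")) list(model) else model
  stopifnot(all(vapply(models, inherits, TRUE, "dixon_unet")))
  d <- dim(channels)
  Z <- d[3]
  S <- patch_slices %||% min(81L, Z)
  if (S > Z) stop("volume has ", Z, " slices but patches need ", S)
  if (policy == "tile") {
    step <- max(1L, as.integer(floor(S * (1 - overlap))))
    starts <- unique(c(seq(0L, Z - S, by = step), Z - S))
  } else {
    starts <- integer()
    covered <- logical(Z)
    draws <- 0
    while (!all(covered) && draws < max_draws) {
      s <- sample.int(Z - S + 1, 1) - 1L
      starts <- c(starts, s)
      covered[(s + 1):(s + S)] <- TRUE
      draws <- draws + 1
    }
    if (!all(covered))
      stop("random patch policy failed to cover every slice within ",
           max_draws, " draws")
    starts <- sort(unique(starts))
  }
  K <- models[[1]]$spec$n_classes
  acc <- array(0, c(d[1], d[2], Z, K))
  coverage <- integer(Z)
  for (s in starts) {
    zr <- (s + 1):(s + S)
    x <- channels[, , zr, , drop = FALSE]
    pm <- 0
    for (m in models)
      pm <- pm + unet_predict(m$ptr, as.numeric(x), c(d[1], d[2], S))
    pm <- pm / length(models)
    acc[, , zr, ] <- acc[, , zr, ] + array(pm, c(d[1], d[2], S, K))
    coverage[zr] <- coverage[zr] + 1L
  }
  if (any(coverage == 0)) stop("incomplete slice coverage")
  for (z in seq_len(Z)) acc[, , z, ] <- acc[, , z, ] / coverage[z]
  tot <- array(rowSums(matrix(acc, ncol = K)), c(d[1], d[2], Z))
  for (k in seq_len(K)) acc[, , , k] <- acc[, , , k] / tot
  list(probs = acc, coverage = coverage)
}

#' Hard labels from class probabilities
#'
#' Voxel-wise argmax; ties resolve to the lowest class id (deterministic).
#'
#' @param probs 4-D array (X, Y, Z, K), classes 0..K-1 along the last axis
#' @return 3-D integer array of class ids
#' @export
argmax_labels <- function(probs) {
  d <- dim(probs)
  K <- d[4]
  lab <- max.col(matrix(probs, ncol = K), ties.method = "first") - 1L
  array(as.integer(lab), d[1:3])
}

#' Majority-vote label fusion
#'
#' Per voxel, the label receiving most votes wins. Ties are broken by the
#' highest mean class probability when probability volumes are supplied,
#' otherwise by the lowest label id; the result is deterministic either way.
#'
#' @param label_list list (length >= 2) of integer 3-D arrays on one grid
#' @param prob_list optional list of matching probability arrays
#'   (X, Y, Z, K)
#' @return fused integer 3-D array
#' @export
ensemble_vote <- function(label_list, prob_list = NULL) {
  stopifnot(length(label_list) >= 2)
  d <- dim(label_list[[1]])
  for (l in label_list)
    if (!identical(dim(l), d)) stop("label volumes must share one grid")
  K <- max(vapply(label_list, function(l) as.integer(max(l)), 0L)) + 1L
  if (!is.null(prob_list)) K <- max(K, dim(prob_list[[1]])[4])
  n <- prod(d)
  counts <- matrix(0L, n, K)
  for (l in label_list) {
    v <- as.integer(l) + 1L
    counts[cbind(seq_len(n), v)] <- counts[cbind(seq_len(n), v)] + 1L
  }
  lead <- max.col(counts, ties.method = "first")
  if (is.null(prob_list)) {
    fused <- lead - 1L
  } else {
    mean_prob <- matrix(0, n, K)
    for (p in prob_list)
      mean_prob <- mean_prob + matrix(p, ncol = dim(p)[4])[, seq_len(K)]
    mean_prob <- mean_prob / length(prob_list)
    top <- counts[cbind(seq_len(n), lead)]
    masked <- ifelse(counts == top, mean_prob, -Inf)
    fused <- max.col(masked, ties.method = "first") - 1L
  }
  array(as.integer(fused), d)
}

#' Segment a full two-leg Dixon volume
#'
#' The volume is split mid-sagittally; the left half is mirrored to look like
#' a right leg; each half is predicted patch-wise (per model, then fused by
#' majority vote when several models are given); the left prediction is
#' mirrored back and the halves are concatenated.
#'
#' @param models a \code{dixon_unet} or a list of them (an ensemble)
#' @param dixon two-leg \code{dixon_volume}
#' @param patch_slices slab thickness for prediction
#' @param scheme muscle scheme of the output labels
#' @param ... passed to \code{\link{predict_volume}}
#' @return \code{label_volume} on the input grid
#' @export
segment_subject <- function(models, dixon, patch_slices = NULL,
                            scheme = NULL, ...) {
  if (inherits(models, "dixon_unet")) models <- list(models)
  stopifnot(inherits(dixon, "dixon_volume"))
  K <- models[[1]]$spec$n_classes
  scheme <- scheme %||% muscle_scheme(K - 1)
  halves <- split_midsagittal(dixon)
  seg_half <- function(half_channels) {
    if (length(models) == 1) {
      pv <- predict_volume(models[[1]], half_channels, patch_slices, ...)
      return(argmax_labels(pv$probs))
    }
    labs <- list(); probs <- list()
    for (m in models) {
      pv <- predict_volume(m, half_channels, patch_slices, ...)
      labs[[length(labs) + 1]] <- argmax_labels(pv$probs)
      probs[[length(probs) + 1]] <- pv$probs
    }
    ensemble_vote(labs, probs)
  }
  right <- seg_half(leg_channels(halves$right))
  left_m <- seg_half(leg_channels(mirror_lr(halves$left)))
  left <- mirror_array(left_m)
  X2 <- dim(right)[1]
  out <- array(0L, dim(dixon$water))
  out[1:X2, , ] <- right
  out[(X2 + 1):(2 * X2), , ] <- left
  label_volume(out, dixon$spacing, scheme)
}

#' Held-out segmentation quality of phantom subjects
#'
#' Segments each subject with the given model(s) and scores the generalized
#' Dice coefficient against the phantom's true label map.
#'
#' @param models \code{dixon_unet} or list of them
#' @param subjects list of phantom subjects (see \code{\link{make_cohort}})
#' @param patch_slices prediction slab thickness
#' @param postprocess apply \code{\link{filter_components}} and
#'   \code{\link{fill_holes}} before scoring
#' @return data frame with one row per subject: \code{subject_id},
#'   \code{gdsc_pct}
#' @export
evaluate_cohort <- function(models, subjects, patch_slices = NULL,
                            postprocess = TRUE) {
  rows <- lapply(subjects, function(su) {
    pred <- segment_subject(models, su$dixon, patch_slices,
                            scheme = su$labels$scheme)
    if (postprocess) pred <- fill_holes(filter_components(pred))
    data.frame(subject_id = su$subject_id %||% NA_integer_,
               gdsc_pct = generalized_dsc(pred, su$labels))
  })
  do.call(rbind, rows)
}

#' Leg scans of a phantom cohort, keyed by subject
#'
#' @param subjects list of phantom subjects
#' @return list of single-leg scans (two per subject), each carrying its
#'   \code{subject_id}
#' @export
cohort_leg_scans <- function(subjects) {
  out <- list()
  for (su in subjects) {
    scans <- leg_scans(su$dixon, su$labels)
    for (s in scans) {
      s$subject_id <- su$subject_id
      out[[length(out) + 1]] <- s
    }
  }
  out
}
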