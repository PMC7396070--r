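#' Experiment configuration
#'
#' Bundles the training protocol and the input/target channel wiring. The
#' contralateral mapping is fixed by construction: `upper_only` feeds the
#' shoulder and elbow of `input_side` and predicts the hip and knee of the
#' opposite side; `upper_plus_lower` additionally feeds the ipsilateral hip
#' and knee.
#'
#' @param input_mode `"upper_only"` or `"upper_plus_lower"`.
#' @param input_side `"L"` or `"R"`; targets are always the opposite side.
#' @param velocities Velocities (km/h) the experiment covers.
#' @param lr Base learning rate (protocol value 0.0005).
#' @param max_iters Upper bound on training iterations/epochs (protocol 1000).
#' @param window_len Input window length in frames (protocol step size 10).
#' @param hidden_size LSTM hidden units.
#' @param seed Seed for initialisation and batch shuffling.
#' @param train_fraction Temporal train split fraction.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_size Minibatch size; `Inf` for full batch.
#' @param peephole_output Output-gate peephole variant, see [cell_step()].
#' @param lead Prediction horizon in frames beyond the window (default 1,
#'   one-step-ahead).
#' @param use_displacement Also feed per-frame angular-displacement channels.
#' @param clamp_output Clamp predicted angles into `[0, 180]` degrees.
#' @param pool_velocities Train one model across velocities instead of one
#'   per velocity.
#' @param tol,patience Early-stopping: training loss is averaged over
#'   25-iteration blocks; stop once `patience` consecutive blocks fail to
#'   improve the best block mean by a relative `tol`.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(input_mode = c("upper_only",
                                             "upper_plus_lower"),
                              input_side = c("R", "L"),
                              velocities = c(3.0, 3.5, 4.0, 4.5),
                              lr = 5e-4, max_iters = 1000, window_len = 10,
                              hidden_size = 8, seed = 1,
                              train_fraction = 0.8,
                              optimizer = c("adam", "sgd"),
                              batch_size = 64,
                              peephole_output = c("prev", "current"),
                              lead = 1, use_displacement = FALSE,
                              clamp_output = TRUE, pool_velocities = FALSE,
                              tol = 5e-3, patience = 3) {
  input_mode <- match.arg(input_mode)
  input_side <- match.arg(input_side)
  optimizer <- match.arg(optimizer)
  peephole_output <- match.arg(peephole_output)
  stopifnot(lr > 0, max_iters >= 0, window_len >= 1,
            train_fraction > 0, train_fraction < 1, lead >= 1)
  target_side <- if (input_side == "R") "L" else "R"
  upper <- paste0(c("shoulder_", "elbow_"), input_side)
  lower <- paste0(c("hip_", "knee_"), input_side)
  inputs <- if (input_mode == "upper_only") upper else c(upper, lower)
  targets <- paste0(c("hip_", "knee_"), target_side)
  structure(list(input_mode = input_mode, input_side = input_side,
                 target_side = target_side, input_channels = inputs,
                 target_channels = targets, velocities = velocities,
                 lr = lr, max_iters = max_iters, window_len = window_len,
                 hidden_size = hidden_size, seed = seed,
                 train_fraction = train_fraction, optimizer = optimizer,
                 batch_size = batch_size, peephole_output = peephole_output,
                 lead = lead, use_displacement = use_displacement,
                 clamp_output = clamp_output,
                 pool_velocities = pool_velocities,
                 tol = tol, patience = patience),
            class = "experiment_config")
}

series_input_matrix <- function(series, cfg) {
  x <- series$angles[, cfg$input_channels, drop = FALSE]
  if (cfg$use_displacement) {
    if (is.null(series$displacement)) series <- angular_displacement(series)
    d <- rbind(0, series$displacement[, cfg$input_channels, drop = FALSE])
    colnames(d) <- paste0("d_", cfg$input_channels)
    x <- cbind(x, d)
  }
  x
}

#' Build supervised windows from an angle series
#'
#' Sliding windows of `window_len` frames with stride 1; the target vector is
#' the target-channel angles at the frame `lead` steps after the window's
#' last input frame. A series of `N` frames yields `N - window_len - lead + 1`
#' examples (with the default `lead = 1`, `N - window_len`). Windows touching
#' a frame marked invalid (`NA`) are dropped. Channels are returned raw; the
#' training step standardises them with statistics from its own split only.
#'
#' @param series A `joint_angle_series`.
#' @param cfg An [experiment_config()].
#' @return A `windowed_dataset`: `inputs` array `(window_len x n_inputs x
#'   n_windows)`, `targets` matrix `(n_windows x n_targets)`, plus the
#'   channel manifest.
#' @export
make_windows <- function(series, cfg) {
  wl <- cfg$window_len
  x <- series_input_matrix(series, cfg)
  y <- series$angles[, cfg$target_channels, drop = FALSE]
  n <- nrow(x)
  n_w <- n - wl - cfg$lead + 1L
  if (n_w < 1L) {
    stop(sprintf("series of %d frames too short for window %d + lead %d",
                 n, wl, cfg$lead), call. = FALSE)
  }
  inputs <- array(NA_real_, dim = c(wl, ncol(x), n_w),
                  dimnames = list(NULL, colnames(x), NULL))
  for (k in seq_len(n_w)) inputs[, , k] <- x[k:(k + wl - 1L), ]
  targets <- y[(wl + cfg$lead):(wl + cfg$lead + n_w - 1L), , drop = FALSE]
  keep <- !(apply(is.na(inputs), 3, any) | apply(is.na(targets), 1, any))
  structure(list(inputs = inputs[, , keep, drop = FALSE],
                 targets = targets[keep, , drop = FALSE],
                 window_index = which(keep),
                 input_channels = colnames(x),
                 target_channels = cfg$target_channels,
                 window_len = wl, lead = cfg$lead,
                 fps = series$fps, time_s = series$time_s),
            class = "windowed_dataset")
}

#' Number of examples in a windowed dataset
#' @param ds A `windowed_dataset`.
#' @return Integer count.
#' @export
n_windows <- function(ds) dim(ds$inputs)[3]

#' Temporal train/evaluation split
#'
#' The first `floor(train_fraction * N)` windows train; windows straddling
#' the boundary (sharing frames with the training block) are dropped; the
#' remainder evaluate. No shuffling: overlapping windows leak aggressively
#' under random splits.
#'
#' @param ds A `windowed_dataset`.
#' @param train_fraction Proportion in (0, 1).
#' @return List with `train` and `eval` datasets.
#' @export
split_train_eval <- function(ds, train_fraction = 0.8) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- n_windows(ds)
  n_tr <- floor(train_fraction * n)
  first_eval <- n_tr + ds$window_len
  if (n_tr < 1L || first_eval > n) {
    stop("split leaves an empty train or evaluation side", call. = FALSE)
  }
  take <- function(idx) {
    out <- ds
    out$inputs <- ds$inputs[, , idx, drop = FALSE]
    out$targets <- ds$targets[idx, , drop = FALSE]
    out$window_index <- ds$window_index[idx]
    out
  }
  list(train = take(seq_len(n_tr)), eval = take(first_eval:n))
}

channel_stats <- function(ds) {
  xm <- apply(ds$inputs, 2, mean)
  xs <- pmax(apply(ds$inputs, 2, stats::sd), 1e-6)  # sd floor, degrees
  ym <- colMeans(ds$targets)
  ys <- pmax(apply(ds$targets, 2, stats::sd), 1e-6)
  list(x_mean = xm, x_sd = xs, y_mean = ym, y_sd = ys)
}

standardize_inputs <- function(inputs, stats) {
  # inputs: wl x n_in x B; stats per input channel
  sweep(sweep(inputs, 2, stats$x_mean, `-`), 2, stats$x_sd, `/`)
}

#' Train the peephole LSTM on a windowed dataset
#'
#' Sequence-to-one regression: each window is run through the LSTM and the
#' readout at the final step is matched to the target vector. Channels are
#' standardised with mean/sd computed from this (training) dataset only; the
#' statistics travel with the returned model so prediction de-standardises
#' consistently. Optimisation is minibatch Adam (or SGD) with global-norm
#' gradient clipping; one iteration is one gradient step on one minibatch
#' (the sense in which deep-learning frameworks count their iteration caps),
#' bounded by `cfg$max_iters`, with plateau-based early stopping.
#'
#' After the gradient phase the linear readout `(Wy, by)` -- the convex part
#' of the model -- is refit exactly by ridge-regularised least squares on
#' the final-step hidden features of the training windows. The recurrent
#' cell is left untouched; this only removes the residual first-order
#' optimisation error in the output layer.
#'
#' @param train A `windowed_dataset` (the training split).
#' @param cfg An [experiment_config()].
#' @return A `gait_model`: `params`, `stats`, `loss_history` (mean epoch
#'   loss, standardised units), the channel manifest and config echo.
#' @export
train_model <- function(train, cfg) {
  B <- n_windows(train)
  if (B < 1L) stop("empty training set")
  stats <- channel_stats(train)
  n_in <- length(train$input_channels)
  n_out <- length(train$target_channels)
  wl <- train$window_len
  params <- lstm_init(n_in, cfg$hidden_size, n_out, seed = cfg$seed)
  xs_all <- aperm(standardize_inputs(train$inputs, stats), c(2, 1, 3))
  y_std <- sweep(sweep(train$targets, 2, stats$y_mean, `-`), 2,
                 stats$y_sd, `/`)
  model <- function(p, hist) {
    structure(list(params = p, stats = stats,
                   input_channels = train$input_channels,
                   target_channels = train$target_channels,
                   window_len = wl, lead = train$lead,
                   peephole_output = cfg$peephole_output,
                   clamp_output = cfg$clamp_output,
                   loss_history = hist, config = cfg),
              class = "gait_model")
  }
  if (cfg$max_iters == 0L) return(model(params, numeric(0)))
  set.seed(cfg$seed + 1L)
  bs <- min(cfg$batch_size, B)
  opt <- NULL
  hist <- numeric(cfg$max_iters)
  # plateau detection on block means of the per-iteration minibatch loss
  block <- 25L
  best_block <- Inf
  stall <- 0L
  ord <- integer(0)
  pos <- 1L
  iter <- 0L
  while (iter < cfg$max_iters) {
    iter <- iter + 1L
    if (pos + bs - 1L > length(ord)) {
      ord <- if (bs < B) sample.int(B) else seq_len(B)
      pos <- 1L
    }
    idx <- ord[pos:(pos + bs - 1L)]
    pos <- pos + bs
    xb <- xs_all[, , idx, drop = FALSE]
    tb <- array(NA_real_, dim = c(n_out, wl, length(idx)))
    tb[, wl, ] <- t(y_std[idx, , drop = FALSE])
    bp <- bptt_gradients(params, xb, tb,
                         peephole_output = cfg$peephole_output)
    if (!is.finite(bp$loss)) {
      stop(sprintf("training diverged (non-finite loss) at iteration %d",
                   iter), call. = FALSE)
    }
    if (cfg$optimizer == "adam") {
      upd <- adam_update(params, bp$grads, opt, lr = cfg$lr)
      params <- upd$params
      opt <- upd$opt
    } else {
      params <- sgd_update(params, bp$grads, lr = cfg$lr)
    }
    hist[iter] <- bp$loss
    if (iter %% block == 0L) {
      bl <- mean(hist[(iter - block + 1L):iter])
      if (bl < best_block * (1 - cfg$tol)) {
        best_block <- bl
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  }
  params <- refit_readout(params, xs_all, y_std, cfg$peephole_output)
  model(params, hist[seq_len(iter)])
}

# Closed-form ridge solve for the readout on final-step hidden features.
refit_readout <- function(params, xs_all, y_std, peephole_output,
                          lambda = 1e-6) {
  wl <- dim(xs_all)[2]
  fwd <- lstm_forward(params, xs_all, peephole_output = peephole_output)
  H <- t(fwd$cache$h[[wl]])                    # B x n_hidden
  X <- cbind(1, H)
  A <- crossprod(X) + diag(c(0, rep(lambda, ncol(H))))
  beta <- solve(A, crossprod(X, y_std))        # (1 + n_hidden) x n_out
  params$by <- as.numeric(beta[1, ])
  params$Wy <- t(beta[-1, , drop = FALSE])
  params
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf(
    "gait_model: [%s] -> [%s], window %d, %d training iterations\n",
    paste(x$input_channels, collapse = ", "),
    paste(x$target_channels, collapse = ", "),
    x$window_len, length(x$loss_history)))
  invisible(x)
}

#' Predict a contralateral trajectory from an angle series
#'
#' Slides the model's window over the series and emits the de-standardised
#' prediction for the frame `lead` steps past each window, so prediction `k`
#' aligns with frame `k + window_len + lead - 1` of the input series.
#'
#' @param model A `gait_model` from [train_model()].
#' @param series A `joint_angle_series` supplying the input channels.
#' @param cfg The [experiment_config()] (channel wiring must match the
#'   model's manifest).
#' @return List: `pred` matrix (n_pred x n_targets, degrees), `frame_index`
#'   into the series, `time_s`.
#' @export
predict_trajectory <- function(model, series, cfg = model$config) {
  if (!identical(sort(cfg$input_channels),
                 sort(intersect(cfg$input_channels,
                                colnames(series$angles))))) {
    stop("series lacks the model's input channels", call. = FALSE)
  }
  ds <- make_windows(series, cfg)
  predict_windows(model, ds)
}

#' Predict on an already-windowed dataset
#'
#' Workhorse behind [predict_trajectory()]: standardises the windows with the
#' model's stored training statistics, runs the forward pass, and
#' de-standardises the final-step readout back to degrees.
#'
#' @param model A `gait_model`.
#' @param ds A `windowed_dataset` whose channel manifest matches the model.
#' @return As [predict_trajectory()], plus the dataset's `truth` targets.
#' @export
predict_windows <- function(model, ds) {
  if (!identical(ds$input_channels, model$input_channels)) {
    stop("channel manifest mismatch between model and dataset", call. = FALSE)
  }
  xs <- aperm(standardize_inputs(ds$inputs, model$stats), c(2, 1, 3))
  fwd <- lstm_forward(model$params, xs,
                      peephole_output = model$peephole_output)
  y_std <- matrix(fwd$y[, ds$window_len, ], nrow = length(model$target_channels))
  pred <- sweep(sweep(t(y_std), 2, model$stats$y_sd, `*`), 2,
                model$stats$y_mean, `+`)
  colnames(pred) <- model$target_channels
  if (model$clamp_output) pred <- pmin(pmax(pred, 0), 180)
  frame_index <- ds$window_index + ds$window_len + ds$lead - 1L
  list(pred = pred, frame_index = frame_index,
       time_s = ds$time_s[frame_index], truth = ds$targets)
}

#' Root-mean-squared error
#'
#' @param pred,truth Equal-length numeric vectors (degrees).
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth)) stop("length mismatch")
  sqrt(mean((pred - truth)^2))
}

joint_label <- function(channel) {
  paste(sub("^.*_", "", channel), sub("_.*$", "", channel))
}

#' Run the full synergy experiment and report RMSE
#'
#' For every velocity and every subject, builds windows, splits temporally,
#' trains a model per contralateral direction (right limbs predicting the
#' left hip/knee, and left limbs predicting the right hip/knee, so all four
#' target joints are covered as in the study's report), predicts the held-out
#' segment, and scores per-joint RMSE in degrees. Cells aggregate mean and sd
#' across subjects; the per-velocity `Total` row is the mean over the four
#' joint entries' subject values.
#'
#' @param series_list List of `joint_angle_series`, each carrying
#'   `subject_id` and `velocity_kmh`.
#' @param cfg An [experiment_config()]; both input-side directions are run
#'   regardless of `cfg$input_side`.
#' @return An `rmse_report` data frame with columns `configuration`,
#'   `velocity_kmh`, `joint`, `rmse_mean_deg`, `rmse_sd_deg` (joint `"Total"`
#'   is the per-velocity aggregate), plus attribute `per_subject`.
#' @export
run_experiment <- function(series_list, cfg) {
  vels <- cfg$velocities
  have <- vapply(series_list, function(s) s$velocity_kmh, numeric(1))
  missing_v <- setdiff(vels, unique(have))
  if (length(missing_v) > 0L) {
    stop("no series for velocity ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  subjects <- unique(vapply(series_list, function(s) s$subject_id,
                            character(1)))
  cells <- list()
  for (v in vels) {
    for (subj in subjects) {
      sel <- which(have == v &
                     vapply(series_list, function(s) s$subject_id,
                            character(1)) == subj)
      if (length(sel) == 0L) next
      for (side in c("R", "L")) {
        side_cfg <- experiment_config(
          input_mode = cfg$input_mode, input_side = side,
          velocities = v, lr = cfg$lr, max_iters = cfg$max_iters,
          window_len = cfg$window_len, hidden_size = cfg$hidden_size,
          seed = cfg$seed, train_fraction = cfg$train_fraction,
          optimizer = cfg$optimizer, batch_size = cfg$batch_size,
          peephole_output = cfg$peephole_output, lead = cfg$lead,
          use_displacement = cfg$use_displacement,
          clamp_output = cfg$clamp_output, tol = cfg$tol,
          patience = cfg$patience)
        train_sets <- list(); eval_sets <- list()
        for (k in sel) {
          sp <- split_train_eval(make_windows(series_list[[k]], side_cfg),
                                 cfg$train_fraction)
          train_sets[[length(train_sets) + 1L]] <- sp$train
          eval_sets[[length(eval_sets) + 1L]] <- sp$eval
        }
        tr <- if (length(train_sets) == 1L) train_sets[[1]] else
          concat_windows(train_sets)
        fit <- train_model(tr, side_cfg)
        for (e in eval_sets) {
          out <- predict_windows(fit, e)
          for (ch in side_cfg$target_channels) {
            cells[[length(cells) + 1L]] <- data.frame(
              configuration = cfg$input_mode, velocity_kmh = v,
              subject = subj, joint = joint_label(ch),
              rmse_deg = rmse(out$pred[, ch], e$targets[, ch]))
          }
        }
      }
    }
  }
  per_subject <- do.call(rbind, cells)
  agg <- stats::aggregate(rmse_deg ~ configuration + velocity_kmh + joint,
                          per_subject, function(x) c(mean(x), stats::sd(x)))
  report <- data.frame(configuration = agg$configuration,
                       velocity_kmh = agg$velocity_kmh, joint = agg$joint,
                       rmse_mean_deg = agg$rmse_deg[, 1],
                       rmse_sd_deg = agg$rmse_deg[, 2])
  tot <- stats::aggregate(rmse_deg ~ configuration + velocity_kmh,
                          per_subject, function(x) c(mean(x), stats::sd(x)))
  totals <- data.frame(configuration = tot$configuration,
                       velocity_kmh = tot$velocity_kmh, joint = "Total",
                       rmse_mean_deg = tot$rmse_deg[, 1],
                       rmse_sd_deg = tot$rmse_deg[, 2])
  report <- rbind(report, totals)
  report <- report[order(report$configuration, report$velocity_kmh,
                         report$joint != "Total", report$joint), ]
  rownames(report) <- NULL
  structure(report, per_subject = per_subject,
            class = c("rmse_report", "data.frame"))
}

concat_windows <- function(sets) {
  out <- sets[[1]]
  out$inputs <- array(
    unlist(lapply(sets, `[[`, "inputs")),
    dim = c(dim(sets[[1]]$inputs)[1:2],
            sum(vapply(sets, n_windows, integer(1)))),
    dimnames = dimnames(sets[[1]]$inputs))
  out$targets <- do.call(rbind, lapply(sets, `[[`, "targets"))
  out$window_index <- unlist(lapply(sets, `[[`, "window_index"))
  out
}

#' Format an RMSE report as the familiar joint-by-velocity table
#'
#' @param report An `rmse_report`.
#' @return Character vector of table lines (also printed).
#' @export
format_rmse_table <- function(report) {
  lines <- character(0)
  for (conf in unique(report$configuration)) {
    sub <- report[report$configuration == conf, ]
    vels <- sort(unique(sub$velocity_kmh))
    lines <- c(lines, sprintf("Configuration: %s", conf),
               paste(c(sprintf("%-8s", ""),
                       sprintf("%12s", paste0(vels, " km/h"))),
                     collapse = ""))
    joints <- c("L hip", "L knee", "R hip", "R knee", "Total")
    for (j in joints) {
      row <- sprintf("%-8s", j)
      for (v in vels) {
        cell <- sub[sub$joint == j & sub$velocity_kmh == v, ]
        row <- paste0(row, sprintf("%12s",
                                   sprintf("%.2f +/- %.2f",
                                           cell$rmse_mean_deg,
                                           cell$rmse_sd_deg)))
      }
      lines <- c(lines, row)
    }
    lines <- c(lines, "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
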