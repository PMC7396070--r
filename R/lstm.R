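#' Numerically stable logistic sigmoid
#'
#' Elementwise `1 / (1 + exp(-x))`, computed on the branch that never
#' overflows, so it saturates cleanly to 0/1 for arguments of magnitude up to
#' (and beyond) 700.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
sigmoid <- function(x) {
  # 1/(1+exp(-x)) saturates exactly to 0 via 1/(1+Inf) for very negative x,
  # and exp(-x) underflows to 0 for very positive x; no overflow warnings
  # are raised on either branch, so the direct form is already stable
  1 / (1 + exp(-x))
}

lstm_gate_names <- function() {
  c("Wxi", "Wxf", "Wxc", "Wxo", "Whi", "Whf", "Whc", "Who",
    "wci", "wcf", "wco", "bi", "bf", "bc", "bo", "Wy", "by")
}

#' Initialise peephole-LSTM parameters
#'
#' One memory cell bank with input, forget and output gates, each gate
#' receiving the input, the previous hidden state, and the cell state through
#' diagonal (elementwise) peephole weights; plus a linear readout from the
#' hidden state. Weight matrices use Glorot-uniform initialisation by
#' default (`"uniform"` gives the flat `uniform(-scale, scale)` alternative);
#' biases start at zero except the forget-gate bias at 1, the standard
#' trainability convention. Peephole weights start at zero.
#'
#' @param n_in Input dimension.
#' @param n_hidden Hidden/cell dimension.
#' @param n_out Readout dimension.
#' @param init `"glorot"` or `"uniform"`.
#' @param scale Half-width for `init = "uniform"`.
#' @param seed Optional integer seed for reproducible draws.
#' @return An `lstm_params` list of weight matrices `Wx*` (hidden x input),
#'   `Wh*` (hidden x hidden), peephole vectors `wci, wcf, wco`, biases, and
#'   readout `Wy` (out x hidden), `by`.
#' @export
lstm_init <- function(n_in, n_hidden, n_out, init = c("glorot", "uniform"),
                      scale = 0.08, seed = NULL) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(nr, nc) {
    lim <- if (init == "glorot") sqrt(6 / (nr + nc)) else scale
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  p <- list(
    Wxi = draw(n_hidden, n_in), Wxf = draw(n_hidden, n_in),
    Wxc = draw(n_hidden, n_in), Wxo = draw(n_hidden, n_in),
    Whi = draw(n_hidden, n_hidden), Whf = draw(n_hidden, n_hidden),
    Whc = draw(n_hidden, n_hidden), Who = draw(n_hidden, n_hidden),
    wci = numeric(n_hidden), wcf = numeric(n_hidden), wco = numeric(n_hidden),
    bi = numeric(n_hidden), bf = rep(1, n_hidden),
    bc = numeric(n_hidden), bo = numeric(n_hidden),
    Wy = draw(n_out, n_hidden), by = numeric(n_out))
  structure(p, n_in = n_in, n_hidden = n_hidden, n_out = n_out,
            class = "lstm_params")
}

#' @export
print.lstm_params <- function(x, ...) {
  cat(sprintf("lstm_params: %d -> %d (peephole cell) -> %d\n",
              attr(x, "n_in"), attr(x, "n_hidden"), attr(x, "n_out")))
  invisible(x)
}

#' Zero-filled LSTM state
#'
#' @param n_hidden Hidden size.
#' @param batch Number of parallel sequences.
#' @return List with hidden activation `h` and memory cell `c`, each
#'   `n_hidden x batch`.
#' @export
lstm_state <- function(n_hidden, batch = 1) {
  z <- matrix(0, n_hidden, batch)
  list(h = z, c = z)
}

as_state_matrix <- function(s, n_hidden, batch) {
  if (is.null(s)) return(lstm_state(n_hidden, batch))
  h <- if (is.matrix(s$h)) s$h else matrix(s$h, n_hidden, batch)
  cc <- if (is.matrix(s$c)) s$c else matrix(s$c, n_hidden, batch)
  list(h = h, c = cc)
}

#' One peephole-LSTM cell step
#'
#' Computes, in order: input gate `i` and forget gate `f` from the input,
#' previous hidden state and previous cell state; candidate
#' `g = tanh(Wxc x + Whc h + bc)`; new cell `c = f*c_prev + i*g`; output gate
#' `o`; and `h = o * tanh(c)`. The output gate's peephole argument is the
#' *previous* cell state by default (`peephole_output = "prev"`, the form the
#' prediction model uses); `"current"` gives the classical variant peeking at
#' the freshly updated cell.
#'
#' @param params An `lstm_params` bundle.
#' @param x Input vector (length `n_in`) or `n_in x batch` matrix.
#' @param state Previous state from [lstm_state()] (or `NULL` for zeros).
#' @param peephole_output `"prev"` or `"current"`.
#' @return List with `state` (new `h`, `c`) and `gates` (`i`, `f`, `o`, `g`).
#' @export
cell_step <- function(params, x, state = NULL,
                      peephole_output = c("prev", "current")) {
  peephole_output <- match.arg(peephole_output)
  H <- attr(params, "n_hidden")
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != attr(params, "n_in")) stop("input dimension mismatch")
  B <- ncol(x)
  state <- as_state_matrix(state, H, B)
  h0 <- state$h; c0 <- state$c
  i <- sigmoid(params$Wxi %*% x + params$Whi %*% h0 + params$wci * c0 +
                 params$bi)
  f <- sigmoid(params$Wxf %*% x + params$Whf %*% h0 + params$wcf * c0 +
                 params$bf)
  g <- tanh(params$Wxc %*% x + params$Whc %*% h0 + params$bc)
  c1 <- f * c0 + i * g
  o_peep <- if (peephole_output == "prev") c0 else c1
  o <- sigmoid(params$Wxo %*% x + params$Who %*% h0 + params$wco * o_peep +
                 params$bo)
  h1 <- o * tanh(c1)
  list(state = list(h = h1, c = c1), gates = list(i = i, f = f, o = o, g = g))
}

as_input_array <- function(xs, n_in) {
  if (is.matrix(xs)) xs <- array(xs, dim = c(nrow(xs), ncol(xs), 1L))
  if (length(dim(xs)) != 3L || dim(xs)[1] != n_in) {
    stop("xs must be n_in x T (x batch)")
  }
  xs
}

#' Full-sequence LSTM forward pass
#'
#' Iterates [cell_step()] over time and applies the linear readout
#' `y_t = Wy h_t + by` at every step, caching all activations needed for
#' backpropagation through time.
#'
#' @param params An `lstm_params` bundle.
#' @param xs Inputs: `n_in x T` matrix (one sequence) or `n_in x T x batch`
#'   array.
#' @param init Initial state (`NULL` for zeros).
#' @param peephole_output See [cell_step()].
#' @return List with `y` (`n_out x T` or `n_out x T x batch`) and `cache`.
#' @export
lstm_forward <- function(params, xs, init = NULL,
                         peephole_output = c("prev", "current")) {
  peephole_output <- match.arg(peephole_output)
  n_in <- attr(params, "n_in")
  H <- attr(params, "n_hidden")
  n_out <- attr(params, "n_out")
  single <- is.matrix(xs)
  xs <- as_input_array(xs, n_in)
  T_len <- dim(xs)[2]; B <- dim(xs)[3]
  if (T_len == 0L) stop("empty input sequence")
  state <- as_state_matrix(init, H, B)
  cache <- list(x = vector("list", T_len), i = vector("list", T_len),
                f = vector("list", T_len), o = vector("list", T_len),
                g = vector("list", T_len), c = vector("list", T_len),
                h = vector("list", T_len), tc = vector("list", T_len),
                c0 = state$c, h0 = state$h,
                peephole_output = peephole_output)
  y <- array(0, dim = c(n_out, T_len, B))
  # the four gate pre-activations share two stacked matmuls per step
  Wx <- rbind(params$Wxi, params$Wxf, params$Wxc, params$Wxo)
  Wh <- rbind(params$Whi, params$Whf, params$Whc, params$Who)
  bb <- c(params$bi, params$bf, params$bc, params$bo)
  r_i <- seq_len(H); r_f <- H + r_i; r_g <- 2L * H + r_i; r_o <- 3L * H + r_i
  h0 <- state$h; c0 <- state$c
  for (t in seq_len(T_len)) {
    x_t <- matrix(xs[, t, ], n_in, B)
    A <- Wx %*% x_t + Wh %*% h0 + bb
    i <- sigmoid(A[r_i, , drop = FALSE] + params$wci * c0)
    f <- sigmoid(A[r_f, , drop = FALSE] + params$wcf * c0)
    g <- tanh(A[r_g, , drop = FALSE])
    c1 <- f * c0 + i * g
    o_peep <- if (peephole_output == "prev") c0 else c1
    o <- sigmoid(A[r_o, , drop = FALSE] + params$wco * o_peep)
    tc <- tanh(c1)
    h1 <- o * tc
    cache$x[[t]] <- x_t
    cache$i[[t]] <- i; cache$f[[t]] <- f
    cache$o[[t]] <- o; cache$g[[t]] <- g
    cache$c[[t]] <- c1; cache$h[[t]] <- h1
    cache$tc[[t]] <- tc
    y[, t, ] <- params$Wy %*% h1 + params$by
    h0 <- h1; c0 <- c1
  }
  if (single) y <- matrix(y, n_out, T_len)
  list(y = y, cache = cache, final_state = list(h = h0, c = c0))
}

#' Mean squared error between output sequences
#'
#' Mean of squared elementwise differences over all timesteps, outputs and
#' batch elements. `NA` entries in `target` mark unscored positions and are
#' excluded from the mean.
#'
#' @param pred,target Equal-shaped numeric arrays.
#' @return Scalar loss.
#' @export
mse_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target)) {
    stop("pred and target shapes differ")
  }
  mean((pred - target)^2, na.rm = TRUE)
}

zero_like_params <- function(params) {
  g <- lapply(params, function(w) w * 0)
  attributes(g) <- attributes(params)
  g
}

# Backward pass through the cached forward; dY has the shape of y.
lstm_backward <- function(params, cache, dY) {
  H <- attr(params, "n_hidden")
  n_in <- attr(params, "n_in")
  n_out <- attr(params, "n_out")
  po <- cache$peephole_output
  T_len <- length(cache$x)
  B <- ncol(cache$x[[1]])
  dY <- array(dY, dim = c(n_out, T_len, B))
  g <- zero_like_params(params)
  Wh <- rbind(params$Whi, params$Whf, params$Whc, params$Who)
  gWx <- matrix(0, 4L * H, n_in)
  gWh <- matrix(0, 4L * H, H)
  gb <- numeric(4L * H)
  r_i <- seq_len(H); r_f <- H + r_i; r_g <- 2L * H + r_i; r_o <- 3L * H + r_i
  dh_next <- matrix(0, H, B)
  dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(T_len))) {
    c_prev <- if (t == 1L) cache$c0 else cache$c[[t - 1L]]
    h_prev <- if (t == 1L) cache$h0 else cache$h[[t - 1L]]
    i <- cache$i[[t]]; f <- cache$f[[t]]; o <- cache$o[[t]]
    gg <- cache$g[[t]]; tc <- cache$tc[[t]]
    dy <- matrix(dY[, t, ], n_out, B)
    g$Wy <- g$Wy + tcrossprod(dy, cache$h[[t]])
    g$by <- g$by + rowSums(dy)
    dh <- crossprod(params$Wy, dy) + dh_next
    do <- dh * tc
    da_o <- do * o * (1 - o)
    dc <- dc_next + dh * o * (1 - tc^2)
    if (po == "current") dc <- dc + params$wco * da_o
    da_i <- dc * gg * i * (1 - i)
    da_f <- dc * c_prev * f * (1 - f)
    da_g <- dc * i * (1 - gg^2)
    da <- rbind(da_i, da_f, da_g, da_o)
    gWx <- gWx + tcrossprod(da, cache$x[[t]])
    gWh <- gWh + tcrossprod(da, h_prev)
    gb <- gb + rowSums(da)
    g$wci <- g$wci + rowSums(da_i * c_prev)
    g$wcf <- g$wcf + rowSums(da_f * c_prev)
    g$wco <- g$wco + rowSums(da_o * (if (po == "prev") c_prev
                                     else cache$c[[t]]))
    dc_prev <- dc * f + params$wci * da_i + params$wcf * da_f
    if (po == "prev") dc_prev <- dc_prev + params$wco * da_o
    dh_next <- crossprod(Wh, da)
    dc_next <- dc_prev
  }
  g$Wxi <- gWx[r_i, , drop = FALSE]; g$Wxf <- gWx[r_f, , drop = FALSE]
  g$Wxc <- gWx[r_g, , drop = FALSE]; g$Wxo <- gWx[r_o, , drop = FALSE]
  g$Whi <- gWh[r_i, , drop = FALSE]; g$Whf <- gWh[r_f, , drop = FALSE]
  g$Whc <- gWh[r_g, , drop = FALSE]; g$Who <- gWh[r_o, , drop = FALSE]
  g$bi <- gb[r_i]; g$bf <- gb[r_f]; g$bc <- gb[r_g]; g$bo <- gb[r_o]
  g
}

#' Exact BPTT gradients of the MSE loss
#'
#' Runs the forward pass, forms the mean-squared-error loss against `targets`
#' (with `NA` entries unscored, e.g. for sequence-to-one prediction where
#' only the final step is supervised), and backpropagates through time to
#' return the analytic gradient for every parameter, including the three
#' peephole vectors, in both output-gate peephole variants.
#'
#' @param params An `lstm_params` bundle.
#' @param xs Inputs as in [lstm_forward()].
#' @param targets Array shaped like the forward output; `NA` = unscored.
#' @param init Initial state.
#' @param peephole_output See [cell_step()].
#' @return List with `grads` (an `lstm_params`-shaped list), `loss`, and the
#'   forward `y`.
#' @export
bptt_gradients <- function(params, xs, targets, init = NULL,
                           peephole_output = c("prev", "current")) {
  peephole_output <- match.arg(peephole_output)
  fwd <- lstm_forward(params, xs, init, peephole_output)
  y <- fwd$y
  if (length(y) != length(targets)) stop("targets shape mismatch")
  resid <- y - targets
  scored <- !is.na(resid)
  m <- sum(scored)
  if (m == 0L) stop("no scored target entries")
  loss <- sum(resid[scored]^2) / m
  dY <- resid * (2 / m)
  dY[!scored] <- 0
  grads <- lstm_backward(params, fwd$cache, dY)
  list(grads = grads, loss = loss, y = y)
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_grads <- function(grads, clip) {
  gn <- grad_global_norm(grads)
  if (is.finite(clip) && gn > clip) {
    grads <- lapply(grads, function(g) g * (clip / gn))
  }
  grads
}

#' Plain SGD parameter update with global-norm clipping
#'
#' @param params,grads Matching `lstm_params`-shaped lists.
#' @param lr Learning rate (> 0).
#' @param clip Maximum global gradient norm before scaling (default 5).
#' @return Updated parameters.
#' @export
sgd_update <- function(params, grads, lr, clip = 5) {
  if (lr <= 0) stop("lr must be positive")
  if (!all(vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradients: aborting update")
  }
  grads <- clip_grads(grads, clip)
  out <- params
  for (nm in names(params)) out[[nm]] <- params[[nm]] - lr * grads[[nm]]
  attributes(out) <- attributes(params)
  out
}

#' One Adam update step
#'
#' Adaptive-moment optimiser matching the TensorFlow-style training protocol
#' the prediction model was tuned under; gradient clipping as in
#' [sgd_update()] is applied first.
#'
#' @param params,grads Matching lists.
#' @param opt Optimiser state from a previous call, or `NULL` to start.
#' @param lr Base learning rate.
#' @param beta1,beta2,eps Adam moment-decay and stabilisation constants.
#' @param clip Maximum global gradient norm.
#' @return List with updated `params` and `opt` state.
#' @export
adam_update <- function(params, grads, opt = NULL, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, clip = 5) {
  if (lr <= 0) stop("lr must be positive")
  if (!all(vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
    stop("non-finite gradients: aborting update")
  }
  grads <- clip_grads(grads, clip)
  if (is.null(opt)) {
    opt <- list(m = lapply(params, function(w) w * 0),
                v = lapply(params, function(w) w * 0), t = 0L)
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  out <- params
  for (nm in names(params)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    out[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  attributes(out) <- attributes(params)
  list(params = out, opt = opt)
}

#' Finite-difference gradient check
#'
#' Compares the analytic BPTT gradient of every parameter group against
#' central finite differences of the loss, element by element. The relative
#' error uses `|a - n| / max(|a| + |n|, floor)`.
#'
#' @param params,xs,targets,init,peephole_output As in [bptt_gradients()].
#' @param eps Perturbation half-width.
#' @return Named numeric vector: max relative error per parameter group.
#' @export
lstm_gradient_check <- function(params, xs, targets, init = NULL,
                                peephole_output = c("prev", "current"),
                                eps = 1e-5) {
  peephole_output <- match.arg(peephole_output)
  analytic <- bptt_gradients(params, xs, targets, init, peephole_output)$grads
  loss_at <- function(p) {
    y <- lstm_forward(p, xs, init, peephole_output)$y
    mse_loss(y, targets)
  }
  errs <- vapply(names(params), function(nm) {
    w <- params[[nm]]
    num <- w * 0
    for (k in seq_along(w)) {
      p_hi <- params; p_hi[[nm]][k] <- w[k] + eps
      attributes(p_hi) <- attributes(params)
      p_lo <- params; p_lo[[nm]][k] <- w[k] - eps
      attributes(p_lo) <- attributes(params)
      num[k] <- (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps)
    }
    a <- analytic[[nm]]
    max(abs(a - num) / pmax(abs(a) + abs(num), 1e-4))
  }, numeric(1))
  errs
}
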