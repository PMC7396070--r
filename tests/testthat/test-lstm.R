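# Independent transcription of one cell step, written directly from the
# gate equations with no shared code, used as an oracle below.
naive_cell <- function(p, x, h0, c0, peephole_output = "prev") {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(p$Wxi %*% x + p$Whi %*% h0 + p$wci * c0 + p$bi)
  f <- sg(p$Wxf %*% x + p$Whf %*% h0 + p$wcf * c0 + p$bf)
  c1 <- f * c0 + i * tanh(p$Wxc %*% x + p$Whc %*% h0 + p$bc)
  cpeep <- if (peephole_output == "prev") c0 else c1
  o <- sg(p$Wxo %*% x + p$Who %*% h0 + p$wco * cpeep + p$bo)
  list(h = o * tanh(c1), c = c1, i = i, f = f, o = o)
}

# Independent standard (non-peephole) LSTM step, for the reduction oracle.
naive_standard_cell <- function(p, x, h0, c0) {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(p$Wxi %*% x + p$Whi %*% h0 + p$bi)
  f <- sg(p$Wxf %*% x + p$Whf %*% h0 + p$bf)
  c1 <- f * c0 + i * tanh(p$Wxc %*% x + p$Whc %*% h0 + p$bc)
  o <- sg(p$Wxo %*% x + p$Who %*% h0 + p$bo)
  list(h = o * tanh(c1), c = c1)
}

test_that("sigmoid matches the logistic formula and saturates silently", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 1 / (1 + exp(-1)))
  expect_equal(sigmoid(1), 0.7310586, tolerance = 1e-6)
  expect_no_warning(lo <- sigmoid(-1000))
  expect_equal(lo, 0)
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(c(-700, 700)), c(0, 1), tolerance = 1e-12)
})

test_that("zero-parameter cell gives half-open gates and zero state", {
  p <- lstm_init(3, 5, 2, seed = 1)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  st <- cell_step(p, c(1, -2, 3))
  expect_equal(as.numeric(st$gates$i), rep(0.5, 5))
  expect_equal(as.numeric(st$gates$f), rep(0.5, 5))
  expect_equal(as.numeric(st$gates$o), rep(0.5, 5))
  expect_equal(as.numeric(st$state$c), rep(0, 5))
  expect_equal(as.numeric(st$state$h), rep(0, 5))
})

test_that("saturated gates implement perfect memory", {
  p <- lstm_init(2, 4, 1, seed = 2)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  p$bf <- rep(50, 4)   # f -> 1
  p$bi <- rep(-50, 4)  # i -> 0
  p$bo <- rep(-50, 4)  # o -> 0
  prev <- list(h = rep(0.3, 4), c = c(1, -2, 0.5, 3))
  st <- cell_step(p, c(0.7, -0.1), prev)
  expect_equal(as.numeric(st$state$c), prev$c, tolerance = 1e-12)
  expect_lt(max(abs(st$state$h)), 1e-12)
})

test_that("cell_step matches an independent transcription on random
          instances, in both peephole variants", {
  set.seed(31)
  for (po in c("prev", "current")) {
    for (k in 1:10) {
      p <- lstm_init(2, 3, 1, seed = 100 + k)
      p$wci <- runif(3, -0.5, 0.5)
      p$wcf <- runif(3, -0.5, 0.5)
      p$wco <- runif(3, -0.5, 0.5)
      x <- rnorm(2)
      h0 <- matrix(rnorm(3) * 0.5)
      c0 <- matrix(rnorm(3))
      got <- cell_step(p, x, list(h = h0, c = c0), peephole_output = po)
      want <- naive_cell(p, x, h0, c0, po)
      expect_equal(as.numeric(got$state$h), as.numeric(want$h),
                   tolerance = 1e-14)
      expect_equal(as.numeric(got$state$c), as.numeric(want$c),
                   tolerance = 1e-14)
      expect_equal(as.numeric(got$gates$i), as.numeric(want$i),
                   tolerance = 1e-14)
    }
  }
})

test_that("zeroed peephole weights reduce exactly to the standard LSTM", {
  for (k in 1:5) {
    p <- lstm_init(3, 4, 2, seed = 40 + k)
    p$wci <- p$wci * 0; p$wcf <- p$wcf * 0; p$wco <- p$wco * 0
    x <- rnorm(3); h0 <- matrix(rnorm(4) * 0.3); c0 <- matrix(rnorm(4))
    got <- cell_step(p, x, list(h = h0, c = c0))
    want <- naive_standard_cell(p, x, h0, c0)
    expect_equal(as.numeric(got$state$h), as.numeric(want$h),
                 tolerance = 1e-14)
    expect_equal(as.numeric(got$state$c), as.numeric(want$c),
                 tolerance = 1e-14)
  }
})

test_that("forward pass composes cell steps with the linear readout", {
  p <- lstm_init(2, 3, 2, seed = 50)
  xs <- matrix(rnorm(2 * 4), 2, 4)
  fwd <- lstm_forward(p, xs)
  # length-1 base case equals one cell_step plus readout
  one <- lstm_forward(p, xs[, 1, drop = FALSE])
  st <- cell_step(p, xs[, 1])
  expect_equal(as.numeric(one$y), as.numeric(p$Wy %*% st$state$h + p$by),
               tolerance = 1e-14)
  # manual composition over all steps
  state <- NULL
  for (t in 1:4) {
    st <- cell_step(p, xs[, t], state)
    expect_equal(as.numeric(fwd$y[, t]),
                 as.numeric(p$Wy %*% st$state$h + p$by), tolerance = 1e-13)
    state <- st$state
  }
  # determinism: same inputs, bit-identical outputs
  expect_identical(fwd$y, lstm_forward(p, xs)$y)
  # zero network outputs the readout bias everywhere
  p0 <- p
  for (nm in names(p0)) p0[[nm]] <- p0[[nm]] * 0
  p0$by <- c(0.3, -0.7)
  y0 <- lstm_forward(p0, xs)$y
  expect_equal(y0, matrix(c(0.3, -0.7), 2, 4), tolerance = 1e-14)
  # hidden activations stay inside (-1, 1)
  expect_lt(max(abs(unlist(fwd$cache$h))), 1)
  expect_error(lstm_forward(p, matrix(numeric(0), 2, 0)), "empty")
})

test_that("mse_loss equals the brute-force double loop", {
  a <- matrix(1:6 / 7, 2, 3)
  expect_equal(mse_loss(a, a), 0)
  expect_equal(mse_loss(a + 2, a), 4)
  set.seed(61)
  p <- matrix(rnorm(12), 3, 4)
  q <- matrix(rnorm(12), 3, 4)
  acc <- 0
  for (i in 1:3) for (j in 1:4) acc <- acc + (p[i, j] - q[i, j])^2
  expect_equal(mse_loss(p, q), acc / 12, tolerance = 1e-14)
})

test_that("analytic BPTT gradients match central finite differences for
          every parameter group and both peephole variants", {
  for (po in c("prev", "current")) {
    prob <- small_lstm_problem(seed = if (po == "prev") 7 else 8)
    errs <- lstm_gradient_check(prob$params, prob$xs, prob$targets,
                                peephole_output = po)
    expect_true(all(errs < 1e-5), info = paste(po, "max err", max(errs)))
    expect_setequal(names(errs), names(prob$params))
  }
})

test_that("gradient check passes with sequence-to-one (NA-masked) targets", {
  prob <- small_lstm_problem(seed = 9)
  tg <- prob$targets
  tg[, 1:5] <- NA  # only the final step supervised
  errs <- lstm_gradient_check(prob$params, prob$xs, tg)
  expect_true(all(errs < 1e-5))
})

test_that("zero-parameter zero-target gradients vanish except the readout
          bias path", {
  p <- lstm_init(3, 4, 2, seed = 70)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  p$by <- c(1, -1)
  xs <- matrix(rnorm(3 * 5), 3, 5)
  tg <- matrix(0, 2, 5)
  g <- bptt_gradients(p, xs, tg)$grads
  # prediction is constant by; all weight-matrix gradients vanish because
  # h == 0 throughout
  expect_equal(max(abs(g$Wy)), 0)
  expect_equal(max(abs(g$Wxc)), 0)
  expect_equal(max(abs(g$Whc)), 0)
  expect_equal(g$by, c(2, -2) / 10 * 5, tolerance = 1e-12)
})

test_that("with peepholes frozen at zero the remaining gradients equal an
          independently coded standard-LSTM BPTT", {
  # independent oracle: numeric differentiation of a naive standard-LSTM
  # loss, no shared forward code
  naive_loss <- function(p, xs, tg) {
    h <- matrix(0, length(p$bi), 1)
    cc <- h
    total <- 0
    for (t in seq_len(ncol(xs))) {
      st <- naive_standard_cell(p, xs[, t], h, cc)
      h <- st$h; cc <- st$c
      y <- p$Wy %*% h + p$by
      total <- total + sum((y - tg[, t])^2)
    }
    total / length(tg)
  }
  p <- lstm_init(2, 3, 1, seed = 80)
  p$wci <- p$wci * 0; p$wcf <- p$wcf * 0; p$wco <- p$wco * 0
  set.seed(81)
  xs <- matrix(rnorm(2 * 5), 2, 5)
  tg <- matrix(rnorm(5), 1, 5)
  g <- bptt_gradients(p, xs, tg)$grads
  eps <- 1e-6
  for (nm in c("Wxi", "Whf", "Wxc", "Who", "bi", "bc", "Wy", "by")) {
    for (k in seq_along(p[[nm]])) {
      hi <- p; hi[[nm]][k] <- hi[[nm]][k] + eps
      lo <- p; lo[[nm]][k] <- lo[[nm]][k] - eps
      num <- (naive_loss(hi, xs, tg) - naive_loss(lo, xs, tg)) / (2 * eps)
      expect_lt(abs(g[[nm]][k] - num) /
                  max(abs(g[[nm]][k]) + abs(num), 1e-3), 1e-5)
    }
  }
})

test_that("sgd_update subtracts lr * grads with global-norm clipping", {
  p <- lstm_init(2, 2, 1, seed = 90)
  z <- lapply(p, function(w) w * 0)
  expect_equal(unclass(sgd_update(p, z, lr = 0.1))[names(p)],
               unclass(p)[names(p)], tolerance = 1e-15)
  # norm-10 gradient clipped to 5 scales the step by one half
  g <- z
  g$by <- 10  # single nonzero entry: global norm 10
  upd <- sgd_update(p, g, lr = 1, clip = 5)
  expect_equal(upd$by, p$by - 5)
  # closed-form descent on a scalar quadratic: L = (w - 3)^2, dL/dw = 2(w-3)
  g2 <- z
  g2$by <- 2 * (p$by - 3)
  upd2 <- sgd_update(p, g2, lr = 0.25, clip = Inf)
  expect_equal(upd2$by, p$by - 0.5 * (p$by - 3), tolerance = 1e-12)
  g_bad <- z
  g_bad$Wy[1] <- NaN
  expect_error(sgd_update(p, g_bad, lr = 0.1), "non-finite")
})

test_that("adam_update descends a quadratic and respects its step cap", {
  p <- lstm_init(1, 1, 1, seed = 91)
  z <- lapply(p, function(w) w * 0)
  g <- z
  g$by <- 4
  upd <- adam_update(p, g, NULL, lr = 0.01)
  # first Adam step has magnitude ~lr regardless of gradient scale
  expect_equal(as.numeric(p$by - upd$params$by), 0.01, tolerance = 1e-6)
  # iterating reduces the quadratic loss
  w <- p$by
  opt <- NULL
  cur <- p
  for (k in 1:200) {
    g$by <- 2 * (cur$by - 3)
    st <- adam_update(cur, g, opt, lr = 0.05)
    cur <- st$params
    opt <- st$opt
  }
  expect_lt(abs(cur$by - 3), abs(w - 3))
})

test_that("model JSON serialisation round-trips weights exactly", {
  s <- lagged_copy_series(n = 200)
  cfg <- fast_config(max_iters = 30)
  sp <- split_train_eval(make_windows(s, cfg), 0.8)
  fit <- train_model(sp$train, cfg)
  f <- tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  for (nm in names(fit$params)) {
    expect_identical(unname(back$params[[nm]]), unname(fit$params[[nm]]))
  }
  p1 <- predict_windows(fit, sp$eval)$pred
  p2 <- predict_windows(back, sp$eval)$pred
  expect_identical(p1, p2)
  unlink(f)
})
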