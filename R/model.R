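#' Network and training configuration
#'
#' The final-stage prediction model is a shallow feed-forward network: an
#' input layer of predictor encodings, one densely connected hidden layer of
#' 32 logistic (sigmoid) units with L2 = 1e-4 kernel regularization on both
#' weight matrices (not biases), and a single logistic output unit trained
#' with binary cross-entropy under Adamax. Training runs in two phases:
#' first with a patient-month batch size of 2^7 and early stopping at
#' patience 2 on test-set loss, then -- continuing from the restored
#' best-test-loss weights -- with batch size 2^14 and patience 4.
#'
#' @param hidden_nodes hidden-layer width.
#' @param l2_penalty L2 kernel regularization coefficient (loss adds
#'   `l2_penalty * sum(W^2)` per weight matrix).
#' @param phase1_batch,phase2_batch mini-batch sizes of the two phases.
#' @param phase1_patience,phase2_patience epochs without test-loss
#'   improvement tolerated before stopping each phase.
#' @param max_epochs per-phase epoch cap (safety net; early stopping is the
#'   intended terminator).
#' @param learning_rate,beta1,beta2,epsilon Adamax hyper-parameters
#'   (Keras-style defaults; the optimizer state is reset at the phase
#'   boundary).
#' @param train_seed seed controlling weight initialization and the
#'   within-epoch shuffle.
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden_nodes = 32L, l2_penalty = 1e-4,
                         phase1_batch = 2L^7L, phase1_patience = 2L,
                         phase2_batch = 2L^14L, phase2_patience = 4L,
                         max_epochs = 100L,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, train_seed = 1L) {
  stopifnot(hidden_nodes >= 1, l2_penalty >= 0,
            phase1_batch >= 1, phase2_batch >= 1,
            phase1_patience >= 1, phase2_patience >= 1, max_epochs >= 1)
  structure(list(hidden_nodes = as.integer(hidden_nodes), l2_penalty = l2_penalty,
                 phase1_batch = as.integer(phase1_batch),
                 phase1_patience = as.integer(phase1_patience),
                 phase2_batch = as.integer(phase2_batch),
                 phase2_patience = as.integer(phase2_patience),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, train_seed = as.integer(train_seed)),
            class = "model_config")
}

#' Build an untrained shallow network
#'
#' Glorot-uniform weight initialization seeded from `cfg$train_seed`; two
#' builds from the same seed produce identical initial weights. Parameter
#' count is `input_width * h + h + h + 1` for `h` hidden nodes.
#'
#' @param input_width number of predictor encodings (columns).
#' @param cfg a [model_config()].
#' @param columns optional column-name vector recorded for scoring-time
#'   checks.
#' @return object of class `risk_model`.
#' @export
build_network <- function(input_width, cfg = model_config(), columns = NULL) {
  if (input_width < 1) stop("input_width must be at least 1")
  h <- cfg$hidden_nodes
  withr::with_seed(derive_seed(cfg$train_seed, 101L), {
    lim1 <- sqrt(6 / (input_width + h))
    W1 <- matrix(runif(input_width * h, -lim1, lim1), input_width, h)
    lim2 <- sqrt(6 / (h + 1))
    W2 <- matrix(runif(h, -lim2, lim2), h, 1)
  })
  structure(list(W1 = W1, b1 = rep(0, h), W2 = W2, b2 = 0,
                 columns = columns, config = cfg, trace = NULL,
                 trained = FALSE),
            class = "risk_model")
}

#' Number of trainable parameters
#' @param model a `risk_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", nrow(x$W1), "inputs ->", ncol(x$W1), "sigmoid ->",
      "1 sigmoid;", n_parameters(x), "parameters;",
      if (isTRUE(x$trained)) "trained" else "untrained", "\n")
  invisible(x)
}

nn_forward <- function(model, x) {
  H <- plogis(sweep(x %*% model$W1, 2, model$b1, `+`))
  p <- plogis(as.vector(H %*% model$W2) + model$b2)
  list(H = H, p = p)
}

# full-objective loss: BCE + L2 on both kernels (biases unpenalized)
nn_objective <- function(model, x, y, l2) {
  bce_loss(nn_forward(model, x)$p, y) +
    l2 * (sum(model$W1^2) + sum(model$W2^2))
}

adamax_init <- function(model) {
  list(m = lapply(model[c("W1", "b1", "W2", "b2")], function(w) w * 0),
       u = lapply(model[c("W1", "b1", "W2", "b2")], function(w) w * 0),
       t = 0L)
}

adamax_step <- function(model, grads, st, cfg) {
  st$t <- st$t + 1L
  corr <- 1 - cfg$beta1 ^ st$t
  for (nm in c("W1", "b1", "W2", "b2")) {
    st$m[[nm]] <- cfg$beta1 * st$m[[nm]] + (1 - cfg$beta1) * grads[[nm]]
    st$u[[nm]] <- pmax(cfg$beta2 * st$u[[nm]], abs(grads[[nm]]))
    model[[nm]] <- model[[nm]] -
      (cfg$learning_rate / corr) * st$m[[nm]] / (st$u[[nm]] + cfg$epsilon)
  }
  list(model = model, state = st)
}

nn_gradients <- function(model, xb, yb, l2) {
  nb <- nrow(xb)
  fw <- nn_forward(model, xb)
  dz2 <- (fw$p - yb) / nb                     # d(meanBCE)/d(preact2)
  gW2 <- crossprod(fw$H, dz2) + 2 * l2 * model$W2
  gb2 <- sum(dz2)
  dH <- matrix(dz2, ncol = 1) %*% t(model$W2)  # nb x h
  dz1 <- dH * fw$H * (1 - fw$H)
  gW1 <- crossprod(xb, dz1) + 2 * l2 * model$W1
  gb1 <- colSums(dz1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

run_phase <- function(model, x_train, y_train, x_test, y_test, cfg,
                      batch, patience, phase_id) {
  st <- adamax_init(model)
  best <- list(model = model,
               loss = bce_loss(nn_forward(model, x_test)$p, y_test),
               epoch = 0L)
  wait <- 0L
  ntr <- nrow(x_train)
  trace <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- withr::with_seed(derive_seed(cfg$train_seed, 1000L * phase_id + epoch),
                            sample.int(ntr))
    starts <- seq(1L, ntr, by = batch)
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, ntr)]
      g <- nn_gradients(model, x_train[idx, , drop = FALSE], y_train[idx],
                        cfg$l2_penalty)
      upd <- adamax_step(model, g, st, cfg)
      model <- upd$model; st <- upd$state
    }
    train_loss <- bce_loss(nn_forward(model, x_train)$p, y_train)
    test_loss <- bce_loss(nn_forward(model, x_test)$p, y_test)
    improved <- test_loss < best$loss
    trace[[epoch]] <- data.table(phase = phase_id, epoch = epoch,
                                 train_loss = train_loss, test_loss = test_loss,
                                 improved = improved)
    if (improved) {
      best <- list(model = model, loss = test_loss, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  tr <- rbindlist(trace[!vapply(trace, is.null, logical(1))])
  tr[, restored := epoch == best$epoch]
  list(model = best$model, trace = tr, best_epoch = best$epoch,
       best_loss = best$loss)
}

#' Train the network with the two-phase batch/early-stopping protocol
#'
#' Phase 1 trains at `phase1_batch` with early stopping (patience
#' `phase1_patience`) monitored on test-set binary cross-entropy; the
#' best-test-loss weights are restored, then phase 2 continues from them at
#' `phase2_batch` with patience `phase2_patience` and restores its own best
#' weights. The per-epoch train/test losses of both phases are kept in
#' `model$trace` with the restored epochs flagged.
#'
#' @param model an untrained [build_network()] model.
#' @param x_train,x_test numeric design matrices with identical columns.
#' @param y_train,y_test binary outcome vectors.
#' @param cfg a [model_config()]; defaults to the one inside `model`.
#' @return the trained `risk_model`.
#' @export
train_network <- function(model, x_train, y_train, x_test, y_test,
                          cfg = model$config) {
  if (!identical(colnames(x_train), colnames(x_test)))
    stop("training and test matrices must share identical columns")
  if (nrow(x_test) == 0L) stop("empty test set: early stopping is undefined")
  if (length(unique(y_train)) < 2L)
    stop("training labels are all ", y_train[1],
         ": cannot fit a binary outcome model")
  stopifnot(nrow(x_train) == length(y_train), nrow(x_test) == length(y_test),
            all(y_train %in% 0:1), all(y_test %in% 0:1))
  model$columns <- colnames(x_train)

  p1 <- run_phase(model, x_train, y_train, x_test, y_test, cfg,
                  cfg$phase1_batch, cfg$phase1_patience, 1L)
  p2 <- run_phase(p1$model, x_train, y_train, x_test, y_test, cfg,
                  cfg$phase2_batch, cfg$phase2_patience, 2L)
  out <- p2$model
  out$config <- cfg
  out$trace <- rbind(p1$trace, p2$trace)
  out$best <- list(phase1 = c(epoch = p1$best_epoch, test_loss = p1$best_loss),
                   phase2 = c(epoch = p2$best_epoch, test_loss = p2$best_loss))
  out$trained <- TRUE
  out
}

#' Score patient-months as endpoint probabilities
#'
#' Deterministic logistic forward pass; the output unit's pre-activation is
#' on the logit scale and is mapped to a probability by the logistic link.
#'
#' @param model a `risk_model`.
#' @param x a design matrix (or [assemble_design_matrix()] result) whose
#'   columns match the training plan.
#' @return numeric probability vector in (0, 1).
#' @export
predict_risk <- function(model, x) {
  if (inherits(x, "design_matrix")) x <- x$x
  if (!is.null(model$columns) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$columns)) {
    missing <- setdiff(model$columns, colnames(x))
    extra <- setdiff(colnames(x), model$columns)
    stop("design-matrix columns do not match the trained model",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
  }
  if (ncol(x) != nrow(model$W1))
    stop("design matrix has ", ncol(x), " columns; model expects ", nrow(model$W1))
  nn_forward(model, x)$p
}
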