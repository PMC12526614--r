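# Binary classifiers for the squat tensor: an LSTM sequence network
# (hand-rolled forward pass, backpropagation through time, and Adam) and a
# soft-margin RBF-kernel SVM (libsvm via e1071; the model contract is the
# returned KKT residual).

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Training configuration for the classifiers
#'
#' The source protocol states no hyperparameters; these are small-data
#' defaults, logged with every model and report for reproducibility.
#'
#' @param hidden LSTM hidden units.
#' @param epochs Training epochs.
#' @param batch Mini-batch size.
#' @param lr Adam learning rate.
#' @param split Training fraction of the stratified train/test split.
#' @param seed Integer seed for initialization, shuffling and the split.
#' @param class_weights Reweight classes inversely to frequency (off by
#'   default, matching the unweighted protocol).
#' @param svm_cost Soft-margin penalty C.
#' @param svm_gamma RBF kernel width; default `NULL` uses
#'   `1 / (n_inputs * mean feature variance)`.
#' @param svm_tolerance SMO termination tolerance; the KKT residual contract
#'   (1e-3) is checked against the trained model.
#' @return A `train_config` list.
#' @export
train_config <- function(hidden = 32L, epochs = 100L, batch = 32L, lr = 1e-3,
                         split = 0.8, seed = 1L, class_weights = FALSE,
                         svm_cost = 1, svm_gamma = NULL, svm_tolerance = 1e-4) {
  abort_if(split <= 0 || split >= 1,
           "configuration error: split fraction must lie in (0, 1)")
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, split = split,
                 seed = as.integer(seed), class_weights = class_weights,
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 svm_tolerance = svm_tolerance),
            class = "train_config")
}

#' Initialize LSTM parameters
#'
#' Uniform `(-r, r)` initialization with `r = 1/sqrt(hidden)`; the forget-gate
#' bias starts at 1 so early training retains memory.
#'
#' @param m Input channels per time step.
#' @param h Hidden units.
#' @return An `lstm_params` list of weight matrices
#'   (`Wui`,`Whi`,`bi`, ... for input/forget/output gates and the input node)
#'   plus the fully connected layer `Wfc` (h x 2), `bfc`.
#' @export
lstm_params <- function(m, h) {
  r <- 1 / sqrt(h)
  mat <- function(a, b) matrix(stats::runif(a * b, -r, r), a, b)
  p <- list(
    Wui = mat(m, h), Whi = mat(h, h), bi = numeric(h),
    Wuf = mat(m, h), Whf = mat(h, h), bf = rep(1, h),
    Wuo = mat(m, h), Who = mat(h, h), bo = numeric(h),
    Wuc = mat(m, h), Whc = mat(h, h), bc = numeric(h),
    Wfc = mat(h, 2), bfc = numeric(2)
  )
  structure(c(p, list(m = as.integer(m), h = as.integer(h))),
            class = "lstm_params")
}

add_bias <- function(z, b) sweep(z, 2, b, "+")

#' One LSTM cell step
#'
#' Gate equations: input gate `X = sigma(U Wui + H Whi + bi)`, forget gate
#' `F` and output gate `Y` analogous (sigmoid keeps them in (0,1)); input
#' node `G = tanh(U Wuc + H Whc + bc)` in (-1,1); cell update
#' `C = F * C_prev + X * G`; hidden state `H = Y * tanh(C)` in (-1,1).
#'
#' @param U Input at this step, `k x m` matrix (or length-m vector).
#' @param state List with `H` and `C` (`k x h` matrices).
#' @param params An `lstm_params`.
#' @param cache Return gate activations alongside the state.
#' @return Updated state list (`H`, `C`, and the gates when `cache = TRUE`).
#' @export
lstm_cell_step <- function(U, state, params, cache = FALSE) {
  if (is.null(dim(U))) U <- matrix(U, 1)
  abort_if(ncol(U) != params$m, "lstm_cell_step: input has ", ncol(U),
           " channels, params expect ", params$m)
  Hp <- state$H; Cp <- state$C
  X <- sigmoid(add_bias(U %*% params$Wui + Hp %*% params$Whi, params$bi))
  F_ <- sigmoid(add_bias(U %*% params$Wuf + Hp %*% params$Whf, params$bf))
  Y <- sigmoid(add_bias(U %*% params$Wuo + Hp %*% params$Who, params$bo))
  G <- tanh(add_bias(U %*% params$Wuc + Hp %*% params$Whc, params$bc))
  C <- F_ * Cp + X * G
  tC <- tanh(C)
  H <- Y * tC
  if (cache) list(H = H, C = C, X = X, F_ = F_, Y = Y, G = G, tC = tC,
                  Hp = Hp, Cp = Cp, U = U)
  else list(H = H, C = C)
}

# Unrolled forward pass over a k x T x m batch; returns logits, softmax
# probabilities and (optionally) the per-step caches for BPTT.
lstm_forward_batch <- function(x, params, cache = FALSE) {
  k <- dim(x)[1]; Tn <- dim(x)[2]
  state <- list(H = matrix(0, k, params$h), C = matrix(0, k, params$h))
  caches <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    st <- lstm_cell_step(matrix(x[, t, ], k, params$m),
                         state, params, cache = cache)
    if (cache) caches[[t]] <- st
    state <- list(H = st$H, C = st$C)
  }
  logits <- add_bias(state$H %*% params$Wfc, params$bfc)
  pm <- apply(logits, 1, max)
  e <- exp(logits - pm)
  probs <- e / rowSums(e)
  list(logits = logits, probs = probs, H = state$H, caches = caches)
}

#' LSTM forward pass for one squat sequence
#'
#' Unrolls the cell from a zero initial state over the sequence, passes the
#' final hidden state through the fully connected layer and softmax.
#'
#' @param sequence `T x m` matrix (one squat; T = 20 in the pipeline).
#' @param params An `lstm_params`.
#' @return List with `score` (probability of class KI), `probs` (both
#'   classes, summing to 1) and `logits`.
#' @export
lstm_forward <- function(sequence, params) {
  sequence <- as.matrix(sequence)
  abort_if(ncol(sequence) != params$m,
           "lstm_forward: sequence has ", ncol(sequence),
           " channels, params expect ", params$m)
  x <- array(sequence, c(1, nrow(sequence), ncol(sequence)))
  fw <- lstm_forward_batch(x, params)
  list(score = fw$probs[1, 2], probs = fw$probs[1, ], logits = fw$logits[1, ])
}

# Cross-entropy loss and full parameter gradient for a batch (BPTT).
lstm_loss_grad <- function(x, y, params, weights = NULL) {
  k <- dim(x)[1]; Tn <- dim(x)[2]
  fw <- lstm_forward_batch(x, params, cache = TRUE)
  w <- weights %||% rep(1, k)
  py <- fw$probs[cbind(seq_len(k), y + 1L)]
  loss <- -sum(w * log(pmax(py, 1e-12))) / sum(w)
  Yk <- matrix(0, k, 2); Yk[cbind(seq_len(k), y + 1L)] <- 1
  dlogits <- (fw$probs - Yk) * w / sum(w)

  g <- lapply(params[1:14], function(p) p * 0)
  g$Wfc <- t(fw$H) %*% dlogits
  g$bfc <- colSums(dlogits)
  dH <- dlogits %*% t(params$Wfc)
  dC <- matrix(0, k, params$h)
  for (t in rev(seq_len(Tn))) {
    cc <- fw$caches[[t]]
    dY <- dH * cc$tC
    dC <- dC + dH * cc$Y * (1 - cc$tC^2)
    dX <- dC * cc$G
    dF <- dC * cc$Cp
    dG <- dC * cc$X
    dCp <- dC * cc$F_
    dXp <- dX * cc$X * (1 - cc$X)
    dFp <- dF * cc$F_ * (1 - cc$F_)
    dYp <- dY * cc$Y * (1 - cc$Y)
    dGp <- dG * (1 - cc$G^2)
    g$Wui <- g$Wui + t(cc$U) %*% dXp; g$Whi <- g$Whi + t(cc$Hp) %*% dXp
    g$bi <- g$bi + colSums(dXp)
    g$Wuf <- g$Wuf + t(cc$U) %*% dFp; g$Whf <- g$Whf + t(cc$Hp) %*% dFp
    g$bf <- g$bf + colSums(dFp)
    g$Wuo <- g$Wuo + t(cc$U) %*% dYp; g$Who <- g$Who + t(cc$Hp) %*% dYp
    g$bo <- g$bo + colSums(dYp)
    g$Wuc <- g$Wuc + t(cc$U) %*% dGp; g$Whc <- g$Whc + t(cc$Hp) %*% dGp
    g$bc <- g$bc + colSums(dGp)
    dH <- dXp %*% t(params$Whi) + dFp %*% t(params$Whf) +
      dYp %*% t(params$Who) + dGp %*% t(params$Whc)
    dC <- dCp
  }
  list(loss = loss, grad = g)
}

#' Train the LSTM classifier
#'
#' Minimizes softmax cross-entropy by mini-batch gradient descent with
#' adaptive moment estimation (Adam); deterministic for a fixed seed.
#'
#' @param dataset A `labeled_dataset` containing both classes (or a plain
#'   `n x T x m` array passed with `labels`).
#' @param cfg A [train_config()].
#' @param labels Optional label vector when `dataset` is a plain array.
#' @return A `squat_lstm` model: `params`, `loss_trace` (mean loss per
#'   epoch), `feature_ids`, `cfg`.
#' @export
train_lstm <- function(dataset, cfg = train_config(), labels = NULL) {
  if (inherits(dataset, "labeled_dataset")) {
    x <- dataset$x; y <- dataset$labels; ids <- dataset$feature_ids
  } else {
    x <- dataset; y <- labels; ids <- seq_len(dim(x)[3])
  }
  abort_if(length(unique(y)) < 2, "train_lstm: single-class training labels")
  n <- dim(x)[1]
  w <- if (isTRUE(cfg$class_weights)) {
    n / (2 * ifelse(y == 1, sum(y == 1), sum(y == 0)))
  } else NULL
  with_seed(cfg$seed, {
    params <- lstm_params(dim(x)[3], cfg$hidden)
    mom <- lapply(params[1:14], function(p) p * 0)
    vel <- lapply(params[1:14], function(p) p * 0)
    step <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    loss_trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1, n)]
        lg <- lstm_loss_grad(x[idx, , , drop = FALSE], y[idx], params, w[idx])
        losses <- c(losses, lg$loss)
        step <- step + 1
        for (nm in names(mom)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * lg$grad[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * lg$grad[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_trace[ep] <- mean(losses)
    }
    structure(list(params = params, loss_trace = loss_trace,
                   feature_ids = ids, cfg = cfg),
              class = "squat_lstm")
  })
}

#' @export
print.squat_lstm <- function(x, ...) {
  cat(sprintf("<squat_lstm> features {%s}, %d hidden units, %d epochs, final loss %.4f\n",
              paste(x$feature_ids, collapse = ","), x$params$h,
              length(x$loss_trace), x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

flatten_tensor <- function(x) {
  matrix(x, dim(x)[1], dim(x)[2] * dim(x)[3])
}

#' Train the RBF-kernel SVM classifier
#'
#' Sequences are flattened to `T * m` vectors and fed to a soft-margin SVM
#' with Gaussian kernel `k(u1, u2) = exp(-gamma * ||u1 - u2||^2)`, solved by
#' libsvm's SMO-type decomposition (e1071).  The returned model records the
#' maximum KKT violation of the dual solution over the training set; the
#' solver is run at tolerance 1e-4 so residuals stay within the 1e-3
#' contract.
#'
#' @param dataset A `labeled_dataset` with both classes (or plain array plus
#'   `labels`).
#' @param cfg A [train_config()]; `svm_cost` and `svm_gamma` apply.
#' @param labels Optional label vector for plain-array input.
#' @return A `squat_svm` model: the fitted libsvm object, `gamma`, `cost`,
#'   `kkt_residual`, `feature_ids`, `cfg`.
#' @export
train_svm <- function(dataset, cfg = train_config(), labels = NULL) {
  if (inherits(dataset, "labeled_dataset")) {
    x <- dataset$x; y <- dataset$labels; ids <- dataset$feature_ids
  } else {
    x <- dataset; y <- labels; ids <- seq_len(dim(x)[3])
  }
  abort_if(length(unique(y)) < 2, "train_svm: single-class training labels")
  xf <- flatten_tensor(x)
  mv <- mean(apply(xf, 2, stats::var))
  gamma <- cfg$svm_gamma %||% (1 / (ncol(xf) * max(mv, .Machine$double.eps)))
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(cfg$seed, {
    e1071::svm(xf, yf, type = "C-classification", kernel = "radial",
               gamma = gamma, cost = cfg$svm_cost, scale = FALSE,
               tolerance = cfg$svm_tolerance %||% 1e-4)
  })
  model <- structure(list(fit = fit, gamma = gamma, cost = cfg$svm_cost,
                          feature_ids = ids, cfg = cfg,
                          kkt_residual = NA_real_),
                     class = "squat_svm")
  f <- svm_decision(model, xf)
  ypm <- ifelse(y == 1, 1, -1)
  alpha <- numeric(nrow(xf))
  alpha[fit$index] <- abs(fit$coefs[, 1])
  yf_margin <- ypm * f
  tolb <- 1e-6 * cfg$svm_cost
  viol <- ifelse(alpha <= tolb, pmax(0, 1 - yf_margin),
                 ifelse(alpha >= cfg$svm_cost - tolb, pmax(0, yf_margin - 1),
                        abs(yf_margin - 1)))
  model$kkt_residual <- max(viol)
  model
}

# Decision values oriented so that positive means class KI ("1").
svm_decision <- function(model, xf) {
  pr <- stats::predict(model$fit, xf, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (grepl("^1/", colnames(dv)[1])) 1 else -1
  sgn * dv[, 1]
}

#' @export
print.squat_svm <- function(x, ...) {
  cat(sprintf("<squat_svm> features {%s}, RBF gamma %.4g, C %.3g, %d SVs, KKT residual %.2g\n",
              paste(x$feature_ids, collapse = ","), x$gamma, x$cost,
              x$fit$tot.nSV, x$kkt_residual))
  invisible(x)
}

check_feature_match <- function(model, dataset) {
  ids <- if (inherits(dataset, "labeled_dataset")) dataset$feature_ids
         else seq_len(dim(dataset)[3])
  abort_if(!identical(as.integer(ids), as.integer(model$feature_ids)),
           "feature-set mismatch: model expects features {",
           paste(model$feature_ids, collapse = ","), "}, data has {",
           paste(ids, collapse = ","), "}")
}

dataset_tensor <- function(dataset) {
  if (inherits(dataset, "labeled_dataset")) dataset$x else dataset
}

#' Predict instability scores and labels
#'
#' LSTM scores are softmax probabilities of class KI with hard labels at
#' `score >= 0.5`; SVM margins are mapped through a logistic link with hard
#' labels at `margin >= 0`.
#'
#' @param object A `squat_lstm` or `squat_svm` model.
#' @param dataset A `labeled_dataset` (or plain array) with the feature set
#'   the model was trained on.
#' @param ... Unused.
#' @return A data frame with `score` in `[0, 1]` and `label` in `{0, 1}`.
#' @name predict-classifiers
NULL

#' @rdname predict-classifiers
#' @export
predict.squat_lstm <- function(object, dataset, ...) {
  check_feature_match(object, dataset)
  x <- dataset_tensor(dataset)
  fw <- lstm_forward_batch(x, object$params)
  data.frame(score = fw$probs[, 2], label = as.integer(fw$probs[, 2] >= 0.5))
}

#' @rdname predict-classifiers
#' @export
predict.squat_svm <- function(object, dataset, ...) {
  check_feature_match(object, dataset)
  xf <- flatten_tensor(dataset_tensor(dataset))
  f <- svm_decision(object, xf)
  data.frame(score = sigmoid(f), label = as.integer(f >= 0))
}

#' Serialize a trained model to JSON
#'
#' Writes weights (LSTM) or support vectors and dual coefficients (SVM) with
#' the training configuration, seed, and feature-set ids to a single JSON
#' container.
#'
#' @param model A `squat_lstm` or `squat_svm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- if (inherits(model, "squat_lstm")) {
    list(type = "lstm", feature_ids = model$feature_ids,
         cfg = unclass(model$cfg),
         params = lapply(model$params[1:14], unclass),
         loss_trace = model$loss_trace)
  } else {
    list(type = "svm", feature_ids = model$feature_ids,
         cfg = unclass(model$cfg), gamma = model$gamma, cost = model$cost,
         kkt_residual = model$kkt_residual,
         support_vectors = unclass(model$fit$SV),
         dual_coefs = as.numeric(model$fit$coefs),
         rho = model$fit$rho)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
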