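# Transfer head: dense 1024 -> 32 (swish) -> 3 (softmax), trained with
# Adam + categorical cross-entropy, early stopping with best-weight
# restore, and a top-k soft-voting ensemble.

PHASES <- c("exhalation", "inhalation", "nonbreathing")
HIDDEN_UNITS <- 32L
N_CLASSES <- 3L

sigmoid <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigmoid(x)

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Training configuration for the transfer head
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param adam_beta1,adam_beta2 Adam moment decay rates (0.9 / 0.999).
#' @param batch_size mini-batch size (default 32).
#' @param max_epochs maximum training epochs (default 100).
#' @param patience early-stopping patience in epochs (default 10).
#' @param shuffle_seed seed for epoch shuffling.
#' @param init_seed seed for weight initialisation.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.001, adam_beta1 = 0.9,
                            adam_beta2 = 0.999, batch_size = 32L,
                            max_epochs = 100L, patience = 10L,
                            shuffle_seed = 1L, init_seed = 1L) {
  stopifnot(batch_size >= 1L, patience >= 0L, max_epochs >= 1L,
            learning_rate >= 0)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 shuffle_seed = as.integer(shuffle_seed),
                 init_seed = as.integer(init_seed)),
            class = "training_config")
}

.new_head <- function(init_seed, input_dim = EMBED_DIM) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(init_seed)
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nrow = nin, ncol = nout)
  }
  structure(list(W1 = glorot(input_dim, HIDDEN_UNITS),
                 b1 = rep(0, HIDDEN_UNITS),
                 W2 = glorot(HIDDEN_UNITS, N_CLASSES),
                 b2 = rep(0, N_CLASSES),
                 init_seed = as.integer(init_seed)),
            class = "transfer_head")
}

#' @export
print.transfer_head <- function(x, ...) {
  cat(sprintf("<transfer_head %dx%d swish -> %d softmax (init_seed %d)>\n",
              nrow(x$W1), ncol(x$W1), ncol(x$W2), x$init_seed))
  invisible(x)
}

#' Forward pass of the transfer head
#'
#' `softmax(W2' swish(W1' e + b1) + b2)` over the classes
#' (exhalation, inhalation, nonbreathing).
#'
#' @param head a `transfer_head`.
#' @param e embedding vector, or a matrix with one embedding per row.
#' @return Named probability vector summing to 1 (or a matrix of them).
#' @export
head_forward <- function(head, e) {
  stopifnot(inherits(head, "transfer_head"))
  single <- is.null(dim(e))
  X <- if (single) matrix(e, nrow = 1) else e
  if (ncol(X) != nrow(head$W1)) {
    stop(sprintf("head_forward: embedding length %d != head input %d",
                 ncol(X), nrow(head$W1)), call. = FALSE)
  }
  if (!all(is.finite(head$W1)) || !all(is.finite(head$W2))) {
    stop("head_forward: non-finite head parameters", call. = FALSE)
  }
  H <- swish(sweep(X %*% head$W1, 2, head$b1, `+`))
  P <- .softmax_rows(sweep(H %*% head$W2, 2, head$b2, `+`))
  colnames(P) <- PHASES
  if (single) P[1, ] else P
}

.xent <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

.one_hot <- function(y) {
  y <- match(as.character(y), PHASES)
  stopifnot(!anyNA(y))
  Y <- matrix(0, nrow = length(y), ncol = N_CLASSES)
  Y[cbind(seq_along(y), y)] <- 1
  Y
}

#' Train the transfer head
#'
#' Mini-batch Adam on categorical cross-entropy. Training stops when the
#' validation loss has not improved for `patience` consecutive epochs and
#' the weights of the best validation epoch are restored. No class
#' balancing is applied: the imbalance toward nonbreathing sounds is kept
#' deliberately so the detector is conservative about calling breathing
#' in noisy surroundings.
#'
#' @param x_train,y_train embeddings (rows) and phase labels
#'   (character/factor over exhalation/inhalation/nonbreathing).
#' @param x_val,y_val validation split (must be non-empty).
#' @param cfg a [training_config()].
#' @return List with `head` (best-epoch weights) and `history`
#'   (`train_loss`, `val_loss`, `best_epoch`, `stopped_epoch`).
#' @export
train_head <- function(x_train, y_train, x_val, y_val,
                       cfg = training_config()) {
  stopifnot(inherits(cfg, "training_config"))
  if (is.null(dim(x_train)) || nrow(x_train) == 0L) {
    stop("train_head: empty training set", call. = FALSE)
  }
  if (is.null(dim(x_val)) || nrow(x_val) == 0L) {
    stop("train_head: validation set must be non-empty", call. = FALSE)
  }
  Y_train <- .one_hot(y_train)
  Y_val <- .one_hot(y_val)
  if (length(unique(as.character(y_train))) == 1L) {
    warning("train_head: training set contains a single class", call. = FALSE)
  }
  head <- .new_head(cfg$init_seed, input_dim = ncol(x_train))
  n <- nrow(x_train)
  # Adam state
  m <- list(W1 = head$W1 * 0, b1 = head$b1 * 0, W2 = head$W2 * 0, b2 = head$b2 * 0)
  v <- m
  t_step <- 0L
  lr <- cfg$learning_rate; b1m <- cfg$adam_beta1; b2m <- cfg$adam_beta2
  eps <- 1e-8
  train_loss <- numeric(0); val_loss <- numeric(0)
  best_loss <- Inf; best <- head; best_epoch <- 0L; wait <- 0L
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed((cfg$shuffle_seed + epoch) %% .Machine$integer.max)
      sample.int(n)
    })
    for (bstart in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[bstart:min(bstart + cfg$batch_size - 1L, n)]
      X <- x_train[idx, , drop = FALSE]
      Y <- Y_train[idx, , drop = FALSE]
      nb <- length(idx)
      # forward
      Z1 <- sweep(X %*% head$W1, 2, head$b1, `+`)
      S1 <- sigmoid(Z1)
      H <- Z1 * S1
      P <- .softmax_rows(sweep(H %*% head$W2, 2, head$b2, `+`))
      # backward (softmax + cross-entropy)
      dZ2 <- (P - Y) / nb
      gW2 <- t(H) %*% dZ2
      gb2 <- colSums(dZ2)
      dH <- dZ2 %*% t(head$W2)
      dZ1 <- dH * (S1 + Z1 * S1 * (1 - S1)) # swish'
      gW1 <- t(X) %*% dZ1
      gb1 <- colSums(dZ1)
      t_step <- t_step + 1L
      corr <- sqrt(1 - b2m^t_step) / (1 - b1m^t_step)
      for (nm in c("W1", "b1", "W2", "b2")) {
        g <- switch(nm, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        m[[nm]] <- b1m * m[[nm]] + (1 - b1m) * g
        v[[nm]] <- b2m * v[[nm]] + (1 - b2m) * g^2
        head[[nm]] <- head[[nm]] - lr * corr * m[[nm]] / (sqrt(v[[nm]]) + eps)
      }
    }
    train_loss[epoch] <- .xent(head_forward(head, x_train), Y_train)
    val_loss[epoch] <- .xent(head_forward(head, x_val), Y_val)
    if (val_loss[epoch] < best_loss) {
      best_loss <- val_loss[epoch]; best <- head
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= max(cfg$patience, 1L)) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  list(head = best,
       history = list(train_loss = train_loss, val_loss = val_loss,
                      best_epoch = best_epoch, best_val_loss = best_loss,
                      stopped_epoch = stopped))
}

#' Select the k best heads by validation loss
#'
#' Ties are broken by candidate index (first candidate wins). The
#' returned ensemble holds the heads sorted by ascending validation loss.
#'
#' @param candidates list of `list(head=, val_loss=)` entries.
#' @param k ensemble size (default 3).
#' @return An `ensemble` object.
#' @export
select_ensemble <- function(candidates, k = 3L) {
  if (length(candidates) < k) {
    stop(sprintf("select_ensemble: need at least %d candidates, got %d",
                 k, length(candidates)), call. = FALSE)
  }
  losses <- vapply(candidates, `[[`, numeric(1), "val_loss")
  picked <- order(losses)[seq_len(k)] # order() is stable: ties -> first index
  structure(list(heads = lapply(candidates[picked], `[[`, "head"),
                 val_losses = losses[picked],
                 indices = picked),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble of %d transfer heads; val losses %s>\n",
              length(x$heads),
              paste(sprintf("%.4f", x$val_losses), collapse = ", ")))
  invisible(x)
}

#' Soft-voting ensemble prediction
#'
#' Arithmetic mean of the member probability vectors with equal weights
#' (argmax of the mean equals argmax of the sum), renormalised to sum
#' to 1.
#'
#' @param ens an `ensemble`.
#' @param e embedding vector or matrix of embeddings (rows).
#' @return Probability vector (or matrix) over the three phases.
#' @export
ensemble_predict <- function(ens, e) {
  stopifnot(inherits(ens, "ensemble"), length(ens$heads) >= 1L)
  single <- is.null(dim(e))
  X <- if (single) matrix(e, nrow = 1) else e
  P <- Reduce(`+`, lapply(ens$heads, head_forward, e = X)) / length(ens$heads)
  P <- P / rowSums(P)
  colnames(P) <- PHASES
  if (single) P[1, ] else P
}

#' Train candidate heads and keep the best k as an ensemble
#'
#' Each candidate gets a distinct derived seed (`base_seed + i` for both
#' initialisation and shuffling), recorded in the head metadata.
#'
#' @param x_train,y_train,x_val,y_val as in [train_head()].
#' @param n_candidates number of candidates (default 20).
#' @param k ensemble size (default 3).
#' @param base_seed base for per-candidate seed derivation.
#' @param cfg a [training_config()]; its seeds are overridden per candidate.
#' @return An `ensemble` with `candidate_losses` attached.
#' @export
train_ensemble <- function(x_train, y_train, x_val, y_val,
                           n_candidates = 20L, k = 3L, base_seed = 1L,
                           cfg = training_config()) {
  candidates <- lapply(seq_len(n_candidates), function(i) {
    ci <- cfg
    ci$init_seed <- as.integer((base_seed + 1000L * i) %% .Machine$integer.max)
    ci$shuffle_seed <- as.integer((base_seed + 2000L * i + 1L) %% .Machine$integer.max)
    fit <- train_head(x_train, y_train, x_val, y_val, ci)
    list(head = fit$head, val_loss = fit$history$best_val_loss)
  })
  ens <- select_ensemble(candidates, k)
  attr(ens, "candidate_losses") <- vapply(candidates, `[[`, numeric(1), "val_loss")
  ens
}

#' Save an ensemble to a portable text weight file
#'
#' JSON with shape-tagged weight arrays and metadata (seeds, backend id),
#' so detection and evaluation never depend on a training framework.
#'
#' @param ens an `ensemble`.
#' @param path output path.
#' @param backend_id name of the embedding backend the heads were trained on.
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(ens, path, backend_id = "surrogate") {
  obj <- list(
    format = "breathphase-ensemble-v1",
    backend_id = backend_id,
    val_losses = ens$val_losses,
    heads = lapply(ens$heads, function(h) {
      list(W1 = list(dim = dim(h$W1), data = as.numeric(h$W1)),
           b1 = h$b1,
           W2 = list(dim = dim(h$W2), data = as.numeric(h$W2)),
           b2 = h$b2,
           init_seed = h$init_seed)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an ensemble saved by [save_ensemble()]
#' @param path weight file path.
#' @return An `ensemble`.
#' @export
load_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "breathphase-ensemble-v1")) {
    stop(sprintf("load_ensemble: '%s' is not a breathphase weight file", path),
         call. = FALSE)
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  heads <- lapply(obj$heads, function(h) {
    structure(list(
      W1 = matrix(num(h$W1$data), nrow = h$W1$dim[[1]], ncol = h$W1$dim[[2]]),
      b1 = num(h$b1),
      W2 = matrix(num(h$W2$data), nrow = h$W2$dim[[1]], ncol = h$W2$dim[[2]]),
      b2 = num(h$b2),
      init_seed = as.integer(h$init_seed)
    ), class = "transfer_head")
  })
  structure(list(heads = heads, val_losses = num(obj$val_losses),
                 backend_id = obj$backend_id),
            class = "ensemble")
}
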