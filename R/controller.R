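## The distal-joint predictor: a small fully-connected network mapping the two
## proximal shoulder angles plus a 5-parameter goal location to the five
## distal joint angles. Training uses the hand-location-as-target
## substitution: every recorded posture is treated as if it had just brought
## the hand onto a hypothetical target at the hand's own location, so the
## contextual input covers the workspace continuously instead of clustering
## at the sparse true targets.

CTRL_INPUT_COLS <- c(PROXIMAL_COLS, LOCATION_COLS)

#' Build training pairs from a session
#'
#' One input/output pair per recorded sample: the input is the proximal
#' shoulder angles plus the hand location of that sample's own posture
#' (recomputed by forward kinematics under the session's morphology); the
#' output is the five distal joint angles of the same posture.
#'
#' @param session An `arm_session` with full 7-DoF angle columns.
#' @return A tibble with input columns `s_fe`, `s_aa`, `x`, `y`, `z`, `incl`,
#'   `azim` and output columns `h_r`, `e_fe`, `f_ps`, `w_fe`, `w_ru`.
#' @export
build_training_pairs <- function(session) {
  if (!inherits(session, "arm_session")) abort("`session` must be an arm_session.")
  missing <- setdiff(ANGLE_COLS, names(session$samples))
  if (length(missing) > 0) {
    abort(paste0(
      "session lacks distal angle columns (",
      paste(missing, collapse = ", "),
      "); residual-limb recordings cannot supply distal outputs to learn."
    ))
  }
  angles <- session$samples[ANGLE_COLS]
  loc <- hand_location(angles, session$morph)
  dplyr::bind_cols(angles[PROXIMAL_COLS], loc, angles[DISTAL_COLS])
}

#' Build a generic (donor-pool) training dataset
#'
#' Concatenates training pairs from donor sessions, adapting them to a user:
#' donor postures recorded on the opposite body side are mirrored to the
#' user's side first, then the contextual hand locations are recomputed under
#' the user's morphology ([remap_hand_locations()]) while the outputs remain
#' the donors' original (side-adjusted) distal joint angles.
#'
#' @param sessions A list of donor `arm_session`s, each carrying its own
#'   morphology.
#' @param user_morph The user's [arm_morphology()].
#' @return A tibble of training pairs, rows concatenated over donors.
#' @export
build_generic_dataset <- function(sessions, user_morph) {
  check_morphology(user_morph)
  if (inherits(sessions, "arm_session")) sessions <- list(sessions)
  if (length(sessions) == 0) abort("need at least one donor session.")
  purrr::map_dfr(sessions, function(s) {
    if (!inherits(s, "arm_session") || !inherits(s$morph, "arm_morphology")) {
      abort("every donor session must be an arm_session with morphology metadata.")
    }
    missing <- setdiff(ANGLE_COLS, names(s$samples))
    if (length(missing) > 0) abort("donor session lacks full 7-DoF angles.")
    angles <- s$samples[ANGLE_COLS]
    if (s$morph$side != user_morph$side) angles <- mirror_angles(angles)
    loc <- remap_hand_locations(angles, user_morph)
    dplyr::bind_cols(angles[PROXIMAL_COLS], loc, angles[DISTAL_COLS])
  })
}

#' Training configuration and the named presets
#'
#' `training_config()` holds the optimisation settings for [train_model()]:
#' minibatch gradient descent on the mean-squared error (Adam or classical
#' SGD with momentum), features and outputs z-scored from the training set.
#' To cancel the gradient noise injected by the dropout layer, the weights
#' visited during the final `tail_average` epochs are averaged into the
#' returned model (Polyak-Ruppert tail averaging; 0 disables it).
#'
#' `preset_own()` and `preset_generic()` record the hyperparameters of the
#' two published training regimes — own-data models (30 epochs, learning rate
#' 1e-4) and generic donor-pool models (10 epochs, learning rate 1.59e-7,
#' momentum 0.95, SGD). Those learning rates were reported without the
#' feature scaling or optimizer they applied to, so under this package's
#' z-scoring they are faithful records of the regimes rather than tuned
#' values; use the `training_config()` defaults when predictive accuracy
#' matters more than protocol fidelity.
#'
#' @param epochs Number of passes over the training pairs (>= 1).
#' @param learning_rate Step size (> 0).
#' @param optimizer `"adam"` (default; beta1 0.9, beta2 0.999) or `"sgd"`.
#' @param momentum Classical momentum coefficient in `[0, 1)` (SGD only).
#' @param batch_size Minibatch size.
#' @param lr_decay_at Epoch after which the learning rate is divided by 10
#'   (a single-step fine-tuning schedule); `Inf` keeps it constant.
#' @param tail_average Number of final epochs whose weights are averaged.
#' @param n_models Number of independently initialised networks trained and
#'   averaged at prediction time (a small deep ensemble; 1 = the single
#'   network of the published protocol). Initialisation luck under the heavy
#'   dropout layer leaves individual networks with occasional localised
#'   biases; averaging 3 removes them.
#' @param input_encoding `"axis"` (default) embeds the two orientation angles
#'   of the goal location as the three components of the unit hand axis
#'   before normalisation, which is continuous everywhere; `"spherical"`
#'   feeds `incl`/`azim` raw (discontinuous at the azimuth seam and the
#'   vertical pole).
#' @param seed Integer seed for weight initialisation, shuffling and dropout.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 30, learning_rate = 1e-4,
                            optimizer = c("adam", "sgd"), momentum = 0.9,
                            batch_size = 64, lr_decay_at = 22,
                            tail_average = 8, n_models = 3,
                            input_encoding = c("axis", "spherical"),
                            seed = NULL) {
  optimizer <- match.arg(optimizer)
  input_encoding <- match.arg(input_encoding)
  if (epochs < 1) abort("`epochs` must be >= 1.")
  check_number(learning_rate, "learning_rate", positive = TRUE)
  if (momentum < 0 || momentum >= 1) abort("`momentum` must be in [0, 1).")
  if (tail_average < 0) abort("`tail_average` must be >= 0.")
  if (!is.numeric(lr_decay_at) || length(lr_decay_at) != 1L || lr_decay_at < 1) {
    abort("`lr_decay_at` must be a single epoch index >= 1 (Inf for none).")
  }
  if (n_models < 1) abort("`n_models` must be >= 1.")
  structure(
    list(
      epochs = as.integer(epochs), learning_rate = learning_rate,
      optimizer = optimizer, momentum = momentum,
      batch_size = as.integer(batch_size), lr_decay_at = lr_decay_at,
      tail_average = as.integer(min(tail_average, epochs)),
      n_models = as.integer(n_models),
      input_encoding = input_encoding, seed = seed
    ),
    class = "training_config"
  )
}

#' @rdname training_config
#' @export
preset_own <- function(seed = NULL) {
  training_config(
    epochs = 30, learning_rate = 1e-4, lr_decay_at = Inf,
    n_models = 1, seed = seed
  )
}

#' @rdname training_config
#' @export
preset_generic <- function(seed = NULL) {
  training_config(
    epochs = 10, learning_rate = 1.59e-7, optimizer = "sgd",
    momentum = 0.95, lr_decay_at = Inf, n_models = 1, seed = seed
  )
}

## Layer widths of the predictor: dense 256 - dense 256 - dropout 0.5 -
## dense 64 - linear 5, ReLU on the hidden layers.
MLP_HIDDEN <- c(256L, 256L, 64L)
MLP_DROPOUT <- 0.5

mlp_init <- function(n_in, n_out) {
  dims <- c(n_in, MLP_HIDDEN, n_out)
  weights <- vector("list", length(dims) - 1L)
  for (i in seq_along(weights)) {
    ## He initialisation for the ReLU stack
    weights[[i]] <- list(
      W = matrix(
        rnorm(dims[i] * dims[i + 1], 0, sqrt(2 / dims[i])),
        dims[i], dims[i + 1]
      ),
      b = rep(0, dims[i + 1])
    )
  }
  weights
}

## Input featurization: the goal-orientation angles can be fed raw
## ("spherical") or embedded as the components of the unit hand axis
## ("axis"), which is continuous across the azimuth seam and the vertical
## pole.
encode_inputs <- function(df, encoding) {
  X <- as.matrix(df[CTRL_INPUT_COLS])
  if (encoding == "spherical") {
    return(X)
  }
  ax <- spherical_to_axis(X[, "incl"], X[, "azim"])
  cbind(
    X[, c("s_fe", "s_aa", "x", "y", "z"), drop = FALSE],
    ax_x = ax[, 1], ax_y = ax[, 2], ax_z = ax[, 3]
  )
}

mlp_forward <- function(weights, X, dropout_mask = NULL) {
  H1 <- pmax(sweep(X %*% weights[[1]]$W, 2, weights[[1]]$b, "+"), 0)
  H2 <- pmax(sweep(H1 %*% weights[[2]]$W, 2, weights[[2]]$b, "+"), 0)
  H2d <- if (is.null(dropout_mask)) H2 else H2 * dropout_mask
  H3 <- pmax(sweep(H2d %*% weights[[3]]$W, 2, weights[[3]]$b, "+"), 0)
  Y <- sweep(H3 %*% weights[[4]]$W, 2, weights[[4]]$b, "+")
  list(H1 = H1, H2 = H2, H2d = H2d, H3 = H3, Y = Y)
}

#' Train the distal-joint predictor
#'
#' Fits the 256-256-dropout(0.5)-64 fully-connected network by minibatch
#' gradient descent (Adam by default, or classical SGD with momentum) on the
#' mean-squared error between predicted and recorded distal joint angles.
#' Inputs and outputs are z-scored per feature from the training set; the
#' normalisation constants are frozen into the model, as are the per-output
#' training ranges used to clip predictions at inference (emulating
#' prosthesis joint limits). Dropout is active only during training; the
#' weights visited during the final `tail_average` epochs are averaged to
#' cancel the gradient noise dropout injects. Given a seed, training is
#' reproducible.
#'
#' @param pairs Training pairs from [build_training_pairs()] /
#'   [build_generic_dataset()] (>= 100 rows).
#' @param config A [training_config()] or preset.
#' @param provenance `"own"` or `"generic"`, recorded in the model.
#' @return An object of class `arm_control_model`.
#' @export
train_model <- function(pairs, config = training_config(),
                        provenance = c("own", "generic")) {
  provenance <- match.arg(provenance)
  if (!inherits(config, "training_config")) abort("`config` must be a training_config.")
  pairs <- as_tibble(pairs)
  missing <- setdiff(c(CTRL_INPUT_COLS, DISTAL_COLS), names(pairs))
  if (length(missing) > 0) {
    abort(paste0("`pairs` lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(pairs) < 100) abort("need at least 100 training pairs.")
  X <- encode_inputs(pairs, config$input_encoding)
  Y <- as.matrix(pairs[DISTAL_COLS])
  in_mean <- colMeans(X)
  in_sd <- pmax(apply(X, 2, sd), 1e-9)
  out_mean <- colMeans(Y)
  out_sd <- pmax(apply(Y, 2, sd), 1e-9)
  Xn <- sweep(sweep(X, 2, in_mean), 2, in_sd, "/")
  Yn <- sweep(sweep(Y, 2, out_mean), 2, out_sd, "/")
  n <- nrow(Xn)
  adam <- config$optimizer == "adam"
  b1 <- 0.9
  b2 <- 0.999

  fit_member <- function() {
    weights <- mlp_init(ncol(Xn), ncol(Yn))
    zeros <- lapply(weights, function(l) list(W = l$W * 0, b = l$b * 0))
    vel <- zeros # SGD velocity, or Adam first moment
    sqr <- zeros # Adam second moment
    acc <- zeros # tail-average accumulator
    n_acc <- 0L
    t_step <- 0L
    keep <- 1 - MLP_DROPOUT
    loss_history <- numeric(config$epochs)
    base_lr <- config$learning_rate
    for (epoch in seq_len(config$epochs)) {
      lr <- if (epoch > config$lr_decay_at) base_lr / 10 else base_lr
      ord <- sample.int(n)
      epoch_loss <- 0
      n_batches <- 0L
      averaging <- epoch > config$epochs - config$tail_average
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- Xn[idx, , drop = FALSE]
        Yb <- Yn[idx, , drop = FALSE]
        m <- length(idx)
        mask <- matrix(
          (runif(m * MLP_HIDDEN[2]) < keep) / keep, m, MLP_HIDDEN[2]
        )
        fw <- mlp_forward(weights, Xb, dropout_mask = mask)
        resid <- fw$Y - Yb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          abort(sprintf(
            "training diverged (non-finite loss) at epoch %d with optimizer=%s, learning_rate=%g, momentum=%g.",
            epoch, config$optimizer, config$learning_rate, config$momentum
          ))
        }
        epoch_loss <- epoch_loss + loss
        n_batches <- n_batches + 1L

        ## backward pass; dLoss/dY = 2 resid / (m * n_out)
        dY <- 2 * resid / (m * ncol(Yb))
        g4 <- list(W = crossprod(fw$H3, dY), b = colSums(dY))
        dH3 <- (dY %*% t(weights[[4]]$W)) * (fw$H3 > 0)
        g3 <- list(W = crossprod(fw$H2d, dH3), b = colSums(dH3))
        dH2 <- (dH3 %*% t(weights[[3]]$W)) * mask * (fw$H2 > 0)
        g2 <- list(W = crossprod(fw$H1, dH2), b = colSums(dH2))
        dH1 <- (dH2 %*% t(weights[[2]]$W)) * (fw$H1 > 0)
        g1 <- list(W = crossprod(Xb, dH1), b = colSums(dH1))
        grads <- list(g1, g2, g3, g4)
        t_step <- t_step + 1L
        for (k in 1:4) {
          for (p in c("W", "b")) {
            g <- grads[[k]][[p]]
            if (adam) {
              vel[[k]][[p]] <- b1 * vel[[k]][[p]] + (1 - b1) * g
              sqr[[k]][[p]] <- b2 * sqr[[k]][[p]] + (1 - b2) * g^2
              step <- lr *
                (vel[[k]][[p]] / (1 - b1^t_step)) /
                (sqrt(sqr[[k]][[p]] / (1 - b2^t_step)) + 1e-8)
              weights[[k]][[p]] <- weights[[k]][[p]] - step
            } else {
              vel[[k]][[p]] <- config$momentum * vel[[k]][[p]] - lr * g
              weights[[k]][[p]] <- weights[[k]][[p]] + vel[[k]][[p]]
            }
            if (averaging) acc[[k]][[p]] <- acc[[k]][[p]] + weights[[k]][[p]]
          }
        }
        if (averaging) n_acc <- n_acc + 1L
      }
      loss_history[epoch] <- epoch_loss / n_batches
    }
    if (n_acc > 0L) {
      ## n_acc counts minibatch updates; each parameter was accumulated once
      ## per update
      weights <- lapply(seq_along(weights), function(k) {
        list(W = acc[[k]]$W / n_acc, b = acc[[k]]$b / n_acc)
      })
    }
    list(weights = weights, loss_history = loss_history)
  }

  with_seed_if(config$seed, {
    members <- lapply(seq_len(config$n_models), function(k) fit_member())
    structure(
      list(
        members = lapply(members, `[[`, "weights"),
        norm = list(
          in_mean = in_mean, in_sd = in_sd,
          out_mean = out_mean, out_sd = out_sd
        ),
        clip = cbind(min = apply(Y, 2, min), max = apply(Y, 2, max)),
        config = config,
        provenance = provenance,
        n_pairs = n,
        loss_history = lapply(members, `[[`, "loss_history"),
        format_version = "1.0"
      ),
      class = "arm_control_model"
    )
  })
}

#' @export
print.arm_control_model <- function(x, ...) {
  cat(sprintf(
    "<arm_control_model> %s, %d pairs, %d network(s) x %d epochs (%s, lr %g), final loss %.4g\n",
    x$provenance, x$n_pairs, length(x$members), x$config$epochs,
    x$config$optimizer, x$config$learning_rate,
    mean(vapply(x$loss_history, function(h) tail(h, 1), numeric(1)))
  ))
  invisible(x)
}

#' Assemble controller inputs
#'
#' Combines proximal shoulder angles with a goal location into the 7-column
#' input table the predictor expects. At training time the location is the
#' hand's own location; at test time it is the target's.
#'
#' @param s_fe,s_aa Proximal angles (radians), recycled against the target.
#' @param target A one-row data frame with the five location columns.
#' @return A tibble with columns `s_fe`, `s_aa`, `x`, `y`, `z`, `incl`, `azim`.
#' @export
control_inputs <- function(s_fe, s_aa, target) {
  loc <- as_tibble(as.data.frame(location_matrix(target)))
  if (nrow(loc) != 1L) abort("`target` must be a single location.")
  n <- max(length(s_fe), length(s_aa))
  dplyr::bind_cols(
    tibble(s_fe = rep_len(s_fe, n), s_aa = rep_len(s_aa, n)),
    loc[rep(1L, n), ]
  )
}

#' Predict the five distal joint angles
#'
#' Deterministic inference (dropout inactive): normalises the inputs with the
#' model's frozen constants, runs the network, denormalises, and clips each
#' output to its training range.
#'
#' @param model An `arm_control_model`, or a [synergy_oracle()] for
#'   ground-truth evaluation.
#' @param newdata Data frame with columns `s_fe`, `s_aa`, `x`, `y`, `z`,
#'   `incl`, `azim` (see [control_inputs()]).
#' @param ... Unused.
#' @return A tibble with columns `h_r`, `e_fe`, `f_ps`, `w_fe`, `w_ru`.
#' @export
predict_distal <- function(model, newdata, ...) UseMethod("predict_distal")

#' @export
predict_distal.arm_control_model <- function(model, newdata, ...) {
  newdata <- as_tibble(newdata)
  missing <- setdiff(CTRL_INPUT_COLS, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` lacks columns: ", paste(missing, collapse = ", ")))
  }
  X <- encode_inputs(newdata, model$config$input_encoding)
  Xn <- sweep(sweep(X, 2, model$norm$in_mean), 2, model$norm$in_sd, "/")
  Yn <- Reduce(`+`, lapply(model$members, function(w) mlp_forward(w, Xn)$Y)) /
    length(model$members)
  Y <- sweep(sweep(Yn, 2, model$norm$out_sd, "*"), 2, model$norm$out_mean, "+")
  for (j in seq_len(ncol(Y))) {
    Y[, j] <- clamp(Y[, j], model$clip[j, "min"], model$clip[j, "max"])
  }
  out <- as_tibble(as.data.frame(Y))
  names(out) <- DISTAL_COLS
  out
}

#' Ground-truth synergy oracle
#'
#' A drop-in replacement for a trained model that answers [predict_distal()]
#' queries with the distal angles of the generating synergy's inverse
#' kinematics for the goal location (independent of the proximal inputs).
#' Used to validate the closed-loop machinery: with the oracle as controller,
#' the hybrid arm reaches every reachable target exactly.
#'
#' @param morph An [arm_morphology()].
#' @param params A [synergy_params()].
#' @return An object of class `synergy_oracle`.
#' @export
synergy_oracle <- function(morph, params = synergy_params()) {
  check_morphology(morph)
  structure(list(morph = morph, params = params), class = "synergy_oracle")
}

#' @export
predict_distal.synergy_oracle <- function(model, newdata, ...) {
  newdata <- as_tibble(newdata)
  locs <- newdata[LOCATION_COLS]
  uniq <- dplyr::distinct(locs)
  pred_u <- purrr::map_dfr(seq_len(nrow(uniq)), function(i) {
    synergy_ik(uniq[i, ], model$morph, model$params)[DISTAL_COLS]
  })
  key <- do.call(paste, c(locs, sep = "\r"))
  key_u <- do.call(paste, c(uniq, sep = "\r"))
  pred_u[match(key, key_u), ]
}

#' One step of hybrid-arm composition
#'
#' Assembles the hybrid arm for one control step: the two proximal DoFs come
#' from the operator, the five distal DoFs from the model's prediction for the
#' current goal, and the whole 7-DoF posture is rendered through forward
#' kinematics.
#'
#' @param model An `arm_control_model` or [synergy_oracle()].
#' @param operator_s_fe,operator_s_aa Operator shoulder angles (radians).
#' @param target One-row data frame with the five location columns.
#' @param morph An [arm_morphology()].
#' @return An `arm_posture`.
#' @export
hybrid_step <- function(model, operator_s_fe, operator_s_aa, target, morph) {
  distal <- predict_distal(model, control_inputs(operator_s_fe, operator_s_aa, target))
  forward_kinematics(
    dplyr::bind_cols(
      tibble(s_fe = operator_s_fe, s_aa = operator_s_aa),
      distal
    ),
    morph
  )
}

#' @export
tidy.arm_control_model <- function(x, ...) {
  dims <- vapply(x$members[[1]], function(l) dim(l$W), integer(2))
  tibble(
    layer = c("dense_1", "dense_2", "dense_3", "output"),
    input_dim = dims[1, ],
    output_dim = dims[2, ],
    activation = c("relu", "relu (dropout 0.5 in training)", "relu", "linear"),
    n_parameters = dims[1, ] * dims[2, ] + dims[2, ]
  )
}

#' @export
glance.arm_control_model <- function(x, ...) {
  tibble(
    provenance = x$provenance,
    n_pairs = x$n_pairs,
    n_models = length(x$members),
    epochs = x$config$epochs,
    optimizer = x$config$optimizer,
    learning_rate = x$config$learning_rate,
    momentum = x$config$momentum,
    batch_size = x$config$batch_size,
    input_encoding = x$config$input_encoding,
    final_loss = mean(vapply(x$loss_history, function(h) tail(h, 1), numeric(1)))
  )
}
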