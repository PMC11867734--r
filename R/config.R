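# Training configuration. Every hyperparameter of the objective and the
# optimizer lives here; the `variant` field reproduces the ablation family
# (plain Poincare embedding / root-only / child-only / all-hierarchical /
# full model) by zeroing penalty weights.

.VARIANTS <- c("poincare", "R", "Ch", "C", "full")

#' Training configuration
#'
#' Collects the embedding dimension, the structural-penalty parameters, the
#' penalty weights and the optimizer schedule. The `variant` switch
#' overrides the four penalty weights to reproduce the standard ablations:
#'
#' * `"poincare"`: all four weights 0 (plain negative-sampling Poincare
#'   embedding; the non-hierarchical baseline).
#' * `"R"`: only `lambda_root` active (root regularization alone).
#' * `"Ch"`: only `lambda_child` active (radial parent/child ordering alone).
#' * `"C"`: `lambda_root`, `lambda_child` and `lambda_cone` active,
#'   `lambda_nonhier` 0 (all hierarchical regularizers, no cone placement of
#'   non-hierarchical nodes).
#' * `"full"`: all four active.
#'
#' @param dim embedding dimension `d`.
#' @param delta radius bound for roots: each root should satisfy
#'   `origin_distance(root) < delta`.
#' @param K entailment-cone aperture scale.
#' @param margin slack of the radial ordering hinge: a parent should be at
#'   least `margin` closer (in hyperbolic distance to the origin) than each
#'   child.
#' @param lambda_root,lambda_child,lambda_cone,lambda_nonhier nonnegative
#'   penalty weights (overridden by `variant` unless `variant = NULL`).
#' @param n_negatives negative samples per positive edge.
#' @param lr learning rate of the projected Riemannian SGD.
#' @param burn_in_epochs,burn_in_factor initial epochs run at
#'   `lr * burn_in_factor` to stabilize the hyperbolic optimization.
#' @param anneal_frac fraction of the final epochs over which the learning
#'   rate decays linearly (cool-down); `0` disables annealing.
#' @param cone_warmup_epochs epochs before the two entailment-cone
#'   penalties activate, letting the distance loss and the radial penalties
#'   lay out the hierarchy's skeleton first (cone forces on a still-random
#'   configuration mostly chatter against the aperture gate). `0` enables
#'   cones from the start.
#' @param polish_sweeps deterministic structural-projection sweeps run after
#'   each cone-active epoch, holding the coupled constraints near their
#'   boundaries against the stochastic pass.
#' @param final_sweeps deterministic structural-projection sweeps run once
#'   after the last epoch (the settling phase: alternating projections onto
#'   the constraint sets with the stochastic objective frozen).
#' @param anneal_floor multiplier the learning rate decays to at the last
#'   epoch.
#' @param epochs number of training epochs.
#' @param init_scale coordinates are initialized i.i.d. uniform on
#'   `[-init_scale, init_scale]`.
#' @param eps_ball boundary margin of [project_to_ball()].
#' @param max_step cap on the Euclidean length of any single point update
#'   (after Riemannian rescaling); prevents hinge gradients from throwing a
#'   point across the ball onto the boundary.
#' @param seed integer RNG seed; training is fully deterministic given the
#'   seed and the (lexicographic) node order.
#' @param variant one of `"poincare"`, `"R"`, `"Ch"`, `"C"`, `"full"`, or
#'   `NULL` to keep the weights exactly as given.
#' @return Object of class `train_config` (a validated named list).
#' @export
train_config <- function(dim = 10L,
                         delta = 0.5,
                         K = 0.1,
                         margin = 0.1,
                         lambda_root = 1.0,
                         lambda_child = 1.0,
                         lambda_cone = 1.0,
                         lambda_nonhier = 1.0,
                         n_negatives = 10L,
                         lr = 0.3,
                         burn_in_epochs = 10L,
                         burn_in_factor = 0.1,
                         anneal_frac = 1 / 3,
                         anneal_floor = 0.02,
                         cone_warmup_epochs = 50L,
                         polish_sweeps = 2L,
                         final_sweeps = 500L,
                         epochs = 300L,
                         init_scale = 1e-3,
                         eps_ball = 1e-5,
                         max_step = 0.1,
                         seed = 1L,
                         variant = "full") {
  cfg <- list(dim = as.integer(dim), delta = delta, K = K, margin = margin,
              lambda_root = lambda_root, lambda_child = lambda_child,
              lambda_cone = lambda_cone, lambda_nonhier = lambda_nonhier,
              n_negatives = as.integer(n_negatives), lr = lr,
              burn_in_epochs = as.integer(burn_in_epochs),
              burn_in_factor = burn_in_factor,
              anneal_frac = anneal_frac, anneal_floor = anneal_floor,
              cone_warmup_epochs = as.integer(cone_warmup_epochs),
              polish_sweeps = as.integer(polish_sweeps),
              final_sweeps = as.integer(final_sweeps),
              epochs = as.integer(epochs),
              init_scale = init_scale, eps_ball = eps_ball,
              max_step = max_step,
              seed = as.integer(seed),
              variant = if (is.null(variant)) NA_character_ else variant)
  if (!is.na(cfg$variant)) {
    cfg$variant <- match.arg(cfg$variant, .VARIANTS)
    on_off <- switch(cfg$variant,
      poincare = c(0, 0, 0, 0),
      R        = c(1, 0, 0, 0),
      Ch       = c(0, 1, 0, 0),
      C        = c(1, 1, 1, 0),
      full     = c(1, 1, 1, 1))
    w <- c(lambda_root, lambda_child, lambda_cone, lambda_nonhier) * on_off
    cfg$lambda_root <- w[1]; cfg$lambda_child <- w[2]
    cfg$lambda_cone <- w[3]; cfg$lambda_nonhier <- w[4]
  }
  validate_config(cfg)
  structure(cfg, class = "train_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$dim >= 1L, cfg$delta > 0, cfg$K > 0, cfg$margin >= 0,
            cfg$lambda_root >= 0, cfg$lambda_child >= 0,
            cfg$lambda_cone >= 0, cfg$lambda_nonhier >= 0,
            cfg$n_negatives >= 1L, cfg$lr > 0,
            cfg$burn_in_epochs >= 0L,
            cfg$burn_in_factor > 0, cfg$burn_in_factor <= 1,
            cfg$anneal_frac >= 0, cfg$anneal_frac < 1,
            cfg$anneal_floor > 0, cfg$anneal_floor <= 1,
            cfg$cone_warmup_epochs >= 0L, cfg$polish_sweeps >= 0L,
            cfg$final_sweeps >= 0L,
            cfg$epochs >= 0L, cfg$init_scale >= 0,
            cfg$eps_ball > 0, cfg$eps_ball < 0.1,
            cfg$max_step > 0)
  invisible(cfg)
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config> variant=%s d=%d delta=%g K=%g margin=%g\n",
              x$variant, x$dim, x$delta, x$K, x$margin))
  cat(sprintf("  lambda (root/child/cone/nonhier) = %g/%g/%g/%g\n",
              x$lambda_root, x$lambda_child, x$lambda_cone, x$lambda_nonhier))
  cat(sprintf("  negatives=%d lr=%g burn-in=%dx%g epochs=%d init_scale=%g eps_ball=%g seed=%d\n",
              x$n_negatives, x$lr, x$burn_in_epochs, x$burn_in_factor,
              x$epochs, x$init_scale, x$eps_ball, x$seed))
  invisible(x)
}

#' Read a training configuration from a flat key-value file
#'
#' One `key = value` (or `key: value` or tab-separated) pair per line;
#' blank lines and `#` comments are ignored. Keys must match
#' [train_config()] argument names exactly; an unknown key is an error.
#' Missing keys take the defaults.
#'
#' @param path path to the config file.
#' @return A [train_config()].
#' @export
read_train_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)[ \t]*[=:\t][ \t]*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) != 3L)
  if (length(bad)) {
    stop(sprintf("config parse error at line: '%s'", lines[bad[1]]), call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  allowed <- names(formals(train_config))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  num <- setdiff(keys, "variant")
  args[num] <- lapply(args[num], function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop(sprintf("non-numeric value '%s' in config", v), call. = FALSE)
    x
  })
  do.call(train_config, args)
}
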