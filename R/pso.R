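# Binary particle swarm optimization over feature masks.  Velocities follow
# the canonical update v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x) with
# fresh uniform draws per component, clamped to [-v_max, v_max]; positions
# are re-sampled through the sigmoid transfer s(v) = 1/(1 + exp(-v)).  The
# fitness (lower is better) trades wrapper classification error against
# subset size.

#' Swarm parameters for binary PSO feature selection
#'
#' @param n_particles swarm size (default 30).
#' @param n_iterations iterations (default 100).
#' @param w_start,w_end inertia weight, decayed linearly across iterations
#'   (0.9 to 0.4).
#' @param c1,c2 cognitive and social learning coefficients (default 2, 2).
#' @param v_max velocity clamp (default 6, near sigmoid saturation).
#' @param w_acc,w_size fitness weights for (1 - accuracy) and subset
#'   fraction; must sum to 1 (defaults 0.99 / 0.01 so accuracy dominates
#'   with mild parsimony pressure).
#' @param inner_k neighbours for the k-NN wrapper classifier (default 5).
#' @param inner_folds stratified CV folds inside the fitness (default 5).
#' @param seed integer seed; the whole run is deterministic given it.
#' @return object of class `swarm_params`.
#' @export
swarm_params <- function(n_particles = 30, n_iterations = 100,
                         w_start = 0.9, w_end = 0.4, c1 = 2, c2 = 2,
                         v_max = 6, w_acc = 0.99, w_size = 0.01,
                         inner_k = 5, inner_folds = 5, seed = 1L) {
  if (n_particles < 2) stop("n_particles must be >= 2")
  if (c1 < 0 || c2 < 0) stop("c1 and c2 must be >= 0")
  if (v_max <= 0) stop("v_max must be > 0")
  if (abs(w_acc + w_size - 1) > 1e-12) stop("w_acc + w_size must equal 1")
  structure(as.list(environment()), class = "swarm_params")
}

#' Velocity update (one particle)
#'
#' @param velocity,position,pbest,gbest numeric vectors of equal length
#'   (position/pbest/gbest are 0/1 masks).
#' @param w current inertia weight.
#' @param params a [swarm_params()].
#' @return clamped new velocity; uses fresh `runif` draws per component.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, w, params) {
  n <- length(velocity)
  if (length(position) != n || length(pbest) != n || length(gbest) != n)
    stop("dimension mismatch in velocity update")
  r1 <- runif(n); r2 <- runif(n)
  v <- w * velocity + params$c1 * r1 * (pbest - position) +
    params$c2 * r2 * (gbest - position)
  pmin(pmax(v, -params$v_max), params$v_max)
}

#' Sigmoid binarization of a velocity vector
#'
#' `bit_j = 1` iff a uniform draw falls below `1/(1 + exp(-v_j))`.  An
#' all-zero mask is repaired by setting one uniformly chosen bit so every
#' particle always selects at least one feature.
#'
#' @param velocity numeric vector.
#' @return integer 0/1 vector.
#' @export
binarize_position <- function(velocity) {
  s <- 1 / (1 + exp(-velocity))
  bits <- as.integer(runif(length(velocity)) < s)
  if (!any(bits)) bits[sample.int(length(bits), 1)] <- 1L
  bits
}

# Stratified fold assignment used by both the PSO fitness and the outer CV.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class `", cl, "` has fewer members (", length(idx),
           ") than folds (", k, ")")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' PSO fitness of a feature mask
#'
#' `f = w_acc * (1 - innerAcc) + w_size * (#selected / N)`, where `innerAcc`
#' is the pooled stratified `inner_folds`-fold CV accuracy of a k-NN
#' (`inner_k`) classifier on the masked, per-fold-standardized columns.
#' Lower is better.
#'
#' @param mask 0/1 vector with at least one bit set.
#' @param X numeric feature matrix.
#' @param y label vector (2 classes).
#' @param params a [swarm_params()].
#' @param folds optional precomputed fold assignment (so every evaluation in
#'   one PSO run shares folds).
#' @return scalar fitness.
#' @export
pso_fitness <- function(mask, X, y, params = swarm_params(), folds = NULL) {
  if (!any(mask == 1)) stop("empty feature mask")
  if (length(unique(y)) < 2) stop("fitness needs at least 2 classes")
  if (is.null(folds)) folds <- .stratified_folds(y, params$inner_folds)
  Xs <- X[, mask == 1, drop = FALSE]
  correct <- 0L
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    mu <- colMeans(Xs[tr, , drop = FALSE])
    sdv <- apply(Xs[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xs[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(Xs[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    pred <- class::knn(Xtr, Xte, factor(y[tr]), k = params$inner_k)
    correct <- correct + sum(pred == y[!tr])
  }
  acc <- correct / length(y)
  params$w_acc * (1 - acc) + params$w_size * mean(mask)
}

#' Run binary PSO feature selection
#'
#' Full swarm loop: random binary initialization, fitness evaluation,
#' personal/global best tracking, velocity update with sigmoid
#' binarization.  The returned global-best fitness history is monotone
#' non-increasing by construction, and the whole run is reproducible from
#' `params$seed`.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y labels (2 classes).
#' @param params a [swarm_params()].
#' @return list with `mask` (0/1 vector), `selected` (column names or
#'   indices), `fitness` (gbest), `history` (per-iteration gbest fitness)
#'   and `n_selected`.
#' @export
run_pso <- function(X, y, params = swarm_params()) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty feature matrix")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  N <- ncol(X)
  with_seed(params$seed, {
    folds <- .stratified_folds(y, params$inner_folds)
    pos <- matrix(rbinom(params$n_particles * N, 1, 0.5),
                  params$n_particles, N)
    for (i in seq_len(params$n_particles))
      if (!any(pos[i, ] == 1)) pos[i, sample.int(N, 1)] <- 1L
    vel <- matrix(runif(params$n_particles * N, -1, 1),
                  params$n_particles, N)
    fit <- vapply(seq_len(params$n_particles), function(i) {
      pso_fitness(pos[i, ], X, y, params, folds)
    }, numeric(1))
    pbest <- pos; pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    history <- numeric(params$n_iterations)
    for (t in seq_len(params$n_iterations)) {
      w <- params$w_start -
        (params$w_start - params$w_end) * (t - 1) / max(1, params$n_iterations - 1)
      for (i in seq_len(params$n_particles)) {
        vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                    w, params)
        pos[i, ] <- binarize_position(vel[i, ])
        f <- pso_fitness(pos[i, ], X, y, params, folds)
        if (f < pbest_fit[i]) { pbest[i, ] <- pos[i, ]; pbest_fit[i] <- f }
        if (f < gbest_fit) { gbest <- pos[i, ]; gbest_fit <- f }
      }
      history[t] <- gbest_fit
    }
    sel <- if (!is.null(colnames(X))) colnames(X)[gbest == 1] else which(gbest == 1)
    list(mask = gbest, selected = sel, fitness = gbest_fit,
         history = history, n_selected = sum(gbest))
  })
}

#' Planted-informative synthetic feature matrix
#'
#' Benchmark for selection recovery: standard-normal noise features with
#' `n_informative` columns whose class means are shifted by `snr` standard
#' deviations.  The informative columns are the first `n_informative`.
#'
#' @param n samples (split evenly between the two classes).
#' @param p features.
#' @param n_informative planted informative features.
#' @param snr class mean shift in SD units (default 2).
#' @param seed integer seed.
#' @return list with `X` (n x p matrix, columns `f1..fp`), `y` (labels
#'   `"MI"` / `"healthy"`) and `informative` (column names).
#' @export
make_planted_matrix <- function(n = 400, p = 50, n_informative = 5,
                                snr = 2, seed = 1L) {
  with_seed(seed, {
    y <- rep(c("MI", "healthy"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    shift <- ifelse(y == "MI", snr / 2, -snr / 2)
    for (j in seq_len(n_informative)) X[, j] <- X[, j] + shift
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = y, informative = colnames(X)[seq_len(n_informative)])
  })
}
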