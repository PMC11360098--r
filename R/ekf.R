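#' Extended Kalman filter model
#'
#' Bundles the state-transition function `f`, the observation function `h`,
#' their Jacobians, and the noise covariances `Q` (process) and `R`
#' (observation). When an analytic Jacobian is not supplied it is computed
#' by central differences. The default is the linear constant-velocity
#' bounding-box model with state `x = [cx, cy, w, h, vx, vy]` and
#' observation `z = [cx, cy, w, h]`, for which the EKF reduces exactly to
#' the ordinary Kalman filter.
#'
#' @param f State-transition function `f(x, dt)`.
#' @param h Observation function `h(x)`.
#' @param Q Process-noise covariance (symmetric PSD).
#' @param R Observation-noise covariance (symmetric PSD).
#' @param F_jac Optional analytic Jacobian `F(x, dt)` of `f`.
#' @param H_jac Optional analytic Jacobian `H(x)` of `h`.
#' @return Object of class `ekf_model`.
#' @export
ekf_model <- function(f, h, Q, R, F_jac = NULL, H_jac = NULL) {
  check_psd(Q, "Q"); check_psd(R, "R")
  structure(list(f = f, h = h, Q = Q, R = R,
                 F_jac = F_jac, H_jac = H_jac),
            class = "ekf_model")
}

check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8)) {
    stop(sprintf("%s must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) {
    stop(sprintf("%s must be positive semi-definite", name), call. = FALSE)
  }
  invisible(TRUE)
}

#' Default constant-velocity bounding-box model
#'
#' State `[cx, cy, w, h, vx, vy]` in pixels; per step the center advances
#' by the velocity, size and velocity are constant. The default noise
#' levels (`Q = diag(1, 1, 0.25, 0.25, 4, 4)` px^2,
#' `R = diag(4, 4, 4, 4)` px^2) assume a roughly 2 px detector jitter and
#' allow a few px/frame of unmodelled acceleration.
#'
#' @param Q,R Optional covariance overrides.
#' @return An [ekf_model()].
#' @export
constant_velocity_model <- function(Q = diag(c(1, 1, 0.25, 0.25, 4, 4)),
                                    R = diag(c(4, 4, 4, 4))) {
  Fm <- function(dt) {
    M <- diag(6)
    M[1, 5] <- dt; M[2, 6] <- dt
    M
  }
  ekf_model(
    f = function(x, dt = 1) as.numeric(Fm(dt) %*% x),
    h = function(x) x[1:4],
    Q = Q, R = R,
    F_jac = function(x, dt = 1) Fm(dt),
    H_jac = function(x) cbind(diag(4), matrix(0, 4, 2))
  )
}

#' Central-difference numeric Jacobian
#'
#' @param fn Vector-valued function of a numeric vector.
#' @param x Point at which to differentiate.
#' @param rel_step Relative step size.
#' @return Jacobian matrix `length(fn(x)) x length(x)`.
#' @export
numeric_jacobian <- function(fn, x, rel_step = 1e-6) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hstep <- rel_step * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hstep
    xm <- x; xm[j] <- xm[j] - hstep
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hstep)
  }
  J
}

symmetrize <- function(M) (M + t(M)) / 2

#' Track state
#'
#' The tracker's persistent record: EKF state vector and covariance, the
#' 64-bit reference appearance hash, a counter of frames since the last
#' detector hit, and the status of the Fig-style control loop.
#'
#' @param x Numeric state vector.
#' @param P Error covariance (symmetric PSD).
#' @param ref_hash Reference dhash (see [dhash()]), or `NULL`.
#' @param frames_since_detection Integer.
#' @param status One of `"initializing"`, `"tracking"`, `"lost"`.
#' @return Object of class `track_state`.
#' @export
track_state <- function(x, P, ref_hash = NULL, frames_since_detection = 0L,
                        status = "tracking") {
  stopifnot(status %in% c("initializing", "tracking", "lost"))
  structure(list(x = as.numeric(x), P = symmetrize(as.matrix(P)),
                 ref_hash = ref_hash,
                 frames_since_detection = as.integer(frames_since_detection),
                 status = status),
            class = "track_state")
}

#' @export
print.track_state <- function(x, ...) {
  cat(sprintf("<track_state> status %s, x = [%s], %d frame(s) since detection\n",
              x$status, paste(sprintf("%.1f", x$x), collapse = ", "),
              x$frames_since_detection))
  invisible(x)
}

#' EKF prediction step
#'
#' Propagates the state through the transition function and the covariance
#' through its (analytic or numeric) Jacobian:
#' `x <- f(x)`, `P <- F P F' + Q`, with `P` re-symmetrized.
#'
#' @param ts A [track_state()] with status not `"lost"`.
#' @param m An [ekf_model()].
#' @param dt Time step (frames or seconds, consistent with `f`).
#' @return The prior [track_state()].
#' @export
ekf_predict <- function(ts, m, dt = 1) {
  if (ts$status == "lost") stop("cannot predict a lost track", call. = FALSE)
  Fj <- if (!is.null(m$F_jac)) m$F_jac(ts$x, dt) else {
    numeric_jacobian(function(x) m$f(x, dt), ts$x)
  }
  x_new <- m$f(ts$x, dt)
  if (!all(is.finite(x_new))) {
    stop(sprintf("numeric failure in ekf_predict; state = [%s]",
                 paste(ts$x, collapse = ", ")), call. = FALSE)
  }
  ts$x <- x_new
  ts$P <- symmetrize(Fj %*% ts$P %*% t(Fj) + m$Q)
  ts
}

#' EKF update (correction) step
#'
#' Standard EKF correction: innovation `y = z - h(x)`,
#' `S = H P H' + R`, gain `K = P H' S^-1`, `x <- x + K y`,
#' `P <- (I - K H) P` (re-symmetrized). A singular innovation covariance is
#' regularized with a 1e-9 diagonal jitter and a warning.
#'
#' @param prior A [track_state()] produced by [ekf_predict()].
#' @param z Observation vector (for the default model, a [bbox()] or its
#'   `[cx, cy, w, h]` vector).
#' @param m An [ekf_model()].
#' @return The posterior [track_state()] with `frames_since_detection = 0`.
#' @export
ekf_update <- function(prior, z, m) {
  if (inherits(z, "bbox")) z <- as.numeric(z[c("cx", "cy", "w", "h")])
  Hj <- if (!is.null(m$H_jac)) m$H_jac(prior$x) else {
    numeric_jacobian(m$h, prior$x)
  }
  y <- z - m$h(prior$x)
  S <- Hj %*% prior$P %*% t(Hj) + m$R
  K <- tryCatch(
    prior$P %*% t(Hj) %*% solve(S),
    error = function(e) {
      warning("singular innovation covariance; applying diagonal jitter",
              call. = FALSE)
      prior$P %*% t(Hj) %*% solve(S + diag(1e-9, nrow(S)))
    })
  prior$x <- prior$x + as.numeric(K %*% y)
  n <- length(prior$x)
  prior$P <- symmetrize((diag(n) - K %*% Hj) %*% prior$P)
  prior$frames_since_detection <- 0L
  prior
}
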