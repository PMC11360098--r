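# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Textbook linear Kalman filter, batch form: given matrices F, H, Q, R and
# a sequence of observations, returns the filtered states and covariances.
# Uses the Joseph-form covariance update, unlike the package's standard
# form, so agreement is a genuine cross-check.
kf_oracle <- function(x0, P0, Fm, Hm, Q, R, zs) {
  n <- length(x0)
  x <- x0; P <- P0
  xs <- list(); Ps <- list()
  I <- diag(n)
  for (k in seq_along(zs)) {
    # predict
    x <- Fm %*% x
    P <- Fm %*% P %*% t(Fm) + Q
    # update (Joseph form)
    S <- Hm %*% P %*% t(Hm) + R
    K <- P %*% t(Hm) %*% solve(S)
    x <- x + K %*% (zs[[k]] - Hm %*% x)
    A <- I - K %*% Hm
    P <- A %*% P %*% t(A) + K %*% R %*% t(K)
    xs[[k]] <- as.numeric(x); Ps[[k]] <- P
  }
  list(x = xs, P = Ps)
}

# Bit-by-bit reference dhash for a patch already at 8 rows x 9 cols:
# no resampling, direct per-pixel comparison, row-major packing.
dhash_reference_8x9 <- function(img) {
  stopifnot(nrow(img) == 8, ncol(img) == 9)
  bits <- integer(0)
  for (r in 1:8) for (c in 1:8) {
    bits <- c(bits, as.integer(img[r, c] > img[r, c + 1]))
  }
  bits
}

# 3x3 homogeneous matrix multiply oracle for the printed foreshortening map
affine_matrix_oracle <- function(u, v, phi_deg) {
  phi <- phi_deg * pi / 180
  M <- matrix(c(cos(phi), 0, 0,
                -sin(phi), 1, 0,
                0, 0, 1), nrow = 3, byrow = TRUE)
  out <- M %*% c(u, v, 1)
  out[1:2] / out[3]
}

# convenience: a noiseless projected upright (or posed) skeleton
synth_skeleton <- function(yaw = 0, distance = 0.75, tilt = 0, drop = 0,
                           noise = 0, seed = 1L, cam = camera_model(),
                           tmpl = pose_template_3d()) {
  project_skeleton(make_skeleton3d(posture_spec(tilt, drop), tmpl),
                   scene_spec(yaw, distance, noise, seed), cam)
}

# a hand-built skeleton with explicit torso keypoints, everything else absent
manual_skeleton <- function(nose = NULL, neck = NULL, rsho = NULL,
                            lsho = NULL, rhip = NULL, lhip = NULL) {
  u <- rep(0, 18); v <- rep(0, 18); conf <- rep(0, 18)
  setkp <- function(i, p) {
    if (!is.null(p)) {
      u[i + 1] <<- p[1]; v[i + 1] <<- p[2]; conf[i + 1] <<- 1
    }
  }
  setkp(0L, nose); setkp(1L, neck); setkp(2L, rsho)
  setkp(5L, lsho); setkp(8L, rhip); setkp(11L, lhip)
  skeleton(u, v, conf)
}
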