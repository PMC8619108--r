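# Constant-velocity Kalman filter for one tracked shoulder point.
# State (x, y, vx, vy) in px and px/frame; measurements are (x, y).

KF_F <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 1, 0, 1, 0,
                 0, 1, 0, 1), 4, 4)  # column-major: x' = x + vx, etc.

KF_H <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4)

# discrete white-noise acceleration covariance, dt = 1
KF_QCV <- matrix(c(1 / 4, 0, 1 / 2, 0,
                   0, 1 / 4, 0, 1 / 2,
                   1 / 2, 0, 1, 0,
                   0, 1 / 2, 0, 1), 4, 4)

#' Initialise a Kalman state at a measured position
#'
#' Velocity starts at zero; position variance starts at the measurement
#' noise, velocity variance at \code{init_velocity_var}.
#'
#' @param x,y Initial shoulder position (px).
#' @param base_measurement_noise Measurement variance (px^2).
#' @param init_velocity_var Initial velocity variance ((px/frame)^2).
#' @return A \code{kalman_state}: list with mean \code{m}, covariance
#'   \code{P}.
#' @export
kf_init <- function(x, y, base_measurement_noise = 4, init_velocity_var = 25) {
  structure(list(m = c(x, y, 0, 0),
                 P = diag(c(base_measurement_noise, base_measurement_noise,
                            init_velocity_var, init_velocity_var))),
            class = "kalman_state")
}

#' Kalman prediction step (constant velocity, one frame)
#'
#' @param s A \code{kalman_state}.
#' @param process_noise Process-noise intensity (px^2/frame^2); scales a
#'   discrete white-noise-acceleration covariance.
#' @return The propagated \code{kalman_state}.
#' @export
#' @examples
#' s <- kf_init(10, 10); s$m[3:4] <- c(1, 0)
#' kf_predict(s, process_noise = 0)$m[1:2]  # (11, 10)
kf_predict <- function(s, process_noise = 1) {
  m <- KF_F %*% s$m
  P <- KF_F %*% s$P %*% t(KF_F) + process_noise * KF_QCV
  structure(list(m = as.vector(m), P = P), class = "kalman_state")
}

#' Kalman update step with scalable measurement noise
#'
#' Standard linear update with measurement covariance
#' \code{base_measurement_noise * noise_scale * I}. Inflating
#' \code{noise_scale} down-weights a suspect measurement (the corrupted-frame
#' fallback); in the limit the prior is returned unchanged. Non-finite
#' measurements are treated as missing (no update).
#'
#' @param s A \code{kalman_state} (the prediction at the current frame).
#' @param z Measured position \code{c(x, y)}.
#' @param noise_scale Multiplier on the measurement variance (default 1).
#' @param base_measurement_noise Base measurement variance (px^2).
#' @return The posterior \code{kalman_state}.
#' @export
kf_update <- function(s, z, noise_scale = 1, base_measurement_noise = 4) {
  if (length(z) != 2 || !all(is.finite(z))) return(s)
  R <- base_measurement_noise * noise_scale * diag(2)
  S <- KF_H %*% s$P %*% t(KF_H) + R
  K <- s$P %*% t(KF_H) %*% solve(S)
  m <- s$m + as.vector(K %*% (z - as.vector(KF_H %*% s$m)))
  IKH <- diag(4) - K %*% KF_H
  P <- IKH %*% s$P %*% t(IKH) + K %*% R %*% t(K)  # Joseph form
  structure(list(m = m, P = (P + t(P)) / 2), class = "kalman_state")
}
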