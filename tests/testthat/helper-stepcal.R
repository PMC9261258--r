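# Shared helpers: small fixtures built in code, an independent RK4
# integrator used as an oracle, and a cache for the expensive end-to-end
# calibration shared across acceptance tests.

# trajectory with one variable following a given function of time
make_traj <- function(times, ..., fn = NULL, var = "y") {
  vals <- if (!is.null(fn)) fn(times) else list(...)[[1L]]
  out <- data.frame(t = times)
  out[[var]] <- vals
  out
}

# Independent fixed-step RK4 integration of the rim ODE, written directly
# from the documented equations (no calls into the package's simulator).
rk4_rim_model <- function(p, n0, times, dt = 1e-3, in_vitro = TRUE) {
  deriv <- function(y) {
    pc <- max(y[1], 0); qc <- max(y[2], 0); nc <- max(y[3], 0)
    vol <- (pc + qc + nc) / p$cancer_cd            # cm^3
    R <- (3 * vol / (4 * pi))^(1 / 3) * 1e4        # um
    g_q <- if (R > 0) (max(R - p$L_p, 0) / R)^3 else 0
    g_n <- if (R > 0) (max(R - p$L_v, 0) / R)^3 else 0
    e_imm <- if (in_vitro) 0 else p$e_imm
    c(p$k_div * pc - p$k_q * g_q * pc - e_imm * pc,
      p$k_q * g_q * pc - p$k_n * g_n * qc - e_imm * qc,
      p$k_n * g_n * qc - p$k_lys * nc)
  }
  y <- c(n0, 0, 0)
  t <- times[1L]
  out <- matrix(NA_real_, length(times), 3L)
  out[1L, ] <- y
  for (i in seq_along(times)[-1L]) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- deriv(y)
      k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2)
      k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  data.frame(t = times, nb_pc = out[, 1L], nb_qc = out[, 2L],
             nb_nc = out[, 3L])
}

# one shared end-to-end calibration for the acceptance tests
.calibration_cache <- new.env(parent = emptyenv())
cached_calibration <- function(seed = 1L) {
  key <- paste0("run_", seed)
  if (is.null(.calibration_cache[[key]])) {
    elapsed <- system.time(
      out <- calibrate_surrogate(seed = seed)
    )[["elapsed"]]
    out$elapsed_s <- elapsed
    .calibration_cache[[key]] <- out
  }
  .calibration_cache[[key]]
}
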