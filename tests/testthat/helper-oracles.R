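# Independent 1D finite-difference oracle: diffusion normal to a fully
# functionalized wall coupled to Langmuir kinetics, backward Euler in time.
# Deliberately shares no code with the package's FEM integrator.
oracle_binding_1d <- function(params, H, t_end, dt, ny = 160, grading = 1.05) {
  h0 <- H * (grading - 1) / (grading^ny - 1)
  hs <- h0 * grading^(0:(ny - 1))
  y <- c(0, cumsum(hs))
  n <- ny + 1
  vol <- numeric(n)
  vol[1] <- hs[1] / 2
  vol[n] <- hs[ny] / 2
  if (n > 2) vol[2:(n - 1)] <- (hs[-ny] + hs[-1]) / 2
  D <- params$D_antigen
  # assemble FV diffusion matrix: vol_i dC_i/dt = sum_faces D (C_j - C_i)/h
  A <- matrix(0, n, n)
  for (i in seq_len(ny)) {
    w <- D / hs[i]
    A[i, i] <- A[i, i] - w;     A[i, i + 1] <- A[i, i + 1] + w
    A[i + 1, i + 1] <- A[i + 1, i + 1] - w; A[i + 1, i] <- A[i + 1, i] + w
  }
  C <- rep(params$C0, n)
  B <- 0
  nst <- ceiling(t_end / dt)
  times <- seq_len(nst) * dt
  Bout <- numeric(nst)
  denom <- 1 + dt * params$k_off
  for (s in seq_len(nst)) {
    # implicit: (V/dt - A) C_new = V/dt C - wall sink at node 1
    M <- diag(vol / dt) - A
    a <- params$k_on * (params$R_T - B) / denom
    r <- params$k_off * B / denom
    M[1, 1] <- M[1, 1] + a
    rhs <- vol / dt * C
    rhs[1] <- rhs[1] + r
    C <- solve(M, rhs)
    B <- (B + dt * params$k_on * (params$R_T - B) * C[1]) / denom
  }
  list(time = times, B = Bout, B_final = B, C = C, y = y)
}

# coarse resolution used for most physics tests (keeps the suite fast while
# staying well inside the graded-mesh asymptotic regime)
RES_COARSE <- 0.5
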