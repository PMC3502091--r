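# Shared fixtures: packaged parameter sets and small helpers used across
# test files.  Everything is built in code; no stored data.

AGENTS <- default_agents()
BODY <- body_params()
ISO <- AGENTS$isoflurane
SEVO <- AGENTS$sevoflurane
DES <- AGENTS$desflurane

# absolute tissue blood flows and capacities for hand arithmetic
tissue_flows <- function(body = BODY) {
  body$q_total * c(vrg = body$f_vrg, mus = body$f_mus, fat = body$f_fat)
}
tissue_capacities <- function(agent, body = BODY) {
  c(vrg = body$v_vrg * agent$lambda_vrg,
    mus = body$v_mus * agent$lambda_mus,
    fat = body$v_fat * agent$lambda_fat)
}

# total agent volume stored in circuit + alveoli + tissues, L vol%
stored_amount <- function(trace_row, agent, body = BODY) {
  caps <- tissue_capacities(agent, body)
  body$v_circuit * trace_row$f_i + body$frc * trace_row$f_a +
    caps[["vrg"]] * trace_row$f_vrg + caps[["mus"]] * trace_row$f_mus +
    caps[["fat"]] * trace_row$f_fat
}

# Independent trajectory oracle for any fixed-settings phase: the model is
# linear, ds/dt = A s + b, solved here by eigendecomposition rather than
# time stepping.
linear_oracle <- function(times, init, f_d, fgf, v_a, agent, body = BODY) {
  q <- tissue_flows(body)
  caps <- tissue_capacities(agent, body)
  qp <- sum(q)
  lbg <- agent$lambda_blood
  A <- matrix(0, 5, 5)
  A[1, 1] <- -(fgf + v_a) / body$v_circuit
  A[1, 2] <- v_a / body$v_circuit
  A[2, 1] <- v_a / body$frc
  A[2, 2] <- -(v_a + lbg * qp) / body$frc
  A[2, 3:5] <- lbg * q / body$frc
  for (i in 1:3) {
    A[2 + i, 2] <- lbg * q[i] / caps[i]
    A[2 + i, 2 + i] <- -lbg * q[i] / caps[i]
  }
  b <- c(fgf * f_d / body$v_circuit, 0, 0, 0, 0)
  eg <- eigen(A)
  V <- eg$vectors
  # particular solution: A sp = -b
  sp <- if (all(abs(b) == 0)) rep(0, 5) else solve(A, -b)
  c0 <- solve(V, init - sp)
  t(vapply(times, function(t) {
    as.numeric(Re(V %*% (c0 * exp(eg$values * t)))) + sp
  }, numeric(5)))
}
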