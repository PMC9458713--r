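# Independent brute-force oracles. These deliberately use naive loops and a
# different formulation path than the package implementation.

# Signed asymmetric modularity, term by term over all ordered pairs
# (self-pairs included; w_ii = 0 but the chance term is not).
oracle_signed_q <- function(W, module_of, gamma = 1) {
  n <- nrow(W)
  Wp <- matrix(pmax(W, 0), n); Wn <- matrix(pmax(-W, 0), n)
  sp <- sn <- numeric(n)
  for (i in 1:n) for (j in 1:n) { sp[i] <- sp[i] + Wp[i, j]; sn[i] <- sn[i] + Wn[i, j] }
  vp <- sum(sp); vn <- sum(sn)
  if (vp == 0 && vn == 0) return(0)
  qp <- qn <- 0
  for (i in 1:n) for (j in 1:n) {
    if (module_of[i] != module_of[j]) next
    if (vp > 0) qp <- qp + (Wp[i, j] - gamma * sp[i] * sp[j] / vp)
    if (vn > 0) qn <- qn + (Wn[i, j] - gamma * sn[i] * sn[j] / vn)
  }
  (if (vp > 0) qp / vp else 0) - (if (vn > 0) qn / (vp + vn) else 0)
}

oracle_pc <- function(W, module_of) {
  n <- nrow(W)
  Wp <- matrix(pmax(W, 0), n)
  out <- numeric(n)
  for (i in 1:n) {
    k <- sum(Wp[i, ])
    if (k == 0) { out[i] <- 0; next }
    acc <- 0
    for (s in sort(unique(module_of))) {
      kis <- sum(Wp[i, module_of == s])
      acc <- acc + (kis / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

oracle_wz <- function(W, module_of) {
  n <- nrow(W)
  Wp <- matrix(pmax(W, 0), n)
  kis <- numeric(n)
  for (i in 1:n) kis[i] <- sum(Wp[i, module_of == module_of[i]])
  out <- numeric(n)
  for (i in 1:n) {
    members <- which(module_of == module_of[i])
    mu <- mean(kis[members])
    sig <- sqrt(sum((kis[members] - mu)^2) / length(members))
    out[i] <- if (sig > 0) (kis[i] - mu) / sig else 0
  }
  out
}

# All set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    k <- length(assign) + 1L
    if (k > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (lab in seq_len(next_label))
      rec(c(assign, lab), max(next_label, lab + 1L))
  }
  rec(integer(0), 1L)
  out
}

oracle_best_partition <- function(W, gamma = 1) {
  parts <- all_partitions(nrow(W))
  qs <- vapply(parts, function(p) oracle_signed_q(W, p, gamma), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# Random small signed symmetric matrix with zero diagonal.
random_signed_fc <- function(n, density = 0.8) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  vals <- runif(sum(ut), -1, 1) * (runif(sum(ut)) < density)
  W[ut] <- vals
  W <- W + t(W)
  diag(W) <- 0
  W
}

# Run-length-encoding oracle for the temporal metrics.
oracle_rle_metrics <- function(labels) {
  r <- rle(labels)
  total <- length(r$values) - 1L
  runs_i <- r$lengths[r$values == "Integrated"]
  runs_s <- r$lengths[r$values == "Segregated"]
  starts <- r$values[-length(r$values)]
  list(
    fraction_integrated = sum(runs_i) / length(labels),
    dwell_integrated = if (length(runs_i)) mean(runs_i) else 0,
    dwell_segregated = if (length(runs_s)) mean(runs_s) else 0,
    n_transitions = total,
    n_is = sum(starts == "Integrated"),
    n_si = sum(starts == "Segregated"))
}

# Hand-coded BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1)
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  pmin(q_sorted, 1)[order(o)]
}

# Discrete-time QP oracle for the fixed-endpoint linear-quadratic problem:
# exact zero-order-hold discretization, piecewise-constant inputs on m
# intervals, trapezoid tracking cost, equality-constrained QP solved through
# its sparse KKT system. Returns the input energy (integral of u'u dt).
oracle_energy_qp <- function(A, x0, xT, rho = 1, T_horizon = 1, m = 400) {
  n <- nrow(A)
  dt <- T_horizon / m
  Ad <- as.matrix(Matrix::expm(A * dt))
  Bd <- solve(A, Ad - diag(n))          # A is stable hence invertible
  nu <- m * n                            # inputs u_0..u_{m-1}
  nx <- m * n                            # states x_1..x_m
  # objective 0.5 z' H z + b' z ; z = (u, x)
  wx <- rep(c(rep(dt, m - 1), dt / 2), each = n)
  H <- Matrix::Diagonal(x = c(rep(2 * dt * rho, nu), 2 * wx))
  b <- c(rep(0, nu), -2 * wx * rep(xT, m))
  # constraints: dynamics (m blocks) + terminal (x_m = xT)
  bi <- function(k) (k - 1L) * n + seq_len(n)
  rc <- expand.grid(r = seq_len(n), c = seq_len(n))
  ti <- list(); tj <- list(); tx <- list()
  for (k in 1:m) {
    rows <- bi(k)
    ti[[length(ti) + 1L]] <- rows;           tj[[length(tj) + 1L]] <- nu + bi(k)
    tx[[length(tx) + 1L]] <- rep(1, n)                        # +x_k
    ti[[length(ti) + 1L]] <- rows[rc$r];     tj[[length(tj) + 1L]] <- bi(k)[rc$c]
    tx[[length(tx) + 1L]] <- -Bd[cbind(rc$r, rc$c)]           # -Bd u_{k-1}
    if (k > 1) {
      ti[[length(ti) + 1L]] <- rows[rc$r]
      tj[[length(tj) + 1L]] <- nu + bi(k - 1L)[rc$c]
      tx[[length(tx) + 1L]] <- -Ad[cbind(rc$r, rc$c)]         # -Ad x_{k-1}
    }
  }
  ti[[length(ti) + 1L]] <- m * n + seq_len(n)
  tj[[length(tj) + 1L]] <- nu + bi(m)
  tx[[length(tx) + 1L]] <- rep(1, n)                          # terminal
  Amat <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                               x = unlist(tx),
                               dims = c(m * n + n, nu + nx))
  rhs <- c(drop(Ad %*% x0), rep(0, (m - 1) * n), xT)
  nc <- m * n + n
  KKT <- rbind(cbind(H, Matrix::t(Amat)),
               cbind(Amat, Matrix::Matrix(0, nc, nc, sparse = TRUE)))
  sol <- Matrix::solve(KKT, c(-b, rhs))
  u <- t(matrix(sol[seq_len(nu)], n, m))       # m x n, rows are intervals
  list(total_energy = dt * sum(u^2),
       nodal_energy = dt * colSums(u^2))
}

# Random stable system + states for control tests.
random_control_problem <- function(n = 5) {
  A0 <- matrix(runif(n * n), n, n)
  A0 <- (A0 + t(A0)) / 2
  diag(A0) <- 0
  A <- stabilize(A0)
  list(A = A, x0 = rnorm(n), xT = rnorm(n))
}
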