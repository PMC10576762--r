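#' @title State-space reduction and time integration
#'
#' @description The network is reduced to a linear time-invariant
#' state-space system driven by the periodic pressure sources: one state
#' per inductor (its flow) and one per capacitor on a free node (its
#' pressure). Zero-compliance internal nodes are eliminated algebraically
#' through nodal analysis; intramyocardial capacitors tied to a pressure
#' source contribute the source's time derivative to their node equation.
#' Integration uses a stiff-capable solver (lsoda by default) with the
#' constant system matrix supplied as the analytic Jacobian.
#'
#' @name solver
NULL

#' Solver settings
#'
#' @param n_beats number of heartbeats to simulate (default 30, minimum 2)
#' @param samples_per_beat reporting-grid resolution (default 200)
#' @param rtol,atol relative tolerance and absolute tolerance; `atol = NULL`
#'   picks per-state values scaled to typical pressures (~1e5 dyn/cm^2)
#'   and flows (~1 cm^3/s)
#' @param frequency_scale joint time/reactance scaling factor (default 1 =
#'   off; 1000 reproduces the block-diagram workaround of compressing time
#'   while dividing C and L by the same factor)
#' @param periodicity_tol relative difference between the last two beats'
#'   mean coronary flows below which the run is flagged converged
#' @param method `"matexp"` (default) propagates the linear system exactly
#'   on the reporting grid with the matrix exponential, summing the
#'   periodic particular solution per Fourier harmonic through the
#'   frequency response — the natural choice here because the vessel
#'   compartments form weakly damped resonators whose ringing forces a
#'   step-controlled integrator to take tens of thousands of steps. Any
#'   other value is passed as an integration method to [deSolve::ode()]
#'   (e.g. `"lsoda"`), which serves as an independent time-stepping route.
#' @return list of class `solver_settings`
#' @export
solver_settings <- function(n_beats = 30, samples_per_beat = 200,
                            rtol = 1e-6, atol = NULL, frequency_scale = 1,
                            periodicity_tol = 0.01, method = "matexp") {
  stopifnot(n_beats >= 2, samples_per_beat >= 20, rtol > 0,
            is.null(atol) || all(atol > 0), frequency_scale > 0,
            periodicity_tol > 0)
  structure(list(n_beats = as.integer(n_beats),
                 samples_per_beat = as.integer(samples_per_beat),
                 rtol = rtol, atol = atol,
                 frequency_scale = frequency_scale,
                 periodicity_tol = periodicity_tol, method = method),
            class = "solver_settings")
}

#' Reduce a network to a linear state-space system
#'
#' States are the flows through every inductive branch followed by the
#' pressures of every free capacitive node; the system reads
#' `dx/dt = A x + B u(t) + Bd du/dt(t)` with `u` the vector of source
#' pressures. Output maps recover all node pressures and branch flows
#' linearly from `(x, u)`. Kirchhoff's current law holds at every node by
#' construction. A free zero-compliance node with no resistive attachment
#' (a pure inductive junction) cannot be eliminated and raises an assembly
#' error.
#'
#' @param network an [lpm_network()]
#' @return object of class `state_space` with matrices `A`, `B`, `Bd` and
#'   the output maps `Cp`, `Dp` (node pressures) and `Cq`, `Dq` (branch
#'   flows)
#' @export
to_state_space <- function(network) {
  stopifnot(inherits(network, "lpm_network"))
  nd <- network$nodes
  br <- network$branches
  src_names <- names(network$sources)
  m <- length(src_names)

  ind <- which(br$L > 0)          # inductive branches: flow states
  res <- which(br$L == 0)         # purely resistive branches
  pinned <- which(!is.na(nd$pin))
  dyn <- which(nd$C > 0 & is.na(nd$pin))
  alg <- which(nd$C == 0 & is.na(nd$pin))
  nL <- length(ind)
  nD <- length(dyn)
  ns <- nL + nD
  if (ns == 0L) stop("network has no states (no inductors or capacitors)")

  id2row <- integer(max(c(0L, nd$node)))
  id2row[nd$node] <- seq_len(nrow(nd))
  pin_src <- match(nd$pin[pinned], src_names)
  cref_src <- match(nd$c_ref, src_names)   # NA where capacitor to ground

  # conductance system for algebraic nodes
  nA <- length(alg)
  if (nA > 0) {
    G <- matrix(0, nA, nA)
    alg_pos <- integer(nrow(nd))
    alg_pos[alg] <- seq_len(nA)
    for (b in res) {
      g <- 1 / br$R[b]
      for (end in c("from", "to")) {
        n_id <- br[[end]][b]
        if (n_id == 0L) next
        i <- id2row[n_id]
        if (i %in% alg) {
          ai <- alg_pos[i]
          G[ai, ai] <- G[ai, ai] + g
          other <- if (end == "from") br$to[b] else br$from[b]
          if (other != 0L) {
            j <- id2row[other]
            if (j %in% alg) G[ai, alg_pos[j]] <- G[ai, alg_pos[j]] - g
          }
        }
      }
    }
    if (any(abs(diag(G)) < .Machine$double.eps)) {
      stop("assembly error: zero-compliance node with no resistive path ",
           "(pure inductive junction) cannot be eliminated")
    }
    Ginv <- solve(G)
  }

  # full linear evaluation: given states x, sources u, source derivatives
  # udot, return state derivatives, all node pressures, all branch flows
  evaluate <- function(x, u, udot) {
    qL <- x[seq_len(nL)]
    Pd <- x[nL + seq_len(nD)]
    P <- numeric(nrow(nd) + 1L)        # index node_id + 1; P[1] = ground
    if (length(pinned)) P[nd$node[pinned] + 1L] <- u[pin_src]
    if (nD) P[nd$node[dyn] + 1L] <- Pd
    if (nA > 0) {
      rhs <- numeric(nA)
      for (b in res) {
        g <- 1 / br$R[b]
        fi <- br$from[b]; ti <- br$to[b]
        fa <- fi != 0L && id2row[fi] %in% alg
        ta <- ti != 0L && id2row[ti] %in% alg
        if (fa && !ta) rhs[alg_pos[id2row[fi]]] <-
            rhs[alg_pos[id2row[fi]]] + g * P[ti + 1L]
        if (ta && !fa) rhs[alg_pos[id2row[ti]]] <-
            rhs[alg_pos[id2row[ti]]] + g * P[fi + 1L]
      }
      for (k in seq_along(ind)) {
        b <- ind[k]
        fi <- br$from[b]; ti <- br$to[b]
        if (fi != 0L && id2row[fi] %in% alg)
          rhs[alg_pos[id2row[fi]]] <- rhs[alg_pos[id2row[fi]]] - qL[k]
        if (ti != 0L && id2row[ti] %in% alg)
          rhs[alg_pos[id2row[ti]]] <- rhs[alg_pos[id2row[ti]]] + qL[k]
      }
      P[nd$node[alg] + 1L] <- Ginv %*% rhs
    }
    flows <- numeric(nrow(br))
    flows[ind] <- qL
    if (length(res)) {
      flows[res] <- (P[br$from[res] + 1L] - P[br$to[res] + 1L]) / br$R[res]
    }
    inflow <- numeric(nrow(nd) + 1L)
    for (b in seq_len(nrow(br))) {
      inflow[br$from[b] + 1L] <- inflow[br$from[b] + 1L] - flows[b]
      inflow[br$to[b] + 1L] <- inflow[br$to[b] + 1L] + flows[b]
    }
    dx <- numeric(ns)
    if (nL) {
      dx[seq_len(nL)] <- (P[br$from[ind] + 1L] - P[br$to[ind] + 1L] -
                            br$R[ind] * qL) / br$L[ind]
    }
    if (nD) {
      dd <- inflow[nd$node[dyn] + 1L] / nd$C[dyn]
      cs <- cref_src[dyn]
      has <- !is.na(cs)
      if (any(has)) dd[has] <- dd[has] + udot[cs[has]]
      dx[nL + seq_len(nD)] <- dd
    }
    list(dx = dx, P = P[-1L], flows = flows)
  }

  z_s <- numeric(ns)
  z_u <- numeric(m)
  A <- matrix(0, ns, ns)
  Cp <- matrix(0, nrow(nd), ns)
  Cq <- matrix(0, nrow(br), ns)
  for (i in seq_len(ns)) {
    e <- z_s; e[i] <- 1
    ev <- evaluate(e, z_u, z_u)
    A[, i] <- ev$dx
    Cp[, i] <- ev$P
    Cq[, i] <- ev$flows
  }
  B <- matrix(0, ns, m)
  Bd <- matrix(0, ns, m)
  Dp <- matrix(0, nrow(nd), m)
  Dq <- matrix(0, nrow(br), m)
  for (j in seq_len(m)) {
    e <- z_u; e[j] <- 1
    ev <- evaluate(z_s, e, z_u)
    B[, j] <- ev$dx
    Dp[, j] <- ev$P
    Dq[, j] <- ev$flows
    Bd[, j] <- evaluate(z_s, z_u, e)$dx
  }
  state_names <- c(if (nL) paste0("q_", br$label[ind]),
                   if (nD) paste0("p_", nd$label[dyn]))
  dimnames(A) <- list(state_names, state_names)
  structure(list(A = A, B = B, Bd = Bd, Cp = Cp, Dp = Dp, Cq = Cq, Dq = Dq,
                 state_names = state_names, node_labels = nd$label,
                 branch_labels = br$label, sources = src_names,
                 n_inductors = nL, n_capacitors = nD, network = network),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State-space system:", length(x$state_names), "states (",
      x$n_inductors, "inductor flows,", x$n_capacitors,
      "capacitor pressures ),", length(x$sources), "sources\n")
  invisible(x)
}

#' Apply the joint frequency/reactance scaling
#'
#' Compresses time by `factor` while dividing every capacitance and
#' inductance by the same factor; resistances and source amplitudes are
#' untouched. The solution of the scaled problem, with its time axis
#' stretched back, reproduces the unscaled solution (the reactive
#' impedances `omega L` and `1/(omega C)` are invariant under the joint
#' scaling).
#'
#' @param network an `lpm_network`
#' @param factor positive scale factor (1 = identity)
#' @return the scaled network (sources included)
#' @export
apply_frequency_scaling <- function(network, factor) {
  .check_positive(factor, "factor")
  if (factor == 1) return(network)
  network <- scale_reactances(network, 1 / factor)
  network$sources <- lapply(network$sources, .scale_source_time, factor)
  network
}

#' Integrate a network over a fixed number of heartbeats
#'
#' Simulates `n_beats` periods from diastolic initial conditions (all
#' capacitor pressures at the inlet diastolic pressure, all inductor flows
#' zero), reports node pressures and branch flows on a uniform grid, mean
#' flow per branch for every beat, and the mean coronary blood flow over
#' the final beat. The run is flagged converged when the last two beats'
#' mean coronary flows agree within the periodicity tolerance.
#'
#' @param network an [lpm_network()] (typically from [assemble_network()])
#' @param settings a [solver_settings()]
#' @param system optional pre-computed [to_state_space()] result for
#'   `network`
#' @return object of class `lpm_simulation`: `time` (s), `pressures`
#'   (matrix, dyn/cm^2, one column per node), `flows` (matrix, cm^3/s, one
#'   column per branch), `beat_flow_means` (beats x branches), `cbf`
#'   (named ml/s vector for the coronary inflow branches, when present),
#'   `converged`, `settings`
#' @export
simulate_network <- function(network, settings = solver_settings(),
                             system = NULL) {
  stopifnot(inherits(network, "lpm_network"))
  fscale <- settings$frequency_scale
  if (fscale != 1) {
    scaled <- apply_frequency_scaling(network, fscale)
    inner <- settings
    inner$frequency_scale <- 1
    sim <- simulate_network(scaled, inner)
    sim$time <- sim$time * fscale      # stretch back to physical time
    sim$settings <- settings
    return(sim)
  }
  if (is.null(system)) system <- to_state_space(network)
  srcs <- network$sources
  periods <- vapply(srcs, `[[`, numeric(1), "period")
  if (diff(range(periods)) > 1e-9 * periods[1]) {
    stop("all sources must share one period")
  }
  T <- periods[[1]]
  nb <- settings$n_beats
  spb <- settings$samples_per_beat
  times <- seq(0, nb * T, length.out = nb * spb + 1L)

  m <- length(srcs)
  H <- max(vapply(srcs, function(s) length(s$fourier$an), integer(1)))
  a0v <- vapply(srcs, function(s) s$fourier$a0, numeric(1))
  An <- Bn <- matrix(0, m, H)
  for (j in seq_len(m)) {
    an <- srcs[[j]]$fourier$an
    An[j, seq_along(an)] <- an
    Bn[j, seq_along(an)] <- srcs[[j]]$fourier$bn
  }
  wk <- seq_len(H) * 2 * pi / T
  Anw <- sweep(An, 2, wk, `*`)
  Bnw <- sweep(Bn, 2, wk, `*`)

  A <- system$A
  BuM <- system$B
  BdM <- system$Bd
  nL <- system$n_inductors
  nD <- system$n_capacitors
  inlet_src <- srcs[[stats::na.omit(network$nodes$pin)[1]]]
  p0 <- if (!is.null(inlet_src$dbp)) {
    pressure_mmhg_to_cgs(inlet_src$dbp)
  } else inlet_src$fourier$a0
  x0 <- c(rep(0, nL), rep(p0, nD))

  if (settings$method == "matexp") {
    # exact propagation of the LTI system on the reporting grid:
    # x(t) = x_p(t) + expm(A t) (x0 - x_p(0)), with the periodic particular
    # solution x_p assembled per harmonic from the frequency response
    ns <- nrow(A)
    Xdc <- tryCatch(solve(A, -BuM %*% a0v), error = function(e) {
      stop("singular system matrix (no DC operating point); ",
           "use an ODE-integrator method such as \"lsoda\"", call. = FALSE)
    })
    XK <- matrix(0i, ns, H)
    I_ns <- diag(ns)
    for (k in seq_len(H)) {
      uhat <- An[, k] - 1i * Bn[, k]       # u_k(t) = Re(uhat e^{i k w0 t})
      w <- wk[k]
      XK[, k] <- solve(1i * w * I_ns - A,
                       (BuM + 1i * w * BdM) %*% uhat)
    }
    EX <- exp(1i * outer(wk, times))       # H x nt
    Xp <- Re(XK %*% EX) + as.vector(Xdc)   # ns x nt
    E <- as.matrix(Matrix::expm(A * (times[2] - times[1])))
    D <- matrix(0, ns, length(times))
    d <- x0 - Xp[, 1]
    D[, 1] <- d
    floor_amp <- 1e-13 * max(abs(d), 1)
    for (j in 2:length(times)) {
      d <- E %*% d
      D[, j] <- d
      if (max(abs(d)) < floor_amp) break   # transient fully decayed
    }
    X <- t(Xp + D)
  } else {
    rhs <- function(t, x, parms) {
      cwt <- cos(wk * t)
      swt <- sin(wk * t)
      u <- a0v + An %*% cwt + Bn %*% swt
      du <- Bnw %*% cwt - Anw %*% swt
      list(A %*% x + BuM %*% u + BdM %*% du)
    }
    jac <- function(t, x, parms) A
    atol <- settings$atol
    if (is.null(atol)) {
      atol <- c(rep(1e-4, nL), rep(1e-1, nD)) * (settings$rtol / 1e-6)
    }
    out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                        method = settings$method, jacfunc = jac,
                        jactype = "fullusr", rtol = settings$rtol,
                        atol = atol)
    if (attr(out, "istate")[1] < 0) {
      stop("integration failed: ",
           paste(attr(out, "istate"), collapse = " "))
    }
    X <- unname(out[, -1L, drop = FALSE])
  }

  COS <- cos(outer(times, wk))
  SIN <- sin(outer(times, wk))
  U <- matrix(a0v, length(times), m, byrow = TRUE) +
    COS %*% t(An) + SIN %*% t(Bn)
  pressures <- X %*% t(system$Cp) + U %*% t(system$Dp)
  flows <- X %*% t(system$Cq) + U %*% t(system$Dq)
  colnames(pressures) <- system$node_labels
  colnames(flows) <- system$branch_labels

  beat_means <- matrix(NA_real_, nb, ncol(flows),
                       dimnames = list(NULL, colnames(flows)))
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * spb + 1L):(b * spb + 1L)
    w <- c(0.5, rep(1, spb - 1L), 0.5) / spb    # trapezoid, uniform grid
    beat_means[b, ] <- w %*% flows[idx, , drop = FALSE]
  }

  cbf_br <- network$meta$cbf_branches
  if (!is.null(cbf_br)) {
    last2 <- beat_means[c(nb - 1L, nb), cbf_br, drop = FALSE]
    conv <- all(abs(last2[2, ] - last2[1, ]) <=
                  settings$periodicity_tol * pmax(abs(last2[2, ]), 1e-12))
    cbf <- stats::setNames(beat_means[nb, cbf_br], names(cbf_br))
  } else {
    keep <- abs(beat_means[nb, ]) > 1e-9 * max(abs(beat_means[nb, ]), 1e-12)
    conv <- all(abs(beat_means[nb, keep] - beat_means[nb - 1L, keep]) <=
                  settings$periodicity_tol * abs(beat_means[nb, keep]))
    cbf <- NULL
  }
  structure(list(time = times, states = X, pressures = pressures,
                 flows = flows, beat_flow_means = beat_means, cbf = cbf,
                 converged = conv, settings = settings, network = network,
                 system = system),
            class = "lpm_simulation")
}

#' @export
print.lpm_simulation <- function(x, ...) {
  nb <- x$settings$n_beats
  cat(sprintf("Simulation: %d beats (period %.3f s), %d states, %s\n",
              nb, diff(range(x$time)) / nb, ncol(x$states),
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$cbf)) {
    cat(sprintf("  mean CBF (final beat): left %.3f ml/s, right %.3f ml/s\n",
                x$cbf[["left"]], x$cbf[["right"]]))
  }
  invisible(x)
}

#' Mean flow of a branch over the final beat
#' @param sim an `lpm_simulation`
#' @param branch branch label
#' @return mean flow, cm^3/s
#' @export
final_beat_mean <- function(sim, branch) {
  stopifnot(inherits(sim, "lpm_simulation"))
  b <- match(branch, colnames(sim$beat_flow_means))
  if (is.na(b)) stop("unknown branch: ", branch)
  unname(sim$beat_flow_means[nrow(sim$beat_flow_means), b])
}
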