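# Steady-state reduced-order network solver.
#
# Pressure losses along a branch combine a Poiseuille (viscous) integral,
#   dP_visc = int 8 mu / (pi r(s)^4) * Q ds,
# with Borda-Carnot expansion losses at each maximal area-expansion event,
#   dP_exp = rho/2 * Q^2 * (1/A_min - 1/A_down)^2,
# all evaluated in SI internally. Because both terms are positive and
# strictly increasing in Q, the network has a unique flow solution; the
# inner solve is a damped Newton iteration on the outlet flows, and the
# outlet resistances are calibrated to the hyperemic inflow by an
# under-relaxed outer rescaling loop.

#' Solver settings
#'
#' @param relaxation Under-relaxation factor alpha in (0, 1] of the outer
#'   resistance-calibration loop.
#' @param flow_tolerance Relative tolerance on total-outflow matching during
#'   calibration.
#' @param inner_tolerance Relative tolerance of the inner flow solve.
#' @param max_iterations Iteration cap for the inner solve (the calibration
#'   loop is capped separately at 200 outer iterations).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(relaxation = 0.5, flow_tolerance = 1e-3,
                            inner_tolerance = 1e-8, max_iterations = 500) {
  if (relaxation <= 0 || relaxation > 1)
    stop_coroflow("domain_error", "relaxation must be in (0, 1]")
  if (flow_tolerance <= 0 || inner_tolerance <= 0 || max_iterations < 1)
    stop_coroflow("domain_error", "tolerances must be positive")
  structure(list(relaxation = relaxation, flow_tolerance = flow_tolerance,
                 inner_tolerance = inner_tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "solver_settings")
}

# Maximal area-expansion events in an area profile (any units).
# Returns data.frame(i_start, i_end) of point indices: each event is a
# maximal run of non-decreasing area containing at least one strict
# increase; A_min is the area at i_start, A_down at i_end.
find_expansion_events <- function(area) {
  n <- length(area)
  if (n < 2L) return(data.frame(i_start = integer(0), i_end = integer(0)))
  dA <- diff(area)
  tol <- max(area) * 1e-10
  down <- dA < -tol
  up <- dA > tol
  blocks <- rle(!down)
  ends <- cumsum(blocks$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- blocks$values &
    vapply(seq_along(starts),
           function(k) blocks$values[k] && any(up[starts[k]:ends[k]]),
           logical(1))
  data.frame(i_start = starts[keep], i_end = ends[keep] + 1L)
}

#' Pressure drop along a vessel segment at a given flow
#'
#' Combines the viscous Poiseuille integral over the sampled radius profile
#' (trapezoidal rule) with Borda-Carnot losses at each maximal
#' area-expansion event. Flow reversal is not supported.
#'
#' @param profile A data.frame with columns `s` (mm, strictly increasing)
#'   and `r` (mm, positive).
#' @param Q Volumetric flow (mL/min), non-negative.
#' @param params A [hemo_params()] object (viscosity and density).
#' @return Pressure drop (mmHg).
#' @export
segment_pressure_drop <- function(profile, Q, params = hemo_params()) {
  if (!is.finite(Q) || Q < 0)
    stop_coroflow("domain_error", "Q must be non-negative (flow reversal unsupported)")
  if (nrow(profile) < 2L || any(diff(profile$s) <= 0) || any(profile$r <= 0))
    stop_coroflow("domain_error", "profile must have increasing s and positive r")
  if (Q == 0) return(0)
  q <- Q * MLMIN_M3S
  s_m <- profile$s * MM_M
  r_m <- profile$r * MM_M
  g <- 8 * params$mu / (pi * r_m^4)
  dp <- trapz(s_m, g) * q
  a_m <- pi * r_m^2
  ev <- find_expansion_events(a_m)
  if (nrow(ev) > 0L) {
    dp <- dp + sum(params$rho / 2 * q^2 *
                     (1 / a_m[ev$i_start] - 1 / a_m[ev$i_end])^2)
  }
  dp / MMHG_PA
}

# ---- network assembly ----------------------------------------------------
# Precomputes, per solve geometry:
#  * outlet ordering, per-branch extended grids (samples plus child attach
#    points), viscous interval weights, interval->outlet membership,
#  * the viscous path-coupling matrix A (outlet x outlet, SI resistance),
#  * expansion events with their Borda-Carnot coefficient and membership.
build_network <- function(tree, params) {
  ch <- tree_children(tree)
  outs <- outlet_ids(tree)
  n_out <- length(outs)
  if (n_out == 0L) stop_coroflow("topology_error", "tree has no outlets")
  out_idx <- stats::setNames(seq_len(n_out), outs)

  # pre-order traversal
  order_ids <- character(0)
  stack <- tree$root_id
  while (length(stack) > 0L) {
    cur <- stack[1L]; stack <- stack[-1L]
    order_ids <- c(order_ids, cur)
    kids <- ch[[cur]]$id
    if (length(kids) > 0L) stack <- c(kids, stack)
  }

  # outlets under each branch's subtree
  sub_out <- stats::setNames(vector("list", length(order_ids)), order_ids)
  for (id in rev(order_ids)) {
    own <- if (id %in% outs) id else character(0)
    kid_out <- unlist(lapply(ch[[id]]$id, function(k) sub_out[[k]]),
                      use.names = FALSE)
    sub_out[[id]] <- c(own, kid_out)
  }

  A <- matrix(0, n_out, n_out)
  events <- list()
  binfo <- stats::setNames(vector("list", length(order_ids)), order_ids)
  for (id in order_ids) {
    b <- tree$branches[[id]]
    kids <- ch[[id]]
    s_ext <- sort(unique(c(b$samples$s, kids$attach_s)))
    r_ext <- stats::approx(b$samples$s, b$samples$r, xout = s_ext,
                           rule = 2)$y
    m <- length(s_ext)
    g <- 8 * params$mu / (pi * (r_ext * MM_M)^4)
    w <- (g[-1] + g[-m]) / 2 * diff(s_ext) * MM_M     # SI resistance per interval
    # membership: outlets whose root-to-outlet path crosses each interval
    Mb <- matrix(FALSE, m - 1L, n_out)
    if (id %in% outs) Mb[, out_idx[[id]]] <- TRUE
    if (nrow(kids) > 0L) {
      for (kk in seq_len(nrow(kids))) {
        cols <- out_idx[sub_out[[kids$id[kk]]]]
        rows <- which(s_ext[-1] <= kids$attach_s[kk] + 1e-9)
        if (length(rows) > 0L) Mb[rows, cols] <- TRUE
      }
    }
    A <- A + crossprod(Mb, Mb * w)
    a_ext <- pi * (r_ext * MM_M)^2
    ev <- find_expansion_events(a_ext)
    ev_rows <- integer(0)
    if (nrow(ev) > 0L) {
      for (k in seq_len(nrow(ev))) {
        coeff <- params$rho / 2 *
          (1 / a_ext[ev$i_start[k]] - 1 / a_ext[ev$i_end[k]])^2
        if (coeff > 0) {
          events[[length(events) + 1L]] <- list(
            coeff = coeff, member = Mb[ev$i_start[k], ],
            branch = id, i_end = ev$i_end[k])
          ev_rows <- c(ev_rows, length(events))
        }
      }
    }
    binfo[[id]] <- list(
      id = id, parent = b$parent_id, attach_s = b$attach_s,
      s_ext = s_ext, w = w, Mb = Mb, event_rows = ev_rows,
      samp_idx = match(b$samples$s, s_ext))
  }
  E <- if (length(events) > 0L)
    do.call(rbind, lapply(events, function(e) as.numeric(e$member)))
  else matrix(0, 0L, n_out)
  cvec <- vapply(events, function(e) e$coeff, numeric(1))
  list(outlets = outs, out_idx = out_idx, order_ids = order_ids,
       sub_out = sub_out, A = A, E = E, cvec = cvec, events = events,
       binfo = binfo)
}

# Path pressure drops (Pa) at outlet flows q (SI).
network_drops <- function(net, q) {
  dp <- as.vector(net$A %*% q)
  if (length(net$cvec) > 0L) {
    qe <- as.vector(net$E %*% q)
    dp <- dp + as.vector(crossprod(net$E, net$cvec * qe^2))
  }
  dp
}

# Inner solve: find outlet flows q (SI) with
#   F(q) = (Pin - p0) - dP_path(q) - R q = 0.
# dP is the sum of a linear viscous part (symmetric PSD matrix A) and
# convex quadratic expansion losses, so the Jacobian A + sum 2 c_e
# (m_e'q) m_e m_e' + diag(R) is symmetric positive definite and damped
# Newton converges quadratically from any positive start; steps are
# backtracked to keep flows positive.
solve_core <- function(net, p_in_pa, p0_pa, r_si, settings, q_init = NULL) {
  n <- length(net$outlets)
  drive <- p_in_pa - p0_pa
  if (any(drive <= 0))
    stop_coroflow("domain_error", "inlet pressure must exceed the reference p0")
  q <- q_init %||% (drive / (r_si + diag(net$A)))
  q <- pmax(q, .Machine$double.xmin)
  res_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  has_ev <- length(net$cvec) > 0L
  f_res <- function(q) drive - network_drops(net, q) - r_si * q
  f_val <- f_res(q)
  for (iter in seq_len(settings$max_iterations)) {
    rel <- max(abs(f_val) / drive)
    res_hist <- c(res_hist, rel)
    if (rel <= settings$inner_tolerance) { converged <- TRUE; break }
    jac <- net$A + diag(r_si, n)
    if (has_ev) {
      qe <- as.vector(net$E %*% q)
      jac <- jac + crossprod(net$E, (2 * net$cvec * qe) * net$E)
    }
    dq <- solve(jac, f_val)
    t_step <- 1
    repeat {
      q_new <- q + t_step * dq
      if (all(q_new > 0)) {
        f_new <- f_res(q_new)
        if (max(abs(f_new)) <= max(abs(f_val)) || t_step < 1e-6) break
      }
      t_step <- t_step / 2
      if (t_step < 1e-12)
        stop_coroflow("convergence_error",
                      "line search failed in the network solve",
                      data = list(residual_history = res_hist))
    }
    q <- q_new
    f_val <- f_new
  }
  list(q = q, converged = converged, iterations = iter,
       residual = utils::tail(res_hist, 1L), res_hist = res_hist)
}

# Reconstruct per-sample pressures (mmHg) from converged outlet flows.
assemble_solution <- function(net, tree, q, p_in_pa, settings, core) {
  entry_p <- stats::setNames(rep(NA_real_, length(net$order_ids)), net$order_ids)
  p_ext <- stats::setNames(vector("list", length(net$order_ids)), net$order_ids)
  entry_p[[tree$root_id]] <- p_in_pa
  press_rows <- vector("list", length(net$order_ids))
  for (i in seq_along(net$order_ids)) {
    id <- net$order_ids[i]
    bi <- net$binfo[[id]]
    qint <- as.vector(bi$Mb %*% q)
    m <- length(bi$s_ext)
    dvec <- numeric(m)
    dvec[-1] <- bi$w * qint
    for (er in bi$event_rows) {
      e <- net$events[[er]]
      qe <- sum(q[e$member])
      dvec[e$i_end] <- dvec[e$i_end] + e$coeff * qe^2
    }
    pe <- entry_p[[id]] - cumsum(c(0, dvec[-1]))
    p_ext[[id]] <- pe
    # seed children entry pressures
    b <- tree$branches[[id]]
    for (cid in names(net$binfo)) {
      ci <- net$binfo[[cid]]
      if (identical(ci$parent, id)) {
        k <- which.min(abs(bi$s_ext - ci$attach_s))
        entry_p[[cid]] <- pe[k]
      }
    }
    press_rows[[i]] <- data.frame(
      branch_id = id,
      s = tree$branches[[id]]$samples$s,
      pressure = pe[bi$samp_idx] / MMHG_PA)
  }
  qn <- stats::setNames(q / MLMIN_M3S, net$outlets)
  branch_flows <- vapply(net$order_ids, function(id)
    sum(qn[net$sub_out[[id]]]), numeric(1))
  structure(list(
    branch_flows = branch_flows,
    outlet_flows = qn,
    sample_pressures = do.call(rbind, press_rows),
    inlet_flow = sum(qn),
    inlet_pressure = p_in_pa / MMHG_PA,
    converged = core$converged,
    iterations = core$iterations,
    residual = core$residual,
    settings = settings
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> inlet %.1f mL/min at %.1f mmHg; %d outlet(s); %s in %d iter (residual %.2e)\n",
    x$inlet_flow, x$inlet_pressure, length(x$outlet_flows),
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual))
  invisible(x)
}

#' Solve steady flow in a coronary tree
#'
#' Finds the outlet flows such that along every root-to-outlet path the
#' inlet pressure minus the cumulative viscous and expansion losses equals
#' the outlet boundary pressure `p0 + R_i Q_i`, with mass conserved at every
#' junction. Per-sample pressures are reconstructed from the converged
#' flows.
#'
#' @param tree A `coronary_tree`.
#' @param inlet_pressure Inlet static pressure (mmHg).
#' @param bcs Outlet boundary conditions: data.frame with columns
#'   `outlet_id`, `R` (mmHg min/mL) and `p0` (mmHg), covering exactly the
#'   tree's outlets (see [build_outlet_bcs()]).
#' @param settings A [solver_settings()] object.
#' @param params A [hemo_params()] object.
#' @param init_flows Optional named vector of starting outlet flows
#'   (mL/min) to warm-start the iteration.
#' @return A `flow_solution` with per-branch flows (mL/min), per-sample
#'   pressures (mmHg), the inlet flow, and convergence diagnostics.
#' @export
solve_flow <- function(tree, inlet_pressure, bcs, settings = solver_settings(),
                       params = hemo_params(), init_flows = NULL) {
  net <- build_network(tree, params)
  solve_flow_net(net, tree, inlet_pressure, bcs, settings, init_flows)
}

solve_flow_net <- function(net, tree, inlet_pressure, bcs, settings,
                           init_flows = NULL) {
  if (!setequal(bcs$outlet_id, net$outlets))
    stop_coroflow("topology_error",
                  "boundary conditions must cover exactly the tree's outlets")
  ord <- match(net$outlets, bcs$outlet_id)
  r_si <- bcs$R[ord] * MMHG_PA / MLMIN_M3S
  p0_pa <- bcs$p0[ord] * MMHG_PA
  if (any(bcs$R <= 0))
    stop_coroflow("domain_error", "outlet resistances must be positive")
  p_in_pa <- inlet_pressure * MMHG_PA
  q0 <- if (is.null(init_flows)) NULL
        else unname(init_flows[net$outlets]) * MLMIN_M3S
  core <- solve_core(net, p_in_pa, p0_pa, r_si, settings, q0)
  if (!core$converged)
    stop_coroflow("convergence_error",
                  "flow solve did not converge in %d iterations (residual %.2e)",
                  core$iterations, core$residual,
                  data = list(residual_history = core$res_hist))
  assemble_solution(net, tree, core$q, p_in_pa, settings, core)
}

#' Export a flow solution per centerline sample
#'
#' Writes one row per sample: `branch_id`, `s` (mm), `P_mmHg` and the
#' branch through-flow `Q_mL_min` entering that branch.
#'
#' @param solution A `flow_solution`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_solution <- function(solution, path) {
  if (!inherits(solution, "flow_solution"))
    stop_coroflow("state_error", "write_solution expects a flow_solution")
  sp <- solution$sample_pressures
  out <- data.frame(branch_id = sp$branch_id, s = sp$s,
                    P_mmHg = sp$pressure,
                    Q_mL_min = unname(solution$branch_flows[sp$branch_id]))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Calibrate outlet resistances to the hyperemic inflow target
#'
#' Uniformly rescales all outlet resistances by a factor beta, updated with
#' an under-relaxation scheme (`beta <- beta * (Q_total/target)^alpha`),
#' until the total outflow matches the hyperemic inflow target within
#' `flow_tolerance`.
#'
#' @param tree A `coronary_tree`.
#' @param inlet_pressure Inlet static pressure (mmHg).
#' @param bcs Initial outlet boundary conditions (see [build_outlet_bcs()]).
#' @param target Hyperemic total inflow target (mL/min).
#' @param settings A [solver_settings()] object.
#' @param params A [hemo_params()] object.
#' @return A list with `bcs` (calibrated), `solution` (final
#'   `flow_solution`), `beta` (applied rescaling factor) and
#'   `outer_iterations`.
#' @export
calibrate_total_flow <- function(tree, inlet_pressure, bcs, target,
                                 settings = solver_settings(),
                                 params = hemo_params()) {
  if (!is.finite(target) || target <= 0)
    stop_coroflow("domain_error", "target flow must be positive")
  net <- build_network(tree, params)
  beta <- 1
  warm <- NULL
  sol <- NULL
  history <- numeric(0)
  for (outer in seq_len(200L)) {
    bcs_k <- bcs
    bcs_k$R <- bcs$R * beta
    sol <- solve_flow_net(net, tree, inlet_pressure, bcs_k, settings, warm)
    ratio <- sol$inlet_flow / target
    history <- c(history, ratio)
    if (abs(ratio - 1) <= settings$flow_tolerance) {
      return(list(bcs = bcs_k, solution = sol, beta = beta,
                  outer_iterations = outer, flow_ratio_history = history))
    }
    if (outer > 1L &&
        abs(ratio - history[outer - 1L]) < 1e-12 * max(1, abs(ratio)))
      stop_coroflow("convergence_error",
                    "total outflow saturates at %.1f%% of the hyperemic target: the tree cannot carry the target flow at this inlet pressure",
                    100 * ratio, data = list(flow_ratio_history = history))
    beta <- beta * ratio^settings$relaxation
    warm <- sol$outlet_flows
  }
  stop_coroflow("convergence_error",
                "calibration did not reach the inflow target in 200 outer iterations",
                data = list(flow_ratio_history = history))
}
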