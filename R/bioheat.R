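# Pennes bioheat solver on the labeled voxel grid.
#
#   rho c dT/dt = div(k grad T) + rho Q - rho_b c_b omega (T - T_b) + rho SAR
#
# with omega (s^-1) the volumetric perfusion rate derived from the tabulated
# W (ml min^-1 kg^-1) — see perfusion_to_volumetric(). Air voxels carry no
# degrees of freedom: tissue faces adjacent to exterior air get the Robin
# condition q = h_ext (T - T_ambient), faces adjacent to internal air
# cavities get h_int. Finite-volume 7-point stencil, harmonic-mean face
# conductivity, backward-Euler implicit time stepping by default.

#' Thermoregulated perfusion response
#'
#' The impaired (conservative) model keeps perfusion at its basal value at
#' every temperature — no vasodilation response. A pluggable `response`
#' function (of the local temperature elevation above `T_ref`, returning a
#' multiplicative factor) supports alternative response curves.
#'
#' @param W_basal basal perfusion, ml min^-1 kg^-1 (scalar or array)
#' @param T_now current temperature (degC; scalar or array)
#' @param model "impaired" (default) or "response"
#' @param response function(dT) -> factor, used when `model = "response"`
#' @param T_ref reference temperature for the response (degC)
#' @return perfusion with the same shape as the broadcast of the inputs
#' @export
thermoregulated_perfusion <- function(W_basal, T_now,
                                      model = c("impaired", "response"),
                                      response = NULL, T_ref = 37) {
  model <- match.arg(model)
  if (any(W_basal < 0)) stop("basal perfusion must be non-negative")
  if (model == "impaired") return(W_basal + 0 * T_now)
  if (is.null(response)) stop("model = 'response' needs a response function")
  W_basal * response(T_now - T_ref)
}

# Assemble the finite-volume system over solved (tissue, non-air) voxels.
# Returns list(A, M, b_const, nodes, d, h_applied, omega) where
#   A T = b is the steady system, M = rho c V diagonal (J/degC).
.assemble_bioheat <- function(vol, tissues, boundary, blood, sar = NULL) {
  d <- dim(vol$data)
  sp_m <- vol$spacing * 1e-3
  Vcell <- prod(sp_m)
  air_labels <- internal_air_labels(vol)
  solved <- vol$data > 0L & !(vol$data %in% air_labels)
  if (!any(solved)) stop("phantom contains no solvable tissue voxel")
  maps <- property_maps(vol, tissues,
                        c("density", "heat_capacity", "thermal_conductivity",
                          "perfusion", "metabolic_rate"), outside = 0)
  rho <- maps$density; cp <- maps$heat_capacity
  kc <- maps$thermal_conductivity
  Q <- maps$metabolic_rate
  W <- maps$perfusion
  if (any(kc[solved] <= 0))
    stop("thermal conductivity must be positive in tissue")
  omega <- perfusion_to_volumetric(W, pmax(rho, .Machine$double.eps))
  omega[!solved] <- 0

  node_id <- array(0L, dim = d)
  nodes <- which(solved)
  node_id[nodes] <- seq_along(nodes)
  n <- length(nodes)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  b_const <- numeric(n)
  h_applied <- FALSE

  internal_air <- array(FALSE, dim = d)
  if (length(air_labels)) internal_air <- array(vol$data %in% air_labels, d)

  for (ax in 1:3) {
    Aface <- prod(sp_m[-ax])
    dist <- sp_m[ax]
    # neighbor in +ax direction
    idx <- arrayInd(nodes, d)
    nb <- idx; nb[, ax] <- nb[, ax] + 1L
    inside <- nb[, ax] <= d[ax]
    nb_lin <- rep(NA_integer_, n)
    nb_lin[inside] <- as.integer((nb[inside, 1]) +
      d[1] * ((nb[inside, 2] - 1L) + d[2] * (nb[inside, 3] - 1L)) - 0L)
    # conduction faces: both solved
    both <- inside & solved[ifelse(is.na(nb_lin), 1L, nb_lin)] & inside
    both[is.na(nb_lin)] <- FALSE
    p <- seq_len(n)[both]
    q <- node_id[nb_lin[both]]
    kp <- kc[nodes[both]]; kq <- kc[nb_lin[both]]
    G <- Aface / dist * (2 * kp * kq / (kp + kq))
    ii <- c(ii, p, q); jj <- c(jj, q, p); xx <- c(xx, -G, -G)
    diag_acc[p] <- diag_acc[p] + G
    diag_acc[q] <- diag_acc[q] + G
    # air faces in both directions (+ax handled here; -ax via symmetry below)
    for (sgn in c(1L, -1L)) {
      nb2 <- idx; nb2[, ax] <- nb2[, ax] + sgn
      off_grid <- nb2[, ax] < 1L | nb2[, ax] > d[ax]
      nb2_lin <- rep(NA_integer_, n)
      ok <- !off_grid
      nb2_lin[ok] <- as.integer(nb2[ok, 1] +
        d[1] * ((nb2[ok, 2] - 1L) + d[2] * (nb2[ok, 3] - 1L)))
      ext_air <- off_grid | (ok & !solved[ifelse(is.na(nb2_lin), 1L, nb2_lin)] &
                               !internal_air[ifelse(is.na(nb2_lin), 1L,
                                                    nb2_lin)])
      int_air <- ok & internal_air[ifelse(is.na(nb2_lin), 1L, nb2_lin)]
      if (any(ext_air) && boundary$h_ext > 0) {
        hA <- boundary$h_ext * Aface
        diag_acc[ext_air] <- diag_acc[ext_air] + hA
        b_const[ext_air] <- b_const[ext_air] + hA * boundary$ambient
        h_applied <- TRUE
      }
      if (any(int_air) && boundary$h_int > 0) {
        hA <- boundary$h_int * Aface
        diag_acc[int_air] <- diag_acc[int_air] + hA
        b_const[int_air] <- b_const[int_air] + hA * boundary$ambient
        h_applied <- TRUE
      }
    }
  }

  P <- blood$rho_b * blood$c_b * omega[nodes] * Vcell    # W/degC
  diag_acc <- diag_acc + P
  b_const <- b_const + P * blood$T_b +
    rho[nodes] * Q[nodes] * Vcell
  if (!is.null(sar)) b_const <- b_const + rho[nodes] * sar[nodes] * Vcell

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  M <- rho[nodes] * cp[nodes] * Vcell
  list(A = A, M = M, b = b_const, nodes = nodes, d = d,
       h_applied = h_applied, omega = omega[nodes], P = P)
}

.thermal_state <- function(Tarr, t, blood, boundary, vol, trace = NULL) {
  structure(list(T = Tarr, t = t, T_b = blood$T_b,
                 ambient = boundary$ambient, trace = trace,
                 spacing = vol$spacing, origin = vol$origin),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  rng <- range(x$T, na.rm = TRUE)
  cat("<thermal_state> t = ", x$t, " s, T in [",
      signif(rng[1], 5), ", ", signif(rng[2], 5), "] degC (T_b = ",
      x$T_b, ", ambient = ", x$ambient, ")\n", sep = "")
  invisible(x)
}

#' Convective boundary specification
#' @param h_ext external-air heat transfer coefficient, W m^-2 degC^-1
#' @param h_int internal-air coefficient, W m^-2 degC^-1
#' @param ambient air temperature, degC
#' @export
boundary_spec <- function(h_ext = 6, h_int = 10, ambient = 23) {
  stopifnot(h_ext >= 0, h_int >= 0)
  list(h_ext = h_ext, h_int = h_int, ambient = ambient)
}

#' Steady-state Pennes solution
#'
#' Solves `0 = div(k grad T) + rho Q - rho_b c_b omega (T - T_b) + rho SAR`
#' with Robin boundaries at tissue-air faces. Used to find the equilibrium
#' temperature in the scanner room before an exposure.
#'
#' @param phantom a [label_volume]
#' @param tissues a `tissue_table`
#' @param boundary a [boundary_spec]
#' @param blood [blood_constants]
#' @param sar optional SAR array (W/kg) as an additional source
#' @return a `thermal_state` (temperature NA outside solved tissue)
#' @export
steady_state <- function(phantom, tissues, boundary = boundary_spec(),
                         blood = blood_constants(), sar = NULL) {
  sys <- .assemble_bioheat(phantom, tissues, boundary, blood, sar)
  if (!sys$h_applied && all(sys$P == 0))
    stop("singular steady-state system: no convective boundary and no ",
         "perfusion; the temperature level is undetermined")
  Tn <- as.numeric(Matrix::solve(sys$A, sys$b))
  Tarr <- array(NA_real_, dim = sys$d)
  Tarr[sys$nodes] <- Tn
  .thermal_state(Tarr, 0, blood, boundary, phantom)
}

#' Transient Pennes solution
#'
#' Integrates the bioheat equation from an initial state for `duration`
#' seconds (default 900 s, a 15 min scan) under a SAR source. Implicit
#' backward Euler (unconditionally stable; one sparse factorization reused
#' across steps) by default; an explicit forward-Euler scheme is available
#' for cross-checks and enforces its stability bound.
#'
#' @param initial a `thermal_state` (typically the [steady_state] output)
#' @param phantom,tissues,boundary,blood as in [steady_state]
#' @param sar SAR array (W/kg) or NULL
#' @param duration seconds to integrate
#' @param dt time step in seconds
#' @param scheme "implicit" or "explicit"
#' @return a `thermal_state` with final field and a `trace` data.frame
#'   (t, T_max, x, y, z in world mm)
#' @export
transient <- function(initial, phantom, tissues, sar = NULL,
                      boundary = boundary_spec(),
                      blood = blood_constants(),
                      duration = 900, dt = 5,
                      scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  sys <- .assemble_bioheat(phantom, tissues, boundary, blood, sar)
  Tn <- initial$T[sys$nodes]
  if (anyNA(Tn)) stop("initial state does not cover all tissue voxels")
  nstep <- ceiling(duration / dt)
  dt <- duration / nstep
  n <- length(Tn)

  if (scheme == "explicit") {
    # forward Euler: dt <= 2 / max_i ((diag_i + sum_j |offdiag_ij|) / M_i)
    rs <- Matrix::rowSums(abs(sys$A))
    bound <- 2 / max(rs / sys$M)
    if (dt > bound)
      stop("explicit scheme unstable: dt = ", dt,
           " exceeds the stability bound ", signif(bound, 6), " s")
  } else {
    lhs <- sys$A + Matrix::Diagonal(n, sys$M / dt)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(lhs), LDL = FALSE)
  }

  trace <- data.frame(t = numeric(nstep + 1), T_max = NA_real_,
                      x = NA_real_, y = NA_real_, z = NA_real_)
  rec <- function(row, tcur, Tv) {
    imax <- which.max(Tv)
    ijk <- arrayInd(sys$nodes[imax], sys$d)
    trace[row, ] <<- c(tcur, Tv[imax],
                       phantom$origin + (ijk - 1) * phantom$spacing)
  }
  rec(1, 0, Tn)
  for (s in seq_len(nstep)) {
    if (scheme == "implicit") {
      rhs <- sys$M / dt * Tn + sys$b
      Tn <- as.numeric(Matrix::solve(ch, rhs))
    } else {
      Tn <- Tn + dt / sys$M * (sys$b - as.numeric(sys$A %*% Tn))
    }
    rec(s + 1, s * dt, Tn)
  }
  Tarr <- array(NA_real_, dim = sys$d)
  Tarr[sys$nodes] <- Tn
  .thermal_state(Tarr, duration, blood, boundary, phantom, trace = trace)
}

#' Maximum temperature over tissue and time
#'
#' @param state a `thermal_state` (with or without a transient trace)
#' @return list: `value` (degC), `location_mm` (world coordinates),
#'   `time_s`
#' @export
max_temperature <- function(state) {
  stopifnot(inherits(state, "thermal_state"))
  v_final <- max(state$T, na.rm = TRUE)
  i <- which(state$T == v_final)[1]
  ijk <- arrayInd(i, dim(state$T))
  loc <- state$origin + (ijk - 1) * state$spacing
  best <- list(value = v_final, location_mm = as.numeric(loc),
               time_s = state$t)
  if (!is.null(state$trace) && nrow(state$trace)) {
    j <- which.max(state$trace$T_max)
    if (state$trace$T_max[j] >= v_final) {
      best <- list(value = state$trace$T_max[j],
                   location_mm = as.numeric(state$trace[j, c("x", "y", "z")]),
                   time_s = state$trace$t[j])
    }
  }
  best
}
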