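# Quasi-static equilibrium solver and protocol engine.
#
# All organ-scale stages are drained (Donnan-equilibrated) elastic solves:
# the long-hold preloads and the slow loading protocols are modeled as
# sequences of equilibria of the swollen, fiber-reinforced solid. Newton's
# method with backtracking line search and adaptive load substepping runs on
# a total-Lagrangian assembly (see src/assembly.cpp); the tangent is a
# finite-difference of the exact internal force, so converged states satisfy
# the exact residual.

#' Solver options
#'
#' @param tol_rel Relative residual tolerance (against the external force
#'   magnitude, or the initial residual of the substep when unloaded).
#' @param tol_abs Absolute residual floor (N).
#' @param max_iter Maximum Newton iterations per substep.
#' @param max_halvings Maximum adaptive substep halvings.
#' @param fd_h Finite-difference step for the element tangent (mm).
#' @return List of options.
#' @export
solver_options <- function(tol_rel = 1e-8, tol_abs = 1e-8, max_iter = 40,
                           max_halvings = 6, fd_h = 1e-6) {
  list(tol_rel = tol_rel, tol_abs = tol_abs, max_iter = max_iter,
       max_halvings = max_halvings, fd_h = fd_h)
}

#' Initial model state
#'
#' Zero displacement, zero swelling activation, no fiber generations, platen
#' at its reference pose.
#'
#' @param mesh A `disc_mesh` with assigned materials.
#' @param env A `disc_environment`.
#' @return Object of class `disc_state`.
#' @export
model_state <- function(mesh, env = disc_environment()) {
  if (is.null(mesh$materials))
    stop("mesh has no material parameters; call assign_region_params() first")
  structure(list(
    u = numeric(3 * nrow(mesh$nodes)),
    alpha = 0,
    generations = list(),
    env = env,
    platen = list(angle = 0, axis = "z", dz = 0, tz = 0),
    log = character(0)
  ), class = "disc_state")
}

# ---- internal plumbing -----------------------------------------------------

.matprops <- function(mesh) {
  regs <- names(mesh$materials)
  tab <- t(vapply(regs, function(r) {
    p <- mesh$materials[[r]]
    c(p$E_m, p$nu, p$beta_m, p$c0F, p$phi0_w,
      ifelse(p$has_fibers, p$E_f, 0), ifelse(p$has_fibers, p$lambda0, 2),
      ifelse(p$has_fibers, p$beta_f, 2), as.numeric(p$has_fibers))
  }, numeric(9)))
  tab[match(mesh$region, regs), , drop = FALSE]
}

.pack_generations <- function(generations, ne) {
  lapply(generations, function(g) {
    Finv <- vapply(seq_len(ne),
                   function(e) as.vector(t(solve(g$F_at_deposition[e, , ]))),
                   numeric(9))
    list(v_dep_flat = as.numeric(t(g$v_dep)),
         F_dep_inv_flat = as.numeric(Finv),
         modulus_scale = g$modulus_scale)
  })
}

.rtphi <- function(env) {
  env$gas_constant * env$temperature * env$osmotic_coefficient * 1e-6
}

# dof ids (1-based) of a node set, for one or more components (1=x,2=y,3=z)
.dofs_of <- function(nodes, comps = 1:3) {
  as.vector(t(outer(3 * (nodes - 1), comps, `+`)))
}

# dofs actually referenced by the current connectivity
.used_dofs <- function(mesh) {
  nd <- sort(unique(as.vector(mesh$elem)))
  .dofs_of(nd)
}

.assemble <- function(mesh, state, want_K, opts) {
  gens <- .pack_generations(state$generations, nrow(mesh$elem))
  asm_system(mesh$nodes, mesh$elem, state$u, .matprops(mesh), gens,
             state$alpha, .rtphi(state$env), state$env$bath_osmolarity,
             want_K, opts$fd_h)
}

# Newton solve with optional one-dimensional force-controlled border (a set
# of dofs moving in lockstep whose summed internal force must balance a
# prescribed load), optional external nodal force vector, and an optional
# penalty spring matrix (ks * S added to force and tangent; used for the
# artificial tie-stiffness ramp-down of the incision).
.newton <- function(mesh, state, fixed, uval, border = NULL, f_ext = NULL,
                    ks = 0, S = NULL, opts = solver_options()) {
  ndof <- length(state$u)
  if (is.null(f_ext)) f_ext <- numeric(ndof)
  u <- state$u
  u[fixed] <- uval[fixed]
  used <- .used_dofs(mesh)
  freemask <- rep(FALSE, ndof)
  freemask[used] <- TRUE
  freemask[fixed] <- FALSE
  bd <- NULL
  if (!is.null(border)) {
    bd <- border$dofs
    freemask[bd] <- FALSE
  }
  free <- which(freemask)
  st <- state
  st$u <- u
  springs <- ks > 0 && !is.null(S)
  resid <- function(st) {
    a <- .assemble(mesh, st, FALSE, opts)
    if (!isTRUE(a$ok)) return(NULL)
    r <- a$f - f_ext
    if (springs) r <- r + ks * as.numeric(S %*% st$u)
    list(r = r, fscale = a$fscale,
         nrm = sqrt(sum(r[free]^2) +
                      if (!is.null(bd)) (sum(r[bd]) - border$load)^2 else 0))
  }
  r0 <- resid(st)
  if (is.null(r0)) stop("inverted element at start of Newton solve")
  # tolerance reference: external force level, or the gross internal force
  # level of the stressed body when the stage carries no external load
  ref <- max(sqrt(sum(f_ext^2)), if (!is.null(bd)) abs(border$load) else 0,
             r0$fscale, r0$nrm)
  tol <- opts$tol_abs + opts$tol_rel * ref
  nrm <- r0$nrm
  nonmono <- 0
  chfac <- NULL      # cached sparse Cholesky factor (pattern reused)
  use_chol <- TRUE
  for (it in seq_len(opts$max_iter)) {
    if (nrm <= tol) {
      st$converged <- TRUE
      st$residual_norm <- nrm
      return(st)
    }
    a <- .assemble(mesh, st, TRUE, opts)
    if (!isTRUE(a$ok)) return(structure(st, failed = TRUE))
    K <- Matrix::sparseMatrix(i = a$Ki, j = a$Kj, x = a$Kx,
                              dims = c(ndof, ndof))
    r <- a$f - f_ext
    if (springs) {
      K <- K + ks * S
      r <- r + ks * as.numeric(S %*% st$u)
    }
    Kff <- K[free, free, drop = FALSE]
    rf <- -r[free]
    if (!is.null(bd)) {
      Kfb <- Matrix::rowSums(K[free, bd, drop = FALSE])
      Kbf <- Matrix::colSums(K[bd, free, drop = FALSE])
      kbb <- sum(K[bd, bd])
      rb <- -(sum(r[bd]) - border$load)
    }
    du <- NULL
    if (use_chol) {
      Ksym <- Matrix::forceSymmetric((Kff + Matrix::t(Kff)) / 2)
      fac <- tryCatch({
        if (is.null(chfac)) Matrix::Cholesky(Ksym, LDL = FALSE, super = TRUE)
        else Matrix::update(chfac, Ksym)
      }, error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fac)) {
        use_chol <- FALSE
      } else {
        chfac <- fac
        if (is.null(bd)) {
          du <- as.numeric(Matrix::solve(chfac, rf, system = "A"))
        } else {
          x1 <- as.numeric(Matrix::solve(chfac, rf, system = "A"))
          x2 <- as.numeric(Matrix::solve(chfac, Kfb, system = "A"))
          db <- (rb - sum(Kbf * x1)) / (kbb - sum(Kbf * x2))
          du <- c(x1 - x2 * db, db)
        }
      }
    }
    if (is.null(du)) {
      # unsymmetric / indefinite fallback
      if (is.null(bd)) {
        A <- Kff
        rhs <- rf
      } else {
        A <- rbind(cbind(Kff, Kfb), c(Kbf, kbb))
        rhs <- c(rf, rb)
      }
      du <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                     error = function(e) NULL)
    }
    if (is.null(du) || any(!is.finite(du)))
      return(structure(st, failed = TRUE))
    s <- 1
    accepted <- FALSE
    best <- NULL
    for (ls in 1:10) {
      st_try <- st
      st_try$u[free] <- st$u[free] + s * du[seq_along(free)]
      if (!is.null(bd))
        st_try$u[bd] <- st$u[bd] + s * du[length(free) + 1]
      rt <- resid(st_try)
      if (!is.null(rt) && is.finite(rt$nrm)) {
        if (rt$nrm < nrm) {
          st <- st_try
          nrm <- rt$nrm
          accepted <- TRUE
          break
        }
        if (is.null(best) || rt$nrm < best$nrm)
          best <- list(st = st_try, nrm = rt$nrm)
      }
      s <- s / 2
    }
    if (!accepted) {
      # non-monotone escape: near the piecewise fiber-engagement kinks the
      # residual can rise transiently; accept the best damped step a few
      # times before declaring failure
      if (!is.null(best) && nonmono < 3 && best$nrm < 10 * nrm) {
        st <- best$st
        nrm <- best$nrm
        nonmono <- nonmono + 1
      } else {
        return(structure(st, failed = TRUE, residual_norm = nrm))
      }
    }
  }
  if (nrm <= tol) {
    st$converged <- TRUE
    st$residual_norm <- nrm
    return(st)
  }
  structure(st, failed = TRUE, residual_norm = nrm)
}

# Run one stage whose boundary conditions are a function of a pseudo-time
# t in (t0, 1]; adaptive halving on Newton failure.
.run_stage <- function(mesh, state, bc_at, nsub = 1, opts = solver_options(),
                       label = "stage") {
  t <- 0
  dt0 <- 1 / nsub
  dt <- dt0
  fails <- 0
  while (t < 1 - 1e-12) {
    tn <- min(1, t + dt)
    bc <- bc_at(tn)
    st <- .newton(mesh, .apply_bc_state(state, bc), bc$fixed, bc$uval,
                  border = bc$border, f_ext = bc$f_ext,
                  ks = bc$ks %||% 0, S = bc$S, opts = opts)
    if (isTRUE(attr(st, "failed"))) {
      fails <- fails + 1
      if (fails > opts$max_halvings)
        stop("convergence error in stage '", label, "' at t = ", signif(tn, 4),
             "; last residual ", signif(attr(st, "residual_norm") %||% NA, 4))
      dt <- dt / 2
      next
    }
    state <- st
    t <- tn
    fails <- 0
    dt <- min(dt0, dt * 2)
  }
  state$log <- c(state$log, label)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.apply_bc_state <- function(state, bc) {
  if (!is.null(bc$alpha)) state$alpha <- bc$alpha
  state
}

# gripped-end boundary conditions: bottom fully fixed, top nodes rigidly
# posed (rotation angle about `axis` through the platen center + axial
# translation dz), evaluated from reference coordinates.
.grip_bc <- function(mesh, angle_deg, dz, axis = "z", alpha = NULL,
                     top_z_border = NULL) {
  ndof <- 3 * nrow(mesh$nodes)
  fixed <- rep(FALSE, ndof)
  uval <- numeric(ndof)
  bot <- mesh$sets$bottom
  top <- mesh$sets$top
  fixed[.dofs_of(bot)] <- TRUE
  Xt <- mesh$nodes[top, , drop = FALSE]
  ut <- .rigid_pose(Xt, angle_deg, dz, axis,
                    c(0, 0, mesh$spec$height))
  if (is.null(top_z_border)) {
    fixed[.dofs_of(top)] <- TRUE
    uval[.dofs_of(top, 1)] <- ut[, 1]
    uval[.dofs_of(top, 2)] <- ut[, 2]
    uval[.dofs_of(top, 3)] <- ut[, 3]
    border <- NULL
  } else {
    fixed[.dofs_of(top, 1:2)] <- TRUE
    uval[.dofs_of(top, 1)] <- ut[, 1]
    uval[.dofs_of(top, 2)] <- ut[, 2]
    border <- list(dofs = .dofs_of(top, 3), load = top_z_border)
  }
  list(fixed = fixed, uval = uval, alpha = alpha, border = border)
}

.rigid_pose <- function(X, angle_deg, dz, axis, center) {
  th <- angle_deg * pi / 180
  Rm <- switch(axis,
    z = matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE),
    x = matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
               byrow = TRUE),
    y = matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
               byrow = TRUE))
  Xc <- sweep(X, 2, center)
  u <- Xc %*% t(Rm) - Xc
  u[, 3] <- u[, 3] + dz
  u
}

# statically determinate 3-2-1 support for a free (released) body: node A
# pinned, node B vertically above A held in x,y, node C a quarter-turn away
# held in y. Removes the six rigid modes without stressing the body.
.support_321 <- function(mesh) {
  nd <- mesh$nodes
  R <- mesh$spec$outer_radius
  H <- mesh$spec$height
  pick <- function(target) {
    d2 <- rowSums(sweep(nd, 2, target)^2)
    which.min(d2)
  }
  A <- pick(c(-R, 0, 0))
  B <- pick(c(nd[A, 1], nd[A, 2], H))
  C <- pick(c(0, -nd[A, 1] * 0 - R, 0))
  fixed <- rep(FALSE, 3 * nrow(nd))
  fixed[.dofs_of(A)] <- TRUE
  fixed[.dofs_of(B, 1:2)] <- TRUE
  fixed[.dofs_of(C, 1)] <- TRUE
  fixed
}

# ---- exported operations ---------------------------------------------------

#' Low-level equilibrium solve
#'
#' Solves for quasi-static equilibrium under explicit boundary conditions.
#' Mostly useful for single-element and patch tests; the protocol stages
#' wrap it with ramping and adaptive substepping.
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A `disc_state` (its `u` is the initial guess; its `alpha`
#'   the swelling activation).
#' @param fixed Logical vector over all dofs (3 per node, x/y/z interleaved).
#' @param uval Prescribed displacement values at the fixed dofs.
#' @param border Optional force-control record `list(dofs=, load=)`: the
#'   listed dofs translate in lockstep and their summed internal force must
#'   equal `load`.
#' @param f_ext Optional external nodal force vector.
#' @param opts [solver_options()].
#' @return Converged `disc_state`; errors on non-convergence.
#' @export
equilibrium_solve <- function(mesh, state, fixed, uval = numeric(length(fixed)),
                              border = NULL, f_ext = NULL, ks = 0, S = NULL,
                              opts = solver_options()) {
  st <- .newton(mesh, state, fixed, uval, border = border, f_ext = f_ext,
                ks = ks, S = S, opts = opts)
  if (isTRUE(attr(st, "failed")))
    stop("convergence error: residual ",
         signif(attr(st, "residual_norm") %||% NA, 4))
  st
}

#' Swell the disc to Donnan equilibrium
#'
#' Ramps the swelling activation (scaling every region's fixed charge
#' density) from the current level to 1 in equilibrium substeps, with both
#' end surfaces gripped. `height_change` simultaneously ramps the superior
#' surface axially (the multigeneration protocol swells to an increased
#' height; swelling-only holds the reference height).
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A `disc_state`.
#' @param height_change Axial displacement of the superior surface (mm).
#' @param nsub Number of swelling substeps.
#' @param opts [solver_options()].
#' @return Swollen `disc_state` (alpha = 1).
#' @export
swell_to_equilibrium <- function(mesh, state, height_change = 0, nsub = 10,
                                 opts = solver_options()) {
  a0 <- state$alpha
  dz0 <- state$platen$dz
  st <- .run_stage(mesh, state, function(t) {
    .grip_bc(mesh, state$platen$angle, dz0 + t * (height_change),
             alpha = a0 + t * (1 - a0))
  }, nsub = nsub, opts = opts, label = "swell")
  st$platen$dz <- dz0 + height_change
  st
}

#' Multigenerational fiber deposition by twist
#'
#' Implements the deposition protocol on a swollen, fiber-free state: twist
#' the superior surface to -Omega and record the +theta fiber generation
#' (deformation-gradient snapshot and pushed-forward ply directions, zero
#' modulus); return to neutral; twist to +Omega and record the -theta
#' generation; return to neutral; then ramp the fiber modulus from zero to
#' full value in equilibrium substeps with all boundaries held fixed.
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A swollen `disc_state` without active fibers.
#' @param Omega Twist angle (degrees).
#' @param nsub_twist Substeps per twist ramp.
#' @param nsub_ramp Substeps for the fiber-modulus ramp.
#' @param opts [solver_options()].
#' @return `disc_state` with two pre-strained generations at full modulus.
#' @export
run_multigen_deposition <- function(mesh, state, Omega, nsub_twist = 3,
                                    nsub_ramp = 10, opts = solver_options()) {
  if (length(state$generations) > 0)
    stop("fibers already active; deposition requires a fiber-free state")
  dz <- state$platen$dz
  ne <- nrow(mesh$elem)
  tz0 <- time_zero_generations(mesh)

  twist_to <- function(st, from, to) {
    .run_stage(mesh, st, function(t) {
      .grip_bc(mesh, from + t * (to - from), dz)
    }, nsub = max(1, nsub_twist), opts = opts,
    label = sprintf("twist_%g", to))
  }
  snapshot <- function(st, sign, id, stage) {
    Fc <- elem_centroid_F(mesh$nodes, mesh$elem, st$u)
    Farr <- array(0, c(ne, 3, 3))
    vdep <- matrix(0, ne, 3)
    v0 <- if (sign > 0) tz0[[1]]$v_dep else tz0[[2]]$v_dep
    for (e in seq_len(ne)) {
      Fe <- matrix(Fc[e, ], 3, 3, byrow = TRUE)
      Farr[e, , ] <- Fe
      w <- Fe %*% v0[e, ]
      vdep[e, ] <- w / sqrt(sum(w^2))
    }
    fiber_generation(id, stage, Farr, sign, vdep, modulus_scale = 0)
  }

  st <- twist_to(state, 0, -Omega)
  gen1 <- snapshot(st, +1, 1L, "twist_minus_omega")
  st$generations <- list(gen1)
  st <- twist_to(st, -Omega, 0)
  st <- twist_to(st, 0, Omega)
  gen2 <- snapshot(st, -1, 2L, "twist_plus_omega")
  st$generations <- list(gen1, gen2)
  st <- twist_to(st, Omega, 0)
  st$platen$angle <- 0

  # ramp fiber modulus 0 -> 1 under fixed boundary conditions
  st <- .run_stage(mesh, st, function(t) {
    bc <- .grip_bc(mesh, 0, dz)
    bc
  }, nsub = 1, opts = opts, label = "pre_ramp_equilibrium")
  for (t in seq_len(nsub_ramp) / nsub_ramp) {
    st$generations <- lapply(st$generations, function(g) {
      g$modulus_scale <- t
      g
    })
    bc <- .grip_bc(mesh, 0, dz)
    st <- equilibrium_solve(mesh, st, bc$fixed, bc$uval, opts = opts)
  }
  st$log <- c(st$log, "fiber_modulus_ramp")
  st
}

#' Activate the classical (time-zero) fiber model
#'
#' Swelling-only mode: both angle-ply fiber sets present at full modulus
#' from model initiation, referenced to the unswollen configuration.
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A `disc_state` (typically fresh).
#' @return The state with two identity-reference generations.
#' @export
activate_time_zero_fibers <- function(mesh, state) {
  state$generations <- time_zero_generations(mesh)
  state
}

#' Apply an axial preload in force control
#'
#' Switches the superior surface to axial force control (in-plane pose held
#' at its current value) and ramps the applied compressive load to `load`,
#' equilibrating at each substep. The long experimental hold is represented
#' by the drained equilibrium solution.
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A converged `disc_state`.
#' @param load Compressive preload magnitude (N).
#' @param nsub Load substeps.
#' @param opts [solver_options()].
#' @return Preloaded `disc_state` (with `platen$tz` updated to the found
#'   axial translation).
#' @export
apply_preload <- function(mesh, state, load, nsub = 5,
                          opts = solver_options()) {
  if (load == 0) return(state)
  a <- .assemble(mesh, state, FALSE, opts)
  top_z <- .dofs_of(mesh$sets$top, 3)
  L0 <- sum(a$f[top_z])
  st <- .run_stage(mesh, state, function(t) {
    .grip_bc(mesh, state$platen$angle, state$platen$dz,
             top_z_border = L0 + t * (-load - L0))
  }, nsub = nsub, opts = opts, label = sprintf("preload_%gN", load))
  st$platen$tz <- st$u[top_z[1]]
  st$platen$dz <- st$u[top_z[1]]
  st
}

#' Release the end grips of a free specimen
#'
#' Replaces the gripped end conditions by a statically determinate 3-2-1
#' support and ramps the former grip reactions to zero (continuation on the
#' released tractions), re-equilibrating at each substep. Used before the
#' bovine incision: the experimental discs were removed from the vertebrae.
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A converged gripped `disc_state`.
#' @param nsub Traction ramp substeps.
#' @param opts [solver_options()].
#' @return Free-standing `disc_state`.
#' @export
release_platens <- function(mesh, state, nsub = 5, opts = solver_options()) {
  a <- .assemble(mesh, state, FALSE, opts)
  r0 <- a$f
  fixed <- .support_321(mesh)
  uval <- numeric(length(fixed))
  uval[fixed] <- state$u[fixed]
  st <- .run_stage(mesh, state, function(t) {
    list(fixed = fixed, uval = uval, f_ext = (1 - t) * r0)
  }, nsub = nsub, opts = opts, label = "release_platens")
  st
}

#' Simulate the radial incision
#'
#' Releases the tied cut-plane faces of a residual-strain-bearing state and
#' re-equilibrates, ramping the released cut tractions to zero. The state
#' should already be free-standing (see [release_platens()]).
#'
#' @param mesh A `disc_mesh` (cut still tied).
#' @param state A converged `disc_state`.
#' @param nsub Traction ramp substeps.
#' @param opts [solver_options()].
#' @return List with the released `mesh` and the opened `state`.
#' @export
simulate_incision <- function(mesh, state, nsub = 3, opts = solver_options(),
                              spring_schedule = 10^seq(0, -5, by = -0.5)) {
  mesh2 <- release_cut(mesh)
  # seed duplicate dofs from their masters
  md <- mesh2$sets$cut_master
  dp <- mesh2$sets$cut_dup
  for (k in seq_along(md)) {
    state$u[.dofs_of(dp[k])] <- state$u[.dofs_of(md[k])]
  }
  # artificial tie springs across the cut pairs: the freshly cut body has a
  # nearly zero-stiffness opening mode, so the tie stiffness is ramped down
  # geometrically instead of continuing directly on the released tractions
  ndof <- length(state$u)
  ii <- .dofs_of(md)
  jj <- .dofs_of(dp)
  S <- Matrix::sparseMatrix(i = c(ii, jj, ii, jj), j = c(ii, jj, jj, ii),
                            x = rep(c(1, 1, -1, -1), each = length(ii)),
                            dims = c(ndof, ndof))
  a <- .assemble(mesh2, state, FALSE, opts)
  r0 <- a$f
  fixed <- .support_321(mesh2)
  uval <- numeric(length(fixed))
  uval[fixed] <- state$u[fixed]
  ks0 <- spring_schedule[1]
  # step 1: remove the released cut tractions under stiff ties
  st <- .run_stage(mesh2, state, function(t) {
    list(fixed = fixed, uval = uval, f_ext = (1 - t) * r0, ks = ks0, S = S)
  }, nsub = nsub, opts = opts, label = "incision_traction_release")
  # step 2: geometric ramp of the tie stiffness, then exact release (ks = 0)
  ks_end <- spring_schedule[length(spring_schedule)]
  st <- .run_stage(mesh2, st, function(t) {
    list(fixed = fixed, uval = uval, ks = ks0 * (ks_end / ks0)^t, S = S)
  }, nsub = length(spring_schedule) - 1, opts = opts,
  label = "incision_spring_rampdown")
  st <- .run_stage(mesh2, st, function(t) {
    list(fixed = fixed, uval = uval)
  }, nsub = 1, opts = opts, label = "incision_release")
  st$log <- c(st$log, "incision")
  list(mesh = mesh2, state = st)
}

#' Run a loading test case
#'
#' Executes one of the loading protocols on a prepared (swollen, optionally
#' multigeneration, optionally preloaded) state and returns the
#' controlled-variable / conjugate-response curve. All cases run as drained
#' quasi-static equilibrium sequences (recorded in the output metadata):
#' rate labels map the control schedule onto pseudo-time.
#'
#' @param mesh A `disc_mesh` with materials.
#' @param state A prepared `disc_state`.
#' @param case One of "slow_ramp", "creep", "stress_relaxation",
#'   "axial_compression", "torsion", "bending", "flexion".
#' @param n_points Number of curve samples.
#' @param opts [solver_options()].
#' @param max_load,max_rotation Optional overrides of the protocol targets.
#' @return List with `curve` (data.frame time, control, response), `state`
#'   (final), and `meta`.
#' @export
run_test_case <- function(mesh, state,
                          case = c("slow_ramp", "creep", "stress_relaxation",
                                   "axial_compression", "torsion", "bending",
                                   "flexion"),
                          n_points = 8, opts = solver_options(),
                          max_load = NULL, max_rotation = NULL) {
  case <- match.arg(case)
  H <- mesh$spec$height
  top <- mesh$sets$top
  top_z <- .dofs_of(top, 3)
  axial_case <- function(target, rate) {
    a <- .assemble(mesh, state, FALSE, opts)
    L0 <- sum(a$f[top_z])
    loads <- seq(0, target, length.out = n_points + 1)[-1]
    tim <- loads / rate
    disp <- numeric(length(loads))
    st <- state
    for (i in seq_along(loads)) {
      st <- .run_stage(mesh, st, function(t) {
        prev <- if (i == 1) L0 else -loads[i - 1]
        .grip_bc(mesh, st$platen$angle, st$platen$dz,
                 top_z_border = prev + t * (-loads[i] - prev))
      }, nsub = 1, opts = opts, label = sprintf("%s_%g", case, loads[i]))
      st$platen$dz <- st$u[top_z[1]]
      disp[i] <- st$u[top_z[1]]
    }
    list(curve = data.frame(time = tim, control = loads, response = disp),
         state = st, meta = list(case = case, mode = "drained_quasistatic"))
  }
  rotation_case <- function(axis, target) {
    angs <- seq(0, target, length.out = n_points + 1)[-1]
    tim <- angs / 0.08
    mom <- numeric(length(angs))
    st <- state
    dz <- st$platen$dz
    for (i in seq_along(angs)) {
      prev <- if (i == 1) 0 else angs[i - 1]
      st <- .run_stage(mesh, st, function(t) {
        .grip_bc(mesh, prev + t * (angs[i] - prev), dz, axis = axis)
      }, nsub = 1, opts = opts, label = sprintf("%s_%g", case, angs[i]))
      a <- .assemble(mesh, st, FALSE, opts)
      mom[i] <- .platen_moment(mesh, st, a$f, axis)
    }
    st$platen$angle <- target
    st$platen$axis <- axis
    list(curve = data.frame(time = tim, control = angs, response = mom),
         state = st, meta = list(case = case, mode = "drained_quasistatic"))
  }
  switch(case,
    slow_ramp = axial_case(max_load %||% 2000, 1),
    creep = {
      out <- axial_case(max_load %||% 1000, 200)
      hold <- out$curve[nrow(out$curve), ]
      out$curve <- rbind(out$curve,
                         data.frame(time = hold$time + c(60, 600),
                                    control = hold$control,
                                    response = hold$response))
      out$meta$note <- "hold phase is the drained equilibrium (flat)"
      out
    },
    stress_relaxation = {
      # 5% compression of current height in displacement control, then hold
      dz_t <- -0.05 * H
      tims <- seq_len(n_points) / n_points * 5
      frc <- numeric(n_points)
      st <- state
      dz0 <- st$platen$dz
      for (i in seq_len(n_points)) {
        st <- .run_stage(mesh, st, function(t) {
          prev <- dz0 + (i - 1) / n_points * dz_t
          .grip_bc(mesh, st$platen$angle, prev + t * (dz_t / n_points))
        }, nsub = 1, opts = opts, label = sprintf("relax_%d", i))
        a <- .assemble(mesh, st, FALSE, opts)
        frc[i] <- sum(a$f[top_z])
      }
      st$platen$dz <- dz0 + dz_t
      list(curve = data.frame(time = tims,
                              control = seq_len(n_points) / n_points * dz_t,
                              response = frc),
           state = st,
           meta = list(case = case, mode = "drained_quasistatic",
                       note = "hold phase is the drained equilibrium (flat)"))
    },
    axial_compression = axial_case(max_load %||% 900, 18),
    torsion = rotation_case("z", max_rotation %||% 3),
    bending = rotation_case("y", max_rotation %||% 3),
    flexion = rotation_case("x", max_rotation %||% 3)
  )
}

# reaction moment (N mm) of the superior surface about the platen axis,
# from the internal force vector and current positions
.platen_moment <- function(mesh, state, f, axis = "z") {
  top <- mesh$sets$top
  x <- mesh$nodes[top, , drop = FALSE] +
    matrix(state$u[.dofs_of(top)], ncol = 3, byrow = TRUE)
  ctr <- c(0, 0, mesh$spec$height)
  r <- sweep(x, 2, ctr)
  fm <- matrix(f[.dofs_of(top)], ncol = 3, byrow = TRUE)
  m <- c(sum(r[, 2] * fm[, 3] - r[, 3] * fm[, 2]),
         sum(r[, 3] * fm[, 1] - r[, 1] * fm[, 3]),
         sum(r[, 1] * fm[, 2] - r[, 2] * fm[, 1]))
  m[match(axis, c("x", "y", "z"))]
}

#' Per-element deformation gradients of a state
#'
#' Deformation gradients (relative to time zero) at every element centroid.
#'
#' @param mesh A `disc_mesh`.
#' @param state A `disc_state`.
#' @return ne x 3 x 3 array.
#' @export
state_deformation_gradients <- function(mesh, state) {
  Fc <- elem_centroid_F(mesh$nodes, mesh$elem, state$u)
  ne <- nrow(mesh$elem)
  arr <- array(0, c(ne, 3, 3))
  for (e in seq_len(ne)) arr[e, , ] <- matrix(Fc[e, ], 3, 3, byrow = TRUE)
  arr
}

#' Per-element Cauchy stress of a state
#'
#' Total Cauchy stress (matrix + fibers + Donnan) at element centroids,
#' through the same constitutive path as the solver.
#'
#' @param mesh A `disc_mesh`.
#' @param state A `disc_state`.
#' @return ne x 3 x 3 array (MPa).
#' @export
state_cauchy_stress <- function(mesh, state) {
  gens <- .pack_generations(state$generations, nrow(mesh$elem))
  S <- elem_centroid_stress(mesh$nodes, mesh$elem, state$u, .matprops(mesh),
                            gens, state$alpha, .rtphi(state$env),
                            state$env$bath_osmolarity)
  ne <- nrow(mesh$elem)
  arr <- array(0, c(ne, 3, 3))
  for (e in seq_len(ne)) arr[e, , ] <- matrix(S[e, ], 3, 3, byrow = TRUE)
  arr
}
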