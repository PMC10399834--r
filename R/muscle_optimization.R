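#' Static muscle-force optimisation problem
#'
#' Moment equilibrium \code{R x = M} with bounds
#' \code{x_passive <= x <= x_max}, under the objective
#' \code{f(x) = sum_i (x_i / PCSA_i)^3} (sum of cubed muscle stresses).
#'
#' @param lever_arms DoF x muscles lever-arm matrix, m.
#' @param targets required joint moments, N.m (length = DoF).
#' @param pcsa physiological cross-sectional areas, cm^2 (> 0).
#' @param x_passive,x_max lower (passive) and upper (maximum) force
#'   bounds, N.
#' @return object of class \code{optimization_problem}.
#' @export
optimization_problem <- function(lever_arms, targets, pcsa, x_passive,
                                 x_max) {
  R <- as.matrix(lever_arms)
  stopifnot(length(targets) == nrow(R), length(pcsa) == ncol(R),
            length(x_passive) == ncol(R), length(x_max) == ncol(R),
            all(pcsa > 0), all(x_passive <= x_max))
  structure(list(lever_arms = R, targets = as.numeric(targets),
                 pcsa = as.numeric(pcsa),
                 x_passive = as.numeric(x_passive),
                 x_max = as.numeric(x_max)),
            class = "optimization_problem")
}

#' @rdname optimization_problem
#' @param msk a \code{toy_musculoskeleton}
#'   (see \code{\link{gen_toy_musculoskeleton}}).
#' @param targets required joint moments, N.m.
#' @export
as_optimization_problem <- function(msk, targets = msk$targets) {
  optimization_problem(msk$lever_arms, targets, msk$pcsa, msk$x_passive,
                       msk$x_max)
}

.obj <- function(x, P) sum((x / P)^3)
.grad <- function(x, P) 3 * x^2 / P^3

# minimum-infeasibility pre-pass: closest Rx to M under the bounds
.feasibility <- function(prob, tol) {
  R <- prob$lever_arms
  M <- prob$targets
  x0 <- (prob$x_passive + prob$x_max) / 2
  fit <- stats::optim(x0, fn = function(x) 0.5 * sum((R %*% x - M)^2),
                      gr = function(x) as.vector(crossprod(R, R %*% x - M)),
                      method = "L-BFGS-B", lower = prob$x_passive,
                      upper = prob$x_max,
                      control = list(maxit = 500, factr = 1e4))
  res <- as.vector(R %*% fit$par - M)
  list(feasible = max(abs(res)) <= tol, residual = res, x = fit$par)
}

.kkt_residual <- function(x, lambda, prob) {
  g <- .grad(x, prob$pcsa) + as.vector(crossprod(prob$lever_arms, lambda))
  scale <- max(1, max(abs(.grad(x, prob$pcsa))))
  tol_act <- 1e-7 * pmax(1, prob$x_max)
  at_lo <- x <= prob$x_passive + tol_act
  at_hi <- x >= prob$x_max - tol_act
  r <- abs(g)
  r[at_lo] <- pmax(0, -g[at_lo]) # multiplier mu_l = g >= 0 required
  r[at_hi] <- pmax(0, g[at_hi])
  max(r) / scale
}

# stationarity-inverted forces for given multipliers: 3 x^2/P^3 = -R'lambda
.x_of_lambda <- function(lambda, prob) {
  c0 <- -as.vector(crossprod(prob$lever_arms, lambda))
  x <- ifelse(c0 > 0, prob$pcsa^1.5 * sqrt(pmax(c0, 0) / 3), 0)
  pmin(pmax(x, prob$x_passive), prob$x_max)
}

.solve_nlp <- function(prob, tol_moment) {
  R <- prob$lever_arms
  M <- prob$targets
  P <- prob$pcsa
  x <- (prob$x_passive + prob$x_max) / 2
  rho <- 1
  iters <- 0L
  target_res <- min(tol_moment, 1e-7 * max(1, max(abs(M))))
  repeat {
    fit <- stats::optim(x, fn = function(x)
      .obj(x, P) + 0.5 * rho * sum((R %*% x - M)^2),
      gr = function(x)
        .grad(x, P) + rho * as.vector(crossprod(R, R %*% x - M)),
      method = "L-BFGS-B", lower = prob$x_passive, upper = prob$x_max,
      control = list(maxit = 2000, factr = 1e1))
    x <- fit$par
    iters <- iters + fit$counts[1]
    res <- max(abs(R %*% x - M))
    if (res <= target_res || rho >= 1e12) break
    rho <- rho * 10
  }
  lambda <- rho * as.vector(R %*% x - M)
  # dual polish: damped Newton on g(lambda) = R x(lambda) - M, where
  # x(lambda) inverts the stationarity condition per muscle
  g <- function(l) as.vector(R %*% .x_of_lambda(l, prob) - M)
  jac <- function(l) {
    c0 <- -as.vector(crossprod(R, l))
    x0 <- .x_of_lambda(l, prob)
    interior <- c0 > 0 & x0 > prob$x_passive + 1e-12 & x0 < prob$x_max - 1e-12
    d <- ifelse(interior, prob$pcsa^1.5 / (2 * sqrt(3 * pmax(c0, 1e-300))), 0)
    -R %*% (d * t(R))
  }
  l <- lambda
  gl <- g(l)
  for (it in 1:100) {
    if (max(abs(gl)) < 1e-10 * max(1, max(abs(M)))) break
    Jl <- jac(l)
    step <- tryCatch(solve(Jl + 1e-12 * diag(nrow(Jl)), -gl),
                     error = function(e) NULL)
    if (is.null(step)) break
    t_ls <- 1
    repeat {
      ln <- l + t_ls * step
      gn <- g(ln)
      if (sum(gn^2) < sum(gl^2) || t_ls < 1e-6) break
      t_ls <- t_ls / 2
    }
    if (sum(gn^2) >= sum(gl^2)) break
    l <- ln
    gl <- gn
  }
  xp <- .x_of_lambda(l, prob)
  resp <- max(abs(R %*% xp - M))
  if (resp <= max(res, target_res)) {
    x <- xp
    lambda <- l
    res <- resp
  }
  list(x = x, lambda = lambda, residual = res, iterations = as.integer(iters))
}

.project_equality <- function(x, R, M) {
  # least-squares projection onto the affine set Rx = M
  corr <- tryCatch(solve(tcrossprod(R), as.vector(R %*% x - M)),
                   error = function(e) NULL)
  if (is.null(corr)) return(x)
  x - as.vector(crossprod(R, corr))
}

.solve_genetic <- function(prob, tol_moment, seed, pop = 60L, gens = 250L) {
  set.seed(seed)
  R <- prob$lever_arms
  M <- prob$targets
  P <- prob$pcsa
  lo <- prob$x_passive
  hi <- prob$x_max
  n <- length(P)
  repair <- function(x) {
    for (k in 1:3) x <- pmin(pmax(.project_equality(x, R, M), lo), hi)
    x
  }
  # penalise any equality violation (not just beyond the band) so the GA
  # targets the same optimum as the NLP; the band only judges convergence
  wpen <- 1e4 * max(1, max(abs(M)))
  fitness <- function(x) .obj(x, P) + wpen * sum(abs(R %*% x - M))
  popx <- t(vapply(seq_len(pop), function(i)
    repair(lo + stats::runif(n) * (hi - lo)), numeric(n)))
  fits <- apply(popx, 1, fitness)
  evals <- pop
  # active-set projected-gradient descent: search directions live in the
  # null space of the equality constraints restricted to the non-active
  # coordinates, and steps are clipped at the bounds, so iterates stay
  # feasible; used as the memetic local-search step on elites (the convex
  # objective makes it converge to the constrained optimum)
  polish <- function(x, steps = 400L) {
    x <- repair(x)
    fx <- fitness(x)
    for (s in seq_len(steps)) {
      g <- .grad(x, P)
      act <- (x <= lo + 1e-10 & g > 0) | (x >= hi - 1e-10 & g < 0)
      free <- which(!act)
      if (length(free) <= nrow(R)) break
      A <- R[, free, drop = FALSE]
      gf <- g[free]
      gp <- tryCatch(
        gf - as.vector(crossprod(A, solve(tcrossprod(A), A %*% gf))),
        error = function(e) NULL)
      if (is.null(gp)) break
      ng <- sqrt(sum(gp^2))
      if (ng < 1e-12 * max(1, max(abs(g)))) break
      # longest feasible step along -gp
      d <- -gp
      tmax <- suppressWarnings(min(
        ifelse(d > 0, (hi[free] - x[free]) / d,
               ifelse(d < 0, (lo[free] - x[free]) / d, Inf))))
      t_ls <- min(1 / ng, tmax)
      improved <- FALSE
      for (bt in 1:40) {
        xn <- x
        xn[free] <- pmin(pmax(x[free] + t_ls * d, lo[free]), hi[free])
        fn <- fitness(xn)
        if (fn < fx - 1e-15 * abs(fx)) {
          x <- xn
          fx <- fn
          improved <- TRUE
          break
        }
        t_ls <- t_ls / 2
      }
      if (!improved) break
    }
    x
  }
  for (g in seq_len(gens)) {
    ord <- order(fits)
    elite <- popx[ord[1:2], , drop = FALSE]
    newpop <- matrix(0, pop, n)
    newpop[1:2, ] <- elite
    for (i in 3:pop) {
      # tournament selection, blend crossover, Gaussian mutation
      pick <- function() {
        c2 <- sample(pop, 2)
        popx[c2[which.min(fits[c2])], ]
      }
      a <- pick(); b <- pick()
      w <- stats::runif(n, -0.25, 1.25)
      child <- w * a + (1 - w) * b
      mut <- stats::rnorm(n, 0, 0.02 * (hi - lo)) *
        (stats::runif(n) < 0.2)
      newpop[i, ] <- repair(child + mut)
    }
    popx <- newpop
    fits <- apply(popx, 1, fitness)
    evals <- evals + pop
    if (g %% 50 == 0) {
      ibest <- which.min(fits)
      popx[ibest, ] <- polish(popx[ibest, ])
      fits[ibest] <- fitness(popx[ibest, ])
    }
  }
  ibest <- which.min(fits)
  x <- polish(popx[ibest, ], steps = 50L)
  list(x = x, lambda = rep(NA_real_, nrow(R)),
       residual = max(abs(R %*% x - M)), iterations = as.integer(evals))
}

#' Solve the static muscle-force optimisation
#'
#' Minimises the sum of cubed muscle stresses subject to moment
#' equilibrium (relaxed to \code{|Rx - M|_inf <= tol_moment}) and the
#' physiological bounds. The primary \code{"nlp"} method is a penalty-ramped
#' quasi-Newton solve with an exact dual (stationarity-inversion) polish;
#' \code{"genetic"} is a real-coded genetic algorithm with feasibility
#' repair and projected-gradient elite polish, provided as a cross-check.
#'
#' @param prob an \code{\link{optimization_problem}}.
#' @param tol_moment equality tolerance band, N.m (default 1).
#' @param method \code{"nlp"} or \code{"genetic"}.
#' @param seed RNG seed (genetic method).
#' @return object of class \code{muscle_solution}: \code{forces} (N),
#'   \code{objective}, \code{equality_residual} (N.m),
#'   \code{iterations}, \code{converged}, \code{kkt_residual} (scaled
#'   stationarity/complementarity residual; NA for the genetic method)
#'   and the multipliers \code{lambda}.
#' @export
solve_muscle_forces <- function(prob, tol_moment = 1,
                                method = c("nlp", "genetic"), seed = 1L) {
  method <- match.arg(method)
  feas <- .feasibility(prob, tol_moment)
  if (!feas$feasible) {
    worst <- which.max(abs(feas$residual))
    stop(sprintf(paste0("infeasible problem: moment component %d ",
                        "unreachable by %.3g N.m under the bounds"),
                 worst, max(abs(feas$residual))))
  }
  sol <- if (method == "nlp") .solve_nlp(prob, tol_moment) else
    .solve_genetic(prob, tol_moment, seed)
  kkt <- if (method == "nlp")
    .kkt_residual(sol$x, sol$lambda, prob) else NA_real_
  structure(list(forces = sol$x, objective = .obj(sol$x, prob$pcsa),
                 equality_residual = sol$residual,
                 iterations = sol$iterations,
                 converged = sol$residual <= tol_moment,
                 kkt_residual = kkt, lambda = sol$lambda,
                 method = method),
            class = "muscle_solution")
}

#' Surrogate joint model for the coupling loop
#'
#' Joint stand-in exposing passive reaction moments and lever arms as
#' functions of the applied muscle forces. The default passive model is
#' linear, \code{passive(x) = P x}; the lever-arm hook perturbs the base
#' matrix as a function of the forces.
#'
#' @param prob base \code{\link{optimization_problem}} (its \code{targets}
#'   are the external joint moments M0).
#' @param passive_gain matrix P (DoF x muscles) of passive-resistance
#'   moments per unit muscle force, N.m/N; zero for a passive-free joint.
#' @param lever_update function(forces, R0) returning the updated lever-arm
#'   matrix; default returns R0 unchanged.
#' @return object of class \code{surrogate_joint}.
#' @export
surrogate_joint <- function(prob, passive_gain = NULL,
                            lever_update = function(x, R0) R0) {
  n_dof <- nrow(prob$lever_arms)
  n_mus <- ncol(prob$lever_arms)
  if (is.null(passive_gain)) passive_gain <- matrix(0, n_dof, n_mus)
  stopifnot(all(dim(passive_gain) == c(n_dof, n_mus)))
  structure(list(prob = prob, M0 = prob$targets,
                 passive = function(x) as.vector(passive_gain %*% x),
                 lever_update = lever_update),
            class = "surrogate_joint")
}

#' Iterative muscle-force / joint-moment coupling
#'
#' Fixed-point loop mirroring the kinematics-driven workflow: solve the
#' static optimisation, apply the muscle forces to the joint, recompute the
#' residual reaction moments (and lever arms) from the passive response,
#' update the targets and repeat. Convergence is declared when the residual
#' moment falls below \code{tol} (default 1 N.m).
#'
#' @param joint a \code{\link{surrogate_joint}}.
#' @param tol convergence tolerance on the residual moments, N.m.
#' @param max_iter iteration cap.
#' @param method,seed passed to \code{\link{solve_muscle_forces}}.
#' @return list with \code{solution} (final \code{muscle_solution}),
#'   \code{converged}, \code{iterations} and \code{trace} (residual norm
#'   per iteration).
#' @export
iterative_coupling <- function(joint, tol = 1, max_iter = 50,
                               method = "nlp", seed = 1L) {
  x <- rep(0, ncol(joint$prob$lever_arms))
  trace <- numeric(0)
  sol <- NULL
  for (k in seq_len(max_iter)) {
    M_req <- joint$M0 - joint$passive(x)
    R <- joint$lever_update(x, joint$prob$lever_arms)
    prob_k <- optimization_problem(R, M_req, joint$prob$pcsa,
                                   joint$prob$x_passive, joint$prob$x_max)
    sol <- solve_muscle_forces(prob_k, tol_moment = min(tol, 1),
                               method = method, seed = seed)
    x <- sol$forces
    resid <- max(abs(joint$M0 - joint$passive(x) - R %*% x))
    trace <- c(trace, resid)
    if (!is.finite(tol) || resid < tol)
      return(list(solution = sol, converged = TRUE, iterations = k,
                  trace = trace))
  }
  list(solution = sol, converged = FALSE, iterations = max_iter,
       trace = trace)
}
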