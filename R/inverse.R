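#' Forward pMC reflectance prediction
#'
#' Predicts spatially resolved reflectance `R(rho)` at candidate optical
#' properties by re-weighting a baseline photon database (perturbation
#' Monte Carlo). Used as the forward model of the inverse solver.
#'
#' @param db Baseline `mc_database` with collision info.
#' @param rho A [grid_spec()] for the reflectance bins.
#' @param region Tissue region whose properties vary.
#' @param mua,musp Candidate absorption and reduced scattering coefficients
#'   (1/mm); `musp` is converted to `mus` through the baseline anisotropy,
#'   `mus = musp / (1 - g)`.
#' @return A tibble with `rho` (bin centers), `reflectance` and `std_error`.
#' @export
forward_reflectance <- function(db, rho, region = 1, mua, musp) {
  stopifnot(inherits(db, "mc_database"))
  if (mua <= 0 || musp <= 0) abort("`mua` and `musp` must be positive")
  g <- region_ops(db$tissue, region)$g
  det <- detector_pmc_r_of_rho(
    rho, perturbation(region, mua = mua, mus = musp / (1 - g))
  )
  tal <- retally_one(db, det)
  tibble(rho = tal$axes$rho$centers, reflectance = as.vector(tal$mean),
         std_error = as.vector(tal$std_error))
}

#' dMC Jacobian of the reflectance prediction
#'
#' Differential Monte Carlo derivatives of `R(rho)` with respect to `mua`
#' and `musp` of one region, evaluated at candidate properties by chaining
#' the dMC scores with the pMC multiplier. The `musp` column applies the
#' chain rule `d/dmusp = (1 / (1 - g)) d/dmus`.
#'
#' @inheritParams forward_reflectance
#' @return A matrix with one row per rho bin and columns `mua`, `musp`.
#' @export
reflectance_jacobian <- function(db, rho, region = 1, mua, musp) {
  stopifnot(inherits(db, "mc_database"))
  if (nrow(db$exits) == 0) abort("the database holds no photons")
  g <- region_ops(db$tissue, region)$g
  pert <- perturbation(region, mua = mua, mus = musp / (1 - g))
  d_mua <- retally_one(db, detector_dmc_d_r_of_rho_d_mua(
    rho, region = region, perturbation = pert))
  d_mus <- retally_one(db, detector_dmc_d_r_of_rho_d_mus(
    rho, region = region, perturbation = pert))
  cbind(mua = as.vector(d_mua$mean),
        musp = as.vector(d_mus$mean) / (1 - g))
}

#' Recover optical properties from spatially resolved reflectance
#'
#' Damped Gauss-Newton (Levenberg-Marquardt) least-squares fit of `mua`
#' and/or `musp` of one tissue region to a measured `R(rho)`, using
#' perturbation Monte Carlo re-weighting of a baseline database as the
#' forward model and differential Monte Carlo tallies as the Jacobian.
#' Parameters are log-transformed, which keeps them positive and makes the
#' steps scale-free. Iteration stops when the relative parameter change
#' drops below `tol` or after `max_iter` iterations; accepted steps never
#' increase the objective. The fit is deterministic given the database and
#' the measurement.
#'
#' Residuals are inverse-variance weighted: `R(rho)` spans orders of
#' magnitude across the detection grid, and the absorption information
#' lives in the low-amplitude tail, so unweighted least squares would let
#' the near-source bins drown it. When the measurement carries no
#' `std_error` column, relative residuals (sigma proportional to the
#' measured value) are used.
#'
#' @param measurement A data frame with columns `rho` (bin centers of
#'   `rho_grid`) and `reflectance`, optionally `std_error`.
#' @param db Baseline `mc_database` with collision info.
#' @param rho_grid The [grid_spec()] the measurement was binned on.
#' @param init Named vector of starting values (subset of `mua`, `musp`);
#'   defaults to the baseline properties of `region`.
#' @param free Which parameters to fit.
#' @param region Tissue region whose properties are recovered.
#' @param truth Optional named vector of true values for error reporting.
#' @param max_iter,tol Iteration controls.
#' @return An `mc_fit`; see [tidy.mc_fit()] and [glance.mc_fit()].
#' @export
mc_inverse_fit <- function(measurement, db, rho_grid,
                           init = NULL, free = c("mua", "musp"),
                           region = 1, truth = NULL,
                           max_iter = 100, tol = 1e-6) {
  stopifnot(inherits(db, "mc_database"))
  free <- match.arg(free, c("mua", "musp"), several.ok = TRUE)
  measurement <- as_tibble(measurement)
  if (!all(c("rho", "reflectance") %in% names(measurement))) {
    abort("`measurement` needs columns rho and reflectance")
  }
  rho_grid <- as_grid(rho_grid, "rho_grid")
  if (nrow(measurement) != rho_grid$count ||
      max(abs(measurement$rho - rho_grid$centers)) > 1e-9) {
    abort("the measurement grid must match `rho_grid` bin centers")
  }
  base <- region_ops(db$tissue, region)
  start <- c(mua = base$mua, musp = base$mus * (1 - base$g))
  if (!is.null(init)) start[names(init)] <- init
  if (any(start[free] <= 0)) abort("initial parameters must be positive")

  y <- measurement$reflectance
  sigma <- if ("std_error" %in% names(measurement)) {
    measurement$std_error
  } else {
    abs(y)
  }
  if (any(sigma <= 0 | !is.finite(sigma))) {
    keep <- sigma > 0 & is.finite(sigma)
    sigma[!keep] <- min(sigma[keep])
  }
  pred_at <- function(p) {
    forward_reflectance(db, rho_grid, region, p[["mua"]],
                        p[["musp"]])$reflectance
  }
  chi2 <- function(r) sum(r^2)

  p <- start
  theta <- log(p[free])
  r <- (pred_at(p) - y) / sigma
  c2 <- chi2(r)
  c2_init <- c2
  lambda <- 1e-3
  history <- list(tibble(iteration = 0L, chi2 = c2,
                         !!!as.list(p[free])))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter && !converged) {
    iter <- iter + 1L
    J_all <- reflectance_jacobian(db, rho_grid, region, p[["mua"]],
                                  p[["musp"]])
    # chain rule to log-parameters: dR/dtheta_j = p_j * dR/dp_j
    J <- sweep(J_all[, free, drop = FALSE] / sigma, 2, p[free], `*`)
    g <- crossprod(J, r)
    H <- crossprod(J)
    accepted <- FALSE
    for (try in 1:25) {
      Hd <- H + lambda * diag(diag(H), nrow = nrow(H))
      step <- tryCatch(solve(Hd, -g), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) {
        lambda <- lambda * 10
        next
      }
      theta_new <- theta + as.vector(step)
      p_new <- p
      p_new[free] <- exp(theta_new)
      r_new <- (pred_at(p_new) - y) / sigma
      c2_new <- chi2(r_new)
      if (!is.finite(c2_new)) {
        abort("non-finite objective during the fit")
      }
      if (c2_new <= c2) {
        rel <- max(abs(exp(step) - 1))
        theta <- theta_new
        p <- p_new
        r <- r_new
        c2 <- c2_new
        lambda <- max(lambda / 10, 1e-12)
        accepted <- TRUE
        if (rel < tol) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    history[[length(history) + 1]] <- tibble(iteration = iter, chi2 = c2,
                                             !!!as.list(p[free]))
    if (!accepted) {
      converged <- TRUE  # no downhill step left at any damping
    }
  }

  structure(
    list(
      par = p[free],
      init = start[free],
      truth = truth,
      region = region,
      free = free,
      chi2_init = c2_init,
      chi2 = c2,
      iterations = iter,
      converged = converged,
      history = bind_rows(history),
      measurement = measurement,
      prediction = pred_at(p)
    ),
    class = "mc_fit"
  )
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<inverse fit> %d iteration(s), chi2 %.4g -> %.4g\n",
              x$iterations, x$chi2_init, x$chi2))
  print(tidy(x))
  invisible(x)
}
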